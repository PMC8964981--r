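# Planted frequency-correlation structures for the synthetic cohorts.
#
# Both presets are factor models (R = L L' + diag(uniquenesses)), so they are
# positive semidefinite by construction and need no post-hoc projection.

#' Check a frequency-correlation matrix
#'
#' Symmetric, unit diagonal, eigenvalues >= -1e-8.
#'
#' @param R Square numeric matrix.
#' @return `R`, invisibly, or an error with a diagnostic.
#' @export
check_correlation_matrix <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    abort("frequency correlation must be a square matrix")
  }
  if (max(abs(R - t(R))) > 1e-10) {
    abort("frequency correlation must be symmetric")
  }
  if (max(abs(diag(R) - 1)) > 1e-10) {
    abort("frequency correlation must have unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf(
      "frequency correlation is not positive semidefinite (min eigenvalue %.3e)",
      min(ev)
    ))
  }
  invisible(R)
}

# Square root of a PSD correlation matrix via eigendecomposition, tolerating
# tiny negative eigenvalues.
corr_sqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R))
}

#' Modular ("healthy-like") planted correlation structure
#'
#' Lineage blocks share a strong within-block correlation (a small fraction
#' of which rides on one global factor); designated bridge subsets load on
#' their own block's factor and on one neighboring block's factor, so
#' consecutive lineage modules are connected through single bridge nodes.
#' The resulting network (at a 0.6 threshold) is a chain of dense lineage
#' modules: high modularity, and high betweenness centralization because
#' inter-module shortest paths funnel through the bridges.
#'
#' All structures are factor models, so one node cannot (and does not)
#' correlate strongly with many mutually uncorrelated blocks — bridge
#' loadings are capped at `1/sqrt(2)` of the unit variance budget.
#'
#' @param lineage Named character vector: subset id -> lineage label.
#' @param within Within-lineage correlation (default 0.8).
#' @param global_share Fraction of the block-factor variance carried by the
#'   global factor (default 0.3). The global component is largely cancelled
#'   by simplex closure, but sharing it reduces block-specific mass
#'   fluctuations and hence spurious closure-induced negative correlations
#'   between blocks.
#' @param bridges Named character vector: bridge subset id -> the *other*
#'   lineage it bridges to (its own lineage is taken from `lineage`).
#' @param bridge_loading Loading of a bridge subset on each of its two block
#'   factors (default 0.7; must satisfy `2 * bridge_loading^2 <= 1`).
#' @return Correlation matrix with one row/column per subset.
#' @export
modular_correlation <- function(lineage, within = 0.8, global_share = 0.2,
                                bridges = NULL, bridge_loading = 0.6) {
  if (2 * bridge_loading^2 + within * global_share > 1) {
    abort("bridge_loading too large: 2*bridge_loading^2 + within*global_share must be <= 1")
  }
  K <- length(lineage)
  blocks <- unique(lineage)
  # columns: global factor, then one factor per lineage block
  L <- matrix(0, K, 1 + length(blocks))
  for (i in seq_len(K)) {
    b <- match(lineage[i], blocks)
    L[i, 1] <- sqrt(within * global_share)
    L[i, 1 + b] <- sqrt(within * (1 - global_share))
  }
  # bridges keep the global loading: without it, simplex closure would
  # anti-correlate them with every global-factor-driven subset
  for (nm in names(bridges)) {
    i <- match(nm, names(lineage))
    if (is.na(i)) abort(sprintf("bridge subset '%s' not found", nm))
    own <- match(lineage[i], blocks)
    other <- match(bridges[[nm]], blocks)
    if (is.na(other)) abort(sprintf("bridge target lineage '%s' not found",
                                    bridges[[nm]]))
    L[i, ] <- 0
    L[i, 1] <- sqrt(within * global_share)
    L[i, 1 + own] <- bridge_loading
    L[i, 1 + other] <- bridge_loading
  }
  R <- L %*% t(L)
  diag(R) <- 1
  dimnames(R) <- list(names(lineage), names(lineage))
  check_correlation_matrix(R)
  R
}

#' Default bridge chain for the modular preset
#'
#' Chains the lineage blocks of a subset table in their order of appearance:
#' for each consecutive lineage pair, the first subset of the earlier
#' lineage becomes the bridge to the later lineage.
#'
#' @param subsets A `subset_spec` tibble.
#' @return Named character vector: bridge subset id -> bridged-to lineage.
#' @export
default_bridges <- function(subsets) {
  blocks <- unique(subsets$lineage)
  if (length(blocks) < 2) return(NULL)
  bridge_node <- map_chr(blocks[-length(blocks)], function(b) {
    subsets$subset_id[subsets$lineage == b][1]
  })
  setNames(blocks[-1], bridge_node)
}

#' Dispersed ("disease-like") planted correlation structure
#'
#' One strong "inflammatory axis" factor cuts across lineages: subsets in
#' `axis_pos` load positively, subsets in `axis_neg` negatively (planting
#' negative correlations between expanding and contracting subsets), while
#' the remaining subsets keep only a weak lineage-block structure. At a 0.6
#' threshold the axis produces one dense cross-lineage blob with a sizable
#' share of negative edges and mostly inter-lineage contacts: low
#' modularity, low centralization, more negative edges than the modular
#' structure.
#'
#' @param lineage Named character vector: subset id -> lineage label.
#' @param axis_pos,axis_neg Names (or indices) of subsets loading
#'   positively / negatively on the axis factor.
#' @param axis_loading Absolute axis loading (default 0.8, i.e. planted
#'   `|r| = 0.64` within and across the axis groups).
#' @param within Residual within-lineage correlation of non-axis subsets
#'   (default 0.5 — mostly below the edge threshold once sampled).
#' @param global_share As in [modular_correlation()] (default 0.3).
#' @return Correlation matrix with one row/column per subset.
#' @export
dispersed_correlation <- function(lineage, axis_pos = integer(),
                                  axis_neg = integer(),
                                  axis_loading = 0.8, within = 0.5,
                                  global_share = 0.3) {
  K <- length(lineage)
  if (is.character(axis_pos)) axis_pos <- match(axis_pos, names(lineage))
  if (is.character(axis_neg)) axis_neg <- match(axis_neg, names(lineage))
  blocks <- unique(lineage)
  # columns: axis factor, global factor, one factor per lineage block
  L <- matrix(0, K, 2 + length(blocks))
  for (i in seq_len(K)) {
    b <- match(lineage[i], blocks)
    L[i, 2] <- sqrt(within * global_share)
    L[i, 2 + b] <- sqrt(within * (1 - global_share))
  }
  for (i in axis_pos) {
    L[i, ] <- 0
    L[i, 1] <- axis_loading
  }
  for (i in axis_neg) {
    L[i, ] <- 0
    L[i, 1] <- -axis_loading
  }
  R <- L %*% t(L)
  diag(R) <- 1
  dimnames(R) <- list(names(lineage), names(lineage))
  check_correlation_matrix(R)
  R
}
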