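# Synthetic two-panel CyTOF cohort generator with known ground truth.
#
# Subject-level subset frequencies follow a Gaussian copula on the logit
# scale (closed to the simplex per panel); cells are Gaussian mixtures in
# arcsinh space, mapped to the raw dual-count scale by the inverse transform
# x = cofactor * sinh(y) and clipped at 0. Batch effects are additive shifts
# in transformed space, which per-batch scale normalization removes exactly.

#' Cohort simulation specification
#'
#' @param panels Named list of [panel_spec()] objects.
#' @param subsets A [subset_spec()] tibble covering the panels.
#' @param n_subjects Named integer vector of subjects per cohort. The default
#'   mirrors a heart-failure case-control design: 18 healthy controls and 32
#'   heart-failure patients split into 14 preserved-EF, 14 reduced-EF and 4
#'   mid-range-EF subjects.
#' @param n_cells_per_sample Cells acquired per subject per panel
#'   (default 20000).
#' @param n_batches Number of acquisition batches; subjects are allocated
#'   round-robin unless `batch_of` is supplied.
#' @param batch_of Optional named vector mapping subject ids to batch labels.
#' @param batch_sd Standard deviation of the per-batch per-marker additive
#'   shifts in transformed space (default 0.25).
#' @param sigma_logit Subject-to-subject dispersion of subset frequencies on
#'   the logit scale (default 0.5).
#' @param frequency_correlation Planted between-subset frequency correlation:
#'   a single matrix used for all cohorts, or a named list keyed by cohort
#'   (entries for `"HC"` / `"HF"` cover their subtypes). Default: a modular
#'   structure for HC ([modular_correlation()], hubs = the resting NK subset
#'   of each panel) and a dispersed structure with negatively-loading
#'   inflammatory subsets for HF ([dispersed_correlation()]).
#' @param cofactor Arcsinh cofactor of the emulated instrument scale
#'   (default 5).
#' @param seed Default RNG seed for [simulate_cohort()].
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(panels = default_panels(),
                            subsets = default_subsets(panels),
                            n_subjects = c(HC = 18, HFpEF = 14, HFrEF = 14,
                                           HFmrEF = 4),
                            n_cells_per_sample = 20000,
                            n_batches = 3,
                            batch_of = NULL,
                            batch_sd = 0.25,
                            sigma_logit = 0.5,
                            frequency_correlation = NULL,
                            cofactor = 5,
                            seed = 1L) {
  if (is.null(frequency_correlation)) {
    lin <- setNames(subsets$lineage, subsets$subset_id)
    frequency_correlation <- list(
      HC = modular_correlation(lin, bridges = default_bridges(subsets)),
      HF = dispersed_correlation(
        lin,
        axis_pos = intersect(c("NK_cyto", "NK_infl", "CD8_eff", "CD8_lag",
                               "B_naive", "B_trans", "cDC", "NK_p2b"),
                             subsets$subset_id),
        axis_neg = intersect(c("CD4_em", "CD8_em", "mono_cl"),
                             subsets$subset_id))
    )
  }
  fc <- frequency_correlation
  if (is.matrix(fc)) check_correlation_matrix(fc) else lapply(fc, check_correlation_matrix)
  structure(
    list(panels = panels, subsets = subsets, n_subjects = n_subjects,
         n_cells_per_sample = n_cells_per_sample, n_batches = n_batches,
         batch_of = batch_of, batch_sd = batch_sd,
         sigma_logit = sigma_logit,
         frequency_correlation = frequency_correlation,
         cofactor = cofactor, seed = seed),
    class = "cohort_sim_spec"
  )
}

# Map a cohort label (possibly an HF subtype) to its case/control group.
case_group <- function(cohort) {
  ifelse(cohort == "HC", "HC", "HF")
}

# Planted correlation matrix for a cohort label.
cohort_correlation <- function(spec, cohort) {
  fc <- spec$frequency_correlation
  if (is.matrix(fc)) return(fc)
  fc[[cohort]] %||% fc[[case_group(cohort)]] %||%
    diag(nrow(spec$subsets))
}

# Total logit-scale shift for a cohort: the case-group shift plus any
# subtype-specific shift (e.g. HFpEF = HF shift + HFpEF shift).
cohort_shift <- function(subsets, cohort) {
  pick <- function(v, nm) if (!is.null(v) && nm %in% names(v)) v[[nm]] else 0
  map_dbl(subsets$cohort_lfc, function(lfc) {
    lfc <- unlist(lfc)
    grp <- case_group(cohort)
    s <- pick(lfc, cohort)
    if (grp != cohort) s <- s + pick(lfc, grp)
    s
  })
}

#' Sample subject-level subset proportions via a Gaussian copula
#'
#' Draws correlated Gaussian scores with the cohort's planted correlation,
#' shifts them onto logit(base proportion) plus the cohort's log-fold-change,
#' maps through the logistic function and closes to the simplex within each
#' panel, so every subject's proportions over one panel's subsets sum to 1.
#'
#' @param spec A [cohort_sim_spec()].
#' @param cohort Cohort label (used for the planted correlation and shifts).
#' @param n_subjects Number of subjects to draw.
#' @param seed RNG seed.
#' @return Tibble with `subject_id`, `cohort`, and one proportion column per
#'   subset (zero rows when `n_subjects = 0`).
#' @export
sample_subject_proportions <- function(spec, cohort,
                                       n_subjects = spec$n_subjects[[cohort]],
                                       seed = spec$seed) {
  subs <- spec$subsets
  K <- nrow(subs)
  R <- cohort_correlation(spec, cohort)
  check_correlation_matrix(R)
  if (nrow(R) != K) abort("frequency correlation dimension != number of subsets")
  if (n_subjects == 0) {
    out <- tibble(subject_id = character(), cohort = character())
    out[subs$subset_id] <- list(numeric())
    return(out)
  }
  set.seed(seed)
  Z <- matrix(rnorm(n_subjects * K), n_subjects, K) %*% t(corr_sqrt(R))
  eta <- sweep(spec$sigma_logit * Z, 2,
               qlogis(subs$base_proportion) + cohort_shift(subs, cohort), "+")
  W <- plogis(eta)
  for (p in unique(subs$panel)) {
    idx <- which(subs$panel == p)
    W[, idx] <- W[, idx, drop = FALSE] / rowSums(W[, idx, drop = FALSE])
  }
  colnames(W) <- subs$subset_id
  bind_cols(
    tibble(subject_id = sprintf("%s_%02d", cohort, seq_len(n_subjects)),
           cohort = rep(cohort, n_subjects)),
    as_tibble(W)
  )
}

#' Synthesize raw-scale cells for one panel
#'
#' Cell counts per subset are multinomial in the subject's true proportions;
#' marker values are Gaussian around the subset's mean profile in arcsinh
#' space (plus the subject's batch shift), then mapped to the raw scale by
#' `cofactor * sinh(y)` and clipped at 0.
#'
#' @param proportions Tibble from [sample_subject_proportions()] (or any
#'   tibble with `subject_id` plus one column per subset of this panel).
#' @param subsets Subset table restricted to `panel` (rows with other panels
#'   are dropped automatically).
#' @param panel A [panel_spec()].
#' @param n_cells Cells per subject.
#' @param batch_shifts Optional matrix (batches x markers) of additive
#'   transformed-space shifts; row names are batch labels.
#' @param batch Named vector mapping subject ids to batch labels (default:
#'   single batch "b1").
#' @param cofactor Arcsinh cofactor (default 5).
#' @param seed RNG seed.
#' @return Cell tibble (one row per cell) with metadata columns
#'   `subject_id`, `cohort`, `batch`, `panel`, `cell_id`, `true_subset` and
#'   one raw-intensity column per marker.
#' @export
synthesize_cells <- function(proportions, subsets, panel, n_cells,
                             batch_shifts = NULL, batch = NULL,
                             cofactor = 5, seed = 1L) {
  if (n_cells <= 0) abort("n_cells must be positive")
  subs <- subsets[subsets$panel == panel$panel_id, ]
  markers <- panel$marker_names
  ids <- proportions$subject_id
  if (is.null(batch)) batch <- setNames(rep("b1", length(ids)), ids)
  P <- as.matrix(proportions[, subs$subset_id, drop = FALSE])
  if (max(abs(rowSums(P) - 1)) > 1e-6) {
    abort("each subject's subset proportions must sum to 1")
  }
  set.seed(seed)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    counts <- as.vector(rmultinom(1, n_cells, P[i, ]))
    lab <- rep(subs$subset_id, counts)
    Y <- matrix(0, n_cells, length(markers), dimnames = list(NULL, markers))
    at <- 1
    for (j in seq_len(nrow(subs))) {
      if (counts[j] == 0) next
      mu <- subs$mean_profile[[j]][markers]
      sdv <- subs$dispersion[[j]][markers]
      block <- matrix(rnorm(counts[j] * length(markers)), counts[j]) *
        rep(sdv, each = counts[j]) + rep(mu, each = counts[j])
      Y[at:(at + counts[j] - 1), ] <- block
      at <- at + counts[j]
    }
    b <- batch[[ids[i]]]
    if (!is.null(batch_shifts)) {
      Y <- Y + rep(batch_shifts[b, markers], each = n_cells)
    }
    raw <- pmax(cofactor * sinh(Y), 0)
    meta <- proportions[i, intersect(c("subject_id", "cohort"), names(proportions))]
    out[[i]] <- bind_cols(
      tibble(subject_id = rep(ids[i], n_cells),
             cohort = rep(meta$cohort %||% NA_character_, n_cells),
             batch = rep(b, n_cells),
             panel = rep(panel$panel_id, n_cells),
             cell_id = seq_len(n_cells),
             true_subset = lab),
      as_tibble(raw)
    )
  }
  list_rbind(out)
}

#' Simulate a full two-panel cohort with ground truth
#'
#' Runs the copula proportion sampler per cohort, allocates subjects to
#' batches, draws per-batch marker shifts, and synthesizes raw-scale cells
#' for every subject on every panel.
#'
#' @param spec A [cohort_sim_spec()].
#' @param seed RNG seed (default `spec$seed`); all stage seeds derive from it.
#' @return A `cytof_sim` list: `cells` (named list of cell tibbles, one per
#'   panel), `sample_sheet` (subject_id, cohort, subtype, batch), and `truth`
#'   (`proportions` wide tibble, `correlations` per cohort, `subsets`,
#'   `batch_shifts` per panel).
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  cohorts <- names(spec$n_subjects)
  props <- imap(cohorts, function(co, i) {
    sample_subject_proportions(spec, co, spec$n_subjects[[co]],
                               seed = seed + 101L * i)
  }) |> list_rbind()
  sheet <- tibble(
    subject_id = props$subject_id,
    cohort = case_group(props$cohort),
    subtype = ifelse(props$cohort == "HC", NA_character_, props$cohort)
  )
  if (is.null(spec$batch_of)) {
    sheet$batch <- sprintf("b%d", rep_len(seq_len(spec$n_batches), nrow(sheet)))
  } else {
    sheet$batch <- unname(spec$batch_of[sheet$subject_id])
  }
  batch_lab <- setNames(sheet$batch, sheet$subject_id)
  set.seed(seed + 17L)
  shifts <- map(spec$panels, function(pn) {
    m <- matrix(rnorm(spec$n_batches * length(pn$marker_names), 0, spec$batch_sd),
                spec$n_batches,
                dimnames = list(sprintf("b%d", seq_len(spec$n_batches)),
                                pn$marker_names))
    m
  })
  cells <- imap(spec$panels, function(pn, nm) {
    synthesize_cells(props, spec$subsets, pn,
                     n_cells = spec$n_cells_per_sample,
                     batch_shifts = shifts[[nm]], batch = batch_lab,
                     cofactor = spec$cofactor,
                     seed = seed + 1000L + match(nm, names(spec$panels)))
  })
  cells <- map(cells, function(tb) {
    tb$cohort <- case_group(tb$cohort)
    tb
  })
  structure(
    list(cells = cells, sample_sheet = sheet,
         truth = list(
           proportions = props,
           correlations = setNames(
             map(cohorts, ~ cohort_correlation(spec, .x)), cohorts),
           subsets = spec$subsets,
           batch_shifts = shifts)),
    class = "cytof_sim"
  )
}

#' @export
print.cytof_sim <- function(x, ...) {
  cat("Synthetic CyTOF cohort:",
      nrow(x$sample_sheet), "subjects,",
      length(x$cells), "panels,",
      format(sum(map_dbl(x$cells, nrow)), big.mark = ","), "cells\n")
  print(count(x$sample_sheet, .data$cohort, .data$subtype))
  invisible(x)
}
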