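# Subject x node frequency matrices and differential abundance testing
# (two-sided Wilcoxon rank-sum, exact by enumeration for small untied
# groups, normal approximation with tie and continuity corrections
# otherwise).

#' Subject-level node frequency matrix
#'
#' Entry (subject, node) is the fraction of the subject's retained cells (in
#' that panel) assigned to the node; nodes with no cells for a subject get
#' 0, so each subject's frequencies over one panel's nodes sum to 1.
#'
#' @param assignments Tibble `subject_id`, `panel`, `node_id` (e.g.
#'   `model$assignments`), one row per cell.
#' @param sample_sheet Tibble `subject_id`, `cohort`, and optionally
#'   `subtype`, `batch`; joined onto the result.
#' @param nodes Optional node metadata tibble (`node_id`, `lineage`, ...) to
#'   join; also guarantees zero-frequency rows for nodes absent from
#'   `assignments`.
#' @return Long tibble: sample-sheet columns, `panel`, `node_id`,
#'   (`lineage`,) `freq`.
#' @export
frequency_matrix <- function(assignments, sample_sheet, nodes = NULL) {
  if (nrow(assignments) == 0) abort("no cell assignments given")
  node_panel <- if (!is.null(nodes) && "panel" %in% names(nodes)) {
    distinct(nodes, .data$node_id, .data$panel)
  } else {
    distinct(assignments, .data$node_id, .data$panel)
  }
  grid <- inner_join(distinct(assignments, .data$subject_id, .data$panel),
                     node_panel, by = "panel",
                     relationship = "many-to-many")
  out <- assignments |>
    count(.data$subject_id, .data$panel, .data$node_id) |>
    right_join(grid, by = c("subject_id", "panel", "node_id")) |>
    mutate(n = coalesce(.data$n, 0L)) |>
    group_by(.data$subject_id, .data$panel) |>
    mutate(freq = .data$n / sum(.data$n)) |>
    ungroup() |>
    select(-"n") |>
    arrange(.data$subject_id, .data$panel, .data$node_id)
  out <- inner_join(sample_sheet, out, by = "subject_id")
  if (!is.null(nodes) && "lineage" %in% names(nodes)) {
    out <- left_join(out, select(nodes, "node_id", "lineage"),
                     by = "node_id")
  }
  out
}

# Exact two-sided Mann-Whitney p by complete enumeration over which of the
# pooled values are assigned to group x (requires no ties for exactness).
rank_sum_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(n + m, n)
  u_all <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
  centre <- n * m / 2
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-12)
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Mann-Whitney U statistic for group `x`. In `"auto"` mode the p-value is
#' exact (complete enumeration of rank assignments) when
#' `min(length(x), length(y)) <= 8` and there are no ties, otherwise a
#' normal approximation with midranks, tie-corrected variance and
#' continuity correction is used.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return One-row tibble: `statistic` (U of `x`), `p_value`, `method`,
#'   `n_x`, `n_y`.
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = min(n, m) <= 8 && !ties
  )
  if (use_exact && ties) {
    abort("exact mode requires untied data; use mode = 'approx'")
  }
  if (use_exact) {
    p <- rank_sum_exact_p(x, y)
    method <- "exact"
  } else {
    N <- n + m
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (12 * N * (N - 1))
    v <- n * m * (N + 1) / 12 - n * m * tie_term
    centre <- n * m / 2
    if (v <= 0) {
      p <- 1
    } else {
      z <- (abs(u - centre) - 0.5) / sqrt(v)
      z <- max(z, 0)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal approximation"
  }
  tibble(statistic = u, p_value = p, method = method, n_x = n, n_y = m)
}

#' Differentially abundant nodes between two groups
#'
#' Runs the rank-sum test per node on subject frequencies. Direction is
#' called from the median difference: `"expanded"` / `"reduced"` in the case
#' group (the second label of `groups`). No multiple-testing correction is
#' applied by default, mirroring the raw `p < 0.05` convention of the
#' analysis this package reproduces; Benjamini-Hochberg is available via
#' `adjust = "BH"` and the significance flag then uses the adjusted values.
#'
#' @param freq Long frequency tibble from [frequency_matrix()].
#' @param groups Length-2 character vector `c(control, case)` of labels in
#'   `group_var`.
#' @param group_var Grouping column (default `"cohort"`; use `"subtype"` for
#'   the HFpEF vs HFrEF contrast).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param mode Passed to [rank_sum_test()].
#' @return Tibble per node: `node_id`, (`panel`, `lineage`,)
#'   `median_control`, `median_case`, `statistic`, `p_value`, `p_adjusted`,
#'   `direction`, `significant`.
#' @export
differential_nodes <- function(freq, groups = c("HC", "HF"),
                               group_var = "cohort", alpha = 0.05,
                               adjust = c("none", "BH"),
                               mode = "auto") {
  adjust <- match.arg(adjust)
  g <- freq[[group_var]]
  if (!all(groups %in% g)) {
    abort(sprintf("grouping label(s) not present in '%s': %s", group_var,
                  paste(setdiff(groups, g), collapse = ", ")))
  }
  sub <- freq[g %in% groups, ]
  n_by_grp <- sub |> distinct(.data$subject_id, grp = .data[[group_var]]) |>
    count(.data$grp)
  if (any(n_by_grp$n < 2)) abort("both groups need at least 2 subjects")
  meta_cols <- intersect(c("panel", "lineage"), names(sub))
  out <- sub |>
    group_by(.data$node_id) |>
    group_modify(function(d, key) {
      xa <- d$freq[d[[group_var]] == groups[1]]
      xb <- d$freq[d[[group_var]] == groups[2]]
      tt <- rank_sum_test(xa, xb, mode = mode)
      md <- median(xb) - median(xa)
      bind_cols(
        d[1, meta_cols, drop = FALSE],
        tibble(median_control = median(xa), median_case = median(xb),
               statistic = tt$statistic, p_value = tt$p_value,
               direction = if (md > 0) "expanded"
                           else if (md < 0) "reduced" else "unchanged")
      )
    }) |>
    ungroup()
  out$p_adjusted <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- out$p_adjusted < alpha
  out
}
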