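# Small fixture builders used across test files (built in code at test time).

tiny_panel <- function(markers = c("CD3", "CD4", "CD8", "CD56"),
                       id = "P1") {
  panel_spec(id, markers, markers[1:2])
}

# subset table on one tiny panel; `pos` lists the positive markers per subset
tiny_subsets <- function(panel = tiny_panel(),
                         ids = c("a", "b"),
                         lineages = c("CD4T", "NK"),
                         pos = list(c("CD3", "CD4"), "CD56"),
                         base = c(0.5, 0.5),
                         lfc = NULL,
                         dispersion = 0.3) {
  k <- length(ids)
  subset_spec(
    subset_id = ids, panel = panel$panel_id, lineage = lineages,
    mean_profile = lapply(pos, function(p)
      subset_profile(panel$marker_names, p)),
    dispersion = rep(list(setNames(rep(dispersion,
                                       length(panel$marker_names)),
                                   panel$marker_names)), k),
    base_proportion = base,
    cohort_lfc = lfc %||% rep(list(c()), k)
  )
}

tiny_spec <- function(..., n_subjects = c(HC = 4, HFpEF = 2, HFrEF = 2),
                      n_cells = 200, n_batches = 2, seed = 1L,
                      frequency_correlation = NULL) {
  subsets <- tiny_subsets(...)
  panel <- tiny_panel()
  cohort_sim_spec(panels = list(P1 = panel), subsets = subsets,
                  n_subjects = n_subjects, n_cells_per_sample = n_cells,
                  n_batches = n_batches, seed = seed,
                  frequency_correlation = frequency_correlation %||%
                    diag(nrow(subsets)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# K independent-ish subsets on one panel with a planted correlation matrix
copula_spec <- function(K, R, base = rep(1 / K, K), sigma_logit = 0.5) {
  panel <- tiny_panel()
  subsets <- subset_spec(
    subset_id = sprintf("s%02d", seq_len(K)),
    panel = "P1",
    lineage = rep("NK", K),
    mean_profile = rep(list(subset_profile(panel$marker_names, "CD56")), K),
    dispersion = rep(list(setNames(rep(0.3, 4), panel$marker_names)), K),
    base_proportion = base,
    cohort_lfc = rep(list(c()), K)
  )
  cohort_sim_spec(panels = list(P1 = panel), subsets = subsets,
                  n_subjects = c(HC = 10), sigma_logit = sigma_logit,
                  frequency_correlation = R)
}
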