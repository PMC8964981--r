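blob_cells <- function(centers, n_each = 100, sd = 0.2, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_each * ncol(centers), mean = rep(centers[i, ],
                                                    each = n_each),
                 sd = sd), n_each)
  }))
  colnames(X) <- paste0("M", seq_len(ncol(centers)))
  dplyr::bind_cols(
    tibble::tibble(subject_id = "s1", cohort = "HC", batch = "b1",
                   panel = "P1", cell_id = seq_len(nrow(X)),
                   true_subset = rep(sprintf("c%d", seq_len(nrow(centers))),
                                     each = n_each)),
    tibble::as_tibble(X)
  )
}

test_that("k-means recovers well-separated blobs and is seed-deterministic", {
  centers <- rbind(c(0, 0), c(6, 6))
  cells <- blob_cells(centers, n_each = 150)
  m <- kmeans_cluster(cells, k = 2, seed = 4)
  agree <- table(cells$true_subset, m$assignments$node_id)
  # perfect partition up to relabeling
  expect_equal(unname(sort(apply(agree, 1, max))), c(150, 150))
  m2 <- kmeans_cluster(cells, k = 2, seed = 4)
  expect_identical(m$assignments, m2$assignments)
  expect_error(kmeans_cluster(cells, k = 1000), "between 1")
})

test_that("k = 1 yields a single node with WCSS equal to total scatter", {
  cells <- blob_cells(rbind(c(0, 0), c(3, 3)), n_each = 50)
  m <- kmeans_cluster(cells, k = 1, seed = 1)
  X <- cell_matrix(cells)
  expect_equal(m$tot_withinss,
               sum(sweep(X, 2, colMeans(X))^2))
  expect_equal(unique(m$assignments$node_id), "P1_N01")
})

test_that("elbow criterion finds a sharp knee and warns on flat curves", {
  # synthetic piecewise-linear WCSS with a knee at k = 4
  k_grid <- 2:10
  wcss <- ifelse(k_grid <= 4, 1000 - 200 * k_grid, 200 - 5 * k_grid)
  sel <- cytofnet:::elbow_point(k_grid, wcss)
  expect_equal(sel$k, 4)
  expect_warning(flat <- cytofnet:::elbow_point(2:6, seq(100, 60, by = -10)),
                 "flat")
  expect_equal(flat$k, 3)  # smallest interior k
})

test_that("elbow selection recovers a planted 5-subset structure within 1", {
  centers <- matrix(c(0, 0, 0, 6, 0, 0, 0, 6, 0, 0, 0, 6, 4, 4, 4),
                    ncol = 3, byrow = TRUE)
  cells <- blob_cells(centers, n_each = 120, sd = 0.3, seed = 2)
  sel <- elbow_select_k(cells, k_grid = 2:12, seed = 3)
  expect_true(abs(sel$k - 5) <= 1)
  # WCSS non-increasing across the restart-optimized grid
  expect_true(all(diff(sel$curve$wcss) <= 1e-6 * sel$curve$wcss[1]))
  expect_error(elbow_select_k(cells, k_grid = c(2, 3)), "at least 3")
})

test_that("node phenotypes match brute-force medians and scale correctly", {
  cells <- blob_cells(rbind(c(0, 1), c(2, 3), c(5, 4)), n_each = 40,
                      seed = 5)
  m <- kmeans_cluster(cells, k = 3, seed = 6)
  phen <- node_phenotype(m, cells)
  # brute-force per-node medians
  for (nd in m$node_ids) {
    idx <- m$assignments$node_id == nd
    for (mk in m$markers) {
      expect_equal(phen$median[phen$node_id == nd & phen$marker == mk],
                   median(cells[[mk]][idx]))
    }
  }
  # scaled medians: mean 0, sd 1 per marker across nodes
  by_marker <- split(phen$scaled_median, phen$marker)
  for (v in by_marker) {
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
})

test_that("node of identical cells has the cell profile as its median", {
  X <- matrix(rep(c(1, 2), each = 30), ncol = 2,
              dimnames = list(NULL, c("M1", "M2")))
  cells <- dplyr::bind_cols(
    tibble::tibble(subject_id = "s", cohort = "HC", batch = "b",
                   panel = "P1", cell_id = 1:30), tibble::as_tibble(X))
  m <- kmeans_cluster(cells, k = 1, seed = 1)
  phen <- node_phenotype(m, cells)
  expect_equal(phen$median[phen$marker == "M1"], 1)
  expect_equal(phen$median[phen$marker == "M2"], 2)
})

test_that("lineage gating follows the ordered rule table", {
  mk_phen <- function(vals) {
    tibble::tibble(node_id = "n1", n_cells = 10,
                   marker = names(vals), median = unname(vals),
                   scaled_median = unname(vals))
  }
  gates <- default_gating_table(c("CD3", "CD4", "CD8", "CD56", "CD19",
                                  "CD14", "CD16", "CD11c"))
  # CD3+CD4+CD8- -> CD4T
  lab <- annotate_lineage(mk_phen(c(CD3 = 1, CD4 = 1, CD8 = -1, CD56 = -1,
                                    CD19 = -1, CD14 = -1, CD16 = -1,
                                    CD11c = -1)), gates)
  expect_equal(lab$lineage, "CD4T")
  # CD3-CD56+ -> NK
  lab <- annotate_lineage(mk_phen(c(CD3 = -1, CD4 = -1, CD8 = -1, CD56 = 1,
                                    CD19 = -1, CD14 = -1, CD16 = -1,
                                    CD11c = -1)), gates)
  expect_equal(lab$lineage, "NK")
  # all negative -> other (fall-through)
  lab <- annotate_lineage(mk_phen(setNames(rep(-1, 8),
                                           c("CD3", "CD4", "CD8", "CD56",
                                             "CD19", "CD14", "CD16",
                                             "CD11c"))), gates)
  expect_equal(lab$lineage, "other")
  # CD3-CD19- with CD14+ -> MonoDC via the any-of clause
  lab <- annotate_lineage(mk_phen(c(CD3 = -1, CD4 = -1, CD8 = -1, CD56 = -1,
                                    CD19 = -1, CD14 = 1, CD16 = -1,
                                    CD11c = -1)), gates)
  expect_equal(lab$lineage, "MonoDC")
  # gate referencing an absent marker errors
  expect_error(
    annotate_lineage(mk_phen(c(CD3 = 1)), default_gating_table()),
    "absent")
  # annotation is a pure function: repeated calls agree
  phen <- mk_phen(c(CD3 = 1, CD4 = 1, CD8 = -1, CD56 = -1, CD19 = -1,
                    CD14 = -1, CD16 = -1, CD11c = -1))
  expect_identical(annotate_lineage(phen, gates),
                   annotate_lineage(phen, gates))
})

test_that("full-panel fit labels planted subsets with their lineages", {
  # five lineually distinct subsets: with several nodes the across-node
  # scaled medians separate positive from negative markers cleanly
  panel <- panel_spec("P1", c("CD3", "CD4", "CD8", "CD56", "CD19", "CD14"),
                      character())
  subsets <- subset_spec(
    subset_id = sprintf("s%d", 1:5), panel = "P1",
    lineage = c("CD4T", "CD8T", "NK", "B", "MonoDC"),
    mean_profile = list(
      subset_profile(panel$marker_names, c("CD3", "CD4")),
      subset_profile(panel$marker_names, c("CD3", "CD8")),
      subset_profile(panel$marker_names, "CD56"),
      subset_profile(panel$marker_names, "CD19"),
      subset_profile(panel$marker_names, "CD14")),
    dispersion = rep(list(setNames(rep(0.35, 6), panel$marker_names)), 5),
    base_proportion = rep(0.2, 5),
    cohort_lfc = rep(list(c()), 5))
  spec <- cohort_sim_spec(panels = list(P1 = panel), subsets = subsets,
                          n_subjects = c(HC = 6),
                          n_cells_per_sample = 400,
                          frequency_correlation = diag(5))
  sim <- simulate_cohort(spec, seed = 12)
  pp <- preprocess_cohort(sim$cells, target = 400, seed = 1)
  cl <- cluster_panel(pp$P1, k = 5, seed = 2)
  expect_setequal(cl$nodes$lineage, c("CD4T", "CD8T", "NK", "B", "MonoDC"))
  expect_equal(sum(cl$nodes$n_cells), nrow(pp$P1))
})
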