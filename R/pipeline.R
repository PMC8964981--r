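# Pipeline orchestration: one configuration drives
# simulate -> preprocess -> cluster -> abundance -> interactome -> report,
# with every stage artifact written to a run directory. Reruns with the
# same config and seeds are byte-identical for tabular outputs.

#' Default pipeline configuration
#'
#' All defaults mirror the analysis conventions this package reproduces:
#' arcsinh cofactor 5, 10,000-cell downsampling, absolute correlation
#' threshold 0.6 (strict), alpha 0.05 with no multiplicity adjustment,
#' Pearson correlation. Every stochastic stage has an explicit seed derived
#' from `seed`.
#'
#' @param out_dir Run directory.
#' @param input_dir Directory of an existing cohort ([read_cohort()]
#'   layout), or `NULL` to simulate.
#' @param sim_spec A [cohort_sim_spec()] used when `input_dir` is `NULL`.
#' @param cofactor,downsample_target,k,k_grid,threshold,strict,alpha,adjust,cor_method
#'   Stage parameters; `k = NULL` triggers elbow selection over `k_grid`.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            sim_spec = NULL,
                            cofactor = 5,
                            downsample_target = 10000,
                            k = NULL,
                            k_grid = seq(10, 120, by = 10),
                            threshold = 0.6,
                            strict = TRUE,
                            alpha = 0.05,
                            adjust = "none",
                            cor_method = "pearson",
                            seed = 1L) {
  structure(
    list(out_dir = out_dir, input_dir = input_dir, sim_spec = sim_spec,
         cofactor = cofactor, downsample_target = downsample_target,
         k = k, k_grid = k_grid, threshold = threshold, strict = strict,
         alpha = alpha, adjust = adjust, cor_method = cor_method,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys error.
#' A `sim_preset: small` key installs the bundled small simulation preset
#' ([small_sim_spec()]).
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (CLI-style precedence).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (identical(raw$sim_preset, "small")) {
    raw$sim_spec <- small_sim_spec(seed = raw$seed %||% 1L)
    raw$sim_preset <- NULL
  }
  over <- list(...)
  raw[names(over)] <- over
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Bundled small simulation preset
#'
#' Two panels of 8 markers (5 shared), three subsets per panel, 10 + 10
#' subjects, 2,000 cells per sample — small enough to run the whole
#' pipeline end to end in well under a minute.
#'
#' @param n_cells Cells per sample (default 2000).
#' @param seed RNG seed.
#' @return A [cohort_sim_spec()].
#' @export
small_sim_spec <- function(n_cells = 2000, seed = 1L) {
  shared <- c("CD3", "CD4", "CD8", "CD19", "CD56")
  p1 <- panel_spec("P1", c(shared, "GZMB", "CD45RO", "TNFa"), shared)
  p2 <- panel_spec("P2", c(shared, "CD14", "IgM", "CD11c"), shared)
  mk <- function(markers, pos) subset_profile(markers, pos)
  dd <- function(markers) setNames(rep(0.35, length(markers)), markers)
  subsets <- subset_spec(
    subset_id = c("CD4T_s", "CD8T_s", "NK_s", "T_s", "B_s", "mono_s"),
    panel = c("P1", "P1", "P1", "P2", "P2", "P2"),
    lineage = c("CD4T", "CD8T", "NK", "otherT", "B", "MonoDC"),
    mean_profile = list(
      mk(p1$marker_names, c("CD3", "CD4")),
      mk(p1$marker_names, c("CD3", "CD8", "GZMB")),
      mk(p1$marker_names, c("CD56")),
      mk(p2$marker_names, c("CD3")),
      mk(p2$marker_names, c("CD19", "IgM")),
      mk(p2$marker_names, c("CD14", "CD11c"))
    ),
    dispersion = list(dd(p1$marker_names), dd(p1$marker_names),
                      dd(p1$marker_names), dd(p2$marker_names),
                      dd(p2$marker_names), dd(p2$marker_names)),
    base_proportion = c(0.4, 0.35, 0.25, 0.5, 0.25, 0.25),
    cohort_lfc = list(c(), c(HF = 0.5), c(HF = 0.7), c(), c(HF = 0.5), c())
  )
  cohort_sim_spec(
    panels = list(P1 = p1, P2 = p2), subsets = subsets,
    n_subjects = c(HC = 10, HFpEF = 5, HFrEF = 5),
    n_cells_per_sample = n_cells, n_batches = 2, seed = seed
  )
}

write_stage <- function(log, stage, msg, path) {
  line <- jsonlite::toJSON(list(stage = stage, message = msg,
                                time = "run"), auto_unbox = TRUE)
  cat(line, "\n", file = path, sep = "", append = TRUE)
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> preprocess -> cluster -> abundance ->
#' interactome -> report, writing every stage's tables under
#' `config$out_dir`: node tables and heatmap matrices (TSV), per-sample
#' assignments, frequency tables, differential-abundance results, edge
#' lists (TSV) and GraphML exports, the comparative network-property table
#' (TSV + JSON), a line-delimited JSON log, and `report.md`.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @return Invisibly, a list of in-memory stage results (`sim`, `processed`,
#'   `clusterings`, `freq`, `differential`, `comparison`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)

  # --- input stage
  if (!is.null(cfg$input_dir)) {
    if (!dir.exists(cfg$input_dir)) {
      abort(sprintf("input stage: input directory does not exist: %s",
                    cfg$input_dir))
    }
    cells <- read_cohort(cfg$input_dir)
    sheet <- readr::read_tsv(file.path(cfg$input_dir, "sample_sheet.tsv"),
                             show_col_types = FALSE)
    sim <- NULL
  } else {
    if (is.null(cfg$sim_spec)) abort("input stage: need input_dir or sim_spec")
    sim <- simulate_cohort(cfg$sim_spec, seed = cfg$seed)
    cells <- sim$cells
    sheet <- sim$sample_sheet
  }
  sheet$batch <- as.character(sheet$batch)
  write_stage(NULL, "input", sprintf("%d subjects, %d panels",
                                     nrow(sheet), length(cells)), log_path)

  # --- preprocess
  processed <- preprocess_cohort(cells, cofactor = cfg$cofactor,
                                 target = cfg$downsample_target,
                                 seed = cfg$seed + 11L)
  counts <- imap(cells, function(tb, nm) {
    tibble(panel = nm,
           subject_id = unique(tb$subject_id),
           n_before = as.integer(table(tb$subject_id)[unique(tb$subject_id)]),
           n_after = as.integer(table(processed[[nm]]$subject_id)[unique(tb$subject_id)]))
  }) |> list_rbind()
  readr::write_tsv(counts, file.path(cfg$out_dir, "cell_counts.tsv"),
                   progress = FALSE)
  write_stage(NULL, "preprocess",
              sprintf("cofactor %g, target %d", cfg$cofactor,
                      cfg$downsample_target), log_path)

  # --- clustering (per panel, pooled over subjects and cohorts)
  clusterings <- imap(processed, function(tb, nm) {
    cluster_panel(tb, k = cfg$k, k_grid = cfg$k_grid,
                  seed = cfg$seed + 23L + match(nm, names(processed)))
  })
  for (nm in names(clusterings)) {
    cl <- clusterings[[nm]]
    readr::write_tsv(cl$nodes,
                     file.path(cfg$out_dir, sprintf("nodes_%s.tsv", nm)),
                     progress = FALSE)
    readr::write_tsv(cl$phenotypes,
                     file.path(cfg$out_dir, sprintf("phenotypes_%s.tsv", nm)),
                     progress = FALSE)
    readr::write_tsv(cl$model$assignments,
                     file.path(cfg$out_dir, sprintf("assignments_%s.tsv", nm)),
                     progress = FALSE)
    heat <- cl$phenotypes |>
      select("node_id", "marker", "scaled_median") |>
      pivot_wider(names_from = "marker", values_from = "scaled_median")
    readr::write_tsv(heat,
                     file.path(cfg$out_dir, sprintf("heatmap_%s.tsv", nm)),
                     progress = FALSE)
  }
  write_stage(NULL, "cluster",
              paste(map_chr(clusterings,
                            ~ sprintf("%s k=%d", .x$model$panel, .x$model$k)),
                    collapse = "; "), log_path)

  # --- abundance
  freq <- imap(clusterings, function(cl, nm) {
    frequency_matrix(cl$model$assignments, sheet, nodes = cl$nodes)
  })
  diffs <- list(HF_vs_HC = map(
    freq, ~ differential_nodes(.x, groups = c("HC", "HF"),
                               alpha = cfg$alpha, adjust = cfg$adjust)))
  if (all(c("HFpEF", "HFrEF") %in% sheet$subtype)) {
    diffs$HFpEF_vs_HFrEF <- map(
      freq, ~ differential_nodes(.x, groups = c("HFrEF", "HFpEF"),
                                 group_var = "subtype",
                                 alpha = cfg$alpha, adjust = cfg$adjust))
  }
  for (contrast in names(diffs)) {
    tab <- list_rbind(diffs[[contrast]])
    readr::write_tsv(tab, file.path(cfg$out_dir,
                                    sprintf("differential_%s.tsv", contrast)),
                     progress = FALSE)
  }
  write_stage(NULL, "abundance",
              sprintf("alpha %g adjust %s", cfg$alpha, cfg$adjust), log_path)

  # --- interactome
  combined <- combine_panels(freq[[1]], freq[[2]])
  comparison <- network_compare(combined, cohorts = c("HC", "HF"),
                                threshold = cfg$threshold,
                                strict = cfg$strict,
                                method = cfg$cor_method)
  readr::write_tsv(table3_format(comparison),
                   file.path(cfg$out_dir, "network_properties.tsv"),
                   progress = FALSE)
  jsonlite::write_json(comparison$properties,
                       file.path(cfg$out_dir, "network_properties.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(comparison$lineage_degrees,
                   file.path(cfg$out_dir, "lineage_degrees.tsv"),
                   progress = FALSE)
  for (co in names(comparison$networks)) {
    nt <- comparison$networks[[co]]
    readr::write_tsv(nt$edges,
                     file.path(cfg$out_dir, sprintf("edges_%s.tsv", co)),
                     progress = FALSE)
    igraph::write_graph(as_igraph(nt),
                        file.path(cfg$out_dir, sprintf("network_%s.graphml", co)),
                        format = "graphml")
  }
  write_stage(NULL, "interactome",
              sprintf("threshold %g strict %s", cfg$threshold, cfg$strict),
              log_path)

  # --- report
  results <- list(sim = sim, processed = processed,
                  clusterings = clusterings, freq = freq,
                  differential = diffs, comparison = comparison,
                  out_dir = cfg$out_dir, config = cfg)
  render_report(cfg$out_dir, config = cfg)
  write_stage(NULL, "report", "report.md written", log_path)
  invisible(results)
}

#' Render the summary report of a completed run
#'
#' Assembles `report.md` from the artifacts in a run directory: the
#' differential-node tables, the comparative network-property table, the
#' signed-edge percentages, the lineage degree table, and the configuration
#' (with seeds) verbatim.
#'
#' @param run_dir Run directory produced by [run_pipeline()].
#' @param config Optional `pipeline_config` to embed (read from the run if
#'   omitted at run time).
#' @return Path of `report.md`, invisibly.
#' @export
render_report <- function(run_dir, config = NULL) {
  need <- file.path(run_dir, "network_properties.tsv")
  if (!file.exists(need)) {
    abort(sprintf("incomplete run: missing %s", need))
  }
  props <- readr::read_tsv(need, show_col_types = FALSE)
  ldeg <- readr::read_tsv(file.path(run_dir, "lineage_degrees.tsv"),
                          show_col_types = FALSE)
  diff_files <- list.files(run_dir, "^differential_.*\\.tsv$",
                           full.names = TRUE)
  lines <- c("# Immune-cell network analysis report", "")
  for (df in diff_files) {
    tab <- readr::read_tsv(df, show_col_types = FALSE)
    sig <- tab[tab$significant, ]
    contrast <- sub("^differential_(.*)\\.tsv$", "\\1", basename(df))
    lines <- c(lines, sprintf("## Differential nodes: %s", contrast), "")
    if (nrow(sig) == 0) {
      lines <- c(lines, "No significantly altered nodes.", "")
    } else {
      lines <- c(lines,
                 sprintf("%d significantly altered node(s):", nrow(sig)),
                 "",
                 sprintf("- %s (%s, p = %.4g, %s)", sig$node_id,
                         sig$lineage %||% "?", sig$p_value, sig$direction),
                 "")
    }
  }
  lines <- c(lines, "## Network properties", "",
             paste0("| property | ", paste(names(props)[-1], collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(props)), collapse = "|"), "|"),
             sprintf("| %s | %s |", props$property,
                     apply(props[-1], 1, function(r)
                       paste(format(r, digits = 6), collapse = " | "))),
             "")
  edges_files <- list.files(run_dir, "^edges_.*\\.tsv$", full.names = TRUE)
  for (ef in edges_files) {
    ed <- readr::read_tsv(ef, show_col_types = FALSE)
    co <- sub("^edges_(.*)\\.tsv$", "\\1", basename(ef))
    m <- nrow(ed)
    nneg <- sum(ed$sign == "negative")
    lines <- c(lines, sprintf(
      "- %s: %d edges, %d negative (%s%%)", co, m, nneg,
      if (m > 0) format(100 * nneg / m, digits = 3) else "NA"))
  }
  lines <- c(lines, "", "## Per-lineage average degree", "",
             sprintf("- %s / %s: %.3f over %d node(s)", ldeg$cohort,
                     ldeg$lineage, ldeg$mean_degree, ldeg$n_nodes), "")
  if (!is.null(config)) {
    cfg_show <- config[setdiff(names(config), "sim_spec")]
    lines <- c(lines, "## Configuration", "", "```yaml",
               strsplit(yaml::as.yaml(cfg_show), "\n")[[1]], "```", "")
  }
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
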