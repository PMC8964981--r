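# Cohort import/export: one file per subject per panel (CSV with a marker
# header row, or FCS 3.0) plus a TSV sample sheet linking subject, cohort,
# batch and panel.

#' Write a cohort to disk
#'
#' Writes one file per subject-panel sample (`<subject>_<panel>.csv` or
#' `.fcs`, marker columns only), a `sample_sheet.tsv`
#' (subject_id, cohort, batch, panel) and returns the file manifest.
#'
#' @param cells Named list of cell tibbles (one per panel), or a single cell
#'   tibble.
#' @param out_dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"fcs"`; anything else errors.
#' @return Manifest tibble: `subject_id`, `cohort`, `batch`, `panel`,
#'   `file`, `n_cells`.
#' @export
write_cohort <- function(cells, out_dir, format = c("csv", "fcs")) {
  format <- match.arg(format)
  if (is.data.frame(cells)) cells <- list(cells)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- map(cells, function(tb) {
    markers <- marker_names(tb)
    split(tb, paste(tb$subject_id, tb$panel)) |>
      map(function(s) {
        fn <- sprintf("%s_%s.%s", s$subject_id[1], s$panel[1], format)
        fp <- file.path(out_dir, fn)
        if (format == "csv") {
          readr::write_csv(s[, markers], fp, progress = FALSE)
        } else {
          write_fcs(cell_matrix(s, markers), fp)
        }
        tibble(subject_id = s$subject_id[1],
               cohort = s$cohort[1] %||% NA_character_,
               batch = s$batch[1] %||% NA_character_,
               panel = s$panel[1], file = fn, n_cells = nrow(s))
      }) |> list_rbind()
  }) |> list_rbind()
  readr::write_tsv(select(manifest, -"file", -"n_cells"),
                   file.path(out_dir, "sample_sheet.tsv"), progress = FALSE)
  manifest
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the per-sample files and
#'   `sample_sheet.tsv`.
#' @param format `"csv"` or `"fcs"`.
#' @return Named list of cell tibbles, one per panel.
#' @export
read_cohort <- function(dir, format = c("csv", "fcs")) {
  format <- match.arg(format)
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  if (!file.exists(sheet_path)) {
    abort(sprintf("no sample sheet found at %s", sheet_path))
  }
  sheet <- readr::read_tsv(sheet_path, show_col_types = FALSE)
  out <- split(sheet, sheet$panel) |>
    map(function(ps) {
      map(seq_len(nrow(ps)), function(i) {
        fp <- file.path(dir, sprintf("%s_%s.%s", ps$subject_id[i],
                                     ps$panel[i], format))
        mat <- if (format == "csv") {
          as.matrix(readr::read_csv(fp, show_col_types = FALSE,
                                    progress = FALSE))
        } else {
          read_fcs(fp)
        }
        bind_cols(
          tibble(subject_id = rep(ps$subject_id[i], nrow(mat)),
                 cohort = rep(ps$cohort[i], nrow(mat)),
                 batch = rep(as.character(ps$batch[i]), nrow(mat)),
                 panel = rep(ps$panel[i], nrow(mat)),
                 cell_id = seq_len(nrow(mat))),
          as_tibble(mat)
        )
      }) |> list_rbind()
    })
  out
}
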