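# Preprocessing: arcsinh transform, batch-wise scale normalization,
# per-sample downsampling. Order of operations follows the analysis design:
# transform -> batch-normalize -> downsample.

#' Arcsinh-transform raw intensities
#'
#' Replaces every marker value `x` by `asinh(x / cofactor)`; monotone and
#' zero-preserving. A cofactor of 5 is the convention for mass cytometry
#' dual counts.
#'
#' @param cells Cell tibble on the raw scale.
#' @param cofactor Positive scalar divisor (default 5).
#' @return Cell tibble on the transformed scale.
#' @export
arcsinh_transform <- function(cells, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    abort("cofactor must be a positive scalar")
  }
  set_cell_matrix(cells, asinh(cell_matrix(cells) / cofactor))
}

#' Invert the arcsinh transform
#'
#' @inheritParams arcsinh_transform
#' @return Cell tibble on the raw scale (`cofactor * sinh(y)`).
#' @export
arcsinh_inverse <- function(cells, cofactor = 5) {
  if (cofactor <= 0) abort("cofactor must be a positive scalar")
  set_cell_matrix(cells, cofactor * sinh(cell_matrix(cells)))
}

#' Batch-wise scale normalization
#'
#' Standardizes each marker column to zero mean and unit standard deviation
#' within each batch, pooling all cells of the batch (all samples) so that
#' between-sample abundance signal within a batch is preserved while
#' additive/scale batch effects are removed. Constant columns map to zero.
#' Samples from different panels should be normalized separately (marker
#' columns differ); the function operates on whatever cell table it is
#' given.
#'
#' @param cells Transformed-scale cell tibble with a `batch` column.
#' @return Cell tibble with batch-standardized marker columns.
#' @export
batch_scale_normalize <- function(cells) {
  if (!"batch" %in% names(cells)) abort("cells must carry a batch column")
  if (nrow(cells) == 0) abort("cannot normalize a batch with zero cells")
  markers <- marker_names(cells)
  X <- cell_matrix(cells, markers)
  for (b in unique(cells$batch)) {
    idx <- which(cells$batch == b)
    sub <- X[idx, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, sd)
    sdv[!is.finite(sdv) | sdv == 0] <- Inf   # constant column -> all zeros
    X[idx, ] <- sweep(sweep(sub, 2, mu, "-"), 2, sdv, "/")
  }
  set_cell_matrix(cells, X)
}

#' Downsample each sample to a fixed number of cells
#'
#' Uniform sampling without replacement of exactly `target` cells per sample
#' (one sample = one `subject_id` x `panel` combination). Samples with fewer
#' cells than the target are kept whole with a warning; no rows are ever
#' fabricated.
#'
#' @param cells Cell tibble.
#' @param target Cells to retain per sample (default 10000).
#' @param seed RNG seed.
#' @return Cell tibble with at most `target` rows per sample, in original
#'   row order within each sample.
#' @export
downsample_cells <- function(cells, target = 10000, seed = 1L) {
  if (target <= 0) abort("target must be positive")
  set.seed(seed)
  key <- paste(cells$subject_id, cells$panel %||% "", sep = "\r")
  short <- character()
  keep <- unlist(lapply(split(seq_len(nrow(cells)), key), function(idx) {
    if (length(idx) <= target) {
      if (length(idx) < target) short <<- c(short, cells$subject_id[idx[1]])
      idx
    } else {
      sort(sample(idx, target))
    }
  }), use.names = FALSE)
  if (length(short) > 0) {
    warn(sprintf("%d sample(s) had fewer than %d cells and were kept whole: %s",
                 length(short), target,
                 paste(unique(short), collapse = ", ")))
  }
  cells[sort(keep), ]
}

#' Run the full preprocessing chain on a simulated or imported cohort
#'
#' Transform (arcsinh, cofactor), batch-normalize, downsample — per panel.
#'
#' @param cells Named list of raw-scale cell tibbles (one per panel), e.g.
#'   `simulate_cohort(spec)$cells`.
#' @param cofactor Arcsinh cofactor (default 5).
#' @param target Downsampling target per sample (default 10000).
#' @param seed RNG seed for downsampling.
#' @return Named list of preprocessed cell tibbles.
#' @export
preprocess_cohort <- function(cells, cofactor = 5, target = 10000, seed = 1L) {
  imap(cells, function(tb, nm) {
    tb |>
      arcsinh_transform(cofactor = cofactor) |>
      batch_scale_normalize() |>
      downsample_cells(target = target,
                       seed = seed + match(nm, names(cells)))
  })
}
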