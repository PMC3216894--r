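#' Quantile normalization
#'
#' Classic quantile normalization of a probes x arrays matrix: each column is
#' replaced by the across-column means of the sorted values, assigned back by
#' rank. Tied ranks receive the mean of the corresponding sorted-column means
#' (average-rank interpolation). Idempotent; after normalization every array
#' holds the identical multiset of values.
#'
#' @param x Numeric matrix, probes in rows, arrays (>= 2) in columns.
#' @return Matrix of the same shape, probe order preserved.
#' @export
quantile_normalize <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (ncol(x) < 2L) stop("need at least 2 arrays to quantile normalize")
  if (anyNA(x)) stop("missing intensities are not supported")
  ref <- rowMeans(apply(x, 2L, sort))
  n <- nrow(x)
  out <- apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (ref[lo] + ref[hi]) / 2
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Rescale each array to a target median
#'
#' @param x Numeric matrix, probes x arrays.
#' @param target_median Target median intensity (default 200).
#' @return Matrix with every column's median equal to `target_median`.
#' @export
rescale_median <- function(x, target_median = 200) {
  if (!is.matrix(x)) x <- as.matrix(x)
  meds <- apply(x, 2L, stats::median)
  if (any(meds <= 0)) stop("non-positive array median; cannot rescale")
  sweep(x, 2L, target_median / meds, "*")
}

#' Normalize an intensity array set
#'
#' Quantile-normalizes the arrays together (in the original analysis, each
#' pair of replicate ChIP measurements together with the two inputs) and then
#' rescales every array to the target median intensity.
#'
#' @param x Numeric matrix, probes x arrays (typically 4 columns:
#'   chip_rep1, chip_rep2, input_rep1, input_rep2).
#' @param params A [signal_params()].
#' @return Normalized matrix.
#' @export
normalize_arrays <- function(x, params = signal_params()) {
  rescale_median(quantile_normalize(x), params$target_median)
}

# index range [lo, hi] of probes (sorted by position within one chromosome)
# whose center is within +/- bw of each probe center
.window_bounds <- function(centers, bw) {
  lo <- findInterval(centers - bw, centers, left.open = TRUE) + 1L
  hi <- findInterval(centers + bw, centers)
  cbind(lo, hi)
}

#' Merge replicate arrays into one track
#'
#' Sliding-window replicate merging: the value at a probe is the median of
#' all replicate values at probes whose center lies within
#' `params$combine_bandwidth` bp (inclusive, center-to-center) of that
#' probe's center on the same chromosome. With the defaults this is the
#' 301 bp / bandwidth-150 window of the original pipeline. A probe with no
#' neighbors gets the median of its own replicate values.
#'
#' @param design An `array_design` (or any list with a `probes` data.frame).
#' @param reps Numeric matrix, probes x replicate arrays, rows aligned to
#'   `design$probes`.
#' @param params A [signal_params()].
#' @return Numeric vector of merged values, one per probe.
#' @export
combine_replicates <- function(design, reps, params = signal_params()) {
  probes <- design$probes
  if (!is.matrix(reps)) reps <- as.matrix(reps)
  if (ncol(reps) < 1L) stop("need at least one replicate array")
  if (nrow(reps) != nrow(probes))
    stop("replicate matrix rows must align with design probes")
  centers <- (probes$start + probes$end) / 2
  out <- numeric(nrow(probes))
  for (ch in unique(probes$chrom)) {
    idx <- which(probes$chrom == ch)
    b <- .window_bounds(centers[idx], params$combine_bandwidth)
    sub <- reps[idx, , drop = FALSE]
    out[idx] <- vapply(seq_along(idx), function(i) {
      stats::median(sub[b[i, 1L]:b[i, 2L], ])
    }, numeric(1))
  }
  out
}

#' Per-probe log2 ratio of merged ChIP over merged input
#'
#' @param chip_merged,input_merged Numeric vectors (merged tracks), aligned.
#' @return log2(chip / input) per probe.
#' @export
log2_ratio <- function(chip_merged, input_merged) {
  if (length(chip_merged) != length(input_merged))
    stop("chip and input tracks must have the same length")
  bad <- which(chip_merged <= 0 | input_merged <= 0)
  if (length(bad))
    stop("non-positive merged value at probe index ", bad[1L])
  log2(chip_merged / input_merged)
}

#' Windowed Z-scores of a log2-ratio track
#'
#' For each probe, the mean log2 ratio of probes within `z_window / 2` bp
#' (center-to-center, inclusive; default window 150 bp) is standardized
#' against the distribution of single-probe log2 ratios on the whole array:
#' `Z = (window_mean - mu) / sigma`. `sigma` is the population standard
#' deviation by default (`params$sd_type`).
#'
#' @param design An `array_design`.
#' @param ratio Numeric vector of log2 ratios aligned to `design$probes`.
#' @param params A [signal_params()].
#' @return Numeric vector of Z-scores.
#' @export
compute_zscores <- function(design, ratio, params = signal_params()) {
  probes <- design$probes
  if (length(ratio) != nrow(probes))
    stop("ratio track must align with design probes")
  if (length(ratio) < 2L) stop("need at least 2 probes")
  mu <- mean(ratio)
  sigma <- stats::sd(ratio)
  if (params$sd_type == "population")
    sigma <- sigma * sqrt((length(ratio) - 1) / length(ratio))
  if (!is.finite(sigma) || sigma == 0)
    stop("zero variance on the array; Z-scores undefined")
  half <- params$z_window / 2
  centers <- (probes$start + probes$end) / 2
  w <- numeric(length(ratio))
  for (ch in unique(probes$chrom)) {
    idx <- which(probes$chrom == ch)
    b <- .window_bounds(centers[idx], half)
    cs <- cumsum(c(0, ratio[idx]))
    w[idx] <- (cs[b[, 2L] + 1L] - cs[b[, 1L]]) / (b[, 2L] - b[, 1L] + 1L)
  }
  (w - mu) / sigma
}

#' Build a signal track from a raw intensity table
#'
#' Full signal stage for one mark in one sample: quantile-normalize the two
#' ChIP and two input replicates together, rescale to median 200, merge the
#' ChIP replicates and the input replicates with the sliding-window median,
#' take per-probe log2(ChIP/input), and compute windowed Z-scores.
#'
#' @param design An `array_design`.
#' @param intensities Data.frame with columns probe_id, chip_rep1, chip_rep2,
#'   input_rep1, input_rep2 (as produced by [simulate_chip_experiment()]),
#'   rows covering every design probe.
#' @param params A [signal_params()].
#' @param mark,sample_label Metadata stored on the track.
#' @return A `signal_track`: data.frame with columns chrom, start, end,
#'   probe_id, ratio, z; attributes `mark` and `sample`.
#' @export
build_signal_track <- function(design, intensities,
                               params = signal_params(),
                               mark = NA_character_,
                               sample_label = NA_character_) {
  probes <- design$probes
  m <- match(probes$probe_id, intensities$probe_id)
  if (anyNA(m))
    stop("intensity table does not cover every design probe")
  cols <- c("chip_rep1", "chip_rep2", "input_rep1", "input_rep2")
  if (!all(cols %in% names(intensities)))
    stop("intensity table must have columns ", paste(cols, collapse = ", "))
  x <- as.matrix(intensities[m, cols])
  x <- normalize_arrays(x, params)
  chip <- combine_replicates(design, x[, c("chip_rep1", "chip_rep2")], params)
  input <- combine_replicates(design, x[, c("input_rep1", "input_rep2")],
                              params)
  ratio <- log2_ratio(chip, input)
  z <- compute_zscores(design, ratio, params)
  track <- data.frame(chrom = probes$chrom, start = probes$start,
                      end = probes$end, probe_id = probes$probe_id,
                      ratio = ratio, z = z, stringsAsFactors = FALSE)
  attr(track, "mark") <- mark
  attr(track, "sample") <- sample_label
  class(track) <- c("signal_track", "data.frame")
  track
}
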