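.empty_regions <- function() {
  data.frame(region_id = character(), chrom = character(), start = integer(),
             end = integer(), n_probes = integer(), n_enriched = integer(),
             max_z = numeric(), probe_idx = I(list()),
             stringsAsFactors = FALSE)
}

.region_row <- function(track, idx, params) {
  idx <- sort(unique(idx))
  data.frame(region_id = NA_character_, chrom = track$chrom[idx[1L]],
             start = min(track$start[idx]), end = max(track$end[idx]),
             n_probes = length(idx),
             n_enriched = sum(track$z[idx] >= params$z_enrich),
             max_z = max(track$z[idx]), probe_idx = I(list(idx)),
             stringsAsFactors = FALSE)
}

#' Flag enriched probes
#'
#' A probe is enriched when its windowed Z-score is at or above the
#' threshold (inclusive: Z = 6.0 is enriched at the default cut-off of 6).
#'
#' @param track A `signal_track`.
#' @param params A [region_params()].
#' @return Logical vector aligned to the track.
#' @export
flag_enriched_probes <- function(track, params = region_params()) {
  track$z >= params$z_enrich
}

#' Build candidate enriched regions
#'
#' Implements the run-formation criteria: an enriched probe is first
#' disqualified if it lacks a measured probe within `flank_bp`
#' (center-to-center) on either side; surviving enriched probes whose
#' consecutive center-to-center gaps are at most `gap_bp` form runs; runs
#' with at least `min_enriched` probes become regions. A region's members are
#' all measured probes between its outermost enriched probes, and its
#' coordinates span from the first member's start to the last member's end.
#'
#' @param flags Logical vector from [flag_enriched_probes()].
#' @param track A `signal_track`.
#' @param params A [region_params()].
#' @return Regions data.frame (region_id, chrom, start, end, n_probes,
#'   n_enriched, max_z, probe_idx list-column of track row indices).
#' @export
build_regions <- function(flags, track, params = region_params()) {
  if (length(flags) != nrow(track))
    stop("flags must align with the track")
  out <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    centers <- (track$start[idx] + track$end[idx]) / 2
    e <- which(flags[idx])
    if (!length(e)) next
    # flank rule: a measured probe within flank_bp on both sides
    ok <- vapply(e, function(i) {
      left <- i > 1L && centers[i] - centers[i - 1L] <= params$flank_bp
      right <- i < length(idx) && centers[i + 1L] - centers[i] <=
        params$flank_bp
      left && right
    }, logical(1))
    e <- e[ok]
    if (length(e) < params$min_enriched) next
    gaps <- diff(centers[e])
    run <- cumsum(c(1, as.integer(gaps > params$gap_bp)))
    for (r in unique(run)) {
      members <- e[run == r]
      if (length(members) < params$min_enriched) next
      span <- seq(min(members), max(members))
      out[[length(out) + 1L]] <- .region_row(track, idx[span], params)
    }
  }
  if (!length(out)) return(.empty_regions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Prolong regions with nearby probes
#'
#' Appends any measured probe (enriched or not) whose center lies within
#' `prolong_bp` of the region's outermost member probe, updating the
#' boundary. By default this is iterated to a fixpoint: a probe absorbed on
#' one pass can pull in the next probe on the following pass. With
#' `params$prolong_single_pass`, only probes within `prolong_bp` of the
#' original tails are absorbed.
#'
#' @param regions Regions data.frame from [build_regions()].
#' @param track A `signal_track`.
#' @param params A [region_params()].
#' @return Regions with updated members and boundaries.
#' @export
prolong_regions <- function(regions, track, params = region_params()) {
  if (nrow(regions) == 0L) return(regions)
  centers <- (track$start + track$end) / 2
  out <- lapply(seq_len(nrow(regions)), function(k) {
    idx <- regions$probe_idx[[k]]
    ch <- regions$chrom[k]
    chrom_idx <- which(track$chrom == ch)
    lo <- min(idx); hi <- max(idx)
    lo_min <- min(chrom_idx); hi_max <- max(chrom_idx)
    if (params$prolong_single_pass) {
      lo0 <- lo; hi0 <- hi
      while (lo > lo_min && centers[lo0] - centers[lo - 1L] <=
             params$prolong_bp) lo <- lo - 1L
      while (hi < hi_max && centers[hi + 1L] - centers[hi0] <=
             params$prolong_bp) hi <- hi + 1L
    } else {
      while (lo > lo_min && centers[lo] - centers[lo - 1L] <=
             params$prolong_bp) lo <- lo - 1L
      while (hi < hi_max && centers[hi + 1L] - centers[hi] <=
             params$prolong_bp) hi <- hi + 1L
    }
    .region_row(track, seq(lo, hi), params)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge nearby regions
#'
#' Regions on the same chromosome whose gap (start of the right minus end of
#' the left) is strictly less than `merge_bp` are unioned, transitively:
#' chains of regions each within the distance collapse into one. Overlapping
#' regions merge as well. Idempotent.
#'
#' @param regions Regions data.frame.
#' @param track A `signal_track` (used to recompute member statistics).
#' @param params A [region_params()].
#' @return Merged, sorted regions.
#' @export
merge_regions <- function(regions, track, params = region_params()) {
  if (nrow(regions) <= 1L) return(regions)
  o <- order(regions$chrom, regions$start, regions$end)
  regions <- regions[o, , drop = FALSE]
  out <- list()
  cur <- NULL
  for (k in seq_len(nrow(regions))) {
    row <- regions[k, , drop = FALSE]
    if (is.null(cur)) {
      cur <- row
    } else if (row$chrom == cur$chrom &&
               row$start - cur$end < params$merge_bp) {
      cur <- .region_row(track, c(cur$probe_idx[[1L]], row$probe_idx[[1L]]),
                         params)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call enriched regions from a Z-score track
#'
#' The full region caller: flag probes at the Z threshold, form candidate
#' regions under the flank/gap/probe-count criteria, prolong region tails,
#' and merge nearby regions — in that order. Output is sorted and
#' non-overlapping, with stable region ids.
#'
#' @param track A `signal_track`.
#' @param params A [region_params()].
#' @return Regions data.frame; attributes `mark` and `sample` copied from
#'   the track.
#' @export
call_enriched_regions <- function(track, params = region_params()) {
  if (nrow(track) == 0L) return(.empty_regions())
  flags <- flag_enriched_probes(track, params)
  regs <- build_regions(flags, track, params)
  regs <- prolong_regions(regs, track, params)
  regs <- merge_regions(regs, track, params)
  if (nrow(regs)) {
    o <- order(regs$chrom, regs$start)
    regs <- regs[o, , drop = FALSE]
    regs$region_id <- sprintf("%s_%s_%04d",
                              if (is.na(attr(track, "mark"))) "region" else
                                attr(track, "mark"),
                              if (is.na(attr(track, "sample"))) "x" else
                                attr(track, "sample"),
                              seq_len(nrow(regs)))
    rownames(regs) <- NULL
  }
  attr(regs, "mark") <- attr(track, "mark")
  attr(regs, "sample") <- attr(track, "sample")
  regs
}
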