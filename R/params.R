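#' Parameter objects
#'
#' Constructors for the parameter sets used by the pipeline stages. Defaults
#' are the constants of the original tiling-array analysis: arrays rescaled to
#' median intensity 200, replicate merging in a 301 bp window (bandwidth
#' 150 bp), Z-scores from 150 bp windows, enrichment at Z >= 6 with at least
#' 2 enriched probes, 110 bp flank and gap rules, 75 bp prolongation, 1000 bp
#' region merging, bivalency/transition support of 3 shared probes (2
#' enriched), a delta-Z separation of 3, a +/- 2.5 kb annotation window, and
#' significance cut-offs 0.001 (differential expression), 0.05 (transition
#' group overlap) and 0.01 (hypermethylation overlap).
#'
#' @name chromtrans-params
NULL

#' @rdname chromtrans-params
#' @param target_median Intensity value every array's median is rescaled to.
#' @param combine_window Width in bp of the replicate-merging window; must be
#'   `2 * combine_bandwidth + 1`.
#' @param combine_bandwidth Half-width in bp of the replicate-merging window.
#' @param z_window Width in bp of the window whose mean log2 ratio is
#'   standardized into a Z-score (probes within `z_window / 2` of the center).
#' @param sd_type `"population"` (divide by n) or `"sample"` (divide by n-1)
#'   standard deviation for the Z-score reference distribution.
#' @export
signal_params <- function(target_median = 200, combine_window = 301L,
                          combine_bandwidth = 150L, z_window = 150L,
                          sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(target_median > 0, combine_window > 0, combine_bandwidth > 0,
            z_window > 0)
  if (combine_window != 2L * combine_bandwidth + 1L)
    stop("combine_window must equal 2 * combine_bandwidth + 1")
  structure(list(target_median = target_median,
                 combine_window = as.integer(combine_window),
                 combine_bandwidth = as.integer(combine_bandwidth),
                 z_window = as.integer(z_window),
                 sd_type = sd_type),
            class = "signal_params")
}

#' @rdname chromtrans-params
#' @param z_enrich Z-score at or above which a probe counts as enriched.
#' @param min_enriched Minimum number of enriched probes per region.
#' @param flank_bp An enriched probe must have a measured probe within this
#'   many bp (center-to-center) on both sides.
#' @param gap_bp Maximum center-to-center gap between consecutive enriched
#'   probes inside a region.
#' @param prolong_bp Probes within this many bp of a region tail are absorbed
#'   (iterated to a fixpoint unless `prolong_single_pass`).
#' @param merge_bp Regions closer than this (strictly) are merged.
#' @param prolong_single_pass If `TRUE`, prolongation runs once instead of to
#'   a fixpoint.
#' @export
region_params <- function(z_enrich = 6, min_enriched = 2L, flank_bp = 110L,
                          gap_bp = 110L, prolong_bp = 75L, merge_bp = 1000L,
                          prolong_single_pass = FALSE) {
  stopifnot(z_enrich > 0, min_enriched >= 1, flank_bp > 0, gap_bp > 0,
            prolong_bp > 0, merge_bp > 0, is.logical(prolong_single_pass))
  structure(list(z_enrich = z_enrich, min_enriched = as.integer(min_enriched),
                 flank_bp = as.integer(flank_bp), gap_bp = as.integer(gap_bp),
                 prolong_bp = as.integer(prolong_bp),
                 merge_bp = as.integer(merge_bp),
                 prolong_single_pass = prolong_single_pass),
            class = "region_params")
}

#' @rdname chromtrans-params
#' @param biv_min_shared_probes Minimum probes shared between a K4 and a K27
#'   region for bivalency.
#' @param biv_min_shared_enriched Of the shared probes, minimum that must be
#'   enriched.
#' @param biv_enriched_in `"each"` requires the enriched shared probes in both
#'   marks separately (strict reading); `"either"` accepts enrichment in one.
#' @param trans_min_shared_probes Minimum probes shared between the normal and
#'   tumor regions of a kept mark.
#' @param trans_min_shared_enriched Of those, minimum enriched in both
#'   conditions.
#' @param delta_z Minimum |maxZ_normal - maxZ_tumor| for a mark whose called
#'   presence changes, so that calls just on opposite sides of the Z cut-off
#'   are not reported as transitions.
#' @export
state_params <- function(biv_min_shared_probes = 3L,
                         biv_min_shared_enriched = 2L,
                         biv_enriched_in = c("each", "either"),
                         trans_min_shared_probes = 3L,
                         trans_min_shared_enriched = 2L,
                         delta_z = 3) {
  biv_enriched_in <- match.arg(biv_enriched_in)
  stopifnot(biv_min_shared_probes >= 1, biv_min_shared_enriched >= 1,
            biv_min_shared_enriched <= biv_min_shared_probes,
            trans_min_shared_probes >= 1, trans_min_shared_enriched >= 1,
            trans_min_shared_enriched <= trans_min_shared_probes,
            delta_z > 0)
  structure(list(biv_min_shared_probes = as.integer(biv_min_shared_probes),
                 biv_min_shared_enriched = as.integer(biv_min_shared_enriched),
                 biv_enriched_in = biv_enriched_in,
                 trans_min_shared_probes = as.integer(trans_min_shared_probes),
                 trans_min_shared_enriched =
                   as.integer(trans_min_shared_enriched),
                 delta_z = delta_z),
            class = "state_params")
}

#' @rdname chromtrans-params
#' @param window_bp Annotation window in bp, applied in both directions from
#'   the TSS (strand-aware).
#' @export
annotation_params <- function(window_bp = 2500L) {
  stopifnot(window_bp > 0)
  structure(list(window_bp = as.integer(window_bp)),
            class = "annotation_params")
}

#' @rdname chromtrans-params
#' @param de_alpha Adjusted-p cut-off for calling a gene differentially
#'   expressed.
#' @param overlap_alpha Cut-off for transition-group over/under-representation
#'   among DE genes.
#' @param meth_alpha Cut-off for over-representation among hypermethylated
#'   genes.
#' @export
stats_params <- function(de_alpha = 0.001, overlap_alpha = 0.05,
                         meth_alpha = 0.01) {
  stopifnot(de_alpha > 0, de_alpha < 1, overlap_alpha > 0, overlap_alpha < 1,
            meth_alpha > 0, meth_alpha < 1)
  structure(list(de_alpha = de_alpha, overlap_alpha = overlap_alpha,
                 meth_alpha = meth_alpha),
            class = "stats_params")
}

#' @rdname chromtrans-params
#' @param probe_spacing Center-to-center probe spacing in bp.
#' @param probe_length Probe length in bp.
#' @param upstream_span Tiled span upstream of the TSS, in bp (transcription
#'   orientation).
#' @param downstream_span Tiled span downstream of the TSS, in bp.
#' @param promoter_gap Minimum gap in bp between consecutive tiled promoter
#'   intervals (keeps annotation unambiguous unless lowered on purpose).
#' @param bg_meanlog,bg_sdlog Mean and sd of the per-probe log (natural)
#'   background intensity (log-normal probe affinities).
#' @param noise_sd Replicate noise sd on the natural-log intensity scale.
#' @param fold_change Linear fold-change applied to ChIP intensities of probes
#'   inside a planted enrichment interval.
#' @param mark_halfwidth Half-width in bp of a planted mark interval around
#'   the TSS.
#' @param expr_noise_sd Residual sd of simulated log2 expression values.
#' @param meth_base_rate Background probability that a gene enters the
#'   simulated hypermethylated list.
#' @param n_pairs Number of simulated normal/tumor patient pairs.
#' @export
sim_params <- function(probe_spacing = 35L, probe_length = 25L,
                       upstream_span = 7500L, downstream_span = 2450L,
                       promoter_gap = 20000L,
                       bg_meanlog = log(200), bg_sdlog = 0.5,
                       noise_sd = 0.25, fold_change = 8,
                       mark_halfwidth = 300L,
                       expr_noise_sd = 0.5, meth_base_rate = 0.05,
                       n_pairs = 24L) {
  stopifnot(probe_spacing > 0, probe_length > 0, upstream_span > 0,
            downstream_span > 0, promoter_gap >= 0, bg_sdlog >= 0,
            noise_sd >= 0, fold_change > 1, mark_halfwidth > 0,
            expr_noise_sd >= 0, meth_base_rate > 0, meth_base_rate < 1,
            n_pairs >= 2)
  structure(list(probe_spacing = as.integer(probe_spacing),
                 probe_length = as.integer(probe_length),
                 upstream_span = as.integer(upstream_span),
                 downstream_span = as.integer(downstream_span),
                 promoter_gap = as.integer(promoter_gap),
                 bg_meanlog = bg_meanlog, bg_sdlog = bg_sdlog,
                 noise_sd = noise_sd, fold_change = fold_change,
                 mark_halfwidth = as.integer(mark_halfwidth),
                 expr_noise_sd = expr_noise_sd,
                 meth_base_rate = meth_base_rate,
                 n_pairs = as.integer(n_pairs)),
            class = "sim_params")
}
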