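#' Find bivalent regions
#'
#' A pair of one H3K4me3 and one H3K27me3 region (same sample) is bivalent
#' when the regions share at least `biv_min_shared_probes` member probes of
#' which at least `biv_min_shared_enriched` are enriched (Z at or above
#' `z_enrich`). With the default strict reading (`biv_enriched_in = "each"`)
#' the enriched-shared-probe count must be met in both marks separately;
#' `"either"` accepts it in one mark. The bivalent interval is the span of
#' the shared probes.
#'
#' @param k4_regions,k27_regions Region data.frames from
#'   [call_enriched_regions()] for the two marks of one sample.
#' @param k4_track,k27_track The matching `signal_track`s (same design).
#' @param params A [state_params()].
#' @param z_enrich Z threshold defining an enriched probe (default 6).
#' @return Data.frame: biv_id, chrom, start, end, n_shared, n_enr_k4,
#'   n_enr_k27, k4_region_id, k27_region_id, probe_idx (list-column).
#' @export
find_bivalent_regions <- function(k4_regions, k27_regions, k4_track,
                                  k27_track, params = state_params(),
                                  z_enrich = 6) {
  if (nrow(k4_track) != nrow(k27_track))
    stop("K4 and K27 tracks must come from the same design")
  out <- list()
  for (i in seq_len(nrow(k4_regions))) {
    a <- k4_regions$probe_idx[[i]]
    for (j in seq_len(nrow(k27_regions))) {
      if (k27_regions$chrom[j] != k4_regions$chrom[i]) next
      shared <- intersect(a, k27_regions$probe_idx[[j]])
      if (length(shared) < params$biv_min_shared_probes) next
      n4 <- sum(k4_track$z[shared] >= z_enrich)
      n27 <- sum(k27_track$z[shared] >= z_enrich)
      hit <- if (params$biv_enriched_in == "each")
        n4 >= params$biv_min_shared_enriched &&
          n27 >= params$biv_min_shared_enriched
      else
        max(n4, n27) >= params$biv_min_shared_enriched
      if (!hit) next
      shared <- sort(shared)
      out[[length(out) + 1L]] <- data.frame(
        biv_id = NA_character_, chrom = k4_regions$chrom[i],
        start = min(k4_track$start[shared]),
        end = max(k4_track$end[shared]),
        n_shared = length(shared), n_enr_k4 = n4, n_enr_k27 = n27,
        k4_region_id = k4_regions$region_id[i],
        k27_region_id = k27_regions$region_id[j],
        probe_idx = I(list(shared)), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(biv_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_shared = integer(), n_enr_k4 = integer(),
                      n_enr_k27 = integer(), k4_region_id = character(),
                      k27_region_id = character(), probe_idx = I(list()),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  o <- order(res$chrom, res$start)
  res <- res[o, , drop = FALSE]
  res$biv_id <- sprintf("BIV_%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Build loci from regions of both marks and conditions
#'
#' A locus is a maximal connected component of probe-sharing regions pooled
#' across marks and conditions (two regions are connected when they share at
#' least one member probe). Loci make normal-vs-tumor state comparison
#' well-defined even when region boundaries shift between conditions.
#'
#' @param regions_by List `regions_by[[condition]][[mark]]` of region
#'   data.frames, conditions `normal`/`tumor`, marks `K4`/`K27`; all called
#'   on tracks from one design.
#' @return Data.frame: locus_id, chrom, start, end, probe_idx (list-column of
#'   the union of member probes), members (list-column data.frame with
#'   condition, mark, region_id, region probe_idx).
#' @export
build_loci <- function(regions_by) {
  rows <- list()
  for (cond in names(regions_by)) {
    for (mark in names(regions_by[[cond]])) {
      regs <- regions_by[[cond]][[mark]]
      for (k in seq_len(nrow(regs))) {
        rows[[length(rows) + 1L]] <- list(
          condition = cond, mark = mark, region_id = regs$region_id[k],
          chrom = regs$chrom[k], idx = regs$probe_idx[[k]])
      }
    }
  }
  if (!length(rows))
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      probe_idx = I(list()), members = I(list()),
                      stringsAsFactors = FALSE))
  # regions are index intervals; union-find via sorted interval sweep
  lo <- vapply(rows, function(r) min(r$idx), numeric(1))
  hi <- vapply(rows, function(r) max(r$idx), numeric(1))
  ch <- vapply(rows, function(r) r$chrom, character(1))
  o <- order(ch, lo)
  comp <- integer(length(rows))
  cur_comp <- 0L
  cur_hi <- -Inf; cur_ch <- ""
  for (r in o) {
    if (ch[r] != cur_ch || lo[r] > cur_hi) {
      cur_comp <- cur_comp + 1L
      cur_ch <- ch[r]; cur_hi <- hi[r]
    } else cur_hi <- max(cur_hi, hi[r])
    comp[r] <- cur_comp
  }
  out <- lapply(seq_len(cur_comp), function(cid) {
    mem <- rows[comp == cid]
    idx <- sort(unique(unlist(lapply(mem, `[[`, "idx"))))
    members <- data.frame(
      condition = vapply(mem, `[[`, character(1), "condition"),
      mark = vapply(mem, `[[`, character(1), "mark"),
      region_id = vapply(mem, `[[`, character(1), "region_id"),
      stringsAsFactors = FALSE)
    members$probe_idx <- I(lapply(mem, `[[`, "idx"))
    data.frame(locus_id = NA_character_, chrom = mem[[1L]]$chrom,
               start = NA_integer_, end = NA_integer_,
               probe_idx = I(list(idx)), members = I(list(members)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$locus_id <- sprintf("LOC_%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

.locus_state <- function(members, condition, biv, locus_idx) {
  sub <- members[members$condition == condition, , drop = FALSE]
  has_biv <- FALSE
  if (nrow(biv)) {
    for (k in seq_len(nrow(biv)))
      if (length(intersect(biv$probe_idx[[k]], locus_idx))) {
        has_biv <- TRUE
        break
      }
  }
  marks <- unique(sub$mark)
  if (has_biv && all(c("K4", "K27") %in% marks))
    list(state = "BIV", semi = FALSE)
  else if (all(c("K4", "K27") %in% marks))
    list(state = "K4+K27", semi = TRUE)
  else if ("K4" %in% marks) list(state = "K4", semi = FALSE)
  else if ("K27" %in% marks) list(state = "K27", semi = FALSE)
  else list(state = "NONE", semi = FALSE)
}

#' Assign per-locus chromatin states for one condition
#'
#' BIV when the locus contains a bivalent region of that condition (and both
#' marks); otherwise the single present mark; NONE when the condition
#' contributes no region. A locus holding both marks without a bivalent pair
#' is recorded as `"K4+K27"` with `semi = TRUE` (semi-bivalency proper is a
#' gene-level call).
#'
#' @param loci Data.frame from [build_loci()].
#' @param bivalent Bivalent regions of this condition
#'   ([find_bivalent_regions()]).
#' @param condition `"normal"` or `"tumor"`.
#' @return Data.frame: locus_id, state, semi.
#' @export
assign_locus_states <- function(loci, bivalent, condition) {
  res <- lapply(seq_len(nrow(loci)), function(k) {
    s <- .locus_state(loci$members[[k]], condition, bivalent,
                      loci$probe_idx[[k]])
    data.frame(locus_id = loci$locus_id[k], state = s$state, semi = s$semi,
               stringsAsFactors = FALSE)
  })
  if (!length(res))
    return(data.frame(locus_id = character(), state = character(),
                      semi = logical(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

.presence <- function(state) {
  switch(state, NONE = c(FALSE, FALSE), K4 = c(TRUE, FALSE),
         K27 = c(FALSE, TRUE), BIV = c(TRUE, TRUE),
         stop("invalid state: ", state))
}

#' Category of a normal-to-tumor state transition
#'
#' The 15 valid ordered state pairs fall into three groups by how many
#' marks' presence changes: none (`mark_kept`, the 3 unchanged states),
#' exactly one (`single_mark_change`, 8 pairs: a single mark gained or
#' lost), or both (`both_marks_change`, 4 pairs: K4 to K27 or vice versa,
#' bivalent gained from or lost to unmarked).
#'
#' @param state_n,state_t States in `{NONE, K4, K27, BIV}`;
#'   `(NONE, NONE)` is rejected.
#' @return One of `"mark_kept"`, `"single_mark_change"`,
#'   `"both_marks_change"`.
#' @export
transition_category <- function(state_n, state_t) {
  if (state_n == "NONE" && state_t == "NONE")
    stop("(NONE, NONE) is not a transition")
  n_changed <- sum(.presence(state_n) != .presence(state_t))
  c("mark_kept", "single_mark_change", "both_marks_change")[n_changed + 1L]
}

.locus_max_z <- function(track, idx) {
  if (!length(idx)) return(NA_real_)
  max(track$z[idx])
}

#' Classify normal-to-tumor transitions at locus level
#'
#' For each locus the normal and tumor states are compared. A mark present
#' in both conditions ("kept") must be supported by a normal/tumor region
#' pair sharing at least `trans_min_shared_probes` probes of which
#' `trans_min_shared_enriched` are enriched in both conditions. A mark whose
#' called presence changes must additionally separate by
#' `|maxZ_normal - maxZ_tumor| >= delta_z` over the locus, so that calls
#' just on opposite sides of the enrichment cut-off are not reported as
#' transitions. Loci failing either requirement are emitted with status
#' `"unresolved"`; loci with a non-bivalent two-mark state get status
#' `"semi"`; all others are `"ok"` transitions with their category.
#'
#' @param loci Data.frame from [build_loci()].
#' @param states_n,states_t Data.frames from [assign_locus_states()].
#' @param tracks List `tracks[[condition]][[mark]]` of `signal_track`s.
#' @param params A [state_params()].
#' @param z_enrich Z threshold defining an enriched probe (default 6).
#' @return Data.frame: locus_id, chrom, start, end, state_normal,
#'   state_tumor, category, status, max_z_k4_normal, max_z_k4_tumor,
#'   max_z_k27_normal, max_z_k27_tumor.
#' @export
classify_transitions <- function(loci, states_n, states_t, tracks,
                                 params = state_params(), z_enrich = 6) {
  track0 <- tracks$normal$K4
  res <- lapply(seq_len(nrow(loci)), function(k) {
    idx <- loci$probe_idx[[k]]
    members <- loci$members[[k]]
    sn <- states_n$state[states_n$locus_id == loci$locus_id[k]]
    st <- states_t$state[states_t$locus_id == loci$locus_id[k]]
    mz <- list()
    for (cond in c("normal", "tumor"))
      for (mark in c("K4", "K27"))
        mz[[paste0("max_z_", tolower(mark), "_", cond)]] <-
          .locus_max_z(tracks[[cond]][[mark]], idx)
    base <- data.frame(locus_id = loci$locus_id[k], chrom = loci$chrom[k],
                       start = min(track0$start[idx]),
                       end = max(track0$end[idx]),
                       state_normal = sn, state_tumor = st,
                       category = NA_character_, status = "ok",
                       stringsAsFactors = FALSE)
    base <- cbind(base, as.data.frame(mz))
    if (sn == "K4+K27" || st == "K4+K27") {
      base$status <- "semi"
      return(base)
    }
    pn <- .presence(sn); pt <- .presence(st)
    marks <- c("K4", "K27")
    ok <- TRUE
    for (m in seq_along(marks)) {
      mark <- marks[m]
      if (pn[m] && pt[m]) {
        # kept mark: need a normal/tumor region pair with common support
        rn <- members[members$condition == "normal" & members$mark == mark, ]
        rt <- members[members$condition == "tumor" & members$mark == mark, ]
        zn <- tracks$normal[[mark]]$z
        zt <- tracks$tumor[[mark]]$z
        supported <- FALSE
        for (a in seq_len(nrow(rn))) {
          for (b in seq_len(nrow(rt))) {
            shared <- intersect(rn$probe_idx[[a]], rt$probe_idx[[b]])
            if (length(shared) < params$trans_min_shared_probes) next
            both_enr <- sum(zn[shared] >= z_enrich & zt[shared] >= z_enrich)
            if (both_enr >= params$trans_min_shared_enriched) {
              supported <- TRUE
              break
            }
          }
          if (supported) break
        }
        if (!supported) ok <- FALSE
      } else if (pn[m] != pt[m]) {
        dz <- abs(mz[[paste0("max_z_", tolower(mark), "_normal")]] -
                    mz[[paste0("max_z_", tolower(mark), "_tumor")]])
        if (!is.finite(dz) || dz < params$delta_z) ok <- FALSE
      }
    }
    if (!ok) {
      base$status <- "unresolved"
    } else {
      base$category <- transition_category(sn, st)
    }
    base
  })
  if (!length(res))
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      state_normal = character(), state_tumor = character(),
                      category = character(), status = character(),
                      max_z_k4_normal = numeric(), max_z_k4_tumor = numeric(),
                      max_z_k27_normal = numeric(),
                      max_z_k27_tumor = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Average signal footprint around anchors
#'
#' Bins the merged log2-ratio signal by offset from a set of anchor
#' positions (TSSs or region centers), strand-aware: offsets on minus-strand
#' anchors are reversed so "downstream" always means in transcription
#' orientation. Returns the per-bin mean over all anchor-probe pairs; bins
#' containing no probe are `NA`.
#'
#' @param track A `signal_track`.
#' @param anchors Data.frame with columns chrom, position, strand.
#' @param flank_bp Half-width of the profiled window.
#' @param bin_bp Bin width; must divide `flank_bp`.
#' @return Data.frame: bin_start, bin_mid, mean, n_probes.
#' @export
footprint <- function(track, anchors, flank_bp = 5000L, bin_bp = 100L) {
  if (nrow(anchors) == 0L) stop("anchor list is empty")
  if (flank_bp %% bin_bp != 0) stop("bin_bp must divide flank_bp")
  centers <- (track$start + track$end) / 2
  offs <- numeric(0); vals <- numeric(0)
  for (a in seq_len(nrow(anchors))) {
    sel <- track$chrom == anchors$chrom[a] &
      abs(centers - anchors$position[a]) <= flank_bp
    if (!any(sel)) next
    d <- centers[sel] - anchors$position[a]
    if (anchors$strand[a] == "-") d <- -d
    offs <- c(offs, d)
    vals <- c(vals, track$ratio[sel])
  }
  n_bins <- 2L * flank_bp %/% bin_bp
  bin_start <- -flank_bp + (seq_len(n_bins) - 1L) * bin_bp
  bin <- pmin(pmax(floor((offs + flank_bp) / bin_bp) + 1L, 1L), n_bins)
  mean_v <- rep(NA_real_, n_bins)
  n_v <- integer(n_bins)
  if (length(bin)) {
    agg <- tapply(vals, bin, mean)
    cnt <- table(bin)
    mean_v[as.integer(names(agg))] <- as.numeric(agg)
    n_v[as.integer(names(cnt))] <- as.integer(cnt)
  }
  data.frame(bin_start = bin_start, bin_mid = bin_start + bin_bp / 2,
             mean = mean_v, n_probes = n_v)
}
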