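# Independent brute-force reference implementations used as oracles.

# Literal quadratic region caller: enrichment flagging, flank
# disqualification against all measured probes, gap-based grouping by
# pairwise scanning, prolongation by repeated single passes over all probes,
# and merging by repeated pairwise union until nothing changes.
oracle_call_regions <- function(track, params) {
  n <- nrow(track)
  centers <- (track$start + track$end) / 2
  enr <- which(track$z >= params$z_enrich)
  qual <- enr[vapply(enr, function(i) {
    d <- centers - centers[i]
    same <- track$chrom == track$chrom[i]
    any(same & d < 0 & -d <= params$flank_bp) &&
      any(same & d > 0 & d <= params$flank_bp)
  }, logical(1))]
  # group qualified probes: i and j belong together when every consecutive
  # step between qualified probes on the path is within gap_bp
  groups <- list()
  for (ch in unique(track$chrom)) {
    q <- qual[track$chrom[qual] == ch]
    if (!length(q)) next
    q <- q[order(centers[q])]
    g <- list(q[1])
    for (i in seq_along(q)[-1]) {
      last <- g[[length(g)]]
      if (centers[q[i]] - centers[last[length(last)]] <= params$gap_bp)
        g[[length(g)]] <- c(last, q[i])
      else g[[length(g) + 1]] <- q[i]
    }
    groups <- c(groups, g)
  }
  groups <- Filter(function(g) length(g) >= params$min_enriched, groups)
  # members: every measured probe between the outermost enriched probes
  members <- lapply(groups, function(g) {
    ch <- track$chrom[g[1]]
    which(track$chrom == ch & centers >= min(centers[g]) &
            centers <= max(centers[g]))
  })
  # prolongation: repeated single passes until fixpoint
  repeat {
    changed <- FALSE
    for (k in seq_along(members)) {
      m <- members[[k]]
      ch <- track$chrom[m[1]]
      add <- which(track$chrom == ch & !(seq_len(n) %in% m) &
                     (abs(centers - min(centers[m])) <= params$prolong_bp |
                        abs(centers - max(centers[m])) <= params$prolong_bp))
      if (length(add)) {
        members[[k]] <- sort(c(m, add))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # merging: repeated pairwise union while any shortest distance < merge_bp
  repeat {
    done <- TRUE
    for (a in seq_along(members)) {
      for (b in seq_along(members)) {
        if (a >= b || is.null(members[[a]]) || is.null(members[[b]])) next
        ma <- members[[a]]; mb <- members[[b]]
        if (track$chrom[ma[1]] != track$chrom[mb[1]]) next
        sa <- min(track$start[ma]); ea <- max(track$end[ma])
        sb <- min(track$start[mb]); eb <- max(track$end[mb])
        dist <- max(sa, sb) - min(ea, eb)
        if (dist < params$merge_bp) {
          members[[a]] <- sort(union(ma, mb))
          members[[b]] <- NULL
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (done) break
  }
  members <- Filter(Negate(is.null), members)
  if (!length(members))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(members, function(m)
    data.frame(chrom = track$chrom[m[1]], start = min(track$start[m]),
               end = max(track$end[m]), n_probes = length(m),
               n_enriched = sum(track$z[m] >= params$z_enrich),
               idx = I(list(sort(m))), stringsAsFactors = FALSE)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# hypergeometric tails from first principles (binomial coefficients only)
oracle_hyper_tails <- function(k, K, n, N) {
  ks <- max(0, n - (N - K)):min(n, K)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  list(p_over = sum(pmf[ks >= k]), p_under = sum(pmf[ks <= k]),
       p_eq = if (k %in% ks) pmf[ks == k] else 0)
}

# naive O(n^2) windowed statistics for the signal oracle
oracle_window_mean <- function(track, half) {
  centers <- (track$start + track$end) / 2
  vapply(seq_len(nrow(track)), function(i) {
    sel <- track$chrom == track$chrom[i] &
      abs(centers - centers[i]) <= half
    mean(track$ratio[sel])
  }, numeric(1))
}

oracle_window_median <- function(probes, reps, bw) {
  centers <- (probes$start + probes$end) / 2
  vapply(seq_len(nrow(probes)), function(i) {
    sel <- probes$chrom == probes$chrom[i] &
      abs(centers - centers[i]) <= bw
    median(as.vector(reps[sel, , drop = FALSE]))
  }, numeric(1))
}
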