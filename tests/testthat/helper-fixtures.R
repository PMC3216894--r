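# small construction helpers shared across test files

# a signal_track built directly from probe start positions and values
make_track <- function(pos, z, ratio = z, chrom = "chr1", probe_len = 25L,
                       mark = "K4", sample_label = "normal") {
  stopifnot(length(pos) == length(z))
  chrom <- rep(chrom, length.out = length(pos))
  o <- order(chrom, pos)
  track <- data.frame(chrom = chrom[o],
                      start = as.integer(pos[o]),
                      end = as.integer(pos[o] + probe_len),
                      probe_id = sprintf("p%04d", seq_along(pos)),
                      ratio = ratio[o], z = z[o], stringsAsFactors = FALSE)
  attr(track, "mark") <- mark
  attr(track, "sample") <- sample_label
  class(track) <- c("signal_track", "data.frame")
  track
}

# an array_design wrapper around explicit probe starts (for signal tests)
make_design <- function(pos, chrom = "chr1", probe_len = 25L) {
  chrom <- rep(chrom, length.out = length(pos))
  o <- order(chrom, pos)
  probes <- data.frame(chrom = chrom[o],
                       start = as.integer(pos[o]),
                       end = as.integer(pos[o] + probe_len),
                       probe_id = sprintf("p%04d", seq_along(pos)),
                       stringsAsFactors = FALSE)
  structure(list(probes = probes, promoters = NULL), class = "array_design")
}

# a region row matching the caller's representation
make_region <- function(track, idx, id = "r1", z_enrich = 6) {
  idx <- sort(idx)
  data.frame(region_id = id, chrom = track$chrom[idx[1]],
             start = min(track$start[idx]), end = max(track$end[idx]),
             n_probes = length(idx),
             n_enriched = sum(track$z[idx] >= z_enrich),
             max_z = max(track$z[idx]), probe_idx = I(list(idx)),
             stringsAsFactors = FALSE)
}

# a truth_table with given states and no planted intervals (for the
# expression / methylation simulators, which only read the states)
make_truth <- function(genes, state_normal, state_tumor = state_normal) {
  structure(list(
    states = data.frame(geneSymbol = genes, state_normal = state_normal,
                        state_tumor = state_tumor, stringsAsFactors = FALSE),
    intervals = data.frame(geneSymbol = character(), condition = character(),
                           mark = character(), chrom = character(),
                           start = integer(), end = integer(),
                           fold_change = numeric(),
                           stringsAsFactors = FALSE)),
    class = "truth_table")
}

# random Z-score tracks exercising the region-caller boundaries: variable
# spacing (including gaps beyond the flank/gap rules), planted clusters, and
# values straddling the Z = 6 cut-off
random_track <- function(n, seed) {
  set.seed(seed)
  n_chrom <- sample(1:2, 1)
  pos <- c(); chrom <- c()
  for (ch in seq_len(n_chrom)) {
    m <- ceiling(n / n_chrom)
    sp <- sample(c(20, 35, 35, 35, 60, 90, 111, 150, 400), m, replace = TRUE)
    pos <- c(pos, cumsum(sp))
    chrom <- c(chrom, rep(paste0("chr", ch), m))
  }
  z <- rnorm(length(pos), 0, 2.5)
  n_clust <- sample(0:4, 1)
  for (k in seq_len(n_clust)) {
    i <- sample(length(pos), 1)
    len <- sample(1:6, 1)
    j <- i:min(i + len, length(pos))
    z[j] <- runif(length(j), 5.5, 10)  # straddles the cut-off
  }
  make_track(pos, z, chrom = chrom)
}
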