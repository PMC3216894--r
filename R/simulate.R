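#' Generate a synthetic promoter tiling-array design
#'
#' Emulates an Affymetrix-style promoter tiling array in which each promoter
#' is tiled from `upstream_span` bp upstream to `downstream_span` bp
#' downstream of its TSS (defaults 7.5 kb / 2.45 kb, transcription
#' orientation) with fixed-length probes at regular spacing. Promoters are
#' placed non-overlapping with at least `promoter_gap` bp between tiled
#' intervals so that region-to-gene annotation is unambiguous by default.
#'
#' With the default 35 bp spacing and 25 bp probes each promoter carries
#' `floor((upstream_span + downstream_span - probe_length) / probe_spacing) + 1`
#' probes (284 with the defaults); probes lie fully inside the tiled span.
#'
#' @param n_promoters Number of promoters (one transcript per gene symbol).
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the design (strand assignment) is a pure
#'   function of `(n_promoters, params, seed)`.
#' @param promoters_per_chrom Promoters placed per synthetic chromosome.
#' @return An object of class `array_design`: a list with `probes`
#'   (data.frame: chrom, start, end, probe_id; 0-based half-open, sorted) and
#'   `promoters` (data.frame: transcript_id, geneSymbol, chrom, strand,
#'   txStart, txEnd, tss, tile_start, tile_end).
#' @export
generate_array_design <- function(n_promoters, params = sim_params(),
                                  seed = 1L, promoters_per_chrom = 50L) {
  if (!is.numeric(n_promoters) || length(n_promoters) != 1L ||
      n_promoters < 1)
    stop("n_promoters must be a positive count")
  n_promoters <- as.integer(n_promoters)
  set.seed(seed)

  span <- params$upstream_span + params$downstream_span
  slot <- span + params$promoter_gap
  idx <- seq_len(n_promoters)
  chrom <- paste0("chr", (idx - 1L) %/% promoters_per_chrom + 1L)
  within <- (idx - 1L) %% promoters_per_chrom
  slot_start <- within * slot + 10000L
  strand <- sample(c("+", "-"), n_promoters, replace = TRUE)
  tss <- ifelse(strand == "+", slot_start + params$upstream_span,
                slot_start + params$downstream_span)
  tile_start <- slot_start
  tile_end <- slot_start + span
  gene_len <- 5000L
  txStart <- ifelse(strand == "+", tss, tss - gene_len)
  txEnd <- ifelse(strand == "+", tss + gene_len, tss)

  promoters <- data.frame(
    transcript_id = sprintf("TX%05d", idx),
    geneSymbol = sprintf("GENE%05d", idx),
    chrom = chrom, strand = strand,
    txStart = as.integer(txStart), txEnd = as.integer(txEnd),
    tss = as.integer(tss),
    tile_start = as.integer(tile_start), tile_end = as.integer(tile_end),
    stringsAsFactors = FALSE)

  n_per <- (span - params$probe_length) %/% params$probe_spacing + 1L
  offs <- (seq_len(n_per) - 1L) * params$probe_spacing
  starts <- rep(promoters$tile_start, each = n_per) + rep(offs, n_promoters)
  probes <- data.frame(
    chrom = rep(promoters$chrom, each = n_per),
    start = as.integer(starts),
    end = as.integer(starts + params$probe_length),
    stringsAsFactors = FALSE)
  o <- order(probes$chrom, probes$start)
  probes <- probes[o, , drop = FALSE]
  probes$probe_id <- sprintf("PR%07d", seq_len(nrow(probes)))
  rownames(probes) <- NULL

  structure(list(probes = probes, promoters = promoters, params = params),
            class = "array_design")
}

#' @export
print.array_design <- function(x, ...) {
  cat("array_design:", nrow(x$probes), "probes,",
      nrow(x$promoters), "promoters on",
      length(unique(x$probes$chrom)), "chromosome(s)\n")
  invisible(x)
}

.valid_states <- c("NONE", "K4", "K27", "BIV")

.state_marks <- function(state) {
  switch(state, NONE = character(), K4 = "K4", K27 = "K27",
         BIV = c("K4", "K27"), stop("unknown state: ", state))
}

#' Plant chromatin states on a design
#'
#' Builds the ground truth used by the ChIP simulator: for each promoter a
#' chromatin state per condition over the alphabet {NONE, K4, K27, BIV}, and
#' for every mark a planted enrichment interval centred on the TSS
#' (half-width `params$mark_halfwidth`) carrying `params$fold_change`. A
#' bivalent promoter gets identical K4 and K27 intervals, so they share all
#' their probes.
#'
#' @param design An `array_design`.
#' @param state_normal,state_tumor Character vectors (length `n_promoters`)
#'   of states in `{NONE, K4, K27, BIV}`.
#' @param params A [sim_params()].
#' @return A `truth_table`: list with `states` (geneSymbol, state_normal,
#'   state_tumor) and `intervals` (geneSymbol, condition, mark, chrom, start,
#'   end, fold_change).
#' @export
plant_states <- function(design, state_normal, state_tumor,
                         params = sim_params()) {
  pr <- design$promoters
  n <- nrow(pr)
  stopifnot(length(state_normal) == n, length(state_tumor) == n)
  if (!all(state_normal %in% .valid_states) ||
      !all(state_tumor %in% .valid_states))
    stop("states must be in {NONE, K4, K27, BIV}")

  states <- data.frame(geneSymbol = pr$geneSymbol,
                       state_normal = state_normal,
                       state_tumor = state_tumor,
                       stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    for (cond in c("normal", "tumor")) {
      st <- if (cond == "normal") state_normal[i] else state_tumor[i]
      for (mark in .state_marks(st)) {
        s <- pr$tss[i] - params$mark_halfwidth
        e <- pr$tss[i] + params$mark_halfwidth
        if (s < pr$tile_start[i] || e > pr$tile_end[i])
          stop("planted interval outside the tiled span for ",
               pr$geneSymbol[i])
        rows[[length(rows) + 1L]] <- data.frame(
          geneSymbol = pr$geneSymbol[i], condition = cond, mark = mark,
          chrom = pr$chrom[i], start = s, end = e,
          fold_change = params$fold_change, stringsAsFactors = FALSE)
      }
    }
  }
  intervals <- if (length(rows)) do.call(rbind, rows) else
    data.frame(geneSymbol = character(), condition = character(),
               mark = character(), chrom = character(), start = integer(),
               end = integer(), fold_change = numeric(),
               stringsAsFactors = FALSE)
  structure(list(states = states, intervals = intervals),
            class = "truth_table")
}

#' All valid normal-to-tumor state pairs
#'
#' The 16 ordered pairs over {NONE, K4, K27, BIV} minus (NONE, NONE): the 15
#' observable transitions.
#'
#' @return data.frame with columns `state_normal`, `state_tumor`.
#' @export
transition_pairs <- function() {
  g <- expand.grid(state_normal = .valid_states, state_tumor = .valid_states,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[!(g$state_normal == "NONE" & g$state_tumor == "NONE"), ]
  rownames(g) <- NULL
  g
}

#' Plant every transition type across a design
#'
#' Assigns each of the 15 valid (normal, tumor) state pairs to
#' `per_transition` promoters (in promoter order); remaining promoters are
#' unmarked in both conditions. This is the default stated world for
#' end-to-end recovery checks: marks stay sparse on the array so that
#' enriched windows can reach high Z-scores.
#'
#' @inheritParams plant_states
#' @param per_transition Promoters per transition type.
#' @return A `truth_table`.
#' @export
plant_transition_mix <- function(design, per_transition = 4L,
                                 params = sim_params()) {
  n <- nrow(design$promoters)
  tp <- transition_pairs()
  need <- nrow(tp) * per_transition
  if (need > n)
    stop("need at least ", need, " promoters for per_transition = ",
         per_transition)
  sn <- rep("NONE", n)
  st <- rep("NONE", n)
  sn[seq_len(need)] <- rep(tp$state_normal, each = per_transition)
  st[seq_len(need)] <- rep(tp$state_tumor, each = per_transition)
  plant_states(design, sn, st, params)
}

#' Simulate a ChIP-chip experiment
#'
#' Draws per-probe intensities for both marks and both conditions: two ChIP
#' replicates and two input replicates each. Background probe affinities are
#' log-normal (`bg_meanlog`, `bg_sdlog`), shared across all arrays of the
#' experiment (the same oligo hybridizes on every array); replicate noise is
#' multiplicative log-normal with sd `noise_sd` on the natural-log scale.
#' ChIP intensities of probes whose center lies inside a planted interval for
#' that mark and condition are multiplied by the interval's fold-change;
#' inputs carry background only.
#'
#' @param design An `array_design`.
#' @param truth A `truth_table`; all intervals must lie within the tiled
#'   span of their promoter's chromosome probes.
#' @param params A [sim_params()].
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return Nested list `res[[condition]][[mark]]`: data.frame with columns
#'   probe_id, chip_rep1, chip_rep2, input_rep1, input_rep2.
#' @export
simulate_chip_experiment <- function(design, truth, params = sim_params(),
                                     seed = 1L) {
  probes <- design$probes
  centers <- (probes$start + probes$end) / 2
  iv <- truth$intervals
  if (nrow(iv)) {
    pr <- design$promoters
    m <- match(iv$geneSymbol, pr$geneSymbol)
    if (anyNA(m)) stop("truth interval for unknown geneSymbol")
    bad <- iv$start < pr$tile_start[m] | iv$end > pr$tile_end[m] |
      iv$chrom != pr$chrom[m]
    if (any(bad))
      stop("truth interval outside the tiled span: ",
           paste(unique(iv$geneSymbol[bad]), collapse = ", "))
  }
  set.seed(seed)
  n <- nrow(probes)
  affinity <- exp(rnorm(n, params$bg_meanlog, params$bg_sdlog))

  fc_for <- function(cond, mark) {
    fc <- rep(1, n)
    sel <- iv$condition == cond & iv$mark == mark
    if (any(sel)) {
      sub <- iv[sel, , drop = FALSE]
      for (j in seq_len(nrow(sub))) {
        hit <- probes$chrom == sub$chrom[j] &
          centers >= sub$start[j] & centers < sub$end[j]
        fc[hit] <- pmax(fc[hit], sub$fold_change[j])
      }
    }
    fc
  }

  out <- list()
  for (cond in c("normal", "tumor")) {
    out[[cond]] <- list()
    for (mark in c("K4", "K27")) {
      fc <- fc_for(cond, mark)
      draw <- function(mult) mult * exp(rnorm(n, 0, params$noise_sd))
      out[[cond]][[mark]] <- data.frame(
        probe_id = probes$probe_id,
        chip_rep1 = affinity * fc * draw(1),
        chip_rep2 = affinity * fc * draw(1),
        input_rep1 = affinity * draw(1),
        input_rep2 = affinity * draw(1),
        stringsAsFactors = FALSE)
    }
  }
  out
}

#' Simulate paired normal/tumor expression
#'
#' Baseline log2 expression depends on the planted normal-condition state:
#' K4-marked genes are expressed above the array average, K27 and bivalent
#' genes are low, unmarked genes intermediate. A per-gene tumor shift
#' (`effects`, log2 units) models hyperactivation or hypersilencing. Columns
#' come in patient pairs (one normal, one tumor per patient) with a matching
#' sample sheet.
#'
#' @param truth A `truth_table`.
#' @param n_pairs Number of patients (default from `params`).
#' @param effects Named numeric vector of per-gene tumor log2 shifts; names
#'   must be gene symbols present in `truth`. Genes not named shift by 0.
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @param baseline Named numeric: baseline log2 expression per normal state.
#' @return List with `expr` (genes x samples matrix, log2 scale) and
#'   `samples` (data.frame: sample_id, patient_id, condition).
#' @export
simulate_expression <- function(truth, n_pairs = NULL, effects = NULL,
                                params = sim_params(), seed = 1L,
                                baseline = c(NONE = 6, K4 = 8, K27 = 4,
                                             BIV = 4)) {
  if (is.null(n_pairs)) n_pairs <- params$n_pairs
  if (n_pairs < 2) stop("n_pairs must be at least 2")
  st <- truth$states
  genes <- st$geneSymbol
  shift <- setNames(rep(0, length(genes)), genes)
  if (!is.null(effects) && length(effects)) {
    if (is.null(names(effects)) || !all(names(effects) %in% genes))
      stop("effects must be named by gene symbols present in the truth table")
    shift[names(effects)] <- effects
  }
  set.seed(seed)
  mu <- baseline[st$state_normal] + rnorm(length(genes), 0, 0.5)
  patient <- rnorm(n_pairs, 0, 0.3)
  samples <- data.frame(
    sample_id = paste0(sprintf("P%02d", rep(seq_len(n_pairs), each = 2)),
                       "_", rep(c("normal", "tumor"), n_pairs)),
    patient_id = sprintf("P%02d", rep(seq_len(n_pairs), each = 2)),
    condition = rep(c("normal", "tumor"), n_pairs),
    stringsAsFactors = FALSE)
  expr <- matrix(0, nrow = length(genes), ncol = nrow(samples),
                 dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    tumor <- samples$condition[j] == "tumor"
    expr[, j] <- mu + patient[match(samples$patient_id[j],
                                    sprintf("P%02d", seq_len(n_pairs)))] +
      (if (tumor) shift else 0) +
      rnorm(length(genes), 0, params$expr_noise_sd)
  }
  list(expr = expr, samples = samples)
}

#' Simulate a hypermethylated-gene list
#'
#' Samples genes into a hypermethylated set at the background rate
#' `params$meth_base_rate`, except genes carrying the K27 mark (K27 or BIV
#' state) in the normal condition, which are sampled at `enrichment_factor`
#' times that rate (capped at 1).
#'
#' @param truth A `truth_table`.
#' @param enrichment_factor Rate multiplier for K27-marked genes; must be
#'   >= 1 (1 = null).
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return Character vector of hypermethylated gene symbols.
#' @export
simulate_methylation_set <- function(truth, enrichment_factor = 5,
                                     params = sim_params(), seed = 1L) {
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  st <- truth$states
  if (nrow(st) == 0L) return(character())
  k27 <- st$state_normal %in% c("K27", "BIV")
  p <- pmin(1, params$meth_base_rate * ifelse(k27, enrichment_factor, 1))
  set.seed(seed)
  st$geneSymbol[runif(nrow(st)) < p]
}
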