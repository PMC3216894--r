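#' Default tumor expression shifts from a truth table
#'
#' The observed coupling between chromatin transitions and expression:
#' genes carrying H3K4me3 in the tumor are hyperactivated (positive log2
#' shift), genes carrying H3K27me3 (or bivalency) in the tumor are
#' hypersilenced (negative shift), unmarked genes do not move.
#'
#' @param truth A `truth_table`.
#' @param k4_shift,k27_shift Log2 shifts (defaults +1 / -1).
#' @return Named numeric vector of per-gene shifts.
#' @export
default_expression_effects <- function(truth, k4_shift = 1, k27_shift = -1) {
  st <- truth$states
  shift <- ifelse(st$state_tumor == "K4", k4_shift,
                  ifelse(st$state_tumor %in% c("K27", "BIV"), k27_shift, 0))
  stats::setNames(shift, st$geneSymbol)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates a promoter tiling design with planted chromatin-state
#' transitions, simulates the ChIP-chip experiment (both marks, both
#' conditions, two ChIP and two input replicates each), processes the signal
#' (quantile normalization to median 200, sliding-window replicate merging,
#' log2 ratios, windowed Z-scores), calls enriched regions, detects bivalent
#' regions, classifies normal-to-tumor transitions, annotates regions to the
#' synthetic transcripts, and runs the expression/methylation statistics.
#' Deterministic given `seed`; when `out_dir` is set, every stage's tables
#' are written (bedGraph/BED/TSV) together with a JSON manifest of all
#' parameter values.
#'
#' @param n_promoters Number of simulated promoters.
#' @param seed Integer seed driving every stochastic stage.
#' @param per_transition Promoters planted per transition type (the 15
#'   valid state pairs); remaining promoters stay unmarked.
#' @param sim,signal,region,state,annotation,stat Parameter objects
#'   ([sim_params()], [signal_params()], [region_params()],
#'   [state_params()], [annotation_params()], [stats_params()]).
#' @param meth_factor Hypermethylation enrichment factor for K27 genes.
#' @param out_dir Optional output directory.
#' @return List with design, truth, tracks, regions, bivalent, loci,
#'   transitions, links, gene_status, gene_transitions, expression, de,
#'   group_overlap, methylation, recovery.
#' @export
run_pipeline <- function(n_promoters = 200L, seed = 1L, per_transition = 4L,
                         sim = sim_params(), signal = signal_params(),
                         region = region_params(), state = state_params(),
                         annotation = annotation_params(),
                         stat = stats_params(), meth_factor = 5,
                         out_dir = NULL) {
  design <- generate_array_design(n_promoters, sim, seed = seed)
  truth <- plant_transition_mix(design, per_transition, sim)
  raw <- simulate_chip_experiment(design, truth, sim, seed = seed + 1L)

  tracks <- list(); regions <- list(); biv <- list()
  for (cond in c("normal", "tumor")) {
    tracks[[cond]] <- list(); regions[[cond]] <- list()
    for (mark in c("K4", "K27")) {
      tracks[[cond]][[mark]] <- build_signal_track(
        design, raw[[cond]][[mark]], signal, mark = mark,
        sample_label = cond)
      regions[[cond]][[mark]] <- call_enriched_regions(
        tracks[[cond]][[mark]], region)
    }
    biv[[cond]] <- find_bivalent_regions(
      regions[[cond]]$K4, regions[[cond]]$K27, tracks[[cond]]$K4,
      tracks[[cond]]$K27, state, z_enrich = region$z_enrich)
  }

  loci <- build_loci(regions)
  states_n <- assign_locus_states(loci, biv$normal, "normal")
  states_t <- assign_locus_states(loci, biv$tumor, "tumor")
  transitions <- classify_transitions(loci, states_n, states_t, tracks,
                                      state, z_enrich = region$z_enrich)

  all_regions <- do.call(rbind, lapply(c("normal", "tumor"), function(cond)
    do.call(rbind, lapply(c("K4", "K27"), function(mark)
      regions[[cond]][[mark]][, c("region_id", "chrom", "start", "end")]))))
  links <- associate_regions(all_regions, design$promoters, annotation)

  gene_status <- list()
  for (cond in c("normal", "tumor")) {
    lk <- list()
    for (mark in c("K4", "K27")) {
      l <- associate_regions(regions[[cond]][[mark]], design$promoters,
                             annotation)
      if (nrow(l)) l$mark <- mark
      lk[[mark]] <- l
    }
    bl <- associate_regions(
      cbind(data.frame(region_id = biv[[cond]]$biv_id),
            biv[[cond]][, c("chrom", "start", "end")]),
      design$promoters, annotation)
    if (nrow(bl)) bl$mark <- "BIV"
    lk$BIV <- bl
    lk <- do.call(rbind, lk[vapply(lk, nrow, integer(1)) > 0])
    gene_status[[cond]] <- if (is.null(lk))
      classify_genes(data.frame(geneSymbol = character(),
                                region_id = character(), mark = character(),
                                stringsAsFactors = FALSE),
                     design$promoters$geneSymbol)
    else classify_genes(lk, design$promoters$geneSymbol)
  }

  gene_trans <- gene_level_transitions(transitions, links, loci)

  effects <- default_expression_effects(truth)
  expression <- simulate_expression(truth, params = sim, effects = effects,
                                    seed = seed + 2L)
  de <- differential_expression(expression$expr, expression$samples, stat)

  universe <- truth$states$geneSymbol
  ok <- gene_trans[gene_trans$status == "ok", , drop = FALSE]
  groups <- split(ok$geneSymbol, paste(ok$state_normal, ok$state_tumor,
                                       sep = "->"))
  groups <- lapply(groups, unique)
  group_overlap <- do.call(rbind, lapply(names(groups), function(g) {
    up <- group_overlap_test(groups[[g]], de$up, universe)
    down <- group_overlap_test(groups[[g]], de$down, universe)
    data.frame(group = g, n_genes = length(groups[[g]]),
               p_over_up = up$p_over, p_under_up = up$p_under,
               p_over_down = down$p_over, p_under_down = down$p_under,
               stringsAsFactors = FALSE)
  }))

  hypermeth <- simulate_methylation_set(truth, meth_factor, sim,
                                        seed = seed + 3L)
  meth_groups <- groups[vapply(groups, length, integer(1)) > 0]
  methylation <- if (length(meth_groups))
    methylation_overlap_test(meth_groups, hypermeth, universe, stat)
  else NULL

  recovery <- evaluate_recovery(gene_trans, truth)

  res <- list(design = design, truth = truth, tracks = tracks,
              regions = regions, bivalent = biv, loci = loci,
              transitions = transitions, links = links,
              gene_status = gene_status, gene_transitions = gene_trans,
              expression = expression, de = de,
              group_overlap = group_overlap, hypermeth = hypermeth,
              methylation = methylation, recovery = recovery,
              seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir, sim, signal,
                                                region, state, annotation,
                                                stat)
  res
}

#' Compare recovered gene states with the planted truth
#'
#' A gene is recovered when its called (normal, tumor) state pair equals the
#' planted pair: genes absent from the transition table must be planted
#' unmarked in both conditions; genes present must have a unique, resolved
#' (`status == "ok"`) state pair equal to the planted one.
#'
#' @param gene_trans Table from [gene_level_transitions()].
#' @param truth A `truth_table`.
#' @return List with `table` (per-gene planted/called/correct) and
#'   `accuracy` (fraction recovered over all genes).
#' @export
evaluate_recovery <- function(gene_trans, truth) {
  st <- truth$states
  called_n <- called_t <- rep("NONE", nrow(st))
  status <- rep("ok", nrow(st))
  for (i in seq_len(nrow(st))) {
    sub <- gene_trans[gene_trans$geneSymbol == st$geneSymbol[i], ,
                      drop = FALSE]
    if (!nrow(sub)) next
    pairs <- unique(paste(sub$state_normal, sub$state_tumor))
    if (length(pairs) > 1L) {
      status[i] <- "ambiguous"
      called_n[i] <- called_t[i] <- NA_character_
    } else {
      called_n[i] <- sub$state_normal[1L]
      called_t[i] <- sub$state_tumor[1L]
      if (any(sub$status != "ok")) status[i] <- sub$status[1L]
    }
  }
  correct <- !is.na(called_n) & status == "ok" &
    called_n == st$state_normal & called_t == st$state_tumor
  tab <- data.frame(geneSymbol = st$geneSymbol,
                    planted_normal = st$state_normal,
                    planted_tumor = st$state_tumor,
                    called_normal = called_n, called_tumor = called_t,
                    status = status, correct = correct,
                    stringsAsFactors = FALSE)
  list(table = tab, accuracy = mean(correct))
}

#' Write pipeline outputs and a manifest
#'
#' @param res Result list from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @param sim,signal,region,state,annotation,stat The parameter objects of
#'   the run.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir, sim = sim_params(),
                                   signal = signal_params(),
                                   region = region_params(),
                                   state = state_params(),
                                   annotation = annotation_params(),
                                   stat = stats_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list(probes = nrow(res$design$probes),
                 promoters = nrow(res$design$promoters))
  for (cond in c("normal", "tumor")) {
    for (mark in c("K4", "K27")) {
      tr <- res$tracks[[cond]][[mark]]
      write_bedgraph(tr, file.path(out_dir,
                                   sprintf("%s_%s_log2ratio.bedgraph",
                                           mark, cond)), value = "ratio")
      write_bedgraph(tr, file.path(out_dir,
                                   sprintf("%s_%s_zscore.bedgraph",
                                           mark, cond)), value = "z")
      write_regions_bed(res$regions[[cond]][[mark]],
                        file.path(out_dir, sprintf("%s_%s_regions.bed",
                                                   mark, cond)))
      counts[[sprintf("regions_%s_%s", mark, cond)]] <-
        nrow(res$regions[[cond]][[mark]])
    }
    bv <- res$bivalent[[cond]]
    write_regions_bed(
      data.frame(region_id = bv$biv_id, chrom = bv$chrom, start = bv$start,
                 end = bv$end, max_z = 10, stringsAsFactors = FALSE),
      file.path(out_dir, sprintf("bivalent_%s.bed", cond)))
    counts[[sprintf("bivalent_%s", cond)]] <- nrow(bv)
    write_tsv(res$gene_status[[cond]],
              file.path(out_dir, sprintf("gene_status_%s.tsv", cond)))
  }
  write_tsv(res$transitions, file.path(out_dir, "transitions.tsv"))
  write_tsv(res$gene_transitions, file.path(out_dir,
                                            "gene_transitions.tsv"))
  write_tsv(res$de$table, file.path(out_dir, "differential_expression.tsv"))
  if (!is.null(res$group_overlap))
    write_tsv(res$group_overlap, file.path(out_dir, "group_overlap.tsv"))
  if (!is.null(res$methylation))
    write_tsv(res$methylation, file.path(out_dir,
                                         "methylation_overlap.tsv"))
  write_tsv(res$recovery$table, file.path(out_dir, "recovery.tsv"))
  counts$loci <- nrow(res$loci)
  counts$transitions_ok <- sum(res$transitions$status == "ok")
  counts$recovery_accuracy <- res$recovery$accuracy
  manifest <- list(seed = res$seed, counts = counts,
                   params = list(sim = unclass(sim),
                                 signal = unclass(signal),
                                 region = unclass(region),
                                 state = unclass(state),
                                 annotation = unclass(annotation),
                                 stats = unclass(stat)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
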