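#' Validate and complete a transcript table
#'
#' @param transcripts Data.frame with columns transcript_id, geneSymbol,
#'   chrom, strand, txStart, txEnd and optionally tss (knownGene-like,
#'   0-based txStart). A missing tss column is derived as txStart on `+` and
#'   txEnd on `-`.
#' @return The table with a tss column.
#' @export
prepare_transcripts <- function(transcripts) {
  need <- c("transcript_id", "geneSymbol", "chrom", "strand", "txStart",
            "txEnd")
  if (!all(need %in% names(transcripts)))
    stop("transcript table must have columns ", paste(need, collapse = ", "))
  if (any(transcripts$txStart >= transcripts$txEnd))
    stop("txStart must be < txEnd")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (is.null(transcripts$tss))
    transcripts$tss <- ifelse(transcripts$strand == "+", transcripts$txStart,
                              transcripts$txEnd)
  bad <- transcripts$tss < transcripts$txStart |
    transcripts$tss > transcripts$txEnd
  if (any(bad))
    stop("tss outside [txStart, txEnd] for ",
         paste(transcripts$transcript_id[bad], collapse = ", "))
  transcripts
}

#' Associate enriched regions with transcripts
#'
#' Two strand-aware rules, evaluated per transcript with the region's
#' nearest edge:
#' (i) *intragenic*: the region overlaps the transcript body
#' `[txStart, txEnd)` by at least 1 bp and begins no more than `window_bp`
#' downstream of the TSS (in transcription orientation; a region spanning
#' the TSS qualifies);
#' (ii) *upstream*: the region overlaps no transcript body at all and ends
#' within `window_bp` upstream of the TSS. A region that is intragenic
#' anywhere never links through rule (ii) — intragenic positioning takes
#' priority. A region may link to several transcripts.
#'
#' @param regions Region data.frame (needs region_id, chrom, start, end).
#' @param transcripts Transcript table (see [prepare_transcripts()]).
#' @param params An [annotation_params()] (default window 2500 bp each way).
#' @return Data.frame of links: region_id, transcript_id, geneSymbol, rule
#'   (`"intragenic"` or `"upstream"`).
#' @export
associate_regions <- function(regions, transcripts,
                              params = annotation_params()) {
  tx <- prepare_transcripts(transcripts)
  w <- params$window_bp
  out <- list()
  for (k in seq_len(nrow(regions))) {
    ch <- regions$chrom[k]; rs <- regions$start[k]; re <- regions$end[k]
    same <- tx[tx$chrom == ch, , drop = FALSE]
    if (!nrow(same)) next
    body <- same$txStart < re & same$txEnd > rs
    plus <- same$strand == "+"
    # distance of the region's near edge downstream of the TSS (<= 0 when
    # the region starts at or upstream of the TSS)
    down <- ifelse(plus, rs - same$tss, same$tss - re)
    rule_i <- body & down <= w
    linked <- which(rule_i)
    rule <- rep("intragenic", length(linked))
    if (!any(body)) {
      up <- ifelse(plus, same$tss - re, rs - same$tss)
      rule_ii <- up >= 0 & up <= w
      linked <- which(rule_ii)
      rule <- rep("upstream", length(linked))
    }
    if (length(linked))
      out[[length(out) + 1L]] <- data.frame(
        region_id = regions$region_id[k],
        transcript_id = same$transcript_id[linked],
        geneSymbol = same$geneSymbol[linked],
        rule = rule, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(region_id = character(), transcript_id = character(),
                      geneSymbol = character(), rule = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify genes by their associated marks
#'
#' From region-transcript links labelled with the region's mark, each gene
#' symbol is classified as: BIVALENT if associated with at least one
#' bivalent region; SEMI_BIVALENT if associated with both an H3K4me3 and an
#' H3K27me3 region but no bivalent region; K4 or K27 if associated with only
#' that mark; NONE otherwise (only reported for genes in `universe`).
#'
#' @param links Data.frame with columns geneSymbol, region_id, mark (values
#'   in `K4`, `K27`, `BIV`).
#' @param universe Optional character vector of all gene symbols; genes with
#'   no links are reported as NONE.
#' @return Data.frame: geneSymbol, status, region_ids (comma-collapsed).
#' @export
classify_genes <- function(links, universe = NULL) {
  genes <- unique(links$geneSymbol)
  res <- lapply(genes, function(g) {
    sub <- links[links$geneSymbol == g, , drop = FALSE]
    marks <- unique(sub$mark)
    status <- if ("BIV" %in% marks) "BIVALENT"
    else if (all(c("K4", "K27") %in% marks)) "SEMI_BIVALENT"
    else if (identical(marks, "K4")) "K4"
    else if (identical(marks, "K27")) "K27"
    else "NONE"
    data.frame(geneSymbol = g, status = status,
               region_ids = paste(sort(unique(sub$region_id)),
                                  collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- if (length(res)) do.call(rbind, res) else
    data.frame(geneSymbol = character(), status = character(),
               region_ids = character(), stringsAsFactors = FALSE)
  if (!is.null(universe)) {
    missing <- setdiff(universe, res$geneSymbol)
    if (length(missing))
      res <- rbind(res, data.frame(geneSymbol = missing, status = "NONE",
                                   region_ids = "", stringsAsFactors = FALSE))
    res <- res[order(res$geneSymbol), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Gene-level transition table
#'
#' Each gene symbol inherits the classified transitions of every locus
#' linked to any of its transcripts. Genes linked to loci with conflicting
#' state pairs report all of them, flagged ambiguous.
#'
#' @param transitions Locus-level table from [classify_transitions()].
#' @param links Region-transcript links carrying region_id and geneSymbol.
#' @param loci Data.frame from [build_loci()] (maps region ids to loci).
#' @return Data.frame: geneSymbol, locus_id, state_normal, state_tumor,
#'   category, status, ambiguous.
#' @export
gene_level_transitions <- function(transitions, links, loci) {
  region2locus <- do.call(rbind, lapply(seq_len(nrow(loci)), function(k) {
    data.frame(region_id = loci$members[[k]]$region_id,
               locus_id = loci$locus_id[k], stringsAsFactors = FALSE)
  }))
  if (is.null(region2locus))
    region2locus <- data.frame(region_id = character(),
                               locus_id = character(),
                               stringsAsFactors = FALSE)
  m <- merge(links, region2locus, by = "region_id")
  m <- unique(m[, c("geneSymbol", "locus_id")])
  tab <- merge(m, transitions[, c("locus_id", "state_normal", "state_tumor",
                                  "category", "status")], by = "locus_id")
  if (!nrow(tab))
    return(data.frame(geneSymbol = character(), locus_id = character(),
                      state_normal = character(), state_tumor = character(),
                      category = character(), status = character(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  tab <- tab[order(tab$geneSymbol, tab$locus_id),
             c("geneSymbol", "locus_id", "state_normal", "state_tumor",
               "category", "status")]
  pair <- paste(tab$state_normal, tab$state_tumor)
  n_distinct <- tapply(pair, tab$geneSymbol, function(x) length(unique(x)))
  tab$ambiguous <- n_distinct[tab$geneSymbol] > 1L
  rownames(tab) <- NULL
  tab
}
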