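#' Read a bedGraph file
#'
#' 4-column bedGraph (chrom, start, end, value), 0-based half-open, optional
#' `track`/`#` header lines. Malformed lines are reported with their line
#' number.
#'
#' @param path File path.
#' @param design Optional `array_design`; when given, every interval must
#'   match a design probe by (chrom, start) and values are returned aligned
#'   to the design probe order (with NA for probes absent from the file).
#' @return Data.frame chrom, start, end, value (or, with a design, also
#'   probe_id, aligned to the design).
#' @export
read_bedgraph <- function(path, design = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 4L)
  if (length(bad))
    stop("malformed bedGraph line ", lineno[bad[1L]], " in ", path)
  df <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 1L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, character(1),
                                               2L))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, character(1),
                                             3L))),
    value = suppressWarnings(as.numeric(vapply(fields, `[[`, character(1),
                                               4L))),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value) |
                 df$start < 0 | df$end <= df$start)
  if (length(bad))
    stop("malformed bedGraph line ", lineno[bad[1L]], " in ", path)
  if (is.null(design)) return(df)
  key <- paste(df$chrom, df$start)
  dkey <- paste(design$probes$chrom, design$probes$start)
  unknown <- which(!key %in% dkey)
  if (length(unknown))
    stop("bedGraph interval not on the design: line ", lineno[unknown[1L]])
  m <- match(dkey, key)
  out <- design$probes
  out$value <- df$value[m]
  out
}

#' Write a value track as bedGraph
#'
#' @param track Data.frame with chrom, start, end and the value column.
#' @param path Output path.
#' @param value Name of the value column (default `"value"`).
#' @param digits Decimal digits written (default 6).
#' @export
write_bedgraph <- function(track, path, value = "value", digits = 6L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                     formatC(track[[value]], digits = digits,
                             format = "f")), con)
  invisible(path)
}

#' Write regions as BED6
#'
#' name = region id, score = `max_z * 100` capped at 1000, strand = ".".
#' Starts with a header comment; an empty region set writes only the header.
#'
#' @param regions Region data.frame.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(regions)) {
    o <- order(regions$chrom, regions$start)
    r <- regions[o, , drop = FALSE]
    score <- pmin(1000, round(r$max_z * 100))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", r$chrom, r$start, r$end,
                       r$region_id, as.integer(score)), con)
  }
  invisible(path)
}

#' Read a BED6 region file written by [write_regions_bed()]
#'
#' @param path File path.
#' @return Data.frame: chrom, start, end, region_id, score, strand.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  if (!any(keep))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), region_id = character(),
                      score = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) != 6L))
    stop("malformed BED6 line in ", path)
  data.frame(chrom = vapply(fields, `[[`, character(1), 1L),
             start = as.integer(vapply(fields, `[[`, character(1), 2L)),
             end = as.integer(vapply(fields, `[[`, character(1), 3L)),
             region_id = vapply(fields, `[[`, character(1), 4L),
             score = as.integer(vapply(fields, `[[`, character(1), 5L)),
             strand = vapply(fields, `[[`, character(1), 6L),
             stringsAsFactors = FALSE)
}

#' Tab-delimited table I/O
#'
#' Plain TSV with a header row, UTF-8, `"."` for missing values — the
#' interchange format of all pipeline tables.
#'
#' @param x Data.frame to write.
#' @param path File path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
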