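# Readers/writers for the plain-text formats the pipeline touches:
# FASTA, chrom.sizes, BED3/BED6, ENCODE narrowPeak, and TSV reports.
# BED-family files are 0-based half-open on disk; in memory intervals are
# GRanges (1-based closed). The conversion start1 = start0 + 1, end1 = end0
# is exact and preserves half-open adjacency: [0,10) and [10,20) become
# [1,10] and [11,20], which do not overlap.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AA_AMBIG <- c("X", "B", "Z", "U")

.stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

.is_int_str <- function(x) grepl("^-?[0-9]+$", x)

#' Read a chrom.sizes file into a Seqinfo genome
#'
#' Parses a two-column, tab-separated chromosome-size table (the UCSC
#' `chrom.sizes` convention) into a [GenomeInfoDb::Seqinfo] object, the
#' genome reference against which peak sets are validated and randomized.
#'
#' @param path Path to a two-column tab-separated file: chromosome name,
#'   length in bp.
#' @return A [GenomeInfoDb::Seqinfo] with one entry per chromosome.
#' @examples
#' f <- tempfile(fileext = ".chrom.sizes")
#' writeLines("chr2R\t25286936", f)
#' read_chrom_sizes(f)
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    .stop_fmt("chrom.sizes file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2L)
      .stop_fmt("chrom.sizes line %d: expected 2 tab-separated columns", i)
    if (!.is_int_str(f[2L]))
      .stop_fmt("chrom.sizes line %d: length '%s' is not an integer", i, f[2L])
  }
  nm <- vapply(fields, `[`, "", 1L)
  len <- as.numeric(vapply(fields, `[`, "", 2L))
  if (any(len <= 0))
    .stop_fmt("chrom.sizes line %d: non-positive length",
              which(len <= 0)[1L])
  if (anyDuplicated(nm))
    .stop_fmt("duplicate chromosome name '%s' in '%s'",
              nm[duplicated(nm)][1L], path)
  GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = len)
}

#' Write a Seqinfo genome as a chrom.sizes file
#'
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  genome <- .as_seqinfo(genome)
  writeLines(paste(GenomeInfoDb::seqnames(genome),
                   GenomeInfoDb::seqlengths(genome), sep = "\t"), path)
  invisible(path)
}

# accept a Seqinfo or a named vector of lengths
.as_seqinfo <- function(genome) {
  if (is(genome, "Seqinfo")) return(genome)
  if (is.numeric(genome) && !is.null(names(genome)))
    return(GenomeInfoDb::Seqinfo(seqnames = names(genome),
                                 seqlengths = unname(genome)))
  stop("'genome' must be a Seqinfo or a named vector of chromosome lengths",
       call. = FALSE)
}

#' Read protein sequences from a FASTA file
#'
#' Record identifiers are the header token up to the first whitespace;
#' sequences are upper-cased and a single trailing stop symbol `*` is
#' stripped. Residues outside the 20 standard amino acids plus the
#' ambiguity codes X, B, Z and U are rejected with the offending record
#' and position named.
#'
#' @param path Path to a text FASTA file (records may be wrapped).
#' @return A named [Biostrings::AAStringSet], in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 some description", "PKV", "WL"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    .stop_fmt("FASTA file '%s' contains no records", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    .stop_fmt("duplicate FASTA identifier '%s'", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*$", "", seqs)
  allowed <- paste0(c(.AA20, .AA_AMBIG), collapse = "")
  bad <- regexpr(sprintf("[^%s]", allowed), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    .stop_fmt("record '%s': invalid residue '%s' at position %d",
              ids[i], substr(seqs[i], bad[i], bad[i]), bad[i])
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs A named [Biostrings::AAStringSet] (or named character
#'   vector) of amino-acid sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read ChIP-seq peak calls from a BED-family file
#'
#' Supports BED3, BED6 and the 10-column ENCODE narrowPeak format. For
#' narrowPeak, the per-peak `height` is the signalValue (column 7) and the
#' summit is `start + peak offset` (column 10), with offset `-1` imputed
#' as the interval midpoint (floored). For BED6 the score column is taken
#' as the height; BED3 peaks have no height. Coordinates on disk are
#' 0-based half-open and are converted to 1-based closed GRanges.
#'
#' @param path Path to a tab-separated peak file.
#' @param genome Optional [GenomeInfoDb::Seqinfo] (or named length
#'   vector). When supplied, a peak on an unknown chromosome or extending
#'   past a chromosome end is an error, never silently dropped.
#' @param dialect One of `"narrowPeak"`, `"bed6"`, `"bed3"`.
#' @return A [GenomicRanges::GRanges], sorted by position, with metadata
#'   columns `name`, `height` (numeric, `NA` for BED3) and `summit`
#'   (1-based absolute coordinate, `NA` for BED3/BED6).
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr2R\t100\t200\tp\t0\t.\t3.5\t-1\t-1\t40", f)
#' read_peaks(f, dialect = "narrowPeak")
#' @export
read_peaks <- function(path, genome = NULL,
                       dialect = c("narrowPeak", "bed6", "bed3")) {
  if (length(dialect) == 1L &&
      !dialect %in% c("narrowPeak", "bed6", "bed3"))
    .stop_fmt("unknown peak dialect '%s'", dialect)
  dialect <- match.arg(dialect)
  ncol_need <- c(narrowPeak = 10L, bed6 = 6L, bed3 = 3L)[[dialect]]
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)

  n <- length(fields)
  chrom <- character(n); s0 <- integer(n); e0 <- integer(n)
  nm <- rep(NA_character_, n); height <- rep(NA_real_, n)
  summit0 <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < ncol_need)
      .stop_fmt("%s line %d: expected %d columns, found %d",
                dialect, lineno[i], ncol_need, length(f))
    if (!.is_int_str(f[2L]) || !.is_int_str(f[3L]))
      .stop_fmt("%s line %d: non-integer coordinates", dialect, lineno[i])
    s0[i] <- as.integer(f[2L]); e0[i] <- as.integer(f[3L])
    if (s0[i] >= e0[i])
      .stop_fmt("%s line %d: start (%d) must be < end (%d)",
                dialect, lineno[i], s0[i], e0[i])
    chrom[i] <- f[1L]
    if (dialect != "bed3") nm[i] <- f[4L]
    if (dialect == "bed6") {
      height[i] <- suppressWarnings(as.numeric(f[5L]))
    } else if (dialect == "narrowPeak") {
      height[i] <- suppressWarnings(as.numeric(f[7L]))
      if (!.is_int_str(f[10L]))
        .stop_fmt("narrowPeak line %d: non-integer peak offset", lineno[i])
      off <- as.integer(f[10L])
      if (off < -1L || (off != -1L && off >= e0[i] - s0[i]))
        .stop_fmt("narrowPeak line %d: peak offset %d outside interval",
                  lineno[i], off)
      summit0[i] <- if (off == -1L)
        s0[i] + (e0[i] - s0[i]) %/% 2L else s0[i] + off
    }
  }

  gr <- GenomicRanges::GRanges(
    seqnames = if (n) chrom else character(),
    ranges = IRanges::IRanges(start = s0 + 1L, end = e0))
  S4Vectors::mcols(gr)$name <- nm
  S4Vectors::mcols(gr)$height <- height
  S4Vectors::mcols(gr)$summit <- summit0 + 1L
  if (!is.null(genome)) gr <- .bind_genome(gr, .as_seqinfo(genome), path)
  sort(gr)
}

# attach a Seqinfo to peaks, erroring on unknown chromosomes / overhangs
.bind_genome <- function(gr, si, path = "peaks") {
  unknown <- setdiff(as.character(unique(GenomicRanges::seqnames(gr))),
                     GenomeInfoDb::seqnames(si))
  if (length(unknown))
    .stop_fmt("'%s' has peaks on chromosome '%s' absent from the genome",
              path, unknown[1L])
  lens <- GenomeInfoDb::seqlengths(si)[as.character(
    GenomicRanges::seqnames(gr))]
  over <- which(GenomicRanges::end(gr) > lens)
  if (length(over))
    .stop_fmt("'%s': peak %d extends past the end of its chromosome",
              path, over[1L])
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(si)
  GenomeInfoDb::seqinfo(gr) <- si
  gr
}

#' Write peaks to a BED-family file
#'
#' Inverse of [read_peaks()]: `read_peaks(write_peaks(x))` reproduces `x`
#' field for field. For narrowPeak, missing heights are written as 0 and
#' summits as explicit offsets (never `-1`), so imputed midpoints survive
#' the round trip.
#'
#' @param peaks A [GenomicRanges::GRanges] as returned by [read_peaks()]
#'   or the generators.
#' @param path Output path.
#' @param dialect One of `"narrowPeak"`, `"bed6"`, `"bed3"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path,
                        dialect = c("narrowPeak", "bed6", "bed3")) {
  dialect <- match.arg(dialect)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  s0 <- GenomicRanges::start(peaks) - 1L
  e0 <- GenomicRanges::end(peaks)
  mc <- S4Vectors::mcols(peaks)
  nm <- if (!is.null(mc$name)) mc$name else rep(NA_character_, length(peaks))
  nm[is.na(nm)] <- sprintf("peak_%d", which(is.na(nm)))
  height <- if (!is.null(mc$height)) mc$height else rep(NA_real_, length(peaks))
  lines <- switch(dialect,
    bed3 = paste(chrom, s0, e0, sep = "\t"),
    bed6 = paste(chrom, s0, e0, nm,
                 ifelse(is.na(height), 0, height), "+", sep = "\t"),
    narrowPeak = {
      summit <- if (!is.null(mc$summit)) mc$summit
                else rep(NA_integer_, length(peaks))
      off <- ifelse(is.na(summit), -1L, summit - 1L - s0)
      paste(chrom, s0, e0, nm, 0L, ".",
            ifelse(is.na(height), 0, height), -1L, -1L, off, sep = "\t")
    })
  writeLines(lines, path)
  invisible(path)
}

#' Build a report table with provenance
#'
#' A report table is a plain `data.frame` carrying a provenance list
#' (input file names, parameters, seed, tool version) that is serialized
#' alongside the rows in the structured output format.
#'
#' @param df A data.frame of report rows.
#' @param provenance Named list of provenance fields; the package version
#'   is added automatically.
#' @return `df` with class `report_table` and a `provenance` attribute.
#' @export
report_table <- function(df, provenance = list()) {
  stopifnot(is.data.frame(df))
  provenance$tool <- paste0("hp1tools ",
                            as.character(utils::packageVersion("hp1tools")))
  attr(df, "provenance") <- provenance
  class(df) <- c("report_table", class(df))
  df
}

#' Write a report table
#'
#' `format = "tsv"` writes a plain tab-separated table (header +
#' rows). `format = "structured"` writes the identical table preceded by
#' a provenance block of `#% key<TAB>value` comment lines, so the two
#' variants carry the same rows.
#'
#' @param table A [report_table()] (or plain data.frame).
#' @param path Output path.
#' @param format `"tsv"` or `"structured"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, format = c("tsv", "structured")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "structured") {
    prov <- attr(table, "provenance")
    for (k in names(prov))
      writeLines(sprintf("#%% %s\t%s", k,
                         paste(format(prov[[k]], digits = 15),
                               collapse = ",")), con)
  }
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read back a report table written by [write_report()]
#'
#' @param path Path to a tsv or structured report.
#' @return A [report_table()]; provenance is populated when the file has
#'   a `#%` header block.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  is_prov <- startsWith(lines, "#% ") | startsWith(lines, "#%\t") |
    grepl("^#% ?", lines)
  prov_lines <- lines[is_prov]
  body <- lines[!is_prov]
  df <- if (length(body) > 1L) {
    utils::read.table(text = body, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, na.strings = "NA")
  } else if (length(body) == 1L) {
    cols <- strsplit(body, "\t", fixed = TRUE)[[1]]
    as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    data.frame()
  }
  prov <- list()
  for (pl in prov_lines) {
    kv <- strsplit(sub("^#% ?", "", pl), "\t", fixed = TRUE)[[1]]
    if (length(kv) >= 2L) prov[[kv[1L]]] <- utils::type.convert(kv[2L],
                                                                as.is = TRUE)
  }
  out <- report_table(df, prov)
  out
}
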