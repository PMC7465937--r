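# Scanning protein sequences for the chromoshadow-domain-binding
# pentapeptide PxVxL and its degenerate variants LxVxL and CxVxL.
#
# Each class is anchored at pattern positions 1, 3 and 5 (P/L/C, V, L);
# positions 2 and 4 are wildcards over the 20 standard amino acids only.
# Ambiguity codes (X/B/Z/U) never satisfy a wildcard or an anchor: an
# unknown residue is not evidence of a motif.

#' Motif classes recognized by the scanner
#' @return Character vector of class names.
#' @export
motif_classes <- function() c("PxVxL", "LxVxL", "CxVxL")

.MOTIF_ANCHOR1 <- c(PxVxL = "P", LxVxL = "L", CxVxL = "C")

# zero-width lookahead so overlapping matches are all found
.motif_regex <- function(class) {
  a1 <- .MOTIF_ANCHOR1[[class]]
  wc <- paste0(.AA20, collapse = "")
  sprintf("(?=%s[%s]V[%s]L)", a1, wc, wc)
}

.empty_hits <- function() {
  data.frame(protein_id = character(), motif_class = character(),
             start = integer(), pentapeptide = character(),
             flank_minus1 = character(), flank_plus1 = character(),
             stringsAsFactors = FALSE)
}

#' Scan one protein for HP1a-binding pentapeptides
#'
#' Tests every length-5 window of the sequence against every requested
#' motif class and reports all matches, including overlapping ones and
#' multiple matches per protein. Wildcard positions (2 and 4) accept any
#' of the 20 standard residues; anchor positions (1, 3, 5) accept only
#' the literal residue, so ambiguity codes never match.
#'
#' @param sequence A single amino-acid sequence (character scalar or
#'   [Biostrings::AAString]); upper-case.
#' @param classes Subset of [motif_classes()] to search for.
#' @param id Protein identifier recorded in the hit table.
#' @return A data.frame with one row per hit: `protein_id`,
#'   `motif_class`, `start` (1-based residue index of the pentapeptide),
#'   `pentapeptide`, and the flanking residues `flank_minus1` /
#'   `flank_plus1` (`"-"` at a sequence edge). Rows are sorted by `start`
#'   then class name. A sequence shorter than 5 residues yields zero rows.
#' @examples
#' scan_protein("PKVWL", id = "p1")
#' scan_protein("PAVALAVAL", id = "p2")  # two overlapping hits
#' @export
scan_protein <- function(sequence, classes = motif_classes(),
                         id = "protein") {
  if (is(sequence, "AAString") || is(sequence, "XStringSet"))
    sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (length(classes) == 0L) stop("'classes' must be non-empty",
                                  call. = FALSE)
  classes <- match.arg(classes, motif_classes(), several.ok = TRUE)
  n <- nchar(sequence)
  if (n < 5L) return(.empty_hits())
  rows <- lapply(classes, function(cl) {
    m <- gregexpr(.motif_regex(cl), sequence, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0L])
    if (length(starts) == 0L) return(NULL)
    data.frame(protein_id = id, motif_class = cl, start = starts,
               pentapeptide = substring(sequence, starts, starts + 4L),
               flank_minus1 = ifelse(starts == 1L, "-",
                                     substring(sequence, starts - 1L,
                                               starts - 1L)),
               flank_plus1 = ifelse(starts + 5L > n, "-",
                                    substring(sequence, starts + 5L,
                                              starts + 5L)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(.empty_hits()), rows))
  out <- out[order(out$start, out$motif_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of proteins for HP1a-binding pentapeptides
#'
#' Applies [scan_protein()] to every record, preserving input order.
#' Proteins without any hit are listed in the `no_hit_ids` attribute of
#' the result, and the full set of scanned identifiers in `scanned_ids`.
#'
#' @param seqs A named [Biostrings::AAStringSet] (as from [read_fasta()]
#'   or [generate_proteome()]) or a named character vector.
#' @param classes Subset of [motif_classes()].
#' @return A hit data.frame as in [scan_protein()], with attributes
#'   `scanned_ids` and `no_hit_ids`.
#' @export
scan_proteome <- function(seqs, classes = motif_classes()) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  stopifnot(is.character(seqs))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must be named", call. = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate protein id '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  hits <- do.call(rbind, c(list(.empty_hits()),
                           lapply(ids, function(i)
                             scan_protein(seqs[[i]], classes, id = i))))
  rownames(hits) <- NULL
  attr(hits, "scanned_ids") <- ids
  attr(hits, "no_hit_ids") <- setdiff(ids, unique(hits$protein_id))
  hits
}

#' Summarize motif occurrence over a cohort of proteins
#'
#' A protein counts once however many hits it carries. The percentage is
#' rounded to the nearest integer with ties away from zero, the
#' convention under which 9 of 13 is 69% and 30 of 86 is 35%.
#'
#' @param hits A hit table from [scan_proteome()] (or [scan_protein()]).
#' @param cohort_ids Protein identifiers making up the cohort; must be a
#'   subset of the scanned identifiers when the hit table carries them.
#' @param label Cohort label for the report.
#' @return A one-row data.frame: `cohort_label`, `n_total`,
#'   `n_with_motif`, `percent`, plus one `n_<class>` column per motif
#'   class counting proteins with at least one hit of that class.
#' @examples
#' seqs <- c(a = "PKVWLAAA", b = "AAAAAAA", c = "GCGVGLG")
#' summarize_cohort(scan_proteome(seqs), names(seqs), "demo")
#' @export
summarize_cohort <- function(hits, cohort_ids, label = "cohort") {
  if (length(cohort_ids) == 0L) stop("empty cohort", call. = FALSE)
  if (anyDuplicated(cohort_ids))
    stop("duplicate ids in cohort", call. = FALSE)
  scanned <- attr(hits, "scanned_ids")
  if (!is.null(scanned) && length(setdiff(cohort_ids, scanned)))
    stop(sprintf("cohort id '%s' was not scanned",
                 setdiff(cohort_ids, scanned)[1L]), call. = FALSE)
  in_cohort <- hits[hits$protein_id %in% cohort_ids, , drop = FALSE]
  n_total <- length(cohort_ids)
  n_with <- length(unique(in_cohort$protein_id))
  pct <- .round_half_away(100 * n_with / n_total)
  out <- data.frame(cohort_label = label, n_total = n_total,
                    n_with_motif = n_with, percent = pct,
                    stringsAsFactors = FALSE)
  for (cl in motif_classes())
    out[[paste0("n_", cl)]] <-
      length(unique(in_cohort$protein_id[in_cohort$motif_class == cl]))
  out
}

# round() in R rounds half to even; the cohort convention is half away
# from zero (e.g. 34.5 -> 35)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
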