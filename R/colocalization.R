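# Peak co-localization: the fraction of query peaks touching a reference
# set, and its significance under a chromosome-aware randomization null.
#
# The null keeps every reference peak on its own chromosome and keeps its
# length, redrawing the start uniformly from the positions at which the
# peak still fits; this preserves per-chromosome peak density and the
# length distribution while destroying positional association.

#' Observed co-localization between two peak sets
#'
#' Counts the query peaks with at least 1 bp of intersection with any
#' reference peak. A query peak counts once however many reference peaks
#' it touches. Intervals that merely abut (half-open adjacency on disk)
#' do not overlap.
#'
#' @param query,ref [GenomicRanges::GRanges] peak sets on the same genome.
#' @param min_overlap Minimum intersection width in bp (default 1).
#' @return A list of class `overlap_stat`: `n_query`, `n_overlapping`,
#'   `pct` (percentage of query peaks co-localizing).
#' @examples
#' g <- GenomeInfoDb::Seqinfo("chrA", 1000)
#' q <- GenomicRanges::GRanges("chrA", IRanges::IRanges(c(1, 21), c(10, 30)),
#'                             seqinfo = g)
#' r <- GenomicRanges::GRanges("chrA", IRanges::IRanges(6, 6), seqinfo = g)
#' overlap_stat(q, r)  # 1 of 2 peaks, 50%
#' @export
overlap_stat <- function(query, ref, min_overlap = 1L) {
  stopifnot(is(query, "GRanges"), is(ref, "GRanges"))
  if (length(query) == 0L)
    stop("empty query peak set: co-localization percentage is undefined",
         call. = FALSE)
  n_hit <- sum(GenomicRanges::countOverlaps(
    query, ref, minoverlap = min_overlap) > 0L)
  structure(list(n_query = length(query), n_overlapping = n_hit,
                 pct = 100 * n_hit / length(query)),
            class = "overlap_stat")
}

#' @export
print.overlap_stat <- function(x, ...) {
  cat(sprintf("overlap_stat: %d / %d query peaks co-localize (%.1f%%)\n",
              x$n_overlapping, x$n_query, x$pct))
  invisible(x)
}

#' Randomize peak positions within their chromosomes
#'
#' Each peak keeps its chromosome and length; the new start is drawn
#' uniformly from the integer positions at which the peak still fits on
#' the chromosome. Heights are carried along; the summit keeps its offset
#' within the peak. Randomized peaks may overlap one another.
#'
#' @param peaks A [GenomicRanges::GRanges] with seqlengths set.
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used (as inside [permutation_test()]).
#' @return A randomized [GenomicRanges::GRanges] of the same length.
#' @export
randomize_peaks <- function(peaks, seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, randomize_peaks(peaks)))
  lens <- GenomeInfoDb::seqlengths(peaks)[as.character(
    GenomicRanges::seqnames(peaks))]
  if (any(is.na(lens)))
    stop("peaks must carry seqlengths for randomization", call. = FALSE)
  w <- GenomicRanges::width(peaks)
  if (any(w > lens))
    stop("an interval is longer than its chromosome", call. = FALSE)
  # uniform integer start0 in [0, len - w]
  s0 <- pmin(floor(runif(length(peaks)) * (lens - w + 1)), lens - w)
  out <- peaks
  old_start <- GenomicRanges::start(peaks)
  IRanges::ranges(out) <- IRanges::IRanges(start = s0 + 1L, width = w)
  mc <- S4Vectors::mcols(out)
  if (!is.null(mc$summit))
    S4Vectors::mcols(out)$summit <-
      mc$summit - old_start + GenomicRanges::start(out)
  out
}

# ---- fast permutation kernel -------------------------------------------
# Works on 0-based half-open integer vectors per chromosome. A query
# [qs,qe) overlaps some reference iff
#   #(ref starts < qe) > #(ref ends <= qs)
# which findInterval gives against sorted start/end vectors.

.perm_prep <- function(query, ref) {
  chroms <- sort(unique(c(as.character(GenomicRanges::seqnames(query)),
                          as.character(GenomicRanges::seqnames(ref)))))
  lens <- GenomeInfoDb::seqlengths(ref)
  qc <- as.character(GenomicRanges::seqnames(query))
  rc <- as.character(GenomicRanges::seqnames(ref))
  list(chroms = chroms,
       q = lapply(setNames(chroms, chroms), function(cc) {
         i <- qc == cc
         list(s0 = GenomicRanges::start(query)[i] - 1L,
              e0 = GenomicRanges::end(query)[i])
       }),
       rw = lapply(setNames(chroms, chroms), function(cc)
         GenomicRanges::width(ref)[rc == cc]),
       len = lens[chroms])
}

.perm_null_counts <- function(prep, n_perm) {
  counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    tot <- 0L
    for (cc in prep$chroms) {
      w <- prep$rw[[cc]]
      if (length(w) == 0L) next
      L <- prep$len[[cc]]
      s0 <- pmin(floor(runif(length(w)) * (L - w + 1)), L - w)
      q <- prep$q[[cc]]
      if (length(q$s0) == 0L) next
      rs <- sort.int(s0, method = "quick")
      re <- sort.int(s0 + w, method = "quick")
      tot <- tot + sum(findInterval(q$e0 - 1L, rs) > findInterval(q$s0, re))
    }
    counts[b] <- tot
  }
  counts
}

#' Permutation test for peak co-localization
#'
#' Holds the query set fixed and randomizes the reference set `n_perm`
#' times with [randomize_peaks()]; the null statistic is the number of
#' co-localizing query peaks recomputed against each randomized
#' reference. The empirical p-value uses the add-one estimator
#' `(1 + b) / (n_perm + 1)`, where `b` counts null draws at least as
#' extreme as the observation under the chosen alternative, so p can
#' never be exactly zero. The z-score is
#' `(observed - null mean) / null sd`, undefined (`NA`) when the null is
#' degenerate (sd 0); enrichment gives z > 0 and depletion (avoidance)
#' gives z < 0.
#'
#' @param query,ref [GenomicRanges::GRanges] peak sets with seqlengths.
#' @param n_perm Number of randomizations (>= 1); default 1000.
#' @param seed Integer seed; recorded in the result.
#' @param alternative `"two-sided"` (default), `"greater"` (enrichment)
#'   or `"less"` (depletion). Two-sided extremeness is measured as
#'   `|stat - null mean| >= |observed - null mean|`.
#' @return A list of class `permutation_result`: `observed` (an
#'   `overlap_stat`), `null_mean`, `null_sd`, `z_score`, `z_defined`,
#'   `p_empirical`, `alternative`, `n_perm`, `seed`, and the vector of
#'   null counts `null_counts`.
#' @examples
#' g <- GenomeInfoDb::Seqinfo(c("chrA", "chrB"), c(1e6, 8e5))
#' pp <- generate_peak_pair(g, n_query = 50, n_ref = 50,
#'                          overlap_frac = 0.4, seed = 7)
#' permutation_test(pp$query, pp$ref, n_perm = 199, seed = 7)
#' @export
permutation_test <- function(query, ref, n_perm = 1000L, seed = 1L,
                             alternative = c("two-sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L)
    stop("'n_perm' must be >= 1", call. = FALSE)
  obs <- overlap_stat(query, ref)
  w <- GenomicRanges::width(ref)
  lens <- GenomeInfoDb::seqlengths(ref)[as.character(
    GenomicRanges::seqnames(ref))]
  if (any(is.na(lens)))
    stop("reference peaks must carry seqlengths", call. = FALSE)
  if (any(w > lens))
    stop("a reference interval is longer than its chromosome",
         call. = FALSE)
  prep <- .perm_prep(query, ref)
  null <- withr::with_seed(seed, .perm_null_counts(prep, n_perm))
  mu <- mean(null)
  sdv <- stats::sd(null)
  if (n_perm == 1L) sdv <- 0
  b <- switch(alternative,
    greater = sum(null >= obs$n_overlapping),
    less = sum(null <= obs$n_overlapping),
    `two-sided` = sum(abs(null - mu) >= abs(obs$n_overlapping - mu)))
  structure(list(
    observed = obs,
    null_mean = mu,
    null_sd = sdv,
    z_score = if (sdv > 0) (obs$n_overlapping - mu) / sdv else NA_real_,
    z_defined = sdv > 0,
    p_empirical = (1 + b) / (n_perm + 1),
    alternative = alternative,
    n_perm = n_perm,
    seed = seed,
    null_counts = null), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0(
    "permutation_result: %d/%d query peaks co-localize (%.1f%%)\n",
    "  null %.2f +/- %.2f over %d permutations (seed %d)\n",
    "  z = %s, empirical p = %.4g (%s)\n"),
    x$observed$n_overlapping, x$observed$n_query, x$observed$pct,
    x$null_mean, x$null_sd, x$n_perm, x$seed,
    if (x$z_defined) sprintf("%.3f", x$z_score) else "undefined",
    x$p_empirical, x$alternative))
  invisible(x)
}

#' One-row report for a permutation test
#'
#' @param result A [permutation_test()] result.
#' @param provenance Extra provenance fields for the report.
#' @return A [report_table()] with columns `n_query`, `n_overlapping`,
#'   `pct`, `null_mean`, `null_sd`, `z_score`, `p_empirical`, `n_perm`,
#'   `seed`, `alternative`.
#' @export
colocalization_report <- function(result, provenance = list()) {
  stopifnot(is(result, "permutation_result"))
  provenance$seed <- result$seed
  report_table(data.frame(
    n_query = result$observed$n_query,
    n_overlapping = result$observed$n_overlapping,
    pct = result$observed$pct,
    null_mean = result$null_mean,
    null_sd = result$null_sd,
    z_score = result$z_score,
    p_empirical = result$p_empirical,
    n_perm = result$n_perm,
    seed = result$seed,
    alternative = result$alternative,
    stringsAsFactors = FALSE), provenance)
}
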