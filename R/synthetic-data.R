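# Seeded generators emulating the statistical structure of the
# pipeline's inputs — proteomes with planted pentapeptide motifs, peak
# pairs with a controlled overlap fraction, and a stepped peak-height
# landscape with a known heterochromatin-euchromatin border — each
# emitting its exact planted truth. Every generator draws from a single
# RNG stream fixed by its seed (no global RNG state leaks out), so the
# same seed always reproduces the same bytes on disk.

#' A small synthetic two-chromosome genome
#'
#' Convenience genome for simulations and examples; the names are
#' deliberately synthetic (not a real assembly).
#'
#' @return A [GenomeInfoDb::Seqinfo] with chrSynA (10 Mb) and
#'   chrSynB (8 Mb).
#' @export
synthetic_genome <- function() {
  GenomeInfoDb::Seqinfo(seqnames = c("chrSynA", "chrSynB"),
                        seqlengths = c(10e6, 8e6))
}

# truncated-normal heights, floored at a small positive value
.draw_heights <- function(n, mean, sd, floor = 0.05) {
  pmax(rnorm(n, mean, sd), floor)
}

#' Generate a synthetic proteome with planted motifs
#'
#' Background residues are drawn uniformly from the 20 standard amino
#' acids; requested motifs are planted with anchors fixed and wildcard
#' positions drawn uniformly. Whole proteins are rejection-resampled
#' until a full scan finds exactly the planted hits — including windows
#' straddling a planted motif's flanks — so the planted set is the exact
#' ground truth, not merely the expected one.
#'
#' @param n_proteins Number of proteins.
#' @param length_mean Mean protein length (residues); lengths are
#'   Poisson-distributed around it.
#' @param planted A data.frame with columns `protein_index` (1-based),
#'   `position` (1-based residue index of the pentapeptide) and
#'   `motif_class`, or `NULL` for a motif-free proteome. Planted motifs
#'   within one protein must not overlap and must fit the protein.
#' @param seed Integer seed.
#' @param max_attempts Resampling attempts per protein before giving up.
#' @return A list: `sequences` (named [Biostrings::AAStringSet], ids
#'   `sp001`, ...), `truth` (data.frame `protein_id`, `start`,
#'   `motif_class`, `pentapeptide`), `seed`.
#' @examples
#' gp <- generate_proteome(5, planted = data.frame(
#'   protein_index = 1, position = 10, motif_class = "PxVxL"), seed = 1)
#' scan_proteome(gp$sequences)  # exactly the planted hit
#' @export
generate_proteome <- function(n_proteins = 100L, length_mean = 500,
                              planted = NULL, seed = 1L,
                              max_attempts = 1000L) {
  stopifnot(n_proteins >= 1L, length_mean >= 5)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("protein_index", "position", "motif_class") %in%
                    names(planted)))
    if (!all(planted$motif_class %in% motif_classes()))
      stop("unknown motif class in 'planted'", call. = FALSE)
    if (!all(planted$protein_index %in% seq_len(n_proteins)))
      stop("'planted' protein_index out of range", call. = FALSE)
  }
  ids <- sprintf("sp%03d", seq_len(n_proteins))
  withr::with_seed(seed, {
    lens <- pmax(5L, rpois(n_proteins, length_mean))
    seqs <- character(n_proteins)
    truth <- list()
    for (i in seq_len(n_proteins)) {
      pl <- if (is.null(planted)) NULL else
        planted[planted$protein_index == i, , drop = FALSE]
      if (!is.null(pl) && nrow(pl)) {
        pl <- pl[order(pl$position), , drop = FALSE]
        if (any(pl$position < 1L | pl$position + 4L > lens[i]))
          stop(sprintf(
            "planted motif out of range in protein %d (length %d)",
            i, lens[i]), call. = FALSE)
        if (nrow(pl) > 1L && any(diff(pl$position) < 5L))
          stop(sprintf("planted motifs overlap in protein %d", i),
               call. = FALSE)
      }
      expected <- if (is.null(pl) || nrow(pl) == 0L) {
        data.frame(start = integer(), motif_class = character())
      } else {
        data.frame(start = as.integer(pl$position),
                   motif_class = as.character(pl$motif_class))
      }
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        s <- sample(.AA20, lens[i], replace = TRUE)
        if (nrow(expected)) {
          for (j in seq_len(nrow(expected))) {
            p <- expected$start[j]
            s[p] <- .MOTIF_ANCHOR1[[expected$motif_class[j]]]
            s[p + 1L] <- sample(.AA20, 1L)
            s[p + 2L] <- "V"
            s[p + 3L] <- sample(.AA20, 1L)
            s[p + 4L] <- "L"
          }
        }
        seq_i <- paste(s, collapse = "")
        hits <- scan_protein(seq_i, id = ids[i])
        if (nrow(hits) == nrow(expected) &&
            all(hits$start == expected$start) &&
            all(hits$motif_class == expected$motif_class)) {
          seqs[i] <- seq_i
          if (nrow(hits))
            truth[[length(truth) + 1L]] <-
              data.frame(protein_id = ids[i], start = hits$start,
                         motif_class = hits$motif_class,
                         pentapeptide = hits$pentapeptide,
                         stringsAsFactors = FALSE)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(
          "could not realize planted motifs in protein %d after %d attempts",
          i, max_attempts), call. = FALSE)
    }
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- ids
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(protein_id = character(), start = integer(),
                 motif_class = character(), pentapeptide = character(),
                 stringsAsFactors = FALSE)
    rownames(truth_df) <- NULL
    list(sequences = out, truth = truth_df, seed = seed)
  })
}

#' Generate a query/reference peak pair with a controlled overlap
#'
#' Reference peaks are placed uniformly over the genome (chromosome
#' chosen proportionally to its length, start uniform given the
#' length). With a numeric `overlap_frac` f, exactly `round(f *
#' n_query)` query peaks are placed to intersect a uniformly chosen
#' reference peak by at least 1 bp, and the remaining query peaks are
#' rejection-placed until they intersect no reference peak — so the
#' observed co-localization count is exact by construction. With
#' `overlap_frac = NULL` the query is placed independently of the
#' reference (the null construction used for calibration studies).
#'
#' @param genome A [GenomeInfoDb::Seqinfo] or named length vector.
#' @param n_query,n_ref Peak counts; defaults 200.
#' @param overlap_frac Planted overlap fraction in `[0, 1]`, or `NULL`
#'   for independent placement.
#' @param length_mean Mean peak length in bp (normal with 15% CV,
#'   floored at 20 bp).
#' @param seed Integer seed.
#' @param max_attempts Rejection attempts per non-overlapping query peak.
#' @return A list: `query`, `ref` (GRanges with `height` and `summit`),
#'   `truth` (list with `overlap_frac`, `n_overlapping_expected`, `seed`).
#' @export
generate_peak_pair <- function(genome = synthetic_genome(),
                               n_query = 200L, n_ref = 200L,
                               overlap_frac = 0.4, length_mean = 300,
                               seed = 1L, max_attempts = 1000L) {
  si <- .as_seqinfo(genome)
  chroms <- GenomeInfoDb::seqnames(si)
  lens <- as.numeric(GenomeInfoDb::seqlengths(si))
  if (!is.null(overlap_frac))
    stopifnot(overlap_frac >= 0, overlap_frac <= 1)
  stopifnot(n_query >= 1L, n_ref >= 1L, length_mean >= 20)

  draw_len <- function(n) pmax(20, round(rnorm(n, length_mean,
                                               0.15 * length_mean)))
  mk_gr <- function(chrom, s0, w) {
    gr <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = s0 + 1, width = w), seqinfo = si)
    S4Vectors::mcols(gr)$name <- sprintf("peak_%d", seq_along(gr))
    S4Vectors::mcols(gr)$height <- .draw_heights(length(gr), 2, 0.5)
    S4Vectors::mcols(gr)$summit <- GenomicRanges::start(gr) +
      GenomicRanges::width(gr) %/% 2L
    gr
  }

  withr::with_seed(seed, {
    # reference: uniform over the genome
    rw <- draw_len(n_ref)
    rc_i <- sample.int(length(chroms), n_ref, replace = TRUE, prob = lens)
    rs0 <- floor(runif(n_ref) * (lens[rc_i] - rw + 1))
    rs0 <- pmin(rs0, lens[rc_i] - rw)
    if (any(rw > lens[rc_i]))
      stop("a reference peak does not fit its chromosome", call. = FALSE)
    ref <- mk_gr(chroms[rc_i], rs0, rw)
    re0 <- rs0 + rw

    n_forced <- if (is.null(overlap_frac)) NA_integer_ else
      as.integer(round(overlap_frac * n_query))
    qw <- draw_len(n_query)
    qc <- character(n_query); qs0 <- numeric(n_query)

    if (is.null(overlap_frac)) {
      qc_i <- sample.int(length(chroms), n_query, replace = TRUE,
                         prob = lens)
      qs0 <- floor(runif(n_query) * (lens[qc_i] - qw + 1))
      qs0 <- pmin(qs0, lens[qc_i] - qw)
      qc <- chroms[qc_i]
    } else {
      # forced-overlap queries: intersect a chosen reference peak >=1 bp
      for (i in seq_len(n_forced)) {
        placed <- FALSE
        for (a in seq_len(max_attempts)) {
          j <- sample.int(n_ref, 1L)
          L <- lens[rc_i[j]]
          lo <- max(0, rs0[j] - qw[i] + 1)
          hi <- min(L - qw[i], re0[j] - 1)
          if (hi < lo) next
          qs0[i] <- lo + floor(runif(1) * (hi - lo + 1))
          qs0[i] <- min(qs0[i], hi)
          qc[i] <- chroms[rc_i[j]]
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place an overlapping query peak", call. = FALSE)
      }
      # remaining queries: rejection-placed to intersect no reference
      if (n_forced < n_query) {
        for (i in seq.int(n_forced + 1L, n_query)) {
          placed <- FALSE
          for (a in seq_len(max_attempts)) {
            ci <- sample.int(length(chroms), 1L, prob = lens)
            L <- lens[ci]
            s <- min(floor(runif(1) * (L - qw[i] + 1)), L - qw[i])
            on_c <- rc_i == ci
            if (!any(s < re0[on_c] & s + qw[i] > rs0[on_c])) {
              qs0[i] <- s; qc[i] <- chroms[ci]; placed <- TRUE
              break
            }
          }
          if (!placed)
            stop(paste("could not place a non-overlapping query peak;",
                       "genome too crowded"), call. = FALSE)
        }
      }
    }
    query <- mk_gr(qc, qs0, qw)
    list(query = sort(query), ref = sort(ref),
         truth = list(kind = "overlap_pair", overlap_frac = overlap_frac,
                      n_query = n_query, n_ref = n_ref,
                      n_overlapping_expected = n_forced, seed = seed))
  })
}

#' Generate a stepped peak-height landscape with a known border
#'
#' Emulates a chromosome arm whose pericentric heterochromatin block has
#' high median peak summit heights and abuts euchromatin with low
#' heights at a known border: per 0.5-Mb bin, a Poisson number of peaks
#' with summits uniform in the bin, heights normal around the high mean
#' before the border and the low mean after it (truncated at a small
#' positive floor).
#'
#' @param chrom_length Arm length in bp (default 25 Mb, about the size
#'   of Drosophila chromosome arm 2R).
#' @param border_pos Planted border in bp; must be a multiple of
#'   `bin_size` (default 7.5 Mb, in the range where the 2R
#'   heterochromatin-euchromatin transition lies).
#' @param high_mean,low_mean Mean summit heights (a.u.) before/after the
#'   border; defaults 3.0 and 0.4.
#' @param sd Height standard deviation (a.u.); default 0.3.
#' @param peaks_per_bin_mean Poisson mean peak count per bin; default 20.
#' @param bin_size Bin width in bp; default 500000.
#' @param chrom Chromosome name for the emitted peaks.
#' @param seed Integer seed.
#' @return A list: `peaks` (narrowPeak-style GRanges with `height` and
#'   `summit`, seqlengths set), `genome` (Seqinfo), `truth` (list of the
#'   planted parameters).
#' @export
generate_landscape <- function(chrom_length = 25e6, border_pos = 7.5e6,
                               high_mean = 3.0, low_mean = 0.4, sd = 0.3,
                               peaks_per_bin_mean = 20, bin_size = 500000,
                               chrom = "chr2R", seed = 1L) {
  stopifnot(chrom_length > 0, bin_size > 0, peaks_per_bin_mean >= 0)
  if (sd < 0) stop("'sd' must be non-negative", call. = FALSE)
  if (!(high_mean > low_mean) || !(low_mean > 0))
    stop("need high_mean > low_mean > 0", call. = FALSE)
  if (border_pos %% bin_size != 0)
    stop("'border_pos' must be a multiple of 'bin_size'", call. = FALSE)
  if (border_pos < 0 || border_pos > chrom_length)
    stop("'border_pos' must lie on the chromosome", call. = FALSE)
  si <- GenomeInfoDb::Seqinfo(chrom, chrom_length)
  n_bins <- ceiling(chrom_length / bin_size)
  withr::with_seed(seed, {
    counts <- rpois(n_bins, peaks_per_bin_mean)
    if (sum(counts) == 0L)
      stop("empty landscape: no peaks drawn", call. = FALSE)
    bin_lo <- (seq_len(n_bins) - 1) * bin_size
    bin_hi <- pmin(seq_len(n_bins) * bin_size, chrom_length)
    summit0 <- unlist(lapply(seq_len(n_bins), function(b) {
      if (counts[b] == 0L) return(numeric())
      sort(floor(bin_lo[b] + runif(counts[b]) * (bin_hi[b] - bin_lo[b])))
    }))
    hetero <- summit0 < border_pos
    h <- .draw_heights(length(summit0),
                       ifelse(hetero, high_mean, low_mean), sd)
    s0 <- pmax(0, summit0 - 100)
    e0 <- pmin(chrom_length, summit0 + 100)
    peaks <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = s0 + 1, end = e0), seqinfo = si)
    S4Vectors::mcols(peaks)$name <- sprintf("lpeak_%d", seq_along(peaks))
    S4Vectors::mcols(peaks)$height <- h
    S4Vectors::mcols(peaks)$summit <- summit0 + 1
    list(peaks = peaks, genome = si,
         truth = list(kind = "landscape", border_pos = border_pos,
                      high_mean = high_mean, low_mean = low_mean,
                      sd = sd, peaks_per_bin_mean = peaks_per_bin_mean,
                      bin_size = bin_size, chrom = chrom,
                      chrom_length = chrom_length, seed = seed))
  })
}
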