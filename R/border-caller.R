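# Epigenomic border calling: bin peak summit heights along a chromosome
# arm from an origin (typically the centromere-proximal end) toward the
# telomere, and mark the border at the first bin whose median height
# drops strictly below the genome-wide median.

# summit positions (0-based); midpoints imputed when absent
.summit0 <- function(peaks) {
  s <- S4Vectors::mcols(peaks)$summit
  s0_int <- GenomicRanges::start(peaks) - 1L
  mid <- s0_int + (GenomicRanges::end(peaks) - s0_int) %/% 2L
  if (is.null(s)) return(mid)
  ifelse(is.na(s), mid, s - 1L)
}

#' Genome-wide median peak summit height
#'
#' The reference level against which binned medians are compared when
#' calling a border: the median of all peak heights over the whole peak
#' set, with the usual even-count convention (mean of the two central
#' values).
#'
#' @param peaks A [GenomicRanges::GRanges] with a `height` metadata
#'   column; every peak must have a height.
#' @return The median height (a.u.).
#' @export
global_median_height <- function(peaks) {
  if (length(peaks) == 0L)
    stop("empty peak set has no median height", call. = FALSE)
  h <- S4Vectors::mcols(peaks)$height
  if (is.null(h) || anyNA(h))
    stop("every peak must carry a height", call. = FALSE)
  median(h)
}

#' Binned median summit-height profile along a chromosome arm
#'
#' Lays fixed-width bins from `origin` toward the telomere-side end of
#' the chromosome (increasing or decreasing coordinates) and computes,
#' per bin, the number of peak summits it contains and the median of
#' their heights. Bins are half-open in scan order: a summit exactly on
#' a bin boundary belongs to the higher-index (origin-distal) bin. For
#' the decreasing direction the mirrored convention makes bins half-open
#' toward the origin; a summit at coordinate 0 that falls on the final
#' boundary is kept in the last bin. Empty bins get `median_height` 0 —
#' a stretch with no peaks cannot be heterochromatin under this
#' statistic.
#'
#' @param peaks A [GenomicRanges::GRanges] with `height` (and optionally
#'   `summit`) metadata and seqlengths; summits are imputed as interval
#'   midpoints when absent.
#' @param chrom Chromosome (arm) to scan; other chromosomes are ignored.
#' @param origin Scan origin in bp (0-based), e.g. the
#'   centromere-proximal end of the arm.
#' @param direction `"increasing"` to scan toward larger coordinates,
#'   `"decreasing"` toward 0.
#' @param bin_size Bin width in bp; default 500000 (0.5 Mb).
#' @return A data.frame of class `bin_profile` with columns `bin_index`
#'   (0-based, scan order), `bin_start`, `bin_end` (genomic bp bounds of
#'   the bin), `n_peaks`, `median_height`; attributes `chrom`, `origin`,
#'   `direction`, `bin_size`.
#' @export
bin_profile <- function(peaks, chrom, origin,
                        direction = c("increasing", "decreasing"),
                        bin_size = 500000L) {
  direction <- match.arg(direction)
  bin_size <- as.numeric(bin_size)
  if (is.na(bin_size) || bin_size <= 0)
    stop("'bin_size' must be positive", call. = FALSE)
  L <- unname(GenomeInfoDb::seqlengths(peaks)[chrom])
  if (length(L) != 1L || is.na(L))
    stop(sprintf("chromosome '%s' has no length in the peak set's genome",
                 chrom), call. = FALSE)
  if (origin < 0 || origin > L)
    stop("'origin' must lie within the chromosome", call. = FALSE)
  span <- if (direction == "increasing") L - origin else origin
  n_bins <- ceiling(span / bin_size)
  if (n_bins == 0L)
    stop("no scannable range between the origin and the chromosome end",
         call. = FALSE)
  on_chrom <- as.character(GenomicRanges::seqnames(peaks)) == chrom
  pk <- peaks[on_chrom]
  h <- S4Vectors::mcols(pk)$height
  if (length(pk) && (is.null(h) || anyNA(h)))
    stop("every peak on the scanned chromosome must carry a height",
         call. = FALSE)
  s0 <- .summit0(pk)
  if (direction == "increasing") {
    idx <- (s0 - origin) %/% bin_size
    keep <- s0 >= origin
    starts <- origin + seq_len(n_bins) * bin_size - bin_size
    ends <- pmin(origin + seq_len(n_bins) * bin_size, L)
  } else {
    idx <- floor((origin - s0) / bin_size)
    idx <- pmin(idx, n_bins - 1)           # boundary hit at coordinate 0
    keep <- s0 <= origin
    ends <- origin - seq_len(n_bins) * bin_size + bin_size
    starts <- pmax(origin - seq_len(n_bins) * bin_size, 0)
  }
  mask <- keep & idx >= 0 & idx < n_bins
  idx <- idx[mask]
  hh <- h[mask]
  out <- data.frame(bin_index = seq_len(n_bins) - 1L,
                    bin_start = starts, bin_end = ends,
                    n_peaks = 0L, median_height = 0)
  if (length(idx)) {
    tab <- tapply(hh, factor(idx, levels = out$bin_index), median)
    cnt <- tapply(hh, factor(idx, levels = out$bin_index), length)
    filled <- !is.na(cnt)
    out$n_peaks[filled] <- cnt[filled]
    out$median_height[filled] <- tab[filled]
  }
  attr(out, "chrom") <- chrom
  attr(out, "origin") <- origin
  attr(out, "direction") <- direction
  attr(out, "bin_size") <- bin_size
  class(out) <- c("bin_profile", class(out))
  out
}

#' Call the epigenomic border from a binned profile
#'
#' Scans bins outward from the origin and marks the border at the first
#' bin whose median summit height falls strictly below the global
#' median; bins exactly at the global median do not trigger. With
#' `min_run > 1` the drop must persist for that many consecutive bins
#' (the border is still the first bin of the run). If no bin qualifies
#' the border is absent (`NA`).
#'
#' @param profile A [bin_profile()].
#' @param global_median Reference height (a.u.), normally
#'   [global_median_height()] of the genome-wide peak set.
#' @param min_run Number of consecutive below-median bins required
#'   (default 1, a single-threshold crossing).
#' @param report Which coordinate of the border bin to report:
#'   `"start"` (default, the origin-proximal boundary — the last
#'   coordinate known to be heterochromatin-adjacent), `"end"` (the
#'   origin-distal boundary) or `"midpoint"`.
#' @return A list of class `border_call`: `chrom`, `border_pos` (bp, `NA`
#'   when absent), `border_mb` (Mb, one decimal), `global_median`,
#'   `bin_size`, `direction`, `origin`, `report`, and the `profile`.
#' @examples
#' g <- GenomeInfoDb::Seqinfo("chr2R", 25e6)
#' lsc <- generate_landscape(seed = 11)
#' prof <- bin_profile(lsc$peaks, "chr2R", origin = 0)
#' call_border(prof, global_median = 0.9)
#' @export
call_border <- function(profile, global_median,
                        min_run = 1L,
                        report = c("start", "end", "midpoint")) {
  report <- match.arg(report)
  stopifnot(is.data.frame(profile), nrow(profile) > 0L,
            is.numeric(global_median), length(global_median) == 1L)
  min_run <- max(1L, as.integer(min_run))
  below <- profile$median_height < global_median
  runs <- rle(below)
  first <- NA_integer_
  pos_in_rle <- cumsum(c(1L, runs$lengths))
  hit <- which(runs$values & runs$lengths >= min_run)
  if (length(hit)) first <- pos_in_rle[hit[1L]]
  direction <- attr(profile, "direction")
  pos <- NA_real_
  if (!is.na(first)) {
    row <- profile[first, ]
    proximal <- if (identical(direction, "decreasing")) row$bin_end
                else row$bin_start
    distal <- if (identical(direction, "decreasing")) row$bin_start
              else row$bin_end
    pos <- switch(report, start = proximal, end = distal,
                  midpoint = floor((row$bin_start + row$bin_end) / 2))
  }
  structure(list(chrom = attr(profile, "chrom") %||% NA_character_,
                 border_pos = pos,
                 border_mb = round(pos / 1e6, 1),
                 global_median = global_median,
                 bin_size = attr(profile, "bin_size") %||% NA_real_,
                 direction = direction %||% "increasing",
                 origin = attr(profile, "origin") %||% NA_real_,
                 report = report,
                 profile = profile),
            class = "border_call")
}

#' @export
print.border_call <- function(x, ...) {
  cat(sprintf("border_call on %s (%s from origin %s, %.1f-Mb bins):\n",
              x$chrom, x$direction, format(x$origin, big.mark = ","),
              x$bin_size / 1e6))
  if (is.na(x$border_pos)) {
    cat("  no bin fell below the global median; border absent\n")
  } else {
    cat(sprintf("  border at %s bp (%.1f Mb); global median %.3g a.u.\n",
                format(x$border_pos, big.mark = ","), x$border_mb,
                x$global_median))
  }
  invisible(x)
}

#' Consensus over border calls from multiple tracks
#'
#' Compares borders called independently from several ChIP-seq tracks on
#' the same chromosome arm (e.g. HP1a alongside Su(var)3-9 and H3K9me3).
#' The calls agree when every pairwise distance between border positions
#' is within `tolerance`; a call with an absent border makes agreement
#' false.
#'
#' @param calls A list of at least two [call_border()] results on the
#'   same chromosome and direction.
#' @param tolerance Maximum pairwise distance in bp for agreement;
#'   default 500000 (one 0.5-Mb bin).
#' @return A list of class `border_consensus`: `chrom`, `agreement`
#'   (logical), `consensus_pos` (median of the present border positions,
#'   bp), `consensus_mb`, `max_pairwise_distance`, `tolerance`,
#'   `n_tracks`, `border_positions`.
#' @export
consensus_border <- function(calls, tolerance = 500000) {
  stopifnot(is.list(calls), length(calls) >= 2L)
  if (!all(vapply(calls, function(x) is(x, "border_call"), TRUE)))
    stop("'calls' must be border_call objects", call. = FALSE)
  chroms <- vapply(calls, `[[`, "", "chrom")
  dirs <- vapply(calls, `[[`, "", "direction")
  if (length(unique(chroms)) != 1L || length(unique(dirs)) != 1L)
    stop("all calls must be on the same chromosome and direction",
         call. = FALSE)
  pos <- vapply(calls, `[[`, 0, "border_pos")
  present <- !is.na(pos)
  maxd <- if (sum(present) >= 2L) max(stats::dist(pos[present])) else NA_real_
  agree <- all(present) && maxd <= tolerance
  cons <- if (any(present)) median(pos[present]) else NA_real_
  structure(list(chrom = chroms[1L], agreement = agree,
                 consensus_pos = cons,
                 consensus_mb = round(cons / 1e6, 1),
                 max_pairwise_distance = maxd, tolerance = tolerance,
                 n_tracks = length(calls), border_positions = pos),
            class = "border_consensus")
}

#' One-row report for a border call (optionally with consensus fields)
#'
#' @param call A [call_border()] result.
#' @param consensus Optional [consensus_border()] result.
#' @param provenance Extra provenance fields.
#' @return A [report_table()].
#' @export
border_report <- function(call, consensus = NULL, provenance = list()) {
  df <- data.frame(chrom = call$chrom, origin = call$origin,
                   direction = call$direction, bin_size = call$bin_size,
                   global_median = call$global_median,
                   border_pos_bp = call$border_pos,
                   border_pos_Mb = call$border_mb,
                   stringsAsFactors = FALSE)
  if (!is.null(consensus)) {
    df$agreement <- consensus$agreement
    df$consensus_pos_bp <- consensus$consensus_pos
    df$consensus_pos_Mb <- consensus$consensus_mb
    df$n_tracks <- consensus$n_tracks
  }
  report_table(df, provenance)
}
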