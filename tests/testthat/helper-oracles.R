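# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use the most literal formulation available
# (explicit window enumeration, all-pairs interval comparison, exhaustive
# placement counting) so they share no code with the package internals.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# exhaustive window-by-window motif scan, character comparisons only
oracle_scan <- function(sequence, classes = c("PxVxL", "LxVxL", "CxVxL")) {
  anchor1 <- c(PxVxL = "P", LxVxL = "L", CxVxL = "C")
  n <- nchar(sequence)
  out <- list()
  if (n >= 5) {
    ch <- strsplit(sequence, "")[[1]]
    for (s in 1:(n - 4)) {
      for (cl in classes) {
        if (ch[s] == anchor1[[cl]] && ch[s + 2] == "V" &&
            ch[s + 4] == "L" &&
            ch[s + 1] %in% AA20 && ch[s + 3] %in% AA20) {
          out[[length(out) + 1]] <- data.frame(
            motif_class = cl, start = s,
            pentapeptide = paste(ch[s:(s + 4)], collapse = ""),
            flank_minus1 = if (s == 1) "-" else ch[s - 1],
            flank_plus1 = if (s + 5 > n) "-" else ch[s + 5],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(motif_class = character(), start = integer(),
                      pentapeptide = character(),
                      flank_minus1 = character(),
                      flank_plus1 = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$motif_class), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# quadratic all-pairs overlap count on 0-based half-open coordinates
oracle_overlap_count <- function(q_chrom, q_s0, q_e0,
                                 r_chrom, r_s0, r_e0) {
  n_hit <- 0L
  for (i in seq_along(q_s0)) {
    hit <- FALSE
    for (j in seq_along(r_s0)) {
      if (q_chrom[i] == r_chrom[j] &&
          q_s0[i] < r_e0[j] && q_e0[i] > r_s0[j]) {
        hit <- TRUE
        break
      }
    }
    n_hit <- n_hit + hit
  }
  n_hit
}

# exact null overlap mean for ONE 1-bp query at 0-based position q0 and
# ONE reference of length L on a single chromosome of length G, by
# enumerating every placement
oracle_exhaustive_null_mean <- function(q0, L, G) {
  hits <- 0L
  for (s in 0:(G - L)) {
    if (s < q0 + 1 && s + L > q0) hits <- hits + 1L
  }
  hits / (G - L + 1)
}

# GRanges from 0-based half-open coordinates
gr0 <- function(chrom, s0, e0, genome = NULL, height = NULL,
                summit0 = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = s0 + 1, end = e0))
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  if (!is.null(height)) S4Vectors::mcols(gr)$height <- height
  if (!is.null(summit0)) S4Vectors::mcols(gr)$summit <- summit0 + 1
  gr
}

random_aa_seq <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# strip attributes/classes so hit tables compare on content only
plain <- function(df) {
  df <- as.data.frame(df)
  attr(df, "scanned_ids") <- NULL
  attr(df, "no_hit_ids") <- NULL
  rownames(df) <- NULL
  df
}

cli_path <- function() {
  file.path(find.package("hp1tools"), "exec", "hp1tools")
}

run_cli <- function(args) {
  out <- suppressWarnings(system2("Rscript", c(cli_path(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("CLI failed: ", paste(out, collapse = "\n"))
  invisible(out)
}
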