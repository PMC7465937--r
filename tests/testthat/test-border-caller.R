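si_arm <- GenomeInfoDb::Seqinfo("chr2R", 25e6)

# peaks with given summit heights at given 0-based summit positions
peaks_at <- function(summit0, height, si = si_arm, chrom = "chr2R") {
  gr0(rep(chrom, length(summit0)), pmax(0, summit0 - 50), summit0 + 50,
      si, height = height, summit0 = summit0)
}

test_that("global median height follows the even-count convention", {
  expect_equal(global_median_height(peaks_at(1:3 * 1000, c(1, 2, 3))), 2)
  expect_equal(global_median_height(peaks_at(1:4 * 1000, c(1, 2, 3, 10))),
               2.5)
  expect_equal(global_median_height(peaks_at(5000, 7)), 7)
  expect_error(global_median_height(peaks_at(5000, 7)[0]), "empty")
  expect_error(global_median_height(peaks_at(5000, NA_real_)), "height")
})

test_that("binning assigns summits half-open from the origin", {
  pk <- peaks_at(c(200000, 500000, 499999), c(1, 2, 3))
  prof <- bin_profile(pk, "chr2R", origin = 0)
  expect_equal(prof$n_peaks[1], 2L)          # 200000 and 499999
  expect_equal(prof$n_peaks[2], 1L)          # the exact-boundary summit
  expect_equal(prof$median_height[2], 2)
  expect_equal(nrow(prof), 50)               # 25 Mb / 0.5 Mb
  # bins tile the scanned range and counts add up
  expect_equal(prof$bin_start[-1], prof$bin_end[-nrow(prof)])
  expect_equal(sum(prof$n_peaks), 3L)
  # empty bins report median 0
  expect_true(all(prof$median_height[prof$n_peaks == 0] == 0))
})

test_that("binning respects the scan direction", {
  pk <- peaks_at(c(24e6 + 100, 23.6e6, 23.5e6), c(1, 2, 3))
  prof <- bin_profile(pk, "chr2R", origin = 24.5e6,
                      direction = "decreasing")
  # scan order runs toward 0; bin 0 is (24e6, 24.5e6]
  expect_equal(prof$n_peaks[1], 1L)
  # 23.6e6 is inside bin 1 (23.5e6, 24e6]; the exact boundary summit
  # 23.5e6 belongs to the higher-index bin 2 in scan order
  expect_equal(prof$n_peaks[2], 1L)
  expect_equal(prof$n_peaks[3], 1L)
  expect_equal(prof$bin_end[1], 24.5e6)
  expect_equal(nrow(prof), 49)

  expect_error(bin_profile(pk, "chr2R", origin = -1), "origin")
  expect_error(bin_profile(pk, "chr2R", origin = 0, bin_size = 0),
               "bin_size")
  expect_error(bin_profile(pk, "chrX", origin = 0), "no length")
})

test_that("summits are imputed at interval midpoints when absent", {
  pk <- peaks_at(c(100000, 700000), c(1, 2))
  pk$summit <- NULL
  prof <- bin_profile(pk, "chr2R", origin = 0)
  expect_equal(prof$n_peaks[1:2], c(1L, 1L))
})

test_that("the border is the first strict drop below the global median", {
  pk <- peaks_at(c(0, 1, 2, 3, 4) * 500000 + 1000,
                 c(3.1, 3.0, 1.4, 0.5, 0.4))
  prof <- bin_profile(pk, "chr2R", origin = 0)
  call <- call_border(prof, global_median = 0.9)
  # bins beyond the five seeded ones are empty (median 0), but the scan
  # stops at the first drop: the 0.5 bin starting at 1.5 Mb
  expect_equal(call$border_pos, 1500000)
  expect_equal(call$border_mb, 1.5)
  # prefix property: every earlier bin is at or above the global median
  before <- prof$median_height[prof$bin_start < call$border_pos]
  expect_true(all(before >= 0.9))
})

test_that("bins exactly at the global median do not trigger", {
  pk <- peaks_at(c(0, 1, 2) * 500000 + 1000, c(2, 0.9, 0.4))
  prof3 <- bin_profile(pk, "chr2R", origin = 0, bin_size = 500000)
  call <- call_border(prof3[1:3, ], global_median = 0.9)
  expect_equal(call$border_pos, 1000000)     # the 0.4 bin, not the 0.9 one
})

test_that("the border is absent when no bin falls below the median", {
  pk <- peaks_at(c(0, 1, 2) * 500000 + 1000, c(3, 3, 3))
  prof <- bin_profile(pk, "chr2R", origin = 0)
  call <- call_border(prof[1:3, ], global_median = 0.9)
  expect_true(is.na(call$border_pos))
})

test_that("reported border coordinate honors the report choice", {
  pk <- peaks_at(c(0, 1, 2, 3) * 500000 + 1000, c(3, 3, 0.1, 0.1))
  prof <- bin_profile(pk, "chr2R", origin = 0)
  expect_equal(call_border(prof, 0.9, report = "start")$border_pos, 1e6)
  expect_equal(call_border(prof, 0.9, report = "end")$border_pos, 1.5e6)
  expect_equal(call_border(prof, 0.9, report = "midpoint")$border_pos,
               1.25e6)
})

test_that("min_run requires a persistent drop", {
  pk <- peaks_at(c(0, 1, 2, 3, 4) * 500000 + 1000,
                 c(3, 0.1, 3, 0.1, 0.1))
  prof <- bin_profile(pk, "chr2R", origin = 0)[1:5, ]
  expect_equal(call_border(prof, 0.9)$border_pos, 5e5)
  expect_equal(call_border(prof, 0.9, min_run = 2)$border_pos, 1.5e6)
})

test_that("border calls are scale-equivariant and order-invariant", {
  ls <- generate_landscape(seed = 19)
  for (c_scale in c(0.1, 1, 17)) {
    pk <- ls$peaks
    pk$height <- pk$height * c_scale
    prof <- bin_profile(pk, "chr2R", origin = 0)
    call <- call_border(prof, 0.9 * c_scale)
    expect_equal(call$border_pos, 7.5e6)
  }
  shuffled <- ls$peaks[withr::with_seed(1, sample(length(ls$peaks)))]
  p1 <- bin_profile(ls$peaks, "chr2R", origin = 0)
  p2 <- bin_profile(shuffled, "chr2R", origin = 0)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
})

test_that("a noiseless stepped landscape is recovered exactly", {
  ls <- generate_landscape(sd = 0, peaks_per_bin_mean = 30, seed = 3)
  prof <- bin_profile(ls$peaks, "chr2R", origin = 0)
  call <- call_border(prof, global_median = 0.9)
  expect_equal(call$border_pos, ls$truth$border_pos)
})

test_that("consensus across tracks compares borders within a tolerance", {
  mk_call <- function(pos_mb) {
    heights <- ifelse((0:49) * 0.5 < pos_mb, 3, 0.1)
    pk <- peaks_at((0:49) * 500000 + 1000, heights)
    call_border(bin_profile(pk, "chr2R", origin = 0), 0.9)
  }
  c73 <- mk_call(7.3)   # border lands at the 7.5 Mb bin boundary
  c74 <- mk_call(7.4)
  expect_equal(consensus_border(list(c73, c73, c73), 5e5)$agreement, TRUE)
  cons <- consensus_border(list(c73, c74), tolerance = 5e5)
  expect_true(cons$agreement)

  # calls one bin apart vs zero tolerance
  c90 <- mk_call(9.0)
  expect_false(consensus_border(list(c73, c90), tolerance = 5e5)$agreement)

  # an absent border defeats agreement
  pk_hi <- peaks_at((0:9) * 500000 + 1000, rep(3, 10))
  no_border <- call_border(bin_profile(pk_hi, "chr2R", origin = 0,
                                       bin_size = 500000)[1:10, ], 0.9)
  attr_profile <- no_border
  expect_false(consensus_border(list(c73, no_border), 5e5)$agreement)

  expect_error(consensus_border(list(c73), 5e5), "length")
  other <- mk_call(7.3)
  other$chrom <- "chr3L"
  expect_error(consensus_border(list(c73, other), 5e5), "same chromosome")
})
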