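test_that("probe ratios follow log2((e4c+pc)/(control+pc))", {
  d <- tibble::tibble(e4c = c(400, 100, 100), control = c(100, 100, 400))
  r <- compute_probe_ratios(d, pseudocount = 0)
  expect_equal(r$log2_ratio, c(2, 0, -2))  # antisymmetric under channel swap
  expect_error(compute_probe_ratios(d[0, ]), "empty")
  expect_error(compute_probe_ratios(tibble::tibble(e4c = 0, control = 0),
                                    pseudocount = 0), "undefined")
  expect_no_error(compute_probe_ratios(tibble::tibble(e4c = 0, control = 0),
                                       pseudocount = 1))
})

test_that("sliding-window smoothing averages midpoints within the window", {
  # middle probe sees all three midpoints inside its +/-100 bp window
  tr <- probe_track(c(100, 150, 210), c(1, 2, 3))
  sm <- smooth_sliding_window(tr, window_bp = 200)
  expect_equal(sm$smoothed_ratio[2], 2)
  expect_equal(sm$smoothed_ratio[1], 1.5)  # sees only itself and the middle
  # isolated probe keeps its own ratio
  iso <- smooth_sliding_window(probe_track(c(100, 5000), c(1.5, 4)), 200)
  expect_equal(iso$smoothed_ratio, c(1.5, 4))
  # constant track unchanged
  const <- smooth_sliding_window(probe_track(seq(0, 1000, 50),
                                             rep(2.5, 21)), 200)
  expect_equal(const$smoothed_ratio, rep(2.5, 21))
})

test_that("smoothing is shift-equivariant and chromosome-local", {
  withr::local_seed(4)
  tr <- probe_track(sort(sample(1:5000, 60)), rnorm(60))
  sm1 <- smooth_sliding_window(tr, 200)
  tr2 <- dplyr::mutate(tr, start = start + 12345, end = end + 12345)
  sm2 <- smooth_sliding_window(tr2, 200)
  expect_equal(sm1$smoothed_ratio, sm2$smoothed_ratio)
  # probes on another chromosome do not leak in
  tr3 <- dplyr::bind_rows(tr, dplyr::mutate(tr, chrom = "chr2",
                                            log2_ratio = log2_ratio + 10))
  sm3 <- smooth_sliding_window(tr3, 200)
  expect_equal(sm3$smoothed_ratio[sm3$chrom == "chr1"], sm1$smoothed_ratio)
})

test_that("hit calling is inclusive at the cut-off and monotone in it", {
  tr <- probe_track(c(100, 400, 700), c(2.0, 1.99, 3.5))
  sm <- smooth_sliding_window(tr, 200)
  hits2 <- call_positive_probes(sm, cutoff = 2)
  expect_setequal(hits2$probe_id, c("p001", "p003"))
  expect_equal(nrow(call_positive_probes(sm, cutoff = Inf)), 0)
  withr::local_seed(8)
  sm_r <- smooth_sliding_window(probe_track(sort(sample(1e5, 200)),
                                            rnorm(200, 1, 1.5)), 200)
  cuts <- sort(runif(5, -1, 4))
  hit_sets <- lapply(cuts, function(cc) {
    call_positive_probes(sm_r, cc)$probe_id
  })
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(hit_sets[[i + 1]] %in% hit_sets[[i]]))
  }
})

test_that("reproducibility filter is a symmetric probe_id intersection", {
  tr <- probe_track(c(100, 400, 700, 1000), c(3, 3, 3, 3))
  sm <- smooth_sliding_window(tr, 200)
  r1 <- sm[1:3, ]
  r2 <- sm[2:4, ]
  both <- reproducible_hits(r1, r2)
  expect_equal(both$probe_id, c("p002", "p003"))
  expect_equal(both$replicate_support, c("both", "both"))
  ba <- reproducible_hits(r2, r1)
  expect_equal(both$probe_id, ba$probe_id)
  expect_identical(reproducible_hits(r1, r1)$probe_id, r1$probe_id)
  expect_equal(nrow(reproducible_hits(r1[1, ], r2[3, ])), 0)
  expect_lte(nrow(both), min(nrow(r1), nrow(r2)))
  # same ids, different coordinates -> different universes
  r2_bad <- dplyr::mutate(r2, start = start + 5)
  expect_error(reproducible_hits(r1, r2_bad), "universe")
})

test_that("peak merging matches an interval-union oracle", {
  hits <- tibble::tibble(chrom = "chr1", start = c(0, 200, 500),
                         end = c(100, 300, 600), smoothed_ratio = 3)
  # gaps of 100 and 200 bp: both merge at max_gap = 200
  expect_equal(nrow(merge_hits_to_peaks(hits, max_gap = 200)), 1)
  expect_equal(nrow(merge_hits_to_peaks(hits, max_gap = 150)), 2)
  expect_equal(nrow(merge_hits_to_peaks(hits, max_gap = 0)), 3)
  touching <- tibble::tibble(chrom = "chr1", start = c(0, 100),
                             end = c(100, 200), smoothed_ratio = 3)
  expect_equal(nrow(merge_hits_to_peaks(touching, max_gap = 0)), 1)

  withr::local_seed(21)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    st <- sort(sample(1:5000, n))
    h <- tibble::tibble(chrom = sample(c("chr1", "chr2"), n, TRUE),
                        start = st, end = st + sample(10:80, n, TRUE),
                        smoothed_ratio = 3)
    gap <- sample(0:100, 1)
    got <- merge_hits_to_peaks(h, max_gap = gap) |>
      dplyr::arrange(chrom, start)
    # oracle: IRanges reduce with min.gapwidth = gap + 1
    want <- lapply(split(h, h$chrom), function(d) {
      rr <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end),
                            min.gapwidth = gap + 1)
      tibble::tibble(chrom = d$chrom[1],
                     start = BiocGenerics::start(rr) - 1,
                     end = BiocGenerics::end(rr))
    })
    want <- dplyr::bind_rows(want) |> dplyr::arrange(chrom, start)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # peaks never overlap
    by_chr <- split(got, got$chrom)
    expect_true(all(vapply(by_chr, function(d) {
      nrow(d) < 2 || all(d$start[-1] > head(d$end, -1))
    }, logical(1))))
  }
})

test_that("peak densities are zero-filled and scale with chromosome size", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(0, 1000),
                          end = c(100, 1100))
  cs <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(2e6, 2e6))
  d <- peak_density_by_chromosome(peaks, cs)
  expect_equal(d$n_peaks, c(2L, 0L))
  expect_equal(d$peaks_per_mb, c(1, 0))
  cs2 <- dplyr::mutate(cs, length = length / 2)
  expect_equal(peak_density_by_chromosome(peaks, cs2)$peaks_per_mb[1], 2)
  expect_error(peak_density_by_chromosome(
    dplyr::mutate(peaks, chrom = "chrX"), cs), "absent")
})
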