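test_that("reads are assigned to bins by fragment midpoint", {
  layout <- tiny_layout(1e4)
  # read [1500,1575): midpoint 1537 -> bin 1
  tr <- bin_stranded_reads(make_reads("chr1", 1500, 1575, "+"), layout)
  expect_equal(tr$F[2], 1)
  expect_equal(sum(tr$F), 1)
  expect_equal(sum(tr$R), 0)

  # two reads, same bin, opposite strands
  tr <- bin_stranded_reads(
    make_reads("chr1", c(1500, 1600), c(1575, 1675), c("+", "-")), layout
  )
  expect_equal(tr$F[2], 1)
  expect_equal(tr$R[2], 1)
})

test_that("binning conserves read counts (direct-count oracle)", {
  set.seed(11)
  layout <- tiny_layout(1e5)
  reads <- random_reads(10000)
  tr <- bin_stranded_reads(reads, layout)
  expect_equal(sum(tr$F) + sum(tr$R), 10000)
  expect_equal(sum(tr$F), sum(reads$strand == "+"))
  expect_equal(attr(tr, "library_size"), 10000)
})

test_that("CPM normalization scales by 1e6/library and preserves F:R ratios", {
  tr <- make_track(F = c(3, 0), R = c(0, 0), stage = "raw_counts")
  cpm <- cpm_normalize(tr, library_size = 1e6)
  expect_equal(cpm$F[1], 3.0)
  expect_equal(cpm$R, c(0, 0)) # all-zero strand stays zero
  expect_error(cpm_normalize(tr, library_size = 0), "positive")

  # partition is scale invariant: identical before and after CPM
  set.seed(3)
  raw <- make_track(F = rpois(50, 20), R = rpois(50, 20), stage = "raw_counts")
  p_raw <- compute_partition(raw)$partition
  p_cpm <- compute_partition(cpm_normalize(raw, 12345))$partition
  expect_equal(p_raw, p_cpm)
})

test_that("uniform blur matches its convolution oracles", {
  # constant arrays are fixed points (edge truncation renormalizes)
  const <- make_track(F = rep(2, 100), R = rep(2, 100))
  expect_equal(uniform_blur(const, 30)$F, rep(2, 100))

  # unit impulse spreads to 1/61 over the 61-bin window
  x <- numeric(301); x[101] <- 1
  imp <- uniform_blur(make_track(F = x, R = x), 30)
  expect_equal(imp$F[71:131], rep(1 / 61, 61))
  expect_equal(imp$F[c(70, 132)], c(0, 0))

  # impulse at the first bin with half-width 2: window {1,2,3} -> 1/3
  x <- numeric(10); x[1] <- 1
  imp <- uniform_blur(make_track(F = x, R = x), 2)
  expect_equal(imp$F[1], 1 / 3)

  # brute-force O(n*w) windowed mean agrees to 1e-12 on random arrays
  set.seed(21)
  for (h in c(0, 1, 7, 30)) {
    v <- runif(200)
    got <- uniform_blur(make_track(F = v, R = rev(v)), h)
    expect_equal(got$F, brute_blur(v, h), tolerance = 1e-12)
    expect_equal(got$R, brute_blur(rev(v), h), tolerance = 1e-12)
  }

  # blur is per chromosome: no bleed across the chromosome boundary
  two <- scarchor:::new_strand_track(
    dplyr::bind_rows(
      make_track(F = c(1, 0, 0), R = rep(0, 3), chrom = "chr1"),
      make_track(F = c(0, 0, 0), R = rep(0, 3), chrom = "chr2")
    ),
    1000, "cpm", 1e6
  )
  sm <- uniform_blur(two, 2)
  expect_equal(sm$F[4:6], c(0, 0, 0))
})

test_that("input correction subtracts, clips at zero, and masks by threshold", {
  ip <- make_track(F = c(1.0, 0.1, 0.2, 0.2), R = c(0.5, 0.5, 0.25, 0.35),
                   stage = "smoothed")
  input <- make_track(F = c(0.4, 0.4, 0, 0), R = c(0.5, 0.5, 0, 0),
                      stage = "smoothed")
  out <- input_correct_and_filter(ip, input, min_cpm = 0.3)
  expect_equal(out$F, c(0.6, 0.0, 0.2, 0.2))
  # masked iff both strands below 0.3
  expect_equal(out$masked, c(FALSE, TRUE, TRUE, FALSE))

  short <- make_track(F = 1, R = 1, stage = "smoothed")
  expect_error(input_correct_and_filter(ip, short), "bin width|grid")
})

test_that("partition formula, flip rule, and bounds", {
  tr <- make_track(F = c(1, 0.8, 0.5, 0), R = c(1, 0.2, 0, 0),
                   stage = "input_corrected")
  pt <- compute_partition(tr)
  expect_equal(pt$partition[1], 0)
  expect_equal(pt$partition[2], 0.6)
  expect_equal(pt$partition[3], 1.0) # bound attained
  expect_true(pt$masked[4])
  expect_equal(pt$mask_reason[4], "zero_coverage")
  expect_equal(pt$coverage, c(2, 1, 0.5, 0))

  flipped <- compute_partition(tr, flip = TRUE)
  expect_equal(flipped$partition[2], -0.6)
})

test_that("partition is antisymmetric under strand swap and invariant to scale", {
  set.seed(5)
  for (i in 1:10) {
    F <- runif(40, 0, 10)
    R <- runif(40, 0, 10)
    p <- compute_partition(make_track(F = F, R = R))$partition
    p_swap <- compute_partition(make_track(F = R, R = F))$partition
    expect_equal(p_swap, -p)
    expect_true(all(abs(p) <= 1))

    s <- runif(1, 0.1, 50)
    p_scaled <- compute_partition(make_track(F = s * F, R = s * R))$partition
    expect_equal(p_scaled, p)
  }
})
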