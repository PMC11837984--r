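test_that("IZ sets are sorted and overlapping zones merged", {
  izs <- iz_set(tibble::tibble(
    chrom = "chr1", start = c(5000, 1000, 1500), end = c(6000, 2000, 2500)
  ))
  expect_equal(nrow(izs), 2)
  expect_equal(izs$start, c(1000, 5000))
  expect_equal(izs$midpoint[1], (1000 + 2500) %/% 2)
})

test_that("windows orient by the sign of their offset from the IZ midpoint", {
  # partition +0.6 at offset +10 and -0.6 at offset -10 around an IZ at bin 20
  vals <- rep(NA_real_, 41)
  vals[21 + 10] <- 0.6
  vals[21 - 10] <- -0.6
  vals[21 + 3] <- NA # masked bin -> no row
  pt <- make_ptrack(vals)
  izs <- tibble::tibble(chrom = "chr1", start = 20000L, end = 21000L)
  wins <- orient_to_iz(pt, izs, flank = 15000)
  expect_equal(nrow(wins), 2)
  expect_equal(sort(wins$offset), c(-10, 10))
  expect_equal(wins$partition_oriented, c(0.6, 0.6))
  expect_equal(wins$partition_raw[wins$offset == -10], -0.6)

  expect_warning(
    orient_to_iz(pt, tibble::tibble(chrom = "chrX", start = 0L, end = 1000L),
                 flank = 5000),
    "unknown"
  )
  expect_error(orient_to_iz(pt, izs, flank = 1500), "multiple")
})

test_that("orientation is involutive under mirroring of the IZ neighborhood", {
  set.seed(13)
  n <- 41
  vals <- runif(n, -1, 1)
  izs <- tibble::tibble(chrom = "chr1", start = 20000L, end = 21000L)
  wins <- orient_to_iz(make_ptrack(vals), izs, flank = 20000)
  # mirror: reverse the neighborhood and negate (a fork-direction flip)
  mirrored <- -rev(vals)
  wins_m <- orient_to_iz(make_ptrack(mirrored), izs, flank = 20000)
  a <- wins[order(wins$offset), ]
  b <- wins_m[order(-wins_m$offset), ]
  expect_equal(a$partition_oriented, b$partition_oriented)
})

test_that("metaprofile averages raw partition per offset", {
  vals <- c(-0.4, -0.2, NA, 0.2, 0.4)
  pt <- make_ptrack(vals)
  izs <- tibble::tibble(chrom = "chr1", start = 2000L, end = 3000L)
  prof <- metaprofile(orient_to_iz(pt, izs, flank = 2000))
  # single IZ: profile equals that IZ's windows; masked offset 0 dropped
  expect_equal(prof$offset, c(-2, -1, 1, 2))
  expect_equal(prof$mean_partition, c(-0.4, -0.2, 0.2, 0.4))
  expect_equal(prof$n, rep(1L, 4))
})

test_that("exact signed-rank p matches exhaustive enumeration (ties included)", {
  # the 5 identical-difference pairs: exact two-sided p = 2/2^5
  a <- c(0.1, 0.2, 0.0, 0.15, 0.05)
  b <- c(0.4, 0.5, 0.3, 0.45, 0.35)
  expect_equal(scarchor:::paired_signed_rank_p(a, b), 0.0625)

  set.seed(17)
  for (i in 1:8) {
    n <- sample(3:9, 1)
    d <- round(rnorm(n), 1) # rounding makes ties likely
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(scarchor:::wilcoxon_exact_p(d), enum_signed_rank_p(d))
  }

  # agrees with the independent exact implementation when there are no ties
  set.seed(19)
  x <- rnorm(12)
  y <- rnorm(12)
  expect_equal(
    scarchor:::paired_signed_rank_p(x, y),
    stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
  )
})

test_that("pooled partition statistics pair bins and handle degenerate input", {
  vals_a <- c(-0.5, -0.3, 0.1, 0.3, 0.5)
  vals_b <- vals_a
  izs <- tibble::tibble(chrom = "chr1", start = 2000L, end = 3000L)
  ta <- orient_to_iz(make_ptrack(vals_a), izs, flank = 2000)
  tb <- orient_to_iz(make_ptrack(vals_b), izs, flank = 2000)
  res <- pooled_partition_stats(ta, tb)
  expect_equal(res$p_value, 1.0) # identical tables, zero diffs dropped
  expect_equal(res$median_a, res$median_b)
  expect_equal(res$n, 4) # offset 0 excluded

  expect_equal(glance(res)$p.value, 1.0)
  td <- tidy(res)
  expect_equal(td$condition, c("a", "b"))
  expect_equal(td$median, rep(res$median_a, 2))

  one <- ta[ta$offset == 1, ]
  expect_error(pooled_partition_stats(one, tb[0, ]), "fewer than 2")
})

test_that("two simulated conditions separate strongly in the paired rank test", {
  cfg_wt <- tiny_cfg(p_lead = 0.5, seed = 301)
  cfg_mut <- tiny_cfg(p_lead = 0.8, seed = 302)
  get_windows <- function(cfg) {
    sim <- simulate_scar_experiment(cfg, marks = "H4K20me2")
    pt <- partition_pipeline(sim$ip$H4K20me2, sim$input, sim$landscape$layout)
    orient_to_iz(pt, sim$landscape$izs)
  }
  wa <- get_windows(cfg_wt)
  wb <- get_windows(cfg_mut)
  res <- pooled_partition_stats(wa, wb)
  expect_gt(res$n, 1000)
  expect_lt(res$p_value, 1e-10)
  expect_gt(res$median_b, res$median_a)
})

test_that("leading fraction maps mean oriented partition linearly to percent", {
  izs <- tibble::tibble(chrom = "chr1", start = 2000L, end = 3000L)
  mk <- function(vals) orient_to_iz(make_ptrack(vals), izs, flank = 2000)

  # symmetric raw profile orients to mean 0 -> 50%
  t0 <- mk(c(0.2, 0.1, 0, 0.1, 0.2))
  expect_equal(leading_fraction(t0, min_offset_bins = 0, n_boot = 10)$estimate, 50)

  # oriented partition 0.6 everywhere -> 80%
  t1 <- mk(c(-0.6, -0.6, 0, 0.6, 0.6))
  expect_equal(leading_fraction(t1, min_offset_bins = 0, n_boot = 10)$estimate, 80)

  # lagging bias: mean oriented -0.16 -> 42%
  t2 <- mk(c(0.16, 0.16, 0, -0.16, -0.16))
  expect_equal(leading_fraction(t2, min_offset_bins = 0, n_boot = 10)$estimate, 42)

  expect_error(leading_fraction(t1, min_offset_bins = 10), "empty|no windows")

  td <- tidy(leading_fraction(t1, min_offset_bins = 0, n_boot = 50))
  expect_named(td, c("estimate", "conf.low", "conf.high", "mean.partition",
                     "n.windows", "n.iz"))
})

test_that("symmetric segregation gives a flat profile and antisymmetric bias", {
  sim <- simulate_scar_experiment(tiny_cfg(p_lead = 0.5, seed = 42),
                                  marks = "H4K20me2")
  pt <- partition_pipeline(sim$ip$H4K20me2, sim$input, sim$landscape$layout)
  wins <- orient_to_iz(pt, sim$landscape$izs)

  # mean partition ~ 0 within Monte-Carlo error
  m <- mean(wins$partition_oriented[wins$offset != 0])
  sem <- stats::sd(wins$partition_oriented[wins$offset != 0]) /
    sqrt(sum(wins$offset != 0))
  # windows are correlated over the 61-bin blur; allow for that in the SEM
  expect_lt(abs(m), 3 * sem * sqrt(61))

  # a biased library yields an antisymmetric S-profile: mean(+k) ~ -mean(-k)
  simb <- simulate_scar_experiment(tiny_cfg(p_lead = 0.8, seed = 43),
                                   marks = "H4K20me2")
  ptb <- partition_pipeline(simb$ip$H4K20me2, simb$input, simb$landscape$layout)
  prof <- metaprofile(orient_to_iz(ptb, simb$landscape$izs))
  up <- prof$mean_partition[match(-(31:100), prof$offset)]
  down <- prof$mean_partition[match(31:100, prof$offset)]
  expect_equal(mean(down), -mean(up), tolerance = 0.05)
  expect_gt(mean(down), 0.3)
})
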