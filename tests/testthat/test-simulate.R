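test_that("presets encode the studied conditions", {
  expect_equal(get_preset("wt")$p_lead, 0.50)
  expect_equal(get_preset("wt")$evict_frac, 0)
  expect_equal(get_preset("dpole4")$p_lead, 0.42)
  expect_equal(get_preset("mcm2-2a")$p_lead, 0.85)
  mut <- get_preset("dpole4-mcm2-2a")
  expect_equal(mut$p_lead, 0.80)
  expect_equal(mut$evict_frac, 0.20)
  expect_equal(mut$redeposit_frac, 0.25)
  expect_equal(mut$redeposit_target, "outside_domains")
  expect_equal(mut$spike_fraction, 5e-4)
  expect_error(get_preset("nope"), "wt.*dpole4")
})

test_that("config validation rejects out-of-range probabilities", {
  expect_error(sim_config(p_lead = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(evict_frac = -0.1), "\\[0, 1\\]")
})

test_that("fork direction flips only at IZ midpoints and termination points", {
  cfg <- tiny_cfg()
  land <- build_landscape(cfg)
  expect_equal(nrow(land$izs), 5)
  mids <- land$izs$midpoint
  expect_equal(diff(mids), rep(cfg$iz_spacing, 4))

  pos <- seq(1e4, cfg$chrom_length - 1e4, by = 1e4)
  dir <- fork_direction(land, rep("chr1", length(pos)), pos)
  expect_true(all(dir %in% c(-1, 1)))
  # 100 kb right of an IZ midpoint: rightward fork
  expect_equal(fork_direction(land, "chr1", mids[2] + 1e5), 1)
  expect_equal(fork_direction(land, "chr1", mids[2] - 1e5), -1)

  flips <- pos[which(diff(dir) != 0)]
  terminations <- (mids[-length(mids)] + mids[-1]) / 2
  boundaries <- sort(c(mids, terminations))
  # every sign change happens at an IZ midpoint or a termination point
  for (f in flips) {
    expect_lte(min(abs(f - boundaries)), 1e4)
  }
  expect_equal(length(flips), length(boundaries) - sum(boundaries > max(pos)))
})

test_that("histone conservation is exact in the truth record", {
  for (seed in 1:3) {
    cfg <- tiny_cfg(evict_frac = 0.3, redeposit_frac = 0.4, seed = seed)
    sim <- simulate_scar_experiment(cfg, marks = "H4K20me2")
    tr <- sim$truth
    expect_identical(tr$n_recycled + tr$n_redeposited + tr$n_lost, tr$n_parental)
    # expected lost fraction = evict * (1 - redeposit)
    expect_equal(tr$n_lost / tr$n_parental, 0.3 * 0.6, tolerance = 0.05)
  }
})

test_that("nucleosome density is conserved across conditions", {
  n_nucl <- function(cfg) {
    sim <- simulate_scar_experiment(cfg, marks = "H4K20me2")
    with(sim$truth, n_recycled + n_redeposited + n_new)
  }
  a <- n_nucl(tiny_cfg(seed = 5))
  b <- n_nucl(tiny_cfg(evict_frac = 0.2, redeposit_frac = 0.25, seed = 5))
  expect_equal(a, b, tolerance = 0.02)
})

test_that("identical config and seed give identical simulations", {
  cfg <- tiny_cfg(p_lead = 0.7, evict_frac = 0.1, redeposit_frac = 0.5, seed = 99)
  s1 <- simulate_scar_experiment(cfg)
  s2 <- simulate_scar_experiment(cfg)
  expect_identical(s1$ip$H4K20me2, s2$ip$H4K20me2)
  expect_identical(s1$ip$H4K20me0, s2$ip$H4K20me0)
  expect_identical(s1$input, s2$input)
  expect_identical(s1$truth, s2$truth)
})

test_that("symmetric recycling yields balanced strands; inputs are uniform", {
  cfg <- tiny_cfg(p_lead = 0.5, seed = 7)
  sim <- simulate_scar_experiment(cfg, marks = "H4K20me2")
  ip <- sim$ip$H4K20me2
  n_f <- sum(ip$strand == "+" & ip$origin == "target")
  n_r <- sum(ip$strand == "-" & ip$origin == "target")
  expect_lt(abs(n_f - n_r) / (n_f + n_r), 4 / sqrt(n_f + n_r))

  inp <- sim$input
  n_fi <- sum(inp$strand == "+")
  expect_lt(abs(n_fi / nrow(inp) - 0.5), 4 / (2 * sqrt(nrow(inp))))

  # spike proportion matches the configured chromatin fraction
  spike_frac <- mean(inp$origin == "spike")
  expect_lt(abs(spike_frac - cfg$spike_fraction), 2e-4)

  # per-bin input counts are approximately Poisson-uniform
  layout <- sim$landscape$layout
  tr <- bin_stranded_reads(inp, layout)
  counts <- tr$F + tr$R
  lambda <- mean(counts)
  expect_lt(abs(stats::var(counts) / lambda - 1), 0.1)
})

test_that("new histones mirror parental histones strand-wise", {
  cfg <- tiny_cfg(p_lead = 0.8, seed = 15, ip_depth = 4e5)
  sim <- simulate_scar_experiment(cfg)
  layout <- sim$landscape$layout
  oriented_mean <- function(reads) {
    pt <- compute_partition(bin_stranded_reads(reads, layout))
    wins <- orient_to_iz(pt, sim$landscape$izs)
    mean(wins$partition_oriented[abs(wins$offset) > 0 & abs(wins$offset) <= 250])
  }
  m_par <- oriented_mean(sim$ip$H4K20me2)
  m_new <- oriented_mean(sim$ip$H4K20me0)
  expect_gt(m_par, 0.5)
  # complementary deposition: new histones mirror the parental partition
  expect_equal(m_new, -m_par, tolerance = 0.1)
})

test_that("ChOR simulation realizes the configured retention losses", {
  cfg <- tiny_cfg(evict_frac = 0.2, redeposit_frac = 0.25, seed = 8,
                  ip_depth = 4e5, input_depth = 2e5)
  chor <- simulate_chor_experiment(cfg)
  expect_equal(chor$truth$in_domain_retention, 0.80, tolerance = 0.02)
  expect_equal(chor$truth$genome_wide_retention, 0.85, tolerance = 0.02)

  bad <- cfg
  bad$spike_fraction <- 1e-3
  expect_error(simulate_chor_experiment(cfg, cfg_ctrl = bad), "identical")
})

test_that("doubling IP depth leaves the efficiency estimate unchanged", {
  run <- function(depth, seed) {
    # generous spike fraction keeps the spike-count noise small at desk scale
    cfg <- tiny_cfg(evict_frac = 0.2, redeposit_frac = 0.25, seed = seed,
                    spike_fraction = 0.02, ip_depth = depth, input_depth = 4e5)
    chor <- simulate_chor_experiment(cfg)
    layout <- chor$landscape$layout
    tr_t <- rrpm_track(chor$treat$ip, layout,
                       spike_counts_from_reads(chor$treat$ip, chor$treat$input))
    tr_c <- rrpm_track(chor$ctrl$ip, layout,
                       spike_counts_from_reads(chor$ctrl$ip, chor$ctrl$input))
    efficiency_change(tr_t, tr_c, "in_domain", peaks = chor$landscape$domains)
  }
  e1 <- run(2e5, seed = 21)
  e2 <- run(4e5, seed = 22)
  expect_lt(abs(e1 - e2), 5)
})

test_that("written simulations are deterministic on disk", {
  cfg <- tiny_cfg(seed = 77, ip_depth = 5e4, input_depth = 2e4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_scar_experiment(cfg, marks = "H4K20me2"), d1)
  write_simulation(simulate_scar_experiment(cfg, marks = "H4K20me2"), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_true(file.exists(file.path(d1, "iz.bed")))
  expect_true(file.exists(file.path(d1, "truth.json")))
})
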