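#' Configure the replication-fork histone segregation simulator
#'
#' The simulator forward-models one round of replication around regularly
#' spaced initiation zones (IZs). Forks move outward from each IZ midpoint;
#' during an EdU pulse a track of `pulse_track` bp on each side of the
#' midpoint is replicated and labeled, and only that nascent chromatin is
#' sampled by the simulated IPs. Each parental nucleosome on a replicated
#' slot is either evicted (probability `evict_frac`) or recycled in place,
#' going to the leading strand with probability `p_lead` and to the lagging
#' strand otherwise. Evicted histones are redeposited with probability
#' `redeposit_frac` (at a uniformly random slot outside mark domains, or
#' anywhere, per `redeposit_target`, on a uniformly random daughter strand,
#' keeping their marks) and are otherwise lost to the soluble pool. New
#' histones fill every slot not occupied by a parental histone, so nucleosome
#' density is conserved. Exogenous spike-in chromatin is a constant pool of
#' `spike_fraction` of total chromatin, identical across conditions.
#'
#' @param n_chroms Number of target chromosomes (default 3).
#' @param chrom_length Chromosome length in bp (default 8e7).
#' @param iz_spacing Distance between IZ midpoints in bp (default 1.6e7).
#'   IZs are placed far apart relative to the labeled track so each track is
#'   analyzed in isolation; this is a deliberate desk-scale idealization.
#' @param pulse_track Length of labeled nascent chromatin on each side of an
#'   IZ midpoint, bp (default 3e5).
#' @param nucleosome_spacing Distance between nucleosome slots, bp (default
#'   200).
#' @param p_lead Probability that a recycled parental histone goes to the
#'   leading strand (default 0.5; applies only to the non-evicted fraction).
#' @param evict_frac Probability a parental histone is evicted instead of
#'   recycled (default 0).
#' @param redeposit_frac Probability an evicted histone is redeposited rather
#'   than lost (default 0).
#' @param redeposit_target `"outside_domains"` (default) or `"uniform"`.
#' @param ip_depth,input_depth Reads per IP / input library (defaults 2e6 and
#'   8e6). The input is sequenced deeper than the IP because the spike-in
#'   scale factor is estimated from the input's spike-read count; at these
#'   depths its Monte-Carlo error contributes well under one percentage point
#'   to the efficiency estimates.
#' @param spike_fraction Spike-in proportion of total chromatin (default
#'   5e-4, i.e. 0.05%).
#' @param fragment_len Sequenced fragment length, bp (default 150).
#' @param seed Integer seed from which all randomness of an experiment flows.
#' @return A `sim_config` object (named list).
#' @export
sim_config <- function(n_chroms = 3, chrom_length = 8e7, iz_spacing = 1.6e7,
                       pulse_track = 3e5, nucleosome_spacing = 200,
                       p_lead = 0.5, evict_frac = 0, redeposit_frac = 0,
                       redeposit_target = c("outside_domains", "uniform"),
                       ip_depth = 2e6, input_depth = 8e6,
                       spike_fraction = 5e-4, fragment_len = 150, seed = 1) {
  redeposit_target <- match.arg(redeposit_target)
  probs <- c(p_lead = p_lead, evict_frac = evict_frac,
             redeposit_frac = redeposit_frac, spike_fraction = spike_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("p_lead, evict_frac, redeposit_frac, spike_fraction must lie in [0, 1]")
  }
  stopifnot(iz_spacing < chrom_length, pulse_track * 2 < iz_spacing)
  structure(
    list(
      n_chroms = n_chroms, chrom_length = chrom_length,
      iz_spacing = iz_spacing, pulse_track = pulse_track,
      nucleosome_spacing = nucleosome_spacing,
      p_lead = p_lead, evict_frac = evict_frac,
      redeposit_frac = redeposit_frac, redeposit_target = redeposit_target,
      ip_depth = ip_depth, input_depth = input_depth,
      spike_fraction = spike_fraction, fragment_len = fragment_len,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sim_config> %d x %s bp chroms, IZ spacing %s, track +/-%s\n",
      "  p_lead=%.2f evict=%.2f redeposit=%.2f (%s)\n",
      "  depths IP %g / input %g, spike %.4f%%, seed %d\n"
    ),
    x$n_chroms, format(x$chrom_length, scientific = FALSE),
    format(x$iz_spacing, scientific = FALSE),
    format(x$pulse_track, scientific = FALSE),
    x$p_lead, x$evict_frac, x$redeposit_frac, x$redeposit_target,
    x$ip_depth, x$input_depth, 100 * x$spike_fraction, x$seed
  ))
  invisible(x)
}

#' Named presets reproducing the studied conditions
#'
#' * `wt`: symmetric recycling, `p_lead = 0.50`, no eviction.
#' * `dpole4`: moderate lagging-strand bias, `p_lead = 0.42`, no eviction.
#' * `mcm2-2a`: strong leading-strand bias, `p_lead = 0.85`, no eviction.
#' * `dpole4-mcm2-2a`: combined leading/lagging recycling defect,
#'   `p_lead = 0.80`, `evict_frac = 0.20`, `redeposit_frac = 0.25` with
#'   redeposition outside cognate domains — i.e. 20% of parental histones are
#'   lost from their cognate domains and a quarter of those reappear
#'   elsewhere, leaving 85% of the parental signal genome-wide.
#'
#' All presets share `spike_fraction = 5e-4` (0.05% of total chromatin) and
#' the default depths.
#'
#' @param name One of `"wt"`, `"dpole4"`, `"mcm2-2a"`, `"dpole4-mcm2-2a"`.
#' @param seed Seed stored in the config (default 1).
#' @return A [sim_config()].
#' @export
get_preset <- function(name, seed = 1) {
  presets <- list(
    "wt" = list(p_lead = 0.50, evict_frac = 0, redeposit_frac = 0),
    "dpole4" = list(p_lead = 0.42, evict_frac = 0, redeposit_frac = 0),
    "mcm2-2a" = list(p_lead = 0.85, evict_frac = 0, redeposit_frac = 0),
    "dpole4-mcm2-2a" = list(p_lead = 0.80, evict_frac = 0.20,
                            redeposit_frac = 0.25)
  )
  if (!name %in% names(presets)) {
    abort(paste0(
      "unknown preset '", name, "'; available: ",
      paste(names(presets), collapse = ", ")
    ))
  }
  p <- presets[[name]]
  sim_config(p_lead = p$p_lead, evict_frac = p$evict_frac,
             redeposit_frac = p$redeposit_frac,
             redeposit_target = "outside_domains", seed = seed)
}

#' Eviction-free control for a treated configuration
#'
#' Same geometry, depths and spike-in proportion, but no eviction (all
#' parental histones recycled), for paired efficiency comparisons.
#'
#' @param cfg A [sim_config()].
#' @return A [sim_config()] with `evict_frac = 0` and `redeposit_frac = 0`.
#' @export
eviction_free <- function(cfg) {
  cfg$evict_frac <- 0
  cfg$redeposit_frac <- 0
  cfg
}

#' Build the simulated genome landscape
#'
#' Places IZs at regular spacing (midpoints at `iz_spacing/2 + k*iz_spacing`),
#' defines fork direction everywhere (rightward downstream of the nearest IZ
#' midpoint, leftward upstream; basins terminate midway between adjacent IZs),
#' and lays two bin-aligned mark domains inside each labeled track, offset
#' from both the IZ midpoint and the track edges.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `layout` ([genome_layout()]; target contigs
#'   `chr1..chrN`, spike contig `dm6_chr2L` implied by the prefix), `izs`
#'   (an [iz_set()] tibble of 30-kb zones), `domains` (interval tibble), and
#'   `spike_contig` (name and length of the spike contig used for simulated
#'   spike reads).
#' @export
build_landscape <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  layout <- genome_layout(setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms))

  mids_per_chrom <- seq(cfg$iz_spacing / 2, cfg$chrom_length - cfg$iz_spacing / 2,
                        by = cfg$iz_spacing)
  izs <- tidyr::crossing(chrom = chroms, mid = mids_per_chrom) |>
    mutate(start = as.integer(.data$mid - 15000),
           end = as.integer(.data$mid + 15000)) |>
    select("chrom", "start", "end") |>
    iz_set()

  # two 120-kb domains per track, clear of the IZ midpoint and track edges
  dom_offsets <- rbind(c(-260000, -140000), c(60000, 180000))
  domains <- purrr::map_dfr(seq_len(nrow(izs)), function(i) {
    tibble(
      chrom = izs$chrom[i],
      start = as.integer(izs$midpoint[i] + dom_offsets[, 1]),
      end = as.integer(izs$midpoint[i] + dom_offsets[, 2])
    )
  }) |>
    arrange(.data$chrom, .data$start)

  list(
    layout = layout, izs = izs, domains = domains,
    spike_contig = list(name = "dm6_chr2L", length = 1e6)
  )
}

#' Replication fork direction at arbitrary positions
#'
#' @param landscape A [build_landscape()] result.
#' @param chrom,pos Vectors of positions (bp).
#' @return `+1` for a rightward-moving fork, `-1` for leftward. Direction
#'   flips only at IZ midpoints and at termination points midway between
#'   adjacent IZs; the midpoint itself is assigned `+1`.
#' @export
fork_direction <- function(landscape, chrom, pos) {
  izs <- landscape$izs
  vapply(seq_along(pos), function(i) {
    mids <- izs$midpoint[izs$chrom == chrom[i]]
    d <- pos[i] - mids[which.min(abs(pos[i] - mids))]
    if (d >= 0) 1 else -1
  }, numeric(1))
}

# Nascent slot table: one row per replicated parental nucleosome slot.
nascent_slots <- function(cfg, landscape) {
  offs <- seq(-cfg$pulse_track, cfg$pulse_track, by = cfg$nucleosome_spacing)
  izs <- landscape$izs
  slots <- tibble(
    chrom = rep(izs$chrom, each = length(offs)),
    iz_id = rep(izs$iz_id, each = length(offs)),
    pos = rep(izs$midpoint, each = length(offs)) + rep(offs, times = nrow(izs)),
    fork_dir = rep(ifelse(rep(offs, times = nrow(izs)) >= 0, 1L, -1L))
  )
  dom <- landscape$domains
  gr_slots <- GenomicRanges::GRanges(slots$chrom,
                                     IRanges::IRanges(slots$pos + 1L, slots$pos + 1L))
  slots$in_domain <- GenomicRanges::countOverlaps(
    gr_slots, intervals_to_granges(dom)
  ) > 0
  slots
}

# chromatin bookkeeping shared by SCAR and ChOR sampling
total_chromatin_slots <- function(cfg) {
  cfg$n_chroms * cfg$chrom_length / cfg$nucleosome_spacing
}

spike_pool_units <- function(cfg) {
  cfg$spike_fraction * total_chromatin_slots(cfg)
}

# Segregate parental histones over the nascent slots. Uses the current RNG
# stream. Returns parental nucleosome table + new-histone occupancy + truth.
segregate_parental <- function(cfg, landscape) {
  slots <- nascent_slots(cfg, landscape)
  n <- nrow(slots)

  evicted <- runif(n) < cfg$evict_frac
  leading <- runif(n) < cfg$p_lead # used only where recycled
  recycled <- !evicted

  # strand of the nascent daughter a histone lands on:
  # rightward fork -> leading = forward; leftward fork -> leading = reverse
  daughter_strand <- function(is_leading, dir) {
    ifelse(is_leading == (dir > 0), "+", "-")
  }

  rec_leading <- leading[recycled]
  rec <- tibble(
    chrom = slots$chrom[recycled],
    iz_id = slots$iz_id[recycled],
    pos = slots$pos[recycled],
    leading = rec_leading,
    strand = daughter_strand(rec_leading, slots$fork_dir[recycled]),
    in_domain = slots$in_domain[recycled],
    origin_in_domain = slots$in_domain[recycled],
    class = "recycled"
  )

  redeposit <- evicted & (runif(n) < cfg$redeposit_frac)
  n_red <- sum(redeposit)
  if (n_red > 0) {
    target_pool <- if (cfg$redeposit_target == "outside_domains") {
      which(!slots$in_domain)
    } else {
      seq_len(n)
    }
    land <- sample(target_pool, n_red, replace = TRUE)
    land_leading <- runif(n_red) < 0.5
    red <- tibble(
      chrom = slots$chrom[land],
      iz_id = slots$iz_id[land],
      pos = slots$pos[land],
      leading = land_leading,
      strand = daughter_strand(land_leading, slots$fork_dir[land]),
      in_domain = slots$in_domain[land],
      origin_in_domain = slots$in_domain[redeposit],
      class = "redeposited"
    )
  } else {
    red <- rec[0, ]
  }

  parental <- bind_rows(rec, red)

  # new histones fill every daughter slot (2 per parental slot) not occupied
  # by a parental histone; nucleosome density is conserved
  slot_key <- paste(slots$chrom, slots$pos)
  par_idx <- match(paste(parental$chrom, parental$pos), slot_key)
  daughter_idx <- par_idx + ifelse(parental$leading, 0L, n)
  occ <- tabulate(daughter_idx, nbins = 2L * n)
  new_count <- pmax(1L - occ, 0L)

  truth <- list(
    n_parental = n,
    n_recycled = nrow(rec),
    n_redeposited = n_red,
    n_lost = n - nrow(rec) - n_red,
    n_new = sum(new_count),
    n_daughter_slots = 2L * n,
    marked_in_domain = sum(parental$origin_in_domain & parental$in_domain),
    marked_genome_wide = sum(parental$origin_in_domain)
  )

  list(slots = slots, parental = parental, new_count = new_count,
       truth = truth)
}

strand_of_new <- function(slots, daughter_leading) {
  ifelse(daughter_leading == (slots$fork_dir > 0), "+", "-")
}

reads_from_positions <- function(chrom, pos, strand, fragment_len) {
  half <- fragment_len %/% 2L
  tibble(
    chrom = chrom,
    start = as.integer(pos - half),
    end = as.integer(pos - half + fragment_len),
    strand = strand,
    origin = "target"
  )
}

spike_reads <- function(n, landscape, fragment_len) {
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), origin = character()))
  }
  pos <- floor(runif(n, fragment_len, landscape$spike_contig$length - fragment_len))
  tibble(
    chrom = landscape$spike_contig$name,
    start = as.integer(pos),
    end = as.integer(pos + fragment_len),
    strand = ifelse(runif(n) < 0.5, "+", "-"),
    origin = "spike"
  )
}

finish_library <- function(target, spike) {
  out <- bind_rows(target, spike)
  attr(out, "totals") <- list(
    target = nrow(target), spike = nrow(spike), discarded = 0L
  )
  out
}

# Sample an IP library for a mark from a segregation outcome. The
# immunoprecipitable pool is the set of nascent nucleosomes carrying the mark;
# spike-in chromatin contributes a constant pool of spike_fraction x total
# chromatin slots, identical across conditions.
sample_ip_library <- function(cfg, landscape, seg, mark, depth = cfg$ip_depth) {
  slots <- seg$slots
  parental <- seg$parental
  n <- nrow(slots)

  if (mark %in% c("H4K20me2")) {
    pool_chrom <- parental$chrom
    pool_pos <- parental$pos
    pool_strand <- parental$strand
    pool_w <- rep(1, nrow(parental))
  } else if (mark %in% c("H3K27me3", "H3K36me3")) {
    keep <- parental$origin_in_domain
    pool_chrom <- parental$chrom[keep]
    pool_pos <- parental$pos[keep]
    pool_strand <- parental$strand[keep]
    pool_w <- rep(1, sum(keep))
  } else if (mark == "H4K20me0") {
    has_new <- which(seg$new_count > 0)
    slot_i <- ((has_new - 1L) %% n) + 1L
    is_leading <- has_new <= n
    pool_chrom <- slots$chrom[slot_i]
    pool_pos <- slots$pos[slot_i]
    pool_strand <- strand_of_new(slots[slot_i, ], is_leading)
    pool_w <- seg$new_count[has_new]
  } else if (mark == "H3") {
    # all nascent nucleosomes: density is conserved, so uniform over daughters
    slot_i <- rep(seq_len(n), 2L)
    is_leading <- rep(c(TRUE, FALSE), each = n)
    pool_chrom <- slots$chrom[slot_i]
    pool_pos <- slots$pos[slot_i]
    pool_strand <- strand_of_new(slots[slot_i, ], is_leading)
    pool_w <- rep(1, 2L * n)
  } else {
    abort(paste0("unknown mark '", mark, "'"))
  }

  m_target <- sum(pool_w)
  k_spike <- spike_pool_units(cfg)
  n_spike <- rbinom(1, depth, k_spike / (k_spike + m_target))
  n_target <- depth - n_spike

  pick <- sample.int(length(pool_w), n_target, replace = TRUE, prob = pool_w)
  target <- reads_from_positions(
    pool_chrom[pick], pool_pos[pick], pool_strand[pick], cfg$fragment_len
  )
  finish_library(target, spike_reads(n_spike, landscape, cfg$fragment_len))
}

#' Simulate a matched input library
#'
#' Two input flavors are generated. `scope = "genome"` is a total-chromatin
#' (pre-capture) input: uniformly random positions over the whole target
#' genome with Bernoulli(0.5) strand, plus spike reads in proportion to the
#' spike pool over total chromatin — the matched input for SCAR partition
#' analysis. `scope = "nascent"` is an EdU-captured input sampling all nascent
#' daughter nucleosomes uniformly (plus the constant spike pool), the matched
#' input for spike-calibrated ChOR quantification.
#'
#' @param cfg A [sim_config()].
#' @param landscape A [build_landscape()] result.
#' @param scope `"genome"` or `"nascent"`.
#' @param seg A segregation outcome (required for `scope = "nascent"`).
#' @param depth Number of reads (default `cfg$input_depth`).
#' @return A read tibble with `origin` column and totals attribute.
#' @export
simulate_input <- function(cfg, landscape, scope = c("genome", "nascent"),
                           seg = NULL, depth = cfg$input_depth) {
  scope <- match.arg(scope)
  k_spike <- spike_pool_units(cfg)
  if (scope == "genome") {
    pool_total <- total_chromatin_slots(cfg)
    n_spike <- rbinom(1, depth, k_spike / (k_spike + pool_total))
    n_target <- depth - n_spike
    chroms <- landscape$layout$chrom_sizes$chrom
    ci <- sample.int(length(chroms), n_target, replace = TRUE)
    pos <- floor(runif(n_target, cfg$fragment_len, cfg$chrom_length - cfg$fragment_len))
    target <- reads_from_positions(
      chroms[ci], pos,
      ifelse(runif(n_target) < 0.5, "+", "-"), cfg$fragment_len
    )
  } else {
    if (is.null(seg)) abort("scope 'nascent' needs a segregation outcome")
    slots <- seg$slots
    n_daughters <- 2L * nrow(slots)
    n_spike <- rbinom(1, depth, k_spike / (k_spike + n_daughters))
    n_target <- depth - n_spike
    slot_i <- sample.int(nrow(slots), n_target, replace = TRUE)
    target <- reads_from_positions(
      slots$chrom[slot_i], slots$pos[slot_i],
      ifelse(runif(n_target) < 0.5, "+", "-"), cfg$fragment_len
    )
  }
  finish_library(target, spike_reads(n_spike, landscape, cfg$fragment_len))
}

#' Simulate a complete SCAR experiment
#'
#' Seeds the RNG from `cfg$seed`, segregates parental histones, and samples
#' one stranded IP library per requested mark plus a matched total-chromatin
#' input. Identical config and seed give byte-identical results.
#'
#' @param cfg A [sim_config()].
#' @param marks Marks to IP (default parental `"H4K20me2"` and new
#'   `"H4K20me0"` histones).
#' @return A list with `landscape`, `ip` (named list of read tibbles),
#'   `input` (read tibble), and `truth` (realized segregation counts; the
#'   conservation identity recycled + redeposited + lost = parental holds
#'   exactly).
#' @export
simulate_scar_experiment <- function(cfg, marks = c("H4K20me2", "H4K20me0")) {
  set.seed(cfg$seed)
  landscape <- build_landscape(cfg)
  seg <- segregate_parental(cfg, landscape)
  ip <- lapply(setNames(marks, marks), function(m) {
    sample_ip_library(cfg, landscape, seg, m)
  })
  input <- simulate_input(cfg, landscape, "genome")
  list(landscape = landscape, ip = ip, input = input, truth = seg$truth)
}

#' Simulate a paired ChOR experiment (treated vs control)
#'
#' Seeds the RNG from `cfg_treat$seed`, builds one shared landscape (both
#' configs must share geometry and spike-in proportion), and for each
#' condition segregates parental histones and samples a strandless-quantified
#' IP of the mark plus an EdU-captured nascent input. Spike-in chromatin is a
#' constant pool, independent of condition.
#'
#' @param cfg_treat Treated-condition [sim_config()].
#' @param cfg_ctrl Control [sim_config()]; defaults to
#'   [eviction_free()]`(cfg_treat)`.
#' @param mark `"H3K27me3"`, `"H3K36me3"` or `"H3"`.
#' @return A list with `landscape`, `treat`/`ctrl` (each a list of `ip` and
#'   `input` read tibbles plus `truth`), and `truth` summarizing realized
#'   in-domain and genome-wide mark retention (treated over control).
#' @export
simulate_chor_experiment <- function(cfg_treat, cfg_ctrl = eviction_free(cfg_treat),
                                     mark = "H3K27me3") {
  if (cfg_ctrl$spike_fraction != cfg_treat$spike_fraction) {
    abort("spike_fraction must be identical across conditions")
  }
  set.seed(cfg_treat$seed)
  landscape <- build_landscape(cfg_treat)
  one <- function(cfg) {
    seg <- segregate_parental(cfg, landscape)
    list(
      ip = sample_ip_library(cfg, landscape, seg, mark),
      input = simulate_input(cfg, landscape, "nascent", seg),
      truth = seg$truth
    )
  }
  ctrl <- one(cfg_ctrl)
  treat <- one(cfg_treat)
  list(
    landscape = landscape, ctrl = ctrl, treat = treat,
    truth = list(
      in_domain_retention =
        treat$truth$marked_in_domain / ctrl$truth$marked_in_domain,
      genome_wide_retention =
        treat$truth$marked_genome_wide / ctrl$truth$marked_genome_wide
    )
  )
}

#' Simulate a histone peptidoform MS1 area table
#'
#' Generates per-peptidoform MS1 areas proportional to ground-truth relative
#' abundances, optionally perturbed by multiplicative lognormal noise with
#' unit mean (so recovery is unbiased), plus one coeluting isobaric pair
#' (H3K36me3 vs H3K27me2K36me1) whose pooled area and analogous fragment-ion
#' intensities are consistent with the generated split.
#'
#' @param truth A tibble with columns `backbone_id`, `modset`, `fraction`
#'   (fractions summing to 1 within each backbone). Defaults to an H3 27-40
#'   K27 methylation-state vector (me0/me1/me2/me3 at 35/30/20/15%).
#' @param noise_cv Coefficient of variation of multiplicative lognormal area
#'   noise (default 0).
#' @param base_area Total area scale (default 1e6).
#' @return A list with `records` (peptidoform tibble usable by
#'   [relative_abundance()]) and `isobaric`: the pooled `total_area`, the
#'   fragment `pairs` table, and the true component areas
#'   (`area_a` = K27me2;K36me1, `area_b` = K27un;K36me3).
#' @export
simulate_ms_table <- function(truth = NULL, noise_cv = 0, base_area = 1e6) {
  if (is.null(truth)) {
    truth <- tibble(
      backbone_id = "H3 27-40",
      modset = c("K27un;K36un", "K27me1;K36un", "K27me2;K36un", "K27me3;K36un"),
      fraction = c(0.35, 0.30, 0.20, 0.15)
    )
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- rlnorm(nrow(truth), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  records <- tibble(
    backbone_id = truth$backbone_id,
    modset = truth$modset,
    charge = 2L,
    ms1_area = base_area * truth$fraction * noise
  )

  # coeluting isobaric pair: H3K27me2K36me1 (a) vs H3K36me3 (b), true 3:1
  area_a <- 0.15 * base_area
  area_b <- 0.05 * base_area
  ion_scale <- c(y7 = 1.0, y5 = 0.6, b3 = 0.3)
  pairs <- tibble(
    ion = names(ion_scale),
    intensity_a = unname(ion_scale) * area_a / base_area * 100,
    intensity_b = unname(ion_scale) * area_b / base_area * 100
  )
  list(
    records = records,
    isobaric = list(
      backbone_id = "H3 27-40",
      modset_a = "K27me2;K36me1", modset_b = "K27un;K36me3",
      total_area = area_a + area_b,
      area_a = area_a, area_b = area_b,
      pairs = pairs
    )
  )
}

#' Write a simulated experiment to disk
#'
#' Emits per-library BED6 read files, `iz.bed`, `domains.bed`,
#' `chrom_sizes.tsv` and `truth.json` into a directory, the on-disk interface
#' consumed by the command-line pipeline.
#'
#' @param sim A [simulate_scar_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed6 <- function(reads, path) {
    lines <- sprintf("%s\t%d\t%d\t.\t0\t%s",
                     reads$chrom, reads$start, reads$end, reads$strand)
    writeLines(lines, path)
  }
  for (m in names(sim$ip)) {
    write_bed6(sim$ip[[m]], file.path(dir, paste0("ip_", m, ".bed")))
  }
  write_bed6(sim$input, file.path(dir, "input.bed"))
  izs <- sim$landscape$izs
  writeLines(sprintf("%s\t%d\t%d", izs$chrom, izs$start, izs$end),
             file.path(dir, "iz.bed"))
  dom <- sim$landscape$domains
  writeLines(sprintf("%s\t%d\t%d", dom$chrom, dom$start, dom$end),
             file.path(dir, "domains.bed"))
  cs <- sim$landscape$layout$chrom_sizes
  writeLines(sprintf("%s\t%d", cs$chrom, cs$length),
             file.path(dir, "chrom_sizes.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
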