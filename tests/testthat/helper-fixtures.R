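# Shared builders for synthetic fixtures; everything is generated in code.

tiny_layout <- function(len = 1e5, chroms = "chr1") {
  genome_layout(setNames(rep(len, length(chroms)), chroms))
}

# a read tibble as read_stranded_reads() would return it (target origin)
make_reads <- function(chrom, start, end, strand) {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, origin = "target"
  )
}

# uniformly random stranded reads on one chromosome
random_reads <- function(n, len = 1e5, read_len = 50) {
  start <- floor(runif(n, 0, len - read_len))
  make_reads("chr1", start, start + read_len,
             ifelse(runif(n) < 0.5, "+", "-"))
}

# strand track with given per-bin F/R values on one chromosome
make_track <- function(F, R, bin_width = 1000, stage = "cpm",
                       library_size = 1e6, chrom = "chr1") {
  n <- length(F)
  tb <- tibble::tibble(
    chrom = chrom,
    start = as.integer((seq_len(n) - 1L) * bin_width),
    end = as.integer(seq_len(n) * bin_width),
    F = F, R = R
  )
  scarchor:::new_strand_track(tb, bin_width, stage, library_size)
}

# partition track with explicit per-bin values (NA = masked)
make_ptrack <- function(partition, bin_width = 1000, chrom = "chr1",
                        coverage = 1) {
  n <- length(partition)
  masked <- is.na(partition)
  structure(
    tibble::tibble(
      chrom = chrom,
      start = as.integer((seq_len(n) - 1L) * bin_width),
      end = as.integer(seq_len(n) * bin_width),
      partition = partition,
      coverage = rep_len(coverage, n),
      masked = masked,
      mask_reason = ifelse(masked, "low_cpm", "ok")
    ),
    bin_width = bin_width,
    class = c("partition_track", class(tibble::tibble()))
  )
}

# small fast simulator config (same geometry family as the defaults)
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_chroms = 1, chrom_length = 8e6, iz_spacing = 1.6e6,
         pulse_track = 3e5, ip_depth = 2e5, input_depth = 1e5),
    list(...)
  )
  do.call(sim_config, args)
}

# independent O(n * w) windowed-mean oracle for the uniform blur
brute_blur <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - h):min(n, i + h)
    mean(x[w])
  }, numeric(1))
}

# independent O(n^2) consensus-peak oracle: pool, sort, merge by gap, keep
# merged intervals overlapping every replicate
brute_consensus <- function(replicate_peaks, merge_dist) {
  pooled <- do.call(rbind, lapply(replicate_peaks, as.data.frame))
  pooled <- pooled[order(pooled$chrom, pooled$start), ]
  merged <- list()
  for (i in seq_len(nrow(pooled))) {
    rec <- pooled[i, ]
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && last$chrom == rec$chrom &&
        rec$start - last$end <= merge_dist) {
      last$end <- max(last$end, rec$end)
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1]] <- rec[c("chrom", "start", "end")]
    }
  }
  overlaps_any <- function(m, tb) {
    any(tb$chrom == m$chrom & tb$start < m$end & tb$end > m$start)
  }
  keep <- vapply(merged, function(m) {
    all(vapply(replicate_peaks, function(tb) overlaps_any(m, tb), logical(1)))
  }, logical(1))
  out <- do.call(rbind, merged[keep])
  if (is.null(out)) {
    data.frame(chrom = character(), start = integer(), end = integer())
  } else {
    out
  }
}

# exact signed-rank reference by explicit enumeration of all 2^n sign
# assignments (tied ranks averaged), two-sided
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

random_intervals <- function(n, span = 10000, max_len = 400) {
  start <- sort(sample.int(span, n))
  tibble::tibble(
    chrom = "chr1",
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE)
  )
}
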