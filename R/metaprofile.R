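#' Load and normalize an initiation-zone set
#'
#' Sorts initiation zones (IZs) and merges overlapping records so the set is
#' non-overlapping; the midpoint `floor((start + end) / 2)` of each zone
#' anchors fork direction: forks move rightward downstream (higher coordinate)
#' of the midpoint and leftward upstream.
#'
#' @param izs An interval tibble (`chrom`, `start`, `end`), e.g. from
#'   [read_intervals()].
#' @return A sorted, non-overlapping interval tibble with columns `chrom`,
#'   `start`, `end`, `iz_id`, `midpoint`.
#' @export
iz_set <- function(izs) {
  izs <- as_tibble(izs)
  gr <- GenomicRanges::reduce(intervals_to_granges(izs))
  out <- granges_to_intervals(gr) |>
    arrange(.data$chrom, .data$start)
  out$iz_id <- seq_len(nrow(out))
  out$midpoint <- (out$start + out$end) %/% 2L
  out
}

intervals_to_granges <- function(tb) {
  GenomicRanges::GRanges(
    seqnames = tb$chrom,
    ranges = IRanges::IRanges(start = tb$start + 1L, end = tb$end)
  )
}

granges_to_intervals <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Orient partition windows around initiation zones
#'
#' For each IZ, collects every unmasked partition bin whose center lies within
#' `flank` of the IZ midpoint. The signed bin offset from the IZ-midpoint bin
#' defines upstream (offset < 0, lower coordinate) and downstream windows.
#' Upstream windows are multiplied by -1 (`partition_oriented =
#' partition_raw * sign(offset)`), so a mark preferentially segregating with
#' the leading strand pools as positive oriented partition on both sides of
#' the IZ: downstream of the midpoint the fork moves rightward and the leading
#' nascent strand maps to the forward genome strand; upstream the assignments
#' swap.
#'
#' @param ptrack A `partition_track` (see [compute_partition()]).
#' @param izs An IZ tibble ([iz_set()] is applied if not already).
#' @param flank Flank distance in bp on each side of the IZ midpoint; must be
#'   a multiple of the bin width (default 250000).
#' @return An `oriented_windows` tibble with columns `iz_id`, `chrom`,
#'   `bin_start`, `offset` (bins), `partition_raw`, `partition_oriented`,
#'   `coverage`. IZs on chromosomes absent from the track are skipped with a
#'   warning. Masked bins contribute no rows.
#' @export
orient_to_iz <- function(ptrack, izs, flank = 250000) {
  bw <- attr(ptrack, "bin_width")
  if (flank %% bw != 0) {
    abort("flank must be a multiple of the track bin width")
  }
  if (!"iz_id" %in% names(izs)) izs <- iz_set(izs)

  known <- izs$chrom %in% unique(ptrack$chrom)
  if (any(!known)) {
    warn(paste0(sum(!known), " IZ(s) on unknown chromosomes skipped"))
    izs <- izs[known, ]
  }
  k <- as.integer(flank / bw)
  offsets <- seq.int(-k, k)
  n_iz <- nrow(izs)

  mid_bin <- izs$midpoint %/% bw
  tab <- tibble(
    iz_id = rep(izs$iz_id, each = length(offsets)),
    chrom = rep(izs$chrom, each = length(offsets)),
    offset = rep(offsets, times = n_iz),
    bin = rep(mid_bin, each = length(offsets)) + rep(offsets, times = n_iz)
  )

  key <- paste(ptrack$chrom, ptrack$start %/% bw)
  idx <- match(paste(tab$chrom, tab$bin), key)
  found <- !is.na(idx) & !ptrack$masked[pmax(idx, 1L)]
  tab <- tab[found, ]
  idx <- idx[found]

  out <- tibble(
    iz_id = tab$iz_id,
    chrom = tab$chrom,
    bin_start = ptrack$start[idx],
    offset = tab$offset,
    partition_raw = ptrack$partition[idx],
    partition_oriented = ptrack$partition[idx] * sign(tab$offset),
    coverage = ptrack$coverage[idx]
  )
  structure(
    out,
    bin_width = bw, flank = flank,
    class = c("oriented_windows", class(tibble()))
  )
}

#' Average partition profile around initiation zones
#'
#' Per signed offset, the mean raw (un-oriented) partition across IZs. A mark
#' biased toward the leading strand yields an S-shaped antisymmetric profile
#' through zero at the IZ midpoint.
#'
#' @param table An `oriented_windows` tibble from [orient_to_iz()].
#' @return A `scar_metaprofile` tibble with columns `offset`, `mean_partition`,
#'   `n` (windows contributing at that offset).
#' @export
metaprofile <- function(table) {
  if (nrow(table) == 0) abort("empty oriented-window table")
  out <- table |>
    group_by(.data$offset) |>
    summarise(mean_partition = mean(.data$partition_raw), n = dplyr::n(),
              .groups = "drop") |>
    arrange(.data$offset)
  structure(
    out,
    bin_width = attr(table, "bin_width"),
    class = c("scar_metaprofile", class(tibble()))
  )
}

# Exact two-sided signed-rank p-value by dynamic programming over doubled
# midranks (equivalent to enumerating all 2^n sign assignments, ties included).
# Zero differences are dropped beforehand by the caller.
wilcoxon_exact_p <- function(d) {
  n <- length(d)
  if (n == 0) return(1)
  r2 <- as.integer(round(2 * rank(abs(d))))
  w2 <- sum(r2[d > 0])
  total <- sum(r2)
  counts <- c(1, numeric(total)) # counts[s + 1] = #subsets with doubled-rank sum s
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  cum <- cumsum(counts)
  p_le <- cum[w2 + 1] / 2^n
  p_ge <- (2^n - ifelse(w2 == 0, 0, cum[w2])) / 2^n
  min(1, 2 * min(p_le, p_ge))
}

paired_signed_rank_p <- function(a, b, exact_max_n = 25) {
  d <- a - b
  d <- d[d != 0] # zero differences dropped, standard convention
  if (length(d) == 0) return(1)
  if (length(d) <= exact_max_n) {
    wilcoxon_exact_p(d)
  } else {
    suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                         correct = TRUE)$p.value
    )
  }
}

#' Compare pooled oriented partition between two conditions
#'
#' Pools oriented partition over IZ-flanking windows for two libraries sharing
#' the same bin universe (same IZs, flank and bin width), pairs windows by
#' genomic bin identity, drops bins masked in either condition as well as the
#' IZ-midpoint bin (offset 0), and reports medians and quartiles per condition
#' together with a two-sided Wilcoxon signed-rank p-value on the paired
#' oriented partitions (exact for n <= 25 pairs with zero differences dropped;
#' normal approximation with continuity correction above).
#'
#' @param table_a,table_b `oriented_windows` tibbles from [orient_to_iz()].
#' @return A `partition_test` object; see [tidy.partition_test()] and
#'   [glance.partition_test()].
#' @export
pooled_partition_stats <- function(table_a, table_b) {
  a <- table_a[table_a$offset != 0, c("chrom", "bin_start", "partition_oriented")]
  b <- table_b[table_b$offset != 0, c("chrom", "bin_start", "partition_oriented")]
  pairs <- inner_join(a, b, by = c("chrom", "bin_start"),
                      suffix = c("_a", "_b"))
  pairs <- pairs[stats::complete.cases(pairs), ]
  if (nrow(pairs) < 2) abort("fewer than 2 shared unmasked bins")
  qa <- quantile(pairs$partition_oriented_a, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- quantile(pairs$partition_oriented_b, c(0.25, 0.5, 0.75), names = FALSE)
  structure(
    list(
      n = nrow(pairs),
      median_a = qa[2], q1_a = qa[1], q3_a = qa[3],
      median_b = qb[2], q1_b = qb[1], q3_b = qb[3],
      p_value = paired_signed_rank_p(pairs$partition_oriented_a,
                                     pairs$partition_oriented_b),
      method = "Wilcoxon signed-rank (paired windows)"
    ),
    class = "partition_test"
  )
}

#' @export
print.partition_test <- function(x, ...) {
  cat("Paired window comparison (", x$method, ")\n", sep = "")
  cat(sprintf("  n pairs: %d\n", x$n))
  cat(sprintf("  median A: %.4f [Q1 %.4f, Q3 %.4f]\n", x$median_a, x$q1_a, x$q3_a))
  cat(sprintf("  median B: %.4f [Q1 %.4f, Q3 %.4f]\n", x$median_b, x$q1_b, x$q3_b))
  cat(sprintf("  two-sided p: %.3g\n", x$p_value))
  invisible(x)
}

#' Leading-strand fraction of a segregating mark
#'
#' Maps the mean oriented partition to the fraction of mark-bearing nascent
#' reads on the leading strand: `100 * (mean(partition_oriented) + 1) / 2`.
#' Windows within `min_offset_bins` of the IZ midpoint are excluded by
#' default: inside the smoothing window the blur mixes the two diverging
#' forks and the partition ramps through zero regardless of the true bias,
#' so those bins measure geometry, not segregation. The default matches the
#' default blur half-width (30 bins).
#'
#' A bootstrap confidence interval is computed by resampling IZs with
#' replacement (windows from the same IZ share fork geometry and smoothing,
#' so the IZ is the exchangeable unit).
#'
#' @param table An `oriented_windows` tibble from [orient_to_iz()].
#' @param min_offset_bins Exclude windows with `|offset| <= min_offset_bins`
#'   (default 30; use 0 to pool every window except offset 0).
#' @param n_boot Bootstrap resamples over IZs (default 1000).
#' @param conf_level Confidence level (default 0.95).
#' @return A `leading_fraction` object with elements `estimate` (percent),
#'   `conf_low`, `conf_high`, `mean_partition`, `n_windows`, `n_iz`.
#' @export
leading_fraction <- function(table, min_offset_bins = 30, n_boot = 1000,
                             conf_level = 0.95) {
  keep <- abs(table$offset) > min_offset_bins
  tb <- table[keep, ]
  if (nrow(tb) == 0) abort("no windows beyond min_offset_bins; empty table")

  to_pct <- function(m) 100 * (m + 1) / 2
  est_mean <- mean(tb$partition_oriented)

  per_iz <- tb |>
    group_by(.data$iz_id) |>
    summarise(s = sum(.data$partition_oriented), n = dplyr::n(), .groups = "drop")
  n_iz <- nrow(per_iz)
  boot <- vapply(seq_len(n_boot), function(i) {
    j <- sample.int(n_iz, n_iz, replace = TRUE)
    sum(per_iz$s[j]) / sum(per_iz$n[j])
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE)

  structure(
    list(
      estimate = to_pct(est_mean),
      conf_low = to_pct(ci[1]),
      conf_high = to_pct(ci[2]),
      mean_partition = est_mean,
      n_windows = nrow(tb),
      n_iz = n_iz,
      min_offset_bins = min_offset_bins
    ),
    class = "leading_fraction"
  )
}

#' @export
print.leading_fraction <- function(x, ...) {
  cat(sprintf(
    "Leading-strand fraction: %.1f%% (%.0f%% CI %.1f-%.1f), %d windows over %d IZs\n",
    x$estimate, 95, x$conf_low, x$conf_high, x$n_windows, x$n_iz
  ))
  invisible(x)
}
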