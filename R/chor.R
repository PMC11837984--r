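#' Tally target and spike-in reads for an IP library and its matched input
#'
#' @param ip_target,ip_spike,input_target,input_spike Non-negative read counts.
#'   Spike counts must be positive for scaling.
#' @return A `spike_counts` object (named list).
#' @examples
#' spike_counts(1e6, 1000, 1e6, 1000)
#' @export
spike_counts <- function(ip_target, ip_spike, input_target, input_spike) {
  counts <- list(
    ip_target = ip_target, ip_spike = ip_spike,
    input_target = input_target, input_spike = input_spike
  )
  if (any(unlist(counts) < 0)) abort("read counts must be non-negative")
  structure(counts, class = "spike_counts")
}

#' @rdname spike_counts
#' @param reads A read tibble from [read_stranded_reads()] (with totals).
#' @param input_reads The matched input read tibble.
#' @export
spike_counts_from_reads <- function(reads, input_reads) {
  ti <- read_totals(reads)
  tn <- read_totals(input_reads)
  spike_counts(ti$target, ti$spike, tn$target, tn$spike)
}

#' @export
print.spike_counts <- function(x, ...) {
  cat(sprintf(
    "<spike_counts> IP %d target / %d spike; input %d target / %d spike\n",
    x$ip_target, x$ip_spike, x$input_target, x$input_spike
  ))
  invisible(x)
}

check_spike <- function(counts) {
  stopifnot(inherits(counts, "spike_counts"))
  if (counts$ip_spike <= 0 || counts$input_spike <= 0) {
    abort(paste(
      "zero spike-in reads: spike-in scaling is undefined;",
      "sequence (or simulate) deeper"
    ))
  }
}

#' Spike-in scale factor for reference-adjusted RPM (RRPM)
#'
#' Returns the multiplicative factor applied to an RPM track to make signal
#' comparable between conditions sharing a constant spike-in chromatin
#' proportion:
#' `alpha = (input_spike / input_total) / (ip_spike / ip_total)`.
#' When IP and input have identical spike fractions (no differential recovery
#' of target chromatin), `alpha = 1` and RRPM reduces to RPM; a condition that
#' recovers less target chromatin per spike-in unit gets proportionally
#' down-scaled. This reduces to classic ChIP-Rx scaling when the inputs are
#' condition-invariant.
#'
#' @param counts A [spike_counts()] object.
#' @return The scale factor alpha (positive scalar).
#' @export
spike_scale_factor <- function(counts) {
  check_spike(counts)
  input_frac <- counts$input_spike / (counts$input_spike + counts$input_target)
  ip_frac <- counts$ip_spike / (counts$ip_spike + counts$ip_target)
  input_frac / ip_frac
}

#' Global spike-in calibrated enrichment ratio
#'
#' The bar-plot statistic: target reads per spike-in read in the IP, relative
#' to the same ratio in the matched input:
#' `(ip_target / ip_spike) / (input_target / input_spike)`. Equal to the total
#' genome-wide RRPM mass up to a constant.
#'
#' @param counts A [spike_counts()] object.
#' @return A positive scalar; 1 when IP and input have identical composition.
#' @export
global_spike_ratio <- function(counts) {
  check_spike(counts)
  if (counts$ip_spike == 0 || counts$input_spike == 0 || counts$input_target == 0) {
    abort("zero denominator in spike ratio")
  }
  (counts$ip_target / counts$ip_spike) /
    (counts$input_target / counts$input_spike)
}

#' Spike-in calibrated per-bin quantification track
#'
#' Bins target reads (strandless, fragment-midpoint rule) into fixed windows,
#' converts to reads per million of the IP's target reads, and multiplies by
#' the spike-in scale factor ([spike_scale_factor()]).
#'
#' @param reads Read tibble (target reads are selected by `origin` if present).
#' @param layout A [genome_layout()].
#' @param counts A [spike_counts()] for the same library.
#' @param bin_width Bin width in bp (default 1000).
#' @return A `quant_track` tibble with columns `chrom`, `start`, `end`, `rrpm`
#'   and attributes `bin_width`, `scale_factor`, `ip_target`.
#' @export
rrpm_track <- function(reads, layout, counts, bin_width = 1000) {
  alpha <- spike_scale_factor(counts)
  binned <- bin_stranded_reads(reads, layout, bin_width)
  out <- tibble(
    chrom = binned$chrom, start = binned$start, end = binned$end,
    rrpm = (binned$F + binned$R) * 1e6 / counts$ip_target * alpha
  )
  structure(
    out,
    bin_width = bin_width, scale_factor = alpha, ip_target = counts$ip_target,
    class = c("quant_track", class(tibble()))
  )
}

#' @export
print.quant_track <- function(x, ...) {
  cat(
    "<quant_track> bin_width=", attr(x, "bin_width"),
    sprintf(" scale_factor=%.4f", attr(x, "scale_factor")),
    sprintf(" total RRPM=%.1f", sum(x$rrpm)), "\n",
    sep = ""
  )
  NextMethod()
}

#' Consensus peaks supported by every replicate
#'
#' Concatenates the peak sets of all replicates, sorts them, merges intervals
#' whose gap is at most `merge_dist` bp, and keeps only merged intervals that
#' overlap (by at least 1 bp) at least one peak from *every* replicate.
#'
#' @param replicate_peaks A list of interval tibbles (`chrom`, `start`, `end`),
#'   one per replicate.
#' @param merge_dist Maximum end-to-start gap (bp) between peaks to merge
#'   (default 500).
#' @return A sorted interval tibble (`chrom`, `start`, `end`) with attributes
#'   `n_replicates` and `merge_dist`. With a single replicate this is simply
#'   its merged peak set. Empty inputs yield an empty consensus with a warning.
#' @export
consensus_peaks <- function(replicate_peaks, merge_dist = 500) {
  stopifnot(length(replicate_peaks) >= 1)
  replicate_peaks <- purrr::map(replicate_peaks, as_tibble)
  if (any(purrr::map_int(replicate_peaks, nrow) == 0)) {
    warn("a replicate has no peaks; consensus is empty")
    out <- tibble(chrom = character(), start = integer(), end = integer())
    return(structure(out, n_replicates = length(replicate_peaks),
                     merge_dist = merge_dist, class = class(out)))
  }
  pooled <- bind_rows(replicate_peaks)
  merged <- GenomicRanges::reduce(
    intervals_to_granges(pooled),
    min.gapwidth = merge_dist + 1L
  )
  in_all <- rep(TRUE, length(merged))
  for (rep_tb in replicate_peaks) {
    hits <- GenomicRanges::countOverlaps(merged, intervals_to_granges(rep_tb))
    in_all <- in_all & hits > 0
  }
  out <- granges_to_intervals(merged[in_all]) |>
    arrange(.data$chrom, .data$start)
  structure(out, n_replicates = length(replicate_peaks),
            merge_dist = merge_dist, class = class(out))
}

#' Select quantification bins overlapping consensus peaks
#'
#' Returns the RRPM value of every fixed-width bin overlapping at least 1 bp
#' of any peak. The bin set depends only on the peaks, never on the signal, so
#' two conditions quantified over the same peaks share a bin universe.
#'
#' @param track A `quant_track` from [rrpm_track()].
#' @param peaks An interval tibble (consensus peaks or domains).
#' @return A tibble with columns `chrom`, `start`, `end`, `rrpm` (one row per
#'   selected bin).
#' @export
quantify_peak_windows <- function(track, peaks) {
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  rrpm = numeric()))
  }
  bins <- intervals_to_granges(track)
  hits <- GenomicRanges::countOverlaps(bins, intervals_to_granges(peaks))
  as_tibble(track)[hits > 0, c("chrom", "start", "end", "rrpm")]
}

#' Recycling-efficiency change between conditions
#'
#' Percent reduction of spike-in calibrated signal in a treated condition
#' relative to a control: `100 * (1 - sum(treated) / sum(control))`; positive
#' values mean loss of signal (reduced recycling efficiency).
#'
#' With `scope = "in_domain"`, both tracks are restricted to bins overlapping
#' `peaks` (the cognate mark domains or consensus peaks) before summing; the
#' two conditions must be quantified on the same genome so the bin universe is
#' shared. With `scope = "genome_wide"`, totals over all target-genome bins
#' are compared. Numeric vectors over a shared bin universe are also accepted.
#'
#' @param treated,control `quant_track`s (or numeric RRPM vectors on the same
#'   bin universe).
#' @param scope `"in_domain"` or `"genome_wide"`.
#' @param peaks Interval tibble required for `scope = "in_domain"` when
#'   passing tracks.
#' @return Percent change (scalar); positive = loss in treated.
#' @export
efficiency_change <- function(treated, control,
                              scope = c("in_domain", "genome_wide"),
                              peaks = NULL) {
  scope <- match.arg(scope)
  pick <- function(x) {
    if (is.numeric(x)) return(x)
    if (scope == "in_domain") {
      if (is.null(peaks)) abort("scope 'in_domain' needs peaks")
      quantify_peak_windows(x, peaks)$rrpm
    } else {
      x$rrpm
    }
  }
  s_t <- sum(pick(treated))
  s_c <- sum(pick(control))
  if (s_c == 0) abort("control signal sums to zero")
  100 * (1 - s_t / s_c)
}
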