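new_strand_track <- function(tb, bin_width, stage, library_size = NA_real_) {
  structure(
    tb,
    bin_width = bin_width,
    stage = stage,
    library_size = library_size,
    class = c("strand_track", class(tibble()))
  )
}

#' @export
print.strand_track <- function(x, ...) {
  cat(
    "<strand_track> stage=", attr(x, "stage"),
    " bin_width=", attr(x, "bin_width"),
    " library_size=", attr(x, "library_size"), "\n",
    sep = ""
  )
  NextMethod()
}

track_stage <- function(track) attr(track, "stage")

bin_grid <- function(layout, bin_width) {
  purrr::map2_dfr(
    layout$chrom_sizes$chrom, layout$chrom_sizes$length,
    function(chrom, len) {
      n <- ceiling(len / bin_width)
      start <- as.integer((seq_len(n) - 1L) * bin_width)
      tibble(
        chrom = chrom,
        start = start,
        end = as.integer(pmin(start + bin_width, len))
      )
    }
  )
}

#' Bin stranded reads into fixed-width windows
#'
#' Counts reads per strand in fixed non-overlapping bins (default 1 kb). Each
#' read is assigned to exactly one bin by the floor of its fragment midpoint,
#' a convention symmetric with respect to strand and bin boundaries. Only
#' target-genome reads are counted; reads whose midpoint falls beyond the
#' recorded chromosome length are dropped.
#'
#' @param reads A read tibble (columns `chrom`, `start`, `end`, `strand`, and
#'   optionally `origin`), e.g. from [read_stranded_reads()].
#' @param layout A [genome_layout()].
#' @param bin_width Bin width in bp (default 1000).
#'
#' @return A `strand_track`: tibble with columns `chrom`, `start`, `end`,
#'   `F`, `R` at stage `"raw_counts"`, with the library size (total binned
#'   target reads, both strands) stored as an attribute for CPM normalization.
#' @export
bin_stranded_reads <- function(reads, layout, bin_width = 1000) {
  stopifnot(bin_width > 0)
  reads <- as_tibble(reads)
  if ("origin" %in% names(reads)) {
    reads <- reads[reads$origin == "target", ]
  }
  reads <- reads[reads$chrom %in% layout$chrom_sizes$chrom, ]
  grid <- bin_grid(layout, bin_width)

  mid <- (reads$start + reads$end) %/% 2L
  bin <- mid %/% bin_width
  len <- setNames(layout$chrom_sizes$length, layout$chrom_sizes$chrom)
  nbin <- ceiling(len / bin_width)
  keep <- bin < nbin[reads$chrom] & mid >= 0
  reads <- reads[keep, ]
  bin <- bin[keep]

  count_strand <- function(s) {
    idx <- reads$strand == s
    counts <- tapply(
      bin[idx],
      factor(reads$chrom[idx], levels = names(nbin)),
      function(b) b,
      simplify = FALSE
    )
    unlist(purrr::imap(as.list(counts), function(b, chrom) {
      if (is.null(b)) numeric(nbin[[chrom]]) else tabulate(b + 1L, nbins = nbin[[chrom]])
    }), use.names = FALSE)
  }

  grid$F <- count_strand("+")
  grid$R <- count_strand("-")
  new_strand_track(grid, bin_width, "raw_counts", library_size = nrow(reads))
}

#' Normalize a raw-count track to counts per million
#'
#' Scales each strand by 1e6 / library size, where the library size is the
#' total retained target reads of the library (both strands combined;
#' per-strand normalization would erase the strand asymmetry the partition
#' statistic measures). Leaves the per-bin F:R ratio unchanged.
#'
#' @param track A `strand_track` at stage `"raw_counts"`.
#' @param library_size Total target reads; defaults to the size recorded when
#'   the track was binned.
#' @return A `strand_track` at stage `"cpm"`.
#' @export
cpm_normalize <- function(track, library_size = NULL) {
  stopifnot(track_stage(track) == "raw_counts")
  library_size <- library_size %||% attr(track, "library_size")
  if (is.null(library_size) || is.na(library_size) || library_size <= 0) {
    abort("library_size must be a positive count")
  }
  out <- as_tibble(track)
  out$F <- out$F * 1e6 / library_size
  out$R <- out$R * 1e6 / library_size
  new_strand_track(out, attr(track, "bin_width"), "cpm", library_size)
}

running_mean_truncated <- function(x, h) {
  n <- length(x)
  if (h == 0 || n == 0) return(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a strand track with a uniform blur
#'
#' Applies a per-chromosome moving average covering `half_width_bins`
#' neighboring bins on each side (window of 2h+1 bins; default 30, i.e. a
#' 61-bin window at 1-kb bins). At chromosome edges the window truncates and
#' the mean is taken over the bins actually present, so constant tracks are
#' exact fixed points of the blur.
#'
#' @param track A `strand_track` at stage `"cpm"`.
#' @param half_width_bins Number of neighboring bins on each side (default 30).
#' @return A `strand_track` at stage `"smoothed"`.
#' @export
uniform_blur <- function(track, half_width_bins = 30) {
  stopifnot(track_stage(track) == "cpm", half_width_bins >= 0)
  out <- as_tibble(track)
  for (col in c("F", "R")) {
    out[[col]] <- unlist(
      lapply(
        split(out[[col]], factor(out$chrom, levels = unique(out$chrom))),
        running_mean_truncated,
        h = half_width_bins
      ),
      use.names = FALSE
    )
  }
  new_strand_track(out, attr(track, "bin_width"), "smoothed",
                   attr(track, "library_size"))
}

#' Subtract the matched input and filter low-coverage windows
#'
#' Per strand and bin, subtracts the input signal from the IP signal, setting
#' negative values to zero. Windows whose input-corrected CPM falls below
#' `min_cpm` on *both* strands are masked and excluded from all downstream
#' statistics (propagated as absent values, never as zeros). The input must
#' have been processed through the identical CPM + blur stages.
#'
#' @param ip,input `strand_track`s at stage `"smoothed"` on the same bin grid.
#' @param min_cpm Both-strand CPM threshold below which a window is masked
#'   (default 0.3).
#' @return A `strand_track` at stage `"input_corrected"` with an additional
#'   logical column `masked`.
#' @export
input_correct_and_filter <- function(ip, input, min_cpm = 0.3) {
  stopifnot(track_stage(ip) == "smoothed", track_stage(input) == "smoothed")
  same_bins <- identical(attr(ip, "bin_width"), attr(input, "bin_width")) &&
    nrow(ip) == nrow(input) &&
    all(ip$chrom == input$chrom) && all(ip$start == input$start)
  if (!same_bins) {
    abort("ip and input tracks must share bin width and chromosome grid")
  }
  out <- as_tibble(ip)
  out$F <- pmax(ip$F - input$F, 0)
  out$R <- pmax(ip$R - input$R, 0)
  out$masked <- out$F < min_cpm & out$R < min_cpm
  new_strand_track(out, attr(ip, "bin_width"), "input_corrected",
                   attr(ip, "library_size"))
}

#' Compute the strand partition statistic
#'
#' Partition = (F - R)/(F + R) per bin: +1 when all signal is on the forward
#' strand, -1 when all on the reverse. Bins already masked by the coverage
#' filter, and bins with F + R = 0, are masked. With `flip = TRUE` the score
#' is multiplied by -1, correcting libraries whose protocol sequences the
#' complementary strand (e.g. xGen UMI adapters) and therefore reports a
#' mirrored ratio.
#'
#' The canonical pipeline applies this to the input-corrected stage; the
#' statistic itself is defined for any strand track (it is invariant to any
#' positive rescaling of both strands, so CPM normalization does not change
#' it).
#'
#' @param track A `strand_track`, normally at stage `"input_corrected"`.
#' @param flip Multiply the score by -1 (default `FALSE`).
#' @return A `partition_track`: tibble with columns `chrom`, `start`, `end`,
#'   `partition`, `coverage` (F + R), `masked`, `mask_reason` (`"ok"`,
#'   `"low_cpm"` or `"zero_coverage"`), with the bin width as an attribute.
#'   `partition` is `NA` on masked bins.
#' @export
compute_partition <- function(track, flip = FALSE) {
  tb <- as_tibble(track)
  coverage <- tb$F + tb$R
  low <- if ("masked" %in% names(tb)) tb$masked else rep(FALSE, nrow(tb))
  zero <- coverage == 0
  masked <- low | zero
  partition <- ifelse(masked, NA_real_, (tb$F - tb$R) / coverage)
  if (flip) partition <- -partition
  out <- tibble(
    chrom = tb$chrom, start = tb$start, end = tb$end,
    partition = partition,
    coverage = coverage,
    masked = masked,
    mask_reason = dplyr::case_when(
      zero ~ "zero_coverage",
      low ~ "low_cpm",
      TRUE ~ "ok"
    )
  )
  structure(
    out,
    bin_width = attr(track, "bin_width"),
    class = c("partition_track", class(tibble()))
  )
}

#' @export
print.partition_track <- function(x, ...) {
  cat(
    "<partition_track> bin_width=", attr(x, "bin_width"),
    " unmasked=", sum(!x$masked), "/", nrow(x), " bins\n",
    sep = ""
  )
  NextMethod()
}

#' Run the full partition pipeline on an IP/input read pair
#'
#' Convenience wrapper chaining the canonical stage order: raw counts ->
#' CPM -> uniform blur -> input correction -> coverage filter -> partition.
#' The input library is processed through the identical CPM + blur stages
#' before subtraction.
#'
#' @param ip_reads,input_reads Read tibbles (target reads; see
#'   [read_stranded_reads()]).
#' @param layout A [genome_layout()].
#' @param bin_width Bin width in bp (default 1000).
#' @param blur_halfwidth Neighboring bins on each side for the uniform blur
#'   (default 30).
#' @param min_cpm Both-strand CPM mask threshold (default 0.3).
#' @param flip Multiply partition by -1 (default `FALSE`).
#' @return A `partition_track` (see [compute_partition()]).
#' @export
partition_pipeline <- function(ip_reads, input_reads, layout,
                               bin_width = 1000, blur_halfwidth = 30,
                               min_cpm = 0.3, flip = FALSE) {
  ip <- bin_stranded_reads(ip_reads, layout, bin_width) |>
    cpm_normalize() |>
    uniform_blur(blur_halfwidth)
  inp <- bin_stranded_reads(input_reads, layout, bin_width) |>
    cpm_normalize() |>
    uniform_blur(blur_halfwidth)
  input_correct_and_filter(ip, inp, min_cpm) |>
    compute_partition(flip = flip)
}
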