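#' Describe the target genome and the spike-in naming rule
#'
#' A genome layout holds the chromosome sizes of the *target* genome together
#' with the contig-name prefix that identifies exogenous spike-in chromatin
#' (e.g. Drosophila contigs in a mouse experiment mapped against a hybrid
#' reference). Reads are classified as target, spike or discarded purely by
#' contig name, so the layout is the single source of truth for read origin.
#'
#' @param chrom_sizes A data frame with columns `chrom` and `length` (bp), or a
#'   named numeric vector of chromosome lengths. Target genome only.
#' @param spike_prefix Contig-name prefix marking spike-in contigs
#'   (default `"dm6_"`).
#'
#' @return An object of class `genome_layout`: a list with elements
#'   `chrom_sizes` (tibble with columns `chrom`, `length`) and `spike_prefix`.
#' @examples
#' genome_layout(c(chr1 = 5e6, chr2 = 3e6))
#' @export
genome_layout <- function(chrom_sizes, spike_prefix = "dm6_") {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- tibble(chrom = names(chrom_sizes), length = unname(chrom_sizes))
  }
  chrom_sizes <- as_tibble(chrom_sizes)
  stopifnot(all(c("chrom", "length") %in% names(chrom_sizes)))
  if (any(chrom_sizes$length <= 0)) {
    abort("all chromosome lengths must be positive")
  }
  is_spike <- startsWith(chrom_sizes$chrom, spike_prefix)
  if (any(is_spike)) {
    warn("spike-prefixed contigs removed from target chrom_sizes")
    chrom_sizes <- chrom_sizes[!is_spike, ]
  }
  structure(
    list(chrom_sizes = chrom_sizes, spike_prefix = spike_prefix),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(
    "<genome_layout> ", nrow(x$chrom_sizes), " target contigs, ",
    format(sum(x$chrom_sizes$length), big.mark = ","), " bp; spike prefix '",
    x$spike_prefix, "'\n",
    sep = ""
  )
  invisible(x)
}

classify_origin <- function(chrom, layout) {
  dplyr::case_when(
    startsWith(chrom, layout$spike_prefix) ~ "spike",
    chrom %in% layout$chrom_sizes$chrom ~ "target",
    TRUE ~ "discarded"
  )
}

#' Read stranded nascent-chromatin reads from BAM or BED6
#'
#' Reads aligned stranded reads, classifies each read as target or spike-in by
#' contig name, and tallies target/spike/discarded counts. Coordinates are
#' 0-based half-open throughout. Every retained read carries a `+`/`-` strand;
#' unstranded BED records are a hard error because the partition statistic is
#' undefined without strand.
#'
#' The `min_mapq` filter applies to BAM alignments only (standing in for an
#' upstream unique-mapping filter). The BED6 score column is *not* a mapping
#' quality and is never filtered on.
#'
#' @param path Path to a `.bam` file or a tab-separated BED6 file.
#' @param layout A [genome_layout()].
#' @param min_mapq Minimum mapping quality for BAM records (default 30).
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `origin`
#'   and attribute `totals`, a named list with counts `target`, `spike`,
#'   `discarded` (retrievable with [read_totals()]). Discarded reads (contigs
#'   neither in the layout nor spike-prefixed) are dropped from the tibble but
#'   tallied.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t1000\t1075\tr1\t0\t+", tf)
#' reads <- read_stranded_reads(tf, genome_layout(c(chr1 = 1e5)))
#' read_totals(reads)
#' @export
read_stranded_reads <- function(path, layout, min_mapq = 30) {
  stopifnot(inherits(layout, "genome_layout"))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    raw <- read_bam_records(path, min_mapq)
  } else {
    raw <- read_bed6_records(path)
  }
  origin <- classify_origin(raw$chrom, layout)
  totals <- list(
    target = sum(origin == "target"),
    spike = sum(origin == "spike"),
    discarded = sum(origin == "discarded")
  )
  if (totals$discarded > 0) {
    warn(paste0(totals$discarded, " read(s) on unknown contigs discarded"))
  }
  out <- raw[origin != "discarded", c("chrom", "start", "end", "strand")]
  out$origin <- origin[origin != "discarded"]
  attr(out, "totals") <- totals
  out
}

#' @rdname read_stranded_reads
#' @param reads A tibble returned by [read_stranded_reads()].
#' @export
read_totals <- function(reads) {
  attr(reads, "totals")
}

read_bed6_records <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc",
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character()
    ))
  }
  bad_strand <- !(raw$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    abort(paste0(
      "unstranded or invalid strand in BED6 record(s), first at line ",
      which(bad_strand)[1]
    ))
  }
  bad_coord <- raw$start >= raw$end
  if (any(bad_coord)) {
    abort(paste0("start >= end at line ", which(bad_coord)[1]))
  }
  raw[, c("chrom", "start", "end", "strand")]
}

read_bam_records <- function(path, min_mapq) {
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "strand", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(rec$pos) & !is.na(rec$mapq) & rec$mapq >= min_mapq
  tibble(
    chrom = as.character(rec$rname)[keep],
    start = rec$pos[keep] - 1L,
    end = rec$pos[keep] - 1L + rec$qwidth[keep],
    strand = as.character(rec$strand)[keep]
  )
}

#' Read genomic intervals from BED-like files
#'
#' Reads the first three (plus optional name) columns of a BED3/BED6/broadPeak
#' file into a sorted interval table. Coordinates are 0-based half-open.
#'
#' @param path Path to a tab-separated file with at least chrom/start/end.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, sorted by
#'   (chrom, start).
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t500\t900", "chr1\t0\t100"), tf)
#' read_intervals(tf)
#' @export
read_intervals <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 3 && nrow(raw) > 0) {
    abort("interval files need at least 3 tab-separated columns")
  }
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  out <- tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    name = if (ncol(raw) >= 4) raw[[4]] else NA_character_
  )
  bad <- out$start >= out$end
  if (any(bad)) {
    abort(paste0("start >= end at line ", which(bad)[1]))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Write a binned track to bedGraph
#'
#' Writes one bedGraph line per bin (0-based half-open). For partition tracks,
#' masked bins are omitted. Values are printed at 6 decimal places, so a
#' write-then-read round trip recovers values to 1e-6.
#'
#' @param track A strand track (from [bin_stranded_reads()] and downstream
#'   stages), a partition track ([compute_partition()]), or a quantification
#'   track ([rrpm_track()]).
#' @param path Output path.
#' @param which Which signal to write: `"forward"`, `"reverse"`, `"partition"`
#'   or `"rrpm"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path,
                           which = c("forward", "reverse", "partition", "rrpm")) {
  which <- match.arg(which)
  tb <- as_tibble(track)
  value <- switch(which,
    forward = tb$F,
    reverse = tb$R,
    partition = tb$partition,
    rrpm = tb$rrpm
  )
  if (is.null(value)) {
    abort(paste0("track has no '", which, "' signal"))
  }
  keep <- !is.na(value)
  if (which == "partition" && "masked" %in% names(tb)) {
    keep <- keep & !tb$masked
  }
  lines <- sprintf(
    "%s\t%d\t%d\t%.6f",
    tb$chrom[keep], tb$start[keep], tb$end[keep], value[keep]
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path Path to a 4-column bedGraph file (no track lines).
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "value"),
    col_types = "ciid",
    progress = FALSE
  )
}
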