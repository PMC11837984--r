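#' Read a histone peptidoform MS1 area table
#'
#' Expects a tab-separated table with columns `backbone_id` (histone plus
#' residue span, e.g. `"H3 27-40"`), `modset` (semicolon-separated site:mod
#' tokens such as `"K27me3;K36un"`, with unmodified sites encoded explicitly
#' as `un`), `charge`, and `ms1_area` (arbitrary units, total MS1 area under
#' the first isotopomers as exported by the upstream search).
#'
#' @param path Path to the TSV file.
#' @return A tibble with the four columns above.
#' @export
read_peptidoform_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    backbone_id = "c", modset = "c", charge = "i", ms1_area = "d"
  ), progress = FALSE)
  if (any(out$ms1_area < 0)) abort("ms1_area must be non-negative")
  out
}

modset_tokens <- function(modset) {
  strsplit(modset, ";", fixed = TRUE)
}

token_site <- function(token) {
  stringr::str_extract(token, "^[A-Z][0-9]+")
}

#' Split an isobaric MS1 area between two coeluting peptidoforms
#'
#' Coeluting isobaric peptidoforms (e.g. H3K36me3 and H3K27me2K36me1) share
#' one MS1 peak; their contributions are resolved from unique MS2 fragment
#' ions. For each analogous ion pair (the same ion species, e.g. y7 vs y7,
#' from species a and b), the intensity ratio a/b is computed, the ratios are
#' averaged, and the MS1 area is split as
#' `area_a = total_area * r / (1 + r)`, `area_b = total_area - area_a`, so the
#' two areas always sum to the total exactly.
#'
#' @param total_area Total MS1 area of the isobaric peak (non-negative).
#' @param pairs A data frame with columns `intensity_a`, `intensity_b` (one
#'   row per analogous ion pair; an `ion` label column is allowed and
#'   ignored). Pairs with `intensity_b = 0` are excluded from the ratio; if no
#'   pair has `intensity_b > 0`, the full area is assigned to species a with a
#'   warning.
#' @param mean_type `"arithmetic"` (default) or `"geometric"` averaging of the
#'   per-ion ratios.
#' @return A named numeric vector `c(area_a = , area_b = )`.
#' @examples
#' resolve_isobaric(100, data.frame(intensity_a = c(30, 60),
#'                                  intensity_b = c(10, 20)))
#' @export
resolve_isobaric <- function(total_area, pairs,
                             mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  stopifnot(total_area >= 0)
  pairs <- as_tibble(pairs)
  if (any(pairs$intensity_a < 0) || any(pairs$intensity_b < 0)) {
    abort("fragment intensities must be non-negative")
  }
  usable <- pairs$intensity_b > 0
  if (!any(usable)) {
    warn("all reference-species fragment intensities are zero; assigning full area to species a")
    return(c(area_a = total_area, area_b = 0))
  }
  ratios <- pairs$intensity_a[usable] / pairs$intensity_b[usable]
  r <- switch(mean_type,
    arithmetic = mean(ratios),
    geometric = exp(mean(log(pmax(ratios, .Machine$double.xmin))))
  )
  area_a <- total_area * r / (1 + r)
  c(area_a = area_a, area_b = total_area - area_a)
}

#' Relative abundance of a histone modification
#'
#' Computes the percent relative abundance of a site:mod token over all
#' peptidoforms of the backbone carrying that site:
#' 100 * (sum of MS1 areas of peptidoforms containing the token) /
#' (sum of MS1 areas of all peptidoforms of the backbone). Charge states are
#' summed. For example, %K18ac on the H3 18-26 peptide sums K18ac;K23un and
#' K18ac;K23ac areas over the total of all four K18/K23 combinations.
#'
#' @param records A peptidoform tibble (see [read_peptidoform_table()]).
#'   Records from other backbones (not carrying the target's site) are
#'   ignored.
#' @param target A site:mod token, e.g. `"K18ac"` or `"K27me3"`.
#' @return Percent (scalar). If no record of the backbone exists or the total
#'   area is zero, the abundance is undefined and `NA` is returned with a
#'   warning (never 0).
#' @export
relative_abundance <- function(records, target) {
  site <- token_site(target)
  toks <- modset_tokens(records$modset)
  has_site <- purrr::map_lgl(toks, function(t) any(token_site(t) == site))
  denom <- sum(records$ms1_area[has_site])
  if (denom == 0) {
    warn(paste0("no MS1 area for site ", site, "; abundance undefined"))
    return(NA_real_)
  }
  has_target <- purrr::map_lgl(toks, function(t) target %in% t)
  100 * sum(records$ms1_area[has_site & has_target]) / denom
}

#' Relative abundances of all observed states at one site
#'
#' Tabulates every modification state observed at a site (e.g. K27un, K27me1,
#' K27me2, K27me3) with its percent relative abundance. Over the exhaustive,
#' mutually exclusive state set of one site the percentages sum to 100.
#'
#' @param records A peptidoform tibble.
#' @param site A site label, e.g. `"K27"`.
#' @return A tibble with columns `state`, `percent`, sorted by state.
#' @export
site_abundances <- function(records, site) {
  toks <- modset_tokens(records$modset)
  states <- sort(unique(unlist(purrr::map(
    toks, function(t) t[token_site(t) == site]
  ))))
  tibble(
    state = states,
    percent = purrr::map_dbl(states, ~ relative_abundance(records, .x))
  )
}
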