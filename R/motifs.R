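# Per-motif-site footprint scores and aggregate cut-count profiles.

site_centers0 <- function(sites) {
  # 0-based centre floor((start0 + end0) / 2); GRanges start is start0 + 1.
  (GenomicRanges::start(sites) - 1L + GenomicRanges::end(sites)) %/% 2L
}

#' Footprint z-scores at individual motif sites
#'
#' Applies the binomial depletion test of [test_depletion()] to each motif
#' site against pooled flanks of `flank_width` bp on each side, with
#' expected counts from the bias model's relative rates. Sites not fully
#' inside an accessible region are dropped (their number is recorded in the
#' `dropped` attribute), restricting scoring to open chromatin.
#'
#' @param track A [cut_track()].
#' @param sites `GRanges` of motif sites; a `tf` metadata column is carried
#'   through if present.
#' @param regions Optional `GRanges` of accessible regions used to filter
#'   sites; `NULL` keeps all sites.
#' @param model A [fit_bias()] model or `NULL` (uniform).
#' @param genome,rates Genome or precomputed [bias_position_rates()]
#'   (needed for `model$k > 0`).
#' @param flank_width Flank width per side (default 50 bp); every site must
#'   be narrower than `2 * flank_width`.
#' @return The filtered `sites` with added columns `obs_in`, `exp_in`,
#'   `obs_flank`, `exp_flank`, `p`, `z`; attribute `dropped` gives the
#'   number of sites outside open chromatin.
#' @export
score_sites <- function(track, sites, regions = NULL, model = NULL,
                        genome = NULL, rates = NULL, flank_width = 50L) {
  stopifnot(is(sites, "GRanges"))
  if (any(GenomicRanges::width(sites) > 2L * flank_width))
    stop("site wider than 2 * flank_width: degenerate flank geometry")
  dropped <- 0L
  if (!is.null(regions)) {
    inside <- IRanges::overlapsAny(sites, regions, type = "within")
    dropped <- sum(!inside)
    sites <- sites[inside]
  }
  use_bias <- !is.null(model) && model$k > 0
  if (use_bias && is.null(rates)) {
    if (is.null(genome)) stop("genome (or rates) required for a k>0 model")
    rates <- bias_position_rates(model, as_genome(genome))
  }
  n <- length(sites)
  oin <- ein <- ofl <- efl <- numeric(n)
  lens <- chrom_lengths(track)
  for (chrom in unique(as.character(GenomeInfoDb::seqnames(sites)))) {
    idx <- which(as.character(GenomeInfoDb::seqnames(sites)) == chrom)
    L <- lens[[chrom]]
    y <- as.numeric(track_window(track, chrom))
    w <- if (use_bias) rates[[chrom]] else rep(1, L)
    cy <- c(0, cumsum(y)); cw <- c(0, cumsum(w))
    s <- GenomicRanges::start(sites)[idx]
    e <- GenomicRanges::end(sites)[idx]
    fl <- pmax(s - flank_width, 1L)
    fr <- pmin(e + flank_width, L)
    oin[idx] <- csum(cy, s, e)
    ein[idx] <- csum(cw, s, e)
    ofl[idx] <- csum(cy, fl, s - 1L) + csum(cy, e + 1L, fr)
    efl[idx] <- csum(cw, fl, s - 1L) + csum(cw, e + 1L, fr)
  }
  tz <- test_depletion(oin, ofl, ein, efl)
  S4Vectors::mcols(sites)$obs_in <- oin
  S4Vectors::mcols(sites)$exp_in <- ein
  S4Vectors::mcols(sites)$obs_flank <- ofl
  S4Vectors::mcols(sites)$exp_flank <- efl
  S4Vectors::mcols(sites)$p <- tz$p
  S4Vectors::mcols(sites)$z <- tz$z
  attr(sites, "dropped") <- dropped
  sites
}

#' Aggregate cut-count profile around motif centres
#'
#' Averages strand-summed counts at each offset in
#' `[-halfwidth, +halfwidth]` relative to the motif centre
#' (`floor((start0 + end0) / 2)` in 0-based coordinates). Minus-strand
#' sites are reversed so that profiles are motif-oriented. Offsets that
#' would fall outside a chromosome are excluded for the affected sites, so
#' the per-offset site count `n` can vary near chromosome ends.
#'
#' @param track A [cut_track()].
#' @param sites Non-empty `GRanges` of motif sites (strand-aware).
#' @param halfwidth Profile half-width in bp (default 100).
#' @return `data.frame(offset, mean, n)`.
#' @export
aggregate_profile <- function(track, sites, halfwidth = 100L) {
  stopifnot(is(sites, "GRanges"))
  if (!length(sites)) stop("need at least one site")
  offs <- -halfwidth:halfwidth
  acc <- numeric(length(offs))
  nn <- integer(length(offs))
  lens <- chrom_lengths(track)
  centers <- site_centers0(sites) + 1L          # 1-based centre
  strands <- as.character(GenomicRanges::strand(sites))
  for (chrom in unique(as.character(GenomeInfoDb::seqnames(sites)))) {
    idx <- which(as.character(GenomeInfoDb::seqnames(sites)) == chrom)
    L <- lens[[chrom]]
    y <- as.numeric(track_window(track, chrom))
    for (i in idx) {
      dir <- if (strands[i] == "-") -1L else 1L
      pos <- centers[i] + dir * offs
      ok <- pos >= 1L & pos <= L
      acc[ok] <- acc[ok] + y[pos[ok]]
      nn[ok] <- nn[ok] + 1L
    }
  }
  data.frame(offset = offs, mean = ifelse(nn > 0, acc / nn, NA_real_), n = nn)
}
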