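# FDR-controlled footprint detection by binomial depletion tests inside
# accessible regions (count-level statistic; no cleavage-shape signatures).

#' Binomial depletion test for a candidate footprint
#'
#' Tests whether an interval's cut count is depleted relative to its flanks.
#' With `n = obs_in + obs_flank` and null proportion
#' `p0 = exp_in / (exp_in + exp_flank)`, the p-value is the lower binomial
#' tail `P(X <= obs_in | n, p0)` and the signed z-score is
#' `(obs_in - n * p0) / sqrt(n * p0 * (1 - p0))` (negative = protected).
#' `n = 0` yields `p = 1`, `z = 0`. All arguments are vectorised.
#'
#' @param obs_in,obs_flank Observed cut counts inside the candidate interval
#'   and in its flanks (non-negative).
#' @param exp_in,exp_flank Expected counts (e.g. bias-model rate sums;
#'   strictly positive). Only their ratio matters.
#' @return `data.frame(p, z)`.
#' @export
#' @examples
#' test_depletion(0, 10, 1, 1)   # p = 2^-10, z = -sqrt(10)
test_depletion <- function(obs_in, obs_flank, exp_in, exp_flank) {
  if (any(obs_in < 0) || any(obs_flank < 0))
    stop("observed counts must be non-negative")
  if (any(exp_in <= 0) || any(exp_flank <= 0))
    stop("expected counts must be positive")
  n <- obs_in + obs_flank
  p0 <- exp_in / (exp_in + exp_flank)
  p <- pbinom(obs_in, n, p0)
  z <- (obs_in - n * p0) / sqrt(n * p0 * (1 - p0))
  zero <- n == 0
  p[zero] <- 1
  z[zero] <- 0
  data.frame(p = p, z = z)
}

#' Call FDR-controlled footprints inside accessible regions
#'
#' Scans every accessible region with candidate windows of all widths in
#' `width_range` (stride-1 starts), scores each window with
#' [test_depletion()] against pooled flanks of `flank_width` bp on each side
#' (expected counts from the bias model's relative rates, locally
#' renormalised), greedily selects non-overlapping candidates in ascending
#' p order (ties: wider window, then leftmost start), applies
#' Benjamini-Hochberg FDR across all selected candidates genome-wide, and
#' returns those with `q <= fdr`.
#'
#' @param track A [cut_track()] (strand-summed counts are tested).
#' @param regions `GRanges` of accessible regions; overlapping ranges are
#'   merged. Regions shorter than `min(width_range) + 2 * flank_width` are
#'   skipped and counted in the `skipped` attribute.
#' @param model A [fit_bias()] model, or `NULL` for uniform expectations.
#' @param genome Genome (`DNAStringSet` / FASTA path), needed when
#'   `model$k > 0` unless `rates` is supplied.
#' @param rates Optional precomputed [bias_position_rates()].
#' @param fdr FDR threshold (default 0.01, i.e. FDR 1%).
#' @param width_range Length-2 integer: min and max footprint width
#'   (default 6-40 bp).
#' @param flank_width Flank width on each side (default 50 bp); must be at
#'   least the maximum footprint width.
#' @param return_candidates If `TRUE`, attach all greedy-selected candidates
#'   (before the FDR cut) as attribute `candidates`.
#' @return `GRanges` of footprints with columns `obs_in`, `exp_in`,
#'   `obs_flank`, `exp_flank`, `p`, `q`, `z`, sorted by position.
#' @export
call_footprints <- function(track, regions, model = NULL, genome = NULL,
                            rates = NULL, fdr = 0.01,
                            width_range = c(6L, 40L), flank_width = 50L,
                            return_candidates = FALSE) {
  wmin <- as.integer(width_range[1]); wmax <- as.integer(width_range[2])
  if (wmin < 1 || wmax < wmin) stop("invalid width_range")
  if (flank_width < wmax)
    stop("flank_width must be at least the maximum footprint width")
  regions <- GenomicRanges::reduce(regions)
  use_bias <- !is.null(model) && model$k > 0
  if (use_bias && is.null(rates)) {
    if (is.null(genome)) stop("genome (or rates) required for a k>0 model")
    rates <- bias_position_rates(model, as_genome(genome))
  }

  sel_list <- list()
  skipped <- 0L
  for (ri in seq_along(regions)) {
    chrom <- as.character(GenomeInfoDb::seqnames(regions))[ri]
    rs <- GenomicRanges::start(regions)[ri]
    re <- GenomicRanges::end(regions)[ri]
    W <- re - rs + 1L
    if (W < wmin + 2L * flank_width) { skipped <- skipped + 1L; next }
    y <- as.numeric(track_window(track, chrom, rs, re))
    w <- if (use_bias) rates[[chrom]][rs:re] else rep(1, W)
    cy <- c(0, cumsum(y))
    cw <- c(0, cumsum(w))

    starts <- integer(0); widths <- integer(0)
    oin <- numeric(0); ein <- numeric(0); ofl <- numeric(0); efl <- numeric(0)
    for (wd in wmin:min(wmax, W - 2L * flank_width)) {
      hi <- W - wd - flank_width + 1L
      if (hi < flank_width + 1L) next
      a <- (flank_width + 1L):hi                      # local start
      b <- a + wd - 1L
      starts <- c(starts, a); widths <- c(widths, rep(wd, length(a)))
      oin <- c(oin, csum(cy, a, b))
      ein <- c(ein, csum(cw, a, b))
      ofl <- c(ofl, csum(cy, a - flank_width, a - 1L) +
                     csum(cy, b + 1L, b + flank_width))
      efl <- c(efl, csum(cw, a - flank_width, a - 1L) +
                     csum(cw, b + 1L, b + flank_width))
    }
    if (!length(starts)) { skipped <- skipped + 1L; next }
    tz <- test_depletion(oin, ofl, ein, efl)
    ord <- order(tz$p, -widths, starts) - 1L
    keep <- greedy_select_cpp(starts, starts + widths - 1L, ord, 1L, W)
    idx <- which(keep)
    sel_list[[length(sel_list) + 1L]] <- data.frame(
      chrom = chrom, start = rs + starts[idx] - 1L,
      width = widths[idx], obs_in = oin[idx], exp_in = ein[idx],
      obs_flank = ofl[idx], exp_flank = efl[idx],
      p = tz$p[idx], z = tz$z[idx], stringsAsFactors = FALSE)
  }

  if (!length(sel_list)) {
    out <- GenomicRanges::GRanges()
    attr(out, "skipped") <- skipped
    return(out)
  }
  cand <- do.call(rbind, sel_list)
  cand$q <- p.adjust(cand$p, method = "BH")
  hits <- cand[cand$q <= fdr, , drop = FALSE]
  out <- GenomicRanges::GRanges(hits$chrom,
           IRanges::IRanges(start = hits$start, width = hits$width))
  for (col in c("obs_in", "exp_in", "obs_flank", "exp_flank", "p", "q", "z"))
    S4Vectors::mcols(out)[[col]] <- hits[[col]]
  out <- sort(out)
  attr(out, "skipped") <- skipped
  attr(out, "n_candidates") <- nrow(cand)
  if (return_candidates) attr(out, "candidates") <- cand
  out
}

#' Depth-matched footprint counts across samples
#'
#' For each sample, subsamples the track to `target_n` events, calls
#' footprints, and counts them; repeated over `rounds` rounds and averaged,
#' so samples of unequal depth are compared fairly.
#'
#' @param tracks Named list of [cut_track()]s.
#' @param target_n Events per round; must not exceed any sample's total.
#' @param regions,model,genome,rates,fdr,width_range,flank_width Passed to
#'   [call_footprints()].
#' @param rounds Subsampling rounds (default 5).
#' @param seeds Per-round seeds (default `1:rounds`), shared across samples.
#' @return `data.frame` with one row per sample: per-round counts
#'   (`round1..`) and their `mean`.
#' @export
count_footprints_subsampled <- function(tracks, target_n, regions,
                                        model = NULL, genome = NULL,
                                        rates = NULL, fdr = 0.01,
                                        width_range = c(6L, 40L),
                                        flank_width = 50L,
                                        rounds = 5L, seeds = NULL) {
  seeds <- seeds %||% seq_len(rounds)
  if (length(seeds) != rounds) stop("need one seed per round")
  if (!is.null(model) && model$k > 0 && is.null(rates))
    rates <- bias_position_rates(model, as_genome(genome))
  rows <- lapply(names(tracks), function(nm) {
    rs <- repeat_subsample(tracks[[nm]], target_n, function(tr)
      length(call_footprints(tr, regions, model = model, rates = rates,
                             fdr = fdr, width_range = width_range,
                             flank_width = flank_width)),
      rounds = rounds, seeds = seeds)
    c(rs$values, rs$mean)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(paste0("round", seq_len(rounds)), "mean")
  out <- cbind(sample = names(tracks), out)
  rownames(out) <- NULL
  out
}
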