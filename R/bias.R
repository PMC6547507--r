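# Nuclease k-mer sequence-bias estimation and bias-adjusted expectations.

# Per-chromosome k-mer machinery shared by fitting and expectation code.
# For a cut at 1-based position j the attributed plus-strand k-mer starts at
# j - floor(k/2) (k = 2: the dinucleotide whose second base is the cut
# base); minus-strand cuts use the mirror-image window, reverse
# complemented. Positions whose window runs off the chromosome or contains
# N get no k-mer (multiplier 1 downstream).
kmer_index <- function(seq_chr, k) {
  codes <- base_codes(seq_chr)
  L <- length(codes)
  kid <- kmer_start_ids(codes, k)
  rc <- revcomp_ids(k)
  pos <- seq_len(L)
  sp <- pos + kmer_plus_offset(k)
  sm <- pos + kmer_minus_offset(k)
  idp <- rep(NA_integer_, L)
  idm <- rep(NA_integer_, L)
  okp <- sp >= 1L & sp <= length(kid)
  okm <- sm >= 1L & sm <= length(kid)
  idp[okp] <- kid[sp[okp]]
  idm[okm] <- rc[kid[sm[okm]] + 1L]
  list(plus = idp, minus = idm, k = k)
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (!is(genome, "DNAStringSet")) stop("genome must be a DNAStringSet or FASTA path")
  if (is.null(names(genome))) stop("genome sequences must be named")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

interval_positions <- function(gr, chrom) {
  gr <- gr[as.character(GenomeInfoDb::seqnames(gr)) == chrom]
  if (!length(gr)) return(integer(0))
  gr <- GenomicRanges::reduce(gr)
  unlist(lapply(seq_along(gr), function(i)
    GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]))
}

#' Estimate the nuclease's k-mer cleavage bias from the data
#'
#' Computes, over the supplied background intervals, the relative cleavage
#' rate `r(w) = (fraction of cuts attributed to k-mer w) / (fraction of
#' interval bases whose k-mer is w)`, renormalised to background-weighted
#' mean 1. Minus-strand cuts are reverse complemented before lookup and a
#' single shared table is returned; background k-mer frequencies likewise
#' average both orientations, so data with no sequence preference yield
#' `r(w) = 1` for every w up to sampling error.
#'
#' @param track A [cut_track()].
#' @param genome `DNAStringSet` or FASTA path.
#' @param intervals `GRanges` of background intervals — normally the
#'   accessible-region peaks, since downstream depletion tests run inside
#'   peaks; pass whole-chromosome intervals for a genome-wide table.
#' @param k K-mer length: 2 (dimer, default) or 4 (tetramer); other small
#'   values work. `k = 0` returns the uniform (unadjusted) model.
#' @return Object of class `bias_model`: list with `k`, `rates` (named
#'   vector over all k-mers; `NA` for k-mers absent from the background,
#'   which are excluded and reported via a message), `background_freq`, and
#'   `background_source`.
#' @export
fit_bias <- function(track, genome, intervals, k = 2L) {
  if (k == 0)
    return(structure(list(k = 0L, rates = NULL, background_freq = NULL,
                          background_source = "uniform"),
                     class = "bias_model"))
  genome <- as_genome(genome)
  nk <- 4L^k
  cutk <- numeric(nk)
  bgk <- numeric(nk)
  n_events <- 0
  for (chrom in names(track$counts)) {
    if (!chrom %in% names(genome)) next
    pos <- interval_positions(intervals, chrom)
    if (!length(pos)) next
    ki <- kmer_index(as.character(genome[[chrom]]), k)
    cc <- track$counts[[chrom]]
    for (strand in c("plus", "minus")) {
      id <- ki[[strand]][pos]
      wt <- as.numeric(cc[[strand]][pos])
      ok <- !is.na(id) & wt > 0
      if (any(ok)) {
        tmp <- rowsum(wt[ok], id[ok])
        cutk[as.integer(rownames(tmp)) + 1L] <-
          cutk[as.integer(rownames(tmp)) + 1L] + tmp[, 1]
      }
      n_events <- n_events + sum(wt)
      okb <- !is.na(id)
      bgk <- bgk + tabulate(id[okb] + 1L, nbins = nk)
    }
  }
  if (n_events < 10 * nk)
    warning("only ", n_events, " cut events in background intervals; ",
            "bias estimates for k = ", k, " may be noisy")
  absent <- bgk == 0
  if (any(absent))
    message(sum(absent), " k-mer(s) absent from background excluded from table")
  cut_frac <- cutk / sum(cutk)
  bg_frac <- bgk / sum(bgk)
  r <- ifelse(absent, NA_real_, cut_frac / bg_frac)
  wmean <- sum(bg_frac[!absent] * r[!absent]) / sum(bg_frac[!absent])
  r <- r / wmean
  structure(list(k = as.integer(k),
                 rates = setNames(r, kmer_strings(k)),
                 background_freq = setNames(bg_frac, kmer_strings(k)),
                 background_source = "supplied intervals"),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  if (x$k == 0) {
    cat("bias_model: uniform (unadjusted)\n")
  } else {
    cat("bias_model: k =", x$k, "(", sum(!is.na(x$rates)), "of",
        length(x$rates), "k-mers )\n")
    cat("  rate range:",
        paste(signif(range(x$rates, na.rm = TRUE), 3), collapse = " - "), "\n")
  }
  invisible(x)
}

# Per-position relative rate for strand-summed counts: the mean of the
# plus-orientation and minus-orientation table rates at each base.
# Positions with no valid k-mer (N, chromosome edge) or an excluded k-mer
# get rate 1.
position_rates <- function(model, seq_chr) {
  L <- nchar(seq_chr)
  if (model$k == 0) return(rep(1, L))
  ki <- kmer_index(seq_chr, model$k)
  r <- unname(model$rates)
  rp <- r[ki$plus + 1L]
  rm_ <- r[ki$minus + 1L]
  rp[is.na(rp)] <- 1
  rm_[is.na(rm_)] <- 1
  (rp + rm_) / 2
}

#' Relative cleavage rates for every genome position
#'
#' Expands a fitted [fit_bias()] model into per-base relative rate vectors,
#' one per chromosome, for strand-summed counts. Precomputing this once and
#' passing it to [call_footprints()] / [score_sites()] avoids repeated
#' k-mer scans of the genome.
#'
#' @param model A `bias_model`.
#' @param genome `DNAStringSet` or FASTA path.
#' @return Named list of numeric vectors (class `bias_rates`).
#' @export
bias_position_rates <- function(model, genome) {
  genome <- as_genome(genome)
  out <- lapply(names(genome), function(chrom)
    position_rates(model, as.character(genome[[chrom]])))
  names(out) <- names(genome)
  class(out) <- "bias_rates"
  out
}

#' Bias-adjusted expected counts over an interval
#'
#' Distributes the observed strand-summed total of an interval over its
#' positions proportionally to the bias model's relative rates (local
#' renormalisation), so the interval total is conserved exactly.
#'
#' @param track A `cut_track`.
#' @param model A `bias_model`.
#' @param interval Single-range `GRanges`.
#' @param genome `DNAStringSet` or FASTA path (needed when `model$k > 0`).
#' @return Numeric vector of per-base expected counts; attribute
#'   `zero_observed` is `TRUE` when the interval contained no cuts (all
#'   zeros returned).
#' @export
expected_counts <- function(track, model, interval, genome = NULL) {
  stopifnot(is(interval, "GRanges"), length(interval) == 1)
  chrom <- as.character(GenomeInfoDb::seqnames(interval))
  s <- GenomicRanges::start(interval)
  e <- GenomicRanges::end(interval)
  y <- track_window(track, chrom, s, e)
  if (model$k == 0) {
    w <- rep(1, length(y))
  } else {
    genome <- as_genome(genome)
    w <- position_rates(model, as.character(genome[[chrom]]))[s:e]
  }
  tot <- sum(y)
  if (tot == 0) {
    out <- numeric(length(y))
    attr(out, "zero_observed") <- TRUE
    return(out)
  }
  out <- tot * w / sum(w)
  attr(out, "zero_observed") <- FALSE
  out
}
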