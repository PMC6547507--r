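# Synthetic-data generator: accessible regions with elevated cleavage,
# k-mer cleavage bias, planted TF motif sites with occupancy- and
# residence-time-dependent protection, and matching truth annotations.

#' Describe one transcription factor for the simulator
#'
#' @param name TF label (unique within a configuration).
#' @param motif Fixed motif string, 6-15 bp of A/C/G/T; planted verbatim into
#'   the genome at each site (reverse complemented on minus-strand sites).
#' @param n_sites Number of motif sites to plant inside accessible regions.
#' @param occupancy Fraction of sites truly bound, in `[0, 1]`.
#' @param protection Maximal fractional reduction of the cleavage rate at a
#'   bound site, in `[0, 1]` (1 = complete protection).
#' @param dynamic Logical; `TRUE` for a short-residence ("dynamic") TF whose
#'   effective protection depends on cross-link capture, `FALSE` for a stably
#'   bound TF.
#' @param residence Intrinsic residence fraction `rho` in `[0, 1]`: the share
#'   of assay time a bound TF actually occupies its site without cross-link
#'   stabilisation. Defaults to 0.1 for dynamic TFs and 1 for stable TFs.
#'
#' @details The effective protection at a bound site is
#'   `delta_eff = protection * (kappa + (1 - kappa) * residence)` where
#'   `kappa` is the cross-link capture efficiency of the sample
#'   (see [simulation_config()]). Without cross-linking (`kappa = 0`) a
#'   dynamic TF protects only during its residence fraction, giving shallow
#'   footprints; `kappa -> 1` freezes transient binding and deepens them.
#' @return An object of class `tf_spec`.
#' @export
#' @examples
#' tf_spec("NFKB1", "GGGACTTTCC", n_sites = 100, occupancy = 0.8,
#'         protection = 0.9, dynamic = TRUE)
tf_spec <- function(name, motif, n_sites, occupancy = 1, protection = 0.9,
                    dynamic = FALSE,
                    residence = if (dynamic) 0.1 else 1.0) {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif))
    stop("motif must contain only A/C/G/T: ", name)
  if (nchar(motif) < 6 || nchar(motif) > 15)
    stop("motif must be 6-15 bp: ", name)
  if (occupancy < 0 || occupancy > 1) stop("occupancy must be in [0,1]")
  if (protection < 0 || protection > 1) stop("protection must be in [0,1]")
  if (residence < 0 || residence > 1) stop("residence must be in [0,1]")
  structure(list(name = as.character(name), motif = motif,
                 n_sites = as.integer(n_sites), occupancy = occupancy,
                 protection = protection, dynamic = isTRUE(dynamic),
                 residence = residence),
            class = "tf_spec")
}

#' Configuration of a synthetic footprinting dataset
#'
#' Bundles every parameter of the generator: genome composition, accessible
#' ("peak") regions with elevated cleavage, a k-mer cleavage-bias table, the
#' planted TFs, and the cross-link capture efficiency.
#'
#' @param genome_length Genome length in bases (single chromosome).
#' @param gc_content GC fraction of the random genome background.
#' @param n_peaks,peak_width Number and fixed width (bp) of non-overlapping
#'   accessible regions.
#' @param peak_rate Expected cuts per base inside peaks (`lambda_peak`).
#' @param background_rate Expected cuts per base outside peaks (`lambda_bg`);
#'   must satisfy `peak_rate > background_rate >= 0`.
#' @param bias_table Named numeric vector of positive multipliers, one per
#'   k-mer (names are k-mers of a common length `k`), applied to the cleavage
#'   rate of each position according to the k-mer attributed to the cut (see
#'   [fit_bias()] for the attribution convention). `NULL` means no sequence
#'   bias. See [random_bias_table()].
#' @param tf_specs List of [tf_spec()] objects; names must be unique.
#' @param crosslink_capture Cross-link capture efficiency `kappa` in
#'   `[0, 1]`: 0 emulates a native (uncross-linked) sample, values near 1 a
#'   strongly cross-linked one.
#' @param tn5_interference Interference strength `iota` in `[0, 1]`,
#'   emulating inhibition of a transposase by cross-linked chromatin: the
#'   global cleavage rate is multiplied by `(1 - kappa * iota)` (fewer
#'   insertions overall) and the effective capture entering the protection
#'   model is attenuated to `kappa * (1 - iota)` (cross-linked, fixed
#'   templates are refractory to transposition, so the capture-deepened
#'   footprints are not sampled). Default 0 (no interference; appropriate
#'   for DNase).
#' @param site_margin Minimum distance (bp) between a planted motif site and
#'   its peak's edges (default 50). Depletion tests compare a candidate
#'   window against flanks that must fit inside the accessible region, so
#'   the outermost `flank_width` bases of a region are untestable by
#'   construction; the default margin matches the default flank width and
#'   mirrors the biological tendency of functional motifs to sit in peak
#'   interiors.
#' @param chrom Chromosome name.
#' @param seed Master seed; every random draw of the generator derives a
#'   deterministic child stream from it, so identical configurations yield
#'   byte-identical outputs.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 1e6, gc_content = 0.41,
                              n_peaks = 200, peak_width = 400,
                              peak_rate = 1.0, background_rate = 0.02,
                              bias_table = NULL, tf_specs = list(),
                              crosslink_capture = 0, tn5_interference = 0,
                              site_margin = 50L, chrom = "chrS1", seed = 1L) {
  if (crosslink_capture < 0 || crosslink_capture > 1)
    stop("crosslink_capture must be in [0,1]")
  if (tn5_interference < 0 || tn5_interference > 1)
    stop("tn5_interference must be in [0,1]")
  if (!(peak_rate > background_rate) || background_rate < 0)
    stop("need peak_rate > background_rate >= 0")
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0,1]")
  if (!is.null(bias_table)) {
    if (is.null(names(bias_table)) || any(bias_table <= 0))
      stop("bias_table must be a named vector of positive multipliers")
    k <- unique(nchar(names(bias_table)))
    if (length(k) != 1) stop("all bias_table k-mers must share one length")
    if (length(bias_table) != 4^k)
      stop("bias_table must cover all ", 4^k, " k-mers of length ", k)
  }
  if (length(tf_specs)) {
    if (!all(vapply(tf_specs, inherits, TRUE, "tf_spec")))
      stop("tf_specs must be a list of tf_spec objects")
    nm <- vapply(tf_specs, `[[`, "", "name")
    if (anyDuplicated(nm)) stop("duplicate TF names: ",
                                paste(nm[duplicated(nm)], collapse = ", "))
    names(tf_specs) <- nm
  }
  if (as.numeric(n_peaks) * peak_width >= genome_length / 2)
    stop("peaks must cover less than half the genome")
  if (length(tf_specs)) {
    wmax <- max(vapply(tf_specs, function(s) nchar(s$motif), 1L))
    if (peak_width < wmax + 2 * site_margin)
      stop("peak_width too small for site_margin and the widest motif")
  }
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, n_peaks = as.integer(n_peaks),
                 peak_width = as.integer(peak_width), peak_rate = peak_rate,
                 background_rate = background_rate, bias_table = bias_table,
                 tf_specs = tf_specs, crosslink_capture = crosslink_capture,
                 tn5_interference = tn5_interference,
                 site_margin = as.integer(site_margin),
                 chrom = chrom, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Random strand-symmetric k-mer bias table
#'
#' Draws log2 rates from a normal distribution and assigns the same
#' multiplier to each k-mer and its reverse complement, reflecting that the
#' nuclease attacks a double-stranded substrate. The table has geometric
#' mean 1.
#'
#' @param k K-mer length (2 = dimer, 4 = tetramer).
#' @param sd Standard deviation of the log2 rates (default 0.5, a realistic
#'   dynamic range of roughly 4-fold between the most and least preferred
#'   dimers).
#' @param seed Seed for the draw.
#' @return Named numeric vector of length `4^k`.
#' @export
random_bias_table <- function(k = 2, sd = 0.5, seed = 1L) {
  nk <- 4L^k
  rc <- revcomp_ids(k) + 1L
  with_seed(child_seed(seed, 97L), {
    lr <- stats::rnorm(nk, 0, sd)
    lr <- (lr + lr[rc]) / 2          # strand symmetry
    lr <- lr - mean(lr)              # geometric mean 1
    setNames(2^lr, kmer_strings(k))
  })
}

delta_effective <- function(spec, kappa) {
  spec$protection * (kappa + (1 - kappa) * spec$residence)
}

#' Simulate a genome with accessible regions and planted motif sites
#'
#' Generates a random genome of the configured GC content, places
#' non-overlapping accessible regions ("peaks"), plants each TF's motif at
#' `n_sites` non-overlapping positions fully inside peaks (random strand;
#' minus-strand sites carry the reverse complement), and draws per-site
#' bound/unbound flags with probability `occupancy`.
#'
#' @param config A [simulation_config()].
#' @param max_attempts_per_site Rejection-sampling budget per requested site;
#'   exceeding it raises an error naming the TF.
#' @return An object of class `crossfoot_sim`: a list with elements
#'   `genome` (named [Biostrings::DNAStringSet-class]), `peaks` (`GRanges`),
#'   `sites` (`GRanges` with columns `tf`, `bound`, `delta_eff`), `truth`
#'   (data.frame with 0-based half-open coordinates: chrom, start, end, tf,
#'   strand, bound, delta_eff), and `config`.
#' @seealso [simulate_cuts()], [write_simulation()]
#' @export
simulate_genome <- function(config, max_attempts_per_site = 200L) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$genome_length
  chrom <- config$chrom

  p <- c((1 - config$gc_content) / 2, config$gc_content / 2,
         config$gc_content / 2, (1 - config$gc_content) / 2)
  bases <- with_seed(child_seed(config$seed, 1L),
                     sample(DNA_BASES, L, replace = TRUE, prob = p))

  # Non-overlapping peaks, uniform over placements, via the spacing trick.
  np <- config$n_peaks
  pw <- config$peak_width
  if (np > 0) {
    free <- L - np * pw - (np - 1L)
    offs <- with_seed(child_seed(config$seed, 2L),
                      sort(sample.int(free + 1L, np, replace = TRUE) - 1L))
    starts0 <- offs + (seq_len(np) - 1L) * (pw + 1L)   # 0-based
    peaks <- GenomicRanges::GRanges(chrom,
               IRanges::IRanges(start = starts0 + 1L, width = pw))
  } else {
    peaks <- GenomicRanges::GRanges()
  }

  # Plant motif sites inside peaks by bounded rejection sampling.
  site_list <- list()
  occupied <- IRanges::IRanges()
  with_seed(child_seed(config$seed, 3L), {
    for (spec in config$tf_specs) {
      w <- nchar(spec$motif)
      if (np == 0 && spec$n_sites > 0)
        stop("cannot place sites for TF ", spec$name, ": no peaks")
      placed <- IRanges::IRanges()
      strands <- character(0)
      attempts <- 0L
      budget <- max_attempts_per_site * max(spec$n_sites, 1L)
      while (length(placed) < spec$n_sites) {
        need <- spec$n_sites - length(placed)
        attempts <- attempts + need
        if (attempts > budget)
          stop("could not place ", spec$n_sites, " sites for TF ",
               spec$name, " after ", budget, " attempts")
        pk <- sample.int(np, need, replace = TRUE)
        mar <- config$site_margin
        off <- mar + sample.int(pw - w - 2L * mar + 1L, need,
                                replace = TRUE) - 1L
        st <- GenomicRanges::start(peaks)[pk] + off      # 1-based
        cand <- IRanges::IRanges(start = st, width = w)
        sr <- sample(c("+", "-"), need, replace = TRUE)
        bad <- IRanges::overlapsAny(cand, occupied) |
               IRanges::overlapsAny(cand, placed)
        # also reject duplicates within the candidate batch
        self <- as.matrix(IRanges::findOverlaps(cand, cand))
        bad[unique(self[self[, 1] > self[, 2], 1])] <- TRUE
        placed <- c(placed, cand[!bad])
        strands <- c(strands, sr[!bad])
      }
      occupied <- c(occupied, placed)
      site_list[[spec$name]] <- list(ranges = placed, strand = strands,
                                     spec = spec)
    }
  })

  sites <- GenomicRanges::GRanges()
  truth <- data.frame()
  kappa <- config$crosslink_capture
  bound_seed <- child_seed(config$seed, 4L)
  i <- 0L
  for (nm in names(site_list)) {
    i <- i + 1L
    sl <- site_list[[nm]]
    spec <- sl$spec
    n <- length(sl$ranges)
    bound <- with_seed(child_seed(bound_seed, i),
                       runif(n) < spec$occupancy)
    de <- ifelse(bound, delta_effective(spec, kappa), 0)
    gr <- GenomicRanges::GRanges(chrom, sl$ranges, strand = sl$strand)
    S4Vectors::mcols(gr)$tf <- spec$name
    S4Vectors::mcols(gr)$bound <- bound
    S4Vectors::mcols(gr)$delta_eff <- de
    sites <- c(sites, gr)
    # embed the motif (reverse complement on minus strand)
    for (j in seq_len(n)) {
      m <- if (sl$strand[j] == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(spec$motif)))
      else spec$motif
      idx <- IRanges::start(sl$ranges)[j]:IRanges::end(sl$ranges)[j]
      bases[idx] <- strsplit(m, "")[[1]]
    }
  }
  if (length(sites)) {
    o <- GenomicRanges::order(sites)
    sites <- sites[o]
    truth <- data.frame(chrom = chrom,
                        start = GenomicRanges::start(sites) - 1L,
                        end = GenomicRanges::end(sites),
                        tf = S4Vectors::mcols(sites)$tf,
                        strand = as.character(GenomicRanges::strand(sites)),
                        bound = S4Vectors::mcols(sites)$bound,
                        delta_eff = S4Vectors::mcols(sites)$delta_eff,
                        stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(chrom = character(), start = integer(),
                        end = integer(), tf = character(),
                        strand = character(), bound = logical(),
                        delta_eff = numeric())
  }

  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- chrom
  structure(list(genome = genome, peaks = peaks, sites = sites,
                 truth = truth, config = config),
            class = "crossfoot_sim")
}

#' Simulate per-base cut counts for a synthetic genome
#'
#' The count at position i on each strand is drawn from a Poisson
#' distribution with mean `m_s(i) = lambda(i) * b_s(i) * p(i) *
#' (1 - kappa * iota) / 2`, where `lambda(i)` is `peak_rate` inside peaks
#' and `background_rate` outside, `p(i) = 1 - delta_eff` inside truly bound
#' motif sites (1 elsewhere), and `b_s(i)` is the bias-table multiplier of
#' the k-mer a cut at i is attributed to on strand s — the plus-strand
#' window for plus cuts and the reverse complement of the mirror-image
#' window for minus cuts, exactly the convention [fit_bias()] uses
#' (multiplier 1 where the window contains N or runs off the chromosome).
#' The strand-summed count is therefore Poisson with mean
#' `m(i) = lambda(i) * b(i) * p(i) * (1 - kappa * iota)` with `b(i)` the
#' mean of the two orientations' multipliers, and with a strand-symmetric
#' bias table (see [random_bias_table()]) the split is 50/50 binomial.
#' With interference (`iota > 0`), `delta_eff` is evaluated at the
#' attenuated capture `kappa * (1 - iota)` and the global rate gains the
#' factor `(1 - kappa * iota)` (see [simulation_config()]).
#'
#' @param sim A `crossfoot_sim` from [simulate_genome()].
#' @param kappa Cross-link capture efficiency; defaults to the value in the
#'   simulation config. Overriding it reuses the same genome, sites, and
#'   bound flags so that samples across a `kappa` grid share one truth.
#' @param iota Interference strength (see [simulation_config()]).
#' @param assay `"DNase"` or `"ATAC"` (label only; the count model is shared).
#' @param label Sample label stored in the track.
#' @param fragments If `TRUE`, also return each cut as a 1-bp read interval
#'   (`GRanges`) whose 5' end is the cut position, for exercising
#'   [extract_cuts()].
#' @param stream Offset added to the RNG child stream, so that several
#'   samples drawn from one `crossfoot_sim` are independent yet reproducible.
#' @return A `cut_track` (see [cut_track()]); with `fragments = TRUE`, a list
#'   `list(track, fragments)`.
#' @export
simulate_cuts <- function(sim, kappa = NULL, iota = NULL,
                          assay = c("DNase", "ATAC"), label = "sim",
                          fragments = FALSE, stream = 0L) {
  stopifnot(inherits(sim, "crossfoot_sim"))
  assay <- match.arg(assay)
  config <- sim$config
  kappa <- kappa %||% config$crosslink_capture
  iota <- iota %||% config$tn5_interference
  L <- config$genome_length
  chrom <- config$chrom

  lam <- rep(config$background_rate, L)
  if (length(sim$peaks)) {
    pk <- IRanges::ranges(sim$peaks)
    idx <- unlist(lapply(seq_along(pk), function(i)
      IRanges::start(pk)[i]:IRanges::end(pk)[i]))
    lam[idx] <- config$peak_rate
  }

  b_plus <- rep(1, L)
  b_minus <- rep(1, L)
  if (!is.null(config$bias_table)) {
    k <- nchar(names(config$bias_table)[1])
    ki <- kmer_index(as.character(sim$genome[[1]]), k)
    tab <- unname(config$bias_table)
    hit <- !is.na(ki$plus)
    b_plus[hit] <- tab[ki$plus[hit] + 1L]
    hit <- !is.na(ki$minus)
    b_minus[hit] <- tab[ki$minus[hit] + 1L]
  }

  # Interference: cross-linked templates are refractory, so both the global
  # rate and the effective capture drop with kappa * iota.
  kappa_eff <- kappa * (1 - iota)
  prot <- rep(1, L)
  if (length(sim$sites)) {
    bound <- S4Vectors::mcols(sim$sites)$bound
    if (any(bound)) {
      bs <- sim$sites[bound]
      tf <- S4Vectors::mcols(bs)$tf
      de <- vapply(tf, function(nm)
        delta_effective(config$tf_specs[[nm]], kappa_eff), numeric(1))
      for (j in seq_along(bs)) {
        idx <- GenomicRanges::start(bs)[j]:GenomicRanges::end(bs)[j]
        prot[idx] <- pmin(prot[idx], 1 - de[j])
      }
    }
  }

  base_mean <- lam * prot * (1 - kappa * iota) / 2
  res <- with_seed(child_seed(config$seed, 5L + stream), {
    plus <- rpois(L, base_mean * b_plus)
    minus <- rpois(L, base_mean * b_minus)
    list(plus = plus, minus = minus)
  })
  plus <- res$plus
  minus <- res$minus

  counts <- list()
  counts[[chrom]] <- list(plus = as.integer(plus), minus = as.integer(minus))
  track <- cut_track(counts, total_mapped = sum(plus) + sum(minus),
                     assay = assay, label = label)
  if (!fragments) return(track)

  pos <- seq_len(L)
  frag_plus <- rep(pos, plus)
  frag_minus <- rep(pos, minus)
  fr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = c(frag_plus, frag_minus), width = 1L),
          strand = rep(c("+", "-"), c(length(frag_plus), length(frag_minus))))
  list(track = track, fragments = fr)
}

#' Emit TSS annotations and a TF-to-motif map
#'
#' Assigns every TF a gene with a transcription start site placed uniformly
#' at random on the chromosome, plus optional decoy genes, and returns the
#' map from TF name to motif string. Used to exercise regulatory-network
#' construction on synthetic data.
#'
#' @param tf_specs List of [tf_spec()]s (unique names required).
#' @param genome_length Chromosome length.
#' @param seed Seed for TSS placement.
#' @param n_decoys Number of decoy genes (named `decoy1`, ...).
#' @param chrom Chromosome name.
#' @return List with `tss` (`GRanges` of width-1 TSS positions, column
#'   `gene`) and `tf_map` (data.frame tf, motif).
#' @export
emit_annotations <- function(tf_specs, genome_length, seed = 1L,
                             n_decoys = 0L, chrom = "chrS1") {
  nm <- vapply(tf_specs, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate TF names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  n <- length(nm) + n_decoys
  pos <- with_seed(child_seed(seed, 6L),
                   sample.int(genome_length, n, replace = TRUE))
  genes <- c(nm, if (n_decoys > 0) paste0("decoy", seq_len(n_decoys)))
  tss <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  S4Vectors::mcols(tss)$gene <- genes
  tf_map <- data.frame(tf = nm,
                       motif = vapply(tf_specs, `[[`, "", "motif"),
                       stringsAsFactors = FALSE)
  list(tss = tss, tf_map = tf_map)
}

#' @export
print.crossfoot_sim <- function(x, ...) {
  cat("crossfoot synthetic dataset\n")
  cat("  genome:", x$config$chrom, "-", x$config$genome_length, "bp\n")
  cat("  peaks:", length(x$peaks), "x", x$config$peak_width, "bp\n")
  cat("  motif sites:", length(x$sites), "over",
      length(x$config$tf_specs), "TFs\n")
  cat("  kappa =", x$config$crosslink_capture, "\n")
  invisible(x)
}
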