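# Per-base, per-strand cut / insertion count tracks and depth operations.

#' Per-base cut count track
#'
#' Container for nucleotide-resolution cleavage (DNase) or insertion (ATAC)
#' counts: two integer vectors (plus / minus strand) per chromosome, plus the
#' total mapped-read count used for depth normalisation.
#'
#' @param counts Named list, one element per chromosome, each a
#'   `list(plus = integer, minus = integer)` of equal length (the chromosome
#'   length).
#' @param total_mapped Total number of mapped reads the track derives from;
#'   must be at least the number of recorded cut events.
#' @param assay `"DNase"` or `"ATAC"`.
#' @param label Sample label.
#' @return An object of class `cut_track`.
#' @export
cut_track <- function(counts, total_mapped, assay = c("DNase", "ATAC"),
                      label = "sample") {
  assay <- match.arg(assay)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named per-chromosome list")
  for (chr in names(counts)) {
    cc <- counts[[chr]]
    if (!is.list(cc) || !all(c("plus", "minus") %in% names(cc)) ||
        length(cc$plus) != length(cc$minus))
      stop("each chromosome needs equal-length 'plus' and 'minus' vectors")
    if (any(cc$plus < 0) || any(cc$minus < 0))
      stop("counts must be non-negative")
  }
  events <- sum(vapply(counts, function(cc)
    sum(as.numeric(cc$plus)) + sum(as.numeric(cc$minus)), numeric(1)))
  if (total_mapped < events)
    stop("total_mapped (", total_mapped, ") < recorded cut events (",
         events, ")")
  structure(list(counts = counts, total_mapped = as.numeric(total_mapped),
                 assay = assay, label = label),
            class = "cut_track")
}

#' @export
print.cut_track <- function(x, ...) {
  cat("cut_track '", x$label, "' (", x$assay, ")\n", sep = "")
  cat("  chromosomes:", paste(names(x$counts), collapse = ", "), "\n")
  cat("  cut events:", format(track_total(x), big.mark = ","),
      "| total_mapped:", format(x$total_mapped, big.mark = ","), "\n")
  invisible(x)
}

#' Total number of recorded cut events in a track
#' @param track A `cut_track`.
#' @return Numeric scalar.
#' @export
track_total <- function(track) {
  sum(vapply(track$counts, function(cc)
    sum(as.numeric(cc$plus)) + sum(as.numeric(cc$minus)), numeric(1)))
}

#' Strand-summed counts over an interval
#' @param track A `cut_track`.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bounds (defaults: whole chromosome).
#' @return Integer vector of per-base plus+minus counts.
#' @export
track_window <- function(track, chrom, start = 1L, end = NULL) {
  cc <- track$counts[[chrom]]
  if (is.null(cc)) stop("unknown chromosome: ", chrom)
  end <- end %||% length(cc$plus)
  cc$plus[start:end] + cc$minus[start:end]
}

chrom_lengths <- function(track)
  vapply(track$counts, function(cc) length(cc$plus), integer(1))

#' Extract per-base cut counts from aligned fragments
#'
#' Converts aligned reads into nucleotide-resolution cut (DNase) or
#' insertion (ATAC) counts. For DNase the counted position is the 5' end of
#' each read on its strand. For ATAC the 5' end is shifted +4 bp on the plus
#' strand and -5 bp on the minus strand to centre counts on the Tn5
#' insertion event (the field-standard offset for the 9-bp target-site
#' duplication); the shift can be disabled or changed via `shift`.
#'
#' @param fragments A `GRanges` of reads, or a path to a BED or BAM file.
#'   BED input is assumed pre-filtered for mapping quality; BAM records with
#'   MAPQ below `mapq_min`, unmapped, or failing vendor QC are excluded.
#' @param assay `"DNase"` or `"ATAC"`.
#' @param genome_sizes Named integer vector of chromosome lengths. Reads on
#'   chromosomes absent from it are skipped (with a warning giving the
#'   count); positions falling outside a chromosome after shifting are
#'   clipped to the boundary and counted there.
#' @param shift Length-2 integer `c(plus, minus)` added to the 5' position.
#'   Default `c(4, -5)` for ATAC, `c(0, 0)` for DNase.
#' @param mapq_min Minimum MAPQ for BAM input (default 10).
#' @param drop_duplicates If `TRUE`, reads with identical chromosome, start,
#'   end, and strand are collapsed to one before counting. Off by default:
#'   footprinting uses cut pileups, where independent fragments legitimately
#'   share 5' ends at high depth.
#' @param label Sample label for the resulting track.
#' @return A [cut_track()]; attribute `clipped` records how many positions
#'   were clipped at chromosome boundaries.
#' @export
extract_cuts <- function(fragments, assay = c("DNase", "ATAC"), genome_sizes,
                         shift = NULL, mapq_min = 10L,
                         drop_duplicates = FALSE, label = "sample") {
  assay <- match.arg(assay)
  shift <- shift %||% if (assay == "ATAC") c(4L, -5L) else c(0L, 0L)
  if (length(shift) != 2) stop("shift must be length 2: c(plus, minus)")
  if (is.null(names(genome_sizes)))
    stop("genome_sizes must be a named vector")

  if (is.character(fragments)) {
    fragments <- if (grepl("\\.bam$", fragments, ignore.case = TRUE))
      read_bam_reads(fragments, mapq_min)
    else rtracklayer::import(fragments, format = "BED")
  }
  stopifnot(is(fragments, "GRanges"))
  if (drop_duplicates) fragments <- unique(fragments)

  chr <- as.character(GenomeInfoDb::seqnames(fragments))
  known <- chr %in% names(genome_sizes)
  if (any(!known))
    warning(sum(!known), " read(s) on unknown chromosomes skipped")
  fragments <- fragments[known]
  chr <- chr[known]
  str <- as.character(GenomicRanges::strand(fragments))
  str[str == "*"] <- "+"

  pos <- ifelse(str == "+",
                GenomicRanges::start(fragments) + shift[1],
                GenomicRanges::end(fragments) + shift[2])
  clipped <- 0L
  counts <- list()
  for (cn in names(genome_sizes)) {
    len <- genome_sizes[[cn]]
    sel <- chr == cn
    p <- pos[sel]
    s <- str[sel]
    out_lo <- p < 1L
    out_hi <- p > len
    clipped <- clipped + sum(out_lo) + sum(out_hi)
    p[out_lo] <- 1L
    p[out_hi] <- len
    counts[[cn]] <- list(
      plus = tabulate(p[s == "+"], nbins = len),
      minus = tabulate(p[s == "-"], nbins = len))
  }
  tr <- cut_track(counts, total_mapped = length(fragments), assay = assay,
                  label = label)
  attr(tr, "clipped") <- clipped
  tr
}

# Minimal BAM reader: mapped, QC-pass, MAPQ-filtered reads as GRanges.
read_bam_reads <- function(path, mapq_min) {
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isNotPassingQualityControls = FALSE)
  par <- Rsamtools::ScanBamParam(flag = flag,
            what = c("rname", "pos", "qwidth", "strand", "mapq"))
  b <- Rsamtools::scanBam(path, param = par)[[1]]
  keep <- !is.na(b$pos) & (is.na(b$mapq) | b$mapq >= mapq_min)
  GenomicRanges::GRanges(as.character(b$rname)[keep],
    IRanges::IRanges(start = b$pos[keep], width = b$qwidth[keep]),
    strand = as.character(b$strand)[keep])
}

#' Depth-normalised fragment density
#'
#' Sums strand-combined counts in non-overlapping windows and scales them to
#' a depth of 10 million mapped reads (factor `1e7 / total_mapped`), the
#' conventional scale for comparing accessibility profiles across samples.
#'
#' @param track A `cut_track` with `total_mapped > 0`.
#' @param window Window width in bp (default 150).
#' @return `GRanges` with a `score` column, ready for bedGraph export via
#'   [rtracklayer::export()].
#' @export
normalize_density <- function(track, window = 150L) {
  if (track$total_mapped <= 0)
    stop("total_mapped must be > 0 to normalise density")
  scale <- 1e7 / track$total_mapped
  out <- GenomicRanges::GRanges()
  for (chr in names(track$counts)) {
    y <- track$counts[[chr]]$plus + track$counts[[chr]]$minus
    L <- length(y)
    n <- ceiling(L / window)
    grp <- rep(seq_len(n), each = window, length.out = L)
    sums <- as.vector(rowsum(as.numeric(y), grp))
    st <- (seq_len(n) - 1L) * window + 1L
    en <- pmin(seq_len(n) * window, L)
    gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, en),
                                 score = sums * scale)
    out <- c(out, gr)
  }
  out
}

#' Subsample a track to a fixed number of cut events
#'
#' Retains exactly `target_n` cut events selected uniformly without
#' replacement from the track's event multiset, so that samples of unequal
#' sequencing depth can be compared fairly. Deterministic given `seed`.
#'
#' @param track A `cut_track`.
#' @param target_n Number of events to keep; must not exceed the track total.
#' @param seed Integer seed for the draw.
#' @return A `cut_track` with `target_n` events and `total_mapped = target_n`.
#' @export
subsample_track <- function(track, target_n, seed = 1L) {
  total <- track_total(track)
  if (target_n > total)
    stop("target_n (", target_n, ") exceeds available events (", total, ")")
  if (target_n == total) {
    out <- track
    out$total_mapped <- total
    return(out)
  }
  # Flatten all (chrom, strand, position) cells, draw event indices, and
  # count how many drawn events land in each cell (multivariate
  # hypergeometric draw).
  flat <- unlist(lapply(track$counts, function(cc)
    c(cc$plus, cc$minus)), use.names = FALSE)
  kept <- integer(length(flat))
  if (target_n > 0) {
    cs <- cumsum(as.numeric(flat))
    picks <- with_seed(seed, sample(total, target_n))
    cell <- findInterval(picks - 0.5, cs) + 1L
    tab <- tabulate(cell, nbins = length(flat))
    kept <- tab
  }
  counts <- list()
  off <- 0L
  for (chr in names(track$counts)) {
    L <- length(track$counts[[chr]]$plus)
    counts[[chr]] <- list(plus = kept[off + seq_len(L)],
                          minus = kept[off + L + seq_len(L)])
    off <- off + 2L * L
  }
  cut_track(counts, total_mapped = target_n, assay = track$assay,
            label = track$label)
}

#' Average a statistic over repeated subsampling rounds
#'
#' Runs [subsample_track()] `rounds` times with distinct seeds, applies
#' `stat_fn` to each subsampled track, and reports the per-round values and
#' their arithmetic mean. Five rounds is the conventional default for
#' depth-matched comparisons of footprint counts across samples.
#'
#' @param track A `cut_track`.
#' @param target_n Events per round.
#' @param stat_fn Function `cut_track -> numeric scalar`.
#' @param rounds Number of rounds (default 5).
#' @param seeds Integer vector of per-round seeds (default `1:rounds`);
#'   identical seed lists reproduce identical output.
#' @return List with `values` (length `rounds`) and `mean`.
#' @export
repeat_subsample <- function(track, target_n, stat_fn, rounds = 5L,
                             seeds = NULL) {
  if (rounds < 1) stop("rounds must be >= 1")
  seeds <- seeds %||% seq_len(rounds)
  if (length(seeds) != rounds) stop("need one seed per round")
  values <- vapply(seeds, function(s)
    as.numeric(stat_fn(subsample_track(track, target_n, seed = s))),
    numeric(1))
  list(values = values, mean = mean(values))
}
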