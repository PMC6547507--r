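# TF regulatory networks from footprints over motif sites near TSSs,
# and comparison of networks across samples.

#' Build a TF regulatory network from footprints
#'
#' Emits a directed edge `A -> B` whenever a footprint overlaps (>= 1 bp) a
#' motif site of TF A whose centre lies within `window` bp of the TSS of
#' gene B. Footprints are expected to be FDR-filtered already (e.g. the
#' `q <= 0.01` output of [call_footprints()]). When a gene has several TSS
#' records, the nearest TSS is used for each evidence record.
#'
#' @param footprints `GRanges` of called footprints (a `q` column, if
#'   present, is carried into the evidence table).
#' @param motif_sites `GRanges` with a `tf` metadata column naming the
#'   regulator of each site.
#' @param tss `GRanges` of width-1 TSS positions with a `gene` metadata
#'   column (gene symbols); missing gene names are an error.
#' @param window Maximum distance (bp) from motif-site centre to TSS
#'   (default 5000, i.e. "within 5 kb").
#' @param label Sample label stored with the network.
#' @return Object of class `crossfoot_network`: list with `edges`
#'   (data.frame `regulator`, `target`, `n_support`), `evidence`
#'   (data.frame, one row per supporting footprint-site-TSS triple with the
#'   signed distance to the TSS), and `label`.
#' @export
build_network <- function(footprints, motif_sites, tss, window = 5000L,
                          label = "sample") {
  stopifnot(is(footprints, "GRanges"), is(motif_sites, "GRanges"),
            is(tss, "GRanges"))
  if (is.null(S4Vectors::mcols(motif_sites)$tf))
    stop("motif_sites must carry a 'tf' metadata column")
  genes <- S4Vectors::mcols(tss)$gene
  if (is.null(genes) || any(is.na(genes)) || any(!nzchar(genes)))
    stop("tss must carry a 'gene' metadata column with gene symbols")

  empty <- data.frame(regulator = character(), target = character(),
                      n_support = integer(), stringsAsFactors = FALSE)
  ev_empty <- data.frame(regulator = character(), target = character(),
                         chrom = character(), fp_start = integer(),
                         fp_end = integer(), q = numeric(),
                         site_start = integer(), site_end = integer(),
                         distance = integer(), stringsAsFactors = FALSE)
  net <- function(edges, evidence)
    structure(list(edges = edges, evidence = evidence, label = label),
              class = "crossfoot_network")
  if (!length(footprints) || !length(motif_sites) || !length(tss))
    return(net(empty, ev_empty))

  hits <- GenomicRanges::findOverlaps(footprints, motif_sites)
  if (!length(hits)) return(net(empty, ev_empty))
  fp_i <- S4Vectors::queryHits(hits)
  site_i <- S4Vectors::subjectHits(hits)

  centers <- site_centers0(motif_sites)[site_i]          # 0-based
  tss_pos <- GenomicRanges::start(tss) - 1L              # 0-based point
  tss_chr <- as.character(GenomeInfoDb::seqnames(tss))
  site_chr <- as.character(GenomeInfoDb::seqnames(motif_sites))[site_i]

  rows <- list()
  for (g in unique(genes)) {
    gi <- which(genes == g)
    same <- outer(site_chr, tss_chr[gi], "==")
    dmat <- abs(outer(centers, tss_pos[gi], "-"))
    dmat[!same] <- NA_real_
    # nearest TSS of this gene per (footprint, site) pair
    dmin <- suppressWarnings(apply(dmat, 1, min, na.rm = TRUE))
    sel <- which(is.finite(dmin) & dmin <= window)
    if (!length(sel)) next
    which_tss <- apply(dmat[sel, , drop = FALSE], 1, which.min)
    signed <- centers[sel] - tss_pos[gi][which_tss]
    q <- S4Vectors::mcols(footprints)$q
    rows[[g]] <- data.frame(
      regulator = S4Vectors::mcols(motif_sites)$tf[site_i[sel]],
      target = g,
      chrom = site_chr[sel],
      fp_start = GenomicRanges::start(footprints)[fp_i[sel]] - 1L,
      fp_end = GenomicRanges::end(footprints)[fp_i[sel]],
      q = if (is.null(q)) NA_real_ else q[fp_i[sel]],
      site_start = GenomicRanges::start(motif_sites)[site_i[sel]] - 1L,
      site_end = GenomicRanges::end(motif_sites)[site_i[sel]],
      distance = as.integer(signed),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(net(empty, ev_empty))
  evidence <- do.call(rbind, rows)
  rownames(evidence) <- NULL
  key <- paste(evidence$regulator, evidence$target, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  edges <- data.frame(regulator = parts[, 1], target = parts[, 2],
                      n_support = as.integer(tab), stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  net(edges, evidence)
}

#' @export
print.crossfoot_network <- function(x, ...) {
  cat("crossfoot_network '", x$label, "': ", nrow(x$edges),
      " edge(s), ", nrow(x$evidence), " evidence record(s)\n", sep = "")
  invisible(x)
}

edge_keys <- function(net) {
  if (inherits(net, "crossfoot_network")) net <- net$edges
  if (!nrow(net)) return(character(0))
  paste(net$regulator, net$target, sep = " -> ")
}

#' Jaccard index between two regulatory networks
#'
#' Intersection over union of the two edge sets (edge identity: exact
#' regulator and target name match). Ranges from 0 (disjoint) to 1
#' (identical). Two empty networks are defined as identical (1, with a
#' warning).
#'
#' @param network_a,network_b `crossfoot_network` objects (or data.frames
#'   with `regulator`/`target` columns).
#' @return Numeric scalar in `[0, 1]`.
#' @export
jaccard_index <- function(network_a, network_b) {
  a <- unique(edge_keys(network_a))
  b <- unique(edge_keys(network_b))
  if (!length(a) && !length(b)) {
    warning("both networks are empty; Jaccard index defined as 1")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise Jaccard similarity matrix of regulatory networks
#'
#' @param networks Named list of at least two `crossfoot_network`s.
#' @param file Optional path; when given, the matrix is written as TSV.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(networks, file = NULL) {
  if (length(networks) < 2) stop("need at least two networks")
  nm <- names(networks) %||% paste0("net", seq_along(networks))
  n <- length(networks)
  m <- diag(1, n)
  dimnames(m) <- list(nm, nm)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <-
      suppressWarnings(jaccard_index(networks[[i]], networks[[j]]))
  }
  if (!is.null(file))
    write.table(data.frame(network = rownames(m), m, check.names = FALSE),
                file, sep = "\t", quote = FALSE, row.names = FALSE)
  m
}

#' Shared and condition-specific regulatory edges
#'
#' Tri-partitions two edge sets into shared edges and edges unique to each
#' network, e.g. to highlight connections recovered only after
#' cross-linking.
#'
#' @param network_a,network_b `crossfoot_network` objects.
#' @return List of data.frames `shared`, `unique_a`, `unique_b` (columns
#'   `regulator`, `target`).
#' @export
edge_diff <- function(network_a, network_b) {
  a <- unique(edge_keys(network_a))
  b <- unique(edge_keys(network_b))
  split_keys <- function(keys) {
    if (!length(keys))
      return(data.frame(regulator = character(), target = character(),
                        stringsAsFactors = FALSE))
    parts <- do.call(rbind, strsplit(keys, " -> ", fixed = TRUE))
    data.frame(regulator = parts[, 1], target = parts[, 2],
               stringsAsFactors = FALSE)
  }
  list(shared = split_keys(sort(intersect(a, b))),
       unique_a = split_keys(sort(setdiff(a, b))),
       unique_b = split_keys(sort(setdiff(b, a))))
}
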