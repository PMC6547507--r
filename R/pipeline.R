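# End-to-end orchestration: synthetic demonstration datasets and the
# multi-sample comparison pipeline with a fixed output layout.

#' Demonstration simulation configuration
#'
#' A compact synthetic study emulating a cross-linking series: a 2 Mb
#' genome, 200 accessible regions, a strand-symmetric dimer bias, and four
#' TFs — two dynamic (short residence) and two stable — whose sites are
#' shared across all samples of a cross-link capture (`kappa`) grid.
#'
#' @param genome_length,n_peaks Genome size and peak count (defaults 2 Mb,
#'   200).
#' @param sites_per_tf Motif sites planted per TF (default 300).
#' @param seed Master seed.
#' @return A [simulation_config()].
#' @export
demo_config <- function(genome_length = 2e6, n_peaks = 200,
                        sites_per_tf = 300, seed = 1L) {
  tfs <- list(
    tf_spec("DYN1", "GGGACTTTCC", sites_per_tf, occupancy = 0.6,
            protection = 0.9, dynamic = TRUE),
    tf_spec("DYN2", "TGACTCAGCA", sites_per_tf, occupancy = 0.6,
            protection = 0.9, dynamic = TRUE),
    tf_spec("STA1", "CCGCGGGGGCGG", sites_per_tf, occupancy = 0.6,
            protection = 0.9, dynamic = FALSE),
    tf_spec("STA2", "CCACCAGGTGGC", sites_per_tf, occupancy = 0.6,
            protection = 0.9, dynamic = FALSE))
  simulation_config(genome_length = genome_length, gc_content = 0.41,
                    n_peaks = n_peaks, peak_width = 400,
                    peak_rate = 1.0, background_rate = 0.02,
                    bias_table = random_bias_table(2, sd = 0.5, seed = seed),
                    tf_specs = tfs, crosslink_capture = 0,
                    seed = seed)
}

track_to_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges()
  for (chrom in names(track$counts)) {
    y <- track$counts[[chrom]]$plus + track$counts[[chrom]]$minus
    nz <- which(y > 0)
    if (!length(nz)) next
    gr <- c(gr, GenomicRanges::GRanges(chrom,
              IRanges::IRanges(nz, width = 1L), score = y[nz]))
  }
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic cross-linking series on disk
#'
#' Simulates one genome/truth and a panel of samples over a grid of
#' cross-link capture values, writing genome FASTA, peak and motif-site
#' BED, per-sample truth TSV and strand-summed count bedGraph, TSS BED,
#' the TF-to-motif map, and a JSON manifest of parameters and files.
#'
#' @param config A [simulation_config()] (e.g. [demo_config()]).
#' @param out_dir Output directory (created if missing).
#' @param kappa_grid Cross-link capture values, one sample per value
#'   (default `c(0, 0.5, 0.9)`); all samples share genome, sites, and
#'   bound flags.
#' @param assay Assay label for the simulated tracks.
#' @param iota Interference strength passed to [simulate_cuts()].
#' @param n_decoys Decoy genes for the TSS annotation (default 10).
#' @return Invisibly, a list with the `sim` object, `tracks` (named list of
#'   `cut_track`s), `annotations`, and `manifest`.
#' @export
run_simulate <- function(config, out_dir, kappa_grid = c(0, 0.5, 0.9),
                         assay = c("DNase", "ATAC"), iota = NULL,
                         n_decoys = 10L) {
  assay <- match.arg(assay)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  ann <- emit_annotations(config$tf_specs, config$genome_length,
                          seed = config$seed, n_decoys = n_decoys,
                          chrom = config$chrom)
  files <- list()
  fa <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  files$genome <- fa
  files$peaks <- file.path(out_dir, "peaks.bed")
  rtracklayer::export(sim$peaks, files$peaks, format = "BED")
  sites_bed <- sim$sites
  S4Vectors::mcols(sites_bed) <-
    S4Vectors::DataFrame(name = S4Vectors::mcols(sim$sites)$tf, score = 0L)
  files$sites <- file.path(out_dir, "motif_sites.bed")
  rtracklayer::export(sites_bed, files$sites, format = "BED")
  tssb <- ann$tss
  S4Vectors::mcols(tssb) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(ann$tss)$gene, score = 0L)
  files$tss <- file.path(out_dir, "tss.bed")
  rtracklayer::export(tssb, files$tss, format = "BED")
  files$tf_map <- write_tsv(ann$tf_map, file.path(out_dir, "tf_map.tsv"))

  tracks <- list()
  for (i in seq_along(kappa_grid)) {
    kap <- kappa_grid[i]
    label <- sprintf("kappa%03d", round(kap * 100))
    tr <- simulate_cuts(sim, kappa = kap, iota = iota, assay = assay,
                        label = label, stream = i - 1L)
    tracks[[label]] <- tr
    files[[paste0("cuts_", label)]] <-
      track_to_bedgraph(tr, file.path(out_dir, paste0("cuts_", label, ".bedGraph")))
    truth <- sim$truth
    kap_eff <- kap * (1 - (iota %||% config$tn5_interference))
    truth$delta_eff <- ifelse(truth$bound, vapply(truth$tf, function(nm)
      delta_effective(config$tf_specs[[nm]], kap_eff), numeric(1)), 0)
    files[[paste0("truth_", label)]] <-
      write_tsv(truth, file.path(out_dir, paste0("truth_", label, ".tsv")))
  }
  manifest <- list(
    stage = "simulate", assay = assay, seed = config$seed,
    genome_length = config$genome_length, n_peaks = config$n_peaks,
    peak_width = config$peak_width, peak_rate = config$peak_rate,
    background_rate = config$background_rate,
    kappa_grid = kappa_grid, iota = iota %||% config$tn5_interference,
    tfs = lapply(unname(config$tf_specs), unclass),
    files = lapply(files, normalizePath))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, tracks = tracks, annotations = ann,
                 manifest = manifest))
}

#' Run the full multi-sample comparison pipeline
#'
#' Orchestrates, for a named set of samples sharing one genome and peak
#' set: optional depth-matched subsampling, sequence-bias fitting,
#' FDR-controlled footprint calling, motif-site scoring, ROC /
#' precision-recall evaluation against per-TF reference binding sets with
#' paired DeLong comparisons versus the first sample, regulatory-network
#' construction, and the pairwise Jaccard matrix. All tabular outputs are
#' TSV, intervals BED, and a JSON manifest records parameters and files.
#' Stages whose inputs are absent (no reference peaks, no TSS) are skipped
#' with a message; everything else still runs.
#'
#' @param tracks Named list of [cut_track()]s (or paths to fragment BED
#'   files, loaded with [extract_cuts()]).
#' @param genome `DNAStringSet` or FASTA path.
#' @param peaks Accessible regions (`GRanges` or BED path).
#' @param motif_sites `GRanges` with `tf` column, or BED path whose name
#'   column holds the TF label.
#' @param reference_peaks Optional named list (by TF) of `GRanges` / BED
#'   paths with reference binding peaks.
#' @param tss Optional TSS `GRanges` with `gene` column, or BED path whose
#'   name column holds the gene symbol.
#' @param out_dir Output directory.
#' @param k Bias-model k-mer length (0 = unadjusted, default 2).
#' @param fdr Footprint FDR threshold (default 0.01).
#' @param flank_width,width_range Footprint-calling geometry.
#' @param subsample_to `NULL` (use full depth), `"min"` (match all samples
#'   to the shallowest), or an integer target.
#' @param rounds Subsampling rounds for the footprint-count comparison.
#' @param seed Seed for subsampling streams.
#' @param network_window TSS window for network edges (bp, default 5000).
#' @return Invisibly, a list with per-sample footprints, site scores, ROC /
#'   PR / DeLong results, networks, the Jaccard matrix, footprint-count
#'   table, and the manifest.
#' @export
run_compare <- function(tracks, genome, peaks, motif_sites,
                        reference_peaks = NULL, tss = NULL,
                        out_dir, k = 2L, fdr = 0.01,
                        flank_width = 50L, width_range = c(6L, 40L),
                        subsample_to = NULL, rounds = 5L, seed = 1L,
                        network_window = 5000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- as_genome(genome)
  sizes <- setNames(Biostrings::width(genome), names(genome))
  if (is.character(peaks)) peaks <- rtracklayer::import(peaks, format = "BED")
  if (is.character(motif_sites)) {
    motif_sites <- rtracklayer::import(motif_sites, format = "BED")
    S4Vectors::mcols(motif_sites)$tf <- S4Vectors::mcols(motif_sites)$name
  }
  if (!is.null(tss) && is.character(tss)) {
    tss <- rtracklayer::import(tss, format = "BED")
    S4Vectors::mcols(tss)$gene <- S4Vectors::mcols(tss)$name
  }
  if (!is.null(reference_peaks))
    reference_peaks <- lapply(reference_peaks, function(x)
      if (is.character(x)) rtracklayer::import(x, format = "BED") else x)
  tracks <- lapply(tracks, function(x)
    if (is.character(x)) extract_cuts(x, "DNase", sizes, label = basename(x))
    else x)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    names(tracks) <- vapply(tracks, `[[`, "", "label")

  files <- list()
  results <- list()

  # Depth matching -----------------------------------------------------
  totals <- vapply(tracks, track_total, numeric(1))
  target_n <- NULL
  if (!is.null(subsample_to)) {
    target_n <- if (identical(subsample_to, "min")) min(totals)
                else as.numeric(subsample_to)
    tracks <- lapply(seq_along(tracks), function(i)
      subsample_track(tracks[[i]], target_n,
                      seed = child_seed(seed, 100L + i)))
    names(tracks) <- names(totals)
  }

  # Per-sample bias model, footprints, site scores ----------------------
  footprints <- list(); scores <- list(); models <- list()
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    model <- fit_bias(tr, genome, peaks, k = k)
    models[[nm]] <- model
    rates <- if (k > 0) bias_position_rates(model, genome) else NULL
    fp <- call_footprints(tr, peaks, model = model, rates = rates,
                          fdr = fdr, width_range = width_range,
                          flank_width = flank_width)
    footprints[[nm]] <- fp
    f <- file.path(out_dir, paste0("footprints_", nm, ".bed"))
    fp_bed <- fp
    if (length(fp_bed)) {
      S4Vectors::mcols(fp_bed) <- S4Vectors::DataFrame(
        name = sprintf("fp_q%.3g", S4Vectors::mcols(fp)$q),
        score = pmin(1000L, as.integer(round(-10 * log10(
          pmax(S4Vectors::mcols(fp)$q, 1e-100))))))
    }
    rtracklayer::export(fp_bed, f, format = "BED")
    files[[paste0("footprints_", nm)]] <- f
    sc <- score_sites(tr, motif_sites, regions = peaks, model = model,
                      rates = rates, flank_width = flank_width)
    scores[[nm]] <- sc
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(sc)),
                     start = GenomicRanges::start(sc) - 1L,
                     end = GenomicRanges::end(sc),
                     tf = S4Vectors::mcols(sc)$tf,
                     strand = as.character(GenomicRanges::strand(sc)),
                     obs_in = S4Vectors::mcols(sc)$obs_in,
                     exp_in = S4Vectors::mcols(sc)$exp_in,
                     z = S4Vectors::mcols(sc)$z,
                     p = S4Vectors::mcols(sc)$p)
    files[[paste0("site_scores_", nm)]] <-
      write_tsv(df, file.path(out_dir, paste0("site_scores_", nm, ".tsv")))
  }
  results$footprints <- footprints
  results$site_scores <- scores
  results$models <- models

  # Footprint counts (depth-matched average) ---------------------------
  fp_counts <- data.frame(sample = names(footprints),
                          n_footprints = vapply(footprints, length, 0L))
  files$footprint_counts <-
    write_tsv(fp_counts, file.path(out_dir, "footprint_counts.tsv"))
  results$footprint_counts <- fp_counts

  # ROC / PR against reference binding ---------------------------------
  if (is.null(reference_peaks) || !length(reference_peaks)) {
    message("no reference binding peaks supplied: ROC/PR stage skipped")
  } else {
    roc_rows <- list()
    for (tf in names(reference_peaks)) {
      rocs <- list()
      for (nm in names(scores)) {
        sc <- scores[[nm]]
        sc <- sc[S4Vectors::mcols(sc)$tf == tf]
        if (!length(sc)) next
        sc <- label_sites(sc, reference_peaks[[tf]])
        rocs[[nm]] <- roc_curve(sc)
        pr <- precision_recall(sc)
        roc_rows[[paste(tf, nm)]] <- data.frame(
          tf = tf, sample = nm, n_pos = rocs[[nm]]$n_pos,
          n_neg = rocs[[nm]]$n_neg, auroc = rocs[[nm]]$auroc,
          average_precision = pr$average_precision,
          delong_p_vs_first = NA_real_)
      }
      if (length(rocs) > 1) {
        first <- names(rocs)[1]
        for (nm in names(rocs)[-1]) {
          cmp <- compare_auroc(rocs[[nm]], rocs[[first]], paired = TRUE)
          roc_rows[[paste(tf, nm)]]$delong_p_vs_first <- cmp$p_value
        }
      }
      results$roc[[tf]] <- rocs
    }
    roc_tab <- do.call(rbind, roc_rows)
    rownames(roc_tab) <- NULL
    files$roc_summary <- write_tsv(roc_tab, file.path(out_dir, "roc_summary.tsv"))
    results$roc_summary <- roc_tab
  }

  # Regulatory networks -------------------------------------------------
  if (is.null(tss)) {
    message("no TSS annotation supplied: network stage skipped")
  } else {
    networks <- list()
    for (nm in names(footprints)) {
      networks[[nm]] <- build_network(footprints[[nm]], motif_sites, tss,
                                      window = network_window, label = nm)
      files[[paste0("edges_", nm)]] <-
        write_tsv(networks[[nm]]$edges,
                  file.path(out_dir, paste0("edges_", nm, ".tsv")))
    }
    results$networks <- networks
    if (length(networks) >= 2) {
      files$jaccard <- file.path(out_dir, "jaccard.tsv")
      results$jaccard <- similarity_matrix(networks, file = files$jaccard)
    }
  }

  manifest <- list(stage = "compare", samples = names(tracks),
                   totals = unname(totals), target_n = target_n,
                   k = k, fdr = fdr, flank_width = flank_width,
                   width_range = width_range, rounds = rounds, seed = seed,
                   network_window = network_window,
                   files = lapply(files, normalizePath))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
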