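# Shared fixture builders: tiny tracks and compact simulations.

# A cut_track built directly from per-strand count vectors.
make_track <- function(plus, minus = NULL, chrom = "chrS1",
                       total_mapped = NULL, assay = "DNase",
                       label = "test") {
  minus <- minus %||% integer(length(plus))
  counts <- setNames(list(list(plus = as.integer(plus),
                               minus = as.integer(minus))), chrom)
  cut_track(counts, total_mapped %||% (sum(plus) + sum(minus)),
            assay = assay, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gr <- function(start, end, chrom = "chrS1", strand = "*", ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand)
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(g)[[nm]] <- extra[[nm]]
  g
}

# A small biased simulation with one TF, used by several suites.
small_sim_config <- function(seed = 1L, n_sites = 100, occupancy = 0.6,
                             protection = 0.9, dynamic = FALSE,
                             genome_length = 5e5, n_peaks = 100,
                             kappa = 0, iota = 0, bias = TRUE,
                             motif = "GGGACTTTCC") {
  simulation_config(
    genome_length = genome_length, n_peaks = n_peaks, peak_width = 400,
    peak_rate = 1.0, background_rate = 0.02,
    bias_table = if (bias) random_bias_table(2, sd = 0.5, seed = 1) else NULL,
    tf_specs = list(tf_spec("TF1", motif, n_sites, occupancy = occupancy,
                            protection = protection, dynamic = dynamic)),
    crosslink_capture = kappa, tn5_interference = iota, seed = seed)
}

# Score one simulated sample at its planted sites and return the labelled
# GRanges (labels = truth bound flags).
scored_labelled_sites <- function(sim, track, k = 2) {
  model <- fit_bias(track, sim$genome, sim$peaks, k = k)
  rates <- if (k > 0) bias_position_rates(model, sim$genome) else NULL
  sc <- score_sites(track, sim$sites, regions = sim$peaks, model = model,
                    rates = rates)
  bound <- sim$sites[S4Vectors::mcols(sim$sites)$bound]
  if (!length(bound)) stop("fixture has no bound sites")
  label_sites(sc, bound)
}

# Minimal network from edge keys like "A>B" (or bare node labels, which
# become self-contained one-token edges).
mknet2 <- function(keys, label = "n") {
  keys <- ifelse(grepl(">", keys), keys, paste0(keys, ">", keys))
  df <- data.frame(regulator = sub(">.*", "", keys),
                   target = sub(".*>", "", keys),
                   stringsAsFactors = FALSE)
  df$n_support <- rep(1L, nrow(df))
  structure(list(edges = df, evidence = NULL, label = label),
            class = "crossfoot_network")
}
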