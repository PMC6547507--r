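# Synthetic-data generator: placement contracts, determinism, and the
# closed-form count model.

test_that("degenerate configurations produce the promised empty outputs", {
  cfg <- simulation_config(genome_length = 1e4, n_peaks = 0, seed = 3)
  sim <- simulate_genome(cfg)
  expect_length(sim$peaks, 0)
  expect_length(sim$sites, 0)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(length(sim$genome[[1]]), 1e4)
})

test_that("planted sites are conserved, in-peak, and occupancy-flagged", {
  cfg <- simulation_config(genome_length = 1e5, n_peaks = 30,
    tf_specs = list(tf_spec("TFA", "GGGACTTTCC", 50, occupancy = 1)),
    seed = 5)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth), 50)
  expect_true(all(IRanges::overlapsAny(sim$sites, sim$peaks,
                                       type = "within")))
  expect_true(all(sim$truth$bound))
  # the motif (or its reverse complement) is embedded verbatim
  g <- sim$genome[[1]]
  for (i in seq_len(5)) {
    s <- as.character(Biostrings::subseq(g, sim$truth$start[i] + 1,
                                         sim$truth$end[i]))
    expected <- if (sim$truth$strand[i] == "-")
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString("GGGACTTTCC")))
    else "GGGACTTTCC"
    expect_identical(s, expected)
  }

  cfg0 <- simulation_config(genome_length = 1e5, n_peaks = 30,
    tf_specs = list(tf_spec("TFA", "GGGACTTTCC", 50, occupancy = 0)),
    seed = 5)
  expect_false(any(simulate_genome(cfg0)$truth$bound))
})

test_that("all emitted intervals satisfy 0 <= start < end <= genome_length", {
  cfg <- small_sim_config(seed = 9, genome_length = 2e5, n_peaks = 40,
                          n_sites = 60)
  sim <- simulate_genome(cfg)
  for (x in list(sim$peaks, sim$sites)) {
    s0 <- GenomicRanges::start(x) - 1L
    e0 <- GenomicRanges::end(x)
    expect_true(all(s0 >= 0 & s0 < e0 & e0 <= cfg$genome_length))
  }
})

test_that("identical configurations reproduce byte-identical outputs", {
  cfg <- small_sim_config(seed = 11, genome_length = 1e5, n_peaks = 20,
                          n_sites = 30)
  a <- simulate_genome(cfg); b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome[[1]]), as.character(b$genome[[1]]))
  expect_identical(a$truth, b$truth)
  ta <- simulate_cuts(a, label = "x"); tb <- simulate_cuts(b, label = "x")
  expect_identical(ta$counts, tb$counts)
})

test_that("impossible site placement fails with an error naming the TF", {
  cfg <- simulation_config(genome_length = 5e3, n_peaks = 1,
    peak_width = 400,
    tf_specs = list(tf_spec("CRAMMED", "GGGACTTTCCAGGAA", 50)), seed = 1)
  expect_error(simulate_genome(cfg, max_attempts_per_site = 20), "CRAMMED")
})

test_that("full protection silences bound sites and zero background is zero", {
  cfg <- simulation_config(genome_length = 1e5, n_peaks = 20,
    peak_rate = 2, background_rate = 0,
    tf_specs = list(tf_spec("TFA", "GGGACTTTCC", 40, occupancy = 1,
                            protection = 1)), seed = 13)
  sim <- simulate_genome(cfg)
  tr <- simulate_cuts(sim)
  y <- track_window(tr, "chrS1")
  in_site <- unlist(mapply(function(s, e) s:e,
                           GenomicRanges::start(sim$sites),
                           GenomicRanges::end(sim$sites)))
  expect_true(all(y[in_site] == 0))
  in_peak <- unlist(mapply(function(s, e) s:e,
                           GenomicRanges::start(sim$peaks),
                           GenomicRanges::end(sim$peaks)))
  expect_true(all(y[-in_peak] == 0))     # lambda_bg = 0
})

test_that("simulated counts match the closed-form mean within 3 SE", {
  # no planted sites: mean over peak bases is lambda_peak * mean bias
  cfg <- simulation_config(genome_length = 1e6, n_peaks = 300,
    peak_width = 400, peak_rate = 1, background_rate = 0.02,
    bias_table = random_bias_table(2, sd = 0.5, seed = 2), seed = 17)
  sim <- simulate_genome(cfg)
  tr <- simulate_cuts(sim)
  ki <- crossfoot:::kmer_index(as.character(sim$genome[[1]]), 2)
  tab <- unname(cfg$bias_table)
  bp <- ifelse(is.na(ki$plus), 1, tab[ki$plus + 1L])
  bm <- ifelse(is.na(ki$minus), 1, tab[ki$minus + 1L])
  m <- rep(cfg$background_rate, cfg$genome_length)
  in_peak <- unlist(mapply(function(s, e) s:e,
                           GenomicRanges::start(sim$peaks),
                           GenomicRanges::end(sim$peaks)))
  m[in_peak] <- cfg$peak_rate
  m <- m * (bp + bm) / 2
  y <- track_window(tr, "chrS1")
  expect_gt(length(in_peak), 1e5)
  obs <- sum(y[in_peak]); expctd <- sum(m[in_peak])
  expect_lt(abs(obs - expctd), 3 * sqrt(expctd))
})

test_that("raising cross-link capture deepens dynamic-TF footprints", {
  cfg <- small_sim_config(seed = 19, n_sites = 300, occupancy = 1,
                          dynamic = TRUE)
  sim <- simulate_genome(cfg)
  in_site_total <- function(kap) {
    tr <- simulate_cuts(sim, kappa = kap)
    y <- track_window(tr, "chrS1")
    idx <- unlist(mapply(function(s, e) s:e,
                         GenomicRanges::start(sim$sites),
                         GenomicRanges::end(sim$sites)))
    sum(y[idx])
  }
  tot <- vapply(c(0, 0.5, 0.9), in_site_total, numeric(1))
  expect_true(all(diff(tot) < 0))
})

test_that("TSS annotation is deterministic and validates TF names", {
  specs <- lapply(1:6, function(i)
    tf_spec(paste0("TF", i), "GGGACTTTCC", 10))
  a <- emit_annotations(specs, 1e5, seed = 3, n_decoys = 0)
  expect_length(a$tss, 6)
  expect_identical(S4Vectors::mcols(a$tss)$gene,
                   paste0("TF", 1:6))
  b <- emit_annotations(specs, 1e5, seed = 3, n_decoys = 0)
  expect_identical(GenomicRanges::start(a$tss), GenomicRanges::start(b$tss))
  d <- emit_annotations(specs, 1e5, seed = 3, n_decoys = 4)
  expect_length(d$tss, 10)
  expect_error(emit_annotations(c(specs, specs[1]), 1e5), "duplicate")
})
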