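# Binomial depletion testing and FDR-controlled footprint calling.

test_that("depletion p-values equal exhaustive binomial enumeration", {
  enum_p <- function(obs, n, p0)
    sum(choose(n, 0:obs) * p0^(0:obs) * (1 - p0)^(n - (0:obs)))
  for (p0 in c(0.1, 0.3, 0.5, 0.7)) {
    for (n in 0:20) {
      for (obs in 0:n) {
        got <- test_depletion(obs, n - obs, p0, 1 - p0)
        expect_equal(got$p, enum_p(obs, n, p0), tolerance = 1e-12)
      }
    }
  }
})

test_that("depletion statistic centres at the null and handles extremes", {
  # obs_in exactly at the null expectation: z = 0, p >= 0.5
  r <- test_depletion(5, 5, 1, 1)
  expect_equal(r$z, 0)
  expect_gte(r$p, 0.5)
  # complete protection with 10 flank cuts at p0 = 0.5
  r2 <- test_depletion(0, 10, 1, 1)
  expect_equal(r2$p, 2^-10)
  expect_equal(r2$z, -sqrt(10), tolerance = 1e-12)
  # n = 0 is defined as no evidence
  r3 <- test_depletion(0, 0, 1, 1)
  expect_equal(r3$p, 1)
  expect_equal(r3$z, 0)
  expect_error(test_depletion(-1, 5, 1, 1), "non-negative")
  expect_error(test_depletion(1, 5, 0, 1), "positive")
})

test_that("uniform tracks produce no footprint calls", {
  tr <- make_track(rep(2L, 600), rep(2L, 600))
  fp <- call_footprints(tr, gr(1, 600))
  expect_length(fp, 0)
})

test_that("a deeply protected site is called and annotated coherently", {
  cfg <- small_sim_config(seed = 41, n_sites = 50, occupancy = 1,
                          protection = 1, motif = "GGGACTTTCCAGG",
                          genome_length = 2e5, n_peaks = 40)
  sim <- simulate_genome(cfg)
  tr <- simulate_cuts(sim)
  model <- fit_bias(tr, sim$genome, sim$peaks, k = 2)
  fp <- call_footprints(tr, sim$peaks, model = model, genome = sim$genome)
  expect_gt(length(fp), 25)
  expect_gt(mean(IRanges::overlapsAny(sim$sites, fp)), 0.9)
  w <- GenomicRanges::width(fp)
  expect_true(all(w >= 6 & w <= 40))
  expect_true(all(fp$q >= fp$p))
  expect_true(all(fp$z < 0))
  expect_true(all(IRanges::overlapsAny(fp, sim$peaks, type = "within")))
})

test_that("footprint calls are translation invariant across chromosomes", {
  set.seed(71)
  y <- as.integer(rpois(500, 2)); y[200:215] <- 0L
  counts <- list(chrA = list(plus = y, minus = integer(500)),
                 chrB = list(plus = y, minus = integer(500)))
  tr <- cut_track(counts, sum(as.numeric(y)) * 2, "DNase", "two")
  regions <- GenomicRanges::GRanges(c("chrA", "chrB"),
                                    IRanges::IRanges(1, 500))
  fp <- call_footprints(tr, regions)
  a <- fp[GenomeInfoDb::seqnames(fp) == "chrA"]
  b <- fp[GenomeInfoDb::seqnames(fp) == "chrB"]
  expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_equal(a$p, b$p)
})

test_that("lowering the FDR threshold never increases the call count", {
  cfg <- small_sim_config(seed = 43, n_sites = 60, occupancy = 1,
                          protection = 0.9, genome_length = 2e5,
                          n_peaks = 40)
  sim <- simulate_genome(cfg)
  tr <- simulate_cuts(sim)
  counts <- vapply(c(0.05, 0.01, 0.001), function(f)
    length(call_footprints(tr, sim$peaks, fdr = f)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("calls depend only on expected-rate ratios, not their scale", {
  cfg <- small_sim_config(seed = 47, n_sites = 40, occupancy = 1,
                          protection = 1, genome_length = 1e5, n_peaks = 20)
  sim <- simulate_genome(cfg)
  tr <- simulate_cuts(sim)
  model <- fit_bias(tr, sim$genome, sim$peaks, k = 2)
  rates <- bias_position_rates(model, sim$genome)
  scaled <- rates
  scaled$chrS1 <- scaled$chrS1 * 7.3
  a <- call_footprints(tr, sim$peaks, model = model, rates = rates)
  b <- call_footprints(tr, sim$peaks, model = model, rates = scaled)
  expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("regions too short for the window geometry are skipped", {
  tr <- make_track(rep(1L, 300))
  fp <- call_footprints(tr, gr(c(1, 150), c(100, 300)))
  expect_equal(attr(fp, "skipped"), 1L)
})

test_that("subsampled footprint counting composes the stages faithfully", {
  cfg <- small_sim_config(seed = 53, n_sites = 40, occupancy = 1,
                          protection = 1, genome_length = 1e5, n_peaks = 20)
  sim <- simulate_genome(cfg)
  tr <- simulate_cuts(sim)
  direct <- length(call_footprints(tr, sim$peaks))
  tab <- count_footprints_subsampled(list(s1 = tr), track_total(tr),
                                     sim$peaks, rounds = 1L)
  expect_equal(tab$round1, direct)
  expect_equal(tab$mean, direct)
  zero <- make_track(integer(1000))
  tab0 <- count_footprints_subsampled(list(z = zero), 0, gr(1, 1000),
                                      rounds = 2L)
  expect_equal(tab0$mean, 0)
})

test_that("cross-link capture increases depth-matched footprint counts", {
  cfg <- small_sim_config(seed = 59, n_sites = 200, occupancy = 1,
                          protection = 0.9, dynamic = TRUE)
  sim <- simulate_genome(cfg)
  native <- simulate_cuts(sim, kappa = 0, label = "native", stream = 0L)
  xl <- simulate_cuts(sim, kappa = 1, label = "xl", stream = 1L)
  target <- min(track_total(native), track_total(xl))
  tab <- count_footprints_subsampled(list(native = native, xl = xl),
                                     target, sim$peaks, rounds = 2L)
  expect_gte(tab$mean[tab$sample == "xl"],
             tab$mean[tab$sample == "native"])
})
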