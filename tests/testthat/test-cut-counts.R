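# Cut extraction, normalisation, and subsampling.

test_that("DNase cuts land on the 5' end and ATAC cuts are Tn5-shifted", {
  sizes <- c(chrS1 = 1000L)
  reads <- gr(c(100, 300), c(135, 335), strand = c("+", "-"))
  dn <- extract_cuts(reads, "DNase", sizes)
  expect_equal(dn$counts$chrS1$plus[100], 1)
  expect_equal(dn$counts$chrS1$minus[335], 1)
  expect_equal(track_total(dn), 2)
  expect_equal(dn$total_mapped, 2)

  at <- extract_cuts(reads, "ATAC", sizes)
  expect_equal(at$counts$chrS1$plus[104], 1)    # +4 on the plus strand
  expect_equal(at$counts$chrS1$minus[330], 1)   # -5 on the minus strand
})

test_that("empty input gives an all-zero track with total_mapped 0", {
  tr <- extract_cuts(GenomicRanges::GRanges(), "DNase", c(chrS1 = 100L))
  expect_equal(track_total(tr), 0)
  expect_equal(tr$total_mapped, 0)
})

test_that("unknown chromosomes are skipped and out-of-bounds cuts clipped", {
  sizes <- c(chrS1 = 200L)
  reads <- gr(c(5, 198, 10), c(40, 200, 45),
              chrom = c("chrS1", "chrS1", "chrUn"), strand = "+")
  expect_warning(tr <- extract_cuts(reads, "ATAC", sizes), "unknown")
  expect_equal(track_total(tr), 2)
  expect_equal(tr$counts$chrS1$plus[200], 1)    # 198 + 4 clipped to 200
  expect_equal(attr(tr, "clipped"), 1)
})

test_that("extraction conserves the number of retained reads", {
  cfg <- small_sim_config(seed = 23, genome_length = 1e5, n_peaks = 20,
                          n_sites = 20)
  sim <- simulate_genome(cfg)
  res <- simulate_cuts(sim, fragments = TRUE)
  sizes <- setNames(cfg$genome_length, cfg$chrom)
  tr <- extract_cuts(res$fragments, "DNase", sizes)
  expect_equal(track_total(tr), length(res$fragments))
  expect_identical(tr$counts$chrS1$plus, res$track$counts$chrS1$plus)
  expect_identical(tr$counts$chrS1$minus, res$track$counts$chrS1$minus)
})

test_that("BED round-trip through rtracklayer preserves cut positions", {
  reads <- gr(c(10, 50), c(30, 70), strand = c("+", "-"))
  f <- tempfile(fileext = ".bed")
  rtracklayer::export(reads, f, format = "BED")
  tr <- extract_cuts(f, "DNase", c(chrS1 = 100L))
  expect_equal(tr$counts$chrS1$plus[10], 1)
  expect_equal(tr$counts$chrS1$minus[70], 1)
})

test_that("density normalisation scales to 10 million mapped reads", {
  tr <- make_track(c(rep(2L, 10), rep(0L, 90)), total_mapped = 1e7)
  d <- normalize_density(tr, window = 10)
  expect_equal(d$score[1], 20)                  # scale factor exactly 1
  tr2 <- make_track(c(rep(0L, 10), 8L, rep(0L, 89)), total_mapped = 2e7)
  expect_equal(normalize_density(tr2, window = 10)$score[2], 4)
  zero <- make_track(integer(50), total_mapped = 10)
  expect_true(all(normalize_density(zero, window = 10)$score == 0))
  none <- make_track(integer(50), total_mapped = 0)
  expect_error(normalize_density(none), "total_mapped")
})

test_that("subsampling hits the exact target and degenerate cases", {
  tr <- make_track(c(3L, 0L, 2L, 5L), c(1L, 1L, 0L, 0L))
  expect_identical(subsample_track(tr, 12, seed = 1)$counts, tr$counts)
  s0 <- subsample_track(tr, 0, seed = 1)
  expect_equal(track_total(s0), 0)
  s5 <- subsample_track(tr, 5, seed = 42)
  expect_equal(track_total(s5), 5)
  expect_true(all(s5$counts$chrS1$plus <= tr$counts$chrS1$plus))
  expect_true(all(s5$counts$chrS1$minus <= tr$counts$chrS1$minus))
  expect_error(subsample_track(tr, 13, seed = 1), "13.*12")
  expect_identical(subsample_track(tr, 5, seed = 7)$counts,
                   subsample_track(tr, 5, seed = 7)$counts)
})

test_that("subsampled interval counts follow the hypergeometric law", {
  # 12 events: 5 in the first two bases ("interval"), 7 elsewhere;
  # exact pmf of the interval count from brute-force subset enumeration.
  plus <- c(3L, 2L, 4L, 3L)
  tr <- make_track(plus)
  target <- 6L
  in_interval <- c(rep(TRUE, 5), rep(FALSE, 7))   # event-level membership
  subsets <- utils::combn(12, target)
  exact <- tabulate(colSums(matrix(in_interval[subsets], nrow = target)) + 1L,
                    nbins = 6) / ncol(subsets)
  expect_equal(exact, stats::dhyper(0:5, 5, 7, target))  # oracle sanity
  draws <- vapply(1:3000, function(s) {
    ss <- subsample_track(tr, target, seed = s)
    sum(ss$counts$chrS1$plus[1:2])
  }, numeric(1))
  emp <- tabulate(draws + 1L, nbins = 6) / length(draws)
  se <- sqrt(exact * (1 - exact) / length(draws))
  expect_true(all(abs(emp - exact) <= 3.5 * se + 1e-12))
})

test_that("mean retained counts scale by target_n / total", {
  cfg <- small_sim_config(seed = 29, genome_length = 1e5, n_peaks = 20,
                          n_sites = 0, bias = FALSE)
  cfg$tf_specs <- list()
  sim <- simulate_genome(cfg)
  tr <- simulate_cuts(sim)
  total <- track_total(tr)
  target <- round(total / 2)
  peak1 <- sim$peaks[1]
  idx <- GenomicRanges::start(peak1):GenomicRanges::end(peak1)
  orig <- sum(track_window(tr, "chrS1")[idx])
  vals <- vapply(1:5, function(s) {
    ss <- subsample_track(tr, target, seed = s)
    sum(track_window(ss, "chrS1")[idx])
  }, numeric(1))
  expected <- orig * target / total
  se <- sqrt(expected * (1 - target / total))
  expect_lt(abs(mean(vals) - expected), 3 * se / sqrt(5) + 1e-9)
})

test_that("repeat_subsample reports per-round values and their mean", {
  tr <- make_track(rep(2L, 50))
  rs <- repeat_subsample(tr, 40, track_total, rounds = 5)
  expect_length(rs$values, 5)
  expect_equal(rs$mean, 40)                      # constant statistic
  a <- repeat_subsample(tr, 40, track_total, rounds = 3, seeds = c(4, 4, 4))
  b <- repeat_subsample(tr, 40, track_total, rounds = 3, seeds = c(4, 4, 4))
  expect_identical(a, b)
  expect_error(repeat_subsample(tr, 40, track_total, rounds = 0), "rounds")
})

test_that("track invariants are enforced at construction", {
  expect_error(make_track(c(-1L, 2L)), "non-negative")
  expect_error(cut_track(list(chrS1 = list(plus = 1:3, minus = 1:2)), 10),
               "equal-length")
  expect_error(make_track(c(5L, 5L), total_mapped = 3), "total_mapped")
})

test_that("BAM input is MAPQ-filtered and duplicate dropping works", {
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chrS1\tLN:1000",
           "r1\t0\tchrS1\t100\t30\t20M\t*\t0\t0\t*\t*",
           "r2\t16\tchrS1\t200\t30\t20M\t*\t0\t0\t*\t*",
           "r3\t0\tchrS1\t100\t30\t20M\t*\t0\t0\t*\t*",   # duplicate of r1
           "r4\t0\tchrS1\t300\t2\t20M\t*\t0\t0\t*\t*")    # low MAPQ
  sf <- tempfile(fileext = ".sam")
  writeLines(sam, sf)
  bf <- Rsamtools::asBam(sf, tempfile(), overwrite = TRUE,
                         indexDestination = FALSE)
  tr <- extract_cuts(bf, "DNase", c(chrS1 = 1000L))
  expect_equal(track_total(tr), 3)                 # low-MAPQ read excluded
  expect_equal(tr$counts$chrS1$plus[100], 2)
  expect_equal(tr$counts$chrS1$minus[219], 1)      # 5' end of minus read
  td <- extract_cuts(bf, "DNase", c(chrS1 = 1000L), drop_duplicates = TRUE)
  expect_equal(track_total(td), 2)
  expect_equal(td$counts$chrS1$plus[100], 1)
})
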