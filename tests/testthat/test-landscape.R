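ci1 <- data.frame(chrom = "A01", length = 10e6)

co_at <- function(mids, chrom = "A01") {
  data.frame(line = rep("L1", length(mids)), chrom = rep(chrom, length(mids)),
             left_bp = mids - 1,
             right_bp = mids + 1, midpoint = mids,
             tract_length = rep(2, length(mids)),
             from = rep("P1", length(mids)), to = rep("P2", length(mids)),
             stringsAsFactors = FALSE)
}

test_that("window frequencies follow the 100 x (count/n) / Mb definition", {
  # 35 midpoints in the first 3-Mb window of a 292-line population
  cos <- co_at(seq(1e5, 2.9e6, length.out = 35))
  p <- window_profile(cos, ci1, n_lines = 292)
  expect_equal(p$n_co[1], 35)
  expect_equal(p$freq[1], 100 * (35 / 292) / 3, tolerance = 1e-12)
  expect_equal(round(p$freq[1], 3), 3.995)

  # no COs -> all zero
  p0 <- window_profile(co_at(numeric(0)), ci1, 292)
  expect_true(all(p0$freq == 0))

  # terminal partial window uses its true span
  cos2 <- co_at(9.95e6)
  p2 <- window_profile(cos2, ci1, 292)
  last <- nrow(p2)
  expect_equal(p2$end[last] - p2$start[last], 1e6)  # 10 Mb chrom, start 9e6+1
  expect_equal(p2$freq[last], 100 * (1 / 292) / 1)
  expect_error(window_profile(cos2, ci1, 292, window = 0), "window")
})

test_that("window counts are half-open and tile back to the event total", {
  set.seed(5)
  cos <- co_at(sort(sample.int(10e6, 200)))
  # non-overlapping tiling: step = window
  p <- window_profile(cos, ci1, 10, window = 3e6, step = 3e6)
  expect_equal(sum(p$n_co), 200)
  # doubling n_lines halves every frequency
  p1 <- window_profile(cos, ci1, 10)
  p2 <- window_profile(cos, ci1, 20)
  expect_equal(p1$freq, 2 * p2$freq)
  # genome-wide identity: count-weighted mean of the tiling equals the total
  mb <- (p$end - p$start) / 1e6
  expect_equal(sum(p$freq * mb) / sum(mb), 100 * (200 / 10) / 10)
})

test_that("hot regions merge overlapping above-threshold windows maximally", {
  ci20 <- data.frame(chrom = "A01", length = 20e6)
  cos <- co_at(c(seq(1.1e6, 2.9e6, by = 1e4),      # hot block ~1-3 Mb
                 seq(15.05e6, 17.9e6, by = 1e4)))  # hot block ~15-18 Mb
  p <- window_profile(cos, ci20, n_lines = 10)
  hot <- detect_hot_regions(p, threshold = 2)
  expect_equal(nrow(hot), 2)
  expect_true(all(hot$peak_freq > 2))
  expect_true(hot$start[1] < 1.1e6 && hot$end[1] > 2.9e6)
  # all-cold profile -> empty
  expect_equal(nrow(detect_hot_regions(p, threshold = 1e6)), 0)
  # two windows sharing 2 Mb merge into one region
  p3 <- window_profile(co_at(seq(1.5e6, 4.5e6, by = 5e3)), ci1, 5)
  h3 <- detect_hot_regions(p3, 2)
  expect_equal(nrow(h3), 1)
  # above-threshold window count is reported alongside
  expect_true(attr(hot, "n_hot_windows") >= nrow(hot))
})

test_that("hot-region boundaries are stable to step refinement", {
  set.seed(7)
  cos <- co_at(c(runif(400, 1e6, 3.5e6), runif(30, 4e6, 10e6)))
  h_coarse <- detect_hot_regions(window_profile(cos, ci1, 20,
                                                window = 3e6, step = 3e6), 2)
  h_fine <- detect_hot_regions(window_profile(cos, ci1, 20,
                                              window = 3e6, step = 1e6), 2)
  expect_equal(nrow(h_coarse), nrow(h_fine))
  expect_lte(abs(h_coarse$start[1] - h_fine$start[1]), 3e6)
  expect_lte(abs(h_coarse$end[1] - h_fine$end[1]), 3e6)
})

test_that("chromosome summaries and the length correlation match closed forms", {
  ci <- data.frame(chrom = c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9)),
                   length = seq(20e6, 56e6, by = 2e6))
  # hand-placed counts
  set.seed(9)
  counts <- rpois(19, 40)
  cos <- do.call(rbind, lapply(1:19, function(k)
    co_at(rep(1e6, counts[k]), chrom = ci$chrom[k])))
  s <- chromosome_summaries(cos, ci, n_lines = 100)
  expect_equal(s$chromosomes$n_co, counts)
  # textbook Pearson formula, independent of stats::cor
  x <- counts; y <- ci$length
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(s$length_correlation, r_hand, tolerance = 1e-12)
  expect_equal(s$genome$n_co, sum(counts))
  expect_equal(s$genome$freq, 100 * sum(counts) / 100 / (sum(ci$length) / 1e6))

  # counts proportional to length -> r exactly 1
  cos_p <- do.call(rbind, lapply(1:19, function(k)
    co_at(rep(1e6, round(ci$length[k] / 1e6)), chrom = ci$chrom[k])))
  expect_equal(chromosome_summaries(cos_p, ci, 10)$length_correlation, 1)
  # equal counts -> r = 0
  cos_e <- do.call(rbind, lapply(1:19, function(k)
    co_at(rep(1e6, 7), chrom = ci$chrom[k])))
  expect_equal(chromosome_summaries(cos_e, ci, 10)$length_correlation, 0,
               tolerance = 1e-12)
  # < 3 chromosomes: undefined
  expect_true(is.na(chromosome_summaries(co_at(1e6), ci1, 10)$length_correlation))
})

test_that("windowed profiles converge to the generating intensity", {
  L <- 6e7
  gm <- piecewise_genome(c(0, 1e7, 3e7, 4e7, L), c(5, 0.2, 5, 0.2))
  n <- 150
  pop <- simulate_population(gm, sim_config(n_lines = n, missing = 0, het = 0,
                                            allele_flip_error = 0, seed = 21))
  co <- call_crossovers(call_bins(pop$geno))
  p <- window_profile(co, pop$geno$chrom_info, n, window = 3e6, step = 3e6)
  lam <- vapply(seq_len(nrow(p)), function(i)
    (meiomap:::genetic_cum(gm, "A01", p$end[i] - 1) -
       meiomap:::genetic_cum(gm, "A01", p$start[i] - 1)) /
      ((p$end[i] - p$start[i]) / 1e6), numeric(1))
  mb <- (p$end - p$start) / 1e6
  se <- 100 * sqrt(lam * mb / 100 / n) / mb
  expect_gte(mean(abs(p$freq - lam) <= 3 * se), 0.95)
})
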