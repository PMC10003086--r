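test_that("cleaning flips short genotype islands to MISSING and strips HET", {
  g1 <- toy_geno(rbind(c("A", "A", "B", "A", "A")))
  c1 <- clean_line_calls(g1, min_run = 2)
  expect_identical(unname(c1$calls[1, ]), c("P1", "P1", "MISSING", "P1", "P1"))

  g2 <- toy_geno(rbind(c("A", "A", "B", "B", "A")))
  c2 <- clean_line_calls(g2, min_run = 2)   # run of 2 >= min_run: untouched
  expect_identical(c2$calls, g2$calls)

  g3 <- toy_geno(rbind(c("A", "H", "A", "B", "B")))
  c3 <- clean_line_calls(g3, min_run = 2)
  expect_identical(unname(c3$calls[1, 2]), "MISSING")
  expect_identical(unname(c3$calls[1, 4:5]), c("P2", "P2"))
  expect_error(clean_line_calls(g1, min_run = 0), "min_run")
})

test_that("cleaning removes injected flip errors but not true double switches", {
  gm <- flat_genome(4e7, 2.5)
  cfg <- sim_config(n_lines = 100, missing = 0, het = 0,
                    allele_flip_error = 0.005, seed = 9)
  pop <- simulate_population(gm, cfg)
  cfg0 <- sim_config(n_lines = 100, missing = 0, het = 0,
                     allele_flip_error = 0, seed = 9)
  clean0 <- simulate_population(gm, cfg0)$geno   # same gametes, no noise
  flipped <- which(pop$geno$calls != clean0$calls)
  cl <- clean_line_calls(pop$geno, min_run = 2)
  # >= 95% of injected singleton errors are masked
  expect_gte(mean(cl$calls[flipped] == "MISSING"), 0.95)
  # and no informative call of the clean matrix was altered to the other parent
  still <- cl$calls[-flipped]
  expect_true(all(still == clean0$calls[-flipped] | still == "MISSING"))
})

test_that("bin boundaries are the union of per-line switch junctions", {
  # line1 switches after marker 3, line2 after marker 5 -> 3 bins
  g <- toy_geno(rbind(c("A", "A", "A", "B", "B", "B"),
                      c("A", "A", "A", "A", "A", "B")))
  b <- call_bins(g)
  expect_equal(nrow(b$bins), 3)
  expect_equal(b$bins$first_marker, c(1, 4, 6))
  expect_equal(b$bins$last_marker, c(3, 5, 6))
  expect_identical(unname(b$geno[1, ]), c("P1", "P2", "P2"))
  expect_identical(unname(b$geno[2, ]), c("P1", "P1", "P2"))

  # no switches anywhere -> one bin per chromosome
  g1 <- toy_geno(matrix("A", 3, 8))
  expect_equal(nrow(call_bins(g1)$bins), 1)
})

test_that("ambiguous markers are assigned to the closest bin by bp distance", {
  # switch between informative markers at 1000 and 9000; missing markers at
  # 2000 (closer to left) and 8500 (closer to right)
  g <- toy_geno(rbind(c("A", "-", "-", "B", "B")),
                pos = c(1000, 2000, 8500, 9000, 9500))
  b <- call_bins(g)
  expect_equal(nrow(b$bins), 2)
  expect_equal(b$bins$last_marker[1], 2)   # marker at 2000 goes left
  expect_equal(b$bins$first_marker[2], 3)  # marker at 8500 goes right
})

test_that("crossover events carry flanking informative markers and skip missing bins", {
  g <- toy_geno(rbind(c("A", "A", "-", "-", "B", "B")),
                pos = c(1, 10, 20, 30, 40, 50))
  co <- call_crossovers(call_bins(g))
  expect_equal(nrow(co), 1)
  expect_equal(co$left_bp, 10)
  expect_equal(co$right_bp, 40)
  expect_equal(co$midpoint, 25)
  expect_equal(co$tract_length, 30)
  expect_identical(co$from, "P1")
  expect_identical(co$to, "P2")
})

test_that("bin/CO calling equals the brute-force per-line caller on random matrices", {
  for (s in 1:200) {
    g <- random_matrix(n_lines = sample(2:10, 1), n_markers = sample(5:50, 1),
                       p_missing = runif(1, 0, 0.3), seed = 1000 + s)
    co <- call_crossovers(call_bins(g))
    bf <- brute_force_cos(g)
    co <- co[order(co$line, co$chrom, co$left_bp), ]
    expect_equal(nrow(co), nrow(bf))
    expect_equal(co$left_bp, bf$left_bp)
    expect_equal(co$right_bp, bf$right_bp)
    expect_identical(co$from, bf$from)
  }
})

test_that("number of bins is one plus the number of distinct switch junctions", {
  for (s in 1:50) {
    g <- random_matrix(n_lines = 6, n_markers = 30, p_missing = 0,
                       seed = 2000 + s)
    b <- call_bins(g)
    bf <- brute_force_cos(g)
    expect_equal(nrow(b$bins), 1 + length(unique(bf$left_bp)))
  }
})

test_that("zero-noise simulated populations recover per-line crossover counts exactly", {
  gm <- default_genome_model()
  cfg <- sim_config(n_lines = 40, missing = 0, het = 0,
                    allele_flip_error = 0, seed = 11)
  pop <- simulate_population(gm, cfg)
  # no noise, so no cleaning: min_run masking would hide true 1-marker islands
  co <- call_crossovers(call_bins(pop$geno))
  # truth restricted to marker-observable COs: inside the marker span and not
  # cancelled by a second CO in the same inter-marker gap
  tr <- pop$truth$co
  obs <- 0L
  for (ch in unique(tr$chrom)) {
    pos <- pop$geno$map$pos[pop$geno$map$chrom == ch]
    t2 <- tr[tr$chrom == ch, ]
    gap <- findInterval(t2$pos - 0.5, pos)  # a CO exactly on a marker switches that marker
    inside <- gap >= 1 & gap < length(pos)
    # parity per (line, gap): an odd number of COs in a gap is one switch
    k <- paste(t2$line, gap)[inside]
    obs <- obs + sum(table(k) %% 2 == 1)
  }
  expect_equal(nrow(co), obs)
  # every detected interval brackets a true CO
  ok <- mapply(function(l, ch, lo, hi)
    any(tr$line == l & tr$chrom == ch & tr$pos >= lo & tr$pos <= hi),
    co$line, co$chrom, co$left_bp, co$right_bp)
  expect_true(all(ok))
})

test_that("missing calls never create unsupported crossovers", {
  for (s in 1:20) {
    g <- random_matrix(8, 40, p_missing = 0, seed = 3000 + s)
    co0 <- call_crossovers(call_bins(g))
    gm <- g
    set.seed(s)
    kill <- sample(length(gm$calls), length(gm$calls) %/% 5)
    gm$calls[kill] <- "MISSING"
    com <- call_crossovers(call_bins(gm))
    # each CO in the degraded matrix is supported by two opposite informative
    # calls of that line at its interval ends
    if (nrow(com)) {
      sup <- mapply(function(l, lo, hi, f, t) {
        i <- match(l, rownames(gm$calls))
        ml <- match(lo, gm$map$pos); mr <- match(hi, gm$map$pos)
        gm$calls[i, ml] == f && gm$calls[i, mr] == t
      }, com$line, com$left_bp, com$right_bp, com$from, com$to)
      expect_true(all(sup))
    }
    expect_lte(nrow(com), nrow(co0))
  }
})

test_that("line summaries compute replacement rate from physical bin spans", {
  # 3 bins of 10, 20, 70 Mb; genotypes P2, P1, P2 on P1 background -> 0.8
  g <- toy_geno(rbind(c("B", "B", "A", "A", "B", "B"),
                      c("A", "A", "B", "B", "A", "A")),  # forces boundaries
                pos = c(1, 10e6 - 1, 10e6 + 1, 30e6 - 1, 30e6 + 1, 100e6),
                chrom_len = 100e6)
  b <- call_bins(g)
  expect_equal(nrow(b$bins), 3)
  expect_equal(b$bins$phys_end - b$bins$phys_start + 1, c(10e6, 20e6, 70e6))
  co <- call_crossovers(b)
  s <- summarize_lines(b, co, background_parent = "P1")
  expect_equal(s$replacement_rate[1], 0.8)
  expect_equal(s$replacement_rate[2], 0.2)
  expect_equal(s$n_co, c(2L, 2L))

  # degenerate rates
  gg <- toy_geno(rbind(rep("A", 4), rep("B", 4)), chrom_len = 4000)
  bb <- call_bins(gg)
  ss <- summarize_lines(bb, call_crossovers(bb), "P1")
  expect_equal(ss$replacement_rate, c(0, 1))
})
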