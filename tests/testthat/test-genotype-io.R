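test_that("reading translates the input alphabet and sorts markers by map position", {
  map <- data.frame(marker_id = c("m1", "m2", "m3", "m4"),
                    chrom = "A01", pos = c(100, 200, 300, 400))
  mp <- withr::local_tempfile(fileext = ".tsv")
  write.table(map, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  # matrix columns deliberately out of map order
  gt <- data.frame(line = c("L1", "L2", "L3"),
                   m3 = c("A", "B", "H"), m1 = c("A", "A", "-"),
                   m4 = c("B", "B", "A"), m2 = c("H", "-", "B"),
                   stringsAsFactors = FALSE)
  xp <- withr::local_tempfile(fileext = ".tsv")
  write.table(gt, xp, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- read_genotypes(mp, xp)
  expect_identical(colnames(g$calls), c("m1", "m2", "m3", "m4"))
  expect_identical(unname(g$calls["L1", ]), c("P1", "HET", "P1", "P2"))
  expect_identical(unname(g$calls["L3", ]), c("MISSING", "P2", "HET", "P1"))

  # round trip is bit-for-bit on the call matrix
  mp2 <- withr::local_tempfile(fileext = ".tsv")
  xp2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, mp2, xp2)
  g2 <- read_genotypes(mp2, xp2)
  expect_identical(g2$calls, g$calls)
  expect_identical(g2$map, g$map)
})

test_that("read errors name the offending marker, call, or duplicate", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  xp <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(marker_id = c("m1", "m2"), chrom = "A01",
                         pos = c(1, 2)), mp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(line = "L1", m1 = "A", mX = "B"), xp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(mp, xp), "mX")

  write.table(data.frame(line = "L1", m1 = "A", m2 = "Z"), xp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(mp, xp), "unparseable.*Z|Z.*m2")

  write.table(data.frame(marker_id = c("m1", "m1"), chrom = "A01",
                         pos = c(1, 2)), mp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(mp, xp), "duplicated marker id")
})

test_that("marker filter drops non-polymorphic and high-missing markers with reasons", {
  # 10 markers: 3 non-polymorphic parents, 1 with 30% missing
  set.seed(1)
  codes <- matrix("A", nrow = 10, ncol = 10)
  codes[, seq(2, 10, 2)] <- "B"
  codes[1:3, 4] <- "-"                      # 30% missing at marker 4
  par <- rbind(rep(c("A", "B"), 5), rep(c("B", "A"), 5))
  par[, 5] <- c("A", "A")                   # same homozygote
  par[, 7] <- c("H", "B")                   # het parent
  par[, 9] <- c("-", "A")                   # missing parent
  g <- toy_geno(codes, parents = par)
  res <- filter_markers(g, max_missing = 0.2, require_parent_polymorphism = TRUE)
  expect_equal(ncol(res$geno$calls), 6)
  expect_equal(unname(res$report$counts["non_polymorphic"]), 3L)
  expect_equal(unname(res$report$counts["high_missing"]), 1L)
  expect_equal(res$report$n_input, res$report$n_retained + nrow(res$report$dropped))
  expect_error(filter_markers(g, max_missing = -1,
                              require_parent_polymorphism = TRUE),
               "all markers dropped")
})

test_that("line filter drops heterozygous/missing lines and QC totals reconcile", {
  codes <- matrix("A", nrow = 4, ncol = 20)
  codes[2, 1:3] <- "H"     # 15% HET -> dropped at max_het = 0.10
  codes[3, 1:2] <- "H"     # 10% HET -> kept (threshold is strict >)
  codes[4, 1:5] <- "-"     # 25% missing -> dropped
  g <- toy_geno(codes)
  res <- filter_lines(g, max_het = 0.10, max_missing = 0.10)
  expect_identical(rownames(res$geno$calls), c("L01", "L03"))
  expect_identical(res$report$dropped$reason, c("high_het", "high_missing"))
  expect_equal(res$report$n_input, 4L)
  expect_equal(res$report$het_fraction[["L02"]], 0.15)
  expect_error(filter_lines(g, max_het = -1, max_missing = -1), "all lines")
})

test_that("a 348-line population with 56 contaminated lines retains 292 after QC", {
  gm <- flat_genome(2e7, cm_per_mb = 2)
  pop <- simulate_population(gm, sim_config(n_lines = 348, seed = 42),
                             noisy_lines = 56, noisy_het = 0.25)
  res <- filter_lines(pop$geno, max_het = 0.10, max_missing = 0.10)
  expect_equal(res$report$n_retained, 292L)
  expect_setequal(res$report$dropped$line, pop$truth$noisy_lines)
})

test_that("marker and line filters commute when decisions are independent", {
  g <- random_matrix(12, 30, p_missing = 0, seed = 3)
  g$calls[2, 1:10] <- "HET"       # line drop, spread over many markers
  g$calls[, 5] <- "MISSING"       # marker drop, all lines equally
  a <- filter_lines(filter_markers(g, 0.5)$geno, 0.2, 0.5)$geno
  b <- filter_markers(filter_lines(g, 0.2, 0.5)$geno, 0.5)$geno
  expect_identical(a$calls, b$calls)
})

test_that("gene annotation reads both 1-based TSV and BED dialects", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = "g1", chrom = "A01", start = 101,
                         end = 200, strand = "+"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- withr::local_tempfile(fileext = ".bed")
  write.table(data.frame("A01", 100, 200, "g1", 0, "+"), bed, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  a <- read_gene_annotation(tsv, "tsv")
  b <- read_gene_annotation(bed, "bed")
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
})
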