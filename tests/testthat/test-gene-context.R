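make_cos <- function(tracts, chrom = "A01", mids = NULL) {
  if (is.null(mids)) mids <- seq(1e6, by = 1e6, length.out = length(tracts))
  n <- length(mids)
  tracts <- rep(tracts, length.out = n)
  data.frame(line = rep("L1", n), chrom = rep(chrom, n),
             left_bp = mids - tracts / 2, right_bp = mids + tracts / 2,
             midpoint = mids, tract_length = tracts,
             from = rep("P1", n), to = rep("P2", n),
             stringsAsFactors = FALSE)
}

# three-regime profile on a 12-Mb chromosome at n = 100 lines:
# 0-4 Mb cold (0 cM/Mb), 4-8 Mb intermediate (~1.3), 8-12 Mb hot (~20)
three_regime_profile <- function() {
  mids <- c(seq(4.1e6, 8e6, by = 7.5e5), seq(8.05e6, 12e6, by = 5e4))
  ci <- data.frame(chrom = "A01", length = 12e6)
  window_profile(make_cos(2, mids = mids), ci, n_lines = 100)
}

test_that("tract-length distribution reports buckets and cumulative fractions", {
  d <- tract_length_distribution(make_cos(rep(5e4, 10)))
  expect_equal(d$pct_le_100kb, 100)
  expect_equal(d$histogram$n[1], 10)
  expect_equal(max(d$histogram$cum_pct), 100)

  d3 <- tract_length_distribution(make_cos(c(5e4, 1.5e5, 8e5)))
  expect_equal(d3$pct_le_100kb, 100 / 3, tolerance = 1e-12)
  expect_equal(d3$pct_le_200kb, 200 / 3, tolerance = 1e-12)
  expect_equal(d3$histogram$n[8], 1)              # 700+ bucket
  expect_identical(d3$histogram$bucket[8], "700+")
  expect_true(!is.unsorted(d3$histogram$cum_pct))

  # invariant to event order
  d3r <- tract_length_distribution(make_cos(c(8e5, 5e4, 1.5e5)))
  expect_equal(d3r$histogram, d3$histogram)
})

genes1 <- data.frame(
  gene_id = c("g1", "g2"), chrom = "A01",
  start = c(100000, 220000), end = c(103000, 224000),
  strand = c("+", "-"), stringsAsFactors = FALSE)

test_that("gene proximity classifies inside/outside and TSS/TTS strand-aware", {
  # midpoint exactly at a + strand gene start: inside, TSS, distance 0
  co1 <- make_cos(rep(10, 3), mids = c(100000, 98000, 101600))
  gp <- gene_proximity(co1, genes1)
  ev <- gp$events
  expect_true(ev$inside[1]); expect_identical(ev$site[1], "TSS")
  expect_equal(ev$distance[1], 0); expect_equal(ev$signed_distance[1], 0)
  # 2 kb upstream of the + strand gene: outside, near TSS, signed -2000
  expect_false(ev$inside[2]); expect_identical(ev$site[2], "TSS")
  expect_equal(ev$distance[2], 2000)
  expect_equal(ev$signed_distance[2], -2000)
  expect_equal(ev$dist_bin[2], -2)
  # midpoint 101600: 1600 from TSS, 1400 from TTS -> TTS side
  expect_identical(ev$site[3], "TTS")

  # equidistant from TSS and TTS resolves to TSS
  co_tie <- make_cos(10, mids = 101500)
  expect_identical(gene_proximity(co_tie, genes1)$events$site, "TSS")

  # minus-strand: TSS is the end coordinate; signed distance flips
  co_m <- make_cos(10, mids = 225000)  # 1 kb beyond g2 end = upstream of TSS
  evm <- gene_proximity(co_m, genes1)$events
  expect_identical(evm$gene_id, "g2")
  expect_identical(evm$site, "TSS")
  expect_equal(evm$signed_distance, -1000)

  # long tracts and geneless chromosomes are excluded but counted
  co_mix <- rbind(make_cos(2e5, mids = 150000),
                  make_cos(10, mids = 5000, chrom = "Z99"))
  gpx <- gene_proximity(co_mix, genes1)
  expect_equal(gpx$n_analyzed, 0)
  expect_equal(gpx$n_excluded_long, 1)
  expect_equal(gpx$n_excluded_no_gene, 1)
  expect_error(gene_proximity(co1, genes1[0, ]), "empty")
})

test_that("proximity class counts reconcile with analyzed events", {
  set.seed(31)
  gm <- flat_genome(2e7, 2)
  f <- simulate_features(gm, n_genes = 300, homolog_blocks = NA,
                        n_background_pairs = 0, seed = 31)
  co <- make_cos(runif(200, 10, 9e4), mids = sort(sample.int(2e7 - 1e5, 200)))
  gp <- gene_proximity(co, f$genes)
  expect_equal(sum(gp$class_counts), gp$n_analyzed)
  expect_equal(gp$n_analyzed + gp$n_excluded_long + gp$n_excluded_no_gene,
               nrow(co))
})

test_that("strata assignment averages overlapping windows and is deterministic", {
  p <- three_regime_profile()
  genes <- data.frame(gene_id = sprintf("g%03d", 1:120), chrom = "A01",
                      start = seq(1e5, 11.8e6, length.out = 120),
                      end = seq(1e5, 11.8e6, length.out = 120) + 1000,
                      strand = "+", stringsAsFactors = FALSE)
  set.seed(30)
  expr <- data.frame(gene_id = genes$gene_id, leaf = rexp(120))
  r1 <- strata_expression(p, genes, expr, n_sample = 10, seed = 3)
  r2 <- strata_expression(p, genes, expr, n_sample = 10, seed = 3)
  expect_identical(r1$gene_strata, r2$gene_strata)
  expect_identical(r1$sampled, r2$sampled)
  gs <- r1$gene_strata
  expect_true(all(gs$stratum[genes$start < 1e6] == "lt1"))
  expect_true(all(gs$stratum[genes$start > 9e6] == "gt2"))
  expect_true(all(gs$stratum[genes$start > 5.1e6 & genes$start < 6e6] == "mid"))
  # sampling is without replacement
  expect_false(anyDuplicated(r1$sampled$lt1) > 0)
  # n_sample larger than the stratum: all genes used, with a warning
  w <- capture_warnings(
    r3 <- strata_expression(p, genes, expr, n_sample = 1000, seed = 1))
  expect_true(any(grepl("using all", w)))
  expect_equal(length(r3$sampled$mid),
               sum(gs$stratum == "mid", na.rm = TRUE))
})

test_that("strata tests flag planted expression shifts", {
  p <- three_regime_profile()
  genes <- data.frame(gene_id = sprintf("g%03d", 1:400), chrom = "A01",
                      start = seq(1e5, 11.8e6, length.out = 400),
                      end = seq(1e5, 11.8e6, length.out = 400) + 1000,
                      strand = "+", stringsAsFactors = FALSE)
  hotg <- genes$start > 7.5e6
  set.seed(77)
  expr <- data.frame(gene_id = genes$gene_id,
                     leaf = rlnorm(400, ifelse(hotg, log(4), log(1)), 1),
                     root = rlnorm(400, 0, 1))
  r <- strata_expression(p, genes, expr, n_sample = 30, seed = 5)
  leaf <- r$results[r$results$tissue == "leaf", ]
  expect_lt(leaf$p_hot_vs_cold, 0.01)
  expect_gt(leaf$mean_gt2, leaf$mean_lt1)
  expect_true(all(c("padj_hot_vs_cold", "significant") %in% names(r$results)))
})
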