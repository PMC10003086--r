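#' Crossover tract-length distribution
#'
#' Histogram of tract lengths (the bp interval between the flanking
#' informative markers of each event) at 100-kb resolution with a terminal
#' "700+" bucket, the cumulative percentage curve, and the fractions of
#' events within 100 kb and 200 kb.
#'
#' @param cos Crossover events ([call_crossovers()]).
#' @param scale Histogram bucket width, bp (default 100 kb).
#' @param cap Lower edge of the terminal open bucket, bp (default 700 kb).
#' @return List of class `tract_distribution`: `histogram` (data frame
#'   `bucket`, `n`, `pct`, `cum_pct`), `n`, `min_bp`, `max_bp`,
#'   `pct_le_100kb`, `pct_le_200kb`.
#' @export
tract_length_distribution <- function(cos, scale = 1e5, cap = 7e5) {
  t <- cos$tract_length
  n_bucket <- cap / scale
  b <- pmin(ceiling(t / scale), n_bucket + 1)
  b[t == 0] <- 1
  labels <- c(sprintf("%d-%d", (seq_len(n_bucket) - 1) * scale / 1e3,
                      seq_len(n_bucket) * scale / 1e3),
              sprintf("%d+", cap / 1e3))
  cnt <- table(factor(b, levels = seq_len(n_bucket + 1)))
  hist <- data.frame(bucket = labels, n = as.integer(cnt),
                     pct = 100 * as.integer(cnt) / max(length(t), 1L),
                     stringsAsFactors = FALSE)
  hist$cum_pct <- cumsum(hist$pct)
  structure(list(histogram = hist, n = length(t),
                 min_bp = if (length(t)) min(t) else NA_real_,
                 max_bp = if (length(t)) max(t) else NA_real_,
                 pct_le_100kb = 100 * mean(t <= 1e5),
                 pct_le_200kb = 100 * mean(t <= 2e5)),
            class = "tract_distribution")
}

#' @export
print.tract_distribution <- function(x, ...) {
  cat(sprintf("tract_distribution: %d events, range %s-%s bp; %.1f%% <= 100 kb, %.1f%% <= 200 kb\n",
              x$n, format(x$min_bp, big.mark = ","),
              format(x$max_bp, big.mark = ","),
              x$pct_le_100kb, x$pct_le_200kb))
  invisible(x)
}

#' Crossover placement relative to the nearest gene
#'
#' Only events with tract length below `max_tract` (default 100 kb) are
#' analyzed, using their midpoints. For each midpoint the nearest gene by bp
#' distance to the gene interval is found (distance 0 inside). Events are
#' classified inside/outside the gene body and near-TSS/near-TTS by which
#' site is closer in bp (strand-aware; ties toward the TSS). The signed
#' distance to the chosen site — positive downstream in gene orientation — is
#' histogrammed at `bin` width (default 1.4 kb, half the typical 2.8 kb
#' transcript).
#'
#' @param cos Crossover events.
#' @param genes Gene annotation (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param max_tract Maximum tract length analyzed, bp.
#' @param bin Histogram bin width, bp.
#' @return List of class `gene_proximity`: `events` (per-CO data frame with
#'   `gene_id`, `inside`, `site`, `distance`, `signed_distance`, `dist_bin`),
#'   `class_counts` (inside/outside x TSS/TTS), `histogram`, `n_analyzed`,
#'   `n_excluded_long`, `n_excluded_no_gene`.
#' @export
gene_proximity <- function(cos, genes, max_tract = 1e5, bin = 1400) {
  if (!nrow(genes)) stop_mm("empty gene annotation")
  keep <- cos$tract_length < max_tract
  n_long <- sum(!keep)
  cos <- cos[keep, , drop = FALSE]
  no_gene <- !(cos$chrom %in% genes$chrom)
  n_nogene <- sum(no_gene)
  cos <- cos[!no_gene, , drop = FALSE]
  res <- vector("list", length(unique(cos$chrom)))
  names(res) <- unique(cos$chrom)
  for (ch in unique(cos$chrom)) {
    gg <- genes[genes$chrom == ch, , drop = FALSE]
    m <- cos$midpoint[cos$chrom == ch]
    # distance from each midpoint to each gene interval (0 inside)
    d <- outer(m, gg$start, function(x, s) s - x)
    d2 <- outer(m, gg$end, function(x, e) x - e)
    dist <- pmax(d, d2, 0)
    j <- max.col(-dist, ties.method = "first")
    ix <- cbind(seq_along(m), j)
    gsel <- gg[j, , drop = FALSE]
    tss <- ifelse(gsel$strand == "+", gsel$start, gsel$end)
    tts <- ifelse(gsel$strand == "+", gsel$end, gsel$start)
    d_tss <- abs(m - tss); d_tts <- abs(m - tts)
    site <- ifelse(d_tss <= d_tts, "TSS", "TTS")  # tie -> TSS
    ref <- ifelse(site == "TSS", tss, tts)
    sgn <- ifelse(gsel$strand == "+", m - ref, ref - m)
    res[[ch]] <- data.frame(
      line = cos$line[cos$chrom == ch], chrom = ch, midpoint = m,
      gene_id = gsel$gene_id, inside = m >= gsel$start & m <= gsel$end,
      site = site, distance = dist[ix], signed_distance = sgn,
      dist_bin = floor(sgn / bin), stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, res)
  if (is.null(ev)) ev <- data.frame(inside = logical(0), site = character(0),
                                    dist_bin = integer(0))
  rownames(ev) <- NULL
  cls <- table(ifelse(ev$inside, "inside", "outside"),
               factor(ev$site, levels = c("TSS", "TTS")))
  hist <- as.data.frame(table(bin = ev$dist_bin, site = ev$site,
                              inside = ev$inside), stringsAsFactors = FALSE)
  hist <- hist[hist$Freq > 0, , drop = FALSE]
  hist$bin <- as.integer(hist$bin)
  structure(list(events = ev, class_counts = cls, histogram = hist,
                 bin_width = bin, n_analyzed = nrow(ev),
                 n_excluded_long = n_long, n_excluded_no_gene = n_nogene),
            class = "gene_proximity")
}

#' Gene expression across crossover-frequency strata
#'
#' Each gene is assigned the mean frequency of the profile windows containing
#' its midpoint (overlapping sliding windows are averaged), then stratified
#' as cold (< 1 cM/Mb), intermediate (1-2) or hot (> 2). Up to `n_sample`
#' genes per stratum are sampled without replacement (all genes, with a
#' warning, when a stratum is smaller). Per tissue, two-sided Wilcoxon
#' rank-sum tests compare hot vs cold and the adjacent pairs; p-values for
#' the primary hot-vs-cold contrast are Benjamini-Hochberg adjusted across
#' tissues.
#'
#' @param p A `recomb_profile` from [window_profile()].
#' @param genes Gene annotation.
#' @param expression Data frame: `gene_id` plus one numeric column per tissue.
#' @param n_sample Genes sampled per stratum (default 1000).
#' @param seed Integer seed for the sampling.
#' @param alpha Significance level for the reported flags.
#' @return List of class `strata_expression`: `gene_strata` (per-gene
#'   frequency and stratum), `sampled` (gene ids used per stratum),
#'   `results` (per tissue: stratum means, p-values `p_hot_vs_cold`,
#'   `p_hot_vs_mid`, `p_mid_vs_cold`, `padj_hot_vs_cold`, `significant`),
#'   `n_sample`, `seed`.
#' @export
strata_expression <- function(p, genes, expression, n_sample = 1000, seed = 1,
                              alpha = 0.05) {
  w <- attr(p, "window")
  mid <- (genes$start + genes$end) / 2
  freq <- rep(NA_real_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    pw <- p[p$chrom == ch, , drop = FALSE]
    if (!nrow(pw)) next
    gix <- which(genes$chrom == ch)
    cs <- c(0, cumsum(pw$freq))
    hi <- findInterval(mid[gix], pw$start)
    lo <- pmax(findInterval(mid[gix] - w, pw$start) + 1L, 1L)
    ok <- hi >= lo
    freq[gix[ok]] <- (cs[hi[ok] + 1] - cs[lo[ok]]) / (hi[ok] - lo[ok] + 1)
  }
  stratum <- cut(freq, c(-Inf, 1, 2, Inf), labels = c("lt1", "mid", "gt2"))
  gs <- data.frame(gene_id = genes$gene_id, freq = freq,
                   stratum = as.character(stratum), stringsAsFactors = FALSE)
  set.seed(seed)
  sampled <- lapply(stats::setNames(nm = c("lt1", "mid", "gt2")), function(s) {
    ids <- gs$gene_id[!is.na(gs$stratum) & gs$stratum == s]
    if (length(ids) < n_sample) {
      warn_mm(sprintf("stratum %s has only %d genes (< n_sample = %d); using all",
                      s, length(ids), n_sample))
      ids
    } else sample(ids, n_sample)
  })
  tissues <- setdiff(names(expression), "gene_id")
  rows <- list()
  for (t in tissues) {
    x <- stats::setNames(expression[[t]], expression$gene_id)
    vals <- lapply(sampled, function(ids) unname(x[ids]))
    if (any(vapply(vals, length, integer(1)) == 0L)) {
      warn_mm("empty stratum; tissue skipped: ", t)
      next
    }
    wt <- function(a, b) stats::wilcox.test(a, b, exact = FALSE)$p.value
    rows[[t]] <- data.frame(
      tissue = t,
      mean_lt1 = mean(vals$lt1), mean_mid = mean(vals$mid),
      mean_gt2 = mean(vals$gt2),
      p_hot_vs_cold = wt(vals$gt2, vals$lt1),
      p_hot_vs_mid = wt(vals$gt2, vals$mid),
      p_mid_vs_cold = wt(vals$mid, vals$lt1),
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  if (!is.null(results)) {
    results$padj_hot_vs_cold <- stats::p.adjust(results$p_hot_vs_cold, "BH")
    results$significant <- results$padj_hot_vs_cold < alpha
    rownames(results) <- NULL
  }
  structure(list(gene_strata = gs, sampled = sampled, results = results,
                 n_sample = n_sample, seed = seed, alpha = alpha),
            class = "strata_expression")
}

#' @export
print.strata_expression <- function(x, ...) {
  if (is.null(x$results)) {
    cat("strata_expression: no tissues analyzed\n")
  } else {
    cat(sprintf("strata_expression: %d tissues, %d significant (hot vs cold, BH < %.2f)\n",
                nrow(x$results), sum(x$results$significant), x$alpha))
  }
  invisible(x)
}
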