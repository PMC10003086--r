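#' Sliding-window crossover frequency profile (cM/Mb)
#'
#' A crossover is assigned to a window iff its midpoint lies in
#' `[start, end)` (half-open, so boundary assignment is unambiguous). The
#' genetic distance accumulated in a window is the direct recombinant-fraction
#' estimate `100 cM x (COs in window / n_lines)` — per-window fractions are
#' small, so no mapping-function correction is applied here (the bin map uses
#' Kosambi; see [build_map()]). Frequency = genetic distance / window span in
#' Mb; the terminal partial window uses its true bp span in the denominator.
#'
#' @param cos Crossover events ([call_crossovers()]).
#' @param chrom_info Data frame `chrom`, `length` (bp).
#' @param n_lines Number of lines in the population.
#' @param window Window span, bp (default 3 Mb).
#' @param step Step between window starts, bp (default 1 Mb).
#' @return Data frame of class `recomb_profile`: `chrom`, `start`, `end`
#'   (half-open bp), `n_co`, `freq` (cM/Mb); attributes `n_lines`, `window`,
#'   `step`.
#' @export
window_profile <- function(cos, chrom_info, n_lines, window = 3e6, step = 1e6) {
  if (window <= 0) stop_mm("window must be positive")
  if (n_lines < 1) stop_mm("n_lines must be >= 1")
  if (window < step) stop_mm("window must be >= step")
  rows <- lapply(seq_len(nrow(chrom_info)), function(k) {
    ch <- chrom_info$chrom[k]
    L <- chrom_info$length[k]
    starts <- seq(1, L, by = step)
    ends <- pmin(starts + window, L + 1)  # half-open [start, end)
    m <- sort(cos$midpoint[cos$chrom == ch])
    n_co <- findInterval(ends - 0.5, m) - findInterval(starts - 0.5, m)
    span_mb <- (ends - starts) / 1e6
    data.frame(chrom = ch, start = starts, end = ends, n_co = n_co,
               freq = 100 * (n_co / n_lines) / span_mb,
               stringsAsFactors = FALSE)
  })
  p <- do.call(rbind, rows)
  attr(p, "n_lines") <- n_lines
  attr(p, "window") <- window
  attr(p, "step") <- step
  class(p) <- c("recomb_profile", "data.frame")
  p
}

#' Detect crossover hot regions
#'
#' Windows whose frequency exceeds `threshold` are merged into maximal
#' regions wherever they overlap or are adjacent; the region span is the
#' union of its window spans.
#'
#' @param p A `recomb_profile` from [window_profile()].
#' @param threshold Hot threshold in cM/Mb (default 2).
#' @param genes Optional gene annotation (adds a per-region gene count, genes
#'   counted by midpoint).
#' @return Data frame of class `hot_regions`: `chrom`, `start`, `end`
#'   (half-open bp), `n_windows`, `peak_freq`, `mean_freq` and optionally
#'   `n_genes`; attribute `n_hot_windows` gives the raw count of
#'   above-threshold windows before merging.
#' @export
detect_hot_regions <- function(p, threshold = 2, genes = NULL) {
  hot <- p[p$freq > threshold, , drop = FALSE]
  out <- list()
  for (ch in unique(hot$chrom)) {
    h <- hot[hot$chrom == ch, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    run_start <- h$start[1]; run_end <- h$end[1]
    peak <- h$freq[1]; acc <- h$freq[1]; n <- 1L
    flush <- function(s, e, pk, mean_f, nw)
      data.frame(chrom = ch, start = s, end = e, n_windows = nw,
                 peak_freq = pk, mean_freq = mean_f, stringsAsFactors = FALSE)
    rows <- list()
    if (nrow(h) > 1) for (i in 2:nrow(h)) {
      if (h$start[i] <= run_end) {  # overlap or adjacency (half-open spans)
        run_end <- max(run_end, h$end[i])
        peak <- max(peak, h$freq[i]); acc <- acc + h$freq[i]; n <- n + 1L
      } else {
        rows[[length(rows) + 1L]] <- flush(run_start, run_end, peak, acc / n, n)
        run_start <- h$start[i]; run_end <- h$end[i]
        peak <- h$freq[i]; acc <- h$freq[i]; n <- 1L
      }
    }
    rows[[length(rows) + 1L]] <- flush(run_start, run_end, peak, acc / n, n)
    out[[ch]] <- do.call(rbind, rows)
  }
  reg <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_windows = integer(0), peak_freq = numeric(0),
               mean_freq = numeric(0), stringsAsFactors = FALSE)
  rownames(reg) <- NULL
  if (!is.null(genes) && nrow(reg)) {
    mid <- (genes$start + genes$end) / 2
    reg$n_genes <- vapply(seq_len(nrow(reg)), function(i)
      sum(genes$chrom == reg$chrom[i] & mid >= reg$start[i] & mid < reg$end[i]),
      integer(1))
  }
  attr(reg, "n_hot_windows") <- nrow(hot)
  attr(reg, "threshold") <- threshold
  class(reg) <- c("hot_regions", "data.frame")
  reg
}

#' Per-chromosome crossover summaries and length correlation
#'
#' @param cos Crossover events.
#' @param chrom_info Data frame `chrom`, `length`.
#' @param n_lines Number of lines.
#' @return List: `chromosomes` (data frame `chrom`, `n_co`, `length`, `freq`
#'   in cM/Mb, `subgenome` = first character of the chromosome name),
#'   `length_correlation` (Pearson r of CO count vs bp length; `NA` with
#'   fewer than 3 chromosomes), `n_chromosomes`, and `genome` (totals:
#'   `n_co`, `mb`, `freq`, per-subgenome `freq`).
#' @export
chromosome_summaries <- function(cos, chrom_info, n_lines) {
  cnt <- table(factor(cos$chrom, levels = chrom_info$chrom))
  df <- data.frame(chrom = chrom_info$chrom, n_co = as.integer(cnt),
                   length = chrom_info$length,
                   freq = 100 * (as.integer(cnt) / n_lines) /
                     (chrom_info$length / 1e6),
                   subgenome = substr(chrom_info$chrom, 1, 1),
                   stringsAsFactors = FALSE)
  r <- if (nrow(df) < 3) NA_real_
  else if (stats::sd(df$n_co) == 0 || stats::sd(df$length) == 0) 0
  else stats::cor(df$n_co, df$length)
  sub <- vapply(split(df, df$subgenome), function(s)
    100 * (sum(s$n_co) / n_lines) / (sum(s$length) / 1e6), numeric(1))
  list(chromosomes = df, length_correlation = r, n_chromosomes = nrow(df),
       genome = list(n_co = sum(df$n_co), mb = sum(df$length) / 1e6,
                     freq = 100 * (sum(df$n_co) / n_lines) /
                       (sum(df$length) / 1e6),
                     subgenome_freq = as.list(sub)))
}

#' Write a recombination profile as bedGraph
#'
#' @param p A `recomb_profile`.
#' @param path Output path (chrom, 0-based start, end, frequency).
#' @export
write_profile <- function(p, path) {
  utils::write.table(data.frame(p$chrom, p$start - 1, p$end - 1, p$freq),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param hot A `hot_regions` data frame (written as BED).
#' @export
write_hot_regions <- function(hot, path) {
  utils::write.table(data.frame(hot$chrom, hot$start - 1, hot$end - 1,
                                sprintf("hot_%d", seq_len(nrow(hot))),
                                round(hot$peak_freq, 3)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Plot a windowed recombination profile
#'
#' One panel per chromosome row is avoided; chromosomes are concatenated on
#' the x axis with the hot threshold drawn as a horizontal line.
#'
#' @param p A `recomb_profile`.
#' @param threshold Hot threshold to draw (cM/Mb).
#' @export
plot_profile <- function(p, threshold = 2) {
  chroms <- unique(p$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) max(p$end[p$chrom == ch]),
                             numeric(1))))
  x <- p$start + offs[match(p$chrom, chroms)]
  graphics::plot(x / 1e6, p$freq, type = "h", col = "grey40",
                 xlab = "cumulative position (Mb)", ylab = "CO frequency (cM/Mb)")
  graphics::abline(h = threshold, col = "firebrick", lty = 2)
  graphics::abline(v = offs[-1] / 1e6, col = "grey85")
  invisible(NULL)
}
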