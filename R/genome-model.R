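#' Build a genome model for meiosis simulation
#'
#' A genome model describes, per chromosome, the physical length, the
#' centromere position, and a piecewise-constant crossover intensity profile
#' \eqn{\lambda(x)} in cM/Mb. The genetic length of a chromosome is the
#' integral of \eqn{\lambda} over its physical length; the expected number of
#' crossovers per gamete on that chromosome is genetic length / 100.
#'
#' @param chrom Character vector of chromosome names.
#' @param length_bp Integer vector of chromosome lengths (bp).
#' @param centromere_bp Integer vector of centromere positions (bp), or `NULL`.
#' @param profiles Named list (one entry per chromosome). Each entry is a list
#'   with `breaks` (bp, starting at 0 and ending at the chromosome length) and
#'   `rate` (cM/Mb for each of the `length(breaks) - 1` pieces).
#' @return An object of class `genome_model` with elements `chrom_info`
#'   (data frame: `chrom`, `length`, `centromere`, `genetic_length`) and
#'   `profiles`.
#' @seealso [default_genome_model()], [simulate_population()]
#' @export
genome_model <- function(chrom, length_bp, centromere_bp = NULL, profiles) {
  stopifnot(length(chrom) == length(length_bp))
  if (anyDuplicated(chrom)) stop_mm("duplicated chromosome names in genome model")
  if (is.null(centromere_bp)) centromere_bp <- round(length_bp / 2)
  if (!all(chrom %in% names(profiles))) {
    stop_mm("profiles missing for chromosome(s): ",
            paste(setdiff(chrom, names(profiles)), collapse = ", "))
  }
  genetic_length <- numeric(length(chrom))
  for (k in seq_along(chrom)) {
    p <- profiles[[chrom[k]]]
    if (!all(is.finite(p$rate))) stop_mm("non-finite crossover intensity on ", chrom[k])
    if (any(p$rate < 0)) stop_mm("negative crossover intensity on ", chrom[k])
    if (length(p$breaks) != length(p$rate) + 1L)
      stop_mm("profile breaks/rate length mismatch on ", chrom[k])
    if (p$breaks[1] != 0 || p$breaks[length(p$breaks)] != length_bp[k])
      stop_mm("profile breaks must span [0, chromosome length] on ", chrom[k])
    if (is.unsorted(p$breaks, strictly = TRUE))
      stop_mm("profile breaks must be strictly increasing on ", chrom[k])
    genetic_length[k] <- sum(p$rate * diff(p$breaks)) / 1e6
  }
  structure(list(
    chrom_info = data.frame(chrom = chrom, length = as.numeric(length_bp),
                            centromere = as.numeric(centromere_bp),
                            genetic_length = genetic_length,
                            stringsAsFactors = FALSE),
    profiles = profiles[chrom]
  ), class = "genome_model")
}

#' Default 19-chromosome allotetraploid (AACC) genome model
#'
#' Chromosome bp lengths approximate the A (ex *B. rapa*) and C
#' (ex *B. oleracea*) subgenomes of *Brassica napus* (~780 Mb total). Each
#' chromosome carries a U-shaped crossover intensity profile: strongly
#' elevated in the distal 10% of either arm, nearly suppressed around the
#' (peri)centromere. Per-chromosome genetic lengths are proportional to
#' physical length and scaled so the expected genome-wide crossover count per
#' gamete is `mean_cos_per_line` (default 23, i.e. ~1.2 per chromosome).
#'
#' @param mean_cos_per_line Expected total crossovers per gamete (genome
#'   genetic length = 100 times this, in cM).
#' @param distal_weights Relative intensity of the 10 equal-width segments of
#'   each chromosome (telomere to telomere).
#' @return A `genome_model`.
#' @export
default_genome_model <- function(mean_cos_per_line = 23,
                                 distal_weights = c(10, 1.2, 0.8, 0.3, 0.05,
                                                    0.05, 0.3, 0.8, 1.2, 10)) {
  chrom <- c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9))
  len_mb <- c(34, 31, 37, 24, 29, 31, 29, 23, 50, 23,   # A01..A10
              45, 55, 68, 60, 50, 44, 49, 45, 56)       # C01..C09
  length_bp <- len_mb * 1e6
  centromere_bp <- round(0.45 * length_bp)
  total_cm <- 100 * mean_cos_per_line
  g_len <- total_cm * length_bp / sum(length_bp)
  w <- distal_weights / sum(distal_weights)
  profiles <- vector("list", length(chrom))
  names(profiles) <- chrom
  for (k in seq_along(chrom)) {
    breaks <- seq(0, length_bp[k], length.out = length(w) + 1L)
    seg_mb <- diff(breaks) / 1e6
    profiles[[k]] <- list(breaks = breaks, rate = g_len[k] * w / seg_mb)
  }
  genome_model(chrom, length_bp, centromere_bp, profiles)
}

# Cumulative genetic position (cM) at physical position bp on one chromosome.
genetic_cum <- function(gm, chrom, bp) {
  p <- gm$profiles[[chrom]]
  if (is.null(p)) stop_mm("unknown chromosome: ", chrom)
  cum <- c(0, cumsum(p$rate * diff(p$breaks) / 1e6))
  i <- findInterval(bp, p$breaks, all.inside = TRUE)
  cum[i] + p$rate[i] * (bp - p$breaks[i]) / 1e6
}

# Inverse of genetic_cum: map genetic positions (cM) to bp (piecewise linear;
# zero-rate pieces collapse to their left edge).
genetic_to_physical <- function(gm, chrom, cm) {
  if (length(cm) == 0L) return(numeric(0))
  p <- gm$profiles[[chrom]]
  cum <- c(0, cumsum(p$rate * diff(p$breaks) / 1e6))
  keep <- !duplicated(cum)
  round(stats::approx(cum[keep], p$breaks[keep], xout = cm, rule = 2)$y)
}

# lambda(x) in cM/Mb at physical positions bp.
lambda_at <- function(gm, chrom, bp) {
  p <- gm$profiles[[chrom]]
  p$rate[findInterval(bp, p$breaks, all.inside = TRUE)]
}

#' @export
print.genome_model <- function(x, ...) {
  ci <- x$chrom_info
  cat(sprintf("genome_model: %d chromosomes, %.0f Mb, %.1f cM (%.2f cM/Mb)\n",
              nrow(ci), sum(ci$length) / 1e6, sum(ci$genetic_length),
              sum(ci$genetic_length) / (sum(ci$length) / 1e6)))
  invisible(x)
}
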