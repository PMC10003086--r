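#' Kosambi mapping function
#'
#' Converts a recombination fraction to map distance,
#' \eqn{d = 25 \ln((1+2r)/(1-2r))} cM, which accounts for moderate crossover
#' interference. Fractions outside `[0, cap]` are clamped with a warning
#' (never silently) to keep the distance finite.
#'
#' @param r Recombination fraction(s).
#' @param cap Clamp value just below the 0.5 pole (default 0.49).
#' @return Map distance(s) in cM.
#' @export
kosambi <- function(r, cap = 0.49) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) {
    warn_mm("recombination fraction(s) outside [0, 0.5) clamped to [0, ", cap, "]")
    r <- pmin(pmax(r, 0), cap)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @param d Map distance(s) in cM.
#' @export
kosambi_inv <- function(d) 0.5 * tanh(d / 50)

#' Recombination fraction between two bins in a DH population
#'
#' The direct DH estimator: the fraction of lines carrying opposite
#' informative parental genotypes at the two bins, among lines informative at
#' both.
#'
#' @param bins A `bin_set`.
#' @param i,j Bin indices (must be on the same chromosome).
#' @return List with `r` (`NA` if no line is informative at both) and
#'   `n_informative`.
#' @export
recombination_fraction <- function(bins, i, j) {
  if (bins$bins$chrom[i] != bins$bins$chrom[j])
    stop_mm("bins on different chromosomes")
  a <- bins$geno[, i]; b <- bins$geno[, j]
  ok <- is_informative(a) & is_informative(b)
  n <- sum(ok)
  list(r = if (n) sum(a[ok] != b[ok]) / n else NA_real_, n_informative = n)
}

# Vectorized adjacent-pair r for one chromosome's genotype columns.
adjacent_rf <- function(geno) {
  n_bin <- ncol(geno)
  if (n_bin < 2L) return(data.frame(r = numeric(0), n = integer(0)))
  inf <- geno == "P1" | geno == "P2"
  ok <- inf[, -n_bin, drop = FALSE] & inf[, -1L, drop = FALSE]
  diff <- (geno[, -n_bin, drop = FALSE] != geno[, -1L, drop = FALSE]) & ok
  n <- colSums(ok)
  data.frame(r = ifelse(n > 0, colSums(diff) / n, NA_real_), n = n)
}

#' Build a genetic linkage map over bins with the Kosambi function
#'
#' Linkage groups are the chromosomes and bin order is physical order (the
#' markers are physically anchored, so no de-novo grouping or ordering is
#' performed). Cumulative cM positions are running sums of Kosambi distances
#' between adjacent bins. Adjacent pairs with no jointly informative line are
#' bridged: the distance is estimated against the next bin that does share
#' informative lines and assigned to the final step of the gap.
#'
#' @param bins A `bin_set`.
#' @return Object of class `linkage_map`: `map` (data frame `chrom`, `bin`,
#'   `cm` (cumulative within chromosome), `bp` (bin start), `r_next`,
#'   `n_informative`), and `stats` (list: `total_cm`, per-`subgenome_cm`,
#'   `n_bins`, `mean_adjacent_cm` = total_cm / n_bins, per-chromosome
#'   lengths).
#' @export
build_map <- function(bins) {
  B <- bins$bins
  rows <- list()
  for (ch in unique(B$chrom)) {
    bidx <- which(B$chrom == ch)
    geno <- bins$geno[, bidx, drop = FALSE]
    rf <- adjacent_rf(geno)
    d <- rep(0, length(bidx))
    if (length(bidx) > 1L) {
      r <- rf$r
      for (t in seq_along(r)) {
        if (!is.na(r[t])) {
          d[t + 1L] <- kosambi(min(r[t], 0.49))
        } else {
          # no jointly informative line: bridge against the nearest earlier
          # bin that shares informative lines, net of distances already laid
          b <- bins$geno[, bidx[t + 1L]]
          for (p in t:1) {
            a <- bins$geno[, bidx[p]]
            ok <- is_informative(a) & is_informative(b)
            if (sum(ok)) {
              span <- kosambi(min(sum(a[ok] != b[ok]) / sum(ok), 0.49))
              laid <- if (p < t) sum(d[(p + 1L):t]) else 0
              d[t + 1L] <- max(0, span - laid)
              break
            }
          }
        }
      }
    }
    rows[[ch]] <- data.frame(chrom = ch, bin = B$bin[bidx], cm = cumsum(d),
                             bp = B$start[bidx],
                             r_next = c(rf$r, NA), n_informative = c(rf$n, NA),
                             stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  per_chrom <- vapply(split(map$cm, factor(map$chrom, unique(map$chrom))), max,
                      numeric(1))
  sub <- vapply(split(per_chrom, substr(names(per_chrom), 1, 1)), sum,
                numeric(1))
  stats <- list(total_cm = sum(per_chrom),
                subgenome_cm = as.list(sub),
                n_bins = nrow(map),
                mean_adjacent_cm = sum(per_chrom) / nrow(map),
                chrom_cm = as.list(per_chrom))
  structure(list(map = map, stats = stats), class = "linkage_map")
}

#' Summary statistics of a linkage map
#'
#' Total map length, per-subgenome totals (by chromosome-name prefix) and the
#' mean adjacent-bin distance, defined as total cM / number of bins.
#'
#' @param map A `linkage_map`, or its `map` data frame.
#' @return List: `total_cm`, `subgenome_cm`, `n_bins`, `mean_adjacent_cm`.
#' @export
map_statistics <- function(map) {
  if (inherits(map, "linkage_map")) return(map$stats)
  per_chrom <- vapply(split(map$cm, factor(map$chrom, unique(map$chrom))), max,
                      numeric(1))
  sub <- vapply(split(per_chrom, substr(names(per_chrom), 1, 1)), sum,
                numeric(1))
  list(total_cm = sum(per_chrom), subgenome_cm = as.list(sub),
       n_bins = nrow(map), mean_adjacent_cm = sum(per_chrom) / nrow(map))
}

#' @export
print.linkage_map <- function(x, ...) {
  s <- x$stats
  cat(sprintf("linkage_map: %d bins, %d group(s), %.1f cM total, %.2f cM/bin\n",
              s$n_bins, length(s$chrom_cm), s$total_cm, s$mean_adjacent_cm))
  invisible(x)
}

#' Write a linkage map as TSV
#'
#' @param map A `linkage_map`.
#' @param path Output path (group, bin, cM, bp).
#' @export
write_linkage_map <- function(map, path) {
  utils::write.table(map$map[, c("chrom", "bin", "cm", "bp")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
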