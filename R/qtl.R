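#' Interval-mapping QTL scan for a DH population (Haley-Knott regression)
#'
#' At every grid position (default every 2 cM) the expected QTL genotype of
#' each line is computed from the nearest informative flanking bins via the
#' standard DH conditional probabilities (two genotype classes; flanking
#' distances converted to recombination fractions with the inverse Kosambi
#' function, combined without interference). The trait is regressed on this
#' expected genotype and \eqn{LOD = (n/2)\log_{10}(RSS_0/RSS_1)}. With
#' cofactors (composite-interval-mapping style) the null and full models both
#' include the cofactor bin genotypes, excluding cofactors within
#' `cofactor_window` cM of the test position. Peaks above `threshold` are
#' reported with 1-LOD-drop support intervals (cM and interpolated bp),
#' additive effects, and the percentage of variance explained at the peak,
#' \eqn{PVE = 1 - 10^{-2 LOD / n}} (no-cofactor model).
#'
#' @param map A `linkage_map` from [build_map()].
#' @param bins The `bin_set` the map was built from.
#' @param trait Data frame `line`, `<value>` (second column is the phenotype)
#'   or a named numeric vector.
#' @param step Grid step in cM (default 2).
#' @param threshold LOD threshold for reporting a QTL (default 2.5).
#' @param cofactors Optional integer vector of cofactor bin indices (columns
#'   of `bins$geno`), e.g. from [select_cofactors()].
#' @param cofactor_window Exclusion window around the test position, cM.
#' @return Object of class `qtl_scan`: `profile` (data frame `chrom`, `cm`,
#'   `bp`, `lod`, `n`), `qtl` (data frame `chrom`, `peak_cm`, `peak_bp`,
#'   `lod`, `ci_lo_cm`, `ci_hi_cm`, `ci_lo_bp`, `ci_hi_bp`, `effect`, `pve`),
#'   `threshold`, `trait_name`.
#' @export
interval_scan <- function(map, bins, trait, step = 2, threshold = 2.5,
                          cofactors = NULL, cofactor_window = 10) {
  if (is.data.frame(trait)) {
    y <- stats::setNames(trait[[2]], trait[[1]])
    trait_name <- names(trait)[2]
  } else {
    y <- trait
    trait_name <- "trait"
  }
  lines <- rownames(bins$geno)
  y <- y[lines]
  if (sum(is.finite(y)) < 30) stop_mm("need at least 30 phenotyped lines")
  M <- map$map
  geno01 <- matrix(NA_real_, nrow(bins$geno), ncol(bins$geno))
  geno01[bins$geno == "P2"] <- 1
  geno01[bins$geno == "P1"] <- 0
  cof_cm <- if (length(cofactors))
    stats::setNames(M$cm[match(cofactors, M$bin)], cofactors) else NULL
  cof_chrom <- if (length(cofactors)) M$chrom[match(cofactors, M$bin)] else NULL

  prof <- list()
  for (ch in unique(M$chrom)) {
    mc <- M[M$chrom == ch, , drop = FALSE]
    bcols <- mc$bin
    cm <- mc$cm
    grid <- unique(c(seq(0, max(cm), by = step), max(cm)))
    # expected P2 probability per line x grid position
    X <- matrix(NA_real_, length(lines), length(grid))
    for (i in seq_along(lines)) {
      gi <- geno01[i, bcols]
      inf <- which(!is.na(gi))
      if (!length(inf)) next
      li <- findInterval(grid, cm[inf])        # nearest informative left
      ri <- li + 1L
      has_l <- li >= 1L
      has_r <- ri <= length(inf)
      p <- rep(NA_real_, length(grid))
      both <- has_l & has_r
      if (any(both)) {
        d1 <- grid[both] - cm[inf[li[both]]]
        d2 <- cm[inf[ri[both]]] - grid[both]
        r1 <- kosambi_inv(d1); r2 <- kosambi_inv(d2)
        r12 <- r1 + r2 - 2 * r1 * r2
        gl <- gi[inf[li[both]]]; gr <- gi[inf[ri[both]]]
        pp <- numeric(sum(both))
        same2 <- gl == 1 & gr == 1
        pp[same2] <- ((1 - r1) * (1 - r2) / (1 - r12))[same2]
        same0 <- gl == 0 & gr == 0
        pp[same0] <- (r1 * r2 / (1 - r12))[same0]
        lr <- gl == 1 & gr == 0
        pp[lr] <- ((1 - r1) * r2 / r12)[lr]
        rl <- gl == 0 & gr == 1
        pp[rl] <- (r1 * (1 - r2) / r12)[rl]
        zero <- r12 == 0
        pp[zero] <- gl[zero]
        p[both] <- pp
      }
      only_l <- has_l & !has_r
      if (any(only_l)) {
        r1 <- kosambi_inv(grid[only_l] - cm[inf[li[only_l]]])
        gl <- gi[inf[li[only_l]]]
        p[only_l] <- ifelse(gl == 1, 1 - r1, r1)
      }
      only_r <- !has_l & has_r
      if (any(only_r)) {
        r2 <- kosambi_inv(cm[inf[ri[only_r]]] - grid[only_r])
        gr <- gi[inf[ri[only_r]]]
        p[only_r] <- ifelse(gr == 1, 1 - r2, r2)
      }
      X[i, ] <- p
    }
    lod <- rep(NA_real_, length(grid))
    nn <- integer(length(grid))
    eff <- rep(NA_real_, length(grid))
    for (j in seq_along(grid)) {
      x <- X[, j]
      ok <- !is.na(x) & is.finite(y)
      n <- sum(ok)
      nn[j] <- n
      if (n < 3 || stats::var(x[ok]) == 0) next
      cof_x <- NULL
      if (length(cofactors)) {
        use <- !(cof_chrom == ch & abs(cof_cm - grid[j]) < cofactor_window)
        if (any(use)) {
          cof_x <- geno01[, cofactors[use], drop = FALSE]
          cof_x[is.na(cof_x)] <- 0.5  # neutral fill for missing cofactor calls
          cof_x <- cof_x[ok, , drop = FALSE]
        }
      }
      yy <- y[ok]; xx <- x[ok]
      if (is.null(cof_x)) {
        r2 <- stats::cor(xx, yy)^2
        lod[j] <- -(n / 2) * log10(1 - r2)
        eff[j] <- stats::coef(stats::lm.fit(cbind(1, xx), yy))[2] / 2
      } else {
        X0 <- cbind(1, cof_x)
        X1 <- cbind(X0, xx)
        rss0 <- sum(stats::lm.fit(X0, yy)$residuals^2)
        fit1 <- stats::lm.fit(X1, yy)
        rss1 <- sum(fit1$residuals^2)
        lod[j] <- (n / 2) * log10(rss0 / rss1)
        eff[j] <- fit1$coefficients[ncol(X1)] / 2
      }
    }
    bp <- stats::approx(cm, mc$bp, xout = grid, rule = 2, ties = "ordered")$y
    prof[[ch]] <- data.frame(chrom = ch, cm = grid, bp = bp, lod = lod,
                             n = nn, effect = eff, stringsAsFactors = FALSE)
  }
  profile <- do.call(rbind, prof)
  rownames(profile) <- NULL
  qtl <- find_peaks(profile, threshold)
  structure(list(profile = profile, qtl = qtl, threshold = threshold,
                 trait_name = trait_name),
            class = "qtl_scan")
}

# Contiguous above-threshold runs -> one QTL each, with 1-LOD-drop intervals.
find_peaks <- function(profile, threshold) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    above <- !is.na(p$lod) & p$lod > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      seg <- starts[k]:ends[k]
      pk <- seg[which.max(p$lod[seg])]
      peak_lod <- p$lod[pk]
      lo <- pk
      while (lo > 1 && !is.na(p$lod[lo - 1]) && p$lod[lo - 1] >= peak_lod - 1)
        lo <- lo - 1
      hi <- pk
      while (hi < nrow(p) && !is.na(p$lod[hi + 1]) && p$lod[hi + 1] >= peak_lod - 1)
        hi <- hi + 1
      n <- p$n[pk]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, peak_cm = p$cm[pk], peak_bp = p$bp[pk], lod = peak_lod,
        ci_lo_cm = p$cm[lo], ci_hi_cm = p$cm[hi],
        ci_lo_bp = min(p$bp[lo], p$bp[hi]), ci_hi_bp = max(p$bp[lo], p$bp[hi]),
        effect = p$effect[pk], pve = 1 - 10^(-2 * peak_lod / n),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), peak_cm = numeric(0),
                      peak_bp = numeric(0), lod = numeric(0),
                      ci_lo_cm = numeric(0), ci_hi_cm = numeric(0),
                      ci_lo_bp = numeric(0), ci_hi_bp = numeric(0),
                      effect = numeric(0), pve = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Forward-stepwise cofactor selection on bin genotypes
#'
#' Picks up to `n_max` cofactor bins by forward stepwise regression of the
#' trait on single-bin genotypes, never adding a bin within `window` cM of an
#' already selected one on the same chromosome.
#'
#' @inheritParams interval_scan
#' @param n_max Maximum number of cofactors (default 5).
#' @param window Minimum cM separation between cofactors.
#' @return Integer vector of selected bin indices (columns of `bins$geno`).
#' @export
select_cofactors <- function(map, bins, trait, n_max = 5, window = 10) {
  if (is.data.frame(trait)) trait <- stats::setNames(trait[[2]], trait[[1]])
  y <- trait[rownames(bins$geno)]
  M <- map$map
  x01 <- matrix(NA_real_, nrow(bins$geno), ncol(bins$geno))
  x01[bins$geno == "P2"] <- 1
  x01[bins$geno == "P1"] <- 0
  x01[is.na(x01)] <- 0.5
  chosen <- integer(0)
  Xc <- matrix(1, length(y), 1)
  for (step in seq_len(n_max)) {
    rss_base <- sum(stats::lm.fit(Xc, y)$residuals^2)
    best <- NA_integer_; best_rss <- rss_base
    for (b in seq_len(ncol(x01))) {
      if (b %in% chosen) next
      mb <- match(b, M$bin)
      if (length(chosen) &&
          any(M$chrom[match(chosen, M$bin)] == M$chrom[mb] &
              abs(M$cm[match(chosen, M$bin)] - M$cm[mb]) < window)) next
      rss <- sum(stats::lm.fit(cbind(Xc, x01[, b]), y)$residuals^2)
      if (rss < best_rss) { best_rss <- rss; best <- b }
    }
    if (is.na(best) || best_rss > 0.99 * rss_base) break
    chosen <- c(chosen, best)
    Xc <- cbind(Xc, x01[, best])
  }
  chosen
}

#' Crossover frequency of QTL support intervals
#'
#' @param scan A `qtl_scan` (or a data frame with `chrom`, `ci_lo_bp`,
#'   `ci_hi_bp`).
#' @param cos Crossover events.
#' @param n_lines Number of lines.
#' @return The QTL table with an added `interval_cm_per_mb` column:
#'   100 x (CO midpoints in the interval / n_lines) / interval Mb.
#' @export
qtl_co_frequency <- function(scan, cos, n_lines) {
  q <- if (inherits(scan, "qtl_scan")) scan$qtl else scan
  if (!nrow(q)) return(cbind(q, interval_cm_per_mb = numeric(0)))
  span <- q$ci_hi_bp - q$ci_lo_bp
  if (any(span <= 0)) stop_mm("zero-length QTL interval")
  q$interval_cm_per_mb <- vapply(seq_len(nrow(q)), function(i) {
    n_co <- sum(cos$chrom == q$chrom[i] & cos$midpoint >= q$ci_lo_bp[i] &
                  cos$midpoint <= q$ci_hi_bp[i])
    100 * (n_co / n_lines) / (span[i] / 1e6)
  }, numeric(1))
  q
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("qtl_scan (%s): %d positions, %d QTL above LOD %.1f\n",
              x$trait_name, nrow(x$profile), nrow(x$qtl), x$threshold))
  if (nrow(x$qtl))
    print(x$qtl[, c("chrom", "peak_cm", "lod", "pve")], digits = 3)
  invisible(x)
}

#' Plot a LOD profile
#'
#' @param scan A `qtl_scan`.
#' @export
plot_lod <- function(scan) {
  p <- scan$profile
  chroms <- unique(p$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) max(p$cm[p$chrom == ch]),
                             numeric(1))))
  x <- p$cm + offs[match(p$chrom, chroms)]
  graphics::plot(x, p$lod, type = "l", xlab = "map position (cM)",
                 ylab = "LOD", main = scan$trait_name)
  graphics::abline(h = scan$threshold, col = "firebrick", lty = 2)
  graphics::abline(v = offs[-1], col = "grey85")
  invisible(NULL)
}
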