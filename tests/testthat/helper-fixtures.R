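# Shared fixture builders (everything generated in code; no stored data).

# Minimal geno_matrix from a character matrix of A/B/H/- style codes.
toy_geno <- function(codes, pos = NULL, chrom = "A01", chrom_len = NULL,
                     parents = NULL) {
  lut <- c(A = "P1", B = "P2", H = "HET", `-` = "MISSING",
           P1 = "P1", P2 = "P2", HET = "HET", MISSING = "MISSING")
  calls <- matrix(lut[codes], nrow = nrow(codes),
                  dimnames = list(rownames(codes) %||%
                                    sprintf("L%02d", seq_len(nrow(codes))),
                                  NULL))
  n <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  map <- data.frame(marker_id = sprintf("m%03d", seq_len(n)),
                    chrom = rep(chrom, length.out = n), pos = pos,
                    stringsAsFactors = FALSE)
  colnames(calls) <- map$marker_id
  ci <- NULL
  if (!is.null(chrom_len))
    ci <- data.frame(chrom = unique(map$chrom), length = chrom_len,
                     centromere = round(chrom_len / 2))
  if (!is.null(parents)) {
    parents <- matrix(lut[parents], nrow = 2,
                      dimnames = list(c("p1", "p2"), map$marker_id))
  }
  meiomap::geno_matrix(calls, map, chrom_info = ci, parents = parents)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-chromosome genome model with a flat or piecewise lambda (cM/Mb).
flat_genome <- function(length_bp = 5e7, cm_per_mb = 2, chrom = "A01") {
  meiomap::genome_model(chrom, length_bp,
                        profiles = stats::setNames(list(list(
                          breaks = c(0, length_bp),
                          rate = cm_per_mb)), chrom))
}

piecewise_genome <- function(breaks, rates, chrom = "A01") {
  meiomap::genome_model(chrom, breaks[length(breaks)],
                        profiles = stats::setNames(list(list(
                          breaks = breaks, rate = rates)), chrom))
}

# Brute-force per-line crossover caller: run-length encoding over informative
# marker calls. Independent of the bin-based implementation.
brute_force_cos <- function(g) {
  out <- list()
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    pos <- g$map$pos[idx]
    for (i in seq_len(nrow(g$calls))) {
      v <- g$calls[i, idx]
      inf <- which(v == "P1" | v == "P2")
      if (length(inf) < 2) next
      vals <- v[inf]
      sw <- which(vals[-1] != vals[-length(vals)])
      for (t in sw) {
        out[[length(out) + 1]] <- data.frame(
          line = rownames(g$calls)[i], chrom = ch,
          left_bp = pos[inf[t]], right_bp = pos[inf[t + 1]],
          from = vals[t], to = vals[t + 1], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(line = character(0), chrom = character(0),
                      left_bp = numeric(0), right_bp = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$line, df$chrom, df$left_bp), ]
}

# Random small genotype matrix (no map structure needed beyond positions).
random_matrix <- function(n_lines, n_markers, p_missing = 0.1, seed = 1) {
  set.seed(seed)
  codes <- matrix(sample(c("P1", "P2", "MISSING"), n_lines * n_markers,
                         replace = TRUE,
                         prob = c((1 - p_missing) / 2, (1 - p_missing) / 2,
                                  p_missing)),
                  nrow = n_lines)
  toy_geno(codes, pos = sort(sample.int(n_markers * 2000, n_markers)))
}
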