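#' Clean per-line genotype calls before segmentation
#'
#' Two rules, applied per line and chromosome: (1) HET calls are set to
#' MISSING — a DH line is homozygous by construction, so a HET call is a
#' genotyping artifact; (2) any maximal run of identical homozygous calls
#' shorter than `min_run` markers that is flanked on both sides by the same
#' opposite genotype is set to MISSING. At ~62 kb marker spacing a
#' single-marker genotype island would imply a double crossover within
#' ~124 kb, which is implausible under interference; such islands are treated
#' as genotyping errors.
#'
#' @param g A [geno_matrix()].
#' @param min_run Minimum credible run length in markers (default 2).
#' @return A cleaned [geno_matrix()].
#' @export
clean_line_calls <- function(g, min_run = 2) {
  if (min_run < 1) stop_mm("min_run must be >= 1")
  calls <- g$calls
  calls[calls == "HET"] <- "MISSING"
  chrom_idx <- split(seq_len(ncol(calls)),
                     factor(g$map$chrom, unique(g$map$chrom)))
  for (idx in chrom_idx) {
    for (i in seq_len(nrow(calls))) {
      v <- calls[i, idx]
      inf <- which(v != "MISSING")
      if (length(inf) < 3L) next
      r <- rle(v[inf])
      if (length(r$lengths) < 3L) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      k <- which(r$lengths < min_run)
      k <- k[k > 1L & k < length(r$lengths)]
      if (length(k)) {
        # flanks of an interior run are always the opposite genotype and equal
        drop <- unlist(lapply(k, function(j) inf[starts[j]:ends[j]]))
        v[drop] <- "MISSING"
        calls[i, idx] <- v
      }
    }
  }
  geno_matrix(calls, g$map, chrom_info = g$chrom_info, parents = g$parents)
}

#' Segment chromosomes into population-level recombination bins
#'
#' A bin is a maximal run of consecutive markers with an identical genotype
#' pattern across the whole population: a bin boundary is placed wherever at
#' least one line switches parental genotype. When a line's switch falls in a
#' run of MISSING calls, the ambiguous markers are assigned to the closest
#' flanking informative marker by bp distance (ties toward the left), so the
#' boundary lands at that split. Each bin's per-line genotype is the consensus
#' of the line's informative calls in the bin (`CONFLICT`, with a warning, if
#' both parental alleles appear — this should not survive
#' [clean_line_calls()]); lines with no informative call in a bin are
#' `MISSING` at that bin and thereby adopt the surrounding consensus
#' downstream.
#'
#' @param g A cleaned [geno_matrix()].
#' @return An object of class `bin_set`: list with `bins` (data frame `bin`,
#'   `chrom`, `first_marker`, `last_marker` (column indices into `g$calls`),
#'   `start`, `end` (first/last marker bp), `phys_start`, `phys_end` (bp span
#'   tiling the chromosome, boundaries at inter-marker midpoints)), `geno`
#'   (lines x bins genotype matrix), and the originating `map`, `chrom_info`,
#'   `calls`.
#' @export
call_bins <- function(g) {
  map <- g$map
  calls <- g$calls
  chroms <- unique(map$chrom)
  bin_rows <- list()
  bin_of_marker <- integer(ncol(calls))
  n_bins <- 0L
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    if (!length(idx)) stop_mm("chromosome with no markers: ", ch)
    pos <- map$pos[idx]
    bounds <- logical(length(idx) - 1L)  # TRUE = boundary after marker t
    for (i in seq_len(nrow(calls))) {
      v <- calls[i, idx]
      inf <- which(v == "P1" | v == "P2")
      if (length(inf) < 2L) next
      vals <- v[inf]
      sw <- which(vals[-1] != vals[-length(vals)])
      for (t in sw) {
        a <- inf[t]; b <- inf[t + 1L]
        if (b == a + 1L) {
          bounds[a] <- TRUE
        } else {
          between <- (a + 1L):(b - 1L)
          left <- (pos[between] - pos[a]) <= (pos[b] - pos[between])
          bounds[a + sum(left)] <- TRUE
        }
      }
    }
    cut_after <- which(bounds)
    starts <- c(1L, cut_after + 1L)
    ends <- c(cut_after, length(idx))
    L <- if (!is.null(g$chrom_info)) {
      g$chrom_info$length[match(ch, g$chrom_info$chrom)]
    } else max(pos)
    # physical tiling: boundaries midway between flanking markers of a cut
    cut_bp <- floor((pos[cut_after] + pos[cut_after + 1L]) / 2)
    phys_start <- c(1, cut_bp + 1)
    phys_end <- c(cut_bp, L)
    for (b in seq_along(starts)) {
      n_bins <- n_bins + 1L
      bin_of_marker[idx[starts[b]:ends[b]]] <- n_bins
      bin_rows[[n_bins]] <- data.frame(
        bin = n_bins, chrom = ch,
        first_marker = idx[starts[b]], last_marker = idx[ends[b]],
        start = pos[starts[b]], end = pos[ends[b]],
        phys_start = phys_start[b], phys_end = phys_end[b],
        stringsAsFactors = FALSE)
    }
  }
  bins <- do.call(rbind, bin_rows)
  grp <- factor(bin_of_marker, levels = seq_len(n_bins))
  cnt_p1 <- t(rowsum((t(calls) == "P1") + 0, grp))
  cnt_p2 <- t(rowsum((t(calls) == "P2") + 0, grp))
  geno <- matrix("MISSING", nrow = nrow(calls), ncol = n_bins,
                 dimnames = list(rownames(calls), NULL))
  geno[cnt_p1 > 0 & cnt_p2 == 0] <- "P1"
  geno[cnt_p2 > 0 & cnt_p1 == 0] <- "P2"
  conf <- cnt_p1 > 0 & cnt_p2 > 0
  if (any(conf)) {
    geno[conf] <- "CONFLICT"
    w <- which(conf, arr.ind = TRUE)
    warn_mm("conflicting calls within bin(s): ",
            paste(utils::head(paste0(rownames(calls)[w[, 1]], "/bin", w[, 2]), 5),
                  collapse = ", "),
            if (nrow(w) > 5) sprintf(" (+%d more)", nrow(w) - 5) else "")
  }
  structure(list(bins = bins, geno = geno, map = map,
                 chrom_info = g$chrom_info, calls = calls),
            class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("bin_set: %d bins on %d chromosome(s), %d lines\n",
              nrow(x$bins), length(unique(x$bins$chrom)), nrow(x$geno)))
  invisible(x)
}

#' Call crossover events at bin junctions
#'
#' For each line, each pair of successive informative bins with opposite
#' parental genotypes (intervening MISSING bins are skipped) yields one
#' crossover. The event interval is bounded by the line's own flanking
#' informative markers: `left_bp` is the last marker of the left bin carrying
#' the left genotype, `right_bp` the first marker of the right bin carrying
#' the right genotype, so tract lengths shrink to a single inter-marker gap
#' when markers are adjacent. The midpoint (integer floor) is the positional
#' representative used by all window and gene analyses.
#'
#' @param bins A `bin_set` from [call_bins()].
#' @return Data frame of class `co_events`: `line`, `chrom`, `left_bp`,
#'   `right_bp`, `midpoint`, `tract_length`, `from`, `to`.
#' @export
call_crossovers <- function(bins) {
  B <- bins$bins
  geno <- bins$geno
  calls <- bins$calls
  out <- vector("list", nrow(geno))
  for (i in seq_len(nrow(geno))) {
    gi <- geno[i, ]
    res <- list()
    for (ch in unique(B$chrom)) {
      bidx <- which(B$chrom == ch)
      inf <- bidx[gi[bidx] %in% c("P1", "P2")]
      if (length(inf) < 2L) next
      vals <- gi[inf]
      sw <- which(vals[-1] != vals[-length(vals)])
      for (t in sw) {
        bl <- inf[t]; br <- inf[t + 1L]
        lmk <- B$first_marker[bl]:B$last_marker[bl]
        rmk <- B$first_marker[br]:B$last_marker[br]
        lpos <- bins$map$pos[lmk[calls[i, lmk] == vals[t]]]
        rpos <- bins$map$pos[rmk[calls[i, rmk] == vals[t + 1L]]]
        res[[length(res) + 1L]] <- data.frame(
          line = rownames(geno)[i], chrom = ch,
          left_bp = max(lpos), right_bp = min(rpos),
          from = vals[t], to = vals[t + 1L], stringsAsFactors = FALSE)
      }
    }
    if (length(res)) out[[i]] <- do.call(rbind, res)
  }
  co <- do.call(rbind, out)
  if (is.null(co))
    co <- data.frame(line = character(0), chrom = character(0),
                     left_bp = numeric(0), right_bp = numeric(0),
                     from = character(0), to = character(0),
                     stringsAsFactors = FALSE)
  co$midpoint <- floor((co$left_bp + co$right_bp) / 2)
  co$tract_length <- co$right_bp - co$left_bp
  rownames(co) <- NULL
  co <- co[, c("line", "chrom", "left_bp", "right_bp", "midpoint",
               "tract_length", "from", "to")]
  class(co) <- c("co_events", "data.frame")
  co
}

#' Per-line crossover counts and replacement rate
#'
#' The replacement rate of a line is the fraction of the physical genome
#' (informative bins only, using the bins' tiling bp spans) carrying the
#' non-background parent's genotype.
#'
#' @param bins A `bin_set`.
#' @param cos Crossover events from [call_crossovers()].
#' @param background_parent `"P1"` or `"P2"`.
#' @return Data frame: `line`, `n_co`, `replacement_rate`, plus one
#'   `co_<chrom>` column per chromosome.
#' @export
summarize_lines <- function(bins, cos, background_parent = "P1") {
  stopifnot(background_parent %in% c("P1", "P2"))
  other <- other_parent(background_parent)
  lines <- rownames(bins$geno)
  len <- bins$bins$phys_end - bins$bins$phys_start + 1
  inf <- bins$geno == "P1" | bins$geno == "P2"
  tot <- as.numeric(inf %*% len)
  repl <- as.numeric((bins$geno == other) %*% len)
  rate <- ifelse(tot > 0, repl / tot, NA_real_)
  per_chrom <- table(factor(cos$line, levels = lines),
                     factor(cos$chrom, levels = unique(bins$bins$chrom)))
  out <- data.frame(line = lines, n_co = as.integer(rowSums(per_chrom)),
                    replacement_rate = rate, stringsAsFactors = FALSE)
  pc <- as.data.frame.matrix(per_chrom)
  names(pc) <- paste0("co_", names(pc))
  cbind(out, pc)
}

#' Write bins, genotypes and crossover events as TSV
#'
#' @param bins A `bin_set`.
#' @param path Output path; one row per bin, bin metadata followed by one
#'   genotype column per line.
#' @export
write_bins <- function(bins, path) {
  df <- cbind(bins$bins, as.data.frame(t(bins$geno), stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @param cos Crossover events.
#' @export
write_crossovers <- function(cos, path) {
  utils::write.table(cos, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
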