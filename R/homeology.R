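#' Detect homologous chromosome segments from gene-pair collinearity
#'
#' A homologous segment is a run of more than `min_run - 1` consecutive
#' homologous gene pairs: ordered by gene index on the first chromosome, a run
#' extends while successive pairs advance by at most `max_gap + 1` gene
#' indices on both chromosomes, monotonically, in either orientation (the
#' orientation is fixed by the first advancing step of the run).
#'
#' @param pairs Data frame `gene_a`, `gene_b` of homologous gene ids.
#' @param genes Gene annotation covering both sides (`gene_id`, `chrom`,
#'   `start`, `end`); gene indices are ranks by start position within each
#'   chromosome.
#' @param min_run Minimum pairs per reported segment (default 11, i.e.
#'   strictly more than 10).
#' @param max_gap Skipped gene indices tolerated between successive pairs
#'   (default 0 = strictly consecutive).
#' @return Data frame of class `homologous_segments`: `chrom_a`, `start_a`,
#'   `end_a`, `chrom_b`, `start_b`, `end_b` (bp spans), `n_pairs`,
#'   `orientation` ("same"/"inverted").
#' @export
find_homologous_segments <- function(pairs, genes, min_run = 11, max_gap = 0) {
  if (anyDuplicated(c(pairs$gene_a, pairs$gene_b)))
    warn_mm("gene(s) appear in multiple homolog pairs; runs use the pair list as given")
  o <- order(factor(genes$chrom, unique(genes$chrom)), genes$start)
  genes <- genes[o, , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(genes)), genes$chrom, FUN = seq_along)
  look <- function(id, what) {
    m <- match(id, genes$gene_id)
    if (anyNA(m)) stop_mm("gene in pair table missing from annotation: ",
                          id[which(is.na(m))[1]])
    switch(what, chrom = genes$chrom[m], idx = idx[m],
           start = genes$start[m], end = genes$end[m])
  }
  df <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                   chrom_a = look(pairs$gene_a, "chrom"),
                   chrom_b = look(pairs$gene_b, "chrom"),
                   ia = look(pairs$gene_a, "idx"),
                   ib = look(pairs$gene_b, "idx"),
                   stringsAsFactors = FALSE)
  segs <- list()
  for (key in unique(paste(df$chrom_a, df$chrom_b))) {
    d <- df[paste(df$chrom_a, df$chrom_b) == key, , drop = FALSE]
    d <- d[order(d$ia, d$ib), , drop = FALSE]
    run <- 1L
    dir <- 0L  # 0 undecided, +1 same, -1 inverted
    starts <- 1L
    emit <- function(from, to, dir) {
      if (to - from + 1L < min_run) return(NULL)
      sub <- d[from:to, , drop = FALSE]
      data.frame(chrom_a = sub$chrom_a[1],
                 start_a = min(look(sub$gene_a, "start")),
                 end_a = max(look(sub$gene_a, "end")),
                 chrom_b = sub$chrom_b[1],
                 start_b = min(look(sub$gene_b, "start")),
                 end_b = max(look(sub$gene_b, "end")),
                 n_pairs = nrow(sub),
                 orientation = if (dir < 0) "inverted" else "same",
                 stringsAsFactors = FALSE)
    }
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      da <- d$ia[i] - d$ia[i - 1L]
      db <- d$ib[i] - d$ib[i - 1L]
      step_ok <- da >= 1L && da <= max_gap + 1L && abs(db) >= 1L &&
        abs(db) <= max_gap + 1L && (dir == 0L || sign(db) == dir)
      if (step_ok) {
        if (dir == 0L) dir <- sign(db)
      } else {
        segs[[length(segs) + 1L]] <- emit(starts, i - 1L, dir)
        starts <- i
        dir <- 0L
      }
    }
    segs[[length(segs) + 1L]] <- emit(starts, nrow(d), dir)
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom_a = character(0), start_a = numeric(0), end_a = numeric(0),
               chrom_b = character(0), start_b = numeric(0), end_b = numeric(0),
               n_pairs = integer(0), orientation = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("homologous_segments", "data.frame")
  out
}

#' Flag candidate homoeologous-exchange lines
#'
#' A screening heuristic, not a proof of exchange: for every line and every
#' homologous segment whose spans on both chromosomes intersect crossover hot
#' regions, the line is flagged when it carries complementary parental
#' genotype runs over the two spans (P2 over span A and P1 over span B, or
#' vice versa) whose bp lengths differ by at most `tol` relative
#' (`max/min - 1 <= tol`). Each run must fully cover its segment span.
#'
#' @param bins A `bin_set` ([call_bins()]).
#' @param segments Homologous segments ([find_homologous_segments()]).
#' @param hot Hot regions ([detect_hot_regions()]).
#' @param tol Relative length tolerance (default 0.25).
#' @return Data frame of class `exchange_candidates`: `line`, segment
#'   coordinates, `geno_a`, `geno_b`, `length_a`, `length_b`, `length_ratio`.
#' @export
flag_exchange_candidates <- function(bins, segments, hot, tol = 0.25) {
  hits <- function(ch, s, e)
    any(hot$chrom == ch & hot$start <= e & hot$end > s)
  keep <- vapply(seq_len(nrow(segments)), function(i)
    hits(segments$chrom_a[i], segments$start_a[i], segments$end_a[i]) &&
    hits(segments$chrom_b[i], segments$start_b[i], segments$end_b[i]),
    logical(1))
  segments <- segments[keep, , drop = FALSE]
  B <- bins$bins
  out <- list()
  # per-line genotype runs (merged consecutive bins with identical genotype)
  line_runs <- function(i, ch) {
    bidx <- which(B$chrom == ch)
    v <- bins$geno[i, bidx]
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    data.frame(geno = r$values,
               start = B$phys_start[bidx[starts]],
               end = B$phys_end[bidx[ends]], stringsAsFactors = FALSE)
  }
  covering_run <- function(runs, s, e) {
    hit <- runs$geno %in% c("P1", "P2") & runs$start <= s & runs$end >= e
    if (!any(hit)) return(NULL)
    runs[which(hit)[1], , drop = FALSE]
  }
  for (i in seq_len(nrow(bins$geno))) {
    for (k in seq_len(nrow(segments))) {
      ra <- covering_run(line_runs(i, segments$chrom_a[k]),
                         segments$start_a[k], segments$end_a[k])
      rb <- covering_run(line_runs(i, segments$chrom_b[k]),
                         segments$start_b[k], segments$end_b[k])
      if (is.null(ra) || is.null(rb) || ra$geno == rb$geno) next
      la <- ra$end - ra$start + 1
      lb <- rb$end - rb$start + 1
      if (max(la, lb) / min(la, lb) - 1 > tol) next
      out[[length(out) + 1L]] <- data.frame(
        line = rownames(bins$geno)[i],
        chrom_a = segments$chrom_a[k], start_a = segments$start_a[k],
        end_a = segments$end_a[k],
        chrom_b = segments$chrom_b[k], start_b = segments$start_b[k],
        end_b = segments$end_b[k],
        geno_a = ra$geno, geno_b = rb$geno,
        length_a = la, length_b = lb, length_ratio = la / lb,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(line = character(0), chrom_a = character(0),
               start_a = numeric(0), end_a = numeric(0),
               chrom_b = character(0), start_b = numeric(0),
               end_b = numeric(0), geno_a = character(0),
               geno_b = character(0), length_a = numeric(0),
               length_b = numeric(0), length_ratio = numeric(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("exchange_candidates", "data.frame")
  res
}

#' Export homologous segments as a circos-style links file
#'
#' @param segments Homologous segments.
#' @param path Output path (chrom_a start_a end_a chrom_b start_b end_b).
#' @export
write_links <- function(segments, path) {
  utils::write.table(segments[, c("chrom_a", "start_a", "end_a",
                                  "chrom_b", "start_b", "end_b")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
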