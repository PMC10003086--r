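#' Construct a genotype matrix object
#'
#' The central container of the pipeline: DH lines x physically ordered
#' markers, with calls in the fixed internal alphabet `P1`, `P2`, `HET`,
#' `MISSING`. Markers are sorted by (chromosome, position); input call
#' alphabets are translated at read time so downstream code never sees them.
#'
#' @param calls Character matrix (lines x markers) over the internal alphabet;
#'   rownames are line ids, colnames marker ids.
#' @param map Data frame with columns `marker_id`, `chrom`, `pos` (1-based bp).
#' @param chrom_info Optional data frame `chrom`, `length`, `centromere`.
#' @param parents Optional 2 x markers character matrix of parental calls.
#' @return An object of class `geno_matrix` (list: `calls`, `map`,
#'   `chrom_info`, `parents`).
#' @export
geno_matrix <- function(calls, map, chrom_info = NULL, parents = NULL) {
  if (!all(c("marker_id", "chrom", "pos") %in% names(map)))
    stop_mm("map needs columns marker_id, chrom, pos")
  if (anyDuplicated(map$marker_id))
    stop_mm("duplicated marker id: ",
            map$marker_id[duplicated(map$marker_id)][1])
  if (anyDuplicated(rownames(calls)))
    stop_mm("duplicated line ids")
  o <- order(factor(map$chrom, levels = unique(map$chrom)), map$pos)
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (anyDuplicated(p))
      stop_mm("duplicated marker position on ", ch)
  }
  if (!is.null(chrom_info)) {
    m <- match(map$chrom, chrom_info$chrom)
    if (anyNA(m)) stop_mm("marker chromosome missing from chrom_info")
    if (any(map$pos > chrom_info$length[m]))
      stop_mm("marker position beyond chromosome length")
  }
  calls <- calls[, map$marker_id, drop = FALSE]
  bad <- !(calls %in% CALL_CODES)
  if (any(bad)) stop_mm("invalid genotype code(s): ",
                        paste(unique(calls[bad]), collapse = ", "))
  if (!is.null(parents)) parents <- parents[, map$marker_id, drop = FALSE]
  structure(list(calls = calls, map = map, chrom_info = chrom_info,
                 parents = parents),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  tab <- table(factor(x$calls, levels = CALL_CODES))
  cat("  calls:", paste(names(tab), format(as.numeric(tab) / length(x$calls),
                                           digits = 3), collapse = ", "), "\n")
  invisible(x)
}

default_alphabet <- function() c(P1 = "A", P2 = "B", HET = "H", MISSING = "-")

#' Read a marker map table
#'
#' @param path TSV with header columns `marker_id`, `chrom`, `pos`.
#' @return Data frame sorted by (chrom, pos).
#' @export
read_marker_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop_mm("marker map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$marker_id))
    stop_mm("duplicated marker id: ", map$marker_id[duplicated(map$marker_id)][1])
  map[order(factor(map$chrom, unique(map$chrom)), map$pos), , drop = FALSE]
}

#' Read chromosome metadata
#'
#' @param path TSV with header columns `chrom`, `length` and optionally
#'   `centromere`.
#' @return Data frame.
#' @export
read_chrom_info <- function(path) {
  ci <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(ci)))
    stop_mm("chromosome info needs columns chrom, length")
  if (is.null(ci$centromere)) ci$centromere <- round(ci$length / 2)
  ci
}

#' Read a genotype matrix from disk
#'
#' The matrix file is a delimited table whose first column holds line ids and
#' whose remaining column names are marker ids; calls are translated from a
#' configurable input alphabet (default `A`/`B`/`H`/`-`) to the internal
#' `P1`/`P2`/`HET`/`MISSING` codes and re-ordered to ascending map position.
#'
#' @param map_path Marker map TSV (see [read_marker_map()]).
#' @param matrix_path Genotype table (TSV by default).
#' @param alphabet Named character vector mapping internal codes to input
#'   symbols, e.g. `c(P1 = "A", P2 = "B", HET = "H", MISSING = "-")`.
#' @param parent_ids Optional length-2 character vector of line ids holding
#'   the two parents; their rows are moved to the `parents` slot.
#' @param chrom_info_path Optional chromosome metadata TSV.
#' @param sep Field separator of the matrix file.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(map_path, matrix_path,
                           alphabet = default_alphabet(), parent_ids = NULL,
                           chrom_info_path = NULL, sep = "\t") {
  map <- read_marker_map(map_path)
  raw <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  unknown <- setdiff(colnames(m), map$marker_id)
  if (length(unknown))
    stop_mm("marker absent from map: ", unknown[1])
  # translate input alphabet -> internal codes
  lut <- stats::setNames(names(alphabet), alphabet)
  bad <- which(!(m %in% names(lut)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop_mm(sprintf("unparseable call '%s' at line %s, marker %s",
                    m[bad[1]], rownames(m)[rc[1]], colnames(m)[rc[2]]))
  }
  calls <- matrix(lut[m], nrow = nrow(m), dimnames = dimnames(m))
  parents <- NULL
  if (!is.null(parent_ids)) {
    miss <- setdiff(parent_ids, rownames(calls))
    if (length(miss)) stop_mm("parent line not in matrix: ", miss[1])
    parents <- calls[parent_ids, , drop = FALSE]
    calls <- calls[setdiff(rownames(calls), parent_ids), , drop = FALSE]
  }
  ci <- if (!is.null(chrom_info_path)) read_chrom_info(chrom_info_path) else NULL
  map <- map[map$marker_id %in% colnames(calls), , drop = FALSE]
  geno_matrix(calls, map, chrom_info = ci, parents = parents)
}

#' Write a genotype matrix (and its marker map) to disk
#'
#' Inverse of [read_genotypes()]: translates internal codes back to the given
#' alphabet. `read_genotypes(write_genotypes(g))` reproduces the call matrix
#' exactly.
#'
#' @param g A [geno_matrix()].
#' @param map_path,matrix_path Output paths.
#' @inheritParams read_genotypes
#' @return Invisibly, `g`.
#' @export
write_genotypes <- function(g, map_path, matrix_path,
                            alphabet = default_alphabet(), sep = "\t") {
  utils::write.table(g$map[, c("marker_id", "chrom", "pos")], map_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- g$calls
  if (!is.null(g$parents)) out <- rbind(out, g$parents)
  m <- matrix(alphabet[out], nrow = nrow(out), dimnames = dimnames(out))
  df <- data.frame(line = rownames(m), m, stringsAsFactors = FALSE,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(g)
}

#' Read a gene annotation table
#'
#' @param path Annotation file.
#' @param format `"tsv"` for a header table with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (1-based inclusive), or `"bed"` for 6-column BED
#'   (0-based half-open; converted to 1-based inclusive on read).
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = b[[4]], chrom = b[[1]],
                        start = b[[2]] + 1L, end = b[[3]],
                        strand = b[[6]], stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(genes)))
      stop_mm("annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (any(genes$start > genes$end)) stop_mm("gene start > end")
  if (!all(genes$strand %in% c("+", "-"))) stop_mm("strand must be + or -")
  genes
}

new_qc_report <- function(axis, n_input, retained, dropped) {
  structure(list(axis = axis, n_input = n_input,
                 n_retained = n_input - nrow(dropped),
                 dropped = dropped,
                 counts = if (nrow(dropped)) table(dropped$reason) else table(character(0)),
                 retained = retained),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC (%s): %d in, %d retained, %d dropped\n",
              x$axis, x$n_input, x$n_retained, nrow(x$dropped)))
  if (nrow(x$dropped)) print(x$counts)
  invisible(x)
}

#' Filter markers on parental polymorphism and missingness
#'
#' Retains markers whose two parents carry opposite homozygous calls (when
#' `require_parent_polymorphism` is set) and whose per-marker missing fraction
#' does not exceed `max_missing`. Every drop is recorded with its reason.
#'
#' @param g A [geno_matrix()].
#' @param max_missing Maximum per-marker MISSING fraction.
#' @param require_parent_polymorphism Require opposite homozygous parents
#'   (needs the `parents` slot).
#' @return List with `geno` (filtered) and `report` (a `qc_report`).
#' @export
filter_markers <- function(g, max_missing = 0.1,
                           require_parent_polymorphism = FALSE) {
  n <- ncol(g$calls)
  reason <- rep(NA_character_, n)
  if (require_parent_polymorphism) {
    if (is.null(g$parents)) stop_mm("parent rows required for polymorphism filter")
    p1 <- g$parents[1, ]; p2 <- g$parents[2, ]
    poly <- is_informative(p1) & is_informative(p2) & p1 != p2
    reason[!poly] <- "non_polymorphic"
  }
  miss <- colMeans(g$calls == "MISSING")
  reason[is.na(reason) & miss > max_missing] <- "high_missing"
  keep <- is.na(reason)
  if (!any(keep)) stop_mm("all markers dropped by filters")
  dropped <- data.frame(marker_id = colnames(g$calls)[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  g2 <- geno_matrix(g$calls[, keep, drop = FALSE],
                    g$map[g$map$marker_id %in% colnames(g$calls)[keep], ],
                    chrom_info = g$chrom_info,
                    parents = if (is.null(g$parents)) NULL else
                      g$parents[, keep, drop = FALSE])
  list(geno = g2,
       report = new_qc_report("markers", n, colnames(g2$calls), dropped))
}

#' Filter DH lines on heterozygosity and missingness
#'
#' A DH line is homozygous by construction, so an elevated HET fraction marks
#' a failed or contaminated genotyping; lines with HET fraction above
#' `max_het` or MISSING fraction above `max_missing` are dropped.
#'
#' @param g A [geno_matrix()].
#' @param max_het Maximum per-line HET fraction (default 0.10).
#' @param max_missing Maximum per-line MISSING fraction (default 0.10).
#' @return List with `geno` (filtered) and `report` (a `qc_report` whose
#'   `het_fraction` element gives the per-line HET fraction of the input).
#' @export
filter_lines <- function(g, max_het = 0.1, max_missing = 0.1) {
  het <- rowMeans(g$calls == "HET")
  miss <- rowMeans(g$calls == "MISSING")
  reason <- rep(NA_character_, nrow(g$calls))
  reason[het > max_het] <- "high_het"
  reason[is.na(reason) & miss > max_missing] <- "high_missing"
  keep <- is.na(reason)
  if (!any(keep)) stop_mm("all lines dropped by filters")
  dropped <- data.frame(line = rownames(g$calls)[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  g2 <- geno_matrix(g$calls[keep, , drop = FALSE], g$map,
                    chrom_info = g$chrom_info, parents = g$parents)
  rep <- new_qc_report("lines", nrow(g$calls), rownames(g2$calls), dropped)
  rep$het_fraction <- het
  list(geno = g2, report = rep)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report` (or a list of them).
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  if (inherits(report, "qc_report")) report <- list(report)
  out <- lapply(report, function(r)
    list(axis = r$axis, n_input = r$n_input, n_retained = r$n_retained,
         dropped = r$dropped,
         het_fraction = if (!is.null(r$het_fraction))
           as.list(stats::setNames(unname(r$het_fraction),
                                   names(r$het_fraction))) else NULL))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
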