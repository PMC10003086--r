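default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    # inputs (all optional when simulate is given)
    map_path = NULL, matrix_path = NULL, chrom_info_path = NULL,
    annotation_path = NULL, expression_path = NULL, pairs_path = NULL,
    trait_path = NULL, parent_ids = NULL,
    # simulation (used when map/matrix paths are absent)
    simulate = list(n_lines = 292, marker_spacing = 62000, missing = 0.01,
                    het = 0.005, allele_flip_error = 0.002,
                    interference_shape = 1, obligate_co = FALSE,
                    noisy_lines = 0, noisy_het = 0.25,
                    mean_cos_per_line = 23, n_genes = 20000,
                    qtl = NULL, h2 = 0.5),
    # stage parameters
    max_marker_missing = 0.1, require_parent_polymorphism = FALSE,
    max_line_het = 0.1, max_line_missing = 0.1,
    min_run = 2, background_parent = "P1",
    window = 3e6, step = 1e6, hot_threshold = 2,
    max_tract = 1e5, proximity_bin = 1400, n_sample = 1000,
    min_homolog_run = 11, max_homolog_gap = 0, exchange_tol = 0.25,
    qtl_step = 2, lod_threshold = 2.5, cofactor_window = 10, n_cofactors = 0
  )
}

merge_config <- function(cfg, defaults, path = "") {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop_mm("unknown config key: ", paste0(path, unknown[1]))
  for (k in names(cfg)) {
    if (is.list(defaults[[k]]) && is.list(cfg[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(cfg[[k]], defaults[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- cfg[[k]]
    }
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML file; keys not in the default configuration are rejected
#'   with a hard error naming the key.
#' @return A complete configuration list.
#' @export
read_pipeline_config <- function(path) {
  merge_config(yaml::read_yaml(path), default_pipeline_config())
}

#' Run the whole recombination-analysis pipeline
#'
#' Executes, in dependency order: input loading (or simulation), marker and
#' line QC, call cleaning, bin segmentation, crossover calling, the windowed
#' cM/Mb landscape with hot regions, tract-length and gene-context analyses,
#' homologous-segment detection with exchange-candidate flagging, the Kosambi
#' bin map, and the QTL scan. Stages whose optional inputs (annotation,
#' expression, pairs, traits) are absent are skipped with a warning. A
#' summary list of headline numbers is returned and, when `out_dir` is set,
#' every table plus `summary.json` (including the resolved configuration and
#' package version) is written there.
#'
#' @param config A configuration list (see [read_pipeline_config()] for the
#'   YAML route); only keys that differ from the defaults need to be given.
#' @return List of class `pipeline_result`: the stage outputs (`geno`, `qc`,
#'   `bins`, `cos`, `profile`, `hot`, `tracts`, `proximity`, `strata`,
#'   `segments`, `exchange`, `map`, `scans`, `truth` when simulated) and
#'   `summary`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(config, default_pipeline_config())
  set.seed(cfg$seed)
  truth <- NULL
  genes <- expr <- pairs <- traits <- NULL
  if (!is.null(cfg$map_path)) {
    g <- read_genotypes(cfg$map_path, cfg$matrix_path,
                        parent_ids = cfg$parent_ids,
                        chrom_info_path = cfg$chrom_info_path)
    if (!is.null(cfg$annotation_path))
      genes <- read_gene_annotation(cfg$annotation_path)
    if (!is.null(cfg$expression_path))
      expr <- utils::read.delim(cfg$expression_path, stringsAsFactors = FALSE,
                                check.names = FALSE)
    if (!is.null(cfg$pairs_path))
      pairs <- utils::read.delim(cfg$pairs_path, stringsAsFactors = FALSE)
    if (!is.null(cfg$trait_path))
      traits <- utils::read.csv(cfg$trait_path, stringsAsFactors = FALSE)
  } else {
    s <- cfg$simulate
    gm <- default_genome_model(mean_cos_per_line = s$mean_cos_per_line)
    scfg <- sim_config(n_lines = s$n_lines, marker_spacing = s$marker_spacing,
                       missing = s$missing, het = s$het,
                       allele_flip_error = s$allele_flip_error,
                       interference_shape = s$interference_shape,
                       obligate_co = s$obligate_co, seed = cfg$seed)
    pop <- simulate_population(gm, scfg, noisy_lines = s$noisy_lines,
                               noisy_het = s$noisy_het)
    g <- pop$geno
    truth <- pop$truth
    if (s$n_genes > 0) {
      feat <- simulate_features(gm, n_genes = s$n_genes, seed = cfg$seed + 1)
      genes <- feat$genes; expr <- feat$expression; pairs <- feat$pairs
      truth$features <- feat$truth
    }
    if (!is.null(s$qtl)) {
      qtl_df <- as.data.frame(s$qtl, stringsAsFactors = FALSE)
      tr <- simulate_trait(g, qtl_df, h2 = s$h2, seed = cfg$seed + 2)
      traits <- tr$trait
      truth$qtl <- tr$truth
    }
  }

  fm <- filter_markers(g, max_missing = cfg$max_marker_missing,
                       require_parent_polymorphism =
                         cfg$require_parent_polymorphism)
  fl <- filter_lines(fm$geno, max_het = cfg$max_line_het,
                     max_missing = cfg$max_line_missing)
  g2 <- fl$geno
  clean <- clean_line_calls(g2, min_run = cfg$min_run)
  bins <- call_bins(clean)
  cos <- call_crossovers(bins)
  n_lines <- nrow(g2$calls)
  ci <- g2$chrom_info
  if (is.null(ci)) {
    agg <- stats::aggregate(pos ~ chrom, g2$map, max)
    ci <- data.frame(chrom = agg$chrom, length = agg$pos,
                     stringsAsFactors = FALSE)
  }
  profile <- window_profile(cos, ci, n_lines, window = cfg$window,
                            step = cfg$step)
  hot <- detect_hot_regions(profile, threshold = cfg$hot_threshold,
                            genes = genes)
  summaries <- chromosome_summaries(cos, ci, n_lines)
  lines_sum <- summarize_lines(bins, cos,
                               background_parent = cfg$background_parent)
  tracts <- tract_length_distribution(cos)
  proximity <- strata <- NULL
  if (!is.null(genes) && nrow(genes)) {
    proximity <- gene_proximity(cos, genes, max_tract = cfg$max_tract,
                                bin = cfg$proximity_bin)
    if (!is.null(expr)) {
      strata <- strata_expression(profile, genes, expr,
                                  n_sample = cfg$n_sample,
                                  seed = cfg$seed)
    } else warn_mm("no expression table; strata stage skipped")
  } else warn_mm("no gene annotation; gene-context stages skipped")
  segments <- exchange <- NULL
  if (!is.null(pairs) && nrow(pairs) && !is.null(genes)) {
    segments <- find_homologous_segments(pairs, genes,
                                         min_run = cfg$min_homolog_run,
                                         max_gap = cfg$max_homolog_gap)
    exchange <- flag_exchange_candidates(bins, segments, hot,
                                         tol = cfg$exchange_tol)
  } else warn_mm("no homolog pairs; homeology stage skipped")
  map <- build_map(bins)
  scans <- NULL
  if (!is.null(traits)) {
    scans <- lapply(names(traits)[-1], function(tn) {
      cof <- NULL
      if (cfg$n_cofactors > 0)
        cof <- select_cofactors(map, bins, traits[, c("line", tn)],
                                n_max = cfg$n_cofactors,
                                window = cfg$cofactor_window)
      interval_scan(map, bins, traits[, c("line", tn)], step = cfg$qtl_step,
                    threshold = cfg$lod_threshold, cofactors = cof,
                    cofactor_window = cfg$cofactor_window)
    })
    names(scans) <- names(traits)[-1]
  } else warn_mm("no trait table; QTL stage skipped")

  ms <- map$stats
  summary <- list(
    n_lines = n_lines,
    n_markers = ncol(g2$calls),
    n_bins = nrow(bins$bins),
    total_cos = nrow(cos),
    mean_cos_per_line = nrow(cos) / n_lines,
    cos_per_chromosome = nrow(cos) / n_lines / nrow(ci),
    genome_cm_per_mb = summaries$genome$freq,
    subgenome_cm_per_mb = summaries$genome$subgenome_freq,
    length_correlation = summaries$length_correlation,
    pct_tracts_le_100kb = tracts$pct_le_100kb,
    pct_tracts_le_200kb = tracts$pct_le_200kb,
    n_hot_regions = nrow(hot),
    n_hot_windows = attr(hot, "n_hot_windows"),
    hot_span_mb = if (nrow(hot)) sum(hot$end - hot$start) / 1e6 else 0,
    map_total_cm = ms$total_cm,
    subgenome_cm = ms$subgenome_cm,
    mean_bin_distance_cm = ms$mean_adjacent_cm,
    n_qtl = if (!is.null(scans))
      sum(vapply(scans, function(s) nrow(s$qtl), integer(1))) else NA,
    seed = cfg$seed,
    version = as.character(utils::packageVersion("meiomap"))
  )
  res <- structure(list(geno = g2, qc = list(markers = fm$report,
                                             lines = fl$report),
                        bins = bins, cos = cos, profile = profile, hot = hot,
                        chromosomes = summaries, lines = lines_sum,
                        tracts = tracts, proximity = proximity,
                        strata = strata, segments = segments,
                        exchange = exchange, map = map, scans = scans,
                        truth = truth, summary = summary, config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_qc_report(res$qc, fp("qc_report.json"))
  write_bins(res$bins, fp("bins.tsv"))
  write_crossovers(res$cos, fp("crossovers.tsv"))
  write_profile(res$profile, fp("profile.bedgraph"))
  write_hot_regions(res$hot, fp("hot_regions.bed"))
  utils::write.table(res$lines, fp("line_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(res$segments)) write_links(res$segments, fp("links.tsv"))
  write_linkage_map(res$map, fp("linkage_map.tsv"))
  if (!is.null(res$scans)) {
    for (tn in names(res$scans))
      utils::write.table(res$scans[[tn]]$profile,
                         fp(sprintf("qtl_scan_%s.tsv", tn)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  cfg_out <- res$config[setdiff(names(res$config), "out_dir")]
  out <- list(summary = res$summary,
              config = cfg_out[!vapply(cfg_out, is.null, logical(1))])
  jsonlite::write_json(out, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("recombination pipeline summary\n")
  cat(sprintf("  lines %d, markers %d, bins %d\n",
              s$n_lines, s$n_markers, s$n_bins))
  cat(sprintf("  COs: %d total, %.1f per line, %.2f per chromosome\n",
              s$total_cos, s$mean_cos_per_line, s$cos_per_chromosome))
  cat(sprintf("  genome-wide %.2f cM/Mb; %d hot regions (%.1f Mb)\n",
              s$genome_cm_per_mb, s$n_hot_regions, s$hot_span_mb))
  cat(sprintf("  map: %.1f cM over %d bins (%.2f cM/bin)\n",
              s$map_total_cm, s$n_bins, s$mean_bin_distance_cm))
  invisible(x)
}
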