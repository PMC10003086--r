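#' Simulation configuration
#'
#' Collects every knob of the meiosis/genotyping simulator. The defaults are
#' the study conditions the rest of the package is validated against: 292 DH
#' lines, ~62 kb mean marker spacing, low genotyping noise, no crossover
#' interference (Poisson counts).
#'
#' @param n_lines Number of DH lines to simulate.
#' @param marker_spacing Mean distance between adjacent markers (bp); marker
#'   positions are drawn uniformly and sorted, so spacings are approximately
#'   exponential with this mean.
#' @param missing Per-call probability of a MISSING call.
#' @param het Per-call probability of a (spurious) HET call.
#' @param allele_flip_error Per-call probability that a homozygous call is
#'   flipped to the opposite parent.
#' @param interference_shape Gamma-renewal shape for crossover interference on
#'   the genetic scale; 1 = no interference (Poisson).
#' @param obligate_co If `TRUE`, chromosomes drawing zero crossovers are
#'   resampled once.
#' @param seed Integer seed; fully determines the simulated population.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 292, marker_spacing = 62000,
                       missing = 0.01, het = 0.005, allele_flip_error = 0.002,
                       interference_shape = 1, obligate_co = FALSE, seed = 1) {
  rates <- c(missing = missing, het = het, flip = allele_flip_error)
  if (any(rates < 0 | rates > 1)) stop_mm("noise rates must lie in [0, 1]")
  if (interference_shape <= 0) stop_mm("interference_shape must be positive")
  structure(list(n_lines = as.integer(n_lines), marker_spacing = marker_spacing,
                 missing = missing, het = het,
                 allele_flip_error = allele_flip_error,
                 interference_shape = interference_shape,
                 obligate_co = obligate_co, seed = as.integer(seed)),
            class = "sim_config")
}

# Crossover positions (cM) on one chromosome of genetic length G.
# shape == 1: homogeneous Poisson. Otherwise a stationary gamma-renewal
# process with shape nu and mean inter-event distance 100 cM; the first event
# uses the equilibrium forward-recurrence time (U * length-biased interval,
# length-biased Gamma(nu) being Gamma(nu + 1)).
draw_co_positions_cm <- function(G, shape) {
  if (!is.finite(G)) stop_mm("non-finite genetic length")
  if (G <= 0) return(numeric(0))
  if (shape == 1) {
    n <- stats::rpois(1L, G / 100)
    return(sort(stats::runif(n, 0, G)))
  }
  rate <- shape / 100
  t <- stats::runif(1) * stats::rgamma(1L, shape + 1, rate)
  pts <- numeric(0)
  while (t < G) {
    pts <- c(pts, t)
    t <- t + stats::rgamma(1L, shape, rate)
  }
  pts
}

#' Simulate a single gamete
#'
#' Draws crossover positions per chromosome on the genetic scale (Poisson or
#' stationary gamma-renewal, see [sim_config()]), maps them to bp by the
#' inverse of the cumulative intensity, and assigns a fair-coin parental
#' phase at the chromosome start. Uses the current RNG stream (seed it
#' yourself, or let [simulate_population()] do it).
#'
#' @param gm A [genome_model()].
#' @param cfg A [sim_config()].
#' @return Named list (one per chromosome) with `phase` ("P1"/"P2" at the
#'   chromosome start) and `co_bp` (sorted crossover positions, bp).
#' @export
simulate_gamete <- function(gm, cfg = sim_config()) {
  ci <- gm$chrom_info
  out <- vector("list", nrow(ci))
  names(out) <- ci$chrom
  for (k in seq_len(nrow(ci))) {
    g <- draw_co_positions_cm(ci$genetic_length[k], cfg$interference_shape)
    if (cfg$obligate_co && length(g) == 0L)
      g <- draw_co_positions_cm(ci$genetic_length[k], cfg$interference_shape)
    out[[k]] <- list(phase = if (stats::runif(1) < 0.5) "P1" else "P2",
                     co_bp = genetic_to_physical(gm, ci$chrom[k], g))
  }
  out
}

#' Simulate a doubled-haploid population with known crossover truth
#'
#' Each DH line is one meiotic product: a gamete is simulated, its parental
#' origin is sampled at the marker positions, and genotyping noise is applied
#' per call in the fixed order allele-flip, then HET, then MISSING. The
#' pre-noise crossover positions are recorded as ground truth. Optionally a
#' subset of lines receives heavy extra HET noise, emulating the poorly
#' genotyped plants a line-QC step should remove.
#'
#' @param gm A [genome_model()].
#' @param cfg A [sim_config()]; `cfg$seed` seeds all randomness.
#' @param noisy_lines Number of lines to contaminate with extra HET calls.
#' @param noisy_het Per-call HET rate applied to the contaminated lines.
#' @return List with `geno` (a [geno_matrix()] including clean parent rows)
#'   and `truth` (list: `co` data frame `line`/`chrom`/`pos`, `phases`,
#'   `noisy_lines`).
#' @export
simulate_population <- function(gm, cfg = sim_config(), noisy_lines = 0,
                                noisy_het = 0.25) {
  if (cfg$n_lines < 2L) stop_mm("n_lines must be at least 2")
  set.seed(cfg$seed)
  ci <- gm$chrom_info
  # marker map: uniform positions, sorted, unique per chromosome
  maps <- lapply(seq_len(nrow(ci)), function(k) {
    n <- max(2L, round(ci$length[k] / cfg$marker_spacing))
    pos <- sort(sample.int(ci$length[k], n))
    data.frame(marker_id = sprintf("%s_m%05d", ci$chrom[k], seq_len(n)),
               chrom = ci$chrom[k], pos = pos, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  n_mark <- nrow(map)
  chrom_idx <- split(seq_len(n_mark), factor(map$chrom, levels = ci$chrom))

  lines <- sprintf("QT%03d", seq_len(cfg$n_lines))
  calls <- matrix("P1", nrow = cfg$n_lines, ncol = n_mark,
                  dimnames = list(lines, map$marker_id))
  truth_line <- character(0); truth_chrom <- character(0); truth_pos <- numeric(0)
  phases <- matrix("", nrow = cfg$n_lines, ncol = nrow(ci),
                   dimnames = list(lines, ci$chrom))
  for (i in seq_len(cfg$n_lines)) {
    gam <- simulate_gamete(gm, cfg)
    for (k in seq_len(nrow(ci))) {
      g <- gam[[k]]
      idx <- chrom_idx[[k]]
      parity <- findInterval(map$pos[idx], g$co_bp) %% 2L
      ori <- ifelse(parity == 0L, g$phase, other_parent(g$phase))
      calls[i, idx] <- ori
      phases[i, k] <- g$phase
      if (length(g$co_bp)) {
        truth_line <- c(truth_line, rep(lines[i], length(g$co_bp)))
        truth_chrom <- c(truth_chrom, rep(ci$chrom[k], length(g$co_bp)))
        truth_pos <- c(truth_pos, g$co_bp)
      }
    }
  }

  # noise, fixed order: flip -> het -> missing, each independent per call
  n_cells <- length(calls)
  if (cfg$allele_flip_error > 0) {
    hit <- stats::runif(n_cells) < cfg$allele_flip_error
    calls[hit] <- other_parent(calls[hit])
  }
  if (cfg$het > 0) calls[stats::runif(n_cells) < cfg$het] <- "HET"
  bad <- character(0)
  if (noisy_lines > 0) {
    bad <- sample(lines, noisy_lines)
    sub <- calls[bad, , drop = FALSE]
    sub[stats::runif(length(sub)) < noisy_het] <- "HET"
    calls[bad, ] <- sub
  }
  if (cfg$missing > 0) calls[stats::runif(n_cells) < cfg$missing] <- "MISSING"

  parents <- matrix(rep(c("P1", "P2"), each = n_mark), nrow = 2L, byrow = TRUE,
                    dimnames = list(c("parent1", "parent2"), map$marker_id))
  g <- geno_matrix(calls, map,
                   chrom_info = ci[, c("chrom", "length", "centromere")],
                   parents = parents)
  truth_co <- data.frame(line = truth_line, chrom = truth_chrom,
                         pos = truth_pos, stringsAsFactors = FALSE)
  o <- order(match(truth_co$line, lines), match(truth_co$chrom, ci$chrom),
             truth_co$pos)
  list(geno = g,
       truth = list(co = truth_co[o, , drop = FALSE], phases = phases,
                    noisy_lines = sort(bad)))
}

default_tissues <- function() {
  c("root", "stem", "leaf", "flower", "bud", "seed", "silique",
    "seedling", "shoot_apex", "petal", "sepal")
}

#' Simulate gene annotations, expression, and homologous gene pairs
#'
#' Genes are placed uniformly along the genome (counts proportional to
#' chromosome length). Each gene's true crossover-intensity stratum is taken
#' from the genome model's \eqn{\lambda} at the gene midpoint (cold < 1 cM/Mb,
#' intermediate 1-2, hot > 2); per-tissue expression is log-normal with
#' arithmetic mean `strata_means[stratum]`. Homologous gene pairs consist of
#' planted collinear blocks (contiguous index runs on designated chromosome
#' pairs) plus random background pairs.
#'
#' @param gm A [genome_model()].
#' @param n_genes Total number of genes.
#' @param strata_means Arithmetic-mean expression for the cold/intermediate/hot
#'   strata (length 3, ordered lambda < 1, 1-2, > 2).
#' @param sdlog Log-scale standard deviation of expression.
#' @param tissues Tissue names (default 11 tissues).
#' @param homolog_blocks `NULL` for the default four distal A01-C01 ... A04-C04
#'   blocks of 40 pairs, `NA` for none, or a data frame with columns
#'   `chrom_a`, `start_index_a`, `chrom_b`, `start_index_b`, `n_pairs`,
#'   `orientation` ("same"/"inverted"); indices are gene ranks along the
#'   chromosome.
#' @param n_background_pairs Random (non-collinear) homolog pairs to add.
#' @param mean_gene_length Mean transcript span (bp).
#' @param seed Integer seed.
#' @return List with `genes` (annotation data frame: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`), `expression` (data frame, `gene_id` +
#'   one column per tissue), `pairs` (data frame `gene_a`/`gene_b`), and
#'   `truth` (per-gene `stratum`, the planted `blocks`).
#' @export
simulate_features <- function(gm, n_genes = 20000, strata_means = c(5, 7, 10),
                              sdlog = 1, tissues = default_tissues(),
                              homolog_blocks = NULL, n_background_pairs = 500,
                              mean_gene_length = 2800, seed = 1) {
  if (length(strata_means) != 3L) stop_mm("strata_means must have 3 values")
  set.seed(seed)
  ci <- gm$chrom_info
  empty <- list(genes = data.frame(gene_id = character(0), chrom = character(0),
                                   start = numeric(0), end = numeric(0),
                                   strand = character(0)),
                expression = data.frame(gene_id = character(0)),
                pairs = data.frame(gene_a = character(0), gene_b = character(0)),
                truth = list(stratum = character(0), blocks = NULL))
  if (n_genes == 0L) return(empty)
  n_per <- pmax(1L, round(n_genes * ci$length / sum(ci$length)))
  genes <- do.call(rbind, lapply(seq_len(nrow(ci)), function(k) {
    n <- n_per[k]
    len <- pmax(200, round(stats::rlnorm(n, log(mean_gene_length) - 0.125, 0.5)))
    start <- sort(sample.int(max(ci$length[k] - max(len), 1L), n))
    data.frame(gene_id = sprintf("%s_g%05d", ci$chrom[k], seq_len(n)),
               chrom = ci$chrom[k], start = start,
               end = pmin(start + len - 1, ci$length[k]),
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  mid <- (genes$start + genes$end) / 2
  lam <- unlist(lapply(split(seq_len(nrow(genes)), factor(genes$chrom, ci$chrom)),
                       function(ix) lambda_at(gm, genes$chrom[ix[1]], mid[ix])),
                use.names = FALSE)
  stratum <- cut(lam, c(-Inf, 1, 2, Inf), labels = c("lt1", "mid", "gt2"))
  mu <- strata_means[as.integer(stratum)]
  expr <- vapply(tissues, function(t)
    stats::rlnorm(nrow(genes), log(mu) - sdlog^2 / 2, sdlog),
    numeric(nrow(genes)))
  expression <- data.frame(gene_id = genes$gene_id, expr,
                           stringsAsFactors = FALSE, check.names = FALSE)

  blocks <- homolog_blocks
  if (is.null(blocks)) {
    ab <- sprintf("A%02d", 1:4); cb <- sprintf("C%02d", 1:4)
    na <- vapply(ab, function(ch) sum(genes$chrom == ch), integer(1))
    nb <- vapply(cb, function(ch) sum(genes$chrom == ch), integer(1))
    blocks <- data.frame(chrom_a = ab, start_index_a = na - 39L,
                         chrom_b = cb, start_index_b = nb - 39L,
                         n_pairs = 40L, orientation = "same",
                         stringsAsFactors = FALSE)
  } else if (length(blocks) == 1L && is.na(blocks)) {
    blocks <- NULL
  }
  pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE)
  used <- character(0)
  if (!is.null(blocks) && nrow(blocks)) {
    occ <- c(unlist(mapply(function(ch, s, n) paste0(ch, ":", s:(s + n - 1L)),
                           blocks$chrom_a, blocks$start_index_a, blocks$n_pairs)),
             unlist(mapply(function(ch, s, n) paste0(ch, ":", s:(s + n - 1L)),
                           blocks$chrom_b, blocks$start_index_b, blocks$n_pairs)))
    if (anyDuplicated(occ)) stop_mm("overlapping homolog blocks")
    for (b in seq_len(nrow(blocks))) {
      ga <- genes$gene_id[genes$chrom == blocks$chrom_a[b]]
      gb <- genes$gene_id[genes$chrom == blocks$chrom_b[b]]
      ia <- blocks$start_index_a[b] + seq_len(blocks$n_pairs[b]) - 1L
      ib <- blocks$start_index_b[b] + seq_len(blocks$n_pairs[b]) - 1L
      if (max(ia) > length(ga) || max(ib) > length(gb) || min(c(ia, ib)) < 1L)
        stop_mm("homolog block exceeds gene count on ",
                blocks$chrom_a[b], "/", blocks$chrom_b[b])
      if (blocks$orientation[b] == "inverted") ib <- rev(ib)
      pairs <- rbind(pairs, data.frame(gene_a = ga[ia], gene_b = gb[ib],
                                       stringsAsFactors = FALSE))
    }
    used <- c(pairs$gene_a, pairs$gene_b)
  }
  if (n_background_pairs > 0) {
    free <- setdiff(genes$gene_id, used)
    n_bg <- min(n_background_pairs, floor(length(free) / 2))
    pick <- sample(free, 2L * n_bg)
    pairs <- rbind(pairs, data.frame(gene_a = pick[seq_len(n_bg)],
                                     gene_b = pick[n_bg + seq_len(n_bg)],
                                     stringsAsFactors = FALSE))
  }
  list(genes = genes, expression = expression, pairs = pairs,
       truth = list(stratum = as.character(stratum), blocks = blocks))
}

#' Simulate a quantitative trait with planted QTL
#'
#' The genetic value of each line is the sum over QTL of +effect (P2 allele at
#' the marker nearest the QTL) or -effect (P1 allele); HET/MISSING calls
#' contribute 0. Gaussian noise is scaled so the realized narrow-sense
#' heritability equals `h2`. Realized per-QTL variance fractions are recorded
#' as truth.
#'
#' @param g A [geno_matrix()].
#' @param qtl Data frame with columns `chrom`, `pos` (bp), `effect`.
#' @param h2 Target heritability in (0, 1].
#' @param seed Integer seed (noise only).
#' @param trait_name Column name for the phenotype.
#' @return List with `trait` (data frame `line`, `<trait_name>`) and `truth`
#'   (QTL table with the anchoring marker and realized `pve`, plus realized
#'   `h2`).
#' @export
simulate_trait <- function(g, qtl, h2 = 0.5, seed = 1, trait_name = "trait") {
  if (h2 <= 0 || h2 > 1) stop_mm("h2 must lie in (0, 1]")
  set.seed(seed)
  map <- g$map
  ci <- g$chrom_info
  X <- matrix(0, nrow = nrow(g$calls), ncol = nrow(qtl))
  marker <- character(nrow(qtl))
  for (j in seq_len(nrow(qtl))) {
    if (!qtl$chrom[j] %in% map$chrom) stop_mm("QTL chromosome not in map: ", qtl$chrom[j])
    L <- if (!is.null(ci)) ci$length[match(qtl$chrom[j], ci$chrom)] else Inf
    if (qtl$pos[j] < 1 || qtl$pos[j] > L)
      stop_mm("QTL position outside chromosome ", qtl$chrom[j])
    ix <- which(map$chrom == qtl$chrom[j])
    m <- ix[which.min(abs(map$pos[ix] - qtl$pos[j]))]
    marker[j] <- map$marker_id[m]
    v <- g$calls[, m]
    X[, j] <- ifelse(v == "P2", 1, ifelse(v == "P1", -1, 0))
  }
  gval <- as.numeric(X %*% qtl$effect)
  var_g <- stats::var(gval)
  var_e <- if (h2 == 1) 0 else var_g * (1 - h2) / h2
  y <- gval + stats::rnorm(length(gval), 0, sqrt(var_e))
  pve <- vapply(seq_len(nrow(qtl)), function(j)
    stats::var(X[, j] * qtl$effect[j]) / stats::var(y), numeric(1))
  trait <- data.frame(line = rownames(g$calls), y, stringsAsFactors = FALSE)
  names(trait)[2] <- trait_name
  truth <- cbind(qtl, marker = marker, pve = pve)
  list(trait = trait,
       truth = list(qtl = truth, h2 = var_g / stats::var(y)))
}
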