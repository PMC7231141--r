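#' Default genome map for simulations
#'
#' One chromosome with SNPs on a regular grid and genes of fixed length
#' spread across the same span, so that for any cis window some SNP-gene
#' pairs fall inside it and some outside (both outcomes of the window
#' assignment are exercised).
#'
#' @param n_snps Number of SNPs.
#' @param n_genes Number of genes.
#' @param chrom Chromosome label.
#' @param snp_spacing Distance between adjacent SNPs, bp.
#' @param gene_length Gene body length, bp.
#' @return List with data frames `snps` (`rsid`, `chrom`, `pos`) and
#'   `genes` (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
default_genome_map <- function(n_snps, n_genes = max(2L, n_snps %/% 50L),
                               chrom = "1", snp_spacing = 10000L,
                               gene_length = 20000L) {
  stopifnot(n_snps >= 1, n_genes >= 1)
  snps <- data.frame(rsid = sprintf("snp%04d", seq_len(n_snps)),
                     chrom = chrom,
                     pos = snp_spacing * seq_len(n_snps),
                     stringsAsFactors = FALSE)
  span <- max(snps$pos)
  starts <- as.integer(seq(1, max(1, span - gene_length), length.out = n_genes))
  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                      chrom = chrom,
                      start = starts, end = starts + gene_length - 1L,
                      strand = "*", stringsAsFactors = FALSE)
  list(snps = snps, genes = genes)
}

#' Simulation configuration
#'
#' Parameters of the population-structured generator. Genotypes follow the
#' Balding-Nichols model: each SNP has an ancestral frequency p drawn
#' uniformly from `ancestral_freq_range`, and each population draws its own
#' frequency from a Beta distribution with mean p and variance
#' F p (1 - p), where F is `fst_differentiated` for the `n_differentiated`
#' designated SNPs and `fst_background` otherwise. Genotypes are then two
#' binomial draws per individual, so within-population Hardy-Weinberg
#' equilibrium holds by construction.
#'
#' When `target_population` is set, each differentiated SNP's most drifted
#' subpopulation frequency (the one farthest from its ancestral p, hence
#' always the maximum or the minimum of the set) is assigned to the target
#' population. This emulates ancestry-enriched susceptibility loci: the
#' target ancestry carries a strictly extreme alt-allele frequency at the
#' differentiated SNPs while the Balding-Nichols marginals are unchanged.
#'
#' @param n_populations Number of populations, >= 2.
#' @param samples_per_population Samples per population, >= 2.
#' @param n_snps Number of SNPs, >= 1.
#' @param fst_background Drift F for background SNPs, in (0, 1).
#' @param fst_differentiated Drift F for differentiated SNPs, in (0, 1).
#' @param n_differentiated Number of strongly differentiated SNPs.
#' @param ancestral_freq_range Interval within (0, 1) for ancestral
#'   frequencies.
#' @param genome_map SNP/gene placements; see [default_genome_map()].
#' @param eqtl_effects Data frame (`rsid`, `gene_id`, `beta`) of additive
#'   cis effects, expression units per alt allele; may have zero rows.
#' @param noise_sd Expression noise standard deviation, > 0.
#' @param survival List with `baseline_hazard` (events/month, > 0),
#'   `log_hazard_per_expression_unit` (unitless), `censoring_rate`
#'   (events/month, >= 0; 0 means no censoring).
#' @param populations Population codes (length `n_populations`).
#' @param target_population Population to carry the extreme allele
#'   frequency at differentiated SNPs, or `NULL` for exchangeable drift.
#' @param low_r2_fraction Optional fraction of SNPs forced to imputation
#'   r2 below 0.25; by default r2 is Uniform(0.2, 1.0).
#' @param seed Integer RNG seed; all generators are pure functions of
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_populations = 3L, samples_per_population = 200L,
                       n_snps = 1000L, fst_background = 0.01,
                       fst_differentiated = 0.25, n_differentiated = 4L,
                       ancestral_freq_range = c(0.1, 0.9),
                       genome_map = default_genome_map(n_snps),
                       eqtl_effects = NULL, noise_sd = 1,
                       survival = list(baseline_hazard = 0.02,
                                       log_hazard_per_expression_unit = 1,
                                       censoring_rate = 0.01),
                       populations = NULL, target_population = NULL,
                       low_r2_fraction = NULL, seed = 1L) {
  stopifnot(n_populations >= 2, samples_per_population >= 2, n_snps >= 1,
            n_differentiated >= 0, n_differentiated <= n_snps)
  for (f in c(fst_background, fst_differentiated))
    if (!(f > 0 && f < 1)) stop("FST parameters must lie in (0, 1)")
  if (!(ancestral_freq_range[1] > 0 && ancestral_freq_range[2] < 1 &&
        ancestral_freq_range[1] <= ancestral_freq_range[2]))
    stop("ancestral_freq_range must be an interval within (0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (survival$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (survival$censoring_rate < 0) stop("censoring_rate must be >= 0")
  if (nrow(genome_map$snps) != n_snps)
    stop("genome_map must place exactly n_snps SNPs")
  if (is.null(populations))
    populations <- paste0("POP", seq_len(n_populations))
  if (length(populations) != n_populations)
    stop("populations must have length n_populations")
  if (!is.null(target_population) && !(target_population %in% populations))
    stop("target_population not among populations")
  if (is.null(eqtl_effects))
    eqtl_effects <- data.frame(rsid = character(), gene_id = character(),
                               beta = numeric())
  bad_snp <- setdiff(eqtl_effects$rsid, genome_map$snps$rsid)
  if (length(bad_snp))
    stop("eqtl_effects reference unknown SNP(s): ",
         paste(bad_snp, collapse = ", "))
  bad_gene <- setdiff(eqtl_effects$gene_id, genome_map$genes$gene_id)
  if (length(bad_gene))
    stop("eqtl_effects reference unknown gene(s): ",
         paste(bad_gene, collapse = ", "))
  if (!is.null(low_r2_fraction))
    stopifnot(low_r2_fraction >= 0, low_r2_fraction <= 1)
  structure(list(n_populations = as.integer(n_populations),
                 samples_per_population = as.integer(samples_per_population),
                 n_snps = as.integer(n_snps), fst_background = fst_background,
                 fst_differentiated = fst_differentiated,
                 n_differentiated = as.integer(n_differentiated),
                 ancestral_freq_range = ancestral_freq_range,
                 genome_map = genome_map, eqtl_effects = eqtl_effects,
                 noise_sd = noise_sd, survival = survival,
                 populations = populations,
                 target_population = target_population,
                 low_r2_fraction = low_r2_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols subpopulation frequency: Beta with mean p, var F p(1-p).
.bn_freq <- function(n, p, f) {
  if (f < 1e-12) return(rep(p, length.out = n))
  rbeta(n, p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

# First RNG draws of the genotype generator: ancestral frequencies and the
# identity of the differentiated SNPs. Kept separate so the planted-scenario
# constructor can learn the truth without simulating genotypes. Must be
# called with the RNG already seeded.
.draw_anc_diff <- function(config) {
  p_anc <- runif(config$n_snps, config$ancestral_freq_range[1],
                 config$ancestral_freq_range[2])
  diff_idx <- if (config$n_differentiated > 0)
    sort(sample.int(config$n_snps, config$n_differentiated)) else integer()
  list(p_anc = p_anc, diff_idx = diff_idx)
}

#' Simulate population-structured genotypes
#'
#' Balding-Nichols generator; see [sim_config()] for the model. Returns the
#' genotypes, the sample-to-population panel, and the identity of the
#' differentiated SNPs (the simulation truth used by recovery tests).
#' Imputation r-squared values are drawn Uniform(0.2, 1.0), optionally with
#' an exact fraction forced below the 0.25 QC threshold.
#'
#' @param config A [sim_config()].
#' @return List with elements `genotypes` ([genotype_matrix()]), `panel`
#'   (data frame `sample_id`, `population`), `truth` (character vector of
#'   differentiated rsids), and `pop_freqs` (populations x SNPs matrix of
#'   the drawn subpopulation allele frequencies).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    K <- config$n_populations
    n <- config$samples_per_population
    M <- config$n_snps
    pops <- config$populations
    ad <- .draw_anc_diff(config)
    p_anc <- ad$p_anc
    diff_idx <- ad$diff_idx
    fst <- rep(config$fst_background, M)
    fst[diff_idx] <- config$fst_differentiated

    freqs <- matrix(NA_real_, nrow = K, ncol = M,
                    dimnames = list(pops, config$genome_map$snps$rsid))
    for (j in seq_len(M)) freqs[, j] <- .bn_freq(K, p_anc[j], fst[j])

    if (!is.null(config$target_population) && length(diff_idx)) {
      tk <- match(config$target_population, pops)
      for (j in diff_idx) {
        far <- which.max(abs(freqs[, j] - p_anc[j]))
        if (far != tk) {
          tmp <- freqs[tk, j]
          freqs[tk, j] <- freqs[far, j]
          freqs[far, j] <- tmp
        }
      }
    }

    calls <- matrix(NA_integer_, nrow = K * n, ncol = M)
    for (k in seq_len(K)) {
      rows <- (k - 1L) * n + seq_len(n)
      calls[rows, ] <- rbinom(n * M, 2L, rep(freqs[k, ], each = n))
    }
    sample_ids <- sprintf("%s_%03d", rep(pops, each = n), rep(seq_len(n), K))
    rownames(calls) <- sample_ids

    r2 <- runif(M, 0.2, 1.0)
    if (!is.null(config$low_r2_fraction)) {
      n_low <- round(config$low_r2_fraction * M)
      low <- sample.int(M, n_low)
      r2[low] <- runif(n_low, 0.05, 0.2499)
      r2[setdiff(seq_len(M), low)] <-
        runif(M - n_low, 0.25, 1.0)
    }

    variants <- data.frame(config$genome_map$snps,
                           ref = "A", alt = "G", r2 = r2,
                           stringsAsFactors = FALSE)
    gm <- genotype_matrix(calls, variants)
    panel <- data.frame(sample_id = sample_ids,
                        population = rep(pops, each = n),
                        stringsAsFactors = FALSE)
    list(genotypes = gm, panel = panel,
         truth = variants$rsid[diff_idx], pop_freqs = freqs)
  })
}

#' Simulate cis-regulated expression
#'
#' Additive model: each gene's expression is the sum of beta x dosage over
#' its configured cis effects plus Gaussian noise with sd `noise_sd`; genes
#' with no effect are pure noise.
#'
#' @param genotypes A [genotype_matrix()] (typically from
#'   [simulate_genotypes()]).
#' @param config A [sim_config()].
#' @return Numeric expression matrix, genes x samples.
#' @export
simulate_expression <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  eff <- config$eqtl_effects
  bad <- setdiff(eff$rsid, genotypes$variants$rsid)
  if (length(bad))
    stop("eqtl effect references SNP(s) absent from genotypes: ",
         paste(bad, collapse = ", "))
  genes <- config$genome_map$genes$gene_id
  samp <- genotypes$sample_ids
  with_seed(config$seed + 1L, {
    expr <- matrix(rnorm(length(genes) * length(samp), sd = config$noise_sd),
                   nrow = length(genes), ncol = length(samp),
                   dimnames = list(genes, samp))
    for (i in seq_len(nrow(eff))) {
      d <- genotypes$calls[, eff$rsid[i]]
      d[is.na(d)] <- 0L
      expr[eff$gene_id[i], ] <- expr[eff$gene_id[i], ] + eff$beta[i] * d
    }
    expr
  })
}

#' Simulate right-censored survival times from expression
#'
#' Proportional-hazards generator: for sample i with expression x_i of the
#' chosen gene, the event time is exponential with hazard
#' `baseline_hazard * exp(log_hazard_per_expression_unit * x_i)`;
#' censoring is an independent exponential with rate `censoring_rate`
#' (0 disables censoring). The record keeps the earlier of the two times
#' and an event indicator.
#'
#' @param expression Expression matrix (genes x samples).
#' @param gene_id Gene whose expression drives the hazard.
#' @param config A [sim_config()].
#' @return Data frame (`sample_id`, `time` months, `event` 0/1,
#'   `expression`).
#' @export
simulate_survival <- function(expression, gene_id, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!gene_id %in% rownames(expression))
    stop("gene not present in expression matrix: ", gene_id)
  sv <- config$survival
  x <- expression[gene_id, ]
  with_seed(config$seed + 2L, {
    rate <- sv$baseline_hazard * exp(sv$log_hazard_per_expression_unit * x)
    t_event <- rexp(length(x), rate)
    t_cens <- if (sv$censoring_rate > 0)
      rexp(length(x), sv$censoring_rate) else rep(Inf, length(x))
    data.frame(sample_id = colnames(expression),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               expression = as.numeric(x),
               stringsAsFactors = FALSE)
  })
}

#' Planted funnel scenario
#'
#' Convenience constructor for the end-to-end study conditions exercised by
#' the recovery tests: ~935 SNPs across three populations of 200 samples,
#' four strongly differentiated SNPs (F = 0.25 against an F = 0.01
#' background) enriched in a target ancestry, each planted with a true
#' additive cis effect on the nearest gene inside the window.
#'
#' Ancestral frequencies are drawn from (0.25, 0.75): the funnel's input
#' SNPs emulate array-genotyped common cis-eQTL candidates (the upstream
#' discovery that produces such a panel is itself restricted to common
#' variants), keeping the planted causal SNPs polymorphic in every
#' subpopulation under strong drift.
#'
#' @param seed Integer seed.
#' @param n_snps Number of SNPs.
#' @param n_differentiated Number of planted differentiated SNPs.
#' @param beta Planted cis effect size (expression units per alt allele).
#' @param window Cis window, bp, used to pick planted genes inside it.
#' @return A [sim_config()].
#' @export
planted_funnel_config <- function(seed = 1L, n_snps = 935L,
                                  n_differentiated = 4L, beta = 1,
                                  window = 1e6) {
  map <- default_genome_map(n_snps)
  freq_range <- c(0.25, 0.75)
  # learn which SNPs the generator will differentiate under this seed: the
  # truth draw is the generator's first RNG consumption, replayed here
  probe <- sim_config(n_snps = n_snps, n_differentiated = n_differentiated,
                      ancestral_freq_range = freq_range,
                      genome_map = map, seed = seed,
                      populations = c("CEU", "CHB", "JPT"),
                      target_population = "JPT")
  truth <- map$snps$rsid[with_seed(seed, .draw_anc_diff(probe))$diff_idx]
  snp_pos <- setNames(map$snps$pos, map$snps$rsid)
  gene_mid <- (map$genes$start + map$genes$end) / 2
  eff <- data.frame(rsid = truth,
                    gene_id = map$genes$gene_id[
                      vapply(snp_pos[truth], function(p)
                        which.min(abs(gene_mid - p)), integer(1))],
                    beta = beta, stringsAsFactors = FALSE)
  sim_config(n_snps = n_snps, n_differentiated = n_differentiated,
             ancestral_freq_range = freq_range,
             genome_map = map, eqtl_effects = eff, seed = seed,
             populations = c("CEU", "CHB", "JPT"),
             target_population = "JPT")
}
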