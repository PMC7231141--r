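#' Per-variant allele counts by population
#'
#' For every variant, counts ref and alt allele copies within each requested
#' population over non-missing calls, giving the 2 x K table tested by
#' [chisq_differentiation()].
#'
#' @param genotypes A [genotype_matrix()].
#' @param panel Panel data frame (`sample_id`, `population`); must cover
#'   every genotyped sample (strict join).
#' @param populations Ordered character vector of populations to count;
#'   default: sorted unique panel codes among the genotyped samples.
#' @return Named list (by rsid) of 2 x K integer matrices with rows
#'   `ref`, `alt` and one column per population. Column sums equal twice
#'   the called sample count in that population.
#' @export
population_allele_counts <- function(genotypes, panel, populations = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  pop_of <- panel_populations(panel, genotypes$sample_ids)
  if (is.null(populations)) populations <- sort(unique(pop_of))
  missing_pop <- setdiff(populations, unique(pop_of))
  if (length(missing_pop))
    stop("population(s) absent from panel: ",
         paste(missing_pop, collapse = ", "))
  calls <- genotypes$calls
  rsids <- genotypes$variants$rsid
  K <- length(populations)
  alt <- matrix(0L, nrow = ncol(calls), ncol = K,
                dimnames = list(rsids, populations))
  ncall <- alt
  for (k in seq_len(K)) {
    rows <- pop_of == populations[k]
    sub <- calls[rows, , drop = FALSE]
    alt[, k] <- as.integer(colSums(sub, na.rm = TRUE))
    ncall[, k] <- as.integer(colSums(!is.na(sub)))
  }
  lapply(setNames(seq_along(rsids), rsids), function(j) {
    matrix(c(2L * ncall[j, ] - alt[j, ], alt[j, ]), nrow = 2, byrow = TRUE,
           dimnames = list(c("ref", "alt"), populations))
  })
}

#' Chi-square test of allele-frequency differentiation
#'
#' Pearson chi-square test of independence on a 2 x K allele-count table
#' (alleles x populations), df = K - 1. Degenerate tables (an all-zero row
#' or column, e.g. a variant monomorphic in every population or a
#' population with no called samples) yield an undefined test with the
#' reason recorded rather than a fabricated statistic.
#'
#' @param table 2 x K matrix of allele counts (rows ref/alt, columns
#'   populations).
#' @return List with `chi2`, `df`, `p`, and `degenerate` (`NA` or the
#'   reason the test is undefined).
#' @export
chisq_differentiation <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2) stop("allele-count table must have 2 rows (ref, alt)")
  if (any(table < 0)) stop("allele counts must be non-negative")
  K <- ncol(table)
  degen <- NA_character_
  if (sum(table) == 0) degen <- "empty table"
  else if (any(colSums(table) == 0)) degen <- "population with zero called alleles"
  else if (any(rowSums(table) == 0)) degen <- "monomorphic across all populations"
  if (!is.na(degen))
    return(list(chi2 = NA_real_, df = K - 1L, p = NA_real_, degenerate = degen))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  chi2 <- sum((table - expected)^2 / expected)
  list(chi2 = chi2, df = K - 1L,
       p = pchisq(chi2, df = K - 1L, lower.tail = FALSE),
       degenerate = NA_character_)
}

#' Per-variant population differentiation records
#'
#' Builds, for every variant, the 2 x K allele-count table, per-population
#' alt-allele frequencies, the chi-square differentiation test, and whether
#' the target population's alt frequency is a strict extremum (the
#' operational reading of "preferentially prevalent in" an ancestry:
#' enrichment of either allele shows up as a strictly maximal or strictly
#' minimal alt frequency in the target).
#'
#' @inheritParams population_allele_counts
#' @param target_population Population whose enrichment is of interest.
#' @return Data frame with columns `rsid`, one `freq_<pop>` column per
#'   population, `chi2`, `df`, `p`, `degenerate`, `target_extreme`.
#' @export
pop_diff_records <- function(genotypes, panel, target_population,
                             populations = NULL) {
  tables <- population_allele_counts(genotypes, panel, populations)
  pops <- colnames(tables[[1]])
  if (!target_population %in% pops)
    stop("target population not among tested populations: ", target_population)
  rec <- lapply(names(tables), function(rs) {
    tab <- tables[[rs]]
    tot <- colSums(tab)
    freqs <- ifelse(tot > 0, tab["alt", ] / tot, NA_real_)
    ts <- chisq_differentiation(tab)
    tf <- freqs[target_population]
    others <- freqs[setdiff(pops, target_population)]
    extreme <- !is.na(tf) && !anyNA(others) &&
      (all(tf > others) || all(tf < others))
    out <- data.frame(rsid = rs, t(freqs), chi2 = ts$chi2, df = ts$df,
                      p = ts$p, degenerate = ts$degenerate,
                      target_extreme = extreme, stringsAsFactors = FALSE)
    names(out)[seq_along(pops) + 1L] <- paste0("freq_", pops)
    out
  })
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  attr(out, "target_population") <- target_population
  attr(out, "populations") <- pops
  out
}

#' Select ancestry-enriched differentiated SNPs
#'
#' A SNP is selected when its differentiation p-value is strictly below the
#' threshold AND the target population's alt-allele frequency is a strict
#' extremum (maximum or minimum) across the tested populations. Variants
#' with a degenerate (untestable) table are skipped with a logged reason.
#'
#' @param records Output of [pop_diff_records()].
#' @param p_threshold Selection threshold on the differentiation p-value
#'   (default 0.001, strict inequality).
#' @return Character vector of selected rsids.
#' @export
select_differential_snps <- function(records, p_threshold = 0.001) {
  skipped <- records$rsid[!is.na(records$degenerate)]
  if (length(skipped))
    message("skipping untestable variant(s): ",
            paste(skipped, collapse = ", "))
  ok <- is.na(records$degenerate)
  sel <- ok & records$p < p_threshold & records$target_extreme
  records$rsid[sel]
}

#' Variance-based per-variant FST estimate
#'
#' Validation helper for the simulator: estimates the fixation index as the
#' (K - 1)-divisor sample variance of subpopulation alt-allele frequencies
#' about the pooled frequency, divided by p(1 - p) of the pooled frequency,
#' clipped to \[0, 1\]. Variants monomorphic in the pooled sample are
#' undefined and returned as `NA`.
#'
#' @inheritParams population_allele_counts
#' @return Named numeric vector of per-variant FST estimates.
#' @export
fst_estimate <- function(genotypes, panel, populations = NULL) {
  tables <- population_allele_counts(genotypes, panel, populations)
  if (ncol(tables[[1]]) < 2) stop("FST requires at least 2 populations")
  vapply(tables, function(tab) {
    tot <- colSums(tab)
    if (any(tot == 0)) return(NA_real_)
    freqs <- tab["alt", ] / tot
    pbar <- sum(tab["alt", ]) / sum(tot)
    if (pbar == 0 || pbar == 1) return(NA_real_)
    v <- sum((freqs - pbar)^2) / (length(freqs) - 1)
    min(1, max(0, v / (pbar * (1 - pbar))))
  }, numeric(1))
}
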