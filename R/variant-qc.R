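#' Allele frequency of a dosage vector
#'
#' @param calls Integer dosage vector (0/1/2, `NA` = missing call).
#' @return List with `alt_freq` (alt-allele frequency over non-missing
#'   calls), `maf` (minor allele frequency, `min(alt_freq, 1 - alt_freq)`),
#'   and `n_called`.
#' @examples
#' allele_frequency(c(0, 0, 1, 2)) # alt_freq 0.375
#' @export
allele_frequency <- function(calls) {
  ok <- !is.na(calls)
  n_called <- sum(ok)
  if (n_called == 0) stop("allele frequency undefined: all calls missing")
  alt <- sum(calls[ok]) / (2 * n_called)
  list(alt_freq = alt, maf = min(alt, 1 - alt), n_called = n_called)
}

# Exact Hardy-Weinberg test: probability of the observed heterozygote count
# conditional on the allele counts, summing configurations no more probable
# than the observed one.
.hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab          # minor-allele copies by construction below
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- lfactorial(n) - lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n_a + hets) / 2) + hets * log(2) +
    lfactorial(n_a) + lfactorial(2 * n - n_a) - lfactorial(2 * n)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, hets)]
  sum(probs[probs <= obs + 1e-12])
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the Pearson chi-square goodness-of-fit test with 1 degree of
#' freedom against expected counts n p^2, 2 n p (1 - p), n (1 - p)^2 at the
#' estimated allele frequency; monomorphic input is in exact equilibrium
#' (chi2 = 0, p = 1). The exact (conditional) test is available via
#' `method = "exact"` and is the better choice when any expected genotype
#' count is below 5; the chi-square path warns in that situation.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @param method `"chisq"` (default), `"exact"`, or `"auto"` (exact
#'   whenever any expected genotype count is below 5, chi-square
#'   otherwise).
#' @return List with `chi2` (NA for the exact test) and `p`.
#' @examples
#' hwe_test(30, 40, 30) # chi2 = 4, p ~ 0.0455
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt,
                     method = c("chisq", "exact", "auto")) {
  method <- match.arg(method)
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required")
  p_alt <- (2 * n_hom_alt + n_het) / (2 * n)
  if (p_alt == 0 || p_alt == 1) return(list(chi2 = 0, p = 1))
  if (method == "auto") {
    expected <- n * c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2)
    method <- if (any(expected < 5)) "exact" else "chisq"
  }
  if (method == "exact") {
    # orient so the first homozygote class carries the minor allele
    if (p_alt <= 0.5) p <- .hwe_exact(n_hom_alt, n_het, n_hom_ref)
    else p <- .hwe_exact(n_hom_ref, n_het, n_hom_alt)
    return(list(chi2 = NA_real_, p = min(1, p)))
  }
  expected <- n * c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2)
  if (any(expected < 5))
    warning("expected genotype count < 5; exact HWE test recommended")
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Three-filter variant quality control
#'
#' Applies the pipeline's SNP filters: imputation accuracy, minor allele
#' frequency, and Hardy-Weinberg equilibrium. Filters are strict-inequality
#' exclusions -- a variant is removed when r2 < `r2_min`, maf < `maf_min`,
#' or HWE p < `hwe_p_min` -- so threshold-boundary values pass. Variants
#' without an imputation r2 are treated as directly observed and pass the
#' r2 filter. Metrics are computed on the pooled sample set with missing
#' dosages excluded pairwise.
#'
#' HWE can be screened on the pooled sample (the default) or within each
#' population of a supplied panel (`hwe_scope = "per_population"`), in
#' which case a variant violates HWE when any single population does
#' (smallest per-population p compared against the threshold; the reported
#' `hwe_chi2`/`hwe_p` are that worst population's). Per-population
#' screening is what [run_funnel()] uses: in a pooled multi-ancestry
#' sample, allele-frequency differentiation itself depresses heterozygosity
#' (the Wahlund effect), so a pooled HWE filter would preferentially
#' discard the ancestry-differentiated SNPs the pipeline is designed to
#' find, while within-population HWE is the generative assumption being
#' checked.
#'
#' @param genotypes A [genotype_matrix()].
#' @param r2_min Imputation r2 exclusion threshold (default 0.25).
#' @param maf_min Minor allele frequency exclusion threshold (default 0.1).
#' @param hwe_p_min HWE p-value exclusion threshold (default 1e-4).
#' @param hwe_method `"chisq"` or `"exact"`, passed to [hwe_test()].
#' @param hwe_scope `"pooled"` (default) or `"per_population"` (requires
#'   `panel`).
#' @param panel Panel data frame, required for per-population HWE.
#' @return List with `kept` (a [genotype_matrix()] of passing variants) and
#'   `report`, a data frame with one row per input variant: `rsid`,
#'   `n_called`, `alt_freq`, `maf`, `hwe_chi2`, `hwe_p`, `imputation_r2`,
#'   `pass`, `fail_reasons` (comma-separated subset of `low_r2`, `low_maf`,
#'   `hwe_violation`).
#' @export
qc_filter <- function(genotypes, r2_min = 0.25, maf_min = 0.1,
                      hwe_p_min = 1e-4,
                      hwe_method = c("chisq", "exact", "auto"),
                      hwe_scope = c("pooled", "per_population"),
                      panel = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  hwe_method <- match.arg(hwe_method)
  hwe_scope <- match.arg(hwe_scope)
  for (th in c(r2_min, maf_min, hwe_p_min))
    if (!(th > 0 && th < 1)) stop("thresholds must lie in (0, 1)")
  M <- nrow(genotypes$variants)
  if (M == 0 || length(genotypes$sample_ids) == 0)
    stop("empty genotype matrix")
  calls <- genotypes$calls
  n_called <- colSums(!is.na(calls))
  if (any(n_called == 0))
    stop("variant(s) with no called samples: ",
         paste(genotypes$variants$rsid[n_called == 0], collapse = ", "))
  alt_freq <- colSums(calls, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(alt_freq, 1 - alt_freq)
  hwe_counts <- function(sub) {
    rbind(colSums(sub == 0L, na.rm = TRUE), colSums(sub == 1L, na.rm = TRUE),
          colSums(sub == 2L, na.rm = TRUE))
  }
  hwe_of <- function(cnt) vapply(seq_len(ncol(cnt)), function(j) {
    if (sum(cnt[, j]) == 0) return(c(NA_real_, 1))
    h <- suppressWarnings(hwe_test(cnt[1, j], cnt[2, j], cnt[3, j],
                                   method = hwe_method))
    c(h$chi2, h$p)
  }, numeric(2))
  if (hwe_scope == "pooled") {
    hwe <- hwe_of(hwe_counts(calls))
  } else {
    if (is.null(panel))
      stop("per-population HWE requires a panel")
    pop_of <- panel_populations(panel, genotypes$sample_ids)
    per_pop <- lapply(sort(unique(pop_of)), function(pp)
      hwe_of(hwe_counts(calls[pop_of == pp, , drop = FALSE])))
    pmat <- do.call(rbind, lapply(per_pop, function(h) h[2, ]))
    cmat <- do.call(rbind, lapply(per_pop, function(h) h[1, ]))
    worst <- apply(pmat, 2, which.min)
    hwe <- rbind(cmat[cbind(worst, seq_len(M))],
                 pmat[cbind(worst, seq_len(M))])
  }
  r2 <- genotypes$variants$r2
  low_r2 <- !is.na(r2) & r2 < r2_min
  low_maf <- maf < maf_min
  hwe_viol <- hwe[2, ] < hwe_p_min
  fail <- mapply(function(a, b, c) paste(
    c("low_r2", "low_maf", "hwe_violation")[c(a, b, c)], collapse = ","),
    low_r2, low_maf, hwe_viol)
  pass <- !(low_r2 | low_maf | hwe_viol)
  report <- data.frame(rsid = genotypes$variants$rsid, n_called = n_called,
                       alt_freq = alt_freq, maf = maf, hwe_chi2 = hwe[1, ],
                       hwe_p = hwe[2, ], imputation_r2 = r2, pass = pass,
                       fail_reasons = fail, row.names = NULL,
                       stringsAsFactors = FALSE)
  kept <- genotype_matrix(calls[, pass, drop = FALSE],
                          genotypes$variants[pass, , drop = FALSE])
  list(kept = kept, report = report)
}
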