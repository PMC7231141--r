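#' Assign SNP-gene cis pairs by genomic window
#'
#' A SNP and gene are paired when they sit on the same chromosome and the
#' SNP lies within `window` bp of the gene: distance is 0 when the SNP
#' falls inside the gene body, otherwise the distance to the nearest gene
#' boundary, with an inclusive comparison at the window edge. All
#' coordinates are 1-based. When the SNP and gene chromosome label styles
#' disagree (e.g. `chr8` vs `8`) the mismatch is an explicit error rather
#' than a silent empty result.
#'
#' @param snps Data frame with columns `rsid`, `chrom`, `pos`.
#' @param genes Annotation data frame (`gene_id`, `chrom`, `start`, `end`).
#' @param window Cis window in bp on either side of the gene (default 1 Mb).
#' @return Data frame of pairs: `rsid`, `gene_id`, `chrom`, `snp_pos`,
#'   `gene_start`, `gene_end`, `distance`, `window`.
#' @examples
#' snps <- data.frame(rsid = "rs4873815", chrom = "8", pos = 144796206)
#' genes <- data.frame(gene_id = "ZNF707", chrom = "8",
#'                     start = 144824516, end = 144849514)
#' assign_cis_pairs(snps, genes, window = 5e5) # distance 28310
#' @export
assign_cis_pairs <- function(snps, genes, window = 1e6) {
  if (window <= 0) stop("window must be > 0")
  snps <- as.data.frame(snps)
  genes <- as.data.frame(genes)
  stopifnot(all(c("rsid", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  empty <- data.frame(rsid = character(), gene_id = character(),
                      chrom = character(), snp_pos = integer(),
                      gene_start = integer(), gene_end = integer(),
                      distance = numeric(), window = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(snps) == 0 || nrow(genes) == 0) return(empty)
  if (!any(unique(snps$chrom) %in% unique(genes$chrom))) {
    strip <- function(x) sub("^chr", "", x)
    if (any(strip(unique(snps$chrom)) %in% strip(unique(genes$chrom))))
      stop("chromosome naming mismatch between SNPs and genes ",
           "(e.g. \"chr8\" vs \"8\"); harmonize labels before pairing")
    return(empty)
  }
  m <- merge(snps[c("rsid", "chrom", "pos")],
             genes[c("gene_id", "chrom", "start", "end")], by = "chrom")
  if (nrow(m) == 0) return(empty)
  inside <- m$pos >= m$start & m$pos <= m$end
  dist <- ifelse(inside, 0, pmin(abs(m$pos - m$start), abs(m$pos - m$end)))
  keep <- dist <= window
  out <- data.frame(rsid = m$rsid[keep], gene_id = m$gene_id[keep],
                    chrom = m$chrom[keep], snp_pos = m$pos[keep],
                    gene_start = m$start[keep], gene_end = m$end[keep],
                    distance = dist[keep],
                    window = rep(window, sum(keep)),
                    stringsAsFactors = FALSE)
  out[order(out$rsid, out$gene_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Per-pair additive linear regression of expression on dosage
#'
#' Ordinary least squares of expression on alt-allele dosage with an
#' intercept (additive 0/1/2 coding, no covariates). Observations are
#' pairwise complete. Pairs with fewer than 3 complete observations or a
#' constant dosage/expression vector are flagged as undefined rather than
#' given a p-value, so they can be excluded from FDR adjustment with a
#' recorded reason.
#'
#' @param dosage Numeric dosage vector.
#' @param expression Numeric expression vector, same length.
#' @return List with `beta` (expression units per alt allele), `se`, `t`,
#'   `df` (n - 2), `p` (two-sided, floored at the smallest positive
#'   double for perfect fits), `n`, `status` (`"ok"` or a skip reason).
#' @export
regress_pair <- function(dosage, expression) {
  if (length(dosage) != length(expression))
    stop("dosage and expression must have equal length")
  ok <- !is.na(dosage) & !is.na(expression)
  x <- as.numeric(dosage[ok]); y <- as.numeric(expression[ok])
  n <- length(x)
  und <- function(status) list(beta = NA_real_, se = NA_real_, t = NA_real_,
                               df = NA_integer_, p = NA_real_, n = n,
                               status = status)
  if (n < 3) return(und("too_few_observations"))
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(und("constant_dosage"))
  if (all(y == y[1])) return(und("constant_expression"))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  rss <- sum((y - mean(y) - beta * (x - mean(x)))^2)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  t <- if (se > 0) beta / se else sign(beta) * Inf
  p <- max(2 * pt(abs(t), df = df, lower.tail = FALSE), .Machine$double.xmin)
  list(beta = beta, se = se, t = t, df = df, p = p, n = n, status = "ok")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted value for the i-th smallest p is `min over j >= i of
#' m p_(j) / j`, capped at 1; ties are kept in stable input order. A pair
#' is declared significant when its adjusted value is at most `alpha`
#' (FDR control at level alpha).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return List with `q` (adjusted values, input order) and `reject`
#'   (logical flags, `q <= alpha`).
#' @examples
#' bh_adjust(c(0.001, 0.8))$q # 0.002, 0.8
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0)
    return(list(q = numeric(), reject = logical()))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- rev(cummin(rev(pvalues[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  list(q = q, reject = q <= alpha)
}

#' Run the full discovery funnel
#'
#' Orchestrates the three-step pipeline on joinable genotype, expression,
#' panel, and annotation inputs: (1) variant QC ([qc_filter()]); (2)
#' selection of SNPs with ancestry-differentiated allele frequencies
#' enriched in the target population ([pop_diff_records()],
#' [select_differential_snps()]); (3) cis-window assignment of the selected
#' SNPs against the full annotation ([assign_cis_pairs()]), per-pair
#' additive regression ([regress_pair()]), and a single global
#' Benjamini-Hochberg adjustment across all tested pairs of the run
#' ([bh_adjust()]). All analyses run on the sample intersection of the
#' three inputs. An empty intermediate stage produces zero downstream
#' counts with a warning, not an error.
#'
#' @param genotypes A [genotype_matrix()].
#' @param panel Panel data frame covering the analysis samples.
#' @param expression Expression matrix (genes x samples).
#' @param genes Gene annotation data frame.
#' @param target_population Ancestry whose allele-frequency enrichment
#'   defines step 2.
#' @param candidate_gene_ids Candidate gene panel that motivated the SNP
#'   set (counted in the funnel report); defaults to all annotated genes.
#' @param window Cis window in bp (default 1 Mb).
#' @param r2_min,maf_min,hwe_p_min QC thresholds, see [qc_filter()].
#' @param hwe_scope HWE screening scope; the funnel defaults to
#'   `"per_population"` because pooled HWE in a multi-ancestry sample
#'   discards differentiated SNPs through the Wahlund effect (see
#'   [qc_filter()]).
#' @param hwe_method HWE test; the funnel defaults to `"auto"` (exact test
#'   when any expected genotype count is below 5, where the chi-square
#'   approximation is anticonservative; Pearson chi-square otherwise).
#' @param p_threshold Differentiation selection threshold (default 0.001).
#' @param alpha FDR level for cis associations (default 0.05).
#' @param populations Populations to test; default: all panel codes.
#' @return Object of class `funnel_result`: list with `funnel` (stage
#'   counts), `associations` (per-pair data frame with `beta`, `se`, `t`,
#'   `p`, `q`, `significant`), `popdiff` (per-variant differentiation
#'   records), `qc` (per-variant QC report), `selected_snps`, and
#'   `samples` (the analysis sample set).
#' @export
run_funnel <- function(genotypes, panel, expression, genes,
                       target_population, candidate_gene_ids = NULL,
                       window = 1e6, r2_min = 0.25, maf_min = 0.1,
                       hwe_p_min = 1e-4,
                       hwe_scope = c("per_population", "pooled"),
                       hwe_method = c("auto", "chisq", "exact"),
                       p_threshold = 0.001, alpha = 0.05,
                       populations = NULL) {
  hwe_scope <- match.arg(hwe_scope)
  hwe_method <- match.arg(hwe_method)
  shared <- intersect_samples(genotypes, expression, panel)
  geno <- genotype_matrix(genotypes$calls[shared, , drop = FALSE],
                          genotypes$variants)
  expr <- expression[, shared, drop = FALSE]
  if (is.null(candidate_gene_ids)) candidate_gene_ids <- genes$gene_id

  qc <- qc_filter(geno, r2_min = r2_min, maf_min = maf_min,
                  hwe_p_min = hwe_p_min, hwe_method = hwe_method,
                  hwe_scope = hwe_scope, panel = panel)
  records <- pop_diff_records(qc$kept, panel, target_population,
                              populations)
  selected <- select_differential_snps(records, p_threshold)
  if (length(selected) == 0)
    warning("no ancestry-differentiated SNPs selected; ",
            "downstream stages are empty")

  snp_rec <- qc$kept$variants[qc$kept$variants$rsid %in% selected, ,
                              drop = FALSE]
  pairs <- assign_cis_pairs(snp_rec, genes, window)
  if (length(selected) > 0 && nrow(pairs) == 0)
    warning("selected SNPs have no genes within the cis window")

  assoc <- pairs
  stats_cols <- c("n", "beta", "se", "t", "df", "p")
  for (cc in stats_cols) assoc[[cc]] <- rep(NA_real_, nrow(pairs))
  assoc$status <- rep("ok", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene_id[i]
    if (!g %in% rownames(expr)) {
      assoc$status[i] <- "no_expression_data"
      next
    }
    fit <- regress_pair(geno$calls[, pairs$rsid[i]], expr[g, ])
    for (cc in stats_cols) assoc[[cc]][i] <- fit[[cc]]
    assoc$status[i] <- fit$status
  }
  skipped <- assoc$status != "ok"
  if (any(skipped))
    message("pair(s) excluded from FDR adjustment: ",
            paste(sprintf("%s-%s (%s)", assoc$rsid[skipped],
                          assoc$gene_id[skipped], assoc$status[skipped]),
                  collapse = ", "))
  assoc$q <- rep(NA_real_, nrow(assoc))
  assoc$significant <- rep(FALSE, nrow(assoc))
  if (any(!skipped)) {
    adj <- bh_adjust(assoc$p[!skipped], alpha = alpha)
    assoc$q[!skipped] <- adj$q
    assoc$significant[!skipped] <- adj$reject
  }

  funnel <- data.frame(
    candidate_genes_in = length(unique(candidate_gene_ids)),
    snps_tested = nrow(genotypes$variants),
    snps_passing_qc = sum(qc$report$pass),
    differential_snps = length(selected),
    cis_pairs = nrow(pairs),
    distinct_cis_genes = length(unique(assoc$gene_id[assoc$significant])))

  structure(list(funnel = funnel, associations = assoc, popdiff = records,
                 qc = qc$report, selected_snps = selected,
                 samples = shared, alpha = alpha, window = window),
            class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("cis-eQTL discovery funnel (", length(x$samples), " samples, window ",
      format(x$window, big.mark = ","), " bp, FDR ", x$alpha, ")\n", sep = "")
  f <- x$funnel
  cat(sprintf("  candidate genes in:    %d\n", f$candidate_genes_in))
  cat(sprintf("  SNPs tested:           %d\n", f$snps_tested))
  cat(sprintf("  SNPs passing QC:       %d\n", f$snps_passing_qc))
  cat(sprintf("  differentiated SNPs:   %d\n", f$differential_snps))
  cat(sprintf("  cis pairs in window:   %d\n", f$cis_pairs))
  cat(sprintf("  distinct cis genes:    %d\n", f$distinct_cis_genes))
  invisible(x)
}
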