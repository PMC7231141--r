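#' Genotype matrix with variant metadata
#'
#' Container for additive alt-allele dosage calls. Rows are samples, columns
#' are biallelic variants; dosages are integers in \{0, 1, 2\} (count of alt
#' alleles) with `NA` marking a missing call. Variant metadata carries the
#' 1-based physical position and, when available, the per-variant imputation
#' accuracy r-squared used by [qc_filter()].
#'
#' @param calls Integer matrix, samples x variants, entries in \{0, 1, 2\}
#'   or `NA`. Row names are sample identifiers, column names variant rsids.
#' @param variants Data frame with columns `rsid`, `chrom`, `pos` (1-based
#'   bp), `ref`, `alt`, and optionally `r2` (imputation r-squared in
#'   \[0, 1\], `NA` for directly observed genotypes), one row per column of
#'   `calls` in the same order.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variants`, `sample_ids`.
#' @examples
#' gm <- genotype_matrix(
#'   calls = matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3,
#'                  dimnames = list(c("S1", "S2", "S3"), c("rs1", "rs2"))),
#'   variants = data.frame(rsid = c("rs1", "rs2"), chrom = "1",
#'                         pos = c(100L, 200L), ref = "A", alt = "G")
#' )
#' gm
#' @export
genotype_matrix <- function(calls, variants) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants)
  need <- c("rsid", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("`variants` is missing column(s): ", paste(miss, collapse = ", "))
  if (!"r2" %in% names(variants)) variants$r2 <- NA_real_
  variants$rsid <- as.character(variants$rsid)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$r2 <- as.numeric(variants$r2)
  if (ncol(calls) != nrow(variants))
    stop("calls has ", ncol(calls), " variant columns but variants has ",
         nrow(variants), " rows")
  dup <- variants$rsid[duplicated(variants$rsid)]
  if (length(dup)) stop("duplicate rsid(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(variants$pos) || any(variants$pos < 1))
    stop("variant positions must be integers >= 1")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage calls must be 0, 1, 2 or NA")
  r2v <- variants$r2[!is.na(variants$r2)]
  if (length(r2v) && (any(r2v < 0) || any(r2v > 1)))
    stop("imputation r2 must lie in [0, 1]")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample identifiers in `calls` row names")
  colnames(calls) <- variants$rsid
  rownames(variants) <- NULL
  structure(list(calls = calls, variants = variants,
                 sample_ids = rownames(calls)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  n_imp <- sum(!is.na(x$variants$r2))
  cat("  variants with imputation r2:", n_imp, "\n")
  cat("  missing call rate:",
      signif(mean(is.na(x$calls)), 3), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

.gt_to_dosage <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)

#' Read genotypes from VCF or tabular dosage file
#'
#' The VCF dialect consumes only the GT field of biallelic records; the
#' dosage is the count of alt alleles. Half-missing or non-diploid GT
#' entries become missing calls. The imputation r-squared is taken from the
#' INFO key `R2` when present. Multi-allelic records are rejected (the
#' pipeline is defined for biallelic SNPs only). The table dialect is a
#' tab-separated file with header columns `rsid`, `chrom`, `pos`, `ref`,
#' `alt`, `r2` followed by one dosage column per sample.
#'
#' @param path Path to the input file.
#' @param dialect `"vcf"` or `"table"`.
#' @return A [genotype_matrix()].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, dialect = c("vcf", "table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "vcf") .read_genotypes_vcf(path) else .read_genotypes_table(path)
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) not supported: ",
         paste(fix$ID[multi], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  gt <- chartr("|", "/", gt)
  dos <- .gt_to_dosage[gt]
  calls <- matrix(dos, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), rownames(gt)), byrow = TRUE)
  r2 <- suppressWarnings(vcfR::extract.info(v, element = "R2", as.numeric = TRUE))
  if (is.null(r2)) r2 <- rep(NA_real_, nrow(fix))
  variants <- data.frame(rsid = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, r2 = r2,
                         stringsAsFactors = FALSE)
  genotype_matrix(calls, variants)
}

.read_genotypes_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", "ref", "alt", "r2")
  if (!identical(names(tab)[seq_along(need)], need))
    stop("genotype table must start with columns ",
         paste(need, collapse = ", "), ": ", path)
  samp <- names(tab)[-seq_along(need)]
  if (length(samp) == 0) stop("genotype table has no sample columns: ", path)
  calls <- t(as.matrix(tab[samp]))
  storage.mode(calls) <- "integer"
  rownames(calls) <- samp
  genotype_matrix(calls, tab[need])
}

#' Write genotypes to VCF or tabular dosage file
#'
#' The VCF writer emits one biallelic record per variant with GT coded
#' `0/0`, `0/1`, `1/1` (missing `./.`) and the imputation r-squared in the
#' INFO `R2` key; phase is not represented (the container stores dosages).
#'
#' @param x A [genotype_matrix()].
#' @param path Output path.
#' @param dialect `"vcf"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, dialect = c("vcf", "table")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "genotype_matrix"))
  if (dialect == "table") {
    tab <- cbind(x$variants[c("rsid", "chrom", "pos", "ref", "alt", "r2")],
                 as.data.frame(t(x$calls), check.names = FALSE))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(x$variants), ncol = length(x$sample_ids))
  ok <- !is.na(t(x$calls))
  gt[ok] <- gt_code[t(x$calls)[ok] + 1L]
  info <- ifelse(is.na(x$variants$r2), ".",
                 sprintf("R2=%.10g", x$variants$r2))
  body <- paste(x$variants$chrom, x$variants$pos, x$variants$rsid,
                x$variants$ref, x$variants$alt, ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation accuracy r-squared\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$sample_ids), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

.norm_strand <- function(s) {
  s <- as.character(s)
  s[is.na(s) | !(s %in% c("+", "-"))] <- "*"
  s
}

#' Read gene annotation from BED or tabular file
#'
#' Internal coordinates are 1-based fully inclusive (the convention in which
#' the pipeline's worked-example coordinates are printed). BED input is
#' 0-based half-open per the standard and is converted at the boundary
#' (start + 1, end unchanged). The table dialect is tab-separated with
#' header `gene_id`, `chrom`, `start`, `end` and optional `strand`.
#'
#' @param path Path to the input file.
#' @param dialect `"bed"` or `"table"`.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`, `-`, or `*` for unknown).
#' @export
read_gene_annotation <- function(path, dialect = c("bed", "table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    ann <- data.frame(
      gene_id = if (!is.null(gr$name)) as.character(gr$name)
                else paste0("gene", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = .norm_strand(as.character(GenomicRanges::strand(gr))),
      stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
    ann <- data.frame(gene_id = as.character(tab$gene_id),
                      chrom = as.character(tab$chrom),
                      start = as.integer(tab$start), end = as.integer(tab$end),
                      strand = if ("strand" %in% names(tab))
                        .norm_strand(tab$strand) else "*",
                      stringsAsFactors = FALSE)
  }
  .validate_annotation(ann)
}

.validate_annotation <- function(ann) {
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup)) stop("duplicate gene_id(s): ", paste(unique(dup), collapse = ", "))
  bad <- ann$start > ann$end
  if (any(bad))
    stop("start > end for gene(s): ", paste(ann$gene_id[bad], collapse = ", "))
  if (any(ann$start < 1)) stop("gene start coordinates must be >= 1")
  rownames(ann) <- NULL
  ann
}

#' Write gene annotation to BED or tabular file
#'
#' @param ann Annotation data frame as returned by [read_gene_annotation()].
#' @param path Output path.
#' @param dialect `"bed"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path, dialect = c("bed", "table")) {
  dialect <- match.arg(dialect)
  ann <- .validate_annotation(as.data.frame(ann))
  if (dialect == "bed") {
    gr <- GenomicRanges::GRanges(
      seqnames = ann$chrom,
      ranges = IRanges::IRanges(start = ann$start, end = ann$end),
      strand = ann$strand)
    S4Vectors::mcols(gr)$name <- ann$gene_id
    rtracklayer::export(gr, path, format = "bed")
  } else {
    write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write expression matrices
#'
#' Tab-separated, genes in rows: the first column `gene_id`, one numeric
#' column per sample (log-scale intensities; unitless).
#'
#' @param path Path to the file.
#' @return `read_expression` returns a numeric matrix, genes x samples, with
#'   gene ids as row names and sample ids as column names.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("expression table must have first column `gene_id`: ", path)
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup)) stop("duplicate gene_id(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(names(tab)[-1]))
    stop("duplicate sample identifiers in expression header")
  m <- as.matrix(tab[-1])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))
    stop("non-numeric expression column(s): ",
         paste(names(tab[-1])[bad], collapse = ", "))
  }
  rownames(m) <- tab$gene_id
  all_missing <- rowSums(!is.na(m)) == 0
  if (any(all_missing))
    stop("gene(s) with no observed values: ",
         paste(rownames(m)[all_missing], collapse = ", "))
  m
}

#' @rdname read_expression
#' @param x Numeric matrix, genes x samples.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  tab <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample-to-population panels
#'
#' Tab-separated, columns `sample_id` and `population`. Population codes are
#' drawn from a finite declared set; pass `populations` to enforce it at
#' read time.
#'
#' @param path Path to the file.
#' @param populations Optional character vector of allowed population codes.
#' @return `read_panel` returns a data frame with columns `sample_id`,
#'   `population`.
#' @export
read_panel <- function(path, populations = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "population"), names(tab))
  if (length(miss)) stop("panel missing column(s): ", paste(miss, collapse = ", "))
  tab$sample_id <- as.character(tab$sample_id)
  tab$population <- as.character(tab$population)
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup)) stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(populations)) {
    bad <- setdiff(unique(tab$population), populations)
    if (length(bad))
      stop("population code(s) outside declared set: ",
           paste(bad, collapse = ", "))
  }
  tab[c("sample_id", "population")]
}

#' @rdname read_panel
#' @param panel Panel data frame (`sample_id`, `population`).
#' @export
write_panel <- function(panel, path) {
  stopifnot(all(c("sample_id", "population") %in% names(panel)))
  write.table(panel[c("sample_id", "population")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write censored survival records
#'
#' Tab-separated, columns `sample_id`, `time` (months, >= 0), `event`
#' (1 = event observed, 0 = right-censored), plus any further numeric
#' covariate columns.
#'
#' @param path Path to the file.
#' @return `read_survival` returns a data frame with columns `sample_id`,
#'   `time`, `event`, and any covariates.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "time", "event"), names(tab))
  if (length(miss)) stop("survival table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab$sample_id <- as.character(tab$sample_id)
  .validate_survival(tab)
}

.validate_survival <- function(tab) {
  if (!is.numeric(tab$time) || anyNA(tab$time) || any(tab$time < 0))
    stop("survival times must be numeric and >= 0")
  if (!all(tab$event %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (event)")
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup)) stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  rownames(tab) <- NULL
  tab
}

#' @rdname read_survival
#' @param surv Survival data frame (`sample_id`, `time`, `event`, ...).
#' @export
write_survival <- function(surv, path) {
  surv <- .validate_survival(as.data.frame(surv))
  write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis sample set shared by genotypes, expression, and panel
#'
#' The pipeline runs on the intersection of the three sample sets, computed
#' once and logged; an empty intersection is an error, not a silent no-op.
#'
#' @param genotypes A [genotype_matrix()].
#' @param expression Expression matrix (genes x samples).
#' @param panel Panel data frame.
#' @return Character vector of shared sample ids, in genotype order.
#' @export
intersect_samples <- function(genotypes, expression, panel) {
  g <- genotypes$sample_ids
  e <- colnames(expression)
  p <- panel$sample_id
  shared <- g[g %in% e & g %in% p]
  if (length(shared) == 0)
    stop("no samples shared by genotypes, expression, and panel")
  message(sprintf(
    "analysis sample set: %d shared (genotypes %d, expression %d, panel %d)",
    length(shared), length(g), length(e), length(p)))
  shared
}

#' Population labels for a sample list
#'
#' Strict join: every requested sample must be present in the panel; a
#' failed lookup is an error naming the sample, never a silent drop.
#'
#' @param panel Panel data frame (`sample_id`, `population`).
#' @param sample_ids Character vector of samples to label.
#' @return Named character vector of population codes.
#' @export
panel_populations <- function(panel, sample_ids) {
  idx <- match(sample_ids, panel$sample_id)
  if (anyNA(idx))
    stop("sample(s) absent from population panel: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  setNames(panel$population[idx], sample_ids)
}
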