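#' Ovarian clear cell adenocarcinoma worked example
#'
#' The published multistep analysis that motivates this package reported
#' four SNPs with Japanese-ancestry-enriched allele frequencies and seven
#' genes associated with them in cis in ovarian clear cell adenocarcinoma.
#' This loader returns those printed records -- SNP positions, gene
#' coordinates (1-based inclusive), and the reported SNP-gene pairs with
#' their regression p-values -- as a small fixture for exercising the
#' cis-window assignment stage. Note that three of the reported pairs lie
#' 640-723 kb from their gene, which is why the default cis window is
#' 1 Mb rather than 500 kb (see the package vignette).
#'
#' @return List with data frames `snps` (`rsid`, `chrom`, `pos`,
#'   `cytoband`), `genes` (`gene_id`, `chrom`, `start`, `end`, `strand`),
#'   and `pairs` (`rsid`, `gene_id`, `p_reported`).
#' @examples
#' ex <- ovcca_example()
#' assign_cis_pairs(ex$snps, ex$genes, window = 1e6)
#' @export
ovcca_example <- function() {
  dir <- system.file("extdata", package = "popcis", mustWork = TRUE)
  snps <- read.delim(file.path(dir, "ovcca_snps.tsv"),
                     stringsAsFactors = FALSE)
  snps$chrom <- as.character(snps$chrom)
  genes <- read_gene_annotation(file.path(dir, "ovcca_genes.tsv"),
                                dialect = "table")
  pairs <- read.delim(file.path(dir, "ovcca_pairs.tsv"),
                      stringsAsFactors = FALSE)
  list(snps = snps, genes = genes, pairs = pairs)
}
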