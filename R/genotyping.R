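#' Call a per-cell genotype from depth and alternate-allele count
#'
#' A cell-locus observation is missing (3) when depth < 10. It is called
#' mutant (1) when the alternate count is >= 3 and the single-cell VAF
#' passes the depth band: VAF >= 15% for depth <= 99, VAF >= 10% for depth
#' >= 100 (both boundaries inclusive). In the 10-19x band the VAF clause is
#' mathematically inert because alt >= 3 implies VAF >= 3/19 > 15%.
#' Everything else is wild type (0), or missing when
#' `ambiguous_as_missing = TRUE` and the alternate evidence (alt >= 3) falls
#' below the VAF band.
#'
#' With `zygosity = TRUE`, mutant calls whose VAF is at least `hom_vaf` are
#' reported as homozygous (2).
#'
#' All arguments are vectorized.
#'
#' @param depth Total read count(s) (DP).
#' @param alt Alternate-allele read count(s), `0 <= alt <= depth`.
#' @param ambiguous_as_missing Treat sub-band alternate evidence as missing
#'   instead of wild type.
#' @param zygosity Emit code 2 for high-VAF mutant calls.
#' @param hom_vaf VAF threshold for homozygous calls (default 0.9).
#' @return Integer vector of codes in `{0, 1, 3}` (or `{0, 1, 2, 3}` with
#'   `zygosity = TRUE`).
#' @export
call_genotype <- function(depth, alt, ambiguous_as_missing = FALSE,
                          zygosity = FALSE, hom_vaf = 0.9) {
  if (any(alt > depth)) stop("alt count cannot exceed depth")
  if (any(depth < 0 | alt < 0)) stop("counts must be non-negative")
  n <- max(length(depth), length(alt))
  depth <- rep_len(depth, n)
  alt <- rep_len(alt, n)
  code <- integer(n)
  missing <- depth < 10
  code[missing] <- 3L
  vaf <- ifelse(depth > 0, alt / depth, 0)
  band_ok <- ifelse(depth >= 100, vaf >= 0.10, vaf >= 0.15)
  mut <- !missing & alt >= 3 & band_ok
  code[mut] <- 1L
  if (ambiguous_as_missing) {
    amb <- !missing & alt >= 3 & !band_ok
    code[amb] <- 3L
  }
  if (zygosity) code[mut & vaf >= hom_vaf] <- 2L
  code
}

#' Call a genotype matrix from read-count matrices
#'
#' @param reads List with integer matrices `depth` and `alt` (cells x loci),
#'   as produced by [simulate_read_counts()].
#' @param ... Passed to [call_genotype()].
#' @return Integer matrix of genotype codes with the input dimnames.
#' @export
call_genotype_matrix <- function(reads, ...) {
  if (!all(dim(reads$depth) == dim(reads$alt)))
    stop("depth and alt matrices must have identical shape")
  G <- matrix(call_genotype(as.vector(reads$depth), as.vector(reads$alt), ...),
              nrow(reads$depth), ncol(reads$depth),
              dimnames = dimnames(reads$alt))
  G
}

#' Estimate the allele-dropout rate from germline heterozygous SNPs
#'
#' Every cell is truly heterozygous at a common germline SNP locus, so any
#' homozygous-looking call there is a dropout event. The estimate is the
#' fraction of non-missing calls at the SNP loci that are homozygous
#' (reference, code 0, or alternate, code 2). Both dropout directions are
#' counted; pass zygosity-mode calls (see [call_genotype()]) so that
#' homozygous-alternate cells are distinguishable from heterozygous ones.
#'
#' @param snp_genotypes Genotype code matrix restricted to known germline
#'   heterozygous SNP loci.
#' @return Estimated allele-dropout proportion.
#' @export
estimate_ado <- function(snp_genotypes) {
  g <- as.vector(snp_genotypes)
  informative <- g != 3L
  if (!any(informative)) stop("all SNP calls are missing")
  sum(g[informative] != 1L) / sum(informative)
}

#' Pooled single-cell VAF at each locus
#'
#' Alternate reads summed over cells divided by total reads summed over
#' cells.
#'
#' @param reads List with matrices `depth` and `alt`.
#' @param loci Optional locus subset (indices or names).
#' @return Named numeric vector of pooled VAFs.
#' @export
compute_scvaf <- function(reads, loci = NULL) {
  depth <- reads$depth
  alt <- reads$alt
  if (!is.null(loci)) {
    depth <- depth[, loci, drop = FALSE]
    alt <- alt[, loci, drop = FALSE]
  }
  tot <- colSums(depth)
  if (any(tot == 0)) stop("zero total depth at some locus")
  colSums(alt) / tot
}

#' Sample-level quality summary
#'
#' @param genotypes Genotype code matrix (all loci).
#' @param reads Optional read-count list for per-locus mean depth.
#' @param snp_loci Column names/indices of germline het SNP loci.
#' @return List with `ado_rate`, `missing_fraction` per locus, `mean_depth`
#'   per locus (if reads given), and `n_cells`.
#' @export
sample_qc <- function(genotypes, reads = NULL, snp_loci = NULL) {
  ado <- if (!is.null(snp_loci))
    estimate_ado(genotypes[, snp_loci, drop = FALSE]) else NA_real_
  list(ado_rate = ado,
       missing_fraction = colMeans(genotypes == 3L),
       mean_depth = if (!is.null(reads)) colMeans(reads$depth) else NULL,
       n_cells = nrow(genotypes))
}

#' Read and write genotype matrices as TSV
#'
#' Tab-separated layout: header row of locus ids, first column `cell_id`,
#' genotype codes 0/1/2/3.
#'
#' @param genotypes Integer code matrix with cell ids as rownames.
#' @param path File path.
#' @return `read_genotype_tsv` returns the integer matrix; the writer
#'   returns `path` invisibly.
#' @export
write_genotype_tsv <- function(genotypes, path) {
  if (nrow(genotypes) == 0L) stop("empty cell set: nothing to write")
  df <- data.frame(cell_id = rownames(genotypes) %||%
                     paste0("cell", seq_len(nrow(genotypes))),
                   genotypes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!identical(names(df)[1], "cell_id"))
    stop("malformed genotype TSV: first column must be cell_id")
  if (nrow(df) == 0L) stop("genotype TSV contains no cells")
  m <- as.matrix(df[, -1, drop = FALSE])
  g <- suppressWarnings(matrix(as.integer(m), nrow(m), ncol(m),
                               dimnames = list(df$cell_id, colnames(m))))
  if (any(is.na(g)) || !all(g %in% c(0L, 1L, 2L, 3L)))
    stop("genotype TSV contains codes outside {0, 1, 2, 3}")
  g
}

#' Read variant annotations from a VCF
#'
#' Parses the sites records of a VCF 4.x file (1-based coordinates) and
#' returns one row per variant with any `GENE` and `AA` INFO fields
#' extracted, for labelling tree events.
#'
#' @param path VCF file path.
#' @return data.frame with chrom, pos, id, ref, alt, gene, protein_change.
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF annotations requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_field <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else x
  }
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
             ref = fix$REF, alt = fix$ALT,
             gene = info_field("GENE"), protein_change = info_field("AA"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
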