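# Plain-text I/O: genotype matrices and phenotypes as TSV so the proxies
# can be applied to user data, plus a minimal haploid VCF export for
# interoperability.

#' Write / read a genotype matrix as TSV
#'
#' Rows are individuals, columns are loci; the header carries locus
#' positions in centimorgans (prefixed `cM_`).
#'
#' @param alleles 0/1 genotype matrix.
#' @param positions Locus positions in Morgans.
#' @param path Output file.
#' @return `write_genotypes_tsv()` returns `path` invisibly;
#'   `read_genotypes_tsv()` returns a list with `alleles` (integer matrix)
#'   and `positions` (Morgans).
#' @export
write_genotypes_tsv <- function(alleles, positions, path) {
  stopifnot(ncol(alleles) == length(positions))
  colnames(alleles) <- sprintf("cM_%g", positions * 100)
  utils::write.table(alleles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  positions <- as.numeric(sub("^cM_", "", colnames(m))) / 100
  storage.mode(m) <- "integer"
  list(alleles = unname(m), positions = positions)
}

#' Write / read phenotypes as a two-column TSV
#'
#' @param y Phenotype vector.
#' @param path Output file.
#' @param ids Optional individual identifiers (default `ind_1 ...`).
#' @return `write_phenotypes_tsv()` returns `path` invisibly;
#'   `read_phenotypes_tsv()` returns a tibble with `id` and `value`.
#' @export
write_phenotypes_tsv <- function(y, path, ids = NULL) {
  ids <- ids %||% paste0("ind_", seq_along(y))
  utils::write.table(data.frame(id = ids, value = y), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE))
}

#' Export haplotypes as a minimal haploid VCF
#'
#' One record per locus on a single chromosome; genetic positions in
#' Morgans are mapped to integer coordinates at 1e6 bp per Morgan. The GT
#' field holds the haploid allele (0 or 1). Arbitrary REF/ALT letters (A/T)
#' are used since the simulator tracks abstract biallelic states.
#'
#' @param alleles 0/1 genotype matrix (individuals x loci).
#' @param positions Locus positions in Morgans.
#' @param path Output file.
#' @param chrom Chromosome name.
#' @return `path`, invisibly.
#' @export
write_vcf_haploid <- function(alleles, positions, path, chrom = "1") {
  stopifnot(ncol(alleles) == length(positions))
  n <- nrow(alleles)
  ids <- paste0("ind_", seq_len(n))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gsaccuracy",
    sprintf("##contig=<ID=%s>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_along(positions), function(j) {
    paste(c(chrom, round(positions[j] * 1e6) + 1, sprintf("locus_%d", j),
            "A", "T", ".", "PASS", ".", "GT", alleles[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
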