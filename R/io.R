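#' Read a tab-separated variant table
#'
#' The canonical plain-text exchange format: a header line naming the
#' fixed columns `CHROM`, `POS`, `REF`, `ALT` (optionally
#' `FUNCTIONAL_CLASS`) followed by one column per strain, and one row
#' per biallelic locus with per-strain calls coded `0`, `1` or `.`
#' (missing).  Anything that is not a confident `0`/`1` call is treated
#' as missing.
#'
#' @param path file path.
#' @return A `genotype_matrix`.
#' @export
read_variant_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  fixed <- c("CHROM", "POS", "REF", "ALT")
  if (!all(fixed %in% names(tab)))
    stop("variant table must have CHROM, POS, REF, ALT columns")
  opt <- intersect("FUNCTIONAL_CLASS", names(tab))
  strain_cols <- setdiff(names(tab), c(fixed, opt))
  if (length(strain_cols) == 0) stop("variant table names no strains")
  pos <- suppressWarnings(as.integer(tab$POS))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop(sprintf("malformed POS at line %d", bad + 1L))
  }
  parse_call <- function(x) ifelse(x == "0", 0L, ifelse(x == "1", 1L, NA_integer_))
  calls <- t(vapply(tab[strain_cols], parse_call, integer(nrow(tab))))
  if (nrow(tab) == 1L) calls <- matrix(calls, ncol = 1L,
                                       dimnames = list(strain_cols, NULL))
  loci <- data.frame(chrom = tab$CHROM, pos = pos, ref = tab$REF,
                     alt = tab$ALT, stringsAsFactors = FALSE)
  if (length(opt)) loci$functional_class <- tab$FUNCTIONAL_CLASS
  genotype_matrix(calls, loci, strain_cols)
}

#' Write a genotype matrix as a tab-separated variant table
#'
#' @param m a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(m, path) {
  calls <- t(m$calls)
  calls[is.na(calls)] <- "."
  out <- data.frame(CHROM = m$loci$chrom, POS = m$loci$pos,
                    REF = m$loci$ref, ALT = m$loci$alt,
                    FUNCTIONAL_CLASS = m$loci$functional_class,
                    calls, check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-(1:5)] <- m$strains
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read strain metadata (strain, niche, optional clade)
#'
#' @param path TSV with columns `strain`, `niche` and optionally
#'   `clade`.
#' @return Data frame with unique strain names.
#' @export
read_strain_metadata <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("strain", "niche") %in% names(tab)))
    stop("metadata must have 'strain' and 'niche' columns")
  if (anyDuplicated(tab$strain)) stop("strain names must be unique")
  tab
}

#' Read and write newick trees
#'
#' Thin wrappers around \pkg{ape}'s newick parser so trees move through
#' the same interface as the rest of the package.  `write_newick` then
#' `read_newick` is the identity up to branch-length formatting.
#'
#' @param path file path.
#' @return `read_newick` returns an \pkg{ape} `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: unreadable tree")
  tr
}

#' @rdname read_newick
#' @param t an \pkg{ape} `phylo` object.
#' @export
write_newick <- function(t, path) {
  ape::write.tree(t, file = path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Optional reader for standard VCF behind the same interface as
#' [read_variant_table()].  Only biallelic SNP records are used; records
#' with multiple alternate alleles are dropped with a warning.  Any
#' genotype that is not a confident homozygous reference or alternate
#' call (heterozygous, multi-allelic or absent) is treated as missing.
#'
#' @param path path to an uncompressed VCF file.
#' @return A `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- strsplit(lines[-1], "\t")
  fields <- matrix(unlist(body), ncol = length(hdr), byrow = TRUE)
  colnames(fields) <- hdr
  strains <- setdiff(hdr, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO", "FORMAT"))
  multi <- grepl(",", fields[, "ALT"])
  if (any(multi))
    warning(sprintf("%d multi-allelic records dropped", sum(multi)))
  snp <- nchar(fields[, "REF"]) == 1L & nchar(fields[, "ALT"]) == 1L & !multi
  fields <- fields[snp, , drop = FALSE]
  gt <- function(x) {
    g <- sub(":.*", "", x)
    ifelse(g %in% c("0", "0/0", "0|0"), 0L,
           ifelse(g %in% c("1", "1/1", "1|1"), 1L, NA_integer_))
  }
  calls <- t(apply(fields[, strains, drop = FALSE], 2, gt))
  if (sum(snp) == 1L) calls <- matrix(calls, ncol = 1L)
  rownames(calls) <- strains
  loci <- data.frame(chrom = fields[, "CHROM"],
                     pos = as.integer(fields[, "POS"]),
                     ref = fields[, "REF"], alt = fields[, "ALT"],
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, loci, strains)
}
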