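#' Construct a genotype matrix
#'
#' The universal exchange object of the package: an ordered strain panel
#' typed at an ordered set of biallelic loci.  Calls are coded `0`
#' (reference allele), `1` (alternate allele) or `NA` (missing); missing
#' calls are a first-class third state and are never imputed.
#'
#' @param calls integer matrix, strains in rows and loci in columns,
#'   over `{0, 1, NA}`.
#' @param loci data frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt` and optionally `functional_class` (one of
#'   `"synonymous"`, `"missense"`, `"regulatory"`, `"other"`,
#'   `"unknown"`; defaults to `"unknown"`).
#' @param strains character vector of unique strain names, one per row
#'   of `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `strains`, `loci` and `calls`.  Loci are sorted by
#'   `(chrom, pos)`; duplicate positions are an error.
#' @export
genotype_matrix <- function(calls, loci, strains) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  strains <- as.character(strains)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (is.null(loci$functional_class)) loci$functional_class <- "unknown"
  fc_levels <- c("synonymous", "missense", "regulatory", "other", "unknown")
  if (!all(loci$functional_class %in% fc_levels))
    stop("unknown functional_class value")
  if (anyDuplicated(strains)) stop("strain names must be unique")
  if (nrow(calls) != length(strains))
    stop("calls must have one row per strain")
  if (ncol(calls) != nrow(loci))
    stop("calls must have one column per locus")
  if (any(loci$pos < 1)) stop("positions are 1-based and must be >= 1")
  if (any(!is.na(calls) & calls != 0L & calls != 1L))
    stop("calls must be 0, 1 or NA")
  if (!is.null(loci$ref) && any(loci$ref == loci$alt))
    stop("ref and alt alleles must differ")
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  if (anyDuplicated(loci[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) locus")
  rownames(loci) <- NULL
  dimnames(calls) <- list(strains, NULL)
  structure(list(strains = strains, loci = loci, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d strains x %d loci (%d missing calls)\n",
              length(x$strains), n_loci(x), sum(is.na(x$calls))))
  invisible(x)
}

#' Number of loci in a genotype matrix
#' @param m a `genotype_matrix`.
#' @return Integer locus count.
#' @export
n_loci <- function(m) nrow(m$loci)

#' Subset a genotype matrix by locus index
#' @param m a `genotype_matrix`.
#' @param idx integer locus indices (kept in genomic order).
#' @return A `genotype_matrix` restricted to the selected loci.
#' @export
subset_loci <- function(m, idx) {
  genotype_matrix(m$calls[, idx, drop = FALSE],
                  m$loci[idx, , drop = FALSE], m$strains)
}

#' Drop loci with too few called strains
#'
#' Retains loci at which at least `min_called` strains have a
#' non-missing call, mirroring coverage filters applied to resequencing
#' panels (e.g. requiring calls in 18 of 19 strains).  Idempotent and
#' monotone in `min_called`.
#'
#' @param m a `genotype_matrix`.
#' @param min_called required number of non-missing calls per locus.
#' @return The filtered `genotype_matrix`, locus order preserved.
#' @export
filter_by_coverage <- function(m, min_called) {
  stopifnot(min_called >= 0, min_called <= length(m$strains))
  keep <- colSums(!is.na(m$calls)) >= min_called
  subset_loci(m, which(keep))
}

#' Flag cross variants present in a wider strain panel
#'
#' A cross locus is "shared" when some panel strain carries the
#' alternate allele at the same (chromosome, position).  Alternate
#' alleles segregating only in the panel (not in the cross) are
#' ignored, as are allele identities: matching is by coordinate.
#'
#' @param cross_loci data frame with columns `chrom` and `pos`.
#' @param panel a `genotype_matrix` for the comparison panel.
#' @return Logical vector, one flag per cross locus.
#' @export
match_cross_variants <- function(cross_loci, panel) {
  key <- function(ch, po) paste(ch, po, sep = ":")
  carried <- colSums(panel$calls == 1L, na.rm = TRUE) > 0
  panel_keys <- key(panel$loci$chrom, panel$loci$pos)[carried]
  key(cross_loci$chrom, cross_loci$pos) %in% panel_keys
}

#' Collapse a clade to its modal pseudo-strain
#'
#' Replaces a set of closely related strains (whose within-clade
#' phylogeny cannot be resolved reliably, e.g. the wine/European clade)
#' by a single pseudo-strain carrying, at every locus, the most
#' frequent non-missing call among the members.  Ties break toward the
#' reference allele; loci where every member is missing stay missing.
#'
#' @param m a `genotype_matrix`.
#' @param members character vector of member strain names.
#' @param name name for the pseudo-strain.
#' @return A `genotype_matrix` with the members replaced by the
#'   pseudo-strain.
#' @export
collapse_clade_to_modal <- function(m, members, name = "clade_modal") {
  if (length(members) == 0) stop("empty member set")
  if (!all(members %in% m$strains)) stop("members must be panel strains")
  sub <- m$calls[members, , drop = FALSE]
  n_alt <- colSums(sub == 1L, na.rm = TRUE)
  n_ref <- colSums(sub == 0L, na.rm = TRUE)
  modal <- ifelse(n_alt + n_ref == 0L, NA_integer_,
                  ifelse(n_alt > n_ref, 1L, 0L))
  keep <- setdiff(m$strains, members)
  calls <- rbind(m$calls[keep, , drop = FALSE], matrix(modal, nrow = 1))
  genotype_matrix(calls, m$loci, c(keep, name))
}
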