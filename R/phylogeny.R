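#' Pairwise SNP-difference distance matrix
#'
#' `d(i, j)` is the raw count of loci at which strains `i` and `j` are
#' both called and their calls differ.  Loci missing in either strain
#' of a pair are excluded from that pair only; no normalisation by the
#' number of co-called loci is applied by default.
#'
#' @param m a `genotype_matrix` (or one restricted to a window via
#'   [subset_loci()]).
#' @param normalize divide each entry by the number of co-called loci
#'   for that pair (off by default, matching raw SNP differences).
#' @return Symmetric numeric matrix with zero diagonal, strain names on
#'   both dimensions.
#' @export
snp_distance_matrix <- function(m, normalize = FALSE) {
  if (length(m$strains) < 3) stop("need at least 3 strains")
  D <- snp_dist_cpp(m$calls, 1L, n_loci(m))
  if (normalize) {
    called <- !is.na(m$calls)
    cc <- tcrossprod(called * 1)
    D <- ifelse(cc > 0, D / cc, 0)
  }
  dimnames(D) <- list(m$strains, m$strains)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with two reproducibility
#' guarantees: negative branch-length estimates are clamped to zero,
#' and ties in the join criterion are broken deterministically toward
#' the pair of lowest-sorting strain names, so equidistant taxa always
#' produce the same tree.  Exact on additive distance matrices.
#'
#' @param d symmetric distance matrix with strain names.
#' @return An unrooted \pkg{ape} `phylo`.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-9))
    stop("distance matrix must be symmetric")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(d)))
  prio <- as.integer(rank(labs, ties.method = "first")) - 1L
  res <- nj_unrooted_cpp(d, prio)
  tr <- structure(list(edge = res$edge, edge.length = res$edge.length,
                       Nnode = res$Nnode, tip.label = labs),
                  class = "phylo", order = "cladewise")
  tr
}

#' Sliding-window specification
#'
#' @param width window width in variants (default 500; 200 is used for
#'   sparser panels).  Must be at least 4.
#' @return A `window_spec` list.
#' @export
window_spec <- function(width = 500) {
  if (width < 4) stop("window width must be at least 4 variants")
  structure(list(width = as.integer(width)), class = "window_spec")
}

# 0-based [lo, hi] window of up to `width` variants centred on idx,
# truncated (shifted, kept at full width) at chromosome ends.
window_bounds <- function(m, idx, width) {
  chrom <- m$loci$chrom
  block <- which(chrom == chrom[idx])
  b0 <- block[1]; b1 <- block[length(block)]
  effw <- min(width, b1 - b0 + 1)
  lo <- idx - (effw - 1) %/% 2
  lo <- max(b0, min(lo, b1 - effw + 1))
  c(lo, lo + effw - 1)
}

#' Local midpoint-rooted phylogeny for one variant
#'
#' Builds the neighbor-joining tree from SNP differences within a
#' window of `w$width` variants centred on the focal variant (truncated
#' at chromosome ends, never crossing chromosomes; the focal variant is
#' included in its own window by default) and midpoint-roots it so that
#' the emergence rules can walk a rooted binary tree.
#'
#' @param m a `genotype_matrix` sorted by position (enforced by
#'   construction).
#' @param idx focal variant index.
#' @param w a [window_spec()].
#' @param include_focal drop the focal variant from its own window when
#'   `FALSE`.
#' @return A rooted \pkg{ape} `phylo`; attribute `low_confidence` is
#'   `TRUE` when the window holds fewer than 4 variants.
#' @export
local_tree_for_variant <- function(m, idx, w = window_spec(),
                                   include_focal = TRUE) {
  bounds <- window_bounds(m, idx, w$width)
  cols <- seq(bounds[1], bounds[2])
  if (!include_focal) cols <- setdiff(cols, idx)
  D <- snp_dist_cpp(m$calls, min(cols), max(cols))
  if (!include_focal && idx >= min(cols) && idx <= max(cols)) {
    Dfoc <- snp_dist_cpp(m$calls, idx, idx)
    D <- D - Dfoc
  }
  prio <- as.integer(rank(m$strains, ties.method = "first")) - 1L
  res <- local_tree_cpp(D, prio)
  tr <- structure(list(edge = res$edge, edge.length = res$edge.length,
                       Nnode = res$Nnode, tip.label = m$strains),
                  class = "phylo", order = "cladewise")
  attr(tr, "low_confidence") <- length(cols) < 4
  tr
}

#' Sliding-window sequence-identity track
#'
#' For each window, the fraction of co-called loci at which the query
#' and reference strains carry the same call; useful for visualising
#' mosaicism (identity to the locally copied founder approaches 1 and
#' drops sharply at recombination breakpoints).
#'
#' @param m a `genotype_matrix`.
#' @param query query strain name.
#' @param reference reference strain name (possibly a collapsed modal
#'   pseudo-strain produced by [collapse_clade_to_modal()]).
#' @param w a [window_spec()].
#' @param stride distance in variants between successive window
#'   centres.
#' @return Data frame: `chrom`, `center_pos`, `identity` in `[0, 1]`
#'   (`NaN` when a window has no co-called loci).
#' @export
identity_track <- function(m, query, reference, w = window_spec(),
                           stride = 1) {
  stopifnot(query %in% m$strains, reference %in% m$strains)
  q <- m$calls[query, ]
  r <- m$calls[reference, ]
  centers <- seq(1, n_loci(m), by = stride)
  out <- lapply(centers, function(i) {
    b <- window_bounds(m, i, w$width)
    cols <- seq(b[1], b[2])
    co <- !is.na(q[cols]) & !is.na(r[cols])
    data.frame(chrom = m$loci$chrom[i], center_pos = m$loci$pos[i],
               identity = if (any(co)) mean(q[cols][co] == r[cols][co])
                          else NaN,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
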