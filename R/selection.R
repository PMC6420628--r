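#' Directional (sign-coherence) test for selection on QTLs
#'
#' Under neutrality the trait-increasing allele of a QTL should come
#' from either parent with equal probability, so nearby QTL pairs from
#' the same parent should be no more frequent than chance.  For every
#' within-trait, within-chromosome QTL pair the distance (in marker
#' index units) is binned; a pair is coherent when both
#' trait-increasing alleles come from the same parent.  The per-bin
#' coherent fraction is computed per trait and averaged across traits;
#' a pooled two-sided binomial test against 0.5 is reported per bin.
#'
#' @param qtls data frame with columns `trait`, `marker` (genome-
#'   ordered index), `chrom`, and `high_parent` (parental origin of the
#'   trait-increasing allele; any two-level coding).
#' @param max_distance largest pair distance (markers) considered.
#' @param bins number of equal-width distance bins.
#' @return Data frame per bin: `bin_lo`, `bin_hi`, `n_pairs`,
#'   `coherent_fraction` (mean over traits; `NA` for empty bins),
#'   `pooled_fraction`, `p_binomial`.
#' @export
coherence_vs_distance <- function(qtls, max_distance = 500, bins = 10) {
  stopifnot(nrow(qtls) >= 2)
  pairs <- list()
  for (tr in unique(qtls$trait)) {
    q <- qtls[qtls$trait == tr, , drop = FALSE]
    if (nrow(q) < 2) next
    idx <- utils::combn(nrow(q), 2)
    same_chr <- q$chrom[idx[1, ]] == q$chrom[idx[2, ]]
    d <- abs(q$marker[idx[1, ]] - q$marker[idx[2, ]])
    keep <- same_chr & d <= max_distance
    if (!any(keep)) next
    pairs[[tr]] <- data.frame(trait = tr, distance = d[keep],
                              coherent = q$high_parent[idx[1, keep]] ==
                                q$high_parent[idx[2, keep]])
  }
  if (!length(pairs)) stop("no within-chromosome QTL pairs in range")
  pp <- do.call(rbind, pairs)
  brk <- seq(0, max_distance, length.out = bins + 1)
  pp$bin <- cut(pp$distance, brk, include.lowest = TRUE, labels = FALSE)
  out <- lapply(seq_len(bins), function(b) {
    sub <- pp[pp$bin == b, , drop = FALSE]
    if (!nrow(sub))
      return(data.frame(bin_lo = brk[b], bin_hi = brk[b + 1], n_pairs = 0L,
                        coherent_fraction = NA_real_,
                        pooled_fraction = NA_real_, p_binomial = NA_real_))
    per_trait <- tapply(sub$coherent, sub$trait, mean)
    bt <- binom.test(sum(sub$coherent), nrow(sub), p = 0.5)
    data.frame(bin_lo = brk[b], bin_hi = brk[b + 1], n_pairs = nrow(sub),
               coherent_fraction = mean(per_trait, na.rm = TRUE),
               pooled_fraction = mean(sub$coherent),
               p_binomial = bt$p.value)
  })
  res <- do.call(rbind, out)
  attr(res, "pooled_p") <- binom.test(sum(pp$coherent), nrow(pp),
                                      p = 0.5)$p.value
  attr(res, "n_pairs_total") <- nrow(pp)
  res
}

#' Fraction of k-occurrence variants confined to one ecological niche
#'
#' For variants whose alternate allele occurs in exactly `k` strains
#' (k = 2 or 3; higher multiplicities are confounded because few niches
#' hold more than three isolates), the fraction whose carriers were all
#' isolated from the same ecological niche.
#'
#' @param m a `genotype_matrix`.
#' @param niches named character vector (by strain) of niche labels.
#' @param k multiplicity, 2 or 3.
#' @param synonymous_only restrict to loci annotated
#'   `functional_class == "synonymous"`.
#' @return List: `fraction`, `n_same_niche`, `n_variants`.
#' @export
niche_sharing_fraction <- function(m, niches, k = 2,
                                   synonymous_only = FALSE) {
  stopifnot(k %in% c(2, 3))
  if (!all(m$strains %in% names(niches)))
    stop("niche labels must cover all strains")
  if (any(!nzchar(niches[m$strains]))) stop("empty niche label")
  keep <- colSums(m$calls == 1L, na.rm = TRUE) == k
  if (synonymous_only)
    keep <- keep & m$loci$functional_class == "synonymous"
  idx <- which(keep)
  if (!length(idx))
    return(list(fraction = NA_real_, n_same_niche = 0L, n_variants = 0L))
  same <- vapply(idx, function(j) {
    carriers <- m$strains[which(m$calls[, j] == 1L)]
    length(unique(niches[carriers])) == 1
  }, logical(1))
  list(fraction = mean(same), n_same_niche = sum(same),
       n_variants = length(idx))
}

#' Neutral null distribution for niche sharing
#'
#' Per replicate, places `n_variants` neutrally on the strain tree
#' (ancestral occurrence with probability proportional to branch
#' length, propagated to all descendants) and computes the same-niche
#' fraction among k-occurrence variants.  The permutation p-value uses
#' add-one smoothing so it is never exactly zero.
#'
#' @param t \pkg{ape} `phylo` whose tips are the strains.
#' @param niches named niche labels covering the tips.
#' @param n_variants variants per replicate.
#' @param k multiplicity (2 or 3).
#' @param n_reps replicates (default 50).
#' @param observed optional observed fraction to compare against.
#' @param genome a [genome_model()] used for variant positions.
#' @return List: `null_fractions`, `mean`, `sd`, and (when `observed`
#'   is given) `p_value` = (1 + #\{null >= observed\}) / (n_reps + 1).
#' @export
niche_null_distribution <- function(t, niches, n_variants, k = 2,
                                    n_reps = 50, observed = NULL,
                                    genome = genome_model()) {
  if (!all(t$tip.label %in% names(niches)))
    stop("niche labels must cover the tree tips")
  fr <- vapply(seq_len(n_reps), function(r) {
    pop <- place_neutral_variants_on_tree(t, n_variants, genome)
    niche_sharing_fraction(pop$matrix, niches, k)$fraction
  }, numeric(1))
  out <- list(null_fractions = fr, mean = mean(fr, na.rm = TRUE),
              sd = sd(fr, na.rm = TRUE))
  if (!is.null(observed))
    out$p_value <- (1 + sum(fr >= observed, na.rm = TRUE)) / (n_reps + 1)
  out
}
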