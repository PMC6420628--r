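.transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
.transversion_partners <- list(A = c("C", "T"), G = c("C", "T"),
                               C = c("A", "G"), T = c("A", "G"))

#' Generate random point mutations
#'
#' Draws `n` single-nucleotide mutations uniformly over the genome
#' (chromosome occupancy is therefore proportional to chromosome
#' length) with transitions and transversions in the ratio
#' `mm$tstv_ratio` in expectation.  Sites in `exclude` and sites
#' already drawn in the same call are redrawn, so reversion within an
#' isolate never occurs.
#'
#' @param n number of mutations (>= 0).
#' @param genome a [genome_model()].
#' @param mm a [mutation_model()].
#' @param exclude genome coordinates (concatenated scale) that must not
#'   be hit, typically sites where the isolate already carries the
#'   alternate allele.
#' @return Data frame with columns `chrom`, `pos`, `gpos`, `ref`,
#'   `alt`, `transition`.
#' @export
generate_random_mutations <- function(n, genome = genome_model(),
                                      mm = mutation_model(),
                                      exclude = numeric(0)) {
  if (n == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      gpos = numeric(0), ref = character(0),
                      alt = character(0), transition = logical(0),
                      stringsAsFactors = FALSE))
  gpos <- draw_unique_gpos(n, genome, exclude)
  loci <- gpos_to_loci(gpos, genome)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  is_ts <- runif(n) < mm$tstv_ratio / (mm$tstv_ratio + 1)
  alt <- character(n)
  alt[is_ts] <- .transition_partner[ref[is_ts]]
  if (any(!is_ts)) {
    pick <- runif(sum(!is_ts)) < 0.5
    tv <- vapply(.transversion_partners[ref[!is_ts]], `[`, "", 1)
    tv2 <- vapply(.transversion_partners[ref[!is_ts]], `[`, "", 2)
    alt[!is_ts] <- ifelse(pick, tv, tv2)
  }
  data.frame(chrom = loci$chrom, pos = loci$pos, gpos = gpos, ref = ref,
             alt = alt, transition = is_ts, stringsAsFactors = FALSE)
}

#' Simulate one meiosis between two haploid genotypes
#'
#' One crossover per chromosome, with the breakpoint uniform in
#' physical bp; the product alternates parental segments, so every
#' output call equals one parent's call at that locus.
#'
#' @param calls_a,calls_b integer call vectors for the two parents over
#'   the same loci.
#' @param loci data frame with `chrom` and `pos` for those loci.
#' @param genome a [genome_model()].
#' @return List with `calls` (the haploid product) and `breakpoints`
#'   (chromosome, breakpoint position, and which parent contributed the
#'   left segment).
#' @export
simulate_meiosis <- function(calls_a, calls_b, loci, genome = genome_model()) {
  stopifnot(length(calls_a) == length(calls_b),
            length(calls_a) == nrow(loci))
  nchr <- length(genome$chrom)
  bp <- ceiling(runif(nchr) * genome$lengths)
  left_a <- runif(nchr) < 0.5
  ci <- match(loci$chrom, genome$chrom)
  from_a <- (loci$pos <= bp[ci]) == left_a[ci]
  calls <- ifelse(from_a, calls_a, calls_b)
  list(calls = as.integer(calls),
       breakpoints = data.frame(chrom = genome$chrom, pos = as.integer(bp),
                                left_parent = ifelse(left_a, "a", "b"),
                                stringsAsFactors = FALSE))
}

#' Admixture simulation parameters
#'
#' Defaults emulate a wild-yeast-like panel: five founder lineages with
#' 30,000 private mutations each, ten mosaic strains produced by random
#' mating of founder pairs (one meiotic crossover per chromosome, one
#' haploid product retained) and 10,000 further private mutations in
#' every one of the 15 strains.
#'
#' @param n_founders,muts_per_founder,n_mosaics,muts_per_strain_post
#'   counts, see description.
#' @return An `admixture_params` list.
#' @export
admixture_params <- function(n_founders = 5, muts_per_founder = 30000,
                             n_mosaics = 10, muts_per_strain_post = 10000) {
  stopifnot(n_founders >= 0, muts_per_founder >= 0, n_mosaics >= 0,
            muts_per_strain_post >= 0)
  if (n_mosaics > 0 && n_founders < 2)
    stop("mosaics require at least two founders")
  structure(list(n_founders = n_founders,
                 muts_per_founder = muts_per_founder,
                 n_mosaics = n_mosaics,
                 muts_per_strain_post = muts_per_strain_post),
            class = "admixture_params")
}

new_simulated_population <- function(matrix, events, balanced, genome,
                                     mosaics = NULL, params = list(),
                                     seed = NULL) {
  gpos <- loci_to_gpos(matrix$loci$chrom, matrix$loci$pos, genome)
  structure(list(matrix = matrix, events = events, balanced = balanced,
                 locus_gpos = gpos, genome = genome, mosaics = mosaics,
                 params = params, seed = seed),
            class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  cat(sprintf(paste0("simulated_population: %d strains x %d loci; ",
                     "%d mutation events, %d balanced loci\n"),
              length(x$matrix$strains), n_loci(x$matrix),
              nrow(x$events), sum(x$balanced)))
  invisible(x)
}

#' True per-locus emergence-event counts from the truth log
#'
#' @param pop a `simulated_population`.
#' @return Integer vector aligned with the population's loci: the
#'   number of independent origination events recorded at each site.
#'   Balanced loci, which have no discrete origination event, count 0.
#' @export
true_emergence_counts <- function(pop) {
  counts <- integer(n_loci(pop$matrix))
  tab <- table(pop$events$gpos)
  idx <- match(as.numeric(names(tab)), pop$locus_gpos)
  counts[idx[!is.na(idx)]] <- as.integer(tab[!is.na(idx)])
  counts
}

#' Number of truly homoplastic loci (>= 2 independent origination events)
#' @param pop a `simulated_population`.
#' @return Integer count.
#' @export
true_homoplasy_count <- function(pop) sum(true_emergence_counts(pop) >= 2)

#' Simulate an admixed mosaic population with a ground-truth event log
#'
#' Builds founder lineages carrying private random mutations, derives
#' mosaic strains by random mating of distinct founder pairs through
#' [simulate_meiosis()], then deposits further private mutations in all
#' strains.  Every de novo mutation is recorded as it occurs, so the
#' true extent of homoplasy (the same site mutated independently in two
#' or more lineages) is computable exactly from the truth log, while
#' the genotype matrix itself is blinded.
#'
#' @param ap an [admixture_params()].
#' @param genome a [genome_model()].
#' @param mm a [mutation_model()].
#' @param seed optional integer seed, recorded in the result.
#' @return A `simulated_population`.
#' @export
build_admixed_population <- function(ap = admixture_params(),
                                     genome = genome_model(),
                                     mm = mutation_model(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  founders <- paste0("founder", seq_len(ap$n_founders))
  mosaics <- if (ap$n_mosaics > 0) paste0("mosaic", seq_len(ap$n_mosaics))
             else character(0)
  strains <- c(founders, mosaics)

  ev_list <- list()
  for (f in seq_len(ap$n_founders)) {
    mu <- generate_random_mutations(ap$muts_per_founder, genome, mm)
    mu$lineage <- rep(founders[f], nrow(mu))
    ev_list[[length(ev_list) + 1L]] <- mu
  }
  founder_ev <- do.call(rbind, ev_list)
  L0 <- sort(unique(founder_ev$gpos))
  loci0 <- gpos_to_loci(L0, genome)
  base_calls <- matrix(0L, nrow = length(strains), ncol = length(L0),
                       dimnames = list(strains, NULL))
  for (f in seq_len(ap$n_founders)) {
    mine <- founder_ev$gpos[founder_ev$lineage == founders[f]]
    base_calls[f, match(mine, L0)] <- 1L
  }

  mosaic_info <- list()
  for (k in seq_len(ap$n_mosaics)) {
    par <- sample.int(ap$n_founders, 2)  # two distinct founders
    mei <- simulate_meiosis(base_calls[par[1], ], base_calls[par[2], ],
                            loci0, genome)
    base_calls[ap$n_founders + k, ] <- mei$calls
    mosaic_info[[mosaics[k]]] <- list(parents = founders[par],
                                      breakpoints = mei$breakpoints)
  }

  post_list <- list()
  for (s in seq_along(strains)) {
    carried <- L0[base_calls[s, ] == 1L]
    mu <- generate_random_mutations(ap$muts_per_strain_post, genome, mm,
                                    exclude = carried)
    mu$lineage <- rep(strains[s], nrow(mu))
    post_list[[s]] <- mu
  }
  post_ev <- do.call(rbind, post_list)

  all_gpos <- sort(unique(c(L0, post_ev$gpos)))
  calls <- matrix(0L, nrow = length(strains), ncol = length(all_gpos),
                  dimnames = list(strains, NULL))
  calls[, match(L0, all_gpos)] <- base_calls
  if (nrow(post_ev))
    calls[cbind(match(post_ev$lineage, strains),
                match(post_ev$gpos, all_gpos))] <- 1L

  founder_ev$phase <- rep("founder", nrow(founder_ev))
  post_ev$phase <- rep("post", nrow(post_ev))
  events <- rbind(founder_ev, post_ev)
  events <- events[order(events$gpos), , drop = FALSE]
  rownames(events) <- NULL
  first <- !duplicated(events$gpos)
  loci <- gpos_to_loci(all_gpos, genome)
  loci$ref <- events$ref[first][match(all_gpos, events$gpos[first])]
  loci$alt <- events$alt[first][match(all_gpos, events$gpos[first])]
  m <- genotype_matrix(calls, loci, strains)
  new_simulated_population(m, events, rep(FALSE, n_loci(m)), genome,
                           mosaics = mosaic_info, params = list(admixture = ap),
                           seed = seed)
}

#' Balancing-selection overlay parameters
#'
#' @param f_ancestral fraction (of the variants already present) of
#'   ancestrally balanced polymorphisms to add, in `[0, 1]`.
#' @param maf_balanced equilibrium minor-allele frequency of the
#'   balanced polymorphisms, in `(0, 0.5]`.
#' @return A `balancing_params` list.
#' @export
balancing_params <- function(f_ancestral = 0.1, maf_balanced = 0.5) {
  if (f_ancestral < 0 || f_ancestral > 1)
    stop("f_ancestral must be in [0, 1]")
  if (maf_balanced <= 0 || maf_balanced > 0.5)
    stop("maf_balanced must be in (0, 0.5]")
  structure(list(f_ancestral = f_ancestral, maf_balanced = maf_balanced),
            class = "balancing_params")
}

#' Overlay balanced ancestral polymorphisms on a simulated population
#'
#' Adds `round(f_ancestral * N_total)` new loci (N_total is the number
#' of variants already present) at fresh random positions.  At each
#' balanced locus every strain independently carries the alternate
#' allele with probability `maf_balanced`, reflecting the odds of
#' sampling either allele when sequencing a single colony from a
#' population in which the polymorphism is maintained.  Balanced loci
#' are flagged in the truth log and carry no origination event.
#'
#' @param pop a `simulated_population`.
#' @param bp a [balancing_params()].
#' @param genome a [genome_model()] (defaults to the population's).
#' @return The augmented `simulated_population`.
#' @export
overlay_balanced_polymorphisms <- function(pop, bp = balancing_params(),
                                           genome = pop$genome) {
  n_new <- round(bp$f_ancestral * n_loci(pop$matrix))
  if (n_new == 0) return(pop)
  S <- length(pop$matrix$strains)
  gpos <- draw_unique_gpos(n_new, genome, exclude = pop$locus_gpos)
  loci <- gpos_to_loci(gpos, genome)
  bases <- c("A", "C", "G", "T")
  loci$ref <- sample(bases, n_new, replace = TRUE)
  is_ts <- runif(n_new) < 0.75
  alt <- .transition_partner[loci$ref]
  tv_pick <- runif(n_new) < 0.5
  tv1 <- vapply(.transversion_partners[loci$ref], `[`, "", 1)
  tv2 <- vapply(.transversion_partners[loci$ref], `[`, "", 2)
  loci$alt <- ifelse(is_ts, alt, ifelse(tv_pick, tv1, tv2))
  new_calls <- matrix(rbinom(S * n_new, 1L, bp$maf_balanced), nrow = S)

  full_loci <- rbind(pop$matrix$loci[, c("chrom", "pos", "ref", "alt")],
                     loci[, c("chrom", "pos", "ref", "alt")])
  full_calls <- cbind(pop$matrix$calls, new_calls)
  balanced <- c(pop$balanced, rep(TRUE, n_new))
  ord <- order(full_loci$chrom, full_loci$pos)
  m <- genotype_matrix(full_calls[, ord, drop = FALSE],
                       full_loci[ord, , drop = FALSE], pop$matrix$strains)
  new_simulated_population(m, pop$events, balanced[ord], genome,
                           mosaics = pop$mosaics,
                           params = c(pop$params, list(balancing = bp)),
                           seed = pop$seed)
}

#' Place neutral variants on a tree
#'
#' Simulates neutrally evolving variation: each variant lands on a
#' branch with probability proportional to branch length and the
#' alternate allele is carried by exactly the leaves descending from
#' that branch (reversions neglected).  Every variant is a single
#' emergence by construction, so a scan of the resulting matrix
#' measures the false multiple-emergence rate of the inference.
#'
#' @param t a rooted or unrooted \pkg{ape} `phylo` with branch lengths.
#' @param n number of variants.
#' @param genome a [genome_model()] providing positions.
#' @param seed optional integer seed.
#' @return A `simulated_population` whose strains are the tree leaves.
#' @export
place_neutral_variants_on_tree <- function(t, n, genome = genome_model(),
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t$edge.length) || sum(t$edge.length) <= 0)
    stop("tree must have positive total branch length")
  ntip <- length(t$tip.label)
  nnode <- max(t$edge)
  # tips below each node
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  ord <- ape::reorder.phylo(t, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; kid <- ord$edge[k, 2]
    below[par, ] <- below[par, ] | below[kid, ]
  }
  eidx <- sample.int(nrow(t$edge), n, replace = TRUE, prob = t$edge.length)
  gpos <- draw_unique_gpos(n, genome)
  loci0 <- gpos_to_loci(gpos, genome)
  # keep variants, calls and the event log in the final locus order
  ord <- order(loci0$chrom, loci0$pos)
  gpos <- gpos[ord]
  eidx <- eidx[ord]
  loci <- loci0[ord, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  loci$ref <- sample(bases, n, replace = TRUE)
  loci$alt <- .transition_partner[loci$ref]
  calls <- matrix(0L, nrow = ntip, ncol = n,
                  dimnames = list(t$tip.label, NULL))
  for (e in unique(eidx))
    calls[below[t$edge[e, 2], ], which(eidx == e)] <- 1L
  m <- genotype_matrix(calls, loci, t$tip.label)
  events <- data.frame(chrom = loci$chrom, pos = loci$pos, gpos = gpos,
                       ref = loci$ref, alt = loci$alt, transition = TRUE,
                       lineage = paste0("edge", eidx), phase = "neutral",
                       stringsAsFactors = FALSE)
  new_simulated_population(m, events, rep(FALSE, n), genome,
                           params = list(tree = t), seed = seed)
}
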