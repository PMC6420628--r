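#' F6 cross simulation parameters
#'
#' Defaults emulate a large inbred haploid mapping panel: 1,125 progeny
#' genotyped at 12,054 segregating markers after six generations of
#' inbreeding, phenotyped in biological duplicate on robotically pinned
#' plates.
#'
#' @param n_progeny,n_markers,n_generations counts.
#' @param qtn data frame of planted causal variants with columns
#'   `marker` (index) and `effect` (in phenotype SD).
#' @param n_replicates replicate colonies per progeny.
#' @param noise_sd replicate noise SD (phenotype units).
#' @param plate_sd SD of the per-plate offset (0 = no plate effect).
#' @param plate_dims rows x columns of a plate.
#' @return A `cross_params` list.
#' @export
cross_params <- function(n_progeny = 1125, n_markers = 12054,
                         n_generations = 6,
                         qtn = data.frame(marker = integer(0),
                                          effect = numeric(0)),
                         n_replicates = 2, noise_sd = 1, plate_sd = 0,
                         plate_dims = c(16, 24)) {
  stopifnot(n_progeny >= 1, n_markers >= 1, n_generations >= 1,
            n_replicates >= 1, noise_sd >= 0, plate_sd >= 0)
  if (anyDuplicated(qtn$marker)) stop("planted markers must be distinct")
  if (any(qtn$marker < 1 | qtn$marker > n_markers))
    stop("planted markers must index existing markers")
  if (any(!is.finite(qtn$effect))) stop("effect sizes must be finite")
  structure(list(n_progeny = n_progeny, n_markers = n_markers,
                 n_generations = n_generations, qtn = qtn,
                 n_replicates = n_replicates, noise_sd = noise_sd,
                 plate_sd = plate_sd, plate_dims = plate_dims),
            class = "cross_params")
}

#' Simulate an inbred F6 cross with planted QTNs
#'
#' Two parental haplotypes (all-reference and all-alternate) are
#' crossed and inbred for `n_generations` rounds of sib-mating: each
#' generation two haploid recombinant products are produced by
#' [simulate_meiosis()] and mated, shrinking linkage blocks; after the
#' final round one haploid is retained per progeny.  Phenotypes are the
#' sum of planted marker effects plus a per-plate offset and replicate
#' noise; replicates share the progeny genotype.
#'
#' @param cp a [cross_params()].
#' @param genome a [genome_model()].
#' @param seed optional integer seed.
#' @return List with `genotypes` (a `genotype_matrix`, progeny as
#'   strains), `phenotypes` (one row per replicate colony: progeny,
#'   replicate, plate, row, col, size), and `truth` (the planted QTN
#'   table and parameters).
#' @export
simulate_f6_cross <- function(cp = cross_params(), genome = genome_model(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gpos <- sort(draw_unique_gpos(cp$n_markers, genome))
  loci <- gpos_to_loci(gpos, genome)
  loci$ref <- "A"
  loci$alt <- "G"
  geno <- matrix(0L, nrow = cp$n_progeny, ncol = cp$n_markers)
  zero <- rep(0L, cp$n_markers)
  one <- rep(1L, cp$n_markers)
  for (p in seq_len(cp$n_progeny)) {
    x <- zero; y <- one
    for (g in seq_len(cp$n_generations)) {
      nx <- simulate_meiosis(x, y, loci, genome)$calls
      ny <- simulate_meiosis(x, y, loci, genome)$calls
      x <- nx; y <- ny
    }
    geno[p, ] <- x
  }
  progeny <- sprintf("seg%04d", seq_len(cp$n_progeny))
  m <- genotype_matrix(geno, loci, progeny)
  # genotype_matrix sorts loci; map planted marker indices accordingly
  ord <- order(loci$chrom, loci$pos)
  marker_map <- match(seq_len(cp$n_markers), ord)

  genetic <- as.numeric(geno %*% replace(numeric(cp$n_markers),
                                         cp$qtn$marker, cp$qtn$effect))
  cap <- prod(cp$plate_dims)
  n_plates_per_rep <- ceiling(cp$n_progeny / cap)
  rows <- list()
  for (r in seq_len(cp$n_replicates)) {
    idx <- seq_len(cp$n_progeny) - 1L
    plate <- (r - 1L) * n_plates_per_rep + idx %/% cap + 1L
    slot <- idx %% cap
    rows[[r]] <- data.frame(progeny = progeny, replicate = r,
                            plate = plate,
                            row = slot %/% cp$plate_dims[2] + 1L,
                            col = slot %% cp$plate_dims[2] + 1L,
                            stringsAsFactors = FALSE)
  }
  pheno <- do.call(rbind, rows)
  plate_eff <- rnorm(max(pheno$plate), 0, cp$plate_sd)
  pheno$size <- genetic[match(pheno$progeny, progeny)] +
    plate_eff[pheno$plate] +
    rnorm(nrow(pheno), 0, cp$noise_sd)
  truth <- cp$qtn
  if (nrow(truth)) truth$sorted_index <- marker_map[truth$marker]
  list(genotypes = m, phenotypes = pheno,
       truth = list(qtn = truth, params = cp, seed = seed))
}
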