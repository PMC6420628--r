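# S288C reference karyotype (R64 assembly lengths, bp)
.yeast_chrom_lengths <- c(
  chrI = 230218L,   chrII = 813184L,   chrIII = 316620L,  chrIV = 1531933L,
  chrV = 576874L,   chrVI = 270161L,   chrVII = 1090940L, chrVIII = 562643L,
  chrIX = 439888L,  chrX = 745751L,    chrXI = 666816L,   chrXII = 1078177L,
  chrXIII = 924431L, chrXIV = 784333L, chrXV = 1091291L,  chrXVI = 948066L)

#' Genome model
#'
#' Chromosome names and lengths used to place simulated variants.  The
#' default is the 16-chromosome S. cerevisiae S288C karyotype (total
#' about 1.2e7 bp); `scale` shrinks every chromosome by a common factor
#' so that small, fast populations keep realistic proportions.  Base
#' composition is uniform.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in
#'   bp.
#' @param scale multiplicative factor applied to all lengths.
#' @return A `genome_model` list with `chrom`, `lengths`, `offsets`
#'   (cumulative start of each chromosome in the concatenated genome)
#'   and `size` (total bp).
#' @export
genome_model <- function(chrom_lengths = .yeast_chrom_lengths, scale = 1) {
  lengths <- pmax(1, round(as.numeric(chrom_lengths) * scale))
  if (sum(lengths) <= 0) stop("total genome length must be positive")
  structure(list(chrom = names(chrom_lengths),
                 lengths = lengths,
                 offsets = cumsum(c(0, lengths[-length(lengths)])),
                 size = sum(lengths)),
            class = "genome_model")
}

#' Point-mutation model
#'
#' @param tstv_ratio transition:transversion ratio kappa (> 0).
#' @param per_bp_rate mutation probability per bp per division.
#' @param effective_population effective population size N_e.
#' @return A `mutation_model` list.
#' @export
mutation_model <- function(tstv_ratio = 3, per_bp_rate = 5e-10,
                           effective_population = 1e6) {
  if (tstv_ratio <= 0) stop("tstv_ratio must be positive")
  if (per_bp_rate <= 0 || per_bp_rate >= 1)
    stop("per_bp_rate must be in (0, 1)")
  structure(list(tstv_ratio = tstv_ratio, per_bp_rate = per_bp_rate,
                 effective_population = effective_population),
            class = "mutation_model")
}

# concatenated-genome coordinate helpers
gpos_to_chrom_idx <- function(gpos, genome) {
  findInterval(gpos, genome$offsets + 1)
}

gpos_to_loci <- function(gpos, genome) {
  ci <- gpos_to_chrom_idx(gpos, genome)
  data.frame(chrom = genome$chrom[ci],
             pos = as.integer(gpos - genome$offsets[ci]),
             stringsAsFactors = FALSE)
}

loci_to_gpos <- function(chrom, pos, genome) {
  genome$offsets[match(chrom, genome$chrom)] + pos
}

# Uniform draws over the concatenated genome, unique and avoiding
# `exclude`; collisions are redrawn (so a site already mutated in the
# same isolate is never hit twice).
draw_unique_gpos <- function(n, genome, exclude = numeric(0)) {
  if (n > genome$size - length(exclude))
    stop("more mutations requested than available sites")
  out <- numeric(0)
  while (length(out) < n) {
    cand <- ceiling(runif(n - length(out)) * genome$size)
    cand <- unique(cand[!(cand %in% exclude) & !(cand %in% out)])
    out <- c(out, cand)
  }
  out
}
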