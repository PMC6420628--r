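#' Mutational exploration timescales
#'
#' Closed-form arithmetic linking population parameters to the time
#' needed for a population to explore every possible point mutation:
#' each genome experiences `mu * G` mutations per generation, the
#' population `mu * G * N_e`; every base pair is hit once per
#' `1 / (mu * N_e)` generations, and three times that accounts for the
#' three possible alternate bases at each site.
#'
#' @param N_e effective population size (default 1e6).
#' @param mu mutation rate per bp per division (default 5e-10).
#' @param G genome size in bp (default 1.2e7).
#' @return An `exploration_estimate` list: `muts_per_genome_per_gen`,
#'   `muts_per_population_per_gen`, `generations_per_bp_hit`,
#'   `generations_all_three_alts`.  A zero mutation rate or population
#'   size yields infinite waiting times rather than an overflow.
#' @export
exploration_timescales <- function(N_e = 1e6, mu = 5e-10, G = 1.2e7) {
  if (N_e < 0 || mu < 0 || G <= 0)
    stop("population size and rates must be non-negative, genome positive")
  per_bp <- if (mu > 0 && N_e > 0) 1 / (mu * N_e) else Inf
  structure(list(muts_per_genome_per_gen = mu * G,
                 muts_per_population_per_gen = mu * G * N_e,
                 generations_per_bp_hit = per_bp,
                 generations_all_three_alts = 3 * per_bp),
            class = "exploration_estimate")
}

#' @export
print.exploration_estimate <- function(x, ...) {
  cat(sprintf("mutations per genome per generation:      %.3g\n",
              x$muts_per_genome_per_gen))
  cat(sprintf("mutations population-wide per generation: %.3g\n",
              x$muts_per_population_per_gen))
  cat(sprintf("generations until a given bp is hit:      %.3g\n",
              x$generations_per_bp_hit))
  cat(sprintf("generations to explore all three alts:    %.3g\n",
              x$generations_all_three_alts))
  invisible(x)
}
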