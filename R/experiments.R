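#' Run a packaged simulation experiment end to end
#'
#' Orchestrates the simulators, scan, and tests into the named study
#' designs.  Every experiment is deterministic given `seed`; the
#' returned bundle embeds the configuration that produced it.
#'
#' Available experiments:
#' \describe{
#'   \item{`admixture_validation`}{replicate admixed populations;
#'     paired true vs inferred homoplasy table.}
#'   \item{`neutral_vs_observed`}{an admixed population's observed scan
#'     counts against the neutral expectation on its own whole-genome
#'     NJ tree.}
#'   \item{`balancing_sweep`}{inferred multiple emergence over a grid
#'     of `f_ancestral` and `maf_balanced`.}
#'   \item{`niche_enrichment`}{same-niche sharing fraction of a
#'     labelled panel against 50 neutral placements.}
#'   \item{`directional_test`}{coherence-versus-distance test on a
#'     mapped (simulated) QTL architecture.}
#'   \item{`mapping_demo`}{simulate an F6 cross with planted QTNs, map
#'     by forward selection, fine-map, and estimate FDR.}
#' }
#'
#' @param name experiment name, see Details.
#' @param seed integer seed; all randomness flows from it.
#' @param scale genome/population scale factor in (0, 1]: 1 is the
#'   full study design; smaller values shrink the genome and all
#'   mutation counts proportionally for quick runs.
#' @param n_reps replicate count override (defaults per experiment).
#' @param w a [window_spec()].
#' @param ... experiment-specific overrides (`f_grid`, `maf_grid` for
#'   the balancing sweep; `cross` a [cross_params()] for the mapping
#'   demo).
#' @return A list with `config` and experiment-specific tables.
#' @export
run_experiment <- function(name = c("admixture_validation",
                                    "neutral_vs_observed",
                                    "balancing_sweep",
                                    "niche_enrichment",
                                    "directional_test",
                                    "mapping_demo"),
                           seed = 1, scale = 1, n_reps = NULL,
                           w = window_spec(), ...) {
  name <- match.arg(name)
  set.seed(seed)
  dots <- list(...)
  genome <- genome_model(scale = scale)
  ap <- admixture_params(
    muts_per_founder = round(30000 * scale),
    muts_per_strain_post = round(10000 * scale))
  config <- list(name = name, seed = seed, scale = scale,
                 window = w$width, n_reps = n_reps, extra = dots)

  if (name == "admixture_validation") {
    reps <- if (is.null(n_reps)) 25 else n_reps
    tab <- do.call(rbind, lapply(seq_len(reps), function(r) {
      pop <- build_admixed_population(ap, genome)
      cmp <- compare_true_vs_inferred(pop, w)
      data.frame(rep = r, true_multiple = cmp$true_multiple,
                 inferred_multiple = cmp$inferred_multiple)
    }))
    return(list(config = config, table = tab,
                mean_true = mean(tab$true_multiple),
                mean_inferred = mean(tab$inferred_multiple)))
  }

  if (name == "neutral_vs_observed") {
    reps <- if (is.null(n_reps)) 10 else n_reps
    pop <- build_admixed_population(ap, genome)
    obs <- genome_scan(pop$matrix, w)
    tree <- neighbor_joining(snp_distance_matrix(pop$matrix))
    neu <- neutral_expectation(tree, n_loci(pop$matrix), reps, w, genome)
    return(list(config = config,
                observed = data.frame(n_shared = obs$n_shared,
                                      n_multiple = obs$n_multiple),
                neutral = neu))
  }

  if (name == "balancing_sweep") {
    reps <- if (is.null(n_reps)) 5 else n_reps
    f_grid <- if (is.null(dots$f_grid)) c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1)
              else dots$f_grid
    maf_grid <- if (is.null(dots$maf_grid)) 2^(-5:-1) else dots$maf_grid
    rows <- list()
    for (f in f_grid) for (maf in maf_grid) {
      vals <- vapply(seq_len(reps), function(r) {
        pop <- build_admixed_population(ap, genome)
        pop <- overlay_balanced_polymorphisms(
          pop, balancing_params(f, maf), genome)
        cmp <- compare_true_vs_inferred(pop, w)
        c(cmp$true_multiple, cmp$inferred_multiple)
      }, numeric(2))
      rows[[length(rows) + 1L]] <- data.frame(
        f_ancestral = f, maf_balanced = maf, n_reps = reps,
        true_mean = mean(vals[1, ]), true_sd = sd(vals[1, ]),
        inferred_mean = mean(vals[2, ]), inferred_sd = sd(vals[2, ]))
    }
    return(list(config = config, table = do.call(rbind, rows)))
  }

  if (name == "niche_enrichment") {
    reps <- if (is.null(n_reps)) 50 else n_reps
    pop <- build_admixed_population(ap, genome)
    strains <- pop$matrix$strains
    niches <- setNames(sample(c("vineyard", "oak", "clinical", "sake",
                                "soil"), length(strains), replace = TRUE),
                       strains)
    tree <- neighbor_joining(snp_distance_matrix(pop$matrix))
    out <- lapply(c(2, 3), function(k) {
      obs <- niche_sharing_fraction(pop$matrix, niches, k)
      nul <- niche_null_distribution(tree, niches,
                                     n_variants = n_loci(pop$matrix),
                                     k = k, n_reps = reps,
                                     observed = obs$fraction,
                                     genome = genome)
      data.frame(k = k, observed = obs$fraction, null_mean = nul$mean,
                 null_sd = nul$sd, p_value = nul$p_value)
    })
    return(list(config = config, table = do.call(rbind, out),
                niches = niches))
  }

  if (name == "directional_test") {
    cp <- if (is.null(dots$cross)) cross_params(
      n_progeny = round(1125 * max(scale, 0.2)),
      n_markers = round(12054 * max(scale, 0.2))) else dots$cross
    # a single-chromosome genome so QTL pair distances are defined
    g1 <- genome_model(c(chrI = round(1.2e7 * scale)))
    sim <- simulate_f6_cross(cp, g1)
    y <- normalize_phenotypes(sim$phenotypes)
    design <- append_pseudo_genotypes(sim$genotypes, sim$phenotypes)
    model <- forward_select(design, y)
    q <- model$qtls
    if (nrow(q) < 2) return(list(config = config, table = NULL,
                                 model = model))
    qtab <- data.frame(trait = "trait1", marker = q$marker,
                       chrom = q$chrom,
                       high_parent = ifelse(q$effect > 0, "alt_parent",
                                            "ref_parent"))
    tab <- coherence_vs_distance(qtab,
                                 max_distance = min(500, cp$n_markers))
    return(list(config = config, table = tab, model = model))
  }

  # mapping_demo
  cp <- if (is.null(dots$cross)) {
    nm <- round(12054 * max(scale, 0.1))
    cross_params(n_progeny = round(1125 * max(scale, 0.2)),
                 n_markers = nm,
                 qtn = data.frame(marker = round(nm * c(0.2, 0.5, 0.8)),
                                  effect = c(0.4, 0.3, 0.2)))
  } else dots$cross
  sim <- simulate_f6_cross(cp, genome)
  y <- normalize_phenotypes(sim$phenotypes)
  design <- append_pseudo_genotypes(sim$genotypes, sim$phenotypes)
  model <- forward_select(design, y)
  fdr <- permutation_fdr(design, y, n_perms = 10)
  fm <- lapply(model$qtls$marker, function(mk)
    fine_map_qtn(model, mk, sim$genotypes, y))
  list(config = config, model = model, fdr = fdr, fine_maps = fm,
       truth = sim$truth)
}
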