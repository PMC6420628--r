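# Small builders shared across test files.  Everything is generated in
# code; no stored fixtures.

toy_matrix <- function() {
  calls <- rbind(S1 = c(0L, 1L, 0L, 1L),
                 S2 = c(1L, 1L, NA, 0L),
                 S3 = c(0L, 0L, 1L, 1L))
  loci <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                     pos = c(100L, 250L, 40L, 90L),
                     ref = c("A", "C", "G", "T"),
                     alt = c("G", "T", "A", "C"))
  genotype_matrix(calls, loci, rownames(calls))
}

random_matrix <- function(n_strains, n_loci, miss = 0.05) {
  calls <- matrix(rbinom(n_strains * n_loci, 1L, 0.4), n_strains)
  calls[runif(length(calls)) < miss] <- NA
  loci <- data.frame(chrom = "chr1",
                     pos = sort(sample.int(10 * n_loci, n_loci)),
                     ref = "A", alt = "G")
  genotype_matrix(calls, loci, paste0("S", seq_len(n_strains)))
}

# a small, fast admixed population at reduced genome scale with the
# window width scaled to keep the window-to-chromosome geometry of the
# full design
small_admixed <- function(seed, scale = 0.05, post = NULL) {
  g <- genome_model(scale = scale)
  ap <- admixture_params(
    muts_per_founder = round(30000 * scale),
    muts_per_strain_post = if (is.null(post)) round(10000 * scale) else post)
  build_admixed_population(ap, g, seed = seed)
}

# all-ones effect coding helper for emergence tests
leaf_calls <- function(t, alt_tips) {
  setNames(as.integer(t$tip.label %in% alt_tips), t$tip.label)
}
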