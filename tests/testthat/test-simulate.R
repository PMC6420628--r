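test_that("random mutations honour the Ts/Tv ratio and uniform placement", {
  expect_equal(nrow(generate_random_mutations(0)), 0L)
  set.seed(101)
  g <- genome_model()
  mu <- generate_random_mutations(1e5, g)
  # transition fraction: kappa/(kappa+1) = 0.75, binomial 3 SE ~ 0.004
  expect_lt(abs(mean(mu$transition) - 0.75), 0.005)
  ts_ok <- c(A = "G", G = "A", C = "T", T = "C")
  expect_true(all(mu$alt[mu$transition] == ts_ok[mu$ref[mu$transition]]))
  expect_true(all(mu$alt[!mu$transition] != ts_ok[mu$ref[!mu$transition]]))
  expect_true(all(mu$ref != mu$alt))
  # chromosome occupancy proportional to lengths
  counts <- table(factor(mu$chrom, levels = g$chrom))
  p <- chisq.test(as.numeric(counts), p = g$lengths / g$size)$p.value
  expect_gt(p, 0.01)
  # excluded sites are never hit; positions unique within a call
  small <- genome_model(scale = 1e-4)  # ~1200 bp genome
  ex <- 1:500
  mu2 <- generate_random_mutations(300, small, exclude = ex)
  expect_false(any(mu2$gpos %in% ex))
  expect_false(anyDuplicated(mu2$gpos) > 0)
  expect_error(generate_random_mutations(5000, small), "available sites")
})

test_that("meiosis produces two-segment mosaics with one breakpoint per chromosome", {
  g <- genome_model()
  loci <- data.frame(chrom = rep(g$chrom, each = 2),
                     pos = rep(c(1000L, 200000L), 16))
  a <- rep(0L, nrow(loci)); b <- rep(1L, nrow(loci))
  set.seed(5)
  same <- simulate_meiosis(a, a, loci, g)
  expect_identical(same$calls, a)
  mei <- simulate_meiosis(a, b, loci, g)
  expect_equal(nrow(mei$breakpoints), 16L)
  expect_true(all(mei$calls %in% c(a, b)))
  # single chromosome, 4 markers: child is a two-segment mosaic and all
  # 5 breakpoint intervals are reachable over seeds
  g1 <- genome_model(c(chrA = 1000L))
  l1 <- data.frame(chrom = "chrA", pos = c(100L, 300L, 600L, 900L))
  pa <- c(0L, 0L, 0L, 0L); pb <- c(1L, 1L, 1L, 1L)
  pats <- replicate(300, {
    ch <- simulate_meiosis(pa, pb, l1, g1)$calls
    paste(ch, collapse = "")
  })
  two_seg <- function(x) {
    v <- as.integer(strsplit(x, "")[[1]])
    sum(diff(v) != 0) <= 1
  }
  expect_true(all(vapply(unique(pats), two_seg, logical(1))))
  expect_gte(length(unique(pats)), 6)  # 0001..0111, 1110..1000, 0000, 1111
})

test_that("admixed populations keep exact mutation bookkeeping and truth homoplasy", {
  g <- genome_model(scale = 0.008)   # ~1e5 bp genome for dense collisions
  ap <- admixture_params(muts_per_founder = 300, muts_per_strain_post = 100)
  pop <- build_admixed_population(ap, g, seed = 31)
  expect_equal(nrow(pop$events), 5 * 300 + 15 * 100)
  expect_equal(length(pop$matrix$strains), 15L)
  # truth log recount: homoplasy = sites with >= 2 origination events
  brute <- sum(table(pop$events$gpos) >= 2)
  expect_equal(true_homoplasy_count(pop), brute)
  expect_gt(brute, 0)  # dense genome: collisions essentially certain
  # every locus corresponds to >= 1 recorded event
  expect_true(all(pop$locus_gpos %in% pop$events$gpos))
  # founders-only, sparse genome: no homoplasy when all sites distinct
  ap0 <- admixture_params(n_mosaics = 0, muts_per_founder = 50,
                          muts_per_strain_post = 0)
  pop0 <- build_admixed_population(ap0, genome_model(), seed = 32)
  expect_equal(true_homoplasy_count(pop0), 0L)
  expect_equal(sum(pop0$matrix$calls), 5 * 50)
})

test_that("identical seeds reproduce identical populations bit for bit", {
  a <- small_admixed(77, scale = 0.01)
  b <- small_admixed(77, scale = 0.01)
  expect_identical(a$matrix$calls, b$matrix$calls)
  expect_identical(a$events, b$events)
  c <- small_admixed(78, scale = 0.01)
  expect_false(identical(a$matrix$calls, c$matrix$calls))
})

test_that("balancing overlay adds the requested loci at the requested frequency", {
  pop <- small_admixed(55, scale = 0.01)
  n0 <- n_loci(pop$matrix)
  expect_identical(
    overlay_balanced_polymorphisms(pop, balancing_params(0, 0.5)), pop)
  set.seed(56)
  bal <- overlay_balanced_polymorphisms(pop, balancing_params(0.5, 2^-5))
  expect_equal(n_loci(bal$matrix), n0 + round(0.5 * n0))
  expect_equal(sum(bal$balanced), round(0.5 * n0))
  # mean alt carriers per balanced locus ~ 15/32, binomial 3 SE
  nb <- sum(bal$balanced)
  carriers <- colSums(bal$matrix$calls[, bal$balanced] == 1L)
  se <- sqrt(15 * 2^-5 * (1 - 2^-5) / nb)
  expect_lt(abs(mean(carriers) - 15 / 32), 3 * se)
  # truth: balanced loci carry no origination events
  expect_false(any(bal$locus_gpos[bal$balanced] %in% bal$events$gpos))
  expect_error(balancing_params(1.2, 0.5), "f_ancestral")
  expect_error(balancing_params(0.1, 0.6), "maf")
})

test_that("neutral placement follows branch lengths and propagates to descendants", {
  t <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
  g <- genome_model()
  set.seed(61)
  pop <- place_neutral_variants_on_tree(t, 1e4, g)
  # per-branch counts proportional to lengths
  eidx <- as.integer(sub("edge", "", pop$events$lineage))
  counts <- tabulate(eidx, nbins = nrow(t$edge))
  p <- chisq.test(counts, p = t$edge.length / sum(t$edge.length))$p.value
  expect_gt(p, 0.01)
  # terminal-branch variants sit in exactly that leaf; internal-branch
  # variants in exactly that clade
  tipA <- which(t$edge[, 2] == which(t$tip.label == "A"))
  onA <- which(eidx == tipA)
  expect_true(all(pop$matrix$calls["A", onA] == 1L))
  expect_true(all(colSums(pop$matrix$calls[, onA, drop = FALSE]) == 1))
  intCD <- which(t$edge[, 2] == ape::getMRCA(t, c("C", "D")))
  onCD <- which(eidx == intCD)
  expect_true(all(colSums(pop$matrix$calls[c("C", "D"), onCD]) == 2))
  expect_true(all(pop$matrix$calls[c("A", "B"), onCD] == 0L))
  # all variants are single emergences in the truth log
  expect_equal(max(table(pop$events$gpos)), 1)
  t0 <- t; t0$edge.length[] <- 0
  expect_error(place_neutral_variants_on_tree(t0, 10, g), "positive")
})

test_that("F6 cross phenotypes reflect planted effects and linkage decays", {
  g <- genome_model(scale = 0.2)
  cp0 <- cross_params(n_progeny = 40, n_markers = 50, noise_sd = 0)
  set.seed(71)
  sim0 <- simulate_f6_cross(cp0, g)
  expect_true(all(sim0$phenotypes$size == sim0$phenotypes$size[1]))
  cp1 <- cross_params(n_progeny = 60, n_markers = 50, noise_sd = 0,
                      qtn = data.frame(marker = 25L, effect = 1))
  sim1 <- simulate_f6_cross(cp1, g, seed = 72)
  vals <- sort(unique(round(sim1$phenotypes$size, 10)))
  expect_equal(length(vals), 2L)
  expect_equal(diff(vals), 1)
  # replicates share genotype-driven phenotype
  expect_equal(nrow(sim1$phenotypes), 2 * 60)
  # linkage decay: adjacent-marker r^2 falls with inter-marker distance
  cp2 <- cross_params(n_progeny = 1000, n_markers = 120)
  sim2 <- simulate_f6_cross(cp2, genome_model(c(chrA = 1e6L)), seed = 73)
  G <- sim2$genotypes$calls
  pos <- sim2$genotypes$loci$pos
  pairs <- t(utils::combn(ncol(G), 2))
  keep <- sample(nrow(pairs), 2000)
  d <- abs(pos[pairs[keep, 1]] - pos[pairs[keep, 2]])
  r2 <- vapply(keep, function(k)
    suppressWarnings(cor(G[, pairs[k, 1]], G[, pairs[k, 2]]))^2,
    numeric(1))
  near <- mean(r2[d < 1e5], na.rm = TRUE)
  far <- mean(r2[d > 5e5], na.rm = TRUE)
  expect_gt(near, far)
})
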