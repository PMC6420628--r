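test_that("emergence rules reproduce hand-traced counts", {
  t4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(as.integer(infer_emergence_events(t4, leaf_calls(t4, c()))), 0L)
  expect_equal(as.integer(infer_emergence_events(t4, leaf_calls(t4, "A"))), 1L)
  # monophyletic alt pair: one emergence on the internal branch
  expect_equal(as.integer(infer_emergence_events(t4,
                                                 leaf_calls(t4, c("A", "B")))), 1L)
  # alt split across the root: two independent emergences
  expect_equal(as.integer(infer_emergence_events(t4,
                                                 leaf_calls(t4, c("A", "C")))), 2L)
  # missing leaves are pruned, not imputed
  calls <- c(A = 1L, B = NA_integer_, C = 0L, D = 0L)
  expect_equal(as.integer(infer_emergence_events(t4, calls)), 1L)
  # non-binary trees are rejected
  t3 <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(infer_emergence_events(t3, leaf_calls(t3, "A")), "binary")
})

test_that("event counts equal the Fitch parsimony score absent EVENT-EVENT merges", {
  # exhaustive: all rooted binary topologies on 5 and 6 leaves x all
  # binary labelings; where a merge occurs the count may only undershoot
  for (n in c(5, 6)) {
    labelings <- as.matrix(expand.grid(rep(list(0:1), n)))
    trees <- phangorn::allTrees(n, rooted = TRUE)
    states <- t(labelings)
    rownames(states) <- trees[[1]]$tip.label
    dat <- phangorn::phyDat(states, type = "USER", levels = c(0, 1))
    for (ti in seq_along(trees)) {
      tr <- trees[[ti]]   # [[ restores tip labels on a compressed multiPhylo
      fitch <- phangorn::parsimony(tr, dat, site = "site")
      for (s in seq_len(nrow(labelings))) {
        lc <- setNames(labelings[s, ], tr$tip.label)
        ev <- infer_emergence_events(tr, lc)
        if (attr(ev, "event_merge")) {
          expect_lte(as.integer(ev), fitch[s])
        } else {
          expect_equal(as.integer(ev), unname(fitch[s]))
        }
      }
    }
  }
})

test_that("event counts match Fitch on random larger trees", {
  set.seed(301)
  for (rep in 1:60) {
    n <- sample(7:10, 1)
    tr <- ape::rtree(n)
    lab <- rbinom(n, 1, 0.5)
    states <- matrix(lab, ncol = 1, dimnames = list(tr$tip.label, NULL))
    dat <- phangorn::phyDat(states, type = "USER", levels = c(0, 1))
    fitch <- phangorn::parsimony(tr, dat, site = "site")[1]
    ev <- infer_emergence_events(tr, setNames(lab, tr$tip.label))
    if (attr(ev, "event_merge")) expect_lte(as.integer(ev), unname(fitch))
    else expect_equal(as.integer(ev), unname(fitch))
    # events are zero iff no leaf carries alt (segregating or absent alt)
    if (sum(lab) == 0) expect_equal(as.integer(ev), 0L)
    if (sum(lab) %in% seq_len(n - 1)) expect_gte(as.integer(ev), 1L)
  }
})

test_that("monophyletic alt clades always yield exactly one event", {
  set.seed(311)
  for (rep in 1:40) {
    tr <- ape::rtree(sample(5:12, 1))
    internal <- setdiff(unique(tr$edge[, 1]), length(tr$tip.label) + 1)
    node <- sample(internal, 1)
    tips <- ape::extract.clade(tr, node)$tip.label
    if (length(tips) == length(tr$tip.label)) next
    ev <- infer_emergence_events(tr, leaf_calls(tr, tips))
    expect_equal(as.integer(ev), 1L)
  }
})

test_that("variant classification handles singletons, sisters, and collapsed clades", {
  set.seed(321)
  src <- ape::rtree(8)
  src$edge.length <- src$edge.length + 0.3
  pop <- place_neutral_variants_on_tree(src, 800, genome_model())
  m <- pop$matrix
  carriers <- colSums(m$calls)
  # a singleton
  i1 <- which(carriers == 1)[1]
  c1 <- classify_variant(m, i1, window_spec(500))
  expect_equal(c1$sharing, "singleton")
  expect_equal(c1$n_events, 1L)
  # a clean clade variant: shared, single emergence
  i2 <- which(carriers >= 2 & carriers < 8)[5]
  c2 <- classify_variant(m, i2, window_spec(500))
  expect_equal(c2$sharing, "shared")
  expect_equal(c2$n_events, 1L)
  expect_false(c2$multiple)
  # collapse: alt confined to collapsed members yields no event within
  sisters <- ape::extract.clade(src, ape::getMRCA(src, src$tip.label[1:2]))$tip.label
  clade <- if (length(sisters) >= 2) sisters[1:2] else src$tip.label[1:2]
  i3 <- which(colSums(m$calls[clade, , drop = FALSE]) == carriers &
                carriers == 2)[1]
  if (!is.na(i3)) {
    c3 <- classify_variant(m, i3, window_spec(500), clade_collapse = clade)
    expect_equal(c3$sharing, "shared")    # counted pre-collapse
    # both carriers collapse into the modal pseudo-strain: one emergence
    # on the clade stem, never two within the clade
    expect_equal(c3$n_events, 1L)
  }
})

test_that("the compiled scan equals locus-by-locus classification", {
  set.seed(331)
  for (rep in 1:3) {
    m <- random_matrix(6, 40, miss = if (rep == 3) 0.1 else 0)
    sc <- genome_scan(m, window_spec(12))
    byhand <- vapply(seq_len(n_loci(m)), function(i)
      classify_variant(m, i, window_spec(12))$n_events, integer(1))
    expect_identical(sc$calls$n_events, byhand)
  }
})

test_that("scan summaries respect count nesting and strain-order invariance", {
  set.seed(341)
  m <- random_matrix(6, 60, miss = 0.05)
  sc <- genome_scan(m, window_spec(20))
  expect_lte(sc$n_multiple, sc$n_shared)
  expect_lte(sc$n_shared, sc$n_total)
  perm <- sample(length(m$strains))
  m2 <- genotype_matrix(m$calls[perm, ], m$loci, m$strains[perm])
  sc2 <- genome_scan(m2, window_spec(20))
  expect_identical(sc$calls$n_events, sc2$calls$n_events)
})

test_that("neutral populations show near-zero multiple emergence; admixture a mild underestimate", {
  set.seed(351)
  src <- ape::rtree(15)
  src$edge.length <- src$edge.length + 0.2
  pop <- place_neutral_variants_on_tree(src, 3000, genome_model())
  sc <- genome_scan(pop$matrix, window_spec(500))
  expect_lt(sc$n_multiple / max(sc$n_shared, 1), 0.02)
  # admixed populations: inferred at most the truth on average, both
  # positive and positively rank-correlated across seeds
  res <- t(vapply(1:5, function(s) {
    p <- small_admixed(400 + s, scale = 0.2)
    cmp <- compare_true_vs_inferred(p, window_spec(100))
    c(true = cmp$true_multiple, inf = cmp$inferred_multiple)
  }, numeric(2)))
  expect_gt(mean(res[, "true"]), 0)
  expect_gt(mean(res[, "inf"]), 0)
  expect_lte(mean(res[, "inf"]), mean(res[, "true"]))
  expect_gt(cor(res[, "true"], res[, "inf"], method = "spearman"), 0)
})

test_that("balancing overlay inflates inferred multiple emergence far above baseline", {
  pop <- small_admixed(371, scale = 0.1)
  base <- genome_scan(pop$matrix, window_spec(50))$n_multiple
  set.seed(372)
  bal <- overlay_balanced_polymorphisms(pop, balancing_params(0.1, 0.5))
  with_bal <- genome_scan(bal$matrix, window_spec(50))$n_multiple
  expect_gt(with_bal, 3 * max(base, 1))
})

test_that("neutral expectations follow the internal-branch-length ratio", {
  expect_equal(unname(attr(neutral_expectation(ape::rtree(5), 0, 3),
                           "mean")), c(0, 0))
  # star tree: every variant lands on a terminal branch -> no sharing
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  ne <- neutral_expectation(star, 200, 3, window_spec(100))
  expect_true(all(ne$n_shared == 0))
  # shared fraction matches the internal / total branch-length ratio
  set.seed(381)
  src <- ape::rtree(15)
  src$edge.length <- src$edge.length + 0.2
  internal <- src$edge[, 2] > length(src$tip.label)
  expected <- sum(src$edge.length[internal]) / sum(src$edge.length)
  nv <- 2000
  ne2 <- neutral_expectation(src, nv, 5, window_spec(500))
  se <- sqrt(expected * (1 - expected) / nv)
  expect_lt(abs(mean(ne2$n_shared) / nv - expected), 3 * se + 3 * sd(ne2$n_shared / nv))
})
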