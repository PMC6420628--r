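#' Count independent emergence events on a rooted tree
#'
#' Walks the tree in postorder, assigning each internal node a state in
#' `{0, 1, EVENT}` from its two children: equal genotypes give that
#' genotype; opposing genotypes create an independent emergence EVENT
#' at that node; an EVENT child paired with a genotype child resolves
#' to the genotype; two EVENT children merge into a single EVENT
#' without counting a new one (a conservative choice that never
#' inflates the event count).  Leaves with missing calls are pruned
#' before the walk.  A root left in the EVENT state contributes only
#' its already-counted events.
#'
#' @param t a rooted \pkg{ape} `phylo`, binary below the root.
#' @param leaf_calls named vector (by tip label) over `{0, 1, NA}`.
#' @return Integer event count, with attributes `states` (the per-node
#'   state annotation, `-1` = EVENT, `NA` = pruned) and
#'   `event_merge` (`TRUE` when an (EVENT, EVENT) merge occurred, in
#'   which case the count may undershoot the parsimony change count).
#' @export
infer_emergence_events <- function(t, leaf_calls) {
  ntip <- length(t$tip.label)
  tab <- tabulate(t$edge[, 1], nbins = max(t$edge))
  if (any(tab[-(ntip + 1)] > 2) || tab[ntip + 1] > 2)
    stop("tree must be binary (resolve multifurcations first)")
  st <- rep(NA_integer_, max(t$edge))
  st[seq_len(ntip)] <- as.integer(leaf_calls[t$tip.label])
  events <- 0L
  merged <- FALSE
  EV <- -1L
  ord <- ape::reorder.phylo(t, "postorder")
  kids <- split(ord$edge[, 2], ord$edge[, 1])
  for (node in unique(ord$edge[, 1])) {
    ch <- st[kids[[as.character(node)]]]
    ch <- ch[!is.na(ch)]
    if (length(ch) == 0) next              # all leaves below pruned
    if (length(ch) == 1) { st[node] <- ch; next }
    a <- ch[1]; b <- ch[2]
    if (a == EV && b == EV) { st[node] <- EV; merged <- TRUE }
    else if (a == EV) st[node] <- b
    else if (b == EV) st[node] <- a
    else if (a == b) st[node] <- a
    else { st[node] <- EV; events <- events + 1L }
  }
  structure(events, states = st, event_merge = merged)
}

#' Classify one variant's sharing and emergence count
#'
#' Optionally collapses a configured clade to its modal pseudo-strain
#' (sharing is still counted on the pre-collapse panel), builds the
#' local midpoint-rooted window tree, and applies the emergence rules
#' to the focal variant.
#'
#' @param m a `genotype_matrix`.
#' @param idx focal variant index.
#' @param w a [window_spec()].
#' @param clade_collapse optional character vector of strain names to
#'   collapse (e.g. the wine/European clade).
#' @param include_focal passed to [local_tree_for_variant()].
#' @return One-row data frame: `chrom`, `pos`, `n_carriers`, `sharing`
#'   (`"singleton"`/`"shared"`/`"absent"`), `n_events`, `multiple`,
#'   `low_confidence`.
#' @export
classify_variant <- function(m, idx, w = window_spec(),
                             clade_collapse = NULL, include_focal = TRUE) {
  n_carriers <- sum(m$calls[, idx] == 1L, na.rm = TRUE)
  mm <- m
  if (!is.null(clade_collapse))
    mm <- collapse_clade_to_modal(m, clade_collapse)
  tr <- local_tree_for_variant(mm, idx, w, include_focal)
  calls <- setNames(mm$calls[, idx], mm$strains)
  ev <- infer_emergence_events(tr, calls)
  data.frame(chrom = m$loci$chrom[idx], pos = m$loci$pos[idx],
             n_carriers = n_carriers,
             sharing = if (n_carriers == 0) "absent"
                       else if (n_carriers == 1) "singleton" else "shared",
             n_events = as.integer(ev),
             multiple = as.integer(ev) >= 2L,
             low_confidence = isTRUE(attr(tr, "low_confidence")),
             stringsAsFactors = FALSE)
}

#' Genome-wide sliding-window emergence scan
#'
#' Applies the emergence inference to every variant: for each locus the
#' window distance matrix is updated incrementally, a neighbor-joining
#' tree is rebuilt, midpoint-rooted, and the ancestral-genotype rules
#' are applied to the focal calls (compiled hot path; identical in
#' result to calling [classify_variant()] locus by locus).
#'
#' @param m a `genotype_matrix`.
#' @param w a [window_spec()].
#' @param clade_collapse optional strain names to collapse to a modal
#'   pseudo-strain before tree building; sharing is counted on the
#'   uncollapsed panel.
#' @return List of class `scan_summary`: `calls` (per-variant table as
#'   in [classify_variant()]), and counts `n_total`, `n_shared`,
#'   `n_multiple` plus a per-chromosome breakdown.
#' @export
genome_scan <- function(m, w = window_spec(), clade_collapse = NULL) {
  n_carriers <- colSums(m$calls == 1L, na.rm = TRUE)
  mm <- m
  if (!is.null(clade_collapse))
    mm <- collapse_clade_to_modal(m, clade_collapse)
  chrom_id <- as.integer(factor(mm$loci$chrom, levels = unique(mm$loci$chrom)))
  prio <- as.integer(rank(mm$strains, ties.method = "first")) - 1L
  res <- emergence_scan_cpp(mm$calls, chrom_id, w$width, prio)
  calls <- data.frame(chrom = m$loci$chrom, pos = m$loci$pos,
                      n_carriers = n_carriers,
                      sharing = ifelse(n_carriers == 0, "absent",
                                ifelse(n_carriers == 1, "singleton",
                                       "shared")),
                      n_events = res$n_events,
                      multiple = res$n_events >= 2L,
                      low_confidence = res$low_confidence,
                      stringsAsFactors = FALSE)
  per_chrom <- aggregate(cbind(n_total = n_events >= 0,
                               n_shared = n_carriers >= 2,
                               n_multiple = n_events >= 2 & n_carriers >= 2) ~
                           chrom, data = calls, FUN = sum)
  structure(list(calls = calls,
                 n_total = nrow(calls),
                 n_shared = sum(calls$sharing == "shared"),
                 n_multiple = sum(calls$multiple & calls$sharing == "shared"),
                 total_events_beyond_first =
                   sum(pmax(calls$n_events - 1L, 0L)[calls$sharing == "shared"]),
                 per_chrom = per_chrom),
            class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf(paste0("emergence scan: %d variants; %d shared (%.1f%%); ",
                     "%d inferred multiple (%.1f%% of shared)\n"),
              x$n_total, x$n_shared, 100 * x$n_shared / max(x$n_total, 1),
              x$n_multiple, 100 * x$n_multiple / max(x$n_shared, 1)))
  invisible(x)
}

#' Neutral expectation of sharing and multiple emergence
#'
#' Places `n_variants` neutrally on the tree (branch choice
#' proportional to branch length, alt propagated to all descendant
#' leaves), scans the resulting matrix, and repeats; the spread across
#' replicates quantifies the neutral expectation in the absence of
#' selection.
#'
#' @param t an \pkg{ape} `phylo` with branch lengths.
#' @param n_variants variants per replicate.
#' @param n_reps number of replicate simulations.
#' @param w a [window_spec()].
#' @param genome a [genome_model()].
#' @return Data frame with one row per replicate (`n_shared`,
#'   `n_multiple`) and attributes `mean` and `sd`.
#' @export
neutral_expectation <- function(t, n_variants, n_reps = 10,
                                w = window_spec(),
                                genome = genome_model()) {
  reps <- lapply(seq_len(n_reps), function(r) {
    if (n_variants == 0)
      return(data.frame(n_shared = 0L, n_multiple = 0L))
    pop <- place_neutral_variants_on_tree(t, n_variants, genome)
    sc <- genome_scan(pop$matrix, w)
    data.frame(n_shared = sc$n_shared, n_multiple = sc$n_multiple)
  })
  out <- do.call(rbind, reps)
  attr(out, "mean") <- colMeans(out)
  attr(out, "sd") <- apply(out, 2, sd)
  out
}

#' Compare true and inferred homoplasy on a simulated population
#'
#' Truth comes from the recorded mutation log; inference runs on the
#' blinded genotype matrix alone.
#'
#' @param pop a `simulated_population`.
#' @param w a [window_spec()].
#' @return List with `true_multiple` (loci with >= 2 recorded
#'   origination events), `inferred_multiple` (shared loci inferred to
#'   have emerged more than once), and the full `scan`.
#' @export
compare_true_vs_inferred <- function(pop, w = window_spec()) {
  sc <- genome_scan(pop$matrix, w)
  list(true_multiple = true_homoplasy_count(pop),
       inferred_multiple = sc$n_multiple,
       scan = sc)
}

#' Write per-variant emergence calls as TSV
#' @param scan a `scan_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_emergence_calls <- function(scan, path) {
  write.table(scan$calls, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
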