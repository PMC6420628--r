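#' Normalize replicate phenotypes to per-progeny Z-scores
#'
#' Averages replicate colony sizes per progeny, then Z-scores across
#' progeny (mean 0, SD 1) so that regression effects are expressed in
#' phenotype standard deviations.
#'
#' @param pheno data frame with columns `progeny` and `size` (one row
#'   per replicate colony).
#' @return Named numeric vector of standardized phenotypes, one per
#'   progeny, in first-appearance order.
#' @export
normalize_phenotypes <- function(pheno) {
  means <- tapply(pheno$size, factor(pheno$progeny,
                                     levels = unique(pheno$progeny)), mean)
  if (length(unique(means)) < 2 || sd(means) == 0)
    stop("phenotype has zero variance across progeny")
  z <- (means - mean(means)) / sd(means)
  setNames(as.numeric(z), names(means))
}

#' Build a mapping design matrix with plate pseudo-genotypes
#'
#' Appends indicator pseudo-genotype columns for plate number and plate
#' position (row and column coordinates) to the marker genotypes, so
#' geometric and plate-to-plate effects are absorbed by the regression
#' instead of surfacing as spurious QTLs.  Pseudo-genotypes are flagged
#' non-genetic and never reported as QTLs.  Constant columns (e.g. a
#' single plate) are dropped.
#'
#' @param m a `genotype_matrix` of progeny (strains are progeny).
#' @param pheno replicate phenotype table (progeny, replicate, plate,
#'   row, col, size).
#' @return A `mapping_design` list: `X` (progeny x predictors),
#'   `genetic` (logical per column), `loci` (marker annotation for the
#'   genetic columns).
#' @export
append_pseudo_genotypes <- function(m, pheno) {
  progeny <- m$strains
  X <- m$calls
  storage.mode(X) <- "double"
  colnames(X) <- sprintf("m%06d", seq_len(ncol(X)))
  pl <- factor(pheno$plate)
  pseudo <- list()
  if (nlevels(pl) > 1) {
    ind <- stats::model.matrix(~ pl - 1)[, -1, drop = FALSE]
    colnames(ind) <- paste0("plate", levels(pl)[-1])
    # per-progeny mean membership across replicates
    agg <- apply(ind, 2, function(v)
      tapply(v, factor(pheno$progeny, levels = progeny), mean))
    pseudo$plate <- agg
  }
  for (coord in c("row", "col")) {
    if (!is.null(pheno[[coord]]) && length(unique(pheno[[coord]])) > 1) {
      v <- tapply(pheno[[coord]],
                  factor(pheno$progeny, levels = progeny), mean)
      pseudo[[coord]] <- matrix(v, ncol = 1,
                                dimnames = list(NULL, paste0("pos_", coord)))
    }
  }
  Z <- if (length(pseudo)) do.call(cbind, pseudo) else
    matrix(0, nrow(X), 0)
  design <- cbind(X, Z)
  genetic <- c(rep(TRUE, ncol(X)), rep(FALSE, ncol(Z)))
  marker_index <- c(seq_len(ncol(X)), rep(NA_integer_, ncol(Z)))
  keep <- apply(design, 2, function(v) var(v) > 0)
  structure(list(X = design[, keep, drop = FALSE],
                 genetic = genetic[keep],
                 marker_index = marker_index[keep],
                 loci = m$loci),
            class = "mapping_design")
}

# residualize columns of M against the column space of Q (orthonormal)
.residualize <- function(M, Q) M - Q %*% crossprod(Q, M)

#' Forward-selection QTL mapping
#'
#' Greedy forward selection on partial F-tests: at each step the
#' predictor with the smallest partial-F p-value is added while that
#' p-value is at most `p_enter`; after termination, terms whose
#' leave-one-out (each term fitted last) p-value exceeds `p_retain` are
#' removed, worst first.  Ties between equally significant markers
#' break toward the lowest genomic coordinate, making the procedure
#' deterministic and invariant to predictor column order.
#'
#' @param design a `mapping_design` from [append_pseudo_genotypes()],
#'   or a plain numeric matrix (all columns treated as genetic).
#' @param y standardized phenotype vector (see
#'   [normalize_phenotypes()]).
#' @param p_enter inclusion threshold (default 1e-3).
#' @param p_retain final retention threshold (default 1e-5).
#' @param max_terms safety cap on selected terms.
#' @return A `qtl_model` list: `terms` (data frame of retained
#'   predictors with effect sizes in phenotype SD, final p-values,
#'   incremental variance explained; pseudo-genotypes flagged),
#'   `qtls` (the genetic rows of `terms`), `fit` (the final `lm`).
#' @export
forward_select <- function(design, y, p_enter = 1e-3, p_retain = 1e-5,
                           max_terms = 50) {
  if (is.matrix(design)) {
    if (is.null(colnames(design)))
      colnames(design) <- sprintf("m%06d", seq_len(ncol(design)))
    design <- structure(list(X = design,
                             genetic = rep(TRUE, ncol(design)),
                             marker_index = seq_len(ncol(design)),
                             loci = NULL),
                        class = "mapping_design")
  }
  X <- design$X
  n <- length(y)
  stopifnot(nrow(X) == n)
  sel <- integer(0)
  Q <- qr.Q(qr(matrix(1, n, 1)))                # intercept only
  repeat {
    if (length(sel) >= max_terms || length(sel) >= n - 2) break
    cand <- setdiff(seq_len(ncol(X)), sel)
    if (!length(cand)) break
    ry <- .residualize(cbind(y), Q)
    RX <- .residualize(X[, cand, drop = FALSE], Q)
    ssx <- colSums(RX^2)
    ok <- ssx > 1e-10 * n                        # collinear -> skip
    if (!any(ok)) break
    r2 <- (crossprod(RX, ry)[, 1])^2 / (ssx * sum(ry^2))
    r2[!ok] <- 0
    df2 <- n - length(sel) - 2
    Fstat <- r2 / (1 - r2) * df2
    pv <- pf(Fstat, 1, df2, lower.tail = FALSE)
    pv[!ok] <- Inf
    best <- which(pv == min(pv))[1]              # lowest coordinate wins ties
    if (pv[best] > p_enter) break
    sel <- c(sel, cand[best])
    Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
  }
  # backward screen at p_retain on leave-one-out F-tests (each term
  # fitted last); one term per predictor column
  term_fit <- function(sel) {
    dfm <- as.data.frame(X[, sel, drop = FALSE])
    lm(y ~ ., data = dfm)
  }
  repeat {
    if (!length(sel)) break
    fit <- term_fit(sel)
    dr <- stats::drop1(fit, test = "F")
    pv <- dr[["Pr(>F)"]][-1]
    if (anyNA(pv)) {                             # collinear selected term
      drop_i <- which(is.na(pv))[length(which(is.na(pv)))]
      warning("dropping collinear predictor ",
              colnames(X)[sel[drop_i]])
      sel <- sel[-drop_i]
      next
    }
    worst <- which.max(pv)
    if (pv[worst] <= p_retain) break
    sel <- sel[-worst]
  }
  if (!length(sel)) {
    terms <- data.frame(column = character(0), marker = integer(0),
                        genetic = logical(0), effect = numeric(0),
                        p = numeric(0), var_explained = numeric(0))
    return(structure(list(terms = terms, qtls = terms, fit = NULL,
                          selected = integer(0), design = design, y = y,
                          p_enter = p_enter, p_retain = p_retain),
                     class = "qtl_model"))
  }
  fit <- term_fit(sel)
  dr <- stats::drop1(fit, test = "F")
  an <- anova(fit)
  ss <- an[["Sum Sq"]]
  tot <- sum((y - mean(y))^2)
  terms <- data.frame(column = colnames(X)[sel],
                      marker = design$marker_index[sel],
                      genetic = design$genetic[sel],
                      effect = unname(stats::coef(fit)[-1]),
                      p = dr[["Pr(>F)"]][-1],
                      var_explained = ss[seq_along(sel)] / tot,
                      stringsAsFactors = FALSE)
  if (!is.null(design$loci) && any(terms$genetic)) {
    gi <- terms$marker[terms$genetic]
    terms$chrom <- NA_character_
    terms$pos <- NA_integer_
    terms$chrom[terms$genetic] <- design$loci$chrom[gi]
    terms$pos[terms$genetic] <- design$loci$pos[gi]
  }
  structure(list(terms = terms, qtls = terms[terms$genetic, , drop = FALSE],
                 fit = fit, selected = sel, design = design, y = y,
                 p_enter = p_enter, p_retain = p_retain),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("qtl_model: %d terms retained (%d genetic QTLs)\n",
              nrow(x$terms), nrow(x$qtls)))
  if (nrow(x$qtls)) print(head(x$qtls, 20))
  invisible(x)
}

#' Per-term variance explained
#'
#' Incremental (selection-order) sums of squares as fractions of the
#' total phenotype variance; the fractions sum to at most 1.
#'
#' @param model a `qtl_model`.
#' @return Named numeric vector of fractions.
#' @export
variance_explained <- function(model) {
  setNames(model$terms$var_explained, model$terms$column)
}

#' Fine-map a QTL to a single nucleotide by in-silico allele swaps
#'
#' For each candidate variant in the linkage neighbourhood of a mapped
#' QTL, tests the null hypothesis that the candidate is not causal
#' relative to every other nearby segregating variant: for each
#' alternative, only progeny whose genotypes separate the two variants
#' (the in-silico analogue of reciprocal hemizygotes) are informative,
#' and the candidate's association with the phenotype residual (other
#' QTLs regressed out) is tested within that recombinant subset.  The
#' QTN score of a candidate is the weakest such evidence
#' (-log10 of the largest p-value over alternatives); the locus is
#' resolved when a unique candidate attains the maximum score and that
#' score is positive evidence.
#'
#' @param model a `qtl_model` containing the QTL.
#' @param qtl marker index (column of the genotype matrix) of the
#'   mapped QTL.
#' @param m the progeny `genotype_matrix`.
#' @param y standardized phenotype.
#' @param r2_min candidates are markers with `r^2 >=` this value to the
#'   QTL marker (linkage neighbourhood; default 0.5).
#' @param window_bp optional window half-width in bp overriding the
#'   r^2 neighbourhood.
#' @return A `qtn_profile` list: `scores` (candidate table with QTN
#'   score per candidate), `resolved`, `best` (marker index or `NA`),
#'   `resolution_bp` (span of the candidate set).
#' @export
fine_map_qtn <- function(model, qtl, m, y, r2_min = 0.5,
                         window_bp = NULL) {
  G <- m$calls
  storage.mode(G) <- "double"
  focal <- G[, qtl]
  if (!is.null(window_bp)) {
    near <- which(m$loci$chrom == m$loci$chrom[qtl] &
                    abs(m$loci$pos - m$loci$pos[qtl]) <= window_bp)
  } else {
    same_chr <- which(m$loci$chrom == m$loci$chrom[qtl])
    r2 <- suppressWarnings(cor(G[, same_chr, drop = FALSE], focal))^2
    r2[is.na(r2)] <- 0
    near <- same_chr[r2 >= r2_min]
  }
  near <- union(near, qtl)
  # residual phenotype with the other selected QTLs held fixed
  others <- setdiff(model$selected[model$design$genetic[model$selected]],
                    near)
  resid_y <- if (length(others)) {
    stats::resid(lm(y ~ model$design$X[, others, drop = FALSE]))
  } else y - mean(y)
  score <- numeric(length(near))
  for (ci in seq_along(near)) {
    cand <- near[ci]
    # direction of the candidate's full-sample association: the
    # recombinant subsets must confirm it, not merely show any signal
    dir <- sign(suppressWarnings(cor(resid_y, G[, cand])))
    if (is.na(dir) || dir == 0) dir <- 1
    worst_p <- 0
    for (alt in setdiff(near, cand)) {
      sep <- which(!is.na(G[, cand]) & !is.na(G[, alt]) &
                     G[, cand] != G[, alt])
      if (length(sep) < 3 || length(unique(G[sep, cand])) < 2) {
        worst_p <- 1                       # inseparable from this alternative
        break
      }
      ft <- lm(resid_y[sep] ~ G[sep, cand])
      sm <- summary(ft)$coefficients
      p <- if (nrow(sm) < 2) 1 else
        pt(dir * sm[2, 3], ft$df.residual, lower.tail = FALSE)
      worst_p <- max(worst_p, p)
    }
    score[ci] <- -log10(max(worst_p, 1e-300))
  }
  ordscore <- order(score, decreasing = TRUE)
  best <- near[ordscore[1]]
  unique_max <- sum(score == max(score)) == 1
  resolved <- unique_max && max(score) > -log10(0.05) &&
    length(near) >= 1
  structure(list(scores = data.frame(marker = near,
                                     chrom = m$loci$chrom[near],
                                     pos = m$loci$pos[near],
                                     qtn_score = score),
                 resolved = resolved,
                 best = if (resolved) best else NA_integer_,
                 resolution_bp = diff(range(m$loci$pos[near]))),
            class = "qtn_profile")
}

#' Empirical FDR by phenotype permutation
#'
#' Re-runs the full forward selection on phenotypes permuted across
#' progeny; the FDR estimate is the mean number of genetic QTLs
#' reported on permuted data divided by the number reported on the real
#' data.
#'
#' @param design a `mapping_design`.
#' @param y standardized phenotype.
#' @param n_perms number of permutations (>= 10).
#' @param p_enter,p_retain forwarded to [forward_select()].
#' @return List: `fdr`, `n_real`, `perm_counts`, `degenerate` (`TRUE`
#'   when the real data yield no QTLs, in which case the ratio is
#'   reported against a count of 1 and flagged).
#' @export
permutation_fdr <- function(design, y, n_perms = 10, p_enter = 1e-3,
                            p_retain = 1e-5) {
  stopifnot(n_perms >= 10)
  real <- forward_select(design, y, p_enter, p_retain)
  n_real <- nrow(real$qtls)
  perm_counts <- vapply(seq_len(n_perms), function(i) {
    yp <- sample(y)
    nrow(forward_select(design, yp, p_enter, p_retain)$qtls)
  }, numeric(1))
  degenerate <- n_real == 0
  list(fdr = mean(perm_counts) / max(n_real, 1),
       n_real = n_real, perm_counts = perm_counts,
       degenerate = degenerate)
}
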