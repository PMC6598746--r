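# RELL multiscale bootstrap, the Approximately Unbiased test, the
# Shimodaira-Hasegawa test, and the reciprocal-incongruence decision rule.

DEFAULT_SCALES <- seq(0.5, 1.4, by = 0.1)

# compress a trees x sites log-likelihood matrix into unique site patterns
ll_patterns <- function(sl) {
  if (!is.null(sl$pat_ll)) {
    return(list(ll = sl$pat_ll, w = sl$pat_weights))
  }
  m <- sl$matrix
  key <- apply(m, 2, paste, collapse = "\r")
  first <- !duplicated(key)
  list(ll = m[, first, drop = FALSE],
       w = as.integer(tabulate(match(key, key[first]), nbins = sum(first))))
}

as_site_lik <- function(x) {
  if (inherits(x, "site_likelihoods")) return(x)
  if (is.matrix(x)) {
    return(structure(list(matrix = x, total = rowSums(x),
                          pat_ll = NULL, pat_weights = NULL),
                     class = "site_likelihoods"))
  }
  stop("expected a site_likelihoods object or a trees x sites matrix")
}

#' RELL bootstrap proportions over a grid of scales
#'
#' For each scale `r`, draws `B` resamples of `round(n * r)` site columns
#' with replacement (multinomial over site patterns) and records the
#' fraction of resamples in which each tree attains the maximum resampled
#' log-likelihood; exact ties are split equally, so columns sum to one.
#'
#' @param sl a `site_likelihoods` object (or plain trees x sites matrix).
#' @param scales resampling scale factors (default 0.5..1.4 by 0.1).
#' @param B total replicates, split evenly across scales.
#' @param seed integer seed.
#' @return matrix of bootstrap proportions, trees x scales, with
#'   attributes `B_per_scale` and `scales`.
#' @export
rell_resample <- function(sl, scales = DEFAULT_SCALES, B = 10000, seed = 1L) {
  sl <- as_site_lik(sl)
  ntree <- nrow(sl$matrix)
  n <- ncol(sl$matrix)
  if (ntree < 2) stop("need >= 2 trees")
  if (n < 2) stop("need >= 2 sites")
  pats <- ll_patterns(sl)
  Bk <- max(1L, round(B / length(scales)))
  set.seed(derive_seed(seed, 555L))
  bp <- matrix(0, ntree, length(scales))
  keep <- logical(length(scales))
  for (k in seq_along(scales)) {
    m <- round(n * scales[k])
    if (m < 1) { warning("scale ", scales[k], " resamples 0 sites; skipped"); next }
    keep[k] <- TRUE
    counts <- rmultinom(Bk, m, prob = pats$w / n)
    totals <- pats$ll %*% counts                       # trees x Bk
    mx <- apply(totals, 2, max)
    ismax <- sweep(totals, 2, mx, "==")
    tie <- colSums(ismax)
    bp[, k] <- rowSums(sweep(ismax, 2, tie, "/")) / Bk
  }
  bp <- bp[, keep, drop = FALSE]
  attr(bp, "scales") <- scales[keep]
  attr(bp, "B_per_scale") <- Bk
  bp
}

#' AU p-value from a multiscale bootstrap curve
#'
#' Fits the signed distance `d` and curvature `c` of the multiscale model
#' `BP(r) = Phi(-(d * sqrt(r) + c / sqrt(r)))`, then
#' `au_p = 1 - pnorm(d - c)`. The fit maximises the exact binomial
#' likelihood of the replicate counts over every scale (so scales where the
#' tree never or always won still inform the curve); a weighted
#' least-squares fit of `qnorm(1 - BP_k)` with binomial-variance weights on
#' the interior scales provides the starting point. A curve at 1 (or 0) on
#' every scale short-circuits to that bound with a degeneracy flag.
#'
#' @param bp_curve bootstrap proportions for one tree, one per scale.
#' @param scales the scale factors.
#' @param B replicates per scale.
#' @return list with elements `c`, `d`, `au_p`, `degenerate`, `n_usable`.
#' @export
au_pvalue <- function(bp_curve, scales, B) {
  stopifnot(length(bp_curve) == length(scales))
  if (length(scales) < 2) stop("fewer than 2 usable scales for the AU fit")
  if (all(bp_curve >= 1)) {
    return(list(c = NA_real_, d = NA_real_, au_p = 1, degenerate = TRUE,
                n_usable = 0L))
  }
  if (all(bp_curve <= 0)) {
    return(list(c = NA_real_, d = NA_real_, au_p = 0, degenerate = TRUE,
                n_usable = 0L))
  }
  usable <- bp_curve > 0 & bp_curve < 1
  # WLS on proportions strictly inside (0,1) (clamped to the resolution of
  # B replicates) initialises the fit
  init <- c(0, 0)
  if (sum(usable) >= 2) {
    eps <- 1 / (2 * B)
    bp <- pmin(pmax(bp_curve[usable], eps), 1 - eps)
    psi <- qnorm(1 - bp)
    w <- B * dnorm(psi)^2 / (bp * (1 - bp))
    X <- cbind(sqrt(scales[usable]), 1 / sqrt(scales[usable]))
    init <- unname(stats::lm.wfit(X, psi, w)$coefficients)
    init[!is.finite(init)] <- 0
  }
  # exact binomial likelihood over ALL scales: a zero count at scale r is
  # strong evidence that d*sqrt(r) + c/sqrt(r) is large, information the
  # clamped least-squares fit cannot carry
  x <- pmin(pmax(round(bp_curve * B), 0), B)
  # a curve pinned to one bound with only a couple of stray counts cannot
  # support the two-parameter fit; it is decisively at that bound
  if (sum(pmin(x, B - x)) <= 2) {
    at_one <- mean(bp_curve) >= 0.5
    return(list(c = NA_real_, d = NA_real_, au_p = as.numeric(at_one),
                degenerate = TRUE, n_usable = sum(usable)))
  }
  nll <- function(par) {
    p <- pnorm(-(par[1] * sqrt(scales) + par[2] / sqrt(scales)))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(x * log(p) + (B - x) * log1p(-p))
  }
  opt <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  d <- opt$par[1]
  cc <- opt$par[2]
  list(c = cc, d = d, au_p = unname(1 - pnorm(d - cc)), degenerate = FALSE,
       n_usable = sum(usable))
}

#' Approximately Unbiased test over a set of trees
#'
#' Runs the multiscale RELL bootstrap and fits the AU p-value for every
#' tree in the candidate set.
#'
#' @inheritParams rell_resample
#' @return object of class `au_result`: `bp` (trees x scales), `au_p`,
#'   fitted `c`/`d`, degeneracy flags, `best` (index of the
#'   maximum-likelihood tree, lowest index on ties).
#' @export
au_test <- function(sl, scales = DEFAULT_SCALES, B = 10000, seed = 1L) {
  sl <- as_site_lik(sl)
  bp <- rell_resample(sl, scales, B, seed)
  Bk <- attr(bp, "B_per_scale")
  sc <- attr(bp, "scales")
  fits <- lapply(seq_len(nrow(bp)), function(i) au_pvalue(bp[i, ], sc, Bk))
  structure(list(
    bp = bp, scales = sc, B_per_scale = Bk, seed = seed,
    au_p = vapply(fits, `[[`, 0, "au_p"),
    d = vapply(fits, `[[`, 0, "d"),
    c = vapply(fits, `[[`, 0, "c"),
    degenerate = vapply(fits, `[[`, NA, "degenerate"),
    total_ll = sl$total,
    best = which.max(sl$total)[1]),
    class = "au_result")
}

#' @export
print.au_result <- function(x, ...) {
  cat("<au_result> ", length(x$au_p), " trees; best tree #", x$best, "\n", sep = "")
  print(round(x$au_p, 4))
  invisible(x)
}

#' Shimodaira-Hasegawa test
#'
#' Centered-RELL null of the log-likelihood deficits
#' `delta_T = max_U l(U) - l(T)`; the p-value is the fraction of resampled
#' centered deficits at least as large as the observed one.
#'
#' @param sl a `site_likelihoods` object (or trees x sites matrix).
#' @param B RELL replicates.
#' @param seed integer seed.
#' @return numeric vector of per-tree p-values.
#' @export
sh_test <- function(sl, B = 10000, seed = 1L) {
  sl <- as_site_lik(sl)
  if (nrow(sl$matrix) < 2) stop("need >= 2 trees")
  pats <- ll_patterns(sl)
  n <- ncol(sl$matrix)
  obs <- sl$total
  delta_obs <- max(obs) - obs
  set.seed(derive_seed(seed, 777L))
  counts <- rmultinom(B, n, prob = pats$w / n)
  totals <- pats$ll %*% counts                 # trees x B
  centered <- totals - rowMeans(totals)
  mx <- apply(centered, 2, max)
  delta_star <- sweep(-centered, 2, mx, `+`)   # max_U - value, per tree x B
  p <- rowMeans(delta_star >= delta_obs)
  unname(p)
}

#' Reciprocal AU verdicts for a three-locus dataset
#'
#' For each base locus, the three focal gene trees are compared together
#' with a set of equiprobable random trees; branch lengths are re-optimised
#' per candidate tree on the base alignment. A focal tree is rejected on a
#' base locus when its AU p-value falls below `alpha`; a locus pair is
#' incongruent only when rejection is reciprocal. A rejection is flagged
#' `resolution_confounded` when the base locus's own tree is more resolved
#' than the compared tree by more than `resolution_margin` internal edges
#' (hypervariable-marker caveat).
#'
#' @param alignments named list of three [locus_alignment]s.
#' @param focal_trees named list of the three per-locus trees (same names).
#' @param specs optional named list of `model_spec`s per locus.
#' @param n_random random trees added to each candidate set.
#' @param B total RELL replicates.
#' @param alpha per-comparison significance level (default 0.05/6).
#' @param resolution_margin internal-edge difference triggering the flag.
#' @param seed integer seed.
#' @return list with `verdicts` (one per unordered locus pair),
#'   `au` (per-base AU results), `best_tree` (per base locus).
#' @export
reciprocal_au <- function(alignments, focal_trees, specs = NULL,
                          n_random = 100, B = 10000, alpha = 0.05 / 6,
                          resolution_margin = 3, seed = 1L) {
  stopifnot(length(alignments) == 3, length(focal_trees) == 3)
  loci <- vapply(alignments, function(a) a$locus_name, character(1))
  names(alignments) <- names(focal_trees) <- loci
  rejected <- matrix(FALSE, 3, 3, dimnames = list(base = loci, tree = loci))
  confounded <- matrix(FALSE, 3, 3, dimnames = list(base = loci, tree = loci))
  au_by_base <- list()
  best_tree <- character(3)
  names(best_tree) <- loci
  pvals <- matrix(NA_real_, 3, 3, dimnames = list(base = loci, tree = loci))
  for (b in seq_along(loci)) {
    base <- loci[b]
    aln <- alignments[[base]]
    spec <- if (!is.null(specs)) specs[[base]] else select_model(aln)
    rand <- generate_random_trees(aln$sample_ids, n_random,
                                  seed = derive_seed(seed, 40L + b))
    cand <- c(focal_trees[loci], rand)
    sl <- site_log_likelihoods(cand, aln, spec)
    au <- au_test(sl, B = B, seed = derive_seed(seed, 50L + b))
    au_by_base[[base]] <- au
    best_tree[base] <- if (au$best <= 3) loci[au$best] else
      sprintf("random_%d", au$best - 3L)
    # a base locus is resolution-confounded when its own tree out-resolves
    # EVERY other focal tree by more than the margin (a hypervariable
    # marker that no other gene tree can explain, regardless of history)
    res <- vapply(focal_trees[loci], resolved_internal_edges, numeric(1))
    base_confounded <- all(res[b] - res[-b] > resolution_margin)
    for (j in seq_along(loci)) {
      pvals[b, j] <- au$au_p[j]
      if (j == b) next
      rejected[b, j] <- au$au_p[j] < alpha
      confounded[b, j] <- rejected[b, j] && base_confounded
    }
  }
  pairs <- combn(3, 2)
  verdicts <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    rx <- rejected[i, j]   # locus j's tree rejected on locus i's data
    ry <- rejected[j, i]
    structure(list(locus_x = loci[i], locus_y = loci[j],
                   rejected_on_x = rx, rejected_on_y = ry,
                   incongruent = rx && ry, alpha = alpha,
                   p_on_x = pvals[i, j], p_on_y = pvals[j, i],
                   resolution_confounded = confounded[i, j] || confounded[j, i]),
              class = "reciprocal_verdict")
  })
  names(verdicts) <- apply(pairs, 2, function(ij) paste(loci[ij], collapse = ".vs."))
  list(verdicts = verdicts, au = au_by_base, best_tree = best_tree,
       p_matrix = pvals, alpha = alpha)
}

#' @export
print.reciprocal_verdict <- function(x, ...) {
  cat("<reciprocal_verdict> ", x$locus_x, " vs ", x$locus_y, ": ",
      if (x$incongruent) "INCONGRUENT" else "not incongruent",
      if (x$resolution_confounded) " [resolution-confounded]" else "",
      "\n  p(", x$locus_y, " tree on ", x$locus_x, " data) = ",
      signif(x$p_on_x, 3), "; p(", x$locus_x, " tree on ", x$locus_y,
      " data) = ", signif(x$p_on_y, 3), "\n", sep = "")
  invisible(x)
}
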