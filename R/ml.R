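# Likelihood side of the workflow: JC/NJ starting trees, substitution-model
# selection by AICc, per-site log-likelihoods, NNI maximum-likelihood
# search, bootstrap with polytomy collapse, and equiprobable random trees.
#
# Convention: in the likelihood engine gaps and N are missing data
# (marginalised); only the parsimony side treats the gap as a fifth state.

aln_to_phydat <- function(aln) {
  m <- aln$matrix
  m[m %in% c("-", "N")] <- "n"
  phangorn::phyDat(tolower(m), type = "DNA")
}

aln_to_dnabin <- function(aln) {
  ape::as.DNAbin(tolower(aln$matrix))
}

jc_distance <- function(aln, cap = 5) {
  d <- ape::dist.dna(aln_to_dnabin(aln), model = "JC69", pairwise.deletion = TRUE)
  bad <- !is.finite(d)
  if (any(bad)) {
    warning("saturated JC distances capped at ", cap)
    d[bad] <- cap
  }
  d
}

#' Neighbour-joining tree from Jukes-Cantor distances
#'
#' Saturated distances are capped (with a warning) and negative NJ branch
#' lengths clamped to zero. If every sequence is identical the star tree is
#' returned with attribute `star = TRUE`.
#'
#' @param aln a [locus_alignment] with >= 3 samples.
#' @return an unrooted `phylo`.
#' @export
build_nj_tree <- function(aln) {
  if (n_samples(aln) < 3) stop("need >= 3 samples for NJ")
  d <- jc_distance(aln)
  if (all(d == 0)) {
    tr <- ape::stree(n_samples(aln), type = "star", tip.label = aln$sample_ids)
    tr$edge.length <- rep(0, nrow(tr$edge))
    attr(tr, "star") <- TRUE
    return(tr)
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

model_df <- function(model, gamma) {
  base <- switch(model, JC = 0L, K80 = 1L, HKY = 4L, GTR = 8L,
                 stop("unknown model: ", model))
  base + if (gamma) 1L else 0L
}

fit_candidate <- function(tree, dat, model, gamma, optimize_topology = FALSE,
                          opt_edge = TRUE) {
  k <- if (gamma) 4L else 1L
  fit <- phangorn::pml(tree, dat, model = model, k = k,
                       shape = if (gamma) 1 else 1)
  phangorn::optim.pml(
    fit, model = model,
    optEdge = opt_edge,
    optBf = model %in% c("HKY", "GTR"),
    optQ = model %in% c("K80", "HKY", "GTR"),
    optGamma = gamma,
    rearrangement = if (optimize_topology) "NNI" else "none",
    control = phangorn::pml.control(trace = 0))
}

#' Select a substitution model by AICc
#'
#' Fits each candidate (branch lengths optimised on a fixed NJ topology)
#' and returns the lowest-AICc model; ties go to the simpler model. With
#' very short alignments the AICc penalty can be undefined for complex
#' candidates, in which case the simplest model is selected with a warning.
#'
#' @param aln a [locus_alignment].
#' @param models candidate substitution models.
#' @param gamma candidate gamma settings (4 discrete categories when TRUE).
#' @return a `model_spec`: model name, gamma flag, fitted shape, base
#'   frequencies, rate matrix, and the AICc table.
#' @export
select_model <- function(aln, models = c("JC", "K80", "HKY", "GTR"),
                         gamma = c(FALSE, TRUE)) {
  dat <- aln_to_phydat(aln)
  tree <- build_nj_tree(aln)
  if (isTRUE(attr(tree, "star"))) tree <- ape::multi2di(tree)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  n_sites <- n_columns(aln)
  grid <- expand.grid(model = models, gamma = gamma, stringsAsFactors = FALSE)
  # simpler models first so ties resolve to them
  grid <- grid[order(mapply(model_df, grid$model, grid$gamma)), ]
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    m <- grid$model[i]; g <- grid$gamma[i]
    fit <- tryCatch(fit_candidate(tree, dat, m, g),
                    error = function(e) NULL)
    if (is.null(fit)) next
    k <- model_df(m, g) + nrow(fit$tree$edge)
    aicc <- -2 * fit$logLik + 2 * k +
      if (n_sites - k - 1 > 0) 2 * k * (k + 1) / (n_sites - k - 1) else Inf
    rows[[length(rows) + 1]] <- list(model = m, gamma = g, logLik = fit$logLik,
                                     df = k, AICc = aicc, fit = fit)
  }
  if (!length(rows)) stop("no candidate model could be fitted")
  tab <- data.frame(model = vapply(rows, `[[`, "", "model"),
                    gamma = vapply(rows, `[[`, NA, "gamma"),
                    logLik = vapply(rows, `[[`, 0, "logLik"),
                    df = vapply(rows, `[[`, 0, "df"),
                    AICc = vapply(rows, `[[`, 0, "AICc"))
  if (any(!is.finite(tab$AICc))) {
    warning("alignment too short for a reliable AICc on complex candidates")
  }
  best <- if (all(!is.finite(tab$AICc))) 1L else which.min(tab$AICc)
  fit <- rows[[best]]$fit
  structure(list(model = tab$model[best], gamma = tab$gamma[best],
                 shape = if (tab$gamma[best]) fit$shape else NULL,
                 bf = fit$bf, Q = fit$Q, k = if (tab$gamma[best]) 4L else 1L,
                 aicc_table = tab),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$model, if (x$gamma) "+G4" else "",
      "  (AICc-selected)\n", sep = "")
  invisible(x)
}

#' Write a model-selection report as JSON
#' @param spec a `model_spec`.
#' @param path output JSON file.
#' @export
write_model_json <- function(spec, path) {
  jsonlite::write_json(list(model = spec$model, gamma = spec$gamma,
                            shape = spec$shape, bf = spec$bf, Q = spec$Q,
                            aicc_table = spec$aicc_table),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

pml_with_spec <- function(tree, dat, spec, opt_edge = TRUE) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  tree <- ape::unroot(tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.05, nrow(tree$edge))
  tree$edge.length[tree$edge.length <= 0] <- 1e-8
  fit <- phangorn::pml(tree, dat, bf = spec$bf, Q = spec$Q, k = spec$k,
                       shape = if (spec$gamma) spec$shape else 1)
  if (opt_edge) {
    fit <- tryCatch(
      phangorn::optim.pml(fit, optEdge = TRUE, optBf = FALSE, optQ = FALSE,
                          optGamma = FALSE,
                          control = phangorn::pml.control(trace = 0, maxit = 10)),
      error = function(e) fit)
  }
  fit
}

#' Per-site log-likelihoods for a set of trees
#'
#' Branch lengths are optimised per tree under the fixed model (pruning
#' algorithm via the likelihood engine); the returned matrix holds natural
#' logs, one row per tree, one column per alignment site. Row sums equal
#' each tree's total log-likelihood.
#'
#' @param trees `multiPhylo` or list of `phylo` (>= 1); polytomies are
#'   resolved with zero-length branches before fitting.
#' @param aln a [locus_alignment].
#' @param spec a `model_spec` from [select_model()].
#' @return object of class `site_likelihoods`: `matrix` (trees x sites),
#'   `total` (per-tree log-likelihood), plus per-pattern structures used by
#'   the RELL resampler.
#' @export
site_log_likelihoods <- function(trees, aln, spec) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (n_columns(aln) < 1) stop("zero-length alignment")
  dat <- aln_to_phydat(aln)
  idx <- attr(dat, "index")
  npat <- attr(dat, "nr")
  wts <- attr(dat, "weight")
  pat_ll <- matrix(NA_real_, length(trees), npat)
  fits <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    fit <- pml_with_spec(trees[[i]], dat, spec)
    sl <- fit$siteLik
    if (is.null(sl)) stop("likelihood engine returned no site likelihoods")
    pat_ll[i, ] <- as.numeric(sl)
    fits[[i]] <- fit$tree
  }
  full <- pat_ll[, idx, drop = FALSE]
  structure(list(trees = trees, fitted_trees = fits, matrix = full,
                 total = rowSums(full), model = spec,
                 pat_ll = pat_ll, pat_weights = wts, pat_index = idx),
            class = "site_likelihoods")
}

#' @export
print.site_likelihoods <- function(x, ...) {
  cat("<site_likelihoods> ", nrow(x$matrix), " trees x ", ncol(x$matrix),
      " sites; total ll range [", round(min(x$total), 2), ", ",
      round(max(x$total), 2), "]\n", sep = "")
  invisible(x)
}

#' Maximum-likelihood tree search
#'
#' NJ starting tree, then alternating branch-length optimisation and
#' NNI accept-if-better moves to a local optimum under the given model.
#'
#' @param aln a [locus_alignment].
#' @param spec a `model_spec`; selected from the data when `NULL`.
#' @return a `phylo` with branch lengths; attribute `logLik` carries the
#'   final log-likelihood.
#' @export
ml_heuristic_search <- function(aln, spec = NULL) {
  if (n_samples(aln) == 2) {
    d <- jc_distance(aln)
    tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                         tip.label = aln$sample_ids, Nnode = 1L,
                         edge.length = c(d[1] / 2, d[1] / 2)),
                    class = "phylo")
    return(tr)
  }
  if (is.null(spec)) spec <- select_model(aln)
  dat <- aln_to_phydat(aln)
  tree <- build_nj_tree(aln)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  fit <- phangorn::pml(tree, dat, bf = spec$bf, Q = spec$Q, k = spec$k,
                       shape = if (spec$gamma) spec$shape else 1)
  # near-invariant data can leave too few distinct sequences for the NNI
  # machinery; the NJ topology with optimised branch lengths then stands
  fit <- tryCatch(
    phangorn::optim.pml(fit, optEdge = TRUE, rearrangement = "NNI",
                        control = phangorn::pml.control(trace = 0)),
    error = function(e) {
      phangorn::optim.pml(fit, optEdge = TRUE, rearrangement = "none",
                          control = phangorn::pml.control(trace = 0))
    })
  out <- fit$tree
  attr(out, "logLik") <- fit$logLik
  out
}

#' Bootstrap supports with polytomy collapse
#'
#' Site columns are resampled with replacement; each replicate tree comes
#' from a reduced search (NJ start plus a single parsimony NNI pass, the
#' fast-search analog). Supports (percent of replicates containing each
#' internal bipartition) are mapped onto the ML tree and internal edges
#' below `collapse_threshold` are collapsed into polytomies.
#'
#' @param aln a [locus_alignment].
#' @param spec optional `model_spec` for the ML tree.
#' @param replicates bootstrap replicates (>= 1).
#' @param collapse_threshold percent support below which edges collapse.
#' @param seed integer seed.
#' @param ml_tree optionally a precomputed ML tree to annotate.
#' @return a `phylo` with node labels holding percent supports; collapsed
#'   to polytomies below the threshold.
#' @export
bootstrap_support <- function(aln, spec = NULL, replicates = 100,
                              collapse_threshold = 50, seed = 1L,
                              ml_tree = NULL) {
  stopifnot(replicates >= 1)
  if (is.null(spec)) spec <- select_model(aln)
  if (is.null(ml_tree)) ml_tree <- ml_heuristic_search(aln, spec)
  set.seed(derive_seed(seed, 77L))
  nc <- n_columns(aln)
  n <- n_samples(aln)
  enc <- encode_five_state(aln)
  # per-pattern pairwise mismatch/valid indicators: a bootstrap replicate is
  # a multinomial over site patterns, so JC distances come from two matrix
  # products instead of re-encoding the resampled alignment
  P <- ncol(enc$pat_masks)
  prs <- combn(n, 2)
  single <- matrix(enc$pat_masks %in% c(1L, 2L, 4L, 8L), n, P)
  Vm <- matrix(0, ncol(prs), P)
  Dm <- matrix(0, ncol(prs), P)
  for (k in seq_len(ncol(prs))) {
    i <- prs[1, k]; j <- prs[2, k]
    v <- single[i, ] & single[j, ]
    Vm[k, ] <- v
    Dm[k, ] <- v & (enc$pat_masks[i, ] != enc$pat_masks[j, ])
  }
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    counts <- as.numeric(rmultinom(1, nc, enc$pat_weights / nc))
    val <- as.numeric(Vm %*% counts)
    mis <- as.numeric(Dm %*% counts)
    ph <- rep(0, length(val))
    ph[val > 0] <- mis[val > 0] / val[val > 0]
    jc <- rep(5, length(ph))
    ok <- ph < 0.7499
    jc[ok] <- -0.75 * log(1 - 4 * ph[ok] / 3)
    # sub-signal jitter so NJ resolves zero-distance ties randomly per
    # replicate; deterministic tie-breaking would pile spurious support
    # onto one arbitrary resolution of identical-sequence clusters
    jc <- jc + runif(length(jc), 0, 1e-9)
    d <- matrix(0, n, n, dimnames = list(aln$sample_ids, aln$sample_ids))
    d[t(prs)] <- jc
    d <- stats::as.dist(d + t(d))
    start <- if (all(d == 0)) NULL else tryCatch(ape::nj(d), error = function(e) NULL)
    if (is.null(start)) {
      # resample carries no signal: resolve the star RANDOMLY so arbitrary
      # resolutions cannot accumulate spurious support across replicates
      start <- ape::multi2di(ape::stree(n, type = "star",
                                        tip.label = aln$sample_ids),
                             random = TRUE)
    }
    if (!ape::is.binary(start)) start <- ape::multi2di(start, random = TRUE)
    present <- counts > 0
    reps[[b]] <- nni_improve_masks(
      start, enc$pat_masks[, present, drop = FALSE], counts[present],
      enc$sample_ids, sweeps = 1, seed = derive_seed(seed, 200L + b))
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(ml_tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(reps))
  tr <- ml_tree
  tr$node.label <- as.character(support)
  collapse_low_support(tr, collapse_threshold)
}

#' Collapse weakly supported internal edges into polytomies
#'
#' @param tree a `phylo` whose node labels are numeric supports (0-100).
#' @param threshold edges whose child node has support `< threshold` are
#'   contracted; the root is never contracted.
#' @return a `phylo`, possibly multifurcating; supports retained as node
#'   labels on surviving nodes.
#' @export
collapse_low_support <- function(tree, threshold) {
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label)) return(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  root <- ntip + 1L
  has_len <- !is.null(tree$edge.length)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- if (has_len) split(tree$edge.length, tree$edge[, 1]) else NULL
  lenof <- function(par, ch) if (has_len) elen[[as.character(par)]][
    match(ch, kids[[as.character(par)]])] else NA_real_
  build <- function(v, par) {
    if (v <= ntip) {
      s <- tree$tip.label[v]
      if (has_len) s <- paste0(s, ":", format(lenof(par, v), digits = 10))
      return(s)
    }
    weak <- v != root && !is.na(sup[v - ntip]) && sup[v - ntip] < threshold
    parts <- vapply(kids[[as.character(v)]], build, character(1), par = v)
    if (weak) return(paste(parts, collapse = ","))  # splice into parent
    lab <- if (is.na(sup[v - ntip])) "" else tree$node.label[v - ntip]
    s <- paste0("(", paste(parts, collapse = ","), ")", lab)
    if (v != root && has_len)
      s <- paste0(s, ":", format(lenof(par, v), digits = 10))
    s
  }
  ape::read.tree(text = paste0(build(root, NA), ";"))
}

#' Random trees under the equiprobable model
#'
#' Each tree is drawn uniformly over unrooted binary labelled topologies by
#' sequential addition at a uniformly chosen edge; deterministic given the
#' seed. Duplicates are permitted.
#'
#' @param labels tip labels (>= 3).
#' @param n number of trees.
#' @param seed integer seed.
#' @return a `multiPhylo` of `n` trees (no branch lengths).
#' @export
generate_random_trees <- function(labels, n, seed = 1L) {
  stopifnot(length(labels) >= 3, n >= 1)
  set.seed(derive_seed(seed, 333L))
  out <- vector("list", n)
  for (k in seq_len(n)) out[[k]] <- random_topology(labels)
  class(out) <- "multiPhylo"
  out
}

random_topology <- function(labels) {
  n <- length(labels)
  if (n == 3) return(ape::read.tree(text = paste0(
    "(", labels[1], ",", labels[2], ",", labels[3], ");")))
  # parent/child arrays, rooted at leaf 1; leaves 1..n, internals n+1..
  parent <- integer(2 * n - 2)
  child1 <- integer(2 * n - 2)
  child2 <- integer(2 * n - 2)
  root_child <- n + 1L
  child1[root_child] <- 2L; child2[root_child] <- 3L
  parent[2L] <- root_child; parent[3L] <- root_child; parent[root_child] <- 1L
  nodes <- c(2L, 3L, root_child)  # nodes owning an insertable parent-edge
  for (k in 4:n) {
    e <- nodes[sample.int(length(nodes), 1)]
    v <- n + k - 2L
    p <- parent[e]
    if (p == 1L) root_child <- v
    else if (child1[p] == e) child1[p] <- v else child2[p] <- v
    parent[v] <- p
    child1[v] <- e; child2[v] <- k
    parent[e] <- v; parent[k] <- v
    nodes <- c(nodes, v, k)
  }
  bld <- function(v) {
    if (v <= n) return(labels[v])
    paste0("(", bld(child1[v]), ",", bld(child2[v]), ")")
  }
  nwk <- paste0("(", labels[1], ",", bld(child1[root_child]), ",",
                bld(child2[root_child]), ");")
  ape::read.tree(text = nwk)
}

# number of resolved internal edges of an unrooted tree
resolved_internal_edges <- function(tree) {
  sum(tree$edge[, 2] > length(tree$tip.label))
}
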