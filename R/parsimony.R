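# Fitch/Hartigan parsimony on the 5-state alphabet and heuristic MP search.

enc_of <- function(x) {
  if (inherits(x, "five_state")) x
  else if (inherits(x, "locus_alignment")) encode_five_state(x)
  else stop("expected a locus_alignment or five_state encoding")
}

# newick strings from the engine use placeholder tips t1..tn
engine_trees <- function(newicks, sample_ids) {
  trees <- lapply(newicks, function(s) {
    tr <- ape::read.tree(text = s)
    tr$tip.label <- sample_ids[as.integer(sub("^t", "", tr$tip.label))]
    tr
  })
  class(trees) <- "multiPhylo"
  trees
}

#' Parsimony length of a tree (Fitch/Hartigan)
#'
#' Minimum number of character-state changes the tree requires for the
#' alignment, with gaps as a fifth state and `N` fully ambiguous.
#' Multifurcating trees are scored exactly via Hartigan's generalisation;
#' the length is invariant to rooting.
#'
#' @param tree an `ape::phylo`; its tips must be a subset of the alignment
#'   sample ids.
#' @param data a [locus_alignment] or `five_state` encoding.
#' @return integer tree length.
#' @export
fitch_length <- function(tree, data) {
  enc <- enc_of(data)
  miss <- setdiff(tree$tip.label, enc$sample_ids)
  if (length(miss)) stop("tree leaves without sequences: ", paste(miss, collapse = ", "))
  keep <- match(tree$tip.label, enc$sample_ids)
  masks <- enc$masks[keep, , drop = FALSE]
  # recompress patterns for the restricted taxon set
  key <- apply(masks, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- masks[, first, drop = FALSE]
  w <- as.integer(tabulate(match(key, key[first]), nbins = sum(first)))
  tree <- ape::reorder.phylo(tree, "postorder")
  .cpp_hartigan_length(tree$edge, length(tree$tip.label), tree$Nnode,
                       storage.mode_int(pat), w)
}

storage.mode_int <- function(m) { storage.mode(m) <- "integer"; m }

uninformative_patterns <- function(pat_masks) {
  # a pattern is parsimony-uninformative if, ignoring ambiguity, at most one
  # non-singleton state is present
  apply(pat_masks, 2, function(col) {
    unamb <- col[col %in% c(1L, 2L, 4L, 8L, 16L)]
    tab <- table(unamb)
    sum(tab >= 2) <= 1
  })
}

mp_degenerate <- function(enc) {
  n <- length(enc$sample_ids)
  nwk <- if (n == 2) paste0("(", enc$sample_ids[1], ",", enc$sample_ids[2], ");")
  else paste0("(", paste(enc$sample_ids, collapse = ","), ");")
  tr <- ape::read.tree(text = nwk)
  len <- fitch_length(tr, enc)
  trees <- c(tr)
  structure(list(best_length = len, trees = trees,
                 search_meta = list(degenerate = TRUE, n_taxa = n)),
            class = "parsimony_result")
}

#' Heuristic maximum-parsimony search
#'
#' Random-sequence-addition starting trees followed by NNI hill-climbing;
#' all equally most-parsimonious trees found on the final plateau are
#' retained up to `maxtrees` (the number of trees stored at any one time).
#' Deterministic given `seed`.
#'
#' @param data a [locus_alignment] or `five_state` encoding.
#' @param addition_replicates number of random-addition starts.
#' @param maxtrees cap on retained equally parsimonious trees.
#' @param seed integer RNG seed for the search.
#' @param exclude_uninformative drop parsimony-uninformative sites before
#'   scoring (changes absolute lengths, not optima).
#' @return `parsimony_result`: `best_length`, `trees` (multiPhylo),
#'   `search_meta`.
#' @export
mp_heuristic_search <- function(data, addition_replicates = 10, maxtrees = 100,
                                seed = 1L, exclude_uninformative = FALSE) {
  enc <- enc_of(data)
  if (length(enc$sample_ids) < 4) return(mp_degenerate(enc))
  pat <- enc$pat_masks
  w <- enc$pat_weights
  if (exclude_uninformative) {
    keep <- !uninformative_patterns(pat)
    pat <- pat[, keep, drop = FALSE]
    w <- w[keep]
    if (ncol(pat) == 0) { pat <- enc$pat_masks[, 1, drop = FALSE] * 0L + 31L; w <- 0L }
  }
  res <- .cpp_mp_search(storage.mode_int(pat), as.integer(w),
                        as.integer(addition_replicates), as.integer(maxtrees),
                        as.integer(seed))
  structure(list(best_length = res$best_length,
                 trees = engine_trees(res$newicks, enc$sample_ids),
                 search_meta = list(addition_replicates = addition_replicates,
                                    maxtrees = maxtrees, seed = seed,
                                    degenerate = FALSE)),
            class = "parsimony_result")
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates every unrooted binary topology (sequential-addition
#' enumeration) and returns the global optimum with all optimal
#' topologies. Refuses more than 9 taxa (135,135 topologies).
#'
#' @inheritParams mp_heuristic_search
#' @export
mp_exhaustive <- function(data, maxtrees = 1000) {
  enc <- enc_of(data)
  n <- length(enc$sample_ids)
  if (n < 4) return(mp_degenerate(enc))
  if (n > 9) stop("exhaustive search refused for ", n, " taxa (cap 9)")
  res <- .cpp_mp_exhaustive(storage.mode_int(enc$pat_masks),
                            as.integer(enc$pat_weights), as.integer(maxtrees))
  structure(list(best_length = res$best_length,
                 trees = engine_trees(res$newicks, enc$sample_ids),
                 search_meta = list(exhaustive = TRUE)),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("<parsimony_result> best length ", x$best_length, ", ",
      length(x$trees), " tree(s) retained\n", sep = "")
  invisible(x)
}

# one capped-NNI improvement pass from a given binary start tree
# (the reduced search used for bootstrap replicates)
nni_improve_masks <- function(tree, masks, weights, sample_ids,
                              sweeps = 1, seed = 1L) {
  tree <- ape::unroot(tree)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  ord <- match(tree$tip.label, sample_ids)
  pat <- masks[ord, , drop = FALSE]
  # relabel tips to 1..n in engine order
  tree$tip.label <- paste0("t", seq_along(tree$tip.label))
  tree$edge.length <- NULL
  res <- .cpp_nni_improve(tree$edge, length(tree$tip.label),
                          storage.mode_int(pat), as.integer(weights),
                          as.integer(sweeps), as.integer(seed))
  out <- engine_trees(res$newick, sample_ids[ord])
  out[[1]]
}

nni_improve_tree <- function(tree, enc, sweeps = 1, seed = 1L) {
  nni_improve_masks(tree, enc$pat_masks, enc$pat_weights, enc$sample_ids,
                    sweeps = sweeps, seed = seed)
}
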