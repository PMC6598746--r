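# Tree-comparison machinery: Robinson-Foulds distance, identification of
# taxa that cannot be reconciled between two gene trees (minimal-removal
# agreement search with soft-polytomy semantics), and tanglegram leaf
# ordering by barycenter crossing reduction.

check_same_leaves <- function(a, b) {
  la <- a$tip.label; lb <- b$tip.label
  if (!setequal(la, lb)) {
    stop("leaf sets differ; only in first: ",
         paste(setdiff(la, lb), collapse = ","), "; only in second: ",
         paste(setdiff(lb, la), collapse = ","))
  }
}

# non-trivial bipartitions as logical membership vectors over sort(labels),
# normalised so the side NOT containing the first label is stored
tree_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) next
    side <- labs %in% below[[ch]]
    k <- sum(side)
    if (k < 2 || k > n - 2) next
    if (side[1]) side <- !side
    out[[length(out) + 1]] <- side
  }
  # deduplicate (polytomies can never produce duplicates, but be safe)
  if (length(out)) out <- out[!duplicated(vapply(out, paste, "", collapse = ""))]
  attr(out, "labels") <- labs
  out
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of non-trivial bipartitions; polytomies
#' allowed; leaf sets must match.
#'
#' @param tree_a,tree_b `phylo` objects on identical leaf sets.
#' @return integer distance.
#' @export
rf_distance <- function(tree_a, tree_b) {
  check_same_leaves(tree_a, tree_b)
  if (length(tree_a$tip.label) < 4) return(0L)
  as.integer(suppressMessages(suppressWarnings(
    phangorn::RF.dist(ape::unroot(tree_a), ape::unroot(tree_b),
                      check.labels = TRUE))))
}

splits_incompatible <- function(s1, s2) {
  # splits over identical label order; incompatible iff all four
  # intersections are non-empty
  any(s1 & s2) && any(s1 & !s2) && any(!s1 & s2) && any(!s1 & !s2)
}

# number of incompatible split pairs between two trees (0 iff the trees are
# compatible, i.e. some common refinement exists: soft-polytomy semantics)
conflict_score <- function(tree_a, tree_b) {
  sa <- tree_splits(tree_a)
  sb <- tree_splits(tree_b)
  if (!length(sa) || !length(sb)) return(0L)
  n <- 0L
  for (x in sa) for (y in sb) if (splits_incompatible(x, y)) n <- n + 1L
  n
}

restricted_pair <- function(tree_a, tree_b, removed) {
  keep <- setdiff(tree_a$tip.label, removed)
  if (length(keep) < 4) return(NULL)
  list(a = ape::keep.tip(tree_a, keep), b = ape::keep.tip(tree_b, keep))
}

pair_conflict <- function(tree_a, tree_b, removed) {
  rp <- restricted_pair(tree_a, tree_b, removed)
  if (is.null(rp)) return(0L)
  conflict_score(rp$a, rp$b)
}

#' Identify the taxa that cannot be reconciled between two trees
#'
#' Searches for the smallest set of leaves whose removal makes the two
#' trees compatible (a polytomy is treated as compatible with any
#' resolution of it). Subsets up to `min(max_remove, exhaustive_cap)` are
#' searched exhaustively in lexicographic order; beyond the cap a greedy
#' round removes the leaf with the highest conflict participation. When no
#' set within `max_remove` reconciles the trees, the best achieved set is
#' reported with `agreement = FALSE`.
#'
#' @param tree_a,tree_b `phylo` objects on identical leaf sets.
#' @param max_remove largest removal set considered.
#' @param exhaustive_cap subset size up to which the search is exhaustive.
#' @return object of class `taxon_conflict_report`: `removed_taxa`,
#'   `residual_conflict`, `residual_rf`, `agreement`, `method`.
#' @export
incongruent_taxa <- function(tree_a, tree_b, max_remove = 3,
                             exhaustive_cap = 3) {
  check_same_leaves(tree_a, tree_b)
  stopifnot(max_remove >= 1)
  labs <- sort(tree_a$tip.label)
  report <- function(removed, method) {
    rp <- restricted_pair(tree_a, tree_b, removed)
    rf <- if (is.null(rp)) 0L else rf_distance(rp$a, rp$b)
    cf <- pair_conflict(tree_a, tree_b, removed)
    structure(list(removed_taxa = removed, residual_conflict = cf,
                   residual_rf = rf, agreement = cf == 0L, method = method),
              class = "taxon_conflict_report")
  }
  if (pair_conflict(tree_a, tree_b, character(0)) == 0L) {
    return(report(character(0), "none_needed"))
  }
  for (size in seq_len(min(max_remove, exhaustive_cap))) {
    subsets <- combn(labs, size, simplify = FALSE)
    for (s in subsets) {
      if (pair_conflict(tree_a, tree_b, s) == 0L) {
        return(report(s, sprintf("exhaustive_size_%d", size)))
      }
    }
  }
  # greedy continuation
  removed <- character(0)
  best <- report(removed, "greedy_partial")
  while (length(removed) < max_remove) {
    remaining <- setdiff(labs, removed)
    scores <- vapply(remaining, function(l) {
      pair_conflict(tree_a, tree_b, c(removed, l))
    }, numeric(1))
    pick <- remaining[which.min(scores)]   # ties: lexicographic (sorted labs)
    removed <- c(removed, pick)
    cand <- report(removed, "greedy")
    if (cand$residual_conflict < best$residual_conflict ||
        length(best$removed_taxa) == 0) best <- cand
    if (cand$residual_conflict == 0L) return(cand)
  }
  best
}

#' @export
print.taxon_conflict_report <- function(x, ...) {
  cat("<taxon_conflict_report> removed: ",
      if (length(x$removed_taxa)) paste(x$removed_taxa, collapse = ", ")
      else "(none)",
      "; residual conflict ", x$residual_conflict,
      "; residual RF ", x$residual_rf,
      if (!x$agreement) " [agreement NOT reached]" else "", "\n", sep = "")
  invisible(x)
}

# plotting order of leaves (cladewise traversal)
leaf_order <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree$tip.label[tree$edge[tree$edge[, 2] <= length(tree$tip.label), 2]]
}

count_crossings <- function(order_a, order_b) {
  pos <- match(order_a, order_b)
  n <- 0L
  for (i in seq_along(pos)) {
    n <- n + sum(pos[seq_len(i - 1)] > pos[i])
  }
  n
}

# reorder children of every internal node of `tree` by the barycenter of
# their leaves' positions in `ref_order`; returns the new leaf order
barycenter_pass <- function(tree, ref_order) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  pos <- match(tree$tip.label, ref_order)
  rec <- function(v) {
    if (v <= ntip) return(list(leaves = tree$tip.label[v], bary = pos[v]))
    parts <- lapply(kids[[as.character(v)]], rec)
    ord <- order(vapply(parts, `[[`, 0, "bary"))
    leaves <- unlist(lapply(parts[ord], `[[`, "leaves"))
    list(leaves = leaves, bary = mean(pos[match(leaves, tree$tip.label)]))
  }
  rec(ntip + 1L)$leaves
}

#' Tanglegram leaf orderings with crossing reduction
#'
#' Iterated barycenter rotations of both trees' internal nodes, keeping the
#' ordering pair with the fewest line crossings.
#'
#' @param tree_a,tree_b `phylo` objects on identical leaf sets.
#' @param iterations alternating barycenter passes.
#' @return list with `order_a`, `order_b`, `crossings`.
#' @export
tanglegram_order <- function(tree_a, tree_b, iterations = 4) {
  check_same_leaves(tree_a, tree_b)
  oa <- leaf_order(tree_a)
  ob <- leaf_order(tree_b)
  best <- list(order_a = oa, order_b = ob, crossings = count_crossings(oa, ob))
  for (i in seq_len(iterations)) {
    ob <- barycenter_pass(tree_b, oa)
    oa <- barycenter_pass(tree_a, ob)
    cr <- count_crossings(oa, ob)
    if (cr < best$crossings) best <- list(order_a = oa, order_b = ob,
                                          crossings = cr)
    if (cr == 0) break
  }
  best
}

#' Serialize a taxon-conflict report to JSON
#' @param report a `taxon_conflict_report` (or named list of them).
#' @param path output file.
#' @export
write_conflict_json <- function(report, path) {
  if (inherits(report, "taxon_conflict_report")) report <- list(report)
  jsonlite::write_json(
    lapply(report, function(r) list(removed_taxa = r$removed_taxa,
                                    residual_conflict = r$residual_conflict,
                                    residual_rf = r$residual_rf,
                                    agreement = r$agreement,
                                    method = r$method)),
    path, auto_unbox = TRUE)
  invisible(path)
}
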