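# Incongruence length difference (partition homogeneity) test:
# permutation null over random reassignment of columns to partitions,
# two-stage replicate gating, and pairwise post-hoc variants.
#
# Significance direction: the defined partitions are MORE parsimonious
# (lower summed MP length) than random reassignments, so the p-value counts
# null sums <= the observed sum, with the add-one Monte-Carlo correction.

#' Search parameters for the parsimony engine inside the ILD test
#'
#' @param addition_replicates random-addition starts per search.
#' @param maxtrees trees stored at any one time.
#' @param exclude_uninformative drop parsimony-uninformative sites.
#' @export
mp_search_params <- function(addition_replicates = 2, maxtrees = 1000,
                             exclude_uninformative = FALSE) {
  list(addition_replicates = addition_replicates, maxtrees = maxtrees,
       exclude_uninformative = exclude_uninformative)
}

# MP length of the sub-alignment made of the given supermatrix columns.
# Column site patterns are invariant under reassignment, so the supermatrix
# is pattern-compressed once and each (permuted) partition is just a
# multiset of pattern ids.
search_length_cols <- function(enc, cols, params, seed) {
  P <- ncol(enc$pat_masks)
  tab <- tabulate(enc$pat_index[cols], nbins = P)
  present <- tab > 0L
  if (params$exclude_uninformative) {
    if (is.null(enc$pat_uninf)) enc$pat_uninf <- uninformative_patterns(enc$pat_masks)
    present <- present & !enc$pat_uninf
    if (!any(present)) return(0)
  }
  n <- sum(present)
  if (length(enc$sample_ids) < 4) {
    aln <- locus_alignment(decode_five_state(enc)[, cols, drop = FALSE], "sub")
    return(mp_degenerate(encode_five_state(aln))$best_length)
  }
  res <- .cpp_mp_search(storage.mode_int(enc$pat_masks[, present, drop = FALSE]),
                        as.integer(tab[present]),
                        as.integer(params$addition_replicates), 1L,
                        as.integer(seed))
  res$best_length
}

#' Observed ILD statistic
#'
#' Sum over partitions of the heuristic MP tree length, every partition
#' searched with identical settings.
#'
#' @param pa a `partitioned_alignment` with >= 2 partitions.
#' @param params [mp_search_params].
#' @param seed integer seed.
#' @return integer summed length.
#' @export
ild_statistic <- function(pa, params = mp_search_params(), seed = 1L) {
  if (nrow(pa$partitions) < 2) stop("need >= 2 partitions")
  lens <- pa$partitions$end - pa$partitions$start + 1L
  if (any(lens < 1)) stop("empty partition")
  enc <- encode_five_state(pa$supermatrix)
  sum(vapply(seq_len(nrow(pa$partitions)), function(i) {
    cols <- pa$partitions$start[i]:pa$partitions$end[i]
    search_length_cols(enc, cols, params, derive_seed(seed, i))
  }, numeric(1)))
}

# statistic on a column reassignment given as a permutation of 1..ncol
reassigned_statistic <- function(enc, sizes, perm, params, seed) {
  off <- 0L
  tot <- 0
  for (i in seq_along(sizes)) {
    cols <- perm[(off + 1L):(off + sizes[i])]
    off <- off + sizes[i]
    tot <- tot + search_length_cols(enc, cols, params, derive_seed(seed, i))
  }
  tot
}

#' Incongruence length difference (partition homogeneity) test
#'
#' Each replicate reassigns the supermatrix columns uniformly at random to
#' partitions (preserving partition sizes, jointly across all partitions)
#' and recomputes the summed MP length with identical search settings.
#' `p = (1 + #\{null sums <= observed\}) / (1 + replicates)`.
#'
#' @param pa a `partitioned_alignment` with >= 2 partitions.
#' @param replicates number of permutation replicates (>= 1).
#' @param maxtrees MaxTrees cap for every search.
#' @param seed integer seed; results are deterministic given it.
#' @param addition_replicates random-addition starts per search.
#' @param exclude_uninformative drop parsimony-uninformative sites.
#' @return object of class `ild_result`.
#' @export
ild_test <- function(pa, replicates = 100, maxtrees = 1000, seed = 1L,
                     addition_replicates = 2, exclude_uninformative = FALSE) {
  stopifnot(replicates >= 1)
  params <- mp_search_params(addition_replicates, maxtrees, exclude_uninformative)
  enc <- encode_five_state(pa$supermatrix)
  sizes <- pa$partitions$end - pa$partitions$start + 1L
  observed <- sum(vapply(seq_len(nrow(pa$partitions)), function(i) {
    cols <- pa$partitions$start[i]:pa$partitions$end[i]
    search_length_cols(enc, cols, params, derive_seed(derive_seed(seed, 0L), i))
  }, numeric(1)))
  ncols <- ncol(pa$supermatrix$matrix)
  set.seed(derive_seed(seed, 1L))
  null_sums <- vapply(seq_len(replicates), function(r) {
    perm <- sample.int(ncols)
    reassigned_statistic(enc, sizes, perm, params, derive_seed(seed, 1000L + r))
  }, numeric(1))
  p <- (1 + sum(null_sums <= observed)) / (1 + replicates)
  structure(list(partitions = pa$partitions,
                 observed_sum = observed, null_sums = null_sums,
                 replicates = replicates, maxtrees = maxtrees,
                 seed = seed, p_value = p),
            class = "ild_result")
}

#' @export
print.ild_result <- function(x, ...) {
  cat("<ild_result> partitions: ", paste(x$partitions$locus, collapse = " | "),
      "\n  observed sum ", x$observed_sum, "; R = ", x$replicates,
      "; MaxTrees = ", x$maxtrees, "; p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Two-stage gated ILD test
#'
#' Stage 1 runs a cheap screen; when its p-value falls below the gate, a
#' confirmatory stage with more replicates and a larger MaxTrees is run and
#' returned.
#'
#' @param pa a `partitioned_alignment`.
#' @param stage1_replicates,stage1_maxtrees screening stage (defaults 100 / 1000).
#' @param stage2_replicates,stage2_maxtrees confirmatory stage (defaults 1000 / 10000).
#' @param gate p-value threshold below which stage 2 runs (default 0.2).
#' @param seed integer seed.
#' @param addition_replicates random-addition starts per search.
#' @return the returned `ild_result` carries `$stage` (1 or 2) and
#'   `$stage1` (the screening result) when stage 2 ran.
#' @export
ild_gated <- function(pa, stage1_replicates = 100, stage1_maxtrees = 1000,
                      stage2_replicates = 1000, stage2_maxtrees = 10000,
                      gate = 0.2, seed = 1L, addition_replicates = 2) {
  s1 <- ild_test(pa, replicates = stage1_replicates, maxtrees = stage1_maxtrees,
                 seed = derive_seed(seed, 11L),
                 addition_replicates = addition_replicates)
  if (s1$p_value < gate) {
    s2 <- ild_test(pa, replicates = stage2_replicates, maxtrees = stage2_maxtrees,
                   seed = derive_seed(seed, 22L),
                   addition_replicates = addition_replicates)
    s2$stage <- 2L
    s2$stage1 <- s1
    s2
  } else {
    s1$stage <- 1L
    s1
  }
}

#' Pairwise post-hoc ILD tests for a three-locus dataset
#'
#' Tests each pair of loci separately and flags significance at a
#' Bonferroni-corrected level (three tests per dataset).
#'
#' @param alignments named list of exactly three [locus_alignment]s.
#' @param replicates permutation replicates per pair.
#' @param maxtrees MaxTrees cap.
#' @param alpha Bonferroni-corrected per-test level (default 0.017, i.e.
#'   0.05/3 rounded).
#' @param seed integer seed.
#' @param addition_replicates random-addition starts per search.
#' @return list of three `ild_result`s (named "A.vs.B") each carrying
#'   `$significant`, plus attribute `alpha`.
#' @export
ild_pairwise <- function(alignments, replicates = 1000, maxtrees = 10000,
                         alpha = 0.017, seed = 1L, addition_replicates = 2) {
  if (length(alignments) != 3) stop("pairwise ILD expects exactly three loci")
  nm <- vapply(alignments, function(a) a$locus_name, character(1))
  pairs <- combn(3, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    pa <- concatenate_partitions(alignments[c(i, j)])
    r <- ild_test(pa, replicates = replicates, maxtrees = maxtrees,
                  seed = derive_seed(seed, 100L + k),
                  addition_replicates = addition_replicates)
    r$significant <- r$p_value < alpha
    r
  })
  names(out) <- apply(pairs, 2, function(ij) paste(nm[ij], collapse = ".vs."))
  attr(out, "alpha") <- alpha
  out
}

#' Serialize ILD results to TSV rows
#' @param results list of `ild_result`s (named).
#' @param path output TSV; one row per test.
#' @param dataset dataset label for the first column.
#' @export
write_ild_tsv <- function(results, path, dataset = "dataset") {
  if (inherits(results, "ild_result")) results <- list(test = results)
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(dataset = dataset, test = nm,
               partitions = paste(r$partitions$locus, collapse = "+"),
               replicates = r$replicates, maxtrees = r$maxtrees,
               p_value = r$p_value,
               significant = isTRUE(r$significant),
               stringsAsFactors = FALSE)
  }))
  write.table_tsv(rows, path)
  invisible(path)
}

write.table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
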