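# Shared fixture builders: random alignments, clade-structured loci
# simulated on known trees, and small independent oracles.

rand_aln <- function(n, L, gaps = TRUE, locus = "x") {
  alpha <- c("A", "C", "G", "T", if (gaps) "-")
  m <- matrix(sample(alpha, n * L, replace = TRUE), n, L)
  rownames(m) <- paste0("s", seq_len(n))
  locus_alignment(m, locus)
}

# a locus whose informative sites each support one clade of a fixed tree:
# members of the clade share a derived base, everyone else keeps "A"
make_clade_locus <- function(ids, clades, sites_per_clade, L,
                             n_singletons = 0, locus = "loc") {
  m <- matrix("A", length(ids), L, dimnames = list(ids, NULL))
  col <- 1L
  for (cl in clades) {
    for (k in seq_len(sites_per_clade)) {
      m[cl, col] <- sample(c("C", "G", "T"), 1)
      col <- col + 1L
    }
  }
  if (n_singletons > 0) {
    for (k in seq_len(n_singletons)) {
      m[sample(length(ids), 1), col] <- sample(c("C", "G", "T"), 1)
      col <- col + 1L
    }
  }
  stopifnot(col <= L + 1)
  # shuffle columns so informative sites are scattered
  locus_alignment(m[, sample(L), drop = FALSE], locus)
}

ten_ids <- paste0("t", 1:10)

# clades of a balanced 10-taxon tree: ((t1,t2),(t3,t4),t5) vs mirror
clades_main <- list(c("t1", "t2"), c("t3", "t4"), c("t1", "t2", "t3", "t4"),
                    c("t1", "t2", "t3", "t4", "t5"),
                    c("t6", "t7"), c("t8", "t9"), c("t6", "t7", "t8", "t9"))
# a maximally conflicting grouping: odd vs even interleaving
clades_conflict <- list(c("t1", "t3"), c("t5", "t7"), c("t1", "t3", "t5", "t7"),
                        c("t1", "t3", "t5", "t7", "t9"),
                        c("t2", "t4"), c("t6", "t8"), c("t2", "t4", "t6", "t8"))

congruent_pair <- function(L = 120, sites_per_clade = 2, n_singletons = 3) {
  a <- make_clade_locus(ten_ids, clades_main, sites_per_clade, L,
                        n_singletons, "locA")
  b <- make_clade_locus(ten_ids, clades_main, sites_per_clade, L,
                        n_singletons, "locB")
  concatenate_partitions(list(a, b))
}

conflicting_pair <- function(L = 120, sites_per_clade = NULL) {
  # 15 informative sites per locus spread over the clades
  a <- make_clade_locus(ten_ids, clades_main, 2, L, 1, "locA")
  extra <- make_clade_locus(ten_ids, clades_main[1:1], 1, 10, 0, "pad")
  b <- make_clade_locus(ten_ids, clades_conflict, 2, L, 1, "locB")
  concatenate_partitions(list(a, b))
}

# independent RF oracle: symmetric difference of non-trivial bipartitions
# enumerated via ape::prop.part on rooted copies
rf_oracle <- function(a, b) {
  split_keys <- function(tr) {
    tr <- ape::unroot(tr)
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    n <- length(labs)
    keys <- vapply(pp, function(idx) {
      side <- sort(labs[idx])
      if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
      other <- sort(setdiff(labs, side))
      paste(min(paste(side, collapse = ","), paste(other, collapse = ",")),
            max(paste(side, collapse = ","), paste(other, collapse = ",")),
            sep = "~")
    }, character(1))
    unique(keys[!is.na(keys)])
  }
  ka <- split_keys(a)
  kb <- split_keys(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

# brute-force Jukes-Cantor likelihood of a 4-taxon unrooted tree by direct
# summation over the two internal nodes' states
jc_lik_4taxa_oracle <- function(states, t_ext, t_int) {
  # states: named A/C/G/T for tips s1..s4; topology ((s1,s2),(s3,s4)) with
  # internal nodes u (next to s1,s2) and v (next to s3,s4);
  # all four external branches t_ext, internal branch t_int
  p_same <- function(t) 0.25 + 0.75 * exp(-4 * t / 3)
  p_diff <- function(t) 0.25 - 0.25 * exp(-4 * t / 3)
  pt <- function(x, y, t) if (x == y) p_same(t) else p_diff(t)
  bases <- c("A", "C", "G", "T")
  tot <- 0
  for (u in bases) for (v in bases) {
    tot <- tot + 0.25 *
      pt(u, states[1], t_ext) * pt(u, states[2], t_ext) *
      pt(u, v, t_int) *
      pt(v, states[3], t_ext) * pt(v, states[4], t_ext)
  }
  tot
}

# canonical topology key from the package-independent split oracle
topo_key <- function(tr) {
  split_keys <- function(tr) {
    pp <- ape::prop.part(ape::unroot(tr))
    labs <- attr(pp, "labels")
    n <- length(labs)
    keys <- vapply(pp, function(idx) {
      side <- sort(labs[idx])
      if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
      other <- sort(setdiff(labs, side))
      paste(min(paste(side, collapse = ","), paste(other, collapse = ",")),
            max(paste(side, collapse = ","), paste(other, collapse = ",")),
            sep = "~")
    }, character(1))
    sort(unique(keys[!is.na(keys)]))
  }
  paste(split_keys(tr), collapse = " | ")
}
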