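# Fitch/Hartigan scoring and the heuristic/exhaustive MP searches, checked
# against independent oracles (phangorn's Fitch engine and full topology
# enumeration).

test_that("tree length has the closed forms for trivial cases", {
  ids <- paste0("s", 1:4)
  m <- matrix("A", 4, 6, dimnames = list(ids, NULL))
  aln <- locus_alignment(m, "x")
  tr <- ape::read.tree(text = "((s1,s2),(s3,s4));")
  expect_equal(fitch_length(tr, aln), 0)

  # 2-leaf tree: length = number of differing columns
  m2 <- matrix(c("A", "C", "G", "T", "-",
                 "A", "C", "T", "T", "A"), 2, 5, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  tr2 <- ape::read.tree(text = "(a,b);")
  expect_equal(fitch_length(tr2, locus_alignment(m2, "x")), 2)

  expect_error(fitch_length(ape::read.tree(text = "(a,zzz);"),
                            locus_alignment(m2, "x")), "zzz")
})

test_that("scoring matches phangorn's Fitch engine on random 5-state data", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:9, 1)
    aln <- rand_aln(n, sample(8:30, 1))
    tr <- ape::rtree(n, tip.label = aln$sample_ids, rooted = FALSE)
    dat <- phangorn::phyDat(aln$matrix, type = "USER",
                            levels = c("A", "C", "G", "T", "-"))
    expect_equal(fitch_length(tr, aln), as.integer(phangorn::fitch(tr, dat)))
  }
})

test_that("length is invariant to rerooting and leaf-order permutation", {
  set.seed(12)
  for (rep in 1:10) {
    aln <- rand_aln(7, 20)
    tr <- ape::rtree(7, tip.label = aln$sample_ids, rooted = FALSE)
    len <- fitch_length(tr, aln)
    rerooted <- ape::root(tr, outgroup = sample(aln$sample_ids, 1),
                          resolve.root = TRUE)
    expect_equal(fitch_length(rerooted, aln), len)
    perm <- sample(aln$sample_ids)
    aln2 <- locus_alignment(aln$matrix[perm, , drop = FALSE], "x")
    expect_equal(fitch_length(tr, aln2), len)
  }
})

test_that("invariant columns add nothing; duplicating all columns doubles length", {
  set.seed(13)
  aln <- rand_aln(6, 15)
  tr <- ape::rtree(6, tip.label = aln$sample_ids, rooted = FALSE)
  len <- fitch_length(tr, aln)
  plus_inv <- locus_alignment(cbind(aln$matrix,
                                    matrix("G", 6, 4)), "x")
  expect_equal(fitch_length(tr, plus_inv), len)
  doubled <- locus_alignment(cbind(aln$matrix, aln$matrix), "x")
  expect_equal(fitch_length(tr, doubled), 2 * len)
})

test_that("polytomies are scored exactly (single-site logic on 4 taxa)", {
  ids <- paste0("s", 1:4)
  # one informative column supporting s1s2|s3s4
  m <- matrix(c("C", "C", "A", "A"), 4, 1, dimnames = list(ids, NULL))
  aln <- locus_alignment(m, "x")
  expect_equal(fitch_length(ape::read.tree(text = "((s1,s2),(s3,s4));"), aln), 1)
  expect_equal(fitch_length(ape::read.tree(text = "((s1,s3),(s2,s4));"), aln), 2)
  expect_equal(fitch_length(ape::read.tree(text = "((s1,s4),(s2,s3));"), aln), 2)
  # hard-polytomy star: both leaf pairs must change from the root state
  expect_equal(fitch_length(ape::read.tree(text = "(s1,s2,s3,s4);"), aln), 2)
})

test_that("exhaustive search finds the global optimum and all optimal trees", {
  ids <- paste0("s", 1:4)
  m <- matrix(c("C", "C", "A", "A"), 4, 1, dimnames = list(ids, NULL))
  res <- mp_exhaustive(locus_alignment(m, "x"))
  expect_equal(res$best_length, 1)
  expect_length(res$trees, 1)
  expect_equal(topo_key(res$trees[[1]]),
               topo_key(ape::read.tree(text = "((s1,s2),(s3,s4));")))

  # invariant alignment: all topologies tie at 0
  inv <- locus_alignment(matrix("T", 5, 8,
                                dimnames = list(paste0("s", 1:5), NULL)), "x")
  res_inv <- mp_exhaustive(inv)
  expect_equal(res_inv$best_length, 0)
  expect_length(res_inv$trees, 15)

  expect_error(mp_exhaustive(rand_aln(10, 10)), "cap")
})

test_that("exhaustive minimum matches enumeration over phangorn-scored topologies", {
  set.seed(14)
  for (rep in 1:6) {
    aln <- rand_aln(7, sample(10:25, 1))
    dat <- phangorn::phyDat(aln$matrix, type = "USER",
                            levels = c("A", "C", "G", "T", "-"))
    all_tr <- phangorn::allTrees(7, rooted = FALSE, tip.label = aln$sample_ids)
    ref <- min(vapply(all_tr, function(t) phangorn::fitch(t, dat), numeric(1)))
    expect_equal(mp_exhaustive(aln)$best_length, as.integer(ref))
  }
})

test_that("heuristic search equals the exhaustive optimum on small instances", {
  set.seed(15)
  for (rep in 1:15) {
    aln <- rand_aln(sample(5:8, 1), sample(10:30, 1))
    h <- mp_heuristic_search(aln, addition_replicates = 20, seed = rep)
    e <- mp_exhaustive(aln)
    expect_equal(h$best_length, e$best_length)
    # every retained tree scores exactly best_length
    for (tr in h$trees) expect_equal(fitch_length(tr, aln), h$best_length)
  }
})

test_that("heuristic search recovers a strongly supported generating topology", {
  set.seed(16)
  ids <- paste0("s", 1:8)
  clades <- list(c("s1", "s2"), c("s3", "s4"), c("s1", "s2", "s3", "s4"),
                 c("s5", "s6"), c("s7", "s8"))
  aln <- make_clade_locus(ids, clades, 30, 160, 0)
  truth <- ape::read.tree(text = "(((s1,s2),(s3,s4)),((s5,s6),(s7,s8)));")
  res <- mp_heuristic_search(aln, addition_replicates = 5, seed = 3)
  expect_equal(topo_key(res$trees[[1]]), topo_key(truth))
})

test_that("maxtrees caps retention without changing best_length", {
  inv <- locus_alignment(matrix("T", 6, 5,
                                dimnames = list(paste0("s", 1:6), NULL)), "x")
  res1 <- mp_heuristic_search(inv, addition_replicates = 3, maxtrees = 1, seed = 1)
  expect_length(res1$trees, 1)
  res5 <- mp_heuristic_search(inv, addition_replicates = 3, maxtrees = 5, seed = 1)
  expect_equal(res1$best_length, res5$best_length)
  expect_lte(length(res5$trees), 5)
})

test_that("fewer than four samples is a flagged degenerate success", {
  m <- matrix(c("A", "C", "A", "A", "G", "A"), 3, 2,
              dimnames = list(c("a", "b", "c"), NULL))
  res <- mp_heuristic_search(locus_alignment(m, "x"))
  expect_true(res$search_meta$degenerate)
  expect_length(res$trees, 1)
  expect_equal(res$best_length,
               fitch_length(res$trees[[1]], locus_alignment(m, "x")))
})

test_that("search is deterministic given the seed", {
  set.seed(17)
  aln <- rand_aln(9, 40)
  a <- mp_heuristic_search(aln, addition_replicates = 4, seed = 42)
  b <- mp_heuristic_search(aln, addition_replicates = 4, seed = 42)
  expect_equal(a$best_length, b$best_length)
  expect_identical(ape::write.tree(a$trees), ape::write.tree(b$trees))
})
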