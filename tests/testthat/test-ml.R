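# NJ starting trees, AICc model selection, per-site log-likelihoods,
# ML search, bootstrap collapse, and equiprobable random trees.

test_that("NJ handles the trivial and degenerate cases", {
  set.seed(31)
  aln3 <- rand_aln(3, 20, gaps = FALSE)
  tr <- build_nj_tree(aln3)
  expect_equal(sort(tr$tip.label), sort(aln3$sample_ids))

  ident <- locus_alignment(matrix("A", 4, 10,
                                  dimnames = list(paste0("s", 1:4), NULL)), "x")
  star <- build_nj_tree(ident)
  expect_true(isTRUE(attr(star, "star")))
  expect_equal(star$Nnode, 1)
  expect_true(all(star$edge.length == 0))
})

test_that("NJ recovers the generating topology from clean clade signal", {
  set.seed(32)
  ids <- paste0("s", 1:6)
  clades <- list(c("s1", "s2"), c("s1", "s2", "s3"), c("s4", "s5"))
  aln <- make_clade_locus(ids, clades, 25, 120, 0)
  truth <- ape::read.tree(text = "(((s1,s2),s3),((s4,s5),s6));")
  expect_equal(rf_oracle(build_nj_tree(aln), truth), 0)
})

test_that("model selection prefers simple models for JC-like data and penalises tiny alignments", {
  set.seed(33)
  ds <- simulate_multilocus_dataset(sim_params(n_hybrids = 0), seed = 5)
  spec <- select_model(ds$alignments$its2)
  expect_true(spec$model %in% c("JC", "K80"))
  expect_false(spec$model == "GTR" && spec$gamma)

  tiny <- rand_aln(5, 10, gaps = FALSE)
  expect_warning(sp <- select_model(tiny), "short|AICc")
  expect_equal(sp$model, "JC")
})

test_that("strong transition bias selects a kappa-bearing model over JC", {
  set.seed(34)
  # two clades separated by many pure transitions (A<->G)
  ids <- paste0("s", 1:8)
  m <- matrix("A", 8, 300, dimnames = list(ids, NULL))
  base <- sample(c("A", "C", "G", "T"), 300, TRUE)
  for (i in 1:8) m[i, ] <- base
  ts_sites <- sample(300, 80)
  tv_sites <- sample(setdiff(1:300, ts_sites), 4)
  flip_ts <- c(A = "G", G = "A", C = "T", T = "C")
  flip_tv <- c(A = "C", G = "T", C = "A", T = "G")
  for (i in 5:8) {
    m[i, ts_sites] <- flip_ts[m[i, ts_sites]]
    m[i, tv_sites] <- flip_tv[m[i, tv_sites]]
  }
  spec <- select_model(locus_alignment(m, "x"))
  expect_true(spec$model %in% c("K80", "HKY", "GTR"))
})

test_that("per-site log-likelihoods have the closed form at zero branch lengths", {
  ids <- paste0("s", 1:4)
  m <- matrix("C", 4, 1, dimnames = list(ids, NULL))
  aln <- locus_alignment(m, "x")
  star <- ape::read.tree(text = "(s1,s2,s3,s4);")
  star$edge.length <- rep(0, nrow(star$edge))
  spec <- structure(list(model = "JC", gamma = FALSE, shape = NULL,
                         bf = rep(0.25, 4), Q = rep(1, 6), k = 1L),
                    class = "model_spec")
  sl <- site_log_likelihoods(list(star), aln, spec)
  # identical states on a zero-length tree: ll = log(1/4)
  expect_equal(unname(sl$matrix[1, 1]), log(0.25), tolerance = 1e-6)
})

test_that("duplicating a column duplicates its log-likelihood entry", {
  set.seed(35)
  aln <- rand_aln(5, 20, gaps = FALSE)
  spec <- structure(list(model = "JC", gamma = FALSE, shape = NULL,
                         bf = rep(0.25, 4), Q = rep(1, 6), k = 1L),
                    class = "model_spec")
  tr <- build_nj_tree(aln)
  sl <- site_log_likelihoods(list(tr), aln, spec)
  doubled <- locus_alignment(cbind(aln$matrix, aln$matrix[, 1, drop = FALSE]), "x")
  sl2 <- site_log_likelihoods(list(tr), doubled, spec)
  expect_equal(sl2$matrix[1, 21], sl2$matrix[1, 1], tolerance = 1e-9)
  # row sums reproduce the totals
  expect_equal(unname(rowSums(sl$matrix)), unname(sl$total), tolerance = 1e-8)
})

test_that("4-taxon JC likelihood matches brute-force summation over internal states", {
  ids <- paste0("s", 1:4)
  t_ext <- 0.07
  t_int <- 0.11
  states_list <- list(c("A", "A", "C", "C"), c("A", "C", "G", "T"),
                      c("T", "T", "T", "T"), c("G", "A", "G", "A"))
  m <- do.call(cbind, states_list)
  rownames(m) <- ids
  aln <- locus_alignment(m, "x")
  tr <- ape::read.tree(text = "((s1:0.07,s2:0.07):0.11,(s3:0.07,s4:0.07):0);")
  # ape stores the unrooted 4-taxon tree with the internal branch split at
  # the root; write explicitly with one internal edge of length t_int
  tr <- ape::unroot(ape::read.tree(
    text = "((s1:0.07,s2:0.07):0.055,(s3:0.07,s4:0.07):0.055);"))
  spec <- structure(list(model = "JC", gamma = FALSE, shape = NULL,
                         bf = rep(0.25, 4), Q = rep(1, 6), k = 1L),
                    class = "model_spec")
  fit <- phyloconflict:::pml_with_spec(tr, phyloconflict:::aln_to_phydat(aln),
                                       spec, opt_edge = FALSE)
  got <- as.numeric(fit$siteLik)[attr(phyloconflict:::aln_to_phydat(aln), "index")]
  want <- vapply(states_list, jc_lik_4taxa_oracle, numeric(1),
                 t_ext = t_ext, t_int = t_int)
  expect_equal(got, log(want), tolerance = 1e-6)
})

test_that("likelihood is invariant to rerooting under a reversible model", {
  set.seed(36)
  aln <- rand_aln(6, 60, gaps = FALSE)
  spec <- structure(list(model = "JC", gamma = FALSE, shape = NULL,
                         bf = rep(0.25, 4), Q = rep(1, 6), k = 1L),
                    class = "model_spec")
  tr <- build_nj_tree(aln)
  sl1 <- site_log_likelihoods(list(tr), aln, spec)
  rerooted <- ape::root(tr, outgroup = aln$sample_ids[3], resolve.root = TRUE)
  sl2 <- site_log_likelihoods(list(rerooted), aln, spec)
  expect_equal(sl1$total, sl2$total, tolerance = 1e-4)
})

test_that("ML search improves on its NJ start and recovers strong signal", {
  set.seed(37)
  ids <- paste0("s", 1:8)
  clades <- list(c("s1", "s2"), c("s3", "s4"), c("s1", "s2", "s3", "s4"),
                 c("s5", "s6"), c("s7", "s8"))
  aln <- make_clade_locus(ids, clades, 20, 150, 0)
  spec <- select_model(aln)
  ml <- ml_heuristic_search(aln, spec)
  truth <- ape::read.tree(text = "(((s1,s2),(s3,s4)),((s5,s6),(s7,s8)));")
  expect_equal(rf_oracle(ml, truth), 0)
  nj_fit <- phyloconflict:::pml_with_spec(build_nj_tree(aln),
                                          phyloconflict:::aln_to_phydat(aln),
                                          spec)
  expect_gte(attr(ml, "logLik"), nj_fit$logLik - 1e-6)
})

test_that("bootstrap keeps clean edges, collapses noise, honours the threshold boundary", {
  set.seed(38)
  ids <- paste0("s", 1:8)
  clades <- list(c("s1", "s2"), c("s3", "s4"), c("s1", "s2", "s3", "s4"),
                 c("s5", "s6"), c("s7", "s8"))
  clean <- make_clade_locus(ids, clades, 20, 150, 0)
  spec <- select_model(clean)
  bt <- bootstrap_support(clean, spec, replicates = 60, seed = 2)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  truth <- ape::read.tree(text = "(((s1,s2),(s3,s4)),((s5,s6),(s7,s8)));")
  expect_equal(rf_oracle(bt, truth), 0)  # nothing collapsed

  # pure noise: invariant columns + singletons -> near-star tree
  noise <- make_clade_locus(ids, list(), 0, 120, 25)
  specn <- select_model(noise)
  btn <- bootstrap_support(noise, specn, replicates = 60, seed = 3)
  expect_lte(btn$Nnode, 3)

  # threshold above 100 collapses everything into a star
  star <- bootstrap_support(clean, spec, replicates = 20,
                            collapse_threshold = 101, seed = 4)
  expect_equal(star$Nnode, 1)
})

test_that("collapse is monotone in the threshold", {
  set.seed(39)
  tr <- ape::rtree(8, rooted = FALSE)
  tr$node.label <- as.character(c(NA, 90, 60, 40, 20, 75))
  n_resolved <- function(t) t$Nnode
  sizes <- vapply(c(10, 50, 80, 101),
                  function(th) n_resolved(collapse_low_support(tr, th)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("random topologies are uniform over the 3- and 5-label spaces", {
  trees3 <- generate_random_trees(c("a", "b", "c"), 5, seed = 1)
  expect_length(trees3, 5)
  expect_equal(length(unique(vapply(trees3, topo_key, ""))), 1)

  trees <- generate_random_trees(paste0("x", 1:5), 1500, seed = 2)
  expect_length(trees, 1500)
  keys <- vapply(trees, topo_key, "")
  tab <- table(keys)
  expect_equal(length(tab), 15)
  expect_gt(stats::chisq.test(as.numeric(tab))$p.value, 0.001)
})

test_that("random tree generation is deterministic given the seed", {
  a <- generate_random_trees(paste0("x", 1:7), 10, seed = 5)
  b <- generate_random_trees(paste0("x", 1:7), 10, seed = 5)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
})
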