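# RELL resampling, AU and SH tests, and the reciprocal-incongruence rule.

fake_sl <- function(mat) phyloconflict:::as_site_lik(mat)

test_that("RELL proportions split ties and respect dominance", {
  ll <- matrix(rep(c(-1.0, -1.0), each = 50), nrow = 2, byrow = TRUE)
  bp <- rell_resample(fake_sl(ll), B = 500, seed = 1)
  expect_true(all(abs(bp - 0.5) < 1e-12))

  dom <- rbind(rep(-1, 40), rep(-1.2, 40))
  bp2 <- rell_resample(fake_sl(dom), B = 500, seed = 1)
  expect_true(all(bp2[1, ] == 1))
  expect_true(all(bp2[2, ] == 0))
})

test_that("RELL proportions sum to one across trees at every scale", {
  set.seed(41)
  ll <- matrix(rnorm(5 * 80, -2, 0.3), 5, 80)
  bp <- rell_resample(fake_sl(ll), B = 1000, seed = 3)
  expect_equal(unname(colSums(bp)), rep(1, ncol(bp)), tolerance = 1e-12)
})

test_that("RELL is self-consistent between pattern-compressed and plain input", {
  set.seed(42)
  base <- matrix(rnorm(3 * 10, -2, 0.5), 3, 10)
  reps <- sample(1:10, 60, replace = TRUE)
  full <- base[, reps]
  bp_full <- rell_resample(fake_sl(full), scales = 1, B = 4000, seed = 9)
  # large-B reference on the same matrix
  bp_ref <- rell_resample(fake_sl(full), scales = 1, B = 40000, seed = 10)
  se <- sqrt(bp_ref * (1 - bp_ref) / 4000)
  expect_true(all(abs(bp_full - bp_ref) <= 3 * se + 1e-9))
})

test_that("AU p-value has its closed forms at the symmetric and degenerate points", {
  scales <- seq(0.5, 1.4, 0.1)
  flat <- au_pvalue(rep(0.5, 10), scales, 1000)
  expect_equal(flat$au_p, 0.5)
  expect_equal(flat$d, 0, tolerance = 1e-12)
  expect_equal(flat$c, 0, tolerance = 1e-12)

  top <- au_pvalue(rep(1, 10), scales, 1000)
  expect_equal(top$au_p, 1)
  expect_true(top$degenerate)
  bot <- au_pvalue(rep(0, 10), scales, 1000)
  expect_equal(bot$au_p, 0)
  expect_true(bot$degenerate)
  expect_error(au_pvalue(0.4, 1, 100), "usable")
  # a tree that only wins at noisy small scales is still firmly rejected
  noisy <- c(0.04, 0.01, rep(0, 8))
  expect_lt(au_pvalue(noisy, scales, 1000)$au_p, 0.05)
})

test_that("the AU test keeps the best tree and orders it above dominated trees", {
  set.seed(43)
  ll <- rbind(rnorm(200, -2, 0.4))
  ll <- rbind(ll, ll[1, ] - abs(rnorm(200, 0.05, 0.02)))  # site-wise dominated
  res <- au_test(fake_sl(ll), B = 2000, seed = 4)
  expect_equal(res$best, 1)
  expect_gte(res$au_p[1], res$au_p[2])
})

test_that("AU and SH are deterministic given the seed", {
  set.seed(44)
  ll <- matrix(rnorm(4 * 100, -2, 0.5), 4, 100)
  a <- au_test(fake_sl(ll), B = 1000, seed = 7)
  b <- au_test(fake_sl(ll), B = 1000, seed = 7)
  expect_identical(a$bp, b$bp)
  expect_identical(a$au_p, b$au_p)
  expect_identical(sh_test(fake_sl(ll), B = 1000, seed = 7),
                   sh_test(fake_sl(ll), B = 1000, seed = 7))
})

test_that("SH gives the best tree p = 1 and is conservative relative to AU", {
  set.seed(45)
  ll <- matrix(rnorm(3 * 150, -2, 0.5), 3, 150)
  p_sh <- sh_test(fake_sl(ll), B = 2000, seed = 1)
  expect_equal(p_sh[which.max(rowSums(ll))], 1, tolerance = 0.01)

  same <- rbind(ll[1, ], ll[1, ], ll[1, ])
  expect_true(all(sh_test(fake_sl(same), B = 500, seed = 2) > 0.95))

  # SH >= AU on the same inputs in the vast majority of cases; candidate
  # trees carry structured per-site advantages of varying strength, the
  # setting where the ordering is meaningful
  cnt <- 0; tot <- 0
  for (rep in 1:20) {
    n <- 150
    llr <- matrix(rnorm(4 * n, -2, 0.5), 4, n)
    llr[1, ] <- llr[1, ] + 0.04           # the generating tree
    llr[3, ] <- llr[3, ] - 0.02           # mildly worse
    llr[4, ] <- llr[4, ] - 0.15           # clearly worse
    sl <- fake_sl(llr)
    p_au <- au_test(sl, B = 1000, seed = rep)$au_p
    p_sh <- sh_test(sl, B = 1000, seed = rep)
    cnt <- cnt + sum(p_sh >= p_au - 0.02)
    tot <- tot + length(p_au)
  }
  expect_gte(cnt / tot, 0.95)
})

test_that("reciprocal AU finds no incongruence among loci sharing one history", {
  set.seed(46)
  ds <- simulate_multilocus_dataset(sim_params(n_hybrids = 0), seed = 21)
  aln <- ds$alignments
  specs <- lapply(aln, select_model)
  trees <- mapply(function(a, s) ml_heuristic_search(a, s), aln, specs,
                  SIMPLIFY = FALSE)
  res <- reciprocal_au(aln, trees, specs = specs, n_random = 20, B = 2000,
                       seed = 5)
  for (v in res$verdicts) expect_false(v$incongruent)
})

test_that("a planted hybrid produces reciprocal organellar-nuclear incongruence", {
  set.seed(47)
  ds <- simulate_multilocus_dataset(sim_params(), seed = 22)
  aln <- ds$alignments
  specs <- lapply(aln, select_model)
  trees <- mapply(function(a, s) ml_heuristic_search(a, s), aln, specs,
                  SIMPLIFY = FALSE)
  res <- reciprocal_au(aln, trees, specs = specs, n_random = 50, B = 4000,
                       seed = 6)
  v <- res$verdicts
  expect_true(v$cob.vs.its2$incongruent || v$its2.vs.psba$incongruent)
  expect_false(v$cob.vs.psba$incongruent)
  # verdicts are symmetric objects: incongruent requires both rejections
  for (x in v) if (x$incongruent) {
    expect_true(x$rejected_on_x && x$rejected_on_y)
  }
})
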