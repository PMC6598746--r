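# Raw-sequence verification rules and background-population profiles.

# a three-locus toy: types P (s1-s3) and Q (s4-s6) differ at diagnostic
# columns in every locus; "hyb" carries P organellar and Q nuclear sequences
toy_dataset <- function(extra = NULL) {
  ids <- c(paste0("s", 1:6), "hyb", names(extra))
  mk <- function(L, diag_cols, qbase, special = list()) {
    m <- matrix("A", length(ids), L, dimnames = list(ids, NULL))
    m[4:6, diag_cols] <- qbase
    for (nm in names(special)) m[nm, ] <- special[[nm]]
    m
  }
  cob <- mk(40, 1:2, "G")
  its <- mk(30, 1:4, "T")
  psb <- mk(50, 1:8, "C")
  # hybrid: organellar like P (all "A"), nuclear like Q
  its["hyb", 1:4] <- "T"
  for (nm in names(extra)) {
    for (loc in names(extra[[nm]])) {
      tgt <- switch(loc, cob = "cob", its = "its", psb = "psb")
      mat <- get(tgt)
      mat[nm, extra[[nm]][[loc]]$cols] <- extra[[nm]][[loc]]$base
      assign(tgt, mat)
    }
  }
  list(cob = locus_alignment(cob, "cob"),
       its2 = locus_alignment(its, "its2"),
       psba = locus_alignment(psb, "psba"))
}

roles <- c(cob = "organellar", its2 = "nuclear", psba = "organellar")

test_that("a sample identical to one group matches it everywhere with zero mismatches", {
  aln <- toy_dataset()
  asg <- assign_groups("s1", aln, flagged_ids = character(0))
  for (pl in asg$per_locus) {
    expect_false(pl$ungrouped)
    expect_equal(pl$mismatches, 0L)
    expect_true("s2" %in% pl$members)
  }
})

test_that("a hybrid matches distinct groups at organellar vs nuclear loci", {
  aln <- toy_dataset()
  asg <- assign_groups("hyb", aln, flagged_ids = character(0))
  expect_true(all(c("s1", "s2", "s3") %in% asg$per_locus$psba$members))
  expect_true(all(c("s4", "s5", "s6") %in% asg$per_locus$its2$members))
  expect_equal(asg$per_locus$psba$mismatches, 0L)
  expect_equal(asg$per_locus$its2$mismatches, 0L)
  expect_length(intersect(asg$per_locus$psba$members,
                          asg$per_locus$its2$members), 0)
  # diagnostic columns separate the two candidate groups at the nuclear locus
  expect_setequal(asg$per_locus$its2$diagnostic_columns, 1:4)

  cls <- classify_flagged_sample(asg, aln, roles)
  expect_equal(cls$verdict, "reticulate")
})

test_that("a hugely divergent sequence at one locus is ungrouped and classified divergent", {
  div <- list(dv1 = list(psb = list(cols = 1:40, base = "T")))
  aln <- toy_dataset(div)
  asg <- assign_groups("dv1", aln, flagged_ids = "hyb")
  expect_true(asg$per_locus$psba$ungrouped)
  expect_gt(asg$per_locus$psba$mismatches, 10)
  cls <- classify_flagged_sample(asg, aln, roles)
  expect_equal(cls$verdict, "divergent_sequence")
  expect_equal(cls$evidence$loci, "psba")
})

test_that("purely autapomorphic conflicts are classified uninformative", {
  aut <- list(au1 = list(its = list(cols = c(10, 20), base = "G")))
  aln <- toy_dataset(aut)
  asg <- assign_groups("au1", aln, flagged_ids = "hyb")
  cls <- classify_flagged_sample(asg, aln, roles)
  expect_equal(cls$verdict, "uninformative")
})

test_that("an unflagged pure-type sample classifies congruent", {
  aln <- toy_dataset()
  asg <- assign_groups("s5", aln, flagged_ids = "hyb")
  cls <- classify_flagged_sample(asg, aln, roles)
  expect_equal(cls$verdict, "congruent")
})

test_that("classification is stable under sample-order permutation", {
  set.seed(61)
  aln <- toy_dataset()
  verdict0 <- classify_flagged_sample(assign_groups("hyb", aln), aln,
                                      roles)$verdict
  for (rep in 1:5) {
    perm <- sample(aln$cob$sample_ids)
    aln2 <- lapply(aln, function(a) {
      locus_alignment(a$matrix[perm, , drop = FALSE], a$locus_name)
    })
    v <- classify_flagged_sample(assign_groups("hyb", aln2), aln2,
                                 roles)$verdict
    expect_equal(v, verdict0)
  }
})

test_that("background profiles summarise counterpart traces as printed", {
  # eight focal samples; seven clean, one carrying a 0.61% trace
  counts <- matrix(0, 8, 2, dimnames = list(paste0("p", 1:8), c("F", "Cp")))
  counts[, "F"] <- 10000
  counts[8, "Cp"] <- round(0.61 / 99.39 * 10000)  # 0.61% of its total
  rc <- structure(counts, class = c("read_count_table", "matrix"))
  bp <- background_profile(rc, "F", "Cp")
  expect_equal(bp$population_size, 8)
  expect_equal(bp$n_with_counterpart, 1)
  expect_equal(bp$median, 0)
  expect_equal(round(max(bp$frequencies), 2), 0.61)

  counts[, "Cp"] <- 0
  rc0 <- structure(counts[, , drop = FALSE], class = c("read_count_table", "matrix"))
  bp0 <- background_profile(rc0, "F", "Cp")
  expect_equal(bp0$mean, 0)
  expect_equal(bp0$n_with_counterpart, 0)

  five <- matrix(c(rep(9800, 5), rep(200, 5)), 5, 2,
                 dimnames = list(paste0("q", 1:5), c("F", "Cp")))
  rc5 <- structure(five, class = c("read_count_table", "matrix"))
  bp5 <- background_profile(rc5, "F", "Cp")
  expect_equal(bp5$mean, 2)
  expect_equal(bp5$median, 2)
  expect_equal(bp5$n_with_counterpart, 5)

  expect_error(background_profile(rc5, "absent", "Cp"), "empty focal")
})

test_that("read-count tables round-trip through CSV with deterministic dominants", {
  m <- matrix(c(50, 50, 10, 90), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("v2", "v1")))
  rc <- structure(m, class = c("read_count_table", "matrix"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_count_table(rc, f)
  back <- read_count_table(f)
  expect_equal(unclass(back)[, c("v2", "v1")], m)
  dom <- dominant_variant(back)
  expect_equal(unname(dom["a"]), "v1")  # tie broken lexicographically
  expect_equal(unname(dom["b"]), "v1")
})

test_that("evidence labelling distinguishes pure-parental from polymorphic populations", {
  aln <- toy_dataset()
  cls <- classify_flagged_sample(assign_groups("hyb", aln), aln, roles)

  expect_equal(ils_vs_hybrid_evidence(cls, NULL, "Q", "P")$label, "indeterminate")

  mk_rc <- function(p_cp_in_P, hyb_cp) {
    m <- matrix(10, 7, 5, dimnames = list(c(paste0("s", 1:6), "hyb"),
                                          c("P", "Q", "bg1", "bg2", "bg3")))
    m[1:3, "P"] <- 9000; m[1:3, "Q"] <- p_cp_in_P
    m[4:6, "Q"] <- 9000; m[4:6, "P"] <- 0
    m[7, "Q"] <- 9000; m[7, "P"] <- hyb_cp
    structure(m, class = c("read_count_table", "matrix"))
  }
  pure <- mk_rc(0, 0)
  expect_equal(ils_vs_hybrid_evidence(cls, pure, "Q", "P")$label,
               "hybridisation-favored")
  mixed <- mk_rc(3000, 2500)
  expect_equal(ils_vs_hybrid_evidence(cls, mixed, "Q", "P")$label,
               "ILS-plausible")
})
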