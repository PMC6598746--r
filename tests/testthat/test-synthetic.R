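# The synthetic multi-locus generator and its ground truth.

test_that("zero divergence and no hybrids yields identical sequences throughout", {
  p <- sim_params(between_radiation = c(cob = 0, its2 = 0, psba = 0),
                  between_type = c(cob = 0, its2 = 0, psba = 0),
                  deletion_length = 0,
                  within_type = c(cob = 0, its2 = 0, psba = 0),
                  n_hybrids = 0)
  ds <- simulate_multilocus_dataset(p, seed = 1)
  for (aln in ds$alignments) {
    expect_equal(length(unique(apply(aln$matrix, 1, paste, collapse = ""))), 1)
  }
})

test_that("default dimensions and truth invariants match the study design", {
  ds <- simulate_multilocus_dataset(sim_params(), seed = 2)
  expect_equal(vapply(ds$alignments, n_columns, numeric(1)),
               c(cob = 787, its2 = 369, psba = 531))
  expect_equal(nrow(ds$truth), 21)  # 4 types x 5 samples + 1 hybrid
  hy <- ds$truth[ds$truth$is_hybrid, ]
  expect_equal(nrow(hy), 1)
  expect_false(hy$nuclear_donor == hy$organellar_donor)
  nh <- ds$truth[!ds$truth$is_hybrid, ]
  expect_true(all(nh$type_cob == nh$type_its2 & nh$type_its2 == nh$type_psba))
  # the hypervariable locus carries the radiation-B deletion block
  gaps <- colSums(ds$alignments$psba$matrix == "-")
  expect_equal(sum(gaps > 0), 49)
})

test_that("the planted hybrid's sequences come from the stated donors", {
  ds <- simulate_multilocus_dataset(sim_params(within_type = c(
    cob = 0, its2 = 0, psba = 0)), seed = 3)
  hy <- ds$truth[ds$truth$is_hybrid, ]
  mm <- function(a, b) sum(a != b)
  its <- ds$alignments$its2$matrix
  expect_equal(mm(its[hy$sample_id, ], ds$consensus$its2[[hy$nuclear_donor]]), 0)
  expect_gte(mm(its[hy$sample_id, ], ds$consensus$its2[[hy$organellar_donor]]), 4)
  for (loc in c("cob", "psba")) {
    m <- ds$alignments[[loc]]$matrix
    expect_equal(mm(m[hy$sample_id, ], ds$consensus[[loc]][[hy$organellar_donor]]), 0)
  }
})

test_that("per-locus nearest types reproduce the recorded truth labels", {
  ds <- simulate_multilocus_dataset(sim_params(n_hybrids = 1), seed = 4)
  for (loc in names(ds$alignments)) {
    m <- ds$alignments[[loc]]$matrix
    cons <- ds$consensus[[loc]]
    for (i in seq_len(nrow(ds$truth))) {
      if (ds$truth$confounder[i] != "none") next
      d <- vapply(cons, function(cs) sum(m[ds$truth$sample_id[i], ] != cs),
                  numeric(1))
      # the recorded type attains the minimum distance (sister types can be
      # identical at a near-invariant locus, so ties are allowed)
      expect_equal(unname(d[ds$truth[[paste0("type_", loc)]][i]]),
                   unname(min(d)))
    }
  }
})

test_that("hybrid-free data gives concordant per-locus NJ trees at type level", {
  set.seed(71)
  for (sd in c(11, 12, 13)) {
    ds <- simulate_multilocus_dataset(sim_params(n_hybrids = 0), seed = sd)
    type_of <- setNames(ds$truth$nuclear_type, ds$truth$sample_id)
    # restrict each locus tree to one exemplar per type; all should agree
    reps <- ds$truth$sample_id[!duplicated(ds$truth$nuclear_type)]
    trees <- lapply(ds$alignments[c("its2", "psba")], function(aln) {
      ape::keep.tip(build_nj_tree(aln), reps)
    })
    expect_equal(rf_distance(trees[[1]], trees[[2]]), 0L)
  }
})

test_that("generation is deterministic given the seed", {
  a <- simulate_multilocus_dataset(sim_params(), seed = 5)
  b <- simulate_multilocus_dataset(sim_params(), seed = 5)
  expect_identical(a$alignments$psba$matrix, b$alignments$psba$matrix)
  expect_identical(a$truth, b$truth)
  rc_a <- simulate_read_counts(a$truth, seed = 6)
  rc_b <- simulate_read_counts(b$truth, seed = 6)
  expect_identical(unclass(rc_a), unclass(rc_b))
})

test_that("read-count tables conserve totals and honour the weight settings", {
  ds <- simulate_multilocus_dataset(sim_params(), seed = 7)
  rc <- simulate_read_counts(ds$truth, total_reads = 5000,
                             dominant_fraction = 1, seed = 8)
  expect_true(all(rowSums(rc) == 5000))
  dom <- dominant_variant(rc)
  expect_equal(unname(dom), ds$truth$nuclear_type)
  # dominant_fraction 1 with zero counterpart: single variant per sample
  expect_true(all(apply(unclass(rc) > 0, 1, sum) == 1))

  rc2 <- simulate_read_counts(ds$truth, total_reads = 50000,
                              counterpart_weight = 0.0061, seed = 9)
  hy <- ds$truth$sample_id[ds$truth$is_hybrid]
  cp <- phyloconflict:::counterpart_of(ds$truth$nuclear_type[1],
                                       sort(unique(ds$truth$nuclear_type)))
  freq <- 100 * rc2[1, cp] / sum(rc2[1, ])
  se <- 100 * sqrt(0.0061 * (1 - 0.0061) / 50000)
  expect_lt(abs(freq - 0.61), 3 * se)
})

test_that("the ILS scenario plants intragenomic polymorphism, not pure parents", {
  ils <- simulate_ils_dataset(sim_params(), seed = 10)
  affected <- ils$truth$sample_id[ils$truth$ils_affected]
  expect_gt(length(affected), 0)
  switched <- ils$truth$sample_id[ils$truth$ils_switched]
  expect_length(switched, 1)
  # every affected sample carries both variants above trace level
  rc <- ils$read_counts
  own <- "C1.1"; cp <- phyloconflict:::counterpart_of(own, colnames(rc)[1:4])
  for (id in affected) {
    expect_gt(100 * rc[id, own] / sum(rc[id, ]), 1)
    expect_gt(100 * rc[id, cp] / sum(rc[id, ]), 1)
  }
  # switched sample's dominant (alignment) nuclear sequence is the counterpart
  expect_equal(ils$truth$nuclear_type[ils$truth$ils_switched], cp)

  # contrast with the hybrid scenario: parental populations essentially pure
  ds <- simulate_multilocus_dataset(sim_params(), seed = 10)
  rch <- simulate_read_counts(ds$truth, seed = 11)
  hy <- ds$truth[ds$truth$is_hybrid, ]
  parents <- ds$truth$sample_id[!ds$truth$is_hybrid &
                                  ds$truth$nuclear_type %in%
                                  c(hy$nuclear_donor, hy$organellar_donor)]
  for (id in parents) {
    other <- setdiff(c(hy$nuclear_donor, hy$organellar_donor),
                     ds$truth$nuclear_type[ds$truth$sample_id == id])
    expect_equal(unname(rch[id, other]), 0)
  }
})

test_that("datasets write to the pipeline's input formats", {
  ds <- simulate_ils_dataset(sim_params(), seed = 12)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "its2.fasta")))
  back <- read_alignment_fasta(file.path(dir, "its2.fasta"), "its2")
  expect_identical(back$matrix, ds$alignments$its2$matrix)
  rc <- read_count_table(file.path(dir, "read_counts.csv"))
  expect_equal(unclass(rc), unclass(ds$read_counts))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth, nrow(ds$truth))
})
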