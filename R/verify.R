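# Raw-sequence verification of flagged samples and the amplicon
# background-population analysis weighing hybridisation against incomplete
# lineage sorting.
#
# A "group" at a locus is an exact-match (or <= delta mismatches,
# single linkage) cluster of at least two non-flagged samples; a flagged
# sample is classified by which groups its per-locus sequences fall into.

seq_mismatches <- function(x, y) {
  # N matches anything; gap is an ordinary state
  sum(x != y & x != "N" & y != "N")
}

consensus_seq <- function(mat) {
  apply(mat, 2, function(col) {
    col <- col[col != "N"]
    if (!length(col)) return("N")
    tab <- table(factor(col, levels = c(ALPHABET, setdiff(unique(col), ALPHABET))))
    names(tab)[which.max(tab)]
  })
}

# columns whose variation is carried by single sequences only (every
# non-majority state occurs in exactly one sample): parsimony-uninformative
# noise that cannot define a group and is masked during group formation
noise_columns <- function(aln) {
  apply(aln$matrix, 2, function(col) {
    col <- col[col != "N"]
    tab <- table(col)
    if (length(tab) <= 1) return(FALSE)
    maj <- names(tab)[which.max(tab)]
    all(tab[names(tab) != maj] <= 1)
  })
}

# single-linkage clusters at <= delta mismatches among the given samples;
# only clusters with >= 2 members count as groups
form_groups <- function(aln, member_ids, delta = 0, cols = NULL) {
  if (is.null(cols)) cols <- seq_len(ncol(aln$matrix))
  m <- aln$matrix[member_ids, cols, drop = FALSE]
  n <- length(member_ids)
  if (n == 0) return(list())
  comp <- seq_len(n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (seq_mismatches(m[i, ], m[j, ]) <= delta) {
        old <- comp[j]; comp[comp == old] <- comp[i]
      }
    }
  }
  out <- list()
  for (cid in unique(comp)) {
    members <- member_ids[comp == cid]
    if (length(members) < 2) next
    out[[length(out) + 1]] <- list(
      members = sort(members),
      consensus = consensus_seq(aln$matrix[members, , drop = FALSE]))
  }
  # stable naming by first member
  if (length(out)) {
    ord <- order(vapply(out, function(g) g$members[1], character(1)))
    out <- out[ord]
    names(out) <- paste0("G", seq_along(out), ".",
                         vapply(out, function(g) g$members[1], character(1)))
  }
  out
}

#' Assign a sample to sequence groups at every locus
#'
#' Groups are exact-match (or `delta`-tolerant, single linkage) clusters of
#' at least two non-flagged samples. The sample is assigned per locus to
#' the group whose consensus it matches with the fewest mismatches; it is
#' `ungrouped` at a locus when no group exists or the nearest group is
#' further than `max_dist` mismatches. Diagnostic columns are the columns
#' whose states separate the two nearest candidate groups.
#'
#' @param sample_id the sample to place.
#' @param alignments named list of [locus_alignment]s (sample present in all).
#' @param flagged_ids samples excluded from group formation (the focal
#'   sample is always excluded).
#' @param delta within-group mismatch tolerance (default 0: exact-match
#'   clusters).
#' @param max_dist mismatch count beyond which the sample is `ungrouped`
#'   (the "highly divergent" threshold). The default `NULL` uses
#'   `max(10, 5%` of the locus length`)` per locus, so ordinary between-type
#'   distances never register as divergence.
#' @return object of class `group_assignment`: per locus the nearest group
#'   label, its members, mismatch count, `ungrouped` flag, diagnostic
#'   columns, and the full group lists.
#' @export
assign_groups <- function(sample_id, alignments, flagged_ids = character(0),
                          delta = 0, max_dist = NULL) {
  stopifnot(delta >= 0)
  max_dist_for <- function(aln) {
    if (!is.null(max_dist)) max_dist else max(10, ceiling(0.05 * n_columns(aln)))
  }
  per_locus <- lapply(alignments, function(aln) {
    if (!sample_id %in% aln$sample_ids) {
      stop("sample '", sample_id, "' missing from locus ", aln$locus_name)
    }
    others <- setdiff(aln$sample_ids, c(sample_id, flagged_ids))
    # group formation and group choice ignore single-sequence noise columns;
    # the divergence call below uses the raw (unmasked) distance
    informative <- which(!noise_columns(aln))
    if (!length(informative)) informative <- seq_len(n_columns(aln))
    groups <- form_groups(aln, others, delta, cols = informative)
    s <- aln$matrix[sample_id, ]
    if (!length(groups)) {
      return(list(group = NA_character_, members = character(0),
                  mismatches = NA_integer_, ungrouped = TRUE,
                  diagnostic_columns = integer(0), groups = groups))
    }
    d_masked <- vapply(groups, function(g) {
      seq_mismatches(s[informative], g$consensus[informative])
    }, numeric(1))
    d <- vapply(groups, function(g) seq_mismatches(s, g$consensus), numeric(1))
    ord <- order(d_masked, d)
    best <- ord[1]
    diag_cols <- integer(0)
    if (length(groups) >= 2) {
      second <- ord[2]
      c1 <- groups[[best]]$consensus
      c2 <- groups[[second]]$consensus
      diag_cols <- which(c1 != c2 & c1 != "N" & c2 != "N")
    }
    list(group = names(groups)[best], members = groups[[best]]$members,
         mismatches = as.integer(d[best]), ungrouped = d[best] > max_dist_for(aln),
         diagnostic_columns = diag_cols, groups = groups)
  })
  structure(list(sample_id = sample_id, per_locus = per_locus,
                 delta = delta, max_dist = max_dist,
                 flagged_ids = flagged_ids),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("<group_assignment> sample ", x$sample_id, "\n", sep = "")
  for (nm in names(x$per_locus)) {
    pl <- x$per_locus[[nm]]
    cat("  ", nm, ": ",
        if (pl$ungrouped) "ungrouped" else
          paste0(pl$group, " (", pl$mismatches, " mismatches)"), "\n", sep = "")
  }
  invisible(x)
}

# columns at locus where the sample differs from the consensus of the
# reference members' sequences
conflict_columns <- function(aln, sample_id, ref_members) {
  cons <- consensus_seq(aln$matrix[ref_members, , drop = FALSE])
  s <- aln$matrix[sample_id, ]
  which(s != cons & s != "N" & cons != "N")
}

is_autapomorphic <- function(aln, sample_id, col) {
  state <- aln$matrix[sample_id, col]
  others <- aln$matrix[setdiff(aln$sample_ids, sample_id), col]
  !(state %in% others)
}

#' Classify a flagged sample
#'
#' Rules applied in order:
#' 1. `divergent_sequence` -- ungrouped at any locus (nearest group further
#'    than the divergence threshold);
#' 2. `uninformative` -- the sample conflicts with its organellar type only
#'    at autapomorphic columns (states unique to this sample), i.e.
#'    parsimony-uninformative variation in a single sequence;
#' 3. `reticulate` -- distinct multi-member groups at an organellar locus
#'    versus the nuclear locus (disjoint memberships);
#' 4. `congruent` otherwise.
#'
#' @param assignment a `group_assignment` from [assign_groups()].
#' @param alignments the same named list of [locus_alignment]s.
#' @param roles named character vector mapping locus name to
#'   "organellar"/"nuclear".
#' @return object of class `flag_classification` with `verdict` and
#'   `evidence`.
#' @export
classify_flagged_sample <- function(assignment, alignments, roles) {
  stopifnot(inherits(assignment, "group_assignment"))
  loci <- names(assignment$per_locus)
  roles <- roles[loci]
  sample_id <- assignment$sample_id
  org <- loci[roles == "organellar"]
  nuc <- loci[roles == "nuclear"]
  if (!length(org) || !length(nuc)) stop("roles must include organellar and nuclear loci")

  verdict <- NULL
  evidence <- list()

  # rule 1: highly divergent sequence at some locus
  ung <- vapply(assignment$per_locus, function(pl) isTRUE(pl$ungrouped), logical(1))
  if (any(ung)) {
    verdict <- "divergent_sequence"
    evidence$rule <- "ungrouped_locus"
    evidence$loci <- loci[ung]
  }

  # reference organellar type: the organellar locus with the most groups
  n_groups <- vapply(assignment$per_locus, function(pl) length(pl$groups), numeric(1))
  ref_locus <- org[order(-n_groups[org])][1]
  ref <- assignment$per_locus[[ref_locus]]

  if (is.null(verdict) && !is.na(ref$group)) {
    cols <- lapply(loci, function(l) {
      conflict_columns(alignments[[l]], sample_id, ref$members)
    })
    names(cols) <- loci
    all_cols <- sum(lengths(cols))
    if (all_cols > 0) {
      auta <- unlist(lapply(loci, function(l) {
        vapply(cols[[l]], function(cc) is_autapomorphic(alignments[[l]],
                                                        sample_id, cc), logical(1))
      }))
      if (all(auta)) {
        verdict <- "uninformative"
        evidence$rule <- "all_conflicts_autapomorphic"
        evidence$conflict_columns <- cols
      }
    }
  }

  if (is.null(verdict)) {
    # rule 3: reticulate pattern, organellar vs nuclear group disjoint;
    # organellar loci tried from the most finely grouped down, so a
    # near-invariant marker whose single group spans several types cannot
    # mask the informative one
    for (ol in org[order(-n_groups[org])]) {
      po <- assignment$per_locus[[ol]]
      pn <- assignment$per_locus[[nuc[1]]]
      if (!is.na(po$group) && !is.na(pn$group) &&
          length(po$members) >= 2 && length(pn$members) >= 2 &&
          !length(intersect(po$members, pn$members))) {
        verdict <- "reticulate"
        evidence$rule <- "disjoint_org_vs_nuc_groups"
        evidence$organellar_locus <- ol
        evidence$organellar_group <- po$members
        evidence$nuclear_group <- pn$members
        break
      }
    }
  }

  if (is.null(verdict)) verdict <- "congruent"
  structure(list(sample_id = sample_id, verdict = verdict,
                 evidence = evidence, assignment = assignment),
            class = "flag_classification")
}

#' @export
print.flag_classification <- function(x, ...) {
  cat("<flag_classification> ", x$sample_id, ": ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Read an NGS read-count table from CSV
#'
#' Rows are samples (first column = sample id), remaining columns are
#' sequence-variant labels holding non-negative read counts.
#' @param path CSV file.
#' @return object of class `read_count_table` (numeric matrix, samples x
#'   variants).
#' @export
read_count_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("negative read counts")
  structure(m, class = c("read_count_table", "matrix"))
}

#' Write a read-count table to CSV
#' @param rc a `read_count_table` (or plain matrix).
#' @param path output CSV.
#' @export
write_count_table <- function(rc, path) {
  df <- data.frame(sample = rownames(rc), unclass(rc), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Dominant variant per sample
#'
#' Argmax of read counts; ties broken deterministically toward the
#' lexicographically first variant label.
#' @param rc a `read_count_table`.
#' @return named character vector, sample id -> variant label.
#' @export
dominant_variant <- function(rc) {
  vars <- colnames(rc)
  ord <- order(vars)
  apply(rc[, ord, drop = FALSE], 1, function(x) vars[ord][which.max(x)])
}

#' Background-population profile of a counterpart variant
#'
#' The focal population is every sample whose dominant variant is
#' `focal_type`; per sample the counterpart frequency is
#' `counterpart reads / total reads * 100`.
#'
#' @param rc a `read_count_table`.
#' @param focal_type variant defining the focal population.
#' @param counterpart_type variant whose background traces are profiled.
#' @return object of class `background_profile` with per-sample
#'   frequencies and summary statistics (mean, median, count of samples
#'   containing the counterpart, population size).
#' @export
background_profile <- function(rc, focal_type, counterpart_type) {
  dom <- dominant_variant(rc)
  pop <- names(dom)[dom == focal_type]
  if (!length(pop)) stop("empty focal population for variant '", focal_type, "'")
  cnt <- if (counterpart_type %in% colnames(rc)) rc[pop, counterpart_type] else
    setNames(rep(0, length(pop)), pop)
  tot <- rowSums(rc[pop, , drop = FALSE])
  freq <- 100 * cnt / tot
  structure(list(focal_type = focal_type, counterpart_type = counterpart_type,
                 frequencies = freq,
                 mean = mean(freq), median = median(freq),
                 n_with_counterpart = sum(freq > 0),
                 population_size = length(pop)),
            class = "background_profile")
}

#' @export
print.background_profile <- function(x, ...) {
  cat("<background_profile> ", x$counterpart_type, " traces in the ",
      x$focal_type, " population (n = ", x$population_size, ")\n",
      "  mean ", signif(x$mean, 3), "%, median ", signif(x$median, 3),
      "%, present in ", x$n_with_counterpart, "/", x$population_size,
      " samples\n", sep = "")
  invisible(x)
}

#' Weigh hybridisation against incomplete lineage sorting
#'
#' A labelled evidence summary, never a statistical test:
#' `hybridisation-favored` when counterpart traces are essentially absent
#' from both parental populations (mean below `trace_threshold` percent)
#' and the flagged sample itself lacks the counterpart nuclear variant;
#' `ILS-plausible` when counterpart variants are widespread in the parental
#' populations (present above trace level in at least
#' `widespread_fraction` of samples) or ancestral variants persist in the
#' flagged sample; `indeterminate` otherwise or when read counts are
#' missing.
#'
#' @param classification a `flag_classification` with verdict `reticulate`.
#' @param rc a `read_count_table`, or `NULL` when unavailable.
#' @param nuclear_type the flagged sample's dominant nuclear variant.
#' @param organellar_type the nuclear variant matching the flagged sample's
#'   organellar identity (the counterpart).
#' @param trace_threshold percent frequency counting as a trace (default 1).
#' @param widespread_fraction fraction of parental samples above trace
#'   level that makes ILS plausible.
#' @return object of class `ils_evidence` with `label` and the two
#'   [background_profile]s.
#' @export
ils_vs_hybrid_evidence <- function(classification, rc, nuclear_type,
                                   organellar_type, trace_threshold = 1,
                                   widespread_fraction = 0.25) {
  lab_out <- function(label, p1 = NULL, p2 = NULL, why = "") {
    structure(list(label = label, sample_id = classification$sample_id,
                   nuclear_type = nuclear_type,
                   organellar_type = organellar_type,
                   profile_nuclear_pop = p1, profile_organellar_pop = p2,
                   note = why),
              class = "ils_evidence")
  }
  if (is.null(rc)) return(lab_out("indeterminate", why = "no read-count table"))
  p_nuc <- tryCatch(background_profile(rc, nuclear_type, organellar_type),
                    error = function(e) NULL)
  p_org <- tryCatch(background_profile(rc, organellar_type, nuclear_type),
                    error = function(e) NULL)
  if (is.null(p_nuc) || is.null(p_org)) {
    return(lab_out("indeterminate", p_nuc, p_org,
                   "parental population(s) unprofiled"))
  }
  sid <- classification$sample_id
  flagged_counterpart <- if (sid %in% rownames(rc) &&
                             organellar_type %in% colnames(rc)) {
    100 * rc[sid, organellar_type] / sum(rc[sid, ])
  } else 0
  widespread <- function(p) {
    mean(p$frequencies > trace_threshold) >= widespread_fraction
  }
  if (widespread(p_nuc) || widespread(p_org) ||
      flagged_counterpart > trace_threshold) {
    return(lab_out("ILS-plausible", p_nuc, p_org,
                   "counterpart variants widespread / ancestral variants retained"))
  }
  if (p_nuc$mean < trace_threshold && p_org$mean < trace_threshold &&
      flagged_counterpart <= trace_threshold) {
    return(lab_out("hybridisation-favored", p_nuc, p_org,
                   "essentially pure parental populations"))
  }
  lab_out("indeterminate", p_nuc, p_org, "mixed trace pattern")
}

#' @export
print.ils_evidence <- function(x, ...) {
  cat("<ils_evidence> ", x$sample_id, " (", x$nuclear_type, " / ",
      x$organellar_type, "): ", x$label, "\n", sep = "")
  invisible(x)
}
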