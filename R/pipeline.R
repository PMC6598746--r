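# Orchestration of the stepwise per-site incongruence procedure:
# gated three-way ILD -> per-locus model selection, ML trees, bootstrap
# with polytomy collapse -> reciprocal AU -> (on evidence of incongruence)
# pairwise ILD -> irreconcilable-taxon search -> per-sample verification
# -> background-population evidence.

#' Pipeline configuration
#'
#' Defaults follow the study design the workflow reproduces: two-stage ILD
#' (100 replicates / MaxTrees 1,000; gate p < 0.2; then 1,000 / 10,000),
#' reciprocal AU with 100 equiprobable random trees and 10,000 RELL
#' replicates at Bonferroni alpha 0.05/6, pairwise ILD at alpha 0.017,
#' bootstraps of 1,000 / 100 / 100 replicates with <50% collapse.
#'
#' @param roles named organellar/nuclear role per locus.
#' @param bootstrap_reps named bootstrap replicates per locus.
#' @param ild_stage1_replicates,ild_stage1_maxtrees,ild_gate,ild_stage2_replicates,ild_stage2_maxtrees
#'   two-stage ILD settings.
#' @param ild_addition_replicates random-addition starts per ILD search.
#' @param ild_alpha significance level for the gated three-way ILD.
#' @param au_n_random,au_B,au_alpha,au_resolution_margin reciprocal AU
#'   settings (alpha defaults to 0.05/6; the rounded 0.0085 preset is
#'   `au_alpha = 0.0085`).
#' @param pairwise_replicates,pairwise_maxtrees,pairwise_alpha post-hoc
#'   pairwise ILD settings.
#' @param collapse_threshold bootstrap percent below which nodes collapse.
#' @param max_remove cap for the irreconcilable-taxon search.
#' @param delta,max_dist,trace_threshold,widespread_fraction verification
#'   thresholds (see [assign_groups()], [ils_vs_hybrid_evidence()]).
#' @param seed master seed; stages derive their own streams from it.
#' @export
pipeline_config <- function(
    roles = c(cob = "organellar", its2 = "nuclear", psba = "organellar"),
    bootstrap_reps = c(cob = 1000, its2 = 100, psba = 100),
    ild_stage1_replicates = 100, ild_stage1_maxtrees = 1000,
    ild_gate = 0.2,
    ild_stage2_replicates = 1000, ild_stage2_maxtrees = 10000,
    ild_addition_replicates = 1,
    ild_alpha = 0.05,
    au_n_random = 100, au_B = 10000, au_alpha = 0.05 / 6,
    au_resolution_margin = 3,
    pairwise_replicates = 1000, pairwise_maxtrees = 10000,
    pairwise_alpha = 0.017,
    collapse_threshold = 50,
    max_remove = 3,
    delta = 0, max_dist = NULL,
    trace_threshold = 1, widespread_fraction = 0.25,
    seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$ild_alpha > 0, cfg$ild_alpha < 1,
            cfg$au_alpha > 0, cfg$au_alpha < 1,
            cfg$pairwise_alpha > 0, cfg$pairwise_alpha < 1,
            cfg$ild_stage1_replicates >= 1, cfg$ild_stage2_replicates >= 1,
            cfg$pairwise_replicates >= 1)
  structure(cfg, class = "pipeline_config")
}

stage_result <- function(ok, value = NULL, error = NULL) {
  list(ok = ok, value = value, error = error)
}

run_stage <- function(expr) {
  tryCatch(stage_result(TRUE, expr),
           error = function(e) stage_result(FALSE, NULL, conditionMessage(e)))
}

#' Run the stepwise incongruence pipeline on one site dataset
#'
#' @param alignments named list of three [locus_alignment]s with matching
#'   sample sets (names must appear in `config$roles`).
#' @param config a [pipeline_config()].
#' @param read_counts optional `read_count_table` for the
#'   background-population stage.
#' @param dataset label used in the report.
#' @return object of class `pipeline_report`.
#' @export
run_site_pipeline <- function(alignments, config = pipeline_config(),
                              read_counts = NULL, dataset = "site") {
  stopifnot(inherits(config, "pipeline_config"))
  loci <- vapply(alignments, function(a) a$locus_name, character(1))
  names(alignments) <- loci
  if (!all(loci %in% names(config$roles))) {
    stop("config$roles lacks loci: ",
         paste(setdiff(loci, names(config$roles)), collapse = ", "))
  }
  seed <- config$seed
  report <- list(dataset = dataset, config = config, stages = list())

  # stage 1: gated three-way ILD on the concatenated supermatrix
  st_ild <- run_stage({
    pa <- concatenate_partitions(alignments)
    ild_gated(pa,
              stage1_replicates = config$ild_stage1_replicates,
              stage1_maxtrees = config$ild_stage1_maxtrees,
              stage2_replicates = config$ild_stage2_replicates,
              stage2_maxtrees = config$ild_stage2_maxtrees,
              gate = config$ild_gate, seed = derive_seed(seed, 1L),
              addition_replicates = config$ild_addition_replicates)
  })
  report$stages$ild <- st_ild
  report$ild <- st_ild$value

  # stage 2: per-locus models, ML trees, bootstrap + collapse
  st_trees <- run_stage({
    out <- list()
    for (i in seq_along(loci)) {
      loc <- loci[i]
      aln <- alignments[[loc]]
      spec <- select_model(aln)
      ml <- ml_heuristic_search(aln, spec)
      boot <- bootstrap_support(
        aln, spec,
        replicates = config$bootstrap_reps[[loc]],
        collapse_threshold = config$collapse_threshold,
        seed = derive_seed(seed, 10L + i), ml_tree = ml)
      out[[loc]] <- list(spec = spec, ml_tree = ml, collapsed_tree = boot)
    }
    out
  })
  report$stages$trees <- st_trees
  report$trees <- st_trees$value

  # stage 3: reciprocal AU on the collapsed per-locus trees
  st_au <- run_stage({
    if (!st_trees$ok) stop("tree stage failed: ", st_trees$error)
    trees <- lapply(report$trees, `[[`, "collapsed_tree")
    specs <- lapply(report$trees, `[[`, "spec")
    reciprocal_au(alignments, trees, specs = specs,
                  n_random = config$au_n_random, B = config$au_B,
                  alpha = config$au_alpha,
                  resolution_margin = config$au_resolution_margin,
                  seed = derive_seed(seed, 20L))
  })
  report$stages$reciprocal_au <- st_au
  report$reciprocal_au <- st_au$value

  # evidence rule: gated ILD significant OR any reciprocal AU incongruence
  # not explained away by a resolution mismatch
  ild_flag <- st_ild$ok && st_ild$value$p_value < config$ild_alpha
  au_flag <- st_au$ok && any(vapply(st_au$value$verdicts, function(v) {
    v$incongruent && !v$resolution_confounded
  }, logical(1)))
  report$evidence_of_incongruence <- ild_flag || au_flag
  report$ild_significant <- ild_flag
  report$au_incongruent <- au_flag

  report$pairwise_ild <- NULL
  report$conflicts <- NULL
  report$classifications <- list()
  report$background <- list()

  if (report$evidence_of_incongruence && st_trees$ok) {
    st_pw <- run_stage({
      ild_pairwise(alignments,
                   replicates = config$pairwise_replicates,
                   maxtrees = config$pairwise_maxtrees,
                   alpha = config$pairwise_alpha,
                   seed = derive_seed(seed, 30L),
                   addition_replicates = config$ild_addition_replicates)
    })
    report$stages$pairwise_ild <- st_pw
    report$pairwise_ild <- st_pw$value

    st_conf <- run_stage({
      if (!st_pw$ok) stop("pairwise ILD failed: ", st_pw$error)
      sig <- names(report$pairwise_ild)[vapply(report$pairwise_ild,
                                               function(r) isTRUE(r$significant),
                                               logical(1))]
      out <- list()
      for (nm in sig) {
        pair <- strsplit(nm, ".vs.", fixed = TRUE)[[1]]
        out[[nm]] <- incongruent_taxa(
          report$trees[[pair[1]]]$collapsed_tree,
          report$trees[[pair[2]]]$collapsed_tree,
          max_remove = config$max_remove)
      }
      out
    })
    report$stages$conflicts <- st_conf
    report$conflicts <- st_conf$value

    st_cls <- run_stage({
      flagged <- sort(unique(unlist(lapply(report$conflicts, `[[`, "removed_taxa"))))
      cls <- list()
      for (sid in flagged) {
        asg <- assign_groups(sid, alignments, flagged_ids = setdiff(flagged, sid),
                             delta = config$delta, max_dist = config$max_dist)
        cls[[sid]] <- classify_flagged_sample(asg, alignments,
                                              roles = config$roles[loci])
      }
      cls
    })
    report$stages$classifications <- st_cls
    report$classifications <- if (st_cls$ok) st_cls$value else list()

    st_bg <- run_stage({
      out <- list()
      for (sid in names(report$classifications)) {
        cl <- report$classifications[[sid]]
        if (cl$verdict != "reticulate") next
        out[[sid]] <- background_evidence_for(cl, alignments, read_counts,
                                              config)
      }
      out
    })
    report$stages$background <- st_bg
    report$background <- if (st_bg$ok) st_bg$value else list()
  }

  report$flagged_samples <- names(report$classifications)
  report$reticulate_samples <- names(report$classifications)[
    vapply(report$classifications, function(c) c$verdict == "reticulate",
           logical(1))]
  class(report) <- "pipeline_report"
  report
}

# derive the flagged sample's parental nuclear variants from its group
# memberships and the read-count table's dominant variants, then weigh
# hybridisation vs ILS
background_evidence_for <- function(classification, alignments, read_counts,
                                    config) {
  if (is.null(read_counts)) {
    return(ils_vs_hybrid_evidence(classification, NULL, NA, NA))
  }
  ev <- classification$evidence
  dom <- dominant_variant(read_counts)
  majority <- function(members) {
    v <- dom[intersect(members, names(dom))]
    if (!length(v)) return(NA_character_)
    names(sort(table(v), decreasing = TRUE))[1]
  }
  nuclear_type <- majority(ev$nuclear_group)
  organellar_type <- majority(ev$organellar_group)
  if (is.na(nuclear_type) || is.na(organellar_type)) {
    return(ils_vs_hybrid_evidence(classification, NULL, NA, NA))
  }
  ils_vs_hybrid_evidence(classification, read_counts, nuclear_type,
                         organellar_type,
                         trace_threshold = config$trace_threshold,
                         widespread_fraction = config$widespread_fraction)
}

#' Run the pipeline on pooled site datasets
#'
#' Per-locus alignments from several sites (disjoint sample ids) are pooled
#' and the same stages run; the report cross-references each flagged
#' sample's source site.
#'
#' @param datasets named list of site datasets, each a named list of three
#'   [locus_alignment]s.
#' @param config a [pipeline_config()].
#' @param read_counts optional pooled `read_count_table`.
#' @return a `pipeline_report` with `$sample_site` mapping.
#' @export
run_aggregate <- function(datasets, config = pipeline_config(),
                          read_counts = NULL) {
  stopifnot(length(datasets) >= 2)
  site_names <- names(datasets)
  if (is.null(site_names)) site_names <- paste0("site", seq_along(datasets))
  all_ids <- unlist(lapply(datasets, function(d) d[[1]]$sample_ids))
  if (anyDuplicated(all_ids)) {
    stop("overlapping sample ids across sites: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  loci <- names(datasets[[1]])
  pooled <- lapply(loci, function(loc) {
    m <- do.call(rbind, lapply(datasets, function(d) d[[loc]]$matrix))
    locus_alignment(m, loc)
  })
  names(pooled) <- loci
  sample_site <- rep(site_names, vapply(datasets,
                                        function(d) length(d[[1]]$sample_ids),
                                        integer(1)))
  names(sample_site) <- all_ids
  rep_out <- run_site_pipeline(pooled, config, read_counts,
                               dataset = paste(site_names, collapse = "+"))
  rep_out$sample_site <- sample_site[rep_out$flagged_samples]
  rep_out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> dataset: ", x$dataset, "\n", sep = "")
  if (!is.null(x$ild)) {
    cat("  gated ILD: p = ", signif(x$ild$p_value, 4),
        " (stage ", x$ild$stage, ", R = ", x$ild$replicates, ")\n", sep = "")
  }
  if (!is.null(x$reciprocal_au)) {
    for (nm in names(x$reciprocal_au$verdicts)) {
      v <- x$reciprocal_au$verdicts[[nm]]
      cat("  AU ", nm, ": ",
          if (v$incongruent) "reciprocally incongruent" else "congruent",
          if (v$resolution_confounded) " [resolution-confounded]" else "",
          "\n", sep = "")
    }
  }
  cat("  evidence of incongruence: ", x$evidence_of_incongruence, "\n", sep = "")
  if (!is.null(x$pairwise_ild)) {
    for (nm in names(x$pairwise_ild)) {
      r <- x$pairwise_ild[[nm]]
      cat("  pairwise ILD ", nm, ": p = ", signif(r$p_value, 4),
          if (r$significant) " *" else "", "\n", sep = "")
    }
  }
  if (length(x$classifications)) {
    for (sid in names(x$classifications)) {
      cat("  flagged ", sid, ": ", x$classifications[[sid]]$verdict, "\n", sep = "")
    }
  } else cat("  flagged samples: none\n")
  for (sid in names(x$background)) {
    cat("  background ", sid, ": ", x$background[[sid]]$label, "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#' @param report a `pipeline_report`.
#' @param path output JSON file.
#' @export
write_report_json <- function(report, path) {
  verd <- NULL
  if (!is.null(report$reciprocal_au)) {
    verd <- lapply(report$reciprocal_au$verdicts, function(v) {
      list(pair = paste(v$locus_x, v$locus_y, sep = ".vs."),
           incongruent = v$incongruent,
           p_on_x = v$p_on_x, p_on_y = v$p_on_y,
           resolution_confounded = v$resolution_confounded)
    })
  }
  pw <- NULL
  if (!is.null(report$pairwise_ild)) {
    pw <- lapply(report$pairwise_ild, function(r) {
      list(p_value = r$p_value, significant = isTRUE(r$significant))
    })
  }
  out <- list(
    dataset = report$dataset,
    ild = if (!is.null(report$ild)) list(p_value = report$ild$p_value,
                                         stage = report$ild$stage,
                                         replicates = report$ild$replicates),
    reciprocal_au = verd,
    evidence_of_incongruence = report$evidence_of_incongruence,
    pairwise_ild = pw,
    conflicts = lapply(report$conflicts, function(cr) {
      list(removed_taxa = cr$removed_taxa, residual_rf = cr$residual_rf)
    }),
    classifications = lapply(report$classifications, function(cl) cl$verdict),
    background = lapply(report$background, function(b) b$label))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Markdown summary of a pipeline report
#' @param report a `pipeline_report`.
#' @param path output Markdown file.
#' @export
write_report_markdown <- function(report, path) {
  lines <- c(paste0("# Incongruence report: ", report$dataset), "")
  if (!is.null(report$ild)) {
    lines <- c(lines, "## Partition homogeneity (ILD)",
               sprintf("- three-way ILD: p = %.4g (stage %d, R = %d, MaxTrees = %d)",
                       report$ild$p_value, report$ild$stage,
                       report$ild$replicates, report$ild$maxtrees), "")
  }
  if (!is.null(report$reciprocal_au)) {
    lines <- c(lines, "## Reciprocal AU tests",
               "| pair | incongruent | p (on X) | p (on Y) | confounded |",
               "|---|---|---|---|---|")
    for (nm in names(report$reciprocal_au$verdicts)) {
      v <- report$reciprocal_au$verdicts[[nm]]
      lines <- c(lines, sprintf("| %s | %s | %.4g | %.4g | %s |", nm,
                                v$incongruent, v$p_on_x, v$p_on_y,
                                v$resolution_confounded))
    }
    lines <- c(lines, "")
  }
  if (!is.null(report$pairwise_ild)) {
    lines <- c(lines, "## Pairwise ILD",
               "| pair | p | significant |", "|---|---|---|")
    for (nm in names(report$pairwise_ild)) {
      r <- report$pairwise_ild[[nm]]
      lines <- c(lines, sprintf("| %s | %.4g | %s |", nm, r$p_value,
                                isTRUE(r$significant)))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Flagged samples")
  if (length(report$classifications)) {
    for (sid in names(report$classifications)) {
      bg <- if (sid %in% names(report$background))
        paste0(" (background: ", report$background[[sid]]$label, ")") else ""
      lines <- c(lines, sprintf("- **%s**: %s%s", sid,
                                report$classifications[[sid]]$verdict, bg))
    }
  } else lines <- c(lines, "- none")
  writeLines(lines, path)
  invisible(path)
}
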