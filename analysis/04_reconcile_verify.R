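#!/usr/bin/env Rscript
# Post-hoc stages for the hybrid site: pairwise ILD at Bonferroni alpha
# 0.017 to locate the incongruence, irreconcilable-taxon search and
# tanglegram ordering on the implicated tree pairs, rule-based raw-sequence
# classification of the flagged samples, and the background-population
# evidence weighing hybridisation against incomplete lineage sorting.

suppressMessages(library(phyloconflict))

data_dir <- "results/data"
if (!dir.exists(data_dir)) stop("run analysis/01_simulate.R first")
loci <- c("cob", "its2", "psba")
alns <- lapply(loci, function(l) {
  read_alignment_fasta(file.path(data_dir, "siteA", paste0(l, ".fasta")), l)
})
names(alns) <- loci
rc <- read_count_table(file.path(data_dir, "siteA", "read_counts.csv"))
roles <- c(cob = "organellar", its2 = "nuclear", psba = "organellar")

message("pairwise ILD (alpha = 0.017):")
pw <- ild_pairwise(alns, seed = 401)
for (nm in names(pw)) {
  message(sprintf("  %s: p = %.4g%s", nm, pw[[nm]]$p_value,
                  if (pw[[nm]]$significant) "  *" else ""))
}
write_ild_tsv(pw, "results/pairwise_ild_siteA.tsv", dataset = "siteA")

# collapsed trees for the implicated pairs
trees <- lapply(names(alns), function(loc) {
  spec <- select_model(alns[[loc]])
  bt <- bootstrap_support(alns[[loc]], spec,
                          replicates = c(cob = 1000, its2 = 100, psba = 100)[[loc]],
                          seed = 410 + match(loc, names(alns)))
  bt
})
names(trees) <- names(alns)

sig <- names(pw)[vapply(pw, function(r) isTRUE(r$significant), logical(1))]
flagged <- character(0)
conflicts <- list()
for (nm in sig) {
  pair <- strsplit(nm, ".vs.", fixed = TRUE)[[1]]
  cr <- incongruent_taxa(trees[[pair[1]]], trees[[pair[2]]])
  conflicts[[nm]] <- cr
  tg <- tanglegram_order(trees[[pair[1]]], trees[[pair[2]]])
  message(sprintf("%s: irreconcilable taxa {%s}; tanglegram crossings %d",
                  nm, paste(cr$removed_taxa, collapse = ", "), tg$crossings))
  flagged <- union(flagged, cr$removed_taxa)
}
write_conflict_json(conflicts, "results/conflicts_siteA.json")

message("\nraw-sequence verification of flagged samples:")
cfg <- pipeline_config()
for (sid in sort(flagged)) {
  asg <- assign_groups(sid, alns, flagged_ids = setdiff(flagged, sid))
  cl <- classify_flagged_sample(asg, alns, roles)
  message("  ", sid, ": ", cl$verdict)
  if (cl$verdict == "reticulate") {
    ev <- phyloconflict:::background_evidence_for(cl, alns, rc, cfg)
    message(sprintf("    background populations (%s / %s): %s",
                    ev$nuclear_type, ev$organellar_type, ev$label))
  }
}
message("\nwritten: results/pairwise_ild_siteA.tsv, results/conflicts_siteA.json")
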