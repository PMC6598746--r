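#!/usr/bin/env Rscript
# Generate the synthetic study sites used throughout the analysis:
#   siteA - one planted hybrid among 21 samples (the positive case)
#   siteB - hybrid-free (the negative control)
#   siteC - no hybrid, one hyper-divergent chloroplast sequence (confounder)
#   siteD - incomplete-lineage-sorting scenario with NGS read counts
# Each site gets three marker alignments (slow organellar "cob", nuclear
# "its2", hypervariable organellar "psba") written as FASTA plus a JSON
# ground-truth table.

suppressMessages(library(phyloconflict))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("siteA: planted hybrid")
siteA <- simulate_multilocus_dataset(sim_params(prefix = "A"), seed = 101)
siteA$read_counts <- simulate_read_counts(siteA$truth, seed = 102)
write_dataset(siteA, file.path(out, "siteA"))
hy <- siteA$truth$sample_id[siteA$truth$is_hybrid]
message("  planted hybrid: ", hy,
        " (nuclear from ", siteA$truth$nuclear_donor[siteA$truth$is_hybrid],
        ", organellar from ", siteA$truth$organellar_donor[siteA$truth$is_hybrid], ")")

message("siteB: hybrid-free control")
siteB <- simulate_multilocus_dataset(sim_params(n_hybrids = 0, prefix = "B"),
                                     seed = 103)
write_dataset(siteB, file.path(out, "siteB"))

message("siteC: divergent-chloroplast confounder")
siteC <- simulate_multilocus_dataset(
  sim_params(n_hybrids = 0, n_divergent_chloroplast = 1, prefix = "C"),
  seed = 104)
write_dataset(siteC, file.path(out, "siteC"))
message("  confounder sample: ",
        siteC$truth$sample_id[siteC$truth$confounder != "none"])

message("siteD: incomplete-lineage-sorting scenario")
siteD <- simulate_ils_dataset(sim_params(prefix = "D"), seed = 105)
write_dataset(siteD, file.path(out, "siteD"))
message("  dominance-switched sample: ",
        siteD$truth$sample_id[siteD$truth$ils_switched])

for (site in c("siteA", "siteB", "siteC", "siteD")) {
  n <- length(read_alignment_fasta(file.path(out, site, "cob.fasta"),
                                   "cob")$sample_ids)
  message(site, ": ", n, " samples x loci cob(787)/its2(369)/psba(531)")
}
message("datasets written under ", out)
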