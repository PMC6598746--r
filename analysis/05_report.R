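#!/usr/bin/env Rscript
# Full orchestrated runs: the stepwise pipeline on each single site, plus
# the pooled (aggregate) analysis of the hybrid site and the clean control.
# Emits machine-readable JSON and a human-readable Markdown report per run.

suppressMessages(library(phyloconflict))

data_dir <- "results/data"
if (!dir.exists(data_dir)) stop("run analysis/01_simulate.R first")
loci <- c("cob", "its2", "psba")
read_site <- function(site) {
  alns <- lapply(loci, function(l) {
    read_alignment_fasta(file.path(data_dir, site, paste0(l, ".fasta")), l)
  })
  names(alns) <- loci
  alns
}
read_rc <- function(site) {
  f <- file.path(data_dir, site, "read_counts.csv")
  if (file.exists(f)) read_count_table(f) else NULL
}

dir.create("results/reports", showWarnings = FALSE, recursive = TRUE)
reports <- list()
for (site in c("siteA", "siteB", "siteD")) {
  cfg <- pipeline_config(seed = 500 + match(site, c("siteA", "siteB", "siteD")))
  rep <- run_site_pipeline(read_site(site), cfg, read_counts = read_rc(site),
                           dataset = site)
  print(rep)
  write_report_json(rep, file.path("results/reports", paste0(site, ".json")))
  write_report_markdown(rep, file.path("results/reports", paste0(site, ".md")))
  reports[[site]] <- rep
}

message("\naggregate run (siteA + siteB pooled):")
agg <- run_aggregate(list(siteA = read_site("siteA"), siteB = read_site("siteB")),
                     pipeline_config(seed = 510))
print(agg)
if (length(agg$flagged_samples)) {
  message("flagged samples trace back to: ",
          paste(names(agg$sample_site), agg$sample_site, sep = "@",
                collapse = ", "))
}
write_report_json(agg, "results/reports/aggregate.json")
write_report_markdown(agg, "results/reports/aggregate.md")

message("\nwritten: results/reports/*.json, results/reports/*.md")
message("site-level and aggregate flags should coincide: the pooled analysis ",
        "re-identifies exactly the samples the single-site run flagged.")
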