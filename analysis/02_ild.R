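#!/usr/bin/env Rscript
# Stage 1 of the stepwise screen: the gated three-way incongruence length
# difference (partition homogeneity) test on each site's concatenated
# supermatrix. Screening uses 100 permutation replicates (MaxTrees 1,000);
# p-values under 0.2 trigger the confirmatory stage with 1,000 replicates
# (MaxTrees 10,000).

suppressMessages(library(phyloconflict))

data_dir <- "results/data"
if (!dir.exists(data_dir)) stop("run analysis/01_simulate.R first")

read_site <- function(site) {
  loci <- c("cob", "its2", "psba")
  alns <- lapply(loci, function(l) {
    read_alignment_fasta(file.path(data_dir, site, paste0(l, ".fasta")), l)
  })
  names(alns) <- loci
  alns
}

rows <- list()
for (site in c("siteA", "siteB", "siteC", "siteD")) {
  alns <- read_site(site)
  pa <- concatenate_partitions(alns)
  res <- ild_gated(pa, seed = 200 + match(site, c("siteA", "siteB", "siteC", "siteD")))
  message(sprintf("%s: three-way ILD p = %.4g (stage %d, R = %d)",
                  site, res$p_value, res$stage, res$replicates))
  rows[[site]] <- data.frame(site = site, p_value = res$p_value,
                             stage = res$stage, replicates = res$replicates,
                             maxtrees = res$maxtrees,
                             observed_sum = res$observed_sum)
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/ild_threeway.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("\nwritten: results/ild_threeway.tsv")
message("expected pattern: only siteA (planted hybrid) and siteD (dominance",
        "-switched sample) reach small p-values; siteB and siteC do not.")
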