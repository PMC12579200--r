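#!/usr/bin/env Rscript
# Step 1: generate the synthetic 36-trio whole-exome cohort with known
# ground truth (spiked de novo SNVs at 1.4e-8/nt/generation, inherited
# variation, missed-heterozygote artifacts) and write it in the standard
# formats the rest of the workflow consumes.

suppressMessages(library(triodnv))

out_dir <- "results/synthetic"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20251)
sim <- simulate_cohort(cfg)

write_vcf(sim$cohort, file.path(out_dir, "cohort.vcf"))
write.table(sim$ped, file.path(out_dir, "cohort.ped"), sep = " ",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(sim$phenotypes, file.path(out_dir, "phenotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth$dnvs, file.path(out_dir, "truth_dnvs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth$artifacts, file.path(out_dir, "truth_artifacts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d trios: %d sites (%d spiked dnSNVs, %d missed-het artifacts)\n",
            cfg$n_trios, n_sites(sim$cohort), nrow(sim$truth$dnvs),
            nrow(sim$truth$artifacts)))
cat(sprintf("expected dnSNVs/proband: %.3f; spiked mean: %.3f\n",
            cfg$true_dnv_rate * cfg$exome_size * 2,
            mean(sim$truth$per_proband)))
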