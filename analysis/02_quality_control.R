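#!/usr/bin/env Rscript
# Step 2: cohort QC on the simulated VCF: genotype-level thresholds and
# missingness, sex imputation from X heterozygosity, KING-robust trio
# validation, and ancestry PCA against a simulated reference panel.

suppressMessages(library(triodnv))

in_dir <- "results/synthetic"
out_dir <- "results/qc"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cohort <- read_vcf(file.path(in_dir, "cohort.vcf"), annotation = "csq")
ped <- read_ped(file.path(in_dir, "cohort.ped"))
tdf <- trios(ped)

qc <- filter_variants(cohort, blacklist = NULL, qc_config())
write.table(qc$report, file.path(out_dir, "variant_qc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("variant QC: %d / %d sites pass\n",
            sum(qc$report$pass), nrow(qc$report)))

sex <- impute_sex(dosage_matrix(qc$cohort, "chrX"))
sex$reported <- ifelse(ped$sex[match(sex$sample, ped$iid)] == 1,
                       "male", "female")
sex$concordant <- sex$sex == sex$reported
write.table(sex, file.path(out_dir, "sex_check.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("sex check: %d / %d concordant with the pedigree\n",
            sum(sex$concordant, na.rm = TRUE), nrow(sex)))

auto <- dosage_matrix(qc$cohort, paste0("chr", 1:22))
kin <- validate_trios(auto, tdf, min_overlap = 1000)
write.table(kin, file.path(out_dir, "kinship.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("kinship: %d / %d trio relationship checks pass\n",
            sum(kin$ok), nrow(kin)))

# ancestry: project cohort probands onto a simulated reference panel
panel <- simulate_reference_panel(n_samples = 120, n_snps = 600, fst = 0.12,
                                  n_cohort = length(tdf$proband), seed = 20252)
pca <- ancestry_pca(panel$cohort, panel$ref, panel$labels)
pcs <- data.frame(id = tdf$proband, pca$cohort_pcs,
                  outlier = pca$outlier)
write.table(pcs, file.path(out_dir, "pcs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("ancestry PCA: %d outliers flagged\n", sum(pca$outlier)))

write_vcf(qc$cohort, file.path(out_dir, "filtered.vcf"))
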