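#' Quality-control configuration
#'
#' Thresholds follow standard trio-WES practice: genotype-level GQ >= 20 and
#' DP >= 20 (failing calls are set missing rather than removing the site),
#' site-level missingness < 10%, blacklist removal, sex-check F-statistic
#' cutoffs 0.8 (male) / 0.2 (female), KING relationship bands at
#' 2^-1.5, 2^-2.5, 2^-3.5, 2^-4.5, and a PCA outlier rule of any of the
#' first `n_pcs` principal components deviating more than `pc_outlier_sd`
#' standard deviations from the target-cluster centroid.
#'
#' @param min_gq,min_dp genotype-level thresholds (default 20, 20)
#' @param max_missingness site-level missingness bound (default 0.10; a site
#'   passes iff missingness is strictly below it)
#' @param sex_f_male,sex_f_female F-statistic cutoffs (default 0.8 / 0.2)
#' @param n_pcs number of leading PCs checked for outliers (default 5)
#' @param pc_outlier_sd centroid deviation threshold in SDs (default 6)
#' @export
qc_config <- function(min_gq = 20, min_dp = 20, max_missingness = 0.10,
                      sex_f_male = 0.8, sex_f_female = 0.2,
                      n_pcs = 5, pc_outlier_sd = 6) {
  assert_that(max_missingness >= 0 && max_missingness <= 1,
              "max_missingness must lie in [0, 1]")
  assert_that(sex_f_female < sex_f_male,
              "female F cutoff must be below the male cutoff")
  structure(as.list(environment()), class = "qc_config")
}

#' Variant-level QC: genotype thresholds, missingness, blacklist
#'
#' Calls with GQ below `min_gq` or DP below `min_dp` are set missing (they
#' then count toward missingness); a site passes iff its cohort-wide
#' missingness is strictly below `max_missingness` and it is outside the
#' blacklist. Filtering is idempotent: passing sites pass again unchanged.
#'
#' @param cohort a [trio_cohort()]
#' @param blacklist `GRanges` from [read_blacklist()] (or NULL)
#' @param config a [qc_config()]
#' @return list: `cohort` (passing sites, low-quality calls set missing),
#'   `report` (per-site pass/fail with primary reason and missingness)
#' @export
filter_variants <- function(cohort, blacklist = NULL, config = qc_config()) {
  low <- (!is.na(cohort$calls$gq) & cohort$calls$gq < config$min_gq) |
         (!is.na(cohort$calls$dp) & cohort$calls$dp < config$min_dp)
  calls <- cohort$calls
  calls$gt[low] <- NA
  miss <- rowMeans(is.na(calls$gt))
  in_bl <- if (is.null(blacklist)) rep(FALSE, n_sites(cohort)) else
    in_blacklist(cohort$sites$chrom, cohort$sites$pos, blacklist)
  reason <- rep("pass", n_sites(cohort))
  reason[miss >= config$max_missingness] <- "missingness"
  reason[in_bl] <- "blacklist"  # blacklist is the primary reason when both
  pass <- reason == "pass"
  report <- data.frame(chrom = cohort$sites$chrom, pos = cohort$sites$pos,
                       ref = cohort$sites$ref, alt = cohort$sites$alt,
                       missingness = miss, pass = pass, reason = reason,
                       stringsAsFactors = FALSE)
  filtered <- trio_cohort(cohort$sites, calls)
  list(cohort = subset_sites(filtered, pass), report = report)
}

#' Impute biological sex from X-chromosome heterozygosity
#'
#' Computes an inbreeding-style F statistic per sample over non-PAR X sites:
#' `F = 1 - observed het / expected het`, with the expectation from
#' Hardy-Weinberg at cohort allele frequencies. `F > sex_f_male` is called
#' male, `F < sex_f_female` female, otherwise undetermined. Fewer than
#' `min_sites` informative (polymorphic, non-missing) sites gives
#' undetermined with a warning.
#'
#' @param x_gt dosage matrix (sites x samples) of non-PAR X sites
#' @param config a [qc_config()]
#' @param min_sites minimum informative sites (default 50)
#' @return data.frame: sample, n_sites, f, sex
#' @export
impute_sex <- function(x_gt, config = qc_config(), min_sites = 50) {
  p <- rowMeans(x_gt, na.rm = TRUE) / 2
  informative <- !is.na(p) & p > 0 & p < 1
  exp_het_site <- 2 * p * (1 - p)
  out <- lapply(colnames(x_gt), function(s) {
    ok <- informative & !is.na(x_gt[, s])
    n <- sum(ok)
    if (n < min_sites) {
      warning(sprintf("sample %s: only %d informative X sites; sex undetermined",
                      s, n))
      return(data.frame(sample = s, n_sites = n, f = NA_real_,
                        sex = "undetermined", stringsAsFactors = FALSE))
    }
    obs <- sum(x_gt[ok, s] == 1)
    expd <- sum(exp_het_site[ok])
    f <- 1 - obs / expd
    sex <- if (f > config$sex_f_male) "male"
           else if (f < config$sex_f_female) "female"
           else "undetermined"
    data.frame(sample = s, n_sites = n, f = f, sex = sex,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' KING-robust kinship coefficient for one sample pair
#'
#' Estimator from genotype concordance counts over shared non-missing
#' autosomal sites: `phi = (N_het,het - 2 * N_opposite_hom) /
#' (N_het_i + N_het_j)`. Robust to population structure; ~0.5 for
#' duplicates, ~0.25 for parent-offspring, ~0 for unrelated pairs.
#'
#' @param gi,gj dosage vectors (0/1/2, NA missing) for the two samples
#' @param min_overlap minimum shared non-missing sites (default 1000)
#' @return list: `phi`, `n` (shared sites), `class` (duplicate /
#'   first_degree / second_degree / third_degree / unrelated / unclassified)
#' @export
king_kinship <- function(gi, gj, min_overlap = 1000) {
  ok <- !is.na(gi) & !is.na(gj)
  n <- sum(ok)
  if (n < min_overlap)
    return(list(phi = NA_real_, n = n, class = "unclassified"))
  gi <- gi[ok]; gj <- gj[ok]
  n_hh <- sum(gi == 1 & gj == 1)
  n_opp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  denom <- sum(gi == 1) + sum(gj == 1)
  if (denom == 0)
    return(list(phi = NA_real_, n = n, class = "unclassified"))
  phi <- (n_hh - 2 * n_opp) / denom
  list(phi = phi, n = n, class = kinship_class(phi))
}

#' Classify a kinship coefficient into standard KING bands
#' @param phi kinship coefficient
#' @export
kinship_class <- function(phi) {
  cuts <- 2^-c(1.5, 2.5, 3.5, 4.5)  # 0.354, 0.177, 0.0884, 0.0442
  if (is.na(phi)) "unclassified"
  else if (phi > cuts[1]) "duplicate"
  else if (phi > cuts[2]) "first_degree"
  else if (phi > cuts[3]) "second_degree"
  else if (phi > cuts[4]) "third_degree"
  else "unrelated"
}

#' Validate trio relationships by pairwise kinship
#'
#' Asserts, per trio, that both parent-proband pairs fall in the
#' first-degree band and that the parents are unrelated (non-consanguineous).
#'
#' @param gt autosomal dosage matrix (sites x samples)
#' @param trio_df data.frame from [trios()]
#' @param min_overlap see [king_kinship()]
#' @return data.frame, one row per checked pair, with `ok` flags
#' @export
validate_trios <- function(gt, trio_df, min_overlap = 1000) {
  rows <- list()
  for (i in seq_len(nrow(trio_df))) {
    tr <- trio_df[i, ]
    pairs <- list(c(tr$proband, tr$father, "parent_child"),
                  c(tr$proband, tr$mother, "parent_child"),
                  c(tr$father, tr$mother, "parents"))
    for (p in pairs) {
      k <- king_kinship(gt[, p[1]], gt[, p[2]], min_overlap)
      expected <- if (p[3] == "parent_child") "first_degree" else "unrelated"
      rows[[length(rows) + 1L]] <- data.frame(
        family = tr$family_id, id1 = p[1], id2 = p[2], role = p[3],
        phi = k$phi, class = k$class, ok = identical(k$class, expected),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Ancestry PCA with reference projection and outlier flags
#'
#' SNP columns are centred by mean dosage and scaled by
#' `sqrt(2 * p * (1 - p))` with `p` the reference allele frequency;
#' monomorphic SNPs are dropped. The SVD is taken on the standardized
#' reference panel and cohort samples are projected onto the reference
#' axes. A cohort sample is flagged an outlier if any of the first `n_pcs`
#' scores deviates more than `pc_outlier_sd` SDs from the target-cluster
#' centroid (cluster statistics from the reference samples of
#' `target_cluster`).
#'
#' @param cohort_gt cohort dosage matrix (samples x SNPs)
#' @param ref_gt reference dosage matrix (samples x SNPs, same SNP order)
#' @param ref_labels cluster label per reference sample
#' @param target_cluster label of the expected ancestry cluster (default 1)
#' @param config a [qc_config()]
#' @return list: `cohort_pcs`, `ref_pcs`, `outlier` (logical per cohort
#'   sample), `rotation`, `kept_snps`
#' @export
ancestry_pca <- function(cohort_gt, ref_gt, ref_labels,
                         target_cluster = 1, config = qc_config()) {
  assert_that(ncol(cohort_gt) == ncol(ref_gt),
              "cohort and reference must share the SNP set")
  p <- colMeans(ref_gt, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  assert_that(any(keep), "no polymorphic SNPs shared with the reference")
  p <- p[keep]
  scale_fac <- sqrt(2 * p * (1 - p))
  std <- function(m) sweep(sweep(m[, keep, drop = FALSE], 2, 2 * p), 2,
                           scale_fac, "/")
  ref_std <- std(ref_gt)
  sv <- svd(ref_std)
  n_pcs <- min(config$n_pcs, ncol(sv$v))
  rot <- sv$v[, seq_len(n_pcs), drop = FALSE]
  ref_pcs <- ref_std %*% rot
  cohort_pcs <- std(cohort_gt) %*% rot
  colnames(ref_pcs) <- colnames(cohort_pcs) <- paste0("PC", seq_len(n_pcs))
  tgt <- ref_labels == target_cluster
  centroid <- colMeans(ref_pcs[tgt, , drop = FALSE])
  sds <- apply(ref_pcs[tgt, , drop = FALSE], 2, sd)
  dev <- sweep(abs(sweep(cohort_pcs, 2, centroid)), 2, sds, "/")
  outlier <- apply(dev > config$pc_outlier_sd, 1, any)
  list(cohort_pcs = cohort_pcs, ref_pcs = ref_pcs, outlier = outlier,
       rotation = rot, kept_snps = which(keep))
}

#' Dosage matrix of a cohort restricted to a chromosome set
#'
#' Convenience accessor: sites x samples dosage matrix for, e.g., autosomes
#' (kinship) or chrX (sex imputation).
#'
#' @param cohort a [trio_cohort()]
#' @param chroms chromosome names to keep (NULL = all)
#' @export
dosage_matrix <- function(cohort, chroms = NULL) {
  idx <- if (is.null(chroms)) rep(TRUE, n_sites(cohort)) else
    cohort$sites$chrom %in% chroms
  cohort$calls$gt[idx, , drop = FALSE]
}
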