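#' De novo filter-cascade configuration
#'
#' Defaults mirror the published cascade: retained classes missense,
#' nonsense, splice, synonymous; site observed in exactly one proband
#' cohort-wide; population MAF < 1% (or absent from the reference
#' population); alt allele in >= 30% of proband reads; <= 5% of each
#' parent's reads; minimum base quality Phred 20; Fisher strand-bias below
#' phred 60; and a per-proband cap of 5 calls (flag only).
#'
#' @param max_af population-frequency cutoff (default 0.01, strict `<`)
#' @param min_proband_alt_fraction kept when `>=` (default 0.30)
#' @param max_parent_alt_fraction removed when `>` (default 0.05)
#' @param min_base_q Phred floor for alt-read base quality (default 20)
#' @param strand_bias_phred_max fail when `-10 log10 p >=` this (default 60)
#' @param max_dnvs_per_proband flag threshold (default 5)
#' @param retained_classes consequence classes kept by the class filter
#' @param cadd_deleterious_cutoff top-1% deleteriousness boundary
#'   (default 20, strict `>`)
#' @export
dnv_filter_config <- function(max_af = 0.01,
                              min_proband_alt_fraction = 0.30,
                              max_parent_alt_fraction = 0.05,
                              min_base_q = 20,
                              strand_bias_phred_max = 60,
                              max_dnvs_per_proband = 5,
                              retained_classes = c("missense", "nonsense",
                                                   "splice", "synonymous"),
                              cadd_deleterious_cutoff = 20) {
  fr <- c(max_af, min_proband_alt_fraction, max_parent_alt_fraction)
  assert_that(all(fr >= 0 & fr <= 1), "fractions must lie in [0, 1]")
  assert_that(min_base_q >= 0 && strand_bias_phred_max >= 0 &&
              cadd_deleterious_cutoff >= 0, "cutoffs must be non-negative")
  structure(as.list(environment()), class = "dnv_filter_config")
}

dnv_filter_names <- c("class", "singleton", "maf", "proband_support",
                      "parent_support", "base_quality", "strand_bias")

#' Detect Mendelian-violation candidates
#'
#' One candidate per (proband, site) where the proband call is heterozygous
#' and both parental calls are homozygous reference, with all three calls
#' non-missing. Sites with a missing call in a trio are skipped for that
#' trio (counted in the returned attribute `n_skipped_missing`).
#'
#' @param cohort a QC-passing [trio_cohort()]
#' @param trio_df data.frame from [trios()]
#' @return data.frame of candidates: proband/father/mother ids, site index
#'   and annotation columns, trio read support
#' @export
detect_mendelian_candidates <- function(cohort, trio_df) {
  gt <- cohort$calls$gt
  out <- list(); skipped <- 0L
  for (i in seq_len(nrow(trio_df))) {
    tr <- trio_df[i, ]
    g <- gt[, c(tr$proband, tr$father, tr$mother), drop = FALSE]
    any_missing <- rowSums(is.na(g)) > 0
    hit <- !any_missing & g[, 1] == 1 & g[, 2] == 0 & g[, 3] == 0
    skipped <- skipped + sum(any_missing)
    if (!any(hit)) next
    idx <- which(hit)
    s <- cohort$sites[idx, , drop = FALSE]
    grab <- function(field, sample) {
      m <- cohort$calls[[field]]
      if (is.null(m)) rep(NA_real_, length(idx)) else m[idx, sample]
    }
    out[[length(out) + 1L]] <- data.frame(
      proband = tr$proband, father = tr$father, mother = tr$mother,
      site = idx, chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
      gene = s$gene, class = s$class, af = s$af, af_absent = s$af_absent,
      cadd = s$cadd,
      p_ad_ref = grab("ad_ref", tr$proband), p_ad_alt = grab("ad_alt", tr$proband),
      f_ad_ref = grab("ad_ref", tr$father), f_ad_alt = grab("ad_alt", tr$father),
      m_ad_ref = grab("ad_ref", tr$mother), m_ad_alt = grab("ad_alt", tr$mother),
      p_ref_fwd = grab("ad_ref_fwd", tr$proband),
      p_ref_rev = grab("ad_ref_rev", tr$proband),
      p_alt_fwd = grab("ad_alt_fwd", tr$proband),
      p_alt_rev = grab("ad_alt_rev", tr$proband),
      min_bq = grab("min_bq", tr$proband),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame()
  attr(res, "n_skipped_missing") <- skipped
  res
}

alt_fraction <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  ifelse(is.na(tot) | tot == 0, NA_real_, ad_alt / tot)
}

#' Apply the candidate filter cascade with a per-filter trail
#'
#' Filters, each recorded pass / fail / not-evaluable:
#' \enumerate{
#'   \item class: consequence class among `retained_classes`
#'   \item singleton: the site's alt allele carried by exactly one proband
#'     cohort-wide (proband genotypes only; parental carriers already fail
#'     the Mendelian step)
#'   \item maf: population frequency strictly below `max_af`, or reported
#'     absent from the reference population
#'   \item proband_support: alt reads / (ref + alt reads) `>=` 30% (boundary
#'     kept)
#'   \item parent_support: each parent's alt fraction `<=` 5% (boundary
#'     kept; `> 5%` removed)
#'   \item base_quality: minimum alt base quality `>=` Phred 20 when
#'     available
#'   \item strand_bias: Fisher exact test on the proband's forward/reverse x
#'     ref/alt read table; fail when `-10 log10 p >=`
#'     `strand_bias_phred_max`
#' }
#' A candidate passes overall iff no filter records fail; a filter whose
#' inputs are unavailable records not-evaluable and cannot fail the
#' candidate. The pass set is invariant to filter order.
#'
#' @param candidates data.frame from [detect_mendelian_candidates()]
#' @param cohort the [trio_cohort()] the candidates came from (for the
#'   cohort-wide singleton count)
#' @param trio_df data.frame from [trios()]
#' @param config a [dnv_filter_config()]
#' @return candidates with `filter_*` outcome columns, `status`
#'   (pass / fail) and a compact `filter_trail` string
#' @export
apply_dnv_filters <- function(candidates, cohort, trio_df,
                              config = dnv_filter_config()) {
  if (nrow(candidates) == 0) {
    candidates$status <- character(0)
    candidates$filter_trail <- character(0)
    return(candidates)
  }
  n <- nrow(candidates)
  res <- matrix("not-evaluable", n, length(dnv_filter_names),
                dimnames = list(NULL, dnv_filter_names))
  pf <- function(x) ifelse(is.na(x), "not-evaluable", ifelse(x, "pass", "fail"))

  res[, "class"] <- pf(candidates$class %in% config$retained_classes)

  # singleton: count probands carrying the alt allele at the site
  gt_prob <- cohort$calls$gt[, trio_df$proband, drop = FALSE]
  carriers <- rowSums(gt_prob >= 1, na.rm = TRUE)
  res[, "singleton"] <- pf(carriers[candidates$site] == 1)

  res[, "maf"] <- pf(ifelse(candidates$af_absent, TRUE,
                            ifelse(is.na(candidates$af), NA,
                                   candidates$af < config$max_af)))

  paf <- alt_fraction(candidates$p_ad_ref, candidates$p_ad_alt)
  res[, "proband_support"] <- pf(ifelse(is.na(paf), NA,
    paf >= config$min_proband_alt_fraction))

  faf <- alt_fraction(candidates$f_ad_ref, candidates$f_ad_alt)
  maf_frac <- alt_fraction(candidates$m_ad_ref, candidates$m_ad_alt)
  par_ok <- ifelse(is.na(faf) | is.na(maf_frac), NA,
                   faf <= config$max_parent_alt_fraction &
                   maf_frac <= config$max_parent_alt_fraction)
  res[, "parent_support"] <- pf(par_ok)

  res[, "base_quality"] <- pf(ifelse(is.na(candidates$min_bq), NA,
    candidates$min_bq >= config$min_base_q))

  sb <- vapply(seq_len(n), function(i) {
    m <- matrix(c(candidates$p_ref_fwd[i], candidates$p_ref_rev[i],
                  candidates$p_alt_fwd[i], candidates$p_alt_rev[i]), 2)
    if (any(is.na(m))) return(NA)
    phred <- -10 * log10(max(fisher.test(m)$p.value, 1e-300))
    phred < config$strand_bias_phred_max
  }, logical(1))
  res[, "strand_bias"] <- pf(sb)

  candidates[paste0("filter_", dnv_filter_names)] <-
    as.data.frame(res, stringsAsFactors = FALSE)
  candidates$status <- ifelse(apply(res == "fail", 1, any), "fail", "pass")
  candidates$filter_trail <- apply(res, 1, function(r)
    paste(paste0(dnv_filter_names, "=", r), collapse = ";"))
  candidates
}

#' Flag probands exceeding the per-proband call cap
#'
#' Probands with more than `max_dnvs_per_proband` passing calls are flagged
#' for exclusion; this is a flag, not a removal.
#'
#' @param candidates filtered candidates (from [apply_dnv_filters()])
#' @param config a [dnv_filter_config()]
#' @return data.frame: proband, n_pass, flagged
#' @export
per_proband_cap <- function(candidates, config = dnv_filter_config()) {
  passing <- candidates[!is.null(candidates$status) &
                          candidates$status == "pass", , drop = FALSE]
  if (nrow(passing) == 0)
    return(data.frame(proband = character(), n_pass = integer(),
                      flagged = logical()))
  tab <- table(passing$proband)
  data.frame(proband = names(tab), n_pass = as.integer(tab),
             flagged = as.integer(tab) > config$max_dnvs_per_proband,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Deleteriousness tier from the CADD PHRED score
#'
#' `top1pct` iff CADD PHRED strictly above the cutoff (default 20: the top
#' 1% of possible human SNVs); `unscored` when the score is missing.
#'
#' @param cadd numeric vector of CADD PHRED scores (NA = unscored)
#' @param config a [dnv_filter_config()]
#' @export
classify_deleteriousness <- function(cadd, config = dnv_filter_config()) {
  ifelse(is.na(cadd), "unscored",
         ifelse(cadd > config$cadd_deleterious_cutoff, "top1pct", "below"))
}

#' Per-proband and per-class summary of passing candidates
#'
#' @param candidates candidate table with `status` and `class` columns (or
#'   a pass-only table without `status`)
#' @param all_probands character vector of every cohort proband, so that
#'   zero-count probands appear in the histogram
#' @return list: `per_proband` (named counts incl. zeros),
#'   `count_histogram` (table of probands by dnSNV count), `class_counts`
#' @export
summarize_candidates <- function(candidates, all_probands) {
  passing <- if ("status" %in% names(candidates))
    candidates[candidates$status == "pass", , drop = FALSE] else candidates
  per <- setNames(integer(length(all_probands)), all_probands)
  if (nrow(passing) > 0) {
    tab <- table(passing$proband)
    per[names(tab)] <- as.integer(tab)
  }
  hist <- table(factor(per, levels = 0:max(c(per, 0))))
  cls <- setNames(integer(4), c("missense", "nonsense", "splice", "synonymous"))
  if (nrow(passing) > 0) {
    tab <- table(passing$class)
    cls[intersect(names(tab), names(cls))] <-
      as.integer(tab[intersect(names(tab), names(cls))])
  }
  list(per_proband = per, count_histogram = hist, class_counts = cls)
}
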