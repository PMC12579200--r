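#' De novo mutation rate with 95% confidence interval
#'
#' `rate = (n_dnvs / n_probands) / (exome_size * n_gametogeneses)`: the mean
#' dnSNV count per proband divided by the diploid mutational target (the
#' coding exome times two gametogeneses). The default interval
#' (`method = "normal-counts"`) is the normal approximation on the
#' per-proband counts, `mean +/- 1.96 sd/sqrt(n)`, rescaled by the target
#' size; `method = "poisson-exact"` uses chi-square bounds on the total
#' count instead.
#'
#' @param n_dnvs total dnSNV count (ignored when `per_proband_counts` given)
#' @param n_probands number of probands
#' @param exome_size coding-exome size in bp (default 33,828,798,
#'   RefSeq hg19)
#' @param n_gametogeneses number of gametogeneses (default 2)
#' @param per_proband_counts optional integer vector of per-proband counts;
#'   required for the normal-counts interval
#' @param method `"normal-counts"` (default) or `"poisson-exact"`
#' @param conf confidence level (default 0.95)
#' @return list: `rate`, `ci` (length 2, lower clamped at 0),
#'   `mean_per_proband`, `method`
#' @export
mutation_rate <- function(n_dnvs = NULL, n_probands = NULL,
                          exome_size = 33828798, n_gametogeneses = 2,
                          per_proband_counts = NULL,
                          method = c("normal-counts", "poisson-exact"),
                          conf = 0.95) {
  method <- match.arg(method)
  if (!is.null(per_proband_counts)) {
    if (!is.null(n_dnvs))
      assert_that(sum(per_proband_counts) == n_dnvs,
                  "per_proband_counts does not sum to n_dnvs")
    n_dnvs <- sum(per_proband_counts)
    if (is.null(n_probands)) n_probands <- length(per_proband_counts)
    assert_that(n_probands == length(per_proband_counts),
                "n_probands does not match per_proband_counts length")
  }
  assert_that(!is.null(n_dnvs) && !is.null(n_probands) && n_probands > 0,
              "need n_dnvs and n_probands > 0")
  assert_that(exome_size > 0, "exome_size must be positive")
  target <- exome_size * n_gametogeneses
  mean_pp <- n_dnvs / n_probands
  rate <- mean_pp / target
  z <- qnorm(1 - (1 - conf) / 2)
  if (method == "normal-counts") {
    assert_that(!is.null(per_proband_counts),
                "normal-counts interval needs per_proband_counts")
    se <- sd(per_proband_counts) / sqrt(n_probands)
    ci <- c(max(0, mean_pp - z * se), mean_pp + z * se) / target
  } else {
    a <- 1 - conf
    lo <- if (n_dnvs == 0) 0 else qchisq(a / 2, 2 * n_dnvs) / 2
    hi <- qchisq(1 - a / 2, 2 * (n_dnvs + 1)) / 2
    ci <- c(lo, hi) / n_probands / target
  }
  list(rate = rate, ci = ci, mean_per_proband = mean_pp, method = method)
}

#' Non-synonymous : synonymous ratio with two-count Poisson exact test
#'
#' Non-synonymous = missense + nonsense + splice. The exact test of rate
#' ratio 1 conditions on the total: given `nonsyn + syn` events, the
#' non-synonymous count is Binomial(total, 1/2) under the null (this is the
#' standard two-count Poisson exact test); the ratio CI is the binomial
#' proportion CI transformed by `p / (1 - p)`.
#'
#' @param class_counts named counts with at least `synonymous`; remaining
#'   classes among missense/nonsense/splice count as non-synonymous
#' @param n_probands optional; adds per-proband averages to the output
#' @return list: `nonsyn`, `syn`, `ratio` (Inf when syn = 0), `p`
#'   (two-sided), `ci` (ratio scale), and per-proband means when
#'   `n_probands` given
#' @export
nonsyn_syn_ratio <- function(class_counts, n_probands = NULL) {
  syn <- class_counts[["synonymous"]] %||% 0
  nonsyn <- sum(unlist(class_counts[intersect(names(class_counts),
                                              c("missense", "nonsense",
                                                "splice"))]))
  assert_that(syn >= 0, "synonymous count must be non-negative")
  total <- nonsyn + syn
  if (total == 0)
    return(list(nonsyn = 0, syn = 0, ratio = NaN, p = 1, ci = c(NA, NA)))
  bt <- stats::binom.test(nonsyn, total, 0.5)
  ci <- bt$conf.int / (1 - bt$conf.int)
  out <- list(nonsyn = nonsyn, syn = syn,
              ratio = if (syn == 0) Inf else nonsyn / syn,
              p = bt$p.value, ci = as.numeric(ci))
  if (!is.null(n_probands)) {
    out$nonsyn_per_proband <- nonsyn / n_probands
    out$syn_per_proband <- syn / n_probands
  }
  out
}

# ---------------------------------------------------------------------------
# Trinucleotide-context mutational model

#' Uniform trinucleotide rate table (for tests and toy models)
#'
#' One row per (trinucleotide context, alt) substitution, all at rate `mu`.
#'
#' @param mu per-generation probability per substitution
#' @return data.frame: context, alt, rate
#' @export
uniform_rate_table <- function(mu = 1e-8) {
  bases <- c("A", "C", "G", "T")
  ctx <- expand.grid(l = bases, m = bases, r = bases, alt = bases,
                     stringsAsFactors = FALSE)
  ctx <- ctx[ctx$m != ctx$alt, ]
  data.frame(context = paste0(ctx$l, ctx$m, ctx$r), alt = ctx$alt,
             rate = mu, stringsAsFactors = FALSE)
}

#' Per-gene, per-class dnSNV probability table from a mutational model
#'
#' For each gene model, every possible SNV (3 alts per site) is enumerated
#' over all CDS positions plus intronic positions within the splice window
#' of each exon boundary. Substitutions are classified by codon translation
#' (synonymous / missense / nonsense; a lost stop codon counts as
#' missense-like "other" is avoided by classing stop-loss with missense)
#' unless the position lies in the splice window, which takes precedence;
#' stop-loss substitutions are classed with missense. The probability of
#' class c in gene g is the sum of the context-specific rates of all
#' substitutions classified c, so the classes partition the total rate mass.
#' Positions containing ambiguous bases (N) or lacking trinucleotide
#' context are skipped and counted.
#'
#' @param gene_models list of gene models as from [simulate_gene_models()]:
#'   each has `name`, `seq`, `exons` (1-based start/end within `seq`)
#' @param rate_table data.frame (context, alt, rate): per-generation
#'   probability of each trinucleotide-context substitution per site
#' @param splice_window `c(intronic, exonic)` distances from each
#'   exon/intron boundary treated as splice (default 8 intronic, 3 exonic)
#' @return data.frame (gene, class, probability), class in
#'   missense / nonsense / splice / synonymous; attribute `n_skipped`
#' @export
build_probability_table <- function(gene_models, rate_table,
                                    splice_window = c(intronic = 8, exonic = 3)) {
  assert_that(all(c("context", "alt", "rate") %in% names(rate_table)),
              "rate_table needs context, alt, rate columns")
  assert_that(all(rate_table$rate >= 0), "rates must be non-negative")
  rates <- setNames(rate_table$rate, paste(rate_table$context,
                                           rate_table$alt, sep = ">"))
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  out <- list(); skipped <- 0L
  for (gm in gene_models) {
    seq <- strsplit(gm$seq, "")[[1]]
    ex <- gm$exons[order(gm$exons$start), , drop = FALSE]
    cds_pos <- unlist(lapply(seq_len(nrow(ex)),
                             function(e) ex$start[e]:ex$end[e]))
    assert_that(length(cds_pos) %% 3 == 0,
                "CDS length of %s not divisible by 3", gm$name)
    cds_index <- setNames(seq_along(cds_pos), cds_pos)

    # splice-window membership (genomic coordinates in seq)
    splice_pos <- integer(0)
    for (e in seq_len(nrow(ex))) {
      # donor side (exon end -> intron) unless last exon; intronic run
      # clamped to the intron
      if (e < nrow(ex)) {
        splice_pos <- c(splice_pos,
                        (ex$end[e] - splice_window[["exonic"]] + 1):ex$end[e],
                        (ex$end[e] + 1):min(ex$end[e] + splice_window[["intronic"]],
                                            ex$start[e + 1] - 1))
      }
      # acceptor side (intron -> exon start) unless first exon
      if (e > 1) {
        splice_pos <- c(splice_pos,
                        max(ex$start[e] - splice_window[["intronic"]],
                            ex$end[e - 1] + 1):(ex$start[e] - 1),
                        ex$start[e]:(ex$start[e] + splice_window[["exonic"]] - 1))
      }
    }
    splice_pos <- unique(splice_pos)
    eval_pos <- sort(unique(c(cds_pos, splice_pos)))

    acc <- c(missense = 0, nonsense = 0, splice = 0, synonymous = 0)
    for (p in eval_pos) {
      if (p < 2 || p > length(seq) - 1) { skipped <- skipped + 3L; next }
      tri <- seq[(p - 1):(p + 1)]
      if (any(!tri %in% bases)) { skipped <- skipped + 3L; next }
      ctx <- paste(tri, collapse = "")
      for (alt in setdiff(bases, seq[p])) {
        rate <- rates[paste(ctx, alt, sep = ">")]
        if (is.na(rate)) { skipped <- skipped + 1L; next }
        cls <- if (p %in% splice_pos) "splice" else {
          ci <- cds_index[[as.character(p)]]
          codon_i <- (ci - 1) %/% 3
          within <- (ci - 1) %% 3
          codon <- seq[cds_pos[codon_i * 3 + 1:3]]
          new_codon <- codon; new_codon[within + 1] <- alt
          aa_old <- code[[paste(codon, collapse = "")]]
          aa_new <- code[[paste(new_codon, collapse = "")]]
          if (aa_new == aa_old) "synonymous"
          else if (aa_new == "*") "nonsense"
          else "missense"  # includes stop-loss substitutions
        }
        acc[cls] <- acc[cls] + rate
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      gene = gm$name, class = names(acc), probability = unname(acc),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "n_skipped") <- skipped
  res
}

#' Observed-vs-expected class enrichment under a Poisson framework
#'
#' `expected(class) = 2 * n_probands * sum over genes of P(gene, class)`
#' (two transmitting copies per proband); the p-value is the Poisson upper
#' tail `P(X >= observed)` at that expectation, and Benjamini-Hochberg FDR
#' is applied across the tested classes.
#'
#' @param observed named vector of observed counts per class
#' @param prob_table data.frame (gene, class, probability) as from
#'   [build_probability_table()]; per-gamete per-generation probabilities
#' @param n_probands cohort size
#' @return data.frame: class, observed, expected, enrichment_ratio, p, p_adj
#' @export
class_enrichment <- function(observed, prob_table, n_probands) {
  assert_that(all(c("gene", "class", "probability") %in% names(prob_table)),
              "prob_table needs gene, class, probability columns")
  classes <- names(observed)
  expected <- vapply(classes, function(cl)
    2 * n_probands * sum(prob_table$probability[prob_table$class == cl]),
    numeric(1))
  p <- vapply(seq_along(classes), function(i) {
    if (expected[i] == 0) {
      if (observed[i] > 0) {
        warning(sprintf("class %s: expected 0 but observed %d", classes[i],
                        observed[i]))
        return(0)
      }
      return(1)
    }
    ppois(observed[i] - 1, expected[i], lower.tail = FALSE)
  }, numeric(1))
  data.frame(class = classes, observed = as.integer(observed),
             expected = expected,
             enrichment_ratio = ifelse(expected > 0, observed / expected, NA),
             p = p, p_adj = bh_fdr(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with enforced monotonicity; input order preserved.
#' Values outside [0, 1] are an error.
#'
#' @param p numeric vector of p-values
#' @return adjusted p-values, same order as the input
#' @export
bh_fdr <- function(p) {
  assert_that(all(!is.na(p)) && all(p >= 0 & p <= 1),
              "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
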