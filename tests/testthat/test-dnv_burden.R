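table1_counts <- function() c(rep(0L, 15), rep(1L, 10), rep(2L, 9), rep(3L, 2))

test_that("mutation rate reproduces the cohort arithmetic", {
  res <- mutation_rate(per_proband_counts = table1_counts())
  expect_equal(signif(res$rate, 3), 1.40e-8)
  expect_equal(round(res$mean_per_proband, 2), 0.94)
  # normal-approximation interval on the per-proband counts
  expect_equal(res$ci, c(9.350526e-09, 1.856783e-08), tolerance = 1e-6)

  zero <- mutation_rate(n_dnvs = 0, n_probands = 36, method = "poisson-exact")
  expect_equal(zero$rate, 0)
  expect_equal(zero$ci[1], 0)
  expect_gt(zero$ci[2], 0)
})

test_that("mutation rate scales linearly in counts, inversely in exome size", {
  base <- mutation_rate(n_dnvs = 30, n_probands = 30, exome_size = 1e7,
                        method = "poisson-exact")
  expect_equal(mutation_rate(n_dnvs = 60, n_probands = 30, exome_size = 1e7,
                             method = "poisson-exact")$rate, 2 * base$rate)
  expect_equal(mutation_rate(n_dnvs = 30, n_probands = 30, exome_size = 2e7,
                             method = "poisson-exact")$rate, base$rate / 2)
  expect_equal(mutation_rate(n_dnvs = 30, n_probands = 60, exome_size = 1e7,
                             method = "poisson-exact")$rate, base$rate / 2)
})

test_that("nonsyn:syn ratio and exact test", {
  res <- nonsyn_syn_ratio(c(missense = 17, nonsense = 0, splice = 3,
                            synonymous = 14), n_probands = 36)
  expect_equal(round(res$ratio, 2), 1.43)
  expect_equal(round(res$nonsyn_per_proband, 2), 0.56)
  expect_equal(round(res$syn_per_proband, 2), 0.39)

  sym <- nonsyn_syn_ratio(c(missense = 5, synonymous = 5))
  expect_equal(sym$ratio, 1)
  expect_equal(sym$p, 1)

  skewed <- nonsyn_syn_ratio(c(missense = 3, synonymous = 0))
  expect_equal(skewed$ratio, Inf)
  # conditional binomial: one-sided tail 0.125, two-sided 0.25
  expect_equal(skewed$p, 0.25)
})

test_that("the exact test matches base R's two-count Poisson test", {
  set.seed(30)
  for (i in 1:20) {
    a <- rpois(1, 15); b <- rpois(1, 10)
    if (a + b == 0) next
    ours <- nonsyn_syn_ratio(c(missense = a, synonymous = b))
    ref <- poisson.test(c(a, b), c(1, 1))
    expect_equal(ours$p, ref$p.value)
  }
})

# Independent brute-force oracle for the probability-table builder: walks
# every site and alternative allele with plain loops, translating codons via
# Biostrings and re-deriving splice membership from first principles.
oracle_prob_table <- function(gm, mu, intronic = 8, exonic = 3) {
  seq <- strsplit(gm$seq, "")[[1]]
  ex <- gm$exons[order(gm$exons$start), ]
  cds_pos <- unlist(Map(`:`, ex$start, ex$end))
  cds <- paste(seq[cds_pos], collapse = "")
  in_splice <- function(p) {
    for (e in seq_len(nrow(ex))) {
      if (e < nrow(ex)) {
        if (p >= ex$end[e] - exonic + 1 && p <= ex$end[e]) return(TRUE)
        if (p > ex$end[e] && p <= min(ex$end[e] + intronic,
                                      ex$start[e + 1] - 1)) return(TRUE)
      }
      if (e > 1) {
        if (p < ex$start[e] && p >= max(ex$start[e] - intronic,
                                        ex$end[e - 1] + 1)) return(TRUE)
        if (p >= ex$start[e] && p <= ex$start[e] + exonic - 1) return(TRUE)
      }
    }
    FALSE
  }
  acc <- c(missense = 0, nonsense = 0, splice = 0, synonymous = 0)
  all_pos <- sort(unique(c(cds_pos, Filter(in_splice, seq_len(length(seq))))))
  for (p in all_pos) {
    if (p < 2 || p > length(seq) - 1) next
    for (alt in setdiff(c("A", "C", "G", "T"), seq[p])) {
      if (in_splice(p)) { acc["splice"] <- acc["splice"] + mu; next }
      ci <- match(p, cds_pos)
      codon_start <- ((ci - 1) %/% 3) * 3 + 1
      codon <- substr(cds, codon_start, codon_start + 2)
      mut <- codon
      substr(mut, (ci - 1) %% 3 + 1, (ci - 1) %% 3 + 1) <- alt
      aa_old <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                                   no.init.codon = TRUE))
      aa_new <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                                   no.init.codon = TRUE))
      cls <- if (aa_new == aa_old) "synonymous"
             else if (aa_new == "*") "nonsense" else "missense"
      acc[cls] <- acc[cls] + mu
    }
  }
  acc
}

test_that("probability table equals exhaustive re-enumeration on toy genes", {
  genes <- simulate_gene_models(n_genes = 20, n_exons = c(1, 2, 3), seed = 37)
  mu <- 2.5e-9
  tab <- build_probability_table(genes, uniform_rate_table(mu))
  for (gm in genes) {
    expected <- oracle_prob_table(gm, mu)
    got <- tab[tab$gene == gm$name, ]
    expect_equal(setNames(got$probability, got$class), expected[got$class],
                 tolerance = 1e-12, info = gm$name)
  }
})

test_that("single-codon-pair gene: every substitution is classified once", {
  # intronless gene with CDS "ATGTAA": 6 sites x 3 alts = 18 substitutions
  gm <- list(name = "MINI", seq = paste0("GG", "ATGTAA", "GG"),
             exons = data.frame(start = 3, end = 8))
  mu <- 1e-8
  tab <- build_probability_table(list(gm), uniform_rate_table(mu))
  expect_equal(sum(tab$probability), 18 * mu, tolerance = 1e-15)
  expected <- oracle_prob_table(gm, mu)
  expect_equal(setNames(tab$probability, tab$class), expected[tab$class],
               tolerance = 1e-15)
  # no splice class without introns
  expect_equal(tab$probability[tab$class == "splice"], 0)
})

test_that("class partition conserves total rate mass", {
  genes <- simulate_gene_models(n_genes = 5, n_exons = 2, seed = 41)
  mu <- 1e-9
  tab <- build_probability_table(genes, uniform_rate_table(mu))
  for (gm in genes) {
    ex <- gm$exons
    n_cds <- sum(ex$end - ex$start + 1)
    # evaluated positions = CDS plus 8 intronic bases on each side of every
    # junction (the exonic splice window already lies inside the CDS)
    n_pos <- n_cds + 16 * (nrow(ex) - 1)
    total <- sum(tab$probability[tab$gene == gm$name])
    expect_equal(total, n_pos * 3 * mu, tolerance = 1e-12)
  }
})

test_that("class enrichment reproduces the published Poisson comparisons", {
  prob <- read.table(system.file("extdata", "class_probabilities_synthetic.tsv",
                                 package = "triodnv"),
                     header = TRUE, sep = "\t")
  enr <- class_enrichment(c(missense = 17, splice = 3, synonymous = 14),
                          prob, n_probands = 36)
  splice <- enr[enr$class == "splice", ]
  expect_equal(splice$p, 0.0173, tolerance = 0.0005 / 0.0173)
  expect_equal(round(splice$enrichment_ratio, 2), 5.60)
  missense <- enr[enr$class == "missense", ]
  expect_equal(missense$p, 0.908, tolerance = 0.01)
  expect_equal(round(missense$enrichment_ratio, 2), 0.75)
  expect_equal(round(enr$enrichment_ratio[enr$class == "synonymous"], 2), 1.39)
  # invariant: ratio * expected = observed
  expect_equal(enr$enrichment_ratio * enr$expected, as.numeric(enr$observed))
  expect_true(all(enr$p_adj >= enr$p))
})

test_that("degenerate enrichment inputs", {
  prob <- data.frame(gene = "G", class = c("missense", "splice"),
                     probability = c(0.1, 0))
  enr <- class_enrichment(c(missense = 0), prob, n_probands = 10)
  expect_equal(enr$p, 1)  # P(X >= 0) = 1
  expect_warning(
    enr0 <- class_enrichment(c(splice = 2), prob, n_probands = 10),
    "expected 0")
  expect_equal(enr0$p, 0)
})

test_that("enrichment p-values are uniform-conservative under the null", {
  set.seed(47)
  expected <- 5.3
  prob <- data.frame(gene = "G", class = "missense",
                     probability = expected / (2 * 36))
  n_rep <- 2000
  p <- vapply(rpois(n_rep, expected), function(x)
    class_enrichment(c(missense = x), prob, 36)$p, numeric(1))
  mc_err <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(p <= 0.05), 0.05 + 3 * mc_err)
})

test_that("BH-FDR adjustment: published values, hand cases, properties", {
  expect_equal(round(bh_fdr(c(0.0173, 0.908, 0.143)), 4),
               c(0.0519, 0.908, 0.2145))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(53)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    adj <- bh_fdr(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in raw p
    expect_identical(bh_fdr(p), adj)                 # deterministic
    expect_true(all(bh_fdr(adj) >= adj - 1e-12))     # re-adjusting never lowers
  }
})

test_that("rate estimator CI covers the simulated truth", {
  set.seed(59)
  lambda <- 1.4e-8 * 33828798 * 2
  n_rep <- 200
  cover <- logical(n_rep); est <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    counts <- rpois(36, lambda)
    m <- mutation_rate(per_proband_counts = counts)
    cover[r] <- m$ci[1] <= 1.4e-8 && 1.4e-8 <= m$ci[2]
    est[r] <- m$rate
  }
  expect_gte(mean(cover), 0.90)
  expect_gt(mean(est), 1.0e-8)
  expect_lt(mean(est), 1.8e-8)
})
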