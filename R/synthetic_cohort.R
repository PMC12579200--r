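#' Simulation configuration for a synthetic trio cohort
#'
#' Defaults emulate the study conditions of a 36-trio whole-exome cohort:
#' a true de novo SNV rate of 1.4e-8 per nucleotide per generation over a
#' 33,828,798 bp coding exome (so the expected number of spiked dnSNVs per
#' proband is `rate * exome_size * 2` gametes, about 0.947), ~100x mean
#' depth, and a small rate of "missed heterozygote" artifacts: a parent
#' truly heterozygous but emitted homozygous-reference with residual alt
#' reads, so the resulting apparent de novo call is rescued only by the
#' parental read-support filter.
#'
#' @param n_trios number of trios (default 36)
#' @param exome_size mutational target size in bp (default 33,828,798)
#' @param true_dnv_rate per-nucleotide per-generation dnSNV rate (default 1.4e-8)
#' @param class_mix named probability vector over missense, nonsense,
#'   splice, synonymous; must sum to 1. The default (0.60, 0.04, 0.05, 0.31)
#'   gives the canonical ~2.23:1 non-synonymous:synonymous expectation.
#' @param n_inherited_sites autosomal inherited sites emitted cohort-wide
#' @param prop_rare_inherited fraction of inherited sites that are
#'   family-private rare variants (the tier that can masquerade as de novo)
#' @param n_x_sites non-PAR X-chromosome sites (for sex imputation)
#' @param missed_het_rate fraction of parental-het transmissions (child het,
#'   other parent homref) emitted as missed-heterozygote artifacts
#' @param artifact_alt_frac range of the artifact parent's residual alt-read
#'   fraction; the default (0.06, 0.25) sits above the 5% parental-read
#'   threshold so every artifact is catchable by that filter
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#' @param base_error per-read error rate used in the genotype-likelihood GQ
#' @param n_genes,gene_length toy gene map over which variants are placed
#' @param effects optional list of non-null clinical effects:
#'   `dnv_per_father_year` (log-linear effect of paternal age on the dnSNV
#'   rate) and `cybocs_per_dnv` (additive effect on CY-BOCS). Default NULL:
#'   covariates are drawn independent of dnSNV count.
#' @param seed RNG seed; the full output is reproducible from it
#' @return a `sim_config` list
#' @export
sim_config <- function(n_trios = 36,
                       exome_size = 33828798,
                       true_dnv_rate = 1.4e-8,
                       class_mix = c(missense = 0.60, nonsense = 0.04,
                                     splice = 0.05, synonymous = 0.31),
                       n_inherited_sites = 1500,
                       prop_rare_inherited = 0.2,
                       n_x_sites = 100,
                       missed_het_rate = 0.002,
                       artifact_alt_frac = c(0.06, 0.25),
                       depth_mean = 100,
                       depth_dispersion = 10,
                       base_error = 0.001,
                       n_genes = 400,
                       gene_length = 3000,
                       effects = NULL,
                       seed = 1L) {
  assert_that(abs(sum(class_mix) - 1) < 1e-8, "class_mix must sum to 1")
  assert_that(all(names(class_mix) %in% DNV_CLASSES),
              "class_mix names must be consequence classes")
  assert_that(exome_size > 0, "exome_size must be positive")
  rates <- c(true_dnv_rate, missed_het_rate, prop_rare_inherited)
  assert_that(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

# Phred-scaled genotype quality from the binomial genotype-likelihood margin
# between the emitted genotype and the best alternative. Deterministic in the
# read counts.
gq_from_counts <- function(ad_ref, ad_alt, emitted_gt, base_error = 0.001) {
  dp <- ad_ref + ad_alt
  p_alt <- c(base_error, 0.5, 1 - base_error)
  n <- length(dp)
  ll <- vapply(p_alt, function(p) dbinom(ad_alt, dp, p, log = TRUE), numeric(n))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  best <- pmax(ll[, 1], ll[, 2], ll[, 3])
  pl <- -10 * (ll - best) / log(10)
  idx <- cbind(seq_len(n), emitted_gt + 1)
  emitted_pl <- pl[idx]
  pl[idx] <- Inf
  margin <- pmin(pl[, 1], pl[, 2], pl[, 3]) - emitted_pl
  as.numeric(pmax(0, pmin(99, round(margin))))
}

# Toy gene map: genes tiled along chr1..chr22 with gaps, used to give
# simulated variants coordinates and gene labels.
toy_gene_map <- function(n_genes, gene_length) {
  chrom <- paste0("chr", rep(1:22, length.out = n_genes))
  idx <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  start <- 1e6 + (idx - 1) * (gene_length + 1000)
  data.frame(gene = sprintf("GENE%03d", seq_len(n_genes)), chrom = chrom,
             start = start, end = start + gene_length - 1,
             stringsAsFactors = FALSE)
}

random_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

random_alt <- function(ref) {
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1), USE.NAMES = FALSE)
}

#' Simulate a trio cohort with known ground truth
#'
#' Generates, per trio: a Poisson number of true de novo SNVs
#' (`Poisson(true_dnv_rate * exome_size * 2)`), inherited autosomal variation
#' (a common tier shared cohort-wide and a family-private rare tier) obeying
#' Mendelian transmission, non-PAR X sites respecting sex, and
#' missed-heterozygote artifacts: sites where one parent is truly
#' heterozygous but the emitted call is homozygous-reference with a residual
#' alt-read fraction drawn from `artifact_alt_frac` - indistinguishable from
#' a de novo variant except by parental read support. Read depths are
#' negative-binomial; alt counts at het sites are `Binomial(depth, 1/2)`;
#' GQ is derived deterministically from the genotype-likelihood margin
#' (artifact parents keep a confident homref call, emulating the
#' reference-biased caller errors that motivate read-level inspection).
#'
#' @param config a [sim_config()]
#' @return list with elements `cohort` (a [trio_cohort()] sorted by
#'   position), `ped` (6-column pedigree data.frame), `phenotypes`
#'   (per-proband clinical table), and `truth` (spiked DNVs, artifact sites,
#'   per-proband true DNV counts, and the kind of every emitted site)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  fam <- sprintf("F%02d", seq_len(cfg$n_trios))
  proband <- sprintf("%s-P", fam); father <- sprintf("%s-FA", fam)
  mother <- sprintf("%s-MO", fam)
  samples <- as.vector(rbind(proband, father, mother))
  n_smp <- length(samples)
  child_sex <- ifelse(runif(cfg$n_trios) < 0.53, 2L, 1L)  # 53% female

  ped <- data.frame(
    fid = rep(fam, each = 3),
    iid = samples,
    pat = as.vector(rbind(father, rep("0", cfg$n_trios), rep("0", cfg$n_trios))),
    mat = as.vector(rbind(mother, rep("0", cfg$n_trios), rep("0", cfg$n_trios))),
    sex = as.vector(rbind(child_sex, rep(1L, cfg$n_trios), rep(2L, cfg$n_trios))),
    phe = as.vector(rbind(rep("2", cfg$n_trios), rep("1", cfg$n_trios),
                          rep("1", cfg$n_trios))),
    stringsAsFactors = FALSE)

  gene_map <- toy_gene_map(cfg$n_genes, cfg$gene_length)
  depth <- function(n) pmax(2, rnbinom(n, size = cfg$depth_dispersion,
                                       mu = cfg$depth_mean))

  sites <- list(); gt <- list(); adr <- list(); ada <- list(); kind <- c()
  artifacts <- list()

  emit_site <- function(chrom, pos, ref, alt, gene, class, af, af_absent, cadd,
                        gts, alt_frac = NULL) {
    # gts: emitted dosage per sample; alt_frac: optional per-sample override
    # of the alt-read fraction (used for artifact parents)
    dp <- depth(n_smp)
    frac <- ifelse(gts == 0, 0, ifelse(gts == 1, 0.5, 1))
    a_alt <- rbinom(n_smp, dp, frac)
    a_alt[gts == 0] <- 0
    a_alt[gts == 2] <- dp[gts == 2] - rbinom(sum(gts == 2), dp[gts == 2], cfg$base_error)
    if (!is.null(alt_frac)) {
      ov <- which(!is.na(alt_frac))
      a_alt[ov] <- pmax(1, round(alt_frac[ov] * dp[ov]))
    }
    sites[[length(sites) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
      class = class, af = af, af_absent = af_absent, cadd = cadd,
      stringsAsFactors = FALSE)
    gt[[length(gt) + 1L]] <<- gts
    ada[[length(ada) + 1L]] <<- a_alt
    adr[[length(adr) + 1L]] <<- dp - a_alt
  }

  used_pos <- new.env()
  fresh_pos <- function() {
    repeat {
      g <- sample(nrow(gene_map), 1)
      p <- sample(gene_map$start[g]:gene_map$end[g], 1)
      key <- paste0(gene_map$chrom[g], ":", p)
      if (is.null(used_pos[[key]])) {
        used_pos[[key]] <- TRUE
        return(list(chrom = gene_map$chrom[g], pos = p, gene = gene_map$gene[g]))
      }
    }
  }
  sim_cadd <- function(class) {
    switch(class,
           missense = min(40, max(0, rnorm(1, 20, 8))),
           nonsense = runif(1, 28, 45),
           splice = runif(1, 0, 35),
           synonymous = runif(1, 0, 16),
           runif(1, 0, 10))
  }

  # --- clinical covariates drawn before DNV counts so paternal-age effects
  # can act on the rate (null by default)
  father_age <- rnorm(cfg$n_trios, 30, 5)
  mother_age <- rnorm(cfg$n_trios, 30, 5)
  beta_fa <- (cfg$effects$dnv_per_father_year %||% 0)
  lambda <- cfg$true_dnv_rate * cfg$exome_size * 2 *
    exp(beta_fa * (father_age - 30))

  # --- spiked de novo SNVs
  n_dnv <- rpois(cfg$n_trios, lambda)
  truth_dnv <- list()
  for (f in seq_len(cfg$n_trios)) {
    for (j in seq_len(n_dnv[f])) {
      loc <- fresh_pos()
      ref <- random_base(1); alt <- random_alt(ref)
      class <- sample(names(cfg$class_mix), 1, prob = cfg$class_mix)
      absent <- runif(1) < 0.5
      af <- if (absent) NA_real_ else runif(1, 1e-6, 1e-3)
      gts <- rep(0, n_smp); gts[3 * f - 2] <- 1  # proband het, parents homref
      emit_site(loc$chrom, loc$pos, ref, alt, loc$gene, class, af, absent,
                round(sim_cadd(class), 2), gts)
      kind <- c(kind, "dnv")
      truth_dnv[[length(truth_dnv) + 1L]] <- data.frame(
        family = fam[f], proband = proband[f],
        chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
        gene = loc$gene, class = class, stringsAsFactors = FALSE)
    }
  }

  # --- inherited autosomal sites (common tier + family-private rare tier)
  n_rare <- round(cfg$prop_rare_inherited * cfg$n_inherited_sites)
  n_common <- cfg$n_inherited_sites - n_rare
  maybe_artifact <- function(gts, f) {
    # one parent het, child het, other parent homref -> candidate for a
    # missed-het emission
    pi <- 3 * f - 2; fi <- 3 * f - 1; mi <- 3 * f
    if (gts[pi] != 1) return(NULL)
    par <- c(fi, mi)[which(gts[c(fi, mi)] == 1)]
    if (length(par) != 1 || any(gts[setdiff(c(fi, mi), par)] != 0)) return(NULL)
    if (runif(1) >= cfg$missed_het_rate) return(NULL)
    par
  }
  transmit <- function(g) if (g == 1) rbinom(1, 1, 0.5) else g / 2

  for (s in seq_len(n_common)) {
    loc <- fresh_pos()
    ref <- random_base(1); alt <- random_alt(ref)
    p <- runif(1, 0.05, 0.95)
    gts <- rep(0, n_smp); alt_frac <- rep(NA_real_, n_smp)
    art_here <- NULL
    for (f in seq_len(cfg$n_trios)) {
      gf <- rbinom(1, 2, p); gm <- rbinom(1, 2, p)
      gc <- transmit(gf) + transmit(gm)
      gts[3 * f - 2] <- gc; gts[3 * f - 1] <- gf; gts[3 * f] <- gm
      par <- maybe_artifact(gts, f)
      if (!is.null(par)) {
        gts[par] <- 0
        alt_frac[par] <- runif(1, cfg$artifact_alt_frac[1], cfg$artifact_alt_frac[2])
        art_here <- rbind(art_here, data.frame(
          family = fam[f], parent = samples[par], alt_frac = alt_frac[par]))
      }
    }
    class <- sample(names(cfg$class_mix), 1, prob = cfg$class_mix)
    emit_site(loc$chrom, loc$pos, ref, alt, loc$gene, class,
              round(p, 4), FALSE, round(sim_cadd(class), 2), gts, alt_frac)
    kind <- c(kind, "inherited_common")
    if (!is.null(art_here)) {
      art_here$chrom <- loc$chrom; art_here$pos <- loc$pos
      art_here$ref <- ref; art_here$alt <- alt
      artifacts[[length(artifacts) + 1L]] <- art_here
    }
  }

  for (s in seq_len(n_rare)) {
    loc <- fresh_pos()
    ref <- random_base(1); alt <- random_alt(ref)
    f <- sample(cfg$n_trios, 1)
    carrier <- sample(c(3 * f - 1, 3 * f), 1)  # one het parent
    gts <- rep(0, n_smp); alt_frac <- rep(NA_real_, n_smp)
    gts[carrier] <- 1
    gts[3 * f - 2] <- rbinom(1, 1, 0.5)  # child inherits with p = 1/2
    par <- maybe_artifact(gts, f)
    if (!is.null(par)) {
      gts[par] <- 0
      alt_frac[par] <- runif(1, cfg$artifact_alt_frac[1], cfg$artifact_alt_frac[2])
    }
    absent <- runif(1) < 0.5
    class <- sample(names(cfg$class_mix), 1, prob = cfg$class_mix)
    emit_site(loc$chrom, loc$pos, ref, alt, loc$gene, class,
              if (absent) NA_real_ else round(runif(1, 1e-6, 0.009), 6),
              absent, round(sim_cadd(class), 2), gts, alt_frac)
    kind <- c(kind, if (is.null(par)) "inherited_rare" else "inherited_rare")
    if (!is.null(par)) {
      artifacts[[length(artifacts) + 1L]] <- data.frame(
        family = fam[f], parent = samples[par], alt_frac = alt_frac[par],
        chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt)
    }
  }

  # --- non-PAR X sites (hemizygous males emitted as homozygous calls)
  sex_of <- setNames(ped$sex, ped$iid)
  for (s in seq_len(cfg$n_x_sites)) {
    pos <- 3e6 + s * 977
    ref <- random_base(1); alt <- random_alt(ref)
    p <- runif(1, 0.1, 0.9)
    gts <- rep(0, n_smp)
    for (f in seq_len(cfg$n_trios)) {
      a_f <- rbinom(1, 1, p)                      # father's single X allele
      g_m <- rbinom(1, 2, p)                      # mother diploid
      a_mt <- if (g_m == 1) rbinom(1, 1, 0.5) else g_m / 2  # transmitted
      gts[3 * f - 1] <- 2 * a_f
      gts[3 * f] <- g_m
      gts[3 * f - 2] <- if (child_sex[f] == 1) 2 * a_mt else a_f + a_mt
    }
    emit_site("chrX", pos, ref, alt, "", "other", round(p, 4), FALSE,
              NA_real_, gts)
    kind <- c(kind, "x")
  }

  # --- assemble matrices
  site_df <- do.call(rbind, sites)
  gt_m <- do.call(rbind, gt)
  ad_alt_m <- do.call(rbind, ada)
  ad_ref_m <- do.call(rbind, adr)
  dimnames(gt_m) <- dimnames(ad_alt_m) <- dimnames(ad_ref_m) <-
    list(NULL, samples)
  dp_m <- ad_ref_m + ad_alt_m
  gq_m <- matrix(0, nrow(gt_m), n_smp, dimnames = list(NULL, samples))
  for (j in seq_len(n_smp))
    gq_m[, j] <- gq_from_counts(ad_ref_m[, j], ad_alt_m[, j], gt_m[, j],
                                cfg$base_error)
  # artifact parents keep a confident homref emission (caller reference bias)
  art_df <- if (length(artifacts)) do.call(rbind, artifacts) else
    data.frame(family = character(), parent = character(),
               alt_frac = numeric(), chrom = character(), pos = integer(),
               ref = character(), alt = character())
  if (nrow(art_df)) {
    key <- paste(site_df$chrom, site_df$pos)
    for (i in seq_len(nrow(art_df))) {
      r <- match(paste(art_df$chrom[i], art_df$pos[i]), key)
      gq_m[r, art_df$parent[i]] <- 50
    }
  }
  alt_fwd <- matrix(rbinom(length(ad_alt_m), ad_alt_m, 0.5), nrow(ad_alt_m),
                    dimnames = dimnames(ad_alt_m))
  ref_fwd <- matrix(rbinom(length(ad_ref_m), ad_ref_m, 0.5), nrow(ad_ref_m),
                    dimnames = dimnames(ad_ref_m))
  calls <- list(gt = gt_m, gq = gq_m, dp = dp_m,
                ad_ref = ad_ref_m, ad_alt = ad_alt_m,
                ad_ref_fwd = ref_fwd, ad_ref_rev = ad_ref_m - ref_fwd,
                ad_alt_fwd = alt_fwd, ad_alt_rev = ad_alt_m - alt_fwd,
                min_bq = matrix(30, nrow(gt_m), n_smp,
                                dimnames = list(NULL, samples)))
  cohort <- trio_cohort(site_df, calls)
  ord <- order(factor(site_df$chrom, levels = c(paste0("chr", 1:22), "chrX")),
               site_df$pos)
  cohort <- subset_sites(cohort, ord)
  kind <- kind[ord]

  # --- phenotypes (null unless effects supplied)
  cybocs <- pmin(36, pmax(8, round(runif(cfg$n_trios, 8, 36) +
    (cfg$effects$cybocs_per_dnv %||% 0) * n_dnv)))
  cybocs[runif(cfg$n_trios) < 6 / 36] <- NA
  father_age_out <- father_age
  father_age_out[runif(cfg$n_trios) < 4 / 36] <- NA
  mother_age_out <- mother_age
  mother_age_out[runif(cfg$n_trios) < 5 / 36] <- NA
  phen <- data.frame(
    id = proband,
    sex = ifelse(child_sex == 2, "female", "male"),
    dnsnv_count = n_dnv,
    father_age_at_conception = round(father_age_out, 1),
    mother_age_at_conception = round(mother_age_out, 1),
    age_at_diagnosis = round(pmin(17.9, pmax(6, rnorm(cfg$n_trios, 13, 2.48))), 1),
    cybocs_total = cybocs,
    first_degree_relative_dx = rbinom(cfg$n_trios, 1, 0.2),
    brain_trauma = rbinom(cfg$n_trios, 1, 0.2),
    comorbidity = rbinom(cfg$n_trios, 1, 0.2),
    stringsAsFactors = FALSE)

  truth <- list(
    dnvs = if (length(truth_dnv)) do.call(rbind, truth_dnv) else
      data.frame(family = character(), proband = character(),
                 chrom = character(), pos = integer(), ref = character(),
                 alt = character(), gene = character(), class = character()),
    artifacts = art_df,
    per_proband = setNames(n_dnv, proband),
    site_kind = kind)
  list(cohort = cohort, ped = ped, phenotypes = phen, truth = truth)
}

#' Simulate a reference genotype panel with ancestry clusters
#'
#' Balding-Nichols model: each SNP has an ancestral frequency and
#' cluster-specific frequencies drawn around it with divergence `fst`.
#' Cohort samples are drawn from cluster 1, except `n_outliers` planted
#' cross-cluster samples. Used to exercise reference-projected PCA and
#' outlier exclusion against known labels.
#'
#' @param n_samples reference panel size
#' @param n_snps number of SNPs (warning, not error, if below `n_samples`)
#' @param n_clusters number of ancestry clusters (>= 1)
#' @param fst divergence between clusters (0 = one panmictic cluster)
#' @param n_cohort cohort samples to draw from cluster 1
#' @param n_outliers of the cohort samples, how many to draw from cluster 2
#' @param seed RNG seed
#' @return list: `ref` (n_samples x n_snps dosage matrix), `labels`
#'   (reference cluster per sample), `cohort` (n_cohort x n_snps matrix),
#'   `cohort_outlier` (logical truth)
#' @export
simulate_reference_panel <- function(n_samples = 100, n_snps = 500,
                                     n_clusters = 2, fst = 0.1,
                                     n_cohort = 36, n_outliers = 0,
                                     seed = 1L) {
  if (n_snps < n_samples)
    warning("fewer SNPs than samples; PCA axes will be noisy")
  assert_that(n_clusters >= 1, "need at least one cluster")
  assert_that(n_outliers == 0 || n_clusters >= 2,
              "outliers need a second cluster to come from")
  set.seed(seed)
  p_anc <- runif(n_snps, 0.1, 0.9)
  freq <- matrix(NA_real_, n_clusters, n_snps)
  for (k in seq_len(n_clusters)) {
    freq[k, ] <- if (fst <= 0) p_anc else
      rbeta(n_snps, p_anc * (1 - fst) / fst, (1 - p_anc) * (1 - fst) / fst)
    freq[k, ] <- pmin(0.99, pmax(0.01, freq[k, ]))
  }
  labels <- rep_len(seq_len(n_clusters), n_samples)
  ref <- t(vapply(labels, function(k) rbinom(n_snps, 2, freq[k, ]),
                  numeric(n_snps)))
  out_truth <- rep(FALSE, n_cohort)
  if (n_outliers > 0) out_truth[sample(n_cohort, n_outliers)] <- TRUE
  cohort <- t(vapply(out_truth, function(o)
    rbinom(n_snps, 2, freq[if (o) 2 else 1, ]), numeric(n_snps)))
  rownames(ref) <- sprintf("REF%03d", seq_len(n_samples))
  rownames(cohort) <- sprintf("S%03d", seq_len(n_cohort))
  list(ref = ref, labels = labels, cohort = cohort, cohort_outlier = out_truth)
}

#' Simulate toy gene models with exon/intron structure
#'
#' Each gene is a random sequence containing `n_exons` coding exons
#' (total CDS length divisible by 3) separated by short introns, with
#' flanking sequence so every position has trinucleotide context. Used to
#' exercise the mutational-model probability-table builder at desk scale.
#'
#' @param n_genes number of genes
#' @param n_exons exons per gene (recycled)
#' @param exon_codons codon count range per exon
#' @param intron_len intron length range
#' @param seed RNG seed
#' @return list of gene models: `name`, `seq` (character scalar),
#'   `exons` (data.frame of start/end, 1-based in `seq`)
#' @export
simulate_gene_models <- function(n_genes = 5, n_exons = 2,
                                 exon_codons = c(4, 12),
                                 intron_len = c(20, 40), seed = 1L) {
  set.seed(seed)
  n_exons <- rep_len(n_exons, n_genes)
  lapply(seq_len(n_genes), function(g) {
    ne <- n_exons[g]
    ex_len <- 3 * sample(exon_codons[1]:exon_codons[2], ne, replace = TRUE)
    in_len <- if (ne > 1) sample(intron_len[1]:intron_len[2], ne - 1,
                                 replace = TRUE) else integer(0)
    flank <- 10
    total <- 2 * flank + sum(ex_len) + sum(in_len)
    seq <- paste(random_base(total), collapse = "")
    starts <- integer(ne); pos <- flank + 1
    for (e in seq_len(ne)) {
      starts[e] <- pos
      pos <- pos + ex_len[e] + if (e < ne) in_len[e] else 0
    }
    list(name = sprintf("TOY%02d", g), seq = seq,
         exons = data.frame(start = starts, end = starts + ex_len - 1))
  })
}
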