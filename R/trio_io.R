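#' Cohort container for biallelic SNV sites with per-sample calls
#'
#' A `trio_cohort` bundles a site table with per-sample call matrices, the
#' unit that flows through QC and the de novo filter cascade. Sites are
#' biallelic SNVs; positions are 1-based throughout the package (BED input is
#' converted at the boundary).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases), `gene` (symbol or ""), `class` (one of
#'   `"missense"`, `"nonsense"`, `"splice"`, `"synonymous"`, `"other"`),
#'   `af` (population allele frequency, `NA` when unannotated or absent),
#'   `af_absent` (logical: reported absent from the reference population,
#'   distinct from frequency 0), `cadd` (CADD PHRED, `NA` when unscored).
#' @param calls named list of numeric matrices, one row per site and one
#'   column per sample: `gt` (0/1/2 alt-allele dosage, `NA` missing), `gq`,
#'   `dp`, `ad_ref`, `ad_alt`, and optionally `ad_ref_fwd`, `ad_ref_rev`,
#'   `ad_alt_fwd`, `ad_alt_rev`, `min_bq`.
#'
#' @return An object of class `trio_cohort`.
#' @export
trio_cohort <- function(sites, calls) {
  required <- c("chrom", "pos", "ref", "alt", "gene", "class",
                "af", "af_absent", "cadd")
  missing_cols <- setdiff(required, names(sites))
  assert_that(length(missing_cols) == 0,
              "sites is missing columns: %s", paste(missing_cols, collapse = ", "))
  assert_that(all(sites$ref %in% c("A", "C", "G", "T")) &&
              all(sites$alt %in% c("A", "C", "G", "T")),
              "ref and alt must be single bases in {A,C,G,T} (SNVs only)")
  assert_that(!any(sites$ref == sites$alt), "ref must differ from alt")
  assert_that(all(sites$class %in% DNV_CLASSES),
              "unknown consequence class in sites$class")
  assert_that(is.matrix(calls$gt), "calls$gt must be a matrix")
  n <- nrow(sites)
  for (nm in names(calls)) {
    if (is.null(calls[[nm]])) next
    assert_that(nrow(calls[[nm]]) == n, "calls$%s has wrong row count", nm)
  }
  samples <- colnames(calls$gt)
  assert_that(!is.null(samples), "calls$gt must have sample column names")
  structure(list(sites = as.data.frame(sites, stringsAsFactors = FALSE),
                 calls = calls, samples = samples),
            class = "trio_cohort")
}

#' @exportS3Method base::print
print.trio_cohort <- function(x, ...) {
  cat(sprintf("trio_cohort: %d biallelic SNV sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Number of sites / samples in a cohort
#' @param cohort a [trio_cohort()]
#' @export
n_sites <- function(cohort) nrow(cohort$sites)

#' @rdname n_sites
#' @export
n_samples <- function(cohort) length(cohort$samples)

#' Extract one site (with its calls) as a list
#'
#' Returns the single-site view used by the filter cascade: the annotation
#' bundle plus one genotype call per sample.
#'
#' @param cohort a [trio_cohort()]
#' @param i site index
#' @export
variant_site <- function(cohort, i) {
  assert_that(i >= 1 && i <= n_sites(cohort), "site index out of range")
  site <- as.list(cohort$sites[i, , drop = FALSE])
  site$calls <- lapply(setNames(cohort$samples, cohort$samples), function(s) {
    cl <- lapply(cohort$calls, function(m) if (is.null(m)) NA_real_ else m[i, s])
    cl$genotype <- c("homref", "het", "homalt")[cl$gt + 1]
    if (is.na(cl$gt)) cl$genotype <- "missing"
    cl
  })
  site
}

#' Subset a cohort by site index
#' @param cohort a [trio_cohort()]
#' @param idx logical or integer site index
#' @export
subset_sites <- function(cohort, idx) {
  trio_cohort(cohort$sites[idx, , drop = FALSE],
              lapply(cohort$calls, function(m)
                if (is.null(m)) NULL else m[idx, , drop = FALSE]))
}

# ---------------------------------------------------------------------------
# Consequence collapsing

#' Collapse VEP-style consequence terms into the four analysis classes
#'
#' Terms are mapped to `missense`, `nonsense`, `splice`, `synonymous` or
#' `other`. Multiple `&`-joined terms are resolved by severity:
#' nonsense > splice > missense > synonymous. Splice includes
#' `splice_region_variant` (not only canonical donor/acceptor sites), since
#' near-exonic positions such as +3 and -4 belong to the splice class here.
#'
#' @param terms character vector of consequence strings, e.g.
#'   `"missense_variant"` or `"splice_region_variant&synonymous_variant"`.
#' @return character vector of classes.
#' @export
collapse_consequence <- function(terms) {
  map <- c(stop_gained = "nonsense",
           splice_donor_variant = "splice",
           splice_acceptor_variant = "splice",
           splice_region_variant = "splice",
           missense_variant = "missense",
           synonymous_variant = "synonymous",
           stop_retained_variant = "synonymous")
  priority <- c("nonsense", "splice", "missense", "synonymous")
  vapply(terms, function(tm) {
    if (is.na(tm) || tm == "") return("other")
    cls <- unname(map[strsplit(tm, "&", fixed = TRUE)[[1]]])
    cls <- cls[!is.na(cls)]
    if (length(cls) == 0) return("other")
    priority[min(match(cls, priority))]
  }, character(1), USE.NAMES = FALSE)
}

# Representative VEP term for each class, used when writing VCF annotations.
class_to_term <- function(class) {
  c(missense = "missense_variant", nonsense = "stop_gained",
    splice = "splice_region_variant", synonymous = "synonymous_variant",
    other = "intergenic_variant")[class]
}

# ---------------------------------------------------------------------------
# VCF

csq_fields <- c("Allele", "Consequence", "SYMBOL", "gnomAD_NFE_AF", "CADD_PHRED")

parse_af_string <- function(x) {
  absent <- !is.na(x) & tolower(x) == "absent"
  af <- suppressWarnings(as.numeric(x))
  af[absent] <- NA_real_
  list(af = af, af_absent = absent)
}

format_af_string <- function(af, af_absent) {
  out <- ifelse(af_absent, "Absent", ifelse(is.na(af), "", sprintf("%.6g", af)))
  out
}

#' Read a multi-sample VCF into a [trio_cohort()]
#'
#' Multi-allelic records are decomposed into one biallelic site per ALT
#' allele; non-SNV alleles (indels, symbolic alleles) are dropped with a
#' message giving the count. Genotypes are recoded allele-wise: a sample's
#' dosage at a split site is its count of that ALT allele.
#'
#' Annotations arrive either through a VEP-style `CSQ` INFO field (fields
#' `Allele|Consequence|SYMBOL|gnomAD_NFE_AF|CADD_PHRED`, declared in the
#' header `Format:` clause) or through a sidecar TSV keyed by
#' chrom, pos, ref, alt with columns `gene`, `consequence`, `population_af`,
#' `cadd_phred`. A population frequency printed `Absent` is kept distinct
#' from 0 (`af_absent = TRUE`) and is not treated as a numeric frequency.
#'
#' @param path VCF 4.x file.
#' @param annotation `"csq"`, `"sidecar"`, or `"none"`.
#' @param sidecar path to the sidecar TSV when `annotation = "sidecar"`.
#' @return a [trio_cohort()]; sites in file order (split alleles adjacent).
#' @export
read_vcf <- function(path, annotation = c("csq", "sidecar", "none"),
                     sidecar = NULL) {
  annotation <- match.arg(annotation)
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  assert_that("GT" %in% fmt_keys, "VCF FORMAT lacks mandatory GT field")

  grab <- function(key, fun = as.numeric) {
    if (!key %in% fmt_keys) return(NULL)
    m <- vcfR::extract.gt(v, element = key, as.numeric = FALSE)
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
    m
  }
  gt_raw <- grab("GT")
  gq_raw <- grab("GQ"); dp_raw <- grab("DP"); ad_raw <- grab("AD")
  adf_raw <- grab("ADF"); adr_raw <- grab("ADR"); mbq_raw <- grab("MBQ")
  samples <- colnames(v@gt)[-1]

  csq_format <- NULL
  if (annotation == "csq") csq_format <- parse_csq_format(v@meta)
  side <- NULL
  if (annotation == "sidecar") {
    assert_that(!is.null(sidecar), "annotation = 'sidecar' needs a sidecar path")
    side <- read_annotation_sidecar(sidecar)
  }

  sites <- list(); mats <- list(); dropped <- 0L
  mat_names <- c("gt", "gq", "dp", "ad_ref", "ad_alt",
                 "ad_ref_fwd", "ad_ref_rev", "ad_alt_fwd", "ad_alt_rev", "min_bq")
  num_row <- function(m, r) {
    if (is.null(m)) rep(NA_real_, length(samples))
    else suppressWarnings(as.numeric(m[r, ]))
  }
  for (r in seq_len(nrow(fix))) {
    ref <- fix[r, "REF"]
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    ad_split <- if (!is.null(ad_raw)) strsplit(ad_raw[r, ], ",", fixed = TRUE)
    adf_split <- if (!is.null(adf_raw)) strsplit(adf_raw[r, ], ",", fixed = TRUE)
    adr_split <- if (!is.null(adr_raw)) strsplit(adr_raw[r, ], ",", fixed = TRUE)
    dp_r <- if (!is.null(dp_raw)) suppressWarnings(as.numeric(dp_raw[r, ]))
    for (k in seq_along(alts)) {
      alt <- alts[k]
      if (!(ref %in% c("A", "C", "G", "T")) || !(alt %in% c("A", "C", "G", "T"))) {
        dropped <- dropped + 1L
        next
      }
      gt_k <- vapply(gt_raw[r, ], function(g) {
        if (is.na(g)) return(NA_real_)
        al <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
        if (any(al == ".")) return(NA_real_)
        sum(al == as.character(k))
      }, numeric(1))
      pick <- function(split_list, j) {
        if (is.null(split_list)) return(rep(NA_real_, length(samples)))
        vapply(split_list, function(x) {
          if (length(x) <= j - 1 || is.na(x[1])) return(NA_real_)
          suppressWarnings(as.numeric(x[j]))
        }, numeric(1))
      }
      ad_ref <- pick(ad_split, 1); ad_alt <- pick(ad_split, k + 1)
      if (!is.null(dp_r)) {
        tot <- vapply(ad_split, function(x)
          if (is.na(x[1])) NA_real_ else sum(suppressWarnings(as.numeric(x))),
          numeric(1))
        bad <- which(!is.na(tot) & !is.na(dp_r) & tot != dp_r)
        assert_that(length(bad) == 0,
                    "AD does not sum to DP at %s:%s sample %s",
                    fix[r, "CHROM"], fix[r, "POS"],
                    paste(samples[bad], collapse = ","))
      }
      ann <- annotate_allele(annotation, csq_format, fix[r, ], alt, side)
      sites[[length(sites) + 1L]] <- data.frame(
        chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        ref = ref, alt = alt, gene = ann$gene, class = ann$class,
        af = ann$af, af_absent = ann$af_absent, cadd = ann$cadd,
        stringsAsFactors = FALSE)
      mats[[length(mats) + 1L]] <- rbind(
        gt = gt_k, gq = num_row(gq_raw, r),
        dp = dp_r %||% rep(NA_real_, length(samples)),
        ad_ref = ad_ref, ad_alt = ad_alt,
        ad_ref_fwd = pick(adf_split, 1), ad_ref_rev = pick(adr_split, 1),
        ad_alt_fwd = pick(adf_split, k + 1), ad_alt_rev = pick(adr_split, k + 1),
        min_bq = num_row(mbq_raw, r))
    }
  }
  if (dropped > 0) message(sprintf("read_vcf: dropped %d non-SNV allele(s)", dropped))
  assert_that(length(sites) > 0, "no biallelic SNV sites in %s", path)
  site_df <- do.call(rbind, sites)
  calls <- lapply(setNames(mat_names, mat_names), function(nm) {
    m <- do.call(rbind, lapply(mats, function(x) x[nm, ]))
    colnames(m) <- samples
    m
  })
  trio_cohort(site_df, calls)
}

validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  assert_that(length(lines) > 0 && startsWith(lines[1], "##fileformat=VCF"),
              "%s: not a VCF (missing ##fileformat header)", path)
  hdr <- which(startsWith(lines, "#CHROM"))
  assert_that(length(hdr) == 1, "%s: missing #CHROM header line", path)
  nfield <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  body <- seq_along(lines) > hdr
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- which(nf != nfield)
  assert_that(length(bad) == 0, "%s: malformed VCF record at line %d",
              path, hdr + bad[1])
  invisible(TRUE)
}

parse_csq_format <- function(meta) {
  ln <- grep("^##INFO=<ID=CSQ", meta, value = TRUE)
  if (length(ln) == 0) return(NULL)
  fmt <- sub('.*Format: ?([^"]+)".*', "\\1", ln[1])
  strsplit(fmt, "|", fixed = TRUE)[[1]]
}

annotate_allele <- function(annotation, csq_format, fix_row, alt, side) {
  blank <- list(gene = "", class = "other", af = NA_real_,
                af_absent = FALSE, cadd = NA_real_)
  if (annotation == "none") return(blank)
  if (annotation == "csq") {
    info <- fix_row["INFO"]
    if (is.null(csq_format) || is.na(info)) return(blank)
    m <- regmatches(info, regexpr("(?:^|;)CSQ=[^;]*", info))
    if (length(m) == 0) return(blank)
    entries <- strsplit(sub("^;?CSQ=", "", m), ",", fixed = TRUE)[[1]]
    for (e in entries) {
      f <- strsplit(e, "|", fixed = TRUE)[[1]]
      f <- c(f, rep("", max(0, length(csq_format) - length(f))))
      names(f) <- csq_format
      if (!is.na(f["Allele"]) && f["Allele"] == alt) {
        af <- parse_af_string(f["gnomAD_NFE_AF"])
        return(list(gene = unname(f["SYMBOL"]),
                    class = collapse_consequence(unname(f["Consequence"])),
                    af = unname(af$af), af_absent = unname(af$af_absent),
                    cadd = suppressWarnings(as.numeric(f["CADD_PHRED"]))))
      }
    }
    return(blank)
  }
  key <- paste(fix_row["CHROM"], fix_row["POS"], fix_row["REF"], alt, sep = ":")
  row <- side[side$key == key, , drop = FALSE]
  if (nrow(row) == 0) return(blank)
  af <- parse_af_string(row$population_af[1])
  list(gene = row$gene[1], class = collapse_consequence(row$consequence[1]),
       af = af$af, af_absent = af$af_absent,
       cadd = suppressWarnings(as.numeric(row$cadd_phred[1])))
}

read_annotation_sidecar <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = "character", quote = "")
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
            "population_af", "cadd_phred")
  assert_that(all(need %in% names(d)),
              "annotation sidecar lacks columns: %s",
              paste(setdiff(need, names(d)), collapse = ", "))
  d$key <- paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  d
}

#' Write a [trio_cohort()] to VCF 4.2
#'
#' Emits `GT:GQ:DP:AD:ADF:ADR:MBQ` per call and a CSQ-style annotation INFO
#' field, so that `read_vcf(write_vcf(x))` round-trips genotypes, read
#' support and the annotation bundle for biallelic SNVs. Output is
#' byte-deterministic for a given cohort.
#'
#' @param cohort a [trio_cohort()]
#' @param path output file
#' @export
write_vcf <- function(cohort, path) {
  s <- cohort$sites
  cl <- cohort$calls
  fmt_num <- function(x) {
    out <- as.character(x)
    out[is.na(x)] <- "."
    out
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: ", paste(csq_fields, collapse = "|"), "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Allelic depths, forward strand\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Allelic depths, reverse strand\">",
    "##FORMAT=<ID=MBQ,Number=1,Type=Integer,Description=\"Minimum base quality of alt reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[cl$gt + 1],
                   nrow = nrow(s), dimnames = dimnames(cl$gt))
  gt_str[is.na(cl$gt)] <- "./."
  body <- vapply(seq_len(nrow(s)), function(i) {
    info <- paste0("CSQ=", s$alt[i], "|", class_to_term(s$class[i]), "|",
                   s$gene[i], "|", format_af_string(s$af[i], s$af_absent[i]),
                   "|", ifelse(is.na(s$cadd[i]), "", sprintf("%.6g", s$cadd[i])))
    pair <- function(a, b) ifelse(is.na(a) | is.na(b), ".",
                                  paste0(fmt_num(a), ",", fmt_num(b)))
    cells <- paste(
      gt_str[i, ], fmt_num(cl$gq[i, ]), fmt_num(cl$dp[i, ]),
      pair(cl$ad_ref[i, ], cl$ad_alt[i, ]),
      pair(cl$ad_ref_fwd[i, ], cl$ad_alt_fwd[i, ]),
      pair(cl$ad_ref_rev[i, ], cl$ad_alt_rev[i, ]),
      fmt_num(cl$min_bq[i, ]), sep = ":")
    paste(c(s$chrom[i], s$pos[i], ".", s$ref[i], s$alt[i], ".", "PASS", info,
            "GT:GQ:DP:AD:ADF:ADR:MBQ", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Pedigree

#' Read a 6-column PED file
#'
#' Columns: family id, individual id, father id, mother id, sex (1 = male,
#' 2 = female, 0 = unknown), phenotype (1 = unaffected, 2 = affected,
#' 0/-9 = missing). Any other sex code is an error.
#'
#' @param path PED file (whitespace-separated, no header)
#' @return data.frame with columns fid, iid, pat, mat, sex, phe
#' @export
read_ped <- function(path) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  assert_that(ncol(d) >= 6, "PED file must have 6 columns")
  names(d)[1:6] <- c("fid", "iid", "pat", "mat", "sex", "phe")
  assert_that(all(d$sex %in% c("0", "1", "2")),
              "unknown sex code in PED: %s",
              paste(unique(setdiff(d$sex, c("0", "1", "2"))), collapse = ","))
  assert_that(!anyDuplicated(d$iid), "duplicate individual ids in PED")
  d$sex <- as.integer(d$sex)
  d[1:6]
}

#' Extract validated trios from a pedigree
#'
#' Each trio must have three distinct members with the proband affected and
#' both parents unaffected.
#'
#' @param ped data.frame from [read_ped()]
#' @param validate check affected-status convention (default TRUE)
#' @return data.frame: family_id, proband, father, mother, proband_sex
#' @export
trios <- function(ped, validate = TRUE) {
  kids <- ped[ped$pat != "0" & ped$mat != "0", , drop = FALSE]
  assert_that(nrow(kids) > 0, "no complete trios in pedigree")
  out <- data.frame(family_id = kids$fid, proband = kids$iid,
                    father = kids$pat, mother = kids$mat,
                    proband_sex = kids$sex, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    ids <- unlist(out[i, c("proband", "father", "mother")])
    assert_that(length(unique(ids)) == 3,
                "trio %s does not have three distinct members", out$family_id[i])
    assert_that(all(c(out$father[i], out$mother[i]) %in% ped$iid),
                "trio %s has parents missing from the pedigree", out$family_id[i])
    if (validate) {
      phe <- setNames(ped$phe, ped$iid)
      assert_that(phe[out$proband[i]] == "2",
                  "proband %s not flagged affected", out$proband[i])
      assert_that(all(phe[c(out$father[i], out$mother[i])] == "1"),
                  "parents of %s not flagged unaffected", out$proband[i])
    }
  }
  out
}

# ---------------------------------------------------------------------------
# BED blacklist

#' Read a BED3 blacklist into a queryable interval set
#'
#' BED is 0-based half-open; the returned `GRanges` is 1-based closed, so a
#' 1-based VCF position `p` falls in a BED interval `[start, end)` iff
#' `p - 1` is in `[start, end)`, i.e. `p` overlaps the converted range.
#'
#' @param path BED file; may be empty (nothing is ever removed).
#' @return a `GRanges` interval set
#' @export
read_blacklist <- function(path) {
  raw <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0)
    return(GenomicRanges::GRanges())
  assert_that(ncol(raw) >= 3, "BED file needs at least 3 columns")
  assert_that(all(raw[[2]] < raw[[3]]),
              "BED interval with start >= end at line %d",
              which(raw[[2]] >= raw[[3]])[1])
  rtracklayer::import(path, format = "BED")
}

#' Test 1-based positions for blacklist membership
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions
#' @param blacklist `GRanges` from [read_blacklist()]
#' @return logical vector
#' @export
in_blacklist <- function(chrom, pos, blacklist) {
  if (length(blacklist) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  # queries on chromosomes absent from the blacklist are simply outside it
  suppressWarnings(GenomicRanges::countOverlaps(q, blacklist) > 0)
}

# ---------------------------------------------------------------------------
# GMT, phenotypes, candidate table

#' Read a GMT gene-set library
#'
#' One tab-separated line per term: term id, description, gene symbols.
#' Symbols are upper-cased at load; empty sets and duplicate term ids are
#' errors.
#'
#' @param path GMT file
#' @return named list; each element has `name` (description) and `genes`
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  assert_that(!anyDuplicated(ids), "duplicate term ids in GMT: %s",
              paste(ids[duplicated(ids)], collapse = ","))
  out <- lapply(parts, function(p) {
    genes <- toupper(trimws(p[-(1:2)]))
    genes <- genes[nzchar(genes)]
    assert_that(length(genes) > 0, "empty gene set for term %s", p[1])
    list(name = p[2], genes = unique(genes))
  })
  names(out) <- ids
  out
}

#' Read the proband phenotype table
#'
#' Tab-separated with header; required columns: `id`, `sex` (male/female or
#' 1/2), `age_at_diagnosis`; optional: `father_age_at_conception`,
#' `mother_age_at_conception`, `cybocs_total`, `first_degree_relative_dx`,
#' `brain_trauma`, `comorbidity`, `dnsnv_count`, `pc1`..`pc5`. Blank cells
#' become `NA` (e.g. a blank CY-BOCS total is missing, not zero).
#'
#' @param path TSV file
#' @return data.frame, one row per proband
#' @export
read_phenotypes <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("NA", ""), quote = "")
  assert_that(all(c("id", "sex") %in% names(d)),
              "phenotype table needs id and sex columns")
  sx <- tolower(as.character(d$sex))
  sx[sx %in% c("1", "m")] <- "male"
  sx[sx %in% c("2", "f")] <- "female"
  bad <- !sx %in% c("male", "female")
  assert_that(!any(bad), "unknown sex code in phenotype table: %s",
              paste(unique(d$sex[bad]), collapse = ","))
  d$sex <- sx
  if ("cybocs_total" %in% names(d)) {
    ok <- is.na(d$cybocs_total) | (d$cybocs_total >= 0 & d$cybocs_total <= 40)
    assert_that(all(ok), "cybocs_total outside [0, 40]")
  }
  d
}

candidate_table_cols <- c("proband", "chrom", "pos_hg19", "ref", "alt", "hgvs",
                          "class", "gene", "population_af", "cadd_phred",
                          "filter_trail")

#' Write / read the candidate dnSNV table (TSV)
#'
#' Column layout mirrors the published per-variant table (proband, position,
#' alleles, HGVS, class, gene, population frequency, CADD PHRED) plus a
#' `filter_trail` column recording each filter's outcome. `population_af`
#' is carried as text so that `Absent` survives a round trip.
#'
#' @param candidates data.frame with at least the columns listed above
#' @param path output TSV
#' @export
write_candidate_table <- function(candidates, path) {
  missing_cols <- setdiff(candidate_table_cols, names(candidates))
  assert_that(length(missing_cols) == 0, "candidate table lacks: %s",
              paste(missing_cols, collapse = ", "))
  extras <- setdiff(names(candidates), candidate_table_cols)
  write.table(candidates[c(candidate_table_cols, extras)], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidate_table
#' @param path TSV produced by [write_candidate_table()] (or shaped like it)
#' @export
read_candidate_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("NA", ""), quote = "",
                  colClasses = "character")
  missing_cols <- setdiff(setdiff(candidate_table_cols, "filter_trail"), names(d))
  assert_that(length(missing_cols) == 0, "candidate table lacks: %s",
              paste(missing_cols, collapse = ", "))
  d$pos_hg19 <- as.integer(d$pos_hg19)
  d$cadd_phred <- as.numeric(d$cadd_phred)
  af <- parse_af_string(d$population_af)
  d$af <- af$af
  d$af_absent <- af$af_absent
  if (!"filter_trail" %in% names(d)) d$filter_trail <- ""
  d
}

#' Read a one-symbol-per-line reference gene list
#' @param path text file, one gene symbol per line
#' @return upper-cased character vector
#' @export
read_gene_list <- function(path) {
  g <- toupper(trimws(readLines(path, warn = FALSE)))
  unique(g[nzchar(g)])
}
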