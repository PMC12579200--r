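# Shared fixture builders: everything is generated in code or read from the
# packaged plain-text fixtures.

table1_path <- function() {
  system.file("extdata", "table1_dnsnvs.tsv", package = "triodnv")
}

load_table1 <- function() read_candidate_table(table1_path())

# The 36 cohort probands behind the published table: 21 with variants plus
# 15 with none.
table1_probands <- function() {
  with_var <- unique(load_table1()$proband)
  c(with_var, sprintf("TOCZ%02d", seq_len(36 - length(with_var))))
}

# Minimal hand-built cohort: `spec` is a list of site specs, each a list
# with chrom/pos/ref/alt/class/af/af_absent/gene/cadd and per-sample call
# rows (gt, ad_ref, ad_alt, gq, dp, ...). Matrices default to clean calls.
mini_cohort <- function(samples, site_specs) {
  n <- length(site_specs)
  m <- function(default) matrix(default, n, length(samples),
                                dimnames = list(NULL, samples))
  calls <- list(gt = m(0), gq = m(99), dp = m(50), ad_ref = m(50),
                ad_alt = m(0), ad_ref_fwd = m(25), ad_ref_rev = m(25),
                ad_alt_fwd = m(0), ad_alt_rev = m(0), min_bq = m(30))
  sites <- do.call(rbind, lapply(seq_along(site_specs), function(i) {
    s <- site_specs[[i]]
    data.frame(chrom = s$chrom %||% "chr1", pos = s$pos %||% (1000 + i),
               ref = s$ref %||% "A", alt = s$alt %||% "G",
               gene = s$gene %||% sprintf("G%d", i),
               class = s$class %||% "missense",
               af = s$af %||% NA_real_,
               af_absent = s$af_absent %||% TRUE,
               cadd = s$cadd %||% 25, stringsAsFactors = FALSE)
  }))
  for (i in seq_along(site_specs)) {
    for (field in intersect(names(site_specs[[i]]), names(calls))) {
      v <- site_specs[[i]][[field]]
      calls[[field]][i, names(v)] <- v
    }
  }
  # keep AD consistent with DP and strand splits consistent with AD
  calls$dp <- calls$ad_ref + calls$ad_alt
  calls$ad_ref_fwd <- floor(calls$ad_ref / 2)
  calls$ad_ref_rev <- calls$ad_ref - calls$ad_ref_fwd
  calls$ad_alt_fwd <- floor(calls$ad_alt / 2)
  calls$ad_alt_rev <- calls$ad_alt - calls$ad_alt_fwd
  trio_cohort(sites, calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-trio pedigree helpers
mini_trio_df <- function(proband = "P1", father = "D1", mother = "M1") {
  data.frame(family_id = "F1", proband = proband, father = father,
             mother = mother, proband_sex = 1L, stringsAsFactors = FALSE)
}

write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("P1", "D1", "M1")) {
  c("##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: Allele|Consequence|SYMBOL|gnomAD_NFE_AF|",
           "CADD_PHRED\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
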