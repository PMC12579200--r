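test_that("single-record VCF maps FORMAT fields onto genotype calls", {
  path <- write_mini_vcf(c(
    vcf_header(),
    paste(c("chr1", "100", ".", "A", "G", ".", "PASS",
            "CSQ=G|missense_variant|GENE1|0.0001|25", "GT:GQ:DP:AD",
            "0/1:99:20:10,10", "0/0:99:20:20,0", "0/0:99:20:20,0"),
          collapse = "\t")))
  co <- read_vcf(path, annotation = "csq")
  expect_equal(n_sites(co), 1)
  expect_equal(unname(co$calls$gt[1, ]), c(1, 0, 0))
  expect_equal(unname(co$calls$ad_alt[1, "P1"]), 10)
  expect_equal(co$sites$gene, "GENE1")
  expect_equal(co$sites$class, "missense")
  expect_equal(co$sites$af, 1e-4)
  s <- variant_site(co, 1)
  expect_equal(s$calls$P1$genotype, "het")
})

test_that("multi-allelic records split into biallelic SNVs; non-SNVs drop", {
  path <- write_mini_vcf(c(
    vcf_header(),
    paste(c("chr1", "100", ".", "G", "A,T", ".", "PASS", ".", "GT:DP:AD",
            "1/2:30:10,12,8", "0/1:30:20,10,0", "0/0:30:30,0,0"),
          collapse = "\t"),
    paste(c("chr1", "200", ".", "G", "GA,C", ".", "PASS", ".", "GT:DP:AD",
            "0/2:30:15,0,15", "0/0:30:30,0,0", "0/0:30:30,0,0"),
          collapse = "\t")))
  expect_message(co <- read_vcf(path, annotation = "none"), "non-SNV")
  # record 1 gives two sites at the same position; record 2 keeps only C
  expect_equal(n_sites(co), 3)
  expect_equal(co$sites$pos, c(100, 100, 200))
  expect_equal(co$sites$alt, c("A", "T", "C"))
  # allele-wise dosage: P1 is 1/2 -> one copy of each alt
  expect_equal(unname(co$calls$gt[1:2, "P1"]), c(1, 1))
  expect_equal(unname(co$calls$ad_alt[1:2, "P1"]), c(12, 8))
  expect_equal(unname(co$calls$ad_ref[1, "P1"]), 10)
})

test_that("malformed VCF and missing GT are rejected with a line reference", {
  bad <- write_mini_vcf(c(vcf_header(), "chr1\t100\tonly-three-fields"))
  expect_error(read_vcf(bad), "line 8")
  nogt <- write_mini_vcf(c(
    vcf_header(),
    paste(c("chr1", "100", ".", "A", "G", ".", "PASS", ".", "DP",
            "20", "20", "20"), collapse = "\t")))
  expect_error(read_vcf(nogt), "GT")
  notvcf <- write_mini_vcf(c("hello", "world"))
  expect_error(read_vcf(notvcf), "fileformat")
})

test_that("missing FORMAT fields become missing calls, not fabricated ones", {
  path <- write_mini_vcf(c(
    vcf_header(),
    paste(c("chr1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "0/0", "./."), collapse = "\t")))
  co <- read_vcf(path, annotation = "none")
  expect_true(all(is.na(co$calls$gq)))
  expect_true(all(is.na(co$calls$ad_alt)))
  expect_true(is.na(co$calls$gt[1, "M1"]))
  expect_equal(unname(co$calls$gt[1, "P1"]), 1)
})

test_that("AD/DP consistency is enforced at parse", {
  path <- write_mini_vcf(c(
    vcf_header(),
    paste(c("chr1", "100", ".", "A", "G", ".", "PASS", ".", "GT:DP:AD",
            "0/1:25:10,10", "0/0:20:20,0", "0/0:20:20,0"), collapse = "\t")))
  expect_error(read_vcf(path, annotation = "none"), "AD does not sum to DP")
})

test_that("sidecar annotation dialect is equivalent to CSQ", {
  side <- tempfile(fileext = ".tsv")
  write.table(data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                         gene = "GENE1", consequence = "splice_region_variant",
                         population_af = "Absent", cadd_phred = 3.2),
              side, sep = "\t", quote = FALSE, row.names = FALSE)
  path <- write_mini_vcf(c(
    vcf_header(),
    paste(c("chr1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "0/0", "0/0"), collapse = "\t")))
  co <- read_vcf(path, annotation = "sidecar", sidecar = side)
  expect_equal(co$sites$class, "splice")
  expect_true(co$sites$af_absent)
  expect_true(is.na(co$sites$af))  # absent is not frequency zero
  expect_equal(co$sites$cadd, 3.2)
})

test_that("VEP consequence terms collapse by severity", {
  expect_equal(collapse_consequence(c(
    "missense_variant", "stop_gained", "splice_donor_variant",
    "splice_region_variant&synonymous_variant", "stop_retained_variant",
    "intron_variant", "")),
    c("missense", "nonsense", "splice", "splice", "synonymous",
      "other", "other"))
})

test_that("BED blacklist uses 0-based half-open coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", bed)
  bl <- read_blacklist(bed)
  expect_true(in_blacklist("chr1", 11, bl))   # 1-based 11 -> 0-based 10
  expect_false(in_blacklist("chr1", 21, bl))  # half-open end
  expect_true(in_blacklist("chr1", 20, bl))
  expect_false(in_blacklist("chr1", 10, bl))
  expect_false(in_blacklist("chr2", 11, bl))

  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(length(read_blacklist(empty)), 0)
  expect_false(any(in_blacklist("chr1", 1:100, read_blacklist(empty))))

  badbed <- tempfile(fileext = ".bed")
  writeLines("chr1\t20\t10", badbed)
  expect_error(read_blacklist(badbed), "start >= end")
})

test_that("BED<->VCF coordinate conversion is self-inverse", {
  set.seed(11)
  start <- sample(0:999999, 200)
  end <- start + sample(1:1000, 200, replace = TRUE)
  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d", start, end), bed)
  bl <- read_blacklist(bed)
  pos <- sample(1:1000000, 500)
  direct <- vapply(pos, function(p) any(p - 1 >= start & p - 1 < end),
                   logical(1))
  expect_equal(in_blacklist(rep("chr1", 500), pos, bl), direct)
})

test_that("GMT parsing builds gene-set libraries", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("GO:0072583\tclathrin-dependent endocytosis\tA\tB",
               "GO:0035091\tphosphatidylinositol binding\tx\ty\tz"), gmt)
  lib <- read_gmt(gmt)
  expect_equal(length(lib[["GO:0072583"]]$genes), 2)
  expect_equal(lib[["GO:0035091"]]$genes, c("X", "Y", "Z"))  # upper-cased

  dup <- tempfile(fileext = ".gmt")
  writeLines(c("GO:1\ta\tA", "GO:1\tb\tB"), dup)
  expect_error(read_gmt(dup), "duplicate")
  empty_set <- tempfile(fileext = ".gmt")
  writeLines("GO:1\tdesc", empty_set)
  expect_error(read_gmt(empty_set), "empty")
})

test_that("candidate table round-trips the published 34-variant fixture", {
  t1 <- load_table1()
  expect_equal(nrow(t1), 34)
  expect_equal(length(unique(t1$gene)), 34)
  out <- tempfile(fileext = ".tsv")
  t1$filter_trail <- ""
  write_candidate_table(t1, out)
  back <- read_candidate_table(out)
  for (col in c("proband", "chrom", "pos_hg19", "ref", "alt", "hgvs",
                "class", "gene", "population_af", "cadd_phred"))
    expect_equal(back[[col]], t1[[col]], info = col)
  # 'Absent' population frequencies survive and stay distinct from zero
  expect_equal(sum(back$af_absent), sum(t1$population_af == "Absent"))
  expect_true(all(is.na(back$af[back$af_absent])))
})

test_that("phenotype table: blank CY-BOCS is missing; bad sex codes error", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsex\tage_at_diagnosis\tcybocs_total",
               "P1\tfemale\t12\t30", "P2\tM\t14\t", "P3\t2\t11\t16"), tsv)
  ph <- read_phenotypes(tsv)
  expect_equal(ph$sex, c("female", "male", "female"))
  expect_true(is.na(ph$cybocs_total[2]))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsex", "P1\txyz"), bad)
  expect_error(read_phenotypes(bad), "sex code")
})

test_that("pedigree trios are validated", {
  ped <- tempfile(fileext = ".ped")
  writeLines(c("F1 P1 D1 M1 1 2", "F1 D1 0 0 1 1", "F1 M1 0 0 2 1"), ped)
  p <- read_ped(ped)
  tdf <- trios(p)
  expect_equal(tdf$proband, "P1")
  expect_equal(tdf$father, "D1")

  bad_sex <- tempfile(fileext = ".ped")
  writeLines("F1 P1 0 0 9 2", bad_sex)
  expect_error(read_ped(bad_sex), "sex code")

  unaffected <- tempfile(fileext = ".ped")
  writeLines(c("F1 P1 D1 M1 1 1", "F1 D1 0 0 1 1", "F1 M1 0 0 2 1"),
             unaffected)
  expect_error(trios(read_ped(unaffected)), "affected")
})

test_that("VCF write-read round-trips calls and annotations", {
  sim <- simulate_cohort(sim_config(n_trios = 4, n_inherited_sites = 40,
                                    n_x_sites = 5, seed = 7))
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$cohort, path)
  back <- read_vcf(path, annotation = "csq")
  expect_equal(unname(back$calls$gt), unname(sim$cohort$calls$gt))
  for (f in c("gq", "dp", "ad_ref", "ad_alt", "ad_alt_fwd", "ad_alt_rev"))
    expect_equal(unname(back$calls[[f]]), unname(sim$cohort$calls[[f]]),
                 info = f, ignore_attr = TRUE)
  expect_equal(back$sites$class, sim$cohort$sites$class)
  expect_equal(back$sites$gene, sim$cohort$sites$gene)
  expect_equal(back$sites$af_absent, sim$cohort$sites$af_absent)
  expect_equal(back$sites$af,
               suppressWarnings(as.numeric(sprintf("%.6g", sim$cohort$sites$af))))
})
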