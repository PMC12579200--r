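#' Overlap of candidate genes against named reference lists
#'
#' Exact symbol intersection per reference list after upper-casing and
#' whitespace stripping; deterministic (alphabetical) ordering of the
#' overlapping genes.
#'
#' @param candidates character vector of candidate gene symbols
#' @param references named list of character vectors (reference gene lists)
#' @return data.frame: list_name, n_overlap, fraction (of candidates),
#'   overlapping_genes (comma-separated)
#' @export
overlap_genes <- function(candidates, references) {
  cand <- unique(toupper(trimws(candidates)))
  cand <- cand[nzchar(cand)]
  if (length(cand) == 0) {
    warning("empty candidate gene set")
    return(data.frame(list_name = character(), n_overlap = integer(),
                      fraction = numeric(), overlapping_genes = character()))
  }
  rows <- lapply(names(references), function(nm) {
    ref <- unique(toupper(trimws(references[[nm]])))
    ov <- sort(intersect(cand, ref))
    data.frame(list_name = nm, n_overlap = length(ov),
               fraction = length(ov) / length(cand),
               overlapping_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hypergeometric gene-set enrichment over a GMT library
#'
#' Per term, the upper-tail hypergeometric p-value `P(X >= k)` for drawing
#' `k` of the term's `K` genes in a query of size `n` from a universe of
#' size `N` (equivalent to the one-sided Fisher exact test on the 2x2
#' overlap table), with Benjamini-Hochberg FDR across the library's terms.
#' Query genes outside the universe are dropped (and counted); the default
#' universe is the union of the library's genes.
#'
#' @param query character vector of gene symbols
#' @param library a [read_gmt()] gene-set library
#' @param universe background gene symbols; `NULL` = union of library genes
#' @return data.frame: term, name, k, n, K, N, odds_ratio, p, p_adj;
#'   attribute `n_dropped` = query genes outside the universe
#' @export
gene_set_enrichment <- function(query, library, universe = NULL) {
  query <- unique(toupper(trimws(query)))
  if (is.null(universe))
    universe <- unique(unlist(lapply(library, `[[`, "genes")))
  universe <- unique(toupper(trimws(universe)))
  sizes <- vapply(library, function(t) length(t$genes), integer(1))
  assert_that(all(sizes <= length(universe)),
              "universe smaller than term %s", names(library)[which.max(sizes)])
  dropped <- setdiff(query, universe)
  query <- intersect(query, universe)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(library), function(id) {
    genes <- intersect(library[[id]]$genes, universe)
    K <- length(genes)
    k <- length(intersect(query, genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    orr <- (k * (N - K - n + k)) / max(1, (K - k) * (n - k))
    data.frame(term = id, name = library[[id]]$name, k = k, n = n, K = K,
               N = N, odds_ratio = orr, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr(out$p)
  attr(out, "n_dropped") <- length(dropped)
  out
}

#' Terms significant in both of two enrichment runs
#'
#' The meta-analysis rule: an enrichment is reported only when the same
#' term is significant (adjusted p below `alpha`) in two runs over two
#' annotation sources.
#'
#' @param run1,run2 data.frames from [gene_set_enrichment()]
#' @param alpha adjusted-p threshold (default 0.05)
#' @export
consensus_terms <- function(run1, run2, alpha = 0.05) {
  sig1 <- run1$term[run1$p_adj < alpha]
  sig2 <- run2$term[run2$p_adj < alpha]
  sort(intersect(sig1, sig2))
}

#' Tissue-expression presence from a TPM matrix
#'
#' A gene is called expressed in a tissue iff its TPM is at or above
#' `threshold` (default 1). Genes absent from the matrix are reported
#' `unmeasured`. The summary flag marks genes expressed in at least one
#' tissue.
#'
#' @param genes character vector of gene symbols
#' @param tpm numeric matrix, genes x tissues (rownames = symbols)
#' @param threshold TPM presence threshold (default 1; `>=` semantics)
#' @return list: `presence` (genes x tissues logical, NA for unmeasured),
#'   `expressed_any` (named logical, NA for unmeasured)
#' @export
expression_presence <- function(genes, tpm, threshold = 1) {
  genes <- unique(toupper(trimws(genes)))
  rownames(tpm) <- toupper(rownames(tpm))
  pres <- matrix(NA, length(genes), ncol(tpm),
                 dimnames = list(genes, colnames(tpm)))
  measured <- intersect(genes, rownames(tpm))
  pres[measured, ] <- tpm[measured, , drop = FALSE] >= threshold
  any_expr <- apply(pres, 1, function(r) if (all(is.na(r))) NA else
    any(r, na.rm = TRUE))
  list(presence = pres, expressed_any = any_expr)
}

#' Load the packaged reference gene lists
#'
#' One file per disorder/source under `inst/extdata/reference_lists/`
#' (one symbol per line), e.g. the OCD rare-variant and OCD GWAS lists.
#'
#' @param dir directory of gene-list files; default the packaged set
#' @return named list of character vectors
#' @export
load_reference_lists <- function(dir = system.file("extdata",
                                                   "reference_lists",
                                                   package = "triodnv")) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  assert_that(length(files) > 0, "no reference lists found in %s", dir)
  out <- lapply(files, read_gene_list)
  names(out) <- sub("\\.txt$", "", basename(files))
  out
}
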