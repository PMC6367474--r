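#' Load an IGH germline gene reference
#'
#' The reference lists every germline gene with its locus (IGHV/IGHD/IGHJ),
#' IMGT functionality class, position along the locus, an optional alias
#' (for gene pairs with identical germline sequences whose assignments are
#' indistinguishable, IGHD4-4/IGHD4-11 and IGHD5-5/IGHD5-18), and an
#' exclusion flag for genes dropped from inference because their assignments
#' are unreliable (IGHV1-69D, which most alleles cannot separate from
#' IGHV1-69, and IGHV4-30-1, which lacks a usable reference annotation).
#'
#' A curated default table following standard IMGT nomenclature ships with
#' the package and is used when `path` is `NULL`; supply your own TSV with
#' the same columns to override it.
#'
#' @param path Path to a tab-separated reference with columns `gene`,
#'   `locus`, `functionality`, `locus_order`, `alias_of`, `exclude`, or
#'   `NULL` for the packaged default.
#' @return A tibble with those columns; `alias_of` is `NA` for canonical
#'   genes and `exclude` is logical.
#' @examples
#' ref <- loadGeneReference()
#' subset(ref, locus == "IGHJ")
#' @export
loadGeneReference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "igh_gene_reference.tsv", package = "ighap",
                        mustWork = TRUE)
  }
  ref <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              na.strings = c("NA", "")))
  required <- c("gene", "locus", "functionality", "locus_order", "alias_of",
                "exclude")
  missing <- setdiff(required, names(ref))
  if (length(missing) > 0) {
    stop("gene reference is missing columns: ", paste(missing, collapse = ", "))
  }
  ref$exclude <- as.logical(ref$exclude)
  ref$locus_order <- as.integer(ref$locus_order)
  bad_locus <- setdiff(unique(ref$locus), c("IGHV", "IGHD", "IGHJ"))
  if (length(bad_locus) > 0) {
    stop("unknown locus in gene reference: ", paste(bad_locus, collapse = ", "))
  }
  dup <- ref %>%
    group_by(.data$locus, .data$locus_order) %>%
    summarise(n = n(), .groups = "drop") %>%
    filter(n > 1L)
  if (nrow(dup) > 0) {
    stop("locus_order indices must be unique within a locus")
  }
  # alias map must be idempotent: an alias target is itself canonical
  alias_targets <- ref$alias_of[!is.na(ref$alias_of)]
  noncanon <- alias_targets[alias_targets %in% ref$gene[!is.na(ref$alias_of)]]
  if (length(noncanon) > 0) {
    stop("alias chains are not allowed: ", paste(unique(noncanon), collapse = ", "))
  }
  ref
}

#' Map gene names to their canonical representative
#'
#' Applies the reference's alias map (identity for canonical or unknown
#' genes). Idempotent by construction.
#'
#' @param genes Character vector of gene names.
#' @param reference A gene reference from [loadGeneReference()].
#' @return Character vector of canonical gene names.
#' @export
canonicalGene <- function(genes, reference = loadGeneReference()) {
  map <- setNames(reference$alias_of, reference$gene)
  out <- map[genes]
  ifelse(is.na(out), genes, unname(out))
}

#' Order genes by their position along the locus
#'
#' @param genes Character vector of gene names.
#' @param reference A gene reference from [loadGeneReference()].
#' @return `genes` sorted by locus then locus position; unknown genes are
#'   placed last in name order.
#' @export
orderByLocus <- function(genes, reference = loadGeneReference()) {
  idx <- match(genes, reference$gene)
  locus_rank <- match(reference$locus[idx], c("IGHV", "IGHD", "IGHJ"))
  ord <- order(is.na(idx), locus_rank, reference$locus_order[idx], genes)
  genes[ord]
}
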