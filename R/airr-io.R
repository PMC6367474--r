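#' Parse an IMGT-style allele call string
#'
#' Decomposes a V/D/J call such as `"IGHV3-23*01"` into locus, gene, family
#' and allele. Multiple assignments separated by commas (or the `" or "` /
#' bracketed ambiguity notations some aligners emit) yield one row per
#' distinct gene*allele token, in input order with duplicates collapsed.
#'
#' @param raw A single non-empty call string.
#' @return A tibble with columns `raw` (the token), `locus`, `gene`,
#'   `family`, `allele` and `multiple` (TRUE when the input held more than
#'   one distinct token).
#' @examples
#' parseAlleleCall("IGHV3-23*01")
#' parseAlleleCall("IGHJ6*02,IGHJ6*03")
#' @export
parseAlleleCall <- function(raw) {
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("allele call must be a single non-empty string")
  }
  tokens <- splitCallTokens(raw)
  tokens <- tokens[!duplicated(tokens)]
  locus <- getLocus(tokens)
  if (anyNA(locus)) {
    bad <- tokens[is.na(locus)][1L]
    stop("malformed allele call token (no IGHV/IGHD/IGHJ locus prefix): '",
         bad, "'")
  }
  tibble(
    raw = tokens,
    locus = locus,
    gene = getGene(tokens),
    family = getFamily(tokens),
    allele = getAllele(tokens),
    multiple = length(tokens) > 1L
  )
}

# split a call string on the separators used for multiple assignments
splitCallTokens <- function(raw) {
  x <- gsub("\\[|\\]|\\(|\\)", "", raw)
  x <- gsub("\\s+or\\s+", ",", x)
  tokens <- trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  tokens[nzchar(tokens)]
}

#' Extract locus, gene, family or allele from single call tokens
#'
#' Vectorized helpers over tokens like `"IGHV3-23*01"`. `getLocus()` returns
#' `NA` for tokens without an IGHV/IGHD/IGHJ prefix; `getAllele()` returns
#' `NA` for gene-only tokens.
#'
#' @param calls Character vector of single-assignment call tokens.
#' @return Character vector of the requested component.
#' @export
getLocus <- function(calls) {
  m <- regmatches(calls, regexpr("^IGH[VDJ]", calls))
  out <- rep(NA_character_, length(calls))
  out[regexpr("^IGH[VDJ]", calls) == 1L] <- m
  out
}

#' @rdname getLocus
#' @export
getGene <- function(calls) {
  sub("\\*.*$", "", calls)
}

#' @rdname getLocus
#' @export
getFamily <- function(calls) {
  sub("-.*$", "", getGene(calls))
}

#' @rdname getLocus
#' @export
getAllele <- function(calls) {
  out <- rep(NA_character_, length(calls))
  has <- grepl("*", calls, fixed = TRUE)
  out[has] <- sub("^[^*]*\\*", "", calls[has])
  out
}

#' Format gene and allele back into a canonical call token
#'
#' Inverse of [parseAlleleCall()] on canonical names.
#'
#' @param gene,allele Character vectors.
#' @return Character vector of `"gene*allele"` tokens.
#' @export
formatAlleleCall <- function(gene, allele) {
  ifelse(is.na(allele) | !nzchar(allele), gene, paste0(gene, "*", allele))
}

# Change-O style header synonyms accepted out of the box
.changeoMap <- c(
  SEQUENCE_ID = "sequence_id", V_CALL = "v_call", D_CALL = "d_call",
  J_CALL = "j_call", DUPCOUNT = "duplicate_count",
  V_MUT = "v_mutation_count", D_MUT = "d_mutation_count",
  SUBJECT = "subject_id"
)

#' Read an AIRR Rearrangement table
#'
#' Reads a tab-separated rearrangement table with AIRR standard column
#' names. A `column_map` (named vector, `file_name = "airr_name"`) renames
#' non-standard headers; Change-O upper-case names are recognized
#' automatically. Mandatory columns after mapping are `sequence_id`,
#' `v_call`, `d_call` and `j_call`. `duplicate_count` defaults to 1 when
#' absent; absent mutation-count columns are reported with a warning (which
#' disables mutation filtering downstream); an absent `subject_id` is filled
#' with `"S1"`.
#'
#' @param path Path to the TSV file.
#' @param column_map Optional named character vector mapping file column
#'   names to AIRR names.
#' @return A tibble with one row per rearrangement.
#' @export
readRearrangements <- function(path, column_map = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), check.names = FALSE)
  if (nrow(df) == 0L) {
    stop("rearrangement file is empty: ", path)
  }
  map <- .changeoMap
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  hit <- names(df) %in% names(map)
  names(df)[hit] <- unname(map[names(df)[hit]])

  mandatory <- c("sequence_id", "v_call", "d_call", "j_call")
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0) {
    stop("rearrangement table is missing mandatory columns: ",
         paste(missing, collapse = ", "))
  }
  if (!"duplicate_count" %in% names(df)) df$duplicate_count <- 1L
  for (col in c("v_mutation_count", "d_mutation_count")) {
    if (!col %in% names(df)) {
      warning("column '", col, "' absent; mutation filtering on it is disabled")
      df[[col]] <- NA_integer_
    }
  }
  if (!"subject_id" %in% names(df)) df$subject_id <- "S1"
  df$duplicate_count <- as.integer(df$duplicate_count)
  df$v_mutation_count <- as.integer(df$v_mutation_count)
  df$d_mutation_count <- as.integer(df$d_mutation_count)
  as_tibble(df)
}

#' Apply germline gene filtration to rearrangement calls
#'
#' Removes call tokens to ORF and pseudogenes, removes genes flagged as
#' excluded in the reference (IGHV1-69D, whose alleles are mostly
#' indistinguishable from IGHV1-69, and IGHV4-30-1), and rewrites genes
#' whose germline sequence is identical to another gene's onto the canonical
#' member of the pair (IGHD4-4 to IGHD4-11, IGHD5-5 to IGHD5-18). Records
#' left without any V or J call are excluded. Genes absent from the
#' reference pass through untouched and are counted in the report. The
#' operation is idempotent.
#'
#' @param records Rearrangement tibble from [readRearrangements()].
#' @param reference Gene reference from [loadGeneReference()].
#' @return A list with `records` (filtered tibble) and `report` (tibble of
#'   `rule`, `count`).
#' @export
applyGeneFiltration <- function(records, reference = loadGeneReference()) {
  drop_fun <- reference$gene[reference$functionality %in% c("ORF", "pseudo")]
  drop_excl <- reference$gene[reference$exclude]
  counts <- c(removed_orf_pseudo = 0L, removed_excluded = 0L,
              aliased = 0L, unknown_gene_tokens = 0L, records_excluded = 0L)

  rewriteColumn <- function(calls) {
    u <- unique(calls[!is.na(calls)])
    if (length(u) == 0L) return(calls)
    new <- vapply(u, function(x) {
      tokens <- splitCallTokens(x)
      genes <- getGene(tokens)
      keep <- !(genes %in% drop_fun) & !(genes %in% drop_excl)
      counts["removed_orf_pseudo"] <<-
        counts["removed_orf_pseudo"] + sum(genes %in% drop_fun)
      counts["removed_excluded"] <<-
        counts["removed_excluded"] + sum(genes %in% drop_excl)
      counts["unknown_gene_tokens"] <<-
        counts["unknown_gene_tokens"] + sum(!genes %in% reference$gene)
      tokens <- tokens[keep]
      genes <- genes[keep]
      canon <- canonicalGene(genes, reference)
      counts["aliased"] <<- counts["aliased"] + sum(canon != genes)
      tokens <- ifelse(canon == genes, tokens,
                       formatAlleleCall(canon, getAllele(tokens)))
      tokens <- tokens[!duplicated(tokens)]
      paste(tokens, collapse = ",")
    }, character(1))
    out <- new[calls]
    out[is.na(calls)] <- NA_character_
    unname(out)
  }

  records$v_call <- rewriteColumn(records$v_call)
  records$d_call <- rewriteColumn(records$d_call)
  records$j_call <- rewriteColumn(records$j_call)

  keep <- nzchar(records$v_call) & !is.na(records$v_call) &
    nzchar(records$j_call) & !is.na(records$j_call)
  counts["records_excluded"] <- sum(!keep)
  list(
    records = records[keep, , drop = FALSE],
    report = tibble(rule = names(counts), count = unname(counts))
  )
}

.haplotypeCols <- c("subject", "anchor_gene", "anchor_A", "anchor_B", "gene",
                    "alleles_chrA", "alleles_chrB", "counts_chrA",
                    "counts_chrB", "lK", "call_state")

#' Write and read haplotype tables
#'
#' The on-disk dialect is a TSV with columns `subject`, `anchor_gene`,
#' `anchor_A`, `anchor_B`, `gene`, `alleles_chrA`, `alleles_chrB`,
#' `counts_chrA`, `counts_chrB`, `lK`, `call_state`. Multiple alleles are
#' joined by commas; a chromosome with no surviving allele carries the
#' literal token `"deleted"`, `"suspected_deleted"`, `"unknown"` or `"NA"`.
#' All rows must share one subject and one anchor definition.
#'
#' @param calls Haplotype tibble from [inferHaplotype()].
#' @param path Output file path.
#' @return `writeHaplotypeTable()` returns `path` invisibly;
#'   `readHaplotypeTable()` returns the tibble.
#' @export
writeHaplotypeTable <- function(calls, path) {
  missing <- setdiff(.haplotypeCols, names(calls))
  if (length(missing) > 0) {
    stop("haplotype table is missing columns: ", paste(missing, collapse = ", "))
  }
  anchors <- unique(calls[, c("subject", "anchor_gene", "anchor_A", "anchor_B")])
  if (nrow(anchors) > 1L) {
    stop("haplotype table mixes subjects or anchor definitions")
  }
  out <- calls[, .haplotypeCols]
  out$lK <- sprintf("%.10g", out$lK)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname writeHaplotypeTable
#' @export
readHaplotypeTable <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", check.names = FALSE,
                   colClasses = "character")
  missing <- setdiff(.haplotypeCols, names(df))
  if (length(missing) > 0) {
    stop("haplotype table is missing columns: ", paste(missing, collapse = ", "))
  }
  df$counts_chrA <- as.integer(df$counts_chrA)
  df$counts_chrB <- as.integer(df$counts_chrB)
  df$lK <- as.numeric(df$lK)
  as_tibble(df)
}

#' Write a deletion table
#'
#' TSV with columns `subject`, `gene`, `state` (one of `present`,
#' `deleted_both`, `deleted_chrA`, `deleted_chrB`, `suspected`, `NA`),
#' `statistic` and `q_or_lK`.
#'
#' @param deletions Deletion tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeDeletionTable <- function(deletions, path) {
  required <- c("subject", "gene", "state", "statistic", "q_or_lK")
  missing <- setdiff(required, names(deletions))
  if (length(missing) > 0) {
    stop("deletion table is missing columns: ", paste(missing, collapse = ", "))
  }
  write.table(deletions[, required], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
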