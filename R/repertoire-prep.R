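#' Filter rearrangements to the inference-grade subset
#'
#' Keeps sequences that look germline enough to carry unambiguous allele
#' information: at most `max_v_mut` mutations in the V segment (default 3),
#' at most `max_d_mut` in the D segment (default 0, i.e. none), and -- when
#' `require_single` -- exactly one V, one D and one J assignment. Subjects
#' whose retained depth falls below `min_depth` (default 2000 sequences) are
#' flagged as failing coverage QC; their records are kept so the caller can
#' decide, but downstream inference should not use them.
#'
#' Set `max_v_mut` or `max_d_mut` to `NULL` to disable that filter (required
#' when the input lacks the corresponding mutation-count column).
#'
#' @param records Rearrangement tibble.
#' @param max_v_mut,max_d_mut Maximum allowed mutation counts, or `NULL`.
#' @param require_single Require single V/D/J assignments.
#' @param min_depth Minimum retained sequences per subject.
#' @return A list with `records` (retained rows), `qc` (per-rule exclusion
#'   counts) and `subjects` (per-subject retained depth and pass flag).
#' @export
filterForInference <- function(records, max_v_mut = 3, max_d_mut = 0,
                               require_single = TRUE, min_depth = 2000) {
  if (nrow(records) == 0L) stop("no records to filter")
  nTokens <- function(x) {
    out <- integer(length(x))
    ok <- !is.na(x) & nzchar(x)
    out[ok] <- lengths(regmatches(x[ok], gregexpr(",", x[ok], fixed = TRUE))) + 1L
    out
  }
  keep <- rep(TRUE, nrow(records))
  qc <- list()

  checkMut <- function(col, cap, label) {
    if (is.null(cap)) return(invisible(NULL))
    vals <- records[[col]]
    if (anyNA(vals)) {
      stop("mutation filter on '", col, "' requested but counts are absent; ",
           "set the corresponding max to NULL to disable")
    }
    fail <- vals > cap
    qc[[label]] <<- sum(fail)
    keep <<- keep & !fail
  }
  checkMut("v_mutation_count", max_v_mut, "v_mutations")
  checkMut("d_mutation_count", max_d_mut, "d_mutations")

  if (require_single) {
    for (col in c("v_call", "d_call", "j_call")) {
      fail <- nTokens(records[[col]]) != 1L
      qc[[paste0("multiple_or_missing_", substr(col, 1, 1))]] <- sum(fail)
      keep <- keep & !fail
    }
  }

  retained <- records[keep, , drop = FALSE]
  subjects <- retained %>%
    group_by(subject_id = .data$subject_id) %>%
    summarise(retained = n(), .groups = "drop")
  # subjects filtered out entirely still appear, with depth 0
  all_subj <- unique(records$subject_id)
  absent <- setdiff(all_subj, subjects$subject_id)
  if (length(absent) > 0) {
    subjects <- bind_rows(subjects, tibble(subject_id = absent, retained = 0L))
  }
  subjects$pass <- subjects$retained >= min_depth
  subjects <- arrange(subjects, .data$subject_id)

  list(
    records = retained,
    qc = tibble(rule = names(qc), excluded_count = as.integer(unlist(qc))),
    subjects = subjects
  )
}

# long format: one row per (record, locus) with gene and allele
.callsLong <- function(records) {
  pieces <- lapply(c(v_call = "v_call", d_call = "d_call", j_call = "j_call"),
                   function(col) {
    calls <- records[[col]]
    ok <- !is.na(calls) & nzchar(calls)
    tibble(
      subject_id = records$subject_id[ok],
      locus = toupper(sub("_call", "", col)),
      call = calls[ok]
    )
  })
  long <- bind_rows(pieces)
  long$locus <- c(V = "IGHV", D = "IGHD", J = "IGHJ")[substr(long$locus, 1, 1)]
  long$gene <- getGene(long$call)
  long$allele <- getAllele(long$call)
  long
}

#' Compute relative gene and allele usage
#'
#' Relative gene usage is the fraction of a subject's rearrangements within
#' a locus that use the gene; allele usage is the within-gene fraction of
#' each allele. Each record counts once (one recombination event), ignoring
#' `duplicate_count`. Genes observed in any subject but absent from another
#' get an explicit usage of 0 for that subject.
#'
#' @param records Filtered, single-assignment rearrangement tibble.
#' @return A list of tibbles: `genes` (`subject_id`, `locus`, `gene`, `n`,
#'   `fraction`), `alleles` (`subject_id`, `locus`, `gene`, `allele`, `n`,
#'   `fraction`) and `totals` (`subject_id`, `locus`, `total`).
#' @export
computeUsage <- function(records) {
  if (nrow(records) == 0L) stop("cannot compute usage of an empty record set")
  long <- .callsLong(records)

  totals <- long %>%
    group_by(.data$subject_id, .data$locus) %>%
    summarise(total = n(), .groups = "drop")

  genes <- long %>%
    group_by(.data$subject_id, .data$locus, .data$gene) %>%
    summarise(n = n(), .groups = "drop")
  # complete over the union of genes seen in the cohort, per locus
  grid <- tidyr::expand_grid(
    subject_id = unique(long$subject_id),
    distinct(long, .data$locus, .data$gene)
  )
  genes <- grid %>%
    left_join(genes, by = c("subject_id", "locus", "gene")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    left_join(totals, by = c("subject_id", "locus")) %>%
    mutate(total = ifelse(is.na(.data$total), 0L, .data$total),
           fraction = ifelse(.data$total > 0, .data$n / .data$total, 0)) %>%
    select(-"total") %>%
    arrange(.data$subject_id, .data$locus, .data$gene)

  alleles <- long %>%
    filter(!is.na(.data$allele)) %>%
    group_by(.data$subject_id, .data$locus, .data$gene, .data$allele) %>%
    summarise(n = n(), .groups = "drop") %>%
    group_by(.data$subject_id, .data$gene) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    arrange(.data$subject_id, .data$locus, .data$gene, .data$allele)

  list(genes = genes, alleles = alleles, totals = totals)
}

#' Summarize per-subject genotypes with zygosity
#'
#' For each subject and gene, retains up to four alleles (descending count,
#' ties broken by allele name), after dropping alleles below
#' `min_allele_fraction` of the gene's sequences. A gene supported by fewer
#' than `min_seqs` sequences (default 10) gets zygosity `NA`; otherwise it
#' is heterozygous when two or more alleles survive, homozygous when one
#' does. The default `min_allele_fraction = 0` describes the full genotype;
#' use 0.30 when screening candidate anchor genes, where weak minor alleles
#' are treated as homozygous.
#'
#' @param records Filtered rearrangement tibble.
#' @param min_seqs Minimum supporting sequences for a defined zygosity.
#' @param min_allele_fraction Within-gene fraction below which an allele is
#'   dropped.
#' @return Tibble with `subject_id`, `locus`, `gene`, `alleles`
#'   (comma-joined, descending count), `count`, `zygosity` and
#'   `minor_fraction` (within-gene fraction of the second most used
#'   retained allele, 0 when fewer than two survive).
#' @export
summarizeGenotype <- function(records, min_seqs = 10, min_allele_fraction = 0) {
  long <- .callsLong(records) %>% filter(!is.na(.data$allele))
  if (nrow(long) == 0L) stop("no resolved allele calls to summarize")
  per_allele <- long %>%
    group_by(.data$subject_id, .data$locus, .data$gene, .data$allele) %>%
    summarise(n = n(), .groups = "drop") %>%
    group_by(.data$subject_id, .data$locus, .data$gene) %>%
    mutate(gene_count = sum(.data$n), fraction = .data$n / .data$gene_count) %>%
    arrange(desc(.data$n), .data$allele, .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    ungroup()

  kept <- per_allele %>%
    filter(.data$fraction >= min_allele_fraction | .data$rank == 1L,
           .data$rank <= 4L)

  kept %>%
    group_by(.data$subject_id, .data$locus, .data$gene) %>%
    summarise(
      alleles = paste(.data$allele, collapse = ","),
      count = first(.data$gene_count),
      n_alleles = n(),
      minor_fraction = if (n() >= 2L) .data$fraction[2L] else 0,
      .groups = "drop"
    ) %>%
    mutate(zygosity = ifelse(.data$count < min_seqs, NA_character_,
                             ifelse(.data$n_alleles >= 2L, "heterozygous",
                                    "homozygous"))) %>%
    select("subject_id", "locus", "gene", "alleles", "count", "zygosity",
           "minor_fraction")
}
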