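#' Define an anchor gene and its chromosome-labelling allele groups
#'
#' A heterozygous anchor gene identifies the two chromosomes: every
#' rearrangement carrying a group-A allele of the anchor is attributed to
#' chromosome A, group-B to chromosome B. Classically the anchor is IGHJ6
#' with groups `"02"` and `"03"`; a group may hold several alleles (e.g.
#' adding `"04"` to the `"02"` group for subjects heterozygous 03/04).
#'
#' @param gene Anchor gene name (e.g. `"IGHJ6"`).
#' @param group_a,group_b Non-empty, disjoint character vectors of allele
#'   designators.
#' @return An `anchorConfig` list with elements `gene`, `group_a`,
#'   `group_b`.
#' @export
anchorConfig <- function(gene, group_a, group_b) {
  if (!nzchar(gene)) stop("anchor gene must be named")
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both anchor allele groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("anchor allele groups must be disjoint")
  }
  structure(list(gene = gene, group_a = group_a, group_b = group_b),
            class = "anchorConfig")
}

#' Inference parameters for haplotype calling
#'
#' @param epsilon Constant allele mis-assignment probability in `[0, 0.5)`;
#'   default 0.01. With `epsilon = 0` the single-chromosome models put zero
#'   mass on cross-chromosome counts, and impossible counts are handled in
#'   log space (certainty capped at `lk_cap`).
#' @param lk_assign Minimum lK to assign an allele to a chromosome
#'   (default 3, i.e. Bayes factor 1000).
#' @param lk_delete Minimum lK to upgrade a suspected deletion to a deletion
#'   call (default 3).
#' @param priors `"uniform"` for equal model priors, `"empirical"` to set
#'   the both-chromosomes prior from the subject-wide fraction of genes with
#'   two observed alleles, or a numeric vector of 3 non-negative weights
#'   (chrA-only, chrB-only, both).
#' @param lk_cap Reporting cap for lK when the runner-up model has zero
#'   likelihood (default 300).
#' @return A `haplotypeParams` list.
#' @export
haplotypeParams <- function(epsilon = 0.01, lk_assign = 3, lk_delete = 3,
                            priors = "uniform", lk_cap = 300) {
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must lie in [0, 0.5)")
  if (is.numeric(priors)) {
    if (length(priors) != 3L || any(priors < 0) || sum(priors) <= 0) {
      stop("numeric priors must be 3 non-negative weights")
    }
    priors <- priors / sum(priors)
  } else if (!priors[1] %in% c("uniform", "empirical")) {
    stop("priors must be 'uniform', 'empirical' or a numeric weight vector")
  }
  structure(list(epsilon = epsilon, lk_assign = lk_assign,
                 lk_delete = lk_delete, priors = priors, lk_cap = lk_cap),
            class = "haplotypeParams")
}

#' Model success probabilities for the three chromosomal hypotheses
#'
#' The count vector for a target allele is \eqn{X = (n_1, n_2)}, its
#' co-occurrences with the anchor's group-A and group-B alleles. Under the
#' chromosome-A-only model the group-A success probability is
#' \eqn{(1+\epsilon)/(1+2\epsilon)}; under chromosome-B-only it is
#' \eqn{\epsilon/(1+2\epsilon)}; under the both-chromosomes model it is
#' \eqn{(p_A+\epsilon)/(1+2\epsilon)} with \eqn{p_A} the group-A share of
#' anchor-bearing sequences.
#'
#' @param epsilon Mis-assignment probability.
#' @param p_a Group-A anchor allele share in `(0, 1)`.
#' @return Named numeric vector `c(chrA=, chrB=, both=)` of group-A success
#'   probabilities.
#' @export
modelTheta <- function(epsilon, p_a) {
  c(chrA = (1 + epsilon) / (1 + 2 * epsilon),
    chrB = epsilon / (1 + 2 * epsilon),
    both = (p_a + epsilon) / (1 + 2 * epsilon))
}

.resolvePriors <- function(priors) {
  if (is.numeric(priors)) return(priors)
  c(1, 1, 1) / 3  # uniform; the empirical mode is resolved per subject
}

#' Score the three chromosomal models for one count vector
#'
#' Computes, for each model, the unnormalized log posterior weight
#' `log Binomial(n1; n1+n2, theta_m) + log prior_m`, ranks the models, and
#' returns the Bayes-factor certainty `lK = log10(best / second)`. When the
#' runner-up has zero likelihood (possible only with `epsilon = 0`), lK is
#' reported as `lk_cap`.
#'
#' @param n1,n2 Co-occurrence counts with anchor groups A and B
#'   (`n1 + n2 >= 1`).
#' @param p_a Group-A anchor share.
#' @param params A [haplotypeParams()] object (numeric or uniform priors).
#' @return A list with `best`, `second` (model names among `"chrA"`,
#'   `"chrB"`, `"both"`), `lK`, and `log_post` (named unnormalized log
#'   posterior vector).
#' @export
scoreModels <- function(n1, n2, p_a, params = haplotypeParams()) {
  if (n1 + n2 < 1) stop("score requires at least one observation")
  theta <- modelTheta(params$epsilon, p_a)
  pri <- .resolvePriors(params$priors)
  log_post <- dbinom(n1, n1 + n2, theta, log = TRUE) + log(pri)
  names(log_post) <- names(theta)
  ord <- order(log_post, decreasing = TRUE)
  best <- names(log_post)[ord[1L]]
  second <- names(log_post)[ord[2L]]
  if (!is.finite(log_post[ord[1L]])) {
    stop("all model posteriors are zero; check p_a and priors")
  }
  lK <- (log_post[ord[1L]] - log_post[ord[2L]]) / log(10)
  lK <- unname(min(lK, params$lk_cap))
  list(best = best, second = second, lK = lK, log_post = log_post)
}

#' Build anchor-conditioned contingency counts
#'
#' Restricts to records whose anchor-locus call is the anchor gene with an
#' allele in one of the two groups, and tallies for every (target gene,
#' allele) how many sequences carry it together with each anchor group.
#' Each record contributes exactly once (one recombination event). Records
#' carrying the anchor gene with an allele outside both groups are excluded
#' and counted.
#'
#' @param records Filtered single-assignment rearrangement tibble for one
#'   subject.
#' @param anchor An [anchorConfig()].
#' @param target_locus Locus of the genes to phase (`"IGHV"`, `"IGHD"`,
#'   `"IGHJ"`); must differ from the anchor's locus only in that the anchor
#'   gene itself is skipped.
#' @return A list with `rows` (tibble `gene`, `allele`, `n1`, `n2`), `p_a`
#'   (group-A share of anchor-bearing records, clamped to
#'   `[1e-6, 1 - 1e-6]`), `n_anchor_a`, `n_anchor_b`, and
#'   `excluded_other_allele`.
#' @export
buildContingency <- function(records, anchor, target_locus) {
  anchor_locus <- getLocus(anchor$gene)
  anchor_col <- c(IGHV = "v_call", IGHD = "d_call", IGHJ = "j_call")[anchor_locus]
  target_col <- c(IGHV = "v_call", IGHD = "d_call", IGHJ = "j_call")[target_locus]

  acall <- records[[anchor_col]]
  is_anchor <- !is.na(acall) & getGene(acall) == anchor$gene
  if (!any(is_anchor)) {
    stop("anchor gene ", anchor$gene, " absent from records")
  }
  aallele <- getAllele(acall)
  in_a <- is_anchor & aallele %in% anchor$group_a
  in_b <- is_anchor & aallele %in% anchor$group_b
  excluded <- sum(is_anchor & !in_a & !in_b)

  n_a <- sum(in_a); n_b <- sum(in_b)
  if (n_a == 0L || n_b == 0L) {
    warning("one anchor allele group has no records; p clamped")
  }
  p_a <- min(max(n_a / max(n_a + n_b, 1L), 1e-6), 1 - 1e-6)

  tcall <- records[[target_col]]
  keep <- (in_a | in_b) & !is.na(tcall) & nzchar(tcall) &
    getGene(tcall) != anchor$gene
  rows <- tibble(
    gene = getGene(tcall[keep]),
    allele = getAllele(tcall[keep]),
    group = ifelse(in_a[keep], "n1", "n2")
  ) %>%
    count(.data$gene, .data$allele, .data$group) %>%
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L)
  for (col in c("n1", "n2")) if (!col %in% names(rows)) rows[[col]] <- 0L
  rows <- rows %>%
    filter(!is.na(.data$allele)) %>%
    arrange(.data$gene, .data$allele)

  list(rows = rows, p_a = p_a, n_anchor_a = n_a, n_anchor_b = n_b,
       excluded_other_allele = excluded)
}

#' Call the chromosomal haplotype of a single gene
#'
#' Each allele is assigned to chromosome A, chromosome B, or both according
#' to its best-scoring model when its certainty reaches `lk_assign`;
#' otherwise it stays unknown. A chromosome to which no allele is assigned
#' is called `deleted` when every observed allele of the gene is placed on
#' the other chromosome with lK above `lk_delete`, `suspected_deleted` when
#' all alleles point to the other chromosome but with weaker evidence, and
#' `unknown` otherwise.
#'
#' @param rows Contingency rows of one gene (`allele`, `n1`, `n2`).
#' @param p_a Group-A anchor share.
#' @param params A [haplotypeParams()].
#' @return One-row tibble: `gene`, `alleles_chrA`, `alleles_chrB`,
#'   `counts_chrA`, `counts_chrB`, `lK`, `call_state`.
#' @export
callGeneHaplotype <- function(rows, p_a, params = haplotypeParams()) {
  stopifnot(nrow(rows) >= 1L, length(unique(rows$gene)) == 1L)
  scores <- lapply(seq_len(nrow(rows)), function(i) {
    scoreModels(rows$n1[i], rows$n2[i], p_a, params)
  })
  best <- vapply(scores, `[[`, character(1), "best")
  lK <- vapply(scores, `[[`, numeric(1), "lK")
  assigned <- lK >= params$lk_assign

  chromState <- function(this, other) {
    on_this <- assigned & best %in% c(this, "both")
    if (any(on_this)) {
      return(paste(sort(rows$allele[on_this]), collapse = ","))
    }
    if (all(best == other)) {
      if (min(lK) > params$lk_delete) "deleted" else "suspected_deleted"
    } else {
      "unknown"
    }
  }
  state_a <- chromState("chrA", "chrB")
  state_b <- chromState("chrB", "chrA")
  tokens <- c("deleted", "suspected_deleted", "unknown")

  call_state <- if (state_a == "deleted") "deleted_chrA"
    else if (state_b == "deleted") "deleted_chrB"
    else if (state_a == "suspected_deleted") "suspected_deleted_chrA"
    else if (state_b == "suspected_deleted") "suspected_deleted_chrB"
    else if (!state_a %in% tokens && !state_b %in% tokens) "assigned_both"
    else if (!state_a %in% tokens || !state_b %in% tokens) "assigned_partial"
    else "unknown"

  tibble(
    gene = rows$gene[1L],
    alleles_chrA = state_a, alleles_chrB = state_b,
    counts_chrA = sum(rows$n1), counts_chrB = sum(rows$n2),
    lK = min(lK), call_state = call_state
  )
}

#' Infer the haplotype of a whole locus from one anchor
#'
#' Runs [buildContingency()] and [callGeneHaplotype()] for every gene of
#' the target locus observed at least once, and emits `NA` rows for
#' reference genes never observed. Deterministic given its inputs.
#'
#' @param records Filtered single-assignment rearrangement tibble for one
#'   subject.
#' @param anchor An [anchorConfig()].
#' @param target_locus Locus to phase.
#' @param params A [haplotypeParams()]; the `"empirical"` priors mode sets
#'   the both-chromosomes prior to the subject-wide fraction of observed
#'   target genes with two or more observed alleles (floored at 0.05).
#' @param reference Gene reference used to order output rows and to add
#'   `NA` rows for unobserved genes; `NULL` to skip both.
#' @return Haplotype tibble in the [writeHaplotypeTable()] dialect.
#' @export
inferHaplotype <- function(records, anchor, target_locus,
                           params = haplotypeParams(),
                           reference = loadGeneReference()) {
  subj <- unique(records$subject_id)
  if (length(subj) != 1L) stop("inferHaplotype expects records of one subject")
  ct <- buildContingency(records, anchor, target_locus)

  if (identical(params$priors, "empirical")) {
    two <- ct$rows %>% group_by(.data$gene) %>%
      summarise(het = n() >= 2L, .groups = "drop")
    pb <- max(mean(two$het), 0.05)
    params$priors <- c((1 - pb) / 2, (1 - pb) / 2, pb)
  }

  calls <- ct$rows %>%
    group_by(.data$gene) %>%
    group_modify(function(df, key) {
      callGeneHaplotype(mutate(df, gene = key$gene), ct$p_a, params)[, -1]
    }) %>%
    ungroup()

  if (!is.null(reference)) {
    ref_genes <- reference %>%
      filter(.data$locus == target_locus,
             .data$functionality == "functional",
             !.data$exclude, is.na(.data$alias_of),
             .data$gene != anchor$gene)
    missing <- setdiff(ref_genes$gene, calls$gene)
    if (length(missing) > 0) {
      calls <- bind_rows(calls, tibble(
        gene = missing, alleles_chrA = "NA", alleles_chrB = "NA",
        counts_chrA = 0L, counts_chrB = 0L, lK = NA_real_, call_state = "NA"
      ))
    }
    calls <- calls[match(orderByLocus(calls$gene, reference), calls$gene), ]
  }

  tibble(
    subject = subj,
    anchor_gene = anchor$gene,
    anchor_A = paste(anchor$group_a, collapse = ","),
    anchor_B = paste(anchor$group_b, collapse = ","),
    calls
  )
}
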