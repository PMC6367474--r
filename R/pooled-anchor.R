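#' Pool haplotype evidence across several heterozygous V anchors
#'
#' A single heterozygous V gene rarely links enough sequences to a D allele
#' to phase it confidently. Because the model posterior is conjugate, the
#' posterior model weights from one V-based inference can serve as the
#' prior for the next: anchors are consumed in sequence, each multiplying
#' the current weight of every (D gene, allele, model) triple by its
#' binomial likelihood. Since the chromosome each V allele sits on is
#' unknown, chromosome labels are re-oriented per D gene so that every
#' gene's dominant allele is attributed to the same chromosome (label A)
#' under every anchor; how uniformly a given anchor's labels already agreed
#' is reported as an orientation-consistency score, a diagnostic for the
#' allele-mix exposure this convention carries. Genes whose relative
#' usage falls below `min_d_usage` (default 1.5\%) are excluded as too
#' weakly expressed, anchors whose minor allele fraction is at most 30\%
#' are screened out, and a single-chromosome deletion is called when the
#' pooled certainty reaches `lk_cutoff` (default 12).
#'
#' @param records Filtered single-assignment rearrangement tibble for one
#'   subject.
#' @param v_anchors List of [anchorConfig()] objects for heterozygous V
#'   genes.
#' @param params A [haplotypeParams()] (uniform or numeric priors).
#' @param min_d_usage Minimum relative D-gene usage (default 0.015).
#' @param lk_cutoff Pooled lK needed to call a deletion (default 12).
#' @param min_minor_fraction Anchor screen: minimum minor-allele fraction
#'   (default 0.30, exclusive).
#' @return A list with `calls` (tibble `subject`, `gene`, `state`,
#'   `lK`), `weights` (per gene and allele: pooled log weights, best and
#'   second model, pooled `lK`), `per_anchor` (each anchor's per-allele lK
#'   contribution and orientation), `anchors_used`, and
#'   `orientation_consistency`.
#' @export
poolInference <- function(records, v_anchors, params = haplotypeParams(),
                          min_d_usage = 0.015, lk_cutoff = 12,
                          min_minor_fraction = 0.30) {
  if (length(v_anchors) == 0L) stop("at least one V anchor is required")
  subj <- unique(records$subject_id)
  if (length(subj) != 1L) stop("poolInference expects records of one subject")
  if (identical(params$priors, "empirical")) {
    stop("pooled inference requires explicit (uniform or numeric) priors")
  }

  # screen anchors by the 30% minor-allele rule
  screened <- list()
  for (a in v_anchors) {
    vc <- records$v_call
    is_a <- !is.na(vc) & getGene(vc) == a$gene
    al <- getAllele(vc)
    n1 <- sum(is_a & al %in% a$group_a)
    n2 <- sum(is_a & al %in% a$group_b)
    minor <- if (n1 + n2 > 0) min(n1, n2) / (n1 + n2) else 0
    if (minor > min_minor_fraction) {
      screened[[length(screened) + 1L]] <- a
    } else {
      warning("anchor ", a$gene, " fails the ", min_minor_fraction * 100,
              "% minor-allele screen (", signif(minor, 3), "); excluded")
    }
  }
  if (length(screened) == 0L) stop("no anchor passed the minor-allele screen")

  usage <- computeUsage(records)
  d_keep <- usage$genes %>%
    filter(.data$locus == "IGHD", .data$fraction >= min_d_usage) %>%
    pull("gene")
  if (length(d_keep) == 0L) stop("no D gene reaches min_d_usage")

  pri <- .resolvePriors(params$priors)
  log_w <- list()  # key "gene|allele" -> named numeric(3)
  per_anchor <- list()

  for (a in screened) {
    ct <- buildContingency(records, a, "IGHD")
    rows <- ct$rows %>% filter(.data$gene %in% d_keep)
    if (nrow(rows) == 0L) next
    # per-gene orientation: relabel so each gene's dominant allele leans to
    # chromosome A; the majority direction before relabeling measures how
    # consistently this anchor's labels already agreed ("allele mix" score)
    dom <- rows %>%
      group_by(.data$gene) %>%
      arrange(desc(.data$n1 + .data$n2), .data$allele, .by_group = TRUE) %>%
      summarise(flip = first(.data$n1) < first(.data$n2), .groups = "drop")
    consistency <- max(mean(dom$flip), mean(!dom$flip))
    rows <- rows %>% left_join(dom, by = "gene")
    for (i in seq_len(nrow(rows))) {
      n1 <- if (rows$flip[i]) rows$n2[i] else rows$n1[i]
      n2 <- if (rows$flip[i]) rows$n1[i] else rows$n2[i]
      p_a <- if (rows$flip[i]) 1 - ct$p_a else ct$p_a
      theta <- modelTheta(params$epsilon, p_a)
      key <- paste0(rows$gene[i], "|", rows$allele[i])
      ll <- dbinom(n1, n1 + n2, theta, log = TRUE)
      names(ll) <- names(theta)
      if (is.null(log_w[[key]])) log_w[[key]] <- log(pri)
      log_w[[key]] <- log_w[[key]] + ll
      ord <- order(ll, decreasing = TRUE)
      per_anchor[[length(per_anchor) + 1L]] <- tibble(
        anchor = a$gene, gene = rows$gene[i], allele = rows$allele[i],
        n1 = n1, n2 = n2, flipped = rows$flip[i],
        anchor_lK = min((ll[ord[1L]] - ll[ord[2L]]) / log(10), params$lk_cap),
        anchor_best = names(ll)[ord[1L]],
        orientation_consistency = consistency
      )
    }
  }
  if (length(log_w) == 0L) stop("no D-gene linkage observed with any anchor")

  weights <- bind_rows(lapply(names(log_w), function(key) {
    lw <- log_w[[key]]
    ord <- order(lw, decreasing = TRUE)
    lK <- (lw[ord[1L]] - lw[ord[2L]]) / log(10)
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    tibble(gene = parts[1L], allele = parts[2L],
           lw_chrA = lw[["chrA"]], lw_chrB = lw[["chrB"]],
           lw_both = lw[["both"]],
           best = names(lw)[ord[1L]], second = names(lw)[ord[2L]],
           lK = unname(min(lK, params$lk_cap)))
  })) %>% arrange(.data$gene, .data$allele)

  calls <- weights %>%
    group_by(.data$gene) %>%
    summarise(
      best = if (length(unique(.data$best)) == 1L) .data$best[1L] else "mixed",
      lK = min(.data$lK),
      .groups = "drop"
    ) %>%
    mutate(
      state = ifelse(.data$best == "chrA" & .data$lK >= lk_cutoff,
                     "deleted_chrB",
              ifelse(.data$best == "chrB" & .data$lK >= lk_cutoff,
                     "deleted_chrA", "present")),
      subject = subj
    ) %>%
    select("subject", "gene", "best", "state", "lK")

  list(
    calls = calls,
    weights = weights,
    per_anchor = if (length(per_anchor)) bind_rows(per_anchor) else tibble(),
    anchors_used = vapply(screened, `[[`, character(1), "gene"),
    orientation_consistency =
      if (length(per_anchor)) {
        mean(bind_rows(per_anchor)$orientation_consistency, na.rm = TRUE)
      } else NA_real_
  )
}

#' Evaluate pooled deletion calls against a reference anchor's calls
#'
#' Treats single-chromosome deletions called by a reference anchor (e.g.
#' IGHJ6 at its own lK threshold) as truth, and computes precision and
#' sensitivity of the pooled calls over a grid of pooled-lK cutoffs. Only
#' (subject, gene) pairs covered by both call sets are compared; a pair is
#' a predicted deletion at cutoff `t` when the pooled best model is a
#' single-chromosome model and its pooled lK is at least `t`.
#'
#' @param pooled_calls Tibble with `subject`, `gene`, `best`, `lK` as
#'   returned in `poolInference()$calls`; the deletion direction is not
#'   compared (chromosome labels of different anchors need not align), only
#'   deletion presence.
#' @param reference_calls Tibble with `subject`, `gene` and logical
#'   `deleted` columns.
#' @param lk_grid Numeric vector of pooled-lK cutoffs.
#' @return Tibble with `lk_cutoff`, `TP`, `FP`, `FN`, `precision`,
#'   `sensitivity`.
#' @export
evaluateAgainstReference <- function(pooled_calls, reference_calls,
                                     lk_grid = seq(0, 20, by = 1)) {
  merged <- inner_join(
    pooled_calls %>% select("subject", "gene", "best", "lK"),
    reference_calls %>% select("subject", "gene", "deleted"),
    by = c("subject", "gene")
  )
  if (nrow(merged) == 0L) {
    stop("pooled and reference calls share no (subject, gene) pairs")
  }
  single_chrom <- merged$best %in% c("chrA", "chrB")
  bind_rows(lapply(lk_grid, function(t) {
    pred <- single_chrom & merged$lK >= t
    tp <- sum(pred & merged$deleted)
    fp <- sum(pred & !merged$deleted)
    fn <- sum(!pred & merged$deleted)
    tibble(
      lk_cutoff = t, TP = tp, FP = fp, FN = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_
    )
  }))
}
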