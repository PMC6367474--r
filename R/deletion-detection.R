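#' Detect two-chromosome gene deletions with a binomial usage test
#'
#' Within a cohort, a gene deleted from both chromosomes of an individual
#' shows near-zero relative usage while the rest of the cohort expresses it.
#' For each gene, subjects whose usage falls below `candidate_thresh`
#' (default 0.001 for V genes, 0.005 for D genes, reflecting the lower
#' reliability of D assignments) become deletion candidates. The null
#' success probability is the lowest usage of the gene among non-candidate
#' subjects with usage above `null_floor`; each candidate's one-sided lower
#' binomial tail \eqn{P(X \le x \mid N, p)} is computed with `x` the
#' subject's sequences mapped to the gene and `N` the subject's total, and
#' Benjamini-Hochberg correction is applied across the gene's candidates.
#' Candidates with `q < q_cutoff` are called `deleted_both`. Genes below the
#' candidate threshold in more than `na_fraction` of subjects are too rarely
#' expressed for the test to mean anything and return `NA` calls for
#' everyone.
#'
#' @param usage Usage list from [computeUsage()].
#' @param locus Locus to test (`"IGHV"`, `"IGHD"` or `"IGHJ"`).
#' @param candidate_thresh Usage below which a subject is a deletion
#'   candidate; defaults to 0.005 for IGHD and 0.001 otherwise.
#' @param q_cutoff BH-adjusted significance cutoff (default 0.01).
#' @param na_fraction Fraction of candidate subjects above which the gene is
#'   reported `NA` (default 0.90).
#' @param null_floor Usage a subject must exceed to contribute to the null
#'   estimate (default 0.001).
#' @return Tibble with `subject_id`, `locus`, `gene`, `x`, `N`, `p`,
#'   `p_value`, `q_value`, `call` and `reason`.
#' @export
detectDoubleDeletions <- function(usage, locus,
                                  candidate_thresh = NULL,
                                  q_cutoff = 0.01, na_fraction = 0.90,
                                  null_floor = 0.001) {
  if (is.null(candidate_thresh)) {
    candidate_thresh <- if (locus == "IGHD") 0.005 else 0.001
  }
  gu <- usage$genes %>% filter(.data$locus == !!locus)
  if (length(unique(gu$subject_id)) < 2L) {
    stop("double-deletion detection needs at least 2 subjects")
  }
  gu <- gu %>%
    left_join(usage$totals %>% filter(.data$locus == !!locus) %>%
                select("subject_id", "total"),
              by = "subject_id")

  out <- gu %>%
    group_by(.data$gene) %>%
    group_modify(function(df, key) {
      cand <- df$fraction < candidate_thresh
      res <- tibble(
        subject_id = df$subject_id,
        x = df$n, N = df$total,
        p = NA_real_, p_value = NA_real_, q_value = NA_real_,
        call = ifelse(cand, "candidate", "not_candidate"),
        reason = NA_character_
      )
      if (mean(cand) > na_fraction) {
        res$call <- "NA"
        res$reason <- "rarely expressed in cohort"
        return(res)
      }
      null_pool <- df$fraction[!cand & df$fraction > null_floor]
      if (any(cand)) {
        if (length(null_pool) == 0L) {
          res$call[cand] <- "NA"
          res$reason[cand] <- "no null estimate"
        } else {
          p0 <- min(null_pool)
          pv <- pbinom(df$n[cand], df$total[cand], p0)
          qv <- p.adjust(pv, method = "BH")
          res$p[cand] <- p0
          res$p_value[cand] <- pv
          res$q_value[cand] <- qv
          res$call[cand] <- ifelse(qv < q_cutoff, "deleted_both", "present")
        }
      }
      res$call[res$call == "not_candidate"] <- "not_candidate"
      res
    }) %>%
    ungroup() %>%
    mutate(locus = !!locus) %>%
    select("subject_id", "locus", "gene", "x", "N", "p", "p_value",
           "q_value", "call", "reason") %>%
    arrange(.data$gene, .data$subject_id)
  out
}

#' Assess bimodality of a gene's cohort usage distribution
#'
#' Deletion calls in a gene are considered reliable when the cohort's usage
#' of that gene is bimodal: a near-zero mode (deleted individuals) well
#' separated from an expressed mode. Gamma distributions are fitted by
#' maximum likelihood to the usage values below and above `split`; the
#' verdict is `"reliable"` when both sides hold at least 3 subjects and the
#' fitted (or, if the fit degenerates, empirical) means differ by at least a
#' factor of 5, `"unreliable"` otherwise.
#'
#' @param fractions Numeric vector of one gene's relative usage across
#'   subjects.
#' @param split Usage threshold separating the two putative modes
#'   (default 0.001).
#' @return A list with `reliable` (logical), per-side summaries `low` and
#'   `high` (`n`, `mean`, gamma `shape` and `rate`, `NA` when the fit
#'   fails), and `ecdf` (the empirical CDF of `fractions`).
#' @export
assessUsageBimodality <- function(fractions, split = 0.001) {
  stopifnot(is.numeric(fractions))
  lo <- fractions[fractions < split]
  hi <- fractions[fractions >= split]

  fitSide <- function(x) {
    pos <- x[x > 0]
    fit <- c(shape = NA_real_, rate = NA_real_)
    if (length(pos) >= 3L && sd(pos) > 0) {
      fit_try <- tryCatch(
        fitdistrplus::fitdist(pos, "gamma", method = "mle")$estimate,
        error = function(e) NULL)
      if (!is.null(fit_try)) fit <- fit_try
    }
    list(n = length(x), mean = if (length(x)) mean(x) else NA_real_,
         shape = unname(fit["shape"]), rate = unname(fit["rate"]))
  }
  low <- fitSide(lo)
  high <- fitSide(hi)

  reliable <- low$n >= 3L && high$n >= 3L &&
    is.finite(low$mean) && is.finite(high$mean) &&
    low$mean >= 0 && high$mean > 0 &&
    (low$mean == 0 || high$mean / low$mean >= 5)
  if (all(fractions == 0)) reliable <- FALSE

  list(reliable = reliable, low = low, high = high, ecdf = ecdf(fractions))
}
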