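#' Single-sample sign test for allele usage bias
#'
#' For every allele pair of a gene observed in heterozygous individuals,
#' asks whether one allele is systematically used more than the other.
#' Each qualifying individual contributes a binary outcome -- whether the
#' pair's first allele (lexicographically smaller designator) accounts for
#' more than half of the pair's sequences -- and the count of successes is
#' referred to an exact two-sided binomial test with success probability
#' 0.5 (ties at exactly 0.5 are dropped). A special case of the binomial
#' test; p values are Benjamini-Hochberg corrected across tested pairs.
#'
#' Individuals enter a pair's test only when their sequencing depth for the
#' gene's locus exceeds `min_depth` (default 10,000) and the gene's relative
#' usage exceeds `min_gene_usage` (default 1\%); pairs observed in fewer
#' than `min_individuals` (default 5) are skipped and reported.
#'
#' @param usage Usage list from [computeUsage()].
#' @param genotypes Genotype tibble from [summarizeGenotype()].
#' @param min_depth Minimum locus sequencing depth per individual.
#' @param min_gene_usage Minimum relative gene usage per individual.
#' @param min_individuals Minimum individuals per tested pair.
#' @return A list with `results` (tibble `gene`, `allele1`, `allele2`, `n`,
#'   `k`, `p_value`, `q_value`) and `skipped` (pairs under the individual
#'   minimum).
#' @export
alleleBiasSignTest <- function(usage, genotypes, min_depth = 10000,
                               min_gene_usage = 0.01, min_individuals = 5) {
  het <- genotypes %>% filter(.data$zygosity %in% "heterozygous")
  if (nrow(het) == 0L) stop("no heterozygous genotypes to test")
  # the pair is the subject's two most used alleles, ordered by name
  pairs <- het %>%
    mutate(a = strsplit(.data$alleles, ",", fixed = TRUE)) %>%
    mutate(allele1 = vapply(.data$a, function(x) min(x[1:2]), character(1)),
           allele2 = vapply(.data$a, function(x) max(x[1:2]), character(1))) %>%
    select("subject_id", "locus", "gene", "allele1", "allele2")

  depth_ok <- usage$totals %>% rename(locus_total = "total")
  gene_ok <- usage$genes %>% select("subject_id", "gene", gene_usage = "fraction")
  counts <- usage$alleles %>% select("subject_id", "gene", "allele", an = "n")

  obs <- pairs %>%
    left_join(depth_ok, by = c("subject_id", "locus")) %>%
    left_join(gene_ok, by = c("subject_id", "gene")) %>%
    left_join(counts, by = c("subject_id", "gene", "allele1" = "allele")) %>%
    rename(n1 = "an") %>%
    left_join(counts, by = c("subject_id", "gene", "allele2" = "allele")) %>%
    rename(n2 = "an") %>%
    filter(.data$locus_total > min_depth,
           .data$gene_usage > min_gene_usage,
           !is.na(.data$n1), !is.na(.data$n2)) %>%
    mutate(frac1 = .data$n1 / (.data$n1 + .data$n2))

  tallied <- obs %>%
    filter(.data$frac1 != 0.5) %>%   # ties carry no sign information
    group_by(.data$gene, .data$allele1, .data$allele2) %>%
    summarise(n = n(), k = sum(.data$frac1 > 0.5), .groups = "drop")

  skipped <- tallied %>% filter(.data$n < min_individuals)
  results <- tallied %>%
    filter(.data$n >= min_individuals) %>%
    mutate(p_value = signTestPValue(.data$k, .data$n)) %>%
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) %>%
    arrange(.data$gene, .data$allele1, .data$allele2)
  list(results = results, skipped = skipped)
}

#' Exact two-sided sign-test p value
#'
#' \eqn{\min(1, 2 \min(P(X \le k), P(X \ge k)))} for
#' \eqn{X \sim Bin(n, 1/2)}; vectorized.
#'
#' @param k Successes.
#' @param n Trials.
#' @return Numeric p values.
#' @export
signTestPValue <- function(k, n) {
  lower <- pbinom(k, n, 0.5)
  upper <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Usage thresholds separating single-chromosome deletions
#'
#' Individuals carrying a single-chromosome deletion of a gene use it at
#' roughly half the rate of individuals with both copies. For each gene,
#' haplotype calls at certainty `lK >= min_lk` (default 10, conservative)
#' split individuals into a 0-deletion and a 1-deletion group; each group's
#' usage is modelled as \eqn{x \sim \mu + \sigma t(\nu = n - 1)} with the
#' sample mean and standard deviation. Sweeping thresholds yields a ROC
#' (1-deletion group positive, called when usage falls below the
#' threshold); the reported threshold per `alpha` is the group-0 model's
#' lower `alpha`-quantile, so its model-based false positive rate is
#' exactly `alpha`, with the 1-deletion model's mass below it as the
#' model-based sensitivity. The group mean ratio and its 95\% Fieller CI
#' ([meanRatioCI()]) are attached.
#'
#' @param usage Usage list from [computeUsage()].
#' @param haplotype_calls Row-bound haplotype tibbles across subjects (the
#'   [writeHaplotypeTable()] dialect).
#' @param min_lk Minimum certainty for group membership (default 10).
#' @param alphas Target false positive rates (default 0.01 and 0.05).
#' @param n_grid ROC threshold grid resolution (default 1000).
#' @return A list with `thresholds` (per gene and alpha: group fits,
#'   threshold, model sensitivity, ratio and CI), `roc` (per gene:
#'   threshold sweep with model FPR/TPR and empirical TP/FP/TN/FN) and
#'   `skipped` (genes without two usable groups, with reasons).
#' @export
estimateSingleDeletionThresholds <- function(usage, haplotype_calls,
                                             min_lk = 10,
                                             alphas = c(0.01, 0.05),
                                             n_grid = 1000) {
  gu <- usage$genes %>% select("subject_id", "gene", "fraction")
  calls <- haplotype_calls %>%
    filter(!is.na(.data$lK), .data$lK >= min_lk) %>%
    mutate(group = ifelse(grepl("^deleted_chr", .data$call_state), 1L,
                   ifelse(.data$call_state == "assigned_both", 0L, NA_integer_))) %>%
    filter(!is.na(.data$group)) %>%
    select(subject_id = "subject", "gene", "group") %>%
    inner_join(gu, by = c("subject_id", "gene"))

  thresholds <- list(); roc <- list(); skipped <- list()
  for (g in unique(calls$gene)) {
    df <- calls %>% filter(.data$gene == g)
    x0 <- df$fraction[df$group == 0L]
    x1 <- df$fraction[df$group == 1L]
    if (length(x0) < 2L || length(x1) < 2L) {
      skipped[[g]] <- tibble(gene = g, reason = "insufficient group sizes")
      next
    }
    if (sd(x0) == 0 || sd(x1) == 0) {
      skipped[[g]] <- tibble(gene = g, reason = "degenerate fit (sd = 0)")
      next
    }
    m0 <- mean(x0); s0 <- sd(x0); nu0 <- length(x0) - 1L
    m1 <- mean(x1); s1 <- sd(x1); nu1 <- length(x1) - 1L

    th_alpha <- m0 + s0 * qt(alphas, nu0)
    grid <- sort(unique(c(
      seq(min(df$fraction), max(df$fraction), length.out = n_grid), th_alpha)))
    fpr <- pt((grid - m0) / s0, nu0)
    tpr <- pt((grid - m1) / s1, nu1)
    roc[[g]] <- tibble(
      gene = g, threshold = grid, fpr_model = fpr, tpr_model = tpr,
      TP = vapply(grid, function(t) sum(x1 < t), integer(1)),
      FP = vapply(grid, function(t) sum(x0 < t), integer(1)),
      TN = vapply(grid, function(t) sum(x0 >= t), integer(1)),
      FN = vapply(grid, function(t) sum(x1 >= t), integer(1))
    )
    ci <- meanRatioCI(x0, x1)
    thresholds[[g]] <- tibble(
      gene = g, alpha = alphas,
      n0 = length(x0), mean0 = m0, sd0 = s0,
      n1 = length(x1), mean1 = m1, sd1 = s1,
      threshold = th_alpha,
      sensitivity = pt((th_alpha - m1) / s1, nu1),
      ratio = ci$estimate, ci_lower = ci$lower, ci_upper = ci$upper
    )
  }
  list(
    thresholds = bind_rows(thresholds),
    roc = bind_rows(roc),
    skipped = bind_rows(skipped)
  )
}

#' Fieller confidence interval for a ratio of two group means
#'
#' Point estimate `mean(x0) / mean(x1)` with a Fieller-theorem interval
#' using Welch-Satterthwaite degrees of freedom for the two independent
#' samples. When the denominator mean is not significantly different from
#' zero at the chosen level (Fieller's `g >= 1`) the interval is unbounded
#' and reported as `NA` with a warning.
#'
#' @param x0,x1 Numeric vectors (numerator and denominator groups, each of
#'   length at least 2).
#' @param conf Confidence level (default 0.95).
#' @return A list with `estimate`, `lower`, `upper`, `conf`.
#' @export
meanRatioCI <- function(x0, x1, conf = 0.95) {
  if (length(x0) < 2L || length(x1) < 2L) stop("both groups need n >= 2")
  m0 <- mean(x0); m1 <- mean(x1)
  if (m1 <= 0) stop("denominator group mean must be positive")
  v0 <- stats::var(x0) / length(x0)
  v1 <- stats::var(x1) / length(x1)
  df <- (v0 + v1)^2 / (v0^2 / (length(x0) - 1) + v1^2 / (length(x1) - 1))
  tq <- qt(1 - (1 - conf) / 2, df)
  rho <- m0 / m1
  g <- tq^2 * v1 / m1^2
  if (g >= 1) {
    warning("denominator mean indistinguishable from zero; unbounded interval")
    return(list(estimate = rho, lower = NA_real_, upper = NA_real_,
                conf = conf))
  }
  half <- (tq / m1) * sqrt(v0 + rho^2 * v1 - g * v0)
  list(
    estimate = rho,
    lower = (rho - half) / (1 - g),
    upper = (rho + half) / (1 - g),
    conf = conf
  )
}

.haplotypeElementSets <- function(h, min_linkages) {
  tokens <- c("deleted", "suspected_deleted", "unknown", "NA")
  h <- h %>% filter(.data$counts_chrA + .data$counts_chrB >= min_linkages)
  sets <- lapply(seq_len(nrow(h)), function(i) {
    els <- character(0)
    if (!h$alleles_chrA[i] %in% tokens && !is.na(h$alleles_chrA[i])) {
      els <- c(els, paste0("A:", strsplit(h$alleles_chrA[i], ",")[[1L]]))
    }
    if (!h$alleles_chrB[i] %in% tokens && !is.na(h$alleles_chrB[i])) {
      els <- c(els, paste0("B:", strsplit(h$alleles_chrB[i], ",")[[1L]]))
    }
    els
  })
  names(sets) <- h$gene
  sets[lengths(sets) > 0]
}

#' Jaccard distance between two haplotypes
#'
#' For each gene resolved in both haplotypes, the distance is one minus the
#' ratio of shared chromosome-resolved allele assignments to the union of
#' assignments; the overall distance is the mean across genes. Genes
#' resolved in only one haplotype are excluded, as are genes with fewer
#' than `min_linkages` supporting sequences; fewer than `min_genes`
#' comparable genes is an error. Because two anchors label chromosomes
#' arbitrarily, `orientation = "auto"` (default) evaluates `h2` both as-is
#' and with its chromosome labels swapped and keeps the smaller mean
#' distance.
#'
#' @param h1,h2 Haplotype tibbles (the [writeHaplotypeTable()] dialect).
#' @param min_genes Minimum comparable genes (default 5).
#' @param min_linkages Minimum supporting sequences per gene (default 5).
#' @param orientation `"auto"`, `"as_is"` or `"swapped"`.
#' @return One-row tibble with `distance`, `genes_compared`, `orientation`.
#' @export
haplotypeJaccard <- function(h1, h2, min_genes = 5, min_linkages = 5,
                             orientation = c("auto", "as_is", "swapped")) {
  orientation <- match.arg(orientation)
  s1 <- .haplotypeElementSets(h1, min_linkages)
  swapLabels <- function(sets) {
    lapply(sets, function(els) {
      chartr("AB", "BA", substr(els, 1, 1)) |>
        paste0(substring(els, 2))
    })
  }
  meanDist <- function(s2) {
    genes <- intersect(names(s1), names(s2))
    if (length(genes) < min_genes) return(NULL)
    d <- vapply(genes, function(g) {
      a <- s1[[g]]; b <- s2[[g]]
      1 - length(intersect(a, b)) / length(union(a, b))
    }, numeric(1))
    list(distance = mean(d), genes = length(genes))
  }
  s2 <- .haplotypeElementSets(h2, min_linkages)
  cand <- list()
  if (orientation %in% c("auto", "as_is")) cand$as_is <- meanDist(s2)
  if (orientation %in% c("auto", "swapped")) cand$swapped <- meanDist(swapLabels(s2))
  cand <- Filter(Negate(is.null), cand)
  if (length(cand) == 0L) {
    stop("insufficient overlap: fewer than ", min_genes, " comparable genes")
  }
  pick <- names(cand)[which.min(vapply(cand, `[[`, numeric(1), "distance"))]
  tibble(distance = cand[[pick]]$distance,
         genes_compared = cand[[pick]]$genes,
         orientation = pick)
}

#' Screen candidate anchor genes by minor-allele fraction
#'
#' A gene can serve as an anchor in a subject only when both alleles are
#' seen often enough for chromosome labels to be trustworthy; the screen
#' requires a minor-allele fraction above `minor_fraction` (default 30\%).
#' When per-subject haplotype distances between anchor pairs are supplied
#' (columns `minor_fraction`, `distance`), a two-sided Wilcoxon rank-sum
#' test compares the distance distributions of anchors above and below the
#' cutoff, supporting the choice of cutoff; with fewer than 3 distances on
#' either side the comparison is reported as `NA`.
#'
#' @param genotypes Genotype tibble from [summarizeGenotype()].
#' @param distances Optional tibble of anchor-pair haplotype distances with
#'   columns `minor_fraction` and `distance`.
#' @param minor_fraction Eligibility cutoff (exclusive; default 0.30).
#' @return A list with `anchors` (per subject and gene: `minor_fraction`,
#'   `eligible`) and `comparison` (`p_value`, `n_above`, `n_below`).
#' @export
screenAnchorCandidates <- function(genotypes, distances = NULL,
                                   minor_fraction = 0.30) {
  cutoff <- minor_fraction  # avoid masking by the column of the same name
  anchors <- genotypes %>%
    mutate(eligible = .data$zygosity %in% "heterozygous" &
             .data$minor_fraction > cutoff) %>%
    select("subject_id", "locus", "gene", "minor_fraction", "eligible")

  comparison <- list(p_value = NA_real_, n_above = 0L, n_below = 0L)
  if (!is.null(distances) && nrow(distances) > 0) {
    above <- distances$distance[distances$minor_fraction > minor_fraction]
    below <- distances$distance[distances$minor_fraction <= minor_fraction]
    comparison$n_above <- length(above)
    comparison$n_below <- length(below)
    if (length(above) >= 3L && length(below) >= 3L) {
      comparison$p_value <-
        wilcox.test(above, below, exact = FALSE)$p.value
    }
  }
  list(anchors = anchors, comparison = comparison)
}
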