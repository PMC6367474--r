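test_that("the sign-test p value equals the exact two-sided binomial tail", {
  expect_equal(signTestPValue(10, 10), 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(signTestPValue(3, 6), 1)
  expect_equal(signTestPValue(15, 20), 2 * sum(dbinom(15:20, 20, 0.5)),
               tolerance = 1e-12)
  # exhaustive agreement with direct enumeration for n <= 30
  for (n in 1:30) {
    for (k in 0:n) {
      direct <- min(1, 2 * min(sum(dbinom(0:k, n, 0.5)),
                               sum(dbinom(k:n, n, 0.5))))
      expect_equal(signTestPValue(k, n), direct, tolerance = 1e-12)
    }
  }
})

test_that("allele bias testing applies depth, usage and cohort-size screens", {
  # 8 deep heterozygous subjects, allele 01 always dominant (70:30),
  # plus one shallow subject that must be screened out
  recs <- dplyr::bind_rows(lapply(1:8, function(i) {
    makeRecords(v = c(rep("IGHV3-23*01", 7000), rep("IGHV3-23*02", 3000),
                      rep("IGHV1-69*01", 2000)),
                subject = sprintf("S%d", i))
  }))
  shallow <- makeRecords(v = c(rep("IGHV3-23*01", 60), rep("IGHV3-23*02", 40)),
                         subject = "S9")
  recs <- dplyr::bind_rows(recs, shallow)
  usage <- computeUsage(recs)
  geno <- summarizeGenotype(recs)
  out <- alleleBiasSignTest(usage, geno, min_depth = 10000,
                            min_individuals = 5)
  row <- out$results[out$results$gene == "IGHV3-23", ]
  expect_equal(row$n, 8L)       # the shallow subject is excluded
  expect_equal(row$k, 8L)
  expect_equal(row$p_value, 2 * 0.5^8, tolerance = 1e-12)

  # a pair seen in too few individuals is skipped, not tested
  out2 <- alleleBiasSignTest(usage, geno, min_depth = 10000,
                             min_individuals = 9)
  expect_equal(nrow(out2$results), 0L)
  expect_equal(out2$skipped$n, 8L)
})

test_that("single-deletion usage thresholds hit the requested model FPR", {
  set.seed(31)
  n0 <- 20; n1 <- 20
  x0 <- rnorm(n0, 0.02, 0.002)
  x1 <- rnorm(n1, 0.01, 0.002)
  usage <- list(genes = tibble::tibble(
    subject_id = sprintf("S%02d", 1:(n0 + n1)),
    locus = "IGHV", gene = "IGHV3-23",
    n = 100L, fraction = c(x0, x1)))
  haps <- tibble::tibble(
    subject = sprintf("S%02d", 1:(n0 + n1)),
    gene = "IGHV3-23",
    call_state = rep(c("assigned_both", "deleted_chrB"), c(n0, n1)),
    lK = 50)
  fit <- estimateSingleDeletionThresholds(usage, haps, alphas = c(0.01, 0.05))
  th <- fit$thresholds
  expect_equal(nrow(th), 2L)
  # the alpha = 0.05 threshold is the fitted group-0 lower quantile, so it
  # separates the group means and has model FPR exactly alpha
  t05 <- th[th$alpha == 0.05, ]
  expect_gt(t05$threshold, mean(x1))
  expect_lt(t05$threshold, mean(x0))
  expect_equal(t05$threshold, mean(x0) + sd(x0) * qt(0.05, n0 - 1),
               tolerance = 1e-12)
  roc_at <- fit$roc[abs(fit$roc$threshold - t05$threshold) < 1e-12, ]
  expect_equal(roc_at$fpr_model, 0.05, tolerance = 1e-6)
  # the stricter alpha is never more permissive
  expect_lt(th$threshold[th$alpha == 0.01], t05$threshold)
  # the mean usage ratio reflects the halved expression
  expect_equal(t05$ratio, mean(x0) / mean(x1), tolerance = 1e-12)

  # identical groups: no separation, sensitivity approximately alpha
  usage_same <- usage
  usage_same$genes$fraction <- rep(x0, 2)[1:(n0 + n1)]
  fit2 <- estimateSingleDeletionThresholds(usage_same, haps)
  expect_equal(fit2$thresholds$sensitivity[fit2$thresholds$alpha == 0.05],
               0.05, tolerance = 0.05)

  # degenerate group is skipped with a reason
  usage_flat <- usage
  usage_flat$genes$fraction[1:n0] <- 0.02
  fit3 <- estimateSingleDeletionThresholds(usage_flat, haps)
  expect_equal(nrow(fit3$thresholds), 0L)
  expect_match(fit3$skipped$reason, "degenerate")
})

test_that("the Fieller ratio interval behaves on known groups", {
  x0 <- c(0.019, 0.021, 0.020, 0.020)
  x1 <- c(0.009, 0.011, 0.010, 0.010)
  ci <- meanRatioCI(x0, x1)
  expect_equal(ci$estimate, 2.0, tolerance = 1e-12)
  expect_true(ci$lower < 2 && ci$upper > 2)

  same <- meanRatioCI(x0, x0)
  expect_equal(same$estimate, 1.0)
  expect_true(same$lower < 1 && same$upper > 1)

  expect_error(meanRatioCI(x0, -x1), "positive")
  expect_error(meanRatioCI(x0, 0.01), "n >= 2")
  expect_warning(meanRatioCI(x0, c(-1, 1.001, -1.0, 1.01)), "unbounded")
})

test_that("haplotype Jaccard distance follows the shared-allele formula", {
  makeHap <- function(genes, a, b, counts = 50L) {
    tibble::tibble(subject = "S1", anchor_gene = "IGHJ6", anchor_A = "02",
                   anchor_B = "03", gene = genes, alleles_chrA = a,
                   alleles_chrB = b, counts_chrA = counts,
                   counts_chrB = counts, lK = 20,
                   call_state = "assigned_both")
  }
  genes <- sprintf("IGHV3-%d", 1:6)
  h1 <- makeHap(genes, "01", "02")
  expect_equal(haplotypeJaccard(h1, h1)$distance, 0)

  # one gene {01} vs {01,04} on chrA, five genes identical -> mean 0.1 over 6?
  h2 <- makeHap(genes, c("01,04", rep("01", 5)), "02")
  d <- haplotypeJaccard(h1, h2, min_genes = 5)
  # gene 1: sets {A:01, B:02} vs {A:01, A:04, B:02} -> 1 - 2/3
  expect_equal(d$distance, (1 - 2 / 3) / 6, tolerance = 1e-12)

  # fully disjoint assignments
  h3 <- makeHap(genes, "03", "04")
  expect_equal(haplotypeJaccard(h1, h3, orientation = "as_is")$distance, 1)

  # swapped chromosome labels are recognized by the auto orientation
  h4 <- makeHap(genes, "02", "01")
  expect_equal(haplotypeJaccard(h1, h4)$distance, 0)
  expect_equal(haplotypeJaccard(h1, h4)$orientation, "swapped")

  # genes with weak linkage are excluded, and too few genes is an error
  h5 <- makeHap(genes, "01", "02", counts = c(1L, rep(50L, 5)))
  expect_equal(haplotypeJaccard(h1, h5)$genes_compared, 5L)
  expect_error(haplotypeJaccard(h1, h1[1:3, ]), "insufficient overlap")

  # symmetry
  expect_equal(haplotypeJaccard(h1, h2)$distance,
               haplotypeJaccard(h2, h1)$distance)
})

test_that("anchor candidates are screened at the 30% minor-allele cutoff", {
  recs <- dplyr::bind_rows(
    makeRecords(v = c(rep("IGHV3-23*01", 65), rep("IGHV3-23*02", 35))),
    makeRecords(v = c(rep("IGHV1-69*01", 80), rep("IGHV1-69*04", 20))))
  geno <- summarizeGenotype(recs)
  out <- screenAnchorCandidates(geno)
  a <- out$anchors
  expect_true(a$eligible[a$gene == "IGHV3-23"])
  expect_false(a$eligible[a$gene == "IGHV1-69"])

  # distance comparison: NA when a side is undersized, a p value otherwise
  d_small <- tibble::tibble(minor_fraction = c(0.4, 0.4, 0.1),
                            distance = c(0.05, 0.06, 0.5))
  expect_true(is.na(screenAnchorCandidates(geno, d_small)$comparison$p_value))
  set.seed(8)
  d_big <- tibble::tibble(
    minor_fraction = rep(c(0.45, 0.1), each = 10),
    distance = c(runif(10, 0, 0.1), runif(10, 0.4, 0.9)))
  cmp <- screenAnchorCandidates(geno, d_big)$comparison
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$n_above, 10L)
})
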