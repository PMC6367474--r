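# build small rearrangement tibbles in code; no fixture files needed
makeRecords <- function(v, d = "IGHD3-10*01", j = "IGHJ6*02", subject = "S1",
                        v_mut = 0L, d_mut = 0L, dup = 1L) {
  n <- max(length(v), length(d), length(j), length(v_mut), length(d_mut))
  tibble::tibble(
    sequence_id = sprintf("%s_seq%05d", subject, seq_len(n)),
    v_call = rep_len(v, n),
    d_call = rep_len(d, n),
    j_call = rep_len(j, n),
    duplicate_count = rep_len(as.integer(dup), n),
    v_mutation_count = rep_len(as.integer(v_mut), n),
    d_mutation_count = rep_len(as.integer(d_mut), n),
    subject_id = subject
  )
}

writeRecords <- function(records, path = tempfile(fileext = ".tsv")) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# records linking one target allele to the two anchor alleles n1/n2 times
linkedRecords <- function(target, n1, n2, anchor_gene = "IGHJ6",
                          a1 = "02", a2 = "03", subject = "S1") {
  j <- c(rep(paste0(anchor_gene, "*", a1), n1),
         rep(paste0(anchor_gene, "*", a2), n2))
  makeRecords(v = target, j = j, subject = subject)
}

# independent brute-force oracle for the three-model Bayes factor:
# direct pmf products from choose(), no shared code with scoreModels()
bruteLK <- function(n1, n2, p_a, epsilon, priors = c(1, 1, 1) / 3) {
  th <- c(1 + epsilon, epsilon, p_a + epsilon) / (1 + 2 * epsilon)
  n <- n1 + n2
  lik <- choose(n, n1) * th^n1 * (1 - th)^n2
  w <- lik * priors
  ord <- order(w, decreasing = TRUE)
  list(best = c("chrA", "chrB", "both")[ord[1]],
       second = c("chrA", "chrB", "both")[ord[2]],
       lK = log10(w[ord[1]] / w[ord[2]]))
}

# a subject with two heterozygous V anchors linked to D genes; counts are
# built by hand so per-anchor likelihoods are known exactly
pooledFixture <- function(n1_a = 8L, n2_a = 0L, n1_b = 6L, n2_b = 0L) {
  dplyr::bind_rows(
    # anchor 1: IGHV3-23 *01/*02 at 50:50; D3-10*01 rides with *01 only
    makeRecords(v = rep(c("IGHV3-23*01", "IGHV3-23*02"), each = 20),
                d = "IGHD1-1*01"),
    makeRecords(v = c(rep("IGHV3-23*01", n1_a), rep("IGHV3-23*02", n2_a)),
                d = "IGHD3-10*01"),
    # anchor 2: IGHV1-69 *01/*04 at 50:50
    makeRecords(v = rep(c("IGHV1-69*01", "IGHV1-69*04"), each = 20),
                d = "IGHD1-1*01"),
    makeRecords(v = c(rep("IGHV1-69*01", n1_b), rep("IGHV1-69*04", n2_b)),
                d = "IGHD3-10*01")
  )
}

pooledAnchors <- list(
  anchorConfig("IGHV3-23", "01", "02"),
  anchorConfig("IGHV1-69", "01", "04")
)
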