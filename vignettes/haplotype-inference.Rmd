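---
title: "Inferring IGH haplotypes and gene deletions from AIRR-seq repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring IGH haplotypes and gene deletions from AIRR-seq repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighap)
library(dplyr)
```

## The problem

The immunoglobulin heavy chain (IGH) locus is among the most structurally
variable regions of the human genome: genes are frequently duplicated,
deleted, or carried in different allelic forms on the two chromosomes.
Direct genomic sequencing of the locus is hard, but every expressed antibody
heavy chain is a VDJ rearrangement drawn from a *single* chromosome. A deep
AIRR-seq repertoire of naive B cells therefore carries, sequence by
sequence, a record of which germline alleles co-occur on the same
chromosome.

The key is an **anchor gene**: a gene that is heterozygous in the subject,
so that its two alleles label the two chromosomes. IGHJ6, heterozygous
(alleles `*02`/`*03`) in roughly a third of people, is the classical anchor.
Every rearrangement using `IGHJ6*02` came from one chromosome, every
`IGHJ6*03` rearrangement from the other; tallying which V (or D) alleles
ride along with each anchor allele phases the whole locus.

## The model

For a target allele, let \(X = (n_1, n_2)\) be the number of sequences in
which it co-occurs with anchor allele group A and group B. Each sequence is
treated as one independent recombination event. Three hypotheses describe
where the allele can live, each a binomial success probability for the
group-A count, built from a constant allele mis-assignment probability
\(\varepsilon\):

* chromosome A only: \(\theta_A = \dfrac{1+\varepsilon}{1+2\varepsilon}\)
* chromosome B only: \(\theta_B = \dfrac{\varepsilon}{1+2\varepsilon}\)
* both chromosomes: \(\theta_{AB} = \dfrac{p+\varepsilon}{1+2\varepsilon}\),

where \(p\) is the group-A share among anchor-bearing sequences (an allele
present on both chromosomes should follow the anchor's own usage split).
Each model's posterior weight is its binomial likelihood times a model
prior; certainty in the winning model is the Bayes factor
\(K\) between the best and second-best posterior weight, reported as
\(lK = \log_{10} K\). An allele is assigned to a chromosome when
\(lK \ge 3\) (Bayes factor 1000). A chromosome on which no allele of a gene
survives is called **deleted** when every observed allele is confidently
placed on the other chromosome (\(lK > 3\)), and **suspected deleted**
when the same configuration holds with weaker evidence.

Model priors default to uniform (1/3 each). An `empirical` mode instead
sets the both-chromosomes prior to the subject-wide fraction of genes with
two observed alleles; we default to uniform because it is explicit and
reproducible, and in practice the likelihood dominates the prior at any
usable depth.

```{r spot}
# five uncontradicted linkages, no mis-assignment: K = 2^5
scoreModels(5, 0, p_a = 0.5, haplotypeParams(epsilon = 0))$lK
log10(32)
```

### Numerical choices

Scoring happens in log space. With \(\varepsilon = 0\) a single
cross-chromosome count makes a single-chromosome model exactly impossible
(likelihood zero, log-likelihood \(-\infty\)); ranking still works, and
when the runner-up model has zero likelihood the reported \(lK\) is capped
(default 300) rather than infinite, keeping output tables finite. The
default \(\varepsilon = 0.01\) reflects that aligner mis-assignment is rare
but never absent; it is configurable, and the simulator lets you check
sensitivity to it. The anchor share \(p\) is clamped to
\([10^{-6}, 1-10^{-6}]\) so a degenerate anchor group produces a warning,
not a crash. Ties in allele retention (genotype summaries keep at most four
alleles per gene) break by descending count, then allele name, making every
output deterministic.

## Two-chromosome deletions: the cohort binomial test

Haplotype inference sees deletions on one chromosome; a gene deleted from
*both* chromosomes simply vanishes and needs a cohort view. For each gene,
subjects whose relative usage falls below a candidate threshold (0.001 for
V genes; 0.005 for D genes, whose assignments are less reliable) are tested
with a one-sided binomial tail \(P(X \le x \mid N, p)\), where \(N\) is the
subject's sequence total and \(p\) is the *lowest* usage of the gene among
non-candidate subjects above the 0.001 floor — a deliberately conservative
null. Benjamini–Hochberg correction is applied within the gene across its
candidates and calls require \(q < 0.01\). Genes below the candidate
threshold in more than 90% of subjects are reported `NA`: the cohort barely
expresses them, so absence of evidence is not evidence of deletion. A
two-gamma fit on either side of the 0.001 split (`assessUsageBimodality()`)
flags genes whose cohort usage is not clearly bimodal, where deletion calls
deserve less trust.

## Pooling V anchors for D-gene deletions

A J6 anchor covers only the third of the population heterozygous for J6.
V-gene heterozygosity is near-universal, but any single V anchor links few
sequences to any D allele. Because the three-model posterior is conjugate,
the posterior weights from one V-based inference can serve as the prior for
the next: `poolInference()` walks a list of heterozygous V anchors
(screened to minor-allele fraction > 30%), multiplying model weights by
each anchor's binomial likelihood. Chromosome labels of different anchors
are arbitrary, so counts are re-oriented per D gene so that the dominant D
allele is always attributed to the same chromosome label — the convention
is exposed to "allele mix" when labels disagree, which is why the pooled
deletion call uses a much stricter certainty, \(lK \ge 12\), and why an
orientation-consistency diagnostic is reported. D genes with relative
usage below 1.5% are excluded as too weakly expressed to pool. Under
uniform priors and a consistent model ranking the pooled \(lK\) is exactly
the sum of per-anchor \(lK\)s, and the final weights do not depend on
anchor order.

## Population statistics

* **Allele usage bias** (`alleleBiasSignTest()`): in heterozygous subjects,
  does one allele of a pair dominate? Each subject contributes a binary
  outcome (first allele above half of the pair's sequences); the count is
  referred to an exact two-sided binomial test at 0.5, ties dropped,
  BH-corrected. Only subjects with locus depth above 10,000 and gene usage
  above 1% are counted, and pairs seen in fewer than 5 individuals are
  skipped: with less data the sign test has essentially no power.
* **Usage thresholds for single-chromosome deletions**
  (`estimateSingleDeletionThresholds()`): subjects confidently haplotyped
  (\(lK \ge 10\), conservative) split into 0-deletion and 1-deletion
  groups per gene; each group's usage is modelled as
  \(x \sim \mu + \sigma\, t(\nu = n-1)\). The threshold reported for level
  \(\alpha\) is the 0-deletion model's lower \(\alpha\)-quantile, so the
  model-based false positive rate is exactly \(\alpha\); a ROC over a
  1000-point sweep (plus the \(\alpha\)-quantiles themselves) gives the
  empirical counts. The group mean ratio carries a 95% Fieller interval
  with Welch degrees of freedom (`meanRatioCI()`); a ratio near 2 is the
  signature of halved expression from a single surviving copy.
* **Jaccard haplotype comparison** (`haplotypeJaccard()`): per shared gene,
  one minus the ratio of shared to united chromosome-resolved allele
  assignments, averaged across genes; genes resolved in only one haplotype
  or supported by fewer than 5 linked sequences are excluded, and fewer
  than 5 comparable genes is an error rather than a noisy number. Two
  anchors label chromosomes arbitrarily, so the default orientation
  evaluates both global label alignments of the second haplotype and keeps
  the smaller distance — the only alignment under which a same-subject
  comparison is meaningful.

## What the simulator emulates — and what it does not

`simulateGenome()`/`simulateRepertoire()` generate exactly the world the
model assumes: a diploid genome with per-chromosome alleles, engineered
deletion blocks, optional mutually-exclusive adjacent-block deletion pairs
(mirroring the alternative V-locus deletion structures seen in people),
per-gene heterozygosity, log-normal gene-usage weights with an optional
per-chromosome expression bias, sequences drawn one chromosome at a time,
and mis-assignment as an \(\varepsilon\)-probability swap to the
homologous chromosome's allele. J-gene weights are fixed to a typical human
profile (IGHJ4 ≈ 40%, IGHJ6 ≈ 30%) rather than drawn, since anchor-based
inference depends on J6's linkage depth; V and D weights are drawn
log-normal and normalized, approximating the skewed usage of real
repertoires without asserting any particular gene's value.

Deliberately absent: somatic hypermutation, clonal lineages, sequencing
error at the nucleotide level, V–D–J pairing preferences, and
aligner-specific ambiguity patterns. Passing tests on simulated data
therefore show that the inference machinery is correct *under its own
assumptions*; they do not show robustness to mutation-driven allele
mis-calls or clonal usage distortion, which real pipelines must control
upstream (naive-cell sorting, mutation filters, collapsing by unique
events).

## Study conditions used in the tests

The test-suite and the acceptance script reproduce the framework's
behaviour at sizes chosen to exercise each property: 1000 random count
configurations against a brute-force oracle; 20 subjects at 10,000
sequences with \(\varepsilon = 0.005\) for single-chromosome deletion
recovery; 100 cohorts of 50 subjects at depth 5000 with 10 engineered
double deletions each for the binomial test's calibration; 100 replicates
of 20-vs-20 subjects with a true twofold usage ratio for the threshold
module; and 20 replicates at depth 50,000 for cross-anchor haplotype
agreement. All runs are seeded and deterministic.

## Known limitations

* A "deletion" is a deletion from the expressed repertoire; a silenced
  regulatory region produces the same signal as a missing gene, and only
  genomic sequencing can tell them apart.
* Anchor-based inference requires the anchor genotype to be correct;
  genes with systematically confusable alleles (the IGHV4-59/IGHV4-61
  complex, IGHV1-69/IGHV1-69D) are excluded from inference for exactly
  this reason, and the shipped gene reference encodes those exclusions.
* The pooled-anchor convention cannot orient a D gene with no observed
  allele, and contradictory orientations across anchors ("allele mix")
  erode the pooled certainty; the orientation-consistency score is
  reported so such subjects can be recognized rather than silently
  mis-called.
* Multi-gene ambiguous calls are treated as multiple assignments and
  excluded from inference; no attempt is made to resolve them.
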