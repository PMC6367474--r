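#' Configuration for the diploid-repertoire simulator
#'
#' Describes the generative process the haplotype model assumes: a diploid
#' IGH genome with per-chromosome allele assignments and deletion blocks,
#' naive (unmutated) rearrangements drawn one chromosome at a time, and a
#' constant probability `epsilon` that a sequence's allele is mis-assigned
#' to the homologous chromosome's allele of the same gene.
#'
#' Gene usage weights default to log-normal draws per locus (`usage_sdlog`,
#' default 1), giving a spread with a few dominant genes like real
#' repertoires; supply a `usage_weights` tibble (`locus`, `gene`, `weight`)
#' to fix them. `bias_sdlog` > 0 adds a per-(gene, chromosome) log-normal
#' expression factor, creating allele usage bias in heterozygous genes.
#'
#' @param n_sequences Sequences per simulated repertoire (default 10000).
#' @param het_prob Per-gene probability of heterozygosity (default 0.3).
#' @param epsilon Allele mis-assignment probability in `[0, 0.5)`
#'   (default 0).
#' @param chrom_prob Probability a rearrangement comes from chromosome 1
#'   (default 0.5).
#' @param usage_weights Optional fixed usage weight tibble.
#' @param usage_sdlog Log-normal sd for generated usage weights.
#' @param bias_sdlog Log-normal sd of per-chromosome expression factors
#'   (default 0 = unbiased).
#' @param het_genes Genes forced heterozygous (e.g. `"IGHJ6"` so a J anchor
#'   always exists).
#' @param deletions List of engineered deletions, each
#'   `list(chrom =, genes =)` with `chrom` 1 or 2.
#' @param mutually_exclusive Optional list of block pairs, each
#'   `list(block1 =, block2 =)` of adjacent gene sets; per chromosome
#'   exactly one block of each pair is deleted.
#' @param allele_pool Allele designators to draw from.
#' @param subject_id Subject label stamped on simulated records.
#' @return A `simulationConfig` list.
#' @export
simulationConfig <- function(n_sequences = 10000, het_prob = 0.3,
                             epsilon = 0, chrom_prob = 0.5,
                             usage_weights = NULL, usage_sdlog = 1,
                             bias_sdlog = 0, het_genes = "IGHJ6",
                             deletions = list(), mutually_exclusive = NULL,
                             allele_pool = c("01", "02", "03", "04"),
                             subject_id = "S1") {
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must lie in [0, 0.5)")
  if (chrom_prob <= 0 || chrom_prob >= 1) stop("chrom_prob must lie in (0, 1)")
  if (!is.null(mutually_exclusive)) {
    for (pair in mutually_exclusive) {
      if (length(intersect(pair$block1, pair$block2)) > 0) {
        stop("mutually exclusive blocks must not share genes")
      }
    }
  }
  structure(list(
    n_sequences = n_sequences, het_prob = het_prob, epsilon = epsilon,
    chrom_prob = chrom_prob, usage_weights = usage_weights,
    usage_sdlog = usage_sdlog, bias_sdlog = bias_sdlog,
    het_genes = het_genes, deletions = deletions,
    mutually_exclusive = mutually_exclusive, allele_pool = allele_pool,
    subject_id = subject_id
  ), class = "simulationConfig")
}

#' Simulate a diploid IGH genome
#'
#' Draws per-chromosome allele assignments for every functional canonical
#' gene of the reference, applies engineered deletions and
#' mutually-exclusive deletion block pairs (mirroring the alternative
#' adjacent-block deletion structure seen in the V locus), and attaches
#' usage weights. Deterministic given `seed`.
#'
#' @param config A [simulationConfig()].
#' @param seed Integer random seed (mandatory).
#' @param reference Gene reference from [loadGeneReference()].
#' @return A `simulatedGenome` list with `genome` (tibble `gene`, `locus`,
#'   `chrom1`, `chrom2`; `"deleted"` marks a deleted copy), `weights`
#'   (tibble `locus`, `gene`, `weight`, `bias1`, `bias2`) and `config`.
#' @export
simulateGenome <- function(config, seed, reference = loadGeneReference()) {
  stopifnot(inherits(config, "simulationConfig"), is.numeric(seed))
  set.seed(seed)
  genes <- reference %>%
    filter(.data$functionality == "functional", !.data$exclude,
           is.na(.data$alias_of)) %>%
    arrange(match(.data$locus, c("IGHV", "IGHD", "IGHJ")), .data$locus_order)

  n <- nrow(genes)
  het <- runif(n) < config$het_prob
  het[genes$gene %in% config$het_genes] <- TRUE
  a1 <- character(n); a2 <- character(n)
  for (i in seq_len(n)) {
    if (het[i]) {
      pick <- sample(config$allele_pool, 2L)
      a1[i] <- pick[1L]; a2[i] <- pick[2L]
    } else {
      a1[i] <- a2[i] <- sample(config$allele_pool, 1L)
    }
  }
  genome <- tibble(gene = genes$gene, locus = genes$locus,
                   chrom1 = a1, chrom2 = a2)

  for (d in config$deletions) {
    col <- paste0("chrom", d$chrom)
    bad <- setdiff(d$genes, genome$gene)
    if (length(bad) > 0) stop("unknown genes in deletion: ",
                              paste(bad, collapse = ", "))
    genome[[col]][genome$gene %in% d$genes] <- "deleted"
  }
  if (!is.null(config$mutually_exclusive)) {
    for (pair in config$mutually_exclusive) {
      for (chrom in 1:2) {
        col <- paste0("chrom", chrom)
        block <- if (runif(1) < 0.5) pair$block1 else pair$block2
        genome[[col]][genome$gene %in% block] <- "deleted"
      }
    }
  }

  if (is.null(config$usage_weights)) {
    weights <- genes %>%
      select("locus", "gene") %>%
      mutate(weight = rlnorm(n, meanlog = 0, sdlog = config$usage_sdlog)) %>%
      group_by(.data$locus) %>%
      mutate(weight = .data$weight / sum(.data$weight)) %>%
      ungroup()
    # the six J genes have a well-known skewed usage profile in human
    # repertoires, with IGHJ4 and IGHJ6 dominating; fix it rather than
    # drawing it, since anchor-based inference leans on J6 linkage depth
    j_usage <- c(IGHJ1 = 0.04, IGHJ2 = 0.08, IGHJ3 = 0.08,
                 IGHJ4 = 0.40, IGHJ5 = 0.10, IGHJ6 = 0.30)
    hit <- weights$gene %in% names(j_usage)
    weights$weight[hit] <- unname(j_usage[weights$gene[hit]])
  } else {
    weights <- config$usage_weights
  }
  weights$bias1 <- if (config$bias_sdlog > 0) {
    rlnorm(nrow(weights), 0, config$bias_sdlog)
  } else rep(1, nrow(weights))
  weights$bias2 <- if (config$bias_sdlog > 0) {
    rlnorm(nrow(weights), 0, config$bias_sdlog)
  } else rep(1, nrow(weights))

  structure(list(genome = genome, weights = weights, config = config),
            class = "simulatedGenome")
}

#' Simulate an AIRR-style naive repertoire from a diploid genome
#'
#' Each sequence picks a chromosome (probability `chrom_prob` for
#' chromosome 1), then draws one V, one D and one J gene from that
#' chromosome's non-deleted genes proportionally to usage weights times the
#' chromosome's expression bias, and emits that chromosome's allele. With
#' probability `epsilon` the emitted allele is replaced by the homologous
#' chromosome's allele of the same gene, when that allele exists and
#' differs. Mutation-count columns are zero (naive repertoire); the output
#' satisfies the AIRR schema used by [readRearrangements()].
#'
#' @param genome A `simulatedGenome` from [simulateGenome()].
#' @param seed Integer random seed (mandatory).
#' @param n_sequences Number of sequences; defaults to the config value.
#' @return Rearrangement tibble.
#' @export
simulateRepertoire <- function(genome, seed, n_sequences = NULL) {
  stopifnot(inherits(genome, "simulatedGenome"))
  set.seed(seed)
  cfg <- genome$config
  n <- if (is.null(n_sequences)) cfg$n_sequences else n_sequences
  chrom <- 1L + (runif(n) >= cfg$chrom_prob)  # 1 or 2

  draw <- matrix(NA_character_, nrow = n, ncol = 3,
                 dimnames = list(NULL, c("IGHV", "IGHD", "IGHJ")))
  g <- genome$genome %>% left_join(genome$weights, by = c("locus", "gene"))
  for (locus in colnames(draw)) {
    gl <- g %>% filter(.data$locus == !!locus)
    for (c_idx in 1:2) {
      allele_col <- paste0("chrom", c_idx)
      bias_col <- paste0("bias", c_idx)
      alive <- gl[[allele_col]] != "deleted"
      if (!any(alive)) {
        stop("all ", locus, " genes deleted on chromosome ", c_idx)
      }
      idx <- which(chrom == c_idx)
      if (length(idx) == 0L) next
      w <- gl$weight[alive] * gl[[bias_col]][alive]
      pick <- sample(which(alive), length(idx), replace = TRUE,
                     prob = w / sum(w))
      allele <- gl[[allele_col]][pick]
      other <- gl[[paste0("chrom", 3L - c_idx)]][pick]
      if (cfg$epsilon > 0) {
        swap <- runif(length(idx)) < cfg$epsilon &
          other != "deleted" & other != allele
        allele[swap] <- other[swap]
      }
      draw[idx, locus] <- formatAlleleCall(gl$gene[pick], allele)
    }
  }

  tibble(
    sequence_id = sprintf("%s_seq%07d", cfg$subject_id, seq_len(n)),
    v_call = draw[, "IGHV"], d_call = draw[, "IGHD"], j_call = draw[, "IGHJ"],
    duplicate_count = 1L,
    v_mutation_count = 0L, d_mutation_count = 0L,
    subject_id = cfg$subject_id
  )
}

#' Emit ground-truth tables for a simulated genome
#'
#' Truth tables are keyed like the inference outputs so they can be joined
#' directly: chromosome 1 maps to label `chrA` and chromosome 2 to `chrB`
#' (anchor group A should therefore be chromosome 1's anchor allele).
#'
#' @param genome A `simulatedGenome`.
#' @return A list with `zygosity` (per gene: surviving alleles and truth
#'   zygosity) and `deletions` (per gene and chromosome label: `deleted`
#'   logical, plus a `state` column naming single/double deletions).
#' @export
emitTruth <- function(genome) {
  stopifnot(inherits(genome, "simulatedGenome"))
  g <- genome$genome
  subject <- genome$config$subject_id

  alleles <- mapply(function(a1, a2) {
    al <- setdiff(unique(c(a1, a2)), "deleted")
    paste(sort(al), collapse = ",")
  }, g$chrom1, g$chrom2)
  n_alleles <- mapply(function(a1, a2) {
    length(setdiff(unique(c(a1, a2)), "deleted"))
  }, g$chrom1, g$chrom2)
  zygosity <- tibble(
    subject_id = subject, gene = g$gene, locus = g$locus,
    alleles = unname(alleles),
    zygosity = ifelse(n_alleles == 0L, "deleted_both",
               ifelse(n_alleles >= 2L, "heterozygous", "homozygous"))
  )

  deletions <- bind_rows(
    tibble(subject_id = subject, gene = g$gene, locus = g$locus,
           chromosome = "chrA", deleted = g$chrom1 == "deleted"),
    tibble(subject_id = subject, gene = g$gene, locus = g$locus,
           chromosome = "chrB", deleted = g$chrom2 == "deleted")
  ) %>%
    group_by(.data$gene) %>%
    mutate(state = c("present", "deleted_single", "deleted_both")
           [sum(.data$deleted) + 1L]) %>%
    ungroup() %>%
    arrange(.data$gene, .data$chromosome)

  list(zygosity = zygosity, deletions = deletions)
}

#' Simulate a cohort-level gene usage table
#'
#' Draws each subject's V-locus gene counts as one multinomial of size
#' `depth` over the supplied usage weights, then zeroes the counts of
#' engineered two-chromosome deletions. Returns the same structure as
#' [computeUsage()] (restricted to the one locus), so cohort-level tests
#' of the binomial deletion test run without simulating full repertoires.
#'
#' @param weights Named numeric vector of gene usage weights (normalized
#'   internally).
#' @param n_subjects Number of subjects.
#' @param depth Sequences per subject.
#' @param deletions Tibble with `subject_id`, `gene` rows to zero out
#'   (engineered double deletions), or `NULL`.
#' @param seed Integer random seed (mandatory).
#' @param locus Locus label (default `"IGHV"`).
#' @return A usage list (`genes`, `totals`) plus the realized `deletions`.
#' @export
simulateUsageCohort <- function(weights, n_subjects, depth, deletions = NULL,
                                seed, locus = "IGHV") {
  set.seed(seed)
  w <- weights / sum(weights)
  counts <- rmultinom(n_subjects, depth, w)  # genes x subjects
  rownames(counts) <- names(weights)
  subjects <- sprintf("S%03d", seq_len(n_subjects))
  colnames(counts) <- subjects
  if (!is.null(deletions)) {
    for (i in seq_len(nrow(deletions))) {
      counts[deletions$gene[i], deletions$subject_id[i]] <- 0L
    }
  }
  totals <- colSums(counts)
  genes <- tibble(
    subject_id = rep(subjects, each = length(weights)),
    locus = locus,
    gene = rep(names(weights), times = n_subjects),
    n = as.integer(counts),
    fraction = as.numeric(sweep(counts, 2, pmax(totals, 1L), "/"))
  )
  list(
    genes = genes,
    totals = tibble(subject_id = subjects, locus = locus,
                    total = as.integer(totals)),
    deletions = deletions
  )
}
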