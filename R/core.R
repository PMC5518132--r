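#' Configuration for the permutation screen test
#'
#' @param n_permutations Number of gene-label permutations T used for each
#'   null distribution. The pooled null then holds `G * T` values, so with
#'   10,000 genes the default T = 10 gives a 100,000-value common null.
#' @param removal_threshold Unadjusted first-round p-value below which (in
#'   either selection direction) a gene is excluded from the second-round
#'   null construction.
#' @param pseudocount Non-negative value added to every raw count before
#'   normalization so that log fold changes stay finite at zero counts.
#' @param fdr_level Target FDR used when reporting hits.
#' @param seed Optional integer seed; when given, results are bit-identical
#'   across runs.
#' @return A `screen_test_config` list.
#' @export
screen_test_config <- function(n_permutations = 10L, removal_threshold = 0.05,
                         pseudocount = 1, fdr_level = 0.05, seed = NULL) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (removal_threshold <= 0 || removal_threshold >= 1) {
    # threshold 0 is expressible by passing a value below 1/null size;
    # we keep the open interval of the contract and treat p < thr strictly
    if (removal_threshold != 0) stop("removal_threshold must be in [0, 1)")
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (fdr_level <= 0 || fdr_level >= 1) stop("fdr_level must be in (0, 1)")
  structure(
    list(
      n_permutations = as.integer(n_permutations),
      removal_threshold = removal_threshold,
      pseudocount = pseudocount,
      fdr_level = fdr_level,
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "screen_test_config"
  )
}

#' Normalize counts to equal library size
#'
#' Adds the pseudocount to every raw count, then multiplies each condition by
#' `mean(total_0, total_1) / total_i` so both conditions end up with the same
#' total without changing within-condition proportions.
#'
#' @param table A [screen_count_table].
#' @param pseudocount Non-negative value added to each raw count first.
#' @return A `normalized_counts` list: `control`, `treatment` (positive
#'   reals), and `factors`, the two applied scale factors.
#' @export
normalize_counts <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "screen_count_table"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  y0 <- table$control + pseudocount
  y1 <- table$treatment + pseudocount
  t0 <- sum(y0)
  t1 <- sum(y1)
  if (t0 <= 0 || t1 <= 0) {
    stop("degenerate library: a condition has total count 0 after the pseudocount")
  }
  m <- mean(c(t0, t1))
  structure(
    list(
      control = y0 * (m / t0),
      treatment = y1 * (m / t1),
      factors = c(control = m / t0, treatment = m / t1)
    ),
    class = "normalized_counts"
  )
}

#' Per-sgRNA natural-log fold changes
#'
#' `r_j = ln(treatment_j / control_j)` on normalized counts.
#'
#' @param norm A `normalized_counts` object.
#' @return Numeric vector of length J, all finite.
#' @export
log_fold_changes <- function(norm) {
  stopifnot(inherits(norm, "normalized_counts"))
  if (any(norm$control <= 0) || any(norm$treatment <= 0)) {
    stop("zero normalized count encountered; use a positive pseudocount")
  }
  log(norm$treatment / norm$control)
}

# Precompute a gene-block layout: ordering of sgRNA indices so every gene's
# sgRNAs are contiguous, plus 0-based block starts and sizes. Gene order is
# first appearance in `gene`.
gene_index <- function(gene) {
  genes <- unique(gene)
  gi <- match(gene, genes)
  ord <- order(gi)
  sizes <- tabulate(gi, nbins = length(genes))
  starts <- c(0L, cumsum(sizes)[-length(sizes)])
  list(genes = genes, ord = ord, starts = as.integer(starts),
       sizes = as.integer(sizes))
}

#' Gene scores: median log fold change
#'
#' The score of gene g is the median of the `r_j` of its sgRNAs; the median
#' makes the score robust to outlying and off-target sgRNAs.
#'
#' @param r Per-sgRNA log fold changes.
#' @param gene Character vector parallel to `r` mapping sgRNAs to genes.
#' @return Named numeric vector of per-gene scores, in first-appearance gene
#'   order.
#' @export
gene_scores <- function(r, gene) {
  if (length(r) != length(gene)) stop("r and gene must be parallel vectors")
  idx <- gene_index(gene)
  out <- group_medians_cpp(r[idx$ord], idx$starts, idx$sizes)
  names(out) <- idx$genes
  out
}

#' Pooled permutation null distribution of gene scores
#'
#' Gene labels are permuted uniformly across sgRNAs while each sgRNA keeps its
#' observed (control, treatment) pair — equivalently, the `r_j` values are
#' shuffled over a fixed gene layout, so the multiset of gene sizes is
#' preserved. Gene scores are recomputed for each of the T permutations and
#' all `G * T` scores are pooled into one common null, shared by every gene.
#'
#' @inheritParams gene_scores
#' @param n_permutations Number of permutations T.
#' @return Numeric vector of `G * T` permuted gene scores. Uses the current
#'   RNG state; seed upstream for reproducibility.
#' @export
permutation_null <- function(r, gene, n_permutations = 10L) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  idx <- gene_index(gene)
  j <- length(r)
  g <- length(idx$genes)
  vals <- numeric(g * n_permutations)
  for (t in seq_len(n_permutations)) {
    rp <- r[sample.int(j)]
    vals[((t - 1L) * g + 1L):(t * g)] <-
      group_medians_cpp(rp[idx$ord], idx$starts, idx$sizes)
  }
  vals
}

#' One-sided empirical p-values against a pooled null
#'
#' For each gene score `R_g`, `p_pos` is the fraction of null values strictly
#' greater than `R_g` and `p_neg` the fraction strictly smaller; ties count
#' toward neither tail. Because a permutation p-value of exactly 0 is not
#' defensible (and breaks Fisher's method), both are floored at
#' `1 / (size + 1)` when `floor = TRUE`.
#'
#' @param scores Numeric vector of observed gene scores.
#' @param null Numeric vector, the pooled permutation null.
#' @param floor Apply the `1/(size+1)` floor (default TRUE).
#' @return Data frame with columns `p_pos`, `p_neg`.
#' @export
empirical_pvalues <- function(scores, null, floor = TRUE) {
  size <- length(null)
  if (size == 0L) stop("null distribution is empty")
  ns <- sort(null)
  n_le <- findInterval(scores, ns)                    # count of null <= score
  n_lt <- findInterval(scores, ns, left.open = TRUE)  # count of null <  score
  p_pos <- (size - n_le) / size
  p_neg <- n_lt / size
  if (floor) {
    fl <- 1 / (size + 1)
    p_pos <- pmax(p_pos, fl)
    p_neg <- pmax(p_neg, fl)
  }
  data.frame(p_pos = p_pos, p_neg = p_neg)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, via [stats::p.adjust()]. Input
#' p-values must lie in (0, 1].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted values in (0, 1].
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Combine replicate p-values with Fisher's method
#'
#' The statistic `-2 * sum_s log(p_gs)` over the S replicates of gene g is
#' referred to the upper tail of a chi-squared distribution with 2S degrees
#' of freedom.
#'
#' @param p_matrix Numeric matrix (or data frame), genes in rows, one column
#'   per replicate; all entries in (0, 1].
#' @return Numeric vector of combined p-values, one per gene.
#' @export
fisher_combine <- function(p_matrix) {
  p_matrix <- as.matrix(p_matrix)
  if (anyNA(p_matrix) || any(p_matrix <= 0) || any(p_matrix > 1)) {
    stop("replicate p-values must lie in (0, 1]")
  }
  s <- ncol(p_matrix)
  if (s < 1L) stop("need at least one replicate column")
  stat <- -2 * rowSums(log(p_matrix))
  pchisq(stat, df = 2 * s, lower.tail = FALSE)
}

# One full single-replicate pass: normalize -> r -> R -> round-1 null ->
# removal -> round-2 null (retained genes only) -> final p for all genes.
screen_test_single <- function(table, config, keep_null = FALSE) {
  norm <- normalize_counts(table, config$pseudocount)
  r <- log_fold_changes(norm)
  gene <- table$gene
  scores <- gene_scores(r, gene)

  null1 <- permutation_null(r, gene, config$n_permutations)
  p1 <- empirical_pvalues(scores, null1)
  removed <- p1$p_pos < config$removal_threshold |
    p1$p_neg < config$removal_threshold

  retained_genes <- names(scores)[!removed]
  if (length(retained_genes) < 2L) {
    warning("fewer than 2 genes retained after round 1; reusing round-1 null")
    null2 <- null1
  } else {
    keep <- gene %in% retained_genes
    null2 <- permutation_null(r[keep], gene[keep], config$n_permutations)
  }
  p2 <- empirical_pvalues(scores, null2)

  res <- data.frame(
    gene = names(scores),
    R = unname(scores),
    p_pos = p2$p_pos,
    fdr_pos = bh_adjust(p2$p_pos),
    p_neg = p2$p_neg,
    fdr_neg = bh_adjust(p2$p_neg),
    removed_round1 = removed,
    stringsAsFactors = FALSE
  )
  class(res) <- c("gene_inference", "data.frame")
  attr(res, "null_size") <- c(round1 = length(null1), round2 = length(null2))
  attr(res, "n_removed_round1") <- sum(removed)
  if (keep_null) {
    attr(res, "null_round1") <- null1
    attr(res, "null_round2") <- null2
  }
  res
}

#' Permutation-based nonparametric screen test
#'
#' Runs the full gene-selection analysis on one count table, or on a list of
#' replicate tables. Per table: counts are normalized to equal totals, each
#' sgRNA gets a natural-log fold change `r_j`, each gene the median of its
#' sgRNAs' `r_j` as score `R_g`; a common null is built by permuting gene
#' labels T times and pooling all permuted gene scores; one-sided empirical
#' p-values are taken against this null; genes significant at the (unadjusted)
#' removal threshold in either direction are then excluded and the null is
#' rebuilt from the remaining genes only, against which final p-values for
#' all genes are computed; BH adjustment is applied separately to the
#' positive- and negative-selection p-value vectors.
#'
#' With a list of replicate tables each replicate is analyzed independently
#' (own normalization and null); the per-gene, per-direction p-values are
#' combined across replicates with [fisher_combine()] and BH is applied to
#' the combined p-values.
#'
#' @param x A [screen_count_table] or a list of them (replicates sharing the
#'   same sgRNA universe).
#' @param config A [screen_test_config].
#' @param keep_null If TRUE, attach the round-1/round-2 null vectors as
#'   attributes (single-table runs only); useful for diagnostics.
#' @return A `gene_inference` data frame: `gene`, `R` (mean across replicates
#'   when combined), `p_pos`, `fdr_pos`, `p_neg`, `fdr_neg`,
#'   `removed_round1` (any replicate).
#' @export
#' @examples
#' tab <- screen_count_table(
#'   sgrna = sprintf("s%d", 1:6),
#'   gene = rep(c("G1", "G2", "G3"), each = 2),
#'   control = c(100, 120, 80, 90, 110, 100),
#'   treatment = c(400, 380, 85, 95, 100, 115)
#' )
#' screen_test(tab, screen_test_config(n_permutations = 20, seed = 1))
screen_test <- function(x, config = screen_test_config(), keep_null = FALSE) {
  stopifnot(inherits(config, "screen_test_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  if (inherits(x, "screen_count_table")) {
    return(screen_test_single(x, config, keep_null = keep_null))
  }
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "screen_count_table"))) {
    stop("x must be a screen_count_table or a list of them")
  }
  if (length(x) == 1L) return(screen_test_single(x[[1L]], config, keep_null))

  ref <- sort(x[[1L]]$sgrna)
  for (k in seq_along(x)[-1L]) {
    if (!identical(sort(x[[k]]$sgrna), ref)) {
      stop("replicates must share the same sgRNA universe ",
           "(replicate ", k, " differs)")
    }
  }
  per_rep <- lapply(x, screen_test_single, config = config)
  genes <- per_rep[[1L]]$gene
  align <- function(field) {
    vapply(per_rep, function(res) res[[field]][match(genes, res$gene)],
           numeric(length(genes)))
  }
  p_pos <- fisher_combine(align("p_pos"))
  p_neg <- fisher_combine(align("p_neg"))
  res <- data.frame(
    gene = genes,
    R = rowMeans(align("R")),
    p_pos = p_pos,
    fdr_pos = bh_adjust(p_pos),
    p_neg = p_neg,
    fdr_neg = bh_adjust(p_neg),
    removed_round1 = Reduce(`|`, lapply(per_rep, function(res) {
      res$removed_round1[match(genes, res$gene)]
    })),
    stringsAsFactors = FALSE
  )
  class(res) <- c("gene_inference", "data.frame")
  attr(res, "n_replicates") <- length(x)
  res
}
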