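test_that("normalization equalizes condition totals with mean-ratio factors", {
  tab <- screen_count_table(
    sgrna = c("s1", "s2"), gene = c("G1", "G2"),
    control = c(40, 60), treatment = c(100, 200)
  )
  norm <- normalize_counts(tab, pseudocount = 0)
  expect_equal(unname(norm$factors), c(2, 2 / 3))
  expect_equal(sum(norm$control), 200)
  expect_equal(sum(norm$treatment), 200)

  # identical conditions: factors 1, values unchanged
  tab2 <- screen_count_table("s1", "G1", control = 50, treatment = 50)
  norm2 <- normalize_counts(tab2, pseudocount = 0)
  expect_equal(unname(norm2$factors), c(1, 1))
  expect_equal(norm2$treatment, 50)
})

test_that("normalization equalizes totals for arbitrary counts (property)", {
  set.seed(101)
  for (k in 1:20) {
    j <- sample(2:40, 1)
    tab <- screen_count_table(
      sgrna = paste0("s", 1:j), gene = paste0("G", 1:j),
      control = rpois(j, 50), treatment = rpois(j, 200)
    )
    norm <- normalize_counts(tab, pseudocount = 1)
    tot <- sum(norm$control)
    expect_lt(abs(sum(norm$treatment) - tot), 1e-8 * tot)
  }
  tab0 <- screen_count_table("s1", "G1", control = 0, treatment = 0)
  expect_error(normalize_counts(tab0, pseudocount = 0), "degenerate")
})

test_that("log fold changes match the element-wise definition", {
  tab <- screen_count_table(
    sgrna = paste0("s", 1:3), gene = paste0("G", 1:3),
    control = c(10, 10, 10), treatment = c(10, 10, 10)
  )
  norm <- normalize_counts(tab, pseudocount = 0)
  expect_equal(log_fold_changes(norm), c(0, 0, 0))

  # Y1 = e * Y0 => r = 1 (up to the shared normalization shift)
  norm_e <- structure(
    list(control = c(2, 5), treatment = exp(1) * c(2, 5),
         factors = c(control = 1, treatment = 1)),
    class = "normalized_counts"
  )
  expect_equal(log_fold_changes(norm_e), c(1, 1))

  # vector case against a scalar loop oracle
  set.seed(7)
  y0 <- runif(50, 1, 100)
  y1 <- runif(50, 1, 100)
  norm_v <- structure(
    list(control = y0, treatment = y1,
         factors = c(control = 1, treatment = 1)),
    class = "normalized_counts"
  )
  r <- log_fold_changes(norm_v)
  for (j in seq_along(y0)) expect_identical(r[j], log(y1[j] / y0[j]))

  norm_zero <- structure(
    list(control = c(0, 1), treatment = c(1, 1),
         factors = c(control = 1, treatment = 1)),
    class = "normalized_counts"
  )
  expect_error(log_fold_changes(norm_zero), "pseudocount")
})

test_that("gene scores are within-gene medians, matching the stats::median oracle", {
  expect_equal(
    unname(gene_scores(c(0.1, 0.9, 0.2), rep("g", 3))), 0.2
  )
  expect_equal(unname(gene_scores(c(0, 1), c("g", "g"))), 0.5)
  expect_equal(unname(gene_scores(-2.3, "g")), -2.3)

  set.seed(11)
  for (k in 1:10) {
    sizes <- sample(1:6, 30, replace = TRUE)
    gene <- rep(paste0("g", 1:30), times = sizes)
    r <- rnorm(length(gene))
    got <- gene_scores(r, gene)
    expect_equal(got, oracle_gene_scores(r, gene))
    # R_g bounded by its gene's r range
    rng <- vapply(split(r, factor(gene, unique(gene))), range, numeric(2))
    expect_true(all(got >= rng[1, ] & got <= rng[2, ]))
  }
})

test_that("permutation null has size G x T and preserves the r multiset", {
  set.seed(3)
  gene <- rep(paste0("g", 1:12), each = 3)
  r <- rnorm(36)
  null <- permutation_null(r, gene, n_permutations = 7)
  expect_length(null, 12 * 7)

  # degenerate: identical r values -> every null value equals them
  null_c <- permutation_null(rep(1.5, 36), gene, n_permutations = 3)
  expect_true(all(null_c == 1.5))

  # single gene holding all sgRNAs: permutation is vacuous
  null_1 <- permutation_null(r, rep("only", 36), n_permutations = 5)
  expect_true(all(null_1 == median(r)))

  # permutation invariance of the pooled r multiset: with singleton genes the
  # per-permutation scores are exactly a permutation of r
  gene_singl <- paste0("g", 1:20)
  r20 <- rnorm(20)
  null_s <- permutation_null(r20, gene_singl, n_permutations = 4)
  for (t in 1:4) {
    expect_equal(sort(null_s[((t - 1) * 20 + 1):(t * 20)]), sort(r20))
  }
})

test_that("empirical p-values match the direct-count oracle, ties in neither tail", {
  null <- c(-1, 0, 1, 2)
  p <- empirical_pvalues(0.5, null, floor = FALSE)
  expect_equal(p$p_pos, 2 / 4)
  expect_equal(p$p_neg, 2 / 4)

  # random property check against the counting oracle
  set.seed(19)
  for (k in 1:10) {
    null <- rnorm(200)
    scores <- c(sample(null, 5), rnorm(5))  # include exact ties
    got <- empirical_pvalues(scores, null, floor = FALSE)
    expect_equal(got, oracle_empirical_p(scores, null))
  }

  # extreme score: flooring kicks in on the empty tail only
  null <- 1:100
  p_hi <- empirical_pvalues(1000, null)
  expect_equal(p_hi$p_pos, 1 / 101)
  expect_equal(p_hi$p_neg, 1)

  # all null values tied with the score: both tails floored
  p_tie <- empirical_pvalues(5, rep(5, 10))
  expect_equal(p_tie$p_pos, 1 / 11)
  expect_equal(p_tie$p_neg, 1 / 11)
})

test_that("tail complementarity: p_pos + p_neg + tie fraction = 1 before flooring", {
  set.seed(23)
  null <- rnorm(500)
  scores <- c(rnorm(20), sample(null, 10))
  p <- empirical_pvalues(scores, null, floor = FALSE)
  ties <- vapply(scores, function(s) mean(null == s), 0)
  expect_equal(p$p_pos + p$p_neg + ties, rep(1, length(scores)))
})

test_that("BH adjustment is the step-up procedure with monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  # fdr >= p rank-wise; output invariant to input ordering
  set.seed(29)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})
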