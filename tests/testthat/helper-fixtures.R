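# Fixtures are built in code; nothing is read from disk unless a test writes
# it first.

# Four sgRNAs, two genes, one sample pair -- the smallest interesting table.
tiny_table <- function() {
  screen_count_table(
    sgrna = c("A_sg1", "A_sg2", "B_sg1", "B_sg2"),
    gene = c("A", "A", "B", "B"),
    control = c(10, 20, 30, 40),
    treatment = c(12, 18, 90, 80)
  )
}

# Write a MAGeCK-style count TSV and return its path.
write_count_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_count_df <- function() {
  data.frame(
    sgRNA = c("A_sg1", "A_sg2", "B_sg1", "B_sg2"),
    Gene = c("A", "A", "B", "B"),
    ctrl = c(10L, 20L, 30L, 40L),
    treat = c(12L, 18L, 90L, 80L),
    check.names = FALSE
  )
}

# Independent brute-force oracles -----------------------------------------

# Direct-count empirical p-values (the quantity the sweep must reproduce).
oracle_empirical_p <- function(scores, null) {
  size <- length(null)
  data.frame(
    p_pos = vapply(scores, function(s) sum(null > s) / size, 0),
    p_neg = vapply(scores, function(s) sum(null < s) / size, 0)
  )
}

# Pairwise-comparison AUC: P(score_pos < score_neg) + 0.5 P(tie),
# enumerated over all (positive, negative) pairs.
oracle_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  grid <- outer(pos, neg, FUN = function(a, b) (a < b) + 0.5 * (a == b))
  mean(grid)
}

# R-median loop oracle for grouped gene scores.
oracle_gene_scores <- function(r, gene) {
  vapply(split(r, factor(gene, levels = unique(gene))), median, 0)
}
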