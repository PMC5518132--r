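#' Construct a screen count table
#'
#' Container for per-sgRNA read counts of one (control, treatment) pair of
#' samples, with the sgRNA-to-gene map. All gene-level inference is driven by
#' this structure: condition 0 is the control, condition 1 the treatment.
#'
#' @param sgrna Character vector of unique sgRNA identifiers (length J).
#' @param gene Character vector, parallel to `sgrna`: the gene each sgRNA
#'   targets. A gene may (and usually does) appear several times.
#' @param control,treatment Non-negative integer count vectors of length J.
#' @param replicate_id Integer tag for the replicate this pair represents.
#'
#' @return An object of class `screen_count_table`: a list with elements
#'   `sgrna`, `gene`, `control`, `treatment`, `replicate_id`.
#' @export
#' @examples
#' screen_count_table(
#'   sgrna = c("g1_a", "g1_b", "g2_a", "g2_b"),
#'   gene = c("G1", "G1", "G2", "G2"),
#'   control = c(10, 20, 30, 40),
#'   treatment = c(12, 18, 90, 80)
#' )
screen_count_table <- function(sgrna, gene, control, treatment,
                               replicate_id = 1L) {
  sgrna <- as.character(sgrna)
  gene <- as.character(gene)
  j <- length(sgrna)
  if (j < 1L) stop("a screen count table needs at least one sgRNA")
  if (length(gene) != j || length(control) != j || length(treatment) != j) {
    stop("sgrna, gene, control and treatment must have identical length")
  }
  if (anyDuplicated(sgrna)) {
    dup <- sgrna[duplicated(sgrna)][1L]
    stop("duplicated sgRNA id: '", dup, "'")
  }
  check_counts <- function(x, what) {
    if (anyNA(x) || any(x < 0) || any(x != trunc(x))) {
      bad <- which(is.na(x) | x < 0 | x != trunc(x))[1L]
      stop(what, " counts must be non-negative integers (row ", bad, ")")
    }
    as.numeric(x)
  }
  structure(
    list(
      sgrna = sgrna, gene = gene,
      control = check_counts(control, "control"),
      treatment = check_counts(treatment, "treatment"),
      replicate_id = as.integer(replicate_id)
    ),
    class = "screen_count_table"
  )
}

#' @export
print.screen_count_table <- function(x, ...) {
  cat(
    "screen_count_table: ", length(x$sgrna), " sgRNAs, ",
    length(unique(x$gene)), " genes (replicate ", x$replicate_id, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Read a tab-delimited sgRNA count table
#'
#' Reads a MAGeCK-style count file: header row with columns `sgRNA`, `Gene`,
#' then one column of raw read counts per sample. Each (control, treatment)
#' column pair yields one [screen_count_table]; pairing is positional,
#' `control_cols[k]` with `treatment_cols[k]`, and never guessed.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @param control_cols,treatment_cols Character vectors (same length S) naming
#'   the control and treatment sample columns, in pairing order.
#' @return A list of S `screen_count_table` objects with `replicate_id`
#'   `1..S`, preserving input row order.
#' @export
read_count_table <- function(path, control_cols, treatment_cols) {
  if (!file.exists(path)) stop("count file not found: ", path)
  if (length(control_cols) != length(treatment_cols)) {
    stop("control_cols and treatment_cols must pair up one-to-one")
  }
  if (length(control_cols) < 1L) stop("at least one sample pair is required")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("sgRNA", "Gene", control_cols, treatment_cols)
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(sQuote(missing), collapse = ", "))
  }
  parse_counts <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) | x < 0 | x != trunc(x))
    if (length(bad)) {
      stop("column '", col, "' row ", bad[1L],
           ": count cell '", df[[col]][bad[1L]],
           "' is not a non-negative integer")
    }
    x
  }
  lapply(seq_along(control_cols), function(k) {
    screen_count_table(
      sgrna = df$sgRNA, gene = df$Gene,
      control = parse_counts(control_cols[k]),
      treatment = parse_counts(treatment_cols[k]),
      replicate_id = k
    )
  })
}

#' Write gene-level results to a TSV file
#'
#' Writes one row per gene with header
#' `Gene, R, p.pos, fdr.pos, p.neg, fdr.neg`. Numeric fields are written at
#' full double precision (15 significant digits) so a read-back round-trips.
#'
#' @param results A `gene_inference` data frame as returned by [screen_test()].
#' @param path Output file path.
#' @export
write_gene_results <- function(results, path) {
  if (!inherits(results, "data.frame") || nrow(results) == 0L) {
    stop("results must be a non-empty gene_inference data frame")
  }
  out <- data.frame(
    Gene = results$gene,
    R = format(results$R, digits = 15, trim = TRUE, scientific = FALSE),
    p.pos = format(results$p_pos, digits = 15, trim = TRUE),
    fdr.pos = format(results$fdr_pos, digits = 15, trim = TRUE),
    p.neg = format(results$p_neg, digits = 15, trim = TRUE),
    fdr.neg = format(results$fdr_neg, digits = 15, trim = TRUE),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a gene-level result table written by [write_gene_results()]
#'
#' @param path Path to the TSV file.
#' @return A `gene_inference` data frame (columns `gene`, `R`, `p_pos`,
#'   `fdr_pos`, `p_neg`, `fdr_neg`).
#' @export
read_gene_results <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  needed <- c("Gene", "R", "p.pos", "fdr.pos", "p.neg", "fdr.neg")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(sQuote(missing), collapse = ", "))
  }
  structure(
    data.frame(
      gene = df$Gene, R = df$R,
      p_pos = df$p.pos, fdr_pos = df$fdr.pos,
      p_neg = df$p.neg, fdr_neg = df$fdr.neg,
      stringsAsFactors = FALSE
    ),
    class = c("gene_inference", "data.frame")
  )
}
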