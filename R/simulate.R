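#' Configuration of the Dirichlet-multinomial screen simulator
#'
#' The generator mimics a pooled CRISPR screen read out by sequencing: each
#' sgRNA is a category of a multinomial at fixed sequencing depth, and the
#' category probabilities are drawn from a Dirichlet whose parameters
#' `gamma_ij = exp(alpha_j + beta_j * i)` carry the sgRNA effects. Baseline
#' intensities `gamma_0j` come from a negative binomial NB(q, p) so the count
#' distribution is right-skewed like real libraries; `beta_j` is the sgRNA
#' effect (log change in mean read count under treatment).
#'
#' @param n_genes Total number of genes G.
#' @param sgrnas_per_gene sgRNAs targeting each gene (typical libraries use
#'   2-6).
#' @param mu_levels Gene-effect means; positive values are
#'   positively selected genes (knockout promotes growth), negative values
#'   essential genes. Default `c(1.5, 1, 0.5, -1, -2, -3)` spans
#'   high/medium/low effects in both directions.
#' @param genes_per_level True-hit genes simulated at each mu level.
#' @param sigma SD of the sgRNA effects around their gene mean.
#' @param nb_q,nb_p Negative-binomial parameters of the baseline intensities
#'   (`q` successes, success probability `p`).
#' @param off_target_rate Fraction of sgRNAs, chosen uniformly library-wide,
#'   whose effect is replaced by a fresh `N(0, sigma^2)` draw to emulate
#'   off-target activity.
#' @param depth Total reads per condition. Default `300 * J` (about 300x
#'   coverage per sgRNA, typical of screen sequencing).
#' @param overdispersion_divisor Every `gamma_ij` is divided by this value;
#'   a smaller total intensity `gamma_i+` means more overdispersion, so
#'   divisor 10 emulates high-noise screens and divisor 5 low-quality
#'   replicate data.
#' @param n_replicates Number of replicate screens drawn from one truth.
#' @param seed Optional integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 10000L, sgrnas_per_gene = 3L,
                       mu_levels = c(1.5, 1, 0.5, -1, -2, -3),
                       genes_per_level = 50L, sigma = 0.4,
                       nb_q = 3, nb_p = 0.08,
                       off_target_rate = 0,
                       depth = NULL,
                       overdispersion_divisor = 1,
                       n_replicates = 1L, seed = NULL) {
  n_hits <- length(mu_levels) * genes_per_level
  if (n_genes < n_hits) {
    stop("n_genes must be at least length(mu_levels) * genes_per_level")
  }
  if (sgrnas_per_gene < 1L) stop("sgrnas_per_gene must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (nb_q < 1 || nb_p <= 0 || nb_p >= 1) stop("need nb_q >= 1 and 0 < nb_p < 1")
  if (off_target_rate < 0 || off_target_rate > 1) {
    stop("off_target_rate must be in [0, 1]")
  }
  if (overdispersion_divisor <= 0) stop("overdispersion_divisor must be > 0")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  j <- n_genes * sgrnas_per_gene
  if (is.null(depth)) depth <- 300 * j
  if (depth < 1) stop("depth must be >= 1")
  structure(
    list(
      n_genes = as.integer(n_genes),
      sgrnas_per_gene = as.integer(sgrnas_per_gene),
      mu_levels = mu_levels,
      genes_per_level = as.integer(genes_per_level),
      sigma = sigma, nb_q = nb_q, nb_p = nb_p,
      off_target_rate = off_target_rate,
      depth = depth,
      overdispersion_divisor = overdispersion_divisor,
      n_replicates = as.integer(n_replicates),
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Draw baseline Dirichlet intensities from a negative binomial
#'
#' Counts are drawn as failures before the `q`-th success with success
#' probability `p` (the standard NB convention), so the mean is
#' `q * (1 - p) / p`. Zero draws are resampled until positive because a
#' Dirichlet parameter must be strictly positive.
#'
#' @param n Number of sgRNAs.
#' @param q,p NB parameters.
#' @return Strictly positive numeric vector of length `n`. Uses the current
#'   RNG state.
#' @export
draw_gamma0 <- function(n, q = 3, p = 0.08) {
  g <- rnbinom(n, size = q, prob = p)
  while (any(zero <- g == 0)) {
    g[zero] <- rnbinom(sum(zero), size = q, prob = p)
  }
  as.numeric(g)
}

#' Draw gene and sgRNA effects (the simulation ground truth)
#'
#' `genes_per_level` genes are assigned uniformly at random (without
#' replacement) to each mu level; their sgRNA effects are drawn
#' `N(mu_g, sigma^2)` and then reflected to the sign of `mu_g`, so every
#' on-target sgRNA of a true hit acts in its gene's direction. Null genes get
#' `beta = 0`. Finally a fraction `off_target_rate` of all sgRNAs, chosen
#' uniformly library-wide, have their effect replaced by a fresh
#' `N(0, sigma^2)` draw and are flagged as off-target.
#'
#' @param config A [sim_config].
#' @return A `truth_table` list with data frames `genes` (gene, direction,
#'   mu) and `sgrnas` (sgrna, gene, beta, off_target). Uses the current RNG
#'   state.
#' @export
draw_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g_total <- config$n_genes
  n_per <- config$sgrnas_per_gene
  j <- g_total * n_per
  genes <- sprintf("gene%05d", seq_len(g_total))
  sgrnas <- sprintf("gene%05d_sg%d",
                    rep(seq_len(g_total), each = n_per),
                    rep(seq_len(n_per), times = g_total))
  gene_of <- rep(genes, each = n_per)

  mu <- numeric(g_total)
  n_levels <- length(config$mu_levels)
  n_hits <- n_levels * config$genes_per_level
  if (n_hits > 0L) {
    hit_idx <- sample.int(g_total, n_hits)
    mu[hit_idx] <- rep(config$mu_levels, each = config$genes_per_level)
  }
  direction <- ifelse(mu > 0, "positive", ifelse(mu < 0, "negative", "null"))

  beta <- numeric(j)
  mu_sg <- rep(mu, each = n_per)
  hit_sg <- mu_sg != 0
  if (any(hit_sg)) {
    b <- rnorm(sum(hit_sg), mean = mu_sg[hit_sg], sd = config$sigma)
    beta[hit_sg] <- sign(mu_sg[hit_sg]) * abs(b)
  }

  off_target <- logical(j)
  n_ot <- round(config$off_target_rate * j)
  if (n_ot > 0L) {
    ot_idx <- sample.int(j, n_ot)
    beta[ot_idx] <- rnorm(n_ot, mean = 0, sd = config$sigma)
    off_target[ot_idx] <- TRUE
  }

  structure(
    list(
      genes = data.frame(gene = genes, direction = direction, mu = mu,
                         stringsAsFactors = FALSE),
      sgrnas = data.frame(sgrna = sgrnas, gene = gene_of, beta = beta,
                          off_target = off_target, stringsAsFactors = FALSE)
    ),
    class = "truth_table"
  )
}

#' Draw one Dirichlet-multinomial count vector
#'
#' A probability vector is drawn from the Dirichlet with parameters `gamma`
#' (as normalized Gamma variates) and counts are then multinomial with
#' `depth` trials, so `E(Y_j) = depth * gamma_j / gamma_+` and the variance
#' exceeds the multinomial one by the factor
#' `(depth + gamma_+) / (1 + gamma_+)`.
#'
#' @param gamma Strictly positive Dirichlet intensities, one per sgRNA.
#' @param depth Total read count.
#' @return Integer count vector summing to `depth`. Uses the current RNG
#'   state.
#' @export
draw_dm_counts <- function(gamma, depth) {
  if (any(gamma <= 0)) stop("all gamma intensities must be > 0")
  if (depth < 1) stop("depth must be >= 1")
  w <- rgamma(length(gamma), shape = gamma, rate = 1)
  s <- sum(w)
  if (s <= 0) stop("degenerate Dirichlet draw; gamma intensities too small")
  as.vector(rmultinom(1, size = depth, prob = w / s))
}

#' Simulate a pooled screen with ground truth
#'
#' Full generator pipeline: baseline intensities `gamma_0j ~ NB(q, p)` (zeros
#' resampled), effects drawn per [draw_effects()], treatment intensities
#' `gamma_1j = gamma_0j * exp(beta_j)`, both conditions divided by the
#' overdispersion divisor, then independent Dirichlet-multinomial count draws
#' at the configured depth for control and treatment. Replicates share the
#' truth and the intensities and differ only in the count draws.
#'
#' @param config A [sim_config].
#' @return A `simulated_screen` list: `tables` (list of
#'   [screen_count_table], one per replicate), `truth` (a `truth_table`),
#'   `gamma0`, `gamma1` (the intensities actually used, after the divisor),
#'   and `config`.
#' @export
#' @examples
#' sim <- simulate_screen(sim_config(
#'   n_genes = 50, genes_per_level = 2, seed = 1
#' ))
#' sim$tables[[1]]
simulate_screen <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  j <- config$n_genes * config$sgrnas_per_gene

  gamma0 <- draw_gamma0(j, config$nb_q, config$nb_p)
  truth <- draw_effects(config)
  gamma1 <- gamma0 * exp(truth$sgrnas$beta)
  d <- config$overdispersion_divisor
  gamma0 <- gamma0 / d
  gamma1 <- gamma1 / d

  tables <- lapply(seq_len(config$n_replicates), function(s) {
    screen_count_table(
      sgrna = truth$sgrnas$sgrna,
      gene = truth$sgrnas$gene,
      control = draw_dm_counts(gamma0, config$depth),
      treatment = draw_dm_counts(gamma1, config$depth),
      replicate_id = s
    )
  })

  structure(
    list(tables = tables, truth = truth, gamma0 = gamma0, gamma1 = gamma1,
         config = config),
    class = "simulated_screen"
  )
}

#' Write simulated counts and truth to TSV files
#'
#' The count file uses the same dialect [read_count_table()] accepts: columns
#' `sgRNA`, `Gene`, then `control_s`/`treatment_s` per replicate. The truth
#' file has one row per sgRNA with its gene's direction and mu plus the
#' sgRNA-level effect and off-target flag.
#'
#' @param sim A `simulated_screen`.
#' @param counts_path,truth_path Output paths.
#' @export
write_simulated_screen <- function(sim, counts_path, truth_path = NULL) {
  stopifnot(inherits(sim, "simulated_screen"))
  df <- data.frame(sgRNA = sim$truth$sgrnas$sgrna,
                   Gene = sim$truth$sgrnas$gene,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (s in seq_along(sim$tables)) {
    df[[paste0("control_", s)]] <- as.integer(sim$tables[[s]]$control)
    df[[paste0("treatment_", s)]] <- as.integer(sim$tables[[s]]$treatment)
  }
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth_path)) {
    tg <- sim$truth$genes
    ts <- sim$truth$sgrnas
    out <- data.frame(
      sgrna = ts$sgrna, gene = ts$gene,
      direction = tg$direction[match(ts$gene, tg$gene)],
      mu = tg$mu[match(ts$gene, tg$gene)],
      beta = ts$beta, off_target = ts$off_target,
      stringsAsFactors = FALSE
    )
    write.table(out, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(counts_path)
}
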