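## Synthetic count data with the statistical structure of the benchmark
## protocol (two-condition negative binomial data with a stated fraction of
## DE genes, optional Poisson genes and multiplicative outliers), a forward
## simulator of the full hierarchical model, and the evaluation metrics
## (ROC AUC, false discovery curves, realized FDR, adjusted Rand index).

#' Generate a two-condition benchmark dataset
#'
#' Per gene, a baseline mean is drawn log-normally and a dispersion from a
#' decreasing mean-dispersion trend with log-normal scatter (parametric
#' stand-ins with a realistic bulk RNA-seq shape; override via the `...`
#' arguments).  A fraction of genes is made differentially expressed by
#' applying a non-zero log-fold-change to condition 2 (symmetric up/down);
#' a fraction is Poisson (dispersion exactly 0); counts are NB (or Poisson)
#' sampled and, with probability `outlier_prob` per cell, multiplied by a
#' continuous Uniform(5, 10) factor and rounded.
#'
#' @param n_genes number of genes N.
#' @param n_per_group replicates per condition (scalar or length 2).
#' @param frac_de fraction of DE genes (e.g. 0, 0.1, 0.3).
#' @param frac_poisson fraction of zero-dispersion genes.
#' @param outlier_prob per-cell probability of a multiplicative outlier.
#' @param de_effect list with `min_l2fc` and `rate`: absolute log2
#'   fold-changes are `min_l2fc + Exponential(rate)`, sign +/- with equal
#'   probability.
#' @param mean_meanlog,mean_sdlog log-normal parameters of baseline means.
#' @param disp_a,disp_b,disp_sdlog dispersion trend `phi = a/m + b` with
#'   mean-one log-normal scatter of log-sd `disp_sdlog`.
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return list with `counts` ([count_matrix()]), `groups` ([group_map()]),
#'   `truth` (data frame: `gene_id`, `is_de`, `log_fc` (natural log,
#'   applied to condition 2), `is_poisson`, `mean`, `dispersion`) and
#'   `outlier_mask` (logical N x M matrix), plus the generating `params`.
#' @export
generate_dataset <- function(n_genes, n_per_group, frac_de = 0.1,
                             frac_poisson = 0, outlier_prob = 0,
                             de_effect = list(min_l2fc = 1.5, rate = 1),
                             mean_meanlog = 4, mean_sdlog = 1.5,
                             disp_a = 3, disp_b = 0.1, disp_sdlog = 0.25,
                             seed = NULL) {
  if (frac_de < 0 || frac_de > 1 || frac_poisson < 0 || frac_poisson > 1 ||
      outlier_prob < 0 || outlier_prob > 1)
    stop("fractions must lie in [0, 1]")
  if (any(n_per_group < 1)) stop("need at least one library per condition")
  if (!is.null(seed)) set.seed(seed)
  n_per_group <- rep_len(as.integer(n_per_group), 2L)
  M <- sum(n_per_group)
  cond <- rep(1:2, n_per_group)

  m0 <- rlnorm(n_genes, mean_meanlog, mean_sdlog)
  scatter <- rlnorm(n_genes, -disp_sdlog^2 / 2, disp_sdlog)
  phi <- (disp_a / m0 + disp_b) * scatter
  is_poisson <- rep(FALSE, n_genes)
  n_pois <- round(frac_poisson * n_genes)
  if (n_pois > 0) is_poisson[sample.int(n_genes, n_pois)] <- TRUE
  phi[is_poisson] <- 0

  is_de <- rep(FALSE, n_genes)
  n_de <- round(frac_de * n_genes)
  if (n_de > 0) is_de[sample.int(n_genes, n_de)] <- TRUE
  log_fc <- numeric(n_genes)
  if (n_de > 0) {
    l2 <- (de_effect$min_l2fc + rexp(n_de, de_effect$rate)) *
      sample(c(-1, 1), n_de, replace = TRUE)
    log_fc[is_de] <- log(2) * l2
  }

  mean_mat <- outer(m0, rep(1, M))
  mean_mat[, cond == 2] <- mean_mat[, cond == 2] * exp(log_fc)
  counts <- matrix(0, n_genes, M)
  for (j in seq_len(M)) {
    counts[, j] <- ifelse(is_poisson,
                          rpois(n_genes, mean_mat[, j]),
                          rnbinom(n_genes, mu = mean_mat[, j],
                                  size = 1 / pmax(phi, 1e-12)))
  }
  outlier_mask <- matrix(runif(n_genes * M) < outlier_prob, n_genes, M)
  if (any(outlier_mask)) {
    f <- runif(sum(outlier_mask), 5, 10)
    counts[outlier_mask] <- round(counts[outlier_mask] * f)
  }

  gene_ids <- sprintf("gene_%0*d", nchar(n_genes), seq_len(n_genes))
  lib_ids <- sprintf("cond%d_rep%d", cond,
                     unlist(lapply(n_per_group, seq_len)))
  cm <- count_matrix(counts, gene_ids, lib_ids)
  gm <- group_map(paste0("cond", cond), library_ids = lib_ids)
  truth <- data.frame(gene_id = gene_ids, is_de = is_de, log_fc = log_fc,
                      is_poisson = is_poisson, mean = m0, dispersion = phi,
                      stringsAsFactors = FALSE)
  list(counts = cm, groups = gm, truth = truth, outlier_mask = outlier_mask,
       params = list(n_genes = n_genes, n_per_group = n_per_group,
                     frac_de = frac_de, frac_poisson = frac_poisson,
                     outlier_prob = outlier_prob, de_effect = de_effect,
                     mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog,
                     disp_a = disp_a, disp_b = disp_b,
                     disp_sdlog = disp_sdlog, seed = seed))
}

#' Forward-simulate the hierarchical generative model
#'
#' Draws global atoms and truncated stick weights, group-level sticks over
#' the global measure, per-(gene, group) indicators, gene-level
#' `(phi_i, p_i)` and counts exactly following the generative process: a
#' normal base measure over fold-change atoms, a global DP draw over it,
#' per-group DP draws over the global measure, log-normal dispersions and
#' `Beta(0.5, 0.5)`-distributed `p_i` setting `mu_i = (1-p)/(p phi)`.
#' The true indicator matrix is recorded for recovery tests; `fixed_atoms`
#' / `fixed_z` allow a controlled truth (e.g. a known number of
#' fold-change clusters) while keeping the observation model intact.
#'
#' @param n_genes number of genes.
#' @param n_per_group libraries per group (vector of length L >= 2).
#' @param hyper list with `mu_beta`, `s2_beta`, `mu_phi`, `s2_phi`.
#' @param gamma group-level DP concentration(s), recycled to L.
#' @param delta global DP concentration.
#' @param trunc truncation of the stick-breaking representations.
#' @param fixed_atoms optional atom dictionary replacing draws from the
#'   base measure.
#' @param fixed_z optional N x L integer matrix of indicators replacing the
#'   DP draws (requires `fixed_atoms`).
#' @param p_shape Beta parameters of `p_i` (default the model's 0.5, 0.5).
#' @param cf normalisation factors (default all 1).
#' @param seed integer seed.
#' @return list with `counts`, `groups`, and `truth` (list: `z`, `atoms`,
#'   `phi`, `p`, `mu`, `beta` = atoms indexed by z).
#' @export
generate_from_model <- function(n_genes, n_per_group,
                                hyper = list(mu_beta = 0, s2_beta = 1,
                                             mu_phi = -1, s2_phi = 0.25),
                                gamma = 1, delta = 1, trunc = 200,
                                fixed_atoms = NULL, fixed_z = NULL,
                                p_shape = c(0.5, 0.5), cf = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(n_per_group)
  if (L < 2L) stop("need at least two groups")
  gamma <- rep_len(gamma, L)
  M <- sum(n_per_group)
  grp <- rep(seq_len(L), n_per_group)
  if (is.null(cf)) cf <- rep(1, M)

  if (is.null(fixed_z)) {
    atoms <- if (is.null(fixed_atoms))
      rnorm(trunc, hyper$mu_beta, sqrt(hyper$s2_beta)) else fixed_atoms
    K <- length(atoms)
    ## global stick over the atom dictionary
    v <- rbeta(K, 1, delta); v[K] <- 1
    w <- v * cumprod(c(1, 1 - v[-K]))
    z <- matrix(0L, n_genes, L)
    for (l in seq_len(L)) {
      ## group sticks whose atoms are draws from the global measure
      vg <- rbeta(trunc, 1, gamma[l]); vg[trunc] <- 1
      wg <- vg * cumprod(c(1, 1 - vg[-trunc]))
      map <- sample.int(K, trunc, replace = TRUE, prob = w)
      z[, l] <- map[sample.int(trunc, n_genes, replace = TRUE, prob = wg)]
    }
  } else {
    if (is.null(fixed_atoms)) stop("fixed_z requires fixed_atoms")
    atoms <- fixed_atoms
    z <- fixed_z
    storage.mode(z) <- "integer"
    if (any(z < 1L) || any(z > length(atoms)))
      stop("fixed_z refers to atoms outside the dictionary")
  }

  phi <- rlnorm(n_genes, hyper$mu_phi, sqrt(hyper$s2_phi))
  p <- rbeta(n_genes, p_shape[1], p_shape[2])
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  mu <- (1 - p) / (p * phi)
  beta <- matrix(atoms[z], n_genes, L)
  counts <- matrix(0, n_genes, M)
  for (j in seq_len(M))
    counts[, j] <- rnbinom(n_genes, mu = cf[j] * mu * exp(beta[, grp[j]]),
                           size = 1 / phi)
  gene_ids <- sprintf("gene_%0*d", nchar(n_genes), seq_len(n_genes))
  lib_ids <- sprintf("group%d_rep%d", grp,
                     unlist(lapply(n_per_group, seq_len)))
  list(counts = count_matrix(counts, gene_ids, lib_ids),
       groups = group_map(paste0("group", grp), library_ids = lib_ids),
       truth = list(z = z, atoms = atoms, phi = phi, p = p, mu = mu,
                    beta = beta))
}

#' ROC area under the curve for a DE ranking
#'
#' Scores are "ascending = more DE-like" (e.g. posterior probabilities of
#' no differential expression).  The AUC is the probability that a random
#' truly-DE gene scores lower than a random non-DE gene, ties counting one
#' half -- the normalised Mann-Whitney statistic.
#'
#' @param scores numeric vector, smaller = stronger DE evidence.
#' @param is_de logical vector of the simulation truth.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, is_de) {
  is_de <- as.logical(is_de)
  n1 <- sum(is_de); n0 <- sum(!is_de)
  if (n1 == 0L || n0 == 0L)
    stop("need at least one DE and one non-DE gene")
  r <- rank(scores)   # average ranks handle ties as 1/2
  (sum(r[!is_de]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

#' False discovery curve
#'
#' Number of truly non-DE genes among the top-k ranked genes (ascending
#' score), for k = 1..`max_discoveries`.  Ties are broken by the original
#' gene order (stable sort).
#'
#' @inheritParams roc_auc
#' @param max_discoveries number of top ranks to report; clipped to N with
#'   a warning.
#' @return integer vector of cumulative false discovery counts.
#' @export
fd_curve <- function(scores, is_de, max_discoveries = length(scores)) {
  is_de <- as.logical(is_de)
  if (sum(is_de) == 0L || sum(!is_de) == 0L)
    stop("need at least one DE and one non-DE gene")
  if (max_discoveries > length(scores)) {
    warning("max_discoveries exceeds the number of genes; clipping")
    max_discoveries <- length(scores)
  }
  ord <- order(scores)   # stable for ties
  cumsum(!is_de[ord])[seq_len(max_discoveries)]
}

#' Realized false discovery rate of a DE call set
#'
#' The fraction of called genes that are truly non-DE; `NA` (undefined)
#' when no gene was called.
#'
#' @param de a `de_result` from [select_threshold()], or a vector of called
#'   gene identifiers/indices.
#' @param truth the truth data frame from [generate_dataset()] (or a
#'   logical `is_de` vector named by gene).
#' @return fraction in `[0, 1]`, or `NA_real_`.
#' @export
realized_fdr <- function(de, truth) {
  called <- if (inherits(de, "de_result")) de$de_set else de
  if (!length(called)) return(NA_real_)
  if (is.data.frame(truth)) {
    is_de <- setNames(truth$is_de, truth$gene_id)
  } else {
    is_de <- truth
  }
  flags <- is_de[called]
  if (anyNA(flags)) stop("called genes missing from the truth table")
  sum(!flags) / length(flags)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two flat clusterings of the same
#' items; 1 means identical partitions, ~0 the chance level.
#'
#' @param a,b cluster label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expct <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expct) return(1)
  (sij - expct) / (mx - expct)
}
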