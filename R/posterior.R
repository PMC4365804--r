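## Differential expression and similarity summaries computed from stored
## indicator samples.  A gene is "not DE" between two groups exactly when
## its fold-change indicators coincide, so everything here reduces to
## averaging indicator agreement over the chain.

resolve_group <- function(samples, g) {
  if (is.numeric(g)) {
    g <- as.integer(g)
    if (g < 1L || g > length(samples$group_names))
      stop("group index out of range")
    return(g)
  }
  i <- match(g, samples$group_names)
  if (is.na(i))
    stop(sprintf("unknown group '%s'; available groups: %s", g,
                 paste(samples$group_names, collapse = ", ")))
  i
}

#' Posterior probability of no differential expression
#'
#' For every gene, the fraction of stored samples in which its indicator in
#' `group_a` equals its indicator in `group_b`:
#' `pi_i = (1/T) * sum_t 1(z_iA = z_iB)`.  Small values mean strong
#' evidence of differential expression.
#'
#' @param samples a `posterior_samples` object from [run_chain()].
#' @param group_a,group_b group names (or indices) present in the chain.
#' @return named numeric vector of `pi_i` in `[0, 1]`.
#' @export
compute_pi <- function(samples, group_a, group_b) {
  if (!length(samples$z_samples)) stop("no stored samples")
  a <- resolve_group(samples, group_a)
  b <- resolve_group(samples, group_b)
  acc <- 0
  for (z in samples$z_samples) acc <- acc + (z[, a] == z[, b])
  setNames(acc / length(samples$z_samples), samples$gene_ids)
}

#' Conditional false discovery rate at a threshold
#'
#' `FDR(pt) = sum_i pi_i 1(pi_i <= pt) / sum_i 1(pi_i <= pt)`: the mean
#' posterior probability of being a false discovery over the discovery set.
#' By construction the value never exceeds the threshold.  An empty
#' discovery set gives `NA` (undefined).
#'
#' @param pi numeric vector of per-gene posterior probabilities in `[0, 1]`.
#' @param threshold the probability cutoff defining the discovery set.
#' @return the conditional FDR, or `NA_real_` for an empty set.
#' @export
fdr_at <- function(pi, threshold) {
  if (any(pi < 0 | pi > 1)) stop("pi values must lie in [0, 1]")
  sel <- pi <= threshold
  if (!any(sel)) return(NA_real_)
  sum(pi[sel]) / sum(sel)
}

#' Conditional FDR curve over all attainable thresholds
#'
#' @inheritParams fdr_at
#' @param thresholds candidate cutoffs; defaults to the sorted unique
#'   observed `pi` values (the FDR is a step function of the threshold, so
#'   these are the only values that matter).
#' @return data frame with `threshold`, `n_discoveries`, `fdr`.
#' @export
fdr_curve <- function(pi, thresholds = sort(unique(pi))) {
  if (any(pi < 0 | pi > 1)) stop("pi values must lie in [0, 1]")
  data.frame(threshold = thresholds,
             n_discoveries = vapply(thresholds,
                                    function(t) sum(pi <= t), integer(1)),
             fdr = vapply(thresholds, function(t) fdr_at(pi, t),
                          numeric(1)))
}

#' Select the DE set at a target conditional FDR
#'
#' Finds the largest attainable threshold (swept over the observed `pi`
#' values) whose conditional FDR does not exceed `target_fdr`, and returns
#' the inclusive discovery set `{i : pi_i <= threshold}`.  Ties at the
#' threshold are all included.  An empty set is possible and is reported
#' with `threshold = NA` and undefined FDR.
#'
#' @inheritParams fdr_at
#' @param target_fdr target conditional FDR in (0, 1).
#' @param gene_ids optional identifiers for the genes (defaults to
#'   `names(pi)` or indices).
#' @return a list of class `de_result`: `pi`, `threshold`, `target_fdr`,
#'   `de_set` (gene ids), `fdr_at_threshold`.
#' @export
select_threshold <- function(pi, target_fdr, gene_ids = NULL) {
  if (target_fdr <= 0 || target_fdr >= 1)
    stop("target_fdr must lie strictly inside (0, 1)")
  if (any(pi < 0 | pi > 1)) stop("pi values must lie in [0, 1]")
  if (is.null(gene_ids))
    gene_ids <- if (!is.null(names(pi))) names(pi)
                else as.character(seq_along(pi))
  cand <- sort(unique(pi))
  ok <- vapply(cand, function(t) fdr_at(pi, t) <= target_fdr, logical(1))
  if (any(ok)) {
    thr <- max(cand[ok])
    sel <- pi <= thr
    res <- list(pi = setNames(pi, gene_ids), threshold = thr,
                target_fdr = target_fdr, de_set = gene_ids[sel],
                fdr_at_threshold = fdr_at(pi, thr))
  } else {
    res <- list(pi = setNames(pi, gene_ids), threshold = NA_real_,
                target_fdr = target_fdr, de_set = character(0),
                fdr_at_threshold = NA_real_)
  }
  structure(res, class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf(paste0("de_result: %d/%d genes called DE at target FDR %.3g",
                     " (threshold %.4g, attained FDR %.4g)\n"),
              length(x$de_set), length(x$pi), x$target_fdr,
              x$threshold, x$fdr_at_threshold))
  invisible(x)
}

#' Posterior gene similarity matrix
#'
#' `s_ii' = (1/T) sum_t (1/L) sum_l 1(z_il = z_i'l)`: the posterior
#' fraction of (sample, group) slots in which two genes share a fold-change
#' cluster.  Symmetric with unit diagonal.
#'
#' @param samples a `posterior_samples` object.
#' @return an N x N numeric matrix with gene ids as dimnames.
#' @export
gene_similarity <- function(samples) {
  if (!length(samples$z_samples)) stop("no stored samples")
  L <- length(samples$group_names)
  N <- length(samples$gene_ids)
  acc <- matrix(0, N, N)
  for (z in samples$z_samples)
    for (l in seq_len(L))
      acc <- acc + outer(z[, l], z[, l], "==")
  s <- acc / (L * length(samples$z_samples))
  dimnames(s) <- list(samples$gene_ids, samples$gene_ids)
  s
}

#' Posterior group similarity matrix
#'
#' Entry (l, l') is the mean over genes of the posterior probability of no
#' differential expression between groups l and l'
#' (`sum_i pi_i / N` evaluated for that pair); the diagonal is 1.
#'
#' @param samples a `posterior_samples` object.
#' @return an L x L symmetric matrix with group names as dimnames.
#' @export
group_similarity <- function(samples) {
  L <- length(samples$group_names)
  if (L < 2L) stop("need at least two groups")
  s <- diag(1, L)
  for (l in seq_len(L - 1L))
    for (m in seq.int(l + 1L, L)) {
      s[l, m] <- s[m, l] <- mean(compute_pi(samples, l, m))
    }
  dimnames(s) <- list(samples$group_names, samples$group_names)
  s
}

#' Hierarchical clustering of sample groups
#'
#' Agglomerative average-linkage clustering of the rows of the group
#' similarity matrix under the Euclidean metric, as used to relate sample
#' groups (e.g. tissues) by their shared expression clusters.
#'
#' @param sim a group similarity matrix from [group_similarity()].
#' @return an `stats::hclust` tree; convert with [as_newick()] for export.
#' @export
cluster_groups <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) < 2L)
    stop("need a similarity matrix over at least two groups")
  hclust(dist(sim), method = "average")
}

#' Consensus gene clusters from the posterior similarity matrix
#'
#' Average-linkage clustering of the dissimilarities `1 - s`, cut at the
#' given height.  The default cutoff of 0.5 optimises the expectation of
#' Binder's loss: genes end up together when their posterior co-clustering
#' probability exceeds one half.
#'
#' @param sim gene similarity matrix from [gene_similarity()].
#' @param cutoff cut height in (0, 1]; default 0.5.
#' @return named integer vector of flat cluster labels.
#' @export
consensus_clusters <- function(sim, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  hc <- hclust(as.dist(1 - sim), method = "average")
  cutree(hc, h = cutoff)
}
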