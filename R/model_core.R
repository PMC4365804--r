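## Core probabilistic model: domain types and deterministic math.
##
## The observation model for counts is negative binomial in
## (mean, dispersion) form: y ~ NB(m, phi) with Var(y) = m + phi * m^2 and
## log m_ij = log c_j + log mu_i + beta_{i,lambda(j)}.  phi = 0 is handled
## as an explicit Poisson branch throughout (never by division).

#' Count matrix of digital gene expression data
#'
#' Bundles a genes-by-libraries matrix of raw (unnormalised) read counts
#' with unique gene and library identifiers.  Counts must be non-negative
#' integers; at least one gene and two libraries are required.
#'
#' @param counts numeric matrix of non-negative integer counts
#'   (genes in rows, libraries in columns).
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(counts)`.
#' @param library_ids character vector of unique library identifiers;
#'   defaults to `colnames(counts)`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `gene_ids`, `library_ids`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         library_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(library_ids)) library_ids <- paste0("lib_", seq_len(ncol(counts)))
  if (nrow(counts) < 1L) stop("count matrix needs at least one gene")
  if (ncol(counts) < 2L) stop("count matrix needs at least two libraries")
  if (anyNA(counts) || !is.numeric(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers (raw read counts, not normalised values)")
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique")
  if (anyDuplicated(library_ids)) stop("library identifiers must be unique")
  if (length(gene_ids) != nrow(counts) || length(library_ids) != ncol(counts))
    stop("identifier lengths do not match the count matrix dimensions")
  counts <- round(counts)
  dimnames(counts) <- list(gene_ids, library_ids)
  structure(list(counts = counts, gene_ids = as.character(gene_ids),
                 library_ids = as.character(library_ids)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Drop genes with zero total count
#'
#' The sampler refuses rows whose counts sum to zero (nothing constrains
#' their parameters); this removes them, mirroring the usual preprocessing
#' of digital expression matrices.
#'
#' @param x a [count_matrix()].
#' @return a [count_matrix()] restricted to genes with positive total
#'   count, with a logical attribute `kept` (length N of the input) for
#'   subsetting companion tables.
#' @export
drop_zero_rows <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rowSums(x$counts) > 0
  out <- count_matrix(x$counts[keep, , drop = FALSE],
                      x$gene_ids[keep], x$library_ids)
  attr(out, "kept") <- keep
  out
}

#' Library-to-group assignment
#'
#' Maps each library to one of `L` sample groups (tissues, conditions, ...).
#' Every group must contain at least one library and `2 <= L <= M`.
#'
#' @param assignment factor, character or integer vector of length M giving
#'   the group of each library, in library order.
#' @param library_ids optional library identifiers (length M).
#' @return An object of class `group_map` with elements `group`
#'   (integer codes 1..L), `group_names`, `n_groups`, `library_ids`.
#' @export
group_map <- function(assignment, library_ids = names(assignment)) {
  f <- if (is.factor(assignment)) assignment else
    factor(assignment, levels = unique(assignment))
  group <- as.integer(f)
  L <- nlevels(f)
  M <- length(group)
  if (anyNA(group)) stop("group assignment contains missing values")
  if (L < 2L) stop("at least two sample groups are required")
  if (L > M) stop("more groups than libraries")
  if (!all(tabulate(group, L) >= 1L)) stop("every group needs >= 1 library")
  structure(list(group = group, group_names = levels(f), n_groups = L,
                 library_ids = library_ids),
            class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  cat(sprintf("group_map: %d libraries in %d groups (%s)\n",
              length(x$group), x$n_groups,
              paste(x$group_names, collapse = ", ")))
  invisible(x)
}

#' Per-library normalisation factors
#'
#' @param c positive numeric vector, one factor per library.
#' @param library_ids optional library identifiers.
#' @return An object of class `norm_factors` (a numeric vector).
#' @export
norm_factors <- function(c, library_ids = names(c)) {
  c <- as.numeric(c)
  if (anyNA(c) || any(c <= 0) || any(!is.finite(c)))
    stop("normalisation factors must be finite and strictly positive")
  names(c) <- library_ids
  structure(c, class = "norm_factors")
}

#' Gene-level negative binomial parameters
#'
#' Holds the per-gene dispersion (on the log scale) and the Beta-distributed
#' success probability `p` that reparameterises the mean expression level as
#' `mu = (1 - p) / (p * phi)`.  `mean_level` is always derived, never free.
#'
#' @param log_dispersion numeric vector, log(phi) per gene.
#' @param p numeric vector in (0,1) per gene.
#' @return A list of class `gene_params` with `log_dispersion`, `p` and the
#'   derived `mean_level`.
#' @export
gene_params <- function(log_dispersion, p) {
  if (length(log_dispersion) != length(p))
    stop("log_dispersion and p must have equal length")
  if (any(!is.finite(log_dispersion))) stop("log_dispersion must be finite")
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  phi <- exp(log_dispersion)
  structure(list(log_dispersion = log_dispersion, p = p,
                 mean_level = (1 - p) / (p * phi)),
            class = "gene_params")
}

#' Negative binomial log-pmf in mean-dispersion form
#'
#' `Var(y) = m + phi * m^2`; `phi = 0` is evaluated on an explicit Poisson
#' branch so the function is continuous in `phi` at zero.  Computation is in
#' log space throughout and survives counts far above 1e4.
#'
#' @param y non-negative integer count(s).
#' @param m positive mean(s).
#' @param phi non-negative dispersion(s).
#' @return log-probability, vectorised over the arguments.
#' @examples
#' nb_logpmf(0, 5, 0.5)   # == -2 * log(3.5)
#' nb_logpmf(3, 2, 0)     # exact Poisson limit
#' @export
nb_logpmf <- function(y, m, phi) {
  n <- max(length(y), length(m), length(phi))
  y <- rep_len(y, n); m <- rep_len(m, n); phi <- rep_len(phi, n)
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("y must be a non-negative integer")
  if (any(m <= 0) || any(!is.finite(m))) stop("mean m must be positive")
  if (any(phi < 0)) stop("dispersion phi must be non-negative")
  out <- numeric(n)
  pois <- phi == 0
  if (any(pois)) out[pois] <- dpois(y[pois], lambda = m[pois], log = TRUE)
  if (any(!pois))
    out[!pois] <- dnbinom(y[!pois], mu = m[!pois], size = 1 / phi[!pois],
                          log = TRUE)
  out
}

#' Negative binomial variance
#'
#' @inheritParams nb_logpmf
#' @return `m + phi * m^2`; equals `m` when `phi = 0` (Poisson).
#' @export
nb_variance <- function(m, phi) {
  if (any(m <= 0)) stop("mean m must be positive")
  if (any(phi < 0)) stop("dispersion phi must be non-negative")
  m + phi * m^2
}

#' Mean expression level from the Beta-reparameterised success probability
#'
#' `mu = (1 - p) / (p * phi)`, the mean of a negative binomial with size
#' `1/phi` and success probability `p`.  Strictly decreasing in both
#' arguments.
#'
#' @param p success probability in (0, 1).
#' @param phi positive dispersion.
#' @return the mean level `mu > 0`.
#' @export
mean_from_p <- function(p, phi) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  if (any(phi <= 0)) stop("phi must be strictly positive here")
  (1 - p) / (p * phi)
}

#' Inverse of [mean_from_p()]
#'
#' @param mu positive mean level.
#' @param phi positive dispersion.
#' @return `p = 1 / (1 + phi * mu)`.
#' @export
p_from_mean <- function(mu, phi) {
  if (any(mu <= 0)) stop("mu must be strictly positive")
  if (any(phi <= 0)) stop("phi must be strictly positive here")
  1 / (1 + phi * mu)
}

#' Cell mean of the observation model
#'
#' `log m_ij = log c_j + log mu_i + beta_il`: normalisation factor times
#' gene mean level times exponentiated log-fold-change.  A fold-change of 0
#' means no change (`m = c * mu`).
#'
#' @param c_j positive normalisation factor.
#' @param mu_i positive mean expression level.
#' @param beta log-fold-change (any real).
#' @return the negative binomial mean `m_ij`.
#' @export
model_mean <- function(c_j, mu_i, beta) {
  if (any(c_j <= 0)) stop("normalisation factor must be positive")
  if (any(mu_i <= 0)) stop("mean level must be positive")
  c_j * mu_i * exp(beta)
}
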