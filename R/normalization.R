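## Median-of-ratios library normalisation (the DESeq scheme), with a
## user-override path.

#' Median-of-ratios size factors
#'
#' For each library j, `c_j` is the median over reference genes of
#' `y_ij / g_i`, where `g_i` is the geometric mean of gene i across all
#' libraries and the reference set contains the genes with strictly
#' positive counts in every library.  Genes containing a zero are excluded
#' from the reference set entirely.  Factors are deliberately not rescaled
#' to unit geometric mean: they only ever enter multiplicatively with the
#' gene mean levels, so any global rescaling is absorbed.
#'
#' @param x a [count_matrix()] or plain count matrix.
#' @return [norm_factors()] of length M, named by library.
#' @examples
#' m <- matrix(c(2, 6, 4, 12), nrow = 2)  # factors 1/sqrt(2), sqrt(2)
#' size_factors(count_matrix(m))
#' @export
size_factors <- function(x) {
  y <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  ref <- rowSums(y > 0) == ncol(y)
  if (!any(ref))
    stop("no gene has strictly positive counts in every library; ",
         "median-of-ratios normalisation is undefined -- supply ",
         "user-defined factors via apply_user_factors()")
  lg <- log(y[ref, , drop = FALSE])
  ratios <- exp(lg - rowMeans(lg))  # y_ij / geometric mean of gene i
  norm_factors(apply(ratios, 2, median), library_ids = colnames(y))
}

#' Use caller-supplied normalisation factors
#'
#' Bypasses [size_factors()]; values are validated and passed through
#' unchanged so externally computed library sizes (or factors from another
#' tool) can drive the model.
#'
#' @param factors positive numeric vector, one value per library, in the
#'   column order of the count matrix.
#' @param x a [count_matrix()], count matrix, or integer library count used
#'   only to check the length.
#' @return [norm_factors()].
#' @export
apply_user_factors <- function(factors, x = length(factors)) {
  m <- if (inherits(x, "count_matrix")) ncol(x$counts)
       else if (is.matrix(x)) ncol(x) else as.integer(x)
  if (length(factors) != m)
    stop(sprintf("expected %d normalisation factors, got %d",
                 m, length(factors)))
  ids <- if (inherits(x, "count_matrix")) x$library_ids else names(factors)
  norm_factors(as.numeric(factors), library_ids = ids)
}
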