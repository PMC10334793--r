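#' Median-of-ratios size factors
#'
#' Computes per-sample size factors with the median-of-ratios method
#' (as defined by DESeq2, which this function delegates to): each sample's
#' factor is the median over genes of `count / geometric-mean-across-samples`,
#' where genes containing a zero anywhere (infinite log geometric mean) are
#' excluded from the median.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @return named positive numeric vector, one factor per sample.
#' @examples
#' m <- matrix(c(10, 100, 4, 20, 200, 8), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("A", "B")))
#' computeSizeFactors(m)  # (1/sqrt(2), sqrt(2))
#' @importFrom DESeq2 estimateSizeFactorsForMatrix
#' @export
computeSizeFactors <- function(counts) {
  check_counts_matrix(counts)
  if (any(colSums(counts) == 0))
    stop("every sample needs at least one nonzero count")
  sf <- tryCatch(
    estimateSizeFactorsForMatrix(counts),
    error = function(e) stop(
      "no gene has nonzero counts in all samples; the gene-wise median of ",
      "ratios is undefined. Consider a pseudo-reference (e.g. add genes ",
      "detected everywhere, or use poscounts-style factors).",
      call. = FALSE))
  stats::setNames(as.numeric(sf), colnames(counts))
}

#' Normalize counts and log-transform
#'
#' Divides each sample by its size factor and applies `log2(x + 1)`.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors optional named per-sample factors; computed with
#'   [computeSizeFactors()] when missing. Compute factors on the *full*
#'   matrix before subsetting to a gene panel (e.g. splicing factors): the
#'   whole-transcriptome factors are the statistically standard choice.
#' @return a [NormalizedExpression-class].
#' @export
normalizeCounts <- function(counts, size_factors = NULL) {
  check_counts_matrix(counts)
  if (is.null(size_factors)) size_factors <- computeSizeFactors(counts)
  if (length(size_factors) != ncol(counts))
    stop("need one size factor per sample")
  if (any(!is.finite(size_factors)) || any(size_factors <= 0))
    stop("size factors must be finite and > 0")
  vals <- log2(sweep(counts, 2, size_factors, "/") + 1)
  new("NormalizedExpression", values = vals,
      sizeFactors = stats::setNames(as.numeric(size_factors),
                                    colnames(counts)))
}

# ssGSEA-style running-sum score for one sample: genes ranked by
# expression, gene-set increments weighted by |rank statistic|^tau, score =
# sum of the running-sum differences (the integral form, not the max).
.rank_ssgsea_one <- function(v, inset, tau = 0.25) {
  ord <- order(v, decreasing = TRUE)
  inset <- inset[ord]
  w <- abs(rank(v)[ord])^tau
  p_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
  p_out <- cumsum(!inset) / sum(!inset)
  sum(p_in - p_out)
}

#' Per-sample pathway activity score
#'
#' Scores each sample for the coordinated expression of a hallmark gene set.
#' The default `"mean-z"` method z-scores every gene-set gene across the
#' scoring samples (sample standard deviation, n-1 denominator; genes with
#' zero variance contribute 0) and averages the z-scores per sample, so
#' scores have mean 0 across the scoring group. The `"rank-ssgsea"`
#' alternative computes a single-sample enrichment statistic from a
#' weighted Kolmogorov-Smirnov running sum over each sample's expression
#' ranks. Downstream correlation analysis is method-agnostic.
#'
#' Score within one cohort at a time (the disease spectrum of a single
#' tumor type): pass that cohort's samples via `samples`.
#'
#' @param expr a [NormalizedExpression-class].
#' @param genes character vector of gene-set gene identifiers.
#' @param genesetName label stored in the result.
#' @param samples optional sample subset defining the scoring group
#'   (default: all samples of `expr`).
#' @param method `"mean-z"` (default) or `"rank-ssgsea"`.
#' @param minGenes minimum gene-set genes that must be present (default 5).
#' @return an [ActivityScores-class].
#' @export
pathwayScore <- function(expr, genes, genesetName = "geneset",
                         samples = NULL,
                         method = c("mean-z", "rank-ssgsea"),
                         minGenes = 5L) {
  stopifnot(is(expr, "NormalizedExpression"))
  method <- match.arg(method)
  vals <- exprValues(expr)
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(vals))
    if (length(missing_s))
      stop("samples absent from expression matrix: ",
           paste(missing_s, collapse = ", "))
    vals <- vals[, samples, drop = FALSE]
  }
  genes <- unique(genes)
  present <- intersect(genes, rownames(vals))
  absent <- setdiff(genes, present)
  if (length(present) < minGenes)
    stop(sprintf(
      "only %d of %d gene-set genes present (floor %d); missing: %s",
      length(present), length(genes), minGenes,
      paste(absent, collapse = ", ")))
  if (length(absent))
    warning(sprintf("%d gene-set gene(s) absent from the matrix: %s",
                    length(absent), paste(absent, collapse = ", ")))
  sub <- vals[present, , drop = FALSE]
  sc <- switch(method,
    "mean-z" = {
      mu <- rowMeans(sub)
      sdev <- apply(sub, 1, stats::sd)
      z <- (sub - mu) / ifelse(sdev == 0, Inf, sdev)  # zero-variance -> 0
      colMeans(z)
    },
    "rank-ssgsea" = {
      inset <- rownames(vals) %in% present
      apply(vals, 2, .rank_ssgsea_one, inset = inset)
    })
  new("ActivityScores", sampleIds = colnames(sub), scores = as.numeric(sc),
      genesetName = genesetName, nGenesUsed = length(present),
      method = method)
}
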