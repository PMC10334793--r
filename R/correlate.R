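#' Pearson correlation with two-sided p-value
#'
#' Standard Pearson r after pairwise deletion of missing pairs, with the
#' two-sided p-value from `t = r * sqrt((n-2)/(1-r^2))` against Student's t
#' with n-2 degrees of freedom (`p = 0` when `|r| = 1`). Zero variance in
#' either variable, or fewer than 3 complete pairs, yields an unevaluable
#' record rather than an error.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n`, `evaluable`.
#' @examples
#' pearsonCorTest(1:5, c(2, 1, 4, 3, 5))  # r = 0.8, p ~ 0.104
#' @export
pearsonCorTest <- function(x, y) {
  stopifnot(length(x) == length(y))
  pearson_r_p(as.numeric(x), as.numeric(y))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' `adj_(i) = min over j >= i of (m/j) * p_(j)`, capped at 1 and returned
#' in input order. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0,1\] (`NA` passed through).
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Correlate exon inclusion with pathway activity, per cohort
#'
#' For every (event, cohort) pair, computes the Pearson correlation of the
#' event's PSI values with the per-sample activity score across that
#' cohort's samples, with pairwise deletion of missing PSI. P-values are
#' BH-adjusted *within* each cohort across events (per-cohort families;
#' pass `adjust = "pooled"` for a single family). Records with fewer than
#' `min_n` complete pairs keep their r but have p and adjusted p withheld
#' (`NA`) and are flagged unevaluable.
#'
#' @param psi a [PsiExperiment-class].
#' @param activity an [ActivityScores-class] (or several concatenated via a
#'   named numeric vector of scores).
#' @param meta `data.frame` with columns `sample` and the cohort column.
#' @param cohort_col name of the cohort column in `meta` (default
#'   `"cohort"`).
#' @param min_n minimum complete pairs for an evaluable record (default 10).
#' @param adjust `"per-cohort"` (default) or `"pooled"` BH family.
#' @return `data.frame` with columns `target_id`, `cohort`, `n`, `r`,
#'   `p_value`, `p_adj`, `direction` (sign of r), `evaluable`.
#' @export
correlatePsiWithActivity <- function(psi, activity, meta,
                                     cohort_col = "cohort", min_n = 10L,
                                     adjust = c("per-cohort", "pooled")) {
  stopifnot(is(psi, "PsiExperiment"))
  .correlate_matrix(psiValues(psi), activity, meta, cohort_col, min_n,
                    match.arg(adjust))
}

#' Correlate gene expression with pathway activity, per cohort
#'
#' As [correlatePsiWithActivity()], with normalized log expression of the
#' requested genes (e.g. a splicing-factor panel) in place of PSI.
#'
#' @param expr a [NormalizedExpression-class].
#' @param genes character vector of gene ids to correlate (default: all).
#' @inheritParams correlatePsiWithActivity
#' @return `data.frame` as in [correlatePsiWithActivity()] with genes as
#'   `target_id`.
#' @export
correlateExpressionWithActivity <- function(expr, genes = NULL, activity,
                                            meta, cohort_col = "cohort",
                                            min_n = 10L,
                                            adjust = c("per-cohort",
                                                       "pooled")) {
  stopifnot(is(expr, "NormalizedExpression"))
  vals <- exprValues(expr)
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(vals))
    if (length(missing_g))
      stop("genes absent from expression matrix: ",
           paste(missing_g, collapse = ", "))
    vals <- vals[genes, , drop = FALSE]
  }
  .correlate_matrix(vals, activity, meta, cohort_col, min_n,
                    match.arg(adjust))
}

.correlate_matrix <- function(m, activity, meta, cohort_col, min_n,
                              adjust) {
  sc <- if (is(activity, "ActivityScores")) scores(activity)
        else activity
  if (is.null(names(sc))) stop("activity scores must be named by sample")
  if (!cohort_col %in% colnames(meta))
    stop("metadata lacks column '", cohort_col, "'")
  shared <- intersect(intersect(colnames(m), names(sc)), meta$sample)
  if (!length(shared))
    stop("no shared samples between the matrix, scores, and metadata")
  cohorts <- split(shared,
                   meta[[cohort_col]][match(shared, meta$sample)])
  out <- lapply(names(cohorts), function(co) {
    ss <- cohorts[[co]]
    stats_df <- row_pearson(m[, ss, drop = FALSE], sc[ss])
    ok <- stats_df$evaluable & stats_df$n >= min_n
    stats_df$p_value[!ok] <- NA_real_
    data.frame(target_id = rownames(m), cohort = co,
               n = stats_df$n, r = stats_df$r,
               p_value = stats_df$p_value,
               p_adj = NA_real_,
               direction = sign(stats_df$r),
               evaluable = ok, stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  if (adjust == "per-cohort") {
    for (co in unique(res$cohort)) {
      idx <- which(res$cohort == co & res$evaluable)
      res$p_adj[idx] <- bhAdjust(res$p_value[idx])
    }
  } else {
    idx <- which(res$evaluable)
    res$p_adj[idx] <- bhAdjust(res$p_value[idx])
  }
  res
}

#' Permutation p-value for a Pearson correlation
#'
#' Permutes `y` `B` times and reports
#' `p = (1 + #permutations with |r_perm| >= |r_obs|) / (B + 1)`, a
#' distribution-free alternative to the t-based p-value.
#'
#' @param x,y numeric vectors.
#' @param B number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `p`, `r_obs`, `B`, `evaluable`.
#' @export
permutationPvalue <- function(x, y, B = 1000L, seed = 1L) {
  stopifnot(B >= 100L, length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(p = NA_real_, r_obs = NA_real_, B = B, evaluable = FALSE))
  r_obs <- stats::cor(x, y)
  with_rng(seed, {
    hits <- sum(vapply(seq_len(B), function(i)
      abs(stats::cor(x, sample(y))) >= abs(r_obs), logical(1)))
    list(p = (1 + hits) / (B + 1), r_obs = r_obs, B = B, evaluable = TRUE)
  })
}
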