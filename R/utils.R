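# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# (or removing) the caller's .Random.seed afterwards. Keeps every simulator
# reproducible without touching global RNG state.
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stop unless x is a validated counts matrix: non-negative integers with
# unique, non-missing dimnames.
check_counts_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in counts matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  invisible(counts)
}

# Two-sided Pearson correlation with the Student-t p-value. Returns
# list(r, p, n, evaluable). Zero variance or n < 3 gives an unevaluable
# record rather than an error: the correlation engine must survive
# constant-PSI events.
pearson_r_p <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, evaluable = FALSE))
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n, evaluable = TRUE)
}

# Row-wise Pearson of each row of `m` against vector `s`, with pairwise
# deletion of missing cells. Vectorized for cohort-scale matrices.
row_pearson <- function(m, s) {
  stopifnot(ncol(m) == length(s))
  ok <- !is.na(m)
  n <- rowSums(ok)
  r <- suppressWarnings(as.vector(stats::cor(t(m), s,
                                             use = "pairwise.complete.obs")))
  evaluable <- n >= 3 & !is.na(r)
  p <- rep(NA_real_, nrow(m))
  idx <- which(evaluable)
  if (length(idx)) {
    ri <- r[idx]; ni <- n[idx]
    p[idx] <- ifelse(abs(ri) >= 1, 0,
                     2 * stats::pt(-abs(ri * sqrt((ni - 2) / (1 - ri^2))),
                                   df = ni - 2))
  }
  data.frame(r = r, p_value = p, n = n, evaluable = evaluable)
}
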