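# Fixtures built in code: a tiny SE event table, writers for the rMATS JC
# dialect, and independent oracles used against the package's
# implementations.

make_event_frame <- function(n = 3L) {
  origin <- (seq_len(n) - 1L) * 1000L
  data.frame(
    geneId = sprintf("ENSG%03d", seq_len(n)),
    geneSymbol = sprintf("GENE%03d", seq_len(n)),
    chrom = "chr11", strand = rep(c("+", "-"), length.out = n),
    exonStart = origin + 100L, exonEnd = origin + 182L,  # 82-nt exon
    upstreamES = origin + 10L, upstreamEE = origin + 60L,
    downstreamES = origin + 300L, downstreamEE = origin + 380L,
    incFormLen = 198L, skipFormLen = 99L,
    row.names = sprintf("EV%03d", seq_len(n)),
    stringsAsFactors = FALSE)
}

make_toy_ses <- function(ijc, sjc, condition = NULL, genome = "hg38") {
  ev <- make_event_frame(nrow(ijc))
  cd <- if (!is.null(condition))
    S4Vectors::DataFrame(condition = condition) else NULL
  SeEventSet(ijc, sjc, ev, colData = cd, genome = genome)
}

# Write a dialect TSV by hand (independent of writeSeTable). IncLevel
# columns are filled from `inc_level1/2` strings supplied by the caller.
write_se_fixture <- function(path, ids, ijc1, sjc1, ijc2, sjc2,
                             inc_form = 198L, skip_form = 99L,
                             inc_level1 = NULL, inc_level2 = NULL) {
  n <- length(ids)
  ev <- make_event_frame(n)
  header <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
              "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
              "downstreamES", "downstreamEE",
              "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
              "IncFormLen", "SkipFormLen")
  if (!is.null(inc_level1)) header <- c(header, "IncLevel1", "IncLevel2")
  rows <- vapply(seq_len(n), function(i) {
    f <- c(ids[i], ev$geneId[i], ev$geneSymbol[i], ev$chrom[i], ev$strand[i],
           ev$exonStart[i], ev$exonEnd[i], ev$upstreamES[i], ev$upstreamEE[i],
           ev$downstreamES[i], ev$downstreamEE[i],
           ijc1[i], sjc1[i], ijc2[i], sjc2[i], inc_form, skip_form)
    if (!is.null(inc_level1)) f <- c(f, inc_level1[i], inc_level2[i])
    paste(f, collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}

# ---- independent oracles ----

# Median-of-ratios by the definition: geometric mean per gene across
# samples; per-sample median of count/geomean over genes with no zero.
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(x) all(x > 0))
  gm <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
  apply(counts[keep, , drop = FALSE], 2, function(col) median(col / gm))
}

# BH step-up directly from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m))
    adj_sorted[i] <- min(1, min((m / seq(i, m)) * sort(p)[seq(i, m)]))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Exact hypergeometric upper tail by enumeration of choose() terms.
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
}

# Maximal G-runs via regex.
oracle_g_runs <- function(seq, min_len = 3) {
  m <- gregexpr(sprintf("G{%d,}", min_len), seq)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + len, length = len)
}

# Brute-force two-group binomial LRT over a psi grid.
oracle_lrt <- function(I1, S1, I2, S2, lI = 1, lS = 1,
                       grid = seq(1e-4, 1 - 1e-4, by = 1e-4)) {
  ll <- function(I, S, psi) {
    q <- psi * lI / (psi * lI + (1 - psi) * lS)
    I * log(q) + S * log(1 - q)
  }
  ll1 <- max(ll(I1, S1, grid)) + max(ll(I2, S2, grid))
  ll0 <- max(ll(I1 + I2, S1 + S2, grid))
  2 * (ll1 - ll0)
}
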