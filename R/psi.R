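#' Percent spliced in from junction counts
#'
#' Length-normalized inclusion ratio of a cassette exon:
#' `psi = (I/lI) / (I/lI + S/lS)` with inclusion junction count `I`,
#' skipping junction count `S`, and effective form lengths `lI`, `lS`.
#' Missing (`NA`) where `I + S = 0` or either count is missing.
#'
#' @param I,S inclusion and skipping junction counts (vectors or matrices
#'   of matching shape; `NA` allowed).
#' @param lI,lS effective inclusion and skipping form lengths (>= 1),
#'   recycled along events (rows, for matrix input).
#' @return psi values in \[0,1\] with `NA` for uncovered cells, same shape
#'   as `I`.
#' @examples
#' psiFromCounts(30, 10, lI = 2, lS = 1)  # 0.6
#' @export
psiFromCounts <- function(I, S, lI = 1, lS = 1) {
  if (any(I < 0, na.rm = TRUE) || any(S < 0, na.rm = TRUE))
    stop("junction counts must be >= 0")
  if (any(lI < 1) || any(lS < 1))
    stop("effective form lengths must be >= 1")
  ni <- if (is.matrix(I)) I / lI else I / rep_len(lI, length(I))
  ns <- if (is.matrix(S)) S / lS else S / rep_len(lS, length(S))
  psi <- ni / (ni + ns)
  psi[!is.na(I) & !is.na(S) & (I + S) == 0] <- NA_real_
  psi
}

#' Percent spliced in from RT-PCR band intensities
#'
#' `100 * inclusion / (inclusion + skip)`, the semiquantitative RT-PCR
#' analogue of the junction-count PSI.
#'
#' @param inclusion_intensity,skip_intensity non-negative band intensities,
#'   not both zero.
#' @return inclusion percentage in \[0, 100\].
#' @export
psiFromBandIntensities <- function(inclusion_intensity, skip_intensity) {
  if (any(inclusion_intensity < 0) || any(skip_intensity < 0))
    stop("band intensities must be >= 0")
  if (any(inclusion_intensity + skip_intensity == 0))
    stop("both band intensities are zero; PSI undefined")
  100 * inclusion_intensity / (inclusion_intensity + skip_intensity)
}

#' Build a PSI matrix from an event set
#'
#' Applies [psiFromCounts()] elementwise and records total junction reads.
#'
#' @param ses an [SeEventSet-class].
#' @return a [PsiExperiment-class] with assays `psi` and `total`; row and
#'   column annotation are carried over from `ses`.
#' @export
buildPsiMatrix <- function(ses) {
  stopifnot(is(ses, "SeEventSet"))
  rd <- rowData(ses)
  psi <- psiFromCounts(ijc(ses), sjc(ses), rd$incFormLen, rd$skipFormLen)
  tot <- ijc(ses) + sjc(ses)
  se <- SummarizedExperiment(assays = list(psi = psi, total = tot),
                             rowData = rd, colData = colData(ses))
  metadata(se) <- metadata(ses)
  new("PsiExperiment", se)
}

# Binomial log-likelihood of inclusion reads at read-level probability q,
# with 0*log(0) = 0.
.binom_ll <- function(I, S, q) {
  ll <- numeric(length(I))
  ll <- ll + ifelse(I > 0, I * log(q), 0) + ifelse(S > 0, S * log(1 - q), 0)
  ll
}

#' Two-group differential splicing test
#'
#' Pools replicate junction counts within each group and performs a
#' likelihood-ratio test of equal inclusion levels. Inclusion reads are
#' modeled as binomial draws from the total junction reads with read-level
#' probability `q(psi) = psi*lI / (psi*lI + (1-psi)*lS)`; because `q` is
#' monotone in `psi`, the per-group maximum-likelihood inclusion level is
#' [psiFromCounts()] applied to the pooled counts, and the null MLE pools
#' both groups. The statistic `2*(ll1 - ll0)` is referred to a 1-df
#' chi-square distribution. Benjamini-Hochberg adjustment is applied across
#' all tested events. This pooled test is an approximation to hierarchical
#' replicate models: replicates are summed, not modeled, and missing (`NA`)
#' replicate counts are dropped from pooling, never imputed.
#'
#' @param ses an [SeEventSet-class].
#' @param groups two-level factor/character assigning each sample column to
#'   a group; defaults to `colData(ses)$condition`, falling back to
#'   `colData(ses)$group`. `delta_psi` is group1 - group2 in the order of
#'   the factor levels (alphabetical for character input).
#' @param min_reads,min_abs_dpsi,max_fdr thresholds used for the
#'   `significant` flag, as in [filterSignificantEvents()].
#' @param read_stat how "junction reads per event" is summarized across all
#'   samples for the read filter: `"mean"` (default), `"min"`, or `"sum"`.
#' @return `data.frame` with one row per event: `event_id`, `psi_group1`,
#'   `psi_group2`, `delta_psi`, `mean_junction_reads`, `lrt_stat`,
#'   `p_value`, `fdr`, `significant`, and `tested` (FALSE for events
#'   skipped because one group had zero total junction reads; such events
#'   carry NA statistics and are excluded from the BH family).
#' @examples
#' # pooled 30/70 vs 50/50 with equal form lengths: LRT stat ~ 8.446
#' ev <- data.frame(geneId = "G", geneSymbol = "G", chrom = "chr1",
#'   strand = "+", exonStart = 0, exonEnd = 82, upstreamES = 0,
#'   upstreamEE = 1, downstreamES = 100, downstreamEE = 101,
#'   incFormLen = 1, skipFormLen = 1)
#' ses <- SeEventSet(matrix(c(30, 50), 1), matrix(c(70, 50), 1), ev,
#'   colData = S4Vectors::DataFrame(condition = c("a", "b")))
#' testDifferentialSplicing(ses)
#' @export
testDifferentialSplicing <- function(ses, groups = NULL, min_reads = 10,
                                     min_abs_dpsi = 0.05, max_fdr = 0.05,
                                     read_stat = c("mean", "min", "sum")) {
  stopifnot(is(ses, "SeEventSet"))
  read_stat <- match.arg(read_stat)
  if (is.null(groups)) {
    groups <- colData(ses)$condition
    if (is.null(groups)) groups <- colData(ses)$group
  }
  if (is.null(groups))
    stop("no group assignment found; supply 'groups'")
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required, got: ",
         paste(levels(groups), collapse = ", "))
  if (any(table(groups) < 1L)) stop("each group needs >= 1 sample")
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  I <- ijc(ses); S <- sjc(ses)
  rd <- rowData(ses)
  lI <- rd$incFormLen; lS <- rd$skipFormLen
  I1 <- rowSums(I[, g1, drop = FALSE], na.rm = TRUE)
  S1 <- rowSums(S[, g1, drop = FALSE], na.rm = TRUE)
  I2 <- rowSums(I[, g2, drop = FALSE], na.rm = TRUE)
  S2 <- rowSums(S[, g2, drop = FALSE], na.rm = TRUE)
  tested <- (I1 + S1) > 0 & (I2 + S2) > 0
  psi1 <- psiFromCounts(I1, S1, lI, lS)
  psi2 <- psiFromCounts(I2, S2, lI, lS)
  q1 <- I1 / (I1 + S1); q2 <- I2 / (I2 + S2)
  q0 <- (I1 + I2) / (I1 + S1 + I2 + S2)
  lrt <- 2 * (.binom_ll(I1, S1, q1) + .binom_ll(I2, S2, q2) -
              .binom_ll(I1 + I2, S1 + S2, q0))
  lrt <- pmax(lrt, 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  lrt[!tested] <- NA_real_; p[!tested] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- bhAdjust(p[tested])
  tot <- I + S
  mjr <- switch(read_stat,
    mean = rowMeans(tot, na.rm = TRUE),
    min = apply(tot, 1, min, na.rm = TRUE),
    sum = rowSums(tot, na.rm = TRUE))
  delta <- psi1 - psi2
  res <- data.frame(
    event_id = rownames(ses),
    psi_group1 = psi1, psi_group2 = psi2, delta_psi = delta,
    mean_junction_reads = mjr, lrt_stat = lrt, p_value = p, fdr = fdr,
    tested = tested, stringsAsFactors = FALSE, row.names = NULL)
  res$significant <- res$tested &
    res$mean_junction_reads > min_reads &
    abs(res$delta_psi) > min_abs_dpsi &
    res$fdr < max_fdr
  res$significant[is.na(res$significant)] <- FALSE
  if (any(!tested))
    attr(res, "skipped") <- rownames(ses)[!tested]
  res
}

#' Filter differential-splicing records to significant events
#'
#' Keeps events with junction reads per event strictly greater than
#' `min_reads`, `|delta PSI|` strictly greater than `min_abs_dpsi`, and FDR
#' strictly below `max_fdr` (defaults 10 / 0.05 / 0.05).
#'
#' @param records output of [testDifferentialSplicing()].
#' @param min_reads,min_abs_dpsi,max_fdr strict thresholds.
#' @return the subset of `records` passing all three filters.
#' @export
filterSignificantEvents <- function(records, min_reads = 10,
                                    min_abs_dpsi = 0.05, max_fdr = 0.05) {
  stopifnot(all(c("mean_junction_reads", "delta_psi", "fdr") %in%
                colnames(records)))
  keep <- !is.na(records$fdr) &
    records$mean_junction_reads > min_reads &
    abs(records$delta_psi) > min_abs_dpsi &
    records$fdr < max_fdr
  records[keep, , drop = FALSE]
}
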