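#' Coordinate keys for skipped-exon events
#'
#' Builds the identity under which events are matched across rMATS runs:
#' event-id strings are ignored entirely (they differ between runs) and
#' only coordinates matter. The default key is
#' `(chrom, strand, exonStart, exonEnd)`; strict mode appends the upstream
#' and downstream flank coordinates. The sign of any inclusion change plays
#' no role in the key, so events shifting in opposite directions in two
#' comparisons still intersect.
#'
#' @param ses an [SeEventSet-class] (or a `data.frame` with the rowData
#'   coordinate columns).
#' @param events optional character vector of event ids (rownames) to key;
#'   default all.
#' @param mode `"default"` or `"strict"`.
#' @return character vector of keys.
#' @export
eventKeys <- function(ses, events = NULL, mode = c("default", "strict")) {
  mode <- match.arg(mode)
  rd <- if (is(ses, "SeEventSet")) as.data.frame(rowData(ses)) else ses
  if (is(ses, "SeEventSet") && !is.null(events))
    rd <- rd[match(events, rownames(ses)), , drop = FALSE]
  key <- paste(rd$chrom, rd$strand, rd$exonStart, rd$exonEnd, sep = ":")
  if (mode == "strict")
    key <- paste(key, rd$upstreamES, rd$upstreamEE,
                 rd$downstreamES, rd$downstreamEE, sep = ":")
  unique(key)
}

#' Match events between two comparisons
#'
#' Keys both event sets with [eventKeys()] and intersects them. The genome
#' build labels (`metadata(x)$genome`) must agree by string equality —
#' coordinates from different builds must not be compared — unless
#' `force = TRUE`.
#'
#' @param sesA,sesB [SeEventSet-class] objects.
#' @param eventsA,eventsB optional event-id subsets (e.g. the significant
#'   events of each comparison).
#' @param mode key mode, see [eventKeys()].
#' @param force skip the genome build check.
#' @return list with `keysA`, `keysB`, `intersection`.
#' @export
matchEvents <- function(sesA, sesB, eventsA = NULL, eventsB = NULL,
                        mode = c("default", "strict"), force = FALSE) {
  mode <- match.arg(mode)
  gA <- metadata(sesA)$genome; gB <- metadata(sesB)$genome
  if (!force && !identical(gA, gB))
    stop(sprintf(
      "genome build labels differ ('%s' vs '%s'); use force = TRUE to override",
      gA, gB))
  a <- eventKeys(sesA, eventsA, mode)
  b <- eventKeys(sesB, eventsB, mode)
  list(keysA = a, keysB = b, intersection = intersect(a, b))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of at
#' least `k` shared events when one set of size `K` and one of size `n`
#' are drawn from a universe of `N`. Computed in log space via
#' [stats::phyper()], so extreme enrichment tails (down to ~1e-300 and
#' below) are represented.
#'
#' @param k observed overlap.
#' @param K,n the two set sizes.
#' @param N universe size.
#' @param log.p return the natural-log probability.
#' @return tail probability (or its log).
#' @examples
#' hypergeometricTail(3, 5, 4, 10)  # 55/210
#' @export
hypergeometricTail <- function(k, K, n, N, log.p = FALSE) {
  if (K > N || n > N) stop("K and n must not exceed the universe N")
  if (k < 0 || K < 0 || n < 0 || N < 0) stop("parameters must be >= 0")
  if (k == 0) return(if (log.p) 0 else 1)
  if (k > min(K, n)) return(if (log.p) -Inf else 0)
  lp <- stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE,
                      log.p = TRUE)
  if (log.p) lp else exp(lp)
}

#' Jaccard index of two keyed sets
#'
#' `|A n B| / |A u B|`; defined as 0 (with a warning) when both sets are
#' empty.
#'
#' @param a,b character vectors (keyed event sets).
#' @return Jaccard index in \[0,1\].
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    warning("both sets empty; Jaccard index defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Jaccard similarity of a reference program against perturbation sets
#'
#' Computes the Jaccard index of a reference event set (e.g. the
#' pathway-controlled splicing program) against each of several
#' perturbation-controlled sets, ranked descending with ties broken by set
#' name.
#'
#' @param reference character vector of keys.
#' @param sets named list of character vectors.
#' @return `data.frame` with `set`, `jaccard`, sorted.
#' @export
pairwiseJaccard <- function(reference, sets) {
  if (length(sets) < 2L) stop("need >= 2 comparison sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be named")
  j <- vapply(sets, function(s)
    suppressWarnings(jaccardIndex(reference, s)), numeric(1))
  out <- data.frame(set = names(sets), jaccard = as.numeric(j),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$jaccard, out$set), , drop = FALSE]
}

#' Three-way Venn region counts
#'
#' Counts of the 7 exclusive regions of three keyed sets; the counts sum
#' to `|A u B u C|`.
#'
#' @param setA,setB,setC character vectors.
#' @return named integer vector with regions `A`, `B`, `C`, `AB`, `AC`,
#'   `BC`, `ABC` (exclusive).
#' @export
threeWayVenn <- function(setA, setB, setC) {
  setA <- unique(setA); setB <- unique(setB); setC <- unique(setC)
  all_keys <- union(union(setA, setB), setC)
  ina <- all_keys %in% setA; inb <- all_keys %in% setB
  inc <- all_keys %in% setC
  cnt <- function(x) sum(x)
  out <- c(
    A = cnt(ina & !inb & !inc),
    B = cnt(!ina & inb & !inc),
    C = cnt(!ina & !inb & inc),
    AB = cnt(ina & inb & !inc),
    AC = cnt(ina & !inb & inc),
    BC = cnt(!ina & inb & inc),
    ABC = cnt(ina & inb & inc))
  storage.mode(out) <- "integer"
  out
}

#' Overlap test for two splicing programs
#'
#' Wraps the Venn sizes, upper-tail hypergeometric enrichment probability,
#' and Jaccard index into an [OverlapResult-class]. The universe `N` is a
#' required, consciously chosen input: the recommended default is the set
#' of events quantifiable (passing the coverage filter) in *both*
#' comparisons, and any reported probability should state the `N` used.
#'
#' @param a,b character vectors of event keys.
#' @param universe universe size N (>= size of each set).
#' @return an [OverlapResult-class].
#' @export
overlapTest <- function(a, b, universe) {
  a <- unique(a); b <- unique(b)
  k <- length(intersect(a, b))
  lp <- hypergeometricTail(k, length(a), length(b), universe, log.p = TRUE)
  new("OverlapResult",
      sizeA = length(a), sizeB = length(b), overlap = as.integer(k),
      universe = as.integer(universe),
      pHyper = exp(lp), logPHyper = lp,
      jaccard = suppressWarnings(jaccardIndex(a, b)))
}
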