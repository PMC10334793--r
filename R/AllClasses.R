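#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData rowData<- colData<-
NULL

#' Skipped-exon event set with per-sample junction counts
#'
#' `SeEventSet` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds one row per cassette (skipped) exon event and one column per
#' sample. Two integer assays are required: `"ijc"` (inclusion junction
#' counts, the reads supporting the exon-included form) and `"sjc"`
#' (skipping junction counts). `rowData` carries the event geometry in the
#' rMATS JC dialect: 0-based half-open exon and flank coordinates, strand,
#' gene annotation, and the effective form lengths `incFormLen` / `skipFormLen`
#' used for length-normalized PSI. All genomic intervals in this package are
#' 0-based half-open, so exon length is `exonEnd - exonStart`.
#'
#' `NA` counts are permitted and mark replicates without junction coverage;
#' they propagate to missing PSI downstream.
#'
#' @slot metadata inherited; `metadata(x)$genome` optionally labels the
#'   genome build and is compared (string equality) when event sets are
#'   intersected.
#' @seealso [SeEventSet()] (constructor), [readSeTable()], [buildPsiMatrix()]
#' @export
setClass("SeEventSet", contains = "SummarizedExperiment")

.required_rowdata <- c("geneId", "geneSymbol", "chrom", "strand",
                       "exonStart", "exonEnd",
                       "upstreamES", "upstreamEE",
                       "downstreamES", "downstreamEE",
                       "incFormLen", "skipFormLen")

setValidity("SeEventSet", function(object) {
  msg <- character()
  if (!all(c("ijc", "sjc") %in% assayNames(object)))
    msg <- c(msg, "assays 'ijc' and 'sjc' are required")
  else {
    for (a in c("ijc", "sjc")) {
      m <- assay(object, a)
      if (any(m < 0, na.rm = TRUE))
        msg <- c(msg, sprintf("assay '%s' contains negative counts", a))
      if (any(!is.na(m) & m != round(m)))
        msg <- c(msg, sprintf("assay '%s' contains non-integer counts", a))
    }
  }
  rd <- rowData(object)
  miss <- setdiff(.required_rowdata, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks: ", paste(miss, collapse = ", ")))
  else {
    if (any(rd$exonStart >= rd$exonEnd))
      msg <- c(msg, "exonStart must be < exonEnd (0-based half-open)")
    if (any(rd$incFormLen < 1) || any(rd$skipFormLen < 1))
      msg <- c(msg, "effective form lengths must be >= 1")
    if (!all(rd$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "event ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an SeEventSet
#'
#' @param ijc,sjc integer matrices (events x samples) of inclusion and
#'   skipping junction counts; `NA` marks uncovered replicates.
#' @param events `data.frame` with one row per event supplying the columns
#'   `geneId`, `geneSymbol`, `chrom`, `strand`, `exonStart`, `exonEnd`,
#'   `upstreamES`, `upstreamEE`, `downstreamES`, `downstreamEE`,
#'   `incFormLen`, `skipFormLen` (coordinates 0-based half-open).
#' @param colData optional `data.frame`/`DataFrame` of sample annotation.
#' @param genome optional genome build label stored in `metadata(x)$genome`.
#' @return an [SeEventSet-class] object.
#' @examples
#' ev <- data.frame(geneId = "G1", geneSymbol = "G1", chrom = "chr1",
#'   strand = "+", exonStart = 100, exonEnd = 182, upstreamES = 10,
#'   upstreamEE = 60, downstreamES = 300, downstreamEE = 380,
#'   incFormLen = 198, skipFormLen = 99)
#' SeEventSet(ijc = matrix(5, 1, 2), sjc = matrix(3, 1, 2), events = ev)
#' @export
SeEventSet <- function(ijc, sjc, events, colData = NULL, genome = NA_character_) {
  ijc <- as.matrix(ijc); sjc <- as.matrix(sjc)
  if (!identical(dim(ijc), dim(sjc)))
    stop("'ijc' and 'sjc' must have identical dimensions")
  if (nrow(events) != nrow(ijc))
    stop("'events' must have one row per event")
  if (is.null(rownames(ijc)))
    rownames(ijc) <- rownames(sjc) <-
      if (!is.null(rownames(events))) rownames(events)
      else sprintf("SE%04d", seq_len(nrow(ijc)))
  if (is.null(colnames(ijc)))
    colnames(ijc) <- colnames(sjc) <- sprintf("S%03d", seq_len(ncol(ijc)))
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(ijc))
  se <- SummarizedExperiment(
    assays = list(ijc = ijc, sjc = sjc),
    rowData = DataFrame(events, row.names = rownames(ijc)),
    colData = colData)
  metadata(se)$genome <- genome
  new("SeEventSet", se)
}

#' Exon inclusion (PSI) matrix
#'
#' `PsiExperiment` extends [SummarizedExperiment::SummarizedExperiment] with
#' assays `"psi"` (inclusion level in \[0,1\], `NA` where no junction reads
#' were observed) and `"total"` (total junction reads I + S per event and
#' sample). A cell is missing if and only if its total is 0 or itself
#' missing.
#'
#' @seealso [buildPsiMatrix()]
#' @export
setClass("PsiExperiment", contains = "SummarizedExperiment")

setValidity("PsiExperiment", function(object) {
  msg <- character()
  if (!all(c("psi", "total") %in% assayNames(object)))
    return("assays 'psi' and 'total' are required")
  psi <- assay(object, "psi"); tot <- assay(object, "total")
  if (any(psi < 0 | psi > 1, na.rm = TRUE))
    msg <- c(msg, "psi values must lie in [0,1]")
  bad <- is.na(psi) != (is.na(tot) | tot == 0)
  if (any(bad))
    msg <- c(msg, "psi must be missing exactly where total junction reads are 0")
  if (length(msg)) msg else TRUE
})

#' Per-sample pathway activity scores
#'
#' One activity score per sample for a named gene set, produced by
#' [pathwayScore()]. Scores from the default `"mean-z"` method have mean 0
#' across the scoring group; scores from `"rank-ssgsea"` are running-sum
#' enrichment statistics on per-sample expression ranks. Downstream code
#' (the correlation engine) treats the scores as an opaque per-sample
#' quantity.
#'
#' @slot sampleIds character, sample identifiers.
#' @slot scores numeric, one finite score per sample.
#' @slot genesetName name of the gene set scored.
#' @slot nGenesUsed number of gene-set genes found in the expression matrix.
#' @slot method scoring method used.
#' @export
setClass("ActivityScores", representation(
  sampleIds = "character",
  scores = "numeric",
  genesetName = "character",
  nGenesUsed = "integer",
  method = "character"))

setValidity("ActivityScores", function(object) {
  msg <- character()
  if (length(object@sampleIds) != length(object@scores))
    msg <- c(msg, "sampleIds and scores lengths differ")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample ids must be unique")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

#' Normalized, log-transformed expression
#'
#' Holds `log2(count / sizeFactor + 1)` values together with the per-sample
#' median-of-ratios size factors they were computed with.
#'
#' @slot values numeric matrix, genes x samples, log2 scale.
#' @slot sizeFactors positive per-sample scaling factors, named by sample.
#' @seealso [normalizeCounts()], [computeSizeFactors()]
#' @export
setClass("NormalizedExpression", representation(
  values = "matrix",
  sizeFactors = "numeric"))

setValidity("NormalizedExpression", function(object) {
  msg <- character()
  if (length(object@sizeFactors) != ncol(object@values))
    msg <- c(msg, "one size factor per sample is required")
  if (any(object@sizeFactors <= 0))
    msg <- c(msg, "size factors must be > 0")
  if (length(msg)) msg else TRUE
})

#' Overlap of two splicing programs
#'
#' Result of [overlapTest()]: Venn-style sizes of two keyed event sets, the
#' upper-tail hypergeometric probability P(X >= k) of seeing at least the
#' observed overlap when drawing from a finite universe, and the Jaccard
#' index |A n B| / |A u B|.
#'
#' @slot sizeA,sizeB set sizes (the hypergeometric K and n).
#' @slot overlap observed intersection size k.
#' @slot universe universe size N.
#' @slot pHyper upper-tail probability P(X >= k).
#' @slot logPHyper natural-log tail probability (finite even when `pHyper`
#'   underflows printing precision).
#' @slot jaccard Jaccard index.
#' @export
setClass("OverlapResult", representation(
  sizeA = "integer", sizeB = "integer", overlap = "integer",
  universe = "integer", pHyper = "numeric", logPHyper = "numeric",
  jaccard = "numeric"))

setValidity("OverlapResult", function(object) {
  msg <- character()
  if (object@overlap > min(object@sizeA, object@sizeB))
    msg <- c(msg, "overlap exceeds the smaller set")
  if (object@sizeA > object@universe || object@sizeB > object@universe)
    msg <- c(msg, "set sizes exceed the universe")
  if (object@jaccard < 0 || object@jaccard > 1)
    msg <- c(msg, "jaccard must lie in [0,1]")
  if (object@pHyper < 0 || object@pHyper > 1)
    msg <- c(msg, "pHyper must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
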