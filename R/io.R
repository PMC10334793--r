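#' Read gene sets from a GMT file
#'
#' Parses the MSigDB GMT layout: one gene set per line, tab-separated, with
#' the set name in column 1, a description (discarded) in column 2, and the
#' member genes in the remaining columns.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene identifiers, one element
#'   per line, in file order.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("HALLMARK_MYC_TARGETS_V2\tdesc\tMYC\tNPM1\tSRM", f)
#' readGmt(f)
#' @export
readGmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(parts) < 3L || !length(genes))
      stop(sprintf("GMT format error: line %d ('%s') has no genes",
                   i, parts[1]))
    if (anyDuplicated(genes)) {
      warning(sprintf("gene set '%s': duplicate genes collapsed", parts[1]))
      genes <- unique(genes)
    }
    nms[i] <- parts[1]
    sets[[i]] <- genes
  }
  names(sets) <- nms
  sets
}

.split_counts <- function(field, n_expected, what, row) {
  out <- lapply(as.character(field), function(s) {
    v <- strsplit(s, ",", fixed = TRUE)[[1]]
    suppressWarnings(as.numeric(ifelse(v == "NA" | v == "", NA, v)))
  })
  len <- lengths(out)
  if (any(len != n_expected))
    stop(sprintf("parse error: row %d has %d %s replicate counts, expected %d",
                 row[which(len != n_expected)[1]],
                 len[len != n_expected][1], what, n_expected))
  m <- do.call(rbind, out)
  if (any(m < 0, na.rm = TRUE) || any(!is.na(m) & m != round(m)))
    stop(sprintf("parse error: negative or non-integer %s count in row %d",
                 what, row[which(apply(m, 1, function(z)
                   any(z < 0 | z != round(z), na.rm = TRUE)))[1]]))
  m
}

#' Read a skipped-exon junction-count table (rMATS JC dialect)
#'
#' Reads the `SE.MATS.JC.txt`-style tab-separated layout: per-event exon and
#' flank coordinates (0-based half-open) plus comma-separated replicate
#' junction counts `IJC_SAMPLE_1` / `SJC_SAMPLE_1` (group 1) and
#' `IJC_SAMPLE_2` / `SJC_SAMPLE_2` (group 2), with effective form lengths
#' `IncFormLen` / `SkipFormLen`. Replicate lists are split into per-sample
#' columns. `NA` entries in a replicate list are kept as missing counts.
#'
#' If `IncLevel1` / `IncLevel2` columns are present, the inclusion levels are
#' re-derived from the counts and compared within +/- 0.001 (the dialect
#' rounds to 3 decimals); a mismatch raises a warning and the count-derived
#' value wins, since counts are the source of truth.
#'
#' @param path file path.
#' @param n_group1,n_group2 declared number of replicates per group; a row
#'   whose replicate list has a different arity is a parse error.
#' @param sample_names optional character vector of `n_group1 + n_group2`
#'   sample ids (group 1 first). Defaults to `G1_R1...`, `G2_R1...`.
#' @param genome optional genome build label stored in the result metadata.
#' @return an [SeEventSet-class]; `colData(x)$group` records the group of
#'   each sample column.
#' @export
readSeTable <- function(path, n_group1, n_group2, sample_names = NULL,
                        genome = NA_character_) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("ID", "chr", "strand", "exonStart_0base", "exonEnd",
            "upstreamES", "upstreamEE", "downstreamES", "downstreamEE",
            "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
            "IncFormLen", "SkipFormLen")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("SE table lacks required columns: ", paste(miss, collapse = ", "))
  rows <- seq_len(nrow(d))
  i1 <- .split_counts(d$IJC_SAMPLE_1, n_group1, "IJC_SAMPLE_1", rows)
  s1 <- .split_counts(d$SJC_SAMPLE_1, n_group1, "SJC_SAMPLE_1", rows)
  i2 <- .split_counts(d$IJC_SAMPLE_2, n_group2, "IJC_SAMPLE_2", rows)
  s2 <- .split_counts(d$SJC_SAMPLE_2, n_group2, "SJC_SAMPLE_2", rows)
  ijc <- cbind(i1, i2); sjc <- cbind(s1, s2)
  if (is.null(sample_names))
    sample_names <- c(sprintf("G1_R%d", seq_len(n_group1)),
                      sprintf("G2_R%d", seq_len(n_group2)))
  if (length(sample_names) != n_group1 + n_group2)
    stop("'sample_names' must name every replicate of both groups")
  colnames(ijc) <- colnames(sjc) <- sample_names
  rownames(ijc) <- rownames(sjc) <- as.character(d$ID)
  events <- data.frame(
    geneId = if ("GeneID" %in% colnames(d)) d$GeneID else as.character(d$ID),
    geneSymbol = if ("geneSymbol" %in% colnames(d)) d$geneSymbol
                 else NA_character_,
    chrom = d$chr, strand = d$strand,
    exonStart = d$exonStart_0base, exonEnd = d$exonEnd,
    upstreamES = d$upstreamES, upstreamEE = d$upstreamEE,
    downstreamES = d$downstreamES, downstreamEE = d$downstreamEE,
    incFormLen = d$IncFormLen, skipFormLen = d$SkipFormLen,
    row.names = as.character(d$ID), stringsAsFactors = FALSE)
  cd <- DataFrame(group = rep(c("1", "2"), c(n_group1, n_group2)),
                  row.names = sample_names)
  ses <- SeEventSet(ijc, sjc, events, colData = cd, genome = genome)
  for (g in 1:2) {
    col <- paste0("IncLevel", g)
    if (!col %in% colnames(d)) next
    stated <- do.call(rbind, lapply(as.character(d[[col]]), function(s) {
      v <- strsplit(s, ",", fixed = TRUE)[[1]]
      suppressWarnings(as.numeric(ifelse(v == "NA", NA, v)))
    }))
    idx <- if (g == 1) seq_len(n_group1) else n_group1 + seq_len(n_group2)
    derived <- psiFromCounts(ijc[, idx, drop = FALSE],
                             sjc[, idx, drop = FALSE],
                             events$incFormLen, events$skipFormLen)
    diff <- abs(stated - derived)
    if (any(diff > 0.001, na.rm = TRUE))
      warning(sprintf(
        "%s disagrees with count-derived inclusion levels (max diff %.4g); using the derived values",
        col, max(diff, na.rm = TRUE)))
  }
  ses
}

#' Write an SeEventSet in the rMATS JC dialect
#'
#' Inverse of [readSeTable()]: emits the tab-separated SE table with
#' comma-joined replicate counts and inclusion levels re-derived from the
#' counts (rounded to 3 decimals, as the dialect does). All count and
#' coordinate fields round-trip exactly.
#'
#' @param ses an [SeEventSet-class].
#' @param path output file path.
#' @param groups sample-to-group assignment; defaults to `colData(ses)$group`.
#' @return invisibly, `path`.
#' @export
writeSeTable <- function(ses, path, groups = NULL) {
  if (is.null(groups)) groups <- colData(ses)$group
  if (is.null(groups))
    stop("no group assignment: supply 'groups' or colData(ses)$group")
  groups <- as.character(groups)
  if (!identical(sort(unique(groups)), c("1", "2")))
    stop("'groups' must assign every sample to group \"1\" or \"2\"")
  g1 <- which(groups == "1"); g2 <- which(groups == "2")
  rd <- rowData(ses)
  joinc <- function(m) apply(m, 1, function(v)
    paste(ifelse(is.na(v), "NA", format(v, scientific = FALSE, trim = TRUE)),
          collapse = ","))
  psi1 <- psiFromCounts(ijc(ses)[, g1, drop = FALSE],
                        sjc(ses)[, g1, drop = FALSE],
                        rd$incFormLen, rd$skipFormLen)
  psi2 <- psiFromCounts(ijc(ses)[, g2, drop = FALSE],
                        sjc(ses)[, g2, drop = FALSE],
                        rd$incFormLen, rd$skipFormLen)
  joinpsi <- function(m) apply(round(m, 3), 1, function(v)
    paste(ifelse(is.na(v), "NA", format(v, scientific = FALSE, trim = TRUE)),
          collapse = ","))
  out <- data.frame(
    ID = rownames(ses), GeneID = rd$geneId, geneSymbol = rd$geneSymbol,
    chr = rd$chrom, strand = rd$strand,
    exonStart_0base = rd$exonStart, exonEnd = rd$exonEnd,
    upstreamES = rd$upstreamES, upstreamEE = rd$upstreamEE,
    downstreamES = rd$downstreamES, downstreamEE = rd$downstreamEE,
    IJC_SAMPLE_1 = joinc(ijc(ses)[, g1, drop = FALSE]),
    SJC_SAMPLE_1 = joinc(sjc(ses)[, g1, drop = FALSE]),
    IJC_SAMPLE_2 = joinc(ijc(ses)[, g2, drop = FALSE]),
    SJC_SAMPLE_2 = joinc(sjc(ses)[, g2, drop = FALSE]),
    IncFormLen = rd$incFormLen, SkipFormLen = rd$skipFormLen,
    IncLevel1 = joinpsi(psi1), IncLevel2 = joinpsi(psi2),
    IncLevelDifference = round(rowMeans(psi1, na.rm = TRUE) -
                               rowMeans(psi2, na.rm = TRUE), 3),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write intervals as 6-column BED
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`; coordinates 0-based half-open, so the BED
#'   feature length is `end - start`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeBed <- function(intervals, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(cols %in% colnames(intervals)))
    stop("intervals need columns: ", paste(cols, collapse = ", "))
  if (nrow(intervals) && any(intervals$start >= intervals$end))
    stop("validation error: start must be < end (0-based half-open)")
  utils::write.table(intervals[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a 6-column BED file
#'
#' @param path file path.
#' @return `data.frame` with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open).
#' @export
readBed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                         comment.char = "#", stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (ncol(d) < 6L) stop("expected 6 BED columns")
  d <- d[, 1:6]
  colnames(d) <- c("chrom", "start", "end", "name", "score", "strand")
  d
}

#' Read a gene-level counts matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids; every
#' count cell must be a non-negative integer.
#'
#' @param path file path.
#' @return integer matrix, genes x samples, with dimnames.
#' @export
readCountsMatrix <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  genes <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0))
    stop("parse error: counts must be non-negative integers")
  rownames(m) <- genes
  storage.mode(m) <- "integer"
  check_counts_matrix(m)
  m
}

#' Write a counts matrix as TSV
#' @param counts integer matrix, genes x samples.
#' @param path output file path.
#' @param idCol header for the gene-id column.
#' @return invisibly, `path`.
#' @export
writeCountsMatrix <- function(counts, path, idCol = "gene_id") {
  check_counts_matrix(counts)
  d <- data.frame(rownames(counts), counts, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d)[1] <- idCol
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path file path to a TSV with at least a `sample` column plus
#'   grouping columns such as `cohort` and `stage` (ordered disease-spectrum
#'   label) or `condition` (e.g. control/KO).
#' @return `data.frame` with unique sample ids.
#' @export
readSampleMetadata <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"sample" %in% colnames(d))
    stop("metadata must contain a 'sample' column")
  if (anyDuplicated(d$sample))
    stop("duplicate sample ids in metadata")
  if (any(!nzchar(d$sample)) || any(is.na(d$sample)))
    stop("missing sample ids in metadata")
  d
}

#' Read named nucleotide sequences from FASTA
#'
#' Sequences are upper-cased and RNA `U` is normalized to `T`, so G-run
#' scanning and tiling always operate on DNA-sense strings.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @importFrom Biostrings readBStringSet
#' @export
readFastaSequences <- function(path) {
  ss <- readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA id: ", nm[duplicated(nm)][1])
  seqs <- chartr("u", "t", toupper(as.character(ss)))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- nm
  seqs
}
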