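#' Find G-runs in a nucleotide sequence
#'
#' Locates all maximal runs of consecutive guanines of at least `min_len`
#' on the given (sense, pre-mRNA) strand. Runs of exactly 3 are classed
#' `"G3"` and runs of 4 or more `"G4plus"`, the motif lengths bound by
#' hnRNP H/F; maximal-run semantics avoid double counting overlapping
#' GGG/GGGG matches. Returned runs never overlap and are separated by at
#' least one non-G base.
#'
#' @param sequence character string over \{A, C, G, T\} (normalize RNA `U`
#'   to `T` first, e.g. via [readFastaSequences()]).
#' @param min_len minimum run length (default 3).
#' @return `data.frame` with 0-based half-open `start`, `end`, plus
#'   `length` and `class`, ascending by `start`.
#' @examples
#' findGRuns("TGGGTAGGGGCGGG")
#' @export
findGRuns <- function(sequence, min_len = 3L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("non-ACGT character '%s' at position %d",
                 chars[bad[1]], bad[1]))
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep])
  out$class <- ifelse(out$length >= 4L, "G4plus", "G3")
  out[order(out$start), , drop = FALSE]
}

#' Design an antisense-oligonucleotide tiling panel
#'
#' Lays out ASO tiles across a target window (e.g. upstream intron + exon +
#' downstream intron). Without a `schedule`, abutting tiles of `tile_len`
#' start at position 0 with step `tile_len`; any remaining stretch shorter
#' than a tile is left uncovered and reported via the `"uncovered"`
#' attribute. With a `schedule` of start offsets, one tile is placed per
#' offset and its overlap with the previous tile is recorded — real panels
#' are largely nonoverlapping but may repeat a few starts. Tile sequences
#' are the reverse complement of the sense window slice (the oligo
#' hybridizes to the pre-mRNA); backbone chemistry is metadata, not
#' modeled.
#'
#' @param window_length length of the target window; inferred from
#'   `sequence` when that is given.
#' @param tile_len tile length in nt (default 18).
#' @param schedule optional integer vector of 0-based tile start offsets.
#' @param sequence optional sense-strand window sequence used to fill the
#'   tile (ASO) sequences.
#' @param prefix tile-id prefix (default "ASO").
#' @return `data.frame` with `tile_id`, 0-based half-open `start`, `end`,
#'   `overlap_with_previous`, `sequence` (NA when no window sequence was
#'   given); attribute `"uncovered"` gives the number of uncovered
#'   trailing nucleotides in default mode.
#' @examples
#' designTiles(376)      # 20 abutting tiles, 16 nt uncovered
#' @importFrom Biostrings DNAStringSet reverseComplement
#' @export
designTiles <- function(window_length = NULL, tile_len = 18L,
                        schedule = NULL, sequence = NULL,
                        prefix = "ASO") {
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (is.null(window_length)) window_length <- nchar(sequence)
    if (window_length != nchar(sequence))
      stop("window_length disagrees with the sequence length")
  }
  if (is.null(window_length)) stop("supply window_length or sequence")
  if (tile_len > window_length)
    stop("tile_len exceeds the window length")
  uncovered <- 0L
  if (is.null(schedule)) {
    starts <- seq.int(0L, window_length - tile_len, by = tile_len)
    uncovered <- window_length - (starts[length(starts)] + tile_len)
  } else {
    starts <- as.integer(schedule)
    if (any(starts < 0L) || any(starts + tile_len > window_length))
      stop("schedule offset out of window: offset + tile_len must be <= window_length")
  }
  ends <- starts + as.integer(tile_len)
  overlap <- c(0L, pmax(0L, ends[-length(ends)] - starts[-1]))
  seqs <- rep(NA_character_, length(starts))
  if (!is.null(sequence)) {
    slices <- substring(sequence, starts + 1L, ends)
    seqs <- as.character(reverseComplement(DNAStringSet(slices)))
  }
  out <- data.frame(
    tile_id = sprintf("%s%02d", prefix, seq_along(starts)),
    start = starts, end = ends,
    overlap_with_previous = overlap,
    sequence = seqs, stringsAsFactors = FALSE)
  attr(out, "uncovered") <- as.integer(uncovered)
  out
}

#' Classify the splicing effect of one ASO
#'
#' Two-sided Student's t-test (equal variances by default; `welch = TRUE`
#' for the unequal-variance form) of replicate PSI measurements for an ASO
#' against the nontargeting control (NTC). A significant increase in
#' inclusion means the ASO unmasked a silencer; a significant decrease
#' means it blocked an enhancer.
#'
#' @param psi_treated,psi_ntc numeric vectors of replicate PSI values
#'   (>= 2 replicates each).
#' @param alpha significance level (default 0.05).
#' @param welch use Welch's unequal-variance t-test.
#' @return list with `mean_psi_treated`, `mean_psi_ntc`, `p_value`,
#'   `direction` (`"increase"`, `"decrease"`, `"ns"`), `element_class`
#'   (`"silencer"`, `"enhancer"`, `"none"`).
#' @examples
#' classifyAsoEffect(c(14.7, 14.8, 14.9), c(9.9, 10.0, 10.1))
#' @export
classifyAsoEffect <- function(psi_treated, psi_ntc, alpha = 0.05,
                              welch = FALSE) {
  if (length(psi_treated) < 2L || length(psi_ntc) < 2L)
    stop("need >= 2 replicates per arm")
  m1 <- mean(psi_treated); m0 <- mean(psi_ntc)
  if (stats::sd(psi_treated) == 0 && stats::sd(psi_ntc) == 0) {
    p <- if (m1 == m0) 1 else 0
  } else {
    p <- stats::t.test(psi_treated, psi_ntc,
                       var.equal = !welch)$p.value
  }
  if (p < alpha && m1 > m0) {
    direction <- "increase"; cls <- "silencer"
  } else if (p < alpha && m1 < m0) {
    direction <- "decrease"; cls <- "enhancer"
  } else {
    direction <- "ns"; cls <- "none"
  }
  list(mean_psi_treated = m1, mean_psi_ntc = m0, p_value = p,
       direction = direction, element_class = cls)
}

#' Classify a whole ASO tiling panel
#'
#' Applies [classifyAsoEffect()] to every tile and reports calls both at
#' the raw per-ASO alpha (matching how tiling screens are conventionally
#' annotated) and after Benjamini-Hochberg adjustment across the panel.
#'
#' @param psi_panel named list: one numeric vector of replicate PSI values
#'   per tile id.
#' @param psi_ntc replicate PSI values of the nontargeting control.
#' @param alpha significance level (default 0.05).
#' @param welch use Welch's t-test.
#' @return `data.frame` with `tile_id`, means, `p_value`, `p_adj`,
#'   `direction`, `element_class` (raw alpha), and `element_class_bh`
#'   (BH-adjusted calls).
#' @export
callAsoPanel <- function(psi_panel, psi_ntc, alpha = 0.05, welch = FALSE) {
  if (is.null(names(psi_panel)) || any(!nzchar(names(psi_panel))))
    stop("'psi_panel' must be a named list of replicate vectors")
  calls <- lapply(psi_panel, classifyAsoEffect, psi_ntc = psi_ntc,
                  alpha = alpha, welch = welch)
  out <- data.frame(
    tile_id = names(psi_panel),
    mean_psi_treated = vapply(calls, `[[`, numeric(1), "mean_psi_treated"),
    mean_psi_ntc = vapply(calls, `[[`, numeric(1), "mean_psi_ntc"),
    p_value = vapply(calls, `[[`, numeric(1), "p_value"),
    direction = vapply(calls, `[[`, character(1), "direction"),
    element_class = vapply(calls, `[[`, character(1), "element_class"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adj <- bhAdjust(out$p_value)
  sig_bh <- out$p_adj < alpha
  out$element_class_bh <- ifelse(
    sig_bh & out$mean_psi_treated > out$mean_psi_ntc, "silencer",
    ifelse(sig_bh & out$mean_psi_treated < out$mean_psi_ntc, "enhancer",
           "none"))
  out
}

# Map a local 0-based half-open interval within a window to genomic
# coordinates. `origin` is the genomic start (0-based) of the window for
# both strands; on the minus strand local position 0 is the window's
# 3'-most genomic base, so intervals are mirror-mapped.
local_to_genomic <- function(start, end, origin, window_length, strand) {
  if (strand == "+") {
    data.frame(start = origin + start, end = origin + end)
  } else {
    data.frame(start = origin + window_length - end,
               end = origin + window_length - start)
  }
}

genomic_to_local <- function(gstart, gend, origin, window_length, strand) {
  if (strand == "+") {
    data.frame(start = gstart - origin, end = gend - origin)
  } else {
    data.frame(start = origin + window_length - gend,
               end = origin + window_length - gstart)
  }
}

#' Build a BED-ready cis-element map
#'
#' Combines ASO tiles (colored by their element call) and G-run intervals
#' into one genomic interval table suitable for [writeBed()]. Local window
#' offsets are converted to genomic coordinates strand-awarely:
#' `window_origin` is the genomic start (0-based) of the window, and on the
#' minus strand local offsets count from the window's 3'-most genomic base
#' (mirror mapping).
#'
#' @param tiles output of [designTiles()].
#' @param calls output of [callAsoPanel()]; every `tile_id` must exist in
#'   `tiles`.
#' @param g_runs output of [findGRuns()] on the window sequence (may be
#'   empty).
#' @param window_origin genomic start of the window, 0-based.
#' @param window_length window length in nt.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @return `data.frame` with `chrom`, `start`, `end`, `name` (tile id with
#'   its element class, or G-run class), `score` (0 none / 500 silencer
#'   region / 1000 enhancer region), `strand`.
#' @export
buildElementMap <- function(tiles, calls, g_runs, window_origin,
                            window_length, chrom, strand = c("+", "-")) {
  strand <- match.arg(strand)
  dangling <- setdiff(calls$tile_id, tiles$tile_id)
  if (length(dangling))
    stop("calls reference unknown tiles: ",
         paste(dangling, collapse = ", "))
  cls <- calls$element_class[match(tiles$tile_id, calls$tile_id)]
  cls[is.na(cls)] <- "none"
  gt <- local_to_genomic(tiles$start, tiles$end, window_origin,
                         window_length, strand)
  tile_df <- data.frame(
    chrom = chrom, start = gt$start, end = gt$end,
    name = paste(tiles$tile_id, cls, sep = "|"),
    score = c(none = 0L, silencer = 500L, enhancer = 1000L)[cls],
    strand = strand, stringsAsFactors = FALSE)
  run_df <- NULL
  if (!is.null(g_runs) && nrow(g_runs)) {
    gr <- local_to_genomic(g_runs$start, g_runs$end, window_origin,
                           window_length, strand)
    run_df <- data.frame(
      chrom = chrom, start = gr$start, end = gr$end,
      name = sprintf("Grun_%s_%d", g_runs$class, seq_len(nrow(g_runs))),
      score = 0L, strand = strand, stringsAsFactors = FALSE)
  }
  out <- rbind(tile_df, run_df)
  rownames(out) <- NULL
  out
}
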