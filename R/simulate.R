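#' Configuration for a synthetic disease-spectrum cohort
#'
#' Builds and validates the parameter list consumed by [simulateCohort()].
#' The generator emulates the statistical structure a pathway-guided
#' splicing analysis assumes: a latent per-sample pathway activity that
#' rises along an ordered disease spectrum (normal -> benign -> tumor),
#' hallmark genes whose expression tracks that activity, and cassette exons
#' whose inclusion is coupled to activity through a logit link.
#'
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param stages `data.frame` with columns `label`, `n`, `activity_mean`,
#'   `activity_sd`: the ordered disease spectrum. The default is a
#'   300-sample, three-stage spectrum (normal/benign/tumor, 100 samples
#'   each) with stage activity means 0, 1, 2 and within-stage sd 0.5.
#' @param n_pathway_genes,n_background_genes numbers of hallmark-responsive
#'   and activity-independent genes (defaults 50 and 450).
#' @param pathway_response log2-fold expression change per unit activity
#'   (beta_g), scalar or one value per pathway gene (default 1).
#' @param n_events number of cassette-exon events.
#' @param coupled_events `data.frame` with columns `event` (index),
#'   `b0`, `b1`: activity-coupled events with true inclusion
#'   `psi_i = plogis(b0 + b1 * a_i)`. All other events get `b1 = 0` and an
#'   intercept drawn from Uniform(-1.5, 1.5). Negative `b1` emulates exons
#'   repressed by pathway activation.
#' @param coverage_mean,coverage_dispersion negative-binomial mean and
#'   dispersion (variance = mu + mu^2/theta) of per-event total junction
#'   reads (defaults 100, 10).
#' @param expression_dispersion NB dispersion of gene counts (default 10).
#' @param inc_form_len,skip_form_len effective form lengths written into
#'   the event table (defaults 198 and 99, a 100-nt read-length geometry).
#' @param cohort cohort label written into the metadata.
#' @return validated config list of class `"CohortConfig"`.
#' @seealso [simulateCohort()]
#' @export
cohortConfig <- function(seed = 1L,
                         stages = data.frame(
                           label = c("normal", "benign", "tumor"),
                           n = c(100L, 100L, 100L),
                           activity_mean = c(0, 1, 2),
                           activity_sd = c(0.5, 0.5, 0.5)),
                         n_pathway_genes = 50L,
                         n_background_genes = 450L,
                         pathway_response = 1,
                         n_events = 500L,
                         coupled_events = data.frame(
                           event = integer(), b0 = numeric(), b1 = numeric()),
                         coverage_mean = 100,
                         coverage_dispersion = 10,
                         expression_dispersion = 10,
                         inc_form_len = 198L,
                         skip_form_len = 99L,
                         cohort = "COHORT1") {
  cfg <- list(seed = seed, stages = stages,
              n_pathway_genes = as.integer(n_pathway_genes),
              n_background_genes = as.integer(n_background_genes),
              pathway_response = pathway_response,
              n_events = as.integer(n_events),
              coupled_events = coupled_events,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              expression_dispersion = expression_dispersion,
              inc_form_len = as.integer(inc_form_len),
              skip_form_len = as.integer(skip_form_len),
              cohort = cohort)
  stopifnot(is.data.frame(stages),
            all(c("label", "n", "activity_mean", "activity_sd") %in%
                colnames(stages)))
  if (any(stages$n < 1L))
    stop("config error: every stage needs n >= 1 samples")
  if (any(stages$activity_sd <= 0))
    stop("config error: activity_sd must be > 0")
  if (cfg$n_pathway_genes < 1L || cfg$n_events < 1L)
    stop("config error: counts must be >= 1")
  if (cfg$coverage_mean <= 0 || cfg$coverage_dispersion <= 0)
    stop("config error: coverage parameters must be > 0")
  if (cfg$inc_form_len < 1L || cfg$skip_form_len < 1L)
    stop("config error: form lengths must be >= 1")
  if (nrow(coupled_events)) {
    stopifnot(all(c("event", "b0", "b1") %in% colnames(coupled_events)))
    if (any(coupled_events$event < 1L | coupled_events$event > cfg$n_events))
      stop("config error: coupled event indices must lie in 1..n_events")
    if (anyDuplicated(coupled_events$event))
      stop("config error: duplicate coupled event indices")
  }
  if (!length(pathway_response) %in% c(1L, cfg$n_pathway_genes))
    stop("config error: pathway_response must be scalar or per pathway gene")
  class(cfg) <- "CohortConfig"
  cfg
}

# Junction-read inclusion probability: reads land on the inclusion form in
# proportion to its effective length, q = psi*lI / (psi*lI + (1-psi)*lS).
.read_prob <- function(psi, lI, lS) psi * lI / (psi * lI + (1 - psi) * lS)

#' Simulate a disease-spectrum cohort with known ground truth
#'
#' Draws per-sample latent activity `a_i ~ Normal(stage mean, stage sd)`,
#' gene counts `NB(mu_g * 2^(beta_g * a_i), theta)` for pathway genes (and
#' activity-independent `NB(mu_g, theta)` for background genes), and for
#' each cassette event total junction reads `T ~ NB(coverage_mean, theta)`
#' split binomially between inclusion and skipping junctions with
#' read-level probability `q = psi*lI / (psi*lI + (1-psi)*lS)`, where
#' `psi_i = plogis(b0 + b1 * a_i)` is the true inclusion level.
#'
#' @param config a [cohortConfig()] object.
#' @return list with elements `counts` (integer matrix genes x samples),
#'   `metadata` (`data.frame` sample/cohort/stage), `events`
#'   ([SeEventSet-class]), and `truth` (list with per-sample `activity`,
#'   per-event `events` parameters with a `coupled` flag, and per-gene
#'   `genes` parameters).
#' @examples
#' sim <- simulateCohort(cohortConfig(seed = 7, n_events = 20,
#'   n_pathway_genes = 10, n_background_genes = 20))
#' dim(sim$counts); sim$events
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  with_rng(config$seed, {
    st <- config$stages
    n_samples <- sum(st$n)
    sample_ids <- sprintf("S%04d", seq_len(n_samples))
    stage <- rep(as.character(st$label), st$n)
    a <- unlist(lapply(seq_len(nrow(st)), function(i)
      stats::rnorm(st$n[i], st$activity_mean[i], st$activity_sd[i])))
    names(a) <- sample_ids

    n_pw <- config$n_pathway_genes; n_bg <- config$n_background_genes
    gene_ids <- c(sprintf("PWY%04d", seq_len(n_pw)),
                  if (n_bg) sprintf("BGD%04d", seq_len(n_bg)))
    mu_g <- stats::rlnorm(n_pw + n_bg, meanlog = log(300), sdlog = 0.7)
    beta <- c(rep_len(config$pathway_response, n_pw), rep(0, n_bg))
    mu <- outer(mu_g, rep(1, n_samples)) *
      2^(outer(beta, rep(1, n_samples)) * outer(rep(1, n_pw + n_bg), a))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = config$expression_dispersion),
                     nrow = n_pw + n_bg,
                     dimnames = list(gene_ids, sample_ids))
    storage.mode(counts) <- "integer"

    n_ev <- config$n_events
    b0 <- stats::runif(n_ev, -1.5, 1.5)
    b1 <- rep(0, n_ev)
    coupled <- rep(FALSE, n_ev)
    ce <- config$coupled_events
    if (nrow(ce)) {
      b0[ce$event] <- ce$b0
      b1[ce$event] <- ce$b1
      coupled[ce$event] <- ce$b1 != 0
    }
    psi_true <- stats::plogis(outer(b0, rep(1, n_samples)) +
                              outer(b1, a))
    tot <- matrix(stats::rnbinom(n_ev * n_samples,
                                 mu = config$coverage_mean,
                                 size = config$coverage_dispersion),
                  nrow = n_ev)
    q <- .read_prob(psi_true, config$inc_form_len, config$skip_form_len)
    inc <- matrix(stats::rbinom(n_ev * n_samples, size = tot, prob = q),
                  nrow = n_ev)
    skp <- tot - inc
    event_ids <- sprintf("SE%05d", seq_len(n_ev))
    dimnames(inc) <- dimnames(skp) <- list(event_ids, sample_ids)

    # synthetic geometry: non-overlapping events on one synthetic contig
    origin <- (seq_len(n_ev) - 1L) * 1000L
    events <- data.frame(
      geneId = sprintf("ENSG%05d", seq_len(n_ev)),
      geneSymbol = sprintf("GENE%05d", seq_len(n_ev)),
      chrom = "chrS", strand = "+",
      exonStart = origin + 300L, exonEnd = origin + 382L,
      upstreamES = origin + 100L, upstreamEE = origin + 200L,
      downstreamES = origin + 500L, downstreamEE = origin + 600L,
      incFormLen = config$inc_form_len, skipFormLen = config$skip_form_len,
      row.names = event_ids, stringsAsFactors = FALSE)
    metadata_df <- data.frame(sample = sample_ids, cohort = config$cohort,
                              stage = stage, stringsAsFactors = FALSE)
    ses <- SeEventSet(inc, skp, events,
                      colData = DataFrame(cohort = config$cohort,
                                          stage = stage,
                                          row.names = sample_ids),
                      genome = "synthetic1")
    truth <- list(
      activity = a,
      events = data.frame(event_id = event_ids, b0 = b0, b1 = b1,
                          coupled = coupled, stringsAsFactors = FALSE),
      genes = data.frame(gene_id = gene_ids, beta = beta, mu = mu_g,
                         pathway = beta != 0, stringsAsFactors = FALSE))
    list(counts = counts, metadata = metadata_df, events = ses,
         truth = truth)
  })
}

#' Simulate a two-group (knockout vs control) splicing experiment
#'
#' Group 1 ("control") inclusion levels are drawn Uniform(0.1, 0.9); for
#' `n_changed` events the group 2 ("KO") level is shifted by `delta_psi`
#' with a random sign, clamped to \[0.01, 0.99\]. A baseline whose clamped
#' shift would be eroded is redrawn (with a notice) so every planted event
#' really carries the full shift. Junction counts are sampled exactly as in
#' [simulateCohort()].
#'
#' @param n_per_group samples per group.
#' @param n_events number of events.
#' @param n_changed number of events with a planted shift (the first
#'   `n_changed` indices; recorded in the truth).
#' @param delta_psi magnitude of the planted inclusion change, in (0, 1].
#' @param coverage NB mean of per-event total junction reads.
#' @param seed integer seed.
#' @param coverage_dispersion NB dispersion (default 10).
#' @param inc_form_len,skip_form_len effective form lengths (198/99).
#' @return list with `events` ([SeEventSet-class]; `colData` has
#'   `condition` control/KO), `metadata`, and `truth` (per-event true psi in
#'   both groups and a `changed` flag).
#' @export
simulateTwoGroup <- function(n_per_group, n_events, n_changed, delta_psi,
                             coverage, seed, coverage_dispersion = 10,
                             inc_form_len = 198L, skip_form_len = 99L) {
  stopifnot(n_per_group >= 1, n_events >= 1,
            n_changed >= 0, n_changed <= n_events,
            delta_psi > 0, delta_psi <= 1, coverage > 0)
  with_rng(seed, {
    psi1 <- stats::runif(n_events, 0.1, 0.9)
    psi2 <- psi1
    changed <- seq_len(n_events) <= n_changed
    resampled <- 0L
    if (n_changed) {
      sgn <- sample(c(-1, 1), n_changed, replace = TRUE)
      for (i in seq_len(n_changed)) {
        tries <- 0L
        while (psi1[i] + sgn[i] * delta_psi < 0.01 ||
               psi1[i] + sgn[i] * delta_psi > 0.99) {
          psi1[i] <- stats::runif(1, 0.1, 0.9)
          tries <- tries + 1L
          if (tries > 1000L) stop("cannot place planted shift")
        }
        resampled <- resampled + (tries > 0L)
        psi2[i] <- psi1[i] + sgn[i] * delta_psi
      }
      if (resampled)
        message(sprintf(
          "resampled %d baseline psi value(s) to preserve the planted shift",
          resampled))
    }
    n <- 2L * n_per_group
    sample_ids <- c(sprintf("CTRL_R%d", seq_len(n_per_group)),
                    sprintf("KO_R%d", seq_len(n_per_group)))
    condition <- rep(c("control", "KO"), each = n_per_group)
    psi_true <- cbind(matrix(psi1, n_events, n_per_group),
                      matrix(psi2, n_events, n_per_group))
    tot <- matrix(stats::rnbinom(n_events * n, mu = coverage,
                                 size = coverage_dispersion),
                  nrow = n_events)
    q <- .read_prob(psi_true, inc_form_len, skip_form_len)
    inc <- matrix(stats::rbinom(n_events * n, size = tot, prob = q),
                  nrow = n_events)
    skp <- tot - inc
    event_ids <- sprintf("SE%05d", seq_len(n_events))
    dimnames(inc) <- dimnames(skp) <- list(event_ids, sample_ids)
    origin <- (seq_len(n_events) - 1L) * 1000L
    events <- data.frame(
      geneId = sprintf("ENSG%05d", seq_len(n_events)),
      geneSymbol = sprintf("GENE%05d", seq_len(n_events)),
      chrom = "chrS", strand = "+",
      exonStart = origin + 300L, exonEnd = origin + 382L,
      upstreamES = origin + 100L, upstreamEE = origin + 200L,
      downstreamES = origin + 500L, downstreamEE = origin + 600L,
      incFormLen = inc_form_len, skipFormLen = skip_form_len,
      row.names = event_ids, stringsAsFactors = FALSE)
    ses <- SeEventSet(inc, skp, events,
                      colData = DataFrame(condition = condition,
                                          row.names = sample_ids),
                      genome = "synthetic1")
    list(events = ses,
         metadata = data.frame(sample = sample_ids, condition = condition,
                               stringsAsFactors = FALSE),
         truth = list(psi_group1 = stats::setNames(psi1, event_ids),
                      psi_group2 = stats::setNames(psi2, event_ids),
                      changed = stats::setNames(changed, event_ids)))
  })
}

#' Simulate a sequence with planted G-runs
#'
#' Background bases are drawn from \{A, C, T\} only, so the planted maximal
#' guanine runs are the only G-runs in the sequence and a scanner must
#' recover exactly the recorded intervals.
#'
#' @param length total sequence length.
#' @param g_run_lengths integer vector of run lengths (each >= 1) to plant,
#'   reported left to right.
#' @param seed integer seed.
#' @return list with `sequence` (character string) and `runs`
#'   (`data.frame` of 0-based half-open `start`, `end`, `length`).
#' @export
simulateGRunSequence <- function(length, g_run_lengths, seed) {
  k <- base::length(g_run_lengths)
  need <- sum(g_run_lengths) + max(0L, k - 1L)  # >=1 non-G spacer between runs
  if (need > length)
    stop("planted runs do not fit in the requested length")
  with_rng(seed, {
    bg <- function(n) if (n > 0)
      paste(sample(c("A", "C", "T"), n, replace = TRUE), collapse = "")
      else ""
    if (k == 0L)
      return(list(sequence = bg(length),
                  runs = data.frame(start = integer(), end = integer(),
                                    length = integer())))
    # distribute the spare non-G bases randomly over the k+1 gaps
    spare <- length - need
    extra <- if (spare > 0) {
      tab <- tabulate(sample.int(k + 1L, spare, replace = TRUE), k + 1L)
    } else rep(0L, k + 1L)
    gaps <- extra + c(0L, rep(1L, max(0L, k - 1L)), 0L)
    pieces <- character(2L * k + 1L)
    starts <- integer(k)
    pos <- 0L
    for (i in seq_len(k)) {
      pieces[2L * i - 1L] <- bg(gaps[i])
      pos <- pos + gaps[i]
      starts[i] <- pos
      pieces[2L * i] <- strrep("G", g_run_lengths[i])
      pos <- pos + g_run_lengths[i]
    }
    pieces[2L * k + 1L] <- bg(gaps[k + 1L])
    list(sequence = paste(pieces, collapse = ""),
         runs = data.frame(start = starts,
                           end = starts + as.integer(g_run_lengths),
                           length = as.integer(g_run_lengths)))
  })
}
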