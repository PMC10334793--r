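test_that("Pearson r and p match hand computation and cor.test", {
  expect_equal(pearsonCorTest(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearsonCorTest(1:5, 2 * (1:5) + 1)$p, 0)
  expect_equal(pearsonCorTest(1:5, -(1:5))$r, -1)

  # hand covariance/variance: r = 8/10 = 0.8; t = 0.8*sqrt(3/0.36)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  res <- pearsonCorTest(x, y)
  expect_equal(res$r, 0.8)
  expect_equal(res$p, 2 * pt(-0.8 * sqrt(3 / 0.36), df = 3))
  expect_equal(res$p, 0.104088, tolerance = 1e-5)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)

  # symmetry and invariance to positive affine transforms
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(pearsonCorTest(a, b)$r, pearsonCorTest(b, a)$r)
    expect_equal(pearsonCorTest(2.5 * a + 1, b)$r, pearsonCorTest(a, b)$r)
    expect_equal(pearsonCorTest(2.5 * a + 1, b)$p, pearsonCorTest(a, b)$p)
  }

  # zero variance is unevaluable, not an error
  expect_false(pearsonCorTest(rep(1, 5), 1:5)$evaluable)
  # pairwise deletion of missing pairs
  expect_equal(pearsonCorTest(c(x, NA), c(y, 1))$n, 5L)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bhAdjust(0.02), 0.02)
  expect_equal(bhAdjust(rep(0.3, 4)), rep(0.3, 4))
  expect_equal(bhAdjust(c(0.01, 0.03, 0.04)), c(0.03, 0.04, 0.04))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0,1\\]")

  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p & adj <= 1))
    # monotone in the sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("PSI-activity correlation recovers a planted repressed exon", {
  cfg <- cohortConfig(seed = 17, n_events = 40, n_pathway_genes = 20,
                      n_background_genes = 50, coverage_mean = 500,
                      coupled_events = data.frame(event = 7L, b0 = 0,
                                                  b1 = -1.5))
  s <- simulateCohort(cfg)
  ne <- normalizeCounts(s$counts)
  sc <- pathwayScore(ne, s$truth$genes$gene_id[s$truth$genes$pathway])
  rec <- correlatePsiWithActivity(buildPsiMatrix(s$events), sc, s$metadata)
  expect_identical(rec$target_id[which.min(rec$r)], "SE00007")
  expect_lt(rec$p_adj[rec$target_id == "SE00007"], 1e-10)
  expect_equal(rec$direction[rec$target_id == "SE00007"], -1)
})

test_that("constant PSI and small n are flagged, never errors", {
  psi <- matrix(c(rep(0.5, 12), runif(12)), 2, byrow = TRUE,
                dimnames = list(c("const", "ok"), sprintf("s%02d", 1:12)))
  tot <- matrix(10, 2, 12, dimnames = dimnames(psi))
  pe <- new("PsiExperiment",
            SummarizedExperiment::SummarizedExperiment(
              assays = list(psi = psi, total = tot)))
  meta <- data.frame(sample = colnames(psi), cohort = "A")
  sc <- setNames(rnorm(12), colnames(psi))
  rec <- correlatePsiWithActivity(pe, sc, meta)
  expect_false(rec$evaluable[rec$target_id == "const"])
  expect_true(is.na(rec$p_value[rec$target_id == "const"]))

  # n below the floor: r reported, p withheld
  psi_na <- psi
  psi_na["ok", 1:8] <- NA
  tot_na <- tot; tot_na["ok", 1:8] <- 0
  pe2 <- new("PsiExperiment",
             SummarizedExperiment::SummarizedExperiment(
               assays = list(psi = psi_na, total = tot_na)))
  rec2 <- correlatePsiWithActivity(pe2, sc, meta, min_n = 10)
  row_ok <- rec2[rec2$target_id == "ok", ]
  expect_false(row_ok$evaluable)
  expect_false(is.na(row_ok$r))
  expect_true(is.na(row_ok$p_value))
})

test_that("BH families are per cohort, unlike pooled adjustment", {
  set.seed(5)
  psi <- matrix(runif(8 * 24), 8, 24,
                dimnames = list(sprintf("e%d", 1:8), sprintf("s%02d", 1:24)))
  tot <- matrix(10, 8, 24, dimnames = dimnames(psi))
  pe <- new("PsiExperiment",
            SummarizedExperiment::SummarizedExperiment(
              assays = list(psi = psi, total = tot)))
  meta <- data.frame(sample = colnames(psi),
                     cohort = rep(c("PRAD", "COAD"), each = 12))
  sc <- setNames(c(sort(runif(12)), rnorm(12)), colnames(psi))
  rec <- correlatePsiWithActivity(pe, sc, meta)
  # per-cohort BH equals applying the oracle to each cohort's p-vector
  for (co in c("PRAD", "COAD")) {
    sub <- rec[rec$cohort == co, ]
    expect_equal(sub$p_adj, oracle_bh(sub$p_value))
  }
  pooled <- correlatePsiWithActivity(pe, sc, meta, adjust = "pooled")
  expect_equal(pooled$p_adj, oracle_bh(pooled$p_value))
  expect_false(isTRUE(all.equal(rec$p_adj, pooled$p_adj)))
  expect_error(correlatePsiWithActivity(pe, sc,
    data.frame(sample = "zzz", cohort = "A")), "shared")
})

test_that("expression-activity correlation behaves like the PSI engine", {
  set.seed(11)
  sc <- setNames(rnorm(30), sprintf("s%02d", 1:30))
  vals <- rbind(self = sc, neg = -sc,
                noise = rnorm(30))
  colnames(vals) <- names(sc)
  ne <- new("NormalizedExpression", values = vals,
            sizeFactors = setNames(rep(1, 30), names(sc)))
  meta <- data.frame(sample = names(sc), cohort = "A")
  rec <- correlateExpressionWithActivity(ne, activity = sc, meta = meta)
  expect_equal(rec$r[rec$target_id == "self"], 1)
  expect_equal(rec$r[rec$target_id == "neg"], -1)
  expect_error(correlateExpressionWithActivity(ne, genes = "nope",
    activity = sc, meta = meta), "absent")
})

test_that("pathway genes correlate positively with activity scores", {
  hits <- vapply(1:5, function(seed) {
    s <- simulateCohort(cohortConfig(seed = seed, n_events = 5,
      n_pathway_genes = 20, n_background_genes = 60,
      stages = data.frame(label = c("n", "b", "t"), n = c(50L, 50L, 50L),
                          activity_mean = c(0, 1, 2),
                          activity_sd = c(0.5, 0.5, 0.5))))
    ne <- normalizeCounts(s$counts)
    genes <- s$truth$genes$gene_id[s$truth$genes$pathway]
    sc <- pathwayScore(ne, genes)
    rec <- correlateExpressionWithActivity(ne, genes = genes,
                                           activity = sc, meta = s$metadata)
    all(rec$r > 0)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("permutation p-values are deterministic and bounded", {
  set.seed(2)
  x <- rnorm(30); y <- x + rnorm(30, sd = 0.1)
  r1 <- permutationPvalue(x, y, B = 200, seed = 5)
  r2 <- permutationPvalue(x, y, B = 200, seed = 5)
  expect_identical(r1, r2)
  # observed r exceeding every permutation -> p = 1/(B+1)
  expect_equal(r1$p, 1 / 201)
  expect_false(permutationPvalue(rep(1, 30), y, B = 100, seed = 1)$evaluable)
})
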