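test_that("median-of-ratios size factors match the hand oracle", {
  m <- matrix(c(10, 100, 4, 20, 200, 8), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  sf <- computeSizeFactors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sf), unname(oracle_size_factors(m)))

  # identical samples -> all factors 1
  m2 <- matrix(rep(c(5L, 9L, 30L), 3), nrow = 3,
               dimnames = list(paste0("g", 1:3), c("A", "B", "C")))
  expect_equal(unname(computeSizeFactors(m2)), rep(1, 3))

  # scale equivariance: doubling one sample doubles its factor ratio
  m3 <- m2; m3[, 2] <- m3[, 2] * 2L
  sf3 <- computeSizeFactors(m3)
  expect_equal(unname(sf3[2] / sf3[1]), 2)

  # random matrices agree with the oracle (odd gene count: the median is
  # then an order statistic, immune to interpolation conventions)
  set.seed(42)
  for (i in 1:5) {
    r <- matrix(rpois(66, 50) + 1L, nrow = 11,
                dimnames = list(sprintf("g%d", 1:11), sprintf("s%d", 1:6)))
    expect_equal(unname(computeSizeFactors(r)),
                 unname(oracle_size_factors(r)))
  }
})

test_that("size factors error when no gene survives the zero filter", {
  m <- matrix(c(0L, 5L, 3L, 0L), 2, dimnames = list(c("g1", "g2"),
                                                    c("A", "B")))
  expect_error(computeSizeFactors(m), "pseudo-reference")
})

test_that("normalization transforms as log2(count/s + 1)", {
  m <- matrix(c(0L, 7L, 14L, 0L), 2, dimnames = list(c("g1", "g2"),
                                                     c("A", "B")))
  ne <- normalizeCounts(m, size_factors = c(A = 1, B = 2))
  expect_equal(exprValues(ne)["g1", "A"], 0)       # log2(0 + 1)
  expect_equal(exprValues(ne)["g2", "A"], log2(8)) # count 7, s = 1 -> 3
  expect_equal(exprValues(ne)["g1", "B"], log2(8)) # 14 / 2 + 1
  expect_equal(unname(sizeFactors(ne)), c(1, 2))

  # doubling counts and size factors jointly leaves values unchanged
  ne2 <- normalizeCounts(m * 2L, size_factors = c(A = 2, B = 4))
  expect_equal(exprValues(ne2), exprValues(ne))

  expect_error(normalizeCounts(m, size_factors = c(1, 0)), "> 0")
})

test_that("mean-z pathway scores follow the z-score definition", {
  vals <- matrix(c(1, 2, 3), 1, dimnames = list("g1", c("a", "b", "c")))
  ne <- new("NormalizedExpression", values = vals,
            sizeFactors = c(a = 1, b = 1, c = 1))
  sc <- pathwayScore(ne, "g1", minGenes = 1)
  # one gene, values (1,2,3), sample (n-1) sd = 1 -> z = (-1, 0, 1)
  expect_equal(unname(scores(sc)), c(-1, 0, 1))

  # identical samples -> all scores 0 (zero-variance genes contribute 0)
  vals2 <- matrix(5, 3, 4, dimnames = list(paste0("g", 1:3),
                                           paste0("s", 1:4)))
  ne2 <- new("NormalizedExpression", values = vals2,
             sizeFactors = setNames(rep(1, 4), paste0("s", 1:4)))
  sc2 <- pathwayScore(ne2, paste0("g", 1:3), minGenes = 1)
  expect_equal(unname(scores(sc2)), rep(0, 4))
})

test_that("scores have mean zero and ignore gene order and duplicates", {
  set.seed(1)
  vals <- matrix(rnorm(200), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("s%02d", 1:10)))
  ne <- new("NormalizedExpression", values = vals,
            sizeFactors = setNames(rep(1, 10), colnames(vals)))
  genes <- sprintf("g%02d", 1:8)
  sc <- pathwayScore(ne, genes)
  expect_lt(abs(mean(scores(sc))), 1e-10)
  # gene order and duplicated entries do not change the score
  sc_perm <- pathwayScore(ne, rev(genes))
  sc_dup <- pathwayScore(ne, c(genes, genes[1]))
  expect_equal(scores(sc_perm), scores(sc))
  expect_equal(scores(sc_dup), scores(sc))
  # duplicated background genes (rows) of the matrix are irrelevant too
  ne_bg <- new("NormalizedExpression",
               values = rbind(vals, dup = vals[20, ]),
               sizeFactors = setNames(rep(1, 10), colnames(vals)))
  expect_equal(scores(pathwayScore(ne_bg, genes)), scores(sc))
})

test_that("missing gene-set genes warn, and the floor errors", {
  vals <- matrix(rnorm(50), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  ne <- new("NormalizedExpression", values = vals,
            sizeFactors = setNames(rep(1, 10), colnames(vals)))
  expect_warning(sc <- pathwayScore(ne, c(paste0("g", 1:5), "absent"),
                                    minGenes = 5), "absent")
  expect_identical(sc@nGenesUsed, 5L)
  expect_error(pathwayScore(ne, c("g1", "g2", "nope"), minGenes = 3),
               "nope")
})

test_that("scores recover the latent activity on simulated cohorts", {
  rs <- vapply(1:3, function(seed) {
    s <- simulateCohort(cohortConfig(seed = seed, n_events = 5,
                                     n_pathway_genes = 30,
                                     n_background_genes = 120,
                                     pathway_response = 0.5,
                                     stages = data.frame(
                                       label = c("n", "b", "t"),
                                       n = c(50L, 50L, 50L),
                                       activity_mean = c(0, 1, 2),
                                       activity_sd = c(0.5, 0.5, 0.5))))
    ne <- normalizeCounts(s$counts)
    genes <- s$truth$genes$gene_id[s$truth$genes$pathway]
    cor(scores(pathwayScore(ne, genes)), s$truth$activity)
  }, numeric(1))
  expect_gt(mean(rs), 0.8)
})

test_that("rank-ssgsea is a monotone alternative scoring method", {
  s <- simulateCohort(cohortConfig(seed = 13, n_events = 5,
                                   n_pathway_genes = 30,
                                   n_background_genes = 120))
  ne <- normalizeCounts(s$counts)
  genes <- s$truth$genes$gene_id[s$truth$genes$pathway]
  sc_z <- pathwayScore(ne, genes, method = "mean-z")
  sc_r <- pathwayScore(ne, genes, method = "rank-ssgsea")
  expect_gt(cor(scores(sc_z), scores(sc_r)), 0.8)
  expect_gt(cor(scores(sc_r), s$truth$activity), 0.8)
})
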