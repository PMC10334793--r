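test_that("G-run scanning finds maximal runs with classes", {
  expect_identical(nrow(findGRuns("ACACAC")), 0L)
  r <- findGRuns("AGGGGT")
  expect_equal(r$start, 1); expect_equal(r$end, 5)
  expect_identical(r$class, "G4plus")
  r2 <- findGRuns("TGGGTAGGGGCGGG")
  expect_equal(r2$start, c(1, 6, 11))
  expect_equal(r2$end, c(4, 10, 14))
  expect_identical(r2$class, c("G3", "G4plus", "G3"))
  expect_error(findGRuns("AGGGN"), "position 5")
})

test_that("G-run scanning equals the regex oracle on random sequences", {
  set.seed(19)
  for (i in 1:300) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE,
                      prob = c(0.2, 0.2, 0.4, 0.2)), collapse = "")
    found <- findGRuns(s)
    expected <- oracle_g_runs(s)
    expect_equal(found$start, expected$start)
    expect_equal(found$end, expected$end)
    # maximality: runs are separated by >= 1 non-G base
    if (nrow(found) > 1)
      expect_true(all(found$start[-1] > found$end[-nrow(found)]))
  }
})

test_that("default tiling abuts tiles and reports uncovered remainder", {
  t36 <- designTiles(36)
  expect_identical(nrow(t36), 2L)
  expect_equal(t36$start, c(0, 18))
  expect_equal(t36$end, c(18, 36))
  expect_identical(attr(t36, "uncovered"), 0L)

  # 94 + 82 + 200 nt window: floor(376/18) = 20 tiles, 16 nt uncovered
  t376 <- designTiles(94 + 82 + 200)
  expect_identical(nrow(t376), 20L)
  expect_identical(attr(t376, "uncovered"), 16L)
  expect_true(all(t376$overlap_with_previous == 0))

  expect_error(designTiles(10, tile_len = 18), "exceeds")
})

test_that("scheduled tiling honors offsets and records overlaps", {
  # a 22-tile panel: mostly abutting, four tiles overlapping their
  # upstream neighbor by 12, 17, 13 and 1 nt
  starts <- c(0, 18, 36, 42, 60, 78, 96, 114, 132, 150, 151, 169, 187,
              205, 223, 241, 259, 277, 282, 300, 318, 335)
  sched <- designTiles(376, schedule = starts)
  expect_identical(nrow(sched), 22L)
  expect_equal(sched$overlap_with_previous[c(4, 11, 19, 22)],
               c(12, 17, 13, 1))
  expect_equal(sum(sched$overlap_with_previous > 0), 4)
  expect_error(designTiles(376, schedule = c(0, 370)), "out of window")
})

test_that("tile sequences are reverse complements of the window slice", {
  s <- "ATGCATGCATGCATGCAT"  # 18 nt window, one tile
  t1 <- designTiles(sequence = s, tile_len = 18)
  expect_identical(t1$sequence,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(s))))
  expect_identical(nchar(t1$sequence), 18L)
})

test_that("ASO effects classify into silencer/enhancer/none", {
  # blocking a silencer raises inclusion above the ~10% NTC baseline
  up <- classifyAsoEffect(c(14.7, 14.8, 14.9), c(9.9, 10.0, 10.1))
  expect_identical(up$direction, "increase")
  expect_identical(up$element_class, "silencer")
  expect_equal(up$mean_psi_treated, 14.8)
  # blocking an enhancer drops inclusion (~6.4%)
  down <- classifyAsoEffect(c(6.3, 6.4, 6.5), c(9.9, 10.0, 10.1))
  expect_identical(down$direction, "decrease")
  expect_identical(down$element_class, "enhancer")
  # identical replicate sets are ns/none
  same <- classifyAsoEffect(c(10, 10.1), c(10, 10.1))
  expect_identical(same$element_class, "none")
  expect_error(classifyAsoEffect(10, c(9, 10)), "replicates")

  # matches stats::t.test exactly
  tt <- t.test(c(14.7, 14.8, 14.9), c(9.9, 10.0, 10.1), var.equal = TRUE)
  expect_equal(up$p_value, tt$p.value)
})

test_that("classification is antisymmetric under arm swap", {
  set.seed(23)
  for (i in 1:20) {
    a <- rnorm(3, mean = runif(1, 5, 20))
    b <- rnorm(3, mean = runif(1, 5, 20))
    ab <- classifyAsoEffect(a, b)
    ba <- classifyAsoEffect(b, a)
    expect_equal(ab$p_value, ba$p_value)
    flip <- c(increase = "decrease", decrease = "increase", ns = "ns")
    expect_identical(ba$direction, unname(flip[ab$direction]))
    flipc <- c(silencer = "enhancer", enhancer = "silencer", none = "none")
    expect_identical(ba$element_class, unname(flipc[ab$element_class]))
  }
})

test_that("panel calls report both raw-alpha and BH-adjusted classes", {
  panel <- list(
    I5_1 = c(14.7, 14.8, 14.9),
    I5_3 = c(6.3, 6.4, 6.5),
    I5_2 = c(9.9, 10.2, 10.0),
    E5_2 = c(10.05, 9.95, 10.0))
  calls <- callAsoPanel(panel, psi_ntc = c(9.9, 10.0, 10.1))
  expect_identical(calls$element_class[calls$tile_id == "I5_1"], "silencer")
  expect_identical(calls$element_class[calls$tile_id == "I5_3"], "enhancer")
  expect_identical(calls$element_class[calls$tile_id == "E5_2"], "none")
  expect_equal(calls$p_adj, unname(bhAdjust(calls$p_value)))
  expect_true(all(c("element_class", "element_class_bh") %in%
                  colnames(calls)))
})

test_that("element maps place tiles and G-runs in genomic coordinates", {
  tiles <- designTiles(36)
  calls <- callAsoPanel(
    list(ASO01 = c(14.7, 14.8, 14.9), ASO02 = c(10.0, 10.1, 9.9)),
    psi_ntc = c(9.9, 10.0, 10.1))
  gruns <- findGRuns("AAAGGGTTTTTTTTTTTTTTTTGGGGAAAAAAAAAA")
  bed <- buildElementMap(tiles, calls, gruns, window_origin = 1000,
                         window_length = 36, chrom = "chr11")
  expect_identical(nrow(bed), 4L)  # 2 tiles + 2 G-runs
  expect_equal(bed$start[1], 1000)
  expect_equal(bed$end[2], 1036)
  expect_identical(bed$name[1], "ASO01|silencer")
  expect_identical(bed$name[2], "ASO02|none")
  expect_equal(bed$start[3], 1003)  # G-run at local 3..6
  # enhancer tile nests its G-runs
  expect_true(bed$start[3] >= bed$start[1] && bed$end[3] <= bed$end[1])

  # dangling call errors
  bad <- calls; bad$tile_id[1] <- "ASO99"
  expect_error(buildElementMap(tiles, bad, gruns, 1000, 36, "chr11"),
               "unknown tiles")
})

test_that("minus-strand mapping mirror-maps and round-trips", {
  set.seed(31)
  L <- 376
  starts <- sample(0:(L - 18), 10)
  ends <- starts + 18
  g <- SpliceActivity:::local_to_genomic(starts, ends, 5000, L, "-")
  back <- SpliceActivity:::genomic_to_local(g$start, g$end, 5000, L, "-")
  expect_equal(back$start, starts)
  expect_equal(back$end, ends)
  # plus strand is a simple shift
  gp <- SpliceActivity:::local_to_genomic(starts, ends, 5000, L, "+")
  expect_equal(gp$start, starts + 5000)
  # lengths are preserved either way
  expect_true(all(g$end - g$start == 18))
})
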