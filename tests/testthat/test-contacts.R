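test_that("readContacts parses triplets, sums mirrored records and round-trips", {
  fx <- writeTinyContacts()
  m <- readContacts(fx$contacts, fx$sizes, 1e4)
  expect_equal(nrow(contactCounts(m)), 2)
  expect_equal(sum(contactCounts(m)$count), 8)

  ## a record on (i,j) and (j,i) collapses into one upper-triangular entry
  writeLines(c("chrom1\tstart1\tchrom2\tstart2\tcount",
               "chrA\t0\tchrA\t10000\t3",
               "chrA\t10000\tchrA\t0\t4"), fx$contacts)
  m2 <- readContacts(fx$contacts, fx$sizes, 1e4)
  expect_equal(nrow(contactCounts(m2)), 1)
  expect_equal(contactCounts(m2)$count, 7)

  ## write -> read preserves all entries exactly
  p <- file.path(fx$dir, "roundtrip.tsv.gz")
  writeContacts(benchMap10(), p)
  sz <- file.path(fx$dir, "bench.sizes")
  writeChromsizes(benchGenome(), sz)
  m3 <- readContacts(p, sz, 1e4)
  expect_identical(contactCounts(m3), contactCounts(benchMap10()))
})

test_that("readContacts reports parse errors with line numbers", {
  fx <- writeTinyContacts()
  writeLines(c("chrom1\tstart1\tchrom2\tstart2\tcount",
               "chrX\t0\tchrA\t0\t5"), fx$contacts)
  expect_error(readContacts(fx$contacts, fx$sizes, 1e4), "line 2")
  writeLines(c("chrom1\tstart1\tchrom2\tstart2\tcount",
               "chrA\t0\tchrA\t0\t2",
               "chrA\t5000\tchrA\t0\t5"), fx$contacts)
  expect_error(readContacts(fx$contacts, fx$sizes, 1e4), "line 3")
  writeLines(c("chrom1\tstart1\tchrom2\tstart2\tcount",
               "chrA\t0\tchrA\t0\t-2"), fx$contacts)
  expect_error(readContacts(fx$contacts, fx$sizes, 1e4), "negative")
})

test_that("normalizeLibrary rescales to the target and is idempotent", {
  m <- benchMap10()
  mn <- normalizeLibrary(m, 1e9)
  expect_equal(totalContacts(mn), 1e9, tolerance = 1e-9)
  ## scale factor example: total 2e6 -> factor 500
  fx <- writeTinyContacts()
  writeLines(c("chrom1\tstart1\tchrom2\tstart2\tcount",
               "chrA\t0\tchrA\t10000\t1000000"), fx$contacts)
  m2 <- readContacts(fx$contacts, fx$sizes, 1e4)
  expect_equal(totalContacts(m2), 2e6)
  m2n <- normalizeLibrary(m2, 1e9)
  expect_equal(contactCounts(m2n)$count, 5e8)  # 1e6 * 500
  ## identity when the target equals the current total
  expect_equal(contactCounts(normalizeLibrary(m2, 2e6))$count, 1e6)
  ## diagonal-only map: {(0,0): 4} -> {(0,0): 8} at target 8
  writeLines(c("chrom1\tstart1\tchrom2\tstart2\tcount",
               "chrA\t0\tchrA\t0\t4"), fx$contacts)
  m3 <- readContacts(fx$contacts, fx$sizes, 1e4)
  expect_equal(contactCounts(normalizeLibrary(m3, 8))$count, 8)
  ## idempotence
  expect_equal(contactCounts(normalizeLibrary(mn, 1e9))$count,
               contactCounts(mn)$count, tolerance = 1e-12)
})

test_that("normalizeLibrary rejects an empty map", {
  g <- makeGenome(0, 1, mic_range = c(1e6, 1e6), seed = 1)
  empty <- new("ContactMap", resolution = 1e4, genome = g,
               counts = data.table::data.table(bin1 = integer(),
                                               bin2 = integer(),
                                               count = numeric()))
  expect_error(normalizeLibrary(empty), "empty")
})

test_that("iceBalance equalizes row sums and matches an independent Sinkhorn oracle", {
  ## fixed point: an equal-row-sum matrix is unchanged up to scale
  m <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3)
  bm <- iceBalance(m, tol = 1e-10, max_iter = 5000)
  expect_equal(balancedMatrix(bm), m, tolerance = 1e-6)
  expect_equal(biasVector(bm), rep(1, 3), tolerance = 1e-4)

  ## oracle: symmetric Sinkhorn iteration written independently
  raw <- matrix(c(0, 2, 2, 2, 0, 6, 2, 6, 0), 3)
  b <- rep(1, 3)
  for (k in 1:20000) {
    w <- raw / outer(b, b)
    b <- b * sqrt(rowSums(w) / mean(rowSums(w)))
  }
  oracle <- raw / outer(b, b)
  oracle <- oracle * sum(raw) / sum(oracle)
  bm2 <- iceBalance(raw, tol = 1e-10, max_iter = 5000)
  rs <- rowSums(balancedMatrix(bm2))
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-9)
  expect_equal(balancedMatrix(bm2), oracle, tolerance = 1e-6)

  ## bias reconstruction: balanced * (b %o% b) recovers the raw matrix
  rec <- balancedMatrix(bm2) * outer(biasVector(bm2), biasVector(bm2))
  expect_lt(max(abs(rec - raw)), 1e-8)
})

test_that("iceBalance masks empty bins and refuses an all-masked matrix", {
  m <- matrix(c(0, 2, 0, 2, 0, 0, 0, 0, 0), 3)
  m[3, ] <- 0; m[, 3] <- 0
  bm <- iceBalance(m)
  expect_false(validBins(bm)[3])
  expect_true(all(balancedMatrix(bm)[3, ] == 0))
  expect_true(is.na(biasVector(bm)[3]))
  expect_error(iceBalance(matrix(0, 4, 4)), "too sparse")
})

test_that("observed/expected flattens distance-only matrices to ones", {
  n <- 30
  D <- abs(outer(1:n, 1:n, "-"))
  m <- (1 + D)^(-0.8) * 100
  bm <- new("BalancedMatrix", chrom = "chr1", resolution = 1e4,
            matrix = m, bias = rep(1, n), valid = rep(TRUE, n))
  ov <- observedOverExpected(bm)
  expect_equal(max(abs(ov$oe - 1)), 0, tolerance = 1e-12)
  expect_equal(ov$decay$expected, (1 + 0:(n - 1))^(-0.8) * 100)
  ## O/E of an all-ones-decay matrix is the identity transformation
  bm2 <- new("BalancedMatrix", chrom = "chr1", resolution = 1e4,
             matrix = ov$oe, bias = rep(1, n), valid = rep(TRUE, n))
  ov2 <- observedOverExpected(bm2)
  expect_equal(ov2$oe, ov$oe, tolerance = 1e-12)
})

test_that("observed/expected separates planted compartment blocks", {
  ## two-block checkerboard in the expected model: within-block O/E above
  ## between-block O/E
  n <- 40
  s <- rep(c(1, -1), each = 20)
  D <- abs(outer(1:n, 1:n, "-"))
  m <- (1 + D)^(-1) * ifelse(outer(s, s) > 0, 2.5, 1)
  bm <- new("BalancedMatrix", chrom = "chr1", resolution = 1e5,
            matrix = m, bias = rep(1, n), valid = rep(TRUE, n))
  ov <- observedOverExpected(bm)
  within <- ov$oe[outer(s, s) > 0 & D > 0]
  between <- ov$oe[outer(s, s) < 0]
  expect_gt(mean(within), mean(between))
})

test_that("interaction summary classes partition all chromosome pairs", {
  m <- benchMap10()
  sm <- interactionSummary(m)
  nch <- length(chromNames(benchGenome()))
  expect_equal(nrow(sm$pairs), nch * (nch + 1) / 2)
  expect_true(all(sm$pairs$frequency >= 0))
  ## all-MIC genome: MAC classes are absent, tests degrade to NA not error
  expect_true(is.na(sm$tests[comparison == "micmic_vs_macmac", p_value]))
  expect_false(is.na(sm$tests[comparison == "intra_vs_inter", p_value]))
})

test_that("intra-chromosomal interactions dominate inter ones", {
  sm <- interactionSummary(benchMap10())
  intra <- sm$pairs[grepl("intra", class), frequency]
  inter <- sm$pairs[grepl("inter", class), frequency]
  expect_gt(min(intra), max(inter))
  expect_lt(sm$tests[comparison == "intra_vs_inter", p_value], 0.05)
})

test_that("the planted MIC-MIC trans boost is recovered across seeds", {
  g <- makeGenome(3, 3, c(5.2e7, 5.5e7), c(6e6, 9e6), seed = 13)
  tr <- plantTruth(g, n_boundaries_per_chrom = 2, n_loops = 0, seed = 13)
  ps <- vapply(1:5, function(s) {
    m <- simulateContacts(g, tr, resolution = 1e5, depth = 5e6,
                          trans_level = 0.05, mic_trans_boost = 2, seed = s)
    sm <- interactionSummary(m)
    cm <- sm$class_means
    expect_gt(cm[class == "inter-MIC-MIC", mean_frequency],
              cm[class == "inter-MAC-MAC", mean_frequency])
    sm$tests[comparison == "micmic_vs_macmac", p_value]
  }, numeric(1))
  expect_true(median(ps) < 0.05)
})
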