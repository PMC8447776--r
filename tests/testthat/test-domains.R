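## naive windowed-mean oracle for the insulation square, written
## independently of the package implementation
naiveInsulation <- function(m, w) {
  n <- nrow(m)
  raw <- rep(NA_real_, n)
  for (i in (w + 1):(n - w + 1)) {
    vals <- m[(i - w):(i - 1), i:(i + w - 1)]
    raw[i] <- mean(vals)
  }
  raw
}

toyBalanced <- function(m, res = 1e4) {
  new("BalancedMatrix", chrom = "chr1", resolution = res, matrix = m,
      bias = rep(1, nrow(m)), valid = rep(TRUE, nrow(m)))
}

test_that("insulation of a uniform matrix is exactly zero", {
  m <- matrix(5, 20, 20)
  tr <- insulationScore(toyBalanced(m), window = 3e4)
  expect_lt(max(abs(tr$score[tr$valid])), 1e-12)
  expect_equal(sum(tr$valid), 15)   # bins with a full in-bounds window
})

test_that("a perfectly insulated junction is the unique insulation minimum", {
  ## 12-bin toy: two 6-bin blocks, zero inter-block contact
  n <- 12; w <- 2
  m <- matrix(0, n, n)
  m[1:6, 1:6] <- 4; m[7:12, 7:12] <- 4
  diag(m) <- 8
  tr <- insulationScore(toyBalanced(m), window = w * 1e4)
  ## oracle: hand-computed windowed means; junction square (rows 5:6 x
  ## cols 7:8 at i = 7) is all zero, every other valid square is not
  raw <- naiveInsulation(m, w)
  expect_equal(which(raw == 0), 7)
  v <- which(tr$valid)
  expect_equal(v[which.min(tr$score[v])], 7)
  expect_equal(sum(tr$score[v] == min(tr$score[v])), 1)
  ## scores agree with the oracle up to the common normalization
  lo <- log2(pmax(raw[v], min(raw[v][raw[v] > 0]) / 2))
  expect_equal(tr$score[v], lo - mean(lo), tolerance = 1e-12)
})

test_that("insulation is invariant to global scaling of the matrix", {
  m <- chromMatrix(benchMap10(), "chr3")[1:80, 1:80]
  m <- m + t(m)
  t1 <- insulationScore(toyBalanced(m))
  t2 <- insulationScore(toyBalanced(m * 7.3))
  expect_equal(t1$score, t2$score, tolerance = 1e-12)
})

test_that("boundary calling honors its threshold and zero-crossing contracts", {
  ## monotone insulation track: no negative-to-positive crossing
  tr <- data.table::data.table(chrom = "chr1", start = (0:99) * 1e4,
                               score = seq(-1, 1, length.out = 100),
                               valid = TRUE)
  expect_equal(nrow(callBoundaries(tr)), 0)
  ## an infinite strength threshold silences every boundary
  expect_equal(nrow(callBoundaries(benchInsulation(),
                                   min_strength = Inf)), 0)
})

test_that("planted boundaries are recovered with high recall and precision", {
  b <- benchBoundaries()
  tb <- truthBoundaries(benchTruth())
  hit <- vapply(seq_len(nrow(tb)), function(k)
    any(b$chrom == tb$chrom[k] & abs(b$start - tb$pos[k]) <= 1e4),
    logical(1))
  prec <- vapply(seq_len(nrow(b)), function(k)
    any(tb$chrom == b$chrom[k] & abs(tb$pos - b$start[k]) <= 1e4),
    logical(1))
  ## achieved on the benchmark fixture: recall ~0.98, precision ~0.93
  expect_gte(mean(hit), 0.8)
  expect_gte(mean(prec), 0.8)
})

test_that("padBoundaries widens 10 kb bins to 90 kb and flags clipped edges", {
  g <- benchGenome()
  raw <- data.table::data.table(chrom = "chr1",
                                start = c(0, 1e6), strength = c(1, 1))
  out <- padBoundaries(raw, g, resolution = 1e4, pad = 4e4)
  ## interior bin [1,000,000, 1,010,000) -> [960,000, 1,050,000)
  expect_equal(out[start == 960000, end], 1050000)
  expect_equal(out[!clipped == TRUE, end - start], 90000)
  ## bin at the chromosome start is clipped to [0, 50,000) and flagged
  expect_equal(out[clipped == TRUE, .(start, end)],
               data.table::data.table(start = 0, end = 50000))
  ## pad = 0 is the identity padding
  out0 <- padBoundaries(raw, g, resolution = 1e4, pad = 0)
  expect_true(all(out0$end - out0$start == 1e4))
  ## count and order preserved
  expect_equal(nrow(out), nrow(raw))
  expect_true(all(diff(out$start) > 0))
})

test_that("boundary overlap statistics behave on identical, disjoint and shifted sets", {
  g <- benchGenome()
  A <- padBoundaries(benchBoundaries(), g)
  self <- boundaryOverlap(A, A)
  expect_equal(self$common_frac_A, 1)
  expect_equal(self$common_frac_B, 1)
  expect_equal(self$jaccard, 1)

  B <- data.table::copy(A)[, `:=`(start = start + 4e4, end = end + 4e4)]
  shifted <- boundaryOverlap(A, B)
  expect_equal(shifted$common_frac_A, 1)  # 40 kb shift < 90 kb width

  far <- data.table::copy(A)[, `:=`(start = start + 2e5, end = end + 2e5)]
  ## a 200 kb shift can still collide with a neighboring boundary, so use
  ## a synthetic disjoint set instead
  C <- data.table::data.table(chrom = "chr1", start = c(0, 1e5),
                              end = c(9e4, 1.9e5))
  D <- data.table::data.table(chrom = "chr2", start = c(0), end = c(9e4))
  disjoint <- boundaryOverlap(C, D)
  expect_equal(disjoint$common_frac_A, 0)
  expect_equal(disjoint$jaccard, 0)
  ## Jaccard is symmetric
  expect_equal(boundaryOverlap(A, B)$jaccard, boundaryOverlap(B, A)$jaccard)
})

test_that("deriveTads spans between boundary midpoints and handles sparse chromosomes", {
  g <- makeGenome(0, 1, mic_range = c(3e6, 3e6), seed = 1)
  bd <- data.table::data.table(chrom = "chr1",
                               start = c(955000, 1955000),
                               end = c(1045000, 2045000))
  tads <- deriveTads(bd, g)
  expect_equal(tads$start, c(0, 1e6, 2e6))
  expect_equal(tads$end, c(1e6, 2e6, 3e6))
  ## fewer than 2 boundaries: single whole-chromosome domain
  t1 <- deriveTads(bd[1], g)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$end - t1$start, 3e6)
  ## domains never smaller than 3 bins
  tads2 <- deriveTads(padBoundaries(benchBoundaries(), benchGenome()),
                      benchGenome())
  expect_true(all(tads2$end - tads2$start >= 3e4))
  ## TADs tile each chromosome without overlap
  gaps <- tads2[, all(abs(start[-1] - end[-.N]) < 1e-9), by = chrom]$V1
  expect_true(all(gaps))
})

test_that("features on a boundary are counted in the boundary, not the TAD", {
  g <- makeGenome(0, 1, mic_range = c(3e6, 3e6), seed = 1)
  bd <- data.table::data.table(chrom = "chr1", start = 955000, end = 1045000)
  tads <- data.table::data.table(chrom = "chr1", start = c(0, 1e6),
                                 end = c(1e6, 3e6))
  feats <- data.table::data.table(chrom = "chr1",
                                  tss = c(955000, 1044999, 1045000, 5e5))
  ct <- countFeatures(tads, bd, feats)
  expect_equal(ct$boundary_count, 2)   # both half-open boundary hits
  expect_equal(ct$tad_count, 2)        # 1045000 falls back into the TAD
})

test_that("boundary-biased features show higher boundary density across seeds", {
  g <- benchGenome()
  bd <- padBoundaries(benchBoundaries(), g)
  tads <- deriveTads(bd, g)
  len <- chromLengths(g)
  bias_ok <- vapply(1:40, function(s) {
    set.seed(s)
    ## place 200 features, 3x density inside boundary intervals
    inb <- runif(200) < (3 * sum(bd$end - bd$start)) /
      (3 * sum(bd$end - bd$start) + (sum(len) - sum(bd$end - bd$start)))
    pos <- numeric(200); chv <- character(200)
    nb <- sum(inb)
    if (nb) {
      pick <- sample(nrow(bd), nb, replace = TRUE,
                     prob = bd$end - bd$start)
      chv[inb] <- bd$chrom[pick]
      pos[inb] <- floor(runif(nb, bd$start[pick], bd$end[pick]))
    }
    out <- sample(names(len), 200 - nb, replace = TRUE, prob = len)
    chv[!inb] <- out
    pos[!inb] <- floor(runif(200 - nb, 0, len[out]))
    ct <- countFeatures(tads, bd, data.table::data.table(chrom = chv,
                                                         tss = pos))
    ct$boundary_density > ct$tad_density
  }, logical(1))
  expect_gte(mean(bias_ok), 0.95)
})
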