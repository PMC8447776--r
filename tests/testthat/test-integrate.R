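test_that("peak enrichment recovers the planted compartment bias", {
  tb <- truthBlocks(compTruth())
  ablocks <- tb[label == "A", .(chrom, start, end)]
  pk <- simulatePeaks(compTruth(), compGenome(), a_bias = 0.9,
                      n_peaks = 400, seed = 23)
  en <- peakFeatureEnrichment(pk$H3ac, ablocks, compGenome(),
                              n_shuffles = 300, seed = 23)
  expect_gt(en$z, 3)
  expect_gt(en$odds_ratio, 1)
  expect_lt(en$fisher_p, 0.01)
  ## the repressive mark is enriched in B, i.e. depleted in A
  enk <- peakFeatureEnrichment(pk$H3K27me3, ablocks, compGenome(),
                               n_shuffles = 300, seed = 23)
  expect_lt(enk$z, -3)
})

test_that("unbiased peaks show no enrichment and edge cases degrade", {
  tb <- truthBlocks(compTruth())
  ablocks <- tb[label == "A", .(chrom, start, end)]
  ## a_bias at the boundary of its domain: approximately null placement
  pk <- simulatePeaks(compTruth(), compGenome(), a_bias = 0.501,
                      n_peaks = 400, seed = 29)
  en <- peakFeatureEnrichment(pk$H3ac, ablocks, compGenome(),
                              n_shuffles = 300, seed = 29)
  expect_lt(abs(en$z), 3)
  ## whole-genome features: odds ratio undefined, flagged not-applicable
  len <- chromLengths(compGenome())
  whole <- data.table::data.table(chrom = names(len), start = 0,
                                  end = as.numeric(len))
  enw <- peakFeatureEnrichment(pk$H3ac, whole, compGenome(),
                               n_shuffles = 50, seed = 1)
  expect_equal(enw$observed_frac, 1)
  expect_true(is.na(enw$odds_ratio))
  ## empty input: not-applicable, no error
  none <- peakFeatureEnrichment(pk$H3ac[0], ablocks, compGenome())
  expect_true(is.na(none$z))
})

test_that("promoter fractions follow the strand-aware half-open convention", {
  genes <- data.table::data.table(
    chrom = "chr1", start = c(5000, 20000), end = c(15000, 30000),
    gene = c("g1", "g2"), score = 0, strand = c("+", "-"),
    tss = c(5000, 29999))
  ## peaks centered in each promoter
  pk_in <- data.table::data.table(
    chrom = "chr1", start = c(4400, 30200), end = c(4600, 30400))
  expect_equal(promoterStats(pk_in, genes), 1)
  ## a peak whose midpoint sits exactly at the + strand TSS is outside
  pk_at <- data.table::data.table(chrom = "chr1", start = 4950, end = 5050)
  expect_equal(promoterStats(pk_at, genes), 0)
})

test_that("random peaks hit promoters at the analytic rate", {
  g <- compGenome()
  ae <- compAnnot()
  len <- chromLengths(g)
  prom_bp <- 1000 * nrow(ae$genes)
  f <- prom_bp / sum(len)
  set.seed(77)
  n <- 20000
  ch <- sample(names(len), n, replace = TRUE, prob = len)
  st <- floor(runif(n, 0, len[ch] - 200))
  pk <- data.table::data.table(chrom = ch, start = st, end = st + 200)
  obs <- promoterStats(pk, ae$genes)
  expect_lt(abs(obs - f), 4 * sqrt(f * (1 - f) / n) + 1e-4)
})

test_that("TSS meta-profiles peak centrally, vanish without peaks and flatten under uniform cover", {
  genes <- data.table::data.table(
    chrom = "chr1", start = seq(1e5, 9e5, 1e5), end = seq(1e5, 9e5, 1e5) + 2e4,
    gene = sprintf("g%d", 1:9), score = 0,
    strand = rep(c("+", "-", "+"), 3))
  genes[, tss := ifelse(strand == "+", start, end - 1)]
  ## one 200 bp peak centered at every TSS
  pk <- data.table::data.table(chrom = "chr1", start = genes$tss - 100,
                               end = genes$tss + 100)
  prof <- tssMetaprofile(pk, genes, flank = 3000, bin = 100)
  expect_equal(nrow(prof), 60)
  central <- prof[position %in% c(-100, 0), mean_coverage]
  expect_true(all(central == max(prof$mean_coverage)))
  ## no peaks: all-zero profile
  p0 <- tssMetaprofile(pk[0], genes)
  expect_true(all(p0$mean_coverage == 0))
  ## uniform coverage: flat profile
  pu <- data.table::data.table(chrom = "chr1", start = 0, end = 1e6)
  pf <- tssMetaprofile(pu, genes)
  expect_true(all(pf$mean_coverage == 100))
})

test_that("mark-expression correlation recovers exact and null relationships", {
  ae <- compAnnot()
  g <- ae$genes
  ## signal exactly proportional to log-expression gives R = 1
  ex <- ae$expression[condition == "cond1"]
  x <- log2(ex$fpkm[match(g$gene, ex$gene)] + 1)
  bp <- pmax(round(50 + 100 * x), 1)
  bp <- pmin(bp, ifelse(g$strand == "+", g$end, g$tss + 1001) -
                  ifelse(g$strand == "+", g$tss - 1000, g$start))
  pk <- data.table::data.table(
    mark = "H3ac", condition = "cond1", chrom = g$chrom,
    start = ifelse(g$strand == "+", g$tss - 1000, g$end - bp),
    end = ifelse(g$strand == "+", g$tss - 1000 + bp, g$end))
  r <- markExpressionCorrelation(pk, g, ae$expression)
  expect_gt(r$r, 0.97)

  ## independent signal: |R| small at ~2000 genes
  set.seed(5)
  pk2 <- data.table::copy(pk)
  pk2[, mark := "null"]
  perm <- sample(nrow(g))
  pk2[, `:=`(chrom = g$chrom[perm],
             start = ifelse(g$strand[perm] == "+", g$tss[perm] - 1000,
                            g$end[perm] - bp),
             end = ifelse(g$strand[perm] == "+", g$tss[perm] - 1000 + bp,
                          g$end[perm]))]
  pk2[, `:=`(start = pmax(start, 0))]
  r2 <- markExpressionCorrelation(pk2, g, ae$expression)
  expect_lt(abs(r2$r), 0.1)
})

test_that("tuned promoter peaks reproduce the target correlations", {
  ae <- compAnnot()
  pp <- simulatePromoterPeaks(ae$genes, ae$expression, target_r = 0.56,
                              seed = 41)
  rp <- markExpressionCorrelation(pp, ae$genes, ae$expression)
  expect_lt(abs(rp$r - 0.56), 0.1)
  pn <- simulatePromoterPeaks(ae$genes, ae$expression, target_r = -0.45,
                              mark = "H3K27me3", seed = 42)
  rn <- markExpressionCorrelation(pn, ae$genes, ae$expression)
  expect_lt(abs(rn$r - (-0.45)), 0.1)
})

test_that("simpleDE calls nothing on identical groups and respects thresholds", {
  set.seed(9)
  counts <- matrix(rnbinom(200 * 6, mu = 300, size = 10), 200, 6)
  res <- simpleDE(counts, rep(c("a", "b"), each = 3))
  expect_true(all(res$results$call == "unchanged" |
                    res$results$padj >= 0.01 |
                    abs(res$results$lfc) <= 1))
  expect_equal(sum(res$results$call != "unchanged"), 0)
  ## infinite lfc threshold: nothing can be called
  res2 <- simpleDE(counts, rep(c("a", "b"), each = 3), lfc_min = Inf)
  expect_true(all(res2$results$call == "unchanged"))
  ## all-zero genes are excluded and listed
  counts0 <- rbind(counts, zero = 0)
  rownames(counts0) <- c(sprintf("g%03d", 1:200), "zero")
  res3 <- simpleDE(counts0, rep(c("a", "b"), each = 3))
  expect_equal(res3$excluded, "zero")
  expect_false("zero" %in% res3$results$gene)
  ## adjusted p-values never fall below raw ones
  expect_true(all(res$results$padj >= res$results$p_value - 1e-12))
})

test_that("simpleDE detects a 4-fold change at its simulation-measured power", {
  ## power measured by simulation for the Welch-t stand-in: at n = 3 per
  ## group and dispersion 0.05 the raw p-value beats 0.01 in ~80% of
  ## seeds (a Welch t with ~4 df is much weaker than a likelihood-based
  ## negative-binomial test); at n = 5 the full up-call (lfc > 1,
  ## BH-adjusted p < 0.01 in a 21-gene panel) fires in ~92% of seeds
  raw3 <- vapply(1:100, function(s) {
    set.seed(s)
    x <- log2(rnbinom(3, mu = 1000, size = 20) + 0.5)
    y <- log2(rnbinom(3, mu = 4000, size = 20) + 0.5)
    t.test(y, x)$p.value < 0.01
  }, logical(1))
  expect_gte(mean(raw3), 0.7)

  called5 <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    counts <- rbind(
      de = rnbinom(10, mu = 1000 * rep(c(1, 4), each = 5), size = 20),
      matrix(rnbinom(10 * 20, mu = 500, size = 20), 20, 10))
    rownames(counts) <- c("de", sprintf("bg%d", 1:20))
    res <- simpleDE(counts, rep(c("a", "b"), each = 5))
    res$results[gene == "de", call] == "up"
  }, logical(1))
  expect_gte(mean(called5), 0.85)
})
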