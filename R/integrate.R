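## Histone-mark / feature integration: enrichment of peaks in compartments,
## boundaries and loop anchors; promoter and TSS statistics; mark-expression
## correlation; and a simple differential-expression stand-in.

## midpoints of 0-based half-open intervals
.mid <- function(start, end) (start + end) %/% 2

## count of positions falling in any interval of X (per chromosome)
.inFeature <- function(X, chrom, pos) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    x <- X[X$chrom == ch]
    sel <- which(chrom == ch)
    if (!nrow(x)) next
    x <- x[order(x$start)]
    idx <- findInterval(pos[sel], x$start)
    out[sel] <- idx >= 1 & pos[sel] < x$end[pmax(idx, 1)]
  }
  out
}

## total bp of overlap between two interval sets (both merged per chrom)
.bpOverlap <- function(A, B) {
  tot <- 0
  for (ch in intersect(unique(A$chrom), unique(B$chrom))) {
    a <- A[A$chrom == ch]; b <- B[B$chrom == ch]
    for (k in seq_len(nrow(a)))
      tot <- tot + sum(pmax(0, pmin(a$end[k], b$end) -
                               pmax(a$start[k], b$start)))
  }
  tot
}

#' Peak enrichment in a genomic feature class
#'
#' Observed statistic: number of peaks whose midpoint lies in a feature
#' interval.  The null repositions each peak uniformly within its own
#' chromosome (lengths preserved) \code{n_shuffles} times; the permutation
#' z-score is (observed - null mean) / null sd.  The odds ratio and Fisher
#' p-value come from the bp-overlap 2x2 table (peak bp in/out of features
#' against non-peak bp in/out), discretized to 100 bp units for the exact
#' test.
#'
#' @param peaks peak table (chrom, start, end)
#' @param features feature interval table (chrom, start, end)
#' @param genome a GenomeLayout
#' @param n_shuffles permutation count
#' @param seed integer random seed
#' @return list with observed count/fraction, permutation z, odds ratio,
#'   Fisher p-value and the 2x2 bp table
#' @export
peakFeatureEnrichment <- function(peaks, features, genome, n_shuffles = 1000,
                                  seed = 1) {
  pk <- as.data.table(peaks); ft <- as.data.table(features)
  if (!nrow(pk) || !nrow(ft))
    return(list(observed = NA_integer_, observed_frac = NA_real_,
                z = NA_real_, odds_ratio = NA_real_,
                fisher_p = NA_real_, table = NULL))
  rng <- pinSeed(seed); on.exit(restoreRNG(rng))
  len <- chromLengths(genome)
  mid <- .mid(pk$start, pk$end)
  obs <- sum(.inFeature(ft, pk$chrom, mid))
  plen <- pk$end - pk$start
  null <- vapply(seq_len(n_shuffles), function(s) {
    st <- floor(runif(nrow(pk), 0, pmax(len[pk$chrom] - plen, 1)))
    sum(.inFeature(ft, pk$chrom, .mid(st, st + plen)))
  }, numeric(1))
  z <- if (sd(null) > 0) (obs - mean(null)) / sd(null) else NA_real_

  in_bp <- .bpOverlap(pk, ft)
  peak_bp <- sum(plen)
  feat_bp <- sum(ft$end - ft$start)
  genome_bp <- sum(len[unique(pk$chrom)])
  a <- in_bp; b <- peak_bp - in_bp
  c_ <- feat_bp - in_bp; d <- genome_bp - peak_bp - c_
  if (b <= 0 || c_ <= 0 || d <= 0) {
    or <- NA_real_; fp <- NA_real_
    tab <- matrix(c(a, b, c_, d), 2)
  } else {
    or <- (a * d) / (b * c_)
    tab <- matrix(round(c(a, b, c_, d) / 100), 2)
    tab[tab == 0] <- 1
    fp <- fisher.test(tab)$p.value
  }
  list(observed = obs, observed_frac = obs / nrow(pk), z = z,
       odds_ratio = or, fisher_p = fp, table = tab)
}

#' Fraction of peaks in gene promoters
#'
#' Promoters are the strand-aware 1 kb region upstream of the TSS:
#' [TSS - 1 kb, TSS) on the + strand and (TSS, TSS + 1 kb] on the -
#' strand (half-open; a peak midpoint exactly at the TSS is outside).
#'
#' @param peaks peak table (chrom, start, end)
#' @param genes gene table (chrom, tss, strand)
#' @param promoter_upstream promoter length in bp
#' @return fraction of peaks with midpoint in any promoter
#' @export
promoterStats <- function(peaks, genes, promoter_upstream = 1000) {
  pk <- as.data.table(peaks); g <- as.data.table(genes)
  prom <- data.table(
    chrom = g$chrom,
    start = ifelse(g$strand == "+", g$tss - promoter_upstream, g$tss + 1),
    end = ifelse(g$strand == "+", g$tss, g$tss + promoter_upstream + 1))
  prom[, start := pmax(start, 0)]
  mean(.inFeature(prom, pk$chrom, .mid(pk$start, pk$end)))
}

#' Strand-oriented TSS meta-profile of peak coverage
#'
#' Average per-bin peak bp coverage in a window of \code{flank} bp on each
#' side of the TSS, oriented 5' to 3' (minus-strand windows reversed).
#'
#' @param peaks peak table (chrom, start, end)
#' @param genes gene table (chrom, tss, strand)
#' @param flank window half-width in bp
#' @param bin profile bin width in bp
#' @return data.table with position (bin start relative to TSS) and
#'   mean_coverage (bp per bin averaged over genes)
#' @export
tssMetaprofile <- function(peaks, genes, flank = 3000, bin = 100) {
  pk <- as.data.table(peaks); g <- as.data.table(genes)
  if (!nrow(g)) stop("at least one gene required")
  nb <- as.integer(2 * flank / bin)
  acc <- numeric(nb)
  for (ch in unique(g$chrom)) {
    p <- pk[pk$chrom == ch]
    gg <- g[g$chrom == ch]
    if (!nrow(gg)) next
    for (k in seq_len(nrow(gg))) {
      ws <- gg$tss[k] - flank
      edges <- ws + (0:nb) * bin
      if (nrow(p)) {
        cover <- vapply(seq_len(nb), function(b)
          sum(pmax(0, pmin(p$end, edges[b + 1]) - pmax(p$start, edges[b]))),
          numeric(1))
      } else cover <- numeric(nb)
      if (gg$strand[k] == "-") cover <- rev(cover)
      acc <- acc + cover
    }
  }
  data.table(position = (0:(nb - 1)) * bin - flank,
             mean_coverage = acc / nrow(g))
}

#' Pearson correlation between mark signal and expression
#'
#' Per-gene mark signal is the total peak bp overlapping the strand-aware
#' window from 1 kb upstream of the TSS to the gene end; expression is
#' log2(FPKM + 1).  One correlation per (mark, condition) present in the
#' peak table.
#'
#' @param peaks peak table with mark and condition columns
#' @param genes gene table (gene, chrom, start, end, strand, tss)
#' @param expression expression table (gene, condition, fpkm)
#' @return data.table with mark, condition, r, p_value, n
#' @export
markExpressionCorrelation <- function(peaks, genes, expression) {
  pk <- as.data.table(peaks); g <- as.data.table(genes)
  ex <- as.data.table(expression)
  win_s <- ifelse(g$strand == "+", pmax(g$tss - 1000, 0), g$start)
  win_e <- ifelse(g$strand == "+", g$end, g$tss + 1001)
  combos <- unique(pk[, .(mark, condition)])
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    mk <- combos$mark[r]; cd <- combos$condition[r]
    p <- pk[pk$mark == mk & pk$condition == cd]
    sig <- numeric(nrow(g))
    for (ch in unique(g$chrom)) {
      sel <- which(g$chrom == ch)
      pc <- p[p$chrom == ch]
      if (!nrow(pc)) next
      for (k in sel)
        sig[k] <- sum(pmax(0, pmin(pc$end, win_e[k]) -
                              pmax(pc$start, win_s[k])))
    }
    e <- ex[ex[["condition"]] == cd]
    fpkm <- e$fpkm[match(g$gene, e$gene)]
    ok <- !is.na(fpkm)
    x <- log2(fpkm[ok] + 1); y <- sig[ok]
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
      return(data.table(mark = mk, condition = cd, r = NA_real_,
                        p_value = NA_real_, n = length(x)))
    ct <- cor.test(y, x)
    data.table(mark = mk, condition = cd, r = unname(ct$estimate),
               p_value = ct$p.value, n = length(x))
  })
  rbindlist(rows)
}

#' Simple differential-expression test
#'
#' Median-of-ratios library normalization, log2 fold change of normalized
#' group means (pseudo-count 0.5), Welch t-test on log2 normalized counts
#' and BH adjustment; genes are called up/down at |lfc| > \code{lfc_min}
#' and adjusted p < \code{padj_max}.  All-zero genes are excluded and
#' listed.  This is a deliberately simple stand-in, not a shrinkage-based
#' negative-binomial model.
#'
#' @param counts numeric matrix, genes x samples
#' @param groups factor/character of length ncol(counts) with 2 levels;
#'   fold change is level 2 over level 1
#' @param lfc_min log2 fold-change call threshold
#' @param padj_max BH-adjusted p-value call threshold
#' @return list with \code{results} (data.table gene, lfc, p_value, padj,
#'   call) and \code{excluded} (all-zero gene ids)
#' @export
simpleDE <- function(counts, groups, lfc_min = 1, padj_max = 0.01) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("at least 2 replicates per group required")
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%05d", seq_len(nrow(counts)))
  zero <- rowSums(counts) == 0
  excluded <- rownames(counts)[zero]
  m <- counts[!zero, , drop = FALSE]
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop("no gene with all-positive counts for size factors")
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE] / ref, 2, median)
  norm <- sweep(m, 2, sf, "/")
  g1 <- groups == levels(groups)[1]
  mu1 <- rowMeans(norm[, g1, drop = FALSE])
  mu2 <- rowMeans(norm[, !g1, drop = FALSE])
  lfc <- log2((mu2 + 0.5) / (mu1 + 0.5))
  ln <- log2(norm + 0.5)
  pv <- vapply(seq_len(nrow(ln)), function(k) {
    x <- ln[k, g1]; y <- ln[k, !g1]
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
    if (se < 1e-10 * max(1, abs(mean(x)), abs(mean(y))))
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    t.test(y, x)$p.value
  }, numeric(1))
  padj <- p.adjust(pv, "BH")
  call <- ifelse(lfc > lfc_min & padj < padj_max, "up",
                 ifelse(lfc < -lfc_min & padj < padj_max, "down", "unchanged"))
  list(results = data.table(gene = rownames(m), lfc = lfc, p_value = pv,
                            padj = padj, call = call),
       excluded = excluded)
}
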