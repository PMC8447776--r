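## Focal chromatin loop calling: local-background (donut) enrichment at
## 10 kb and 25 kb within 1 Mb, cross-resolution merging, compartment
## labelling and loop-gene coupling.

## summed-area table: S[(r+1), (c+1)] = sum of m[1..r, 1..c]
satBuild <- function(m) {
  n <- nrow(m)
  S <- matrix(0, n + 1, n + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  S
}

## rectangle sums over vectors of (clipped) row/col bounds, 1-based closed
satSum <- function(S, r1, r2, c1, c2) {
  n <- nrow(S) - 1
  r1 <- pmax(r1, 1); c1 <- pmax(c1, 1)
  r2 <- pmin(r2, n); c2 <- pmin(c2, n)
  bad <- r1 > r2 | c1 > c2
  v <- S[cbind(r2 + 1, c2 + 1)] - S[cbind(r1, c2 + 1)] -
       S[cbind(r2 + 1, c1)] + S[cbind(r1, c1)]
  v[bad] <- 0
  v
}

#' Call chromatin loops on one balanced chromosome matrix
#'
#' HICCUPS-style local enrichment: for every pixel within the distance
#' band, the expected signal under each of four neighborhoods (donut
#' annulus, lower-left quadrant, horizontal stripe, vertical stripe) is
#' the neighborhood's observed/expected ratio times the distance-decay
#' expectation at the pixel.  A pixel is called when its observed value
#' exceeds \code{min_fold} times every neighborhood expectation and its
#' Poisson upper-tail p-value against the largest expectation survives
#' per-chromosome BH correction at \code{fdr}.  Neighborhoods touching
#' masked bins renormalize by their unmasked pixel count; pixels with more
#' than half of a neighborhood masked are dropped.
#'
#' @param bm a BalancedMatrix
#' @param max_dist maximum anchor separation in bp (default 1 Mb)
#' @param peak_width inner peak half-width p in bins
#' @param donut_width outer neighborhood half-width w in bins
#' @param fdr BH false-discovery rate
#' @param min_fold minimum observed/expected fold over all neighborhoods
#' @return data.table with chrom, start1, start2 (anchor bin starts, bp),
#'   resolution, observed, e_donut, e_ll, e_h, e_v, p_value, q_value
#' @export
callLoops <- function(bm, max_dist = 1e6, peak_width = 1, donut_width = 5,
                      fdr = 0.1, min_fold = 1.5) {
  res <- bm@resolution
  m <- bm@matrix; valid <- bm@valid; n <- nrow(m)
  p <- peak_width; w <- donut_width
  empty <- data.table(chrom = character(), start1 = numeric(),
                      start2 = numeric(), resolution = numeric(),
                      observed = numeric(), e_donut = numeric(),
                      e_ll = numeric(), e_h = numeric(), e_v = numeric(),
                      p_value = numeric(), q_value = numeric())
  if (n <= 2 * w + 1) {
    warning(sprintf("chromosome %s smaller than the donut footprint", bm@chrom))
    return(empty)
  }
  ov <- observedOverExpected(bm)
  expd <- ov$decay$expected
  Emat <- matrix(0, n, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    Emat[cbind(i, i + d)] <- expd[d + 1]
    Emat[cbind(i + d, i)] <- expd[d + 1]
  }
  U <- outer(as.numeric(valid), as.numeric(valid))
  O <- m * U; Emat <- Emat * U
  So <- satBuild(O); Se <- satBuild(Emat); Su <- satBuild(U)

  maxd <- as.integer(max_dist / res)
  cand <- as.data.table(which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE))
  setnames(cand, c("i", "j"))
  cand <- cand[j - i > p & j - i <= maxd & valid[i] & valid[j]]
  if (!nrow(cand)) return(empty)
  i <- cand$i; j <- cand$j

  nbh <- function(S) {
    outer_ <- satSum(S, i - w, i + w, j - w, j + w)
    inner_ <- satSum(S, i - p, i + p, j - p, j + p)
    rowseg <- satSum(S, i, i, j - w, j + w) - satSum(S, i, i, j - p, j + p)
    colseg <- satSum(S, i - w, i + w, j, j) - satSum(S, i - p, i + p, j, j)
    donut <- outer_ - inner_ - rowseg - colseg
    ll <- satSum(S, i + 1, i + w, j - w, j - 1) -
          satSum(S, i + 1, i + p, j - p, j - 1)
    h <- satSum(S, i - p, i + p, j - w, j + w) - inner_
    v <- satSum(S, i - w, i + w, j - p, j + p) - inner_
    list(donut = donut, ll = ll, h = h, v = v)
  }
  so <- nbh(So); se <- nbh(Se); su <- nbh(Su)
  ## full (unclipped, unmasked) neighborhood areas for the masking rule
  area <- list(
    donut = (2 * w + 1)^2 - (2 * p + 1)^2 - 2 * (w - p) - 2 * (w - p),
    ll = w^2 - p^2,
    h = (2 * p + 1) * (2 * w + 1) - (2 * p + 1)^2,
    v = (2 * p + 1) * (2 * w + 1) - (2 * p + 1)^2)

  pix_e <- Emat[cbind(i, j)]
  exp_of <- function(nm) {
    ok <- su[[nm]] / area[[nm]] >= 0.5 & se[[nm]] > 0
    e <- ifelse(ok, so[[nm]] / se[[nm]] * pix_e, Inf)
    e
  }
  e_donut <- exp_of("donut"); e_ll <- exp_of("ll")
  e_h <- exp_of("h"); e_v <- exp_of("v")
  obs <- O[cbind(i, j)]
  lam <- pmax(e_donut, e_ll, e_h, e_v)
  ## Poisson upper tail P(X >= obs | lam), continuous in obs via the
  ## regularized gamma function (equals ppois at integer obs)
  pv <- ifelse(is.finite(lam),
               ifelse(obs <= 0, 1, pgamma(lam, shape = obs)), 1)
  qv <- p.adjust(pv, method = "BH")
  fold_ok <- is.finite(lam) &
    obs > min_fold * e_donut & obs > min_fold * e_ll &
    obs > min_fold * e_h & obs > min_fold * e_v
  keep <- fold_ok & qv <= fdr
  if (!any(keep)) return(empty)
  data.table(chrom = bm@chrom, start1 = (i[keep] - 1) * res,
             start2 = (j[keep] - 1) * res, resolution = res,
             observed = obs[keep], e_donut = e_donut[keep],
             e_ll = e_ll[keep], e_h = e_h[keep], e_v = e_v[keep],
             p_value = pv[keep], q_value = qv[keep])
}

#' Cluster candidate pixels and merge calls across resolutions
#'
#' Single-linkage clustering of candidate pixels within a Chebyshev radius
#' of \code{radius} bins (per chromosome, per resolution); each cluster is
#' represented by its most significant pixel (a "loop peak"), and a peak's
#' anchors are its "peak loci".  When the anchors of a coarser-resolution
#' peak both overlap a 10 kb peak's anchors, the 10 kb call takes
#' precedence and the coarser call is dropped.
#'
#' @param candidates list of per-resolution candidate tables from
#'   \code{callLoops} (single chromosomes may simply be concatenated)
#' @param radius clustering Chebyshev radius in bins
#' @return list with \code{loops} (representative table with span column),
#'   \code{n_peaks}, \code{n_loci}
#' @export
clusterAndMerge <- function(candidates, radius = 2) {
  if (is.data.frame(candidates)) candidates <- list(candidates)
  reps <- list()
  for (cd in candidates) {
    cd <- as.data.table(cd)
    if (!nrow(cd)) next
    for (rs in unique(cd$resolution)) {
      sub <- cd[resolution == rs]
      for (ch in unique(sub$chrom)) {
        px <- sub[chrom == ch]
        k <- nrow(px)
        parent <- seq_len(k)
        find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
        bi <- px$start1 / rs; bj <- px$start2 / rs
        if (k > 1) {
          ord <- order(bi, bj)
          for (a in 1:(k - 1)) {
            b <- a + 1
            while (b <= k && bi[ord[b]] - bi[ord[a]] <= radius) {
              if (abs(bj[ord[a]] - bj[ord[b]]) <= radius) {
                ra <- find(ord[a]); rb <- find(ord[b])
                if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
              }
              b <- b + 1
            }
          }
        }
        root <- vapply(seq_len(k), find, integer(1))
        px[, cluster := root]
        rep_ <- px[order(q_value, p_value, start1, start2),
                   .SD[1], by = cluster][, cluster := NULL]
        reps[[length(reps) + 1]] <- rep_
      }
    }
  }
  if (!length(reps))
    return(list(loops = data.table(), n_peaks = 0L, n_loci = 0L))
  allr <- rbindlist(reps, fill = TRUE)
  fine <- min(allr$resolution)
  keep <- rep(TRUE, nrow(allr))
  fr <- allr[resolution == fine]
  if (nrow(fr) && any(allr$resolution > fine)) {
    for (k in which(allr$resolution > fine)) {
      r <- allr[k]
      ov1 <- fr$chrom == r$chrom & fr$start1 < r$start1 + r$resolution &
             fr$start1 + fine > r$start1
      ov2 <- fr$chrom == r$chrom & fr$start2 < r$start2 + r$resolution &
             fr$start2 + fine > r$start2
      if (any(ov1 & ov2)) keep[k] <- FALSE
    }
  }
  loops <- allr[keep]
  loops[, span := start2 - start1]
  setorder(loops, chrom, start1, start2)
  anchors <- unique(rbindlist(list(
    loops[, .(chrom, start = start1, end = start1 + resolution)],
    loops[, .(chrom, start = start2, end = start2 + resolution)])))
  list(loops = loops[], n_peaks = nrow(loops), n_loci = nrow(anchors))
}

#' Label loops by the compartment of their anchors
#'
#' A loop is A if both anchor midpoints fall in A bins of the profile, B
#' if both fall in B bins, and mixed otherwise (anchors in masked bins are
#' mixed and flagged).  Also returns per-label counts and a 50 kb-binned
#' span histogram.
#'
#' @param loops loop table from \code{clusterAndMerge}
#' @param profile a CompartmentProfile (100 kb typical)
#' @return list with \code{loops} (labelled), \code{counts},
#'   \code{span_hist}
#' @export
assignCompartment <- function(loops, profile) {
  lp <- copy(as.data.table(loops))
  if (!nrow(lp))
    return(list(loops = lp, counts = c(A = 0L, B = 0L, mixed = 0L),
                span_hist = data.table()))
  bins <- profile@bins
  m1 <- lp$start1 + lp$resolution / 2
  m2 <- lp$start2 + lp$resolution / 2
  l1 <- blockLabelAt(bins, lp$chrom, m1, "label")
  l2 <- blockLabelAt(bins, lp$chrom, m2, "label")
  lab <- ifelse(l1 == "A" & l2 == "A", "A",
                ifelse(l1 == "B" & l2 == "B", "B", "mixed"))
  lab[is.na(lab)] <- "mixed"
  flagged <- is.na(l1) | is.na(l2) | l1 == "masked" | l2 == "masked"
  lp[, `:=`(compartment = lab, anchor_masked = flagged)]
  counts <- c(A = sum(lab == "A"), B = sum(lab == "B"),
              mixed = sum(lab == "mixed"))
  hist <- lp[, .N, by = .(span_bin = (span %/% 5e4) * 5e4)][order(span_bin)]
  list(loops = lp[], counts = counts, span_hist = hist)
}

#' Loop-gene coupling and expression at a high-FPKM threshold
#'
#' A gene is loop-coupled when its TSS falls inside any loop anchor
#' interval [start, start + resolution).  Reports the fraction of coupled
#' and uncoupled genes exceeding \code{fpkm_high} (among genes with TSS
#' on loop-bearing chromosomes) with a two-proportion test.
#'
#' @param loops loop table from \code{clusterAndMerge}
#' @param genes gene table (gene, chrom, tss)
#' @param expression expression table (gene, condition, fpkm)
#' @param condition condition matching the loop set
#' @param fpkm_high high-expression FPKM threshold (default 20)
#' @return list with per-gene flags and the two fractions plus p-value
#' @export
loopGeneCoupling <- function(loops, genes, expression, condition = "cond1",
                             fpkm_high = 20) {
  lp <- as.data.table(loops); g <- as.data.table(genes)
  ex <- as.data.table(expression)
  ex <- ex[ex[["condition"]] == condition]
  if (!nrow(lp)) {
    return(list(genes = data.table(), coupled_high_frac = NA_real_,
                uncoupled_high_frac = NA_real_, p_value = NA_real_,
                n_coupled = 0L, n_uncoupled = 0L))
  }
  anchors <- rbindlist(list(
    lp[, .(chrom, start = start1, end = start1 + resolution)],
    lp[, .(chrom, start = start2, end = start2 + resolution)]))
  g <- g[g$chrom %in% unique(lp$chrom)]
  coupled <- vapply(seq_len(nrow(g)), function(k) {
    a <- anchors[anchors$chrom == g$chrom[k]]
    any(a$start <= g$tss[k] & g$tss[k] < a$end)
  }, logical(1))
  fpkm <- ex$fpkm[match(g$gene, ex$gene)]
  high <- fpkm > fpkm_high
  tab <- table(coupled = factor(coupled, c(TRUE, FALSE)),
               high = factor(high, c(TRUE, FALSE)))
  pv <- if (all(rowSums(tab) > 0))
    suppressWarnings(prop.test(tab[, 1], rowSums(tab))$p.value)
    else NA_real_
  list(genes = data.table(gene = g$gene, coupled = coupled, fpkm = fpkm),
       coupled_high_frac = if (any(coupled)) mean(high[coupled]) else NA_real_,
       uncoupled_high_frac = if (any(!coupled)) mean(high[!coupled]) else NA_real_,
       p_value = pv, n_coupled = sum(coupled), n_uncoupled = sum(!coupled))
}
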