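## Insulation-score TAD boundary detection, fixed-width boundary padding
## (10 kb bin + 40 kb per side = 90 kb), TAD derivation and feature counts.

#' Insulation score track for one chromosome
#'
#' For each bin i, the mean balanced signal in the w x w square upstream
#' rows (i-w .. i-1) by downstream columns (i .. i+w-1), where
#' w = window / resolution; the score is the log2 ratio of that mean to
#' its chromosome-wide geometric mean, so unmasked scores average exactly
#' zero.  Bins whose window exits the chromosome, or whose square is more
#' than half masked, are masked.
#'
#' @param bm a BalancedMatrix (10 kb resolution typical)
#' @param window square window size in bp (multiple of the resolution,
#'   at least 2 bins)
#' @param max_masked_frac square masked-pixel fraction above which the bin
#'   is masked
#' @return data.table with columns chrom, start, score, valid
#' @export
insulationScore <- function(bm, window = 1e5, max_masked_frac = 0.5) {
  res <- bm@resolution
  if (window %% res != 0 || window / res < 2)
    stop("window must be a multiple of the resolution and >= 2 bins")
  w <- as.integer(window / res)
  m <- bm@matrix; vmask <- bm@valid; n <- nrow(m)
  raw <- rep(NA_real_, n)
  if (n < 3 * w) {
    warning(sprintf("chromosome %s shorter than 3 windows: all bins masked",
                    bm@chrom))
  } else {
    U <- outer(as.numeric(vmask), as.numeric(vmask))
    cm <- apply(rbind(0, m), 2, cumsum)
    cu <- apply(rbind(0, U), 2, cumsum)
    rsum <- function(S, r1, r2, c1, c2) {
      ## sum over rows r1..r2 for columns c1..c2, vectorised over bins
      tot <- 0
      for (cc in 0:(w - 1)) {
        col <- c1 + cc
        tot <- tot + (S[cbind(r2 + 1, col)] - S[cbind(r1, col)])
      }
      tot
    }
    i <- (w + 1):(n - w + 1)
    sq_sum <- rsum(cm, i - w, i - 1, i, i + w - 1)
    sq_n <- rsum(cu, i - w, i - 1, i, i + w - 1)
    ok <- sq_n / w^2 >= (1 - max_masked_frac) & sq_n > 0
    vals <- ifelse(ok, sq_sum / sq_n, NA_real_)
    ## an all-zero square (perfectly insulated junction) is a deep minimum,
    ## not missing data: floor it below the smallest positive mean
    if (any(!is.na(vals) & vals > 0) && any(!is.na(vals) & vals == 0))
      vals[!is.na(vals) & vals == 0] <- min(vals[!is.na(vals) & vals > 0]) / 2
    vals[!is.na(vals) & vals <= 0] <- NA_real_
    raw[i] <- vals
  }
  ok <- !is.na(raw)
  score <- rep(NA_real_, n)
  if (any(ok)) score[ok] <- log2(raw[ok]) - mean(log2(raw[ok]))
  data.table(chrom = bm@chrom, start = (seq_len(n) - 1) * res,
             score = score, valid = ok)
}

#' Call raw TAD boundary bins from an insulation track
#'
#' The delta vector at bin i is the mean score over the dw bins to the
#' right minus the mean over the dw bins to the left; boundaries sit at
#' negative-to-positive zero crossings of delta, at the local insulation
#' minimum, and are kept when the minimum's depth (lower of the flanking
#' maxima within dw bins minus the minimum) reaches \code{min_strength}.
#' Ties take the leftmost bin.
#'
#' @param track insulation track from \code{insulationScore}
#' @param resolution bin size in bp
#' @param delta_window delta half-window in bp
#' @param min_strength minimum boundary depth in log2 units
#' @return data.table with columns chrom, start (bin start bp), strength
#' @export
callBoundaries <- function(track, resolution = 1e4, delta_window = 1e5,
                           min_strength = 0.1) {
  dw <- as.integer(delta_window / resolution)
  out <- lapply(split(track, track$chrom), function(tr) {
    s <- tr$score; n <- length(s)
    if (n < 2 * dw + 1) return(NULL)
    delta <- rep(NA_real_, n)
    for (i in (dw + 1):(n - dw)) {
      left <- s[(i - dw):(i - 1)]; right <- s[(i + 1):(i + dw)]
      if (all(is.na(left)) || all(is.na(right))) next
      delta[i] <- mean(right, na.rm = TRUE) - mean(left, na.rm = TRUE)
    }
    cross <- which(!is.na(delta[-n]) & !is.na(delta[-1]) &
                     delta[-n] <= 0 & delta[-1] > 0)
    if (!length(cross)) return(NULL)
    recs <- lapply(cross, function(i) {
      lo <- max(1, i - dw); hi <- min(n, i + dw)
      seg <- s[lo:hi]
      if (all(is.na(seg))) return(NULL)
      mb <- lo + which.min(seg) - 1           # leftmost minimum
      left_max <- suppressWarnings(max(s[max(1, mb - dw):mb], na.rm = TRUE))
      right_max <- suppressWarnings(max(s[mb:min(n, mb + dw)], na.rm = TRUE))
      strength <- min(left_max, right_max) - s[mb]
      if (!is.finite(strength) || strength < min_strength) return(NULL)
      data.table(chrom = tr$chrom[1], start = (mb - 1) * resolution,
                 strength = strength)
    })
    rbindlist(recs)
  })
  bd <- rbindlist(out)
  if (!nrow(bd))
    return(data.table(chrom = character(), start = numeric(),
                      strength = numeric()))
  bd <- unique(bd, by = c("chrom", "start"))
  setorder(bd, chrom, start)
  bd[]
}

#' Pad raw boundary bins to fixed-width final boundaries
#'
#' Each raw boundary bin [s, s + res) is widened by \code{pad} bp on each
#' side, giving final boundaries of width res + 2*pad (90 kb for a 10 kb
#' bin and the default 40 kb padding, absorbing replicate-to-replicate
#' boundary jitter).  Intervals running off a chromosome end are clipped
#' and flagged rather than silently shortened.
#'
#' @param raw data.table from \code{callBoundaries} (chrom, start, strength)
#' @param genome a GenomeLayout
#' @param resolution raw boundary bin size in bp
#' @param pad padding per side in bp
#' @return data.table with chrom, start, end, strength, clipped
#' @export
padBoundaries <- function(raw, genome, resolution = 1e4, pad = 4e4) {
  len <- chromLengths(genome)
  out <- copy(as.data.table(raw))
  if (!nrow(out))
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric(), strength = numeric(),
                      clipped = logical()))
  if (!"strength" %in% names(out)) out[, strength := NA_real_]
  out[, `:=`(s0 = start - pad, e0 = start + resolution + pad)]
  out[, chrlen := len[chrom]]
  out[, clipped := s0 < 0 | e0 > chrlen]
  out[, `:=`(start = pmax(s0, 0), end = pmin(e0, chrlen))]
  out[, c("s0", "e0", "chrlen") := NULL]
  setcolorder(out, c("chrom", "start", "end", "strength", "clipped"))
  setorder(out, chrom, start)
  out[]
}

#' Boundary overlap statistics between two boundary sets
#'
#' A boundary in A is "common" when its interval intersects at least one
#' interval of B by >= 1 bp.  Reports |common|/|A|, |common|/|B| and the
#' bp Jaccard index of the merged interval sets.
#'
#' @param setA,setB padded boundary tables (chrom, start, end)
#' @return list with common_frac_A, common_frac_B, jaccard, n_A, n_B
#' @export
boundaryOverlap <- function(setA, setB) {
  A <- as.data.table(setA); B <- as.data.table(setB)
  if (!nrow(A) || !nrow(B)) {
    return(list(common_frac_A = 0, common_frac_B = 0, jaccard = 0,
                n_A = nrow(A), n_B = nrow(B)))
  }
  hitsIn <- function(X, Y) {
    vapply(seq_len(nrow(X)), function(k) {
      y <- Y[Y$chrom == X$chrom[k]]
      any(y$start < X$end[k] & y$end > X$start[k])
    }, logical(1))
  }
  merge1 <- function(X) {
    X <- X[order(chrom, start)]
    X[, grp := {
      ce <- cummax(end)
      cumsum(c(TRUE, start[-1] > head(ce, -1)))
    }, by = chrom]
    X[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  }
  mA <- merge1(copy(A)); mB <- merge1(copy(B))
  inter <- 0
  for (ch in union(mA$chrom, mB$chrom)) {
    a <- mA[chrom == ch]; b <- mB[chrom == ch]
    if (!nrow(a) || !nrow(b)) next
    for (k in seq_len(nrow(a)))
      inter <- inter + sum(pmax(0, pmin(a$end[k], b$end) -
                                   pmax(a$start[k], b$start)))
  }
  uni <- sum(mA$end - mA$start) + sum(mB$end - mB$start) - inter
  list(common_frac_A = mean(hitsIn(A, B)),
       common_frac_B = mean(hitsIn(B, A)),
       jaccard = if (uni > 0) inter / uni else 0,
       n_A = nrow(A), n_B = nrow(B))
}

#' Derive TAD intervals from padded boundaries
#'
#' TADs span between consecutive boundary midpoints, plus the two
#' chromosome-end domains; domains shorter than \code{min_bins} bins are
#' merged into the smaller neighbor.  A chromosome with fewer than 2
#' boundaries yields a single whole-chromosome domain.
#'
#' @param boundaries padded boundary table (chrom, start, end)
#' @param genome a GenomeLayout
#' @param resolution bin size in bp (for the minimum TAD size)
#' @param min_bins minimum TAD size in bins
#' @return data.table with chrom, start, end
#' @export
deriveTads <- function(boundaries, genome, resolution = 1e4, min_bins = 3) {
  len <- chromLengths(genome)
  bd <- as.data.table(boundaries)
  out <- lapply(chromNames(genome), function(ch) {
    b <- bd[bd$chrom == ch]
    if (nrow(b) < 2)
      return(data.table(chrom = ch, start = 0, end = len[[ch]]))
    mids <- sort((b$start + b$end) / 2)
    edges <- c(0, mids, len[[ch]])
    sizes <- diff(edges)
    ## merge short domains into the smaller neighbor
    while (length(sizes) > 1 && any(sizes < min_bins * resolution)) {
      k <- which.min(sizes)
      if (sizes[k] >= min_bins * resolution) break
      nb <- if (k == 1) 2 else if (k == length(sizes)) length(sizes) - 1
            else if (sizes[k - 1] <= sizes[k + 1]) k - 1 else k + 1
      drop_edge <- if (nb < k) k else k + 1
      edges <- edges[-drop_edge]
      sizes <- diff(edges)
    }
    data.table(chrom = ch, start = head(edges, -1), end = tail(edges, -1))
  })
  rbindlist(out)
}

#' Count features (by TSS) in TADs and TAD boundaries
#'
#' A feature whose TSS falls inside any boundary interval is counted in
#' boundaries; otherwise it is counted in the TAD containing the TSS
#' (half-open containment).  Densities per Mb accompany the raw counts
#' since boundary and TAD total lengths differ grossly.
#'
#' @param tads TAD table (chrom, start, end)
#' @param boundaries padded boundary table (chrom, start, end)
#' @param features table with chrom and tss columns (e.g. genes or DEGs)
#' @return list with boundary_count, tad_count, boundary_mb, tad_mb,
#'   boundary_density, tad_density
#' @export
countFeatures <- function(tads, boundaries, features) {
  f <- as.data.table(features)
  bd <- as.data.table(boundaries); td <- as.data.table(tads)
  in_any <- function(X, chv, pos) {
    vapply(seq_along(pos), function(k) {
      x <- X[X[["chrom"]] == chv[k]]
      any(x$start <= pos[k] & pos[k] < x$end)
    }, logical(1))
  }
  inb <- in_any(bd, f$chrom, f$tss)
  int <- !inb & in_any(td, f$chrom, f$tss)
  bmb <- sum(bd$end - bd$start) / 1e6
  ## TAD bp excludes boundary bp so densities refer to disjoint territory
  tmb <- max(sum(td$end - td$start) / 1e6 - bmb, 0)
  list(boundary_count = sum(inb), tad_count = sum(int),
       boundary_mb = bmb, tad_mb = tmb,
       boundary_density = if (bmb > 0) sum(inb) / bmb else NA_real_,
       tad_density = if (tmb > 0) sum(int) / tmb else NA_real_)
}
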