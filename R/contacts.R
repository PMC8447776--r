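## Contact-map input, normalization and summaries.

#' Read a chromosome-sizes table
#'
#' Two-column TSV (chrom, length) without header.
#'
#' @param path file path
#' @param mac_threshold MAC/MIC split in bp
#' @return a \linkS4class{GenomeLayout}
#' @export
readChromsizes <- function(path, mac_threshold = 5e7) {
  dt <- fread(path, header = FALSE, col.names = c("chrom", "length"))
  new("GenomeLayout", chromNames = dt$chrom,
      chromLengths = as.numeric(dt$length), macThreshold = mac_threshold)
}

#' Write a chromosome-sizes table
#' @param genome a GenomeLayout
#' @param path output path
#' @export
writeChromsizes <- function(genome, path) {
  fwrite(data.table(chrom = chromNames(genome),
                    length = as.integer(chromLengths(genome))),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read sparse triplet contacts into a ContactMap
#'
#' Expects a (possibly gzipped) TSV with header columns chrom1, start1,
#' chrom2, start2, count; coordinates 0-based and multiples of the
#' resolution.  Records on both (i,j) and (j,i) are summed into one
#' upper-triangular entry.
#'
#' @param path contacts TSV path
#' @param chromsizes_path chromosome-sizes TSV path
#' @param resolution bin size in bp
#' @param mac_threshold MAC/MIC split passed to the GenomeLayout
#' @return a \linkS4class{ContactMap}
#' @export
readContacts <- function(path, chromsizes_path, resolution,
                         mac_threshold = 5e7) {
  genome <- readChromsizes(chromsizes_path, mac_threshold)
  ## readLines handles gzip transparently, so no extra dependency is
  ## needed for .gz triplet files
  dt <- if (grepl("\\.gz$", path))
    fread(text = readLines(path), header = TRUE)
  else fread(path, header = TRUE)
  setnames(dt, c("chrom1", "start1", "chrom2", "start2", "count"))
  known <- chromNames(genome)
  bad <- which(!(dt$chrom1 %in% known) | !(dt$chrom2 %in% known))
  if (length(bad))
    stop(sprintf("unknown chromosome at line %d: %s/%s", bad[1] + 1,
                 dt$chrom1[bad[1]], dt$chrom2[bad[1]]))
  mis <- which(dt$start1 %% resolution != 0 | dt$start2 %% resolution != 0)
  if (length(mis))
    stop(sprintf("coordinate not a multiple of %d at line %d",
                 as.integer(resolution), mis[1] + 1))
  neg <- which(dt$count < 0)
  if (length(neg)) stop(sprintf("negative count at line %d", neg[1] + 1))
  b1 <- globalBin(genome, resolution, dt$chrom1, dt$start1)
  b2 <- globalBin(genome, resolution, dt$chrom2, dt$start2)
  ct <- data.table(bin1 = pmin(b1, b2), bin2 = pmax(b1, b2),
                   count = as.numeric(dt$count))
  ct <- ct[, .(count = sum(count)), by = .(bin1, bin2)]
  setorder(ct, bin1, bin2)
  new("ContactMap", resolution = resolution, genome = genome, counts = ct)
}

#' Write a ContactMap as gzipped sparse triplet TSV
#' @param map a ContactMap
#' @param path output path (".gz" for gzip)
#' @export
writeContacts <- function(map, path) {
  bt <- binTable(map@genome, map@resolution)
  ct <- map@counts
  out <- data.table(chrom1 = bt$chrom[ct$bin1], start1 = bt$start[ct$bin1],
                    chrom2 = bt$chrom[ct$bin2], start2 = bt$start[ct$bin2],
                    count = ct$count)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Genome-wide total contact count
#'
#' Off-diagonal entries count twice (both orientations of a read pair),
#' diagonal entries once.
#'
#' @param map a ContactMap
#' @return numeric total
#' @export
totalContacts <- function(map) {
  ct <- map@counts
  if (!nrow(ct)) return(0)
  sum(ct$count[ct$bin1 == ct$bin2]) + 2 * sum(ct$count[ct$bin1 < ct$bin2])
}

#' Library-size normalization to a fixed total
#'
#' Scales every count so the genome-wide total (off-diagonal twice,
#' diagonal once) equals \code{target_total}; tissues normalized to the
#' same total (1e9 by default) become directly comparable.
#'
#' @param map a ContactMap
#' @param target_total target genome-wide total
#' @return a rescaled ContactMap
#' @export
normalizeLibrary <- function(map, target_total = 1e9) {
  tot <- totalContacts(map)
  if (tot <= 0) stop("cannot normalize an empty contact map")
  ct <- copy(map@counts)
  ct[, count := count * (target_total / tot)]
  new("ContactMap", resolution = map@resolution, genome = map@genome,
      counts = ct)
}

#' Dense intra-chromosomal matrix for one chromosome
#'
#' @param map a ContactMap
#' @param chrom chromosome name
#' @return symmetric numeric matrix of the chromosome's bins
#' @export
chromMatrix <- function(map, chrom) {
  nb <- chromBinCounts(map@genome, map@resolution)
  off <- chromBinOffsets(map@genome, map@resolution)
  if (!chrom %in% names(nb)) stop("unknown chromosome: ", chrom)
  n <- nb[[chrom]]; o <- off[[chrom]]
  ct <- map@counts[bin1 > o & bin1 <= o + n & bin2 > o & bin2 <= o + n]
  m <- matrix(0, n, n)
  if (nrow(ct)) {
    m[cbind(ct$bin1 - o, ct$bin2 - o)] <- ct$count
    m[cbind(ct$bin2 - o, ct$bin1 - o)] <- ct$count
  }
  m
}

#' ICE (iterative correction) balancing of one chromosome
#'
#' Iterative proportional fitting of multiplicative per-bin biases until
#' the unmasked row sums agree to a relative tolerance.  Bins with zero
#' coverage, or coverage below the given quantile of non-zero coverages,
#' are masked (zero rows/columns, NA bias).  The converged matrix is
#' rescaled to preserve the total signal of the unmasked submatrix, so
#' balanced = raw / (bias \%o\% bias).
#'
#' @param mat square symmetric non-negative matrix
#' @param chrom chromosome name recorded on the result
#' @param resolution bin size in bp recorded on the result
#' @param max_iter iteration cap
#' @param tol convergence tolerance on max relative row-sum deviation
#' @param min_coverage_quantile coverage quantile below which bins are masked
#' @return a \linkS4class{BalancedMatrix}
#' @export
iceBalance <- function(mat, chrom = "chr", resolution = 1e4, max_iter = 200,
                       tol = 1e-5, min_coverage_quantile = 0.02) {
  n <- nrow(mat)
  if (ncol(mat) != n) stop("matrix must be square")
  if (any(mat < 0)) stop("matrix must be non-negative")
  cov <- rowSums(mat)
  valid <- cov > 0
  if (any(valid)) {
    ## type-1 (inverted ECDF) quantile: the cut is an observed coverage
    ## value, so tiny matrices do not mask their minimum-coverage bin
    q <- quantile(cov[valid], min_coverage_quantile, names = FALSE, type = 1)
    valid <- valid & cov >= q
  }
  if (!any(valid)) stop("matrix too sparse: all bins masked")
  b <- rep(1, n)
  sub <- mat[valid, valid, drop = FALSE]
  bv <- rep(1, sum(valid))
  for (it in seq_len(max_iter)) {
    bal <- sub / outer(bv, bv)
    s <- rowSums(bal)
    target <- mean(s)
    dev <- max(abs(s / target - 1))
    if (dev < tol) break
    bv <- bv * sqrt(s / target)
  }
  bal <- sub / outer(bv, bv)
  ## preserve total signal of the unmasked submatrix
  sc <- sum(sub) / sum(bal)
  bal <- bal * sc
  bv <- bv / sqrt(sc)
  out <- matrix(0, n, n)
  out[valid, valid] <- bal
  b <- rep(NA_real_, n)
  b[valid] <- bv
  new("BalancedMatrix", chrom = chrom, resolution = resolution,
      matrix = out, bias = b, valid = valid)
}

#' Balance every chromosome of a ContactMap
#'
#' @param map a ContactMap
#' @param ... passed to \code{iceBalance}
#' @return named list of BalancedMatrix, one per chromosome
#' @export
balanceAll <- function(map, ...) {
  out <- lapply(chromNames(map@genome), function(ch)
    iceBalance(chromMatrix(map, ch), chrom = ch,
               resolution = map@resolution, ...))
  setNames(out, chromNames(map@genome))
}

#' Observed/expected transformation and distance-decay profile
#'
#' Expected value at bin distance d is the mean balanced signal over
#' unmasked pairs at that distance; O/E divides each unmasked entry by the
#' expected value of its distance (0 where the expected value is 0).
#'
#' @param bm a BalancedMatrix
#' @return list with elements \code{oe} (matrix), \code{decay} (data.table
#'   distance, expected), \code{valid} (logical mask)
#' @export
observedOverExpected <- function(bm) {
  m <- bm@matrix; valid <- bm@valid; n <- nrow(m)
  expd <- numeric(n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    vals <- m[cbind(i, i + d)]
    ok <- valid[i] & valid[i + d]
    expd[d + 1] <- if (any(ok)) mean(vals[ok]) else 0
  }
  oe <- matrix(0, n, n)
  for (d in 0:(n - 1)) {
    if (expd[d + 1] <= 0) next
    i <- seq_len(n - d)
    ok <- valid[i] & valid[i + d]
    if (!any(ok)) next
    io <- i[ok]
    oe[cbind(io, io + d)] <- m[cbind(io, io + d)] / expd[d + 1]
    oe[cbind(io + d, io)] <- oe[cbind(io, io + d)]
  }
  list(oe = oe, decay = data.table(distance = 0:(n - 1), expected = expd),
       valid = valid)
}

#' Interaction-frequency summary by chromosome-pair class
#'
#' Per chromosome pair, frequency = total contact count divided by the
#' number of bin pairs (upper triangle incl. diagonal for intra pairs,
#' full rectangle for inter pairs).  Pairs are classed as intra-MAC,
#' intra-MIC, inter MAC-MAC, inter MIC-MIC or inter MAC-MIC, and Welch
#' t-tests compare intra vs inter frequencies and MIC-MIC vs each other
#' inter class.  Classes with fewer than two members yield NA tests.
#'
#' @param map a ContactMap
#' @return list with \code{pairs} (per-pair table), \code{class_means},
#'   and \code{tests} (data.table comparison, statistic, p_value)
#' @export
interactionSummary <- function(map) {
  genome <- map@genome
  if (length(chromNames(genome)) < 2)
    stop("interaction summary needs at least two chromosomes")
  nb <- chromBinCounts(genome, map@resolution)
  off <- chromBinOffsets(genome, map@resolution)
  mac <- isMac(genome)
  ct <- map@counts
  bt <- binTable(genome, map@resolution)
  ch1 <- bt$chrom[ct$bin1]; ch2 <- bt$chrom[ct$bin2]
  totals <- data.table(c1 = ch1, c2 = ch2, count = ct$count)[
    , .(total = sum(count)), by = .(c1, c2)]
  chs <- chromNames(genome)
  grid <- as.data.table(expand.grid(i = seq_along(chs), j = seq_along(chs)))
  grid <- grid[i <= j]
  pairs <- grid[, {
    a <- chs[i]; b <- chs[j]
    tot <- totals[(c1 == a & c2 == b) | (c1 == b & c2 == a), sum(total)]
    npairs <- if (a == b) nb[[a]] * (nb[[a]] + 1) / 2
              else as.numeric(nb[[a]]) * nb[[b]]
    cls <- if (a == b) {
      if (mac[[a]]) "intra-MAC" else "intra-MIC"
    } else if (mac[[a]] && mac[[b]]) "inter-MAC-MAC"
      else if (!mac[[a]] && !mac[[b]]) "inter-MIC-MIC"
      else "inter-MAC-MIC"
    .(chrom1 = a, chrom2 = b, total = tot, n_bin_pairs = npairs,
      frequency = tot / npairs, class = cls)
  }, by = .(i, j)][, c("i", "j") := NULL]
  class_means <- pairs[, .(mean_frequency = mean(frequency), n = .N),
                       by = class]
  welch <- function(x, y) {
    if (length(x) < 2 || length(y) < 2 || (sd(x) == 0 && sd(y) == 0))
      return(list(statistic = NA_real_, p_value = NA_real_))
    tt <- t.test(x, y)
    list(statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  intra <- pairs[grepl("^intra", class), frequency]
  inter <- pairs[grepl("^inter", class), frequency]
  micmic <- pairs[class == "inter-MIC-MIC", frequency]
  tests <- rbindlist(list(
    c(list(comparison = "intra_vs_inter"), welch(intra, inter)),
    c(list(comparison = "micmic_vs_macmac"),
      welch(micmic, pairs[class == "inter-MAC-MAC", frequency])),
    c(list(comparison = "micmic_vs_macmic"),
      welch(micmic, pairs[class == "inter-MAC-MIC", frequency]))))
  list(pairs = pairs, class_means = class_means, tests = tests)
}
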