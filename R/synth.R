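## Synthetic-data generator: genomes, planted structure, contact maps,
## annotation/expression and histone-mark peaks.  The generative model is
## multiplicative: expected intra-chromosomal intensity at bin distance d is
## (1+d)^(-alpha), times a compartment factor when two bins share an A/B
## label, a TAD factor when they lie between the same adjacent planted
## boundaries, and a loop factor in the 1-bin neighborhood of a planted
## anchor pair; counts are Poisson.

#' Generate a karyotype with macro- and micro-chromosomes
#'
#' Draws chromosome lengths uniformly from a macro range (entirely above the
#' MAC/MIC threshold) and a micro range (entirely below), names them
#' \code{chr1..chrN} in order of decreasing length.
#'
#' @param n_mac,n_mic number of macro-/micro-chromosomes
#' @param mac_range,mic_range length-2 numeric bp intervals to draw lengths
#'   from; \code{mac_range} must lie entirely above \code{mac_threshold} and
#'   \code{mic_range} entirely below it
#' @param seed integer random seed
#' @param mac_threshold MAC/MIC split in bp (default 50 Mb)
#' @return a \linkS4class{GenomeLayout}
#' @examples
#' makeGenome(2, 3, c(6e7, 9e7), c(1e7, 3e7), seed = 1)
#' @export
makeGenome <- function(n_mac, n_mic, mac_range = c(6e7, 1.6e8),
                       mic_range = c(1e7, 4.5e7), seed = 1,
                       mac_threshold = 5e7) {
  if (n_mac < 0 || n_mic < 0) stop("chromosome counts must be >= 0")
  if (n_mac > 0 && min(mac_range) <= mac_threshold)
    stop("mac_range must lie entirely above the MAC/MIC threshold")
  if (n_mic > 0 && max(mic_range) >= mac_threshold)
    stop("mic_range must lie entirely below the MAC/MIC threshold")
  rng <- pinSeed(seed); on.exit(restoreRNG(rng))
  lens <- c(if (n_mac > 0) runif(n_mac, mac_range[1], mac_range[2]),
            if (n_mic > 0) runif(n_mic, mic_range[1], mic_range[2]))
  lens <- round(lens / 1e4) * 1e4    # whole 10 kb for clean bin tiling
  lens <- sort(lens, decreasing = TRUE)
  new("GenomeLayout", chromNames = paste0("chr", seq_along(lens)),
      chromLengths = lens, macThreshold = mac_threshold)
}

#' Plant compartment blocks, TAD boundaries and loop anchors
#'
#' Tiles each chromosome with alternating A/B compartment blocks (starting
#' with A), flags a fraction of blocks as switching to the opposite label in
#' a second condition, places TAD boundaries away from chromosome ends with
#' a minimum separation, and draws focal loop anchor pairs whose span is at
#' most \code{max_loop_span} (1 Mb by default), preferentially inside A
#' blocks to mimic euchromatic-loop predominance.
#'
#' @param genome a GenomeLayout
#' @param comp_block_bp compartment block size in bp; must be a multiple of
#'   the 100 kb compartment bin size
#' @param n_boundaries_per_chrom additional TAD boundaries planted per
#'   chromosome; compartment block junctions insulate under the
#'   multiplicative contact model and are recorded as boundaries too
#' @param n_loops total loop anchor pairs planted genome-wide
#' @param max_loop_span maximum anchor1-to-anchor2 distance in bp (<= 1 Mb)
#' @param p_A probability that a loop is constrained to A blocks
#' @param switch_fraction fraction of compartment blocks flipping label in
#'   condition 2
#' @param min_boundary_sep minimum separation between planted boundaries, bp
#' @param insulation_window insulation window used to keep boundaries away
#'   from chromosome ends (margin = 2 windows), bp
#' @param seed integer random seed
#' @return a \linkS4class{SyntheticTruth}
#' @export
plantTruth <- function(genome, comp_block_bp = 1e6, n_boundaries_per_chrom = 8,
                       n_loops = 50, max_loop_span = 1e6, p_A = 0.7,
                       switch_fraction = 0.2, min_boundary_sep = 5e5,
                       insulation_window = 1e5, seed = 1) {
  if (comp_block_bp %% 1e5 != 0)
    stop("comp_block_bp must be a multiple of the 100 kb compartment bin size")
  if (max_loop_span > 1e6) stop("max_loop_span must be <= 1,000,000 bp")
  rng <- pinSeed(seed); on.exit(restoreRNG(rng))
  len <- chromLengths(genome)
  res <- 1e4   # structural coordinates aligned to the 10 kb TAD grid

  blocks <- rbindlist(lapply(names(len), function(ch) {
    s <- seq(0, len[[ch]] - 1, by = comp_block_bp)
    e <- pmin(s + comp_block_bp, len[[ch]])
    lab <- rep(c("A", "B"), length.out = length(s))
    data.table(chrom = ch, start = s, end = e, label = lab)
  }))
  flip <- runif(nrow(blocks)) < switch_fraction
  blocks[, label2 := ifelse(flip, ifelse(label == "A", "B", "A"), label)]

  ## compartment block junctions insulate and are boundaries themselves;
  ## n_boundaries_per_chrom additional boundaries subdivide the blocks
  margin <- 2 * insulation_window
  bounds <- rbindlist(lapply(names(len), function(ch) {
    junc <- blocks[chrom == ch & start > 0, start]
    junc <- junc[junc >= margin & junc <= len[[ch]] - margin]
    pos <- junc
    if (n_boundaries_per_chrom > 0) {
      lo <- margin; hi <- len[[ch]] - margin
      span <- hi - lo - (n_boundaries_per_chrom - 1) * min_boundary_sep
      if (span <= 0)
        stop(sprintf("chromosome %s too short for %d boundaries", ch,
                     n_boundaries_per_chrom))
      u <- sort(runif(n_boundaries_per_chrom, 0, span))
      extra <- lo + u + (seq_len(n_boundaries_per_chrom) - 1) * min_boundary_sep
      extra <- round(extra / res) * res
      near <- vapply(extra, function(p) any(abs(p - junc) < 2e5), logical(1))
      pos <- sort(unique(c(junc, extra[!near])))
    }
    if (!length(pos)) return(NULL)
    data.table(chrom = ch, pos = pos)
  }))

  la <- NULL
  if (n_loops > 0) {
    amargin <- 1e5
    eligible <- names(len)[len >= 2 * amargin + max_loop_span + res]
    if (!length(eligible))
      stop(sprintf("chromosome %s too short for loops with span %g",
                   names(len)[1], max_loop_span))
    w <- len[eligible] / sum(len[eligible])
    recs <- vector("list", n_loops)
    for (k in seq_len(n_loops)) {
      ch <- sample(eligible, 1, prob = w)
      wantA <- runif(1) < p_A
      for (try in 1:300) {
        span <- sample(seq(5e4, max_loop_span, by = res), 1)
        a1 <- sample(seq(amargin, len[[ch]] - amargin - span, by = res), 1)
        a2 <- a1 + span
        if (!wantA) break
        labs <- blockLabelAt(blocks, c(ch, ch), c(a1, a2) + res / 2)
        if (all(labs == "A")) break
      }
      recs[[k]] <- data.table(chrom = ch, anchor1 = a1, anchor2 = a2)
    }
    la <- unique(rbindlist(recs))
  }
  if (is.null(la)) la <- data.table(chrom = character(), anchor1 = numeric(),
                                    anchor2 = numeric())
  setorder(bounds, chrom, pos)
  new("SyntheticTruth", compartmentBlocks = blocks, boundaries = bounds,
      loopAnchors = la,
      params = list(comp_block_bp = comp_block_bp, n_loops = n_loops,
                    max_loop_span = max_loop_span, p_A = p_A,
                    switch_fraction = switch_fraction, seed = seed))
}

#' Simulate a binned Hi-C contact map with planted structure
#'
#' Poisson counts around a multiplicative expected model: power-law distance
#' decay \code{(1+d)^-decay_alpha} (d in bins) times compartment, TAD and
#' loop enrichment factors from the planted truth.  Inter-chromosomal
#' expected intensity is \code{trans_level} times the mean intra intensity,
#' boosted by \code{mic_trans_boost} for MIC-MIC pairs (micro-chromosomes
#' sit spatially closer).  Intensities are scaled so the genome-wide total
#' count is approximately \code{depth}.
#'
#' @param genome a GenomeLayout
#' @param truth a SyntheticTruth
#' @param resolution bin size in bp
#' @param depth target genome-wide total contact count
#' @param decay_alpha distance-decay exponent
#' @param comp_strength fold enrichment for same-compartment bin pairs
#' @param tad_strength fold enrichment for same-TAD bin pairs
#' @param loop_strength fold enrichment in the 1-bin neighborhood of a
#'   planted anchor pair
#' @param trans_level inter-chromosomal intensity as a fraction of the mean
#'   intra intensity
#' @param mic_trans_boost extra factor for MIC-MIC chromosome pairs
#' @param seed integer random seed
#' @return a \linkS4class{ContactMap}
#' @export
simulateContacts <- function(genome, truth, resolution = 1e4, depth = 1e7,
                             decay_alpha = 1.0, comp_strength = 2.5,
                             tad_strength = 2.0, loop_strength = 8,
                             trans_level = 0.01, mic_trans_boost = 2,
                             seed = 1) {
  checkScalar(depth, "depth"); checkScalar(resolution, "resolution")
  rng <- pinSeed(seed); on.exit(restoreRNG(rng))
  nb <- chromBinCounts(genome, resolution)
  off <- chromBinOffsets(genome, resolution)
  len <- chromLengths(genome)
  blocks <- truthBlocks(truth)
  bounds <- truthBoundaries(truth)
  loops <- truthLoops(truth)

  intra <- list(); intra_upper_sum <- 0; intra_full_sum <- 0; intra_px <- 0
  for (ch in names(nb)) {
    n <- nb[[ch]]
    mid <- (seq_len(n) - 0.5) * resolution
    mid <- pmin(mid, len[[ch]] - 1)
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    E <- (1 + D)^(-decay_alpha)
    lab <- blockLabelAt(blocks, rep(ch, n), mid)
    if (!all(is.na(lab))) {
      same <- outer(lab, lab, "==")
      same[is.na(same)] <- FALSE
      E[same] <- E[same] * comp_strength
    }
    bp <- bounds[chrom == ch, pos]
    tid <- findInterval(mid, sort(bp))
    sameT <- outer(tid, tid, "==")
    E[sameT] <- E[sameT] * tad_strength
    lp <- loops[chrom == ch]
    if (nrow(lp)) for (r in seq_len(nrow(lp))) {
      i0 <- lp$anchor1[r] %/% resolution + 1
      j0 <- lp$anchor2[r] %/% resolution + 1
      ri <- max(1, i0 - 1):min(n, i0 + 1)
      rj <- max(1, j0 - 1):min(n, j0 + 1)
      E[ri, rj] <- E[ri, rj] * loop_strength
      E[rj, ri] <- E[rj, ri] * loop_strength
    }
    intra[[ch]] <- E
    ut <- upper.tri(E, diag = TRUE)
    intra_upper_sum <- intra_upper_sum + sum(E[ut])
    intra_full_sum <- intra_full_sum + sum(E)
    intra_px <- intra_px + n * n
  }

  mean_intra <- intra_full_sum / intra_px
  mac <- isMac(genome)
  chs <- names(nb)
  trans_lam <- 0
  pair_lam <- list()
  if (trans_level > 0 && length(chs) > 1) {
    for (a in seq_along(chs)[-length(chs)]) for (b in (a + 1):length(chs)) {
      lam <- trans_level * mean_intra *
        (if (!mac[[chs[a]]] && !mac[[chs[b]]]) mic_trans_boost else 1)
      pair_lam[[paste(a, b)]] <- lam
      trans_lam <- trans_lam + lam * nb[[a]] * nb[[b]]
    }
  }
  scale <- depth / (intra_upper_sum + trans_lam)

  recs <- list()
  for (ch in names(nb)) {
    E <- intra[[ch]] * scale
    n <- nb[[ch]]
    ut <- which(upper.tri(E, diag = TRUE))
    cnt <- rpois(length(ut), E[ut])
    keep <- cnt > 0
    ij <- arrayInd(ut[keep], c(n, n))
    recs[[length(recs) + 1]] <- data.table(
      bin1 = ij[, 1] + off[[ch]], bin2 = ij[, 2] + off[[ch]],
      count = as.numeric(cnt[keep]))
  }
  if (trans_level > 0 && length(chs) > 1) {
    for (key in names(pair_lam)) {
      ab <- as.integer(strsplit(key, " ")[[1]])
      n1 <- nb[[ab[1]]]; n2 <- nb[[ab[2]]]
      lam <- pair_lam[[key]] * scale
      tot <- rpois(1, lam * n1 * n2)
      if (tot == 0) next
      cells <- sample.int(n1 * n2, tot, replace = TRUE)
      agg <- data.table(cell = cells)[, .N, by = cell]
      i <- (agg$cell - 1) %% n1 + 1
      j <- (agg$cell - 1) %/% n1 + 1
      recs[[length(recs) + 1]] <- data.table(
        bin1 = i + off[[ab[1]]], bin2 = j + off[[ab[2]]],
        count = as.numeric(agg$N))
    }
  }
  ct <- rbindlist(recs)
  ct <- ct[, .(count = sum(count)), by = .(bin1, bin2)]
  setorder(ct, bin1, bin2)
  new("ContactMap", resolution = resolution, genome = genome, counts = ct)
}

#' Simulate gene annotation and two-condition expression
#'
#' Genes are placed Poisson along each chromosome with compartment-dependent
#' density (A blocks gene-dense).  Counts are negative-binomial around a
#' log-normal baseline; genes whose TSS falls in a block planted as
#' switching receive a mean log2 fold change of \code{+lfc_switch_effect}
#' (B to A) or \code{-lfc_switch_effect} (A to B) in condition 2.  FPKM is
#' derived as count / (gene kb x library size in millions).
#'
#' @param genome a GenomeLayout
#' @param truth a SyntheticTruth (provides compartment blocks and switches)
#' @param genes_per_mb_A,genes_per_mb_B gene density in A and B blocks
#'   (A must be denser)
#' @param lfc_switch_effect planted log2 fold change magnitude for switching
#'   genes
#' @param dispersion negative-binomial dispersion (size = 1/dispersion)
#' @param seed integer random seed
#' @return list with elements \code{genes} (data.table: chrom, start, end,
#'   gene, score, strand, tss; 0-based half-open) and \code{expression}
#'   (data.table: gene, condition, count, fpkm)
#' @export
simulateAnnotationAndExpression <- function(genome, truth, genes_per_mb_A = 12,
                                            genes_per_mb_B = 4,
                                            lfc_switch_effect = 1.5,
                                            dispersion = 0.1, seed = 1) {
  if (genes_per_mb_A <= genes_per_mb_B)
    stop("A compartment must be gene-dense: genes_per_mb_A > genes_per_mb_B")
  rng <- pinSeed(seed); on.exit(restoreRNG(rng))
  blocks <- truthBlocks(truth)
  len <- chromLengths(genome)
  glist <- list()
  for (r in seq_len(nrow(blocks))) {
    b <- blocks[r]
    dens <- if (b$label == "A") genes_per_mb_A else genes_per_mb_B
    ng <- rpois(1, dens * (b$end - b$start) / 1e6)
    if (ng == 0) next
    gstart <- round(runif(ng, b$start, b$end - 1))
    glen <- pmin(pmax(round(rlnorm(ng, log(12000), 0.6)), 4000), 1e5)
    gend <- pmin(gstart + glen, len[[b$chrom]])
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    glist[[length(glist) + 1]] <- data.table(
      chrom = b$chrom, start = gstart, end = gend, strand = strand)
  }
  genes <- rbindlist(glist)
  setorder(genes, chrom, start)
  ## genes are kept non-overlapping (with a 1.2 kb guard for the upstream
  ## promoter) so per-gene promoter/body windows are disjoint
  genes <- genes[, {
    keep <- logical(.N); last_end <- -Inf
    for (k in seq_len(.N)) {
      if (start[k] >= last_end + 1200) { keep[k] <- TRUE; last_end <- end[k] }
    }
    .SD[keep]
  }, by = chrom]
  genes[, gene := sprintf("g%05d", seq_len(.N))]
  genes[, score := 0]
  genes[, tss := ifelse(strand == "+", start, end - 1)]
  setcolorder(genes, c("chrom", "start", "end", "gene", "score", "strand", "tss"))

  lab1 <- blockLabelAt(blocks, genes$chrom, genes$tss, "label")
  lab2 <- blockLabelAt(blocks, genes$chrom, genes$tss, "label2")
  delta <- ifelse(lab1 == "B" & lab2 == "A", lfc_switch_effect,
                  ifelse(lab1 == "A" & lab2 == "B", -lfc_switch_effect, 0))
  mu1 <- rlnorm(nrow(genes), log(300), 1)
  mu2 <- mu1 * 2^delta
  size <- 1 / dispersion
  c1 <- rnbinom(nrow(genes), mu = mu1, size = size)
  c2 <- rnbinom(nrow(genes), mu = mu2, size = size)
  kb <- (genes$end - genes$start) / 1000
  expr <- rbindlist(list(
    data.table(gene = genes$gene, condition = "cond1", count = c1,
               fpkm = c1 / (kb * sum(c1) / 1e6)),
    data.table(gene = genes$gene, condition = "cond2", count = c2,
               fpkm = c2 / (kb * sum(c2) / 1e6))))
  list(genes = genes, expression = expr)
}

#' Simulate compartment-biased histone-mark peaks
#'
#' H3ac peaks fall in A blocks with probability \code{a_bias} and
#' H3K27me3 peaks in B blocks with the same probability; peak lengths are
#' exponential around \code{peak_len_mean}.  Overlapping peaks within one
#' mark are resolved by dropping later overlapping intervals.
#'
#' @param truth a SyntheticTruth
#' @param genome a GenomeLayout
#' @param a_bias probability of the mark falling in its preferred
#'   compartment (0.5 < a_bias <= 1)
#' @param peak_len_mean mean peak length in bp
#' @param n_peaks peaks generated per mark
#' @param condition condition id recorded on the peaks
#' @param seed integer random seed
#' @return named list of two data.tables (H3ac, H3K27me3) with columns
#'   mark, condition, chrom, start, end, signal
#' @export
simulatePeaks <- function(truth, genome, a_bias = 0.9, peak_len_mean = 1500,
                          n_peaks = 500, condition = "cond1", seed = 1) {
  if (a_bias <= 0.5 || a_bias > 1) stop("a_bias must be in (0.5, 1]")
  rng <- pinSeed(seed); on.exit(restoreRNG(rng))
  blocks <- truthBlocks(truth)
  len <- chromLengths(genome)
  one_mark <- function(mark, target) {
    tb <- blocks[label == target]
    ob <- blocks[label != target]
    pick <- runif(n_peaks) < a_bias
    src <- ifelse(pick, "t", "o")
    plen <- pmax(round(rexp(n_peaks, 1 / peak_len_mean)), 100)
    recs <- lapply(seq_len(n_peaks), function(k) {
      pool <- if (src[k] == "t") tb else ob
      b <- pool[sample.int(nrow(pool), 1, prob = pool$end - pool$start)]
      mid <- round(runif(1, b$start, b$end - 1))
      s <- max(0, mid - plen[k] %/% 2)
      e <- min(len[[b$chrom]], s + plen[k])
      data.table(mark = mark, condition = condition, chrom = b$chrom,
                 start = s, end = e, signal = rlnorm(1, log(10), 0.5))
    })
    pk <- rbindlist(recs)
    setorder(pk, chrom, start, end)
    keep <- pk[, {
      ok <- rep(TRUE, .N); last_end <- -1
      for (i in seq_len(.N)) {
        if (start[i] < last_end) ok[i] <- FALSE
        else last_end <- end[i]
      }
      .(start = start, end = end, signal = signal, ok = ok)
    }, by = .(mark, condition, chrom)]
    keep[ok == TRUE][, ok := NULL][]
  }
  list(H3ac = one_mark("H3ac", "A"), H3K27me3 = one_mark("H3K27me3", "B"))
}

#' Simulate promoter-anchored peaks with a target mark-expression correlation
#'
#' Gene-anchored generator used to benchmark mark-expression correlation
#' recovery: each gene receives one peak inside its promoter-plus-body
#' window whose length (bp) is a Gaussian-copula transform of the gene's
#' log2(FPKM+1), so the Pearson correlation between per-gene peak bp and
#' expression approximates \code{target_r} (positive or negative).
#'
#' @param genes gene annotation table (as from
#'   \code{simulateAnnotationAndExpression})
#' @param expression expression table with columns gene, condition, fpkm
#' @param condition condition whose FPKM drives the coupling
#' @param mark mark name recorded on the peaks
#' @param target_r target Pearson correlation (in [-1, 1])
#' @param mean_bp,sd_bp mean and spread of the per-gene peak length
#' @param seed integer random seed
#' @return data.table with columns mark, condition, chrom, start, end, signal
#' @export
simulatePromoterPeaks <- function(genes, expression, condition = "cond1",
                                  mark = "H3ac", target_r = 0.56,
                                  mean_bp = 2000, sd_bp = 600, seed = 1) {
  if (abs(target_r) > 1) stop("target_r must be in [-1, 1]")
  rng <- pinSeed(seed); on.exit(restoreRNG(rng))
  ex <- as.data.table(expression)
  ex <- ex[ex[["condition"]] == condition]
  ex <- ex[match(genes$gene, ex$gene)]
  x <- log2(ex$fpkm + 1)
  z <- (x - mean(x)) / sd(x)
  s <- target_r * z + sqrt(1 - target_r^2) * rnorm(length(z))
  bp <- pmax(round(mean_bp + sd_bp * s), 0)
  win_s <- ifelse(genes$strand == "+", genes$tss - 1000, genes$start)
  win_e <- ifelse(genes$strand == "+", genes$end, genes$tss + 1001)
  bp <- pmin(bp, win_e - win_s)
  keep <- bp >= 50
  start <- ifelse(genes$strand == "+", win_s, win_e - bp)
  end <- start + bp
  data.table(mark = mark, condition = condition,
             chrom = genes$chrom[keep], start = start[keep],
             end = end[keep], signal = bp[keep] / 100)[order(chrom, start)]
}
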