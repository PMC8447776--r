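## A/B compartment calling from the leading eigenvector of the O/E
## correlation matrix, orientation by gene density, and compartment-switch
## classification against expression changes.

#' Leading eigenvector of the contact correlation matrix
#'
#' Computes the Pearson correlation matrix of the O/E matrix over unmasked
#' bins (with the diagonal excluded from the correlation input), and
#' returns the eigenvector of the largest-magnitude eigenvalue, zero-filled
#' at masked bins and scaled to unit norm.  The sign is arbitrary at this
#' stage; see \code{\link{orientAndLabel}}.
#'
#' @param oe intra-chromosomal O/E matrix
#' @param valid logical mask of unmasked bins
#' @param chrom chromosome name (used in error messages)
#' @return numeric eigenvector of length \code{nrow(oe)}
#' @export
compartmentEigenvector <- function(oe, valid = rep(TRUE, nrow(oe)),
                                   chrom = "chr") {
  if (sum(valid) < 10)
    stop(sprintf("chromosome %s: fewer than 10 unmasked bins", chrom))
  sub <- oe[valid, valid, drop = FALSE]
  ## Pearson correlation of columns with the distance-0 (diagonal) entries
  ## excluded pairwise: for columns i, j the rows i and j are dropped.
  ## Computed in closed form (diagonal zeroed, then sums corrected), which
  ## is exact and needs a single matrix product.
  n <- nrow(sub)
  M0 <- sub; diag(M0) <- 0
  S <- colSums(M0); Q <- colSums(M0^2)
  m <- n - 2
  SUMI <- matrix(S, n, n) - M0          # sum of col i over rows not in {i,j}
  SQI <- matrix(Q, n, n) - M0^2
  CROSS <- crossprod(M0)
  num <- CROSS - SUMI * t(SUMI) / m
  varI <- SQI - SUMI^2 / m
  if (any(varI[row(varI) != col(varI)] <= 0))
    stop(sprintf("chromosome %s: degenerate correlation matrix (constant rows)",
                 chrom))
  C <- num / sqrt(varI * t(varI))
  diag(C) <- 1
  if (any(!is.finite(C)))
    stop(sprintf("chromosome %s: degenerate correlation matrix", chrom))
  eg <- eigen(C, symmetric = TRUE)
  k <- which.max(abs(eg$values))
  v <- eg$vectors[, k]
  out <- numeric(nrow(oe))
  out[valid] <- v
  out / sqrt(sum(out^2))
}

#' Orient an eigenvector by gene density and label A/B bins
#'
#' Flips the eigenvector sign if its Pearson correlation with gene density
#' over unmasked bins is negative (A compartments are gene-dense), then
#' labels positive bins A and negative bins B.  Zero-variance gene density
#' leaves the orientation unresolved: labels are still emitted, with a
#' warning and a FALSE orientation flag.
#'
#' @param eigenvector numeric per-bin eigenvector
#' @param gene_density numeric per-bin gene counts
#' @param valid logical mask of unmasked bins
#' @return list with \code{eigen} (oriented), \code{label} (character
#'   A/B/masked), \code{resolved} (logical orientation flag)
#' @export
orientAndLabel <- function(eigenvector, gene_density,
                           valid = rep(TRUE, length(eigenvector))) {
  if (length(eigenvector) != length(gene_density))
    stop("eigenvector and gene_density must have equal length")
  resolved <- TRUE
  if (sd(gene_density[valid]) == 0 || sd(eigenvector[valid]) == 0) {
    warning("gene-density orientation unresolved (zero variance)")
    resolved <- FALSE
  } else if (cor(eigenvector[valid], gene_density[valid]) < 0) {
    eigenvector <- -eigenvector
  }
  label <- rep("masked", length(eigenvector))
  label[valid & eigenvector > 0] <- "A"
  label[valid & eigenvector < 0] <- "B"
  list(eigen = eigenvector, label = label, resolved = resolved)
}

#' Call A/B compartments genome-wide
#'
#' Balances each chromosome (unless balanced matrices are supplied),
#' applies the O/E transformation, extracts the leading eigenvector of the
#' correlation matrix, and orients it by gene density (genes overlapping
#' each bin).
#'
#' @param map a ContactMap at compartment resolution (100 kb typical)
#' @param genes gene annotation data.table (chrom, start, end, ...)
#' @param balanced optional pre-computed list of BalancedMatrix
#' @param ... passed to \code{iceBalance}
#' @return a \linkS4class{CompartmentProfile}
#' @export
callCompartments <- function(map, genes, balanced = NULL, ...) {
  genome <- map@genome
  res <- map@resolution
  if (is.null(balanced)) balanced <- balanceAll(map, ...)
  bt <- binTable(genome, res)
  gd <- geneDensity(genes, genome, res)
  recs <- list(); resolved <- logical(0)
  for (ch in chromNames(genome)) {
    bm <- balanced[[ch]]
    ov <- observedOverExpected(bm)
    ev <- compartmentEigenvector(ov$oe, ov$valid, chrom = ch)
    dens <- gd[bt$chrom == ch]
    ol <- orientAndLabel(ev, dens, ov$valid)
    recs[[ch]] <- data.table(chrom = ch,
                             start = bt$start[bt$chrom == ch],
                             end = bt$end[bt$chrom == ch],
                             eigen = ol$eigen, label = ol$label,
                             gene_density = dens)
    resolved[ch] <- ol$resolved
  }
  new("CompartmentProfile", genome = genome, resolution = res,
      bins = rbindlist(recs), orientationResolved = resolved)
}

#' Per-bin gene density (genes overlapping each bin)
#'
#' @param genes gene table with chrom, start, end (0-based half-open)
#' @param genome a GenomeLayout
#' @param resolution bin size in bp
#' @return integer vector over the genome-wide bin table
#' @export
geneDensity <- function(genes, genome, resolution) {
  bt <- binTable(genome, resolution)
  dens <- integer(nrow(bt))
  g <- as.data.table(genes)
  for (ch in unique(g$chrom)) {
    sel <- which(bt$chrom == ch)
    if (!length(sel)) next
    gg <- g[g$chrom == ch]
    first <- gg$start %/% resolution
    last <- (gg$end - 1) %/% resolution
    nb <- length(sel)
    cov <- integer(nb + 1)
    f <- pmin(pmax(first, 0), nb - 1) + 1
    l <- pmin(pmax(last, 0), nb - 1) + 1
    for (k in seq_along(f)) {
      cov[f[k]] <- cov[f[k]] + 1L
      cov[l[k] + 1L] <- cov[l[k] + 1L] - 1L
    }
    dens[sel] <- cumsum(cov[seq_len(nb)])
  }
  dens
}

#' Cross-classify two compartment profiles into switch categories
#'
#' Each bin is classed A->A, A->B, B->A or B->B from its labels in the two
#' profiles; a bin masked in either profile is masked.  Fractions are
#' computed over unmasked bins genome-wide and per chromosome.
#'
#' @param profile1,profile2 CompartmentProfile objects on the same genome
#'   and resolution
#' @return a \linkS4class{SwitchTable}
#' @export
switchClassify <- function(profile1, profile2) {
  if (profile1@resolution != profile2@resolution)
    stop("resolution mismatch between profiles")
  if (!identical(chromNames(profile1@genome), chromNames(profile2@genome)))
    stop("profiles are on different genomes")
  b1 <- profile1@bins; b2 <- profile2@bins
  if (nrow(b1) != nrow(b2)) stop("profiles have different bin counts")
  cat_ <- ifelse(b1$label == "masked" | b2$label == "masked", "masked",
                 paste0(b1$label, "->", b2$label))
  bins <- data.table(chrom = b1$chrom, start = b1$start, end = b1$end,
                     category = cat_)
  lev <- c("A->A", "A->B", "B->A", "B->B")
  unm <- bins[category != "masked"]
  gf <- setNames(as.numeric(table(factor(unm$category, lev)) / nrow(unm)), lev)
  cf <- unm[, {
    tb <- table(factor(category, lev)) / .N
    as.list(as.numeric(tb))
  }, by = chrom]
  setnames(cf, c("chrom", lev))
  new("SwitchTable", bins = bins, genomeFractions = gf, chromFractions = cf)
}

#' Per-gene log2 fold change from a two-condition expression table
#'
#' log2((FPKM2 + 1) / (FPKM1 + 1)) per gene.
#'
#' @param expression data.table with gene, condition, fpkm
#' @param cond1,cond2 condition ids (fold change of cond2 over cond1)
#' @return named numeric vector of log2 fold changes
#' @export
geneLogFC <- function(expression, cond1 = "cond1", cond2 = "cond2") {
  ex <- as.data.table(expression)
  e1 <- ex[ex[["condition"]] == cond1]
  e2 <- ex[ex[["condition"]] == cond2]
  e2 <- e2[match(e1$gene, e2$gene)]
  setNames(log2((e2$fpkm + 1) / (e1$fpkm + 1)), e1$gene)
}

#' Test expression change across compartment-switch categories
#'
#' Genes are assigned the switch category of the bin containing their TSS;
#' each switching category (A->B, B->A) is compared against the pooled
#' stable group (A->A plus B->B) by a two-sided Wilcoxon rank-sum test on
#' per-gene log2 fold changes.  Categories with fewer than 2 genes (or an
#' empty stable group) are reported not-applicable rather than erroring.
#'
#' @param switch a SwitchTable
#' @param expr_lfc named numeric per-gene log2 fold change
#' @param genes gene table with gene, chrom, tss columns
#' @return data.table with category, n, median_lfc, statistic, p_value
#' @export
switchExpressionTest <- function(switch, expr_lfc, genes) {
  g <- as.data.table(genes)
  bins <- switch@bins
  res <- bins$end[1] - bins$start[1]
  cat_of_gene <- blockLabelAt(bins, g$chrom, g$tss, "category")
  lfc <- expr_lfc[g$gene]
  ok <- !is.na(cat_of_gene) & cat_of_gene != "masked" & !is.na(lfc)
  dt <- data.table(category = cat_of_gene[ok], lfc = as.numeric(lfc[ok]))
  stable <- dt[category %in% c("A->A", "B->B"), lfc]
  rows <- lapply(c("A->A", "A->B", "B->A", "B->B"), function(cc) {
    x <- dt[category == cc, lfc]
    n <- length(x)
    med <- if (n) median(x) else NA_real_
    if (cc %in% c("A->B", "B->A") && n >= 2 && length(stable) >= 2) {
      wt <- wilcox.test(x, stable)
      data.table(category = cc, n = n, median_lfc = med,
                 statistic = unname(wt$statistic), p_value = wt$p.value)
    } else {
      data.table(category = cc, n = n, median_lfc = med,
                 statistic = NA_real_, p_value = NA_real_)
    }
  })
  rbindlist(rows)
}
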