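## Bin bookkeeping: bins are 0-based half-open [k*res, (k+1)*res) per
## chromosome; the genome-wide index space concatenates chromosomes in
## GenomeLayout order and is 1-based.

#' Number of bins per chromosome at a resolution
#'
#' @param genome a GenomeLayout
#' @param resolution bin size in bp
#' @return named integer vector of bin counts
#' @export
chromBinCounts <- function(genome, resolution) {
  setNames(as.integer(ceiling(genome@chromLengths / resolution)),
           genome@chromNames)
}

## first global bin (1-based) of each chromosome
chromBinOffsets <- function(genome, resolution) {
  nb <- chromBinCounts(genome, resolution)
  setNames(cumsum(c(0L, nb[-length(nb)])), names(nb))
}

#' Genome-wide bin table at a resolution
#'
#' @inheritParams chromBinCounts
#' @return data.table with columns chrom, start, end, bin (global 1-based)
#' @export
binTable <- function(genome, resolution) {
  nb <- chromBinCounts(genome, resolution)
  len <- chromLengths(genome)
  dt <- rbindlist(lapply(names(nb), function(ch) {
    s <- seq(0, by = resolution, length.out = nb[[ch]])
    data.table(chrom = ch, start = s, end = pmin(s + resolution, len[[ch]]))
  }))
  dt[, bin := seq_len(.N)]
  dt[]
}

## global bin index for (chrom, bp position)
globalBin <- function(genome, resolution, chrom, pos) {
  off <- chromBinOffsets(genome, resolution)
  unname(off[chrom]) + pos %/% resolution + 1L
}

#' Derive a child seed from a global seed
#'
#' Deterministic fan-out of one global seed into per-component seeds, used
#' by the pipeline so that each stage has an independent stream. The result
#' always fits a 32-bit integer.
#'
#' @param seed integer global seed
#' @param k integer component index (>= 1); the derivation order is
#'   documented in the run configuration schema
#' @return integer child seed
#' @export
childSeed <- function(seed, k) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + 1103 * k) %% 2147483647)
}

## Pin the RNG to a fixed kind for a seeded stream, returning the previous
## state; byte-identical simulator output must not depend on the ambient
## RNG kind, and the caller's RNG state is restored afterwards.
pinSeed <- function(seed) {
  state <- list(
    kind = RNGkind(),
    seed = if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv(), inherits = FALSE) else NULL)
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  state
}

restoreRNG <- function(state) {
  suppressWarnings(RNGkind(state$kind[1], state$kind[2], state$kind[3]))
  if (!is.null(state$seed))
    assign(".Random.seed", state$seed, globalenv())
  invisible(NULL)
}

## stops unless x is a single number satisfying the predicate
checkScalar <- function(x, what, positive = TRUE) {
  if (length(x) != 1 || !is.finite(x) || (positive && x <= 0))
    stop(sprintf("'%s' must be a single positive finite number", what),
         call. = FALSE)
  invisible(x)
}

## label of block containing each midpoint (vectorised per chromosome);
## blocks is a tiling data.table(chrom, start, end, <labelcol>)
blockLabelAt <- function(blocks, chrom, pos, labelcol = "label") {
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    b <- blocks[blocks$chrom == ch]
    if (!nrow(b)) next
    sel <- which(chrom == ch)
    idx <- findInterval(pos[sel], b$start)
    ok <- idx >= 1 & pos[sel] < b$end[pmax(idx, 1)]
    out[sel[ok]] <- b[[labelcol]][idx[ok]]
  }
  out
}
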