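#' @import methods
#' @importFrom data.table data.table as.data.table setkey setkeyv := fread fwrite rbindlist setorder copy
NULL

#' GenomeLayout: chromosome names, lengths and the macro/micro split
#'
#' Holds an ordered karyotype. Chromosomes longer than \code{macThreshold}
#' (default 50 Mb) are classified as macro-chromosomes (MAC), shorter ones as
#' micro-chromosomes (MIC). Lengths exactly equal to the threshold are
#' disallowed so the classification is total.
#'
#' @slot chromNames character, unique chromosome identifiers.
#' @slot chromLengths numeric, chromosome lengths in bp.
#' @slot macThreshold numeric scalar, MAC/MIC split in bp.
#' @export
setClass("GenomeLayout",
  representation(chromNames = "character",
                 chromLengths = "numeric",
                 macThreshold = "numeric"),
  prototype(macThreshold = 5e7))

setValidity("GenomeLayout", function(object) {
  msg <- NULL
  if (length(object@chromNames) != length(object@chromLengths))
    msg <- c(msg, "chromNames and chromLengths differ in length")
  if (anyDuplicated(object@chromNames))
    msg <- c(msg, "chromosome names must be unique")
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (length(object@macThreshold) != 1 || object@macThreshold <= 0)
    msg <- c(msg, "macThreshold must be a positive scalar")
  if (any(object@chromLengths == object@macThreshold))
    msg <- c(msg, "chromosome length equal to macThreshold is disallowed")
  if (is.null(msg)) TRUE else msg
})

#' SyntheticTruth: planted chromatin structures with known coordinates
#'
#' Records the ground truth planted by the simulator: alternating A/B
#' compartment blocks (with an optional switched label for a second
#' condition), TAD boundary positions, and focal loop anchor pairs.
#' All coordinates are 0-based half-open bp.
#'
#' @slot compartmentBlocks data.table with columns chrom, start, end,
#'   label (condition 1) and label2 (condition 2).
#' @slot boundaries data.table with columns chrom, pos (junction bp).
#' @slot loopAnchors data.table with columns chrom, anchor1, anchor2 (bp).
#' @slot params list of generator parameters.
#' @export
setClass("SyntheticTruth",
  representation(compartmentBlocks = "data.table",
                 boundaries = "data.table",
                 loopAnchors = "data.table",
                 params = "list"))

setValidity("SyntheticTruth", function(object) {
  msg <- NULL
  b <- object@compartmentBlocks
  if (nrow(b)) {
    bad <- b[, any(diff(start) <= 0) || any(start[-1] != end[-.N]), by = chrom]
    if (any(bad$V1)) msg <- c(msg, "compartment blocks must tile each chromosome")
  }
  bd <- object@boundaries
  if (nrow(bd) && any(bd[, any(diff(pos) <= 0), by = chrom]$V1))
    msg <- c(msg, "boundary positions must be strictly increasing per chromosome")
  la <- object@loopAnchors
  if (nrow(la) && any(la$anchor2 <= la$anchor1))
    msg <- c(msg, "loop anchor2 must exceed anchor1")
  if (is.null(msg)) TRUE else msg
})

#' ContactMap: sparse symmetric binned contact counts
#'
#' Genome-wide contact counts at a fixed bin resolution, stored as an
#' upper-triangular sparse triplet over the concatenated per-chromosome
#' bin index space (1-based global bins, bin1 <= bin2), symmetry implied.
#'
#' @slot resolution numeric, bin size in bp.
#' @slot genome GenomeLayout.
#' @slot counts data.table with integer columns bin1, bin2 and numeric count.
#' @export
setClass("ContactMap",
  representation(resolution = "numeric",
                 genome = "GenomeLayout",
                 counts = "data.table"))

setValidity("ContactMap", function(object) {
  msg <- NULL
  ct <- object@counts
  if (!all(c("bin1", "bin2", "count") %in% names(ct)))
    return("counts must have columns bin1, bin2, count")
  if (nrow(ct)) {
    if (any(ct$count < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(ct$bin1 > ct$bin2)) msg <- c(msg, "counts must be upper-triangular (bin1 <= bin2)")
    nb <- sum(chromBinCounts(object@genome, object@resolution))
    if (max(ct$bin2) > nb || min(ct$bin1) < 1)
      msg <- c(msg, "bin index outside genome bin range")
  }
  if (is.null(msg)) TRUE else msg
})

#' BalancedMatrix: ICE-balanced intra-chromosomal matrix
#'
#' Dense symmetric balanced matrix for one chromosome together with the
#' multiplicative per-bin bias vector and the validity mask. The balanced
#' matrix satisfies balanced = raw / (bias %o% bias) on unmasked bins;
#' masked bins have zero rows and columns and NA bias.
#'
#' @slot chrom character, chromosome name.
#' @slot resolution numeric, bin size in bp.
#' @slot matrix numeric matrix, the balanced signal.
#' @slot bias numeric vector of per-bin biases (NA at masked bins).
#' @slot valid logical vector, TRUE for unmasked bins.
#' @export
setClass("BalancedMatrix",
  representation(chrom = "character",
                 resolution = "numeric",
                 matrix = "matrix",
                 bias = "numeric",
                 valid = "logical"))

setValidity("BalancedMatrix", function(object) {
  n <- nrow(object@matrix)
  msg <- NULL
  if (ncol(object@matrix) != n) msg <- c(msg, "matrix must be square")
  if (length(object@bias) != n || length(object@valid) != n)
    msg <- c(msg, "bias and valid must match matrix dimension")
  if (is.null(msg)) TRUE else msg
})

#' CompartmentProfile: per-bin A/B compartment calls
#'
#' Genome-wide 100 kb (by default) eigenvector track with A/B labels and
#' gene density, oriented so that the eigenvector correlates positively
#' with gene density (A = positive = gene-dense).
#'
#' @slot genome GenomeLayout.
#' @slot resolution numeric, bin size in bp.
#' @slot bins data.table with columns chrom, start, end, eigen, label
#'   (one of "A", "B", "masked"), gene_density.
#' @slot orientationResolved named logical per chromosome; FALSE where
#'   gene density had zero variance and the sign could not be oriented.
#' @export
setClass("CompartmentProfile",
  representation(genome = "GenomeLayout",
                 resolution = "numeric",
                 bins = "data.table",
                 orientationResolved = "logical"))

setValidity("CompartmentProfile", function(object) {
  b <- object@bins
  if (!all(c("chrom", "start", "end", "eigen", "label", "gene_density") %in% names(b)))
    return("bins must have columns chrom, start, end, eigen, label, gene_density")
  if (!all(b$label %in% c("A", "B", "masked")))
    return("labels must be A, B or masked")
  TRUE
})

#' SwitchTable: cross-classification of two compartment profiles
#'
#' @slot bins data.table with columns chrom, start, end, category
#'   (one of "A->A", "A->B", "B->A", "B->B", "masked").
#' @slot genomeFractions named numeric, category fractions over unmasked bins.
#' @slot chromFractions data.table of per-chromosome category fractions.
#' @export
setClass("SwitchTable",
  representation(bins = "data.table",
                 genomeFractions = "numeric",
                 chromFractions = "data.table"))

## ---- show methods ----

setMethod("show", "GenomeLayout", function(object) {
  mac <- isMac(object)
  cat(sprintf("GenomeLayout: %d chromosomes (%d MAC > %.0f Mb, %d MIC), %.1f Mb total\n",
              length(object@chromNames), sum(mac), object@macThreshold / 1e6,
              sum(!mac), sum(object@chromLengths) / 1e6))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d compartment blocks, %d boundaries, %d loops\n",
              nrow(object@compartmentBlocks), nrow(object@boundaries),
              nrow(object@loopAnchors)))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d bp resolution, %d non-zero entries, total %.4g\n",
              as.integer(object@resolution), nrow(object@counts),
              totalContacts(object)))
})

setMethod("show", "BalancedMatrix", function(object) {
  cat(sprintf("BalancedMatrix: %s, %d bins at %d bp (%d masked)\n",
              object@chrom, nrow(object@matrix), as.integer(object@resolution),
              sum(!object@valid)))
})

setMethod("show", "CompartmentProfile", function(object) {
  tab <- table(object@bins$label)
  cat(sprintf("CompartmentProfile: %d bp bins; A=%d B=%d masked=%d\n",
              as.integer(object@resolution),
              sum(object@bins$label == "A"), sum(object@bins$label == "B"),
              sum(object@bins$label == "masked")))
})

setMethod("show", "SwitchTable", function(object) {
  f <- object@genomeFractions
  cat("SwitchTable fractions:",
      paste(sprintf("%s=%.3f", names(f), f), collapse = " "), "\n")
})

## ---- accessors ----

#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @export
setGeneric("macThreshold", function(x) standardGeneric("macThreshold"))
#' @export
setGeneric("isMac", function(x) standardGeneric("isMac"))
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))
#' @export
setGeneric("genomeLayout", function(x) standardGeneric("genomeLayout"))
#' @export
setGeneric("balancedMatrix", function(x) standardGeneric("balancedMatrix"))
#' @export
setGeneric("biasVector", function(x) standardGeneric("biasVector"))
#' @export
setGeneric("validBins", function(x) standardGeneric("validBins"))
#' @export
setGeneric("compartmentBins", function(x) standardGeneric("compartmentBins"))
#' @export
setGeneric("truthBlocks", function(x) standardGeneric("truthBlocks"))
#' @export
setGeneric("truthBoundaries", function(x) standardGeneric("truthBoundaries"))
#' @export
setGeneric("truthLoops", function(x) standardGeneric("truthLoops"))
#' @export
setGeneric("switchBins", function(x) standardGeneric("switchBins"))
#' @export
setGeneric("switchFractions", function(x) standardGeneric("switchFractions"))

#' @describeIn GenomeLayout chromosome names
setMethod("chromNames", "GenomeLayout", function(x) x@chromNames)
#' @describeIn GenomeLayout chromosome lengths in bp (named)
setMethod("chromLengths", "GenomeLayout",
          function(x) setNames(x@chromLengths, x@chromNames))
#' @describeIn GenomeLayout MAC/MIC split threshold in bp
setMethod("macThreshold", "GenomeLayout", function(x) x@macThreshold)
#' @describeIn GenomeLayout logical, TRUE for macro-chromosomes
setMethod("isMac", "GenomeLayout",
          function(x) setNames(x@chromLengths > x@macThreshold, x@chromNames))

#' @describeIn ContactMap bin resolution in bp
setMethod("resolution", "ContactMap", function(x) x@resolution)
#' @describeIn ContactMap sparse triplet table of counts
setMethod("contactCounts", "ContactMap", function(x) copy(x@counts))
#' @describeIn ContactMap the GenomeLayout
setMethod("genomeLayout", "ContactMap", function(x) x@genome)

#' @describeIn BalancedMatrix the dense balanced matrix
setMethod("balancedMatrix", "BalancedMatrix", function(x) x@matrix)
#' @describeIn BalancedMatrix the per-bin bias vector
setMethod("biasVector", "BalancedMatrix", function(x) x@bias)
#' @describeIn BalancedMatrix logical mask of unmasked bins
setMethod("validBins", "BalancedMatrix", function(x) x@valid)
#' @describeIn BalancedMatrix bin resolution in bp
setMethod("resolution", "BalancedMatrix", function(x) x@resolution)

#' @describeIn CompartmentProfile per-bin table
setMethod("compartmentBins", "CompartmentProfile", function(x) copy(x@bins))
#' @describeIn CompartmentProfile bin resolution in bp
setMethod("resolution", "CompartmentProfile", function(x) x@resolution)
#' @describeIn CompartmentProfile the GenomeLayout
setMethod("genomeLayout", "CompartmentProfile", function(x) x@genome)

#' @describeIn SyntheticTruth planted compartment blocks
setMethod("truthBlocks", "SyntheticTruth", function(x) copy(x@compartmentBlocks))
#' @describeIn SyntheticTruth planted boundary positions
setMethod("truthBoundaries", "SyntheticTruth", function(x) copy(x@boundaries))
#' @describeIn SyntheticTruth planted loop anchors
setMethod("truthLoops", "SyntheticTruth", function(x) copy(x@loopAnchors))

#' @describeIn SwitchTable per-bin switch categories
setMethod("switchBins", "SwitchTable", function(x) copy(x@bins))
#' @describeIn SwitchTable genome-wide category fractions
setMethod("switchFractions", "SwitchTable", function(x) x@genomeFractions)
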