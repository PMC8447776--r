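## Plain-text writers/readers for the pipeline's artifacts.  All tabular
## genomic intervals in the package are 0-based half-open, matching BED.

#' Write genes as BED6 (name = gene id, strand in column 6)
#' @param genes gene table (chrom, start, end, gene, score, strand)
#' @param path output path
#' @export
writeGenesBed <- function(genes, path) {
  g <- as.data.table(genes)
  fwrite(g[, .(chrom, start = as.integer(start), end = as.integer(end),
               gene, score, strand)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read genes from BED6; TSS derived from strand
#' @param path BED6 path
#' @return gene data.table with tss column
#' @export
readGenesBed <- function(path) {
  g <- fread(path, header = FALSE,
             col.names = c("chrom", "start", "end", "gene", "score", "strand"))
  g[, tss := ifelse(strand == "+", start, end - 1)]
  g[]
}

#' Write the expression table as TSV (gene, condition, count, fpkm)
#' @param expression expression table
#' @param path output path
#' @export
writeExpression <- function(expression, path) {
  fwrite(as.data.table(expression), path, sep = "\t")
  invisible(path)
}

#' Read an expression TSV
#' @param path TSV path
#' @export
readExpression <- function(path) fread(path)

#' Write peaks as BED6 with the signal in the score column
#' @param peaks peak table (mark, condition, chrom, start, end, signal)
#' @param path output path
#' @export
writePeaksBed <- function(peaks, path) {
  p <- as.data.table(peaks)
  fwrite(p[, .(chrom, start = as.integer(start), end = as.integer(end),
               name = paste(mark, condition, seq_len(.N), sep = "_"),
               score = signal, strand = ".")],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read peaks from BED6 written by \code{writePeaksBed}
#' @param path BED path
#' @export
readPeaksBed <- function(path) {
  p <- fread(path, header = FALSE,
             col.names = c("chrom", "start", "end", "name", "signal", "strand"))
  parts <- tstrsplit(p$name, "_", fixed = TRUE)
  p[, `:=`(mark = parts[[1]], condition = parts[[2]])]
  p[, c("name", "strand") := NULL]
  setcolorder(p, c("mark", "condition", "chrom", "start", "end", "signal"))
  p[]
}

#' Write the planted truth as JSON
#' @param truth a SyntheticTruth
#' @param path output path
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(
    list(compartment_blocks = truthBlocks(truth),
         boundaries = truthBoundaries(truth),
         loop_anchors = truthLoops(truth),
         params = truth@params),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a per-bin numeric track as bedGraph
#' @param bins data.table with chrom, start, end and a value column
#' @param value name of the value column
#' @param path output path
#' @export
writeBedgraph <- function(bins, value, path) {
  b <- as.data.table(bins)
  fwrite(data.table(chrom = b$chrom, start = as.integer(b$start),
                    end = as.integer(b$end), value = b[[value]]),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write compartment labels (or any labelled bins) as BED4
#' @param bins data.table with chrom, start, end and a label column
#' @param label name of the label column
#' @param path output path
#' @export
writeLabelsBed <- function(bins, label, path) {
  b <- as.data.table(bins)
  fwrite(data.table(chrom = b$chrom, start = as.integer(b$start),
                    end = as.integer(b$end), name = b[[label]]),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write boundaries as BED with strength and clipped-flag columns
#' @param boundaries padded boundary table
#' @param path output path
#' @export
writeBoundariesBed <- function(boundaries, path) {
  b <- as.data.table(boundaries)
  fwrite(b[, .(chrom, start = as.integer(start), end = as.integer(end),
               name = sprintf("boundary_%d", seq_len(.N)),
               score = round(strength, 4),
               flag = ifelse(clipped, "clipped", "full"))],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write loops as 10-column BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name, q-value,
#' compartment label, resolution.
#'
#' @param loops labelled loop table
#' @param path output path
#' @export
writeLoopsBedpe <- function(loops, path) {
  lp <- as.data.table(loops)
  if (!"compartment" %in% names(lp)) lp[, compartment := "."]
  fwrite(lp[, .(chrom1 = chrom, start1 = as.integer(start1),
                end1 = as.integer(start1 + resolution),
                chrom2 = chrom, start2 = as.integer(start2),
                end2 = as.integer(start2 + resolution),
                name = sprintf("loop_%d", seq_len(.N)),
                q_value = signif(q_value, 4),
                label = compartment, resolution = as.integer(resolution))],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
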