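## Shared synthetic fixtures, built once per test run.  The "bench" fixture
## mirrors the package's benchmark conditions: a 3-microchromosome ~30 Mb
## genome, 50 planted loops, depth 1e7, contact maps at 10 kb and 25 kb.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

benchGenome <- function() memo("genome",
  makeGenome(0, 3, mic_range = c(8e6, 1.2e7), seed = 7))

benchTruth <- function() memo("truth",
  plantTruth(benchGenome(), n_boundaries_per_chrom = 6, n_loops = 50,
             seed = 7))

benchMap10 <- function() memo("map10",
  simulateContacts(benchGenome(), benchTruth(), resolution = 1e4,
                   depth = 1e7, seed = 7))

benchMap25 <- function() memo("map25",
  simulateContacts(benchGenome(), benchTruth(), resolution = 2.5e4,
                   depth = 1e7, seed = 8))

benchBal10 <- function() memo("bal10", balanceAll(benchMap10()))
benchBal25 <- function() memo("bal25", balanceAll(benchMap25()))

benchInsulation <- function() memo("ins",
  data.table::rbindlist(lapply(benchBal10(), insulationScore)))

benchBoundaries <- function() memo("bounds", callBoundaries(benchInsulation()))

benchLoopCalls <- function() memo("loopcalls", {
  c10 <- data.table::rbindlist(lapply(benchBal10(), callLoops))
  c25 <- data.table::rbindlist(lapply(benchBal25(), callLoops))
  clusterAndMerge(list(c10, c25))
})

## compartment-scale fixture: 4 x ~20 Mb genome at 100 kb, depth 1e7
compGenome <- function() memo("cgenome",
  makeGenome(0, 4, mic_range = c(1.8e7, 2.2e7), seed = 11))

compTruth <- function() memo("ctruth",
  plantTruth(compGenome(), n_boundaries_per_chrom = 4, n_loops = 0,
             seed = 11))

compMap <- function() memo("cmap",
  simulateContacts(compGenome(), compTruth(), resolution = 1e5,
                   depth = 1e7, seed = 11))

compAnnot <- function() memo("cannot",
  simulateAnnotationAndExpression(compGenome(), compTruth(), seed = 11))

compProfile <- function() memo("cprof",
  callCompartments(compMap(), compAnnot()$genes))

## condition-2 profile derived from the planted switch labels
compProfile2 <- function() memo("cprof2", {
  prof <- compProfile()
  b <- compartmentBins(prof)
  tb <- truthBlocks(compTruth())
  mid <- (b$start + b$end) / 2
  l1 <- chromhier:::blockLabelAt(tb, b$chrom, mid, "label")
  l2 <- chromhier:::blockLabelAt(tb, b$chrom, mid, "label2")
  flip <- !is.na(l1) & !is.na(l2) & l1 != l2
  unm <- b$label != "masked"
  b$label[unm & flip] <- ifelse(b$label[unm & flip] == "A", "B", "A")
  b$eigen[unm & flip] <- -b$eigen[unm & flip]
  new("CompartmentProfile", genome = genomeLayout(prof),
      resolution = resolution(prof), bins = b,
      orientationResolved = prof@orientationResolved)
})

## tiny deterministic contact file on disk
writeTinyContacts <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  sizes <- file.path(dir, "chrom.sizes")
  writeLines(c("chrA\t50000", "chrB\t30000"), sizes)
  contacts <- file.path(dir, "contacts.tsv")
  writeLines(c("chrom1\tstart1\tchrom2\tstart2\tcount",
               "chrA\t0\tchrA\t0\t5",
               "chrA\t0\tchrA\t10000\t3"), contacts)
  list(dir = dir, sizes = sizes, contacts = contacts)
}
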