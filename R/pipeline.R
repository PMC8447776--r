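## End-to-end orchestration with a strict config, seed fan-out and a
## hashed output manifest.

#' Default run configuration
#'
#' All numeric constants used across the pipeline, overridable via a YAML
#' config.  The global seed fans out to per-stage child seeds through
#' \code{\link{childSeed}} in this fixed order: 1 genome, 2 truth,
#' 3 compartment-resolution contacts, 4 TAD/loop-resolution contacts,
#' 5 coarse loop-resolution contacts, 6 annotation/expression, 7 peaks,
#' 8 enrichment shuffles.
#'
#' @return nested configuration list
#' @export
defaultConfig <- function() {
  list(
    seed = 1,
    genome = list(n_mac = 0, n_mic = 3, mac_range = c(6e7, 1.6e8),
                  mic_range = c(8e6, 1.2e7), mac_threshold = 5e7),
    truth = list(comp_block_bp = 1e6, n_boundaries_per_chrom = 8,
                 n_loops = 50, max_loop_span = 1e6, p_A = 0.7,
                 switch_fraction = 0.2),
    contacts = list(depth = 1e7, decay_alpha = 1.0, comp_strength = 2.5,
                    tad_strength = 2.0, loop_strength = 8,
                    trans_level = 0.01, mic_trans_boost = 2,
                    target_total = 1e9),
    resolutions = list(compartment = 1e5, tad = 1e4, loop = c(1e4, 2.5e4)),
    domains = list(window = 1e5, delta_window = 1e5, min_strength = 0.1,
                   pad = 4e4),
    loops = list(max_dist = 1e6, fdr = 0.1, min_fold = 1.5,
                 peak_width = 1, donut_width = 5, fpkm_high = 20),
    expression = list(genes_per_mb_A = 12, genes_per_mb_B = 4,
                      lfc_switch_effect = 1.5, dispersion = 0.1),
    peaks = list(a_bias = 0.9, peak_len_mean = 1500, n_peaks = 500),
    de = list(lfc_min = 1, padj_max = 0.01),
    integrate = list(n_shuffles = 200, promoter_upstream = 1000))
}

#' Read and validate a run configuration from YAML
#'
#' Unknown keys (at top level or within a section) are rejected; values
#' present in the file override the defaults.
#'
#' @param path YAML file path
#' @return validated configuration list
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- defaultConfig()
  bad <- setdiff(names(user), names(base))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    if (is.list(base[[sec]])) {
      badk <- setdiff(names(user[[sec]]), names(base[[sec]]))
      if (length(badk))
        stop(sprintf("unknown keys in config section '%s': %s", sec,
                     paste(badk, collapse = ", ")))
      base[[sec]][names(user[[sec]])] <- user[[sec]]
    } else base[[sec]] <- user[[sec]]
  }
  validateConfig(base)
  base
}

validateConfig <- function(cfg) {
  bp_keys <- c(cfg$resolutions$compartment, cfg$resolutions$tad,
               cfg$resolutions$loop, cfg$domains$window, cfg$domains$pad,
               cfg$loops$max_dist)
  if (any(bp_keys <= 0 | bp_keys %% 1000 != 0))
    stop("bp-valued config entries must be positive multiples of 1 kb")
  invisible(cfg)
}

#' Run the full synthetic-data pipeline
#'
#' simulate -> library normalization -> interaction summary -> compartments
#' (both conditions via the planted switch labels) -> switch classification
#' and expression test -> insulation/TAD boundaries -> loops (both
#' resolutions, merged) -> peak/feature integration.  Writes all artifacts
#' under \code{outdir} and a JSON manifest with md5 hashes and the seed;
#' identical config and seed give identical manifest hashes.
#'
#' @param config configuration list (see \code{defaultConfig})
#' @param outdir output directory (created if needed)
#' @param seed optional override of \code{config$seed}
#' @param verbose print per-stage log lines
#' @return (invisibly) the manifest list
#' @export
runAll <- function(config = defaultConfig(), outdir = tempfile("chromhier_"),
                   seed = NULL, verbose = TRUE) {
  if (!is.null(seed)) config$seed <- seed
  validateConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]
  say <- function(stage, ...) if (verbose)
    message(sprintf("[%6.1fs] %s %s", proc.time()[3] - t0, stage,
                    paste(..., collapse = " ")))
  paths <- character(0)
  keep <- function(p) { paths[length(paths) + 1] <<- p; p }
  stage <- "simulate"
  manifest <- list(seed = config$seed, stages = character(0))
  res_c <- config$resolutions$compartment
  res_t <- config$resolutions$tad
  res_l <- sort(unlist(config$resolutions$loop))

  out <- tryCatch({
    g <- config$genome; tr <- config$truth; cc <- config$contacts
    genome <- makeGenome(g$n_mac, g$n_mic, g$mac_range, g$mic_range,
                         seed = childSeed(config$seed, 1),
                         mac_threshold = g$mac_threshold)
    truth <- plantTruth(genome, tr$comp_block_bp, tr$n_boundaries_per_chrom,
                        tr$n_loops, tr$max_loop_span, tr$p_A,
                        tr$switch_fraction, seed = childSeed(config$seed, 2))
    keep(writeChromsizes(genome, file.path(outdir, "chrom.sizes")))
    keep(writeTruthJson(truth, file.path(outdir, "truth.json")))
    say(stage, sprintf("genome %.1f Mb, %d loops planted",
                       sum(chromLengths(genome)) / 1e6, tr$n_loops))

    simContacts <- function(res, k) simulateContacts(
      genome, truth, resolution = res, depth = cc$depth,
      decay_alpha = cc$decay_alpha, comp_strength = cc$comp_strength,
      tad_strength = cc$tad_strength, loop_strength = cc$loop_strength,
      trans_level = cc$trans_level, mic_trans_boost = cc$mic_trans_boost,
      seed = childSeed(config$seed, k))
    map_c <- simContacts(res_c, 3)
    map_t <- simContacts(res_t, 4)
    map_l2 <- if (length(res_l) > 1) simContacts(res_l[2], 5) else NULL
    keep(writeContacts(map_t, file.path(outdir, "contacts.tsv.gz")))

    ae <- simulateAnnotationAndExpression(
      genome, truth, config$expression$genes_per_mb_A,
      config$expression$genes_per_mb_B, config$expression$lfc_switch_effect,
      config$expression$dispersion, seed = childSeed(config$seed, 6))
    keep(writeGenesBed(ae$genes, file.path(outdir, "genes.bed")))
    keep(writeExpression(ae$expression, file.path(outdir, "expression.tsv")))
    pks <- simulatePeaks(truth, genome, config$peaks$a_bias,
                         config$peaks$peak_len_mean, config$peaks$n_peaks,
                         seed = childSeed(config$seed, 7))
    keep(writePeaksBed(rbindlist(pks), file.path(outdir, "peaks.bed")))

    stage <- "normalize"
    ## library normalization makes libraries comparable; boundary and loop
    ## statistics run on the raw-count scale (Poisson testing needs counts)
    map_t_raw <- map_t
    map_l2_raw <- map_l2
    map_c <- normalizeLibrary(map_c, cc$target_total)
    map_t <- normalizeLibrary(map_t, cc$target_total)
    if (!is.null(map_l2)) map_l2 <- normalizeLibrary(map_l2, cc$target_total)
    summ <- interactionSummary(map_c)
    jsonlite::write_json(summ[c("class_means", "tests")],
                         keep(file.path(outdir, "interaction_summary.json")),
                         digits = NA, dataframe = "rows")
    say(stage, sprintf("total normalized to %.3g", cc$target_total))

    stage <- "compartments"
    prof1 <- callCompartments(map_c, ae$genes)
    keep(writeBedgraph(compartmentBins(prof1), "eigen",
                       file.path(outdir, "eigenvector.bedgraph")))
    keep(writeLabelsBed(compartmentBins(prof1), "label",
                        file.path(outdir, "compartments.bed")))
    say(stage, "profile called")

    stage <- "switches"
    ## condition-2 profile from the planted switch labels (the synthetic
    ## pipeline has one contact library; switch truth drives condition 2)
    b2 <- compartmentBins(prof1)
    lab2 <- blockLabelAt(truthBlocks(truth), b2$chrom,
                         (b2$start + b2$end) / 2, "label2")
    lab1 <- blockLabelAt(truthBlocks(truth), b2$chrom,
                         (b2$start + b2$end) / 2, "label")
    flip <- !is.na(lab1) & !is.na(lab2) & lab1 != lab2
    b2[label != "masked" & flip,
       label := ifelse(label == "A", "B", "A")]
    b2[label != "masked" & flip, eigen := -eigen]
    prof2 <- new("CompartmentProfile", genome = prof1@genome,
                 resolution = prof1@resolution, bins = b2,
                 orientationResolved = prof1@orientationResolved)
    sw <- switchClassify(prof1, prof2)
    keep(writeLabelsBed(switchBins(sw), "category",
                        file.path(outdir, "switches.bed")))
    lfc <- geneLogFC(ae$expression)
    swt <- switchExpressionTest(sw, lfc, ae$genes)
    fwrite(swt, keep(file.path(outdir, "switch_expression.tsv")), sep = "\t")
    say(stage, sprintf("opposite-switch fraction %.3f",
                       sum(switchFractions(sw)[c("A->B", "B->A")])))

    stage <- "tads"
    bal_t <- balanceAll(map_t_raw)
    ins <- rbindlist(lapply(bal_t, insulationScore,
                            window = config$domains$window))
    keep(writeBedgraph(ins[valid == TRUE,
                           .(chrom, start, end = start + res_t, score)],
                       "score", file.path(outdir, "insulation.bedgraph")))
    raw_b <- callBoundaries(ins, res_t, config$domains$delta_window,
                            config$domains$min_strength)
    bset <- padBoundaries(raw_b, genome, res_t, config$domains$pad)
    keep(writeBoundariesBed(bset, file.path(outdir, "boundaries.bed")))
    tads <- deriveTads(bset, genome, res_t)
    fwrite(tads, keep(file.path(outdir, "tads.bed")), sep = "\t",
           col.names = FALSE)
    say(stage, sprintf("%d boundaries, %d TADs", nrow(bset), nrow(tads)))

    stage <- "loops"
    cands <- lapply(bal_t, callLoops, max_dist = config$loops$max_dist,
                    peak_width = config$loops$peak_width,
                    donut_width = config$loops$donut_width,
                    fdr = config$loops$fdr, min_fold = config$loops$min_fold)
    cands <- list(rbindlist(cands))
    if (!is.null(map_l2_raw)) {
      bal_l2 <- balanceAll(map_l2_raw)
      cands[[2]] <- rbindlist(lapply(bal_l2, callLoops,
                                     max_dist = config$loops$max_dist,
                                     peak_width = config$loops$peak_width,
                                     donut_width = config$loops$donut_width,
                                     fdr = config$loops$fdr,
                                     min_fold = config$loops$min_fold))
    }
    merged <- clusterAndMerge(cands)
    lab <- assignCompartment(merged$loops, prof1)
    keep(writeLoopsBedpe(lab$loops, file.path(outdir, "loops.bedpe")))
    cpl <- loopGeneCoupling(merged$loops, ae$genes, ae$expression,
                            fpkm_high = config$loops$fpkm_high)
    say(stage, sprintf("%d loop peaks, %d loci", merged$n_peaks,
                       merged$n_loci))

    stage <- "integrate"
    ablocks <- compartmentBins(prof1)[label == "A", .(chrom, start, end)]
    bblocks <- compartmentBins(prof1)[label == "B", .(chrom, start, end)]
    enr <- list(
      H3ac_in_A = peakFeatureEnrichment(pks$H3ac, ablocks, genome,
                                        config$integrate$n_shuffles,
                                        seed = childSeed(config$seed, 8)),
      H3K27me3_in_B = peakFeatureEnrichment(pks$H3K27me3, bblocks, genome,
                                            config$integrate$n_shuffles,
                                            seed = childSeed(config$seed, 8)))
    prom <- list(
      H3ac = promoterStats(pks$H3ac, ae$genes,
                           config$integrate$promoter_upstream),
      H3K27me3 = promoterStats(pks$H3K27me3, ae$genes,
                               config$integrate$promoter_upstream))
    mec <- markExpressionCorrelation(rbindlist(pks), ae$genes, ae$expression)
    jsonlite::write_json(
      list(enrichment = lapply(enr, function(e)
             e[c("observed", "observed_frac", "z", "odds_ratio", "fisher_p")]),
           promoter_fraction = prom,
           mark_expression = mec,
           loop_gene_coupling = cpl[c("coupled_high_frac",
                                      "uncoupled_high_frac", "p_value",
                                      "n_coupled", "n_uncoupled")]),
      keep(file.path(outdir, "integration.json")),
      digits = NA, dataframe = "rows", auto_unbox = TRUE)
    say(stage, "done")

    manifest$stages <- c("simulate", "normalize", "compartments", "switches",
                         "tads", "loops", "integrate")
    manifest$files <- lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
    manifest
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    manifest$files <- lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(out)
}
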