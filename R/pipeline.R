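# End-to-end orchestration: build-ref -> map (composite and genome-only) ->
# mappability -> quantify -> specificity, with report tables and always-on
# intermediate artifacts.

.log <- function(...) message("[pseudoquant] ", ...)

#' Assemble and validate a pipeline configuration
#'
#' @param genome Genome FASTA path or named `DNAStringSet`.
#' @param transcripts Spliced parent mRNA FASTA path or `DNAStringSet`.
#' @param annotations Pseudogene BED path or annotated `GRanges`.
#' @param reads Named list/vector: per sample, a FASTQ path or a named
#'   `DNAStringSet`.
#' @param outDir Output directory, or `NULL` for in-memory results only.
#' @param L Read length (bp).
#' @param m Uniqueome mismatch budget.
#' @param rpkmDenominator `"pre_uniqueome"` (reads uniquely mapped to the
#'   composite reference; default) or `"post_uniqueome"` (after mappability
#'   filtering).
#' @param thresholds RPKM thresholds for the exceedance summary.
#' @param trackGenomeOnly If `TRUE`, mappability ignores decoy contigs.
#' @param seed Seed recorded for provenance (the pipeline itself is
#'   deterministic).
#' @return A validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(genome, transcripts, annotations, reads,
                           outDir = NULL, L = 75L, m = 4L,
                           rpkmDenominator = c("pre_uniqueome",
                                               "post_uniqueome"),
                           thresholds = c(1, 2, 5, 10, 15),
                           trackGenomeOnly = FALSE, seed = 1L) {
  rpkmDenominator <- match.arg(rpkmDenominator)
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    stop("'reads' must be named by sample")
  for (x in list(genome = genome, transcripts = transcripts,
                 annotations = annotations)) {
    if (is.character(x) && length(x) == 1L && !file.exists(x))
      stop("input file does not exist: ", x)
  }
  structure(list(genome = genome, transcripts = transcripts,
                 annotations = annotations, reads = reads, outDir = outDir,
                 L = as.integer(L), m = as.integer(m),
                 rpkmDenominator = rpkmDenominator, thresholds = thresholds,
                 trackGenomeOnly = isTRUE(trackGenomeOnly),
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Expected keys mirror the arguments of [pipelineConfig()]; `reads` is a
#' mapping from sample name to FASTQ path.  Relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  pipelineConfig(
    genome = rel(y$genome), transcripts = rel(y$transcripts),
    annotations = rel(y$annotations),
    reads = stats::setNames(rel(unlist(y$reads)), names(y$reads)),
    outDir = y$outDir %||% NULL, L = y$L %||% 75L, m = y$m %||% 4L,
    rpkmDenominator = y$rpkmDenominator %||% "pre_uniqueome",
    thresholds = y$thresholds %||% c(1, 2, 5, 10, 15),
    trackGenomeOnly = y$trackGenomeOnly %||% FALSE, seed = y$seed %||% 1L)
}

.loadSeqInput <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(readDNAStringSet(x))
  .asDNAStringSet(x)
}

.loadAnnInput <- function(x) {
  if (is(x, "GRanges")) return(x)
  loadAnnotations(x)
}

.loadReadsInput <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  readReadsFASTQ(x)
}

#' Run the full pseudogene-transcription pipeline
#'
#' Stages: composite-reference construction, exact-unique mapping of every
#' sample against both the composite and the plain genome, extended-uniqueome
#' computation, mappability filtering, RPKM/coverage quantification, and
#' Jensen-Shannon tissue-specificity scoring.  Report tables (mapping ratio,
#' per-sample statistics, top expression, RPKM threshold summary, specificity
#' distribution) are produced with [makeReportTables()].  With
#' `config$outDir` set, every intermediate artifact (composite FASTA, hit
#' BEDs, track BED, stats/expression TSVs) is written so each reported
#' number can be recomputed from files.
#'
#' @param config A `pipelineConfig` (see [pipelineConfig()]).
#' @return A list: `se` (pseudogene x sample `SummarizedExperiment`),
#'   `stats`, `ratios`, `specificity`, `tables`, `track`, and `outDir`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  L <- config$L; m <- config$m
  stage <- function(name, expr) {
    .log("stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  genome <- stage("load-inputs", .loadSeqInput(config$genome))
  transcripts <- .loadSeqInput(config$transcripts)
  ann <- .loadAnnInput(config$annotations)
  proc <- filterProcessed(ann)
  .log(length(proc), " processed pseudogene(s) of ", length(ann),
       " annotated")

  composite <- stage("build-ref", buildComposite(genome, transcripts))
  idxC <- stage("index-composite", buildIndex(composite, L))
  idxG <- stage("index-genome", buildIndex(genomeOnly(composite), L))
  track <- stage("mappability",
                 computeUniqueStarts(composite, L, m,
                                     genomeOnly = config$trackGenomeOnly))
  .log("uniqueome: ", sum(lengths(uniqueStarts(track))),
       " unique starts (L = ", L, ", m = ", m, ")")

  samples <- names(config$reads)
  statsRows <- list(); ratioRows <- list(); records <- list()
  hitStore <- list()
  for (s in samples) {
    reads <- .loadReadsInput(config$reads[[s]])
    mc <- stage(paste0("map-composite:", s), mapUnique(idxC, reads, s))
    mg <- stage(paste0("map-genome:", s), mapUnique(idxG, reads, s))
    filtered <- stage(paste0("uniqueome-filter:", s),
                      intersectHits(mc$hits, track))
    denom <- switch(config$rpkmDenominator,
                    pre_uniqueome = mc$stats$uniquely_mapped,
                    post_uniqueome = length(filtered))
    records[[s]] <- quantifySample(filtered, proc, track,
                                   totalMapped = max(denom, 1L), sample = s)
    statsRows[[s]] <- cbind(mc$stats,
      uniquely_mapped_plain = mg$stats$uniquely_mapped,
      uniquely_mapped_after_uniqueome = length(filtered))
    pgC <- sum(countReadsPerFeature(mc$hits, proc))
    pgG <- sum(countReadsPerFeature(mg$hits, proc))
    ratioRows[[s]] <- data.frame(sample = s, pseudogene_composite = pgC,
                                 pseudogene_plain = pgG,
                                 ratio = compositeRatio(pgC, pgG))
    hitStore[[s]] <- list(composite = mc$hits, plain = mg$hits,
                          filtered = filtered)
    .log("sample ", s, ": ", mc$stats$uniquely_mapped,
         " uniquely mapped (composite), ", length(filtered),
         " after uniqueome")
  }
  statsDf <- do.call(rbind, c(statsRows, make.row.names = FALSE))
  ratioDf <- do.call(rbind, c(ratioRows, make.row.names = FALSE))
  se <- expressionSE(records, proc)
  spec <- stage("specificity", specificityTable(se))
  tables <- makeReportTables(se, statsDf, spec, ratioDf,
                             thresholds = config$thresholds)

  outDir <- config$outDir
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeComposite(composite, file.path(outDir, "composite.fa"))
    exportTrackBED(track, file.path(outDir, "unique_starts.bed"))
    writeAnnotations(proc, file.path(outDir, "pseudogenes.processed.bed"))
    for (s in samples) {
      exportHitsBED(hitStore[[s]]$composite,
                    file.path(outDir, paste0(s, ".composite.hits.bed")))
      exportHitsBED(hitStore[[s]]$plain,
                    file.path(outDir, paste0(s, ".plain.hits.bed")))
      exportHitsBED(hitStore[[s]]$filtered,
                    file.path(outDir, paste0(s, ".filtered.hits.bed")))
      .writeTSV(records[[s]], file.path(outDir, paste0(s, ".expr.tsv")))
    }
    .writeTSV(statsDf, file.path(outDir, "mapping_stats.tsv"))
    rpkmMat <- SummarizedExperiment::assay(se, "rpkm")
    .writeTSV(data.frame(pseudogene_id = rownames(rpkmMat), rpkmMat,
                         check.names = FALSE),
              file.path(outDir, "rpkm_matrix.tsv"))
    .writeTSV(spec, file.path(outDir, "specificity.tsv"))
    for (nm in names(tables))
      .writeTSV(tables[[nm]], file.path(outDir, paste0("table_", nm, ".tsv")))
    cfgEcho <- config[c("L", "m", "rpkmDenominator", "thresholds",
                        "trackGenomeOnly", "seed")]
    yaml::write_yaml(cfgEcho, file.path(outDir, "config_used.yaml"))
    .log("report bundle written to ", outDir)
  }
  list(se = se, stats = statsDf, ratios = ratioDf, specificity = spec,
       tables = tables, track = track, outDir = outDir)
}

#' Build report tables
#'
#' Produces the pipeline's five summary tables with deterministic column
#' order and table-style rounding (ratios 2 dp, RPKM 1 dp, coverage 3 dp,
#' specificity 3 dp):
#' \describe{
#'   \item{ratios}{Per-sample pseudogene read counts in the composite vs the
#'     plain genome with their ratio, plus an `Average` row (mean of the
#'     per-sample ratios, 2 dp).}
#'   \item{stats}{Per-sample mapping statistics.}
#'   \item{top_expression}{Per pseudogene: parent, location, tissue with max
#'     RPKM, max and total RPKM, specificity, coverage in the max tissue;
#'     sorted by max RPKM descending.}
#'   \item{thresholds}{Per sample (and combined), percentage of pseudogene
#'     RPKM values above each threshold.}
#'   \item{specificity_hist}{Histogram of specificity scores plus counts
#'     above 0.5 and 0.8.}
#' }
#'
#' @param se `SummarizedExperiment` from [expressionSE()].
#' @param stats Per-sample statistics `data.frame`.
#' @param spec Specificity table from [specificityTable()].
#' @param ratios Per-sample ratio `data.frame` (`sample`,
#'   `pseudogene_composite`, `pseudogene_plain`, `ratio`).
#' @param thresholds RPKM thresholds.
#' @return Named list of `data.frame`s.
#' @export
makeReportTables <- function(se, stats, spec, ratios,
                             thresholds = c(1, 2, 5, 10, 15)) {
  rpkmMat <- SummarizedExperiment::assay(se, "rpkm")
  covMat <- SummarizedExperiment::assay(se, "coverage")
  rr <- SummarizedExperiment::rowRanges(se)

  ratioTab <- ratios
  if (nrow(ratios)) {
    avg <- data.frame(sample = "Average",
                      pseudogene_composite = round(mean(
                        ratios$pseudogene_composite)),
                      pseudogene_plain = round(mean(ratios$pseudogene_plain)),
                      ratio = round(mean(ratios$ratio, na.rm = TRUE), 2))
    ratioTab <- rbind(ratios, avg)
  }

  topTab <- if (nrow(spec)) {
    ids <- spec$pseudogene_id
    covAtMax <- vapply(seq_along(ids), function(i)
      covMat[ids[i], spec$max_tissue[i]], numeric(1))
    out <- data.frame(
      pseudogene_id = ids,
      parent = mcols(rr[ids])$parent,
      location = formatLocation(rr[ids]),
      max_tissue = spec$max_tissue,
      max_rpkm = round(spec$max_rpkm, 1),
      total_rpkm = round(spec$total_rpkm, 1),
      specificity = round(spec$specificity, 3),
      coverage = round(covAtMax, 3),
      stringsAsFactors = FALSE)
    out[order(-out$max_rpkm, out$pseudogene_id), , drop = FALSE]
  } else data.frame(pseudogene_id = character(0), parent = character(0),
                    location = character(0), max_tissue = character(0),
                    max_rpkm = numeric(0), total_rpkm = numeric(0),
                    specificity = numeric(0), coverage = numeric(0))

  thrTab <- if (length(rpkmMat)) {
    rows <- lapply(colnames(rpkmMat), function(s)
      data.frame(sample = s,
                 t(round(thresholdSummary(rpkmMat[, s], thresholds), 2)),
                 check.names = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      sample = "All",
      t(round(thresholdSummary(as.numeric(rpkmMat), thresholds), 2)),
      check.names = FALSE)
    do.call(rbind, c(rows, make.row.names = FALSE))
  } else data.frame(sample = character(0))

  dist <- specificityDistribution(spec$specificity)
  hist <- dist$histogram
  aboveTab <- data.frame(threshold = names(dist$above),
                         count = as.integer(dist$above))

  list(ratios = ratioTab, stats = stats, top_expression = topTab,
       thresholds = thrTab, specificity_hist = hist,
       specificity_above = aboveTab)
}
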