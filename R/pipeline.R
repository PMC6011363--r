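#' @include AllClasses.R synthetic-data.R diff-stats.R as-events.R
NULL

#' Pipeline configuration
#'
#' Bundles inputs and thresholds for \code{\link{runPipeline}}.  Default
#' thresholds are the classical calling rules: genes |FC| > 1.5 and
#' FDR < 0.01; NAT transcripts FDR < 0.01 (no fold-change gate); AS events
#' P < 0.05; enrichment corrected P <= 0.05.
#'
#' @param simulate Generate all inputs with the synthetic-data module
#'   (default TRUE).
#' @param sim A \code{\link{simulationConfig}} used when simulating.
#' @param annotationPath GTF of transcript models (required when not
#'   simulating).
#' @param countsPath Wide TSV of counts, features x samples, header row of
#'   sample names (required when not simulating).
#' @param samplesPath TSV with columns sample, condition, library_size
#'   (required when not simulating).
#' @param junctionCountsPath,regionCoveragePath Optional TSVs for the AS
#'   stage (see \code{\link{countEventSupport}}).
#' @param termMapPath TSV with columns term, gene.  Required when
#'   \code{enrichment} is on and not simulating.
#' @param enrichment Run the GO-enrichment stage (default TRUE).
#' @param geneFc,geneFdr,natFdr,asP,enrichP Calling thresholds.
#' @param strandMode Strandedness protocol for any fragment counting.
#' @param minOverlap Minimum NAT span overlap in nt.
#' @return list of class \code{PipelineConfig}; invalid combinations fail
#'   here, before any compute.
#' @export
pipelineConfig <- function(simulate = TRUE, sim = simulationConfig(),
                           annotationPath = NULL, countsPath = NULL,
                           samplesPath = NULL, junctionCountsPath = NULL,
                           regionCoveragePath = NULL, termMapPath = NULL,
                           enrichment = TRUE, geneFc = 1.5,
                           geneFdr = 0.01, natFdr = 0.01, asP = 0.05,
                           enrichP = 0.05, strandMode = "reverse",
                           minOverlap = 1L) {
  for (v in c(geneFdr, natFdr, asP, enrichP))
    if (v <= 0 || v > 1) stop("config error: thresholds must lie in (0, 1]")
  if (geneFc <= 0) stop("config error: fold-change threshold must be > 0")
  if (!simulate) {
    for (p in c(annotationPath, countsPath, samplesPath))
      if (is.null(p) || !file.exists(p))
        stop("config error: missing required input file: ",
             if (is.null(p)) "(unset)" else p)
    if (enrichment && is.null(termMapPath))
      stop("config error: enrichment enabled but no term map supplied")
  }
  if (!is.null(termMapPath) && !file.exists(termMapPath))
    stop("config error: term map not found: ", termMapPath)
  cfg <- list(simulate = simulate, sim = sim,
              annotationPath = annotationPath, countsPath = countsPath,
              samplesPath = samplesPath,
              junctionCountsPath = junctionCountsPath,
              regionCoveragePath = regionCoveragePath,
              termMapPath = termMapPath, enrichment = enrichment,
              geneFc = geneFc, geneFdr = geneFdr, natFdr = natFdr,
              asP = asP, enrichP = enrichP, strandMode = strandMode,
              minOverlap = as.integer(minOverlap))
  class(cfg) <- "PipelineConfig"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# simulated GO term map: one term enriched in the planted up/down features,
# background terms drawn uniformly
.simulateTermMap <- function(truth, seed) {
  set.seed(seed + 3L)
  genes <- truth$features$feature_id
  diffG <- truth$features$feature_id[truth$features$differential]
  rows <- list()
  nPick <- min(30L, length(diffG))
  if (nPick > 0L)
    rows[[1L]] <- data.frame(
      term = "T:planted", gene = c(sample(diffG, nPick),
                                   sample(genes, 5L)))
  for (t in seq_len(20L))
    rows[[length(rows) + 1L]] <- data.frame(
      term = sprintf("T:bg%02d", t),
      gene = sample(genes, sample(20:60, 1L)))
  unique(do.call(rbind, rows))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> NAT discovery -> AS enumeration ->
#' differential expression (genes and NATs) -> differential AS ->
#' enrichment, writing every stage table, a JSON summary and a manifest
#' (input md5 hashes, package version, seed) into \code{outDir}.  A stage
#' failure aborts with the stage name.  Rerunning with the same
#' configuration reproduces every output byte for byte.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (config$simulate) {
    ann <- .stage("simulate-annotation", generateAnnotation(config$sim))
    ts <- ann$transcripts
    truth <- ann$truth
    .stage("simulate-annotation",
           writeGTF(ts, file.path(outDir, "annotation.gtf")))
  } else {
    ts <- .stage("read-annotation", readGTF(config$annotationPath))
  }

  nps <- .stage("nat-discovery",
                findNatPairs(ts, minOverlap = config$minOverlap))
  writeNatPairs(nps, file.path(outDir, "nat_pairs.tsv"),
                file.path(outDir, "nat_overlaps.bed"))

  aes <- .stage("as-enumeration", enumerateEvents(ts))
  writeAsEvents(aes, file.path(outDir, "as_events.tsv"),
                file.path(outDir, "as_regions.bed"))

  if (config$simulate) {
    simc <- .stage("simulate-counts", simulateCounts(truth, config$sim))
    se <- simc$se
    jc <- simc$junctionCounts
    rc <- simc$regionCoverage
    cnt <- as.data.frame(assay(se, "counts"))
    .writeTSV(cbind(feature_id = rownames(cnt), cnt),
              file.path(outDir, "counts.tsv"))
    .writeTSV(jc, file.path(outDir, "junction_counts.tsv"))
    .writeTSV(rc, file.path(outDir, "region_coverage.tsv"))
    .writeTSV(data.frame(sample = colnames(se),
                         condition = colData(se)$condition,
                         library_size = colData(se)$library_size),
              file.path(outDir, "samples.tsv"))
  } else {
    se <- .stage("read-counts", {
      cnt <- utils::read.table(config$countsPath, header = TRUE,
                               sep = "\t", row.names = 1,
                               check.names = FALSE)
      smp <- utils::read.table(config$samplesPath, header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
      countMatrix(as.matrix(cnt),
                  condition = setNames(smp$condition, smp$sample),
                  librarySize = setNames(smp$library_size, smp$sample))
    })
    jc <- if (!is.null(config$junctionCountsPath))
      utils::read.table(config$junctionCountsPath, header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE) else NULL
    rc <- if (!is.null(config$regionCoveragePath))
      utils::read.table(config$regionCoveragePath, header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE) else NULL
  }

  de <- .stage("differential-expression",
               nbDifferentialExpression(se, fcThreshold = config$geneFc,
                                        fdrThreshold = config$geneFdr))
  .writeTSV(de, file.path(outDir, "diff_expression.tsv"))

  natTx <- unique(c(mcols(natPairs(nps))$plus_tx,
                    mcols(natPairs(nps))$minus_tx))
  deNat <- .stage("differential-nats", {
    sub <- de[de$feature_id %in% natTx,
              setdiff(colnames(de), c("significant", "direction"))]
    callDifferential(sub, fdrThreshold = config$natFdr, fcGate = FALSE)
  })
  .writeTSV(deNat, file.path(outDir, "diff_nats.tsv"))

  diffAs <- NULL
  if (!is.null(jc) && length(aes)) {
    diffAs <- .stage("differential-as", {
      evc <- suppressWarnings(
        countEventSupport(aes, jc, rc,
                          readLength = if (config$simulate)
                            config$sim$readLength else 125))
      cond <- if (config$simulate)
        setNames(colData(se)$condition, colnames(se))
      else setNames(colData(se)$condition, colnames(se))
      testDifferentialAS(evc, cond, pThreshold = config$asP)
    })
    .writeTSV(diffAs, file.path(outDir, "diff_as.tsv"))
  }

  enr <- NULL
  if (config$enrichment) {
    enr <- .stage("enrichment", {
      tm <- if (!is.null(config$termMapPath))
        utils::read.table(config$termMapPath, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      else .simulateTermMap(truth, config$sim$seed)
      td <- txData(ts)
      gmap <- setNames(td$gene_id, td$transcript_id)
      feat2gene <- function(f) {
        g <- gmap[f]; g[is.na(g)] <- f[is.na(g)]; unique(g)
      }
      universe <- feat2gene(de$feature_id)
      sig <- feat2gene(de$feature_id[de$significant])
      if (is.null(config$termMapPath)) {
        tm$gene <- unname(gmap[tm$gene])
      }
      hypergeometricEnrichment(sig, universe, tm, alpha = config$enrichP)
    })
    .writeTSV(enr, file.path(outDir, "enrichment.tsv"))
  }

  pairClass <- table(factor(mcols(natPairs(nps))$nat_class,
                            levels = NAT_CLASSES))
  evType <- table(factor(mcols(asEvents(aes))$event_type,
                         levels = AS_TYPES))
  summary <- list(
    nat_pairs = c(list(total = length(nps)), as.list(pairClass)),
    lnc_nat_pairs = sum(mcols(natPairs(nps))$lnc_nat),
    as_events = c(list(total = length(aes)), as.list(evType)),
    significant_genes = sum(de$significant),
    significant_nats = sum(deNat$significant),
    differential_as_events = if (is.null(diffAs)) 0L
                             else sum(diffAs$significant),
    enriched_terms = if (is.null(enr)) 0L else sum(enr$significant))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  files <- sort(list.files(outDir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    seed = if (config$simulate) config$sim$seed else NA,
    package_version = as.character(utils::packageVersion("cisNATseq")),
    thresholds = config[c("geneFc", "geneFdr", "natFdr", "asP",
                          "enrichP")],
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(outDir, f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
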