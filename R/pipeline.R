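#' Assemble and validate a pipeline configuration
#'
#' Either the six input paths (expression matrix, condition map, GFF3,
#' attributes TSV, OBO, GAF) or a \linkS4class{SyntheticSpec} must be
#' given. The stringent cutoff may not exceed the highly stringent one.
#'
#' @param outDir output directory (created if needed).
#' @param matrixPath,conditionMapPath,gff3Path,attributesPath,oboPath,gafPath
#'   input files; ignored when \code{synthetic} is supplied.
#' @param synthetic optional \linkS4class{SyntheticSpec}; when given, the
#'   inputs are generated and written to \code{outDir} first.
#' @param stringent,highlyStringent the dual stringency cutoffs.
#' @param calibrationCandidates candidate thresholds for the permutation
#'   null.
#' @param seed master seed for permutation (and synthetic generation when
#'   \code{synthetic} carries no seed override).
#' @param alpha,correction,enrichMode GO-enrichment controls.
#' @param floorQuantile expression floor percentile for the SM core survey.
#' @param minCores minimum core partners in the trans-regulator scan.
#' @param queryGenes genes for which per-query sub-network, prioritized and
#'   enrichment TSVs are emitted (sub-network emission is by request; the
#'   summary table always covers all genes).
#' @param pseudocount log2 pseudocount for zero intensities.
#' @return validated config list of class \code{coexPipelineConfig}.
#' @export
pipelineConfig <- function(outDir,
                           matrixPath = NULL, conditionMapPath = NULL,
                           gff3Path = NULL, attributesPath = NULL,
                           oboPath = NULL, gafPath = NULL,
                           synthetic = NULL,
                           stringent = 0.5, highlyStringent = 0.7,
                           calibrationCandidates = c(0.3, 0.4, 0.5, 0.6, 0.7),
                           seed = 1L, alpha = 0.05,
                           correction = c("none", "bonferroni"),
                           enrichMode = c("combined", "positive_only",
                                          "negative_only"),
                           floorQuantile = 0.2, minCores = 2L,
                           queryGenes = character(0), pseudocount = 1) {
  correction <- match.arg(correction)
  enrichMode <- match.arg(enrichMode)
  if (stringent > highlyStringent)
    stop("invalid cutoffs: stringent must be <= highlyStringent")
  if (is.null(synthetic)) {
    paths <- c(matrixPath, conditionMapPath, gff3Path, attributesPath,
               oboPath, gafPath)
    if (length(paths) != 6L)
      stop("either a synthetic spec or all six input paths are required")
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
  } else if (!methods::is(synthetic, "SyntheticSpec")) {
    stop("synthetic must be a SyntheticSpec")
  }
  structure(list(outDir = outDir, matrixPath = matrixPath,
                 conditionMapPath = conditionMapPath, gff3Path = gff3Path,
                 attributesPath = attributesPath, oboPath = oboPath,
                 gafPath = gafPath, synthetic = synthetic,
                 stringent = stringent, highlyStringent = highlyStringent,
                 calibrationCandidates = calibrationCandidates,
                 seed = as.integer(seed), alpha = alpha,
                 correction = correction, enrichMode = enrichMode,
                 floorQuantile = floorQuantile,
                 minCores = as.integer(minCores),
                 queryGenes = queryGenes, pseudocount = pseudocount),
            class = "coexPipelineConfig")
}

# per-gene partner counts at a cutoff, covering every gene
.geneNetworkSizes <- function(corr, cutoff) {
  e <- corEdges(corr)
  e <- e[abs(e$rho) >= cutoff, , drop = FALSE]
  genes <- corr@allGenes
  cnt <- function(ids) {
    t <- table(factor(ids, levels = genes))
    as.integer(t)
  }
  data.frame(gene_id = genes,
             n_positive = cnt(c(e$gene_a[e$rho > 0], e$gene_b[e$rho > 0])),
             n_negative = cnt(c(e$gene_a[e$rho < 0], e$gene_b[e$rho < 0])),
             stringsAsFactors = FALSE)
}

#' Run the full co-expression analysis end-to-end
#'
#' Stage order: read (or simulate) and collapse the compendium, calibrate
#' the threshold against the permutation null, all-pairs correlation at the
#' stringent threshold, global network summaries at both stringencies plus
#' the per-gene network-size table, per-query sub-network / prioritized /
#' enrichment TSVs, the chromosomal landscape, and the SM cluster survey
#' and trans-regulator scan. Every stage writes TSVs under the configured
#' output directory and the run manifest (JSON) records parameters and row
#' counts; rerunning an identical config reproduces identical outputs.
#'
#' @param config a config from \code{\link{pipelineConfig}}.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "coexPipelineConfig"))
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pj <- function(...) file.path(out, ...)
  files <- list()
  note <- function(stage, path, nrows) {
    files[[length(files) + 1L]] <<- list(stage = stage,
                                         file = basename(path),
                                         rows = nrows)
  }
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$synthetic)) {
    stage("simulate", {
      sim <- generateCompendium(config$synthetic)
      catalog <- generateCatalog(config$synthetic, sim$truth)
      onto <- generateOntology(config$synthetic, sim$truth)
      truth <- onto$truth
      comp <- sim$compendium
      catalogObj <- catalog
      dagObj <- onto$dag
      annObj <- onto$annotations
      writeCompendium(comp, pj("compendium_matrix.tsv"),
                      pj("condition_map.tsv"))
      writeCatalog(catalog, pj("catalog.gff3"), pj("catalog_attributes.tsv"))
      writeOntology(onto$dag, pj("ontology.obo"))
      writeAnnotations(onto$annotations, pj("annotations.gaf"))
      note("simulate", pj("compendium_matrix.tsv"), nrow(comp))
    })
  } else {
    stage("read", {
      comp <- readCompendium(config$matrixPath, config$conditionMapPath)
      catalogObj <- readCatalog(config$gff3Path, config$attributesPath)
      dagObj <- readOntology(config$oboPath)
      annObj <- readAnnotations(config$gafPath, catalogObj, dagObj)
    })
  }

  stage("collapse", {
    comp <- collapseConditions(comp, config$pseudocount)
  })
  mat <- conditionLog2(comp)

  stage("calibrate", {
    calib <- calibrateThreshold(mat, config$calibrationCandidates,
                                seed = config$seed)
    writeCalibration(calib, pj("calibration.tsv"))
    note("calibrate", pj("calibration.tsv"), length(calib@candidates))
    calibObj <- calib
  })

  stage("correlate", {
    corrObj <- allPairsCorrelation(mat, config$stringent)
    writeEdges(corrObj, pj("edges.tsv"))
    note("correlate", pj("edges.tsv"), nrow(corEdges(corrObj)))
  })

  stage("subnetworks", {
    summ <- rbind(networkSummary(corrObj, config$stringent, catalogObj),
                  networkSummary(corrObj, config$highlyStringent, catalogObj))
    .writeTsv(summ, pj("network_summary.tsv"))
    note("subnetworks", pj("network_summary.tsv"), nrow(summ))
    for (cut in c(config$stringent, config$highlyStringent)) {
      sz <- .geneNetworkSizes(corrObj, cut)
      p <- pj(sprintf("gene_network_sizes_%.2f.tsv", cut))
      .writeTsv(sz, p, c(cutoff = format(cut)))
      note("subnetworks", p, nrow(sz))
    }
  })

  background <- intersect(geneIds(comp), geneIds(catalogObj))
  if (length(config$queryGenes)) {
    stage("queries", {
      dir.create(pj("subnetworks"), showWarnings = FALSE)
      dir.create(pj("enrichment"), showWarnings = FALSE)
      annObj <- propagateAnnotations(annObj, dagObj)
      for (g in config$queryGenes) {
        for (cut in c(config$stringent, config$highlyStringent)) {
          sn <- extractSubnetwork(corrObj, g, cut)
          p <- pj("subnetworks", sprintf("%s_%.2f.tsv", g, cut))
          writeSubnetwork(sn, catalogObj, p)
          note("queries", p, subNetworkSize(sn))
          if (subNetworkSize(sn) > 0) {
            et <- enrichSubnetwork(sn, annObj, dagObj, background,
                                   mode = config$enrichMode,
                                   alpha = config$alpha,
                                   correction = config$correction)
            pe <- pj("enrichment", sprintf("%s_%.2f.tsv", g, cut))
            writeEnrichment(et, pe, c(query = g, cutoff = format(cut),
                                      mode = config$enrichMode))
            note("queries", pe, nrow(et))
          }
        }
        pr <- prioritizeSubnetwork(
          extractSubnetwork(corrObj, g, config$stringent), catalogObj)
        p <- pj("subnetworks", sprintf("%s_prioritized.tsv", g))
        .writeTsv(informantPartners(pr), p, c(query = g))
        note("queries", p, nrow(informantPartners(pr)))
      }
    })
  }

  stage("landscape", {
    prof <- classifyLoci(chromosomalLandscape(comp, catalogObj))
    writeLandscape(prof, pj("landscape.tsv"))
    note("landscape", pj("landscape.tsv"), nrow(prof))
  })

  stage("smscan", {
    clusters <- smClusters(catalogObj)
    if (length(clusters)) {
      survey <- coreExpressionSurvey(comp, clusters,
                                     floorQuantile = config$floorQuantile)
      .writeTsv(survey, pj("sm_core_survey.tsv"),
                c(floor = format(attr(survey, "floor"), digits = 6)))
      note("smscan", pj("sm_core_survey.tsv"), nrow(survey))
      coh <- clusterCoherence(corrObj, clusters, config$stringent)
      .writeTsv(coh, pj("sm_cluster_coherence.tsv"),
                c(tf_coexpressed_fraction =
                    format(attr(coh, "tf_coexpressed_fraction"))))
      note("smscan", pj("sm_cluster_coherence.tsv"), nrow(coh))
      cand <- scanTransRegulators(corrObj, catalogObj, config$stringent,
                                  config$minCores)
      .writeTsv(cand, pj("sm_regulator_candidates.tsv"),
                c(cutoff = format(config$stringent),
                  min_cores = config$minCores))
      note("smscan", pj("sm_regulator_candidates.tsv"), nrow(cand))
    }
  })

  manifest <- list(
    package = "coexatlas",
    version = as.character(utils::packageVersion("coexatlas")),
    parameters = list(
      stringent = config$stringent,
      highly_stringent = config$highlyStringent,
      calibration_candidates = config$calibrationCandidates,
      seed = config$seed, alpha = config$alpha,
      correction = config$correction, enrich_mode = config$enrichMode,
      floor_quantile = config$floorQuantile, min_cores = config$minCores,
      pseudocount = config$pseudocount,
      synthetic = !is.null(config$synthetic),
      synthetic_seed = if (!is.null(config$synthetic))
        config$synthetic@seed else NULL),
    calibration = list(status = calibrationStatus(calibObj),
                       chosen_threshold = chosenThreshold(calibObj)),
    outputs = files)
  jsonlite::write_json(manifest, pj("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
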