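#' Accessors for pipeline objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("conditionLog2", function(x) standardGeneric("conditionLog2"))

#' @rdname accessors
#' @export
setMethod("conditionLog2", "ExpressionCompendium", function(x) {
  if (ncol(x@conditionLog2) == 0)
    stop("conditionLog2 is unset; run collapseConditions() first")
  x@conditionLog2
})

#' @rdname accessors
#' @export
setGeneric("hasConditionLog2", function(x) standardGeneric("hasConditionLog2"))

#' @rdname accessors
#' @export
setMethod("hasConditionLog2", "ExpressionCompendium",
          function(x) ncol(x@conditionLog2) > 0)

#' @rdname accessors
#' @export
setGeneric("arrayConditions", function(x) standardGeneric("arrayConditions"))

#' @rdname accessors
#' @export
setMethod("arrayConditions", "ExpressionCompendium", function(x) {
  stats::setNames(as.character(colData(x)$condition), colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionCompendium", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneCatalog", function(x) names(x@ranges))

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname accessors
#' @export
setMethod("geneRanges", "GeneCatalog", function(x) x@ranges)

#' Catalog attributes as a data.frame
#'
#' @param x a \linkS4class{GeneCatalog}.
#' @return data.frame keyed by \code{gene_id} with chromosome, start, end,
#'   strand and all functional flags.
#' @export
setGeneric("geneAttributes", function(x) standardGeneric("geneAttributes"))

#' @rdname geneAttributes
#' @export
setMethod("geneAttributes", "GeneCatalog", function(x) {
  gr <- x@ranges
  mc <- as.data.frame(S4Vectors::mcols(gr))
  data.frame(gene_id = names(gr),
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             mc, row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("informantGenes", function(x) standardGeneric("informantGenes"))

#' @rdname accessors
#' @export
setMethod("informantGenes", "GeneCatalog", function(x) {
  names(x@ranges)[S4Vectors::mcols(x@ranges)$informant_category != "none"]
})

#' @rdname accessors
#' @export
setGeneric("corEdges", function(x) standardGeneric("corEdges"))

#' @rdname accessors
#' @export
setMethod("corEdges", "CorrelationResult", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("validGenes", function(x) standardGeneric("validGenes"))

#' @rdname accessors
#' @export
setMethod("validGenes", "CorrelationResult", function(x) x@validGenes)

#' @rdname accessors
#' @export
setGeneric("reportThreshold", function(x) standardGeneric("reportThreshold"))

#' @rdname accessors
#' @export
setMethod("reportThreshold", "CorrelationResult", function(x) x@reportThreshold)

#' @rdname accessors
#' @export
setGeneric("nPairsTotal", function(x) standardGeneric("nPairsTotal"))

#' @rdname accessors
#' @export
setMethod("nPairsTotal", "CorrelationResult", function(x) x@nPairsTotal)

#' @rdname accessors
#' @export
setGeneric("chosenThreshold", function(x) standardGeneric("chosenThreshold"))

#' @rdname accessors
#' @export
setMethod("chosenThreshold", "NullCalibration", function(x) x@chosenThreshold)

#' @rdname accessors
#' @export
setGeneric("calibrationStatus", function(x) standardGeneric("calibrationStatus"))

#' @rdname accessors
#' @export
setMethod("calibrationStatus", "NullCalibration", function(x) x@status)

#' @rdname accessors
#' @export
setGeneric("exceedanceCounts", function(x) standardGeneric("exceedanceCounts"))

#' @rdname accessors
#' @export
setMethod("exceedanceCounts", "NullCalibration", function(x) {
  stats::setNames(x@exceedance, format(x@candidates))
})

#' @rdname accessors
#' @export
setGeneric("queryGene", function(x) standardGeneric("queryGene"))

#' @rdname accessors
#' @export
setMethod("queryGene", "SubNetwork", function(x) x@queryGene)

#' @rdname accessors
#' @export
setMethod("queryGene", "PrioritizedSubNetwork", function(x) x@queryGene)

#' @rdname accessors
#' @export
setGeneric("positivePartners", function(x) standardGeneric("positivePartners"))

#' @rdname accessors
#' @export
setMethod("positivePartners", "SubNetwork", function(x) x@positive)

#' @rdname accessors
#' @export
setGeneric("negativePartners", function(x) standardGeneric("negativePartners"))

#' @rdname accessors
#' @export
setMethod("negativePartners", "SubNetwork", function(x) x@negative)

#' @rdname accessors
#' @export
setGeneric("subNetworkSize", function(x) standardGeneric("subNetworkSize"))

#' @rdname accessors
#' @export
setMethod("subNetworkSize", "SubNetwork",
          function(x) nrow(x@positive) + nrow(x@negative))

#' @rdname accessors
#' @export
setGeneric("informantPartners", function(x) standardGeneric("informantPartners"))

#' @rdname accessors
#' @export
setMethod("informantPartners", "PrioritizedSubNetwork", function(x) x@partners)

#' @rdname accessors
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' @rdname accessors
#' @export
setMethod("ontologyTerms", "OntologyDAG", function(x) x@terms)

#' @rdname accessors
#' @export
setGeneric("termParents", function(x) standardGeneric("termParents"))

#' @rdname accessors
#' @export
setMethod("termParents", "OntologyDAG", function(x) x@parents)

#' @rdname accessors
#' @export
setGeneric("ontologyRoots", function(x) standardGeneric("ontologyRoots"))

#' @rdname accessors
#' @export
setMethod("ontologyRoots", "OntologyDAG", function(x) x@roots)

#' @rdname accessors
#' @export
setGeneric("directAnnotations", function(x) standardGeneric("directAnnotations"))

#' @rdname accessors
#' @export
setMethod("directAnnotations", "AnnotationMap", function(x) x@direct)

#' @rdname accessors
#' @export
setGeneric("propagatedAnnotations",
           function(x) standardGeneric("propagatedAnnotations"))

#' @rdname accessors
#' @export
setMethod("propagatedAnnotations", "AnnotationMap", function(x) {
  if (!length(x@propagated))
    stop("annotations not yet propagated; run propagateAnnotations() first")
  x@propagated
})

#' @rdname accessors
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))

#' @rdname accessors
#' @export
setMethod("moduleMembership", "GroundTruth", function(x) x@moduleMembership)

#' @rdname accessors
#' @export
setGeneric("plantedRegulators", function(x) standardGeneric("plantedRegulators"))

#' @rdname accessors
#' @export
setMethod("plantedRegulators", "GroundTruth", function(x) x@plantedRegulators)

#' @rdname accessors
#' @export
setGeneric("signatureTerms", function(x) standardGeneric("signatureTerms"))

#' @rdname accessors
#' @export
setMethod("signatureTerms", "GroundTruth", function(x) x@termToModule)

setMethod("show", "ExpressionCompendium", function(object) {
  cond <- unique(colData(object)$condition)
  cat(sprintf("ExpressionCompendium: %d genes x %d arrays (%d conditions)\n",
              nrow(object), ncol(object), length(cond)))
  cat(sprintf("  conditionLog2: %s\n",
              if (hasConditionLog2(object)) "filled" else "unset"))
})

setMethod("show", "GeneCatalog", function(object) {
  mc <- S4Vectors::mcols(object@ranges)
  cat(sprintf(paste0("GeneCatalog: %d genes on %d chromosome(s); %d TF, ",
                     "%d informant, %d SM-cluster genes (%d cores)\n"),
              length(object@ranges),
              length(unique(as.character(GenomicRanges::seqnames(object@ranges)))),
              sum(mc$is_tf), sum(mc$informant_category != "none"),
              sum(!is.na(mc$sm_cluster_id)), sum(mc$is_sm_core)))
})

setMethod("show", "CorrelationResult", function(object) {
  e <- object@edges
  cat(sprintf(paste0("CorrelationResult: %d edges at |rho| >= %.2f ",
                     "(%d positive / %d negative)\n"),
              nrow(e), object@reportThreshold,
              sum(e$rho > 0), sum(e$rho < 0)))
  cat(sprintf("  %d valid genes, %s pairs evaluated over %d conditions\n",
              length(object@validGenes),
              format(object@nPairsTotal, big.mark = ","),
              object@nConditions))
})

setMethod("show", "NullCalibration", function(object) {
  cat(sprintf("NullCalibration (%s): seed %d, %s null pairs, max |rho| = %.4f\n",
              object@status, object@seed,
              format(object@nNullPairs, big.mark = ","),
              object@maxAbsRhoNull))
  print(exceedanceCounts(object))
  if (object@status == "calibrated")
    cat(sprintf("  chosen threshold: %.2f\n", object@chosenThreshold))
})

setMethod("show", "SubNetwork", function(object) {
  cat(sprintf("SubNetwork of %s at |rho| >= %.2f: %d partners (%d+/%d-)\n",
              object@queryGene, object@cutoff, subNetworkSize(object),
              nrow(object@positive), nrow(object@negative)))
})

setMethod("show", "PrioritizedSubNetwork", function(object) {
  cat(sprintf("PrioritizedSubNetwork of %s: %d informant partners\n",
              object@queryGene, nrow(object@partners)))
})

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG: %d terms, %d is_a edges, root(s): %s\n",
              nrow(object@terms),
              length(unlist(object@parents, use.names = FALSE)),
              paste(object@roots, collapse = ", ")))
})

setMethod("show", "AnnotationMap", function(object) {
  cat(sprintf("AnnotationMap: %d annotated genes (%s), %d rows dropped\n",
              length(object@direct),
              if (length(object@propagated)) "propagated" else "direct only",
              object@nDropped))
})

setMethod("show", "GroundTruth", function(object) {
  mm <- object@moduleMembership
  cat(sprintf("GroundTruth: %d module genes in %d modules, %d planted regulator(s)\n",
              sum(!is.na(mm)),
              length(unique(mm[!is.na(mm)])),
              length(object@plantedRegulators)))
})
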