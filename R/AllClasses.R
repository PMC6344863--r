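#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' ExpressionCompendium: a gene x array expression compendium
#'
#' Container for a normalized (linear-scale) gene x array intensity matrix
#' together with the array-to-condition mapping, extending
#' \linkS4class{SummarizedExperiment}. The derived condition-level log2
#' matrix (one column per distinct cultivation condition) is filled by
#' \code{\link{collapseConditions}} and retrieved with
#' \code{\link{conditionLog2}}.
#'
#' @slot conditionLog2 numeric matrix, genes x conditions, on log2 scale;
#'   a 0 x 0 matrix until \code{collapseConditions} has been run.
#'
#' @seealso \code{\link{readCompendium}}, \code{\link{collapseConditions}}
#' @export
setClass("ExpressionCompendium",
  contains = "SummarizedExperiment",
  representation(conditionLog2 = "matrix"),
  prototype(conditionLog2 = matrix(numeric(0), 0, 0))
)

setValidity("ExpressionCompendium", function(object) {
  msg <- character(0)
  ids <- rownames(object)
  arr <- colnames(object)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate or missing gene ids: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (is.null(arr) || anyDuplicated(arr))
    msg <- c(msg, "duplicate or missing array ids")
  cond <- colData(object)$condition
  if (is.null(cond) || anyNA(cond))
    msg <- c(msg, "every array must map to exactly one condition")
  x <- assay(object, "intensity")
  if (!all(is.finite(x)))
    msg <- c(msg, "intensities must all be finite")
  else if (any(x < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (ncol(object@conditionLog2) > 0 && !is.null(cond)) {
    if (ncol(object@conditionLog2) != length(unique(cond)))
      msg <- c(msg, "conditionLog2 must have one column per distinct condition")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCompendium
#'
#' @param intensities numeric matrix of non-negative linear-scale values,
#'   genes as rows (rownames = gene ids), arrays as columns (colnames =
#'   array ids).
#' @param arrayConditions character vector, one condition label per array,
#'   either named by array id or in column order.
#' @return An \linkS4class{ExpressionCompendium} with \code{conditionLog2}
#'   unset.
#' @export
ExpressionCompendium <- function(intensities, arrayConditions) {
  if (!is.null(names(arrayConditions))) {
    missing <- setdiff(colnames(intensities), names(arrayConditions))
    if (length(missing))
      stop("arrays without a condition assignment: ",
           paste(missing, collapse = ", "))
    arrayConditions <- arrayConditions[colnames(intensities)]
  }
  if (length(arrayConditions) != ncol(intensities))
    stop("arrayConditions must cover every array exactly once")
  se <- SummarizedExperiment(
    assays = list(intensity = intensities),
    colData = DataFrame(condition = unname(arrayConditions),
                        row.names = colnames(intensities)))
  new("ExpressionCompendium", se)
}

#' GeneCatalog: per-gene coordinates and functional attributes
#'
#' Wraps a \linkS4class{GRanges} of gene coordinates (1-based inclusive)
#' whose metadata columns carry the flags used throughout the pipeline:
#' \code{is_tf}, \code{is_chromatin}, \code{is_hypothetical},
#' \code{informant_category} (one of \code{none},
#' \code{verified_Aniger}, \code{verified_Anidulans},
#' \code{verified_Afumigatus}, \code{verified_Aoryzae}, \code{sm_core}),
#' \code{sm_cluster_id} (NA when the gene is in no secondary-metabolite
#' cluster) and \code{is_sm_core}.
#'
#' @slot ranges GRanges with the metadata columns above; names are gene ids.
#' @export
setClass("GeneCatalog", representation(ranges = "GRanges"))

.informantLevels <- c("none", "verified_Aniger", "verified_Anidulans",
                      "verified_Afumigatus", "verified_Aoryzae", "sm_core")

setValidity("GeneCatalog", function(object) {
  gr <- object@ranges
  mc <- S4Vectors::mcols(gr)
  msg <- character(0)
  need <- c("is_tf", "is_chromatin", "is_hypothetical",
            "informant_category", "sm_cluster_id", "is_sm_core")
  absent <- setdiff(need, colnames(mc))
  if (length(absent))
    return(sprintf("missing catalog attributes: %s",
                   paste(absent, collapse = ", ")))
  if (is.null(names(gr)) || anyDuplicated(names(gr)))
    msg <- c(msg, "gene ids must be unique names on the ranges")
  if (!all(mc$informant_category %in% .informantLevels))
    msg <- c(msg, "unknown informant_category level")
  if (any(mc$is_sm_core & is.na(mc$sm_cluster_id)))
    msg <- c(msg, "secondary-metabolite core genes must carry a cluster id")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneCatalog
#'
#' @param ranges GRanges with unique gene-id names and the metadata columns
#'   documented in \linkS4class{GeneCatalog} (missing flag columns are
#'   filled with their neutral values).
#' @return A \linkS4class{GeneCatalog}.
#' @export
GeneCatalog <- function(ranges) {
  mc <- S4Vectors::mcols(ranges)
  n <- length(ranges)
  if (is.null(mc$is_tf)) mc$is_tf <- rep(FALSE, n)
  if (is.null(mc$is_chromatin)) mc$is_chromatin <- rep(FALSE, n)
  if (is.null(mc$is_hypothetical)) mc$is_hypothetical <- rep(FALSE, n)
  if (is.null(mc$informant_category)) mc$informant_category <- rep("none", n)
  if (is.null(mc$sm_cluster_id)) mc$sm_cluster_id <- rep(NA_character_, n)
  if (is.null(mc$is_sm_core)) mc$is_sm_core <- rep(FALSE, n)
  S4Vectors::mcols(ranges) <- mc
  new("GeneCatalog", ranges = ranges)
}

#' OntologyDAG: a rooted is_a DAG of ontology terms
#'
#' @slot terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace}.
#' @slot parents named list mapping each term id to the character vector of
#'   its direct is_a parents (empty for roots).
#' @slot roots character vector of root term ids.
#' @export
setClass("OntologyDAG",
  representation(terms = "data.frame", parents = "list", roots = "character"))

setValidity("OntologyDAG", function(object) {
  ids <- object@terms$id
  msg <- character(0)
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate term ids")
  if (!all(names(object@parents) %in% ids))
    msg <- c(msg, "parent map keys must be known terms")
  tgt <- unique(unlist(object@parents, use.names = FALSE))
  if (length(tgt) && !all(tgt %in% ids))
    msg <- c(msg, sprintf("is_a edge to unknown term: %s",
                          paste(setdiff(tgt, ids), collapse = ", ")))
  if (.hasCycle(object@parents, ids))
    msg <- c(msg, "term graph contains a cycle")
  if (length(msg)) msg else TRUE
})

# Kahn topological check on the child -> parents map
.hasCycle <- function(parents, ids) {
  indeg <- vapply(ids, function(i) {
    p <- parents[[i]]
    if (is.null(p)) 0L else length(p)
  }, integer(1))
  children <- list()
  for (ch in names(parents)) for (p in parents[[ch]])
    children[[p]] <- c(children[[p]], ch)
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  seen < length(ids)
}

#' AnnotationMap: direct and propagated gene-to-term annotations
#'
#' @slot direct named list, gene id -> character vector of directly
#'   annotated term ids.
#' @slot propagated named list, gene id -> ancestor-closed term set (empty
#'   until \code{\link{propagateAnnotations}} has been run).
#' @slot nDropped integer, number of input annotation rows dropped because
#'   they referenced unknown genes or terms.
#' @export
setClass("AnnotationMap",
  representation(direct = "list", propagated = "list", nDropped = "integer"),
  prototype(propagated = list(), nDropped = 0L))

setValidity("AnnotationMap", function(object) {
  if (length(object@propagated)) {
    ok <- vapply(names(object@direct), function(g) {
      all(object@direct[[g]] %in% object@propagated[[g]])
    }, logical(1))
    if (!all(ok)) return("direct annotations must be a subset of propagated")
  }
  TRUE
})

#' CorrelationResult: thresholded all-pairs Spearman edge set
#'
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b} (id
#'   order, \code{gene_a < gene_b}) and \code{rho}; only pairs with
#'   \code{|rho| >= reportThreshold} are stored.
#' @slot reportThreshold numeric storage threshold.
#' @slot validGenes character, genes with non-constant profiles (the only
#'   genes entering pairing).
#' @slot allGenes character, all genes in the input matrix.
#' @slot nPairsTotal numeric, number of unordered valid pairs evaluated.
#' @slot nConditions integer, number of columns correlations were computed
#'   over.
#' @export
setClass("CorrelationResult",
  representation(edges = "data.frame", reportThreshold = "numeric",
                 validGenes = "character", allGenes = "character",
                 nPairsTotal = "numeric", nConditions = "integer"))

setValidity("CorrelationResult", function(object) {
  e <- object@edges
  msg <- character(0)
  if (nrow(e)) {
    if (any(e$gene_a >= e$gene_b)) msg <- c(msg, "edges must satisfy gene_a < gene_b")
    if (any(abs(e$rho) < object@reportThreshold - 1e-12))
      msg <- c(msg, "stored edge below report threshold")
    if (any(abs(e$rho) > 1 + 1e-12)) msg <- c(msg, "rho outside [-1, 1]")
  }
  v <- length(object@validGenes)
  if (abs(object@nPairsTotal - v * (v - 1) / 2) > 0.5)
    msg <- c(msg, "nPairsTotal must equal v*(v-1)/2 over valid genes")
  if (length(msg)) msg else TRUE
})

#' NullCalibration: permutation-null threshold calibration
#'
#' @slot candidates sorted numeric candidate thresholds.
#' @slot exceedance numeric, per candidate the count of permuted-data pairs
#'   at \code{|rho| >=} that candidate.
#' @slot maxAbsRhoNull numeric, largest \code{|rho|} observed in the null.
#' @slot chosenThreshold numeric, smallest candidate with zero exceedances
#'   (NA when uncalibrated).
#' @slot status "calibrated" or "uncalibrated".
#' @slot nNullPairs numeric, number of null pairs evaluated.
#' @slot seed integer master seed of the permutation.
#' @export
setClass("NullCalibration",
  representation(candidates = "numeric", exceedance = "numeric",
                 maxAbsRhoNull = "numeric", chosenThreshold = "numeric",
                 status = "character", nNullPairs = "numeric",
                 seed = "integer"))

setValidity("NullCalibration", function(object) {
  msg <- character(0)
  if (is.unsorted(object@candidates, strictly = TRUE))
    msg <- c(msg, "candidates must be strictly increasing")
  if (any(diff(object@exceedance) > 0))
    msg <- c(msg, "exceedance counts must be non-increasing in the threshold")
  if (object@status == "calibrated") {
    ch <- object@chosenThreshold
    zero <- object@candidates[object@exceedance == 0]
    if (!length(zero) || ch != min(zero))
      msg <- c(msg, "chosenThreshold must be the smallest zero-exceedance candidate")
  }
  if (length(msg)) msg else TRUE
})

#' SubNetwork: one query gene's co-expression partners at a stringency
#'
#' @slot queryGene query gene id.
#' @slot cutoff the stringency cutoff applied to \code{|rho|}.
#' @slot positive data.frame (\code{gene}, \code{rho > 0}) sorted by
#'   \code{|rho|} descending.
#' @slot negative data.frame (\code{gene}, \code{rho < 0}) sorted likewise.
#' @export
setClass("SubNetwork",
  representation(queryGene = "character", cutoff = "numeric",
                 positive = "data.frame", negative = "data.frame"))

setValidity("SubNetwork", function(object) {
  msg <- character(0)
  both <- rbind(object@positive, object@negative)
  if (nrow(both)) {
    if (object@queryGene %in% both$gene)
      msg <- c(msg, "query gene cannot be its own partner")
    if (any(abs(both$rho) < object@cutoff - 1e-12))
      msg <- c(msg, "partner below the stringency cutoff")
  }
  if (nrow(object@positive) && any(object@positive$rho <= 0))
    msg <- c(msg, "positive partners must have rho > 0")
  if (nrow(object@negative) && any(object@negative$rho >= 0))
    msg <- c(msg, "negative partners must have rho < 0")
  if (length(msg)) msg else TRUE
})

#' PrioritizedSubNetwork: informant-ORF overlay of a sub-network
#'
#' @slot queryGene query gene id.
#' @slot cutoff stringency cutoff inherited from the source sub-network.
#' @slot partners data.frame (\code{gene}, \code{rho},
#'   \code{informant_category}) restricted to informant ORFs.
#' @export
setClass("PrioritizedSubNetwork",
  representation(queryGene = "character", cutoff = "numeric",
                 partners = "data.frame"))

#' GroundTruth: planted structure of a synthetic compendium
#'
#' @slot moduleMembership named integer, gene id -> planted module index
#'   (NA for background genes).
#' @slot loadingSigns named character ("+" or "-") for every module gene.
#' @slot plantedRegulators character, ids of planted trans-regulator genes.
#' @slot termToModule named integer, signature term id -> module index.
#' @export
setClass("GroundTruth",
  representation(moduleMembership = "integer", loadingSigns = "character",
                 plantedRegulators = "character", termToModule = "integer"))

setValidity("GroundTruth", function(object) {
  members <- names(object@moduleMembership)[!is.na(object@moduleMembership)]
  if (!all(members %in% names(object@loadingSigns)))
    return("every module gene must carry a loading sign")
  TRUE
})
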