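#' Derive secondary-metabolite clusters from a catalog
#'
#' @param catalog a \linkS4class{GeneCatalog}.
#' @return named list, one element per cluster id, each a list with
#'   \code{members} (gene ids in coordinate order), \code{cores}
#'   (PKS/NRPS-type anchor genes) and \code{embedded_tfs} (member genes
#'   flagged as transcription factors).
#' @export
smClusters <- function(catalog) {
  at <- geneAttributes(catalog)
  at <- at[!is.na(at$sm_cluster_id), , drop = FALSE]
  if (!nrow(at)) return(stats::setNames(list(), character(0)))
  at <- at[order(at$chromosome, at$start), , drop = FALSE]
  lapply(split(at, at$sm_cluster_id), function(d) {
    list(members = d$gene_id,
         cores = d$gene_id[d$is_sm_core],
         embedded_tfs = d$gene_id[d$is_tf])
  })
}

#' Survey core-gene expression across conditions
#'
#' A core gene is flagged expressed iff its condition-level log2 value
#' exceeds the floor in at least one condition. The default floor is the
#' 20th percentile of all gene-condition values — a platform-free,
#' monotone-invariant surrogate for array present/absent calls.
#'
#' @param compendium an \linkS4class{ExpressionCompendium} with
#'   \code{conditionLog2} filled.
#' @param clusters cluster list from \code{\link{smClusters}}.
#' @param floor expression floor on the log2 scale, or NULL for the default
#'   percentile rule.
#' @param floorQuantile percentile used when \code{floor} is NULL.
#' @return data.frame (\code{cluster_id}, \code{core_gene},
#'   \code{expressed}); the floor is attached as \code{attr(, "floor")}.
#' @export
coreExpressionSurvey <- function(compendium, clusters, floor = NULL,
                                 floorQuantile = 0.2) {
  cl <- conditionLog2(compendium)
  if (is.null(floor))
    floor <- stats::quantile(cl, floorQuantile, names = FALSE)
  rows <- lapply(names(clusters), function(cid) {
    cores <- clusters[[cid]]$cores
    if (!length(cores)) return(NULL)
    expressed <- vapply(cores, function(g) {
      if (!g %in% rownames(cl)) {
        warning(sprintf("core gene %s absent from compendium; flagged unexpressed", g))
        return(FALSE)
      }
      any(cl[g, ] > floor)
    }, logical(1))
    data.frame(cluster_id = cid, core_gene = cores,
               expressed = unname(expressed), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster_id = character(0), core_gene = character(0),
                      expressed = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "floor") <- floor
  out
}

#' Co-expression coherence of each SM cluster
#'
#' For each cluster and each core gene, the fraction of non-core members
#' co-expressed with that core (\code{|rho| >= cutoff}); the reported
#' fraction is the max over cores. \code{contiguous_tf_coexpressed} is TRUE
#' when any embedded TF is co-expressed with a core. Clusters whose cores
#' all have constant profiles are marked not evaluable. The genome-wide
#' fraction of evaluable clusters with a co-expressed contiguous TF is
#' attached as \code{attr(, "tf_coexpressed_fraction")}.
#'
#' @param corr a \linkS4class{CorrelationResult} with report threshold at
#'   or below \code{cutoff}.
#' @param clusters cluster list from \code{\link{smClusters}}.
#' @param cutoff stringency cutoff.
#' @return data.frame (\code{cluster_id}, \code{evaluable},
#'   \code{member_coexpression_fraction}, \code{has_embedded_tf},
#'   \code{contiguous_tf_coexpressed}).
#' @export
clusterCoherence <- function(corr, clusters, cutoff = reportThreshold(corr)) {
  if (cutoff < reportThreshold(corr))
    stop("cutoff below the correlation result's report threshold")
  e <- corEdges(corr)
  e <- e[abs(e$rho) >= cutoff, , drop = FALSE]
  valid <- validGenes(corr)
  partnersOf <- function(g)
    c(e$gene_b[e$gene_a == g], e$gene_a[e$gene_b == g])
  rows <- lapply(names(clusters), function(cid) {
    cl <- clusters[[cid]]
    cores <- intersect(cl$cores, valid)
    if (!length(cores))
      return(data.frame(cluster_id = cid, evaluable = FALSE,
                        member_coexpression_fraction = NA_real_,
                        has_embedded_tf = length(cl$embedded_tfs) > 0,
                        contiguous_tf_coexpressed = NA,
                        stringsAsFactors = FALSE))
    nonCore <- setdiff(cl$members, cl$cores)
    frac <- 0; tfCo <- FALSE
    for (core in cores) {
      p <- partnersOf(core)
      if (length(nonCore))
        frac <- max(frac, mean(nonCore %in% p))
      tfCo <- tfCo || any(cl$embedded_tfs %in% p)
    }
    data.frame(cluster_id = cid, evaluable = TRUE,
               member_coexpression_fraction = if (length(nonCore)) frac else NA_real_,
               has_embedded_tf = length(cl$embedded_tfs) > 0,
               contiguous_tf_coexpressed = tfCo, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster_id = character(0), evaluable = logical(0),
                      member_coexpression_fraction = numeric(0),
                      has_embedded_tf = logical(0),
                      contiguous_tf_coexpressed = logical(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  ev <- out$evaluable %in% TRUE
  attr(out, "tf_coexpressed_fraction") <-
    if (any(ev)) mean(out$contiguous_tf_coexpressed[ev]) else NA_real_
  out
}

#' Scan for trans-acting regulator candidates of SM core genes
#'
#' Every transcription factor or chromatin-regulator gene located outside
#' all SM clusters is scored by how many SM core genes it is positively
#' (\code{rho >= +cutoff}) and negatively (\code{rho <= -cutoff})
#' co-expressed with. Candidates reaching \code{minCores} total core
#' partners are returned sorted by total core count descending, ties broken
#' by gene id — so the ranking is independent of catalog row order.
#'
#' @param corr a \linkS4class{CorrelationResult}.
#' @param catalog a \linkS4class{GeneCatalog}.
#' @param cutoff stringency cutoff.
#' @param minCores minimum total core partners to qualify.
#' @return data.frame (\code{gene}, \code{is_tf}, \code{is_chromatin},
#'   \code{n_cores_positive}, \code{n_cores_negative}, \code{pattern},
#'   \code{rank}).
#' @export
scanTransRegulators <- function(corr, catalog,
                                cutoff = reportThreshold(corr),
                                minCores = 2L) {
  at <- geneAttributes(catalog)
  cores <- at$gene_id[at$is_sm_core]
  if (!length(cores)) stop("catalog contains no SM core genes")
  flagged <- at[(at$is_tf | at$is_chromatin) & is.na(at$sm_cluster_id), ,
                drop = FALSE]
  if (!nrow(flagged)) {
    warning("no out-of-cluster TF or chromatin-regulator genes in catalog")
    return(data.frame(gene = character(0), is_tf = logical(0),
                      is_chromatin = logical(0),
                      n_cores_positive = integer(0),
                      n_cores_negative = integer(0),
                      pattern = character(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  e <- corEdges(corr)
  coreEdge <- (e$gene_a %in% cores) != (e$gene_b %in% cores)  # exactly one side
  e <- e[coreEdge, , drop = FALSE]
  other <- ifelse(e$gene_a %in% cores, e$gene_b, e$gene_a)
  res <- lapply(flagged$gene_id, function(g) {
    rho <- e$rho[other == g]
    c(pos = sum(rho >= cutoff), neg = sum(rho <= -cutoff))
  })
  pos <- vapply(res, `[[`, numeric(1), "pos")
  neg <- vapply(res, `[[`, numeric(1), "neg")
  keep <- pos + neg >= minCores
  out <- data.frame(gene = flagged$gene_id[keep],
                    is_tf = flagged$is_tf[keep],
                    is_chromatin = flagged$is_chromatin[keep],
                    n_cores_positive = as.integer(pos[keep]),
                    n_cores_negative = as.integer(neg[keep]),
                    stringsAsFactors = FALSE)
  out$pattern <- ifelse(out$n_cores_positive > 0 & out$n_cores_negative > 0,
                        "positive_and_negative",
                        ifelse(out$n_cores_negative > 0, "negative_only",
                               "positive_only"))
  out <- out[order(-(out$n_cores_positive + out$n_cores_negative),
                   out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Spearman correlation between two specific genes
#'
#' @param compendium an \linkS4class{ExpressionCompendium} with
#'   \code{conditionLog2} filled.
#' @param geneA,geneB gene ids.
#' @return Spearman rho of the two condition-level profiles (1.0 for a gene
#'   against itself).
#' @export
regulatorPairCorrelation <- function(compendium, geneA, geneB) {
  cl <- conditionLog2(compendium)
  for (g in c(geneA, geneB))
    if (!g %in% rownames(cl)) stop("gene absent from compendium: ", g)
  spearmanRho(cl[geneA, ], cl[geneB, ])
}
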