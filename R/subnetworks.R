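#' Extract one gene's co-expression sub-network
#'
#' Partners are exactly the stored edges incident to the query gene with
#' \code{|rho| >= cutoff}, partitioned into positively and negatively
#' correlated lists and sorted by \code{|rho|} descending.
#'
#' @param corr a \linkS4class{CorrelationResult} whose report threshold is
#'   at or below \code{cutoff}.
#' @param gene query gene id (must have a non-constant profile).
#' @param cutoff stringency cutoff (the conventional stringent and highly
#'   stringent levels are 0.5 and 0.7).
#' @return A \linkS4class{SubNetwork}.
#' @export
extractSubnetwork <- function(corr, gene, cutoff = reportThreshold(corr)) {
  if (cutoff < reportThreshold(corr))
    stop("cutoff below the correlation result's report threshold")
  if (!gene %in% validGenes(corr)) {
    stop(sprintf("gene '%s' is %s", gene,
                 if (gene %in% corr@allGenes)
                   "constant-profile (excluded from pairing)"
                 else "absent from the correlation result"))
  }
  e <- corEdges(corr)
  sel <- (e$gene_a == gene | e$gene_b == gene) & abs(e$rho) >= cutoff
  partner <- ifelse(e$gene_a[sel] == gene, e$gene_b[sel], e$gene_a[sel])
  rho <- e$rho[sel]
  ord <- order(-abs(rho), partner)
  partner <- partner[ord]; rho <- rho[ord]
  mk <- function(keep) data.frame(gene = partner[keep], rho = rho[keep],
                                  stringsAsFactors = FALSE, row.names = NULL)
  new("SubNetwork", queryGene = gene, cutoff = cutoff,
      positive = mk(rho > 0), negative = mk(rho < 0))
}

#' Overlay informant ORFs on a sub-network
#'
#' Filters a sub-network's partners to informant ORFs (genes whose catalog
#' \code{informant_category} is not \code{none}) and attaches the category,
#' yielding the prioritized sub-network used for guilt-by-association
#' function transfer.
#'
#' @param subnet a \linkS4class{SubNetwork}.
#' @param catalog a \linkS4class{GeneCatalog} with informant flags.
#' @return A \linkS4class{PrioritizedSubNetwork}.
#' @export
prioritizeSubnetwork <- function(subnet, catalog) {
  at <- geneAttributes(catalog)
  cat_of <- stats::setNames(at$informant_category, at$gene_id)
  both <- rbind(positivePartners(subnet), negativePartners(subnet))
  if (nrow(both)) {
    both <- both[order(-abs(both$rho), both$gene), , drop = FALSE]
    keep <- !is.na(cat_of[both$gene]) & cat_of[both$gene] != "none"
    partners <- data.frame(gene = both$gene[keep], rho = both$rho[keep],
                           informant_category = unname(cat_of[both$gene[keep]]),
                           stringsAsFactors = FALSE, row.names = NULL)
  } else {
    partners <- data.frame(gene = character(0), rho = numeric(0),
                           informant_category = character(0),
                           stringsAsFactors = FALSE)
  }
  new("PrioritizedSubNetwork", queryGene = queryGene(subnet),
      cutoff = subnet@cutoff, partners = partners)
}

#' Summarize the global co-expression network at a cutoff
#'
#' @param corr a \linkS4class{CorrelationResult} with report threshold at or
#'   below \code{cutoff}.
#' @param cutoff stringency cutoff.
#' @param catalog a \linkS4class{GeneCatalog} supplying informant and
#'   hypothetical flags.
#' @return one-row data.frame: \code{cutoff}, \code{n_gene_networks} (genes
#'   with at least one partner), \code{n_edges_positive},
#'   \code{n_edges_negative}, \code{n_edges_total},
#'   \code{n_genes_with_informant_partner},
#'   \code{n_hypothetical_with_partner}.
#' @export
networkSummary <- function(corr, cutoff, catalog) {
  if (cutoff < reportThreshold(corr))
    stop("cutoff below the correlation result's report threshold")
  e <- corEdges(corr)
  e <- e[abs(e$rho) >= cutoff, , drop = FALSE]
  at <- geneAttributes(catalog)
  informants <- at$gene_id[at$informant_category != "none"]
  hypo <- at$gene_id[at$is_hypothetical]
  connected <- unique(c(e$gene_a, e$gene_b))
  withInf <- unique(c(e$gene_b[e$gene_a %in% informants],
                      e$gene_a[e$gene_b %in% informants]))
  data.frame(cutoff = cutoff,
             n_gene_networks = length(connected),
             n_edges_positive = sum(e$rho > 0),
             n_edges_negative = sum(e$rho < 0),
             n_edges_total = nrow(e),
             n_genes_with_informant_partner = length(withInf),
             n_hypothetical_with_partner = length(intersect(connected, hypo)))
}

#' Write one sub-network as a per-query TSV
#'
#' @param subnet a \linkS4class{SubNetwork}.
#' @param catalog a \linkS4class{GeneCatalog} for partner attributes.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeSubnetwork <- function(subnet, catalog, path) {
  at <- geneAttributes(catalog)
  both <- rbind(positivePartners(subnet), negativePartners(subnet))
  both <- both[order(-abs(both$rho), both$gene), , drop = FALSE]
  i <- match(both$gene, at$gene_id)
  out <- data.frame(partner_gene = both$gene,
                    rho = round(both$rho, 6),
                    sign = ifelse(both$rho > 0, "+", "-"),
                    informant_category = at$informant_category[i],
                    is_tf = at$is_tf[i],
                    is_hypothetical = at$is_hypothetical[i],
                    stringsAsFactors = FALSE, row.names = NULL)
  .writeTsv(out, path, c(query = queryGene(subnet),
                         cutoff = format(subnet@cutoff)))
}

#' Write the thresholded network as an edge-list TSV
#'
#' @param corr a \linkS4class{CorrelationResult}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeEdges <- function(corr, path) {
  e <- corEdges(corr)
  e$rho <- round(e$rho, 6)
  .writeTsv(e, path, c(report_threshold = format(reportThreshold(corr)),
                       n_valid_genes = length(validGenes(corr)),
                       n_pairs_total = format(nPairsTotal(corr),
                                              scientific = FALSE)))
}

#' Write a calibration report TSV
#'
#' @param calib a \linkS4class{NullCalibration}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeCalibration <- function(calib, path) {
  df <- data.frame(candidate = calib@candidates,
                   exceedance_count = calib@exceedance)
  .writeTsv(df, path,
            c(seed = calib@seed,
              n_null_pairs = format(calib@nNullPairs, scientific = FALSE),
              max_abs_rho_null = format(calib@maxAbsRhoNull, digits = 6),
              status = calib@status,
              chosen_threshold = format(calib@chosenThreshold)))
}
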