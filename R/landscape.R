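#' Chromosomal expression landscape
#'
#' Mean condition-level log2 expression per gene (unweighted over all
#' conditions), ordered along the genome: within each chromosome genes are
#' sorted by start coordinate. Genes present in the compendium but absent
#' from the catalog are excluded with a logged count.
#'
#' @param compendium an \linkS4class{ExpressionCompendium} with
#'   \code{conditionLog2} filled.
#' @param catalog a \linkS4class{GeneCatalog}.
#' @return data.frame with columns \code{gene_id}, \code{chromosome},
#'   \code{start}, \code{mean_log2} and (after \code{\link{classifyLoci}})
#'   \code{expression_class}.
#' @export
chromosomalLandscape <- function(compendium, catalog) {
  cl <- conditionLog2(compendium)
  at <- geneAttributes(catalog)
  shared <- intersect(rownames(cl), at$gene_id)
  if (!length(shared))
    stop("no genes shared between catalog and compendium")
  missing <- setdiff(rownames(cl), at$gene_id)
  if (length(missing))
    message(length(missing), " compendium gene(s) absent from catalog, excluded")
  at <- at[at$gene_id %in% shared, c("gene_id", "chromosome", "start")]
  at$mean_log2 <- rowMeans(cl)[at$gene_id]
  at <- at[order(at$chromosome, at$start), , drop = FALSE]
  rownames(at) <- NULL
  at
}

#' Classify loci into low / medium / high expression
#'
#' Quantile thresholds on \code{mean_log2} (genome-wide terciles by
#' default): genes at or below the lower quantile are \code{low}, genes
#' strictly above the upper quantile are \code{high}, the rest
#' \code{medium} — so boundary ties always fall to the lower class. A
#' degenerate all-equal profile yields all-\code{medium} with a warning.
#'
#' @param profile data.frame from \code{\link{chromosomalLandscape}}.
#' @param quantiles length-2 numeric, the lower and upper quantile levels.
#' @return the profile with an \code{expression_class} column; thresholds
#'   are attached as \code{attr(, "thresholds")}.
#' @export
classifyLoci <- function(profile, quantiles = c(1 / 3, 2 / 3)) {
  stopifnot(length(quantiles) == 2, quantiles[1] <= quantiles[2])
  x <- profile$mean_log2
  if (length(unique(x)) == 1L) {
    warning("degenerate expression distribution; all loci classed medium")
    profile$expression_class <- rep("medium", nrow(profile))
    attr(profile, "thresholds") <- c(lower = x[1], upper = x[1])
    return(profile)
  }
  q <- stats::quantile(x, quantiles, names = FALSE)
  cls <- ifelse(x <= q[1], "low", ifelse(x > q[2], "high", "medium"))
  profile$expression_class <- cls
  attr(profile, "thresholds") <- c(lower = q[1], upper = q[2])
  profile
}

#' Write a landscape profile TSV
#'
#' @param profile classified profile from \code{\link{classifyLoci}}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeLandscape <- function(profile, path) {
  th <- attr(profile, "thresholds")
  params <- if (is.null(th)) character(0) else
    c(lower_threshold = format(th[["lower"]]),
      upper_threshold = format(th[["upper"]]))
  .writeTsv(profile, path, params)
}
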