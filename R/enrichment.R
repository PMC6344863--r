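# ancestor closure per term, memoised over the DAG
.termAncestors <- function(dag) {
  parents <- termParents(dag)
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    p <- parents[[id]]
    res <- if (length(p)) unique(c(p, unlist(lapply(p, anc),
                                             use.names = FALSE)))
           else character(0)
    memo[[id]] <- res
    res
  }
  for (id in names(parents)) anc(id)
  as.list(memo)
}

#' Ancestor closure of a term set
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param terms character vector of term ids.
#' @return the input terms plus all their is_a ancestors.
#' @export
termAncestorClosure <- function(dag, terms) {
  anc <- .termAncestors(dag)
  unique(c(terms, unlist(anc[terms], use.names = FALSE)))
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Closes each gene's direct term set under is_a ancestor edges, so that a
#' gene annotated to a term is counted for every ancestor up to the root.
#' Idempotent. Annotations to terms unknown to the DAG are dropped with a
#' logged count.
#'
#' @param annotations an \linkS4class{AnnotationMap}.
#' @param dag an \linkS4class{OntologyDAG}.
#' @return the AnnotationMap with the \code{propagated} slot filled.
#' @export
propagateAnnotations <- function(annotations, dag) {
  anc <- .termAncestors(dag)
  known <- ontologyTerms(dag)$id
  direct <- directAnnotations(annotations)
  dropped <- 0L
  prop <- lapply(direct, function(ts) {
    bad <- !(ts %in% known)
    dropped <<- dropped + sum(bad)
    ts <- ts[!bad]
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
  if (dropped)
    message(dropped, " annotation(s) to unknown terms dropped")
  if (dropped) {
    annotations@direct <- lapply(direct, function(ts) ts[ts %in% known])
  }
  annotations@propagated <- prop
  annotations@nDropped <- annotations@nDropped + as.integer(dropped)
  methods::validObject(annotations)
  annotations
}

#' Term enrichment of a study set by Fisher's exact test
#'
#' One-sided (upper-tail) Fisher's exact test per term: with N background
#' genes, K of them annotated to the term, and a study set of n genes k of
#' which are annotated, \code{p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) /
#' C(N,n)} — the hypergeometric tail. Terms with K = 0 in the background
#' are excluded. Counting uses propagated annotations (true-path rule) by
#' default.
#'
#' @param studyGenes character vector, must be a subset of
#'   \code{backgroundGenes}.
#' @param backgroundGenes character vector (typically all catalog genes
#'   present in the compendium; unannotated genes count toward N).
#' @param annotations an \linkS4class{AnnotationMap}.
#' @param dag an \linkS4class{OntologyDAG} (for term names and, if needed,
#'   propagation).
#' @param alpha significance level for the enriched flag.
#' @param correction \code{"none"} (flag on the raw p) or
#'   \code{"bonferroni"} (flag on \code{min(1, p * m)} with m the number of
#'   tested terms).
#' @param propagate use the ancestor-closed annotation sets (set FALSE for
#'   a direct-annotation sensitivity check).
#' @return data.frame with columns \code{term_id}, \code{term_name},
#'   \code{k}, \code{n}, \code{K}, \code{N}, \code{p_value},
#'   \code{p_bonferroni}, \code{enriched}, sorted by p-value.
#' @export
enrichTerms <- function(studyGenes, backgroundGenes, annotations, dag,
                        alpha = 0.05, correction = c("none", "bonferroni"),
                        propagate = TRUE) {
  correction <- match.arg(correction)
  studyGenes <- unique(studyGenes)
  backgroundGenes <- unique(backgroundGenes)
  offenders <- setdiff(studyGenes, backgroundGenes)
  if (length(offenders))
    stop("study gene(s) absent from background: ",
         paste(utils::head(offenders, 10L), collapse = ", "))
  annSets <- if (propagate) {
    if (!length(annotations@propagated))
      annotations <- propagateAnnotations(annotations, dag)
    propagatedAnnotations(annotations)
  } else directAnnotations(annotations)
  annSets <- annSets[names(annSets) %in% backgroundGenes]
  genes <- rep(names(annSets), lengths(annSets))
  terms <- unlist(annSets, use.names = FALSE)
  Ktab <- table(terms)
  inStudy <- genes %in% studyGenes
  ktab <- table(terms[inStudy])
  tid <- names(Ktab)
  K <- as.integer(Ktab)
  k <- as.integer(ktab[tid]); k[is.na(k)] <- 0L
  N <- length(backgroundGenes)
  n <- length(studyGenes)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  m <- length(tid)
  pb <- pmin(1, p * m)
  nameOf <- stats::setNames(ontologyTerms(dag)$name, ontologyTerms(dag)$id)
  out <- data.frame(term_id = tid,
                    term_name = unname(nameOf[tid]),
                    k = k, n = n, K = K, N = N,
                    p_value = p, p_bonferroni = pb,
                    enriched = (if (correction == "bonferroni") pb else p) < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment of a sub-network's partner genes
#'
#' Assembles the study set from a sub-network (combined partners by
#' default, or the positive-only / negative-only sign classes) and
#' delegates to \code{\link{enrichTerms}} against the supplied background.
#'
#' @param subnet a \linkS4class{SubNetwork}.
#' @param annotations an \linkS4class{AnnotationMap}.
#' @param dag an \linkS4class{OntologyDAG}.
#' @param backgroundGenes background gene set (all catalog genes present in
#'   the compendium).
#' @param mode which partners form the study set.
#' @param ... passed to \code{\link{enrichTerms}}.
#' @return an enrichment data.frame (empty, with a warning, when the study
#'   set is empty).
#' @export
enrichSubnetwork <- function(subnet, annotations, dag, backgroundGenes,
                             mode = c("combined", "positive_only",
                                      "negative_only"), ...) {
  mode <- match.arg(mode)
  study <- switch(mode,
    combined = c(positivePartners(subnet)$gene,
                 negativePartners(subnet)$gene),
    positive_only = positivePartners(subnet)$gene,
    negative_only = negativePartners(subnet)$gene)
  if (!length(study)) {
    warning(sprintf("empty %s study set for query %s", mode,
                    queryGene(subnet)))
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0),
                      p_bonferroni = numeric(0), enriched = logical(0),
                      stringsAsFactors = FALSE))
  }
  enrichTerms(study, backgroundGenes, annotations, dag, ...)
}

#' Write an enrichment table TSV
#'
#' @param table data.frame from \code{\link{enrichTerms}}.
#' @param path output TSV path.
#' @param params named character vector echoed in the header comment.
#' @return invisibly, the path.
#' @export
writeEnrichment <- function(table, path, params = character(0)) {
  .writeTsv(table, path, params)
}
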