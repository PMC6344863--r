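#' Read a gene catalog from GFF3 coordinates plus an attributes TSV
#'
#' Gene coordinates are taken from features of type \code{gene} in the GFF3
#' (1-based inclusive, via rtracklayer); functional flags come from the
#' attributes TSV with columns \code{gene_id}, \code{is_tf},
#' \code{is_chromatin}, \code{is_hypothetical}, \code{informant_category},
#' \code{sm_cluster_id}, \code{is_sm_core}.
#'
#' @param gff3Path GFF3 file of gene features carrying an ID attribute.
#' @param attributesPath attributes TSV.
#' @return A \linkS4class{GeneCatalog}.
#' @export
readCatalog <- function(gff3Path, attributesPath) {
  gr <- rtracklayer::import(gff3Path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("GFF3 gene feature without an ID attribute")
  names(gr) <- ids
  S4Vectors::mcols(gr) <- NULL
  at <- .readTsv(attributesPath)
  if (!all(ids %in% at$gene_id))
    stop("attributes TSV missing gene(s): ",
         paste(utils::head(setdiff(ids, at$gene_id)), collapse = ", "))
  at <- at[match(ids, at$gene_id), , drop = FALSE]
  smc <- as.character(at$sm_cluster_id)
  smc[!nzchar(smc) | smc == "NA" | is.na(smc)] <- NA_character_
  S4Vectors::mcols(gr) <- DataFrame(
    is_tf = as.logical(at$is_tf),
    is_chromatin = as.logical(at$is_chromatin),
    is_hypothetical = as.logical(at$is_hypothetical),
    informant_category = as.character(at$informant_category),
    sm_cluster_id = smc,
    is_sm_core = as.logical(at$is_sm_core))
  GeneCatalog(gr)
}

#' Write a gene catalog as GFF3 + attributes TSV
#'
#' @param catalog a \linkS4class{GeneCatalog}.
#' @param gff3Path,attributesPath output paths.
#' @return invisibly, the GFF3 path.
#' @export
writeCatalog <- function(catalog, gff3Path, attributesPath) {
  gr <- geneRanges(catalog)
  out <- GenomicRanges::granges(gr)
  out$source <- "coexatlas"
  out$type <- "gene"
  out$ID <- names(gr)
  names(out) <- NULL
  rtracklayer::export(out, gff3Path, format = "gff3")
  at <- geneAttributes(catalog)
  at$sm_cluster_id[is.na(at$sm_cluster_id)] <- "NA"
  .writeTsv(at[, c("gene_id", "is_tf", "is_chromatin", "is_hypothetical",
                   "informant_category", "sm_cluster_id", "is_sm_core")],
            attributesPath, c(n_genes = nrow(at)))
  invisible(gff3Path)
}

#' Read an OBO 1.2 ontology (is_a subset)
#'
#' Minimal OBO reader honouring \code{id}, \code{name}, \code{namespace} and
#' \code{is_a} tags of \code{[Term]} stanzas; obsolete terms are skipped.
#' Terms are restricted to one namespace (biological_process by default);
#' terms without a namespace tag are kept.
#'
#' @param oboPath OBO file path.
#' @param namespace namespace to retain, or NULL for all.
#' @return An \linkS4class{OntologyDAG}.
#' @export
readOntology <- function(oboPath, namespace = "biological_process") {
  lines <- readLines(oboPath)
  termStarts <- which(lines == "[Term]")
  if (!length(termStarts)) stop("no [Term] stanzas in ", oboPath)
  bounds <- c(termStarts, length(lines) + 1L)
  recs <- list()
  for (i in seq_along(termStarts)) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    tag <- sub(":.*$", "", chunk)
    val <- trimws(sub("^[a-z_]+: *", "", chunk))
    if (any(tag == "is_obsolete" & val == "true")) next
    id <- val[tag == "id"][1L]
    if (is.na(id)) next
    ns <- val[tag == "namespace"]
    if (!is.null(namespace) && length(ns) && !(ns[1L] %in% namespace)) next
    isa <- sub(" *!.*$", "", val[tag == "is_a"])
    recs[[id]] <- list(
      name = if (any(tag == "name")) val[tag == "name"][1L] else id,
      namespace = if (length(ns)) ns[1L] else NA_character_,
      parents = isa)
  }
  ids <- names(recs)
  parents <- lapply(recs, function(r) r$parents)
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown))
    stop("is_a edge to unknown term: ", paste(unknown, collapse = ", "))
  terms <- data.frame(
    id = ids,
    name = vapply(recs, function(r) r$name, character(1)),
    namespace = vapply(recs, function(r) r$namespace, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  roots <- ids[lengths(parents) == 0L]
  new("OntologyDAG", terms = terms, parents = parents, roots = roots)
}

#' Write an ontology as OBO 1.2
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param oboPath output path.
#' @return invisibly, the path.
#' @export
writeOntology <- function(dag, oboPath) {
  terms <- ontologyTerms(dag)
  parents <- termParents(dag)
  con <- file(oboPath, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", "ontology: coexatlas-synthetic", ""),
             con)
  for (i in seq_len(nrow(terms))) {
    id <- terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", terms$name[i]),
                 paste0("namespace: ", terms$namespace[i]),
                 sprintf("is_a: %s", parents[[id]]),
                 ""), con)
  }
  invisible(oboPath)
}

#' Read gene annotations from a GAF 2.x file
#'
#' Honours columns 2 (gene id) and 5 (term id); duplicate gene-term rows
#' collapse to one annotation (set semantics). Rows for genes absent from
#' the catalog are dropped with a logged count, as are rows referencing
#' terms absent from the ontology when one is supplied.
#'
#' @param gafPath GAF file path.
#' @param catalog a \linkS4class{GeneCatalog} delimiting known genes.
#' @param dag optional \linkS4class{OntologyDAG} delimiting known terms.
#' @return An \linkS4class{AnnotationMap} (direct annotations only).
#' @export
readAnnotations <- function(gafPath, catalog, dag = NULL) {
  lines <- readLines(gafPath)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  dropped <- 0L
  direct <- list()
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    gene <- vapply(parts, `[`, character(1), 2L)
    term <- vapply(parts, `[`, character(1), 5L)
    known <- gene %in% geneIds(catalog)
    if (!is.null(dag)) known <- known & term %in% ontologyTerms(dag)$id
    dropped <- sum(!known)
    if (dropped)
      message(dropped, " annotation row(s) dropped (unknown gene or term)")
    direct <- lapply(split(term[known], gene[known]),
                     function(x) sort(unique(x)))
  }
  new("AnnotationMap", direct = direct, propagated = list(),
      nDropped = as.integer(dropped))
}

#' Write direct annotations as GAF 2.2
#'
#' Columns 2 (gene id) and 5 (term id) carry the annotation; the other
#' columns are filled with fixed placeholders.
#'
#' @param annotations an \linkS4class{AnnotationMap} (direct slot used).
#' @param gafPath output path.
#' @return invisibly, the path.
#' @export
writeAnnotations <- function(annotations, gafPath) {
  direct <- directAnnotations(annotations)
  genes <- rep(names(direct), lengths(direct))
  terms <- unlist(direct, use.names = FALSE)
  con <- file(gafPath, open = "wt")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  if (length(genes)) {
    rows <- paste("SYNT", genes, genes, "", terms, "SYNT:0000001", "IEA", "",
                  "P", "", "", "protein", "taxon:0", "20240101", "SYNT", "",
                  "", sep = "\t")
    writeLines(rows, con)
  }
  invisible(gafPath)
}
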