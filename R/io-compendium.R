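.pkgHeader <- function(params = character(0)) {
  v <- tryCatch(as.character(utils::packageVersion("coexatlas")),
                error = function(e) "dev")
  c(sprintf("# coexatlas %s", v),
    if (length(params)) sprintf("# %s", paste(names(params), params,
                                              sep = "=", collapse = "; ")))
}

# tab-separated writer with commented provenance header
.writeTsv <- function(df, path, params = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.pkgHeader(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read an expression compendium from TSV files
#'
#' @param matrixPath TSV with genes as rows (first column = gene id) and
#'   arrays as columns, linear-scale non-negative intensities.
#' @param conditionMapPath 2-column TSV mapping array id to condition.
#' @return An \linkS4class{ExpressionCompendium} with \code{conditionLog2}
#'   unset.
#' @export
readCompendium <- function(matrixPath, conditionMapPath) {
  tab <- .readTsv(matrixPath)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene id in expression matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(!is.finite(m)))
    stop("non-finite intensity values in expression matrix")
  if (any(m < 0))
    stop("negative intensity values in expression matrix")
  cm <- .readTsv(conditionMapPath, header = TRUE)
  cmap <- stats::setNames(as.character(cm[[2L]]), as.character(cm[[1L]]))
  orphan <- setdiff(names(cmap), colnames(m))
  if (length(orphan))
    stop("condition map references absent array id(s): ",
         paste(orphan, collapse = ", "))
  unmapped <- setdiff(colnames(m), names(cmap))
  if (length(unmapped))
    stop("array(s) without a condition: ", paste(unmapped, collapse = ", "))
  ExpressionCompendium(m, cmap)
}

#' Collapse replicate arrays to condition-level log2 profiles
#'
#' Each linear intensity v is mapped to \code{log2(v + pseudocount)} (the
#' pseudocount, default 1, is applied only when the matrix contains a zero),
#' then the condition-level value is the arithmetic mean of its arrays' log2
#' values ("log2 mean"). Condition columns are ordered by sorted condition
#' name, so the result is invariant to array order.
#'
#' @param compendium an \linkS4class{ExpressionCompendium}.
#' @param pseudocount offset added before log2 when zeros are present.
#' @return the compendium with \code{conditionLog2} filled.
#' @examples
#' m <- matrix(c(4, 16), 1, 2, dimnames = list("g1", c("a1", "a2")))
#' comp <- ExpressionCompendium(m, c(a1 = "c1", a2 = "c1"))
#' conditionLog2(collapseConditions(comp))  # (2 + 4) / 2 = 3
#' @export
collapseConditions <- function(compendium, pseudocount = 1) {
  x <- assay(compendium, "intensity")
  pc <- if (any(x == 0)) pseudocount else 0
  lg <- log2(x + pc)
  cond <- as.character(colData(compendium)$condition)
  levels <- sort(unique(cond))
  cl <- vapply(levels, function(cc) {
    rowMeans(lg[, cond == cc, drop = FALSE])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) cl <- matrix(cl, nrow = 1L,
                                  dimnames = list(rownames(x), levels))
  compendium@conditionLog2 <- cl
  methods::validObject(compendium)
  compendium
}

#' Write an expression compendium as matrix + condition-map TSVs
#'
#' @param compendium an \linkS4class{ExpressionCompendium}.
#' @param matrixPath,conditionMapPath output TSV paths.
#' @return invisibly, the matrix path.
#' @export
writeCompendium <- function(compendium, matrixPath, conditionMapPath) {
  m <- assay(compendium, "intensity")
  df <- data.frame(gene_id = rownames(m),
                   format(m, digits = 10, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(df, matrixPath,
            c(n_genes = nrow(m), n_arrays = ncol(m)))
  cmap <- data.frame(array_id = colnames(m),
                     condition = as.character(colData(compendium)$condition),
                     stringsAsFactors = FALSE)
  .writeTsv(cmap, conditionMapPath, c(n_arrays = ncol(m)))
  invisible(matrixPath)
}
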