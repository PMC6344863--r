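writeTinyCompendium <- function(dir, mat, map) {
  mp <- file.path(dir, "m.tsv"); cp <- file.path(dir, "c.tsv")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(map, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, map = cp)
}

test_that("reading a compendium validates ids, mapping and intensities", {
  dir <- withr::local_tempdir()
  mat <- matrix(1:12, 3, 4,
                dimnames = list(c("g1", "g2", "g3"), paste0("a", 1:4)))
  map <- data.frame(array_id = paste0("a", 1:4),
                    condition = c("c1", "c1", "c2", "c2"))
  p <- writeTinyCompendium(dir, mat, map)
  comp <- readCompendium(p$matrix, p$map)
  expect_identical(length(unique(arrayConditions(comp))), 2L)

  # duplicate gene row id names the duplicate
  df <- read.delim(p$matrix)
  df$gene_id[2] <- "g1"
  write.table(df, p$matrix, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCompendium(p$matrix, p$map), "g1")

  # orphan array in the map is listed
  p <- writeTinyCompendium(dir, mat,
                           rbind(map, data.frame(array_id = "a9",
                                                 condition = "c3")))
  expect_error(readCompendium(p$matrix, p$map), "a9")

  # array without a condition is a hard error
  p <- writeTinyCompendium(dir, mat, map[-1, ])
  expect_error(readCompendium(p$matrix, p$map), "a1")

  # negative intensity is a hard error
  mat[1, 1] <- -3
  p <- writeTinyCompendium(dir, mat, map)
  expect_error(readCompendium(p$matrix, p$map), "negative")
})

test_that("condition collapse is the mean of per-array log2 values", {
  m <- matrix(c(4, 16, 8, 8), 1, 4,
              dimnames = list("g1", paste0("a", 1:4)))
  comp <- ExpressionCompendium(m, c(a1 = "c1", a2 = "c1", a3 = "c2",
                                    a4 = "c2"))
  cl <- conditionLog2(collapseConditions(comp))
  expect_equal(cl["g1", "c1"], 3)         # (log2 4 + log2 16) / 2
  expect_equal(cl["g1", "c2"], 3)         # single value per array pair
})

test_that("single-array conditions pass through and the pseudocount only fires on zeros", {
  m <- matrix(c(4, 16), 1, 2, dimnames = list("g1", c("a1", "a2")))
  comp <- ExpressionCompendium(m, c(a1 = "c1", a2 = "c2"))
  cl <- conditionLog2(collapseConditions(comp))
  expect_equal(unname(cl["g1", c("c1", "c2")]), c(2, 4))  # no pseudocount
  m0 <- matrix(c(0, 3), 1, 2, dimnames = list("g1", c("a1", "a2")))
  comp0 <- ExpressionCompendium(m0, c(a1 = "c1", a2 = "c2"))
  cl0 <- conditionLog2(collapseConditions(comp0))
  expect_equal(unname(cl0["g1", ]), c(log2(1), log2(4)))
})

test_that("collapse is invariant to array order and counts conditions from the map", {
  sp <- syntheticSpec(nGenes = 40, nConditions = 155, seed = 8)
  sim <- generateCompendium(sp)
  comp <- sim$compendium
  cl <- conditionLog2(collapseConditions(comp))
  expect_identical(ncol(cl), 155L)
  perm <- sample(ncol(comp))
  shuffled <- ExpressionCompendium(
    SummarizedExperiment::assay(comp, "intensity")[, perm],
    arrayConditions(comp)[perm])
  expect_equal(conditionLog2(collapseConditions(shuffled)), cl)
})

test_that("compendium and catalog round-trip losslessly through their file formats", {
  dir <- withr::local_tempdir()
  sp <- smallModuleSpec(seed = 21, nGenes = 60, nConditions = 12)
  sim <- generateCompendium(sp)
  writeCompendium(sim$compendium, file.path(dir, "m.tsv"),
                  file.path(dir, "c.tsv"))
  back <- readCompendium(file.path(dir, "m.tsv"), file.path(dir, "c.tsv"))
  expect_identical(geneIds(back), geneIds(sim$compendium))
  expect_identical(arrayConditions(back), arrayConditions(sim$compendium))
  expect_equal(SummarizedExperiment::assay(back, "intensity"),
               SummarizedExperiment::assay(sim$compendium, "intensity"),
               tolerance = 1e-6)

  catalog <- generateCatalog(sp, sim$truth)
  writeCatalog(catalog, file.path(dir, "g.gff3"), file.path(dir, "at.tsv"))
  back <- readCatalog(file.path(dir, "g.gff3"), file.path(dir, "at.tsv"))
  expect_identical(geneAttributes(back), geneAttributes(catalog))
})

test_that("ontology and annotations round-trip through OBO and GAF", {
  dir <- withr::local_tempdir()
  sp <- smallModuleSpec(seed = 22, nGenes = 60, nConditions = 12)
  sim <- generateCompendium(sp)
  catalog <- generateCatalog(sp, sim$truth)
  onto <- generateOntology(sp, sim$truth)
  writeOntology(onto$dag, file.path(dir, "o.obo"))
  dag <- readOntology(file.path(dir, "o.obo"))
  expect_identical(ontologyTerms(dag), ontologyTerms(onto$dag))
  expect_identical(termParents(dag)[ontologyTerms(dag)$id],
                   termParents(onto$dag)[ontologyTerms(dag)$id])
  writeAnnotations(onto$annotations, file.path(dir, "a.gaf"))
  ann <- readAnnotations(file.path(dir, "a.gaf"), catalog, dag)
  expect_identical(directAnnotations(ann),
                   directAnnotations(onto$annotations))
})

test_that("GAF rows collapse to set semantics and unknown genes are dropped with a count", {
  dir <- withr::local_tempdir()
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100), width = 50))
  names(gr) <- c("g1", "g2")
  catalog <- GeneCatalog(gr)
  gaf <- file.path(dir, "x.gaf")
  row <- function(g, t) paste("DB", g, g, "", t, "REF", "IEA", "", "P", "",
                              "", "protein", "taxon:0", "20240101", "DB",
                              "", "", sep = "\t")
  writeLines(c("!gaf-version: 2.2", row("g1", "T:1"), row("g1", "T:1"),
               row("gX", "T:1"), row("g2", "T:2")), gaf)
  expect_message(ann <- readAnnotations(gaf, catalog), "1 annotation row")
  expect_identical(directAnnotations(ann)$g1, "T:1")
  expect_identical(ann@nDropped, 1L)
})

test_that("an OBO is_a edge to an unknown term is a hard error", {
  dir <- withr::local_tempdir()
  obo <- file.path(dir, "bad.obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: T:1", "name: root",
               "namespace: biological_process", "", "[Term]", "id: T:2",
               "name: child", "namespace: biological_process",
               "is_a: T:9 ! missing", ""), obo)
  expect_error(readOntology(obo), "T:9")
})
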