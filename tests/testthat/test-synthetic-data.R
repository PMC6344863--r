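test_that("a fixed seed reproduces the compendium, catalog and ontology exactly", {
  sp <- smallModuleSpec(seed = 5)
  a <- generateCompendium(sp)
  b <- generateCompendium(sp)
  expect_identical(SummarizedExperiment::assay(a$compendium, "intensity"),
                   SummarizedExperiment::assay(b$compendium, "intensity"))
  expect_identical(moduleMembership(a$truth), moduleMembership(b$truth))
  expect_identical(geneAttributes(generateCatalog(sp, a$truth)),
                   geneAttributes(generateCatalog(sp, b$truth)))
  oa <- generateOntology(sp, a$truth)
  ob <- generateOntology(sp, b$truth)
  expect_identical(termParents(oa$dag), termParents(ob$dag))
  expect_identical(directAnnotations(oa$annotations),
                   directAnnotations(ob$annotations))
})

test_that("module sizes exceeding the gene count are rejected with a sizing error", {
  expect_error(
    generateCompendium(syntheticSpec(nGenes = 30,
                                     modules = list(coexModule(40)))),
    "sizing")
})

test_that("a structureless compendium has no pair reaching |rho| = 0.5", {
  m <- nullMatrix(200, 155, seed = 42)
  corr <- allPairsCorrelation(m, 0.5)
  expect_identical(nrow(corEdges(corr)), 0L)
  expect_equal(nPairsTotal(corr), 200 * 199 / 2)
})

test_that("a planted module reaches the designed within-module Spearman strength", {
  sp <- syntheticSpec(nGenes = 100, nConditions = 155,
                      modules = list(coexModule(20, loadingMean = 1.5,
                                                loadingSd = 0.2)),
                      noiseSd = 0.5, seed = 9)
  cc <- collapsedCompendium(sp)
  members <- names(which(moduleMembership(cc$truth) == 1L))
  m <- conditionLog2(cc$comp)[members, ]
  rk <- apply(m, 1, rank)  # conditions x genes
  rhos <- abs(stats::cor(rk)[upper.tri(diag(length(members)))])
  expect_gte(stats::median(rhos), 0.7)
})

test_that("replicate layout emulates 283 arrays over 155 conditions by default", {
  sp <- syntheticSpec(nGenes = 10)
  sim <- generateCompendium(sp)
  expect_identical(ncol(sim$compendium), 283L)
  expect_identical(length(unique(arrayConditions(sim$compendium))), 155L)
})

test_that("SM clusters are contiguous coordinate runs with exactly one core", {
  sp <- syntheticSpec(nGenes = 300, nConditions = 20, nSmClusters = 3,
                      smClusterSizeRange = c(6, 6), seed = 2)
  sim <- generateCompendium(sp)
  catalog <- generateCatalog(sp, sim$truth)
  at <- geneAttributes(catalog)
  clustered <- at[!is.na(at$sm_cluster_id), ]
  expect_identical(length(unique(clustered$sm_cluster_id)), 3L)
  for (cid in unique(clustered$sm_cluster_id)) {
    d <- clustered[clustered$sm_cluster_id == cid, ]
    expect_identical(sum(d$is_sm_core), 1L)
    expect_identical(length(unique(d$chromosome)), 1L)
    # sort-and-check: members form an unbroken run in coordinate order
    d <- d[order(d$start), ]
    onChr <- at[at$chromosome == d$chromosome[1], ]
    onChr <- onChr[order(onChr$start), ]
    idx <- match(d$gene_id, onChr$gene_id)
    expect_identical(idx, seq(min(idx), max(idx)))
  }
})

test_that("cluster demand exceeding the gene supply raises a sizing error", {
  sp <- syntheticSpec(nGenes = 20, nConditions = 10, nSmClusters = 10,
                      smClusterSizeRange = c(5, 5), seed = 1)
  sim <- generateCompendium(sp)
  expect_error(generateCatalog(sp, sim$truth), "sizing")
})

test_that("zero informant fraction propagates to empty prioritized sub-networks", {
  sp <- syntheticSpec(nGenes = 80, nConditions = 40,
                      modules = list(coexModule(15)),
                      informantFraction = 0, nSmClusters = 0, seed = 4)
  cc <- collapsedCompendium(sp)
  catalog <- generateCatalog(sp, cc$truth)
  corr <- allPairsCorrelation(conditionLog2(cc$comp), 0.5)
  member <- names(which(moduleMembership(cc$truth) == 1L))[1]
  pr <- prioritizeSubnetwork(extractSubnetwork(corr, member, 0.5), catalog)
  expect_identical(nrow(informantPartners(pr)), 0L)
})

test_that("generated ontologies are acyclic for many seeds and obey the true-path root", {
  for (seed in 1:20) {
    sp <- syntheticSpec(nGenes = 60, nConditions = 10,
                        modules = list(coexModule(10)), seed = seed)
    sim <- generateCompendium(sp)
    onto <- generateOntology(sp, sim$truth)
    expect_true(validObject(onto$dag, complete = TRUE))
    expect_identical(length(ontologyRoots(onto$dag)), 1L)
    ann <- propagateAnnotations(onto$annotations, onto$dag)
    prop <- propagatedAnnotations(ann)
    # root annotates every annotated gene after propagation
    expect_true(all(vapply(prop, function(ts)
      ontologyRoots(onto$dag) %in% ts, logical(1))))
  }
})

test_that("the signature term is concentrated in its module and rare in background", {
  sp <- smallModuleSpec(seed = 13)
  sim <- generateCompendium(sp)
  onto <- generateOntology(sp, sim$truth)
  mm <- moduleMembership(onto$truth)
  direct <- directAnnotations(onto$annotations)
  for (sig in names(signatureTerms(onto$truth))) {
    mod <- signatureTerms(onto$truth)[[sig]]
    members <- names(which(mm == mod))
    annotated <- names(direct)[vapply(direct, function(ts) sig %in% ts,
                                      logical(1))]
    expect_gte(length(intersect(annotated, members)) / length(members), 0.8)
    bg <- setdiff(names(mm), members)
    expect_lte(length(intersect(annotated, bg)) / length(bg),
               sp@annotationRate)
  }
})
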