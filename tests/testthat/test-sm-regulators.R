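# design: one 63-gene module whose block carries 20 three-gene clusters
# (one core each) plus a planted out-of-cluster regulator on the same factor
regulatorFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- syntheticSpec(
        nGenes = 300, nConditions = 155,
        modules = list(coexModule(63, loadingMean = 1.5, loadingSd = 0.2,
                                  negativeFraction = 0)),
        nSmClusters = 20, smClusterSizeRange = c(3, 3),
        nPlantedRegulators = 1, tfInClusterFraction = 0.3, seed = 61)
      cc <- collapsedCompendium(sp)
      catalog <- generateCatalog(sp, cc$truth)
      cache <<- list(spec = sp, comp = cc$comp, truth = cc$truth,
                     catalog = catalog, clusters = smClusters(catalog),
                     corr = allPairsCorrelation(conditionLog2(cc$comp), 0.5))
    }
    cache
  }
})

test_that("core expression flags obey the floor rule", {
  fx <- regulatorFixture()
  survey <- coreExpressionSurvey(fx$comp, fx$clusters)
  expect_identical(nrow(survey), 20L)
  floorVal <- attr(survey, "floor")
  cl <- conditionLog2(fx$comp)
  for (i in seq_len(nrow(survey)))
    expect_identical(survey$expressed[i],
                     any(cl[survey$core_gene[i], ] > floorVal))
  # a core pinned below the floor is unexpressed; one excursion suffices
  low <- cl[survey$core_gene[1], , drop = FALSE] * 0 + (floorVal - 1)
  lowComp <- fx$comp
  lowComp@conditionLog2[survey$core_gene[1], ] <- low
  s2 <- coreExpressionSurvey(lowComp, fx$clusters, floor = floorVal)
  expect_false(s2$expressed[s2$core_gene == survey$core_gene[1]])
  low[1, 1] <- floorVal + 0.1
  lowComp@conditionLog2[survey$core_gene[1], ] <- low
  s3 <- coreExpressionSurvey(lowComp, fx$clusters, floor = floorVal)
  expect_true(s3$expressed[s3$core_gene == survey$core_gene[1]])
})

test_that("module-backed clusters are coherent and background clusters are not", {
  fx <- regulatorFixture()
  coh <- clusterCoherence(fx$corr, fx$clusters, 0.5)
  expect_true(all(coh$evaluable))
  expect_true(all(coh$member_coexpression_fraction >= 0.9))
  expect_true(all(coh$member_coexpression_fraction <= 1))
  # clusters without an embedded TF are vacuously not TF-co-expressed
  noTf <- !coh$has_embedded_tf
  expect_true(any(noTf))
  expect_false(any(coh$contiguous_tf_coexpressed[noTf]))
  # planted design: 30% of clusters embed a TF and those are co-expressed
  expect_equal(attr(coh, "tf_coexpressed_fraction"),
               round(0.3 * 20) / 20, tolerance = 1 / 20)

  # background-only cluster: genes with no planted factor
  bgCluster <- list(bg = list(
    members = sprintf("g%04d", 200:205),
    cores = "g0200", embedded_tfs = character(0)))
  cohBg <- clusterCoherence(fx$corr, bgCluster, 0.5)
  expect_lte(cohBg$member_coexpression_fraction, 0.2)
})

test_that("the planted out-of-cluster regulator ranks first with near-complete core coverage", {
  fx <- regulatorFixture()
  cand <- scanTransRegulators(fx$corr, fx$catalog, 0.5, minCores = 2)
  reg <- plantedRegulators(fx$truth)
  expect_identical(cand$gene[1], reg)
  expect_gte(cand$n_cores_positive[1] + cand$n_cores_negative[1], 18)
  expect_identical(cand$pattern[1], "positive_only")
})

test_that("in-cluster TFs are excluded and minCores gates the candidate list", {
  fx <- regulatorFixture()
  at <- geneAttributes(fx$catalog)
  inClusterTf <- at$gene_id[at$is_tf & !is.na(at$sm_cluster_id)]
  expect_gt(length(inClusterTf), 0)
  cand <- scanTransRegulators(fx$corr, fx$catalog, 0.5, minCores = 2)
  expect_false(any(inClusterTf %in% cand$gene))
  expect_identical(nrow(scanTransRegulators(fx$corr, fx$catalog, 0.5,
                                            minCores = 50)), 0L)
})

test_that("the candidate ranking is stable under catalog row permutation", {
  fx <- regulatorFixture()
  cand <- scanTransRegulators(fx$corr, fx$catalog, 0.5, minCores = 2)
  gr <- geneRanges(fx$catalog)
  perm <- sample(length(gr))
  cand2 <- scanTransRegulators(fx$corr, GeneCatalog(gr[perm]), 0.5,
                               minCores = 2)
  expect_identical(cand$gene, cand2$gene)
  expect_identical(cand$rank, cand2$rank)
})

test_that("pair correlation matches single-pair semantics and planted geometry", {
  fx <- regulatorFixture()
  reg <- plantedRegulators(fx$truth)
  expect_equal(regulatorPairCorrelation(fx$comp, reg, reg), 1.0)
  # same-factor, same-sign loading partner correlates strongly
  member <- names(which(moduleMembership(fx$truth) == 1L))[1]
  expect_gte(regulatorPairCorrelation(fx$comp, reg, member), 0.8)
  # background gene on an independent profile stays below threshold
  expect_lt(abs(regulatorPairCorrelation(fx$comp, reg, "g0250")), 0.5)
})
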