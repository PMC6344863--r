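tinyDag <- function() {
  # root -> {b1, b2} -> {m1, m2} -> leaves; l3 has two parents
  terms <- data.frame(
    id = c("T:root", "T:b1", "T:b2", "T:m1", "T:m2", "T:l1", "T:l2", "T:l3"),
    name = c("root", "b1", "b2", "m1", "m2", "l1", "l2", "l3"),
    namespace = "biological_process", stringsAsFactors = FALSE)
  parents <- list("T:root" = character(0), "T:b1" = "T:root",
                  "T:b2" = "T:root", "T:m1" = "T:b1", "T:m2" = "T:b2",
                  "T:l1" = "T:m1", "T:l2" = "T:m2",
                  "T:l3" = c("T:m1", "T:m2"))
  new("OntologyDAG", terms = terms, parents = parents, roots = "T:root")
}

test_that("true-path propagation closes annotation sets and is idempotent", {
  dag <- tinyDag()
  ann <- new("AnnotationMap",
             direct = list(g1 = "T:l1", g2 = "T:l3", g3 = "T:m2"),
             propagated = list(), nDropped = 0L)
  p1 <- propagateAnnotations(ann, dag)
  prop <- propagatedAnnotations(p1)
  expect_setequal(prop$g1, c("T:l1", "T:m1", "T:b1", "T:root"))
  expect_setequal(prop$g2,
                  c("T:l3", "T:m1", "T:m2", "T:b1", "T:b2", "T:root"))
  p2 <- propagateAnnotations(p1, dag)
  expect_identical(propagatedAnnotations(p2), prop)
})

test_that("annotations to unknown terms are dropped with a logged count", {
  dag <- tinyDag()
  ann <- new("AnnotationMap", direct = list(g1 = c("T:l1", "T:zzz")),
             propagated = list(), nDropped = 0L)
  expect_message(p <- propagateAnnotations(ann, dag), "dropped")
  expect_identical(p@nDropped, 1L)
  expect_false("T:zzz" %in% propagatedAnnotations(p)$g1)
})

test_that("propagated per-term counts dominate those of every child", {
  sp <- smallModuleSpec(seed = 29, nGenes = 100, nConditions = 12)
  sim <- generateCompendium(sp)
  onto <- generateOntology(sp, sim$truth)
  ann <- propagateAnnotations(onto$annotations, onto$dag)
  prop <- propagatedAnnotations(ann)
  genes <- rep(names(prop), lengths(prop))
  terms <- unlist(prop, use.names = FALSE)
  count <- table(terms)
  for (child in names(termParents(onto$dag)))
    for (parent in termParents(onto$dag)[[child]])
      expect_gte(count[parent], count[child])
})

test_that("Fisher p-values match the log-gamma hypergeometric oracle to 1e-10", {
  dag <- tinyDag()
  set.seed(41)
  genes <- sprintf("g%03d", 1:400)
  direct <- lapply(stats::setNames(genes, genes), function(g)
    sample(c("T:l1", "T:l2", "T:l3", "T:m1"),
           sample(0:2, 1), replace = FALSE))
  direct <- direct[lengths(direct) > 0]
  ann <- new("AnnotationMap", direct = direct, propagated = list(),
             nDropped = 0L)
  for (nStudy in c(10, 50)) {
    study <- sample(genes, nStudy)
    tab <- enrichTerms(study, genes, ann, dag)
    for (i in seq_len(nrow(tab))) {
      expect_equal(tab$p_value[i],
                   lgammaHyperTail(tab$k[i], tab$K[i], tab$N[i], tab$n[i]),
                   tolerance = 1e-10)
    }
  }
})

test_that("the documented hypergeometric example reproduces the direct tail sum", {
  # N=1000, K=50, n=10, k=5: direct summation gives 5.341195257e-05
  expect_equal(lgammaHyperTail(5, 50, 1000, 10), 5.341195257017984e-05,
               tolerance = 1e-10)
  dag <- tinyDag()
  genes <- sprintf("g%04d", 1:1000)
  direct <- lapply(stats::setNames(genes[1:50], genes[1:50]),
                   function(g) "T:l1")
  ann <- new("AnnotationMap", direct = direct, propagated = list(),
             nDropped = 0L)
  study <- c(genes[1:5], genes[101:105])  # k = 5 of n = 10
  tab <- enrichTerms(study, genes, ann, dag)
  expect_equal(tab$p_value[tab$term_id == "T:l1"], 5.341195257017984e-05,
               tolerance = 1e-10)
})

test_that("study = background gives p = 1 everywhere and the root is never enriched", {
  sp <- smallModuleSpec(seed = 37, nGenes = 80, nConditions = 12)
  sim <- generateCompendium(sp)
  onto <- generateOntology(sp, sim$truth)
  genes <- names(moduleMembership(sim$truth))
  tab <- enrichTerms(genes, genes, onto$annotations, onto$dag)
  expect_true(all(tab$p_value == 1))
  sub <- sample(genes, 20)
  tab2 <- enrichTerms(sub, genes, onto$annotations, onto$dag)
  root <- ontologyRoots(onto$dag)
  if (root %in% tab2$term_id)
    expect_false(tab2$enriched[tab2$term_id == root])
})

test_that("study genes outside the background are a hard error", {
  dag <- tinyDag()
  ann <- new("AnnotationMap", direct = list(g1 = "T:l1"),
             propagated = list(), nDropped = 0L)
  expect_error(enrichTerms(c("g1", "gX"), "g1", ann, dag), "gX")
})

test_that("Bonferroni mode never reports more enriched terms than uncorrected", {
  sp <- smallModuleSpec(seed = 43, nGenes = 120, nConditions = 155)
  cc <- collapsedCompendium(sp)
  onto <- generateOntology(sp, cc$truth)
  corr <- allPairsCorrelation(conditionLog2(cc$comp), 0.5)
  member <- names(which(moduleMembership(cc$truth) == 1L))[1]
  sn <- extractSubnetwork(corr, member, 0.5)
  bg <- geneIds(cc$comp)
  raw <- enrichSubnetwork(sn, onto$annotations, onto$dag, bg,
                          correction = "none")
  bonf <- enrichSubnetwork(sn, onto$annotations, onto$dag, bg,
                           correction = "bonferroni")
  expect_lte(sum(bonf$enriched), sum(raw$enriched))
  expect_equal(bonf$p_bonferroni, pmin(1, bonf$p_value * nrow(bonf)))
})

test_that("sign-mode study sets partition the combined set and empty sets warn", {
  sp <- smallModuleSpec(seed = 47, nGenes = 120, nConditions = 155)
  cc <- collapsedCompendium(sp)
  onto <- generateOntology(sp, cc$truth)
  corr <- allPairsCorrelation(conditionLog2(cc$comp), 0.5)
  member <- names(which(moduleMembership(cc$truth) == 1L))[1]
  sn <- extractSubnetwork(corr, member, 0.5)
  bg <- geneIds(cc$comp)
  comb <- enrichSubnetwork(sn, onto$annotations, onto$dag, bg)
  expect_identical(unique(comb$n), subNetworkSize(sn))
  pos <- positivePartners(sn)$gene
  neg <- negativePartners(sn)$gene
  expect_identical(sort(c(pos, neg)),
                   sort(union(pos, neg)))  # disjoint sign classes
  lonely <- new("SubNetwork", queryGene = "q", cutoff = 0.5,
                positive = data.frame(gene = "p1", rho = 0.9),
                negative = data.frame(gene = character(0),
                                      rho = numeric(0)))
  expect_warning(out <- enrichSubnetwork(lonely, onto$annotations, onto$dag,
                                         bg, mode = "negative_only"),
                 "empty")
  expect_identical(nrow(out), 0L)
})

test_that("each planted module's signature term is enriched in member sub-networks", {
  sp <- smallModuleSpec(seed = 53, nGenes = 150, nConditions = 155)
  cc <- collapsedCompendium(sp)
  onto <- generateOntology(sp, cc$truth)
  corr <- allPairsCorrelation(conditionLog2(cc$comp), 0.5)
  bg <- geneIds(cc$comp)
  sig <- signatureTerms(onto$truth)
  for (term in names(sig)) {
    members <- names(which(moduleMembership(onto$truth) == sig[[term]]))
    sn <- extractSubnetwork(corr, members[1], 0.5)
    tab <- enrichSubnetwork(sn, onto$annotations, onto$dag, bg)
    expect_lt(tab$p_value[tab$term_id == term], 0.05)
  }
})
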