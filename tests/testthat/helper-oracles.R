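# Independent oracles and small fixture builders used across the suite.

# naive per-pair Spearman: rank-then-Pearson via stats::cor
naiveSpearman <- function(x, y) stats::cor(rank(x), rank(y))

# arbitrary-precision-style hypergeometric upper tail via log-gamma sums,
# independent of stats::phyper
lgammaHyperTail <- function(k, K, N, n) {
  lgchoose <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  i <- k:min(n, K)
  sum(exp(lgchoose(K, i) + lgchoose(N - K, n - i) - lgchoose(N, n)))
}

# small two-module spec reused by several module tests
smallModuleSpec <- function(seed = 11, nGenes = 150, nConditions = 60,
                            moduleSizes = c(15, 12)) {
  syntheticSpec(
    nGenes = nGenes, nConditions = nConditions,
    modules = lapply(moduleSizes, function(s)
      coexModule(s, loadingMean = 1.5, loadingSd = 0.2,
                 negativeFraction = 0.25)),
    nSmClusters = 2, smClusterSizeRange = c(5, 5),
    nPlantedRegulators = 1, seed = seed)
}

collapsedCompendium <- function(spec) {
  sim <- generateCompendium(spec)
  list(comp = collapseConditions(sim$compendium), truth = sim$truth)
}

# structureless compendium matrix on the log2 scale
nullMatrix <- function(nGenes, nConditions, seed) {
  sim <- generateCompendium(syntheticSpec(
    nGenes = nGenes, nConditions = nConditions, modules = list(),
    seed = seed))
  conditionLog2(collapseConditions(sim$compendium))
}
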