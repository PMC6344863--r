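#' Specification of a synthetic expression compendium
#'
#' Holds every tunable of the synthetic-data generator: compendium geometry
#' (genes, conditions, replicate arrays), the log-normal expression baseline,
#' planted co-expression modules with mixed-sign loadings, secondary-
#' metabolite cluster layout, regulator/TF/informant designations, and the
#' synthetic ontology. Defaults emulate a microarray meta-analysis
#' compendium: 283 arrays over 155 cultivation conditions (128 duplicated,
#' 27 singleton), log2 baselines centred at 6 (sd 2), gene-condition noise
#' sd 0.5 and replicate-array noise sd 0.1 on the log2 scale.
#'
#' @slot nGenes,nConditions compendium dimensions.
#' @slot replicates integer vector of arrays per condition.
#' @slot modules list of module descriptors from \code{\link{coexModule}}.
#' @slot noiseSd gene-condition noise sd (log2 scale).
#' @slot baselineLog2Mean,baselineLog2Sd baseline expression distribution.
#' @slot arrayNoiseSd replicate-array noise sd (log2 scale).
#' @slot nSmClusters,smClusterSizeRange secondary-metabolite cluster layout.
#' @slot tfFraction,informantFraction,hypotheticalFraction catalog flag rates.
#' @slot tfInClusterFraction fraction of SM clusters embedding a pathway TF.
#' @slot nPlantedRegulators trans-regulators loaded on module factors but
#'   placed outside every cluster.
#' @slot nChromosomes synthetic chromosome count.
#' @slot ontologyTerms,annotationRate synthetic ontology size and background
#'   annotation rate.
#' @slot seed master seed; a fixed seed yields byte-identical artifacts.
#' @export
setClass("SyntheticSpec",
  representation(
    nGenes = "integer", nConditions = "integer", replicates = "integer",
    modules = "list", noiseSd = "numeric",
    baselineLog2Mean = "numeric", baselineLog2Sd = "numeric",
    arrayNoiseSd = "numeric",
    nSmClusters = "integer", smClusterSizeRange = "integer",
    tfFraction = "numeric", informantFraction = "numeric",
    hypotheticalFraction = "numeric", tfInClusterFraction = "numeric",
    nPlantedRegulators = "integer", nChromosomes = "integer",
    ontologyTerms = "integer", annotationRate = "numeric",
    seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  sizes <- vapply(object@modules, function(m) m$size, numeric(1))
  if (sum(sizes) + object@nPlantedRegulators > object@nGenes)
    msg <- c(msg, sprintf(
      "sizing error: module sizes (%d) plus planted regulators (%d) exceed nGenes (%d)",
      sum(sizes), object@nPlantedRegulators, object@nGenes))
  props <- c(object@tfFraction, object@informantFraction,
             object@hypotheticalFraction, object@tfInClusterFraction,
             object@annotationRate,
             vapply(object@modules, function(m) m$negativeFraction, numeric(1)))
  if (any(props < 0 | props > 1))
    msg <- c(msg, "all proportions must lie in [0, 1]")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (length(object@replicates) != object@nConditions)
    msg <- c(msg, "replicates must give one array count per condition")
  if (any(object@replicates < 1L))
    msg <- c(msg, "every condition needs at least one array")
  if (object@smClusterSizeRange[1] > object@smClusterSizeRange[2])
    msg <- c(msg, "smClusterSizeRange must be (min, max)")
  if (length(msg)) msg else TRUE
})

#' Describe one planted co-expression module
#'
#' A module is a set of genes sharing one latent per-condition factor.
#' Loadings are drawn from N(loadingMean, loadingSd^2) and a
#' \code{negativeFraction} of members have their loading negated, planting
#' negatively correlated partners.
#'
#' @param size number of member genes.
#' @param loadingMean,loadingSd loading distribution (log2 scale).
#' @param negativeFraction proportion of members with negated loadings.
#' @return list descriptor consumed by \code{\link{syntheticSpec}}.
#' @export
coexModule <- function(size, loadingMean = 1.5, loadingSd = 0.2,
                       negativeFraction = 0.25) {
  stopifnot(size >= 2, loadingSd >= 0,
            negativeFraction >= 0, negativeFraction <= 1)
  list(size = as.integer(size), loadingMean = loadingMean,
       loadingSd = loadingSd, negativeFraction = negativeFraction)
}

#' Construct a SyntheticSpec
#'
#' @param nGenes,nConditions compendium dimensions.
#' @param replicates arrays per condition: a single count, a vector, or NULL
#'   for the default 283-over-155-style layout (the first ~83\% of
#'   conditions get a duplicate array).
#' @param modules list of \code{\link{coexModule}} descriptors.
#' @param noiseSd,baselineLog2Mean,baselineLog2Sd,arrayNoiseSd noise model.
#' @param nSmClusters,smClusterSizeRange secondary-metabolite cluster layout.
#' @param tfFraction,informantFraction,hypotheticalFraction,tfInClusterFraction
#'   catalog flag rates.
#' @param nPlantedRegulators planted out-of-cluster trans-regulators.
#' @param nChromosomes synthetic chromosome count.
#' @param ontologyTerms,annotationRate synthetic ontology controls.
#' @param seed master seed.
#' @return A validated \linkS4class{SyntheticSpec}.
#' @examples
#' sp <- syntheticSpec(nGenes = 200, modules = list(coexModule(20)), seed = 7)
#' @export
syntheticSpec <- function(nGenes = 1000, nConditions = 155, replicates = NULL,
                          modules = list(), noiseSd = 0.5,
                          baselineLog2Mean = 6, baselineLog2Sd = 2,
                          arrayNoiseSd = 0.1,
                          nSmClusters = 0, smClusterSizeRange = c(4, 8),
                          tfFraction = 0.05, informantFraction = 0.09,
                          hypotheticalFraction = 0.45,
                          tfInClusterFraction = 0.3,
                          nPlantedRegulators = 0, nChromosomes = 8,
                          ontologyTerms = 30, annotationRate = 0.05,
                          seed = 1) {
  nConditions <- as.integer(nConditions)
  if (is.null(replicates)) {
    # 128 of 155 conditions carry a duplicate array (283 arrays total)
    nDup <- round(128 / 155 * nConditions)
    replicates <- rep(1L, nConditions)
    if (nDup > 0) replicates[seq_len(nDup)] <- 2L
  } else if (length(replicates) == 1L) {
    replicates <- rep(as.integer(replicates), nConditions)
  } else {
    replicates <- as.integer(replicates)
  }
  new("SyntheticSpec",
      nGenes = as.integer(nGenes), nConditions = nConditions,
      replicates = replicates, modules = modules, noiseSd = noiseSd,
      baselineLog2Mean = baselineLog2Mean, baselineLog2Sd = baselineLog2Sd,
      arrayNoiseSd = arrayNoiseSd,
      nSmClusters = as.integer(nSmClusters),
      smClusterSizeRange = as.integer(smClusterSizeRange),
      tfFraction = tfFraction, informantFraction = informantFraction,
      hypotheticalFraction = hypotheticalFraction,
      tfInClusterFraction = tfInClusterFraction,
      nPlantedRegulators = as.integer(nPlantedRegulators),
      nChromosomes = as.integer(nChromosomes),
      ontologyTerms = as.integer(ontologyTerms),
      annotationRate = annotationRate, seed = as.integer(seed))
}

.syntheticGeneIds <- function(n) {
  sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
}

#' Generate a synthetic expression compendium with planted modules
#'
#' Single-latent-factor model: each planted module m has one standard-normal
#' factor value per condition; member gene g takes the condition-level log2
#' value \code{baseline_g + a_g * f_mc + eps} with \code{eps ~ N(0,
#' noiseSd^2)}, where loadings \code{a_g} follow the module descriptor and a
#' negativeFraction of them are negated. Background genes are baseline plus
#' noise. Replicate arrays add independent N(0, arrayNoiseSd^2) around the
#' condition value; the stored intensity matrix is \code{2^log2}. Planted
#' regulators load positively (at the module's loadingMean) on module
#' factors, cycling over modules.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with elements \code{compendium}
#'   (\linkS4class{ExpressionCompendium}, conditionLog2 unset) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' sim <- generateCompendium(
#'   syntheticSpec(nGenes = 100, nConditions = 30,
#'                 modules = list(coexModule(10)), seed = 1))
#' sim$compendium
#' @export
generateCompendium <- function(spec) {
  methods::validObject(spec)
  set.seed(spec@seed)
  n <- spec@nGenes; C <- spec@nConditions
  ids <- .syntheticGeneIds(n)
  baseline <- stats::rnorm(n, spec@baselineLog2Mean, spec@baselineLog2Sd)

  nMod <- length(spec@modules)
  membership <- rep(NA_integer_, n)
  loading <- numeric(n)
  cursor <- 0L
  for (m in seq_len(nMod)) {
    mod <- spec@modules[[m]]
    idx <- cursor + seq_len(mod$size)
    a <- stats::rnorm(mod$size, mod$loadingMean, mod$loadingSd)
    nNeg <- round(mod$negativeFraction * mod$size)
    if (nNeg > 0) {
      neg <- sample(mod$size, nNeg)
      a[neg] <- -a[neg]
    }
    membership[idx] <- m
    loading[idx] <- a
    cursor <- cursor + mod$size
  }
  regulatorIds <- character(0)
  if (spec@nPlantedRegulators > 0) {
    if (nMod == 0)
      stop("planted regulators require at least one module")
    regIdx <- cursor + seq_len(spec@nPlantedRegulators)
    regMod <- ((seq_len(spec@nPlantedRegulators) - 1L) %% nMod) + 1L
    membership[regIdx] <- regMod
    loading[regIdx] <- vapply(regMod,
      function(m) spec@modules[[m]]$loadingMean, numeric(1))
    regulatorIds <- ids[regIdx]
  }

  fac <- matrix(stats::rnorm(max(nMod, 1L) * C), max(nMod, 1L), C)
  log2cond <- matrix(stats::rnorm(n * C, 0, spec@noiseSd), n, C) + baseline
  inMod <- which(!is.na(membership))
  if (length(inMod))
    log2cond[inMod, ] <- log2cond[inMod, ] +
      loading[inMod] * fac[membership[inMod], , drop = FALSE]

  conds <- sprintf("cond%03d", seq_len(C))
  condIdx <- rep(seq_len(C), spec@replicates)
  A <- length(condIdx)
  arrLog2 <- log2cond[, condIdx, drop = FALSE] +
    matrix(stats::rnorm(n * A, 0, spec@arrayNoiseSd), n, A)
  repNo <- unlist(lapply(spec@replicates, seq_len), use.names = FALSE)
  arrayIds <- sprintf("%s_a%d", conds[condIdx], repNo)
  intensities <- 2^arrLog2
  dimnames(intensities) <- list(ids, arrayIds)

  signs <- if (length(inMod)) ifelse(loading[inMod] >= 0, "+", "-")
           else character(0)
  truth <- new("GroundTruth",
               moduleMembership = stats::setNames(membership, ids),
               loadingSigns = stats::setNames(signs, ids[inMod]),
               plantedRegulators = regulatorIds,
               termToModule = stats::setNames(integer(0), character(0)))
  comp <- ExpressionCompendium(intensities,
                               stats::setNames(conds[condIdx], arrayIds))
  list(compendium = comp, truth = truth)
}

#' Generate a gene catalog with contiguous SM clusters
#'
#' Lays the genes of a synthetic compendium onto chromosomes with 1-based,
#' non-overlapping coordinates (gene order = generation order, so planted
#' modules occupy contiguous blocks). Secondary-metabolite clusters are
#' carved as contiguous runs, preferentially inside module blocks so that
#' cluster members are genuinely co-expressed; each cluster's first gene is
#' its core (PKS/NRPS surrogate, informant category \code{sm_core}) and the
#' first \code{tfInClusterFraction} of clusters embed a pathway TF as their
#' second gene. Planted regulators are flagged as TFs but always lie outside
#' every cluster run.
#'
#' @param spec the \linkS4class{SyntheticSpec} used for the compendium.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @return A \linkS4class{GeneCatalog}.
#' @export
generateCatalog <- function(spec, truth) {
  set.seed(spec@seed + 1L)
  ids <- names(truth@moduleMembership)
  n <- length(ids)
  sizes <- vapply(spec@modules, function(m) m$size, integer(1))
  nModGenes <- sum(sizes)
  nReg <- length(truth@plantedRegulators)

  # cluster placement over gene-index runs
  nSm <- spec@nSmClusters
  clusterId <- rep(NA_character_, n)
  isCore <- rep(FALSE, n)
  embeddedTf <- rep(FALSE, n)
  clusterRuns <- list()
  if (nSm > 0) {
    rng <- spec@smClusterSizeRange
    clSizes <- if (rng[1] == rng[2]) rep(rng[1], nSm) else
      sample(seq(rng[1], rng[2]), nSm, replace = TRUE)
    # available contiguous regions: each module block, then the background
    blocks <- list()
    cursor <- 0L
    for (s in sizes) {
      blocks[[length(blocks) + 1L]] <- c(cursor + 1L, cursor + s)
      cursor <- cursor + s
    }
    bgStart <- nModGenes + nReg + 1L
    if (bgStart <= n) blocks[[length(blocks) + 1L]] <- c(bgStart, n)
    bi <- 1L; pos <- if (length(blocks)) blocks[[1L]][1L] else 1L
    nTfClusters <- round(spec@tfInClusterFraction * nSm)
    for (j in seq_len(nSm)) {
      s <- clSizes[j]
      while (bi <= length(blocks) && pos + s - 1L > blocks[[bi]][2L]) {
        bi <- bi + 1L
        if (bi <= length(blocks)) pos <- blocks[[bi]][1L]
      }
      if (bi > length(blocks))
        stop("sizing error: cluster demand exceeds gene supply")
      run <- pos:(pos + s - 1L)
      cid <- sprintf("smc%02d", j)
      clusterId[run] <- cid
      isCore[run[1L]] <- TRUE
      if (j <= nTfClusters && s >= 2L) embeddedTf[run[2L]] <- TRUE
      clusterRuns[[cid]] <- run
      pos <- pos + s
    }
  }

  isTf <- embeddedTf
  isTf[ids %in% truth@plantedRegulators] <- TRUE
  nTfTarget <- round(spec@tfFraction * n)
  # background TF flags emulate unrelated regulators: drawn outside planted
  # modules and outside cluster runs
  pool <- which(!isTf & !isCore & is.na(clusterId) &
                is.na(truth@moduleMembership))
  extra <- nTfTarget - sum(isTf)
  if (extra > 0 && length(pool))
    isTf[sample(pool, min(extra, length(pool)))] <- TRUE

  informant <- rep("none", n)
  informant[isCore] <- "sm_core"
  nInf <- round(spec@informantFraction * n)
  verified <- c("verified_Aniger", "verified_Anidulans",
                "verified_Afumigatus", "verified_Aoryzae")
  pool <- which(informant == "none")
  extra <- nInf - sum(isCore)
  if (extra > 0 && length(pool)) {
    pick <- sample(pool, min(extra, length(pool)))
    # rates proportional to the verified-ORF counts 247/639/218/81
    informant[pick] <- sample(verified, length(pick), replace = TRUE,
                              prob = c(247, 639, 218, 81))
  }

  isHyp <- rep(FALSE, n)
  pool <- which(informant == "none")
  nHyp <- round(spec@hypotheticalFraction * n)
  if (nHyp > 0 && length(pool))
    isHyp[sample(pool, min(nHyp, length(pool)))] <- TRUE

  # chromosome boundaries, nudged so no cluster straddles one
  nChr <- min(spec@nChromosomes, n)
  bnd <- floor(seq_len(nChr - 1L) * n / nChr)
  for (run in clusterRuns) {
    inside <- bnd >= run[1L] & bnd < run[length(run)]
    bnd[inside] <- run[1L] - 1L
  }
  bnd <- sort(unique(bnd[bnd > 0L & bnd < n]))
  chrOf <- findInterval(seq_len(n) - 1L, bnd) + 1L
  posInChr <- stats::ave(seq_len(n), chrOf, FUN = seq_along)
  start <- (posInChr - 1L) * 1500L + 1L
  gr <- GenomicRanges::GRanges(
    seqnames = sprintf("chr%02d", chrOf),
    ranges = IRanges::IRanges(start = start, end = start + 1199L),
    strand = rep(c("+", "-"), length.out = n))
  names(gr) <- ids
  S4Vectors::mcols(gr) <- DataFrame(
    is_tf = isTf, is_chromatin = rep(FALSE, n), is_hypothetical = isHyp,
    informant_category = informant, sm_cluster_id = clusterId,
    is_sm_core = isCore)
  GeneCatalog(gr)
}

#' Generate a synthetic is_a ontology and gene annotations
#'
#' Builds a rooted four-level is_a DAG (root, 3 branches, 4 mid-level terms,
#' leaves; every third leaf carries a second parent so the graph is a DAG
#' rather than a tree). For each planted module one signature leaf annotates
#' 90\% of module members plus at most \code{annotationRate/2} of background
#' genes, guaranteeing downstream enrichment of the signature term in module
#' sub-networks; remaining leaves annotate random genes at
#' \code{annotationRate}.
#'
#' @param spec the \linkS4class{SyntheticSpec}.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @return list with \code{dag} (\linkS4class{OntologyDAG}),
#'   \code{annotations} (\linkS4class{AnnotationMap}, direct only) and
#'   \code{truth} (input truth with the signature term -> module map filled).
#' @export
generateOntology <- function(spec, truth) {
  set.seed(spec@seed + 2L)
  nMod <- length(spec@modules)
  nTerms <- spec@ontologyTerms
  nBranch <- 3L; nMid <- 4L
  nLeaves <- nTerms - 1L - nBranch - nMid
  if (nLeaves < max(nMod, 1L))
    stop("ontologyTerms too small for the planted module count")
  tid <- sprintf("ST:%07d", seq_len(nTerms))
  root <- tid[1L]
  branches <- tid[1L + seq_len(nBranch)]
  mids <- tid[1L + nBranch + seq_len(nMid)]
  leaves <- tid[1L + nBranch + nMid + seq_len(nLeaves)]

  parents <- list()
  parents[root] <- list(character(0))
  for (i in seq_along(branches)) parents[[branches[i]]] <- root
  for (i in seq_along(mids))
    parents[[mids[i]]] <- branches[((i - 1L) %% nBranch) + 1L]
  for (i in seq_along(leaves)) {
    p <- mids[((i - 1L) %% nMid) + 1L]
    if (i %% 3L == 0L) p <- c(p, mids[(i %% nMid) + 1L])
    parents[[leaves[i]]] <- p
  }
  terms <- data.frame(
    id = tid,
    name = c("biological_process",
             sprintf("synthetic process %d", seq_len(nTerms - 1L))),
    namespace = "biological_process", stringsAsFactors = FALSE)
  dag <- new("OntologyDAG", terms = terms, parents = parents, roots = root)
  methods::validObject(dag)  # fail loudly on any cycle

  ids <- names(truth@moduleMembership)
  membership <- truth@moduleMembership
  ann <- list()
  addAnn <- function(genes, term) {
    for (g in genes) ann[[g]] <<- c(ann[[g]], term)
  }
  sigTerms <- stats::setNames(integer(0), character(0))
  for (m in seq_len(nMod)) {
    sig <- leaves[m]
    members <- ids[!is.na(membership) & membership == m]
    addAnn(sample(members, ceiling(0.9 * length(members))), sig)
    bg <- ids[is.na(membership) | membership != m]
    nBg <- round(0.5 * spec@annotationRate * length(bg))
    if (nBg > 0) addAnn(sample(bg, nBg), sig)
    sigTerms[sig] <- m
  }
  for (leaf in setdiff(leaves, leaves[seq_len(nMod)])) {
    k <- round(spec@annotationRate * length(ids))
    if (k > 0) addAnn(sample(ids, k), leaf)
  }
  ann <- lapply(ann, function(x) sort(unique(x)))
  ann <- ann[order(names(ann))]
  truth@termToModule <- sigTerms
  list(dag = dag,
       annotations = new("AnnotationMap", direct = ann,
                         propagated = list(), nDropped = 0L),
       truth = truth)
}
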