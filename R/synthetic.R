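# Synthetic perturbational compendium generator with planted ground truth.
# Counts are negative binomial around cell-type base means, with planted
# multiplicative response modules in a fraction of treated cells, a shared
# lognormal replicate effect per (condition, replicate, gene), and a
# per-cell lognormal library-size factor.

#' SyntheticSpec: parameters of the synthetic compendium
#'
#' @slot cellTypes,cytokines labels of the simulated populations and
#'   treatments (conditions are the cytokines plus \code{"PBS"}).
#' @slot nReplicates replicate mice per condition (>= 2).
#' @slot cellsPerCondition cells per (cell type, condition).
#' @slot nGenes gene universe size.
#' @slot baselineMeanlog,baselineSdlog lognormal prior of per-gene base
#'   mean counts.
#' @slot cellTypeSdlog lognormal spread of per-(gene, cell type) identity
#'   factors.
#' @slot dispersion negative binomial gene dispersion (size = 1 /
#'   dispersion).
#' @slot repEffectSd lognormal sd of the shared per-(condition, replicate,
#'   gene) factor.
#' @slot libSizeSd lognormal sd of the per-cell library factor.
#' @slot moduleSize,moduleLog2Fc,respondingFraction planted response
#'   modules: genes per (cytokine, cell type), their log2 fold change, and
#'   the fraction of treated cells that respond.
#' @slot seed default generation seed.
#' @export
setClass("SyntheticSpec",
         representation(cellTypes = "character", cytokines = "character",
                        nReplicates = "integer",
                        cellsPerCondition = "integer", nGenes = "integer",
                        baselineMeanlog = "numeric",
                        baselineSdlog = "numeric",
                        cellTypeSdlog = "numeric", dispersion = "numeric",
                        repEffectSd = "numeric", libSizeSd = "numeric",
                        moduleSize = "integer", moduleLog2Fc = "numeric",
                        respondingFraction = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (object@nReplicates < 2L) msgs <- c(msgs, "nReplicates must be >= 2")
  if (object@respondingFraction <= 0 || object@respondingFraction > 1)
    msgs <- c(msgs, "respondingFraction must be in (0, 1]")
  if (object@moduleSize >= object@nGenes)
    msgs <- c(msgs, "moduleSize must be smaller than nGenes")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", length(object@cytokines), "cytokines x",
      length(object@cellTypes), "cell types x", object@nReplicates,
      "replicates;", object@cellsPerCondition, "cells/(type,condition);",
      object@nGenes, "genes\n")
  cat("  modules:", object@moduleSize, "genes, log2FC",
      object@moduleLog2Fc, ", responding fraction",
      object@respondingFraction, "\n")
})

#' Construct a SyntheticSpec
#'
#' @param cellTypes,cytokines population and treatment labels.
#' @param nReplicates,cellsPerCondition,nGenes design sizes.
#' @param baselineMeanlog,baselineSdlog,cellTypeSdlog,dispersion,
#'   repEffectSd,libSizeSd noise model parameters.
#' @param moduleSize,moduleLog2Fc,respondingFraction planted effects
#'   (set \code{moduleLog2Fc = 0} or \code{moduleSize = 0} for a null
#'   compendium).
#' @param seed default generation seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(cellTypes = c("B", "NK", "CD8T", "cDC1"),
                          cytokines = c("IFNb", "IFNg", "IL-1b", "TNF",
                                        "IL-4", "IL-18"),
                          nReplicates = 3, cellsPerCondition = 200,
                          nGenes = 2000, baselineMeanlog = log(0.5),
                          baselineSdlog = 1, cellTypeSdlog = 0.3,
                          dispersion = 0.5, repEffectSd = 0.05,
                          libSizeSd = 0.3, moduleSize = 30,
                          moduleLog2Fc = 2, respondingFraction = 0.8,
                          seed = 1) {
  new("SyntheticSpec", cellTypes = cellTypes, cytokines = cytokines,
      nReplicates = as.integer(nReplicates),
      cellsPerCondition = as.integer(cellsPerCondition),
      nGenes = as.integer(nGenes), baselineMeanlog = baselineMeanlog,
      baselineSdlog = baselineSdlog, cellTypeSdlog = cellTypeSdlog,
      dispersion = dispersion, repEffectSd = repEffectSd,
      libSizeSd = libSizeSd, moduleSize = as.integer(moduleSize),
      moduleLog2Fc = moduleLog2Fc,
      respondingFraction = respondingFraction, seed = as.integer(seed))
}

#' The default synthetic benchmark design
#'
#' Six cytokines by four cell types with three replicate mice, 200 cells
#' per (cell type, condition), 2,000 genes, and planted 30-gene response
#' modules at log2FC 2 in 80% of treated cells -- a desk-scale stand-in
#' for an in vivo perturbational compendium that exercises every pipeline
#' stage end to end.
#'
#' @param ... overrides forwarded to \code{\link{syntheticSpec}}.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
defaultBenchmarkSpec <- function(...) syntheticSpec(...)

# ligand genes for a synthetic cytokine: catalog symbols when the name is
# in the default catalog, otherwise a synthetic "<name>_lig" symbol
.synthLigands <- function(cytokines) {
  cat <- defaultCatalog()
  lapply(stats::setNames(cytokines, cytokines), function(cyt)
    if (cyt %in% cytokineNames(cat)) ligandGenes(cat, cyt)
    else paste0(gsub("[^A-Za-z0-9]", "", cyt), "_lig"))
}

.synthReceptors <- function(cytokines) {
  cat <- defaultCatalog()
  unique(unlist(lapply(cytokines, function(cyt)
    if (cyt %in% cytokineNames(cat))
      unlist(receptorOptions(cat, cyt)) else character())))
}

#' Generate a synthetic compendium with ground truth
#'
#' Counts are drawn as \code{NB(mu, size = 1/dispersion)} with
#' \code{mu = base mean x cell-type factor x planted module multiplier
#' (responding treated cells only) x replicate factor x library factor}.
#' Ligand genes of the simulated cytokines are planted as constitutively
#' produced by one designated producer cell type each; receptor genes are
#' expressed everywhere at a moderate level. A few ribosomal /
#' mitochondrial / unlabelled decoy symbols exercise the exclusion
#' policies and are never used for planted modules.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed generation seed (default: the spec's).
#' @return list with \code{compendium} (raw counts
#'   \linkS4class{CytokineCompendium}) and \code{truth} (list with
#'   \code{degs}, \code{responding}, \code{producers}, \code{profiles},
#'   \code{spec}, \code{seed}).
#' @export
generateCompendium <- function(spec, seed = NULL) {
  if (is.null(seed)) seed <- spec@seed
  .withSeed(seed, .generateCompendium(spec, seed))
}

.generateCompendium <- function(spec, seed) {
  cts <- spec@cellTypes; cyts <- spec@cytokines
  conds <- c(.PBS, cyts)
  lig <- .synthLigands(cyts)
  rec <- .synthReceptors(cyts)
  decoys <- c("Rps3", "Rpl13", "mt-Nd1", "mt-Co1", "Gm10099",
              "0610009B22Rik")
  special <- unique(c(unlist(lig), rec, decoys))
  nRegular <- spec@nGenes - length(special)
  if (nRegular < 1L)
    stop("nGenes too small for the ", length(special),
         " planted ligand/receptor/decoy genes")
  genes <- c(sprintf("gene%04d", seq_len(nRegular)), special)
  G <- length(genes)
  base <- rlnorm(G, spec@baselineMeanlog, spec@baselineSdlog)
  names(base) <- genes
  base[decoys] <- 1.0
  base[intersect(rec, genes)] <- 0.5
  ctFac <- matrix(rlnorm(G * length(cts), 0, spec@cellTypeSdlog), G,
                  length(cts), dimnames = list(genes, cts))
  # constitutive producers: cytokine i produced by cell type (i mod T)
  producers <- data.frame(cytokine = cyts,
                          cell_type = cts[(seq_along(cyts) - 1L) %%
                                          length(cts) + 1L],
                          stringsAsFactors = FALSE)
  for (i in seq_along(cyts)) {
    lgenes <- lig[[i]]
    base[lgenes] <- 1
    ctFac[lgenes, ] <- 0.02
    ctFac[lgenes, producers$cell_type[i]] <- 1.5
  }
  ctFac[intersect(rec, genes), ] <- 1
  ctFac[decoys, ] <- 1
  # planted modules drawn from detectably expressed regular genes
  eligible <- setdiff(genes[base >= 0.25], special)
  modules <- list()
  if (spec@moduleSize > 0 && spec@moduleLog2Fc != 0)
    for (ct in cts) for (cyt in cyts)
      modules[[paste(ct, cyt, sep = "\r")]] <-
        sample(eligible, spec@moduleSize)
  repFac <- array(rlnorm(length(conds) * spec@nReplicates * G, 0,
                         spec@repEffectSd),
                  dim = c(G, spec@nReplicates, length(conds)),
                  dimnames = list(genes, NULL, conds))
  blocks <- list(); metas <- list(); responding <- list()
  cellCounter <- 0L
  for (ct in cts) for (cond in conds) {
    n <- spec@cellsPerCondition
    repIds <- rep(seq_len(spec@nReplicates), length.out = n)
    libFac <- rlnorm(n, 0, spec@libSizeSd)
    mu0 <- base * ctFac[, ct]
    mu <- matrix(mu0, G, n, dimnames = list(genes, NULL))
    key <- paste(ct, cond, sep = "\r")
    respond <- rep(FALSE, n)
    if (cond != .PBS && !is.null(modules[[key]])) {
      respond <- seq_len(n) %in%
        sample(n, round(spec@respondingFraction * n))
      mu[modules[[key]], respond] <-
        mu[modules[[key]], respond] * 2^spec@moduleLog2Fc
    }
    mu <- mu * repFac[, repIds, cond]
    mu <- sweep(mu, 2, libFac, `*`)
    counts <- matrix(rnbinom(G * n, mu = mu, size = 1 / spec@dispersion),
                     G, n)
    ids <- sprintf("cell%06d", cellCounter + seq_len(n))
    cellCounter <- cellCounter + n
    dimnames(counts) <- list(genes, ids)
    blocks[[key]] <- counts
    metas[[key]] <- data.frame(cell = ids, cell_type = ct,
                               condition = cond,
                               replicate = paste0("m", repIds),
                               stringsAsFactors = FALSE)
    if (cond != .PBS)
      responding[[key]] <- data.frame(cell = ids, cell_type = ct,
                                      cytokine = cond,
                                      responding = respond,
                                      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)
  comp <- CytokineCompendium(as(counts, "CsparseMatrix"),
                             meta$cell_type, meta$condition,
                             meta$replicate)
  degs <- do.call(rbind, lapply(names(modules), function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    data.frame(cell_type = parts[1L], cytokine = parts[2L],
               gene = modules[[key]], log2fc = spec@moduleLog2Fc,
               stringsAsFactors = FALSE)
  }))
  # expected normalized-log profiles (library factor integrates out)
  profiles <- lapply(stats::setNames(cts, cts), function(ct) {
    m0 <- base * ctFac[, ct]
    ctrl <- log1p(1e4 * m0 / sum(m0))
    treat <- lapply(stats::setNames(cyts, cyts), function(cyt) {
      m1 <- m0
      key <- paste(ct, cyt, sep = "\r")
      if (!is.null(modules[[key]]))
        m1[modules[[key]]] <- m1[modules[[key]]] *
          (1 + spec@respondingFraction * (2^spec@moduleLog2Fc - 1))
      log1p(1e4 * m1 / sum(m1))
    })
    list(control = ctrl, treated = treat)
  })
  list(compendium = comp,
       truth = list(degs = degs,
                    responding = do.call(rbind, responding),
                    producers = producers, profiles = profiles,
                    modules = modules, spec = spec,
                    seed = as.integer(seed)))
}

#' Generate a user query around planted truth profiles
#'
#' Draws pseudo-cells around the planted post-treatment and control mean
#' profiles of one (cytokine, cell type) with Gaussian noise in
#' normalized-log space (clamped at zero). With \code{noiseSd = 0} the
#' query differential equals the planted differential exactly.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{generateCompendium}}.
#' @param cytokine,cellType the planted combination to emulate.
#' @param noiseSd per-gene Gaussian noise sd (default 0.2).
#' @param nCells pseudo-cells per matrix (default 50).
#' @param seed sampling seed.
#' @return list with normalized genes x cells matrices \code{condition}
#'   and \code{control}.
#' @export
generateQuery <- function(truth, cytokine, cellType, noiseSd = 0.2,
                          nCells = 50, seed = 1) {
  if (!cellType %in% names(truth$profiles))
    stop("unknown cell type: ", cellType)
  prof <- truth$profiles[[cellType]]
  if (!cytokine %in% names(prof$treated))
    stop("unknown cytokine: ", cytokine)
  .withSeed(seed, {
    G <- length(prof$control)
    noise <- function(mu) {
      m <- matrix(rnorm(G * nCells, 0, noiseSd), G, nCells) + mu
      m <- pmax(m, 0)
      dimnames(m) <- list(names(prof$control),
                          paste0("q", seq_len(nCells)))
      m
    }
    list(condition = noise(prof$treated[[cytokine]]),
         control = noise(prof$control))
  })
}
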