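# Polarization states: subclustering, hypergeometric calling, similarity
# and naming.

test_that("subclustering separates planted blobs and is deterministic", {
  set.seed(31)
  nGenes <- 20
  blob <- function(center, n) matrix(rnorm(nGenes * n, center, 0.05),
                                     nGenes, n)
  A <- cbind(blob(0, 30), blob(5, 30))
  dimnames(A) <- list(sprintf("g%02d", 1:nGenes), sprintf("c%02d", 1:60))
  comp <- rawValueCompendium(A, rep("T", 60),
                             rep(c("X", "PBS"), 30), rep("m1", 60))
  lab <- subcluster(comp, nPcs = 5, seed = 2)
  expect_identical(length(unique(lab)), 2L)
  expect_identical(length(unique(lab[1:30])), 1L)
  expect_identical(length(unique(lab[31:60])), 1L)
  expect_identical(lab, subcluster(comp, nPcs = 5, seed = 2))
  # identical cells collapse to one cluster
  B <- matrix(1, nGenes, 25,
              dimnames = list(rownames(A), sprintf("d%02d", 1:25)))
  compB <- rawValueCompendium(B, rep("T", 25), rep("PBS", 25),
                              rep("m1", 25))
  expect_identical(length(unique(subcluster(compB, nPcs = 3))), 1L)
  expect_error(subcluster(compB, nPcs = 30), "more cells")
})

test_that("state calling matches the hypergeometric oracle and the FDR
           gate", {
  # cluster of 10 holding 8 cells of a cytokine that owns 20 of 100 cells
  labels <- stats::setNames(rep(2L, 100), sprintf("c%03d", 1:100))
  labels[1:10] <- 1L
  cond <- rep("PBS", 100)
  cond[c(1:8, 89:100)] <- "X"  # 8 in the cluster + 12 outside = 20 total
  states <- callStates(labels, cond, cellType = "T")
  expect_length(states, 1L)
  drv <- states[[1]]@drivers
  expect_identical(drv$cytokine[1], "X")
  expect_equal(drv$p[1], oracleHyperP(8, 100, 20, 10), tolerance = 1e-12)
  expect_equal(drv$p[1],
               phyper(7, 20, 80, 10, lower.tail = FALSE),
               tolerance = 1e-15)
  # background-rate composition is not called
  set.seed(5)
  cond2 <- sample(rep(c("X", "PBS"), 50))
  expect_length(callStates(labels, cond2, cellType = "T"), 0L)
  # a driver at fdr above alpha is not called
  expect_length(callStates(labels, cond, cellType = "T", alpha = 1e-9),
                0L)
})

test_that("a planted polarized subpopulation is called with its driver", {
  spec <- syntheticSpec(cellTypes = "NK", cytokines = c("X", "Y"),
                       cellsPerCondition = 90, nGenes = 300,
                       moduleSize = 30, moduleLog2Fc = 2,
                       respondingFraction = 0.8, seed = 17)
  sim <- generateCompendium(spec)
  comp <- suppressMessages(normalizeLog(sim$compendium))
  states <- suppressWarnings(
    callPolarizationStates(comp, "NK", abbrev = "NK", seed = 4))
  expect_gte(length(states), 1L)
  topDrivers <- vapply(states, function(s) s@drivers$cytokine[1], "")
  expect_true(all(topDrivers %in% c("X", "Y")))
  expect_true(all(vapply(states, function(s) s@drivers$fdr[1], 0) < 0.01))
  # null data yield no states (whether or not a stray gene clears the
  # discrimination threshold by chance)
  nullspec <- syntheticSpec(cellTypes = "NK", cytokines = "X",
                            cellsPerCondition = 50, nGenes = 150,
                            moduleSize = 0, seed = 23)
  nsim <- generateCompendium(nullspec)
  ncomp <- suppressMessages(normalizeLog(nsim$compendium))
  ns <- suppressWarnings(callPolarizationStates(ncomp, "NK"))
  expect_length(ns, 0L)
})

test_that("state markers recover planted overexpression", {
  set.seed(12)
  nGenes <- 40; n <- 60
  counts <- matrix(rpois(nGenes * n, 5), nGenes, n,
                   dimnames = list(sprintf("g%02d", 1:nGenes),
                                   sprintf("c%02d", 1:n)))
  stateCells <- sprintf("c%02d", 1:20)
  counts[c("g01", "g02"), 1:20] <- rpois(40, 20)  # 4-fold in the state
  comp <- normalizeLog(CytokineCompendium(
    counts, rep("T", n), rep(c("X", "PBS"), each = n / 2),
    rep("m1", n)))
  st <- new("PolarizationState", id = "T-a", cellType = "T",
            cells = stateCells, drivers = data.frame(),
            markers = data.frame(), profile = numeric())
  st <- stateMarkers(st, comp)
  expect_true(all(c("g01", "g02") %in% st@markers$gene[1:2]))
  expect_true(all(diff(st@markers$log2fc) <= 0))  # sorted descending
  allCells <- new("PolarizationState", id = "", cellType = "T",
                  cells = colnames(comp), drivers = data.frame(),
                  markers = data.frame(), profile = numeric())
  expect_error(stateMarkers(allCells, comp), "every cell")
})

test_that("Jaccard and uniqueness follow the set arithmetic", {
  expect_equal(jaccardIndex(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccardIndex(character(), character()), 1)
  expect_equal(jaccardIndex("a", "b"), 0)
})

test_that("state similarity produces symmetric matrices, uniqueness and a
           dendrogram", {
  # engineered profiles: states up-sets {a,b,c} and {b,c,d} over PBS
  genes <- c("a", "b", "c", "d", "e", "f")
  mkCells <- function(prefix, up, n = 4) {
    m <- matrix(0.1, length(genes), n,
                dimnames = list(genes, paste0(prefix, 1:n)))
    m[up, ] <- 2
    m
  }
  vals <- cbind(mkCells("s1_", c("a", "b", "c")),
                mkCells("s2_", c("b", "c", "d")),
                mkCells("p", character()))
  comp <- rawValueCompendium(vals, rep("T", 12),
                             c(rep("X", 4), rep("Y", 4), rep("PBS", 4)),
                             rep("m1", 12))
  mkState <- function(id, cells) new("PolarizationState", id = id,
                                     cellType = "T", cells = cells,
                                     drivers = data.frame(),
                                     markers = data.frame(),
                                     profile = numeric())
  states <- list(mkState("T-e", paste0("s1_", 1:4)),
                 mkState("T-f", paste0("s2_", 1:4)))
  sim <- stateSimilarity(states, comp)
  expect_equal(sim$jaccardUp["T-e", "T-f"], 0.5)
  expect_equal(sim$jaccardUp, t(sim$jaccardUp))
  expect_equal(unname(diag(sim$jaccardUp)), c(1, 1))
  expect_true(all(sim$jaccardDown >= 0 & sim$jaccardDown <= 1))
  expect_true(all(sim$pearson >= -1 - 1e-12 & sim$pearson <= 1 + 1e-12))
  # mutual Jaccard 0.5 (no down-genes) -> uniqueness 2 each
  expect_equal(unname(sim$uniqueness), c(2, 2))
  # identical states: Pearson and Jaccard 1
  sim2 <- stateSimilarity(list(states[[1]], states[[1]]), comp)
  expect_equal(sim2$pearson[1, 2], 1, tolerance = 1e-12)
  expect_equal(sim2$jaccardUp[1, 2], 1)
  # duplicate states decrease uniqueness
  sim3 <- stateSimilarity(c(states, states[1]), comp)
  expect_lt(sim3$uniqueness[["T-e"]], sim$uniqueness[["T-e"]])
  expect_error(stateSimilarity(states[1], comp), "at least 2")
  # dendrogram exports as Newick
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeStateTree(sim, nwk)
  expect_match(readLines(nwk), "T-e")
})

test_that("reserved letters a-d map to the canonical driver classes", {
  mk <- function(driver, n) new("PolarizationState", id = "",
                                cellType = "NK",
                                cells = sprintf("%s%02d", driver, 1:n),
                                drivers = data.frame(
                                  cytokine = driver, k = n, p = 1e-6,
                                  fdr = 1e-5,
                                  stringsAsFactors = FALSE),
                                markers = data.frame(),
                                profile = numeric())
  states <- list(mk("IFNb", 30), mk("IFNg", 20), mk("IL-1b", 25),
                 mk("TNF", 15), mk("IL-18", 40), mk("IL-2", 10))
  named <- nameStates(states, "NK")
  ids <- vapply(named, function(s) s@id, "")
  expect_identical(ids[1:4], c("NK-a", "NK-b", "NK-c", "NK-d"))
  # remaining states take e, f, ... by decreasing size
  expect_identical(ids[5], "NK-e")  # IL-18, 40 cells
  expect_identical(ids[6], "NK-f")  # IL-2, 10 cells
})

test_that("discriminating genes honour the threshold and exclusions", {
  genes <- c("big", "mid", "Fos", "Rps9")
  mk <- function(v) matrix(rep(v, 5), 4, 5, dimnames = list(genes, NULL))
  vals <- cbind(mk(log1p(c(3, 0.9, 3, 3))), mk(log1p(c(0.2, 0.2, 0.2, 0.2))))
  colnames(vals) <- sprintf("c%02d", 1:10)
  comp <- rawValueCompendium(vals, rep("T", 10),
                             rep(c("X", "PBS"), each = 5),
                             rep("m1", 10))
  got <- suppressMessages(discriminatingGenes(comp, "T"))
  # |log2FC| of "mid" = log2(1.9/1.2) ~ 0.66 < 0.75; Fos/Rps9 excluded
  expect_identical(got, "big")
  expect_error(discriminatingGenes(comp, "T", fcThreshold = 5),
               "lower threshold")
})
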