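# Enrichment of user data against a synthetic reference.

# one shared small reference for the whole file
refSpec <- syntheticSpec(cellTypes = c("NK", "B"),
                         cytokines = c("IFNb", "TNF", "IL-18"),
                         cellsPerCondition = 60, nGenes = 300, seed = 33)
refSim <- generateCompendium(refSpec)
refComp <- suppressMessages(normalizeLog(refSim$compendium))

test_that("a reference cytokine's own up-signature tops the gene-set
           enrichment", {
  tg <- refSim$truth$degs
  sig <- tg$gene[tg$cell_type == "NK" & tg$cytokine == "IFNb"]
  res <- enrichGeneSet(sig, refComp, "NK")
  expect_identical(res$cytokine[1], "IFNb")
  expect_lt(res$fdr[1], 0.05)
  expect_identical(res$direction[1], "condition")
  expect_error(enrichGeneSet(character(), refComp, "NK"), "empty")
  expect_error(enrichGeneSet(sig, refComp, "Mast"), "unknown cell type")
})

test_that("hypergeometric mode reduces to the closed-form overlap test", {
  # engineered reference: 5 planted genes with complete treated/control
  # separation plus a high-variance housekeeping gene that absorbs the
  # library-size shift, so exactly the planted genes are significant
  set.seed(44)
  genes <- c(sprintf("g%02d", 1:10), "Actb")
  n <- 20
  counts <- matrix(rpois(10 * 2 * n, 8), 10, 2 * n)
  counts <- rbind(counts, rnbinom(2 * n, mu = 10000, size = 2))
  dimnames(counts) <- list(genes, sprintf("c%02d", 1:(2 * n)))
  counts[1:5, 1:n] <- counts[1:5, 1:n] + 80
  comp <- normalizeLog(CytokineCompendium(
    counts, rep("T", 2 * n), rep(c("X", "PBS"), each = n),
    rep("m1", 2 * n)))
  res <- enrichGeneSet(genes[1:5], comp, "T", mode = "hypergeometric")
  # the signature holds the 5 planted genes plus the housekeeping gene,
  # whose relative abundance drops when the planted genes rise
  expect_identical(res$signature_size, 6L)
  expect_equal(res$overlap, 5L)
  # universe 11, signature 6, query 5, overlap 5 -> closed form
  expect_equal(res$p, 6 / choose(11, 5), tolerance = 1e-12)
  expect_equal(res$p, oracleHyperP(5, 11, 6, 5), tolerance = 1e-12)
})

test_that("transcriptome projection recovers the planted cytokine and is
           exactly antisymmetric", {
  q <- generateQuery(refSim$truth, "TNF", "NK", noiseSd = 0.2, seed = 5)
  res <- enrichTranscriptome(q$condition, q$control, refComp, "NK",
                             userNormalized = TRUE)
  expect_identical(res$cytokine[1], "TNF")
  expect_lt(res$fdr[res$cytokine == "TNF"], 0.05)
  # swapping condition and control flips every effect size exactly
  swapped <- enrichTranscriptome(q$control, q$condition, refComp, "NK",
                                 userNormalized = TRUE)
  m <- merge(res, swapped, by = "cytokine")
  expect_equal(m$effect_size.x, -m$effect_size.y, tolerance = 1e-12)
  expect_identical(swapped$direction[swapped$cytokine == "TNF"],
                   "control")
  # projection scores are invariant to positive rescaling of the user
  # differential vector
  qn <- generateQuery(refSim$truth, "TNF", "NK", noiseSd = 0, seed = 5)
  base <- enrichTranscriptome(qn$condition, qn$control, refComp, "NK",
                              userNormalized = TRUE)
  doubled <- enrichTranscriptome(
    qn$control + 2 * (qn$condition - qn$control), qn$control, refComp,
    "NK", userNormalized = TRUE)
  mm <- merge(base, doubled, by = "cytokine")
  expect_equal(mm$effect_size.x, mm$effect_size.y, tolerance = 1e-10)
})

test_that("a null query produces zero effect sizes and no discoveries", {
  q <- generateQuery(refSim$truth, "TNF", "NK", noiseSd = 0, seed = 6)
  res <- enrichTranscriptome(q$condition, q$condition, refComp, "NK",
                             userNormalized = TRUE)
  expect_true(all(res$effect_size == 0))
  expect_true(all(res$p == 1))
})

test_that("the expression floor and shared-gene guard are enforced", {
  q <- generateQuery(refSim$truth, "IFNb", "NK", noiseSd = 0, seed = 7)
  expect_error(enrichTranscriptome(q$condition, q$control, refComp, "NK",
                                   minExpr = 1e9, userNormalized = TRUE),
               "fewer than 10 shared genes")
  res <- enrichTranscriptome(q$condition, q$control, refComp, "NK",
                             userNormalized = TRUE,
                             catalog = defaultCatalog())
  expect_true(is.logical(res$receptor_expressed))
  # receptor genes are planted as expressed in the generator
  expect_true(res$receptor_expressed[res$cytokine == "IFNb"])
})

test_that("polarization enrichment max-normalizes and reports unpolarized
           inputs as all zero", {
  states <- suppressWarnings(
    callPolarizationStates(refComp, "NK", abbrev = "NK", seed = 2))
  expect_gte(length(states), 2L)
  q <- generateQuery(refSim$truth, "IL-18", "NK", noiseSd = 0.1,
                     seed = 8)
  res <- enrichPolarization(q$condition, q$control, states, refComp,
                            "NK", userNormalized = TRUE)
  expect_true(attr(res, "polarized"))
  expect_equal(max(res$normalized_es), 1)
  expect_true(all(res$normalized_es >= 0 & res$normalized_es <= 1))
  # the IL-18-driven state carries the maximal score
  top <- res$state[which.max(res$normalized_es)]
  drivers <- vapply(states, function(s) s@drivers$cytokine[1], "")
  expect_identical(unname(drivers[top]), "IL-18")
  # a null query is unpolarized: every score 0
  null <- enrichPolarization(q$control, q$control, states, refComp,
                             "NK", userNormalized = TRUE)
  expect_false(attr(null, "polarized"))
  expect_true(all(null$normalized_es == 0))
  empty <- enrichPolarization(q$condition, q$control, list(), refComp,
                              "NK", userNormalized = TRUE)
  expect_identical(nrow(empty), 0L)
  expect_false(attr(empty, "polarized"))
})

test_that("communication networks apply the FDR, production and receptor
           thresholds", {
  enr <- list(
    NK = data.frame(cytokine = c("IFNb", "TNF", "IL-18"),
                    effect_size = c(0.4, 0.3, -0.5),
                    p = c(1e-5, 0.004, 1e-6),
                    fdr = c(3e-5, 0.02, 3e-6),
                    direction = c("condition", "condition", "control"),
                    receptor_expressed = c(TRUE, TRUE, FALSE)))
  userExpr <- list(
    NK = rbind(Il18 = rep(0.5, 4), Il12a = rep(0.3, 4),
               Il12b = rep(0.02, 4), Tnf = rep(0.04, 4)),
    B = rbind(Il18 = rep(0.01, 4), Il12a = rep(0.02, 4),
              Il12b = rep(0.01, 4), Tnf = rep(0.3, 4)))
  net <- communicationNetwork(enr, userExpr, defaultCatalog())
  # responders: only IFNb (fdr 3e-5 < 0.01 and positive effect);
  # TNF fails the FDR gate at 0.02, IL-18 is control-enriched
  expect_identical(net$responders$cytokine, "IFNb")
  # producers: NK expresses IL-18 and one IL-12 subunit (asterisk), B
  # expresses TNF
  pk <- paste(net$producers$cell_type, net$producers$cytokine)
  expect_true(all(c("NK IL-18", "NK IL-12", "B TNF") %in% pk))
  expect_false("NK TNF" %in% pk)  # 0.04 below the 0.1 production gate
  expect_true(net$producers$multimeric[net$producers$cytokine == "IL-12"][1])
})
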