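# Differential expression, signature cascade, magnitude map, concordance,
# gene-set scoring and secondary responses.

test_that("differentialExpression uses the exact kernel and the stated
           fold-change convention", {
  # 2v2 cells, one informative gene -> exact enumeration p
  counts <- cbind(t1 = c(10, 100), t2 = c(20, 100),
                  c1 = c(300, 100), c2 = c(400, 100))
  rownames(counts) <- c("hit", "flat")
  comp <- normalizeLog(CytokineCompendium(counts, rep("T", 4),
                                          c("X", "X", "PBS", "PBS"),
                                          c("m1", "m2", "m1", "m2")))
  de <- differentialExpression(comp, "T", "X")
  expect_equal(de$p[de$gene == "hit"], 1 / 3, tolerance = 1e-12)
  expect_true(de$log2fc[de$gene == "hit"] < 0)
  # de-logged mean 3 vs 1 with pseudocount 1 -> log2(4/2) = 1
  expect_equal(log2FoldChange(log1p(c(3, 3)), log1p(c(1, 1))), 1)
  # identical groups -> p = 1, log2fc = 0
  expect_equal(log2FoldChange(log1p(c(2, 4)), log1p(c(4, 2))), 0)
  expect_error(differentialExpression(comp, "T", "missing"),
               ">= 2 cells")
})

test_that("the signature cascade filters in order and excludes category
           genes", {
  set.seed(42)
  nGenes <- 80; half <- 60
  genes <- c(sprintf("g%03d", 1:77), "Rps5", "mt-Nd1", "Gm10099")
  cond <- rep(c("X", "PBS"), each = half)
  reps <- rep(rep(c("m1", "m2", "m3"), each = half / 3), 2)
  counts <- matrix(rpois(nGenes * 2 * half, 6), nGenes, 2 * half,
                   dimnames = list(genes, sprintf("c%03d", 1:(2 * half))))
  # plant strong signal in 5 regular genes and in the category decoys
  for (g in c("g001", "g002", "g003", "g004", "g005",
              "Rps5", "mt-Nd1", "Gm10099"))
    counts[g, cond == "X"] <- rpois(half, 30)
  # g006: strong effect in a rare gene (low detection in treated cells)
  counts["g006", ] <- 0
  counts["g006", which(cond == "X")[1:5]] <- 40
  comp <- normalizeLog(CytokineCompendium(counts, rep("T", 2 * half),
                                          cond, reps))
  sig <- suppressMessages(buildSignature(comp, "T", "X"))
  called <- signatureGenes(sig)
  expect_true(all(c("g001", "g002", "g003", "g004", "g005") %in% called))
  # category exclusions beat numeric filters
  expect_false(any(c("Rps5", "mt-Nd1", "Gm10099") %in% called))
  # pct gate: g006 is expressed in <10% of treated cells
  expect_false("g006" %in% called)
  expect_true(all(signatureTable(sig)$fdr < 0.05))
  expect_true(all(abs(signatureTable(sig)$log2fc) > 0.25))
  expect_true(all(signatureTable(sig)$n_replicates_passing >= 2))
  # monotonicity: raising any threshold never adds entries
  tighter <- suppressMessages(
    buildSignature(comp, "T", "X", minAbsLog2Fc = 1.0))
  expect_true(all(signatureGenes(tighter) %in% called))
  stricter <- suppressMessages(
    buildSignature(comp, "T", "X", fdrMax = 0.001, minPct = 0.5,
                   minReplicates = 3))
  expect_true(all(signatureGenes(stricter) %in% called))
})

test_that("replicate consistency gate drops single-mouse effects", {
  set.seed(8)
  half <- 60
  genes <- sprintf("g%02d", 1:40)
  cond <- rep(c("X", "PBS"), each = half)
  reps <- rep(rep(c("m1", "m2", "m3"), each = half / 3), 2)
  counts <- matrix(rpois(40 * 2 * half, 6), 40, 2 * half,
                   dimnames = list(genes, sprintf("c%03d", 1:(2 * half))))
  # g01 responds in all mice, g02 only in mouse 1
  counts["g01", cond == "X"] <- rpois(half, 30)
  oneMouse <- cond == "X" & reps == "m1"
  counts["g02", oneMouse] <- rpois(sum(oneMouse), 60)
  comp <- normalizeLog(CytokineCompendium(counts, rep("T", 2 * half),
                                          cond, reps))
  sig <- suppressMessages(buildSignature(comp, "T", "X"))
  expect_true("g01" %in% signatureGenes(sig))
  expect_false("g02" %in% signatureGenes(sig))
})

test_that("winsorized scaling matches the hand computation on 1..20", {
  d <- 1:20
  p95 <- quantile(d, 0.95, type = 7, names = FALSE)
  expect_equal(p95, 19.05)
  got <- winsorizedScale(d)
  expect_equal(got, pmin(d, 19.05) / 19.05 * 100, tolerance = 1e-12)
  expect_equal(max(got), 100)
  expect_true(all(got >= 0 & got <= 100))
  expect_equal(winsorizedScale(rep(0, 5)), rep(0, 5))
})

test_that("responseMagnitude omits sparse combos and bounds values", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:30)
  nA <- 12; nB <- 3; nP <- 12  # cytokine B has too few cells
  counts <- matrix(rpois(30 * (nA + nB + nP), 5), 30,
                   dimnames = list(genes,
                                   sprintf("c%02d", 1:(nA + nB + nP))))
  counts[1:5, 1:nA] <- counts[1:5, 1:nA] + 25
  comp <- normalizeLog(CytokineCompendium(
    counts, rep("T", nA + nB + nP),
    c(rep("A", nA), rep("B", nB), rep("PBS", nP)),
    rep("m1", nA + nB + nP)))
  mm <- responseMagnitude(comp, "T", seed = 9)
  expect_setequal(mm$cytokine, "A")      # B omitted: < 5 cells
  expect_true(all(mm$magnitude >= 0 & mm$magnitude <= 100))
  expect_equal(max(mm$magnitude), 100)
  # determinism under the seed
  mm2 <- responseMagnitude(comp, "T", seed = 9)
  expect_identical(mm, mm2)
  expect_error(responseMagnitude(comp, "NK"), "unknown cell type")
})

test_that("replicate concordance is Pearson on per-mouse differential
           vectors", {
  # hand-built expression: replicate vectors (1,2,3) and (3,2,1)
  vals <- cbind(t_m1 = c(1, 2, 3), t_m2 = c(3, 2, 1),
                p_m1 = c(0, 0, 0), p_m2 = c(0, 0, 0))
  rownames(vals) <- c("a", "b", "c")
  comp <- rawValueCompendium(vals, rep("T", 4),
                             c("X", "X", "PBS", "PBS"),
                             c("m1", "m2", "m1", "m2"))
  cc <- replicateConcordance(comp, "T", "X", c("a", "b", "c"))
  expect_equal(cc["m1", "m2"], -1, tolerance = 1e-12)
  expect_equal(diag(cc), c(m1 = 1, m2 = 1))
  # identical replicates correlate exactly
  vals2 <- vals; vals2[, "t_m2"] <- vals2[, "t_m1"]
  comp2 <- rawValueCompendium(vals2, rep("T", 4),
                              c("X", "X", "PBS", "PBS"),
                              c("m1", "m2", "m1", "m2"))
  cc2 <- replicateConcordance(comp2, "T", "X", c("a", "b", "c"))
  expect_equal(cc2["m1", "m2"], 1, tolerance = 1e-12)
  # degenerate inputs
  expect_warning(
    few <- replicateConcordance(comp, "T", "X", "a"), "fewer than 2")
  expect_true(all(is.na(few)))
  one <- rawValueCompendium(vals[, c(1, 3), drop = FALSE], rep("T", 2),
                            c("X", "PBS"), c("m1", "m1"))
  expect_warning(
    empty <- replicateConcordance(one, "T", "X", c("a", "b", "c")),
    "fewer than 2 replicates")
  expect_identical(dim(empty), c(0L, 0L))
})

test_that("gene-set scores sum expression with a contribution-0
           convention for absent genes", {
  vals <- cbind(c1 = c(a = 1, b = 2), c2 = c(a = 0, b = 0))
  comp <- rawValueCompendium(vals, c("T", "T"), c("PBS", "PBS"),
                             c("m1", "m1"))
  expect_equal(unname(geneSetScore(comp, c("a", "b"))), c(3, 0))
  expect_warning(s <- geneSetScore(comp, c("a", "b", "zz")), "absent")
  expect_equal(unname(s), c(3, 0))
  expect_error(geneSetScore(comp, character()), "empty")
})

test_that("access AUC separates treated from control scores", {
  expect_equal(accessAuc(c(2, 3), c(1, 2.5)), 0.75)
  expect_equal(accessAuc(c(10, 11), c(1, 2)), 1)
  expect_error(accessAuc(numeric(), 1), "non-empty")
})

test_that("secondary-response scores detect a doubled signature and stay
           flat for PBS-like treatments", {
  set.seed(15)
  n <- 20  # cells per condition
  genes <- sprintf("g%02d", 1:12)
  conds <- c(rep("IFNg", n), rep("Mimic", n), rep("Inert", n),
             rep("PBS", n))
  reps <- rep("m1", 4 * n)
  counts <- matrix(rpois(12 * 4 * n, 10), 12, 4 * n,
                   dimnames = list(genes, sprintf("c%03d", 1:(4 * n))))
  # donor cytokine drives genes g01-g04 hard (strict signature)
  for (g in c("g01", "g02", "g03", "g04")) {
    counts[g, conds == "IFNg"] <- rpois(n, 120)
    counts[g, conds == "Mimic"] <- rpois(n, 60)  # half the donor effect
  }
  comp <- normalizeLog(CytokineCompendium(counts, rep("T", 4 * n),
                                          conds, reps))
  res <- suppressMessages(secondaryResponseScore(comp, "IFNg"))
  mimic <- res[res$cytokine == "Mimic", ]
  inert <- res[res$cytokine == "Inert", ]
  expect_gt(mimic$score_log2fc, 0.5)
  expect_lt(mimic$fdr, 0.05)
  expect_lt(abs(inert$score_log2fc), 0.3)
  expect_gt(inert$fdr, 0.05)
  expect_gt(mimic$n_signature_genes, 0)
})
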