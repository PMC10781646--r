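# Shared fixtures and independent oracles built in code.

suppressPackageStartupMessages({
  library(Matrix)
  library(SummarizedExperiment)
})

# expression matrix of a compendium (assay 1)
compExpr <- function(x) SummarizedExperiment::assay(x, 1L)

# independent oracle: two-sided rank-sum p by brute-force enumeration of
# all C(n1+n2, n1) label assignments (combn over indices, not the DP used
# in the package)
oracleRankSumP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  sets <- utils::combn(n1 + n2, n1)
  ws <- apply(sets, 2, function(idx) sum(r[idx]))
  pl <- mean(ws <= w + 1e-9)
  pu <- mean(ws >= w - 1e-9)
  min(1, 2 * min(pl, pu))
}

# independent oracle: upper-tail hypergeometric by explicit summation
oracleHyperP <- function(k, N, K, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# independent oracle: AUC by explicit pair counting
oracleAuc <- function(x, y) {
  s <- 0
  for (xi in x) for (yi in y)
    s <- s + (xi > yi) + 0.5 * (xi == yi)
  s / (length(x) * length(y))
}

# a small deterministic raw-count compendium: 6 genes x 9 cells, one cell
# type, one cytokine + PBS, 3 replicates on each side
toyCompendium <- function() {
  genes <- c("Cd19", "Actb", "Rps5", "mt-Nd1", "Gm10099", "Il6")
  counts <- matrix(0L, 6, 9, dimnames = list(
    genes, paste0("c", 1:9)))
  set.seed(11)
  counts[] <- rpois(length(counts), 5)
  CytokineCompendium(counts,
                     cellType = rep("B", 9),
                     condition = rep(c("IL-6", "PBS", "PBS"), each = 3),
                     replicate = rep(c("m1", "m2", "m3"), 3))
}

# a compendium wrapping explicit expression values without renormalizing
# (for functions that read expression directly); flagged non-normalized
rawValueCompendium <- function(values, cellType, condition, replicate) {
  CytokineCompendium(values, cellType, condition, replicate,
                     normalized = FALSE)
}

# small planted-effect compendium builder: nGenes Poisson background plus
# `planted` genes multiplied by `fold` in treated cells of one cell type
plantedCompendium <- function(nGenes = 60, nCells = 40, planted = 1:5,
                              fold = 6, seed = 5) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(nGenes))
  cond <- rep(c("X", "PBS"), each = nCells / 2)
  reps <- rep(rep(c("m1", "m2", "m3"), length.out = nCells / 2), 2)
  counts <- matrix(rpois(nGenes * nCells, 4), nGenes, nCells,
                   dimnames = list(genes,
                                   sprintf("cell%03d", seq_len(nCells))))
  counts[planted, cond == "X"] <-
    rpois(length(planted) * sum(cond == "X"), 4 * fold)
  CytokineCompendium(counts, rep("T", nCells), cond, reps)
}
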