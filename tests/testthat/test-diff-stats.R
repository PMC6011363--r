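nbMatrix <- function(n, mu, phi, reps = 3, seed = 1) {
  set.seed(seed)
  cm <- sapply(seq_len(2 * reps), function(i) {
    if (phi == 0) rpois(n, mu) else rnbinom(n, size = 1 / phi, mu = mu)
  })
  rownames(cm) <- paste0("f", seq_len(n))
  countMatrix(cm, condition = rep(c("A", "B"), each = reps),
              librarySize = rep(sum(mu), 2 * reps))
}

test_that("common-dispersion estimation brackets the simulated truth", {
  set.seed(2)
  mu <- exp(rnorm(2000, log(200), 1))
  poi <- nbMatrix(2000, mu, phi = 0, seed = 3)
  expect_lte(estimateCommonDispersion(poi), 0.02)
  nb <- nbMatrix(2000, mu, phi = 0.1, seed = 4)
  est <- estimateCommonDispersion(nb)
  expect_gte(est, 0.05); expect_lte(est, 0.2)
  # constant counts across replicates: zero variance, zero dispersion
  cmc <- matrix(50, nrow = 5, ncol = 4,
                dimnames = list(paste0("f", 1:5), NULL))
  sec <- countMatrix(cmc, condition = rep(c("A", "B"), each = 2),
                     librarySize = rep(1e5, 4))
  expect_equal(estimateCommonDispersion(sec), 0)
  # unreplicated design cannot estimate
  se1 <- countMatrix(cmc[, 1:2], condition = c("A", "B"),
                     librarySize = rep(1e5, 2))
  expect_error(estimateCommonDispersion(se1), "replicate")
})

test_that("dispersion estimate agrees with edgeR's qCML common dispersion within 2x", {
  set.seed(6)
  mu <- exp(rnorm(3000, log(300), 1))
  nb <- nbMatrix(3000, mu, phi = 0.1, seed = 7)
  est <- estimateCommonDispersion(nb)
  dge <- edgeR::DGEList(
    counts = SummarizedExperiment::assay(nb),
    group = SummarizedExperiment::colData(nb)$condition)
  ref <- edgeR::estimateCommonDisp(dge)$common.dispersion
  expect_gt(est / ref, 0.5)
  expect_lt(est / ref, 2)
})

test_that("the conditional exact test matches closed forms and is symmetric", {
  # equal pooled counts at equal libraries sit at the conditional mode
  expect_equal(nbExactTest(c(10, 12), c(12, 10), 0.1), 1)
  # Poisson two-sided conditional test: a=0, b=20 gives 2 * 0.5^20
  expect_equal(nbExactTest(0, 20, 0), 2 * 0.5^20, tolerance = 1e-12)
  # symmetry under group swap
  p1 <- nbExactTest(c(5, 9), c(20, 31), 0.1)
  p2 <- nbExactTest(c(20, 31), c(5, 9), 0.1)
  expect_equal(p1, p2, tolerance = 1e-12)
  # a common rescaling of every library leaves the test unchanged
  p3 <- nbExactTest(c(10, 10), c(40, 40), 0,
                    libSizesA = c(3, 3), libSizesB = c(3, 3))
  expect_equal(p3, nbExactTest(c(10, 10), c(40, 40), 0), tolerance = 1e-12)
  expect_error(nbExactTest(1, 2, -0.1), "dispersion")
})

test_that("exact test equals exhaustive enumeration for small totals", {
  set.seed(8)
  for (phi in c(0, 0.1)) {
    for (rep in 1:50) {
      t <- sample(1:50, 1)
      a <- sample(0:t, 1)
      nA <- sample(1:3, 1); nB <- sample(1:3, 1)
      got <- nbExactTest(rep(a / nA, nA), rep((t - a) / nB, nB), phi)
      want <- oracleNBExact(a, t - a, nA, nB, phi)
      expect_equal(got, want, tolerance = 1e-10,
                   info = sprintf("t=%d a=%d nA=%d nB=%d phi=%g",
                                  t, a, nA, nB, phi))
    }
  }
})

test_that("BH adjustment matches the hand-computed step-up and preserves order", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFDR(0.2), 0.2)
  expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
  # step-up on a case with distinct adjusted values, computed by hand:
  # sorted p = .01,.04,.9 -> m*p/j = .03,.06,.9 -> cummin from top = .03,.06,.9
  expect_equal(bhFDR(c(0.9, 0.01, 0.04)), c(0.9, 0.03, 0.06))
  set.seed(9)
  p <- runif(200)
  q <- bhFDR(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
})

test_that("significance calling applies the gene and NAT threshold rules", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    log2fc = c(1, log2(1.4), -2),
                    fdr = c(0.005, 1e-4, 0.02))
  gene <- callDifferential(res)
  expect_equal(gene$significant, c(TRUE, FALSE, FALSE))
  expect_equal(gene$direction, c("up", "up", "down"))
  nat <- callDifferential(res, fcGate = FALSE)
  expect_equal(nat$significant, c(TRUE, TRUE, FALSE))
})

test_that("hypergeometric enrichment equals tail summation and flags the planted term", {
  universe <- paste0("g", 1:20)
  res <- hypergeometricEnrichment(paste0("g", 1:5), universe,
                                  list(TM = paste0("g", 1:5)))
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p_value, 1 / 15504, tolerance = 1e-9)

  # k = 0 has upper-tail probability 1
  res0 <- hypergeometricEnrichment(paste0("g", 6:10), universe,
                                   list(TM = paste0("g", 1:5)))
  expect_equal(res0$p_value, 1)

  set.seed(11)
  for (rep in 1:30) {
    N <- sample(10:60, 1)
    uni <- paste0("x", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    term <- sample(uni, K)
    gset <- sample(uni, n)
    got <- hypergeometricEnrichment(gset, uni, list(tm = term))
    expect_equal(got$p_value,
                 oracleHyper(N, K, n, length(intersect(term, gset))),
                 tolerance = 1e-10)
  }
  expect_error(hypergeometricEnrichment("g1", character(0), list()),
               "universe")
})

test_that("differential-expression pipeline recovers strong planted effects", {
  set.seed(12)
  n <- 400
  mu <- exp(rnorm(n, log(300), 0.8))
  lfc <- numeric(n); lfc[1:40] <- sample(c(-2, 2), 40, TRUE)
  cm <- cbind(sapply(1:3, function(i) rnbinom(n, size = 10, mu = mu)),
              sapply(1:3, function(i) rnbinom(n, size = 10,
                                              mu = mu * 2^lfc)))
  rownames(cm) <- paste0("f", 1:n)
  se <- countMatrix(cm, condition = rep(c("A", "B"), each = 3),
                    librarySize = rep(sum(mu), 6))
  de <- nbDifferentialExpression(se)
  expect_gte(mean(de$significant[1:40]), 0.8)
  expect_lte(sum(de$significant[41:n]) / max(1, sum(de$significant)), 0.1)
  expect_equal(de$direction[1:40][lfc[1:40] > 0][1], "up")
})
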