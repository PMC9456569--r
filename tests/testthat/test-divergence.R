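test_that("divergence magnitude is |L_P| for informative genes", {
  resP <- makeResult(c("g1", "g2", "g3"), L = c(0, 2, -1.5))
  cls <- data.frame(gene_id = c("g1", "g2", "g3"),
                    informative_regulation = c(TRUE, TRUE, FALSE),
                    regulation = c("conserved", "all_cis", "all_trans"))
  d <- divergenceMagnitude(resP, cls)
  expect_equal(d$gene_id, c("g1", "g2"))   # g3 uninformative, dropped
  expect_equal(d$magnitude, c(0, 2))       # RR = 4 x SS  ->  |log2| = 2
  expect_equal(d$category, c("conserved", "all_cis"))
})

test_that("category comparisons detect shifts and respect identity", {
  set.seed(20)
  same <- abs(rnorm(60, 1, 0.3))
  d <- data.frame(gene_id = sprintf("g%d", 1:120),
                  magnitude = c(same, same),
                  category = rep(c("all_cis", "all_trans"), each = 60))
  cc <- compareCategories(d)
  # a category against an identical copy of itself: null center, p = 1
  expect_equal(cc$pairs$p, 1)
  expect_equal(cc$pairs$median_diff, 0)

  # a one-log2-unit median shift at n = 200/category is detected
  set.seed(21)
  d2 <- data.frame(
    gene_id = sprintf("g%d", 1:400),
    magnitude = c(abs(rnorm(200, 0.3, 0.3)), abs(rnorm(200, 1.3, 0.3))),
    category = rep(c("conserved", "cis_plus_trans"), each = 200))
  cc2 <- compareCategories(d2)
  expect_lt(cc2$pairs$padj, 1e-6)
  # pairs are ordered alphabetically: cis_plus_trans listed first
  expect_equal(cc2$pairs$category1, "cis_plus_trans")
  expect_gt(cc2$pairs$median_diff, 0)  # cis_plus_trans > conserved

  # null case: two samples from one distribution are rarely significant
  set.seed(22)
  hits <- vapply(1:20, function(i) {
    dn <- data.frame(gene_id = sprintf("g%d", 1:200),
                     magnitude = abs(rnorm(200, 1, 0.5)),
                     category = rep(c("a", "b"), each = 100))
    compareCategories(dn)$pairs$p < 0.05
  }, NA)
  expect_lte(sum(hits), 3)   # ~1 expected at the 5% level over 20 runs

  # small categories skipped with a warning; <2 usable categories errors
  d3 <- rbind(d2, data.frame(gene_id = "x", magnitude = 1,
                             category = "tiny"))
  expect_warning(compareCategories(d3), "tiny")
  expect_error(
    suppressWarnings(compareCategories(d3[c(1, 2, 401), ])),
    "at least two")
})

test_that("shifted-log VST stabilizes variance against the mean", {
  expect_equal(vstTransform(matrix(0), sizeFactors = 1)[1], 0)
  expect_equal(vstTransform(matrix(3), sizeFactors = 1)[1], 2)
  expect_error(vstTransform(matrix(-1), sizeFactors = 1), "non-negative")

  set.seed(23)
  mu <- rep(2^seq(4, 12, length.out = 40), each = 5)
  k <- matrix(rnbinom(length(mu) * 10, mu = mu, size = 20), ncol = 10)
  v <- vstTransform(k, sizeFactors = rep(1, 10))
  rawSlope <- coef(lm(apply(k, 1, var) ~ rowMeans(k)))[2]
  vstSlope <- coef(lm(apply(v, 1, var) ~ rowMeans(v)))[2]
  expect_lt(abs(vstSlope), abs(rawSlope))
})

test_that("PCA is deterministic, orthonormal and reconstructive", {
  set.seed(24)
  m <- matrix(rnorm(200 * 6, sd = 2), 200,
              dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:6)))
  # duplicated samples get identical scores
  m2 <- cbind(m, s7 = m[, 1])
  p <- runPCA(m2, nComponents = 3, nTopGenes = 100)
  expect_equal(p$scores["s1", ], p$scores["s7", ], tolerance = 1e-10)

  # full-rank reconstruction of the centred matrix
  pf <- runPCA(m, nComponents = 5, nTopGenes = 100)
  x <- m[pf$genes, ]
  x <- x - rowMeans(x)
  expect_equal(pf$scores %*% t(pf$loadings), t(x), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(pf$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)

  # variance explained: sorted, non-negative, sums to <= 1
  expect_true(all(diff(pf$varianceExplained) <= 1e-12))
  expect_lte(sum(pf$varianceExplained), 1 + 1e-12)

  expect_warning(runPCA(m[, 1:3], nComponents = 5), "reducing")
  expect_error(runPCA(m[, 1, drop = FALSE]), "two samples")
})

test_that("PC1 separates strongly shifted groups", {
  set.seed(25)
  base <- rnorm(300, 8, 1)
  shift <- c(rep(0, 240), rep(3, 60))
  mk <- function(off) matrix(rpois(300 * 3, 2^(base + off * shift)), 300)
  m <- vstTransform(cbind(mk(0), mk(1)), sizeFactors = rep(1, 6))
  p <- runPCA(m, nComponents = 2, nTopGenes = 200)
  g1 <- p$scores[1:3, 1]; g2 <- p$scores[4:6, 1]
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))
})

test_that("Spearman correlation handles ties exactly as average ranks", {
  up <- c(1, 2, 3, 4, 5)
  expect_equal(correlateExpressionPhenotype(up, up)$rho, 1)
  expect_equal(correlateExpressionPhenotype(up, rev(up))$rho, -1)

  # tied data, n = 5: rho must equal Pearson on hand-built average ranks
  x <- c(3, 1, 4, 1, 5)
  y <- c(2, 7, 1, 8, 2)
  bruteRank <- function(v) {  # average ranks, written out longhand
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, 0)
  }
  want <- cor(bruteRank(x), bruteRank(y))
  got <- correlateExpressionPhenotype(x, y)
  expect_equal(got$rho, want, tolerance = 1e-12)
  # exact permutation p: validate against direct enumeration of 5! orders
  perms <- asediverge:::.permutations(5)
  null <- apply(perms, 1, function(ix) cor(bruteRank(x), bruteRank(y[ix])))
  expect_equal(got$p, mean(abs(null) >= abs(want) - 1e-12))

  # constant vector: NA, not an error
  expect_true(is.na(correlateExpressionPhenotype(rep(1, 5), up)$rho))
  expect_error(correlateExpressionPhenotype(1:2, 1:2), "at least 3")
})
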