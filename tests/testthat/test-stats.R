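mkTable <- function(values, metabolites = NULL, samples = NULL) {
  if (is.null(metabolites))
    metabolites <- paste0("m", seq_len(ncol(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  dimnames(values) <- list(samples, metabolites)
  values
}

test_that("per-metabolite z-scaling standardizes every column", {
  set.seed(1)
  x <- mkTable(matrix(rlnorm(60), 10, 6))
  z <- zscale(x, "per_metabolite")
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 6), tolerance = 1e-12)
  # idempotence
  expect_equal(zscale(z, "per_metabolite"), z, tolerance = 1e-12)
  # constant column maps to zero with a warning
  x2 <- x; x2[, 3] <- 5
  expect_warning(z2 <- zscale(x2, "per_metabolite"), "zero-variance")
  expect_true(all(z2[, 3] == 0))
})

test_that("global z-scaling standardizes the whole matrix", {
  set.seed(2)
  x <- mkTable(matrix(rnorm(40, 10, 3), 8, 5))
  z <- zscale(x, "global")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(z)), 1, tolerance = 1e-12)
  expect_error(zscale(x[1, , drop = FALSE]), "2 samples")
})

test_that("ANOVA ranking reproduces hand-computed F statistics", {
  # identical groups: no between-group variance
  x <- mkTable(matrix(c(1, 2, 1, 2), 4, 1))
  rk0 <- anovaRank(x, c("a", "a", "b", "b"), threshold = 5)
  expect_equal(rk0$fStatistic, 0)

  # planted separation with small within-group noise
  eps <- 0.01
  y <- c(0, eps, -eps, 1, 1 + eps, 1 - eps)
  g <- rep(c("lo", "hi"), each = 3)
  x2 <- mkTable(matrix(y, 6, 1))
  rk <- anovaRank(x2, g, threshold = 5)
  expect_equal(rk$fStatistic, handFStatistic(y, g), tolerance = 1e-12)
  expect_true(rk$selected)

  # ranking is sorted descending and is a permutation
  set.seed(3)
  x3 <- mkTable(cbind(rnorm(8), rep(c(0, 10), each = 4) + rnorm(8, 0, .1),
                      rnorm(8)))
  rk3 <- anovaRank(x3, rep(c("a", "b"), each = 4))
  expect_equal(rk3$rank, 1:3)
  expect_false(is.unsorted(rev(rk3$fStatistic)))
  expect_equal(rk3$metabolite[1], "m2")
  for (j in 1:3)
    expect_equal(rk3$fStatistic[rk3$metabolite == colnames(x3)[j]],
                 handFStatistic(x3[, j], rep(c("a", "b"), each = 4)),
                 tolerance = 1e-12)
})

test_that("ANOVA ranking validates its class structure", {
  x <- mkTable(matrix(rnorm(10), 5, 2))
  expect_error(anovaRank(x, c("a", "a", "a", "a", "b")), "b")
  expect_error(anovaRank(x, rep("a", 5)), "2 classes")
})

test_that("the F statistic is invariant under affine transforms", {
  set.seed(4)
  y <- rnorm(12); g <- rep(letters[1:3], each = 4)
  x <- mkTable(matrix(y, 12, 1))
  f0 <- anovaRank(x, g)$fStatistic
  for (ab in list(c(2, 0), c(-3, 7), c(0.01, -2))) {
    xt <- mkTable(matrix(ab[1] * y + ab[2], 12, 1))
    expect_equal(anovaRank(xt, g)$fStatistic, f0, tolerance = 1e-9)
  }
})

test_that("PCA explains collinear data with one component", {
  t <- seq(-1, 1, length.out = 20)
  x <- mkTable(cbind(2 * t + 1, -3 * t + 4))
  p <- runPCA(x, 2)
  expect_equal(p$explainedVariance[1], 1, tolerance = 1e-12)
  expect_false(is.unsorted(rev(p$explainedVariance)))
})

test_that("full-rank PCA reconstructs the data matrix", {
  set.seed(5)
  x <- mkTable(matrix(rnorm(50), 10, 5))
  p <- runPCA(x, 5)
  rec <- p$scores %*% t(p$loadings) +
    matrix(p$center, 10, 5, byrow = TRUE)
  expect_equal(unname(rec), unname(x), tolerance = 1e-9)
  expect_equal(sum(p$explainedVariance), 1, tolerance = 1e-12)
  expect_error(runPCA(x, 6), "nComponents")
})

test_that("PC1 separates well-separated synthetic clusters", {
  set.seed(6)
  a <- matrix(rnorm(30, 0, 0.2), 6, 5)
  b <- matrix(rnorm(30, 5, 0.2), 6, 5)
  x <- mkTable(rbind(a, b))
  p <- runPCA(x, 2)
  sil <- silhouette1d(p$scores[, 1], rep(c(TRUE, FALSE), each = 6))
  expect_gt(sil, 0)
})

test_that("hierarchical ordering is deterministic and groups duplicates", {
  x <- mkTable(matrix(c(0, 0, 5, 5, 0.01, 0), 2, 3))
  ord <- hierarchicalOrder(x, axis = "metabolites")
  expect_setequal(ord, 1:3)
  # identical items 1 and 3 merge first, so they sit adjacent
  pos <- match(c(1, 3), ord)
  expect_equal(abs(diff(pos)), 1)
  two <- mkTable(matrix(rnorm(4), 2, 2))
  expect_equal(sort(hierarchicalOrder(two, "samples")), 1:2)
})

test_that("correlation-difference maps behave like Fig-style contrasts", {
  set.seed(7)
  a <- mkTable(matrix(rnorm(200), 50, 4))
  b <- mkTable(matrix(rnorm(200), 50, 4))
  expect_true(all(correlationDifference(a, a) == 0))
  dAB <- correlationDifference(a, b)
  dBA <- correlationDifference(b, a)
  expect_equal(dAB, -dBA, tolerance = 1e-12)
  expect_equal(dAB, t(dAB), tolerance = 1e-12)
  expect_true(all(diag(dAB) == 0))

  # plant a perfect correlation in A only
  a2 <- a; a2[, 2] <- a2[, 1]
  dr <- correlationDifference(a2, b)
  expect_gt(dr[1, 2], 0.8)

  flat <- a; flat[, 3] <- 1
  expect_warning(dflat <- correlationDifference(flat, b), "zero-variance")
  expect_true(all(is.na(dflat[3, -3])))
  expect_error(correlationDifference(a[1:2, ], b), "3 samples")
})

test_that("over-representation p-values match exhaustive enumeration", {
  # closed form: universe 10, pathway 5, selected = the pathway
  u <- paste0("x", 1:10)
  pw <- list(hit = u[1:5])
  res <- oraHypergeometric(u[1:5], pw, u)
  expect_equal(res$pValue, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5L)
  expect_equal(res$pValue, enumerateHyperP(u, pw$hit, 5, 5),
               tolerance = 1e-12)

  # selected = universe forces the overlap
  resAll <- oraHypergeometric(u, pw, u)
  expect_equal(resAll$pValue, 1.0)

  # disjoint pathway
  resNone <- oraHypergeometric(u[6:10], list(p = u[1:3]), u[4:10])
  expect_equal(resNone$overlap, 0L)
  expect_equal(resNone$pValue, 1.0)

  # systematic sweep against the enumeration oracle
  set.seed(8)
  for (N in c(5, 8, 12)) {
    uni <- paste0("g", seq_len(N))
    for (K in unique(c(1, N %/% 2, N - 1))) {
      pth <- list(pw = sample(uni, K))
      for (n in unique(c(1, N %/% 2, N))) {
        selected <- sample(uni, n)
        p <- oraHypergeometric(selected, pth, uni)
        k <- length(intersect(selected, pth$pw))
        expect_equal(p$pValue, enumerateHyperP(uni, pth$pw, n, k),
                     tolerance = 1e-12,
                     info = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }

  expect_error(oraHypergeometric("a", list(p = "a"), character(0)),
               "empty universe")
  expect_error(oraHypergeometric("z", list(p = "a"), c("a", "b")),
               "subset")
  adj <- oraHypergeometric(u[1:5], list(a = u[1:5], b = u[6:8]), u,
                           adjust = TRUE)
  expect_true("pAdjusted" %in% names(adj))
})

test_that("GMT files parse into named member lists", {
  tf <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tm1\tm2\tm3", "setB\tdesc\tm2\tm4"), tf)
  sets <- readGMT(tf)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setB, c("m2", "m4"))
  writeLines("broken\tonly-desc", tf)
  expect_error(readGMT(tf), "malformed")
})
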