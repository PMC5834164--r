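test_that("pairwise SD matrix: shift invariance and brute-force equality", {
  x <- randomCq(g = 3, nCond = 2, nRep = 2, seed = 21)
  m <- cqValues(x)
  m["g2", ] <- m["g1", ] + 1.7          # constant offset
  x2 <- CqExperiment(m, sampleConditions(x), sampleReplicates(x))
  V <- pairwiseSdMatrix(x2)
  expect_equal(V["g1", "g2"], 0)
  expect_equal(V, t(V))
  expect_equal(diag(V), c(g1 = 0, g2 = 0, g3 = 0))

  y <- randomCq(g = 3, nCond = 2, nRep = 2, seed = 22)
  expect_equal(pairwiseSdMatrix(y), bfPairwiseSd(cqValues(y)),
               tolerance = 1e-12)
})

test_that("per-sample loading offsets cancel in the pairwise kernel", {
  x <- randomCq(g = 4, nCond = 2, nRep = 3, seed = 23)
  off <- seq(-1, 1.5, length.out = ncol(x))
  x2 <- CqExperiment(sweep(cqValues(x), 2, off, "+"),
                     sampleConditions(x), sampleReplicates(x))
  expect_equal(pairwiseSdMatrix(x2), pairwiseSdMatrix(x),
               tolerance = 1e-12)
})

test_that("pairwise SD requires 3 complete samples per pair and drops pairwise", {
  x <- randomCq(g = 2, nCond = 1, nRep = 4, seed = 24)
  m <- cqValues(x)
  m[1, 1:2] <- NA
  x2 <- CqExperiment(m, sampleConditions(x), sampleReplicates(x))
  expect_error(pairwiseSdMatrix(x2), "g1 / g2")
  m[1, 2] <- 20
  x3 <- CqExperiment(m, sampleConditions(x), sampleReplicates(x))
  expect_equal(pairwiseSdMatrix(x3)[1, 2],
               sd((m[1, ] - m[2, ])[-1]))
})

test_that("amplification efficiencies rescale Cq by log2(E) in the kernel", {
  x <- randomCq(g = 3, nCond = 2, nRep = 3, seed = 25)
  e <- geneEfficiencies(rownames(x), E = c(2, 1.8, 1.9))
  V <- pairwiseSdMatrix(x, e)
  m <- cqValues(x) * log2(e[rownames(x)])
  expect_equal(V, bfPairwiseSd(m), tolerance = 1e-12)
})

test_that("geNorm: exact-copy genes tie at rank 1 and the next gene gets rank 3", {
  set.seed(26)
  base <- runif(9, 18, 25)
  m <- rbind(X = base + rnorm(9, 0, 0.01),
             Y = base + rnorm(9, 0, 0.01),
             Z = base + rnorm(9, 0, 1.5),
             W = base + rnorm(9, 0, 2.5))
  x <- CqExperiment(m, condition = rep(c("A", "B", "C"), each = 3))
  tb <- stabilityTable(geNorm(x))
  expect_equal(tb$rank[tb$gene %in% c("X", "Y")], c(1L, 1L))
  expect_true(all(tb$tied_pair[tb$gene %in% c("X", "Y")]))
  expect_equal(tb$rank[tb$gene == "Z"], 3L)
  expect_equal(tb$rank[tb$gene == "W"], 4L)
})

test_that("geNorm excludes the noisy gene first and the exact pair reaches M = 0", {
  set.seed(27)
  base <- runif(6, 18, 25)
  m <- rbind(A = base, B = base, C = base + rnorm(6, 0, 0.8))
  x <- CqExperiment(m, condition = rep(c("u", "v"), each = 3))
  res <- geNorm(x)
  tb <- stabilityTable(res)
  expect_equal(tb$excluded_at[tb$gene == "C"], 1L)
  expect_equal(tb$value[tb$gene %in% c("A", "B")], c(0, 0))
})

test_that("first-pass geNorm M equals the mean of brute-force pairwise SDs", {
  x <- randomCq(g = 5, nCond = 2, nRep = 3, seed = 28)
  tb <- stabilityTable(geNorm(x))
  Vbf <- bfPairwiseSd(cqValues(x))
  expected <- rowSums(Vbf) / (nrow(Vbf) - 1)
  expect_equal(tb$m_first[match(names(expected), tb$gene)],
               unname(expected), tolerance = 1e-12)
})

test_that("geNorm needs at least 3 genes", {
  x <- randomCq(g = 2, nCond = 2, nRep = 3, seed = 29)
  expect_error(geNorm(x), "3 genes")
})

test_that("delta-Ct method equals first-iteration geNorm M under E = 2", {
  for (seed in 31:40) {
    x <- randomCq(g = sample(3:7, 1), nCond = 3, nRep = 3, seed = seed)
    dct <- stabilityTable(deltaCtStability(x))
    gn <- stabilityTable(geNorm(x))
    expect_equal(dct$value[match(gn$gene, dct$gene)], gn$m_first,
                 tolerance = 1e-12)
  }
})

test_that("delta-Ct method: two genes share the statistic; a duplicate lowers it", {
  x <- randomCq(g = 2, nCond = 2, nRep = 3, seed = 41)
  tb <- stabilityTable(deltaCtStability(x))
  expect_equal(tb$value[1], tb$value[2])
  expect_equal(tb$value[1], sd(cqValues(x)[1, ] - cqValues(x)[2, ]))

  y <- randomCq(g = 4, nCond = 2, nRep = 3, seed = 42)
  before <- stabilityTable(deltaCtStability(y))
  m2 <- rbind(cqValues(y), g1copy = cqValues(y)["g1", ])
  y2 <- CqExperiment(m2, sampleConditions(y), sampleReplicates(y))
  after <- stabilityTable(deltaCtStability(y2))
  expect_lt(after$value[after$gene == "g1"],
            before$value[before$gene == "g1"])
})

test_that("BestKeeper matches direct formula evaluation", {
  x <- randomCq(g = 4, nCond = 3, nRep = 2, seed = 43)
  tb <- stabilityTable(bestKeeper(x))
  bf <- bfBestKeeper(cqValues(x))
  i <- match(bf$gene, tb$gene)
  expect_equal(tb$value[i], bf$sd, tolerance = 1e-12)
  expect_equal(tb$cv[i], bf$cv, tolerance = 1e-12)
  expect_equal(tb$r[i], bf$r, tolerance = 1e-12)
  expect_equal(tb$rank, rank(tb$value, ties.method = "min"))
})

test_that("BestKeeper degenerate cases: constant gene, single gene, non-positive Cq", {
  m <- rbind(flat = rep(20, 6),
             var1 = c(18, 19, 20, 21, 22, 23),
             var2 = c(25, 24, 23, 22, 21, 25))
  x <- CqExperiment(m, condition = rep(c("A", "B"), each = 3))
  tb <- stabilityTable(bestKeeper(x))
  expect_equal(tb$value[tb$gene == "flat"], 0)
  expect_equal(tb$cv[tb$gene == "flat"], 0)
  expect_equal(tb$rank[tb$gene == "flat"], 1L)

  x1 <- CqExperiment(m[1, , drop = FALSE] + c(0, 1, 2, 0, 1, 2),
                     condition = rep(c("A", "B"), each = 3))
  tb1 <- stabilityTable(bestKeeper(x1))
  expect_equal(tb1$r, 1)

  mBad <- m; mBad[1, 1] <- -1
  expect_error(bestKeeper(CqExperiment(mBad,
                                       rep(c("A", "B"), each = 3))),
               "geometric mean")
})

test_that("NormFinder: degenerate minimum, variance ordering and group checks", {
  base <- c(20, 21, 22, 20.5, 21.5, 23)
  m <- rbind(a = base, b = base + 2, c = base - 1)
  x <- CqExperiment(m, condition = rep(c("A", "B"), each = 3))
  tb <- stabilityTable(normFinder(x))
  expect_equal(tb$value, c(0, 0, 0))

  ## residual SDs 0.1 and 0.4 (constructed), single group
  dev <- c(-1, 0, 1, -1, 1, 0) / sd(c(-1, 0, 1, -1, 1, 0))
  m2 <- rbind(lowvar = 20 + 0.15 * dev, highvar = 25 - 0.6 * dev,
              anchor = rep(22, 6))
  x2 <- CqExperiment(m2, condition = rep("A", 6))
  expect_warning(res <- normFinder(x2), "single group")
  tb2 <- stabilityTable(res)
  expect_lt(tb2$value[tb2$gene == "lowvar"],
            tb2$value[tb2$gene == "highvar"])
  expect_equal(tb2$mean_abs_bias, c(0, 0, 0))

  x3 <- randomCq(g = 3, nCond = 3, nRep = 2, seed = 44)
  expect_error(normFinder(x3, groups = c("A", "A", "A", "A", "A", "B")),
               "B")
})

test_that("a gene with a planted one-condition shift gets the worst NormFinder value", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed + 500)
    cond <- rep(paste0("c", 1:4), each = 3)
    m <- matrix(rnorm(5 * 12, 0, 0.15) + rep(runif(5, 18, 24), 12),
                nrow = 5, dimnames = list(paste0("g", 1:5), NULL))
    m[1, cond == "c2"] <- m[1, cond == "c2"] + 1.0
    x <- CqExperiment(m, condition = cond)
    tb <- stabilityTable(normFinder(x))
    if (tb$gene[which.max(tb$value)] == "g1") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("Cq spread summary uses linear-interpolation quartiles and flags wide genes", {
  m <- rbind(flat = rep(20, 8), spread = 1:8)
  x <- CqExperiment(m, condition = paste0("c", 1:8),
                    replicate = rep(1L, 8))
  sp <- cqSpread(x)
  f <- sp[sp$gene == "flat", ]
  expect_equal(unlist(f[c("min", "q1", "median", "q3", "max")]),
               rep(20, 5), ignore_attr = TRUE)
  expect_identical(f$outliers, "")
  s <- sp[sp$gene == "spread", ]
  expect_equal(s$median, 4.5)
  expect_equal(s$q1, quantile(1:8, 0.25, type = 7, names = FALSE))
  expect_equal(s$q3, quantile(1:8, 0.75, type = 7, names = FALSE))
  expect_equal(s$span, 7)
  expect_gt(s$span_rank, f$span_rank)
})

test_that("drifting genes rank worst by Cq span in the hatching scenario", {
  sim <- simulateCq(hatchingScenario(), seed = 45)
  panel <- names(sim$truth$role)[sim$truth$role != "pulse"]
  sp <- cqSpread(sim$cq[panel, ])
  expect_equal(sp$gene[which.max(sp$span)], "Act-1")
})

test_that("loading offsets leave geNorm, delta-Ct and NormFinder untouched but not BestKeeper", {
  x <- randomCq(g = 5, nCond = 4, nRep = 3, seed = 46)
  set.seed(47)
  off <- rnorm(ncol(x), 0, 2)
  x2 <- CqExperiment(sweep(cqValues(x), 2, off, "+"),
                     sampleConditions(x), sampleReplicates(x))
  for (fn in list(deltaCtStability, geNorm, normFinder)) {
    a <- stabilityTable(fn(x)); b <- stabilityTable(fn(x2))
    expect_equal(b$value[match(a$gene, b$gene)], a$value,
                 tolerance = 1e-9)
  }
  a <- stabilityTable(bestKeeper(x))
  b <- stabilityTable(bestKeeper(x2))
  expect_gt(max(abs(b$value[match(a$gene, b$gene)] - a$value)), 0.1)
})

test_that("scaling all Cq deviations by c scales the statistics by c", {
  x <- randomCq(g = 4, nCond = 2, nRep = 3, seed = 48)
  m <- cqValues(x)
  c0 <- 2.5
  mu <- rowMeans(m)
  m2 <- sweep(sweep(m, 1, mu, "-") * c0, 1, mu, "+")
  x2 <- CqExperiment(m2, sampleConditions(x), sampleReplicates(x))
  for (fn in list(deltaCtStability, normFinder, bestKeeper)) {
    a <- stabilityTable(fn(x)); b <- stabilityTable(fn(x2))
    expect_equal(b$value[match(a$gene, b$gene)], c0 * a$value,
                 tolerance = 1e-9)
  }
})
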