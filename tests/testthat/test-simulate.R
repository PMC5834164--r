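test_that("the frozen hatching scenario has the expected design bookkeeping", {
  cfg <- hatchingScenario()
  expect_equal(nrow(cfg@roster), 14L)
  expect_equal(length(cfg@conditions), 8L)
  sim <- simulateCq(cfg, seed = 71)
  expect_equal(dim(sim$cq), c(14L, 24L))
  expect_equal(unname(table(sampleConditions(sim$cq))[cfg@conditions]),
               rep(3L, 8L), ignore_attr = TRUE)
  expect_equal(sum(sim$truth$role == "stable"), 3L)
})

test_that("the same seed reproduces tables bit-identically; seeds differ otherwise", {
  cfg <- hatchingScenario()
  a <- simulateCq(cfg, seed = 72)
  b <- simulateCq(cfg, seed = 72)
  expect_identical(cqValues(a$cq), cqValues(b$cq))
  expect_identical(a$truth, b$truth)
  c <- simulateCq(cfg, seed = 73)
  expect_false(identical(cqValues(a$cq), cqValues(c$cq)))

  k1 <- simulateCounts(cfg, seed = 72)
  k2 <- simulateCounts(cfg, seed = 72)
  expect_identical(SummarizedExperiment::assay(k1$counts),
                   SummarizedExperiment::assay(k2$counts))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(74)
  r1 <- runif(1)
  set.seed(74)
  invisible(simulateCq(hatchingScenario(), seed = 75))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("at zero noise stable genes sit exactly at their baseline Cq", {
  ro <- rbind(
    data.frame(gene = c("s1", "s2", "s3"), role = "stable",
               baseCq = c(20, 22, 24), amplitude = 0, conditions = "",
               extraNoise = 0, meanExpr = 1000))
  cfg <- simulationConfig(roster = ro, sigmaTech = 0, sigmaLoad = 0)
  sim <- simulateCq(cfg, seed = 76)
  m <- cqValues(sim$cq)
  expect_equal(unname(m), matrix(rep(c(20, 22, 24), 24), nrow = 3),
               tolerance = 0)
  expect_equal(max(pairwiseSdMatrix(sim$cq)), 0)
  expect_equal(stabilityTable(deltaCtStability(sim$cq))$value,
               rep(0, 3))
})

test_that("a noise-free pulse propagates through 2^-ddCt as an exact fold change", {
  ro <- rbind(
    data.frame(gene = c("r1", "r2", "r3"), role = "stable",
               baseCq = c(20, 21, 22), amplitude = 0, conditions = "",
               extraNoise = 0, meanExpr = 1000),
    data.frame(gene = "tgt", role = "pulse", baseCq = 26,
               amplitude = log2(10), conditions = "PRD_8h",
               extraNoise = 0, meanExpr = 100))
  cfg <- simulationConfig(roster = ro, sigmaTech = 0, sigmaLoad = 0)
  sim <- simulateCq(cfg, seed = 77)
  res <- deltaDeltaCt(sim$cq, "tgt", c("r1", "r2", "r3"),
                      calibrator = "dry_cyst")
  s <- expressionSummary(res)
  expect_equal(s$mean_fc[s$condition == "PRD_8h"], 10)
  expect_equal(s$mean_fc[s$condition == "J2"], 1)
})

test_that("stable-gene Cq dispersion converges to the tech/load quadrature", {
  ro <- data.frame(gene = "s1", role = "stable", baseCq = 20,
                   amplitude = 0, conditions = "", extraNoise = 0,
                   meanExpr = 1000)
  cfg <- simulationConfig(conditions = c("a", "b"), cqReplicates = 500L,
                          roster = ro, sigmaTech = 0.15, sigmaLoad = 0.3)
  sim <- simulateCq(cfg, seed = 78)
  expected <- sqrt(0.15^2 + 0.3^2)
  expect_equal(sd(cqValues(sim$cq)[1, ]), expected,
               tolerance = 0.05)
})

test_that("count means track the configured library-fraction model", {
  ## Poisson limit: one stable gene, many replicate libraries
  ro <- rbind(
    data.frame(gene = "g1", role = "stable", baseCq = 20,
               amplitude = 0, conditions = "", extraNoise = 0,
               meanExpr = 300),
    data.frame(gene = "g2", role = "stable", baseCq = 20,
               amplitude = 0, conditions = "", extraNoise = 0,
               meanExpr = 700))
  cfg <- simulationConfig(conditions = c("a", "b"),
                          countReplicates = 100L, roster = ro,
                          dispersion = 0, libSizeRange = c(1e4, 1e4))
  sim <- simulateCounts(cfg, seed = 79)
  k <- SummarizedExperiment::assay(sim$counts)
  mu <- 1e4 * 0.3                       # fraction 300/1000
  se <- sqrt(mu / ncol(k))
  expect_lt(abs(mean(k["g1", ]) - mu), 3 * se)
  expect_equal(sim$truth$fractions["g1", "a"], 0.3)
})

test_that("doubling the library size doubles expected counts", {
  ro <- data.frame(gene = c("g1", "g2"), role = "stable",
                   baseCq = 20, amplitude = 0, conditions = "",
                   extraNoise = 0, meanExpr = c(400, 600))
  mk <- function(lib) {
    cfg <- simulationConfig(conditions = c("a", "b"),
                            countReplicates = 200L, roster = ro,
                            dispersion = 0,
                            libSizeRange = c(lib, lib))
    sim <- simulateCounts(cfg, seed = 80)
    mean(SummarizedExperiment::assay(sim$counts)["g1", ])
  }
  m1 <- mk(5e3); m2 <- mk(1e4)
  expect_equal(m2 / m1, 2, tolerance = 0.05)
})

test_that("dropout genes are zero in their condition and fail the filter", {
  cfg <- screenScenario(nResponsive = 20, nDropout = 1)
  sim <- simulateCounts(cfg, seed = 81)
  k <- SummarizedExperiment::assay(sim$counts)
  cond <- sampleConditions(sim$counts)
  expect_true(all(k["dropout_01", cond == "PRD_1h"] == 0))
  expect_true(any(k["dropout_01", cond != "PRD_1h"] > 0))
  expect_true("dropout_01" %in% zeroExpressionFilter(sim$counts)$excluded)
})

test_that("roster validation rejects malformed configurations", {
  ro <- data.frame(gene = "g", role = "mystery", baseCq = 20,
                   amplitude = 0, conditions = "", extraNoise = 0,
                   meanExpr = 10)
  expect_error(simulationConfig(roster = ro), "unknown role")
  ro2 <- ro; ro2$role <- "stable"
  expect_error(simulationConfig(roster = ro2, sigmaTech = -1),
               "sigmaTech")
  expect_error(simulationConfig(roster = ro2,
                                libSizeRange = c(10, 5)),
               "libSizeRange")
})
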