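## small deterministic Cq table: 2 refs + 1 target over 3 conditions
makeExprTable <- function(targetShift = c(A = 0, B = 0, C = 0),
                          noise = 0, seed = 61, nRep = 3) {
  set.seed(seed)
  cond <- rep(names(targetShift), each = nRep)
  ref1 <- 20 + rnorm(length(cond), 0, noise)
  ref2 <- 24 + rnorm(length(cond), 0, noise)
  tgt <- 26 - targetShift[cond] + rnorm(length(cond), 0, noise)
  m <- rbind(r1 = ref1, r2 = ref2, t1 = unname(tgt))
  CqExperiment(m, condition = cond)
}

test_that("reference index is the per-sample mean of reference Cq", {
  x <- randomCq(g = 3, nCond = 8, nRep = 3, seed = 62)
  idx <- referenceIndex(x, rownames(x))
  expect_equal(idx, colMeans(cqValues(x)))
  m <- cqValues(x)
  expect_equal(referenceIndex(x, "g2"), m["g2", ])

  m["g1", 4] <- NA
  x2 <- CqExperiment(m, sampleConditions(x), sampleReplicates(x))
  expect_error(referenceIndex(x2, c("g1", "g2")), "g1")
  expect_error(referenceIndex(x, c("g1", "nope")), "nope")
})

test_that("a target tracking the reference index has fold change 1 everywhere", {
  x <- makeExprTable(noise = 0)
  m <- cqValues(x)
  m["t1", ] <- colMeans(m[c("r1", "r2"), ])
  x <- CqExperiment(m, sampleConditions(x), sampleReplicates(x))
  res <- deltaDeltaCt(x, targets = "t1", refs = c("r1", "r2"),
                      calibrator = "A")
  expect_equal(expressionSummary(res)$mean_fc, rep(1, 3))
})

test_that("a planted log2(10)-cycle drop yields a 10-fold change at zero noise", {
  x <- makeExprTable(targetShift = c(A = 0, B = log2(10), C = 0))
  res <- deltaDeltaCt(x, "t1", c("r1", "r2"), calibrator = "A")
  s <- expressionSummary(res)
  expect_equal(s$mean_fc[s$condition == "B"], 10)
  expect_equal(s$mean_fc[s$condition == "A"], 1)
  expect_equal(s$sem_fc[s$condition == "B"], 0)
})

test_that("the calibrator's mean fold change is exactly 1 regardless of noise", {
  x <- makeExprTable(targetShift = c(A = 0, B = 2, C = 1), noise = 0.4,
                     seed = 63)
  res <- deltaDeltaCt(x, "t1", c("r1", "r2"), calibrator = "A")
  s <- expressionSummary(res)
  ## mean of 2^-ddCt over calibrator replicates is 1 only on the dCt
  ## scale; the method centres dCt on the calibrator mean, so check that
  reps <- res@replicates
  expect_equal(mean(reps$delta_delta_ct[reps$condition == "A"]), 0,
               tolerance = 1e-12)
  expect_equal(prod(reps$fold_change[reps$condition == "A"])^(1/3), 1,
               tolerance = 1e-12)
})

test_that("input validation: absent targets, overlapping sets, absent calibrator", {
  x <- makeExprTable()
  expect_error(deltaDeltaCt(x, "ghost", c("r1", "r2"), "A"), "ghost")
  expect_error(deltaDeltaCt(x, "r1", c("r1", "r2"), "A"), "disjoint")
  expect_error(deltaDeltaCt(x, "t1", c("r1", "r2"), "Z"), "calibrator")
})

test_that("loading offsets shared by all genes leave fold changes unchanged", {
  x <- makeExprTable(targetShift = c(A = 0, B = 1.5, C = 0.5),
                     noise = 0.2, seed = 64)
  set.seed(65)
  off <- rnorm(ncol(x), 0, 1)
  x2 <- CqExperiment(sweep(cqValues(x), 2, off, "+"),
                     sampleConditions(x), sampleReplicates(x))
  a <- expressionSummary(deltaDeltaCt(x, "t1", c("r1", "r2"), "A"))
  b <- expressionSummary(deltaDeltaCt(x2, "t1", c("r1", "r2"), "A"))
  expect_equal(b$mean_fc, a$mean_fc, tolerance = 1e-9)
  expect_equal(b$sem_fc, a$sem_fc, tolerance = 1e-9)
})

test_that("reference set order does not matter", {
  x <- makeExprTable(targetShift = c(A = 0, B = 1, C = 0), noise = 0.1,
                     seed = 66)
  a <- expressionSummary(deltaDeltaCt(x, "t1", c("r1", "r2"), "A"))
  b <- expressionSummary(deltaDeltaCt(x, "t1", c("r2", "r1"), "A"))
  expect_equal(a$mean_fc, b$mean_fc, tolerance = 1e-12)
  expect_equal(a$letters, b$letters)
})

test_that("well-separated groups get disjoint letters; equal groups share one", {
  ## separation of 10 within-group SDs
  x <- makeExprTable(targetShift = c(A = 0, B = 3), noise = 0.3,
                     seed = 67)
  res <- deltaDeltaCt(x, "t1", c("r1", "r2"), "A")
  s <- expressionSummary(res)
  expect_equal(s$letters[s$condition == "B"], "a")  # highest FC
  expect_equal(s$letters[s$condition == "A"], "b")

  xe <- makeExprTable(targetShift = c(A = 0, B = 0, C = 0))
  resE <- deltaDeltaCt(xe, "t1", c("r1", "r2"), "A")
  expect_equal(unique(expressionSummary(resE)$letters), "a")
})

test_that("zero within-group variance with unequal means yields all-distinct letters", {
  x <- makeExprTable(targetShift = c(A = 0, B = 1, C = 2), noise = 0)
  res <- deltaDeltaCt(x, "t1", c("r1", "r2"), "A")
  s <- expressionSummary(res)
  expect_setequal(s$letters, c("a", "b", "c"))
  expect_equal(s$letters[order(-s$mean_fc)], c("a", "b", "c"))
})

test_that("identically distributed conditions share a letter in most seeded replicates", {
  shared <- 0L
  for (seed in 1:20) {
    x <- makeExprTable(targetShift = c(A = 0, B = 0, C = 0, D = 0),
                       noise = 0.3, seed = 100 + seed)
    s <- expressionSummary(deltaDeltaCt(x, "t1", c("r1", "r2"), "A"))
    common <- Reduce(intersect, strsplit(s$letters, ""))
    if (length(common) > 0) shared <- shared + 1L
  }
  expect_gte(shared, 18L)
})

test_that("compact letters agree with multcomp's display on a multi-group case", {
  skip_if_not_installed("multcomp")
  set.seed(68)
  cond <- rep(LETTERS[1:5], each = 4)
  shift <- c(A = 0, B = 0.2, C = 2, D = 2.1, E = 5)
  dct <- shift[cond] + rnorm(length(cond), 0, 0.3)
  ## package letters via an ExpressionResult built from these dCt values
  m <- rbind(r1 = rep(20, length(cond)),
             t1 = 20 + dct)
  x <- CqExperiment(m, condition = cond)
  res <- deltaDeltaCt(x, "t1", "r1", calibrator = "A")
  s <- expressionSummary(res)
  fit <- multcomp::glht(stats::aov(dct ~ g, data.frame(dct = dct,
                                                       g = factor(cond))),
                        linfct = multcomp::mcp(g = "Tukey"))
  cl <- multcomp::cld(fit)$mcletters$Letters
  ## same partition: two conditions share a letter in ours iff in theirs
  shares <- function(lets, a, b)
    length(intersect(strsplit(lets[a], "")[[1]],
                     strsplit(lets[b], "")[[1]])) > 0
  ours <- setNames(s$letters, s$condition)
  for (a in LETTERS[1:4]) for (b in LETTERS[(match(a, LETTERS) + 1):5])
    expect_equal(shares(ours, a, b), shares(cl, a, b),
                 info = paste(a, b))
})
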