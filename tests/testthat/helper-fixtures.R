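## Fixture builders and independent brute-force oracles used across the
## suite. Oracles use plain loops and direct formulas, deliberately
## sharing no code with the package internals.

## random Cq table: g genes x (nCond conditions * nRep replicates)
randomCq <- function(g = 5, nCond = 4, nRep = 3, seed = 1,
                     lo = 15, hi = 30) {
  set.seed(seed)
  conds <- paste0("c", seq_len(nCond))
  cond <- rep(conds, each = nRep)
  m <- matrix(runif(g * nCond * nRep, lo, hi), nrow = g,
              dimnames = list(paste0("g", seq_len(g)), NULL))
  CqExperiment(m, condition = cond,
               replicate = rep(seq_len(nRep), nCond))
}

## brute-force pairwise SD of Cq differences (E = 2), loop form
bfPairwiseSd <- function(m) {
  g <- nrow(m)
  V <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(g)) for (k in seq_len(g)) {
    if (j == k) next
    d <- m[j, ] - m[k, ]
    d <- d[!is.na(d)]
    mu <- sum(d) / length(d)
    V[j, k] <- sqrt(sum((d - mu)^2) / (length(d) - 1))
  }
  V
}

## brute-force BestKeeper descriptives
bfBestKeeper <- function(m) {
  idx <- numeric(ncol(m))
  for (s in seq_len(ncol(m))) idx[s] <- prod(m[, s])^(1 / nrow(m))
  out <- data.frame(gene = rownames(m), sd = NA_real_, cv = NA_real_,
                    r = NA_real_)
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    mu <- mean(v)
    sdv <- sqrt(sum((v - mu)^2) / (length(v) - 1))
    out$sd[i] <- sdv
    out$cv[i] <- 100 * sdv / mu
    out$r[i] <- sum((v - mu) * (idx - mean(idx))) /
      sqrt(sum((v - mu)^2) * sum((idx - mean(idx))^2))
  }
  out
}

## brute-force geometric mean of a rank vector
bfGeomean <- function(r) prod(r)^(1 / length(r))

## tiny long-format Cq file on disk; returns the path
writeCqFixture <- function(df, sep = "\t") {
  p <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  write.table(df, p, sep = sep, quote = FALSE, row.names = FALSE)
  p
}

## long-format data.frame from a matrix + condition labels
longCq <- function(m, cond, repl = NULL) {
  if (is.null(repl)) repl <- ave(seq_along(cond), cond, FUN = seq_along)
  data.frame(gene = rep(rownames(m), times = ncol(m)),
             sample = rep(paste(cond, repl, sep = "_"), each = nrow(m)),
             condition = rep(cond, each = nrow(m)),
             replicate = rep(repl, each = nrow(m)),
             cq = as.vector(m))
}

## published per-method rank tables bundled with the package
rankFixture <- function(which = c("rnaseq", "qpcr", "pallida")) {
  which <- match.arg(which)
  f <- switch(which,
    rnaseq = "grostochiensis_rnaseq_method_ranks.tsv",
    qpcr = "grostochiensis_qpcr_method_ranks.tsv",
    pallida = "gpallida_qpcr_method_ranks.tsv")
  readRankTable(system.file("extdata", f, package = "refstab"))
}
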