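## The four Cq-based stability statistics. All four read the Cq matrix
## of a CqExperiment; geNorm and the comparative delta-Ct method share
## the pairwise-SD kernel, BestKeeper works on raw Cq descriptives, and
## NormFinder decomposes -Cq (log2 expression up to a constant) into
## intergroup bias and intragroup variance.

## competition ("1223") ranks for an ordering key; rows tie iff all key
## columns are exactly equal
.competitionRanks <- function(keys) {
    keys <- lapply(keys, unname)
    ord <- do.call(order, keys)
    n <- length(ord)
    rk <- integer(n)
    pos <- 1L
    for (i in seq_len(n)) {
        if (i > 1L) {
            same <- all(vapply(keys, function(k)
                identical(k[ord[i]], k[ord[i - 1L]]), logical(1)))
            if (!same) pos <- i
        }
        rk[ord[i]] <- pos
    }
    rk
}

.effWeights <- function(genes, efficiencies) {
    if (is.null(efficiencies)) return(stats::setNames(rep(1, length(genes)),
                                                      genes))
    if (is.null(names(efficiencies)))
        stop("'efficiencies' must be named by gene")
    miss <- setdiff(genes, names(efficiencies))
    if (length(miss))
        stop("missing efficiency for gene(s): ",
             paste(miss, collapse = ", "))
    log2(efficiencies[genes])
}

#' Pairwise standard deviation of Cq differences
#'
#' For genes j, k computes \eqn{V_{jk} = SD_s[\log_2(E_j) Cq_{js} -
#' \log_2(E_k) Cq_{ks}]} over samples s (sample SD, n-1 divisor),
#' dropping samples with a missing value in either gene. With all
#' efficiencies E = 2 this is the SD of the plain Cq difference, the
#' shared kernel of geNorm and the comparative delta-Ct method. A
#' per-sample loading offset added to every gene cancels in the
#' difference, which is exactly why these statistics target
#' normalization-relevant stability.
#'
#' @param x a \linkS4class{CqExperiment} with >= 2 genes.
#' @param efficiencies optional named per-gene amplification factors
#'   (see \code{\link{geneEfficiencies}}); \code{NULL} means E = 2 for
#'   every gene.
#'
#' @return symmetric numeric matrix with zero diagonal, in cycles.
#' @export
pairwiseSdMatrix <- function(x, efficiencies = NULL) {
    m <- cqValues(x)
    if (nrow(m) < 2L) stop("need at least 2 genes")
    w <- .effWeights(rownames(m), efficiencies)
    m <- m * w
    g <- nrow(m)
    V <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
    for (j in seq_len(g - 1L)) {
        for (k in (j + 1L):g) {
            d <- m[j, ] - m[k, ]
            d <- d[!is.na(d)]
            if (length(d) < 3L)
                stop("fewer than 3 complete samples for pair ",
                     rownames(m)[j], " / ", rownames(m)[k])
            V[j, k] <- V[k, j] <- stats::sd(d)
        }
    }
    V
}

#' geNorm expression-stability measure M with iterative exclusion
#'
#' The geNorm M value of a gene is the mean pairwise variation
#' (\code{\link{pairwiseSdMatrix}}) of that gene with all other
#' remaining candidates. The least stable gene (highest M; ties broken
#' by removing the alphabetically last) is excluded and M is recomputed
#' until two genes remain; those two cannot be distinguished by the
#' procedure and are reported tied at rank 1, with the next gene at
#' rank 3 (competition ranking).
#'
#' @inheritParams pairwiseSdMatrix
#' @return a \linkS4class{StabilityResult}; \code{value} is the M value
#'   at the iteration the gene was excluded (for the final pair, their
#'   M on the two-gene set), \code{m_first} the first-pass M on the full
#'   panel, \code{excluded_at} the exclusion order (1 = first excluded;
#'   0 for the final pair) and \code{tied_pair} flags the final pair.
#' @export
geNorm <- function(x, efficiencies = NULL) {
    m <- cqValues(x)
    if (nrow(m) < 3L)
        stop("geNorm ranking is undefined for fewer than 3 genes")
    V <- pairwiseSdMatrix(x, efficiencies)
    genes <- rownames(V)
    mFirst <- rowSums(V) / (nrow(V) - 1L)
    current <- genes
    exclOrder <- character(0)
    exclM <- numeric(0)
    Vc <- V
    while (length(current) > 2L) {
        M <- rowSums(Vc) / (length(current) - 1L)
        worst <- which(M == max(M))
        ## deterministic tie-break: alphabetically last of the tied set
        drop <- names(worst)[order(names(worst))][length(worst)]
        exclOrder <- c(exclOrder, drop)
        exclM <- c(exclM, M[[drop]])
        current <- setdiff(current, drop)
        Vc <- Vc[current, current, drop = FALSE]
    }
    finalM <- Vc[1L, 2L]
    tb <- data.frame(gene = genes, value = NA_real_,
                     rank = NA_integer_, m_first = unname(mFirst),
                     excluded_at = 0L, tied_pair = FALSE,
                     stringsAsFactors = FALSE)
    rownames(tb) <- genes
    tb[current, "value"] <- finalM
    tb[current, "rank"] <- 1L
    tb[current, "tied_pair"] <- TRUE
    nexcl <- length(exclOrder)
    for (i in seq_len(nexcl)) {
        gn <- exclOrder[i]
        tb[gn, "value"] <- exclM[i]
        ## reverse exclusion order; final pair occupies ranks 1 and 2
        tb[gn, "rank"] <- 2L + (nexcl - i + 1L)
        tb[gn, "excluded_at"] <- i
    }
    tb <- tb[order(tb$rank, tb$gene), , drop = FALSE]
    rownames(tb) <- NULL
    new("StabilityResult", method = "geNorm", table = tb)
}

#' Comparative delta-Ct stability statistic
#'
#' The stability of gene j is the mean over all other genes k of the
#' pairwise SD \eqn{V_{jk}} — a single pass of the geNorm kernel with
#' no iteration. With all E = 2 it equals the first-iteration geNorm M
#' exactly. Exact ties receive fractional (average) ranks.
#'
#' @inheritParams pairwiseSdMatrix
#' @return a \linkS4class{StabilityResult} (\code{value} in cycles).
#' @export
deltaCtStability <- function(x, efficiencies = NULL) {
    V <- pairwiseSdMatrix(x, efficiencies)
    val <- rowSums(V) / (nrow(V) - 1L)
    tb <- data.frame(gene = rownames(V), value = unname(val),
                     rank = rank(val, ties.method = "average"),
                     stringsAsFactors = FALSE)
    tb <- tb[order(tb$rank, tb$gene), , drop = FALSE]
    rownames(tb) <- NULL
    new("StabilityResult", method = "deltaCt", table = tb)
}

#' BestKeeper descriptive stability statistics
#'
#' Per gene, the SD of its Cq values (cycles, sample convention, n-1
#' divisor) and the coefficient of variation CV\% = 100 SD / mean; the
#' BestKeeper index is the per-sample geometric mean of all genes' Cq,
#' and each gene's Pearson correlation r with the index is reported.
#' Genes are ranked ascending by SD, ties broken by higher r then gene
#' name. Each gene uses its non-missing samples; the index uses the
#' genes available in each sample.
#'
#' Unlike the difference-based methods, BestKeeper's SD is sensitive to
#' per-sample loading offsets — a documented asymmetry of the method.
#'
#' @param x a \linkS4class{CqExperiment}; all Cq must be positive
#'   (geometric mean undefined otherwise).
#' @return a \linkS4class{StabilityResult} with auxiliary columns
#'   \code{cv} (percent) and \code{r}.
#' @export
bestKeeper <- function(x) {
    m <- cqValues(x)
    if (nrow(m) < 1L) stop("need at least 1 gene")
    if (any(m[!is.na(m)] <= 0))
        stop("non-positive Cq: BestKeeper geometric mean undefined")
    index <- apply(m, 2L, function(col) exp(mean(log(col[!is.na(col)]))))
    sdv <- apply(m, 1L, stats::sd, na.rm = TRUE)
    mu <- rowMeans(m, na.rm = TRUE)
    cv <- 100 * sdv / mu
    r <- vapply(seq_len(nrow(m)), function(i) {
        ok <- !is.na(m[i, ])
        if (nrow(m) == 1L) return(1)
        if (stats::sd(m[i, ok]) == 0 || stats::sd(index[ok]) == 0)
            return(NA_real_)
        stats::cor(m[i, ok], index[ok])
    }, numeric(1))
    rk <- .competitionRanks(list(sdv, -ifelse(is.na(r), -Inf, r)))
    tb <- data.frame(gene = rownames(m), value = unname(sdv), rank = rk,
                     cv = unname(cv), r = unname(r),
                     stringsAsFactors = FALSE)
    tb <- tb[order(tb$rank, tb$gene), , drop = FALSE]
    rownames(tb) <- NULL
    new("StabilityResult", method = "BestKeeper", table = tb)
}

#' NormFinder-style bias-plus-variance stability value
#'
#' Works on \eqn{y = -Cq} (log2 expression up to an additive constant
#' under E = 2). Per sample, the across-gene mean is removed (the
#' sample effect); for each gene and condition group the intergroup
#' bias d (the group's deviation from the gene's across-group mean,
#' summing to zero over groups) and the intragroup SD s are computed
#' from the residuals. The stability value is the across-group mean of
#' |d| + s: both a systematic group effect and a noisy response make a
#' gene a poor reference.
#'
#' This is the simplified bias + variance form; the original
#' small-sample shrinkage corrections are intentionally not applied, so
#' the value's absolute scale is not comparable with other software,
#' while the ranking behaviour is.
#'
#' Samples with a missing value in any gene are excluded (the sample
#' effect is estimated across all genes).
#'
#' @param x a \linkS4class{CqExperiment} with >= 3 genes.
#' @param groups optional grouping factor per sample; defaults to the
#'   condition labels. Every group must have >= 2 samples. A single
#'   group is allowed with a warning: all biases are zero and the value
#'   reduces to the mean within-group SD.
#' @return a \linkS4class{StabilityResult} with auxiliary columns
#'   \code{mean_abs_bias} and \code{mean_group_sd} (both cycles).
#' @export
normFinder <- function(x, groups = NULL) {
    m <- cqValues(x)
    if (nrow(m) < 3L) stop("need at least 3 genes")
    if (is.null(groups)) groups <- sampleConditions(x)
    groups <- as.character(groups)
    complete <- colSums(is.na(m)) == 0L
    m <- m[, complete, drop = FALSE]
    groups <- groups[complete]
    tabg <- table(groups)
    if (any(tabg < 2L))
        stop("group(s) with fewer than 2 samples: ",
             paste(names(tabg)[tabg < 2L], collapse = ", "))
    if (length(tabg) == 1L)
        warning("single group: stability reduces to mean within-group SD")
    y <- -m
    u <- sweep(y, 2L, colMeans(y))          # remove sample effect
    gl <- names(tabg)
    bias <- matrix(0, nrow(m), length(gl),
                   dimnames = list(rownames(m), gl))
    gsd <- bias
    for (g in gl) {
        sel <- groups == g
        bias[, g] <- rowMeans(u[, sel, drop = FALSE])
        gsd[, g] <- apply(u[, sel, drop = FALSE], 1L, stats::sd)
    }
    bias <- bias - rowMeans(bias)           # sum over groups is zero
    rho <- rowMeans(abs(bias) + gsd)
    rk <- .competitionRanks(list(rho))
    tb <- data.frame(gene = rownames(m), value = unname(rho), rank = rk,
                     mean_abs_bias = unname(rowMeans(abs(bias))),
                     mean_group_sd = unname(rowMeans(gsd)),
                     stringsAsFactors = FALSE)
    tb <- tb[order(tb$rank, tb$gene), , drop = FALSE]
    rownames(tb) <- NULL
    new("StabilityResult", method = "NormFinder", table = tb)
}

#' Per-gene Cq spread summary (box-plot style)
#'
#' Descriptive variability of the raw Cq values per gene: median,
#' quartiles (type 7, linear interpolation), whiskers at the most
#' extreme values within 1.5 IQR of the quartiles, outliers beyond the
#' whiskers, and the total span (max - min). The span rank (1 =
#' narrowest) gives the naive range-based ordering that a box-plot
#' comparison suggests — informative, but not a substitute for the
#' model-based stability statistics.
#'
#' @param x a \linkS4class{CqExperiment}.
#' @return data.frame with one row per gene: \code{n}, \code{min},
#'   \code{q1}, \code{median}, \code{q3}, \code{max},
#'   \code{whisker_low}, \code{whisker_high}, \code{outliers}
#'   (semicolon-joined), \code{span}, \code{span_rank}.
#' @export
cqSpread <- function(x) {
    m <- cqValues(x)
    rows <- lapply(rownames(m), function(g) {
        v <- m[g, ]
        v <- v[!is.na(v)]
        if (length(v) < 1L) stop("no Cq values for gene ", g)
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7,
                             names = FALSE)
        iqr <- q[3] - q[1]
        lowFence <- q[1] - 1.5 * iqr
        highFence <- q[3] + 1.5 * iqr
        inl <- v[v >= lowFence & v <= highFence]
        out <- v[v < lowFence | v > highFence]
        data.frame(gene = g, n = length(v), min = min(v), q1 = q[1],
                   median = q[2], q3 = q[3], max = max(v),
                   whisker_low = min(inl), whisker_high = max(inl),
                   outliers = paste(format(out, trim = TRUE),
                                    collapse = ";"),
                   span = max(v) - min(v), stringsAsFactors = FALSE)
    })
    tb <- do.call(rbind, rows)
    tb$span_rank <- rank(tb$span, ties.method = "average")
    rownames(tb) <- NULL
    tb
}

#' @rdname stabilityTable
#' @param x a \linkS4class{StabilityResult}.
#' @return the per-gene statistics data.frame.
#' @export
setMethod("stabilityTable", "StabilityResult", function(x) x@table)

#' Extract per-gene ranks
#' @param x a \linkS4class{StabilityResult} or
#'   \linkS4class{ComprehensiveRanking}.
#' @param ... unused.
#' @return named integer/numeric vector of ranks (1 = most stable).
#' @rdname geneRanks
#' @export
setMethod("geneRanks", "StabilityResult", function(x, ...) {
    stats::setNames(x@table$rank, x@table$gene)
})

setMethod("show", "StabilityResult", function(object) {
    cat("StabilityResult [", object@method, "]: ",
        nrow(object@table), " genes\n", sep = "")
    top <- utils::head(object@table, 3L)
    cat("  most stable:",
        paste(sprintf("%s (%.3g)", top$gene, top$value), collapse = ", "),
        "\n")
})
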