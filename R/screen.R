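## RNA-Seq candidate screen: library-size normalization, a raw-count
## zero-expression filter at the condition level, and a log2-scale
## dispersion score that ranks genes by how constant their expression
## is across all samples.

#' Library-size normalization of a count matrix
#'
#' Scales each sample so that its normalization factor — the total
#' count, or the upper quartile of its nonzero counts — equals the
#' across-sample geometric mean of the factors. This removes
#' sequencing-depth differences while keeping values on the original
#' count scale.
#'
#' @param x a \linkS4class{CountExperiment}.
#' @param method \code{"total"} (total-count, the default) or
#'   \code{"uq"} (upper quartile of nonzero counts; requires >= 4
#'   nonzero genes per sample).
#' @return numeric matrix of normalized expression values (>= 0).
#' @export
normalizeCounts <- function(x, method = c("total", "uq")) {
    method <- match.arg(method)
    k <- assay(x, "counts")
    f <- switch(method,
        total = colSums(k),
        uq = apply(k, 2L, function(col) {
            nz <- col[col > 0]
            if (length(nz) < 4L)
                stop("degenerate sample for upper-quartile ",
                     "normalization (<4 nonzero genes)")
            stats::quantile(nz, 0.75, type = 7, names = FALSE)
        }))
    if (any(f <= 0)) stop("non-positive normalization factor")
    target <- exp(mean(log(f)))
    sweep(k, 2L, f, "/") * target
}

#' Condition-level zero-expression filter
#'
#' A gene is excluded if and only if the sum of its raw counts within
#' any single condition is zero — absence in a whole condition, not a
#' single dropout replicate, disqualifies a reference candidate. The
#' filter always runs on raw counts so normalization or pseudocounts
#' can never mask absence.
#'
#' @param x a \linkS4class{CountExperiment}.
#' @return list with character vectors \code{kept} and \code{excluded}.
#' @export
zeroExpressionFilter <- function(x) {
    k <- assay(x, "counts")
    cond <- sampleConditions(x)
    condSums <- vapply(unique(cond), function(co)
        rowSums(k[, cond == co, drop = FALSE]),
        numeric(nrow(k)))
    excl <- rownames(k)[apply(condSums == 0, 1L, any)]
    list(kept = setdiff(rownames(k), excl), excluded = excl)
}

#' Screen a count matrix for candidate reference genes
#'
#' The screen normalizes (\code{\link{normalizeCounts}}), transforms to
#' log2(x + 1), removes genes failing the raw-count
#' \code{\link{zeroExpressionFilter}}, and scores each remaining gene
#' by the standard deviation of its log2 expression across all samples
#' (lower = more stable). The secondary statistic is the range (max -
#' min) of the per-condition mean log2 expression, used to break score
#' ties, with gene name as the final tie-break. The \code{k} best genes
#' are flagged as selected candidates.
#'
#' @param x a \linkS4class{CountExperiment}.
#' @param k number of candidates to select (>= 1). If fewer genes pass
#'   the filter, all are selected with a warning.
#' @param norm normalization method, see \code{\link{normalizeCounts}}.
#' @return a \linkS4class{ScreenResult}.
#' @export
screenCandidates <- function(x, k = 4L, norm = c("total", "uq")) {
    norm <- match.arg(norm)
    stopifnot(k >= 1L)
    expr <- log2(normalizeCounts(x, norm) + 1)
    filt <- zeroExpressionFilter(x)
    cond <- sampleConditions(x)
    condMeans <- vapply(unique(cond), function(co)
        rowMeans(expr[, cond == co, drop = FALSE]),
        numeric(nrow(expr)))
    score <- apply(expr, 1L, stats::sd)
    rng <- apply(condMeans, 1L, function(v) max(v) - min(v))
    tb <- data.frame(gene = rownames(expr), score = unname(score),
                     range = unname(rng),
                     status = ifelse(rownames(expr) %in% filt$kept,
                                     "kept", "excluded_zero_expression"),
                     stringsAsFactors = FALSE)
    tb$score[tb$status != "kept"] <- NA_real_
    tb$range[tb$status != "kept"] <- NA_real_
    kept <- tb[tb$status == "kept", ]
    ord <- order(kept$score, kept$range, kept$gene)
    kept$rank <- NA_integer_
    kept$rank[ord] <- seq_len(nrow(kept))
    tb$rank <- kept$rank[match(tb$gene, kept$gene)]
    nsel <- min(k, nrow(kept))
    if (k > nrow(kept))
        warning("k = ", k, " exceeds the ", nrow(kept),
                " genes passing the filter; selecting all")
    tb$selected <- !is.na(tb$rank) & tb$rank <= nsel
    tb <- tb[order(is.na(tb$rank), tb$rank, tb$gene), , drop = FALSE]
    rownames(tb) <- NULL
    new("ScreenResult", table = tb, k = as.integer(k), normMethod = norm)
}

#' Convert normalized counts to pseudo-Cq values
#'
#' Maps log2 expression onto the Cq scale (Cq = offset - log2
#' expression; one cycle per two-fold change, lower Cq = higher
#' expression) so the Cq-based stability methods can be run on RNA-Seq
#' data. This is an interpretation layer: the resulting values are not
#' instrument Cq, but their differences carry the same log2-scale
#' information the stability statistics consume.
#'
#' @param x a \linkS4class{CountExperiment}.
#' @param norm normalization method, see \code{\link{normalizeCounts}}.
#' @param offset additive constant placing pseudo-Cq in a realistic
#'   positive range (default 30).
#' @param genes optional subset of genes to convert.
#' @return a \linkS4class{CqExperiment}.
#' @export
countsToCq <- function(x, norm = c("total", "uq"), offset = 30,
                       genes = NULL) {
    norm <- match.arg(norm)
    expr <- log2(normalizeCounts(x, norm) + 1)
    if (!is.null(genes)) {
        miss <- setdiff(genes, rownames(expr))
        if (length(miss))
            stop("gene(s) absent: ", paste(miss, collapse = ", "))
        expr <- expr[genes, , drop = FALSE]
    }
    cq <- offset - expr
    if (any(cq <= 0))
        stop("offset too small: non-positive pseudo-Cq produced")
    CqExperiment(cq, condition = sampleConditions(x),
                 replicate = sampleReplicates(x),
                 sampleNames = colnames(expr))
}

#' @rdname selectedGenes
#' @param x a \linkS4class{ScreenResult}.
#' @return character vector of the selected candidate genes, best first.
#' @export
setMethod("selectedGenes", "ScreenResult", function(x) {
    tb <- x@table
    tb$gene[tb$selected]
})

setMethod("show", "ScreenResult", function(object) {
    tb <- object@table
    cat("ScreenResult (", object@normMethod, " normalization): ",
        sum(tb$status == "kept"), " kept / ",
        sum(tb$status != "kept"), " excluded\n", sep = "")
    cat("  selected:", paste(tb$gene[tb$selected], collapse = ", "),
        "\n")
})
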