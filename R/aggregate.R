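## RefFinder-style aggregation: per-method ranks are the "weights", and
## a gene's comprehensive score is the geometric mean of its ranks.

#' Convert stability scores to ranks
#'
#' Numeric scores receive ascending competition ranks ("1223" style:
#' exact ties share the smallest rank, the next distinct score skips
#' accordingly). A \linkS4class{StabilityResult} returns the ranks its
#' method's own tie policy produced (notably geNorm's final pair tied
#' at rank 1 with the next gene at rank 3).
#'
#' @param s numeric score vector (named by gene) or a
#'   \linkS4class{StabilityResult}.
#' @return rank vector named by gene.
#' @examples
#' ranksFromScores(c(a = 0.2, b = 0.2, c = 0.5))  # 1 1 3
#' @export
ranksFromScores <- function(s) {
    if (is(s, "StabilityResult")) return(geneRanks(s))
    stopifnot(is.numeric(s), all(is.finite(s)))
    stats::setNames(.competitionRanks(list(s)), names(s))
}

#' Comprehensive (geometric-mean) ranking across stability methods
#'
#' Aggregates per-method ranks into the overall comprehensive ranking:
#' each gene's score is the geometric mean of its ranks over the M >= 2
#' methods, genes are sorted ascending, and exact geometric-mean ties
#' are broken by the arithmetic mean of ranks and then by gene name
#' (annotated in \code{tie_note}).
#'
#' @param ranks one of: a named list of rank vectors (each named by
#'   gene) or \linkS4class{StabilityResult} objects; or a data.frame /
#'   matrix of rank columns with genes as rownames (as returned by
#'   \code{\link{readRankTable}}).
#' @return a \linkS4class{ComprehensiveRanking}.
#' @examples
#' comprehensiveRanking(data.frame(m1 = c(2, 1), m2 = c(8, 1),
#'                                 row.names = c("g1", "g2")))
#' @export
comprehensiveRanking <- function(ranks) {
    if (is.data.frame(ranks) || is.matrix(ranks)) {
        mat <- as.matrix(ranks)
        if (is.null(rownames(mat))) stop("rank table must name its genes")
    } else {
        if (!is.list(ranks) || length(ranks) < 2L)
            stop("need a list of >= 2 rank vectors")
        vecs <- lapply(ranks, function(r)
            if (is(r, "StabilityResult")) geneRanks(r) else r)
        genes <- names(vecs[[1L]])
        for (i in seq_along(vecs)) {
            miss <- setdiff(genes, names(vecs[[i]]))
            extra <- setdiff(names(vecs[[i]]), genes)
            if (length(miss) || length(extra))
                stop("method ", i, " does not cover the same gene set ",
                     "(missing: ", paste(miss, collapse = ", "), ")")
        }
        mat <- vapply(vecs, function(v) as.numeric(v[genes]),
                      numeric(length(genes)))
        rownames(mat) <- genes
        if (is.null(colnames(mat)))
            colnames(mat) <- paste0("method", seq_len(ncol(mat)))
    }
    if (ncol(mat) < 2L) stop("need >= 2 methods to aggregate")
    if (any(is.na(mat)))
        stop("missing rank for gene(s): ",
             paste(rownames(mat)[rowSums(is.na(mat)) > 0],
                   collapse = ", "))
    geomean <- exp(rowMeans(log(mat)))
    amean <- rowMeans(mat)
    ord <- order(geomean, amean, rownames(mat))
    tb <- data.frame(gene = rownames(mat)[ord],
                     as.data.frame(mat[ord, , drop = FALSE]),
                     geomean = geomean[ord], amean = amean[ord],
                     stringsAsFactors = FALSE, check.names = FALSE)
    tb$final_rank <- seq_len(nrow(tb))
    tied <- duplicated(tb$geomean) | duplicated(tb$geomean,
                                                fromLast = TRUE)
    tb$tie_note <- ifelse(tied, "geomean tie broken by mean rank, name",
                          "")
    rownames(tb) <- NULL
    new("ComprehensiveRanking", table = tb, methods = colnames(mat))
}

#' Sum two comprehensive rankings across datasets
#'
#' Combines the comprehensive rankings obtained from two expression
#' platforms (for example an RNA-Seq screen and a qRT-PCR panel of the
#' same candidates) by summing, per gene, both the geometric-mean
#' scores and the final ranks, then sorting ascending by summed score.
#'
#' @param c1,c2 \linkS4class{ComprehensiveRanking} objects over the
#'   same gene set.
#' @return data.frame with columns \code{gene}, \code{geomean_sum},
#'   \code{rank_sum} and \code{final_rank}.
#' @export
aggregateAcrossDatasets <- function(c1, c2) {
    stopifnot(is(c1, "ComprehensiveRanking"),
              is(c2, "ComprehensiveRanking"))
    g1 <- c1@table$gene
    g2 <- c2@table$gene
    if (!setequal(g1, g2))
        stop("gene sets differ: ",
             paste(union(setdiff(g1, g2), setdiff(g2, g1)),
                   collapse = ", "))
    i2 <- match(g1, g2)
    gs <- c1@table$geomean + c2@table$geomean[i2]
    rs <- c1@table$final_rank + c2@table$final_rank[i2]
    ord <- order(gs, rs, g1)
    out <- data.frame(gene = g1[ord], geomean_sum = gs[ord],
                      rank_sum = rs[ord],
                      final_rank = seq_along(ord),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' @rdname rankingTable
#' @param x a \linkS4class{ComprehensiveRanking}.
#' @return the aggregated table (one row per gene, best first).
#' @export
setMethod("rankingTable", "ComprehensiveRanking", function(x) x@table)

#' @rdname geneRanks
#' @export
setMethod("geneRanks", "ComprehensiveRanking", function(x, ...) {
    stats::setNames(x@table$final_rank, x@table$gene)
})

#' Most stable genes of a comprehensive ranking
#'
#' @param x a \linkS4class{ComprehensiveRanking}.
#' @param n how many genes (default 3: using at least three reference
#'   genes is the generally recommended practice).
#' @return character vector of gene names, best first.
#' @rdname recommendedGenes
#' @export
setMethod("recommendedGenes", "ComprehensiveRanking", function(x, n = 3L) {
    utils::head(x@table$gene, n)
})

setMethod("show", "ComprehensiveRanking", function(object) {
    cat("ComprehensiveRanking over", length(object@methods),
        "methods,", nrow(object@table), "genes\n")
    cat("  order:", paste(utils::head(object@table$gene, 5L),
                          collapse = " > "),
        if (nrow(object@table) > 5L) "..." else "", "\n")
})
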