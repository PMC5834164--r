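## Multi-reference 2^-ddCt relative quantification: target Cq is
## normalized against the mean Cq of the reference set (equivalent to
## the geometric mean of their linear-scale quantities under E = 2),
## fold changes are expressed relative to a calibrator condition, and
## treatments are compared by one-way ANOVA + Tukey HSD on the
## replicate-level delta-Ct values, summarized as compact letters.

#' Per-sample reference index
#'
#' The arithmetic mean of the reference genes' Cq in each sample —
#' under E = 2 this is the log2 of the geometric mean of their
#' linear-scale quantities, the standard multi-reference normalizer.
#'
#' @param x a \linkS4class{CqExperiment}.
#' @param refs reference gene identifiers (all must be present with
#'   non-missing Cq in every sample).
#' @return named numeric vector, one index value (cycles) per sample.
#' @export
referenceIndex <- function(x, refs) {
    m <- cqValues(x)
    miss <- setdiff(refs, rownames(m))
    if (length(miss))
        stop("reference gene(s) absent: ", paste(miss, collapse = ", "))
    sub <- m[refs, , drop = FALSE]
    if (any(is.na(sub))) {
        idx <- which(is.na(sub), arr.ind = TRUE)[1L, ]
        stop("missing Cq for reference gene ", refs[idx[1L]],
             " in sample ", colnames(sub)[idx[2L]])
    }
    colMeans(sub)
}

#' Relative expression by the 2^-ddCt method
#'
#' For each replicate sample, \eqn{\Delta Ct = Cq_{target} - index},
#' \eqn{\Delta\Delta Ct = \Delta Ct - mean(\Delta Ct)} over the
#' calibrator replicates, and the fold change is \eqn{2^{-\Delta\Delta
#' Ct}}. Per condition, the mean fold change and its SEM (SD of the
#' replicate fold changes / sqrt(n)) are reported; the calibrator's
#' mean fold change is 1 by construction. Tukey compact letters (on the
#' replicate delta-Ct values) are attached; see
#' \code{\link{tukeyLetters}}.
#'
#' With per-gene \code{efficiencies} supplied, Cq values are first
#' scaled by log2(E) (efficiency-corrected, Pfaffl-type quantification);
#' the default is the classic method with implicit E = 2.
#'
#' @param x a \linkS4class{CqExperiment}.
#' @param targets target gene identifiers (disjoint from \code{refs}).
#' @param refs reference gene set for the normalization index.
#' @param calibrator condition whose mean expression defines fold
#'   change 1.
#' @param efficiencies optional named per-gene amplification factors.
#' @param alpha significance level for the Tukey letters.
#' @return an \linkS4class{ExpressionResult}.
#' @export
deltaDeltaCt <- function(x, targets, refs, calibrator,
                         efficiencies = NULL, alpha = 0.05) {
    m <- cqValues(x)
    missT <- setdiff(targets, rownames(m))
    if (length(missT))
        stop("target gene(s) absent: ", paste(missT, collapse = ", "))
    if (length(intersect(targets, refs)))
        stop("targets must be disjoint from references: ",
             paste(intersect(targets, refs), collapse = ", "))
    cond <- sampleConditions(x)
    if (!calibrator %in% cond)
        stop("calibrator condition absent: ", calibrator)
    w <- .effWeights(rownames(m), efficiencies)
    mw <- m * w
    xw <- x
    SummarizedExperiment::assay(xw, "cq") <- mw
    index <- referenceIndex(xw, refs)
    repRows <- list()
    sumRows <- list()
    for (tg in targets) {
        ok <- !is.na(mw[tg, ])
        dct <- mw[tg, ok] - index[ok]
        cc <- cond[ok]
        if (!calibrator %in% cc)
            stop("no non-missing ", tg, " measurement in calibrator")
        ddct <- dct - mean(dct[cc == calibrator])
        fc <- 2^(-ddct)
        repRows[[tg]] <- data.frame(
            target = tg, sample = names(dct), condition = cc,
            delta_ct = unname(dct), delta_delta_ct = unname(ddct),
            fold_change = unname(fc), stringsAsFactors = FALSE)
        for (co in unique(cond)) {
            v <- fc[cc == co]
            sumRows[[paste(tg, co)]] <- data.frame(
                target = tg, condition = co, n = length(v),
                mean_fc = mean(v),
                sem_fc = if (length(v) > 1)
                             stats::sd(v) / sqrt(length(v)) else NA_real_,
                stringsAsFactors = FALSE)
        }
    }
    res <- new("ExpressionResult",
               summary = do.call(rbind, c(sumRows,
                                          make.row.names = FALSE)),
               replicates = do.call(rbind, c(repRows,
                                             make.row.names = FALSE)),
               calibrator = calibrator, refGenes = as.character(refs))
    lets <- tukeyLetters(res, alpha = alpha)
    key <- paste(res@summary$target, res@summary$condition)
    res@summary$letters <- lets$letters[match(key, paste(lets$target,
                                                         lets$condition))]
    res
}

#' Tukey HSD compact-letter display per target gene
#'
#' One-way ANOVA on the replicate-level delta-Ct values (log scale,
#' where residuals are closest to homoscedastic normal), Tukey HSD on
#' all condition pairs, then the insert-and-absorb compact-letter
#' algorithm: two conditions share a letter if and only if they are not
#' significantly different. Letters are assigned so that "a" belongs to
#' the condition with the highest mean fold change.
#'
#' If every condition has zero within-group variance, conditions with
#' unequal means are treated as significantly different (no numerical
#' failure).
#'
#' @param e an \linkS4class{ExpressionResult}.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with columns \code{target}, \code{condition},
#'   \code{letters}.
#' @export
tukeyLetters <- function(e, alpha = 0.05) {
    stopifnot(is(e, "ExpressionResult"))
    rep <- e@replicates
    out <- list()
    for (tg in unique(rep$target)) {
        d <- rep[rep$target == tg, ]
        tab <- table(d$condition)
        if (length(tab) < 2L || any(tab < 2L))
            stop("need >= 2 conditions with >= 2 replicates for ", tg)
        ## order conditions by decreasing mean FC (= increasing mean dCt
        ## relative to calibrator); "a" goes to the highest expression
        mfc <- tapply(d$fold_change, d$condition, mean)
        condOrder <- names(sort(mfc, decreasing = TRUE))
        p <- .tukeyPvalues(d$delta_ct, d$condition)
        sig <- p < alpha
        lets <- .compactLetters(sig, condOrder)
        out[[tg]] <- data.frame(target = tg, condition = condOrder,
                                letters = lets[condOrder],
                                stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, make.row.names = FALSE))
}

## symmetric matrix of Tukey HSD adjusted p-values over condition pairs
.tukeyPvalues <- function(values, groups) {
    groups <- factor(groups)
    lv <- levels(groups)
    p <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
    wss <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
    if (wss <= .Machine$double.eps * sum(values^2) + 1e-300) {
        ## degenerate: zero within-group variance everywhere
        mu <- tapply(values, groups, mean)
        for (i in seq_along(lv)) for (j in seq_along(lv))
            p[i, j] <- as.numeric(mu[i] == mu[j])
        diag(p) <- 1
        return(p)
    }
    fit <- stats::aov(values ~ groups)
    tk <- stats::TukeyHSD(fit)$groups
    prs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (k in seq_len(nrow(tk))) {
        a <- prs[[k]][1L]; b <- prs[[k]][2L]
        p[a, b] <- p[b, a] <- tk[k, "p adj"]
    }
    p
}

## insert-and-absorb compact letter display.
## sig: symmetric logical matrix (TRUE = significantly different);
## condOrder: groups ordered so the first receives letter "a".
.compactLetters <- function(sig, condOrder) {
    cols <- list(condOrder)              # start: all groups together
    for (i in seq_along(condOrder)) {
        for (j in seq_along(condOrder)) {
            if (j <= i) next
            a <- condOrder[i]; b <- condOrder[j]
            if (!sig[a, b]) next
            newCols <- list()
            for (col in cols) {
                if (a %in% col && b %in% col) {
                    newCols <- c(newCols, list(setdiff(col, a)),
                                 list(setdiff(col, b)))
                } else newCols <- c(newCols, list(col))
            }
            ## absorb: drop columns that are subsets of another column
            keep <- rep(TRUE, length(newCols))
            for (u in seq_along(newCols)) {
                for (v in seq_along(newCols)) {
                    if (u == v || !keep[u]) next
                    if (all(newCols[[u]] %in% newCols[[v]]) &&
                        (length(newCols[[u]]) < length(newCols[[v]]) ||
                         (u > v && length(newCols[[u]]) ==
                                   length(newCols[[v]])))) {
                        keep[u] <- FALSE
                        break
                    }
                }
            }
            cols <- newCols[keep]
        }
    }
    ## letter columns ordered by their best (earliest) member
    first <- vapply(cols, function(col)
        min(match(col, condOrder)), numeric(1))
    cols <- cols[order(first)]
    letters1 <- c(letters, paste0(rep(letters, each = 26),
                                  rep(letters, 26)))
    lab <- vapply(condOrder, function(g) {
        idx <- which(vapply(cols, function(col) g %in% col, logical(1)))
        paste(letters1[idx], collapse = "")
    }, character(1))
    lab
}

#' @rdname expressionSummary
#' @param x an \linkS4class{ExpressionResult}.
#' @return per-(target, condition) summary data.frame with mean fold
#'   change, SEM, replicate count and Tukey letters.
#' @export
setMethod("expressionSummary", "ExpressionResult", function(x) x@summary)

setMethod("show", "ExpressionResult", function(object) {
    cat("ExpressionResult: ", length(unique(object@summary$target)),
        " target(s), calibrator '", object@calibrator, "', refs: ",
        paste(object@refGenes, collapse = ", "), "\n", sep = "")
})
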