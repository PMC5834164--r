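#' Build a CqExperiment from a Cq matrix and sample metadata
#'
#' @param cq numeric matrix of Cq values, genes in rows (rownames = gene
#'   identifiers), replicate samples in columns. \code{NA} marks a
#'   missing measurement.
#' @param condition condition label per sample (length = ncol(cq)).
#' @param replicate integer replicate index per sample (>= 1; unique
#'   within each condition). Defaults to 1, 2, ... within condition.
#' @param sampleNames optional sample identifiers; defaults to
#'   \code{condition_replicate}, the convention when samples are known
#'   only by treatment and replicate.
#'
#' @return a validated \linkS4class{CqExperiment}.
#' @examples
#' cq <- matrix(c(20, 21, 20.5, 21.5), 2,
#'              dimnames = list(c("g1", "g2"), NULL))
#' CqExperiment(cq, condition = c("A", "A"), replicate = 1:2)
#' @export
CqExperiment <- function(cq, condition, replicate = NULL,
                         sampleNames = NULL) {
    cq <- as.matrix(cq)
    storage.mode(cq) <- "double"
    if (is.null(rownames(cq)))
        stop("'cq' must have gene identifiers as rownames")
    condition <- as.character(condition)
    if (length(condition) != ncol(cq))
        stop("'condition' must have one entry per sample")
    if (is.null(replicate)) {
        replicate <- stats::ave(seq_along(condition), condition,
                                FUN = seq_along)
    }
    replicate <- as.integer(replicate)
    if (is.null(sampleNames))
        sampleNames <- paste(condition, replicate, sep = "_")
    colnames(cq) <- sampleNames
    se <- SummarizedExperiment(
        assays = list(cq = cq),
        colData = DataFrame(condition = condition, replicate = replicate,
                            row.names = sampleNames))
    new("CqExperiment", se)
}

#' Build a CountExperiment from a count matrix and sample metadata
#'
#' @param counts matrix of non-negative integral read counts, genes in
#'   rows, samples in columns.
#' @param condition,replicate per-sample metadata as in
#'   \code{\link{CqExperiment}}.
#' @param sampleNames optional sample identifiers.
#'
#' @return a validated \linkS4class{CountExperiment}.
#' @export
CountExperiment <- function(counts, condition, replicate = NULL,
                            sampleNames = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("'counts' must have gene identifiers as rownames")
    condition <- as.character(condition)
    if (length(condition) != ncol(counts))
        stop("'condition' must have one entry per sample")
    if (is.null(replicate))
        replicate <- stats::ave(seq_along(condition), condition,
                                FUN = seq_along)
    replicate <- as.integer(replicate)
    if (is.null(sampleNames)) {
        sampleNames <- colnames(counts)
        if (is.null(sampleNames))
            sampleNames <- paste(condition, replicate, sep = "_")
    }
    colnames(counts) <- sampleNames
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(condition = condition, replicate = replicate,
                            row.names = sampleNames))
    new("CountExperiment", se)
}

#' Extract the Cq assay
#' @param x a \linkS4class{CqExperiment}.
#' @return numeric matrix of Cq values (genes x samples).
#' @rdname cqValues
#' @export
setMethod("cqValues", "CqExperiment", function(x) assay(x, "cq"))

#' Per-sample condition and replicate metadata
#' @param x a \linkS4class{CqExperiment} or \linkS4class{CountExperiment}.
#' @return character vector of condition labels (or integer replicate
#'   indices), named by sample.
#' @rdname sampleConditions
#' @export
setMethod("sampleConditions", "SummarizedExperiment", function(x) {
    stats::setNames(as.character(colData(x)$condition), colnames(x))
})

#' @rdname sampleConditions
#' @export
setMethod("sampleReplicates", "SummarizedExperiment", function(x) {
    stats::setNames(as.integer(colData(x)$replicate), colnames(x))
})

setMethod("show", "CqExperiment", function(object) {
    cd <- colData(object)
    cat("CqExperiment:", nrow(object), "genes x", ncol(object),
        "samples\n")
    cat("  conditions:", paste(unique(cd$condition), collapse = ", "),
        "\n")
    nm <- sum(is.na(assay(object, "cq")))
    if (nm > 0) cat("  missing Cq cells:", nm, "\n")
})

setMethod("show", "CountExperiment", function(object) {
    cd <- colData(object)
    cat("CountExperiment:", nrow(object), "genes x", ncol(object),
        "samples\n")
    cat("  conditions:", paste(unique(cd$condition), collapse = ", "),
        "\n")
    ls <- colSums(assay(object, "counts"))
    cat("  library sizes:", min(ls), "-", max(ls), "\n")
})

#' Validated per-gene amplification efficiencies
#'
#' The amplification efficiency E is the per-cycle amplification factor:
#' E = 2 is perfect doubling (often reported as 100 percent). Values may
#' be given either as factors in (1, 2] or in percent in (0, 100], which
#' are converted to factors via E = 1 + percent/100.
#'
#' @param genes gene identifiers.
#' @param E efficiencies, one per gene or a single value recycled;
#'   default 2 (perfect doubling).
#' @param percent logical; if TRUE, \code{E} is interpreted as percent.
#'
#' @return named numeric vector of per-cycle amplification factors.
#' @examples
#' geneEfficiencies(c("GR", "Act-1"), E = c(80, 89), percent = TRUE)
#' @export
geneEfficiencies <- function(genes, E = 2, percent = FALSE) {
    if (percent) {
        if (any(E <= 0 | E > 100))
            stop("percent efficiencies must lie in (0, 100]")
        E <- 1 + E / 100
    }
    E <- rep_len(as.numeric(E), length(genes))
    if (any(!is.finite(E)) || any(E <= 1 | E > 2))
        stop("amplification factors must lie in (1, 2]")
    stats::setNames(E, genes)
}
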