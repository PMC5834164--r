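## Readers and writers for the tabular formats the pipeline exchanges:
## long-format Cq tables, count matrices with sample metadata, rank
## tables, and TSV result tables with fixed 6-significant-digit floats.

.detectSep <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) "\t" else ","
}

.normHeader <- function(x) tolower(trimws(x))

#' Read a long-format Cq table
#'
#' Expects a delimited text file (TSV or CSV, auto-detected) with
#' columns \code{gene}, \code{condition}, \code{replicate}, \code{cq}
#' and optionally \code{sample} (case-insensitive header match). When
#' \code{sample} is absent, sample identifiers are formed as
#' \code{condition_replicate}. The literal fields \code{NA} or empty
#' Cq cells are recorded as missing.
#'
#' @param path path to the file.
#' @param sep field separator; \code{NULL} (default) auto-detects tab
#'   versus comma from the header line.
#'
#' @return a \linkS4class{CqExperiment}. Row order of the input file
#'   never affects downstream statistics: genes and samples are ordered
#'   by first appearance, and all statistics are computed from the
#'   resulting matrix.
#' @export
readCqTable <- function(path, sep = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(sep)) sep <- .detectSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "\"", comment.char = "")
    names(df) <- .normHeader(names(df))
    for (col in c("gene", "condition", "replicate", "cq"))
        if (!col %in% names(df))
            stop("format error: missing column '", col, "'")
    if (!"sample" %in% names(df))
        df$sample <- paste(df$condition, df$replicate, sep = "_")
    cqChr <- trimws(df$cq)
    missing <- is.na(cqChr) | cqChr %in% c("", "NA", "NaN", "na")
    cqNum <- suppressWarnings(as.numeric(cqChr))
    bad <- which(!missing & is.na(cqNum))
    if (length(bad))
        stop("parse error: non-numeric Cq '", cqChr[bad[1]],
             "' at data row ", bad[1])
    cqNum[missing] <- NA_real_
    repNum <- suppressWarnings(as.integer(df$replicate))
    if (any(is.na(repNum)))
        stop("parse error: non-integer replicate at data row ",
             which(is.na(repNum))[1])
    if (anyDuplicated(paste(df$gene, df$sample, sep = "\r"))) {
        d <- df[duplicated(paste(df$gene, df$sample, sep = "\r")), ]
        stop("integrity error: duplicate (gene, sample) entry: ",
             d$gene[1], ", ", d$sample[1])
    }
    genes <- unique(df$gene)
    samples <- unique(df$sample)
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(df$gene, genes), match(df$sample, samples))] <- cqNum
    cond <- df$condition[match(samples, df$sample)]
    repl <- repNum[match(samples, df$sample)]
    CqExperiment(m, condition = cond, replicate = repl,
                 sampleNames = samples)
}

#' Read an RNA-Seq count matrix with sample metadata
#'
#' @param path count matrix file: genes in rows, samples in columns,
#'   first header token \code{gene} (TSV or CSV, auto-detected).
#' @param metaPath metadata file with columns \code{sample},
#'   \code{condition}, \code{replicate}.
#'
#' @return a \linkS4class{CountExperiment} with samples in matrix
#'   column order.
#' @export
readCountMatrix <- function(path, metaPath) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (!file.exists(metaPath)) stop("file not found: ", metaPath)
    sep <- .detectSep(path)
    m <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
    if (.normHeader(names(m)[1]) != "gene")
        stop("format error: first column must be 'gene'")
    genes <- as.character(m[[1]])
    mat <- as.matrix(m[, -1, drop = FALSE])
    if (!is.numeric(mat))
        stop("parse error: non-numeric count values")
    if (any(mat < 0) || any(mat != round(mat)))
        stop("parse error: counts must be non-negative integers")
    rownames(mat) <- genes
    meta <- utils::read.table(metaPath, header = TRUE,
                              sep = .detectSep(metaPath),
                              stringsAsFactors = FALSE, check.names = FALSE)
    names(meta) <- .normHeader(names(meta))
    for (col in c("sample", "condition", "replicate"))
        if (!col %in% names(meta))
            stop("format error: metadata missing column '", col, "'")
    unknown <- setdiff(meta$sample, colnames(mat))
    if (length(unknown))
        stop("integrity error: metadata sample(s) absent from matrix: ",
             paste(unknown, collapse = ", "))
    absent <- setdiff(colnames(mat), meta$sample)
    if (length(absent))
        stop("integrity error: matrix sample(s) absent from metadata: ",
             paste(absent, collapse = ", "))
    idx <- match(colnames(mat), meta$sample)
    CountExperiment(mat, condition = meta$condition[idx],
                    replicate = as.integer(meta$replicate[idx]),
                    sampleNames = colnames(mat))
}

#' Read a table of pre-computed per-method ranks
#'
#' Accepts a delimited file with a \code{gene} column followed by one
#' numeric rank column per method (for instance, rank columns
#' transcribed from a published comparison), suitable for direct
#' aggregation with \code{\link{comprehensiveRanking}}.
#'
#' @param path path to the file.
#' @return data.frame with rownames = genes and one numeric column per
#'   method.
#' @export
readRankTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                            stringsAsFactors = FALSE, check.names = FALSE)
    names(df)[1] <- .normHeader(names(df)[1])
    if (names(df)[1] != "gene")
        stop("format error: first column must be 'gene'")
    out <- df[, -1, drop = FALSE]
    rownames(out) <- df$gene
    if (!all(vapply(out, is.numeric, logical(1))))
        stop("parse error: rank columns must be numeric")
    out
}

## fixed float formatting: 6 significant digits, re-read bit-identically
.fmtCol <- function(x) {
    if (is.double(x)) {
        out <- vapply(x, function(v) {
            if (is.na(v)) "NA" else format(signif(v, 6), scientific = FALSE)
        }, character(1))
        out
    } else as.character(x)
}

.writeTsv <- function(df, path) {
    out <- as.data.frame(lapply(df, .fmtCol), check.names = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = names(df))
    names(out) <- names(df)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df) > 0)
        utils::write.table(out, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    invisible(NULL)
}

#' Write a result table as TSV
#'
#' Writes with a stable column order and fixed float formatting (6
#' significant digits) so that re-reading reproduces the values exactly
#' at that precision. Stability results are written sorted by rank and
#' then gene name.
#'
#' @param x a result object or plain data.frame.
#' @param path output path.
#' @param ... unused.
#' @return invisibly, the path written.
#' @rdname writeResultTable
#' @export
setMethod("writeResultTable", "data.frame", function(x, path, ...) {
    .writeTsv(x, path)
    invisible(path)
})

#' @rdname writeResultTable
#' @export
setMethod("writeResultTable", "StabilityResult", function(x, path, ...) {
    tb <- x@table
    tb <- tb[order(tb$rank, tb$gene), , drop = FALSE]
    .writeTsv(tb, path)
    invisible(path)
})

#' @rdname writeResultTable
#' @export
setMethod("writeResultTable", "ComprehensiveRanking",
    function(x, path, ...) {
        .writeTsv(x@table, path)
        invisible(path)
    })

#' @rdname writeResultTable
#' @export
setMethod("writeResultTable", "ExpressionResult", function(x, path, ...) {
    .writeTsv(x@summary, path)
    invisible(path)
})

#' @rdname writeResultTable
#' @export
setMethod("writeResultTable", "ScreenResult", function(x, path, ...) {
    .writeTsv(x@table, path)
    invisible(path)
})

#' Write a CqExperiment back to long format
#'
#' Inverse of \code{\link{readCqTable}}; missing cells are written as
#' \code{NA}.
#'
#' @param x a \linkS4class{CqExperiment}.
#' @param path output path (TSV).
#' @return invisibly, the path written.
#' @export
writeCqTable <- function(x, path) {
    stopifnot(is(x, "CqExperiment"))
    m <- cqValues(x)
    df <- data.frame(
        gene = rep(rownames(m), times = ncol(m)),
        sample = rep(colnames(m), each = nrow(m)),
        condition = rep(sampleConditions(x), each = nrow(m)),
        replicate = rep(sampleReplicates(x), each = nrow(m)),
        cq = as.vector(m),
        stringsAsFactors = FALSE)
    .writeTsv(df, path)
    invisible(path)
}

#' Write a CountExperiment as matrix + metadata files
#'
#' @param x a \linkS4class{CountExperiment}.
#' @param path output path for the count matrix (TSV, genes in rows).
#' @param metaPath output path for the sample metadata (TSV).
#' @return invisibly, \code{c(path, metaPath)}.
#' @export
writeCountMatrix <- function(x, path, metaPath) {
    stopifnot(is(x, "CountExperiment"))
    m <- assay(x, "counts")
    df <- data.frame(gene = rownames(m), as.data.frame(m,
        check.names = FALSE), check.names = FALSE,
        stringsAsFactors = FALSE)
    .writeTsv(df, path)
    meta <- data.frame(sample = colnames(m),
                       condition = sampleConditions(x),
                       replicate = sampleReplicates(x),
                       stringsAsFactors = FALSE)
    .writeTsv(meta, metaPath)
    invisible(c(path, metaPath))
}
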