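## Orchestration of the full reference-gene workflow:
## screen (counts) -> four stability methods (Cq) -> comprehensive
## ranking (optionally on both platforms, summed) -> 2^-ddCt validation
## of target genes against the recommended reference set.

.stageRun <- function(record, name, outDir, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
        if (!is.null(outDir))
            writeLines(paste0("FAILED at stage: ", name, "\n",
                              conditionMessage(res)),
                       file.path(outDir, "FAILED"))
        stop("stage '", name, "': ", conditionMessage(res),
             call. = FALSE)
    }
    record[[name]] <- res
    record
}

#' Run the full reference-gene selection workflow
#'
#' Executes, in order: the RNA-Seq candidate screen (when counts are
#' given), the four Cq stability methods on the candidate panel, the
#' comprehensive geometric-mean ranking (on qPCR data, and additionally
#' on pseudo-Cq RNA-Seq data with a summed cross-platform table when
#' counts cover the panel), and the 2^-ddCt validation of target genes
#' (when targets are given) normalized by the recommended reference
#' set. Stages that lack their inputs are recorded as
#' \code{"skipped"}. When \code{outDir} is given every stage writes its
#' TSV table plus a machine-readable JSON summary; on a stage failure
#' the partial outputs are retained next to a \code{FAILED} marker
#' naming the stage.
#'
#' @param cq a \linkS4class{CqExperiment} or path to a long-format Cq
#'   table.
#' @param counts optional \linkS4class{CountExperiment} or path to a
#'   count matrix (then \code{countsMeta} must be the metadata path).
#' @param countsMeta metadata path when \code{counts} is a path.
#' @param targets target genes for the validation stage (default: none).
#' @param refs reference set for validation; default: the top
#'   \code{nRefs} genes of the comprehensive ranking.
#' @param calibrator calibrator condition for fold changes; default:
#'   the first condition of the Cq table.
#' @param k candidates to select in the screen stage.
#' @param nRefs size of the recommended reference set (default 3; at
#'   least three reference genes are generally recommended).
#' @param alpha significance level for Tukey letters.
#' @param norm count normalization method.
#' @param efficiencies optional named per-gene amplification factors.
#' @param outDir optional output directory for TSV/JSON artifacts.
#' @param seed seed recorded in the run (the pipeline itself is
#'   deterministic).
#' @return a \linkS4class{PipelineRun}.
#' @export
runPipeline <- function(cq, counts = NULL, countsMeta = NULL,
                        targets = character(0), refs = NULL,
                        calibrator = NULL, k = 4L, nRefs = 3L,
                        alpha = 0.05, norm = "total",
                        efficiencies = NULL, outDir = NULL,
                        seed = 1L) {
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    st <- list()
    st <- .stageRun(st, "read_cq_table", outDir, {
        if (is.character(cq)) readCqTable(cq) else {
            stopifnot(is(cq, "CqExperiment")); cq
        }
    })
    cqx <- st$read_cq_table
    if (is.null(calibrator))
        calibrator <- sampleConditions(cqx)[1L]
    if (!is.null(counts)) {
        st <- .stageRun(st, "read_count_matrix", outDir, {
            if (is.character(counts)) readCountMatrix(counts, countsMeta)
            else { stopifnot(is(counts, "CountExperiment")); counts }
        })
        st <- .stageRun(st, "screen", outDir,
                        screenCandidates(st$read_count_matrix, k = k,
                                         norm = norm))
    } else {
        st$read_count_matrix <- "skipped"
        st$screen <- "skipped"
    }
    panel <- setdiff(rownames(cqx), targets)
    cqPanel <- cqx[panel, ]
    st <- .stageRun(st, "cq_spread", outDir, cqSpread(cqPanel))
    st <- .stageRun(st, "stability", outDir, list(
        deltaCt = deltaCtStability(cqPanel, efficiencies),
        BestKeeper = bestKeeper(cqPanel),
        NormFinder = normFinder(cqPanel),
        geNorm = geNorm(cqPanel, efficiencies)))
    st <- .stageRun(st, "comprehensive", outDir,
                    comprehensiveRanking(st$stability))
    if (!identical(st$read_count_matrix, "skipped") &&
        all(panel %in% rownames(st$read_count_matrix))) {
        st <- .stageRun(st, "rnaseq_ranking", outDir, {
            pc <- countsToCq(st$read_count_matrix, norm = norm,
                             genes = panel)
            comprehensiveRanking(list(
                deltaCt = deltaCtStability(pc),
                BestKeeper = bestKeeper(pc),
                NormFinder = normFinder(pc),
                geNorm = geNorm(pc)))
        })
        st <- .stageRun(st, "cross_platform", outDir,
                        aggregateAcrossDatasets(st$comprehensive,
                                                st$rnaseq_ranking))
    } else {
        st$rnaseq_ranking <- "skipped"
        st$cross_platform <- "skipped"
    }
    if (is.null(refs))
        refs <- recommendedGenes(st$comprehensive, nRefs)
    if (length(targets)) {
        st <- .stageRun(st, "expression", outDir,
                        deltaDeltaCt(cqx, targets = targets,
                                     refs = refs,
                                     calibrator = calibrator,
                                     efficiencies = efficiencies,
                                     alpha = alpha))
    } else st$expression <- "skipped"

    cfg <- list(targets = targets, refs = refs, calibrator = calibrator,
                k = k, nRefs = nRefs, alpha = alpha, norm = norm,
                efficiencies = efficiencies)
    outputs <- character(0)
    if (!is.null(outDir)) {
        wr <- function(obj, name) {
            p <- file.path(outDir, name)
            writeResultTable(obj, p)
            p
        }
        outputs <- c(outputs, wr(st$cq_spread, "cq_spread.tsv"))
        for (mn in names(st$stability))
            outputs <- c(outputs, wr(st$stability[[mn]],
                                     paste0("stability_", tolower(mn),
                                            ".tsv")))
        outputs <- c(outputs, wr(st$comprehensive, "comprehensive.tsv"))
        if (!identical(st$rnaseq_ranking, "skipped")) {
            outputs <- c(outputs,
                         wr(st$rnaseq_ranking, "comprehensive_rnaseq.tsv"),
                         wr(st$cross_platform, "cross_platform.tsv"))
        }
        if (!identical(st$screen, "skipped"))
            outputs <- c(outputs, wr(st$screen, "screen.tsv"))
        if (!identical(st$expression, "skipped"))
            outputs <- c(outputs, wr(st$expression, "expression.tsv"))
        summaryJson <- file.path(outDir, "summary.json")
        jsonlite::write_json(list(
            recommended_references = refs,
            comprehensive_order = st$comprehensive@table$gene,
            stages = stats::setNames(lapply(names(st), function(n)
                if (identical(st[[n]], "skipped")) "skipped" else "ok"),
                names(st)),
            seed = seed, config = cfg[!vapply(cfg, is.null, logical(1))]),
            summaryJson, auto_unbox = TRUE, digits = NA)
        outputs <- c(outputs, summaryJson)
    }
    new("PipelineRun", stages = st, config = cfg,
        seed = as.integer(seed), outputs = outputs)
}

#' Render a markdown report of a pipeline run
#'
#' Produces a deterministic human-readable report: the per-gene Cq
#' spread summary, the four stability-method tables, the comprehensive
#' ranking (per-method columns side by side), and, when available, the
#' screen and the validation fold-change table with Tukey letters.
#' Sections whose stage was skipped or unavailable are marked so.
#'
#' @param run a \linkS4class{PipelineRun}.
#' @param path optional file to write the report to.
#' @return character vector of markdown lines (invisibly when
#'   \code{path} is given).
#' @export
renderReport <- function(run, path = NULL) {
    stopifnot(is(run, "PipelineRun"))
    st <- run@stages
    mdTable <- function(df) {
        num <- vapply(df, is.double, logical(1))
        df[num] <- lapply(df[num], function(v) signif(v, 4))
        hdr <- paste("|", paste(names(df), collapse = " | "), "|")
        sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "),
                     "|")
        rows <- apply(df, 1L, function(r)
            paste("|", paste(r, collapse = " | "), "|"))
        c(hdr, sep, rows)
    }
    section <- function(title, obj, fmt) {
        if (is.null(obj) || identical(obj, "skipped"))
            c(paste("##", title), "", "_unavailable_", "")
        else c(paste("##", title), "", fmt(obj), "")
    }
    out <- c("# Reference gene stability report", "")
    out <- c(out, section("Cq spread (per gene)", st$cq_spread, mdTable))
    if (!identical(st$stability, "skipped") && !is.null(st$stability)) {
        for (mn in names(st$stability))
            out <- c(out, section(paste("Stability:", mn),
                                  stabilityTable(st$stability[[mn]]),
                                  mdTable))
    }
    out <- c(out, section("Comprehensive ranking",
                          if (is.null(st$comprehensive) ||
                              identical(st$comprehensive, "skipped"))
                              "skipped" else rankingTable(st$comprehensive),
                          mdTable))
    out <- c(out, section("RNA-Seq screen",
                          if (identical(st$screen, "skipped")) "skipped"
                          else st$screen@table, mdTable))
    out <- c(out, section("Cross-platform summed ranking",
                          st$cross_platform, mdTable))
    out <- c(out, section("Relative expression (2^-ddCt)",
                          if (identical(st$expression, "skipped"))
                              "skipped"
                          else expressionSummary(st$expression), mdTable))
    out <- c(out, paste("_recommended references:",
                        paste(run@config$refs, collapse = ", "), "_"))
    if (!is.null(path)) {
        writeLines(out, path)
        return(invisible(out))
    }
    out
}

setMethod("show", "PipelineRun", function(object) {
    ok <- vapply(object@stages, function(s)
        if (identical(s, "skipped")) "skipped" else "ok", character(1))
    cat("PipelineRun (seed ", object@seed, ")\n", sep = "")
    for (n in names(ok)) cat("  ", n, ": ", ok[[n]], "\n", sep = "")
})
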