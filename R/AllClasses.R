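#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' CqExperiment: replicate-level quantification-cycle measurements
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"cq"}
#' (genes in rows, replicate samples in columns) with mandatory column
#' metadata \code{condition} (treatment label) and \code{replicate}
#' (integer index, >= 1, unique within a condition). Missing Cq values
#' are stored as \code{NA}; each downstream stability method applies its
#' own missing-data policy.
#'
#' Cq is on the PCR-cycle scale: one cycle is approximately a two-fold
#' change in template, and a lower Cq means higher expression.
#'
#' @export
setClass("CqExperiment", contains = "SummarizedExperiment")

setValidity("CqExperiment", function(object) {
    msg <- character()
    if (!("cq" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'cq' is required")
    cd <- colData(object)
    if (!all(c("condition", "replicate") %in% colnames(cd)))
        return("colData must contain 'condition' and 'replicate'")
    rep <- cd$replicate
    if (any(is.na(rep)) || any(rep < 1L) || any(rep != as.integer(rep)))
        msg <- c(msg, "replicate indices must be integers >= 1")
    ## replicate indices must not repeat within a condition
    key <- paste(cd$condition, rep, sep = "\r")
    if (anyDuplicated(key))
        msg <- c(msg, "duplicated (condition, replicate) pair")
    if (length(msg) == 0L) {
        cq <- assay(object, "cq")
        if (any(!is.na(cq) & !is.finite(cq)))
            msg <- c(msg, "non-finite Cq values must be coded NA")
    }
    if (length(msg)) msg else TRUE
})

#' CountExperiment: RNA-Seq gene x sample read counts
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"counts"}
#' of non-negative integral read counts and column metadata
#' \code{condition} and \code{replicate}. At least two conditions are
#' required and every library size (column sum) must be positive.
#'
#' @export
setClass("CountExperiment", contains = "SummarizedExperiment")

setValidity("CountExperiment", function(object) {
    msg <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'counts' is required")
    cd <- colData(object)
    if (!all(c("condition", "replicate") %in% colnames(cd)))
        return("colData must contain 'condition' and 'replicate'")
    k <- assay(object, "counts")
    if (any(is.na(k)) || any(k < 0) || any(k != round(k)))
        msg <- c(msg, "counts must be non-negative integers")
    if (length(unique(cd$condition)) < 2L)
        msg <- c(msg, "at least two conditions are required")
    if (length(msg) == 0L && any(colSums(k) <= 0))
        msg <- c(msg, paste("zero library size for sample(s):",
                            paste(colnames(k)[colSums(k) <= 0], collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' StabilityResult: one stability method's statistics and ranks
#'
#' @slot method method identifier ("geNorm", "deltaCt", "BestKeeper",
#'   "NormFinder" or "screen-derived pseudo methods").
#' @slot table per-gene statistics: always columns \code{gene},
#'   \code{value} (the method's stability statistic, lower = more stable)
#'   and \code{rank}; plus method-specific auxiliary columns (BestKeeper:
#'   \code{cv}, \code{r}; geNorm: \code{m_first}, \code{excluded_at},
#'   \code{tied_pair}; NormFinder: per-group bias and SD summaries).
#'
#' @export
setClass("StabilityResult",
    representation(method = "character", table = "data.frame"))

setValidity("StabilityResult", function(object) {
    tb <- object@table
    need <- c("gene", "value", "rank")
    if (!all(need %in% colnames(tb)))
        return("table must contain gene, value and rank columns")
    if (anyDuplicated(tb$gene)) return("duplicated gene in table")
    TRUE
})

#' ComprehensiveRanking: RefFinder-style aggregated ranking
#'
#' @slot table one row per gene: per-method rank columns, \code{geomean}
#'   (geometric mean of ranks), \code{final_rank} and \code{tie_note}.
#' @slot methods the method identifiers that were aggregated.
#'
#' @export
setClass("ComprehensiveRanking",
    representation(table = "data.frame", methods = "character"))

#' ExpressionResult: multi-reference 2^-ddCt quantification
#'
#' @slot summary per (target, condition): mean fold change, SEM of the
#'   replicate fold changes, replicate count and Tukey letter(s).
#' @slot replicates replicate-level delta-Ct and fold-change values.
#' @slot calibrator calibrator condition (mean fold change 1 by
#'   construction).
#' @slot refGenes reference gene set whose mean Cq formed the
#'   normalization index.
#'
#' @export
setClass("ExpressionResult",
    representation(summary = "data.frame", replicates = "data.frame",
                   calibrator = "character", refGenes = "character"))

#' ScreenResult: RNA-Seq candidate reference-gene screen
#'
#' @slot table per gene: stability \code{score} (SD of log2 expression
#'   across samples), \code{range} (max - min of per-condition mean log2
#'   expression), \code{status} ("kept" or "excluded_zero_expression"),
#'   \code{selected} flag for the top-k, and \code{rank} among kept genes.
#' @slot k number of candidates requested.
#' @slot normMethod library-size normalization used.
#'
#' @export
setClass("ScreenResult",
    representation(table = "data.frame", k = "integer",
                   normMethod = "character"))

#' SimulationConfig: generative model for synthetic Cq tables and counts
#'
#' Describes a hatching-style time-course design: condition labels, the
#' number of qPCR and RNA-Seq replicates, and a gene roster assigning
#' each gene a role with its generative parameters. See
#' \code{\link{simulateCq}} for the generative equations.
#'
#' @slot conditions ordered condition labels.
#' @slot cqReplicates qPCR replicates per condition.
#' @slot countReplicates RNA-Seq replicates per condition.
#' @slot roster data.frame with columns \code{gene}, \code{role} (one of
#'   stable, variable, drift, pulse, dropout), \code{baseCq},
#'   \code{amplitude} (pulse: log2 fold change; drift: total trend in
#'   cycles; variable: SD of per-condition effects in cycles),
#'   \code{conditions} (comma-separated target conditions for pulse or
#'   dropout roles), \code{extraNoise} (additional per-gene technical SD,
#'   cycles), \code{meanExpr} (relative linear-scale expression used for
#'   count simulation).
#' @slot sigmaTech technical replicate SD on the Cq scale (cycles).
#' @slot sigmaLoad per-sample loading-offset SD (cycles).
#' @slot dispersion negative-binomial dispersion for count simulation.
#' @slot libSizeRange min/max RNA-Seq library size.
#'
#' @export
setClass("SimulationConfig",
    representation(conditions = "character", cqReplicates = "integer",
                   countReplicates = "integer", roster = "data.frame",
                   sigmaTech = "numeric", sigmaLoad = "numeric",
                   dispersion = "numeric", libSizeRange = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (length(object@conditions) < 1L || anyDuplicated(object@conditions))
        msg <- c(msg, "conditions must be non-empty and unique")
    ro <- object@roster
    need <- c("gene", "role", "baseCq", "amplitude", "conditions",
              "extraNoise", "meanExpr")
    if (!all(need %in% colnames(ro)))
        msg <- c(msg, paste("roster must contain columns:",
                            paste(need, collapse = ", ")))
    else {
        if (nrow(ro) < 1L) msg <- c(msg, "roster must be non-empty")
        if (anyDuplicated(ro$gene)) msg <- c(msg, "duplicated roster gene")
        ok <- ro$role %in% c("stable", "variable", "drift", "pulse", "dropout")
        if (!all(ok))
            msg <- c(msg, paste("unknown role(s):",
                                paste(unique(ro$role[!ok]), collapse = ", ")))
        if (any(!is.finite(ro$amplitude)))
            msg <- c(msg, "amplitudes must be finite")
    }
    if (object@sigmaTech < 0 || object@sigmaLoad < 0)
        msg <- c(msg, "sigmaTech and sigmaLoad must be >= 0")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    if (length(object@libSizeRange) != 2L ||
        any(object@libSizeRange <= 0) ||
        diff(object@libSizeRange) < 0)
        msg <- c(msg, "libSizeRange must be an increasing positive pair")
    if (length(msg)) msg else TRUE
})

#' PipelineRun: record of a full reference-gene workflow run
#'
#' Captures everything needed to reproduce a run: the configuration,
#' the per-stage results (or a "skipped"/"FAILED" marker), and the seed.
#'
#' @slot stages named list of stage results.
#' @slot config the run configuration (named list snapshot).
#' @slot seed integer seed used for any randomized stage.
#' @slot outputs named character vector of files written (may be empty).
#'
#' @export
setClass("PipelineRun",
    representation(stages = "list", config = "list", seed = "integer",
                   outputs = "character"))
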