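## Seeded generators for Cq tables and RNA-Seq count matrices with a
## known ground truth, emulating a cyst-nematode hatching time-course:
## eight developmental conditions, triplicate qPCR, duplicate RNA-Seq,
## planted stable references, stage-responsive pulse genes, a drifting
## pseudo-reference, additive per-sample loading offsets on the Cq
## scale, and optional condition-level dropout genes for the
## zero-expression filter.

## run expr with a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' The eight hatching time-course conditions
#'
#' Dry cyst, hydrated cyst, hydrated cyst exposed to potato root
#' diffusate (PRD) for 1 h, 8 h, 24 h, 48 h and 7 d, and fully hatched
#' infective J2 larvae.
#'
#' @return ordered character vector of 8 condition labels.
#' @export
hatchingConditions <- function() {
    c("dry_cyst", "hydrated_cyst", "PRD_1h", "PRD_8h", "PRD_24h",
      "PRD_48h", "PRD_7d", "J2")
}

#' Build a SimulationConfig
#'
#' @param conditions ordered condition labels.
#' @param cqReplicates qPCR replicates per condition (default 3).
#' @param countReplicates RNA-Seq replicates per condition (default 2).
#' @param roster gene roster data.frame; see
#'   \linkS4class{SimulationConfig}.
#' @param sigmaTech technical Cq SD per replicate (cycles).
#' @param sigmaLoad per-sample loading-offset SD (cycles).
#' @param dispersion negative-binomial dispersion for counts (0 =
#'   Poisson).
#' @param libSizeRange min/max library size for count simulation.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(conditions = hatchingConditions(),
                             cqReplicates = 3L, countReplicates = 2L,
                             roster, sigmaTech = 0.15, sigmaLoad = 0.3,
                             dispersion = 0.05,
                             libSizeRange = c(8e5, 1.2e6)) {
    new("SimulationConfig", conditions = as.character(conditions),
        cqReplicates = as.integer(cqReplicates),
        countReplicates = as.integer(countReplicates),
        roster = as.data.frame(roster, stringsAsFactors = FALSE),
        sigmaTech = sigmaTech, sigmaLoad = sigmaLoad,
        dispersion = dispersion, libSizeRange = libSizeRange)
}

.rosterRow <- function(gene, role, baseCq, amplitude = 0,
                       conditions = "", extraNoise = 0,
                       meanExpr = 2^(28 - baseCq)) {
    data.frame(gene = gene, role = role, baseCq = baseCq,
               amplitude = amplitude, conditions = conditions,
               extraNoise = extraNoise, meanExpr = meanExpr,
               stringsAsFactors = FALSE)
}

#' Frozen hatching-study scenario
#'
#' A 14-gene roster mimicking an 11-candidate reference panel plus 3
#' validation targets across the 8 hatching conditions (24 qPCR
#' samples): 3 planted stable references, 6 mildly variable candidates
#' (per-condition effects of SD 0.3 cycles), one strongly drifting
#' pseudo-reference (2.0-cycle monotone trend with 2.0-cycle replicate
#' noise, an actin-like failure mode whose overall Cq spread exceeds
#' the largest target effect), one high-variance candidate
#' (0.8-cycle extra technical noise), and three pulse targets
#' overexpressed at specific stages: a neprilysin-like gene (10-fold at
#' 8 h of PRD exposure), a chitinase-like gene (6.5-fold at 24-48 h)
#' and an endoglucanase-like gene (4-fold at 48 h).
#'
#' Technical noise is 0.15 cycles and the per-sample loading-offset SD
#' is 0.3 cycles.
#'
#' @return a \linkS4class{SimulationConfig}.
#' @export
hatchingScenario <- function() {
    ro <- rbind(
        .rosterRow("GR",        "stable",   20.5),
        .rosterRow("PMP-3",     "stable",   22.0),
        .rosterRow("aaRS",      "stable",   21.0),
        .rosterRow("AMA-1",     "variable", 23.0, amplitude = 0.3),
        .rosterRow("MDH-1",     "variable", 19.5, amplitude = 0.3),
        .rosterRow("mce1",      "variable", 24.0, amplitude = 0.3),
        .rosterRow("ArgRS",     "variable", 21.5, amplitude = 0.3),
        .rosterRow("CSQ-1",     "variable", 25.0, amplitude = 0.35),
        .rosterRow("Y45F10D.4", "variable", 24.5, amplitude = 0.35),
        .rosterRow("Act-1",     "drift",    18.5, amplitude = 2.0,
                   extraNoise = 2.0),
        .rosterRow("EIF-3",     "variable", 20.0, amplitude = 0.5,
                   extraNoise = 0.8),
        .rosterRow("NEP-1",     "pulse",    26.0, amplitude = log2(10),
                   conditions = "PRD_8h"),
        .rosterRow("cht-2",     "pulse",    25.5, amplitude = log2(6.5),
                   conditions = "PRD_24h,PRD_48h"),
        .rosterRow("eng",       "pulse",    26.5, amplitude = log2(4),
                   conditions = "PRD_48h"))
    simulationConfig(roster = ro)
}

#' Screening scenario: planted stable genes in a responsive background
#'
#' A count-simulation roster with \code{nStable} constant-expression
#' genes hidden among \code{nResponsive} condition-responsive genes
#' (per-condition log2 effects of SD \code{responseSd}) and
#' \code{nDropout} genes silenced in one condition, across the 8
#' hatching conditions with duplicate libraries. The negative-binomial
#' dispersion is set so that, at the simulated depths, a constant
#' gene's log2 count noise is close to \code{log2NoiseSd}.
#'
#' @param nStable planted stable genes (default 4).
#' @param nResponsive condition-responsive background genes (default
#'   500).
#' @param nDropout genes with zero counts in one condition (default 1).
#' @param responseSd SD of per-condition log2 effects for responsive
#'   genes (default 1).
#' @param log2NoiseSd target log2-scale noise SD for high-expression
#'   genes (default 0.1).
#' @return a \linkS4class{SimulationConfig}.
#' @export
screenScenario <- function(nStable = 4L, nResponsive = 500L,
                           nDropout = 1L, responseSd = 1,
                           log2NoiseSd = 0.1) {
    conds <- hatchingConditions()
    ## deterministic log-uniform spread of mean expression levels
    exprOf <- function(n, lo = 9, hi = 13)
        2^seq(lo, hi, length.out = max(n, 2L))[seq_len(n)]
    rows <- list()
    if (nStable > 0)
        rows <- c(rows, list(.rosterRow(
            sprintf("stable_%02d", seq_len(nStable)), "stable",
            baseCq = 17, meanExpr = 2^11)))
    if (nResponsive > 0)
        rows <- c(rows, list(.rosterRow(
            sprintf("resp_%04d", seq_len(nResponsive)), "variable",
            baseCq = 17, amplitude = responseSd,
            meanExpr = exprOf(nResponsive))))
    if (nDropout > 0)
        rows <- c(rows, list(.rosterRow(
            sprintf("dropout_%02d", seq_len(nDropout)), "dropout",
            baseCq = 17, conditions = conds[3L], meanExpr = 2^11)))
    disp <- max((log2NoiseSd * log(2))^2 - 1 / 1500, 0)
    simulationConfig(roster = do.call(rbind, rows),
                     dispersion = disp)
}

.conditionEffects <- function(cfg) {
    ## log2-scale expression effect per gene x condition (positive =
    ## overexpressed = lower Cq); variable-gene effects are drawn from
    ## the current RNG stream
    conds <- cfg@conditions
    ro <- cfg@roster
    eff <- matrix(0, nrow(ro), length(conds),
                  dimnames = list(ro$gene, conds))
    for (i in seq_len(nrow(ro))) {
        role <- ro$role[i]
        if (role == "pulse") {
            tgt <- strsplit(ro$conditions[i], ",", fixed = TRUE)[[1L]]
            eff[i, trimws(tgt)] <- ro$amplitude[i]
        } else if (role == "drift") {
            eff[i, ] <- -ro$amplitude[i] *
                (seq_along(conds) - 1L) / max(length(conds) - 1L, 1L)
        } else if (role == "variable") {
            eff[i, ] <- stats::rnorm(length(conds), 0, ro$amplitude[i])
        }
    }
    eff
}

#' Simulate a replicate-level Cq table with known ground truth
#'
#' Generative model, per gene g and sample s with condition c(s):
#' \deqn{Cq(g, s) = \mu_g - \Delta_g(c(s)) + L_s + \epsilon_{gs}}
#' where \eqn{\mu_g} is the gene's baseline Cq, \eqn{\Delta_g} the
#' role-defined log2 expression effect (zero for stable genes, the
#' pulse amplitude in pulse conditions, a monotone trend for drift
#' genes, per-condition draws for variable genes), \eqn{L_s \sim
#' N(0, \sigma_{load})} a per-sample loading offset and
#' \eqn{\epsilon \sim N(0, \sqrt{\sigma_{tech}^2 + extraNoise_g^2})}
#' technical noise. Lower Cq means higher expression.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param seed integer seed; the same seed yields bit-identical output
#'   and the caller's RNG state is left untouched.
#' @return list with elements \code{cq} (a
#'   \linkS4class{CqExperiment}) and \code{truth} (list: per-gene
#'   \code{role}, log2 effect matrix \code{effects}, expected Cq matrix
#'   \code{expectedCq}, per-sample \code{loadOffsets}).
#' @export
simulateCq <- function(cfg, seed = 1L) {
    stopifnot(is(cfg, "SimulationConfig"))
    validObject(cfg)
    .withSeed(seed, {
        conds <- cfg@conditions
        ro <- cfg@roster
        cond <- rep(conds, each = cfg@cqReplicates)
        repl <- rep(seq_len(cfg@cqReplicates), times = length(conds))
        samples <- paste(cond, repl, sep = "_")
        eff <- .conditionEffects(cfg)
        load <- stats::rnorm(length(samples), 0, cfg@sigmaLoad)
        names(load) <- samples
        sdg <- sqrt(cfg@sigmaTech^2 + ro$extraNoise^2)
        expected <- sweep(-eff, 1L, ro$baseCq, "+")   # baseCq - effect
        cq <- expected[, cond, drop = FALSE]
        cq <- sweep(cq, 2L, load, "+") +
            matrix(stats::rnorm(nrow(ro) * length(samples)),
                   nrow(ro)) * sdg
        colnames(cq) <- samples
        truth <- list(role = stats::setNames(ro$role, ro$gene),
                      effects = eff, expectedCq = expected,
                      loadOffsets = load, sigmaTech = cfg@sigmaTech,
                      sigmaLoad = cfg@sigmaLoad)
        list(cq = CqExperiment(cq, condition = cond, replicate = repl,
                               sampleNames = samples),
             truth = truth)
    })
}

#' Simulate an RNA-Seq count matrix with known ground truth
#'
#' Per gene g and sample s, counts are drawn from a negative binomial
#' with mean \eqn{libsize_s \cdot q_g(c(s)) / \sum_g q_g(c(s))}, where
#' \eqn{q_g(c) = meanExpr_g \cdot 2^{\Delta_g(c)}} is the true
#' linear-scale expression, and the configured dispersion (0 gives
#' Poisson). Dropout-role genes are forced to zero counts in their
#' designated condition(s). Library sizes are drawn uniformly from the
#' configured range.
#'
#' @inheritParams simulateCq
#' @return list with elements \code{counts} (a
#'   \linkS4class{CountExperiment}) and \code{truth} (list: per-gene
#'   \code{role}, log2 effect matrix \code{effects}, expected-fraction
#'   matrix \code{fractions} (gene x condition), \code{libSizes}).
#' @export
simulateCounts <- function(cfg, seed = 1L) {
    stopifnot(is(cfg, "SimulationConfig"))
    validObject(cfg)
    .withSeed(seed, {
        conds <- cfg@conditions
        ro <- cfg@roster
        cond <- rep(conds, each = cfg@countReplicates)
        repl <- rep(seq_len(cfg@countReplicates), times = length(conds))
        samples <- paste("rna", cond, repl, sep = "_")
        eff <- .conditionEffects(cfg)
        q <- sweep(2^eff, 1L, ro$meanExpr, "*")
        for (i in which(ro$role == "dropout")) {
            tgt <- trimws(strsplit(ro$conditions[i], ",",
                                   fixed = TRUE)[[1L]])
            q[i, tgt] <- 0
        }
        frac <- sweep(q, 2L, colSums(q), "/")
        lib <- round(stats::runif(length(samples), cfg@libSizeRange[1L],
                                  cfg@libSizeRange[2L]))
        mu <- sweep(frac[, cond, drop = FALSE], 2L, lib, "*")
        n <- length(mu)
        k <- if (cfg@dispersion > 0)
            stats::rnbinom(n, mu = mu, size = 1 / cfg@dispersion)
        else stats::rpois(n, mu)
        k <- matrix(k, nrow = nrow(ro),
                    dimnames = list(ro$gene, samples))
        k[mu == 0] <- 0L
        truth <- list(role = stats::setNames(ro$role, ro$gene),
                      effects = eff, fractions = frac,
                      libSizes = stats::setNames(lib, samples))
        list(counts = CountExperiment(k, condition = cond,
                                      replicate = repl,
                                      sampleNames = samples),
             truth = truth)
    })
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", nrow(object@roster), "genes,",
        length(object@conditions), "conditions,",
        object@cqReplicates, "qPCR /", object@countReplicates,
        "RNA-Seq replicates\n")
    cat("  roles:", paste(sprintf("%s=%d",
        names(table(object@roster$role)),
        as.integer(table(object@roster$role))), collapse = ", "), "\n")
    cat("  sigmaTech =", object@sigmaTech, "cycles, sigmaLoad =",
        object@sigmaLoad, "cycles\n")
})
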