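PIPELINE_DEFAULTS <- list(
    matrix_path = NULL, genes_path = NULL, cells_path = NULL,
    alleles_path = NULL,
    simulate = FALSE, sim = list(),
    rho_min = 0.63, sex_low = 50, sex_high = 100,
    top_n_global = 500, top_n_day = 250,
    pre_threshold = 12.5, silhouette_min = 0.45,
    fdr_level = 0.05, window = 25,
    min_reads = 3, minor_min_reads = 2, minor_min_frac = 0.1,
    min_snvs = 25,
    embed_method = "pca", perplexity = 30, seed = 0,
    stages = c("qc", "pseudotime", "lineage", "genes", "dosage",
               "allelic"))

#' Build a validated pipeline configuration
#'
#' Starts from the defaults (which reproduce the reference-parameterized
#' run: QC at Spearman rho >= 0.63, sex thresholds 50/100, top 500/250
#' variable genes, pre-lineage gate 12.5, 25-gene dose window, allelic
#' thresholds 3/2/0.1, >= 25 SNVs) and overrides the supplied fields.
#' Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults, or a single named list.
#' @return A validated configuration list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
    over <- list(...)
    if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
        over <- over[[1]]
    unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
    if (length(unknown))
        stop("unknown configuration keys: ",
             paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
    stopifnot(cfg$rho_min >= -1, cfg$fdr_level > 0, cfg$fdr_level <= 1,
              cfg$window >= 1, cfg$min_reads >= 1)
    structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of configuration overrides.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    pipelineConfig(yaml::read_yaml(path))
}

#' Run the full staged analysis
#'
#' Executes (optionally) simulation, QC and sex classification,
#' variable-gene selection and pseudo-time, lineage calling,
#' lineage-gene rankings, dosage statistics and allelic statistics,
#' writing per-stage TSVs, a JSON summary and a log under `outDir`.
#' Rerunning with the same configuration and seed gives byte-identical
#' summaries.
#'
#' @param config a `PipelineConfig` (see [pipelineConfig()]).
#' @param outDir output directory (created if absent).
#' @param seed integer seed forwarded to simulation and embedding.
#' @return Invisibly, a list with the stage objects and the summary.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, seed = 1) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(outDir, "pipeline.log")
    logf <- function(...) {
        msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
        message(msg)
        cat(msg, "\n", file = logPath, append = TRUE)
    }
    cat("config:", jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                    null = "null"), "\n",
        file = logPath)
    logf("seed %d", seed)
    stage <- "input"
    res <- list()
    tryCatch({
        if (isTRUE(config$simulate)) {
            stage <- "simulate"
            simArgs <- utils::modifyList(list(seed = seed), config$sim)
            sim <- do.call(simConfig, simArgs)
            out <- simulateExperiment(sim)
            ds <- out$expression; ac <- out$alleles
            res$truth <- out$truth
        } else {
            for (p in c("matrix_path", "genes_path", "cells_path"))
                if (is.null(config[[p]]) || !file.exists(config[[p]]))
                    stop("missing input path: ", p)
            ds <- readExpression(config$matrix_path, config$genes_path,
                                 config$cells_path)
            ac <- if (!is.null(config$alleles_path))
                readAlleleCounts(config$alleles_path) else NULL
        }
        logf("input: %d genes x %d cells", nrow(ds), ncol(ds))

        stage <- "qc"
        ds <- qcFilter(ds, config$rho_min)
        sx <- classifySex(ds, low = config$sex_low,
                          high = config$sex_high)
        ds <- sx$expression
        keep <- qcPass(ds)
        dsQC <- ds[, keep]
        logf("qc: %d/%d cells pass", sum(keep), length(keep))
        utils::write.table(as.data.frame(colData(ds)),
                           file.path(outDir, "cells_qc.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

        stage <- "pseudotime"
        nf <- fitTechnicalNoise(dsQC)
        vs <- variabilityScores(dsQC, nf)
        genesGlobal <- topVariableGenes(
            vs, min(config$top_n_global, nrow(vs)))
        coords <- embed2D(dsQC, genesGlobal, config$embed_method,
                          seed = seed, perplexity = config$perplexity)
        pt <- assignPseudotime(coords, cellDay(dsQC), embryoId(dsQC))
        res$noiseFit <- nf; res$coords <- coords; res$pseudotime <- pt
        logf("pseudotime: embryo range %.1f-%.1f",
             min(embryoPseudotime(pt)), max(embryoPseudotime(pt)))

        stage <- "lineage"
        polar <- grep("^(POL|CCR7|CYP19A1|DLX5|ERVFRD1|GCM1)",
                      rownames(dsQC), value = TRUE)
        callOnce <- function(ptUse) callLineages(
            dsQC, ptUse, nf,
            preThreshold = config$pre_threshold,
            topN = config$top_n_day,
            silhouetteMin = config$silhouette_min,
            polarGenes = polar)
        calls <- callOnce(pt)
        res$calls <- calls
        utils::write.table(
            data.frame(cell_id = colnames(dsQC),
                       pseudotime = cellPseudotime(pt)[colnames(dsQC)]),
            file.path(outDir, "pseudotime.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        utils::write.table(lineageCalls(calls),
                           file.path(outDir, "lineage_calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        countsTab <- lineageCountsTable(calls, dsQC)
        logf("lineage: %s",
             paste(colnames(countsTab), colSums(countsTab),
                   sep = "=", collapse = " "))

        stage <- "genes"
        rankings <- list()
        for (d in 5:7) {
            r <- tryCatch(lineageSpecific(dsQC, calls, d),
                          error = function(e) NULL)
            if (!is.null(r)) rankings[[as.character(d)]] <- r
        }
        maintained <- if (length(rankings) == 3)
            maintainedGenes(unname(rankings)) else NULL
        res$rankings <- rankings; res$maintained <- maintained
        if (!is.null(maintained))
            for (L in names(maintained))
                utils::write.table(maintained[[L]],
                    file.path(outDir, sprintf("maintained_%s.tsv", L)),
                    sep = "\t", quote = FALSE, row.names = FALSE)

        stage <- "dosage"
        fm <- list()
        for (d in intersect(4:7, unique(cellDay(dsQC))))
            fm[[paste0("E", d)]] <- tryCatch(
                fmRatioPerGene(dsQC, d), error = function(e) NULL)
        res$fmRatios <- fm
        dosage <- lapply(fm, function(f) if (is.null(f)) NULL else
            list(chrX_median = f$chrXMedian,
                 autosome_median = f$autosomeMedian))

        stage <- "allelic"
        allelicSummary <- NULL
        if (!is.null(ac)) {
            rb <- relativeBiallelicRatio(
                ac, cells = colnames(dsQC), minSnvs = config$min_snvs,
                minReads = config$min_reads,
                minorMinReads = config$minor_min_reads,
                minorMinFrac = config$minor_min_frac)
            res$relBiallelic <- rb
            utils::write.table(rb,
                file.path(outDir, "relative_biallelic.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            sexQ <- cellSex(dsQC); dayQ <- cellDay(dsQC)
            med <- function(sel) stats::median(rb$ratio[
                match(colnames(dsQC)[sel], rb$cell_id)], na.rm = TRUE)
            allelicSummary <- list(
                female_median_ratio_by_day = lapply(
                    stats::setNames(nm = sort(unique(dayQ))),
                    function(d) med(sexQ == "female" & dayQ == d)))
        }

        stage <- "summary"
        summary <- list(
            n_cells_input = length(keep), n_cells_qc = sum(keep),
            seed = seed,
            lineage_counts = as.data.frame(countsTab),
            maintained_significant = if (!is.null(maintained))
                vapply(maintained, function(m) sum(m$significant),
                       integer(1)) else NULL,
            dosage = dosage, allelic = allelicSummary)
        json <- jsonlite::toJSON(summary, auto_unbox = TRUE,
                                 digits = NA, null = "null",
                                 pretty = TRUE)
        writeLines(json, file.path(outDir, "summary.json"))
        res$summary <- summary
        logf("done")
    }, error = function(e) {
        stop("pipeline stage '", stage, "' failed: ",
             conditionMessage(e), call. = FALSE)
    })
    invisible(res)
}
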