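#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assays assays<- rowData colData rowData<- colData<-
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

REQUIRED_GENE_COLS <- c("gene_id", "chrom", "start", "length_bp", "is_spikein")
REQUIRED_CELL_COLS <- c("cell_id", "embryo_id", "day")

#' Container for a gene-by-cell RPKM matrix with gene and cell annotation
#'
#' `EmbryoExpression` extends
#' \linkS4class{SingleCellExperiment} with required annotation columns.
#' Rows are genes with `gene_id`, `chrom`, `start` (1-based), `length_bp`
#' and `is_spikein`; columns are cells with `cell_id`, `embryo_id`,
#' embryonic `day` (integer 3--7), optional `subday` ("early"/"late"),
#' `sex` ("female"/"male"/"unknown") and a QC flag `qc_pass`.
#' The primary assay is named `"rpkm"`.
#'
#' @export
setClass("EmbryoExpression", contains = "SingleCellExperiment")

setValidity("EmbryoExpression", function(object) {
    msg <- character()
    if (!"rpkm" %in% names(assays(object)))
        msg <- c(msg, "assay 'rpkm' is required")
    gd <- rowData(object)
    cd <- colData(object)
    miss <- setdiff(REQUIRED_GENE_COLS, colnames(gd))
    if (length(miss))
        msg <- c(msg, paste("missing gene annotation columns:",
                            paste(miss, collapse = ", ")))
    miss <- setdiff(REQUIRED_CELL_COLS, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("missing cell metadata columns:",
                            paste(miss, collapse = ", ")))
    if (!length(msg)) {
        if (anyDuplicated(gd$gene_id))
            msg <- c(msg, "gene IDs must be unique")
        if (anyDuplicated(cd$cell_id))
            msg <- c(msg, "cell IDs must be unique")
        v <- assay(object, "rpkm")
        if (any(!is.finite(v)))
            msg <- c(msg, "expression values must be finite")
        else if (any(v < 0))
            msg <- c(msg, "expression values must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an EmbryoExpression object
#'
#' @param rpkm numeric gene-by-cell matrix of RPKM values.
#' @param genes data.frame of gene annotation with columns `gene_id`,
#'   `chrom`, `start`, `length_bp`, `is_spikein` (rows parallel to the
#'   matrix rows).
#' @param cells data.frame of cell metadata with columns `cell_id`,
#'   `embryo_id`, `day`, and optionally `subday`, `sex`, `qc_pass`.
#' @return An \linkS4class{EmbryoExpression} object.
#' @examples
#' sim <- simulateExperiment(simConfig(nGenes = 100, nSpikeins = 10,
#'     nEmbryosPerDay = c(`4` = 2), seed = 1))
#' sim$expression
#' @export
EmbryoExpression <- function(rpkm, genes, cells) {
    rpkm <- as.matrix(rpkm)
    genes <- as.data.frame(genes)
    cells <- as.data.frame(cells)
    if (nrow(genes) != nrow(rpkm))
        stop("gene annotation has ", nrow(genes), " rows but matrix has ",
             nrow(rpkm), " gene rows")
    if (nrow(cells) != ncol(rpkm))
        stop("cell metadata has ", nrow(cells), " rows but matrix has ",
             ncol(rpkm), " cell columns")
    if (!"subday" %in% colnames(cells)) cells$subday <- NA_character_
    if (!"sex" %in% colnames(cells)) cells$sex <- "unknown"
    if (!"qc_pass" %in% colnames(cells)) cells$qc_pass <- NA
    cells$day <- as.integer(cells$day)
    rownames(rpkm) <- genes$gene_id
    colnames(rpkm) <- cells$cell_id
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(rpkm = rpkm),
        rowData = DataFrame(genes, row.names = genes$gene_id),
        colData = DataFrame(cells, row.names = cells$cell_id))
    new("EmbryoExpression", sce)
}

#' @describeIn EmbryoExpression-accessors the RPKM matrix.
#' @export
rpkm <- function(x) assay(x, "rpkm")

#' Accessors for EmbryoExpression annotation
#'
#' Convenience accessors for the annotation columns used throughout the
#' pipeline. `logExpr` returns `log2(RPKM + 1)`, the transform used for
#' all correlation, PCA and embedding work.
#'
#' @param x an \linkS4class{EmbryoExpression} object.
#' @name EmbryoExpression-accessors
#' @return Vectors parallel to genes or cells, or a matrix for
#'   `rpkm`/`logExpr`.
NULL

#' @describeIn EmbryoExpression-accessors log2(RPKM + 1) matrix.
#' @export
logExpr <- function(x) log2(assay(x, "rpkm") + 1)

#' @describeIn EmbryoExpression-accessors logical spike-in flag per gene.
#' @export
spikeinFlag <- function(x) as.logical(rowData(x)$is_spikein)

#' @describeIn EmbryoExpression-accessors chromosome per gene.
#' @export
geneChrom <- function(x) as.character(rowData(x)$chrom)

#' @describeIn EmbryoExpression-accessors embryonic day per cell.
#' @export
cellDay <- function(x) as.integer(colData(x)$day)

#' @describeIn EmbryoExpression-accessors embryo ID per cell.
#' @export
embryoId <- function(x) as.character(colData(x)$embryo_id)

#' @describeIn EmbryoExpression-accessors sex per cell.
#' @export
cellSex <- function(x) as.character(colData(x)$sex)

#' @describeIn EmbryoExpression-accessors QC flag per cell.
#' @export
qcPass <- function(x) colData(x)$qc_pass

setMethod("show", "EmbryoExpression", function(object) {
    cat("EmbryoExpression:", nrow(object), "genes x", ncol(object), "cells\n")
    cat("  spike-ins:", sum(spikeinFlag(object)), "\n")
    tab <- table(cellDay(object))
    cat("  cells per day:", paste(sprintf("E%s=%d", names(tab), tab),
                                  collapse = ", "), "\n")
    sx <- table(factor(cellSex(object), c("female", "male", "unknown")))
    cat("  sex:", paste(names(sx), sx, sep = "=", collapse = ", "), "\n")
})

#' Per-cell, per-SNV allele read counts
#'
#' Holds rows of (cell_id, snv_id, chrom, pos, gene_id, ref_reads,
#' alt_reads). Reference/alternative are arbitrary labels: parental phase
#' is unknown, and all derived statistics are phase-free.
#'
#' @export
setClass("AlleleCounts", representation(counts = "data.frame"))

ALLELE_COLS <- c("cell_id", "snv_id", "chrom", "pos", "gene_id",
                 "ref_reads", "alt_reads")

setValidity("AlleleCounts", function(object) {
    df <- object@counts
    miss <- setdiff(ALLELE_COLS, colnames(df))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (nrow(df)) {
        if (any(df$ref_reads < 0) || any(df$alt_reads < 0))
            return("read counts must be non-negative")
        if (anyDuplicated(df[, c("cell_id", "snv_id")]))
            return("(cell_id, snv_id) pairs must be unique")
    }
    TRUE
})

#' Construct an AlleleCounts table
#' @param counts data.frame with columns cell_id, snv_id, chrom, pos,
#'   gene_id, ref_reads, alt_reads.
#' @return An \linkS4class{AlleleCounts} object.
#' @export
AlleleCounts <- function(counts) {
    counts <- as.data.frame(counts)
    new("AlleleCounts", counts = counts)
}

#' @describeIn AlleleCounts the underlying data.frame.
#' @param x an AlleleCounts object.
#' @export
alleleCounts <- function(x) x@counts

setMethod("show", "AlleleCounts", function(object) {
    df <- object@counts
    cat("AlleleCounts:", nrow(df), "rows;",
        length(unique(df$cell_id)), "cells;",
        length(unique(df$snv_id)), "SNVs\n")
})

#' Ground truth of a simulated experiment
#'
#' Per-cell truth (pseudo-time, sex, lineage, trophectoderm subpopulation,
#' degradation flag), per-gene program membership and activation wave, and
#' per-cell X-allele activity factors (maternal, paternal).
#'
#' @export
setClass("SimTruth", representation(cells = "data.frame",
                                    genes = "data.frame",
                                    alleleFactors = "matrix",
                                    config = "list"))

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", nrow(object@cells), "cells,", nrow(object@genes),
        "genes; dosage mode:", object@config$dosageMode, "\n")
    print(table(lineage = object@cells$lineage, day = object@cells$day))
})

#' Spike-in technical-noise fit
#'
#' Parameters of the technical mean--variance model CV^2 = a1/mu + alpha0
#' fitted on spike-in transcripts, plus the baseline biological CV added
#' when scoring gene variability.
#'
#' @export
setClass("NoiseFit", representation(a1 = "numeric", alpha0 = "numeric",
                                    cvBio = "numeric"))

setValidity("NoiseFit", function(object) {
    if (length(object@a1) != 1 || object@a1 < 0)
        return("a1 must be a single non-negative number")
    TRUE
})

setMethod("show", "NoiseFit", function(object) {
    cat(sprintf("NoiseFit: CV^2 = %.3g/mu + %.3g (baseline biological CV %.2f)\n",
                object@a1, object@alpha0, object@cvBio))
})

#' Principal-curve pseudo-time assignment
#'
#' Per-cell arc-length positions (rescaled so embryo means regress on
#' embryonic day with slope 2.5 and intercept 0), per-embryo means, and
#' the fitted curve vertices.
#'
#' @export
setClass("PseudotimeAssignment", representation(lambda = "numeric",
                                                embryo = "numeric",
                                                curve = "matrix"))

setMethod("show", "PseudotimeAssignment", function(object) {
    cat("PseudotimeAssignment:", length(object@lambda), "cells,",
        length(object@embryo), "embryos; range",
        sprintf("[%.2f, %.2f]\n", min(object@lambda), max(object@lambda)))
})

#' @describeIn PseudotimeAssignment per-cell pseudo-time.
#' @param x a PseudotimeAssignment.
#' @export
cellPseudotime <- function(x) x@lambda

#' @describeIn PseudotimeAssignment per-embryo mean pseudo-time.
#' @export
embryoPseudotime <- function(x) x@embryo

#' Per-cell lineage calls
#'
#' One row per cell: lineage (pre, TE, ICM-unresolved, EPI, PE),
#' trophectoderm subpopulation (polar/mural/NA), the silhouette of the
#' accepted split and the marker score used for labeling.
#'
#' @export
setClass("LineageCalls", representation(table = "data.frame"))

setValidity("LineageCalls", function(object) {
    df <- object@table
    need <- c("cell_id", "lineage", "te_subpop", "silhouette", "marker_score")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    ok <- df$lineage %in% c("pre", "TE", "ICM-unresolved", "EPI", "PE")
    if (!all(ok)) return("invalid lineage labels")
    TRUE
})

#' @describeIn LineageCalls the per-cell call table.
#' @param x a LineageCalls object.
#' @export
lineageCalls <- function(x) x@table

setMethod("show", "LineageCalls", function(object) {
    cat("LineageCalls:", nrow(object@table), "cells\n")
    print(table(object@table$lineage))
})

#' Moving-average female-to-male dose track along a chromosome
#'
#' Per expressed gene (ordered by start position) the ratio of the female
#' to male mean RPKM averaged over the `window` positionally nearest
#' expressed genes, per embryonic day.
#'
#' @export
setClass("DoseTrack", representation(chrom = "character",
                                     positions = "numeric",
                                     geneIds = "character",
                                     ratio = "matrix",
                                     window = "numeric"))

setValidity("DoseTrack", function(object) {
    if (is.unsorted(object@positions))
        return("positions must be sorted ascending")
    if (any(object@ratio <= 0))
        return("ratios must be positive")
    TRUE
})

setMethod("show", "DoseTrack", function(object) {
    cat("DoseTrack:", object@chrom, "-", length(object@positions),
        "genes, window", object@window, "; days:",
        paste(colnames(object@ratio), collapse = ", "), "\n")
})

#' Lineage-segregation profile
#'
#' Per-cell signed distance to the linear decision surface separating two
#' matured lineages in the diffusion-component space, plus the surface
#' parameters (unit normal `w` and offset `b`).
#'
#' @export
setClass("SegregationProfile", representation(distance = "numeric",
                                              surface = "list",
                                              classes = "character"))

setMethod("show", "SegregationProfile", function(object) {
    cat("SegregationProfile:", length(object@distance), "cells;",
        "classes:", paste(object@classes, collapse = " vs "), "\n")
})

#' @describeIn SegregationProfile per-cell signed distances.
#' @param x a SegregationProfile.
#' @export
segregationDistance <- function(x) x@distance
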