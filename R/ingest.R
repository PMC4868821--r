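#' Read an expression dataset from disk
#'
#' The matrix may be tab-separated text (genes as rows, header line of
#' cell IDs, first column of gene IDs) or MatrixMarket (`.mtx`; row and
#' column order follow the annotation tables, cross-checked against
#' sibling `<matrix>.genes`/`<matrix>.cells` ID files when present).
#' Gene annotation columns: `gene_id`, `chrom`, `start`, `length_bp`,
#' `is_spikein`; cell metadata columns: `cell_id`, `embryo_id`, `day`,
#' optionally `subday`, `sex`, `qc_pass`. Coordinates are 1-based.
#'
#' @param matrixPath path to the `.tsv` or `.mtx` matrix.
#' @param genesPath path to the gene annotation TSV.
#' @param cellsPath path to the cell metadata TSV.
#' @return An \linkS4class{EmbryoExpression}.
#' @export
readExpression <- function(matrixPath, genesPath, cellsPath) {
    genes <- utils::read.delim(genesPath, stringsAsFactors = FALSE)
    cells <- utils::read.delim(cellsPath, stringsAsFactors = FALSE)
    if (anyDuplicated(genes$gene_id))
        stop("duplicate gene ID: ",
             genes$gene_id[duplicated(genes$gene_id)][1])
    if (anyDuplicated(cells$cell_id))
        stop("duplicate cell ID: ",
             cells$cell_id[duplicated(cells$cell_id)][1])
    if (grepl("\\.mtx$", matrixPath)) {
        m <- as.matrix(Matrix::readMM(matrixPath))
        gidPath <- paste0(matrixPath, ".genes")
        cidPath <- paste0(matrixPath, ".cells")
        if (file.exists(gidPath)) {
            ids <- readLines(gidPath)
            if (!identical(ids, genes$gene_id))
                stop("gene IDs in ", gidPath,
                     " do not match the annotation table")
        }
        if (file.exists(cidPath)) {
            ids <- readLines(cidPath)
            if (!identical(ids, cells$cell_id))
                stop("cell IDs in ", cidPath,
                     " do not match the metadata table")
        }
    } else {
        df <- utils::read.delim(matrixPath, stringsAsFactors = FALSE,
                                check.names = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- df[[1]]
        if (!identical(rownames(m), genes$gene_id)) {
            bad <- if (nrow(m) == nrow(genes))
                paste0("(first mismatch: row ",
                       which(rownames(m) != genes$gene_id)[1], ")")
            else sprintf("(%d matrix rows vs %d annotation rows)",
                         nrow(m), nrow(genes))
            stop("matrix gene IDs do not match the annotation table ",
                 bad)
        }
        if (!identical(colnames(m), cells$cell_id))
            stop("matrix cell IDs do not match the metadata table")
    }
    if (nrow(m) != nrow(genes) || ncol(m) != nrow(cells))
        stop("matrix is ", nrow(m), " x ", ncol(m),
             " but annotation describes ", nrow(genes), " genes and ",
             nrow(cells), " cells")
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg))
        stop("negative value at gene row ", neg[1, 1], ", cell column ",
             neg[1, 2])
    EmbryoExpression(m, genes, cells)
}

#' Write an expression dataset to disk
#'
#' Inverse of [readExpression()]; the round trip is lossless up to float
#' formatting. With an `.mtx` matrix path, sibling `.genes`/`.cells` ID
#' files are written alongside.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @inheritParams readExpression
#' @return Invisibly, the three paths written.
#' @export
writeExpression <- function(x, matrixPath, genesPath, cellsPath) {
    gd <- as.data.frame(rowData(x))
    cd <- as.data.frame(colData(x))
    utils::write.table(gd, genesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(cd, cellsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    m <- assay(x, "rpkm")
    if (grepl("\\.mtx$", matrixPath)) {
        Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), matrixPath)
        writeLines(rownames(m), paste0(matrixPath, ".genes"))
        writeLines(colnames(m), paste0(matrixPath, ".cells"))
    } else {
        df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                         stringsAsFactors = FALSE)
        utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(c(matrixPath, genesPath, cellsPath))
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = count / (length/1000) / (total/1e6)`.
#'
#' @param counts integer gene-by-cell read-count matrix.
#' @param lengths per-gene transcript length in bp (> 0).
#' @param totals per-cell mapped-read totals (> 0).
#' @param genes,cells optional annotation tables; when supplied an
#'   \linkS4class{EmbryoExpression} is returned, otherwise the RPKM
#'   matrix.
#' @return RPKM matrix or \linkS4class{EmbryoExpression}.
#' @examples
#' computeRPKM(matrix(100), lengths = 1000, totals = 1e6)  # 100
#' @export
computeRPKM <- function(counts, lengths, totals, genes = NULL,
                        cells = NULL) {
    counts <- as.matrix(counts)
    if (any(lengths <= 0)) stop("gene lengths must be positive")
    if (any(totals <= 0)) stop("per-cell totals must be positive")
    r <- counts / (lengths / 1000)
    r <- sweep(r, 2, totals / 1e6, "/")
    if (is.null(genes)) return(r)
    EmbryoExpression(r, genes, cells)
}

#' Expressed-gene mask and per-cell expressed-gene counts
#'
#' A gene is expressed in a cell when its value meets the threshold
#' (inclusive; default RPKM >= 1).
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param threshold expression threshold (> 0).
#' @return list with `mask` (gene x cell logical) and `counts` (per-cell
#'   number of expressed genes).
#' @export
expressedMask <- function(x, threshold = 1) {
    if (threshold <= 0) stop("threshold must be positive")
    mask <- assay(x, "rpkm") >= threshold
    list(mask = mask, counts = colSums(mask))
}

#' Filter cells by maximum Spearman correlation
#'
#' A cell passes QC when its maximum Spearman correlation to any other
#' cell is at least `rhoMin` (default 0.63). Correlations are computed
#' over all non-spike-in genes; Spearman's rank correlation is invariant
#' to the monotone log transform used elsewhere.
#'
#' @param x an \linkS4class{EmbryoExpression} with at least two cells.
#' @param rhoMin correlation threshold.
#' @return `x` with `qc_pass` and `max_cor` set in the cell metadata.
#' @export
qcFilter <- function(x, rhoMin = 0.63) {
    if (ncol(x) < 2) stop("QC filtering needs at least two cells")
    v <- assay(x, "rpkm")[!spikeinFlag(x), , drop = FALSE]
    rho <- stats::cor(v, method = "spearman")
    diag(rho) <- -Inf
    maxCor <- apply(rho, 2, max)
    colData(x)$max_cor <- maxCor
    colData(x)$qc_pass <- maxCor >= rhoMin
    x
}

#' Classify cell and embryo sex from Y-chromosome expression
#'
#' Sums the RPKM of Y-linked genes per cell: below `low` is female,
#' above `high` is male, between is unknown. Embryo sex is a majority
#' vote over its classified cells; an embryo whose classified cells
#' disagree is flagged.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param yGeneIds Y-gene IDs; defaults to all genes annotated on chrY.
#' @param low,high classification thresholds on the Y RPKM sum.
#' @return list with `expression` (`x` with per-cell `sex` and `y_sum`
#'   set) and `embryos` (data.frame of embryo-level sex and a conflict
#'   flag).
#' @export
classifySex <- function(x, yGeneIds = NULL, low = 50, high = 100) {
    if (is.null(yGeneIds))
        yGeneIds <- rownames(x)[geneChrom(x) == "chrY"]
    if (!length(yGeneIds))
        stop("no Y-chromosome genes in the annotation")
    ySum <- colSums(assay(x, "rpkm")[yGeneIds, , drop = FALSE])
    sex <- rep("unknown", ncol(x))
    sex[ySum < low] <- "female"
    sex[ySum > high] <- "male"
    colData(x)$sex <- sex
    colData(x)$y_sum <- ySum
    emb <- split(sex, embryoId(x))
    embryos <- data.frame(
        embryo_id = names(emb),
        sex = vapply(emb, function(s) {
            s <- s[s != "unknown"]
            if (!length(s)) return("unknown")
            names(sort(table(s), decreasing = TRUE))[1]
        }, character(1)),
        conflict = vapply(emb, function(s)
            all(c("female", "male") %in% s), logical(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    list(expression = x, embryos = embryos)
}

#' Zygotic activation summary of ubiquitous Y genes
#'
#' Per male cell, the mean expression of a set of ubiquitously expressed
#' Y genes, normalized to the median of that statistic over E4--E7 male
#' cells, with a two-sided Mann-Whitney-Wilcoxon comparison of E3
#' against E4.
#'
#' @param x an \linkS4class{EmbryoExpression} with sex assigned.
#' @param yGeneIds Y-gene set (non-empty); defaults to all chrY genes.
#' @return list with `perCell` (data.frame cell_id, day, normalized
#'   value), `perDay` (median per day) and `pValue` (E3 vs E4 MWW, `NA`
#'   with a warning when no male E3 cells exist).
#' @export
yZgaSummary <- function(x, yGeneIds = NULL) {
    if (is.null(yGeneIds))
        yGeneIds <- rownames(x)[geneChrom(x) == "chrY"]
    if (!length(yGeneIds)) stop("empty Y gene set")
    male <- cellSex(x) == "male"
    day <- cellDay(x)
    if (length(unique(day[male])) < 2)
        stop("male cells present at fewer than two days")
    stat <- colMeans(assay(x, "rpkm")[yGeneIds, male, drop = FALSE])
    ref <- stats::median(stat[day[male] >= 4])
    norm <- stat / ref
    dayM <- day[male]
    p <- NA_real_
    if (any(dayM == 3) && any(dayM == 4)) {
        p <- stats::wilcox.test(norm[dayM == 3], norm[dayM == 4],
                                exact = FALSE)$p.value
    } else warning("no male E3 cells: E3 vs E4 test skipped")
    list(perCell = data.frame(cell_id = colnames(x)[male], day = dayM,
                              normalized = norm, row.names = NULL),
         perDay = tapply(norm, dayM, stats::median),
         pValue = p)
}
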