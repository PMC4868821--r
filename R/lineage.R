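#' Marker panel for labeling a two-way split
#'
#' Two disjoint gene sets with weights +1 and -1; a cluster whose mean
#' weighted marker score is higher receives the name of the +1 set.
#'
#' @param positive,negative character vectors of marker gene IDs.
#' @param positiveName,negativeName lineage names attached to the sets.
#' @return A list of class `MarkerPanel`.
#' @export
markerPanel <- function(positive, negative, positiveName, negativeName) {
    if (length(intersect(positive, negative)))
        stop("marker sets must be disjoint")
    structure(list(positive = positive, negative = negative,
                   positiveName = positiveName,
                   negativeName = negativeName),
              class = "MarkerPanel")
}

#' Default marker panels
#'
#' Panels for the TE/ICM and EPI/PE splits, read from the editable YAML
#' file shipped at `inst/extdata/marker_panels.yaml` (well-known
#' lineage markers; the synthetic-data generator names its program genes
#' after them so the panels apply to simulated data directly).
#'
#' @param path optional path to an alternative YAML panel file.
#' @return Named list of `MarkerPanel` objects (`te_icm`, `epi_pe`).
#' @export
defaultMarkerPanels <- function(path = system.file("extdata",
        "marker_panels.yaml", package = "embryolin")) {
    y <- yaml::read_yaml(path)
    list(te_icm = markerPanel(y$TE, y$ICM, "TE", "ICM"),
         epi_pe = markerPanel(y$EPI, y$PE, "EPI", "PE"))
}

#' Two-way k-medoids clustering in PCA subspace
#'
#' PAM clustering of cells on the first `nPcs` principal-component
#' scores of `log2(RPKM + 1)` over the given genes. Medoid
#' initialization uses PAM's greedy build step, making the result
#' deterministic.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param cells cell IDs to cluster (>= 2k).
#' @param genes gene IDs to use.
#' @param nPcs number of principal components.
#' @param k number of clusters (>= 2; the mean silhouette is undefined
#'   for k = 1).
#' @return list with `labels` (named integer vector), `silhouette`
#'   (mean silhouette width), `scores` (PC score matrix).
#' @export
clusterTwo <- function(x, cells, genes, nPcs = 2, k = 2) {
    if (k < 2) stop("k must be at least 2 (silhouette undefined for k = 1)")
    if (length(cells) < 2 * k)
        stop("need at least ", 2 * k, " cells, got ", length(cells))
    L <- t(logExpr(x)[genes, cells, drop = FALSE])
    nPcs <- min(nPcs, ncol(L), nrow(L) - 1)
    sc <- stats::prcomp(L, center = TRUE)$x[, seq_len(nPcs), drop = FALSE]
    fit <- cluster::pam(sc, k, pamonce = 0)
    list(labels = stats::setNames(fit$clustering, cells),
         silhouette = fit$silinfo$avg.width,
         scores = sc)
}

## per-cell weighted marker score: mean over panel genes of
## weight x z-scored log expression (z across the given cells)
panelScore <- function(x, cells, panel) {
    genes <- c(panel$positive, panel$negative)
    miss <- setdiff(genes, rownames(x))
    if (length(miss))
        stop("marker genes absent from dataset: ",
             paste(miss, collapse = ", "))
    L <- logExpr(x)[genes, cells, drop = FALSE]
    z <- t(scale(t(L)))
    z[!is.finite(z)] <- 0          # constant marker across cells
    w <- ifelse(genes %in% panel$positive, 1, -1)
    colMeans(z * w)
}

#' Label two clusters with lineage names via a marker panel
#'
#' @param labels named two-level cluster vector (from [clusterTwo()]).
#' @param x an \linkS4class{EmbryoExpression}.
#' @param panel a [markerPanel()].
#' @return list with `lineage` (named character vector per cell) and
#'   `score` (per-cell marker score, positive toward the +1 set).
#' @export
labelClusters <- function(labels, x, panel) {
    cells <- names(labels)
    lv <- unique(labels)
    if (length(lv) != 2 || any(table(labels) == 0))
        stop("labels must contain two non-empty clusters")
    score <- panelScore(x, cells, panel)
    m1 <- mean(score[labels == lv[1]])
    m2 <- mean(score[labels == lv[2]])
    nm <- c(panel$positiveName, panel$negativeName)
    assign <- if (m1 >= m2) stats::setNames(nm, lv) else
        stats::setNames(rev(nm), lv)
    list(lineage = stats::setNames(assign[as.character(labels)], cells),
         score = score)
}

#' Per-cell polar-gene score
#'
#' Z-scores each polar gene's log expression across the given
#' trophectoderm cells, then averages over genes per cell.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param teCells trophectoderm cell IDs.
#' @param polarGenes non-empty polar gene set.
#' @return Named numeric vector of per-cell mean z-scores.
#' @export
polarScore <- function(x, teCells, polarGenes) {
    if (!length(polarGenes)) stop("empty polar gene list")
    L <- logExpr(x)[polarGenes, teCells, drop = FALSE]
    z <- t(scale(t(L)))
    z[!is.finite(z)] <- 0
    colMeans(z)
}

#' Hierarchical per-day lineage classification
#'
#' Implements the staged calling scheme: cells of days 3--4 and cells in
#' embryos whose pseudo-time is below `preThreshold` are pre-lineage.
#' For each later day, the remaining cells are split by [clusterTwo()]
#' on the day's top `topN` variable genes and labeled ICM/TE by marker
#' panel; ICM cells are split again (variable genes recomputed among
#' them) and labeled EPI/PE; TE cells of days 6--7 are split on PC1--2
#' and labeled polar/mural by polar-gene score. A split is accepted only
#' when its mean silhouette reaches `silhouetteMin`; otherwise the cells
#' stay unresolved at that level (ICM cells become `ICM-unresolved`).
#'
#' @param x a QC-passed \linkS4class{EmbryoExpression}.
#' @param pt a \linkS4class{PseudotimeAssignment} covering the cells.
#' @param noiseFit a \linkS4class{NoiseFit} for variable-gene scoring.
#' @param panels marker panels as from [defaultMarkerPanels()].
#' @param polarGenes gene set scoring the polar TE subpopulation.
#' @param preThreshold embryo-level pseudo-time gate below which cells
#'   are pre-lineage (12.5 corresponds to day 5).
#' @param topN number of variable genes per split.
#' @param silhouetteMin minimum mean silhouette to accept a split.
#' @param excludeSexChroms drop chrX/chrY genes from the split-defining
#'   variable-gene pools, so that the sex axis (X dosage, Y expression)
#'   cannot masquerade as a lineage split in mixed-sex strata.
#' @return A \linkS4class{LineageCalls}.
#' @export
callLineages <- function(x, pt, noiseFit,
                         panels = defaultMarkerPanels(),
                         polarGenes = NULL,
                         preThreshold = 12.5, topN = 250,
                         silhouetteMin = 0.45,
                         excludeSexChroms = TRUE) {
    if (is.null(pt)) stop("pseudotime assignment is required")
    day <- cellDay(x)
    emb <- embryoId(x)
    sexGenes <- rownames(x)[geneChrom(x) %in% c("chrX", "chrY")]
    pickGenes <- function(vs) {
        if (excludeSexChroms)
            vs <- vs[!vs$gene_id %in% sexGenes, , drop = FALSE]
        topVariableGenes(vs, min(topN, nrow(vs)))
    }
    embPt <- embryoPseudotime(pt)[emb]
    out <- data.frame(cell_id = colnames(x), lineage = "pre",
                      te_subpop = NA_character_, silhouette = NA_real_,
                      marker_score = NA_real_, stringsAsFactors = FALSE,
                      row.names = colnames(x))
    for (d in intersect(5:7, unique(day))) {
        cand <- colnames(x)[day == d & embPt >= preThreshold]
        if (length(cand) < 4) next
        vs <- variabilityScores(x, noiseFit, cells = cand)
        genes <- pickGenes(vs)
        cl <- clusterTwo(x, cand, genes)
        if (cl$silhouette < silhouetteMin) next   # no groupings identified
        lab <- labelClusters(cl$labels, x, panels$te_icm)
        out[cand, "lineage"] <- unname(lab$lineage)
        out[cand, "silhouette"] <- cl$silhouette
        out[cand, "marker_score"] <- lab$score[cand]
        ## EPI vs PE within ICM
        icm <- cand[lab$lineage == "ICM"]
        if (length(icm) >= 4) {
            vsI <- variabilityScores(x, noiseFit, cells = icm)
            clI <- clusterTwo(x, icm, pickGenes(vsI))
            if (clI$silhouette >= silhouetteMin) {
                labI <- labelClusters(clI$labels, x, panels$epi_pe)
                out[icm, "lineage"] <- unname(labI$lineage)
                out[icm, "silhouette"] <- clI$silhouette
                out[icm, "marker_score"] <- labI$score[icm]
            } else out[icm, "lineage"] <- "ICM-unresolved"
        } else if (length(icm))
            out[icm, "lineage"] <- "ICM-unresolved"
        ## polar vs mural within TE, days 6-7
        te <- cand[lab$lineage == "TE"]
        if (d >= 6 && length(te) >= 4 && length(polarGenes)) {
            vsT <- variabilityScores(x, noiseFit, cells = te)
            clT <- clusterTwo(x, te, pickGenes(vsT))
            if (clT$silhouette >= silhouetteMin) {
                ps <- polarScore(x, te, intersect(polarGenes, rownames(x)))
                mns <- tapply(ps, clT$labels[te], mean)
                polarCl <- names(which.max(mns))
                out[te, "te_subpop"] <-
                    ifelse(clT$labels[te] == as.integer(polarCl),
                           "polar", "mural")
            }
        }
    }
    new("LineageCalls", table = out)
}

#' Cell counts per lineage and embryonic day
#'
#' @param calls a \linkS4class{LineageCalls}.
#' @param x the matching \linkS4class{EmbryoExpression}.
#' @return A day x lineage count table.
#' @export
lineageCountsTable <- function(calls, x) {
    df <- lineageCalls(calls)
    table(day = cellDay(x)[match(df$cell_id, colnames(x))],
          lineage = factor(df$lineage,
                           c("pre", "TE", "ICM-unresolved", "EPI", "PE")))
}
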