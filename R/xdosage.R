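#' Per-gene expression trend over embryonic days
#'
#' Spearman correlation of each expressed gene's RPKM across cells of
#' one sex against the embryonic day label (default E4--E7), with a
#' Mann-Whitney-Wilcoxon comparison of the chrX correlation
#' distributions between sexes when both are supplied.
#'
#' @param x an \linkS4class{EmbryoExpression} with sex assigned.
#' @param days days included in the trend.
#' @param sex `"female"`, `"male"` or `c("female", "male")`.
#' @param minExprFrac expressed-gene filter (fraction of cells at
#'   RPKM >= 1).
#' @return data.frame with gene_id, chrom, sex, rho (missing for
#'   constant genes); when both sexes are computed,
#'   `attr(, "tests")` holds the chrX female-vs-male MWW p-value and
#'   the autosomal one.
#' @export
geneTimeTrend <- function(x, days = 4:7, sex = c("female", "male"),
                          minExprFrac = 0.05) {
    out <- list()
    for (s in sex) {
        cells <- cellSex(x) == s & cellDay(x) %in% days
        if (length(unique(cellDay(x)[cells])) < 2)
            stop("fewer than 2 days with ", s, " cells")
        v <- assay(x, "rpkm")[!spikeinFlag(x), cells, drop = FALSE]
        v <- v[rowMeans(v >= 1) >= minExprFrac, , drop = FALSE]
        day <- cellDay(x)[cells]
        rho <- suppressWarnings(
            apply(v, 1, function(y)
                if (stats::sd(y) == 0) NA_real_ else
                stats::cor(y, day, method = "spearman")))
        out[[s]] <- data.frame(gene_id = rownames(v),
                               chrom = geneChrom(x)[match(rownames(v),
                                                          rownames(x))],
                               sex = s, rho = rho, row.names = NULL,
                               stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    if (length(sex) == 2) {
        xf <- res$rho[res$sex == "female" & res$chrom == "chrX"]
        xm <- res$rho[res$sex == "male" & res$chrom == "chrX"]
        af <- res$rho[res$sex == "female" &
                      !res$chrom %in% c("chrX", "chrY")]
        am <- res$rho[res$sex == "male" &
                      !res$chrom %in% c("chrX", "chrY")]
        attr(res, "tests") <- list(
            chrX_female_vs_male =
                stats::wilcox.test(xf, xm, exact = FALSE)$p.value,
            autosome_female_vs_male =
                stats::wilcox.test(af, am, exact = FALSE)$p.value)
    }
    res
}

## cells of a day/lineage stratum split by sex
stratumCells <- function(x, day, lineage = NULL, calls = NULL) {
    sel <- cellDay(x) == day
    if (!is.null(lineage)) {
        if (is.null(calls)) stop("lineage restriction requires calls")
        df <- lineageCalls(calls)
        sel <- sel & df$lineage[match(colnames(x), df$cell_id)] == lineage
    }
    sex <- cellSex(x)
    list(female = colnames(x)[sel & sex == "female"],
         male = colnames(x)[sel & sex == "male"])
}

#' Per-gene female-to-male expression ratios
#'
#' For each transcribed gene (mean RPKM >= 1 in at least one sex within
#' the stratum) the pseudo-counted ratio
#' `(mean_female + 1)/(mean_male + 1)`, with the chrX median, the
#' autosomal reference median, and a Mann-Whitney-Wilcoxon test of chrX
#' ratios against autosomal ratios.
#'
#' @param x an \linkS4class{EmbryoExpression} with sex assigned.
#' @param day embryonic day.
#' @param lineage optional lineage restriction (needs `calls`).
#' @param calls optional \linkS4class{LineageCalls}.
#' @param pseudoCount pseudo-count added to both means (0.5 keeps the
#'   ratio stabilized for lowly expressed genes while remaining nearly
#'   unbiased for transcribed genes).
#' @return list with `perGene` (data.frame gene_id, chrom, ratio),
#'   `chrXMedian`, `autosomeMedian`, `pChrXvsAutosome`.
#' @export
fmRatioPerGene <- function(x, day, lineage = NULL, calls = NULL,
                           pseudoCount = 0.5) {
    cs <- stratumCells(x, day, lineage, calls)
    if (!length(cs$female) || !length(cs$male))
        stop("stratum is empty for at least one sex")
    v <- assay(x, "rpkm")[!spikeinFlag(x), , drop = FALSE]
    mf <- rowMeans(v[, cs$female, drop = FALSE])
    mm <- rowMeans(v[, cs$male, drop = FALSE])
    keep <- mf >= 1 | mm >= 1
    chrom <- geneChrom(x)[match(rownames(v), rownames(x))]
    keep <- keep & chrom != "chrY"
    ratio <- (mf[keep] + pseudoCount) / (mm[keep] + pseudoCount)
    chrom <- chrom[keep]
    isX <- chrom == "chrX"
    list(perGene = data.frame(gene_id = names(ratio), chrom = chrom,
                              ratio = as.numeric(ratio), row.names = NULL,
                              stringsAsFactors = FALSE),
         chrXMedian = stats::median(ratio[isX]),
         autosomeMedian = stats::median(ratio[!isX]),
         pChrXvsAutosome = if (sum(isX) >= 2 && sum(!isX) >= 2)
             stats::wilcox.test(ratio[isX], ratio[!isX],
                                exact = FALSE)$p.value else NA_real_)
}

## indices of the `window` positionally nearest genes for position i of
## n ordered genes, truncated symmetrically at the chromosome ends
maWindowIndices <- function(i, n, window) {
    h <- min((window - 1) %/% 2, i - 1, n - i)
    seq(i - h, i + h)
}

#' Moving-average female-to-male dose track along a chromosome
#'
#' Orders the chromosome's transcribed genes by start position and, at
#' each gene, takes the ratio of the female to the male mean RPKM
#' averaged over the `window` nearest genes (window truncated
#' symmetrically at the ends), per requested day.
#'
#' @param x an \linkS4class{EmbryoExpression} with sex assigned.
#' @param chrom chromosome ID.
#' @param days embryonic days (one track column per day).
#' @param window window size in genes (default 25).
#' @param cells optional restriction to a subset of cells (e.g. one
#'   embryo for screening); sex is still taken from the metadata.
#' @return A \linkS4class{DoseTrack}.
#' @export
movingAverageTrack <- function(x, chrom, days = 4:7, window = 25,
                               cells = NULL) {
    v <- assay(x, "rpkm")
    if (!is.null(cells)) v <- v[, cells, drop = FALSE]
    onChrom <- geneChrom(x) == chrom & !spikeinFlag(x)
    expressed <- rowMeans(v >= 1)[onChrom] >= 0.05
    ids <- rownames(x)[onChrom][expressed]
    if (length(ids) < window)
        stop("fewer than ", window, " expressed genes on ", chrom)
    pos <- rowData(x)[ids, "start"]
    ord <- order(pos, ids)
    ids <- ids[ord]; pos <- pos[ord]
    day <- cellDay(x)[match(colnames(v), colnames(x))]
    sex <- cellSex(x)[match(colnames(v), colnames(x))]
    n <- length(ids)
    ratio <- matrix(NA_real_, n, length(days),
                    dimnames = list(ids, paste0("E", days)))
    for (j in seq_along(days)) {
        f <- rowMeans(v[ids, day == days[j] & sex == "female",
                        drop = FALSE])
        m <- rowMeans(v[ids, day == days[j] & sex == "male",
                        drop = FALSE])
        for (i in seq_len(n)) {
            w <- maWindowIndices(i, n, window)
            ratio[i, j] <- (mean(f[w]) + 1) / (mean(m[w]) + 1)
        }
    }
    new("DoseTrack", chrom = chrom, positions = as.numeric(pos),
        geneIds = ids, ratio = ratio, window = window)
}

#' Total X-chromosome output per cell
#'
#' Sums RPKM over a fixed chrX gene set per cell, stratified by sex and
#' day, with Mann-Whitney-Wilcoxon tests of female E-min vs E-max and
#' female vs male per day. The default gene set is the intersection of
#' genes expressed (mean RPKM >= 1) at every day.
#'
#' @param x an \linkS4class{EmbryoExpression} with sex assigned.
#' @param geneSet fixed chrX gene set; `NULL` for the default.
#' @return list with `perCell` (data.frame cell_id, sex, day, sum),
#'   `tests` (named p-values).
#' @export
totalXOutput <- function(x, geneSet = NULL) {
    v <- assay(x, "rpkm")
    day <- cellDay(x); sex <- cellSex(x)
    if (is.null(geneSet)) {
        onX <- geneChrom(x) == "chrX"
        expr <- vapply(sort(unique(day)), function(d)
            rowMeans(v[, day == d, drop = FALSE]) >= 1,
            logical(nrow(v)))
        geneSet <- rownames(x)[onX & rowSums(expr) == ncol(expr)]
    }
    if (!length(geneSet)) stop("empty gene set")
    s <- colSums(v[geneSet, , drop = FALSE])
    perCell <- data.frame(cell_id = colnames(x), sex = sex, day = day,
                          xsum = s, row.names = NULL,
                          stringsAsFactors = FALSE)
    dmin <- min(day); dmax <- max(day)
    tests <- list()
    fem <- sex == "female"
    if (any(fem & day == dmin) && any(fem & day == dmax))
        tests[[sprintf("female_E%d_vs_E%d", dmin, dmax)]] <-
            stats::wilcox.test(s[fem & day == dmin],
                               s[fem & day == dmax],
                               exact = FALSE)$p.value
    for (d in sort(unique(day)))
        if (any(fem & day == d) && any(sex == "male" & day == d))
            tests[[sprintf("female_vs_male_E%d", d)]] <-
                stats::wilcox.test(s[fem & day == d],
                                   s[sex == "male" & day == d],
                                   exact = FALSE)$p.value
    list(perCell = perCell, geneSet = geneSet, tests = tests)
}

#' Fraction of cells expressing a gene above thresholds
#'
#' Empirical per-sex, per-day fractions of cells whose expression of one
#' gene exceeds each threshold; non-increasing in the threshold.
#'
#' @param x an \linkS4class{EmbryoExpression} with sex assigned.
#' @param gene gene ID.
#' @param thresholds numeric thresholds.
#' @return data.frame with sex, day, threshold, fraction.
#' @export
geneFractionAbove <- function(x, gene, thresholds = c(0, 1, 5, 10)) {
    if (!gene %in% rownames(x)) stop("gene not present: ", gene)
    v <- assay(x, "rpkm")[gene, ]
    day <- cellDay(x); sex <- cellSex(x)
    grid <- expand.grid(sex = c("female", "male"),
                        day = sort(unique(day)),
                        threshold = thresholds,
                        stringsAsFactors = FALSE)
    grid$fraction <- mapply(function(s, d, th) {
        i <- sex == s & day == d
        if (!any(i)) return(NA_real_)
        mean(v[i] > th)
    }, grid$sex, grid$day, grid$threshold)
    grid
}

#' Screen an embryo for a suspected X0 karyotype
#'
#' Compares the embryo's chrX moving-average expression with same-day
#' female and male reference profiles (other embryos). A sex-called
#' female embryo is flagged when its profile is closer to the male
#' reference over at least `minFrac` of positions. Male embryos are
#' skipped.
#'
#' @param x an \linkS4class{EmbryoExpression} with sex assigned.
#' @param embryo embryo ID to screen.
#' @param window moving-average window in genes.
#' @param minFrac fraction of positions required to flag.
#' @return list with `flag`, `applicable`, `fracCloserToMale` and the
#'   three per-gene mean profiles.
#' @export
x0Screen <- function(x, embryo, window = 25, minFrac = 0.8) {
    emb <- embryoId(x)
    day <- unique(cellDay(x)[emb == embryo])
    embSexTab <- table(cellSex(x)[emb == embryo])
    embSex <- names(sort(embSexTab, decreasing = TRUE))[1]
    if (embSex == "male")
        return(list(flag = FALSE, applicable = FALSE))
    others <- emb != embryo & cellDay(x) %in% day
    fRef <- others & cellSex(x) == "female"
    mRef <- others & cellSex(x) == "male"
    if (!any(fRef) || !any(mRef))
        stop("no same-day reference embryos of both sexes")
    v <- assay(x, "rpkm")
    onX <- geneChrom(x) == "chrX" & !spikeinFlag(x)
    ids <- rownames(x)[onX]
    expressed <- rowMeans(v[ids, , drop = FALSE] >= 1) >= 0.05
    ids <- ids[expressed]
    if (length(ids) < window)
        stop("fewer than ", window, " expressed chrX genes")
    pos <- rowData(x)[ids, "start"]
    ord <- order(pos, ids); ids <- ids[ord]
    prof <- function(sel) {
        m <- rowMeans(v[ids, sel, drop = FALSE])
        n <- length(m)
        vapply(seq_len(n), function(i)
            mean(m[maWindowIndices(i, n, window)]), numeric(1))
    }
    pe <- prof(emb == embryo)
    pf <- prof(fRef)
    pm <- prof(mRef)
    closerMale <- abs(log2(pe + 1) - log2(pm + 1)) <
        abs(log2(pe + 1) - log2(pf + 1))
    frac <- mean(closerMale)
    list(flag = frac >= minFrac, applicable = TRUE,
         fracCloserToMale = frac,
         profiles = data.frame(gene_id = ids, embryo = pe, female = pf,
                               male = pm, stringsAsFactors = FALSE))
}
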