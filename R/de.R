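#' Rank-based differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on `log2(RPKM + 1)`.
#' `z` is the signed normal quantile of the p-value with the sign of the
#' pseudo-counted fold change `log2fc = log2((meanA + 1)/(meanB + 1))`;
#' FDR is Benjamini-Hochberg across the tested genes. Genes expressed
#' (RPKM >= 1) in fewer than `minExprFrac` of both groups are excluded
#' from testing.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param cellsA,cellsB disjoint cell ID vectors (>= 3 cells each).
#' @param minExprFrac expression filter fraction (default 0.1).
#' @return data.frame with gene_id, mean_a, mean_b, log2fc, z, p, fdr.
#' @export
deTwoGroups <- function(x, cellsA, cellsB, minExprFrac = 0.1) {
    if (length(cellsA) < 3 || length(cellsB) < 3)
        stop("each group needs at least 3 cells")
    v <- assay(x, "rpkm")[!spikeinFlag(x), , drop = FALSE]
    va <- v[, cellsA, drop = FALSE]
    vb <- v[, cellsB, drop = FALSE]
    keep <- rowMeans(va >= 1) >= minExprFrac |
        rowMeans(vb >= 1) >= minExprFrac
    va <- va[keep, , drop = FALSE]
    vb <- vb[keep, , drop = FALSE]
    la <- log2(va + 1); lb <- log2(vb + 1)
    p <- vapply(seq_len(nrow(la)), function(i) {
        if (all(c(la[i, ], lb[i, ]) == la[i, 1]))
            return(1)
        suppressWarnings(stats::wilcox.test(la[i, ], lb[i, ],
                                            exact = FALSE)$p.value)
    }, numeric(1))
    p[!is.finite(p)] <- 1
    ma <- rowMeans(va); mb <- rowMeans(vb)
    log2fc <- log2((ma + 1) / (mb + 1))
    z <- stats::qnorm(pmax(p / 2, .Machine$double.xmin),
                      lower.tail = FALSE) * sign(log2fc)
    z[log2fc == 0] <- 0
    data.frame(gene_id = rownames(va), mean_a = ma, mean_b = mb,
               log2fc = log2fc, z = z, p = p,
               fdr = stats::p.adjust(p, "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Stouffer combination of signed Z scores
#'
#' `sum(z)/sqrt(k)` with a two-sided normal p-value.
#'
#' @param zs non-empty vector of finite signed Z scores.
#' @return list with `z` and `p`.
#' @examples
#' stoufferZ(c(1.96, 1.96))$z  # 2.772
#' @export
stoufferZ <- function(zs) {
    if (!length(zs)) stop("empty Z-score list")
    if (any(!is.finite(zs))) stop("Z scores must be finite")
    z <- sum(zs) / sqrt(length(zs))
    list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Lineage-specific genes within one embryonic day
#'
#' For each lineage L among TE, EPI and PE, combines the per-gene Z
#' scores of L versus each of the other two lineages (Stouffer's
#' method), with BH FDR across genes.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param calls a \linkS4class{LineageCalls}.
#' @param day embryonic day with all three lineages called.
#' @return Named list (TE, EPI, PE) of data.frames with gene_id,
#'   combined z, p, fdr, significant (FDR <= 0.05) and rank, plus the
#'   two underlying contrasts in `attr(, "contrasts")`.
#' @export
lineageSpecific <- function(x, calls, day) {
    df <- lineageCalls(calls)
    dayOf <- cellDay(x)[match(df$cell_id, colnames(x))]
    cells <- split(df$cell_id[dayOf == day], df$lineage[dayOf == day])
    lins <- c("TE", "EPI", "PE")
    miss <- lins[!lins %in% names(cells) |
                 vapply(cells[lins], length, 1L) < 3]
    if (length(miss))
        stop("missing or too-small lineage at day ", day, ": ",
             paste(miss, collapse = ", "))
    out <- list()
    for (L in lins) {
        others <- setdiff(lins, L)
        d1 <- deTwoGroups(x, cells[[L]], cells[[others[1]]])
        d2 <- deTwoGroups(x, cells[[L]], cells[[others[2]]])
        common <- intersect(d1$gene_id, d2$gene_id)
        z1 <- d1$z[match(common, d1$gene_id)]
        z2 <- d2$z[match(common, d2$gene_id)]
        z <- (z1 + z2) / sqrt(2)
        p <- 2 * stats::pnorm(-abs(z))
        r <- data.frame(gene_id = common, z = z, p = p,
                        fdr = stats::p.adjust(p, "BH"),
                        stringsAsFactors = FALSE)
        r$significant <- r$fdr <= 0.05
        r <- r[order(-r$z), ]
        r$rank <- seq_len(nrow(r))
        rownames(r) <- NULL
        attr(r, "contrasts") <- list(d1, d2)
        out[[L]] <- r
    }
    out
}

#' Genes maintaining lineage specificity across days
#'
#' Stouffer-combines each lineage's within-day combined Z scores over
#' the given days (genes missing a day are excluded), with BH FDR and
#' descending rank.
#'
#' @param rankings list of per-day results from [lineageSpecific()],
#'   e.g. `list(rankingsE5, rankingsE6, rankingsE7)`.
#' @return Named list (TE, EPI, PE) of data.frames with gene_id,
#'   maintained z, p, fdr, significant, rank.
#' @export
maintainedGenes <- function(rankings) {
    lins <- c("TE", "EPI", "PE")
    out <- list()
    for (L in lins) {
        tabs <- lapply(rankings, `[[`, L)
        common <- Reduce(intersect, lapply(tabs, `[[`, "gene_id"))
        zmat <- vapply(tabs, function(t) t$z[match(common, t$gene_id)],
                       numeric(length(common)))
        z <- rowSums(zmat) / sqrt(ncol(zmat))
        p <- 2 * stats::pnorm(-abs(z))
        r <- data.frame(gene_id = common, z = z, p = p,
                        fdr = stats::p.adjust(p, "BH"),
                        stringsAsFactors = FALSE)
        r$significant <- r$fdr <= 0.05
        r <- r[order(-r$z), ]
        r$rank <- seq_len(nrow(r))
        rownames(r) <- NULL
        out[[L]] <- r
    }
    out
}

#' Within-embryo expression variability regressed on pseudo-time
#'
#' Per gene and embryo, the squared coefficient of variation of
#' `log2(RPKM + 1)` across the embryo's cells, computed only where the
#' embryo expresses the gene (mean RPKM >= 2; the CV of a barely
#' detected gene measures dropout noise, not regulation). Embryos with fewer
#' than 3 cells are skipped. Ordinary least squares of the score on the
#' embryo's mean pseudo-time, plus the embryo time at which the score
#' peaks; genes scored in fewer than 3 embryos get missing results.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param pt a \linkS4class{PseudotimeAssignment}.
#' @return data.frame with gene_id, slope, p, peak_time.
#' @export
embryoVariabilityRegression <- function(x, pt) {
    emb <- embryoId(x)
    keepEmb <- names(which(table(emb) >= 3))
    if (length(keepEmb) < 3) stop("need at least 3 embryos with >= 3 cells")
    L <- logExpr(x)[!spikeinFlag(x), , drop = FALSE]
    tEmb <- embryoPseudotime(pt)[keepEmb]
    rawExpr <- assay(x, "rpkm")[!spikeinFlag(x), , drop = FALSE]
    cv2 <- vapply(keepEmb, function(e) {
        Le <- L[, emb == e, drop = FALSE]
        m <- rowMeans(Le)
        v <- apply(Le, 1, stats::var)
        expressed <- rowMeans(rawExpr[, emb == e, drop = FALSE]) >= 2
        ifelse(expressed & m > 0, v / m^2, NA_real_)
    }, numeric(nrow(L)))
    res <- t(vapply(seq_len(nrow(cv2)), function(i) {
        ok <- !is.na(cv2[i, ])
        if (sum(ok) < 3) return(c(NA_real_, NA_real_, NA_real_))
        y <- cv2[i, ok]; t0 <- tEmb[ok]
        tc <- t0 - mean(t0)
        denom <- sum(tc^2)
        if (denom == 0) return(c(NA_real_, NA_real_, NA_real_))
        b <- sum(tc * y) / denom
        r <- y - (mean(y) + b * tc)
        s2 <- sum(r^2) / (length(y) - 2)
        p <- if (s2 == 0) ifelse(b == 0, 1, 0) else
            2 * stats::pt(-abs(b / sqrt(s2 / denom)), length(y) - 2)
        c(b, p, t0[which.max(y)])
    }, numeric(3)))
    data.frame(gene_id = rownames(L), slope = res[, 1], p = res[, 2],
               peak_time = res[, 3], row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Stage-wise gene-gene correlation modules
#'
#' Pearson correlations of `log2(RPKM + 1)` between the given genes
#' within each stage, with average-linkage hierarchical clustering of
#' `1 - r` cut at `cutHeight` to define modules. Genes constant within
#' a stage get missing correlations.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param genes gene IDs to correlate.
#' @param stages named list of cell-ID vectors (>= 3 cells each).
#' @param cutHeight dendrogram cut height on 1 - r.
#' @return Named list per stage: `cor` (gene x gene matrix) and
#'   `modules` (named integer vector of module memberships).
#' @export
stageGeneCorrelations <- function(x, genes, stages, cutHeight = 0.7) {
    out <- list()
    for (s in names(stages)) {
        cells <- stages[[s]]
        if (length(cells) < 3)
            stop("stage ", s, " has fewer than 3 cells")
        L <- t(logExpr(x)[genes, cells, drop = FALSE])
        sds <- apply(L, 2, stats::sd)
        r <- suppressWarnings(stats::cor(L))
        r[sds == 0, ] <- NA
        r[, sds == 0] <- NA
        ok <- sds > 0
        mod <- rep(NA_integer_, length(genes))
        names(mod) <- genes
        if (sum(ok) >= 2) {
            d <- stats::as.dist(1 - r[ok, ok])
            hc <- stats::hclust(d, method = "average")
            mod[ok] <- stats::cutree(hc, h = cutHeight)
        }
        out[[s]] <- list(cor = r, modules = mod)
    }
    out
}

#' Female-versus-male differential expression within a stratum
#'
#' Runs [deTwoGroups()] (female as group A) within one embryonic day
#' and optionally one lineage, and summarizes significant genes by
#' chromosome class plus the percentage of genes at fold-change >= 2
#' with a bootstrap standard deviation over cells.
#'
#' @param x an \linkS4class{EmbryoExpression} with sex assigned.
#' @param day embryonic day.
#' @param lineage optional lineage restriction (needs `calls`).
#' @param calls optional \linkS4class{LineageCalls}.
#' @param nBoot bootstrap resamples of cells (default 100).
#' @param fdrMax significance level on the FDR.
#' @return list with `de` (the DE table with a `chrom` column),
#'   `counts` (significant genes by chrX/chrY/autosome and direction),
#'   `fcPct` (percentage of tested genes at FC >= 2 up in females and
#'   in males, with bootstrap SDs).
#' @export
sexDE <- function(x, day, lineage = NULL, calls = NULL, nBoot = 100,
                  fdrMax = 0.05) {
    sel <- cellDay(x) == day
    if (!is.null(lineage)) {
        if (is.null(calls)) stop("lineage restriction requires calls")
        df <- lineageCalls(calls)
        sel <- sel & df$lineage[match(colnames(x), df$cell_id)] == lineage
    }
    sex <- cellSex(x)
    f <- colnames(x)[sel & sex == "female"]
    m <- colnames(x)[sel & sex == "male"]
    if (!length(f) || !length(m))
        stop("stratum does not contain both sexes")
    de <- deTwoGroups(x, f, m)
    de$chrom <- geneChrom(x)[match(de$gene_id, rownames(x))]
    cls <- ifelse(de$chrom == "chrX", "chrX",
                  ifelse(de$chrom == "chrY", "chrY", "autosome"))
    sig <- de$fdr <= fdrMax
    counts <- table(class = cls[sig],
                    direction = ifelse(de$z[sig] > 0, "female_up",
                                       "male_up"))
    pctFC <- function(d) c(
        female_up = 100 * mean(d$log2fc >= 1),
        male_up = 100 * mean(d$log2fc <= -1))
    obs <- pctFC(de)
    boot <- replicate(nBoot, {
        fb <- sample(f, replace = TRUE)
        mb <- sample(m, replace = TRUE)
        v <- assay(x, "rpkm")[de$gene_id, , drop = FALSE]
        fc <- log2((rowMeans(v[, fb, drop = FALSE]) + 1) /
                   (rowMeans(v[, mb, drop = FALSE]) + 1))
        c(100 * mean(fc >= 1), 100 * mean(fc <= -1))
    })
    fcPct <- data.frame(direction = c("female_up", "male_up"),
                        pct = as.numeric(obs),
                        sd = apply(boot, 1, stats::sd))
    list(de = de, counts = counts, fcPct = fcPct)
}
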