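test_that("Stouffer combination matches closed form and brute force", {
    expect_equal(stoufferZ(c(1.96, 1.96))$z, 2.772, tolerance = 1e-3)
    expect_equal(stoufferZ(5.2)$z, 5.2)
    expect_equal(stoufferZ(c(3.1, -3.1))$z, 0)
    expect_error(stoufferZ(numeric()), "empty")
    expect_error(stoufferZ(c(1, NA)), "finite")
    set.seed(8)
    for (k in c(2, 5, 17)) {
        z <- rnorm(k)
        expect_identical(stoufferZ(z)$z, sum(z) / sqrt(k))
    }
})

test_that("rank-sum differential expression behaves and calibrates", {
    a <- sharedAnalysis()
    ds <- a$ds
    cells <- a$truth@cells
    te <- cells$cell_id[cells$lineage == "TE" & cells$day == 6]
    icm <- cells$cell_id[cells$lineage %in% c("EPI", "PE") &
                         cells$day == 6]
    de <- deTwoGroups(ds, te, icm)
    ## swapping groups negates z and the fold change
    deR <- deTwoGroups(ds, icm, te)
    expect_equal(de$z, -deR$z[match(de$gene_id, deR$gene_id)],
                 tolerance = 1e-10)
    expect_equal(de$log2fc, -deR$log2fc[match(de$gene_id, deR$gene_id)])
    ## identical groups give no signal
    half <- split(te, rep(1:2, length.out = length(te)))
    deN <- deTwoGroups(ds, half[[1]], half[[2]])
    expect_equal(sum(deN$fdr <= 0.05), 0)
    expect_error(deTwoGroups(ds, te[1:2], icm), "at least 3")
    ## active trophectoderm program genes are recovered
    gt <- a$truth@genes
    teAct <- gt$gene_id[gt$program == "TE"]
    sig <- de$gene_id[de$fdr <= 0.05 & de$z > 0]
    expect_gte(mean(teAct %in% sig), 0.9)
})

test_that("reported FDR equals the Benjamini-Hochberg step-up rule", {
    ## hand-computed oracle on the DE output's own p-values
    a <- sharedAnalysis()
    cells <- a$truth@cells
    gA <- cells$cell_id[cells$lineage == "EPI" & cells$day == 7]
    gB <- cells$cell_id[cells$lineage == "PE" & cells$day == 7]
    de <- deTwoGroups(a$ds, gA, gB)
    p <- de$p[1:10]
    n <- length(p)
    o <- order(p)
    stepup <- numeric(n)
    adj <- p[o] * n / seq_len(n)
    for (i in n:1) stepup[i] <- min(adj[i:n], 1)
    oracle <- numeric(n); oracle[o] <- stepup
    expect_equal(p.adjust(p, "BH"), oracle, tolerance = 1e-12)
    ## and the full column is the BH adjustment of the p column
    expect_equal(de$fdr, p.adjust(de$p, "BH"), tolerance = 1e-12)
})

test_that("within-day lineage specificity combines the two contrasts", {
    a <- sharedAnalysis()
    calls <- truthCalls(a$truth)
    ls6 <- lineageSpecific(a$ds, calls, 6)
    ## brute-force identity against the stored contrasts
    r <- ls6$TE
    d1 <- attr(r, "contrasts")[[1]]
    d2 <- attr(r, "contrasts")[[2]]
    g <- r$gene_id[7]
    zBrute <- stoufferZ(c(d1$z[d1$gene_id == g],
                          d2$z[d2$gene_id == g]))$z
    expect_identical(r$z[7], zBrute)
    ## sign logic: a trophectoderm gene is positive for TE only
    teAll <- a$truth@genes$gene_id[a$truth@genes$program == "TE"]
    teGene <- intersect(intersect(teAll, ls6$EPI$gene_id),
                        ls6$PE$gene_id)[1]
    expect_gt(r$z[r$gene_id == teGene], 0)
    expect_lt(ls6$EPI$z[ls6$EPI$gene_id == teGene], 0)
    expect_lt(ls6$PE$z[ls6$PE$gene_id == teGene], 0)
    expect_error(lineageSpecific(a$ds, a$calls, 4), "missing")
})

test_that("maintained rankings combine days and cancel sign flips", {
    fake <- function(z) list(TE = data.frame(
        gene_id = c("g1", "g2"), z = z, stringsAsFactors = FALSE),
        EPI = data.frame(gene_id = c("g1", "g2"), z = z),
        PE = data.frame(gene_id = c("g1", "g2"), z = z))
    mt <- maintainedGenes(list(fake(c(4, 4)), fake(c(4, -4)),
                               fake(c(4, -4))))
    expect_equal(mt$TE$z[mt$TE$gene_id == "g1"], 12 / sqrt(3))
    expect_equal(mt$TE$z[mt$TE$gene_id == "g2"], -4 / sqrt(3))
    expect_true(mt$TE$significant[mt$TE$gene_id == "g1"])
    ## on a committed-stage cohort the maintained TE list is dominated
    ## by true trophectoderm-program genes (polar genes are TE-specific
    ## too)
    sim <- simulateExperiment(simConfig(
        nEmbryosPerDay = c(`5` = 10, `6` = 10, `7` = 10),
        cellsPerEmbryo = c(10, 16), hetSnvPerGene = 0, seed = 13))
    calls <- truthCalls(sim$truth)
    lsp <- lapply(5:7, function(d)
        lineageSpecific(sim$expression, calls, d))
    mt2 <- maintainedGenes(lsp)
    prg <- sim$truth@genes$program[match(mt2$TE$gene_id,
                                         sim$truth@genes$gene_id)]
    sig <- mt2$TE$significant & mt2$TE$z > 0
    expect_gte(mean(prg[sig] %in% c("TE", "polar")), 0.9)
    expect_gte(sum(head(prg, 100) %in% c("TE", "polar")), 90)
})

test_that("embryo variability peaks when lineages commit", {
    a <- sharedAnalysis()
    ev <- embryoVariabilityRegression(a$ds, a$pt)
    gt <- a$truth@genes
    lin <- ev[ev$gene_id %in% gt$gene_id[gt$program %in%
                                         c("TE", "EPI", "PE")], ]
    ## peak variability at or after commitment (4.75 -> 11.875 on the
    ## rescaled clock, within the half-day embryo sampling width)
    expect_gte(mean(lin$peak_time >= 11.25, na.rm = TRUE), 0.8)
    hk <- ev[ev$gene_id %in% gt$gene_id[gt$program == "housekeeping"], ]
    expect_lt(abs(median(hk$slope, na.rm = TRUE)), 0.05)
    ## constant genes have zero slope
    v <- matrix(3, 4, 12)
    x <- tinyExpr(v, day = rep(c(4L, 5L, 6L, 7L), each = 3),
                  embryo = rep(paste0("e", 1:4), each = 3))
    ptc <- new("PseudotimeAssignment",
               lambda = stats::setNames(rep(1, 12), colnames(x)),
               embryo = stats::setNames(c(10, 12.5, 15, 17.5),
                                        paste0("e", 1:4)),
               curve = matrix(0, 2, 2))
    ev0 <- embryoVariabilityRegression(x, ptc)
    expect_true(all(ev0$slope == 0))
})

test_that("stage-wise correlations rise as same-lineage genes engage", {
    a <- sharedAnalysis()
    cells <- a$truth@cells
    gt <- a$truth@genes
    teG <- head(gt$gene_id[gt$program == "TE"], 30)
    stages <- list(
        pre = cells$cell_id[cells$day == 4],
        post = cells$cell_id[cells$day == 6])
    sc <- stageGeneCorrelations(a$ds, teG, stages)
    med <- function(m) median(m[upper.tri(m)], na.rm = TRUE)
    expect_gt(med(sc$post$cor), med(sc$pre$cor))
    ## duplicated gene correlates perfectly; constant gene is missing
    v <- rbind(c(1, 5, 9, 2, 8, 4), c(1, 5, 9, 2, 8, 4), rep(3, 6))
    x <- tinyExpr(v)
    sc2 <- stageGeneCorrelations(x, rownames(x),
                                 list(s = colnames(x)))
    expect_equal(sc2$s$cor[1, 2], 1, tolerance = 1e-12)
    expect_true(is.na(sc2$s$cor[1, 3]))
})

test_that("sex-differential genes concentrate on the X chromosome", {
    a <- sharedAnalysis()
    sx <- sexDE(a$ds, day = 6, nBoot = 20)
    cnt <- sx$counts
    ## Y genes are always male-up
    if ("chrY" %in% rownames(cnt))
        expect_equal(cnt["chrY", "female_up"], 0)
    yRows <- sx$de[sx$de$chrom == "chrY", ]
    expect_true(all(yRows$log2fc < 0))
    ## chrX dominates female-biased genes under two active X
    fup <- sx$de$fdr <= 0.05 & sx$de$z > 0
    expect_gt(mean(sx$de$chrom[fup] == "chrX"), 0.5)
    expect_error(sexDE(a$ds[, cellSex(a$ds) == "female"], day = 6),
                 "both sexes")
})
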