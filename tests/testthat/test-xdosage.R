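test_that("expression-time trends detect female X downregulation", {
    ## a gene decreasing linearly with day has rho -1
    v <- matrix(rep(c(8, 6, 4, 2), each = 2), nrow = 1)
    x <- tinyExpr(v, day = rep(4:7, each = 2),
                  sex = rep("female", 8),
                  embryo = rep(paste0("e", 1:4), each = 2))
    tr <- geneTimeTrend(x, sex = "female")
    expect_equal(tr$rho[1], -1)
    ## under dampening, female chrX trends negative, males do not
    damp <- sharedDampSim()
    ds <- damp$expression
    tr2 <- geneTimeTrend(ds)
    xf <- median(tr2$rho[tr2$sex == "female" & tr2$chrom == "chrX"],
                 na.rm = TRUE)
    xm <- median(tr2$rho[tr2$sex == "male" & tr2$chrom == "chrX"],
                 na.rm = TRUE)
    expect_lt(xf, 0)
    expect_lt(xf, xm)
    tst <- attr(tr2, "tests")
    expect_lt(tst$chrX_female_vs_male, 0.01)
    expect_gt(tst$autosome_female_vs_male, 0.05)
})

test_that("female-to-male ratios track the simulated dose", {
    sim <- sharedSim()
    fm4 <- fmRatioPerGene(sim$expression, 4)
    expect_lt(abs(fm4$chrXMedian - 2), 0.25)
    expect_lt(abs(fm4$autosomeMedian - 1), 0.1)
    expect_lt(fm4$pChrXvsAutosome, 1e-6)
    damp <- sharedDampSim()
    fm7 <- fmRatioPerGene(damp$expression, 7)
    expect_lt(abs(fm7$chrXMedian - 1.1), 0.15)
    ## identical sexes give unit ratios
    v <- matrix(c(4, 4, 4, 4, 8, 8, 8, 8), nrow = 2, byrow = TRUE)
    x <- tinyExpr(v, day = rep(5L, 4),
                  sex = rep(c("female", "male"), 2),
                  embryo = paste0("e", 1:4))
    fmE <- fmRatioPerGene(x, 5)
    expect_true(all(fmE$perGene$ratio == 1))
})

test_that("moving-average tracks match a brute-force oracle exactly", {
    set.seed(12)
    nG <- 200
    v <- matrix(rnbinom(nG * 40, mu = 20, size = 3), nG)
    x <- tinyExpr(v, day = rep(5L, 40),
                  sex = rep(c("female", "male"), 20),
                  embryo = rep(paste0("e", 1:4), each = 10))
    rowData(x)$start <- sample.int(1e7, nG)
    tk <- movingAverageTrack(x, "chr1", days = 5, window = 25)
    ## independent O(n*w) recomputation
    sex <- cellSex(x)
    f <- rowMeans(rpkm(x)[tk@geneIds, sex == "female"])
    m <- rowMeans(rpkm(x)[tk@geneIds, sex == "male"])
    n <- length(tk@geneIds)
    oracle <- vapply(seq_len(n), function(i) {
        h <- min(12, i - 1, n - i)
        idx <- (i - h):(i + h)
        (mean(f[idx]) + 1) / (mean(m[idx]) + 1)
    }, numeric(1))
    expect_identical(unname(tk@ratio[, 1]), oracle)
    ## equal sexes are flat at one
    v2 <- matrix(rep(c(6, 6), each = 1), nrow = 1)
    x2 <- tinyExpr(matrix(6, 30, 8), day = rep(5L, 8),
                   sex = rep(c("female", "male"), 4),
                   embryo = paste0("e", 1:8))
    tk2 <- movingAverageTrack(x2, "chr1", days = 5, window = 5)
    expect_true(all(tk2@ratio == 1))
    expect_error(movingAverageTrack(x2, "chr1", days = 5,
                                    window = 100), "fewer than")
    ## dampening is chromosome-wide: the chrX track drops E4 to E7
    damp <- sharedDampSim()
    tkX <- movingAverageTrack(damp$expression, "chrX", days = c(4, 7))
    expect_gt(median(tkX@ratio[, 1]), 1.6)
    expect_lt(median(tkX@ratio[, 2]), 1.3)
    tkA <- movingAverageTrack(damp$expression, "chr1", days = c(4, 7))
    expect_lt(abs(median(tkA@ratio[, 2]) - 1), 0.1)
})

test_that("total X output drops in females under dampening only", {
    sim <- sharedSim()
    tx <- totalXOutput(sim$expression)
    pc <- tx$perCell
    med <- tapply(pc$xsum, list(pc$sex, pc$day), median)
    expect_gt(med["female", "4"] / med["male", "4"], 1.6)
    damp <- sharedDampSim()
    txd <- totalXOutput(damp$expression)
    pcd <- txd$perCell
    medd <- tapply(pcd$xsum, list(pcd$sex, pcd$day), median)
    expect_lt(medd["female", "7"] / medd["female", "4"], 0.75)
    expect_lt(abs(medd["male", "7"] / medd["male", "4"] - 1), 0.2)
    expect_lt(txd$tests[[grep("female_E", names(txd$tests))[1]]], 0.01)
    ## single-gene sum is the gene's value
    x <- tinyExpr(matrix(c(3, 7), 1), chrom = "chrX",
                  day = c(4L, 7L), sex = c("female", "female"),
                  embryo = c("e1", "e2"))
    expect_equal(unname(totalXOutput(x, "g01")$perCell$xsum), c(3, 7))
})

test_that("expression fractions above thresholds behave monotonically", {
    sim <- sharedSim()
    fr <- geneFractionAbove(sim$expression, "XIST", c(0, 1, 5, 1e9))
    ## monotone non-increasing in the threshold
    for (s in c("female", "male")) for (d in 5:7) {
        ff <- fr$fraction[fr$sex == s & fr$day == d]
        expect_true(all(diff(ff[order(fr$threshold[fr$sex == s &
                                                   fr$day == d])]) <= 0))
    }
    expect_true(all(fr$fraction[fr$threshold == 1e9] == 0))
    ## XIST is female-biased from E5 on at every threshold
    for (d in 5:7) for (th in c(1, 5)) {
        f <- fr$fraction[fr$sex == "female" & fr$day == d &
                         fr$threshold == th]
        m <- fr$fraction[fr$sex == "male" & fr$day == d &
                         fr$threshold == th]
        expect_gte(f, m)
    }
    expect_error(geneFractionAbove(sim$expression, "NOPE"), "NOPE")
})

test_that("the X0 screen flags single-X female embryos only", {
    sim <- simulateExperiment(simConfig(
        nEmbryosPerDay = c(`5` = 8), cellsPerEmbryo = c(10, 14),
        nX0Embryos = 1, seed = 7))
    ds <- sim$expression
    cells <- sim$truth@cells
    x0emb <- unique(cells$embryo_id[cells$x0])
    expect_length(x0emb, 1)
    r0 <- x0Screen(ds, x0emb)
    expect_true(r0$applicable)
    expect_true(r0$flag)
    normalF <- setdiff(unique(cells$embryo_id[cells$sex == "female"]),
                       x0emb)[1]
    expect_false(x0Screen(ds, normalF)$flag)
    maleEmb <- unique(cells$embryo_id[cells$sex == "male"])[1]
    expect_false(x0Screen(ds, maleEmb)$applicable)
})
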