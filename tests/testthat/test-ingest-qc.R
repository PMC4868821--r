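makeFixtureFiles <- function(dir, mtx = FALSE) {
    m <- matrix(c(0, 1.5, 3, 2, 0, 7), nrow = 3,
                dimnames = list(c("gA", "gB", "gC"), c("c1", "c2")))
    genes <- data.frame(gene_id = rownames(m), chrom = "chr1",
                        start = c(100, 200, 300), length_bp = 1000L,
                        is_spikein = FALSE)
    cells <- data.frame(cell_id = colnames(m), embryo_id = "e1",
                        day = 5L)
    x <- EmbryoExpression(m, genes, cells)
    mp <- file.path(dir, if (mtx) "m.mtx" else "m.tsv")
    gp <- file.path(dir, "genes.tsv")
    cp <- file.path(dir, "cells.tsv")
    writeExpression(x, mp, gp, cp)
    list(x = x, matrix = mp, genes = gp, cells = cp)
}

test_that("datasets round-trip through TSV and MatrixMarket losslessly", {
    d <- withr::local_tempdir()
    f <- makeFixtureFiles(d)
    y <- readExpression(f$matrix, f$genes, f$cells)
    expect_equal(dim(y), c(3L, 2L))
    expect_equal(rpkm(y), rpkm(f$x), tolerance = 1e-8)
    fm <- makeFixtureFiles(d, mtx = TRUE)
    ym <- readExpression(fm$matrix, fm$genes, fm$cells)
    expect_equal(rpkm(ym), rpkm(y), tolerance = 1e-8)
    expect_equal(as.data.frame(rowData(ym)), as.data.frame(rowData(y)))
})

test_that("malformed inputs fail with informative parse errors", {
    d <- withr::local_tempdir()
    f <- makeFixtureFiles(d)
    ## annotation row count mismatch
    g <- utils::read.delim(f$genes)
    utils::write.table(g[1:2, ], f$genes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_error(readExpression(f$matrix, f$genes, f$cells), "match")
    ## duplicate gene IDs
    g2 <- utils::read.delim(file.path(d, "genes.tsv"))
    f2 <- makeFixtureFiles(d)
    g2 <- utils::read.delim(f2$genes)
    g2$gene_id <- c("gA", "gA", "gC")
    utils::write.table(g2, f2$genes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_error(readExpression(f2$matrix, f2$genes, f2$cells),
                 "duplicate gene ID: gA")
    ## negative values
    f3 <- makeFixtureFiles(d)
    tab <- utils::read.delim(f3$matrix, check.names = FALSE)
    tab[2, 2] <- -1
    utils::write.table(tab, f3$matrix, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_error(readExpression(f3$matrix, f3$genes, f3$cells),
                 "negative value")
})

test_that("RPKM arithmetic matches its definition and is scale-free", {
    expect_equal(computeRPKM(matrix(100), 1000, 1e6)[1, 1], 100)
    expect_equal(computeRPKM(matrix(0), 1000, 1e6)[1, 1], 0)
    expect_equal(computeRPKM(matrix(10), 500, 2e6)[1, 1], 10)
    cnt <- matrix(rpois(20, 50), 4)
    tot <- colSums(cnt) + 1000
    expect_equal(computeRPKM(cnt, c(500, 1000, 2000, 800), tot),
                 computeRPKM(2 * cnt, c(500, 1000, 2000, 800), 2 * tot))
    expect_error(computeRPKM(matrix(1), 1000, 0), "positive")
})

test_that("expressed-gene threshold is inclusive", {
    x <- tinyExpr(matrix(c(0, 0, 0, 1.0, 0.99, 7), nrow = 3))
    em <- expressedMask(x)
    expect_equal(unname(em$counts), c(0L, 2L))
    expect_true(em$mask[1, 2])          # exactly 1.0 counts
    expect_false(em$mask[2, 2])
    expect_error(expressedMask(x, threshold = 0), "positive")
})

test_that("QC keeps correlated cells and is idempotent", {
    x <- tinyExpr(cbind(c(1, 5, 9, 2), c(1, 5, 9, 2)))
    q <- qcFilter(x)
    expect_true(all(qcPass(q)))
    sim <- sharedSim()
    dg <- degradeCells(sim$expression, 5, seed = 3)
    q1 <- qcFilter(dg$expression)
    expect_false(any(qcPass(q1)[dg$degraded]))
    keep <- colnames(q1)[qcPass(q1)]
    q2 <- qcFilter(q1[, keep])
    expect_true(all(qcPass(q2)))        # nothing new removed
    expect_true(all(qcPass(qcFilter(x, rhoMin = -1))))
    expect_error(qcFilter(x[, 1]), "two cells")
})

test_that("sex classification follows the Y-sum thresholds and truth", {
    v <- matrix(c(0, 5, 9, 150, 75, 3), nrow = 3, byrow = FALSE)
    x <- tinyExpr(v, chrom = c("chrY", "chrY", "chr1"))
    ## cell 1: Y sum 5 -> female; cell 2: Y sum 225 -> male
    cs <- classifySex(x)
    expect_equal(unname(cellSex(cs$expression)[1]), "female")
    expect_equal(unname(cellSex(cs$expression)[2]), "male")
    x2 <- tinyExpr(matrix(c(75, 0), 2), chrom = c("chrY", "chr1"))
    expect_equal(unname(cellSex(classifySex(x2)$expression)),
                 "unknown")
    expect_error(classifySex(tinyExpr(matrix(1))), "Y-chromosome")
    ## full agreement with simulated truth on clean data
    sim <- sharedSim()
    cs <- classifySex(sim$expression)
    expect_identical(unname(cellSex(cs$expression)),
                     sim$truth@cells$sex)
    expect_false(any(cs$embryos$conflict))
})

test_that("Y-gene activation rises between E3 and E4", {
    sim <- sharedSim()
    ds <- classifySex(sim$expression)$expression
    z <- yZgaSummary(ds)
    expect_lt(z$perDay[["3"]], z$perDay[["4"]])
    expect_lt(z$pValue, 0.01)
    expect_error(yZgaSummary(ds, character()), "empty")
    ## all-equal expression normalizes to 1
    v <- matrix(60, 2, 6)
    x <- tinyExpr(v, chrom = c("chrY", "chrY"),
                  day = c(3L, 3L, 4L, 5L, 6L, 7L), sex = rep("male", 6),
                  embryo = paste0("e", 1:6))
    z2 <- yZgaSummary(x)
    expect_true(all(z2$perCell$normalized == 1))
})
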