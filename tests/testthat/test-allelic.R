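test_that("SNV classification applies the detection and minor rules", {
    cls <- classifySNV(c(0, 10, 20, 1, 5), c(0, 10, 1, 1, 45))
    expect_equal(cls$call,
                 c("undetected", "biallelic", "mono_ref", "undetected",
                   "biallelic"))
    expect_equal(cls$ratio[2], 0.5)
    expect_true(is.na(cls$ratio[1]))
    expect_error(classifySNV(-1, 3), "non-negative")
    ## scaling both counts up never demotes a biallelic call
    set.seed(9)
    ref <- rpois(500, 6); alt <- rpois(500, 6)
    c1 <- classifySNV(ref, alt)$call
    c10 <- classifySNV(ref * 10L, alt * 10L)$call
    expect_false(any(c1 == "biallelic" & c10 != "biallelic"))
})

test_that("biallelic fractions respect the SNV coverage floor", {
    mk <- function(n, nBi, chrom = "chrX") data.frame(
        cell_id = "c1", snv_id = sprintf("s%03d", seq_len(n)),
        chrom = chrom, pos = seq_len(n), gene_id = "g",
        ref_reads = ifelse(seq_len(n) <= nBi, 5L, 10L),
        alt_reads = ifelse(seq_len(n) <= nBi, 5L, 0L),
        stringsAsFactors = FALSE)
    expect_equal(biallelicFraction(AlleleCounts(mk(30, 30)), "c1",
                                   "chrX"), 1.0)
    expect_true(is.na(biallelicFraction(AlleleCounts(mk(24, 24)), "c1",
                                        "chrX")))
    expect_equal(biallelicFraction(AlleleCounts(mk(30, 3)), "c1",
                                   "chrX"), 0.1)
})

test_that("relative chrX ratios match identical allelic behavior", {
    ## same biallelic behavior on chrX and autosomes gives ratio one
    rows <- do.call(rbind, lapply(c("chrX", "chr1", "chr2"), function(ch)
        data.frame(cell_id = "c1",
                   snv_id = paste0(ch, "_", 1:40), chrom = ch,
                   pos = 1:40, gene_id = "g",
                   ref_reads = rep(c(5L, 10L), 20),
                   alt_reads = rep(c(5L, 0L), 20),
                   stringsAsFactors = FALSE)))
    rb <- relativeBiallelicRatio(AlleleCounts(rows))
    expect_equal(rb$ratio, 1.0)
    expect_equal(rb$ratio_chr1, 1.0)
})

test_that("allelic histograms expose monoallelic male X expression", {
    sim <- sharedSim()
    cells <- sim$truth@cells
    m7 <- cells$cell_id[cells$sex == "male" & cells$day == 7]
    h <- allelicRatioHistogram(sim$alleles, m7, "chrX")
    outer <- (h$counts[1] + h$counts[length(h$counts)]) / sum(h$counts)
    expect_gte(outer, 0.95)
    ## balanced biallelic data modes at one half
    bal <- data.frame(cell_id = "c1", snv_id = sprintf("s%d", 1:50),
                      chrom = "chr1", pos = 1:50, gene_id = "g",
                      ref_reads = 10L, alt_reads = 10L)
    hb <- allelicRatioHistogram(AlleleCounts(bal), "c1", "chr1")
    expect_equal(which.max(hb$counts), 5L, tolerance = 1)
    he <- allelicRatioHistogram(sim$alleles, character(), "chrX")
    expect_equal(sum(he$counts), 0L)
})

test_that("gene-level allele tables group cells by embryo", {
    cm <- data.frame(cell_id = sprintf("c%d", 1:6),
                     embryo_id = rep(c("e1", "e2"), each = 3))
    ac <- AlleleCounts(data.frame(
        cell_id = c("c1", "c4"), snv_id = "s1", chrom = "chrX",
        pos = 1L, gene_id = "XIST", ref_reads = c(4L, 6L),
        alt_reads = c(5L, 0L), stringsAsFactors = FALSE))
    tab <- geneAlleleBarplotData(ac, "XIST", cm)
    expect_equal(nrow(tab), 6L)
    expect_equal(sum(tab$no_reads), 4L)
    expect_error(geneAlleleBarplotData(ac, "ATRX", cm), "no SNV")
    ## under dampening XIST stays biallelic in expressing female cells
    damp <- sharedDampSim()
    cells <- damp$truth@cells
    fem <- cells$cell_id[cells$sex == "female" & cells$day >= 5]
    df <- alleleCounts(damp$alleles)
    xi <- df[df$gene_id == "XIST" & df$cell_id %in% fem, ]
    cls <- classifySNV(xi$ref_reads, xi$alt_reads)
    det <- cls$call != "undetected"
    expect_gte(mean(cls$call[det] == "biallelic"), 0.8)
})

test_that("male chrX biallelic signal marks maternal RNA clearance", {
    sim <- sharedSim()
    cells <- sim$truth@cells
    males <- cells$cell_id[cells$sex == "male"]
    zga <- maleXBiallelicZga(sim$alleles, males,
                             cells$day[match(males, cells$cell_id)])
    med <- tapply(zga$perCell$chrx, zga$perCell$day, median,
                  na.rm = TRUE)
    expect_gt(med[["3"]], med[["4"]] + 0.2)
    expect_lt(zga$pValue, 0.01)
    ## chr1 control shows no such drop
    med1 <- tapply(zga$perCell$chr1, zga$perCell$day, median,
                   na.rm = TRUE)
    expect_lt(abs(med1[["3"]] - med1[["4"]]), 0.15)
    ## single-day input yields fractions but no test
    m4 <- males[cells$day[match(males, cells$cell_id)] == 4]
    z4 <- maleXBiallelicZga(sim$alleles, m4, rep(4, length(m4)))
    expect_true(is.na(z4$pValue))
})

test_that("Fisher comparison equals the hypergeometric tail oracle", {
    ac <- AlleleCounts(data.frame(
        cell_id = rep(c("a1", "b1"), each = 20),
        snv_id = rep(sprintf("s%d", 1:20), 2), chrom = "chrX",
        pos = 1:20, gene_id = "g",
        ref_reads = c(rep(5L, 12), rep(10L, 8), rep(5L, 3),
                      rep(10L, 17)),
        alt_reads = c(rep(5L, 12), rep(0L, 8), rep(5L, 3),
                      rep(0L, 17)), stringsAsFactors = FALSE))
    res <- compareBiallelicProportions(ac, "a1", "b1", "chrX")
    expect_equal(unname(res$table["A", ]), c(12, 8))
    expect_equal(unname(res$table["B", ]), c(3, 17))
    ## two-sided Fisher p as the sum of hypergeometric probabilities no
    ## larger than the observed table's
    m <- res$table
    k <- sum(m["A", ]); n <- sum(m); K <- sum(m[, "bi"])
    probs <- dhyper(0:min(k, K), K, n - K, k)
    pObs <- dhyper(m["A", "bi"], K, n - K, k)
    oracle <- sum(probs[probs <= pObs * (1 + 1e-7)])
    expect_equal(res$p, oracle, tolerance = 1e-10)
})

test_that("allele tables survive a TSV round trip", {
    sim <- sharedSim()
    df <- head(alleleCounts(sim$alleles), 100)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeAlleleCounts(AlleleCounts(df), path)
    back <- readAlleleCounts(path)
    expect_equal(alleleCounts(back), df, ignore_attr = TRUE)
})
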