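#' Classify per-cell SNV allelic expression
#'
#' A site with fewer than `minReads` total reads is undetected;
#' otherwise it is biallelic when the minor allele has at least
#' `minorMinReads` reads *and* at least `minorMinFrac` of the total,
#' else monoallelic for the major allele. Vectorized over sites.
#'
#' @param refReads,altReads non-negative read counts.
#' @param minReads detection threshold on total reads.
#' @param minorMinReads,minorMinFrac biallelic thresholds on the minor
#'   allele.
#' @return data.frame with `call` (undetected, mono_ref, mono_alt,
#'   biallelic) and `ratio` (alt/(ref+alt), `NA` when undetected).
#' @examples
#' classifySNV(c(0, 10, 20), c(0, 10, 1))$call
#' @export
classifySNV <- function(refReads, altReads, minReads = 3,
                        minorMinReads = 2, minorMinFrac = 0.1) {
    if (any(refReads < 0) || any(altReads < 0))
        stop("read counts must be non-negative")
    tot <- refReads + altReads
    minor <- pmin(refReads, altReads)
    call <- rep("undetected", length(tot))
    det <- tot >= minReads
    bi <- det & minor >= minorMinReads & minor / tot >= minorMinFrac
    call[det & !bi & altReads > refReads] <- "mono_alt"
    call[det & !bi & altReads <= refReads] <- "mono_ref"
    call[bi] <- "biallelic"
    data.frame(call = call,
               ratio = ifelse(det, altReads / tot, NA_real_),
               stringsAsFactors = FALSE)
}

## per-cell detected/biallelic tallies for one chromosome filter
alleleTally <- function(df, chromFilter = NULL, exclude = c("chrY"),
                        ...) {
    if (!is.null(chromFilter)) df <- df[df$chrom %in% chromFilter, ]
    df <- df[!df$chrom %in% exclude, ]
    cls <- classifySNV(df$ref_reads, df$alt_reads, ...)
    det <- cls$call != "undetected"
    data.frame(cell_id = df$cell_id, detected = det,
               biallelic = cls$call == "biallelic",
               stringsAsFactors = FALSE)
}

#' Biallelic fraction of a cell's SNVs
#'
#' Fraction of detected SNVs (chromosome-filtered) called biallelic;
#' missing when fewer than `minSnvs` SNVs are detected.
#'
#' @param ac an \linkS4class{AlleleCounts}.
#' @param cell cell ID.
#' @param chromFilter chromosomes to keep (`NULL` = all but chrY).
#' @param minSnvs minimum detected SNVs (default 25).
#' @param ... thresholds passed to [classifySNV()].
#' @return A single fraction, or `NA` when under-covered.
#' @export
biallelicFraction <- function(ac, cell, chromFilter = NULL,
                              minSnvs = 25, ...) {
    df <- alleleCounts(ac)
    df <- df[df$cell_id == cell, ]
    t <- alleleTally(df, chromFilter, ...)
    nDet <- sum(t$detected)
    if (nDet < minSnvs) return(NA_real_)
    sum(t$biallelic) / nDet
}

#' Relative chrX biallelic ratio per cell
#'
#' Per cell, the chrX biallelic fraction divided by the autosomal
#' biallelic fraction; also computed per autosomal chromosome as
#' negative controls. Cells with an undefined or zero autosomal
#' fraction, or with fewer than `minSnvs` detected chrX SNVs, are
#' missing.
#'
#' @param ac an \linkS4class{AlleleCounts}.
#' @param cells cell IDs (default: all cells in the table).
#' @param minSnvs minimum detected SNVs per fraction (default 25).
#' @param controlChroms autosomes reported individually.
#' @param ... thresholds passed to [classifySNV()].
#' @return data.frame with cell_id, chrx_fraction, autosome_fraction,
#'   ratio, and one `ratio_<chrom>` column per control chromosome.
#' @export
relativeBiallelicRatio <- function(ac, cells = NULL, minSnvs = 25,
                                   controlChroms = c("chr1", "chr2",
                                                     "chr3"), ...) {
    df <- alleleCounts(ac)
    if (is.null(cells)) cells <- sort(unique(df$cell_id))
    autos <- setdiff(unique(df$chrom), c("chrX", "chrY"))
    rows <- lapply(cells, function(cl) {
        d <- df[df$cell_id == cl, ]
        fx <- fracOf(d, "chrX", minSnvs, ...)
        fa <- fracOf(d, autos, minSnvs, ...)
        ratio <- if (is.na(fx) || is.na(fa) || fa == 0) NA_real_ else
            fx / fa
        ctl <- vapply(controlChroms, function(ch) {
            fc <- fracOf(d, ch, minSnvs, ...)
            if (is.na(fc) || is.na(fa) || fa == 0) NA_real_ else fc / fa
        }, numeric(1))
        c(chrx_fraction = fx, autosome_fraction = fa, ratio = ratio,
          stats::setNames(ctl, paste0("ratio_", controlChroms)))
    })
    out <- data.frame(cell_id = cells, do.call(rbind, rows),
                      stringsAsFactors = FALSE, row.names = NULL)
    out
}

fracOf <- function(d, chroms, minSnvs, ...) {
    t <- alleleTally(d, chroms, ...)
    nDet <- sum(t$detected)
    if (nDet < minSnvs) return(NA_real_)
    sum(t$biallelic) / nDet
}

#' Histogram of allelic expression ratios
#'
#' Bins alt/(ref+alt) over all detected (cell, SNV) pairs on one
#' chromosome.
#'
#' @param ac an \linkS4class{AlleleCounts}.
#' @param cells cell IDs to include.
#' @param chrom chromosome.
#' @param breaks histogram breakpoints on \[0, 1\].
#' @param ... thresholds passed to [classifySNV()].
#' @return list with `counts`, `breaks` and the underlying `ratios`.
#' @export
allelicRatioHistogram <- function(ac, cells, chrom,
                                  breaks = seq(0, 1, 0.1), ...) {
    df <- alleleCounts(ac)
    df <- df[df$cell_id %in% cells & df$chrom == chrom, ]
    cls <- classifySNV(df$ref_reads, df$alt_reads, ...)
    r <- cls$ratio[cls$call != "undetected"]
    if (!length(r))
        return(list(counts = integer(length(breaks) - 1),
                    breaks = breaks, ratios = numeric()))
    h <- graphics::hist(r, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)
    list(counts = h$counts, breaks = breaks, ratios = r)
}

#' Per-cell allele counts of one gene, grouped by embryo
#'
#' Tidy table for allele-specific barplots: one row per cell and SNV of
#' the gene, with embryo grouping and a flag for cells lacking any
#' spanning read.
#'
#' @param ac an \linkS4class{AlleleCounts}.
#' @param gene gene ID with at least one SNV in the table.
#' @param cellMeta data.frame with cell_id and embryo_id covering the
#'   cells of interest.
#' @param embryos optional embryo subset.
#' @return data.frame with embryo_id, cell_id, snv_id, ref_reads,
#'   alt_reads, no_reads.
#' @export
geneAlleleBarplotData <- function(ac, gene, cellMeta, embryos = NULL) {
    df <- alleleCounts(ac)
    df <- df[df$gene_id == gene, ]
    if (!nrow(df)) stop("gene has no SNV in the table: ", gene)
    snvs <- unique(df$snv_id)
    if (!is.null(embryos))
        cellMeta <- cellMeta[cellMeta$embryo_id %in% embryos, ]
    grid <- expand.grid(cell_id = cellMeta$cell_id, snv_id = snvs,
                        stringsAsFactors = FALSE)
    grid$embryo_id <- cellMeta$embryo_id[match(grid$cell_id,
                                               cellMeta$cell_id)]
    i <- match(paste(grid$cell_id, grid$snv_id),
               paste(df$cell_id, df$snv_id))
    grid$ref_reads <- ifelse(is.na(i), 0L, df$ref_reads[i])
    grid$alt_reads <- ifelse(is.na(i), 0L, df$alt_reads[i])
    grid$no_reads <- grid$ref_reads + grid$alt_reads == 0
    grid[order(grid$embryo_id, grid$cell_id, grid$snv_id),
         c("embryo_id", "cell_id", "snv_id", "ref_reads", "alt_reads",
           "no_reads")]
}

#' Biallelic chrX fraction of male cells per day
#'
#' Tracks the zygotic-genome-activation indicator of lingering maternal
#' transcripts: the per-cell fraction of detected chrX SNVs called
#' biallelic in male cells, by embryonic day, with chr1 as a control
#' and a Mann-Whitney-Wilcoxon comparison of E3 against E4 when both
#' are present.
#'
#' @param ac an \linkS4class{AlleleCounts}.
#' @param maleCells male cell IDs.
#' @param days per-cell day labels parallel to `maleCells`.
#' @param minSnvs minimum detected SNVs per cell.
#' @param ... thresholds passed to [classifySNV()].
#' @return list with `perCell` (cell_id, day, chrX and chr1 fractions)
#'   and `pValue` (E3 vs E4 on chrX, `NA` for single-day input).
#' @export
maleXBiallelicZga <- function(ac, maleCells, days, minSnvs = 10, ...) {
    df <- alleleCounts(ac)
    perCell <- data.frame(
        cell_id = maleCells, day = days,
        chrx = vapply(maleCells, function(cl)
            fracOf(df[df$cell_id == cl, ], "chrX", minSnvs, ...),
            numeric(1)),
        chr1 = vapply(maleCells, function(cl)
            fracOf(df[df$cell_id == cl, ], "chr1", minSnvs, ...),
            numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    p <- NA_real_
    if (all(c(3, 4) %in% days)) {
        a <- perCell$chrx[perCell$day == 3]
        b <- perCell$chrx[perCell$day == 4]
        if (sum(!is.na(a)) && sum(!is.na(b)))
            p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
    }
    list(perCell = perCell, pValue = p)
}

#' Fisher test of biallelic proportions between two cell groups
#'
#' Builds the 2x2 table of biallelic versus monoallelic detected SNV
#' calls on one chromosome for two groups of cells and applies the
#' two-sided Fisher's exact test.
#'
#' @param ac an \linkS4class{AlleleCounts}.
#' @param cellsA,cellsB cell ID groups.
#' @param chrom chromosome.
#' @param ... thresholds passed to [classifySNV()].
#' @return list with `table` (2x2 matrix) and `p`.
#' @export
compareBiallelicProportions <- function(ac, cellsA, cellsB, chrom,
                                        ...) {
    df <- alleleCounts(ac)
    tally <- function(cells) {
        t <- alleleTally(df[df$cell_id %in% cells &
                            df$chrom == chrom, ], ...)
        c(bi = sum(t$biallelic), mono = sum(t$detected & !t$biallelic))
    }
    m <- rbind(A = tally(cellsA), B = tally(cellsB))
    list(table = m, p = stats::fisher.test(m)$p.value)
}

#' Read a SNV catalog from a VCF file
#'
#' Extracts (snv_id, chrom, pos) from a VCF; genotype fields are not
#' interpreted (reference/alternative are arbitrary labels downstream).
#'
#' @param path VCF path.
#' @return data.frame with snv_id, chrom, pos (1-based).
#' @export
snvCatalogFromVCF <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("the vcfR package is required to read VCF catalogs")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    data.frame(snv_id = fix$ID, chrom = fix$CHROM,
               pos = as.integer(fix$POS), stringsAsFactors = FALSE)
}

#' Read/write an allele-count table
#'
#' TSV with columns cell_id, snv_id, chrom, pos, gene_id, ref_reads,
#' alt_reads.
#'
#' @param path TSV path.
#' @return An \linkS4class{AlleleCounts}.
#' @export
readAlleleCounts <- function(path) {
    AlleleCounts(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname readAlleleCounts
#' @param ac an \linkS4class{AlleleCounts} to write.
#' @export
writeAlleleCounts <- function(ac, path) {
    utils::write.table(alleleCounts(ac), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
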