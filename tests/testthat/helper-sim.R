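## Shared simulated fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
    .fixtures[[key]]
}

## reference experiment under the two-active-X regime
sharedSim <- function() memo("sim", simulateExperiment(simConfig(seed = 42)))

## matching experiment under chromosome-wide dampening
sharedDampSim <- function() memo("damp",
    simulateExperiment(simConfig(dosageMode = "dampening", seed = 77)))

## noise fit, variable genes, embedding, pseudo-time and lineage calls
## for the reference experiment
sharedAnalysis <- function() memo("analysis", {
    sim <- sharedSim()
    ds <- sim$expression
    nf <- fitTechnicalNoise(ds)
    vs <- variabilityScores(ds, nf)
    g500 <- topVariableGenes(vs, 500)
    coords <- embed2D(ds, g500, "pca", seed = 0)
    pt <- assignPseudotime(coords, cellDay(ds), embryoId(ds))
    polar <- grep("^(POL|CCR7|CYP19A1|DLX5|ERVFRD1|GCM1)",
                  rownames(ds), value = TRUE)
    calls <- callLineages(ds, pt, nf, polarGenes = polar)
    list(ds = ds, truth = sim$truth, alleles = sim$alleles, nf = nf,
         vs = vs, g500 = g500, coords = coords, pt = pt, calls = calls,
         polar = polar)
})

## lineage calls taken from simulation truth (for gene-level statistics
## that should not inherit classifier error)
truthCalls <- function(truth) {
    cells <- truth@cells
    new("LineageCalls", table = data.frame(
        cell_id = cells$cell_id, lineage = cells$lineage,
        te_subpop = cells$te_subpop, silhouette = NA_real_,
        marker_score = NA_real_, stringsAsFactors = FALSE))
}

## small fully explicit expression fixture
tinyExpr <- function(values, chrom = NULL, day = NULL, sex = NULL,
                     embryo = NULL) {
    values <- as.matrix(values)
    nG <- nrow(values); nC <- ncol(values)
    if (is.null(chrom)) chrom <- rep("chr1", nG)
    genes <- data.frame(gene_id = sprintf("g%02d", seq_len(nG)),
                        chrom = chrom, start = seq_len(nG) * 1000,
                        length_bp = 1000L, is_spikein = FALSE)
    cells <- data.frame(cell_id = sprintf("c%02d", seq_len(nC)),
                        embryo_id = if (is.null(embryo))
                            rep("e1", nC) else embryo,
                        day = if (is.null(day)) rep(5L, nC) else day)
    if (!is.null(sex)) cells$sex <- sex
    EmbryoExpression(values, genes, cells)
}

## rank-based AUROC
aucRank <- function(pos, neg) {
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
}

## reduced configuration for repeated null-structure runs
nullDayConfig <- function(seed) simConfig(
    nGenes = 800, nSpikeins = 40, nXGenes = 60,
    lineageGeneCounts = c(TE = 30, EPI = 30, PE = 30),
    nPolarGenes = 10, nTemporalGenes = 120, nMaternalGenes = 20,
    nEmbryosPerDay = c(`4` = 6), cellsPerEmbryo = c(9, 13), seed = seed)
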