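#' Configuration of a synthetic preimplantation experiment
#'
#' Defines the generative conditions of a simulated allele-resolved
#' Smart-seq2-like experiment spanning embryonic days E3--E7: embryo and
#' cell numbers, gene programs (three lineages with early/mid/late
#' activation waves, polar trophectoderm genes, temporal and maternal
#' transcripts, Y genes, XIST/XACT), the X-dosage regime, technical noise
#' calibrated on spike-ins, and allele-level read sampling.
#'
#' @section Dosage regimes:
#' `two_active` keeps both female X alleles fully active (female:male
#' expression 2); `dampening` multiplies *both* alleles by the per-day
#' factor of `dampeningSchedule` (non-increasing); `xci` silences one
#' whole X per affected cell, with the per-day completion fraction of
#' `xciSchedule` (non-decreasing).
#'
#' @export
setClass("SimConfig", representation(
    nEmbryosPerDay = "numeric", cellsPerEmbryo = "numeric",
    nGenes = "numeric", nSpikeins = "numeric", nXGenes = "numeric",
    lineageGeneCounts = "numeric", waveFractions = "numeric",
    nPolarGenes = "numeric", nTemporalGenes = "numeric",
    nMaternalGenes = "numeric",
    coexpressionLevel = "numeric", commitDay = "numeric",
    dosageMode = "character", dampeningSchedule = "numeric",
    xciSchedule = "numeric",
    burstDispersion = "numeric", dropoutShape = "numeric",
    techNoise = "numeric", hetSnvPerGene = "numeric",
    snvReadRate = "numeric", allelicOverdispersion = "numeric",
    maternalCarryover = "numeric", yDayThreeLevel = "numeric",
    nX0Embryos = "numeric", seed = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    frac <- c(object@waveFractions, object@coexpressionLevel,
              object@xciSchedule, object@maternalCarryover,
              object@yDayThreeLevel)
    if (any(frac < 0 | frac > 1))
        msg <- c(msg, "all fractions must lie in [0, 1]")
    if (any(object@dampeningSchedule <= 0 | object@dampeningSchedule > 1))
        msg <- c(msg, "dampening factors must lie in (0, 1]")
    if (is.unsorted(rev(object@dampeningSchedule)))
        msg <- c(msg, "dampeningSchedule must be non-increasing in day")
    if (is.unsorted(object@xciSchedule))
        msg <- c(msg, "xciSchedule must be non-decreasing in day")
    if (!object@dosageMode %in% c("two_active", "dampening", "xci"))
        msg <- c(msg, "dosageMode must be two_active, dampening or xci")
    if (object@nGenes < 400)
        msg <- c(msg, "nGenes must be at least 400")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", sum(object@nEmbryosPerDay), "embryos over days",
        paste0("E", names(object@nEmbryosPerDay), collapse = ","), "\n")
    cat("  genes:", object@nGenes, "+", object@nSpikeins, "spike-ins;",
        "dosage mode:", object@dosageMode, "; seed:", object@seed, "\n")
})

#' Build a simulation configuration
#'
#' All arguments have defaults describing the reference conditions; any
#' subset can be overridden. Supplying `dampeningSchedule` together with
#' `dosageMode = "xci"` (or `xciSchedule` with a non-XCI mode) is a
#' configuration error.
#'
#' @param nEmbryosPerDay named integer vector, embryos per embryonic day
#'   (names in `"3"`..`"7"`).
#' @param cellsPerEmbryo length-2 integer range of cells sampled per embryo.
#' @param nGenes,nSpikeins number of biological genes and spike-ins.
#' @param nXGenes number of X-linked genes (within `nGenes`).
#' @param lineageGeneCounts named vector (TE, EPI, PE) of program sizes.
#' @param waveFractions named fractions (early, mid, late) of each program.
#' @param nPolarGenes,nTemporalGenes,nMaternalGenes sizes of the polar-TE,
#'   temporally trending and maternally deposited gene sets.
#' @param coexpressionLevel fraction of the committed expression level at
#'   which uncommitted cells co-express early-wave genes of all lineages.
#' @param commitDay day at which lineages become mutually exclusive.
#' @param dosageMode one of `"two_active"`, `"dampening"`, `"xci"`.
#' @param dampeningSchedule named per-day per-allele factor in (0, 1],
#'   non-increasing (dampening mode only).
#' @param xciSchedule named per-day completion fraction in \[0, 1\],
#'   non-decreasing (xci mode only).
#' @param burstDispersion gamma dispersion of the per-cell biological
#'   burst factor (CV^2 of bursting; 0.25 corresponds to CV 0.5).
#' @param dropoutShape named (midpoint, slope) of the logistic
#'   mean-dependent dropout curve on log2(mu + 1).
#' @param techNoise named (a1, alpha0) of the spike-in technical model
#'   CV^2 = a1/mu + alpha0.
#' @param hetSnvPerGene heterozygous SNVs simulated per gene.
#' @param snvReadRate expected SNV-spanning reads per RPKM unit.
#' @param allelicOverdispersion beta-binomial concentration of allele
#'   sampling (larger = closer to binomial).
#' @param maternalCarryover fraction of E3 male chrX reads attributable to
#'   lingering maternal transcripts of the second allele.
#' @param yDayThreeLevel male Y-gene expression at E3 relative to E4+
#'   (incomplete zygotic genome activation).
#' @param nX0Embryos number of day-5 female embryos simulated with a
#'   single X (X0 karyotype).
#' @param seed integer seed; a fixed seed gives identical output.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 7)
#' cfg
#' @export
simConfig <- function(nEmbryosPerDay = c(`3` = 6, `4` = 6, `5` = 8,
                                         `6` = 8, `7` = 8),
                      cellsPerEmbryo = c(8L, 16L),
                      nGenes = 2000, nSpikeins = 60, nXGenes = 160,
                      lineageGeneCounts = c(TE = 100, EPI = 100, PE = 100),
                      waveFractions = c(early = 1/3, mid = 1/3, late = 1/3),
                      nPolarGenes = 60, nTemporalGenes = 250,
                      nMaternalGenes = 50,
                      coexpressionLevel = 0.5, commitDay = 4.75,
                      dosageMode = c("two_active", "dampening", "xci"),
                      dampeningSchedule = NULL, xciSchedule = NULL,
                      burstDispersion = 0.25,
                      dropoutShape = c(midpoint = 0.5, slope = 0.5),
                      techNoise = c(a1 = 5, alpha0 = 0.1),
                      hetSnvPerGene = 1, snvReadRate = 1.5,
                      allelicOverdispersion = 20,
                      maternalCarryover = 0.3, yDayThreeLevel = 0.3,
                      nX0Embryos = 0, seed = 1) {
    dosageMode <- match.arg(dosageMode)
    if (!is.null(dampeningSchedule) && dosageMode != "dampening")
        stop("dampeningSchedule given but dosageMode is '", dosageMode, "'")
    if (!is.null(xciSchedule) && dosageMode != "xci")
        stop("xciSchedule given but dosageMode is '", dosageMode, "'")
    if (is.null(dampeningSchedule))
        dampeningSchedule <- c(`3` = 1, `4` = 1, `5` = 0.85,
                               `6` = 0.7, `7` = 0.55)
    if (is.null(xciSchedule))
        xciSchedule <- c(`3` = 0, `4` = 0, `5` = 0.2, `6` = 0.4, `7` = 0.6)
    new("SimConfig",
        nEmbryosPerDay = nEmbryosPerDay, cellsPerEmbryo = cellsPerEmbryo,
        nGenes = nGenes, nSpikeins = nSpikeins, nXGenes = nXGenes,
        lineageGeneCounts = lineageGeneCounts, waveFractions = waveFractions,
        nPolarGenes = nPolarGenes, nTemporalGenes = nTemporalGenes,
        nMaternalGenes = nMaternalGenes,
        coexpressionLevel = coexpressionLevel, commitDay = commitDay,
        dosageMode = dosageMode, dampeningSchedule = dampeningSchedule,
        xciSchedule = xciSchedule,
        burstDispersion = burstDispersion, dropoutShape = dropoutShape,
        techNoise = techNoise, hetSnvPerGene = hetSnvPerGene,
        snvReadRate = snvReadRate,
        allelicOverdispersion = allelicOverdispersion,
        maternalCarryover = maternalCarryover,
        yDayThreeLevel = yDayThreeLevel,
        nX0Embryos = nX0Embryos, seed = seed)
}

## Named marker genes embedded in the simulated programs so that the
## default marker panels apply directly to simulated data.
SIM_MARKERS <- list(
    TE  = c("GATA2", "GATA3", "DAB2", "PTGES", "EMP2", "TGFBR3",
            "PDGFA", "CLDN4"),
    EPI = c("NANOG", "PRDM14", "SOX2", "TDGF1", "GDF3", "DPPA5",
            "ARGFX", "NODAL"),
    PE  = c("GATA4", "HNF1B", "PDGFRA", "COL4A1", "FGFR2", "LAMA4",
            "LINC00261", "FRZB"),
    polar = c("CCR7", "CYP19A1", "DLX5", "ERVFRD1", "GCM1"))

Y_GENE_COUNT <- 12L

simGeneTable <- function(config) {
    nL <- config@lineageGeneCounts
    ids <- list()
    ids$Y <- sprintf("YG%02d", seq_len(Y_GENE_COUNT))
    ids$X <- c("XIST", "XACT",
               sprintf("XG%03d", seq_len(config@nXGenes - 2)))
    for (L in c("TE", "EPI", "PE")) {
        mk <- SIM_MARKERS[[L]]
        extra <- nL[[L]] - length(mk)
        ids[[L]] <- c(mk, sprintf("%s%03d", L, seq_len(max(0, extra))))
    }
    ids$polar <- c(SIM_MARKERS$polar,
                   sprintf("POL%03d", seq_len(config@nPolarGenes -
                                              length(SIM_MARKERS$polar))))
    ids$temporal <- sprintf("TMP%03d", seq_len(config@nTemporalGenes))
    ids$maternal <- sprintf("MAT%03d", seq_len(config@nMaternalGenes))
    nHK <- config@nGenes - config@nXGenes - sum(nL) - config@nPolarGenes -
        config@nTemporalGenes - config@nMaternalGenes
    if (nHK < 50)
        stop("nGenes too small for the configured program sizes")
    ids$hk <- sprintf("HK%04d", seq_len(nHK - Y_GENE_COUNT))
    program <- rep(c("Y", "xlinked", "TE", "EPI", "PE", "polar",
                     "temporal", "maternal", "housekeeping"),
                   times = c(lengths(ids)[c("Y", "X", "TE", "EPI", "PE",
                                            "polar", "temporal",
                                            "maternal")], length(ids$hk)))
    gene_id <- unlist(ids, use.names = FALSE)
    stopifnot(length(gene_id) == config@nGenes)
    chrom <- rep(NA_character_, config@nGenes)
    chrom[program == "Y"] <- "chrY"
    chrom[program == "xlinked"] <- "chrX"
    auto <- is.na(chrom)
    chrom[auto] <- paste0("chr", 1 + (seq_len(sum(auto)) - 1L) %% 6L)
    ## wave per lineage gene, cycled so every wave holds named markers
    wave <- rep(NA_character_, config@nGenes)
    wnames <- c("early", "mid", "late")
    for (L in c("TE", "EPI", "PE")) {
        idx <- which(program == L)
        k <- round(length(idx) * config@waveFractions /
                   sum(config@waveFractions))
        k[3] <- length(idx) - k[1] - k[2]
        ## round-robin so the named markers spread across waves
        rem <- k; j <- 0L
        for (i in seq_along(idx)) {
            repeat { j <- j %% 3L + 1L; if (rem[j] > 0) break }
            wave[idx[i]] <- wnames[j]; rem[j] <- rem[j] - 1L
        }
    }
    ## positions: random ascending per chromosome
    start <- integer(config@nGenes)
    for (ch in unique(chrom)) {
        i <- which(chrom == ch)
        start[i] <- sort(sample.int(2e8L, length(i)))
    }
    g <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                    length_bp = sample(500:5000, config@nGenes, TRUE),
                    is_spikein = FALSE, program = program, wave = wave,
                    stringsAsFactors = FALSE)
    s <- data.frame(gene_id = sprintf("ERCC-%04d", seq_len(config@nSpikeins)),
                    chrom = "spikein", start = seq_len(config@nSpikeins),
                    length_bp = 1000L, is_spikein = TRUE,
                    program = "spikein", wave = NA_character_,
                    stringsAsFactors = FALSE)
    rbind(g, s)
}

#' Per-cell X-allele activity factors under a dosage regime
#'
#' Returns the (maternal, paternal) activity of the two female X alleles:
#' `two_active` gives (1, 1); `dampening` gives (d, d) with `d` looked up
#' in the schedule for the given day; `xci` silences one allele (chosen
#' uniformly) per cell with the day's completion probability, otherwise
#' (1, 1). Draws use the current RNG state.
#'
#' @param mode dosage regime.
#' @param day embryonic day used for schedule lookup.
#' @param n number of cells.
#' @param dampeningSchedule,xciSchedule named per-day schedules; defaults
#'   are those of [simConfig()].
#' @return An `n` x 2 matrix with values in \[0, 1\].
#' @examples
#' xAlleleFactors("dampening", day = 7, n = 2)
#' @export
xAlleleFactors <- function(mode = c("two_active", "dampening", "xci"),
                           day, n = 1,
                           dampeningSchedule = c(`3` = 1, `4` = 1,
                               `5` = 0.85, `6` = 0.7, `7` = 0.55),
                           xciSchedule = c(`3` = 0, `4` = 0, `5` = 0.2,
                               `6` = 0.4, `7` = 0.6)) {
    mode <- match.arg(mode)
    f <- matrix(1, n, 2, dimnames = list(NULL, c("maternal", "paternal")))
    if (mode == "dampening") {
        d <- if (as.character(day) %in% names(dampeningSchedule))
            dampeningSchedule[[as.character(day)]] else NULL
        if (is.null(d) || d < 0 || d > 1)
            stop("dampening factor for day ", day, " missing or outside [0, 1]")
        f[] <- d
    } else if (mode == "xci") {
        cc <- if (as.character(day) %in% names(xciSchedule))
            xciSchedule[[as.character(day)]] else NULL
        if (is.null(cc) || cc < 0 || cc > 1)
            stop("xci completion for day ", day, " missing or outside [0, 1]")
        hit <- stats::runif(n) < cc
        side <- 1L + (stats::runif(n) < 0.5)
        f[cbind(which(hit), side[hit])] <- 0
    }
    f
}

simCellTable <- function(config) {
    rows <- list()
    eIdx <- 0L
    for (d in as.integer(names(config@nEmbryosPerDay))) {
        nE <- config@nEmbryosPerDay[[as.character(d)]]
        for (e in seq_len(nE)) {
            eIdx <- eIdx + 1L
            sex <- if (e %% 2L == 1L) "female" else "male"
            embryo <- sprintf("E%d.%02d", d, e)
            tE <- d + stats::runif(1, -0.3, 0.3)
            nC <- sample(config@cellsPerEmbryo[1]:config@cellsPerEmbryo[2], 1)
            tC <- tE + stats::runif(nC, -0.1, 0.1)
            rows[[eIdx]] <- data.frame(
                cell_id = sprintf("%s.c%02d", embryo, seq_len(nC)),
                embryo_id = embryo, day = d, subday = NA_character_,
                sex = sex, pseudotime = tC, stringsAsFactors = FALSE)
        }
    }
    cells <- do.call(rbind, rows)
    ## lineage truth: pre iff true pseudo-time < commit day
    committed <- cells$pseudotime >= config@commitDay
    lin <- rep("pre", nrow(cells))
    lin[committed] <- sample(c("TE", "EPI", "PE"), sum(committed), TRUE,
                             prob = c(0.5, 0.25, 0.25))
    cells$lineage <- lin
    ## polar/mural among TE cells of day >= 6, half of each embryo
    cells$te_subpop <- NA_character_
    for (em in unique(cells$embryo_id)) {
        i <- which(cells$embryo_id == em & cells$lineage == "TE" &
                   cells$day >= 6)
        if (length(i) >= 2) {
            pol <- sample(i, ceiling(length(i) / 2))
            cells$te_subpop[pol] <- "polar"
            cells$te_subpop[setdiff(i, pol)] <- "mural"
        } else if (length(i) == 1) cells$te_subpop[i] <- "mural"
    }
    ## X0 embryos: first nX0Embryos female day-5 embryos
    cells$x0 <- FALSE
    if (config@nX0Embryos > 0) {
        fem5 <- unique(cells$embryo_id[cells$sex == "female" &
                                       cells$day == 5])
        x0 <- utils::head(fem5, config@nX0Embryos)
        cells$x0 <- cells$embryo_id %in% x0
    }
    cells
}

XIST_FEMALE_LEVEL <- c(`3` = 0.5, `4` = 5, `5` = 20, `6` = 30, `7` = 40)

## Expected RPKM matrix (genes x cells) before noise; also returns the
## per-cell (maternal, paternal) X activity factors.
simExpectedMeans <- function(config, genes, cells) {
    nG <- nrow(genes); nC <- nrow(cells)
    base <- numeric(nG)
    prog <- genes$program
    base[prog %in% c("housekeeping", "temporal", "maternal")] <-
        2^stats::rnorm(sum(prog %in% c("housekeeping", "temporal",
                                       "maternal")), 3, 2.5)
    base[prog == "xlinked"] <- 2^stats::rnorm(sum(prog == "xlinked"), 4.2, 0.8)
    base[prog == "Y"] <- 2^stats::runif(sum(prog == "Y"), 5.2, 7)
    offLevel <- stats::runif(sum(prog %in% c("TE", "EPI", "PE", "polar")),
                             0.5, 2)
    base[prog %in% c("TE", "EPI", "PE", "polar")] <- offLevel
    base <- pmin(pmax(base, 0.3), 500)
    fold <- numeric(nG)
    ## trophectoderm divergence dominates; epiblast vs primitive
    ## endoderm is a weaker, later contrast
    fold[prog == "TE"] <- 2^stats::runif(sum(prog == "TE"), 3.5, 5.5)
    fold[prog %in% c("EPI", "PE")] <-
        2^stats::runif(sum(prog %in% c("EPI", "PE")), 2.8, 4.2)
    fold[prog == "polar"] <- 2^stats::runif(sum(prog == "polar"), 2.8, 4)
    slope <- numeric(nG)
    iT <- which(prog == "temporal")
    slope[iT] <- sample(c(-1, 1), length(iT), TRUE) *
        stats::runif(length(iT), 0.3, 1.0)

    t <- cells$pseudotime
    day <- cells$day
    female <- cells$sex == "female" & !cells$x0
    mu <- matrix(rep(base, nC), nG, nC)

    ## temporal trends and maternal decay
    mu[iT, ] <- mu[iT, ] * 2^outer(slope[iT], t - 5)
    iM <- which(prog == "maternal")
    mu[iM, ] <- mu[iM, ] * rep(2^(-1.2 * (t - 3)), each = length(iM))

    ## lineage programs; activation is asynchronous per gene and cell
    ## (Bernoulli with a logistic ramp in time), so that pre-lineage
    ## cells form a continuum rather than an artificial on/off split
    waveDay <- c(early = config@commitDay - 1, mid = config@commitDay,
                 late = config@commitDay + 1)
    for (L in c("TE", "EPI", "PE")) {
        iL <- which(prog == L)
        for (w in names(waveDay)) {
            iw <- iL[genes$wave[iL] == w]
            if (!length(iw)) next
            ramp <- stats::plogis((t - waveDay[[w]]) / 0.25)
            isLin <- cells$lineage == L
            boost <- matrix(1, length(iw), nC)
            ## committed cells: smooth coherent activation in time
            if (any(isLin))
                boost[, isLin] <- outer(fold[iw], ramp[isLin], `^`)
            if (w == "early") {
                ## uncommitted co-expression turns on slowly and
                ## uniformly: the pre-lineage state is homogeneous
                ## within a day, and heterogeneity only appears when
                ## lineages commit
                pre <- cells$lineage == "pre"
                rampCo <- stats::plogis((t - waveDay[[w]]) / 0.7)
                if (any(pre))
                    boost[, pre] <- outer(
                        1 + config@coexpressionLevel * (fold[iw] - 1),
                        rampCo[pre],
                        function(b, r) b^r)
            }
            mu[iw, ] <- mu[iw, ] * boost
        }
    }
    ## polar genes in polar TE cells
    iP <- which(prog == "polar")
    pol <- !is.na(cells$te_subpop) & cells$te_subpop == "polar"
    if (any(pol))
        mu[iP, pol] <- mu[iP, pol] * rep(fold[iP], sum(pol))

    ## Y genes: male only, reduced at E3
    iY <- which(prog == "Y")
    male <- cells$sex == "male"
    yfac <- ifelse(male, ifelse(day == 3, config@yDayThreeLevel, 1), 0)
    mu[iY, ] <- mu[iY, ] * rep(yfac, each = length(iY))

    ## X dosage: per-allele rate is half the two-active female level
    af <- matrix(0, nC, 2, dimnames = list(cells$cell_id,
                                           c("maternal", "paternal")))
    af[male | cells$x0, 1] <- 1
    for (d in unique(day)) {
        i <- which(female & day == d)
        if (!length(i)) next
        af[i, ] <- xAlleleFactors(config@dosageMode, d, length(i),
                                  config@dampeningSchedule,
                                  config@xciSchedule)
    }
    iX <- which(genes$chrom == "chrX" &
                !genes$gene_id %in% c("XIST", "XACT"))
    xdose <- rowSums(af) / 2       # female two-active = 1, male = 0.5
    mu[iX, ] <- mu[iX, ] * rep(xdose, each = length(iX))

    ## XIST: female ramp (escapes dampening, expressed also from the
    ## silenced X under xci); male sporadic low. XACT: on from E4, higher
    ## in females.
    iXIST <- which(genes$gene_id == "XIST")
    mu[iXIST, ] <- ifelse(female, XIST_FEMALE_LEVEL[as.character(day)], 0.3)
    iXACT <- which(genes$gene_id == "XACT")
    mu[iXACT, ] <- ifelse(day >= 4, ifelse(female, 8, 3), 0.3)

    ## spike-ins: fixed concentrations across cells, wide dynamic range
    iS <- which(genes$is_spikein)
    muS <- 2^stats::runif(length(iS), -1, 7)
    mu[iS, ] <- rep(muS, nC)

    list(mu = mu, alleleFactors = af, fold = fold, slope = slope)
}

## Gamma-Poisson sampling with spike-in-calibrated technical noise and
## mean-dependent logistic dropout (biological genes only).
simSampleValues <- function(config, genes, mu) {
    a1 <- config@techNoise[["a1"]]
    alpha0 <- config@techNoise[["alpha0"]]
    phi <- config@burstDispersion
    nG <- nrow(mu); nC <- ncol(mu)
    v <- matrix(0, nG, nC)
    iS <- which(genes$is_spikein)
    iB <- which(!genes$is_spikein)
    ## technical layer: NB with CV^2 = a1/mu + alpha0, realised as a
    ## scaled NB so the model holds exactly
    v[iS, ] <- a1 * stats::rnbinom(length(iS) * nC,
                                   mu = mu[iS, ] / a1, size = 1 / alpha0)
    burst <- stats::rgamma(length(iB) * nC, shape = 1 / phi, scale = phi)
    muB <- mu[iB, ] * burst
    v[iB, ] <- a1 * stats::rnbinom(length(iB) * nC,
                                   mu = muB / a1, size = 1 / alpha0)
    mid <- config@dropoutShape[["midpoint"]]
    slo <- config@dropoutShape[["slope"]]
    pdrop <- stats::plogis((mid - log2(mu[iB, ] + 1)) / slo)
    drop <- stats::runif(length(iB) * nC) < pdrop
    vb <- v[iB, ]
    vb[drop] <- 0
    v[iB, ] <- vb
    v
}

simAlleleCounts <- function(config, genes, cells, values, af) {
    snvGenes <- which(!genes$is_spikein & genes$chrom != "chrY")
    nS <- length(snvGenes) * config@hetSnvPerGene
    snv <- data.frame(
        snv_id = sprintf("rs%06d", seq_len(nS)),
        gene = rep(snvGenes, each = config@hetSnvPerGene),
        stringsAsFactors = FALSE)
    snv$chrom <- genes$chrom[snv$gene]
    snv$pos <- genes$start[snv$gene] +
        sample.int(500L, nS, replace = TRUE)
    snv$gene_id <- genes$gene_id[snv$gene]
    nC <- nrow(cells)
    ## per-embryo phase: is the maternal allele the reference allele?
    embryos <- unique(cells$embryo_id)
    phase <- matrix(stats::runif(nS * length(embryos)) < 0.5, nS,
                    length(embryos), dimnames = list(NULL, embryos))
    lam <- values[snv$gene, , drop = FALSE] * config@snvReadRate
    tot <- stats::rpois(length(lam), lam)
    dim(tot) <- dim(lam)
    keep <- which(tot > 0, arr.ind = TRUE)
    if (!nrow(keep))
        return(AlleleCounts(data.frame(cell_id = character(),
            snv_id = character(), chrom = character(), pos = integer(),
            gene_id = character(), ref_reads = integer(),
            alt_reads = integer())))
    si <- keep[, 1]; ci <- keep[, 2]
    T <- tot[keep]
    matIsRef <- phase[cbind(si, match(cells$embryo_id[ci], embryos))]
    isX <- snv$chrom[si] == "chrX"
    isXIST <- snv$gene_id[si] == "XIST"
    fm <- af[ci, 1]; fp <- af[ci, 2]
    sexC <- cells$sex[ci]; dayC <- cells$day[ci]
    ## expected fraction of reads from the maternal allele
    pm <- ifelse(isX, ifelse(fm + fp > 0, fm / (fm + fp), 0.5), 0.5)
    ## XIST is transcribed from both X alleles while dampening proceeds;
    ## under xci it is expressed from the silenced chromosome
    if (config@dosageMode == "xci") {
        sil <- isXIST & (fm == 0 | fp == 0)
        pm[sil] <- ifelse(fm[sil] == 0, 1, 0)
        pm[isXIST & !(fm == 0 | fp == 0)] <- 0.5
    } else pm[isXIST] <- 0.5
    ## lingering maternal transcripts: male E3 chrX reads partly derive
    ## from the second (grand-maternal) allele
    mono <- isX & (sexC == "male" | cells$x0[ci])
    pm[mono] <- 1
    carry <- mono & dayC == 3
    pm[carry] <- 1 - config@maternalCarryover
    pRef <- ifelse(matIsRef, pm, 1 - pm)
    ## beta-binomial overdispersion around the allele-activity ratio
    nu <- config@allelicOverdispersion
    inner <- pRef > 0 & pRef < 1
    p <- pRef
    p[inner] <- stats::rbeta(sum(inner), pRef[inner] * nu,
                             (1 - pRef[inner]) * nu)
    ref <- stats::rbinom(length(T), T, p)
    df <- data.frame(cell_id = cells$cell_id[ci],
                     snv_id = snv$snv_id[si],
                     chrom = snv$chrom[si], pos = snv$pos[si],
                     gene_id = snv$gene_id[si],
                     ref_reads = ref, alt_reads = T - ref,
                     stringsAsFactors = FALSE)
    df <- df[order(df$cell_id, df$snv_id), ]
    rownames(df) <- NULL
    AlleleCounts(df)
}

#' Simulate an allele-resolved preimplantation scRNA-seq experiment
#'
#' Generates an RPKM-like expression matrix with spike-ins obeying the
#' technical model CV^2 = a1/mu + alpha0, lineage programs with
#' activation waves and an uncommitted co-expression state, sex-linked
#' expression (Y genes, XIST/XACT), female X output following the chosen
#' dosage regime, and per-SNV allele read counts drawn with beta-binomial
#' overdispersion around the allele-activity ratio. Output is
#' deterministic for a fixed `seed` in the configuration.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A list with elements `expression`
#'   (\linkS4class{EmbryoExpression}), `alleles`
#'   (\linkS4class{AlleleCounts}) and `truth` (\linkS4class{SimTruth}).
#' @examples
#' sim <- simulateExperiment(simConfig(nGenes = 120, nSpikeins = 10,
#'     nXGenes = 20, nTemporalGenes = 10, nMaternalGenes = 5,
#'     lineageGeneCounts = c(TE = 5, EPI = 5, PE = 5), nPolarGenes = 5,
#'     nEmbryosPerDay = c(`4` = 2, `5` = 2), seed = 1))
#' sim$expression
#' @export
simulateExperiment <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    genes <- simGeneTable(config)
    cells <- simCellTable(config)
    exp <- simExpectedMeans(config, genes, cells)
    values <- simSampleValues(config, genes, exp$mu)
    alleles <- simAlleleCounts(config, genes, cells, values,
                               exp$alleleFactors)
    ds <- EmbryoExpression(
        values,
        genes[, c("gene_id", "chrom", "start", "length_bp", "is_spikein")],
        cells[, c("cell_id", "embryo_id", "day", "subday", "sex")])
    truthCells <- cells
    truthCells$degraded <- FALSE
    truth <- new("SimTruth", cells = truthCells,
                 genes = genes[, c("gene_id", "chrom", "program", "wave")],
                 alleleFactors = exp$alleleFactors,
                 config = list(dosageMode = config@dosageMode,
                               commitDay = config@commitDay,
                               seed = config@seed,
                               techNoise = config@techNoise))
    list(expression = ds, alleles = alleles, truth = truth)
}

#' Replace cells with within-cell permuted profiles
#'
#' Produces low-quality "cells" by permuting each selected cell's values
#' across genes, destroying the gene-level structure that drives
#' cell-cell correlation while preserving the value distribution.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param nBad number of cells to degrade.
#' @param seed RNG seed for selecting cells and permutations.
#' @return list with `expression` (modified dataset) and `degraded`
#'   (character vector of degraded cell IDs).
#' @export
degradeCells <- function(x, nBad, seed = 1) {
    if (nBad >= ncol(x)) stop("nBad must be smaller than the number of cells")
    if (nBad == 0) return(list(expression = x, degraded = character()))
    set.seed(seed)
    bad <- sample(colnames(x), nBad)
    v <- assay(x, "rpkm")
    for (b in bad) v[, b] <- v[sample.int(nrow(v)), b]
    assays(x)$rpkm <- v
    list(expression = x, degraded = bad)
}
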