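## Diffusion-map coordinates of a cell x feature matrix.
## Gaussian kernel with the median-pairwise-distance bandwidth
## (parameter-free and deterministic), row-normalized to a Markov
## transition matrix; components are the leading non-trivial right
## eigenvectors scaled by their eigenvalues.
diffusionMapCoords <- function(L, nComponents) {
    n <- nrow(L)
    if (nComponents > n - 1)
        stop("nComponents must be at most cells - 1")
    D <- as.matrix(stats::dist(L))
    sigma <- stats::median(D[upper.tri(D)])
    if (sigma == 0) stop("degenerate input: all cells coincide")
    K <- exp(-D^2 / (2 * sigma^2))
    deg <- rowSums(K)
    if (any(deg - 1 < 1e-12))
        stop("kernel graph disconnected; increase the bandwidth")
    ## symmetrized normalization shares eigenvectors with the Markov matrix
    S <- K / sqrt(deg %o% deg)
    es <- eigen(S, symmetric = TRUE)
    comp <- seq(2, nComponents + 1)
    psi <- es$vectors[, comp, drop = FALSE] / sqrt(deg)
    coords <- sweep(psi, 2, es$values[comp], "*")
    ## fix sign for determinism: largest-magnitude loading positive
    for (j in seq_len(ncol(coords))) {
        k <- which.max(abs(coords[, j]))
        if (coords[k, j] < 0) coords[, j] <- -coords[, j]
    }
    rownames(coords) <- rownames(L)
    colnames(coords) <- paste0("DC", seq_len(ncol(coords)))
    coords
}

#' Diffusion-map embedding on a gene set
#'
#' Diffusion components of `log2(RPKM + 1)` over the given genes
#' (typically the lineage-specific genes). The kernel bandwidth is the
#' median pairwise distance, making the embedding deterministic.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param genes gene IDs (present in `x`).
#' @param nComponents number of diffusion components (< number of cells).
#' @return cell x `nComponents` coordinate matrix.
#' @export
diffusionEmbedding <- function(x, genes, nComponents = 3) {
    miss <- setdiff(genes, rownames(x))
    if (length(miss))
        stop("genes absent from dataset: ", paste(miss, collapse = ", "))
    diffusionMapCoords(t(logExpr(x)[genes, , drop = FALSE]), nComponents)
}

#' Fit the lineage decision surface
#'
#' Linear soft-margin support vector machine (C = 1) trained on the
#' matured cells of the two classes; all supplied coordinates are then
#' scored by signed distance to the separating hyperplane. Training
#' cells of the first class level score positive.
#'
#' @param coords cell x d coordinates (e.g. diffusion components).
#' @param labels factor/character of class labels for the training
#'   cells, `NA` for cells to score only; both classes need >= 5 cells.
#' @param cost soft-margin cost.
#' @return A \linkS4class{SegregationProfile}.
#' @export
fitSegregationSurface <- function(coords, labels, cost = 1) {
    lab <- factor(labels)
    train <- !is.na(labels)
    lv <- levels(lab)
    if (length(lv) != 2)
        stop("need exactly two classes, got ", length(lv))
    if (any(table(lab[train]) < 5))
        stop("both classes need at least 5 matured cells")
    ## normalized component units: a single global scale keeps the
    ## embedding's shape (and rotation invariance) while giving the
    ## soft-margin problem a sensible magnitude
    s <- sqrt(mean(apply(coords[train, , drop = FALSE], 2,
                         stats::var)))
    if (s == 0) stop("degenerate coordinates")
    coords <- coords / s
    fit <- e1071::svm(coords[train, , drop = FALSE], lab[train],
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    nw <- sqrt(sum(w^2))
    d <- (coords %*% w + b) / nw
    ## orient: first class level positive
    if (mean(d[train & lab == lv[1]]) < 0) d <- -d
    new("SegregationProfile",
        distance = stats::setNames(drop(d), rownames(coords)),
        surface = list(w = w / nw, b = b / nw), classes = lv)
}

#' Segregation magnitude versus developmental time
#'
#' Averages |signed distance| per embryo, orders embryos by pseudo-time
#' and fits the least-squares two-level step function to locate the
#' rise of lineage segregation; the changepoint is the midpoint between
#' the two embryos flanking the fitted step. The time at which the
#' profile first reaches 90% of the post-rise plateau is reported
#' alongside.
#'
#' @param profile a \linkS4class{SegregationProfile}.
#' @param pt a \linkS4class{PseudotimeAssignment} covering the same
#'   cells.
#' @param embryoIds per-cell embryo IDs (same order as the profile).
#' @return list with `perEmbryo` (data.frame embryo, time, mean
#'   |distance|), `changepoint` (embryo time of the rise, `NA` when the
#'   profile is flat) and `plateau` (post-rise mean).
#' @export
segregationVsTime <- function(profile, pt, embryoIds) {
    d <- abs(segregationDistance(profile))
    emb <- tapply(d, embryoIds, mean)
    t <- embryoPseudotime(pt)[names(emb)]
    if (length(emb) < 3) stop("need at least 3 embryos")
    ord <- order(t)
    y <- as.numeric(emb)[ord]; tt <- as.numeric(t)[ord]
    n <- length(y)
    ## least-squares piecewise-constant (one changepoint) fit
    sse <- vapply(seq_len(n - 1), function(k) {
        sum((y[1:k] - mean(y[1:k]))^2) +
            sum((y[(k + 1):n] - mean(y[(k + 1):n]))^2)
    }, numeric(1))
    k <- which.min(sse)
    plateau <- mean(y[(k + 1):n])
    lo <- mean(y[1:k])
    flat <- stats::sd(y) == 0 || (plateau - lo) < 0.05 * max(abs(y))
    cp <- if (flat) NA_real_ else (tt[k] + tt[k + 1]) / 2
    t90 <- if (flat) NA_real_ else tt[min(which(y >= 0.9 * plateau))]
    list(perEmbryo = data.frame(embryo_id = names(emb)[ord], time = tt,
                                mean_abs_distance = y,
                                stringsAsFactors = FALSE),
         changepoint = cp, plateauTime = t90, plateau = plateau)
}
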