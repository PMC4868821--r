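#' Fit the spike-in technical-noise model
#'
#' Least-squares fit of CV^2 = a1/mu + alpha0 on spike-in transcripts.
#' A negative fitted slope is clamped to zero (refit as a flat model),
#' since technical variance cannot decrease with 1/mean.
#'
#' @param x an \linkS4class{EmbryoExpression}, or a numeric vector of
#'   spike-in means (then `cv2` must be given).
#' @param cv2 squared coefficients of variation matching `x` when `x` is
#'   a vector of means.
#' @param cvBio baseline biological CV added when scoring genes.
#' @return A \linkS4class{NoiseFit}.
#' @examples
#' fitTechnicalNoise(c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000),
#'                   cv2 = 5 / c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000) + 0.1)
#' @export
fitTechnicalNoise <- function(x, cv2 = NULL, cvBio = 0.5) {
    if (is(x, "EmbryoExpression")) {
        v <- assay(x, "rpkm")[spikeinFlag(x), , drop = FALSE]
        mu <- rowMeans(v)
        cv2 <- apply(v, 1, stats::var) / mu^2
    } else mu <- as.numeric(x)
    keep <- is.finite(mu) & mu > 0 & is.finite(cv2)
    mu <- mu[keep]; cv2 <- cv2[keep]
    if (length(mu) < 10)
        stop("need at least 10 spike-ins with positive mean")
    fit <- stats::lm(cv2 ~ I(1 / mu))
    a1 <- unname(stats::coef(fit)[2])
    alpha0 <- unname(stats::coef(fit)[1])
    if (a1 < 0) {       # flat technical noise
        a1 <- 0
        alpha0 <- mean(cv2)
    }
    new("NoiseFit", a1 = a1, alpha0 = max(alpha0, 0), cvBio = cvBio)
}

#' Variability scores against the technical-noise baseline
#'
#' For each expressed non-spike-in gene the observed CV^2 is compared
#' with the expected CV^2 at its mean, `a1/mu + alpha0 + cvBio^2`. The
#' score is the ratio observed/expected with an F-like tail probability
#' (`pf` with n-1 numerator degrees of freedom); genes rank descending
#' by ratio, ties broken by gene ID.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param fit a \linkS4class{NoiseFit}.
#' @param cells optional subset of cell IDs.
#' @param minExprFrac minimum fraction of cells at RPKM >= 1 for a gene
#'   to count as expressed and be scored.
#' @return data.frame with gene_id, mean, cv2, expected_cv2, score
#'   (ratio), p, rank; ordered by rank.
#' @export
variabilityScores <- function(x, fit, cells = NULL, minExprFrac = 0.05) {
    v <- assay(x, "rpkm")
    if (!is.null(cells)) v <- v[, cells, drop = FALSE]
    v <- v[!spikeinFlag(x), , drop = FALSE]
    frac <- rowMeans(v >= 1)
    v <- v[frac >= minExprFrac, , drop = FALSE]
    mu <- rowMeans(v)
    cv2 <- apply(v, 1, stats::var) / mu^2
    expected <- fit@a1 / mu + fit@alpha0 + fit@cvBio^2
    score <- cv2 / expected
    n <- ncol(v)
    p <- stats::pf(score, n - 1, Inf, lower.tail = FALSE)
    out <- data.frame(gene_id = rownames(v), mean = mu, cv2 = cv2,
                      expected_cv2 = expected, score = score, p = p,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$score, out$gene_id), ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Top variable genes
#'
#' @param scores data.frame from [variabilityScores()].
#' @param n number of genes; must not exceed the number scored.
#' @return Character vector of the first `n` gene IDs by rank.
#' @export
topVariableGenes <- function(scores, n) {
    if (n > nrow(scores))
        stop("requested ", n, " genes but only ", nrow(scores),
             " were scored")
    utils::head(scores$gene_id, n)
}

#' Two-dimensional embedding of cells
#'
#' Embeds cells with t-SNE, PCA (first two principal-component scores)
#' or a diffusion map, always on `log2(RPKM + 1)` over the given genes.
#' Deterministic for a fixed seed.
#'
#' @param x an \linkS4class{EmbryoExpression}.
#' @param genes gene IDs to use.
#' @param method `"tsne"`, `"pca"` or `"diffusion"`.
#' @param seed RNG seed (t-SNE initialization).
#' @param perplexity t-SNE perplexity.
#' @return cell x 2 coordinate matrix (rownames are cell IDs).
#' @export
embed2D <- function(x, genes, method = c("tsne", "pca", "diffusion"),
                    seed = 0, perplexity = 30) {
    method <- match.arg(method)
    L <- t(logExpr(x)[genes, , drop = FALSE])
    coords <- switch(method,
        pca = stats::prcomp(L, center = TRUE, scale. = FALSE)$x[, 1:2],
        tsne = {
            set.seed(seed)
            perplexity <- min(perplexity, floor((nrow(L) - 1) / 3))
            Rtsne::Rtsne(L, dims = 2, perplexity = perplexity,
                         check_duplicates = FALSE, pca = TRUE,
                         partial_pca = FALSE, verbose = FALSE)$Y
        },
        diffusion = diffusionMapCoords(L, 2))
    rownames(coords) <- colnames(x)
    colnames(coords) <- c("dim1", "dim2")
    coords
}

## Hastie-Stuetzle principal curve: iterate projection onto the current
## polyline and per-coordinate spline smoothing against arc length.
principalCurve <- function(pts, lambda0 = NULL, maxIter = 50,
                           tol = 1e-4, df = NULL) {
    if (nrow(unique(pts)) < 3)
        stop("degenerate input: cells are (nearly) coincident")
    rng <- max(apply(pts, 2, function(z) diff(range(z))))
    if (rng == 0) stop("degenerate input: cells are coincident")
    if (is.null(lambda0)) lambda0 <- stats::prcomp(pts)$x[, 1]
    lambda <- lambda0
    proj <- pts
    for (it in seq_len(maxIter)) {
        ord <- order(lambda)
        dfj <- if (is.null(df)) min(8, max(4, floor(nrow(pts) / 20))) else df
        sm <- vapply(seq_len(ncol(pts)), function(j) {
            fj <- tryCatch(
                stats::predict(stats::smooth.spline(lambda, pts[, j],
                                                    df = dfj),
                               lambda)$y,
                error = function(e)     # near-degenerate scatter
                    unname(stats::fitted(stats::lm(
                        pts[, j] ~ stats::poly(lambda, 3)))))
            fj
        }, numeric(nrow(pts)))
        ## arc length along the smoothed curve, in lambda order
        smo <- sm[ord, , drop = FALSE]
        seg <- sqrt(rowSums(diff(smo)^2))
        newLambda <- numeric(nrow(pts))
        newLambda[ord] <- cumsum(c(0, seg))
        newProj <- sm
        shift <- mean(sqrt(rowSums((newProj - proj)^2))) / rng
        proj <- newProj
        lambda <- newLambda
        if (shift < tol) break
    }
    list(lambda = lambda, curve = proj[order(lambda), , drop = FALSE])
}

## Project points onto a polyline; returns arc-length positions.
projectOnCurve <- function(pts, curve) {
    segStart <- curve[-nrow(curve), , drop = FALSE]
    segEnd <- curve[-1, , drop = FALSE]
    d <- segEnd - segStart
    len2 <- rowSums(d^2)
    cum <- c(0, cumsum(sqrt(len2)))
    vapply(seq_len(nrow(pts)), function(i) {
        w <- pts[i, ]
        tpar <- rowSums(sweep(-segStart, 2, w, "+") * d) / pmax(len2, 1e-12)
        tpar <- pmin(pmax(tpar, 0), 1)
        px <- segStart + d * tpar
        dist2 <- rowSums(sweep(px, 2, w, "-")^2)
        k <- which.min(dist2)
        cum[k] + tpar[k] * sqrt(len2[k])
    }, numeric(1))
}

#' Assign principal-curve pseudo-time
#'
#' Fits a principal curve to the (non-excluded) cells in a 2-D
#' embedding; every cell, including excluded ones, is assigned the arc
#' length of its orthogonal projection onto the curve. Orientation is
#' chosen so pseudo-time increases with the day labels, and positions
#' are linearly rescaled so that per-embryo mean pseudo-times regress on
#' embryonic day with slope 2.5 and intercept 0 (day 5 maps to 12.5).
#'
#' @param coords cell x 2 coordinates (e.g. from [embed2D()]).
#' @param dayLabels per-cell embryonic day.
#' @param embryoIds per-cell embryo IDs (for the per-embryo means).
#' @param excludeMask logical per-cell mask of cells excluded from the
#'   curve fit (e.g. inner-cell-mass cells) but still projected.
#' @return A \linkS4class{PseudotimeAssignment}.
#' @export
assignPseudotime <- function(coords, dayLabels, embryoIds,
                             excludeMask = NULL) {
    n <- nrow(coords)
    if (is.null(excludeMask)) excludeMask <- rep(FALSE, n)
    fitPts <- coords[!excludeMask, , drop = FALSE]
    ## the iterative fit can settle on a curve that threads the cloud
    ## orthogonally to developmental time; fit from both principal-axis
    ## initializations and keep the curve most consistent with the day
    ## labels (the quantity pseudo-time is meant to refine)
    pcInit <- stats::prcomp(fitPts)$x
    fits <- lapply(1:2, function(j) principalCurve(fitPts, pcInit[, j]))
    lambdas <- lapply(fits, function(f) projectOnCurve(coords, f$curve))
    best <- which.max(vapply(lambdas, function(l)
        abs(stats::cor(l, dayLabels)), numeric(1)))
    pcv <- fits[[best]]
    lambda <- lambdas[[best]]
    if (stats::cor(lambda, dayLabels) < 0)
        lambda <- max(lambda) - lambda
    embMean <- tapply(lambda, embryoIds, mean)
    embDay <- tapply(dayLabels, embryoIds, mean)
    cal <- stats::lm(embMean ~ embDay)
    a <- stats::coef(cal)[1]; b <- stats::coef(cal)[2]
    if (!is.finite(b) || b <= 0)
        stop("pseudo-time calibration failed: no day gradient")
    lambda <- 2.5 * (lambda - a) / b
    emb <- tapply(lambda, embryoIds, mean)
    names(lambda) <- rownames(coords)
    new("PseudotimeAssignment", lambda = lambda,
        embryo = stats::setNames(as.numeric(emb), names(emb)),
        curve = pcv$curve)
}
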