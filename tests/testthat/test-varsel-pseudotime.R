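test_that("technical-noise fit recovers and degrades gracefully", {
    mu <- c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000, 2000, 40)
    fit <- fitTechnicalNoise(mu, cv2 = 5 / mu + 0.1)
    expect_equal(fit@a1, 5, tolerance = 1e-6)
    expect_equal(fit@alpha0, 0.1, tolerance = 1e-6)
    flat <- fitTechnicalNoise(mu, cv2 = rep(0.3, length(mu)))
    expect_equal(flat@a1, 0)
    expect_equal(flat@alpha0, 0.3, tolerance = 1e-6)
    expect_error(fitTechnicalNoise(c(1, 2), cv2 = c(1, 1)),
                 "at least 10")
})

test_that("variability scores baseline at one for unprogrammed genes", {
    a <- sharedAnalysis()
    hk <- a$truth@genes$gene_id[a$truth@genes$program == "housekeeping"]
    vs <- a$vs
    hkScores <- vs$score[vs$gene_id %in% hk]
    expect_gt(median(hkScores), 0.7)
    expect_lt(median(hkScores), 1.4)
    ## spike-ins never appear in the ranking
    expect_false(any(grepl("^ERCC-", vs$gene_id)))
})

test_that("scores are invariant to gene order and capture programs", {
    a <- sharedAnalysis()
    ds <- a$ds
    perm <- sample(nrow(ds))
    dsPerm <- EmbryoExpression(rpkm(ds)[perm, ],
                               as.data.frame(rowData(ds))[perm, ],
                               as.data.frame(colData(ds)))
    vs2 <- variabilityScores(dsPerm, a$nf)
    expect_identical(vs2$gene_id, a$vs$gene_id)
    ## lineage and sex-program genes dominate the top of the ranking
    gt <- a$truth@genes
    progSet <- c(gt$gene_id[gt$program %in% c("TE", "EPI", "PE",
                                              "polar", "Y")], "XIST")
    expect_gte(mean(progSet %in% a$g500), 0.9)
})

test_that("top-gene selection validates n and breaks ties by ID", {
    sc <- data.frame(gene_id = c("b", "a", "c"),
                     score = c(2, 2, 1), stringsAsFactors = FALSE)
    sc <- sc[order(-sc$score, sc$gene_id), ]
    expect_identical(topVariableGenes(sc, 0), character())
    expect_identical(topVariableGenes(sc, 2), c("a", "b"))
    expect_error(topVariableGenes(sc, 4), "only 3")
})

test_that("embeddings separate groups and are deterministic", {
    set.seed(1)
    v <- cbind(matrix(rnbinom(50 * 30, mu = 5, size = 2), 50),
               matrix(rnbinom(50 * 30, mu = 60, size = 2), 50))
    x <- tinyExpr(v, day = rep(c(4L, 6L), each = 30),
                  embryo = rep(c("e1", "e2"), each = 30))
    grp <- rep(1:2, each = 30)
    for (m in c("tsne", "pca", "diffusion")) {
        co <- embed2D(x, rownames(x), m, seed = 0, perplexity = 10)
        cen <- rbind(colMeans(co[grp == 1, ]), colMeans(co[grp == 2, ]))
        between <- sqrt(sum((cen[1, ] - cen[2, ])^2))
        within <- mean(sqrt(rowSums((co - cen[grp, ])^2)))
        expect_gt(between, within)
    }
    co1 <- embed2D(x, rownames(x), "tsne", seed = 3, perplexity = 10)
    co2 <- embed2D(x, rownames(x), "tsne", seed = 3, perplexity = 10)
    expect_identical(co1, co2)
    ## pca method is exactly the first two principal components
    L <- t(logExpr(x))
    expect_equal(unname(embed2D(x, rownames(x), "pca")),
                 unname(prcomp(L)$x[, 1:2]), tolerance = 1e-8)
    expect_error(embed2D(x, rownames(x), "umap"), "arg")
})

test_that("pseudo-time on a line recovers order and the day scale", {
    set.seed(2)
    n <- 60
    pos <- sort(runif(n, 0, 10))
    coords <- cbind(pos, rnorm(n, 0, 0.05))
    rownames(coords) <- sprintf("c%02d", seq_len(n))
    day <- 3L + findInterval(pos, quantile(pos, c(.2, .4, .6, .8)))
    emb <- paste0("e", rep(1:12, each = 5))
    pt <- assignPseudotime(coords, day, emb)
    lam <- cellPseudotime(pt)
    expect_gt(cor(lam, pos), 0.99)
    cal <- lm(embryoPseudotime(pt) ~ tapply(day, emb, mean))
    expect_equal(unname(coef(cal)[2]), 2.5, tolerance = 0.2)
    ## reversing the day labels flips the orientation
    ptR <- assignPseudotime(coords, rev(day)[rank(pos)], emb)
    expect_lt(cor(cellPseudotime(ptR), pos), -0.99)
    ## orientation invariant: correlation with day is non-negative
    expect_gte(cor(lam, day), 0)
    expect_error(assignPseudotime(coords[c(1, 1, 1), ], day[1:3],
                                  emb[1:3]), "degenerate|gradient")
})

test_that("simulated development is ordered by inferred pseudo-time", {
    a <- sharedAnalysis()
    lam <- cellPseudotime(a$pt)
    tt <- a$truth@cells$pseudotime
    nonICM <- !a$truth@cells$lineage %in% c("EPI", "PE")
    expect_gte(cor(lam[nonICM], tt[nonICM], method = "spearman"), 0.9)
    ## per-embryo values are the means of member cells
    e1 <- names(embryoPseudotime(a$pt))[1]
    expect_equal(unname(embryoPseudotime(a$pt)[e1]),
                 mean(lam[embryoId(a$ds) == e1]))
})
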