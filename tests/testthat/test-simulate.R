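test_that("genotype simulation follows Hardy-Weinberg frequencies", {
    n <- 10000
    g <- simulateGenotypes(n, 5, maf = 0.2, seed = 101)
    p <- c(0.64, 0.32, 0.04)
    for (j in 1:5) {
        freq <- tabulate(g[, j] + 1L, 3) / n
        tol <- 3 * sqrt(p * (1 - p) / n)
        expect_true(all(abs(freq - p) < tol), info = paste("marker", j))
    }
    g5 <- simulateGenotypes(5000, 2, maf = 0.5, seed = 102)
    freq <- tabulate(g5[, 1] + 1L, 3) / 5000
    expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.03))
    expect_error(simulateGenotypes(10, 2, maf = 0.7), "maf")
})

test_that("trait generation draws around the penetrance-grid means", {
    grids <- defaultModelGrids()
    cfg <- simulationConfig(n = 6000, m = 4, maf = 0.4, sigma = 0.1,
                            grids = grids["model2"], seed = 111)
    x <- simulateDataset(cfg)
    g <- genotypeMatrix(x); tr <- trait(x)
    f <- gridValues(grids$model2)
    for (i in 0:2) for (j in 0:2) {
        inCell <- g[, 1] == i & g[, 2] == j
        if (sum(inCell) < 20) next
        expect_true(abs(mean(tr[inCell]) - f[i + 1, j + 1]) <
                    3 * 0.1 / sqrt(sum(inCell)) + 1e-9,
                    info = paste("cell", i, j))
    }
    # sigma -> 0 degenerates to the cell mean
    cfg0 <- simulationConfig(n = 50, m = 4, maf = 0.4, sigma = 0,
                             grids = grids["model2"], seed = 112)
    x0 <- simulateDataset(cfg0)
    g0 <- genotypeMatrix(x0)
    expect_equal(trait(x0),
                 f[cbind(g0[, 1] + 1, g0[, 2] + 1)], tolerance = 1e-12)
})

test_that("two-model mixtures weight the grid means", {
    grids <- defaultModelGrids()
    cfg <- simulationConfig(n = 40, m = 6, maf = 0.4, sigma = 0,
                            grids = grids[c("model1", "model2")],
                            weights = c(0.5, 0.5), seed = 121)
    x <- simulateDataset(cfg)
    g <- genotypeMatrix(x)
    f1 <- gridValues(grids$model1); f2 <- gridValues(grids$model2)
    mu <- 0.5 * f1[cbind(g[, 1] + 1, g[, 2] + 1)] +
          0.5 * f2[cbind(g[, 3] + 1, g[, 4] + 1)]
    expect_equal(trait(x), mu, tolerance = 1e-12)
    # weights (1, 0) reproduce the single-model generator exactly
    cfgA <- simulationConfig(n = 80, m = 6, maf = 0.3, sigma = 0.2,
                             grids = grids["model1"], seed = 122)
    cfgB <- simulationConfig(n = 80, m = 6, maf = 0.3, sigma = 0.2,
                             grids = grids[c("model1", "model2")],
                             weights = c(1, 0), seed = 122)
    expect_equal(trait(simulateDataset(cfgA)), trait(simulateDataset(cfgB)))
})

test_that("ordinal transfer reproduces the normal-theory proportions", {
    set.seed(131)
    tr <- rnorm(100000)
    lv <- qtToOrdinal(tr)
    expected <- c(pnorm(-0.5), pnorm(0.5) - pnorm(-0.5), 1 - pnorm(0.5))
    expect_equal(as.numeric(table(lv)) / length(lv), expected,
                 tolerance = 0.01)
    expect_equal(qtToOrdinal(c(rnorm(500), 0))[501], 2L)
    expect_error(qtToOrdinal(rep(3, 10)), "sd")
})

test_that("null datasets decouple trait from genotypes and reproduce", {
    x <- simulateNull(4000, 5, maf = 0.3, seed = 141)
    g <- genotypeMatrix(x); tr <- trait(x)
    for (j in 1:5)
        expect_lt(abs(cor(g[, j], tr)), 3 / sqrt(4000))
    y <- simulateNull(4000, 5, maf = 0.3, seed = 141)
    expect_identical(genotypeMatrix(y), g)
    expect_identical(trait(y), tr)
    expect_length(causalPairs(x), 0)  # no causal pairs recorded
})

test_that("default model grids are distinct and use the canonical levels", {
    grids <- defaultModelGrids()
    expect_length(grids, 5)
    vals <- lapply(grids, gridValues)
    for (v in vals)
        expect_true(all(v %in% c(0.01, 0.25, 0.5)))
    for (i in 1:4) for (j in (i + 1):5)
        expect_false(identical(vals[[i]], vals[[j]]))
    # each grid carries signal: at least two distinct cell means, and the
    # mean trait differs across at least one marginal genotype
    for (v in vals) {
        expect_gt(length(unique(as.vector(v))), 1)
        expect_true(length(unique(round(rowMeans(v), 10))) >= 2 ||
                    length(unique(round(colMeans(v), 10))) >= 2)
    }
})

test_that("grid files override defaults of the same name", {
    dir <- withr::local_tempdir()
    writeLines(c("- [0.5, 0.5, 0.5]", "- [0.25, 0.25, 0.25]",
                 "- [0.01, 0.01, 0.01]"),
               file.path(dir, "model1.yaml"))
    grids <- defaultModelGrids(configDir = dir)
    expect_equal(gridValues(grids$model1)[1, ], rep(0.5, 3))
    expect_equal(gridValues(grids$model2),
                 gridValues(defaultModelGrids()$model2))
})
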