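test_that("cell indexing is base-3 over the marker set", {
    geno <- rbind(c(0L, 0L, 0L), c(2L, 1L, 0L), c(2L, 2L, 2L))
    expect_equal(as.integer(indexCells(geno, c(1, 2))), c(0L, 5L, 8L))
    expect_equal(as.integer(indexCells(geno, c(1, 2, 3))), c(0L, 5L, 26L))
    # bijective over all two-marker combinations
    full <- as.matrix(expand.grid(0:2, 0:2))
    storage.mode(full) <- "integer"
    expect_equal(sort(as.integer(indexCells(full, c(1, 2)))), 0:8)
    genoNA <- geno; genoNA[1, 1] <- NA
    expect_error(indexCells(genoNA, c(1, 2)), "missing")
})

test_that("fuzzy counts use extended cells and traditional class sizes", {
    sch <- intervalScheme(c(0, 1, 2, 3))
    P <- schemeMidpoints(sch)
    # one sample at P3 in cell 0 (single marker, code 0)
    cells <- indexCells(matrix(0L, 1, 1), 1)
    cnt <- fuzzyCounts(cells, P[3], sch)
    expect_equal(cnt$nij[1, ], c(-1, 0, 1))
    expect_equal(cnt$nplus, c(0, 0, 1))
    # empty cells get all-zero rows
    cells2 <- indexCells(matrix(c(0L, 2L), 2, 1), 1)
    cnt2 <- fuzzyCounts(cells2, c(P[1], P[3]), sch)
    expect_equal(cnt2$nij[2, ], c(0, 0, 0))
    expect_equal(cnt2$nij[1, ], c(1, 0, -1))
})

test_that("cell labeling maximizes the count/class-size ratio", {
    expect_equal(labelCells(rbind(c(-1, 0, 1)), c(1, 1, 1)), 3L)
    # tie broken to the lower level: ratios (0.5, 0.5, -0.5)
    expect_equal(labelCells(rbind(c(0.5, 0.5, -1)), c(1, 1, 2)), 1L)
    # empty cell unlabeled
    expect_equal(labelCells(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 1, 1)),
                 c(NA_integer_, 1L))
    # zero-size classes are skipped in the argmax
    expect_equal(labelCells(rbind(c(5, 1, 0)), c(0, 1, 1)), 2L)
    expect_error(labelCells(rbind(c(1, 1, 1)), c(0, 0, 0)), "class sizes")
})

test_that("fuzzy balanced accuracy matches hand-computed cases", {
    sch <- intervalScheme(c(0, 1, 2, 3))
    P <- schemeMidpoints(sch)
    # single cell, one sample at P3, labeled 3 -> (1/3) * 1/1
    cells <- indexCells(matrix(0L, 1, 1), 1)
    expect_equal(fuzzyBalancedAccuracy(cells, 3L, P[3], sch), 1 / 3)
    # all samples at midpoints, labels match -> exactly 1
    geno <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L), 6, 1)
    tr <- c(P[1], P[1], P[2], P[2], P[3], P[3])
    cells6 <- indexCells(geno, 1)
    expect_equal(fuzzyBalancedAccuracy(cells6, c(1L, 2L, 3L), tr, sch), 1)
    # all cells unlabeled -> 0
    expect_equal(fuzzyBalancedAccuracy(cells6, rep(NA_integer_, 3), tr, sch),
                 0)
})

test_that("crisp balanced accuracy is mean per-class recall", {
    cells <- structure(c(0L, 0L, 1L, 1L), order = 1L)
    expect_equal(crispBalancedAccuracy(cells, c(1L, 2L, NA), c(1, 1, 2, 2)),
                 1)
    # everything predicted class 1 on balanced 2-class data -> 0.5
    expect_equal(crispBalancedAccuracy(cells, c(1L, 1L, NA), c(1, 1, 2, 2)),
                 0.5)
    # binary case equals (TP/(TP+FN) + TN/(TN+FP))/2
    cats <- c(1, 1, 1, 2, 2)
    cellsB <- structure(c(0L, 0L, 1L, 1L, 1L), order = 1L)
    labs <- c(1L, 2L, NA)
    tp <- 2; fn <- 1; tn <- 2; fp <- 0
    expect_equal(crispBalancedAccuracy(cellsB, labs, cats),
                 (tp / (tp + fn) + tn / (tn + fp)) / 2)
})

test_that("tau-b agrees with exhaustive pair enumeration", {
    expect_equal(tauB(c(1, 2, 3, 1), c(1, 2, 3, 1)), 1)
    expect_equal(tauB(c(1, 2, 3), c(3, 2, 1)), -1)
    a <- c(1, 1, 2, 3); b <- c(1, 2, 2, 3)
    expect_equal(tauB(a, b), oracleTauB(a, b))
    set.seed(11)
    for (rep in 1:10) {
        a <- sample(1:3, 12, replace = TRUE)
        b <- sample(1:3, 12, replace = TRUE)
        if (length(unique(a)) < 2 || length(unique(b)) < 2) next
        expect_equal(tauB(a, b), oracleTauB(a, b), tolerance = 1e-12)
    }
    expect_warning(z <- tauB(c(1, 1, 1), c(1, 2, 3)), "constant")
    expect_equal(z, 0)
})
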