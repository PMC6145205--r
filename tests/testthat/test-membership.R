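test_that("equal-length scheme partitions the range with correct midpoints", {
    sch <- equalLengthScheme(c(0, 3), J = 3)
    expect_equal(schemeBorders(sch), c(0, 1, 2, 3))
    expect_equal(schemeMidpoints(sch), c(0.5, 1.5, 2.5))

    sch2 <- equalLengthScheme(c(0, 1), J = 2)
    expect_equal(schemeBorders(sch2), c(0, 0.5, 1))
    expect_equal(schemeMidpoints(sch2), c(0.25, 0.75))

    sch5 <- equalLengthScheme(runif(50), J = 5)
    b <- schemeBorders(sch5)
    expect_equal(schemeMidpoints(sch5)[2], (b[2] + b[3]) / 2)

    expect_error(equalLengthScheme(rep(2, 10), J = 3), "degenerate")
    expect_error(equalLengthScheme(c(0, 1), J = 1), "J")
})

test_that("deviation scheme cuts at mean +/- sd/2", {
    x <- c(-4, -2, 0, 2, 4)   # mean 0, sd sqrt(10)
    sdv <- sd(x)
    sch <- deviationScheme(x)
    expect_equal(schemeBorders(sch), c(-4, -sdv / 2, sdv / 2, 4))
    expect_error(deviationScheme(rep(1, 5)), "sd")
    # interior border at/below the observed minimum -> empty level
    expect_error(deviationScheme(c(0, 0, 0, 10)), "range")
})

test_that("traditional membership reproduces the piecewise-linear forms", {
    sch <- intervalScheme(c(0, 1, 2, 3))
    P <- schemeMidpoints(sch)
    expect_equal(muTraditional(sch, 1, P[1]), 1)
    expect_equal(sapply(1:3, function(j) muTraditional(sch, j, P[2])),
                 c(0, 1, 0))
    expect_equal(muTraditional(sch, 1, (P[1] + P[2]) / 2), 0.5)
    expect_equal(muTraditional(sch, 3, P[3] + 10), 1)
    # dense-grid cross-check against the scalar re-derivation
    xs <- seq(-0.5, 3.5, length.out = 201)
    for (j in 1:3)
        expect_equal(muTraditional(sch, j, xs),
                     vapply(xs, function(x) oracleMuTrad(P, j, x),
                            numeric(1)))
})

test_that("extended membership matches the printed forms and identities", {
    sch <- intervalScheme(c(0, 1, 2, 3))
    P <- schemeMidpoints(sch)
    expect_equal(muExtended(sch, 1, P[3]), -1)
    expect_equal(sapply(1:3, function(j) muExtended(sch, j, P[2])),
                 c(0, 1, 0))
    expect_equal(muExtended(sch, 3, P[1]), -1)
    xs <- seq(-0.5, 3.5, length.out = 201)
    # transformation identities relative to the traditional family
    extL <- ifelse(xs <= P[2], muTraditional(sch, 1, xs),
                   ifelse(xs <= P[3], (P[2] - xs) / (P[2] - P[1]), -1))
    extA <- ifelse(xs <= P[1], (xs - P[1]) / (P[2] - P[1]),
                   ifelse(xs <= P[3], muTraditional(sch, 2, xs),
                          (P[3] - xs) / (P[3] - P[2])))
    extH <- ifelse(xs <= P[1], -1,
                   ifelse(xs <= P[2], (xs - P[2]) / (P[3] - P[2]),
                          muTraditional(sch, 3, xs)))
    expect_equal(muExtended(sch, 1, xs), extL)
    expect_equal(muExtended(sch, 2, xs), extA)
    expect_equal(muExtended(sch, 3, xs), extH)
})

test_that("membership families satisfy their global invariants", {
    for (scheme in list(intervalScheme(c(0, 1, 2, 3)),
                        intervalScheme(c(-2, -0.3, 0.4, 5)),
                        intervalScheme(seq(0, 10, length.out = 6)))) {
        J <- nLevels(scheme)
        b <- schemeBorders(scheme)
        xs <- seq(b[1], b[J + 1], length.out = 501)
        Tm <- membershipMatrix(scheme, xs, "traditional")
        # partition of unity on the observed range, values in [0, 1]
        expect_equal(rowSums(Tm), rep(1, length(xs)), tolerance = 1e-12)
        expect_true(all(Tm >= 0 & Tm <= 1))
        Em <- membershipMatrix(scheme, xs, "extended")
        # boundary levels stay within [-1, 1]; L non-increasing, H
        # non-decreasing
        expect_true(all(Em[, 1] >= -1 & Em[, 1] <= 1))
        expect_true(all(Em[, J] >= -1 & Em[, J] <= 1))
        expect_true(all(diff(Em[, 1]) <= 1e-12))
        expect_true(all(diff(Em[, J]) >= -1e-12))
    }
})

test_that("L/H antisymmetry holds between P1 and P3 for equal widths", {
    sch <- intervalScheme(c(0, 1, 2, 3))
    P <- schemeMidpoints(sch)
    xs <- seq(P[1], P[3], length.out = 101)
    expect_equal(muExtended(sch, 1, xs) + muExtended(sch, 3, xs),
                 rep(0, length(xs)), tolerance = 1e-12)
    # middle level is never clamped: infimum on the range is -0.5
    xsAll <- seq(0, 3, length.out = 1001)
    expect_equal(min(muExtended(sch, 2, xsAll)), -0.5, tolerance = 1e-3)
})

test_that("J=5 generalization keeps the triangular/clamped geometry", {
    sch <- intervalScheme(seq(0, 5, length.out = 6))
    P <- schemeMidpoints(sch)
    xs <- seq(0, 5, length.out = 401)
    for (j in 1:5) {
        expect_equal(muExtended(sch, j, xs),
                     vapply(xs, function(x) oracleMuExt(P, j, x),
                            numeric(1)))
        expect_equal(muExtended(sch, j, P[j]), 1)
    }
    # interior level clamps at -1 two midpoints away
    expect_equal(muExtended(sch, 3, P[1] - 1), -1)
    expect_equal(muExtended(sch, 3, P[5] + 1), -1)
})

test_that("crisp assignment uses upper-closed intervals", {
    sch <- intervalScheme(c(0, 1, 2, 3))
    expect_equal(crispCategory(sch, c(0.5, 1, 1.5, 2, 2.5)),
                 c(1L, 1L, 2L, 2L, 3L))
    expect_equal(crispCategory(sch, -5), 1L)
    expect_equal(crispCategory(sch, 99), 3L)
})
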