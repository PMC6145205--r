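test_that("search enumerates all C(m, order) marker sets with bounded GCVC", {
    inst <- randomInstance(40, 4, seed = 21)
    x <- MarkerData(inst$geno, inst$trait)
    res <- crossValidatedSearch(x, order = 2, folds = 5, topK = 2, seed = 1)
    expect_equal(res@nModels, choose(4, 2))
    cand <- candidates(res)
    expect_true(all(cand$gcvc >= 1 & cand$gcvc <= 5))
    expect_true(all(diff(cand$mtsbca) <= 1e-12))
    # per-fold top-K lists have K sets of the right order
    expect_length(res@perFoldTopK, 5)
    expect_true(all(vapply(res@perFoldTopK, dim, integer(2))[1, ] == 2))
})

test_that("vectorized search equals the naive per-sample reference", {
    set.seed(31)
    cases <- expand.grid(n = c(30, 60), m = c(4, 6), order = 1:3,
                         method = c("gfqmdr", "fqmdr", "omdr", "mdr"),
                         stringsAsFactors = FALSE)
    # 20 sampled instances across sizes, orders and scorers
    cases <- cases[sample(nrow(cases), 20), ]
    for (i in seq_len(nrow(cases))) {
        cs <- cases[i, ]
        inst <- randomInstance(cs$n, cs$m, seed = 300 + i)
        scheme <- deviationScheme(inst$trait)
        set.seed(400 + i)
        fold <- gfqmdr:::makeFolds(crispCategory(scheme, inst$trait), 3L)
        sm <- gfqmdr:::scorerMatrices(cs$method, scheme, inst$trait)
        fast <- gfqmdr:::cpp_cv_search(
            gfqmdr:::asIntMatrix(inst$geno),
            utils::combn(cs$m, cs$order) - 1L, as.integer(fold), 3L,
            sm$cellM, sm$classM, sm$scoreType)
        slow <- oracleSearch(inst$geno, inst$trait, scheme, cs$order, fold,
                             cs$method)
        expect_equal(fast$train, slow$train, tolerance = 1e-12,
                     info = paste("train", cs$method, cs$n, cs$m, cs$order))
        expect_equal(fast$test, slow$test, tolerance = 1e-12,
                     info = paste("test", cs$method, cs$n, cs$m, cs$order))
    }
})

test_that("training scores are invariant under joint sample permutation", {
    inst <- randomInstance(50, 5, seed = 41)
    scheme <- deviationScheme(inst$trait)
    set.seed(42)
    fold <- gfqmdr:::makeFolds(crispCategory(scheme, inst$trait), 5L)
    perm <- sample.int(50)
    for (method in c("gfqmdr", "mdr")) {
        sm <- gfqmdr:::scorerMatrices(method, scheme, inst$trait)
        a <- gfqmdr:::cpp_cv_search(gfqmdr:::asIntMatrix(inst$geno),
                                    utils::combn(5, 2) - 1L,
                                    as.integer(fold), 5L, sm$cellM,
                                    sm$classM, sm$scoreType)
        smP <- gfqmdr:::scorerMatrices(method, scheme, inst$trait[perm])
        b <- gfqmdr:::cpp_cv_search(gfqmdr:::asIntMatrix(inst$geno[perm, ]),
                                    utils::combn(5, 2) - 1L,
                                    as.integer(fold[perm]), 5L, smP$cellM,
                                    smP$classM, smP$scoreType)
        expect_equal(a$train, b$train, tolerance = 1e-12)
    }
})

test_that("search is deterministic given a seed", {
    inst <- randomInstance(60, 6, seed = 51)
    x <- MarkerData(inst$geno, inst$trait)
    r1 <- crossValidatedSearch(x, order = 2, folds = 5, seed = 9)
    r2 <- crossValidatedSearch(x, order = 2, folds = 5, seed = 9)
    expect_identical(candidates(r1)$markers, candidates(r2)$markers)
    expect_equal(candidates(r1)$mtsbca, candidates(r2)$mtsbca)
})

test_that("permutation p-values behave at the extremes", {
    # strong signal: observed beats every permutation
    cfg <- simulationConfig(n = 150, m = 6, maf = 0.4, sigma = 0.05,
                            seed = 61)
    x <- simulateDataset(cfg)
    p <- permutationPValue(x, c(1, 2), nPerm = 50, seed = 62)
    expect_equal(p, 0)
    # alpha = 1 retains every candidate with a computed p-value
    res <- crossValidatedSearch(x, order = 2, folds = 5, seed = 63)
    res <- computePValues(res, x, nPerm = 20, seed = 64)
    sel <- finalSelection(res, alpha = 1)
    expect_equal(nrow(sel), nrow(candidates(res)))
    # selection keeps only candidates strictly below alpha
    resHi <- res
    resHi@candidates$pValue <- seq(0.2, 0.9,
                                   length.out = nrow(candidates(res)))
    expect_equal(nrow(finalSelection(resHi, alpha = 0.01)), 0)
    # plus-one correction bounds p away from 0
    p1 <- permutationPValue(x, c(1, 2), nPerm = 20, seed = 65,
                            plusOne = TRUE)
    expect_equal(p1, 1 / 21)
})

test_that("search validates its inputs", {
    inst <- randomInstance(30, 4, seed = 71)
    x <- MarkerData(inst$geno, inst$trait)
    expect_error(crossValidatedSearch(x, order = 5), "order")
    g <- inst$geno; g[2, 2] <- NA
    xNA <- MarkerData(g, inst$trait)
    expect_error(crossValidatedSearch(xNA, order = 2), "missing")
})
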