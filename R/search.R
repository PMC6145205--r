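# Scorer plumbing: every method reduces to (per-cell counting family,
# class-size family, score type) fed to the shared C++ kernel.
#   gfqmdr: extended cell counts / traditional class sizes / fuzzy score
#   fqmdr:  traditional    / traditional / fuzzy score
#   mdr:    crisp indicator / crisp indicator / mean per-class recall
#   omdr:   crisp indicator / crisp indicator / tau-b
scorerMatrices <- function(method, scheme, trait) {
    crisp <- crispCategory(scheme, trait)
    ind <- matrix(0, length(trait), scheme@J)
    ind[cbind(seq_along(trait), crisp)] <- 1
    switch(method,
        gfqmdr = list(cellM = membershipMatrix(scheme, trait, "extended"),
                      classM = membershipMatrix(scheme, trait, "traditional"),
                      scoreType = 1L),
        fqmdr = list(cellM = membershipMatrix(scheme, trait, "traditional"),
                     classM = membershipMatrix(scheme, trait, "traditional"),
                     scoreType = 1L),
        mdr = list(cellM = ind, classM = ind, scoreType = 2L),
        omdr = list(cellM = ind, classM = ind, scoreType = 3L),
        stop("unknown method: ", method))
}

# Stratified fold assignment: within each crisp category, samples are
# shuffled and dealt round-robin so no fold loses a whole category.
makeFolds <- function(categories, L) {
    fold <- integer(length(categories))
    for (g in unique(categories)) {
        idx <- which(categories == g)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(sample.int(L), length(idx))
    }
    if (any(vapply(seq_len(L), function(l)
            length(unique(categories[fold == l])), integer(1)) <
            length(unique(categories))))
        warning("a fold has an empty category; fold kept")
    fold
}

#' Cross-validated exhaustive interaction search
#'
#' Scores every m-way marker set as a multi-locus genotype classifier under
#' L-fold cross-validation.  Per fold, all C(m, order) models are fitted on
#' the training part and ranked by training score; the top-K are retained and
#' scored on the held-out fold.  Across folds each retained model gets its
#' generalized cross-validation consistency (GCVC, folds in which it was
#' top-K) and its maximum testing balanced classification accuracy (MTSBCA).
#' Candidates are ranked by MTSBCA, with GCVC and then marker order as tie
#' breaks.
#'
#' The interval scheme is fitted once on the full trait (discretization
#' precedes the cross-validation partition); held-out scores recompute the
#' fuzzy counts on the held-out samples with the training labels.
#'
#' @param x a \linkS4class{MarkerData} with complete genotypes and trait.
#' @param scheme an \linkS4class{IntervalScheme}, or NULL to fit one via
#'   \code{schemeType}.
#' @param order interaction order (markers per set).
#' @param folds number of CV folds L (default 10).
#' @param topK per-fold retention K (default 3).
#' @param method scorer: "gfqmdr" (default), "fqmdr", "omdr" or "mdr".
#' @param seed optional integer seed for the fold assignment.
#' @param schemeType scheme fitted when \code{scheme} is NULL: "deviation"
#'   (mean +/- sd/2, for roughly normal traits) or "equal" (equal-length
#'   intervals).
#' @param J number of ordinal levels when fitting an equal-length scheme.
#' @return a \linkS4class{SearchResult}.
#' @examples
#' cfg <- simulationConfig(n = 100, m = 6, maf = 0.4, sigma = 0.1, seed = 7)
#' x <- simulateDataset(cfg)
#' res <- crossValidatedSearch(x, order = 2, folds = 5, seed = 1)
#' candidates(res)[1, ]
#' @export
crossValidatedSearch <- function(x, scheme = NULL, order = 2L, folds = 10L,
                                 topK = 3L,
                                 method = c("gfqmdr", "fqmdr", "omdr", "mdr"),
                                 seed = NULL,
                                 schemeType = c("deviation", "equal"),
                                 J = 3L) {
    method <- match.arg(method)
    schemeType <- match.arg(schemeType)
    order <- as.integer(order); folds <- as.integer(folds)
    topK <- as.integer(topK)
    geno <- if (is(x, "MarkerData")) genotypeMatrix(x) else x
    tr <- if (is(x, "MarkerData")) trait(x) else attr(x, "trait")
    if (anyNA(geno) || anyNA(tr))
        stop("missing values present; run imputeMissing() first")
    m <- ncol(geno)
    if (order > m) stop("order exceeds the number of markers")
    if (folds < 2L) stop("need at least 2 folds")
    if (is.null(scheme))
        scheme <- if (schemeType == "deviation") deviationScheme(tr)
                  else equalLengthScheme(tr, J)
    crisp <- crispCategory(scheme, tr)
    if (!is.null(seed)) set.seed(seed)
    fold <- makeFolds(crisp, folds)

    combos <- utils::combn(m, order)
    sm <- scorerMatrices(method, scheme, tr)
    res <- cpp_cv_search(asIntMatrix(geno), combos - 1L,
                         as.integer(fold), folds, sm$cellM, sm$classM,
                         sm$scoreType)
    trainS <- res$train; testS <- res$test
    ncomb <- ncol(combos)

    topkIdx <- lapply(seq_len(folds), function(l) {
        ord <- base::order(-trainS[, l], seq_len(ncomb))
        ord[seq_len(min(topK, ncomb))]
    })
    retained <- sort(unique(unlist(topkIdx)))
    gcvc <- vapply(retained, function(i)
        sum(vapply(topkIdx, function(tk) i %in% tk, logical(1))), integer(1))
    mtsbca <- vapply(seq_along(retained), function(k) {
        i <- retained[k]
        ls <- which(vapply(topkIdx, function(tk) i %in% tk, logical(1)))
        max(testS[i, ls])
    }, numeric(1))
    ordCand <- base::order(-mtsbca, -gcvc, retained)
    retained <- retained[ordCand]
    ids <- if (is(x, "MarkerData")) markerIds(x) else colnames(geno)
    if (is.null(ids)) ids <- paste0("M", seq_len(m))
    idxList <- lapply(retained, function(i) combos[, i])
    cand <- DataFrame(
        markers = vapply(idxList, function(ii)
            paste(ids[ii], collapse = ","), character(1)),
        idx = IntegerList(idxList),
        mtsbca = mtsbca[ordCand],
        gcvc = gcvc[ordCand],
        pValue = NA_real_)
    perFold <- lapply(topkIdx, function(tk) combos[, tk, drop = FALSE])
    new("SearchResult", method = method, order = order, folds = folds,
        topK = topK, candidates = cand, perFoldTopK = perFold,
        scheme = scheme, nModels = ncomb)
}

asIntMatrix <- function(m) {
    storage.mode(m) <- "integer"
    m
}

#' Permutation p-value for a candidate marker set
#'
#' The observed statistic is the candidate's full-data training score (the
#' selection statistic).  For each permutation the trait is shuffled against
#' the genotype rows and the null statistic recomputed: either the maximum
#' score over every same-order marker set ("max_over_all", selection-aware,
#' the default and the type-I-error procedure) or the candidate's own score
#' ("candidate", cheaper).  p = #(null >= observed) / nPerm; \code{plusOne}
#' applies the (b + 1)/(nPerm + 1) correction.
#'
#' @param x a \linkS4class{MarkerData} (complete data).
#' @param snpSet integer vector of marker indices of the candidate.
#' @param scheme an \linkS4class{IntervalScheme} (NULL: deviation scheme).
#' @param nPerm number of permutations (default 1000).
#' @param method scorer name.
#' @param nullStatistic "max_over_all" or "candidate".
#' @param seed optional seed for the permutation stream.
#' @param plusOne logical; apply the +1 small-sample correction.
#' @return numeric p-value in [0, 1].
#' @export
permutationPValue <- function(x, snpSet, scheme = NULL, nPerm = 1000L,
                              method = c("gfqmdr", "fqmdr", "omdr", "mdr"),
                              nullStatistic = c("max_over_all", "candidate"),
                              seed = NULL, plusOne = FALSE) {
    method <- match.arg(method)
    nullStatistic <- match.arg(nullStatistic)
    nPerm <- as.integer(nPerm)
    if (nPerm < 1L) stop("nPerm must be >= 1")
    geno <- genotypeMatrix(x)
    tr <- trait(x)
    if (anyNA(geno) || anyNA(tr))
        stop("missing values present; run imputeMissing() first")
    if (is.null(scheme)) scheme <- deviationScheme(tr)
    snpSet <- sort(as.integer(snpSet))
    n <- nrow(geno)
    if (!is.null(seed)) set.seed(seed)
    perms <- vapply(seq_len(nPerm), function(i) sample.int(n), integer(n))
    sm <- scorerMatrices(method, scheme, tr)
    candCombo <- matrix(snpSet - 1L, ncol = 1L)
    obs <- cpp_perm_scores(asIntMatrix(geno), candCombo, sm$cellM,
                           sm$classM, matrix(seq_len(n)), sm$scoreType)[1L, 1L]
    nullCombos <- if (nullStatistic == "max_over_all")
        utils::combn(ncol(geno), length(snpSet)) - 1L else candCombo
    nullS <- cpp_perm_scores(asIntMatrix(geno), nullCombos, sm$cellM,
                             sm$classM, perms, sm$scoreType)
    nullStat <- apply(nullS, 2L, max)
    b <- sum(nullStat >= obs)
    if (plusOne) (b + 1) / (nPerm + 1) else b / nPerm
}

#' Fill in permutation p-values for ranked candidates
#'
#' Walks the candidate table in rank order computing [permutationPValue()]
#' for each.  With \code{earlyStopAlpha} set, computation stops at the first
#' candidate whose p-value falls below it (enough to decide the best
#' significant model); remaining p-values stay \code{NA}.
#'
#' @param result a \linkS4class{SearchResult}.
#' @param x the \linkS4class{MarkerData} the search was run on.
#' @param nPerm permutations per candidate.
#' @param nullStatistic "candidate" or "max_over_all".
#' @param maxCandidates cap on the number of candidates processed.
#' @param earlyStopAlpha optional significance level for early stopping.
#' @param seed optional seed.
#' @param plusOne apply the +1 correction.
#' @return the \linkS4class{SearchResult} with its pValue column updated.
#' @export
computePValues <- function(result, x, nPerm = 1000L,
                           nullStatistic = c("candidate", "max_over_all"),
                           maxCandidates = Inf, earlyStopAlpha = NULL,
                           seed = NULL, plusOne = FALSE) {
    nullStatistic <- match.arg(nullStatistic)
    cand <- result@candidates
    if (!is.null(seed)) set.seed(seed)
    k <- min(nrow(cand), maxCandidates)
    for (i in seq_len(k)) {
        cand$pValue[i] <- permutationPValue(
            x, cand$idx[[i]], scheme = result@scheme, nPerm = nPerm,
            method = result@method, nullStatistic = nullStatistic,
            plusOne = plusOne)
        if (!is.null(earlyStopAlpha) && cand$pValue[i] < earlyStopAlpha)
            break
    }
    result@candidates <- cand
    result
}

#' Final selection of significant interactions
#'
#' Retains candidates with a computed permutation p-value below alpha,
#' preserving the MTSBCA/GCVC ranking.
#'
#' @param result a \linkS4class{SearchResult} with p-values computed.
#' @param alpha significance level (default 0.01).
#' @return a \code{DataFrame} subset of the candidate table.
#' @export
finalSelection <- function(result, alpha = 0.01) {
    cand <- result@candidates
    cand[!is.na(cand$pValue) & cand$pValue < alpha, , drop = FALSE]
}

#' Write a candidate table as TSV with a JSON metadata sidecar
#'
#' @param result a \linkS4class{SearchResult}.
#' @param path output TSV path (one row per candidate).
#' @param metaPath optional JSON sidecar path (scheme borders, parameters).
#' @param seed seed to record in the sidecar, if any.
#' @return \code{path}, invisibly.
#' @export
writeCandidates <- function(result, path, metaPath = NULL, seed = NULL) {
    cand <- result@candidates
    df <- data.frame(order = result@order,
                     markers = cand$markers,
                     mtsbca = cand$mtsbca,
                     gcvc = cand$gcvc,
                     p_value = cand$pValue)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(metaPath)) {
        meta <- list(method = result@method, order = result@order,
                     folds = result@folds, topK = result@topK,
                     models_per_fold = result@nModels,
                     scheme = list(J = result@scheme@J,
                                   borders = result@scheme@borders,
                                   midpoints = result@scheme@midpoints),
                     seed = seed)
        jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
    }
    invisible(path)
}
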