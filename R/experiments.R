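#' Construct an experiment specification
#'
#' @param design "hit_ratio", "type1" or "realdata".
#' @param sim a \linkS4class{SimulationConfig} (per-replicate template).
#' @param method scorer name.
#' @param replicates number of replicate datasets.
#' @param folds,topK cross-validation parameters (L and K).
#' @param alpha significance level for final selection.
#' @param nPerm permutations per p-value.
#' @param nullStatistic "candidate" (default for hit-ratio runs) or
#'   "max_over_all" (the selection-aware null used for type-I error).
#' @param seed master seed; replicate r is fully reproducible from seed + r.
#' @return an \linkS4class{ExperimentSpec}.
#' @export
experimentSpec <- function(design = c("hit_ratio", "type1", "realdata"),
                           sim, method = "gfqmdr", replicates = 100L,
                           folds = 10L, topK = 3L, alpha = 0.01,
                           nPerm = 1000L,
                           nullStatistic = c("candidate", "max_over_all"),
                           seed = 1L) {
    design <- match.arg(design)
    nullSupplied <- !missing(nullStatistic)
    nullStatistic <- match.arg(nullStatistic)
    if (design == "type1" && !nullSupplied)
        nullStatistic <- "max_over_all"
    new("ExperimentSpec", design = design, method = method,
        replicates = as.integer(replicates), sim = sim,
        folds = as.integer(folds), topK = as.integer(topK),
        alpha = as.numeric(alpha), nPerm = as.integer(nPerm),
        nullStatistic = nullStatistic, seed = as.integer(seed))
}

#' Hit ratio of a detection experiment
#'
#' Proportion of replicates in which the true causal marker pair is detected
#' as the best pair.  Per replicate: simulate, run the cross-validated
#' search, compute permutation p-values down the candidate ranking, apply
#' the final selection at alpha.  For a single-model design a hit requires
#' the causal pair to be the top-ranked significant candidate; for mixture
#' designs each model scores a hit when its pair appears among the
#' significant candidates (reported per model, the "a:b" convention).
#'
#' @param spec an \linkS4class{ExperimentSpec} with design "hit_ratio" and a
#'   sim config holding at least one causal model.
#' @param verbose print one log line per replicate.
#' @return named list: \code{hits} (integer per model), \code{ratio}
#'   (proportion per model), \code{replicates}.
#' @export
hitRatio <- function(spec, verbose = FALSE) {
    sim <- spec@sim
    nModels <- length(sim@grids)
    if (nModels < 1L) stop("hit-ratio design needs at least one causal model")
    hits <- integer(nModels)
    single <- nModels == 1L
    for (r in seq_len(spec@replicates)) {
        set.seed(spec@seed + r)
        x <- simulateDataset(sim)
        res <- crossValidatedSearch(x, order = 2L, folds = spec@folds,
                                    topK = spec@topK, method = spec@method,
                                    schemeType = "deviation")
        res <- computePValues(res, x, nPerm = spec@nPerm,
                              nullStatistic = spec@nullStatistic,
                              earlyStopAlpha = if (single) spec@alpha else NULL)
        sel <- finalSelection(res, spec@alpha)
        selSets <- lapply(sel$idx, sort)
        for (t in seq_len(nModels)) {
            causal <- sort(sim@causalPairs[[t]])
            hit <- if (single)
                nrow(sel) > 0L && identical(selSets[[1L]], causal)
            else any(vapply(selSets, identical, logical(1), causal))
            hits[t] <- hits[t] + hit
        }
        if (verbose)
            message(sprintf("replicate %d: seed=%d best=%s p=%s", r,
                            spec@seed + r,
                            if (nrow(sel)) sel$markers[1L] else "none",
                            if (nrow(sel)) format(sel$pValue[1L]) else "NA"))
    }
    list(hits = hits, ratio = hits / spec@replicates,
         replicates = spec@replicates)
}

#' Type-I error rate of the permutation procedure
#'
#' Per replicate: simulate a null dataset, identify the strongest same-order
#' interaction by full-data training score, and compute its permutation
#' p-value against the max-over-all-sets null (the observed statistic is
#' itself a maximum, so the null must be too).  Returns the fraction of
#' replicates with p below alpha, which is calibrated to alpha for a valid
#' procedure.
#'
#' @param spec an \linkS4class{ExperimentSpec} with design "type1" and a
#'   null sim config.
#' @param order interaction order searched (default 2).
#' @return named list: \code{rate}, \code{rejections}, \code{replicates},
#'   \code{pValues}.
#' @export
typeIError <- function(spec, order = 2L) {
    sim <- spec@sim
    if (length(sim@grids))
        stop("type-I design requires a null sim config (no causal model)")
    pvals <- numeric(spec@replicates)
    combos <- utils::combn(sim@m, order) - 1L
    for (r in seq_len(spec@replicates)) {
        set.seed(spec@seed + r)
        x <- simulateDataset(sim)
        tr <- trait(x)
        scheme <- deviationScheme(tr)
        sm <- scorerMatrices(spec@method, scheme, tr)
        geno <- asIntMatrix(genotypeMatrix(x))
        n <- length(tr)
        obs <- max(cpp_perm_scores(geno, combos, sm$cellM, sm$classM,
                                   matrix(seq_len(n)), sm$scoreType))
        perms <- vapply(seq_len(spec@nPerm), function(i) sample.int(n),
                        integer(n))
        nullS <- cpp_perm_scores(geno, combos, sm$cellM, sm$classM, perms,
                                 sm$scoreType)
        pvals[r] <- mean(apply(nullS, 2L, max) >= obs)
    }
    rej <- sum(pvals < spec@alpha)
    list(rate = rej / spec@replicates, rejections = rej,
         replicates = spec@replicates, pValues = pvals)
}

#' Candidate table across methods and orders
#'
#' Runs the cross-validated search for every method x order combination on
#' one dataset and reports the top-k candidates with their MTSBCA, GCVC and
#' (optionally) permutation p-values -- the layout used to compare scorers
#' on real datasets.
#'
#' @param x a \linkS4class{MarkerData} (imputed).
#' @param orders integer vector of interaction orders.
#' @param k candidates reported per method/order.
#' @param methods scorer names.
#' @param folds CV folds.
#' @param scheme optional \linkS4class{IntervalScheme}; default equal-length
#'   intervals with J = 3.
#' @param nPerm permutations per p-value (0 skips p-values).
#' @param nullStatistic permutation null mode.
#' @param seed seed (fold assignment and permutations).
#' @return data.frame with one row per method x order x rank.
#' @export
realdataTable <- function(x, orders = 2:4, k = 3L,
                          methods = c("gfqmdr", "fqmdr", "omdr", "mdr"),
                          folds = 10L, scheme = NULL, nPerm = 0L,
                          nullStatistic = "candidate", seed = 1L) {
    if (is.null(scheme)) scheme <- equalLengthScheme(trait(x), 3L)
    rows <- list()
    for (method in methods) {
        for (ord in orders) {
            res <- crossValidatedSearch(x, scheme = scheme, order = ord,
                                        folds = folds, topK = k,
                                        method = method, seed = seed)
            if (nPerm > 0L)
                res <- computePValues(res, x, nPerm = nPerm,
                                      nullStatistic = nullStatistic,
                                      maxCandidates = k, seed = seed)
            cand <- candidates(res)
            kk <- min(k, nrow(cand))
            rows[[length(rows) + 1L]] <- data.frame(
                method = method, order = ord, rank = seq_len(kk),
                markers = cand$markers[seq_len(kk)],
                mtsbca = cand$mtsbca[seq_len(kk)],
                gcvc = cand$gcvc[seq_len(kk)],
                p_value = cand$pValue[seq_len(kk)])
        }
    }
    do.call(rbind, rows)
}

#' Read an experiment specification from YAML
#'
#' The YAML mirrors [experimentSpec()]: top-level keys design, method,
#' replicates, folds, topK, alpha, nPerm, nullStatistic, seed, and a
#' \code{sim} block (n, m, maf, sigma, models, weights, causalPairs,
#' sigmaAsVariance, null).  \code{models} names default grids
#' ("model1".."model5") or paths to grid files.
#'
#' @param path YAML file path.
#' @param gridDir optional directory of grid overrides passed to
#'   [defaultModelGrids()].
#' @return an \linkS4class{ExperimentSpec}.
#' @export
readExperimentSpec <- function(path, gridDir = NULL) {
    y <- yaml::read_yaml(path)
    if (is.null(y$sim)) stop("spec file lacks a 'sim' block")
    sim <- simConfigFromList(y$sim, gridDir)
    args <- list(design = y$design %||% "hit_ratio", sim = sim)
    for (key in c("method", "replicates", "folds", "topK", "alpha", "nPerm",
                  "nullStatistic", "seed"))
        if (!is.null(y[[key]])) args[[key]] <- y[[key]]
    do.call(experimentSpec, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a SimulationConfig from a YAML file or parsed list
#'
#' Keys: n, m, maf, sigma, models (default grid names or grid file paths),
#' weights, causalPairs, sigmaAsVariance, null, seed.
#'
#' @param x path to a YAML file, or an already-parsed named list.
#' @param gridDir optional grid-override directory for
#'   [defaultModelGrids()].
#' @return a \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(x, gridDir = NULL) {
    if (is.character(x)) x <- yaml::read_yaml(x)
    simConfigFromList(x, gridDir)
}

simConfigFromList <- function(s, gridDir = NULL) {
    # YAML 1.1 parses a bare `n` key as the boolean FALSE (and `y` as TRUE);
    # map those back to the intended field names
    names(s)[names(s) == "FALSE"] <- "n"
    names(s)[names(s) == "TRUE"] <- "y"
    grids <- NULL
    if (!is.null(s$models) && !isTRUE(s$null)) {
        all <- defaultModelGrids(gridDir)
        grids <- lapply(s$models, function(nm) {
            if (nm %in% names(all)) all[[nm]]
            else readPenetranceGrid(nm)
        })
    }
    simulationConfig(
        n = s$n, m = s$m, maf = s$maf, sigma = s$sigma, grids = grids,
        causalPairs = s$causalPairs, weights = s$weights, seed = s$seed,
        sigmaAsVariance = isTRUE(s$sigmaAsVariance), null = isTRUE(s$null))
}
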