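#' @import methods
#' @importFrom Rcpp evalCpp
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom IRanges IntegerList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @useDynLib gfqmdr, .registration = TRUE
NULL

# -- IntervalScheme -----------------------------------------------------------

#' Ordinal interval scheme for a quantitative trait
#'
#' An \code{IntervalScheme} partitions the observed range of a quantitative
#' trait into \code{J} ordered intervals (levels).  The borders are
#' \eqn{Q_{min} = b_0 < b_1 < \dots < b_J = Q_{max}} and each level \eqn{j}
#' carries a midpoint \eqn{P_j = (b_{j-1} + b_j)/2}, the anchor point of its
#' membership functions.
#'
#' @slot J integer, number of ordinal levels (>= 2).
#' @slot borders numeric vector of length \code{J + 1}, strictly increasing.
#' @slot midpoints numeric vector of length \code{J}, interval midpoints.
#'
#' @seealso [equalLengthScheme()], [deviationScheme()], [muTraditional()],
#'   [muExtended()], [crispCategory()]
#' @export
setClass("IntervalScheme",
    representation(J = "integer", borders = "numeric", midpoints = "numeric"))

setValidity("IntervalScheme", function(object) {
    msg <- NULL
    J <- object@J
    if (length(J) != 1L || is.na(J) || J < 2L)
        msg <- c(msg, "J must be a single integer >= 2")
    else {
        if (length(object@borders) != J + 1L)
            msg <- c(msg, "borders must have length J + 1")
        else if (any(!is.finite(object@borders)) ||
                 any(diff(object@borders) <= 0))
            msg <- c(msg, "borders must be finite and strictly increasing")
        if (length(object@midpoints) != J)
            msg <- c(msg, "midpoints must have length J")
        else if (length(object@borders) == J + 1L) {
            mid <- (object@borders[-1L] + object@borders[-(J + 1L)]) / 2
            if (max(abs(mid - object@midpoints)) > 1e-8 * diff(range(object@borders)))
                msg <- c(msg, "midpoints must be the interval midpoints of borders")
        }
    }
    if (is.null(msg)) TRUE else msg
})

# -- MarkerData ---------------------------------------------------------------

#' Genotype matrix plus quantitative trait
#'
#' \code{MarkerData} is a \linkS4class{SummarizedExperiment} with a single
#' \code{"genotype"} assay (markers in rows, samples in columns; codes 0/1/2 =
#' copies of the minor allele, \code{NA} = missing) and the quantitative trait
#' in \code{colData(x)$trait}.  SSLP or other categorical markers are mapped
#' onto the 0/1/2 coding at read time.
#'
#' @seealso [readDataset()], [imputeMissing()], [simulateDataset()],
#'   [crossValidatedSearch()]
#' @export
setClass("MarkerData", contains = "SummarizedExperiment")

setValidity("MarkerData", function(object) {
    msg <- NULL
    if (!"genotype" %in% SummarizedExperiment::assayNames(object))
        return("assay 'genotype' is required")
    g <- assay(object, "genotype")
    ok <- is.na(g) | g %in% 0:2
    if (!all(ok))
        msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
    if (!"trait" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'trait' column")
    else if (!is.numeric(colData(object)$trait))
        msg <- c(msg, "trait must be numeric")
    if (is.null(msg)) TRUE else msg
})

# -- PenetranceGrid -----------------------------------------------------------

#' Two-locus penetrance grid
#'
#' A 3 x 3 matrix giving the mean trait value for each joint genotype of two
#' biallelic causal markers; rows/columns are indexed by minor-allele copies
#' (0, 1, 2).  Simulated traits are normal noise around these means.
#'
#' @slot values numeric 3 x 3 matrix of cell means.
#'
#' @seealso [penetranceGrid()], [defaultModelGrids()], [simulateQT()]
#' @export
setClass("PenetranceGrid", representation(values = "matrix"))

setValidity("PenetranceGrid", function(object) {
    v <- object@values
    if (!is.numeric(v) || !identical(dim(v), c(3L, 3L)))
        return("values must be a numeric 3 x 3 matrix")
    if (any(!is.finite(v)))
        return("values must be finite")
    TRUE
})

# -- SimulationConfig ---------------------------------------------------------

#' Simulation configuration
#'
#' Describes one synthetic dataset: sample size, marker count, minor allele
#' frequency of the independent Hardy-Weinberg background, the trait noise
#' standard deviation sigma, and one or more (penetrance grid, causal marker
#' pair) interaction models combined with weights.
#'
#' @slot n integer sample count.
#' @slot m integer marker count.
#' @slot maf minor allele frequency in (0, 0.5].
#' @slot sigma trait noise (standard deviation by default).
#' @slot grids list of \linkS4class{PenetranceGrid}, one per model.
#' @slot causalPairs list of integer pairs (1-based marker indices).
#' @slot weights numeric model weights, same length as \code{grids}.
#' @slot sigmaAsVariance logical; interpret \code{sigma} as a variance.
#' @slot seed integer seed recorded with the config (NA when unset).
#'
#' @seealso [simulationConfig()], [simulateDataset()]
#' @export
setClass("SimulationConfig",
    representation(n = "integer", m = "integer", maf = "numeric",
                   sigma = "numeric", grids = "list", causalPairs = "list",
                   weights = "numeric", sigmaAsVariance = "logical",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (object@m < 2L) msg <- c(msg, "m must be >= 2")
    if (object@maf <= 0 || object@maf > 0.5)
        msg <- c(msg, "maf must be in (0, 0.5]")
    if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
    k <- length(object@grids)
    if (length(object@causalPairs) != k || length(object@weights) != k)
        msg <- c(msg, "grids, causalPairs and weights must have equal length")
    if (k > 0) {
        if (!all(vapply(object@grids, is, logical(1), "PenetranceGrid")))
            msg <- c(msg, "grids must all be PenetranceGrid objects")
        idx <- unlist(object@causalPairs)
        if (any(idx < 1L) || any(idx > object@m))
            msg <- c(msg, "causal marker indices out of range")
        if (anyDuplicated(idx))
            msg <- c(msg, "causal pairs must be disjoint")
    }
    if (is.null(msg)) TRUE else msg
})

# -- SearchResult -------------------------------------------------------------

#' Result of a cross-validated interaction search
#'
#' Holds the ranked candidate marker sets of one exhaustive m-way search:
#' for each candidate the maximum testing balanced classification accuracy
#' across folds (MTSBCA), the generalized cross-validation consistency
#' (GCVC, the number of folds in which the set ranked among the top-K
#' training models) and, once computed, a permutation p-value.
#'
#' @slot method scorer used: "gfqmdr", "fqmdr", "omdr" or "mdr".
#' @slot order interaction order (number of markers per set).
#' @slot folds number of cross-validation folds L.
#' @slot topK K used for per-fold retention and GCVC.
#' @slot candidates \code{DataFrame} with columns \code{markers}, \code{idx}
#'   (IntegerList of marker indices), \code{mtsbca}, \code{gcvc},
#'   \code{pValue}; sorted by MTSBCA, GCVC, then marker indices.
#' @slot perFoldTopK list (length L) of integer matrices, the top-K marker
#'   index sets per fold (columns are sets).
#' @slot scheme the \linkS4class{IntervalScheme} used.
#' @slot nModels number of marker sets evaluated per fold.
#'
#' @seealso [crossValidatedSearch()], [computePValues()], [finalSelection()]
#' @export
setClass("SearchResult",
    representation(method = "character", order = "integer", folds = "integer",
                   topK = "integer", candidates = "DFrame",
                   perFoldTopK = "list", scheme = "IntervalScheme",
                   nModels = "integer"))

# -- ExperimentSpec -----------------------------------------------------------

#' Replicate-level experiment specification
#'
#' @slot design "hit_ratio", "type1" or "realdata".
#' @slot method scorer name.
#' @slot replicates number of replicate datasets.
#' @slot sim the \linkS4class{SimulationConfig} for each replicate.
#' @slot folds,topK cross-validation parameters.
#' @slot alpha significance level for final selection.
#' @slot nPerm permutations per p-value.
#' @slot nullStatistic "candidate" or "max_over_all".
#' @slot seed master seed; replicate r uses seed + r.
#'
#' @seealso [experimentSpec()], [hitRatio()], [typeIError()]
#' @export
setClass("ExperimentSpec",
    representation(design = "character", method = "character",
                   replicates = "integer", sim = "SimulationConfig",
                   folds = "integer", topK = "integer", alpha = "numeric",
                   nPerm = "integer", nullStatistic = "character",
                   seed = "integer"))

setValidity("ExperimentSpec", function(object) {
    msg <- NULL
    if (!object@design %in% c("hit_ratio", "type1", "realdata"))
        msg <- c(msg, "design must be hit_ratio, type1 or realdata")
    if (!object@method %in% c("gfqmdr", "fqmdr", "omdr", "mdr"))
        msg <- c(msg, "unknown method")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (object@alpha <= 0 || object@alpha > 1)
        msg <- c(msg, "alpha must be in (0, 1]")
    if (!object@nullStatistic %in% c("candidate", "max_over_all"))
        msg <- c(msg, "nullStatistic must be candidate or max_over_all")
    if (is.null(msg)) TRUE else msg
})
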