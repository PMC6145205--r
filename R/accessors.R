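#' Accessors for MarkerData
#'
#' \code{genotypeMatrix} returns the sample-by-marker integer code matrix,
#' \code{trait} the quantitative trait vector, \code{markerIds} and
#' \code{sampleIds} the identifiers, and \code{causalPairs} the ground-truth
#' causal marker pairs recorded by the simulator (\code{NULL} for real data).
#'
#' @param x a \linkS4class{MarkerData} object.
#' @param ... unused.
#' @return \code{genotypeMatrix}: integer matrix n samples x m markers;
#'   \code{trait}: numeric vector of length n.
#' @name MarkerData-accessors
#' @aliases genotypeMatrix trait markerIds sampleIds causalPairs
NULL

#' @rdname MarkerData-accessors
#' @export
setMethod("genotypeMatrix", "MarkerData", function(x, ...) {
    t(assay(x, "genotype"))
})

#' @rdname MarkerData-accessors
#' @export
setMethod("trait", "MarkerData", function(x, ...) {
    colData(x)$trait
})

#' @rdname MarkerData-accessors
#' @export
setMethod("markerIds", "MarkerData", function(x, ...) rownames(x))

#' @rdname MarkerData-accessors
#' @export
setMethod("sampleIds", "MarkerData", function(x, ...) colnames(x))

#' @rdname MarkerData-accessors
#' @export
setMethod("causalPairs", "MarkerData", function(x, ...) {
    metadata(x)$causalPairs
})

#' Accessors for IntervalScheme
#'
#' @param x an \linkS4class{IntervalScheme}.
#' @param ... unused.
#' @name IntervalScheme-accessors
#' @aliases nLevels schemeBorders schemeMidpoints
NULL

#' @rdname IntervalScheme-accessors
#' @export
setMethod("nLevels", "IntervalScheme", function(x, ...) x@J)

#' @rdname IntervalScheme-accessors
#' @export
setMethod("schemeBorders", "IntervalScheme", function(x, ...) x@borders)

#' @rdname IntervalScheme-accessors
#' @export
setMethod("schemeMidpoints", "IntervalScheme", function(x, ...) x@midpoints)

#' Accessors for SearchResult
#'
#' \code{candidates} returns the ranked candidate table (a
#' \code{\link[S4Vectors]{DataFrame}} with columns \code{markers},
#' \code{idx}, \code{mtsbca}, \code{gcvc}, \code{pValue}).
#'
#' @param x a \linkS4class{SearchResult}.
#' @param ... unused.
#' @name SearchResult-accessors
#' @aliases candidates
NULL

#' @rdname SearchResult-accessors
#' @export
setMethod("candidates", "SearchResult", function(x, ...) x@candidates)

#' @rdname PenetranceGrid
#' @export
setMethod("gridValues", "PenetranceGrid", function(x, ...) x@values)

# -- show methods -------------------------------------------------------------

setMethod("show", "IntervalScheme", function(object) {
    cat("IntervalScheme with", object@J, "levels\n")
    cat("  borders:  ", paste(signif(object@borders, 5), collapse = ", "), "\n")
    cat("  midpoints:", paste(signif(object@midpoints, 5), collapse = ", "), "\n")
})

setMethod("show", "MarkerData", function(object) {
    callNextMethod()
    tr <- colData(object)$trait
    cat("trait: n =", length(tr), "| mean =", signif(mean(tr, na.rm = TRUE), 4),
        "| missing =", sum(is.na(tr)), "\n")
    cp <- metadata(object)$causalPairs
    if (!is.null(cp))
        cat("causal pairs:",
            paste(vapply(cp, function(p) paste(p, collapse = "-"),
                         character(1)), collapse = ", "), "\n")
})

setMethod("show", "PenetranceGrid", function(object) {
    cat("PenetranceGrid (rows/cols = minor-allele copies 0,1,2):\n")
    print(object@values)
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: n =", object@n, ", m =", object@m,
        ", MAF =", object@maf, ", sigma =", object@sigma,
        if (object@sigmaAsVariance) "(variance)" else "(sd)", "\n")
    if (length(object@grids)) {
        cat("  models:", length(object@grids), "| causal pairs:",
            paste(vapply(object@causalPairs,
                         function(p) paste(p, collapse = "-"),
                         character(1)), collapse = ", "),
            "| weights:", paste(object@weights, collapse = ", "), "\n")
    } else cat("  null design (no causal model)\n")
})

setMethod("show", "SearchResult", function(object) {
    cat("SearchResult:", object@method, "| order =", object@order,
        "| L =", object@folds, "| K =", object@topK,
        "| models evaluated per fold =", object@nModels, "\n")
    cd <- object@candidates
    cat("candidates:", nrow(cd), "\n")
    if (nrow(cd)) {
        n <- min(5L, nrow(cd))
        df <- data.frame(markers = cd$markers[seq_len(n)],
                         mtsbca = signif(cd$mtsbca[seq_len(n)], 4),
                         gcvc = cd$gcvc[seq_len(n)],
                         pValue = cd$pValue[seq_len(n)])
        print(df, row.names = FALSE)
        if (nrow(cd) > n) cat("  ...", nrow(cd) - n, "more\n")
    }
})

setMethod("show", "ExperimentSpec", function(object) {
    cat("ExperimentSpec:", object@design, "| method =", object@method,
        "| replicates =", object@replicates, "| L =", object@folds,
        "| K =", object@topK, "| alpha =", object@alpha,
        "| nPerm =", object@nPerm, "| null =", object@nullStatistic,
        "| seed =", object@seed, "\n")
    show(object@sim)
})
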