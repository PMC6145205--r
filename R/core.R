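#' Base-3 cell index of multi-locus genotypes
#'
#' Encodes the joint genotype of a set of markers as a single cell id in
#' 0 .. 3^m - 1, the i-th multi-locus genotype of the m-way model.
#'
#' @param x a \linkS4class{MarkerData} object or a sample-by-marker integer
#'   matrix with codes 0/1/2.
#' @param snpSet integer vector of marker indices (columns of the genotype
#'   matrix).
#' @return integer vector of cell ids (0-based), with attribute
#'   \code{"order"} = length(snpSet).
#' @export
indexCells <- function(x, snpSet) {
    geno <- if (is(x, "MarkerData")) genotypeMatrix(x) else x
    snpSet <- as.integer(snpSet)
    if (any(snpSet < 1L) || any(snpSet > ncol(geno)))
        stop("snpSet indices out of range")
    g <- geno[, snpSet, drop = FALSE]
    if (anyNA(g))
        stop("missing genotype codes present; impute first")
    if (any(g < 0L | g > 2L))
        stop("genotype codes must be 0, 1 or 2")
    cells <- as.integer(g %*% 3L^(seq_along(snpSet) - 1L))
    structure(cells, order = length(snpSet))
}

#' Fuzzy per-cell counts and class sizes
#'
#' Per-cell counts \eqn{n_{ij}} accumulate the membership of every sample in
#' cell i for level j using the selected family (extended by default, the
#' generalized fuzzy classifier; traditional for the FQMDR baseline).  The
#' class sizes \eqn{n_{+j}} always accumulate the traditional membership of
#' all samples, so they stay non-negative.
#'
#' @param cells cell index vector from [indexCells()].
#' @param trait numeric trait vector, same length.
#' @param scheme an \linkS4class{IntervalScheme}.
#' @param cellFamily membership family for the per-cell counts.
#' @return list with \code{nij} (3^order x J matrix) and \code{nplus}
#'   (length-J vector).
#' @export
fuzzyCounts <- function(cells, trait, scheme,
                        cellFamily = c("extended", "traditional")) {
    cellFamily <- match.arg(cellFamily)
    if (length(cells) != length(trait))
        stop("cells and trait lengths differ")
    ord <- attr(cells, "order")
    if (is.null(ord)) ord <- max(1L, ceiling(log(max(cells) + 1) / log(3)))
    ncell <- 3L^ord
    M <- membershipMatrix(scheme, trait, cellFamily)
    tmp <- rowsum(M, group = cells)
    nij <- matrix(0, ncell, scheme@J)
    nij[as.integer(rownames(tmp)) + 1L, ] <- tmp
    nplus <- colSums(membershipMatrix(scheme, trait, "traditional"))
    list(nij = nij, nplus = nplus)
}

#' Label cells by the fuzzy ratio rule
#'
#' Each cell is assigned the level maximizing \eqn{n_{ij}/n_{+j}} over levels
#' with positive class size; ties break toward the lower level.  Cells with
#' no training samples are unlabeled (\code{NA}).
#'
#' @param nij per-cell count matrix (cells x J).
#' @param nplus class size vector (length J).
#' @param cellN optional integer vector of per-cell sample counts; when
#'   omitted, rows that are identically zero are treated as empty.
#' @return integer vector of labels (1..J or NA).
#' @export
labelCells <- function(nij, nplus, cellN = NULL) {
    if (all(nplus <= 0)) stop("all class sizes are zero")
    ratio <- sweep(nij, 2L, nplus, "/")
    ratio[, nplus <= 0] <- -Inf
    labels <- max.col(ratio, ties.method = "first")
    empty <- if (is.null(cellN)) rowSums(abs(nij)) == 0 else cellN == 0L
    labels[empty] <- NA_integer_
    as.integer(labels)
}

#' Generalized fuzzy balanced accuracy
#'
#' The fuzzy balanced classification accuracy of a labeled m-way model:
#' \deqn{\frac{1}{J} \sum_i n_{i,c(i)} / n_{+c(i)}}
#' where the per-cell counts use the selected membership family and the class
#' sizes the traditional family.  Unlabeled cells and labels whose class size
#' is zero contribute 0.  When \code{cells}/\code{trait} come from a held-out
#' fold and \code{labels} from training, this is the testing accuracy.
#'
#' @param cells cell index vector from [indexCells()].
#' @param labels training labels from [labelCells()] (length 3^order).
#' @param trait numeric trait vector aligned with \code{cells}.
#' @param scheme an \linkS4class{IntervalScheme}.
#' @param cellFamily "extended" (generalized fuzzy) or "traditional" (FQMDR).
#' @return a single numeric score.
#' @export
fuzzyBalancedAccuracy <- function(cells, labels, trait, scheme,
                                  cellFamily = c("extended", "traditional")) {
    cellFamily <- match.arg(cellFamily)
    cnt <- fuzzyCounts(cells, trait, scheme, cellFamily)
    J <- scheme@J
    s <- 0
    for (i in seq_along(labels)) {
        c_i <- labels[i]
        if (is.na(c_i)) next
        if (cnt$nplus[c_i] <= 0) next
        s <- s + cnt$nij[i, c_i] / cnt$nplus[c_i]
    }
    s / J
}

#' Crisp balanced accuracy (mean per-class recall)
#'
#' The J-class generalization of (sensitivity + specificity)/2: the mean over
#' non-empty classes of the fraction of their members assigned to the correct
#' class.  Samples falling into unlabeled cells count as errors.
#'
#' @param cells cell index vector from [indexCells()].
#' @param labels cell labels (1..J or NA), length 3^order.
#' @param categories integer vector of true crisp levels per sample.
#' @return numeric score in [0, 1].
#' @export
crispBalancedAccuracy <- function(cells, labels, categories) {
    pred <- labels[cells + 1L]
    recalls <- vapply(sort(unique(categories)), function(j) {
        inClass <- categories == j
        sum(pred[inClass] == j, na.rm = TRUE) / sum(inClass)
    }, numeric(1))
    mean(recalls)
}

#' Kendall's tau-b ordinal association
#'
#' Tie-corrected Kendall rank correlation between true and predicted ordinal
#' categories, the OMDR baseline's model score.  When either vector is
#' constant the coefficient is undefined and 0 is returned with a warning.
#'
#' @param trueCat,predCat equal-length vectors of ordinal levels.
#' @return numeric in [-1, 1].
#' @export
tauB <- function(trueCat, predCat) {
    if (length(trueCat) != length(predCat)) stop("lengths differ")
    if (length(trueCat) < 2L) stop("need at least 2 observations")
    if (length(unique(trueCat)) < 2L || length(unique(predCat)) < 2L) {
        warning("tau-b undefined for a constant vector; returning 0")
        return(0)
    }
    stats::cor(as.numeric(trueCat), as.numeric(predCat), method = "kendall")
}
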