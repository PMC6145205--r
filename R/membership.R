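#' Build an interval scheme from explicit borders
#'
#' @param borders strictly increasing numeric vector of length J + 1.
#' @return an \linkS4class{IntervalScheme}; midpoints are
#'   \eqn{P_j = (b_{j-1} + b_j)/2}.
#' @export
intervalScheme <- function(borders) {
    borders <- as.numeric(borders)
    J <- length(borders) - 1L
    new("IntervalScheme", J = J, borders = borders,
        midpoints = (borders[-1L] + borders[-(J + 1L)]) / 2)
}

#' Equal-length interval scheme
#'
#' Partitions the observed trait range \eqn{[Q_{min}, Q_{max}]} into J
#' intervals of equal width.  This is the discretization of choice for real
#' traits whose distribution is not approximately normal.
#'
#' @param trait numeric trait vector (finite values).
#' @param J number of ordinal levels (>= 2), default 3.
#' @return an \linkS4class{IntervalScheme}.
#' @examples
#' equalLengthScheme(c(0, 1.2, 3), J = 3)
#' @export
equalLengthScheme <- function(trait, J = 3L) {
    J <- as.integer(J)
    if (J < 2L) stop("J must be >= 2")
    trait <- trait[is.finite(trait)]
    if (!length(trait)) stop("trait has no finite values")
    lo <- min(trait); hi <- max(trait)
    if (hi <= lo) stop("degenerate trait range: all values equal")
    intervalScheme(seq(lo, hi, length.out = J + 1L))
}

#' Mean +/- sd/2 interval scheme
#'
#' Three-level scheme for approximately normal traits: interior borders at
#' \eqn{\mu - \sigma/2} and \eqn{\mu + \sigma/2} (sample mean and standard
#' deviation), outer borders at the observed minimum and maximum.  Under a
#' normal trait the three levels receive about 31\%, 38\% and 31\% of the
#' samples.
#'
#' @param trait numeric trait vector with at least 2 distinct finite values.
#' @return an \linkS4class{IntervalScheme} with J = 3.
#' @export
deviationScheme <- function(trait) {
    trait <- trait[is.finite(trait)]
    if (length(trait) < 2L) stop("need at least 2 trait values")
    mu <- mean(trait); sdv <- stats::sd(trait)
    if (sdv == 0) stop("degenerate trait: sd is 0")
    b1 <- mu - sdv / 2; b2 <- mu + sdv / 2
    lo <- min(trait); hi <- max(trait)
    if (b1 <= lo || b2 >= hi)
        stop("mean +/- sd/2 borders fall outside the observed trait range; ",
             "a level would be empty (consider equalLengthScheme)")
    intervalScheme(c(lo, b1, b2, hi))
}

#' Traditional fuzzy membership (range [0, 1])
#'
#' Piecewise-linear membership of a trait value in ordinal level \code{j}.
#' Boundary levels saturate at 1 beyond their midpoint and ramp linearly to 0
#' at the adjacent midpoint; interior levels are triangular with peak 1 at
#' their own midpoint and feet at the adjacent midpoints.  The J levels form
#' a partition of unity on \eqn{[Q_{min}, Q_{max}]}.
#'
#' @param scheme an \linkS4class{IntervalScheme}.
#' @param j level index in 1..J.
#' @param x numeric vector of trait values.
#' @return numeric vector in [0, 1], same length as \code{x}.
#' @export
muTraditional <- function(scheme, j, x) {
    P <- scheme@midpoints; J <- scheme@J
    j <- as.integer(j)
    if (j < 1L || j > J) stop("level index out of range")
    if (j == 1L) {
        ifelse(x <= P[1L], 1,
               ifelse(x <= P[2L], (P[2L] - x) / (P[2L] - P[1L]), 0))
    } else if (j == J) {
        ifelse(x <= P[J - 1L], 0,
               ifelse(x <= P[J], (x - P[J - 1L]) / (P[J] - P[J - 1L]), 1))
    } else {
        ifelse(x >= P[j - 1L] & x <= P[j],
               (x - P[j - 1L]) / (P[j] - P[j - 1L]),
               ifelse(x > P[j] & x <= P[j + 1L],
                      (P[j + 1L] - x) / (P[j + 1L] - P[j]), 0))
    }
}

#' Extended fuzzy membership (range [-1, 1])
#'
#' Generalization of [muTraditional()] in which trait values far from a level
#' count against it.  For the low level (j = 1) the membership is 1 up to
#' \eqn{P_1}, descends linearly through 0 at \eqn{P_2} down to \eqn{-1} at
#' \eqn{P_3} (equal-width intervals), and is \eqn{-1} beyond \eqn{P_3}; the
#' high level mirrors this.  The middle level keeps its linear slopes beyond
#' the adjacent midpoints without clamping (for J = 3 its infimum on the
#' observed range is -0.5 under equal-width intervals).  For J > 3, interior
#' levels continue their triangular slopes past the adjacent midpoints and
#' clamp at -1 one further midpoint away.
#'
#' @inheritParams muTraditional
#' @return numeric vector, same length as \code{x}.
#' @export
muExtended <- function(scheme, j, x) {
    P <- scheme@midpoints; J <- scheme@J
    j <- as.integer(j)
    if (j < 1L || j > J) stop("level index out of range")
    if (J == 2L) {
        # no third midpoint exists: clamp the continued slope at -1
        if (j == 1L)
            return(ifelse(x <= P[1L], 1,
                          pmax((P[2L] - x) / (P[2L] - P[1L]), -1)))
        return(ifelse(x > P[2L], 1,
                      pmax((x - P[1L]) / (P[2L] - P[1L]), -1)))
    }
    if (j == 1L) {
        # the descending branch is clipped at -1 so that unequal interval
        # widths (deviation schemes) cannot push the membership below -1;
        # for equal-width intervals the clip never binds and the piecewise
        # form is exact
        ifelse(x <= P[1L], 1,
               ifelse(x <= P[3L],
                      pmax((P[2L] - x) / (P[2L] - P[1L]), -1), -1))
    } else if (j == J) {
        ifelse(x <= P[J - 2L], -1,
               ifelse(x <= P[J],
                      pmax((x - P[J - 1L]) / (P[J] - P[J - 1L]), -1), 1))
    } else {
        left <- (x - P[j - 1L]) / (P[j] - P[j - 1L])
        right <- (P[j + 1L] - x) / (P[j + 1L] - P[j])
        if (j - 2L >= 1L) left <- pmax(left, -1)
        if (j + 2L <= J) right <- pmax(right, -1)
        ifelse(x <= P[j], left, right)
    }
}

#' Membership matrix for all levels
#'
#' @param scheme an \linkS4class{IntervalScheme}.
#' @param x numeric trait vector.
#' @param family "traditional" or "extended".
#' @return numeric matrix, length(x) rows by J columns.
#' @export
membershipMatrix <- function(scheme, x,
                             family = c("traditional", "extended")) {
    family <- match.arg(family)
    f <- if (family == "traditional") muTraditional else muExtended
    matrix(vapply(seq_len(scheme@J), function(j) f(scheme, j, x),
                  numeric(length(x))),
           nrow = length(x), ncol = scheme@J)
}

#' Crisp ordinal category of a trait value
#'
#' Assigns each value to the interval it falls in; intervals are open on the
#' left and closed on the right, so a value exactly on an interior border
#' goes to the lower level.  Values below the first border map to level 1 and
#' above the last border to level J.
#'
#' @param scheme an \linkS4class{IntervalScheme}.
#' @param x numeric trait vector.
#' @return integer vector of levels in 1..J.
#' @export
crispCategory <- function(scheme, x) {
    J <- scheme@J
    cat <- rep(1L, length(x))
    for (b in scheme@borders[seq(2L, J)])
        cat <- cat + (x > b)
    as.integer(cat)
}
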