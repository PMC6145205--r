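#' Construct a penetrance grid
#'
#' @param values numeric 3 x 3 matrix of per-cell mean trait values
#'   (rows = minor-allele copies at the first marker, columns at the second).
#' @return a \linkS4class{PenetranceGrid}.
#' @export
penetranceGrid <- function(values) {
    new("PenetranceGrid", values = matrix(as.numeric(values), 3L, 3L))
}

#' Default two-locus interaction model grids
#'
#' Five distinct 3 x 3 penetrance grids over the canonical mean levels
#' {0.01, 0.25, 0.5} (normal, low risk, high risk).  The layouts are
#' synthetic stand-ins covering the usual epistasis motifs (checkerboard,
#' anti-diagonal gradient, diagonal, corner and center models); at low trait
#' noise the detection experiments are insensitive to the exact layout, and
#' any grid can be overridden from a YAML/JSON file of the same model name.
#'
#' @param configDir optional directory; files \code{<name>.yaml|yml|json}
#'   replace the default grid of that name.
#' @return named list of five \linkS4class{PenetranceGrid} objects.
#' @examples
#' defaultModelGrids()$model1
#' @export
defaultModelGrids <- function(configDir = NULL) {
    lo <- 0.01; mid <- 0.25; hi <- 0.5
    grids <- list(
        model1 = penetranceGrid(matrix(c(lo, hi, lo,
                                         hi, lo, hi,
                                         lo, hi, lo), 3, 3, byrow = TRUE)),
        model2 = penetranceGrid(matrix(c(lo, mid, hi,
                                         mid, hi, mid,
                                         hi, mid, lo), 3, 3, byrow = TRUE)),
        model3 = penetranceGrid(matrix(c(hi, mid, lo,
                                         mid, mid, mid,
                                         lo, mid, hi), 3, 3, byrow = TRUE)),
        model4 = penetranceGrid(matrix(c(lo, lo, hi,
                                         lo, mid, lo,
                                         hi, lo, lo), 3, 3, byrow = TRUE)),
        model5 = penetranceGrid(matrix(c(mid, lo, mid,
                                         lo, hi, lo,
                                         mid, lo, mid), 3, 3, byrow = TRUE)))
    if (!is.null(configDir)) {
        for (nm in names(grids)) {
            for (ext in c("yaml", "yml", "json")) {
                f <- file.path(configDir, paste0(nm, ".", ext))
                if (file.exists(f)) {
                    grids[[nm]] <- readPenetranceGrid(f)
                    break
                }
            }
        }
    }
    grids
}

#' Read a penetrance grid from YAML or JSON
#'
#' The file holds a 3 x 3 numeric array (list of three rows).
#'
#' @param path file path (.yaml/.yml or .json).
#' @return a \linkS4class{PenetranceGrid}.
#' @export
readPenetranceGrid <- function(path) {
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.list(raw)) raw <- do.call(rbind, lapply(raw, as.numeric))
    if (is.null(dim(raw)) || !all(dim(raw) == c(3L, 3L)))
        stop("grid file must contain a 3 x 3 numeric array: ", path)
    penetranceGrid(matrix(as.numeric(raw), 3L, 3L, byrow = FALSE))
}

#' Construct a simulation configuration
#'
#' @param n sample count.
#' @param m marker count.
#' @param maf minor allele frequency in (0, 0.5].
#' @param sigma trait noise level (standard deviation of the normal around
#'   each cell mean unless \code{sigmaAsVariance}).
#' @param grids list of \linkS4class{PenetranceGrid} (or a single grid);
#'   default: model1 of [defaultModelGrids()].
#' @param causalPairs list of integer pairs of causal marker indices;
#'   default: markers (1,2) for the first model, (3,4) for the second, ...
#' @param weights model weights (default: equal, or 1 for a single model).
#' @param seed optional integer recorded in the config (used by
#'   [simulateDataset()]).
#' @param sigmaAsVariance interpret \code{sigma} as the variance instead of
#'   the standard deviation.
#' @param null logical; TRUE builds a null design with no causal model.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(n, m, maf, sigma, grids = NULL,
                             causalPairs = NULL, weights = NULL, seed = NULL,
                             sigmaAsVariance = FALSE, null = FALSE) {
    if (null) {
        grids <- list(); causalPairs <- list(); weights <- numeric(0)
    } else {
        if (is.null(grids)) grids <- defaultModelGrids()["model1"]
        if (is(grids, "PenetranceGrid")) grids <- list(grids)
        k <- length(grids)
        if (is.null(causalPairs))
            causalPairs <- lapply(seq_len(k), function(t)
                c(2L * t - 1L, 2L * t))
        causalPairs <- lapply(causalPairs, as.integer)
        if (is.null(weights)) weights <- rep(1 / k, k)
    }
    new("SimulationConfig", n = as.integer(n), m = as.integer(m),
        maf = as.numeric(maf), sigma = as.numeric(sigma),
        grids = grids, causalPairs = causalPairs,
        weights = as.numeric(weights),
        sigmaAsVariance = isTRUE(sigmaAsVariance),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Simulate independent Hardy-Weinberg genotypes
#'
#' Each marker is an independent biallelic SNP with genotype frequencies
#' ((1-q)^2, 2q(1-q), q^2) at minor allele frequency q; codes are copies of
#' the minor allele.
#'
#' @param n sample count.
#' @param m marker count.
#' @param maf minor allele frequency in (0, 0.5].
#' @param seed optional seed.
#' @return integer matrix n x m with dimnames S1..Sn / M1..Mm.
#' @export
simulateGenotypes <- function(n, m, maf, seed = NULL) {
    if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
    if (!is.null(seed)) set.seed(seed)
    p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    g <- matrix(sample(0:2, n * m, replace = TRUE, prob = p), n, m)
    dimnames(g) <- list(paste0("S", seq_len(n)), paste0("M", seq_len(m)))
    g
}

#' Simulate a quantitative trait from penetrance grids
#'
#' Each sample's trait is drawn from a normal distribution whose mean is the
#' weighted sum of the penetrance-grid cells selected by its genotypes at the
#' causal pairs, and whose standard deviation is sigma (or sqrt(sigma) when
#' the config flags sigma as a variance).
#'
#' @param genotypes integer matrix n x m of codes 0/1/2.
#' @param config a \linkS4class{SimulationConfig} with at least one model.
#' @return numeric trait vector of length n.
#' @export
simulateQT <- function(genotypes, config) {
    k <- length(config@grids)
    if (k == 0L) stop("config has no causal model; use simulateNull()")
    n <- nrow(genotypes)
    mu <- numeric(n)
    for (t in seq_len(k)) {
        pr <- config@causalPairs[[t]]
        f <- config@grids[[t]]@values
        mu <- mu + config@weights[t] *
            f[cbind(genotypes[, pr[1L]] + 1L, genotypes[, pr[2L]] + 1L)]
    }
    sdv <- if (config@sigmaAsVariance) sqrt(config@sigma) else config@sigma
    stats::rnorm(n, mean = mu, sd = sdv)
}

#' Simulate a complete dataset from a configuration
#'
#' Draws genotypes and trait and packs them into a \linkS4class{MarkerData}
#' whose metadata records the causal pairs and the config echo.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed optional seed (overrides the one recorded in the config).
#' @return a \linkS4class{MarkerData}.
#' @export
simulateDataset <- function(config, seed = NULL) {
    if (is.null(seed) && !is.na(config@seed)) seed <- config@seed
    if (!is.null(seed)) set.seed(seed)
    g <- simulateGenotypes(config@n, config@m, config@maf)
    tr <- if (length(config@grids)) simulateQT(g, config)
          else stats::rnorm(config@n)
    md <- MarkerData(g, tr)
    metadata(md)$causalPairs <- config@causalPairs
    metadata(md)$config <- list(
        n = config@n, m = config@m, maf = config@maf, sigma = config@sigma,
        sigmaAsVariance = config@sigmaAsVariance,
        weights = config@weights, seed = seed)
    md
}

#' Simulate a null dataset (trait independent of genotypes)
#'
#' @param n sample count.
#' @param m marker count.
#' @param maf minor allele frequency.
#' @param seed optional seed.
#' @return a \linkS4class{MarkerData} with a standard-normal trait.
#' @export
simulateNull <- function(n, m, maf, seed = NULL) {
    cfg <- simulationConfig(n = n, m = m, maf = maf, sigma = 1, null = TRUE,
                            seed = seed)
    simulateDataset(cfg)
}

#' Transfer a quantitative trait to a three-level ordinal trait
#'
#' Cuts at the sample mean +/- sd/2 (the discretization appropriate for
#' approximately normal traits); for a standard normal trait the expected
#' level proportions are about (0.309, 0.383, 0.309).
#'
#' @param trait numeric trait vector.
#' @return integer vector of levels 1 (low), 2 (middle), 3 (high).
#' @export
qtToOrdinal <- function(trait) {
    crispCategory(deviationScheme(trait), trait)
}
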