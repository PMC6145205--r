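#' Construct a MarkerData object
#'
#' @param genotypes sample-by-marker matrix of codes 0/1/2 (NA = missing).
#' @param trait numeric trait vector of length \code{nrow(genotypes)};
#'   defaults to all-NA (genotypes only).
#' @param markerIds,sampleIds identifiers; default to the dimnames of
#'   \code{genotypes} or generated M1../S1.. names.
#' @return a \linkS4class{MarkerData}.
#' @examples
#' g <- simulateGenotypes(20, 5, maf = 0.3, seed = 1)
#' MarkerData(g, rnorm(20))
#' @export
MarkerData <- function(genotypes, trait = NULL,
                       markerIds = colnames(genotypes),
                       sampleIds = rownames(genotypes)) {
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "integer"
    n <- nrow(genotypes); m <- ncol(genotypes)
    if (is.null(markerIds)) markerIds <- paste0("M", seq_len(m))
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(n))
    if (is.null(trait)) trait <- rep(NA_real_, n)
    if (length(trait) != n)
        stop("trait length does not match the number of samples")
    a <- t(genotypes)
    dimnames(a) <- list(markerIds, sampleIds)
    se <- SummarizedExperiment(
        assays = list(genotype = a),
        colData = DataFrame(trait = as.numeric(trait), row.names = sampleIds))
    new("MarkerData", se)
}

.missingTokens <- c("", "NA", "N/A", "na", "?", "-", ".")

# Map one marker's raw strings onto 0/1/2 codes.  Numeric 0/1/2 pass
# through; otherwise (SSLP allele labels) the sorted unique labels are
# assigned codes in order, or a user codeMap (named label -> code) is used.
.mapMarkerCodes <- function(vals, marker, codeMap = NULL) {
    vals <- trimws(as.character(vals))
    miss <- is.na(vals) | vals %in% .missingTokens
    out <- rep(NA_integer_, length(vals))
    obs <- vals[!miss]
    if (!length(obs)) return(out)
    if (!is.null(codeMap)) {
        mapped <- codeMap[obs]
        if (anyNA(mapped))
            stop("marker ", marker, ": alleles missing from codeMap: ",
                 paste(unique(obs[is.na(mapped)]), collapse = ", "))
        out[!miss] <- as.integer(mapped)
        return(out)
    }
    suppressWarnings(num <- as.numeric(obs))
    if (!anyNA(num) && all(num %in% 0:2)) {
        out[!miss] <- as.integer(num)
        return(out)
    }
    lev <- sort(unique(obs))
    if (length(lev) > 3L)
        stop("marker ", marker, " has more than 3 allele codes: ",
             paste(lev, collapse = ", "))
    out[!miss] <- match(obs, lev) - 1L
    out
}

#' Read a genotype/phenotype dataset from TSV files
#'
#' The genotype file is tabular text with a header row of marker ids and a
#' first column of sample ids; the phenotype file has two columns (sample id,
#' trait value).  Rows are joined by sample id, so row order need not match.
#' Genotype entries are mapped to 0/1/2 codes; unparseable entries become
#' missing; markers with more than three distinct codes raise an error.
#'
#' @param genotypePath path to the genotype TSV.
#' @param phenotypePath path to the phenotype TSV.
#' @param codeMap optional named integer vector mapping allele labels to
#'   codes (applied to every marker), for SSLP data.
#' @return a \linkS4class{MarkerData}; provenance (paths) is stored in its
#'   metadata.
#' @seealso [imputeMissing()], [writeDataset()]
#' @export
readDataset <- function(genotypePath, phenotypePath, codeMap = NULL) {
    gdf <- utils::read.delim(genotypePath, check.names = FALSE,
                             colClasses = "character")
    pdf <- utils::read.delim(phenotypePath, check.names = FALSE,
                             colClasses = "character")
    if (ncol(pdf) < 2L) stop("phenotype file needs two columns (id, value)")
    gids <- trimws(gdf[[1L]])
    pids <- trimws(pdf[[1L]])
    onlyG <- setdiff(gids, pids); onlyP <- setdiff(pids, gids)
    if (length(onlyG) || length(onlyP))
        stop("sample ids do not match; only in genotypes: ",
             paste(utils::head(onlyG, 5), collapse = ", "),
             "; only in phenotypes: ",
             paste(utils::head(onlyP, 5), collapse = ", "))
    pdf <- pdf[match(gids, pids), , drop = FALSE]
    markers <- colnames(gdf)[-1L]
    codes <- vapply(seq_along(markers), function(j)
        .mapMarkerCodes(gdf[[j + 1L]], markers[j], codeMap),
        integer(length(gids)))
    codes <- matrix(codes, nrow = length(gids),
                    dimnames = list(gids, markers))
    tr <- suppressWarnings(as.numeric(pdf[[2L]]))
    md <- MarkerData(codes, tr, markerIds = markers, sampleIds = gids)
    metadata(md)$provenance <- list(genotypes = genotypePath,
                                    phenotypes = phenotypePath)
    md
}

#' Write a dataset as genotype + phenotype TSV files
#'
#' Inverse of [readDataset()]: round-tripping reproduces codes and trait
#' values exactly.
#'
#' @param x a \linkS4class{MarkerData}.
#' @param genotypePath,phenotypePath output paths.
#' @return \code{genotypePath}, invisibly.
#' @export
writeDataset <- function(x, genotypePath, phenotypePath) {
    g <- genotypeMatrix(x)
    gdf <- data.frame(sample = sampleIds(x), g, check.names = FALSE)
    colnames(gdf) <- c("sample", markerIds(x))
    utils::write.table(gdf, genotypePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pdf <- data.frame(sample = sampleIds(x), trait = trait(x))
    utils::write.table(pdf, phenotypePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(genotypePath)
}

#' Impute missing genotypes and trait values
#'
#' Missing genotype codes become the modal code of their marker (ties break
#' to the lower code); missing trait values become the mean of the observed
#' values.  Imputation counts are logged in the object metadata.  The
#' operation is idempotent.
#'
#' @param x a \linkS4class{MarkerData}.
#' @return the imputed \linkS4class{MarkerData}.
#' @export
imputeMissing <- function(x) {
    g <- genotypeMatrix(x)
    nGeno <- 0L
    for (j in seq_len(ncol(g))) {
        miss <- is.na(g[, j])
        if (!any(miss)) next
        obs <- g[!miss, j]
        if (!length(obs))
            stop("marker ", markerIds(x)[j], " is entirely missing")
        tab <- table(obs)
        mode <- as.integer(names(tab)[which.max(tab)])  # ties: lower code
        g[miss, j] <- mode
        nGeno <- nGeno + sum(miss)
    }
    tr <- trait(x)
    nTrait <- sum(is.na(tr))
    if (nTrait) {
        if (all(is.na(tr))) stop("trait is entirely missing")
        tr[is.na(tr)] <- mean(tr, na.rm = TRUE)
    }
    out <- MarkerData(g, tr, markerIds = markerIds(x),
                      sampleIds = sampleIds(x))
    metadata(out) <- metadata(x)
    metadata(out)$imputation <- list(genotypes = nGeno, trait = nTrait)
    out
}

#' Import genotype dosages from a VCF file
#'
#' Optional interoperability importer: converts the GT field of a VCF into
#' 0/1/2 minor-allele dosage codes.  Requires the VariantAnnotation package.
#'
#' @param vcfPath path to an (uncompressed or bgzipped) VCF.
#' @param trait optional numeric trait vector aligned with the VCF samples.
#' @return a \linkS4class{MarkerData}.
#' @export
readVcfGenotypes <- function(vcfPath, trait = NULL) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("readVcfGenotypes requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(vcfPath)
    gt <- VariantAnnotation::geno(vcf)$GT
    dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dose[clean %in% c("0/0")] <- 0L
    dose[clean %in% c("0/1", "1/0")] <- 1L
    dose[clean %in% c("1/1")] <- 2L
    MarkerData(t(dose), trait, markerIds = rownames(gt),
               sampleIds = colnames(gt))
}
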