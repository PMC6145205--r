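# Independent reference implementations used as oracles.  Everything here is
# deliberately scalar / loop-based and re-derives the piecewise membership
# forms from the interval midpoints, so it shares no code path with the
# vectorized package internals or the C++ kernel.

oracleMuTrad <- function(P, j, x) {
    J <- length(P)
    if (j == 1) {
        if (x <= P[1]) 1
        else if (x <= P[2]) (P[2] - x) / (P[2] - P[1])
        else 0
    } else if (j == J) {
        if (x <= P[J - 1]) 0
        else if (x <= P[J]) (x - P[J - 1]) / (P[J] - P[J - 1])
        else 1
    } else {
        if (x >= P[j - 1] && x <= P[j]) (x - P[j - 1]) / (P[j] - P[j - 1])
        else if (x > P[j] && x <= P[j + 1]) (P[j + 1] - x) / (P[j + 1] - P[j])
        else 0
    }
}

oracleMuExt <- function(P, j, x) {
    J <- length(P)
    if (j == 1) {
        if (x <= P[1]) 1
        else if (x <= P[3]) max((P[2] - x) / (P[2] - P[1]), -1)
        else -1
    } else if (j == J) {
        if (x <= P[J - 2]) -1
        else if (x <= P[J]) max((x - P[J - 1]) / (P[J] - P[J - 1]), -1)
        else 1
    } else {
        v <- if (x <= P[j]) (x - P[j - 1]) / (P[j] - P[j - 1])
             else (P[j + 1] - x) / (P[j + 1] - P[j])
        lo <- if (x <= P[j]) j - 2 >= 1 else j + 2 <= J
        if (lo) max(v, -1) else v
    }
}

# Naive per-sample cross-validated search for any scorer.  geno is an
# n x m 0/1/2 matrix, fold a 1..L vector.  Returns train/test score
# matrices (ncomb x L) with combos in combn() order.
oracleSearch <- function(geno, trait, scheme, order, fold, method) {
    P <- schemeMidpoints(scheme)
    J <- nLevels(scheme)
    borders <- schemeBorders(scheme)
    crispOne <- function(x) 1 + sum(x > borders[2:J])
    L <- max(fold)
    combos <- utils::combn(ncol(geno), order)
    ncomb <- ncol(combos)
    train <- matrix(0, ncomb, L)
    test <- matrix(0, ncomb, L)
    ncell <- 3^order
    cellOf <- function(s, set) {
        id <- 0
        for (t in seq_along(set)) id <- id + geno[s, set[t]] * 3^(t - 1)
        id + 1
    }
    cellCnt <- function(idx, set) {
        # per-cell counts (family by method), class sizes, sample counts
        nij <- matrix(0, ncell, J)
        nplus <- numeric(J)
        nsamp <- integer(ncell)
        for (s in idx) {
            i <- cellOf(s, set)
            nsamp[i] <- nsamp[i] + 1
            for (j in seq_len(J)) {
                v <- switch(method,
                    gfqmdr = oracleMuExt(P, j, trait[s]),
                    fqmdr = oracleMuTrad(P, j, trait[s]),
                    as.numeric(crispOne(trait[s]) == j))
                nij[i, j] <- nij[i, j] + v
                nplus[j] <- nplus[j] +
                    if (method %in% c("gfqmdr", "fqmdr"))
                        oracleMuTrad(P, j, trait[s])
                    else as.numeric(crispOne(trait[s]) == j)
            }
        }
        list(nij = nij, nplus = nplus, nsamp = nsamp)
    }
    lab <- function(cnt) {
        labels <- rep(NA_integer_, ncell)
        for (i in seq_len(ncell)) {
            if (cnt$nsamp[i] == 0) next
            best <- NA; bestv <- -Inf
            for (j in seq_len(J)) {
                if (cnt$nplus[j] <= 0) next
                v <- cnt$nij[i, j] / cnt$nplus[j]
                if (v > bestv) { bestv <- v; best <- j }
            }
            labels[i] <- best
        }
        labels
    }
    scoreOf <- function(cnt, labels, idx, set) {
        if (method %in% c("gfqmdr", "fqmdr")) {
            s <- 0
            for (i in seq_len(ncell)) {
                if (is.na(labels[i])) next
                if (cnt$nplus[labels[i]] <= 0) next
                s <- s + cnt$nij[i, labels[i]] / cnt$nplus[labels[i]]
            }
            s / J
        } else if (method == "mdr") {
            cats <- vapply(idx, function(s) crispOne(trait[s]), numeric(1))
            pred <- vapply(idx, function(s) labels[cellOf(s, set)],
                           numeric(1))
            recalls <- c()
            for (j in seq_len(J)) {
                inj <- cats == j
                if (!any(inj)) next
                recalls <- c(recalls, sum(!is.na(pred[inj]) &
                                          pred[inj] == j) / sum(inj))
            }
            if (length(recalls)) mean(recalls) else 0
        } else {  # omdr: tau-b by exhaustive pair enumeration
            cats <- vapply(idx, function(s) crispOne(trait[s]), numeric(1))
            pred <- vapply(idx, function(s) labels[cellOf(s, set)],
                           numeric(1))
            keep <- !is.na(pred)
            oracleTauB(cats[keep], pred[keep])
        }
    }
    for (ci in seq_len(ncomb)) {
        set <- combos[, ci]
        for (l in seq_len(L)) {
            tri <- which(fold != l)
            tei <- which(fold == l)
            cntTr <- cellCnt(tri, set)
            labels <- lab(cntTr)
            train[ci, l] <- scoreOf(cntTr, labels, tri, set)
            cntTe <- cellCnt(tei, set)
            test[ci, l] <- scoreOf(cntTe, labels, tei, set)
        }
    }
    list(train = train, test = test)
}

# Kendall tau-b by brute force over all pairs.
oracleTauB <- function(a, b) {
    n <- length(a)
    if (n < 2) return(0)
    C <- 0; D <- 0; Ta <- 0; Tb <- 0
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            da <- a[i] - a[j]; db <- b[i] - b[j]
            if (da == 0 && db == 0) { Ta <- Ta + 1; Tb <- Tb + 1 }
            else if (da == 0) Ta <- Ta + 1
            else if (db == 0) Tb <- Tb + 1
            else if (da * db > 0) C <- C + 1
            else D <- D + 1
        }
    }
    n0 <- n * (n - 1) / 2
    den <- sqrt((n0 - Ta) * (n0 - Tb))
    if (den <= 0) return(0)
    (C - D) / den
}
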