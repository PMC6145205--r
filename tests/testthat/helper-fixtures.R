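# Constructed fixtures.

# Midpoint-aligned fixture: every trait value sits exactly on an interval
# midpoint and every genotype cell mixes at most two ADJACENT categories.
# In that regime the extended, traditional and crisp counting families agree
# on every cell's own-class count, so all scorers must coincide.
midpointFixture <- function() {
    scheme <- intervalScheme(c(0, 1, 2, 3))   # midpoints 0.5, 1.5, 2.5
    P <- schemeMidpoints(scheme)
    # single marker -> 3 cells (codes 0,1,2)
    geno <- matrix(c(rep(0L, 4), rep(1L, 4), rep(2L, 4)), ncol = 1)
    # cell 0: 3 low + 1 mid ; cell 1: 4 mid ; cell 2: 1 mid + 3 high
    trait <- c(P[1], P[1], P[1], P[2],
               P[2], P[2], P[2], P[2],
               P[2], P[3], P[3], P[3])
    colnames(geno) <- "M1"
    list(scheme = scheme, geno = geno, trait = trait,
         # crisp bookkeeping: class sizes (3, 6, 3); labels (1, 2, 3);
         # mean per-class recall = (3/3 + 4/6 + 3/3) / 3 = 8/9
         expectedLabels = c(1L, 2L, 3L),
         expectedScore = 8 / 9)
}

# Small random instance for oracle-equivalence checks.
randomInstance <- function(n, m, seed) {
    set.seed(seed)
    geno <- matrix(sample(0:2, n * m, replace = TRUE,
                          prob = c(0.36, 0.48, 0.16)), n, m)
    colnames(geno) <- paste0("M", seq_len(m))
    rownames(geno) <- paste0("S", seq_len(n))
    trait <- rnorm(n)
    list(geno = geno, trait = trait)
}
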