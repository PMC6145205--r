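#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// score types: 1 = fuzzy balanced accuracy (zero-fill for
// unlabeled cells / empty classes), 2 = mean per-class recall over non-empty
// classes (crisp MDR), 3 = Kendall tau-b from the true x predicted table
// (OMDR; samples in unlabeled cells excluded).

static inline int ipow3(int k) {
    int r = 1;
    for (int i = 0; i < k; ++i) r *= 3;
    return r;
}

static double tau_b_from_table(const std::vector<double>& tab, int J) {
    double P = 0.0, Q = 0.0;
    for (int a = 0; a < J; ++a) {
        for (int b = 0; b < J; ++b) {
            double nab = tab[a * J + b];
            if (nab == 0.0) continue;
            double con = 0.0, dis = 0.0;
            for (int a2 = a + 1; a2 < J; ++a2) {
                for (int b2 = 0; b2 < J; ++b2) {
                    if (b2 > b) con += tab[a2 * J + b2];
                    else if (b2 < b) dis += tab[a2 * J + b2];
                }
            }
            P += nab * con;
            Q += nab * dis;
        }
    }
    double n = 0.0;
    std::vector<double> rows(J, 0.0), cols(J, 0.0);
    for (int a = 0; a < J; ++a)
        for (int b = 0; b < J; ++b) {
            rows[a] += tab[a * J + b];
            cols[b] += tab[a * J + b];
            n += tab[a * J + b];
        }
    double n2 = n * (n - 1.0) / 2.0, tr = 0.0, tc = 0.0;
    for (int a = 0; a < J; ++a) tr += rows[a] * (rows[a] - 1.0) / 2.0;
    for (int b = 0; b < J; ++b) tc += cols[b] * (cols[b] - 1.0) / 2.0;
    double den = std::sqrt((n2 - tr) * (n2 - tc));
    if (!(den > 0.0)) return 0.0;
    return (P - Q) / den;
}

// argmax_j cnt[j]/denom[j] over levels with denom > 0; ties -> lower level.
static inline int argmax_ratio(const double* cnt, const double* denom, int J) {
    int best = -1;
    double bestv = 0.0;
    for (int j = 0; j < J; ++j) {
        if (!(denom[j] > 0.0)) continue;
        double v = cnt[j] / denom[j];
        if (best < 0 || v > bestv) {
            best = j;
            bestv = v;
        }
    }
    return best;
}

static double score_cells(const std::vector<double>& cnt, const double* denom,
                          const std::vector<int>& labels, int ncell, int J,
                          int scoreType) {
    if (scoreType == 1) {
        double s = 0.0;
        for (int i = 0; i < ncell; ++i) {
            int c = labels[i];
            if (c < 0) continue;
            if (!(denom[c] > 0.0)) continue;
            s += cnt[i * J + c] / denom[c];
        }
        return s / J;
    } else if (scoreType == 2) {
        std::vector<double> correct(J, 0.0);
        for (int i = 0; i < ncell; ++i) {
            int c = labels[i];
            if (c < 0) continue;
            correct[c] += cnt[i * J + c];
        }
        double s = 0.0;
        int used = 0;
        for (int j = 0; j < J; ++j) {
            if (denom[j] > 0.0) {
                s += correct[j] / denom[j];
                ++used;
            }
        }
        return used ? s / used : 0.0;
    } else {
        std::vector<double> tab(J * J, 0.0);
        for (int i = 0; i < ncell; ++i) {
            int c = labels[i];
            if (c < 0) continue;
            for (int a = 0; a < J; ++a) tab[a * J + c] += cnt[i * J + a];
        }
        return tau_b_from_table(tab, J);
    }
}

// Cross-validated exhaustive scan.
// geno: n x m codes 0..2; combos: order x ncomb (0-based column indices);
// fold: 1..L per sample; cellM: n x J per-cell counting family; classM:
// n x J class-size family.  Returns ncomb x L training and testing scores.
// [[Rcpp::export]]
List cpp_cv_search(const IntegerMatrix& geno, const IntegerMatrix& combos,
                   const IntegerVector& fold, int L,
                   const NumericMatrix& cellM, const NumericMatrix& classM,
                   int scoreType) {
    const int n = geno.nrow();
    const int order = combos.nrow();
    const int ncomb = combos.ncol();
    const int J = cellM.ncol();
    const int ncell = ipow3(order);

    std::vector<double> classF(L * J, 0.0), classTot(J, 0.0);
    for (int s = 0; s < n; ++s) {
        int l = fold[s] - 1;
        for (int j = 0; j < J; ++j) {
            double v = classM(s, j);
            classF[l * J + j] += v;
            classTot[j] += v;
        }
    }

    NumericMatrix train(ncomb, L), test(ncomb, L);
    std::vector<int> cell(n);
    std::vector<double> cntF((size_t)L * ncell * J), tot(ncell * J);
    std::vector<int> nF(L * ncell), nTot(ncell);
    std::vector<double> trainCnt(ncell * J), testCnt(ncell * J);
    std::vector<double> denomTrain(J), denomTest(J);
    std::vector<int> labels(ncell);

    for (int c = 0; c < ncomb; ++c) {
        for (int s = 0; s < n; ++s) {
            int id = 0, p3 = 1;
            for (int t = 0; t < order; ++t) {
                id += geno(s, combos(t, c)) * p3;
                p3 *= 3;
            }
            cell[s] = id;
        }
        std::fill(cntF.begin(), cntF.end(), 0.0);
        std::fill(nF.begin(), nF.end(), 0);
        for (int s = 0; s < n; ++s) {
            int l = fold[s] - 1;
            size_t base = ((size_t)l * ncell + cell[s]) * J;
            for (int j = 0; j < J; ++j) cntF[base + j] += cellM(s, j);
            nF[l * ncell + cell[s]]++;
        }
        std::fill(tot.begin(), tot.end(), 0.0);
        std::fill(nTot.begin(), nTot.end(), 0);
        for (int l = 0; l < L; ++l)
            for (int i = 0; i < ncell; ++i) {
                nTot[i] += nF[l * ncell + i];
                for (int j = 0; j < J; ++j)
                    tot[i * J + j] += cntF[((size_t)l * ncell + i) * J + j];
            }
        for (int l = 0; l < L; ++l) {
            for (int j = 0; j < J; ++j) {
                denomTrain[j] = classTot[j] - classF[l * J + j];
                denomTest[j] = classF[l * J + j];
            }
            for (int i = 0; i < ncell; ++i) {
                int nTr = nTot[i] - nF[l * ncell + i];
                for (int j = 0; j < J; ++j) {
                    trainCnt[i * J + j] =
                        tot[i * J + j] - cntF[((size_t)l * ncell + i) * J + j];
                    testCnt[i * J + j] = cntF[((size_t)l * ncell + i) * J + j];
                }
                labels[i] = (nTr == 0)
                    ? -1
                    : argmax_ratio(&trainCnt[i * J], denomTrain.data(), J);
            }
            train(c, l) = score_cells(trainCnt, denomTrain.data(), labels,
                                      ncell, J, scoreType);
            test(c, l) = score_cells(testCnt, denomTest.data(), labels,
                                     ncell, J, scoreType);
        }
    }
    return List::create(_["train"] = train, _["test"] = test);
}

// Full-data training scores under trait permutations.
// perms: n x P matrix of 1-based sample indices; column p gives the permuted
// trait row used for sample s.  Genotypes (and hence cell occupancy) are
// fixed; class sizes are permutation-invariant.  Returns ncomb x P scores.
// [[Rcpp::export]]
NumericMatrix cpp_perm_scores(const IntegerMatrix& geno,
                              const IntegerMatrix& combos,
                              const NumericMatrix& cellM,
                              const NumericMatrix& classM,
                              const IntegerMatrix& perms, int scoreType) {
    const int n = geno.nrow();
    const int order = combos.nrow();
    const int ncomb = combos.ncol();
    const int J = cellM.ncol();
    const int ncell = ipow3(order);
    const int P = perms.ncol();

    std::vector<double> classTot(J, 0.0);
    for (int s = 0; s < n; ++s)
        for (int j = 0; j < J; ++j) classTot[j] += classM(s, j);

    std::vector<int> cells((size_t)ncomb * n);
    std::vector<int> cellN((size_t)ncomb * ncell, 0);
    for (int c = 0; c < ncomb; ++c) {
        for (int s = 0; s < n; ++s) {
            int id = 0, p3 = 1;
            for (int t = 0; t < order; ++t) {
                id += geno(s, combos(t, c)) * p3;
                p3 *= 3;
            }
            cells[(size_t)c * n + s] = id;
            cellN[(size_t)c * ncell + id]++;
        }
    }

    NumericMatrix out(ncomb, P);
    std::vector<double> cnt(ncell * J);
    std::vector<int> labels(ncell);
    // row-major copy of the permuted counting family, rebuilt per
    // permutation so the per-combo accumulation streams contiguously
    std::vector<double> permM((size_t)n * J);
    for (int p = 0; p < P; ++p) {
        for (int s = 0; s < n; ++s) {
            int r = perms(s, p) - 1;
            for (int j = 0; j < J; ++j) permM[(size_t)s * J + j] = cellM(r, j);
        }
        for (int c = 0; c < ncomb; ++c) {
            std::fill(cnt.begin(), cnt.end(), 0.0);
            const int* cl = &cells[(size_t)c * n];
            const double* pm = permM.data();
            if (J == 3) {
                for (int s = 0; s < n; ++s) {
                    double* dst = &cnt[cl[s] * 3];
                    const double* src = pm + (size_t)s * 3;
                    dst[0] += src[0];
                    dst[1] += src[1];
                    dst[2] += src[2];
                }
            } else {
                for (int s = 0; s < n; ++s) {
                    double* dst = &cnt[cl[s] * J];
                    const double* src = pm + (size_t)s * J;
                    for (int j = 0; j < J; ++j) dst[j] += src[j];
                }
            }
            const int* cN = &cellN[(size_t)c * ncell];
            for (int i = 0; i < ncell; ++i)
                labels[i] = (cN[i] == 0)
                    ? -1
                    : argmax_ratio(&cnt[i * J], classTot.data(), J);
            out(c, p) = score_cells(cnt, classTot.data(), labels, ncell, J,
                                    scoreType);
        }
        if (p % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}
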