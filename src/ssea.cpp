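#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted KS running-sum walk over samples already in rank order
// (descending expression). member[i] marks sample-set membership at rank i.
// Member steps add vp[i] / sum(member vp); non-member steps subtract
// 1/(N - k). Returns the signed running-sum value of maximal absolute
// deviation (first occurrence). If all member weights are zero the walk
// falls back to unweighted increments 1/k (tie/zero rule).
static double es_walk(const std::vector<double>& vp,
                      const std::vector<char>& member, int k, int N) {
    double sum_vp = 0.0;
    for (int i = 0; i < N; ++i)
        if (member[i]) sum_vp += vp[i];
    const bool unweighted = (sum_vp <= 0.0);
    const double dec = 1.0 / (double)(N - k);
    double cs = 0.0, best = 0.0, bestabs = 0.0;
    for (int i = 0; i < N; ++i) {
        if (member[i])
            cs += unweighted ? (1.0 / (double)k) : vp[i] / sum_vp;
        else
            cs -= dec;
        double a = std::fabs(cs);
        if (a > bestabs) { bestabs = a; best = cs; }
    }
    return best;
}

// Enrichment scores for every transcript (row of vals) against the observed
// sample set and a bank of permuted sets. Samples are ranked per transcript
// by expression descending, ties broken by tiekey descending. When perm has
// rows it supplies the permuted sets (shared across transcripts); when it is
// empty and nperm > 0, each transcript draws its own nperm independent
// uniform subsets of size |obs| from R's RNG stream.
// Returns a G x (nperm + 1) matrix, observed ES in column 0.
// [[Rcpp::export(name = ".ssea_es_matrix")]]
NumericMatrix ssea_es_matrix(NumericMatrix vals, NumericVector tiekey,
                             LogicalMatrix perm, LogicalVector obs,
                             double p, int nperm = -1) {
    const int G = vals.nrow(), N = vals.ncol();
    const bool shared = (nperm < 0);
    if (shared) nperm = perm.nrow();
    if (tiekey.size() != N || obs.size() != N ||
        (shared && perm.ncol() != N))
        stop("dimension mismatch in ssea_es_matrix");
    int k = 0;
    for (int j = 0; j < N; ++j) if (obs[j]) ++k;
    if (k < 1 || k >= N) stop("sample set must be a non-empty proper subset");

    NumericMatrix out(G, nperm + 1);
    std::vector<int> ord(N), pos(N), draw(N);
    std::vector<double> vp(N);
    std::vector<char> mem(N);
    GetRNGstate();

    for (int g = 0; g < G; ++g) {
        for (int j = 0; j < N; ++j) ord[j] = j;
        NumericMatrix::Row row = vals(g, _);
        std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
            if (row[a] != row[b]) return row[a] > row[b];
            return tiekey[a] > tiekey[b];
        });
        // pos[sample] = rank of that sample in the walk
        for (int j = 0; j < N; ++j) pos[ord[j]] = j;
        for (int j = 0; j < N; ++j) {
            double v = row[ord[j]];
            vp[j] = (p == 1.0) ? v : std::pow(v, p);
        }
        for (int j = 0; j < N; ++j) mem[j] = obs[ord[j]] ? 1 : 0;
        out(g, 0) = es_walk(vp, mem, k, N);
        for (int q = 0; q < nperm; ++q) {
            if (shared) {
                int kq = 0;
                for (int j = 0; j < N; ++j) {
                    mem[j] = perm(q, ord[j]) ? 1 : 0;
                    kq += mem[j];
                }
                out(g, q + 1) = es_walk(vp, mem, kq, N);
            } else {
                // partial Fisher-Yates: k distinct samples uniform at random
                for (int j = 0; j < N; ++j) draw[j] = j;
                std::fill(mem.begin(), mem.end(), 0);
                for (int j = 0; j < k; ++j) {
                    int r = j + (int)(unif_rand() * (N - j));
                    if (r >= N) r = N - 1;
                    std::swap(draw[j], draw[r]);
                    mem[pos[draw[j]]] = 1;
                }
                out(g, q + 1) = es_walk(vp, mem, k, N);
            }
        }
    }
    PutRNGstate();
    return out;
}
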