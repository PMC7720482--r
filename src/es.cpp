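#include <Rcpp.h>
using namespace Rcpp;

// Weighted KS running-sum enrichment scores for a batch of member index sets.
//
// stats:    ranking statistics in ranked (descending) order, length N
// idx:      n_sets x k integer matrix of 1-based member positions (unsorted ok)
// exponent: GSEA weight exponent; 0 gives the classical KS statistic
//
// A hit at position i adds |stats_i|^exponent / NR (NR = sum over hits); a
// miss adds -1/(N - k). If every hit statistic is zero (NR == 0) hits
// contribute uniformly 1/k. The score is the running-sum value of maximal
// absolute magnitude, the positive extreme winning an exact tie. The walk is
// evaluated position by position with sequential double-precision additions
// so results are bit-identical to a naive R loop over the same increments.
// [[Rcpp::export]]
NumericVector cpp_es_batch(NumericVector stats, IntegerMatrix idx, double exponent) {
    const int N = stats.size();
    const int n_sets = idx.nrow();
    const int k = idx.ncol();
    if (k <= 0 || k >= N)
        stop("member set size must be in [1, N - 1]");

    std::vector<double> w(N);
    for (int i = 0; i < N; ++i)
        w[i] = std::pow(std::fabs(stats[i]), exponent);

    std::vector<double> hit(N, -1.0); // hit increment at position, -1 = miss
    NumericVector out(n_sets);

    for (int s = 0; s < n_sets; ++s) {
        for (int j = 0; j < k; ++j) {
            int pos = idx(s, j) - 1;
            if (pos < 0 || pos >= N)
                stop("member index out of range");
            if (hit[pos] >= 0.0)
                stop("duplicate member index within one set");
            hit[pos] = 0.0;
        }
        // NR summed in ranked-position order: bit-identical to the R walk
        double NR = 0.0;
        for (int i = 0; i < N; ++i)
            if (hit[i] == 0.0)
                NR += w[i];

        const double miss_inc = 1.0 / (double)(N - k);
        double cum = 0.0, max_p = 0.0, min_p = 0.0;
        for (int i = 0; i < N; ++i) {
            if (hit[i] == 0.0)
                cum += (NR > 0.0) ? (w[i] / NR) : (1.0 / (double)k);
            else
                cum -= miss_inc;
            if (cum > max_p) max_p = cum;
            if (cum < min_p) min_p = cum;
        }
        out[s] = (max_p >= -min_p) ? max_p : min_p;

        for (int j = 0; j < k; ++j)
            hit[idx(s, j) - 1] = -1.0;
    }
    return out;
}
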