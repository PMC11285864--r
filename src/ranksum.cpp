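#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact two-sided p-value of the (midrank x 2, hence integer) rank-sum
// permutation distribution: counts k-subsets of the pooled scaled ranks by
// a dynamic programme over (subset size, sum). Counts are doubles; they are
// exact integers well past any pooled size this package enumerates, and the
// p-value is a ratio of partial sums so late rounding is immaterial.
//
// ranks2: scaled ranks (2 x midrank) of all N pooled observations
// m:      size of the enumerated group (caller passes the smaller group)
// sum_x2: observed scaled rank sum of that group
// [[Rcpp::export]]
double exact_ranksum_p_cpp(IntegerVector ranks2, int m, double sum_x2) {
    const int N = ranks2.size();
    long S = 0;
    for (int i = 0; i < N; ++i) S += ranks2[i];
    std::vector< std::vector<double> > dp(
        m + 1, std::vector<double>(S + 1, 0.0));
    dp[0][0] = 1.0;
    for (int idx = 0; idx < N; ++idx) {
        const int r = ranks2[idx];
        // descending k: dp[k+1] reads dp[k] values not yet holding this item
        const int ktop = std::min(idx, m - 1);
        for (int k = ktop; k >= 0; --k) {
            const std::vector<double>& src = dp[k];
            std::vector<double>& dst = dp[k + 1];
            for (long s = S - r; s >= 0; --s)
                if (src[s] != 0.0) dst[s + r] += src[s];
        }
    }
    const double mu = static_cast<double>(m) * S / N;
    const double d = std::fabs(sum_x2 - mu);
    double total = 0.0, tail = 0.0;
    for (long s = 0; s <= S; ++s) {
        const double c = dp[m][s];
        if (c != 0.0) {
            total += c;
            if (std::fabs(static_cast<double>(s) - mu) >= d - 1e-9) tail += c;
        }
    }
    return tail / total;
}
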