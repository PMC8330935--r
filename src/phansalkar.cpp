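#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mirror (symmetric, edge-inclusive) index reflection: -1 -> 0, n -> n-1.
// A single reflection suffices because the window radius is validated to be
// smaller than the image side.
static inline int reflect(int i, int n) {
    if (i < 0) return -1 - i;
    if (i >= n) return 2 * n - 1 - i;
    return i;
}

// Per-pixel Phansalkar threshold map over a digital disk window.
//
// t = mu * (1 + p * exp(-q * mu) + k * (sigma / r - 1))
//
// sigma is the population (divide-by-N) standard deviation of the window.
// The accumulation order (dx outer, dy inner, both from -radius to +radius)
// and the statement-by-statement arithmetic are part of the contract: the
// pure-R reference implementation reproduces this map bit-for-bit.
// [[Rcpp::export(name = ".phansalkarMap")]]
NumericMatrix phansalkar_map_cpp(NumericMatrix img, int radius,
                                 double k, double r, double p, double q) {
    int n = img.nrow();
    int m = img.ncol();
    if (radius < 1)
        stop("radius must be >= 1");
    if (radius >= n || radius >= m)
        stop("radius larger than image half-width");

    // Precompute disk offsets in fixed order.
    std::vector<int> offx, offy;
    int r2 = radius * radius;
    for (int dx = -radius; dx <= radius; ++dx)
        for (int dy = -radius; dy <= radius; ++dy)
            if (dx * dx + dy * dy <= r2) {
                offx.push_back(dx);
                offy.push_back(dy);
            }
    int nw = (int) offx.size();

    NumericMatrix out(n, m);
    for (int j = 0; j < m; ++j) {
        for (int i = 0; i < n; ++i) {
            double s = 0.0;
            double sq = 0.0;
            for (int w = 0; w < nw; ++w) {
                int ii = reflect(i + offy[w], n);
                int jj = reflect(j + offx[w], m);
                double v = img(ii, jj);
                s = s + v;
                sq = sq + v * v;
            }
            double mu = s / nw;
            double ex2 = sq / nw;
            double mumu = mu * mu;
            double var = ex2 - mumu;
            if (var < 0.0) var = 0.0;
            double sg = std::sqrt(var);
            double pe = p * std::exp(-q * mu);
            double kk = k * (sg / r - 1.0);
            double t = mu * (1.0 + pe + kk);
            out(i, j) = t;
        }
    }
    return out;
}
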