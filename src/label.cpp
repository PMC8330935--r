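#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a logical mask (ImageJ particle
// behaviour: pixels touching diagonally belong to one particle). Pixels
// where valid is FALSE never join a component. Labels are assigned in
// column-major scan order starting at 1; 0 marks background.
// [[Rcpp::export(name = ".labelComponents")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, LogicalMatrix valid) {
    int n = mask.nrow();
    int m = mask.ncol();
    if (valid.nrow() != n || valid.ncol() != m)
        stop("mask and validity must share one grid");

    IntegerMatrix lab(n, m);
    std::vector<int> stack;
    int next = 0;

    for (int j = 0; j < m; ++j) {
        for (int i = 0; i < n; ++i) {
            if (!mask(i, j) || !valid(i, j) || lab(i, j) != 0) continue;
            ++next;
            lab(i, j) = next;
            stack.clear();
            stack.push_back(j * n + i);
            while (!stack.empty()) {
                int idx = stack.back();
                stack.pop_back();
                int ci = idx % n;
                int cj = idx / n;
                for (int dj = -1; dj <= 1; ++dj) {
                    for (int di = -1; di <= 1; ++di) {
                        if (di == 0 && dj == 0) continue;
                        int ii = ci + di;
                        int jj = cj + dj;
                        if (ii < 0 || ii >= n || jj < 0 || jj >= m) continue;
                        if (mask(ii, jj) && valid(ii, jj) &&
                            lab(ii, jj) == 0) {
                            lab(ii, jj) = next;
                            stack.push_back(jj * n + ii);
                        }
                    }
                }
            }
        }
    }
    return lab;
}
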