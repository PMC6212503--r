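#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh global alignment on a precomputed column-score matrix.
// score[i][j] is the score for pairing position i of A with position j of B
// (1-based positions map to 0-based matrix indices). A gap run of length k
// costs gapOpen + k * gapExtend. Tie-break during traceback prefers the
// diagonal move, then up (consume A / gap in B), then left (gap in A).
//
// Returns the optimal score and the alignment path as two integer vectors of
// equal length; entry 0 denotes a gap, otherwise the (1-based) position of
// the consumed residue.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_dp")]]
List nw_dp(NumericMatrix score, double gapOpen, double gapExtend) {
    const int n = score.nrow();   // length of A
    const int m = score.ncol();   // length of B

    // M: i aligned to j; X: gap in B (A consumed); Y: gap in A (B consumed)
    std::vector<double> M((n + 1) * (m + 1), NEG_INF);
    std::vector<double> X((n + 1) * (m + 1), NEG_INF);
    std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
    const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

    M[IDX(0, 0)] = 0.0;
    for (int i = 1; i <= n; ++i) X[IDX(i, 0)] = -(gapOpen + i * gapExtend);
    for (int j = 1; j <= m; ++j) Y[IDX(0, j)] = -(gapOpen + j * gapExtend);

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double s = score(i - 1, j - 1);
            double d = M[IDX(i - 1, j - 1)];
            if (X[IDX(i - 1, j - 1)] > d) d = X[IDX(i - 1, j - 1)];
            if (Y[IDX(i - 1, j - 1)] > d) d = Y[IDX(i - 1, j - 1)];
            M[IDX(i, j)] = (d == NEG_INF) ? NEG_INF : d + s;

            double xo = M[IDX(i - 1, j)] - (gapOpen + gapExtend);
            double xe = X[IDX(i - 1, j)] - gapExtend;
            double yc = Y[IDX(i - 1, j)] - (gapOpen + gapExtend);
            if (yc > xo) xo = yc;  // closing one gap type and opening the other
            X[IDX(i, j)] = (xo > xe) ? xo : xe;

            double yo = M[IDX(i, j - 1)] - (gapOpen + gapExtend);
            double ye = Y[IDX(i, j - 1)] - gapExtend;
            double xc = X[IDX(i, j - 1)] - (gapOpen + gapExtend);
            if (xc > yo) yo = xc;
            Y[IDX(i, j)] = (yo > ye) ? yo : ye;
        }
    }

    // final state: prefer M, then X, then Y on ties
    double best = M[IDX(n, m)];
    int state = 0;
    if (X[IDX(n, m)] > best) { best = X[IDX(n, m)]; state = 1; }
    if (Y[IDX(n, m)] > best) { best = Y[IDX(n, m)]; state = 2; }

    // traceback
    std::vector<int> pa, pb;
    int i = n, j = m;
    const double EPS = 1e-9;
    while (i > 0 || j > 0) {
        if (state == 0) {
            if (i == 0 || j == 0) stop("internal error: bad traceback (M)");
            double cur = M[IDX(i, j)];
            double s = score(i - 1, j - 1);
            pa.push_back(i); pb.push_back(j);
            // which predecessor produced cur? prefer M, then X, then Y
            if (std::abs(M[IDX(i - 1, j - 1)] + s - cur) < EPS) state = 0;
            else if (std::abs(X[IDX(i - 1, j - 1)] + s - cur) < EPS) state = 1;
            else state = 2;
            --i; --j;
        } else if (state == 1) {
            if (i == 0) stop("internal error: bad traceback (X)");
            double cur = X[IDX(i, j)];
            pa.push_back(i); pb.push_back(0);
            if (std::abs(M[IDX(i - 1, j)] - (gapOpen + gapExtend) - cur) < EPS) state = 0;
            else if (std::abs(X[IDX(i - 1, j)] - gapExtend - cur) < EPS) state = 1;
            else state = 2;
            --i;
        } else {
            if (j == 0) stop("internal error: bad traceback (Y)");
            double cur = Y[IDX(i, j)];
            pa.push_back(0); pb.push_back(j);
            if (std::abs(M[IDX(i, j - 1)] - (gapOpen + gapExtend) - cur) < EPS) state = 0;
            else if (std::abs(Y[IDX(i, j - 1)] - gapExtend - cur) < EPS) state = 2;
            else state = 1;
            --j;
        }
    }
#undef IDX

    const int L = (int) pa.size();
    IntegerVector ra(L), rb(L);
    for (int k = 0; k < L; ++k) {  // reverse
        ra[k] = pa[L - 1 - k];
        rb[k] = pb[L - 1 - k];
    }
    return List::create(_["score"] = best, _["a"] = ra, _["b"] = rb);
}
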