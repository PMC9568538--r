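#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise Manhattan (city-block) distances between the rows of A and B.
// Returns an nrow(A) x nrow(B) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_manhattan_dist(NumericMatrix A, NumericMatrix B) {
    const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
    if (B.ncol() != d) stop("column dimensions differ");
    NumericMatrix out(na, nb);
    for (int j = 0; j < nb; ++j) {
        for (int i = 0; i < na; ++i) {
            double s = 0.0;
            for (int l = 0; l < d; ++l)
                s += std::fabs(A(i, l) - B(j, l));
            out(i, j) = s;
        }
    }
    return out;
}

// Objective and gradient of the feature-selection NCA criterion.
//
// F(w) = sum_j p_j - lambda * sum_l w_l^2,  where
//   p_j   = sum_{i != j, y_i = y_j} p_ij,
//   p_ij  = exp(-d_w(x_j, x_i)/sigma) / sum_{i != j} exp(-d_w(x_j, x_i)/sigma),
//   d_w(a, b) = sum_l w_l^2 * |a_l - b_l|   (weighted city-block distance).
//
// dF/dw_l = (2 w_l / sigma) * sum_j sum_{i != j} p_ij (p_j - [y_i = y_j]) |x_jl - x_il|
//           - 2 lambda w_l
//
// Softmax terms are shifted by the per-sample minimum distance for numerical
// stability. X is N x D (rows = samples), y integer class codes.
// [[Rcpp::export]]
List cpp_nca_objgrad(NumericMatrix X, IntegerVector y, NumericVector w,
                     double sigma, double lambda) {
    const int n = X.nrow(), d = X.ncol();
    if (y.size() != n) stop("length(y) != nrow(X)");
    if (w.size() != d) stop("length(w) != ncol(X)");
    std::vector<double> w2(d);
    double wss = 0.0;
    for (int l = 0; l < d; ++l) { w2[l] = w[l] * w[l]; wss += w2[l]; }

    std::vector<double> dist(n), p(n);
    std::vector<double> acc(d, 0.0);
    double obj = 0.0;

    for (int j = 0; j < n; ++j) {
        double dmin = R_PosInf;
        for (int i = 0; i < n; ++i) {
            if (i == j) { dist[i] = R_PosInf; continue; }
            double s = 0.0;
            for (int l = 0; l < d; ++l)
                s += w2[l] * std::fabs(X(j, l) - X(i, l));
            dist[i] = s;
            if (s < dmin) dmin = s;
        }
        double z = 0.0;
        for (int i = 0; i < n; ++i) {
            p[i] = (i == j) ? 0.0 : std::exp(-(dist[i] - dmin) / sigma);
            z += p[i];
        }
        double pj = 0.0;
        for (int i = 0; i < n; ++i) {
            p[i] /= z;
            if (i != j && y[i] == y[j]) pj += p[i];
        }
        obj += pj;
        for (int i = 0; i < n; ++i) {
            if (i == j) continue;
            double coef = p[i] * (pj - ((y[i] == y[j]) ? 1.0 : 0.0));
            if (coef == 0.0) continue;
            for (int l = 0; l < d; ++l)
                acc[l] += coef * std::fabs(X(j, l) - X(i, l));
        }
    }
    obj -= lambda * wss;

    NumericVector grad(d);
    for (int l = 0; l < d; ++l)
        grad[l] = (2.0 * w[l] / sigma) * acc[l] - 2.0 * lambda * w[l];
    return List::create(_["objective"] = obj, _["gradient"] = grad);
}
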