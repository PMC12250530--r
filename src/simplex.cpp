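// Dense two-phase primal simplex for the small steady-state LPs used by
// fba()/fva()/ko_effect_matrix():
//
//     optimise c'v   s.t.  S v = 0,  lb <= v <= ub
//
// The problem is shifted to x = v - lb >= 0; finite upper bounds become
// explicit slack rows (x_j + s_j = ub_j - lb_j), equality rows receive
// artificial variables for phase 1. Phase 1 is solved once per bound set and
// the resulting feasible tableau is re-costed for each objective, so a full
// FVA sweep pays the feasibility work only once (the "shared factorisation"
// reading of FastMM-style sequential LPs). Dantzig pricing with a Bland's
// rule fallback guards against cycling. All tableaus are tiny (toy-network
// scale), so a dense full tableau is the robust choice.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double PIV_TOL = 1e-9;

// Full-tableau iteration, minimisation. T has M constraint rows plus the
// reduced-cost row at index M; column N is the rhs with T(M, N) = -z.
// Columns with index >= allowed never enter the basis (artificials).
// Returns 0 optimal, 2 unbounded, 3 iteration limit.
int simplex_iterate(arma::mat &T, std::vector<int> &basis, int allowed,
                    int maxit)
{
    const int M = static_cast<int>(T.n_rows) - 1;
    const int N = static_cast<int>(T.n_cols) - 1;
    bool bland = false;
    int stall = 0;
    double last = -T(M, N);

    for (int it = 0; it < maxit; ++it) {
        int j = -1;
        if (!bland) {
            double best = -PIV_TOL;
            for (int k = 0; k < allowed; ++k)
                if (T(M, k) < best) { best = T(M, k); j = k; }
        } else {
            for (int k = 0; k < allowed; ++k)
                if (T(M, k) < -PIV_TOL) { j = k; break; }
        }
        if (j < 0) return 0;

        int piv = -1;
        double minratio = std::numeric_limits<double>::infinity();
        for (int i = 0; i < M; ++i) {
            double a = T(i, j);
            if (a > PIV_TOL) {
                double ratio = T(i, N) / a;
                if (piv < 0 || ratio < minratio - 1e-12 ||
                    (ratio <= minratio + 1e-12 && basis[i] < basis[piv])) {
                    minratio = ratio;
                    piv = i;
                }
            }
        }
        if (piv < 0) return 2;

        T.row(piv) /= T(piv, j);
        for (int i = 0; i <= M; ++i) {
            if (i == piv) continue;
            double f = T(i, j);
            if (f != 0.0) T.row(i) -= f * T.row(piv);
        }
        basis[piv] = j;

        double z = -T(M, N);
        if (z < last - 1e-12) { last = z; stall = 0; }
        else if (++stall > 2 * M + 20) bland = true;
    }
    return 3;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
List lp_solve_cpp(const arma::mat &S, const arma::vec &lb, const arma::vec &ub,
                  const arma::mat &objectives, const IntegerVector &senses,
                  bool want_solutions)
{
    const int m1 = S.n_rows;
    const int n = S.n_cols;
    if (!lb.is_finite())
        stop("all lower bounds must be finite");
    for (int j = 0; j < n; ++j)
        if (ub[j] < lb[j] - 1e-12)
            stop("lower bound exceeds upper bound for variable %d", j + 1);

    // slack rows only for finite upper bounds
    std::vector<int> ubrow;
    for (int j = 0; j < n; ++j)
        if (std::isfinite(ub[j])) ubrow.push_back(j);
    const int m2 = static_cast<int>(ubrow.size());
    const int M = m1 + m2;
    const int N = n + m2 + m1;          // structural + slacks + artificials
    const int nreal = n + m2;           // columns allowed to enter
    const int maxit = 200 * (M + N) + 1000;

    arma::vec b0 = -S * lb;
    arma::mat T(M + 1, N + 1, arma::fill::zeros);
    std::vector<int> basis(M);

    double bmax = 0.0;
    for (int i = 0; i < m1; ++i) {
        double s = (b0[i] < 0.0) ? -1.0 : 1.0;
        for (int j = 0; j < n; ++j) T(i, j) = s * S(i, j);
        T(i, N) = s * b0[i];
        T(i, n + m2 + i) = 1.0;
        basis[i] = n + m2 + i;
        bmax = std::max(bmax, T(i, N));
    }
    for (int k = 0; k < m2; ++k) {
        int j = ubrow[k];
        T(m1 + k, j) = 1.0;
        T(m1 + k, n + k) = 1.0;
        T(m1 + k, N) = std::max(ub[j] - lb[j], 0.0);
        basis[m1 + k] = n + k;
    }

    // phase-1 reduced costs: minimise sum of artificials
    for (int i = 0; i < m1; ++i) T.row(M) -= T.row(i);
    for (int i = 0; i < m1; ++i) T(M, n + m2 + i) += 1.0;

    int st1 = simplex_iterate(T, basis, nreal, maxit);
    double z1 = -T(M, N);
    bool feasible = (st1 == 0) && (z1 <= 1e-7 * (1.0 + bmax));

    const int K = objectives.n_rows;
    IntegerVector status(K);
    NumericVector value(K);
    NumericMatrix sols;
    if (want_solutions) sols = NumericMatrix(n, K);

    if (!feasible) {
        for (int q = 0; q < K; ++q) {
            status[q] = 1;
            value[q] = NA_REAL;
        }
        return List::create(_["feasible"] = false, _["status"] = status,
                            _["value"] = value,
                            _["solution"] = want_solutions ? (SEXP)sols
                                                           : R_NilValue);
    }

    // pivot basic artificials out where possible (redundant rows stay inert)
    for (int i = 0; i < M; ++i) {
        if (basis[i] < nreal) continue;
        int j = -1;
        for (int k = 0; k < nreal; ++k)
            if (std::abs(T(i, k)) > 1e-7) { j = k; break; }
        if (j < 0) continue;
        T.row(i) /= T(i, j);
        for (int r = 0; r <= M; ++r) {
            if (r == i) continue;
            double f = T(r, j);
            if (f != 0.0) T.row(r) -= f * T.row(i);
        }
        basis[i] = j;
    }

    for (int q = 0; q < K; ++q) {
        arma::mat T2 = T;
        std::vector<int> basis2 = basis;
        const bool maximize = senses[q] > 0;

        arma::rowvec cost(nreal, arma::fill::zeros);
        for (int j = 0; j < n; ++j)
            cost[j] = maximize ? -objectives(q, j) : objectives(q, j);

        // re-cost the feasible tableau for this objective
        T2.row(M).zeros();
        for (int k = 0; k < nreal; ++k) T2(M, k) = cost[k];
        for (int i = 0; i < M; ++i) {
            int b = basis2[i];
            double cb = (b < nreal) ? cost[b] : 0.0;
            if (cb != 0.0) T2.row(M) -= cb * T2.row(i);
        }

        int st = simplex_iterate(T2, basis2, nreal, maxit);
        status[q] = st;
        if (st == 0) {
            double shift = 0.0;
            for (int j = 0; j < n; ++j) shift += objectives(q, j) * lb[j];
            double z2 = -T2(M, N);
            value[q] = (maximize ? -z2 : z2) + shift;
        } else {
            value[q] = (st == 2)
                ? (maximize ? R_PosInf : R_NegInf)
                : NA_REAL;
        }
        if (want_solutions) {
            for (int j = 0; j < n; ++j) sols(j, q) = lb[j];
            if (st == 0)
                for (int i = 0; i < M; ++i)
                    if (basis2[i] < n) sols(basis2[i], q) += T2(i, N);
        }
    }

    return List::create(_["feasible"] = true, _["status"] = status,
                        _["value"] = value,
                        _["solution"] = want_solutions ? (SEXP)sols
                                                       : R_NilValue);
}
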