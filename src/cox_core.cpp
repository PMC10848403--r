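#include <Rcpp.h>
using namespace Rcpp;

// Counting-process Cox partial likelihood with optional covariate-by-time
// columns.  Rows are (start, stop] intervals; the risk set at an event time
// t is {i : start_i < t <= stop_i}.  Fixed covariates live in Xf; each
// column j of Xt contributes a term Xt(i,j) * g_j(t), with g_j evaluated
// at the unique event times and passed in as gvals (m x pt).  Efron or
// Breslow handling of event-time ties across subjects.
//
// Risk-set membership depends only on the interval layout, so it is
// resolved once per design (cox_risk_index) and the per-event index
// vectors are reused by every likelihood, derivative and residual pass.

// [[Rcpp::export]]
List cox_risk_index(NumericVector start, NumericVector stop,
                    IntegerVector status, NumericVector etimes) {
    const int n = start.size(), m = etimes.size();
    List ridx(m), didx(m);
    for (int k = 0; k < m; ++k) {
        const double tk = etimes[k];
        std::vector<int> r, d;
        for (int i = 0; i < n; ++i) {
            if (start[i] < tk && tk <= stop[i]) {
                r.push_back(i);
                if (status[i] == 1 && stop[i] == tk) d.push_back(i);
            }
        }
        ridx[k] = wrap(r);
        didx[k] = wrap(d);
    }
    return List::create(_["risk"] = ridx, _["death"] = didx);
}

// design row i evaluated at event-time index k
static inline void xrow(const NumericMatrix& Xf, const NumericMatrix& Xt,
                        const NumericMatrix& gvals, int i, int k, double* x) {
    const int pf = Xf.ncol(), pt = Xt.ncol();
    for (int j = 0; j < pf; ++j) x[j] = Xf(i, j);
    for (int j = 0; j < pt; ++j) x[pf + j] = Xt(i, j) * gvals(k, j);
}

// [[Rcpp::export]]
List cox_core(NumericMatrix Xf, NumericMatrix Xt, NumericMatrix gvals,
              List ridx, List didx,
              NumericVector beta, bool efron, int deriv) {
    const int m = ridx.size();
    const int pf = Xf.ncol(), pt = Xt.ncol(), p = pf + pt;
    const int n = Xf.nrow();

    double loglik = 0.0;
    NumericVector grad(p);
    NumericMatrix info(p, p);

    // per-row linear predictor pieces: eta_i(t) = etaf_i + etat_i * g(t)
    // (only valid when pt <= 1; with several td columns fall back to xrow)
    std::vector<double> etaf(n, 0.0), etat(n, 0.0);
    for (int i = 0; i < n; ++i) {
        double e = 0.0;
        for (int j = 0; j < pf; ++j) e += Xf(i, j) * beta[j];
        etaf[i] = e;
        e = 0.0;
        for (int j = 0; j < pt; ++j) e += Xt(i, j) * beta[pf + j];
        etat[i] = e;
    }
    const bool simple_td = (pt <= 1);

    std::vector<double> x(p), S1(p), S1d(p), sumxd(p), xbar(p);
    std::vector<double> S2(p * p), S2d(p * p);

    for (int k = 0; k < m; ++k) {
        IntegerVector rk = ridx[k], dk = didx[k];
        const int d = dk.size();
        if (d == 0) continue;
        double S0 = 0.0, S0d = 0.0, sum_eta_d = 0.0;
        std::fill(S1.begin(), S1.end(), 0.0);
        std::fill(S1d.begin(), S1d.end(), 0.0);
        std::fill(sumxd.begin(), sumxd.end(), 0.0);
        if (deriv >= 2) {
            std::fill(S2.begin(), S2.end(), 0.0);
            std::fill(S2d.begin(), S2d.end(), 0.0);
        }
        const double gk = (pt == 1) ? gvals(k, 0) : 0.0;

        int dpos = 0;
        for (int ii = 0; ii < rk.size(); ++ii) {
            const int i = rk[ii];
            double eta;
            if (simple_td) {
                eta = etaf[i] + etat[i] * gk;
                if (deriv >= 1) {
                    for (int j = 0; j < pf; ++j) x[j] = Xf(i, j);
                    if (pt == 1) x[pf] = Xt(i, 0) * gk;
                }
            } else {
                xrow(Xf, Xt, gvals, i, k, x.data());
                eta = 0.0;
                for (int j = 0; j < p; ++j) eta += x[j] * beta[j];
            }
            const double w = std::exp(eta);
            const bool isdead = (dpos < d && dk[dpos] == i);
            S0 += w;
            if (deriv >= 1) {
                for (int j = 0; j < p; ++j) S1[j] += w * x[j];
                if (deriv >= 2)
                    for (int a = 0; a < p; ++a)
                        for (int b = a; b < p; ++b)
                            S2[a * p + b] += w * x[a] * x[b];
            }
            if (isdead) {
                ++dpos;
                sum_eta_d += eta;
                S0d += w;
                if (deriv >= 1) {
                    for (int j = 0; j < p; ++j) {
                        sumxd[j] += x[j];
                        S1d[j] += w * x[j];
                    }
                    if (deriv >= 2)
                        for (int a = 0; a < p; ++a)
                            for (int b = a; b < p; ++b)
                                S2d[a * p + b] += w * x[a] * x[b];
                }
            }
        }
        if (S0 <= 0.0) Rcpp::stop("empty risk set at an event time");

        loglik += sum_eta_d;
        for (int l = 0; l < d; ++l) {
            const double f = efron ? (double)l / d : 0.0;
            const double den = S0 - f * S0d;
            loglik -= std::log(den);
            if (deriv >= 1) {
                for (int j = 0; j < p; ++j) {
                    xbar[j] = (S1[j] - f * S1d[j]) / den;
                    grad[j] += (sumxd[j] / d) - xbar[j];
                }
                if (deriv >= 2) {
                    for (int a = 0; a < p; ++a)
                        for (int b = a; b < p; ++b) {
                            const double v =
                                (S2[a * p + b] - f * S2d[a * p + b]) / den -
                                xbar[a] * xbar[b];
                            info(a, b) += v;
                            if (a != b) info(b, a) += v;
                        }
                }
            }
        }
    }

    List out = List::create(_["loglik"] = loglik);
    if (deriv >= 1) out["grad"] = grad;
    if (deriv >= 2) out["info"] = info;
    return out;
}

// Score residuals (one row per interval, summed by cluster in R for the
// sandwich) and Schoenfeld residuals (one row per event).  Evaluated at
// the fitted beta.  Under Efron ties the d tied events at a time are
// spread over d sub-steps with the event mass of earlier sub-steps
// progressively removed; Breslow is the f = 0 special case.
// [[Rcpp::export]]
List cox_resid(NumericMatrix Xf, NumericMatrix Xt, NumericMatrix gvals,
               NumericVector etimes, List ridx, List didx,
               NumericVector beta, bool efron) {
    const int m = ridx.size();
    const int pf = Xf.ncol(), pt = Xt.ncol(), p = pf + pt;
    const int n = Xf.nrow();

    NumericMatrix score(n, p);
    std::vector<double> x(p), S1(p), S1d(p);
    std::vector<double> wts, xs;

    int ndeath_total = 0;
    for (int k = 0; k < m; ++k)
        ndeath_total += ((IntegerVector)didx[k]).size();
    NumericMatrix schoen(ndeath_total, p);
    NumericVector schoen_time(ndeath_total);
    IntegerVector schoen_row(ndeath_total);
    int srow = 0;

    for (int k = 0; k < m; ++k) {
        IntegerVector rk = ridx[k], dk = didx[k];
        const int d = dk.size();
        if (d == 0) continue;
        const int nr = rk.size();
        double S0 = 0.0, S0d = 0.0;
        std::fill(S1.begin(), S1.end(), 0.0);
        std::fill(S1d.begin(), S1d.end(), 0.0);
        wts.assign(nr, 0.0);
        xs.assign((size_t)nr * p, 0.0);

        int dpos = 0;
        std::vector<bool> isdead(nr, false);
        for (int ii = 0; ii < nr; ++ii) {
            const int i = rk[ii];
            xrow(Xf, Xt, gvals, i, k, x.data());
            double eta = 0.0;
            for (int j = 0; j < p; ++j) eta += x[j] * beta[j];
            const double w = std::exp(eta);
            wts[ii] = w;
            for (int j = 0; j < p; ++j) xs[(size_t)ii * p + j] = x[j];
            S0 += w;
            for (int j = 0; j < p; ++j) S1[j] += w * x[j];
            if (dpos < d && dk[dpos] == i) {
                isdead[ii] = true;
                ++dpos;
                S0d += w;
                for (int j = 0; j < p; ++j) S1d[j] += w * x[j];
            }
        }

        std::vector<double> den(d), xbar((size_t)d * p), xbarbar(p, 0.0);
        for (int l = 0; l < d; ++l) {
            const double f = efron ? (double)l / d : 0.0;
            den[l] = S0 - f * S0d;
            for (int j = 0; j < p; ++j) {
                xbar[(size_t)l * p + j] = (S1[j] - f * S1d[j]) / den[l];
                xbarbar[j] += xbar[(size_t)l * p + j] / d;
            }
        }

        for (int ii = 0; ii < nr; ++ii) {
            const int i = rk[ii];
            const double w = wts[ii];
            const double* xi = &xs[(size_t)ii * p];
            for (int l = 0; l < d; ++l) {
                const double f = efron ? (double)l / d : 0.0;
                const double share = isdead[ii] ? (1.0 - f) : 1.0;
                for (int j = 0; j < p; ++j)
                    score(i, j) -=
                        share * w * (xi[j] - xbar[(size_t)l * p + j]) / den[l];
            }
            if (isdead[ii])
                for (int j = 0; j < p; ++j) score(i, j) += xi[j] - xbarbar[j];
        }

        for (int ii = 0; ii < nr; ++ii) {
            if (!isdead[ii]) continue;
            const double* xi = &xs[(size_t)ii * p];
            for (int j = 0; j < p; ++j) schoen(srow, j) = xi[j] - xbarbar[j];
            schoen_time[srow] = etimes[k];
            schoen_row[srow] = rk[ii] + 1;  // 1-based interval row
            ++srow;
        }
    }

    return List::create(_["score"] = score, _["schoenfeld"] = schoen,
                        _["schoenfeld_time"] = schoen_time,
                        _["schoenfeld_row"] = schoen_row);
}
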