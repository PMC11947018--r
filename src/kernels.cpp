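#include <Rcpp.h>
using namespace Rcpp;

static inline double logistic(double x) {
  // stable on both tails
  if (x >= 0.0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Mean over draws s of a_s^2 P_s (1 - P_s) per item, with theta draws paired
// to item-parameter draws by index (the BMI criterion average).
// a, b: S x I matrices of item-parameter draws; theta: length-S ability draws.
// [[Rcpp::export]]
NumericVector cpp_bmi_criterion(NumericMatrix a, NumericMatrix b,
                                NumericVector theta) {
  const int S = a.nrow(), I = a.ncol();
  if (b.nrow() != S || b.ncol() != I || theta.size() != S)
    stop("draw dimensions do not align");
  NumericVector out(I);
  for (int i = 0; i < I; ++i) {
    double acc = 0.0;
    const double *ai = &a(0, i), *bi = &b(0, i);
    for (int s = 0; s < S; ++s) {
      double p = logistic(ai[s] * (theta[s] - bi[s]));
      acc += ai[s] * ai[s] * p * (1.0 - p);
    }
    out[i] = acc / S;
  }
  return out;
}

// Draw-averaged probability of a correct response on a fixed theta grid:
// out(g, i) = mean over s of P(grid_g; a_si, b_si).
// [[Rcpp::export]]
NumericMatrix cpp_pbar_grid(NumericMatrix a, NumericMatrix b,
                            NumericVector grid) {
  const int S = a.nrow(), I = a.ncol(), G = grid.size();
  if (b.nrow() != S || b.ncol() != I)
    stop("draw dimensions do not align");
  NumericMatrix out(G, I);
  for (int i = 0; i < I; ++i) {
    const double *ai = &a(0, i), *bi = &b(0, i);
    for (int g = 0; g < G; ++g) {
      double acc = 0.0;
      const double th = grid[g];
      for (int s = 0; s < S; ++s)
        acc += logistic(ai[s] * (th - bi[s]));
      out(g, i) = acc / S;
    }
  }
  return out;
}

// Bernoulli 2PL log-likelihood over a respondent x item matrix with NA for
// structural missingness: per-respondent sums, per-item sums, and the total.
// [[Rcpp::export]]
List cpp_masked_ll(NumericMatrix U, NumericVector theta,
                   NumericVector a, NumericVector b) {
  const int R = U.nrow(), I = U.ncol();
  if (theta.size() != R || a.size() != I || b.size() != I)
    stop("dimensions do not align");
  NumericVector row(R), col(I);
  double total = 0.0;
  for (int i = 0; i < I; ++i) {
    const double ai = a[i], bi = b[i];
    double ci = 0.0;
    const double *ui = &U(0, i);
    for (int j = 0; j < R; ++j) {
      const double u = ui[j];
      if (ISNAN(u)) continue;
      const double x = ai * (theta[j] - bi);
      // log P = -log(1+exp(-x)); log(1-P) = -log(1+exp(x)), stable forms
      double lp, lq;
      if (x >= 0.0) {
        const double e = std::exp(-x);
        lq = -x - std::log1p(e);
        lp = -std::log1p(e);
      } else {
        const double e = std::exp(x);
        lp = x - std::log1p(e);
        lq = -std::log1p(e);
      }
      const double ll = u == 1.0 ? lp : lq;
      ci += ll;
      row[j] += ll;
    }
    col[i] = ci;
    total += ci;
  }
  return List::create(_["row"] = row, _["col"] = col, _["total"] = total);
}

// Bounded per-item M-step for the Bock-Aitkin EM: maximize the expected
// complete-data log-likelihood sum_k r_k log P_k + (n_k - r_k) log(1 - P_k)
// over a in [a_lo, a_hi], b in [b_lo, b_hi]. Newton in slope/intercept space
// with box projection and objective-guarded step halving; guarded 1-D
// coordinate steps when the joint step stalls. Returns 3 x I: a, b, and a
// flag (1 = KKT not certified, caller may refine).
// [[Rcpp::export]]
NumericMatrix cpp_mstep_2pl(NumericMatrix r, NumericMatrix n,
                            NumericVector nodes,
                            NumericVector a0, NumericVector b0,
                            double a_lo, double a_hi,
                            double b_lo, double b_hi) {
  const int I = r.nrow(), K = r.ncol();
  NumericMatrix out(3, I);
  std::vector<double> p(K);
  for (int i = 0; i < I; ++i) {
    double a = std::min(std::max(a0[i], a_lo), a_hi);
    double b = std::min(std::max(b0[i], b_lo), b_hi);
    double c1 = a, c0 = -a * b;
    auto Qf = [&](double cc1, double cc0) {
      double q = 0.0;
      for (int k = 0; k < K; ++k) {
        const double x = cc1 * nodes[k] + cc0;
        double lp, lq;
        if (x >= 0.0) {
          const double e = std::exp(-x);
          lp = -std::log1p(e); lq = -x - std::log1p(e);
        } else {
          const double e = std::exp(x);
          lp = x - std::log1p(e); lq = -std::log1p(e);
        }
        q += r(i, k) * lp + (n(i, k) - r(i, k)) * lq;
      }
      return q;
    };
    double Q = Qf(c1, c0);
    bool certified = false;
    for (int it = 0; it < 25; ++it) {
      double g1 = 0, g0 = 0, h11 = 0, h10 = 0, h00 = 0;
      for (int k = 0; k < K; ++k) {
        const double pk = logistic(c1 * nodes[k] + c0);
        const double gk = r(i, k) - n(i, k) * pk;
        const double wk = n(i, k) * pk * (1.0 - pk);
        g1 += gk * nodes[k]; g0 += gk;
        h11 += wk * nodes[k] * nodes[k]; h10 += wk * nodes[k]; h00 += wk;
      }
      const double bb = -c0 / c1;
      // KKT in (a, b): gradient small or pushing outward at a bound
      const double ga = g1 - bb * g0;
      const double gb = -c1 * g0;
      const bool ok_a = std::fabs(ga) < 1e-8 ||
        (c1 <= a_lo + 1e-12 && ga < 0) || (c1 >= a_hi - 1e-12 && ga > 0);
      const bool ok_b = std::fabs(gb) < 1e-8 ||
        (bb <= b_lo + 1e-12 && gb < 0) || (bb >= b_hi - 1e-12 && gb > 0);
      if (ok_a && ok_b) { certified = true; break; }

      const double det = h11 * h00 - h10 * h10;
      bool accepted = false;
      if (std::isfinite(det) && det > 1e-12) {
        const double d1 = (h00 * g1 - h10 * g0) / det;
        const double d0 = (h11 * g0 - h10 * g1) / det;
        double step = 1.0;
        for (int h = 0; h < 12; ++h) {
          double n1 = std::min(std::max(c1 + step * d1, a_lo), a_hi);
          double nb = std::min(std::max(-(c0 + step * d0) / n1, b_lo), b_hi);
          double n0 = -nb * n1;
          double Qn = Qf(n1, n0);
          if (std::isfinite(Qn) && Qn >= Q - 1e-12 &&
              (std::fabs(n1 - c1) > 1e-15 || std::fabs(n0 - c0) > 1e-15)) {
            c1 = n1; c0 = n0; Q = Qn; accepted = true; break;
          }
          step *= 0.5;
        }
      }
      if (!accepted) {
        // guarded 1-D coordinate steps: b then a
        double curv_b = c1 * c1 * h00;
        if (curv_b > 1e-12) {
          double db = gb / curv_b, step = 1.0;
          for (int h = 0; h < 10; ++h) {
            double nb2 = std::min(std::max(bb + step * db, b_lo), b_hi);
            double Qn = Qf(c1, -nb2 * c1);
            if (Qn >= Q - 1e-12 && std::fabs(nb2 - bb) > 1e-15) {
              c0 = -nb2 * c1; Q = Qn; accepted = true; break;
            }
            step *= 0.5;
          }
        }
        const double bcur = -c0 / c1;
        double curv_a = 0;
        for (int k = 0; k < K; ++k) {
          const double pk = logistic(c1 * (nodes[k] - bcur));
          const double wk = n(i, k) * pk * (1.0 - pk);
          const double d = nodes[k] - bcur;
          curv_a += wk * d * d;
        }
        if (curv_a > 1e-12) {
          double g1b = 0;
          for (int k = 0; k < K; ++k) {
            const double pk = logistic(c1 * (nodes[k] - bcur));
            g1b += (r(i, k) - n(i, k) * pk) * (nodes[k] - bcur);
          }
          double da = g1b / curv_a, step = 1.0;
          for (int h = 0; h < 10; ++h) {
            double na = std::min(std::max(c1 + step * da, a_lo), a_hi);
            double Qn = Qf(na, -bcur * na);
            if (Qn >= Q - 1e-12 && std::fabs(na - c1) > 1e-15) {
              c1 = na; c0 = -bcur * na; Q = Qn; accepted = true; break;
            }
            step *= 0.5;
          }
        }
        if (!accepted) break;  // no direction improves: leave to caller
      }
    }
    out(0, i) = c1;
    out(1, i) = -c0 / c1;
    out(2, i) = certified ? 0.0 : 1.0;
  }
  return out;
}
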