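// Single-site Gibbs sampler for the social-genetic-effects animal model.
//
// Effect layout (0-based offsets passed from R):
//   [fixed | a_D | a_S | pen | group | pe | litter_l | litter_k]
// The coefficient structure is W'W (general CSC, both triangles stored)
// plus sigma_e^2 times the prior precision:
//   genetic pair    : Cinv (x) Kinv          (Kinv = H^-1 or A^-1)
//   litter pair     : Binv (x) I             (l and k share levels)
//   scalar terms    : I / sigma_t^2
// Location effects are updated one site at a time from their Gaussian full
// conditionals; variance blocks from inverse-Wishart / scaled-inverse-
// chi-square full conditionals.  All randomness comes from R's RNG so a
// set.seed() on the R side makes the chain reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct CSC {
  IntegerVector iv, pv;
  NumericVector xv;
  const int *i;
  const int *p;
  const double *x;
  int ncol;
  explicit CSC(S4 m)
      : iv(m.slot("i")), pv(m.slot("p")), xv(m.slot("x")) {
    IntegerVector dim = m.slot("Dim");
    i = INTEGER(iv);
    p = INTEGER(pv);
    x = REAL(xv);
    ncol = dim[1];
  }
};

inline void inv2(double a, double b, double d,
                 double &ia, double &ib, double &id) {
  double det = a * d - b * b;
  if (det <= 0.0 || !std::isfinite(det))
    stop("2x2 covariance block became non-positive-definite");
  ia = d / det;
  ib = -b / det;
  id = a / det;
}

// Draw Sigma ~ inverse-Wishart(df, S) for 2x2 scale S (Bartlett).
inline void riwish2(double df, double s11, double s12, double s22,
                    double &c11, double &c12, double &c22) {
  double i11, i12, i22;
  inv2(s11, s12, s22, i11, i12, i22);
  double l11 = std::sqrt(i11);
  double l21 = i12 / l11;
  double l22 = std::sqrt(i22 - l21 * l21);
  double a11 = std::sqrt(R::rchisq(df));
  double a21 = norm_rand();
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  double t11 = l11 * a11;
  double t21 = l21 * a11 + l22 * a21;
  double t22 = l22 * a22;
  double w11 = t11 * t11;
  double w12 = t11 * t21;
  double w22 = t21 * t21 + t22 * t22;
  inv2(w11, w12, w22, c11, c12, c22);
}

inline double scalar_var_draw(double ss, double df_data, double nu0,
                              double s0) {
  double df = df_data + nu0;
  if (df <= 0.0) stop("nonpositive degrees of freedom in variance draw");
  return (ss + nu0 * s0) / R::rchisq(df);
}

} // namespace

// [[Rcpp::export]]
List gibbs_sampler_cpp(S4 WtW_, NumericVector Wty, double yty, int n_records,
                       S4 Kinv_, IntegerVector off, IntegerVector len,
                       List prior, List start, int n_rounds, int burn_in,
                       int thin, bool update_variances) {
  CSC WtW(WtW_);
  CSC Kinv(Kinv_);
  const int p_tot = Wty.size();
  if (WtW.ncol != p_tot) stop("WtW dimension mismatch");

  const int o_aD = off[1], o_aS = off[2], o_c = off[3], o_g = off[4],
            o_pe = off[5], o_l = off[6], o_k = off[7];
  const int n_aD = len[1], n_aS = len[2], n_c = len[3], n_g = len[4],
            n_pe = len[5], n_l = len[6], n_k = len[7];
  const bool has_aS = n_aS > 0, has_l = n_l > 0;
  if (n_aD != Kinv.ncol) stop("Kinv dimension mismatch");
  if (has_l && n_k != n_l) stop("l and k must share levels");

  // priors
  const double nu_g = as<double>(prior["nu_g"]);
  NumericMatrix S_g = prior["S_g"];
  const double nu_lk = as<double>(prior["nu_lk"]);
  NumericMatrix S_lk = prior["S_lk"];
  const double nu_sc = as<double>(prior["nu_scalar"]);
  const double s0_sc = as<double>(prior["s_scalar"]);
  const double nu_e = as<double>(prior["nu_e"]);
  const double s0_e = as<double>(prior["s_e"]);

  // state: variance components
  double c11 = as<double>(start["var_aD"]);
  double c12 = has_aS ? as<double>(start["cov_aDaS"]) : 0.0;
  double c22 = has_aS ? as<double>(start["var_aS"]) : 0.0;
  double b11 = has_l ? as<double>(start["var_l"]) : 0.0;
  double b12 = has_l ? as<double>(start["cov_lk"]) : 0.0;
  double b22 = has_l ? as<double>(start["var_k"]) : 0.0;
  double vc = n_c > 0 ? as<double>(start["var_c"]) : 0.0;
  double vg = n_g > 0 ? as<double>(start["var_g"]) : 0.0;
  double vpe = n_pe > 0 ? as<double>(start["var_pe"]) : 0.0;
  double ve = as<double>(start["var_e"]);

  double ci11 = 0, ci12 = 0, ci22 = 0, bi11 = 0, bi12 = 0, bi22 = 0;
  if (has_aS) inv2(c11, c12, c22, ci11, ci12, ci22);
  if (has_l) inv2(b11, b12, b22, bi11, bi12, bi22);

  std::vector<double> theta(p_tot, 0.0);
  const int n_keep = (n_rounds - burn_in) / thin;
  NumericMatrix samples(n_keep, 10);
  std::vector<double> theta_sum(p_tot, 0.0);
  int kept = 0;

  for (int round = 1; round <= n_rounds; ++round) {
    if (round % 512 == 0) checkUserInterrupt();

    // ---- location effects, single site ----
    for (int j = 0; j < p_tot; ++j) {
      double dot = 0.0, diag = 0.0;
      for (int k = WtW.p[j]; k < WtW.p[j + 1]; ++k) {
        const int r = WtW.i[k];
        const double v = WtW.x[k];
        if (r == j)
          diag = v;
        else
          dot += v * theta[r];
      }
      double dpri = 0.0;
      if (j >= o_aD && j < o_aD + n_aD) {
        const int i0 = j - o_aD;
        for (int k = Kinv.p[i0]; k < Kinv.p[i0 + 1]; ++k) {
          const int m = Kinv.i[k];
          const double kv = Kinv.x[k];
          if (has_aS) {
            if (m == i0)
              dpri += ve * ci11 * kv;
            else
              dot += ve * ci11 * kv * theta[o_aD + m];
            dot += ve * ci12 * kv * theta[o_aS + m];
          } else {
            if (m == i0)
              dpri += ve * kv / c11;
            else
              dot += ve * kv / c11 * theta[o_aD + m];
          }
        }
      } else if (has_aS && j >= o_aS && j < o_aS + n_aS) {
        const int i0 = j - o_aS;
        for (int k = Kinv.p[i0]; k < Kinv.p[i0 + 1]; ++k) {
          const int m = Kinv.i[k];
          const double kv = Kinv.x[k];
          if (m == i0)
            dpri += ve * ci22 * kv;
          else
            dot += ve * ci22 * kv * theta[o_aS + m];
          dot += ve * ci12 * kv * theta[o_aD + m];
        }
      } else if (n_c > 0 && j >= o_c && j < o_c + n_c) {
        dpri = ve / vc;
      } else if (n_g > 0 && j >= o_g && j < o_g + n_g) {
        dpri = ve / vg;
      } else if (n_pe > 0 && j >= o_pe && j < o_pe + n_pe) {
        dpri = ve / vpe;
      } else if (has_l && j >= o_l && j < o_l + n_l) {
        dpri = ve * bi11;
        dot += ve * bi12 * theta[o_k + (j - o_l)];
      } else if (has_l && j >= o_k && j < o_k + n_k) {
        dpri = ve * bi22;
        dot += ve * bi12 * theta[o_l + (j - o_k)];
      }
      const double cjj = diag + dpri;
      if (cjj <= 0.0) { // empty fixed column
        theta[j] = 0.0;
        continue;
      }
      theta[j] = (Wty[j] - dot) / cjj + norm_rand() * std::sqrt(ve / cjj);
    }

    // ---- variance components ----
    if (update_variances) {
      // genetic block: scatter a' Kinv a
      double s11 = 0.0, s12 = 0.0, s22 = 0.0;
      for (int i0 = 0; i0 < Kinv.ncol; ++i0) {
        const double aDi = theta[o_aD + i0];
        const double aSi = has_aS ? theta[o_aS + i0] : 0.0;
        for (int k = Kinv.p[i0]; k < Kinv.p[i0 + 1]; ++k) {
          const int m = Kinv.i[k];
          const double kv = Kinv.x[k];
          s11 += kv * theta[o_aD + m] * aDi;
          if (has_aS) {
            s12 += kv * theta[o_aD + m] * aSi;
            s22 += kv * theta[o_aS + m] * aSi;
          }
        }
      }
      if (has_aS) {
        riwish2(nu_g + n_aD, S_g(0, 0) + s11, S_g(0, 1) + s12,
                S_g(1, 1) + s22, c11, c12, c22);
        inv2(c11, c12, c22, ci11, ci12, ci22);
      } else {
        c11 = scalar_var_draw(s11, (double)n_aD, nu_sc, s0_sc);
      }

      if (has_l) {
        double t11 = 0.0, t12 = 0.0, t22 = 0.0;
        for (int i0 = 0; i0 < n_l; ++i0) {
          const double li = theta[o_l + i0];
          const double ki = theta[o_k + i0];
          t11 += li * li;
          t12 += li * ki;
          t22 += ki * ki;
        }
        riwish2(nu_lk + n_l, S_lk(0, 0) + t11, S_lk(0, 1) + t12,
                S_lk(1, 1) + t22, b11, b12, b22);
        inv2(b11, b12, b22, bi11, bi12, bi22);
      }

      if (n_c > 0) {
        double ss = 0.0;
        for (int i0 = 0; i0 < n_c; ++i0) ss += theta[o_c + i0] * theta[o_c + i0];
        vc = scalar_var_draw(ss, (double)n_c, nu_sc, s0_sc);
      }
      if (n_g > 0) {
        double ss = 0.0;
        for (int i0 = 0; i0 < n_g; ++i0) ss += theta[o_g + i0] * theta[o_g + i0];
        vg = scalar_var_draw(ss, (double)n_g, nu_sc, s0_sc);
      }
      if (n_pe > 0) {
        double ss = 0.0;
        for (int i0 = 0; i0 < n_pe; ++i0)
          ss += theta[o_pe + i0] * theta[o_pe + i0];
        vpe = scalar_var_draw(ss, (double)n_pe, nu_sc, s0_sc);
      }

      // residual: e'e = y'y - 2 theta'W'y + theta' W'W theta
      double qf = 0.0, lin = 0.0;
      for (int j = 0; j < p_tot; ++j) {
        lin += Wty[j] * theta[j];
        double colsum = 0.0;
        for (int k = WtW.p[j]; k < WtW.p[j + 1]; ++k)
          colsum += WtW.x[k] * theta[WtW.i[k]];
        qf += colsum * theta[j];
      }
      double ee = yty - 2.0 * lin + qf;
      if (ee < 0.0) ee = 0.0; // numerical guard
      ve = scalar_var_draw(ee, (double)n_records, nu_e, s0_e);
      if (!std::isfinite(ve) || ve <= 0.0)
        stop("divergent chain: residual variance became non-finite at round %d",
             round);
    }

    // ---- record ----
    if (round > burn_in && (round - burn_in) % thin == 0) {
      samples(kept, 0) = c11;
      samples(kept, 1) = has_aS ? c22 : NA_REAL;
      samples(kept, 2) = has_aS ? c12 : NA_REAL;
      samples(kept, 3) = n_c > 0 ? vc : NA_REAL;
      samples(kept, 4) = n_g > 0 ? vg : NA_REAL;
      samples(kept, 5) = n_pe > 0 ? vpe : NA_REAL;
      samples(kept, 6) = has_l ? b11 : NA_REAL;
      samples(kept, 7) = has_l ? b22 : NA_REAL;
      samples(kept, 8) = has_l ? b12 : NA_REAL;
      samples(kept, 9) = ve;
      for (int j = 0; j < p_tot; ++j) theta_sum[j] += theta[j];
      ++kept;
    }
  }

  NumericVector theta_mean(p_tot);
  for (int j = 0; j < p_tot; ++j)
    theta_mean[j] = kept > 0 ? theta_sum[j] / kept : NA_REAL;

  return List::create(_["samples"] = samples, _["theta_mean"] = theta_mean,
                      _["n_kept"] = kept);
}
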