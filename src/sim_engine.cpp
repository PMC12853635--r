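#include <Rcpp.h>
using namespace Rcpp;

// Sequential simulation of (social, alcohol, mood) paths on the fixed
// measurement grid. All randomness enters through the pre-drawn uniform
// matrices (one per variable draw), so the R side owns the RNG stream and
// common-random-number coupling across treatment arms is exact.

static inline double clip_lp(double x) {
  if (x > 35.0) return 35.0;
  if (x < -35.0) return -35.0;
  return x;
}

static inline double expit_clip(double x) {
  return 1.0 / (1.0 + std::exp(-clip_lp(x)));
}

// [[Rcpp::export(name = ".sim_engine_cpp")]]
List sim_engine_cpp(NumericVector off_s, NumericVector off_z,
                    NumericVector off_c, NumericVector off_m,
                    NumericVector sp, NumericVector zo, NumericVector co,
                    NumericVector ms, NumericVector cuts,
                    LogicalVector intervene, IntegerVector init,
                    int n_paths, NumericMatrix uS, NumericMatrix uZ,
                    NumericMatrix uP, NumericMatrix uY) {
  const int Tn = off_s.size();
  IntegerMatrix S(n_paths, Tn), AU(n_paths, Tn), Y(n_paths, Tn);
  for (int i = 0; i < n_paths; ++i) {
    S(i, 0) = init[0];
    AU(i, 0) = init[1];
    Y(i, 0) = init[2];
  }
  // slope scalars: sp = (alcohol_prev, mood_prev); zo/co = (mood_prev,
  // social); ms = (alcohol_now, alcohol_prev, mood_prev, social)
  const double s_ap = sp[0], s_mp = sp[1];
  const double z_mp = zo[0], z_so = zo[1];
  const double c_mp = co[0], c_so = co[1];
  const double m_an = ms[0], m_ap = ms[1], m_mp = ms[2], m_so = ms[3];

  for (int t = 1; t < Tn; ++t) {
    const bool iv = intervene[t];
    const double os = off_s[t], oz = off_z[t], oc = off_c[t], om = off_m[t];
    for (int i = 0; i < n_paths; ++i) {
      const double ap = AU(i, t - 1), mp = Y(i, t - 1);
      const int s = uS(i, t - 1) < expit_clip(os + s_ap * ap + s_mp * mp);
      S(i, t) = s;
      int au = 0;
      if (!iv) {
        const double pi0 = expit_clip(oz + z_mp * mp + z_so * s);
        if (uZ(i, t - 1) >= pi0) {
          const double lam = std::exp(clip_lp(oc + c_mp * mp + c_so * s));
          au = (int) R::qpois(uP(i, t - 1), lam, 1, 0);
        }
      }
      AU(i, t) = au;
      const double eta = om + m_an * au + m_ap * ap + m_mp * mp + m_so * s;
      const double u = uY(i, t - 1);
      int y = -2;
      for (int j = 0; j < 4; ++j) {
        double a = cuts[j];
        // infinite cutpoints encode zero-probability boundary categories
        double pge = (a == R_PosInf) ? 1.0 : (a == R_NegInf) ? 0.0
                                           : expit_clip(a + eta);
        if (u > 1.0 - pge) ++y;
      }
      Y(i, t) = y;
    }
  }
  return List::create(Named("S") = S, Named("AU") = AU, Named("Y") = Y);
}
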