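// Gridded steady-state energetics kernel.
//
// Evaluates, for a batch of trait variants, the hourly thermoregulatory
// cascade over every landscape cell and model day, and aggregates the
// monthly survival/breeding classification and the per-pixel invasion-risk
// flag. The per-hour math is the exact closed form of the R reference
// path (solve_heat_balance / thermoregulate); a test asserts agreement.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List grid_energetics_cpp(NumericVector ta, NumericVector trad,
                         NumericVector sol, NumericVector rhov,
                         LogicalVector active, NumericMatrix wind,
                         int ncell,
                         NumericMatrix scal, NumericMatrix areaEff,
                         NumericMatrix hfree, NumericMatrix hforc,
                         NumericMatrix solc, NumericMatrix rins,
                         NumericMatrix wet, LogicalVector shade,
                         int ncold, double hr, double wexp, double band,
                         bool detailed) {
  const int nvar = scal.nrow();
  const int P = areaEff.ncol();
  const int S = wet.ncol();
  if (S != 1 + ncold + 3) stop("inconsistent state count");
  if (S > 16) stop("state count exceeds kernel limit");

  LogicalMatrix at_risk(ncell, nvar);
  NumericMatrix max_mult(ncell, nvar);
  NumericVector fraction(nvar);

  LogicalMatrix surv_out, breed_out;
  NumericMatrix mult_out;
  IntegerMatrix reason_out;
  if (detailed) {
    if (nvar != 1) stop("detailed output requires a single variant");
    surv_out = LogicalMatrix(ncell, 12);
    breed_out = LogicalMatrix(ncell, 12);
    mult_out = NumericMatrix(ncell, 12);
    reason_out = IntegerMatrix(ncell, 12);
  }

  const double *pta = REAL(ta), *ptr = REAL(trad), *pso = REAL(sol),
               *prv = REAL(rhov);
  const int *pac = LOGICAL(active);

  std::vector<double> a(S), b(S), c(S), d(S), mvals(S),
      av(P), hfv(P), hcv(P), scv(P), riv(P * S), wetv(S);
  std::vector<char> shd(S);
  for (int s = 0; s < S; ++s) shd[s] = (char)shade[s];

  for (int v = 0; v < nvar; ++v) {
    const double tb = scal(v, 0);        // core - skin offset applied
    const double rhov_tb = scal(v, 1);
    const double eta = scal(v, 2);
    const double f_resp = scal(v, 3);
    const double act_mult = scal(v, 4);
    const double breed_mult = scal(v, 5);
    const double bmr = scal(v, 6);
    const double intake = scal(v, 7);
    const int breed_dur = (int)scal(v, 8);
    const double lewis = scal(v, 9);
    for (int p = 0; p < P; ++p) {
      av[p] = areaEff(v, p); hfv[p] = hfree(v, p);
      hcv[p] = hforc(v, p); scv[p] = solc(v, p);
      for (int s = 0; s < S; ++s) riv[s * P + p] = rins(v, s * P + p);
    }
    for (int s = 0; s < S; ++s) wetv[s] = wet(v, s);

    int n_at_risk = 0;
    for (int cell = 0; cell < ncell; ++cell) {
      bool surv_all = true;
      bool breed_ok[12];
      double maxm = 0.0;
      for (int m = 0; m < 12; ++m) {
        const double vms = wind(cell, m);
        const double vpow = std::pow(vms, wexp);
        double ec = 0.0;
        for (int s = 0; s < S; ++s) { a[s] = b[s] = c[s] = d[s] = 0.0; }
        for (int p = 0; p < P; ++p) {
          double hc = hcv[p] * vpow;
          if (hfv[p] > hc) hc = hfv[p];
          const double hx = hc + hr;
          const double w = hc / hx;
          const double sterm = scv[p] / (av[p] * hx);
          const double ihx = 1.0 / hx;
          for (int s = 0; s < S; ++s) {
            const double g = av[p] / (riv[s * P + p] + ihx);
            a[s] += g;
            b[s] += g * w;
            c[s] += g * (1.0 - w);
            if (!shd[s]) d[s] += g * sterm;
          }
          ec += av[p] * hc;
        }

        double sum_surv = 0.0, sum_breed = 0.0;
        bool overheat_surv = false, overheat_breed = false;
        for (int h = 0; h < 24; ++h) {
          const R_xlen_t k = cell + (R_xlen_t)ncell * (m + 12 * h);
          const double taa = pta[k], trr = ptr[k], ss = pso[k];
          const double devap = std::max(0.0, rhov_tb - prv[k]);
          const bool act = pac[k];
          const double denom = 1.0 - (act ? eta : 0.0) - f_resp;
          const double evw = ec * lewis * devap;
          // lazy per-state evaluation of the closed-form requirement
          char have[16] = {0};
          auto mval = [&](int s) {
            if (!have[s]) {
              const double q = a[s] * tb - b[s] * taa - c[s] * trr
                               - d[s] * ss;
              mvals[s] = (q + wetv[s] * evw) / denom;
              have[s] = 1;
            }
            return mvals[s];
          };
          for (int mode = 0; mode < 2; ++mode) {
            const double target = bmr * (act ? act_mult : 1.0)
                                  * (mode == 1 ? breed_mult : 1.0);
            const double tol = band * target;
            double mfin = mval(0);
            bool banded = std::fabs(mfin - target) <= tol;
            if (!banded && mfin > target + tol) {
              for (int s = 1; s <= ncold; ++s) {
                mfin = mval(s);
                if (std::fabs(mfin - target) <= tol) { banded = true; break; }
              }
            } else if (!banded) {
              for (int s = ncold + 1; s < S; ++s) {
                mfin = mval(s);
                if (std::fabs(mfin - target) <= tol) { banded = true; break; }
              }
              if (!banded && mfin < bmr) {
                if (mode == 0) overheat_surv = true;
                else overheat_breed = true;
              }
            }
            if (mode == 0) sum_surv += mfin; else sum_breed += mfin;
          }
        }
        const double mult_surv = sum_surv / 24.0 / bmr;
        const double mult_breed = sum_breed / 24.0 / bmr;
        const bool s_ok = !overheat_surv && mult_surv <= intake;
        const bool b_ok = !overheat_breed && mult_breed <= intake;
        if (!s_ok) surv_all = false;
        breed_ok[m] = b_ok;
        if (mult_surv > maxm) maxm = mult_surv;
        if (detailed) {
          surv_out(cell, m) = s_ok;
          breed_out(cell, m) = b_ok;
          mult_out(cell, m) = mult_surv;
          reason_out(cell, m) = s_ok ? 0 : (overheat_surv ? 2 : 1);
        }
      }
      // circular run of consecutive breeding-suitable months
      int best = 0, run = 0;
      for (int i = 0; i < 24; ++i) {
        if (breed_ok[i % 12]) { ++run; if (run > best) best = run; }
        else run = 0;
      }
      if (best > 12) best = 12;
      const bool risk = surv_all && best >= breed_dur;
      at_risk(cell, v) = risk;
      max_mult(cell, v) = maxm;
      if (risk) ++n_at_risk;
    }
    fraction[v] = (double)n_at_risk / ncell;
  }

  List out = List::create(_["at_risk"] = at_risk,
                          _["max_monthly_multiple"] = max_mult,
                          _["fraction_at_risk"] = fraction);
  if (detailed) {
    out["survival_ok"] = surv_out;
    out["breeding_ok"] = breed_out;
    out["daily_mean_multiple"] = mult_out;
    out["failure_reason"] = reason_out;
  }
  return out;
}
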