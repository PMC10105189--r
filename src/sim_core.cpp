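#include <Rcpp.h>
using namespace Rcpp;

// Euler core of the insurance-demand feedback simulator.
// One row is recorded per day (or per substep when emit_substeps):
// t, inpt, pu_admit, pr_admit, pu_discharge, pr_discharge, using_pu,
// using_pr, pu_occu, pr_occu, diff_occu, effect_occu, effect_tax, hi.
// Stocks and hi are start-of-step values; flows/occupancies/effects are
// the values in force during the step.
// [[Rcpp::export]]
NumericMatrix sim_core_cpp(NumericVector inpt, NumericVector los,
                           NumericVector pub, NumericVector prb,
                           LogicalVector tax_on, double tax_input,
                           double use_hi, double selfpay, double sev,
                           double od, double bdiff, double b, bool clamp,
                           double sgn, double tau, double dt, int m,
                           bool matched_init, bool flow_basis,
                           bool emit_substeps) {
  const int n_days = inpt.size();
  const int n_rec = emit_substeps ? n_days * m : n_days;
  NumericMatrix rec(n_rec, 14);

  double hi = std::min(std::max(b, 0.0), 1.0);
  double u_pu = 0.0, u_pr = 0.0;
  double o1 = 0.0, o2 = 0.0, o3 = 0.0;  // occupancy-effect delay stages
  double x1 = 0.0, x2 = 0.0, x3 = 0.0;  // tax-effect delay stages
  bool tax_started = false;
  int k = 0;

  for (int i = 0; i < n_days; ++i) {
    const double in_i = inpt[i], los_i = los[i];
    const double pub_i = pub[i], prb_i = prb[i];
    const bool tax_i = tax_on[i];
    for (int j = 0; j < m; ++j) {
      const double pu_adm =
          in_i * (hi * (1.0 - use_hi) + (1.0 - hi) * (1.0 - selfpay));
      const double pr_adm = in_i - pu_adm;
      double pu_oc, pr_oc;
      if (flow_basis) {
        pu_oc = pu_adm * los_i / pub_i;
        pr_oc = pr_adm * los_i * sev / prb_i;
      } else {
        pu_oc = u_pu / pub_i;
        pr_oc = u_pr / prb_i;
      }
      const double gap = sgn * (pu_oc - pr_oc);
      const double occ_in = (gap - bdiff) * od;
      if (i == 0 && j == 0 && matched_init) {
        o1 = o2 = o3 = occ_in * tau;
      }
      if (tax_i && !tax_started) tax_started = true;  // zero history
      const double eff_occ = o3 / tau;
      const double eff_tax = tax_started ? x3 / tau : 0.0;

      if (emit_substeps || j == 0) {
        rec(k, 0) = (double)i + j * dt;
        rec(k, 1) = in_i;
        rec(k, 2) = pu_adm;
        rec(k, 3) = pr_adm;
        rec(k, 4) = u_pu / los_i;
        rec(k, 5) = u_pr / (los_i * sev);
        rec(k, 6) = u_pu;
        rec(k, 7) = u_pr;
        rec(k, 8) = pu_oc;
        rec(k, 9) = pr_oc;
        rec(k, 10) = gap;
        rec(k, 11) = clamp ? std::max(0.0, eff_occ) : eff_occ;
        rec(k, 12) = eff_tax;
        rec(k, 13) = hi;
        ++k;
      }

      // synchronous Euler update of the delay cascades
      const double n1 = o1 + dt * (occ_in - o1 / tau);
      const double n2 = o2 + dt * (o1 / tau - o2 / tau);
      const double n3 = o3 + dt * (o2 / tau - o3 / tau);
      o1 = n1; o2 = n2; o3 = n3;
      if (tax_started) {
        const double t1 = x1 + dt * (tax_input - x1 / tau);
        const double t2 = x2 + dt * (x1 / tau - x2 / tau);
        const double t3 = x3 + dt * (x2 / tau - x3 / tau);
        x1 = t1; x2 = t2; x3 = t3;
      }

      // stocks: first-order discharge, floored at zero
      const double pu_dis = u_pu / los_i;
      const double pr_dis = u_pr / (los_i * sev);
      u_pu = std::max(0.0, u_pu + dt * (pu_adm - pu_dis));
      u_pr = std::max(0.0, u_pr + dt * (pr_adm - pr_dis));

      // new penetration from the delayed effects
      const double eo = o3 / tau;
      const double et = tax_started ? x3 / tau : 0.0;
      const double e = clamp ? std::max(0.0, eo) : eo;
      hi = std::min(std::max(b + e + et, 0.0), 1.0);
    }
  }
  return rec;
}
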