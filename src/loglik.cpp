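// Hot path of the simulation-based binned likelihood: per parameter
// evaluation, simulate every condition's responses from fixed base draws,
// bin the localization errors on the 0.1-degree grid, and accumulate the
// floored log-probability of the observed trials' bins.
//
// The data-side binning structure is precomputed in R (make_fit_context):
// per-axis mode uses dense bin->slot lookup tables per condition, so the
// simulation loop does two array lookups per draw; 2D mode (non-default)
// builds small per-condition hash maps of the occupied joint bins.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-axis quadratic forms of the two marginal likelihoods; normalizers
// and exponentials are assembled once per draw across both axes.
static inline double q_common_1d(double m, double v, double pi0,
                                 double sm2, double sv2, double sp2,
                                 double invD) {
  return ((m - v) * (m - v) * sp2 + (m - pi0) * (m - pi0) * sv2 +
          (v - pi0) * (v - pi0) * sm2) * invD;
}

static inline double q_sep_1d(double m, double v, double pi0,
                              double inv_a, double inv_b) {
  return (m - pi0) * (m - pi0) * inv_a + (v - pi0) * (v - pi0) * inv_b;
}

// par: the 15 parameters in canonical order (sigma_mx ft/st/nt, sigma_my
// ft/st/nt, sigma_v 50/300/1000, sigma_f, sigma_pi_x, sigma_pi_y, pi_x,
// pi_y, p_c). rule: 0 mixture, 1 selection, 2 matching.
// lookup_x/lookup_y: nbins x ncond slot tables (-1 = bin unoccupied by
// data); trial_slot_x/y index into the global slot count vectors.
// [[Rcpp::export]]
double loglik_binned_cpp(NumericVector par,
                         NumericMatrix pre, NumericMatrix post,
                         IntegerVector tgt_idx, IntegerVector view_idx,
                         NumericMatrix zm1, NumericMatrix zm2,
                         NumericMatrix zv1, NumericMatrix zv2,
                         NumericMatrix u,
                         IntegerVector trial_cond,
                         IntegerVector trial_ix, IntegerVector trial_iy,
                         IntegerMatrix lookup_x, IntegerMatrix lookup_y,
                         IntegerVector trial_slot_x,
                         IntegerVector trial_slot_y,
                         int nslot_x, int nslot_y,
                         int rule, bool mode2d, int nbins,
                         double bin_width, double window, double floor_prob,
                         NumericVector ft, NumericVector st) {
  const int ncond = pre.nrow();
  const int nsims = zm1.nrow();
  const int ntrial = trial_cond.size();

  const double smx[3] = {par[0], par[1], par[2]};
  const double smy[3] = {par[3], par[4], par[5]};
  const double sv_[3] = {par[6], par[7], par[8]};
  const double sf2 = par[9] * par[9];
  const double spx2 = par[10] * par[10], spy2 = par[11] * par[11];
  const double pix = par[12], piy = par[13];
  const double pc = par[14];

  std::vector<std::vector<int>> cond_trials(ncond);
  for (int t = 0; t < ntrial; ++t) cond_trials[trial_cond[t]].push_back(t);

  std::vector<int> cntx(mode2d ? 0 : nslot_x, 0),
      cnty(mode2d ? 0 : nslot_y, 0);
  const double lam = floor_prob;
  double loglik = 0.0;

  for (int c = 0; c < ncond; ++c) {
    const std::vector<int>& trials = cond_trials[c];
    if (trials.empty()) continue;

    const int tg = tgt_idx[c], vw = view_idx[c];
    const double smx2 = smx[tg] * smx[tg], smy2 = smy[tg] * smy[tg];
    const double sv2 = sv_[vw] * sv_[vw];

    // percept means: foveal shrinkage toward FT (memory) / landing = ST
    const double wx_m = smx2 / (smx2 + sf2), wy_m = smy2 / (smy2 + sf2);
    const double wv = sv2 / (sv2 + sf2);
    const double mmx = pre(c, 0) + (ft[0] - pre(c, 0)) * wx_m;
    const double mmy = pre(c, 1) + (ft[1] - pre(c, 1)) * wy_m;
    const double vmx = post(c, 0) + (st[0] - post(c, 0)) * wv;
    const double vmy = post(c, 1) + (st[1] - post(c, 1)) * wv;

    // precision weights of the conditional estimates
    const double wmx = 1.0 / smx2, wmy = 1.0 / smy2, wvv = 1.0 / sv2;
    const double wpx = 1.0 / spx2, wpy = 1.0 / spy2;
    const double den_cx = wmx + wvv + wpx, den_cy = wmy + wvv + wpy;
    const double den_sx = wmx + wpx, den_sy = wmy + wpy;

    // likelihood normalizers, shared by all draws of this condition
    const double Dx = smx2 * sv2 + smx2 * spx2 + sv2 * spx2;
    const double Dy = smy2 * sv2 + smy2 * spy2 + sv2 * spy2;
    const double invDx = 1.0 / Dx, invDy = 1.0 / Dy;
    const double ax = smx2 + spx2, bx = sv2 + spx2;
    const double ay = smy2 + spy2, by = sv2 + spy2;
    const double inv_ax = 1.0 / ax, inv_bx = 1.0 / bx;
    const double inv_ay = 1.0 / ay, inv_by = 1.0 / by;
    // p(C|mv) = sigmoid(logit(pc) + log(norm_c/norm_s) - (qc - qs)/2)
    const double logit_prior =
        (pc > 0.0 && pc < 1.0)
            ? std::log(pc / (1.0 - pc)) +
              0.5 * std::log((ax * bx * ay * by) / (Dx * Dy))
            : 0.0;

    std::unordered_map<int, int> slot2d;
    std::vector<int> cnt2d;
    if (mode2d) {
      for (int t : trials) {
        int key = trial_ix[t] * nbins + trial_iy[t];
        if (!slot2d.count(key)) { int s = slot2d.size(); slot2d[key] = s; }
      }
      cnt2d.assign(slot2d.size(), 0);
    }

    const int* lx = mode2d ? nullptr : &lookup_x(0, c);
    const int* ly = mode2d ? nullptr : &lookup_y(0, c);

    for (int i = 0; i < nsims; ++i) {
      const double mx = mmx + smx[tg] * zm1(i, c);
      const double my = mmy + smy[tg] * zm2(i, c);
      const double vx = vmx + sv_[vw] * zv1(i, c);
      const double vy = vmy + sv_[vw] * zv2(i, c);

      double pC;
      if (pc <= 0.0) pC = 0.0;
      else if (pc >= 1.0) pC = 1.0;
      else {
        const double qc = q_common_1d(mx, vx, pix, smx2, sv2, spx2, invDx) +
                          q_common_1d(my, vy, piy, smy2, sv2, spy2, invDy);
        const double qs = q_sep_1d(mx, vx, pix, inv_ax, inv_bx) +
                          q_sep_1d(my, vy, piy, inv_ay, inv_by);
        pC = 1.0 / (1.0 + std::exp(-(logit_prior - 0.5 * (qc - qs))));
      }

      const double cx = (mx * wmx + vx * wvv + pix * wpx) / den_cx;
      const double cy = (my * wmy + vy * wvv + piy * wpy) / den_cy;
      const double sx = (mx * wmx + pix * wpx) / den_sx;
      const double sy = (my * wmy + piy * wpy) / den_sy;

      double rx, ry;
      if (rule == 0) {            // mixture: posterior-weighted average
        rx = pC * cx + (1.0 - pC) * sx;
        ry = pC * cy + (1.0 - pC) * sy;
      } else if (rule == 1) {     // selection: ties integrate
        const bool pick = pC >= 0.5;
        rx = pick ? cx : sx; ry = pick ? cy : sy;
      } else {                    // probability matching
        const bool pick = u(i, c) < pC;
        rx = pick ? cx : sx; ry = pick ? cy : sy;
      }

      int ix = (int)std::floor((rx - pre(c, 0) + window) / bin_width);
      int iy = (int)std::floor((ry - pre(c, 1) + window) / bin_width);
      ix = ix < 0 ? 0 : (ix >= nbins ? nbins - 1 : ix);
      iy = iy < 0 ? 0 : (iy >= nbins ? nbins - 1 : iy);

      if (mode2d) {
        auto it = slot2d.find(ix * nbins + iy);
        if (it != slot2d.end()) ++cnt2d[it->second];
      } else {
        const int sx_ = lx[ix];
        if (sx_ >= 0) ++cntx[sx_];
        const int sy_ = ly[iy];
        if (sy_ >= 0) ++cnty[sy_];
      }
    }

    if (mode2d) {
      const double total_bins = (double)nbins * nbins;
      for (int t : trials) {
        const int cnt = cnt2d[slot2d[trial_ix[t] * nbins + trial_iy[t]]];
        loglik += std::log((1.0 - lam) * cnt / nsims + lam / total_bins);
      }
    }
  }

  if (!mode2d) {
    for (int t = 0; t < ntrial; ++t) {
      loglik += std::log((1.0 - lam) * cntx[trial_slot_x[t]] / nsims +
                         lam / nbins);
      loglik += std::log((1.0 - lam) * cnty[trial_slot_y[t]] / nsims +
                         lam / nbins);
    }
  }
  return loglik;
}
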