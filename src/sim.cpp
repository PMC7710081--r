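#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Spiking schemes. Values must match scheme_code() on the R side.
static const int SCHEME_RESET = 0;
static const int SCHEME_MIXING = 1;
static const int SCHEME_SUMMATION = 2;

// Core tick loop shared by all input providers. inputI/inputEff are callables
// (t, j) -> mechanoreceptor drive (Hz) / effective indentation (mm).
template <typename FI, typename FE>
static std::vector<int> run_branches(int nticks, int nbranch, double dt_ms,
                                     double max_rate, int scheme,
                                     double spike_thresh, FI inputI,
                                     FE inputEff) {
  std::vector<int> spikes;
  const double dt_s = dt_ms / 1000.0;
  if (scheme == SCHEME_SUMMATION) {
    // single accumulator driven by the summed drive, same saturation,
    // adaptation (summed drive must increase) and indentation threshold.
    // At rest the accumulator is primed (phase 1): the time from the last
    // spike is infinite at stimulus onset, so an onset transient can fire
    // immediately once the drive is increasing and above threshold.
    double phase = 1.0, prev = 0.0;
    for (int t = 0; t < nticks; ++t) {
      double Isum = 0.0, effsum = 0.0;
      for (int j = 0; j < nbranch; ++j) {
        Isum += inputI(t, j);
        effsum += inputEff(t, j);
      }
      phase += std::min(Isum, max_rate) * dt_s;
      if (phase >= 1.0 && Isum > prev && effsum >= spike_thresh) {
        spikes.push_back(t);
        phase -= 1.0;
      }
      if (phase > 1.0) phase = 1.0;  // held at ceiling while blocked
      prev = Isum;
    }
    return spikes;
  }
  std::vector<double> phase(nbranch, 1.0), prev(nbranch, 0.0);
  for (int t = 0; t < nticks; ++t) {
    int spiker = -1;
    for (int j = 0; j < nbranch; ++j) {
      const double I = inputI(t, j);
      phase[j] += std::min(I, max_rate) * dt_s;
      if (phase[j] >= 1.0 && I > prev[j] && inputEff(t, j) >= spike_thresh) {
        if (spiker < 0) {
          spikes.push_back(t);  // at most one neuron spike per tick
          spiker = j;
        }
        if (scheme == SCHEME_MIXING || j == spiker) phase[j] -= 1.0;
      }
      if (phase[j] > 1.0) phase[j] = 1.0;
      prev[j] = I;
    }
    if (scheme == SCHEME_RESET && spiker >= 0) {
      // retrograde propagation: the spike resets initiation at the *other*
      // zones; the spiking zone keeps its own post-spike phase remainder,
      // so a single-branch neuron behaves identically under all schemes
      for (int j = 0; j < nbranch; ++j)
        if (j != spiker) phase[j] = 0.0;
    }
  }
  return spikes;
}

// Generic driver: precomputed drive (Hz) and effective indentation (mm)
// matrices, nticks x nbranch. Returns 1-based spike tick indices.
// [[Rcpp::export]]
IntegerVector sim_drive_cpp(NumericMatrix I, NumericMatrix eff, double dt_ms,
                            double max_rate, int scheme, double spike_thresh) {
  std::vector<int> sp = run_branches(
      I.nrow(), I.ncol(), dt_ms, max_rate, scheme, spike_thresh,
      [&](int t, int j) { return I(t, j); },
      [&](int t, int j) { return eff(t, j); });
  IntegerVector out(sp.size());
  for (size_t i = 0; i < sp.size(); ++i) out[i] = sp[i] + 1;
  return out;
}

// Fast path for an infinite moving edge. b[j] is the mechanoreceptor's signed
// offset along the edge normal, s(t) = s0 + slope * t the line offset, so
// d(t, j) = |b[j] - s(t)|. A[j] is the local stimulus amplitude (mm) at the
// mechanoreceptor (noise already applied), w the shared input weight.
// [[Rcpp::export]]
IntegerVector sim_edge_cpp(NumericVector b, double s0, double slope,
                           NumericVector A, double w, double r1, double r2,
                           double max_rate, int nticks, double dt_ms,
                           int scheme, double spike_thresh) {
  const int n = b.size();
  const double reach = r1 + r2;
  std::vector<double> effbuf(static_cast<size_t>(nticks) * n);
  for (int t = 0; t < nticks; ++t) {
    const double s = s0 + slope * (t * dt_ms);
    for (int j = 0; j < n; ++j) {
      const double d = std::fabs(b[j] - s);
      double eff = 0.0;
      if (d <= reach)
        eff = A[j] * (1.0 - 1.0 / (1.0 + std::exp(-5.0 * (d / r1 - 1.0))));
      effbuf[static_cast<size_t>(t) * n + j] = eff;
    }
  }
  std::vector<int> sp = run_branches(
      nticks, n, dt_ms, max_rate, scheme, spike_thresh,
      [&](int t, int j) { return w * effbuf[static_cast<size_t>(t) * n + j]; },
      [&](int t, int j) { return effbuf[static_cast<size_t>(t) * n + j]; });
  IntegerVector out(sp.size());
  for (size_t i = 0; i < sp.size(); ++i) out[i] = sp[i] + 1;
  return out;
}

// Classifier fitness for a whole GA generation. F: stacked PSP features,
// rows = ticks of all trials concatenated, cols = (neuron x channel) inputs.
// group: 1-based trial id per row. Wpos/Wneg: weight matrices, one column per
// genome, for the unit tuned to the trial's positive / negative label.
// is_pos[trial]: whether the trial's correct unit is the positive one.
// Returns success rate (ties count 1/2) and mean margin per genome.
// [[Rcpp::export]]
List classifier_eval_cpp(NumericMatrix F, IntegerVector group,
                         NumericMatrix Wpos, NumericMatrix Wneg,
                         LogicalVector is_pos) {
  const int rows = F.nrow(), M = F.ncol(), G = Wpos.ncol();
  const int ntrial = is_pos.size();
  NumericVector success(G), margin(G);
  std::vector<double> ypos(rows), yneg(rows);
  for (int g = 0; g < G; ++g) {
    std::fill(ypos.begin(), ypos.end(), 0.0);
    std::fill(yneg.begin(), yneg.end(), 0.0);
    for (int m = 0; m < M; ++m) {
      const double wp = Wpos(m, g), wn = Wneg(m, g);
      const double* col = &F(0, m);
      if (wp != 0.0)
        for (int r = 0; r < rows; ++r) ypos[r] += wp * col[r];
      if (wn != 0.0)
        for (int r = 0; r < rows; ++r) yneg[r] += wn * col[r];
    }
    std::vector<double> rpos(ntrial, -std::numeric_limits<double>::infinity());
    std::vector<double> rneg(ntrial, -std::numeric_limits<double>::infinity());
    for (int r = 0; r < rows; ++r) {
      const int tr = group[r] - 1;
      rpos[tr] = std::max(rpos[tr], ypos[r]);
      rneg[tr] = std::max(rneg[tr], yneg[r]);
    }
    double ok = 0.0, msum = 0.0;
    for (int tr = 0; tr < ntrial; ++tr) {
      const double m2 = is_pos[tr] ? rpos[tr] - rneg[tr] : rneg[tr] - rpos[tr];
      if (m2 > 0.0)
        ok += 1.0;
      else if (m2 == 0.0)
        ok += 0.5;
      msum += m2;
    }
    success[g] = ok / ntrial;
    margin[g] = msum / ntrial;
  }
  return List::create(_["success"] = success, _["margin"] = margin);
}

// Maximum of each column of M within each consecutive row group (1-based ids).
// [[Rcpp::export]]
NumericMatrix group_col_max_cpp(NumericMatrix M, IntegerVector group,
                                int ngroup) {
  const int rows = M.nrow(), cols = M.ncol();
  NumericMatrix out(ngroup, cols);
  std::fill(out.begin(), out.end(), -std::numeric_limits<double>::infinity());
  for (int c = 0; c < cols; ++c)
    for (int r = 0; r < rows; ++r) {
      const int g = group[r] - 1;
      if (M(r, c) > out(g, c)) out(g, c) = M(r, c);
    }
  return out;
}
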