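#include <Rcpp.h>
using namespace Rcpp;

// Core trial loop for one agent. Payoffs arrive already normalized.
//
// Uses R's RNG stream (unif_rand) with a fixed draw order per trial:
//   [lapse draw, only when epsilon > 0] -> choice draw -> loss draw
// so a run is bit-identical to the pure-R reference engine under the same
// seed; the test suite relies on that equivalence as a dual-route check.
//
// rule: 0 = matching (values rectified at value_floor), 1 = softmax.
// On a lapse trial the choice draw itself indexes a uniform deck.
// decay_unchosen: optionally decays unchosen values toward 0 at rate M.
// [[Rcpp::export(name = ".run_agent_cpp")]]
List run_agent_cpp(NumericVector gain, NumericVector loss_mag,
                   NumericVector loss_prob, double memory, double gs,
                   double ls, int n_trials, int rule, double temperature,
                   double value_floor, double epsilon, double v_init,
                   bool decay_unchosen) {
  const int k = gain.size();
  std::vector<double> v(k, v_init), p(k), w(k);
  IntegerVector choice(n_trials);
  NumericVector gain_out(n_trials), loss_out(n_trials), gn_out(n_trials);
  NumericMatrix values(n_trials, k), probs(n_trials, k);

  for (int t = 0; t < n_trials; ++t) {
    // long double accumulators mirror R's extended-precision sum()/cumsum()
    if (rule == 0) {
      long double s = 0.0;
      for (int j = 0; j < k; ++j) {
        w[j] = v[j] > value_floor ? v[j] : value_floor;
        s += w[j];
      }
      for (int j = 0; j < k; ++j) p[j] = w[j] / (double)s;
    } else {
      double vmax = v[0];
      for (int j = 1; j < k; ++j) vmax = std::max(vmax, v[j]);
      long double s = 0.0;
      for (int j = 0; j < k; ++j) {
        w[j] = std::exp((v[j] - vmax) / temperature);
        s += w[j];
      }
      for (int j = 0; j < k; ++j) p[j] = w[j] / (double)s;
    }

    bool lapse = false;
    if (epsilon > 0.0) lapse = unif_rand() < epsilon;
    double u = unif_rand();
    int deck;
    if (lapse) {
      deck = std::min((int)(u * k), k - 1);
    } else {
      deck = k - 1;
      long double c = 0.0;
      for (int j = 0; j < k; ++j) {
        c += p[j];
        if (u < (double)c) { deck = j; break; }
      }
    }

    double loss = (unif_rand() < loss_prob[deck]) ? loss_mag[deck] : 0.0;
    double gn = gain[deck] * gs - loss * ls;
    if (decay_unchosen)
      for (int j = 0; j < k; ++j)
        if (j != deck) v[j] = memory * v[j];
    v[deck] = memory * v[deck] + (1.0 - memory) * gn;

    choice[t] = deck + 1;
    gain_out[t] = gain[deck];
    loss_out[t] = loss;
    gn_out[t] = gn;
    for (int j = 0; j < k; ++j) {
      values(t, j) = v[j];
      probs(t, j) = p[j];
    }
  }

  return List::create(_["choice"] = choice, _["gain"] = gain_out,
                      _["loss"] = loss_out, _["net_gain"] = gn_out,
                      _["values"] = values, _["probs"] = probs);
}
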