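#include <Rcpp.h>
using namespace Rcpp;

// Online Kohonen self-organizing map with a Gaussian grid neighbourhood.
// The learning rate and neighbourhood radius both decay linearly over
// the presentation schedule. `order` holds the 0-based presentation
// order for every epoch, generated on the R side from a seeded RNG so
// training is fully reproducible.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix data, NumericMatrix proto_init,
                   IntegerMatrix order, NumericMatrix grid_pos,
                   double alpha0, double alpha1,
                   double radius0, double radius1) {
  NumericMatrix proto = clone(proto_init);
  const int n = data.nrow(), d = data.ncol(), m = proto.nrow();
  const int epochs = order.nrow();
  NumericVector qe(epochs);
  const double total = (double)epochs * n;
  double step = 0;

  for (int e = 0; e < epochs; ++e) {
    double qsum = 0;
    for (int t = 0; t < n; ++t, ++step) {
      double frac = (total <= 1) ? 0.0 : step / (total - 1.0);
      double alpha = alpha0 + (alpha1 - alpha0) * frac;
      double radius = radius0 + (radius1 - radius0) * frac;
      if (radius < 1e-6) radius = 1e-6;
      int i = order(e, t);

      int best = 0; double bestd = R_PosInf;
      for (int u = 0; u < m; ++u) {
        double s = 0;
        for (int k = 0; k < d; ++k) {
          double df = data(i, k) - proto(u, k); s += df * df;
        }
        if (s < bestd) { bestd = s; best = u; }
      }
      qsum += std::sqrt(bestd);

      double denom = 2.0 * radius * radius;
      for (int u = 0; u < m; ++u) {
        double gr = grid_pos(u, 0) - grid_pos(best, 0);
        double gc = grid_pos(u, 1) - grid_pos(best, 1);
        double h = std::exp(-(gr * gr + gc * gc) / denom);
        if (h < 1e-8) continue;
        for (int k = 0; k < d; ++k)
          proto(u, k) += alpha * h * (data(i, k) - proto(u, k));
      }
    }
    qe[e] = qsum / n;
  }

  IntegerVector label(n);
  NumericVector bmu_dist(n);
  for (int i = 0; i < n; ++i) {
    int best = 0; double bestd = R_PosInf;
    for (int u = 0; u < m; ++u) {
      double s = 0;
      for (int k = 0; k < d; ++k) {
        double df = data(i, k) - proto(u, k); s += df * df;
      }
      if (s < bestd) { bestd = s; best = u; }
    }
    label[i] = best + 1;
    bmu_dist[i] = std::sqrt(bestd);
  }
  return List::create(_["prototypes"] = proto, _["labels"] = label,
                      _["qe"] = qe, _["bmu_dist"] = bmu_dist);
}
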