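#include <Rcpp.h>
using namespace Rcpp;

// Vector field of the logic-derived ODE system.
//
// x:     current state (length N)
// spec:  per dynamic node, a list with
//          inputs0 : 0-based indices of the node's distinct inputs
//          n_h     : Hill exponents, one per input
//          Kn      : K^n_h, one per input (precomputed)
//          grid    : (2^d x d) 0/1 matrix of Boolean input vertices
//          truth   : Boolean update value at each vertex
//          target0 : 0-based index of the node
//          tau     : time constant
// fixed0: 0-based indices of clamped nodes (cues), dx forced to 0
//
// Every other node relaxes to 0 with unit time constant; dynamic nodes
// follow (Bbar - x) / tau with Bbar the multilinear interpolation of the
// truth table at the Hill-transformed inputs.
// [[Rcpp::export(name = ".logic_ode_rhs")]]
NumericVector logic_ode_rhs(NumericVector x, List spec,
                            IntegerVector fixed0) {
  const int N = x.size();
  NumericVector dx(N);
  for (int i = 0; i < N; ++i) dx[i] = -x[i];

  const int n_nodes = spec.size();
  for (int s = 0; s < n_nodes; ++s) {
    List nd = spec[s];
    IntegerVector inputs = nd["inputs0"];
    NumericVector n_h = nd["n_h"];
    NumericVector Kn = nd["Kn"];
    NumericMatrix grid = nd["grid"];
    NumericVector truth = nd["truth"];
    const int target = as<int>(nd["target0"]);
    const double tau = as<double>(nd["tau"]);

    const int d = inputs.size();
    std::vector<double> w(d);
    for (int j = 0; j < d; ++j) {
      double xi = x[inputs[j]];
      if (xi < 0) xi = 0; else if (xi > 1) xi = 1;
      const double xn = std::pow(xi, n_h[j]);
      w[j] = xn * (1.0 + Kn[j]) / (xn + Kn[j]);
    }
    double bbar = 0.0;
    const int R = grid.nrow();
    for (int r = 0; r < R; ++r) {
      double weight = 1.0;
      for (int j = 0; j < d; ++j)
        weight *= grid(r, j) == 1.0 ? w[j] : 1.0 - w[j];
      bbar += weight * truth[r];
    }
    dx[target] = (bbar - x[target]) / tau;
  }
  for (int k = 0; k < fixed0.size(); ++k) dx[fixed0[k]] = 0.0;
  return dx;
}
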