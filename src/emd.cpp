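// R-facing wrapper for the transport solver (see emd.h).

#include <Rcpp.h>
#include "emd.h"

// [[Rcpp::export]]
double cpp_transport(Rcpp::NumericVector supply, Rcpp::NumericVector demand,
                     Rcpp::NumericMatrix cost) {
  if (cost.nrow() != supply.size() || cost.ncol() != demand.size())
    Rcpp::stop("cost matrix dimensions must match the mass vectors");
  std::vector<double> a(supply.begin(), supply.end());
  std::vector<double> b(demand.begin(), demand.end());
  return schoolphi::transport_min_cost(
      a, b, [&](int i, int j) { return cost(i, j); });
}
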