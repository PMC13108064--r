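// Hot kernels of the neural-network training loop: im2col/col2im for 1D
// convolution, max pooling, batch normalization, and the Adam update.
// Layout matches R/nn_layers.R: sequence activations are (C, L, B) arrays,
// unrolled activations are (features x columns) matrices, column-major.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector X, int C, int L, int B, int k) {
  int Lo = L - k + 1;
  NumericMatrix M(k * C, Lo * B);
  const double* x = X.begin();
  double* m = M.begin();
  int nrowM = k * C;
  for (int b = 0; b < B; ++b) {
    for (int p = 0; p < Lo; ++p) {
      double* mcol = m + (size_t)(b * Lo + p) * nrowM;
      const double* xbase = x + (size_t)b * C * L + (size_t)p * C;
      for (int j = 0; j < k; ++j) {
        const double* xs = xbase + (size_t)j * C;
        double* md = mcol + j * C;
        for (int c = 0; c < C; ++c) md[c] = xs[c];
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dM, int C, int L, int B, int k) {
  int Lo = L - k + 1;
  NumericVector dX((size_t)C * L * B);
  double* dx = dX.begin();
  const double* dm = dM.begin();
  int nrowM = k * C;
  for (int b = 0; b < B; ++b) {
    for (int p = 0; p < Lo; ++p) {
      const double* mcol = dm + (size_t)(b * Lo + p) * nrowM;
      double* xbase = dx + (size_t)b * C * L + (size_t)p * C;
      for (int j = 0; j < k; ++j) {
        const double* ms = mcol + j * C;
        double* xd = xbase + (size_t)j * C;
        for (int c = 0; c < C; ++c) xd[c] += ms[c];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(C, L, B);
  return dX;
}

// max pool size 2 along positions; returns Y (C, Lo, B) and the argmax mask
// [[Rcpp::export]]
List cpp_pool2_fwd(NumericVector X, int C, int L, int B) {
  int Lo = L / 2;
  NumericVector Y((size_t)C * Lo * B);
  LogicalVector mask((size_t)C * Lo * B);
  const double* x = X.begin();
  double* y = Y.begin();
  int* mk = LOGICAL(mask);
  for (int b = 0; b < B; ++b) {
    for (int p = 0; p < Lo; ++p) {
      const double* x1 = x + (size_t)b * C * L + (size_t)(2 * p) * C;
      const double* x2 = x1 + C;
      double* yd = y + (size_t)b * C * Lo + (size_t)p * C;
      int* md = mk + (size_t)b * C * Lo + (size_t)p * C;
      for (int c = 0; c < C; ++c) {
        bool first = x1[c] >= x2[c];
        yd[c] = first ? x1[c] : x2[c];
        md[c] = first;
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(C, Lo, B);
  return List::create(_["Y"] = Y, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericVector cpp_pool2_bwd(NumericVector dY, LogicalVector mask,
                            int C, int L, int B) {
  int Lo = L / 2;
  NumericVector dX((size_t)C * L * B);
  const double* dy = dY.begin();
  const int* mk = LOGICAL(mask);
  double* dx = dX.begin();
  for (int b = 0; b < B; ++b) {
    for (int p = 0; p < Lo; ++p) {
      const double* ys = dy + (size_t)b * C * Lo + (size_t)p * C;
      const int* ms = mk + (size_t)b * C * Lo + (size_t)p * C;
      double* x1 = dx + (size_t)b * C * L + (size_t)(2 * p) * C;
      double* x2 = x1 + C;
      for (int c = 0; c < C; ++c) {
        if (ms[c]) x1[c] = ys[c]; else x2[c] = ys[c];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(C, L, B);
  return dX;
}

// batch norm forward over rows (channels) of Z (F x N); returns xhat, Y,
// batch mean and inverse SD
// [[Rcpp::export]]
List cpp_bn_fwd(NumericMatrix Z, NumericVector gamma, NumericVector beta,
                double eps) {
  int F = Z.nrow(), N = Z.ncol();
  NumericVector mu(F), inv_std(F);
  NumericMatrix xhat(F, N), Y(F, N);
  const double* z = Z.begin();
  const double* ga = gamma.begin();
  const double* be = beta.begin();
  double* pmu = mu.begin();
  double* pis = inv_std.begin();
  std::vector<double> s2v(F, 0.0);
  for (int j = 0; j < N; ++j) {
    const double* zc = z + (size_t)j * F;
    for (int f = 0; f < F; ++f) {
      pmu[f] += zc[f];
      s2v[f] += zc[f] * zc[f];
    }
  }
  for (int f = 0; f < F; ++f) {
    double m = pmu[f] / N;
    double var = s2v[f] / N - m * m;
    pmu[f] = m;
    pis[f] = 1.0 / std::sqrt(var + eps);
  }
  double* xh = xhat.begin();
  double* y = Y.begin();
  for (int j = 0; j < N; ++j) {
    const double* zc = z + (size_t)j * F;
    double* xc = xh + (size_t)j * F;
    double* yc = y + (size_t)j * F;
    for (int f = 0; f < F; ++f) {
      double v = (zc[f] - pmu[f]) * pis[f];
      xc[f] = v;
      yc[f] = ga[f] * v + be[f];
    }
  }
  return List::create(_["xhat"] = xhat, _["Y"] = Y, _["mean"] = mu,
                      _["inv_std"] = inv_std);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix dY, NumericMatrix xhat, NumericVector inv_std,
                NumericVector gamma) {
  int F = dY.nrow(), N = dY.ncol();
  NumericVector s1(F), s2(F);
  const double* dy = dY.begin();
  const double* xh = xhat.begin();
  const double* ga = gamma.begin();
  const double* is = inv_std.begin();
  double* p1 = s1.begin();
  double* p2 = s2.begin();
  for (int j = 0; j < N; ++j) {
    const double* dc = dy + (size_t)j * F;
    const double* xc = xh + (size_t)j * F;
    for (int f = 0; f < F; ++f) {
      double dxh = ga[f] * dc[f];
      p1[f] += dxh;
      p2[f] += dxh * xc[f];
    }
  }
  NumericMatrix dZ(F, N);
  double* dz = dZ.begin();
  for (int j = 0; j < N; ++j) {
    const double* dc = dy + (size_t)j * F;
    const double* xc = xh + (size_t)j * F;
    double* zc = dz + (size_t)j * F;
    for (int f = 0; f < F; ++f) {
      double dxh = ga[f] * dc[f];
      zc[f] = (dxh - p1[f] / N - xc[f] * (p2[f] / N)) * is[f];
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = s2, _["dbeta"] = s1);
}

// Adam step over a list of parameters; returns updated copies (the moment
// buffers m and v are updated in place, they are owned by the optimizer)
// [[Rcpp::export]]
List cpp_adam_step(List params, List grads, List m, List v, int t,
                   double lr, double beta1, double beta2, double eps) {
  double bc1 = 1.0 - std::pow(beta1, t);
  double bc2 = 1.0 - std::pow(beta2, t);
  CharacterVector nms = grads.names();
  List out = clone(params);
  for (int i = 0; i < grads.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    NumericVector gv = grads[nm];
    NumericVector mv = m[nm];
    NumericVector vvv = v[nm];
    NumericVector pv = out[nm];
    const double* g = gv.begin();
    double* mm = mv.begin();
    double* vv = vvv.begin();
    double* p = pv.begin();
    R_xlen_t n = gv.size();
    for (R_xlen_t j = 0; j < n; ++j) {
      mm[j] = beta1 * mm[j] + (1 - beta1) * g[j];
      vv[j] = beta2 * vv[j] + (1 - beta2) * g[j] * g[j];
      p[j] -= lr * (mm[j] / bc1) / (std::sqrt(vv[j] / bc2) + eps);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector X) {
  NumericVector Y(X.size());
  const double* x = X.begin();
  double* y = Y.begin();
  R_xlen_t n = X.size();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  Y.attr("dim") = X.attr("dim");
  return Y;
}

// [[Rcpp::export]]
NumericVector cpp_drelu(NumericVector dY, NumericVector X) {
  NumericVector dX(dY.size());
  const double* dy = dY.begin();
  const double* x = X.begin();
  double* dx = dX.begin();
  R_xlen_t n = dY.size();
  for (R_xlen_t i = 0; i < n; ++i) dx[i] = x[i] > 0 ? dy[i] : 0.0;
  dX.attr("dim") = dY.attr("dim");
  return dX;
}

// inverted dropout given pre-drawn uniforms (RNG stays on the R side)
// [[Rcpp::export]]
List cpp_dropout_fwd(NumericVector X, NumericVector U, double p) {
  R_xlen_t n = X.size();
  NumericVector Y(n), mask(n);
  const double* x = X.begin();
  const double* u = U.begin();
  double* y = Y.begin();
  double* mk = mask.begin();
  double keep = 1.0 / (1.0 - p);
  for (R_xlen_t i = 0; i < n; ++i) {
    double m = u[i] >= p ? keep : 0.0;
    mk[i] = m;
    y[i] = x[i] * m;
  }
  Y.attr("dim") = X.attr("dim");
  mask.attr("dim") = X.attr("dim");
  return List::create(_["Y"] = Y, _["mask"] = mask);
}
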