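// Core of the velocity-field network: fused forward / reverse passes of the
// FA-NN -> FPE -> DF-NN multilayer perceptron. The trilinear code lookup and
// all orchestration stay in R; this file only removes the elementwise and
// allocation overhead of the dense layer stack on large point batches.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat asMat(SEXP s) {
  NumericMatrix m(s);
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
static arma::vec asVec(SEXP s) {
  NumericVector v(s);
  return arma::vec(v.begin(), v.size(), false, true);
}

static void leakyInplace(arma::mat& a, arma::mat& ag, double slope) {
  ag.set_size(a.n_rows, a.n_cols);
  double* pa = a.memptr();
  double* pg = ag.memptr();
  const arma::uword n = a.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    if (pa[i] > 0) {
      pg[i] = 1.0;
    } else {
      pg[i] = slope;
      pa[i] *= slope;
    }
  }
}

static arma::mat fpe(const arma::mat& u, int n_e) {
  const arma::uword w = u.n_cols;
  arma::mat out(u.n_rows, (2 * n_e + 1) * w);
  out.cols(0, w - 1) = u;
  if (n_e >= 1) {
    out.cols(w, 2 * w - 1) = arma::sin(M_PI * u);
    out.cols(2 * w, 3 * w - 1) = arma::cos(M_PI * u);
  }
  // higher octaves by the double-angle identities on the base octave
  for (int e = 2; e <= n_e; ++e) {
    const arma::mat s = out.cols((2 * e - 3) * w, (2 * e - 2) * w - 1);
    const arma::mat c = out.cols((2 * e - 2) * w, (2 * e - 1) * w - 1);
    out.cols((2 * e - 1) * w, 2 * e * w - 1) = 2.0 * (s % c);
    out.cols(2 * e * w, (2 * e + 1) * w - 1) = 1.0 - 2.0 * (s % s);
  }
  return out;
}

// params: list in order fa1.W, fa1.b, ..., df1.W, df1.b, ..., head.W, head.b
// [[Rcpp::export]]
List cpp_mlp_forward(const arma::mat& x, const arma::mat& zbar, List params,
                     int fa_layers, int df_layers, int n_e, double slope) {
  int ip = 0;
  arma::mat h = arma::join_rows(x, zbar);
  List faIn(fa_layers), faAg(fa_layers);
  for (int l = 0; l < fa_layers; ++l) {
    faIn[l] = h;
    arma::mat W = asMat(params[ip++]);
    arma::vec b = asVec(params[ip++]);
    h = h * W;
    h.each_row() += b.t();
    if (l < fa_layers - 1) {
      arma::mat ag;
      leakyInplace(h, ag, slope);
      faAg[l] = ag;
    }
  }
  arma::mat u = h;
  arma::mat enc = fpe(u, n_e);
  h = arma::join_rows(enc, zbar);
  List dfIn(df_layers), dfAg(df_layers);
  for (int l = 0; l < df_layers; ++l) {
    dfIn[l] = h;
    arma::mat W = asMat(params[ip++]);
    arma::vec b = asVec(params[ip++]);
    h = h * W;
    h.each_row() += b.t();
    arma::mat ag;
    leakyInplace(h, ag, slope);
    dfAg[l] = ag;
  }
  arma::mat Wh = asMat(params[ip++]);
  arma::vec bh = asVec(params[ip++]);
  arma::mat v = h * Wh;
  v.each_row() += bh.t();
  return List::create(_["v"] = v, _["u"] = u, _["faIn"] = faIn,
                      _["faAg"] = faAg, _["dfIn"] = dfIn, _["dfAg"] = dfAg,
                      _["dfOut"] = h);
}

// [[Rcpp::export]]
List cpp_mlp_backward(const arma::mat& dv, List cache, List params,
                      int fa_layers, int df_layers, int n_e, double slope,
                      int code_channels) {
  List faIn = cache["faIn"], faAg = cache["faAg"];
  List dfIn = cache["dfIn"], dfAg = cache["dfAg"];
  arma::mat u = asMat(cache["u"]);
  arma::mat dfOut = asMat(cache["dfOut"]);
  const int np = 2 * (fa_layers + df_layers) + 2;
  List grads(np);
  int ip = np - 2;
  arma::mat Wh = asMat(params[ip]);
  grads[ip] = wrap(arma::mat(dfOut.t() * dv));
  grads[ip + 1] = wrap(arma::vec(arma::sum(dv, 0).t()));
  arma::mat dh = dv * Wh.t();
  for (int l = df_layers - 1; l >= 0; --l) {
    arma::mat da = dh % asMat(dfAg[l]);
    arma::mat hin = asMat(dfIn[l]);
    ip = 2 * (fa_layers + l);
    arma::mat W = asMat(params[ip]);
    grads[ip] = wrap(arma::mat(hin.t() * da));
    grads[ip + 1] = wrap(arma::vec(arma::sum(da, 0).t()));
    dh = da * W.t();
  }
  const arma::uword w = u.n_cols;
  arma::mat dzbar =
      dh.cols(dh.n_cols - code_channels, dh.n_cols - 1);
  // FPE backward; the sin/cos blocks are reused from the forward encoding
  // (first df layer input) instead of being recomputed
  arma::mat enc = (df_layers > 0) ? asMat(dfIn[0]) : fpe(u, n_e);
  arma::mat du = dh.cols(0, w - 1);
  for (int e = 1; e <= n_e; ++e) {
    const double f = std::pow(2.0, e - 1) * M_PI;
    du += f * (enc.cols(2 * e * w, (2 * e + 1) * w - 1) %
                   dh.cols((2 * e - 1) * w, 2 * e * w - 1) -
               enc.cols((2 * e - 1) * w, 2 * e * w - 1) %
                   dh.cols(2 * e * w, (2 * e + 1) * w - 1));
  }
  dh = du;
  for (int l = fa_layers - 1; l >= 0; --l) {
    arma::mat da = (l < fa_layers - 1) ? arma::mat(dh % asMat(faAg[l])) : dh;
    arma::mat hin = asMat(faIn[l]);
    ip = 2 * l;
    arma::mat W = asMat(params[ip]);
    grads[ip] = wrap(arma::mat(hin.t() * da));
    grads[ip + 1] = wrap(arma::vec(arma::sum(da, 0).t()));
    dh = da * W.t();
  }
  arma::mat dx = dh.cols(0, 2);
  dzbar += dh.cols(3, dh.n_cols - 1);
  return List::create(_["dx"] = dx, _["dzbar"] = dzbar,
                      _["dparams"] = grads);
}
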