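#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensor batches are numeric arrays with dim (H, W, C, N), column-major,
// row index (northing) fastest. Conv weights are (k*k*Cin) x Cout matrices
// whose row order is (ki, kj, ci) with ki fastest, matching im2col below.

static void im2col_one(const double* x, int H, int W, int C,
                       int k, int stride, int pad,
                       int Ho, int Wo, arma::mat& M) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      double* col = M.colptr(p);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < k; ++kj) {
          int wi = wo * stride + kj - pad;
          for (int ki = 0; ki < k; ++ki) {
            int hi = ho * stride + ki - pad;
            int row = ki + k * (kj + k * c);
            col[row] = (hi >= 0 && hi < H && wi >= 0 && wi < W)
              ? x[hi + H * (wi + W * c)] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                           int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int KK = w.nrow();
  int k = (int) std::lround(std::sqrt((double) KK / C));
  if (k * k * C != KK) stop("weight rows inconsistent with input channels");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int Cout = w.ncol();
  arma::mat Wm(w.begin(), KK, Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y((R_xlen_t) Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat M(KK, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (R_xlen_t) n * H * W * C, H, W, C,
               k, stride, pad, Ho, Wo, M);
    arma::mat Yn = M.t() * Wm;       // (Ho*Wo) x Cout, matches (Ho,Wo,Cout)
    Yn.each_row() += bv;
    std::copy(Yn.begin(), Yn.end(), y.begin() + (R_xlen_t) n * Ho * Wo * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                  int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dd = dy.attr("dim");
  int Ho = dd[0], Wo = dd[1], Cout = dd[2];
  int KK = w.nrow();
  int k = (int) std::lround(std::sqrt((double) KK / C));
  arma::mat Wm(w.begin(), KK, Cout, false);
  NumericVector dx((R_xlen_t) H * W * C * N);
  dx.attr("dim") = d;
  arma::mat dW(KK, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat M(KK, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (R_xlen_t) n * H * W * C;
    double* dxn = dx.begin() + (R_xlen_t) n * H * W * C;
    im2col_one(xn, H, W, C, k, stride, pad, Ho, Wo, M);
    arma::mat dYn(dy.begin() + (R_xlen_t) n * Ho * Wo * Cout,
                  Ho * Wo, Cout, false);
    dW += M * dYn;
    db += arma::sum(dYn, 0);
    arma::mat dM = Wm * dYn.t();    // KK x (Ho*Wo)
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int p = ho + Ho * wo;
        const double* col = dM.colptr(p);
        for (int c = 0; c < C; ++c) {
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              dxn[hi + H * (wi + W * c)] += col[ki + k * (kj + k * c)];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Exact t-SNE gradient descent (symmetric P, Student-t kernel in the
// embedding), with early exaggeration, gains and momentum as in the
// original algorithm. Deterministic given P and Y0.
// [[Rcpp::export]]
arma::mat cpp_tsne_grad(const arma::mat& P, arma::mat Y, int maxIter,
                        double lr, double exaggeration, int exagIter,
                        double initialMomentum, double finalMomentum,
                        int momentumSwitch) {
  int n = Y.n_rows, dims = Y.n_cols;
  arma::mat iY(n, dims, arma::fill::zeros);
  arma::mat gains(n, dims, arma::fill::ones);
  for (int iter = 0; iter < maxIter; ++iter) {
    arma::mat Pc = (iter < exagIter) ? arma::mat(P * exaggeration) : P;
    arma::colvec sumY = arma::sum(arma::square(Y), 1);
    arma::mat num = -2.0 * (Y * Y.t());
    num.each_col() += sumY;
    num.each_row() += sumY.t();
    num = 1.0 / (1.0 + num);
    num.diag().zeros();
    double s = arma::accu(num);
    if (s <= 0) s = 1e-12;
    arma::mat Q = num / s;
    Q.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
    arma::mat L = (Pc - Q) % num;
    arma::colvec rs = arma::sum(L, 1);
    arma::mat dY = 4.0 * (Y.each_col() % rs - L * Y);
    for (int j = 0; j < dims; ++j) {
      for (int i = 0; i < n; ++i) {
        bool sameSign = (dY(i, j) > 0) == (iY(i, j) > 0);
        double g = sameSign ? gains(i, j) * 0.8 : gains(i, j) + 0.2;
        gains(i, j) = g < 0.01 ? 0.01 : g;
      }
    }
    double momentum = iter < momentumSwitch ? initialMomentum : finalMomentum;
    iY = momentum * iY - lr * (gains % dY);
    Y += iY;
    Y.each_row() -= arma::mean(Y, 0);
  }
  return Y;
}
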