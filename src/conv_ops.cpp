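// Compact CPU kernels for the 2D convolutional network and component labeling.
// Tensor layout follows R column-major arrays: x[H, W, C, N] (row index fastest).
// Weights: conv w[kh, kw, Cin, Cout]; transposed conv w[k, k, Cin, Cout] with
// kernel size equal to the stride (non-overlapping upsampling blocks).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword idx4(arma::uword i, arma::uword j, arma::uword c,
                               arma::uword n, arma::uword H, arma::uword W,
                               arma::uword C) {
  return i + H * (j + W * (c + C * n));
}

// im2col for one sample: returns (Ho*Wo) x (kh*kw*Cin)
static void im2col_one(const double* x, arma::uword H, arma::uword W,
                       arma::uword C, int kh, int kw, int stride, int pad,
                       arma::uword Ho, arma::uword Wo, arma::mat& K) {
  for (arma::uword c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        arma::uword col = ki + kh * (kj + kw * c);
        double* Kcol = K.colptr(col);
        for (arma::uword wo = 0; wo < Wo; ++wo) {
          long jj = (long)wo * stride - pad + kj;
          bool jok = jj >= 0 && jj < (long)W;
          for (arma::uword ho = 0; ho < Ho; ++ho) {
            long ii = (long)ho * stride - pad + ki;
            double v = 0.0;
            if (jok && ii >= 0 && ii < (long)H)
              v = x[ii + H * (jj + W * c)];
            Kcol[ho + Ho * wo] = v;
          }
        }
      }
    }
  }
}

// col2im (adjoint): accumulate K (Ho*Wo x kh*kw*Cin) back into dx for one sample
static void col2im_one(const arma::mat& K, double* dx, arma::uword H,
                       arma::uword W, arma::uword C, int kh, int kw, int stride,
                       int pad, arma::uword Ho, arma::uword Wo) {
  for (arma::uword c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        arma::uword col = ki + kh * (kj + kw * c);
        const double* Kcol = K.colptr(col);
        for (arma::uword wo = 0; wo < Wo; ++wo) {
          long jj = (long)wo * stride - pad + kj;
          if (jj < 0 || jj >= (long)W) continue;
          for (arma::uword ho = 0; ho < Ho; ++ho) {
            long ii = (long)ho * stride - pad + ki;
            if (ii < 0 || ii >= (long)H) continue;
            dx[ii + H * (jj + W * c)] += Kcol[ho + Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  arma::uword Cout = wd[3];
  if ((arma::uword)wd[2] != C) stop("conv2d: channel mismatch");
  arma::uword Ho = (H + 2 * pad - kh) / stride + 1;
  arma::uword Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Cout, false, true);
  arma::mat K(Ho * Wo, kh * kw * C);
  for (arma::uword n = 0; n < N; ++n) {
    im2col_one(x.begin() + idx4(0, 0, 0, n, H, W, C), H, W, C, kh, kw, stride,
               pad, Ho, Wo, K);
    arma::mat Y = K * Wm;
    for (arma::uword co = 0; co < Cout; ++co)
      Y.col(co) += b[co];
    std::copy(Y.begin(), Y.end(), y.begin() + idx4(0, 0, 0, n, Ho, Wo, Cout));
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy, int stride,
                int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  arma::uword Cout = wd[3];
  arma::uword Ho = yd[0], Wo = yd[1];
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Cout, false, true);
  arma::mat dWm(dw.begin(), kh * kw * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat K(Ho * Wo, kh * kw * C);
  for (arma::uword n = 0; n < N; ++n) {
    const double* xs = x.begin() + idx4(0, 0, 0, n, H, W, C);
    arma::mat dY(const_cast<double*>(dy.begin()) +
                     idx4(0, 0, 0, n, Ho, Wo, Cout),
                 Ho * Wo, Cout, false, true);
    im2col_one(xs, H, W, C, kh, kw, stride, pad, Ho, Wo, K);
    dWm += K.t() * dY;
    dbv += arma::sum(dY, 0).t();
    arma::mat dK = dY * Wm.t();
    col2im_one(dK, dx.begin() + idx4(0, 0, 0, n, H, W, C), H, W, C, kh, kw,
               stride, pad, Ho, Wo);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution, kernel size == stride (no overlap, no padding).
// [[Rcpp::export(name = ".convt2d_fwd")]]
NumericVector convt2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                          int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  arma::uword Cout = wd[3];
  if (k != stride || wd[1] != k) stop("convt2d: kernel must equal stride");
  if ((arma::uword)wd[2] != C) stop("convt2d: channel mismatch");
  arma::uword Ho = H * stride, Wo = W * stride;
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  // Wm: Cin x (k*k*Cout) — reorder from w[k,k,Cin,Cout]
  arma::mat Wm(C, (arma::uword)k * k * Cout);
  for (arma::uword co = 0; co < Cout; ++co)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki)
        for (arma::uword c = 0; c < C; ++c)
          Wm(c, ki + k * (kj + k * co)) =
              w[ki + k * (kj + k * (c + C * co))];
  for (arma::uword n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + idx4(0, 0, 0, n, H, W, C),
                H * W, C, false, true);
    arma::mat Y = X * Wm;  // (H*W) x (k*k*Cout)
    double* yp = y.begin() + idx4(0, 0, 0, n, Ho, Wo, Cout);
    for (arma::uword co = 0; co < Cout; ++co)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          const double* Yc = Y.colptr(ki + k * (kj + k * co));
          for (arma::uword j = 0; j < W; ++j)
            for (arma::uword i = 0; i < H; ++i)
              yp[(stride * i + ki) + Ho * ((stride * j + kj) + Wo * co)] =
                  Yc[i + H * j] + b[co];
        }
  }
  return y;
}

// [[Rcpp::export(name = ".convt2d_bwd")]]
List convt2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  arma::uword Cout = wd[3];
  arma::uword Ho = H * stride, Wo = W * stride;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(C, (arma::uword)k * k * Cout);
  for (arma::uword co = 0; co < Cout; ++co)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki)
        for (arma::uword c = 0; c < C; ++c)
          Wm(c, ki + k * (kj + k * co)) =
              w[ki + k * (kj + k * (c + C * co))];
  arma::mat dWm(C, (arma::uword)k * k * Cout, arma::fill::zeros);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat dYg(H * W, (arma::uword)k * k * Cout);
  for (arma::uword n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + idx4(0, 0, 0, n, Ho, Wo, Cout);
    for (arma::uword co = 0; co < Cout; ++co)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          double* Gc = dYg.colptr(ki + k * (kj + k * co));
          for (arma::uword j = 0; j < W; ++j)
            for (arma::uword i = 0; i < H; ++i)
              Gc[i + H * j] =
                  dyp[(stride * i + ki) + Ho * ((stride * j + kj) + Wo * co)];
        }
    arma::mat X(const_cast<double*>(x.begin()) + idx4(0, 0, 0, n, H, W, C),
                H * W, C, false, true);
    dWm += X.t() * dYg;
    for (arma::uword co = 0; co < Cout; ++co)
      for (arma::uword col = (arma::uword)k * k * co;
           col < (arma::uword)k * k * (co + 1); ++col)
        dbv[co] += arma::accu(dYg.col(col));
    arma::mat dX = dYg * Wm.t();
    std::copy(dX.begin(), dX.end(), dx.begin() + idx4(0, 0, 0, n, H, W, C));
  }
  for (arma::uword co = 0; co < Cout; ++co)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki)
        for (arma::uword c = 0; c < C; ++c)
          dw[ki + k * (kj + k * (c + C * co))] =
              dWm(c, ki + k * (kj + k * co));
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Connected-component labeling by BFS. 2D: connectivity 4 or 8 on an H x W
// matrix. 3D: 26-connectivity on an H x W x D array (dims from the input).
// Labels are assigned in scan order of the first pixel (rows, then columns,
// then slices), starting at 1.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(IntegerVector mask, int connectivity) {
  IntegerVector md = mask.attr("dim");
  int H = md[0], W = md[1], D = md.size() == 3 ? (int)md[2] : 1;
  IntegerVector lab(mask.size());
  lab.attr("dim") = mask.attr("dim");
  std::vector<std::array<int, 3>> nb;
  if (md.size() == 3 && connectivity == 26) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          if (di || dj || dz) nb.push_back({di, dj, dz});
  } else if (connectivity == 8) {
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di)
        if (di || dj) nb.push_back({di, dj, 0});
  } else if (connectivity == 4) {
    nb = {{{1, 0, 0}}, {{-1, 0, 0}}, {{0, 1, 0}}, {{0, -1, 0}}};
  } else {
    stop("unsupported connectivity");
  }
  int next = 0;
  std::queue<int> q;
  for (int z = 0; z < D; ++z)
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j) {
        int p = i + H * (j + W * z);
        if (mask[p] == 0 || lab[p] != 0) continue;
        lab[p] = ++next;
        q.push(p);
        while (!q.empty()) {
          int c = q.front();
          q.pop();
          int ci = c % H, rest = c / H, cj = rest % W, cz = rest / W;
          for (auto& d : nb) {
            int ni = ci + d[0], nj = cj + d[1], nz = cz + d[2];
            if (ni < 0 || ni >= H || nj < 0 || nj >= W || nz < 0 || nz >= D)
              continue;
            int np = ni + H * (nj + W * nz);
            if (mask[np] != 0 && lab[np] == 0) {
              lab[np] = next;
              q.push(np);
            }
          }
        }
      }
  return lab;
}

// Fused batch-norm (+ optional ReLU) forward. x: (H, W, C, N).
// Training mode computes batch statistics and updated running stats;
// inference uses the running statistics.
// [[Rcpp::export(name = ".bnrelu_fwd")]]
List bnrelu_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, bool training,
                double momentum, double eps, bool relu) {
  IntegerVector xd = x.attr("dim");
  arma::uword HW = (arma::uword)xd[0] * xd[1], C = xd[2], N = xd[3];
  arma::uword m = HW * N;
  NumericVector mu(C), var_(C);
  if (training) {
    for (arma::uword n = 0; n < N; ++n)
      for (arma::uword c = 0; c < C; ++c) {
        const double* p = x.begin() + HW * (c + C * n);
        double s = 0, s2 = 0;
        for (arma::uword i = 0; i < HW; ++i) {
          s += p[i];
          s2 += p[i] * p[i];
        }
        mu[c] += s;
        var_[c] += s2;
      }
    for (arma::uword c = 0; c < C; ++c) {
      mu[c] /= m;
      var_[c] = std::max(var_[c] / m - mu[c] * mu[c], 0.0);
    }
  } else {
    for (arma::uword c = 0; c < C; ++c) {
      mu[c] = rmean[c];
      var_[c] = rvar[c];
    }
  }
  NumericVector inv(C), newm(C), newv(C);
  for (arma::uword c = 0; c < C; ++c) {
    inv[c] = 1.0 / std::sqrt(var_[c] + eps);
    newm[c] = training ? (1 - momentum) * rmean[c] + momentum * mu[c] : rmean[c];
    newv[c] = training ? (1 - momentum) * rvar[c] + momentum * var_[c] : rvar[c];
  }
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double* p = x.begin() + HW * (c + C * n);
      double* q = y.begin() + HW * (c + C * n);
      double sc = gamma[c] * inv[c], sh = beta[c] - sc * mu[c];
      if (relu) {
        for (arma::uword i = 0; i < HW; ++i) {
          double v = p[i] * sc + sh;
          q[i] = v > 0 ? v : 0.0;
        }
      } else {
        for (arma::uword i = 0; i < HW; ++i) q[i] = p[i] * sc + sh;
      }
    }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv"] = inv,
                      _["mean"] = newm, _["var"] = newv);
}

// Fused batch-norm (+ ReLU mask from y) backward.
// [[Rcpp::export(name = ".bnrelu_bwd")]]
List bnrelu_bwd(NumericVector dy, NumericVector x, NumericVector y,
                NumericVector gamma, NumericVector mu, NumericVector inv,
                bool training, bool relu) {
  IntegerVector xd = x.attr("dim");
  arma::uword HW = (arma::uword)xd[0] * xd[1], C = xd[2], N = xd[3];
  arma::uword m = HW * N;
  NumericVector dg(C), db(C);
  // first pass: per-channel sums of masked dy and masked dy * xhat
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      arma::uword o = HW * (c + C * n);
      const double* pd = dy.begin() + o;
      const double* px = x.begin() + o;
      const double* py = y.begin() + o;
      double s1 = 0, s2 = 0;
      for (arma::uword i = 0; i < HW; ++i) {
        double d = pd[i];
        if (relu && py[i] <= 0) d = 0;
        s1 += d;
        s2 += d * (px[i] - mu[c]) * inv[c];
      }
      db[c] += s1;
      dg[c] += s2;
    }
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      arma::uword o = HW * (c + C * n);
      const double* pd = dy.begin() + o;
      const double* px = x.begin() + o;
      const double* py = y.begin() + o;
      double* q = dx.begin() + o;
      double gi = gamma[c] * inv[c];
      if (training) {
        for (arma::uword i = 0; i < HW; ++i) {
          double d = pd[i];
          if (relu && py[i] <= 0) d = 0;
          double xh = (px[i] - mu[c]) * inv[c];
          q[i] = gi / m * (m * d - db[c] - xh * dg[c]);
        }
      } else {
        for (arma::uword i = 0; i < HW; ++i) {
          double d = pd[i];
          if (relu && py[i] <= 0) d = 0;
          q[i] = d * gi;
        }
      }
    }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}
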