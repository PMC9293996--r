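// Low-level kernels for the anisotropic U-Net: valid 3D convolution,
// in-plane max pooling, in-plane transposed convolution, and 6-connected
// component labeling. Activations are (batch*nx*ny*nz) x channels matrices,
// voxel index = x + nx*(y + ny*z), samples stacked along rows.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef long long ll;

// Gather the shifted sub-block for one kernel offset into G (orows x Cin).
static void gather_offset(const double* X, ll nvox, ll nx, ll ny, ll nz,
                          ll B, int Cin, ll ox, ll oy, ll oz,
                          int dx, int dy, int dz, arma::mat& G) {
  const ll orows = B * ox * oy * oz;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* src = X + (ll)ci * (B * nvox);
    double* dst = G.colptr(ci);
    ll r = 0;
    for (ll s = 0; s < B; ++s) {
      const double* sbase = src + s * nvox;
      for (ll z = 0; z < oz; ++z) {
        for (ll y = 0; y < oy; ++y) {
          const double* run = sbase + dx + nx * ((y + dy) + ny * (z + dz));
          std::memcpy(dst + r, run, sizeof(double) * ox);
          r += ox;
        }
      }
    }
  }
}

// Scatter-add dG (orows x Cin) back into dX at one kernel offset.
static void scatter_offset(double* dX, ll nvox, ll nx, ll ny, ll nz,
                           ll B, int Cin, ll ox, ll oy, ll oz,
                           int dx, int dy, int dz, const arma::mat& dG) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* dst = dX + (ll)ci * (B * nvox);
    const double* src = dG.colptr(ci);
    ll r = 0;
    for (ll s = 0; s < B; ++s) {
      double* sbase = dst + s * nvox;
      for (ll z = 0; z < oz; ++z) {
        for (ll y = 0; y < oy; ++y) {
          double* run = sbase + dx + nx * ((y + dy) + ny * (z + dz));
          const double* add = src + r;
          for (ll x = 0; x < ox; ++x) run[x] += add[x];
          r += ox;
        }
      }
    }
  }
}

// Valid convolution, kernel (kx,ky,kz). W has dim (kx*ky*kz, Cin, Cout)
// flattened column-major as passed from R (array dim c(kx*ky*kz, Cin, Cout)).
// [[Rcpp::export]]
NumericMatrix cpp_conv3d_fwd(NumericMatrix Xr, IntegerVector dims,
                             NumericVector Wr, IntegerVector ksz,
                             NumericVector bias) {
  const ll nx = dims[0], ny = dims[1], nz = dims[2], B = dims[3];
  const int kx = ksz[0], ky = ksz[1], kz = ksz[2];
  const int Cin = Xr.ncol();
  const ll nvox = nx * ny * nz;
  const ll ox = nx - kx + 1, oy = ny - ky + 1, oz = nz - kz + 1;
  if (ox < 1 || oy < 1 || oz < 1)
    stop("convolution input smaller than kernel");
  const int Cout = bias.size();
  const ll orows = B * ox * oy * oz;
  NumericMatrix Outr(orows, Cout);
  arma::mat Out((double*)Outr.begin(), orows, Cout, false, true);
  for (int co = 0; co < Cout; ++co) Out.col(co).fill(bias[co]);
  arma::mat G(orows, Cin);
  const ll koff = (ll)kx * ky * kz;
  for (int dz = 0; dz < kz; ++dz)
    for (int dy = 0; dy < ky; ++dy)
      for (int dx = 0; dx < kx; ++dx) {
        gather_offset(Xr.begin(), nvox, nx, ny, nz, B, Cin, ox, oy, oz,
                      dx, dy, dz, G);
        ll o = dx + kx * (dy + (ll)ky * dz);
        arma::mat Wo(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wo(ci, co) = Wr[o + koff * (ci + (ll)Cin * co)];
        Out += G * Wo;
      }
  return Outr;
}

// Backward pass of the valid convolution: returns dX, dW, db.
// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericMatrix Xr, IntegerVector dims,
                    NumericVector Wr, IntegerVector ksz,
                    NumericMatrix dOutr) {
  const ll nx = dims[0], ny = dims[1], nz = dims[2], B = dims[3];
  const int kx = ksz[0], ky = ksz[1], kz = ksz[2];
  const int Cin = Xr.ncol();
  const ll nvox = nx * ny * nz;
  const ll ox = nx - kx + 1, oy = ny - ky + 1, oz = nz - kz + 1;
  const ll orows = B * ox * oy * oz;
  const int Cout = dOutr.ncol();
  if ((ll)dOutr.nrow() != orows) stop("dOut shape mismatch");
  arma::mat dOut((double*)dOutr.begin(), orows, Cout, false, true);
  NumericMatrix dXr(B * nvox, Cin);
  NumericVector dWr(Wr.size());
  NumericVector db(Cout);
  arma::vec dbv = arma::sum(dOut, 0).t();
  for (int co = 0; co < Cout; ++co) db[co] = dbv[co];
  arma::mat G(orows, Cin);
  const ll koff = (ll)kx * ky * kz;
  for (int dz = 0; dz < kz; ++dz)
    for (int dy = 0; dy < ky; ++dy)
      for (int dx = 0; dx < kx; ++dx) {
        ll o = dx + kx * (dy + (ll)ky * dz);
        gather_offset(Xr.begin(), nvox, nx, ny, nz, B, Cin, ox, oy, oz,
                      dx, dy, dz, G);
        arma::mat dWo = G.t() * dOut;               // Cin x Cout
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            dWr[o + koff * (ci + (ll)Cin * co)] = dWo(ci, co);
        arma::mat Wo(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wo(ci, co) = Wr[o + koff * (ci + (ll)Cin * co)];
        arma::mat dG = dOut * Wo.t();               // orows x Cin
        scatter_offset(dXr.begin(), nvox, nx, ny, nz, B, Cin, ox, oy, oz,
                       dx, dy, dz, dG);
      }
  return List::create(_["dx"] = dXr, _["dw"] = dWr, _["db"] = db);
}

// In-plane 2x2x1 max pooling; nx, ny must be even. Returns pooled values
// and the flat row index (0-based, into the input) of each maximum.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericMatrix Xr, IntegerVector dims) {
  const ll nx = dims[0], ny = dims[1], nz = dims[2], B = dims[3];
  if (nx % 2 || ny % 2) stop("pooling requires even in-plane extent");
  const int C = Xr.ncol();
  const ll nvox = nx * ny * nz;
  const ll ox = nx / 2, oy = ny / 2, oz = nz;
  const ll orows = B * ox * oy * oz;
  NumericMatrix Outr(orows, C);
  NumericMatrix Idx(orows, C);  // stored as double to hold large indices
  for (int c = 0; c < C; ++c) {
    const double* src = Xr.begin() + (ll)c * (B * nvox);
    double* out = Outr.begin() + (ll)c * orows;
    double* idx = Idx.begin() + (ll)c * orows;
    ll r = 0;
    for (ll s = 0; s < B; ++s) {
      const double* sb = src + s * nvox;
      for (ll z = 0; z < oz; ++z)
        for (ll y = 0; y < oy; ++y)
          for (ll x = 0; x < ox; ++x) {
            ll i00 = 2 * x + nx * (2 * y + ny * z);
            ll cand[4] = { i00, i00 + 1, i00 + nx, i00 + nx + 1 };
            ll best = cand[0];
            double bv = sb[best];
            for (int k = 1; k < 4; ++k)
              if (sb[cand[k]] > bv) { bv = sb[cand[k]]; best = cand[k]; }
            out[r] = bv;
            idx[r] = (double)(s * nvox + best);
            ++r;
          }
    }
  }
  return List::create(_["out"] = Outr, _["idx"] = Idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(NumericMatrix Idx, IntegerVector dims,
                              NumericMatrix dOutr) {
  const ll nx = dims[0], ny = dims[1], nz = dims[2], B = dims[3];
  const int C = dOutr.ncol();
  const ll nrows = B * nx * ny * nz;
  NumericMatrix dXr(nrows, C);
  const ll orows = dOutr.nrow();
  for (int c = 0; c < C; ++c) {
    double* dx = dXr.begin() + (ll)c * nrows;
    const double* g = dOutr.begin() + (ll)c * orows;
    const double* idx = Idx.begin() + (ll)c * orows;
    for (ll r = 0; r < orows; ++r) dx[(ll)idx[r]] += g[r];
  }
  return dXr;
}

// In-plane transposed convolution, kernel 2x2x1, stride 2: output extent
// (2nx, 2ny, nz). W dim (4, Cin, Cout) with offset index dx + 2*dy.
// [[Rcpp::export]]
NumericMatrix cpp_upconv_fwd(NumericMatrix Xr, IntegerVector dims,
                             NumericVector Wr, NumericVector bias) {
  const ll nx = dims[0], ny = dims[1], nz = dims[2], B = dims[3];
  const int Cin = Xr.ncol(), Cout = bias.size();
  const ll nvox = nx * ny * nz, irows = B * nvox;
  const ll mx = 2 * nx, my = 2 * ny;
  const ll ovox = mx * my * nz, orows = B * ovox;
  NumericMatrix Outr(orows, Cout);
  arma::mat X((double*)Xr.begin(), irows, Cin, false, true);
  for (int co = 0; co < Cout; ++co)
    std::fill(Outr.begin() + (ll)co * orows,
              Outr.begin() + (ll)(co + 1) * orows, bias[co]);
  for (int dy = 0; dy < 2; ++dy)
    for (int dx = 0; dx < 2; ++dx) {
      arma::mat Wo(Cin, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wo(ci, co) = Wr[(dx + 2 * dy) + 4 * (ci + (ll)Cin * co)];
      arma::mat M = X * Wo;  // irows x Cout
      for (int co = 0; co < Cout; ++co) {
        double* out = Outr.begin() + (ll)co * orows;
        const double* src = M.colptr(co);
        ll r = 0;
        for (ll s = 0; s < B; ++s) {
          double* ob = out + s * ovox;
          for (ll z = 0; z < nz; ++z)
            for (ll y = 0; y < ny; ++y) {
              double* run = ob + dx + mx * ((2 * y + dy) + my * z);
              for (ll x = 0; x < nx; ++x) run[2 * x] += src[r++];
            }
        }
      }
    }
  return Outr;
}

// [[Rcpp::export]]
List cpp_upconv_bwd(NumericMatrix Xr, IntegerVector dims,
                    NumericVector Wr, NumericMatrix dOutr) {
  const ll nx = dims[0], ny = dims[1], nz = dims[2], B = dims[3];
  const int Cin = Xr.ncol(), Cout = dOutr.ncol();
  const ll nvox = nx * ny * nz, irows = B * nvox;
  const ll mx = 2 * nx, my = 2 * ny, ovox = mx * my * nz, orows = B * ovox;
  if ((ll)dOutr.nrow() != orows) stop("dOut shape mismatch");
  arma::mat X((double*)Xr.begin(), irows, Cin, false, true);
  NumericMatrix dXr(irows, Cin);
  arma::mat dX((double*)dXr.begin(), irows, Cin, false, true);
  NumericVector dWr(Wr.size());
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* g = dOutr.begin() + (ll)co * orows;
    double acc = 0;
    for (ll r = 0; r < orows; ++r) acc += g[r];
    db[co] = acc;
  }
  arma::mat G(irows, Cout);
  for (int dy = 0; dy < 2; ++dy)
    for (int dx = 0; dx < 2; ++dx) {
      for (int co = 0; co < Cout; ++co) {
        const double* g = dOutr.begin() + (ll)co * orows;
        double* dst = G.colptr(co);
        ll r = 0;
        for (ll s = 0; s < B; ++s) {
          const double* gb = g + s * ovox;
          for (ll z = 0; z < nz; ++z)
            for (ll y = 0; y < ny; ++y) {
              const double* run = gb + dx + mx * ((2 * y + dy) + my * z);
              for (ll x = 0; x < nx; ++x) dst[r++] = run[2 * x];
            }
        }
      }
      arma::mat dWo = X.t() * G;  // Cin x Cout
      arma::mat Wo(Cin, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci) {
          dWr[(dx + 2 * dy) + 4 * (ci + (ll)Cin * co)] = dWo(ci, co);
          Wo(ci, co) = Wr[(dx + 2 * dy) + 4 * (ci + (ll)Cin * co)];
        }
      dX += G * Wo.t();
    }
  return List::create(_["dx"] = dXr, _["dw"] = dWr, _["db"] = db);
}

// 6-connected component labeling of a binary 3D array, labels assigned in
// column-major scan order of the first voxel encountered per component.
// [[Rcpp::export]]
IntegerVector cpp_label6(IntegerVector mask, IntegerVector dims) {
  const ll nx = dims[0], ny = dims[1], nz = dims[2];
  const ll n = nx * ny * nz;
  IntegerVector lab(n);
  std::vector<ll> stack;
  int next = 0;
  for (ll i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      ll v = stack.back(); stack.pop_back();
      ll x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      const ll nb[6] = { v - 1, v + 1, v - nx, v + nx,
                         v - nx * ny, v + nx * ny };
      const bool ok[6] = { x > 0, x < nx - 1, y > 0, y < ny - 1,
                           z > 0, z < nz - 1 };
      for (int k = 0; k < 6; ++k) {
        if (!ok[k]) continue;
        ll u = nb[k];
        if (mask[u] != 0 && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---- small-channel direct convolution paths ------------------------------
// For few channels the per-offset GEMM is memory-bound; a direct loop with
// the kernel tap in a register streams the input once per (co, tap).

// [[Rcpp::export]]
NumericMatrix cpp_conv3d_fwd_direct(NumericMatrix Xr, IntegerVector dims,
                                    NumericVector Wr, IntegerVector ksz,
                                    NumericVector bias) {
  const ll nx = dims[0], ny = dims[1], nz = dims[2], B = dims[3];
  const int kx = ksz[0], ky = ksz[1], kz = ksz[2];
  const int Cin = Xr.ncol(), Cout = bias.size();
  const ll nvox = nx * ny * nz;
  const ll ox = nx - kx + 1, oy = ny - ky + 1, oz = nz - kz + 1;
  if (ox < 1 || oy < 1 || oz < 1) stop("convolution input smaller than kernel");
  const ll ovox = ox * oy * oz, orows = B * ovox;
  const ll koff = (ll)kx * ky * kz;
  NumericMatrix Outr(orows, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* outc = Outr.begin() + (ll)co * orows;
    std::fill(outc, outc + orows, bias[co]);
    for (ll s = 0; s < B; ++s) {
      double* ob = outc + s * ovox;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* ib = Xr.begin() + (ll)ci * (B * nvox) + s * nvox;
        for (ll zo = 0; zo < oz; ++zo)
          for (int dz = 0; dz < kz; ++dz)
            for (ll yo = 0; yo < oy; ++yo)
              for (int dy = 0; dy < ky; ++dy) {
                // all kx taps fused: each input row is streamed once
                double wv[8];
                for (int dx = 0; dx < kx; ++dx)
                  wv[dx] = Wr[dx + kx * (dy + (ll)ky * dz) +
                              koff * (ci + (ll)Cin * co)];
                const double* irow = ib + nx * ((yo + dy) + ny * (zo + dz));
                double* orow = ob + ox * (yo + oy * zo);
                if (kx == 3) {
                  const double w0 = wv[0], w1 = wv[1], w2 = wv[2];
                  for (ll x = 0; x < ox; ++x)
                    orow[x] += w0 * irow[x] + w1 * irow[x + 1] + w2 * irow[x + 2];
                } else if (kx == 1) {
                  const double w0 = wv[0];
                  for (ll x = 0; x < ox; ++x) orow[x] += w0 * irow[x];
                } else {
                  for (ll x = 0; x < ox; ++x) {
                    double acc = 0;
                    for (int dx = 0; dx < kx; ++dx) acc += wv[dx] * irow[x + dx];
                    orow[x] += acc;
                  }
                }
              }
      }
    }
  }
  return Outr;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd_direct(NumericMatrix Xr, IntegerVector dims,
                           NumericVector Wr, IntegerVector ksz,
                           NumericMatrix dOutr) {
  const ll nx = dims[0], ny = dims[1], nz = dims[2], B = dims[3];
  const int kx = ksz[0], ky = ksz[1], kz = ksz[2];
  const int Cin = Xr.ncol(), Cout = dOutr.ncol();
  const ll nvox = nx * ny * nz;
  const ll ox = nx - kx + 1, oy = ny - ky + 1, oz = nz - kz + 1;
  const ll ovox = ox * oy * oz, orows = B * ovox;
  if ((ll)dOutr.nrow() != orows) stop("dOut shape mismatch");
  const ll koff = (ll)kx * ky * kz;
  NumericMatrix dXr(B * nvox, Cin);
  NumericVector dWr(Wr.size());
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* gc = dOutr.begin() + (ll)co * orows;
    double acc = 0;
    for (ll r = 0; r < orows; ++r) acc += gc[r];
    db[co] = acc;
    for (ll s = 0; s < B; ++s) {
      const double* gb = gc + s * ovox;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* ib = Xr.begin() + (ll)ci * (B * nvox) + s * nvox;
        double* dib = dXr.begin() + (ll)ci * (B * nvox) + s * nvox;
        for (ll zo = 0; zo < oz; ++zo)
          for (int dz = 0; dz < kz; ++dz)
            for (ll yo = 0; yo < oy; ++yo)
              for (int dy = 0; dy < ky; ++dy) {
                // all kx taps fused: input and gradient rows streamed once
                const ll wbase = kx * (dy + (ll)ky * dz) +
                  koff * (ci + (ll)Cin * co);
                double wv[8], wacc[8];
                for (int dx = 0; dx < kx; ++dx) {
                  wv[dx] = Wr[dx + wbase];
                  wacc[dx] = 0;
                }
                const double* irow = ib + nx * ((yo + dy) + ny * (zo + dz));
                double* dirow = dib + nx * ((yo + dy) + ny * (zo + dz));
                const double* grow = gb + ox * (yo + oy * zo);
                if (kx == 3) {
                  const double w0 = wv[0], w1 = wv[1], w2 = wv[2];
                  double a0 = 0, a1 = 0, a2 = 0;
                  for (ll x = 0; x < ox; ++x) {
                    const double g = grow[x];
                    a0 += irow[x] * g;
                    a1 += irow[x + 1] * g;
                    a2 += irow[x + 2] * g;
                    dirow[x] += w0 * g;
                    dirow[x + 1] += w1 * g;
                    dirow[x + 2] += w2 * g;
                  }
                  wacc[0] = a0; wacc[1] = a1; wacc[2] = a2;
                } else {
                  for (ll x = 0; x < ox; ++x) {
                    const double g = grow[x];
                    for (int dx = 0; dx < kx; ++dx) {
                      wacc[dx] += irow[x + dx] * g;
                      dirow[x + dx] += wv[dx] * g;
                    }
                  }
                }
                for (int dx = 0; dx < kx; ++dx) dWr[dx + wbase] += wacc[dx];
              }
      }
    }
  }
  return List::create(_["dx"] = dXr, _["dw"] = dWr, _["db"] = db);
}

// ---- fused batch-norm + ReLU ---------------------------------------------

// [[Rcpp::export]]
List cpp_colstats(NumericMatrix Xr) {
  const ll n = Xr.nrow(); const int C = Xr.ncol();
  NumericVector mu(C), va(C);
  for (int c = 0; c < C; ++c) {
    const double* x = Xr.begin() + (ll)c * n;
    double s = 0, s2 = 0;
    for (ll i = 0; i < n; ++i) { s += x[i]; s2 += x[i] * x[i]; }
    mu[c] = s / n;
    double v = s2 / n - mu[c] * mu[c];
    va[c] = v > 0 ? v : 0;
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}

// y = relu(g * (x - mu) * inv + be). The activation overwrites the
// convolution output in place (the caller owns that temporary); xhat is the
// only new allocation.
// [[Rcpp::export]]
List cpp_bn_relu_fwd(NumericMatrix Xr, NumericVector mu, NumericVector inv,
                     NumericVector g, NumericVector be) {
  const ll n = Xr.nrow(); const int C = Xr.ncol();
  NumericMatrix xhat(n, C);
  for (int c = 0; c < C; ++c) {
    double* x = Xr.begin() + (ll)c * n;
    double* xh = xhat.begin() + (ll)c * n;
    const double m = mu[c], iv = inv[c], gg = g[c], bb = be[c];
    for (ll i = 0; i < n; ++i) {
      const double h = (x[i] - m) * iv;
      xh[i] = h;
      const double y = gg * h + bb;
      x[i] = y > 0 ? y : 0;
    }
  }
  return List::create(_["act"] = Xr, _["xhat"] = xhat);
}

// Backward of BN+ReLU given dAct, the forward act (for the ReLU mask) and
// xhat. dAct is overwritten in place with the gradient w.r.t. the
// convolution output (the caller owns that temporary).
// [[Rcpp::export]]
List cpp_bn_relu_bwd(NumericMatrix dActr, NumericMatrix act,
                     NumericMatrix xhat, NumericVector inv, NumericVector g) {
  const ll n = dActr.nrow(); const int C = dActr.ncol();
  NumericVector dg(C), dbe(C);
  for (int c = 0; c < C; ++c) {
    double* da = dActr.begin() + (ll)c * n;
    const double* a = act.begin() + (ll)c * n;
    const double* xh = xhat.begin() + (ll)c * n;
    const double gg = g[c], iv = inv[c];
    double s_d = 0, s_dg = 0;
    for (ll i = 0; i < n; ++i) {
      const double d = a[i] > 0 ? da[i] : 0;
      da[i] = d;                       // temporarily the masked gradient
      s_dg += d * xh[i];
      s_d += d;
    }
    dg[c] = s_dg; dbe[c] = s_d;
    const double m1 = gg * s_d / n;     // mean of dxhat
    const double m2 = gg * s_dg / n;    // mean of dxhat * xhat
    for (ll i = 0; i < n; ++i)
      da[i] = iv * (gg * da[i] - m1 - xh[i] * m2);
  }
  return List::create(_["dx"] = dActr, _["dg"] = dg, _["dbe"] = dbe);
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Large activation matrices churn through malloc every iteration; keeping
// big blocks in the heap arena (instead of mmap/munmap cycles) avoids
// repeated page faults during training.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
}
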