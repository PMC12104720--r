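// Nested residual-U segmentation network ("two-level nested U") with deep
// supervision, implemented directly on BLAS GEMM (im2col) so a scaled-down
// preset trains on one CPU. All state (weights, Adam moments, batch-norm
// running statistics) lives on the R side as flat numeric vectors; these
// routines are pure functions of (config, weights, inputs) plus the running
// statistics they return updated, which keeps checkpointing and determinism
// trivial.
#include <RcppArmadillo.h>
#include <functional>
#include <memory>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ConvSpec {
  int cin, cout, k, dil, bn;
};

// Parameter/graph layout of one residual U-block (RSU).
// Plain variant (depth L >= 2): convin, conv1..conv_{L-1}, bottom conv_L
// (dilation 2), decoder convd_{L-1}..convd_1. Dilated variant (no pooling):
// dilation doubles per level instead.
void rsu_specs(std::vector<ConvSpec>& out, int cin, int mid, int cout, int L,
               bool dilated) {
  auto add = [&](int a, int b, int d) { out.push_back({a, b, 3, d, 1}); };
  add(cin, cout, 1);  // convin
  if (!dilated) {
    add(cout, mid, 1);                          // conv1
    for (int i = 2; i <= L - 1; ++i) add(mid, mid, 1);
    add(mid, mid, 2);                           // bottom, dilation 2
    for (int i = L - 1; i >= 2; --i) add(2 * mid, mid, 1);
    add(2 * mid, cout, 1);                      // convd1
  } else {
    add(cout, mid, 1);
    for (int i = 2; i <= L; ++i) add(mid, mid, 1 << (i - 1));
    for (int i = L - 1; i >= 2; --i) add(2 * mid, mid, 1 << (i - 2));
    add(2 * mid, cout, 1);
  }
}

struct NetCfg {
  int n_stages, in_ch;
  std::vector<int> depths, dilated, enc_out, enc_mid, dec_out, dec_mid;
};

NetCfg parse_cfg(const List& cfg) {
  NetCfg c;
  c.n_stages = as<int>(cfg["n_stages"]);
  c.in_ch = as<int>(cfg["in_channels"]);
  c.depths = as<std::vector<int>>(cfg["rsu_depths"]);
  c.dilated = as<std::vector<int>>(cfg["dilated"]);
  c.enc_out = as<std::vector<int>>(cfg["enc_out"]);
  c.enc_mid = as<std::vector<int>>(cfg["enc_mid"]);
  c.dec_out = as<std::vector<int>>(cfg["dec_out"]);
  c.dec_mid = as<std::vector<int>>(cfg["dec_mid"]);
  return c;
}

std::vector<ConvSpec> net_specs(const NetCfg& c) {
  std::vector<ConvSpec> sp;
  const int n = c.n_stages;
  for (int s = 0; s < n; ++s) {
    int cin = (s == 0) ? c.in_ch : c.enc_out[s - 1];
    rsu_specs(sp, cin, c.enc_mid[s], c.enc_out[s], c.depths[s],
              c.dilated[s] != 0);
  }
  for (int s = n - 2; s >= 0; --s) {  // decoder, deepest first
    int up_ch = (s == n - 2) ? c.enc_out[n - 1] : c.dec_out[s + 1];
    rsu_specs(sp, c.enc_out[s] + up_ch, c.dec_mid[s], c.dec_out[s],
              c.depths[s], c.dilated[s] != 0);
  }
  for (int s = 0; s < n - 1; ++s) sp.push_back({c.dec_out[s], 1, 3, 1, 0});
  sp.push_back({c.enc_out[n - 1], 1, 3, 1, 0});  // deepest encoder side
  sp.push_back({n, 1, 1, 1, 0});                 // fused 1x1 over side logits
  return sp;
}

typedef std::vector<arma::cube> Batch;  // one H x W x C cube per sample

struct Node {
  Batch v, g;
};
typedef std::shared_ptr<Node> NP;

void alloc_grad(const NP& n) {
  if (!n->g.empty()) return;
  n->g.resize(n->v.size());
  for (size_t i = 0; i < n->v.size(); ++i)
    n->g[i] = arma::zeros<arma::cube>(arma::size(n->v[i]));
}

// im2col for a 3x3 kernel with dilation d and same-size zero padding.
// Output: (H*W) x (9*C); column q = ki + 3*kj + 9*c.
arma::mat im2col3(const arma::cube& x, int d) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(H * (size_t)W, 9 * (size_t)C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int oi = (ki - 1) * d, oj = (kj - 1) * d;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        if (i1 <= i0 || j1 <= j0) continue;
        double* dst = cols.colptr(ki + 3 * kj + 9 * c);
        for (int j = j0; j < j1; ++j)
          std::memcpy(dst + i0 + (size_t)j * H, xc.colptr(j + oj) + i0 + oi,
                      sizeof(double) * (i1 - i0));
      }
    }
  }
  return cols;
}

void col2im3_add(const arma::mat& gcols, arma::cube& gx, int d) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    arma::mat& gc = gx.slice(c);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int oi = (ki - 1) * d, oj = (kj - 1) * d;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        if (i1 <= i0 || j1 <= j0) continue;
        const double* src = gcols.colptr(ki + 3 * kj + 9 * c);
        for (int j = j0; j < j1; ++j) {
          double* dst = gc.colptr(j + oj) + i0 + oi;
          const double* s = src + i0 + (size_t)j * H;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += s[i];
        }
      }
    }
  }
}

// Precomputed 1-D linear interpolation stencil (align-corners = false).
struct Lin1D {
  std::vector<int> a, b;
  std::vector<double> wa, wb;
};
Lin1D lin_stencil(int n_in, int n_out) {
  Lin1D s;
  s.a.resize(n_out); s.b.resize(n_out); s.wa.resize(n_out); s.wb.resize(n_out);
  const double scale = (double)n_in / n_out;
  for (int i = 0; i < n_out; ++i) {
    double src = (i + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int lo = (int)std::floor(src);
    int hi = std::min(lo + 1, n_in - 1);
    double f = src - lo;
    s.a[i] = lo; s.b[i] = hi; s.wa[i] = 1 - f; s.wb[i] = f;
  }
  return s;
}

struct Engine {
  bool training = false, record = false;
  const double* W = nullptr;
  double* G = nullptr;
  size_t wlen = 0, wpos = 0;
  double* R = nullptr;  // running BN stats: [mean, var] per BN conv
  size_t rlen = 0, rpos = 0;
  std::vector<ConvSpec> specs;
  size_t spos = 0;
  double bn_eps = 1e-5, bn_mom = 0.1;
  std::vector<std::function<void()>> tape;

  ConvSpec pop_spec(int cin_expect) {
    if (spos >= specs.size()) stop("network walk exceeded layout");
    ConvSpec s = specs[spos++];
    if (s.cin != cin_expect)
      stop("layout mismatch: expected cin %d, layout has %d", cin_expect,
           s.cin);
    return s;
  }

  // conv (+ optional batch-norm + ReLU, when spec.bn) consuming the next
  // layout entry. Side/fused convolutions (bn = 0) are linear.
  NP convunit(NP x) {
    const int N = x->v.size();
    const int H = x->v[0].n_rows, Wd = x->v[0].n_cols, C = x->v[0].n_slices;
    ConvSpec s = pop_spec(C);
    const size_t kk = (size_t)s.k * s.k;
    const size_t woff = wpos;
    arma::mat Wm(const_cast<double*>(W) + wpos, kk * s.cin, s.cout, false,
                 true);
    wpos += kk * s.cin * s.cout;
    const size_t boff = wpos;
    arma::rowvec bv(const_cast<double*>(W) + boff, s.cout, false, true);
    wpos += s.cout;
    size_t gamoff = 0, betoff = 0, roff = 0;
    if (s.bn) {
      gamoff = wpos; wpos += s.cout;
      betoff = wpos; wpos += s.cout;
      roff = rpos; rpos += 2 * (size_t)s.cout;
    }

    // linear part
    Batch z(N);
    for (int n = 0; n < N; ++n) {
      arma::mat y;
      if (s.k == 3) {
        y = im2col3(x->v[n], s.dil) * Wm;
      } else {
        arma::mat xin(const_cast<double*>(x->v[n].memptr()), H * (size_t)Wd,
                      C, false, true);
        y = xin * Wm;
      }
      y.each_row() += bv;
      z[n] = arma::cube(y.memptr(), H, Wd, s.cout);
    }

    NP out = std::make_shared<Node>();
    arma::vec mean, var;
    if (s.bn) {
      const double m = (double)N * H * Wd;
      mean.zeros(s.cout); var.zeros(s.cout);
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < s.cout; ++c) mean(c) += arma::accu(z[n].slice(c));
      mean /= m;
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < s.cout; ++c)
          var(c) += arma::accu(arma::square(z[n].slice(c) - mean(c)));
      var /= m;
      if (training) {  // update running stats
        for (int c = 0; c < s.cout; ++c) {
          R[roff + c] = (1 - bn_mom) * R[roff + c] + bn_mom * mean(c);
          R[roff + s.cout + c] = (1 - bn_mom) * R[roff + s.cout + c] +
                                 bn_mom * var(c);
        }
      } else {
        for (int c = 0; c < s.cout; ++c) {
          mean(c) = R[roff + c];
          var(c) = R[roff + s.cout + c];
        }
      }
      const double* gam = W + gamoff;
      const double* bet = W + betoff;
      out->v.resize(N);
      for (int n = 0; n < N; ++n) {
        out->v[n].set_size(H, Wd, s.cout);
        for (int c = 0; c < s.cout; ++c) {
          const double sd = std::sqrt(var(c) + bn_eps);
          arma::mat t = gam[c] * ((z[n].slice(c) - mean(c)) / sd) + bet[c];
          t.transform([](double v) { return v > 0 ? v : 0.0; });  // ReLU
          out->v[n].slice(c) = t;
        }
      }
    } else {
      out->v = z;  // linear logits
    }

    if (record) {
      alloc_grad(out);
      alloc_grad(x);
      NP xi = x;
      Engine* E = this;
      bool train_stats = training;
      // keep pre-BN activations for backward (z moved into closure)
      std::shared_ptr<Batch> zkeep =
          s.bn ? std::make_shared<Batch>(std::move(z)) : nullptr;
      tape.push_back([E, xi, out, s, woff, boff, gamoff, betoff, mean, var,
                      zkeep, H, Wd, C, N, kk, train_stats]() {
        arma::mat Wm(const_cast<double*>(E->W) + woff, kk * s.cin, s.cout,
                     false, true);
        arma::mat Gw(E->G + woff, kk * s.cin, s.cout, false, true);
        double* Gb = E->G + boff;
        const double m = (double)N * H * Wd;
        for (int n = 0; n < N; ++n) {
          arma::mat gz(H * (size_t)Wd, s.cout);
          if (s.bn) {
            const double* gam = E->W + gamoff;
            double* Ggam = E->G + gamoff;
            double* Gbet = E->G + betoff;
            for (int c = 0; c < s.cout; ++c) {
              const double sd = std::sqrt(var(c) + E->bn_eps);
              arma::mat xhat = ((*zkeep)[n].slice(c) - mean(c)) / sd;
              // ReLU mask from stored output
              arma::mat mask =
                  arma::conv_to<arma::mat>::from(out->v[n].slice(c) > 0);
              arma::mat gy = out->g[n].slice(c) % mask;
              Ggam[c] += arma::accu(gy % xhat);
              Gbet[c] += arma::accu(gy);
              arma::mat dz;
              if (train_stats) {
                // batch statistics took part in the forward pass
                double sum_gy = 0, sum_gy_xhat = 0;
                for (int n2 = 0; n2 < N; ++n2) {
                  arma::mat xh2 = ((*zkeep)[n2].slice(c) - mean(c)) / sd;
                  arma::mat mask2 =
                      arma::conv_to<arma::mat>::from(out->v[n2].slice(c) > 0);
                  arma::mat gy2 = out->g[n2].slice(c) % mask2;
                  sum_gy += arma::accu(gy2);
                  sum_gy_xhat += arma::accu(gy2 % xh2);
                }
                dz = (gam[c] / sd) *
                     (gy - sum_gy / m - xhat * (sum_gy_xhat / m));
              } else {
                dz = (gam[c] / sd) * gy;
              }
              std::memcpy(gz.colptr(c), dz.memptr(),
                          sizeof(double) * H * (size_t)Wd);
            }
          } else {
            std::memcpy(gz.memptr(), out->g[n].memptr(),
                        sizeof(double) * H * (size_t)Wd * s.cout);
          }
          // conv backward
          for (int c = 0; c < s.cout; ++c) Gb[c] += arma::accu(gz.col(c));
          if (s.k == 3) {
            arma::mat cols = im2col3(xi->v[n], s.dil);
            Gw += cols.t() * gz;
            arma::mat gcols = gz * Wm.t();
            col2im3_add(gcols, xi->g[n], s.dil);
          } else {
            arma::mat xin(const_cast<double*>(xi->v[n].memptr()),
                          H * (size_t)Wd, C, false, true);
            Gw += xin.t() * gz;
            arma::mat gxm(xi->g[n].memptr(), H * (size_t)Wd, C, false, true);
            gxm += gz * Wm.t();
          }
        }
      });
    }
    return out;
  }

  NP maxpool2(NP x) {
    const int N = x->v.size();
    const int H = x->v[0].n_rows, Wd = x->v[0].n_cols, C = x->v[0].n_slices;
    if (H % 2 || Wd % 2) stop("maxpool2: spatial size must be even");
    const int H2 = H / 2, W2 = Wd / 2;
    NP out = std::make_shared<Node>();
    out->v.resize(N);
    auto idx = std::make_shared<std::vector<arma::ucube>>(N);
    for (int n = 0; n < N; ++n) {
      out->v[n].set_size(H2, W2, C);
      (*idx)[n].set_size(H2, W2, C);
      for (int c = 0; c < C; ++c) {
        const arma::mat& xc = x->v[n].slice(c);
        for (int j = 0; j < W2; ++j)
          for (int i = 0; i < H2; ++i) {
            int bi = 2 * i, bj = 2 * j, ai = bi, aj = bj;
            double best = xc(bi, bj);
            if (xc(bi + 1, bj) > best) { best = xc(bi + 1, bj); ai = bi + 1; }
            if (xc(bi, bj + 1) > best) { best = xc(bi, bj + 1); aj = bj + 1; ai = bi; }
            if (xc(bi + 1, bj + 1) > best) { best = xc(bi + 1, bj + 1); ai = bi + 1; aj = bj + 1; }
            out->v[n](i, j, c) = best;
            (*idx)[n](i, j, c) = ai + (size_t)aj * H;
          }
      }
    }
    if (record) {
      alloc_grad(out); alloc_grad(x);
      NP xi = x;
      tape.push_back([xi, out, idx, H, H2, W2, C, N]() {
        for (int n = 0; n < N; ++n)
          for (int c = 0; c < C; ++c) {
            double* gx = xi->g[n].slice_memptr(c);
            for (int j = 0; j < W2; ++j)
              for (int i = 0; i < H2; ++i)
                gx[(*idx)[n](i, j, c)] += out->g[n](i, j, c);
          }
      });
    }
    return out;
  }

  NP resize_bilinear(NP x, int H2, int W2) {
    const int N = x->v.size();
    const int H = x->v[0].n_rows, Wd = x->v[0].n_cols, C = x->v[0].n_slices;
    if (H == H2 && Wd == W2) return x;
    Lin1D ri = lin_stencil(H, H2), rj = lin_stencil(Wd, W2);
    NP out = std::make_shared<Node>();
    out->v.resize(N);
    for (int n = 0; n < N; ++n) {
      out->v[n].set_size(H2, W2, C);
      for (int c = 0; c < C; ++c) {
        const arma::mat& xc = x->v[n].slice(c);
        arma::mat& yc = out->v[n].slice(c);
        for (int j = 0; j < W2; ++j)
          for (int i = 0; i < H2; ++i)
            yc(i, j) =
                rj.wa[j] * (ri.wa[i] * xc(ri.a[i], rj.a[j]) +
                            ri.wb[i] * xc(ri.b[i], rj.a[j])) +
                rj.wb[j] * (ri.wa[i] * xc(ri.a[i], rj.b[j]) +
                            ri.wb[i] * xc(ri.b[i], rj.b[j]));
      }
    }
    if (record) {
      alloc_grad(out); alloc_grad(x);
      NP xi = x;
      tape.push_back([xi, out, ri, rj, H2, W2, C, N]() {
        for (int n = 0; n < N; ++n)
          for (int c = 0; c < C; ++c) {
            arma::mat& gx = xi->g[n].slice(c);
            const arma::mat& gy = out->g[n].slice(c);
            for (int j = 0; j < W2; ++j)
              for (int i = 0; i < H2; ++i) {
                const double g = gy(i, j);
                gx(ri.a[i], rj.a[j]) += ri.wa[i] * rj.wa[j] * g;
                gx(ri.b[i], rj.a[j]) += ri.wb[i] * rj.wa[j] * g;
                gx(ri.a[i], rj.b[j]) += ri.wa[i] * rj.wb[j] * g;
                gx(ri.b[i], rj.b[j]) += ri.wb[i] * rj.wb[j] * g;
              }
          }
      });
    }
    return out;
  }

  NP concat(NP a, NP b) {
    const int N = a->v.size();
    NP out = std::make_shared<Node>();
    out->v.resize(N);
    const int Ca = a->v[0].n_slices;
    for (int n = 0; n < N; ++n)
      out->v[n] = arma::join_slices(a->v[n], b->v[n]);
    if (record) {
      alloc_grad(out); alloc_grad(a); alloc_grad(b);
      NP ai = a, bi = b;
      tape.push_back([ai, bi, out, Ca, N]() {
        const int Cb = bi->v[0].n_slices;
        for (int n = 0; n < N; ++n) {
          ai->g[n] += out->g[n].slices(0, Ca - 1);
          bi->g[n] += out->g[n].slices(Ca, Ca + Cb - 1);
        }
      });
    }
    return out;
  }

  NP add(NP a, NP b) {
    const int N = a->v.size();
    NP out = std::make_shared<Node>();
    out->v.resize(N);
    for (int n = 0; n < N; ++n) out->v[n] = a->v[n] + b->v[n];
    if (record) {
      alloc_grad(out); alloc_grad(a); alloc_grad(b);
      NP ai = a, bi = b;
      tape.push_back([ai, bi, out, N]() {
        for (int n = 0; n < N; ++n) {
          ai->g[n] += out->g[n];
          bi->g[n] += out->g[n];
        }
      });
    }
    return out;
  }

  void run_backward() {
    for (auto it = tape.rbegin(); it != tape.rend(); ++it) (*it)();
  }
};

NP rsu_forward(Engine& E, NP x, int L, bool dilated) {
  NP hxin = E.convunit(x);
  if (!dilated) {
    std::vector<NP> h(L - 1);
    h[0] = E.convunit(hxin);
    for (int i = 1; i < L - 1; ++i) h[i] = E.convunit(E.maxpool2(h[i - 1]));
    NP hb = E.convunit(h[L - 2]);                 // bottom, dilation 2
    NP d = E.convunit(E.concat(hb, h[L - 2]));    // convd_{L-1}
    for (int i = L - 3; i >= 0; --i) {
      NP up = E.resize_bilinear(d, h[i]->v[0].n_rows, h[i]->v[0].n_cols);
      d = E.convunit(E.concat(up, h[i]));
    }
    return E.add(d, hxin);
  }
  std::vector<NP> h(L);
  h[0] = E.convunit(hxin);
  for (int i = 1; i < L; ++i) h[i] = E.convunit(h[i - 1]);
  NP d = h[L - 1];
  for (int i = L - 2; i >= 0; --i) d = E.convunit(E.concat(d, h[i]));
  return E.add(d, hxin);
}

// Full forward pass; returns the n side logit nodes followed by the fused
// logit node (all at input resolution).
std::vector<NP> net_forward(Engine& E, const NetCfg& c, NP input) {
  const int n = c.n_stages;
  const int H0 = input->v[0].n_rows, W0 = input->v[0].n_cols;
  std::vector<NP> hx(n);
  NP cur = input;
  for (int s = 0; s < n; ++s) {
    hx[s] = rsu_forward(E, cur, c.depths[s], c.dilated[s] != 0);
    if (s < n - 1) cur = E.maxpool2(hx[s]);
  }
  std::vector<NP> dec(n - 1);
  NP d = hx[n - 1];
  for (int s = n - 2; s >= 0; --s) {
    NP up = E.resize_bilinear(d, hx[s]->v[0].n_rows, hx[s]->v[0].n_cols);
    d = rsu_forward(E, E.concat(up, hx[s]), c.depths[s], c.dilated[s] != 0);
    dec[s] = d;
  }
  std::vector<NP> logits;
  for (int s = 0; s < n - 1; ++s)
    logits.push_back(E.resize_bilinear(E.convunit(dec[s]), H0, W0));
  logits.push_back(E.resize_bilinear(E.convunit(hx[n - 1]), H0, W0));
  NP cat = logits[0];
  for (int s = 1; s < n; ++s) cat = E.concat(cat, logits[s]);
  logits.push_back(E.convunit(cat));  // fused
  return logits;
}

size_t spec_param_len(const std::vector<ConvSpec>& sp) {
  size_t len = 0;
  for (const auto& s : sp) {
    len += (size_t)s.k * s.k * s.cin * s.cout + s.cout;
    if (s.bn) len += 2 * (size_t)s.cout;
  }
  return len;
}

size_t spec_running_len(const std::vector<ConvSpec>& sp) {
  size_t len = 0;
  for (const auto& s : sp)
    if (s.bn) len += 2 * (size_t)s.cout;
  return len;
}

Batch array_to_batch(const NumericVector& x, int H, int W, int N) {
  Batch b(N);
  for (int n = 0; n < N; ++n) {
    b[n].set_size(H, W, 1);
    std::memcpy(b[n].memptr(), x.begin() + (size_t)n * H * W,
                sizeof(double) * H * (size_t)W);
  }
  return b;
}

inline double sigmoid(double z) {
  return z >= 0 ? 1.0 / (1.0 + std::exp(-z)) : std::exp(z) / (1 + std::exp(z));
}

inline double softplus(double z) {
  return z > 0 ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z));
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_u2net_layout")]]
IntegerMatrix cpp_u2net_layout(List cfg) {
  NetCfg c = parse_cfg(cfg);
  std::vector<ConvSpec> sp = net_specs(c);
  IntegerMatrix m(sp.size(), 5);
  colnames(m) = CharacterVector::create("cin", "cout", "k", "dil", "bn");
  for (size_t i = 0; i < sp.size(); ++i) {
    m(i, 0) = sp[i].cin; m(i, 1) = sp[i].cout; m(i, 2) = sp[i].k;
    m(i, 3) = sp[i].dil; m(i, 4) = sp[i].bn;
  }
  return m;
}

// Shared driver. y has length 0 for inference.
// [[Rcpp::export(name = "cpp_u2net_run")]]
List cpp_u2net_run(List cfg, NumericVector weights, NumericVector running,
                   NumericVector x, IntegerVector dims, NumericVector y,
                   bool train) {
  NetCfg c = parse_cfg(cfg);
  const int H = dims[0], W = dims[1], N = dims[2];
  const int div = 1 << (c.n_stages - 1);
  if (H % div || W % div)
    stop("input spatial size (%d x %d) not divisible by %d", H, W, div);

  Engine E;
  E.specs = net_specs(c);
  E.wlen = spec_param_len(E.specs);
  E.rlen = spec_running_len(E.specs);
  if ((size_t)weights.size() != E.wlen)
    stop("weight vector length %d, expected %d", weights.size(), (int)E.wlen);
  if ((size_t)running.size() != E.rlen)
    stop("running-stats length %d, expected %d", running.size(), (int)E.rlen);

  NumericVector running_out = clone(running);
  NumericVector grad;
  E.W = weights.begin();
  E.R = running_out.begin();
  E.training = train;
  E.record = train;
  if (train) {
    grad = NumericVector(E.wlen);  // zero-initialised
    E.G = grad.begin();
  }

  NP input = std::make_shared<Node>();
  input->v = array_to_batch(x, H, W, N);
  std::vector<NP> logits = net_forward(E, c, input);
  if (E.wpos != E.wlen) stop("internal: parameter walk incomplete");
  if (E.rpos != E.rlen) stop("internal: running-stat walk incomplete");

  const int n_maps = logits.size();  // n sides + fused
  // probabilities (fused first in the returned list for convenience)
  NumericVector fused((size_t)H * W * N);
  List sides(n_maps - 1);
  for (int m = 0; m < n_maps; ++m) {
    NumericVector pm((size_t)H * W * N);
    for (int nn = 0; nn < N; ++nn) {
      const double* z = logits[m]->v[nn].memptr();
      double* p = pm.begin() + (size_t)nn * H * W;
      for (size_t i = 0; i < (size_t)H * W; ++i) p[i] = sigmoid(z[i]);
    }
    pm.attr("dim") = IntegerVector::create(H, W, N);
    if (m == n_maps - 1) fused = pm; else sides[m] = pm;
  }

  if (!train)
    return List::create(_["fused"] = fused, _["sides"] = sides,
                        _["running"] = running_out);

  // deep-supervision loss: per-map per-pixel mean binary cross-entropy on
  // logits, summed over the side maps and the fused map
  if ((size_t)y.size() != (size_t)H * W * N) stop("target size mismatch");
  const double scale = 1.0 / ((double)N * H * W);
  double loss = 0;
  for (int m = 0; m < n_maps; ++m) {
    for (int nn = 0; nn < N; ++nn) {
      const double* z = logits[m]->v[nn].memptr();
      const double* t = y.begin() + (size_t)nn * H * W;
      double* g = logits[m]->g[nn].memptr();
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        loss += scale * (softplus(z[i]) - t[i] * z[i]);
        g[i] = scale * (sigmoid(z[i]) - t[i]);
      }
    }
  }
  E.run_backward();

  return List::create(_["loss"] = loss, _["grad"] = grad,
                      _["fused"] = fused, _["running"] = running_out);
}
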