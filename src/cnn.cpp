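// 3D convolutional subject-identification network: forward pass, softmax
// cross-entropy backprop and Adam, in single precision.
//
// Layer plan (integer matrix, one row per layer):
//   col 0: type   0 = conv k=3 s=1 zero-pad 1
//                 1 = average pooling k=2 s=2
//                 2 = dense on flattened feature map
//                 3 = dense on globally mean-pooled channels
//   col 1: cin    input channels
//   col 2: cout   output channels (dense: n_subjects)
//   col 3-5: input spatial dims (dx, dy, dz) at this layer
//
// Activations are held as (batch * nvox) x channels matrices, voxels
// linearised x-fastest to match R's array order. Convolutions run as
// im2col + sgemm; weights for conv layers are (27*cin) x cout with row
// index o*cin + c for neighbourhood offset o = (ox+1) + 3(oy+1) + 9(oz+1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {


// OpenBLAS sgemm is slow for the very tall, narrow products convolution
// produces (n = 8..128 output channels), so the three conv gemms use
// cache-tiled kernels: M is blocked so the accumulator tile stays in L1
// and the inner loops vectorise over unit-stride column segments.

// The kernel bodies are written once and instantiated twice: an AVX2+FMA
// version (picked at runtime when the CPU supports it) and a baseline one.
#if defined(__GNUC__) && defined(__x86_64__)
#define FMRISID_INLINE inline __attribute__((always_inline))
#define FMRISID_AVX __attribute__((target("avx2,fma")))
#define FMRISID_HAS_DISPATCH 1
#else
#define FMRISID_INLINE inline
#define FMRISID_AVX
#define FMRISID_HAS_DISPATCH 0
#endif

bool cpu_has_avx2() {
#if FMRISID_HAS_DISPATCH
  static const bool ok =
      __builtin_cpu_supports("avx2") && __builtin_cpu_supports("fma");
  return ok;
#else
  return false;
#endif
}

// Y(M x N) = C(M x K) * W(K x N), all col-major; overwrites Y.
// M is tiled so the accumulator block stays in L1; K is unrolled by 8 so
// each accumulator load/store amortises eight FMAs.
FMRISID_INLINE void gemm_small_n_body(const fmat& C, const fmat& W, fmat& Y) {
  const int M = C.n_rows, K = C.n_cols, N = W.n_cols;
  const int TM = 256, TN = 16;
  std::vector<float> acc(TM * TN);
  for (int i0 = 0; i0 < M; i0 += TM) {
    const int tm = std::min(TM, M - i0);
    for (int j0 = 0; j0 < N; j0 += TN) {
      const int tn = std::min(TN, N - j0);
      std::fill(acc.begin(), acc.begin() + tm * tn, 0.0f);
      int k = 0;
      for (; k + 8 <= K; k += 8) {
        const float* c0 = C.colptr(k) + i0;
        const float* c1 = C.colptr(k + 1) + i0;
        const float* c2 = C.colptr(k + 2) + i0;
        const float* c3 = C.colptr(k + 3) + i0;
        const float* c4 = C.colptr(k + 4) + i0;
        const float* c5 = C.colptr(k + 5) + i0;
        const float* c6 = C.colptr(k + 6) + i0;
        const float* c7 = C.colptr(k + 7) + i0;
        for (int j = 0; j < tn; ++j) {
          const float* wk = &W(k, j0 + j);
          const float w0 = wk[0], w1 = wk[1], w2 = wk[2], w3 = wk[3];
          const float w4 = wk[4], w5 = wk[5], w6 = wk[6], w7 = wk[7];
          float* a = acc.data() + j * tm;
          for (int i = 0; i < tm; ++i) {
            a[i] += c0[i] * w0 + c1[i] * w1 + c2[i] * w2 + c3[i] * w3 +
                    c4[i] * w4 + c5[i] * w5 + c6[i] * w6 + c7[i] * w7;
          }
        }
      }
      for (; k < K; ++k) {
        const float* c = C.colptr(k) + i0;
        for (int j = 0; j < tn; ++j) {
          const float w = W(k, j0 + j);
          float* a = acc.data() + j * tm;
          for (int i = 0; i < tm; ++i) a[i] += c[i] * w;
        }
      }
      for (int j = 0; j < tn; ++j)
        std::memcpy(Y.colptr(j0 + j) + i0, acc.data() + j * tm,
                    tm * sizeof(float));
    }
  }
}

#if FMRISID_HAS_DISPATCH
FMRISID_AVX void gemm_small_n_avx(const fmat& C, const fmat& W, fmat& Y) {
  gemm_small_n_body(C, W, Y);
}
#endif
void gemm_small_n(const fmat& C, const fmat& W, fmat& Y) {
#if FMRISID_HAS_DISPATCH
  if (cpu_has_avx2()) return gemm_small_n_avx(C, W, Y);
#endif
  gemm_small_n_body(C, W, Y);
}

// dW(K x N) += C(M x K)^T * D(M x N); K*N assumed small (fits in cache).
FMRISID_INLINE void gemm_tn_acc_body(const fmat& C, const fmat& D, fmat& dW) {
  const int M = C.n_rows, K = C.n_cols, N = D.n_cols;
  const int TM = 512;
  for (int i0 = 0; i0 < M; i0 += TM) {
    const int tm = std::min(TM, M - i0);
    int k = 0;
    for (; k + 2 <= K; k += 2) {
      const float* c0 = C.colptr(k) + i0;
      const float* c1 = C.colptr(k + 1) + i0;
      int j = 0;
      for (; j + 2 <= N; j += 2) {
        const float* d0 = D.colptr(j) + i0;
        const float* d1 = D.colptr(j + 1) + i0;
        float s00[8] = {0}, s01[8] = {0}, s10[8] = {0}, s11[8] = {0};
        int i = 0;
        for (; i + 8 <= tm; i += 8) {
          for (int l = 0; l < 8; ++l) {
            s00[l] += c0[i + l] * d0[i + l];
            s01[l] += c0[i + l] * d1[i + l];
            s10[l] += c1[i + l] * d0[i + l];
            s11[l] += c1[i + l] * d1[i + l];
          }
        }
        float t00 = 0, t01 = 0, t10 = 0, t11 = 0;
        for (; i < tm; ++i) {
          t00 += c0[i] * d0[i]; t01 += c0[i] * d1[i];
          t10 += c1[i] * d0[i]; t11 += c1[i] * d1[i];
        }
        for (int l = 0; l < 8; ++l) {
          t00 += s00[l]; t01 += s01[l]; t10 += s10[l]; t11 += s11[l];
        }
        dW(k, j) += t00; dW(k, j + 1) += t01;
        dW(k + 1, j) += t10; dW(k + 1, j + 1) += t11;
      }
      for (; j < N; ++j) {
        const float* d0 = D.colptr(j) + i0;
        float t0 = 0, t1 = 0;
        for (int i = 0; i < tm; ++i) { t0 += c0[i] * d0[i]; t1 += c1[i] * d0[i]; }
        dW(k, j) += t0; dW(k + 1, j) += t1;
      }
    }
    for (; k < K; ++k) {
      const float* c = C.colptr(k) + i0;
      for (int j = 0; j < N; ++j) {
        const float* d = D.colptr(j) + i0;
        float t = 0;
        for (int i = 0; i < tm; ++i) t += c[i] * d[i];
        dW(k, j) += t;
      }
    }
  }
}

#if FMRISID_HAS_DISPATCH
FMRISID_AVX void gemm_tn_acc_avx(const fmat& C, const fmat& D, fmat& dW) {
  gemm_tn_acc_body(C, D, dW);
}
#endif
void gemm_tn_acc(const fmat& C, const fmat& D, fmat& dW) {
#if FMRISID_HAS_DISPATCH
  if (cpu_has_avx2()) return gemm_tn_acc_avx(C, D, dW);
#endif
  gemm_tn_acc_body(C, D, dW);
}

struct Plan {
  imat layers;
  int n_layers() const { return layers.n_rows; }
  int type(int l) const { return layers(l, 0); }
  int cin(int l) const { return layers(l, 1); }
  int cout(int l) const { return layers(l, 2); }
  int dx(int l) const { return layers(l, 3); }
  int dy(int l) const { return layers(l, 4); }
  int dz(int l) const { return layers(l, 5); }
  int nvox(int l) const { return dx(l) * dy(l) * dz(l); }
};

// Gather 3x3x3 neighbourhoods of A (batch*nvox x cin) into C (batch*nvox x 27*cin).
void im2col(const fmat& A, fmat& C, int dx, int dy, int dz, int cin, int batch) {
  const int nvox = dx * dy * dz;
  C.zeros();
  for (int oz = -1; oz <= 1; ++oz) {
    for (int oy = -1; oy <= 1; ++oy) {
      for (int ox = -1; ox <= 1; ++ox) {
        const int o = (ox + 1) + 3 * (oy + 1) + 9 * (oz + 1);
        const int x0 = std::max(0, -ox), x1 = std::min(dx - 1, dx - 1 - ox);
        if (x1 < x0) continue;
        const int run = x1 - x0 + 1;
        const int z0 = std::max(0, -oz), z1 = std::min(dz - 1, dz - 1 - oz);
        const int y0 = std::max(0, -oy), y1 = std::min(dy - 1, dy - 1 - oy);
        for (int c = 0; c < cin; ++c) {
          const float* src = A.colptr(c);
          float* dst = C.colptr(o * cin + c);
          for (int s = 0; s < batch; ++s) {
            const int base = s * nvox;
            if (ox == 0 && oy == 0) {
              // full (x, y) planes are contiguous: one copy per sample
              const int dsti = base + dx * dy * z0;
              const int srci = base + dx * dy * (z0 + oz);
              std::memcpy(dst + dsti, src + srci,
                          (size_t)dx * dy * (z1 - z0 + 1) * sizeof(float));
            } else if (ox == 0) {
              for (int z = z0; z <= z1; ++z) {
                const int dsti = base + dx * (y0 + dy * z);
                const int srci = base + dx * ((y0 + oy) + dy * (z + oz));
                std::memcpy(dst + dsti, src + srci,
                            (size_t)dx * (y1 - y0 + 1) * sizeof(float));
              }
            } else {
              for (int z = z0; z <= z1; ++z) {
                for (int y = y0; y <= y1; ++y) {
                  const int dsti = base + x0 + dx * (y + dy * z);
                  const int srci = base + (x0 + ox) + dx * ((y + oy) + dy * (z + oz));
                  std::memcpy(dst + dsti, src + srci, run * sizeof(float));
                }
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col: dA += fold(dC).
void col2im_add(const fmat& dC, fmat& dA, int dx, int dy, int dz, int cin, int batch) {
  const int nvox = dx * dy * dz;
  for (int oz = -1; oz <= 1; ++oz) {
    for (int oy = -1; oy <= 1; ++oy) {
      for (int ox = -1; ox <= 1; ++ox) {
        const int o = (ox + 1) + 3 * (oy + 1) + 9 * (oz + 1);
        const int x0 = std::max(0, -ox), x1 = std::min(dx - 1, dx - 1 - ox);
        if (x1 < x0) continue;
        const int run = x1 - x0 + 1;
        for (int c = 0; c < cin; ++c) {
          const float* src = dC.colptr(o * cin + c);
          float* dst = dA.colptr(c);
          for (int s = 0; s < batch; ++s) {
            const int base = s * nvox;
            for (int z = std::max(0, -oz); z <= std::min(dz - 1, dz - 1 - oz); ++z) {
              for (int y = std::max(0, -oy); y <= std::min(dy - 1, dy - 1 - oy); ++y) {
                const float* sp = src + base + x0 + dx * (y + dy * z);
                float* dp = dst + base + (x0 + ox) + dx * ((y + oy) + dy * (z + oz));
                for (int i = 0; i < run; ++i) dp[i] += sp[i];
              }
            }
          }
        }
      }
    }
  }
}

void avgpool(const fmat& A, fmat& Y, int dx, int dy, int dz, int ch, int batch) {
  const int ox_ = dx / 2, oy_ = dy / 2, oz_ = dz / 2;
  const int nvox = dx * dy * dz, onv = ox_ * oy_ * oz_;
  for (int c = 0; c < ch; ++c) {
    const float* a = A.colptr(c);
    float* y = Y.colptr(c);
    for (int s = 0; s < batch; ++s) {
      for (int z = 0; z < oz_; ++z)
        for (int yy = 0; yy < oy_; ++yy)
          for (int x = 0; x < ox_; ++x) {
            float acc = 0.0f;
            for (int k = 0; k < 2; ++k)
              for (int j = 0; j < 2; ++j)
                for (int i = 0; i < 2; ++i)
                  acc += a[s * nvox + (2 * x + i) + dx * ((2 * yy + j) + dy * (2 * z + k))];
            y[s * onv + x + ox_ * (yy + oy_ * z)] = acc * 0.125f;
          }
    }
  }
}

void avgpool_back(const fmat& dY, fmat& dA, int dx, int dy, int dz, int ch, int batch) {
  const int ox_ = dx / 2, oy_ = dy / 2, oz_ = dz / 2;
  const int nvox = dx * dy * dz, onv = ox_ * oy_ * oz_;
  for (int c = 0; c < ch; ++c) {
    const float* dy_ = dY.colptr(c);
    float* da = dA.colptr(c);
    for (int s = 0; s < batch; ++s) {
      for (int z = 0; z < oz_; ++z)
        for (int yy = 0; yy < oy_; ++yy)
          for (int x = 0; x < ox_; ++x) {
            const float g = dy_[s * onv + x + ox_ * (yy + oy_ * z)] * 0.125f;
            for (int k = 0; k < 2; ++k)
              for (int j = 0; j < 2; ++j)
                for (int i = 0; i < 2; ++i)
                  da[s * nvox + (2 * x + i) + dx * ((2 * yy + j) + dy * (2 * z + k))] = g;
          }
    }
  }
}

struct Weights {
  std::vector<fmat> W;
  std::vector<fvec> b;
};

Weights unpack_weights(const Rcpp::List& wl) {
  Weights w;
  for (int i = 0; i < wl.size(); ++i) {
    Rcpp::List layer = wl[i];
    w.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(layer["W"])));
    w.b.push_back(conv_to<fvec>::from(Rcpp::as<vec>(layer["b"])));
  }
  return w;
}

// Forward pass for one batch; if `acts` is non-null the per-layer inputs are
// kept for backprop. Returns logits (n_subjects x batch).
struct Grads {
  std::vector<fmat> dW;
  std::vector<fvec> db;
};

// Preallocated per-batch-size buffers: activations (acts[l] is the input to
// layer l, acts[L] the dense feature matrix), im2col matrices per conv
// layer, and the gradient mirror of acts. Reused across iterations so the
// steady state allocates nothing.
struct Workspace {
  int batch = -1;
  std::vector<fmat> acts, cols, dacts;
  fmat logits, dlog;
};

void init_workspace(Workspace& ws, const Plan& plan, const Weights& w, int batch) {
  if (ws.batch == batch) return;
  ws.batch = batch;
  ws.acts.clear(); ws.cols.clear(); ws.dacts.clear();
  const int L = plan.n_layers();
  ws.acts.emplace_back(plan.nvox(0) * batch, plan.cin(0));
  for (int l = 0; l < L; ++l) {
    const int nvox = plan.nvox(l);
    if (plan.type(l) == 0) {
      ws.cols.emplace_back(nvox * batch, 27 * plan.cin(l));
      ws.acts.emplace_back(nvox * batch, plan.cout(l));
    } else if (plan.type(l) == 1) {
      ws.acts.emplace_back(nvox / 8 * batch, plan.cin(l));
    } else {
      const int nfeat = (plan.type(l) == 2) ? nvox * plan.cin(l) : plan.cin(l);
      ws.acts.emplace_back(nfeat, batch);
    }
  }
  for (int l = 0; l < L; ++l)
    ws.dacts.emplace_back(size(ws.acts[l]));
  const int nsub = plan.cout(L - 1);
  ws.logits.set_size(nsub, batch);
  ws.dlog.set_size(nsub, batch);
}

// Forward pass for one batch into ws.logits (n_subjects x batch).
void forward_ws(const fmat& X, const Plan& plan, const Weights& w,
                Workspace& ws) {
  const int batch = X.n_cols;
  const int nvox0 = plan.nvox(0);
  for (int s = 0; s < batch; ++s)
    for (int c = 0; c < plan.cin(0); ++c)
      std::memcpy(ws.acts[0].colptr(c) + s * nvox0, X.colptr(s) + c * nvox0,
                  nvox0 * sizeof(float));
  int wi = 0, ci = 0;
  const int L = plan.n_layers();
  for (int l = 0; l < L; ++l) {
    const int nvox = plan.nvox(l);
    const fmat& A = ws.acts[l];
    fmat& Y = ws.acts[l + 1];
    if (plan.type(l) == 0) {
      fmat& C = ws.cols[ci++];
      im2col(A, C, plan.dx(l), plan.dy(l), plan.dz(l), plan.cin(l), batch);
      gemm_small_n(C, w.W[wi], Y);
      Y.each_row() += w.b[wi].t();
      Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });  // ReLU
      ++wi;
    } else if (plan.type(l) == 1) {
      avgpool(A, Y, plan.dx(l), plan.dy(l), plan.dz(l), plan.cin(l), batch);
    } else if (plan.type(l) == 2) {
      for (int s = 0; s < batch; ++s)
        for (int c = 0; c < plan.cin(l); ++c)
          std::memcpy(Y.colptr(s) + c * nvox, A.colptr(c) + s * nvox,
                      nvox * sizeof(float));
      ws.logits = w.W[wi].t() * Y;
      ws.logits.each_col() += w.b[wi];
      ++wi;
    } else {  // global mean pool + dense
      for (int s = 0; s < batch; ++s)
        for (int c = 0; c < plan.cin(l); ++c) {
          float acc = 0.0f;
          const float* a = A.colptr(c) + s * nvox;
          for (int v = 0; v < nvox; ++v) acc += a[v];
          Y(c, s) = acc / nvox;
        }
      ws.logits = w.W[wi].t() * Y;
      ws.logits.each_col() += w.b[wi];
      ++wi;
    }
  }
}

// Softmax cross-entropy loss and full backward pass; returns mean loss.
float backward_ws(const fmat& X, const ivec& labels, const Plan& plan,
                  const Weights& w, Workspace& ws, Grads& g, float* batch_acc) {
  const int batch = X.n_cols;
  forward_ws(X, plan, w, ws);

  // softmax + CE
  float loss = 0.0f;
  int ncorrect = 0;
  for (int s = 0; s < batch; ++s) {
    fvec l = ws.logits.col(s);
    const float m = l.max();
    fvec e = exp(l - m);
    const float Z = accu(e);
    fvec p = e / Z;
    loss += -(l(labels(s)) - m - std::log(Z));
    if ((int)l.index_max() == labels(s)) ++ncorrect;
    p(labels(s)) -= 1.0f;
    ws.dlog.col(s) = p / batch;
  }
  loss /= batch;
  *batch_acc = (float)ncorrect / batch;

  int wi = w.W.size() - 1;
  int ci = (int)ws.cols.size();
  const int L = plan.n_layers();
  for (int l = L - 1; l >= 0; --l) {
    const int nvox = plan.nvox(l);
    fmat& dA = ws.dacts[l];  // gradient wrt the input of layer l
    if (plan.type(l) == 2 || plan.type(l) == 3) {
      const fmat& F = ws.acts[L];
      g.dW[wi] += F * ws.dlog.t();
      g.db[wi] += sum(ws.dlog, 1);
      const fmat dF = w.W[wi] * ws.dlog;
      --wi;
      if (plan.type(l) == 2) {
        for (int s = 0; s < batch; ++s)
          for (int c = 0; c < plan.cin(l); ++c)
            std::memcpy(dA.colptr(c) + s * nvox, dF.colptr(s) + c * nvox,
                        nvox * sizeof(float));
      } else {
        for (int s = 0; s < batch; ++s)
          for (int c = 0; c < plan.cin(l); ++c) {
            const float gv = dF(c, s) / nvox;
            float* dp = dA.colptr(c) + s * nvox;
            for (int v = 0; v < nvox; ++v) dp[v] = gv;
          }
      }
    } else if (plan.type(l) == 1) {
      avgpool_back(ws.dacts[l + 1], dA, plan.dx(l), plan.dy(l), plan.dz(l),
                   plan.cin(l), batch);
    } else {  // conv
      fmat& dY = ws.dacts[l + 1];
      const fmat& out = ws.acts[l + 1];  // post-ReLU output of this layer
      for (uword i = 0; i < out.n_elem; ++i)
        if (out[i] <= 0.0f) dY[i] = 0.0f;
      const fmat& C = ws.cols[--ci];
      gemm_tn_acc(C, dY, g.dW[wi]);
      g.db[wi] += sum(dY, 0).t();
      const fmat Wt = w.W[wi].t();
      fmat& dC = ws.cols[ci];  // reuse the im2col buffer for dC
      gemm_small_n(dY, Wt, dC);
      --wi;
      dA.zeros();
      col2im_add(dC, dA, plan.dx(l), plan.dy(l), plan.dz(l), plan.cin(l), batch);
    }
  }
  return loss;
}

Rcpp::List pack_weights(const Weights& w) {
  Rcpp::List out(w.W.size());
  for (size_t i = 0; i < w.W.size(); ++i) {
    out[i] = Rcpp::List::create(
        Rcpp::Named("W") = conv_to<mat>::from(w.W[i]),
        Rcpp::Named("b") = conv_to<vec>::from(w.b[i]));
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(const arma::mat& X, const arma::imat& plan_mat,
                          const Rcpp::List& weights, int chunk = 16) {
  Plan plan{plan_mat};
  Weights w = unpack_weights(weights);
  const int n = X.n_cols;
  fmat Xf = conv_to<fmat>::from(X);
  Workspace ws;
  mat out;
  bool first = true;
  for (int start = 0; start < n; start += chunk) {
    const int end = std::min(n, start + chunk);
    init_workspace(ws, plan, w, end - start);
    forward_ws(Xf.cols(start, end - 1), plan, w, ws);
    if (first) { out.set_size(ws.logits.n_rows, n); first = false; }
    out.cols(start, end - 1) = conv_to<mat>::from(ws.logits);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::mat& X, const arma::ivec& labels,
                         const arma::imat& plan_mat, const Rcpp::List& weights,
                         const arma::vec& lr_rates, const arma::ivec& lr_iters,
                         int batch_size, int seed, int log_every) {
  Plan plan{plan_mat};
  Weights w = unpack_weights(weights);
  const int n = X.n_cols;
  fmat Xf = conv_to<fmat>::from(X);

  // Adam state
  Grads g, m, v;
  for (size_t i = 0; i < w.W.size(); ++i) {
    g.dW.push_back(fmat(size(w.W[i]), fill::zeros));
    g.db.push_back(fvec(size(w.b[i]), fill::zeros));
    m.dW.push_back(fmat(size(w.W[i]), fill::zeros));
    m.db.push_back(fvec(size(w.b[i]), fill::zeros));
    v.dW.push_back(fmat(size(w.W[i]), fill::zeros));
    v.db.push_back(fvec(size(w.b[i]), fill::zeros));
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;

  std::mt19937 rng((uint32_t)seed);
  std::vector<double> log_iter, log_lr, log_loss, log_acc;
  Workspace ws;
  init_workspace(ws, plan, w, batch_size);

  int iter = 0;
  double b1t = 1.0, b2t = 1.0;
  for (uword stage = 0; stage < lr_rates.n_elem; ++stage) {
    const float lr = (float)lr_rates(stage);
    for (int si = 0; si < lr_iters(stage); ++si) {
      ++iter;
      fmat Xb(Xf.n_rows, batch_size);
      ivec yb(batch_size);
      for (int s = 0; s < batch_size; ++s) {
        const int idx = (int)(rng() % (uint32_t)n);
        Xb.col(s) = Xf.col(idx);
        yb(s) = labels(idx);
      }
      for (size_t i = 0; i < g.dW.size(); ++i) { g.dW[i].zeros(); g.db[i].zeros(); }
      float bacc = 0.0f;
      const float loss = backward_ws(Xb, yb, plan, w, ws, g, &bacc);
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged: non-finite loss at iteration %d", iter);

      b1t *= b1; b2t *= b2;
      const float c1 = 1.0f / (1.0f - (float)b1t), c2 = 1.0f / (1.0f - (float)b2t);
      for (size_t i = 0; i < w.W.size(); ++i) {
        m.dW[i] = b1 * m.dW[i] + (1.0f - b1) * g.dW[i];
        v.dW[i] = b2 * v.dW[i] + (1.0f - b2) * square(g.dW[i]);
        w.W[i] -= lr * (c1 * m.dW[i]) / (sqrt(c2 * v.dW[i]) + eps);
        m.db[i] = b1 * m.db[i] + (1.0f - b1) * g.db[i];
        v.db[i] = b2 * v.db[i] + (1.0f - b2) * square(g.db[i]);
        w.b[i] -= lr * (c1 * m.db[i]) / (sqrt(c2 * v.db[i]) + eps);
      }
      if (iter % log_every == 0 || iter == 1) {
        log_iter.push_back(iter); log_lr.push_back(lr);
        log_loss.push_back(loss); log_acc.push_back(bacc);
      }
      if (iter % 200 == 0) Rcpp::checkUserInterrupt();
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = pack_weights(w),
      Rcpp::Named("log") = Rcpp::DataFrame::create(
          Rcpp::Named("iteration") = log_iter, Rcpp::Named("lr") = log_lr,
          Rcpp::Named("loss") = log_loss, Rcpp::Named("accuracy") = log_acc));
}
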