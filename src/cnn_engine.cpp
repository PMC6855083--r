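// Compact CPU engine for the convolutional networks used in this package:
// 2-D "same" convolution (im2col + BLAS gemm), batch normalization, ReLU,
// non-overlapping floor max-pooling, dense head with optional dropout,
// softmax, and the summed-Bernoulli / categorical cross-entropy losses,
// with full backpropagation.  Templated over float (training speed) and
// double (gradient verification).
//
// Activation layout: a branch activation is a (C x N*H*W) matrix; within
// sample n, pixel (h, w) sits at column n*H*W + w*H + h.  Branch inputs are
// passed from R as numeric vectors in exactly that order (H*W fastest,
// samples consecutive).  Convolution weights for a (kh x kw, cin -> cout)
// layer form a (cin*kh*kw x cout) matrix with patch index
// q = c*kh*kw + dh*kw + dw.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// Large activation buffers (hundreds of MB) are allocated and freed every
// minibatch; keep them on the heap instead of per-allocation mmap so pages
// are reused across steps rather than refaulted.
static void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 1 << 30);
    mallopt(M_TRIM_THRESHOLD, 1 << 30);
    done = true;
  }
#endif
}

using namespace Rcpp;
using namespace arma;

static const double BN_EPS = 1e-5;

// probability clip before logarithms: 1e-12 in double; in float the
// complement 1 - 1e-12 is not representable, so use 1e-7 (just above
// float epsilon) there
template <typename eT> struct prob_clip { static constexpr eT value = (eT)1e-12; };
template <> struct prob_clip<float> { static constexpr float value = 1e-7f; };

enum OpCode { OP_CONV = 1, OP_BN = 2, OP_RELU = 3, OP_POOL = 4 };

struct OpSpec {
  int code;
  int a, b, c, d; // CONV: kh kw cin cout; BN: channels; POOL: ph pw
};

struct BranchSpec {
  int h, w, cin;
  std::vector<OpSpec> ops;
};

struct ArchSpec {
  std::vector<BranchSpec> branches;
  int fc_in, fc_hidden, n_classes;
};

static ArchSpec parse_arch(const List& arch) {
  ArchSpec spec;
  List branches = arch["branches"];
  for (int bi = 0; bi < branches.size(); ++bi) {
    List br = branches[bi];
    BranchSpec bs;
    bs.h = Rcpp::as<int>(br["h"]);
    bs.w = Rcpp::as<int>(br["w"]);
    bs.cin = Rcpp::as<int>(br["cin"]);
    IntegerMatrix ops = br["ops"];
    for (int i = 0; i < ops.nrow(); ++i) {
      OpSpec op;
      op.code = ops(i, 0);
      op.a = ops(i, 1); op.b = ops(i, 2); op.c = ops(i, 3); op.d = ops(i, 4);
      bs.ops.push_back(op);
    }
    spec.branches.push_back(bs);
  }
  spec.fc_in = Rcpp::as<int>(arch["fc_in"]);
  spec.fc_hidden = Rcpp::as<int>(arch["fc_hidden"]);
  spec.n_classes = Rcpp::as<int>(arch["n_classes"]);
  return spec;
}

template <typename eT>
struct Cursor {
  const double* p;
  R_xlen_t i, n;
  Cursor(const NumericVector& v) : p(v.begin()), i(0), n(v.size()) {}
  Mat<eT> mat(uword r, uword c) {
    if (i + (R_xlen_t)(r * c) > n) stop("parameter vector too short");
    Mat<eT> M(r, c);
    for (uword k = 0; k < r * c; ++k) M(k) = (eT)p[i++];
    return M;
  }
  Col<eT> col(uword r) {
    if (i + (R_xlen_t)r > n) stop("parameter vector too short");
    Col<eT> v(r);
    for (uword k = 0; k < r; ++k) v(k) = (eT)p[i++];
    return v;
  }
};

// parsed parameters / gradients, aligned with op indices
template <typename eT>
struct BranchParams {
  std::vector< Mat<eT> > W;          // conv weights per op (empty if not conv)
  std::vector< Col<eT> > b, g, be;   // conv bias, BN gamma, BN beta
  std::vector< Col<eT> > rm, rv;     // BN running mean / var (state)
};

template <typename eT>
struct Params {
  std::vector< BranchParams<eT> > br;
  Mat<eT> W1, W2;
  Col<eT> b1, b2;
};

template <typename eT>
static Params<eT> parse_params(const ArchSpec& as, const NumericVector& par) {
  Cursor<eT> cur(par);
  Params<eT> P;
  for (const BranchSpec& bs : as.branches) {
    BranchParams<eT> bp;
    size_t nops = bs.ops.size();
    bp.W.resize(nops); bp.b.resize(nops); bp.g.resize(nops); bp.be.resize(nops);
    bp.rm.resize(nops); bp.rv.resize(nops);
    for (size_t i = 0; i < nops; ++i) {
      const OpSpec& op = bs.ops[i];
      if (op.code == OP_CONV) {
        bp.W[i] = cur.mat((uword)op.c * op.a * op.b, op.d);
        bp.b[i] = cur.col(op.d);
      } else if (op.code == OP_BN) {
        bp.g[i] = cur.col(op.a);
        bp.be[i] = cur.col(op.a);
      }
    }
    P.br.push_back(bp);
  }
  P.W1 = cur.mat(as.fc_in, as.fc_hidden);
  P.b1 = cur.col(as.fc_hidden);
  P.W2 = cur.mat(as.fc_hidden, as.n_classes);
  P.b2 = cur.col(as.n_classes);
  if (cur.i != cur.n) stop("parameter vector length mismatch");
  return P;
}

template <typename eT>
static void parse_bn_state(const ArchSpec& as, const NumericVector& state,
                           Params<eT>& P) {
  Cursor<eT> cur(state);
  for (size_t bi = 0; bi < as.branches.size(); ++bi) {
    const BranchSpec& bs = as.branches[bi];
    for (size_t i = 0; i < bs.ops.size(); ++i) {
      if (bs.ops[i].code == OP_BN) {
        P.br[bi].rm[i] = cur.col(bs.ops[i].a);
        P.br[bi].rv[i] = cur.col(bs.ops[i].a);
      }
    }
  }
  if (cur.i != cur.n) stop("bn_state length mismatch");
}

// Patch index q = (dh*kw + dw)*cin + c: channels fastest, so each (pixel,
// kernel-cell) block is a contiguous run of cin values in both the patch
// matrix column and the activation column -> plain memcpy / vector adds.
template <typename eT>
static void im2col(const Mat<eT>& A, uword n, int H, int W, int kh, int kw,
                   Mat<eT>& B) {
  const int cin = A.n_rows;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const uword off = n * (uword)H * W;
  const uword nq = (uword)cin * kh * kw;
  for (int w = 0; w < W; ++w) {
    const bool w_edge = (w < pw) || (w >= W - (kw - 1 - pw));
    for (int h = 0; h < H; ++h) {
      const uword pcol = (uword)w * H + h;
      eT* bcol = B.colptr(pcol);
      // zero-pad only columns whose patch leaves the frame
      if (w_edge || h < ph || h >= H - (kh - 1 - ph)) {
        std::memset(bcol, 0, nq * sizeof(eT));
      }
      for (int dh = 0; dh < kh; ++dh) {
        const int hh = h + dh - ph;
        if (hh < 0 || hh >= H) continue;
        for (int dw = 0; dw < kw; ++dw) {
          const int ww = w + dw - pw;
          if (ww < 0 || ww >= W) continue;
          const uword src = off + (uword)ww * H + hh;
          std::memcpy(bcol + (uword)(dh * kw + dw) * cin, A.colptr(src),
                      cin * sizeof(eT));
        }
      }
    }
  }
}

template <typename eT>
static void col2im_add(const Mat<eT>& B, uword n, int H, int W, int kh, int kw,
                       Mat<eT>& dA) {
  const int cin = dA.n_rows;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const uword off = n * (uword)H * W;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const uword pcol = (uword)w * H + h;
      const eT* bcol = B.colptr(pcol);
      for (int dh = 0; dh < kh; ++dh) {
        const int hh = h + dh - ph;
        if (hh < 0 || hh >= H) continue;
        for (int dw = 0; dw < kw; ++dw) {
          const int ww = w + dw - pw;
          if (ww < 0 || ww >= W) continue;
          eT* dst = dA.colptr(off + (uword)ww * H + hh);
          const eT* src = bcol + (uword)(dh * kw + dw) * cin;
          for (int c = 0; c < cin; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// caches for backward; ReLU runs in place, so the activation "after op i"
// may live in an earlier slot: alias[k] maps "after k ops" to its storage
// index in acts
template <typename eT>
struct BranchCache {
  std::vector< Mat<eT> > acts;
  std::vector<int> alias;        // alias[k]: storage index of state after k ops
  std::vector<int> Hs, Ws;       // spatial dims entering each op
  std::vector< Mat<uword> > poolarg;
  std::vector< Col<eT> > bn_mean, bn_var;
  const Mat<eT>& after(int k) const { return acts[alias[k]]; }
};

template <typename eT>
static Mat<eT> branch_forward(const BranchSpec& bs, const BranchParams<eT>& bp,
                              Mat<eT> input, int N, bool training,
                              BranchCache<eT>* cache) {
  int H = bs.h, W = bs.w;
  size_t nops = bs.ops.size();
  Mat<eT> local;
  Mat<eT>* cur;
  if (cache) {
    cache->acts.resize(nops + 1);
    cache->alias.assign(nops + 1, 0);
    cache->Hs.resize(nops); cache->Ws.resize(nops);
    cache->poolarg.resize(nops);
    cache->bn_mean.resize(nops); cache->bn_var.resize(nops);
    cache->acts[0] = std::move(input);
    cur = &cache->acts[0];
  } else {
    local = std::move(input);
    cur = &local;
  }
  // store a freshly computed op output (fresh matrices get their own slot;
  // in-place ops alias the previous slot)
  auto place = [&](size_t i, Mat<eT>&& out) {
    if (cache) {
      cache->acts[i + 1] = std::move(out);
      cache->alias[i + 1] = (int)(i + 1);
      cur = &cache->acts[i + 1];
    } else {
      local = std::move(out);
      cur = &local;
    }
  };
  arma::wall_clock opt_;
  const bool prof = std::getenv("ECGSQC_PROF") != nullptr;
  for (size_t i = 0; i < nops; ++i) {
    const OpSpec& op = bs.ops[i];
    if (prof) opt_.tic();
    if (cache) { cache->Hs[i] = H; cache->Ws[i] = W; }
    if (op.code == OP_CONV) {
      const int kh = op.a, kw = op.b, cin = op.c, cout = op.d;
      const uword HW = (uword)H * W;
      const Mat<eT>& A = *cur;
      Mat<eT> out;
      const Mat<eT> Wt = bp.W[i].t();
      if (kh == 1 && kw == 1) {
        // 1x1 convolution is a plain channel mix: no patch matrix needed
        out = Wt * A;
      } else {
        // patch matrix over a chunk of samples: large enough that the gemm
        // is not call-overhead bound, small enough to stay cache-resident
        const int cs = std::max(1, (int)(4096 / HW));
        out.set_size(cout, (uword)N * HW);
        Mat<eT> B((uword)cin * kh * kw, (uword)cs * HW);
        for (int n0 = 0; n0 < N; n0 += cs) {
          const int nc = std::min(cs, N - n0);
          for (int k = 0; k < nc; ++k) {
            Mat<eT> Bv(B.colptr((uword)k * HW), B.n_rows, HW, false, true);
            im2col(A, (uword)(n0 + k), H, W, kh, kw, Bv);
          }
          // gemm writes straight into the output block
          Mat<eT> outv(out.colptr((uword)n0 * HW), cout, (uword)nc * HW,
                       false, true);
          const Mat<eT> Bv2(B.colptr(0), B.n_rows, (uword)nc * HW, false, true);
          outv = Wt * Bv2;
        }
      }
      out.each_col() += bp.b[i];
      place(i, std::move(out));
    } else if (op.code == OP_BN) {
      Mat<eT>& X = *cur;
      const uword C = X.n_rows, M = X.n_cols;
      Col<eT> m, v;
      if (training) {
        // single pass: per-channel sum and sum of squares
        Col<eT> s1(C, fill::zeros), s2(C, fill::zeros);
        for (uword j = 0; j < M; ++j) {
          const eT* a = X.colptr(j);
          eT* ps1 = s1.memptr(); eT* ps2 = s2.memptr();
          for (uword c = 0; c < C; ++c) { ps1[c] += a[c]; ps2[c] += a[c] * a[c]; }
        }
        m = s1 / (eT)M;
        v = s2 / (eT)M - square(m);
        v.transform([](eT x) { return x > (eT)0 ? x : (eT)0; });
      } else {
        m = bp.rm[i];
        v = bp.rv[i];
      }
      if (cache) { cache->bn_mean[i] = m; cache->bn_var[i] = v; }
      Col<eT> scale = bp.g[i] / sqrt(v + (eT)BN_EPS);
      const eT* psc = scale.memptr();
      const eT* pm = m.memptr();
      const eT* pbe = bp.be[i].memptr();
      if (cache) {
        // keep the pre-normalization activation for backward
        Mat<eT> out(C, M);
        for (uword j = 0; j < M; ++j) {
          const eT* a = X.colptr(j);
          eT* o = out.colptr(j);
          for (uword c = 0; c < C; ++c) o[c] = (a[c] - pm[c]) * psc[c] + pbe[c];
        }
        place(i, std::move(out));
      } else {
        for (uword j = 0; j < M; ++j) {
          eT* a = X.colptr(j);
          for (uword c = 0; c < C; ++c) a[c] = (a[c] - pm[c]) * psc[c] + pbe[c];
        }
        if (false) {}
      }
    } else if (op.code == OP_RELU) {
      cur->transform([](eT x) { return x > (eT)0 ? x : (eT)0; });
      if (cache) cache->alias[i + 1] = cache->alias[i];
    } else if (op.code == OP_POOL) {
      const int ph = op.a, pw = op.b;
      const int Ho = H / ph, Wo = W / pw;
      const Mat<eT>& A = *cur;
      const uword C = A.n_rows;
      Mat<eT> out(C, (uword)N * Ho * Wo);
      Mat<uword> arg;
      if (cache) arg.set_size(C, (uword)N * Ho * Wo);
      for (int n = 0; n < N; ++n) {
        for (int wo = 0; wo < Wo; ++wo) {
          for (int ho = 0; ho < Ho; ++ho) {
            const uword ocol = (uword)n * Ho * Wo + (uword)wo * Ho + ho;
            eT* obest = out.colptr(ocol);
            uword* oarg = cache ? arg.colptr(ocol) : nullptr;
            bool first = true;
            for (int dw = 0; dw < pw; ++dw) {
              const uword icolb = (uword)n * H * W + (uword)(wo * pw + dw) * H;
              for (int dh = 0; dh < ph; ++dh) {
                const uword icol = icolb + (uword)(ho * ph + dh);
                const eT* acol = A.colptr(icol);
                if (first) {
                  std::memcpy(obest, acol, C * sizeof(eT));
                  if (oarg) for (uword c = 0; c < C; ++c) oarg[c] = icol;
                  first = false;
                } else {
                  for (uword c = 0; c < C; ++c) {
                    if (acol[c] > obest[c]) {
                      obest[c] = acol[c];
                      if (oarg) oarg[c] = icol;
                    }
                  }
                }
              }
            }
          }
        }
      }
      if (cache) cache->poolarg[i] = std::move(arg);
      H = Ho; W = Wo;
      place(i, std::move(out));
    }
    if (prof) Rcpp::Rcout << "fwd op " << i << " code " << op.code << ": " << opt_.toc() << "\n";
  }
  return *cur;
}

template <typename eT>
static Mat<eT> branch_backward(const BranchSpec& bs, const BranchParams<eT>& bp,
                               const BranchCache<eT>& cache, const Mat<eT>& dOut,
                               int N, BranchParams<eT>& grad) {
  Mat<eT> dA = dOut;
  arma::wall_clock opt_;
  const bool prof = std::getenv("ECGSQC_PROF") != nullptr;
  for (int i = (int)bs.ops.size() - 1; i >= 0; --i) {
    const OpSpec& op = bs.ops[i];
    if (prof) opt_.tic();
    const int H = cache.Hs[i], W = cache.Ws[i];
    if (op.code == OP_CONV) {
      const int kh = op.a, kw = op.b, cin = op.c;
      const uword HW = (uword)H * W;
      const bool need_input_grad = (i > 0);  // the raw input has no gradient
      Col<eT> db = sum(dA, 1);
      if (kh == 1 && kw == 1) {
        const Mat<eT>& A = cache.after(i);
        grad.W[i] = A * dA.t();
        grad.b[i] = std::move(db);
        if (need_input_grad) {
          dA = bp.W[i] * dA;
        } else {
          dA.reset();
        }
      } else {
        const Mat<eT>& A = cache.after(i);
        Mat<eT> dW(bp.W[i].n_rows, bp.W[i].n_cols, fill::zeros);
        Mat<eT> dIn(cin, need_input_grad ? (uword)N * HW : 0, fill::zeros);
        const int cs = std::max(1, (int)(4096 / HW));
        Mat<eT> B((uword)cin * kh * kw, (uword)cs * HW);
        Mat<eT> dB;
        for (int n0 = 0; n0 < N; n0 += cs) {
          const int nc = std::min(cs, N - n0);
          for (int k = 0; k < nc; ++k) {
            Mat<eT> Bv(B.colptr((uword)k * HW), B.n_rows, HW, false, true);
            im2col(A, (uword)(n0 + k), H, W, kh, kw, Bv);
          }
          // zero-copy view of this chunk's output gradient
          const Mat<eT> dOn(const_cast<eT*>(dA.colptr((uword)n0 * HW)),
                            dA.n_rows, (uword)nc * HW, false, true);
          const Mat<eT> Bv2(B.colptr(0), B.n_rows, (uword)nc * HW, false, true);
          dW += Bv2 * dOn.t();
          if (need_input_grad) {
            dB = bp.W[i] * dOn;
            for (int k = 0; k < nc; ++k) {
              const Mat<eT> dBv(const_cast<eT*>(dB.colptr((uword)k * HW)),
                                dB.n_rows, HW, false, true);
              col2im_add(dBv, (uword)(n0 + k), H, W, kh, kw, dIn);
            }
          }
        }
        grad.W[i] = std::move(dW);
        grad.b[i] = std::move(db);
        dA = std::move(dIn);
      }
    } else if (op.code == OP_BN) {
      const Mat<eT>& X = cache.after(i);
      const Col<eT>& m = cache.bn_mean[i];
      const Col<eT>& v = cache.bn_var[i];
      const uword C = X.n_rows;
      const uword M = X.n_cols;
      Col<eT> invstd = 1.0 / sqrt(v + (eT)BN_EPS);
      Col<eT> dgamma(C, fill::zeros), dbeta(C, fill::zeros);
      const eT* pm = m.memptr();
      const eT* pis = invstd.memptr();
      // pass 1: dgamma = sum dY*xhat, dbeta = sum dY (xhat recomputed)
      for (uword j = 0; j < M; ++j) {
        const eT* x = X.colptr(j);
        const eT* dy = dA.colptr(j);
        eT* pg = dgamma.memptr(); eT* pb = dbeta.memptr();
        for (uword c = 0; c < C; ++c) {
          pg[c] += dy[c] * (x[c] - pm[c]) * pis[c];
          pb[c] += dy[c];
        }
      }
      // pass 2: dX = g*invstd/M * (M*dY - dbeta - xhat*dgamma), in place
      Col<eT> scale = bp.g[i] % invstd / (eT)M;
      const eT* psc = scale.memptr();
      const eT* pg = dgamma.memptr();
      const eT* pb = dbeta.memptr();
      for (uword j = 0; j < M; ++j) {
        const eT* x = X.colptr(j);
        eT* dy = dA.colptr(j);
        for (uword c = 0; c < C; ++c) {
          const eT xhat = (x[c] - pm[c]) * pis[c];
          dy[c] = psc[c] * ((eT)M * dy[c] - pb[c] - xhat * pg[c]);
        }
      }
      grad.g[i] = std::move(dgamma);
      grad.be[i] = std::move(dbeta);
    } else if (op.code == OP_RELU) {
      const Mat<eT>& Y = cache.after(i + 1);
      const eT* y = Y.memptr();
      eT* d = dA.memptr();
      for (uword k = 0; k < dA.n_elem; ++k) d[k] *= (eT)(y[k] > (eT)0);
    } else if (op.code == OP_POOL) {
      // sequential sweep: every input column is written exactly once
      const Mat<uword>& arg = cache.poolarg[i];
      const int ph = op.a, pw = op.b;
      const int Ho = H / ph, Wo = W / pw;
      const uword C = dA.n_rows;
      const bool exact = (H % ph == 0) && (W % pw == 0);
      Mat<eT> dIn(C, (uword)N * H * W, fill::none);
      if (!exact) dIn.zeros();
      for (int n = 0; n < N; ++n) {
        for (int wo = 0; wo < Wo; ++wo) {
          for (int ho = 0; ho < Ho; ++ho) {
            const uword ocol = (uword)n * Ho * Wo + (uword)wo * Ho + ho;
            const eT* pd = dA.colptr(ocol);
            const uword* pa = arg.colptr(ocol);
            for (int dw = 0; dw < pw; ++dw) {
              const uword icolb = (uword)n * H * W + (uword)(wo * pw + dw) * H;
              for (int dh = 0; dh < ph; ++dh) {
                const uword icol = icolb + (uword)(ho * ph + dh);
                eT* di = dIn.colptr(icol);
                for (uword c = 0; c < C; ++c) {
                  di[c] = (pa[c] == icol) ? pd[c] : (eT)0;
                }
              }
            }
          }
        }
      }
      dA = std::move(dIn);
    }
    if (prof) Rcpp::Rcout << "bwd op " << i << " code " << op.code << ": " << opt_.toc() << "\n";
  }
  return dA;
}

// flatten branch output (C x N*Hf*Wf) into per-sample feature columns
template <typename eT>
static void features_from_branch(const Mat<eT>& A, int N, Mat<eT>& F,
                                 uword row0) {
  const uword block = A.n_cols / N;         // Hf*Wf
  const uword C = A.n_rows;
  for (int n = 0; n < N; ++n) {
    for (uword p = 0; p < block; ++p) {
      for (uword c = 0; c < C; ++c) {
        F(row0 + p * C + c, n) = A(c, (uword)n * block + p);
      }
    }
  }
}

template <typename eT>
static void branch_grad_from_features(const Mat<eT>& dF, int N, uword row0,
                                      uword C, uword block, Mat<eT>& dA) {
  dA.set_size(C, (uword)N * block);
  for (int n = 0; n < N; ++n) {
    for (uword p = 0; p < block; ++p) {
      for (uword c = 0; c < C; ++c) {
        dA(c, (uword)n * block + p) = dF(row0 + p * C + c, n);
      }
    }
  }
}

template <typename eT>
static Mat<eT> softmax_cols(const Mat<eT>& Z) {
  Mat<eT> O = Z;
  for (uword j = 0; j < O.n_cols; ++j) {
    Col<eT> col = O.col(j);
    col -= col.max();
    col = exp(col);
    O.col(j) = col / accu(col);
  }
  return O;
}

template <typename eT>
static List engine_run(const ArchSpec& as, const NumericVector& par,
                       const List& inputs, const IntegerVector& y,
                       const NumericVector& bn_state,
                       Nullable<NumericMatrix> dropout_mask,
                       bool training, bool want_grad, int loss_type) {
  Params<eT> P = parse_params<eT>(as, par);
  if (!training) parse_bn_state(as, bn_state, P);
  const size_t nbr = as.branches.size();
  if ((size_t)inputs.size() != nbr) stop("inputs must have one element per branch");

  // N from first input
  NumericVector x0 = inputs[0];
  const BranchSpec& b0 = as.branches[0];
  const uword block0 = (uword)b0.h * b0.w * b0.cin;
  if (x0.size() % block0 != 0) stop("input size is not a multiple of the branch frame");
  const int N = (int)(x0.size() / block0);
  if (N == 0) stop("empty input batch");

  std::vector< BranchCache<eT> > caches(nbr);
  const bool want_cache = want_grad || training;  // training stats live in the cache
  std::vector<uword> feat_row0(nbr), feat_C(nbr), feat_block(nbr);
  Mat<eT> F(as.fc_in, N);
  uword row0 = 0;
  for (size_t bi = 0; bi < nbr; ++bi) {
    const BranchSpec& bs = as.branches[bi];
    NumericVector xv = inputs[bi];
    const uword block = (uword)bs.h * bs.w * bs.cin;
    if ((uword)xv.size() != block * N) stop("branch input size mismatch");
    Mat<eT> A(bs.cin, (uword)bs.h * bs.w * N);
    // input order: channel-major? branch inputs have cin = 1 here; general
    // case fills channel rows from contiguous per-sample planes
    const double* src = xv.begin();
    if (bs.cin == 1) {
      for (uword k = 0; k < A.n_elem; ++k) A(k) = (eT)src[k];
    } else {
      const uword hw = (uword)bs.h * bs.w;
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < bs.cin; ++c)
          for (uword p = 0; p < hw; ++p)
            A(c, (uword)n * hw + p) = (eT)src[(uword)n * block + (uword)c * hw + p];
    }
    Mat<eT> out = branch_forward<eT>(bs, P.br[bi], std::move(A), N, training,
                                     want_cache ? &caches[bi] : nullptr);
    feat_row0[bi] = row0;
    feat_C[bi] = out.n_rows;
    feat_block[bi] = out.n_cols / N;
    features_from_branch(out, N, F, row0);
    row0 += out.n_rows * (out.n_cols / N);
  }
  if (row0 != (uword)as.fc_in) stop("fc_in does not match flattened feature size");

  Mat<eT> Z1 = P.W1.t() * F;
  Z1.each_col() += P.b1;
  Mat<eT> H1 = Z1;
  H1.transform([](eT x) { return x > (eT)0 ? x : (eT)0; });
  Mat<eT> mask;
  bool has_mask = dropout_mask.isNotNull();
  Mat<eT> H1d = H1;
  if (has_mask) {
    NumericMatrix mm(dropout_mask);
    if ((uword)mm.nrow() != (uword)as.fc_hidden || mm.ncol() != N)
      stop("dropout mask must be fc_hidden x N");
    mask.set_size(as.fc_hidden, N);
    for (uword k = 0; k < mask.n_elem; ++k) mask(k) = (eT)mm[k];
    H1d %= mask;
  }
  Mat<eT> Z2 = P.W2.t() * H1d;
  Z2.each_col() += P.b2;
  Mat<eT> O = softmax_cols(Z2);
  const eT pclip = prob_clip<eT>::value;
  Mat<eT> Oc = clamp(O, pclip, (eT)1 - pclip);

  NumericMatrix probs(as.n_classes, N);
  for (uword k = 0; k < O.n_elem; ++k) probs[k] = (double)O(k);

  double loss = NA_REAL;
  const bool have_y = y.size() > 0;
  Mat<eT> Y;
  if (have_y) {
    if (y.size() != N) stop("y must have one label per sample");
    Y.zeros(as.n_classes, N);
    for (int n = 0; n < N; ++n) {
      int cls = y[n];
      if (cls < 0 || cls >= as.n_classes) stop("class label out of range");
      Y(cls, n) = (eT)1;
    }
    if (loss_type == 0) {
      // summed Bernoulli terms over all output units
      loss = (double)accu(-(Y % log(Oc) + (1.0 - Y) % log(1.0 - Oc))) / N;
    } else {
      loss = (double)accu(-(Y % log(Oc))) / N;
    }
  }

  // batch BN statistics (mean then var per BN op, traversal order),
  // available from any training-mode pass so running statistics can be
  // recalibrated with full passes after optimization
  std::vector<double> stats;
  if (training) {
    for (size_t bi = 0; bi < nbr; ++bi) {
      const BranchSpec& bs = as.branches[bi];
      for (size_t i = 0; i < bs.ops.size(); ++i) {
        if (bs.ops[i].code == OP_BN) {
          const Col<eT>& m = caches[bi].bn_mean[i];
          const Col<eT>& v = caches[bi].bn_var[i];
          for (uword k = 0; k < m.n_elem; ++k) stats.push_back((double)m(k));
          for (uword k = 0; k < v.n_elem; ++k) stats.push_back((double)v(k));
        }
      }
    }
  }
  if (!want_grad) {
    return List::create(_["probs"] = probs, _["loss"] = loss,
                        _["bn_batch"] = wrap(stats));
  }
  if (!have_y) stop("gradients require labels");

  // loss -> softmax input.  For the summed-Bernoulli form the gradient is
  // evaluated analytically through the softmax:
  //   dz_i = (O_i - y_i) + (1 - y_i) r_i - O_i * S,
  //   r_j = O_j / (1 - O_j),  S = sum_j (1 - y_j) r_j,
  // with 1 - O_j floored at the probability clip.  The naive composition
  // dL/dO * dO/dz loses the (1/O_t) * O_t cancellation once softmax
  // saturates in finite precision and the gradient spuriously vanishes.
  Mat<eT> dZ2(as.n_classes, N);
  if (loss_type == 0) {
    const int K = as.n_classes;
    for (int n = 0; n < N; ++n) {
      eT S = 0;
      Col<eT> r(K);
      for (int j = 0; j < K; ++j) {
        r(j) = O(j, n) / std::max((eT)1 - O(j, n), pclip);
        if (Y(j, n) == (eT)0) S += r(j);
      }
      for (int i = 0; i < K; ++i) {
        dZ2(i, n) = ((O(i, n) - Y(i, n)) + ((eT)1 - Y(i, n)) * r(i) -
                     O(i, n) * S) / (eT)N;
      }
    }
  } else {
    dZ2 = (O - Y) / (eT)N;
  }

  Params<eT> Gr;
  Gr.W2 = H1d * dZ2.t();
  Gr.b2 = sum(dZ2, 1);
  Mat<eT> dH1d = P.W2 * dZ2;
  if (has_mask) dH1d %= mask;
  Mat<eT> dZ1 = dH1d % conv_to< Mat<eT> >::from(H1 > (eT)0);
  Gr.W1 = F * dZ1.t();
  Gr.b1 = sum(dZ1, 1);
  Mat<eT> dF = P.W1 * dZ1;

  Gr.br.resize(nbr);
  for (size_t bi = 0; bi < nbr; ++bi) {
    const BranchSpec& bs = as.branches[bi];
    size_t nops = bs.ops.size();
    Gr.br[bi].W.resize(nops); Gr.br[bi].b.resize(nops);
    Gr.br[bi].g.resize(nops); Gr.br[bi].be.resize(nops);
    Mat<eT> dA;
    branch_grad_from_features(dF, N, feat_row0[bi], feat_C[bi], feat_block[bi], dA);
    branch_backward<eT>(bs, P.br[bi], caches[bi], dA, N, Gr.br[bi]);
  }

  // flatten gradient in parameter order
  NumericVector grad(par.size());
  R_xlen_t gi = 0;
  for (size_t bi = 0; bi < nbr; ++bi) {
    const BranchSpec& bs = as.branches[bi];
    for (size_t i = 0; i < bs.ops.size(); ++i) {
      if (bs.ops[i].code == OP_CONV) {
        const Mat<eT>& dW = Gr.br[bi].W[i];
        for (uword k = 0; k < dW.n_elem; ++k) grad[gi++] = (double)dW(k);
        const Col<eT>& db = Gr.br[bi].b[i];
        for (uword k = 0; k < db.n_elem; ++k) grad[gi++] = (double)db(k);
      } else if (bs.ops[i].code == OP_BN) {
        const Col<eT>& dg = Gr.br[bi].g[i];
        for (uword k = 0; k < dg.n_elem; ++k) grad[gi++] = (double)dg(k);
        const Col<eT>& dbe = Gr.br[bi].be[i];
        for (uword k = 0; k < dbe.n_elem; ++k) grad[gi++] = (double)dbe(k);
      }
    }
  }
  for (uword k = 0; k < Gr.W1.n_elem; ++k) grad[gi++] = (double)Gr.W1(k);
  for (uword k = 0; k < Gr.b1.n_elem; ++k) grad[gi++] = (double)Gr.b1(k);
  for (uword k = 0; k < Gr.W2.n_elem; ++k) grad[gi++] = (double)Gr.W2(k);
  for (uword k = 0; k < Gr.b2.n_elem; ++k) grad[gi++] = (double)Gr.b2(k);
  if (gi != par.size()) stop("internal gradient packing error");

  return List::create(_["probs"] = probs, _["loss"] = loss,
                      _["grad"] = grad, _["bn_batch"] = wrap(stats));
}

//' @noRd
// [[Rcpp::export(name = ".cnn_run_cpp")]]
List cnn_run_cpp(List arch, NumericVector par, List inputs, IntegerVector y,
                 NumericVector bn_state, Nullable<NumericMatrix> dropout_mask,
                 bool training, bool want_grad, int loss_type,
                 bool single_precision) {
  tune_allocator();
  ArchSpec as = parse_arch(arch);
  if (single_precision) {
    return engine_run<float>(as, par, inputs, y, bn_state, dropout_mask,
                             training, want_grad, loss_type);
  }
  return engine_run<double>(as, par, inputs, y, bn_state, dropout_mask,
                            training, want_grad, loss_type);
}
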