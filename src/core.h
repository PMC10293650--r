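// Float32 compute core for the 3D encoder-decoder network.
//
// Tensors are (nx, ny, nz, c, n) column-major, voxel index fastest.  3x3x3
// stride-1 convolutions use a zero-padded copy of each sample so that every
// kernel offset becomes a pure row offset, turning the convolution into 27
// accumulating sgemm calls on row-range subviews (no im2col buffer).
// Transposed convolutions (kernel 3, stride 2, output 2x) are realized as the
// backward-data pass of a strided convolution via im2col/col2im.

#ifndef QSMDI_CORE_H
#define QSMDI_CORE_H

#include <RcppArmadillo.h>
#include <cstring>
#include <vector>

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* a, const int* lda, const float* b,
                       const int* ldb, const float* beta, float* c,
                       const int* ldc);

namespace qsmdi {

using arma::fmat;
using arma::fvec;

// C (m x n) = alpha * op(A) op(B) + beta * C, column-major with leading
// dimensions; used for the row-offset subview products so no submatrix
// copies are made.
inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

struct FTensor {
  int nx = 0, ny = 0, nz = 0, c = 0, n = 0;
  std::vector<float> v;
  long nvox() const { return (long)nx * ny * nz; }
  long sample_stride() const { return nvox() * c; }
  long size() const { return sample_stride() * n; }
  void resize(int nx_, int ny_, int nz_, int c_, int n_,
              bool zero = false) {
    nx = nx_; ny = ny_; nz = nz_; c = c_; n = n_;
    v.resize(size());
    if (zero) std::fill(v.begin(), v.end(), 0.0f);
  }
  float* sample(int s) { return v.data() + (long)s * sample_stride(); }
  const float* sample(int s) const { return v.data() + (long)s * sample_stride(); }
};

// ---- padding helpers (pad = 1 ring of zeros) -------------------------------

inline void pad_sample(const float* x, int nx, int ny, int nz, int c,
                       fmat& Xpad) {
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  const long npad = (long)px * py * pz;
  Xpad.zeros(npad, c);
  for (int ci = 0; ci < c; ++ci) {
    const float* xc = x + (long)ci * nx * ny * nz;
    float* pc = Xpad.colptr(ci);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        std::memcpy(pc + 1 + (long)px * ((y + 1) + (long)py * (z + 1)),
                    xc + (long)nx * (y + (long)ny * z), sizeof(float) * nx);
  }
}

// extract interior rows of a padded (npad x c) matrix into a sample slice,
// adding an optional per-channel bias
inline void unpad_sample(const fmat& Ypad, int nx, int ny, int nz, int c,
                         const fvec* bias, float* y) {
  const int px = nx + 2, py = ny + 2;
  for (int co = 0; co < c; ++co) {
    const float* yp = Ypad.colptr(co);
    float* yd = y + (long)co * nx * ny * nz;
    const float bc = bias ? (*bias)[co] : 0.0f;
    for (int z = 0; z < nz; ++z)
      for (int yy = 0; yy < ny; ++yy) {
        const float* src = yp + 1 + (long)px * ((yy + 1) + (long)py * (z + 1));
        float* dst = yd + (long)nx * (yy + (long)ny * z);
        for (int x = 0; x < nx; ++x) dst[x] = src[x] + bc;
      }
  }
}

// ---- 3x3x3 stride-1 convolution (shift-gemm) -------------------------------
// W: 27 matrices (cin x cout), index t = tx + 3*ty + 9*tz.
//
// Each sample is zero-padded and tripled along the channel axis into
// X3(r, tx*cin + ci) = Xpad(r + tx - 1, ci), so all 27 kernel offsets reduce
// to the nine (ty, tz) row offsets, each a single accumulating sgemm with
// inner dimension 3*cin (BLAS handles these far better than width-8 panels).
// Rows clipped by the +-1 x-shift only ever pair with padding rows, which
// are zero or discarded, so the clipping is harmless.

// stack three x-shifted copies of a column block
inline void xshift3(const fmat& XP, fmat& X3) {
  const long npad = XP.n_rows;
  const int c = XP.n_cols;
  X3.set_size(npad, 3 * c);
  for (int ci = 0; ci < c; ++ci) {
    const float* src = XP.colptr(ci);
    for (int tx = 0; tx < 3; ++tx) {
      float* dst = X3.colptr(tx * c + ci);
      if (tx == 0) {              // X3(r) = XP(r - 1)
        dst[0] = 0.0f;
        std::memcpy(dst + 1, src, sizeof(float) * (npad - 1));
      } else if (tx == 1) {
        std::memcpy(dst, src, sizeof(float) * npad);
      } else {                    // X3(r) = XP(r + 1)
        std::memcpy(dst, src + 1, sizeof(float) * (npad - 1));
        dst[npad - 1] = 0.0f;
      }
    }
  }
}

// pad + triple-stack in one pass: middle block is the padded sample, side
// blocks its +-1 row shifts (no intermediate padded copy)
inline void pad3_sample(const float* x, int nx, int ny, int nz, int c,
                        fmat& X3) {
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  const long npad = (long)px * py * pz;
  X3.set_size(npad, 3 * c);
  for (int ci = 0; ci < c; ++ci) {
    float* mid = X3.colptr(c + ci);
    std::memset(mid, 0, sizeof(float) * npad);
    const float* xc = x + (long)ci * nx * ny * nz;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        std::memcpy(mid + 1 + (long)px * ((y + 1) + (long)py * (z + 1)),
                    xc + (long)nx * (y + (long)ny * z), sizeof(float) * nx);
    float* lo = X3.colptr(ci);
    lo[0] = 0.0f;
    std::memcpy(lo + 1, mid, sizeof(float) * (npad - 1));
    float* hi = X3.colptr(2 * c + ci);
    std::memcpy(hi, mid + 1, sizeof(float) * (npad - 1));
    hi[npad - 1] = 0.0f;
  }
}

// padcache (if given) stores X3 per sample for reuse in conv3_bw
inline void conv3_fw(const FTensor& x, const std::vector<fmat>& W,
                     const fvec& b, FTensor& y,
                     std::vector<fmat>* padcache) {
  const int cin = x.c, cout = W[0].n_cols;
  y.resize(x.nx, x.ny, x.nz, cout, x.n);
  const int px = x.nx + 2, py = x.ny + 2, pz = x.nz + 2;
  const long npad = (long)px * py * pz;
  if (padcache) padcache->resize(x.n);
  // Wstack[tyz](tx*cin + ci, co) = W[tx + 3*tyz](ci, co)
  std::vector<fmat> Wstack(9);
  for (int tyz = 0; tyz < 9; ++tyz) {
    Wstack[tyz].set_size(3 * cin, cout);
    for (int tx = 0; tx < 3; ++tx)
      Wstack[tyz].rows(tx * cin, tx * cin + cin - 1) = W[tx + 3 * tyz];
  }
  // narrow outputs: one wide gemm (n = 9*cout) plus shifted folds beats
  // nine thin-panel gemms; wide outputs: accumulate per (ty, tz) offset
  const bool wide = 9 * cout <= 96;
  fmat Wall;
  if (wide) {
    Wall.set_size(3L * cin, 9L * cout);
    for (int tyz = 0; tyz < 9; ++tyz)
      Wall.cols((long)tyz * cout, (long)tyz * cout + cout - 1) = Wstack[tyz];
  }
  fmat X3local, Ypad(npad, cout), Y9;
  for (int s = 0; s < x.n; ++s) {
    fmat& X3 = padcache ? (*padcache)[s] : X3local;
    pad3_sample(x.sample(s), x.nx, x.ny, x.nz, cin, X3);
    Ypad.zeros();
    if (wide) {
      // Y9(rho, tyz*cout + co) = X3(rho) Wstack[tyz]; output row is
      // r = rho - offyz, so fold with a shifted contiguous add
      Y9 = X3 * Wall;
      for (int tyz = 0; tyz < 9; ++tyz) {
        const int ty = tyz % 3, tz = tyz / 3;
        const long off = (long)px * ((ty - 1) + (long)py * (tz - 1));
        const long a = std::max(0L, -off), e = npad - 1 - std::max(0L, off);
        for (int co = 0; co < cout; ++co) {
          const float* src = Y9.colptr((long)tyz * cout + co) + (a + off);
          float* dst = Ypad.colptr(co) + a;
          for (long i = 0; i <= e - a; ++i) dst[i] += src[i];
        }
      }
    } else {
      for (int tyz = 0; tyz < 9; ++tyz) {
        const int ty = tyz % 3, tz = tyz / 3;
        const long offyz = (long)px * ((ty - 1) + (long)py * (tz - 1));
        const long a = std::max(0L, -offyz), e = npad - 1 - std::max(0L, offyz);
        sgemm('N', 'N', int(e - a + 1), cout, 3 * cin, 1.0f,
              X3.memptr() + (a + offyz), int(npad),
              Wstack[tyz].memptr(), 3 * cin, 1.0f, Ypad.memptr() + a,
              int(npad));
      }
    }
    unpad_sample(Ypad, x.nx, x.ny, x.nz, cout, &b, y.sample(s));
  }
}

inline void conv3_bw(const std::vector<fmat>& padcache,
                     const std::vector<fmat>& W, const FTensor& dy,
                     FTensor* dx, std::vector<fmat>& dW, fvec& db) {
  const int cin = W[0].n_rows, cout = W[0].n_cols;
  const int nx = dy.nx, ny = dy.ny, nz = dy.nz;
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  const long npad = (long)px * py * pz;
  dW.assign(27, fmat(cin, cout));
  db.zeros(cout);
  if (dx) dx->resize(nx, ny, nz, cin, dy.n);
  // Backward-data pairs dY3 block b (x-shift +(b-1)) with the x-mirrored
  // weight W[(2-b) + 3*tyz], since dX(u) reads dY at u - off_t.
  std::vector<fmat> Vstack(9);
  for (int tyz = 0; tyz < 9; ++tyz) {
    Vstack[tyz].set_size(3 * cout, cin);
    for (int b = 0; b < 3; ++b)
      Vstack[tyz].rows(b * cout, b * cout + cout - 1) =
        W[(2 - b) + 3 * tyz].t();
  }
  fmat dY3, dXpad;
  fmat dY9(npad, 9L * cout);
  fmat dWall(3L * cin, 9L * cout, arma::fill::zeros);
  for (int s = 0; s < dy.n; ++s) {
    // dY3(r, tx*cout + co) = dYpad(r + tx - 1, co); middle block is dYpad
    pad3_sample(dy.sample(s), nx, ny, nz, cout, dY3);
    const float* dYpad = dY3.colptr(cout);
    const fmat& X3 = padcache[s];
    const float* dys = dy.sample(s);
    for (int co = 0; co < cout; ++co) {
      double acc = 0.0;
      const float* dyc = dys + (long)co * dy.nvox();
      for (long i = 0; i < dy.nvox(); ++i) acc += dyc[i];
      db[co] += float(acc);
    }
    // dY9(rho, tyz*cout + co) = dYpad(rho - offyz, co); terms clipped by the
    // shift only ever multiply padding rows of X3 or zero rows of dYpad
    for (int tyz = 0; tyz < 9; ++tyz) {
      const int ty = tyz % 3, tz = tyz / 3;
      const long off = (long)px * ((ty - 1) + (long)py * (tz - 1));
      for (int co = 0; co < cout; ++co) {
        float* dst = dY9.colptr((long)tyz * cout + co);
        const float* src = dYpad + (long)co * npad;
        std::memset(dst, 0, sizeof(float) * npad);
        std::memcpy(dst + std::max(0L, off), src + std::max(0L, -off),
                    sizeof(float) * (npad - std::labs(off)));
      }
    }
    // all 27 weight gradients in one product:
    // dWall(tx*cin + ci, tyz*cout + co) = sum_rho X3(rho) dY9(rho)
    //   = sum_r Xpad(r + off_t, ci) dY(r, co) with t = tx + 3*tyz
    sgemm('T', 'N', 3 * cin, 9 * cout, int(npad), 1.0f, X3.memptr(),
          int(npad), dY9.memptr(), int(npad), 1.0f, dWall.memptr(),
          3 * cin);
    if (dx) {
      dXpad.zeros(npad, cin);
      for (int tyz = 0; tyz < 9; ++tyz) {
        const int ty = tyz % 3, tz = tyz / 3;
        const long offyz = (long)px * ((ty - 1) + (long)py * (tz - 1));
        // dX(u) = sum_t dY(u - off_t) W_t^T: dY3 stacks the x-shifts, so
        // only the nine -offyz row offsets remain
        const long a2 = std::max(0L, offyz),
                   e2 = npad - 1 + std::min(0L, offyz);
        sgemm('N', 'N', int(e2 - a2 + 1), cin, 3 * cout, 1.0f,
              dY3.memptr() + (a2 - offyz), int(npad),
              Vstack[tyz].memptr(), 3 * cout, 1.0f,
              dXpad.memptr() + a2, int(npad));
      }
      unpad_sample(dXpad, nx, ny, nz, cin, nullptr, dx->sample(s));
    }
  }
  for (int tyz = 0; tyz < 9; ++tyz)
    for (int tx = 0; tx < 3; ++tx)
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          dW[tx + 3 * tyz](ci, co) =
            dWall((long)tx * cin + ci, (long)tyz * cout + co);
}

// ---- 1x1x1 convolution ------------------------------------------------------

inline void conv1_fw(const FTensor& x, const fmat& W, const fvec& b,
                     FTensor& y) {
  const int cout = W.n_cols;
  y.resize(x.nx, x.ny, x.nz, cout, x.n);
  const long nv = x.nvox();
  for (int s = 0; s < x.n; ++s) {
    const fmat Xm(const_cast<float*>(x.sample(s)), nv, x.c, false, true);
    fmat Ym(y.sample(s), nv, cout, false, true);
    Ym = Xm * W;
    Ym.each_row() += b.t();
  }
}

inline void conv1_bw(const FTensor& x, const fmat& W, const FTensor& dy,
                     FTensor* dx, fmat& dW, fvec& db) {
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(W.n_cols);
  if (dx) dx->resize(x.nx, x.ny, x.nz, x.c, x.n);
  const long nv = x.nvox();
  for (int s = 0; s < x.n; ++s) {
    const fmat Xm(const_cast<float*>(x.sample(s)), nv, x.c, false, true);
    const fmat dYm(const_cast<float*>(dy.sample(s)), nv, dy.c, false, true);
    dW += Xm.t() * dYm;
    db += arma::sum(dYm, 0).t();
    if (dx) {
      fmat dXm(dx->sample(s), nv, x.c, false, true);
      dXm = dYm * W.t();
    }
  }
}

// ---- im2col / col2im (kernel 3, used by the transposed convolution) --------

inline int conv_out_size(int n, int stride) { return (n + 2 - 3) / stride + 1; }

inline void im2col3(const float* x, int nx, int ny, int nz, int c, int stride,
                    fmat& colT) {
  const int ox = conv_out_size(nx, stride), oy = conv_out_size(ny, stride),
            oz = conv_out_size(nz, stride);
  const long nvox_in = (long)nx * ny * nz;
  colT.set_size((long)ox * oy * oz, 27L * c);
  for (int ci = 0; ci < c; ++ci) {
    const float* xc = x + ci * nvox_in;
    for (int t = 0; t < 27; ++t) {
      const int tx = t % 3, ty = (t / 3) % 3, tz = t / 9;
      float* col = colT.colptr(t + 27L * ci);
      for (int z = 0; z < oz; ++z) {
        const int iz = z * stride + tz - 1;
        for (int y = 0; y < oy; ++y) {
          const int iy = y * stride + ty - 1;
          float* dst = col + (long)ox * (y + (long)oy * z);
          if (iz < 0 || iz >= nz || iy < 0 || iy >= ny) {
            std::memset(dst, 0, sizeof(float) * ox);
            continue;
          }
          const float* src = xc + (long)nx * (iy + (long)ny * iz);
          for (int x_ = 0; x_ < ox; ++x_) {
            const int ix = x_ * stride + tx - 1;
            dst[x_] = (ix >= 0 && ix < nx) ? src[ix] : 0.0f;
          }
        }
      }
    }
  }
}

inline void col2im3(const fmat& colT, int nx, int ny, int nz, int c, int stride,
                    float* x) {
  const int ox = conv_out_size(nx, stride), oy = conv_out_size(ny, stride),
            oz = conv_out_size(nz, stride);
  const long nvox_in = (long)nx * ny * nz;
  for (int ci = 0; ci < c; ++ci) {
    float* xc = x + ci * nvox_in;
    for (int t = 0; t < 27; ++t) {
      const int tx = t % 3, ty = (t / 3) % 3, tz = t / 9;
      const float* col = colT.colptr(t + 27L * ci);
      for (int z = 0; z < oz; ++z) {
        const int iz = z * stride + tz - 1;
        if (iz < 0 || iz >= nz) continue;
        for (int y = 0; y < oy; ++y) {
          const int iy = y * stride + ty - 1;
          if (iy < 0 || iy >= ny) continue;
          const float* src = col + (long)ox * (y + (long)oy * z);
          float* dst = xc + (long)nx * (iy + (long)ny * iz);
          for (int x_ = 0; x_ < ox; ++x_) {
            const int ix = x_ * stride + tx - 1;
            if (ix >= 0 && ix < nx) dst[ix] += src[x_];
          }
        }
      }
    }
  }
}

// ---- transposed convolution: kernel 3, stride 2, pad 1, output pad 1 -------
// Maps (n^3, cin) -> ((2n)^3, cout).  Weight Wm is (27*cout x cin): the
// weight of the underlying stride-2 convolution (cout -> cin) whose
// backward-data pass this layer computes.

inline void convt3_fw(const FTensor& x, const fmat& Wm, const fvec& b,
                      FTensor& y) {
  const int cout = Wm.n_rows / 27, cin = Wm.n_cols;
  const int ox = 2 * x.nx, oy = 2 * x.ny, oz = 2 * x.nz;
  y.resize(ox, oy, oz, cout, x.n, true);
  const long out_vox = (long)ox * oy * oz;
  for (int s = 0; s < x.n; ++s) {
    const fmat Xm(const_cast<float*>(x.sample(s)), x.nvox(), cin, false, true);
    fmat colT = Xm * Wm.t();                  // (nvox_in x 27*cout)
    float* ys = y.sample(s);
    col2im3(colT, ox, oy, oz, cout, 2, ys);   // y was zero-initialized
    for (int co = 0; co < cout; ++co) {
      float* yc = ys + co * out_vox;
      const float bc = b[co];
      for (long i = 0; i < out_vox; ++i) yc[i] += bc;
    }
  }
}

inline void convt3_bw(const FTensor& x, const fmat& Wm, const FTensor& dy,
                      FTensor* dx, fmat& dWm, fvec& db) {
  const int cout = Wm.n_rows / 27, cin = Wm.n_cols;
  dWm.zeros(Wm.n_rows, Wm.n_cols);
  db.zeros(cout);
  if (dx) dx->resize(x.nx, x.ny, x.nz, cin, x.n);
  const long out_vox = dy.nvox();
  fmat colT;
  for (int s = 0; s < x.n; ++s) {
    im2col3(dy.sample(s), dy.nx, dy.ny, dy.nz, cout, 2, colT);
    const fmat Xm(const_cast<float*>(x.sample(s)), x.nvox(), cin, false, true);
    dWm += colT.t() * Xm;
    const float* dys = dy.sample(s);
    for (int co = 0; co < cout; ++co) {
      double acc = 0.0;
      const float* dyc = dys + co * out_vox;
      for (long i = 0; i < out_vox; ++i) acc += dyc[i];
      db[co] += float(acc);
    }
    if (dx) {
      fmat dXm(dx->sample(s), x.nvox(), cin, false, true);
      dXm = colT * Wm;
    }
  }
}

// ---- 2x2x2 max pooling ------------------------------------------------------

inline void maxpool_fw(const FTensor& x, FTensor& y, std::vector<long>& idx) {
  const int ox = x.nx / 2, oy = x.ny / 2, oz = x.nz / 2;
  y.resize(ox, oy, oz, x.c, x.n);
  idx.assign(y.size(), 0);
  long o = 0;
  for (int s = 0; s < x.n; ++s)
    for (int c = 0; c < x.c; ++c) {
      const long base = ((long)s * x.c + c) * x.nvox();
      for (int z = 0; z < oz; ++z)
        for (int yy = 0; yy < oy; ++yy)
          for (int xx = 0; xx < ox; ++xx) {
            float best = -std::numeric_limits<float>::infinity();
            long besti = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dyy = 0; dyy < 2; ++dyy)
                for (int dxx = 0; dxx < 2; ++dxx) {
                  const long i = base + (2 * xx + dxx) +
                    (long)x.nx * ((2 * yy + dyy) + (long)x.ny * (2 * z + dz));
                  if (x.v[i] > best) { best = x.v[i]; besti = i; }
                }
            y.v[o] = best;
            idx[o] = besti;
            ++o;
          }
    }
}

inline void maxpool_bw(const FTensor& dy, const std::vector<long>& idx,
                       int nx, int ny, int nz, FTensor& dx) {
  dx.resize(nx, ny, nz, dy.c, dy.n, true);
  for (long i = 0; i < (long)dy.size(); ++i) dx.v[idx[i]] += dy.v[i];
}

// ---- batch normalization (per channel over space x batch) -------------------

inline void bn_fw(const FTensor& x, const fvec& gamma, const fvec& beta,
                  fvec& rmean, fvec& rvar, float eps, float momentum,
                  bool training, FTensor& y, fvec& mean, fvec& var) {
  y.resize(x.nx, x.ny, x.nz, x.c, x.n);
  mean.set_size(x.c); var.set_size(x.c);
  const long nv = x.nvox();
  const double ntot = double(nv) * x.n;
  for (int c = 0; c < x.c; ++c) {
    double m, v;
    if (training) {
      double acc = 0, acc2 = 0;
      for (int s = 0; s < x.n; ++s) {
        const float* xc = x.sample(s) + c * nv;
        for (long i = 0; i < nv; ++i) { acc += xc[i]; acc2 += double(xc[i]) * xc[i]; }
      }
      m = acc / ntot;
      v = std::max(acc2 / ntot - m * m, 0.0);
      rmean[c] = (1 - momentum) * rmean[c] + momentum * float(m);
      rvar[c] = (1 - momentum) * rvar[c] + momentum * float(v);
    } else {
      m = rmean[c]; v = rvar[c];
    }
    mean[c] = float(m); var[c] = float(v);
    const float ivar = 1.0f / std::sqrt(float(v) + eps);
    const float g = gamma[c], b = beta[c];
    for (int s = 0; s < x.n; ++s) {
      const float* xc = x.sample(s) + c * nv;
      float* yc = y.sample(s) + c * nv;
      for (long i = 0; i < nv; ++i) yc[i] = g * (xc[i] - float(m)) * ivar + b;
    }
  }
}

inline void bn_bw(const FTensor& x, const FTensor& dy, const fvec& gamma,
                  const fvec& mean, const fvec& var, float eps,
                  FTensor& dx, fvec& dgamma, fvec& dbeta) {
  dx.resize(x.nx, x.ny, x.nz, x.c, x.n);
  dgamma.zeros(x.c); dbeta.zeros(x.c);
  const long nv = x.nvox();
  const double ntot = double(nv) * x.n;
  for (int c = 0; c < x.c; ++c) {
    const float m = mean[c];
    const float ivar = 1.0f / std::sqrt(var[c] + eps);
    double sdy = 0, sdyx = 0;
    for (int s = 0; s < x.n; ++s) {
      const float* xc = x.sample(s) + c * nv;
      const float* dyc = dy.sample(s) + c * nv;
      for (long i = 0; i < nv; ++i) {
        sdy += dyc[i];
        sdyx += double(dyc[i]) * (xc[i] - m) * ivar;
      }
    }
    dgamma[c] = float(sdyx);
    dbeta[c] = float(sdy);
    const float g = gamma[c];
    const float c1 = float(sdy / ntot), c2 = float(sdyx / ntot);
    for (int s = 0; s < x.n; ++s) {
      const float* xc = x.sample(s) + c * nv;
      const float* dyc = dy.sample(s) + c * nv;
      float* dxc = dx.sample(s) + c * nv;
      for (long i = 0; i < nv; ++i) {
        const float xhat = (xc[i] - m) * ivar;
        dxc[i] = g * ivar * (dyc[i] - c1 - xhat * c2);
      }
    }
  }
}

// ---- ReLU -------------------------------------------------------------------

inline void relu_fw(FTensor& x) {
  for (auto& e : x.v) if (e < 0) e = 0;
}

inline void relu_bw(const FTensor& y, FTensor& dy) {
  for (long i = 0; i < (long)dy.size(); ++i) if (y.v[i] <= 0) dy.v[i] = 0;
}

// ---- R interop --------------------------------------------------------------

inline FTensor from_r(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 5)
    Rcpp::stop("expected a 5-D array (nx, ny, nz, channels, batch)");
  FTensor t;
  t.resize(d[0], d[1], d[2], d[3], d[4]);
  const double* p = REAL(x);
  for (long i = 0; i < (long)t.size(); ++i) t.v[i] = float(p[i]);
  return t;
}

inline Rcpp::NumericVector to_r(const FTensor& t) {
  Rcpp::NumericVector y((R_xlen_t)t.size());
  y.attr("dim") = Rcpp::IntegerVector::create(t.nx, t.ny, t.nz, t.c, t.n);
  double* p = REAL(y);
  for (long i = 0; i < (long)t.size(); ++i) p[i] = double(t.v[i]);
  return y;
}

// conv weight (3,3,3,cin,cout) R array -> 27 matrices (cin x cout)
inline std::vector<fmat> conv_w_from_r(const Rcpp::NumericVector& w) {
  Rcpp::IntegerVector d = w.attr("dim");
  if (d.size() != 5 || d[0] != 3 || d[1] != 3 || d[2] != 3)
    Rcpp::stop("conv weight must be a (3,3,3,cin,cout) array");
  const int cin = d[3], cout = d[4];
  std::vector<fmat> W(27, fmat(cin, cout));
  const double* p = REAL(w);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int t = 0; t < 27; ++t)
        W[t](ci, co) = float(p[t + 27L * (ci + (long)cin * co)]);
  return W;
}

inline Rcpp::NumericVector conv_w_to_r(const std::vector<fmat>& W) {
  const int cin = W[0].n_rows, cout = W[0].n_cols;
  Rcpp::NumericVector w((R_xlen_t)27 * cin * cout);
  w.attr("dim") = Rcpp::IntegerVector::create(3, 3, 3, cin, cout);
  double* p = REAL(w);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int t = 0; t < 27; ++t)
        p[t + 27L * (ci + (long)cin * co)] = double(W[t](ci, co));
  return w;
}

// transposed-conv weight (3,3,3,cout,cin) R array -> (27*cout x cin) matrix
inline fmat convt_w_from_r(const Rcpp::NumericVector& w) {
  Rcpp::IntegerVector d = w.attr("dim");
  if (d.size() != 5 || d[0] != 3)
    Rcpp::stop("transposed-conv weight must be a (3,3,3,cout,cin) array");
  const int cout = d[3], cin = d[4];
  fmat Wm(27L * cout, cin);
  const double* p = REAL(w);
  for (int ci = 0; ci < cin; ++ci)
    for (int co = 0; co < cout; ++co)
      for (int t = 0; t < 27; ++t)
        Wm(t + 27L * co, ci) = float(p[t + 27L * (co + (long)cout * ci)]);
  return Wm;
}

inline Rcpp::NumericVector convt_w_to_r(const fmat& Wm) {
  const int cout = Wm.n_rows / 27, cin = Wm.n_cols;
  Rcpp::NumericVector w((R_xlen_t)27 * cin * cout);
  w.attr("dim") = Rcpp::IntegerVector::create(3, 3, 3, cout, cin);
  double* p = REAL(w);
  for (int ci = 0; ci < cin; ++ci)
    for (int co = 0; co < cout; ++co)
      for (int t = 0; t < 27; ++t)
        p[t + 27L * (co + (long)cout * ci)] = double(Wm(t + 27L * co, ci));
  return w;
}

inline fvec fvec_from_r(const Rcpp::NumericVector& x) {
  fvec v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v[i] = float(x[i]);
  return v;
}

inline Rcpp::NumericVector fvec_to_r(const fvec& v) {
  Rcpp::NumericVector x(v.n_elem);
  for (size_t i = 0; i < v.n_elem; ++i) x[i] = double(v[i]);
  return x;
}

} // namespace qsmdi

#endif
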