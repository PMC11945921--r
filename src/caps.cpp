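// Hot kernels for the capsule network: im2col/col2im for the 1-D
// convolutions and the dynamic-routing inner loops. Layouts match the R
// side: activations (channels, positions, batch), capsule predictions
// (D, Q, R, B), all column-major.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector A, int cin, int L, int B, int k,
                         int stride) {
  const int P = (L - k) / stride + 1;
  NumericMatrix out(cin * k, P * B);
  const double *a = A.begin();
  double *o = out.begin();
  for (int b = 0; b < B; ++b) {
    const double *ab = a + (size_t)b * cin * L;
    for (int p = 0; p < P; ++p) {
      const double *win = ab + (size_t)(p * stride) * cin;
      double *col = o + ((size_t)(b * P + p)) * (cin * k);
      std::copy(win, win + (size_t)cin * k, col);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dAcol, int cin, int L, int B, int k,
                         int stride) {
  const int P = (L - k) / stride + 1;
  NumericVector dA((size_t)cin * L * B);
  const double *src = dAcol.begin();
  double *d = dA.begin();
  for (int b = 0; b < B; ++b) {
    double *db = d + (size_t)b * cin * L;
    for (int p = 0; p < P; ++p) {
      double *win = db + (size_t)(p * stride) * cin;
      const double *col = src + ((size_t)(b * P + p)) * (cin * k);
      for (int i = 0; i < cin * k; ++i) win[i] += col[i];
    }
  }
  dA.attr("dim") = IntegerVector::create(cin, L, B);
  return dA;
}

static inline void squash_col(const double *s, double *v, int D) {
  double n2 = 0.0;
  for (int d = 0; d < D; ++d) n2 += s[d] * s[d];
  const double f = std::sqrt(n2) / (1.0 + n2);
  for (int d = 0; d < D; ++d) v[d] = s[d] * f;
}

// Routing by agreement. uhat has dims (D, Q, R, B); returns the squashed
// output capsules v (D, R, B), the final coupling coefficients C
// (Q, R, B) and the final pre-squash vote sums s (D, R, B).
// [[Rcpp::export]]
List routing_cpp(NumericVector uhat, int D, int Q, int R, int B,
                 int iters) {
  NumericVector v((size_t)D * R * B), s((size_t)D * R * B);
  NumericVector C((size_t)Q * R * B);
  std::vector<double> blog((size_t)Q * R * B, 0.0);
  const double *U = uhat.begin();
  double *vp = v.begin(), *sp = s.begin(), *cp = C.begin();

  for (int it = 0; it < iters; ++it) {
    // softmax over R for every (q, b)
    for (int b = 0; b < B; ++b) {
      for (int q = 0; q < Q; ++q) {
        double m = -1e300;
        for (int r = 0; r < R; ++r) {
          double bv = blog[(size_t)q + (size_t)r * Q + (size_t)b * Q * R];
          if (bv > m) m = bv;
        }
        double tot = 0.0;
        for (int r = 0; r < R; ++r) {
          size_t ix = (size_t)q + (size_t)r * Q + (size_t)b * Q * R;
          double e = std::exp(blog[ix] - m);
          cp[ix] = e;
          tot += e;
        }
        for (int r = 0; r < R; ++r) {
          cp[(size_t)q + (size_t)r * Q + (size_t)b * Q * R] /= tot;
        }
      }
    }
    // vote sums s_rb = sum_q C_qrb * uhat_(.,q,r,b), then squash
    for (int b = 0; b < B; ++b) {
      for (int r = 0; r < R; ++r) {
        double *srb = sp + ((size_t)r + (size_t)b * R) * D;
        std::fill(srb, srb + D, 0.0);
        const double *Urb = U + ((size_t)r + (size_t)b * R) * D * Q;
        const double *Crb = cp + ((size_t)r * Q + (size_t)b * Q * R);
        for (int q = 0; q < Q; ++q) {
          const double c = Crb[q];
          const double *uq = Urb + (size_t)q * D;
          for (int d = 0; d < D; ++d) srb[d] += c * uq[d];
        }
        squash_col(srb, vp + ((size_t)r + (size_t)b * R) * D, D);
      }
    }
    // agreement update (skipped on the final pass)
    if (it + 1 < iters) {
      for (int b = 0; b < B; ++b) {
        for (int r = 0; r < R; ++r) {
          const double *Urb = U + ((size_t)r + (size_t)b * R) * D * Q;
          const double *vrb = vp + ((size_t)r + (size_t)b * R) * D;
          double *brb = &blog[(size_t)r * Q + (size_t)b * Q * R];
          for (int q = 0; q < Q; ++q) {
            const double *uq = Urb + (size_t)q * D;
            double acc = 0.0;
            for (int d = 0; d < D; ++d) acc += uq[d] * vrb[d];
            brb[q] += acc;
          }
        }
      }
    }
  }
  v.attr("dim") = IntegerVector::create(D, R, B);
  s.attr("dim") = IntegerVector::create(D, R, B);
  C.attr("dim") = IntegerVector::create(Q, R, B);
  return List::create(Named("v") = v, Named("C") = C, Named("s") = s);
}

// dUhat[d,q,r,b] = C[q,r,b] * ds[d,r,b]
// [[Rcpp::export]]
NumericVector routing_grad_cpp(NumericVector ds, NumericVector C, int D,
                               int Q, int R, int B) {
  NumericVector dU((size_t)D * Q * R * B);
  const double *dsp = ds.begin();
  const double *cp = C.begin();
  double *out = dU.begin();
  for (int b = 0; b < B; ++b) {
    for (int r = 0; r < R; ++r) {
      const double *dsrb = dsp + ((size_t)r + (size_t)b * R) * D;
      const double *Crb = cp + ((size_t)r * Q + (size_t)b * Q * R);
      double *Orb = out + ((size_t)r + (size_t)b * R) * D * Q;
      for (int q = 0; q < Q; ++q) {
        const double c = Crb[q];
        double *oq = Orb + (size_t)q * D;
        for (int d = 0; d < D; ++d) oq[d] = c * dsrb[d];
      }
    }
  }
  dU.attr("dim") = IntegerVector::create(D, Q, R, B);
  return dU;
}

// Fused digit-capsule layer for position-shared transforms. The vote sums
// factor as s_rb = sum_m W_mr * (sum_p C_pmrb * u_pmb), so routing never
// materializes the full (D, Q, R, B) prediction tensor.
//
// u: primary capsules (cdim, P, maps, B); W: (Dh, cdim, maps, R).
// Returns v (Dh, R, B), coupling C (P, maps, R, B) and pre-squash s.
// [[Rcpp::export]]
List caps_digit_fwd_cpp(NumericVector u, NumericVector W, int cdim, int P,
                        int maps, int B, int Dh, int R, int iters) {
  const double *up = u.begin(), *wp = W.begin();
  NumericVector v((size_t)Dh * R * B), s((size_t)Dh * R * B);
  NumericVector C((size_t)P * maps * R * B);
  std::vector<double> blog((size_t)P * maps * R * B, 0.0);
  std::vector<double> g((size_t)cdim * maps * R), wt(cdim);
  double *vp = v.begin(), *sp = s.begin(), *cp = C.begin();
  const size_t uM = (size_t)cdim * P, uB = uM * maps;
  const size_t wM = (size_t)Dh * cdim, wR = wM * maps;
  const size_t cM = (size_t)P, cR = cM * maps, cB = cR * R;

  for (int it = 0; it < iters; ++it) {
    // softmax over r for every (p, m, b)
    for (int b = 0; b < B; ++b) {
      for (int m = 0; m < maps; ++m) {
        for (int p = 0; p < P; ++p) {
          size_t base = (size_t)p + m * cM + b * cB;
          double mx = -1e300;
          for (int r = 0; r < R; ++r) {
            double bv = blog[base + (size_t)r * cR];
            if (bv > mx) mx = bv;
          }
          double tot = 0.0;
          for (int r = 0; r < R; ++r) {
            double e = std::exp(blog[base + (size_t)r * cR] - mx);
            cp[base + (size_t)r * cR] = e;
            tot += e;
          }
          for (int r = 0; r < R; ++r) cp[base + (size_t)r * cR] /= tot;
        }
      }
    }
    for (int b = 0; b < B; ++b) {
      // g[c, m, r] = sum_p C[p,m,r,b] * u[c,p,m,b]
      std::fill(g.begin(), g.end(), 0.0);
      for (int r = 0; r < R; ++r) {
        for (int m = 0; m < maps; ++m) {
          const double *Cmr = cp + (size_t)m * cM + (size_t)r * cR +
            (size_t)b * cB;
          const double *um = up + (size_t)m * uM + (size_t)b * uB;
          double *gmr = &g[(size_t)cdim * (m + (size_t)maps * r)];
          for (int p = 0; p < P; ++p) {
            const double coef = Cmr[p];
            const double *uc = um + (size_t)p * cdim;
            for (int c = 0; c < cdim; ++c) gmr[c] += coef * uc[c];
          }
        }
      }
      // s[d, r, b] = sum_{m,c} W[d,c,m,r] * g[c,m,r]
      for (int r = 0; r < R; ++r) {
        double *srb = sp + ((size_t)r + (size_t)b * R) * Dh;
        std::fill(srb, srb + Dh, 0.0);
        for (int m = 0; m < maps; ++m) {
          const double *Wmr = wp + (size_t)m * wM + (size_t)r * wR;
          const double *gmr = &g[(size_t)cdim * (m + (size_t)maps * r)];
          for (int c = 0; c < cdim; ++c) {
            const double gc = gmr[c];
            const double *wc = Wmr + (size_t)c * Dh;
            for (int d = 0; d < Dh; ++d) srb[d] += wc[d] * gc;
          }
        }
        squash_col(srb, vp + ((size_t)r + (size_t)b * R) * Dh, Dh);
      }
      // agreement update via wt[c] = sum_d W[d,c,m,r] * v[d,r,b]
      if (it + 1 < iters) {
        for (int r = 0; r < R; ++r) {
          const double *vrb = vp + ((size_t)r + (size_t)b * R) * Dh;
          for (int m = 0; m < maps; ++m) {
            const double *Wmr = wp + (size_t)m * wM + (size_t)r * wR;
            for (int c = 0; c < cdim; ++c) {
              double acc = 0.0;
              const double *wc = Wmr + (size_t)c * Dh;
              for (int d = 0; d < Dh; ++d) acc += wc[d] * vrb[d];
              wt[c] = acc;
            }
            const double *um = up + (size_t)m * uM + (size_t)b * uB;
            double *brb = &blog[(size_t)m * cM + (size_t)r * cR +
                                (size_t)b * cB];
            for (int p = 0; p < P; ++p) {
              const double *uc = um + (size_t)p * cdim;
              double acc = 0.0;
              for (int c = 0; c < cdim; ++c) acc += uc[c] * wt[c];
              brb[p] += acc;
            }
          }
        }
      }
    }
  }
  v.attr("dim") = IntegerVector::create(Dh, R, B);
  s.attr("dim") = IntegerVector::create(Dh, R, B);
  C.attr("dim") = IntegerVector::create(P, maps, R, B);
  return List::create(Named("v") = v, Named("C") = C, Named("s") = s);
}

// Backward of the fused layer. ds_task drives the gradient flowing to the
// primary capsules; ds_w (task + any unsupervised term) drives the
// transform-weight gradient.
// [[Rcpp::export]]
List caps_digit_bwd_cpp(NumericVector u, NumericVector W, NumericVector C,
                        NumericVector ds_task, NumericVector ds_w,
                        int cdim, int P, int maps, int B, int Dh, int R) {
  const double *up = u.begin(), *wp = W.begin(), *cp = C.begin();
  const double *dtp = ds_task.begin(), *dwp = ds_w.begin();
  NumericVector dW((size_t)Dh * cdim * maps * R);
  NumericVector du((size_t)cdim * P * maps * B);
  double *dWp = dW.begin(), *dup = du.begin();
  std::vector<double> g((size_t)cdim), h((size_t)cdim);
  const size_t uM = (size_t)cdim * P, uB = uM * maps;
  const size_t wM = (size_t)Dh * cdim, wR = wM * maps;
  const size_t cM = (size_t)P, cR = cM * maps, cB = cR * R;

  for (int b = 0; b < B; ++b) {
    for (int r = 0; r < R; ++r) {
      const double *dt = dtp + ((size_t)r + (size_t)b * R) * Dh;
      const double *dw = dwp + ((size_t)r + (size_t)b * R) * Dh;
      for (int m = 0; m < maps; ++m) {
        const double *Cmr = cp + (size_t)m * cM + (size_t)r * cR +
          (size_t)b * cB;
        const double *um = up + (size_t)m * uM + (size_t)b * uB;
        const double *Wmr = wp + (size_t)m * wM + (size_t)r * wR;
        double *dWmr = dWp + (size_t)m * wM + (size_t)r * wR;
        // g[c] = sum_p C[p] u[c,p]
        std::fill(g.begin(), g.end(), 0.0);
        for (int p = 0; p < P; ++p) {
          const double coef = Cmr[p];
          const double *uc = um + (size_t)p * cdim;
          for (int c = 0; c < cdim; ++c) g[c] += coef * uc[c];
        }
        // dW[d,c,m,r] += ds_w[d] * g[c]
        for (int c = 0; c < cdim; ++c) {
          double *col = dWmr + (size_t)c * Dh;
          const double gc = g[c];
          for (int d = 0; d < Dh; ++d) col[d] += dw[d] * gc;
        }
        // h[c] = sum_d W[d,c,m,r] * ds_task[d]
        for (int c = 0; c < cdim; ++c) {
          const double *wc = Wmr + (size_t)c * Dh;
          double acc = 0.0;
          for (int d = 0; d < Dh; ++d) acc += wc[d] * dt[d];
          h[c] = acc;
        }
        // du[c,p,m,b] += C[p] * h[c]
        double *dum = dup + (size_t)m * uM + (size_t)b * uB;
        for (int p = 0; p < P; ++p) {
          const double coef = Cmr[p];
          double *dc = dum + (size_t)p * cdim;
          for (int c = 0; c < cdim; ++c) dc[c] += coef * h[c];
        }
      }
    }
  }
  dW.attr("dim") = IntegerVector::create(Dh, cdim, maps, R);
  du.attr("dim") = IntegerVector::create(cdim, P, maps, B);
  return List::create(Named("dW") = dW, Named("du") = du);
}
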