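// Minibatch Adam trainer for the Tybalt-style VAE.
//
// The R side owns all randomness: `perms` holds one shuffled cell order per
// epoch and `noise` one standard-normal row per (epoch, cell), both drawn
// from R's RNG, so the compiled and the pure-R training loops consume the
// same stream.  The trainer is templated over the working precision:
// single precision is the default (the convention of the deep-learning
// frameworks this model family is trained with, and twice as fast), double
// precision matches the pure-R reference loop to float accuracy and is used
// by the cross-check tests.  Elementwise stages (Adam, the
// sigmoid/cross-entropy output, the KL gradients) are fused single-pass
// loops; layer products go through BLAS via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

#ifdef __SSE2__
#include <immintrin.h>
#endif

using namespace arma;

// gradients routinely underflow float32 into denormals, which stall the
// FPU by orders of magnitude; flush-to-zero during training restores full
// speed at no practical cost for SGD
struct scoped_ftz {
#ifdef __SSE2__
  unsigned int old_csr;
  scoped_ftz() : old_csr(_mm_getcsr()) { _mm_setcsr(old_csr | 0x8040); }
  ~scoped_ftz() { _mm_setcsr(old_csr); }
#else
  scoped_ftz() {}
#endif
};

// one fused Adam step: P -= lr * mhat / (sqrt(vhat) + eps)
template <typename T>
static void adam_update(Mat<T>& P, Mat<T>& M, Mat<T>& V, const Mat<T>& G,
                        T lr, T c1, T c2) {
  const T b1 = (T)0.9, b2 = (T)0.999, aeps = (T)1e-8;
  T* p = P.memptr();
  T* m = M.memptr();
  T* v = V.memptr();
  const T* g = G.memptr();
  const uword n = P.n_elem;
  for (uword i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + ((T)1 - b1) * g[i];
    v[i] = b2 * v[i] + ((T)1 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + aeps);
  }
}

// sigmoid output + reconstruction loss + its gradient wrt logits, one pass.
// BCE per element from the logit l: softplus(l) - x*l, with the logit
// clamped where the usual 1e-7 output clipping would bite; gradient
// (sigmoid(l) - x)/bsz.
template <typename T>
static double recon_stage(const Mat<T>& logits, const Mat<T>& xb, int bsz,
                          bool bce, Mat<T>& dl) {
  const double clip = 1e-7;
  const double lim = std::log((1.0 - clip) / clip);
  double loss = 0.0;
  const T* l = logits.memptr();
  const T* x = xb.memptr();
  T* d = dl.memptr();
  const uword n = logits.n_elem;
  if (bce) {
    for (uword i = 0; i < n; ++i) {
      double li = (double)l[i];
      double s = 1.0 / (1.0 + std::exp(-li));
      double lc = std::min(std::max(li, -lim), lim);
      double sp = (lc > 0) ? lc + std::log1p(std::exp(-lc))
                           : std::log1p(std::exp(lc));
      loss += sp - (double)x[i] * lc;
      d[i] = (T)((s - (double)x[i]) / bsz);
    }
  } else {
    for (uword i = 0; i < n; ++i) {
      double s = 1.0 / (1.0 + std::exp(-(double)l[i]));
      double e = s - (double)x[i];
      loss += e * e;
      d[i] = (T)(2.0 * e * s * (1.0 - s) / bsz);
    }
  }
  return loss / bsz;
}

// z, KL and the prior part of the mu/logvar gradients, one pass
template <typename T>
static double latent_stage(const Mat<T>& mu, const Mat<T>& lv,
                           const Mat<T>& eps, T w, int bsz,
                           Mat<T>& z, Mat<T>& g_mu, Mat<T>& g_lv) {
  double kl = 0.0;
  const T* pm = mu.memptr();
  const T* pl = lv.memptr();
  const T* pe = eps.memptr();
  T* pz = z.memptr();
  T* gm = g_mu.memptr();
  T* gl = g_lv.memptr();
  const uword n = mu.n_elem;
  for (uword i = 0; i < n; ++i) {
    double sd = std::exp(0.5 * (double)pl[i]);
    pz[i] = pm[i] + (T)sd * pe[i];
    kl += 0.5 * ((double)pm[i] * pm[i] + sd * sd - pl[i] - 1.0);
    gm[i] = (T)(w * pm[i] / (T)bsz);
    gl[i] = (T)(0.5 * w * ((T)(sd * sd) - (T)1) / (T)bsz);
  }
  return kl / bsz;
}

template <typename T>
static inline void relu_inplace(Mat<T>& h, const Mat<T>& a) {
  T* ph = h.memptr();
  const T* pa = a.memptr();
  for (uword i = 0; i < h.n_elem; ++i)
    if (pa[i] <= 0) ph[i] = 0;
}

template <typename T>
static Rcpp::List train_impl(Rcpp::List params_in,
                             const arma::mat& X_in,
                             const arma::imat& perms,
                             const arma::mat& noise_in,
                             int n_hidden, int batch_size, double lr_in,
                             const arma::vec& klw, bool bce) {
  const int n = X_in.n_rows;
  const int epochs = perms.n_rows;
  const int H = n_hidden;
  const T lr = (T)lr_in;

  Mat<T> X = conv_to<Mat<T>>::from(X_in);
  Mat<T> noise = conv_to<Mat<T>>::from(noise_in);

  std::vector<std::string> names;
  for (int i = 1; i <= H; ++i) {
    names.push_back("enc" + std::to_string(i) + ".W");
    names.push_back("enc" + std::to_string(i) + ".b");
  }
  names.insert(names.end(), {"mu.W", "mu.b", "lv.W", "lv.b"});
  for (int i = 1; i <= H; ++i) {
    names.push_back("dec" + std::to_string(i) + ".W");
    names.push_back("dec" + std::to_string(i) + ".b");
  }
  names.insert(names.end(), {"out.W", "out.b"});

  const int np = names.size();
  std::vector<Mat<T>> P(np), G(np), M(np), V(np);
  for (int j = 0; j < np; ++j) {
    if (names[j].back() == 'b') {
      P[j] = conv_to<Mat<T>>::from(mat(Rcpp::as<rowvec>(params_in[names[j]])));
    } else {
      P[j] = conv_to<Mat<T>>::from(Rcpp::as<mat>(params_in[names[j]]));
    }
    G[j] = zeros<Mat<T>>(P[j].n_rows, P[j].n_cols);
    M[j] = zeros<Mat<T>>(P[j].n_rows, P[j].n_cols);
    V[j] = zeros<Mat<T>>(P[j].n_rows, P[j].n_cols);
  }
  const int enc0 = 0, mu0 = 2 * H, dec0 = 2 * H + 4, out0 = 4 * H + 4;

  long step = 0;
  mat history(epochs, 3);
  bool diverged = false;
  int div_epoch = 0, div_batch = 0;
  double div_recon = 0, div_kl = 0;

  std::vector<Mat<T>> h_in(H), act(H), d_in(H), dact(H);

  for (int e = 0; e < epochs && !diverged; ++e) {
    const T w = (T)klw(e);
    double ep_tot = 0, ep_rec = 0, ep_kl = 0;
    int n_batches = 0;
    for (int s = 0; s < n; s += batch_size) {
      const int bsz = std::min(batch_size, n - s);
      uvec idx(bsz), nidx(bsz);
      for (int t = 0; t < bsz; ++t) {
        idx(t) = perms(e, s + t) - 1;
        nidx(t) = (uword)e * n + s + t;
      }
      Mat<T> xb = X.rows(idx);
      Mat<T> eps = noise.rows(nidx);

      // encoder
      Mat<T> h = xb;
      for (int i = 0; i < H; ++i) {
        h_in[i] = h;
        act[i] = h * P[enc0 + 2 * i];
        act[i].each_row() += P[enc0 + 2 * i + 1].row(0);
        h = act[i];
        relu_inplace(h, act[i]);
      }
      Mat<T> mu = h * P[mu0]; mu.each_row() += P[mu0 + 1].row(0);
      Mat<T> lv = h * P[mu0 + 2]; lv.each_row() += P[mu0 + 3].row(0);
      if (!mu.is_finite() || !lv.is_finite()) {
        diverged = true; div_epoch = e + 1; div_batch = s / batch_size + 1;
        div_recon = NA_REAL; div_kl = NA_REAL;
        break;
      }

      Mat<T> z(bsz, mu.n_cols), g_mu(bsz, mu.n_cols), g_lv(bsz, mu.n_cols);
      double kl = latent_stage(mu, lv, eps, w, bsz, z, g_mu, g_lv);

      // decoder on the posterior sample
      Mat<T> d = z;
      for (int i = 0; i < H; ++i) {
        d_in[i] = d;
        dact[i] = d * P[dec0 + 2 * i];
        dact[i].each_row() += P[dec0 + 2 * i + 1].row(0);
        d = dact[i];
        relu_inplace(d, dact[i]);
      }
      Mat<T> logits = d * P[out0]; logits.each_row() += P[out0 + 1].row(0);

      Mat<T> dl(bsz, logits.n_cols);
      double rec = recon_stage(logits, xb, bsz, bce, dl);
      double tot = rec + (double)w * kl;
      if (!std::isfinite(tot)) {
        diverged = true; div_epoch = e + 1; div_batch = s / batch_size + 1;
        div_recon = rec; div_kl = kl;
        break;
      }
      ep_tot += tot; ep_rec += rec; ep_kl += kl; ++n_batches;

      // backward
      G[out0] = d.t() * dl;
      G[out0 + 1] = sum(dl, 0);
      Mat<T> gd = dl * P[out0].t();
      for (int i = H - 1; i >= 0; --i) {
        relu_inplace(gd, dact[i]);
        G[dec0 + 2 * i] = d_in[i].t() * gd;
        G[dec0 + 2 * i + 1] = sum(gd, 0);
        gd = gd * P[dec0 + 2 * i].t();
      }
      // add the decoder's pull on z to the prior's pull
      {
        const T* pg = gd.memptr();
        const T* pe = eps.memptr();
        const T* pl = lv.memptr();
        T* gm = g_mu.memptr();
        T* gl = g_lv.memptr();
        for (uword i = 0; i < gd.n_elem; ++i) {
          T sd = (T)std::exp(0.5 * (double)pl[i]);
          gm[i] += pg[i];
          gl[i] += (T)0.5 * pg[i] * pe[i] * sd;
        }
      }
      G[mu0] = h.t() * g_mu;
      G[mu0 + 1] = sum(g_mu, 0);
      G[mu0 + 2] = h.t() * g_lv;
      G[mu0 + 3] = sum(g_lv, 0);
      Mat<T> gh = g_mu * P[mu0].t() + g_lv * P[mu0 + 2].t();
      for (int i = H - 1; i >= 0; --i) {
        relu_inplace(gh, act[i]);
        G[enc0 + 2 * i] = h_in[i].t() * gh;
        G[enc0 + 2 * i + 1] = sum(gh, 0);
        gh = gh * P[enc0 + 2 * i].t();
      }

      ++step;
      const T c1 = (T)1 - (T)std::pow(0.9, (double)step);
      const T c2 = (T)1 - (T)std::pow(0.999, (double)step);
      for (int j = 0; j < np; ++j)
        adam_update(P[j], M[j], V[j], G[j], lr, c1, c2);
    }
    if (!diverged) {
      history(e, 0) = ep_tot / n_batches;
      history(e, 1) = ep_rec / n_batches;
      history(e, 2) = ep_kl / n_batches;
    }
  }

  Rcpp::List out_params(np);
  Rcpp::CharacterVector out_names(np);
  for (int j = 0; j < np; ++j) {
    out_names[j] = names[j];
    mat pj = conv_to<mat>::from(P[j]);
    if (names[j].back() == 'b') {
      out_params[j] = Rcpp::NumericVector(pj.begin(), pj.end());
    } else {
      out_params[j] = Rcpp::wrap(pj);
    }
  }
  out_params.attr("names") = out_names;
  return Rcpp::List::create(
    Rcpp::Named("params") = out_params,
    Rcpp::Named("history") = history,
    Rcpp::Named("diverged") = diverged,
    Rcpp::Named("epoch") = div_epoch,
    Rcpp::Named("batch") = div_batch,
    Rcpp::Named("recon") = div_recon,
    Rcpp::Named("kl") = div_kl
  );
}

// [[Rcpp::export]]
Rcpp::List train_vae_cpp(Rcpp::List params_in,
                         const arma::mat& X,
                         const arma::imat& perms,
                         const arma::mat& noise,
                         int n_hidden,
                         int batch_size,
                         double lr,
                         const arma::vec& klw,
                         bool bce,
                         bool single_precision) {
  if (single_precision) {
    scoped_ftz guard;
    return train_impl<float>(params_in, X, perms, noise, n_hidden,
                             batch_size, lr, klw, bce);
  }
  return train_impl<double>(params_in, X, perms, noise, n_hidden,
                            batch_size, lr, klw, bce);
}
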