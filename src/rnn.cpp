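// Leaky firing-rate RNN: forward Euler simulation and backpropagation
// through time. Dynamics per step (alpha = dt/tau):
//   r <- (1 - alpha) * r + alpha * softplus(W_rec r + W_in u + b + s * eps)
// with s = sigma_rec * sqrt(2/alpha) so that the integrated noise variance
// over a fixed wall-clock interval is invariant to the choice of dt.
// Outputs: z = logistic(W_out r), read out at every step.
//
// Noise draws come from an internal mt19937_64 + Box-Muller generator so a
// forward pass is a pure function of (weights, inputs, seed).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Marsaglia-Tsang ziggurat tables for the standard normal (128 layers)
struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    const double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};
static const ZigTables zig;

// xoshiro256++ seeded through splitmix64; normal draws via the ziggurat.
// Self-contained so a forward pass is a pure, platform-stable function of
// (weights, inputs, seed).
struct Gauss {
  uint64_t s[4];
  uint64_t buf = 0;
  bool half = false;
  explicit Gauss(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {   // splitmix64
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next64() {
    const uint64_t out = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return out;
  }
  uint32_t next32() {
    if (half) { half = false; return static_cast<uint32_t>(buf >> 32); }
    buf = next64(); half = true;
    return static_cast<uint32_t>(buf);
  }
  double unif() {   // (0, 1)
    return (static_cast<double>(next32()) + 0.5) * (1.0 / 4294967296.0);
  }
  double operator()() {
    const int32_t hz = static_cast<int32_t>(next32());
    const uint32_t iz = hz & 127;
    const uint32_t a = hz < 0 ? static_cast<uint32_t>(-(int64_t)hz)
                              : static_cast<uint32_t>(hz);
    if (a < zig.kn[iz]) return hz * zig.wn[iz];
    return nfix(hz, iz);
  }
  double nfix(int32_t hz, uint32_t iz) {
    const double r = 3.442619855899;
    for (;;) {
      double x = hz * zig.wn[iz];
      if (iz == 0) {                 // tail
        double y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      if (zig.fn[iz] + unif() * (zig.fn[iz - 1] - zig.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      hz = static_cast<int32_t>(next32());
      iz = hz & 127;
      const uint32_t a = hz < 0 ? static_cast<uint32_t>(-(int64_t)hz)
                                : static_cast<uint32_t>(hz);
      if (a < zig.kn[iz]) return hz * zig.wn[iz];
    }
  }
  void fill(arma::mat& m) {
    for (arma::uword i = 0; i < m.n_elem; ++i) m[i] = (*this)();
  }
};

inline double softplus1(double x) {
  return x > 0.0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}
inline double logistic1(double x) {
  return x > 0.0 ? 1.0 / (1.0 + std::exp(-x))
                 : std::exp(x) / (1.0 + std::exp(x));
}

inline void softplus_mat(const arma::mat& a, arma::mat& out) {
  out.set_size(a.n_rows, a.n_cols);
  for (arma::uword i = 0; i < a.n_elem; ++i) out[i] = softplus1(a[i]);
}
inline void logistic_mat(const arma::mat& a, arma::mat& out) {
  out.set_size(a.n_rows, a.n_cols);
  for (arma::uword i = 0; i < a.n_elem; ++i) out[i] = logistic1(a[i]);
}
// softplus and its derivative (the logistic) from one exp() evaluation:
// with e = exp(-|x|), softplus = max(x, 0) + log1p(e) and
// logistic = 1/(1+e) for x > 0, e/(1+e) otherwise
inline void softplus_both_mat(const arma::mat& a, arma::mat& sp,
                              arma::mat& fp) {
  sp.set_size(a.n_rows, a.n_cols);
  fp.set_size(a.n_rows, a.n_cols);
  for (arma::uword i = 0; i < a.n_elem; ++i) {
    const double x = a[i];
    const double e = std::exp(-std::fabs(x));
    if (x > 0.0) {
      sp[i] = x + std::log1p(e);
      fp[i] = 1.0 / (1.0 + e);
    } else {
      sp[i] = std::log1p(e);
      fp[i] = e / (1.0 + e);
    }
  }
}

} // namespace

// Forward pass over a trial batch.
// U: cube (n_in x B x T). Returns rates (n_rec x B x T) and outputs
// (n_out x B x T). Halts with an error naming the first bad step if the
// state becomes non-finite.
// [[Rcpp::export]]
List rnn_forward_cpp(const arma::mat& W_in, const arma::mat& W_rec,
                     const arma::mat& W_out, const arma::vec& b,
                     const arma::cube& U, double alpha, double sigma_rec,
                     const arma::vec& r0, double seed) {
  const arma::uword n_rec = W_rec.n_rows, T = U.n_slices, B = U.n_cols;
  const arma::uword n_out = W_out.n_rows;
  const double s_noise = sigma_rec * std::sqrt(2.0 / alpha);
  Gauss g(static_cast<uint64_t>(seed));

  arma::cube rates(n_rec, B, T), outputs(n_out, B, T);
  arma::mat r = arma::repmat(r0, 1, B);
  arma::mat a, fr, eps(n_rec, B);

  // input projection for all timesteps in one GEMM
  const arma::mat Uin(const_cast<double*>(U.memptr()), U.n_rows, B * T,
                      false, true);
  arma::mat WU = W_in * Uin;              // n_rec x (B*T)

  for (arma::uword t = 0; t < T; ++t) {
    a = W_rec * r + WU.cols(t * B, t * B + B - 1);
    a.each_col() += b;
    if (sigma_rec > 0.0) { g.fill(eps); a += s_noise * eps; }
    softplus_mat(a, fr);
    r = (1.0 - alpha) * r + alpha * fr;
    if (!r.is_finite())
      stop("non-finite network state at timestep %d", (int)(t + 1));
    rates.slice(t) = r;
    logistic_mat(W_out * r, outputs.slice(t));
  }
  return List::create(_["rates"] = rates, _["outputs"] = outputs);
}

// Forward + backward pass: masked mean-squared-error loss
//   L = sum(mask * (z - target)^2) / sum(mask)
// and its gradients with respect to W_in, W_rec, W_out, b, obtained by
// reverse-mode differentiation through the unrolled dynamics.
// [[Rcpp::export]]
List rnn_grad_cpp(const arma::mat& W_in, const arma::mat& W_rec,
                  const arma::mat& W_out, const arma::vec& b,
                  const arma::cube& U, const arma::cube& target,
                  const arma::cube& mask, double alpha, double sigma_rec,
                  const arma::vec& r0, double seed) {
  const arma::uword n_rec = W_rec.n_rows, T = U.n_slices, B = U.n_cols;
  const double s_noise = sigma_rec * std::sqrt(2.0 / alpha);
  const double msum = arma::accu(mask);
  if (msum <= 0.0) stop("loss mask sums to zero");
  Gauss g(static_cast<uint64_t>(seed));

  // forward, caching rates and f'(a) = logistic(a) for the backward sweep
  arma::cube rates(n_rec, B, T), fprime(n_rec, B, T);
  arma::mat r = arma::repmat(r0, 1, B);
  arma::mat a, fr, eps(n_rec, B), z;
  double loss = 0.0;
  arma::cube dz_cache(W_out.n_rows, B, T);

  const arma::mat Uin(const_cast<double*>(U.memptr()), U.n_rows, B * T,
                      false, true);
  arma::mat WU = W_in * Uin;              // n_rec x (B*T), one GEMM

  for (arma::uword t = 0; t < T; ++t) {
    a = W_rec * r + WU.cols(t * B, t * B + B - 1);
    a.each_col() += b;
    if (sigma_rec > 0.0) { g.fill(eps); a += s_noise * eps; }
    softplus_both_mat(a, fr, fprime.slice(t));
    r = (1.0 - alpha) * r + alpha * fr;
    if (!r.is_finite())
      stop("non-finite network state at timestep %d", (int)(t + 1));
    rates.slice(t) = r;
    logistic_mat(W_out * r, z);
    const arma::mat diff = z - target.slice(t);
    loss += arma::accu(mask.slice(t) % diff % diff);
    // dL/d(pre-logistic) for the readout at this step
    dz_cache.slice(t) = (2.0 / msum) * mask.slice(t) % diff % z % (1.0 - z);
  }
  loss /= msum;

  // backward through time
  arma::mat gW_in(arma::size(W_in), arma::fill::zeros);
  arma::mat gW_rec(arma::size(W_rec), arma::fill::zeros);
  arma::mat gW_out(arma::size(W_out), arma::fill::zeros);
  arma::vec gb(n_rec, arma::fill::zeros);
  arma::mat dr(n_rec, B, arma::fill::zeros), da;

  for (arma::uword t = T; t-- > 0;) {
    gW_out += dz_cache.slice(t) * rates.slice(t).t();
    dr += W_out.t() * dz_cache.slice(t);
    da = alpha * (fprime.slice(t) % dr);
    if (t == 0) {
      gW_rec += da * arma::repmat(r0, 1, B).t();
    } else {
      gW_rec += da * rates.slice(t - 1).t();
    }
    gW_in += da * U.slice(t).t();
    gb += arma::sum(da, 1);
    dr = (1.0 - alpha) * dr + W_rec.t() * da;
  }

  return List::create(_["loss"] = loss, _["gW_in"] = gW_in,
                      _["gW_rec"] = gW_rec, _["gW_out"] = gW_out,
                      _["gb"] = gb);
}
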