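// Monte Carlo photon transport over voxel phantoms.
//
// Analog transport with Woodcock (delta) tracking against a global
// majorant cross-section, free-electron Klein-Nishina Compton sampling
// (Kahn's composition-rejection method), Thomson-distributed Rayleigh
// scattering, and local deposition of transferred energy (collision
// kerma): photoelectric events deposit the full photon energy, Compton
// events deposit E - E', photons below the 5 keV cutoff deposit their
// remaining energy and terminate. Lengths are mm externally, cm
// internally for attenuation; energies keV.

#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

static const double MEC2 = 510.99895;  // keV

struct Rng {
  std::mt19937_64 gen;
  std::uniform_real_distribution<double> uni;
  explicit Rng(uint64_t seed) : gen(seed), uni(0.0, 1.0) {}
  double operator()() { return uni(gen); }
};

// ---- samplers ------------------------------------------------------------

// Kahn's method for Klein-Nishina: returns x = E/E'; cos(theta) follows
// from the Compton relation.
static double kahn_sample_x(double k, Rng& rng) {
  for (;;) {
    double r1 = rng(), r2 = rng(), r3 = rng();
    if (r1 <= (1.0 + 2.0 * k) / (9.0 + 2.0 * k)) {
      double x = 1.0 + 2.0 * k * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) return x;
    } else {
      double x = (1.0 + 2.0 * k) / (1.0 + 2.0 * k * r2);
      double ct = 1.0 - (x - 1.0) / k;
      if (r3 <= 0.5 * (ct * ct + 1.0 / x)) return x;
    }
  }
}

// Thomson angular distribution ~ (1 + cos^2) via rejection on cos(theta).
static double thomson_sample_ct(Rng& rng) {
  for (;;) {
    double mu = 2.0 * rng() - 1.0;
    if (rng() <= 0.5 * (1.0 + mu * mu)) return mu;
  }
}

static void rotate_direction(double* u, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cf = std::cos(phi), sf = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) < 0.99999) {
    double a = std::sqrt(1.0 - uz * uz);
    u[0] = ux * ct + st * (ux * uz * cf - uy * sf) / a;
    u[1] = uy * ct + st * (uy * uz * cf + ux * sf) / a;
    u[2] = uz * ct - a * st * cf;
  } else {
    u[0] = st * cf;
    u[1] = st * sf;
    u[2] = (uz > 0 ? ct : -ct);
  }
  double n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= n; u[1] /= n; u[2] /= n;
}

// ---- source --------------------------------------------------------------

struct Source {
  double pos[3];
  double u0x, u0y;           // in-plane central direction
  double fan_half, cone_half;
  double e_lo, e_step;
  NumericVector cdf;         // spectrum CDF over bins
  NumericVector mu_al;       // Al linear attenuation on the bin grid, 1/cm
  NumericVector bw_theta;    // bowtie grid, degrees (signed)
  NumericVector bw_tcm;      // bowtie thickness, cm
  int n_bins;
};

static Source unpack_source(const List& src) {
  Source s;
  NumericVector p = src["pos"];
  s.pos[0] = p[0]; s.pos[1] = p[1]; s.pos[2] = p[2];
  double sid = as<double>(src["sid_mm"]);
  s.u0x = -s.pos[0] / sid;
  s.u0y = -s.pos[1] / sid;
  s.fan_half = as<double>(src["fan_half_rad"]);
  s.cone_half = as<double>(src["cone_half_rad"]);
  s.e_lo = as<double>(src["e_lo"]);
  s.e_step = as<double>(src["e_step"]);
  s.cdf = src["cdf"];
  s.mu_al = src["mu_al_grid"];
  s.bw_theta = src["bowtie_theta"];
  s.bw_tcm = src["bowtie_tcm"];
  s.n_bins = s.cdf.size();
  return s;
}

static double interp_clamped(const NumericVector& x, const NumericVector& y,
                             double xo) {
  int n = x.size();
  if (xo <= x[0]) return y[0];
  if (xo >= x[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= xo) lo = mid; else hi = mid;
  }
  double f = (xo - x[lo]) / (x[hi] - x[lo]);
  return y[lo] + f * (y[hi] - y[lo]);
}

// Sample one photon; fills pos(3), dir(3), energy, weight.
static void emit_photon(const Source& s, Rng& rng, double* pos, double* dir,
                        double& energy, double& weight) {
  pos[0] = s.pos[0]; pos[1] = s.pos[1]; pos[2] = s.pos[2];
  double phi = (2.0 * rng() - 1.0) * s.fan_half;       // fan angle
  double psi = (2.0 * rng() - 1.0) * s.cone_half;      // cone angle
  double cph = std::cos(phi), sph = std::sin(phi);
  double ux = s.u0x * cph - s.u0y * sph;
  double uy = s.u0x * sph + s.u0y * cph;
  double cps = std::cos(psi);
  dir[0] = ux * cps; dir[1] = uy * cps; dir[2] = std::sin(psi);
  // inverse-CDF energy sampling, uniform within the 0.5 keV bin
  double u = rng();
  int lo = 0, hi = s.n_bins - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (s.cdf[mid] < u) lo = mid + 1; else hi = mid;
  }
  energy = s.e_lo + (lo + rng()) * s.e_step;
  int eidx = lo;
  double t_cm = interp_clamped(s.bw_theta, s.bw_tcm, phi * 180.0 / M_PI);
  weight = std::exp(-s.mu_al[eidx] * t_cm);
}

// [[Rcpp::export]]
NumericMatrix cpp_initial_photons(int n, List src, int seed) {
  Source s = unpack_source(src);
  Rng rng(static_cast<uint64_t>(seed));
  NumericMatrix out(n, 8);
  double pos[3], dir[3], e, w;
  for (int i = 0; i < n; ++i) {
    emit_photon(s, rng, pos, dir, e, w);
    out(i, 0) = pos[0]; out(i, 1) = pos[1]; out(i, 2) = pos[2];
    out(i, 3) = dir[0]; out(i, 4) = dir[1]; out(i, 5) = dir[2];
    out(i, 6) = e; out(i, 7) = w;
  }
  return out;
}

// ---- transport -----------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_projection(IntegerVector mat_id, NumericVector density,
                        IntegerVector dims, NumericVector spacing,
                        NumericVector origin, IntegerVector label,
                        int n_labels, NumericMatrix mu_tot,
                        NumericMatrix f_pe, NumericMatrix f_coh,
                        NumericMatrix muen, double e_lo, double e_step,
                        List src, double cutoff_kev, int n_photons,
                        int n_batches, int seed,
                        double majorant_floor) {
  Source s = unpack_source(src);
  Rng rng(static_cast<uint64_t>(seed));
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n_e = mu_tot.nrow();
  const size_t nvox = static_cast<size_t>(nx) * ny * nz;
  // grid box in mm: voxel (0,0,0) center at origin
  double blo[3], bhi[3];
  for (int a = 0; a < 3; ++a) {
    blo[a] = origin[a] - 0.5 * spacing[a];
    bhi[a] = blo[a] + spacing[a] * dims[a];
  }
  // per-material max density -> global majorant per energy index
  int n_mat = mu_tot.ncol();
  std::vector<double> max_dens(n_mat, 0.0);
  for (size_t v = 0; v < nvox; ++v) {
    int m = mat_id[v] - 1;
    if (density[v] > max_dens[m]) max_dens[m] = density[v];
  }
  std::vector<double> sig_max(n_e, 0.0);
  for (int e = 0; e < n_e; ++e) {
    for (int m = 0; m < n_mat; ++m) {
      double v = mu_tot(e, m) * max_dens[m];
      if (v > sig_max[e]) sig_max[e] = v;
    }
    if (sig_max[e] < majorant_floor) sig_max[e] = majorant_floor;
  }
  NumericVector edep(nvox);
  NumericMatrix batch_region(n_labels + 1, n_batches);
  NumericMatrix batch_kerma(n_labels + 1, n_batches);
  double emitted = 0.0;
  long uncollided = 0, missed = 0;
  double pos[3], dir[3], energy, weight;
  for (int b = 0; b < n_batches; ++b) {
    int nb = n_photons / n_batches + (b < n_photons % n_batches ? 1 : 0);
    for (int i = 0; i < nb; ++i) {
      emit_photon(s, rng, pos, dir, energy, weight);
      // ray-box entry
      double t0 = 0.0, t1 = 1e30;
      bool hit = true;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(dir[a]) < 1e-12) {
          if (pos[a] < blo[a] || pos[a] > bhi[a]) { hit = false; break; }
        } else {
          double ta = (blo[a] - pos[a]) / dir[a];
          double tb = (bhi[a] - pos[a]) / dir[a];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
          if (t0 > t1) { hit = false; break; }
        }
      }
      if (!hit) { ++missed; continue; }
      for (int a = 0; a < 3; ++a) pos[a] += dir[a] * (t0 + 1e-9);
      emitted += weight * energy;
      int ncoll = 0;
      bool alive = true;
      while (alive) {
        int eidx = static_cast<int>((energy - e_lo) / e_step);
        if (eidx < 0) eidx = 0;
        if (eidx >= n_e) eidx = n_e - 1;
        double sm = sig_max[eidx];
        if (sm <= 0.0) break;
        double step_mm = -std::log(rng()) / sm * 10.0;
        for (int a = 0; a < 3; ++a) pos[a] += dir[a] * step_mm;
        if (pos[0] < blo[0] || pos[0] >= bhi[0] || pos[1] < blo[1] ||
            pos[1] >= bhi[1] || pos[2] < blo[2] || pos[2] >= bhi[2]) {
          if (ncoll == 0) ++uncollided;
          break;
        }
        int ix = static_cast<int>((pos[0] - blo[0]) / spacing[0]);
        int iy = static_cast<int>((pos[1] - blo[1]) / spacing[1]);
        int iz = static_cast<int>((pos[2] - blo[2]) / spacing[2]);
        if (ix >= nx) ix = nx - 1;
        if (iy >= ny) iy = ny - 1;
        if (iz >= nz) iz = nz - 1;
        size_t v = static_cast<size_t>(ix) +
          static_cast<size_t>(nx) * (iy + static_cast<size_t>(ny) * iz);
        int m = mat_id[v] - 1;
        // track-length (collision) kerma estimator: every Woodcock
        // collision point estimates ds = 1/sig_max of track length
        {
          double ks = weight * energy * muen(eidx, m) * density[v] / sm;
          batch_kerma(0, b) += ks;
          int l = label[v];
          if (l > 0) batch_kerma(l, b) += ks;
        }
        double sig = mu_tot(eidx, m) * density[v];
        if (rng() * sm > sig) continue;  // fictitious interaction
        ++ncoll;
        double upe = f_pe(eidx, m), ucoh = f_coh(eidx, m);
        double r = rng();
        double dep = 0.0;
        if (r < upe) {  // photoelectric: full local absorption
          dep = weight * energy;
          alive = false;
        } else if (r < upe + ucoh) {  // Rayleigh: deflect, no deposit
          double ct = thomson_sample_ct(rng);
          rotate_direction(dir, ct, 2.0 * M_PI * rng());
        } else {  // Compton
          double k = energy / MEC2;
          double x = kahn_sample_x(k, rng);
          double eprime = energy / x;
          double ct = 1.0 - (x - 1.0) / k;
          dep = weight * (energy - eprime);
          if (eprime < cutoff_kev) {
            dep += weight * eprime;
            alive = false;
          } else {
            energy = eprime;
            rotate_direction(dir, ct, 2.0 * M_PI * rng());
          }
        }
        if (dep > 0.0) {
          edep[v] += dep;
          batch_region(0, b) += dep;
          int l = label[v];
          if (l > 0) batch_region(l, b) += dep;
        }
      }
    }
  }
  return List::create(_["edep_kev"] = edep,
                      _["batch_region_kev"] = batch_region,
                      _["batch_kerma_kev"] = batch_kerma,
                      _["n_photons"] = n_photons,
                      _["emitted_kev"] = emitted,
                      _["uncollided"] = uncollided,
                      _["missed"] = missed, _["seed"] = seed);
}

// ---- exposed samplers for verification ----------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double energy_kev, int n, int seed) {
  Rng rng(static_cast<uint64_t>(seed));
  NumericMatrix out(n, 2);
  double k = energy_kev / MEC2;
  for (int i = 0; i < n; ++i) {
    double x = kahn_sample_x(k, rng);
    out(i, 0) = energy_kev / x;
    out(i, 1) = 1.0 - (x - 1.0) / k;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_rayleigh(int n, int seed) {
  Rng rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = thomson_sample_ct(rng);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_sample_branch(NumericVector probs, int n, int seed) {
  Rng rng(static_cast<uint64_t>(seed));
  double p1 = probs[0], p2 = probs[0] + probs[1];
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double u = rng();
    out[i] = u < p1 ? 1 : (u < p2 ? 2 : 3);
  }
  return out;
}

// Free-path sampling in an infinite homogeneous medium by delta
// tracking against a majorant; used to verify Woodcock equivalence with
// direct exponential sampling.
// [[Rcpp::export]]
NumericVector cpp_free_path_woodcock(double mu, double mu_major, int n,
                                     int seed) {
  Rng rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double d = 0.0;
    for (;;) {
      d += -std::log(rng()) / mu_major;
      if (rng() * mu_major <= mu) break;
    }
    out[i] = d;
  }
  return out;
}
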