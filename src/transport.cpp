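// Photon-packet Monte Carlo transport in a plane-parallel layered medium.
//
// Conventions (all internal lengths in cm):
//   * z = 0 at the upper surface, increasing downward; layer i occupies
//     [zb[i], zb[i+1]).
//   * Pencil beam enters at the origin along +z; the specular fraction is
//     split off analytically at entry.
//   * Implicit capture: at every interaction the packet deposits
//     w * mua/mut and continues with the scattered remainder.
//   * Russian roulette below w_threshold; the survival boost is debited from
//     the absorbed pool (and killed weight credited to it) so the energy
//     budget specular + diffuse + transmitted + absorbed closes exactly.
//   * Escaping weight is scored by exit annulus over all exit angles;
//     weight landing beyond max_r goes to an overflow bucket.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double rnd_open() {
  // unif_rand() may return exact 0; reject so that -log() is finite
  double u;
  do {
    u = unif_rand();
  } while (u <= 0.0 || u >= 1.0);
  return u;
}

// Probability (over the uniform exit azimuth) that a photon exiting at
// radius r lands inside a detector circle of radius rho centred at
// distance d from the source axis.
static inline double detect_prob(double r, double d, double rho) {
  if (r + d <= rho) return 1.0;
  if (r >= d + rho || d >= r + rho) return 0.0;
  if (r <= 0.0 || d <= 0.0) return 0.0;  // covered by the cases above
  double c = (r * r + d * d - rho * rho) / (2.0 * r * d);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return std::acos(c) / M_PI;
}

// [[Rcpp::export]]
List cpp_transport(NumericVector thickness, NumericVector mua,
                   NumericVector mus, NumericVector g, NumericVector n_layer,
                   double n_above, double n_below, int n_photons,
                   double bin_w, double max_r, double w_threshold,
                   double p_survive, bool record_paths, bool vis_enabled,
                   double det_dist, double det_radius, double vis_dr,
                   double vis_dz) {
  const int k = thickness.size();
  if (k < 1) stop("at least one layer required");

  std::vector<double> zb(k + 1, 0.0);
  for (int i = 0; i < k; ++i) zb[i + 1] = zb[i] + thickness[i];
  const double depth = zb[k];

  const int nbins = (int)std::floor(max_r / bin_w + 0.5);
  std::vector<double> bins(nbins, 0.0);

  int vis_nr = 0, vis_nz = 0;
  std::vector<double> vismap;
  if (vis_enabled) {
    vis_nr = (int)std::ceil(max_r / vis_dr);
    vis_nz = (int)std::ceil(depth / vis_dz);
    vismap.assign((size_t)vis_nr * vis_nz, 0.0);
  }
  // per-photon trajectory buffer: (cell index, pathlength) pairs
  std::vector<int> buf_cell;
  std::vector<double> buf_len;

  // pathlength records
  std::vector<double> rec_r, rec_w, rec_L;
  std::vector<int> rec_h;
  if (record_paths) {
    rec_r.reserve(n_photons);
    rec_w.reserve(n_photons);
    rec_h.reserve(n_photons);
    rec_L.reserve((size_t)n_photons * k);
  }
  std::vector<double> Lbuf(k, 0.0);

  // specular reflection at normal incidence
  double rsp = 0.0;
  if (n_above != n_layer[0]) {
    double t = (n_above - n_layer[0]) / (n_above + n_layer[0]);
    rsp = t * t;
  }

  long double acc_spec = 0.0L, acc_diff = 0.0L, acc_trans = 0.0L,
              acc_abs = 0.0L, acc_over = 0.0L, acc_det = 0.0L;
  long n_capped = 0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int lay = 0;
    double w = 1.0 - rsp;
    acc_spec += rsp;
    if (record_paths) std::fill(Lbuf.begin(), Lbuf.end(), 0.0);
    if (vis_enabled) {
      buf_cell.clear();
      buf_len.clear();
    }

    bool alive = true;
    int exit_top = -1;  // 0 top, 1 bottom when terminated by escape
    long nstep = 0;

    while (alive) {
      if (++nstep > 20000000L) {  // safety net; never reached in practice
        acc_abs += w;
        ++n_capped;
        break;
      }
      double s = -std::log(rnd_open());  // dimensionless optical step

      // propagate, possibly across several boundaries
      for (;;) {
        const double mut = mua[lay] + mus[lay];
        const double step = s / mut;
        double db;
        if (uz > 0.0)
          db = (zb[lay + 1] - z) / uz;
        else if (uz < 0.0)
          db = (zb[lay] - z) / uz;  // uz < 0, zb <= z -> db >= 0
        else
          db = R_PosInf;

        if (step < db) {
          x += ux * step;
          y += uy * step;
          z += uz * step;
          if (record_paths) Lbuf[lay] += step;
          if (vis_enabled) {
            int ir = (int)(std::sqrt(x * x + y * y) / vis_dr);
            if (ir >= vis_nr) ir = vis_nr - 1;
            int iz = (int)(z / vis_dz);
            if (iz >= vis_nz) iz = vis_nz - 1;
            if (iz < 0) iz = 0;
            buf_cell.push_back(ir * vis_nz + iz);
            buf_len.push_back(step);
          }
          break;  // interaction
        }

        // hit a boundary
        x += ux * db;
        y += uy * db;
        const bool up = (uz < 0.0);
        z = up ? zb[lay] : zb[lay + 1];
        if (record_paths) Lbuf[lay] += db;
        if (vis_enabled) {
          int ir = (int)(std::sqrt(x * x + y * y) / vis_dr);
          if (ir >= vis_nr) ir = vis_nr - 1;
          int iz = (int)(z / vis_dz);
          if (iz >= vis_nz) iz = vis_nz - 1;
          if (iz < 0) iz = 0;
          buf_cell.push_back(ir * vis_nz + iz);
          buf_len.push_back(db);
        }
        s -= db * mut;

        const double ni = n_layer[lay];
        const double nt = up ? (lay == 0 ? n_above : n_layer[lay - 1])
                             : (lay == k - 1 ? n_below : n_layer[lay + 1]);
        bool crosses;
        if (ni == nt) {
          crosses = true;
        } else {
          const double ci = std::fabs(uz);
          const double eta = ni / nt;
          const double sin2t = eta * eta * (1.0 - ci * ci);
          double Rf, ct = 0.0;
          if (sin2t >= 1.0) {
            Rf = 1.0;
          } else {
            ct = std::sqrt(1.0 - sin2t);
            const double rs =
                (ni * ci - nt * ct) / (ni * ci + nt * ct);
            const double rp =
                (ni * ct - nt * ci) / (ni * ct + nt * ci);
            Rf = 0.5 * (rs * rs + rp * rp);
          }
          if (Rf >= 1.0 || unif_rand() < Rf) {
            uz = -uz;  // internally reflected, stay in layer
            crosses = false;
          } else {
            ux *= eta;
            uy *= eta;
            uz = up ? -ct : ct;
            crosses = true;
          }
        }

        if (crosses) {
          if (up) {
            if (lay == 0) {
              exit_top = 0;
              alive = false;
              break;
            }
            --lay;
          } else {
            if (lay == k - 1) {
              exit_top = 1;
              alive = false;
              break;
            }
            ++lay;
          }
        }
        if (s <= 0.0) {
          // consumed the whole optical step exactly at a boundary
          break;
        }
      }

      if (!alive) break;

      // interaction: implicit capture + Henyey-Greenstein scatter
      const double mut = mua[lay] + mus[lay];
      if (mua[lay] > 0.0) {
        const double da = w * mua[lay] / mut;
        acc_abs += da;
        w -= da;
      }

      double cost;
      const double gg = g[lay];
      if (std::fabs(gg) < 1e-6) {
        cost = 2.0 * unif_rand() - 1.0;
      } else {
        const double tmp =
            (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * unif_rand());
        cost = (1.0 + gg * gg - tmp * tmp) / (2.0 * gg);
        if (cost > 1.0) cost = 1.0;
        if (cost < -1.0) cost = -1.0;
      }
      const double sint = std::sqrt(1.0 - cost * cost);
      const double phi = 2.0 * M_PI * unif_rand();
      const double cosp = std::cos(phi), sinp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = sint * cosp;
        uy = sint * sinp;
        uz = (uz >= 0.0 ? cost : -cost);
      } else {
        const double den = std::sqrt(1.0 - uz * uz);
        const double uxn =
            sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
        const double uyn =
            sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
        const double uzn = -sint * cosp * den + uz * cost;
        const double nrm =
            std::sqrt(uxn * uxn + uyn * uyn + uzn * uzn);
        ux = uxn / nrm;
        uy = uyn / nrm;
        uz = uzn / nrm;
      }

      // Russian roulette with absorbed-pool bookkeeping
      if (w < w_threshold) {
        if (unif_rand() < p_survive) {
          acc_abs -= w * (1.0 / p_survive - 1.0);
          w /= p_survive;
        } else {
          acc_abs += w;
          alive = false;
        }
      }
    }

    if (exit_top == 0) {
      const double r = std::sqrt(x * x + y * y);
      acc_diff += w;
      const int b = (int)(r / bin_w);
      if (b < nbins)
        bins[b] += w;
      else
        acc_over += w;
      if (record_paths) {
        rec_r.push_back(r);
        rec_h.push_back(0);
        rec_w.push_back(w);
        for (int i = 0; i < k; ++i) rec_L.push_back(Lbuf[i]);
      }
      if (vis_enabled) {
        const double pd = detect_prob(r, det_dist, det_radius);
        if (pd > 0.0) {
          const double mult = w * pd;
          acc_det += mult;
          for (size_t j = 0; j < buf_cell.size(); ++j)
            vismap[buf_cell[j]] += buf_len[j] * mult;
        }
      }
    } else if (exit_top == 1) {
      acc_trans += w;
      if (record_paths) {
        rec_r.push_back(std::sqrt(x * x + y * y));
        rec_h.push_back(1);
        rec_w.push_back(w);
        for (int i = 0; i < k; ++i) rec_L.push_back(Lbuf[i]);
      }
    }
  }

  const double inv_n = 1.0 / (double)n_photons;
  NumericVector out_bins(nbins);
  for (int i = 0; i < nbins; ++i) out_bins[i] = bins[i] * inv_n;

  List out = List::create(
      _["bins"] = out_bins, _["overflow"] = (double)(acc_over * inv_n),
      _["specular"] = (double)(acc_spec * inv_n),
      _["diffuse_total"] = (double)(acc_diff * inv_n),
      _["transmitted"] = (double)(acc_trans * inv_n),
      _["absorbed"] = (double)(acc_abs * inv_n),
      _["n_capped"] = (double)n_capped);

  if (record_paths) {
    const int nrec = (int)rec_r.size();
    NumericMatrix L(nrec, k);
    for (int i = 0; i < nrec; ++i)
      for (int j = 0; j < k; ++j) L(i, j) = rec_L[(size_t)i * k + j];
    out["path_radius"] = NumericVector(rec_r.begin(), rec_r.end());
    out["path_hemisphere"] = IntegerVector(rec_h.begin(), rec_h.end());
    out["path_weight"] = NumericVector(rec_w.begin(), rec_w.end());
    out["path_lengths"] = L;
  }
  if (vis_enabled) {
    NumericMatrix V(vis_nz, vis_nr);  // rows = depth cells, cols = radius
    for (int ir = 0; ir < vis_nr; ++ir)
      for (int iz = 0; iz < vis_nz; ++iz)
        V(iz, ir) = vismap[(size_t)ir * vis_nz + iz];
    out["visitation"] = V;
    out["detected_weight"] = (double)(acc_det * inv_n);
    out["vis_dr"] = vis_dr;
    out["vis_dz"] = vis_dz;
  }
  return out;
}

// Beer-Lambert reweighting of recorded photon pathlengths onto radial bins.
// L: n x k per-layer pathlengths (cm); w: terminal weights; bin: 0-based
// radial bin per photon with value nbins meaning overflow; Mua: m x k
// absorption triples (cm^-1). Returns m x (nbins + 1) weight sums (last
// column = overflow).
// [[Rcpp::export]]
NumericMatrix cpp_rescale_bins(NumericMatrix L, NumericVector w,
                               IntegerVector bin, NumericMatrix Mua,
                               int nbins) {
  const int n = L.nrow(), k = L.ncol(), m = Mua.nrow();
  if (w.size() != n || bin.size() != n)
    stop("length mismatch between pathlength records");
  if (Mua.ncol() != k) stop("mua triple dimension mismatch");
  NumericMatrix out(m, nbins + 1);
  for (int t = 0; t < m; ++t) {
    std::vector<double> a(k);
    for (int j = 0; j < k; ++j) a[j] = Mua(t, j);
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int j = 0; j < k; ++j) e += a[j] * L(i, j);
      const double ww = w[i] * std::exp(-e);
      int b = bin[i];
      if (b < 0) b = 0;
      if (b > nbins) b = nbins;
      out(t, b) += ww;
    }
  }
  return out;
}

// Summed reweighted weight per mua row (no binning); used for the
// transmitted side of the energy budget after rescaling.
// [[Rcpp::export]]
NumericVector cpp_rescale_total(NumericMatrix L, NumericVector w,
                                NumericMatrix Mua) {
  const int n = L.nrow(), k = L.ncol(), m = Mua.nrow();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int j = 0; j < k; ++j) e += Mua(t, j) * L(i, j);
      acc += w[i] * std::exp(-e);
    }
    out[t] = acc;
  }
  return out;
}
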