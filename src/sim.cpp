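// Particle-based Monte Carlo engine for perisynaptic glutamate spillover.
//
// Geometry (lengths in nm): two truncated hemispheres (pre/post) separated by
// a thin apposition zone, embedded in a cubic lattice of cuboid obstacles
// (neighbouring neurites) separated by narrow extracellular gaps.  The central
// 1x1x2 block of lattice cells is vacated to host the synapse; the four inner
// faces of the lateral obstacles act as the astroglial (PAP) membrane, split
// into four azimuthal sectors that carry independent transporter scenarios.
//
// Internal units: nm, microseconds.  D is supplied in nm^2/us.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// ---- deterministic RNG (xoshiro256++, splitmix64 seeding, polar normals) ----
struct Rng {
  uint64_t s[4];
  bool have_spare;
  double spare;

  explicit Rng(uint64_t seed) : have_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {  // Marsaglia polar, deterministic across platforms
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; have_spare = true;
    return u * f;
  }
};

// ---- geometry ----
struct Geom {
  double P;     // obstacle lattice pitch
  double a2;    // obstacle half-side
  double hc;    // half apposition height (cleft half-width in z)
  double R2;    // hemisphere radius^2
  double zc;    // hemisphere sphere-centre offset
  double domxy; // domain half-extent in x,y
  double domz;  // domain half-extent in z
  double cb;    // cavity half-width = P - a/2 (inner wall plane)
};

Geom make_geom(const NumericVector& g) {
  Geom G;
  G.P = g["pitch"]; G.a2 = 0.5 * g["side"]; G.hc = g["hc"];
  double R = g["radius"]; G.R2 = R * R; G.zc = g["zc"];
  G.domxy = g["domxy"]; G.domz = g["domz"];
  G.cb = G.P - G.a2;
  return G;
}

// classify point: 0 free, 1 hemisphere solid, 2 obstacle solid
// (for obstacles, *ix/*iy/*kz give the lattice cell)
inline int classify(const Geom& G, double x, double y, double z,
                    int* ix, int* iy, int* kz) {
  if (z >= G.hc) {
    const double dz = z - G.zc;
    if (x * x + y * y + dz * dz <= G.R2) return 1;
  } else if (z <= -G.hc) {
    const double dz = z + G.zc;
    if (x * x + y * y + dz * dz <= G.R2) return 1;
  }
  double i = std::round(x / G.P); i = std::max(-1.0, std::min(1.0, i));
  double j = std::round(y / G.P); j = std::max(-1.0, std::min(1.0, j));
  double k = std::floor(z / G.P); k = std::max(-2.0, std::min(1.0, k));
  const double cz = (k + 0.5) * G.P;
  if (std::fabs(x - i * G.P) <= G.a2 && std::fabs(y - j * G.P) <= G.a2 &&
      std::fabs(z - cz) <= G.a2) {
    if (i == 0.0 && j == 0.0 && (k == 0.0 || k == -1.0)) return 0; // synapse cell
    *ix = (int)i; *iy = (int)j; *kz = (int)k;
    return 2;
  }
  return 0;
}

inline bool in_solid(const Geom& G, double x, double y, double z) {
  int a, b, c;
  return classify(G, x, y, z, &a, &b, &c) != 0;
}

}  // namespace

// Voxelized extracellular-fraction integration. Each voxel is probed at 8
// interior points offset +/- pitch*sqrt(3)/8 per axis (2x2x2 rule with an
// irrational offset fraction), so axis-aligned membrane faces can never land
// exactly on sample points at any pitch; the per-face assignment bias is a
// few percent of the pitch.
// [[Rcpp::export]]
double cpp_ecs_fraction(NumericVector geom, double pitch) {
  Geom G = make_geom(geom);
  const double x0 = -G.domxy, z0 = -G.domz;
  const int nx = (int)std::round(2.0 * G.domxy / pitch);
  const int nz = (int)std::round(2.0 * G.domz / pitch);
  const double q = pitch * 0.2165063509461097;  // sqrt(3)/8
  int64_t free_n = 0, tot = 0;
  for (int k = 0; k < nz; ++k) {
    const double z = z0 + (k + 0.5) * pitch;
    for (int i = 0; i < nx; ++i) {
      const double x = x0 + (i + 0.5) * pitch;
      for (int j = 0; j < nx; ++j) {
        const double y = x0 + (j + 0.5) * pitch;
        for (int sx = -1; sx <= 1; sx += 2)
          for (int sy = -1; sy <= 1; sy += 2)
            for (int sz = -1; sz <= 1; sz += 2) {
              if (!in_solid(G, x + sx * q, y + sy * q, z + sz * q)) ++free_n;
              ++tot;
            }
      }
    }
  }
  return (double)free_n / (double)tot;
}

// [[Rcpp::export]]
double cpp_ecs_mc(NumericVector geom, int n, double seed) {
  Geom G = make_geom(geom);
  Rng rng((uint64_t)seed);
  int64_t free_n = 0;
  for (int i = 0; i < n; ++i) {
    const double x = (2.0 * rng.unif() - 1.0) * G.domxy;
    const double y = (2.0 * rng.unif() - 1.0) * G.domxy;
    const double z = (2.0 * rng.unif() - 1.0) * G.domz;
    if (!in_solid(G, x, y, z)) ++free_n;
  }
  return (double)free_n / (double)n;
}

// Free 3D Brownian motion from the origin; positions recorded at given steps.
// [[Rcpp::export]]
List cpp_free_diffusion(int n, double D, double dt, IntegerVector record_steps,
                        double seed) {
  Rng rng((uint64_t)seed);
  const double sd = std::sqrt(2.0 * D * dt);
  std::vector<double> x(n, 0.0), y(n, 0.0), z(n, 0.0);
  const int nrec = record_steps.size();
  int maxstep = 0;
  for (int r = 0; r < nrec; ++r) maxstep = std::max(maxstep, record_steps[r]);
  List out(nrec);
  int r = 0;
  for (int step = 1; step <= maxstep; ++step) {
    for (int i = 0; i < n; ++i) {
      x[i] += sd * rng.norm();
      y[i] += sd * rng.norm();
      z[i] += sd * rng.norm();
    }
    while (r < nrec && record_steps[r] == step) {
      NumericMatrix pos(n, 3);
      for (int i = 0; i < n; ++i) { pos(i,0)=x[i]; pos(i,1)=y[i]; pos(i,2)=z[i]; }
      out[r++] = pos;
    }
  }
  return out;
}

// Main simulation: release at cleft centre, diffuse, wall capture by
// transporter patches, extrasynaptic NMDAR cluster kinetics.
//
// patches: rows (sector[1-4], umin, umax, vmin, vmax, pcap)
// nsites:  transporter capacity per sector (length 4)
// rec:     receptor matrix (x, y, z, sector[1-4]); may have 0 rows
// rates:   t_unbind, t_uptake, r_unbind1, r_unbind2, r_open, r_close  [per ms]
//          p_bind, bind_radius [nm]
// cfg:     n_mol, D [nm^2/us], dt [us], t_total [us], bin [us], probe [nm]
// [[Rcpp::export]]
List cpp_sim_run(NumericVector geom, NumericMatrix patches, IntegerVector nsites,
                 NumericMatrix rec, NumericVector rates, NumericVector cfg,
                 NumericVector snapshot_times, double seed) {
  Geom G = make_geom(geom);
  Rng rng((uint64_t)seed);

  const int n_mol = (int)cfg["n_mol"];
  const double D = cfg["D"], dt = cfg["dt"], t_total = cfg["t_total"];
  const double bin = cfg["bin"], probe2 = cfg["probe"] * cfg["probe"];
  const double sd = std::sqrt(2.0 * D * dt);
  const int nsteps = (int)std::ceil(t_total / dt);
  const int nbins = (int)std::ceil(t_total / bin);
  const double dt_ms = dt * 1e-3;

  // transition probabilities per step (rates are per ms)
  const double p_tun = -std::expm1(-rates["t_unbind"] * dt_ms);
  const double p_tup = -std::expm1(-rates["t_uptake"] * dt_ms);
  const double p_ru1 = -std::expm1(-rates["r_unbind1"] * dt_ms);
  const double p_ru2 = -std::expm1(-rates["r_unbind2"] * dt_ms);
  const double p_rop = -std::expm1(-rates["r_open"] * dt_ms);
  const double p_rcl = -std::expm1(-rates["r_close"] * dt_ms);
  const double p_bind = rates["p_bind"];
  const double br2 = rates["bind_radius"] * rates["bind_radius"];

  // molecules: status 0 free, 1 transporter-bound, 2 receptor-bound,
  //            3 taken up, 4 escaped (free, outside domain, frozen)
  std::vector<double> mx(n_mol, 0.0), my(n_mol, 0.0), mz(n_mol, 0.0);
  std::vector<int> status(n_mol, 0), msec(n_mol, -1);
  std::vector<uint8_t> contact(n_mol, 0);  // sector bitmask

  // receptors
  const int n_rec = rec.nrow();
  std::vector<double> rx(n_rec), ry(n_rec), rz(n_rec);
  std::vector<double> nx_(n_rec), ny_(n_rec), nz_(n_rec);  // outward normals
  std::vector<int> rsec(n_rec), rn(n_rec, 0), ropen(n_rec, 0);
  std::vector<int> rmol(2 * (n_rec > 0 ? n_rec : 1), -1);
  double band_lo2 = 1e30, band_hi2 = 0.0;
  for (int i = 0; i < n_rec; ++i) {
    rx[i] = rec(i, 0); ry[i] = rec(i, 1); rz[i] = rec(i, 2);
    rsec[i] = (int)rec(i, 3) - 1;
    const double r2 = rx[i]*rx[i] + ry[i]*ry[i] + rz[i]*rz[i];
    band_lo2 = std::min(band_lo2, r2); band_hi2 = std::max(band_hi2, r2);
    // outward normal of postsynaptic sphere (centre (0,0,-zc))
    double dx = rx[i], dy = ry[i], dz = rz[i] + G.zc;
    const double nn = std::sqrt(dx*dx + dy*dy + dz*dz);
    nx_[i] = dx / nn; ny_[i] = dy / nn; nz_[i] = dz / nn;
  }
  const double brad = std::sqrt(br2);
  const double blo = (n_rec > 0) ? std::max(0.0, std::sqrt(band_lo2) - brad) : 0.0;
  const double bhi = (n_rec > 0) ? std::sqrt(band_hi2) + brad : 0.0;
  const double blo2 = blo * blo, bhi2 = bhi * bhi;

  // per-sector running counters
  int tbound[4] = {0,0,0,0}, uptak[4] = {0,0,0,0};
  int nopen[4] = {0,0,0,0}, nact[4] = {0,0,0,0};
  double open_int[4] = {0,0,0,0}, act_int[4] = {0,0,0,0};
  int peak_open[4] = {0,0,0,0};

  const int n_patch = patches.nrow();

  // outputs
  NumericVector time_ms(nbins);
  IntegerVector free_ct(nbins), dwell_ct(nbins);
  IntegerMatrix tbound_m(nbins, 4), uptake_m(nbins, 4), recstate_m(nbins, 16);
  const int nsnap = snapshot_times.size();
  List snaps(nsnap);
  std::vector<int> snap_step(nsnap);
  for (int s = 0; s < nsnap; ++s)
    snap_step[s] = std::max(1, (int)std::round(snapshot_times[s] / dt));

  int bin_idx = 0;
  const double steps_per_bin = bin / dt;

  for (int step = 1; step <= nsteps; ++step) {
    // --- diffusion + wall interaction + receptor encounter ---
    for (int m = 0; m < n_mol; ++m) {
      const int st = status[m];
      if (st == 0) {
        const double x0 = mx[m], y0 = my[m], z0 = mz[m];
        const double x1 = x0 + sd * rng.norm();
        const double y1 = y0 + sd * rng.norm();
        const double z1 = z0 + sd * rng.norm();
        if (std::fabs(x1) > G.domxy || std::fabs(y1) > G.domxy ||
            std::fabs(z1) > G.domz) {
          status[m] = 4;  // escaped: free, no longer tracked
          mx[m] = x1; my[m] = y1; mz[m] = z1;
          continue;
        }
        int ix = 0, iy = 0, kz = 0;
        const int cls = classify(G, x1, y1, z1, &ix, &iy, &kz);
        if (cls == 0) {
          mx[m] = x1; my[m] = y1; mz[m] = z1;
        } else if (cls == 2 && (std::abs(ix) + std::abs(iy) == 1) &&
                   (kz == 0 || kz == -1) &&
                   std::fabs(x0) < G.cb && std::fabs(y0) < G.cb) {
          // hit an inner cavity wall (astroglial membrane): sector + patch test
          int s;
          double u;
          if (ix == 1)       { s = 0; u = y1; }
          else if (iy == 1)  { s = 1; u = -x1; }
          else if (ix == -1) { s = 2; u = -y1; }
          else               { s = 3; u = x1; }
          contact[m] |= (uint8_t)(1 << s);
          bool captured = false;
          if (nsites[s] > 0 && tbound[s] < nsites[s]) {
            const double v = z1;
            for (int p = 0; p < n_patch; ++p) {
              if ((int)patches(p, 0) - 1 != s) continue;
              if (u >= patches(p, 1) && u <= patches(p, 2) &&
                  v >= patches(p, 3) && v <= patches(p, 4)) {
                const double avail =
                    (double)(nsites[s] - tbound[s]) / (double)nsites[s];
                if (rng.unif() < patches(p, 5) * avail) captured = true;
                break;
              }
            }
          }
          if (captured) {
            status[m] = 1; msec[m] = s; ++tbound[s];
            // rests at its last free position, adjacent to the wall
          }
          // else: rejected move (reflection); stay at (x0,y0,z0)
        }
        // cls==1 or non-wall obstacle: rejected move (reflection)

        // receptor encounter (broad phase: near the cluster radial band)
        if (status[m] == 0 && n_rec > 0 && mz[m] < 0.0) {
          const double r2 = mx[m]*mx[m] + my[m]*my[m] + mz[m]*mz[m];
          if (r2 >= blo2 && r2 <= bhi2) {
            for (int i = 0; i < n_rec; ++i) {
              if (rn[i] >= 2 || ropen[i]) continue;
              const double dx = mx[m]-rx[i], dy = my[m]-ry[i], dz = mz[m]-rz[i];
              if (dx*dx + dy*dy + dz*dz <= br2 && rng.unif() < p_bind) {
                rmol[2*i + rn[i]] = m; ++rn[i];
                if (rn[i] == 2) { ++nact[rsec[i]]; }
                status[m] = 2; msec[m] = rsec[i];
                contact[m] |= (uint8_t)(1 << rsec[i]);
                break;
              }
            }
          }
        }
      } else if (st == 1) {
        // transporter-bound: uptake or stochastic unbinding
        const double u = rng.unif();
        if (u < p_tup) {
          status[m] = 3; ++uptak[msec[m]]; --tbound[msec[m]];
        } else if (u < p_tup + p_tun) {
          status[m] = 0; --tbound[msec[m]];  // released where it bound
        }
      }
      // st==2 handled by receptor loop; st==3/4 inert
    }

    // --- receptor state transitions ---
    for (int i = 0; i < n_rec; ++i) {
      if (ropen[i]) {
        if (rng.unif() < p_rcl) { ropen[i] = 0; --nopen[rsec[i]]; }
      } else if (rn[i] == 2) {
        const double u = rng.unif();
        if (u < p_rop) {
          ropen[i] = 1; ++nopen[rsec[i]];
          if (nopen[rsec[i]] > peak_open[rsec[i]])
            peak_open[rsec[i]] = nopen[rsec[i]];
        } else if (u < p_rop + p_ru2) {
          const int m = rmol[2*i + 1]; rmol[2*i + 1] = -1; --rn[i];
          --nact[rsec[i]];
          status[m] = 0;
          mx[m] = rx[i] + 2.0*nx_[i]; my[m] = ry[i] + 2.0*ny_[i];
          mz[m] = rz[i] + 2.0*nz_[i];
        }
      } else if (rn[i] == 1) {
        if (rng.unif() < p_ru1) {
          const int m = rmol[2*i]; rmol[2*i] = rmol[2*i + 1]; rmol[2*i+1] = -1;
          --rn[i];
          status[m] = 0;
          mx[m] = rx[i] + 2.0*nx_[i]; my[m] = ry[i] + 2.0*ny_[i];
          mz[m] = rz[i] + 2.0*nz_[i];
        }
      }
    }

    for (int s = 0; s < 4; ++s) {
      open_int[s] += nopen[s] * dt_ms;
      act_int[s] += nact[s] * dt_ms;
    }

    // --- snapshots ---
    for (int s = 0; s < nsnap; ++s) {
      if (snap_step[s] == step) {
        NumericMatrix pos(n_mol, 4);
        for (int m = 0; m < n_mol; ++m) {
          pos(m,0)=mx[m]; pos(m,1)=my[m]; pos(m,2)=mz[m]; pos(m,3)=status[m];
        }
        snaps[s] = pos;
      }
    }

    // --- binning ---
    if (step >= (bin_idx + 1) * steps_per_bin - 1e-9 || step == nsteps) {
      if (bin_idx < nbins) {
        int nf = 0, dw = 0;
        for (int m = 0; m < n_mol; ++m) {
          const int st = status[m];
          if (st == 0 || st == 4) ++nf;
          if (st == 0 &&
              mx[m]*mx[m] + my[m]*my[m] + mz[m]*mz[m] > probe2) ++dw;
        }
        free_ct[bin_idx] = nf; dwell_ct[bin_idx] = dw;
        time_ms[bin_idx] = step * dt_ms;
        for (int s = 0; s < 4; ++s) {
          tbound_m(bin_idx, s) = tbound[s];
          uptake_m(bin_idx, s) = uptak[s];
        }
        int rs[16] = {0};
        for (int i = 0; i < n_rec; ++i) {
          int state = ropen[i] ? 3 : rn[i];  // 0,1,2 closed; 3 open
          ++rs[4 * rsec[i] + state];
        }
        for (int q = 0; q < 16; ++q) recstate_m(bin_idx, q) = rs[q];
        ++bin_idx;
      }
    }
  }

  int multi = 0, any = 0;
  for (int m = 0; m < n_mol; ++m) {
    if (contact[m]) {
      ++any;
      const uint8_t c = contact[m];
      int bits = (c & 1) + ((c >> 1) & 1) + ((c >> 2) & 1) + ((c >> 3) & 1);
      if (bits > 1) ++multi;
    }
  }

  return List::create(
      _["time_ms"] = time_ms, _["free"] = free_ct, _["dwell"] = dwell_ct,
      _["tbound"] = tbound_m, _["uptake"] = uptake_m,
      _["recstate"] = recstate_m,
      _["open_integral"] = NumericVector(open_int, open_int + 4),
      _["act_integral"] = NumericVector(act_int, act_int + 4),
      _["peak_open"] = IntegerVector(peak_open, peak_open + 4),
      _["contact_any"] = any, _["contact_multi"] = multi,
      _["snapshots"] = snaps);
}
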