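// RIS ensemble generation: enumerate torsion assignments, pre-build local
// chain frames, sweep uniform random rigid rotations, reject conformations
// crossing the wall, bin accepted ones into layers and collapse duplicate
// occupancy vectors with multiplicities.

#include <Rcpp.h>
#include <random>
#include <unordered_map>
#include <vector>
#include <string>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// deterministic uniform in [0,1) from a 64-bit Mersenne generator
static inline double u01(std::mt19937_64 &g) {
  return (g() >> 11) * (1.0 / 9007199254740992.0);
}

struct Vec3 { double x, y, z; };

static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// local-frame coordinates for one torsion assignment (internal bond-angle
// convention; trans = 180 degrees continues the planar zig-zag)
static void build_local(int N, const int *assign, double b, double ths,
                        const double *phi_states, std::vector<Vec3> &coords) {
  coords[0] = {0.0, 0.0, 0.0};
  if (N == 1) return;
  std::vector<Vec3> u(N - 1);
  u[0] = {0.0, 0.0, 1.0};
  double sth = std::sin(ths), cth = std::cos(ths);
  if (N >= 3) u[1] = {sth, 0.0, cth};
  for (int i = 2; i < N - 1; ++i) {
    Vec3 e1 = u[i - 1];
    Vec3 prev = u[i - 2];
    double d = dot(prev, e1);
    Vec3 p = {prev.x - d * e1.x, prev.y - d * e1.y, prev.z - d * e1.z};
    double np = std::sqrt(dot(p, p));
    if (np < 1e-12) {
      u[i] = {cth * e1.x, cth * e1.y, cth * e1.z};
      if (std::fabs(sth) > 1e-12) { u[i].x += sth; }
      continue;
    }
    Vec3 ep = {p.x / np, p.y / np, p.z / np};
    Vec3 en = cross(e1, ep);
    double phi = phi_states[assign[i - 2]];
    double cp = std::cos(phi), sp = std::sin(phi);
    u[i] = {cth * e1.x - sth * (cp * ep.x + sp * en.x),
            cth * e1.y - sth * (cp * ep.y + sp * en.y),
            cth * e1.z - sth * (cp * ep.z + sp * en.z)};
  }
  for (int i = 1; i < N; ++i) {
    coords[i] = {coords[i - 1].x + b * u[i - 1].x,
                 coords[i - 1].y + b * u[i - 1].y,
                 coords[i - 1].z + b * u[i - 1].z};
  }
}

// [[Rcpp::export]]
List ris_ensemble_cpp(LogicalVector is_A, double bond_length,
                      double bond_angle_deg, NumericVector torsions_deg,
                      double first_z, int n_layers, double dz,
                      int rotations_per_state, double seed,
                      double max_conformations) {
  const int N = is_A.size();
  const double ths = (180.0 - bond_angle_deg) * M_PI / 180.0;
  double phi_states[3];
  for (int s = 0; s < 3; ++s) phi_states[s] = torsions_deg[s] * M_PI / 180.0;
  const int d = N >= 3 ? N - 3 : 0;
  long n_assign = 1;
  for (int i = 0; i < d; ++i) n_assign *= 3;

  // pre-build all local-frame conformations
  std::vector<std::vector<Vec3>> locals((size_t)n_assign,
                                        std::vector<Vec3>((size_t)N));
  {
    std::vector<int> assign(d > 0 ? d : 1, 0);
    for (long a = 0; a < n_assign; ++a) {
      long rem = a;
      for (int i = 0; i < d; ++i) { assign[i] = rem % 3; rem /= 3; }
      build_local(N, assign.data(), bond_length, ths, phi_states, locals[(size_t)a]);
    }
  }

  // bound on the highest reachable layer
  int Lmax = (int)std::floor((first_z + bond_length * (N - 1)) / dz) + 1;
  if (Lmax > n_layers) Lmax = n_layers;

  std::mt19937_64 gen((uint64_t)seed);
  std::unordered_map<std::string, double> table;
  std::vector<std::string> order;  // first-seen order for determinism
  std::string key((size_t)(2 * Lmax), '\0');
  std::vector<unsigned char> occA((size_t)Lmax), occG((size_t)Lmax);

  const double zmaxg = n_layers * dz;
  long accepted = 0, attempted = 0;
  const long cap = max_conformations > 0 ? (long)max_conformations : -1;
  bool done = false;

  for (int r = 0; r < rotations_per_state && !done; ++r) {
    for (long a = 0; a < n_assign; ++a) {
      // uniform random rotation from a uniform unit quaternion
      double q0, q1, q2, q3, nq;
      do {
        q0 = 2.0 * u01(gen) - 1.0; q1 = 2.0 * u01(gen) - 1.0;
        q2 = 2.0 * u01(gen) - 1.0; q3 = 2.0 * u01(gen) - 1.0;
        nq = q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3;
      } while (nq < 1e-8 || nq > 1.0);
      double s = 1.0 / std::sqrt(nq);
      q0 *= s; q1 *= s; q2 *= s; q3 *= s;
      // third row of the rotation matrix (only z is needed) and full rows
      double R[3][3] = {
        {1 - 2 * (q2 * q2 + q3 * q3), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2)},
        {2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1 * q1 + q3 * q3), 2 * (q2 * q3 - q0 * q1)},
        {2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1 * q1 + q2 * q2)}
      };
      ++attempted;
      const std::vector<Vec3> &loc = locals[(size_t)a];
      std::fill(occA.begin(), occA.end(), 0);
      std::fill(occG.begin(), occG.end(), 0);
      bool ok = true;
      for (int i = 0; i < N; ++i) {
        double z = R[2][0] * loc[i].x + R[2][1] * loc[i].y + R[2][2] * loc[i].z
                   + first_z;
        if (z < 0.0 || z >= zmaxg) { ok = false; break; }
        int k = (int)std::floor(z / dz);
        if (k >= Lmax) { ok = false; break; }  // numerically at the bound
        if (is_A[i]) ++occA[(size_t)k]; else ++occG[(size_t)k];
      }
      if (!ok) continue;
      for (int k = 0; k < Lmax; ++k) {
        key[(size_t)k] = (char)occA[(size_t)k];
        key[(size_t)(Lmax + k)] = (char)occG[(size_t)k];
      }
      auto it = table.find(key);
      if (it == table.end()) { table.emplace(key, 1.0); order.push_back(key); }
      else it->second += 1.0;
      ++accepted;
      if (cap > 0 && accepted >= cap) { done = true; break; }
    }
  }

  // trim to the highest occupied layer
  int Lc = 1;
  for (const auto &k : order)
    for (int j = Lmax - 1; j >= Lc; --j)
      if (k[(size_t)j] != 0 || k[(size_t)(Lmax + j)] != 0) { if (j + 1 > Lc) Lc = j + 1; break; }

  const int nu = (int)order.size();
  IntegerMatrix nA(nu, Lc), nG(nu, Lc);
  NumericVector m(nu);
  for (int i = 0; i < nu; ++i) {
    const std::string &k = order[(size_t)i];
    for (int j = 0; j < Lc; ++j) {
      nA(i, j) = (int)(unsigned char)k[(size_t)j];
      nG(i, j) = (int)(unsigned char)k[(size_t)(Lmax + j)];
    }
    m[i] = table[k];
  }
  return List::create(_["nA"] = nA, _["nG"] = nG, _["m"] = m,
                      _["accepted"] = (double)accepted,
                      _["attempted"] = (double)attempted,
                      _["layers_used"] = Lc);
}

// single-conformation embedding, mirroring the R reference implementation
// [[Rcpp::export]]
NumericMatrix ris_embed_cpp(IntegerVector assignment, int n_monomers,
                            double bond_length, double bond_angle_deg,
                            NumericVector torsions_deg, double first_z,
                            NumericMatrix rotation) {
  const double ths = (180.0 - bond_angle_deg) * M_PI / 180.0;
  double phi_states[3];
  for (int s = 0; s < 3; ++s) phi_states[s] = torsions_deg[s] * M_PI / 180.0;
  std::vector<int> assign(assignment.size());
  for (int i = 0; i < assignment.size(); ++i) assign[(size_t)i] = assignment[i] - 1;
  std::vector<Vec3> loc((size_t)n_monomers);
  build_local(n_monomers, assign.data(), bond_length, ths, phi_states, loc);
  NumericMatrix out(n_monomers, 3);
  for (int i = 0; i < n_monomers; ++i) {
    out(i, 0) = rotation(0, 0) * loc[(size_t)i].x + rotation(0, 1) * loc[(size_t)i].y + rotation(0, 2) * loc[(size_t)i].z;
    out(i, 1) = rotation(1, 0) * loc[(size_t)i].x + rotation(1, 1) * loc[(size_t)i].y + rotation(1, 2) * loc[(size_t)i].z;
    out(i, 2) = rotation(2, 0) * loc[(size_t)i].x + rotation(2, 1) * loc[(size_t)i].y + rotation(2, 2) * loc[(size_t)i].z + first_z;
  }
  return out;
}
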