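// Compiled core: internal-coordinate (NeRF) conformation building, batch
// non-bonded energy evaluation for the stochastic sampler, Shrake-Rupley
// accessible surface area, implicit-membrane insertion scanning, and
// residue-environment scores.  All randomness lives on the R side; every
// routine here is deterministic in its inputs.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// Place atom D given bonded parent A, angle reference B, torsion reference C.
static inline void nerf_place(const double* A, const double* B, const double* C,
                              double bond, double theta_deg, double chi_deg,
                              double* D) {
  const double theta = theta_deg * DEG, chi = chi_deg * DEG;
  double bc[3] = {A[0] - B[0], A[1] - B[1], A[2] - B[2]};
  double nb = std::sqrt(bc[0]*bc[0] + bc[1]*bc[1] + bc[2]*bc[2]);
  for (int k = 0; k < 3; ++k) bc[k] /= nb;
  double ab[3] = {B[0] - C[0], B[1] - C[1], B[2] - C[2]};
  double n[3] = {ab[1]*bc[2] - ab[2]*bc[1],
                 ab[2]*bc[0] - ab[0]*bc[2],
                 ab[0]*bc[1] - ab[1]*bc[0]};
  double nn = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
  if (nn < 1e-10) { n[0] = 0; n[1] = 0; n[2] = 1; nn = 1; }
  for (int k = 0; k < 3; ++k) n[k] /= nn;
  double m[3] = {n[1]*bc[2] - n[2]*bc[1],
                 n[2]*bc[0] - n[0]*bc[2],
                 n[0]*bc[1] - n[1]*bc[0]};
  const double d0 = -bond * std::cos(theta);
  const double d1 =  bond * std::sin(theta) * std::cos(chi);
  const double d2 = -bond * std::sin(theta) * std::sin(chi);
  for (int k = 0; k < 3; ++k)
    D[k] = A[k] + d0 * bc[k] + d1 * m[k] + d2 * n[k];
}

// Build coordinates from the flattened Z-matrix.  ref[abc] are 0-based atom
// indices (-1 for the three seed atoms).  dtype: 0 constant, 1 phi[dres],
// 2 psi[dres]; the residue dihedral (degrees) is added to doff.
static void build_coords_impl(const IntegerVector& refa, const IntegerVector& refb,
                              const IntegerVector& refc, const NumericVector& bond,
                              const NumericVector& ang, const IntegerVector& dtype,
                              const IntegerVector& dres, const NumericVector& doff,
                              const NumericVector& phi, const NumericVector& psi,
                              double* xyz /* natoms*3, atom-major */) {
  const int n = refa.size();
  for (int i = 0; i < n; ++i) {
    double* D = xyz + 3 * i;
    if (refa[i] < 0) {            // seed atom 0 at origin
      D[0] = D[1] = D[2] = 0.0;
      continue;
    }
    if (refb[i] < 0) {            // seed atom 1 on +x
      const double* A = xyz + 3 * refa[i];
      D[0] = A[0] + bond[i]; D[1] = A[1]; D[2] = A[2];
      continue;
    }
    if (refc[i] < 0) {            // seed atom 2 in the xy plane
      const double* A = xyz + 3 * refa[i];
      const double* B = xyz + 3 * refb[i];
      double ux = B[0] - A[0], uy = B[1] - A[1];
      double nu = std::sqrt(ux*ux + uy*uy);
      ux /= nu; uy /= nu;
      const double ct = std::cos(ang[i] * DEG), st = std::sin(ang[i] * DEG);
      D[0] = A[0] + bond[i] * (ct * ux - st * uy);
      D[1] = A[1] + bond[i] * (ct * uy + st * ux);
      D[2] = A[2];
      continue;
    }
    double chi = doff[i];
    if (dtype[i] == 1) chi += phi[dres[i]];
    else if (dtype[i] == 2) chi += psi[dres[i]];
    nerf_place(xyz + 3 * refa[i], xyz + 3 * refb[i], xyz + 3 * refc[i],
               bond[i], ang[i], chi, D);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_build_coords(IntegerVector refa, IntegerVector refb,
                               IntegerVector refc, NumericVector bond,
                               NumericVector ang, IntegerVector dtype,
                               IntegerVector dres, NumericVector doff,
                               NumericVector phi, NumericVector psi) {
  const int n = refa.size();
  std::vector<double> xyz(3 * n);
  build_coords_impl(refa, refb, refc, bond, ang, dtype, dres, doff,
                    phi, psi, xyz.data());
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = xyz[3 * i + k];
  return out;
}

static inline double dihedral_deg(const double* p1, const double* p2,
                                  const double* p3, const double* p4) {
  double b1[3], b2[3], b3[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = p2[k] - p1[k];
    b2[k] = p3[k] - p2[k];
    b3[k] = p4[k] - p3[k];
  }
  double n1[3] = {b1[1]*b2[2] - b1[2]*b2[1], b1[2]*b2[0] - b1[0]*b2[2],
                  b1[0]*b2[1] - b1[1]*b2[0]};
  double n2[3] = {b2[1]*b3[2] - b2[2]*b3[1], b2[2]*b3[0] - b2[0]*b3[2],
                  b2[0]*b3[1] - b2[1]*b3[0]};
  double nb2 = std::sqrt(b2[0]*b2[0] + b2[1]*b2[1] + b2[2]*b2[2]);
  double m[3] = {n1[1]*b2[2] - n1[2]*b2[1], n1[2]*b2[0] - n1[0]*b2[2],
                 n1[0]*b2[1] - n1[1]*b2[0]};
  double x = n1[0]*n2[0] + n1[1]*n2[1] + n1[2]*n2[2];
  double y = (m[0]*n2[0] + m[1]*n2[1] + m[2]*n2[2]) / nb2;
  return std::atan2(y, x) / DEG;
}

// [[Rcpp::export]]
NumericVector cpp_measure_dihedrals(NumericMatrix coords, IntegerMatrix idx) {
  const int n = idx.nrow(), na = coords.nrow();
  std::vector<double> xyz(3 * na);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) xyz[3 * i + k] = coords(i, k);
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = dihedral_deg(xyz.data() + 3 * (idx(i, 0) - 1),
                          xyz.data() + 3 * (idx(i, 1) - 1),
                          xyz.data() + 3 * (idx(i, 2) - 1),
                          xyz.data() + 3 * (idx(i, 3) - 1));
  return out;
}

// Smoothstep dielectric: 1 below dlo (A), 80 above dhi, cubic in between.
static inline double eps_smooth(double d, double dlo, double dhi,
                                double elo, double ehi) {
  if (d <= dlo) return elo;
  if (d >= dhi) return ehi;
  const double t = (d - dlo) / (dhi - dlo);
  return elo + (ehi - elo) * t * t * (3.0 - 2.0 * t);
}

struct PairData {
  std::vector<int> i, j, tp;
  std::vector<double> qq;       // k_coulomb * q_i * q_j (0 for uncharged)
  std::vector<double> A, B;     // Lennard-Jones pair coefficients
  std::vector<char> heavy;      // both atoms heavy (clash bookkeeping)
  // residue-pair blocks (optional; empty = no pruning)
  std::vector<int> block_start, block_ri, block_rj, charged_start;
};

static PairData unpack_pairs(const List& pairs) {
  PairData p;
  IntegerVector pi = pairs["i"], pj = pairs["j"], tp = pairs["tp"];
  NumericVector qq = pairs["qq"];
  LogicalVector hv = pairs["heavy"];
  const int n = pi.size();
  p.i.assign(pi.begin(), pi.end());
  p.j.assign(pj.begin(), pj.end());
  p.tp.assign(tp.begin(), tp.end());
  p.qq.assign(qq.begin(), qq.end());
  if (pairs.containsElementNamed("A")) {
    NumericVector A = pairs["A"], B = pairs["B"];
    p.A.assign(A.begin(), A.end());
    p.B.assign(B.begin(), B.end());
  }
  p.heavy.resize(n);
  for (int k = 0; k < n; ++k) p.heavy[k] = hv[k] ? 1 : 0;
  if (pairs.containsElementNamed("block_start")) {
    IntegerVector bs = pairs["block_start"], bri = pairs["block_ri"],
                  brj = pairs["block_rj"], cs = pairs["charged_start"];
    p.block_start.assign(bs.begin(), bs.end());
    p.block_ri.assign(bri.begin(), bri.end());
    p.block_rj.assign(brj.begin(), brj.end());
    p.charged_start.assign(cs.begin(), cs.end());
  }
  return p;
}

// Tabulated Lennard-Jones + hydrophobicity kernel, indexed by squared
// distance: ftab is (nbins+1) x ntp, column tp holds F_tp(d) at
// d^2 = b * cut2 / nbins.  Coulomb is evaluated exactly (smoothstep
// dielectric, no transcendentals).
struct Kernel {
  const double* ftab; int nbins, ntp;
  const double* focc_i; const double* focc_j;  // occlusion tables (may be 0)
  double cut2, inv_bin;
  double dlo, dhi, elo, ehi;    // dielectric (Angstrom units)
  inline double pair_energy(double d2, int tp, double qq) const {
    double e = 0.0;
    if (d2 < cut2) {
      double x = d2 * inv_bin;
      int b = (int)x;
      double w = x - b;
      const double* col = ftab + (size_t)tp * (nbins + 1);
      e += col[b] * (1.0 - w) + col[b + 1] * w;
    }
    if (qq != 0.0) {
      double d = std::sqrt(d2);
      e += qq / (eps_smooth(d, dlo, dhi, elo, ehi) * d);
    }
    return e;
  }
  // short-range interleaved single-precision table (hydrophobicity
  // energy, occ_i, occ_j per bin, uniform in d^2 up to occ_cut2);
  // Lennard-Jones and Coulomb are evaluated analytically with streamed
  // per-pair coefficients
  const float* comb;
  double occ_cut2, occ_inv_bin;
  int occ_nbins;
  inline double pair_energy_occ(double d2, int tp, double A, double B,
                                double qq,
                                double& occ_a, double& occ_b) const {
    double e = 0.0;
    if (d2 < cut2) {
      const double inv2 = 1.0 / std::max(d2, 0.64);
      const double inv6 = inv2 * inv2 * inv2;
      e += (A * inv6 - B) * inv6;
      if (d2 < occ_cut2) {
        const double x = d2 * occ_inv_bin;
        const int b = (int)x;
        const double w = x - b, w1 = 1.0 - w;
        const float* c0 = comb + (size_t)tp * 3 * (occ_nbins + 1) + 3 * b;
        e += c0[0] * w1 + c0[3] * w;
        occ_a += c0[1] * w1 + c0[4] * w;
        occ_b += c0[2] * w1 + c0[5] * w;
      }
    }
    if (qq != 0.0) {
      double d = std::sqrt(d2);
      e += qq / (eps_smooth(d, dlo, dhi, elo, ehi) * d);
    }
    return e;
  }
};

static Kernel make_kernel(const NumericMatrix& ftab, double cut,
                          const NumericVector& diel) {
  Kernel k;
  k.ftab = &ftab(0, 0);
  k.focc_i = 0; k.focc_j = 0;
  k.comb = 0; k.occ_cut2 = 0;
  k.nbins = ftab.nrow() - 1;
  k.ntp = ftab.ncol();
  k.cut2 = cut * cut;
  k.inv_bin = k.nbins / k.cut2;
  k.dlo = diel[0]; k.dhi = diel[1]; k.elo = diel[2]; k.ehi = diel[3];
  return k;
}

// kernel over the short-range interleaved (pho, occ_i, occ_j) table;
// the float copy must outlive the kernel
static Kernel make_kernel_comb(const NumericMatrix& comb,
                               std::vector<float>& store, double cut,
                               double short_cut,
                               const NumericVector& diel) {
  Kernel k;
  k.ftab = 0; k.focc_i = 0; k.focc_j = 0;
  store.assign(comb.begin(), comb.end());
  k.comb = store.data();
  k.occ_nbins = comb.nrow() / 3 - 1;
  k.nbins = k.occ_nbins;
  k.ntp = comb.ncol();
  k.cut2 = cut * cut;
  k.occ_cut2 = short_cut * short_cut;
  k.occ_inv_bin = k.occ_nbins / k.occ_cut2;
  k.inv_bin = k.occ_inv_bin;
  k.dlo = diel[0]; k.dhi = diel[1]; k.elo = diel[2]; k.ehi = diel[3];
  return k;
}

// pair sweep with residue-block pruning: blocks whose CA-CA distance
// exceeds cutoff + reach_i + reach_j contribute nothing (and cannot
// clash).  Returns the energy; min squared heavy distance via md2.
static inline double pair_sweep(const PairData& pd, const Kernel& K,
                                const double* xyz,
                                const int* ca_idx, const double* reach,
                                double cutoff, double* occ, double& md2) {
  double e = 0.0;
  const int nblock = (int)pd.block_ri.size();
  for (int b = 0; b < nblock; ++b) {
    const int ri = pd.block_ri[b], rj = pd.block_rj[b];
    if (ri != rj) {
      const double* ca1 = xyz + 3 * ca_idx[ri];
      const double* ca2 = xyz + 3 * ca_idx[rj];
      const double dx = ca1[0] - ca2[0], dy = ca1[1] - ca2[1],
                   dz = ca1[2] - ca2[2];
      const double lim = cutoff + reach[ri] + reach[rj];
      if (dx * dx + dy * dy + dz * dz > lim * lim) continue;
    }
    const int p1 = pd.block_start[b], cs = pd.charged_start.empty()
      ? pd.block_start[b + 1] : pd.charged_start[b];
    const int p2 = pd.block_start[b + 1];
    for (int p = p1; p < cs; ++p) {          // neutral pairs
      const double* a = xyz + 3 * pd.i[p];
      const double* c = xyz + 3 * pd.j[p];
      const double dx = a[0] - c[0], dy = a[1] - c[1], dz = a[2] - c[2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      e += K.pair_energy_occ(d2, pd.tp[p], pd.A[p], pd.B[p], 0.0,
                             occ[pd.i[p]], occ[pd.j[p]]);
      if (pd.heavy[p] && d2 < md2) md2 = d2;
    }
    for (int p = cs; p < p2; ++p) {          // charged pairs
      const double* a = xyz + 3 * pd.i[p];
      const double* c = xyz + 3 * pd.j[p];
      const double dx = a[0] - c[0], dy = a[1] - c[1], dz = a[2] - c[2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      e += K.pair_energy_occ(d2, pd.tp[p], pd.A[p], pd.B[p], pd.qq[p],
                             occ[pd.i[p]], occ[pd.j[p]]);
      if (pd.heavy[p] && d2 < md2) md2 = d2;
    }
  }
  return e;
}

// fast clash predicate: any non-bonded heavy pair below the floor?  Block
// pruning uses the much tighter clash radius, and the scan exits on the
// first hit.
static inline bool clash_scan(const PairData& pd, const double* xyz,
                              const int* ca_idx, const double* reach,
                              double clash_floor) {
  const double clash2 = clash_floor * clash_floor;
  const int nblock = (int)pd.block_ri.size();
  for (int b = 0; b < nblock; ++b) {
    const int ri = pd.block_ri[b], rj = pd.block_rj[b];
    if (ri != rj) {
      const double* ca1 = xyz + 3 * ca_idx[ri];
      const double* ca2 = xyz + 3 * ca_idx[rj];
      const double dx = ca1[0] - ca2[0], dy = ca1[1] - ca2[1],
                   dz = ca1[2] - ca2[2];
      const double lim = clash_floor + reach[ri] + reach[rj];
      if (dx * dx + dy * dy + dz * dz > lim * lim) continue;
    }
    const int p1 = pd.block_start[b], p2 = pd.block_start[b + 1];
    for (int p = p1; p < p2; ++p) {
      if (!pd.heavy[p]) continue;
      const double* a = xyz + 3 * pd.i[p];
      const double* c = xyz + 3 * pd.j[p];
      const double dx = a[0] - c[0], dy = a[1] - c[1], dz = a[2] - c[2];
      if (dx * dx + dy * dy + dz * dz < clash2) return true;
    }
  }
  return false;
}

// Energies (and minimal heavy-atom non-bonded distances) for a batch of
// state assignments.  states is nstruct x nres, 1-based state indices.
// w is the per-atom burial weight: E_env = sum_i w_i * max(0, 1 - occ_i)
// with occ the pairwise occlusion-fraction sum (all zeros disables it).
// [[Rcpp::export]]
List cpp_energy_states(IntegerMatrix states,
                       NumericVector state_phi, NumericVector state_psi,
                       List zmat, List pairs,
                       NumericMatrix comb, double short_cut,
                       NumericVector w,
                       IntegerVector ca_idx, NumericVector reach,
                       double cutoff, NumericVector dielectric) {
  IntegerVector refa = zmat["refa"], refb = zmat["refb"], refc = zmat["refc"];
  NumericVector bond = zmat["bond"], ang = zmat["ang"], doff = zmat["doff"];
  IntegerVector dtype = zmat["dtype"], dres = zmat["dres"];
  PairData pd = unpack_pairs(pairs);
  std::vector<float> comb_store;
  Kernel K = make_kernel_comb(comb, comb_store, cutoff, short_cut,
                              dielectric);

  const int ns = states.nrow(), nres = states.ncol(), natoms = refa.size();
  const int npair = pd.i.size();
  NumericVector energy(ns), mindist(ns);
  std::vector<double> xyz(3 * natoms), occ(natoms);
  NumericVector phi(nres), psi(nres);

  for (int s = 0; s < ns; ++s) {
    for (int r = 0; r < nres; ++r) {
      const int st = states(s, r) - 1;
      phi[r] = state_phi[st];
      psi[r] = state_psi[st];
    }
    build_coords_impl(refa, refb, refc, bond, ang, dtype, dres, doff,
                      phi, psi, xyz.data());
    std::fill(occ.begin(), occ.end(), 0.0);
    double md2 = std::numeric_limits<double>::max();
    double e = pair_sweep(pd, K, xyz.data(), &ca_idx[0], &reach[0],
                          cutoff, occ.data(), md2);
    for (int a2 = 0; a2 < natoms; ++a2)
      e += w[a2] * std::max(0.0, 1.0 - occ[a2]);
    energy[s] = e;
    mindist[s] = std::sqrt(md2);
  }
  return List::create(_["energy"] = energy, _["min_heavy_dist"] = mindist);
}

// Exact per-pair energy components for one coordinate set (used by the
// R-level energy functions on arbitrary atom tables).  Returns the three
// summed components; formulas are supplied via per-pair parameters computed
// in R: A, B (Lennard-Jones), phomag = delta_ij * sqrt(|Etr_i*Etr_j|),
// r0i, r0j, qq (k*qi*qj).
// [[Rcpp::export]]
List cpp_energy_components(NumericMatrix coords,
                           IntegerVector pi, IntegerVector pj,
                           NumericVector A, NumericVector B,
                           NumericVector phomag, NumericVector r0i,
                           NumericVector r0j, NumericVector qq,
                           double rsol, NumericVector dielectric) {
  const int na = coords.nrow(), np = pi.size();
  std::vector<double> xyz(3 * na);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) xyz[3 * i + k] = coords(i, k);
  double evdw = 0, ecoul = 0, epho = 0;
  for (int p = 0; p < np; ++p) {
    const double* a = xyz.data() + 3 * (pi[p] - 1);
    const double* b = xyz.data() + 3 * (pj[p] - 1);
    const double dx = a[0]-b[0], dy = a[1]-b[1], dz = a[2]-b[2];
    const double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    const double inv6 = 1.0 / (d*d*d*d*d*d);
    evdw += A[p] * inv6 * inv6 - B[p] * inv6;
    if (qq[p] != 0.0)
      ecoul += qq[p] / (eps_smooth(d, dielectric[0], dielectric[1],
                                   dielectric[2], dielectric[3]) * d);
    if (phomag[p] != 0.0) {
      // coverage of solvent-augmented spheres + exponential decay, both
      // clamped at hard-sphere contact
      const double Ri = r0i[p] + rsol, Rj = r0j[p] + rsol;
      const double dc = std::max(d, r0i[p] + r0j[p]);
      double f = 0.0;
      if (dc < Ri + Rj) {
        const double hi = Ri - (dc*dc + Ri*Ri - Rj*Rj) / (2.0 * dc);
        const double hj = Rj - (dc*dc + Rj*Rj - Ri*Ri) / (2.0 * dc);
        const double fi = std::min(1.0, std::max(0.0, hi / (2.0 * Ri)));
        const double fj = std::min(1.0, std::max(0.0, hj / (2.0 * Rj)));
        f = 0.5 * (fi + fj);
      }
      epho += phomag[p] * f *
        std::exp(-(dc - r0i[p] - r0j[p]) / (2.0 * rsol));
    }
  }
  return List::create(_["vdw"] = evdw, _["coulomb"] = ecoul, _["pho"] = epho);
}

// Shrake-Rupley accessible surface area with a fixed deterministic point
// set (points: npts x 3 unit vectors).  radii already include the probe.
// [[Rcpp::export]]
NumericVector cpp_asa(NumericMatrix coords, NumericVector radii,
                      NumericMatrix points) {
  const int na = coords.nrow(), npts = points.nrow();
  std::vector<double> xyz(3 * na), pt(3 * npts);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) xyz[3 * i + k] = coords(i, k);
  for (int i = 0; i < npts; ++i)
    for (int k = 0; k < 3; ++k) pt[3 * i + k] = points(i, k);
  NumericVector asa(na);
  std::vector<std::pair<double, int> > nbr;
  for (int i = 0; i < na; ++i) {
    const double ri = radii[i];
    nbr.clear();
    for (int j = 0; j < na; ++j) {
      if (j == i) continue;
      const double dx = xyz[3*i] - xyz[3*j], dy = xyz[3*i+1] - xyz[3*j+1],
                   dz = xyz[3*i+2] - xyz[3*j+2];
      const double lim = ri + radii[j];
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < lim * lim) nbr.push_back(std::make_pair(d2, j));
    }
    std::sort(nbr.begin(), nbr.end());   // nearest first: earlier rejection
    int acc = 0;
    for (int p = 0; p < npts; ++p) {
      const double px = xyz[3*i] + ri * pt[3*p],
                   py = xyz[3*i+1] + ri * pt[3*p+1],
                   pz = xyz[3*i+2] + ri * pt[3*p+2];
      bool free_pt = true;
      for (size_t q = 0; q < nbr.size(); ++q) {
        const int j = nbr[q].second;
        const double dx = px - xyz[3*j], dy = py - xyz[3*j+1],
                     dz = pz - xyz[3*j+2];
        if (dx*dx + dy*dy + dz*dz < radii[j] * radii[j]) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    asa[i] = 4.0 * M_PI * ri * ri * acc / npts;
  }
  return asa;
}

// Implicit-membrane insertion scan.  For each rigid rotation (rots: K x 9,
// row-major 3x3 matrices applied to centered coordinates) and each z offset
// of the centroid, the membrane potential is
//   E(z) = sum_i u_i * (1 - C(z_i))
// with u_i = S_i * (alip - Etr_i) and C the water-phase interface function
// C(z) = 1 / (1 + exp(alpha * (z0 - |z|))) (z0, alpha in Angstrom units).
// Returns the per-z minimum over rotations and the global optimum.
// [[Rcpp::export]]
List cpp_insertion_scan(NumericMatrix coords, NumericVector u,
                        NumericMatrix rots, NumericVector zgrid,
                        double z0, double alpha) {
  const int na = coords.nrow(), nrot = rots.nrow(), nz = zgrid.size();
  // center on centroid
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < na; ++i) { cx += coords(i,0); cy += coords(i,1); cz += coords(i,2); }
  cx /= na; cy /= na; cz /= na;
  std::vector<double> x(na), y(na), z(na);
  for (int i = 0; i < na; ++i) {
    x[i] = coords(i,0) - cx; y[i] = coords(i,1) - cy; z[i] = coords(i,2) - cz;
  }
  // lookup table for 1 - C(z) on |z| in [0, zmax_tab]
  const double zmax_tab = 40.0;
  const int ntab = 4000;
  std::vector<double> burial(ntab + 1);
  for (int b = 0; b <= ntab; ++b) {
    const double az = zmax_tab * b / ntab;
    burial[b] = 1.0 - 1.0 / (1.0 + std::exp(alpha * (z0 - az)));
  }
  const double tab_scale = ntab / zmax_tab;

  NumericVector best_e_z(nz), best_rot_z(nz);
  double gbest = std::numeric_limits<double>::max();
  int gbest_rot = -1, gbest_z = -1;
  std::fill(best_e_z.begin(), best_e_z.end(),
            std::numeric_limits<double>::max());
  std::vector<double> za(na);
  for (int r = 0; r < nrot; ++r) {
    const double m20 = rots(r, 6), m21 = rots(r, 7), m22 = rots(r, 8);
    for (int i = 0; i < na; ++i)
      za[i] = m20 * x[i] + m21 * y[i] + m22 * z[i];
    for (int g = 0; g < nz; ++g) {
      const double zoff = zgrid[g];
      double e = 0.0;
      for (int i = 0; i < na; ++i) {
        double az = std::fabs(za[i] + zoff);
        if (az >= zmax_tab) continue;          // fully aqueous: burial 0
        const double t = az * tab_scale;
        const int b = (int)t;
        const double w = t - b;
        e += u[i] * (burial[b] * (1.0 - w) + burial[b + 1] * w);
      }
      if (e < best_e_z[g]) { best_e_z[g] = e; best_rot_z[g] = r + 1; }
      if (e < gbest) { gbest = e; gbest_rot = r; gbest_z = g; }
    }
  }
  return List::create(_["profile_energy"] = best_e_z,
                      _["profile_rot"] = best_rot_z,
                      _["best_energy"] = gbest,
                      _["best_rot"] = gbest_rot + 1,
                      _["best_z"] = zgrid[gbest_z]);
}

// Residue-environment score: for each residue, the sum of tabulated
// Lennard-Jones + hydrophobicity pair terms (no Coulomb) between its atoms
// and atoms of other residues within the cutoff.  Each qualifying pair
// contributes its full term to both residues.
// [[Rcpp::export]]
NumericVector cpp_env_scores(NumericMatrix coords, List pairs,
                             IntegerVector resid, int nres,
                             NumericMatrix ftab, double table_cutoff,
                             double env_cutoff) {
  PairData pd = unpack_pairs(pairs);
  NumericVector dummy_diel = NumericVector::create(2.0, 10.0, 1.0, 80.0);
  Kernel K = make_kernel(ftab, table_cutoff, dummy_diel);
  const int na = coords.nrow(), np = pd.i.size();
  std::vector<double> xyz(3 * na);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) xyz[3 * i + k] = coords(i, k);
  const double ec2 = env_cutoff * env_cutoff;
  NumericVector score(nres);
  for (int p = 0; p < np; ++p) {
    const int ri = resid[pd.i[p]] - 1, rj = resid[pd.j[p]] - 1;
    if (ri == rj) continue;
    const double* a = xyz.data() + 3 * pd.i[p];
    const double* b = xyz.data() + 3 * pd.j[p];
    const double dx = a[0]-b[0], dy = a[1]-b[1], dz = a[2]-b[2];
    const double d2 = dx*dx + dy*dy + dz*dz;
    if (d2 >= ec2) continue;
    const double e = K.pair_energy(d2, pd.tp[p], 0.0);
    score[ri] += e;
    score[rj] += e;
  }
  return score;
}

// ---------------------------------------------------------------------------
// Full sampling run (hydrophobic environment): the per-step loop lives here
// so the archive, memoization and clash resampling carry no interpreter
// overhead.  Deterministic: own xoshiro256** RNG seeded from R.

namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion
    for (int k = 0; k < 4; ++k) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[k] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

inline uint64_t hash_states(const int* st, int n) {
  uint64_t h = 1469598103934665603ULL;
  for (int k = 0; k < n; ++k) {
    h ^= (uint64_t)st[k];
    h *= 1099511628211ULL;
  }
  return h;
}

} // namespace

typedef std::unordered_map<uint64_t, std::pair<double, char> > EnergyMemo;

// Persistent energy memo (state-string hash -> energy, clash flag) that a
// caller can share across runs on the same sequence: energies are
// seed-independent, so re-scans with different master seeds reuse them.
// [[Rcpp::export]]
SEXP cpp_new_memo() {
  Rcpp::XPtr<EnergyMemo> ptr(new EnergyMemo(), true);
  return ptr;
}

// [[Rcpp::export]]
double cpp_memo_size(SEXP memo) {
  Rcpp::XPtr<EnergyMemo> ptr(memo);
  return (double)ptr->size();
}

// [[Rcpp::export]]
List cpp_run_peplook(NumericVector state_phi, NumericVector state_psi,
                     List zmat, List pairs, NumericMatrix comb,
                     double short_cut, NumericVector w,
                     IntegerVector ca_idx, NumericVector reach,
                     double cutoff, NumericVector dielectric,
                     IntegerVector resid_of_atom,
                     int n_res, int m_per_step, int total_steps,
                     double fav_frac, double unf_frac,
                     int couples_per_update, double boost, double damp,
                     double prob_floor, int archive_size,
                     double clash_floor, int max_retries,
                     double seed, SEXP memo_ptr) {
  IntegerVector refa = zmat["refa"], refb = zmat["refb"], refc = zmat["refc"];
  NumericVector bnd = zmat["bond"], ang = zmat["ang"], doff = zmat["doff"];
  IntegerVector dtype = zmat["dtype"], dres = zmat["dres"];
  PairData pd = unpack_pairs(pairs);
  std::vector<float> comb_store;
  Kernel K = make_kernel_comb(comb, comb_store, cutoff, short_cut,
                              dielectric);
  const int natoms = refa.size();
  const int npair = (int)pd.i.size();
  const int nstates = state_phi.size();
  const double clash2 = clash_floor * clash_floor;

  Rng rng((uint64_t)seed);

  std::vector<double> probs((size_t)nstates * n_res, 1.0 / nstates);
  std::vector<double> cdf((size_t)nstates * n_res);
  std::vector<double> xyz(3 * natoms), occ(natoms);
  NumericVector phi(n_res), psi(n_res);

  // memo: state-hash -> (energy, clash); either run-local or shared
  EnergyMemo local_memo;
  EnergyMemo& memo = Rf_isNull(memo_ptr)
    ? local_memo : *Rcpp::XPtr<EnergyMemo>(memo_ptr);
  if (memo.empty()) memo.reserve((size_t)m_per_step * total_steps / 4);

  // archive: sorted by energy, dedup by hash
  struct Entry { double e; uint64_t h; std::vector<int> st; };
  std::vector<Entry> archive;
  archive.reserve(archive_size + 1);

  std::vector<int> st(n_res);
  std::vector<std::vector<int> > step_states((size_t)m_per_step,
                                             std::vector<int>(n_res));
  std::vector<double> step_e(m_per_step);
  std::vector<double> prime_trace(total_steps);

  auto evaluate = [&](const int* s_, double& e_out, char& clash_out,
                      uint64_t& h_out) {
    const uint64_t h = hash_states(s_, n_res);
    h_out = h;
    auto it = memo.find(h);
    if (it != memo.end()) {
      e_out = it->second.first;
      clash_out = it->second.second;
      return false;               // not new
    }
    for (int r = 0; r < n_res; ++r) {
      phi[r] = state_phi[s_[r] - 1];
      psi[r] = state_psi[s_[r] - 1];
    }
    build_coords_impl(refa, refb, refc, bnd, ang, dtype, dres, doff,
                      phi, psi, xyz.data());
    if (clash_scan(pd, xyz.data(), &ca_idx[0], &reach[0], clash_floor)) {
      // clashing structures never reach the archive and rank at the very
      // bottom; their exact wall energy is irrelevant
      e_out = 1e9;
      clash_out = 1;
      memo.emplace(h, std::make_pair(1e9, (char)1));
      return true;
    }
    std::fill(occ.begin(), occ.end(), 0.0);
    double md2 = std::numeric_limits<double>::max();
    double e = pair_sweep(pd, K, xyz.data(), &ca_idx[0], &reach[0],
                          cutoff, occ.data(), md2);
    for (int a2 = 0; a2 < natoms; ++a2)
      e += w[a2] * std::max(0.0, 1.0 - occ[a2]);
    e_out = e;
    clash_out = 0;
    memo.emplace(h, std::make_pair(e, (char)0));
    return true;                  // newly evaluated
  };

  for (int step = 0; step < total_steps; ++step) {
    // per-position cumulative distributions
    for (int p = 0; p < n_res; ++p) {
      double acc = 0.0;
      for (int s2 = 0; s2 < nstates; ++s2) {
        acc += probs[(size_t)p * nstates + s2];
        cdf[(size_t)p * nstates + s2] = acc;
      }
      cdf[(size_t)p * nstates + nstates - 1] = 1.0;
    }
    for (int m = 0; m < m_per_step; ++m) {
      double e = 0.0; char clash = 0; uint64_t h = 0;
      for (int attempt = 0; attempt <= max_retries; ++attempt) {
        for (int r = 0; r < n_res; ++r) {
          const double u = rng.unif();
          const double* c0 = cdf.data() + (size_t)r * nstates;
          int lo = 0, hi = nstates - 1;
          while (lo < hi) {
            const int mid = (lo + hi) / 2;
            if (c0[mid] < u) lo = mid + 1; else hi = mid;
          }
          st[r] = lo + 1;
        }
        const bool fresh = evaluate(st.data(), e, clash, h);
        if (!clash) break;
        (void)fresh;
      }
      step_states[m] = st;
      step_e[m] = e;
      // archive candidate (dedup by hash)
      bool have = false;
      for (size_t a2 = 0; a2 < archive.size(); ++a2)
        if (archive[a2].h == h) { have = true; break; }
      if (!have) {
        if ((int)archive.size() < archive_size ||
            e < archive.back().e) {
          Entry en; en.e = e; en.h = h; en.st = st;
          archive.insert(std::upper_bound(
              archive.begin(), archive.end(), en,
              [](const Entry& x, const Entry& y) { return x.e < y.e; }), en);
          if ((int)archive.size() > archive_size) archive.pop_back();
        }
      }
    }
    prime_trace[step] = archive.empty() ? NA_REAL : archive.front().e;

    // --- probability update: tier-exclusive couples ---
    std::vector<int> ord(m_per_step);
    for (int m = 0; m < m_per_step; ++m) ord[m] = m;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a2, int b2) { return step_e[a2] < step_e[b2]; });
    int nfav = std::max(1, (int)(m_per_step * fav_frac));
    int nunf = std::max(1, (int)(m_per_step * unf_frac));
    std::unordered_map<int, double> fav_best, unf_worst;
    for (int k = 0; k < nfav; ++k) {
      const int row = ord[k];
      for (int r = 0; r < n_res; ++r) {
        const int code = r * nstates + step_states[row][r] - 1;
        auto it = fav_best.find(code);
        if (it == fav_best.end() || step_e[row] < it->second)
          fav_best[code] = step_e[row];
      }
    }
    for (int k = 0; k < nunf; ++k) {
      const int row = ord[m_per_step - 1 - k];
      for (int r = 0; r < n_res; ++r) {
        const int code = r * nstates + step_states[row][r] - 1;
        auto it = unf_worst.find(code);
        if (it == unf_worst.end() || step_e[row] > it->second)
          unf_worst[code] = step_e[row];
      }
    }
    std::vector<std::pair<double, int> > only_f, only_u;
    for (auto& kv : fav_best)
      if (unf_worst.find(kv.first) == unf_worst.end())
        only_f.push_back(std::make_pair(kv.second, kv.first));
    for (auto& kv : unf_worst)
      if (fav_best.find(kv.first) == fav_best.end())
        only_u.push_back(std::make_pair(-kv.second, kv.first));
    std::sort(only_f.begin(), only_f.end());
    std::sort(only_u.begin(), only_u.end());
    const int nf = std::min((int)only_f.size(), couples_per_update);
    const int nu = std::min((int)only_u.size(), couples_per_update);
    for (int k = 0; k < nf; ++k) {
      const int code = only_f[k].second;
      probs[(size_t)(code / nstates) * nstates + code % nstates] *= boost;
    }
    for (int k = 0; k < nu; ++k) {
      const int code = only_u[k].second;
      probs[(size_t)(code / nstates) * nstates + code % nstates] *= damp;
    }
    // water-fill renormalization with floor
    for (int p = 0; p < n_res; ++p) {
      double* col = probs.data() + (size_t)p * nstates;
      double tot = 0;
      for (int s2 = 0; s2 < nstates; ++s2) tot += col[s2];
      int nlow = 0; double freesum = 0;
      for (int s2 = 0; s2 < nstates; ++s2) {
        col[s2] /= tot;
        if (col[s2] < prob_floor) ++nlow; else freesum += col[s2];
      }
      if (nlow > 0) {
        const double scale = (1.0 - prob_floor * nlow) / freesum;
        for (int s2 = 0; s2 < nstates; ++s2)
          col[s2] = col[s2] < prob_floor ? prob_floor : col[s2] * scale;
      }
    }
  }

  const int na_out = (int)archive.size();
  IntegerMatrix out_states(na_out, n_res);
  NumericVector out_e(na_out);
  for (int k = 0; k < na_out; ++k) {
    out_e[k] = archive[k].e;
    for (int r = 0; r < n_res; ++r) out_states(k, r) = archive[k].st[r];
  }
  NumericMatrix out_probs(nstates, n_res);
  for (int p = 0; p < n_res; ++p)
    for (int s2 = 0; s2 < nstates; ++s2)
      out_probs(s2, p) = probs[(size_t)p * nstates + s2];
  return List::create(_["states"] = out_states, _["energy"] = out_e,
                      _["prime_trace"] = NumericVector(prime_trace.begin(),
                                                       prime_trace.end()),
                      _["probabilities"] = out_probs,
                      _["n_unique_evaluated"] = (double)memo.size());
}
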