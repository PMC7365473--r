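#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Screened-Coulomb pair sums between two planar point-charge sets.
// Charges in units of e, coordinates in nm, energies in kBT.
// kernel: q_i * q_j * (lB / r) * exp(-r / lDH); lDH = Inf turns screening off.
// Pairs with r > cutoff contribute 0 (cutoff = Inf for the literal sum).
// Coincident charged sites (r < 1e-12 nm, both charges non-zero) are an
// error: the point-charge kernel is singular there.

static inline double pair_kernel(double q, double r, double lB, double inv_ldh) {
  return q * lB * std::exp(-r * inv_ldh) / r;
}

static bool is_sorted_asc(const NumericVector& z) {
  for (int i = 1; i < z.size(); ++i) if (z[i] < z[i - 1]) return false;
  return true;
}

// [[Rcpp::export]]
double cpp_pair_energy(NumericVector ax, NumericVector az, NumericVector aq,
                       NumericVector bx, NumericVector bz, NumericVector bq,
                       double lB, double lDH, double cutoff) {
  const int na = ax.size(), nb = bx.size();
  const double inv_ldh = std::isfinite(lDH) ? 1.0 / lDH : 0.0;
  const bool use_cut = std::isfinite(cutoff);
  const double cut2 = cutoff * cutoff;
  // with a sorted fixed chain, restrict each partner site to the axial
  // window |dz| <= cutoff by binary search
  const bool windowed = use_cut && is_sorted_asc(az);

  double axmin = R_PosInf, axmax = R_NegInf;
  double azmin = R_PosInf, azmax = R_NegInf;
  for (int i = 0; i < na; ++i) {
    if (ax[i] < axmin) axmin = ax[i];
    if (ax[i] > axmax) axmax = ax[i];
    if (az[i] < azmin) azmin = az[i];
    if (az[i] > azmax) azmax = az[i];
  }

  const double* azp = az.begin();
  double e = 0.0;
  for (int j = 0; j < nb; ++j) {
    const double qj = bq[j];
    if (qj == 0.0) continue;
    const double xj = bx[j], zj = bz[j];
    if (use_cut) {  // whole-site reject: closest approach to A's bounding box
      double dx = (xj < axmin) ? axmin - xj : (xj > axmax ? xj - axmax : 0.0);
      double dz = (zj < azmin) ? azmin - zj : (zj > azmax ? zj - azmax : 0.0);
      if (dx * dx + dz * dz > cut2) continue;
    }
    int i0 = 0, i1 = na;
    if (windowed) {
      i0 = std::lower_bound(azp, azp + na, zj - cutoff) - azp;
      i1 = std::upper_bound(azp + i0, azp + na, zj + cutoff) - azp;
    }
    double ej = 0.0;
    for (int i = i0; i < i1; ++i) {
      const double qi = aq[i];
      if (qi == 0.0) continue;
      const double dx = ax[i] - xj, dz = az[i] - zj;
      const double r2 = dx * dx + dz * dz;
      if (use_cut && r2 > cut2) continue;
      if (r2 < 1e-24)
        stop("coincident charged sites between the two chains (pair %d, %d)",
             i + 1, j + 1);
      ej += pair_kernel(qi, std::sqrt(r2), lB, inv_ldh);
    }
    e += qj * ej;
  }
  return e;
}

// Per-site energies of chain B against the whole of chain A (same kernel and
// cutoff semantics as cpp_pair_energy); used to decompose straight/bent parts.
// [[Rcpp::export]]
NumericVector cpp_site_energies(NumericVector ax, NumericVector az, NumericVector aq,
                                NumericVector bx, NumericVector bz, NumericVector bq,
                                double lB, double lDH, double cutoff) {
  const int na = ax.size(), nb = bx.size();
  const double inv_ldh = std::isfinite(lDH) ? 1.0 / lDH : 0.0;
  const bool use_cut = std::isfinite(cutoff);
  const double cut2 = cutoff * cutoff;
  const bool windowed = use_cut && is_sorted_asc(az);
  const double* azp = az.begin();
  NumericVector out(nb);

  for (int j = 0; j < nb; ++j) {
    const double qj = bq[j];
    if (qj == 0.0) continue;
    const double xj = bx[j], zj = bz[j];
    int i0 = 0, i1 = na;
    if (windowed) {
      i0 = std::lower_bound(azp, azp + na, zj - cutoff) - azp;
      i1 = std::upper_bound(azp + i0, azp + na, zj + cutoff) - azp;
    }
    double e = 0.0;
    for (int i = i0; i < i1; ++i) {
      const double qi = aq[i];
      if (qi == 0.0) continue;
      const double dx = ax[i] - xj, dz = az[i] - zj;
      const double r2 = dx * dx + dz * dz;
      if (use_cut && r2 > cut2) continue;
      if (r2 < 1e-24)
        stop("coincident charged sites between the two chains (pair %d, %d)",
             i + 1, j + 1);
      e += pair_kernel(qi, std::sqrt(r2), lB, inv_ldh);
    }
    out[j] = qj * e;
  }
  return out;
}
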