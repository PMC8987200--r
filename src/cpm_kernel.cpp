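// Monte Carlo kernel for the 2D Cellular Potts Model.
//
// The lattice is an integer matrix with dim (width, height); element (x, z)
// in 0-based coordinates lives at column-major index x + z*W.  Label codes:
// MEDIUM = 0, SUBSTRATE = -1, WALL = -2, cells are positive integers.
// Per-cell caches (area, boundary-link count, substrate-adhesion pixel
// count, coordinate sums for the centroid) are indexed by cell id and
// updated in place; substrate and wall are frozen and never take part in a
// copy, so the substrate-adjacency mask is static geometry.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

#define MEDIUM 0
#define SUBSTRATE (-1)
#define WALL (-2)

// first 4 offsets: von Neumann (order 1); all 8: Moore (order 2)
static const int DX[8] = {1, -1, 0, 0, 1, 1, -1, -1};
static const int DZ[8] = {0, 0, 1, -1, 1, -1, 1, -1};

static inline int n_offsets(int order) { return order >= 2 ? 8 : 4; }

// contact energy J for one unordered neighbour pair: lambda_adh_cc between
// unlike cells, lambda_adh_cs between a cell and the substrate, zero when
// either site is medium or wall, zero within one cell.
static inline double Jpair(int u, int v, double jcc, double jcs) {
  if (u >= 1) {
    if (v >= 1) return (u == v) ? 0.0 : jcc;
    if (v == SUBSTRATE) return jcs;
    return 0.0;
  }
  if (u == SUBSTRATE && v >= 1) return jcs;
  return 0.0;
}

// Energy change of copying label `a` onto site (xj, zj) currently holding
// label `b` (a != b, both non-frozen, site strictly interior).  Only the
// terms of cells a and b and the contact links incident on the target site
// change; a cell shrinking to area 0 loses its area and perimeter terms
// entirely.
static double site_delta(const int *lab, int W,
                         const double *area, const double *bnd,
                         int xj, int zj, int a, int b,
                         double la, double lc, double jcc, double jcs,
                         double A0, int per_order, int con_order,
                         int *dLa_out, int *dLb_out) {
  double dE = 0.0;

  if (a >= 1) {
    double Aa = area[a - 1];
    dE += la * ((Aa + 1 - A0) * (Aa + 1 - A0) - (Aa - A0) * (Aa - A0));
  }
  if (b >= 1) {
    double Ab = area[b - 1];
    if (Ab <= 1.0)  // cell death: its (A - A0)^2 term is removed outright
      dE += -la * (1.0 - A0) * (1.0 - A0);
    else
      dE += la * ((Ab - 1 - A0) * (Ab - 1 - A0) - (Ab - A0) * (Ab - A0));
  }

  // Boundary-link changes are confined to cells a and b: a link from the
  // target site to any third label is "unlike" both before and after.
  const int nP = n_offsets(per_order);
  int ka = 0, kb = 0;
  for (int t = 0; t < nP; ++t) {
    int l = lab[(xj + DX[t]) + (zj + DZ[t]) * W];
    if (l == a) ++ka;
    if (l == b) ++kb;
  }
  int dLa = (nP - ka) - ka;
  int dLb = kb - (nP - kb);
  if (a >= 1) {
    double La = bnd[a - 1];
    dE += lc * ((La + dLa) * (La + dLa) - La * La);
  }
  if (b >= 1) {
    double Lb = bnd[b - 1];
    double Lb_after = (area[b - 1] <= 1.0) ? 0.0 : (Lb + dLb);
    dE += lc * (Lb_after * Lb_after - Lb * Lb);
  }

  const int nC = n_offsets(con_order);
  for (int t = 0; t < nC; ++t) {
    int l = lab[(xj + DX[t]) + (zj + DZ[t]) * W];
    dE += Jpair(a, l, jcc, jcs) - Jpair(b, l, jcc, jcs);
  }

  *dLa_out = dLa;
  *dLb_out = dLb;
  return dE;
}

// [[Rcpp::export]]
double cpm_delta_site(IntegerMatrix labels, NumericVector area,
                      NumericVector bnd, int xj, int zj, int a,
                      double lambda_area, double lambda_cont,
                      double j_cc, double j_cs, double A0,
                      int perimeter_order, int contact_order) {
  int W = labels.nrow();
  int b = labels(xj, zj);
  int dLa, dLb;
  return site_delta(INTEGER(labels), W, REAL(area), REAL(bnd), xj, zj, a, b,
                    lambda_area, lambda_cont, j_cc, j_cs, A0,
                    perimeter_order, contact_order, &dLa, &dLb);
}

// Run `n_attempts` elementary steps, mutating the label matrix and the
// per-cell caches in place.  Uses R's RNG (seed via set.seed in R).
// [[Rcpp::export]]
List cpm_run_steps(IntegerMatrix labels, NumericVector area,
                   NumericVector bnd, NumericVector ns,
                   NumericVector sumx, NumericVector sumz,
                   LogicalVector subadj, int n_attempts,
                   double lambda_area, double lambda_cont,
                   double j_cc, double j_cs, double A0, double temperature,
                   int perimeter_order, int contact_order) {
  const int W = labels.nrow(), H = labels.ncol();
  const int N = W * H;
  int *lab = INTEGER(labels);
  double *ar = REAL(area), *bd = REAL(bnd), *nsv = REAL(ns);
  double *sx = REAL(sumx), *sz = REAL(sumz);
  int *sa = LOGICAL(subadj);

  RNGScope scope;
  double attempted = 0, accepted = 0, same = 0, frozen = 0;
  double de_sum = 0.0;

  for (int it = 0; it < n_attempts; ++it) {
    ++attempted;
    int idx = (int)(unif_rand() * N);
    if (idx >= N) idx = N - 1;
    int li = lab[idx];
    if (li == WALL || li == SUBSTRATE) { ++frozen; continue; }  // frozen source
    int xi = idx % W, zi = idx / W;
    int d = (int)(unif_rand() * 4.0);
    if (d > 3) d = 3;
    // any non-wall source is interior, so the neighbour is in bounds
    int xj = xi + DX[d], zj = zi + DZ[d];
    int jdx = xj + zj * W;
    int lj = lab[jdx];
    if (lj == WALL || lj == SUBSTRATE) { ++frozen; continue; }  // frozen target
    if (lj == li) { ++same; continue; }

    int dLa, dLb;
    double dE = site_delta(lab, W, ar, bd, xj, zj, li, lj,
                           lambda_area, lambda_cont, j_cc, j_cs, A0,
                           perimeter_order, contact_order, &dLa, &dLb);
    bool acc = (dE <= 0.0) || (unif_rand() < std::exp(-dE / temperature));
    if (!acc) continue;

    ++accepted;
    de_sum += dE;
    lab[jdx] = li;
    if (li >= 1) {
      ar[li - 1] += 1.0;
      bd[li - 1] += dLa;
      sx[li - 1] += xj;
      sz[li - 1] += zj;
      if (sa[jdx]) nsv[li - 1] += 1.0;
    }
    if (lj >= 1) {
      ar[lj - 1] -= 1.0;
      bd[lj - 1] += dLb;
      sx[lj - 1] -= xj;
      sz[lj - 1] -= zj;
      if (sa[jdx]) nsv[lj - 1] -= 1.0;
      if (ar[lj - 1] <= 0.0) {  // shrunk to nothing: clear the record
        ar[lj - 1] = 0.0; bd[lj - 1] = 0.0; nsv[lj - 1] = 0.0;
        sx[lj - 1] = 0.0; sz[lj - 1] = 0.0;
      }
    }
  }

  return List::create(_["attempted"] = attempted,
                      _["accepted"] = accepted,
                      _["rejected_same_label"] = same,
                      _["rejected_frozen"] = frozen,
                      _["delta_e"] = de_sum);
}
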