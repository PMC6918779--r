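#include <Rcpp.h>
using namespace Rcpp;

// Minimum-image displacement on a periodic interval of length L.
static inline double minimg(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// Core geometry + gradient kernel for the vertex-model energy
//   E = sum_a K/2 (A_a - A0_a)^2 + sum_<ij> Lambda l_ij + sum_a Gamma/2 L_a^2
// on a flat periodic box (Lx, Ly).  Junction tension is accumulated as
// Lambda/2 per directed edge (each junction appears in exactly two cell
// loops on the torus, so it is counted once in total).
//
// idx: 0-based flat concatenation of counter-clockwise cell loops
// ptr: 0-based offsets into idx, length n_cells + 1
// A0 : per-cell target areas
//
// Returns per-cell area/perimeter, per-vertex forces (-dE/dr), per-flat-edge
// minimum-image lengths, the generalised gradients dE/dLx, dE/dLy under
// uniform dilation of each axis (used for the global drag dynamics), and E.
// [[Rcpp::export]]
List vm_kernel(NumericMatrix v, IntegerVector idx, IntegerVector ptr,
               double Lx, double Ly,
               double K, double Lambda, double Gamma,
               NumericVector A0) {
  const int nc = ptr.size() - 1;
  const int nv = v.nrow();
  const int nflat = idx.size();
  if (A0.size() != nc) stop("A0 must have one entry per cell");

  NumericVector area(nc), perim(nc), fx(nv), fy(nv), elen(nflat);
  double gLx = 0.0, gLy = 0.0, energy = 0.0;

  std::vector<double> ux, uy, ex, ey, el;

  for (int c = 0; c < nc; ++c) {
    const int s = ptr[c], e = ptr[c + 1], n = e - s;
    if (n < 3) stop("cell %d has fewer than 3 vertices", c + 1);
    ux.assign(n, 0.0); uy.assign(n, 0.0);
    ex.assign(n, 0.0); ey.assign(n, 0.0); el.assign(n, 0.0);

    ux[0] = v(idx[s], 0);
    uy[0] = v(idx[s], 1);
    for (int k = 0; k < n; ++k) {
      const int i = idx[s + k], j = idx[s + (k + 1) % n];
      const double dx = minimg(v(j, 0) - v(i, 0), Lx);
      const double dy = minimg(v(j, 1) - v(i, 1), Ly);
      const double l = std::sqrt(dx * dx + dy * dy);
      if (l < 1e-12) stop("zero-length edge in cell %d", c + 1);
      ex[k] = dx; ey[k] = dy; el[k] = l;
      elen[s + k] = l;
      if (k < n - 1) { ux[k + 1] = ux[k] + dx; uy[k + 1] = uy[k] + dy; }
    }

    double A = 0.0, P = 0.0;
    for (int k = 0; k < n; ++k) {
      const int k1 = (k + 1) % n;
      A += ux[k] * uy[k1] - ux[k1] * uy[k];
      P += el[k];
    }
    A *= 0.5;
    area[c] = A; perim[c] = P;

    const double ka = K * (A - A0[c]);       // dE/dA for this cell
    const double coef = 0.5 * Lambda + Gamma * P; // dE/dl per directed edge
    energy += 0.5 * ka * (A - A0[c]) + 0.5 * Gamma * P * P + 0.5 * Lambda * P;
    gLx += ka * A / Lx;
    gLy += ka * A / Ly;

    for (int k = 0; k < n; ++k) {
      const int i = idx[s + k];
      const int km = (k + n - 1) % n, k1 = (k + 1) % n;
      // shoelace gradient (unwrap offsets are constant, so d/dr is exact)
      fx[i] -= ka * 0.5 * (uy[k1] - uy[km]);
      fy[i] -= ka * 0.5 * (ux[km] - ux[k1]);
      // edge k runs i_k -> i_{k+1}
      const int j = idx[s + k1];
      const double uxk = ex[k] / el[k], uyk = ey[k] / el[k];
      fx[i] += coef * uxk; fy[i] += coef * uyk;
      fx[j] -= coef * uxk; fy[j] -= coef * uyk;
      gLx += coef * ex[k] * ex[k] / (el[k] * Lx);
      gLy += coef * ey[k] * ey[k] / (el[k] * Ly);
    }
  }

  return List::create(_["area"] = area, _["perim"] = perim,
                      _["fx"] = fx, _["fy"] = fy, _["elen"] = elen,
                      _["gLx"] = gLx, _["gLy"] = gLy,
                      _["energy"] = energy);
}
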