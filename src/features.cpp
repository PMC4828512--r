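#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Integral-volume lookup with zero guard below the origin.
static inline double ivol_at(const double *I, int nx, int ny, int nz,
                             int x, int y, int z) {
  if (x < 0 || y < 0 || z < 0) return 0.0;
  return I[x + (size_t)nx * (y + (size_t)ny * z)];
}

// Sum of the box [x0,x1]x[y0,y1]x[z0,z1] (inclusive) from an inclusive
// 3D prefix-sum array.
static inline double box_sum(const double *I, int nx, int ny, int nz,
                             int x0, int x1, int y0, int y1, int z0, int z1) {
  double s = ivol_at(I, nx, ny, nz, x1, y1, z1)
           - ivol_at(I, nx, ny, nz, x0 - 1, y1, z1)
           - ivol_at(I, nx, ny, nz, x1, y0 - 1, z1)
           - ivol_at(I, nx, ny, nz, x1, y1, z0 - 1)
           + ivol_at(I, nx, ny, nz, x0 - 1, y0 - 1, z1)
           + ivol_at(I, nx, ny, nz, x0 - 1, y1, z0 - 1)
           + ivol_at(I, nx, ny, nz, x1, y0 - 1, z0 - 1)
           - ivol_at(I, nx, ny, nz, x0 - 1, y0 - 1, z0 - 1);
  return s;
}

// Haar-like responses from an integral volume over the edge-padded image.
// `blocks` has one row per weighted block term:
//   (feature index 0-based, xlo, xhi, ylo, yhi, zlo, zhi, weight)
// with offsets relative to the centre voxel, inclusive. The response of a
// feature is sum_b weight_b * mean(block_b).
// [[Rcpp::export]]
NumericMatrix haar_eval_cpp(NumericVector ivol, IntegerVector pdim,
                            IntegerMatrix vox, int pad,
                            NumericMatrix blocks, int n_feat) {
  const int nx = pdim[0], ny = pdim[1], nz = pdim[2];
  const double *I = REAL(ivol);
  const int nv = vox.nrow(), nb = blocks.nrow();
  NumericMatrix out(nv, n_feat);

  std::vector<int> bf(nb), bx0(nb), bx1(nb), by0(nb), by1(nb), bz0(nb), bz1(nb);
  std::vector<double> bw(nb), bn(nb);
  for (int b = 0; b < nb; b++) {
    bf[b]  = (int)blocks(b, 0);
    bx0[b] = (int)blocks(b, 1); bx1[b] = (int)blocks(b, 2);
    by0[b] = (int)blocks(b, 3); by1[b] = (int)blocks(b, 4);
    bz0[b] = (int)blocks(b, 5); bz1[b] = (int)blocks(b, 6);
    bw[b]  = blocks(b, 7);
    bn[b]  = (double)(bx1[b] - bx0[b] + 1) * (by1[b] - by0[b] + 1) *
             (bz1[b] - bz0[b] + 1);
  }
  for (int v = 0; v < nv; v++) {
    const int cx = vox(v, 0) + pad, cy = vox(v, 1) + pad, cz = vox(v, 2) + pad;
    double *row = &out(v, 0); // column-major: use out(v, f) accessor instead
    (void)row;
    for (int b = 0; b < nb; b++) {
      double s = box_sum(I, nx, ny, nz,
                         cx + bx0[b], cx + bx1[b],
                         cy + by0[b], cy + by1[b],
                         cz + bz0[b], cz + bz1[b]);
      out(v, bf[b]) += bw[b] * s / bn[b];
    }
  }
  return out;
}

static void glcm_stats(const std::vector<double> &P, int G, double *stats) {
  // energy, contrast, correlation, inverse difference moment
  double energy = 0.0, contrast = 0.0, idm = 0.0;
  std::vector<double> pi(G, 0.0), pj(G, 0.0);
  for (int i = 0; i < G; i++)
    for (int j = 0; j < G; j++) {
      double p = P[i + G * j];
      energy += p * p;
      contrast += (double)(i - j) * (i - j) * p;
      idm += p / (1.0 + (double)(i - j) * (i - j));
      pi[i] += p;
      pj[j] += p;
    }
  double mi = 0.0, mj = 0.0;
  for (int i = 0; i < G; i++) { mi += i * pi[i]; mj += i * pj[i]; }
  double vi = 0.0, vj = 0.0;
  for (int i = 0; i < G; i++) {
    vi += (i - mi) * (i - mi) * pi[i];
    vj += (i - mj) * (i - mj) * pj[i];
  }
  double corr = 0.0, sd = std::sqrt(vi) * std::sqrt(vj);
  if (sd > 0) {
    double cov = 0.0;
    for (int i = 0; i < G; i++)
      for (int j = 0; j < G; j++)
        cov += (i - mi) * (j - mj) * P[i + G * j];
    corr = cov / sd;
  }
  stats[0] = energy; stats[1] = contrast; stats[2] = corr; stats[3] = idm;
}

// Haralick features on the mean-projection subimages of cubic neighbourhoods.
// For each neighbourhood size n in `sizes` and each projection axis, the GLCM
// (G levels, min-max quantisation per subimage, offset (1,0) symmetrised) is
// accumulated and (energy, contrast, correlation, IDM) computed.
// Output column order: size-major, then projection axis (x,y,z), then statistic.
// [[Rcpp::export]]
NumericMatrix haralick_eval_cpp(NumericVector pvol, IntegerVector pdim,
                                IntegerMatrix vox, int pad,
                                IntegerVector sizes, int G) {
  const int nx = pdim[0], ny = pdim[1];
  const double *V = REAL(pvol);
  const int nv = vox.nrow(), ns = sizes.size();
  NumericMatrix out(nv, ns * 3 * 4);
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;

  int nmax = 0;
  for (int s = 0; s < ns; s++) nmax = std::max(nmax, (int)sizes[s]);
  std::vector<double> proj(nmax * nmax);
  std::vector<int> q(nmax * nmax);
  std::vector<double> P(G * G);
  double stats[4];

  for (int v = 0; v < nv; v++) {
    const int cx = vox(v, 0) + pad, cy = vox(v, 1) + pad, cz = vox(v, 2) + pad;
    int col = 0;
    for (int s = 0; s < ns; s++) {
      const int n = sizes[s], r = (n - 1) / 2;
      const size_t base = (cx - r) * sx + (cy - r) * sy + (cz - r) * sz;
      for (int axis = 0; axis < 3; axis++) {
        // project by averaging along `axis`; (u,v) = remaining axes in order
        size_t su, sv, sa;
        if (axis == 0)      { sa = sx; su = sy; sv = sz; }
        else if (axis == 1) { sa = sy; su = sx; sv = sz; }
        else                { sa = sz; su = sx; sv = sy; }
        for (int iu = 0; iu < n; iu++)
          for (int iv = 0; iv < n; iv++) {
            double acc = 0.0;
            size_t off = base + iu * su + iv * sv;
            for (int ia = 0; ia < n; ia++) acc += V[off + ia * sa];
            proj[iu + n * iv] = acc / n;
          }
        // min-max quantisation to G levels (constant -> all level 0)
        double mn = proj[0], mx = proj[0];
        for (int k = 1; k < n * n; k++) {
          if (proj[k] < mn) mn = proj[k];
          if (proj[k] > mx) mx = proj[k];
        }
        if (mx > mn) {
          for (int k = 0; k < n * n; k++) {
            int lev = (int)std::floor((proj[k] - mn) / (mx - mn) * G);
            q[k] = lev >= G ? G - 1 : lev;
          }
        } else {
          for (int k = 0; k < n * n; k++) q[k] = 0;
        }
        // symmetrised GLCM at offset (1,0) in (u,v) coordinates
        std::fill(P.begin(), P.end(), 0.0);
        for (int iu = 0; iu + 1 < n; iu++)
          for (int iv = 0; iv < n; iv++) {
            int a = q[iu + n * iv], b = q[iu + 1 + n * iv];
            P[a + G * b] += 1.0;
            P[b + G * a] += 1.0;
          }
        double tot = 2.0 * (n - 1) * n;
        for (int k = 0; k < G * G; k++) P[k] /= tot;
        glcm_stats(P, G, stats);
        for (int k = 0; k < 4; k++) out(v, col + k) = stats[k];
        col += 4;
      }
    }
  }
  return out;
}
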