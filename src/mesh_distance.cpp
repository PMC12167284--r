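#include <Rcpp.h>
using namespace Rcpp;

// Closest-point-on-triangle (Ericson, Real-Time Collision Detection, 5.1.5).
// Returns squared distance from p to triangle (a, b, c).
static inline double pointTriDist2(const double p[3], const double a[3],
                                   const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) q[k] = a[k] + v * ab[k];
      } else {
        double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
        } else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int k = 0; k < 3; ++k) q[k] = a[k] + w * ac[k];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k = 0; k < 3; ++k) q[k] = b[k] + w * (c[k] - b[k]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int k = 0; k < 3; ++k) q[k] = a[k] + ab[k]*v + ac[k]*w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// Minimum Euclidean distance from each query point to a triangle mesh.
// V: n x 3 vertices, F: m x 3 one-based triangle indices.
// Brute force over triangles with a centroid/bounding-radius prune.
// [[Rcpp::export]]
NumericVector cpp_points_to_mesh_dist(NumericMatrix P, NumericMatrix V,
                                      IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  std::vector<double> tri(9 * (size_t)nf), cen(3 * (size_t)nf),
      rad(nf);
  for (int f = 0; f < nf; ++f) {
    for (int j = 0; j < 3; ++j) {
      int vi = F(f, j) - 1;
      for (int k = 0; k < 3; ++k) tri[9*(size_t)f + 3*j + k] = V(vi, k);
    }
    double cx = 0, cy = 0, cz = 0;
    for (int j = 0; j < 3; ++j) {
      cx += tri[9*(size_t)f + 3*j + 0];
      cy += tri[9*(size_t)f + 3*j + 1];
      cz += tri[9*(size_t)f + 3*j + 2];
    }
    cen[3*(size_t)f+0] = cx / 3; cen[3*(size_t)f+1] = cy / 3;
    cen[3*(size_t)f+2] = cz / 3;
    double r2 = 0;
    for (int j = 0; j < 3; ++j) {
      double dx = tri[9*(size_t)f+3*j+0] - cen[3*(size_t)f+0];
      double dy = tri[9*(size_t)f+3*j+1] - cen[3*(size_t)f+1];
      double dz = tri[9*(size_t)f+3*j+2] - cen[3*(size_t)f+2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double dx = p[0] - cen[3*(size_t)f+0];
      double dy = p[1] - cen[3*(size_t)f+1];
      double dz = p[2] - cen[3*(size_t)f+2];
      double dc = std::sqrt(dx*dx + dy*dy + dz*dz) - rad[f];
      if (dc > 0 && dc*dc >= best) continue;
      double d2 = pointTriDist2(p, &tri[9*(size_t)f],
                                &tri[9*(size_t)f+3], &tri[9*(size_t)f+6]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
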