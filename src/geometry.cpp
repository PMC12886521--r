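#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Area-coverage rasterization of a filled, rotated ellipse.
//
// Pixel convention: row/col, 0-based, pixel centers at integer coordinates;
// each pixel covers [r-0.5, r+0.5] x [c-0.5, c+0.5]. Coverage is estimated by
// an ss x ss subsample grid per pixel, so sub-pixel axis changes move the
// rendered boundary band smoothly.
//
// [[Rcpp::export]]
NumericMatrix ellipse_coverage_cpp(int nrow, int ncol,
                                   double center_r, double center_c,
                                   double semi_minor, double semi_major,
                                   double orientation_deg, int ss) {
  NumericMatrix out(nrow, ncol);
  const double th = orientation_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double a2 = semi_major * semi_major;
  const double b2 = semi_minor * semi_minor;
  // cheap reject radius: anything farther than semi_major + pixel diagonal is 0,
  // anything closer than semi_minor - diagonal is 1
  const double rmax = semi_major + 0.75;
  const double rmin = semi_minor - 0.75;
  const double inv_ss = 1.0 / ss;
  for (int r = 0; r < nrow; ++r) {
    for (int c = 0; c < ncol; ++c) {
      const double dr = r - center_r;
      const double dc = c - center_c;
      const double d = std::sqrt(dr * dr + dc * dc);
      if (d > rmax) { out(r, c) = 0.0; continue; }
      if (d < rmin) { out(r, c) = 1.0; continue; }
      int inside = 0;
      for (int i = 0; i < ss; ++i) {
        const double rr = dr + (i + 0.5) * inv_ss - 0.5;
        for (int j = 0; j < ss; ++j) {
          const double cc = dc + (j + 0.5) * inv_ss - 0.5;
          // rotate into ellipse frame: x along major axis (orientation measured
          // from the column axis, counter-clockwise in row/col space)
          const double x = cc * ct + rr * st;
          const double y = -cc * st + rr * ct;
          if (x * x / a2 + y * y / b2 <= 1.0) ++inside;
        }
      }
      out(r, c) = inside * inv_ss * inv_ss;
    }
  }
  return out;
}

static inline double bilinear(const NumericMatrix& m, double r, double c) {
  const int nr = m.nrow(), nc = m.ncol();
  if (r < 0.0 || c < 0.0 || r > nr - 1.0 || c > nc - 1.0) return 0.0;
  const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  const int r1 = (r0 + 1 < nr) ? r0 + 1 : r0;
  const int c1 = (c0 + 1 < nc) ? c0 + 1 : c0;
  const double fr = r - r0, fc = c - c0;
  return m(r0, c0) * (1 - fr) * (1 - fc) + m(r1, c0) * fr * (1 - fc) +
         m(r0, c1) * (1 - fr) * fc + m(r1, c1) * fr * fc;
}

// Separable Gaussian smoothing of a mask. The 0.5 level set of the smoothed
// 0/1 field localizes a straight edge exactly, independent of its orientation,
// which removes the staircase error of interpolating a hard binary mask.
// [[Rcpp::export]]
NumericMatrix smooth_mask_cpp(NumericMatrix mask, double sigma) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (sigma <= 0) return clone(mask);
  const int rad = (int)std::ceil(2.5 * sigma);
  std::vector<double> k(2 * rad + 1);
  double ksum = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += k[i + rad];
  }
  for (double& v : k) v /= ksum;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        s += k[i + rad] * mask(rr, c);
      }
      tmp(r, c) = s;
    }
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double s = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
        s += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = s;
    }
  return out;
}

// Chord lengths of a (possibly smoothed, in [0,1]) mask along lines through a
// fixed point.
//
// For each angle, the mask is sampled bilinearly at `step`-px spacing along the
// line through (center_r, center_c); the in-mask run containing the center is
// delimited by linear interpolation of the 0.5 crossing between successive
// samples. If the center itself is outside the mask (bilinear value < 0.5) the
// longest in-mask run on the line is used instead and `center_inside` is FALSE.
// `max_t` bounds the sweep radius (px); pass the mask's bounding radius around
// the center to avoid sampling empty space.
//
// [[Rcpp::export]]
List chord_lengths_cpp(NumericMatrix mask, double center_r, double center_c,
                       NumericVector angles_rad, double step, double max_t) {
  const int na = angles_rad.size();
  NumericVector len(na);
  const double diag = std::sqrt((double)mask.nrow() * mask.nrow() +
                                (double)mask.ncol() * mask.ncol());
  if (max_t <= 0 || max_t > diag) max_t = diag;
  const int nsteps = (int)std::ceil(max_t / step);
  const double v0 = bilinear(mask, center_r, center_c);
  const bool center_inside = v0 >= 0.5;

  std::vector<double> vals(2 * nsteps + 1);
  for (int k = 0; k < na; ++k) {
    const double dr = std::sin(angles_rad[k]);
    const double dc = std::cos(angles_rad[k]);
    if (center_inside) {
      // walk outwards from the center to the first 0.5 crossing on each side;
      // deep interior (value > 0.9) is crossed in coarse jumps, the edge
      // neighborhood at the fine step, so the crossing is still resolved at
      // sub-pixel resolution
      const double coarse = 4.0 * step;
      double walk_edge = 0.0;
      for (int side = 0; side < 2; ++side) {
        const double sgn = side == 0 ? 1.0 : -1.0;
        double t = 0.0, vprev = v0, tend = 0.0;
        bool done = false;
        while (!done && std::fabs(t) < max_t) {
          double dt = vprev > 0.9 ? coarse : step;
          double tnew = t + sgn * dt;
          double v = bilinear(mask, center_r + tnew * dr, center_c + tnew * dc);
          if (v < 0.5 && dt > step) {
            // overshot with a coarse jump: redo this stretch at fine step
            tnew = t + sgn * step;
            v = bilinear(mask, center_r + tnew * dr, center_c + tnew * dc);
            dt = step;
          }
          if (v < 0.5 && dt == step) {
            tend = tnew - sgn * step + sgn * step * (vprev - 0.5) / (vprev - v);
            done = true;
          } else {
            t = tnew; vprev = v; tend = tnew;
          }
        }
        if (side == 0) walk_edge = tend; else walk_edge -= tend;
      }
      len[k] = walk_edge;
    } else {
      for (int i = 0; i <= 2 * nsteps; ++i) {
        const double t = (i - nsteps) * step;
        vals[i] = bilinear(mask, center_r + t * dr, center_c + t * dc);
      }
      // longest in-mask run anywhere on the line
      double best = 0.0;
      int i = 0;
      while (i <= 2 * nsteps) {
        if (vals[i] >= 0.5) {
          int j = i;
          while (j + 1 <= 2 * nsteps && vals[j + 1] >= 0.5) ++j;
          double t_lo = (i - nsteps) * step;
          double t_hi = (j - nsteps) * step;
          if (i > 0) t_lo -= step * (vals[i] - 0.5) / (vals[i] - vals[i - 1]);
          if (j < 2 * nsteps) t_hi += step * (vals[j] - 0.5) / (vals[j] - vals[j + 1]);
          if (t_hi - t_lo > best) best = t_hi - t_lo;
          i = j + 1;
        } else {
          ++i;
        }
      }
      len[k] = best;
    }
  }
  return List::create(_["lengths"] = len, _["center_inside"] = center_inside);
}
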