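#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// The forward light model is separable in the gantry frame: a column profile
// over the leaf axis (one amplitude per leaf, piecewise constant across the
// leaf's pixel strip) times an exponential attenuation along the beam axis,
// masked to the scintillator disc.  A frame at gantry angle theta is the 0
// degree pattern rotated about the isocenter pixel, so we evaluate the
// pattern at back-rotated coordinates instead of resampling a rendered
// image; this avoids interpolation error in the forward direction.

static inline double pattern_value(double dx, double dy, double ct, double st,
                                   double discR2, double pitch, double leafMid,
                                   double muPx, const double *amp, int nLeaves) {
  double rr = dx * dx + dy * dy;
  if (rr > discR2) return 0.0;
  double u = dx * ct + dy * st;   // leaf axis in the gantry frame
  double v = -dx * st + dy * ct;  // beam axis (negative = source side)
  int m = (int)std::floor(u / pitch + leafMid + 0.5);
  if (m < 1 || m > nLeaves) return 0.0;
  double a = amp[m - 1];
  if (a <= 0.0) return 0.0;
  return a * std::exp(-muPx * v);
}

// Render a stack of 8-bit frames.  leafAmp: nLeaves x nFrames expected ROI
// amplitudes (pixel value per frame at the leaf's own strip, centre row);
// angles in radians (clockwise gantry rotation).  Gaussian pixel noise uses
// the R RNG stream so that renders are reproducible under set.seed().
// Quantization rounds half away from zero and clips to [0, 255].
// [[Rcpp::export]]
RawVector cpp_render_stack(NumericMatrix leafAmp, NumericVector angles,
                           int nx, int ny, double cx, double cy,
                           double discR, double pitch, double leafMid,
                           double muPx, double bg, double noiseSd) {
  const int nLeaves = leafAmp.nrow();
  const int nF = leafAmp.ncol();
  if (angles.size() != nF) stop("angles must have one entry per frame");
  const double discR2 = discR * discR;
  RawVector out(R_xlen_t(nx) * ny * nF);
  unsigned char *px = (unsigned char *)RAW(out);
  std::vector<double> att(ny);
  R_xlen_t k = 0;
  for (int f = 0; f < nF; ++f) {
    const double *amp = &leafAmp(0, f);
    double th = angles[f];
    double ct = std::cos(th), st = std::sin(th);
    bool zero = (th == 0.0);
    std::vector<double> colv;
    if (zero) {  // static gantry: column lookup and row attenuation factorize
      colv.resize(nx);
      for (int x = 0; x < nx; ++x) {
        int m = (int)std::floor((x + 1 - cx) / pitch + leafMid + 0.5);
        colv[x] = (m >= 1 && m <= nLeaves) ? amp[m - 1] : 0.0;
      }
      for (int y = 0; y < ny; ++y) att[y] = std::exp(-muPx * (y + 1 - cy));
    }
    for (int y = 0; y < ny; ++y) {
      double dy = y + 1 - cy;
      for (int x = 0; x < nx; ++x) {
        double dx = x + 1 - cx;
        double val;
        if (zero) {
          double rr = dx * dx + dy * dy;
          val = (rr <= discR2 && colv[x] > 0.0) ? colv[x] * att[y] : 0.0;
        } else {
          val = pattern_value(dx, dy, ct, st, discR2, pitch, leafMid, muPx,
                              amp, nLeaves);
        }
        val += bg;
        if (noiseSd > 0.0) val += R::rnorm(0.0, noiseSd);
        double q = std::round(val);  // round() is half-away-from-zero
        if (q < 0.0) q = 0.0;
        if (q > 255.0) q = 255.0;
        px[k++] = (unsigned char)q;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nF);
  return out;
}

// Un-quantized, noise-free single frame of the light model (no background),
// used for model-level checks such as superposition.
// [[Rcpp::export]]
NumericMatrix cpp_render_frame_values(NumericVector leafAmp, double angle,
                                      int nx, int ny, double cx, double cy,
                                      double discR, double pitch,
                                      double leafMid, double muPx) {
  const int nLeaves = leafAmp.size();
  const double discR2 = discR * discR;
  double ct = std::cos(angle), st = std::sin(angle);
  NumericMatrix out(nx, ny);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      out(x, y) = pattern_value(x + 1 - cx, y + 1 - cy, ct, st, discR2, pitch,
                                leafMid, muPx, &leafAmp[0], nLeaves);
  return out;
}

static inline double sample_frame(const unsigned char *fr, int nx, int ny,
                                  double x, double y, double fill) {
  if (x < 1.0 || x > nx || y < 1.0 || y > ny) return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 >= nx) x0 = nx - 1;
  if (y0 >= ny) y0 = ny - 1;
  double fx = x - x0, fy = y - y0;
  const unsigned char *p = fr + (x0 - 1) + R_xlen_t(nx) * (y0 - 1);
  double v00 = p[0], v10 = p[1], v01 = p[nx], v11 = p[nx + 1];
  return (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
         (1 - fx) * fy * v01 + fx * fy * v11;
}

// Bilinear samples of every frame at a fixed set of base points, each point
// rotated forward by that frame's gantry angle about (cx, cy).  Sampling the
// forward-rotated coordinates is the back-rotation of the image restricted
// to the points that are actually read.  angles in radians; with all angles
// zero this is plain (sub)pixel sampling.
// [[Rcpp::export]]
NumericMatrix cpp_sample_stack(RawVector stack, NumericMatrix pts,
                               NumericVector angles, double cx, double cy,
                               double fill) {
  IntegerVector dim = stack.attr("dim");
  const int nx = dim[0], ny = dim[1], nF = dim[2];
  if (angles.size() != nF) stop("angles must have one entry per frame");
  const int np = pts.nrow();
  const unsigned char *base = (const unsigned char *)RAW(stack);
  NumericMatrix out(np, nF);
  for (int f = 0; f < nF; ++f) {
    const unsigned char *fr = base + R_xlen_t(nx) * ny * f;
    double th = angles[f];
    double ct = std::cos(th), st = std::sin(th);
    for (int i = 0; i < np; ++i) {
      double u = pts(i, 0) - cx, v = pts(i, 1) - cy;
      double x = cx + u * ct - v * st;
      double y = cy + u * st + v * ct;
      out(i, f) = sample_frame(fr, nx, ny, x, y, fill);
    }
  }
  return out;
}

// Full-image rotation by `angle` (radians, same clockwise convention as the
// renderer) about (cx, cy) with bilinear interpolation; out-of-bounds pixels
// are filled with `fill`.  rotate(rotate(X, a), -a) ~ X away from edges.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_frame(NumericMatrix frame, double angle, double cx,
                               double cy, double fill) {
  const int nx = frame.nrow(), ny = frame.ncol();
  double ct = std::cos(angle), st = std::sin(angle);
  NumericMatrix out(nx, ny);
  for (int y = 0; y < ny; ++y) {
    double dy = y + 1 - cy;
    for (int x = 0; x < nx; ++x) {
      double dx = x + 1 - cx;
      // value at the source location in the unrotated image
      double u = dx * ct + dy * st;
      double v = -dx * st + dy * ct;
      double sx = cx + u, sy = cy + v;
      if (sx < 1.0 || sx > nx || sy < 1.0 || sy > ny) {
        out(x, y) = fill;
        continue;
      }
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      if (x0 >= nx) x0 = nx - 1;
      if (y0 >= ny) y0 = ny - 1;
      double fx = sx - x0, fy = sy - y0;
      out(x, y) = (1 - fx) * (1 - fy) * frame(x0 - 1, y0 - 1) +
                  fx * (1 - fy) * frame(x0, y0 - 1) +
                  (1 - fx) * fy * frame(x0 - 1, y0) + fx * fy * frame(x0, y0);
    }
  }
  return out;
}
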