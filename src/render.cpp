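#include <Rcpp.h>
using namespace Rcpp;

// Render one phantom depth frame.
//
// The scene is a bed plane at `bed` mm from the camera carrying a
// cosine-squared dome (elliptical support, semi-axes a, b mm, centred at
// (tcx, tcy) mm on the plane, instantaneous height Ht mm at the apex).
// Each pixel's depth solves d = bed - h(X(d), Y(d)) where X(d), Y(d) is
// the pinhole ray at depth d; since h << bed the fixed-point iteration
// converges in a few steps (3 used). Gaussian noise (sd sigma, mm) is
// added per pixel, then depths are quantised to 0.1 mm integer units
// (round half to even, the sensor container convention).
//
// Uses R's RNG so that sequences are reproducible from set.seed().
// [[Rcpp::export(name = ".render_frame_cpp")]]
IntegerMatrix render_frame_cpp(int width, int height,
                               double fx, double fy, double cx, double cy,
                               double bed, double tcx, double tcy,
                               double a, double b, double Ht,
                               double sigma) {
  IntegerMatrix out(width, height);
  RNGScope scope;
  for (int v = 0; v < height; ++v) {
    for (int u = 0; u < width; ++u) {
      double d = bed;
      for (int it = 0; it < 3; ++it) {
        double X = (u - cx) * d / fx - tcx;
        double Y = (v - cy) * d / fy - tcy;
        double r2 = (X / a) * (X / a) + (Y / b) * (Y / b);
        double h = 0.0;
        if (r2 < 1.0) {
          double c = std::cos(M_PI * std::sqrt(r2) / 2.0);
          h = Ht * c * c;
        }
        d = bed - h;
        if (h == 0.0) break;  // ray misses the dome: already exact
      }
      if (sigma > 0.0) d += norm_rand() * sigma;
      out(u, v) = (int)std::nearbyint(d * 10.0);
    }
  }
  return out;
}
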