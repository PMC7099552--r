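#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Parallel-beam projector trio in pixel units.
//
// Conventions (shared with the R side): image is S x S, row 0 at the top;
// pixel (i, j) sits at x = j - (S-1)/2, y = (S-1)/2 - i. A view at angle
// theta measures line integrals along rays x*cos(theta) + y*sin(theta) = t,
// with t = (b - (nb-1)/2) * d for 0-based bin b and bin spacing d.
//
// Joseph's method steps the ray along its dominant image axis with linear
// interpolation across the other axis; the backprojector below is its exact
// transpose, so <A x, y> == <x, At y> to rounding error — the adjoint
// property the Landweber analysis assumes.

// [[Rcpp::export]]
NumericMatrix cpp_joseph_forward(NumericMatrix img, NumericVector angles_deg,
                                 int n_bins, double bin_spacing) {
  const int S = img.nrow();
  const int V = angles_deg.size();
  const double c0 = (S - 1) / 2.0;
  const double b0 = (n_bins - 1) / 2.0;
  NumericMatrix out(V, n_bins);
  for (int v = 0; v < V; ++v) {
    const double th = angles_deg[v] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    const bool row_step = std::fabs(st) <= std::fabs(ct);
    const double w = 1.0 / (row_step ? std::fabs(ct) : std::fabs(st));
    for (int b = 0; b < n_bins; ++b) {
      const double t = (b - b0) * bin_spacing;
      double acc = 0.0;
      if (row_step) {
        for (int i = 0; i < S; ++i) {
          const double y = c0 - i;
          const double fx = (t - y * st) / ct + c0;  // column coordinate
          const int j0 = (int)std::floor(fx);
          const double a = fx - j0;
          if (j0 >= 0 && j0 < S) acc += (1.0 - a) * img(i, j0);
          if (j0 + 1 >= 0 && j0 + 1 < S) acc += a * img(i, j0 + 1);
        }
      } else {
        for (int j = 0; j < S; ++j) {
          const double x = j - c0;
          const double fy = c0 - (t - x * ct) / st;  // row coordinate
          const int i0 = (int)std::floor(fy);
          const double a = fy - i0;
          if (i0 >= 0 && i0 < S) acc += (1.0 - a) * img(i0, j);
          if (i0 + 1 >= 0 && i0 + 1 < S) acc += a * img(i0 + 1, j);
        }
      }
      out(v, b) = acc * w;
    }
  }
  return out;
}

// Exact transpose of cpp_joseph_forward: scatter each weighted sample back.
// [[Rcpp::export]]
NumericMatrix cpp_joseph_backward(NumericMatrix sino, NumericVector angles_deg,
                                  int image_size, double bin_spacing) {
  const int S = image_size;
  const int V = angles_deg.size();
  const int n_bins = sino.ncol();
  const double c0 = (S - 1) / 2.0;
  const double b0 = (n_bins - 1) / 2.0;
  NumericMatrix img(S, S);
  for (int v = 0; v < V; ++v) {
    const double th = angles_deg[v] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    const bool row_step = std::fabs(st) <= std::fabs(ct);
    const double w = 1.0 / (row_step ? std::fabs(ct) : std::fabs(st));
    for (int b = 0; b < n_bins; ++b) {
      const double t = (b - b0) * bin_spacing;
      const double pw = sino(v, b) * w;
      if (pw == 0.0) continue;
      if (row_step) {
        for (int i = 0; i < S; ++i) {
          const double y = c0 - i;
          const double fx = (t - y * st) / ct + c0;
          const int j0 = (int)std::floor(fx);
          const double a = fx - j0;
          if (j0 >= 0 && j0 < S) img(i, j0) += (1.0 - a) * pw;
          if (j0 + 1 >= 0 && j0 + 1 < S) img(i, j0 + 1) += a * pw;
        }
      } else {
        for (int j = 0; j < S; ++j) {
          const double x = j - c0;
          const double fy = c0 - (t - x * ct) / st;
          const int i0 = (int)std::floor(fy);
          const double a = fy - i0;
          if (i0 >= 0 && i0 < S) img(i0, j) += (1.0 - a) * pw;
          if (i0 + 1 >= 0 && i0 + 1 < S) img(i0 + 1, j) += a * pw;
        }
      }
    }
  }
  return img;
}

// Pixel-driven backprojection used by FBP: each pixel reads the filtered
// view at its radial coordinate with linear interpolation between bins.
// Returns the plain sum over views; the caller applies the pi/V weighting.
// [[Rcpp::export]]
NumericMatrix cpp_pixel_backproject(NumericMatrix q, NumericVector angles_deg,
                                    int image_size, double bin_spacing) {
  const int S = image_size;
  const int V = angles_deg.size();
  const int n_bins = q.ncol();
  const double c0 = (S - 1) / 2.0;
  const double b0 = (n_bins - 1) / 2.0;
  NumericMatrix img(S, S);
  for (int v = 0; v < V; ++v) {
    const double th = angles_deg[v] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    for (int i = 0; i < S; ++i) {
      const double y = c0 - i;
      for (int j = 0; j < S; ++j) {
        const double x = j - c0;
        const double fb = (x * ct + y * st) / bin_spacing + b0;
        const int k = (int)std::floor(fb);
        const double a = fb - k;
        double val = 0.0;
        if (k >= 0 && k < n_bins) val += (1.0 - a) * q(v, k);
        if (k + 1 >= 0 && k + 1 < n_bins) val += a * q(v, k + 1);
        img(i, j) += val;
      }
    }
  }
  return img;
}
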