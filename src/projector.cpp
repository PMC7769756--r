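// 2D parallel-beam projector with an exact adjoint, plus OSEM with
// attenuation factors in the system model. Ray-driven sampling with bilinear
// interpolation; forward and back projection share the same weights so the
// adjoint identity <Px, y> = <x, P'y> holds to rounding error.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Geom {
  int n;        // image is n x n pixels
  int nbins;    // radial bins
  int nang;     // angles over [0, pi)
  double bw;    // bin width, mm
  double p;     // pixel size, mm
  double step;  // sampling step along the ray, mm
  double half_len;  // half ray length, mm
};

inline Geom make_geom(int n, int nbins, int nang, double bw, double p,
                      double step) {
  Geom g;
  g.n = n; g.nbins = nbins; g.nang = nang; g.bw = bw; g.p = p; g.step = step;
  g.half_len = 0.75 * n * p;
  return g;
}

// Accumulate one ray: either integrate the image (forward) or scatter a
// value into the image (adjoint).
template <bool Forward>
inline double trace_ray(const Geom& g, double* img, double s, double cs,
                        double sn, double val) {
  const int nsteps = (int)std::floor(2.0 * g.half_len / g.step) + 1;
  const double t0 = -g.half_len;
  const double c = (g.n - 1) / 2.0;
  const double sval = val * g.step;  // adjoint carries the same step factor
  double acc = 0.0;
  for (int k = 0; k < nsteps; ++k) {
    const double t = t0 + k * g.step;
    const double x = -s * sn + t * cs;
    const double y = s * cs + t * sn;
    const double u = x / g.p + c;
    const double v = y / g.p + c;
    if (u < 0.0 || u > g.n - 1 || v < 0.0 || v > g.n - 1) continue;
    int iu = (int)u; if (iu > g.n - 2) iu = g.n - 2;
    int iv = (int)v; if (iv > g.n - 2) iv = g.n - 2;
    const double fu = u - iu, fv = v - iv;
    const double w00 = (1 - fu) * (1 - fv), w10 = fu * (1 - fv);
    const double w01 = (1 - fu) * fv, w11 = fu * fv;
    double* base = img + iu + g.n * iv;
    if (Forward) {
      acc += w00 * base[0] + w10 * base[1] + w01 * base[g.n] +
             w11 * base[g.n + 1];
    } else {
      base[0] += w00 * sval; base[1] += w10 * sval;
      base[g.n] += w01 * sval; base[g.n + 1] += w11 * sval;
    }
  }
  return acc * g.step;
}

inline double bin_offset(const Geom& g, int r) {
  return (r - (g.nbins - 1) / 2.0) * g.bw;
}

void forward(const Geom& g, const double* img, double* sino) {
  std::vector<double> buf(img, img + g.n * g.n);
  for (int a = 0; a < g.nang; ++a) {
    const double phi = M_PI * a / g.nang;
    const double cs = std::cos(phi), sn = std::sin(phi);
    for (int r = 0; r < g.nbins; ++r) {
      sino[r + g.nbins * a] =
          trace_ray<true>(g, buf.data(), bin_offset(g, r), cs, sn, 0.0);
    }
  }
}

void backward(const Geom& g, const double* sino, double* img) {
  for (int a = 0; a < g.nang; ++a) {
    const double phi = M_PI * a / g.nang;
    const double cs = std::cos(phi), sn = std::sin(phi);
    for (int r = 0; r < g.nbins; ++r) {
      const double val = sino[r + g.nbins * a];
      if (val != 0.0)
        trace_ray<false>(g, img, bin_offset(g, r), cs, sn, val);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, int nang, int nbins,
                                  double bin_width, double pixel_size,
                                  double step) {
  const Geom g = make_geom(img.nrow(), nbins, nang, bin_width, pixel_size,
                           step);
  NumericMatrix sino(nbins, nang);
  forward(g, img.begin(), sino.begin());
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_back_project(NumericMatrix sino, int n, double bin_width,
                               double pixel_size, double step) {
  const Geom g = make_geom(n, sino.nrow(), sino.ncol(), bin_width, pixel_size,
                           step);
  NumericMatrix img(n, n);
  std::fill(img.begin(), img.end(), 0.0);
  backward(g, sino.begin(), img.begin());
  return img;
}

// OSEM reconstruction of one frame-slice. counts and acf are nbins x nang;
// scale multiplies the attenuated projection to give expected counts
// (counts_scale * duration * decay). n_subsets = 1 gives plain MLEM.
// [[Rcpp::export]]
NumericMatrix cpp_osem(NumericMatrix counts, NumericMatrix acf, double scale,
                       int n, double bin_width, double pixel_size, double step,
                       int n_iter, int n_subsets) {
  const int nbins = counts.nrow(), nang = counts.ncol();
  const Geom g = make_geom(n, nbins, nang, bin_width, pixel_size, step);
  const double eps = 1e-12;

  // subset sensitivity images: P'(scale * acf) restricted to subset angles
  std::vector<std::vector<double>> sens(n_subsets,
                                        std::vector<double>(n * n, 0.0));
  for (int sub = 0; sub < n_subsets; ++sub) {
    for (int a = sub; a < nang; a += n_subsets) {
      const double phi = M_PI * a / nang;
      const double cs = std::cos(phi), sn = std::sin(phi);
      for (int r = 0; r < nbins; ++r) {
        const double w = scale * acf(r, a);
        if (w > 0.0)
          trace_ray<false>(g, sens[sub].data(), bin_offset(g, r), cs, sn, w);
      }
    }
  }

  NumericMatrix x(n, n);
  // start from a uniform image on the support of the total sensitivity
  for (int i = 0; i < n * n; ++i) {
    double stot = 0.0;
    for (int sub = 0; sub < n_subsets; ++sub) stot += sens[sub][i];
    x[i] = (stot > eps) ? 1.0 : 0.0;
  }

  std::vector<double> upd(n * n);
  for (int it = 0; it < n_iter; ++it) {
    for (int sub = 0; sub < n_subsets; ++sub) {
      std::fill(upd.begin(), upd.end(), 0.0);
      for (int a = sub; a < nang; a += n_subsets) {
        const double phi = M_PI * a / nang;
        const double cs = std::cos(phi), sn = std::sin(phi);
        for (int r = 0; r < nbins; ++r) {
          const double s = bin_offset(g, r);
          const double proj = trace_ray<true>(g, x.begin(), s, cs, sn, 0.0);
          const double yhat = scale * acf(r, a) * proj;
          const double y = counts(r, a);
          double ratio = 0.0;
          if (yhat > eps) ratio = y / yhat;
          const double w = scale * acf(r, a) * ratio;
          if (w != 0.0) trace_ray<false>(g, upd.data(), s, cs, sn, w);
        }
      }
      for (int i = 0; i < n * n; ++i) {
        if (sens[sub][i] > eps) {
          x[i] *= upd[i] / sens[sub][i];
        } else {
          x[i] = 0.0;
        }
      }
    }
  }
  return x;
}
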