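// VGG16-style convolutional forward pass (13 conv layers, 3x3 kernels,
// zero padding 1, ReLU, 2x2 max pooling between blocks), single precision,
// im2col + BLAS GEMM. Returns per-layer mean post-ReLU activation
// (the activation-energy statistic) and optionally the full feature maps.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Patch matrix for a 3x3/pad-1 convolution: P(i + H*j, c*9 + a + 3*b) =
// A(i + a - 1, j + b - 1, c), zero outside the image.
static arma::fmat im2col3(const arma::fcube& A) {
  const arma::uword H = A.n_rows, W = A.n_cols, C = A.n_slices;
  arma::fmat P(H * W, C * 9, arma::fill::zeros);
  arma::fmat T(H, W);
  for (arma::uword c = 0; c < C; ++c) {
    for (int a = 0; a < 3; ++a) {
      for (int b = 0; b < 3; ++b) {
        const int du = a - 1, dv = b - 1;
        T.zeros();
        const arma::uword i0 = du < 0 ? 1 : 0;
        const arma::uword i1 = du > 0 ? H - 2 : H - 1;
        const arma::uword j0 = dv < 0 ? 1 : 0;
        const arma::uword j1 = dv > 0 ? W - 2 : W - 1;
        T.submat(i0, j0, i1, j1) =
          A.slice(c).submat(i0 + du, j0 + dv, i1 + du, j1 + dv);
        P.col(c * 9 + a + 3 * b) = arma::vectorise(T);
      }
    }
  }
  return P;
}

static arma::fcube maxpool2(const arma::fcube& A) {
  const arma::uword H = A.n_rows / 2, W = A.n_cols / 2, C = A.n_slices;
  arma::fcube B(H, W, C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < W; ++j)
      for (arma::uword i = 0; i < H; ++i) {
        const float v1 = A(2 * i, 2 * j, c), v2 = A(2 * i + 1, 2 * j, c);
        const float v3 = A(2 * i, 2 * j + 1, c), v4 = A(2 * i + 1, 2 * j + 1, c);
        B(i, j, c) = std::max(std::max(v1, v2), std::max(v3, v4));
      }
  return B;
}

// [[Rcpp::export(name = ".cppVGGForward")]]
List cppVGGForward(NumericVector img, List weights, bool returnMaps) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3 || d[0] != 224 || d[1] != 224 || d[2] != 3)
    stop("input image must be 224 x 224 x 3");
  arma::fcube A(224, 224, 3);
  std::copy(img.begin(), img.end(), A.begin());

  const int nLayers = weights.size();
  if (nLayers != 13) stop("backbone must have 13 convolutional layers");
  const bool poolAfter[13] = {false, true, false, true, false, false, true,
                              false, false, true, false, false, false};
  NumericVector uae(13);
  List maps(returnMaps ? 13 : 0);

  for (int l = 0; l < nLayers; ++l) {
    List lw = weights[l];
    NumericVector Wv = lw["W"];
    NumericVector bv = lw["b"];
    IntegerVector wd = Wv.attr("dim"); // 3 x 3 x inC x outC
    const arma::uword inC = wd[2], outC = wd[3];
    if (inC != A.n_slices) stop("layer %d: channel mismatch", l + 1);
    // reorder kernel to P's column layout: row c*9 + a + 3*b
    arma::fmat Wm(inC * 9, outC);
    const double* wp = Wv.begin();
    for (arma::uword o = 0; o < outC; ++o)
      for (arma::uword c = 0; c < inC; ++c)
        for (int b = 0; b < 3; ++b)
          for (int a = 0; a < 3; ++a)
            Wm(c * 9 + a + 3 * b, o) =
              (float)wp[a + 3 * b + 9 * c + 9 * inC * o];
    arma::frowvec bias(outC);
    for (arma::uword o = 0; o < outC; ++o) bias(o) = (float)bv[o];

    arma::fmat P = im2col3(A);
    arma::fmat Out = P * Wm;
    Out.each_row() += bias;
    Out.clamp(0.0f, std::numeric_limits<float>::max());

    double s = 0.0; // accumulate in double: maps can exceed 3e6 elements
    for (const float* p = Out.begin(); p != Out.end(); ++p) s += *p;
    uae[l] = s / Out.n_elem;
    const arma::uword H = A.n_rows, W = A.n_cols;
    arma::fcube Anew(H, W, outC);
    std::copy(Out.begin(), Out.end(), Anew.begin());
    if (returnMaps) {
      NumericVector m(H * W * outC);
      std::copy(Anew.begin(), Anew.end(), m.begin());
      m.attr("dim") = IntegerVector::create(H, W, outC);
      maps[l] = m;
    }
    A = poolAfter[l] ? maxpool2(Anew) : std::move(Anew);
  }
  return List::create(_["uae"] = uae, _["maps"] = maps);
}
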