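#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored channel-first as R arrays with dim (C, H, W, B),
// i.e. channel index varies fastest (column-major).  im2col lowers a
// batched convolution to one GEMM: the output matrix has C*k*k rows and
// oH*oW*B columns, column index = ((b*oW + ow)*oH + oh), row index =
// c + C*(ki + k*kj).  Out-of-range taps read as zero (zero padding).

// [[Rcpp::export]]
NumericMatrix im2col_chwb(NumericVector x, int C, int H, int W, int B,
                          int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, oH * oW * B);
  const double* px = x.begin();
  double* po = out.begin();
  const int nrow = C * k * k;
  for (int b = 0; b < B; ++b) {
    const double* xb = px + (size_t)b * C * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        double* col = po + (size_t)nrow * (((size_t)b * oW + ow) * oH + oh);
        const int ih0 = oh * stride - pad;
        const int iw0 = ow * stride - pad;
        for (int kj = 0; kj < k; ++kj) {
          const int iw = iw0 + kj;
          for (int ki = 0; ki < k; ++ki) {
            const int ih = ih0 + ki;
            double* dst = col + C * (ki + k * kj);
            if (ih >= 0 && ih < H && iw >= 0 && iw < W) {
              const double* src = xb + (size_t)C * (ih + (size_t)H * iw);
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            } else {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back into an array of dim
// (C, H, W, B).  Used for conv backward (data gradient) and for the
// forward pass of transposed convolution.

// [[Rcpp::export]]
NumericVector col2im_chwb(NumericMatrix cols, int C, int H, int W, int B,
                          int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector x((size_t)C * H * W * B);
  double* px = x.begin();
  const double* po = cols.begin();
  const int nrow = C * k * k;
  for (int b = 0; b < B; ++b) {
    double* xb = px + (size_t)b * C * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const double* col = po + (size_t)nrow * (((size_t)b * oW + ow) * oH + oh);
        const int ih0 = oh * stride - pad;
        const int iw0 = ow * stride - pad;
        for (int kj = 0; kj < k; ++kj) {
          const int iw = iw0 + kj;
          if (iw < 0 || iw >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int ih = ih0 + ki;
            if (ih < 0 || ih >= H) continue;
            const double* src = col + C * (ki + k * kj);
            double* dst = xb + (size_t)C * (ih + (size_t)H * iw);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}
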