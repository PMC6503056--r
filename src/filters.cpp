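#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int i, int n) {
    if (i < 0) return 0;
    if (i >= n) return n - 1;
    return i;
}

// Separable correlation: columns filtered with kc (vertical), rows with kr
// (horizontal). Kernels must have odd length. Border: replicate padding.
// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(const NumericMatrix& img,
                           const NumericVector& kc,
                           const NumericVector& kr) {
    const int nr = img.nrow(), nc = img.ncol();
    const int hc = kc.size() / 2, hr = kr.size() / 2;
    NumericMatrix tmp(nr, nc), out(nr, nc);
    const double* ip = &img[0];
    const double* kcp = &kc[0];
    const double* krp = &kr[0];
    double* tp = &tmp[0];
    double* op = &out[0];
    // vertical pass
    for (int j = 0; j < nc; ++j) {
        const double* col = ip + (size_t)j * nr;
        double* tcol = tp + (size_t)j * nr;
        for (int i = 0; i < hc && i < nr; ++i) {
            double s = 0.0;
            for (int u = -hc; u <= hc; ++u)
                s += kcp[u + hc] * col[clampi(i + u, nr)];
            tcol[i] = s;
        }
        for (int i = hc; i < nr - hc; ++i) {
            double s = 0.0;
            const double* c0 = col + i - hc;
            for (int u = 0; u < 2 * hc + 1; ++u) s += kcp[u] * c0[u];
            tcol[i] = s;
        }
        for (int i = std::max(hc, nr - hc); i < nr; ++i) {
            double s = 0.0;
            for (int u = -hc; u <= hc; ++u)
                s += kcp[u + hc] * col[clampi(i + u, nr)];
            tcol[i] = s;
        }
    }
    // horizontal pass
    for (int j = 0; j < nc; ++j) {
        double* ocol = op + (size_t)j * nr;
        const bool interior = (j >= hr && j < nc - hr);
        for (int v = -hr; v <= hr; ++v) {
            const int jj = interior ? j + v : clampi(j + v, nc);
            const double* tcol = tp + (size_t)jj * nr;
            const double w = krp[v + hr];
            if (v == -hr)
                for (int i = 0; i < nr; ++i) ocol[i] = w * tcol[i];
            else
                for (int i = 0; i < nr; ++i) ocol[i] += w * tcol[i];
        }
    }
    return out;
}

// Direct 2-D correlation with an odd-sized kernel, evaluated only at pixels
// where eval != 0 (everything else returns 0). Replicate padding.
// [[Rcpp::export]]
NumericMatrix cpp_conv2_masked(const NumericMatrix& img,
                               const NumericMatrix& kernel,
                               const IntegerMatrix& eval) {
    const int nr = img.nrow(), nc = img.ncol();
    const int kr = kernel.nrow(), kcn = kernel.ncol();
    const int hr = kr / 2, hc = kcn / 2;
    NumericMatrix out(nr, nc);
    const double* ip = &img[0];
    const double* kp = &kernel[0];
    const int* ep = &eval[0];
    double* op = &out[0];
    for (int j = 0; j < nc; ++j) {
        const int* ecol = ep + (size_t)j * nr;
        double* ocol = op + (size_t)j * nr;
        const bool jint = (j >= hc && j < nc - hc);
        for (int i = 0; i < nr; ++i) {
            if (!ecol[i]) continue;
            double s = 0.0;
            if (jint && i >= hr && i < nr - hr) {
                for (int v = 0; v < kcn; ++v) {
                    const double* icol = ip + (size_t)(j + v - hc) * nr + i - hr;
                    const double* kcol = kp + (size_t)v * kr;
                    for (int u = 0; u < kr; ++u) s += kcol[u] * icol[u];
                }
            } else {
                for (int v = -hc; v <= hc; ++v) {
                    const double* icol = ip + (size_t)clampi(j + v, nc) * nr;
                    const double* kcol = kp + (size_t)(v + hc) * kr;
                    for (int u = -hr; u <= hr; ++u)
                        s += kcol[u + hr] * icol[clampi(i + u, nr)];
                }
            }
            ocol[i] = s;
        }
    }
    return out;
}

// Additive paste of a patch into a canvas at (row0, col0), 0-based top-left;
// parts falling outside the canvas are dropped. Modifies canvas in place.
// [[Rcpp::export]]
void cpp_paste_add(NumericMatrix canvas, const NumericMatrix& patch,
                   int row0, int col0) {
    const int nr = canvas.nrow(), nc = canvas.ncol();
    for (int j = 0; j < patch.ncol(); ++j) {
        int cj = col0 + j;
        if (cj < 0 || cj >= nc) continue;
        for (int i = 0; i < patch.nrow(); ++i) {
            int ci = row0 + i;
            if (ci < 0 || ci >= nr) continue;
            canvas(ci, cj) += patch(i, j);
        }
    }
}

// Sum of anisotropic Gaussian blobs. blobs: one row per blob with columns
// (row_center, col_center, sigma_major, sigma_minor, angle_rad, amplitude),
// 0-based coordinates. Evaluated over an nr x nc patch.
// [[Rcpp::export]]
NumericMatrix cpp_render_blobs(int nr, int nc, const NumericMatrix& blobs) {
    NumericMatrix out(nr, nc);
    double* op = &out[0];
    for (int b = 0; b < blobs.nrow(); ++b) {
        const double r0 = blobs(b, 0), c0 = blobs(b, 1);
        const double sa = blobs(b, 2), sb = blobs(b, 3);
        const double th = blobs(b, 4), amp = blobs(b, 5);
        const double ct = std::cos(th), st = std::sin(th);
        const double ext = 4.0 * std::max(sa, sb);
        const int i0 = std::max(0, (int)std::floor(r0 - ext));
        const int i1 = std::min(nr - 1, (int)std::ceil(r0 + ext));
        const int j0 = std::max(0, (int)std::floor(c0 - ext));
        const int j1 = std::min(nc - 1, (int)std::ceil(c0 + ext));
        const double isa2 = 1.0 / (sa * sa), isb2 = 1.0 / (sb * sb);
        for (int j = j0; j <= j1; ++j) {
            double* ocol = op + (size_t)j * nr;
            const double dc = j - c0;
            for (int i = i0; i <= i1; ++i) {
                const double dr = i - r0;
                const double x = ct * dr + st * dc;
                const double y = -st * dr + ct * dc;
                ocol[i] += amp * std::exp(-0.5 * (x * x * isa2 + y * y * isb2));
            }
        }
    }
    return out;
}
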