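#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Fractional (Grunwald-Letnikov) time stepper for the Delta-Notch lattice
// model. State layout is component-major: all D, then all N, then all A, each
// block of length n_cells; the per-component history is kept contiguous so the
// memory convolution is a straight dot product.
//
// One step (per component x):
//   x_k = rhs(x_{k-1}) * h^q - sum_{j=1}^{m} c_j x_{k-j} + x_0 * S_m
// where m is the (possibly truncated) memory length and S_m = sum_{j=0}^m c_j
// is the Caputo starting-term correction (dropped when ic_correction = false).
// With euler = true the step is plain x_k = x_{k-1} + h * rhs.

// [[Rcpp::export(name = ".gl_notch_cpp")]]
List gl_notch_cpp(NumericVector x0,            // length 3 * n_cells
                  List neighbors,              // 0-based integer vectors
                  NumericVector lambda_eff,    // per-cell lambda^alpha
                  double lambda_n, double f, double d, double a, double b,
                  double theta,                // effective (alpha-powered)
                  double h, double hq,
                  int n_steps, NumericVector cj, // c_0..c_{n_steps}
                  int window, int stride,
                  bool euler, bool ic_correction,
                  double diverge_tol)
{
    const int nc = lambda_eff.size();
    const int ncomp = 3 * nc;
    if (x0.size() != ncomp) stop("internal: x0 size mismatch");

    std::vector< std::vector<int> > nbr(nc);
    for (int i = 0; i < nc; ++i) {
        IntegerVector v = neighbors[i];
        nbr[i].assign(v.begin(), v.end());
    }

    // history, one contiguous series per component
    const std::size_t T = static_cast<std::size_t>(n_steps) + 1;
    std::vector<double> H(static_cast<std::size_t>(ncomp) * T);
    for (int c = 0; c < ncomp; ++c) H[c * T] = x0[c];

    std::vector<double> csum(T);
    {
        double s = 0.0;
        for (std::size_t j = 0; j < T; ++j) { s += cj[j]; csum[j] = s; }
    }
    // reversed copy of the weights: W[u] = c_{n_steps - u}, so that the memory
    // convolution at step k is a dot product of two forward-contiguous ranges
    std::vector<double> W(T);
    for (std::size_t u = 0; u < T; ++u) W[u] = cj[n_steps - u];

    const int n_rec = n_steps / stride + 1 + ((n_steps % stride) ? 1 : 0);
    NumericMatrix rec(n_rec, ncomp);
    NumericVector rec_t(n_rec);
    int r = 0;
    for (int c = 0; c < ncomp; ++c) rec(0, c) = x0[c];
    rec_t[0] = 0.0;
    r = 1;

    std::vector<double> rhs(ncomp), sumD(nc), sumN(nc);

    for (int k = 1; k <= n_steps; ++k) {
        const std::size_t km1 = static_cast<std::size_t>(k - 1);
        const double *D = &H[0 * (std::size_t)nc * T] + km1; // strided access helpers below
        (void)D;

        // neighbour sums at t_{k-1}
        for (int i = 0; i < nc; ++i) {
            double sd = 0.0, sn = 0.0;
            const std::vector<int> &v = nbr[i];
            for (std::size_t u = 0; u < v.size(); ++u) {
                const int j = v[u];
                sd += H[(std::size_t)j * T + km1];
                sn += H[((std::size_t)nc + j) * T + km1];
            }
            sumD[i] = sd; sumN[i] = sn;
        }
        for (int i = 0; i < nc; ++i) {
            const double Di = H[(std::size_t)i * T + km1];
            const double Ni = H[((std::size_t)nc + i) * T + km1];
            const double Ai = H[((std::size_t)(2 * nc) + i) * T + km1];
            const double S = sumD[i] * Ni;
            rhs[i]          = lambda_eff[i] / (1.0 + theta * Ai) - f * Di * sumN[i] - d * Di;
            rhs[nc + i]     = lambda_n + f * sumD[i] * Ni - d * Ni;
            rhs[2 * nc + i] = a * S / (b + S) - d * Ai;
        }

        const int m = (window > 0 && window < k) ? window : k;
        for (int c = 0; c < ncomp; ++c) {
            const double *x = &H[(std::size_t)c * T];
            double xk;
            if (euler) {
                xk = x[km1] + h * rhs[c];
            } else {
                // sum_{j=1}^{m} c_j x[k-j] = sum_{i=k-m}^{k-1} x[i] W[n-k+i];
                // four independent accumulators break the FP dependency chain
                const double *xs = x + (k - m);
                const double *ws = &W[(std::size_t)(n_steps - k) + (k - m)];
                double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
                int i = 0;
                for (; i + 4 <= m; i += 4) {
                    s0 += xs[i]     * ws[i];
                    s1 += xs[i + 1] * ws[i + 1];
                    s2 += xs[i + 2] * ws[i + 2];
                    s3 += xs[i + 3] * ws[i + 3];
                }
                for (; i < m; ++i) s0 += xs[i] * ws[i];
                const double mem = (s0 + s1) + (s2 + s3);
                xk = rhs[c] * hq - mem;
                if (ic_correction) xk += csum[m] * x[0];
            }
            if (!std::isfinite(xk) || std::fabs(xk) > diverge_tol) {
                const int comp = c / nc, cell = c % nc;
                const char *nm = comp == 0 ? "D" : (comp == 1 ? "N" : "A");
                stop("trajectory diverged at t = %f (cell %d, component %s)",
                     k * h, cell + 1, nm);
            }
            H[(std::size_t)c * T + k] = xk;
        }

        if (k % stride == 0 || k == n_steps) {
            for (int c = 0; c < ncomp; ++c) rec(r, c) = H[(std::size_t)c * T + k];
            rec_t[r] = k * h;
            ++r;
        }
    }

    return List::create(_["times"] = rec_t[Range(0, r - 1)],
                        _["states"] = rec(Range(0, r - 1), _));
}
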