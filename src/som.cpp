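#include <Rcpp.h>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Toroidal per-axis distance between two grid positions, 0-based.
static inline int torus_axis_dist(int a, int b, int size) {
    int d = std::abs(a - b);
    return std::min(d, size - d);
}

// Sequential-update Kohonen training on a toroidal grid with a triangular
// (linearly decaying) neighbourhood kernel.  Optionally trains a
// counter-propagation output layer alongside: output weights of every
// neuron in the winner's neighbourhood move toward the sample's target
// vector with the same learning factor, while the winner is always chosen
// from the input layer alone.
//
// Matrices are passed variable-major (transposed) so each neuron's weight
// vector is contiguous in memory.
//
// wT       : p x nNeurons initial input-layer weights; neuron index is
//            row-major over the grid (neuron = row * cols + col)
// xT       : p x n training data
// orders   : epochs x n matrix of 0-based sample indices (presentation
//            order per epoch; generated in R so all randomness flows
//            through R's RNG)
// lr0      : initial learning rate; lr(t) = lr0 * (1 - t/T)
// span0    : initial neighbourhood span; span(t) = round(span0 * (1 - t/T));
//            neurons at toroidal Chebyshev distance d <= span(t) update
//            with factor lr(t) * (1 - d / (span(t) + 1))
// targetsT : optional k x n output targets (counter-propagation layer)
// outT     : optional k x nNeurons initial output weights
// [[Rcpp::export(name = ".som_train_cpp")]]
List som_train_cpp(NumericMatrix wT, NumericMatrix xT, IntegerMatrix orders,
                   int rows, int cols, double lr0, int span0,
                   Nullable<NumericMatrix> targetsT = R_NilValue,
                   Nullable<NumericMatrix> outT = R_NilValue) {
    const int p = wT.nrow();
    const int nNeurons = wT.ncol();
    const int n = xT.ncol();
    const int epochs = orders.nrow();
    if (nNeurons != rows * cols)
        stop("weight matrix must have rows * cols columns");
    if (xT.nrow() != p)
        stop("data and weights disagree in dimension");

    NumericMatrix W = clone(wT);
    double *w = W.begin();
    const double *x = xT.begin();

    bool hasOut = targetsT.isNotNull();
    NumericMatrix T_, O_;
    double *ow = nullptr;
    const double *tg = nullptr;
    int k = 0;
    if (hasOut) {
        T_ = as<NumericMatrix>(targetsT);
        O_ = clone(as<NumericMatrix>(outT));
        k = T_.nrow();
        if (T_.ncol() != n || O_.ncol() != nNeurons || O_.nrow() != k)
            stop("target/output-weight dimensions inconsistent");
        ow = O_.begin();
        tg = T_.begin();
    }

    for (int t = 0; t < epochs; ++t) {
        const double frac = 1.0 - (double)t / (double)epochs;
        const double lr = lr0 * frac;
        const int span = (int)std::lround((double)span0 * frac);
        if (lr <= 0.0) continue;
        for (int s = 0; s < n; ++s) {
            const int i = orders(t, s);
            const double *xi = x + (size_t)i * p;
            // winner: minimum Euclidean distance, exact ties to the
            // smallest row-major index (strict < keeps the first minimum)
            double best = R_PosInf;
            int win = 0;
            for (int m = 0; m < nNeurons; ++m) {
                const double *wm = w + (size_t)m * p;
                double d2 = 0.0;
                for (int j = 0; j < p; ++j) {
                    const double diff = wm[j] - xi[j];
                    d2 += diff * diff;
                }
                if (d2 < best) { best = d2; win = m; }
            }
            const int wr = win / cols;
            const int wc = win % cols;
            const double *ti = hasOut ? tg + (size_t)i * k : nullptr;
            for (int r = 0; r < rows; ++r) {
                const int dr = torus_axis_dist(r, wr, rows);
                if (dr > span) continue;
                for (int c = 0; c < cols; ++c) {
                    const int dc = torus_axis_dist(c, wc, cols);
                    const int d = dr > dc ? dr : dc;
                    if (d > span) continue;
                    const double f = lr * (1.0 - (double)d / (double)(span + 1));
                    const int m = r * cols + c;
                    double *wm = w + (size_t)m * p;
                    for (int j = 0; j < p; ++j)
                        wm[j] += f * (xi[j] - wm[j]);
                    if (hasOut) {
                        double *om = ow + (size_t)m * k;
                        for (int j = 0; j < k; ++j)
                            om[j] += f * (ti[j] - om[j]);
                    }
                }
            }
        }
    }

    if (hasOut)
        return List::create(_["weightsT"] = W, _["outputT"] = O_);
    return List::create(_["weightsT"] = W);
}

// Brute-force best-matching units for a batch of inputs (both matrices
// variable-major); 0-based neuron indices, ties to the smallest row-major
// index.
// [[Rcpp::export(name = ".som_bmu_cpp")]]
IntegerVector som_bmu_cpp(NumericMatrix wT, NumericMatrix xT) {
    const int p = wT.nrow();
    const int nNeurons = wT.ncol();
    const int n = xT.ncol();
    if (xT.nrow() != p) stop("data and weights disagree in dimension");
    const double *w = wT.begin();
    const double *x = xT.begin();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        const double *xi = x + (size_t)i * p;
        double best = R_PosInf;
        int win = 0;
        for (int m = 0; m < nNeurons; ++m) {
            const double *wm = w + (size_t)m * p;
            double d2 = 0.0;
            for (int j = 0; j < p; ++j) {
                const double diff = wm[j] - xi[j];
                d2 += diff * diff;
            }
            if (d2 < best) { best = d2; win = m; }
        }
        out[i] = win;
    }
    return out;
}
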