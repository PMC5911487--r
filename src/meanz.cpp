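#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Tie-corrected normal-approximation rank-sum z for two ascending-sorted
// samples. W = rank sum of sample a in the combined sample; positive z means
// a is stochastically larger than b. Zero variance (all values tied) -> 0.
static double ranksum_z_sorted(const double *a, int n1, const double *b, int n2) {
    const int n = n1 + n2;
    double W = 0.0, tiesum = 0.0;
    int i = 0, j = 0;
    long assigned = 0;
    while (i < n1 || j < n2) {
        double v;
        if (i < n1 && (j >= n2 || a[i] <= b[j]))
            v = a[i];
        else
            v = b[j];
        int ca = 0, cb = 0;
        while (i < n1 && a[i] == v) { ++ca; ++i; }
        while (j < n2 && b[j] == v) { ++cb; ++j; }
        const int g = ca + cb;
        const double avg = assigned + (g + 1) / 2.0;
        W += avg * ca;
        const double gd = g;
        tiesum += gd * gd * gd - gd;
        assigned += g;
    }
    const double EW = n1 * (n + 1) / 2.0;
    const double var = (double)n1 * n2 / 12.0 *
        ((n + 1) - tiesum / ((double)n * (n - 1)));
    if (var <= 0.0) return 0.0;
    return (W - EW) / std::sqrt(var);
}

// [[Rcpp::export]]
double cpp_ranksum_z(NumericVector x, NumericVector y) {
    if (x.size() == 0 || y.size() == 0)
        stop("both samples must be non-empty");
    std::vector<double> a(x.begin(), x.end()), b(y.begin(), y.end());
    std::sort(a.begin(), a.end());
    std::sort(b.begin(), b.end());
    return ranksum_z_sorted(a.data(), a.size(), b.data(), b.size());
}

// Circular running means of `trace`: resp[f] = mean(trace[f .. f+wr-1]) and
// base[f] = mean(trace[f-wb .. f-1]), indices modulo T (f is 0-based).
static void window_means(const NumericVector &trace, int wr, int wb,
                         std::vector<double> &resp, std::vector<double> &base) {
    const int T = trace.size();
    std::vector<double> pref(2 * T + 1, 0.0);
    for (int i = 0; i < 2 * T; ++i) pref[i + 1] = pref[i] + trace[i % T];
    resp.resize(T);
    base.resize(T);
    for (int f = 0; f < T; ++f) {
        resp[f] = (pref[f + wr] - pref[f]) / wr;
        const int s = f - wb + T;
        base[f] = (pref[s + wb] - pref[s]) / wb;
    }
}

static inline int wrap(int i, int T) {
    i %= T;
    return i < 0 ? i + T : i;
}

// Per-trial responses of the trace rotated by `shift` frames, read at the
// original (0-based) onset/offset frame indices: mean(F, response window) /
// mean(F, baseline window) - 1.
// [[Rcpp::export]]
NumericMatrix cpp_null_responses(NumericVector trace, IntegerVector onsetIdx,
                                 IntegerVector offsetIdx, int wr, int wb,
                                 IntegerVector shifts) {
    const int T = trace.size(), nt = onsetIdx.size(), ns = shifts.size();
    if (wr < 1 || wb < 1) stop("window sizes must be >= 1 frame");
    if (wr > T || wb > T) stop("window larger than trace");
    std::vector<double> resp, base;
    window_means(trace, wr, wb, resp, base);
    NumericMatrix out(ns, nt);
    for (int s = 0; s < ns; ++s) {
        const int sh = shifts[s];
        for (int t = 0; t < nt; ++t) {
            const double b = base[wrap(onsetIdx[t] - sh, T)];
            if (b <= 0.0) stop("degenerate baseline (mean <= 0) in shifted trace");
            out(s, t) = resp[wrap(offsetIdx[t] - sh, T)] / b - 1.0;
        }
    }
    return out;
}

// One rank-sum z per circular shift: real per-trial responses (shift 0, no
// wrap assumed valid by the caller) vs. the responses of the rotated trace.
// [[Rcpp::export]]
NumericVector cpp_shuffle_z(NumericVector trace, IntegerVector onsetIdx,
                            IntegerVector offsetIdx, int wr, int wb,
                            IntegerVector shifts) {
    const int T = trace.size(), nt = onsetIdx.size(), ns = shifts.size();
    if (nt < 1) stop("no trials");
    if (wr < 1 || wb < 1) stop("window sizes must be >= 1 frame");
    if (wr > T || wb > T) stop("window larger than trace");
    std::vector<double> resp, base;
    window_means(trace, wr, wb, resp, base);

    std::vector<double> real(nt);
    for (int t = 0; t < nt; ++t) {
        const double b = base[wrap(onsetIdx[t], T)];
        if (b <= 0.0) stop("degenerate baseline (mean <= 0) in trial window");
        real[t] = resp[wrap(offsetIdx[t], T)] / b - 1.0;
    }
    std::vector<double> realSorted(real);
    std::sort(realSorted.begin(), realSorted.end());

    NumericVector z(ns);
    std::vector<double> nul(nt);
    for (int s = 0; s < ns; ++s) {
        const int sh = shifts[s];
        for (int t = 0; t < nt; ++t) {
            const double b = base[wrap(onsetIdx[t] - sh, T)];
            if (b <= 0.0) stop("degenerate baseline (mean <= 0) in shifted trace");
            nul[t] = resp[wrap(offsetIdx[t] - sh, T)] / b - 1.0;
        }
        std::sort(nul.begin(), nul.end());
        z[s] = ranksum_z_sorted(realSorted.data(), nt, nul.data(), nt);
    }
    return z;
}
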