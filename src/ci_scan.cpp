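#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Exact upper tail P(X >= h) for a sum of independent Bernoulli trials.
// Homogeneous probabilities use the binomial tail directly; heterogeneous
// ones use a capped dynamic program over whichever of the success / failure
// counts is smaller, absorbing mass once the bound is crossed.
static double tail_ge(const std::vector<double>& p, int h) {
    int n = (int)p.size();
    if (h <= 0) return 1.0;
    if (h > n) return 0.0;
    bool homo = true;
    for (int i = 1; i < n; ++i) if (p[i] != p[0]) { homo = false; break; }
    if (homo) return R::pbinom((double)(h - 1), (double)n, p[0], 0, 0);
    if (h <= n - h + 1) {
        // DP over success counts 0..h-1, absorbing at >= h
        std::vector<double> f(h, 0.0); f[0] = 1.0;
        double absorbed = 0.0;
        for (int i = 0; i < n; ++i) {
            absorbed += f[h - 1] * p[i];
            for (int k = h - 1; k >= 1; --k)
                f[k] = f[k] * (1.0 - p[i]) + f[k - 1] * p[i];
            f[0] *= (1.0 - p[i]);
        }
        return absorbed;
    } else {
        // P(X >= h) = P(failures <= n - h); DP over failure counts
        int cap = n - h;
        std::vector<double> f(cap + 1, 0.0); f[0] = 1.0;
        for (int i = 0; i < n; ++i) {
            double q = 1.0 - p[i];
            for (int k = cap; k >= 1; --k)
                f[k] = f[k] * p[i] + f[k - 1] * q;
            f[0] *= p[i];
        }
        double s = 0.0;
        for (int k = 0; k <= cap; ++k) s += f[k];
        return std::min(1.0, s);
    }
}

// [[Rcpp::export]]
double tailGECpp(NumericVector probs, int h) {
    std::vector<double> p(probs.begin(), probs.end());
    return tail_ge(p, h);
}

// Greedy earliest occurrence matching: scan left occurrences in time
// order, joining each to the earliest unused right occurrence whose start
// lies within [end + d1, end + d2] in the same sample. Returns 1-based
// index vectors (leftMap, rightMap) of the matched rows.
// [[Rcpp::export]]
List pairOccurrencesCpp(IntegerVector lStart, IntegerVector lEnd,
                        IntegerVector rStart, IntegerVector rEnd,
                        IntegerVector sampL, IntegerVector sampR,
                        int d1, int d2) {
    int nl = lStart.size(), nr = rStart.size();
    std::vector<bool> used(nr, false);
    std::vector<int> lm, rm;
    int jmin = 0;
    for (int i = 0; i < nl; ++i) {
        long lo = (long)lEnd[i] + d1, hi = (long)lEnd[i] + d2;
        for (int j = jmin; j < nr; ++j) {
            if (rStart[j] > hi) break;
            if (used[j]) { if (j == jmin) ++jmin; continue; }
            if (rStart[j] >= lo && sampR[j] == sampL[i]) {
                used[j] = true;
                lm.push_back(i + 1);
                rm.push_back(j + 1);
                break;
            }
        }
    }
    return List::create(_["leftMap"] = wrap(lm), _["rightMap"] = wrap(rm));
}

struct Cand { double p; int d1, d2, hits; bool set; };

static void consider(Cand& best, double p, int d1, int d2, int hits,
                     double alpha) {
    if (p > alpha) return;
    int w = d2 - d1;
    if (!best.set || p < best.p ||
        (p == best.p && (w < best.d2 - best.d1 ||
                         (w == best.d2 - best.d1 && d1 < best.d1)))) {
        best.p = p; best.d1 = d1; best.d2 = d2; best.hits = hits;
        best.set = true;
    }
}

// Scan candidate intervals [d1, d2] whose endpoints are drawn from the
// observed next-following distances: for each left point a, the distance
// to the first right point b >= a within the same sample. A left point is
// a hit for [d1, d2] when its next-following distance lies in the
// interval. Under the null of independent placement at per-unit rate q,
// the per-trial hit probability (with the window truncated at the sample
// end to width w) is (1-q)^d1 * (1 - (1-q)^w): the next right point must
// skip the d1 units before the window and land inside it. Returns the
// qualifying candidate minimizing the exact tail probability (ties:
// narrower, then smaller d1). For a fixed d1 only the minimal d2 reaching
// each distinct hit count is evaluated: widening at constant hit count can
// only raise the tail probability and loses the narrower-wins tie-break.
//
// a, b: sorted occurrence times; sampA/sampB: sample index per point;
// sampEndA: end time of each a point's sample; rate: per-unit null rate
// N_B / T of the right series.
// [[Rcpp::export]]
SEXP ciScanCpp(IntegerVector a, IntegerVector b,
               IntegerVector sampA, IntegerVector sampB,
               IntegerVector sampEndA,
               double rate, int dmax, double alpha, int nmin,
               std::string mode) {
    int na = a.size(), nb = b.size();
    Cand best; best.set = false;
    if (na == 0 || nb == 0) return R_NilValue;

    std::vector<double> ptrial(na);
    auto evalInterval = [&](int d1, int d2, int hits) {
        bool homo = true;
        int wfull = d2 - d1 + 1;
        double skip = std::pow(1.0 - rate, (double)d1);
        for (int i = 0; i < na; ++i) {
            long lo = (long)a[i] + d1;
            long hi = std::min((long)a[i] + d2, (long)sampEndA[i]);
            long w = hi - lo + 1;
            if (w < 0) w = 0;
            if (w > wfull) w = wfull;
            ptrial[i] = (w == 0) ? 0.0
                : skip * (1.0 - std::pow(1.0 - rate, (double)w));
            if (w != wfull) homo = false;
        }
        double p = homo
            ? R::pbinom((double)(hits - 1), (double)na, ptrial[0], 0, 0)
            : tail_ge(ptrial, hits);
        consider(best, p, d1, d2, hits, alpha);
    };

    // next-following distance per left point (same sample); hits are
    // counted as distinct right points, since n recurrences of "B follows
    // A" require n distinct B occurrences (several A sharing one next B
    // count once)
    struct Link { int d, bidx; };
    std::vector<Link> dist;
    {
        int j0 = 0;
        for (int i = 0; i < na; ++i) {
            while (j0 < nb && b[j0] < a[i]) ++j0;
            for (int j = j0; j < nb; ++j) {
                long d = (long)b[j] - a[i];
                if (d > dmax) break;
                if (sampB[j] == sampA[i]) {
                    dist.push_back({(int)d, j});
                    break;                    // first following only
                }
            }
        }
    }
    if (dist.empty()) return R_NilValue;

    if (mode == "fixed11") {
        if (dmax < 1) return R_NilValue;
        int hits = 0;
        for (size_t k = 0; k < dist.size(); ++k)
            if (dist[k].d == 1) ++hits;       // distinct b automatically
        if (hits >= nmin) evalInterval(1, 1, hits);
    } else {
        std::sort(dist.begin(), dist.end(),
                  [](const Link& x, const Link& y) { return x.d < y.d; });
        std::vector<int> dval, doff;
        for (size_t k = 0; k < dist.size(); ++k)
            if (k == 0 || dist[k].d != dist[k - 1].d) {
                dval.push_back(dist[k].d);
                doff.push_back((int)k);
            }
        doff.push_back((int)dist.size());
        int K = (int)dval.size();
        // selection control: candidate intervals are seeded by the K
        // distinct observed distances; nested candidates sharing a seed
        // are near-duplicates, so the family-level threshold divides
        // alpha by K (Bonferroni over effective candidates)
        alpha = alpha / (double)K;
        std::vector<int> stamp(nb, -1);
        for (int i0 = 0; i0 < K; ++i0) {
            int d1 = dval[i0];
            int h = 0, hEval = 0;
            for (int jj = i0; jj < K; ++jj) {
                for (int k = doff[jj]; k < doff[jj + 1]; ++k) {
                    int bi = dist[k].bidx;
                    if (stamp[bi] != i0) { stamp[bi] = i0; ++h; }
                }
                if (h > hEval && h >= nmin) {
                    evalInterval(d1, dval[jj], h);
                    hEval = h;
                }
            }
        }
    }
    if (!best.set) return R_NilValue;
    return List::create(_["d1"] = best.d1, _["d2"] = best.d2,
                        _["pValue"] = best.p, _["nHits"] = best.hits);
}
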