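#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double subst(char a, char b, double match, double mismatch) {
    // N is treated as a mismatch against every base, including N
    if (a == 'N' || b == 'N') return mismatch;
    return (a == b) ? match : mismatch;
}

// Global alignment with affine gaps (Gotoh): a gap of length L costs
// gap_open + gap_extend * (L - 1).  Traceback ties resolve in the order
// diagonal, gap-in-b (consume a), gap-in-a (consume b), so the output is
// deterministic.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
    const int n = (int)a.size(), m = (int)b.size();
    const int W = m + 1;
    // H: best overall; E: ends with gap in b (consumes a); F: gap in a
    std::vector<double> H((n + 1) * W, NEG_INF), E((n + 1) * W, NEG_INF),
        F((n + 1) * W, NEG_INF);
    H[0] = 0.0;
    for (int i = 1; i <= n; ++i) {
        E[i * W] = gap_open + gap_extend * (i - 1);
        H[i * W] = E[i * W];
    }
    for (int j = 1; j <= m; ++j) {
        F[j] = gap_open + gap_extend * (j - 1);
        H[j] = F[j];
    }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const int ij = i * W + j, up = (i - 1) * W + j, lf = ij - 1;
            double e = std::max(H[up] + gap_open, E[up] + gap_extend);
            double f = std::max(H[lf] + gap_open, F[lf] + gap_extend);
            double d = H[(i - 1) * W + (j - 1)] +
                subst(a[i - 1], b[j - 1], match, mismatch);
            E[ij] = e;
            F[ij] = f;
            H[ij] = std::max(d, std::max(e, f));
        }
    }
    // traceback
    std::string out_a, out_b;
    out_a.reserve(n + m);
    out_b.reserve(n + m);
    int i = n, j = m;
    int state = 0; // 0 = H, 1 = E (gap in b), 2 = F (gap in a)
    const double eps = 1e-9;
    while (i > 0 || j > 0) {
        const int ij = i * W + j;
        if (state == 0) {
            double d = (i > 0 && j > 0)
                ? H[(i - 1) * W + (j - 1)] +
                      subst(a[i - 1], b[j - 1], match, mismatch)
                : NEG_INF;
            if (i > 0 && j > 0 && std::abs(H[ij] - d) < eps) {
                out_a.push_back(a[--i]);
                out_b.push_back(b[--j]);
            } else if (i > 0 && std::abs(H[ij] - E[ij]) < eps) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) { // gap in b, consume a
            const int up = (i - 1) * W + j;
            bool from_open = std::abs(E[ij] - (H[up] + gap_open)) < eps;
            out_a.push_back(a[--i]);
            out_b.push_back('-');
            // prefer closing the gap (back to H) on ties
            state = from_open ? 0 : 1;
        } else { // gap in a, consume b
            const int lf = ij - 1;
            bool from_open = std::abs(F[ij] - (H[lf] + gap_open)) < eps;
            out_a.push_back('-');
            out_b.push_back(b[--j]);
            state = from_open ? 0 : 2;
        }
    }
    std::reverse(out_a.begin(), out_a.end());
    std::reverse(out_b.begin(), out_b.end());
    return List::create(_["aligned_a"] = out_a, _["aligned_b"] = out_b,
                        _["score"] = H[n * W + m]);
}

// Best ungapped overlap merge of a forward read and the reverse-complemented
// mate.  Offsets d >= 0 place the mate start inside the forward read; the
// candidate with the most matching bases wins (ties -> longest overlap).
// [[Rcpp::export(name = ".merge_pair_cpp")]]
List merge_pair_cpp(std::string s1, IntegerVector q1,
                    std::string s2, IntegerVector q2,
                    int min_overlap, double max_mismatch_frac) {
    const int n1 = (int)s1.size(), n2 = (int)s2.size();
    int best_d = -1, best_matches = -1, best_len = 0;
    for (int d = 0; d + min_overlap <= n1; ++d) {
        int len = std::min(n1 - d, n2);
        if (len < min_overlap) break;
        int matches = 0;
        for (int k = 0; k < len; ++k) {
            char c1 = s1[d + k], c2 = s2[k];
            if (c1 == c2 && c1 != 'N') ++matches;
        }
        double mm = (double)(len - matches) / (double)len;
        if (mm > max_mismatch_frac) continue;
        if (matches > best_matches) {
            best_matches = matches;
            best_d = d;
            best_len = len;
        }
    }
    if (best_d < 0)
        return List::create(_["ok"] = false);
    std::string out = s1.substr(0, best_d);
    std::vector<int> outq(q1.begin(), q1.begin() + best_d);
    for (int k = 0; k < best_len; ++k) {
        char c1 = s1[best_d + k], c2 = s2[k];
        int a1 = q1[best_d + k], a2 = q2[k];
        if (c1 == c2) {
            out.push_back(c1);
            outq.push_back(std::max(a1, a2));
        } else if (a2 > a1) { // disagreement: higher quality wins, tie -> r1
            out.push_back(c2);
            outq.push_back(a2);
        } else {
            out.push_back(c1);
            outq.push_back(a1);
        }
    }
    for (int k = best_len; k < n2; ++k) {
        out.push_back(s2[k]);
        outq.push_back(q2[k]);
    }
    return List::create(_["ok"] = true, _["merged"] = out,
                        _["quals"] = wrap(outq), _["offset"] = best_d,
                        _["overlap"] = best_len,
                        _["mismatches"] = best_len - best_matches);
}

// Longest read suffix matching an adapter prefix (>= min_match nt, at most
// one mismatch per 10 nt) is removed; returns the number of bases to keep.
// [[Rcpp::export(name = ".trim_adapter_cpp")]]
int trim_adapter_cpp(std::string read, std::string adapter, int min_match) {
    const int n = (int)read.size(), na = (int)adapter.size();
    int kmax = std::min(n, na);
    for (int k = kmax; k >= min_match; --k) {
        int allowed = k / 10, mism = 0;
        bool ok = true;
        for (int t = 0; t < k; ++t) {
            if (read[n - k + t] != adapter[t]) {
                if (++mism > allowed) { ok = false; break; }
            }
        }
        if (ok) return n - k;
    }
    return n;
}
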