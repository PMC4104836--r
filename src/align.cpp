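#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment kernels shared by the pairwise and profile-search
// modules.  Gap convention throughout: a gap of length k costs
// gap_open + gap_extend * (k - 1), i.e. gap_open is the cost of the first
// gapped position.  Residues are 1-based integer codes into the substitution
// matrix (the R side appends an all-zero row/column for the X wildcard).

static const int NEG = INT_MIN / 4;

// Score-only Smith-Waterman; H and Fcol are caller-provided scratch of size
// nb + 1 so the all-pairs driver can reuse allocations.
static int sw_score_core(const int* a, int na, const int* b, int nb,
                         const int* sub, int nsub, int go, int ge,
                         std::vector<int>& H, std::vector<int>& Fcol) {
    std::fill(H.begin(), H.begin() + nb + 1, 0);
    std::fill(Fcol.begin(), Fcol.begin() + nb + 1, NEG);
    int best = 0;
    for (int i = 1; i <= na; ++i) {
        int diag = 0;
        int Erow = NEG;
        int Hleft = 0;
        const int* srow = sub + (size_t)(a[i - 1] - 1) * nsub;
        for (int j = 1; j <= nb; ++j) {
            int f = Fcol[j] - ge;
            int f2 = H[j] - go;
            if (f2 > f) f = f2;
            Fcol[j] = f;
            int e = Erow - ge;
            int e2 = Hleft - go;
            if (e2 > e) e = e2;
            Erow = e;
            int h = diag + srow[b[j - 1] - 1];
            if (f > h) h = f;
            if (e > h) h = e;
            if (h < 0) h = 0;
            diag = H[j];
            H[j] = h;
            Hleft = h;
            if (h > best) best = h;
        }
    }
    return best;
}

// [[Rcpp::export]]
int cpp_sw_score(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                 int gap_open, int gap_extend) {
    int na = a.size(), nb = b.size();
    if (na == 0 || nb == 0) return 0;
    std::vector<int> H(nb + 1), F(nb + 1);
    return sw_score_core(&a[0], na, &b[0], nb, &sub[0], sub.nrow(),
                         gap_open, gap_extend, H, F);
}

// Scores for every unordered pair i < j, in column-major pair order
// (1,2),(1,3),...,(1,n),(2,3),...  Sequences are a list of integer vectors.
// [[Rcpp::export]]
IntegerVector cpp_sw_all_pairs(List seqs, IntegerMatrix sub,
                               int gap_open, int gap_extend) {
    int n = seqs.size();
    std::vector<std::vector<int> > xs(n);
    int maxlen = 1;
    for (int i = 0; i < n; ++i) {
        IntegerVector v = seqs[i];
        xs[i] = std::vector<int>(v.begin(), v.end());
        if ((int)xs[i].size() > maxlen) maxlen = xs[i].size();
    }
    std::vector<int> H(maxlen + 1), F(maxlen + 1);
    R_xlen_t npair = (R_xlen_t)n * (n - 1) / 2;
    IntegerVector out(npair);
    R_xlen_t k = 0;
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            out[k++] = sw_score_core(xs[i].data(), xs[i].size(),
                                     xs[j].data(), xs[j].size(),
                                     &sub[0], sub.nrow(), gap_open, gap_extend,
                                     H, F);
        }
        Rcpp::checkUserInterrupt();
    }
    return out;
}

// Full Smith-Waterman with traceback.  End cell: maximum score, first reached
// in row-major order (smallest i, then smallest j).  Traceback tie-break:
// diagonal > up (gap in b) > left (gap in a).
// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
    int na = a.size(), nb = b.size();
    int nsub = sub.nrow();
    std::vector<int> H((size_t)(na + 1) * (nb + 1), 0);
    std::vector<int> E((size_t)(na + 1) * (nb + 1), NEG);
    std::vector<int> F((size_t)(na + 1) * (nb + 1), NEG);
    size_t W = nb + 1;
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= na; ++i) {
        const int* srow = &sub[0] + (size_t)(a[i - 1] - 1) * nsub;
        for (int j = 1; j <= nb; ++j) {
            size_t c = i * W + j, up = (i - 1) * W + j, lf = i * W + j - 1;
            int f = F[up] - gap_extend, f2 = H[up] - gap_open;
            F[c] = f2 > f ? f2 : f;
            int e = E[lf] - gap_extend, e2 = H[lf] - gap_open;
            E[c] = e2 > e ? e2 : e;
            int h = H[(i - 1) * W + j - 1] + srow[b[j - 1] - 1];
            if (F[c] > h) h = F[c];
            if (E[c] > h) h = E[c];
            if (h < 0) h = 0;
            H[c] = h;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    if (best <= 0) {
        return List::create(_["score"] = 0, _["a_start"] = NA_INTEGER,
                            _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                            _["b_end"] = NA_INTEGER, _["matches"] = 0,
                            _["mismatches"] = 0, _["gap_opens"] = 0,
                            _["gaps"] = 0, _["length"] = 0);
    }
    int i = bi, j = bj, state = 0; // 0 = H, 1 = F (up), 2 = E (left)
    int matches = 0, mismatches = 0, gaps = 0, gapopens = 0, len = 0;
    int a_end = bi, b_end = bj, a_start = bi, b_start = bj;
    while (i > 0 && j > 0) {
        size_t c = i * W + j;
        if (state == 0) {
            if (H[c] == 0) break;
            const int s = sub[(size_t)(a[i - 1] - 1) * nsub + (b[j - 1] - 1)];
            if (H[c] == H[(i - 1) * W + j - 1] + s) {
                if (a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
                ++len; a_start = i; b_start = j; --i; --j;
            } else if (H[c] == F[c]) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) { // gap in b, consume a
            ++gaps; ++len; a_start = i;
            size_t up = (i - 1) * W + j;
            if (F[c] == F[up] - gap_extend && i > 1) {
                --i;
            } else {
                ++gapopens; --i; state = 0;
            }
        } else { // gap in a, consume b
            ++gaps; ++len; b_start = j;
            size_t lf = i * W + j - 1;
            if (E[c] == E[lf] - gap_extend && j > 1) {
                --j;
            } else {
                ++gapopens; --j; state = 0;
            }
        }
    }
    return List::create(_["score"] = best, _["a_start"] = a_start,
                        _["a_end"] = a_end, _["b_start"] = b_start,
                        _["b_end"] = b_end, _["matches"] = matches,
                        _["mismatches"] = mismatches, _["gap_opens"] = gapopens,
                        _["gaps"] = gaps, _["length"] = len);
}

// First centroid (1-based index) whose local-alignment identity with `query`
// is >= threshold; 0 if none.  Identity = matches / alignment columns
// (gap columns included), matching align_local().
// [[Rcpp::export]]
int cpp_greedy_first_match(IntegerVector query, List centroids,
                           IntegerMatrix sub, int gap_open, int gap_extend,
                           double threshold) {
    int n = centroids.size();
    for (int k = 0; k < n; ++k) {
        IntegerVector c = centroids[k];
        List al = cpp_sw_align(query, c, sub, gap_open, gap_extend);
        int len = as<int>(al["length"]);
        if (len > 0) {
            double ident = as<int>(al["matches"]) / (double)len;
            if (ident >= threshold) return k + 1;
        }
        if (k % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return 0;
}

// Profile (PSSM) vs sequence local alignment with affine gaps and traceback.
// pssm: L x A matrix of per-column residue scores (bits); target codes index
// its columns.  Returns the optimal score and the 1-based envelope on the
// target plus the profile span.
// [[Rcpp::export]]
List cpp_pssm_align(NumericMatrix pssm, IntegerVector t,
                    double gap_open, double gap_extend) {
    int L = pssm.nrow(), nt = t.size();
    const double DNEG = -1e18;
    std::vector<double> H((size_t)(L + 1) * (nt + 1), 0.0);
    std::vector<double> E((size_t)(L + 1) * (nt + 1), DNEG);
    std::vector<double> F((size_t)(L + 1) * (nt + 1), DNEG);
    size_t W = nt + 1;
    double best = 0.0; int bi = 0, bj = 0;
    for (int i = 1; i <= L; ++i) {
        for (int j = 1; j <= nt; ++j) {
            size_t c = i * W + j, up = (i - 1) * W + j, lf = i * W + j - 1;
            double f = F[up] - gap_extend, f2 = H[up] - gap_open;
            F[c] = f2 > f ? f2 : f;
            double e = E[lf] - gap_extend, e2 = H[lf] - gap_open;
            E[c] = e2 > e ? e2 : e;
            double h = H[(i - 1) * W + j - 1] + pssm(i - 1, t[j - 1] - 1);
            if (F[c] > h) h = F[c];
            if (E[c] > h) h = E[c];
            if (h < 0) h = 0;
            H[c] = h;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    if (best <= 0.0) {
        return List::create(_["score"] = 0.0, _["t_start"] = NA_INTEGER,
                            _["t_end"] = NA_INTEGER, _["q_start"] = NA_INTEGER,
                            _["q_end"] = NA_INTEGER);
    }
    int i = bi, j = bj, state = 0;
    int t_start = bj, q_start = bi;
    const double eps = 1e-9;
    while (i > 0 && j > 0) {
        size_t c = i * W + j;
        if (state == 0) {
            if (H[c] <= eps && H[c] >= -eps && H[c] == 0.0) break;
            double d = H[(i - 1) * W + j - 1] + pssm(i - 1, t[j - 1] - 1);
            if (std::abs(H[c] - d) < eps) {
                q_start = i; t_start = j; --i; --j;
                if (i == 0 || j == 0) break;
                if (H[i * W + j] == 0.0) break;
            } else if (std::abs(H[c] - F[c]) < eps) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) { // gap in target, consume profile column
            q_start = i;
            size_t up = (i - 1) * W + j;
            if (std::abs(F[c] - (F[up] - gap_extend)) < eps && i > 1) --i;
            else { --i; state = 0; }
        } else { // consume target residue
            t_start = j;
            size_t lf = i * W + j - 1;
            if (std::abs(E[c] - (E[lf] - gap_extend)) < eps && j > 1) --j;
            else { --j; state = 0; }
        }
    }
    return List::create(_["score"] = best, _["t_start"] = t_start,
                        _["t_end"] = bj, _["q_start"] = q_start,
                        _["q_end"] = bi);
}
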