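#include <Rcpp.h>
using namespace Rcpp;

// Base-pair predicates on the DNA alphabet (T stands for U).
static inline bool wc(char a, char b) {
    return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G');
}
static inline bool gu(char a, char b) {
    return (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}
static inline bool canpair(char a, char b, bool allow_gu) {
    return wc(a, b) || (allow_gu && gu(a, b));
}

// Exhaustive search for the best two-segment hairpin inside seq[from..to]
// (1-based, inclusive): an outer arm of s1 contiguous pairs anchored at the
// outermost pair (i1, j1), an internal loop with >= min_pocket unpaired nt on
// each strand (the ASE pocket), an inner arm of s2 pairs anchored at
// (i2, j2), and an apical loop of >= min_loop nt.  Pairs are WC or G:U.
// Objective: maximize s1 + s2; ties: larger s1, smaller i1, larger j1,
// smaller i2, larger j2.  Returns integer vector
// c(i1, j1, s1, i2, j2, s2) or integer(0) when no placement satisfies
// s1, s2 >= min_arm and s1 + s2 >= min_total.
// [[Rcpp::export]]
IntegerVector cpp_hairpin_search(std::string seq, int from, int to,
                                 int min_arm, int min_total, int min_pocket,
                                 int min_loop, bool allow_gu) {
    int n = to - from + 1;
    if (n < 2 * min_total + 2 * min_pocket + min_loop) return IntegerVector(0);
    const char *s = seq.c_str() + (from - 1);  // 0-based local window

    // run[i][j]: length of the contiguous pairing run anchored at the
    // outermost pair (i, j), extending inwards.
    std::vector<std::vector<short>> run(n, std::vector<short>(n, 0));
    for (int span = 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            if (canpair(s[i], s[j], allow_gu)) {
                run[i][j] = (i + 1 <= j - 1 && span >= 2)
                                ? (short)(run[i + 1][j - 1] + 1)
                                : 1;
            }
        }
    }

    // Usable inner-arm length at anchor (i2, j2), capped by the apical loop.
    // s2 <= (j2 - i2 + 1 - min_loop) / 2.
    std::vector<std::vector<short>> s2m(n, std::vector<short>(n, 0));
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            int cap = (j - i + 1 - min_loop) / 2;
            int v = run[i][j] < cap ? run[i][j] : cap;
            if (v >= min_arm) s2m[i][j] = (short)v;
        }
    }
    // best[a][b] = max over i2 >= a, j2 <= b of s2m[i2][j2].
    std::vector<std::vector<short>> best(n + 1, std::vector<short>(n + 1, 0));
    for (int a = n - 1; a >= 0; --a) {
        for (int b = 0; b < n; ++b) {
            short v = s2m[a][b];
            if (best[a + 1][b] > v) v = best[a + 1][b];
            if (b > 0 && best[a][b - 1] > v) v = best[a][b - 1];
            best[a][b] = v;
        }
    }

    int best_total = 0;
    for (int i1 = 0; i1 < n; ++i1) {
        for (int j1 = i1 + 1; j1 < n; ++j1) {
            int r1 = run[i1][j1];
            if (r1 < min_arm) continue;
            for (int s1 = min_arm; s1 <= r1; ++s1) {
                int a = i1 + s1 + min_pocket;       // min i2
                int b = j1 - s1 - min_pocket;       // max j2
                if (a >= n || b < 0 || a > b) continue;
                int s2 = best[a][b];
                if (s2 >= min_arm && s1 + s2 > best_total)
                    best_total = s1 + s2;
            }
        }
    }
    if (best_total < min_total) return IntegerVector(0);

    // Second pass: apply the deterministic tie-break ordering.
    int Bi1 = -1, Bj1 = -1, Bs1 = -1, Bi2 = -1, Bj2 = -1, Bs2 = -1;
    for (int s1 = best_total - min_arm; s1 >= min_arm; --s1) {
        int s2 = best_total - s1;
        if (s2 < min_arm) continue;
        for (int i1 = 0; i1 < n && Bi1 < 0; ++i1) {
            for (int j1 = n - 1; j1 > i1; --j1) {
                if (run[i1][j1] < s1) continue;
                int a = i1 + s1 + min_pocket;
                int b = j1 - s1 - min_pocket;
                if (a >= n || b < 0 || a > b) continue;
                if (best[a][b] < s2) continue;
                // find inner anchor: smallest i2, then largest j2.
                for (int i2 = a; i2 < n && Bi1 < 0; ++i2) {
                    for (int j2 = b; j2 > i2; --j2) {
                        if (s2m[i2][j2] >= s2) {
                            Bi1 = i1; Bj1 = j1; Bs1 = s1;
                            Bi2 = i2; Bj2 = j2; Bs2 = s2;
                            break;
                        }
                    }
                }
                if (Bi1 >= 0) break;
            }
        }
        if (Bi1 >= 0) break;
    }
    if (Bi1 < 0) return IntegerVector(0);  // unreachable, defensive
    IntegerVector out = IntegerVector::create(
        Bi1 + from, Bj1 + from, Bs1, Bi2 + from, Bj2 + from, Bs2);
    out.names() = CharacterVector::create("i1", "j1", "s1", "i2", "j2", "s2");
    return out;
}

// Anchored antisense duplex scan for C/D box guides.  The guide 3' end sits
// `gap` nt (0..max_gap) upstream of the box start b (1-based in `seq`); the
// duplex extends box-distally while positions pair (WC, or G:U counted as a
// wobble up to max_wobble), staying inside the `window` nt upstream of the
// box.  One row per (gap, target anchor) with length >= min_len:
// guide_start, guide_end, target_start, target_end, length, wobbles, gap.
// [[Rcpp::export]]
IntegerMatrix cpp_cd_duplex_scan(std::string seq, int box_start, int window,
                                 int max_gap, std::string target, int min_len,
                                 int max_wobble) {
    int m = (int)target.size();
    std::vector<std::array<int, 7>> hits;
    for (int g = 0; g <= max_gap; ++g) {
        int e = box_start - 1 - g;           // 1-based guide 3' end
        if (e < 1) continue;
        int lo = box_start - window;         // guide must stay >= lo
        if (lo < 1) lo = 1;
        for (int p = 1; p <= m; ++p) {
            int len = 0, wob = 0;
            while (true) {
                int gpos = e - len, tpos = p + len;
                if (gpos < lo || tpos > m) break;
                char a = seq[gpos - 1], b = target[tpos - 1];
                if (wc(a, b)) { ++len; continue; }
                if (gu(a, b) && wob < max_wobble) { ++wob; ++len; continue; }
                break;
            }
            if (len >= min_len) {
                hits.push_back({e - len + 1, e, p, p + len - 1, len, wob, g});
            }
        }
    }
    IntegerMatrix out((int)hits.size(), 7);
    for (int i = 0; i < (int)hits.size(); ++i)
        for (int k = 0; k < 7; ++k) out(i, k) = hits[i][k];
    colnames(out) = CharacterVector::create(
        "guide_start", "guide_end", "target_start", "target_end",
        "length", "wobbles", "gap");
    return out;
}

// Bipartite H/ACA pocket scan.  For each target position u with target[u]
// == 'T' (the candidate pseudouridine), searches for two duplex segments
// flanking an unpaired U-N dinucleotide: the right pocket strand (window
// [pr_from, pr_to] of seq) pairs target[u-1], target[u-2], ... reading seq
// 5'->3' from some start q; the left pocket strand (window [pl_from, pl_to])
// pairs target[u+2], target[u+3], ... reading seq 3'->5' from some end q'.
// Segment lengths a and b are maximized per side (ties: smallest q, largest
// q').  Rows with a >= min_side, b >= min_side, a + b >= min_total:
// u, a, b, right_start, left_end.
// [[Rcpp::export]]
IntegerMatrix cpp_bipartite_scan(std::string seq, int pl_from, int pl_to,
                                 int pr_from, int pr_to, std::string target,
                                 int min_side, int min_total, bool allow_gu) {
    int m = (int)target.size();
    int n = (int)seq.size();
    std::vector<std::array<int, 5>> hits;
    for (int u = 2; u + 1 <= m; ++u) {
        if (target[u - 1] != 'T') continue;
        int a_best = 0, qa = 0;
        for (int q = pr_from; q <= pr_to && q <= n; ++q) {
            int a = 0;
            while (q + a <= pr_to && u - 1 - a >= 1 &&
                   canpair(seq[q + a - 1], target[u - 2 - a], allow_gu))
                ++a;
            if (a > a_best) { a_best = a; qa = q; }
        }
        int b_best = 0, qb = 0;
        for (int q = pl_to; q >= pl_from && q >= 1; --q) {
            int b = 0;
            while (q - b >= pl_from && u + 2 + b <= m &&
                   canpair(seq[q - b - 1], target[u + 1 + b], allow_gu))
                ++b;
            if (b > b_best) { b_best = b; qb = q; }
        }
        if (a_best >= min_side && b_best >= min_side &&
            a_best + b_best >= min_total)
            hits.push_back({u, a_best, b_best, qa, qb});
    }
    IntegerMatrix out((int)hits.size(), 5);
    for (int i = 0; i < (int)hits.size(); ++i)
        for (int k = 0; k < 5; ++k) out(i, k) = hits[i][k];
    colnames(out) = CharacterVector::create(
        "u", "a", "b", "right_start", "left_end");
    return out;
}
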