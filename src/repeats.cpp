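#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Suffix array by prefix doubling with radix (counting) sort.
// O(n log n); adequate for the multi-hundred-kb texts this package handles.
static void build_suffix_array(const std::vector<int>& s, std::vector<int>& sa) {
    int n = (int)s.size();
    sa.resize(n);
    std::vector<int> rank_(n), tmp(n), cnt;
    int alpha = 0;
    for (int i = 0; i < n; ++i) alpha = std::max(alpha, s[i] + 1);
    cnt.assign(std::max(alpha, n) + 1, 0);
    for (int i = 0; i < n; ++i) cnt[s[i]]++;
    for (int i = 1; i < (int)cnt.size(); ++i) cnt[i] += cnt[i - 1];
    for (int i = n - 1; i >= 0; --i) sa[--cnt[s[i]]] = i;
    rank_[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
        rank_[sa[i]] = rank_[sa[i - 1]] + (s[sa[i]] != s[sa[i - 1]] ? 1 : 0);
    std::vector<int> sa2(n), rank2(n);
    for (int k = 1; k < n; k <<= 1) {
        // sort by second key: suffixes starting at n-k..n-1 have empty second key
        int p = 0;
        for (int i = n - k; i < n; ++i) sa2[p++] = i;
        for (int i = 0; i < n; ++i)
            if (sa[i] >= k) sa2[p++] = sa[i] - k;
        // stable counting sort by first key (rank_)
        int classes = rank_[sa[n - 1]] + 1;
        cnt.assign(classes + 1, 0);
        for (int i = 0; i < n; ++i) cnt[rank_[i]]++;
        for (int i = 1; i <= classes; ++i) cnt[i] += cnt[i - 1];
        for (int i = n - 1; i >= 0; --i) sa[--cnt[rank_[sa2[i]]]] = sa2[i];
        // recompute ranks
        rank2[sa[0]] = 0;
        for (int i = 1; i < n; ++i) {
            int a = sa[i], b = sa[i - 1];
            int ra2 = (a + k < n) ? rank_[a + k] : -1;
            int rb2 = (b + k < n) ? rank_[b + k] : -1;
            rank2[a] = rank2[b] + ((rank_[a] != rank_[b] || ra2 != rb2) ? 1 : 0);
        }
        rank_.swap(rank2);
        if (rank_[sa[n - 1]] == n - 1) break;
    }
}

// Kasai's algorithm: lcp[i] = LCP(sa[i-1], sa[i]), lcp[0] = 0.
static void build_lcp(const std::vector<int>& s, const std::vector<int>& sa,
                      std::vector<int>& lcp) {
    int n = (int)s.size();
    std::vector<int> inv(n);
    for (int i = 0; i < n; ++i) inv[sa[i]] = i;
    lcp.assign(n, 0);
    int h = 0;
    for (int i = 0; i < n; ++i) {
        if (inv[i] > 0) {
            int j = sa[inv[i] - 1];
            while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
            lcp[inv[i]] = h;
            if (h > 0) --h;
        } else h = 0;
    }
}

// Enumerate all maximal repeats (left- and right-diverse repeated substrings)
// of length >= min_len in the concatenated text. The text must already
// contain unique separator symbols between biological sequences so that no
// repeat spans a boundary. Returns, per maximal repeat: its length and the
// 0-based start positions of every occurrence in the text.
//
// Right-maximality: every lcp-interval string (taking the interval's lcp
// value as the length) is right-diverse by construction. Left-maximality:
// checked through BWT character diversity over the interval, O(1) per
// interval via a prefix-sum over bwt[i] != bwt[i-1].
// [[Rcpp::export]]
List cpp_maximal_repeats(IntegerVector text, int min_len) {
    int n = text.size();
    if (n < 2 || min_len < 1) return List::create();
    std::vector<int> s(text.begin(), text.end());
    std::vector<int> sa, lcp;
    build_suffix_array(s, sa);
    build_lcp(s, sa, lcp);

    // diversity prefix sums over BWT (char preceding each suffix; start-of-
    // text counts as a unique char)
    std::vector<int> div(n + 1, 0);
    for (int i = 1; i < n; ++i) {
        int a = sa[i] > 0 ? s[sa[i] - 1] : -1;
        int b = sa[i - 1] > 0 ? s[sa[i - 1] - 1] : -2;
        div[i + 1] = div[i] + ((a != b || a == -1) ? 1 : 0);
    }
    // also flag the case where both are start-of-text: impossible (unique)

    std::vector<int> rep_len;
    std::vector<std::vector<int> > rep_occ;

    // stack-based lcp-interval enumeration: entries (lcp, left boundary)
    std::vector<std::pair<int, int> > st;
    st.push_back(std::make_pair(0, 0));
    for (int i = 1; i <= n; ++i) {
        int l = (i < n) ? lcp[i] : 0;
        int left = i - 1;
        while (!st.empty() && st.back().first > l) {
            int ilen = st.back().first;
            left = st.back().second;
            st.pop_back();
            // interval [left, i-1] with string length ilen
            if (ilen >= min_len) {
                // left-diverse if any adjacent BWT pair differs inside it
                if (div[i] - div[left + 1] > 0) {
                    std::vector<int> occ;
                    occ.reserve(i - left);
                    for (int k = left; k < i; ++k) occ.push_back(sa[k]);
                    rep_len.push_back(ilen);
                    rep_occ.push_back(occ);
                }
            }
        }
        if (st.empty() || st.back().first < l)
            st.push_back(std::make_pair(l, left));
    }

    int m = (int)rep_len.size();
    List out(m);
    for (int i = 0; i < m; ++i) {
        out[i] = List::create(Named("len") = rep_len[i],
                              Named("occ") = wrap(rep_occ[i]));
    }
    return out;
}
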