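#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <map>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// CLC-style short-read mapper: k-mer seeding plus banded glocal alignment
// (global in the read, local in the reference). A read is counted only where
// it aligns end-to-end at >= min_sim identity (identity = matches / alignment
// columns); reads whose best score is attained at two or more distinct loci
// are dropped as ambiguous, matching best-hit semantics.

static inline int base_code(char c) {
    switch (c) {
        case 'A': case 'a': return 0;
        case 'C': case 'c': return 1;
        case 'G': case 'g': return 2;
        case 'T': case 't': return 3;
        default: return 4;
    }
}
static inline char code_base(int c) { return "ACGTN"[c]; }

struct Aln {
    int ref = -1;          // 0-based reference index
    int strand = 0;        // 0 = forward, 1 = reverse
    int score = INT32_MIN;
    int ref_start = -1;    // 0-based, inclusive
    int matches = 0;
    int aln_len = 0;
    std::string ops;       // M/X/I/D over the (oriented) read, read 5'->3'
};

struct Candidate { int ref; int diag; int votes; };

// banded DP; returns false if the band never fits inside the reference
static bool banded_align(const std::vector<int>& read,
                         const std::vector<int>& ref,
                         int diag, int band, Aln& out) {
    const int m = (int)read.size();
    const int n = (int)ref.size();
    const int w = 2 * band + 1;
    const int NEG = INT32_MIN / 4;
    std::vector<int> prev(w, NEG), cur(w, NEG);
    std::vector<unsigned char> tb((size_t)m * w, 0); // 1 diag, 2 up(ins), 3 left(del), 4 start
    for (int i = 0; i < m; ++i) {
        int jlo = diag + i - band, jhi = diag + i + band;
        bool any = false;
        for (int j = jlo; j <= jhi; ++j) {
            int b = j - (diag + i) + band; // band column
            cur[b] = NEG;
            if (j < 0 || j >= n) continue;
            int sub = (read[i] == ref[j] && read[i] < 4) ? 1 : -1;
            int best, dir;
            if (i == 0) { best = sub; dir = 4; }
            else {
                // diagonal: prev row, same band column
                best = (prev[b] > NEG ? prev[b] : NEG) + sub; dir = 1;
            }
            // up: gap in reference (insertion in read): prev row, j same
            if (i > 0) {
                int bu = b + 1; // j - (diag+i-1) + band = b+1
                if (bu < w && prev[bu] > NEG && prev[bu] - 1 > best) { best = prev[bu] - 1; dir = 2; }
            }
            // left: gap in read (deletion): same row, j-1
            if (b - 1 >= 0 && cur[b - 1] > NEG && cur[b - 1] - 1 > best) { best = cur[b - 1] - 1; dir = 3; }
            cur[b] = best;
            tb[(size_t)i * w + b] = (unsigned char)dir;
            any = true;
        }
        if (!any) return false;
        prev.swap(cur);
    }
    // best end in last row
    int bestb = -1, best = NEG;
    for (int b = 0; b < w; ++b)
        if (prev[b] > best) { best = prev[b]; bestb = b; }
    if (bestb < 0 || best <= NEG / 2) return false;
    // traceback
    std::string ops;
    int i = m - 1, j = (diag + m - 1) + (bestb - band);
    int matches = 0;
    while (i >= 0) {
        int b = j - (diag + i) + band;
        unsigned char dir = tb[(size_t)i * w + b];
        if (dir == 1 || dir == 4) {
            bool eq = (j >= 0 && j < (int)ref.size() && read[i] == ref[j] && read[i] < 4);
            ops.push_back(eq ? 'M' : 'X');
            if (eq) ++matches;
            --i; --j;
            if (dir == 4) break;
        } else if (dir == 2) { ops.push_back('I'); --i; }
        else if (dir == 3) { ops.push_back('D'); --j; }
        else break;
    }
    std::reverse(ops.begin(), ops.end());
    // a valid mapping anchors the whole read inside the reference: terminal
    // insertions mean the read overhangs its reference span (typically a
    // contig end or a circular origin) and such placements are rejected
    if (ops.empty() || ops.front() == 'I' || ops.back() == 'I') return false;
    out.score = best;
    out.ref_start = j + 1;
    out.matches = matches;
    out.aln_len = (int)ops.size();
    out.ops = ops;
    return true;
}

// [[Rcpp::export]]
List cpp_map_short_reads(CharacterVector reads, CharacterVector refs,
                         int k, double min_sim, double len_frac, int band,
                         int max_candidates) {
    const int nref = refs.size();
    const int nread = reads.size();

    std::vector<std::vector<int> > R(nref);
    for (int r = 0; r < nref; ++r) {
        const char* s = CHAR(STRING_ELT(refs, r));
        int L = (int)LENGTH(STRING_ELT(refs, r));
        R[r].resize(L);
        for (int i = 0; i < L; ++i) R[r][i] = base_code(s[i]);
    }

    // k-mer index over references
    std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > idx;
    idx.reserve(1 << 20);
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int r = 0; r < nref; ++r) {
        uint64_t h = 0; int run = 0;
        for (int i = 0; i < (int)R[r].size(); ++i) {
            int c = R[r][i];
            if (c > 3) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)c) & mask;
            if (++run >= k) idx[h].push_back(std::make_pair(r, i - k + 1));
        }
    }

    IntegerVector out_ref(nread, 0);       // 1-based ref, 0 unmapped, -1 ambiguous
    IntegerVector out_strand(nread, NA_INTEGER); // 1 = +, -1 = -
    IntegerVector out_start(nread, NA_INTEGER);  // 1-based
    NumericVector out_ident(nread, NA_REAL);

    // pileup counts: 5 rows (A,C,G,T,del) per reference
    std::vector<IntegerMatrix> counts;
    for (int r = 0; r < nref; ++r) counts.push_back(IntegerMatrix(5, (int)R[r].size()));
    // insertions keyed by (ref, position-before [0-based], sequence)
    std::map<std::pair<std::pair<int,int>, std::string>, int> ins;

    std::vector<Candidate> cands;
    for (int q = 0; q < nread; ++q) {
        const char* s = CHAR(STRING_ELT(reads, q));
        int m = (int)LENGTH(STRING_ELT(reads, q));
        if (m < k) continue;
        std::vector<int> fwd(m), rev(m);
        for (int i = 0; i < m; ++i) fwd[i] = base_code(s[i]);
        for (int i = 0; i < m; ++i) {
            int c = fwd[m - 1 - i];
            rev[i] = (c < 4) ? 3 - c : 4;
        }
        Aln best, second;
        for (int strand = 0; strand < 2; ++strand) {
            const std::vector<int>& rd = (strand == 0) ? fwd : rev;
            // seed hits -> (ref, diagonal) pairs, clustered within the band
            std::vector<std::pair<int,int> > hits; // (ref, diag)
            int step = std::max(1, k / 2);
            std::vector<int> offs;
            for (int off = 0; off + k <= m; off += step) offs.push_back(off);
            if (offs.empty() || offs.back() != m - k) offs.push_back(m - k);
            for (size_t oi = 0; oi < offs.size(); ++oi) {
                int off = offs[oi];
                uint64_t h = 0; bool ok = true;
                for (int i = 0; i < k; ++i) {
                    if (rd[off + i] > 3) { ok = false; break; }
                    h = (h << 2) | (uint64_t)rd[off + i];
                }
                if (!ok) continue;
                std::unordered_map<uint64_t, std::vector<std::pair<int,int> > >::iterator it = idx.find(h & mask);
                if (it == idx.end()) continue;
                if ((int)it->second.size() > 1000) continue; // hyper-repetitive seed
                for (size_t t = 0; t < it->second.size(); ++t)
                    hits.push_back(std::make_pair(it->second[t].first,
                                                  it->second[t].second - off));
            }
            std::sort(hits.begin(), hits.end());
            cands.clear();
            size_t a0 = 0;
            while (a0 < hits.size()) {
                size_t a1 = a0;
                while (a1 + 1 < hits.size() && hits[a1 + 1].first == hits[a0].first &&
                       hits[a1 + 1].second - hits[a0].second <= band) ++a1;
                Candidate c;
                c.ref = hits[a0].first;
                c.diag = hits[(a0 + a1) / 2].second; // median diagonal of cluster
                c.votes = (int)(a1 - a0 + 1);
                cands.push_back(c);
                a0 = a1 + 1;
            }
            std::sort(cands.begin(), cands.end(),
                      [](const Candidate& a, const Candidate& b) { return a.votes > b.votes; });
            int ncand = std::min((int)cands.size(), max_candidates);
            for (int ci = 0; ci < ncand; ++ci) {
                Aln a;
                if (!banded_align(rd, R[cands[ci].ref], cands[ci].diag, band, a)) continue;
                a.ref = cands[ci].ref; a.strand = strand;
                bool same_locus = (a.ref == best.ref && a.strand == best.strand &&
                                   best.ref_start >= 0 && std::abs(a.ref_start - best.ref_start) <= 2 * band);
                if (a.score > best.score) {
                    if (!same_locus) second = best;
                    best = a;
                } else if (!same_locus && a.score > second.score) {
                    second = a;
                }
            }
        }
        if (best.ref < 0 || best.aln_len == 0) continue;
        double ident = (double)best.matches / (double)best.aln_len;
        double frac = 1.0; // full-read (glocal) alignment by construction
        if (ident < min_sim || frac < len_frac) continue;
        if (second.score == best.score) { out_ref[q] = -1; continue; } // ambiguous
        out_ref[q] = best.ref + 1;
        out_strand[q] = (best.strand == 0) ? 1 : -1;
        out_start[q] = best.ref_start + 1;
        out_ident[q] = ident;
        // add to pileup
        const std::vector<int>& rd = (best.strand == 0) ? fwd : rev;
        int i = 0, j = best.ref_start;
        IntegerMatrix& cm = counts[best.ref];
        std::string pending;
        int pend_pos = -1;
        for (size_t t = 0; t < best.ops.size(); ++t) {
            char op = best.ops[t];
            if (op == 'M' || op == 'X') {
                if (!pending.empty()) {
                    ins[std::make_pair(std::make_pair(best.ref, pend_pos), pending)]++;
                    pending.clear();
                }
                int c = rd[i];
                if (c < 4 && j >= 0 && j < cm.ncol()) cm(c, j)++;
                ++i; ++j;
            } else if (op == 'D') {
                if (!pending.empty()) {
                    ins[std::make_pair(std::make_pair(best.ref, pend_pos), pending)]++;
                    pending.clear();
                }
                if (j >= 0 && j < cm.ncol()) cm(4, j)++;
                ++j;
            } else if (op == 'I') {
                if (pending.empty()) pend_pos = j - 1; // insert after ref pos j-1
                if (rd[i] < 4) pending.push_back(code_base(rd[i]));
                ++i;
            }
        }
        if (!pending.empty())
            ins[std::make_pair(std::make_pair(best.ref, pend_pos), pending)]++;
    }

    // flatten insertions
    int ni = (int)ins.size();
    IntegerVector ins_ref(ni), ins_pos(ni), ins_count(ni);
    CharacterVector ins_seq(ni);
    int t = 0;
    for (std::map<std::pair<std::pair<int,int>, std::string>, int>::iterator it = ins.begin();
         it != ins.end(); ++it, ++t) {
        ins_ref[t] = it->first.first.first + 1;
        ins_pos[t] = it->first.first.second + 1; // 1-based position after which to insert (0 = before start)
        ins_seq[t] = it->first.second;
        ins_count[t] = it->second;
    }

    List pl(nref);
    for (int r = 0; r < nref; ++r) pl[r] = counts[r];
    return List::create(Named("read_ref") = out_ref,
                        Named("read_strand") = out_strand,
                        Named("read_start") = out_start,
                        Named("read_identity") = out_ident,
                        Named("counts") = pl,
                        Named("ins_ref") = ins_ref,
                        Named("ins_pos") = ins_pos,
                        Named("ins_seq") = ins_seq,
                        Named("ins_count") = ins_count);
}
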