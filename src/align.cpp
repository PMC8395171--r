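#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// 2-bit base codes; 4 = ambiguous (N etc.), never matches anything.
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
    }
}

static std::vector<uint8_t> encode_seq(const std::string& s) {
    std::vector<uint8_t> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t)base_code(s[i]);
    return v;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t>& v) {
    std::vector<uint8_t> r(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
        uint8_t b = v[v.size() - 1 - i];
        r[i] = (b < 4) ? (uint8_t)(3 - b) : (uint8_t)4;
    }
    return r;
}

struct Hit {
    int chrom;
    int start;
    char strand;
    int matched;
};

// matched bases of a full-length ungapped placement; ambiguous bases mismatch
static inline int count_matched(const std::vector<uint8_t>& g, int start,
                                const std::vector<uint8_t>& o) {
    int matched = 0;
    for (size_t i = 0; i < o.size(); ++i)
        if (o[i] < 4 && g[start + i] == o[i]) ++matched;
    return matched;
}

// early-abort variant for the exhaustive scan
static inline int count_matched_abort(const std::vector<uint8_t>& g, int start,
                                      const std::vector<uint8_t>& o,
                                      int max_mm) {
    int mm = 0;
    const int m = (int)o.size();
    for (int i = 0; i < m; ++i) {
        if (o[i] >= 4 || g[start + i] != o[i]) {
            if (++mm > max_mm) return -1;
        }
    }
    return m - mm;
}

// Screen a set of oligos against a genome.  mode: seed-and-extend over an
// exact k-mer index (heuristic near the retention threshold) or an
// exhaustive per-diagonal scan (complete).  Coordinates are 0-based
// half-open on the plus strand; minus-strand hits are reported at the
// plus-strand coordinates of the reverse-complement site.  Placements must
// lie fully within a chromosome.
// [[Rcpp::export]]
DataFrame cpp_screen(CharacterVector chrom_names, CharacterVector chrom_seqs,
                     CharacterVector oligo_seqs,
                     int k, int min_match, double min_frac, int max_hits,
                     bool exhaustive) {
    const int n_chrom = chrom_seqs.size();
    std::vector<std::vector<uint8_t> > genome(n_chrom);
    std::vector<std::string> cnames(n_chrom);
    for (int c = 0; c < n_chrom; ++c) {
        genome[c] = encode_seq(as<std::string>(chrom_seqs[c]));
        cnames[c] = as<std::string>(chrom_names[c]);
    }

    // k-mer index over the plus strand of the genome (minus strand is
    // handled by seeding with the reverse complement of the oligo)
    std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > index;
    if (!exhaustive) {
        if (k < 1 || k > 31) stop("seed length k must be in 1..31");
        const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        for (int c = 0; c < n_chrom; ++c) {
            const std::vector<uint8_t>& g = genome[c];
            if ((int)g.size() < k) continue;
            uint64_t h = 0; int valid = 0;
            for (int i = 0; i < (int)g.size(); ++i) {
                if (g[i] < 4) { h = ((h << 2) | g[i]) & mask; ++valid; }
                else { h = 0; valid = 0; }
                if (valid >= k) index[h].push_back(std::make_pair(c, i - k + 1));
            }
        }
    }

    std::vector<int> out_oligo, out_chrom, out_start, out_matched, out_span;
    std::vector<std::string> out_strand;

    const int n_oligo = oligo_seqs.size();
    for (int oi = 0; oi < n_oligo; ++oi) {
        std::string oseq = as<std::string>(oligo_seqs[oi]);
        std::vector<uint8_t> fwd = encode_seq(oseq);
        const int m = (int)fwd.size();
        const int thr = std::max(min_match,
                                 (int)std::ceil(min_frac * m - 1e-9));
        std::vector<uint8_t> rev = revcomp(fwd);
        std::vector<Hit> hits;

        for (int s = 0; s < 2; ++s) {
            const std::vector<uint8_t>& o = (s == 0) ? fwd : rev;
            const char strand = (s == 0) ? '+' : '-';
            if (exhaustive) {
                const int max_mm = m - thr;
                if (max_mm < 0) continue;
                for (int c = 0; c < n_chrom; ++c) {
                    const std::vector<uint8_t>& g = genome[c];
                    const int L = (int)g.size();
                    for (int st = 0; st + m <= L; ++st) {
                        int matched = count_matched_abort(g, st, o, max_mm);
                        if (matched >= thr) {
                            Hit h; h.chrom = c; h.start = st;
                            h.strand = strand; h.matched = matched;
                            hits.push_back(h);
                        }
                    }
                }
            } else {
                if (m < k) continue;
                const uint64_t mask = (1ULL << (2 * k)) - 1;
                // seeds merged per (chrom, diagonal): one full placement each
                std::unordered_set<uint64_t> seen;
                uint64_t h = 0; int valid = 0;
                for (int j = 0; j < m; ++j) {
                    if (o[j] < 4) { h = ((h << 2) | o[j]) & mask; ++valid; }
                    else { h = 0; valid = 0; }
                    if (valid < k) continue;
                    const int joff = j - k + 1;  // k-mer start within oligo
                    std::unordered_map<uint64_t,
                        std::vector<std::pair<int,int> > >::const_iterator it =
                        index.find(h);
                    if (it == index.end()) continue;
                    for (size_t q = 0; q < it->second.size(); ++q) {
                        const int c = it->second[q].first;
                        const int start = it->second[q].second - joff;
                        if (start < 0 || start + m > (int)genome[c].size())
                            continue;
                        uint64_t key = ((uint64_t)c << 33) | (uint64_t)start;
                        if (!seen.insert(key).second) continue;
                        int matched = count_matched(genome[c], start, o);
                        if (matched >= thr) {
                            Hit hh; hh.chrom = c; hh.start = start;
                            hh.strand = strand; hh.matched = matched;
                            hits.push_back(hh);
                        }
                    }
                }
            }
        }

        // best hits first; deterministic tie-break by chromosome name,
        // start, then strand (+ before -)
        std::sort(hits.begin(), hits.end(),
                  [&cnames](const Hit& a, const Hit& b) {
                      if (a.matched != b.matched) return a.matched > b.matched;
                      if (cnames[a.chrom] != cnames[b.chrom])
                          return cnames[a.chrom] < cnames[b.chrom];
                      if (a.start != b.start) return a.start < b.start;
                      return a.strand < b.strand;
                  });
        const int keep = std::min((int)hits.size(), max_hits);
        for (int i = 0; i < keep; ++i) {
            out_oligo.push_back(oi + 1);
            out_chrom.push_back(hits[i].chrom + 1);
            out_start.push_back(hits[i].start);
            out_strand.push_back(std::string(1, hits[i].strand));
            out_matched.push_back(hits[i].matched);
            out_span.push_back(m);
        }
    }

    return DataFrame::create(
        Named("oligo") = wrap(out_oligo),
        Named("chrom_idx") = wrap(out_chrom),
        Named("start") = wrap(out_start),
        Named("strand") = wrap(out_strand),
        Named("matched_bases") = wrap(out_matched),
        Named("span_bp") = wrap(out_span),
        Named("stringsAsFactors") = false);
}
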