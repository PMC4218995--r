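#include <Rcpp.h>
using namespace Rcpp;

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string &s) {
    std::string out(s.rbegin(), s.rend());
    for (size_t k = 0; k < out.size(); ++k) out[k] = comp(out[k]);
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t k = 0; k < seqs.size(); ++k)
        out[k] = revcomp(as<std::string>(seqs[k]));
    return out;
}

// Best ungapped full-length placement of each read against every subject,
// both strands, by exhaustive offset scan with early abandon.
//
// Subjects must be passed sorted by subject id: ties on mismatch count keep
// the first subject encountered, i.e. the lexicographically smallest id;
// within a subject the forward strand and the leftmost offset win ties.
// A read with no placement at <= max_mismatch[k] mismatches gets subject 0.
// [[Rcpp::export]]
List cpp_best_hits(CharacterVector reads, CharacterVector subjects,
                   IntegerVector max_mismatch) {
    const R_xlen_t nr = reads.size(), ns = subjects.size();
    std::vector<std::string> subj(ns);
    for (R_xlen_t s = 0; s < ns; ++s) subj[s] = as<std::string>(subjects[s]);

    IntegerVector subject_idx(nr), mismatches(nr), position(nr), strand(nr);

    for (R_xlen_t k = 0; k < nr; ++k) {
        const std::string fwd = as<std::string>(reads[k]);
        const std::string rev = revcomp(fwd);
        const int w = (int) fwd.size();
        int best = max_mismatch[k] + 1;           // abandon limit
        int bsub = 0, bmm = NA_INTEGER, bpos = NA_INTEGER, bstr = NA_INTEGER;
        bool done = false;

        for (R_xlen_t s = 0; s < ns && !done; ++s) {
            const std::string &ref = subj[s];
            const int L = (int) ref.size();
            if (L < w) continue;
            for (int str = 0; str < 2 && !done; ++str) {
                const char *q = (str == 0 ? fwd : rev).c_str();
                for (int o = 0; o + w <= L; ++o) {
                    int mm = 0;
                    const char *r = ref.c_str() + o;
                    for (int j = 0; j < w; ++j) {
                        if (q[j] != r[j] && ++mm >= best) break;
                    }
                    if (mm < best) {              // strict: first-found wins ties
                        best = mm;
                        bsub = (int) s + 1;
                        bmm  = mm;
                        bpos = o + 1;
                        bstr = (str == 0 ? 1 : -1);
                        if (best == 0) { done = true; break; }
                    }
                }
            }
        }
        subject_idx[k] = bsub;
        mismatches[k]  = bmm;
        position[k]    = bpos;
        strand[k]      = bstr;
    }
    return List::create(_["subject"] = subject_idx, _["mismatches"] = mismatches,
                        _["position"] = position, _["strand"] = strand);
}
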