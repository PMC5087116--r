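#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// Column count layout shared across the package: A, C, G, T, del, other.

// Decode samtools mpileup read-base strings into per-column base counts.
// Grammar handled: '.'/',' = reference base; ACGTacgt = that base (case
// folded); '*' = deletion; 'N'/'n', '>' and '<' = other; '^' consumes the
// following mapping-quality character; '$' consumed; '+NN<seq>'/'-NN<seq>'
// indel suffixes consumed and not counted.  Decoded totals must equal the
// stated depth.
// [[Rcpp::export(name = ".decode_read_bases")]]
IntegerMatrix decode_read_bases(CharacterVector bases, CharacterVector ref,
                                IntegerVector depth, CharacterVector contig,
                                IntegerVector pos) {
    R_xlen_t n = bases.size();
    IntegerMatrix out(n, 6);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *s = CHAR(STRING_ELT(bases, i));
        const char *r = CHAR(STRING_ELT(ref, i));
        char rb = (char) std::toupper((unsigned char) r[0]);
        int cnt[6] = {0, 0, 0, 0, 0, 0};
        int total = 0;
        const char *p = s;
        while (*p) {
            char c = *p;
            if (c == '^') {          // start-of-read marker + mapping quality
                p += (p[1] ? 2 : 1);
                continue;
            }
            if (c == '$') { ++p; continue; }   // end-of-read marker
            if (c == '+' || c == '-') {        // indel suffix: sign, length, seq
                ++p;
                long len = 0;
                bool have_digit = false;
                while (*p >= '0' && *p <= '9') {
                    len = len * 10 + (*p - '0');
                    ++p;
                    have_digit = true;
                }
                if (!have_digit)
                    stop("malformed indel suffix in read-base string at %s:%d",
                         CHAR(STRING_ELT(contig, i)), pos[i]);
                for (long k = 0; k < len && *p; ++k) ++p;
                continue;
            }
            int idx = -1;
            char u = (char) std::toupper((unsigned char) c);
            if (c == '.' || c == ',') u = rb;
            if (u == 'A') idx = 0;
            else if (u == 'C') idx = 1;
            else if (u == 'G') idx = 2;
            else if (u == 'T') idx = 3;
            else if (c == '*') idx = 4;
            else if (c == '>' || c == '<' || u == 'N') idx = 5;
            else
                stop("illegal character '%c' in read-base string at %s:%d",
                     c, CHAR(STRING_ELT(contig, i)), pos[i]);
            ++cnt[idx];
            ++total;
            ++p;
        }
        if (total != depth[i])
            stop("depth mismatch at %s:%d: stated %d, decoded %d",
                 CHAR(STRING_ELT(contig, i)), pos[i], depth[i], total);
        for (int j = 0; j < 6; ++j) out(i, j) = cnt[j];
    }
    return out;
}

// Fill per-column base counts for one mutant's pileup.  mut_code gives the
// mutant genome base per position (0=A,1=C,2=G,3=T,4=N); depth is drawn by
// the caller (vectorised rpois).  Each read reports the genome base with
// probability 1 - error_rate, else uniform over the other three bases.
// N positions always report 'other'.  Error draws use R's RNG stream so
// set.seed() governs reproducibility.
// [[Rcpp::export(name = ".fill_columns")]]
List fill_columns(IntegerVector mut_code, IntegerVector depth,
                  double error_rate) {
    R_xlen_t n = mut_code.size();
    IntegerVector A(no_init(n)), C(no_init(n)), G(no_init(n)),
        T(no_init(n)), other(no_init(n));
    const int *mc = INTEGER(mut_code), *dp = INTEGER(depth);
    int *pa = INTEGER(A), *pc = INTEGER(C), *pg = INTEGER(G),
        *pt = INTEGER(T), *po = INTEGER(other);
    for (R_xlen_t i = 0; i < n; ++i) {
        int d = dp[i];
        int code = mc[i];
        int c[5] = {0, 0, 0, 0, 0};
        if (d > 0) {
            if (code >= 4) {
                c[4] = d;
            } else if (error_rate <= 0.0) {
                c[code] = d;
            } else {
                for (int rd = 0; rd < d; ++rd) {
                    if (unif_rand() < error_rate) {
                        int k = (int) (unif_rand() * 3.0);
                        if (k > 2) k = 2;
                        int b, seen = 0;
                        for (b = 0; b < 4; ++b) {
                            if (b == code) continue;
                            if (seen == k) break;
                            ++seen;
                        }
                        ++c[b];
                    } else {
                        ++c[code];
                    }
                }
            }
        }
        pa[i] = c[0]; pc[i] = c[1]; pg[i] = c[2]; pt[i] = c[3];
        po[i] = c[4];
    }
    return List::create(_["A"] = A, _["C"] = C, _["G"] = G, _["T"] = T,
                        _["other"] = other);
}

// Apply the three-predicate SNV filter to a block of pileup columns.
// ref_code: 0..3 for unmasked upper-case A/C/G/T, -1 for masked or N
// positions (skipped entirely).  A call is emitted where depth >= min_cov
// and the unique highest-count non-reference base reaches min_af of the
// substitution-supporting reads (A+C+G+T).  Returns the callable-base count
// (depth-passing unmasked positions), the callable G/C count, and the call
// rows.  The frequency comparison uses a 1e-9 absolute tolerance on counts
// so exact boundary fractions are kept.
// [[Rcpp::export(name = ".snv_filter")]]
List snv_filter(IntegerVector ref_code, IntegerVector depth,
                IntegerVector A, IntegerVector C,
                IntegerVector G, IntegerVector T,
                int min_cov, double min_af) {
    R_xlen_t n = ref_code.size();
    double callable = 0, callable_gc = 0;
    std::vector<int> idx, alt;
    std::vector<double> freq;
    for (R_xlen_t i = 0; i < n; ++i) {
        int rc = ref_code[i];
        if (rc < 0) continue;
        if (depth[i] < min_cov) continue;
        ++callable;
        if (rc == 1 || rc == 2) ++callable_gc;
        int c[4] = {A[i], C[i], G[i], T[i]};
        int denom = c[0] + c[1] + c[2] + c[3];
        if (denom <= 0) continue;
        int best = -1, bestc = -1;
        bool tie = false;
        for (int b = 0; b < 4; ++b) {
            if (b == rc) continue;
            if (c[b] > bestc) { bestc = c[b]; best = b; tie = false; }
            else if (c[b] == bestc) tie = true;
        }
        if (best < 0 || bestc <= 0 || tie) continue;
        if ((double) bestc + 1e-9 < min_af * (double) denom) continue;
        idx.push_back((int) (i + 1));
        alt.push_back(best);
        freq.push_back((double) bestc / (double) denom);
    }
    return List::create(_["callable"] = callable,
                        _["callable_gc"] = callable_gc,
                        _["idx"] = wrap(idx), _["alt"] = wrap(alt),
                        _["freq"] = wrap(freq));
}
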