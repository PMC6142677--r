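#include <Rcpp.h>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline int base_index(char b) {
  switch (b) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// Simulate reads from one haplotype: substitution errors at error_rate,
// Phred qualities (constant high for correct bases, uniform low band for
// errors), NM = mismatches against the reference. Uses R's RNG throughout
// so set.seed() upstream makes results reproducible.
// [[Rcpp::export]]
List cpp_make_reads(std::string hap, std::string ref, IntegerVector starts,
                    int read_len, double error_rate, int qual_correct,
                    int err_q_lo, int err_q_hi) {
  int n = starts.size();
  CharacterVector seqs(n), quals(n);
  IntegerVector nm(n);
  std::string seq(read_len, 'N'), qual(read_len, '!');
  for (int i = 0; i < n; ++i) {
    int s = starts[i];
    for (int j = 0; j < read_len; ++j) {
      seq[j] = hap[s + j];
      qual[j] = (char)(33 + qual_correct);
    }
    // number of error bases ~ Binomial(read_len, error_rate)
    int ne = (error_rate > 0.0) ? (int)R::rbinom(read_len, error_rate) : 0;
    for (int e = 0; e < ne; ++e) {
      int p = (int)(unif_rand() * read_len);
      if (p >= read_len) p = read_len - 1;
      char orig = seq[p];
      char sub = orig;
      while (sub == orig) sub = BASES[(int)(unif_rand() * 4) % 4];
      seq[p] = sub;
      int q = err_q_lo + (int)(unif_rand() * (err_q_hi - err_q_lo + 1));
      if (q > err_q_hi) q = err_q_hi;
      qual[p] = (char)(33 + q);
    }
    int mism = 0;
    for (int j = 0; j < read_len; ++j)
      if (seq[j] != ref[s + j]) ++mism;
    nm[i] = mism;
    seqs[i] = seq;
    quals[i] = qual;
  }
  return List::create(_["seq"] = seqs, _["qual"] = quals, _["nm"] = nm);
}

// Per-position A/C/G/T counts from aligned records. Positions are 0-based;
// CIGAR ops M/=/X consume read+ref (bases counted when qual >= min_baseq),
// I and S consume read only, D consumes ref only.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(IntegerVector pos, CharacterVector seq,
                         CharacterVector qual, CharacterVector cigar,
                         CharacterVector read_id, int target_len,
                         int min_baseq) {
  int n = pos.size();
  IntegerMatrix counts(target_len, 4);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seq, i));
    const char *q = CHAR(STRING_ELT(qual, i));
    const char *c = CHAR(STRING_ELT(cigar, i));
    int rpos = pos[i]; // reference cursor
    int rdpos = 0;     // read cursor
    int len = 0;
    for (const char *p = c; *p; ++p) {
      if (*p >= '0' && *p <= '9') {
        len = len * 10 + (*p - '0');
        continue;
      }
      char op = *p;
      if (op == 'M' || op == '=' || op == 'X') {
        if (rpos + len > target_len)
          stop("read '%s' overhangs target end",
               std::string(CHAR(STRING_ELT(read_id, i))).c_str());
        for (int j = 0; j < len; ++j) {
          if ((int)q[rdpos + j] - 33 >= min_baseq) {
            int b = base_index(s[rdpos + j]);
            if (b >= 0) counts(rpos + j, b) += 1;
          }
        }
        rpos += len;
        rdpos += len;
      } else if (op == 'I' || op == 'S') {
        rdpos += len;
      } else if (op == 'D') {
        rpos += len;
        if (rpos > target_len)
          stop("read '%s' overhangs target end",
               std::string(CHAR(STRING_ELT(read_id, i))).c_str());
      } else {
        stop("unsupported CIGAR op '%c' in read '%s'", op,
             std::string(CHAR(STRING_ELT(read_id, i))).c_str());
      }
      len = 0;
    }
  }
  return counts;
}

// Arithmetic mean Phred score per quality string (offset 33).
// [[Rcpp::export]]
NumericVector cpp_mean_qual(CharacterVector qual) {
  int n = qual.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(qual, i));
    long sum = 0;
    int len = 0;
    for (const char *p = q; *p; ++p, ++len) sum += (int)(*p) - 33;
    out[i] = len > 0 ? (double)sum / len : NA_REAL;
  }
  return out;
}

// Reference-consuming length of each CIGAR (M/=/X/D ops).
// [[Rcpp::export]]
IntegerVector cpp_cigar_ref_len(CharacterVector cigar) {
  int n = cigar.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *c = CHAR(STRING_ELT(cigar, i));
    int len = 0, tot = 0;
    for (const char *p = c; *p; ++p) {
      if (*p >= '0' && *p <= '9') {
        len = len * 10 + (*p - '0');
      } else {
        if (*p == 'M' || *p == '=' || *p == 'X' || *p == 'D') tot += len;
        len = 0;
      }
    }
    out[i] = tot;
  }
  return out;
}
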