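#include <Rcpp.h>
using namespace Rcpp;

// Elementwise Hamming distance between paired equal-length strings.
// If max_mm >= 0, counting stops early and max_mm + 1 is reported for
// any pair exceeding the bound (sufficient for thresholded screens).
// [[Rcpp::export]]
IntegerVector hamming_pairs(CharacterVector x, CharacterVector y,
                            int max_mm = -1) {
  R_xlen_t n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(x, i));
    const char *b = CHAR(STRING_ELT(y, i));
    int d = 0;
    int j = 0;
    for (; a[j] != '\0' && b[j] != '\0'; ++j) {
      if (a[j] != b[j]) {
        ++d;
        if (max_mm >= 0 && d > max_mm) break;
      }
    }
    if (max_mm < 0 && (a[j] != '\0' || b[j] != '\0'))
      stop("strings in a pair must have equal length");
    out[i] = d;
  }
  return out;
}

// 0-based offset of the first mismatching position per pair (-1 if equal).
// [[Rcpp::export]]
IntegerVector first_mismatch_pairs(CharacterVector x, CharacterVector y) {
  R_xlen_t n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(x, i));
    const char *b = CHAR(STRING_ELT(y, i));
    int off = -1;
    for (int j = 0; a[j] != '\0' && b[j] != '\0'; ++j) {
      if (a[j] != b[j]) { off = j; break; }
    }
    out[i] = off;
  }
  return out;
}

// Length of the prefix that survives trailing low-quality trimming:
// the maximal suffix whose every base has Phred < min_q is removed.
// Qualities are Phred+offset encoded characters.
// [[Rcpp::export]]
IntegerVector trailing_keep_len(CharacterVector qual, int min_q,
                                int offset = 33) {
  R_xlen_t n = qual.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(qual, i));
    int len = (int) strlen(q);
    int keep = len;
    while (keep > 0 && ((int) q[keep - 1]) - offset < min_q) --keep;
    out[i] = keep;
  }
  return out;
}

// Accumulate per-position base-quality sums over mapped reads.
// tag_idx is 1-based into the tag set; every read covers all tag_len
// positions of its tag. Returns an n_tags x tag_len numeric matrix.
// [[Rcpp::export]]
NumericMatrix position_qual_sums(IntegerVector tag_idx, CharacterVector qual,
                                 int n_tags, int tag_len, int offset = 33) {
  NumericMatrix out(n_tags, tag_len);
  R_xlen_t n = tag_idx.size();
  if (qual.size() != n) stop("tag_idx and qual must have equal length");
  for (R_xlen_t i = 0; i < n; ++i) {
    int t = tag_idx[i] - 1;
    if (t < 0 || t >= n_tags) stop("tag index out of range");
    const char *q = CHAR(STRING_ELT(qual, i));
    for (int j = 0; j < tag_len && q[j] != '\0'; ++j)
      out(t, j) += ((int) q[j]) - offset;
  }
  return out;
}

// Plant substitution errors consistent with per-base Phred qualities:
// each base is substituted with probability 10^(-q/10) (q from the
// parallel quality string, Phred+33) and replaced by an N with
// probability n_rate. Uses R's RNG, so results are seed-reproducible.
// [[Rcpp::export]]
CharacterVector mutate_reads(CharacterVector seqs, CharacterVector quals,
                             double n_rate = 0.0) {
  R_xlen_t n = seqs.size();
  if (quals.size() != n) stop("seqs and quals must have equal length");
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  double perr[128];
  for (int q = 0; q < 128; ++q)
    perr[q] = q > 33 ? std::pow(10.0, -((double)(q - 33)) / 10.0) : 1.0;
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    const char *q = CHAR(STRING_ELT(quals, i));
    buf.assign(s);
    for (size_t j = 0; j < buf.size() && q[j] != '\0'; ++j) {
      if (unif_rand() < perr[(int) q[j]]) {
        char cur = buf[j];
        char nb;
        do { nb = bases[(int)(unif_rand() * 4.0) & 3]; } while (nb == cur);
        buf[j] = nb;
      }
      if (n_rate > 0.0 && unif_rand() < n_rate) buf[j] = 'N';
    }
    out[i] = buf;
  }
  return out;
}

// Greedy collapse of markers with identical segregation on shared calls.
// geno: markers x samples integer matrix, 0 = missing, rows already sorted
// by decreasing quality. Two markers co-segregate when they agree at every
// progeny called in both and share at least min_shared such progeny.
// Each marker joins the first (highest-quality) matching representative.
// Returns 1-based representative row index per marker.
// [[Rcpp::export]]
IntegerVector collapse_groups(IntegerMatrix geno, int min_shared) {
  int m = geno.nrow(), n = geno.ncol();
  IntegerVector rep(m);
  std::vector<int> reps;
  reps.reserve(m);
  for (int i = 0; i < m; ++i) {
    int assigned = -1;
    for (size_t k = 0; k < reps.size(); ++k) {
      int r = reps[k];
      int shared = 0;
      bool ok = true;
      for (int j = 0; j < n; ++j) {
        int a = geno(i, j), b = geno(r, j);
        if (a != 0 && b != 0) {
          if (a != b) { ok = false; break; }
          ++shared;
        }
      }
      if (ok && shared >= min_shared) { assigned = r; break; }
    }
    if (assigned < 0) {
      reps.push_back(i);
      assigned = i;
    }
    rep[i] = assigned + 1;
  }
  return rep;
}
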