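#include <Rcpp.h>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// Hamming distance of `read` placed at `pos` on `ref`, with early abandon
// once the count exceeds `thr`. A read 'N' never matches (counts as a
// mismatch even against a reference 'N').
static int placement_mm(const std::string& read, const std::string& ref,
                        size_t pos, int thr) {
  int mm = 0;
  for (size_t j = 0; j < read.size(); ++j) {
    char r = read[j];
    if (r == 'N' || r != ref[pos + j]) {
      if (++mm > thr) return mm;
    }
  }
  return mm;
}

// Best ungapped placement per read over all references and both strands.
// References must be passed pre-sorted in tie-break order (lexicographic by
// family name): scanning family-major, '+' before '-', starts ascending, and
// replacing the incumbent only on a strict mismatch-count improvement yields
// exactly the documented deterministic tie rule.
//
// Returns parallel vectors: ref index (1-based, NA if unmapped), strand
// (0 = '+', 1 = '-'), 0-based start, mismatch count, and a flag for reads
// longer than every reference.
// [[Rcpp::export(name = ".align_core")]]
List align_core(CharacterVector reads, CharacterVector ref_seqs, int max_mm) {
  const int n = reads.size(), nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  for (int k = 0; k < nref; ++k) refs[k] = as<std::string>(ref_seqs[k]);

  IntegerVector out_ref(n, NA_INTEGER), out_strand(n, NA_INTEGER),
                out_start(n, NA_INTEGER), out_mm(n, NA_INTEGER);
  LogicalVector too_long(n);

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const size_t w = fwd.size();
    if (w == 0) { too_long[i] = true; continue; }
    std::string rev = revcomp(fwd);
    bool fits = false;
    int best = max_mm + 1;

    for (int k = 0; k < nref && best > 0; ++k) {
      const std::string& ref = refs[k];
      if (ref.size() < w) continue;
      fits = true;
      const size_t nmax = ref.size() - w;
      for (int strand = 0; strand < 2 && best > 0; ++strand) {
        const std::string& rd = (strand == 0) ? fwd : rev;
        for (size_t pos = 0; pos <= nmax; ++pos) {
          int mm = placement_mm(rd, ref, pos, best - 1);
          if (mm < best) {
            best = mm;
            out_ref[i] = k + 1;
            out_strand[i] = strand;
            out_start[i] = (int)pos;
            out_mm[i] = mm;
            if (best == 0) break;
          }
        }
      }
    }
    too_long[i] = !fits;
  }
  return List::create(_["ref"] = out_ref, _["strand"] = out_strand,
                      _["start"] = out_start, _["mismatches"] = out_mm,
                      _["too_long"] = too_long);
}

// 3' adapter trimming: for each read report the trimmed length. A candidate
// occurrence is a read suffix of length L (min_overlap <= L <= adapter
// length) matching the length-L adapter prefix with at most
// floor(max_error_rate * L) mismatches; the longest qualifying suffix wins.
// [[Rcpp::export(name = ".trim_core")]]
IntegerVector trim_core(CharacterVector reads, std::string adapter,
                        int min_overlap, double max_error_rate) {
  const int n = reads.size();
  const int na = adapter.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const int nr = rd.size();
    int keep = nr;
    const int lmax = std::min(nr, na);
    for (int L = lmax; L >= min_overlap; --L) {
      const int p = nr - L;
      const int allowed = (int)std::floor(max_error_rate * L);
      int mm = 0;
      for (int j = 0; j < L; ++j) {
        if (rd[p + j] != adapter[j] && ++mm > allowed) break;
      }
      if (mm <= allowed) { keep = p; break; }
    }
    out[i] = keep;
  }
  return out;
}
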