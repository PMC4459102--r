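#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// ---- small sequence utilities ------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0; case 'C': case 'c': return 1;
  case 'G': case 'g': return 2; case 'T': case 't': return 3;
  default: return -1;
  }
}

// ---- paired-read merging -----------------------------------------------------

// Overlap-merge mate pairs. For a candidate fragment length f, mate1 covers
// merged positions [0, len1) and reverse-complemented mate2 covers
// [f - len2, f); the overlap is their intersection. Score = matches -
// mismatches over the overlap (N always mismatches); best score wins, ties
// broken toward the longer overlap, then the shorter fragment (collapses
// read-through fully). In the overlap the higher-quality base and its quality
// are kept (ties: mate1).
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mm_frac) {
  int n = seq1.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector overlap(n);
  CharacterVector status(n);

  for (int r = 0; r < n; ++r) {
    std::string s1 = as<std::string>(seq1[r]);
    std::string q1 = as<std::string>(qual1[r]);
    std::string s2 = as<std::string>(seq2[r]);
    std::string q2 = as<std::string>(qual2[r]);
    std::string rc2 = revcomp(s2);
    std::string rq2(q2.rbegin(), q2.rend());
    int l1 = s1.size(), l2 = s2.size();

    int best_f = -1, best_ov = -1, best_mm = 0;
    double best_score = R_NegInf;
    for (int f = 1; f <= l1 + l2 - min_overlap; ++f) {
      int lo = std::max(0, f - l2);
      int hi = std::min(l1, f);
      int ov = hi - lo;
      if (ov < min_overlap) continue;
      int match = 0, mm = 0;
      for (int x = lo; x < hi; ++x) {
        char b1 = s1[x], b2 = rc2[x - (f - l2)];
        if (b1 == b2 && base_code(b1) >= 0) ++match; else ++mm;
      }
      double score = match - mm;
      bool better = score > best_score ||
        (score == best_score && (ov > best_ov ||
                                 (ov == best_ov && f < best_f)));
      if (better) {
        best_score = score; best_f = f; best_ov = ov; best_mm = mm;
      }
    }

    if (best_f < 0 || best_score <= 0 ||
        (double)best_mm / best_ov > max_mm_frac) {
      mseq[r] = NA_STRING; mqual[r] = NA_STRING;
      overlap[r] = NA_INTEGER; status[r] = "unmerged";
      continue;
    }
    int f = best_f;
    std::string ms(f, 'N'), mq(f, '!');
    for (int x = 0; x < f; ++x) {
      bool in1 = x < l1;
      bool in2 = x >= f - l2;
      if (in1 && in2) {
        char c1 = q1[x], c2 = rq2[x - (f - l2)];
        if (c2 > c1) { ms[x] = rc2[x - (f - l2)]; mq[x] = c2; }
        else         { ms[x] = s1[x];             mq[x] = c1; }
      } else if (in1) { ms[x] = s1[x]; mq[x] = q1[x]; }
      else            { ms[x] = rc2[x - (f - l2)]; mq[x] = rq2[x - (f - l2)]; }
    }
    mseq[r] = ms; mqual[r] = mq;
    overlap[r] = best_ov; status[r] = "merged";
  }
  return List::create(_["seq"] = mseq, _["qual"] = mqual,
                      _["overlap"] = overlap, _["status"] = status);
}

// ---- k-mer seeded banded damage-aware mapper ---------------------------------

struct AlnResult {
  bool ok = false;
  double score = R_NegInf;
  int ref_start = -1, ref_end = -1;
  std::string cigar;
};

// Banded affine alignment of `read` against `ref` (extended/doubled reference),
// global in the read, free ref ends, centred on diagonal `diag`
// (ref_pos - read_pos). Damage-aware scoring multiplies the mismatch penalty
// for C(ref)->T(read) by (1 - decay^p5) and for G(ref)->A(read) by
// (1 - decay^p3), p5/p3 = 1-based distance from the aligned sequence's 5'/3'
// end, so terminal deamination-type mismatches are cheap and the discount
// fades into the read interior.
static AlnResult band_align(const std::string& read, const std::string& ref,
                            int diag, int band,
                            bool damage_aware, double decay,
                            double match, double mismatch,
                            double gap_open, double gap_ext) {
  const int m = read.size();
  const int R = ref.size();
  const int W = 2 * band + 1;
  const double NEG = -1e18;
  AlnResult res;

  // state matrices in band coordinates: d = j - (diag + i) + band
  std::vector<double> M((m + 1) * W, NEG), I((m + 1) * W, NEG),
                      D((m + 1) * W, NEG);
  std::vector<uint8_t> tbM((m + 1) * W, 0), tbI((m + 1) * W, 0),
                       tbD((m + 1) * W, 0);
  auto idx = [W](int i, int d) { return i * W + d; };

  for (int d = 0; d < W; ++d) {
    int j = diag + 0 + d - band;
    if (j >= 0 && j <= R) M[idx(0, d)] = 0.0;  // free ref start
  }
  for (int i = 1; i <= m; ++i) {
    char rb = read[i - 1];
    int p5 = i, p3 = m - i + 1;
    for (int d = 0; d < W; ++d) {
      int j = diag + i + d - band;  // ref bases consumed
      if (j < 0 || j > R) continue;
      // M: consume read i, ref j (diagonal, same d in row i-1)
      if (j >= 1) {
        double prev = NEG; uint8_t from = 0;
        double pm = M[idx(i - 1, d)], pi = I[idx(i - 1, d)],
               pd = D[idx(i - 1, d)];
        if (pm >= pi && pm >= pd) { prev = pm; from = 0; }
        else if (pi >= pd)        { prev = pi; from = 1; }
        else                      { prev = pd; from = 2; }
        if (prev > NEG / 2) {
          char qb = ref[j - 1];
          double s;
          if (rb == qb && base_code(rb) >= 0) s = match;
          else {
            s = mismatch;
            if (damage_aware) {
              if ((qb == 'C' || qb == 'c') && (rb == 'T' || rb == 't'))
                s = mismatch * (1.0 - std::pow(decay, (double)p5));
              else if ((qb == 'G' || qb == 'g') && (rb == 'A' || rb == 'a'))
                s = mismatch * (1.0 - std::pow(decay, (double)p3));
            }
          }
          M[idx(i, d)] = prev + s;
          tbM[idx(i, d)] = from;
        }
      }
      // I: consume read base only; cell (i-1, j) is d+1 in row i-1
      if (d + 1 < W) {
        double om = M[idx(i - 1, d + 1)], oi = I[idx(i - 1, d + 1)];
        double vo = om + gap_open, ve = oi + gap_ext;
        if (vo >= ve) { I[idx(i, d)] = vo; tbI[idx(i, d)] = 0; }
        else          { I[idx(i, d)] = ve; tbI[idx(i, d)] = 1; }
      }
      // D: consume ref base only; cell (i, j-1) is d-1 in same row
      if (d - 1 >= 0 && j >= 1) {
        double om = M[idx(i, d - 1)], od = D[idx(i, d - 1)];
        double vo = om + gap_open, ve = od + gap_ext;
        if (vo >= ve) { D[idx(i, d)] = vo; tbD[idx(i, d)] = 0; }
        else          { D[idx(i, d)] = ve; tbD[idx(i, d)] = 1; }
      }
    }
  }

  // best end cell in last row (free ref end), prefer smallest j on ties
  double best = NEG; int bestd = -1; uint8_t best_state = 0;
  for (int d = 0; d < W; ++d) {
    int j = diag + m + d - band;
    if (j < 0 || j > R) continue;
    double vm = M[idx(m, d)], vi = I[idx(m, d)], vd = D[idx(m, d)];
    double v = std::max(vm, std::max(vi, vd));
    if (v > best) {
      best = v; bestd = d;
      best_state = (vm >= vi && vm >= vd) ? 0 : (vi >= vd ? 1 : 2);
    }
  }
  if (bestd < 0 || best <= NEG / 2) return res;

  // traceback
  int i = m, d = bestd;
  uint8_t st = best_state;
  std::string ops;
  while (i > 0) {
    if (st == 0) {            // M
      ops.push_back('M');
      st = tbM[idx(i, d)];
      --i;                    // same d
    } else if (st == 1) {     // I
      ops.push_back('I');
      st = tbI[idx(i, d)] == 0 ? 0 : 1;
      --i; ++d;
    } else {                  // D
      ops.push_back('D');
      st = tbD[idx(i, d)] == 0 ? 0 : 2;
      --d;
    }
  }
  int ref_start = diag + i + d - band;  // i == 0
  int ref_end = diag + m + bestd - band;
  if (ref_start < 0) return res;

  // compress ops (reversed) into CIGAR
  std::string cigar;
  int run = 0; char cur = 0;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    if (*it == cur) ++run;
    else {
      if (run > 0) cigar += std::to_string(run) + cur;
      cur = *it; run = 1;
    }
  }
  if (run > 0) cigar += std::to_string(run) + cur;

  res.ok = true; res.score = best;
  res.ref_start = ref_start; res.ref_end = ref_end;
  res.cigar = cigar;
  return res;
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector seqs, CharacterVector quals,
                   std::string ref, bool circular, bool damage_aware,
                   double decay, double match, double mismatch,
                   double gap_open, double gap_ext, double score_frac,
                   int k, int band, int max_candidates) {
  int L = ref.size();
  std::string ext = circular ? ref + ref : ref;
  const int R = ext.size();

  // k-mer index of the (doubled) reference
  std::unordered_map<uint64_t, std::vector<int>> index;
  if (R >= k) {
    uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (int i = 0; i < R; ++i) {
      int c = base_code(ext[i]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[kmer].push_back(i - k + 1);
    }
  }

  int n = seqs.size();
  LogicalVector mapped(n);
  IntegerVector start(n), end(n);
  CharacterVector strand(n), cigar(n), seq_ref(n), qual_ref(n);
  NumericVector score(n);

  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(seqs[r]);
    std::string q = quals.size() == n ? as<std::string>(quals[r])
                                      : std::string(fwd.size(), 'F');
    int m = fwd.size();
    AlnResult best;
    char best_strand = '+';

    for (int o = 0; o < 2; ++o) {
      std::string s = (o == 0) ? fwd : revcomp(fwd);
      if (m < k) break;
      // diagonal voting
      std::unordered_map<int, int> votes;
      uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
      int run = 0;
      for (int i = 0; i < m; ++i) {
        int c = base_code(s[i]);
        if (c < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          auto it = index.find(kmer);
          if (it != index.end())
            for (int pos : it->second) votes[pos - (i - k + 1)]++;
        }
      }
      if (votes.empty()) continue;
      std::vector<std::pair<int, int>> diags(votes.begin(), votes.end());
      std::sort(diags.begin(), diags.end(),
                [](const std::pair<int, int>& a, const std::pair<int, int>& b) {
                  return a.second != b.second ? a.second > b.second
                                              : a.first < b.first;
                });
      std::vector<int> chosen;
      for (auto& dv : diags) {
        bool close = false;
        for (int c : chosen)
          if (std::abs(c - dv.first) <= band) { close = true; break; }
        if (!close) chosen.push_back(dv.first);
        if ((int)chosen.size() >= max_candidates) break;
      }
      for (int diag : chosen) {
        AlnResult a = band_align(s, ext, diag, band, damage_aware, decay,
                                 match, mismatch, gap_open, gap_ext);
        if (a.ok && a.score > best.score) {
          best = a; best_strand = (o == 0) ? '+' : '-';
        }
      }
    }

    if (!best.ok || best.score < score_frac * m) {
      mapped[r] = false;
      start[r] = NA_INTEGER; end[r] = NA_INTEGER;
      strand[r] = NA_STRING; cigar[r] = NA_STRING;
      seq_ref[r] = NA_STRING; qual_ref[r] = NA_STRING;
      score[r] = NA_REAL;
      continue;
    }
    int s0 = best.ref_start, e0 = best.ref_end;
    if (circular && s0 >= L) { s0 -= L; e0 -= L; }
    mapped[r] = true;
    start[r] = s0; end[r] = e0;
    strand[r] = std::string(1, best_strand);
    cigar[r] = best.cigar;
    score[r] = best.score;
    if (best_strand == '+') { seq_ref[r] = fwd; qual_ref[r] = q; }
    else {
      seq_ref[r] = revcomp(fwd);
      std::string rq(q.rbegin(), q.rend());
      qual_ref[r] = rq;
    }
  }
  return List::create(_["mapped"] = mapped, _["start"] = start,
                      _["end"] = end, _["strand"] = strand,
                      _["score"] = score, _["cigar"] = cigar,
                      _["seq"] = seq_ref, _["qual"] = qual_ref);
}

// ---- pileup ------------------------------------------------------------------

// Per-position base counts (rows A,C,G,T) from reference-oriented aligned
// sequences; positions taken modulo L when circular.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(IntegerVector starts, CharacterVector cigars,
                         CharacterVector seqs, int L, bool circular) {
  IntegerMatrix counts(4, L);
  int n = starts.size();
  for (int r = 0; r < n; ++r) {
    if (starts[r] == NA_INTEGER) continue;
    std::string cig = as<std::string>(cigars[r]);
    std::string s = as<std::string>(seqs[r]);
    int refoff = 0, readoff = 0;
    size_t i = 0;
    while (i < cig.size()) {
      int len = 0;
      while (i < cig.size() && isdigit(cig[i])) len = len * 10 + (cig[i++] - '0');
      char op = cig[i++];
      if (op == 'M') {
        for (int x = 0; x < len; ++x) {
          int p = starts[r] + refoff + x;
          if (circular) p %= L;
          if (p < 0 || p >= L) continue;
          int c = base_code(s[readoff + x]);
          if (c >= 0) counts(c, p)++;
        }
        refoff += len; readoff += len;
      } else if (op == 'I') readoff += len;
      else if (op == 'D') refoff += len;
    }
  }
  return counts;
}

// ---- terminal misincorporation counting --------------------------------------

// Counts of (reference base -> read base) pairs at the first K positions from
// the read 5' and 3' ends, in READ orientation: for '-' strand records both
// bases are complemented and positions measured from the stored sequence's
// far end. Returns two integer vectors of length K*16 laid out as
// (position-1)*16 + ref*4 + read (A,C,G,T = 0..3).
// [[Rcpp::export]]
List cpp_damage_counts(IntegerVector starts, CharacterVector cigars,
                       CharacterVector seqs, CharacterVector strands,
                       std::string ref, int K, bool circular) {
  int L = ref.size();
  IntegerVector c5(K * 16, 0), c3(K * 16, 0);
  int n = starts.size();
  for (int r = 0; r < n; ++r) {
    if (starts[r] == NA_INTEGER) continue;
    std::string cig = as<std::string>(cigars[r]);
    std::string s = as<std::string>(seqs[r]);
    bool minus = as<std::string>(strands[r]) == "-";
    int m = s.size();
    int refoff = 0, readoff = 0;
    size_t i = 0;
    while (i < cig.size()) {
      int len = 0;
      while (i < cig.size() && isdigit(cig[i])) len = len * 10 + (cig[i++] - '0');
      char op = cig[i++];
      if (op == 'M') {
        for (int x = 0; x < len; ++x) {
          int p = starts[r] + refoff + x;
          if (circular) p %= L;
          if (p < 0 || p >= L) continue;
          char X = ref[p], Y = s[readoff + x];
          if (minus) { X = comp_base(X); Y = comp_base(Y); }
          int xc = base_code(X), yc = base_code(Y);
          if (xc < 0 || yc < 0) continue;
          int p5 = minus ? (m - (readoff + x)) : (readoff + x + 1);
          int p3 = minus ? (readoff + x + 1) : (m - (readoff + x));
          if (p5 <= K) c5[(p5 - 1) * 16 + xc * 4 + yc]++;
          if (p3 <= K) c3[(p3 - 1) * 16 + xc * 4 + yc]++;
        }
        refoff += len; readoff += len;
      } else if (op == 'I') readoff += len;
      else if (op == 'D') refoff += len;
    }
  }
  return List::create(_["five"] = c5, _["three"] = c3);
}

// ---- deamination simulator ---------------------------------------------------

// Apply overhang-restricted cytosine deamination to read-oriented fragment
// sequences. sense: 0 = template strand of a double-strand library (C->T at
// rate decay^p5*dss + (1-decay^p5)*dds), 1 = complementary strand (G->A at
// the same rate in distance-from-3' p3), 2 = single-strand protocol (C->T,
// overhang probability combined over both ends). Uses R's RNG.
// [[Rcpp::export]]
List cpp_apply_damage(CharacterVector seqs, IntegerVector sense,
                      double decay, double dss, double dds) {
  int n = seqs.size();
  CharacterVector out(n);
  List positions(n);
  RNGScope scope;
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int m = s.size();
    std::vector<int> hit;
    int sn = sense[r];
    for (int i = 0; i < m; ++i) {
      double p5 = std::pow(decay, (double)(i + 1));
      double p3 = std::pow(decay, (double)(m - i));
      double rate;
      char target, to;
      if (sn == 0) { rate = p5 * dss + (1 - p5) * dds; target = 'C'; to = 'T'; }
      else if (sn == 1) { rate = p3 * dss + (1 - p3) * dds; target = 'G'; to = 'A'; }
      else {
        double pss = 1.0 - (1.0 - p5) * (1.0 - p3);
        rate = pss * dss + (1 - pss) * dds; target = 'C'; to = 'T';
      }
      if (s[i] == target && rate > 0 && unif_rand() < rate) {
        s[i] = to;
        hit.push_back(i + 1);
      }
    }
    out[r] = s;
    positions[r] = IntegerVector(hit.begin(), hit.end());
  }
  return List::create(_["seq"] = out, _["positions"] = positions);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
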