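// Core compute kernels: seed-and-extend banded local alignment against a
// doubled (circularised) reference, quality-filtered pileup, per-read base
// extraction for phasing, and homopolymer-run read lengths for length
// heteroplasmy.  Coordinates entering/leaving R are 1-based on the circle.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int baseIdx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'T': c = 'A'; break;
    case 'C': c = 'G'; break; case 'G': c = 'C'; break;
    default: break;
    }
  }
  return r;
}

// ---- k-mer index ---------------------------------------------------------

struct KmerIndex {
  int k;
  std::unordered_map<uint32_t, std::vector<int32_t>> map;
};

static bool encodeKmer(const std::string& s, int pos, int k, uint32_t& out) {
  uint32_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = baseIdx(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint32_t)b;
  }
  out = v;
  return true;
}

static void buildIndex(const std::string& ref, int k, KmerIndex& idx) {
  idx.k = k;
  idx.map.clear();
  int n = (int)ref.size() - k;
  idx.map.reserve(n > 0 ? n : 1);
  for (int p = 0; p <= n; ++p) {
    uint32_t v;
    if (encodeKmer(ref, p, k, v)) {
      auto& vec = idx.map[v];
      if (vec.size() < 128) vec.push_back(p);
    }
  }
}

// ---- banded affine local alignment ---------------------------------------

struct AlnResult {
  bool ok = false;
  int score = 0;
  int pos0 = 0;          // 0-based start on doubled reference
  int matches = 0;
  int aln_cols = 0;      // columns consuming reference (M + D)
  int read_aligned = 0;  // read bases aligned (M + I)
  std::string cigar;
};

// Align full read locally within the band around diagonal D (read offset 0
// maps near reference offset D on the doubled reference).  Scoring: match
// +1, mismatch -1, gap open+extend for the first gap base, extend for each
// further base (defaults 2 and 1).
static AlnResult bandedAlign(const std::string& read, const std::string& ref,
                             int D, int B,
                             int match, int mismatch,
                             int gapOpen, int gapExt) {
  AlnResult res;
  const int m = (int)read.size();
  const int width = 2 * B + 1;
  const int NEG = -1000000;
  const int openCost = gapOpen + gapExt;
  if (D - B < 0 || D + m + B >= (int)ref.size()) return res;

  std::vector<int> Hprev(width, 0), Hcur(width, 0);
  std::vector<int> Fprev(width, NEG), Fcur(width, NEG);
  // traceback: per cell byte; bits 0-1: H src (0 local start, 1 diag, 2 E, 3 F)
  // bit 2: E from extend; bit 3: F from extend
  std::vector<uint8_t> tb((size_t)(m + 1) * width, 0);

  int best = 0, bi = 0, br = 0;
  for (int i = 1; i <= m; ++i) {
    int E = NEG;         // gap in read (ref consumed), scans left to right
    uint8_t eExt = 0;
    for (int r = 0; r < width; ++r) {
      const int j = i + r;              // column index, refpos = D - B + j - 1
      const int refp = D - B + j - 1;
      uint8_t t = 0;
      // E: from (i, r-1)
      int eOpen = (r > 0 ? Hcur[r - 1] : NEG) - openCost;
      int eExtS = E - gapExt;
      if (r == 0) { E = NEG; eExt = 0; }
      else if (eOpen >= eExtS) { E = eOpen; eExt = 0; }
      else { E = eExtS; eExt = 1; }
      // F: from (i-1, r+1)
      int fOpen = (r < width - 1 ? Hprev[r + 1] : NEG) - openCost;
      int fExtS = (r < width - 1 ? Fprev[r + 1] : NEG) - gapExt;
      int F; uint8_t fExt;
      if (fOpen >= fExtS) { F = fOpen; fExt = 0; }
      else { F = fExtS; fExt = 1; }
      Fcur[r] = F;
      // H
      int sub = (baseIdx(read[i - 1]) >= 0 &&
                 read[i - 1] == ref[refp]) ? match : mismatch;
      int diag = Hprev[r] + sub;   // (i-1, j-1) keeps r
      int h = 0; uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (E > h) { h = E; src = 2; }
      if (F > h) { h = F; src = 3; }
      t = src | (eExt << 2) | (fExt << 3);
      Hcur[r] = h;
      tb[(size_t)i * width + r] = t;
      if (h > best) { best = h; bi = i; br = r; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  if (best <= 0) return res;

  // traceback
  std::string ops;  // reversed
  int i = bi, r = br;
  int endI = bi;
  int state = 0;  // 0 = H
  while (true) {
    uint8_t t = tb[(size_t)i * width + r];
    if (state == 0) {
      uint8_t src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        const int refp = D - B + (i + r) - 1;
        ops.push_back(read[i - 1] == ref[refp] ? '=' : 'X');
        i -= 1;  // r unchanged
        if (i == 0) break;
      } else if (src == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) {  // E: ref consumed, move (i, r-1)
      ops.push_back('D');
      uint8_t ext = (tb[(size_t)i * width + r] >> 2) & 1;
      r -= 1;
      if (!ext) state = 0;
      if (r < 0) break;
    } else {  // F: read consumed, move (i-1, r+1)
      ops.push_back('I');
      uint8_t ext = (tb[(size_t)i * width + r] >> 3) & 1;
      i -= 1; r += 1;
      if (!ext) state = 0;
      if (i == 0 || r >= width) break;
    }
  }
  std::reverse(ops.begin(), ops.end());
  const int startI = i;            // read bases before alignment (soft clip)
  const int startJ = i + r;        // first aligned column is startJ + 1
  res.pos0 = D - B + startJ;       // 0-based ref offset of first column
  // build cigar with leading/trailing soft clips
  std::string cig;
  auto addOp = [&cig](int len, char op) {
    if (len > 0) cig += std::to_string(len) + op;
  };
  addOp(startI, 'S');
  int runLen = 0; char runOp = 0;
  int matches = 0, alnCols = 0, readAligned = 0;
  for (char o : ops) {
    char op = (o == '=' || o == 'X') ? 'M' : o;
    if (o == '=') { ++matches; }
    if (op == 'M') { ++alnCols; ++readAligned; }
    else if (op == 'D') { ++alnCols; }
    else { ++readAligned; }
    if (op == runOp) ++runLen;
    else { addOp(runLen, runOp ? runOp : 'M'); runOp = op; runLen = 1; }
  }
  addOp(runLen, runOp);
  addOp(m - endI, 'S');
  res.cigar = cig;
  res.matches = matches;
  res.aln_cols = alnCols;
  res.read_aligned = readAligned;
  res.score = best;
  res.ok = true;
  return res;
}

// collect candidate canonical diagonals (0-based) with seed support
static std::vector<std::pair<int, int>> seedDiagonals(
    const std::string& read, const KmerIndex& idx, int L, int B) {
  const int k = idx.k;
  const int m = (int)read.size();
  std::vector<std::pair<int, int>> out;  // (canonical diag, support)
  if (m < k) return out;
  std::vector<int> diags;
  int nseed = std::min(8, m - k + 1);
  int step = std::max(1, (m - k) / std::max(1, nseed - 1));
  for (int o = 0; o <= m - k; o += step) {
    uint32_t v;
    if (!encodeKmer(read, o, k, v)) continue;
    auto it = idx.map.find(v);
    if (it == idx.map.end()) continue;
    for (int p : it->second) {
      int d = p - o;
      int c = ((d % L) + L) % L;
      diags.push_back(c);
    }
  }
  if (diags.empty()) return out;
  std::sort(diags.begin(), diags.end());
  int cur = diags[0], support = 1;
  for (size_t i = 1; i <= diags.size(); ++i) {
    if (i < diags.size() && diags[i] - cur <= B) {
      ++support;
    } else {
      out.push_back({cur, support});
      if (i < diags.size()) { cur = diags[i]; support = 1; }
    }
  }
  std::sort(out.begin(), out.end(),
            [](const std::pair<int, int>& a, const std::pair<int, int>& b) {
              return a.second > b.second;
            });
  if (out.size() > 6) out.resize(6);
  return out;
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector seqs, CharacterVector quals,
                   std::string refseq, bool circular,
                   double min_len_frac, double min_sim_frac,
                   int k = 15, int band = 8,
                   int match = 1, int mismatch = 1,
                   int gap_open = 2, int gap_ext = 1) {
  const int L = (int)refseq.size();
  std::string ref2 = circular ? refseq + refseq : refseq;
  KmerIndex idx;
  buildIndex(ref2, k, idx);
  const int n = seqs.size();
  IntegerVector status(n), pos(n), score(n), nmatch(n), alncols(n),
      readaln(n);
  CharacterVector cigar(n), strand(n), oseq(n), oqual(n);
  NumericVector lenfrac(n), simfrac(n);

  for (int ii = 0; ii < n; ++ii) {
    std::string fwd = as<std::string>(seqs[ii]);
    std::string q = as<std::string>(quals[ii]);
    std::string rev = revcomp(fwd);
    const int m = (int)fwd.size();
    AlnResult best, second;
    char bestStrand = '+';
    for (int ori = 0; ori < 2; ++ori) {
      const std::string& rd = ori == 0 ? fwd : rev;
      auto cands = seedDiagonals(rd, idx, L, band);
      for (auto& cs : cands) {
        int D = cs.first;
        if (D - band < 0) D += L;                     // stay inside ref2
        if (D + m + band >= (int)ref2.size()) continue;
        AlnResult r = bandedAlign(rd, ref2, D, band, match, -mismatch,
                                  gap_open, gap_ext);
        if (!r.ok) continue;
        if (!best.ok || r.score > best.score) {
          // demote previous best unless same circular locus
          if (best.ok) {
            int d = std::abs(((best.pos0 % L) - (r.pos0 % L)));
            d = std::min(d, L - d);
            if (d > 2 * band) second = best;
          }
          best = r; bestStrand = ori == 0 ? '+' : '-';
        } else if (r.score > second.score || !second.ok) {
          int d = std::abs(((best.pos0 % L) - (r.pos0 % L)));
          d = std::min(d, L - d);
          if (d > 2 * band) second = r;
        }
      }
    }
    if (!best.ok) {
      status[ii] = 3;  // unmapped
      cigar[ii] = ""; strand[ii] = "+"; oseq[ii] = fwd; oqual[ii] = q;
      continue;
    }
    double lf = m > 0 ? (double)best.read_aligned / m : 0.0;
    double sf = best.aln_cols > 0 ? (double)best.matches / best.aln_cols
                                  : 0.0;
    lenfrac[ii] = lf; simfrac[ii] = sf;
    pos[ii] = (best.pos0 % L) + 1;
    score[ii] = best.score;
    nmatch[ii] = best.matches;
    alncols[ii] = best.aln_cols;
    readaln[ii] = best.read_aligned;
    cigar[ii] = best.cigar;
    strand[ii] = bestStrand == '+' ? "+" : "-";
    if (bestStrand == '+') { oseq[ii] = fwd; oqual[ii] = q; }
    else {
      oseq[ii] = rev;
      std::string rq(q.rbegin(), q.rend());
      oqual[ii] = rq;
    }
    if (second.ok && second.score == best.score) {
      status[ii] = 2;  // ambiguous multi-mapper
    } else if (lf + 1e-12 < min_len_frac || sf + 1e-12 < min_sim_frac) {
      status[ii] = 1;  // rejected by fraction thresholds
    } else {
      status[ii] = 0;
    }
  }
  return List::create(
      _["status"] = status, _["pos"] = pos, _["strand"] = strand,
      _["cigar"] = cigar, _["score"] = score, _["matches"] = nmatch,
      _["aln_cols"] = alncols, _["read_aligned"] = readaln,
      _["length_fraction"] = lenfrac, _["similarity_fraction"] = simfrac,
      _["seq"] = oseq, _["qual"] = oqual);
}

// ---- sequencing error injection ------------------------------------------

// Per-base miscalls at error_rate; positions within boost_window bases 3'
// of a homopolymer run >= run_min get error_rate * boost, with the miscall
// biased toward the run's base (prob 0.75) when it differs from the true
// base.  Uses R's RNG, so results are deterministic under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double error_rate,
                               double boost, int boost_window = 3,
                               int run_min = 4) {
  const char BASES[4] = {'A', 'C', 'G', 'T'};
  const int n = seqs.size();
  CharacterVector out(n);
  for (int ii = 0; ii < n; ++ii) {
    std::string s = as<std::string>(seqs[ii]);
    const int m = (int)s.size();
    std::vector<char> runbase(m, 0);  // run base boosting this position
    int runStart = 0;
    for (int i = 1; i <= m; ++i) {
      if (i == m || s[i] != s[runStart]) {
        int runLen = i - runStart;
        if (runLen >= run_min) {
          for (int t = i; t < std::min(m, i + boost_window); ++t) {
            runbase[t] = s[runStart];
          }
        }
        runStart = i;
      }
    }
    for (int i = 0; i < m; ++i) {
      double rate = runbase[i] ? error_rate * boost : error_rate;
      if (R::runif(0, 1) < rate) {
        char truth = s[i];
        char sub;
        if (runbase[i] && runbase[i] != truth && R::runif(0, 1) < 0.75) {
          sub = runbase[i];
        } else {
          do {
            sub = BASES[(int)std::floor(R::runif(0, 1) * 4) & 3];
          } while (sub == truth);
        }
        s[i] = sub;
      }
    }
    out[ii] = s;
  }
  return out;
}

// ---- cigar walking utilities ---------------------------------------------

struct CigOp { int len; char op; };

static std::vector<CigOp> parseCigar(const std::string& cig) {
  std::vector<CigOp> ops;
  int len = 0;
  for (char c : cig) {
    if (c >= '0' && c <= '9') len = len * 10 + (c - '0');
    else { ops.push_back({len, c}); len = 0; }
  }
  return ops;
}

// [[Rcpp::export]]
List cpp_pileup(IntegerVector pos, CharacterVector strand,
                CharacterVector cigar, CharacterVector seq,
                CharacterVector qual, int L,
                int radius = 5, int minq = 30, int qoffset = 33) {
  IntegerMatrix counts(L, 5);   // A C G T del
  IntegerMatrix fwd(L, 5);
  NumericMatrix qualsum(L, 4);
  std::unordered_map<std::string, std::pair<int, int>> insmap;
  const int n = pos.size();
  for (int ii = 0; ii < n; ++ii) {
    if (pos[ii] == NA_INTEGER) continue;
    std::string s = as<std::string>(seq[ii]);
    std::string q = as<std::string>(qual[ii]);
    bool isFwd = as<std::string>(strand[ii]) == "+";
    auto ops = parseCigar(as<std::string>(cigar[ii]));
    int rp = pos[ii] - 1;  // 0-based circle
    int ri = 0;
    const int m = (int)s.size();
    auto windowOK = [&](int center) {
      int lo = std::max(0, center - radius);
      int hi = std::min(m - 1, center + radius);
      double sum = 0;
      for (int t = lo; t <= hi; ++t) sum += q[t] - qoffset;
      return (q[center] - qoffset) >= minq &&
             sum / (hi - lo + 1) >= (double)minq;
    };
    for (auto& o : ops) {
      if (o.op == 'S') { ri += o.len; continue; }
      if (o.op == 'M') {
        for (int t = 0; t < o.len; ++t) {
          int b = baseIdx(s[ri]);
          if (b >= 0 && windowOK(ri)) {
            counts(rp, b) += 1;
            qualsum(rp, b) += q[ri] - qoffset;
            if (isFwd) fwd(rp, b) += 1;
          }
          ri += 1; rp = (rp + 1) % L;
        }
      } else if (o.op == 'D') {
        bool ok = ri < m && windowOK(std::min(ri, m - 1));
        for (int t = 0; t < o.len; ++t) {
          if (ok) {
            counts(rp, 4) += 1;
            if (isFwd) fwd(rp, 4) += 1;
          }
          rp = (rp + 1) % L;
        }
      } else if (o.op == 'I') {
        int anchor = (rp - 1 + L) % L;
        bool ok = windowOK(ri);
        std::string insseq = s.substr(ri, o.len);
        if (ok) {
          std::string key = std::to_string(anchor + 1) + ":" + insseq;
          auto& e = insmap[key];
          e.first += 1;
          if (isFwd) e.second += 1;
        }
        ri += o.len;
      }
    }
  }
  int ni = (int)insmap.size();
  IntegerVector ipos(ni), icount(ni), ifwd(ni);
  CharacterVector iseq(ni);
  int t = 0;
  for (auto& kv : insmap) {
    auto colon = kv.first.find(':');
    int pv = 0;
    for (size_t ci = 0; ci < colon; ++ci) {
      pv = pv * 10 + (kv.first[ci] - '0');
    }
    ipos[t] = pv;
    iseq[t] = kv.first.substr(colon + 1);
    icount[t] = kv.second.first;
    ifwd[t] = kv.second.second;
    ++t;
  }
  return List::create(_["counts"] = counts, _["fwd"] = fwd,
                      _["qualsum"] = qualsum,
                      _["ins"] = DataFrame::create(
                          _["pos"] = ipos, _["inserted"] = iseq,
                          _["count"] = icount, _["fwd"] = ifwd,
                          _["stringsAsFactors"] = false));
}

// Base carried by each alignment at each requested reference position
// ("" when the alignment does not cover the position with an M column).
// [[Rcpp::export]]
CharacterMatrix cpp_bases_at(IntegerVector pos, CharacterVector cigar,
                             CharacterVector seq, IntegerVector positions,
                             int L) {
  const int n = pos.size(), p = positions.size();
  CharacterMatrix out(n, p);
  std::vector<int> want(p);
  for (int j = 0; j < p; ++j) want[j] = positions[j] - 1;
  for (int ii = 0; ii < n; ++ii) {
    for (int j = 0; j < p; ++j) out(ii, j) = "";
    if (pos[ii] == NA_INTEGER) continue;
    std::string s = as<std::string>(seq[ii]);
    auto ops = parseCigar(as<std::string>(cigar[ii]));
    int rp = pos[ii] - 1, ri = 0;
    for (auto& o : ops) {
      if (o.op == 'S' || o.op == 'I') { ri += o.len; continue; }
      if (o.op == 'M') {
        for (int t = 0; t < o.len; ++t) {
          for (int j = 0; j < p; ++j) {
            if (rp == want[j]) out(ii, j) = std::string(1, s[ri]);
          }
          ri += 1; rp = (rp + 1) % L;
        }
      } else if (o.op == 'D') {
        for (int t = 0; t < o.len; ++t) {
          for (int j = 0; j < p; ++j) {
            if (rp == want[j]) out(ii, j) = "-";
          }
          rp = (rp + 1) % L;
        }
      }
    }
  }
  return out;
}

// Number of read bases each alignment carries across a homopolymer region
// [a, b] (1-based, non-wrapping), counting M bases at the region's
// positions plus inserted bases anchored at [a-1, b].  NA when the
// alignment does not fully span [a-1, b+1].
// [[Rcpp::export]]
IntegerVector cpp_region_read_lengths(IntegerVector pos,
                                      CharacterVector cigar,
                                      int a, int b, int L) {
  const int n = pos.size();
  IntegerVector out(n, NA_INTEGER);
  const int a0 = a - 1, b0 = b - 1;
  for (int ii = 0; ii < n; ++ii) {
    if (pos[ii] == NA_INTEGER) continue;
    auto ops = parseCigar(as<std::string>(cigar[ii]));
    int s0 = pos[ii] - 1;
    int refLen = 0;
    for (auto& o : ops) if (o.op == 'M' || o.op == 'D') refLen += o.len;
    auto covered = [&](int p0) {
      int off = ((p0 - s0) % L + L) % L;
      return off < refLen;
    };
    if (!covered((a0 - 1 + L) % L) || !covered((b0 + 1) % L)) continue;
    int rp = s0, cnt = 0;
    auto inRegion = [&](int p0) { return p0 >= a0 && p0 <= b0; };
    for (auto& o : ops) {
      if (o.op == 'S') continue;
      if (o.op == 'M') {
        for (int t = 0; t < o.len; ++t) {
          if (inRegion(rp)) ++cnt;
          rp = (rp + 1) % L;
        }
      } else if (o.op == 'D') {
        for (int t = 0; t < o.len; ++t) rp = (rp + 1) % L;
      } else if (o.op == 'I') {
        int anchor = (rp - 1 + L) % L;
        if (anchor >= a0 - 1 && anchor <= b0) cnt += o.len;
      }
    }
    out[ii] = cnt;
  }
  return out;
}
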