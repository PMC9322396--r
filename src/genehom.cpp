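// Core alignment kernels: ungapped seeded extension of a protein query
// against a translated frame (HSP generation), and a splice-aware local
// codon alignment of a protein against genomic DNA with canonical GT..AG
// introns between codons (phase 0).

#include <Rcpp.h>
#include <unordered_map>
#include <deque>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const char *BLOSUM_ALPHA = "ARNDCQEGHILKMFPSTWYVBJZX*";
static const int NEG = -100000000;

static inline void build_aa_lookup(int *lut) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; BLOSUM_ALPHA[i]; ++i) lut[(unsigned char)BLOSUM_ALPHA[i]] = i;
}

static inline char translate_codon(char a, char b, char c) {
  static const char bases[] = "TCAG";
  static const char code[] =
      "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";
  auto bi = [](char x) -> int {
    switch (x) {
      case 'T': return 0; case 'C': return 1; case 'A': return 2; case 'G': return 3;
      default: return -1;
    }
  };
  int i = bi(a), j = bi(b), k = bi(c);
  if (i < 0 || j < 0 || k < 0) return 'X';
  return code[i * 16 + j * 4 + k];
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string query, std::string subject,
                          IntegerMatrix blosum, int k, int xdrop,
                          int min_score) {
  int lut[256];
  build_aa_lookup(lut);
  int m = query.size(), n = subject.size();
  std::vector<int> q(m), s(n);
  for (int i = 0; i < m; ++i) { int v = lut[(unsigned char)query[i]]; q[i] = v < 0 ? 23 : v; }
  for (int i = 0; i < n; ++i) { int v = lut[(unsigned char)subject[i]]; s[i] = v < 0 ? 23 : v; }

  std::vector<int> B(25 * 25);
  for (int i = 0; i < 25; ++i)
    for (int j = 0; j < 25; ++j) B[i * 25 + j] = blosum(i, j);
  auto sc = [&](int qi, int si) { return B[q[qi] * 25 + s[si]]; };

  std::vector<int> qs_out, qe_out, ss_out, se_out, sco_out;
  if (m < k || n < k) {
    return DataFrame::create(_["qstart"] = qs_out, _["qend"] = qe_out,
                             _["sstart"] = ss_out, _["send"] = se_out,
                             _["score"] = sco_out);
  }

  // index query k-mers over the 20 standard residues
  std::unordered_map<uint32_t, std::vector<int>> qmap;
  for (int i = 0; i + k <= m; ++i) {
    uint32_t code = 0; bool ok = true;
    for (int t = 0; t < k; ++t) {
      if (q[i + t] >= 20) { ok = false; break; }
      code = code * 20u + (uint32_t)q[i + t];
    }
    if (ok) qmap[code].push_back(i);
  }

  std::unordered_map<long long, int> covered;  // diagonal -> rightmost send
  for (int j = 0; j + k <= n; ++j) {
    uint32_t code = 0; bool ok = true;
    for (int t = 0; t < k; ++t) {
      if (s[j + t] >= 20) { ok = false; break; }
      code = code * 20u + (uint32_t)s[j + t];
    }
    if (!ok) continue;
    auto it = qmap.find(code);
    if (it == qmap.end()) continue;
    for (int qi : it->second) {
      long long diag = (long long)j - qi;
      auto cv = covered.find(diag);
      if (cv != covered.end() && j <= cv->second) continue;
      int seed = 0;
      for (int t = 0; t < k; ++t) seed += sc(qi + t, j + t);
      // extend right
      int cur = seed, best_r = 0, ext_r = 0;
      for (int t = 1; qi + k - 1 + t < m && j + k - 1 + t < n; ++t) {
        cur += sc(qi + k - 1 + t, j + k - 1 + t);
        if (cur - seed > best_r) { best_r = cur - seed; ext_r = t; }
        if (best_r - (cur - seed) > xdrop) break;
      }
      // extend left
      cur = 0; int best_l = 0, ext_l = 0;
      for (int t = 1; qi - t >= 0 && j - t >= 0; ++t) {
        cur += sc(qi - t, j - t);
        if (cur > best_l) { best_l = cur; ext_l = t; }
        if (best_l - cur > xdrop) break;
      }
      int total = seed + best_r + best_l;
      int hq0 = qi - ext_l, hq1 = qi + k - 1 + ext_r;
      int hs0 = j - ext_l, hs1 = j + k - 1 + ext_r;
      if (total >= min_score) {
        qs_out.push_back(hq0 + 1); qe_out.push_back(hq1 + 1);
        ss_out.push_back(hs0 + 1); se_out.push_back(hs1 + 1);
        sco_out.push_back(total);
      }
      long long d2 = diag;
      auto cv2 = covered.find(d2);
      if (cv2 == covered.end() || hs1 > cv2->second) covered[d2] = hs1;
    }
  }
  return DataFrame::create(_["qstart"] = qs_out, _["qend"] = qe_out,
                           _["sstart"] = ss_out, _["send"] = se_out,
                           _["score"] = sco_out);
}

// [[Rcpp::export]]
List cpp_spliced_align(std::string query, std::string dna,
                       IntegerMatrix blosum, int gap_open, int gap_extend,
                       int intron_cost, int min_intron, int max_intron) {
  int lut[256];
  build_aa_lookup(lut);
  int m = query.size(), n = dna.size();
  if ((double)(m + 1) * (double)(n + 1) > 8e7)
    stop("spliced alignment window too large");
  std::vector<int> q(m);
  for (int i = 0; i < m; ++i) { int v = lut[(unsigned char)query[i]]; q[i] = v < 0 ? 23 : v; }
  std::vector<int> B(25 * 25);
  for (int i = 0; i < 25; ++i)
    for (int j = 0; j < 25; ++j) B[i * 25 + j] = blosum(i, j);

  // aa index of the codon ending at 1-based position j
  std::vector<int> codon_aa(n + 1, 23);
  for (int j = 3; j <= n; ++j) {
    char aa = translate_codon(dna[j - 3], dna[j - 2], dna[j - 1]);
    int v = lut[(unsigned char)aa];
    codon_aa[j] = v < 0 ? 23 : v;
  }
  std::vector<bool> donor(n + 2, false), acceptor(n + 1, false);
  for (int j = 0; j + 1 < n; ++j)
    if (dna[j] == 'G' && dna[j + 1] == 'T') donor[j] = true;  // donor[j']: GT at j'+1,j'+2 (1-based)
  for (int p = 2; p <= n; ++p)
    if (dna[p - 2] == 'A' && dna[p - 1] == 'G') acceptor[p] = true;

  size_t W = (size_t)n + 1;
  std::vector<int> M((size_t)(m + 1) * W, NEG), X((size_t)(m + 1) * W, NEG),
      Y((size_t)(m + 1) * W, NEG);
  auto idx = [&](int i, int j) { return (size_t)i * W + (size_t)j; };

  int best = 0, bi = -1, bj = -1;
  std::vector<int> A(W, NEG);  // intron arrival values for the previous row

  for (int i = 1; i <= m; ++i) {
    // A[p] = max over donors j' in [p-max_intron, p-min_intron] of
    //        M[i-1][j'] - intron_cost, valid only at acceptors p
    std::fill(A.begin(), A.end(), NEG);
    std::deque<std::pair<int, int>> dq;  // (j', value) decreasing values
    for (int p = 0; p <= n; ++p) {
      int enter = p - min_intron;  // newest donor candidate
      if (enter >= 0 && donor[enter]) {
        int val = M[idx(i - 1, enter)];
        if (val > NEG / 2) {
          val -= intron_cost;
          while (!dq.empty() && dq.back().second <= val) dq.pop_back();
          dq.push_back({enter, val});
        }
      }
      while (!dq.empty() && dq.front().first < p - max_intron) dq.pop_front();
      if (acceptor[p] && !dq.empty()) A[p] = dq.front().second;
    }
    for (int j = 1; j <= n; ++j) {
      if (j >= 3) {
        int s = B[q[i - 1] * 25 + codon_aa[j]];
        int prev = 0;
        int pm = M[idx(i - 1, j - 3)];
        int px = X[idx(i - 1, j - 3)];
        int py = Y[idx(i - 1, j - 3)];
        int pi = A[j - 3];
        if (pm > prev) prev = pm;
        if (px > prev) prev = px;
        if (py > prev) prev = py;
        if (pi > prev) prev = pi;
        M[idx(i, j)] = s + prev;
        int xo = M[idx(i, j - 3)] > NEG / 2 ? M[idx(i, j - 3)] - gap_open : NEG;
        int xe = X[idx(i, j - 3)] > NEG / 2 ? X[idx(i, j - 3)] - gap_extend : NEG;
        X[idx(i, j)] = xo > xe ? xo : xe;
      }
      int yo = M[idx(i - 1, j)] > NEG / 2 ? M[idx(i - 1, j)] - gap_open : NEG;
      int ye = Y[idx(i - 1, j)] > NEG / 2 ? Y[idx(i - 1, j)] - gap_extend : NEG;
      Y[idx(i, j)] = yo > ye ? yo : ye;
      if (M[idx(i, j)] > best) { best = M[idx(i, j)]; bi = i; bj = j; }
    }
  }

  if (bi < 0) {
    return List::create(_["score"] = 0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER,
                        _["exons"] = IntegerMatrix(0, 2),
                        _["ops"] = CharacterVector());
  }

  // traceback (state 0 = M, 1 = X, 2 = Y); ties: M > X > Y > intron > start
  std::vector<std::string> ops;
  std::vector<std::pair<int, int>> exons;  // collected backwards
  int i = bi, j = bj, state = 0;
  int cur_end = bj;
  int qstart = bi;
  bool done = false;
  while (!done) {
    if (state == 0) {
      int v = M[idx(i, j)];
      int s = B[q[i - 1] * 25 + codon_aa[j]];
      int prev = v - s;
      ops.push_back("M");
      if (i >= 1 && j >= 6 && prev == M[idx(i - 1, j - 3)]) {
        i -= 1; j -= 3;
      } else if (i >= 1 && j >= 6 && prev == X[idx(i - 1, j - 3)]) {
        state = 1; i -= 1; j -= 3;
      } else if (i >= 1 && j >= 6 && prev == Y[idx(i - 1, j - 3)]) {
        state = 2; i -= 1; j -= 3;
      } else {
        // intron arrival?
        int p = j - 3;
        bool found = false;
        if (p >= 2 && acceptor[p] && prev > NEG / 2) {
          int lo = p - max_intron > 0 ? p - max_intron : 0;
          int hi = p - min_intron;
          for (int jp = hi; jp >= lo; --jp) {  // prefer the shortest intron
            if (donor[jp] && M[idx(i - 1, jp)] - intron_cost == prev) {
              exons.push_back({p + 1, cur_end});
              ops.push_back("N" + std::to_string(p - jp));
              cur_end = jp;
              i -= 1; j = jp;
              found = true;
              break;
            }
          }
        }
        if (!found) {
          // local start: first codon of the alignment is at j-2..j
          qstart = i;
          exons.push_back({j - 2, cur_end});
          done = true;
        }
      }
    } else if (state == 1) {
      int v = X[idx(i, j)];
      ops.push_back("I");
      if (j >= 3 && M[idx(i, j - 3)] > NEG / 2 && v == M[idx(i, j - 3)] - gap_open) {
        state = 0; j -= 3;
      } else {
        j -= 3;  // extend
      }
    } else {
      int v = Y[idx(i, j)];
      ops.push_back("D");
      if (i >= 1 && M[idx(i - 1, j)] > NEG / 2 && v == M[idx(i - 1, j)] - gap_open) {
        state = 0; i -= 1;
      } else {
        i -= 1;
      }
    }
  }

  IntegerMatrix ex(exons.size(), 2);
  for (size_t e = 0; e < exons.size(); ++e) {
    ex(exons.size() - 1 - e, 0) = exons[e].first;
    ex(exons.size() - 1 - e, 1) = exons[e].second;
  }
  colnames(ex) = CharacterVector::create("start", "end");
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["qstart"] = qstart, _["qend"] = bi,
                      _["exons"] = ex, _["ops"] = wrap(ops));
}
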