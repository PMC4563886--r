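// Seeded Smith-Waterman local alignment: a word-indexed candidate filter
// followed by full affine-gap (Gotoh) dynamic programming with traceback.
// Protein scoring uses BLOSUM62; nucleotide scoring uses match/mismatch.
// E-values use fixed Karlin-Altschul constants supplied from R and are
// approximate by design; downstream identity/overlap thresholds do the
// real filtering.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const char AA_ALPHABET[] = "ARNDCQEGHILKMFPSTWYVBZX*";
static const int AA_N = 24;

// BLOSUM62, row/column order as AA_ALPHABET.
static const int BLOSUM62[AA_N][AA_N] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1, 0,-4},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, 0,-1,-4},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0,-1,-4},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-2,-4},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0, 3,-1,-4},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-2,-1,-4},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0,-1,-4},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3,-3,-1,-4},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4,-3,-1,-4},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0, 1,-1,-4},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3,-1,-1,-4},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3,-1,-4},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-1,-2,-4},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, 0, 0,-4},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1, 0,-4},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-3,-2,-4},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2,-1,-4},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2,-1,-4},
  {-2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  {-1, 0, 0, 1,-3, 3, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1,-1,-1,-4},
  {-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4, 1}
};

static inline int aa_code(char c) {
  switch (toupper(c)) {
    case 'A': return 0;  case 'R': return 1;  case 'N': return 2;
    case 'D': return 3;  case 'C': return 4;  case 'Q': return 5;
    case 'E': return 6;  case 'G': return 7;  case 'H': return 8;
    case 'I': return 9;  case 'L': return 10; case 'K': return 11;
    case 'M': return 12; case 'F': return 13; case 'P': return 14;
    case 'S': return 15; case 'T': return 16; case 'W': return 17;
    case 'Y': return 18; case 'V': return 19; case 'B': return 20;
    case 'Z': return 21; case 'X': return 22; case '*': return 23;
    default: return -1;
  }
}

static inline int nt_code(char c) {
  switch (toupper(c)) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; default: return -1;
  }
}

struct AlnResult {
  int score = 0, n_ident = 0, aln_len = 0, mismatches = 0, gap_opens = 0;
  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;  // 1-based
};

// Gotoh local alignment: rolling score rows plus a byte traceback matrix.
// Traceback byte layout: bits 0-1 = H source (0 stop, 1 diagonal, 2 E,
// 3 F), bit 2 = E opened here, bit 3 = F opened here.
template <typename ScoreFn>
static AlnResult gotoh_local(const std::vector<int>& q,
                             const std::vector<int>& s,
                             int gap_open, int gap_extend, ScoreFn sub) {
  const int m = (int)q.size(), n = (int)s.size();
  AlnResult out;
  if (m == 0 || n == 0) return out;
  const int NEG = -1000000000;
  static std::vector<int> Hprev, Hcur, Fcol;
  static std::vector<uint8_t> tb;
  if ((int)Hprev.size() < n + 1) {
    Hprev.resize(n + 1);
    Hcur.resize(n + 1);
    Fcol.resize(n + 1);
  }
  size_t need = (size_t)(m + 1) * (n + 1);
  if (tb.size() < need) tb.resize(need);
  std::fill(Hprev.begin(), Hprev.begin() + n + 1, 0);
  std::fill(Fcol.begin(), Fcol.begin() + n + 1, NEG);
  const int go = gap_open + gap_extend, ge = gap_extend;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0;
    int e = NEG;
    const int qi = q[i - 1];
    uint8_t* tbrow = tb.data() + (size_t)i * (n + 1);
    for (int j = 1; j <= n; ++j) {
      int e_open = Hcur[j - 1] - go;
      e = std::max(e_open, e - ge);
      int f_open = Hprev[j] - go;
      int f = std::max(f_open, Fcol[j] - ge);
      Fcol[j] = f;
      int d = Hprev[j - 1] + sub(qi, s[j - 1]);
      int h = d;
      uint8_t dir = 1;
      if (e > h) { h = e; dir = 2; }
      if (f > h) { h = f; dir = 3; }
      if (h <= 0) { h = 0; dir = 0; }
      Hcur[j] = h;
      tbrow[j] = dir | (e == e_open ? 4 : 0) | (f == f_open ? 8 : 0);
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best == 0) return out;
  out.score = best;
  out.q_end = bi;
  out.s_end = bj;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
  bool in_gap = false;
  while (i > 0 && j > 0) {
    uint8_t code = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      int dir = code & 3;
      if (dir == 0) break;
      if (dir == 1) {
        out.aln_len++;
        if (q[i - 1] == s[j - 1]) out.n_ident++; else out.mismatches++;
        in_gap = false;
        --i; --j;
      } else if (dir == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      out.aln_len++;
      if (!in_gap) { out.gap_opens++; in_gap = true; }
      bool open = (code & 4) != 0;
      --j;
      if (open) { state = 0; in_gap = false; }
    } else {
      out.aln_len++;
      if (!in_gap) { out.gap_opens++; in_gap = true; }
      bool open = (code & 8) != 0;
      --i;
      if (open) { state = 0; in_gap = false; }
    }
  }
  out.q_start = i + 1;
  out.s_start = j + 1;
  return out;
}

static std::vector<int> encode_protein(const std::string& s,
                                       const std::string& label) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = aa_code(s[i]);
    if (c < 0)
      stop("non-amino-acid character '%s' in sequence %s",
           std::string(1, s[i]).c_str(), label.c_str());
    v[i] = c;
  }
  return v;
}

static inline int blosum(int a, int b) { return BLOSUM62[a][b]; }

// [[Rcpp::export(name = ".align_pair_protein_cpp")]]
List align_pair_protein_cpp(std::string a, std::string b,
                            int gap_open = 11, int gap_extend = 1) {
  std::vector<int> qa = encode_protein(a, "a"), qb = encode_protein(b, "b");
  AlnResult r = gotoh_local(qa, qb, gap_open, gap_extend, blosum);
  return List::create(_["score"] = r.score, _["n_ident"] = r.n_ident,
                      _["aln_length"] = r.aln_len,
                      _["mismatches"] = r.mismatches,
                      _["gap_opens"] = r.gap_opens,
                      _["q_start"] = r.q_start, _["q_end"] = r.q_end,
                      _["s_start"] = r.s_start, _["s_end"] = r.s_end);
}

// [[Rcpp::export(name = ".protein_search_cpp")]]
DataFrame protein_search_cpp(CharacterVector queries, CharacterVector qnames,
                             CharacterVector subjects, CharacterVector snames,
                             int word_size = 3, int min_seed_hits = 1,
                             int gap_open = 11, int gap_extend = 1,
                             double max_evalue = 10.0,
                             double lambda = 0.267, double K = 0.041,
                             bool exclude_self = true) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<int>> senc(ns);
  double db_len = 0;
  for (int j = 0; j < ns; ++j) {
    senc[j] = encode_protein(as<std::string>(subjects[j]),
                             as<std::string>(snames[j]));
    db_len += senc[j].size();
  }
  // word index: word code -> sorted unique subject ids
  std::unordered_map<uint32_t, std::vector<int>> index;
  for (int j = 0; j < ns; ++j) {
    const std::vector<int>& s = senc[j];
    if ((int)s.size() < word_size) continue;
    std::vector<uint32_t> words;
    for (size_t p = 0; p + word_size <= s.size(); ++p) {
      uint32_t w = 0;
      bool ok = true;
      for (int k = 0; k < word_size; ++k) {
        int c = s[p + k];
        if (c >= 22) { ok = false; break; }  // skip X and *
        w = w * 24u + (uint32_t)c;
      }
      if (ok) words.push_back(w);
    }
    std::sort(words.begin(), words.end());
    words.erase(std::unique(words.begin(), words.end()), words.end());
    for (uint32_t w : words) index[w].push_back(j);
  }

  std::vector<std::string> o_q, o_s;
  std::vector<double> o_pid, o_len, o_mm, o_go, o_qs, o_qe, o_ss, o_se,
      o_ev, o_bit;
  std::vector<int> count(ns, 0);
  std::vector<int> touched;
  const double log2K = std::log(K);

  for (int qi = 0; qi < nq; ++qi) {
    std::vector<int> q = encode_protein(as<std::string>(queries[qi]),
                                        as<std::string>(qnames[qi]));
    if ((int)q.size() < word_size) continue;
    std::vector<uint32_t> words;
    for (size_t p = 0; p + word_size <= q.size(); ++p) {
      uint32_t w = 0;
      bool ok = true;
      for (int k = 0; k < word_size; ++k) {
        int c = q[p + k];
        if (c >= 22) { ok = false; break; }
        w = w * 24u + (uint32_t)c;
      }
      if (ok) words.push_back(w);
    }
    std::sort(words.begin(), words.end());
    words.erase(std::unique(words.begin(), words.end()), words.end());
    touched.clear();
    for (uint32_t w : words) {
      auto it = index.find(w);
      if (it == index.end()) continue;
      for (int j : it->second) {
        if (count[j] == 0) touched.push_back(j);
        count[j]++;
      }
    }
    std::string qname = as<std::string>(qnames[qi]);
    for (int j : touched) {
      int c = count[j];
      count[j] = 0;
      if (c < min_seed_hits) continue;
      if (exclude_self && qname == as<std::string>(snames[j])) continue;
      AlnResult r = gotoh_local(q, senc[j], gap_open, gap_extend, blosum);
      if (r.score <= 0) continue;
      double bit = (lambda * r.score - log2K) / std::log(2.0);
      double ev = (double)q.size() * db_len * std::pow(2.0, -bit);
      if (ev > max_evalue) continue;
      o_q.push_back(qname);
      o_s.push_back(as<std::string>(snames[j]));
      o_pid.push_back(100.0 * r.n_ident / std::max(1, r.aln_len));
      o_len.push_back(r.aln_len);
      o_mm.push_back(r.mismatches);
      o_go.push_back(r.gap_opens);
      o_qs.push_back(r.q_start);
      o_qe.push_back(r.q_end);
      o_ss.push_back(r.s_start);
      o_se.push_back(r.s_end);
      o_ev.push_back(ev);
      o_bit.push_back(bit);
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
      _["query_id"] = o_q, _["subject_id"] = o_s, _["pct_identity"] = o_pid,
      _["aln_length"] = o_len, _["mismatches"] = o_mm, _["gap_opens"] = o_go,
      _["q_start"] = o_qs, _["q_end"] = o_qe, _["s_start"] = o_ss,
      _["s_end"] = o_se, _["evalue"] = o_ev, _["bitscore"] = o_bit,
      _["stringsAsFactors"] = false);
}

// Nucleotide seed-and-extend: exact k-mer seeds against an indexed subject,
// diagonal clustering, then local DP restricted to a window around each
// cluster.
// [[Rcpp::export(name = ".nucleotide_search_cpp")]]
DataFrame nucleotide_search_cpp(CharacterVector queries,
                                CharacterVector qnames,
                                CharacterVector subjects,
                                CharacterVector snames,
                                int word_size = 11, int match = 2,
                                int mismatch = -3, int gap_open = 5,
                                int gap_extend = 2, double max_evalue = 1e-5,
                                double lambda = 0.625, double K = 0.41,
                                int min_cluster_seeds = 2) {
  const int nq = queries.size(), ns = subjects.size();
  auto sub_nt = [match, mismatch](int a, int b) {
    return a == b ? match : mismatch;
  };
  std::vector<std::string> sseq(ns);
  double db_len = 0;
  for (int j = 0; j < ns; ++j) {
    sseq[j] = as<std::string>(subjects[j]);
    db_len += sseq[j].size();
  }
  // index the (small) queries, scan each (large) subject once
  std::vector<std::string> qseq(nq);
  std::vector<std::vector<int>> qenc_all(nq);
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> qindex;
  const uint64_t mask = ((uint64_t)1 << (2 * word_size)) - 1;
  // bit prefilter over a 24-bit hash of each indexed word: subject scanning
  // tests the bit before paying for a hash-map lookup
  auto mix = [](uint64_t x) {
    x ^= x >> 33; x *= 0xff51afd7ed558ccdULL; x ^= x >> 33;
    return x;
  };
  std::vector<uint64_t> prefilter((1u << 24) / 64, 0);
  auto pf_set = [&](uint64_t w) {
    uint64_t h = mix(w) & ((1u << 24) - 1);
    prefilter[h >> 6] |= (uint64_t)1 << (h & 63);
  };
  auto pf_test = [&](uint64_t w) {
    uint64_t h = mix(w) & ((1u << 24) - 1);
    return (prefilter[h >> 6] >> (h & 63)) & 1;
  };
  for (int qi = 0; qi < nq; ++qi) {
    qseq[qi] = as<std::string>(queries[qi]);
    const int qlen = (int)qseq[qi].size();
    std::vector<int>& qenc = qenc_all[qi];
    qenc.resize(qlen);
    uint64_t w = 0;
    int run = 0;
    for (int p = 0; p < qlen; ++p) {
      qenc[p] = nt_code(qseq[qi][p]);
      if (qenc[p] < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)qenc[p]) & mask;
      if (++run >= word_size) {
        qindex[w].emplace_back(qi, p - word_size + 1);
        pf_set(w);
      }
    }
  }
  std::vector<std::string> o_q, o_s;
  std::vector<double> o_pid, o_len, o_mm, o_go, o_qs, o_qe, o_ss, o_se,
      o_ev, o_bit;
  const double log2K = std::log(K);
  // seeds per query for the subject being scanned
  std::vector<std::vector<std::pair<int, int>>> seeds_by_q(nq);
  for (int j = 0; j < ns; ++j) {
    for (auto& v : seeds_by_q) v.clear();
    {
      const std::string& s = sseq[j];
      uint64_t w = 0;
      int run = 0;
      for (size_t p = 0; p < s.size(); ++p) {
        int c = nt_code(s[p]);
        if (c < 0) { run = 0; w = 0; continue; }
        w = ((w << 2) | (uint64_t)c) & mask;
        if (++run >= word_size) {
          if (!pf_test(w)) continue;
          auto it = qindex.find(w);
          if (it == qindex.end()) continue;
          int spos = (int)p - word_size + 1;
          for (auto& qp : it->second)
            seeds_by_q[qp.first].emplace_back(spos - qp.second, spos);
        }
      }
    }
    for (int qi = 0; qi < nq; ++qi) {
      const int qlen = (int)qseq[qi].size();
      if (qlen < word_size) continue;
      const std::vector<int>& qenc = qenc_all[qi];
      std::vector<std::pair<int, int>>& seeds = seeds_by_q[qi];
      if (seeds.empty()) continue;
      std::sort(seeds.begin(), seeds.end());
      // cluster by diagonal (band of 2 * word_size)
      std::vector<std::tuple<int, int, int>> clusters;  // count, dmin, dmax
      size_t k = 0;
      while (k < seeds.size()) {
        size_t k2 = k;
        while (k2 + 1 < seeds.size() &&
               seeds[k2 + 1].first - seeds[k].first <= 2 * word_size)
          ++k2;
        clusters.emplace_back((int)(k2 - k + 1), seeds[k].first,
                              seeds[k2].first);
        k = k2 + 1;
      }
      std::sort(clusters.begin(), clusters.end(),
                [](auto& a, auto& b) {
                  return std::get<0>(a) > std::get<0>(b);
                });
      AlnResult best;
      int best_off = 0;
      int ncl = std::min((size_t)3, clusters.size());
      for (int ci = 0; ci < ncl; ++ci) {
        if (std::get<0>(clusters[ci]) < min_cluster_seeds) continue;
        // subject window from the cluster's diagonal range: wide enough for
        // the full query plus a 64 bp gap allowance on either side
        int dmin = std::get<1>(clusters[ci]), dmax = std::get<2>(clusters[ci]);
        int w0 = std::max(0, dmin - 64);
        int w1 = std::min((int)sseq[j].size(),
                          dmax + qlen + word_size + 64);
        if (w1 <= w0) continue;
        std::vector<int> win(w1 - w0);
        bool okwin = true;
        for (int p = w0; p < w1; ++p) {
          win[p - w0] = nt_code(sseq[j][p]);
          if (win[p - w0] < 0) win[p - w0] = -9;  // never matches
        }
        (void)okwin;
        std::vector<int> qok(qenc);
        for (auto& c : qok) if (c < 0) c = -8;
        AlnResult r = gotoh_local(qok, win, gap_open, gap_extend, sub_nt);
        if (r.score > best.score) { best = r; best_off = w0; }
      }
      if (best.score <= 0) continue;
      double bit = (lambda * best.score - log2K) / std::log(2.0);
      double ev = (double)qlen * db_len * std::pow(2.0, -bit);
      if (ev > max_evalue) continue;
      o_q.push_back(as<std::string>(qnames[qi]));
      o_s.push_back(as<std::string>(snames[j]));
      o_pid.push_back(100.0 * best.n_ident / std::max(1, best.aln_len));
      o_len.push_back(best.aln_len);
      o_mm.push_back(best.mismatches);
      o_go.push_back(best.gap_opens);
      o_qs.push_back(best.q_start);
      o_qe.push_back(best.q_end);
      o_ss.push_back(best.s_start + best_off);
      o_se.push_back(best.s_end + best_off);
      o_ev.push_back(ev);
      o_bit.push_back(bit);
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
      _["query_id"] = o_q, _["subject_id"] = o_s, _["pct_identity"] = o_pid,
      _["aln_length"] = o_len, _["mismatches"] = o_mm, _["gap_opens"] = o_go,
      _["q_start"] = o_qs, _["q_end"] = o_qe, _["s_start"] = o_ss,
      _["s_end"] = o_se, _["evalue"] = o_ev, _["bitscore"] = o_bit,
      _["stringsAsFactors"] = false);
}
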