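#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <tuple>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// A,C,G,T -> 0..3, anything else (incl. N) -> 4.  Code 4 never matches,
// not even against itself: ambiguous bases must not inflate identity.
static inline uint8_t base_code(char c) {
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
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static inline char comp_char(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_char(s[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_str(as<std::string>(x[i]));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Windowed ungapped identity scan
// ---------------------------------------------------------------------------

struct WinHit {
  bool found = false;
  double identity = -1.0;
  int oa = 0, ob = 0;
  bool rc = false;
};

// Scan every (offset_a, offset_b) pair (all diagonals, sliding window) of A
// against B for a length-w block with >= min_matches matching columns.
// Tie-break: highest identity, then forward orientation before rc (enforced
// by caller scanning forward first: a candidate from a later orientation only
// displaces the incumbent on strictly higher identity), then smallest
// (offset_a, offset_b).  first_hit returns on the first qualifying window.
static void scan_orientation(const std::vector<uint8_t>& A,
                             const std::vector<uint8_t>& B,
                             int w, int min_matches, bool rc, bool first_hit,
                             WinHit& best) {
  const int La = (int)A.size(), Lb = (int)B.size();
  if (La < w || Lb < w) return;
  for (int d = -(Lb - w); d <= La - w; ++d) {
    int ob0 = std::max(0, -d);
    int ob1 = std::min(Lb - w, La - w - d);
    if (ob1 < ob0) continue;
    int cnt = 0;
    const int oa0 = ob0 + d;
    for (int t = 0; t < w; ++t)
      cnt += (A[oa0 + t] == B[ob0 + t] && A[oa0 + t] < 4);
    for (int ob = ob0;;) {
      const int oa = ob + d;
      if (cnt >= min_matches) {
        const double id = (double)cnt / w;
        bool take = false;
        if (!best.found) take = true;
        else if (id > best.identity + 1e-12) take = true;
        else if (id > best.identity - 1e-12 && rc == best.rc &&
                 (oa < best.oa || (oa == best.oa && ob < best.ob))) take = true;
        if (take) {
          best.found = true; best.identity = id;
          best.oa = oa; best.ob = ob; best.rc = rc;
        }
        if (first_hit) return;
      }
      if (ob == ob1) break;
      cnt -= (A[ob + d] == B[ob] && A[ob + d] < 4);
      cnt += (A[ob + d + w] == B[ob + w] && A[ob + d + w] < 4);
      ++ob;
    }
  }
}

static WinHit best_window_hit(const std::vector<uint8_t>& A,
                              const std::string& b, int w, double min_identity,
                              bool scan_rc, bool first_hit) {
  WinHit best;
  const int min_matches = (int)std::ceil(min_identity * w - 1e-9);
  std::vector<uint8_t> Bf = encode_seq(b);
  scan_orientation(A, Bf, w, min_matches, false, first_hit, best);
  if (best.found && first_hit) return best;
  if (scan_rc) {
    std::vector<uint8_t> Br = encode_seq(revcomp_str(b));
    scan_orientation(A, Br, w, min_matches, true, first_hit, best);
  }
  return best;
}

// [[Rcpp::export]]
List cpp_best_window_match(std::string a, std::string b, int window,
                           double min_identity, bool scan_rc = true,
                           bool first_hit = false) {
  std::vector<uint8_t> A = encode_seq(a);
  WinHit h = best_window_hit(A, b, window, min_identity, scan_rc, first_hit);
  if (!h.found)
    return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["offset_a"] = h.oa,
                      _["offset_b"] = h.ob, _["identity"] = h.identity,
                      _["orientation"] = h.rc ? "reverse-complement" : "forward");
}

// Existence check used by the partitioner: does candidate i share a window
// match with ANY probe (either orientation)?
// [[Rcpp::export]]
LogicalVector cpp_any_window_match(CharacterVector candidates,
                                   CharacterVector probes, int window,
                                   double min_identity, bool scan_rc = true) {
  const int min_matches = (int)std::ceil(min_identity * window - 1e-9);
  std::vector<std::vector<uint8_t> > P, Prc;
  for (R_xlen_t j = 0; j < probes.size(); ++j) {
    std::string p = as<std::string>(probes[j]);
    P.push_back(encode_seq(p));
    if (scan_rc) Prc.push_back(encode_seq(revcomp_str(p)));
  }
  LogicalVector out(candidates.size());
  for (R_xlen_t i = 0; i < candidates.size(); ++i) {
    std::vector<uint8_t> C = encode_seq(as<std::string>(candidates[i]));
    bool hit = false;
    for (size_t j = 0; j < P.size() && !hit; ++j) {
      WinHit h;
      scan_orientation(C, P[j], window, min_matches, false, true, h);
      if (!h.found && scan_rc)
        scan_orientation(C, Prc[j], window, min_matches, true, true, h);
      hit = h.found;
    }
    out[i] = hit;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Greedy guide extension (de novo step)
// ---------------------------------------------------------------------------

// Scan only the diagonals of A x B that carry a shared exact 32-mer.  Sound
// whenever a qualifying window is guaranteed to contain an exact run of at
// least 32 bases (pigeonhole: <= m mismatches in a width-w window leaves a
// run >= ceil((w-m)/(m+1))); the caller checks that guarantee.  Within the
// candidate diagonals the evaluation and tie-break are identical to the
// exhaustive scan, and no other diagonal can host a qualifying window.
static const int SEED_LEN = 32;

static bool seed_guarantee(int w, double min_identity) {
  const int m = (int)std::floor((1.0 - min_identity) * w + 1e-9);
  return (w - m + m) / (m + 1) >= SEED_LEN; // ceil((w-m)/(m+1)) >= 32
}

static void seeded_scan(const std::vector<uint8_t>& A,
                        const std::unordered_map<uint64_t, std::vector<int> >& aidx,
                        const std::vector<uint8_t>& B, int w, int min_matches,
                        bool rc, WinHit& best) {
  const int La = (int)A.size(), Lb = (int)B.size();
  if (La < w || Lb < w) return;
  std::vector<int> diags;
  uint64_t code;
  for (int p = 0; p + SEED_LEN <= Lb; ++p) {
    bool ok = true;
    code = 0;
    for (int t = 0; t < SEED_LEN; ++t) {
      if (B[p + t] >= 4) { ok = false; break; }
      code = (code << 2) | B[p + t];
    }
    if (!ok) continue;
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
        aidx.find(code);
    if (it == aidx.end()) continue;
    for (size_t h = 0; h < it->second.size(); ++h)
      diags.push_back(it->second[h] - p);
  }
  std::sort(diags.begin(), diags.end());
  diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
  for (size_t di = 0; di < diags.size(); ++di) {
    const int d = diags[di];
    if (d < -(Lb - w) || d > La - w) continue;
    int ob0 = std::max(0, -d);
    int ob1 = std::min(Lb - w, La - w - d);
    if (ob1 < ob0) continue;
    int cnt = 0;
    const int oa0 = ob0 + d;
    for (int t = 0; t < w; ++t)
      cnt += (A[oa0 + t] == B[ob0 + t] && A[oa0 + t] < 4);
    for (int ob = ob0;;) {
      const int oa = ob + d;
      if (cnt >= min_matches) {
        const double id = (double)cnt / w;
        bool take = false;
        if (!best.found) take = true;
        else if (id > best.identity + 1e-12) take = true;
        else if (id > best.identity - 1e-12 && rc == best.rc &&
                 (oa < best.oa || (oa == best.oa && ob < best.ob))) take = true;
        if (take) {
          best.found = true; best.identity = id;
          best.oa = oa; best.ob = ob; best.rc = rc;
        }
      }
      if (ob == ob1) break;
      cnt -= (A[ob + d] == B[ob] && A[ob + d] < 4);
      cnt += (A[ob + d + w] == B[ob + w] && A[ob + d + w] < 4);
      ++ob;
    }
  }
}

static std::unordered_map<uint64_t, std::vector<int> >
build_seed_index(const std::vector<uint8_t>& A) {
  std::unordered_map<uint64_t, std::vector<int> > idx;
  const int La = (int)A.size();
  for (int p = 0; p + SEED_LEN <= La; ++p) {
    bool ok = true;
    uint64_t code = 0;
    for (int t = 0; t < SEED_LEN; ++t) {
      if (A[p + t] >= 4) { ok = false; break; }
      code = (code << 2) | A[p + t];
    }
    if (ok) idx[code].push_back(p);
  }
  return idx;
}

// Runs the full restart loop for one growing guide sequence: scan the pool in
// order; a read whose best >=min_identity window anchors it with an overhang
// extends the guide (guide bases win inside the overlap) and restarts the
// search; an anchored read without overhang is marked satisfied and skipped
// for the remainder of this guide's loop.
// [[Rcpp::export]]
List cpp_extend_guide(std::string ggs, CharacterVector reads, int window,
                      double min_identity) {
  const int n = reads.size();
  std::vector<std::string> fwd(n), rc(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(reads[i]);
    rc[i] = revcomp_str(fwd[i]);
  }
  const bool seeded = seed_guarantee(window, min_identity);
  const int min_matches = (int)std::ceil(min_identity * window - 1e-9);
  LogicalVector used(n, false), satisfied(n, false);
  bool restart = true;
  while (restart) {
    restart = false;
    std::vector<uint8_t> G = encode_seq(ggs);
    const int Lg = (int)ggs.size();
    std::unordered_map<uint64_t, std::vector<int> > gidx;
    if (seeded) gidx = build_seed_index(G);
    for (int i = 0; i < n; ++i) {
      if (used[i] || satisfied[i]) continue;
      WinHit h;
      if (seeded) {
        seeded_scan(G, gidx, encode_seq(fwd[i]), window, min_matches, false, h);
        seeded_scan(G, gidx, encode_seq(rc[i]), window, min_matches, true, h);
      } else {
        h = best_window_hit(G, fwd[i], window, min_identity, true, false);
      }
      if (!h.found) continue;
      const std::string& oriented = h.rc ? rc[i] : fwd[i];
      const int Lr = (int)oriented.size();
      const int start = h.oa - h.ob;
      const int left = start < 0 ? -start : 0;
      const int right = start + Lr > Lg ? start + Lr - Lg : 0;
      if (left > 0 || right > 0) {
        std::string ext;
        if (left > 0) ext += oriented.substr(0, left);
        ext += ggs;
        if (right > 0) ext += oriented.substr(Lr - right);
        ggs = ext;
        used[i] = true;
        restart = true;
        break;
      } else {
        satisfied[i] = true;
      }
    }
  }
  return List::create(_["ggs"] = ggs, _["used"] = used,
                      _["satisfied"] = satisfied);
}

// ---------------------------------------------------------------------------
// Free-end-gap global identity
// ---------------------------------------------------------------------------

// Needleman-Wunsch with lightly penalised end gaps: match +1, mismatch -1,
// internal gap -2, terminal gap -1 per base.  End gaps cost half an internal
// gap so that terminal overhangs are preferred over internal gaps, but a
// substitution is preferred over shifting a sequence by its ends (AAAA vs
// AAAT aligns as a substitution, identity 0.75, not as an overhang).
// Identity = matches / alignment columns between the first and last aligned
// pair of the optimal traceback (terminal overhangs excluded).
// [[Rcpp::export]]
double cpp_global_identity(std::string a, std::string b) {
  std::vector<uint8_t> A = encode_seq(a), B = encode_seq(b);
  const int n = (int)A.size(), m = (int)B.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<int> score((size_t)(n + 1) * (m + 1));
  std::vector<uint8_t> dir((size_t)(n + 1) * (m + 1), 0); // 0 diag, 1 up, 2 left
  const size_t W = m + 1;
  for (int j = 0; j <= m; ++j) { score[j] = -j; dir[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    score[i * W] = -i;
    dir[i * W] = 1;
    for (int j = 1; j <= m; ++j) {
      const bool mt = (A[i - 1] == B[j - 1] && A[i - 1] < 4);
      int s = score[(i - 1) * W + (j - 1)] + (mt ? 1 : -1);
      uint8_t d = 0;
      if (score[(i - 1) * W + j] - 2 > s) { s = score[(i - 1) * W + j] - 2; d = 1; }
      if (score[i * W + (j - 1)] - 2 > s) { s = score[i * W + (j - 1)] - 2; d = 2; }
      score[i * W + j] = s;
      dir[i * W + j] = d;
    }
  }
  // Best end over the last row and last column, charging the remaining
  // terminal gap at -1 per base.
  int bi = n, bj = m, bs = score[(size_t)n * W + m];
  for (int j = 0; j <= m; ++j) {
    const int s = score[(size_t)n * W + j] - (m - j);
    if (s > bs) { bs = s; bi = n; bj = j; }
  }
  for (int i = 0; i <= n; ++i) {
    const int s = score[(size_t)i * W + m] - (n - i);
    if (s > bs) { bs = s; bi = i; bj = m; }
  }
  // Traceback from (bi, bj) to the first row/column.
  int i = bi, j = bj, matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    const uint8_t d = dir[(size_t)i * W + j];
    if (d == 0) {
      matches += (A[i - 1] == B[j - 1] && A[i - 1] < 4);
      --i; --j;
    } else if (d == 1) {
      --i;
    } else {
      --j;
    }
    ++cols;
  }
  if (cols == 0) return 0.0;
  return (double)matches / (double)cols;
}

// ---------------------------------------------------------------------------
// K-mer index + vote mapping
// ---------------------------------------------------------------------------

static bool kmer_code(const std::vector<uint8_t>& s, int pos, int k,
                      uint64_t& out) {
  uint64_t v = 0;
  for (int t = 0; t < k; ++t) {
    if (s[pos + t] >= 4) return false;
    v = (v << 2) | s[pos + t];
  }
  out = v;
  return true;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > KTable;

static KTable build_ktable(const std::vector<std::vector<uint8_t> >& G, int k) {
  KTable tab;
  for (size_t g = 0; g < G.size(); ++g) {
    const int L = (int)G[g].size();
    for (int p = 0; p + k <= L; ++p) {
      uint64_t code;
      if (kmer_code(G[g], p, k, code))
        tab[code].push_back(std::make_pair((int)g, p));
    }
  }
  return tab;
}

// Enumerate the index as a table (for inspection and the brute-force oracle).
// [[Rcpp::export]]
DataFrame cpp_kmer_table(CharacterVector guides, int k) {
  std::vector<std::string> gs(guides.size());
  std::vector<std::vector<uint8_t> > G(guides.size());
  for (R_xlen_t g = 0; g < guides.size(); ++g) {
    gs[g] = as<std::string>(guides[g]);
    G[g] = encode_seq(gs[g]);
  }
  std::vector<std::string> km;
  std::vector<int> gid, pos;
  for (size_t g = 0; g < G.size(); ++g) {
    const int L = (int)G[g].size();
    for (int p = 0; p + k <= L; ++p) {
      uint64_t code;
      if (!kmer_code(G[g], p, k, code)) continue;
      km.push_back(gs[g].substr(p, k));
      gid.push_back((int)g + 1);
      pos.push_back(p);
    }
  }
  return DataFrame::create(_["kmer"] = km, _["guide"] = gid, _["pos"] = pos,
                           _["stringsAsFactors"] = false);
}

// Map each read to its max-vote (guide, offset, orientation) bin.
// Ties: lowest guide id, then lowest offset, then forward before rc.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector guides, int k) {
  std::vector<std::vector<uint8_t> > G(guides.size());
  for (R_xlen_t g = 0; g < guides.size(); ++g)
    G[g] = encode_seq(as<std::string>(guides[g]));
  KTable tab = build_ktable(G, k);

  const int n = (int)reads.size();
  IntegerVector r_guide(n, NA_INTEGER), r_offset(n, NA_INTEGER),
      r_votes(n, NA_INTEGER);
  CharacterVector r_orient(n, NA_STRING);
  LogicalVector r_mapped(n, false);

  for (int i = 0; i < n; ++i) {
    std::string fs = as<std::string>(reads[i]);
    // bins keyed (guide, offset, orient 0=fwd 1=rc); std::map for stable order
    std::map<std::tuple<int, int, int>, int> bins;
    for (int ori = 0; ori < 2; ++ori) {
      std::string s = ori ? revcomp_str(fs) : fs;
      std::vector<uint8_t> S = encode_seq(s);
      const int L = (int)S.size();
      for (int p = 0; p + k <= L; ++p) {
        uint64_t code;
        if (!kmer_code(S, p, k, code)) continue;
        KTable::const_iterator it = tab.find(code);
        if (it == tab.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          const int g = it->second[h].first, q = it->second[h].second;
          bins[std::make_tuple(g, q - p, ori)] += 1;
        }
      }
    }
    if (bins.empty()) continue;
    int bg = -1, bo = 0, bor = 0, bv = -1;
    for (std::map<std::tuple<int, int, int>, int>::const_iterator it =
             bins.begin();
         it != bins.end(); ++it) {
      const int g = std::get<0>(it->first), off = std::get<1>(it->first),
                ori = std::get<2>(it->first), v = it->second;
      bool take = false;
      if (v > bv) take = true;
      else if (v == bv) {
        if (g < bg) take = true;
        else if (g == bg) {
          if (off < bo) take = true;
          else if (off == bo && ori < bor) take = true;
        }
      }
      if (take) { bv = v; bg = g; bo = off; bor = ori; }
    }
    r_guide[i] = bg + 1;
    r_offset[i] = bo;
    r_orient[i] = bor ? "reverse-complement" : "forward";
    r_votes[i] = bv;
    r_mapped[i] = true;
  }
  return DataFrame::create(_["read"] = seq_len(n), _["guide"] = r_guide,
                           _["offset"] = r_offset, _["orientation"] = r_orient,
                           _["votes"] = r_votes, _["mapped"] = r_mapped,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Hamming clustering + consensus
// ---------------------------------------------------------------------------

// Single-linkage connected components: fragments i, j link when
// matches / length >= min_identity (N matches nothing).  Labels are 1-based,
// numbered by first appearance.
// [[Rcpp::export]]
IntegerVector cpp_hamming_components(CharacterVector frags,
                                     double min_identity) {
  const int n = (int)frags.size();
  std::vector<std::vector<uint8_t> > F(n);
  for (int i = 0; i < n; ++i) F[i] = encode_seq(as<std::string>(frags[i]));
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int i = 0; i < n; ++i) {
    const int L = (int)F[i].size();
    const int need = (int)std::ceil(min_identity * L - 1e-9);
    for (int j = i + 1; j < n; ++j) {
      if ((int)F[j].size() != L) continue;
      if (find(i) == find(j)) continue;
      int cnt = 0;
      for (int t = 0; t < L; ++t)
        cnt += (F[i][t] == F[j][t] && F[i][t] < 4);
      if (cnt >= need) parent[find(j)] = find(i);
    }
  }
  IntegerVector lab(n);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (remap.find(r) == remap.end()) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}

// Majority base per column over A,C,G,T; ties -> lexicographically smallest;
// a column with no unambiguous base -> N.
// [[Rcpp::export]]
String cpp_consensus(CharacterVector frags) {
  const int n = (int)frags.size();
  if (n == 0) return NA_STRING;
  std::vector<std::vector<uint8_t> > F(n);
  size_t L = 0;
  for (int i = 0; i < n; ++i) {
    F[i] = encode_seq(as<std::string>(frags[i]));
    if (F[i].size() > L) L = F[i].size();
  }
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string cons(L, 'N');
  for (size_t t = 0; t < L; ++t) {
    int cnt[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i)
      if (t < F[i].size() && F[i][t] < 4) cnt[F[i][t]] += 1;
    int best = -1, bc = 0;
    for (int b = 0; b < 4; ++b)
      if (cnt[b] > bc) { bc = cnt[b]; best = b; }
    if (best >= 0) cons[t] = bases[best];
  }
  return String(cons);
}

// Best ungapped placement identity of a whole fragment against each reference
// (both orientations).  Used for per-window source labelling.
// [[Rcpp::export]]
NumericVector cpp_best_fragment_identity(std::string frag,
                                         CharacterVector refs,
                                         bool scan_rc = true) {
  const int w = (int)frag.size();
  NumericVector out(refs.size());
  for (R_xlen_t r = 0; r < refs.size(); ++r) {
    std::vector<uint8_t> R = encode_seq(as<std::string>(refs[r]));
    WinHit h = best_window_hit(R, frag, w, 0.0, scan_rc, false);
    out[r] = h.found ? h.identity : 0.0;
  }
  return out;
}
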