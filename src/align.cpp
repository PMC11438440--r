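// Seeded, gapped local alignment and pileup consensus.
//
// Scoring follows the blastn cost convention: match reward r, mismatch
// penalty p (negative), and a gap of length L contributes -(gap_open +
// L * gap_extend). Alignment is banded affine-gap Smith-Waterman around a
// seed diagonal; a band wide enough to cover the whole matrix makes it
// exact full local alignment (used by the oracle tests).

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static const double NEG_INF = -1e18;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N and anything else: never matches
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// ---------------------------------------------------------------------------
// Banded affine local alignment
// ---------------------------------------------------------------------------

struct Aln {
  bool ok = false;
  double score = 0.0;
  // 0-based half-open on query (q) and subject (s)
  int qs = 0, qe = 0, ss = 0, se = 0;
  int matches = 0, mismatches = 0, gap_opens = 0, gap_cols = 0, cols = 0;
  std::string qaln, saln;
};

// Row i in 1..m indexes query; columns j restricted to a window of width
// 2*band+1 centred on j = i + diag. Window offset k = j - (i + diag - band).
// Diagonal steps keep k; horizontal (subject gap consumed) is k-1 in the same
// row; vertical (query consumed) is k+1 in the previous row.
static Aln banded_sw(const std::string& q, const std::string& s,
                     long diag, long band,
                     double match, double mismatch,
                     double gopen, double gext,
                     bool want_alignment) {
  Aln out;
  const long m = (long)q.size(), n = (long)s.size();
  if (m == 0 || n == 0) return out;
  const long W = 2 * band + 1;

  std::vector<double> Hprev(W, NEG_INF), Hcur(W, NEG_INF);
  std::vector<double> Fprev(W, NEG_INF), Fcur(W, NEG_INF);
  std::vector<double> Ecur(W, NEG_INF);
  // traceback byte: bits 0-1 H source (0 stop, 1 diag, 2 E, 3 F);
  // bit 2: E extends; bit 3: F extends
  std::vector<uint8_t> tb;
  if ((double)m * W > 5e8) stop("alignment band too large");
  tb.assign((size_t)m * W, 0);

  double best = 0.0;
  long best_i = -1, best_k = -1;
  bool any_window = false;

  for (long i = 1; i <= m; ++i) {
    const long c = i + diag;           // window centre column
    const long j_lo = std::max(1L, c - band);
    const long j_hi = std::min(n, c + band);
    std::fill(Hcur.begin(), Hcur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    std::fill(Ecur.begin(), Ecur.end(), NEG_INF);
    if (j_lo > j_hi) continue;
    any_window = true;
    const int qi = base_code(q[i - 1]);
    for (long j = j_lo; j <= j_hi; ++j) {
      const long k = j - (c - band);
      uint8_t t = 0;
      // E: gap consuming subject (horizontal), same row k-1
      double e = NEG_INF;
      if (k - 1 >= 0) {
        const double open_from = (Hcur[k - 1] > NEG_INF / 2) ? Hcur[k - 1] - gopen - gext : NEG_INF;
        const double ext_from  = (Ecur[k - 1] > NEG_INF / 2) ? Ecur[k - 1] - gext : NEG_INF;
        if (ext_from > open_from) { e = ext_from; t |= 4; } else e = open_from;
      }
      Ecur[k] = e;
      // F: gap consuming query (vertical), previous row k+1
      double f = NEG_INF;
      if (k + 1 < W) {
        const double open_from = (Hprev[k + 1] > NEG_INF / 2) ? Hprev[k + 1] - gopen - gext : NEG_INF;
        const double ext_from  = (Fprev[k + 1] > NEG_INF / 2) ? Fprev[k + 1] - gext : NEG_INF;
        if (ext_from > open_from) { f = ext_from; t |= 8; } else f = open_from;
      }
      Fcur[k] = f;
      // H
      const int sj = base_code(s[j - 1]);
      const bool is_match = (qi == sj && qi != 4);
      const double sub = is_match ? match : mismatch;
      double dcand = (Hprev[k] > NEG_INF / 2) ? Hprev[k] + sub : NEG_INF;
      bool dfresh = false;
      if (i == 1 || j == 1) {
        // diagonal predecessor lies outside the matrix: H = 0 start
        const double fresh = 0.0 + sub;
        if (fresh > dcand) { dcand = fresh; dfresh = true; }
      }
      double h = 0.0; uint8_t src = 0;
      if (dcand > h) { h = dcand; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      Hcur[k] = h;
      if (dfresh && src == 1) t |= 16;  // diagonal move starts the alignment
      tb[(size_t)(i - 1) * W + k] = (uint8_t)(t | src);
      if (h > best) { best = h; best_i = i; best_k = k; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  if (!any_window || best <= 0.0 || best_i < 0) return out;

  // traceback
  long i = best_i, k = best_k;
  long j = (i + diag - band) + k;
  out.qe = (int)i; out.se = (int)j;
  std::string qa, sa;
  int state = 0;  // 0 = in H
  while (i >= 1 && j >= 1) {
    const uint8_t t = tb[(size_t)(i - 1) * W + k];
    const uint8_t src = t & 3;
    if (state == 0) {
      if (src == 0) break;
      if (src == 1) {
        qa.push_back(q[i - 1]); sa.push_back(s[j - 1]);
        if (base_code(q[i - 1]) == base_code(s[j - 1]) && base_code(q[i - 1]) != 4)
          out.matches++; else out.mismatches++;
        --i; --j;  // diagonal move keeps k
        if ((t & 16) || i == 0 || j == 0) break;  // alignment started here
        const long c2 = i + diag;
        const long j_lo2 = std::max(1L, c2 - band), j_hi2 = std::min(n, c2 + band);
        if (j < j_lo2 || j > j_hi2) break;
        k = j - (c2 - band);
      } else if (src == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) {
      // E: consume subject base (gap in query)
      qa.push_back('-'); sa.push_back(s[j - 1]);
      out.gap_cols++;
      const bool ext = (t & 4) != 0;
      if (!ext) { out.gap_opens++; state = 0; }
      --j; --k;
      if (k < 0) break;
    } else {
      // F: consume query base (gap in subject)
      qa.push_back(q[i - 1]); sa.push_back('-');
      out.gap_cols++;
      const bool ext = (t & 8) != 0;
      if (!ext) { out.gap_opens++; state = 0; }
      --i; ++k;
      if (k >= W) break;
      const long c2 = i + diag;
      const long j_lo2 = std::max(1L, c2 - band);
      k = j - (c2 - band);
      if (j < j_lo2) break;
    }
  }
  out.qs = (int)i; out.ss = (int)j;
  out.cols = (int)qa.size();
  out.score = best;
  out.ok = true;
  if (want_alignment) {
    std::reverse(qa.begin(), qa.end());
    std::reverse(sa.begin(), sa.end());
    out.qaln = qa; out.saln = sa;
  }
  return out;
}

static List aln_to_list(const Aln& a, bool with_strings) {
  List out = List::create(
    _["ok"] = a.ok, _["score"] = a.score,
    _["qstart"] = a.qs, _["qend"] = a.qe,
    _["sstart"] = a.ss, _["send"] = a.se,
    _["matches"] = a.matches, _["mismatches"] = a.mismatches,
    _["gap_opens"] = a.gap_opens, _["gap_cols"] = a.gap_cols,
    _["cols"] = a.cols);
  if (with_strings) {
    out["qaln"] = a.qaln;
    out["saln"] = a.saln;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_align(std::string query, std::string subject, double diag, int band,
               double match, double mismatch, double gap_open,
               double gap_extend, bool alignment = true) {
  Aln a = banded_sw(query, subject, (long)diag, (long)band,
                    match, mismatch, gap_open, gap_extend, alignment);
  return aln_to_list(a, alignment);
}

// ---------------------------------------------------------------------------
// Seeding
// ---------------------------------------------------------------------------

struct SeedIndex {
  int word;
  // packed word -> (subject index, position)
  std::unordered_map<uint32_t, std::vector<std::pair<int32_t, int32_t>>> idx;
};

static void index_sequence(SeedIndex& si, const std::string& s, int sub_idx) {
  const int w = si.word;
  const long n = (long)s.size();
  if (n < w) return;
  uint32_t code = 0;
  const uint32_t mask = (w == 16) ? 0xFFFFFFFFu : ((1u << (2 * w)) - 1u);
  int valid = 0;
  for (long i = 0; i < n; ++i) {
    const int b = base_code(s[i]);
    if (b == 4) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)b) & mask;
    if (++valid >= w) si.idx[code].push_back({(int32_t)sub_idx, (int32_t)(i - w + 1)});
  }
}

template <typename F>
static void scan_query(const SeedIndex& si, const std::string& q, F&& emit) {
  const int w = si.word;
  const long n = (long)q.size();
  if (n < w) return;
  uint32_t code = 0;
  const uint32_t mask = (w == 16) ? 0xFFFFFFFFu : ((1u << (2 * w)) - 1u);
  int valid = 0;
  for (long i = 0; i < n; ++i) {
    const int b = base_code(q[i]);
    if (b == 4) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)b) & mask;
    if (++valid >= w) {
      auto it = si.idx.find(code);
      if (it != si.idx.end())
        for (const auto& hit : it->second) emit((long)(i - w + 1), hit.first, (long)hit.second);
    }
  }
}

// Exhaustive exact word matches on both strands.
// Positions 0-based; for the minus strand, qpos refers to the start, on the
// original query, of the word whose reverse complement matches the subject.
// [[Rcpp::export]]
DataFrame cpp_find_seeds(std::string query, std::string subject, int word) {
  if (word < 4 || word > 16) stop("word size must be in [4, 16]");
  SeedIndex si; si.word = word;
  index_sequence(si, subject, 0);
  std::vector<int> qpos, spos;
  std::vector<std::string> strand;
  scan_query(si, query, [&](long qp, int, long sp) {
    qpos.push_back((int)qp); spos.push_back((int)sp); strand.push_back("+");
  });
  const std::string qrc = revcomp(query);
  const long qlen = (long)query.size();
  scan_query(si, qrc, [&](long qp, int, long sp) {
    qpos.push_back((int)(qlen - word - qp)); spos.push_back((int)sp);
    strand.push_back("-");
  });
  return DataFrame::create(_["qpos"] = qpos, _["spos"] = spos,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Search: seed, cluster by diagonal, banded extension, best HSP per subject
// ---------------------------------------------------------------------------

struct Cluster { long diag; int count; };

static std::vector<Cluster> cluster_diags(std::vector<long>& diags, long band,
                                          int min_seeds, int max_clusters) {
  std::vector<Cluster> out;
  if (diags.empty()) return out;
  std::sort(diags.begin(), diags.end());
  size_t start = 0;
  std::vector<Cluster> all;
  for (size_t i = 1; i <= diags.size(); ++i) {
    if (i == diags.size() || diags[i] - diags[i - 1] > band) {
      const size_t cnt = i - start;
      if ((int)cnt >= min_seeds)
        all.push_back({diags[start + cnt / 2], (int)cnt});
      start = i;
    }
  }
  std::sort(all.begin(), all.end(),
            [](const Cluster& a, const Cluster& b) { return a.count > b.count; });
  for (size_t i = 0; i < all.size() && (int)i < max_clusters; ++i) out.push_back(all[i]);
  return out;
}

struct SearchHit {
  int query, subject;
  std::string strand;
  Aln aln;  // subject coordinates raw (possibly on doubled sequence)
};

static void search_one(const std::string& qfwd,
                       const SeedIndex& si,
                       const std::vector<std::string>& subj_used,
                       const std::vector<int>& subj_len,
                       const std::vector<bool>& circ,
                       long band, int min_seeds, int max_clusters,
                       double match, double mismatch, double gopen, double gext,
                       double min_score, bool want_alignment,
                       std::vector<SearchHit>& hits, int query_idx) {
  const std::string qrc = revcomp(qfwd);
  const long qlen = (long)qfwd.size();
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& q = (strand == 0) ? qfwd : qrc;
    // seeds grouped per subject
    std::unordered_map<int, std::vector<long>> per_sub;
    scan_query(si, q, [&](long qp, int sub, long sp) {
      per_sub[sub].push_back(sp - qp);
    });
    for (auto& kv : per_sub) {
      const int sub = kv.first;
      std::vector<Cluster> cl = cluster_diags(kv.second, band, min_seeds, max_clusters);
      Aln best_alns[4]; int n_best = 0;
      std::vector<long> done_diags;
      for (const Cluster& c : cl) {
        if (circ[sub]) {
          // the doubled subject repeats every alignment L columns later;
          // skip the duplicate cluster
          bool dup = false;
          for (long d : done_diags) {
            if (std::abs(std::abs(c.diag - d) - (long)subj_len[sub]) <= band) {
              dup = true; break;
            }
          }
          if (dup) continue;
        }
        done_diags.push_back(c.diag);
        Aln a = banded_sw(q, subj_used[sub], c.diag, band, match, mismatch,
                          gopen, gext, want_alignment);
        if (a.ok && a.score >= min_score && n_best < 4) best_alns[n_best++] = a;
      }
      if (n_best == 0) continue;
      // de-duplicate circular doubles: keep best per (sstart mod L) window
      const int L = subj_len[sub];
      std::vector<Aln> kept;
      std::sort(best_alns, best_alns + n_best,
                [](const Aln& a, const Aln& b) { return a.score > b.score; });
      for (int i = 0; i < n_best; ++i) {
        bool dup = false;
        if (circ[sub]) {
          for (const Aln& k : kept) {
            long d1 = ((best_alns[i].ss % L) + L) % L;
            long d2 = ((k.ss % L) + L) % L;
            long dd = std::abs(d1 - d2);
            if (std::min(dd, (long)L - dd) < 50) { dup = true; break; }
          }
        } else if (!kept.empty()) {
          // linear subject: max_hsps = 1, keep the best only
          dup = true;
        }
        if (!dup) kept.push_back(best_alns[i]);
      }
      // best HSP per (subject, strand): keep the single best after dedupe
      Aln& a = kept[0];
      SearchHit h;
      h.query = query_idx; h.subject = sub;
      h.strand = (strand == 0) ? "+" : "-";
      if (strand == 1) {  // map back to original query coordinates
        const int nqs = (int)(qlen - a.qe), nqe = (int)(qlen - a.qs);
        a.qs = nqs; a.qe = nqe;
      }
      h.aln = a;
      hits.push_back(h);
    }
  }
}

// [[Rcpp::export]]
List cpp_search(CharacterVector queries,
                CharacterVector subjects, LogicalVector circular,
                int word, int band, int min_seeds, int max_clusters,
                double match, double mismatch, double gap_open,
                double gap_extend, double min_score) {
  const int ns = subjects.size();
  SeedIndex si; si.word = word;
  std::vector<std::string> subj_used(ns);
  std::vector<int> subj_len(ns);
  std::vector<bool> circ(ns);
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(subjects[i]);
    subj_len[i] = (int)s.size();
    circ[i] = circular[i];
    subj_used[i] = circ[i] ? s + s : s;
    index_sequence(si, subj_used[i], i);
  }
  std::vector<SearchHit> hits;
  for (int qi = 0; qi < queries.size(); ++qi) {
    search_one(as<std::string>(queries[qi]), si, subj_used, subj_len, circ,
               band, min_seeds, max_clusters, match, mismatch,
               gap_open, gap_extend, min_score, false, hits, qi);
  }
  // reduce to best HSP per (query, subject): max_hsps = 1
  std::map<std::pair<int,int>, size_t> best;
  for (size_t i = 0; i < hits.size(); ++i) {
    auto key = std::make_pair(hits[i].query, hits[i].subject);
    auto it = best.find(key);
    if (it == best.end() || hits[i].aln.score > hits[it->second].aln.score)
      best[key] = i;
  }
  const size_t n = best.size();
  IntegerVector query_i(n), subject_i(n), qstart(n), qend(n), sstart(n), send(n),
      matches(n), mismatches_v(n), gap_opens(n), gap_cols(n), cols(n);
  NumericVector score(n);
  CharacterVector strand(n);
  size_t r = 0;
  for (auto& kv : best) {
    const SearchHit& h = hits[kv.second];
    const Aln& a = h.aln;
    const int L = subj_len[h.subject];
    long ss = a.ss, se = a.se;
    if (circ[h.subject] && ss >= L) { ss -= L; se -= L; }
    query_i[r] = h.query + 1; subject_i[r] = h.subject + 1;
    qstart[r] = a.qs; qend[r] = a.qe;
    sstart[r] = (int)ss; send[r] = (int)se;
    matches[r] = a.matches; mismatches_v[r] = a.mismatches;
    gap_opens[r] = a.gap_opens; gap_cols[r] = a.gap_cols; cols[r] = a.cols;
    score[r] = a.score; strand[r] = h.strand;
    ++r;
  }
  return List::create(
    _["query"] = query_i, _["subject"] = subject_i, _["score"] = score,
    _["matches"] = matches, _["mismatches"] = mismatches_v,
    _["gap_opens"] = gap_opens, _["gap_cols"] = gap_cols, _["cols"] = cols,
    _["qstart"] = qstart, _["qend"] = qend,
    _["sstart"] = sstart, _["send"] = send, _["strand"] = strand);
}

// ---------------------------------------------------------------------------
// Pileup consensus against a (possibly circular) template
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pileup(std::string templ, bool circular, CharacterVector reads,
                int word, int band, int min_seeds,
                double match, double mismatch, double gap_open,
                double gap_extend, double min_score,
                double min_pident, int min_cols,
                bool build_consensus) {
  const int L = (int)templ.size();
  SeedIndex si; si.word = word;
  std::vector<std::string> subj_used(1);
  subj_used[0] = circular ? templ + templ : templ;
  std::vector<int> subj_len(1, L);
  std::vector<bool> circ(1, circular);
  index_sequence(si, subj_used[0], 0);

  // counts: A C G T deletion
  std::vector<std::array<int, 5>> counts((size_t)L, {0, 0, 0, 0, 0});
  std::vector<int> cov(L, 0);
  std::map<int, std::unordered_map<std::string, int>> ins;

  const int nr = reads.size();
  IntegerVector r_sstart(nr, NA_INTEGER), r_send(nr, NA_INTEGER);
  NumericVector r_score(nr, NA_REAL), r_pident(nr, NA_REAL);
  IntegerVector r_cols(nr, NA_INTEGER);
  CharacterVector r_strand(nr, NA_STRING);
  LogicalVector r_aligned(nr, false);

  for (int ri = 0; ri < nr; ++ri) {
    std::vector<SearchHit> hits;
    search_one(as<std::string>(reads[ri]), si, subj_used, subj_len, circ,
               band, min_seeds, 3, match, mismatch, gap_open, gap_extend,
               min_score, true, hits, ri);
    if (hits.empty()) continue;
    size_t bi = 0;
    for (size_t i = 1; i < hits.size(); ++i)
      if (hits[i].aln.score > hits[bi].aln.score) bi = i;
    const Aln& a = hits[bi].aln;
    const double pid = a.cols > 0 ? 100.0 * a.matches / a.cols : 0.0;
    if (pid < min_pident || a.cols < min_cols) continue;
    r_aligned[ri] = true;
    r_score[ri] = a.score; r_pident[ri] = pid; r_cols[ri] = a.cols;
    long ss = a.ss, se = a.se;
    if (circular && ss >= L) { ss -= L; se -= L; }
    r_sstart[ri] = (int)ss; r_send[ri] = (int)se;
    r_strand[ri] = hits[bi].strand;
    // tally columns
    long p = a.ss;  // raw (doubled) subject position of next subject base
    const std::string& qa = a.qaln;
    const std::string& sa = a.saln;
    std::string pending_ins;
    for (size_t c = 0; c < qa.size(); ++c) {
      if (sa[c] == '-') {           // insertion relative to template
        pending_ins.push_back(qa[c]);
        continue;
      }
      if (!pending_ins.empty()) {
        int anchor = (int)(((p - 1) % L + L) % L);  // after previous template base
        ins[anchor][pending_ins]++;
        pending_ins.clear();
      }
      const int tp = (int)(p % L);
      if (qa[c] == '-') counts[tp][4]++;            // deletion
      else {
        const int b = base_code(qa[c]);
        if (b < 4) counts[tp][b]++; else counts[tp][4]++;
      }
      cov[tp]++;
      ++p;
    }
  }

  IntegerVector depth(L);
  for (int p = 0; p < L; ++p) depth[p] = cov[p];

  std::string consensus;
  LogicalVector low_cov(L);
  if (build_consensus) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    consensus.reserve((size_t)L + 64);
    for (int p = 0; p < L; ++p) {
      if (cov[p] == 0) {
        consensus.push_back(templ[p]);
        low_cov[p] = true;
      } else {
        int bmax = 0;
        const int tb = base_code(templ[p]);
        for (int b = 1; b < 5; ++b)
          if (counts[p][b] > counts[p][bmax] ||
              (counts[p][b] == counts[p][bmax] && b == tb))
            bmax = b;
        if (bmax < 4) consensus.push_back(bases[bmax]);
        // bmax == 4: majority deletion, emit nothing
      }
      auto it = ins.find(p);
      if (it != ins.end() && cov[p] > 0) {
        const std::string* best_s = nullptr; int best_c = 0;
        for (const auto& kv : it->second)
          if (kv.second > best_c) { best_c = kv.second; best_s = &kv.first; }
        if (best_s && 2 * best_c > cov[p]) consensus += *best_s;
      }
    }
  }

  return List::create(
    _["consensus"] = consensus,
    _["depth"] = depth,
    _["low_coverage"] = low_cov,
    _["aligned"] = r_aligned,
    _["score"] = r_score, _["pident"] = r_pident, _["cols"] = r_cols,
    _["sstart"] = r_sstart, _["send"] = r_send, _["strand"] = r_strand);
}

// ---------------------------------------------------------------------------
// Small utilities
// ---------------------------------------------------------------------------

// Mean read Q-score: -10 log10(mean per-base error probability), Phred+33.
// [[Rcpp::export]]
NumericVector cpp_mean_qscore(CharacterVector quals) {
  const int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(quals, i));
    double sum = 0.0; long len = 0;
    for (const char* p = s; *p; ++p, ++len)
      sum += std::pow(10.0, -((double)(*p - 33)) / 10.0);
    out[i] = (len == 0) ? NA_REAL : -10.0 * std::log10(sum / (double)len);
  }
  return out;
}

// Upper-quartile multiplicity, over all reads, of each read's canonical
// k-mers. High-copy (mitochondrial) reads stand out against single-copy
// background; the 75th percentile is robust to the majority of k-mers
// being unique when reads carry ~5% error.
// [[Rcpp::export]]
NumericVector cpp_kmer_read_scores(CharacterVector reads, int k) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::unordered_map<uint64_t, int> tab;
  const int n = reads.size();
  auto canon_scan = [&](const std::string& s, auto&& f) {
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      const int b = base_code(s[i]);
      if (b == 4) { valid = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
      if (++valid >= k) f(std::min(fwd, rev));
    }
  };
  for (int i = 0; i < n; ++i) {
    const std::string s = as<std::string>(reads[i]);
    canon_scan(s, [&](uint64_t km) { tab[km]++; });
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const std::string s = as<std::string>(reads[i]);
    std::vector<int> mult;
    canon_scan(s, [&](uint64_t km) { mult.push_back(tab[km]); });
    if (mult.empty()) { out[i] = 0; continue; }
    const size_t at = (3 * mult.size()) / 4;
    std::nth_element(mult.begin(), mult.begin() + at, mult.end());
    out[i] = mult[at];
  }
  return out;
}
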