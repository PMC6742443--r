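// Seeded, banded alignment engine.
//
// The reverse-read-mapping stages all reduce to aligning many short queries
// (2 kb tiling or junction fragments, trimmed read segments, 100 bp short
// reads) against longer targets (long reads, a draft, a reference).  Exact
// k-mer seeds are clustered by diagonal and each cluster is verified with a
// banded Smith-Waterman restricted to that diagonal, which keeps the whole
// pipeline dependency-free and fast enough for simulated genomes at a few
// hundred-fold coverage.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char rcBase(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = rcBase(r[i]);
  return r;
}

// ---------------------------------------------------------------------------
// k-mer index: 2-bit rolling encoding, positions of every k-mer of a string

typedef std::unordered_map<uint64_t, std::vector<int> > KmerMap;

static void indexKmers(const std::string& s, int k, KmerMap& map) {
  map.clear();
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t key = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = baseCode(s[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run >= k) map[key].push_back(i - k + 1);
  }
}

static bool encodeKmer(const std::string& s, int pos, int k, uint64_t& key) {
  key = 0;
  for (int i = 0; i < k; ++i) {
    int b = baseCode(s[pos + i]);
    if (b < 0) return false;
    key = (key << 2) | (uint64_t)b;
  }
  return true;
}

// ---------------------------------------------------------------------------
// Banded local alignment (Smith-Waterman restricted to one diagonal band)
//
// Aligns q[q0,q1) against t[t0,t1) with the constraint
// | (j - i) - off | <= band   (i: index into the q segment, j: into the t
// segment).  Scoring: match +1, mismatch -2, gap -2 (linear).  Reports the
// best local alignment: score, matches, alignment columns, longest internal
// gap run, aligned intervals in absolute (0-based, half-open) coordinates
// and, when `path` is non-null, the alignment operations from start to end
// (op 1 = aligned pair, 2 = gap-in-target i.e. query insertion, 3 =
// gap-in-query i.e. deletion; qi/tj are absolute positions).

struct AlnOp { int qi, tj; uint8_t op; };

struct AlnResult {
  int score, matches, alnLen, maxGap;
  int qs, qe, ts, te;
  bool ok;
};

static const int SC_MATCH = 1, SC_MISMATCH = -2, SC_GAP = -2;
static const int NEG_INF = INT32_MIN / 4;

static AlnResult bandedLocal(const std::string& q, int q0, int q1,
                             const std::string& t, int t0, int t1,
                             int off, int band,
                             std::vector<AlnOp>* path = NULL) {
  AlnResult res; res.ok = false;
  res.score = res.matches = res.alnLen = res.maxGap = 0;
  res.qs = res.qe = res.ts = res.te = 0;
  const int m = q1 - q0, n = t1 - t0;
  if (m <= 0 || n <= 0) return res;
  const int W = 2 * band + 1;
  static std::vector<int> Hprev, Hcur;
  static std::vector<uint8_t> moves;
  Hprev.assign(W, 0); Hcur.assign(W, 0);
  moves.assign((size_t)m * W, 0);

  int best = 0, bi = -1, bb = -1;
  for (int i = 0; i < m; ++i) {
    const char qc = q[q0 + i];
    // valid band offsets for this row: j = i + off - band + b in [0, n)
    const int bLo = std::max(0, band - i - off);
    const int bHi = std::min(W - 1, n - 1 - i - off + band);
    for (int b = 0; b < bLo && b < W; ++b) Hcur[b] = 0;
    for (int b = bHi + 1; b < W; ++b) Hcur[b] = 0;
    for (int b = bLo; b <= bHi; ++b) {
      const int j = i + off - band + b;
      const int diagBase = (i > 0 && j > 0) ? Hprev[b] : 0;
      const int vDiag = diagBase +
        ((qc == t[t0 + j]) ? SC_MATCH : SC_MISMATCH);
      const int vUp = (i == 0 || b + 1 >= W) ? NEG_INF : Hprev[b + 1] + SC_GAP;
      const int vLeft = (b == 0 || j == 0) ? NEG_INF : Hcur[b - 1] + SC_GAP;
      int v = 0; uint8_t mv = 0;
      if (vDiag > v) { v = vDiag; mv = 1; }
      if (vUp > v) { v = vUp; mv = 2; }
      if (vLeft > v) { v = vLeft; mv = 3; }
      Hcur[b] = v;
      moves[(size_t)i * W + b] = mv;
      if (v > best) { best = v; bi = i; bb = b; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) return res;

  int i = bi, b = bb;
  int matches = 0, cols = 0, gapRun = 0, maxGap = 0;
  const int je = bi + off - band + bb;
  res.qe = q0 + bi + 1; res.te = t0 + je + 1;
  int qs = res.qe, ts = res.te;
  if (path) path->clear();
  while (i >= 0) {
    const uint8_t mv = moves[(size_t)i * W + b];
    if (mv == 0) break;
    const int j = i + off - band + b;
    if (j < 0) break;
    if (mv == 1) {
      if (q[q0 + i] == t[t0 + j]) ++matches;
      ++cols; gapRun = 0;
      qs = q0 + i; ts = t0 + j;
      if (path) { AlnOp op = { q0 + i, t0 + j, 1 }; path->push_back(op); }
      --i;
    } else if (mv == 2) {            // gap in target: query insertion
      ++cols; if (++gapRun > maxGap) maxGap = gapRun;
      qs = q0 + i;
      if (path) { AlnOp op = { q0 + i, t0 + j, 2 }; path->push_back(op); }
      --i; ++b;
    } else {                         // gap in query: deletion at target col
      ++cols; if (++gapRun > maxGap) maxGap = gapRun;
      ts = t0 + j;
      if (path) { AlnOp op = { q0 + i, t0 + j, 3 }; path->push_back(op); }
      --b;
    }
  }
  if (path) std::reverse(path->begin(), path->end());
  res.ok = true;
  res.score = best; res.matches = matches; res.alnLen = cols;
  res.maxGap = maxGap; res.qs = qs; res.ts = ts;
  return res;
}

// ---------------------------------------------------------------------------
// Seed clustering by diagonal

struct Seed { int qpos, tpos; };

struct Cluster { std::vector<Seed> seeds; long diagSum; };

static void clusterSeeds(std::vector<Seed>& seeds, int bandTol,
                         std::vector<Cluster>& out) {
  out.clear();
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    const int da = a.tpos - a.qpos, db = b.tpos - b.qpos;
    if (da != db) return da < db;
    return a.qpos < b.qpos;
  });
  Cluster cur; cur.diagSum = 0;
  int lastDiag = 0;
  for (size_t s = 0; s < seeds.size(); ++s) {
    const int d = seeds[s].tpos - seeds[s].qpos;
    if (!cur.seeds.empty() && d - lastDiag > bandTol) {
      out.push_back(cur);
      cur.seeds.clear(); cur.diagSum = 0;
    }
    cur.seeds.push_back(seeds[s]);
    cur.diagSum += d;
    lastDiag = d;
  }
  if (!cur.seeds.empty()) out.push_back(cur);
  // within each cluster: order by qpos and enforce increasing tpos
  for (size_t c = 0; c < out.size(); ++c) {
    std::vector<Seed>& v = out[c].seeds;
    std::sort(v.begin(), v.end(), [](const Seed& a, const Seed& b) {
      return a.qpos < b.qpos;
    });
    std::vector<Seed> keep;
    int lastT = -1;
    for (size_t s = 0; s < v.size(); ++s)
      if (v[s].tpos > lastT) { keep.push_back(v[s]); lastT = v[s].tpos; }
    v.swap(keep);
  }
}

static void collectSeeds(const std::string& q, const KmerMap& idx,
                         int k, int stride, size_t maxHits,
                         std::vector<Seed>& seeds) {
  seeds.clear();
  const int Lq = (int)q.size();
  for (int p = 0; p + k <= Lq; p += stride) {
    uint64_t key;
    if (!encodeKmer(q, p, k, key)) continue;
    KmerMap::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    if (it->second.size() > maxHits) continue;   // low-complexity guard
    for (size_t j = 0; j < it->second.size(); ++j) {
      Seed s; s.qpos = p; s.tpos = it->second[j];
      seeds.push_back(s);
    }
  }
}

// ---------------------------------------------------------------------------
// Fragment-to-read mapping ("reverse read mapping" work-horse)
//
// frags: query sequences; reads: targets.  Both strands of every fragment
// are tried.  Returns one row per verified seed cluster with identity >=
// minIdentity and alignment length >= minLen.  Fragment intervals are
// reported in the fragment's own forward coordinates for both strands.

// [[Rcpp::export]]
DataFrame cpp_map_fragments(CharacterVector reads, CharacterVector frags,
                            int k = 15, int stride = 40, int band = 60,
                            double minIdentity = 0.8, int minLen = 200,
                            int minSeeds = 3) {
  const int nReads = reads.size(), nFrags = frags.size();
  std::vector<std::string> F(nFrags), Frc(nFrags);
  for (int f = 0; f < nFrags; ++f) {
    F[f] = as<std::string>(frags[f]);
    Frc[f] = revcomp(F[f]);
  }

  // index strided seeds of every fragment (both strands) once; reads are
  // then scanned position-by-position, so the cost scales with total read
  // bases rather than reads x fragments
  typedef std::unordered_map<uint64_t,
            std::vector<std::pair<int,int> > > SeedIndex; // (frag*2+strand, fpos)
  SeedIndex seedIdx;
  for (int f = 0; f < nFrags; ++f) {
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& fs = strand ? Frc[f] : F[f];
      const int Lf = (int)fs.size();
      for (int p = 0; p + k <= Lf; p += stride) {
        uint64_t key;
        if (!encodeKmer(fs, p, k, key)) continue;
        seedIdx[key].push_back(std::make_pair(f * 2 + strand, p));
      }
    }
  }

  std::vector<int> o_read, o_frag, o_rs, o_re, o_fs, o_fe,
                   o_aln, o_match, o_gap;
  std::vector<char> o_strand;

  std::vector<Cluster> clusters;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;

  for (int r = 0; r < nReads; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    const int Lr = (int)rd.size();
    if (Lr < k) continue;
    // collect seed matches per (fragment, strand) by rolling over the read
    std::unordered_map<int, std::vector<Seed> > perFrag;
    uint64_t key = 0;
    int run = 0;
    for (int i = 0; i < Lr; ++i) {
      int b = baseCode(rd[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run < k) continue;
      SeedIndex::const_iterator it = seedIdx.find(key);
      if (it == seedIdx.end()) continue;
      if (it->second.size() > 64) continue;     // low-complexity guard
      const int rpos = i - k + 1;
      for (size_t j = 0; j < it->second.size(); ++j) {
        Seed s; s.qpos = it->second[j].second; s.tpos = rpos;
        perFrag[it->second[j].first].push_back(s);
      }
    }
    for (std::unordered_map<int, std::vector<Seed> >::iterator pf =
           perFrag.begin(); pf != perFrag.end(); ++pf) {
      const int f = pf->first / 2, strand = pf->first % 2;
      const std::string& fs = strand ? Frc[f] : F[f];
      const int Lf = (int)fs.size();
      clusterSeeds(pf->second, band, clusters);
      for (size_t c = 0; c < clusters.size(); ++c) {
        const Cluster& cl = clusters[c];
        if ((int)cl.seeds.size() < minSeeds) continue;
        const int d0 = (int)(cl.diagSum / (long)cl.seeds.size());
        // clip the fragment to the region the read can cover on diagonal d0
        const int f0 = std::max(0, -d0 - band);
        const int f1 = std::min(Lf, Lr - d0 + band);
        if (f1 - f0 < k) continue;
        // a clipped fragment can never reach minLen columns: skip the DP
        if (f1 - f0 + band < minLen) continue;
        const int t0 = std::max(0, f0 + d0 - band);
        const int t1 = std::min(Lr, f1 + d0 + band);
        AlnResult a = bandedLocal(fs, f0, f1, rd, t0, t1,
                                  f0 + d0 - t0, band);
        if (!a.ok || a.alnLen < minLen) continue;
        const double ident = (double)a.matches / (double)a.alnLen;
        if (ident < minIdentity) continue;
        int fragS = a.qs, fragE = a.qe;
        if (strand) { fragS = Lf - a.qe; fragE = Lf - a.qs; }
        o_read.push_back(r + 1); o_frag.push_back(f + 1);
        o_rs.push_back(a.ts); o_re.push_back(a.te);
        o_fs.push_back(fragS); o_fe.push_back(fragE);
        o_aln.push_back(a.alnLen); o_match.push_back(a.matches);
        o_gap.push_back(a.maxGap);
        o_strand.push_back(strand ? '-' : '+');
      }
    }
  }
  const int nh = (int)o_read.size();
  CharacterVector strandCol(nh);
  NumericVector ident(nh);
  for (int i = 0; i < nh; ++i) {
    strandCol[i] = std::string(1, o_strand[i]);
    ident[i] = (double)o_match[i] / (double)o_aln[i];
  }
  return DataFrame::create(
    _["readIdx"] = wrap(o_read), _["fragIdx"] = wrap(o_frag),
    _["readStart"] = wrap(o_rs), _["readEnd"] = wrap(o_re),
    _["fragStart"] = wrap(o_fs), _["fragEnd"] = wrap(o_fe),
    _["strand"] = strandCol, _["identity"] = ident,
    _["alnLen"] = wrap(o_aln), _["maxGap"] = wrap(o_gap),
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Short-read mapping by exact-seed + Hamming verification
//
// ref must be the doubled sequence for circular references (refLen = true
// length); placements are reported modulo refLen.  Substitution-only
// verification matches the simulator's short-read error model.  A read is
// "unique" when exactly one placement scores within `nearTol` mismatches of
// the best.

// [[Rcpp::export]]
DataFrame cpp_map_short_reads(CharacterVector reads, std::string ref,
                              int refLen, int k = 15, int maxMismatch = 6,
                              int nearTol = 5) {
  KmerMap idx;
  indexKmers(ref, k, idx);
  const int nReads = reads.size();
  const int Lref = (int)ref.size();

  IntegerVector o_pos(nReads), o_mm(nReads), o_nbest(nReads);
  CharacterVector o_strand(nReads);
  LogicalVector o_mapped(nReads), o_unique(nReads);

  std::vector<int> cand;
  for (int r = 0; r < nReads; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    const std::string rc = revcomp(rd);
    const int L = (int)rd.size();
    int bestMM = maxMismatch + 1, bestPos = -1;
    char bestStrand = '+';
    std::vector<std::pair<int,int> > hits;   // (position, mismatches)
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = strand ? rc : rd;
      cand.clear();
      const int step = std::max(1, (L - k) / 4);
      for (int off = 0; off + k <= L; off += step) {
        uint64_t key;
        if (!encodeKmer(s, off, k, key)) continue;
        KmerMap::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j) {
          const int p = it->second[j] - off;
          if (p >= 0 && p + L <= Lref) cand.push_back(p);
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        const int p = cand[ci];
        if (p >= refLen) continue;           // doubled-copy duplicate
        int mm = 0;
        for (int i = 0; i < L && mm <= maxMismatch; ++i)
          if (s[i] != ref[p + i]) ++mm;
        if (mm <= maxMismatch) {
          hits.push_back(std::make_pair(p, mm));
          if (mm < bestMM) { bestMM = mm; bestPos = p;
                             bestStrand = strand ? '-' : '+'; }
        }
      }
    }
    if (bestPos < 0) {
      o_mapped[r] = false; o_unique[r] = false;
      o_pos[r] = NA_INTEGER; o_mm[r] = NA_INTEGER; o_nbest[r] = 0;
      o_strand[r] = NA_STRING;
      continue;
    }
    int nBest = 0;
    for (size_t h = 0; h < hits.size(); ++h)
      if (hits[h].second <= bestMM + nearTol) ++nBest;
    o_mapped[r] = true;
    o_pos[r] = bestPos % refLen;
    o_mm[r] = bestMM;
    o_nbest[r] = nBest;
    o_unique[r] = (nBest == 1);
    o_strand[r] = std::string(1, bestStrand);
  }
  return DataFrame::create(
    _["mapped"] = o_mapped, _["pos"] = o_pos, _["strand"] = o_strand,
    _["mismatches"] = o_mm, _["nPlacements"] = o_nbest,
    _["unique"] = o_unique, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Draft-anchored pileup for consensus and polishing
//
// Aligns every segment to the draft (seed + banded local, better strand
// chosen by seed count) and tallies, per draft column, votes for
// A/C/G/T/deletion, plus the most frequent insertion immediately preceding
// each column (position p = insertion between draft columns p-1 and p).

// [[Rcpp::export]]
List cpp_pileup(std::string draft, CharacterVector segs,
                int k = 15, int stride = 20, int band = 80,
                int minSeeds = 2) {
  const int L = (int)draft.size();
  KmerMap idx;
  indexKmers(draft, k, idx);

  IntegerMatrix counts(5, L);   // rows: A, C, G, T, deletion
  std::vector<std::unordered_map<std::string, int> > ins(L + 1);
  IntegerVector depth(L);
  int nAligned = 0;

  std::vector<Seed> seeds;
  std::vector<Cluster> clusters;
  std::vector<AlnOp> path;

  for (int si = 0; si < segs.size(); ++si) {
    const std::string s0 = as<std::string>(segs[si]);
    const std::string s1 = revcomp(s0);
    // pick strand and cluster by seed support
    int bestStrand = -1, bestN = 0;
    long bestDiagSum = 0;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = strand ? s1 : s0;
      collectSeeds(s, idx, k, stride, 16, seeds);
      clusterSeeds(seeds, band, clusters);
      for (size_t c = 0; c < clusters.size(); ++c)
        if ((int)clusters[c].seeds.size() > bestN) {
          bestN = (int)clusters[c].seeds.size();
          bestStrand = strand;
          bestDiagSum = clusters[c].diagSum;
        }
    }
    if (bestStrand < 0 || bestN < minSeeds) continue;
    const std::string& s = bestStrand ? s1 : s0;
    const int Ls = (int)s.size();
    const int d0 = (int)(bestDiagSum / (long)bestN);
    const int q0 = std::max(0, -d0 - band);
    const int q1 = std::min(Ls, L - d0 + band);
    if (q1 - q0 < k) continue;
    const int t0 = std::max(0, q0 + d0 - band);
    const int t1 = std::min(L, q1 + d0 + band);
    AlnResult a = bandedLocal(s, q0, q1, draft, t0, t1,
                              q0 + d0 - t0, band, &path);
    if (!a.ok) continue;
    ++nAligned;
    std::string pendIns;
    int pendCol = -1;
    for (size_t p = 0; p < path.size(); ++p) {
      const AlnOp& op = path[p];
      if (op.op == 1) {
        if (!pendIns.empty()) {
          ins[op.tj][pendIns] += 1;
          pendIns.clear();
        }
        const int bc = baseCode(s[op.qi]);
        if (bc >= 0) { counts(bc, op.tj) += 1; depth[op.tj] += 1; }
      } else if (op.op == 2) {       // segment insertion before column tj
        pendIns.push_back(s[op.qi]);
        pendCol = op.tj;
      } else {                       // deletion: segment skips draft column
        if (!pendIns.empty()) { ins[op.tj][pendIns] += 1; pendIns.clear(); }
        counts(4, op.tj) += 1;
        depth[op.tj] += 1;
      }
    }
    if (!pendIns.empty() && pendCol >= 0) ins[pendCol][pendIns] += 1;
  }

  // export the majority insertion per position
  std::vector<int> insPos, insCount;
  std::vector<std::string> insSeq;
  for (int p = 0; p <= L; ++p) {
    if (ins[p].empty()) continue;
    int bn = 0; std::string bs;
    for (std::unordered_map<std::string,int>::const_iterator it =
           ins[p].begin(); it != ins[p].end(); ++it)
      if (it->second > bn ||
          (it->second == bn && it->first < bs)) {
        bn = it->second; bs = it->first;
      }
    insPos.push_back(p); insCount.push_back(bn); insSeq.push_back(bs);
  }
  return List::create(
    _["counts"] = counts, _["depth"] = depth,
    _["insPos"] = wrap(insPos), _["insSeq"] = wrap(insSeq),
    _["insCount"] = wrap(insCount), _["nAligned"] = nAligned);
}

// ---------------------------------------------------------------------------
// Ungapped seed-and-extend repeat scan support: extend a seed diagonal
// under (+reward, -penalty) scoring with an X-drop, returning the maximal
// scoring segment containing the seed.  Positions are 0-based.

// [[Rcpp::export]]
List cpp_ungapped_extend(std::string a, std::string b,
                         int seedA, int seedB, int seedLen,
                         int reward = 1, int penalty = 20, int xdrop = 40) {
  const int La = (int)a.size(), Lb = (int)b.size();
  int score = seedLen * reward;
  // extend right
  int bestScore = score, bestRight = seedA + seedLen;
  {
    int i = seedA + seedLen, j = seedB + seedLen, s = score;
    while (i < La && j < Lb) {
      s += (a[i] == b[j]) ? reward : -penalty;
      ++i; ++j;
      if (s > bestScore) { bestScore = s; bestRight = i; }
      if (bestScore - s > xdrop) break;
    }
  }
  // extend left
  int finalScore = bestScore, bestLeft = seedA;
  {
    int i = seedA - 1, j = seedB - 1, s = bestScore;
    while (i >= 0 && j >= 0) {
      s += (a[i] == b[j]) ? reward : -penalty;
      if (s > finalScore) { finalScore = s; bestLeft = i; }
      if (finalScore - s > xdrop) break;
      --i; --j;
    }
  }
  const int len = bestRight - bestLeft;
  int matches = 0;
  const int offset = seedB - seedA;
  for (int i = bestLeft; i < bestRight; ++i)
    if (a[i] == b[i + offset]) ++matches;
  return List::create(
    _["startA"] = bestLeft, _["endA"] = bestRight,
    _["startB"] = bestLeft + offset, _["endB"] = bestRight + offset,
    _["score"] = finalScore, _["length"] = len,
    _["identity"] = (double)matches / (double)len);
}
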