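// Core lattice routines for HP folding on the 3D FCC lattice.
// All randomness uses R's RNG (unif_rand) so results are reproducible
// from set.seed() across the R/C++ boundary.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Direction labels 1..12; label l uses index l-1.
// 1 FL(+1,+1,0)  2 FR(+1,-1,0)  3 FU(-1,+1,0)  4 FD(-1,-1,0)
// 5 BL(+1,0,+1)  6 BR(+1,0,-1)  7 BU(-1,0,+1)  8 BD(-1,0,-1)
// 9 LU(0,+1,+1) 10 LD(0,+1,-1) 11 RU(0,-1,+1) 12 RD(0,-1,-1)
static const int DX[12] = { 1, 1,-1,-1, 1, 1,-1,-1, 0, 0, 0, 0};
static const int DY[12] = { 1,-1, 1,-1, 0, 0, 0, 0, 1, 1,-1,-1};
static const int DZ[12] = { 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1};

static inline int64_t packKey(int x, int y, int z) {
  return ((int64_t)(x + 2048) * 4096 + (y + 2048)) * 4096 + (z + 2048);
}

static inline bool adjacentPts(int ax, int ay, int az, int bx, int by, int bz) {
  int dx = std::abs(ax - bx), dy = std::abs(ay - by), dz = std::abs(az - bz);
  return dx <= 1 && dy <= 1 && dz <= 1 && (dx + dy + dz) == 2;
}

// label (1..12) for step q - p, or 0 if not adjacent
static inline int stepLabel(int px, int py, int pz, int qx, int qy, int qz) {
  int dx = qx - px, dy = qy - py, dz = qz - pz;
  for (int l = 0; l < 12; ++l)
    if (DX[l] == dx && DY[l] == dy && DZ[l] == dz) return l + 1;
  return 0;
}

static inline int rint_unif(int n) {
  // uniform integer in 0..n-1 from R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static void checkLabels(const IntegerVector& labels) {
  for (int i = 0; i < labels.size(); ++i)
    if (labels[i] == NA_INTEGER || labels[i] < 1 || labels[i] > 12)
      stop("invalid direction label: labels must be integers in 1..12");
}

// [[Rcpp::export(name = ".decode_labels")]]
IntegerMatrix decode_labels(IntegerVector labels) {
  checkLabels(labels);
  int n = labels.size() + 1;
  IntegerMatrix out(n, 3);
  int x = 0, y = 0, z = 0;
  for (int i = 1; i < n; ++i) {
    int l = labels[i - 1] - 1;
    x += DX[l]; y += DY[l]; z += DZ[l];
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
  }
  return out;
}

// [[Rcpp::export(name = ".encode_coords")]]
IntegerVector encode_coords(IntegerMatrix coords) {
  int n = coords.nrow();
  if (n < 1) stop("need at least one point");
  IntegerVector labels(n - 1);
  for (int i = 1; i < n; ++i) {
    int l = stepLabel(coords(i - 1, 0), coords(i - 1, 1), coords(i - 1, 2),
                      coords(i, 0), coords(i, 1), coords(i, 2));
    if (l == 0) stop("consecutive points are not lattice-adjacent (row %d -> %d)", i, i + 1);
    labels[i - 1] = l;
  }
  return labels;
}

// [[Rcpp::export(name = ".is_saw_labels")]]
bool is_saw_labels(IntegerVector labels) {
  checkLabels(labels);
  int n = labels.size() + 1;
  std::unordered_set<int64_t> occ;
  occ.reserve(2 * n);
  int x = 0, y = 0, z = 0;
  occ.insert(packKey(0, 0, 0));
  for (int i = 1; i < n; ++i) {
    int l = labels[i - 1] - 1;
    x += DX[l]; y += DY[l]; z += DZ[l];
    if (!occ.insert(packKey(x, y, z)).second) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".contacts_coords")]]
int contacts_coords(IntegerMatrix coords, LogicalVector isH) {
  int n = coords.nrow();
  if (isH.size() != n) stop("sequence length and coordinate count differ");
  int cnt = 0;
  for (int i = 0; i < n - 2; ++i) {
    if (!isH[i]) continue;
    for (int j = i + 2; j < n; ++j) {
      if (!isH[j]) continue;
      if (adjacentPts(coords(i, 0), coords(i, 1), coords(i, 2),
                      coords(j, 0), coords(j, 1), coords(j, 2)))
        ++cnt;
    }
  }
  return cnt;
}

// HH contacts with at least one endpoint in `sel` (0-based indices)
static int contribContacts(const std::vector<int>& x, const std::vector<int>& y,
                           const std::vector<int>& z, const LogicalVector& isH,
                           const std::vector<char>& inSel,
                           const std::vector<int>& sel) {
  int n = (int)x.size(), cnt = 0;
  for (size_t s = 0; s < sel.size(); ++s) {
    int i = sel[s];
    if (!isH[i]) continue;
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= 1 || !isH[j]) continue;
      if (inSel[j] && j < i) continue;  // count in-selection pairs once
      if (adjacentPts(x[i], y[i], z[i], x[j], y[j], z[j])) ++cnt;
    }
  }
  return cnt;
}

static bool sawExtend(std::vector<int>& x, std::vector<int>& y, std::vector<int>& z,
                      std::unordered_set<int64_t>& occ, int n) {
  int m = (int)x.size();
  if (m == n) return true;
  int order[12];
  for (int i = 0; i < 12; ++i) order[i] = i;
  for (int i = 11; i > 0; --i) {      // Fisher-Yates from R RNG
    int j = rint_unif(i + 1);
    std::swap(order[i], order[j]);
  }
  for (int k = 0; k < 12; ++k) {
    int l = order[k];
    int nx = x.back() + DX[l], ny = y.back() + DY[l], nz = z.back() + DZ[l];
    int64_t key = packKey(nx, ny, nz);
    if (occ.count(key)) continue;
    x.push_back(nx); y.push_back(ny); z.push_back(nz);
    occ.insert(key);
    if (sawExtend(x, y, z, occ, n)) return true;
    occ.erase(key);
    x.pop_back(); y.pop_back(); z.pop_back();
  }
  return false;
}

// [[Rcpp::export(name = ".random_saw")]]
IntegerVector random_saw(int n) {
  if (n < 1) stop("chain length must be >= 1");
  std::vector<int> x, y, z;
  x.reserve(n); y.reserve(n); z.reserve(n);
  x.push_back(0); y.push_back(0); z.push_back(0);
  std::unordered_set<int64_t> occ;
  occ.insert(packKey(0, 0, 0));
  if (!sawExtend(x, y, z, occ, n))
    stop("random walk generation failed");  // cannot happen on FCC at these sizes
  IntegerVector labels(n - 1);
  for (int i = 1; i < n; ++i)
    labels[i - 1] = stepLabel(x[i - 1], y[i - 1], z[i - 1], x[i], y[i], z[i]);
  return labels;
}

// ---------------- rotation-based crossover ----------------

// perms: 17 x 12 integer matrix, row r = label permutation of rotation r+1.
// cut: number of head labels taken from labA (1 .. n-2).
// [[Rcpp::export(name = ".crossover_candidates")]]
List crossover_candidates(IntegerVector labA, IntegerVector labB, int cut,
                          IntegerMatrix perms, bool includeIdentity) {
  int m = labA.size();
  if (labB.size() != m) stop("parents have different chain lengths");
  if (m < 2) stop("parents must encode chains of length >= 3");
  if (cut < 1 || cut > m - 1) stop("cut point out of range");
  checkLabels(labA); checkLabels(labB);
  int tailLen = m - cut;
  std::vector<int> tail(tailLen);
  for (int i = 0; i < tailLen; ++i) tail[i] = labB[cut + i];
  int nrot = perms.nrow();
  List offspring;
  IntegerVector rotUsed;
  IntegerVector cand(m);
  for (int i = 0; i < cut; ++i) cand[i] = labA[i];
  for (int r = includeIdentity ? 0 : 1; r <= nrot; ++r) {
    for (int i = 0; i < tailLen; ++i)
      cand[cut + i] = (r == 0) ? tail[i] : perms(r - 1, tail[i] - 1);
    if (is_saw_labels(cand)) {
      offspring.push_back(clone(cand));
      rotUsed.push_back(r);  // 0 = identity, 1..17 = rotation index
    }
  }
  return List::create(_["offspring"] = offspring, _["rotation"] = rotUsed,
                      _["cut"] = cut);
}

// ---------------- generalized pull move ----------------

// One GPM attempt on (x,y,z); on success overwrites coords and returns new
// contact count, else returns -1 and leaves coords unchanged.
static int gpmAttempt(std::vector<int>& x, std::vector<int>& y, std::vector<int>& z,
                      const LogicalVector& isH, int curContacts) {
  int n = (int)x.size();
  if (n < 2) return -1;
  int i = rint_unif(n);
  int d = (unif_rand() < 0.5) ? 1 : -1;
  int prev = i - d;

  std::unordered_set<int64_t> occ;
  occ.reserve(2 * n);
  for (int k = 0; k < n; ++k) occ.insert(packKey(x[k], y[k], z[k]));

  std::vector<int> nx(x), ny(y), nz(z);
  std::vector<int> moved;
  std::vector<char> inMoved(n, 0);

  // relocate residue i
  occ.erase(packKey(x[i], y[i], z[i]));
  int ax, ay, az;  // site whose neighbourhood receives residue i
  if (prev >= 0 && prev < n) { ax = x[prev]; ay = y[prev]; az = z[prev]; }
  else {
    int nb = i + d;  // terminal residue: its single chain neighbour
    ax = x[nb]; ay = y[nb]; az = z[nb];
  }
  int cx[12], cy[12], cz[12], m = 0;
  for (int l = 0; l < 12; ++l) {
    int px = ax + DX[l], py = ay + DY[l], pz = az + DZ[l];
    if (!occ.count(packKey(px, py, pz))) { cx[m] = px; cy[m] = py; cz[m] = pz; ++m; }
  }
  if (m == 0) return -1;
  int pick = rint_unif(m);
  nx[i] = cx[pick]; ny[i] = cy[pick]; nz[i] = cz[pick];
  occ.insert(packKey(nx[i], ny[i], nz[i]));
  moved.push_back(i); inMoved[i] = 1;

  // propagate the pull toward direction d
  for (int j = i + d; j >= 0 && j < n; j += d) {
    int pj = j - d;  // already repositioned
    if (adjacentPts(nx[pj], ny[pj], nz[pj], x[j], y[j], z[j])) break;
    occ.erase(packKey(x[j], y[j], z[j]));
    m = 0;
    for (int l = 0; l < 12; ++l) {
      int px = nx[pj] + DX[l], py = ny[pj] + DY[l], pz = nz[pj] + DZ[l];
      if (!adjacentPts(px, py, pz, x[j], y[j], z[j])) continue;  // common neighbour
      if (occ.count(packKey(px, py, pz))) continue;
      cx[m] = px; cy[m] = py; cz[m] = pz; ++m;
    }
    if (m == 0) return -1;  // blocked: abort, caller keeps original
    pick = rint_unif(m);
    nx[j] = cx[pick]; ny[j] = cy[pick]; nz[j] = cz[pick];
    occ.insert(packKey(nx[j], ny[j], nz[j]));
    moved.push_back(j); inMoved[j] = 1;
  }

  int newContacts = curContacts
    - contribContacts(x, y, z, isH, inMoved, moved)
    + contribContacts(nx, ny, nz, isH, inMoved, moved);
  if (newContacts <= curContacts) return -1;  // strict improvement required
  x.swap(nx); y.swap(ny); z.swap(nz);
  return newContacts;
}

// [[Rcpp::export(name = ".gpm_sweep")]]
List gpm_sweep(IntegerVector labels, LogicalVector isH, int attempts) {
  checkLabels(labels);
  int n = labels.size() + 1;
  if (isH.size() != n) stop("sequence length and chain length differ");
  std::vector<int> x(n), y(n), z(n);
  x[0] = y[0] = z[0] = 0;
  for (int i = 1; i < n; ++i) {
    int l = labels[i - 1] - 1;
    x[i] = x[i - 1] + DX[l]; y[i] = y[i - 1] + DY[l]; z[i] = z[i - 1] + DZ[l];
  }
  IntegerMatrix cm(n, 3);
  for (int i = 0; i < n; ++i) { cm(i,0)=x[i]; cm(i,1)=y[i]; cm(i,2)=z[i]; }
  int contacts = contacts_coords(cm, isH);
  int accepted = 0;
  for (int a = 0; a < attempts; ++a) {
    int res = gpmAttempt(x, y, z, isH, contacts);
    if (res >= 0) { contacts = res; ++accepted; }
  }
  IntegerVector out(n - 1);
  for (int i = 1; i < n; ++i)
    out[i - 1] = stepLabel(x[i-1], y[i-1], z[i-1], x[i], y[i], z[i]);
  return List::create(_["labels"] = out, _["contacts"] = contacts,
                      _["accepted"] = accepted, _["attempts"] = attempts);
}

// ---------------- K-site move ----------------

// Admissible lower bound on FCC step count between two lattice points.
// [[Rcpp::export(name = ".step_bound")]]
int step_bound(IntegerVector p, IntegerVector q) {
  if (p.size() != 3 || q.size() != 3) stop("points must be integer triples");
  int dx = std::abs(p[0]-q[0]), dy = std::abs(p[1]-q[1]), dz = std::abs(p[2]-q[2]);
  int cheb = std::max(dx, std::max(dy, dz));
  int l1 = (dx + dy + dz + 1) / 2;
  return std::max(cheb, l1);
}

static inline int stepBound3(int dx, int dy, int dz) {
  dx = std::abs(dx); dy = std::abs(dy); dz = std::abs(dz);
  int cheb = std::max(dx, std::max(dy, dz));
  int l1 = (dx + dy + dz + 1) / 2;
  return std::max(cheb, l1);
}

struct KSiteSearch {
  int K;
  bool hasFar, prune;
  int fx, fy, fz;                       // far anchor
  const std::unordered_set<int64_t>* occ;
  std::vector<int> px, py, pz;          // current partial path
  // best complete candidate
  bool found = false;
  int bestContacts = -1;
  std::vector<int> bx, by, bz;
  double candidates = 0;
  // full-chain context for scoring
  const std::vector<int>* X; const std::vector<int>* Y; const std::vector<int>* Z;
  const LogicalVector* isH;
  std::vector<int> segIdx;              // chain indices of path points in path order
  int baseContacts = 0, segContrib = 0;
  std::vector<char> inSeg;

  void evaluate() {
    ++candidates;
    // build replacement coordinates
    std::vector<int> nx(*X), ny(*Y), nz(*Z);
    for (int k = 0; k < K; ++k) {
      nx[segIdx[k]] = px[k]; ny[segIdx[k]] = py[k]; nz[segIdx[k]] = pz[k];
    }
    int c = baseContacts - segContrib
      + contribContacts(nx, ny, nz, *isH, inSeg, segIdx);
    if (!found || c > bestContacts) {   // first-found wins ties
      found = true; bestContacts = c; bx = nx; by = ny; bz = nz;
    }
  }

  void dfs(int cx, int cy, int cz, int placed) {
    if (placed == K) {
      if (hasFar && !adjacentPts(cx, cy, cz, fx, fy, fz)) return;
      evaluate();
      return;
    }
    for (int l = 0; l < 12; ++l) {      // deterministic label order
      int qx = cx + DX[l], qy = cy + DY[l], qz = cz + DZ[l];
      if (occ->count(packKey(qx, qy, qz))) continue;
      bool onPath = false;
      for (int t = 0; t < placed; ++t)
        if (px[t] == qx && py[t] == qy && pz[t] == qz) { onPath = true; break; }
      if (onPath) continue;
      if (prune && hasFar &&
          (placed + 1) + stepBound3(qx - fx, qy - fy, qz - fz) > K + 1) continue;
      px[placed] = qx; py[placed] = qy; pz[placed] = qz;
      dfs(qx, qy, qz, placed + 1);
    }
  }
};

// start: 0-based first index of the segment, or -1 to draw uniformly.
// [[Rcpp::export(name = ".ksite_move")]]
List ksite_move(IntegerVector labels, LogicalVector isH, int K, int start,
                bool prune) {
  checkLabels(labels);
  int n = labels.size() + 1;
  if (isH.size() != n) stop("sequence length and chain length differ");
  if (K < 1 || K > n) stop("invalid K: must satisfy 1 <= K <= chain length");
  List unchanged = List::create(_["accepted"] = false, _["labels"] = labels,
                                _["delta"] = 0, _["candidates"] = 0.0,
                                _["start"] = NA_INTEGER);
  if (K == n) return unchanged;  // no anchor residue: degenerate, no move
  if (start < 0) start = rint_unif(n - K + 1);
  if (start > n - K) stop("segment start out of range");

  std::vector<int> x(n), y(n), z(n);
  x[0] = y[0] = z[0] = 0;
  for (int i = 1; i < n; ++i) {
    int l = labels[i - 1] - 1;
    x[i] = x[i-1] + DX[l]; y[i] = y[i-1] + DY[l]; z[i] = z[i-1] + DZ[l];
  }
  IntegerMatrix cm(n, 3);
  for (int i = 0; i < n; ++i) { cm(i,0)=x[i]; cm(i,1)=y[i]; cm(i,2)=z[i]; }
  int baseContacts = contacts_coords(cm, isH);

  int left = start - 1, right = start + K;  // anchors (may be out of range)
  std::unordered_set<int64_t> occ;
  occ.reserve(2 * n);
  for (int i = 0; i < n; ++i)
    if (i < start || i >= start + K) occ.insert(packKey(x[i], y[i], z[i]));

  KSiteSearch S;
  S.K = K; S.prune = prune; S.occ = &occ;
  S.X = &x; S.Y = &y; S.Z = &z; S.isH = &isH;
  S.px.assign(K, 0); S.py.assign(K, 0); S.pz.assign(K, 0);
  S.inSeg.assign(n, 0);
  for (int i = start; i < start + K; ++i) S.inSeg[i] = 1;
  S.baseContacts = baseContacts;

  int rootX, rootY, rootZ;
  if (left >= 0) {
    rootX = x[left]; rootY = y[left]; rootZ = z[left];
    S.hasFar = (right < n);
    if (S.hasFar) { S.fx = x[right]; S.fy = y[right]; S.fz = z[right]; }
    for (int k = 0; k < K; ++k) S.segIdx.push_back(start + k);
  } else {
    // segment touches the chain head: grow from the right anchor backwards
    rootX = x[right]; rootY = y[right]; rootZ = z[right];
    S.hasFar = false;
    for (int k = 0; k < K; ++k) S.segIdx.push_back(start + K - 1 - k);
  }
  {
    std::vector<int> seg(S.segIdx);
    S.segContrib = contribContacts(x, y, z, isH, S.inSeg, seg);
  }
  S.dfs(rootX, rootY, rootZ, 0);

  if (!S.found) { unchanged["start"] = start + 1; return unchanged; }
  bool differs = false;
  for (int i = start; i < start + K && !differs; ++i)
    differs = (S.bx[i] != x[i] || S.by[i] != y[i] || S.bz[i] != z[i]);
  if (!differs || S.bestContacts < baseContacts) {
    unchanged["candidates"] = S.candidates;
    unchanged["start"] = start + 1;
    return unchanged;
  }
  IntegerVector out(n - 1);
  for (int i = 1; i < n; ++i)
    out[i - 1] = stepLabel(S.bx[i-1], S.by[i-1], S.bz[i-1], S.bx[i], S.by[i], S.bz[i]);
  return List::create(_["accepted"] = true, _["labels"] = out,
                      _["delta"] = S.bestContacts - baseContacts,
                      _["candidates"] = S.candidates,
                      _["start"] = start + 1);
}

// ---------------- exhaustive enumeration oracle ----------------

struct EnumState {
  int n;
  LogicalVector isH;
  std::vector<int> x, y, z;
  std::unordered_set<int64_t> occ;
  int best = -1;
  double walks = 0;
  bool keep;
  int maxKeep;
  std::vector<std::vector<int>> bestWalksX, bestWalksY, bestWalksZ;

  void leaf(int contacts, double weight) {
    walks += weight;
    if (contacts > best) {
      best = contacts;
      bestWalksX.clear(); bestWalksY.clear(); bestWalksZ.clear();
    }
    if (keep && contacts == best && (int)bestWalksX.size() < maxKeep) {
      bestWalksX.push_back(x); bestWalksY.push_back(y); bestWalksZ.push_back(z);
    }
  }

  void grow(int contacts, double weight) {
    int m = (int)x.size();
    if (m == n) { leaf(contacts, weight); return; }
    for (int l = 0; l < 12; ++l) {
      int nx = x.back() + DX[l], ny = y.back() + DY[l], nz = z.back() + DZ[l];
      int64_t key = packKey(nx, ny, nz);
      if (occ.count(key)) continue;
      int add = 0;
      if (isH[m]) {
        for (int j = 0; j <= m - 2; ++j)
          if (isH[j] && adjacentPts(x[j], y[j], z[j], nx, ny, nz)) ++add;
      }
      x.push_back(nx); y.push_back(ny); z.push_back(nz); occ.insert(key);
      grow(contacts + add, weight);
      occ.erase(key); x.pop_back(); y.pop_back(); z.pop_back();
    }
  }

  // symmetry-reduced: prefix of label-1 steps, then a canonical branch label
  // (orbit representative under the 2-fold rotation about (1,1,0)) with
  // weight 2 for the paired orbits.
  void growReduced(int canonical[12], int weights[12]) {
    // all-collinear walk (labels all 1)
    {
      std::vector<int> cx(n), cy(n), cz(n);
      int contacts = 0;
      for (int i = 0; i < n; ++i) { cx[i] = i; cy[i] = i; cz[i] = 0; }
      // collinear points at |i-j|>=2 are never adjacent, so contacts = 0
      walks += 12;
      if (contacts > best) best = contacts;
      if (keep && contacts == best && (int)bestWalksX.size() < maxKeep) {
        bestWalksX.push_back(cx); bestWalksY.push_back(cy); bestWalksZ.push_back(cz);
      }
    }
    // walks with a first non-collinear step at position b (1-based step index >= 2)
    for (int b = 2; b <= n - 1; ++b) {
      x.assign(1, 0); y.assign(1, 0); z.assign(1, 0);
      occ.clear(); occ.insert(packKey(0, 0, 0));
      for (int i = 1; i < b; ++i) {
        x.push_back(i); y.push_back(i); z.push_back(0);
        occ.insert(packKey(i, i, 0));
      }
      for (int l = 0; l < 12; ++l) {
        if (!canonical[l]) continue;
        int nx = x.back() + DX[l], ny = y.back() + DY[l], nz = z.back() + DZ[l];
        int64_t key = packKey(nx, ny, nz);
        if (occ.count(key)) continue;  // excludes the backtrack label 4
        int m = (int)x.size();
        int add = 0;
        if (isH[m]) {
          for (int j = 0; j <= m - 2; ++j)
            if (isH[j] && adjacentPts(x[j], y[j], z[j], nx, ny, nz)) ++add;
        }
        x.push_back(nx); y.push_back(ny); z.push_back(nz); occ.insert(key);
        grow(add, 12.0 * weights[l]);
        occ.erase(key); x.pop_back(); y.pop_back(); z.pop_back();
      }
    }
  }
};

// [[Rcpp::export(name = ".enumerate_optimum")]]
List enumerate_optimum(LogicalVector isH, bool reduce, bool keepOptimal,
                       int maxKeep) {
  int n = isH.size();
  if (n < 1) stop("empty sequence");
  EnumState S;
  S.n = n; S.isH = isH; S.keep = keepOptimal; S.maxKeep = maxKeep;
  S.occ.reserve(4 * n);
  if (n == 1) {
    List lab;
    if (keepOptimal) lab.push_back(IntegerVector(0));
    return List::create(_["optimal"] = 0, _["walks"] = 1.0,
                        _["optimal_labels"] = lab);
  }
  if (!reduce) {
    S.x.assign(1, 0); S.y.assign(1, 0); S.z.assign(1, 0);
    S.occ.insert(packKey(0, 0, 0));
    S.grow(0, 1.0);
  } else {
    // 180-degree rotation about the label-1 axis (1,1,0): orbit structure of
    // the labels. Fixed: 1, 4. The other ten pair into five orbits.
    int sigma[12];
    for (int l = 0; l < 12; ++l) {
      // R = rotation by pi about unit axis (1,1,0)/sqrt(2): v -> 2(k.v)k - v
      int vx = DX[l], vy = DY[l], vz = DZ[l];
      int sx = vy, sy = vx, sz = -vz;  // closed form for this axis
      sigma[l] = stepLabel(0, 0, 0, sx, sy, sz) - 1;
    }
    int canonical[12], weights[12];
    for (int l = 0; l < 12; ++l) {
      if (l == 0 || l == 3) { canonical[l] = 0; weights[l] = 0; continue; }
      canonical[l] = (l <= sigma[l]);
      weights[l] = (sigma[l] == l) ? 1 : 2;
    }
    S.growReduced(canonical, weights);
  }
  List lab;
  if (keepOptimal) {
    for (size_t w = 0; w < S.bestWalksX.size(); ++w) {
      IntegerVector lv(n - 1);
      for (int i = 1; i < n; ++i)
        lv[i - 1] = stepLabel(S.bestWalksX[w][i-1], S.bestWalksY[w][i-1],
                              S.bestWalksZ[w][i-1], S.bestWalksX[w][i],
                              S.bestWalksY[w][i], S.bestWalksZ[w][i]);
      lab.push_back(lv);
    }
  }
  return List::create(_["optimal"] = S.best, _["walks"] = S.walks,
                      _["optimal_labels"] = lab);
}
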