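// Cellular Potts (GGH) lattice engine.
//
// State lives in a C++ struct behind an external pointer; R drives the
// Monte-Carlo loop in chunks and attaches hooks (mitosis, link-target
// updates, tracking) between chunks. All stochasticity flows through the
// single splitmix64 generator owned by the state, so a run is reproducible
// from (initial state, seed) alone.
//
// Conventions:
//  - owner grid is width x height, entry [x, y] = cell id sigma (1-based);
//    x runs horizontally, y vertically with y increasing downward.
//  - perimeter = count of unit edges between a cell's sites and sites it
//    does not own (4-neighbourhood edge-count convention).
//  - copy attempts use the 1st-order (4) neighbourhood; contact energy uses
//    a configurable neighbourhood of order 1 to 4 (4 to 20 neighbours).
//  - a fixed frame one site thick at the lattice border is never overwritten.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <queue>

using namespace Rcpp;

static const int NTYPES = 6; // OCC, IPC, CLEFT(A), MITOTIC, MATRIX, CLEFT(B)
// the two cleft walls carry distinct internal codes (3 and 6) so the
// wall-wall contact energy can differ from intra-wall cohesion; both are
// presented as type CLEFT at the R level
static const int TYPE_MATRIX = 5;

struct CpmState {
  int W, H;
  std::vector<int> owner;               // site -> sigma (1-based)
  // per-cell bookkeeping, indexed by sigma (entry 0 unused)
  std::vector<int>    type;
  std::vector<double> area, targetArea, lamA;
  std::vector<double> perim, targetPerim, lamP;
  std::vector<double> sumX, sumY;       // sums of owned-site coordinates
  std::vector<char>   constrained;
  // FPP links
  std::vector<int>    linkA, linkB;
  std::vector<double> linkLam, linkL;
  std::vector<std::vector<int> > cellLinks; // sigma -> link indices
  double J[NTYPES][NTYPES];
  int contactOrder;                     // 1..4
  double T;
  long long step, attempts, accepts;
  uint64_t rng;

  inline int idx(int x, int y) const { return x + y * W; }
  inline bool inGrid(int x, int y) const { return x >= 0 && x < W && y >= 0 && y < H; }
  inline bool isFrame(int x, int y) const {
    return x == 0 || y == 0 || x == W - 1 || y == H - 1;
  }
  inline double nextU() {
    // splitmix64; uniform double in [0, 1)
    uint64_t z = (rng += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    z = z ^ (z >> 31);
    return (z >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double cellJ(int ta, int tb) const { return J[ta - 1][tb - 1]; }
};

static const int DX4[4] = { 1, -1, 0, 0 };
static const int DY4[4] = { 0, 0, 1, -1 };
// neighbourhood offsets by increasing range: order 1 = first 4, order 2 =
// first 8, order 3 = first 12, order 4 = all 20
static const int DXN[20] = { 1, -1, 0, 0, 1, 1, -1, -1, 2, -2, 0, 0,
                             2, 2, -2, -2, 1, 1, -1, -1 };
static const int DYN[20] = { 0, 0, 1, -1, 1, -1, 1, -1, 0, 0, 2, -2,
                             1, -1, 1, -1, 2, -2, 2, -2 };
static const int NBRS_OF_ORDER[5] = { 0, 4, 8, 12, 20 };

static CpmState* ptrOf(SEXP xp) {
  Rcpp::XPtr<CpmState> p(xp);
  return p.get();
}

// ---- bookkeeping -----------------------------------------------------------

static void recountCell(const CpmState& S, int sigma,
                        double& a, double& p, double& sx, double& sy) {
  a = p = sx = sy = 0.0;
  for (int y = 0; y < S.H; ++y) {
    for (int x = 0; x < S.W; ++x) {
      if (S.owner[S.idx(x, y)] != sigma) continue;
      a += 1.0; sx += x + 1; sy += y + 1; // 1-based coordinates, as in R
      for (int d = 0; d < 4; ++d) {
        int nx = x + DX4[d], ny = y + DY4[d];
        if (!S.inGrid(nx, ny) || S.owner[S.idx(nx, ny)] != sigma) p += 1.0;
      }
    }
  }
}

static void recountAll(CpmState& S) {
  int nc = (int)S.type.size() - 1;
  std::fill(S.area.begin(), S.area.end(), 0.0);
  std::fill(S.perim.begin(), S.perim.end(), 0.0);
  std::fill(S.sumX.begin(), S.sumX.end(), 0.0);
  std::fill(S.sumY.begin(), S.sumY.end(), 0.0);
  for (int y = 0; y < S.H; ++y) {
    for (int x = 0; x < S.W; ++x) {
      int s = S.owner[S.idx(x, y)];
      if (s < 1 || s > nc) stop("owner grid references unknown cell id");
      S.area[s] += 1.0; S.sumX[s] += x + 1; S.sumY[s] += y + 1;
      for (int d = 0; d < 4; ++d) {
        int nx = x + DX4[d], ny = y + DY4[d];
        if (!S.inGrid(nx, ny) || S.owner[S.idx(nx, ny)] != s) S.perim[s] += 1.0;
      }
    }
  }
}

static void rebuildCellLinks(CpmState& S) {
  S.cellLinks.assign(S.type.size(), std::vector<int>());
  for (int k = 0; k < (int)S.linkA.size(); ++k) {
    S.cellLinks[S.linkA[k]].push_back(k);
    S.cellLinks[S.linkB[k]].push_back(k);
  }
}

// ---- energy terms ----------------------------------------------------------

static double contactEnergyFull(const CpmState& S) {
  // unordered neighbouring site pairs with different owners
  const int* DX = DXN;
  const int* DY = DYN;
  int nn = NBRS_OF_ORDER[S.contactOrder];
  double e = 0.0;
  for (int y = 0; y < S.H; ++y) {
    for (int x = 0; x < S.W; ++x) {
      int s = S.owner[S.idx(x, y)];
      for (int d = 0; d < nn; ++d) {
        int nx = x + DX[d], ny = y + DY[d];
        if (!S.inGrid(nx, ny)) continue;
        // count each unordered pair once
        if (ny < y || (ny == y && nx <= x)) continue;
        int s2 = S.owner[S.idx(nx, ny)];
        if (s2 != s) e += S.cellJ(S.type[s], S.type[s2]);
      }
    }
  }
  return e;
}

static double areaEnergyFull(const CpmState& S) {
  double e = 0.0;
  for (int s = 1; s < (int)S.type.size(); ++s) {
    if (!S.constrained[s]) continue;
    double d = S.area[s] - S.targetArea[s];
    e += S.lamA[s] * d * d;
  }
  return e;
}

static double perimEnergyFull(const CpmState& S) {
  double e = 0.0;
  for (int s = 1; s < (int)S.type.size(); ++s) {
    if (!S.constrained[s]) continue;
    double d = S.perim[s] - S.targetPerim[s];
    e += S.lamP[s] * d * d;
  }
  return e;
}

static double fppEnergyFull(const CpmState& S) {
  double e = 0.0;
  for (int k = 0; k < (int)S.linkA.size(); ++k) {
    int a = S.linkA[k], b = S.linkB[k];
    if (S.area[a] <= 0 || S.area[b] <= 0) stop("FPP link references an empty cell");
    double ax = S.sumX[a] / S.area[a], ay = S.sumY[a] / S.area[a];
    double bx = S.sumX[b] / S.area[b], by = S.sumY[b] / S.area[b];
    double l = std::sqrt((ax - bx) * (ax - bx) + (ay - by) * (ay - by));
    double d = l - S.linkL[k];
    e += S.linkLam[k] * d * d;
  }
  return e;
}

// ---- incremental delta H ---------------------------------------------------

// change in H if site (x,y), owned by sigOld, is overwritten by sigNew
static double deltaH(const CpmState& S, int x, int y, int sigOld, int sigNew) {
  double dH = 0.0;
  int i = S.idx(x, y);
  int tOld = S.type[sigOld], tNew = S.type[sigNew];

  // contact term over the contact neighbourhood of the rewritten site
  const int* DX = DXN;
  const int* DY = DYN;
  int nn = NBRS_OF_ORDER[S.contactOrder];
  for (int d = 0; d < nn; ++d) {
    int nx = x + DX[d], ny = y + DY[d];
    if (!S.inGrid(nx, ny)) continue;
    int sk = S.owner[S.idx(nx, ny)];
    int tk = S.type[sk];
    if (sk != sigNew) dH += S.cellJ(tNew, tk);
    if (sk != sigOld) dH -= S.cellJ(tOld, tk);
  }

  // area term
  if (S.constrained[sigOld]) {
    double a = S.area[sigOld], A = S.targetArea[sigOld];
    dH += S.lamA[sigOld] * ((a - 1 - A) * (a - 1 - A) - (a - A) * (a - A));
  }
  if (S.constrained[sigNew]) {
    double a = S.area[sigNew], A = S.targetArea[sigNew];
    dH += S.lamA[sigNew] * ((a + 1 - A) * (a + 1 - A) - (a - A) * (a - A));
  }

  // perimeter term (4-neighbourhood edge count)
  int cOld = 0, cNew = 0;
  for (int d = 0; d < 4; ++d) {
    int nx = x + DX4[d], ny = y + DY4[d];
    if (!S.inGrid(nx, ny)) continue;
    int sk = S.owner[S.idx(nx, ny)];
    if (sk == sigOld) ++cOld;
    if (sk == sigNew) ++cNew;
  }
  if (S.constrained[sigOld]) {
    double p = S.perim[sigOld], P = S.targetPerim[sigOld];
    double pNew = p - (4.0 - 2.0 * cOld);
    dH += S.lamP[sigOld] * ((pNew - P) * (pNew - P) - (p - P) * (p - P));
  }
  if (S.constrained[sigNew]) {
    double p = S.perim[sigNew], P = S.targetPerim[sigNew];
    double pNew = p + (4.0 - 2.0 * cNew);
    dH += S.lamP[sigNew] * ((pNew - P) * (pNew - P) - (p - P) * (p - P));
  }

  // FPP term: centroids of the two touched cells shift
  bool anyLinks = !S.cellLinks[sigOld].empty() || !S.cellLinks[sigNew].empty();
  if (anyLinks) {
    double px = x + 1, py = y + 1;
    double oxO = S.sumX[sigOld] / S.area[sigOld], oyO = S.sumY[sigOld] / S.area[sigOld];
    double nxO = S.sumX[sigNew] / S.area[sigNew], nyO = S.sumY[sigNew] / S.area[sigNew];
    double aO = S.area[sigOld] - 1.0;
    double oxN = aO > 0 ? (S.sumX[sigOld] - px) / aO : oxO;
    double oyN = aO > 0 ? (S.sumY[sigOld] - py) / aO : oyO;
    double nxN = (S.sumX[sigNew] + px) / (S.area[sigNew] + 1.0);
    double nyN = (S.sumY[sigNew] + py) / (S.area[sigNew] + 1.0);
    for (int pass = 0; pass < 2; ++pass) {
      int c = pass == 0 ? sigOld : sigNew;
      const std::vector<int>& ls = S.cellLinks[c];
      for (size_t q = 0; q < ls.size(); ++q) {
        int k = ls[q];
        int a = S.linkA[k], b = S.linkB[k];
        // a link joining sigOld and sigNew would be visited twice; count once
        if (pass == 1 && (a == sigOld || b == sigOld)) continue;
        double axO, ayO, bxO, byO, axN, ayN, bxN, byN;
        if (a == sigOld)      { axO = oxO; ayO = oyO; axN = oxN; ayN = oyN; }
        else if (a == sigNew) { axO = nxO; ayO = nyO; axN = nxN; ayN = nyN; }
        else { axO = axN = S.sumX[a] / S.area[a]; ayO = ayN = S.sumY[a] / S.area[a]; }
        if (b == sigOld)      { bxO = oxO; byO = oyO; bxN = oxN; byN = oyN; }
        else if (b == sigNew) { bxO = nxO; byO = nyO; bxN = nxN; byN = nyN; }
        else { bxO = bxN = S.sumX[b] / S.area[b]; byO = byN = S.sumY[b] / S.area[b]; }
        double lO = std::sqrt((axO - bxO) * (axO - bxO) + (ayO - byO) * (ayO - byO));
        double lN = std::sqrt((axN - bxN) * (axN - bxN) + (ayN - byN) * (ayN - byN));
        double dO = lO - S.linkL[k], dN = lN - S.linkL[k];
        dH += S.linkLam[k] * (dN * dN - dO * dO);
      }
    }
  }
  return dH;
}

static void applyCopy(CpmState& S, int x, int y, int sigOld, int sigNew) {
  int i = S.idx(x, y);
  int cOld = 0, cNew = 0;
  for (int d = 0; d < 4; ++d) {
    int nx = x + DX4[d], ny = y + DY4[d];
    if (!S.inGrid(nx, ny)) continue;
    int sk = S.owner[S.idx(nx, ny)];
    if (sk == sigOld) ++cOld;
    if (sk == sigNew) ++cNew;
  }
  S.owner[i] = sigNew;
  S.area[sigOld] -= 1.0; S.area[sigNew] += 1.0;
  S.perim[sigOld] -= 4.0 - 2.0 * cOld;
  S.perim[sigNew] += 4.0 - 2.0 * cNew;
  S.sumX[sigOld] -= x + 1; S.sumY[sigOld] -= y + 1;
  S.sumX[sigNew] += x + 1; S.sumY[sigNew] += y + 1;
}

// ---- exported interface ----------------------------------------------------

// [[Rcpp::export]]
SEXP cpm_create(IntegerMatrix owner, IntegerVector cellType,
                NumericVector targetArea, NumericVector lambdaArea,
                NumericVector targetPerim, NumericVector lambdaPerim,
                LogicalVector constrained, NumericMatrix J,
                int contactOrder, double temperature, double seed) {
  if (J.nrow() != NTYPES || J.ncol() != NTYPES)
    stop("contact table must be 6x6 (OCC, IPC, CLEFT, MITOTIC, MATRIX, CLEFT)");
  if (contactOrder < 1 || contactOrder > 4)
    stop("contactOrder must be 1, 2, 3 or 4");
  if (temperature <= 0) stop("temperature must be > 0");
  for (int a = 0; a < NTYPES; ++a)
    for (int b = 0; b < NTYPES; ++b)
      if (std::abs(J(a, b) - J(b, a)) > 1e-12) stop("contact table must be symmetric");

  CpmState* S = new CpmState();
  S->W = owner.nrow(); S->H = owner.ncol();
  S->owner.resize((size_t)S->W * S->H);
  for (int y = 0; y < S->H; ++y)
    for (int x = 0; x < S->W; ++x)
      S->owner[S->idx(x, y)] = owner(x, y);

  int nc = cellType.size();
  S->type.resize(nc + 1); S->targetArea.resize(nc + 1); S->lamA.resize(nc + 1);
  S->targetPerim.resize(nc + 1); S->lamP.resize(nc + 1); S->constrained.resize(nc + 1);
  S->area.resize(nc + 1); S->perim.resize(nc + 1); S->sumX.resize(nc + 1); S->sumY.resize(nc + 1);
  for (int s = 1; s <= nc; ++s) {
    S->type[s] = cellType[s - 1];
    if (S->type[s] < 1 || S->type[s] > NTYPES) { delete S; stop("unknown cell type code"); }
    S->targetArea[s] = targetArea[s - 1]; S->lamA[s] = lambdaArea[s - 1];
    S->targetPerim[s] = targetPerim[s - 1]; S->lamP[s] = lambdaPerim[s - 1];
    S->constrained[s] = constrained[s - 1] ? 1 : 0;
    if (S->type[s] == TYPE_MATRIX && S->constrained[s])
      { delete S; stop("the matrix cell must be unconstrained"); }
  }
  for (int a = 0; a < NTYPES; ++a)
    for (int b = 0; b < NTYPES; ++b)
      S->J[a][b] = J(a, b);
  S->contactOrder = contactOrder;
  S->T = temperature;
  S->step = S->attempts = S->accepts = 0;
  S->rng = (uint64_t)seed;
  recountAll(*S);
  rebuildCellLinks(*S);
  Rcpp::XPtr<CpmState> xp(S, true);
  return xp;
}

// [[Rcpp::export]]
List cpm_run(SEXP xp, int nSteps) {
  CpmState& S = *ptrOf(xp);
  if (nSteps < 0) stop("nSteps must be >= 0");
  long long N = (long long)S.W * S.H;
  long long att0 = S.attempts, acc0 = S.accepts;
  for (int m = 0; m < nSteps; ++m) {
    for (long long t = 0; t < N; ++t) {
      ++S.attempts;
      int site = (int)(S.nextU() * N); if (site >= N) site = (int)N - 1;
      int x = site % S.W, y = site / S.W;
      int dir = (int)(S.nextU() * 4.0); if (dir > 3) dir = 3;
      int tx = x + DX4[dir], ty = y + DY4[dir];
      if (!S.inGrid(tx, ty) || S.isFrame(tx, ty)) continue;
      int sigNew = S.owner[S.idx(x, y)];
      int sigOld = S.owner[S.idx(tx, ty)];
      if (sigOld == sigNew) continue;
      // never annihilate a non-matrix cell
      if (S.area[sigOld] <= 1.0 && S.type[sigOld] != TYPE_MATRIX) continue;
      double dH = deltaH(S, tx, ty, sigOld, sigNew);
      bool acc = dH < 0.0 ? true : (S.nextU() < std::exp(-dH / S.T));
      if (acc) {
        applyCopy(S, tx, ty, sigOld, sigNew);
        ++S.accepts;
      }
    }
    ++S.step;
  }
  return List::create(_["attempts"] = (double)(S.attempts - att0),
                      _["accepts"] = (double)(S.accepts - acc0));
}

// [[Rcpp::export]]
List cpm_info(SEXP xp) {
  CpmState& S = *ptrOf(xp);
  return List::create(_["width"] = S.W, _["height"] = S.H,
                      _["step"] = (double)S.step,
                      _["attempts"] = (double)S.attempts,
                      _["accepts"] = (double)S.accepts,
                      _["temperature"] = S.T,
                      _["contactOrder"] = S.contactOrder,
                      _["nCells"] = (int)S.type.size() - 1,
                      _["nLinks"] = (int)S.linkA.size());
}

// [[Rcpp::export]]
void cpm_set_step(SEXP xp, double step) { ptrOf(xp)->step = (long long)step; }

// [[Rcpp::export]]
void cpm_set_temperature(SEXP xp, double T) {
  if (T <= 0) stop("temperature must be > 0");
  ptrOf(xp)->T = T;
}

// [[Rcpp::export]]
IntegerMatrix cpm_owner(SEXP xp) {
  CpmState& S = *ptrOf(xp);
  IntegerMatrix out(S.W, S.H);
  for (int y = 0; y < S.H; ++y)
    for (int x = 0; x < S.W; ++x)
      out(x, y) = S.owner[S.idx(x, y)];
  return out;
}

// [[Rcpp::export]]
List cpm_cells(SEXP xp) {
  CpmState& S = *ptrOf(xp);
  int nc = (int)S.type.size() - 1;
  IntegerVector id(nc), type(nc);
  NumericVector area(nc), tA(nc), lA(nc), perim(nc), tP(nc), lP(nc), cx(nc), cy(nc);
  LogicalVector cons(nc);
  for (int s = 1; s <= nc; ++s) {
    id[s - 1] = s; type[s - 1] = S.type[s];
    area[s - 1] = S.area[s]; tA[s - 1] = S.targetArea[s]; lA[s - 1] = S.lamA[s];
    perim[s - 1] = S.perim[s]; tP[s - 1] = S.targetPerim[s]; lP[s - 1] = S.lamP[s];
    cx[s - 1] = S.area[s] > 0 ? S.sumX[s] / S.area[s] : NA_REAL;
    cy[s - 1] = S.area[s] > 0 ? S.sumY[s] / S.area[s] : NA_REAL;
    cons[s - 1] = S.constrained[s] != 0;
  }
  return List::create(_["id"] = id, _["type"] = type, _["area"] = area,
                      _["targetArea"] = tA, _["lambdaArea"] = lA,
                      _["perimeter"] = perim, _["targetPerim"] = tP,
                      _["lambdaPerim"] = lP, _["cx"] = cx, _["cy"] = cy,
                      _["constrained"] = cons);
}

// [[Rcpp::export]]
void cpm_set_links(SEXP xp, IntegerVector a, IntegerVector b,
                   NumericVector lambda, NumericVector L) {
  CpmState& S = *ptrOf(xp);
  int n = a.size();
  if (b.size() != n || lambda.size() != n || L.size() != n)
    stop("link vectors must have equal length");
  int nc = (int)S.type.size() - 1;
  for (int k = 0; k < n; ++k) {
    if (a[k] < 1 || a[k] > nc || b[k] < 1 || b[k] > nc) stop("link references unknown cell");
    if (a[k] == b[k]) stop("link endpoints must differ");
    if (L[k] < 0 || lambda[k] < 0) stop("link lambda and target length must be >= 0");
  }
  S.linkA.assign(a.begin(), a.end());
  S.linkB.assign(b.begin(), b.end());
  S.linkLam.assign(lambda.begin(), lambda.end());
  S.linkL.assign(L.begin(), L.end());
  rebuildCellLinks(S);
}

// [[Rcpp::export]]
List cpm_links(SEXP xp) {
  CpmState& S = *ptrOf(xp);
  return List::create(_["a"] = IntegerVector(S.linkA.begin(), S.linkA.end()),
                      _["b"] = IntegerVector(S.linkB.begin(), S.linkB.end()),
                      _["lambda"] = NumericVector(S.linkLam.begin(), S.linkLam.end()),
                      _["L"] = NumericVector(S.linkL.begin(), S.linkL.end()));
}

// [[Rcpp::export]]
void cpm_set_link_targets(SEXP xp, IntegerVector idx, NumericVector L) {
  CpmState& S = *ptrOf(xp);
  for (int k = 0; k < idx.size(); ++k) {
    int i = idx[k] - 1;
    if (i < 0 || i >= (int)S.linkL.size()) stop("link index out of range");
    if (L[k] < 0) stop("target length must be >= 0");
    S.linkL[i] = L[k];
  }
}

// [[Rcpp::export]]
List cpm_energy(SEXP xp) {
  CpmState& S = *ptrOf(xp);
  double ec = contactEnergyFull(S), ea = areaEnergyFull(S),
         ep = perimEnergyFull(S), ef = fppEnergyFull(S);
  return List::create(_["contact"] = ec, _["area"] = ea, _["perimeter"] = ep,
                      _["fpp"] = ef, _["total"] = ec + ea + ep + ef);
}

// [[Rcpp::export]]
double cpm_delta_energy(SEXP xp, int sx, int sy, int tx, int ty) {
  CpmState& S = *ptrOf(xp);
  if (!S.inGrid(sx - 1, sy - 1) || !S.inGrid(tx - 1, ty - 1)) stop("site out of grid");
  int sigNew = S.owner[S.idx(sx - 1, sy - 1)];
  int sigOld = S.owner[S.idx(tx - 1, ty - 1)];
  if (sigNew == sigOld) stop("source and target share an owner");
  return deltaH(S, tx - 1, ty - 1, sigOld, sigNew);
}

// [[Rcpp::export]]
void cpm_apply_copy(SEXP xp, int sx, int sy, int tx, int ty) {
  CpmState& S = *ptrOf(xp);
  if (!S.inGrid(sx - 1, sy - 1) || !S.inGrid(tx - 1, ty - 1)) stop("site out of grid");
  int sigNew = S.owner[S.idx(sx - 1, sy - 1)];
  int sigOld = S.owner[S.idx(tx - 1, ty - 1)];
  if (sigNew == sigOld) stop("source and target share an owner");
  applyCopy(S, tx - 1, ty - 1, sigOld, sigNew);
}

// [[Rcpp::export]]
int cpm_accept_trials(SEXP xp, double dH, int n) {
  CpmState& S = *ptrOf(xp);
  int acc = 0;
  for (int i = 0; i < n; ++i) {
    bool a = dH < 0.0 ? true : (S.nextU() < std::exp(-dH / S.T));
    if (a) ++acc;
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpm_runif(SEXP xp, int n) {
  CpmState& S = *ptrOf(xp);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = S.nextU();
  return out;
}

// [[Rcpp::export]]
List cpm_audit(SEXP xp) {
  // full recount from the owner grid vs cached bookkeeping
  CpmState& S = *ptrOf(xp);
  int nc = (int)S.type.size() - 1;
  double dA = 0, dP = 0, dC = 0, totalArea = 0;
  for (int s = 1; s <= nc; ++s) {
    double a, p, sx, sy;
    recountCell(S, s, a, p, sx, sy);
    totalArea += a;
    dA = std::max(dA, std::abs(a - S.area[s]));
    dP = std::max(dP, std::abs(p - S.perim[s]));
    if (a > 0 && S.area[s] > 0) {
      dC = std::max(dC, std::abs(sx / a - S.sumX[s] / S.area[s]));
      dC = std::max(dC, std::abs(sy / a - S.sumY[s] / S.area[s]));
    }
  }
  return List::create(_["maxAreaError"] = dA, _["maxPerimError"] = dP,
                      _["maxCentroidError"] = dC, _["totalArea"] = totalArea,
                      _["latticeSites"] = (double)S.W * S.H);
}

// [[Rcpp::export]]
IntegerVector cpm_fragments(SEXP xp) {
  // connected (4-neighbourhood) components per cell
  CpmState& S = *ptrOf(xp);
  int nc = (int)S.type.size() - 1;
  IntegerVector comp(nc);
  std::vector<char> seen((size_t)S.W * S.H, 0);
  for (int y = 0; y < S.H; ++y) {
    for (int x = 0; x < S.W; ++x) {
      int i = S.idx(x, y);
      if (seen[i]) continue;
      int s = S.owner[i];
      comp[s - 1] += 1;
      std::queue<int> q; q.push(i); seen[i] = 1;
      while (!q.empty()) {
        int j = q.front(); q.pop();
        int jx = j % S.W, jy = j / S.W;
        for (int d = 0; d < 4; ++d) {
          int nx = jx + DX4[d], ny = jy + DY4[d];
          if (!S.inGrid(nx, ny)) continue;
          int k = S.idx(nx, ny);
          if (!seen[k] && S.owner[k] == s) { seen[k] = 1; q.push(k); }
        }
      }
    }
  }
  return comp;
}

// [[Rcpp::export]]
void cpm_set_cell(SEXP xp, int sigma, int type, double targetArea,
                  double targetPerim) {
  CpmState& S = *ptrOf(xp);
  if (sigma < 1 || sigma >= (int)S.type.size()) stop("unknown cell id");
  if (type < 1 || type > NTYPES) stop("unknown cell type code");
  S.type[sigma] = type;
  S.targetArea[sigma] = targetArea;
  S.targetPerim[sigma] = targetPerim;
}

// [[Rcpp::export]]
bool cpm_touches_matrix(SEXP xp, int sigma) {
  CpmState& S = *ptrOf(xp);
  for (int y = 0; y < S.H; ++y)
    for (int x = 0; x < S.W; ++x) {
      if (S.owner[S.idx(x, y)] != sigma) continue;
      for (int d = 0; d < 4; ++d) {
        int nx = x + DX4[d], ny = y + DY4[d];
        if (!S.inGrid(nx, ny)) continue;
        int s2 = S.owner[S.idx(nx, ny)];
        if (S.type[s2] == TYPE_MATRIX) return true;
      }
    }
  return false;
}

// [[Rcpp::export]]
List cpm_divide(SEXP xp, int sigma, double theta) {
  // split the cell's sites into two equal halves (+-1) by the line through
  // the centroid with orientation theta; the half on the positive side
  // becomes a new cell. Minor disconnected fragments of either half are
  // reassigned to the other daughter to keep both 4-connected.
  CpmState& S = *ptrOf(xp);
  if (sigma < 1 || sigma >= (int)S.type.size()) stop("unknown cell id");
  if (S.area[sigma] < 2) stop("cell too small to divide");

  std::vector<int> sites;
  for (int y = 0; y < S.H; ++y)
    for (int x = 0; x < S.W; ++x)
      if (S.owner[S.idx(x, y)] == sigma) sites.push_back(S.idx(x, y));

  double cx = S.sumX[sigma] / S.area[sigma], cy = S.sumY[sigma] / S.area[sigma];
  double nx = -std::sin(theta), ny = std::cos(theta);
  std::vector<std::pair<double, int> > proj(sites.size());
  for (size_t i = 0; i < sites.size(); ++i) {
    int x = sites[i] % S.W, y = sites[i] / S.W;
    proj[i] = std::make_pair(nx * (x + 1 - cx) + ny * (y + 1 - cy), sites[i]);
  }
  std::stable_sort(proj.begin(), proj.end());
  size_t half = proj.size() / 2;

  // new cell inherits the parent's energy parameters
  int newSig = (int)S.type.size();
  S.type.push_back(S.type[sigma]);
  S.targetArea.push_back(S.targetArea[sigma]); S.lamA.push_back(S.lamA[sigma]);
  S.targetPerim.push_back(S.targetPerim[sigma]); S.lamP.push_back(S.lamP[sigma]);
  S.constrained.push_back(S.constrained[sigma]);
  S.area.push_back(0); S.perim.push_back(0); S.sumX.push_back(0); S.sumY.push_back(0);
  S.cellLinks.push_back(std::vector<int>());

  for (size_t i = half; i < proj.size(); ++i) S.owner[proj[i].second] = newSig;

  // reconnect: within each daughter keep the largest 4-connected component,
  // hand minor components to the sibling
  for (int pass = 0; pass < 2; ++pass) {
    int who = pass == 0 ? sigma : newSig;
    int other = pass == 0 ? newSig : sigma;
    // component labelling restricted to 'who'
    std::vector<int> mine;
    for (size_t i = 0; i < sites.size(); ++i)
      if (S.owner[sites[i]] == who) mine.push_back(sites[i]);
    if (mine.empty()) continue;
    std::vector<int> label((size_t)S.W * S.H, 0);
    int nlab = 0; std::vector<int> compSize;
    for (size_t i = 0; i < mine.size(); ++i) {
      if (label[mine[i]]) continue;
      ++nlab; compSize.push_back(0);
      std::queue<int> q; q.push(mine[i]); label[mine[i]] = nlab;
      while (!q.empty()) {
        int j = q.front(); q.pop(); ++compSize[nlab - 1];
        int jx = j % S.W, jy = j / S.W;
        for (int d = 0; d < 4; ++d) {
          int ax = jx + DX4[d], ay = jy + DY4[d];
          if (!S.inGrid(ax, ay)) continue;
          int k = S.idx(ax, ay);
          if (!label[k] && S.owner[k] == who) { label[k] = nlab; q.push(k); }
        }
      }
    }
    if (nlab > 1) {
      int keep = 1;
      for (int l = 2; l <= nlab; ++l) if (compSize[l - 1] > compSize[keep - 1]) keep = l;
      for (size_t i = 0; i < mine.size(); ++i)
        if (label[mine[i]] != keep) S.owner[mine[i]] = other;
    }
  }

  // refresh bookkeeping for the two daughters
  double a, p, sx, sy;
  recountCell(S, sigma, a, p, sx, sy);
  S.area[sigma] = a; S.perim[sigma] = p; S.sumX[sigma] = sx; S.sumY[sigma] = sy;
  recountCell(S, newSig, a, p, sx, sy);
  S.area[newSig] = a; S.perim[newSig] = p; S.sumX[newSig] = sx; S.sumY[newSig] = sy;

  return List::create(_["parent"] = sigma, _["daughter"] = newSig,
                      _["parentArea"] = S.area[sigma],
                      _["daughterArea"] = S.area[newSig]);
}

// [[Rcpp::export]]
double cpm_finger_depth(SEXP xp, int x0, int x1, int y0, int y1, int from) {
  // deepest run of matrix-owned sites entering the window from one edge:
  // from = 1 top (scan +y), 2 bottom (-y), 3 left (+x), 4 right (-x)
  CpmState& S = *ptrOf(xp);
  --x0; --x1; --y0; --y1;
  if (x0 < 0 || y0 < 0 || x1 >= S.W || y1 >= S.H || x0 > x1 || y0 > y1)
    stop("window out of grid");
  double best = 0;
  if (from == 1 || from == 2) {
    for (int x = x0; x <= x1; ++x) {
      int run = 0;
      if (from == 1) { for (int y = y0; y <= y1; ++y) { if (S.type[S.owner[S.idx(x, y)]] == TYPE_MATRIX) ++run; else break; } }
      else           { for (int y = y1; y >= y0; --y) { if (S.type[S.owner[S.idx(x, y)]] == TYPE_MATRIX) ++run; else break; } }
      if (run > best) best = run;
    }
  } else if (from == 3 || from == 4) {
    for (int y = y0; y <= y1; ++y) {
      int run = 0;
      if (from == 3) { for (int x = x0; x <= x1; ++x) { if (S.type[S.owner[S.idx(x, y)]] == TYPE_MATRIX) ++run; else break; } }
      else           { for (int x = x1; x >= x0; --x) { if (S.type[S.owner[S.idx(x, y)]] == TYPE_MATRIX) ++run; else break; } }
      if (run > best) best = run;
    }
  } else stop("'from' must be 1..4");
  return best;
}
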