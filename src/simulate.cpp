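#include <Rcpp.h>
using namespace Rcpp;

// Lattice exclusion process: agents are s x s squares (s odd) whose centres
// sit on integer sites of an L x L lattice; two agents overlap iff their
// centre offsets are < s in both axes, i.e. iff their footprints share a
// site. Occupancy of footprint sites is kept in a byte grid so overlap
// checks are O(s^2).

static inline bool footprint_free(const std::vector<unsigned char>& occ,
                                  int L, int h, int cx, int cy) {
  for (int x = cx - h; x <= cx + h; ++x) {
    const unsigned char* col = &occ[(size_t)(x - 1) * L];
    for (int y = cy - h; y <= cy + h; ++y) {
      if (col[y - 1]) return false;
    }
  }
  return true;
}

static inline void mark_footprint(std::vector<unsigned char>& occ,
                                  int L, int h, int cx, int cy) {
  for (int x = cx - h; x <= cx + h; ++x) {
    unsigned char* col = &occ[(size_t)(x - 1) * L];
    for (int y = cy - h; y <= cy + h; ++y) col[y - 1] = 1;
  }
}

static inline int runif_int(int lo, int hi) {  // uniform on {lo, ..., hi}
  int v = lo + (int)(unif_rand() * (hi - lo + 1));
  return v > hi ? hi : v;
}

// [[Rcpp::export]]
IntegerMatrix cpp_place_agents(int L, int s, int n_target, int max_attempts) {
  if (s < 1 || s % 2 == 0) stop("agent side 's' must be odd and >= 1");
  int h = (s - 1) / 2;
  if (L < s) stop("lattice smaller than one agent");
  std::vector<unsigned char> occ((size_t)L * L, 0);
  IntegerMatrix centres(n_target, 2);
  int placed = 0;
  long long attempts = 0;
  while (placed < n_target) {
    if (++attempts > max_attempts) {
      stop("failed to place %d non-overlapping agents after %d attempts; "
           "the requested density is too high, lower rho0",
           n_target, max_attempts);
    }
    int cx = runif_int(h + 1, L - h);
    int cy = runif_int(h + 1, L - h);
    if (footprint_free(occ, L, h, cx, cy)) {
      mark_footprint(occ, L, h, cx, cy);
      centres(placed, 0) = cx;
      centres(placed, 1) = cy;
      ++placed;
    }
  }
  return centres;
}

// Random sequential update with proliferation: per step, n agents (n fixed
// at the start of the step) are selected uniformly with replacement from
// the current population; each selected agent divides with probability R,
// placing a daughter centre offset by exactly s along one of the four axis
// directions (footprints touch without overlapping). Attempts whose
// daughter footprint overlaps anything or crosses the no-flux boundary are
// aborted silently.
// [[Rcpp::export]]
IntegerMatrix cpp_proliferate(IntegerMatrix centres, int L, int s,
                              double R, int steps) {
  if (s < 1 || s % 2 == 0) stop("agent side 's' must be odd and >= 1");
  int h = (s - 1) / 2;
  std::vector<int> xs, ys;
  xs.reserve(centres.nrow() * 2);
  ys.reserve(centres.nrow() * 2);
  std::vector<unsigned char> occ((size_t)L * L, 0);
  for (int i = 0; i < centres.nrow(); ++i) {
    xs.push_back(centres(i, 0));
    ys.push_back(centres(i, 1));
    mark_footprint(occ, L, h, centres(i, 0), centres(i, 1));
  }
  const int dx[4] = {1, -1, 0, 0};
  const int dy[4] = {0, 0, 1, -1};
  for (int step = 0; step < steps; ++step) {
    int n_step = (int)xs.size();
    for (int draw = 0; draw < n_step; ++draw) {
      int idx = runif_int(0, (int)xs.size() - 1);
      if (R < 1.0 && unif_rand() >= R) continue;
      int dir = runif_int(0, 3);
      int cx = xs[idx] + dx[dir] * s;
      int cy = ys[idx] + dy[dir] * s;
      if (cx < h + 1 || cx > L - h || cy < h + 1 || cy > L - h) continue;
      if (!footprint_free(occ, L, h, cx, cy)) continue;
      mark_footprint(occ, L, h, cx, cy);
      xs.push_back(cx);
      ys.push_back(cy);
    }
  }
  IntegerMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i];
    out(i, 1) = ys[i];
  }
  return out;
}
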