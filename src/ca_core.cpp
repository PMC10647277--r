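#include <Rcpp.h>
using namespace Rcpp;

// Moore-neighborhood offsets, fixed order (row offset, col offset).
// The R reference sweep in the test helpers replays this exact order.
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// bias codes: 0 = isotropic, 1 = drop the two backward diagonals,
// 2 = drop all three backward sites. "Backward" = away from the wound
// center column; cells sitting exactly on the center column are unbiased.
static inline bool bias_excluded(int dr, int dc, int col, int center, int bias) {
    if (bias == 0 || col == center) return false;
    int back = (col < center) ? -1 : 1;
    if (dc != back) return false;
    if (bias == 1) return dr != 0;
    return true; // bias == 2
}

// Collect empty neighbor sites of (r, c). Rows wrap periodically; columns
// do not (the first/last columns are reservoir edges).
static int collect_candidates(const IntegerMatrix& g, int r, int c,
                              int center, int bias, int* cr, int* cc) {
    const int n = g.nrow(), m = g.ncol();
    int k = 0;
    for (int i = 0; i < 8; ++i) {
        int col = c + DC[i];
        if (col < 0 || col >= m) continue;
        if (bias_excluded(DR[i], DC[i], c, center, bias)) continue;
        int row = (r + DR[i] + n) % n;
        if (g(row, col) == 0) {
            cr[k] = row;
            cc[k] = col;
            ++k;
        }
    }
    return k;
}

// One asynchronous sweep: visit every currently occupied site once in a
// fresh random permutation; each draws lambda ~ U[0,1] and migrates
// (lambda < pm) or proliferates into a uniformly chosen empty neighbor;
// fully surrounded cells are quiescent. Afterwards, vacant sites in the
// first and last columns refill with probability f (reservoir boundary).
static void sweep_once(IntegerMatrix& g, double pm, double f, int center,
                       int bias, bool prolif, bool refill) {
    const int n = g.nrow(), m = g.ncol();
    std::vector<int> occ;
    occ.reserve(static_cast<size_t>(n) * m);
    // column-major ascending, matching R's which(grid == 1)
    for (int c = 0; c < m; ++c)
        for (int r = 0; r < n; ++r)
            if (g(r, c) == 1) occ.push_back(c * n + r);

    const int N = static_cast<int>(occ.size());
    for (int i = N - 1; i > 0; --i) { // Fisher–Yates with R's RNG
        int j = static_cast<int>(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(occ[i], occ[j]);
    }

    int cr[8], cc[8];
    for (int i = 0; i < N; ++i) {
        int r = occ[i] % n, c = occ[i] / n;
        if (g(r, c) == 0) continue; // vacated earlier in this sweep
        int k = collect_candidates(g, r, c, center, bias, cr, cc);
        if (k == 0) continue;       // contact inhibition: quiescent
        double lambda = unif_rand();
        if (lambda < pm) {
            int j = static_cast<int>(unif_rand() * k);
            if (j >= k) j = k - 1;
            g(cr[j], cc[j]) = 1;
            g(r, c) = 0;
        } else if (prolif) {
            int j = static_cast<int>(unif_rand() * k);
            if (j >= k) j = k - 1;
            g(cr[j], cc[j]) = 1; // daughter; mother stays
        }
    }

    if (refill && m >= 1) {
        for (int r = 0; r < n; ++r)
            if (g(r, 0) == 0 && unif_rand() < f) g(r, 0) = 1;
        if (m > 1)
            for (int r = 0; r < n; ++r)
                if (g(r, m - 1) == 0 && unif_rand() < f) g(r, m - 1) = 1;
    }
}

// Wound area in lattice sites: empty sites within the initial wound band
// (columns lo..hi, 0-based inclusive) that have at least one empty Moore
// neighbor (rows wrap). Isolated single-site vacancies are below the
// resolution of image-based wound-edge detection and do not count.
static int wound_area_sites_internal(const IntegerMatrix& g, int lo, int hi) {
    const int n = g.nrow(), m = g.ncol();
    int total = 0;
    for (int c = lo; c <= hi; ++c) {
        for (int r = 0; r < n; ++r) {
            if (g(r, c) == 1) continue;
            bool open = false;
            for (int i = 0; i < 8 && !open; ++i) {
                int cc = c + DC[i];
                if (cc < 0 || cc >= m) continue;
                int rr = (r + DR[i] + n) % n;
                if (g(rr, cc) == 0) open = true;
            }
            if (open) ++total;
        }
    }
    return total;
}

// [[Rcpp::export]]
IntegerMatrix cpp_sweep(IntegerMatrix grid, double pm, double f, int center0,
                        int bias, bool prolif, bool refill) {
    IntegerMatrix g = clone(grid);
    sweep_once(g, pm, f, center0, bias, prolif, refill);
    return g;
}

// [[Rcpp::export]]
int cpp_wound_area(IntegerMatrix grid, int band_lo0, int band_hi0) {
    return wound_area_sites_internal(grid, band_lo0, band_hi0);
}

// [[Rcpp::export]]
List cpp_simulate(IntegerMatrix grid, double pm, double f, int center0,
                  int band_lo0, int band_hi0, int bias, bool prolif,
                  bool refill, int max_steps) {
    IntegerMatrix g = clone(grid);
    std::vector<int> areas;
    areas.reserve(max_steps + 1);
    int a0 = wound_area_sites_internal(g, band_lo0, band_hi0);
    areas.push_back(a0);
    bool closed = (a0 == 0);
    int s = 0;
    while (s < max_steps && !closed) {
        sweep_once(g, pm, f, center0, bias, prolif, refill);
        ++s;
        int a = wound_area_sites_internal(g, band_lo0, band_hi0);
        areas.push_back(a);
        closed = (a == 0);
    }
    return List::create(_["areas"] = wrap(areas), _["grid"] = g,
                        _["steps"] = s, _["closed"] = closed);
}
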