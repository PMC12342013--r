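#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Fenwick (binary indexed) tree over per-clone HSC counts.
// Clone selection for a birth/death event is proportional to h_i, so we
// need O(log C) weighted sampling with O(log C) updates.
struct Fenwick {
    int n;
    int highbit;
    std::vector<long long> tree;
    Fenwick(const IntegerVector &init) {
        n = init.size();
        tree.assign(n + 1, 0LL);
        for (int i = 0; i < n; ++i) tree[i + 1] = init[i];
        for (int i = 1; i <= n; ++i) {
            int j = i + (i & -i);
            if (j <= n) tree[j] += tree[i];
        }
        highbit = 1;
        while ((highbit << 1) <= n) highbit <<= 1;
    }
    void update(int i, long long delta) { // i is 0-based
        for (int j = i + 1; j <= n; j += j & -j) tree[j] += delta;
    }
    // smallest 0-based index such that prefix sum > u (u in [0, total))
    int find(long long u) const {
        int idx = 0;
        long long cum = 0;
        for (int mask = highbit; mask; mask >>= 1) {
            int next = idx + mask;
            if (next <= n && cum + tree[next] <= u) {
                idx = next;
                cum += tree[next];
            }
        }
        return idx;
    }
};

// Exact logistic step for the deterministic untagged pool with the tagged
// population frozen at hstar over the step:
//   dh0/dt = h0 * (A - B*h0),  A = r_h0*(1 - hstar/K) - mu_h,  B = r_h0/K
static inline double advance_h0(double h0, double hstar, double r_h0,
                                double mu_h, double K, double dt) {
    if (h0 <= 0.0 || dt <= 0.0) return h0 > 0.0 ? h0 : 0.0;
    double A = r_h0 * (1.0 - hstar / K) - mu_h;
    double B = r_h0 / K;
    if (std::fabs(A) < 1e-14) {
        return h0 / (1.0 + B * h0 * dt);
    }
    double e = std::exp(A * dt);
    return A * h0 * e / (A + B * h0 * (e - 1.0));
}

// Coupled logistic birth-death of tagged HSC clones (exact jump process)
// with a deterministic untagged pool sharing the same carrying capacity.
// Per-cell birth propensity is clamped at zero once h >= K; death rate is
// mu_h per cell. Rates are refreshed at least every dt_max days.
//
// Returns the event log (time, 1-based clone, +1/-1), the untagged and
// tagged populations tabulated on a uniform grid, and final clone sizes.
// [[Rcpp::export]]
List cpp_simulate_hsc(IntegerVector h_init, double h0_init, double r_h0,
                      double mu_h, double K, double t_max, double dt_max,
                      double grid_dt) {
    int C = h_init.size();
    long long hstar = 0;
    for (int i = 0; i < C; ++i) {
        if (h_init[i] < 0) stop("negative initial clone size");
        hstar += h_init[i];
    }
    Fenwick fen(h_init);
    std::vector<int> h(h_init.begin(), h_init.end());
    double h0 = h0_init;

    int n_grid = (int)std::floor(t_max / grid_dt + 1e-9) + 1;
    NumericVector grid_t(n_grid), h0_grid(n_grid), hstar_grid(n_grid);
    for (int g = 0; g < n_grid; ++g) grid_t[g] = g * grid_dt;

    std::vector<double> ev_t;
    std::vector<int> ev_c, ev_d;
    size_t max_events = 300000000;

    double t = 0.0;
    int next_grid = 0;
    h0_grid[0] = h0; hstar_grid[0] = (double)hstar; next_grid = 1;

    while (t < t_max - 1e-12) {
        double htot = (double)hstar + h0;
        if (htot > 10.0 * K + 1e9)
            stop("propensity overflow: total HSC population far exceeds K");
        double b = r_h0 * (1.0 - htot / K);
        if (b < 0.0) b = 0.0;
        double R = (double)hstar * (b + mu_h);

        double dt;
        bool event;
        if (R <= 0.0) {
            dt = dt_max;
            event = false;
        } else {
            dt = exp_rand() / R;
            if (dt > dt_max) { dt = dt_max; event = false; }
            else event = true;
        }
        double t_new = t + dt;
        if (t_new >= t_max) { t_new = t_max; event = false; }

        // advance the untagged pool through any grid points crossed
        while (next_grid < n_grid && grid_t[next_grid] <= t_new + 1e-12) {
            double g = grid_t[next_grid];
            h0 = advance_h0(h0, (double)hstar, r_h0, mu_h, K, g - t);
            t = g;
            h0_grid[next_grid] = h0;
            hstar_grid[next_grid] = (double)hstar;
            ++next_grid;
        }
        h0 = advance_h0(h0, (double)hstar, r_h0, mu_h, K, t_new - t);
        t = t_new;

        if (event) {
            double u = unif_rand() * (double)hstar;
            long long ui = (long long)u;
            if (ui >= hstar) ui = hstar - 1;
            int clone = fen.find(ui);
            bool birth = unif_rand() * (b + mu_h) < b;
            int delta = birth ? 1 : -1;
            h[clone] += delta;
            hstar += delta;
            fen.update(clone, delta);
            if (ev_t.size() >= max_events) stop("event budget exceeded");
            ev_t.push_back(t);
            ev_c.push_back(clone + 1);
            ev_d.push_back(delta);
        }
    }
    // fill any remaining grid slots (e.g. when t_max sits on the last one)
    while (next_grid < n_grid) {
        double g = grid_t[next_grid];
        h0 = advance_h0(h0, (double)hstar, r_h0, mu_h, K, g - t);
        t = g;
        h0_grid[next_grid] = h0;
        hstar_grid[next_grid] = (double)hstar;
        ++next_grid;
    }

    return List::create(
        _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
        _["clone"] = IntegerVector(ev_c.begin(), ev_c.end()),
        _["delta"] = IntegerVector(ev_d.begin(), ev_d.end()),
        _["grid_t"] = grid_t,
        _["h0_grid"] = h0_grid,
        _["hstar_grid"] = hstar_grid,
        _["h_final"] = IntegerVector(h.begin(), h.end()),
        _["h0_final"] = h0);
}
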