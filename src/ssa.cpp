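#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fenwick (binary-indexed) tree over reaction propensities: O(log R)
// updates and inverse-CDF sampling, so each Gillespie step costs
// O(|dependents| * log R) instead of O(R).
struct Fenwick {
    int n;
    std::vector<double> tree;  // 1-based partial sums
    std::vector<double> val;   // current leaf values
    int top;                   // highest power of two <= n

    void init(int n_) {
        n = n_;
        tree.assign(n + 1, 0.0);
        val.assign(n, 0.0);
        top = 1;
        while ((top << 1) <= n) top <<= 1;
    }
    void add(int i, double delta) {
        for (++i; i <= n; i += i & -i) tree[i] += delta;
    }
    void set(int i, double v) {
        if (v < 0) v = 0;
        add(i, v - val[i]);
        val[i] = v;
    }
    double total() const {
        double s = 0.0;
        for (int i = n; i > 0; i -= i & -i) s += tree[i];
        return s;
    }
    // smallest index with prefix sum >= u (0-based)
    int search(double u) const {
        int pos = 0;
        double rem = u;
        for (int pw = top; pw > 0; pw >>= 1) {
            int nxt = pos + pw;
            if (nxt <= n && tree[nxt] < rem) {
                rem -= tree[nxt];
                pos = nxt;
            }
        }
        return pos < n ? pos : n - 1;
    }
    void rebuild() {
        std::fill(tree.begin(), tree.end(), 0.0);
        for (int i = 0; i < n; ++i) add(i, val[i]);
    }
};

// Direct-method stochastic simulation of a mass-action network.
// Species/reaction indices are 0-based; -1 marks an absent slot.
// keff holds the full static effective constant per reaction (collision
// prefactor and completion bias already applied); templated reactions are
// additionally multiplied by the template factor at evaluation time, as a
// step function of template presence (or proportionally to its count).
// [[Rcpp::export]]
List ssa_run_cpp(IntegerVector r1, IntegerVector r2,
                 IntegerVector p1, IntegerVector p2,
                 NumericVector keff,
                 IntegerVector tmpl, double tmpl_factor, bool tmpl_proportional,
                 IntegerVector nuclearity,
                 NumericVector init, NumericVector grid,
                 bool check_mass) {
    const int nR = r1.size();
    const int nS = init.size();
    const int nG = grid.size();
    std::vector<double> x(init.begin(), init.end());

    // dependency lists: reactions whose propensity involves species s
    std::vector<std::vector<int>> deps(nS);
    for (int j = 0; j < nR; ++j) {
        deps[r1[j]].push_back(j);
        if (r2[j] >= 0 && r2[j] != r1[j]) deps[r2[j]].push_back(j);
        if (tmpl[j] >= 0 && tmpl[j] != r1[j] && tmpl[j] != r2[j])
            deps[tmpl[j]].push_back(j);
    }

    Fenwick fen;
    fen.init(nR > 0 ? nR : 1);
    auto prop = [&](int j) -> double {
        double h;
        if (r2[j] < 0) {
            h = x[r1[j]];
        } else if (r1[j] == r2[j]) {
            h = x[r1[j]] * (x[r1[j]] - 1.0) / 2.0;
        } else {
            h = x[r1[j]] * x[r2[j]];
        }
        double f = 1.0;
        if (tmpl[j] >= 0) {
            double tc = x[tmpl[j]];
            f = tmpl_proportional ? 1.0 + (tmpl_factor - 1.0) * tc
                                  : (tc >= 1.0 ? tmpl_factor : 1.0);
        }
        return keff[j] * f * h;
    };
    for (int j = 0; j < nR; ++j) fen.set(j, prop(j));

    double mass0 = 0.0;
    for (int s = 0; s < nS; ++s) mass0 += nuclearity[s] * x[s];

    NumericMatrix out(nS, nG);
    auto record = [&](int g) {
        for (int s = 0; s < nS; ++s) out(s, g) = x[s];
        if (check_mass) {
            double m = 0.0;
            for (int s = 0; s < nS; ++s) m += nuclearity[s] * x[s];
            if (m != mass0) stop("mass conservation violated during simulation");
        }
    };

    double t = 0.0;
    int g = 0;
    double events = 0.0;
    long steps_since_rebuild = 0;
    while (g < nG && grid[g] <= t) record(g++);

    while (g < nG) {
        double total = fen.total();
        if (total <= 0.0) {
            // exhausted: hold the current state to the horizon
            while (g < nG) record(g++);
            break;
        }
        double tnew = t + exp_rand() / total;
        while (g < nG && grid[g] <= tnew) record(g++);
        if (g >= nG) break;
        t = tnew;

        int j = fen.search(unif_rand() * total);
        if (fen.val[j] <= 0.0) {
            // guard against accumulated floating-point drift
            for (int k = 0; k < nR; ++k) fen.set(k, prop(k));
            fen.rebuild();
            total = fen.total();
            if (total <= 0.0) continue;
            j = fen.search(unif_rand() * total);
        }

        x[r1[j]] -= 1.0;
        if (r2[j] >= 0) x[r2[j]] -= 1.0;
        x[p1[j]] += 1.0;
        if (p2[j] >= 0) x[p2[j]] += 1.0;
        if (x[r1[j]] < 0 || (r2[j] >= 0 && x[r2[j]] < 0))
            stop("internal error: negative species count");
        events += 1.0;

        int changed[4] = {r1[j], r2[j], p1[j], p2[j]};
        for (int c = 0; c < 4; ++c) {
            int s = changed[c];
            if (s < 0) continue;
            bool dup = false;
            for (int cc = 0; cc < c; ++cc) if (changed[cc] == s) dup = true;
            if (dup) continue;
            for (int dj : deps[s]) fen.set(dj, prop(dj));
        }
        if (++steps_since_rebuild >= 1048576) {
            for (int k = 0; k < nR; ++k) fen.val[k] = prop(k);
            fen.rebuild();
            steps_since_rebuild = 0;
        }
    }

    return List::create(_["counts"] = out, _["events"] = events,
                        _["final_time"] = t);
}
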