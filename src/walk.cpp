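#include <Rcpp.h>
using namespace Rcpp;

// Draw a uniformly random active node (0-based) using R's RNG.
static int random_active(const std::vector<bool>& active, int n_active, int n) {
    int k = (int)std::floor(unif_rand() * n_active);
    if (k >= n_active) k = n_active - 1;
    int seen = -1;
    for (int i = 0; i < n; ++i) {
        if (active[i]) {
            if (++seen == k) return i;
        }
    }
    return -1; // unreachable when n_active > 0
}

// One regulated random walk on a similarity matrix S (symmetric, diag 1).
// From the current node the walk moves to an active node j != current with
// probability proportional to S(current, j); a node is removed once it has
// accumulated `m` visits.  After a removal the walk continues from the
// removed node's position (its similarity row over the remaining active
// nodes), so a tight cluster is exhausted before the walk drifts on; only
// when the current row carries no mass onto active nodes does the walk
// teleport to a uniformly random active node.  Every step is exactly one
// visit, so the walk terminates after at most m * n steps.
//
// Returns the removal order (1-based node indices), the step index of each
// removal, and a flag per removal telling whether the walk teleported since
// the previous removal (a natural segment boundary).
// [[Rcpp::export]]
List regulated_walk_cpp(const NumericMatrix& S, const int m) {
    const int n = S.nrow();
    std::vector<int> visits(n, 0);
    std::vector<bool> active(n, true);
    int n_active = n;

    IntegerVector removal_order(n);
    IntegerVector removal_steps(n);
    LogicalVector teleported(n);
    int removed = 0, step = 0;
    bool teleport_seen = false;

    int cur = random_active(active, n_active, n);
    while (n_active > 0) {
        ++step;
        if (++visits[cur] >= m) {
            active[cur] = false;
            --n_active;
            removal_order[removed] = cur + 1;
            removal_steps[removed] = step;
            teleported[removed] = teleport_seen;
            teleport_seen = false;
            ++removed;
            if (n_active == 0) break;
            // continue from the removed node's position (fall through)
        }
        double tot = 0.0;
        for (int j = 0; j < n; ++j)
            if (active[j] && j != cur) tot += S(cur, j);
        if (tot <= 0.0) {
            // dead-end row: teleport to a uniformly random active node
            // (staying on the sole remaining node is not a teleport)
            int nxt = random_active(active, n_active, n);
            if (nxt != cur) teleport_seen = true;
            cur = nxt;
        } else {
            double u = unif_rand() * tot, acc = 0.0;
            int nxt = -1;
            for (int j = 0; j < n; ++j) {
                if (active[j] && j != cur) {
                    acc += S(cur, j);
                    if (u <= acc) { nxt = j; break; }
                }
            }
            if (nxt < 0) { // numerical guard
                for (int j = n - 1; j >= 0; --j)
                    if (active[j] && j != cur) { nxt = j; break; }
            }
            cur = nxt;
        }
    }
    return List::create(_["removal_order"] = removal_order,
                        _["removal_steps"] = removal_steps,
                        _["teleported"] = teleported);
}
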