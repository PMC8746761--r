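#include <Rcpp.h>
using namespace Rcpp;

// Backward-Euler (implicit) integration of a passive dendritic tree with a
// Hines-ordered direct solve. Compartments must be numbered so that
// parent[i] < i (parent[root] = -1). Synaptic conductances are imposed
// per-sample at single compartments. In voltage-clamp mode an access
// conductance g_access ties the soma to v_hold; in current-clamp mode
// I_inj is injected at inj_comp.
// [[Rcpp::export(name = ".cable_integrate")]]
NumericVector cable_integrate(IntegerVector parent, NumericVector cm,
                              NumericVector gpas, NumericVector gax,
                              double e_pas,
                              int e_comp, NumericVector ge, double e_rev,
                              int i_comp, NumericVector gi, double i_rev,
                              int inj_comp, NumericVector I_inj,
                              bool vc, double g_access, double v_hold,
                              int rec_comp, double dt, double v_init) {
    int N = parent.size();
    int T = I_inj.size();
    if ((e_comp >= 0 && ge.size() != T) || (i_comp >= 0 && gi.size() != T))
        stop("synaptic conductance traces must match the stimulus length");
    std::vector<double> V(N, v_init), d(N), b(N);
    NumericVector out(T);
    out[0] = v_init;
    for (int t = 1; t < T; ++t) {
        // assemble diagonal and rhs for the step to time t
        for (int i = 0; i < N; ++i) {
            double g_extra = 0.0, rhs_extra = 0.0;
            if (i == e_comp && e_comp >= 0) {
                g_extra += ge[t];
                rhs_extra += ge[t] * e_rev;
            }
            if (i == i_comp && i_comp >= 0) {
                g_extra += gi[t];
                rhs_extra += gi[t] * i_rev;
            }
            if (i == inj_comp && !vc) rhs_extra += I_inj[t];
            if (i == inj_comp && vc) {
                g_extra += g_access;
                rhs_extra += g_access * v_hold;
            }
            d[i] = cm[i] / dt + gpas[i] + g_extra;
            b[i] = cm[i] / dt * V[i] + gpas[i] * e_pas + rhs_extra;
        }
        // add axial couplings to the diagonals
        for (int i = 1; i < N; ++i) {
            d[i] += gax[i];
            d[parent[i]] += gax[i];
        }
        // Hines elimination: children before parents
        for (int i = N - 1; i >= 1; --i) {
            int p = parent[i];
            double f = gax[i] / d[i];
            d[p] -= gax[i] * f;
            b[p] += b[i] * f;
        }
        V[0] = b[0] / d[0];
        for (int i = 1; i < N; ++i)
            V[i] = (b[i] + gax[i] * V[parent[i]]) / d[i];
        out[t] = V[rec_comp];
        if (std::fabs(out[t]) > 1.0)
            stop("cable simulation diverged; reduce dt");
    }
    return out;
}
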