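#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of a passive single-compartment neuron attached
// to an electrode with series resistance Rs and (optionally, k = 1) stray
// pipette capacitance Cp. Per step:
//   I_cell = Im                 (k = 0)
//          = (Vp - Vm) / Rs     (k = 1)
//   Ic     = Im - (Vp - Vm)/Rs  (k = 1; current charging Cp)
//   dVm    = (dt/C) * (-gl (Vm-Vl) - ge (Vm-Ve) - gi (Vm-Vi) + I_cell)
//   dVp    = dt * Ic / Cp       (k = 1); Vp = Vm + Im * Rs (k = 0)
// Rs may be a per-sample trace (length n) or a scalar (length 1).
// [[Rcpp::export(name = ".point_euler")]]
List point_euler(NumericVector ge, NumericVector gi, NumericVector Im,
                 NumericVector Rs, double dt, double C, double gl,
                 double Vl, double Ve, double Vi, int k, double Cp,
                 double V_init) {
    int n = Im.size();
    if (ge.size() != n || gi.size() != n)
        stop("conductance and current traces must have equal length");
    bool rs_trace = Rs.size() > 1;
    if (rs_trace && Rs.size() != n)
        stop("Rs trace must match the current trace length");
    NumericVector Vm(n), Vp(n);
    Vm[0] = V_init;
    double rs0 = rs_trace ? Rs[0] : Rs[0];
    Vp[0] = (k == 1) ? V_init : V_init + Im[0] * rs0;
    for (int i = 0; i < n - 1; ++i) {
        double rs = rs_trace ? Rs[i] : Rs[0];
        double icell, ic = 0.0;
        if (k == 1) {
            icell = (Vp[i] - Vm[i]) / rs;
            ic = Im[i] - icell;
        } else {
            icell = Im[i];
        }
        double dVm = (dt / C) * (-gl * (Vm[i] - Vl) - ge[i] * (Vm[i] - Ve)
                                 - gi[i] * (Vm[i] - Vi) + icell);
        Vm[i + 1] = Vm[i] + dVm;
        if (k == 1) {
            Vp[i + 1] = Vp[i] + dt * ic / Cp;
        } else {
            double rs1 = rs_trace ? Rs[i + 1] : Rs[0];
            Vp[i + 1] = Vm[i + 1] + Im[i + 1] * rs1;
        }
        if (std::fabs(Vm[i + 1]) > 1.0 || std::fabs(Vp[i + 1]) > 10.0)
            stop("simulation diverged (|V| > 1 V); reduce dt");
    }
    return List::create(_["V_m"] = Vm, _["V_p"] = Vp);
}
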