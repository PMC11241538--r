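#include <Rcpp.h>
using namespace Rcpp;

// Explicit upwind finite-volume solver for 1-D advection-dispersion of a
// tracer through a tube of axially varying cross-section:
//   d(A C)/dt + d(Q C)/dx = d(A D dC/dx)/dx
// Conservative by construction: cell masses are updated from face fluxes,
// so  sum(m) + massOut == massIn  to round-off at every step.
//
// vol      cell volumes, mL (A_i * dx / 1000)
// aFace    interior face areas, mm^2 (length n - 1)
// dx       grid spacing, mm
// disp     dispersion coefficient, mm^2/s
// q        volumetric flow per substep, mL/s (length nsteps)
// src      tracer source rate into cell 1 per substep, mL/s (length nsteps)
// dt       substep, s
// nsub     substeps per recorded frame
// nframes  number of recorded frames
// [[Rcpp::export(name = ".advectCore")]]
List advectCore(NumericVector vol, NumericVector aFace, double dx,
                double disp, NumericVector q, NumericVector src, double dt,
                int nsub, int nframes) {
    const int n = vol.size();
    std::vector<double> m(n, 0.0), C(n, 0.0);
    NumericMatrix conc(n, nframes);
    NumericVector massIn(nframes), massOut(nframes);
    double cumIn = 0.0, cumOut = 0.0;
    bool bad = false;
    int step = 0;

    for (int f = 0; f < nframes; ++f) {
        for (int s = 0; s < nsub; ++s, ++step) {
            const double Q = q[step];
            for (int i = 0; i < n; ++i) C[i] = m[i] / vol[i];
            // advective fluxes (upwind, Q >= 0): F[i] = flux across the
            // face between cell i-1 and i; inlet carries no tracer.
            // dispersive fluxes on interior faces.
            double Fprev = 0.0;  // inlet face
            for (int i = 0; i < n; ++i) {
                double Fnext;
                if (i < n - 1) {
                    Fnext = Q * C[i] -
                        disp * aFace[i] / 1000.0 * (C[i + 1] - C[i]) / dx;
                } else {
                    Fnext = Q * C[i];  // open outflow
                }
                m[i] += dt * (Fprev - Fnext);
                Fprev = Fnext;
            }
            cumOut += dt * Fprev;
            m[0] += dt * src[step];
            cumIn += dt * src[step];
        }
        for (int i = 0; i < n; ++i) {
            conc(i, f) = m[i] / vol[i];
            if (!std::isfinite(conc(i, f)) || conc(i, f) < -1e-9) bad = true;
        }
        massIn[f] = cumIn;
        massOut[f] = cumOut;
    }
    return List::create(_["conc"] = conc, _["massIn"] = massIn,
                        _["massOut"] = massOut, _["unstable"] = bad);
}
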