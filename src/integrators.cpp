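#include <Rcpp.h>
using namespace Rcpp;

// Deterministic part of a stimulus protocol.
// kind: 0 = constant, 1 = pulse (level inside [t_on, t_off)), 2 = step
// (level from t_on on).  Right-continuous at discontinuities.
static inline double stim_level(double t, int kind, double base, double level,
                                double t_on, double t_off) {
    if (kind == 1) return (t >= t_on && t < t_off) ? level : base;
    if (kind == 2) return (t >= t_on) ? level : base;
    return base;
}

// Dimensionless vector field.  The single authoritative transcription of the
// model: autocatalytic protein production saturating in phi and hyperbolically
// inhibited by mu, linear protein decay; constitutive plus protein-driven
// miRNA transcription and linear decay, the whole miRNA equation carrying the
// timescale ratio eps.
static inline void rhs(double phi, double mu, double a, double beta,
                       double kappa, double gamma, double eps,
                       double *dphi, double *dmu) {
    const double D = 1.0 + phi * phi + gamma * mu;
    *dphi = a + kappa * phi * phi / D - phi;
    *dmu  = eps * (beta + phi - mu);
}

// [[Rcpp::export]]
NumericVector rhs_dimless_cpp(double phi, double mu, double alpha, double beta,
                              double kappa, double gamma, double eps) {
    double dphi, dmu;
    rhs(phi, mu, alpha, beta, kappa, gamma, eps, &dphi, &dmu);
    return NumericVector::create(dphi, dmu);
}

static inline void rk4_step(double *phi, double *mu, double t, double dt,
                            double beta, double kappa, double gamma, double eps,
                            int kind, double base, double level, double t_on,
                            double t_off) {
    double k1p, k1m, k2p, k2m, k3p, k3m, k4p, k4m;
    const double a1 = stim_level(t, kind, base, level, t_on, t_off);
    const double a2 = stim_level(t + 0.5 * dt, kind, base, level, t_on, t_off);
    const double a4 = stim_level(t + dt, kind, base, level, t_on, t_off);
    rhs(*phi, *mu, a1, beta, kappa, gamma, eps, &k1p, &k1m);
    rhs(*phi + 0.5 * dt * k1p, *mu + 0.5 * dt * k1m, a2, beta, kappa, gamma,
        eps, &k2p, &k2m);
    rhs(*phi + 0.5 * dt * k2p, *mu + 0.5 * dt * k2m, a2, beta, kappa, gamma,
        eps, &k3p, &k3m);
    rhs(*phi + dt * k3p, *mu + dt * k3m, a4, beta, kappa, gamma, eps, &k4p,
        &k4m);
    *phi += dt / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);
    *mu  += dt / 6.0 * (k1m + 2.0 * k2m + 2.0 * k3m + k4m);
}

// Fixed-step integration of the dimensionless model under a piecewise-constant
// stimulus protocol, optionally with additive Gaussian noise on the phi
// equation (stimulus noise): classical RK4 drift stages plus an additive
// increment sigma*sqrt(dt)*z per step, which reduces bitwise to RK4 when
// sigma = 0.  States are clamped at zero after each step (counted).
//
// z: pre-generated noise increments, one per step, already scaled to
// sigma*sqrt(dt)*N(0,1) (may be empty when sigma = 0).
// threshold/track_cross: first-passage detection of phi falling below
// threshold (returns -1 when never crossed).
// [[Rcpp::export]]
List integrate_core_cpp(double phi0, double mu0, double beta, double kappa,
                        double gamma, double eps, int kind, double base,
                        double level, double t_on, double t_off, double t_end,
                        double dt, double sigma, NumericVector z, int thin,
                        double threshold, bool track_cross) {
    if (dt <= 0.0 || t_end <= 0.0) stop("dt and t_end must be positive");
    const int n_steps = (int)std::lround(t_end / dt);
    if (sigma > 0.0 && z.size() < n_steps)
        stop("noise increment vector shorter than the number of steps");
    const int n_rec = n_steps / thin + 1;
    NumericVector t_out(n_rec), a_out(n_rec), phi_out(n_rec), mu_out(n_rec);
    double phi = phi0, mu = mu0, t = 0.0;
    int clamp_count = 0, i_rec = 0;
    double first_cross = -1.0;

    t_out[0] = 0.0;
    a_out[0] = stim_level(0.0, kind, base, level, t_on, t_off);
    phi_out[0] = phi;
    mu_out[0] = mu;
    i_rec = 1;

    for (int i = 0; i < n_steps; i++) {
        rk4_step(&phi, &mu, t, dt, beta, kappa, gamma, eps, kind, base, level,
                 t_on, t_off);
        if (sigma > 0.0) phi += z[i];
        if (phi < 0.0) { phi = 0.0; clamp_count++; }
        if (mu < 0.0) { mu = 0.0; clamp_count++; }
        if (!std::isfinite(phi) || !std::isfinite(mu))
            stop("non-finite state at t = %f (step %d)", t + dt, i + 1);
        t = (i + 1) * dt;
        if (track_cross && first_cross < 0.0 && phi < threshold)
            first_cross = t;
        if ((i + 1) % thin == 0) {
            t_out[i_rec] = t;
            a_out[i_rec] = stim_level(t, kind, base, level, t_on, t_off);
            phi_out[i_rec] = phi;
            mu_out[i_rec] = mu;
            i_rec++;
        }
    }
    return List::create(_["t"] = t_out, _["alpha"] = a_out, _["phi"] = phi_out,
                        _["mu"] = mu_out, _["clamp_count"] = clamp_count,
                        _["first_cross"] = first_cross);
}

// Quasi-static linear ramp of alpha from a_from to a_to over t_ramp, used by
// the hysteresis sweep.  Deterministic only.
// [[Rcpp::export]]
List integrate_ramp_cpp(double phi0, double mu0, double beta, double kappa,
                        double gamma, double eps, double a_from, double a_to,
                        double t_ramp, double dt, int thin) {
    if (dt <= 0.0 || t_ramp <= 0.0) stop("dt and t_ramp must be positive");
    const int n_steps = (int)std::lround(t_ramp / dt);
    const int n_rec = n_steps / thin + 1;
    NumericVector t_out(n_rec), a_out(n_rec), phi_out(n_rec), mu_out(n_rec);
    const double slope = (a_to - a_from) / t_ramp;
    double phi = phi0, mu = mu0;
    int i_rec = 0;
    t_out[0] = 0.0; a_out[0] = a_from; phi_out[0] = phi; mu_out[0] = mu;
    i_rec = 1;
    for (int i = 0; i < n_steps; i++) {
        const double t = i * dt;
        double k1p, k1m, k2p, k2m, k3p, k3m, k4p, k4m;
        const double a1 = a_from + slope * t;
        const double a2 = a_from + slope * (t + 0.5 * dt);
        const double a4 = a_from + slope * (t + dt);
        rhs(phi, mu, a1, beta, kappa, gamma, eps, &k1p, &k1m);
        rhs(phi + 0.5 * dt * k1p, mu + 0.5 * dt * k1m, a2, beta, kappa, gamma,
            eps, &k2p, &k2m);
        rhs(phi + 0.5 * dt * k2p, mu + 0.5 * dt * k2m, a2, beta, kappa, gamma,
            eps, &k3p, &k3m);
        rhs(phi + dt * k3p, mu + dt * k3m, a4, beta, kappa, gamma, eps, &k4p,
            &k4m);
        phi += dt / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);
        mu  += dt / 6.0 * (k1m + 2.0 * k2m + 2.0 * k3m + k4m);
        if (phi < 0.0) phi = 0.0;
        if (mu < 0.0) mu = 0.0;
        if (!std::isfinite(phi) || !std::isfinite(mu))
            stop("non-finite state during ramp at t = %f", t + dt);
        if ((i + 1) % thin == 0) {
            t_out[i_rec] = (i + 1) * dt;
            a_out[i_rec] = a_from + slope * ((i + 1) * dt);
            phi_out[i_rec] = phi;
            mu_out[i_rec] = mu;
            i_rec++;
        }
    }
    return List::create(_["t"] = t_out, _["alpha"] = a_out, _["phi"] = phi_out,
                        _["mu"] = mu_out);
}
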