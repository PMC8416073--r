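#include <Rcpp.h>
using namespace Rcpp;

// Right-hand side of the BLIMP1 (p) / BCL6 (b) / IRF4 (r) network.
// Hill coefficient 2 throughout; BcR signalling adds to BCL6 degradation,
// CD40 signalling adds to IRF4 production; both are gated by the BCL6
// repression term kb^2/(kb^2+b^2).
static inline void grn_rhs_c(const double p, const double b, const double r,
                             const double *q, const double bcr_on,
                             const double aff, double *out) {
  const double mu_p = q[0], mu_b = q[1], mu_r = q[2];
  const double sg_p = q[3], sg_b = q[4], sg_r = q[5];
  const double kp2 = q[6] * q[6], kb2 = q[7] * q[7], kr2 = q[8] * q[8];
  const double la_p = q[9], la_b = q[10], la_r = q[11];
  const double bcr0 = q[12], cd0 = q[13];

  const double hb_rep = kb2 / (kb2 + b * b);
  const double hp_rep = kp2 / (kp2 + p * p);
  const double hr_rep = kr2 / (kr2 + r * r);
  const double hr_act = r * r / (kr2 + r * r);

  const double bcr = bcr0 * bcr_on * hb_rep;
  const double cd40 = cd0 * aff * hb_rep;

  out[0] = mu_p + sg_p * hb_rep + sg_p * hr_act - la_p * p;
  out[1] = mu_b + sg_b * hp_rep * hb_rep * hr_rep - (la_b + bcr) * b;
  out[2] = mu_r + sg_r * hr_act + cd40 - la_r * r;
}

static inline void rk4_step(double *p, double *b, double *r, const double *q,
                            const double bcr_on, const double aff,
                            const double h) {
  double k1[3], k2[3], k3[3], k4[3];
  grn_rhs_c(*p, *b, *r, q, bcr_on, aff, k1);
  grn_rhs_c(*p + 0.5 * h * k1[0], *b + 0.5 * h * k1[1], *r + 0.5 * h * k1[2],
            q, bcr_on, aff, k2);
  grn_rhs_c(*p + 0.5 * h * k2[0], *b + 0.5 * h * k2[1], *r + 0.5 * h * k2[2],
            q, bcr_on, aff, k3);
  grn_rhs_c(*p + h * k3[0], *b + h * k3[1], *r + h * k3[2],
            q, bcr_on, aff, k4);
  *p += h / 6.0 * (k1[0] + 2.0 * k2[0] + 2.0 * k3[0] + k4[0]);
  *b += h / 6.0 * (k1[1] + 2.0 * k2[1] + 2.0 * k3[1] + k4[1]);
  *r += h / 6.0 * (k1[2] + 2.0 * k2[2] + 2.0 * k3[2] + k4[2]);
  // a step may undershoot 0 by O(h^5); clip
  if (*p < 0) *p = 0;
  if (*b < 0) *b = 0;
  if (*r < 0) *r = 0;
}

//' Advance many cells' TF states by one engine step (nsub RK4 substeps).
//'
//' @noRd
// [[Rcpp::export]]
NumericMatrix grn_update_cpp(NumericVector p, NumericVector b, NumericVector r,
                             NumericVector bcr_on, NumericVector aff,
                             NumericVector params, double dt, int nsub) {
  const int n = p.size();
  if (b.size() != n || r.size() != n || bcr_on.size() != n || aff.size() != n)
    stop("state/signal vectors must have equal length");
  if (params.size() != 14) stop("params must have length 14");
  const double h = dt / nsub;
  NumericMatrix out(n, 3);
  const double *q = params.begin();
  for (int i = 0; i < n; ++i) {
    double pi = p[i], bi = b[i], ri = r[i];
    for (int s = 0; s < nsub; ++s)
      rk4_step(&pi, &bi, &ri, q, bcr_on[i], aff[i], h);
    if (!R_finite(pi) || !R_finite(bi) || !R_finite(ri))
      stop("non-finite TF concentration during integration (cell %d)", i + 1);
    out(i, 0) = pi; out(i, 1) = bi; out(i, 2) = ri;
  }
  return out;
}

//' Fixed-step RK4 trajectory for a single cell under constant signals.
//'
//' @noRd
// [[Rcpp::export]]
NumericMatrix grn_traj_cpp(NumericVector state, NumericVector params,
                           double bcr_on, double aff, double dt, int n_steps) {
  if (state.size() != 3) stop("state must have length 3");
  if (params.size() != 14) stop("params must have length 14");
  NumericMatrix out(n_steps + 1, 3);
  double p = state[0], b = state[1], r = state[2];
  const double *q = params.begin();
  out(0, 0) = p; out(0, 1) = b; out(0, 2) = r;
  for (int s = 1; s <= n_steps; ++s) {
    rk4_step(&p, &b, &r, q, bcr_on, aff, dt);
    if (!R_finite(p) || !R_finite(b) || !R_finite(r))
      stop("non-finite TF concentration during integration at step %d", s);
    out(s, 0) = p; out(s, 1) = b; out(s, 2) = r;
  }
  return out;
}
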