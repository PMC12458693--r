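#ifndef WATNET_MC_H
#define WATNET_MC_H

#include "rng.h"
#include <cmath>

// Shoemake's uniform random unit quaternion
inline void random_quat(Xoshiro &g, double *q) {
  double u1 = g.runif(), u2 = g.runif(), u3 = g.runif();
  double a = std::sqrt(1.0 - u1), b = std::sqrt(u1);
  double t2 = 2.0 * M_PI * u2, t3 = 2.0 * M_PI * u3;
  q[0] = b * std::cos(t3);
  q[1] = a * std::sin(t2);
  q[2] = a * std::cos(t2);
  q[3] = b * std::sin(t3);
}

// random small rotation: uniform angle in [-max_rot, max_rot] about a
// uniform random axis, as a quaternion
inline void make_dq(Xoshiro &g, double max_rot, double *dq) {
  double v[3], n2;
  do {
    v[0] = 2.0 * g.runif() - 1.0;
    v[1] = 2.0 * g.runif() - 1.0;
    v[2] = 2.0 * g.runif() - 1.0;
    n2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
  } while (n2 > 1.0 || n2 < 1e-12);
  double n = std::sqrt(n2);
  double ang = (2.0 * g.runif() - 1.0) * max_rot;
  double s = std::sin(0.5 * ang) / n;
  dq[0] = std::cos(0.5 * ang);
  dq[1] = s * v[0]; dq[2] = s * v[1]; dq[3] = s * v[2];
}

inline void apply_dq(const double *dq, const double *q, double *out) {
  out[0] = dq[0] * q[0] - dq[1] * q[1] - dq[2] * q[2] - dq[3] * q[3];
  out[1] = dq[0] * q[1] + dq[1] * q[0] + dq[2] * q[3] - dq[3] * q[2];
  out[2] = dq[0] * q[2] - dq[1] * q[3] + dq[2] * q[0] + dq[3] * q[1];
  out[3] = dq[0] * q[3] + dq[1] * q[2] - dq[2] * q[1] + dq[3] * q[0];
  double nn = std::sqrt(out[0] * out[0] + out[1] * out[1] +
                        out[2] * out[2] + out[3] * out[3]);
  for (int j = 0; j < 4; ++j) out[j] /= nn;
}

inline void perturb_quat(Xoshiro &g, const double *q, double max_rot, double *out) {
  double dq[4];
  make_dq(g, max_rot, dq);
  apply_dq(dq, q, out);
}

#endif
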