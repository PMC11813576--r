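// Trajectory cores for the kinetic Monte Carlo capture simulators.
//
// All samplers draw from R's RNG stream (so set.seed() controls everything);
// particles are simulated to completion one at a time, which makes the record
// sequence a deterministic function of the seed alone.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// uniform on the open interval (0,1); boundary draws are rejected so that
// inverse-CDF formulas never see 0 or 1
static inline double runif_open() {
  double u;
  do {
    u = unif_rand();
  } while (u <= 0.0 || u >= 1.0);
  return u;
}

// inverse complementary error function: erfc(x) = v  =>  x = erfcinv(v)
static inline double erfcinv(double v) {
  return R::qnorm(v / 2.0, 0.0, 1.0, 0, 0) / M_SQRT2;
}

struct Vec3 {
  double x, y, z;
};
static inline Vec3 v3(double x, double y, double z) { Vec3 v = {x, y, z}; return v; }
static inline Vec3 operator+(Vec3 a, Vec3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec3 operator*(double s, Vec3 a) { return v3(s * a.x, s * a.y, s * a.z); }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(Vec3 a) { return std::sqrt(dot(a, a)); }

// orthonormal pair perpendicular to the unit vector n
static inline void frame(Vec3 n, Vec3 &e1, Vec3 &e2) {
  Vec3 a = std::fabs(n.x) < 0.5 ? v3(1, 0, 0) : v3(0, 1, 0);
  e1 = cross(n, a);
  double s = norm3(e1);
  e1 = (1.0 / s) * e1;
  e2 = cross(n, e1);
}

// ---- propagator samplers -------------------------------------------------

// Projector I: first-passage time to the bounding plane from height z0,
// t* = z0^2 / (4 D erfcinv(nu)^2), lateral displacements N(0, 2 D t*)
static inline double plane_impact_time(double z0, double D) {
  if (z0 <= 0.0) return 0.0;
  double nu = runif_open();
  double q = erfcinv(nu);
  return z0 * z0 / (4.0 * D * q * q);
}

// dimensionless hemisphere exit time tau solving P_T(tau) = xi by linear
// interpolation in the precomputed table; log-tail asymptotic for xi near 1
static inline double hemi_tau(double xi, const std::vector<double> &tau,
                              const std::vector<double> &cdf) {
  if (xi > 1.0 - 1e-3) return std::log(2.0 / (1.0 - xi));
  if (xi <= cdf.front()) return tau.front();
  size_t hi = std::upper_bound(cdf.begin(), cdf.end(), xi) - cdf.begin();
  if (hi >= cdf.size()) return tau.back();
  size_t lo = hi - 1;
  double w = (xi - cdf[lo]) / (cdf[hi] - cdf[lo]);
  return tau[lo] + w * (tau[hi] - tau[lo]);
}

struct HemiTable {
  std::vector<double> tau, cdf;
};

// Projector II: exit from hemisphere of radius R centred at p with pole n;
// increments the elapsed time and moves the particle to the exit point
static inline void hemi_exit(Vec3 &p, double &t, double R, double D, Vec3 n,
                             const HemiTable &H) {
  double xi = runif_open();
  double tau = hemi_tau(xi, H.tau, H.cdf);
  t += R * R * tau / (D * M_PI * M_PI);
  double eta = TWO_PI * unif_rand();
  double zeta = runif_open();
  double s = std::sqrt(std::max(0.0, 1.0 - zeta * zeta));
  Vec3 e1, e2;
  frame(n, e1, e2);
  p = p + R * ((s * std::cos(eta)) * e1 + (s * std::sin(eta)) * e2 + zeta * n);
}

struct ReinsTable {
  double ratio;      // launch/landing radius ratio R
  int n_mu, n_nu;
  const double *theta;  // n_mu x n_nu, column-major (R matrix)
};

// Projector III: escape with probability 1 - 1/R, otherwise reinsertion onto
// the sphere of radius |p - c|/R about c.  Returns true if the particle
// escaped.  Time is incremented by the tabulated unit-sphere time rescaled
// by (landing radius)^2 / D.
static inline bool reinsert(Vec3 &p, double &t, Vec3 c, double D,
                            const ReinsTable &T) {
  double Rr = T.ratio;
  double mu = runif_open();
  if (mu >= 1.0 / Rr) return true;
  double q = erfcinv(Rr * mu);
  double t_unit = (Rr - 1.0) * (Rr - 1.0) / (4.0 * q * q);
  Vec3 u = p - c;
  double r0 = norm3(u);
  double Rl = r0 / Rr;
  t += t_unit * Rl * Rl / D;
  int i = (int)std::floor(mu * Rr * T.n_mu);
  if (i < 0) i = 0;
  if (i >= T.n_mu) i = T.n_mu - 1;
  double nu = unif_rand();
  int j = (int)std::floor(nu * T.n_nu);
  if (j < 0) j = 0;
  if (j >= T.n_nu) j = T.n_nu - 1;
  double th = T.theta[i + (size_t)T.n_mu * j];
  double phi = TWO_PI * unif_rand();
  u = (1.0 / r0) * u;
  Vec3 e1, e2;
  frame(u, e1, e2);
  double st = std::sin(th);
  p = c + Rl * (std::cos(th) * u + (st * std::cos(phi)) * e1 + (st * std::sin(phi)) * e2);
  return false;
}

// ---- half-space machine --------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_simulate_halfspace(NumericMatrix release, NumericMatrix pores,
                                     NumericVector disc_center, double disc_radius,
                                     double ratio, double D,
                                     NumericVector hemi_tau_grid, NumericVector hemi_cdf,
                                     NumericMatrix theta_table, double safety_cap) {
  int M = release.nrow();
  int N = pores.nrow();
  HemiTable H;
  H.tau.assign(hemi_tau_grid.begin(), hemi_tau_grid.end());
  H.cdf.assign(hemi_cdf.begin(), hemi_cdf.end());
  ReinsTable T;
  T.ratio = ratio;
  T.n_mu = theta_table.nrow();
  T.n_nu = theta_table.ncol();
  T.theta = theta_table.begin();
  Vec3 dc = v3(disc_center[0], disc_center[1], 0.0);

  NumericMatrix out(M, 7);
  for (int m = 0; m < M; ++m) {
    Vec3 p = v3(release(m, 0), release(m, 1), release(m, 2));
    double t = 0.0;
    double steps = 0.0;
    int outcome = 3, hit = 0;  // 1 captured, 2 escaped, 3 lost
    while (steps < safety_cap) {
      if (p.z > 0.0) {  // Stage I: project to the bounding plane
        double dt = plane_impact_time(p.z, D);
        double s = std::sqrt(2.0 * D * dt);
        p.x += s * norm_rand();
        p.y += s * norm_rand();
        p.z = 0.0;
        t += dt;
        steps += 1.0;
      }
      // on the plane: capture test against every pore
      double dmin = R_PosInf;
      int kmin = -1;
      for (int k = 0; k < N; ++k) {
        double dx = p.x - pores(k, 0), dy = p.y - pores(k, 1);
        double d = std::sqrt(dx * dx + dy * dy) - pores(k, 2);
        if (d < dmin) { dmin = d; kmin = k; }
      }
      if (N > 0 && dmin <= 0.0) {  // boundary counts as inside
        outcome = 1; hit = kmin + 1;
        break;
      }
      double dx = p.x - dc.x, dy = p.y - dc.y;
      double rdisc = std::sqrt(dx * dx + dy * dy);
      if (N > 0 && rdisc <= disc_radius) {
        // Stage IIa: hemisphere of radius = distance to the absorbing set
        hemi_exit(p, t, dmin, D, v3(0, 0, 1), H);
        steps += 1.0;
      } else {
        // Stage IIb: escape or reinsertion about the disc centre
        bool esc = reinsert(p, t, dc, D, T);
        steps += 1.0;
        if (esc) { outcome = 2; break; }
        if (p.z < 0.0) p.z = -p.z;  // image reflection into the half-space
      }
    }
    out(m, 0) = outcome;
    out(m, 1) = t;
    out(m, 2) = hit;
    out(m, 3) = p.x; out(m, 4) = p.y; out(m, 5) = p.z;
    out(m, 6) = steps;
  }
  return out;
}

// ---- convex polyhedron machine -------------------------------------------

struct Poly {
  int F;
  const double *nx, *ny, *nz, *off;   // face plane n.x = off
  std::vector<std::vector<Vec3> > ring;  // face vertex rings
  std::vector<int> absorber;
  std::vector<std::vector<int> > adj;    // face adjacency (shared edges)
};

static inline double signed_dist(const Poly &P, int f, Vec3 p) {
  return P.nx[f] * p.x + P.ny[f] * p.y + P.nz[f] * p.z - P.off[f];
}

// exact argmax of the signed distance; lowest index wins ties
static int scan_face(const Poly &P, Vec3 p, double &best) {
  best = R_NegInf;
  int arg = -1;
  for (int f = 0; f < P.F; ++f) {
    double d = signed_dist(P, f, p);
    if (d > best) { best = d; arg = f; }
  }
  return arg;
}

// hill-climb on the face adjacency graph; any face with positive signed
// distance gives a valid separating plane, so a local maximum is acceptable
static int climb_face(const Poly &P, Vec3 p, int seed, double &best) {
  int cur = seed;
  double dcur = signed_dist(P, cur, p);
  for (;;) {
    int nxt = -1;
    double dbest = dcur;
    const std::vector<int> &nb = P.adj[cur];
    for (size_t i = 0; i < nb.size(); ++i) {
      double d = signed_dist(P, nb[i], p);
      if (d > dbest) { dbest = d; nxt = nb[i]; }
    }
    if (nxt < 0) break;
    cur = nxt;
    dcur = dbest;
  }
  best = dcur;
  return cur;
}

// convex polygon membership (boundary counts as inside)
static inline bool in_face(const Poly &P, int f, Vec3 p, double tol) {
  const std::vector<Vec3> &r = P.ring[f];
  Vec3 n = v3(P.nx[f], P.ny[f], P.nz[f]);
  size_t nv = r.size();
  for (size_t i = 0; i < nv; ++i) {
    Vec3 a = r[i], b = r[(i + 1) % nv];
    if (dot(cross(b - a, p - a), n) < -tol) return false;
  }
  return true;
}

// distance from an interior point to the polygon boundary
static inline double inscribed_radius(const Poly &P, int f, Vec3 p) {
  const std::vector<Vec3> &r = P.ring[f];
  size_t nv = r.size();
  double dmin = R_PosInf;
  for (size_t i = 0; i < nv; ++i) {
    Vec3 a = r[i], b = r[(i + 1) % nv];
    Vec3 e = b - a;
    double L2 = dot(e, e);
    double w = L2 > 0.0 ? dot(p - a, e) / L2 : 0.0;
    if (w < 0.0) w = 0.0;
    if (w > 1.0) w = 1.0;
    Vec3 q = a + w * e;
    double d = norm3(p - q);
    if (d < dmin) dmin = d;
  }
  return dmin;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_polyhedron(NumericMatrix release, NumericMatrix verts,
                                      IntegerVector face_idx, IntegerVector face_off,
                                      NumericMatrix normals, NumericVector plane_off,
                                      IntegerVector absorber,
                                      IntegerVector adj_idx, IntegerVector adj_off,
                                      NumericVector ball_center, double Ra,
                                      double ratio, double D,
                                      NumericVector hemi_tau_grid, NumericVector hemi_cdf,
                                      NumericMatrix theta_table, double safety_cap) {
  int M = release.nrow();
  Poly P;
  P.F = normals.nrow();
  std::vector<double> nxv(P.F), nyv(P.F), nzv(P.F), offv(P.F);
  for (int f = 0; f < P.F; ++f) {
    nxv[f] = normals(f, 0); nyv[f] = normals(f, 1); nzv[f] = normals(f, 2);
    offv[f] = plane_off[f];
  }
  P.nx = &nxv[0]; P.ny = &nyv[0]; P.nz = &nzv[0]; P.off = &offv[0];
  P.ring.resize(P.F);
  P.absorber.resize(P.F);
  for (int f = 0; f < P.F; ++f) {
    P.absorber[f] = absorber[f];
    for (int i = face_off[f]; i < face_off[f + 1]; ++i) {
      int v = face_idx[i];
      P.ring[f].push_back(v3(verts(v, 0), verts(v, 1), verts(v, 2)));
    }
  }
  P.adj.resize(P.F);
  for (int f = 0; f < P.F; ++f)
    for (int i = adj_off[f]; i < adj_off[f + 1]; ++i)
      P.adj[f].push_back(adj_idx[i]);

  HemiTable H;
  H.tau.assign(hemi_tau_grid.begin(), hemi_tau_grid.end());
  H.cdf.assign(hemi_cdf.begin(), hemi_cdf.end());
  ReinsTable T;
  T.ratio = ratio;
  T.n_mu = theta_table.nrow();
  T.n_nu = theta_table.ncol();
  T.theta = theta_table.begin();
  Vec3 c = v3(ball_center[0], ball_center[1], ball_center[2]);
  double gate = ratio * Ra;
  bool use_climb = P.F > 64;
  // geometric tolerance tied to the body diameter
  double diam = 0.0;
  for (int v = 0; v < verts.nrow(); ++v) {
    Vec3 q = v3(verts(v, 0), verts(v, 1), verts(v, 2)) - c;
    double d = norm3(q);
    if (d > diam) diam = d;
  }
  double tol = 1e-12 * 2.0 * diam;
  // particles ground onto a face edge by alternating projections stall at
  // h = 0; lifting the impact height to this scale (a one-part-in-1e9
  // spatial bias) restores the multiplicative escape from the edge
  double eps_geo = 1e-9 * diam;

  NumericMatrix out(M, 7);
  for (int m = 0; m < M; ++m) {
    Vec3 p = v3(release(m, 0), release(m, 1), release(m, 2));
    double t = 0.0, steps = 0.0;
    int outcome = 3, hit = 0, cur = -1;
    while (steps < safety_cap) {
      // Stage I: escape or reinsertion while outside the ball Ba
      double r = norm3(p - c);
      if (r > gate) {
        bool esc = reinsert(p, t, c, D, T);
        steps += 1.0;
        if (esc) { outcome = 2; break; }
        continue;
      }
      // Stage II: separating face plane (largest signed distance)
      double h;
      int f;
      if (use_climb && cur >= 0) {
        f = climb_face(P, p, cur, h);
        if (h <= 0.0) f = scan_face(P, p, h);
      } else {
        f = scan_face(P, p, h);
      }
      cur = f;
      Vec3 n = v3(P.nx[f], P.ny[f], P.nz[f]);
      if (h < eps_geo) {
        // effectively on the surface: interact with the face that actually
        // contains the particle (coplanar faces make the argmax ambiguous),
        // then lift the particle to a true height eps_geo above that plane
        // so the projected foot lies exactly on it
        for (int g = 0; g < P.F; ++g) {
          if (signed_dist(P, g, p) > -eps_geo && in_face(P, g, p, eps_geo)) {
            f = g;
            cur = f;
            n = v3(P.nx[f], P.ny[f], P.nz[f]);
            break;
          }
        }
        double ht = signed_dist(P, f, p);
        p = p + (eps_geo - ht) * n;
        h = eps_geo;
      }
      Vec3 e1, e2;
      frame(n, e1, e2);
      bool done = false;
      // Stage III/IV: walk on the target face plane until capture or exit
      for (;;) {
        if (steps >= safety_cap) break;
        double dt = plane_impact_time(h, D);
        double s = std::sqrt(2.0 * D * dt);
        Vec3 foot = p - h * n;
        p = foot + (s * norm_rand()) * e1 + (s * norm_rand()) * e2;
        t += dt;
        steps += 1.0;
        if (!in_face(P, f, p, tol)) break;       // back to Stage I
        if (P.absorber[f] > 0) {                  // absorbed
          outcome = 1; hit = P.absorber[f];
          done = true;
          break;
        }
        double rin = inscribed_radius(P, f, p);
        if (rin <= tol) break;                    // grazing an edge: rebulk
        double xi = runif_open();
        double tau = hemi_tau(xi, H.tau, H.cdf);
        t += rin * rin * tau / (D * M_PI * M_PI);
        double eta = TWO_PI * unif_rand();
        double zeta = runif_open();
        double sz = std::sqrt(std::max(0.0, 1.0 - zeta * zeta));
        p = p + rin * ((sz * std::cos(eta)) * e1 + (sz * std::sin(eta)) * e2 + zeta * n);
        steps += 1.0;
        h = rin * zeta;                           // project back to same face
      }
      if (done) break;
    }
    out(m, 0) = outcome;
    out(m, 1) = t;
    out(m, 2) = hit;
    out(m, 3) = p.x; out(m, 4) = p.y; out(m, 5) = p.z;
    out(m, 6) = steps;
  }
  return out;
}

// ---- smallest enclosing ball (Welzl, move-to-front) ----------------------

struct Ball {
  Vec3 c;
  double r2;
};

static Ball ball2(Vec3 a, Vec3 b) {
  Vec3 c = 0.5 * (a + b);
  Vec3 d = a - c;
  Ball B = {c, dot(d, d)};
  return B;
}
static bool ball_has(const Ball &B, Vec3 p, double eps) {
  Vec3 d = p - B.c;
  return dot(d, d) <= B.r2 * (1.0 + eps) + eps;
}
// circumsphere of 3 points (in their plane)
static Ball ball3(Vec3 a, Vec3 b, Vec3 c) {
  Vec3 ab = b - a, ac = c - a;
  Vec3 n = cross(ab, ac);
  double n2 = dot(n, n);
  if (n2 <= 0.0) return ball2(a, b);
  Vec3 num = cross(dot(ab, ab) * ac - dot(ac, ac) * ab, n);
  Vec3 cc = a + (0.5 / n2) * num;
  Vec3 d = a - cc;
  Ball B = {cc, dot(d, d)};
  return B;
}
// circumsphere of 4 points
static Ball ball4(Vec3 a, Vec3 b, Vec3 c, Vec3 d) {
  double A[3][3] = {{b.x - a.x, b.y - a.y, b.z - a.z},
                    {c.x - a.x, c.y - a.y, c.z - a.z},
                    {d.x - a.x, d.y - a.y, d.z - a.z}};
  double rhs[3] = {0.5 * (dot(b, b) - dot(a, a)),
                   0.5 * (dot(c, c) - dot(a, a)),
                   0.5 * (dot(d, d) - dot(a, a))};
  double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
             - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
             + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) < 1e-300) return ball3(a, b, c);
  double inv[3][3];
  inv[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) / det;
  inv[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) / det;
  inv[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) / det;
  inv[1][0] = (A[1][2] * A[2][0] - A[1][0] * A[2][2]) / det;
  inv[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) / det;
  inv[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) / det;
  inv[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) / det;
  inv[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) / det;
  inv[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) / det;
  Vec3 cc = v3(inv[0][0] * rhs[0] + inv[0][1] * rhs[1] + inv[0][2] * rhs[2],
               inv[1][0] * rhs[0] + inv[1][1] * rhs[1] + inv[1][2] * rhs[2],
               inv[2][0] * rhs[0] + inv[2][1] * rhs[1] + inv[2][2] * rhs[2]);
  Vec3 dd = a - cc;
  Ball B = {cc, dot(dd, dd)};
  return B;
}

// smallest ball with the support set on its boundary
static Ball ball_trivial(const std::vector<Vec3> &S) {
  Ball B = {v3(0, 0, 0), -1.0};
  size_t n = S.size();
  if (n == 0) return B;
  if (n == 1) { B.c = S[0]; B.r2 = 0.0; return B; }
  if (n == 2) return ball2(S[0], S[1]);
  const double eps = 1e-12;
  // try small subsets first, keep the smallest that contains all of S
  Ball best = {v3(0, 0, 0), R_PosInf};
  bool found = false;
  for (size_t i = 0; i < n; ++i)
    for (size_t j = i + 1; j < n; ++j) {
      Ball C = ball2(S[i], S[j]);
      bool ok = true;
      for (size_t k = 0; k < n; ++k) ok = ok && ball_has(C, S[k], eps);
      if (ok && C.r2 < best.r2) { best = C; found = true; }
    }
  if (found) return best;
  if (n >= 3) {
    for (size_t i = 0; i < n; ++i)
      for (size_t j = i + 1; j < n; ++j)
        for (size_t k = j + 1; k < n; ++k) {
          Ball C = ball3(S[i], S[j], S[k]);
          bool ok = true;
          for (size_t l = 0; l < n; ++l) ok = ok && ball_has(C, S[l], eps);
          if (ok && C.r2 < best.r2) { best = C; found = true; }
        }
  }
  if (found) return best;
  if (n < 4) return ball3(S[0], S[1], S[2]);
  return ball4(S[0], S[1], S[2], S[3]);
}

static Ball welzl(std::vector<Vec3> &P, size_t n, std::vector<Vec3> S) {
  if (n == 0 || S.size() == 4) return ball_trivial(S);
  Ball B = welzl(P, n - 1, S);
  if (B.r2 >= 0.0 && ball_has(B, P[n - 1], 1e-12)) return B;
  S.push_back(P[n - 1]);
  Ball B2 = welzl(P, n - 1, S);
  // move-to-front: keep boundary points early to bound recursion in practice
  Vec3 tmp = P[n - 1];
  for (size_t i = n - 1; i > 0; --i) P[i] = P[i - 1];
  P[0] = tmp;
  return B2;
}

// [[Rcpp::export]]
NumericVector cpp_min_ball(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<Vec3> P(n);
  for (int i = 0; i < n; ++i) P[i] = v3(pts(i, 0), pts(i, 1), pts(i, 2));
  // deterministic shuffle for expected-linear behaviour
  unsigned s = 12345u;
  for (int i = n - 1; i > 0; --i) {
    s = s * 1103515245u + 12345u;
    int j = (int)(s % (unsigned)(i + 1));
    std::swap(P[i], P[j]);
  }
  Ball B = welzl(P, n, std::vector<Vec3>());
  return NumericVector::create(B.c.x, B.c.y, B.c.z, std::sqrt(std::max(0.0, B.r2)));
}

// ---- tangential mesh relaxation ------------------------------------------

// projected gradient descent on the repulsive energy sum_{i<j} 1/|x_i - x_j|;
// vertices stay on the unit sphere, rows of `fixed` equal to 1 do not move
// [[Rcpp::export]]
NumericMatrix cpp_relax_sphere_mesh(NumericMatrix verts, IntegerVector fixed,
                                    int iterations, double step) {
  int n = verts.nrow();
  std::vector<Vec3> x(n);
  for (int i = 0; i < n; ++i) x[i] = v3(verts(i, 0), verts(i, 1), verts(i, 2));
  std::vector<Vec3> g(n);
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < n; ++i) g[i] = v3(0, 0, 0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        Vec3 d = x[i] - x[j];
        double r2 = dot(d, d);
        double w = 1.0 / (r2 * std::sqrt(r2));  // -grad of 1/r
        g[i] = g[i] + w * d;
        g[j] = g[j] - w * d;
      }
    for (int i = 0; i < n; ++i) {
      if (fixed[i]) continue;
      Vec3 gt = g[i] - dot(g[i], x[i]) * x[i];  // tangential component
      Vec3 xn = x[i] + step * gt;
      double s = norm3(xn);
      if (s > 0) x[i] = (1.0 / s) * xn;
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i].x; out(i, 1) = x[i].y; out(i, 2) = x[i].z;
  }
  return out;
}

// ---- Euler-Maruyama oracle (tests only) ----------------------------------

// fine-step Brownian dynamics from (0,0,R0) absorbed on the unit sphere, with
// a Brownian-bridge crossing correction; returns (theta, time) of each hit
// [[Rcpp::export]]
NumericMatrix cpp_bd_sphere_hits(int n_walkers, double R0, double D, double dt,
                                 double t_max, double r_escape) {
  std::vector<double> th, tt;
  double sd = std::sqrt(2.0 * D * dt);
  int n_steps = (int)std::ceil(t_max / dt);
  for (int w = 0; w < n_walkers; ++w) {
    Vec3 p = v3(0, 0, R0);
    double d_prev = R0 - 1.0;
    bool alive = true;
    for (int k = 1; k <= n_steps && alive; ++k) {
      Vec3 q = p + v3(sd * norm_rand(), sd * norm_rand(), sd * norm_rand());
      double r = norm3(q);
      double d_new = r - 1.0;
      if (d_new <= 0.0) {
        Vec3 mid = 0.5 * (p + q);
        th.push_back(std::acos(std::min(1.0, std::max(-1.0, mid.z / norm3(mid)))));
        tt.push_back(k * dt);
        alive = false;
      } else {
        // probability the bridge crossed the sphere between the endpoints
        double pc = std::exp(-d_prev * d_new / (D * dt));
        if (unif_rand() < pc) {
          Vec3 mid = 0.5 * (p + q);
          th.push_back(std::acos(std::min(1.0, std::max(-1.0, mid.z / norm3(mid)))));
          tt.push_back((k - 0.5) * dt);
          alive = false;
        } else if (r > r_escape) {
          alive = false;
        }
      }
      p = q;
      d_prev = d_new;
    }
  }
  NumericMatrix out(th.size(), 2);
  for (size_t i = 0; i < th.size(); ++i) {
    out(i, 0) = th[i];
    out(i, 1) = tt[i];
  }
  return out;
}
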