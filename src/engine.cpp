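// Planar neuromusculoskeletal simulation core: articulated rigid-body dynamics,
// Hill-type muscle-tendon units, Hunt-Crossley contact, reflex controllers and
// the fixed-step rollout loop. All angles use a clockwise-from-vertical
// ("forward lean positive") convention; rotation matrix R(theta) maps local to
// world with R*(0,1) = (sin, cos). With qdd = 0 every angular bias acceleration
// vanishes in a tree of pin joints, which the bias-force pass exploits.

#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline arma::vec2 rot(double th, const arma::vec2& u) {
  double c = std::cos(th), s = std::sin(th);
  return arma::vec2({ c * u[0] + s * u[1], -s * u[0] + c * u[1] });
}
// S*v with S = dR/dtheta * R^T = [[0,1],[-1,0]]
static inline arma::vec2 sperp(const arma::vec2& v) {
  return arma::vec2({ v[1], -v[0] });
}

// ---------------------------------------------------------------------------
// Model containers
// ---------------------------------------------------------------------------

struct Model {
  int nseg = 0, nq = 0, nm = 0, nc = 0;
  arma::vec mass, inertia;
  arma::mat com;          // 2 x nseg, local COM
  std::vector<int> parent, jkind, dof; // jkind: 0 free root, 1 pin-to-ground, 2 pin
  arma::mat ap, ac;       // 2 x nseg anchors (parent frame / child frame)
  arma::vec sgn;
  // per-dof passive elements
  arma::vec damping, kpass, qpass, klim, qlo, qhi, blim;
  // muscles
  arma::vec fmax, lopt, lslack, vmax, L0, mdelay;
  arma::mat arms;         // nm x nq, moment arms (positive drives dof positive)
  std::vector<int> mgroup, mside, antag;
  // muscle constants
  double tau_act = 0.01, tau_deact = 0.04, flW = 0.45, fvshape = 0.25,
         fvecc = 1.4, sigma = 25.0, rho = 1.0597;
  // contact spheres
  std::vector<int> cseg, csurf, cside;
  arma::mat coff;         // 2 x nc
  arma::vec crad, ck, cp, cc, cmu;
  bool has_chair = false;
  double chair_x0 = 0, chair_x1 = 0, chair_top = 0;
  double g = 9.81;
  double vt_reg = 0.05;   // friction regularization velocity, m/s
  // indices for the full body model (-1 when absent)
  bool has_idx = false;
  int hip[2] = { -1, -1 }, knee[2] = { -1, -1 }, ankle[2] = { -1, -1 };
  int lumbar = -1, thoracic = -1, pelvis_seg = 0, torso_seg = -1;
  arma::vec2 head_local = { 0, 0 };
  std::vector<std::string> dof_names, mus_names;
};

static Model parse_model(const List& cm) {
  Model M;
  M.mass = as<arma::vec>(cm["mass"]);
  M.inertia = as<arma::vec>(cm["inertia"]);
  M.com = as<arma::mat>(cm["com"]);
  M.parent = as<std::vector<int>>(cm["parent"]);
  M.jkind = as<std::vector<int>>(cm["jkind"]);
  M.dof = as<std::vector<int>>(cm["dof"]);
  M.ap = as<arma::mat>(cm["ap"]);
  M.ac = as<arma::mat>(cm["ac"]);
  M.sgn = as<arma::vec>(cm["sgn"]);
  M.nseg = M.mass.n_elem;
  M.nq = as<int>(cm["nq"]);
  M.damping = as<arma::vec>(cm["damping"]);
  M.kpass = as<arma::vec>(cm["kpass"]);
  M.qpass = as<arma::vec>(cm["qpass"]);
  M.klim = as<arma::vec>(cm["klim"]);
  M.qlo = as<arma::vec>(cm["qlo"]);
  M.qhi = as<arma::vec>(cm["qhi"]);
  M.blim = as<arma::vec>(cm["blim"]);
  M.fmax = as<arma::vec>(cm["fmax"]);
  M.nm = M.fmax.n_elem;
  if (M.nm > 0) {
    M.lopt = as<arma::vec>(cm["lopt"]);
    M.lslack = as<arma::vec>(cm["lslack"]);
    M.vmax = as<arma::vec>(cm["vmax"]);
    M.L0 = as<arma::vec>(cm["L0"]);
    M.arms = as<arma::mat>(cm["arms"]);
    M.mgroup = as<std::vector<int>>(cm["mgroup"]);
    M.mside = as<std::vector<int>>(cm["mside"]);
    M.antag = as<std::vector<int>>(cm["antag"]);
    M.mdelay = as<arma::vec>(cm["mdelay"]);
    M.mus_names = as<std::vector<std::string>>(cm["mus_names"]);
  }
  List mp = cm["mpar"];
  M.tau_act = as<double>(mp["tau_act"]);
  M.tau_deact = as<double>(mp["tau_deact"]);
  M.flW = as<double>(mp["fl_width"]);
  M.fvshape = as<double>(mp["fv_shape"]);
  M.fvecc = as<double>(mp["fv_ecc"]);
  M.sigma = as<double>(mp["specific_tension"]);
  M.rho = as<double>(mp["density"]);
  M.cseg = as<std::vector<int>>(cm["cseg"]);
  M.nc = M.cseg.size();
  if (M.nc > 0) {
    M.coff = as<arma::mat>(cm["coff"]);
    M.crad = as<arma::vec>(cm["crad"]);
    M.ck = as<arma::vec>(cm["ck"]);
    M.cp = as<arma::vec>(cm["cpow"]);
    M.cc = as<arma::vec>(cm["cdamp"]);
    M.cmu = as<arma::vec>(cm["cmu"]);
    M.csurf = as<std::vector<int>>(cm["csurf"]);
    M.cside = as<std::vector<int>>(cm["cside"]);
  }
  M.has_chair = as<bool>(cm["has_chair"]);
  if (M.has_chair) {
    M.chair_x0 = as<double>(cm["chair_x0"]);
    M.chair_x1 = as<double>(cm["chair_x1"]);
    M.chair_top = as<double>(cm["chair_top"]);
  }
  M.g = as<double>(cm["gravity"]);
  M.vt_reg = as<double>(cm["vt_reg"]);
  M.dof_names = as<std::vector<std::string>>(cm["dof_names"]);
  M.has_idx = as<bool>(cm["has_idx"]);
  if (M.has_idx) {
    IntegerVector ix = cm["idx"]; // 0-based
    M.hip[0] = ix["hip_r"];   M.hip[1] = ix["hip_l"];
    M.knee[0] = ix["knee_r"]; M.knee[1] = ix["knee_l"];
    M.ankle[0] = ix["ankle_r"]; M.ankle[1] = ix["ankle_l"];
    M.lumbar = ix["lumbar"];  M.thoracic = ix["thoracic"];
    M.pelvis_seg = ix["pelvis_seg"]; M.torso_seg = ix["torso_seg"];
    NumericVector hl = cm["head_local"];
    M.head_local = { hl[0], hl[1] };
  }
  return M;
}

// ---------------------------------------------------------------------------
// Kinematics
// ---------------------------------------------------------------------------

struct Kin {
  arma::mat pos;    // 2 x nseg (segment origin, world)
  arma::vec theta, omega;
  arma::mat vel;    // 2 x nseg
  arma::cube Jpos;  // 2 x nq x nseg
  arma::mat Jang;   // nseg x nq
  arma::mat abias;  // 2 x nseg (origin bias acceleration, qdd = 0)
};

static Kin kinematics(const Model& M, const arma::vec& q, const arma::vec& qd) {
  Kin K;
  int n = M.nseg, nq = M.nq;
  K.pos.zeros(2, n); K.vel.zeros(2, n);
  K.theta.zeros(n); K.omega.zeros(n);
  K.Jpos.zeros(2, nq, n); K.Jang.zeros(n, nq);
  K.abias.zeros(2, n);
  for (int i = 0; i < n; ++i) {
    if (M.jkind[i] == 0) {              // planar free root: q = (x, y, tilt)
      K.pos.col(i) = arma::vec2({ q[0], q[1] });
      K.theta[i] = q[2];
      K.vel.col(i) = arma::vec2({ qd[0], qd[1] });
      K.omega[i] = qd[2];
      K.Jpos(0, 0, i) = 1.0; K.Jpos(1, 1, i) = 1.0;
      K.Jang(i, 2) = 1.0;
    } else if (M.jkind[i] == 1) {       // pin anchored to the world
      int d = M.dof[i];
      double th = M.sgn[i] * q[d];
      arma::vec2 rc = rot(th, M.ac.col(i));
      K.theta[i] = th;
      K.omega[i] = M.sgn[i] * qd[d];
      K.pos.col(i) = M.ap.col(i) - rc;
      K.vel.col(i) = -K.omega[i] * sperp(rc);
      K.Jang(i, d) = M.sgn[i];
      arma::vec2 dp = -M.sgn[i] * sperp(rc);
      K.Jpos(0, d, i) = dp[0]; K.Jpos(1, d, i) = dp[1];
      K.abias.col(i) = K.omega[i] * K.omega[i] * rc;
    } else {                            // pin joint to parent
      int p = M.parent[i], d = M.dof[i];
      arma::vec2 rp = rot(K.theta[p], M.ap.col(i));
      arma::vec2 Xj = K.pos.col(p) + rp;
      double th = K.theta[p] + M.sgn[i] * q[d];
      arma::vec2 rc = rot(th, M.ac.col(i));
      K.theta[i] = th;
      K.omega[i] = K.omega[p] + M.sgn[i] * qd[d];
      K.pos.col(i) = Xj - rc;
      arma::vec2 vXj = K.vel.col(p) + K.omega[p] * sperp(rp);
      K.vel.col(i) = vXj - K.omega[i] * sperp(rc);
      // Jacobians
      arma::rowvec Jap = K.Jang.row(p);
      arma::mat JXj = K.Jpos.slice(p) + sperp(rp) * Jap;
      K.Jang.row(i) = Jap;
      K.Jang(i, d) += M.sgn[i];
      K.Jpos.slice(i) = JXj - sperp(rc) * K.Jang.row(i);
      // bias acceleration (all angular bias accels vanish with qdd = 0)
      arma::vec2 aXj = K.abias.col(p) - K.omega[p] * K.omega[p] * rp;
      K.abias.col(i) = aXj + K.omega[i] * K.omega[i] * rc;
    }
  }
  return K;
}

struct Dyn {
  arma::mat Mmat;
  arma::vec h;    // velocity-product bias force
  arma::vec Qg;   // generalized gravity force
  arma::mat Jcom; // stacked (2*nseg) x nq for reuse
  arma::mat acomb;// 2 x nseg COM bias accelerations
  arma::mat comw; // 2 x nseg world COM
};

static Dyn dynamics_terms(const Model& M, const Kin& K) {
  Dyn D;
  int nq = M.nq;
  D.Mmat.zeros(nq, nq); D.h.zeros(nq); D.Qg.zeros(nq);
  D.Jcom.zeros(2 * M.nseg, nq);
  D.acomb.zeros(2, M.nseg);
  D.comw.zeros(2, M.nseg);
  arma::vec2 gv = { 0.0, -M.g };
  for (int i = 0; i < M.nseg; ++i) {
    arma::vec2 ci = rot(K.theta[i], M.com.col(i));
    arma::mat Jc = K.Jpos.slice(i) + sperp(ci) * K.Jang.row(i);
    arma::vec2 ab = K.abias.col(i) - K.omega[i] * K.omega[i] * ci;
    D.Mmat += M.mass[i] * (Jc.t() * Jc) +
              M.inertia[i] * (K.Jang.row(i).t() * K.Jang.row(i));
    D.h += M.mass[i] * (Jc.t() * ab);
    D.Qg += M.mass[i] * (Jc.t() * gv);
    D.Jcom.rows(2 * i, 2 * i + 1) = Jc;
    D.acomb.col(i) = ab;
    D.comw.col(i) = K.pos.col(i) + ci;
  }
  return D;
}

// ---------------------------------------------------------------------------
// Muscle model (scalar pieces shared by the loop and the R-level evaluators)
// ---------------------------------------------------------------------------

static inline double fl_act(double lt, double W) {
  double x = (lt - 1.0) / W;
  return std::exp(-x * x);
}
static inline double fv_hill(double vt, double shape, double ecc) {
  double vs = -vt; // shortening positive
  if (vs >= 0.0) {
    if (vs >= 1.0) return 0.0;
    return (1.0 - vs) / (1.0 + vs / shape);
  }
  double ve = -vs;
  double slope0 = 1.0 + 1.0 / shape;            // |slope| at v = 0
  double gg = slope0 / (ecc - 1.0);
  return ecc - (ecc - 1.0) / (1.0 + gg * ve);
}
static inline double fp_pass(double lt) {
  if (lt <= 1.0) return 0.0;
  double f = (std::exp(4.0 * (lt - 1.0) / 0.6) - 1.0) / (std::exp(4.0) - 1.0);
  return std::min(f, 3.0);
}
static inline double hc_force(double delta, double ddelta, double k, double p,
                              double c) {
  if (delta <= 0.0) return 0.0;
  double mult = 1.0 + 1.5 * c * ddelta;
  if (mult < 0.0) mult = 0.0;
  if (mult > 2.0) mult = 2.0;  // cap impact amplification for stability
  return k * std::pow(delta, p) * mult;
}
static inline double fric_force(double fn, double slip, double mu, double vreg) {
  return -mu * fn * std::tanh(slip / vreg);
}
// exact solution of da/dt = (u - a)/tau over one step with u held constant
static inline double act_step(double u, double a, double dt, double ta,
                              double td) {
  double tau = (u > a) ? ta : td;
  double an = u + (a - u) * std::exp(-dt / tau);
  if (an < 0.0) an = 0.0;
  if (an > 1.0) an = 1.0;
  return an;
}
static inline double musc_mass(double fmax, double lopt, double sigma,
                               double rho) {
  // PCSA [cm^2] = fmax / sigma; volume [cm^3] = PCSA * lopt[cm]; mass [kg]
  return (fmax / sigma) * (lopt * 100.0) * rho / 1000.0;
}

// ---------------------------------------------------------------------------
// Reflex controller
// ---------------------------------------------------------------------------

enum Grp { ILPSO = 0, GMAX, ADM, RF, VAS, HAM, BFSH, GAS, SOL, TA };
enum LegState { EARLY_ST = 0, LATE_ST, LIFTOFF, SWING, LANDING };

struct StandState {
  arma::vec KC, KL, LO, KFp, KFm, KP, KV; // length 10 (per muscle group)
  double theta0 = 0.0;
  double trunk[6] = { 0, 0, 0, 0, 0, 0 }; // lumbar q0,kp,kv; thoracic q0,kp,kv
};

struct GaitPar {
  std::map<std::string, double> v;
  double operator()(const std::string& k) const {
    auto it = v.find(k);
    if (it == v.end()) stop("gait parameter '" + k + "' missing");
    return it->second;
  }
};

struct Controller {
  int kind = 0;                    // 0 none, 1 constant, 2 reflex stw
  arma::vec const_u;
  double t_state2 = 0.3, t_gait = 1.5, stance_thr = 0.2;
  StandState st[2];
  GaitPar gp;
  bool has_gait = false;
  // runtime
  int leg_state[2] = { EARLY_ST, EARLY_ST }; // [right, left]
  double leg_entry[2] = { 0, 0 };
  bool gait_started = false;
};

static StandState parse_stand(const List& s) {
  StandState out;
  out.KC = as<arma::vec>(s["KC"]);  out.KL = as<arma::vec>(s["KL"]);
  out.LO = as<arma::vec>(s["LO"]);  out.KFp = as<arma::vec>(s["KFp"]);
  out.KFm = as<arma::vec>(s["KFm"]); out.KP = as<arma::vec>(s["KP"]);
  out.KV = as<arma::vec>(s["KV"]);
  out.theta0 = as<double>(s["theta0"]);
  NumericVector tr = s["trunk"];
  for (int i = 0; i < 6; ++i) out.trunk[i] = tr[i];
  return out;
}

static Controller parse_ctrl(const List& c) {
  Controller C;
  C.kind = as<int>(c["kind"]);
  if (C.kind == 1) C.const_u = as<arma::vec>(c["u"]);
  if (C.kind == 2) {
    C.t_state2 = as<double>(c["t_state2"]);
    C.t_gait = as<double>(c["t_gait"]);
    C.stance_thr = as<double>(c["stance_thr"]);
    List stl = c["stand"];
    C.st[0] = parse_stand(stl[0]);
    C.st[1] = parse_stand(stl[1]);
    C.has_gait = as<bool>(c["has_gait"]);
    if (C.has_gait) {
      NumericVector gv = c["gait"];
      CharacterVector nm = gv.names();
      for (int i = 0; i < gv.size(); ++i)
        C.gp.v[as<std::string>(nm[i])] = gv[i];
    }
  }
  return C;
}

// Ring buffers for delayed feedback
struct DelayBuf {
  arma::mat lt, ft;        // nm x cap
  arma::vec th, thd;       // cap
  int cap = 0, head = -1;  // head = index of most recent sample (step count)
  double dt = 1e-3;
  void init(int nm, int cap_, double dt_, const arma::vec& lt0,
            const arma::vec& ft0, double th0, double thd0) {
    cap = cap_; dt = dt_; head = 0;
    lt.set_size(std::max(nm, 1), cap); ft.set_size(std::max(nm, 1), cap);
    th.set_size(cap); thd.set_size(cap);
    for (int j = 0; j < cap; ++j) {
      if (nm > 0) { lt.col(j) = lt0; ft.col(j) = ft0; }
      th[j] = th0; thd[j] = thd0;
    }
  }
  void push(const arma::vec& ltv, const arma::vec& ftv, double thv,
            double thdv) {
    head += 1;
    int j = head % cap;
    if (ltv.n_elem > 0) { lt.col(j) = ltv; ft.col(j) = ftv; }
    th[j] = thv; thd[j] = thdv;
  }
  // delayed lookup with linear interpolation; clamps to oldest stored sample
  double look(const arma::mat& buf, int row, double delay) const {
    double s = delay / dt;
    int k = (int)std::floor(s);
    double w = s - k;
    int i1 = head - k, i0 = i1 - 1;
    int lo = std::max(0, head - (cap - 1));
    if (i1 < lo) i1 = lo;
    if (i0 < lo) i0 = lo;
    double v1 = buf(row, i1 % cap), v0 = buf(row, i0 % cap);
    return (1.0 - w) * v1 + w * v0;
  }
  double look_v(const arma::vec& buf, double delay) const {
    double s = delay / dt;
    int k = (int)std::floor(s);
    double w = s - k;
    int i1 = head - k, i0 = i1 - 1;
    int lo = std::max(0, head - (cap - 1));
    if (i1 < lo) i1 = lo;
    if (i0 < lo) i0 = lo;
    return (1.0 - w) * buf[i1 % cap] + w * buf[i0 % cap];
  }
};

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Stand-phase excitation for muscle m under stand-state gains
static double stand_u(const Model& M, const StandState& S, const DelayBuf& B,
                      int m) {
  int g = M.mgroup[m];
  double d = M.mdelay[m];
  double u = S.KC[g];
  double ltd = B.look(B.lt, m, d);
  if (S.KL[g] != 0.0) u += S.KL[g] * std::max(0.0, ltd - S.LO[g]);
  if (S.KFp[g] != 0.0) u += S.KFp[g] * B.look(B.ft, m, d);
  int am = M.antag[m];
  if (S.KFm[g] != 0.0 && am >= 0) u -= S.KFm[g] * B.look(B.ft, am, d);
  if (S.KP[g] != 0.0 || S.KV[g] != 0.0) {
    double th = B.look_v(B.th, d), thd = B.look_v(B.thd, d);
    u += S.KP[g] * (th - S.theta0) + S.KV[g] * thd;
  }
  return clamp01(u);
}

// Gait-phase excitation for muscle m given its leg's machine state
static double gait_u(const Model& M, const Controller& C, const DelayBuf& B,
                     int m, int ls, const arma::vec& q) {
  const GaitPar& P = C.gp;
  int g = M.mgroup[m];
  int side = M.mside[m];
  double d = M.mdelay[m];
  double th = B.look_v(B.th, d), thd = B.look_v(B.thd, d);
  double dth = th - P("THETA0_G");
  double u = 0.01;
  bool stance = (ls == EARLY_ST || ls == LATE_ST || ls == LANDING);
  switch (g) {
  case SOL:
    if (stance) u = P("C_SOL") + P("G_SOL_F") * B.look(B.ft, m, d);
    break;
  case GAS:
    if (stance) u = P("C_GAS") + P("G_GAS_F") * B.look(B.ft, m, d);
    if (ls == LATE_ST || ls == LIFTOFF) u += P("C_GAS_PUSH");
    break;
  case TA: {
    u = P("C_TA") + P("G_TA_L") *
          std::max(0.0, B.look(B.lt, m, d) - P("LO_TA_G"));
    if (stance) {
      int sol = (side == 0) ? SOL : (10 + SOL); // same-leg soleus index
      u -= P("G_TA_FSOL") * B.look(B.ft, sol, d);
    }
    break;
  }
  case VAS: {
    if (ls == EARLY_ST || ls == LANDING)
      u = P("C_VAS_G") + P("G_VAS_F") * B.look(B.ft, m, d);
    if (ls == LATE_ST)
      u = P("S_VAS_LO") * (P("C_VAS_G") + P("G_VAS_F") * B.look(B.ft, m, d));
    if (ls == LANDING) u += P("C_VAS_LD");
    // knee over-extension protection
    double qk = q[M.knee[side]];
    u -= P("K_KO") * std::max(0.0, qk - (-0.06));
    break;
  }
  case GMAX:
    if (stance) u = P("C_GMAX_G") +
      std::max(0.0, P("G_GMAX_P") * dth + P("G_GMAX_V") * thd);
    if (ls == SWING) u = P("C_GMAX_SW");
    if (ls == LANDING) u += P("C_GMAX_LD");
    break;
  case ADM:
    if (stance) u = P("C_ADM_G") +
      0.5 * std::max(0.0, P("G_GMAX_P") * dth + P("G_GMAX_V") * thd);
    break;
  case HAM:
    if (stance) u = P("C_HAM_G") +
      std::max(0.0, P("G_HAM_P") * dth + P("G_HAM_V") * thd);
    if (ls == SWING)
      u = P("G_HAM_SWF") * B.look(B.ft, m, d) +
          P("G_HAM_SWL") * std::max(0.0, B.look(B.lt, m, d) - P("LO_HAM_SW"));
    if (ls == LANDING) u += P("C_HAM_LD");
    break;
  case ILPSO:
    if (stance) u = P("C_ILP_ST") +
      std::max(0.0, -P("G_ILP_P") * dth - P("G_ILP_V") * thd);
    if (ls == LATE_ST) u += P("C_ILP_PUSH");
    if (ls == LIFTOFF) u = P("C_ILP_LF");
    if (ls == SWING)
      u = P("C_ILP_SW") + P("G_ILP_L") *
            std::max(0.0, B.look(B.lt, m, d) - P("LO_ILP"));
    break;
  case BFSH:
    if (ls == LIFTOFF) u = P("C_BFSH_LF");
    break;
  case RF:
    if (stance) u = P("C_RF_ST");
    if (ls == SWING) u = P("C_RF_SW");
    break;
  }
  return clamp01(u);
}

// ---------------------------------------------------------------------------
// Exported scalar evaluators (used by R wrappers and tests)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".fl_curve_cpp")]]
NumericVector fl_curve_cpp(NumericVector lt, double width) {
  NumericVector out(lt.size());
  for (int i = 0; i < lt.size(); ++i) out[i] = fl_act(lt[i], width);
  return out;
}

// [[Rcpp::export(name = ".fv_curve_cpp")]]
NumericVector fv_curve_cpp(NumericVector vt, double shape, double ecc) {
  NumericVector out(vt.size());
  for (int i = 0; i < vt.size(); ++i) out[i] = fv_hill(vt[i], shape, ecc);
  return out;
}

// [[Rcpp::export(name = ".fp_curve_cpp")]]
NumericVector fp_curve_cpp(NumericVector lt) {
  NumericVector out(lt.size());
  for (int i = 0; i < lt.size(); ++i) out[i] = fp_pass(lt[i]);
  return out;
}

// [[Rcpp::export(name = ".mtu_force_cpp")]]
double mtu_force_cpp(double fmax, double lopt, double lslack, double vmax,
                     double L, double v, double a, double width, double shape,
                     double ecc) {
  double lt = (L - lslack) / lopt;
  if (lt < 0.01) lt = 0.01;
  double vt = v / (lopt * vmax);
  double F = fmax * (a * fl_act(lt, width) * fv_hill(vt, shape, ecc) +
                     fp_pass(lt));
  return F > 0.0 ? F : 0.0;
}

// [[Rcpp::export(name = ".activation_step_cpp")]]
double activation_step_cpp(double u, double a, double dt, double tau_act,
                           double tau_deact) {
  return act_step(u, a, dt, tau_act, tau_deact);
}

// [[Rcpp::export(name = ".muscle_mass_cpp")]]
double muscle_mass_cpp(double fmax, double lopt, double sigma, double rho) {
  return musc_mass(fmax, lopt, sigma, rho);
}

// [[Rcpp::export(name = ".metabolic_rates_cpp")]]
NumericVector metabolic_rates_cpp(double a, double F, double vfiber, double lt,
                                  double fmax, double lopt, double sigma,
                                  double rho, double width) {
  double m = musc_mass(fmax, lopt, sigma, rho);
  double vs = std::max(0.0, -vfiber);
  double Adot = 133.0 * m * a;
  double Mdot = 74.0 * m * a * fl_act(lt, width);
  double Sdot = 0.25 * F * vs;
  double Wdot = F * vs;
  return NumericVector::create(_["Adot"] = Adot, _["Mdot"] = Mdot,
                               _["Sdot"] = Sdot, _["Wdot"] = Wdot);
}

// [[Rcpp::export(name = ".hc_normal_cpp")]]
double hc_normal_cpp(double delta, double ddelta, double k, double p,
                     double c) {
  return hc_force(delta, ddelta, k, p, c);
}

// [[Rcpp::export(name = ".friction_cpp")]]
double friction_cpp(double normal, double slip, double mu, double vreg) {
  return fric_force(normal, slip, mu, vreg);
}

// [[Rcpp::export(name = ".forward_dynamics_cpp")]]
NumericVector forward_dynamics_cpp(List cmodel, NumericVector q,
                                   NumericVector qd, NumericVector applied) {
  Model M = parse_model(cmodel);
  arma::vec qv = as<arma::vec>(q), qdv = as<arma::vec>(qd);
  Kin K = kinematics(M, qv, qdv);
  Dyn D = dynamics_terms(M, K);
  arma::vec Q = as<arma::vec>(applied);
  arma::vec qdd = arma::solve(D.Mmat, Q + D.Qg - D.h, arma::solve_opts::likely_sympd);
  return wrap(qdd);
}

// [[Rcpp::export(name = ".mass_matrix_cpp")]]
List mass_matrix_cpp(List cmodel, NumericVector q, NumericVector qd) {
  Model M = parse_model(cmodel);
  Kin K = kinematics(M, as<arma::vec>(q), as<arma::vec>(qd));
  Dyn D = dynamics_terms(M, K);
  // potential energy (for conservation checks): sum m g y_com
  double pe = 0.0;
  for (int i = 0; i < M.nseg; ++i) pe += M.mass[i] * M.g * D.comw(1, i);
  return List::create(_["M"] = D.Mmat, _["bias"] = D.h, _["Qg"] = D.Qg,
                      _["pe"] = pe, _["com"] = D.comw);
}

// [[Rcpp::export(name = ".muscle_geometry_cpp")]]
List muscle_geometry_cpp(List cmodel, NumericVector q) {
  Model M = parse_model(cmodel);
  arma::vec qv = as<arma::vec>(q);
  arma::vec L = M.L0 - M.arms * qv;
  return List::create(_["length"] = L, _["arms"] = M.arms);
}

// shared contact evaluation; fills per-sphere forces (world) and point
static void eval_contacts(const Model& M, const Kin& K, arma::mat& cf,
                          arma::mat& cpts) {
  cf.zeros(2, M.nc);
  cpts.zeros(2, M.nc);
  for (int j = 0; j < M.nc; ++j) {
    int s = M.cseg[j];
    arma::vec2 u = M.coff.col(j);
    arma::vec2 ru = rot(K.theta[s], u);
    arma::vec2 Cw = K.pos.col(s) + ru;
    arma::vec2 Cv = K.vel.col(s) + K.omega[s] * sperp(ru);
    double fn = 0, ft = 0;
    arma::vec2 pt = Cw;
    if (M.csurf[j] == 0) {              // ground plane y = 0
      double delta = M.crad[j] - Cw[1];
      double ddelta = -Cv[1];
      fn = hc_force(delta, ddelta, M.ck[j], M.cp[j], M.cc[j]);
      ft = fric_force(fn, Cv[0], M.cmu[j], M.vt_reg);
      pt = { Cw[0], Cw[1] - M.crad[j] };
    } else if (M.has_chair) {           // chair box top surface
      double bot = Cw[1] - M.crad[j];
      if (Cw[0] > M.chair_x0 && Cw[0] < M.chair_x1 && bot < M.chair_top &&
          bot > M.chair_top - 0.15) {
        double delta = M.chair_top - bot;
        double ddelta = -Cv[1];
        // fade near the front/back edges so seat-off is smooth
        double e = 0.02;
        double w = std::min(1.0, std::min((M.chair_x1 - Cw[0]) / e,
                                          (Cw[0] - M.chair_x0) / e));
        if (w < 0.0) w = 0.0;
        fn = w * hc_force(delta, ddelta, M.ck[j], M.cp[j], M.cc[j]);
        ft = fric_force(fn, Cv[0], M.cmu[j], M.vt_reg);
        pt = { Cw[0], M.chair_top };
      }
    }
    cf(0, j) = ft; cf(1, j) = fn;
    cpts.col(j) = pt;
  }
}

// [[Rcpp::export(name = ".contact_eval_cpp")]]
List contact_eval_cpp(List cmodel, NumericVector q, NumericVector qd) {
  Model M = parse_model(cmodel);
  Kin K = kinematics(M, as<arma::vec>(q), as<arma::vec>(qd));
  arma::mat cf, cpts;
  eval_contacts(M, K, cf, cpts);
  double ground = 0, chair = 0;
  for (int j = 0; j < M.nc; ++j) {
    if (M.csurf[j] == 0) ground += cf(1, j); else chair += cf(1, j);
  }
  return List::create(_["forces"] = cf.t(), _["points"] = cpts.t(),
                      _["ground_fy"] = ground, _["chair_fy"] = chair);
}

// ---------------------------------------------------------------------------
// Rollout
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(List cmodel, List ctrl, NumericVector q0, NumericVector qd0,
                  NumericVector a0, List opts) {
  Model M = parse_model(cmodel);
  Controller C = parse_ctrl(ctrl);
  double dt = as<double>(opts["dt"]);
  double out_dt = as<double>(opts["out_dt"]);
  double duration = as<double>(opts["duration"]);
  double fall_floor = as<double>(opts["fall_floor"]);
  double qd_cap = as<double>(opts["qd_cap"]);
  int out_every = std::max(1, (int)std::lround(out_dt / dt));
  int nsteps = (int)std::lround(duration / dt);
  int nq = M.nq, nm = M.nm;

  arma::vec q = as<arma::vec>(q0), qd = as<arma::vec>(qd0);
  arma::vec a = as<arma::vec>(a0);
  if ((int)a.n_elem != nm) a = arma::vec(nm, arma::fill::value(0.02));

  // column layout
  std::vector<std::string> cols;
  cols.push_back("t");
  for (auto& n : M.dof_names) cols.push_back(n);
  for (auto& n : M.dof_names) cols.push_back("d_" + n);
  for (auto& n : M.mus_names) cols.push_back("u_" + n);
  for (auto& n : M.mus_names) cols.push_back("a_" + n);
  for (auto& n : M.mus_names) cols.push_back("F_" + n);
  for (auto& n : M.mus_names) cols.push_back("lce_" + n);
  for (auto& n : M.mus_names) cols.push_back("E_" + n);
  const char* fixedc[] = { "grf_r_fx", "grf_r_fy", "grf_l_fx", "grf_l_fy",
                           "chair_fx", "chair_fy" };
  for (auto& n : fixedc) cols.push_back(n);
  bool loads = M.has_idx;
  if (loads) {
    const char* lc[] = { "load_hip_r", "load_knee_r", "load_ankle_r",
                         "load_hip_l", "load_knee_l", "load_ankle_l",
                         "tau_lumbar", "tau_thoracic", "lim_knee_r",
                         "lim_knee_l", "head_ax", "head_ay" };
    for (auto& n : lc) cols.push_back(n);
  }
  cols.push_back("mode"); cols.push_back("state_leg_r");
  cols.push_back("state_leg_l");
  int ncol = cols.size();
  int nout = nsteps / out_every + 1;
  arma::mat out(nout, ncol, arma::fill::zeros);
  int irow = 0;

  // subtree membership for joint loads: for each dof, which segments hang
  // below the joint driven by that dof
  std::vector<std::vector<int>> subtree(nq);
  if (loads) {
    for (int i = 0; i < M.nseg; ++i) {
      if (M.jkind[i] != 2 && M.jkind[i] != 1) continue;
      int d = M.dof[i];
      // walk all segments, include those whose chain passes through i
      for (int s2 = 0; s2 < M.nseg; ++s2) {
        int cur = s2;
        while (cur >= 0) {
          if (cur == i) { subtree[d].push_back(s2); break; }
          cur = M.parent[cur];
        }
      }
    }
  }

  // delay buffers
  double maxdel = 0.0;
  for (int m = 0; m < nm; ++m) maxdel = std::max(maxdel, M.mdelay[m]);
  int cap = (int)std::ceil(maxdel / dt) + 3;
  DelayBuf B;
  {
    arma::vec lt0(std::max(nm, 1), arma::fill::zeros), ft0 = lt0;
    if (nm > 0) {
      arma::vec L = M.L0 - M.arms * q;
      for (int m = 0; m < nm; ++m)
        lt0[m] = std::max(0.01, (L[m] - M.lslack[m]) / M.lopt[m]);
      ft0.zeros();
    }
    double th0 = (nq >= 3) ? q[2] : 0.0, thd0 = (nq >= 3) ? qd[2] : 0.0;
    B.init(nm, cap, dt, lt0.head(std::max(nm, 1)), ft0, th0, thd0);
  }

  std::string status = "ok";
  C.leg_state[0] = EARLY_ST; C.leg_state[1] = EARLY_ST;

  arma::mat cf, cpts;
  arma::vec F(std::max(nm, 1), arma::fill::zeros);
  arma::vec lt(std::max(nm, 1), arma::fill::ones);
  arma::vec Ldot(std::max(nm, 1), arma::fill::zeros);

  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    Kin K = kinematics(M, q, qd);
    // muscle state
    arma::vec u(std::max(nm, 1), arma::fill::zeros);
    if (nm > 0) {
      arma::vec L = M.L0 - M.arms * q;
      Ldot = -(M.arms * qd);
      for (int m = 0; m < nm; ++m)
        lt[m] = std::max(0.01, (L[m] - M.lslack[m]) / M.lopt[m]);
    }
    // controller mode
    int mode = 0;
    if (C.kind == 2) {
      if (t < C.t_state2) mode = 0;
      else if (t < C.t_gait) mode = 1;
      else mode = 2;
    }
    // contact (needed for dynamics and for the gait machine)
    eval_contacts(M, K, cf, cpts);
    double grf[2][2] = { { 0, 0 }, { 0, 0 } }; // [side][x/y]
    double chair_f[2] = { 0, 0 };
    for (int j = 0; j < M.nc; ++j) {
      if (M.csurf[j] == 1) { chair_f[0] += cf(0, j); chair_f[1] += cf(1, j); }
      else if (M.cside[j] >= 0) {
        grf[M.cside[j]][0] += cf(0, j); grf[M.cside[j]][1] += cf(1, j);
      }
    }
    double bw = arma::accu(M.mass) * M.g;
    // gait state machine
    if (C.kind == 2 && mode == 2) {
      if (!C.gait_started) {
        C.gait_started = true;
        C.leg_state[0] = EARLY_ST; C.leg_state[1] = LATE_ST; // left steps first
        C.leg_entry[0] = C.leg_entry[1] = t;
      }
      for (int s = 0; s < 2; ++s) {
        int o = 1 - s;
        double load = grf[s][1], oload = grf[o][1];
        double dwell = t - C.leg_entry[s];
        int ls = C.leg_state[s], ns = ls;
        double ank_x = 0, oank_x = 0;
        {
          // ankle joint world x: child segment origin of ankle dof
          for (int i = 0; i < M.nseg; ++i) {
            if (M.jkind[i] == 2 && M.dof[i] == M.ankle[s]) ank_x = K.pos(0, i);
            if (M.jkind[i] == 2 && M.dof[i] == M.ankle[o]) oank_x = K.pos(0, i);
          }
        }
        switch (ls) {
        case EARLY_ST:
          if (dwell > 0.05 && oload > C.stance_thr * bw && oank_x > ank_x &&
              C.leg_state[o] != SWING && C.leg_state[o] != LIFTOFF)
            ns = LATE_ST;
          break;
        case LATE_ST:
          if (dwell > 0.03 && load < C.stance_thr * bw) ns = LIFTOFF;
          break;
        case LIFTOFF:
          if (dwell > 0.03 && load < 1.0) ns = SWING;
          break;
        case SWING:
          if (dwell > 0.1 && q[M.hip[s]] > C.gp("HIP_SW_THR")) ns = LANDING;
          break;
        case LANDING:
          if (load > C.stance_thr * bw) ns = EARLY_ST;
          break;
        }
        if (ns != ls) { C.leg_state[s] = ns; C.leg_entry[s] = t; }
      }
    }
    // excitations
    double tau_trunk[2] = { 0, 0 };
    if (C.kind == 1) {
      u = C.const_u;
    } else if (C.kind == 2) {
      if (mode < 2) {
        const StandState& S = C.st[mode];
        for (int m = 0; m < nm; ++m) u[m] = stand_u(M, S, B, m);
        tau_trunk[0] = S.trunk[1] * (S.trunk[0] - q[M.lumbar]) -
                       S.trunk[2] * qd[M.lumbar];
        tau_trunk[1] = S.trunk[4] * (S.trunk[3] - q[M.thoracic]) -
                       S.trunk[5] * qd[M.thoracic];
      } else {
        for (int m = 0; m < nm; ++m)
          u[m] = gait_u(M, C, B, m, C.leg_state[M.mside[m]], q);
        tau_trunk[0] = C.gp("TR_L_KP") * (C.gp("TR_L_Q0") - q[M.lumbar]) -
                       C.gp("TR_L_KV") * qd[M.lumbar];
        tau_trunk[1] = C.gp("TR_T_KP") * (C.gp("TR_T_Q0") - q[M.thoracic]) -
                       C.gp("TR_T_KV") * qd[M.thoracic];
      }
    }
    // activation and force
    arma::vec anew = a;
    if (nm > 0) {
      for (int m = 0; m < nm; ++m) {
        anew[m] = act_step(u[m], a[m], dt, M.tau_act, M.tau_deact);
        double vt = Ldot[m] / (M.lopt[m] * M.vmax[m]);
        double Fm = M.fmax[m] * (anew[m] * fl_act(lt[m], M.flW) *
                                 fv_hill(vt, M.fvshape, M.fvecc) +
                                 fp_pass(lt[m]));
        F[m] = Fm > 0.0 ? Fm : 0.0;
      }
      // push current signals for delayed feedback
      arma::vec ftn = F / M.fmax;
      double th0 = (nq >= 3) ? q[2] : 0.0, thd0 = (nq >= 3) ? qd[2] : 0.0;
      B.push(lt, ftn, th0, thd0);
    }
    // generalized forces
    arma::vec Q(nq, arma::fill::zeros);
    if (nm > 0) Q += M.arms.t() * F;
    double limtau[2] = { 0, 0 }; // knee limit torque magnitudes r/l
    for (int d = 0; d < nq; ++d) {
      Q[d] += -M.damping[d] * qd[d];
      if (M.kpass[d] > 0.0) Q[d] += M.kpass[d] * (M.qpass[d] - q[d]);
      if (M.klim[d] > 0.0) {
        double tl = 0.0;
        if (q[d] < M.qlo[d]) tl = M.klim[d] * (M.qlo[d] - q[d]) -
                                  M.blim[d] * qd[d];
        else if (q[d] > M.qhi[d]) tl = -M.klim[d] * (q[d] - M.qhi[d]) -
                                       M.blim[d] * qd[d];
        Q[d] += tl;
        if (loads && d == M.knee[0]) limtau[0] = std::fabs(tl);
        if (loads && d == M.knee[1]) limtau[1] = std::fabs(tl);
      }
    }
    if (loads) { Q[M.lumbar] += tau_trunk[0]; Q[M.thoracic] += tau_trunk[1]; }
    // contact to generalized forces
    for (int j = 0; j < M.nc; ++j) {
      double fx = cf(0, j), fy = cf(1, j);
      if (fx == 0.0 && fy == 0.0) continue;
      int s = M.cseg[j];
      arma::vec2 rl = cpts.col(j) - K.pos.col(s);
      arma::mat Jp = K.Jpos.slice(s) + sperp(rl) * K.Jang.row(s);
      Q += Jp.t() * arma::vec2({ fx, fy });
    }
    // dynamics
    Dyn D = dynamics_terms(M, K);
    arma::vec qdd = arma::solve(D.Mmat, Q + D.Qg - D.h,
                                arma::solve_opts::likely_sympd);
    // record
    if (step % out_every == 0 && irow < nout) {
      int cidx = 0;
      out(irow, cidx++) = t;
      for (int d = 0; d < nq; ++d) out(irow, cidx++) = q[d];
      for (int d = 0; d < nq; ++d) out(irow, cidx++) = qd[d];
      for (int m = 0; m < nm; ++m) out(irow, cidx++) = u[m];
      for (int m = 0; m < nm; ++m) out(irow, cidx++) = anew[m];
      for (int m = 0; m < nm; ++m) out(irow, cidx++) = F[m];
      for (int m = 0; m < nm; ++m) out(irow, cidx++) = lt[m];
      for (int m = 0; m < nm; ++m) {
        double mm = musc_mass(M.fmax[m], M.lopt[m], M.sigma, M.rho);
        double vs = std::max(0.0, -Ldot[m]);
        double Edot = 133.0 * mm * anew[m] +
                      74.0 * mm * anew[m] * fl_act(lt[m], M.flW) +
                      0.25 * F[m] * vs + F[m] * vs;
        out(irow, cidx++) = Edot;
      }
      out(irow, cidx++) = grf[0][0]; out(irow, cidx++) = grf[0][1];
      out(irow, cidx++) = grf[1][0]; out(irow, cidx++) = grf[1][1];
      out(irow, cidx++) = chair_f[0]; out(irow, cidx++) = chair_f[1];
      if (loads) {
        arma::vec2 gv = { 0.0, -M.g };
        int dofs[6] = { M.hip[0], M.knee[0], M.ankle[0],
                        M.hip[1], M.knee[1], M.ankle[1] };
        for (int k2 = 0; k2 < 6; ++k2) {
          int d = dofs[k2];
          arma::vec2 Fr = { 0, 0 };
          for (int s2 : subtree[d]) {
            arma::mat Jc = D.Jcom.rows(2 * s2, 2 * s2 + 1);
            arma::vec2 acom = Jc * qdd + D.acomb.col(s2);
            Fr += M.mass[s2] * (acom - gv);
          }
          for (int j = 0; j < M.nc; ++j) {
            bool in = false;
            for (int s2 : subtree[d]) if (M.cseg[j] == s2) { in = true; break; }
            if (in) Fr -= cf.col(j);
          }
          double msum = 0.0;
          for (int m = 0; m < nm; ++m)
            if (M.arms(m, d) != 0.0) msum += F[m];
          out(irow, cidx++) = arma::norm(Fr) + msum;
        }
        out(irow, cidx++) = tau_trunk[0];
        out(irow, cidx++) = tau_trunk[1];
        out(irow, cidx++) = limtau[0];
        out(irow, cidx++) = limtau[1];
        // head point acceleration
        int ts = M.torso_seg;
        arma::vec2 hl = rot(K.theta[ts], M.head_local);
        arma::mat Jh = K.Jpos.slice(ts) + sperp(hl) * K.Jang.row(ts);
        arma::vec2 ah = Jh * qdd + (K.abias.col(ts) -
                        K.omega[ts] * K.omega[ts] * hl);
        out(irow, cidx++) = ah[0];
        out(irow, cidx++) = ah[1];
      }
      out(irow, cidx++) = mode;
      out(irow, cidx++) = C.leg_state[0];
      out(irow, cidx++) = C.leg_state[1];
      irow++;
    }
    if (step == nsteps) break;
    // integrate (semi-implicit Euler)
    qd += qdd * dt;
    q += qd * dt;
    a = anew;
    // failure checks
    double pelv_y = (M.jkind[0] == 0) ? q[1] : 1.0;
    if (pelv_y < fall_floor) { status = "fell"; break; }
    if (arma::abs(qd).max() > qd_cap || !q.is_finite()) {
      status = "blowup"; break;
    }
  }
  out.resize(irow, ncol);
  return List::create(_["status"] = status, _["data"] = out,
                      _["colnames"] = wrap(cols),
                      _["t_end"] = out(irow - 1, 0));
}
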