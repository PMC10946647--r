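// Core numerical engine: Felsenstein pruning over compressed site
// patterns, Metropolis-Hastings proposals (NNI, SPR, branch-length and
// parameter scaling, simplex moves) and the full sampling loop.
//
// Node numbering follows ape: tips 1..nTip, root nTip+1 (a trifurcation in
// the unrooted representation), internal nodes nTip+1..2*nTip-2. The edge
// matrix is (parent, child) rows in arbitrary order; traversals are
// derived on the fly.

#include <RcppArmadillo.h>
using namespace Rcpp;

static const double LOG_ZERO = -1e300;

struct Model {
  arma::vec pi;    // 4
  arma::vec er;    // 6
  double shape;
  double pinv;
  int ncat;
  bool jc;
};

// ---- rate mixture -------------------------------------------------------

// mean-of-interval discretization of Gamma(shape, rate = shape), k equal
// probability categories; category means average exactly 1
static arma::vec discretize_gamma(double shape, int k) {
  arma::vec r(k);
  if (k == 1) { r(0) = 1.0; return r; }
  arma::vec cum(k + 1);
  cum(0) = 0.0; cum(k) = 1.0;
  for (int i = 1; i < k; ++i) {
    double q = R::qgamma((double)i / k, shape, 1.0 / shape, 1, 0);
    cum(i) = R::pgamma(q, shape + 1.0, 1.0 / shape, 1, 0);
  }
  for (int i = 0; i < k; ++i) r(i) = k * (cum(i + 1) - cum(i));
  return r;
}

// site-rate classes: invariable class (rate 0) w.p. pinv, Gamma classes
// share the rest equally
static void rate_mixture(const Model& m, arma::vec& rates,
                         arma::vec& probs) {
  if (m.jc) {
    rates = arma::vec{1.0};
    probs = arma::vec{1.0};
    return;
  }
  arma::vec g = discretize_gamma(m.shape, m.ncat);
  if (m.pinv > 0.0) {
    rates.set_size(m.ncat + 1);
    probs.set_size(m.ncat + 1);
    rates(0) = 0.0; probs(0) = m.pinv;
    for (int i = 0; i < m.ncat; ++i) {
      rates(i + 1) = g(i);
      probs(i + 1) = (1.0 - m.pinv) / m.ncat;
    }
  } else {
    rates = g;
    probs.set_size(m.ncat);
    probs.fill(1.0 / m.ncat);
  }
}

// ---- transition probabilities ------------------------------------------

struct Eigensys {
  arma::mat left;    // inv(sqrt(D)) * V
  arma::mat right;   // V' * sqrt(D)
  arma::vec lambda;
};

// symmetric eigendecomposition of the reversible rate matrix normalized to
// unit mean rate at stationarity
static Eigensys gtr_eigensys(const Model& m) {
  static const int pr[6][2] = {{0,1},{0,2},{0,3},{1,2},{1,3},{2,3}};
  arma::mat Q(4, 4, arma::fill::zeros);
  for (int p = 0; p < 6; ++p) {
    int i = pr[p][0], j = pr[p][1];
    Q(i, j) = m.er(p) * m.pi(j);
    Q(j, i) = m.er(p) * m.pi(i);
  }
  for (int i = 0; i < 4; ++i) Q(i, i) = -arma::accu(Q.row(i)) + Q(i, i);
  double mu = 0.0;
  for (int i = 0; i < 4; ++i) mu -= m.pi(i) * Q(i, i);
  Q /= mu;
  arma::vec sq = arma::sqrt(m.pi);
  arma::mat S = Q;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) S(i, j) *= sq(i) / sq(j);
  S = (S + S.t()) / 2.0;
  arma::vec lam;
  arma::mat V;
  arma::eig_sym(lam, V, S);
  Eigensys e;
  e.lambda = lam;
  e.left = V; e.right = V.t();
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      e.left(i, j) /= sq(i);
      e.right(i, j) *= sq(j);
    }
  return e;
}

static void pmatrix_gtr(const Eigensys& e, double d, arma::mat& P) {
  arma::vec ex = arma::exp(e.lambda * d);
  P = e.left * arma::diagmat(ex) * e.right;
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
}

static void pmatrix_jc(double d, arma::mat& P) {
  double ee = std::exp(-4.0 * d / 3.0);
  P.fill(0.25 - 0.25 * ee);
  P.diag().fill(0.25 + 0.75 * ee);
}

// ---- pruning likelihood -------------------------------------------------

struct Topo {
  int nNode, root;
  std::vector<int> order;                        // postorder internal nodes
  std::vector<std::vector<std::pair<int,int>>> kids;  // node -> (child,row)
};

static Topo build_topo(const arma::imat& edge, int nTip) {
  Topo t;
  int E = edge.n_rows;
  t.nNode = E + 1;  // unrooted binary with trifurcating root: 2*nTip - 2
  t.root = nTip;           // 0-based index of node nTip+1
  t.kids.assign(t.nNode, {});
  for (int e = 0; e < E; ++e)
    t.kids[edge(e, 0) - 1].push_back({edge(e, 1) - 1, e});
  // iterative postorder over internal nodes
  t.order.reserve(t.nNode - nTip);
  std::vector<std::pair<int,int>> stack;  // (node, child index)
  stack.push_back({t.root, 0});
  while (!stack.empty()) {
    auto& top = stack.back();
    if (top.second < (int)t.kids[top.first].size()) {
      int ch = t.kids[top.first][top.second].first;
      ++top.second;
      if (ch >= nTip) stack.push_back({ch, 0});
    } else {
      t.order.push_back(top.first);
      stack.pop_back();
    }
  }
  return t;
}

// reusable pruning workspace: indicator partials for tips (constant for a
// dataset) and scratch partials for internal nodes
struct PruneWork {
  std::vector<arma::mat> partial;  // nNode mats of 4 x nPat
  arma::mat tmp;
  void init(int nNode, int nTip, const arma::imat& patterns) {
    int nPat = patterns.n_cols;
    partial.assign(nNode, arma::mat());
    for (int tip = 0; tip < nTip; ++tip) {
      partial[tip].zeros(4, nPat);
      for (int p = 0; p < nPat; ++p)
        partial[tip](patterns(tip, p), p) = 1.0;
    }
    for (int nd = nTip; nd < nNode; ++nd) partial[nd].set_size(4, nPat);
    tmp.set_size(4, nPat);
  }
};

// log likelihood of compressed patterns (0..3 codes) on the tree
static double pruning_loglik(const arma::imat& edge, const arma::vec& bl,
                             int nTip, const arma::imat& patterns,
                             const arma::vec& weights, const Model& m,
                             PruneWork& wk) {
  Topo t = build_topo(edge, nTip);
  int nPat = patterns.n_cols;
  arma::vec rates, probs;
  rate_mixture(m, rates, probs);
  Eigensys es;
  if (!m.jc) es = gtr_eigensys(m);
  arma::vec sitelik(nPat, arma::fill::zeros);
  arma::mat P(4, 4);
  for (arma::uword c = 0; c < rates.n_elem; ++c) {
    double r = rates(c);
    for (int node : t.order) {
      arma::mat& L = wk.partial[node];
      L.ones();
      for (auto& ce : t.kids[node]) {
        double d = r * bl(ce.second);
        if (m.jc) pmatrix_jc(d, P); else pmatrix_gtr(es, d, P);
        wk.tmp = P * wk.partial[ce.first];
        L %= wk.tmp;
      }
    }
    sitelik += probs(c) * (wk.partial[t.root].t() * m.pi);
  }
  double ll = 0.0;
  for (int p = 0; p < nPat; ++p) {
    if (sitelik(p) <= 0.0 || !std::isfinite(sitelik(p))) return LOG_ZERO;
    ll += weights(p) * std::log(sitelik(p));
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_pruning_loglik(IntegerMatrix edgeR, NumericVector blR, int nTip,
                          IntegerMatrix patternsR, NumericVector weightsR,
                          NumericVector pi, NumericVector er, double shape,
                          double pinv, int ncat, bool jc) {
  arma::imat edge(edgeR.nrow(), 2);
  for (int i = 0; i < edgeR.nrow(); ++i) {
    edge(i, 0) = edgeR(i, 0);
    edge(i, 1) = edgeR(i, 1);
  }
  arma::vec bl(blR.begin(), blR.size());
  arma::imat pat(patternsR.nrow(), patternsR.ncol());
  for (int i = 0; i < patternsR.nrow(); ++i)
    for (int j = 0; j < patternsR.ncol(); ++j)
      pat(i, j) = patternsR(i, j);
  arma::vec w(weightsR.begin(), weightsR.size());
  Model m{arma::vec(pi.begin(), 4), arma::vec(er.begin(), 6),
          shape, pinv, ncat, jc};
  PruneWork wk;
  wk.init(edge.n_rows + 1, nTip, pat);
  return pruning_loglik(edge, bl, nTip, pat, w, m, wk);
}

// ---- priors -------------------------------------------------------------

static double ldirichlet(const arma::vec& x, const arma::vec& a) {
  double s = R::lgammafn(arma::accu(a));
  for (arma::uword i = 0; i < x.n_elem; ++i)
    s += (a(i) - 1.0) * std::log(x(i)) - R::lgammafn(a(i));
  return s;
}

struct Prior {
  double blRate;
  arma::vec piAlpha, erAlpha;
  double shapeRate, pinvA, pinvB;
  bool gtr;
};

static double log_prior(const arma::vec& bl, const Model& m,
                        const Prior& pr) {
  double lp = bl.n_elem * std::log(pr.blRate) - pr.blRate * arma::accu(bl);
  if (pr.gtr) {
    lp += ldirichlet(m.pi, pr.piAlpha);
    lp += ldirichlet(m.er, pr.erAlpha);
    lp += R::dexp(m.shape, 1.0 / pr.shapeRate, 1);
    lp += R::dbeta(m.pinv, pr.pinvA, pr.pinvB, 1);
  }
  return lp;
}

// ---- moves --------------------------------------------------------------

// move ids: 0 nni, 1 spr, 2 blScale, 3 betaSimplexPi, 4 dirSimplexPi,
//           5 betaSimplexEr, 6 dirSimplexEr, 7 scaleShape, 8 betaProbPinv

static int runif_int(int n) {  // uniform on 0..n-1
  int k;
  do { k = (int)(R::unif_rand() * n); } while (k >= n);
  return k;
}

// returns log Hastings ratio; LOG_ZERO marks an invalid proposal
static double move_nni(arma::imat& edge, int nTip) {
  int E = edge.n_rows;
  std::vector<int> internal;
  for (int e = 0; e < E; ++e)
    if (edge(e, 1) > nTip) internal.push_back(e);
  if (internal.empty()) return LOG_ZERO;
  int r = internal[runif_int(internal.size())];
  int u = edge(r, 0), v = edge(r, 1);
  int rv[2], nv = 0, ry = -1;
  for (int e = 0; e < E; ++e) {
    if (edge(e, 0) == v && nv < 2) rv[nv++] = e;
    if (edge(e, 0) == u && e != r && ry < 0) ry = e;
  }
  int rx = rv[runif_int(2)];
  edge(rx, 0) = u;
  edge(ry, 0) = v;
  return 0.0;
}

static double move_spr(arma::imat& edge, arma::vec& bl, int nTip) {
  int E = edge.n_rows, root = nTip + 1;
  std::vector<int> prunable;
  for (int e = 0; e < E; ++e)
    if (edge(e, 0) != root) prunable.push_back(e);
  if (prunable.empty()) return LOG_ZERO;
  int rs = prunable[runif_int(prunable.size())];
  int p = edge(rs, 0), s = edge(rs, 1);
  int rp = -1, ro = -1;
  for (int e = 0; e < E; ++e) {
    if (edge(e, 1) == p) rp = e;
    if (edge(e, 0) == p && e != rs) ro = e;
  }
  int o = edge(ro, 1);
  double lm = bl(rp) + bl(ro);
  // mark rows inside the pruned subtree
  std::vector<bool> inSub(E, false);
  std::vector<int> stack{s};
  while (!stack.empty()) {
    int nd = stack.back(); stack.pop_back();
    if (nd <= nTip) continue;
    for (int e = 0; e < E; ++e)
      if (edge(e, 0) == nd) { inSub[e] = true; stack.push_back(edge(e, 1)); }
  }
  std::vector<int> targets;
  for (int e = 0; e < E; ++e)
    if (e != rs && e != rp && e != ro && !inSub[e]) targets.push_back(e);
  int pick = runif_int(targets.size() + 1);  // last slot = merged edge
  if (pick == (int)targets.size()) {
    // re-insert on the merged (g,o) edge: only the split point moves
    double u = R::unif_rand() * lm;
    bl(rp) = u;
    bl(ro) = lm - u;
    return 0.0;
  }
  int rt = targets[pick];
  int b = edge(rt, 1);
  double L = bl(rt);
  double u = R::unif_rand() * L;
  edge(rp, 1) = o;  bl(rp) = lm;        // merged edge g -> o
  edge(ro, 0) = p;  edge(ro, 1) = b;  bl(ro) = L - u;  // p -> b
  edge(rt, 1) = p;  bl(rt) = u;         // a -> p
  return std::log(L) - std::log(lm);
}

static double move_bl_scale(arma::vec& bl, double lambda) {
  int r = runif_int(bl.n_elem);
  double f = std::exp(lambda * (R::unif_rand() - 0.5));
  bl(r) *= f;
  return std::log(f);
}

static double move_scale(double& x, double lambda) {
  double f = std::exp(lambda * (R::unif_rand() - 0.5));
  x *= f;
  return std::log(f);
}

static double move_beta_simplex(arma::vec& x, double a) {
  int K = x.n_elem;
  int i = runif_int(K);
  double xi = x(i);
  double xn = R::rbeta(a * xi + 1.0, a * (1.0 - xi) + 1.0);
  if (xn <= 0.0 || xn >= 1.0) return LOG_ZERO;
  double f = (1.0 - xn) / (1.0 - xi);
  for (int j = 0; j < K; ++j) x(j) *= f;
  x(i) = xn;
  double lh = R::dbeta(xi, a * xn + 1.0, a * (1.0 - xn) + 1.0, 1) -
              R::dbeta(xn, a * xi + 1.0, a * (1.0 - xi) + 1.0, 1) +
              (K - 2) * std::log(f);
  return lh;
}

static double move_dir_simplex(arma::vec& x, double a) {
  int K = x.n_elem;
  arma::vec af = a * x + 1.0, xn(K);
  double s = 0.0;
  for (int i = 0; i < K; ++i) {
    xn(i) = R::rgamma(af(i), 1.0);
    s += xn(i);
  }
  xn /= s;
  if (xn.min() <= 0.0) return LOG_ZERO;
  arma::vec ar = a * xn + 1.0;
  double lh = ldirichlet(x, ar) - ldirichlet(xn, af);
  x = xn;
  return lh;
}

static double move_beta_prob(double& p, double a) {
  double pn = R::rbeta(a * p + 1.0, a * (1.0 - p) + 1.0);
  if (pn <= 0.0 || pn >= 1.0) return LOG_ZERO;
  double lh = R::dbeta(p, a * pn + 1.0, a * (1.0 - pn) + 1.0, 1) -
              R::dbeta(pn, a * p + 1.0, a * (1.0 - p) + 1.0, 1);
  p = pn;
  return lh;
}

static double apply_move(int mv, arma::imat& edge, arma::vec& bl, Model& m,
                         int nTip, double tuning) {
  switch (mv) {
  case 0: return move_nni(edge, nTip);
  case 1: return move_spr(edge, bl, nTip);
  case 2: return move_bl_scale(bl, tuning);
  case 3: return move_beta_simplex(m.pi, tuning);
  case 4: return move_dir_simplex(m.pi, tuning);
  case 5: return move_beta_simplex(m.er, tuning);
  case 6: return move_dir_simplex(m.er, tuning);
  case 7: return move_scale(m.shape, tuning);
  case 8: return move_beta_prob(m.pinv, tuning);
  }
  return LOG_ZERO;
}

// single proposal, exposed for unit testing and the applyMove() wrapper
// [[Rcpp::export]]
List cpp_propose_move(IntegerMatrix edgeR, NumericVector blR, int nTip,
                      NumericVector pi, NumericVector er, double shape,
                      double pinv, int moveId, double tuning) {
  arma::imat edge(edgeR.nrow(), 2);
  for (int i = 0; i < edgeR.nrow(); ++i) {
    edge(i, 0) = edgeR(i, 0);
    edge(i, 1) = edgeR(i, 1);
  }
  arma::vec bl(blR.begin(), blR.size());
  Model m{arma::vec(pi.begin(), 4), arma::vec(er.begin(), 6),
          shape, pinv, 4, false};
  double lh = apply_move(moveId, edge, bl, m, nTip, tuning);
  IntegerMatrix eout(edge.n_rows, 2);
  for (arma::uword i = 0; i < edge.n_rows; ++i) {
    eout(i, 0) = edge(i, 0);
    eout(i, 1) = edge(i, 1);
  }
  return List::create(_["edge"] = eout,
                      _["bl"] = NumericVector(bl.begin(), bl.end()),
                      _["pi"] = NumericVector(m.pi.begin(), m.pi.end()),
                      _["er"] = NumericVector(m.er.begin(), m.er.end()),
                      _["shape"] = m.shape, _["pinv"] = m.pinv,
                      _["logHastings"] = lh);
}

// ---- the chain ----------------------------------------------------------

// [[Rcpp::export]]
List cpp_mcmc_chain(IntegerMatrix edgeR, NumericVector blR, int nTip,
                    NumericVector pi0, NumericVector er0, double shape0,
                    double pinv0, bool jc, int ncat,
                    IntegerMatrix patternsR, NumericVector weightsR,
                    double blRate, NumericVector piAlpha,
                    NumericVector erAlpha, double shapeRate, double pinvA,
                    double pinvB, NumericVector moveWeights,
                    NumericVector tunings0, int burnin, int sampleIters,
                    int thin, int tuneInterval, bool tuneDuringSampling,
                    bool priorOnly) {
  const int nMoves = 9;
  arma::imat edge(edgeR.nrow(), 2);
  for (int i = 0; i < edgeR.nrow(); ++i) {
    edge(i, 0) = edgeR(i, 0);
    edge(i, 1) = edgeR(i, 1);
  }
  arma::vec bl(blR.begin(), blR.size());
  Model m{arma::vec(pi0.begin(), 4), arma::vec(er0.begin(), 6),
          shape0, pinv0, ncat, jc};
  arma::imat pat(patternsR.nrow(), patternsR.ncol());
  for (int i = 0; i < patternsR.nrow(); ++i)
    for (int j = 0; j < patternsR.ncol(); ++j)
      pat(i, j) = patternsR(i, j);
  arma::vec wts(weightsR.begin(), weightsR.size());
  Prior pr{blRate, arma::vec(piAlpha.begin(), 4),
           arma::vec(erAlpha.begin(), 6), shapeRate, pinvA, pinvB, !jc};

  arma::vec mw(moveWeights.begin(), nMoves);
  double wsum = arma::accu(mw);
  int W = (int)std::lround(wsum);
  if (W < 1) W = 1;
  arma::vec cumw = arma::cumsum(mw) / wsum;
  arma::vec tune(tunings0.begin(), nMoves);

  PruneWork wk;
  wk.init(edge.n_rows + 1, nTip, pat);
  double curLik = priorOnly ? 0.0
    : pruning_loglik(edge, bl, nTip, pat, wts, m, wk);
  double curPrior = log_prior(bl, m, pr);
  if (curLik <= LOG_ZERO / 2 || !std::isfinite(curPrior))
    stop("initial state has zero posterior density; re-seed and redraw "
         "the starting state from the prior");

  int nSamp = thin > 0 ? sampleIters / thin : 0;
  List sampEdges(nSamp), sampBls(nSamp);
  NumericMatrix sampPi(nSamp, 4), sampEr(nSamp, 6);
  NumericVector sampShape(nSamp), sampPinv(nSamp), sampLP(nSamp);
  IntegerVector sampIter(nSamp);
  arma::ivec proposed(nMoves, arma::fill::zeros);
  arma::ivec accepted(nMoves, arma::fill::zeros);
  arma::ivec winProp(nMoves, arma::fill::zeros);
  arma::ivec winAcc(nMoves, arma::fill::zeros);
  // tunable boldness direction: +1 when larger tuning = bolder (scales),
  // -1 when larger tuning = more timid (Beta/Dirichlet concentrations)
  const int tdir[nMoves] = {0, 0, 1, -1, -1, -1, -1, 1, -1};

  int total = burnin + sampleIters;
  int si = 0;
  arma::imat pedge;
  arma::vec pbl;
  for (int iter = 1; iter <= total; ++iter) {
    for (int j = 0; j < W; ++j) {
      double u = R::unif_rand();
      int mv = 0;
      while (mv < nMoves - 1 && u > cumw(mv)) ++mv;
      pedge = edge;
      pbl = bl;
      Model pm = m;
      double lh = apply_move(mv, pedge, pbl, pm, nTip, tune(mv));
      ++proposed(mv); ++winProp(mv);
      if (lh <= LOG_ZERO / 2) continue;
      if (pbl.min() <= 0.0 || pm.shape <= 0.0) continue;
      double pPrior = log_prior(pbl, pm, pr);
      if (!std::isfinite(pPrior)) continue;
      double pLik = priorOnly ? 0.0
        : pruning_loglik(pedge, pbl, nTip, pat, wts, pm, wk);
      if (pLik <= LOG_ZERO / 2) continue;
      double logR = (pLik + pPrior) - (curLik + curPrior) + lh;
      if (logR >= 0.0 || std::log(R::unif_rand()) < logR) {
        edge = pedge; bl = pbl; m = pm;
        curLik = pLik; curPrior = pPrior;
        ++accepted(mv); ++winAcc(mv);
      }
    }
    bool tuneNow = (iter % tuneInterval == 0) &&
      (iter <= burnin || tuneDuringSampling);
    if (tuneNow) {
      for (int mv = 0; mv < nMoves; ++mv) {
        if (tdir[mv] == 0 || winProp(mv) == 0) continue;
        double acc = (double)winAcc(mv) / winProp(mv);
        double d = acc - 0.44;
        if (d > 0.5) d = 0.5;
        if (d < -0.5) d = -0.5;
        tune(mv) *= std::exp(tdir[mv] * d);
        if (tune(mv) < 1e-3) tune(mv) = 1e-3;
        if (tune(mv) > 1e6) tune(mv) = 1e6;
      }
      winProp.zeros(); winAcc.zeros();
    }
    if (iter > burnin && thin > 0) {
      int k = iter - burnin;
      if (k % thin == 0 && si < nSamp) {
        IntegerMatrix eout(edge.n_rows, 2);
        for (arma::uword i = 0; i < edge.n_rows; ++i) {
          eout(i, 0) = edge(i, 0);
          eout(i, 1) = edge(i, 1);
        }
        sampEdges[si] = eout;
        sampBls[si] = NumericVector(bl.begin(), bl.end());
        for (int c = 0; c < 4; ++c) sampPi(si, c) = m.pi(c);
        for (int c = 0; c < 6; ++c) sampEr(si, c) = m.er(c);
        sampShape[si] = m.shape;
        sampPinv[si] = m.pinv;
        sampLP[si] = curLik + curPrior;
        sampIter[si] = iter - burnin;
        ++si;
      }
    }
  }
  return List::create(
    _["edges"] = sampEdges, _["bls"] = sampBls, _["pi"] = sampPi,
    _["er"] = sampEr, _["shape"] = sampShape, _["pinv"] = sampPinv,
    _["logPosterior"] = sampLP, _["iteration"] = sampIter,
    _["proposed"] = IntegerVector(proposed.begin(), proposed.end()),
    _["accepted"] = IntegerVector(accepted.begin(), accepted.end()),
    _["tunings"] = NumericVector(tune.begin(), tune.end()));
}
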