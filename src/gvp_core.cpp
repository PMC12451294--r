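// Compiled core of the GVP-style equivariant denoiser: forward pass and
// analytic backpropagation over one (possibly batched) heterogeneous
// graph. Mirrors the reference R implementation (R/gvp.R) exactly up to
// floating-point summation order; the test-suite cross-checks the two.
//
// Vector channels are stored stacked: a (3n) x dv matrix whose row
// blocks hold the x, y and z components.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::as;

static inline mat sigmoid_m(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// norms over the three stacked blocks -> n x c
static mat sv_norm(const mat& V, uword n, double eps2 = 1e-8) {
  return sqrt(square(V.rows(0, n - 1)) + square(V.rows(n, 2 * n - 1)) +
              square(V.rows(2 * n, 3 * n - 1)) + eps2);
}

// componentwise dot across blocks -> n x c
static mat sv_dot(const mat& A, const mat& B, uword n) {
  mat D = A % B;
  return D.rows(0, n - 1) + D.rows(n, 2 * n - 1) + D.rows(2 * n, 3 * n - 1);
}

// gate a stacked matrix by an n x c invariant gate
static mat sv_scale(const mat& V, const mat& g) {
  return V % join_cols(g, g, g);
}

static mat sv_index(const mat& V, const uvec& idx, uword n) {
  uvec stacked = join_cols(idx, idx + n, idx + 2 * n);
  return V.rows(stacked);
}

static mat scatter_add(const mat& M, const uvec& idx, uword n) {
  mat out(n, M.n_cols, fill::zeros);
  for (uword e = 0; e < idx.n_elem; ++e) out.row(idx(e)) += M.row(e);
  return out;
}

struct LayerCache {
  mat S_in, VinE, VhE, nhE, preE, sigE, smE, gE, VmuE;
  mat inN, VinN, VhN, nhN, preN, sigN, suN, gN, VmuN;
};

struct EdgeParams { mat Wh, Ws, Wg, Wmu; rowvec bs, bg; };
struct NodeParams { mat Uh, Us, Ug, Umu; rowvec bu, bg; };

static EdgeParams edge_params(const List& l) {
  EdgeParams p;
  p.Wh = as<mat>(l["Wh"]); p.Ws = as<mat>(l["Ws"]);
  p.Wg = as<mat>(l["Wg"]); p.Wmu = as<mat>(l["Wmu"]);
  p.bs = as<rowvec>(l["bs"]); p.bg = as<rowvec>(l["bg"]);
  return p;
}

static NodeParams node_params(const List& l) {
  NodeParams p;
  p.Uh = as<mat>(l["Uh"]); p.Us = as<mat>(l["Us"]);
  p.Ug = as<mat>(l["Ug"]); p.Umu = as<mat>(l["Umu"]);
  p.bu = as<rowvec>(l["bu"]); p.bg = as<rowvec>(l["bg"]);
  return p;
}

// [[Rcpp::export(name = ".gvp_core")]]
List gvp_core(List params, int n_layers, int ds, int dv, int n_rbf,
              double rbf_max, const arma::mat& X, const arma::mat& S_raw,
              const arma::ivec& edge_src1, const arma::ivec& edge_dst1,
              const arma::ivec& edge_type1, int n_pharm,
              bool want_grads,
              const arma::mat& eps_true_x, const arma::mat& eps_true_f) {
  const uword n = X.n_rows;
  const uword ne = edge_src1.n_elem;
  uvec src = conv_to<uvec>::from(edge_src1 - 1);
  uvec dst = conv_to<uvec>::from(edge_dst1 - 1);

  // edge geometry
  vec dx(ne), dy(ne), dz(ne), d(ne);
  for (uword e = 0; e < ne; ++e) {
    dx(e) = X(src(e), 0) - X(dst(e), 0);
    dy(e) = X(src(e), 1) - X(dst(e), 1);
    dz(e) = X(src(e), 2) - X(dst(e), 2);
    d(e) = std::sqrt(dx(e) * dx(e) + dy(e) * dy(e) + dz(e) * dz(e) + 1e-12);
  }
  mat U = join_cols(mat(dx / d), mat(dy / d), mat(dz / d));
  mat edge_static(ne, n_rbf + 3, fill::zeros);
  double w = rbf_max / (n_rbf - 1);
  for (int m = 0; m < n_rbf; ++m) {
    double mu = m * w;
    for (uword e = 0; e < ne; ++e) {
      double t = (d(e) - mu) / w;
      edge_static(e, m) = std::exp(-t * t);
    }
  }
  for (uword e = 0; e < ne; ++e) edge_static(e, n_rbf + edge_type1(e) - 1) = 1.0;

  vec deg(n, fill::zeros);
  for (uword e = 0; e < ne; ++e) deg(dst(e)) += 1.0;
  vec inv_deg = 1.0 / clamp(deg, 1.0, datum::inf);

  const List emb = params["emb"];
  const mat embW = as<mat>(emb["W"]);
  const rowvec embb = as<rowvec>(emb["b"]);
  const List layers = params["layers"];
  const List outp = params["out"];
  const vec wv = as<vec>(outp["wv"]);
  const mat Wf = as<mat>(outp["Wf"]);
  const rowvec bf = as<rowvec>(outp["bf"]);

  mat S = S_raw * embW.t();
  S.each_row() += embb;
  mat V(3 * n, dv, fill::zeros);

  std::vector<LayerCache> caches(n_layers);
  std::vector<EdgeParams> eps_l(n_layers);
  std::vector<NodeParams> nps_l(n_layers);

  for (int l = 0; l < n_layers; ++l) {
    List lay = layers[l];
    eps_l[l] = edge_params(lay["edge"]);
    nps_l[l] = node_params(lay["node"]);
    const EdgeParams& pe = eps_l[l];
    const NodeParams& pn = nps_l[l];
    LayerCache& cl = caches[l];

    cl.S_in = S;
    cl.VinE = join_rows(sv_index(V, src, n), U);
    cl.VhE = cl.VinE * pe.Wh.t();
    cl.nhE = sv_norm(cl.VhE, ne);
    const mat Ws_dst = pe.Ws.cols(0, ds - 1);
    const mat Ws_src = pe.Ws.cols(ds, 2 * ds - 1);
    const mat Ws_es = pe.Ws.cols(2 * ds, 2 * ds + n_rbf + 2);
    const mat Ws_nh = pe.Ws.cols(pe.Ws.n_cols - dv, pe.Ws.n_cols - 1);
    mat base_dst = S * Ws_dst.t();
    base_dst.each_row() += pe.bs;
    mat base_src = S * Ws_src.t();
    cl.preE = base_dst.rows(dst) + base_src.rows(src) +
      edge_static * Ws_es.t() + cl.nhE * Ws_nh.t();
    cl.sigE = sigmoid_m(cl.preE);
    cl.smE = cl.preE % cl.sigE;
    mat gpreE = cl.smE * pe.Wg.t();
    gpreE.each_row() += pe.bg;
    cl.gE = sigmoid_m(gpreE);
    cl.VmuE = cl.VhE * pe.Wmu.t();
    mat VmE = sv_scale(cl.VmuE, cl.gE);

    mat s_agg = scatter_add(cl.smE, dst, n);
    s_agg.each_col() %= inv_deg;
    uvec dst3 = join_cols(dst, dst + n, dst + 2 * n);
    mat V_agg = scatter_add(VmE, dst3, 3 * n);
    V_agg.each_col() %= join_cols(inv_deg, inv_deg, inv_deg);

    cl.VinN = join_rows(V, V_agg);
    cl.VhN = cl.VinN * pn.Uh.t();
    cl.nhN = sv_norm(cl.VhN, n);
    cl.inN = join_rows(S, s_agg, cl.nhN);
    cl.preN = cl.inN * pn.Us.t();
    cl.preN.each_row() += pn.bu;
    cl.sigN = sigmoid_m(cl.preN);
    cl.suN = cl.preN % cl.sigN;
    mat gpreN = cl.suN * pn.Ug.t();
    gpreN.each_row() += pn.bg;
    cl.gN = sigmoid_m(gpreN);
    cl.VmuN = cl.VhN * pn.Umu.t();
    mat VuN = sv_scale(cl.VmuN, cl.gN);

    S += cl.suN;
    V += VuN;
  }

  uvec pharm = regspace<uvec>(0, n_pharm - 1);
  mat Sp = S.rows(pharm);
  mat eps_f = Sp * Wf.t();
  eps_f.each_row() += bf;
  vec ex = sv_index(V, pharm, n) * wv;
  mat eps_x(n_pharm, 3);
  for (int k = 0; k < 3; ++k) {
    eps_x.col(k) = ex.subvec(k * n_pharm, (k + 1) * n_pharm - 1);
  }
  if (!eps_x.is_finite() || !eps_f.is_finite()) {
    Rcpp::stop("Denoiser produced non-finite output (training instability).");
  }

  List out = List::create(Rcpp::Named("eps_x") = eps_x,
                          Rcpp::Named("eps_f") = eps_f);
  if (!want_grads) return out;

  // MSE loss over all pharm-node components and its gradient
  const double n_comp = 9.0 * n_pharm;
  mat rx = eps_x - eps_true_x;
  mat rf = eps_f - eps_true_f;
  out["loss"] = (accu(square(rx)) + accu(square(rf))) / n_comp;
  mat d_eps_x_in = (2.0 / n_comp) * rx;
  mat d_eps_f_in = (2.0 / n_comp) * rf;

  // ---- backward ----
  List glayers(n_layers);
  mat dS(n, ds, fill::zeros);
  dS.rows(pharm) = d_eps_f_in * Wf;
  mat gWf = d_eps_f_in.t() * Sp;
  rowvec gbf = sum(d_eps_f_in, 0);

  vec dex(3 * n_pharm);
  for (int k = 0; k < 3; ++k) {
    dex.subvec(k * n_pharm, (k + 1) * n_pharm - 1) = d_eps_x_in.col(k);
  }
  mat Vp = sv_index(V, pharm, n);
  vec gwv = Vp.t() * dex;
  mat dV(3 * n, dv, fill::zeros);
  uvec pharm3 = join_cols(pharm, pharm + n, pharm + 2 * n);
  dV.rows(pharm3) = dex * wv.t();

  for (int l = n_layers - 1; l >= 0; --l) {
    const LayerCache& cl = caches[l];
    const EdgeParams& pe = eps_l[l];
    const NodeParams& pn = nps_l[l];

    // node update backward
    mat dgN = sv_dot(dV, cl.VmuN, n);
    mat dVmuN = sv_scale(dV, cl.gN);
    mat dgpreN = dgN % cl.gN % (1.0 - cl.gN);
    mat gUg = dgpreN.t() * cl.suN;
    rowvec gbg2 = sum(dgpreN, 0);
    mat dsu = dS + dgpreN * pn.Ug;
    mat dpreN = dsu % (cl.sigN % (1.0 + cl.preN % (1.0 - cl.sigN)));
    mat gUs = dpreN.t() * cl.inN;
    rowvec gbu = sum(dpreN, 0);
    mat dcomb = dpreN * pn.Us;
    mat dsvN = dcomb.cols(0, 2 * ds - 1);
    mat dnhN = dcomb.cols(2 * ds, 2 * ds + dv - 1);
    mat dVhN = sv_scale(cl.VhN, dnhN / cl.nhN) + dVmuN * pn.Umu;
    mat gUmu = dVmuN.t() * cl.VhN;
    mat dVinN = dVhN * pn.Uh;
    mat gUh = dVhN.t() * cl.VinN;

    mat dS_node = dS + dsvN.cols(0, ds - 1);
    mat ds_agg = dsvN.cols(ds, 2 * ds - 1);
    mat dV_node = dV + dVinN.cols(0, dv - 1);
    mat dV_agg = dVinN.cols(dv, 2 * dv - 1);

    // aggregation backward
    dV_agg.each_col() %= join_cols(inv_deg, inv_deg, inv_deg);
    uvec dst3 = join_cols(dst, dst + n, dst + 2 * n);
    mat dVmE = dV_agg.rows(dst3);
    mat dsmE = ds_agg.rows(dst);
    dsmE.each_col() %= inv_deg.elem(dst);

    // edge message backward
    mat dgE = sv_dot(dVmE, cl.VmuE, ne);
    mat dVmuE = sv_scale(dVmE, cl.gE);
    mat dgpreE = dgE % cl.gE % (1.0 - cl.gE);
    mat gWg = dgpreE.t() * cl.smE;
    rowvec gbg = sum(dgpreE, 0);
    dsmE += dgpreE * pe.Wg;
    mat dpreE = dsmE % (cl.sigE % (1.0 + cl.preE % (1.0 - cl.sigE)));
    const mat Ws_dst = pe.Ws.cols(0, ds - 1);
    const mat Ws_src = pe.Ws.cols(ds, 2 * ds - 1);
    const mat Ws_nh = pe.Ws.cols(pe.Ws.n_cols - dv, pe.Ws.n_cols - 1);
    mat sc_dst = scatter_add(dpreE, dst, n);
    mat sc_src = scatter_add(dpreE, src, n);
    mat gWs = join_rows(sc_dst.t() * cl.S_in, sc_src.t() * cl.S_in,
                        dpreE.t() * edge_static, dpreE.t() * cl.nhE);
    rowvec gbs = sum(dpreE, 0);
    mat dnhE = dpreE * Ws_nh;
    mat dVhE = sv_scale(cl.VhE, dnhE / cl.nhE) + dVmuE * pe.Wmu;
    mat gWmu = dVmuE.t() * cl.VhE;
    mat dVinE = dVhE * pe.Wh;
    mat gWh = dVhE.t() * cl.VinE;

    dS = dS_node + sc_dst * Ws_dst + sc_src * Ws_src;
    uvec src3 = join_cols(src, src + n, src + 2 * n);
    dV = dV_node + scatter_add(dVinE.cols(0, dv - 1), src3, 3 * n);

    glayers[l] = List::create(
      Rcpp::Named("edge") = List::create(
        Rcpp::Named("Wh") = gWh, Rcpp::Named("Ws") = gWs,
        Rcpp::Named("bs") = gbs, Rcpp::Named("Wg") = gWg,
        Rcpp::Named("bg") = gbg, Rcpp::Named("Wmu") = gWmu),
      Rcpp::Named("node") = List::create(
        Rcpp::Named("Uh") = gUh, Rcpp::Named("Us") = gUs,
        Rcpp::Named("bu") = gbu, Rcpp::Named("Ug") = gUg,
        Rcpp::Named("bg") = gbg2, Rcpp::Named("Umu") = gUmu));
  }

  mat gembW = dS.t() * S_raw;
  rowvec gembb = sum(dS, 0);
  out["grads"] = List::create(
    Rcpp::Named("emb") = List::create(Rcpp::Named("W") = gembW,
                                      Rcpp::Named("b") = gembb),
    Rcpp::Named("layers") = glayers,
    Rcpp::Named("out") = List::create(Rcpp::Named("wv") = gwv,
                                      Rcpp::Named("Wf") = gWf,
                                      Rcpp::Named("bf") = gbf));
  return out;
}
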