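// Dynamic-graph temporal GCN encoder: forward pass and hand-derived
// reverse-mode gradients. The R level owns the attention module and the
// optimiser; this file owns the per-time-step recurrence
// window -> fuse -> diffusion -> dynamic adjacency -> temporal average ->
// top-k -> graph-convolutional GRU, plus the linear softmax heads.

#include <RcppArmadillo.h>
#include <deque>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// Symmetric normalisation with a scale-covariant self-loop:
// B = S + mean(S[S>0]) * I (S has zero diagonal on the dynamic path),
// A_hat = D^-1/2 B D^-1/2. All-zero S yields the identity.
static mat normalize_dyn(const mat& s, vec& d_out, double& npos_out,
                         bool& is_identity) {
  double total = accu(s);
  const uword m = s.n_rows;
  if (total <= 0.0) {
    is_identity = true;
    d_out = ones<vec>(m);
    npos_out = 0.0;
    return eye<mat>(m, m);
  }
  is_identity = false;
  double npos = 0.0;
  for (const double* p = s.memptr(); p != s.memptr() + s.n_elem; ++p)
    if (*p > 0.0) npos += 1.0;
  mat b = s;
  b.diag() += total / npos;
  vec d = sum(b, 1);
  vec dm = 1.0 / sqrt(d);
  d_out = d;
  npos_out = npos;
  b.each_col() %= dm;
  b.each_row() %= dm.t();
  return b;
}

// Row-wise top-k with ties broken toward the lower column index
// (stable sort on descending value), matching the R reference.
static mat topk_rows(const mat& x, int k, mat& keep_mask) {
  const uword m = x.n_rows, nc = x.n_cols;
  keep_mask.zeros(m, nc);
  if ((uword)k >= nc) {
    keep_mask.ones();
    return x;
  }
  mat out(m, nc, fill::zeros);
  std::vector<uword> idx(nc);
  for (uword i = 0; i < m; ++i) {
    for (uword j = 0; j < nc; ++j) idx[j] = j;
    const rowvec row = x.row(i);
    std::stable_sort(idx.begin(), idx.end(),
                     [&row](uword a, uword b) { return row[a] > row[b]; });
    for (int j = 0; j < k; ++j) {
      out(i, idx[j]) = row[idx[j]];
      keep_mask(i, idx[j]) = 1.0;
    }
  }
  return out;
}

struct Cache {
  cube I, H, U, R, C, An, DE1, DE2, T, S, Keep;
  mat d;
  vec npos;
  std::vector<char> idty;
};

struct Grads {
  mat th1, th2, wu, wr, wc;
  rowvec bu, br, bc;
  mat dxp;
};

// Shared forward pass. With `grad` true, fills the cache; with `collect`
// true, accumulates the sparsified adjacency and its max row edge count.
static mat encode_forward(const mat& xp, const mat& th1, const mat& th2,
                          const mat& wu, const mat& wr, const mat& wc,
                          const rowvec& bu, const rowvec& br, const rowvec& bc,
                          const mat& apre, int K, int navg, double alpha,
                          int kedges, int dh, bool static_graph,
                          bool grad, Cache& cc, bool collect,
                          mat& adj_sum, int& max_row_edges) {
  const int n = xp.n_rows, m = xp.n_cols;
  const int f = K + dh;
  mat h(m, dh, fill::zeros);
  std::deque<mat> buffer;
  if (grad) {
    cc.I.set_size(m, f, n);
    cc.H.set_size(m, dh, n + 1);
    cc.H.slice(0).zeros();
    cc.U.set_size(m, dh, n); cc.R.set_size(m, dh, n); cc.C.set_size(m, dh, n);
    cc.An.set_size(m, m, n);
    if (!static_graph) {
      cc.DE1.set_size(m, th1.n_cols, n); cc.DE2.set_size(m, th2.n_cols, n);
      cc.T.set_size(m, m, n); cc.S.set_size(m, m, n); cc.Keep.set_size(m, m, n);
      cc.d.set_size(m, n); cc.npos.set_size(n);
      cc.idty.assign(n, 0);
    }
  }
  mat an_static;
  if (static_graph) an_static = apre;
  if (collect) { adj_sum.zeros(m, m); max_row_edges = 0; }
  // preallocated per-step workspaces (assignment into a correctly sized
  // arma::mat re-uses its memory)
  const int fp = th1.n_cols;
  mat it(m, f, fill::zeros), an, ai(m, f), de1(m, fp), de2(m, fp),
      tt(m, m), et(m, m), mt(m, m), s(m, m), keep(m, m),
      anit(m, f), anh(m, dh), anrh(m, dh),
      pu(m, dh), pr(m, dh), u(m, dh), r(m, dh), pc(m, dh), c(m, dh),
      hnew(m, dh);
  const mat wu_i = wu.rows(0, f - 1), wu_h = wu.rows(f, f + dh - 1);
  const mat wr_i = wr.rows(0, f - 1), wr_h = wr.rows(f, f + dh - 1);
  const mat wc_i = wc.rows(0, f - 1), wc_h = wc.rows(f, f + dh - 1);
  for (int t = 0; t < n; ++t) {
    // dynamic node features I_t = [window^T | h]
    it.cols(0, K - 1).zeros();
    for (int j = 0; j < K; ++j) {
      int tm = t - K + 1 + j;
      if (tm >= 0) it.col(j) = xp.row(tm).t();
    }
    it.cols(K, f - 1) = h;
    if (static_graph) {
      an = an_static;
    } else {
      ai = apre * it;
      de1 = tanh(alpha * (ai * th1));
      de2 = tanh(alpha * (ai * th2));
      tt = tanh(alpha * (de1 * de2.t() - de2 * de1.t()));
      et = tt;
      et.elem(find(tt < 0)).zeros();
      buffer.push_back(et);
      if ((int)buffer.size() > navg) buffer.pop_front();
      mt.zeros();
      for (const mat& e : buffer) mt += e;
      mt /= (double)buffer.size();
      s = topk_rows(mt, kedges, keep);
      vec d; double npos; bool idty;
      an = normalize_dyn(s, d, npos, idty);
      if (collect) {
        adj_sum += s;
        int nnz = (int)max(sum(conv_to<mat>::from(s != 0), 1));
        if (nnz > max_row_edges) max_row_edges = nnz;
      }
      if (grad) {
        cc.DE1.slice(t) = de1; cc.DE2.slice(t) = de2;
        cc.T.slice(t) = tt; cc.S.slice(t) = s; cc.Keep.slice(t) = keep;
        cc.d.col(t) = d; cc.npos(t) = npos; cc.idty[t] = idty ? 1 : 0;
      }
    }
    // gates: A[I|h] W = (A I) W_top + (A h) W_bottom; A h is the last
    // dh columns of A I because I_t already ends in h
    anit = an * it;
    anh = anit.cols(K, f - 1);
    pu = anit * wu_i + anh * wu_h; pu.each_row() += bu;
    pr = anit * wr_i + anh * wr_h; pr.each_row() += br;
    u = 1.0 / (1.0 + exp(-pu));
    r = 1.0 / (1.0 + exp(-pr));
    anrh = an * (r % h);
    pc = anit * wc_i + anrh * wc_h; pc.each_row() += bc;
    c = tanh(pc);
    hnew = u % h + (1.0 - u) % c;
    if (grad) {
      cc.I.slice(t) = it; cc.An.slice(t) = an;
      cc.U.slice(t) = u; cc.R.slice(t) = r; cc.C.slice(t) = c;
      cc.H.slice(t + 1) = hnew;
    }
    h = hnew;
  }
  return h;
}

// Reverse pass given dL/dh_N. Mirrors encode_forward step by step.
static Grads encode_backward(const mat& xp, const mat& th1, const mat& th2,
                             const mat& wu, const mat& wr, const mat& wc,
                             const mat& apre, int K, int navg, double alpha,
                             int dh, bool static_graph, const Cache& cc,
                             const mat& d_hn) {
  const int n = xp.n_rows, m = xp.n_cols;
  const int f = K + dh;
  Grads g;
  g.th1.zeros(size(th1)); g.th2.zeros(size(th2));
  g.wu.zeros(size(wu)); g.wr.zeros(size(wr)); g.wc.zeros(size(wc));
  g.bu.zeros(wu.n_cols); g.br.zeros(wr.n_cols); g.bc.zeros(wc.n_cols);
  g.dxp.zeros(n, m);
  mat dh_next = d_hn;
  std::deque<mat> pend;   // dM_s / count_s for s in [t, t + navg - 1]
  const mat wu_i = wu.rows(0, f - 1), wu_h = wu.rows(f, f + dh - 1);
  const mat wr_i = wr.rows(0, f - 1), wr_h = wr.rows(f, f + dh - 1);
  const mat wc_i = wc.rows(0, f - 1), wc_h = wc.rows(f, f + dh - 1);
  const int m_ = xp.n_cols;
  mat anit(m_, f), anrh(m_, dh), rh(m_, dh), du(m_, dh), dc(m_, dh),
      dhprev(m_, dh), dpc(m_, dh), dpr(m_, dh), dpu(m_, dh),
      dan(m_, m_), di(m_, f), t1(m_, dh), dr(m_, dh), drh(m_, dh);
  for (int t = n - 1; t >= 0; --t) {
    const mat& it = cc.I.slice(t);
    const mat& hprev = cc.H.slice(t);
    const mat& u = cc.U.slice(t);
    const mat& r = cc.R.slice(t);
    const mat& c = cc.C.slice(t);
    const mat& an = cc.An.slice(t);
    rh = r % hprev;
    anit = an * it;                       // last dh cols equal an * hprev
    anrh = an * rh;
    du = dh_next % (hprev - c);
    dc = dh_next % (1.0 - u);
    dhprev = dh_next % u;
    // candidate gate: P_c = A [I | r%h] W_c + b_c
    dpc = dc % (1.0 - c % c);
    g.wc.rows(0, f - 1) += anit.t() * dpc;
    g.wc.rows(f, f + dh - 1) += anrh.t() * dpc;
    g.bc += sum(dpc, 0);
    dan = dpc * (it * wc_i + rh * wc_h).t();
    t1 = an.t() * dpc;
    di = t1 * wc_i.t();
    drh = t1 * wc_h.t();
    dr = drh % hprev;
    dhprev += drh % r;
    // reset gate
    dpr = dr % r % (1.0 - r);
    g.wr.rows(0, f - 1) += anit.t() * dpr;
    g.wr.rows(f, f + dh - 1) += anit.cols(K, f - 1).t() * dpr;
    g.br += sum(dpr, 0);
    dan += dpr * (it * wr_i + hprev * wr_h).t();
    t1 = an.t() * dpr;
    di += t1 * wr_i.t();
    dhprev += t1 * wr_h.t();
    // update gate
    dpu = du % u % (1.0 - u);
    g.wu.rows(0, f - 1) += anit.t() * dpu;
    g.wu.rows(f, f + dh - 1) += anit.cols(K, f - 1).t() * dpu;
    g.bu += sum(dpu, 0);
    dan += dpu * (it * wu_i + hprev * wu_h).t();
    t1 = an.t() * dpu;
    di += t1 * wu_i.t();
    dhprev += t1 * wu_h.t();
    if (!static_graph) {
      // through A_hat = D^-1/2 (S + sI) D^-1/2 with s = sum(S)/npos
      mat dmt(m, m, fill::zeros);
      if (!cc.idty[t]) {
        vec d = cc.d.col(t);
        vec dmv = 1.0 / sqrt(d);
        mat ga = dan % an;
        vec dd = -(sum(ga, 1) + sum(ga, 0).t()) / (2.0 * d);
        mat db = dan;
        db.each_col() %= dmv;
        db.each_row() %= dmv.t();
        db.each_col() += dd;
        mat ppos = conv_to<mat>::from(cc.S.slice(t) > 0);
        mat ds = db + (trace(db) / cc.npos(t)) * ppos;
        dmt = ds % cc.Keep.slice(t);
      }
      // temporal average: M_t averages the last min(navg, t+1) matrices
      double cnt = std::min(navg, t + 1);
      pend.push_front(dmt / cnt);
      if ((int)pend.size() > navg) pend.pop_back();
      mat de_t(m, m, fill::zeros);
      for (const mat& p : pend) de_t += p;
      const mat& tt = cc.T.slice(t);
      mat dt = de_t % conv_to<mat>::from(tt > 0);          // ReLU
      mat drm = alpha * (dt % (1.0 - tt % tt));            // tanh(alpha .)
      mat skew = drm - drm.t();
      const mat& de1 = cc.DE1.slice(t);
      const mat& de2 = cc.DE2.slice(t);
      mat dde1 = skew * de2;      // (G - G') DE2
      mat dde2 = -skew * de1;     // (G' - G) DE1
      mat ddf1 = alpha * (dde1 % (1.0 - de1 % de1));
      mat ddf2 = alpha * (dde2 % (1.0 - de2 % de2));
      mat ai = apre * it;
      g.th1 += ai.t() * ddf1;
      g.th2 += ai.t() * ddf2;
      di += apre.t() * (ddf1 * th1.t() + ddf2 * th2.t());
    }
    // I_t = [window^T | h_{t-1}]
    for (int j = 0; j < K; ++j) {
      int tm = t - K + 1 + j;
      if (tm >= 0) g.dxp.row(tm) += di.col(j).t();
    }
    dhprev += di.cols(K, f - 1);
    dh_next = dhprev;
  }
  return g;
}

static mat get_mat(const List& params, const char* nm) {
  return Rcpp::as<mat>(params[nm]);
}

// [[Rcpp::export]]
List dtgcn_encode_cpp(const arma::mat& xp, const List& params,
                      const arma::mat& apre, int K, int navg, double alpha,
                      int kedges, int dh, bool static_graph, bool collect) {
  Cache cc;
  mat adj_sum;
  int max_edges = 0;
  rowvec bu = get_mat(params, "bu").row(0);
  rowvec br = get_mat(params, "br").row(0);
  rowvec bc = get_mat(params, "bc").row(0);
  mat h = encode_forward(xp, get_mat(params, "theta1"), get_mat(params, "theta2"),
                         get_mat(params, "Wu"), get_mat(params, "Wr"),
                         get_mat(params, "Wc"), bu, br, bc, apre, K, navg,
                         alpha, kedges, dh, static_graph, false, cc,
                         collect && !static_graph, adj_sum, max_edges);
  List out = List::create(Named("hidden") = h);
  if (collect) {
    if (static_graph) {
      out["mean_adjacency"] = R_NilValue;   // caller substitutes the static graph
      out["max_row_edges"] = R_NilValue;
    } else {
      out["mean_adjacency"] = adj_sum / (double)xp.n_rows;
      out["max_row_edges"] = max_edges;
    }
  }
  return out;
}

// One clip: forward, softmax heads, cross-entropy, full backward.
// heads: list of list(W = (M*dh) x C, b = 1 x C, y = 1-based class).
// [[Rcpp::export]]
List dtgcn_train_step_cpp(const arma::mat& xp, const List& params,
                          const arma::mat& apre, int K, int navg,
                          double alpha, int kedges, int dh,
                          bool static_graph, const List& heads) {
  Cache cc;
  mat adj_sum;
  int max_edges = 0;
  mat th1 = get_mat(params, "theta1"), th2 = get_mat(params, "theta2");
  mat wu = get_mat(params, "Wu"), wr = get_mat(params, "Wr"),
      wc = get_mat(params, "Wc");
  rowvec bu = get_mat(params, "bu").row(0);
  rowvec br = get_mat(params, "br").row(0);
  rowvec bc = get_mat(params, "bc").row(0);
  mat h = encode_forward(xp, th1, th2, wu, wr, wc, bu, br, bc, apre, K,
                         navg, alpha, kedges, dh, static_graph, true, cc,
                         false, adj_sum, max_edges);
  const int m = xp.n_cols;
  vec hvec = vectorise(h);
  mat d_hn(m, dh, fill::zeros);
  const int nheads = heads.size();
  Rcpp::NumericVector ce(nheads);
  List probs(nheads), head_grads(nheads);
  for (int i = 0; i < nheads; ++i) {
    List hd = heads[i];
    mat w = Rcpp::as<mat>(hd["W"]);
    rowvec b = Rcpp::as<mat>(hd["b"]).row(0);
    int y = Rcpp::as<int>(hd["y"]);   // 1-based
    rowvec logits = hvec.t() * w + b;
    rowvec z = logits - logits.max();
    rowvec p = exp(z);
    p /= accu(p);
    double py = std::max(p(y - 1), 1e-12);
    ce[i] = -std::log(py);
    rowvec dlog = p;
    dlog(y - 1) -= 1.0;
    head_grads[i] = List::create(Named("W") = mat(hvec * dlog),
                                 Named("b") = mat(dlog));
    d_hn += reshape(w * dlog.t(), m, dh);
    probs[i] = Rcpp::NumericVector(p.begin(), p.end());
  }
  Grads g = encode_backward(xp, th1, th2, wu, wr, wc, apre, K, navg, alpha,
                            dh, static_graph, cc, d_hn);
  List grads = List::create(
      Named("theta1") = g.th1, Named("theta2") = g.th2,
      Named("Wu") = g.wu, Named("Wr") = g.wr, Named("Wc") = g.wc,
      Named("bu") = mat(g.bu), Named("br") = mat(g.br),
      Named("bc") = mat(g.bc), Named("heads") = head_grads);
  return List::create(Named("hidden") = h, Named("ce") = ce,
                      Named("probs") = probs, Named("grads") = grads,
                      Named("dxprime") = g.dxp);
}
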