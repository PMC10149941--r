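// Dual-branch multi-channel 1-D CNN with soft (MSE between task vectors)
// and hard (concatenated shared layer) parameter sharing.
//
// Layout per task branch:
//   embedding (V x D) -> per-channel conv1d (kernel k_c, F filters) ->
//   activation -> global max pooling -> dropout -> [dense(U) -> activation]
//   -> channel concat -> [aux dense(A) concat] = task vector.
// Shared layer = concat of task vectors; one softmax head per task reads
// the full shared layer.
//
// Gradients are exact analytic backprop (verified against finite
// differences in the test suite). All dropout randomness flows through an
// explicit integer seed so training is bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

constexpr double LOG_EPS = 1e-7;

struct Config {
  int n_tasks;       // 1 (single-task baseline) or 2
  int L;             // sequence length
  int D;             // embedding dim
  int F;             // filters per channel
  int U;             // dense units per channel (ignored if !use_dense)
  bool use_dense;    // MTL branches have a dense layer; the baseline does not
  std::vector<int> kernels;
  int act;           // 0 = relu, 1 = leaky relu
  double leaky_alpha;
  double dropout_p;
  double l1, l2;
  double lambda;     // weight of the soft-share MSE term
  int aux_units;     // 0 = no auxiliary input
  int aux_dim;       // number of lexicon categories
  int n_classes;
};

Config parse_config(const List& cfg) {
  Config c;
  c.n_tasks = as<int>(cfg["n_tasks"]);
  c.L = as<int>(cfg["max_len"]);
  c.D = as<int>(cfg["embed_dim"]);
  c.F = as<int>(cfg["n_filters"]);
  c.U = as<int>(cfg["dense_units"]);
  c.use_dense = as<bool>(cfg["use_dense"]);
  c.kernels = as<std::vector<int>>(cfg["kernel_sizes"]);
  c.act = as<int>(cfg["act"]);
  c.leaky_alpha = as<double>(cfg["leaky_alpha"]);
  c.dropout_p = as<double>(cfg["dropout_p"]);
  c.l1 = as<double>(cfg["l1_factor"]);
  c.l2 = as<double>(cfg["l2_factor"]);
  c.lambda = as<double>(cfg["soft_share_weight"]);
  c.aux_units = as<int>(cfg["aux_units"]);
  c.aux_dim = as<int>(cfg["aux_dim"]);
  c.n_classes = as<int>(cfg["n_classes"]);
  return c;
}

int task_vec_width(const Config& c) {
  int w = static_cast<int>(c.kernels.size()) * (c.use_dense ? c.U : c.F);
  return w + c.aux_units;
}

// Parameter tensor names in canonical order; mirrored on the R side.
std::vector<std::string> param_names(const Config& c) {
  std::vector<std::string> nm;
  for (int t = 1; t <= c.n_tasks; ++t) {
    std::string ts = std::to_string(t);
    nm.push_back("embed_" + ts);
    for (size_t ch = 0; ch < c.kernels.size(); ++ch) {
      std::string cs = std::to_string(ch + 1);
      nm.push_back("conv_W_" + ts + "_" + cs);
      nm.push_back("conv_b_" + ts + "_" + cs);
      if (c.use_dense) {
        nm.push_back("dense_W_" + ts + "_" + cs);
        nm.push_back("dense_b_" + ts + "_" + cs);
      }
    }
    if (c.aux_units > 0) {
      nm.push_back("aux_W_" + ts);
      nm.push_back("aux_b_" + ts);
    }
  }
  for (int t = 1; t <= c.n_tasks; ++t) {
    nm.push_back("head_W_" + std::to_string(t));
    nm.push_back("head_b_" + std::to_string(t));
  }
  return nm;
}

bool is_regularized(const std::string& nm) {
  // L1/L2 weight decay on convolution and fully connected kernels only
  // (not embeddings, biases, or softmax heads).
  return nm.rfind("conv_W", 0) == 0 || nm.rfind("dense_W", 0) == 0 ||
         nm.rfind("aux_W", 0) == 0;
}

typedef std::map<std::string, arma::mat> ParamMap;

ParamMap list_to_params(const List& lst, const std::vector<std::string>& names) {
  ParamMap p;
  for (const auto& nm : names) {
    if (!lst.containsElementNamed(nm.c_str()))
      stop("missing parameter tensor '%s'", nm.c_str());
    p[nm] = as<arma::mat>(lst[nm]);
  }
  return p;
}

List params_to_list(const ParamMap& p, const std::vector<std::string>& names) {
  List out;
  for (const auto& nm : names) out[nm] = wrap(p.at(nm));
  return out;
}

arma::mat activate(const arma::mat& x, const Config& c) {
  if (c.act == 0) return arma::clamp(x, 0.0, arma::datum::inf);
  arma::mat y = x;
  y.for_each([&](double& v) { if (v < 0) v *= c.leaky_alpha; });
  return y;
}

arma::mat activate_grad(const arma::mat& pre, const Config& c) {
  arma::mat g(pre.n_rows, pre.n_cols);
  if (c.act == 0) {
    g = arma::conv_to<arma::mat>::from(pre > 0);
  } else {
    g.fill(c.leaky_alpha);
    g.elem(arma::find(pre > 0)).fill(1.0);
  }
  return g;
}

// Cached per-branch forward state needed for backprop.
struct BranchCache {
  arma::mat Xe;                       // (B*L) x D embedded input
  std::vector<arma::mat> conv_pre;    // (B*Lc) x F pre-activation
  std::vector<arma::umat> pool_arg;   // B x F argmax row index into conv_pre
  std::vector<arma::mat> pooled_drop; // B x F after dropout
  std::vector<arma::mat> drop_mask;   // B x F inverted-dropout mask
  std::vector<arma::mat> dense_pre;   // B x U
  std::vector<arma::mat> dense_out;   // B x U (or pooled_drop if no dense)
  arma::mat aux_pre, aux_out;         // B x A
  arma::mat task_vec;                 // B x width
};

arma::mat embed_rows(const arma::mat& E, const arma::imat& X) {
  const int B = X.n_rows, L = X.n_cols;
  arma::mat Xe(B * L, E.n_cols);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < L; ++t)
      Xe.row(b * L + t) = E.row(X(b, t));
  return Xe;
}

BranchCache branch_forward(const ParamMap& P, const Config& c, int task,
                           const arma::imat& X, const arma::mat* AUX,
                           bool training, std::mt19937& rng) {
  const int B = X.n_rows;
  const std::string ts = std::to_string(task);
  BranchCache bc;
  bc.Xe = embed_rows(P.at("embed_" + ts), X);

  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const int nch = static_cast<int>(c.kernels.size());
  std::vector<arma::mat> chan_out(nch);

  for (int ch = 0; ch < nch; ++ch) {
    const int k = c.kernels[ch], Lc = c.L - k + 1;
    const std::string cs = std::to_string(ch + 1);
    const arma::mat& W = P.at("conv_W_" + ts + "_" + cs); // (k*D) x F
    const arma::mat& bb = P.at("conv_b_" + ts + "_" + cs); // 1 x F

    arma::mat C(B * Lc, c.F, arma::fill::zeros);
    for (int o = 0; o < k; ++o) {
      arma::mat Po = bc.Xe * W.rows(o * c.D, (o + 1) * c.D - 1);
      for (int b = 0; b < B; ++b)
        C.rows(b * Lc, (b + 1) * Lc - 1) +=
            Po.rows(b * c.L + o, b * c.L + o + Lc - 1);
    }
    C.each_row() += bb;
    bc.conv_pre.push_back(C);
    arma::mat A = activate(C, c);

    arma::mat pooled(B, c.F);
    arma::umat argidx(B, c.F);
    for (int b = 0; b < B; ++b) {
      arma::mat blk = A.rows(b * Lc, (b + 1) * Lc - 1);
      for (int f = 0; f < c.F; ++f) {
        arma::uword am = blk.col(f).index_max();
        pooled(b, f) = blk(am, f);
        argidx(b, f) = b * Lc + am;
      }
    }
    bc.pool_arg.push_back(argidx);

    arma::mat mask(B, c.F, arma::fill::ones);
    if (training && c.dropout_p > 0) {
      for (arma::uword i = 0; i < mask.n_elem; ++i)
        mask(i) = unif(rng) < c.dropout_p ? 0.0 : 1.0 / (1.0 - c.dropout_p);
    }
    bc.drop_mask.push_back(mask);
    arma::mat pd = pooled % mask;
    bc.pooled_drop.push_back(pd);

    if (c.use_dense) {
      arma::mat dpre = pd * P.at("dense_W_" + ts + "_" + cs);
      dpre.each_row() += P.at("dense_b_" + ts + "_" + cs);
      bc.dense_pre.push_back(dpre);
      bc.dense_out.push_back(activate(dpre, c));
    } else {
      bc.dense_pre.push_back(arma::mat());
      bc.dense_out.push_back(pd);
    }
    chan_out[ch] = bc.dense_out.back();
  }

  arma::mat v = chan_out[0];
  for (int ch = 1; ch < nch; ++ch) v = arma::join_rows(v, chan_out[ch]);

  if (c.aux_units > 0) {
    if (AUX == nullptr) stop("auxiliary input expected but not supplied");
    bc.aux_pre = (*AUX) * P.at("aux_W_" + ts);
    bc.aux_pre.each_row() += P.at("aux_b_" + ts);
    bc.aux_out = activate(bc.aux_pre, c);
    v = arma::join_rows(v, bc.aux_out);
  }
  bc.task_vec = v;
  return bc;
}

arma::mat softmax_rows(const arma::mat& z) {
  arma::mat e = arma::exp(z.each_col() - arma::max(z, 1));
  return e.each_col() / arma::sum(e, 1);
}

struct ForwardResult {
  std::vector<BranchCache> branches;
  arma::mat shared;
  std::vector<arma::mat> logits, probs;
};

ForwardResult full_forward(const ParamMap& P, const Config& c,
                           const std::vector<arma::imat>& X,
                           const std::vector<const arma::mat*>& AUX,
                           bool training, std::mt19937& rng) {
  ForwardResult fr;
  for (int t = 0; t < c.n_tasks; ++t)
    fr.branches.push_back(
        branch_forward(P, c, t + 1, X[t], AUX[t], training, rng));
  fr.shared = fr.branches[0].task_vec;
  for (int t = 1; t < c.n_tasks; ++t)
    fr.shared = arma::join_rows(fr.shared, fr.branches[t].task_vec);
  for (int t = 0; t < c.n_tasks; ++t) {
    std::string ts = std::to_string(t + 1);
    arma::mat z = fr.shared * P.at("head_W_" + ts);
    z.each_row() += P.at("head_b_" + ts);
    fr.logits.push_back(z);
    fr.probs.push_back(softmax_rows(z));
  }
  return fr;
}

double cce_loss(const arma::mat& probs, const arma::ivec& y) {
  double s = 0;
  for (arma::uword b = 0; b < probs.n_rows; ++b)
    s += -std::log(std::max(probs(b, y(b)), LOG_EPS));
  return s / probs.n_rows;
}

double reg_penalty(const ParamMap& P, const Config& c,
                   const std::vector<std::string>& names) {
  double r = 0;
  for (const auto& nm : names)
    if (is_regularized(nm)) {
      const arma::mat& W = P.at(nm);
      r += c.l1 * arma::accu(arma::abs(W)) + c.l2 * arma::accu(W % W);
    }
  return r;
}

struct LossParts {
  double total_data;  // sum of CCE terms + lambda * soft-share MSE
  double reg;
  std::vector<double> cce;
  double mse;
};

// Forward + (optionally) analytic gradients for one batch.
LossParts forward_backward(const ParamMap& P, const Config& c,
                           const std::vector<arma::imat>& X,
                           const std::vector<arma::ivec>& Y,
                           const std::vector<const arma::mat*>& AUX,
                           bool training, std::mt19937& rng,
                           ParamMap* grads,
                           const std::vector<std::string>& names) {
  ForwardResult fr = full_forward(P, c, X, AUX, training, rng);
  const int B = X[0].n_rows;
  const int W = task_vec_width(c);

  LossParts lp;
  lp.total_data = 0;
  lp.mse = 0;
  for (int t = 0; t < c.n_tasks; ++t) {
    lp.cce.push_back(cce_loss(fr.probs[t], Y[t]));
    lp.total_data += lp.cce.back();
  }
  if (c.n_tasks == 2) {
    arma::mat diff = fr.branches[0].task_vec - fr.branches[1].task_vec;
    lp.mse = arma::accu(diff % diff) / (static_cast<double>(B) * W);
    lp.total_data += c.lambda * lp.mse;
  }
  lp.reg = reg_penalty(P, c, names);
  if (grads == nullptr) return lp;

  ParamMap& G = *grads;
  for (const auto& nm : names)
    G[nm] = arma::mat(P.at(nm).n_rows, P.at(nm).n_cols, arma::fill::zeros);

  // Softmax heads. d(logits) = (p - onehot(y)) / B for mean CCE.
  arma::mat dShared(B, c.n_tasks * W, arma::fill::zeros);
  for (int t = 0; t < c.n_tasks; ++t) {
    std::string ts = std::to_string(t + 1);
    arma::mat dz = fr.probs[t];
    for (int b = 0; b < B; ++b) dz(b, Y[t](b)) -= 1.0;
    dz /= B;
    G["head_W_" + ts] = fr.shared.t() * dz;
    G["head_b_" + ts] = arma::sum(dz, 0);
    dShared += dz * P.at("head_W_" + ts).t();
  }

  const int nch = static_cast<int>(c.kernels.size());
  for (int t = 0; t < c.n_tasks; ++t) {
    std::string ts = std::to_string(t + 1);
    BranchCache& bc = fr.branches[t];
    arma::mat dv = dShared.cols(t * W, (t + 1) * W - 1);
    if (c.n_tasks == 2 && c.lambda > 0) {
      arma::mat diff = fr.branches[0].task_vec - fr.branches[1].task_vec;
      double coef = c.lambda * 2.0 / (static_cast<double>(B) * W);
      dv += (t == 0 ? coef : -coef) * diff;
    }

    arma::mat dXe(B * c.L, c.D, arma::fill::zeros);
    int col0 = 0;
    const int chan_w = c.use_dense ? c.U : c.F;
    for (int ch = 0; ch < nch; ++ch) {
      std::string cs = std::to_string(ch + 1);
      const int k = c.kernels[ch], Lc = c.L - k + 1;
      arma::mat dH = dv.cols(col0, col0 + chan_w - 1);
      col0 += chan_w;

      arma::mat dPooledDrop;
      if (c.use_dense) {
        arma::mat dpre = dH % activate_grad(bc.dense_pre[ch], c);
        G["dense_W_" + ts + "_" + cs] = bc.pooled_drop[ch].t() * dpre;
        G["dense_b_" + ts + "_" + cs] = arma::sum(dpre, 0);
        dPooledDrop = dpre * P.at("dense_W_" + ts + "_" + cs).t();
      } else {
        dPooledDrop = dH;
      }
      arma::mat dPooled = dPooledDrop % bc.drop_mask[ch];

      arma::mat dA(B * Lc, c.F, arma::fill::zeros);
      for (int b = 0; b < B; ++b)
        for (int f = 0; f < c.F; ++f)
          dA(bc.pool_arg[ch](b, f), f) += dPooled(b, f);
      arma::mat dC = dA % activate_grad(bc.conv_pre[ch], c);

      const arma::mat& Wc = P.at("conv_W_" + ts + "_" + cs);
      arma::mat& dWc = G["conv_W_" + ts + "_" + cs];
      G["conv_b_" + ts + "_" + cs] = arma::sum(dC, 0);
      for (int o = 0; o < k; ++o) {
        arma::mat Xsub(B * Lc, c.D);
        for (int b = 0; b < B; ++b)
          Xsub.rows(b * Lc, (b + 1) * Lc - 1) =
              bc.Xe.rows(b * c.L + o, b * c.L + o + Lc - 1);
        dWc.rows(o * c.D, (o + 1) * c.D - 1) = Xsub.t() * dC;
        arma::mat dXsub = dC * Wc.rows(o * c.D, (o + 1) * c.D - 1).t();
        for (int b = 0; b < B; ++b)
          dXe.rows(b * c.L + o, b * c.L + o + Lc - 1) +=
              dXsub.rows(b * Lc, (b + 1) * Lc - 1);
      }
    }

    if (c.aux_units > 0) {
      arma::mat dAuxOut = dv.cols(col0, col0 + c.aux_units - 1);
      arma::mat dpre = dAuxOut % activate_grad(bc.aux_pre, c);
      G["aux_W_" + ts] = AUX[t]->t() * dpre;
      G["aux_b_" + ts] = arma::sum(dpre, 0);
    }

    arma::mat& dE = G["embed_" + ts];
    for (int b = 0; b < B; ++b)
      for (int tt = 0; tt < c.L; ++tt)
        dE.row(X[t](b, tt)) += dXe.row(b * c.L + tt);
  }

  // Weight-decay gradients on regularized kernels.
  for (const auto& nm : names)
    if (is_regularized(nm)) {
      const arma::mat& Wm = P.at(nm);
      G[nm] += c.l1 * arma::sign(Wm) + 2.0 * c.l2 * Wm;
    }
  return lp;
}

std::vector<arma::imat> parse_X(const List& Xlist, int n_tasks) {
  std::vector<arma::imat> X;
  for (int t = 0; t < n_tasks; ++t)
    X.push_back(as<arma::imat>(Xlist[t]));
  return X;
}

std::vector<const arma::mat*> parse_aux(const List& AuxList, int n_tasks,
                                        std::vector<arma::mat>& store) {
  std::vector<const arma::mat*> out(n_tasks, nullptr);
  store.resize(n_tasks);
  if (AuxList.size() == 0) return out;
  if (AuxList.size() < n_tasks)
    stop("auxiliary input list is shorter than the number of tasks");
  for (int t = 0; t < n_tasks; ++t) {
    RObject el = AuxList[t];
    if (!el.isNULL()) {
      store[t] = as<arma::mat>(el);
      out[t] = &store[t];
    }
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_param_names(List cfg) {
  Config c = parse_config(cfg);
  std::vector<std::string> nm = param_names(c);
  return List::create(_["names"] = wrap(nm),
                      _["task_vec_width"] = task_vec_width(c));
}

// [[Rcpp::export]]
List cpp_forward(List params, List cfg, List X, List AUX, bool training,
                 int dropout_seed) {
  Config c = parse_config(cfg);
  std::vector<std::string> names = param_names(c);
  ParamMap P = list_to_params(params, names);
  std::vector<arma::imat> Xv = parse_X(X, c.n_tasks);
  std::vector<arma::mat> aux_store;
  std::vector<const arma::mat*> AUXv = parse_aux(AUX, c.n_tasks, aux_store);
  std::mt19937 rng(static_cast<unsigned int>(dropout_seed));
  ForwardResult fr = full_forward(P, c, Xv, AUXv, training, rng);
  List probs(c.n_tasks), vecs(c.n_tasks);
  for (int t = 0; t < c.n_tasks; ++t) {
    probs[t] = wrap(fr.probs[t]);
    vecs[t] = wrap(fr.branches[t].task_vec);
  }
  return List::create(_["probs"] = probs, _["task_vecs"] = vecs,
                      _["shared"] = wrap(fr.shared));
}

// [[Rcpp::export]]
List cpp_loss_and_grads(List params, List cfg, List X, List Y, List AUX,
                        bool training, int dropout_seed,
                        bool compute_grads) {
  Config c = parse_config(cfg);
  std::vector<std::string> names = param_names(c);
  ParamMap P = list_to_params(params, names);
  std::vector<arma::imat> Xv = parse_X(X, c.n_tasks);
  std::vector<arma::ivec> Yv;
  for (int t = 0; t < c.n_tasks; ++t) Yv.push_back(as<arma::ivec>(Y[t]));
  std::vector<arma::mat> aux_store;
  std::vector<const arma::mat*> AUXv = parse_aux(AUX, c.n_tasks, aux_store);
  std::mt19937 rng(static_cast<unsigned int>(dropout_seed));

  ParamMap G;
  LossParts lp = forward_backward(P, c, Xv, Yv, AUXv, training, rng,
                                  compute_grads ? &G : nullptr, names);
  List out = List::create(
      _["loss_data"] = lp.total_data, _["loss_reg"] = lp.reg,
      _["loss_total"] = lp.total_data + lp.reg,
      _["cce"] = wrap(lp.cce), _["soft_share_mse"] = lp.mse);
  if (compute_grads) out["grads"] = params_to_list(G, names);
  return out;
}

// One full epoch of mini-batch Adam over rows in stored order (no
// shuffling: batch composition is identical across epochs, preserving
// positive-with-positive task alignment).
// [[Rcpp::export]]
List cpp_train_epoch(List params, List adam_m, List adam_v, int adam_t,
                     List cfg, List X, List Y, List AUX, double lr,
                     int batch_size, int dropout_seed) {
  Config c = parse_config(cfg);
  std::vector<std::string> names = param_names(c);
  ParamMap P = list_to_params(params, names);
  ParamMap M, V;
  bool fresh = adam_m.size() == 0;
  for (const auto& nm : names) {
    if (fresh) {
      M[nm] = arma::mat(P[nm].n_rows, P[nm].n_cols, arma::fill::zeros);
      V[nm] = arma::mat(P[nm].n_rows, P[nm].n_cols, arma::fill::zeros);
    } else {
      M[nm] = as<arma::mat>(adam_m[nm]);
      V[nm] = as<arma::mat>(adam_v[nm]);
    }
  }

  std::vector<arma::imat> Xv = parse_X(X, c.n_tasks);
  std::vector<arma::ivec> Yv;
  for (int t = 0; t < c.n_tasks; ++t) Yv.push_back(as<arma::ivec>(Y[t]));
  std::vector<arma::mat> aux_store;
  std::vector<const arma::mat*> AUXv = parse_aux(AUX, c.n_tasks, aux_store);

  const int n = Xv[0].n_rows;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  std::mt19937 rng(static_cast<unsigned int>(dropout_seed));

  double tot_data = 0, tot_reg = 0, tot_mse = 0;
  std::vector<double> tot_cce(c.n_tasks, 0.0);
  int n_batches = 0;

  for (int start = 0; start < n; start += batch_size) {
    int end = std::min(start + batch_size, n) - 1;
    std::vector<arma::imat> Xb;
    std::vector<arma::ivec> Yb;
    std::vector<arma::mat> auxb_store(c.n_tasks);
    std::vector<const arma::mat*> AUXb(c.n_tasks, nullptr);
    for (int t = 0; t < c.n_tasks; ++t) {
      Xb.push_back(Xv[t].rows(start, end));
      Yb.push_back(Yv[t].subvec(start, end));
      if (AUXv[t] != nullptr) {
        auxb_store[t] = AUXv[t]->rows(start, end);
        AUXb[t] = &auxb_store[t];
      }
    }
    ParamMap G;
    LossParts lp =
        forward_backward(P, c, Xb, Yb, AUXb, true, rng, &G, names);
    tot_data += lp.total_data;
    tot_reg += lp.reg;
    tot_mse += lp.mse;
    for (int t = 0; t < c.n_tasks; ++t) tot_cce[t] += lp.cce[t];
    ++n_batches;

    ++adam_t;
    double bc1 = 1.0 - std::pow(b1, adam_t);
    double bc2 = 1.0 - std::pow(b2, adam_t);
    for (const auto& nm : names) {
      arma::mat& g = G[nm];
      M[nm] = b1 * M[nm] + (1 - b1) * g;
      V[nm] = b2 * V[nm] + (1 - b2) * (g % g);
      P[nm] -= lr * (M[nm] / bc1) / (arma::sqrt(V[nm] / bc2) + eps);
    }
  }

  for (int t = 0; t < c.n_tasks; ++t) tot_cce[t] /= n_batches;
  return List::create(
      _["params"] = params_to_list(P, names),
      _["adam_m"] = params_to_list(M, names),
      _["adam_v"] = params_to_list(V, names), _["adam_t"] = adam_t,
      _["train_loss_data"] = tot_data / n_batches,
      _["train_loss_reg"] = tot_reg / n_batches,
      _["train_cce"] = wrap(tot_cce),
      _["train_soft_share_mse"] = tot_mse / n_batches,
      _["n_batches"] = n_batches);
}
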