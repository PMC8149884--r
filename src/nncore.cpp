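// Core numerical kernels: batched evaluation of the bounded MLP synthesis
// function, and gradient training of the unrolled Euler dynamics
// (backpropagation through time) with Adam.
//
// Parameter layout (R side): a network is a list(W1, b1, W2, b2, W3, b3)
// with W1: n_in x h1, W2: h1 x h2, W3: h2 x n_out (n_out = n_genes for the
// shared architecture, 1 for per-gene networks).  "per_gene" passes a list
// of n_genes such sublists.
//
// The structural mask is an (n_genes + n_inputs) x n_genes 0/1 matrix;
// column j multiplies the regulator vector elementwise before gene j's
// synthesis component is evaluated (0 = link forbidden).

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Net {
  arma::mat W1, W2, W3;
  arma::vec b1, b2, b3;
};

static Net net_from_list(const List& p) {
  Net n;
  n.W1 = as<arma::mat>(p["W1"]);
  n.b1 = as<arma::vec>(p["b1"]);
  n.W2 = as<arma::mat>(p["W2"]);
  n.b2 = as<arma::vec>(p["b2"]);
  n.W3 = as<arma::mat>(p["W3"]);
  n.b3 = as<arma::vec>(p["b3"]);
  return n;
}

static List net_to_list(const Net& n) {
  return List::create(_["W1"] = n.W1, _["b1"] = n.b1,
                      _["W2"] = n.W2, _["b2"] = n.b2,
                      _["W3"] = n.W3, _["b3"] = n.b3);
}

static std::vector<Net> parse_nets(const List& params, const std::string& arch) {
  std::vector<Net> nets;
  if (arch == "shared") {
    nets.push_back(net_from_list(params));
  } else {
    for (R_xlen_t j = 0; j < params.size(); ++j)
      nets.push_back(net_from_list(params[j]));
  }
  return nets;
}

static inline void relu_inplace(arma::mat& z) {
  z.transform([](double v) { return v > 0.0 ? v : 0.0; });
}

static inline arma::mat sigm(const arma::mat& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// forward through one net; X must already be masked; A1/A2 are outputs
static arma::mat net_forward(const Net& net, const arma::mat& X,
                             arma::mat& A1, arma::mat& A2) {
  A1 = X * net.W1;
  A1.each_row() += net.b1.t();
  relu_inplace(A1);
  A2 = A1 * net.W2;
  A2.each_row() += net.b2.t();
  relu_inplace(A2);
  arma::mat Z3 = A2 * net.W3;
  Z3.each_row() += net.b3.t();
  return sigm(Z3);
}

static bool mask_uniform(const arma::mat& mask) {
  for (arma::uword j = 1; j < mask.n_cols; ++j)
    if (arma::any(mask.col(j) != mask.col(0))) return false;
  return true;
}

// Batched f(g, I): X is batch x (n_genes + n_inputs), returns batch x n_genes.
// [[Rcpp::export]]
arma::mat mlp_eval_cpp(List params, std::string arch, arma::mat mask,
                       arma::mat X, int n_genes) {
  std::vector<Net> nets = parse_nets(params, arch);
  arma::mat A1, A2;
  if (arch == "shared" && mask_uniform(mask)) {
    arma::mat Xm = X;
    Xm.each_row() %= mask.col(0).t();
    return net_forward(nets[0], Xm, A1, A2);
  }
  arma::mat F(X.n_rows, n_genes);
  for (int j = 0; j < n_genes; ++j) {
    arma::mat Xm = X;
    Xm.each_row() %= mask.col(j).t();
    const Net& net = (arch == "shared") ? nets[0] : nets[j];
    arma::mat out = net_forward(net, Xm, A1, A2);
    F.col(j) = (arch == "shared") ? out.col(j) : out.col(0);
  }
  return F;
}

struct Adam {
  std::vector<arma::mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  void init(const std::vector<arma::mat*>& ps) {
    for (auto p : ps) {
      m.push_back(arma::zeros<arma::mat>(p->n_rows, p->n_cols));
      v.push_back(arma::zeros<arma::mat>(p->n_rows, p->n_cols));
    }
  }
  void step(std::vector<arma::mat*>& ps, const std::vector<arma::mat*>& gs,
            double lr) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t k = 0; k < ps.size(); ++k) {
      m[k] = b1 * m[k] + (1.0 - b1) * (*gs[k]);
      v[k] = b2 * v[k] + (1.0 - b2) * arma::square(*gs[k]);
      *ps[k] -= lr * (m[k] / c1) / (arma::sqrt(v[k] / c2) + eps);
    }
  }
};

// Train the unrolled dynamics g(t+1) = (1 - gamma dt) g(t) + f(g, I) dt
// (+ optional Gaussian state noise, clipped at 0) against pooled
// square-root-of-sum-of-squares target loss.
//
// G0: n_cond x n_genes initial states (trainable genes overridden by
// sigmoid(theta)); inputs: cube n_cond x n_inputs x (N_T + 1);
// tgt_idx: K x 3 integer matrix of 0-based (condition, time, gene).
//
// When `couple` is true the inputs cube only fixes the horizon: the
// input block is recomputed every step as P * G (P a sparse
// neighbour-averaging matrix over the batch rows, e.g. block-circulant
// for a periodic lattice), and its gradient is routed back through P^T.
// [[Rcpp::export]]
List train_rnn_cpp(List params, std::string arch, arma::mat mask,
                   arma::mat G0, LogicalVector init_trainable,
                   arma::vec init_theta, arma::cube inputs,
                   arma::imat tgt_idx, arma::vec tgt_val,
                   double gamma, double dt, double noise_sd,
                   int max_iter, double lr, double tol, int patience,
                   int seed, bool couple = false,
                   Nullable<S4> coupling = R_NilValue,
                   Nullable<NumericVector> tgt_weight = R_NilValue) {
#ifdef __GLIBC__
  // keep the per-iteration matrix temporaries on the heap: the default
  // mmap threshold makes every MB-sized scratch allocation an
  // mmap/munmap round trip, which is ruinously slow under virtualised
  // paging
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  // ... and stop the allocator from returning the scratch space to the
  // OS after every iteration (heap trim), which re-faults it on the next
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
  arma::vec W(tgt_idx.n_rows, arma::fill::ones);
  if (tgt_weight.isNotNull()) W = as<arma::vec>(tgt_weight.get());
  arma::sp_mat P;
  if (couple) {
    if (coupling.isNull()) stop("coupling matrix required when couple = TRUE");
    P = as<arma::sp_mat>(coupling.get());
  }
  std::vector<Net> nets = parse_nets(params, arch);
  const int B = G0.n_rows, n_genes = G0.n_cols;
  const int n_inputs = inputs.n_cols;
  const int NT = inputs.n_slices - 1;
  const int n_in = n_genes + n_inputs;
  const double a = 1.0 - gamma * dt;
  const bool fast = (arch == "shared") && mask_uniform(mask);
  const int K = tgt_idx.n_rows;

  // vec params (biases) handled as 1-col mats for the optimizer
  std::vector<arma::mat> bmats;  // b1,b2,b3 per net
  for (auto& n : nets) {
    bmats.push_back(arma::mat(n.b1));
    bmats.push_back(arma::mat(n.b2));
    bmats.push_back(arma::mat(n.b3));
  }
  arma::mat theta(n_genes, 1);
  theta.col(0) = init_theta;

  // parameter and gradient registries
  std::vector<arma::mat*> pptr;
  std::vector<arma::mat> grads;
  {
    size_t bi = 0;
    for (size_t k = 0; k < nets.size(); ++k) {
      pptr.push_back(&nets[k].W1);
      pptr.push_back(&bmats[bi++]);
      pptr.push_back(&nets[k].W2);
      pptr.push_back(&bmats[bi++]);
      pptr.push_back(&nets[k].W3);
      pptr.push_back(&bmats[bi++]);
    }
    pptr.push_back(&theta);
    for (auto p : pptr) grads.push_back(arma::zeros<arma::mat>(p->n_rows, p->n_cols));
  }
  std::vector<arma::mat*> gptr;
  for (auto& g : grads) gptr.push_back(&g);
  Adam adam;
  adam.init(pptr);

  // per-net views into the grad registry: order W1,b1,W2,b2,W3,b3
  auto gW1 = [&](int k) -> arma::mat& { return grads[6 * k + 0]; };
  auto gb1 = [&](int k) -> arma::mat& { return grads[6 * k + 1]; };
  auto gW2 = [&](int k) -> arma::mat& { return grads[6 * k + 2]; };
  auto gb2 = [&](int k) -> arma::mat& { return grads[6 * k + 3]; };
  auto gW3 = [&](int k) -> arma::mat& { return grads[6 * k + 4]; };
  auto gb3 = [&](int k) -> arma::mat& { return grads[6 * k + 5]; };
  arma::mat& gtheta = grads.back();

  const int h1 = nets[0].W1.n_cols, h2 = nets[0].W2.n_cols;

  arma::cube G(B, n_genes, NT + 1);
  arma::cube Xraw(B, n_in, NT);
  arma::cube Fs(B, n_genes, NT);
  arma::cube A1s, A2s;                       // fast path
  std::vector<arma::cube> A1g, A2g;          // per-gene path
  if (fast) {
    A1s.set_size(B, h1, NT);
    A2s.set_size(B, h2, NT);
  } else {
    A1g.assign(n_genes, arma::cube(B, h1, NT));
    A2g.assign(n_genes, arma::cube(B, h2, NT));
  }

  std::mt19937_64 rng((unsigned long long)seed);
  std::normal_distribution<double> nd(0.0, 1.0);

  std::vector<double> history;
  history.reserve(max_iter);
  double best_loss = std::numeric_limits<double>::infinity();
  std::vector<Net> best_nets = nets;
  std::vector<arma::mat> best_b = bmats;
  arma::mat best_theta = theta;
  double ref_loss = std::numeric_limits<double>::infinity();
  int last_improve = 0;
  bool diverged = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    // ---- forward ----
    arma::mat g0 = G0;
    for (int j = 0; j < n_genes; ++j)
      if (init_trainable[j])
        g0.col(j).fill(1.0 / (1.0 + std::exp(-theta(j, 0))));
    G.slice(0) = g0;

    for (int t = 0; t < NT; ++t) {
      arma::mat X = couple
        ? arma::join_rows(G.slice(t), arma::mat(P * G.slice(t)))
        : arma::join_rows(G.slice(t), inputs.slice(t));
      Xraw.slice(t) = X;
      arma::mat F(B, n_genes);
      if (fast) {
        arma::mat Xm = X;
        Xm.each_row() %= mask.col(0).t();
        arma::mat A1, A2;
        F = net_forward(nets[0], Xm, A1, A2);
        A1s.slice(t) = A1;
        A2s.slice(t) = A2;
      } else {
        for (int j = 0; j < n_genes; ++j) {
          arma::mat Xm = X;
          Xm.each_row() %= mask.col(j).t();
          const Net& net = (arch == "shared") ? nets[0] : nets[j];
          arma::mat A1, A2;
          arma::mat out = net_forward(net, Xm, A1, A2);
          A1g[j].slice(t) = A1;
          A2g[j].slice(t) = A2;
          F.col(j) = (arch == "shared") ? out.col(j) : out.col(0);
        }
      }
      Fs.slice(t) = F;
      arma::mat Gn = a * G.slice(t) + dt * F;
      if (noise_sd > 0.0) {
        for (arma::uword q = 0; q < Gn.n_elem; ++q) Gn(q) += noise_sd * nd(rng);
      }
      Gn.transform([](double v) { return v > 0.0 ? v : 0.0; });
      G.slice(t + 1) = Gn;
    }

    // ---- loss ----
    double S = 0.0;
    for (int k = 0; k < K; ++k) {
      double r = G(tgt_idx(k, 0), tgt_idx(k, 2), tgt_idx(k, 1)) - tgt_val(k);
      S += W(k) * r * r;
    }
    double L = std::sqrt(S);
    if (!std::isfinite(L)) { diverged = true; break; }
    history.push_back(L);
    if (L < best_loss) {
      best_loss = L;
      best_nets = nets;
      best_b = bmats;
      best_theta = theta;
    }
    if (best_loss < ref_loss - tol) { ref_loss = best_loss; last_improve = iter; }
    if (iter - last_improve >= patience) break;
    if (L == 0.0) break;  // nothing to improve, gradient is zero

    // ---- backward ----
    for (auto& g : grads) g.zeros();
    arma::cube TG(B, n_genes, NT + 1, arma::fill::zeros);
    for (int k = 0; k < K; ++k) {
      double r = G(tgt_idx(k, 0), tgt_idx(k, 2), tgt_idx(k, 1)) - tgt_val(k);
      TG(tgt_idx(k, 0), tgt_idx(k, 2), tgt_idx(k, 1)) += W(k) * r / L;
    }
    arma::mat D = TG.slice(NT);
    for (int t = NT - 1; t >= 0; --t) {
      // pass-through of the clip at zero applied to g(t+1)
      D %= arma::conv_to<arma::mat>::from(G.slice(t + 1) > 0);
      arma::mat dF = dt * D;
      const arma::mat& X = Xraw.slice(t);
      arma::mat dX(B, n_in, arma::fill::zeros);
      if (fast) {
        const arma::mat& A1 = A1s.slice(t);
        const arma::mat& A2 = A2s.slice(t);
        const arma::mat& F = Fs.slice(t);
        arma::mat dZ3 = dF % F % (1.0 - F);
        gW3(0) += A2.t() * dZ3;
        gb3(0) += arma::sum(dZ3, 0).t();
        arma::mat dZ2 = dZ3 * nets[0].W3.t();
        dZ2.elem(arma::find(A2 <= 0)).zeros();
        gW2(0) += A1.t() * dZ2;
        gb2(0) += arma::sum(dZ2, 0).t();
        arma::mat dZ1 = dZ2 * nets[0].W2.t();
        dZ1.elem(arma::find(A1 <= 0)).zeros();
        arma::mat Xm = X;
        Xm.each_row() %= mask.col(0).t();
        gW1(0) += Xm.t() * dZ1;
        gb1(0) += arma::sum(dZ1, 0).t();
        dX = dZ1 * nets[0].W1.t();
        dX.each_row() %= mask.col(0).t();
      } else {
        for (int j = 0; j < n_genes; ++j) {
          const bool shared = (arch == "shared");
          const Net& net = shared ? nets[0] : nets[j];
          const int k = shared ? 0 : j;
          const arma::mat& A1 = A1g[j].slice(t);
          const arma::mat& A2 = A2g[j].slice(t);
          arma::vec fj = Fs.slice(t).col(j);
          arma::vec dz3 = dF.col(j) % fj % (1.0 - fj);
          arma::mat dA2;
          if (shared) {
            gW3(k).col(j) += A2.t() * dz3;
            gb3(k)(j, 0) += arma::accu(dz3);
            dA2 = dz3 * net.W3.col(j).t();
          } else {
            gW3(k) += A2.t() * dz3;
            gb3(k)(0, 0) += arma::accu(dz3);
            dA2 = dz3 * net.W3.t();
          }
          arma::mat dZ2 = dA2;
          dZ2.elem(arma::find(A2 <= 0)).zeros();
          gW2(k) += A1.t() * dZ2;
          gb2(k) += arma::sum(dZ2, 0).t();
          arma::mat dZ1 = dZ2 * net.W2.t();
          dZ1.elem(arma::find(A1 <= 0)).zeros();
          arma::mat Xm = X;
          Xm.each_row() %= mask.col(j).t();
          gW1(k) += Xm.t() * dZ1;
          gb1(k) += arma::sum(dZ1, 0).t();
          arma::mat dXj = dZ1 * net.W1.t();
          dXj.each_row() %= mask.col(j).t();
          dX += dXj;
        }
      }
      arma::mat Dprev = a * D + dX.cols(0, n_genes - 1) + TG.slice(t);
      if (couple && n_inputs > 0) {
        Dprev += P.t() * dX.cols(n_genes, n_in - 1);
      }
      D = Dprev;
    }
    for (int j = 0; j < n_genes; ++j) {
      if (init_trainable[j]) {
        double s = 1.0 / (1.0 + std::exp(-theta(j, 0)));
        gtheta(j, 0) = arma::accu(D.col(j)) * s * (1.0 - s);
      }
    }

    // ---- update ----
    // copy bias columns back into nets after the Adam step
    adam.step(pptr, gptr, lr);
    {
      size_t bi = 0;
      for (auto& n : nets) {
        n.b1 = bmats[bi++].col(0);
        n.b2 = bmats[bi++].col(0);
        n.b3 = bmats[bi++].col(0);
      }
    }
  }

  // rebuild best parameter list in the input layout
  {
    size_t bi = 0;
    for (auto& n : best_nets) {
      n.b1 = best_b[bi++].col(0);
      n.b2 = best_b[bi++].col(0);
      n.b3 = best_b[bi++].col(0);
    }
  }
  List out_params;
  if (arch == "shared") {
    out_params = net_to_list(best_nets[0]);
  } else {
    out_params = List(n_genes);
    for (int j = 0; j < n_genes; ++j) out_params[j] = net_to_list(best_nets[j]);
  }
  return List::create(
      _["params"] = out_params,
      _["init_theta"] = arma::vec(best_theta.col(0)),
      _["loss_history"] = history,
      _["best_loss"] = best_loss,
      _["diverged"] = diverged);
}
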