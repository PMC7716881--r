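// Core numerics for the S-CTRNN: batched forward pass with integrated
// (sensory/prior-mixed) input, backpropagation through time under the
// heteroscedastic Gaussian negative log-likelihood, Adam optimization of
// weights and per-class initial states, initial-state inference with frozen
// weights, closed-loop generation, and dynamic time warping.
//
// Conventions
//   - sequences are stored as cubes X(I, N, T): slice t holds the 2-D points
//     of all N sequences at time step t+1 (1-based steps t = 1..T)
//   - initial states are stored column-wise: Init is C x S (class s in col s)
//   - all randomness is drawn from R's RNG so that set.seed() in R gives
//     bit-reproducible runs
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Grads {
  mat Winp, Wrec, Wout, Wvar, Init;
};

// Forward pass (training style: first raw point fed unmixed, subsequent
// inputs mixed with the previous step's prediction) and, optionally, the
// full backward pass.  Targets of the likelihood are the integrated inputs
// of the next step, treated as data (no gradient flows through the mixing).
//
// Returns the summed output NLL over sequences, the T-1 predicted steps and
// both output dimensions; n_el receives the number of summed elements.
// BPTT storage reused across epochs
struct Workspace {
  cube Hs, Ys, Vs, Es, Xin;
  Workspace(uword C, uword O, uword I, uword N, uword T)
      : Hs(C, N, T), Ys(O, N, T - 1), Vs(O, N, T - 1), Es(O, N, T - 1),
        Xin(I, N, T) {}
};

static double forward_backward(const cube& X, const uvec& cls,
                               const mat& Winp, const mat& Wrec,
                               const mat& Wout, const mat& Wvar,
                               const mat& Init,
                               double tau, double chi, double K,
                               double vfloor, double vdist,
                               bool use_noise, bool literal_noise,
                               bool want_grads, bool init_prior,
                               Grads* g, double* nll_init_out,
                               unsigned long* n_el, Workspace& ws) {
  const uword I = X.n_rows, N = X.n_cols, T = X.n_slices;
  const uword C = Wrec.n_rows, O = Wout.n_rows;
  const double leak = 1.0 - 1.0 / tau, gain = 1.0 / tau;

  cube& Hs = ws.Hs;   // slice t = h_t, t = 0..T-1 (slice 0 = tanh(u0))
  cube& Ys = ws.Ys;
  cube& Vs = ws.Vs;
  cube& Es = ws.Es;
  cube& Xin = ws.Xin; // slice t-1 = integrated input of step t

  mat U(C, N);
  for (uword n = 0; n < N; ++n) U.col(n) = Init.col(cls(n));
  Hs.slice(0) = tanh(U);

  Xin.slice(0) = X.slice(0);   // no prediction exists at t=0
  double nll = 0.0;
  for (uword t = 1; t < T; ++t) {
    U = leak * U + gain * (Winp * Xin.slice(t - 1) + Wrec * Hs.slice(t - 1));
    mat H = tanh(U);
    Hs.slice(t) = H;
    mat Y = tanh(Wout * H);
    mat V = exp(Wvar * H + K) + vfloor;
    Ys.slice(t - 1) = Y;
    Vs.slice(t - 1) = V;

    // integrated input for step t+1, also the target of this prediction
    mat Xn = chi * X.slice(t) + (1.0 - chi) * Y;
    if (use_noise) {
      const double w = literal_noise ? 1.0 : (1.0 - chi);
      if (w != 0.0) {
        for (uword j = 0; j < N; ++j)
          for (uword i = 0; i < O; ++i)
            Xn(i, j) += w * R::norm_rand() * std::sqrt(V(i, j));
      }
    }
    Xin.slice(t) = Xn;

    mat E = Xn - Y;
    Es.slice(t - 1) = E;
    nll += accu(log(2.0 * M_PI * V) + square(E) / (2.0 * V));
  }
  *n_el = (unsigned long)N * (T - 1) * O;

  // initial-state likelihood (distance prior among classes)
  double nll_init = 0.0;
  const uword S = Init.n_cols;
  vec u0bar = mean(Init, 1);
  if (init_prior) {
    for (uword s = 0; s < S; ++s) {
      vec d = Init.col(s) - u0bar;
      nll_init += C * std::log(2.0 * M_PI * vdist) + dot(d, d) / (2.0 * vdist);
    }
  }
  *nll_init_out = nll_init;

  if (!want_grads) return nll;

  g->Winp.zeros(C, I); g->Wrec.zeros(C, C);
  g->Wout.zeros(O, C); g->Wvar.zeros(O, C);
  g->Init.zeros(C, S);

  mat dU_next(C, N, fill::zeros);
  for (uword tt = T - 1; tt >= 1; --tt) {
    const mat& H = Hs.slice(tt);
    const mat& Y = Ys.slice(tt - 1);
    const mat& V = Vs.slice(tt - 1);
    const mat& E = Es.slice(tt - 1);
    mat dA = (-E / V) % (1.0 - square(Y));
    mat dB = (1.0 / V - square(E) / (2.0 * square(V))) % (V - vfloor);
    mat gH = Wout.t() * dA + Wvar.t() * dB;
    if (tt < T - 1) gH += gain * (Wrec.t() * dU_next);
    mat dU = gH % (1.0 - square(H));
    if (tt < T - 1) dU += leak * dU_next;
    g->Wout += dA * H.t();
    g->Wvar += dB * H.t();
    g->Wrec += gain * (dU * Hs.slice(tt - 1).t());
    g->Winp += gain * (dU * Xin.slice(tt - 1).t());
    dU_next = dU;
  }
  // through h0 = tanh(u0) and the leak path into u1
  mat gH0 = gain * (Wrec.t() * dU_next);
  mat dU0 = gH0 % (1.0 - square(Hs.slice(0))) + leak * dU_next;
  for (uword n = 0; n < N; ++n) g->Init.col(cls(n)) += dU0.col(n);
  if (init_prior)
    for (uword s = 0; s < S; ++s)
      g->Init.col(s) += (Init.col(s) - u0bar) / vdist;

  return nll;
}

struct AdamState {
  mat m, v;
  AdamState(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(mat& w, const mat& grad, double lr, double b1, double b2,
            double eps, double t) {
    m = b1 * m + (1.0 - b1) * grad;
    v = b2 * v + (1.0 - b2) * square(grad);
    double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
};

// convergence rule: every check_interval epochs, compare the mean of the
// last `window` batch-mean NLL values with the mean of the window before,
// and require the fluctuation (sd) of the last window to be small
static bool converged_now(const std::vector<double>& h, int window,
                          double mean_thresh, double sd_thresh) {
  const int n = (int)h.size();
  if (n < 2 * window) return false;
  double m_cur = 0.0, m_prev = 0.0;
  for (int i = n - window; i < n; ++i) m_cur += h[i];
  for (int i = n - 2 * window; i < n - window; ++i) m_prev += h[i];
  m_cur /= window; m_prev /= window;
  double ss = 0.0;
  for (int i = n - window; i < n; ++i) ss += (h[i] - m_cur) * (h[i] - m_cur);
  double sd = std::sqrt(ss / (window - 1));
  return (m_prev - m_cur) < mean_thresh && sd < sd_thresh;
}

// [[Rcpp::export(name = ".sctrnn_train_cpp")]]
Rcpp::List sctrnn_train_cpp(const arma::cube& X, const arma::uvec& cls,
                            arma::mat Winp, arma::mat Wrec, arma::mat Wout,
                            arma::mat Wvar, arma::mat Init,
                            double tau, double chi, double K, double vfloor,
                            double vdist, bool literal_noise,
                            int max_epochs, int check_interval, int window,
                            double mean_thresh, double sd_thresh,
                            double lr, double beta1, double beta2,
                            double adam_eps) {
  const bool use_noise = (chi < 1.0) || literal_noise;
  Grads g;
  double nll_init;
  unsigned long n_el;
  Workspace ws(Wrec.n_rows, Wout.n_rows, X.n_rows, X.n_cols, X.n_slices);
  std::vector<double> hist;
  hist.reserve(max_epochs);
  AdamState aWinp(Winp.n_rows, Winp.n_cols), aWrec(Wrec.n_rows, Wrec.n_cols),
      aWout(Wout.n_rows, Wout.n_cols), aWvar(Wvar.n_rows, Wvar.n_cols),
      aInit(Init.n_rows, Init.n_cols);
  bool conv = false;
  int epochs = 0;
  for (int e = 0; e < max_epochs; ++e) {
    double nll = forward_backward(X, cls, Winp, Wrec, Wout, Wvar, Init, tau,
                                  chi, K, vfloor, vdist, use_noise,
                                  literal_noise, true, true, &g, &nll_init,
                                  &n_el, ws);
    if (!std::isfinite(nll) || !g.Wrec.is_finite())
      Rcpp::stop("non-finite loss at epoch %d: training diverged "
                 "(extreme parameter values can destabilize the updates)",
                 e + 1);
    double t = e + 1.0;
    aWinp.step(Winp, g.Winp, lr, beta1, beta2, adam_eps, t);
    aWrec.step(Wrec, g.Wrec, lr, beta1, beta2, adam_eps, t);
    aWout.step(Wout, g.Wout, lr, beta1, beta2, adam_eps, t);
    aWvar.step(Wvar, g.Wvar, lr, beta1, beta2, adam_eps, t);
    aInit.step(Init, g.Init, lr, beta1, beta2, adam_eps, t);
    hist.push_back(nll / X.n_cols);  // batch-mean NLL per sequence
    epochs = e + 1;
    if ((e + 1) % check_interval == 0 &&
        converged_now(hist, window, mean_thresh, sd_thresh)) {
      conv = true;
      break;
    }
    if ((e + 1) % 500 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("W_inp") = Winp, Rcpp::Named("W_rec") = Wrec,
      Rcpp::Named("W_out") = Wout, Rcpp::Named("W_var") = Wvar,
      Rcpp::Named("initial_states") = Init, Rcpp::Named("nll") = hist,
      Rcpp::Named("epochs") = epochs, Rcpp::Named("converged") = conv);
}

// [[Rcpp::export(name = ".sctrnn_grads_cpp")]]
Rcpp::List sctrnn_grads_cpp(const arma::cube& X, const arma::uvec& cls,
                            const arma::mat& Winp, const arma::mat& Wrec,
                            const arma::mat& Wout, const arma::mat& Wvar,
                            const arma::mat& Init,
                            double tau, double chi, double K, double vfloor,
                            double vdist, bool use_noise, bool literal_noise,
                            bool init_prior) {
  Grads g;
  double nll_init;
  unsigned long n_el;
  Workspace ws(Wrec.n_rows, Wout.n_rows, X.n_rows, X.n_cols, X.n_slices);
  double nll = forward_backward(X, cls, Winp, Wrec, Wout, Wvar, Init, tau,
                                chi, K, vfloor, vdist, use_noise,
                                literal_noise, true, init_prior, &g,
                                &nll_init, &n_el, ws);
  return Rcpp::List::create(
      Rcpp::Named("nll_output") = nll, Rcpp::Named("nll_init") = nll_init,
      Rcpp::Named("W_inp") = g.Winp, Rcpp::Named("W_rec") = g.Wrec,
      Rcpp::Named("W_out") = g.Wout, Rcpp::Named("W_var") = g.Wvar,
      Rcpp::Named("initial_states") = g.Init);
}

// Open-loop / mixed forward trace for one batch of driving sequences.
// Returns per-step integrated inputs, activations h_1..h_T (plus h_0),
// predicted means and variances for steps 1..T.
// [[Rcpp::export(name = ".sctrnn_forward_cpp")]]
Rcpp::List sctrnn_forward_cpp(const arma::cube& X, const arma::mat& U0,
                              const arma::mat& Winp, const arma::mat& Wrec,
                              const arma::mat& Wout, const arma::mat& Wvar,
                              double tau, double chi, double K, double vfloor,
                              bool use_noise, bool literal_noise) {
  const uword I = X.n_rows, N = X.n_cols, T = X.n_slices;
  const uword C = Wrec.n_rows, O = Wout.n_rows;
  const double leak = 1.0 - 1.0 / tau, gain = 1.0 / tau;
  cube Hs(C, N, T), Ys(O, N, T), Vs(O, N, T), Xin(I, N, T);
  mat U = U0;
  mat H0 = tanh(U);
  mat Hprev = H0;
  for (uword t = 0; t < T; ++t) {
    mat x;
    if (t == 0) {
      x = X.slice(0);
    } else {
      x = chi * X.slice(t) + (1.0 - chi) * Ys.slice(t - 1);
      if (use_noise) {
        const double w = literal_noise ? 1.0 : (1.0 - chi);
        if (w != 0.0)
          for (uword j = 0; j < N; ++j)
            for (uword i = 0; i < O; ++i)
              x(i, j) += w * R::norm_rand() * std::sqrt(Vs(i, j, t - 1));
      }
    }
    Xin.slice(t) = x;
    U = leak * U + gain * (Winp * x + Wrec * Hprev);
    mat H = tanh(U);
    Hs.slice(t) = H;
    Ys.slice(t) = tanh(Wout * H);
    Vs.slice(t) = exp(Wvar * H + K) + vfloor;
    Hprev = H;
  }
  return Rcpp::List::create(
      Rcpp::Named("x_in") = Xin, Rcpp::Named("h") = Hs,
      Rcpp::Named("y") = Ys, Rcpp::Named("v") = Vs,
      Rcpp::Named("h0") = H0);
}

// Closed-loop (proactive) generation: the readout of the initial state is
// the first input, every later input is the previous predicted mean.
// [[Rcpp::export(name = ".sctrnn_generate_cpp")]]
Rcpp::List sctrnn_generate_cpp(const arma::vec& u0, const arma::mat& Winp,
                               const arma::mat& Wrec, const arma::mat& Wout,
                               const arma::mat& Wvar, double tau, double K,
                               double vfloor, int T) {
  const uword C = Wrec.n_rows, O = Wout.n_rows;
  const double leak = 1.0 - 1.0 / tau, gain = 1.0 / tau;
  mat traj(O, T), acts(C, T), vars(O, T);
  vec U = u0;
  vec h = tanh(U);
  vec y = tanh(Wout * h);
  vec v = exp(Wvar * h + K) + vfloor;
  for (int t = 0; t < T; ++t) {
    traj.col(t) = y;
    acts.col(t) = h;
    vars.col(t) = v;
    U = leak * U + gain * (Winp * y + Wrec * h);
    h = tanh(U);
    y = tanh(Wout * h);
    v = exp(Wvar * h + K) + vfloor;
  }
  return Rcpp::List::create(Rcpp::Named("trajectory") = traj.t(),
                            Rcpp::Named("activations") = acts,
                            Rcpp::Named("variances") = vars.t());
}

// Initial-state inference: weights frozen, open-loop drive (chi = 1, noise
// off), Adam updates on the initial states only.  Each column of U0 is
// optimized against the corresponding sequence of X.
// [[Rcpp::export(name = ".sctrnn_infer_cpp")]]
Rcpp::List sctrnn_infer_cpp(const arma::cube& X, arma::mat U0,
                            const arma::mat& Winp, const arma::mat& Wrec,
                            const arma::mat& Wout, const arma::mat& Wvar,
                            double tau, double K, double vfloor,
                            int epochs, double lr, double beta1, double beta2,
                            double adam_eps) {
  const uword N = X.n_cols;
  uvec cls = regspace<uvec>(0, N - 1);
  Grads g;
  double nll_init;
  unsigned long n_el;
  Workspace ws(U0.n_rows, Wout.n_rows, X.n_rows, X.n_cols, X.n_slices);
  AdamState a(U0.n_rows, U0.n_cols);
  std::vector<double> hist;
  hist.reserve(epochs);
  for (int e = 0; e < epochs; ++e) {
    double nll = forward_backward(X, cls, Winp, Wrec, Wout, Wvar, U0, tau,
                                  1.0, K, vfloor, 1.0, false, false, true,
                                  false, &g, &nll_init, &n_el, ws);
    if (!std::isfinite(nll))
      Rcpp::stop("non-finite loss during initial-state inference at epoch %d",
                 e + 1);
    a.step(U0, g.Init, lr, beta1, beta2, adam_eps, e + 1.0);
    hist.push_back(nll / N);
    if ((e + 1) % 500 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("initial_states") = U0,
                            Rcpp::Named("nll") = hist);
}

// Classic dynamic time warping: Euclidean local cost between column vectors,
// unit steps (match/insert/delete), no window, unnormalized accumulated cost.
// [[Rcpp::export(name = ".dtw_cpp")]]
double dtw_cpp(const arma::mat& a, const arma::mat& b) {
  const uword Ta = a.n_cols, Tb = b.n_cols;
  vec prev(Tb + 1, fill::value(datum::inf));
  vec curr(Tb + 1);
  prev(0) = 0.0;
  for (uword i = 1; i <= Ta; ++i) {
    curr.fill(datum::inf);
    for (uword j = 1; j <= Tb; ++j) {
      double c = norm(a.col(i - 1) - b.col(j - 1), 2);
      curr(j) = c + std::min(prev(j - 1), std::min(prev(j), curr(j - 1)));
    }
    prev = curr;
  }
  return prev(Tb);
}
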