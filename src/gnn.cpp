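// Edge-weighted residual propagation network: forward pass, analytic
// gradients of the batch-NSE loss, and the Nesterov-SGD training loop.
// All randomness (shuffling, edge-noise augmentation) goes through R's RNG
// so that set.seed() at the R level makes training bit-reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Forward pass for one subject; X has n rows and K+1 columns, column k
// holding the state after k layers (column 0 is the all-ones dummy input).
static void forward_states(const arma::mat& A, const arma::cube& W,
                           const arma::mat& B, bool residual, arma::mat& X) {
  const arma::uword K = W.n_slices;
  X.col(0).ones();
  for (arma::uword k = 0; k < K; ++k) {
    X.col(k + 1) = (W.slice(k) % A) * X.col(k) + B.col(k);
    if (residual) X.col(k + 1) += X.col(k);
  }
}

// [[Rcpp::export]]
NumericVector cppForwardCohort(const arma::cube& A, const arma::cube& W,
                               const arma::mat& B, bool residual, int roi0) {
  const arma::uword n = A.n_rows, S = A.n_slices, K = W.n_slices;
  arma::mat X(n, K + 1);
  NumericVector preds(S);
  for (arma::uword s = 0; s < S; ++s) {
    forward_states(A.slice(s), W, B, residual, X);
    preds[s] = X(roi0, K);
  }
  return preds;
}

// Batch loss = NSE of ROI predictions against targets, normalized by the
// within-batch total sum of squares. Accumulates gradients into gW/gB
// (assumed zeroed by the caller). Returns the loss.
static double batch_loss_grad(const arma::cube& Ab, const arma::vec& yb,
                              const arma::cube& W, const arma::mat& B,
                              bool residual, int roi0,
                              arma::cube& gW, arma::mat& gB) {
  const arma::uword n = Ab.n_rows, b = Ab.n_slices, K = W.n_slices;
  const double my = arma::mean(yb);
  const double sst = arma::accu(arma::square(yb - my));
  if (sst < 1e-12)
    stop("batch targets are (numerically) constant; NSE loss undefined");
  arma::mat X(n, K + 1);
  double sse = 0.0;
  arma::vec g(n), gprev(n);
  for (arma::uword s = 0; s < b; ++s) {
    const arma::mat& As = Ab.slice(s);
    forward_states(As, W, B, residual, X);
    const double resid = yb(s) - X(roi0, K);
    sse += resid * resid;
    g.zeros();
    g(roi0) = -2.0 * resid / sst;
    for (int k = (int)K - 1; k >= 0; --k) {
      gB.col(k) += g;
      gW.slice(k) += (g * X.col(k).t()) % As;
      gprev = (W.slice(k) % As).t() * g;
      if (residual) gprev += g;
      g = gprev;
    }
  }
  return sse / sst;
}

// [[Rcpp::export]]
List cppLossGrad(const arma::cube& A, const arma::vec& y,
                 const arma::cube& W, const arma::mat& B,
                 bool residual, int roi0) {
  arma::cube gW(W.n_rows, W.n_cols, W.n_slices, arma::fill::zeros);
  arma::mat gB(B.n_rows, B.n_cols, arma::fill::zeros);
  double loss = batch_loss_grad(A, y, W, B, residual, roi0, gW, gB);
  return List::create(_["loss"] = loss, _["gW"] = gW, _["gB"] = gB);
}

// [[Rcpp::export]]
List cppTrain(const arma::cube& A, const arma::vec& y,
              arma::cube W, arma::mat B, bool residual, int roi0,
              int batchSize, int epochs, double lr0, double momentum,
              double decayFactor, IntegerVector decayEpochs,
              bool augment, const arma::mat& sdMat) {
  const arma::uword n = A.n_rows, S = A.n_slices, K = W.n_slices;
  arma::cube vW(n, n, K, arma::fill::zeros),
             gW(n, n, K, arma::fill::zeros);
  arma::mat vB(n, K, arma::fill::zeros), gB(n, K, arma::fill::zeros);
  std::vector<arma::uword> idx(S);
  for (arma::uword s = 0; s < S; ++s) idx[s] = s;
  NumericVector trace(epochs);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    int nDecayed = 0;
    for (int d = 0; d < decayEpochs.size(); ++d)
      if (decayEpochs[d] <= epoch) ++nDecayed;
    const double lr = lr0 * std::pow(decayFactor, nDecayed);

    // Fisher-Yates shuffle driven by R's RNG
    for (arma::uword i = S - 1; i > 0; --i) {
      arma::uword j = (arma::uword)std::floor(unif_rand() * (double)(i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }

    double epochLoss = 0.0;
    int nBatches = 0;
    for (arma::uword start = 0; start < S; start += (arma::uword)batchSize) {
      const arma::uword end = std::min(start + (arma::uword)batchSize, S);
      const arma::uword b = end - start;
      arma::cube Ab(n, n, b);
      arma::vec yb(b);
      for (arma::uword s = 0; s < b; ++s) {
        Ab.slice(s) = A.slice(idx[start + s]);
        yb(s) = y(idx[start + s]);
        if (augment) {
          arma::mat& Aslice = Ab.slice(s);
          for (arma::uword c = 0; c < n; ++c)
            for (arma::uword r = 0; r < n; ++r) {
              const double sd = sdMat(r, c);
              const double z = norm_rand();  // always consumed: determinism
              if (sd > 0) Aslice(r, c) += sd * z;
            }
        }
      }
      gW.zeros(); gB.zeros();
      const double loss =
        batch_loss_grad(Ab, yb, W, B, residual, roi0, gW, gB);
      if (!std::isfinite(loss))
        stop("training loss became non-finite at epoch %d, batch %d",
             epoch + 1, nBatches + 1);
      // Nesterov momentum (PyTorch convention)
      vW = momentum * vW + gW;
      vB = momentum * vB + gB;
      W -= lr * (gW + momentum * vW);
      B -= lr * (gB + momentum * vB);
      epochLoss += loss;
      ++nBatches;
    }
    trace[epoch] = epochLoss / nBatches;
    if (epoch % 50 == 0) checkUserInterrupt();
  }
  return List::create(_["W"] = W, _["B"] = B, _["loss"] = trace);
}
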