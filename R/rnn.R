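# Compact single-layer gated recurrent network (GRU) classifier.
#
# Implemented directly on BLAS matrix operations: forward pass and
# backpropagation through time over a fixed-length step list, softmax
# cross-entropy with per-class weights, Adam updates on minibatches.
# Gradients are exercised against numerical differentiation in the tests.

.sigm <- function(x) 1 / (1 + exp(-x))

.rnn_init <- function(d, h, k, rng_sd = 0.1) {
  rm <- function(a, b) matrix(rnorm(a * b, 0, rng_sd), a, b)
  list(Wz = rm(d, h), Uz = rm(h, h), bz = rep(0, h),
       Wr = rm(d, h), Ur = rm(h, h), br = rep(0, h),
       Wc = rm(d, h), Uc = rm(h, h), bc = rep(0, h),
       Wo = rm(h, k), bo = rep(0, k))
}

# forward pass; returns cache when training
.rnn_forward <- function(par, xs, cache = FALSE) {
  n <- nrow(xs[[1]]); h <- ncol(par$Uz); T_ <- length(xs)
  H <- matrix(0, n, h)
  st <- if (cache) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    X <- xs[[t]]
    Z <- .sigm(sweep(X %*% par$Wz + H %*% par$Uz, 2, par$bz, "+"))
    R <- .sigm(sweep(X %*% par$Wr + H %*% par$Ur, 2, par$br, "+"))
    C <- tanh(sweep(X %*% par$Wc + (R * H) %*% par$Uc, 2, par$bc, "+"))
    Hn <- (1 - Z) * H + Z * C
    if (cache) st[[t]] <- list(H_prev = H, Z = Z, R = R, C = C)
    H <- Hn
  }
  logits <- sweep(H %*% par$Wo, 2, par$bo, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  P <- e / rowSums(e)
  list(P = P, H = H, states = st)
}

# weighted cross-entropy loss and full gradient
.rnn_loss_grad <- function(par, xs, y, w) {
  fw <- .rnn_forward(par, xs, cache = TRUE)
  n <- length(y); sw <- sum(w)
  loss <- -sum(w * log(pmax(fw$P[cbind(seq_len(n), y)], 1e-12))) / sw
  dL <- fw$P
  dL[cbind(seq_len(n), y)] <- dL[cbind(seq_len(n), y)] - 1
  dL <- dL * (w / sw)
  g <- lapply(par, function(p) p * 0)
  g$Wo <- t(fw$H) %*% dL
  g$bo <- colSums(dL)
  dH <- dL %*% t(par$Wo)
  for (t in rev(seq_along(xs))) {
    s <- fw$states[[t]]; X <- xs[[t]]
    dZ <- dH * (s$C - s$H_prev)
    dC <- dH * s$Z
    dHp <- dH * (1 - s$Z)
    dAc <- dC * (1 - s$C^2)
    g$Wc <- g$Wc + t(X) %*% dAc
    g$Uc <- g$Uc + t(s$R * s$H_prev) %*% dAc
    g$bc <- g$bc + colSums(dAc)
    dRH <- dAc %*% t(par$Uc)
    dR <- dRH * s$H_prev
    dHp <- dHp + dRH * s$R
    dAr <- dR * s$R * (1 - s$R)
    g$Wr <- g$Wr + t(X) %*% dAr
    g$Ur <- g$Ur + t(s$H_prev) %*% dAr
    g$br <- g$br + colSums(dAr)
    dHp <- dHp + dAr %*% t(par$Ur)
    dAz <- dZ * s$Z * (1 - s$Z)
    g$Wz <- g$Wz + t(X) %*% dAz
    g$Uz <- g$Uz + t(s$H_prev) %*% dAz
    g$bz <- g$bz + colSums(dAz)
    dH <- dHp + dAz %*% t(par$Uz)
  }
  list(loss = loss, grad = g)
}

#' Fit a gated recurrent network classifier
#'
#' Single-layer GRU over fixed-length right-aligned sequences with a
#' softmax head, trained by minibatch Adam on class-weighted cross-entropy.
#' Deterministic under a fixed seed.
#'
#' @param xs List of `T` step matrices, each `n x d` (step 1 oldest).
#' @param y Integer class labels in `1..k` (or factor).
#' @param k Number of classes (default `max(y)`).
#' @param hidden Hidden-state size.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param class_weights Numeric length-`k` loss weights (default inverse
#'   class frequency, normalized).
#' @param seed Integer seed for initialization and shuffling.
#' @param verbose Print the loss each epoch.
#' @return An `slhs_rnn` model object.
#' @export
rnn_fit <- function(xs, y, k = NULL, hidden = 16L, epochs = 12L,
                    learning_rate = 0.02, batch_size = 1024L,
                    class_weights = NULL, seed = 1L, verbose = FALSE) {
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  k <- k %||% max(y)
  n <- nrow(xs[[1]]); d <- ncol(xs[[1]])
  if (n != length(y)) .stopf("labels and sequences disagree in length")
  if (is.null(class_weights)) {
    tab <- tabulate(y, k)
    class_weights <- ifelse(tab > 0, n / (k * pmax(tab, 1)), 0)
  }
  w <- class_weights[y]
  set.seed(seed)
  par <- .rnn_init(d, hidden, k)
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- lapply(xs, function(m_) m_[idx, , drop = FALSE])
      lg <- .rnn_loss_grad(par, xb, y[idx], w[idx])
      tot <- tot + lg$loss * length(idx)
      step <- step + 1
      for (nmp in names(par)) {
        g <- lg$grad[[nmp]]
        m[[nmp]] <- b1 * m[[nmp]] + (1 - b1) * g
        v[[nmp]] <- b2 * v[[nmp]] + (1 - b2) * g^2
        mh <- m[[nmp]] / (1 - b1^step)
        vh <- v[[nmp]] / (1 - b2^step)
        par[[nmp]] <- par[[nmp]] - learning_rate * mh / (sqrt(vh) + eps)
      }
    }
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, tot / n))
  }
  structure(list(par = par, k = k, d = d, hidden = hidden),
            class = "slhs_rnn")
}

#' Predict class probabilities from a fitted recurrent network
#'
#' @param object An `slhs_rnn` model.
#' @param xs Step-matrix list as in [rnn_fit()].
#' @param chunk Rows per forward-pass chunk.
#' @param ... Unused.
#' @return `n x k` probability matrix (rows sum to 1).
#' @export
predict.slhs_rnn <- function(object, xs, chunk = 8192L, ...) {
  n <- nrow(xs[[1]])
  out <- matrix(NA_real_, n, object$k)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    xb <- lapply(xs, function(m_) m_[idx, , drop = FALSE])
    out[idx, ] <- .rnn_forward(object$par, xb)$P
  }
  out
}
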