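# Trainable heads over the fixed conv stem, with hand-derived gradients.
# Each head is a list: n_par, init(seed) -> par vector, fwd(par, batch) ->
# list(z = logits, cache), bwd(par, batch, cache, dz) -> gradient vector.
# Batches are: matrix (dense), n x T x d array (recurrent), or a list of
# token matrices (attention).

make_mlp_head <- function(d, h) {
  idx <- list(W1 = seq_len(d * h),
              b1 = d * h + seq_len(h),
              W2 = d * h + h + seq_len(h),
              b2 = d * h + 2L * h + 1L)
  unpack <- function(par) list(
    W1 = matrix(par[idx$W1], d, h), b1 = par[idx$b1],
    W2 = par[idx$W2], b2 = par[idx$b2])
  list(
    n_par = d * h + 2L * h + 1L,
    # hidden layer: random projection features; output layer: zero-init so
    # the initial predictor is exactly uninformative (score 0.5) and every
    # bit of logit movement is gradient-driven -- essential at tiny
    # learning rates, where a random initial logit could never be unlearned
    init = function(seed) with_seed(seed, c(
      rnorm(d * h, sd = 1 / sqrt(d)), rep(0, h),
      rep(0, h), 0)),
    fwd = function(par, X) {
      p <- unpack(par)
      H <- tanh(sweep(X %*% p$W1, 2, p$b1, `+`))
      z <- drop(H %*% p$W2) + p$b2
      list(z = z, cache = H)
    },
    bwd = function(par, X, cache, dz) {
      p <- unpack(par)
      H <- cache
      dW2 <- drop(crossprod(H, dz))
      db2 <- sum(dz)
      dA <- (dz %o% p$W2) * (1 - H^2)
      g <- numeric(length(par))
      g[idx$W1] <- crossprod(X, dA)
      g[idx$b1] <- colSums(dA)
      g[idx$W2] <- dW2
      g[idx$b2] <- db2
      g
    })
}

make_rnn_head <- function(d, m) {
  idx <- list(W = seq_len(d * m),
              U = d * m + seq_len(m * m),
              b = d * m + m * m + seq_len(m),
              v = d * m + m * m + m + seq_len(m),
              cc = d * m + m * m + 2L * m + 1L)
  unpack <- function(par) list(
    W = matrix(par[idx$W], d, m), U = matrix(par[idx$U], m, m),
    b = par[idx$b], v = par[idx$v], cc = par[idx$cc])
  list(
    n_par = d * m + m * m + 2L * m + 1L,
    init = function(seed) with_seed(seed, c(
      rnorm(d * m, sd = 1 / sqrt(d)), rnorm(m * m, sd = 0.5 / sqrt(m)),
      rep(0, m), rep(0, m), 0)),  # zero-init readout (see make_mlp_head)
    fwd = function(par, X) {  # X: n x T x d
      p <- unpack(par)
      n <- dim(X)[1]; Tn <- dim(X)[2]
      Hs <- vector("list", Tn)
      h <- matrix(0, n, m)
      for (t in seq_len(Tn)) {
        a <- X[, t, , drop = FALSE]
        dim(a) <- c(n, d)
        h <- tanh(sweep(a %*% p$W + h %*% p$U, 2, p$b, `+`))
        Hs[[t]] <- h
      }
      z <- drop(h %*% p$v) + p$cc
      list(z = z, cache = Hs)
    },
    bwd = function(par, X, cache, dz) {
      p <- unpack(par)
      n <- dim(X)[1]; Tn <- dim(X)[2]
      Hs <- cache
      g <- numeric(length(par))
      dW <- matrix(0, d, m); dU <- matrix(0, m, m); db <- numeric(m)
      dh <- dz %o% p$v
      for (t in rev(seq_len(Tn))) {
        da <- dh * (1 - Hs[[t]]^2)
        a <- X[, t, , drop = FALSE]
        dim(a) <- c(n, d)
        dW <- dW + crossprod(a, da)
        db <- db + colSums(da)
        hprev <- if (t > 1) Hs[[t - 1]] else matrix(0, n, m)
        dU <- dU + crossprod(hprev, da)
        dh <- da %*% t(p$U)
      }
      g[idx$W] <- dW; g[idx$U] <- dU; g[idx$b] <- db
      g[idx$v] <- crossprod(Hs[[Tn]], dz)
      g[idx$cc] <- sum(dz)
      g
    })
}

make_attn_head <- function(k) {
  idx <- list(q = seq_len(k), w = k + seq_len(k), b = 2L * k + 1L)
  unpack <- function(par) list(q = par[idx$q], w = par[idx$w], b = par[idx$b])
  list(
    n_par = 2L * k + 1L,
    init = function(seed) with_seed(seed, c(
      rnorm(k, sd = 0.5), rep(0, k), 0)),  # zero-init readout
    fwd = function(par, batch) {  # batch: list of P x k token matrices
      p <- unpack(par)
      caches <- vector("list", length(batch))
      z <- numeric(length(batch))
      for (i in seq_along(batch)) {
        A <- batch[[i]]
        s <- drop(A %*% p$q)
        s <- s - max(s)
        al <- exp(s); al <- al / sum(al)
        pooled <- drop(crossprod(A, al))
        z[i] <- sum(p$w * pooled) + p$b
        caches[[i]] <- list(al = al, pooled = pooled)
      }
      list(z = z, cache = caches)
    },
    bwd = function(par, batch, cache, dz) {
      p <- unpack(par)
      g <- numeric(length(par))
      for (i in seq_along(batch)) {
        A <- batch[[i]]
        al <- cache[[i]]$al
        pooled <- cache[[i]]$pooled
        g[idx$w] <- g[idx$w] + dz[i] * pooled
        g[idx$b] <- g[idx$b] + dz[i]
        dpooled <- dz[i] * p$w
        dal <- drop(A %*% dpooled)
        ds <- al * (dal - sum(al * dal))
        g[idx$q] <- g[idx$q] + drop(crossprod(A, ds))
      }
      g
    })
}

# Stable binary cross-entropy with logits; returns mean loss and d(loss)/dz
# (already divided by the batch size).
bce_with_logits <- function(z, y) {
  loss <- mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
  list(loss = loss, dz = (stats::plogis(z) - y) / length(z))
}

# One Adam step; `state` carries (m, v, t).
adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state)) state <- list(m = numeric(length(par)),
                                    v = numeric(length(par)), t = 0L)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}
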