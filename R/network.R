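# Native minibatch neural-network engine.
#
# Materializes a topology_spec as a trainable network: stacked 1-D
# convolutions along the time axis (valid padding, stride 1, channels as
# depth), optional max-pooling, then dense layers that are feed-forward,
# LSTM or GRU, and a softmax output. Gradients are computed by manual
# backpropagation (including backpropagation through time); six learning
# rules are provided. Everything is plain R matrix algebra: batches are
# (N x T x C) arrays for sequences and (N x F) matrices once flattened.
#
# Conventions that the topology grammar leaves open:
# * recurrent layers return their full hidden sequence when the next dense
#   layer is recurrent, otherwise the last hidden state (the usual stacked
#   RNN convention);
# * a feed-forward layer flattens whatever it receives;
# * a recurrent layer receiving a flat vector treats it as a length-1
#   sequence;
# * the layer activation of an LSTM/GRU replaces the tanh of the candidate
#   and cell-output transforms (gates stay sigmoid);
# * L1/L2 regularization applies to input-kernel weights with coefficient
#   1e-4; gradients are clipped to a global norm of 5 for stability with
#   ReLU recurrences.

GN_REG_LAMBDA <- 1e-4
GN_CLIP_NORM <- 5

sigmoid <- function(x) 1 / (1 + exp(-x))

act_fun <- function(name) {
  switch(name,
         linear = list(f = identity, df = function(a) 1),
         ReLU = list(f = function(a) pmax(a, 0), df = function(a) (a > 0) * 1),
         gn_stop(sprintf("unknown activation '%s'", name),
                 "gennas_argument_error"))
}

glorot <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Build a trainable network from a topology
#'
#' Computes layer shapes, checks feasibility (the time axis must stay at
#' least one step long through all convolutions and poolings, and the total
#' parameter count must stay under `param_ceiling`) and initializes weights
#' (Glorot uniform; LSTM forget-gate bias 1).
#'
#' Infeasible topologies raise a condition of class `gennas_infeasible`,
#' which fitness evaluation maps to 0.
#'
#' @param spec a [topology_spec()].
#' @param n_channels input channels `C`.
#' @param n_classes output classes.
#' @param seed optional seed for weight initialization.
#' @param param_ceiling resource guard: maximum trainable parameter count
#'   before a topology is declared infeasible (out-of-memory surrogate).
#' @return an object of class `gn_model`.
#' @export
build_model <- function(spec, n_channels, n_classes, seed = NULL,
                        param_ceiling = 5e6) {
  stopifnot(inherits(spec, "topology_spec"))
  gn_assert(n_channels >= 1 && n_classes >= 2, "need channels and >= 2 classes")
  shapes <- model_shapes(spec, n_channels, n_classes)
  if (!shapes$feasible)
    gn_stop(shapes$reason, "gennas_infeasible")
  if (shapes$n_params > param_ceiling)
    gn_stop(sprintf("parameter count %d exceeds ceiling %g",
                    shapes$n_params, param_ceiling), "gennas_infeasible")
  shapes$n_classes <- as.integer(n_classes)
  layers <- with_seed(seed, init_layers(spec, shapes))
  structure(list(spec = spec, n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes), layers = layers,
                 n_params = shapes$n_params),
            class = "gn_model")
}

# Shape/feasibility bookkeeping shared by build_model and the resource guard.
model_shapes <- function(spec, n_channels, n_classes) {
  t <- spec$window_size; f <- n_channels
  n_params <- 0
  conv <- list()
  for (cl in spec$conv_layers) {
    if (t < cl$kernel_size)
      return(list(feasible = FALSE,
                  reason = sprintf(
                    "time axis (%d) shorter than kernel (%d)", t,
                    cl$kernel_size)))
    t_out <- t - cl$kernel_size + 1L
    if (cl$pool > 1) t_out <- t_out %/% cl$pool
    if (t_out < 1)
      return(list(feasible = FALSE, reason = "time axis collapsed by pooling"))
    n_params <- n_params + cl$kernel_size * f * cl$kernels + cl$kernels
    conv[[length(conv) + 1]] <- list(t_in = t, f_in = f, t_out = t_out,
                                     f_out = cl$kernels)
    t <- t_out; f <- cl$kernels
  }
  dense <- list()
  seq_now <- TRUE
  for (i in seq_along(spec$dense_layers)) {
    dl <- spec$dense_layers[[i]]
    nxt <- if (i < length(spec$dense_layers))
      spec$dense_layers[[i + 1]]$type else NA
    if (dl$type == "feedforward") {
      f_in <- if (seq_now) t * f else f
      n_params <- n_params + f_in * dl$units + dl$units
      dense[[i]] <- list(f_in = f_in, seq_out = FALSE)
      seq_now <- FALSE; f <- dl$units; t <- 1L
    } else {
      f_in <- f                       # flat input becomes a length-1 sequence
      gates <- if (dl$type == "LSTM") 4L else 3L
      n_params <- n_params + gates * dl$units * (f_in + dl$units + 1)
      ret_seq <- identical(nxt, "LSTM") || identical(nxt, "GRU")
      dense[[i]] <- list(f_in = f_in, seq_out = ret_seq)
      if (!seq_now) t <- 1L
      seq_now <- ret_seq
      f <- dl$units
      if (!ret_seq) t <- 1L
    }
  }
  f_last <- if (seq_now) t * f else f
  n_params <- n_params + f_last * n_classes + n_classes
  list(feasible = TRUE, conv = conv, dense = dense, f_last = f_last,
       n_params = n_params)
}

init_layers <- function(spec, shapes) {
  n_classes <- shapes$n_classes
  layers <- list()
  for (i in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[i]]; sh <- shapes$conv[[i]]
    layers[[length(layers) + 1]] <- list(
      kind = "conv", cs = cl$kernel_size, pool = cl$pool,
      act = cl$activation,
      params = list(W = glorot(cl$kernel_size * sh$f_in, cl$kernels),
                    b = numeric(cl$kernels)))
  }
  for (i in seq_along(spec$dense_layers)) {
    dl <- spec$dense_layers[[i]]; sh <- shapes$dense[[i]]
    u <- dl$units
    if (dl$type == "feedforward") {
      layers[[length(layers) + 1]] <- list(
        kind = "dense", act = dl$activation, dropout = dl$dropout,
        regularizer = dl$regularizer,
        params = list(W = glorot(sh$f_in, u), b = numeric(u)))
    } else if (dl$type == "LSTM") {
      b <- numeric(4 * u)
      b[(u + 1):(2 * u)] <- 1      # forget-gate bias
      layers[[length(layers) + 1]] <- list(
        kind = "lstm", act = dl$activation, dropout = dl$dropout,
        regularizer = dl$regularizer, units = u, seq_out = sh$seq_out,
        params = list(W = glorot(sh$f_in, 4 * u, c(sh$f_in, 4 * u)),
                      U = glorot(u, 4 * u, c(u, 4 * u)), b = b))
    } else {
      layers[[length(layers) + 1]] <- list(
        kind = "gru", act = dl$activation, dropout = dl$dropout,
        regularizer = dl$regularizer, units = u, seq_out = sh$seq_out,
        params = list(W = glorot(sh$f_in, 3 * u, c(sh$f_in, 3 * u)),
                      U = glorot(u, 3 * u, c(u, 3 * u)),
                      b = numeric(3 * u)))
    }
  }
  layers[[length(layers) + 1]] <- list(
    kind = "out",
    params = list(W = glorot(shapes$f_last, n_classes),
                  b = numeric(n_classes)))
  layers
}

## ---- layer forward/backward ------------------------------------------------

conv_fwd <- function(layer, S) {
  d <- dim(S); N <- d[[1]]; T <- d[[2]]; Cin <- d[[3]]
  cs <- layer$cs; ck <- length(layer$params$b)
  Tc <- T - cs + 1L
  Z <- matrix(rep(layer$params$b, each = N * Tc), N * Tc, ck)
  Xk <- vector("list", cs)
  for (k in seq_len(cs)) {
    xk <- S[, k:(k + Tc - 1L), , drop = FALSE]
    dim(xk) <- c(N * Tc, Cin)
    Xk[[k]] <- xk
    rows <- ((k - 1L) * Cin + 1L):(k * Cin)
    Z <- Z + xk %*% layer$params$W[rows, , drop = FALSE]
  }
  af <- act_fun(layer$act)
  A <- af$f(Z)
  cache <- list(Xk = Xk, Z = Z, N = N, T = T, Cin = Cin, Tc = Tc)
  dim(A) <- c(N, Tc, ck)
  if (layer$pool > 1) {
    cp <- layer$pool; Tp <- Tc %/% cp
    out <- A[, (seq_len(Tp) - 1L) * cp + 1L, , drop = FALSE]
    arg <- array(1L, dim(out))
    if (cp > 1) for (j in 2:cp) {
      Bj <- A[, (seq_len(Tp) - 1L) * cp + j, , drop = FALSE]
      m <- Bj > out
      out[m] <- Bj[m]; arg[m] <- j
    }
    cache$arg <- arg; cache$Tp <- Tp
    list(out = out, cache = cache)
  } else {
    list(out = A, cache = cache)
  }
}

conv_bwd <- function(layer, cache, dout) {
  N <- cache$N; Tc <- cache$Tc; Cin <- cache$Cin
  cs <- layer$cs; ck <- length(layer$params$b)
  if (layer$pool > 1) {
    cp <- layer$pool; Tp <- cache$Tp
    dA <- array(0, c(N, Tc, ck))
    for (j in seq_len(cp)) {
      m <- cache$arg == j
      dj <- array(0, c(N, Tp, ck)); dj[m] <- dout[m]
      dA[, (seq_len(Tp) - 1L) * cp + j, ] <-
        dA[, (seq_len(Tp) - 1L) * cp + j, , drop = FALSE] + dj
    }
  } else dA <- dout
  af <- act_fun(layer$act)
  dZ <- dA * array(af$df(cache$Z), dim(dA))
  dim(dZ) <- c(N * Tc, ck)
  dW <- matrix(0, cs * Cin, ck)
  dS <- array(0, c(N, cache$T, Cin))
  for (k in seq_len(cs)) {
    rows <- ((k - 1L) * Cin + 1L):(k * Cin)
    dW[rows, ] <- crossprod(cache$Xk[[k]], dZ)
    dxk <- dZ %*% t(layer$params$W[rows, , drop = FALSE])
    dim(dxk) <- c(N, Tc, Cin)
    dS[, k:(k + Tc - 1L), ] <- dS[, k:(k + Tc - 1L), , drop = FALSE] + dxk
  }
  list(grads = list(W = dW, b = colSums(dZ)), dS = dS)
}

dense_fwd <- function(layer, X, train) {
  if (length(dim(X)) == 3) { N <- dim(X)[[1]]; dim(X) <- c(N, prod(dim(X)[-1])) }
  Z <- X %*% layer$params$W
  Z <- sweep(Z, 2, layer$params$b, "+")
  af <- act_fun(layer$act)
  A <- af$f(Z)
  mask <- NULL
  if (train && layer$dropout > 0) {
    keep <- 1 - layer$dropout
    mask <- matrix(stats::rbinom(length(A), 1, keep) / keep, nrow(A), ncol(A))
    A <- A * mask
  }
  list(out = A, cache = list(X = X, Z = Z, mask = mask))
}

dense_bwd <- function(layer, cache, dout) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  af <- act_fun(layer$act)
  dZ <- dout * af$df(cache$Z)
  list(grads = list(W = crossprod(cache$X, dZ), b = colSums(dZ)),
       dS = dZ %*% t(layer$params$W))
}

as_sequence <- function(X) {
  if (length(dim(X)) == 3) X
  else array(X, c(nrow(X), 1L, ncol(X)))
}

lstm_fwd <- function(layer, S, train) {
  S <- as_sequence(S)
  N <- dim(S)[[1]]; T <- dim(S)[[2]]; u <- layer$units
  W <- layer$params$W; U <- layer$params$U; b <- layer$params$b
  af <- act_fun(layer$act)
  h <- matrix(0, N, u); cc <- matrix(0, N, u)
  steps <- vector("list", T)
  Hs <- if (layer$seq_out) array(0, c(N, T, u)) else NULL
  for (t in seq_len(T)) {
    Xt <- matrix(S[, t, ], N)
    A <- Xt %*% W + h %*% U + matrix(b, N, 4 * u, byrow = TRUE)
    i <- sigmoid(A[, 1:u, drop = FALSE])
    f <- sigmoid(A[, (u + 1):(2 * u), drop = FALSE])
    o <- sigmoid(A[, (2 * u + 1):(3 * u), drop = FALSE])
    Ag <- A[, (3 * u + 1):(4 * u), drop = FALSE]
    g <- af$f(Ag)
    c_prev <- cc
    cc <- f * c_prev + i * g
    hc <- af$f(cc)
    h_prev <- h
    h <- o * hc
    steps[[t]] <- list(Xt = Xt, i = i, f = f, o = o, g = g, Ag = Ag,
                       c_prev = c_prev, cc = cc, hc = hc, h_prev = h_prev)
    if (layer$seq_out) Hs[, t, ] <- h
  }
  out <- if (layer$seq_out) Hs else h
  mask <- NULL
  if (train && layer$dropout > 0) {
    keep <- 1 - layer$dropout
    mask <- array(stats::rbinom(length(out), 1, keep) / keep, dim(out))
    out <- out * mask
  }
  list(out = out, cache = list(steps = steps, N = N, T = T, mask = mask,
                               in_dim = dim(S)))
}

lstm_bwd <- function(layer, cache, dout) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  N <- cache$N; T <- cache$T; u <- layer$units
  W <- layer$params$W; U <- layer$params$U
  af <- act_fun(layer$act)
  dW <- array(0, dim(W)); dU <- array(0, dim(U)); db <- numeric(4 * u)
  dS <- array(0, cache$in_dim)
  dh_next <- matrix(0, N, u); dc_next <- matrix(0, N, u)
  for (t in rev(seq_len(T))) {
    st <- cache$steps[[t]]
    dh <- dh_next
    if (layer$seq_out) dh <- dh + matrix(dout[, t, ], N)
    else if (t == T) dh <- dh + dout
    do <- dh * st$hc
    dc <- dc_next + dh * st$o * af$df(st$cc)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_next <- dc * st$f
    dA <- cbind(di * st$i * (1 - st$i), df * st$f * (1 - st$f),
                do * st$o * (1 - st$o), dg * af$df(st$Ag))
    dW <- dW + crossprod(st$Xt, dA)
    dU <- dU + crossprod(st$h_prev, dA)
    db <- db + colSums(dA)
    dh_next <- dA %*% t(U)
    dS[, t, ] <- dA %*% t(W)
  }
  list(grads = list(W = dW, U = dU, b = db), dS = dS)
}

gru_fwd <- function(layer, S, train) {
  S <- as_sequence(S)
  N <- dim(S)[[1]]; T <- dim(S)[[2]]; u <- layer$units
  W <- layer$params$W; U <- layer$params$U; b <- layer$params$b
  af <- act_fun(layer$act)
  h <- matrix(0, N, u)
  steps <- vector("list", T)
  Hs <- if (layer$seq_out) array(0, c(N, T, u)) else NULL
  iz <- 1:u; ir <- (u + 1):(2 * u); ig <- (2 * u + 1):(3 * u)
  for (t in seq_len(T)) {
    Xt <- matrix(S[, t, ], N)
    AX <- Xt %*% W + matrix(b, N, 3 * u, byrow = TRUE)
    z <- sigmoid(AX[, iz, drop = FALSE] + h %*% U[, iz, drop = FALSE])
    r <- sigmoid(AX[, ir, drop = FALSE] + h %*% U[, ir, drop = FALSE])
    rh <- r * h
    Ag <- AX[, ig, drop = FALSE] + rh %*% U[, ig, drop = FALSE]
    g <- af$f(Ag)
    h_prev <- h
    h <- (1 - z) * h_prev + z * g
    steps[[t]] <- list(Xt = Xt, z = z, r = r, g = g, Ag = Ag, rh = rh,
                       h_prev = h_prev)
    if (layer$seq_out) Hs[, t, ] <- h
  }
  out <- if (layer$seq_out) Hs else h
  mask <- NULL
  if (train && layer$dropout > 0) {
    keep <- 1 - layer$dropout
    mask <- array(stats::rbinom(length(out), 1, keep) / keep, dim(out))
    out <- out * mask
  }
  list(out = out, cache = list(steps = steps, N = N, T = T, mask = mask,
                               in_dim = dim(S)))
}

gru_bwd <- function(layer, cache, dout) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  N <- cache$N; T <- cache$T; u <- layer$units
  W <- layer$params$W; U <- layer$params$U
  af <- act_fun(layer$act)
  iz <- 1:u; ir <- (u + 1):(2 * u); ig <- (2 * u + 1):(3 * u)
  dW <- array(0, dim(W)); dU <- array(0, dim(U)); db <- numeric(3 * u)
  dS <- array(0, cache$in_dim)
  dh_next <- matrix(0, N, u)
  for (t in rev(seq_len(T))) {
    st <- cache$steps[[t]]
    dh <- dh_next
    if (layer$seq_out) dh <- dh + matrix(dout[, t, ], N)
    else if (t == T) dh <- dh + dout
    dz <- dh * (st$g - st$h_prev)
    dg <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    dAg <- dg * af$df(st$Ag)
    drh <- dAg %*% t(U[, ig, drop = FALSE])
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    dAz <- dz * st$z * (1 - st$z)
    dAr <- dr * st$r * (1 - st$r)
    dh_prev <- dh_prev + dAz %*% t(U[, iz, drop = FALSE]) +
      dAr %*% t(U[, ir, drop = FALSE])
    dA <- cbind(dAz, dAr, dAg)
    dW <- dW + crossprod(st$Xt, dA)
    dU[, iz] <- dU[, iz] + crossprod(st$h_prev, dAz)
    dU[, ir] <- dU[, ir] + crossprod(st$h_prev, dAr)
    dU[, ig] <- dU[, ig] + crossprod(st$rh, dAg)
    db <- db + colSums(dA)
    dS[, t, ] <- dA %*% t(W)
    dh_next <- dh_prev
  }
  list(grads = list(W = dW, U = dU, b = db), dS = dS)
}

## ---- full network forward/backward -----------------------------------------

# X: N x w x C array (one window per row of the leading axis)
model_forward <- function(model, X, train = FALSE) {
  S <- X
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    r <- switch(layer$kind,
                conv = conv_fwd(layer, S),
                dense = dense_fwd(layer, S, train),
                lstm = lstm_fwd(layer, S, train),
                gru = gru_fwd(layer, S, train),
                out = {
                  if (length(dim(S)) == 3) dim(S) <- c(dim(S)[[1]],
                                                       prod(dim(S)[-1]))
                  Z <- sweep(S %*% layer$params$W, 2, layer$params$b, "+")
                  list(out = Z, cache = list(X = S))
                })
    r$cache$out_dim <- dim(r$out)
    caches[[li]] <- r$cache
    S <- r$out
  }
  list(logits = S, caches = caches)
}

model_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  d <- dlogits
  for (li in rev(seq_along(model$layers))) {
    layer <- model$layers[[li]]
    r <- switch(layer$kind,
                conv = conv_bwd(layer, caches[[li]], d),
                dense = dense_bwd(layer, caches[[li]], d),
                lstm = lstm_bwd(layer, caches[[li]], d),
                gru = gru_bwd(layer, caches[[li]], d),
                out = list(grads = list(W = crossprod(caches[[li]]$X, d),
                                        b = colSums(d)),
                           dS = d %*% t(layer$params$W)))
    grads[[li]] <- r$grads
    d <- r$dS
    # reshape the incoming gradient to the shape the producing layer emitted
    if (li > 1) dim(d) <- caches[[li - 1]]$out_dim
  }
  grads
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# cross-entropy loss and gradient; y is 0-based class index
softmax_xent <- function(logits, y) {
  N <- nrow(logits)
  P <- softmax_rows(logits)
  idx <- cbind(seq_len(N), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dlogits = dZ / N, probs = P)
}

## ---- optimizers ------------------------------------------------------------

#' Create an optimizer
#'
#' Returns a stateful updater implementing one of six learning rules:
#' SGD, AdaGrad, AdaDelta, RMSProp, Adam, Adamax. Hyperparameters other
#' than the learning rate use the customary defaults (rho = 0.9 / 0.95,
#' beta1 = 0.9, beta2 = 0.999, eps = 1e-7).
#'
#' @param name optimizer name.
#' @param lr learning rate.
#' @return a function `update(param, grad, key)` returning the new
#'   parameter value; `key` identifies the parameter slot for state.
#' @export
make_optimizer <- function(name, lr) {
  gn_assert(name %in% GN_OPTIMIZERS, sprintf("unknown optimizer '%s'", name))
  eps <- 1e-7
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  get_st <- function(key, init) {
    if (!exists(key, envir = st, inherits = FALSE)) st[[key]] <- init
    st[[key]]
  }
  step <- function() st$t <- st$t + 1L   # called once per minibatch
  update <- switch(
    name,
    SGD = function(p, g, key) p - lr * g,
    AdaGrad = function(p, g, key) {
      acc <- get_st(key, array(0, dim(as.array(g)))) + g^2
      st[[key]] <- acc
      p - lr * g / (sqrt(acc) + eps)
    },
    AdaDelta = function(p, g, key) {
      rho <- 0.95
      Eg <- get_st(paste0(key, ".Eg"), array(0, dim(as.array(g))))
      Ed <- get_st(paste0(key, ".Ed"), array(0, dim(as.array(g))))
      Eg <- rho * Eg + (1 - rho) * g^2
      dx <- -sqrt(Ed + eps) / sqrt(Eg + eps) * g
      Ed <- rho * Ed + (1 - rho) * dx^2
      st[[paste0(key, ".Eg")]] <- Eg; st[[paste0(key, ".Ed")]] <- Ed
      p + lr * dx
    },
    RMSProp = function(p, g, key) {
      rho <- 0.9
      Eg <- rho * get_st(key, array(0, dim(as.array(g)))) + (1 - rho) * g^2
      st[[key]] <- Eg
      p - lr * g / (sqrt(Eg) + eps)
    },
    Adam = function(p, g, key) {
      b1 <- 0.9; b2 <- 0.999; t <- st$t
      m <- b1 * get_st(paste0(key, ".m"), array(0, dim(as.array(g)))) +
        (1 - b1) * g
      v <- b2 * get_st(paste0(key, ".v"), array(0, dim(as.array(g)))) +
        (1 - b2) * g^2
      st[[paste0(key, ".m")]] <- m; st[[paste0(key, ".v")]] <- v
      mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
      p - lr * mh / (sqrt(vh) + eps)
    },
    Adamax = function(p, g, key) {
      b1 <- 0.9; b2 <- 0.999; t <- st$t
      m <- b1 * get_st(paste0(key, ".m"), array(0, dim(as.array(g)))) +
        (1 - b1) * g
      uu <- pmax(b2 * get_st(paste0(key, ".u"), array(0, dim(as.array(g)))),
                 abs(g))
      st[[paste0(key, ".m")]] <- m; st[[paste0(key, ".u")]] <- uu
      p - (lr / (1 - b1^t)) * m / (uu + eps)
    })
  list(update = update, step = step)
}

# one optimizer step over all layers, with regularization and norm clipping
apply_gradients <- function(model, grads, opt) {
  gnorm2 <- 0
  for (li in seq_along(grads))
    for (nm in names(grads[[li]]))
      gnorm2 <- gnorm2 + sum(grads[[li]][[nm]]^2)
  scale <- if (sqrt(gnorm2) > GN_CLIP_NORM) GN_CLIP_NORM / sqrt(gnorm2) else 1
  opt$step()
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    for (nm in names(layer$params)) {
      g <- grads[[li]][[nm]] * scale
      if (nm == "W" && !is.null(layer$regularizer)) {
        if (layer$regularizer == "L2")
          g <- g + 2 * GN_REG_LAMBDA * layer$params$W
        else if (layer$regularizer == "L1")
          g <- g + GN_REG_LAMBDA * sign(layer$params$W)
      }
      model$layers[[li]]$params[[nm]] <-
        opt$update(layer$params[[nm]], g, sprintf("L%d.%s", li, nm))
    }
  }
  model
}

#' Sum of absolute parameter values (initialization fingerprint)
#' @param model a `gn_model`.
#' @return a number.
#' @export
model_checksum <- function(model) {
  sum(vapply(model$layers, function(l)
    sum(vapply(l$params, function(p) sum(abs(p)), numeric(1))), numeric(1)))
}

#' @export
print.gn_model <- function(x, ...) {
  cat("<gn_model> ", n_conv(x$spec), " conv + ", n_dense(x$spec),
      " dense, ", x$n_params, " parameters, ", x$n_classes, " classes\n",
      sep = "")
  invisible(x)
}
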