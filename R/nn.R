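# Native 1-D CNN and LSTM regressors for spectra, trained with Adam on
# mean-squared error. Written in plain matrix algebra (no external deep
# learning runtime); batches are processed fully vectorized.

# ---- shared machinery ------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# Rows scaled to unit L2 norm (the "L2 normalize" input convention).
l2_normalize_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Clip the global gradient norm (keeps early LSTM epochs stable).
clip_grads <- function(grads, max_norm = 5) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

flat3 <- function(A) { d <- dim(A); dim(A) <- c(d[1] * d[2], d[3]); A }
unflat3 <- function(M, n, L) { dim(M) <- c(n, L, ncol(M)); M }

# im2col for kernel-3 "same" convolution on an (n, L, C) activation array:
# returns the (n*L) x (3C) design matrix of shifted channel blocks.
im2col3 <- function(A) {
  d <- dim(A); n <- d[1]; L <- d[2]; C <- d[3]
  Apad <- array(0, c(n, L + 2L, C))
  Apad[, 2:(L + 1L), ] <- A
  cbind(flat3(Apad[, 1:L, , drop = FALSE]),
        flat3(Apad[, 2:(L + 1L), , drop = FALSE]),
        flat3(Apad[, 3:(L + 2L), , drop = FALSE]))
}

# Adjoint of im2col3: scatter a (n*L) x (3C) gradient back onto (n, L, C).
col2im3 <- function(dM, n, L, C) {
  dApad <- array(0, c(n, L + 2L, C))
  for (o in 0:2) {
    blk <- unflat3(dM[, (o * C + 1L):((o + 1L) * C), drop = FALSE], n, L)
    dApad[, (1L + o):(L + o), ] <- dApad[, (1L + o):(L + o), , drop = FALSE] + blk
  }
  dApad[, 2:(L + 1L), , drop = FALSE]
}

# ---- 1-D convolutional network --------------------------------------------

cnn_init_params <- function(B, channels, pool_size) {
  cin <- c(1L, channels[-length(channels)])
  params <- list()
  for (l in seq_along(channels)) {
    fan_in <- 3L * cin[l]
    params[[paste0("W", l)]] <- matrix(rnorm(fan_in * channels[l], sd = sqrt(2 / fan_in)),
                                       fan_in, channels[l])
    params[[paste0("b", l)]] <- rep(0, channels[l])
  }
  L_pool <- if (B >= pool_size) B %/% pool_size else B
  n_flat <- L_pool * channels[length(channels)]
  params$Wfc <- matrix(rnorm(n_flat, sd = sqrt(1 / n_flat)), n_flat, 1)
  params$bfc <- 0
  params
}

cnn_forward <- function(X, params, channels, pool_size, dropout = 0,
                        train = FALSE) {
  n <- nrow(X); B <- ncol(X)
  A <- array(X, c(n, B, 1L))
  cache <- list(M = list(), Z = list())
  for (l in seq_along(channels)) {
    M <- im2col3(A)
    Z <- sweep(M %*% params[[paste0("W", l)]], 2L, params[[paste0("b", l)]], "+")
    A_new <- unflat3(pmax(Z, 0), n, B)
    cache$M[[l]] <- M
    cache$Z[[l]] <- Z
    A <- A_new
  }
  # max pooling (width = stride = pool_size) when the axis allows it
  do_pool <- B >= pool_size && pool_size > 1L
  if (do_pool) {
    Lp <- B %/% pool_size
    C <- dim(A)[3]
    slabs <- lapply(seq_len(pool_size), function(o) {
      A[, seq.int(o, by = pool_size, length.out = Lp), , drop = FALSE]
    })
    P <- slabs[[1]]; argmax <- array(1L, dim(P))
    for (o in 2:pool_size) {
      upd <- slabs[[o]] > P
      P[upd] <- slabs[[o]][upd]
      argmax[upd] <- o
    }
    cache$argmax <- argmax
  } else {
    Lp <- B; P <- A
  }
  Fm <- P; dim(Fm) <- c(n, Lp * dim(P)[3])
  if (train && dropout > 0) {
    mask <- matrix(runif(length(Fm)) >= dropout, nrow(Fm), ncol(Fm)) / (1 - dropout)
    Fm <- Fm * mask
    cache$drop_mask <- mask
  }
  cache$Fflat <- Fm
  cache$do_pool <- do_pool
  cache$Lp <- Lp
  out <- drop(Fm %*% params$Wfc) + params$bfc
  list(out = out, cache = cache)
}

cnn_backward <- function(X, params, channels, pool_size, fw, dout) {
  n <- nrow(X); B <- ncol(X)
  cache <- fw$cache
  grads <- list()
  dF <- outer(dout, drop(params$Wfc))
  grads$Wfc <- t(cache$Fflat) %*% matrix(dout, ncol = 1)
  grads$bfc <- sum(dout)
  if (!is.null(cache$drop_mask)) dF <- dF * cache$drop_mask
  C_last <- channels[length(channels)]
  if (cache$do_pool) {
    Lp <- cache$Lp
    dP <- dF; dim(dP) <- c(n, Lp, C_last)  # inverse of the (n, L*C) flatten
    dA <- array(0, c(n, B, C_last))
    for (o in seq_len(pool_size)) {
      sel <- cache$argmax == o
      slab <- array(0, dim(dP)); slab[sel] <- dP[sel]
      dA[, seq.int(o, by = pool_size, length.out = Lp), ] <- slab
    }
  } else {
    dA <- dF; dim(dA) <- c(n, B, C_last)
  }
  for (l in rev(seq_along(channels))) {
    dZ <- flat3(dA)
    dZ[cache$Z[[l]] <= 0] <- 0
    grads[[paste0("W", l)]] <- t(cache$M[[l]]) %*% dZ
    grads[[paste0("b", l)]] <- colSums(dZ)
    dM <- dZ %*% t(params[[paste0("W", l)]])
    C_in <- if (l == 1L) 1L else channels[l - 1L]
    dA <- col2im3(dM, n, B, C_in)
  }
  grads
}

# Train the CNN regressor; y is standardized internally.
cnn_train <- function(X, y, channels = c(16L, 32L, 64L), pool_size = 2L,
                      dropout = 0.5, lr = 0.001, epochs = 400L,
                      batch_size = 64L, seed = 1L) {
  X <- l2_normalize_rows(as_matrix(X))
  n <- nrow(X); B <- ncol(X)
  y_mean <- mean(y); y_sd <- sd(y)
  # constant target: train against zeros and pin predictions to the mean
  if (is.na(y_sd) || y_sd == 0) y_sd <- 0
  yt <- if (y_sd == 0) rep(0, length(y)) else (y - y_mean) / y_sd
  with_seed(seed, {
    params <- cnn_init_params(B, channels, pool_size)
    state <- adam_init(params)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq.int(1L, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        if (length(bi) < 2L) next
        fw <- cnn_forward(X[bi, , drop = FALSE], params, channels, pool_size,
                          dropout, train = TRUE)
        dout <- 2 * (fw$out - yt[bi]) / length(bi)
        grads <- cnn_backward(X[bi, , drop = FALSE], params, channels, pool_size, fw, dout)
        grads <- clip_grads(grads)
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params; state <- upd$state
      }
    }
    list(params = params, channels = channels, pool_size = pool_size,
         y_mean = y_mean, y_sd = y_sd, n_bands = B)
  })
}

cnn_predict <- function(model, X) {
  X <- l2_normalize_rows(as_matrix(X))
  out <- cnn_forward(X, model$params, model$channels, model$pool_size)$out
  out * model$y_sd + model$y_mean
}

# ---- LSTM ------------------------------------------------------------------

lstm_init_params <- function(H) {
  params <- list(
    Wx = matrix(rnorm(4L * H, sd = 0.3), 1L, 4L * H),
    Wh = matrix(rnorm(H * 4L * H, sd = sqrt(1 / H)), H, 4L * H),
    b  = rep(0, 4L * H),
    Wfc = matrix(rnorm(H, sd = sqrt(1 / H)), H, 1),
    bfc = 0
  )
  params$b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
  params
}

lstm_forward <- function(X, params, H, dropout = 0, train = FALSE) {
  n <- nrow(X); Tt <- ncol(X)
  gi <- 1:H; gf <- (H + 1L):(2L * H); gg <- (2L * H + 1L):(3L * H); go <- (3L * H + 1L):(4L * H)
  Hs <- array(0, c(n, H, Tt + 1L)); Cs <- array(0, c(n, H, Tt + 1L))
  I <- array(0, c(n, H, Tt)); Fg <- I; G <- I; O <- I; tC <- I
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  for (t in seq_len(Tt)) {
    Z <- X[, t, drop = FALSE] %*% params$Wx + h %*% params$Wh
    Z <- sweep(Z, 2L, params$b, "+")
    i <- sigmoid(Z[, gi, drop = FALSE]); f <- sigmoid(Z[, gf, drop = FALSE])
    g <- tanh(Z[, gg, drop = FALSE]);    o <- sigmoid(Z[, go, drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[, , t] <- i; Fg[, , t] <- f; G[, , t] <- g; O[, , t] <- o
    tC[, , t] <- tc; Hs[, , t + 1L] <- h; Cs[, , t + 1L] <- cc
  }
  Fm <- h
  drop_mask <- NULL
  if (train && dropout > 0) {
    drop_mask <- matrix(runif(length(Fm)) >= dropout, n, H) / (1 - dropout)
    Fm <- Fm * drop_mask
  }
  out <- drop(Fm %*% params$Wfc) + params$bfc
  list(out = out, Hs = Hs, Cs = Cs, I = I, Fg = Fg, G = G, O = O, tC = tC,
       Ffinal = Fm, drop_mask = drop_mask)
}

lstm_backward <- function(X, params, H, fw, dout) {
  n <- nrow(X); Tt <- ncol(X)
  grads <- list(Wx = params$Wx * 0, Wh = params$Wh * 0, b = params$b * 0,
                Wfc = t(fw$Ffinal) %*% matrix(dout, ncol = 1), bfc = sum(dout))
  dH <- outer(dout, drop(params$Wfc))
  if (!is.null(fw$drop_mask)) dH <- dH * fw$drop_mask
  dC <- matrix(0, n, H)
  for (t in rev(seq_len(Tt))) {
    i <- fw$I[, , t]; f <- fw$Fg[, , t]; g <- fw$G[, , t]; o <- fw$O[, , t]
    tc <- fw$tC[, , t]
    c_prev <- fw$Cs[, , t]
    h_prev <- fw$Hs[, , t]
    do_ <- dH * tc
    dC <- dC + dH * o * (1 - tc^2)
    di <- dC * g; dg <- dC * i; df <- dC * c_prev
    dZ <- cbind(di * i * (1 - i), df * f * (1 - f), dg * (1 - g^2), do_ * o * (1 - o))
    grads$Wx <- grads$Wx + crossprod(X[, t, drop = FALSE], dZ)
    grads$Wh <- grads$Wh + crossprod(h_prev, dZ)
    grads$b <- grads$b + colSums(dZ)
    dH <- dZ %*% t(params$Wh)
    dC <- dC * f
  }
  grads
}

lstm_train <- function(X, y, hidden_units = 20L, dropout = 0.5, lr = 0.001,
                       epochs = 40L, batch_size = 64L, seed = 1L) {
  X <- l2_normalize_rows(as_matrix(X))
  n <- nrow(X)
  y_mean <- mean(y); y_sd <- sd(y)
  # constant target: train against zeros and pin predictions to the mean
  if (is.na(y_sd) || y_sd == 0) y_sd <- 0
  yt <- if (y_sd == 0) rep(0, length(y)) else (y - y_mean) / y_sd
  with_seed(seed, {
    params <- lstm_init_params(hidden_units)
    state <- adam_init(params)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq.int(1L, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        if (length(bi) < 2L) next
        Xb <- X[bi, , drop = FALSE]
        fw <- lstm_forward(Xb, params, hidden_units, dropout, train = TRUE)
        dout <- 2 * (fw$out - yt[bi]) / length(bi)
        grads <- clip_grads(lstm_backward(Xb, params, hidden_units, fw, dout))
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params; state <- upd$state
      }
    }
    list(params = params, hidden_units = hidden_units,
         y_mean = y_mean, y_sd = y_sd, n_bands = ncol(X))
  })
}

lstm_predict <- function(model, X) {
  X <- l2_normalize_rows(as_matrix(X))
  out <- lstm_forward(X, model$params, model$hidden_units)$out
  out * model$y_sd + model$y_mean
}
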