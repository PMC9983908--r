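## Minimal CNN engine: conv 3x3 (same padding), batch normalization,
## relu, 2x2 max pooling, dense, dropout, softmax cross-entropy, Adamax.
## Activations for a batch of B images are held as a C x (H*W*B) matrix
## whose columns are grouped per image; convolution is im2col + one BLAS
## GEMM, with gather/scatter index tables precomputed per layer at build
## time.  Verified against a numerical-gradient oracle in the tests.

.conv_indices <- function(H, W) {
  Hp <- H + 2L; Wp <- W + 2L
  ii <- rep(2:(H + 1L), times = W)
  jj <- rep(2:(W + 1L), each = H)
  inner <- ii + (jj - 1L) * Hp
  offs <- expand.grid(di = -1:1, dj = -1:1)
  g <- vapply(seq_len(9), function(k) {
    (ii + offs$di[k]) + (jj + offs$dj[k] - 1L) * Hp
  }, integer(H * W))
  list(inner = inner, g = t(g), Hp = Hp, Wp = Wp)   # g: 9 x HW
}

.pool_indices <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(ab) {
    (2L * io - 1L + ab[1]) + (2L * jo - 2L + ab[2]) * H
  })
}

.layer_conv <- function(Cin, Cout, H, W) {
  idx <- .conv_indices(H, W)
  fan_in <- Cin * 9
  list(type = "conv", Cin = Cin, Cout = Cout, H = H, W = W, idx = idx,
       W_ = matrix(stats::rnorm(Cout * fan_in, 0, sqrt(2 / fan_in)), Cout, fan_in),
       b_ = numeric(Cout))
}

.layer_bn <- function(C) {
  list(type = "bn", C = C, gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C), momentum = 0.1, eps = 1e-5)
}

.layer_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       W_ = matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in),
       b_ = numeric(n_out))
}

.im2col_batch <- function(X, layer, B) {
  HW <- layer$H * layer$W
  C <- layer$Cin
  idx <- layer$idx
  gvec <- as.vector(idx$g)
  cols <- matrix(0, C * 9L, HW * B)
  xp <- matrix(0, C, idx$Hp * idx$Wp)
  for (b in seq_len(B)) {
    sel <- (b - 1L) * HW + seq_len(HW)
    xp[, idx$inner] <- X[, sel, drop = FALSE]
    cb <- xp[, gvec, drop = FALSE]
    dim(cb) <- c(C * 9L, HW)
    cols[, sel] <- cb
  }
  cols
}

.col2im_batch <- function(dcols, layer, B) {
  HW <- layer$H * layer$W
  C <- layer$Cin
  idx <- layer$idx
  dX <- matrix(0, C, HW * B)
  for (b in seq_len(B)) {
    sel <- (b - 1L) * HW + seq_len(HW)
    dxp <- matrix(0, C, idx$Hp * idx$Wp)
    db <- dcols[, sel, drop = FALSE]
    dim(db) <- c(C, 9L, HW)
    for (k in seq_len(9)) {
      gk <- idx$g[k, ]
      dxp[, gk] <- dxp[, gk] + db[, k, ]
    }
    dX[, sel] <- dxp[, idx$inner, drop = FALSE]
  }
  dX
}

.forward_layer <- function(layer, X, B, train) {
  switch(layer$type,
    conv = {
      cols <- .im2col_batch(X, layer, B)
      list(out = layer$W_ %*% cols + layer$b_, cache = list(cols = cols), layer = layer)
    },
    bn = {
      if (train) {
        mu <- rowMeans(X)
        v <- rowMeans(X^2) - mu^2
        layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
        layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
      } else {
        mu <- layer$run_mean
        v <- layer$run_var
      }
      ivar <- 1 / sqrt(v + layer$eps)
      xhat <- (X - mu) * ivar
      list(out = layer$gamma * xhat + layer$beta,
           cache = list(xhat = xhat, ivar = ivar), layer = layer)
    },
    relu = list(out = pmax(X, 0), cache = list(mask = X > 0), layer = layer),
    pool = {
      HW <- layer$H * layer$W
      HWo <- HW %/% 4L
      C <- nrow(X)
      Y <- matrix(-Inf, C, HWo * B)
      arg <- matrix(1L, C, HWo * B)
      for (b in seq_len(B)) {
        sin <- (b - 1L) * HW
        sout <- (b - 1L) * HWo + seq_len(HWo)
        for (k in seq_len(4)) {
          cand <- X[, sin + layer$p[[k]], drop = FALSE]
          upd <- cand > Y[, sout, drop = FALSE]
          Y[, sout][upd] <- cand[upd]
          arg[, sout][upd] <- k
        }
      }
      list(out = Y, cache = list(arg = arg), layer = layer)
    },
    flatten = {
      HW <- layer$H * layer$W
      dim(X) <- c(nrow(X) * HW, B)
      list(out = X, cache = NULL, layer = layer)
    },
    dense = list(out = layer$W_ %*% X + layer$b_, cache = list(x = X), layer = layer),
    dropout = {
      if (train && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- matrix(stats::rbinom(length(X), 1, keep), nrow(X)) / keep
        list(out = X * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(out = X, cache = list(mask = NULL), layer = layer)
      }
    },
    stop_arg("unknown layer type: ", layer$type)
  )
}

.backward_layer <- function(layer, cache, X_in, dY, B) {
  switch(layer$type,
    conv = {
      dW <- dY %*% t(cache$cols)
      db <- rowSums(dY)
      dcols <- crossprod(layer$W_, dY)
      list(dX = .col2im_batch(dcols, layer, B), grads = list(W_ = dW, b_ = db))
    },
    bn = {
      xhat <- cache$xhat
      N <- ncol(dY)
      dgamma <- rowSums(dY * xhat)
      dbeta <- rowSums(dY)
      dxhat <- dY * layer$gamma
      dX <- (cache$ivar / N) *
        (N * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
      list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dX = dY * cache$mask, grads = NULL),
    pool = {
      HW <- layer$H * layer$W
      HWo <- HW %/% 4L
      C <- nrow(dY)
      dX <- matrix(0, C, HW * B)
      for (b in seq_len(B)) {
        sin <- (b - 1L) * HW
        sout <- (b - 1L) * HWo + seq_len(HWo)
        for (k in seq_len(4)) {
          m <- cache$arg[, sout, drop = FALSE] == k
          tgt <- sin + layer$p[[k]]
          dX[, tgt] <- dX[, tgt] + dY[, sout, drop = FALSE] * m
        }
      }
      list(dX = dX, grads = NULL)
    },
    flatten = {
      C <- layer$C
      dim(dY) <- c(C, layer$H * layer$W * B)
      list(dX = dY, grads = NULL)
    },
    dense = list(dX = crossprod(layer$W_, dY),
                 grads = list(W_ = dY %*% t(cache$x), b_ = rowSums(dY))),
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = NULL)
      else list(dX = dY * cache$mask, grads = NULL)
    }
  )
}

.forward_pass <- function(model, X, B, train = FALSE) {
  caches <- vector("list", length(model$layers))
  inputs <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    inputs[i] <- list(X)
    r <- .forward_layer(model$layers[[i]], X, B, train)
    if (!is.null(r$layer)) model$layers[[i]] <- r$layer
    caches[i] <- list(r$cache)   # [i] <- list(): keep NULL caches as slots
    X <- r$out
  }
  list(out = X, caches = caches, inputs = inputs, model = model)
}

.softmax <- function(Z) {
  Z <- Z - rep(apply(Z, 2, max), each = nrow(Z))
  E <- exp(Z)
  E / rep(colSums(E), each = nrow(Z))
}

.backward_pass <- function(model, fw, dY, B) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    r <- .backward_layer(model$layers[[i]], fw$caches[[i]], fw$inputs[[i]], dY, B)
    grads[i] <- list(r$grads)    # keep NULL grads as slots

    dY <- r$dX
  }
  grads
}

## Adamax parameter update (infinity-norm variant of Adam)
.adamax_step <- function(model, grads, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  model$opt_t <- model$opt_t + 1L
  corr <- lr / (1 - b1^model$opt_t)
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      key <- paste0(i, ".", nm)
      m <- model$opt_m[[key]]
      u <- model$opt_u[[key]]
      if (is.null(m)) { m <- g[[nm]] * 0; u <- g[[nm]] * 0 }
      m <- b1 * m + (1 - b1) * g[[nm]]
      u <- pmax(b2 * u, abs(g[[nm]]))
      model$opt_m[[key]] <- m
      model$opt_u[[key]] <- u
      model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] - corr * m / (u + eps)
    }
  }
  model
}
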