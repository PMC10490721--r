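# Minimal neural-network engine: dense / ReLU / 3x3 convolution /
# 2x2 max-pool / global-average-pool layers with softmax cross-entropy
# and ADAM, all in base R on BLAS matrix products. Inputs are either
# N x D matrices (dense nets) or N x T x F x C arrays (convolutional
# nets). Gradients are exercised against numerical differentiation in
# the test suite.

he_init <- function(n_in, dims) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / n_in)), dim = dims)
}

nn_layer_dense <- function(d_in, d_out) {
  list(type = "dense", W = he_init(d_in, c(d_in, d_out)),
       b = numeric(d_out))
}
nn_layer_relu <- function() list(type = "relu")
nn_layer_conv <- function(c_in, n_f) {
  list(type = "conv", W = he_init(9 * c_in, c(9 * c_in, n_f)),
       b = numeric(n_f), c_in = c_in, n_f = n_f)
}
nn_layer_pool <- function() list(type = "pool")
nn_layer_gap <- function() list(type = "gap")
# parameter-free average-pool decimation by (kt, kf) along time and
# frequency; used to shrink redundant log-spectral inputs before the
# conv blocks
nn_layer_fpool <- function(kt, kf) {
  list(type = "fpool", kt = as.integer(kt), kf = as.integer(kf))
}

# im2col for valid 3x3 convolution on an (N, T, F, C) array:
# rows index (n, t, f) positions, columns the 9*C kernel taps.
im2col3 <- function(A) {
  d <- dim(A)
  N <- d[1]; T_ <- d[2]; F_ <- d[3]; C <- d[4]
  T2 <- T_ - 2L; F2 <- F_ - 2L
  cols <- vector("list", 9L)
  k <- 1L
  for (df in 0:2) {
    for (dt in 0:2) {
      sl <- A[, dt + seq_len(T2), df + seq_len(F2), , drop = FALSE]
      dim(sl) <- c(N * T2 * F2, C)
      cols[[k]] <- sl
      k <- k + 1L
    }
  }
  do.call(cbind, cols)
}

col2im3 <- function(dcol, d) {
  N <- d[1]; T_ <- d[2]; F_ <- d[3]; C <- d[4]
  T2 <- T_ - 2L; F2 <- F_ - 2L
  dA <- array(0, dim = d)
  k <- 1L
  for (df in 0:2) {
    for (dt in 0:2) {
      sl <- dcol[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
      dim(sl) <- c(N, T2, F2, C)
      dA[, dt + seq_len(T2), df + seq_len(F2), ] <-
        dA[, dt + seq_len(T2), df + seq_len(F2), , drop = FALSE] + sl
      k <- k + 1L
    }
  }
  dA
}

nn_forward_layer <- function(layer, x) {
  switch(layer$type,
    dense = {
      out <- sweep(x %*% layer$W, 2, layer$b, "+")
      list(out = out, cache = x)
    },
    relu = {
      out <- pmax(x, 0)
      list(out = out, cache = x > 0)
    },
    conv = {
      d <- dim(x)
      col <- im2col3(x)
      out <- sweep(col %*% layer$W, 2, layer$b, "+")
      dim(out) <- c(d[1], d[2] - 2L, d[3] - 2L, layer$n_f)
      list(out = out, cache = list(col = col, d_in = d))
    },
    pool = {
      d <- dim(x)
      T2 <- d[2] %/% 2L; F2 <- d[3] %/% 2L
      if (T2 == 0L || F2 == 0L) {
        stop("input too small for a 2x2 max-pool (", d[2], "x", d[3],
             "); reduce the decimation or the network depth", call. = FALSE)
      }
      it <- seq_len(T2) * 2L; jf <- seq_len(F2) * 2L
      a11 <- x[, it - 1L, jf - 1L, , drop = FALSE]
      a21 <- x[, it, jf - 1L, , drop = FALSE]
      a12 <- x[, it - 1L, jf, , drop = FALSE]
      a22 <- x[, it, jf, , drop = FALSE]
      out <- pmax(a11, a21, a12, a22)
      m11 <- a11 == out
      m21 <- a21 == out & !m11
      m12 <- a12 == out & !m11 & !m21
      m22 <- !m11 & !m21 & !m12
      list(out = out, cache = list(m = list(m11, m21, m12, m22), d_in = d))
    },
    gap = {
      d <- dim(x)
      B <- aperm(x, c(2, 3, 1, 4))
      dim(B) <- c(d[2] * d[3], d[1] * d[4])
      out <- matrix(colMeans(B), d[1], d[4])
      list(out = out, cache = d)
    },
    fpool = {
      d <- dim(x)
      kt <- layer$kt; kf <- layer$kf
      T2 <- d[2] %/% kt; F2 <- d[3] %/% kf
      x2 <- x[, seq_len(T2 * kt), seq_len(F2 * kf), , drop = FALSE]
      dim(x2) <- c(d[1], kt, T2, kf, F2, d[4])
      out <- array(0, dim = c(d[1], T2, F2, d[4]))
      for (it in seq_len(kt)) for (jf in seq_len(kf)) {
        sl <- x2[, it, , jf, , , drop = FALSE]
        dim(sl) <- c(d[1], T2, F2, d[4])
        out <- out + sl
      }
      out <- out / (kt * kf)
      list(out = out, cache = d)
    },
    stop("unknown layer type: ", layer$type)
  )
}

nn_backward_layer <- function(layer, dout, cache) {
  switch(layer$type,
    dense = list(dx = dout %*% t(layer$W),
                 grads = list(W = crossprod(cache, dout),
                              b = colSums(dout))),
    relu = list(dx = dout * cache, grads = NULL),
    conv = {
      d <- dim(dout)
      dmat <- dout
      dim(dmat) <- c(d[1] * d[2] * d[3], d[4])
      dW <- crossprod(cache$col, dmat)
      db <- colSums(dmat)
      dcol <- dmat %*% t(layer$W)
      list(dx = col2im3(dcol, cache$d_in), grads = list(W = dW, b = db))
    },
    pool = {
      d <- cache$d_in
      T2 <- d[2] %/% 2L; F2 <- d[3] %/% 2L
      it <- seq_len(T2) * 2L; jf <- seq_len(F2) * 2L
      dx <- array(0, dim = d)
      m <- cache$m
      dx[, it - 1L, jf - 1L, ] <- dout * m[[1]]
      dx[, it, jf - 1L, ] <- dx[, it, jf - 1L, , drop = FALSE] + dout * m[[2]]
      dx[, it - 1L, jf, ] <- dx[, it - 1L, jf, , drop = FALSE] + dout * m[[3]]
      dx[, it, jf, ] <- dx[, it, jf, , drop = FALSE] + dout * m[[4]]
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache
      nm <- d[2] * d[3]
      dB <- matrix(rep(as.vector(dout) / nm, each = nm), nm, d[1] * d[4])
      dim(dB) <- c(d[2], d[3], d[1], d[4])
      list(dx = aperm(dB, c(3, 1, 2, 4)), grads = NULL)
    },
    fpool = {
      d <- cache
      kt <- layer$kt; kf <- layer$kf
      T2 <- d[2] %/% kt; F2 <- d[3] %/% kf
      d6 <- array(0, dim = c(d[1], kt, T2, kf, F2, d[4]))
      g <- dout / (kt * kf)
      dim(g) <- c(d[1], 1L, T2, 1L, F2, d[4])
      for (it in seq_len(kt)) for (jf in seq_len(kf)) {
        d6[, it, , jf, , ] <- g
      }
      dim(d6) <- c(d[1], kt * T2, kf * F2, d[4])
      dx <- array(0, dim = d)
      dx[, seq_len(kt * T2), seq_len(kf * F2), ] <- d6
      list(dx = dx, grads = NULL)
    }
  )
}

nn_forward <- function(model, x, with_cache = FALSE) {
  caches <- if (with_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    r <- nn_forward_layer(model$layers[[i]], x)
    x <- r$out
    if (with_cache) caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy loss over integer labels y in 0..(K-1); returns loss and
# the gradient at the logits.
softmax_xent <- function(logits, y) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dz <- p
  dz[idx] <- dz[idx] - 1
  list(loss = loss, dz = dz / n)
}

nn_backward <- function(model, caches, dz) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    r <- nn_backward_layer(model$layers[[i]], dz, caches[[i]])
    dz <- r$dx
    grads[i] <- list(r$grads)     # may be NULL; keep the slot
  }
  grads
}

adam_state <- function(model) {
  lapply(model$layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b)))
  })
}

adam_step <- function(model, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - b1^t
  corr2 <- 1 - b2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    model$layers[[i]]$W <- model$layers[[i]]$W -
      lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    model$layers[[i]]$b <- model$layers[[i]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}

nn_accuracy <- function(model, x, y) {
  p <- nn_forward(model, x)$out
  mean(max.col(p, ties.method = "first") - 1L == y)
}

nn_loss <- function(model, x, y) {
  softmax_xent(nn_forward(model, x)$out, y)$loss
}

# One full training run with early stopping on validation-1 accuracy;
# the weights of the best validation-1 epoch are restored at the end.
nn_train_run <- function(model, x, y, xv1, yv1, lr, batch_size = 16,
                         max_epochs = 200, patience = 20) {
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  state <- adam_state(model)
  t_step <- 0
  best_acc <- -Inf
  best_model <- model
  best_epoch <- 0L
  wait <- 0L
  take <- function(a, idx) {
    if (is.matrix(a)) a[idx, , drop = FALSE] else a[idx, , , , drop = FALSE]
  }
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(n, s + batch_size - 1L)]
      fw <- nn_forward(model, take(x, idx), with_cache = TRUE)
      l <- softmax_xent(fw$out, y[idx])
      grads <- nn_backward(model, fw$caches, l$dz)
      t_step <- t_step + 1
      up <- adam_step(model, grads, state, lr, t_step)
      model <- up$model
      state <- up$state
    }
    acc <- nn_accuracy(model, xv1, yv1)
    if (acc > best_acc + 1e-12) {
      best_acc <- acc
      best_model <- model
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > patience) break
    }
  }
  list(model = best_model, val1_acc = best_acc, epochs = epoch,
       best_epoch = best_epoch)
}
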