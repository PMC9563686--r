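# Internal neural-network primitives for the variational autoencoder.
#
# Layers are plain lists; forward passes return the output plus whatever the
# backward pass needs (the cache). All matrices are batch x features so the
# heavy lifting is dense BLAS gemm calls. Gradients follow the standard
# fully-connected / batch-normalization / ELU formulas.

layer_dense <- function(n_in, n_out) {
  # He-style initialization, suited to ELU nonlinearities
  list(type = "dense",
       W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

layer_batchnorm <- function(n, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", gamma = rep(1, n), beta = rep(0, n),
       running_mean = rep(0, n), running_var = rep(1, n),
       momentum = momentum, eps = eps)
}

layer_elu <- function(alpha = 1) list(type = "elu", alpha = alpha)

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    dense = {
      out <- x %*% layer$W
      out <- sweep(out, 2L, layer$b, "+")
      list(out = out, cache = list(x = x))
    },
    batchnorm = {
      if (training) {
        m <- colMeans(x)
        v <- colMeans(x^2) - m^2            # population variance of the batch
        v <- pmax(v, 0)
      } else {
        m <- layer$running_mean
        v <- layer$running_var
      }
      inv <- 1 / sqrt(v + layer$eps)
      xc <- sweep(x, 2L, m, "-")
      xhat <- sweep(xc, 2L, inv, "*")
      out <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
      list(out = out,
           cache = list(xc = xc, xhat = xhat, inv = inv,
                        batch_mean = m, batch_var = v, training = training))
    },
    elu = {
      out <- ifelse(x > 0, x, layer$alpha * (exp(pmin(x, 50)) - 1))
      list(out = out, cache = list(x = x, out = out))
    },
    stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    dense = {
      list(dx = dout %*% t(layer$W),
           grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
    },
    batchnorm = {
      n <- nrow(cache$xhat)
      dgamma <- colSums(dout * cache$xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2L, layer$gamma, "*")
      if (cache$training && n > 1L) {
        # backprop through the batch statistics
        t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
        t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
        dx <- sweep(t1 - t2, 2L, cache$inv, "*")
      } else {
        dx <- sweep(dxhat, 2L, cache$inv, "*")
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    elu = {
      grad <- ifelse(cache$x > 0, 1, cache$out + layer$alpha)
      list(dx = dout * grad, grads = NULL)
    })
}

# Update running batch-norm statistics after a training forward pass
layer_update_running <- function(layer, cache) {
  if (layer$type == "batchnorm" && isTRUE(cache$training)) {
    mom <- layer$momentum
    layer$running_mean <- mom * layer$running_mean + (1 - mom) * cache$batch_mean
    layer$running_var <- mom * layer$running_var + (1 - mom) * cache$batch_var
  }
  layer
}

stack_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

stack_backward <- function(layers, dout, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], dout, caches[[i]])
    dout <- bw$dx
    grads[i] <- list(bw$grads)   # keep NULL slots (parameter-free layers)
  }
  list(dx = dout, grads = grads)
}

# Adam optimizer state and update over a nested grads structure ------------

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.list(p)) adam_init(p)
    else list(m = p * 0, v = p * 0)
  })
}

adam_step <- function(param, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Apply Adam to every trainable parameter of a layer list
layers_adam_update <- function(layers, grads, states, lr, t) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- adam_step(layers[[i]][[nm]], g[[nm]], states[[i]][[nm]], lr, t)
      layers[[i]][[nm]] <- st$param
      states[[i]][[nm]] <- st$state
    }
  }
  list(layers = layers, states = states)
}

layers_adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- intersect(names(l), c("W", "b", "gamma", "beta"))
    if (!length(nm)) return(NULL)
    stats::setNames(lapply(nm, function(n) list(m = l[[n]] * 0, v = l[[n]] * 0)), nm)
  })
}

layers_n_params <- function(layers) {
  sum(vapply(layers, function(l) {
    nm <- intersect(names(l), c("W", "b", "gamma", "beta"))
    sum(vapply(nm, function(n) length(l[[n]]), 0L))
  }, 0))
}
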