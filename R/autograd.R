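# Minimal reverse-mode automatic differentiation on dense matrices.
#
# All trainable models in the package (structure-scale encoders, the
# network-scale GIN, the pair classifiers) are expressed as compositions of the
# primitives below. A "tape" records nodes in creation order (which is a valid
# topological order); ag_backward() walks it in reverse, accumulating gradients
# into nodes created with ag_param(). Sparse constants (normalized adjacencies,
# incidence/pooling matrices) enter through ag_spmm() and are never
# differentiated.

ag_tape <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- vector("list", 64L)
  env$n <- 0L
  env
}

ag_push <- function(tape, value, parents = list(), backward = NULL,
                    param_name = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$param_name <- param_name
  node$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  node$id <- tape$n
  tape$nodes[[tape$n]] <- node
  node
}

#' @noRd
ag_const <- function(tape, x) {
  ag_push(tape, as.matrix(x))
}

# Parameter leaf: gradients are collected under `name` by ag_backward().
ag_param <- function(tape, x, name) {
  ag_push(tape, as.matrix(x), param_name = name)
}

ag_value <- function(node) node$value

# Walk the tape backwards from `loss` (a 1x1 node); returns a named list of
# gradients for every parameter node reached.
ag_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  grads <- list()
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad)) next
    if (!is.null(node$param_name)) {
      nm <- node$param_name
      grads[[nm]] <- if (is.null(grads[[nm]])) node$grad else grads[[nm]] + node$grad
    }
    if (is.null(node$backward)) next
    pgrads <- node$backward(node$grad, node)
    for (k in seq_along(node$parents)) {
      pg <- pgrads[[k]]
      if (is.null(pg)) next
      p <- node$parents[[k]]
      p$grad <- if (is.null(p$grad)) pg else p$grad + pg
    }
  }
  grads
}

ag_matmul <- function(tape, a, b) {
  ag_push(tape, a$value %*% b$value, list(a, b), function(g, node) {
    list(g %*% t(node$parents[[2]]$value), t(node$parents[[1]]$value) %*% g)
  })
}

# Sparse-constant times dense: S is a Matrix::sparseMatrix, not differentiated.
ag_spmm <- function(tape, S, b) {
  node <- ag_push(tape, as.matrix(S %*% b$value), list(b), function(g, node) {
    list(as.matrix(Matrix::crossprod(node$S, g)))
  })
  node$S <- S
  node
}

# Elementwise add; b may be a 1 x d row (bias broadcast over rows).
ag_add <- function(tape, a, b) {
  broadcast <- nrow(b$value) == 1L && nrow(a$value) > 1L
  val <- if (broadcast) sweep(a$value, 2L, b$value[1L, ], "+") else a$value + b$value
  ag_push(tape, val, list(a, b), function(g, node) {
    gb <- if (nrow(node$parents[[2]]$value) == 1L && nrow(g) > 1L) {
      matrix(colSums(g), 1L)
    } else g
    list(g, gb)
  })
}

# Elementwise product; b may be a 1 x d row broadcast over rows.
ag_mul <- function(tape, a, b) {
  broadcast <- nrow(b$value) == 1L && nrow(a$value) > 1L
  val <- if (broadcast) sweep(a$value, 2L, b$value[1L, ], "*") else a$value * b$value
  ag_push(tape, val, list(a, b), function(g, node) {
    av <- node$parents[[1]]$value; bv <- node$parents[[2]]$value
    if (nrow(bv) == 1L && nrow(g) > 1L) {
      list(sweep(g, 2L, bv[1L, ], "*"), matrix(colSums(g * av), 1L))
    } else {
      list(g * bv, g * av)
    }
  })
}

ag_scale <- function(tape, a, s) {
  node <- ag_push(tape, a$value * s, list(a), function(g, node) list(g * node$s_))
  node$s_ <- s
  node
}

ag_relu <- function(tape, a) {
  ag_push(tape, pmax(a$value, 0), list(a), function(g, node) {
    list(g * (node$parents[[1]]$value > 0))
  })
}

ag_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  node <- ag_push(tape, v, list(a), function(g, node) {
    list(g * node$value * (1 - node$value))
  })
  node
}

# Select rows (gather); backward scatter-adds into the source rows.
ag_rows <- function(tape, a, idx) {
  node <- ag_push(tape, a$value[idx, , drop = FALSE], list(a), function(g, node) {
    gb <- matrix(0, nrow(node$parents[[1]]$value), ncol(g))
    acc <- rowsum(g, group = node$idx_)
    gb[as.integer(rownames(acc)), ] <- acc
    list(gb)
  })
  node$idx_ <- as.integer(idx)
  node
}

# Assemble a single N x d matrix from several nodes, placing the rows of
# nodes[[k]] at positions idx_list[[k]]; backward routes row gradients back.
ag_scatter_rows <- function(tape, nodes, idx_list, N) {
  d <- ncol(nodes[[1L]]$value)
  val <- matrix(0, N, d)
  for (k in seq_along(nodes)) val[idx_list[[k]], ] <- nodes[[k]]$value
  node <- ag_push(tape, val, nodes, function(g, node) {
    lapply(node$idx_list_, function(idx) g[idx, , drop = FALSE])
  })
  node$idx_list_ <- idx_list
  node
}

ag_cbind <- function(tape, a, b) {
  ag_push(tape, cbind(a$value, b$value), list(a, b), function(g, node) {
    da <- ncol(node$parents[[1]]$value)
    list(g[, seq_len(da), drop = FALSE], g[, -seq_len(da), drop = FALSE])
  })
}

ag_mean <- function(tape, a) {
  node <- ag_push(tape, matrix(mean(a$value), 1L, 1L), list(a), function(g, node) {
    list(matrix(g[1L] / length(node$parents[[1]]$value),
                nrow(node$parents[[1]]$value), ncol(node$parents[[1]]$value)))
  })
  node
}

# Replace every row by the column mean (used by scale-ablation forward passes).
ag_rowmean_broadcast <- function(tape, a) {
  n <- nrow(a$value)
  val <- matrix(colMeans(a$value), n, ncol(a$value), byrow = TRUE)
  ag_push(tape, val, list(a), function(g, node) {
    n <- nrow(g)
    list(matrix(colSums(g) / n, n, ncol(g), byrow = TRUE))
  })
}

# Batch normalization over rows (per-column batch statistics).
# state: environment with running_mean / running_var; training switches between
# batch statistics (and running-stat updates) and stored statistics.
ag_batchnorm <- function(tape, a, state, training, momentum = 0.1, eps = 1e-5) {
  x <- a$value
  n <- nrow(x)
  if (training && n > 1L) {
    mu <- colMeans(x)
    va <- colMeans(sweep(x, 2L, mu, "-")^2)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  sd_ <- sqrt(va + eps)
  xhat <- sweep(sweep(x, 2L, mu, "-"), 2L, sd_, "/")
  node <- ag_push(tape, xhat, list(a), function(g, node) {
    if (node$train_) {
      # dx = (g - mean(g) - xhat * mean(g * xhat)) / sd, per column
      xh <- node$value
      gm <- colMeans(g)
      gx <- colMeans(g * xh)
      dx <- sweep(g, 2L, gm, "-") - sweep(xh, 2L, gx, "*")
      dx <- sweep(dx, 2L, node$sd_, "/")
      list(dx)
    } else {
      list(sweep(g, 2L, node$sd_, "/"))
    }
  })
  node$sd_ <- sd_
  node$train_ <- training && n > 1L
  node
}

# Layer normalization over columns (per-row statistics), as in the geometric
# encoder's residual update.
ag_layernorm <- function(tape, a, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  va <- rowMeans(sweep(x, 1L, mu, "-")^2)
  sd_ <- sqrt(va + eps)
  xhat <- sweep(sweep(x, 1L, mu, "-"), 1L, sd_, "/")
  node <- ag_push(tape, xhat, list(a), function(g, node) {
    xh <- node$value
    d <- ncol(g)
    gm <- rowMeans(g)
    gx <- rowMeans(g * xh)
    dx <- sweep(g, 1L, gm, "-") - sweep(xh, 1L, gx, "*")
    dx <- sweep(dx, 1L, node$sd_, "/")
    list(dx)
  })
  node$sd_ <- sd_
  node
}

# Inverted dropout; the mask is drawn from the current RNG stream so runs are
# reproducible under a fixed seed.
ag_dropout <- function(tape, a, p, training) {
  if (!training || p <= 0) return(a)
  mask <- matrix(stats::rbinom(length(a$value), 1L, 1 - p), nrow(a$value)) / (1 - p)
  node <- ag_push(tape, a$value * mask, list(a), function(g, node) {
    list(g * node$mask_)
  })
  node$mask_ <- mask
  node
}

# Mean binary cross-entropy with logits (numerically stable); `y` is a constant
# target matrix in [0,1] (hard labels or soft pseudo-label distributions).
ag_bce_logits <- function(tape, z, y) {
  zv <- z$value
  loss <- mean(pmax(zv, 0) - zv * y + log1p(exp(-abs(zv))))
  node <- ag_push(tape, matrix(loss, 1L, 1L), list(z), function(g, node) {
    zv <- node$parents[[1]]$value
    p <- 1 / (1 + exp(-zv))
    list(g[1L] * (p - node$y_) / length(zv))
  })
  node$y_ <- y
  node
}

# Mean softmax cross-entropy over rows; `y` rows are probability vectors.
ag_softmax_ce <- function(tape, z, y) {
  zv <- z$value
  zs <- sweep(zv, 1L, apply(zv, 1L, max), "-")
  lse <- log(rowSums(exp(zs)))
  logp <- sweep(zs, 1L, lse, "-")
  loss <- -mean(rowSums(y * logp))
  node <- ag_push(tape, matrix(loss, 1L, 1L), list(z), function(g, node) {
    p <- exp(node$logp_)
    list(g[1L] * (p - node$y_) / nrow(p))
  })
  node$y_ <- y
  node$logp_ <- logp
  node
}

# ---- parameter containers and the optimizer -------------------------------

# Xavier/Glorot-uniform initialization from the current RNG stream.
nn_linear <- function(d_in, d_out) {
  lim <- sqrt(6 / (d_in + d_out))
  list(W = matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out),
       b = matrix(0, 1L, d_out))
}

nn_bn_state <- function(d) {
  env <- new.env(parent = emptyenv())
  env$running_mean <- rep(0, d)
  env$running_var <- rep(1, d)
  env
}

bn_state_clone <- function(state) {
  env <- new.env(parent = emptyenv())
  env$running_mean <- state$running_mean
  env$running_var <- state$running_var
  env
}

# AdamW with decoupled weight decay over a flat named list of matrices.
adamw_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 1e-2) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    decay <- if (grepl("\\.b$|_b$", nm)) 0 else weight_decay
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + decay * params[[nm]])
  }
  list(params = params, state = state)
}
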