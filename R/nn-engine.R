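# Reverse-mode gradient engine for the 1D network.
#
# Tensors are dense arrays of dim (L, N, C): sample position, batch, channel.
# With this layout the (L*N, C) matrix view needed by the GEMM-based
# convolution and by batch normalization is a free `dim<-`, and concatenation
# along channels is plain vector concatenation. A forward pass records nodes
# on a tape (creation order = topological order); backward walks the tape in
# reverse, each node scattering its gradient to its parents. Parameters are
# environments carrying $val/$grad plus Adam state.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tp, val, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val; nd$grad <- NULL; nd$parents <- parents; nd$bw <- bw
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- nd
  nd
}

ad_param <- function(val) {
  p <- new.env(parent = emptyenv())
  p$val <- val; p$grad <- NULL
  p$m <- NULL; p$v <- NULL            # Adam moments, allocated lazily
  p
}

ad_zero_grads <- function(params) for (p in params) p$grad <- NULL

# backpropagate from a scalar loss node through every recorded node
ad_backward <- function(tp, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

# (L*N, C) matrix whose rows are zero-padded shifts along the sample axis:
# out[t, n] = m[t + off, n]; M has L*N rows grouped sample-major
shift_rows <- function(M, off, L, N) {
  if (off == 0L) return(M)
  t_src <- seq_len(L) + off
  bad <- t_src < 1L | t_src > L
  t_src[bad] <- 1L
  idx <- rep(seq.int(0L, by = L, length.out = N), each = L) + t_src
  Ms <- M[idx, , drop = FALSE]
  Ms[rep.int(bad, N), ] <- 0
  Ms
}

# same-padding 1D convolution; cv$w is a (C_in * k, C_out) matrix with rows
# ordered channel-fastest within kernel tap; cv$b (length-C_out bias) is NULL
# for convolutions feeding a batch-normalization layer, which would cancel it
op_conv1d <- function(tp, x, cv, k) {
  xv <- x$val
  d <- dim(xv); L <- d[1L]; N <- d[2L]; C_in <- d[3L]
  p <- (k - 1L) %/% 2L
  Xm <- xv; dim(Xm) <- c(L * N, C_in)
  M <- if (k == 1L) Xm else {
    cols <- vector("list", k)
    for (j in seq_len(k)) cols[[j]] <- shift_rows(Xm, j - 1L - p, L, N)
    do.call(cbind, cols)
  }
  Y <- M %*% cv$w$val
  C_out <- ncol(Y)
  has_bias <- !is.null(cv$b)
  if (has_bias) Y <- Y + rep(cv$b$val, each = L * N)
  dim(Y) <- c(L, N, C_out)
  parents <- if (has_bias) list(x, cv$w, cv$b) else list(x, cv$w)
  ad_node(tp, Y, parents = parents, bw = function(g) {
    dim(g) <- c(L * N, C_out)
    gW <- crossprod(M, g)
    gXm <- g %*% t(cv$w$val)            # (L*N, C_in * k)
    if (k == 1L) gx <- gXm else {
      gx <- matrix(0, L * N, C_in)
      for (j in seq_len(k)) {
        off <- j - 1L - p
        gx <- gx + shift_rows(gXm[, ((j - 1L) * C_in + 1L):(j * C_in), drop = FALSE],
                              -off, L, N)
      }
    }
    dim(gx) <- d
    if (has_bias) list(gx, gW, colSums(g)) else list(gx, gW)
  })
}

# batch normalization over (position, batch) per channel
op_batchnorm <- function(tp, x, bn, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x$val); L <- d[1L]; N <- d[2L]; C <- d[3L]
  m <- L * N
  xm <- x$val; dim(xm) <- c(m, C)
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    va <- colMeans(xc^2)
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    bn$run_var  <- (1 - momentum) * bn$run_var + momentum * va
  } else {
    mu <- bn$run_mean
    xc <- xm - rep(mu, each = m)
    va <- bn$run_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  a <- bn$gamma$val * inv_sd
  ym <- xc * rep(a, each = m) + rep(bn$beta$val, each = m)
  dim(ym) <- d
  ad_node(tp, ym, parents = list(x, bn$gamma, bn$beta), bw = function(g) {
    dim(g) <- c(m, C)
    gbeta <- colSums(g)
    s_xc <- colSums(g * xc)
    ggamma <- s_xc * inv_sd
    if (train) {
      # d/dx of gamma * (x - mu)/sqrt(var + eps) with batch statistics
      gxm <- (g - rep(gbeta / m, each = m) -
                xc * rep(inv_sd^2 * s_xc / m, each = m)) * rep(a, each = m)
    } else {
      gxm <- g * rep(a, each = m)
    }
    dim(gxm) <- d
    list(gxm, ggamma, gbeta)
  })
}

op_relu <- function(tp, x) {
  mask <- x$val > 0
  ad_node(tp, x$val * mask, parents = list(x), bw = function(g) list(g * mask))
}

op_add <- function(tp, a, b) {
  ad_node(tp, a$val + b$val, parents = list(a, b), bw = function(g) list(g, g))
}

# concatenate along the channel axis (last margin: plain vector concat)
op_concat <- function(tp, xs) {
  d1 <- dim(xs[[1L]]$val)
  Cs <- vapply(xs, function(x) dim(x$val)[3L], 0L)
  out <- unlist(lapply(xs, function(x) as.vector(x$val)), use.names = FALSE)
  dim(out) <- c(d1[1L], d1[2L], sum(Cs))
  ends <- cumsum(Cs)
  ad_node(tp, out, parents = xs, bw = function(g) {
    lapply(seq_along(xs), function(i)
      g[, , (ends[i] - Cs[i] + 1L):ends[i], drop = FALSE])
  })
}

# non-overlapping max-pooling by a factor of 2 along the sample axis
op_maxpool2 <- function(tp, x) {
  d <- dim(x$val); L <- d[1L]
  odd <- x$val[seq(1L, L, 2L), , , drop = FALSE]
  even <- x$val[seq(2L, L, 2L), , , drop = FALSE]
  take_odd <- odd >= even
  ad_node(tp, pmax(odd, even), parents = list(x), bw = function(g) {
    gx <- array(0, d)
    gx[seq(1L, L, 2L), , ] <- g * take_odd
    gx[seq(2L, L, 2L), , ] <- g * !take_odd
    list(gx)
  })
}

op_maxpool <- function(tp, x, factor) {
  q <- as.integer(round(log2(factor)))
  for (i in seq_len(q)) x <- op_maxpool2(tp, x)
  x
}

# nearest-neighbour upsampling by an integer factor along the sample axis
op_upnearest <- function(tp, x, factor) {
  if (factor == 1L) return(x)
  d <- dim(x$val); L <- d[1L]; N <- d[2L]; C <- d[3L]
  idx <- rep(seq_len(L), each = factor)
  ad_node(tp, x$val[idx, , , drop = FALSE], parents = list(x), bw = function(g) {
    dim(g) <- c(factor, L * N * C)
    gx <- colSums(g)
    dim(gx) <- d
    list(gx)
  })
}

# mean-squared-error loss between a prediction node and a fixed target array
op_mse <- function(tp, pred, target) {
  diff <- pred$val - target
  m <- length(diff)
  ad_node(tp, sum(diff^2) / m, parents = list(pred),
          bw = function(g) list((2 * g / m) * diff))
}

# mean of several scalar loss nodes (deep supervision)
op_mean_scalar <- function(tp, losses) {
  k <- length(losses)
  ad_node(tp, mean(vapply(losses, `[[`, 0, "val")), parents = losses,
          bw = function(g) rep(list(g / k), k))
}

# ---- parameter construction ------------------------------------------------

# uniform fan-in initialisation for a conv kernel (C_in * k, C_out)
init_conv <- function(c_in, c_out, k, bias = TRUE) {
  s <- sqrt(6 / (c_in * k))
  list(w = ad_param(matrix(stats::runif(c_in * k * c_out, -s, s), c_in * k, c_out)),
       b = if (bias) ad_param(numeric(c_out)))
}

init_bn <- function(c) {
  bn <- new.env(parent = emptyenv())
  bn$gamma <- ad_param(rep(1, c))
  bn$beta <- ad_param(numeric(c))
  bn$run_mean <- numeric(c)
  bn$run_var <- rep(1, c)
  bn
}

conv_params <- function(cv) if (is.null(cv$b)) list(cv$w) else list(cv$w, cv$b)
bn_params <- function(bn) list(bn$gamma, bn$beta)

# ---- Adam optimizer --------------------------------------------------------

adam_state <- function(params, lr = 5e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params; st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$t <- 0L
  class(st) <- "adam_state"
  st
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (p in opt$params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) { p$m <- p$grad * 0; p$v <- p$grad * 0 }
    p$m <- b1 * p$m + (1 - b1) * p$grad
    p$v <- b2 * p$v + (1 - b2) * p$grad^2
    p$val <- p$val - opt$lr * (p$m / c1) / (sqrt(p$v / c2) + opt$eps)
  }
  invisible(opt)
}
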