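#' Total filter budget of a decoder fusion block
#'
#' Each decoder of a depth-`d` network concatenates `d` same-resolution
#' feature maps of `n_base` channels each and fuses them with a multi-residual
#' block carrying `W = n_base * d` filters.
#'
#' @param n_base per-path channel count (the base filter number `n`).
#' @param d network depth (number of scales).
#' @return Integer filter budget `W`.
#' @examples
#' filter_budget(64, 5)  # 320
#' @export
filter_budget <- function(n_base, d) {
  if (n_base < 1 || d < 1 || n_base %% 1 != 0 || d %% 1 != 0)
    stop("n_base and d must be positive integers")
  as.integer(n_base * d)
}

#' Branch widths of a multi-residual block
#'
#' The three chained convolution branches split a total budget `W` as
#' `round(W/6)`, `round(W/3)` and the remainder, so the concatenated output
#' has exactly `W` channels while the receptive field grows branch by branch.
#'
#' @param W total filter budget; at least 6 (below that the narrowest branch
#'   would be empty).
#' @return Integer vector `c(w1, w2, w3)` summing to `W`.
#' @examples
#' multires_widths(320)  # 53 107 160
#' @export
multires_widths <- function(W) {
  if (W %% 1 != 0 || W < 6)
    stop("W must be an integer >= 6 (got ", W, "); a narrower budget would leave a branch empty")
  w1 <- round(W / 6); w2 <- round(W / 3)
  as.integer(c(w1, w2, W - w1 - w2))
}

#' Residual-convolutional block count along a residual path
#'
#' Skip connections are replaced by residual paths whose depth grows with the
#' semantic gap they bridge: inter (encoder-to-decoder) paths from origin
#' level `L` carry `d - L` blocks, intra (decoder-to-decoder) paths carry
#' `d - L + 1`. Shallower origins therefore get more blocks — in a depth-5
#' network the inter paths carry 4, 3, 2, 1 blocks from the shallowest to the
#' deepest encoder origin.
#'
#' @param side `"inter"` (encoder origin) or `"intra"` (decoder origin,
#'   including the bottleneck at level `d`).
#' @param origin_level level the path starts from.
#' @param d network depth.
#' @return Positive integer block count.
#' @export
respath_blocks <- function(side = c("inter", "intra"), origin_level, d) {
  side <- match.arg(side)
  if (origin_level < 1 || origin_level > d)
    stop("origin_level must lie in 1..", d)
  if (side == "inter") {
    if (origin_level >= d)
      stop("inter paths originate from encoder levels 1..", d - 1L)
    as.integer(d - origin_level)
  } else {
    if (origin_level < 2L)
      stop("intra paths originate from decoder levels 2..", d)
    as.integer(d - origin_level + 1L)
  }
}

#' Architecture specification
#'
#' @param depth number of scales `d` (>= 2).
#' @param n_base per-path channel count `n` (>= 1); the decoder fusion budget
#'   is `W = n * depth`, which must be at least 6.
#' @param kernel convolution kernel length in samples (odd).
#' @param pool downsampling factor between scales (2, non-overlapping
#'   max-pooling).
#' @param input_length segment length in samples; must be divisible by
#'   `pool^(depth-1)`.
#' @param deep_supervision add per-decoder side outputs trained jointly with
#'   the final output.
#' @return An `arch_spec` object.
#' @export
arch_spec <- function(depth = 3L, n_base = 8L, kernel = 3L, pool = 2L,
                      input_length = 512L, deep_supervision = FALSE) {
  depth <- as.integer(depth); n_base <- as.integer(n_base)
  kernel <- as.integer(kernel); pool <- as.integer(pool)
  input_length <- as.integer(input_length)
  if (depth < 2L) stop("depth must be >= 2")
  if (n_base < 1L) stop("n_base must be >= 1")
  if (kernel %% 2L == 0L) stop("kernel length must be odd")
  if (pool != 2L) stop("only pool = 2 is supported")
  if (input_length %% pool^(depth - 1L) != 0L)
    stop("input_length (", input_length, ") must be divisible by pool^(depth-1) = ",
         pool^(depth - 1L))
  if (filter_budget(n_base, depth) < 6L)
    stop("n_base * depth must be >= 6 for a valid fusion block")
  structure(list(depth = depth, n_base = n_base, kernel = kernel, pool = pool,
                 input_length = input_length, deep_supervision = deep_supervision),
            class = "arch_spec")
}

# ---- building blocks -------------------------------------------------------

# multi-residual block: three chained kernel-k branches (widths w1 <= w2 <= w3,
# each conv + batchnorm + relu), concatenated to W channels, plus a 1-length
# conv residual shortcut; element-wise sum then batchnorm + relu
new_mrb <- function(W, c_in, k) {
  wd <- multires_widths(W)
  list(W = W, widths = wd, c_in = c_in, k = k,
       c1 = init_conv(c_in, wd[1L], k, bias = FALSE),  bn1 = init_bn(wd[1L]),
       c2 = init_conv(wd[1L], wd[2L], k, bias = FALSE), bn2 = init_bn(wd[2L]),
       c3 = init_conv(wd[2L], wd[3L], k, bias = FALSE), bn3 = init_bn(wd[3L]),
       res = init_conv(c_in, W, 1L, bias = FALSE),
       bn_out = init_bn(W))
}

mrb_params <- function(blk) c(
  conv_params(blk$c1), bn_params(blk$bn1),
  conv_params(blk$c2), bn_params(blk$bn2),
  conv_params(blk$c3), bn_params(blk$bn3),
  conv_params(blk$res), bn_params(blk$bn_out))

mrb_forward <- function(tp, x, blk, train) {
  k <- blk$k
  b1 <- op_relu(tp, op_batchnorm(tp, op_conv1d(tp, x, blk$c1, k), blk$bn1, train))
  b2 <- op_relu(tp, op_batchnorm(tp, op_conv1d(tp, b1, blk$c2, k), blk$bn2, train))
  b3 <- op_relu(tp, op_batchnorm(tp, op_conv1d(tp, b2, blk$c3, k), blk$bn3, train))
  cc <- op_concat(tp, list(b1, b2, b3))
  sc <- op_conv1d(tp, x, blk$res, 1L)
  op_relu(tp, op_batchnorm(tp, op_add(tp, cc, sc), blk$bn_out, train))
}

# one residual-convolutional block: kernel-k conv and parallel 1-length conv,
# element-wise added, then batchnorm + relu
new_resblock <- function(c_in, c_out, k) {
  list(c3 = init_conv(c_in, c_out, k, bias = FALSE),
       c1 = init_conv(c_in, c_out, 1L, bias = FALSE),
       bn = init_bn(c_out), k = k)
}

resblock_params <- function(b) c(conv_params(b$c3), conv_params(b$c1), bn_params(b$bn))

resblock_forward <- function(tp, x, b, train) {
  a <- op_conv1d(tp, x, b$c3, b$k)
  r <- op_conv1d(tp, x, b$c1, 1L)
  op_relu(tp, op_batchnorm(tp, op_add(tp, a, r), b$bn, train))
}

#' Build a residual path
#'
#' A residual path replaces a direct skip connection: the source feature map
#' is first brought to the destination scale (non-overlapping max-pooling for
#' shallower encoder origins, nearest interpolation for deeper decoder
#' origins, identity at the same scale) and then refined by `n_blocks`
#' residual-convolutional blocks of `channels` output channels each.
#'
#' @param side `"inter"` or `"intra"`.
#' @param origin_level,destination_level source and target scales;
#'   `destination_level < origin ` scale relationships determine the
#'   resolution operator.
#' @param d network depth.
#' @param in_channels channels of the source feature map.
#' @param channels output channels of every block (the per-path width).
#' @param kernel convolution kernel length.
#' @return A `respath` component usable inside the assembled network.
#' @export
build_respath <- function(side, origin_level, destination_level, d,
                          in_channels, channels, kernel = 3L) {
  side <- match.arg(side, c("inter", "intra"))
  if (destination_level < 1L || destination_level >= d)
    stop("destination_level must lie in 1..", d - 1L)
  nb <- respath_blocks(side, origin_level, d)
  if (side == "inter") {
    if (origin_level > destination_level)
      stop("inter paths originate at the destination scale or shallower")
    res_op <- if (origin_level == destination_level) "identity" else "max-pool"
    factor <- 2L^(destination_level - origin_level)
  } else {
    if (origin_level <= destination_level)
      stop("intra paths originate from deeper decoder levels")
    res_op <- "nearest-interpolation"
    factor <- 2L^(origin_level - destination_level)
  }
  blocks <- vector("list", nb)
  cin <- in_channels
  for (i in seq_len(nb)) {
    blocks[[i]] <- new_resblock(cin, channels, kernel)
    cin <- channels
  }
  structure(list(side = side, origin = origin_level, dest = destination_level,
                 n_blocks = nb, res_op = res_op, factor = factor,
                 in_channels = in_channels, channels = channels,
                 blocks = blocks),
            class = "respath")
}

respath_params <- function(p) do.call(c, lapply(p$blocks, resblock_params))

respath_forward <- function(tp, x, path, train) {
  x <- switch(path$res_op,
              "identity" = x,
              "max-pool" = op_maxpool(tp, x, path$factor),
              "nearest-interpolation" = op_upnearest(tp, x, path$factor))
  for (b in path$blocks) x <- resblock_forward(tp, x, b, train)
  x
}

#' Build a multi-residual block component
#'
#' Standalone constructor for one multi-residual block (see
#' [multires_widths()] for the branch arithmetic), mainly useful for
#' inspecting shapes and widths outside a full network.
#'
#' @param W total filter budget.
#' @param in_channels input channel count.
#' @param kernel convolution kernel length.
#' @return A `multires_block` component with `$W`, `$widths` and parameters.
#' @export
build_multires_block <- function(W, in_channels, kernel = 3L) {
  blk <- new_mrb(W, in_channels, as.integer(kernel))
  class(blk) <- "multires_block"
  blk
}

#' Run a component forward (evaluation mode)
#'
#' Applies a `multires_block` or `respath` to a numeric input array of
#' dimension (length, channels, batch) and returns the output array; used for
#' shape inspection and testing of individual components.
#'
#' @param component a `multires_block` or `respath`.
#' @param x numeric array (L, C, N) or matrix (L, C) treated as batch of 1.
#' @return Output array of dimension (L', C', N).
#' @export
component_forward <- function(component, x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x)[1L], 1L, dim(x)[2L])
  else x <- aperm(x, c(1L, 3L, 2L))    # public (L, C, N) -> internal (L, N, C)
  tp <- ad_tape()
  node <- ad_node(tp, x)
  out <- if (inherits(component, "multires_block"))
    mrb_forward(tp, node, component, train = FALSE)
  else respath_forward(tp, node, component, train = FALSE)
  aperm(out$val, c(1L, 3L, 2L))
}

# ---- full network ----------------------------------------------------------

#' Assemble the full-scale multi-residual encoder-decoder network
#'
#' Builds the 1D denoising network: an encoder of multi-residual blocks with
#' geometric channel growth (`max(6, n_base * 2^(i-1))` at level `i`), and
#' `depth - 1` decoders that each aggregate exactly `depth` same-resolution
#' feature maps — one per shallower/same-level encoder through inter residual
#' paths, one per deeper decoder (the bottleneck standing in as decoder
#' `depth`) through intra residual paths — concatenated to
#' `W = n_base * depth` channels and fused by a multi-residual block of
#' budget `W`. A final 1-length convolution maps the shallowest decoder to a
#' single linear output channel the length of the input.
#'
#' @param spec an [arch_spec()].
#' @param seed optional seed controlling weight initialisation (uniform
#'   fan-in), for reproducible networks.
#' @return An `mrunet3p_net` with parameters, per-path census (`$structure`)
#'   and forward machinery.
#' @export
assemble_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  build <- function() {
    d <- spec$depth; n <- spec$n_base; k <- spec$kernel
    W_dec <- filter_budget(n, d)
    enc_budget <- pmax(6L, n * 2L^(seq_len(d) - 1L))
    enc <- vector("list", d)
    cin <- 1L
    for (i in seq_len(d)) {
      enc[[i]] <- new_mrb(enc_budget[i], cin, k)
      cin <- enc_budget[i]
    }
    dec <- vector("list", d - 1L)          # dec[[L]] for L in 1..d-1
    census <- list()
    for (L in seq_len(d - 1L)) {
      paths <- list()
      for (e in seq_len(L))               # inter: encoder levels 1..L
        paths[[length(paths) + 1L]] <-
          build_respath("inter", e, L, d, enc_budget[e], n, k)
      for (o in (L + 1L):d)               # intra: deeper decoders incl. bottleneck
        paths[[length(paths) + 1L]] <-
          build_respath("intra", o, L, d,
                        if (o == d) enc_budget[d] else W_dec, n, k)
      dec[[L]] <- list(paths = paths, fuse = new_mrb(W_dec, W_dec, k))
      for (p in paths)
        census[[length(census) + 1L]] <- data.frame(
          dest_level = L, side = p$side, origin_level = p$origin,
          n_blocks = p$n_blocks, res_op = p$res_op, factor = p$factor,
          in_channels = p$in_channels, channels = p$channels)
    }
    head <- init_conv(W_dec, 1L, 1L)
    ds_heads <- NULL
    if (spec$deep_supervision) {
      ds_heads <- lapply(2L:d, function(L)
        init_conv(if (L == d) enc_budget[d] else W_dec, 1L, 1L))
      names(ds_heads) <- paste0("level", 2L:d)
    }
    params <- c(
      do.call(c, lapply(enc, mrb_params)),
      do.call(c, lapply(dec, function(dl)
        c(do.call(c, lapply(dl$paths, respath_params)), mrb_params(dl$fuse)))),
      conv_params(head),
      if (!is.null(ds_heads)) do.call(c, lapply(ds_heads, conv_params)))
    structure(list(spec = spec, enc = enc, dec = dec, head = head,
                   ds_heads = ds_heads, params = params,
                   enc_budget = enc_budget, W_dec = W_dec,
                   structure = do.call(rbind, census), seed = seed),
              class = "mrunet3p_net")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

n_params <- function(net) sum(vapply(net$params, function(p) length(p$val), 0))

#' @export
print.mrunet3p_net <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<mrunet3p_net> depth %d, n_base %d (fusion budget W = %d), kernel %d, input length %d\n",
              s$depth, s$n_base, x$W_dec, s$kernel, s$input_length))
  cat(sprintf("  encoder budgets: %s | %d residual paths | %s trainable parameters\n",
              paste(x$enc_budget, collapse = "/"), nrow(x$structure),
              format(n_params(x), big.mark = ",")))
  if (s$deep_supervision) cat("  deep supervision: on\n")
  invisible(x)
}

# forward pass on a tape; returns list(final = node, sides = list of nodes)
net_forward_tape <- function(tp, net, x_arr, train) {
  spec <- net$spec; d <- spec$depth
  x <- ad_node(tp, x_arr)
  E <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    if (i > 1L) h <- op_maxpool2(tp, h)
    h <- mrb_forward(tp, h, net$enc[[i]], train)
    E[[i]] <- h
  }
  D <- vector("list", d)
  D[[d]] <- E[[d]]                       # bottleneck doubles as decoder d
  for (L in (d - 1L):1L) {
    dl <- net$dec[[L]]
    ins <- vector("list", d)
    pi <- 0L
    for (e in seq_len(L)) {
      pi <- pi + 1L
      ins[[pi]] <- respath_forward(tp, E[[e]], dl$paths[[pi]], train)
    }
    for (o in (L + 1L):d) {
      pi <- pi + 1L
      ins[[pi]] <- respath_forward(tp, D[[o]], dl$paths[[pi]], train)
    }
    D[[L]] <- mrb_forward(tp, op_concat(tp, ins), dl$fuse, train)
  }
  final <- op_conv1d(tp, D[[1L]], net$head, 1L)
  sides <- NULL
  if (spec$deep_supervision && !is.null(net$ds_heads)) {
    sides <- lapply(seq_along(net$ds_heads), function(i) {
      L <- i + 1L
      y <- op_conv1d(tp, D[[L]], net$ds_heads[[i]], 1L)
      op_upnearest(tp, y, 2L^(L - 1L))
    })
  }
  list(final = final, sides = sides)
}

# (N, L) matrix of series -> (L, N, 1) input array
mat_to_input <- function(y) {
  array(t(y), c(ncol(y), nrow(y), 1L))
}

#' Forward pass of an assembled network
#'
#' Runs a batch of normalized contaminated series through the network in
#' evaluation mode (batch-normalization uses running statistics) and returns
#' the predicted normalized clean series. With deep supervision enabled, the
#' per-decoder side outputs are attached as the `"sides"` attribute.
#'
#' @param net an `mrunet3p_net`.
#' @param y numeric matrix, one segment per row; row length must equal the
#'   network's `input_length`.
#' @param batch_size forward mini-batch size (memory control only).
#' @return Matrix of predictions, same shape as `y`.
#' @export
net_forward <- function(net, y, batch_size = 64L) {
  y <- rbind(y)
  if (ncol(y) != net$spec$input_length)
    stop("input length ", ncol(y), " does not match the network's input_length ",
         net$spec$input_length)
  n <- nrow(y)
  out <- matrix(0, n, ncol(y))
  sides_acc <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    tp <- ad_tape()
    fw <- net_forward_tape(tp, net, mat_to_input(y[idx, , drop = FALSE]), train = FALSE)
    out[idx, ] <- t(fw$final$val[, , 1L])
    if (!is.null(fw$sides)) {
      sb <- lapply(fw$sides, function(s) t(s$val[, , 1L]))
      sides_acc <- if (is.null(sides_acc)) sb
        else Map(rbind, sides_acc, sb)
    }
  }
  if (!is.null(sides_acc)) attr(out, "sides") <- sides_acc
  out
}
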