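test_that("filter budget and branch widths follow the block arithmetic", {
  expect_equal(filter_budget(64, 5), 320L)
  expect_equal(filter_budget(1, 1), 1L)
  expect_equal(filter_budget(32, 4), 128L)
  expect_error(filter_budget(0, 5), "positive")
  expect_error(filter_budget(2.5, 2), "integers")

  expect_equal(multires_widths(320), c(53L, 107L, 160L))
  expect_equal(multires_widths(6), c(1L, 2L, 3L))
  w <- multires_widths(256)
  expect_equal(w, c(43L, 85L, 128L))
  expect_equal(sum(w), 256L)
  # the split always conserves the budget
  for (W in c(6, 7, 24, 31, 100, 320))
    expect_equal(sum(multires_widths(W)), W)
  expect_error(multires_widths(5), ">= 6")
})

test_that("residual-path block counts decrease toward deeper origins", {
  expect_equal(respath_blocks("inter", 1, 5), 4L)
  expect_equal(respath_blocks("inter", 2, 5), 3L)
  expect_equal(respath_blocks("inter", 3, 5), 2L)
  expect_equal(respath_blocks("inter", 4, 5), 1L)
  expect_equal(respath_blocks("intra", 5, 5), 1L)
  expect_equal(respath_blocks("intra", 2, 5), 4L)
  expect_error(respath_blocks("inter", 5, 5), "encoder levels")
  expect_error(respath_blocks("intra", 1, 5), "decoder levels")
  expect_error(respath_blocks("inter", 0, 5), "origin_level")
  expect_error(respath_blocks("inter", 6, 5), "origin_level")
})

test_that("multi-residual blocks emit exactly their budget in channels", {
  blk <- withr::with_seed(1, build_multires_block(W = 24, in_channels = 3))
  x <- withr::with_seed(2, array(stats::rnorm(16 * 3 * 2), c(16, 3, 2)))
  out <- component_forward(blk, x)
  expect_equal(dim(out), c(16L, 24L, 2L))
  expect_equal(sum(blk$widths), 24L)

  blk6 <- withr::with_seed(3, build_multires_block(W = 6, in_channels = 1))
  out6 <- component_forward(blk6, matrix(stats::rnorm(16), 16, 1))
  expect_equal(dim(out6), c(16L, 6L, 1L))
})

test_that("residual paths match destination resolution and width", {
  d <- 5
  # shallow encoder origin: 4 blocks, max-pool to 1/4 length
  p13 <- withr::with_seed(4, build_respath("inter", 1, 3, d,
                                           in_channels = 6, channels = 8))
  expect_equal(p13$n_blocks, 4L)
  expect_equal(p13$res_op, "max-pool")
  expect_equal(p13$factor, 4L)
  x <- withr::with_seed(5, array(stats::rnorm(32 * 6 * 2), c(32, 6, 2)))
  expect_equal(dim(component_forward(p13, x)), c(8L, 8L, 2L))

  # deep decoder origin: nearest interpolation up by 4
  p53 <- withr::with_seed(6, build_respath("intra", 5, 3, d,
                                           in_channels = 6, channels = 8))
  expect_equal(p53$res_op, "nearest-interpolation")
  xs <- withr::with_seed(7, array(stats::rnorm(8 * 6 * 2), c(8, 6, 2)))
  expect_equal(dim(component_forward(p53, xs)), c(32L, 8L, 2L))

  # same-scale path leaves length unchanged
  p33 <- withr::with_seed(8, build_respath("inter", 3, 3, d,
                                           in_channels = 6, channels = 8))
  expect_equal(p33$res_op, "identity")
  expect_equal(dim(component_forward(p33, x)), c(32L, 8L, 2L))

  expect_error(build_respath("inter", 4, 3, d, 6, 8), "shallower")
  expect_error(build_respath("intra", 2, 3, d, 6, 8), "deeper")
})

test_that("the assembled network has the full-scale path census", {
  spec <- arch_spec(depth = 5, n_base = 6, input_length = 64)
  net <- assemble_network(spec, seed = 1)
  st <- net$structure
  # d-1 decoders, each receiving exactly d incoming paths
  expect_equal(sort(unique(st$dest_level)), 1:4)
  counts <- table(st$dest_level)
  expect_true(all(counts == 5))
  # decoder 3 receives 3 inter + 2 intra paths
  d3 <- st[st$dest_level == 3, ]
  expect_equal(sum(d3$side == "inter"), 3L)
  expect_equal(sum(d3$side == "intra"), 2L)
  # inter block counts from shallowest origin: 4, 3, 2 at decoder 3
  expect_equal(d3$n_blocks[d3$side == "inter"][order(d3$origin_level[d3$side == "inter"])],
               c(4L, 3L, 2L))
  # every decoder concatenates n_base * d channels and fuses with budget W
  expect_equal(net$W_dec, filter_budget(6, 5))
  expect_true(all(vapply(net$dec, function(dl) dl$fuse$W, 0L) == net$W_dec))
  expect_true(all(st$channels == spec$n_base))
})

test_that("forward pass preserves shape, is deterministic and validates input", {
  for (len in c(512L, 1024L)) {
    spec <- arch_spec(depth = 3, n_base = 8, input_length = len)
    net <- assemble_network(spec, seed = 3)
    y <- withr::with_seed(len, matrix(stats::rnorm(2 * len), 2, len))
    z <- net_forward(net, y)
    expect_equal(dim(z), c(2L, len))
    expect_true(all(is.finite(z)))
  }
  spec <- arch_spec(depth = 3, n_base = 8, input_length = 64)
  netA <- assemble_network(spec, seed = 11)
  netB <- assemble_network(spec, seed = 11)
  y <- withr::with_seed(1, matrix(stats::rnorm(3 * 64), 3, 64))
  expect_identical(net_forward(netA, y), net_forward(netB, y))
  # zero input through a fresh network stays finite
  expect_true(all(is.finite(net_forward(netA, matrix(0, 2, 64)))))
  expect_error(net_forward(netA, matrix(0, 2, 128)), "input_length")
  expect_error(arch_spec(depth = 4, input_length = 100), "divisible")
})

test_that("deep supervision yields one side output per deeper decoder", {
  spec <- arch_spec(depth = 5, n_base = 6, input_length = 64,
                    deep_supervision = TRUE)
  net <- assemble_network(spec, seed = 2)
  y <- withr::with_seed(2, matrix(stats::rnorm(2 * 64), 2, 64))
  z <- net_forward(net, y)
  sides <- attr(z, "sides")
  expect_length(sides, 4L)                  # 4 side outputs + 1 final at d = 5
  for (s in sides) expect_equal(dim(s), c(2L, 64L))
})

test_that("one optimizer step moves every trainable tensor", {
  spec <- arch_spec(depth = 3, n_base = 8, input_length = 32)
  net <- assemble_network(spec, seed = 5)
  before <- lapply(net$params, function(p) p$val)
  opt <- eegdenoise:::adam_state(net$params, lr = 5e-4)
  x <- withr::with_seed(6, matrix(stats::rnorm(4 * 32), 4, 32))
  tgt <- withr::with_seed(7, matrix(stats::rnorm(4 * 32), 4, 32))
  eegdenoise:::train_batch(net, opt, eegdenoise:::mat_to_input(x),
                           eegdenoise:::mat_to_input(tgt), FALSE)
  moved <- mapply(function(b, p) any(b != p$val), before, net$params)
  expect_true(all(moved))
})
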