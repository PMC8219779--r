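test_that("single-map convolution matches the quadruple-loop oracle", {
  set.seed(5)
  for (rep in 1:5) {
    map <- matrix(rnorm(64), 8, 8)
    kernel <- matrix(rnorm(9), 3, 3)
    bias <- rnorm(1)
    expect_equal(conv2d_single(map, kernel, bias),
                 oracle_conv(map, kernel, bias), tolerance = 1e-12)
  }
  # identity kernel on non-negative input
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  m <- matrix(runif(36), 6, 6)
  expect_equal(conv2d_single(m, delta, 0), m)
  # RELU clamps a negative bias with a zero kernel
  expect_equal(conv2d_single(m, matrix(0, 3, 3), -1), matrix(0, 6, 6))
  expect_error(conv2d_single(m, matrix(0, 2, 2), 0), "3x3")
})

test_that("max-pooling matches the exhaustive window scan", {
  expect_equal(maxpool(matrix(7, 8, 8)), matrix(7, 2, 2))
  expect_equal(dim(maxpool(matrix(0, 256, 256))), c(64, 64))
  set.seed(6)
  m <- matrix(rnorm(64), 8, 8)
  expect_equal(maxpool(m), oracle_maxpool(m))
  expect_error(maxpool(matrix(0, 6, 6)), "divisible")
})

test_that("the convolution part has exactly 84 filters, 756 weights, 84 biases", {
  cnn <- build_cnn(49, input_size = 256, seed = 1)
  expect_length(cnn$conv$block1, 4)
  expect_length(cnn$conv$block2, 16)
  expect_length(cnn$conv$block3, 64)
  filters <- unlist(cnn$conv, recursive = FALSE)
  expect_length(filters, 84)
  expect_equal(sum(vapply(filters, function(f) length(f$kernel), numeric(1))),
               756)
  expect_equal(sum(vapply(filters, function(f) length(f$bias), numeric(1))),
               84)
  counts <- count_parameters(cnn)
  expect_equal(unname(counts["n_weights"]), 756 + 1024 * 49 + 49 * 49)
  expect_equal(unname(counts["n_biases"]), 84 + 49 + 49)
})

test_that("forward_conv produces the 4/16/64 map trace at the right sizes", {
  cnn <- build_cnn(49, input_size = 256, seed = 2)
  img <- matrix(runif(256 * 256), 256, 256)
  maps <- forward_conv(cnn$conv, img)
  expect_length(maps, 64)
  expect_true(all(vapply(maps, function(m) all(dim(m) == c(4, 4)),
                         logical(1))))
  expect_true(all(unlist(maps) >= 0))  # RELU non-negativity
  # intermediate block sizes via a manual pass
  b1 <- lapply(cnn$conv$block1, function(f)
    maxpool(conv2d_single(img, f$kernel, f$bias)))
  expect_length(b1, 4)
  expect_equal(dim(b1[[1]]), c(64, 64))
  expect_error(forward_conv(cnn$conv, matrix(0, 100, 100)), "divisible")
})

test_that("zero conv weights and biases propagate zeros", {
  cnn <- build_cnn(49, input_size = 64, seed = 3)
  p <- kmcloc:::net_params(cnn)
  cnn0 <- kmcloc:::net_set_params(cnn, rep(0, length(p)))
  maps <- forward_conv(cnn0$conv, matrix(0, 64, 64))
  expect_true(all(unlist(maps) == 0))
  out <- forward_cnn(cnn0, rep(0, 64 * 64))
  expect_equal(as.vector(out), rep(0.5, 49))
})

test_that("flatten is map-major, length 1024, and a bijection", {
  maps <- lapply(0:63, function(v) matrix(v, 4, 4))
  flat <- flatten_maps(maps)
  expect_length(flat, 1024)
  expect_true(all(flat[1:16] == 0))
  expect_true(all(flat[1009:1024] == 63))
  # reshape back recovers the maps
  set.seed(8)
  maps <- lapply(1:64, function(i) matrix(rnorm(16), 4, 4))
  flat <- flatten_maps(maps)
  back <- lapply(1:64, function(i)
    matrix(flat[((i - 1) * 16 + 1):(i * 16)], 4, 4, byrow = TRUE))
  expect_equal(back, maps)
})

test_that("forward_conv composes per-map conv and pool oracles (tiny analog)", {
  cnn <- build_cnn(49, input_size = 64, seed = 4)
  img <- matrix(runif(64 * 64), 64, 64)
  maps <- forward_conv(cnn$conv, img)
  # independent composition on the 64x64 analog (final maps are 1x1)
  cur <- list(img)
  for (blk in 1:3) {
    nxt <- list()
    for (f in seq_along(cnn$conv[[blk]])) {
      src <- cur[[ceiling(f / 4)]]
      filt <- cnn$conv[[blk]][[f]]
      nxt[[f]] <- oracle_maxpool(oracle_conv(src, filt$kernel, filt$bias))
    }
    cur <- nxt
  }
  expect_equal(maps, cur, tolerance = 1e-12)
  # end-to-end equals head applied to the oracle flatten
  out <- forward_cnn(cnn, as.vector(t(img)))
  oracle_out <- oracle_forward(cnn$layers, cnn$hidden_activation,
                               flatten_maps(cur))
  expect_equal(as.vector(out), oracle_out, tolerance = 1e-10)
})

test_that("the per-map tree isolates branches", {
  cnn <- build_cnn(49, input_size = 64, seed = 9)
  # make all biases zero so a dead branch cannot revive through a bias
  mask <- kmcloc:::net_bias_mask(cnn)
  p <- kmcloc:::net_params(cnn)
  p[mask] <- 0
  cnn <- kmcloc:::net_set_params(cnn, p)
  # kill block-1 filter 2: its 4 block-2 children read map 2, their 16
  # block-3 descendants are maps 17..32 of the output
  for (k in 1:9) cnn$conv$block1[[2]]$kernel[k] <- 0
  img <- matrix(runif(64 * 64), 64, 64)
  maps <- forward_conv(cnn$conv, img)
  expect_true(all(unlist(maps[17:32]) == 0))
  expect_true(any(unlist(maps[c(1:16, 33:64)]) != 0))
})

test_that("cnn head options are validated", {
  expect_error(build_cnn(c(49, 49, 49)), "one or two")
  expect_error(build_cnn(49, input_size = 100), "divisible")
  relu_net <- build_cnn(c(49, 49), "relu", input_size = 64, seed = 1)
  expect_equal(relu_net$hidden_activation, "relu")
  expect_length(relu_net$layers, 3)
})
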