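test_that("BCM preserves shape, clamps at zero, and maps zero to zero", {
  set.seed(1)
  p <- bcm_init(3L, 5L, kernel_size = 3L)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  y <- bcm_forward(x, p)
  expect_identical(dim(y), c(8L, 8L, 5L))
  expect_true(all(y >= 0))
  # fresh BN has zero shift, so zero input stays zero in inference mode
  y0 <- bcm_forward(array(0, c(8, 8, 3)), p)
  expect_true(all(y0 == 0))
  expect_error(bcm_forward(array(0, c(8, 8, 4)), p), "channel mismatch")
})

test_that("DCM concatenation arithmetic matches the dense-block contract", {
  set.seed(2)
  p <- dcm_init(16L, n_layers = 4L, growth = 8L)
  x <- array(rnorm(6 * 6 * 16), c(6, 6, 16))
  with_input <- dcm_forward(x, p, include_input = TRUE)
  expect_identical(dim(with_input)[3], 16L + 4L * 8L)
  without <- dcm_forward(x, p, include_input = FALSE)
  expect_identical(dim(without)[3], 4L * 8L)
  # the encoder-side output literally contains the input as its first slab
  expect_identical(with_input[, , 1:16], x)
  # one-layer block degenerates to a single BCM (plus the input slab)
  p1 <- dcm_init(4L, n_layers = 1L, growth = 2L)
  x1 <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  expect_identical(dcm_forward(x1, p1, include_input = FALSE),
                   bcm_forward(x1, p1$layers$l1))
})

test_that("dense connectivity: silencing layer k spares earlier channels", {
  set.seed(3)
  p <- dcm_init(6L, n_layers = 3L, growth = 4L)
  x <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  base <- dcm_forward(x, p, include_input = TRUE)
  k <- 2L
  p$layers[[k]]$conv$w[] <- 0
  p$layers[[k]]$bn$gamma[] <- 0
  probed <- dcm_forward(x, p, include_input = TRUE)
  # channels contributed before layer k (input + layer 1) are untouched
  before <- 6L + (k - 1L) * 4L
  expect_identical(probed[, , 1:before], base[, , 1:before])
  # layer k's own slab is silenced; later slabs are free to change
  expect_true(all(probed[, , (before + 1):(before + 4)] == 0))
})

test_that("transitions halve/double spatial size and invert each other", {
  set.seed(4)
  td <- bcm_init(8L, 8L, kernel_size = 1L)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  down <- transition_down(x, td)
  expect_identical(dim(down), c(8L, 8L, 8L))
  tu <- bcm_init(8L, 4L, kernel_size = 3L)
  up <- transition_up(down, tu)
  expect_identical(dim(up)[1:2], c(16L, 16L))
  expect_lt(dim(up)[3], dim(down)[3])  # depth decreases on the way up
  # four applications of pooling: 64 -> 4
  y <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  for (i in 1:4) y <- rnafoldnet:::.maxpool_forward(y)$out
  expect_identical(dim(y)[1:2], c(4L, 4L))
})

test_that("encoder depths increase strictly along the pathway", {
  model <- init_network(tiny_net_config(), seed = 1)
  expect_true(all(diff(c(tiny_net_config()$feature_channels,
                         model$enc_depths)) > 0))
})

test_that("residual skip-add is an elementwise sum with strict wiring", {
  a <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  b <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  expect_identical(residual_skip_add(a, b), a + b)
  expect_identical(residual_skip_add(a, b), residual_skip_add(b, a))
  expect_identical(residual_skip_add(a, array(0, dim(a))), a)
  expect_error(residual_skip_add(a, array(0, c(4, 4, 2))), "wiring error")
})

test_that("symmetrize returns a symmetric normalization of raw + raw^T", {
  set.seed(6)
  raw <- matrix(rnorm(25), 5)
  S <- symmetrize(raw)
  expect_lte(max(abs(S - t(S))), 1e-5)
  # antisymmetric raw cancels exactly: raw + raw^T = 0, and fresh
  # normalization parameters map zero to zero
  anti <- raw - t(raw)
  expect_true(all(symmetrize(anti) == 0))
  expect_error(symmetrize(matrix(0, 2, 3)), "square")
})

test_that("full forward yields symmetric L x L maps across lengths", {
  cfg <- tiny_net_config()
  model <- init_network(cfg, seed = 7)
  set.seed(7)
  for (L in c(5L, 16L, 23L)) {
    conf <- build_input_conformation(random_rna(L))
    S <- network_forward(model, conf)
    expect_identical(dim(S), c(L, L))
    expect_lte(max(abs(S - t(S))), 1e-5)
  }
  # determinism in inference mode
  conf <- build_input_conformation(random_rna(20L))
  expect_identical(network_forward(model, conf), network_forward(model, conf))
})

test_that("over-length sequences are refused with a clear message", {
  cfg <- network_config(feature_channels = 2L, dcm_layers = 1L, growth = 2L,
                        num_levels = 1L, max_length = 30L)
  model <- init_network(cfg, seed = 1)
  conf <- build_input_conformation(random_rna(31L))
  expect_error(network_forward(model, conf), "exceeds the configured maximum")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(11)
  cfg <- tiny_net_config()
  model <- init_network(cfg, seed = 2)
  s <- random_rna(17L)
  conf <- build_input_conformation(s)
  target <- matrix(0, 17, 17); target[1, 10] <- target[10, 1] <- 1
  fw <- rnafoldnet:::.net_apply(model, conf, training = TRUE, keep = TRUE)
  lo <- pair_loss(fw$S, target, positive_weight = 5)
  g <- rnafoldnet:::.net_backward(fw$model, fw, lo$grad)
  eps <- 1e-5
  loss_at <- function(m) {
    f <- rnafoldnet:::.net_apply(m, conf, training = TRUE, keep = FALSE)
    pair_loss(f$S, target, positive_weight = 5)$loss
  }
  check_leaf <- function(get, set, gleaf, n_probe = 3L) {
    vals <- get(model)
    for (k in sample(length(vals), min(n_probe, length(vals)))) {
      up <- vals; up[k] <- up[k] + eps
      dn <- vals; dn[k] <- dn[k] - eps
      num <- (loss_at(set(model, up)) - loss_at(set(model, dn))) / (2 * eps)
      expect_equal(num, gleaf[k], tolerance = 1e-4)
    }
  }
  check_leaf(function(m) m$params$fe$b1$conv$w,
             function(m, v) { m$params$fe$b1$conv$w[] <- v; m },
             g$fe$b1$conv$w)
  check_leaf(function(m) m$params$dec$lev1$layers$l2$conv$w,
             function(m, v) { m$params$dec$lev1$layers$l2$conv$w[] <- v; m },
             g$dec$lev1$layers$l2$conv$w)
  check_leaf(function(m) m$params$enc$lev2$layers$l1$bn$beta,
             function(m, v) { m$params$enc$lev2$layers$l1$bn$beta <- v; m },
             g$enc$lev2$layers$l1$bn$beta)
  check_leaf(function(m) m$params$head$bn$gamma,
             function(m, v) { m$params$head$bn$gamma <- v; m },
             g$head$bn$gamma)
})

test_that("gradient reaches the first convolution (no dead paths)", {
  cfg <- tiny_net_config()
  model <- init_network(cfg, seed = 3)
  set.seed(12)
  conf <- build_input_conformation(random_rna(16L))
  target <- matrix(0, 16, 16); target[2, 9] <- target[9, 2] <- 1
  fw <- rnafoldnet:::.net_apply(model, conf, training = TRUE, keep = TRUE)
  lo <- pair_loss(fw$S, target)
  g <- rnafoldnet:::.net_backward(fw$model, fw, lo$grad)
  expect_gt(sum(abs(g$fe$b1$conv$w)), 0)
})

test_that("checkpoints and config files round-trip", {
  cfg <- tiny_net_config()
  model <- init_network(cfg, seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, model$params)
  expect_equal(unclass(back$cfg), unclass(model$cfg))
  set.seed(1)
  conf <- build_input_conformation(random_rna(12L))
  expect_identical(network_forward(back, conf), network_forward(model, conf))
  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_network_config(cfg, ypath)
  expect_equal(unclass(read_network_config(ypath)), unclass(cfg))
  expect_error(load_checkpoint(ypath))
})
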