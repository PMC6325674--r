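# Restricted Boltzmann machine pre-training and DBN regression.

test_that("zero pre-training epochs return the seeded initialization", {
  v <- random_fps(20, 8, seed = 1)
  r <- rbm_train(v, 4, epochs = 0, seed = 123)
  W0 <- satox:::with_seed(123, matrix(rnorm(8 * 4, sd = 0.01), 8, 4))
  expect_equal(r$W, W0)
  expect_equal(r$b_vis, numeric(8))
  expect_equal(r$b_hid, numeric(4))
})

test_that("constant all-zero data drives reconstruction error to zero", {
  v <- matrix(0, 40, 8)
  r <- rbm_train(v, 4, epochs = 300, lr0 = 0.5, decay = 0, batch = 40,
                 l2 = 0, seed = 2)
  expect_lt(tail(r$recon_error, 1), 0.02)
})

test_that("pre-training reduces reconstruction error on structured data", {
  set.seed(10)
  proto <- matrix(rbinom(4 * 64, 1, 0.5), 4, 64)
  v <- proto[sample(1:4, 200, replace = TRUE), ]
  v <- (v + matrix(rbinom(200 * 64, 1, 0.05), 200)) %% 2
  r <- rbm_train(v, 16, epochs = 20, lr0 = 0.1, batch = 50, seed = 3)
  expect_lt(tail(r$recon_error, 1), r$recon_error[1])
})

test_that("RBM validates input domain and dimensions", {
  expect_error(rbm_train(matrix(c(0, 2), 1), 2), "\\[0, 1\\]")
  r <- rbm_train(random_fps(10, 8, seed = 4), 4, epochs = 1)
  expect_identical(dim(r$W), c(8L, 4L))
  expect_error(rbm_hidden(r, matrix(0, 2, 9)), "width")
})

test_that("a two-layer toy schedule gives one RBM with the right dims", {
  x <- random_fps(30, 8, seed = 5)
  st <- dbn_pretrain(x, c(8, 4), dbn_control(pretrain_epochs = 2, batch = 10))
  expect_length(st$layers, 1L)
  expect_identical(dim(st$layers[[1]]$W), c(8L, 4L))
  expect_error(dbn_pretrain(x, c(16, 4)), "visible")
  expect_error(dbn_pretrain(x, c(8, 4, 6)), "decreasing")
  expect_error(dbn_pretrain(x * 0.5, c(8, 4)), "binary")
})

test_that("stacked layers train on the previous layer's hidden probabilities", {
  x <- random_fps(100, 16, seed = 6)
  ctl <- dbn_control(pretrain_epochs = 3, batch = 25, seed = 77)
  st <- dbn_pretrain(x, c(16, 8, 4), ctl)
  # oracle: retrain layer 2 in isolation on layer 1's forward pass
  h1 <- rbm_hidden(st$layers[[1]], x)
  r2 <- rbm_train(h1, 4, epochs = 3, lr0 = ctl$lr0, decay = ctl$decay,
                  batch = 25, cd_steps = ctl$cd_steps, l2 = ctl$l2,
                  seed = satox:::derive_seed(77, 2))
  expect_equal(st$layers[[2]]$W, r2$W)
  expect_equal(st$layers[[2]]$b_hid, r2$b_hid)
})

test_that("analytic fine-tuning gradients match finite differences", {
  set.seed(8)
  x <- matrix(rbinom(5 * 8, 1, 0.5), 5, 8)
  y <- runif(5, 1, 10)
  params <- list(W = list(matrix(rnorm(8 * 4, sd = 0.3), 8, 4)),
                 b = list(rnorm(4, sd = 0.1)),
                 head_w = rnorm(4, sd = 0.3), head_b = 0.2)
  for (l2 in c(0, 1e-2)) {
    an <- satox:::.dbn_grads(params, x, y, l2)
    loss_at <- function(p) satox:::.dbn_grads(p, x, y, l2)$loss
    eps <- 1e-6
    num_w <- params$W[[1]]
    for (i in seq_along(num_w)) {
      p2 <- params; p2$W[[1]][i] <- p2$W[[1]][i] + eps
      p3 <- params; p3$W[[1]][i] <- p3$W[[1]][i] - eps
      num_w[i] <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
    }
    expect_equal(an$grads$W[[1]], num_w, tolerance = 1e-4)
    num_hw <- params$head_w
    for (i in seq_along(num_hw)) {
      p2 <- params; p2$head_w[i] <- p2$head_w[i] + eps
      p3 <- params; p3$head_w[i] <- p3$head_w[i] - eps
      num_hw[i] <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
    }
    expect_equal(an$grads$head_w, num_hw, tolerance = 1e-4)
  }
})

test_that("the network can overfit a single training example", {
  x <- random_fps(1, 16, p = 0.5, seed = 9)
  fit <- sa_dbn(x, 5.0, layer_sizes = c(16, 4),
                control = dbn_control(pretrain_epochs = 2, finetune_epochs = 800,
                                      lr0 = 0.1, batch = 1, seed = 9))
  expect_equal(predict(fit, x), 5.0, tolerance = 0.1)
})

test_that("zero fine-tuning epochs leave the zero head untouched", {
  x <- random_fps(20, 16, seed = 10)
  y <- runif(20, 1, 10)
  fit <- sa_dbn(x, y, c(16, 4),
                dbn_control(pretrain_epochs = 1, finetune_epochs = 0, seed = 1))
  expect_equal(fit$head_w, numeric(4))
  expect_equal(fit$head_b, 0)
  # zero head outputs 0, clamped to the bottom of the SAscore domain
  expect_equal(predict(fit, x), rep(1, 20))
})

test_that("prediction is deterministic, batched = row-by-row, and clamped", {
  d <- gen_sascore_data(n = 120, n_bits = 32, noise_sd = 0.3, seed = 11)
  fit <- sa_dbn(d$x, d$y, c(32, 8),
                dbn_control(pretrain_epochs = 2, finetune_epochs = 40,
                            batch = 30, seed = 11))
  p <- predict(fit, d$x)
  expect_identical(p, predict(fit, d$x))
  one_by_one <- vapply(seq_len(20), function(i) predict(fit, d$x[i, , drop = FALSE]),
                       numeric(1))
  expect_equal(one_by_one, p[1:20])
  expect_true(all(p >= 1 & p <= 10))
  dup <- predict(fit, d$x[c(3, 3), ])
  expect_identical(dup[1], dup[2])              # identical rows, identical scores
  expect_equal(dup[2], p[3], tolerance = 1e-12) # batch-shape float slack
  expect_error(predict(fit, matrix(0, 2, 33)), "width")
  # same seed, same model
  fit2 <- sa_dbn(d$x, d$y, c(32, 8),
                 dbn_control(pretrain_epochs = 2, finetune_epochs = 40,
                             batch = 30, seed = 11))
  expect_identical(predict(fit2, d$x), p)
})

test_that("empty or invalid regression targets are rejected", {
  x <- random_fps(10, 8, seed = 12)
  st <- dbn_pretrain(x, c(8, 4), dbn_control(pretrain_epochs = 1))
  expect_error(dbn_finetune(st, x[0, , drop = FALSE], numeric(0)), "empty")
  expect_error(dbn_finetune(st, x, rep(11, 10)), "\\[1, 10\\]")
})

test_that("the default architecture is 1024-512-128-32", {
  expect_equal(eval(formals(sa_dbn)$layer_sizes), c(1024, 512, 128, 32))
  expect_equal(eval(formals(dbn_pretrain)$layer_sizes), c(1024, 512, 128, 32))
})
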