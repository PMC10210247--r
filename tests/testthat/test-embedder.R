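test_that("sigmoid_transform satisfies its algebraic identities", {
  expect_equal(sigmoid_transform(0, 0.5, 6, 6), 0)
  expect_equal(sigmoid_transform(0.5, 0.5, 6, 6), 0.5)
  # sigma = 1, a = 6, b = 6, r = 2: 1 - 1/(1 + (2 - 1) * 2^6)^(6/6)... = 64/65
  expect_equal(sigmoid_transform(2, 1, 6, 6), 64 / 65)
  set.seed(41)
  for (k in 1:100) {
    sg <- runif(1, 0.05, 5); a <- runif(1, 0.5, 10); b <- runif(1, 0.5, 10)
    expect_equal(sigmoid_transform(0, sg, a, b), 0)
    expect_lt(abs(sigmoid_transform(sg, sg, a, b) - 0.5), 1e-12)
    r <- sort(runif(20, 0, 10 * sg))
    expect_true(all(diff(sigmoid_transform(r, sg, a, b)) >= 0))  # monotone
    expect_true(all(sigmoid_transform(r, sg, a, b) < 1))
  }
  expect_error(sigmoid_transform(-1, 1, 6, 6), "input error")
  expect_error(sigmoid_transform(1, -1, 6, 6), "input error")
})

test_that("sigmoid derivative matches finite differences", {
  set.seed(42)
  r <- runif(30, 0.01, 5)
  for (p in list(c(0.5, 6, 6), c(1, 2, 6), c(2, 1, 3))) {
    an <- rinmap:::sigmoid_transform_deriv(r, p[1], p[2], p[3])
    fd <- (sigmoid_transform(r + 1e-7, p[1], p[2], p[3]) -
             sigmoid_transform(r - 1e-7, p[1], p[2], p[3])) / 2e-7
    expect_equal(an, fd, tolerance = 1e-5)
  }
})

test_that("reconstruction_cost is the elementwise mean squared difference", {
  X <- rbind(c(0, 0), c(2, 2))
  expect_equal(reconstruction_cost(X, X), 0)
  expect_equal(reconstruction_cost(matrix(0), matrix(1)), 1)
  expect_equal(reconstruction_cost(X, rbind(c(1, 1), c(1, 1))), 1)
  expect_error(reconstruction_cost(X, matrix(0, 3, 2)), "input error")
})

test_that("sketch_distance_cost matches hand-derived pair values", {
  sp <- sigmoid_params()
  # identical rows: all distances 0, s(0) = 0, cost 0
  X <- matrix(1, 4, 3); Z <- matrix(2, 4, 2)
  expect_equal(sketch_distance_cost(X, Z, sp), 0)
  # 2-point batch with R12 = sigma_h, r12 = 0: (0.5 - 0)^2
  X2 <- rbind(rep(0, 3), c(sp$sigma_h, 0, 0))
  Z2 <- matrix(0, 2, 2)
  expect_equal(sketch_distance_cost(X2, Z2, sp), 0.25)
  # perfectly matched transformed distances: zero cost
  # (use sigma_l = sigma_h so Z = X projected achieves equality on 1-d data)
  sp_eq <- sigmoid_params(sigma_h = 1, a_h = 2, b_h = 6,
                          sigma_l = 1, a_l = 2, b_l = 6)
  X3 <- cbind(c(0, 1, 3), 0, 0)
  Z3 <- cbind(c(0, 1, 3), 0)
  expect_equal(sketch_distance_cost(X3, Z3, sp_eq), 0)
  expect_error(sketch_distance_cost(X3[1, , drop = FALSE],
                                    Z3[1, , drop = FALSE], sp), "input error")
})

test_that("sketch_distance_cost is invariant under rigid motion of Z and joint permutation", {
  set.seed(43)
  sp <- sigmoid_params()
  X <- matrix(runif(8 * 5), 8, 5)
  Z <- matrix(rnorm(8 * 2), 8, 2)
  ref <- sketch_distance_cost(X, Z, sp)
  for (k in 1:5) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Zr <- sweep(Z %*% R, 2, rnorm(2, 0, 10), "+")
    expect_equal(sketch_distance_cost(X, Zr, sp), ref)
    perm <- sample(8)
    expect_equal(sketch_distance_cost(X[perm, ], Z[perm, ], sp), ref)
  }
})

test_that("backpropagated gradients match finite differences on a 5-point batch", {
  set.seed(44)
  X <- matrix(runif(5 * 4), 5, 4)
  cfg <- encodermap_config(n_steps = 1, batch_size = 5,
                           hidden_widths = c(6, 5), latent_dim = 2, seed = 9)
  sp <- sigmoid_params()
  set.seed(9)
  net <- rinmap:::init_network(4, cfg$hidden_widths, cfg$latent_dim)
  cg <- rinmap:::encodermap_cost_grad(net, X, cfg, sp)
  eps <- 1e-6
  max_rel <- 0
  for (l in seq_along(net$layers)) for (p in c("W", "b")) {
    g <- cg$grads[[l]][[paste0("d", p)]]
    for (k in seq_along(net$layers[[l]][[p]])) {
      n2 <- net
      n2$layers[[l]][[p]][k] <- n2$layers[[l]][[p]][k] + eps
      cp <- rinmap:::encodermap_cost_grad(n2, X, cfg, sp)$total
      n2$layers[[l]][[p]][k] <- n2$layers[[l]][[p]][k] - 2 * eps
      cm <- rinmap:::encodermap_cost_grad(n2, X, cfg, sp)$total
      fd <- (cp - cm) / (2 * eps)
      rel <- abs(fd - g[k]) / max(abs(fd), abs(g[k]), 1e-8)
      max_rel <- max(max_rel, rel)
    }
  }
  expect_lt(max_rel, 1e-4)
})

test_that("training reduces the cost and is reproducible per seed", {
  set.seed(45)
  X <- matrix(runif(120 * 6), 120, 6)
  cfg <- encodermap_config(n_steps = 80, batch_size = 40,
                           hidden_widths = c(16, 16), learning_rate = 1e-3,
                           seed = 7)
  m1 <- train_encodermap(X, cfg, sigmoid_params())
  m2 <- train_encodermap(X, cfg, sigmoid_params())
  expect_identical(m1$final_projection, m2$final_projection)
  expect_lt(m1$trace$total[80], m1$trace$total[1])
  expect_equal(nrow(m1$trace), 80)
  # different seed gives a different model
  m3 <- train_encodermap(X, encodermap_config(n_steps = 80, batch_size = 40,
                                              hidden_widths = c(16, 16),
                                              learning_rate = 1e-3, seed = 8),
                         sigmoid_params())
  expect_false(identical(m1$final_projection, m3$final_projection))
})

test_that("constant input collapses the projection and is reconstructed", {
  X <- matrix(0.6, 100, 5)
  cfg <- encodermap_config(n_steps = 400, batch_size = 100,
                           hidden_widths = c(16, 16), learning_rate = 1e-2,
                           w_dist = 0, seed = 3)
  m <- train_encodermap(X, cfg, sigmoid_params())
  expect_lt(m$trace$auto[400], m$trace$auto[1])
  pm <- project_map(m, X)
  expect_lt(max(apply(pm$coords, 2, function(v) diff(range(v)))), 1e-8)
  expect_lt(reconstruction_cost(X, reconstruct(m, X)), 1e-3)
})

test_that("well-separated clusters stay linearly separable in the 2-d map", {
  set.seed(46)
  centers <- matrix(rnorm(3 * 10), 3, 10) * 10
  lab <- rep(1:3, each = 200)
  X <- centers[lab, ] + matrix(rnorm(600 * 10, 0, 0.5), 600, 10)
  cfg <- encodermap_config(n_steps = 200, batch_size = 150,
                           hidden_widths = c(32, 32), learning_rate = 1e-4,
                           seed = 12)
  m <- train_encodermap(X, cfg, sigmoid_params(sigma_h = 10))
  Z <- project_map(m, X)$coords
  # one-vs-rest logistic classifiers on the 2-d coordinates
  acc <- mean(sapply(1:3, function(cl) {
    y <- as.integer(lab == cl)
    fit <- suppressWarnings(glm(y ~ Z[, 1] + Z[, 2], family = binomial))
    mean((fitted(fit) > 0.5) == (y == 1))
  }))
  expect_gte(acc, 0.95)
})

test_that("projection is deterministic and consistent with cached training state", {
  set.seed(47)
  X <- matrix(runif(60 * 5), 60, 5)
  cfg <- encodermap_config(n_steps = 30, batch_size = 60,
                           hidden_widths = c(8, 8), seed = 2)
  m <- train_encodermap(X, cfg, sigmoid_params())
  p1 <- project_map(m, X)
  p2 <- project_map(m, X)
  expect_identical(p1$coords, p2$coords)
  expect_identical(p1$coords, m$final_projection)
  # identical frames project to identical rows
  Xdup <- rbind(X[1, ], X[1, ])
  expect_equal(project_map(m, Xdup)$coords[1, ],
               project_map(m, Xdup)$coords[2, ])
  # decoder-encoder pathway agrees with the cost-function pathway
  cg <- rinmap:::encodermap_cost_grad(m$net, X, cfg, sigmoid_params())
  expect_equal(reconstruction_cost(X, reconstruct(m, X)), cg$auto)
  expect_error(project_map(m, X[, 1:3]), "input error")
  expect_error(reconstruct(m, X[, 1:3]), "input error")
})

test_that("model checkpoints round-trip through JSON with identical projections", {
  set.seed(48)
  X <- matrix(runif(50 * 4), 50, 4)
  cfg <- encodermap_config(n_steps = 20, batch_size = 50,
                           hidden_widths = c(8L, 8L), seed = 5)
  m <- train_encodermap(X, cfg, sigmoid_preset("twodomain"))
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(project_map(m2, X)$coords, project_map(m, X)$coords)
  expect_equal(m2$params$sigma_h, 1.0)
  expect_equal(m2$config$n_steps, 20L)
  expect_error(load_model(tempfile()), "I/O error")
})

test_that("training rejects invalid inputs and flags divergence", {
  X <- matrix(runif(40), 10, 4)
  Xbad <- X; Xbad[3, 2] <- NaN
  cfg <- encodermap_config(n_steps = 5, batch_size = 10, hidden_widths = c(4L))
  expect_error(train_encodermap(Xbad, cfg, sigmoid_params()), "input error")
  expect_error(train_encodermap(X[1:5, ], cfg, sigmoid_params()), "input error")
  expect_error(encodermap_config(batch_size = 1), "input error")
  expect_error(encodermap_config(learning_rate = 0), "input error")
  expect_error(encodermap_config(periodicity = 2 * pi), "input error")
  expect_error(sigmoid_params(sigma_h = -1), "input error")
})
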