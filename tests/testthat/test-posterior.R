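test_that("the V conditional collapses to known forms", {
  p <- 4
  gr <- identity_graph(p)
  X <- matrix(runif(4 * p, 0, 2), 4, p)
  # B = I, L = I, eta = 0: mean is X itself
  vc <- v_conditional(X, diag(4), gr, sigma2 = 0.5, eta = 0)
  expect_equal(unname(vc$M), X)
  # general B, eta = 0: ridge-free least squares
  set.seed(2)
  B <- matrix(runif(4 * 2, 0.5, 2), 4, 2)
  vc2 <- v_conditional(X, B, gr, sigma2 = 0.5, eta = 0)
  expect_equal(unname(vc2$M), solve(crossprod(B), crossprod(B, X)))
  # row covariance is sigma2 * (B'B)^-1
  expect_equal(vc2$row_cov, 0.5 * solve(crossprod(B)))
})

test_that("the scalar conditional mean matches maximizing the exact log posterior", {
  # c = p = n = 1: M = x/b - sigma2*eta/(b^2 l)
  b <- 1.3; l <- 0.9; x <- 2.0; sigma2 <- 0.3; eta <- 0.8
  gr <- build_laplacian(matrix(0, 1, 1), ridge_eps = l)
  vc <- v_conditional(matrix(x), matrix(b), gr, sigma2, eta)
  expect_equal(vc$M[1, 1], x / b - sigma2 * eta / (b^2 * l))
  # independent oracle: maximize the exact log joint over V on [0, 10]
  opt <- optimize(function(v) log_joint_density(matrix(x), matrix(b), matrix(v),
                                                sigma2, eta, gr),
                  interval = c(0, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, vc$M[1, 1], tolerance = 1e-6)
})

test_that("collinear reference profiles raise an informative error", {
  gr <- identity_graph(3)
  B <- cbind(c(1, 2, 1), c(2, 4, 2))          # second column = 2 * first
  X <- matrix(1, 3, 3)
  expect_error(v_conditional(X, B, gr, 1, 1), "collinear")
})

test_that("noise-scale conditional has the stated shape and scale", {
  n <- 100; p <- 50; c_ <- 5
  set.seed(4)
  B <- matrix(runif(n * c_, 0.5, 1.5), n, c_)
  V <- matrix(runif(c_ * p), c_, p)
  gr <- identity_graph(p)
  X <- B %*% V                                 # E = 0
  par <- sigma2_posterior_params(X, B, V, gr)
  expect_equal(par$shape, 1e-4 + n * p / 2 + c_ * p / 2)   # 2625.0001
  expect_equal(par$scale, 1e-4)                             # b1 alone when E = 0
  par_lik <- sigma2_posterior_params(X, B, V, gr, shape_mode = "likelihood_only")
  expect_equal(par_lik$shape, 1e-4 + n * p / 2)
  # trace term: tr(L_pd E'E) for a non-trivial residual
  X2 <- X + 0.2
  par2 <- sigma2_posterior_params(X2, B, V, gr)
  E <- X2 - B %*% V
  expect_equal(par2$scale, 1e-4 + sum(diag(gr$L_pd %*% crossprod(E))) / 2)
  # fixed seed -> identical draws
  set.seed(10); d1 <- sample_sigma2(X2, B, V, gr)
  set.seed(10); d2 <- sample_sigma2(X2, B, V, gr)
  expect_identical(d1, d2)
})

test_that("sparsity-rate conditional has the stated shape, scale and mean", {
  c_ <- 5; p <- 50
  V0 <- matrix(0, c_, p)
  par0 <- eta_posterior_params(V0)
  expect_equal(par0$shape, 1e-4 + c_ * p)                  # 250.0001
  expect_equal(par0$scale, 1e4)                            # 1/(0 + 1e-4)
  V <- matrix(runif(c_ * p), c_, p)
  par <- eta_posterior_params(V)
  expect_equal(par$scale, 1 / (sum(V) + 1e-4))
  # Monte-Carlo mean matches shape * scale within 3 SE
  set.seed(77)
  draws <- replicate(1e5, sample_eta(V))
  mu <- par$shape * par$scale
  se <- sqrt(par$shape) * par$scale / sqrt(1e5)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("sigma2 and eta draws follow their stated conditional laws (KS)", {
  set.seed(123)
  n <- 20; p <- 10; c_ <- 3
  B <- matrix(runif(n * c_, 0.5, 1.5), n, c_)
  V <- matrix(runif(c_ * p), c_, p)
  gr <- identity_graph(p)
  X <- pmax(B %*% V + matrix(rnorm(n * p, sd = 0.3), n, p), 0)
  par <- sigma2_posterior_params(X, B, V, gr)
  s2 <- replicate(2e4, sample_sigma2(X, B, V, gr))
  ks1 <- suppressWarnings(stats::ks.test(s2, function(q)
    stats::pgamma(1 / q, shape = par$shape, rate = par$scale, lower.tail = FALSE)))
  expect_gt(ks1$p.value, 0.01)
  pare <- eta_posterior_params(V)
  et <- replicate(2e4, sample_eta(V))
  ks2 <- suppressWarnings(stats::ks.test(et, "pgamma",
                                         shape = pare$shape, scale = pare$scale))
  expect_gt(ks2$p.value, 0.01)
})

test_that("log joint density behaves as a validation oracle", {
  gr <- identity_graph(2)
  B <- matrix(c(1, 0.5, 0.2, 1.4), 2, 2)
  X <- matrix(c(1, 2, 0.5, 1), 2, 2)
  V <- matrix(0.3, 2, 2)
  expect_equal(log_joint_density(X, B, V - 1, 1, 1, gr), -Inf)
  # with B = 0 the exponential prior alone drives V to 0
  B0 <- matrix(0, 2, 2)
  vals <- sapply(c(0, 0.2, 0.5, 1), function(v)
    log_joint_density(X, B0, matrix(v, 2, 2), 1, 1, gr))
  expect_true(all(diff(vals) < 0))
  # 1x1 case matches an independently written scalar formula
  b <- 1.2; l <- 0.7; x <- 1.5; v <- 0.4; s2 <- 0.6; eta <- 0.9
  g1 <- build_laplacian(matrix(0, 1, 1), ridge_eps = l)
  a1 <- b1 <- a2 <- 1e-4; b2 <- 1e4
  manual <- -0.5 * log(2 * pi * s2) + 0.5 * log(l) - l * (x - b * v)^2 / (2 * s2) +
    log(eta) - eta * v +
    a1 * log(b1) - lgamma(a1) - (a1 + 1) * log(s2) - b1 / s2 +
    -a2 * log(b2) - lgamma(a2) + (a2 - 1) * log(eta) - eta / b2
  expect_equal(log_joint_density(matrix(x), matrix(b), matrix(v), s2, eta, g1),
               manual)
})

test_that("the log-joint conditional of V matches the TMN kernel on a 2x2 case", {
  # quadratic + linear log density: central differences are exact, so the
  # finite-difference gradient at the conditional mean must vanish
  set.seed(31)
  n <- 5
  B <- matrix(runif(n * 2, 0.5, 2), n, 2)
  lay <- make_region_layout(c(2, 1), n_regions = 1)
  gr <- build_spatial_graph(spot_geometry(lay$coords),
                            graph_config(sigma_A2 = 2, ridge_eps = 0.05))
  V_star <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2)
  X <- B %*% V_star
  sigma2 <- 0.05; eta <- 0.1
  vc <- v_conditional(X, B, gr, sigma2, eta)
  expect_true(all(vc$M > 0.05))
  h <- 1e-4
  grad <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    Vp <- vc$M; Vm <- vc$M
    Vp[i, j] <- Vp[i, j] + h; Vm[i, j] <- Vm[i, j] - h
    grad[i, j] <- (log_joint_density(X, B, Vp, sigma2, eta, gr) -
                   log_joint_density(X, B, Vm, sigma2, eta, gr)) / (2 * h)
  }
  expect_lt(max(abs(grad)), 1e-8)
})
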