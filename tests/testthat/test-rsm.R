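ccd <- generate_ccd(celecoxib_factors())

test_that("noise-free responses recover the generating coefficients", {
  for (rn in c("Y1", "Y2")) {
    truth <- reference_surface(rn)
    resp <- generate_doe_dataset(ccd, truth, noise_sd = 0)
    fit <- fit_quadratic(ccd, resp, rn)
    expect_equal(coef(fit), coef(truth), tolerance = 1e-6)
    # block offsets must vanish for a surface-only truth
    expect_equal(unname(fit$block_effects), c(0, 0), tolerance = 1e-8)
  }
})

test_that("least squares equals the normal-equations oracle", {
  set.seed(7)
  for (rep in 1:5) {
    X <- matrix(runif(20 * 3, 0, 2), 20, 3)
    y <- rnorm(20, sd = 3)
    dm <- cbind(1, qbdoe:::.quad_features(X))
    beta_oracle <- solve(crossprod(dm), crossprod(dm, y))
    d <- structure(
      data.frame(run_order = 1:20, code = sprintf("R%02d", 1:20),
                 block = 1L, point_type = "cube",
                 coded_X1 = X[, 1], coded_X2 = X[, 2], coded_X3 = X[, 3],
                 X1 = X[, 1], X2 = X[, 2], X3 = X[, 3]),
      design_kind = "ccd", factor_columns = c("X1", "X2", "X3"),
      class = c("design_matrix", "data.frame"))
    fit <- fit_quadratic(d, data.frame(code = d$code, Y = y), "Y",
                         block_handling = "ignore")
    expect_equal(unname(coef(fit)), drop(beta_oracle), tolerance = 1e-8)
  }
})

test_that("constant responses give a pure-intercept model", {
  resp <- data.frame(code = ccd$code, Y = rep(5.5, 20))
  fit <- fit_quadratic(ccd, resp, "Y")
  expect_equal(unname(coef(fit)), c(5.5, rep(0, 9)), tolerance = 1e-9)
})

test_that("predict evaluates the full quadratic polynomial", {
  m <- reference_surface("Y1")
  expect_equal(round(predict(m, c(1.5, 0.2, 0.5)), 1), 83.1)
  expect_equal(predict(m, c(1, 0.1, 1)), 30.5, tolerance = 0.05)
  z <- quadratic_model(c("a", "b", "c"), 0, c(0, 0, 0), c(0, 0, 0),
                       c(0, 0, 0))
  expect_equal(predict(z, c(3, -2, 7)), 0)
  expect_error(predict(m, c(1, 2)), "3 factor")
  # matrix input
  expect_equal(predict(m, rbind(c(1.5, 0.2, 0.5), c(1, 0.1, 1)))[1],
               predict(m, c(1.5, 0.2, 0.5)))
})

test_that("predictions agree across coded and actual scales", {
  truth <- reference_surface("Y2")
  resp <- generate_doe_dataset(ccd, truth, noise_sd = 3, seed = 11)
  fa <- fit_quadratic(ccd, resp, "Y2", scale = "actual")
  fc <- fit_quadratic(ccd, resp, "Y2", scale = "coded")
  fs <- celecoxib_factors()
  set.seed(3)
  cc <- matrix(runif(30, -1.5, 1.5), 10, 3)
  act <- sapply(1:3, function(j) coded_to_actual(fs[[j]], cc[, j]))
  expect_equal(predict(fc, cc), predict(fa, act), tolerance = 1e-9)
})

test_that("ANOVA decomposition is internally consistent", {
  resp <- generate_doe_dataset(ccd, reference_surface("Y1"), noise_sd = 6,
                               seed = 5)
  a <- rsm_anova(ccd, resp, "Y1")
  ss <- function(term) a$sum_sq[a$term == term]
  df <- function(term) a$df[a$term == term]
  # sequential additivity: block + model + residual = corrected total
  expect_equal(ss("Block") + ss("Model") + ss("Residual"), ss("Cor Total"),
               tolerance = 1e-9 * ss("Cor Total"))
  # residual split
  expect_equal(ss("Lack of Fit") + ss("Pure Error"), ss("Residual"),
               tolerance = 1e-9 * ss("Residual"))
  expect_equal(df("Lack of Fit") + df("Pure Error"), df("Residual"))
  expect_equal(df("Block") + 9 + df("Residual"), df("Cor Total"))
  # R^2 definition
  expect_equal(attr(a, "r_squared"), 1 - ss("Residual") / ss("Cor Total"),
               tolerance = 1e-12)
  # pure error matches a direct replicate computation (6 centres, per block)
  y <- resp$Y1[match(ccd$code, resp$code)]
  ctr <- ccd$point_type == "center"
  pe <- sum(tapply(y[ctr], ccd$block[ctr],
                   function(v) sum((v - mean(v))^2)))
  expect_equal(ss("Pure Error"), pe, tolerance = 1e-9)
})

test_that("an exact quadratic yields zero residual and undefined F", {
  resp <- generate_doe_dataset(ccd, reference_surface("Y2"), noise_sd = 0)
  a <- rsm_anova(ccd, resp, "Y2")
  expect_lt(a$sum_sq[a$term == "Residual"], 1e-14 *
              a$sum_sq[a$term == "Cor Total"])
  expect_equal(attr(a, "r_squared"), 1, tolerance = 1e-12)
})

test_that("coefficient estimates converge as noise shrinks", {
  truth <- reference_surface("Y2")
  err <- sapply(c(1, 0.1, 0.01), function(s) {
    resp <- generate_doe_dataset(ccd, truth, noise_sd = s, seed = 99)
    max(abs(coef(fit_quadratic(ccd, resp, "Y2")) - coef(truth)))
  })
  expect_true(all(diff(err) < 0))
  # linear-model error is proportional to sigma for a fixed noise shape
  expect_equal(err[1] / err[3], 100, tolerance = 1e-6)
  expect_lt(err[3], 1e-2 * max(abs(coef(truth))))
})

test_that("screening recovers a single active factor exactly", {
  pb <- generate_plackett_burman(6)
  y <- pb$F1  # response = coded level of factor 1
  eff <- screen_effects(pb, data.frame(code = pb$code, Y = y), "Y")
  expect_equal(eff$effect[eff$factor == "F1"], 2)
  expect_equal(unname(eff$effect[eff$factor != "F1"]), rep(0, 5))
  expect_equal(eff$factor[1], "F1")  # ranked by |effect|
  # all-equal responses: all effects zero
  eff0 <- screen_effects(pb, data.frame(code = pb$code, Y = rep(3, 12)), "Y")
  expect_equal(eff0$effect, rep(0, 6))
})

test_that("dummy-column t-tests hold their type-I error rate", {
  pb <- generate_plackett_burman(6)
  set.seed(123)
  n_sim <- 1000L
  flags <- replicate(n_sim, {
    y <- rnorm(12)
    mean(screen_effects(pb, data.frame(code = pb$code, Y = y), "Y",
                        alpha_level = 0.05)$significant)
  })
  rate <- mean(flags)
  mc_se <- sqrt(0.05 * 0.95 / (n_sim * 6))
  expect_lt(abs(rate - 0.05), 4 * mc_se + 0.01)
})
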