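test_that("feature expansion counts and ordering are deterministic", {
  tab <- data.frame(a = runif(20), b = runif(20))
  s2 <- feature_spec(tab, classes = "linear")
  expect_equal(length(s2$features), 2)
  # ten variables with all classes: 10 + 10 + 45
  tab10 <- as.data.frame(matrix(runif(200), 20, 10))
  names(tab10) <- BIOCLIM_VARS
  s65 <- feature_spec(tab10)
  expect_equal(length(s65$features), 65)
  nm <- vapply(s65$features, `[[`, "", "name")
  expect_identical(nm[1:10], BIOCLIM_VARS)
  expect_identical(nm[11:20], paste0(BIOCLIM_VARS, "^2"))
  expect_match(nm[21], "MTEMP\\*TEMPR")
  # constant variable dropped with its features
  tabc <- data.frame(MTEMP = runif(10), TEMPR = rep(3, 10))
  expect_warning(sc <- feature_spec(tabc), "constant")
  expect_equal(length(sc$features), 2)   # linear + quadratic of MTEMP only
  expect_identical(sc$dropped, "TEMPR")
})

test_that("two-cell fit recovers the closed-form weight ln(7/3)", {
  # background features {0, 1}; presence mean 0.7; beta 0:
  # q(f=1) must equal 0.7, so lambda solves e^l/(1+e^l) = 0.7.
  # bisection oracle for the anchor
  f <- function(l) exp(l) / (1 + exp(l)) - 0.7
  lo <- 0; hi <- 5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  Xp <- matrix(c(rep(1, 7), rep(0, 3)), ncol = 1)
  Xb <- matrix(c(0, 1), ncol = 1)
  fit <- maxent_fit_design(Xp, Xb, beta = 0)
  expect_equal(unname(fit$lambda), lo, tolerance = 1e-7)
  expect_equal(unname(fit$lambda), log(7 / 3), tolerance = 1e-7)
  raw <- exp(c(0, 1) * fit$lambda - fit$logZ)
  expect_equal(raw, c(0.3, 0.7), tolerance = 1e-7)
})

test_that("no-signal data give the uniform model with H = log m", {
  Xp <- matrix(rep(0.5, 6), ncol = 1)
  Xb <- matrix(rep(0.5, 10), ncol = 1)
  expect_warning(fit <- maxent_fit_design(Xp, Xb, beta = 0), NA)
  expect_equal(unname(fit$lambda), 0)
  expect_equal(fit$H, log(10))
})

test_that("probabilities conserve, constraints match at beta 0 and slacken at beta > 0", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      Xb <- matrix(runif(80 * 3), 80, 3)
      Xp <- matrix(runif(25 * 3, 0.25, 0.95), 25, 3)
    })
    f0 <- maxent_fit_design(Xp, Xb, beta = 0)
    q <- exp(Xb %*% f0$lambda - f0$logZ)
    expect_lt(abs(sum(q) - 1), 1e-9)
    expect_lt(max(abs(crossprod(Xb, q) - colMeans(Xp))), 1e-6)
    for (b in c(0.5, 1)) {
      fb <- maxent_fit_design(Xp, Xb, beta = b)
      qb <- exp(Xb %*% fb$lambda - fb$logZ)
      slack <- abs(as.vector(crossprod(Xb, qb)) - colMeans(Xp))
      bound <- b * sqrt(pmax(colMeans(Xp^2) - colMeans(Xp)^2, 0)) /
        sqrt(nrow(Xp))
      expect_true(all(slack <= bound + 1e-6))
    }
  }
})

test_that("L1 regularization shrinks the single-feature weight", {
  Xp <- matrix(c(rep(1, 7), rep(0, 3)), ncol = 1)
  Xb <- matrix(c(0, 1), ncol = 1)
  l0 <- abs(maxent_fit_design(Xp, Xb, beta = 0)$lambda)
  prev <- l0
  for (b in c(0.5, 1, 2)) {
    lb <- abs(maxent_fit_design(Xp, Xb, beta = b)$lambda)
    expect_lte(lb, prev + 1e-9)
    prev <- lb
  }
})

test_that("fit agrees with a derivative-free oracle on random instances", {
  # a slice of the broader acceptance sweep; the full 20-instance version
  # lives in the acceptance tests
  for (seed in 1:4) {
    withr::with_seed(seed, {
      m <- sample(20:60, 1); p <- sample(1:3, 1)
      Xb <- matrix(runif(m * p), m, p)
      Xp <- matrix(runif(12 * p, 0.2, 0.9), 12, p)
    })
    b <- c(0, 0.5, 1)[(seed %% 3) + 1]
    fit <- maxent_fit_design(Xp, Xb, beta = b)
    ora <- oracle_fit(Xp, Xb, b)
    expect_lt(max(abs(fit$lambda - ora$lambda)), 1e-4)
    expect_lt(abs(fit_objective(fit, Xp, Xb) - ora$objective), 1e-8)
  }
})

test_that("the penalized objective is monotone along the optimizer trace", {
  withr::with_seed(9, {
    Xb <- matrix(runif(200), 50, 4)
    Xp <- matrix(runif(40, 0.3, 1), 10, 4)
  })
  fit <- maxent_fit_design(Xp, Xb, beta = 0.5)
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("logistic output anchors at 0.5 for the uniform model and is monotone", {
  tab <- data.frame(MTEMP = runif(30, 10, 20))
  bg <- data.frame(MTEMP = runif(50, 10, 20))
  # uniform: presences drawn to match the background means exactly
  fitu <- maxent_fit(bg, bg, beta = 0, classes = "linear")
  expect_equal(unname(fitu$lambda), 0, tolerance = 1e-6)
  expect_equal(predict_logistic(fitu, tab), rep(0.5, 30), tolerance = 1e-6)
  # fitted two-cell example: logistic increasing in the raw score
  Xp <- data.frame(v = c(rep(1, 7), rep(0, 3)))
  Xb <- data.frame(v = c(0, 1))
  fit <- maxent_fit(Xp, Xb, beta = 0, classes = "linear")
  lo <- predict_logistic(fit, data.frame(v = c(0, 1)))
  expect_lt(lo[1], lo[2])
  raw <- predict_raw(fit, data.frame(v = c(0, 1)))
  expect_equal(lo, exp(fit$H) * raw / (1 + exp(fit$H) * raw))
})

test_that("projection clamps to training bounds outside the envelope", {
  st <- tiny_stack(6, 6)
  # train inside a sub-region so part of the stack is out of bounds
  ctr <- cell_center(st$layers$MTEMP, rep(2:4, each = 3), rep(2:4, 3))
  pts <- data.frame(id = paste0("p", 1:9), x = ctr[, "x"], y = ctr[, "y"])
  tab <- extract_values(st, pts)
  fit <- maxent_fit(tab[c("MTEMP", "PREC")], tab[c("MTEMP", "PREC")],
                    beta = 0.5, classes = c("linear", "quadratic"))
  # inside the training range clamp is the identity
  inside <- tab[c("MTEMP", "PREC")]
  expect_equal(predict_raw(fit, inside, clamp = TRUE),
               predict_raw(fit, inside, clamp = FALSE))
  # a cell beyond the max scores as if at the max when clamped
  beyond <- data.frame(MTEMP = max(tab$MTEMP) + 10, PREC = tab$PREC[1])
  at_max <- data.frame(MTEMP = max(tab$MTEMP), PREC = tab$PREC[1])
  expect_equal(predict_raw(fit, beyond, clamp = TRUE),
               predict_raw(fit, at_max, clamp = FALSE))
  # unclamped, a positive-weight linear response keeps growing
  Xp <- data.frame(v = runif(40, 0.6, 1)); Xb <- data.frame(v = runif(80))
  flin <- maxent_fit(Xp, Xb, beta = 0, classes = "linear")
  expect_gt(flin$lambda[["v"]], 0)
  hi <- predict_raw(flin, data.frame(v = 2), clamp = FALSE)
  at1 <- predict_raw(flin, data.frame(v = max(c(Xp$v, Xb$v))), clamp = FALSE)
  expect_gt(hi, at1)
  expect_equal(predict_raw(flin, data.frame(v = 2), clamp = TRUE), at1)
})

test_that("variable contributions sum to 100, split ties evenly, rank-match drop-one refits", {
  # single variable: everything credited to it
  Xp <- data.frame(MTEMP = runif(30, 15, 25))
  Xb <- data.frame(MTEMP = runif(60, 10, 28))
  f1 <- maxent_fit(Xp, Xb, beta = 0.5, classes = "linear")
  ct1 <- variable_contribution(f1)
  expect_equal(ct1$percent[ct1$variable == "MTEMP"], 100)
  # duplicated column: symmetric 50/50 by construction
  Xp2 <- data.frame(a = Xp$MTEMP, b = Xp$MTEMP)
  Xb2 <- data.frame(a = Xb$MTEMP, b = Xb$MTEMP)
  f2 <- maxent_fit(Xp2, Xb2, beta = 0.5, classes = "linear")
  ct2 <- variable_contribution(f2)
  expect_equal(sort(ct2$percent), c(50, 50))
  expect_equal(unname(f2$lambda["a"]), unname(f2$lambda["b"]))
  # three-variable synthetic fit: percentages sum to 100 and the ranking
  # agrees with the loss of likelihood from dropping each variable
  withr::with_seed(31, {
    n <- 400
    bg <- data.frame(u = runif(n), v = runif(n), w = runif(n))
    keep <- runif(n) < exp(3 * bg$u + 1.5 * bg$v) / exp(4.5)
    pres <- bg[keep, ][1:60, ]
  })
  f3 <- maxent_fit(pres, bg, beta = 0, classes = "linear")
  ct3 <- variable_contribution(f3)
  expect_equal(sum(ct3$percent), 100)
  drop_gain <- vapply(c("u", "v", "w"), function(dropv) {
    vars <- setdiff(c("u", "v", "w"), dropv)
    sub <- maxent_fit(pres[vars], bg[vars], beta = 0, classes = "linear")
    # likelihood lost without this variable (higher = more important)
    mean(log(predict_raw(f3, pres))) - mean(log(predict_raw(sub, pres[vars])))
  }, 0.0)
  expect_equal(order(-ct3$percent[match(c("u", "v", "w"), ct3$variable)]),
               order(-drop_gain))
})

test_that("single-variable jackknife flags the true driver and the noise variable", {
  withr::with_seed(17, {
    n <- 800
    bg <- data.frame(driver = runif(n), noise = runif(n))
    keep <- runif(n) < exp(4 * bg$driver) / exp(4)
    pres <- bg[keep, ][1:80, ]
    test_p <- bg[keep, ][81:160, ]
  })
  jk <- jackknife_single(pres, bg, test_p, beta = 0.5)
  expect_identical(jk$variable, c("driver", "noise", "(all)"))
  expect_lt(abs(jk$auc[jk$variable == "noise"] - 0.5), 0.05)
  expect_gt(jk$auc[jk$variable == "driver"],
            jk$auc[jk$variable == "noise"])
  # one-variable input: jackknife equals the full model
  jk1 <- jackknife_single(pres["driver"], bg["driver"], test_p["driver"],
                          beta = 0.5)
  expect_equal(jk1$auc[1], jk1$auc[2], tolerance = 1e-9)
})

test_that("model serialization reloads and projects bit-identically", {
  st <- tiny_stack(6, 6)
  bg <- sample_background(st, mk_grid(matrix(1, 6, 6)), 100, 1)
  btab <- extract_values(st, bg)
  msk <- range_mask(mk_grid({m <- matrix(0, 6, 6); m[4:6, 1:3] <- 1; m}),
                    "modern")
  pts <- sample_presence(msk, sample_design(9, 1, 3), 1)
  ptab <- extract_values(st, pts)
  # tiny_stack holds some spatially constant layers; dropping them is the
  # documented behaviour
  fit <- suppressWarnings(maxent_fit(ptab[BIOCLIM_VARS], btab[BIOCLIM_VARS],
                                     beta = 1))
  p <- withr::local_tempfile(fileext = ".json")
  write_model(fit, p)
  fit2 <- read_model(p)
  m1 <- project_model(fit, st)
  m2 <- project_model(fit2, st)
  # identical up to the double-precision text round-trip of the weights
  expect_equal(m1$logistic$values, m2$logistic$values, tolerance = 1e-12)
  expect_equal(fit2$lambda, fit$lambda, tolerance = 1e-14)
  expect_equal(fit2$H, fit$H)
  expect_identical(fit2$spec$variables, fit$spec$variables)
})

test_that("parameter recovery from a known Gibbs truth (dev-scale)", {
  sc <- cached("sc_recovery_small", gen_scenario(list(rows = 48, cols = 48,
                                                      seed = 5)))
  ptab <- suppressMessages(
    extract_values(sc$stack, sample_from_truth(sc, 600, seed = 5)))
  btab <- suppressMessages(
    extract_values(sc$stack,
                   sample_background(sc$stack, sc$native_region, 4000, 5)))
  vars <- names(sc$true_weights)
  fit <- maxent_fit(ptab[vars], btab[vars], beta = 0, classes = "linear")
  rel <- abs(fit$lambda[vars] - sc$true_weights) / sc$true_weights
  expect_lt(max(rel), 0.25)   # looser than the full-scale acceptance run
  map <- project_model(fit, sc$stack, clamp = FALSE)
  nat <- !is.na(sc$native_region$values) & sc$native_region$values == 1
  expect_gt(cor(map$logistic$values[nat], sc$truth$values[nat],
                method = "spearman"), 0.9)
})
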