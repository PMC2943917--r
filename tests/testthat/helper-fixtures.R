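# Shared fixtures: everything is built in code at test time.

mk_grid <- function(m, origin = c(0, nrow(as.matrix(m))), cell_size = 1,
                    nodata = -9999) {
  grid_create(as.matrix(m), origin = origin, cell_size = cell_size,
              nodata = nodata)
}

# a small internally consistent bioclim stack with independent
# temperature (north-south) and moisture (west-east) gradients
tiny_stack <- function(nr = 8, nc = 8) {
  tgrad <- matrix(rep(seq(10, 28, length.out = nr), nc), nr, nc)
  pgrad <- matrix(rep(seq(1200, 300, length.out = nc), each = nr), nr, nc)
  L <- list(
    MTEMP = tgrad, TEMPR = matrix(10, nr, nc),
    ISO = matrix(0.5, nr, nc), TEMPS = matrix(2, nr, nc),
    MTWM = tgrad + 6, MTCM = tgrad - 6,
    PREC = pgrad, PRECS = matrix(20, nr, nc),
    PWQ = pgrad * 0.4, PDQ = pgrad * 0.1)
  bioclim_stack(lapply(L, mk_grid))
}

# constant monthly climate helper
const_monthly <- function(tmin = 10, tmax = 20, prec = 50, nr = 2, nc = 2) {
  monthly_climate(
    tmin = replicate(12, mk_grid(matrix(tmin, nr, nc)), simplify = FALSE),
    tmax = replicate(12, mk_grid(matrix(tmax, nr, nc)), simplify = FALSE),
    prec = replicate(12, mk_grid(matrix(prec, nr, nc)), simplify = FALSE))
}

# derivative-free direct maximization of the same penalized objective:
# cyclic 1-D golden-section/parabolic search per coordinate. Independent of
# the package's gradient-based coordinate descent.
oracle_fit <- function(Xp, Xb, beta) {
  pmean <- colMeans(Xp)
  m_p <- nrow(Xp)
  psd <- sqrt(pmax(colMeans(Xp^2) - pmean^2, 0))
  pen <- beta * psd / sqrt(m_p)
  J <- function(l) {
    u <- Xb %*% l
    mx <- max(u)
    -sum(l * pmean) + mx + log(sum(exp(u - mx))) + sum(pen * abs(l))
  }
  l <- numeric(ncol(Xp))
  Jc <- J(l)
  repeat {
    for (j in seq_along(l)) {
      o <- stats::optimize(function(t) J(replace(l, j, t)),
                           c(l[j] - 20, l[j] + 20), tol = 1e-12)
      l[j] <- o$minimum
    }
    Jn <- J(l)
    if (Jc - Jn < 1e-13) break
    Jc <- Jn
  }
  list(lambda = l, objective = Jc, J = J)
}

# penalized objective of a fitted nm_maxent on its training design
fit_objective <- function(fit, Xp, Xb) {
  pmean <- colMeans(Xp)
  psd <- sqrt(pmax(colMeans(Xp^2) - pmean^2, 0))
  pen <- fit$beta * psd / sqrt(nrow(Xp))
  u <- Xb %*% fit$lambda
  mx <- max(u)
  -sum(fit$lambda * pmean) + mx + log(sum(exp(u - mx))) +
    sum(pen * abs(fit$lambda))
}

# memoised scenarios so heavy acceptance blocks can share computations
.nm_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .nm_cache)) {
    assign(key, force(expr), envir = .nm_cache)
  }
  get(key, envir = .nm_cache)
}

# fit all replicate runs for one period of a scenario and return the
# cumulative maps and transfer-region fractions used by several checks
period_summary <- function(sc, period, seed, n_sets = 10, n_points = 100) {
  mask <- if (period == "historical") sc$historical_mask else sc$modern_mask
  cfg <- experiment_config(scenario = sc, n_sets = n_sets,
                           n_points = n_points, seed = seed)
  runs <- suppressMessages(fit_replicates(sc$stack, mask, sc$native_region,
                                          cfg))
  cum_mtss <- cumulative_map(lapply(runs, function(r)
    binarize(r$map, mtss(r$train_scores, r$bg_scores))))
  cum_mtp <- cumulative_map(lapply(runs, function(r)
    binarize(r$map, mtp(r$train_scores))))
  list(runs = runs, cum_mtss = cum_mtss, cum_mtp = cum_mtp,
       frac_mtss = suitable_area(cum_mtss, sc$transfer_region)$fraction,
       frac_mtp = suitable_area(cum_mtp, sc$transfer_region)$fraction)
}

count_covered <- function(binary_map, pts) {
  rc <- locate_cell(binary_map, pts$x, pts$y)
  sum(binary_map$values[cbind(rc$row, rc$col)] == 1, na.rm = TRUE)
}
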