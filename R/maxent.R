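#' Fit a maximum-entropy presence-only model
#'
#' Finds the Gibbs distribution q(x) = exp(lambda . f(x)) / Z over the
#' background sample that maximizes the mean penalized log-likelihood of the
#' presences,
#'   mean_presences\[lambda . f(x)\] - log Z - sum_j beta_j |lambda_j|,
#' with per-feature penalty beta_j = beta * s_j / sqrt(m_p) (s_j = presence
#' SD of feature j, m_p = number of presences). This is the maximum-entropy
#' distribution subject to relaxed feature-mean constraints: at the optimum
#' |E_q\[f_j\] - presence mean of f_j| <= beta_j, with equality constraints
#' recovered at beta = 0.
#'
#' The optimizer is deterministic: cyclic coordinate-wise proximal Newton
#' updates with soft-thresholding of the L1 term and monotone step halving,
#' followed by a quasi-Newton (L-BFGS-B) polish on the active set with signs
#' fixed, iterated with KKT checks until no inactive feature violates its
#' bound. Convergence: relative objective improvement below `tol` (default
#' 1e-8) or `max_iter` sweeps (default 500); non-convergence returns the
#' model flagged, with a warning carrying the final gradient norm.
#'
#' Exactly identical feature columns (same presence and background values)
#' are fitted as one representative and the coefficient and credited gain
#' are split evenly across the group — a symmetric, deterministic tie-break
#' that leaves the objective unchanged.
#'
#' @param presence,background data.frames of predictor columns (presence
#'   rows and background rows).
#' @param beta regularization multiplier (default 1; 0 = exact constraint
#'   matching).
#' @param classes feature classes, see [feature_spec()].
#' @param max_iter,tol optimizer controls.
#' @return object of class `nm_maxent`: feature spec with clamp bounds,
#'   weights `lambda`, normalizer `Z` (and `logZ`), entropy `H` (nats) of
#'   the fitted distribution over the background, per-variable gain credits,
#'   and the objective trace.
#' @export
maxent_fit <- function(presence, background, beta = 1,
                       classes = c("linear", "quadratic", "product"),
                       max_iter = 500, tol = 1e-8) {
  stopifnot(nrow(presence) >= 1, nrow(background) >= 2, beta >= 0)
  vars <- names(presence)[vapply(presence, is.numeric, TRUE)]
  vars <- setdiff(vars, c("id", "valid"))
  spec <- feature_spec(rbind(presence[vars], background[vars]),
                       classes = classes)
  presence <- presence[vars]; background <- background[vars]
  Xp <- featurize(spec, presence)
  Xb <- featurize(spec, background)
  fit <- maxent_fit_design(Xp, Xb, beta = beta, max_iter = max_iter, tol = tol,
                           var_map = lapply(seq_along(spec$features),
                                            function(k) feature_vars(spec, k)))
  fit$spec <- spec
  fit
}

#' Fit the max-ent model on pre-built design matrices
#'
#' Lower-level entry point used by [maxent_fit()] and by tests that need
#' full control of the design. Same objective and optimizer.
#'
#' @param Xp,Xb numeric design matrices (presences / background), same
#'   columns.
#' @param beta regularization multiplier.
#' @param max_iter,tol optimizer controls.
#' @param var_map optional list mapping each column to the source variable
#'   name(s) used for gain attribution; defaults to the column names.
#' @return an `nm_maxent` without a feature spec (no projection support).
#' @export
maxent_fit_design <- function(Xp, Xb, beta = 1, max_iter = 500, tol = 1e-8,
                              var_map = NULL) {
  Xp <- as.matrix(Xp); Xb <- as.matrix(Xb)
  stopifnot(ncol(Xp) == ncol(Xb), nrow(Xb) >= 2, beta >= 0)
  pfull <- ncol(Xp)
  if (is.null(colnames(Xp))) colnames(Xp) <- colnames(Xb) <- paste0("f", seq_len(pfull))
  if (is.null(var_map)) var_map <- as.list(colnames(Xp))
  m_p <- nrow(Xp); m <- nrow(Xb)

  # group exactly-identical columns (presence AND background) for symmetric
  # tie-breaking; fit representatives only
  key <- vapply(seq_len(pfull), function(j)
    paste(c(Xp[, j], Xb[, j]), collapse = "\r"), "")
  grp <- match(key, key)            # index of first occurrence
  reps <- sort(unique(grp))
  gsize <- tabulate(match(grp, reps), nbins = length(reps))

  XpR <- Xp[, reps, drop = FALSE]; XbR <- Xb[, reps, drop = FALSE]
  pmean <- colMeans(XpR)
  psd <- sqrt(pmax(colMeans(XpR^2) - pmean^2, 0))   # population SD
  pen <- beta * psd / sqrt(m_p)
  k <- length(reps)

  lam <- numeric(k)
  u <- numeric(m)                                    # Xb %*% lam
  lse <- function(u) { mx <- max(u); mx + log(sum(exp(u - mx))) }
  objective <- function(lam, u) -sum(lam * pmean) + lse(u) + sum(pen * abs(lam))
  J <- objective(lam, u)
  gains <- numeric(k)
  trace <- J

  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    Jsweep <- J
    q <- exp(u - max(u)); q <- q / sum(q)
    for (j in seq_len(k)) {
      xj <- XbR[, j]
      Eq <- sum(q * xj)
      g <- Eq - pmean[j]
      h <- sum(q * xj^2) - Eq^2
      if (h < 1e-12) next
      z <- lam[j] * h - g
      newlam <- sign(z) * max(abs(z) - pen[j], 0) / h
      d <- newlam - lam[j]
      if (d == 0) next
      # monotone safeguard: halve the proximal step until J decreases
      repeat {
        unew <- u + d * xj
        lamj <- lam[j] + d
        Jnew <- -sum(lam * pmean) - d * pmean[j] + lse(unew) +
          sum(pen * abs(lam)) - pen[j] * abs(lam[j]) + pen[j] * abs(lamj)
        if (Jnew <= J + 1e-14 || abs(d) < 1e-15) break
        d <- d / 2
      }
      if (Jnew < J) {
        gains[j] <- gains[j] + (J - Jnew)
        lam[j] <- lam[j] + d
        u <- unew
        q <- exp(u - max(u)); q <- q / sum(q)
        J <- Jnew
      }
    }
    trace <- c(trace, J)
    if ((Jsweep - J) <= tol * max(1, abs(Jsweep))) { converged <- TRUE; break }
  }

  # quasi-Newton polish on the active set (signs fixed), then KKT check on
  # the inactive features; re-enter coordinate descent if any is violated
  for (round in 1:6) {
    act <- if (beta == 0) seq_len(k) else which(lam != 0)
    if (length(act)) {
      sg <- ifelse(lam[act] == 0, 1, sign(lam[act]))
      fn <- function(th) {
        l <- sg * th
        -sum(l * pmean[act]) + lse(XbR[, act, drop = FALSE] %*% l) +
          sum(pen[act] * th)
      }
      gr <- function(th) {
        l <- sg * th
        uu <- as.vector(XbR[, act, drop = FALSE] %*% l)
        qq <- exp(uu - max(uu)); qq <- qq / sum(qq)
        sg * (as.vector(crossprod(XbR[, act, drop = FALSE], qq)) - pmean[act]) +
          pen[act]
      }
      th0 <- abs(lam[act])
      opt <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                          lower = if (beta == 0) -Inf else 0,
                          control = list(maxit = 200, factr = 10))
      lam_new <- lam
      lam_new[act] <- if (beta == 0) opt$par * sg else sg * pmax(opt$par, 0)
      u_new <- as.vector(XbR %*% lam_new)
      J_new <- objective(lam_new, u_new)
      if (J_new < J - 1e-15) {
        dl <- abs(lam_new - lam)
        if (sum(dl) > 0) gains <- gains + (J - J_new) * dl / sum(dl)
        lam <- lam_new; u <- u_new; J <- J_new
        trace <- c(trace, J)
      }
    }
    q <- exp(u - max(u)); q <- q / sum(q)
    g_all <- as.vector(crossprod(XbR, q)) - pmean
    kkt_bad <- which(lam == 0 & abs(g_all) > pen + 1e-9)
    if (beta == 0 || !length(kkt_bad)) break
    # one corrective coordinate sweep over violators
    for (j in kkt_bad) {
      xj <- XbR[, j]
      Eq <- sum(q * xj); g <- Eq - pmean[j]
      h <- max(sum(q * xj^2) - Eq^2, 1e-12)
      z <- lam[j] * h - g
      d <- sign(z) * max(abs(z) - pen[j], 0) / h - lam[j]
      unew <- u + d * xj
      lamj <- lam[j] + d
      Jnew <- objective(replace(lam, j, lamj), unew)
      if (Jnew < J) {
        gains[j] <- gains[j] + (J - Jnew)
        lam[j] <- lamj; u <- unew; J <- Jnew
        q <- exp(u - max(u)); q <- q / sum(q)
      }
    }
  }

  q <- exp(u - max(u)); q <- q / sum(q)
  grad_norm <- max(abs(pmax(abs(as.vector(crossprod(XbR, q)) - pmean) - pen, 0)))
  if (!converged && grad_norm < 1e-6) converged <- TRUE  # polish finished the job
  if (!converged) {
    warning(sprintf(
      "max-ent fit did not converge in %d sweeps (KKT residual %.3g); model returned flagged",
      max_iter, grad_norm), call. = FALSE)
  }

  # expand representatives back to the full feature set (even split)
  lambda <- numeric(pfull)
  gain_full <- numeric(pfull)
  for (i in seq_along(reps)) {
    members <- which(grp == reps[i])
    lambda[members] <- lam[i] / length(members)
    gain_full[members] <- gains[i] / length(members)
  }
  names(lambda) <- colnames(Xp)

  # per-variable gain credits (product features split evenly across sources)
  var_gain <- list()
  for (j in seq_len(pfull)) {
    vs <- var_map[[j]]
    for (v in vs) {
      var_gain[[v]] <- (if (is.null(var_gain[[v]])) 0 else var_gain[[v]]) +
        gain_full[j] / length(vs)
    }
  }

  logZ_rel <- lse(u)                     # log sum_b exp(u)
  H <- -sum(q * log(pmax(q, 1e-300)))
  structure(list(
    spec = NULL,
    lambda = lambda,
    logZ = logZ_rel,
    Z = exp(logZ_rel),
    H = H,
    beta = beta,
    penalty = stats::setNames(pen[match(grp, reps)] , colnames(Xp)),
    presence_mean = stats::setNames(pmean[match(grp, reps)], colnames(Xp)),
    presence_sd = stats::setNames(psd[match(grp, reps)], colnames(Xp)),
    n_presence = m_p,
    n_background = m,
    background_q = as.vector(q),
    var_gain = var_gain,
    objective = J,
    trace = trace,
    iterations = iter,
    converged = converged,
    kkt_residual = grad_norm
  ), class = "nm_maxent")
}

#' @export
print.nm_maxent <- function(x, ...) {
  cat(sprintf(
    "<nm_maxent> %d features, beta = %g, %d presences / %d background\n",
    length(x$lambda), x$beta, x$n_presence, x$n_background))
  cat(sprintf("  entropy H = %.4f nats, %d active weights, converged: %s\n",
              x$H, sum(x$lambda != 0), x$converged))
  invisible(x)
}

# linear predictor for a feature matrix
maxent_eta <- function(model, X) as.vector(X %*% model$lambda)

#' Raw (background-normalized) prediction
#'
#' exp(lambda . f(x)) / Z with Z summed over the background, so raw values
#' over the background cells sum to exactly 1.
#'
#' @param model an `nm_maxent` fitted with [maxent_fit()].
#' @param newdata data.frame of predictor columns.
#' @param clamp clip predictors to the training bounds first.
#' @return numeric vector of positive raw densities.
#' @export
predict_raw <- function(model, newdata, clamp = FALSE) {
  stopifnot(!is.null(model$spec))
  X <- featurize(model$spec, newdata, clamp = clamp)
  exp(maxent_eta(model, X) - model$logZ)
}

#' Logistic prediction in \[0, 1\]
#'
#' logistic = e^H * q_raw / (1 + e^H * q_raw), a strictly increasing
#' transform of the raw density anchored so the uniform model (lambda = 0,
#' H = log m) scores exactly 0.5 everywhere: 0.5 is the suitability of a
#' "typical" presence environment.
#'
#' @inheritParams predict_raw
#' @return numeric vector in \[0, 1\].
#' @export
predict_logistic <- function(model, newdata, clamp = FALSE) {
  stopifnot(!is.null(model$spec))
  X <- featurize(model$spec, newdata, clamp = clamp)
  stats::plogis(model$H + maxent_eta(model, X) - model$logZ)
}

#' Project a fitted model across a bioclim stack
#'
#' Scores every defined cell of the stack. With `clamp = TRUE` (the
#' default for transfer) each predictor is first clipped to its training
#' range, preventing the fitted exponential response from being
#' extrapolated beyond the environments seen in training. Cells with nodata
#' in any predictor propagate nodata.
#'
#' @param model an `nm_maxent` from [maxent_fit()].
#' @param stack an `nm_stack` whose layer names include the model's
#'   variables.
#' @param clamp clip to training bounds (default TRUE).
#' @param run_id,species_label,period free-text tags carried on the map.
#' @return object of class `nm_suitmap`: `logistic` and `raw` grids plus
#'   tags.
#' @export
project_model <- function(model, stack, clamp = TRUE, run_id = "run",
                          species_label = "species", period = "modern") {
  stopifnot(inherits(stack, "nm_stack"), !is.null(model$spec))
  miss <- setdiff(model$spec$variables, names(stack$layers))
  if (length(miss)) {
    stop("stack is missing layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ref <- stack$layers[[1]]
  tab <- as.data.frame(lapply(stack$layers[model$spec$variables],
                              function(g) as.vector(g$values)))
  names(tab) <- model$spec$variables
  ok <- stats::complete.cases(tab)
  eta <- rep(NA_real_, nrow(tab))
  X <- featurize(model$spec, tab[ok, , drop = FALSE], clamp = clamp)
  eta[ok] <- maxent_eta(model, X)
  rawv <- exp(eta - model$logZ)
  logi <- stats::plogis(model$H + eta - model$logZ)
  shape <- dim(ref$values)
  mk <- function(v) grid_create(matrix(v, shape[1], shape[2]),
                                origin = ref$origin, cell_size = ref$cell_size,
                                nodata = ref$nodata, crs_label = ref$crs_label)
  structure(list(logistic = mk(logi), raw = mk(rawv),
                 run_id = run_id, species_label = species_label,
                 period = period, clamped = clamp),
            class = "nm_suitmap")
}

#' Percent contribution of each variable
#'
#' Path attribution over the optimizer trajectory: every objective
#' improvement is credited to the source variable(s) of the updated feature
#' (split evenly for product features), and credits are normalized to sum
#' to 100 over variables. This mirrors the training-gain heuristic commonly
#' reported for max-ent models; it is order-dependent in principle and is
#' validated in the test suite by rank agreement with drop-one refits.
#'
#' @param model an `nm_maxent`.
#' @return data.frame with columns `variable`, `percent`.
#' @export
variable_contribution <- function(model) {
  g <- unlist(model$var_gain)
  if (is.null(g) || !length(g) || sum(g) <= 0) {
    warning("no positive training gain recorded; returning uniform contributions",
            call. = FALSE)
    vars <- if (!is.null(model$spec)) model$spec$variables else names(model$var_gain)
    return(data.frame(variable = vars,
                      percent = rep(100 / length(vars), length(vars))))
  }
  data.frame(variable = names(g), percent = 100 * as.numeric(g) / sum(g),
             row.names = NULL)
}

#' Jackknife of single variables
#'
#' Refits the model with each variable alone (its linear/quadratic
#' features) and reports the discrimination (AUC of the test presences
#' against the background) of every single-variable model, plus the
#' all-variable reference fit. A variable whose fit fails is reported as
#' `NA` with a warning and the others continue.
#'
#' @param presence,background training tables as in [maxent_fit()].
#' @param test_presence table of test presence rows scored for AUC.
#' @param beta regularization multiplier.
#' @param classes feature classes used for the single-variable fits
#'   (product is ignored there; it needs two variables).
#' @return data.frame with columns `variable`, `auc`; last row is `"(all)"`.
#' @export
jackknife_single <- function(presence, background, test_presence, beta = 1,
                             classes = c("linear", "quadratic")) {
  vars <- intersect(c(BIOCLIM_VARS, names(presence)), names(presence))
  vars <- unique(vars[vapply(presence[vars], is.numeric, TRUE)])
  if (length(vars) < 1) stop("no numeric predictor columns", call. = FALSE)
  one <- function(v) {
    tryCatch({
      m <- maxent_fit(presence[, v, drop = FALSE],
                      background[, v, drop = FALSE],
                      beta = beta, classes = setdiff(classes, "product"))
      auc_score(predict_raw(m, test_presence),
                predict_raw(m, background))
    }, error = function(e) {
      warning(sprintf("jackknife fit failed for %s: %s", v,
                      conditionMessage(e)), call. = FALSE)
      NA_real_
    })
  }
  res <- vapply(vars, one, 0.0)
  full <- maxent_fit(presence[, vars, drop = FALSE],
                     background[, vars, drop = FALSE],
                     beta = beta, classes = classes)
  data.frame(variable = c(vars, "(all)"),
             auc = c(res, auc_score(predict_raw(full, test_presence),
                                    predict_raw(full, background))),
             row.names = NULL)
}

#' Serialize / restore a fitted model
#'
#' Versioned JSON document holding the feature spec, clamp bounds, weights,
#' normalizer, entropy and regularization — everything needed to reload and
#' reproduce projections to full double-precision text accuracy.
#'
#' @param model an `nm_maxent` with a feature spec.
#' @param path destination file.
#' @return `path` / the restored `nm_maxent`.
#' @export
write_model <- function(model, path) {
  stopifnot(!is.null(model$spec))
  doc <- list(
    format = "nichemax-model", version = 1L,
    classes = model$spec$classes,
    variables = model$spec$variables,
    dropped = model$spec$dropped,
    lower = as.list(model$spec$lower),
    upper = as.list(model$spec$upper),
    lambda = as.list(model$lambda),
    logZ = model$logZ, H = model$H, beta = model$beta,
    n_presence = model$n_presence, n_background = model$n_background,
    presence_mean = as.list(model$presence_mean),
    presence_sd = as.list(model$presence_sd),
    var_gain = model$var_gain,
    converged = model$converged)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "nichemax-model")) {
    stop("not a nichemax model document: ", path, call. = FALSE)
  }
  # rebuild the feature spec structurally (bounds come from the document)
  fake <- as.data.frame(rbind(unlist(doc$lower), unlist(doc$upper)))
  names(fake) <- doc$variables
  spec <- feature_spec(fake, classes = doc$classes)
  spec$lower <- unlist(doc$lower)[spec$variables]
  spec$upper <- unlist(doc$upper)[spec$variables]
  spec$dropped <- as.character(doc$dropped)
  structure(list(
    spec = spec,
    lambda = stats::setNames(as.numeric(doc$lambda), names(doc$lambda)),
    logZ = doc$logZ, Z = exp(doc$logZ), H = doc$H, beta = doc$beta,
    presence_mean = unlist(doc$presence_mean),
    presence_sd = unlist(doc$presence_sd),
    n_presence = doc$n_presence, n_background = doc$n_background,
    var_gain = as.list(doc$var_gain),
    converged = doc$converged), class = "nm_maxent")
}
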