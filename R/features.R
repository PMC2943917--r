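#' Build a feature specification from training data
#'
#' Features are built on variables standardized to \[0,1\] by the training
#' min/max (presences plus background), which makes clamp bounds and L1
#' penalties scale-free: `linear` is the standardized value, `quadratic` its
#' square, `product` the pairwise products of standardized values. Column
#' order is deterministic: variables in canonical order, then squares, then
#' lexicographic pairs. The training min/max double as the clamp bounds used
#' when projecting to new regions.
#'
#' Variables constant on the training data carry no information and are
#' dropped (with a warning), together with the features built on them.
#'
#' @param table data.frame of predictor columns (training presences and
#'   background rows together).
#' @param classes subset of `c("linear", "quadratic", "product")`.
#' @return object of class `nm_featspec`.
#' @export
feature_spec <- function(table, classes = c("linear", "quadratic", "product")) {
  classes <- match.arg(classes, several.ok = TRUE)
  vars <- names(table)[vapply(table, is.numeric, TRUE)]
  if (nrow(table) < 2) stop("need at least 2 training rows", call. = FALSE)
  # canonical bioclim order first, any other numeric columns after, as given
  vars <- c(intersect(BIOCLIM_VARS, vars), setdiff(vars, BIOCLIM_VARS))
  lo <- vapply(vars, function(v) min(table[[v]], na.rm = TRUE), 0)
  hi <- vapply(vars, function(v) max(table[[v]], na.rm = TRUE), 0)
  const <- hi - lo == 0
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(vars[const], collapse = ", "), call. = FALSE)
  }
  keep <- vars[!const]
  if (!length(keep)) stop("all variables constant on training data", call. = FALSE)

  feats <- list()
  if ("linear" %in% classes) {
    feats <- c(feats, lapply(keep, function(v) list(name = v, class = "linear",
                                                   vars = v)))
  }
  if ("quadratic" %in% classes) {
    feats <- c(feats, lapply(keep, function(v) list(name = paste0(v, "^2"),
                                                   class = "quadratic",
                                                   vars = v)))
  }
  if ("product" %in% classes && length(keep) >= 2) {
    for (i in seq_len(length(keep) - 1)) {
      for (j in (i + 1):length(keep)) {
        feats <- c(feats, list(list(name = paste0(keep[i], "*", keep[j]),
                                    class = "product",
                                    vars = c(keep[i], keep[j]))))
      }
    }
  }
  structure(list(classes = classes, variables = keep,
                 dropped = vars[const],
                 lower = lo[!const], upper = hi[!const],
                 features = feats),
            class = "nm_featspec")
}

#' @export
print.nm_featspec <- function(x, ...) {
  cat(sprintf("<nm_featspec> %d features (%s) on %d variables\n",
              length(x$features), paste(x$classes, collapse = "+"),
              length(x$variables)))
  invisible(x)
}

#' Expand predictor rows into the model's design matrix
#'
#' @param spec an `nm_featspec`.
#' @param table data.frame holding at least the spec's variables.
#' @param clamp clip each variable to its training bounds before
#'   standardizing (used when projecting outside the training region).
#' @return numeric matrix, one column per feature, named.
#' @export
featurize <- function(spec, table, clamp = FALSE) {
  miss <- setdiff(spec$variables, names(table))
  if (length(miss)) {
    stop("missing predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  z <- sapply(spec$variables, function(v) {
    x <- as.numeric(table[[v]])
    if (clamp) x <- pmin(pmax(x, spec$lower[[v]]), spec$upper[[v]])
    (x - spec$lower[[v]]) / (spec$upper[[v]] - spec$lower[[v]])
  })
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, spec$variables))
  X <- matrix(0, nrow(z), length(spec$features),
              dimnames = list(NULL, vapply(spec$features, `[[`, "", "name")))
  for (k in seq_along(spec$features)) {
    f <- spec$features[[k]]
    X[, k] <- switch(f$class,
                     linear    = z[, f$vars],
                     quadratic = z[, f$vars]^2,
                     product   = z[, f$vars[1]] * z[, f$vars[2]])
  }
  X
}

# source variables of feature k, for gain attribution
feature_vars <- function(spec, k) spec$features[[k]]$vars
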