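#' @keywords internal
"_PACKAGE"

#' Canonical bioclimatic predictor names
#'
#' The ten predictors used throughout the package, in canonical order:
#' annual mean temperature (MTEMP, degC), mean monthly temperature range
#' (TEMPR, degC), isothermality (ISO, ratio of mean monthly range to annual
#' range, 0-1), temperature seasonality (TEMPS, SD of monthly mean
#' temperature, degC), max temperature of the warmest month (MTWM), min
#' temperature of the coldest month (MTCM), annual precipitation (PREC, mm),
#' precipitation seasonality (PRECS, CV of monthly precipitation, percent),
#' and precipitation of the wettest / driest quarter (PWQ / PDQ, mm).
#'
#' Note the scales: ISO is reported as a 0-1 ratio and TEMPS as an SD in
#' degC -- not the x100 integer packing some distributed climate products
#' use. Envelope plots and clamp bounds depend on this.
#'
#' @export
BIOCLIM_VARS <- c("MTEMP", "TEMPR", "ISO", "TEMPS", "MTWM",
                  "MTCM", "PREC", "PRECS", "PWQ", "PDQ")

#' Bundle monthly climate layers
#'
#' @param tmin,tmax,prec lists of 12 aligned `nm_grid` layers each
#'   (temperature degC, precipitation mm/month).
#' @return object of class `nm_monthly`.
#' @export
monthly_climate <- function(tmin, tmax, prec) {
  stopifnot(length(tmin) == 12, length(tmax) == 12, length(prec) == 12)
  all36 <- c(tmin, tmax, prec)
  for (g in all36) stop_if_unaligned(all36[[1]], g, "monthly layers")
  for (i in 1:12) {
    d <- tmax[[i]]$values - tmin[[i]]$values
    if (any(d < 0, na.rm = TRUE)) {
      stop(sprintf("tmax < tmin in month %d for %d cell(s)", i,
                   sum(d < 0, na.rm = TRUE)), call. = FALSE)
    }
    if (any(prec[[i]]$values < 0, na.rm = TRUE)) {
      stop(sprintf("negative precipitation in month %d", i), call. = FALSE)
    }
  }
  structure(list(tmin = tmin, tmax = tmax, prec = prec), class = "nm_monthly")
}

#' Bundle the ten bioclim layers into a stack
#'
#' @param layers named list of exactly the ten canonical `nm_grid` layers.
#' @param check validate the stack's ordering invariants (default TRUE).
#' @return object of class `nm_stack`.
#' @export
bioclim_stack <- function(layers, check = TRUE) {
  if (!setequal(names(layers), BIOCLIM_VARS) || length(layers) != 10) {
    stop("a bioclim stack needs exactly the layers ",
         paste(BIOCLIM_VARS, collapse = ", "), call. = FALSE)
  }
  layers <- layers[BIOCLIM_VARS]
  for (g in layers) stop_if_unaligned(layers[[1]], g, "bioclim layers")
  if (check) {
    chk <- function(cond, lab) {
      if (any(!cond, na.rm = TRUE)) {
        stop("bioclim stack invariant violated: ", lab, call. = FALSE)
      }
    }
    v <- lapply(layers, `[[`, "values")
    chk(v$ISO > 0 & v$ISO <= 1 + 1e-9, "ISO in (0, 1]")
    chk(v$TEMPS >= 0, "TEMPS >= 0")
    chk(v$PREC >= v$PWQ - 1e-9 & v$PWQ >= v$PDQ - 1e-9 & v$PDQ >= -1e-9,
        "PREC >= PWQ >= PDQ >= 0")
    chk(v$MTWM >= v$MTEMP - 1e-9 & v$MTEMP >= v$MTCM - 1e-9,
        "MTWM >= MTEMP >= MTCM")
  }
  structure(list(layers = layers), class = "nm_stack")
}

#' @export
print.nm_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<nm_stack> 10 bioclim layers, %d x %d cells\n",
              nrow(g$values), ncol(g$values)))
  invisible(x)
}

#' Derive the ten bioclimatic predictors from monthly climate
#'
#' Per cell, with monthly mean temperature m_i = (tmax_i + tmin_i)/2:
#' MTEMP = mean(m_i); TEMPR = mean(tmax_i - tmin_i);
#' ISO = TEMPR / (max tmax_i - min tmin_i); TEMPS = population SD of m_i;
#' MTWM = max tmax_i; MTCM = min tmin_i; PREC = sum prec_i;
#' PRECS = 100 * population SD(prec_i) / mean(prec_i) (0 where the mean is 0);
#' PWQ / PDQ = max / min precipitation over the 12 wrap-around consecutive
#' 3-month windows (quarters, Dec-Jan-Feb included).
#'
#' Population (n) rather than sample (n-1) SD is used throughout: the 12
#' months are the full population of months. Cells whose annual temperature
#' range is zero get ISO = nodata (logged via a message).
#'
#' @param monthly an `nm_monthly`.
#' @return an `nm_stack`.
#' @export
derive_bioclim <- function(monthly) {
  stopifnot(inherits(monthly, "nm_monthly"))
  ref <- monthly$tmin[[1]]
  shp <- dim(ref$values)
  arr <- function(lst) {
    a <- array(NA_real_, c(shp, 12))
    for (i in 1:12) a[, , i] <- lst[[i]]$values
    a
  }
  tmin <- arr(monthly$tmin); tmax <- arr(monthly$tmax); prc <- arr(monthly$prec)
  tmean <- (tmax + tmin) / 2

  pop_sd <- function(a) {
    mu <- apply(a, c(1, 2), mean)
    sqrt(apply((a - array(mu, c(shp, 12)))^2, c(1, 2), mean))
  }
  MTEMP <- apply(tmean, c(1, 2), mean)
  TEMPR <- apply(tmax - tmin, c(1, 2), mean)
  MTWM  <- apply(tmax, c(1, 2), max)
  MTCM  <- apply(tmin, c(1, 2), min)
  annual_range <- MTWM - MTCM
  ISO <- TEMPR / annual_range
  flat <- !is.na(annual_range) & annual_range == 0
  if (any(flat)) {
    ISO[flat] <- NA_real_
    message(sprintf("derive_bioclim: ISO undefined (zero annual range) in %d cell(s); set to nodata",
                    sum(flat)))
  }
  TEMPS <- pop_sd(tmean)
  PREC <- apply(prc, c(1, 2), sum)
  pmu <- PREC / 12
  PRECS <- ifelse(pmu > 0, 100 * pop_sd(prc) / pmu, 0)
  PRECS[is.na(pmu)] <- NA_real_

  # 12 wrap-around quarters: months (i, i+1, i+2) mod 12
  qsum <- array(NA_real_, c(shp, 12))
  for (i in 1:12) {
    idx <- ((i - 1):(i + 1)) %% 12 + 1
    qsum[, , i] <- prc[, , idx[1]] + prc[, , idx[2]] + prc[, , idx[3]]
  }
  PWQ <- apply(qsum, c(1, 2), max)
  PDQ <- apply(qsum, c(1, 2), min)

  as_layer <- function(m) grid_create(m, origin = ref$origin,
                                      cell_size = ref$cell_size,
                                      nodata = ref$nodata,
                                      crs_label = ref$crs_label)
  bioclim_stack(lapply(
    stats::setNames(list(MTEMP, TEMPR, ISO, TEMPS, MTWM, MTCM,
                         PREC, PRECS, PWQ, PDQ), BIOCLIM_VARS),
    as_layer))
}

#' Extract predictor values at points
#'
#' Returns one row per point with the ten layer values of the cell
#' containing it (half-open membership, see [locate_cell()]). Rows whose
#' cell has nodata in any layer are flagged invalid and should be dropped
#' downstream; the count is reported via a message.
#'
#' @param stack an `nm_stack`.
#' @param points data.frame with columns `id`, `x`, `y`.
#' @return data.frame: `id`, the ten variables, and logical `valid`.
#' @export
extract_values <- function(stack, points) {
  stopifnot(inherits(stack, "nm_stack"))
  ref <- stack$layers[[1]]
  rc <- locate_cell(ref, points$x, points$y)
  if (anyNA(rc$row)) {
    bad <- points$id[is.na(rc$row)][1]
    stop(sprintf("point '%s' falls outside the grid extent", as.character(bad)),
         call. = FALSE)
  }
  idx <- cbind(rc$row, rc$col)
  out <- data.frame(id = points$id)
  for (v in BIOCLIM_VARS) out[[v]] <- stack$layers[[v]]$values[idx]
  out$valid <- stats::complete.cases(out[BIOCLIM_VARS])
  if (any(!out$valid)) {
    message(sprintf("extract_values: %d point(s) on nodata cells flagged invalid",
                    sum(!out$valid)))
  }
  out
}
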