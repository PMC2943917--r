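#' Envelope scatter data for two variables
#'
#' Builds the table behind the classic two-variable climate-envelope
#' scatter: values of `var_x` and `var_y` for points sampled in the native
#' range, across the native continent, across the transfer continent, and
#' at a handful of focal localities (e.g. naturalized introduction sites).
#' Focal rows are additionally flagged `interior`/`exterior` with respect
#' to the rectangular hull of the native-range rows in the (x, y) plane.
#'
#' @param stack an `nm_stack`.
#' @param var_x,var_y layer names.
#' @param native_range,native_continent,transfer_continent,focal
#'   data.frames of points (`id`, `x`, `y`); any may be NULL to skip.
#' @return data.frame with columns `group`, `x`, `y`, and `position`
#'   (focal rows only; NA elsewhere).
#' @export
envelope_scatter <- function(stack, var_x, var_y,
                             native_range = NULL, native_continent = NULL,
                             transfer_continent = NULL, focal = NULL) {
  for (v in c(var_x, var_y)) {
    if (!v %in% names(stack$layers)) {
      stop("unknown variable name: ", v, call. = FALSE)
    }
  }
  pull <- function(pts, group) {
    if (is.null(pts) || !nrow(pts)) return(NULL)
    tab <- extract_values(stack, pts)
    data.frame(group = group, x = tab[[var_x]], y = tab[[var_y]],
               position = NA_character_)
  }
  out <- rbind(pull(native_range, "native_range"),
               pull(native_continent, "native_continent"),
               pull(transfer_continent, "transfer_continent"),
               pull(focal, "focal"))
  nat <- out[out$group == "native_range", ]
  if (nrow(nat) && any(out$group == "focal")) {
    inx <- out$x >= min(nat$x, na.rm = TRUE) & out$x <= max(nat$x, na.rm = TRUE)
    iny <- out$y >= min(nat$y, na.rm = TRUE) & out$y <= max(nat$y, na.rm = TRUE)
    out$position[out$group == "focal"] <-
      ifelse((inx & iny)[out$group == "focal"], "interior", "exterior")
  }
  out
}

#' Climate-novelty grid for a projection region
#'
#' Counts, per cell, how many of the model's source variables fall outside
#' the training clamp bounds (the rectangular training envelope). A count
#' of 0 is exactly the condition under which clamped and unclamped
#' projections agree at that cell. A per-variable breakdown of which
#' variables are clamped where is returned alongside.
#'
#' @param model an `nm_maxent` with a feature spec.
#' @param stack an `nm_stack`.
#' @param region optional boolean `nm_grid`; cells outside it are nodata.
#' @return list: `count` (an `nm_grid` of out-of-bounds variable counts)
#'   and `clamped` (named list of boolean `nm_grid`s, one per variable).
#' @export
novelty <- function(model, stack, region = NULL) {
  stopifnot(!is.null(model$spec))
  ref <- stack$layers[[1]]
  if (!is.null(region)) stop_if_unaligned(ref, region, "stack and region")
  cnt <- matrix(0, nrow(ref$values), ncol(ref$values))
  clamped <- list()
  for (v in model$spec$variables) {
    val <- stack$layers[[v]]$values
    out <- (val < model$spec$lower[[v]] | val > model$spec$upper[[v]]) * 1
    cnt <- cnt + out
    clamped[[v]] <- grid_create(out, origin = ref$origin,
                                cell_size = ref$cell_size,
                                nodata = ref$nodata, crs_label = ref$crs_label)
  }
  if (!is.null(region)) {
    cnt[is.na(region$values) | region$values != 1] <- NA_real_
  }
  list(count = grid_create(cnt, origin = ref$origin, cell_size = ref$cell_size,
                           nodata = ref$nodata, crs_label = ref$crs_label),
       clamped = clamped)
}

#' Suitable area within a region
#'
#' @param binary_map boolean `nm_grid` (1 = suitable).
#' @param region boolean `nm_grid` delimiting the region of interest.
#' @return list: `count` of suitable cells inside the region and
#'   `fraction` of the region's cells that are suitable.
#' @export
suitable_area <- function(binary_map, region) {
  stop_if_unaligned(binary_map, region, "map and region")
  inreg <- !is.na(region$values) & region$values == 1
  if (!any(inreg)) stop("empty region", call. = FALSE)
  suit <- !is.na(binary_map$values) & binary_map$values == 1
  n <- sum(suit & inreg)
  list(count = n, fraction = n / sum(inreg))
}
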