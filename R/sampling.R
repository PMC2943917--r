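#' Range mask
#'
#' A boolean occupancy grid (1 = inside the range) tagged with its time
#' period. When both periods exist for a species the modern range must be
#' nested inside the historical one; [check_nested()] enforces this.
#'
#' @param mask an `nm_grid` of 0/1 values (`NA` = nodata).
#' @param period `"modern"` or `"historical"`.
#' @param species_label free-text species tag.
#' @return object of class `nm_mask`.
#' @export
range_mask <- function(mask, period = c("modern", "historical"),
                       species_label = "species") {
  period <- match.arg(period)
  stopifnot(is_grid(mask))
  v <- mask$values
  if (!all(v[!is.na(v)] %in% c(0, 1))) {
    stop("range mask values must be 0/1 (or nodata)", call. = FALSE)
  }
  if (sum(v == 1, na.rm = TRUE) < 1) {
    stop("range mask has no occupied cells", call. = FALSE)
  }
  structure(list(mask = mask, period = period,
                 species_label = species_label),
            class = "nm_mask")
}

#' Linear indices of the occupied cells of a range mask
#'
#' @param m an `nm_mask`.
#' @return integer vector of column-major cell indices.
#' @export
mask_cells <- function(m) which(!is.na(m$mask$values) & m$mask$values == 1)

#' Check modern-within-historical nesting
#'
#' @param modern,historical `nm_mask` objects for the same species.
#' @return `TRUE` invisibly, or an error listing the violating cell count.
#' @export
check_nested <- function(modern, historical) {
  stop_if_unaligned(modern$mask, historical$mask, "range masks")
  extra <- setdiff(mask_cells(modern), mask_cells(historical))
  if (length(extra)) {
    stop(sprintf("modern range is not nested in historical: %d cell(s) outside",
                 length(extra)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Replicated sampling design
#'
#' Defaults mirror the standard pseudo-presence layout: ten sets of 100
#' random points per species and time period.
#'
#' @param n_points points per set (default 100).
#' @param n_sets number of replicate sets (default 10).
#' @param seed master seed.
#' @param with_replacement sample cells with replacement (default FALSE;
#'   intended only for tiny masks, and logged when used).
#' @return object of class `nm_design`.
#' @export
sample_design <- function(n_points = 100, n_sets = 10, seed = 1,
                          with_replacement = FALSE) {
  stopifnot(n_points >= 1, n_sets >= 1)
  structure(list(n_points = as.integer(n_points), n_sets = as.integer(n_sets),
                 seed = as.integer(seed),
                 with_replacement = isTRUE(with_replacement)),
            class = "nm_design")
}

# Deterministic child-stream seed: polynomial rolling hash of the master
# seed and the stream labels, mod 2^31 - 1. Independent of execution order.
derive_seed <- function(master, ...) {
  p <- 2147483647
  h <- (as.numeric(master) %% p + p) %% p
  for (tok in c(...)) {
    for (b in utf8ToInt(paste0("|", as.character(tok)))) {
      h <- (h * 131 + b) %% p
    }
  }
  as.integer(h)
}

# run code under a derived seed without disturbing the caller's RNG state
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

points_from_cells <- function(grid, cells, ids, role, period, seed) {
  rc <- arrayInd(cells, dim(grid$values))
  xy <- cell_center(grid, rc[, 1], rc[, 2])
  df <- data.frame(id = ids, x = xy[, "x"], y = xy[, "y"])
  attr(df, "role") <- role
  attr(df, "period") <- period
  attr(df, "seed") <- seed
  df
}

#' Sample pseudo-presence points from a range mask
#'
#' Cells are drawn uniformly among occupied non-nodata cells and the point
#' is placed at the cell center (predictors are cell-constant, so sub-cell
#' jitter adds no information and centers make results exactly
#' reproducible). The draw is a deterministic function of
#' (seed, species_label, period, role, set_index); distinct `set_index`
#' values give independent streams.
#'
#' @param mask an `nm_mask`.
#' @param design an `nm_design`.
#' @param set_index replicate index (0-based or 1-based, caller's choice —
#'   it only labels the stream).
#' @param role stream label, default `"train"`.
#' @return data.frame of `id`, `x`, `y` with role/period/seed attributes.
#' @export
sample_presence <- function(mask, design, set_index, role = "train") {
  cells <- mask_cells(mask)
  if (!design$with_replacement && length(cells) < design$n_points) {
    stop(sprintf(
      "mask has only %d occupied cells but %d points requested without replacement",
      length(cells), design$n_points), call. = FALSE)
  }
  if (design$with_replacement) {
    message("sample_presence: sampling cells with replacement")
  }
  sd <- derive_seed(design$seed, mask$species_label, mask$period, role, set_index)
  pick <- with_rng(sd, cells[sample.int(length(cells), design$n_points,
                                        replace = design$with_replacement)])
  points_from_cells(mask$mask, pick,
                    sprintf("%s_%s_%s%d_p%d", mask$species_label, mask$period,
                            role, set_index, seq_along(pick)),
                    role, mask$period, sd)
}

#' Sample pseudo-absence points from the complement of a range
#'
#' Points are drawn uniformly among cells that are inside `region` and
#' outside the mask; same determinism contract as [sample_presence()].
#'
#' @param mask an `nm_mask`.
#' @param region boolean `nm_grid` delimiting the sampling region.
#' @param n_points number of points.
#' @param seed master seed.
#' @param set_index stream label (default 0).
#' @return data.frame of `id`, `x`, `y`.
#' @export
sample_absence <- function(mask, region, n_points, seed, set_index = 0) {
  stop_if_unaligned(mask$mask, region, "mask and region")
  pool <- setdiff(which(!is.na(region$values) & region$values == 1),
                  mask_cells(mask))
  if (length(pool) < n_points) {
    stop(sprintf("only %d cells in region outside the range, %d requested",
                 length(pool), n_points), call. = FALSE)
  }
  sd <- derive_seed(seed, mask$species_label, mask$period, "absence", set_index)
  pick <- with_rng(sd, pool[sample.int(length(pool), n_points)])
  points_from_cells(mask$mask, pick,
                    sprintf("%s_%s_abs%d_p%d", mask$species_label, mask$period,
                            set_index, seq_len(n_points)),
                    "test", mask$period, sd)
}

#' Sample background (available-environment) points
#'
#' The background characterizes the environments available in the study
#' region; it is the normalization domain of the max-ent distribution. If
#' the region holds at most `max_n` valid cells, all cell centers are
#' returned in row-major order; otherwise a uniform random subset of
#' exactly `max_n` distinct cells is drawn.
#'
#' @param stack an `nm_stack` (cells with nodata in any layer are excluded).
#' @param region boolean `nm_grid`.
#' @param max_n background cap (default 10000).
#' @param seed master seed.
#' @return data.frame of `id`, `x`, `y`.
#' @export
sample_background <- function(stack, region, max_n = 10000, seed = 1) {
  ref <- stack$layers[[1]]
  stop_if_unaligned(ref, region, "stack and region")
  defined <- Reduce(`&`, lapply(stack$layers, function(g) !is.na(g$values)))
  pool <- which(!is.na(region$values) & region$values == 1 & defined)
  if (!length(pool)) stop("background region is empty", call. = FALSE)
  if (length(pool) > max_n) {
    sd <- derive_seed(seed, "background", max_n)
    pool <- sort(with_rng(sd, pool[sample.int(length(pool), max_n)]))
  }
  points_from_cells(ref, pool, sprintf("bg_p%d", seq_along(pool)),
                    "background", "none", seed)
}
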