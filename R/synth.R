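#' Generate synthetic monthly climate on two disjoint continents
#'
#' Builds a single raster holding two rectangular regions — a "native" and
#' a "transfer" continent — separated by a nodata sea gap, with the
#' statistical structure the analysis assumes: a north-south mean
#' temperature gradient (row 1 = north = cold), a seasonal sinusoid whose
#' amplitude grows with latitude, a positive diurnal/monthly temperature
#' range, an east-west (continentality) moisture gradient with a seasonal
#' phase, and smoothed Gaussian noise on every field. Temperature varying
#' with latitude and moisture with longitude keeps the two main gradients
#' near-orthogonal, as on a real continent with a maritime west coast. The transfer continent is generated with shifted
#' gradient parameters (colder and more seasonal by default) so that part
#' of it is non-analog with respect to the native climate.
#'
#' Everything is deterministic per `seed`. `smoothness = Inf` gives
#' spatially constant noise fields (the limiting case where temperature
#' varies only with latitude band).
#'
#' @param rows,cols size of each continent (both >= 4).
#' @param seed master seed.
#' @param smoothness Gaussian kernel width (cells) of the noise fields.
#' @param gap width of the nodata strip between the continents.
#' @param native,transfer parameter lists; see Details. Transfer defaults:
#'   `t_offset = -4` (degC), `amp_mult = 1.3`, `prec_mult = 0.9`.
#' @return list: `monthly` (an `nm_monthly`), `native_region` and
#'   `transfer_region` (boolean `nm_grid`s on the shared raster).
#' @export
gen_climate <- function(rows = 64, cols = 64, seed = 1, smoothness = 3,
                        gap = 8, native = list(), transfer = list()) {
  if (rows < 4 || cols < 4) stop("degenerate size: need rows, cols >= 4",
                                 call. = FALSE)
  nat <- utils::modifyList(list(
    t_base = 28, t_range = 18,       # mean annual temp 10..28 degC S->N
    amp_base = 2, amp_range = 10,    # seasonal amplitude grows northward
    diurnal = 8,                     # mean monthly temperature range
    p_base = 80, p_grad = 1.2,       # mm/month; linear west-east drying
    p_season = 0.6, p_phase = 7,     # wet-season strength and peak month
    t_offset = 0, amp_mult = 1, prec_mult = 1), native)
  tra <- utils::modifyList(utils::modifyList(nat, list(
    t_offset = -4, amp_mult = 1.3, prec_mult = 0.9)), transfer)

  nc_all <- 2 * cols + gap
  coldness <- (seq_len(rows) - 0.5) / rows        # 1-based row 1 = north
  coldness <- 1 - coldness                         # ~1 north, ~0 south
  smooth_field <- function(sub_seed, sd0 = 1) {
    if (!is.finite(smoothness)) return(matrix(0, rows, cols))
    with_rng(sub_seed, {
      z <- matrix(stats::rnorm(rows * cols), rows, cols)
      k <- stats::dnorm(seq(-ceiling(3 * smoothness), ceiling(3 * smoothness)),
                        sd = smoothness)
      k <- k / sum(k)
      sm <- function(m) {
        # separable convolution with edge renormalization
        conv1 <- function(x) {
          n <- length(x); half <- (length(k) - 1) / 2
          xp <- c(rep(x[1], half), x, rep(x[n], half))
          as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
        }
        m <- apply(m, 2, conv1)
        t(apply(m, 1, conv1))
      }
      z <- sm(z)
      s <- stats::sd(as.vector(z))
      if (s > 0) z / s * sd0 else z
    })
  }

  region_fields <- function(par, tag) {
    noiseT <- smooth_field(derive_seed(seed, tag, "T"), 1.0)
    noiseP <- smooth_field(derive_seed(seed, tag, "P"), 6)
    noiseD <- smooth_field(derive_seed(seed, tag, "D"), 1.0)
    tmean_ann <- par$t_base + par$t_offset - par$t_range * coldness
    tmean_ann <- matrix(tmean_ann, rows, cols) + noiseT
    amp <- (par$amp_base + par$amp_range * coldness) * par$amp_mult
    amp <- matrix(amp, rows, cols)
    diurnal <- pmax(2, par$diurnal + 2 * noiseD)
    dryness <- (seq_len(cols) - 0.5) / cols       # 0 wet west, 1 dry east
    wet <- pmax(5, par$p_base * par$prec_mult *
                  (1 + par$p_grad * (0.5 - matrix(dryness, rows, cols,
                                                  byrow = TRUE))) + noiseP)
    tmin <- tmax <- prc <- vector("list", 12)
    for (m in 1:12) {
      seas <- amp * cos(2 * pi * (m - 7) / 12)
      tm <- tmean_ann + seas
      tmin[[m]] <- tm - diurnal / 2
      tmax[[m]] <- tm + diurnal / 2
      prc[[m]] <- pmax(0, wet * (1 + par$p_season *
                                   cos(2 * pi * (m - par$p_phase) / 12)))
    }
    list(tmin = tmin, tmax = tmax, prec = prc)
  }
  natf <- region_fields(nat, "native")
  traf <- region_fields(tra, "transfer")

  paste_layers <- function(i, comp) {
    m <- matrix(NA_real_, rows, nc_all)
    m[, seq_len(cols)] <- natf[[comp]][[i]]
    m[, (cols + gap + 1):nc_all] <- traf[[comp]][[i]]
    grid_create(m, origin = c(0, rows), cell_size = 1, nodata = -9999,
                crs_label = "synthetic")
  }
  monthly <- monthly_climate(
    tmin = lapply(1:12, paste_layers, comp = "tmin"),
    tmax = lapply(1:12, paste_layers, comp = "tmax"),
    prec = lapply(1:12, paste_layers, comp = "prec"))

  region_grid <- function(colrange) {
    m <- matrix(0, rows, nc_all)
    m[, colrange] <- 1
    grid_create(m, origin = c(0, rows), cell_size = 1, nodata = -9999,
                crs_label = "synthetic")
  }
  list(monthly = monthly,
       native_region = region_grid(seq_len(cols)),
       transfer_region = region_grid((cols + gap + 1):nc_all))
}

#' True niche and occupancy from known Gibbs weights
#'
#' The ground-truth suitability is the exponential-family density
#' exp(lambda* . z) over the bioclim variables, with each variable
#' standardized to \[0,1\] by its native-region min/max and the density
#' normalized over the native region. The occupancy threshold is set so a
#' target fraction of native cells is occupied (ties, which only arise for
#' the all-zero-weight uniform truth, are broken by a seeded random
#' ordering); the historical range is exactly the occupied set.
#'
#' Truth uses linear terms only, so the fitted linear weights of a model
#' trained on truth-simulated presences are directly comparable to
#' `true_weights`.
#'
#' @param stack an `nm_stack`.
#' @param true_weights named numeric over (a subset of) the canonical
#'   variables; zeros allowed, all-zero gives the uniform truth.
#' @param native_region boolean `nm_grid`.
#' @param occ_frac target occupied fraction of the native region.
#' @param seed used only for tie-breaking.
#' @return list: `suitability` (`nm_grid`, normalized over native cells),
#'   `threshold`, `historical_mask` (`nm_mask`), `z_bounds` (the
#'   standardization bounds used).
#' @export
gen_truth <- function(stack, true_weights, native_region, occ_frac = 0.2,
                      seed = 1) {
  stopifnot(inherits(stack, "nm_stack"))
  bad <- setdiff(names(true_weights), BIOCLIM_VARS)
  if (length(bad)) stop("unknown variable(s) in true_weights: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  ref <- stack$layers[[1]]
  stop_if_unaligned(ref, native_region, "stack and native region")
  inreg <- !is.na(native_region$values) & native_region$values == 1

  eta <- matrix(0, nrow(ref$values), ncol(ref$values))
  defined <- matrix(TRUE, nrow(ref$values), ncol(ref$values))
  zb <- list()
  for (v in names(true_weights)) {
    val <- stack$layers[[v]]$values
    defined <- defined & !is.na(val)
    lo <- min(val[inreg], na.rm = TRUE); hi <- max(val[inreg], na.rm = TRUE)
    zb[[v]] <- c(lo, hi)
    if (hi > lo) eta <- eta + true_weights[[v]] * (val - lo) / (hi - lo)
  }
  eta[!defined] <- NA_real_
  s <- exp(eta)
  s <- s / sum(s[inreg & defined])
  suit <- grid_create(s, origin = ref$origin, cell_size = ref$cell_size,
                      nodata = ref$nodata, crs_label = ref$crs_label)

  native_cells <- which(inreg & defined)
  k <- max(1L, round(occ_frac * length(native_cells)))
  tie <- with_rng(derive_seed(seed, "truth-ties"),
                  stats::runif(length(native_cells)))
  ord <- order(-s[native_cells], tie)
  occ <- native_cells[ord[seq_len(k)]]
  thr <- min(s[occ])
  mk <- matrix(0, nrow(ref$values), ncol(ref$values))
  mk[!defined] <- NA_real_
  mk[occ] <- 1
  hist_mask <- range_mask(grid_create(mk, origin = ref$origin,
                                      cell_size = ref$cell_size,
                                      nodata = ref$nodata,
                                      crs_label = ref$crs_label),
                          period = "historical")
  list(suitability = suit, threshold = thr, historical_mask = hist_mask,
       z_bounds = zb)
}

#' Contract a historical range into a modern one
#'
#' Removes `ceiling(fraction * |historical|)` occupied cells. With
#' `bias = "cold_edge"` the historically occupied cells with the lowest
#' annual mean temperature are removed (ties broken by cell index), the
#' mechanism behind human-driven loss of range at the cold edge; with
#' `bias = "random"` removal is uniform.
#'
#' @param historical an `nm_mask` (period historical).
#' @param stack an `nm_stack` (provides MTEMP for the cold-edge ordering).
#' @param fraction in \[0, 1).
#' @param bias `"cold_edge"` or `"random"`.
#' @param seed used for `bias = "random"`.
#' @return an `nm_mask` with period `"modern"`, nested in `historical`.
#' @export
contract_range <- function(historical, stack, fraction,
                           bias = c("cold_edge", "random"), seed = 1) {
  bias <- match.arg(bias)
  if (!(fraction >= 0 && fraction < 1)) {
    stop("'fraction' must be in [0, 1)", call. = FALSE)
  }
  cells <- mask_cells(historical)
  nrem <- ceiling(fraction * length(cells))
  removed <- if (nrem == 0) integer(0) else if (bias == "cold_edge") {
    mt <- stack$layers$MTEMP$values[cells]
    cells[order(mt, cells)[seq_len(nrem)]]
  } else {
    with_rng(derive_seed(seed, "contract", historical$species_label),
             cells[sample.int(length(cells), nrem)])
  }
  v <- historical$mask$values
  v[removed] <- 0
  range_mask(grid_create(v, origin = historical$mask$origin,
                         cell_size = historical$mask$cell_size,
                         nodata = historical$mask$nodata,
                         crs_label = historical$mask$crs_label),
             period = "modern", species_label = historical$species_label)
}

#' Generate a complete synthetic scenario
#'
#' Bundles climate, derived bioclim stack, ground-truth niche, historical
#' and (contracted) modern range masks, the two continent regions, and a
#' small set of naturalized-introduction points: cells in the transfer
#' region whose true suitability is at or above the occupancy threshold,
#' emulating localities where the species has established outside its
#' native continent.
#'
#' @param config named list overriding any of the defaults: `rows`, `cols`
#'   (64), `gap` (8), `seed` (1), `smoothness` (3), `true_weights`
#'   (MTEMP 3.0, PREC 1.5 — a warm-wet niche), `occ_frac` (0.2),
#'   `contraction` (list(fraction = 0.5, bias = "cold_edge")), `n_intro`
#'   (4), `native`, `transfer` (climate parameter lists).
#' @return object of class `nm_scenario`.
#' @export
gen_scenario <- function(config = list()) {
  cfg <- utils::modifyList(list(
    rows = 64, cols = 64, gap = 8, seed = 1, smoothness = 3,
    true_weights = c(MTEMP = 3.0, PREC = 2.0),
    occ_frac = 0.2,
    contraction = list(fraction = 0.5, bias = "cold_edge"),
    n_intro = 4, native = list(), transfer = list()), config)

  clim <- gen_climate(cfg$rows, cfg$cols, seed = cfg$seed,
                      smoothness = cfg$smoothness, gap = cfg$gap,
                      native = cfg$native, transfer = cfg$transfer)
  stack <- suppressMessages(derive_bioclim(clim$monthly))
  truth <- gen_truth(stack, cfg$true_weights, clim$native_region,
                     occ_frac = cfg$occ_frac, seed = cfg$seed)
  modern <- contract_range(truth$historical_mask, stack,
                           fraction = cfg$contraction$fraction,
                           bias = cfg$contraction$bias, seed = cfg$seed)

  # introduction points: transfer cells whose true suitability clears the
  # native occupancy threshold
  ref <- stack$layers[[1]]
  tr <- !is.na(clim$transfer_region$values) & clim$transfer_region$values == 1
  qual <- which(tr & !is.na(truth$suitability$values) &
                  truth$suitability$values >= truth$threshold)
  if (length(qual) < cfg$n_intro) {
    warning(sprintf(
      "only %d transfer cell(s) clear the occupancy threshold (%d requested)",
      length(qual), cfg$n_intro), call. = FALSE)
    pick <- qual
  } else {
    pick <- with_rng(derive_seed(cfg$seed, "introductions"),
                     sort(qual[sample.int(length(qual), cfg$n_intro)]))
  }
  rc <- arrayInd(pick, dim(ref$values))
  xy <- cell_center(ref, rc[, 1], rc[, 2])
  intro <- data.frame(id = sprintf("intro_%d", seq_along(pick)),
                      x = xy[, "x"], y = xy[, "y"])

  structure(list(monthly = clim$monthly, stack = stack,
                 native_region = clim$native_region,
                 transfer_region = clim$transfer_region,
                 true_weights = cfg$true_weights,
                 truth = truth$suitability,
                 occ_threshold = truth$threshold,
                 historical_mask = truth$historical_mask,
                 modern_mask = modern,
                 intro_points = intro,
                 config = cfg),
            class = "nm_scenario")
}

#' @export
print.nm_scenario <- function(x, ...) {
  cat(sprintf(
    "<nm_scenario> %dx%d per continent, seed %d; historical %d cells, modern %d, %d introduction points\n",
    x$config$rows, x$config$cols, x$config$seed,
    length(mask_cells(x$historical_mask)), length(mask_cells(x$modern_mask)),
    nrow(x$intro_points)))
  invisible(x)
}

#' Sample presences from the true Gibbs niche
#'
#' Draws cells over the native region with probability proportional to the
#' true suitability (with replacement — independent draws from the truth
#' distribution), placing points at cell centers. Used for parameter
#' recovery against the known weights.
#'
#' @param scenario an `nm_scenario`.
#' @param n number of presence draws.
#' @param seed master seed.
#' @return data.frame of `id`, `x`, `y`.
#' @export
sample_from_truth <- function(scenario, n, seed = 1) {
  s <- scenario$truth$values
  inreg <- !is.na(scenario$native_region$values) &
    scenario$native_region$values == 1 & !is.na(s)
  cells <- which(inreg)
  pr <- s[cells] / sum(s[cells])
  pick <- with_rng(derive_seed(seed, "truth-draws"),
                   cells[sample.int(length(cells), n, replace = TRUE,
                                    prob = pr)])
  ref <- scenario$truth
  rc <- arrayInd(pick, dim(ref$values))
  xy <- cell_center(ref, rc[, 1], rc[, 2])
  data.frame(id = sprintf("truth_p%d", seq_len(n)), x = xy[, "x"],
             y = xy[, "y"])
}

#' Write / read a scenario directory
#'
#' Serializes a scenario as plain text: 36 monthly grids, the two region
#' grids, both masks and the truth grid as ESRI ASCII, the introduction
#' points as CSV, and a JSON manifest holding the true weights, occupancy
#' threshold and full config (seeds included). [read_scenario()] restores
#' it; regeneration from the manifest's config is bit-identical.
#'
#' @param scenario an `nm_scenario`.
#' @param dir destination directory (created if needed).
#' @return `dir` / the restored `nm_scenario`.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in 1:12) {
    write_grid(scenario$monthly$tmin[[i]], file.path(dir, sprintf("tmin_%02d.asc", i)))
    write_grid(scenario$monthly$tmax[[i]], file.path(dir, sprintf("tmax_%02d.asc", i)))
    write_grid(scenario$monthly$prec[[i]], file.path(dir, sprintf("prec_%02d.asc", i)))
  }
  write_grid(scenario$native_region, file.path(dir, "native_region.asc"))
  write_grid(scenario$transfer_region, file.path(dir, "transfer_region.asc"))
  write_grid(scenario$historical_mask$mask, file.path(dir, "historical_mask.asc"))
  write_grid(scenario$modern_mask$mask, file.path(dir, "modern_mask.asc"))
  write_grid(scenario$truth, file.path(dir, "true_suitability.asc"))
  write_points(scenario$intro_points, file.path(dir, "introduction_points.csv"))
  cfg <- scenario$config
  cfg$true_weights <- as.list(cfg$true_weights)   # keep names through JSON
  jsonlite::write_json(
    list(format = "nichemax-scenario", version = 1L,
         true_weights = as.list(scenario$true_weights),
         occ_threshold = scenario$occ_threshold,
         config = cfg),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "nichemax-scenario")) {
    stop("not a nichemax scenario directory: ", dir, call. = FALSE)
  }
  rd <- function(f) read_grid(file.path(dir, f))
  monthly <- monthly_climate(
    tmin = lapply(1:12, function(i) rd(sprintf("tmin_%02d.asc", i))),
    tmax = lapply(1:12, function(i) rd(sprintf("tmax_%02d.asc", i))),
    prec = lapply(1:12, function(i) rd(sprintf("prec_%02d.asc", i))))
  stack <- suppressMessages(derive_bioclim(monthly))
  cfg <- man$config
  cfg$true_weights <- unlist(cfg$true_weights)
  structure(list(
    monthly = monthly, stack = stack,
    native_region = rd("native_region.asc"),
    transfer_region = rd("transfer_region.asc"),
    true_weights = unlist(man$true_weights),
    truth = rd("true_suitability.asc"),
    occ_threshold = man$occ_threshold,
    historical_mask = range_mask(rd("historical_mask.asc"), "historical"),
    modern_mask = range_mask(rd("modern_mask.asc"), "modern"),
    intro_points = read_points(file.path(dir, "introduction_points.csv")),
    config = cfg), class = "nm_scenario")
}
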