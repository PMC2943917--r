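#' Minimum training presence (MTP) threshold
#'
#' The lowest model score among the training presences: a generous
#' criterion with zero training omission.
#'
#' @param train_scores numeric vector of training-presence scores.
#' @return the threshold (a real).
#' @export
mtp <- function(train_scores) {
  if (!length(train_scores)) stop("empty score vector", call. = FALSE)
  min(train_scores)
}

#' Maximum sensitivity-plus-specificity (MTSS) threshold
#'
#' Scans the sorted unique observed scores as candidate thresholds under
#' the rule "score >= t implies presence" and returns the candidate
#' maximizing sensitivity + specificity; ties resolve to the smallest such
#' threshold (deterministic).
#'
#' @param presence_scores,absence_scores numeric score vectors.
#' @return the threshold (a real).
#' @export
mtss <- function(presence_scores, absence_scores) {
  if (!length(presence_scores) || !length(absence_scores)) {
    stop("empty score vector", call. = FALSE)
  }
  cand <- sort(unique(c(presence_scores, absence_scores)))
  best_t <- cand[1]; best <- -Inf
  for (t in cand) {
    ss <- mean(presence_scores >= t) + mean(absence_scores < t)
    if (ss > best + 1e-12) { best <- ss; best_t <- t }
  }
  best_t
}

#' Binarize a suitability map
#'
#' A cell is suitable iff its logistic score is >= `t`; nodata propagates.
#'
#' @param map an `nm_suitmap` or an `nm_grid` of scores.
#' @param t threshold.
#' @return boolean `nm_grid` (1 = suitable).
#' @export
binarize <- function(map, t) {
  g <- if (inherits(map, "nm_suitmap")) map$logistic else map
  stopifnot(is_grid(g))
  grid_create((g$values >= t) * 1, origin = g$origin, cell_size = g$cell_size,
              nodata = g$nodata, crs_label = g$crs_label)
}

#' Cumulative (union) map over replicate runs
#'
#' A cell is suitable iff at least one run marks it suitable — each run
#' thresholded by its own criterion value before the union.
#'
#' @param binary_maps list of aligned boolean `nm_grid`s.
#' @return boolean `nm_grid`.
#' @export
cumulative_map <- function(binary_maps) {
  stopifnot(length(binary_maps) >= 1)
  ref <- binary_maps[[1]]
  acc <- ref$values
  for (g in binary_maps[-1]) {
    stop_if_unaligned(ref, g, "binary maps")
    acc <- pmax(acc, g$values, na.rm = FALSE)
  }
  grid_create(acc, origin = ref$origin, cell_size = ref$cell_size,
              nodata = ref$nodata, crs_label = ref$crs_label)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random presence outscores a random reference point,
#' counting ties as 1/2: the mean over all pairs of
#' \[presence > reference\] + 0.5 \[tie\]. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param presence_scores,reference_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(presence_scores, reference_scores) {
  n1 <- length(presence_scores); n2 <- length(reference_scores)
  if (!n1 || !n2) stop("empty score vector", call. = FALSE)
  r <- rank(c(presence_scores, reference_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Confusion (error) matrix of a binary map against test points
#'
#' Presence points on suitable cells count as true positives, absence
#' points on unsuitable cells as true negatives, and so on. Points on
#' nodata cells are excluded with a logged count.
#'
#' @param binary_map boolean `nm_grid`.
#' @param presence_points,absence_points data.frames of `id`, `x`, `y`.
#' @return object of class `nm_confusion`: counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(binary_map, presence_points, absence_points) {
  val_at <- function(pts) {
    rc <- locate_cell(binary_map, pts$x, pts$y)
    if (anyNA(rc$row)) {
      bad <- pts$id[is.na(rc$row)][1]
      stop(sprintf("point '%s' falls outside the map extent",
                   as.character(bad)), call. = FALSE)
    }
    binary_map$values[cbind(rc$row, rc$col)]
  }
  vp <- val_at(presence_points); va <- val_at(absence_points)
  drop_n <- sum(is.na(vp)) + sum(is.na(va))
  if (drop_n) {
    message(sprintf("confusion: %d point(s) on nodata cells excluded", drop_n))
  }
  vp <- vp[!is.na(vp)]; va <- va[!is.na(va)]
  structure(list(tp = sum(vp == 1), fn = sum(vp == 0),
                 fp = sum(va == 1), tn = sum(va == 0)),
            class = "nm_confusion")
}

#' @export
print.nm_confusion <- function(x, ...) {
  cat(sprintf("<nm_confusion> tp %d fp %d fn %d tn %d (sens %.3f spec %.3f)\n",
              x$tp, x$fp, x$fn, x$tn,
              x$tp / (x$tp + x$fn), x$tn / (x$tn + x$fp)))
  invisible(x)
}

#' Cohen's kappa of a confusion matrix
#'
#' (p_o - p_e) / (1 - p_e) with observed agreement p_o = (tp + tn)/N and
#' chance agreement p_e = \[(tp+fp)(tp+fn) + (fn+tn)(fp+tn)\]/N^2; defined
#' as 0 when p_e = 1. Note the cited evaluation literature sometimes labels
#' "proportion of specific agreement" as kappa; those are different
#' statistics, and Cohen's kappa is what is computed here.
#'
#' @param cm an `nm_confusion` (or list with tp/fp/fn/tn).
#' @return kappa in \[-1, 1\].
#' @export
kappa_stat <- function(cm) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  stopifnot(n >= 1)
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) +
           (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  if (abs(1 - pe) < 1e-15) return(0)
  (po - pe) / (1 - pe)
}

#' Threshold and evaluate a set of replicate runs, with period transfer
#'
#' For each replicate run (a fitted model + its suitability map + training
#' scores), computes per-run AUC of the test presences against the
#' reference scores, applies each run's own MTP and MTSS thresholds,
#' unions the per-run binary maps into cumulative maps, and scores those
#' against presence/absence test points with Cohen's kappa. Train and test
#' periods are recorded so cross-period (transfer) rows are explicit.
#'
#' By default MTSS is computed from the training presences against the
#' model's background sample ("training sensitivity plus specificity");
#' the held-out absences are reserved for kappa. Set
#' `mtss_reference = "absence"` to use the test absences instead.
#'
#' @param runs list of run objects as produced by [fit_replicates()]: each
#'   has `model`, `map` (`nm_suitmap`), `train_scores`, `bg_scores`.
#' @param test_presence,test_absence data.frames of test points.
#' @param train_period,test_period period labels for the report.
#' @param criteria thresholds to apply, subset of `c("MTP", "MTSS")`.
#' @param mtss_reference `"background"` (default) or `"absence"`.
#' @return object of class `nm_eval`: per-run table, `auc_mean`, `auc_sd`,
#'   kappa per criterion, the cumulative maps, and the period labels.
#' @export
evaluate_transfer <- function(runs, test_presence, test_absence,
                              train_period = "modern",
                              test_period = train_period,
                              criteria = c("MTP", "MTSS"),
                              mtss_reference = c("background", "absence")) {
  stopifnot(length(runs) >= 1)
  mtss_reference <- match.arg(mtss_reference)
  criteria <- match.arg(criteria, several.ok = TRUE)

  score_at <- function(map, pts) {
    rc <- locate_cell(map$logistic, pts$x, pts$y)
    map$logistic$values[cbind(rc$row, rc$col)]
  }
  per_run <- lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    sp <- score_at(r$map, test_presence)
    sa <- score_at(r$map, test_absence)
    keep <- !is.na(sp); sp <- sp[keep]
    sa <- sa[!is.na(sa)]
    t_mtp <- mtp(r$train_scores)
    absref <- if (mtss_reference == "background") r$bg_scores else sa
    t_mtss <- mtss(r$train_scores, absref)
    list(auc = auc_score(sp, r$bg_scores),
         mtp = t_mtp, mtss = t_mtss,
         bin_mtp = binarize(r$map, t_mtp),
         bin_mtss = binarize(r$map, t_mtss))
  })
  aucs <- vapply(per_run, `[[`, 0.0, "auc")
  kappas <- list(); cum <- list()
  if ("MTP" %in% criteria) {
    cum$MTP <- cumulative_map(lapply(per_run, `[[`, "bin_mtp"))
    kappas$MTP <- kappa_stat(confusion(cum$MTP, test_presence, test_absence))
  }
  if ("MTSS" %in% criteria) {
    cum$MTSS <- cumulative_map(lapply(per_run, `[[`, "bin_mtss"))
    kappas$MTSS <- kappa_stat(confusion(cum$MTSS, test_presence, test_absence))
  }
  tab <- data.frame(run = seq_along(runs),
                    auc = aucs,
                    mtp = vapply(per_run, `[[`, 0.0, "mtp"),
                    mtss = vapply(per_run, `[[`, 0.0, "mtss"))
  structure(list(runs = tab,
                 auc_mean = mean(aucs),
                 auc_sd = if (length(aucs) > 1) stats::sd(aucs) else 0,
                 kappa = kappas,
                 cumulative = cum,
                 n_runs = length(runs),
                 train_period = train_period,
                 test_period = test_period),
            class = "nm_eval")
}

#' @export
print.nm_eval <- function(x, ...) {
  cat(sprintf("<nm_eval> train %s / test %s: AUC %.3f +/- %.3f over %d runs\n",
              x$train_period, x$test_period, x$auc_mean, x$auc_sd, x$n_runs))
  for (k in names(x$kappa)) cat(sprintf("  kappa_%s = %.3f\n", k, x$kappa[[k]]))
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' One row per run plus a summary row, mirroring the usual performance
#' table layout (AUC mean +/- SD, kappa per cumulative criterion, train and
#' test period columns). Run metadata are written as comment header lines.
#'
#' @param ev an `nm_eval`.
#' @param path destination CSV.
#' @param meta optional named list written into the comment header.
#' @export
write_eval <- function(ev, path, meta = list()) {
  hdr <- c(sprintf("# train_period=%s test_period=%s n_runs=%d",
                   ev$train_period, ev$test_period, ev$n_runs),
           if (length(meta)) sprintf("# %s", paste(names(meta),
                                                   unlist(meta),
                                                   sep = "=", collapse = " ")))
  tab <- ev$runs
  tab$kappa_MTP <- NA_real_; tab$kappa_MTSS <- NA_real_
  summary_row <- data.frame(run = NA_integer_, auc = ev$auc_mean,
                            mtp = NA_real_, mtss = NA_real_,
                            kappa_MTP = if (!is.null(ev$kappa$MTP)) ev$kappa$MTP else NA_real_,
                            kappa_MTSS = if (!is.null(ev$kappa$MTSS)) ev$kappa$MTSS else NA_real_)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(rbind(tab, summary_row), con, row.names = FALSE)
  invisible(path)
}
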