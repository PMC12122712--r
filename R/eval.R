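#' Random train/validation split of occurrence records
#'
#' Seeded uniform split into `round(fraction * n)` training records and the
#' remainder for validation; disjoint and exhaustive.
#'
#' @param occ an [occurrence_set()] (at least 5 records).
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with elements `train` and `validation`.
#' @export
split_train_validation <- function(occ, fraction = 0.8, seed = 1) {
  n <- nrow(occ)
  if (n < 5) stop("need at least 5 records to split", call. = FALSE)
  n_train <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = occ[sort(idx), , drop = FALSE],
       validation = occ[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney estimator: the probability that a random presence score
#' exceeds a random background score, with ties counting one half.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  stopifnot(np > 0, nb > 0)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Threshold maximizing sensitivity + specificity
#'
#' Scans candidate thresholds (midpoints between adjacent sorted unique
#' scores, so every distinct classification is considered) and returns the
#' one maximizing sensitivity (presence scores `>= tau`) plus specificity
#' (background scores `< tau`, background standing in for absences). Ties
#' are broken toward the smaller threshold, i.e. the more inclusive range.
#'
#' @param presence_scores,background_scores numeric score vectors
#'   (suitabilities in `(0, 1)`).
#' @return an object of class `evaluation_report`: `threshold`,
#'   `sensitivity`, `specificity`, `auc`, confusion counts `tp`, `fp`,
#'   `tn`, `fn`, and `n_presence` / `n_background`.
#' @export
max_sens_spec_threshold <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  s <- sort(unique(c(presence_scores, background_scores)))
  cand <- if (length(s) == 1) s else (s[-1] + s[-length(s)]) / 2
  best <- NULL
  for (tau in cand) {
    sens <- mean(presence_scores >= tau)
    spec <- mean(background_scores < tau)
    if (is.null(best) || sens + spec > best$sum + 1e-12) {
      best <- list(tau = tau, sens = sens, spec = spec, sum = sens + spec)
    }
  }
  tp <- sum(presence_scores >= best$tau)
  fn <- sum(presence_scores < best$tau)
  fp <- sum(background_scores >= best$tau)
  tn <- sum(background_scores < best$tau)
  structure(list(threshold = best$tau, sensitivity = best$sens,
                 specificity = best$spec,
                 auc = auc(presence_scores, background_scores),
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 n_presence = length(presence_scores),
                 n_background = length(background_scores)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> AUC %.3f, threshold %.3f (sens %.3f, spec %.3f)\n",
    x$auc, x$threshold, x$sensitivity, x$specificity))
  cat(sprintf("  confusion: TP %d FP %d TN %d FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Binarize a suitability raster at a threshold
#'
#' A cell is suitable iff its suitability is `>= tau` (cells exactly at the
#' threshold are inside the range); `NA` cells stay `NA`.
#'
#' @param suitability numeric suitability matrix.
#' @param grid the [make_grid()] it lives on.
#' @param tau threshold in `(0, 1)`.
#' @return an object of class `binary_range_map`: `grid`, `suitable`
#'   (logical matrix), `threshold`.
#' @export
binarize <- function(suitability, grid, tau) {
  stopifnot(tau > 0, tau < 1)
  structure(list(grid = grid, suitable = suitability >= tau,
                 threshold = tau),
            class = "binary_range_map")
}

#' @export
print.binary_range_map <- function(x, ...) {
  n_valid <- sum(!is.na(x$suitable))
  cat(sprintf(
    "<binary_range_map> %d / %d valid cells suitable at threshold %.3f\n",
    sum(x$suitable, na.rm = TRUE), n_valid, x$threshold))
  invisible(x)
}

#' Range saturation: occurrence points and cells inside the predicted range
#'
#' @param occ an [occurrence_set()].
#' @param brm a [binarize()]d range map.
#' @return list with `point_saturation` (fraction of occurrence points whose
#'   cell is suitable; points on nodata cells count as unsuitable) and
#'   `cell_saturation` (fraction of valid cells suitable).
#' @export
range_saturation <- function(occ, brm) {
  stopifnot(nrow(occ) > 0)
  idx <- cell_index(brm$grid, occ$lon, occ$lat)
  flat <- ifelse(is.na(idx$row), NA_integer_,
                 (idx$col - 1L) * brm$grid$n_rows + idx$row)
  inside <- brm$suitable[flat]
  inside[is.na(inside)] <- FALSE
  valid <- !is.na(brm$suitable)
  list(point_saturation = mean(inside),
       cell_saturation = sum(brm$suitable[valid]) / sum(valid))
}
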