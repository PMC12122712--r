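#' Encode per-cell range change between two binary maps
#'
#' Uses the current-minus-twice-future integer encoding on binary
#' suitability: code `= current - 2 * future` with `current, future` in
#' `{0, 1}`, giving
#' \itemize{
#'   \item `0` — unsuitable now and in the future (still unsuitable),
#'   \item `-2` — unsuitable now, suitable in the future (expansion),
#'   \item `1` — suitable now, unsuitable in the future (contraction),
#'   \item `-1` — suitable in both periods (persistence).
#' }
#' Nodata cells propagate as `NA`.
#'
#' @param current,future [binarize()]d range maps on one grid.
#' @return an object of class `range_change_map`: `grid`, `codes` (integer
#'   matrix over `{0, -2, 1, -1}`), `legend`.
#' @export
encode_change <- function(current, future) {
  stopifnot(inherits(current, "binary_range_map"),
            inherits(future, "binary_range_map"))
  if (!grid_equal(current$grid, future$grid)) {
    stop("current and future maps are not on the same grid", call. = FALSE)
  }
  codes <- as.integer(current$suitable) - 2L * as.integer(future$suitable)
  codes <- matrix(codes, current$grid$n_rows, current$grid$n_cols)
  structure(list(
    grid = current$grid, codes = codes,
    legend = c(`0` = "still unsuitable", `-2` = "expansion",
               `1` = "contraction", `-1` = "persistence")),
    class = "range_change_map")
}

#' @export
print.range_change_map <- function(x, ...) {
  cat("<range_change_map>\n")
  tab <- table(factor(x$codes[!is.na(x$codes)], levels = c(0, -2, 1, -1)))
  for (code in names(tab)) {
    cat(sprintf("  %3s %-16s %d\n", code, x$legend[[code]], tab[[code]]))
  }
  invisible(x)
}

#' Summarize a range-change map into counts and percentages
#'
#' Counts cells per code and reports expansion and contraction as
#' percentages of the *current* range size
#' (`n_contraction + n_persistence`). When the current range is empty the
#' percentages are `NA` (undefined) while the counts remain valid. With
#' `latitude_weighted = TRUE` each cell is weighted by the cosine of its
#' center latitude, approximating relative cell area on the geographic grid.
#'
#' @param rcm an [encode_change()] result.
#' @param latitude_weighted weight cells by `cos(latitude)`? Default FALSE.
#' @return an object of class `change_summary` with fields
#'   `n_still_unsuitable`, `n_expansion`, `n_contraction`, `n_persistence`,
#'   `current_range`, `future_range`, `expansion_pct`, `contraction_pct`.
#' @export
summarize_change <- function(rcm, latitude_weighted = FALSE) {
  stopifnot(inherits(rcm, "range_change_map"))
  w <- if (latitude_weighted) {
    cos(latitude_matrix(rcm$grid) * pi / 180)
  } else {
    matrix(1, rcm$grid$n_rows, rcm$grid$n_cols)
  }
  valid <- !is.na(rcm$codes)
  count <- function(code) sum(w[valid & rcm$codes == code])
  n0 <- count(0L); ne <- count(-2L); nc <- count(1L); np <- count(-1L)
  cur <- nc + np
  fut <- ne + np
  structure(list(
    n_still_unsuitable = n0, n_expansion = ne, n_contraction = nc,
    n_persistence = np, current_range = cur, future_range = fut,
    expansion_pct = if (cur > 0) 100 * ne / cur else NA_real_,
    contraction_pct = if (cur > 0) 100 * nc / cur else NA_real_,
    latitude_weighted = latitude_weighted),
    class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf(
    "<change_summary> persistence %g, expansion %g (%.1f%%), contraction %g (%.1f%%), still unsuitable %g\n",
    x$n_persistence, x$n_expansion, x$expansion_pct,
    x$n_contraction, x$contraction_pct, x$n_still_unsuitable))
  invisible(x)
}

#' Long-format table of per-scenario change summaries
#'
#' @param summaries named list of [summarize_change()] results; names of the
#'   form `"<SSP>_<timeline>"`, or supply `ssp`/`timeline` columns via a
#'   list of lists `list(ssp =, timeline =, summary =)`.
#' @return data.frame with columns `ssp`, `timeline`, `metric`, `value`
#'   (metrics: the four counts plus expansion/contraction percentages).
#' @export
change_report <- function(summaries) {
  if (length(summaries) == 0) {
    return(data.frame(ssp = character(), timeline = character(),
                      metric = character(), value = numeric()))
  }
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    if (is.list(s) && !inherits(s, "change_summary")) {
      ssp <- s$ssp; timeline <- s$timeline; s <- s$summary
    } else {
      parts <- strsplit(names(summaries)[i], "_", fixed = TRUE)[[1]]
      ssp <- parts[1]
      timeline <- paste(parts[-1], collapse = "_")
    }
    metrics <- c(n_still_unsuitable = s$n_still_unsuitable,
                 n_expansion = s$n_expansion,
                 n_contraction = s$n_contraction,
                 n_persistence = s$n_persistence,
                 expansion_pct = s$expansion_pct,
                 contraction_pct = s$contraction_pct)
    data.frame(ssp = ssp, timeline = timeline, metric = names(metrics),
               value = unname(metrics), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
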