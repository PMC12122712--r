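#' Feature expansion specification for the maximum-entropy model
#'
#' Controls which feature classes are expanded from the (min-max scaled)
#' predictor variables. By default the classes are chosen automatically from
#' the presence sample size when fitting: linear + quadratic below 80
#' presences, plus hinge and product at 80 or more.
#'
#' @param classes subset of `c("linear", "quadratic", "product", "hinge")`.
#' @param n_knots hinge knot grid size per variable (default 50).
#' @param reg_multiplier global regularization multiplier (default 1).
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(classes = c("linear", "quadratic", "product",
                                     "hinge"),
                         n_knots = 50, reg_multiplier = 1) {
  classes <- match.arg(classes, several.ok = TRUE)
  structure(list(classes = classes, n_knots = n_knots,
                 reg_multiplier = reg_multiplier),
            class = "feature_spec")
}

# Per-class regularization weights, interpolated on the presence sample size
# (smaller samples get stronger shrinkage), in the spirit of the defaults
# used by maximum-entropy SDM software. Hinge features use a constant 0.5.
class_beta <- function(class, n_presence) {
  if (class == "hinge") return(0.5)
  stats::approx(x = c(0, 10, 30, 100),
                y = c(1.0, 1.0, 0.2, 0.05),
                xout = n_presence, rule = 2)$y
}

#' Expand scaled variables into model features
#'
#' Variables are min-max scaled to `[0, 1]` (scaling fitted on the supplied
#' data when `scaling` is `NULL`, i.e. on training presence + background;
#' otherwise values are clamped into the stored training range first — the
#' projection-time clamping rule). Features: linear `s`; quadratic `s^2`;
#' product `s_i * s_j` for each variable pair; hinge
#' `max(0, (s - k)/(1 - k))` and `max(0, (k - s)/k)` on an even knot grid.
#' Constant variables are excluded with a warning.
#'
#' @param x data.frame or matrix of raw predictor values.
#' @param spec a [feature_spec()].
#' @param scaling optional fitted scaling (from a previous call) to reuse.
#' @return list: `features` (numeric matrix), `scaling` (per-variable
#'   min/max), `meta` (data.frame: feature name, class, variable(s), knot),
#'   `variables` (retained variable names).
#' @export
build_features <- function(x, spec = feature_spec(), scaling = NULL) {
  x <- as.data.frame(x)
  if (is.null(scaling)) {
    rng <- lapply(x, range)
    const <- names(x)[vapply(rng, function(r) r[1] == r[2], logical(1))]
    if (length(const)) {
      warning("constant variable(s) excluded from features: ",
              paste(const, collapse = ", "), call. = FALSE)
      x <- x[, setdiff(names(x), const), drop = FALSE]
      rng <- rng[setdiff(names(rng), const)]
    }
    if (ncol(x) == 0) stop("no non-constant variables left", call. = FALSE)
    scaling <- list(min = vapply(rng, `[`, numeric(1), 1),
                    max = vapply(rng, `[`, numeric(1), 2))
  } else {
    x <- x[, names(scaling$min), drop = FALSE]
  }
  vars <- names(scaling$min)
  s <- vapply(vars, function(v) {
    val <- pmin(pmax(x[[v]], scaling$min[[v]]), scaling$max[[v]])  # clamp
    (val - scaling$min[[v]]) / (scaling$max[[v]] - scaling$min[[v]])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) s <- matrix(s, nrow = 1, dimnames = list(NULL, vars))

  feats <- list(); meta <- list()
  add <- function(name, class, var, values, knot = NA_real_) {
    feats[[name]] <<- values
    meta[[name]] <<- data.frame(feature = name, class = class, variable = var,
                                knot = knot, stringsAsFactors = FALSE)
  }
  if ("linear" %in% spec$classes) {
    for (v in vars) add(v, "linear", v, s[, v])
  }
  if ("quadratic" %in% spec$classes) {
    for (v in vars) add(paste0(v, "^2"), "quadratic", v, s[, v]^2)
  }
  if ("product" %in% spec$classes && length(vars) > 1) {
    for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
      vi <- vars[i]; vj <- vars[j]
      add(paste0(vi, "*", vj), "product", paste(vi, vj, sep = ","),
          s[, vi] * s[, vj])
    }
  }
  if ("hinge" %in% spec$classes) {
    knots <- seq(0, 1, length.out = spec$n_knots)
    for (v in vars) {
      for (k in knots[knots < 1]) {
        add(sprintf("h(%s>%.4f)", v, k), "hinge", v,
            pmax(0, (s[, v] - k) / (1 - k)), knot = k)
      }
      for (k in knots[knots > 0]) {
        add(sprintf("h(%s<%.4f)", v, k), "hinge", v,
            pmax(0, (k - s[, v]) / k), knot = k)
      }
    }
  }
  fm <- do.call(cbind, feats)
  colnames(fm) <- names(feats)
  list(features = fm, scaling = scaling,
       meta = do.call(rbind, meta), variables = vars)
}
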