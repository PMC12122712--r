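#' Pairwise Pearson correlation among predictor layers
#'
#' Computes the Pearson correlation matrix of the stack's layers over jointly
#' valid cells, optionally on a seeded uniform subsample of cells. Constant
#' layers get `NA` correlations and are flagged.
#'
#' @param stack a [climate_stack()] with at least two layers.
#' @param sample_size optional number of cells to subsample.
#' @param seed seed for the subsample.
#' @return an object of class `correlation_report`: `variables`, `matrix`
#'   (symmetric, unit diagonal), `constant` (flagged layer names),
#'   `n_cells`.
#' @export
correlation_matrix <- function(stack, sample_size = NULL, seed = 1) {
  vars <- layer_names(stack)
  if (length(vars) < 2) stop("need at least two layers", call. = FALSE)
  keep <- which(stack$mask)
  if (length(keep) < 3) stop("need at least 3 jointly valid cells",
                             call. = FALSE)
  if (!is.null(sample_size) && sample_size < length(keep)) {
    keep <- with_seed(seed, sort(sample(keep, sample_size)))
  }
  x <- vapply(stack$layers[vars], function(m) m[keep],
              numeric(length(keep)))
  const <- vars[apply(x, 2, function(v) sd(v) == 0 || !is.finite(sd(v)))]
  r <- suppressWarnings(cor(x))
  diag(r) <- 1
  if (length(const)) {
    warning("constant layer(s) flagged: ", paste(const, collapse = ", "),
            call. = FALSE)
  }
  structure(list(variables = vars, matrix = r, constant = const,
                 n_cells = length(keep)),
            class = "correlation_report")
}

#' Greedy elimination of collinear predictors
#'
#' Repeatedly finds the pair with the largest `|r|` strictly above
#' `threshold` and drops the member with the larger mean absolute correlation
#' to all currently retained variables (ties broken by dropping the variable
#' appearing later in the input layer order). `protected` variables are never
#' dropped; two protected variables above the threshold are an error. The
#' retained set always satisfies pairwise `|r| <= threshold`.
#'
#' @param report a [correlation_matrix()] result.
#' @param threshold collinearity cutoff (default 0.7, strict `>`).
#' @param protected variable names that must be retained.
#' @return list with `retained` (character vector, input order) and `trace`
#'   (data.frame: `dropped`, `against`, `abs_r` per elimination step).
#' @export
eliminate_collinear <- function(report, threshold = 0.7, protected = NULL) {
  stopifnot(inherits(report, "correlation_report"))
  vars <- report$variables
  r <- abs(report$matrix)
  diag(r) <- 0
  r[is.na(r)] <- 0  # constant layers cannot trigger elimination
  protected <- intersect(protected %||% character(), vars)
  keep <- vars
  trace <- list()
  repeat {
    sub <- r[keep, keep, drop = FALSE]
    # pairs strictly above threshold with at least one droppable member
    sub_max <- max(sub)
    if (sub_max <= threshold) break
    idx <- which(sub == sub_max, arr.ind = TRUE)[1, ]
    a <- keep[idx[1]]; b <- keep[idx[2]]
    if (all(c(a, b) %in% protected)) {
      stop(sprintf(
        "protected variables '%s' and '%s' are collinear (|r| = %.3f > %.2f)",
        a, b, sub_max, threshold), call. = FALSE)
    }
    drop <- if (a %in% protected) b else if (b %in% protected) a else {
      ma <- mean(sub[a, setdiff(keep, a)])
      mb <- mean(sub[b, setdiff(keep, b)])
      if (ma > mb) a
      else if (mb > ma) b
      else c(a, b)[which.max(match(c(a, b), vars))]  # tie: later in order
    }
    trace[[length(trace) + 1L]] <- data.frame(
      dropped = drop, against = setdiff(c(a, b), drop), abs_r = sub_max,
      stringsAsFactors = FALSE)
    keep <- setdiff(keep, drop)
  }
  list(retained = vars[vars %in% keep],
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(dropped = character(), against = character(),
                               abs_r = numeric()))
}
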