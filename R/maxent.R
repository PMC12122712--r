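#' Fit a presence/background maximum-entropy niche model
#'
#' Fits the Gibbs density over background cells,
#' `q(x) = exp(beta' f(x)) / Z`, by maximizing the L1-penalized
#' log-likelihood
#' `mean_presence(beta' f) - log mean_background(exp(beta' f)) -
#'  sum_j lambda_j |beta_j|`
#' (the maximum-entropy dual; equivalently an infinitely-weighted L1
#' logistic regression of presence against background). Optimization is
#' accelerated proximal gradient descent on an adaptively grown working set;
#' convergence is declared when the maximum KKT violation is at most `tol`.
#' The fit is deterministic given its inputs.
#'
#' @param presence_features numeric feature matrix of presence records.
#' @param background_features numeric feature matrix of background points
#'   (same columns).
#' @param reg_multiplier global multiplier on the regularization schedule.
#' @param lambda optional explicit per-feature penalty vector, overriding the
#'   default schedule `reg_multiplier * beta_class(n_presence) *
#'   sd_presence_j / sqrt(n_presence)` (presence sd floored at 0.05 so no
#'   feature is ever unpenalized).
#' @param feature_meta feature metadata from [build_features()] (used for
#'   per-class regularization weights; optional when `lambda` is given).
#' @param seed accepted for interface uniformity; the fit itself is
#'   deterministic and does not consume randomness.
#' @param tol KKT convergence tolerance (default 1e-5).
#' @param max_iter iteration cap (default 10000); exceeding it without
#'   convergence is an error reporting the residual gradient norm.
#' @return an object of class `maxent_model`: `beta` (named coefficient
#'   vector), `alpha` (normalizer: raw predictions sum to 1 over the
#'   training background), `entropy` (H of the fitted background
#'   distribution, used by the logistic output transform), `lambda`,
#'   `n_presence`, `n_background`, `iterations`, `kkt`.
#' @export
fit_maxent <- function(presence_features, background_features,
                       reg_multiplier = 1, lambda = NULL,
                       feature_meta = NULL, seed = NULL,
                       tol = 1e-5, max_iter = 10000) {
  Fp <- as.matrix(presence_features)
  Fb <- as.matrix(background_features)
  stopifnot(ncol(Fp) == ncol(Fb))
  m <- nrow(Fp); nb <- nrow(Fb)
  if (m < 10) stop("need at least 10 presence records", call. = FALSE)
  if (nb < m) stop("background must be at least as large as presence",
                   call. = FALSE)
  p <- ncol(Fb)
  if (is.null(lambda)) {
    sd_p <- apply(Fp, 2, sd)
    sd_p <- pmax(sd_p, 0.05)
    betas <- if (!is.null(feature_meta)) {
      vapply(feature_meta$class, class_beta, numeric(1), n_presence = m)
    } else rep(class_beta("linear", m), p)
    lambda <- reg_multiplier * betas * sd_p / sqrt(m)
  }
  stopifnot(length(lambda) == p, all(lambda >= 0))

  mp <- colMeans(Fp)
  beta <- numeric(p)

  grad_full <- function(beta) {
    eta <- drop(Fb %*% beta)
    M <- max(eta); w <- exp(eta - M)
    sw <- sum(w); q <- w / sw
    list(g = drop(crossprod(Fb, q)) - mp, q = q, lse = M + log(sw))
  }
  kkt_violation <- function(beta, g) {
    v <- pmax(0, abs(g) - lambda)
    nz <- which(beta != 0)
    v[nz] <- abs(g[nz] + lambda[nz] * sign(beta[nz]))
    v
  }
  # accelerated proximal gradient with backtracking on a column subset
  fista <- function(beta0, cols, budget) {
    A <- Fb[, cols, drop = FALSE]
    mpA <- mp[cols]; lamA <- lambda[cols]
    b <- beta0
    fsmooth <- function(bb) {
      eta <- drop(A %*% bb)
      M <- max(eta)
      M + log(sum(exp(eta - M))) - sum(mpA * bb)
    }
    gsmooth <- function(bb) {
      eta <- drop(A %*% bb)
      M <- max(eta); w <- exp(eta - M)
      drop(crossprod(A, w / sum(w))) - mpA
    }
    obj <- function(bb) fsmooth(bb) + sum(lamA * abs(bb))
    L <- 1; tt <- 1; y <- b; b_prev <- b
    f_best <- obj(b)
    it <- 0
    while (it < budget) {
      it <- it + 1
      gy <- gsmooth(y); fy <- fsmooth(y)
      repeat {
        u <- y - gy / L
        z <- sign(u) * pmax(0, abs(u) - lamA / L)
        dz <- z - y
        if (fsmooth(z) <= fy + sum(gy * dz) + L / 2 * sum(dz^2) + 1e-12) break
        L <- L * 2
        if (L > 1e12) break
      }
      b_prev <- b; b <- z
      t_new <- (1 + sqrt(1 + 4 * tt^2)) / 2
      y <- b + ((tt - 1) / t_new) * (b - b_prev)
      tt <- t_new
      if (obj(b) > f_best + 1e-12) { y <- b; tt <- 1 }  # adaptive restart
      f_best <- min(f_best, obj(b))
      L <- L / 1.2  # let the step size grow back
      if (it %% 10 == 0) {
        g <- gsmooth(b)
        v <- pmax(0, abs(g) - lamA)
        nz <- which(b != 0)
        v[nz] <- abs(g[nz] + lamA[nz] * sign(b[nz]))
        if (max(v) <= tol / 2) break
      }
    }
    list(beta = b, iters = it)
  }

  used <- 0
  repeat {
    gf <- grad_full(beta)
    viol <- kkt_violation(beta, gf$g)
    if (max(viol) <= tol) break
    if (used >= max_iter) {
      stop(sprintf(
        "maxent fit did not converge in %d iterations (max KKT violation %.3g)",
        max_iter, max(viol)), call. = FALSE)
    }
    worst <- order(viol, decreasing = TRUE)
    worst <- worst[viol[worst] > tol][seq_len(min(200, sum(viol > tol)))]
    cols <- sort(union(which(beta != 0), worst))
    res <- fista(beta[cols], cols, budget = min(500, max_iter - used))
    beta[cols] <- res$beta
    used <- used + res$iters
  }
  gf <- grad_full(beta)
  q <- gf$q
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  nm <- colnames(Fb) %||% paste0("f", seq_len(p))
  names(beta) <- nm
  structure(list(beta = beta, alpha = -gf$lse, entropy = H,
                 lambda = stats::setNames(lambda, nm),
                 n_presence = m, n_background = nb,
                 iterations = used, kkt = max(kkt_violation(beta, gf$g))),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features (%d active), %d presences / %d background\n",
    length(x$beta), sum(x$beta != 0), x$n_presence, x$n_background))
  cat(sprintf("  entropy H = %.4f, converged after %d iterations (KKT %.2g)\n",
              x$entropy, x$iterations, x$kkt))
  invisible(x)
}

#' Fit a maximum-entropy SDM from raw predictor values
#'
#' Convenience wrapper: min-max scaling is fitted on the pooled training
#' presence + background values, features are expanded per `spec` (default:
#' class set chosen by presence sample size — linear + quadratic below 80
#' presences, plus hinge and product at 80 or more), and [fit_maxent()] is
#' run with the default regularization schedule.
#'
#' @param presence_data data.frame of raw predictor values at presence
#'   records.
#' @param background_data data.frame of raw predictor values at background
#'   points (same columns).
#' @param spec optional [feature_spec()]; `NULL` selects classes
#'   automatically.
#' @param reg_multiplier regularization multiplier (default 1).
#' @return a `maxent_sdm` object wrapping the fitted `maxent_model` together
#'   with the feature scaling and metadata needed for prediction.
#' @export
maxent_sdm <- function(presence_data, background_data, spec = NULL,
                       reg_multiplier = 1) {
  presence_data <- as.data.frame(presence_data)
  background_data <- as.data.frame(background_data)
  stopifnot(identical(names(presence_data), names(background_data)))
  m <- nrow(presence_data)
  if (is.null(spec)) {
    classes <- if (m >= 80) c("linear", "quadratic", "product", "hinge")
               else c("linear", "quadratic")
    spec <- feature_spec(classes = classes,
                         reg_multiplier = reg_multiplier)
  }
  all_data <- rbind(presence_data, background_data)
  fx <- build_features(all_data, spec)
  Fp <- fx$features[seq_len(m), , drop = FALSE]
  Fb <- fx$features[m + seq_len(nrow(background_data)), , drop = FALSE]
  fit <- fit_maxent(Fp, Fb, reg_multiplier = spec$reg_multiplier,
                    feature_meta = fx$meta)
  structure(list(fit = fit, spec = spec, scaling = fx$scaling,
                 meta = fx$meta, variables = fx$variables),
            class = "maxent_sdm")
}

#' @export
print.maxent_sdm <- function(x, ...) {
  cat("<maxent_sdm> variables:", paste(x$variables, collapse = ", "), "\n")
  print(x$fit)
  invisible(x)
}

#' Predict suitability for new predictor values
#'
#' Variables are clamped into the training range before feature expansion
#' (so conditions beyond the training envelope predict as at the envelope
#' boundary). The `"raw"` output is the Gibbs density normalized over the
#' training background (sums to 1 there); the `"logistic"` output is
#' `raw * e^H / (1 + raw * e^H)`, mapping the typical background cell to
#' about 0.5.
#'
#' @param object a [maxent_sdm()] model.
#' @param newdata data.frame with the model's predictor columns.
#' @param type `"logistic"` (default) or `"raw"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.maxent_sdm <- function(object, newdata, type = c("logistic", "raw"),
                               ...) {
  type <- match.arg(type)
  missing <- setdiff(object$variables, names(newdata))
  if (length(missing)) {
    stop("newdata lacks model variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fx <- build_features(newdata[, object$variables, drop = FALSE],
                       object$spec, scaling = object$scaling)
  eta <- drop(fx$features %*% object$fit$beta) + object$fit$alpha
  if (type == "raw") return(exp(eta))
  plogis(eta + object$fit$entropy)
}

#' Predict a suitability raster over a climate stack
#'
#' @param model a [maxent_sdm()] model.
#' @param stack a [climate_stack()] carrying all model variables.
#' @param type `"logistic"` (default) or `"raw"`.
#' @return numeric matrix of per-cell suitability; masked cells are `NA`.
#' @export
predict_suitability <- function(model, stack, type = "logistic") {
  missing <- setdiff(model$variables, layer_names(stack))
  if (length(missing)) {
    stop("stack lacks model variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- stack_table(stack, model$variables)
  pred <- predict(model, tab, type = type)
  out <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  out[cbind(tab$row, tab$col)] <- pred
  out
}

# Training gain of a coefficient vector on given feature matrices:
# mean presence linear predictor minus log mean background exp, i.e. the
# improvement over the uniform background distribution (gain 0 at beta = 0).
maxent_gain <- function(beta, Fp, Fb) {
  eta_b <- drop(Fb %*% beta)
  M <- max(eta_b)
  mean(drop(Fp %*% beta)) - (M + log(sum(exp(eta_b - M))) - log(nrow(Fb)))
}

#' Percent contribution of variables by permutation importance
#'
#' For each predictor variable, its values are permuted jointly across the
#' pooled presence + background records, features are rebuilt with the
#' training scaling, and the drop in training gain (floored at zero, averaged
#' over permutations) is recorded; drops are normalized to sum to 100.
#'
#' @param model a [maxent_sdm()] model.
#' @param presence_data,background_data the raw training predictor values.
#' @param n_permutations permutations per variable (default 5).
#' @param seed integer seed for the permutations.
#' @return data.frame with columns `variable`, `contribution` (percent,
#'   summing to 100).
#' @export
percent_contribution <- function(model, presence_data, background_data,
                                 n_permutations = 5, seed = 1) {
  presence_data <- as.data.frame(presence_data)
  background_data <- as.data.frame(background_data)
  m <- nrow(presence_data)
  all_data <- rbind(presence_data, background_data)[, model$variables,
                                                    drop = FALSE]
  fx <- build_features(all_data, model$spec, scaling = model$scaling)
  Fp <- fx$features[seq_len(m), , drop = FALSE]
  Fb <- fx$features[-seq_len(m), , drop = FALSE]
  beta <- model$fit$beta
  gain_full <- maxent_gain(beta, Fp, Fb)
  drops <- with_seed(seed, {
    vapply(model$variables, function(v) {
      mean(vapply(seq_len(n_permutations), function(k) {
        perm <- all_data
        perm[[v]] <- perm[[v]][sample.int(nrow(perm))]
        fxp <- build_features(perm, model$spec, scaling = model$scaling)
        max(0, gain_full - maxent_gain(beta, fxp$features[seq_len(m), ,
                                                          drop = FALSE],
                                       fxp$features[-seq_len(m), ,
                                                    drop = FALSE]))
      }, numeric(1)))
    }, numeric(1))
  })
  total <- sum(drops)
  contribution <- if (total > 0) 100 * drops / total
                  else rep(100 / length(drops), length(drops))
  data.frame(variable = model$variables, contribution = contribution,
             row.names = NULL)
}
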