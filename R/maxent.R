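#' Presence-background maximum-entropy modelling
#'
#' A from-scratch implementation of the Maxent model family: the model is the
#' Gibbs distribution over background cells q(x) = exp(lambda . f(x)) / Z
#' whose feature expectations match those at presence points, subject to
#' per-feature L1 regularization. Fitting minimises the penalized negative
#' presence log-likelihood, a convex objective, by accelerated proximal
#' gradient descent (FISTA) with backtracking. Features are the five Maxent
#' classes: linear, quadratic, product, threshold, hinge.
#'
#' @name maxent
NULL

MAXENT_CLASSES <- c("linear", "quadratic", "product", "threshold", "hinge")

#' Feature specification for a candidate model
#'
#' @param classes subset of `c("linear", "quadratic", "product", "threshold",
#'   "hinge")`; single-letter abbreviations `l q p t h` are accepted.
#' @param n_knots number of knots for threshold/hinge features (at background
#'   quantiles), default 50.
#' @param reg_multiplier positive scalar inflating the default per-class
#'   penalties; the candidate grids use {0.3, 0.5, 0.75, 1, 3, 5}.
#' @return A list of class `feature_spec`.
#' @export
feature_spec <- function(classes = c("linear", "quadratic"), n_knots = 50,
                         reg_multiplier = 1) {
  short <- c(l = "linear", q = "quadratic", p = "product", t = "threshold",
             h = "hinge")
  classes <- unname(vapply(classes, function(cl) {
    if (cl %in% names(short)) short[[cl]] else cl
  }, character(1)))
  if (length(classes) == 0L || !all(classes %in% MAXENT_CLASSES))
    stop("configuration error: unknown or empty feature-class set", call. = FALSE)
  if (reg_multiplier <= 0)
    stop("configuration error: reg_multiplier must be positive", call. = FALSE)
  structure(list(classes = unique(classes), n_knots = as.integer(n_knots),
                 reg_multiplier = reg_multiplier),
            class = "feature_spec")
}

#' Fit feature scaling on background values
#'
#' Records per-predictor background min/max/mean/sd and the knot positions
#' (background quantiles on the scaled `[0, 1]` axis) used by threshold and
#' hinge features. Prediction clamps to this support.
#'
#' @param background data.frame of background predictor values.
#' @param predictor_names predictors to scale.
#' @param n_knots number of interior quantile knots.
#' @return A list of class `feature_scaling`.
#' @export
feature_scaling <- function(background, predictor_names, n_knots = 50) {
  sc <- lapply(predictor_names, function(p) {
    v <- background[[p]]
    lo <- min(v); hi <- max(v)
    s <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
    kn <- unique(stats::quantile(s, probs = seq_len(n_knots) / (n_knots + 1),
                                 names = FALSE, type = 7))
    kn <- kn[kn > 1e-9 & kn < 1 - 1e-9]
    list(min = lo, max = hi, mean = mean(v), sd = stats::sd(v), knots = kn)
  })
  names(sc) <- predictor_names
  structure(sc, class = "feature_scaling")
}

scale01 <- function(v, sc) {
  if (sc$max > sc$min) pmin(1, pmax(0, (v - sc$min) / (sc$max - sc$min)))
  else v * 0
}

#' Expand predictor values into the model feature basis
#'
#' Builds the design matrix over the requested feature classes on predictors
#' scaled to `[0, 1]` by the background range (values outside the background
#' support are clamped; the clamped count is recorded as an attribute):
#' linear = scaled value, quadratic = its square, product = pairwise
#' products, threshold = indicator(scaled > knot), hinge = forward
#' `max(0, s - k)/(1 - k)` and reverse `max(0, k - s)/k` per knot.
#'
#' @param values data.frame (or matrix) of raw predictor values.
#' @param spec a [feature_spec()].
#' @param scaling a [feature_scaling()].
#' @return Numeric matrix with a `classes` attribute naming each column's
#'   feature class and an `n_clamped` attribute.
#' @export
expand_features <- function(values, spec, scaling) {
  preds <- names(scaling)
  raw <- vapply(preds, function(p) as.numeric(values[[p]]),
                numeric(nrow(as.data.frame(values))))
  raw <- matrix(raw, ncol = length(preds), dimnames = list(NULL, preds))
  n_clamped <- 0L
  S <- raw
  for (p in preds) {
    sc <- scaling[[p]]
    n_clamped <- n_clamped + sum(raw[, p] < sc$min | raw[, p] > sc$max)
    S[, p] <- scale01(raw[, p], sc)
  }
  cols <- list(); classes <- character(0)
  add <- function(m, cl, nm) {
    colnames(m) <- nm
    cols[[length(cols) + 1L]] <<- m
    classes <<- c(classes, rep(cl, ncol(m)))
  }
  if ("linear" %in% spec$classes) add(S, "linear", preds)
  if ("quadratic" %in% spec$classes)
    add(S^2, "quadratic", paste0(preds, "^2"))
  if ("product" %in% spec$classes && length(preds) >= 2L) {
    pr <- utils::combn(preds, 2L)
    m <- apply(pr, 2L, function(pp) S[, pp[1L]] * S[, pp[2L]])
    m <- matrix(m, nrow = nrow(S))
    add(m, "product", apply(pr, 2L, paste, collapse = "*"))
  }
  if ("threshold" %in% spec$classes) {
    for (p in preds) {
      kn <- scaling[[p]]$knots
      if (length(kn) == 0L) next
      m <- outer(S[, p], kn, function(s, k) as.numeric(s > k))
      add(m, "threshold", sprintf("thr(%s,%.4g)", p, kn))
    }
  }
  if ("hinge" %in% spec$classes) {
    for (p in preds) {
      kn <- scaling[[p]]$knots
      if (length(kn) == 0L) next
      fwd <- outer(S[, p], kn, function(s, k) pmax(0, s - k) / (1 - k))
      rev <- outer(S[, p], kn, function(s, k) pmax(0, k - s) / k)
      add(fwd, "hinge", sprintf("hinge(%s,%.4g)", p, kn))
      add(rev, "hinge", sprintf("rhinge(%s,%.4g)", p, kn))
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "classes") <- classes
  attr(out, "n_clamped") <- n_clamped
  out
}

# published Maxent default per-class regularization, interpolated by
# presence count
default_class_beta <- function(class, np) {
  tbl <- switch(class,
    linear    = list(x = c(0, 10, 30, 100), y = c(1, 1, 0.2, 0.05)),
    quadratic = list(x = c(0, 10, 17, 30, 100), y = c(1.3, 1.3, 0.8, 0.5, 0.25)),
    product   = list(x = c(0, 10, 17, 30, 100), y = c(2.6, 2.6, 1.6, 0.9, 0.55)),
    threshold = list(x = c(0, 100), y = c(2, 1)),
    hinge     = list(x = c(0, 1), y = c(0.5, 0.5)))
  stats::approx(tbl$x, tbl$y, xout = np, rule = 2)$y
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a maximum-entropy model
#'
#' Minimises the penalized negative Gibbs log-likelihood
#' `-(1/m) sum_presence [lambda . f(x_i) - log Z] + sum_j beta_j |lambda_j|`
#' with `log Z = log sum_background exp(lambda . f(x))`, where
#' `beta_j = reg_multiplier x default class penalty(presence count) x
#' sd_j(presences) / sqrt(presence count)` (published Maxent defaults).
#' The convex objective is solved by FISTA with backtracking line search, to
#' a subgradient optimality tolerance of 1e-6 or 500 iterations; degenerate
#' (constant-over-background) feature columns are dropped before fitting.
#'
#' @param presences,background data.frames containing the predictor columns
#'   (e.g. from [extract_predictors()]).
#' @param spec a [feature_spec()].
#' @param predictor_names predictors to use; defaults to the scaling of all
#'   shared numeric predictor columns must be provided explicitly.
#' @param tol subgradient optimality tolerance (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @return An object of class `maxent_model`.
#' @export
fit_maxent <- function(presences, background, spec, predictor_names,
                       tol = 1e-6, max_iter = 500L) {
  m <- nrow(presences); B <- nrow(background)
  if (m < max(10L, 2L * length(spec$classes)))
    stop("insufficient-data error: too few presences to fit", call. = FALSE)
  if (B < 100L)
    stop("insufficient-data error: need at least 100 background cells",
         call. = FALSE)
  scaling <- feature_scaling(background, predictor_names, spec$n_knots)
  Fb <- expand_features(background, spec, scaling)
  Fp <- expand_features(presences, spec, scaling)
  classes <- attr(Fb, "classes")
  keep <- apply(Fb, 2L, function(v) stats::sd(v) > 1e-12)
  Fb <- Fb[, keep, drop = FALSE]
  Fp <- Fp[, keep, drop = FALSE]
  classes <- classes[keep]
  J <- ncol(Fb)
  if (J == 0L) {
    # no informative constraints: the maximum-entropy solution is uniform
    return(structure(list(
      feature_spec = spec, predictor_names = predictor_names,
      scaling = scaling, coefficients = stats::setNames(numeric(0), character(0)),
      feature_classes = character(0), beta = numeric(0),
      logZ = log(B), entropy = log(B), n_params = 0L,
      n_presence = m, n_background = B, converged = TRUE, n_iter = 0L
    ), class = "maxent_model"))
  }

  sd_p <- apply(Fp, 2L, stats::sd)
  beta <- spec$reg_multiplier *
    vapply(classes, default_class_beta, numeric(1), np = m) *
    pmax(sd_p, 0.05) / sqrt(m)

  fbar <- colMeans(Fp)
  smooth_obj <- function(lam) {
    eta <- drop(Fb %*% lam)
    -sum(fbar * lam) + logsumexp(eta)
  }
  smooth_grad <- function(lam) {
    eta <- drop(Fb %*% lam)
    q <- exp(eta - logsumexp(eta))
    drop(crossprod(Fb, q)) - fbar
  }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  lam <- numeric(J); yv <- lam; tk <- 1
  L <- 1
  f_lam <- smooth_obj(lam)
  obj_old <- f_lam + sum(beta * abs(lam))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- smooth_grad(yv)
    f_y <- smooth_obj(yv)
    repeat {
      lam_new <- soft(yv - g / L, beta / L)
      dlt <- lam_new - yv
      if (smooth_obj(lam_new) <=
          f_y + sum(g * dlt) + L / 2 * sum(dlt^2) + 1e-12) break
      L <- L * 2
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yv <- lam_new + ((tk - 1) / tk_new) * (lam_new - lam)
    lam <- lam_new; tk <- tk_new
    obj <- smooth_obj(lam) + sum(beta * abs(lam))
    if (obj > obj_old + 1e-12) { yv <- lam; tk <- 1 }  # momentum restart
    if (it %% 10L == 0L || abs(obj - obj_old) < 1e-12) {
      gg <- smooth_grad(lam)
      viol <- ifelse(abs(lam) > 1e-10,
                     abs(gg + sign(lam) * beta),
                     pmax(abs(gg) - beta, 0))
      if (max(viol) < tol) { converged <- TRUE; break }
    }
    obj_old <- obj
  }
  if (!converged && it >= max_iter)
    warning("maxent fit did not reach tolerance; returning best iterate")

  eta <- drop(Fb %*% lam)
  logZ <- logsumexp(eta)
  q <- exp(eta - logZ)
  structure(list(
    feature_spec = spec, predictor_names = predictor_names,
    scaling = scaling, coefficients = stats::setNames(lam, colnames(Fb)),
    feature_classes = classes, beta = beta,
    logZ = logZ, entropy = -sum(q * log(q + 1e-300)),
    n_params = sum(abs(lam) > 1e-8),
    n_presence = m, n_background = B,
    converged = converged, n_iter = it
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %s features, rm = %g, %d predictors, k = %d nonzero of %d\n",
    paste(substr(x$feature_spec$classes, 1, 1), collapse = ""),
    x$feature_spec$reg_multiplier, length(x$predictor_names),
    x$n_params, length(x$coefficients)))
  invisible(x)
}

# linear predictor at new data (data.frame of predictor values)
maxent_eta <- function(model, values) {
  Fm <- expand_features(values, model$feature_spec, model$scaling)
  Fm <- Fm[, names(model$coefficients), drop = FALSE]
  drop(Fm %*% model$coefficients)
}

# indices and values of region cells where all predictors are valid
stack_region_values <- function(stack, region_mask, predictor_names) {
  rg_check_aligned(region_mask, stack[[predictor_names[1L]]])
  ok <- !is.na(region_mask$values) & region_mask$values == 1
  for (p in predictor_names) ok <- ok & !is.na(stack[[p]]$values)
  cells <- which(ok)
  vals <- as.data.frame(lapply(stack[predictor_names],
                               function(g) g$values[cells]))
  names(vals) <- predictor_names
  list(cells = cells, values = vals)
}

#' Predict the raw (Gibbs) output over a region
#'
#' Raw output is `exp(lambda . f(x)) / Z` with `Z` taken over the model's
#' fitting background; with `normalize = TRUE` (the default, appropriate when
#' the region is the calibration region) values are renormalized to sum to 1
#' over the region's valid cells, the form required by the AICc criterion.
#'
#' @param model a fitted `maxent_model`.
#' @param stack named list of predictor `raster_grid`s.
#' @param region_mask binary `raster_grid`.
#' @param normalize renormalize over the prediction region (default TRUE).
#' @return `raster_grid` of raw values (`NA` outside the region).
#' @export
predict_raw <- function(model, stack, region_mask, normalize = TRUE) {
  miss <- setdiff(model$predictor_names, names(stack))
  if (length(miss))
    stop("configuration error: missing predictor layer(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  rv <- stack_region_values(stack, region_mask, model$predictor_names)
  eta <- maxent_eta(model, rv$values)
  raw <- if (normalize) {
    exp(eta - logsumexp(eta))
  } else {
    exp(eta - model$logZ)
  }
  out <- rg_like(region_mask)
  out$values[rv$cells] <- raw
  out
}

#' Predict suitability (cloglog output) over a region
#'
#' The cloglog transform of Maxent 3.4:
#' `1 - exp(-exp(H) * raw)`, where `H` is the entropy of the fitted Gibbs
#' distribution over the background and `raw` is normalized over that
#' background. Bounded in `[0, 1]` and monotone in the raw output.
#'
#' @inheritParams predict_raw
#' @return `raster_grid` of suitability in `[0, 1]`.
#' @export
predict_suitability <- function(model, stack, region_mask) {
  raw_bg <- predict_raw(model, stack, region_mask, normalize = FALSE)
  out <- rg_like(region_mask)
  ok <- !is.na(raw_bg$values)
  out$values[ok] <- 1 - exp(-exp(model$entropy) * raw_bg$values[ok])
  out
}

# suitability at occurrence points (data.frame with predictor columns)
suitability_at_points <- function(model, points) {
  eta <- maxent_eta(model, points)
  q <- exp(eta - model$logZ)
  1 - exp(-exp(model$entropy) * q)
}
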