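#' Specification of a logistic risk model
#'
#' The validated family comprises three binary logistic regressions that
#' differ in predictor basis and prediction horizon: a vital-signs model
#' with linear predictor relationships and a 24 h horizon (optionally
#' built by forward stepwise selection), and two models with restricted
#' cubic splines for non-linear relationships at 4 h (MICU) and 6 h (SICU)
#' horizons.
#'
#' @param name Model name.
#' @param feature_names Predictors entering the model (default: all
#'   computed features, see [feature_names()]).
#' @param basis `"linear"` or `"rcs"` (restricted cubic spline).
#' @param horizon_hours Label horizon: epochs within `(0, horizon]` hours
#'   before an event are positives.
#' @param knot_probs Quantile probabilities of the development data at
#'   which spline knots are placed (default 0.10/0.50/0.90; >= 3 knots).
#' @param selection `"none"` or `"forward"` (AIC forward stepwise).
#' @return List of class `"risk_model_spec"`.
#' @export
risk_model_spec <- function(name, feature_names = ventrisk::feature_names(),
                            basis = c("linear", "rcs"),
                            horizon_hours = 24,
                            knot_probs = c(0.1, 0.5, 0.9),
                            selection = c("none", "forward")) {
  basis <- match.arg(basis)
  selection <- match.arg(selection)
  stopifnot(horizon_hours > 0, length(knot_probs) >= 3,
            all(diff(knot_probs) > 0))
  structure(list(name = name, feature_names = feature_names, basis = basis,
                 horizon_hours = horizon_hours, knot_probs = knot_probs,
                 selection = selection),
            class = "risk_model_spec")
}

#' The three default model specifications
#'
#' @param feature_names Predictor set shared by all three models.
#' @return Named list of [risk_model_spec()]s: `politano` (linear, 24 h),
#'   `moss_micu` (splines, 4 h), `moss_sicu` (splines, 6 h).
#' @export
default_model_specs <- function(feature_names = ventrisk::feature_names()) {
  list(
    politano = risk_model_spec("politano", feature_names, basis = "linear",
                               horizon_hours = 24),
    moss_micu = risk_model_spec("moss_micu", feature_names, basis = "rcs",
                                horizon_hours = 4),
    moss_sicu = risk_model_spec("moss_sicu", feature_names, basis = "rcs",
                                horizon_hours = 6)
  )
}

#' Binary outcome labels for feature epochs
#'
#' An epoch is a positive iff the admission has an event and the epoch
#' ends within `(0, horizon]` hours before it (an epoch exactly at the
#' event time is a 0: the interval is open at 0). Epochs of patients never
#' emergently intubated, and pre-event epochs farther than the horizon,
#' are 0. Censored epochs are dropped from the output.
#'
#' @param window_ends Sorted epoch end times, minutes.
#' @param event_times Numeric event time(s) in minutes, or `NULL`/`NA`.
#' @param horizon_hours Label horizon in hours.
#' @param censored Logical mask aligned with `window_ends`.
#' @return Tibble `window_end_min`, `label` for uncensored epochs.
#' @export
label_epochs <- function(window_ends, event_times, horizon_hours,
                         censored = rep(FALSE, length(window_ends))) {
  keep <- !censored
  ends <- window_ends[keep]
  lab <- rep(0L, length(ends))
  event_times <- event_times[!is.na(event_times)]
  for (ev in event_times) {
    d <- ev - ends
    lab[d > 0 & d <= horizon_hours * 60] <- 1L
  }
  tibble::tibble(window_end_min = ends, label = lab)
}

#' Restricted-cubic-spline basis of one variable
#'
#' Truncated-power restricted cubic spline: for `k` knots the basis has
#' `k - 1` columns (the variable itself plus `k - 2` non-linear terms),
#' linear beyond the boundary knots, with the usual `(t_k - t_1)^2`
#' normalisation. Values below the first knot contribute zero to the
#' non-linear columns.
#'
#' @param x Numeric vector.
#' @param knots Increasing numeric knots (>= 3).
#' @return Matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  stopifnot(k >= 3, all(diff(knots) > 0))
  p3 <- function(u) pmax(u, 0)^3
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (knots[k] - knots[1])^2
  cols <- lapply(seq_len(k - 2), function(j) {
    (p3(x - knots[j]) -
       p3(x - tk1) * (tk - knots[j]) / (tk - tk1) +
       p3(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / norm
  })
  out <- cbind(x, do.call(cbind, cols))
  colnames(out) <- c("lin", paste0("nl", seq_len(k - 2)))
  out
}

#' Design matrix for a risk model
#'
#' Linear basis: the (imputed) features unchanged. Spline basis: per
#' feature, the restricted-cubic-spline columns with knots at the
#' configured quantiles of the development data. The intercept column is
#' added at fit time, not here.
#'
#' @param features Feature tibble (imputed: no missing values among the
#'   model's features).
#' @param spec A [risk_model_spec()].
#' @param knots Named list of per-feature knot vectors; when `NULL`,
#'   computed from `features` at `spec$knot_probs` (development usage).
#' @return List with `X` (design matrix) and `knots`.
#' @export
make_basis <- function(features, spec, knots = NULL) {
  for (nm in spec$feature_names) {
    if (!nm %in% names(features)) {
      stop("feature missing from data: ", nm, call. = FALSE)
    }
    bad <- which(!is.finite(features[[nm]]))
    if (length(bad)) {
      stop(sprintf("non-finite value in feature '%s' at row %d", nm, bad[1]),
           call. = FALSE)
    }
  }
  if (spec$basis == "linear") {
    X <- as.matrix(features[spec$feature_names])
    return(list(X = X, knots = NULL))
  }
  if (is.null(knots)) {
    knots <- lapply(features[spec$feature_names], function(x) {
      kn <- unname(quantile(x, spec$knot_probs, type = 7))
      if (any(diff(kn) <= 0)) kn <- NULL  # degenerate: fall back to linear
      kn
    })
  }
  blocks <- lapply(spec$feature_names, function(nm) {
    if (is.null(knots[[nm]])) {
      b <- matrix(features[[nm]], ncol = 1)
      colnames(b) <- nm
    } else {
      b <- rcs_basis(features[[nm]], knots[[nm]])
      colnames(b) <- paste0(nm, "_", colnames(b))
    }
    b
  })
  list(X = do.call(cbind, blocks), knots = knots)
}

#' Fit a logistic risk model
#'
#' Maximum-likelihood binary logistic regression on the model's basis.
#' With `selection = "forward"` predictors enter one at a time (a spline
#' feature enters with all of its basis columns) while the AIC improves.
#' Complete or quasi-complete separation is stabilised by refitting with a
#' weak ridge penalty (`lambda = 1e-6` on slopes only) and flagged in the
#' returned object.
#'
#' @param features Imputed development feature tibble.
#' @param labels Integer 0/1 vector aligned with `features` rows.
#' @param spec A [risk_model_spec()].
#' @return Object of class `"fitted_risk_model"`: `spec`, `coefficients`
#'   (intercept first), `knots`, `train_mean_p` (mean fitted event
#'   probability on the development set), `selected` features, `method`.
#' @export
fit_model <- function(features, labels, spec) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  basis <- make_basis(features, spec)
  feat_use <- spec$feature_names

  if (spec$selection == "forward") {
    feat_use <- forward_select(features, labels, spec, basis$knots)
    spec_sel <- spec
    spec_sel$feature_names <- feat_use
    basis <- make_basis(features, spec_sel, knots = basis$knots[feat_use])
  }

  fit <- logistic_fit(basis$X, labels)
  p <- plogis(drop(cbind(1, basis$X) %*% fit$beta))
  structure(list(
    spec = spec,
    selected = feat_use,
    coefficients = fit$beta,
    knots = basis$knots,
    train_mean_p = mean(p),
    method = fit$method
  ), class = "fitted_risk_model")
}

# glm ML fit; ridge IRLS fallback on non-convergence/separation.
logistic_fit <- function(X, y, ridge_lambda = 1e-6) {
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- tryCatch(
    suppressWarnings(glm.fit(Xi, y, family = binomial())),
    error = function(e) NULL
  )
  ok <- !is.null(fit) && fit$converged && all(is.finite(fit$coefficients)) &&
    (length(fit$coefficients) == 1 || max(abs(fit$coefficients[-1])) < 50)
  if (ok) {
    return(list(beta = fit$coefficients, method = "ml"))
  }
  list(beta = ridge_logistic(Xi, y, ridge_lambda), method = "ridge")
}

# IRLS with penalty lambda on all coefficients except the intercept.
ridge_logistic <- function(Xi, y, lambda, max_iter = 100, tol = 1e-10) {
  p <- ncol(Xi)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  beta[1] <- qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xi * w)
    beta_new <- solve(XtW %*% Xi + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

model_aic <- function(X, y) {
  fit <- logistic_fit(X, y)
  eta <- drop(cbind(1, X) %*% fit$beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  2 * (ncol(X) + 1) - 2 * ll
}

forward_select <- function(features, labels, spec, knots) {
  remaining <- spec$feature_names
  chosen <- character(0)
  block <- function(nms) {
    s <- spec; s$feature_names <- nms
    make_basis(features, s, knots = knots[nms])$X
  }
  # AIC of the intercept-only model
  ll0 <- {
    p0 <- mean(labels)
    sum(labels * log(p0) + (1 - labels) * log(1 - p0))
  }
  best_aic <- 2 - 2 * ll0
  repeat {
    if (!length(remaining)) break
    cand_aic <- vapply(remaining, function(nm) {
      model_aic(block(c(chosen, nm)), labels)
    }, numeric(1))
    j <- which.min(cand_aic)
    if (cand_aic[j] - best_aic < 0) {
      best_aic <- cand_aic[j]
      chosen <- c(chosen, remaining[j])
      remaining <- remaining[-j]
    } else break
  }
  if (!length(chosen)) chosen <- remaining[1]  # never return an empty model
  chosen
}

#' @export
print.fitted_risk_model <- function(x, ...) {
  cat(sprintf("<fitted_risk_model> %s: %s basis, horizon %g h, %d coefficients\n",
              x$spec$name, x$spec$basis, x$spec$horizon_hours,
              length(x$coefficients)))
  cat(sprintf("  fit: %s; train mean event probability %.4g\n",
              x$method, x$train_mean_p))
  invisible(x)
}

#' Relative-risk series from a fitted model
#'
#' The model's predicted event probability is divided by the mean
#' predicted probability on its development set, yielding the
#' fold-increase over the average ("relative risk", mean 1 on the
#' development set by construction).
#'
#' @param model A `"fitted_risk_model"`.
#' @param features Imputed feature tibble (must carry the model's
#'   features; `admission_id` and `window_end_min` are propagated when
#'   present).
#' @param cap Optional upper cap applied to the relative risk (default
#'   `Inf`: uncapped).
#' @return Tibble `admission_id`, `window_end_min`, `relative_risk`,
#'   `censored` (`FALSE`; censored epochs have no feature rows upstream).
#' @export
predict_relative_risk <- function(model, features, cap = Inf) {
  spec <- model$spec
  spec$feature_names <- model$selected
  basis <- make_basis(features, spec, knots = model$knots)
  p <- plogis(drop(cbind(1, basis$X) %*% model$coefficients))
  rr <- pmin(p / model$train_mean_p, cap)
  tibble::tibble(
    admission_id = if ("admission_id" %in% names(features)) {
      features$admission_id
    } else NA_character_,
    window_end_min = if ("window_end_min" %in% names(features)) {
      features$window_end_min
    } else NA_real_,
    relative_risk = rr,
    censored = FALSE
  )
}
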