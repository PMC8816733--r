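#' Fit a cosolvency model to a solubility dataset
#'
#' Single fitting interface over the three algebraic cosolvency models:
#'
#' * `"jouyban_acree"`: temperature-spanning model; intercept-free least
#'   squares of the ln-scale excess on the mixing-term regressors
#'   (see [ja_fit()]).
#' * `"wilson"`: isothermal two-constant local-composition model, fitted
#'   separately at each temperature present (see [wilson_fit()]).
#' * `"loglinear"`: log-linear (Yalkowsky) model; the solubilization power is
#'   either taken from the neat-solvent anchors (`sigma = "anchors"`,
#'   correlative) or from the solute's log P and the cosolvent `M`, `N`
#'   constants (`sigma = "logP"`, predictive).
#'
#' All three models reproduce the neat-solvent anchors exactly at
#' `f1 = 0` and `f1 = 1` by construction.
#'
#' @param data A [solubility_dataset()] (its `"primary_solute"` records are
#'   used) or a data frame with columns `f1`, `T`, `C` on a single
#'   concentration scale.
#' @param model Which cosolvency model to fit.
#' @param n_terms Number of Jouyban-Acree mixing coefficients (1--3).
#' @param sigma Source of the log-linear solubilization power.
#' @param logP,MN Solute log P and cosolvent constants for
#'   `sigma = "logP"`; default log P is read from the dataset metadata and
#'   `MN` defaults to the ethanol constants.
#' @return An object of classes `c("cosolv_<model>", "cosolv_fit")` with
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`
#'   and `simulate` methods.
#' @examples
#' fit <- cosolv_fit(asa_ethanol_water(), "jouyban_acree")
#' coef(fit)
#' summary(fit)
#' @export
cosolv_fit <- function(data, model = c("jouyban_acree", "wilson", "loglinear"),
                       n_terms = 3, sigma = c("anchors", "logP"),
                       logP = attr(data, "solute_logP"),
                       MN = ethanol_loglinear_constants()) {
  model <- match.arg(model)
  sigma <- match.arg(sigma)
  d <- .model_frame(data)
  anchors <- .ja_anchors(d$f1, d$T, d$C)
  params <- switch(model,
    jouyban_acree = ja_fit(d, n_terms = n_terms),
    wilson = {
      fits <- lapply(sort(unique(d$T)), function(tt)
        wilson_fit(d[d$T == tt, , drop = FALSE]))
      names(fits) <- as.character(sort(unique(d$T)))
      fits
    },
    loglinear = {
      if (sigma == "logP") {
        if (is.null(logP) || is.na(logP))
          stop("sigma = \"logP\" needs the solute log P")
        s <- loglinear_sigma_from_logP(logP, MN)
        setNames(rep(s, length(anchors)), names(anchors))
      } else {
        vapply(anchors, function(a) loglinear_sigma(a[["C1"]], a[["C2"]]), numeric(1))
      }
    })
  obj <- structure(list(model = model, params = params, anchors = anchors,
                        data = d, sigma_source = if (model == "loglinear") sigma,
                        call = match.call()),
                   class = c(paste0("cosolv_", model), "cosolv_fit"))
  obj$fitted <- predict(obj)
  obj
}

#' @export
coef.cosolv_fit <- function(object, ...) {
  switch(object$model,
    jouyban_acree = object$params$J,
    wilson = {
      unlist(lapply(names(object$params), function(tt)
        setNames(c(object$params[[tt]]$lambda12, object$params[[tt]]$lambda21),
                 paste0(c("lambda12_", "lambda21_"), tt, "K"))))
    },
    loglinear = setNames(as.numeric(object$params),
                         paste0("sigma_", names(object$params), "K")))
}

#' Predict solubilities from a fitted cosolvency model
#'
#' @param object A [cosolv_fit()] object.
#' @param newdata Data frame with columns `f1` and `T`; defaults to the
#'   training grid. Temperatures must be ones the fit carries anchors for
#'   (the models interpolate in composition, not temperature).
#' @param ... Unused.
#' @return Numeric vector of predicted solubilities on the training scale.
#' @export
predict.cosolv_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  f1 <- newdata$f1
  T <- newdata$T
  an <- .anchor_lookup(object$anchors, T)
  switch(object$model,
    jouyban_acree = ja_predict(object$params, an[, "C1"], an[, "C2"], f1, T),
    wilson = {
      out <- numeric(length(f1))
      for (tt in unique(T)) {
        p <- object$params[[as.character(tt)]]
        if (is.null(p)) stop("no Wilson fit at T = ", tt, " K")
        i <- T == tt
        out[i] <- wilson_predict(p$lambda12, p$lambda21,
                                 an[i, "C1"][1], an[i, "C2"][1], f1[i])
      }
      out
    },
    stop("unknown model: ", object$model))
}

#' @export
predict.cosolv_loglinear <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  an <- .anchor_lookup(object$anchors, newdata$T)
  s <- as.numeric(object$params[as.character(newdata$T)])
  if (anyNA(s)) stop("no fitted sigma for requested temperature(s)")
  exp(log(an[, "C2"]) + s * newdata$f1)
}

#' @export
fitted.cosolv_fit <- function(object, ...) object$fitted

#' Residuals of a cosolvency fit
#'
#' @param object A [cosolv_fit()] object.
#' @param type `"ln"` (default; the scale the models are fitted on) or
#'   `"response"`.
#' @param ... Unused.
#' @export
residuals.cosolv_fit <- function(object, type = c("ln", "response"), ...) {
  type <- match.arg(type)
  if (type == "ln") log(object$data$C) - log(object$fitted)
  else object$data$C - object$fitted
}

#' @export
print.cosolv_fit <- function(x, ...) {
  label <- c(jouyban_acree = "Jouyban-Acree", wilson = "modified Wilson",
             loglinear = "log-linear (Yalkowsky)")[[x$model]]
  cat(sprintf("Cosolvency fit: %s model, %d points, T = %s K\n", label,
              nrow(x$data), paste(names(x$anchors), collapse = ", ")))
  if (x$model == "loglinear")
    cat(sprintf("  sigma source: %s\n", x$sigma_source))
  print(round(coef(x), 4))
  invisible(x)
}

#' Summarize a cosolvency fit
#'
#' Reports the coefficients and mean relative deviations (per temperature,
#' pooled over points and averaged over temperatures) of the back-calculated
#' solubilities.
#'
#' @param object A [cosolv_fit()] object.
#' @param ... Unused.
#' @return An object of class `summary.cosolv_fit`.
#' @export
summary.cosolv_fit <- function(object, ...) {
  rep_ <- evaluate_predictions(object$fitted, object$data$C,
                               f1 = object$data$f1, T = object$data$T,
                               model = object$model)
  structure(list(fit = object, report = rep_), class = "summary.cosolv_fit")
}

#' @export
print.summary.cosolv_fit <- function(x, ...) {
  print(x$fit)
  print(x$report)
  invisible(x)
}

#' Plot observed and back-calculated solubility profiles
#'
#' Observed points and model curves versus cosolvent fraction, one colour per
#' temperature, log-scaled concentration axis.
#'
#' @param x A [cosolv_fit()] object.
#' @param npoints Curve resolution.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.cosolv_fit <- function(x, npoints = 101, ...) {
  d <- x$data
  Ts <- sort(unique(d$T))
  cols <- setNames(seq_along(Ts) + 1, Ts)
  plot(d$f1, d$C, log = "y", pch = 19, col = cols[as.character(d$T)],
       xlab = "cosolvent volume fraction f1", ylab = "solubility",
       main = paste("cosolvency fit:", x$model), ...)
  for (tt in Ts) {
    grid <- data.frame(f1 = seq(0, 1, length.out = npoints), T = tt)
    lines(grid$f1, predict(x, grid), col = cols[as.character(tt)])
  }
  legend("bottomright", legend = paste(Ts, "K"), col = cols, pch = 19, lty = 1)
  invisible(x)
}

#' Simulate datasets from a fitted cosolvency model
#'
#' Draws replicate synthetic datasets with the fitted model as the truth and
#' multiplicative (ln-scale Gaussian) measurement noise, mirroring the
#' design of the training data.
#'
#' @param object A [cosolv_fit()] object.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed (RNG state is restored afterwards).
#' @param noise_sd Noise standard deviation on `ln C`.
#' @param ... Unused.
#' @return A list of `nsim` [solubility_dataset()] objects.
#' @export
simulate.cosolv_fit <- function(object, nsim = 1, seed = 1, noise_sd = 0.05, ...) {
  lapply(seq_len(nsim), function(k)
    simulate_solubility_dataset(
      truth = object, f1 = sort(unique(object$data$f1)),
      T = sort(unique(object$data$T)),
      noise_sd = noise_sd, seed = seed + k - 1L))
}
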