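#' Multistart nonlinear least squares
#'
#' Minimises the residual sum of squares of a nonlinear model by
#' Levenberg-Marquardt from each of several start vectors and keeps the
#' best converged solution (lowest SSR). Parameter covariance is the
#' asymptotic `sigma^2 (J'J)^-1` with `sigma^2 = SSR / (N - p)`;
#' standard errors are the square roots of its diagonal and are `NA`
#' (flagged, not an error) when `N <= p`. If no start converges, the best
#' attempt is returned with `converged = FALSE`.
#'
#' @param formula Model formula, e.g. `y ~ eps * exp(-n / tau) + omega`.
#' @param data Data frame holding the variables in `formula`.
#' @param starts List of named numeric start vectors (one per start).
#' @return A list with `params`, `se`, `ssr`, `sigma2`, `r_squared`,
#'   `adj_r_squared`, `n_points`, `n_params`, `converged`.
#' @export
nls_multistart <- function(formula, data, starts) {
  stopifnot(length(starts) >= 1L)
  n_params <- length(starts[[1L]])
  if (nrow(data) < n_params + 1L) {
    warn("Fewer points than parameters + 1; fit is weakly determined.")
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                     ptol = 1e-15)
  attempts <- lapply(starts, function(st) {
    tryCatch({
      fit <- suppressWarnings(
        minpack.lm::nlsLM(formula, data = data, start = as.list(st),
                          control = ctrl)
      )
      list(fit = fit, ssr = sum(stats::resid(fit)^2), converged = fit$convInfo$isConv)
    }, error = function(e) NULL)
  })
  attempts <- Filter(Negate(is.null), attempts)
  if (length(attempts) == 0L) {
    return(list(params = starts[[1L]], se = setNames(rep(NA_real_, n_params),
                                                     names(starts[[1L]])),
                ssr = NA_real_, sigma2 = NA_real_, r_squared = NA_real_,
                adj_r_squared = NA_real_, n_points = nrow(data),
                n_params = n_params, converged = FALSE))
  }
  conv <- vapply(attempts, `[[`, logical(1), "converged")
  ssrs <- vapply(attempts, `[[`, numeric(1), "ssr")
  pick <- if (any(conv)) which(conv)[which.min(ssrs[conv])] else which.min(ssrs)
  best <- attempts[[pick]]

  params <- coef(best$fit)
  N <- nrow(data); p <- n_params
  se <- setNames(rep(NA_real_, p), names(params))
  sigma2 <- NA_real_
  if (N > p) {
    sigma2 <- best$ssr / (N - p)
    v <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
    if (!is.null(v)) se <- sqrt(pmax(diag(v), 0))
  }
  response <- eval(formula[[2L]], data)
  gof <- goodness_of_fit(response, stats::fitted(best$fit), p)
  c(list(params = params, se = se, ssr = best$ssr, sigma2 = sigma2,
         n_points = N, n_params = p, converged = best$converged && any(conv)),
    gof)
}

#' Coefficient of determination for a nonlinear fit
#'
#' `R^2 = 1 - SSR / SST` with SST about the mean of the observations, and
#' `adjusted R^2 = 1 - (1 - R^2)(N - 1)/(N - p)`. A constant response
#' (SST = 0) yields `NA` (flagged, not an error); negative values are
#' legitimate and reported as-is.
#'
#' @param observed Observed response values.
#' @param fitted Fitted model values.
#' @param n_params Number of fitted parameters `p`.
#' @return A list with `r_squared` and `adj_r_squared`.
#' @export
goodness_of_fit <- function(observed, fitted, n_params) {
  N <- length(observed)
  sst <- sum((observed - mean(observed))^2)
  ssr <- sum((observed - fitted)^2)
  if (sst == 0) return(list(r_squared = NA_real_, adj_r_squared = NA_real_))
  r2 <- 1 - ssr / sst
  adj <- if (N > n_params) 1 - (1 - r2) * (N - 1) / (N - n_params) else NA_real_
  list(r_squared = r2, adj_r_squared = adj)
}

new_decay_fit <- function(res, model, asymptote_name, start_n, points) {
  structure(
    list(
      model = model,
      epsilon = unname(res$params[["eps"]]),
      tau = unname(res$params[["tau"]]),
      asymptote = unname(res$params[["asym"]]),
      asymptote_name = asymptote_name,
      se_epsilon = unname(res$se[["eps"]]),
      se_tau = unname(res$se[["tau"]]),
      se_asymptote = unname(res$se[["asym"]]),
      r_squared = res$r_squared,
      adj_r_squared = res$adj_r_squared,
      ssr = res$ssr,
      n_points = res$n_points,
      n_params = res$n_params,
      converged = res$converged,
      start_n = start_n,
      points = points
    ),
    class = "decay_fit"
  )
}

decay_starts <- function(points) {
  eps0 <- points$median[1L] - points$median[nrow(points)]
  asym0 <- points$median[nrow(points)]
  lapply(c(0.5, 1, 2, 4, 8), function(tau0) {
    c(eps = eps0, tau = tau0, asym = asym0)
  })
}

#' Fit the exponential-decay core-genome model
#'
#' Fits `F(n) = eps * exp(-n / tau) + asym` to the median core-gene curve
#' by multistart Levenberg-Marquardt least squares. The asymptote is the
#' extrapolated core-genome size as the number of sampled genomes grows
#' (commonly written Omega); `tau` is the decay constant in units of
#' genomes. Starts sweep `tau` over 0.5-8 with `eps0` the first-to-last
#' median drop and the asymptote started at the last median.
#'
#' @param curve Curve tibble from [summarize_curve()] (the `kind ==
#'   "core"` rows are used), or any tibble with columns `n`, `median`.
#' @param start_n First `n` included in the fit (core default 1).
#' @return A `decay_fit` object; see [tidy.decay_fit()] /
#'   [glance.decay_fit()].
#' @export
fit_core_decay <- function(curve, start_n = 1L) {
  pts <- decay_points(curve, "core", start_n)
  res <- nls_multistart(median ~ eps * exp(-n / tau) + asym, pts,
                        decay_starts(pts))
  fit <- new_decay_fit(res, "core_decay", "omega", start_n, pts)
  if (isTRUE(fit$asymptote < 0)) {
    warn("Fitted core-genome asymptote is negative; reported unclamped.")
  }
  fit
}

#' Fit the exponential-decay new-gene model
#'
#' Same model family as [fit_core_decay()] applied to the median
#' new-gene curve; the asymptote is the long-run rate of new-gene
#' discovery per added genome (commonly written tg(theta)). A strictly
#' positive asymptote indicates genomes keep contributing novel genes no
#' matter how many are sequenced.
#'
#' @inheritParams fit_core_decay
#' @param start_n First `n` included (default 2: the `n = 1` point is the
#'   whole genome and is usually excluded).
#' @return A `decay_fit` object.
#' @export
fit_new_decay <- function(curve, start_n = 2L) {
  pts <- decay_points(curve, "new", start_n)
  res <- nls_multistart(median ~ eps * exp(-n / tau) + asym, pts,
                        decay_starts(pts))
  fit <- new_decay_fit(res, "new_decay", "tg_theta", start_n, pts)
  if (isTRUE(fit$asymptote < 0)) {
    warn("Fitted new-gene asymptote is negative; reported unclamped.")
  }
  fit
}

decay_points <- function(curve, kind, start_n) {
  pts <- as_tibble(curve)
  if ("kind" %in% names(pts)) pts <- dplyr::filter(pts, .data$kind == !!kind)
  if (!all(c("n", "median") %in% names(pts))) {
    abort("`curve` needs columns n and median (see summarize_curve()).")
  }
  pts <- pts |> dplyr::filter(.data$n >= start_n) |> arrange(.data$n)
  if (nrow(pts) < 4L) {
    warn(sprintf("Only %d points at n >= %d; decay fit is weakly determined.",
                 nrow(pts), start_n))
  }
  pts[c("n", "median")]
}

#' Fit the Heaps power law and call the pan-genome open or closed
#'
#' Fits `P_s(n) = kappa * n^-alpha` to the median new-gene curve by
#' nonlinear least squares (not log-log regression). The exponent decides
#' the verdict: `alpha <= 1` means new-gene discovery decays slowly
#' enough that the pan-genome is open (unbounded); `alpha > 1` means it
#' is closed. Zero medians cannot lie on a power law and are excluded
#' with a warning.
#'
#' @inheritParams fit_new_decay
#' @return A `heaps_fit` object with fields `kappa`, `alpha`, standard
#'   errors, `r_squared`, `verdict`, `low_confidence`.
#' @export
fit_heaps <- function(curve, start_n = 2L) {
  pts <- as_tibble(curve)
  if ("kind" %in% names(pts)) pts <- dplyr::filter(pts, .data$kind == "new")
  pts <- pts |> dplyr::filter(.data$n >= start_n) |> arrange(.data$n)
  n_zero <- sum(pts$median <= 0)
  if (n_zero > 0L) {
    warn(sprintf("%d non-positive medians excluded from the power-law fit.",
                 n_zero))
    pts <- dplyr::filter(pts, .data$median > 0)
  }
  low_confidence <- nrow(pts) < 4L
  if (low_confidence) {
    warn("Fewer than 4 positive points; power-law fit is low-confidence.")
  }
  if (nrow(pts) < 2L) {
    return(structure(list(kappa = NA_real_, alpha = NA_real_,
                          se_kappa = NA_real_, se_alpha = NA_real_,
                          r_squared = NA_real_, adj_r_squared = NA_real_,
                          n_points = nrow(pts), converged = FALSE,
                          verdict = NA_character_, low_confidence = TRUE,
                          start_n = start_n, points = pts[c("n", "median")]),
                     class = "heaps_fit"))
  }
  # log-log regression supplies the primary start; fixed fallbacks guard it
  ll <- stats::lm(log(median) ~ log(n), data = pts)
  starts <- c(
    list(c(kappa = exp(unname(coef(ll)[1L])), alpha = -unname(coef(ll)[2L]))),
    lapply(c(0.5, 1, 2, 5), function(a) {
      c(kappa = pts$median[1L] * pts$n[1L]^a, alpha = a)
    })
  )
  res <- nls_multistart(median ~ kappa * n^-alpha, pts[c("n", "median")],
                        starts)
  alpha <- unname(res$params[["alpha"]])
  structure(
    list(kappa = unname(res$params[["kappa"]]), alpha = alpha,
         se_kappa = unname(res$se[["kappa"]]), se_alpha = unname(res$se[["alpha"]]),
         r_squared = res$r_squared, adj_r_squared = res$adj_r_squared,
         n_points = res$n_points, converged = res$converged,
         verdict = if (is.na(alpha)) NA_character_
                   else if (alpha > 1) "closed" else "open",
         low_confidence = low_confidence, start_n = start_n,
         points = pts[c("n", "median")]),
    class = "heaps_fit"
  )
}

#' Model predictions from fitted rarefaction models
#' @param object A `decay_fit` or `heaps_fit`.
#' @param n Strain counts to predict at.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.decay_fit <- function(object, n, ...) {
  object$epsilon * exp(-n / object$tau) + object$asymptote
}

#' @rdname predict.decay_fit
#' @export
predict.heaps_fit <- function(object, n, ...) {
  object$kappa * n^-object$alpha
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit: %s> F(n) = eps * exp(-n/tau) + %s\n",
              x$model, x$asymptote_name))
  cat(sprintf("  eps = %.4g +/- %.3g | tau = %.4g +/- %.3g | %s = %.4g +/- %.3g\n",
              x$epsilon, x$se_epsilon, x$tau, x$se_tau,
              x$asymptote_name, x$asymptote, x$se_asymptote))
  cat(sprintf("  n = %d points (n >= %d) | R2 = %.5f | adj R2 = %.5f | converged: %s\n",
              x$n_points, x$start_n, x$r_squared, x$adj_r_squared, x$converged))
  invisible(x)
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat("<heaps_fit> P_s(n) = kappa * n^-alpha\n")
  cat(sprintf("  kappa = %.4g +/- %.3g | alpha = %.4g +/- %.3g\n",
              x$kappa, x$se_kappa, x$alpha, x$se_alpha))
  cat(sprintf("  R2 = %.5f | verdict: %s pan-genome%s\n",
              x$r_squared, x$verdict,
              if (isTRUE(x$low_confidence)) " (low confidence)" else ""))
  invisible(x)
}
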