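# Hill-equation dose-response fitting and cooperativity comparison.

#' Hill curve
#'
#' `R(c) = bottom + (top - bottom) * c^n / (c^n + ec50^n)`, evaluated in a
#' numerically stable logistic form.
#'
#' @param concentration positive concentrations.
#' @param ec50 half-maximal concentration (> 0).
#' @param n Hill coefficient.
#' @param top,bottom plateaus (`bottom` at zero dose for this increasing
#'   form).
#' @return Response vector.
#' @export
hill_curve <- function(concentration, ec50, n, top = 1, bottom = 0) {
  frac <- stats::plogis(n * (log(concentration) - log(ec50)))
  bottom + (top - bottom) * frac
}

#' Fit the Hill equation to a dose-response table
#'
#' Least-squares fit of the four-parameter Hill model. The optimization runs
#' on `(log10 EC50, log n)` only: for every candidate `(EC50, n)` the two
#' plateaus are profiled out by linear least squares, which makes the search
#' two-dimensional and the noiseless round-trip essentially exact. Five
#' log-spaced EC50 starting points (Hill coefficient starting at 1) guard
#' against local minima.
#'
#' For `direction = "decreasing"` the roles of the plateaus are swapped:
#' `top` is the response at zero dose and `bottom` the high-dose plateau, so
#' `bottom <= top` always refers to response values.
#'
#' @param data a [gen_dose_response()] table or any data.frame with columns
#'   `concentration` and `response` (replicates as repeated rows).
#' @param direction `"increasing"`, `"decreasing"`, or `"auto"` (default:
#'   inferred from the correlation between log concentration and response).
#' @param constraints list with optional fixed `top` and/or `bottom` values,
#'   e.g. `list(bottom = 0, top = 1)` for fraction data.
#' @param n_bounds allowed Hill-coefficient range (default `[0.1, 10]`).
#' @param ec50_span EC50 bounds as multiples of the concentration range
#'   (default `[min(c)/100, max(c)*100]`).
#' @return Object of class `hill_fit` with elements `ec50`, `hill_n`, `top`,
#'   `bottom`, `direction`, `rss`, `converged`, `stderr` (named vector over
#'   free parameters), `n_obs`, `data`.
#' @export
fit_hill <- function(data, direction = c("auto", "increasing", "decreasing"),
                     constraints = list(), n_bounds = c(0.1, 10),
                     ec50_span = c(1 / 100, 100)) {
  direction <- match.arg(direction)
  d <- as.data.frame(data)
  if (!all(c("concentration", "response") %in% names(d)))
    stop("data needs columns 'concentration' and 'response'")
  conc <- d$concentration; resp <- d$response
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (any(!is.finite(resp))) stop("responses must be finite")
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations")
  span <- diff(range(resp))
  if (span <= 0.05 * max(abs(resp), .Machine$double.eps))
    stop("unidentifiable EC50: responses do not leave the plateau")
  if (direction == "auto") {
    direction <- if (cor(log(conc), resp) >= 0) "increasing" else "decreasing"
  }
  lc <- log(conc)
  top_fix <- constraints$top
  bottom_fix <- constraints$bottom

  # profiled plateaus for a given (log10 ec50, log n)
  profile_fit <- function(par) {
    u <- stats::plogis(exp(par[2]) * (lc - log(10^par[1])))
    if (direction == "decreasing") u <- 1 - u
    if (is.null(top_fix) && is.null(bottom_fix)) {
      um <- mean(u); rm_ <- mean(resp)
      suu <- sum((u - um)^2)
      b <- if (suu > 0) sum((u - um) * (resp - rm_)) / suu else 0
      a <- rm_ - b * um
      bottom <- a; top <- a + b
    } else if (!is.null(bottom_fix) && is.null(top_fix)) {
      b <- sum((resp - bottom_fix) * u) / max(sum(u^2), .Machine$double.eps)
      bottom <- bottom_fix; top <- bottom_fix + b
    } else if (is.null(bottom_fix) && !is.null(top_fix)) {
      v <- 1 - u
      b <- sum((top_fix - resp) * v) / max(sum(v^2), .Machine$double.eps)
      top <- top_fix; bottom <- top_fix - b
    } else {
      top <- top_fix; bottom <- bottom_fix
    }
    pred <- bottom + (top - bottom) * u
    list(rss = sum((resp - pred)^2), top = top, bottom = bottom)
  }
  obj <- function(par) profile_fit(par)$rss

  lo <- c(log10(min(conc) * ec50_span[1]), log(n_bounds[1]))
  hi <- c(log10(max(conc) * ec50_span[2]), log(n_bounds[2]))
  starts <- log10(exp(seq(log(min(conc)), log(max(conc)), length.out = 5)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(c(s, log(1)), obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(factr = 1e1, pgtol = 1e-14, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("Hill fit failed from every start")
  # polish: a derivative-free pass shrinks the last ~1e-6 of parameter error
  best2 <- optim(best$par, obj, method = "Nelder-Mead",
                 control = list(abstol = 0, reltol = 1e-15, maxit = 2000))
  best2$par <- pmin(pmax(best2$par, lo), hi)
  if (obj(best2$par) <= best$value) {
    best2$value <- obj(best2$par)
    best2$convergence <- best$convergence
    best <- best2
  }

  prof <- profile_fit(best$par)
  ec50 <- 10^best$par[1]; hill_n <- exp(best$par[2])
  free <- c(ec50 = TRUE, hill_n = TRUE,
            top = is.null(top_fix), bottom = is.null(bottom_fix))
  se <- hill_stderr(conc, resp, ec50, hill_n, prof$top, prof$bottom,
                    direction, free, prof$rss)
  structure(list(ec50 = ec50, hill_n = hill_n, top = prof$top,
                 bottom = prof$bottom, direction = direction,
                 rss = prof$rss, converged = best$convergence == 0,
                 stderr = se, n_obs = length(resp), data = d),
            class = "hill_fit")
}

# Asymptotic standard errors from the Jacobian at the optimum.
hill_stderr <- function(conc, resp, ec50, n, top, bottom, direction, free,
                        rss) {
  predfun <- function(p) {
    u <- stats::plogis(p["hill_n"] * (log(conc) - log(p["ec50"])))
    if (direction == "decreasing") u <- 1 - u
    p["bottom"] + (p["top"] - p["bottom"]) * u
  }
  p0 <- c(ec50 = ec50, hill_n = n, top = top, bottom = bottom)
  names_free <- names(free)[free]
  J <- sapply(names_free, function(nm) {
    h <- max(abs(p0[nm]) * 1e-6, 1e-10)
    pp <- p0; pp[nm] <- pp[nm] + h
    pm <- p0; pm[nm] <- pm[nm] - h
    (predfun(pp) - predfun(pm)) / (2 * h)
  })
  J <- matrix(J, ncol = length(names_free),
              dimnames = list(NULL, names_free))
  dof <- length(resp) - length(names_free)
  if (dof <= 0) return(setNames(rep(NA_real_, length(names_free)), names_free))
  s2 <- rss / dof
  V <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(V)) return(setNames(rep(NA_real_, length(names_free)), names_free))
  sqrt(pmax(diag(V), 0))
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s): EC50 = %.4g, n = %.3f, top = %.4g, bottom = %.4g\n",
              x$direction, x$ec50, x$hill_n, x$top, x$bottom))
  cat(sprintf("  RSS = %.4g over %d observations; converged: %s\n",
              x$rss, x$n_obs, x$converged))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, concentration, ...) {
  u <- stats::plogis(object$hill_n * (log(concentration) - log(object$ec50)))
  if (object$direction == "decreasing") u <- 1 - u
  object$bottom + (object$top - object$bottom) * u
}

#' Compare binding and killing dose-response fits
#'
#' Summarizes the hallmark of threshold-driven permeabilization: binding is
#' non-cooperative (Hill coefficient near 1) while killing is steeply
#' cooperative. Curves with `n <= 1.5` are classified non-cooperative and
#' `n >= 2` cooperative (in between: `"intermediate"`).
#'
#' @param binding,killing converged [fit_hill()] objects.
#' @return Object of class `cooperativity_report`: `ec50_ratio`
#'   (killing/binding), `hill_n_ratio`, `binding_class`, `killing_class`.
#' @export
compare_binding_killing <- function(binding, killing) {
  stopifnot(inherits(binding, "hill_fit"), inherits(killing, "hill_fit"))
  if (!binding$converged || !killing$converged)
    stop("both fits must have converged")
  classify <- function(n)
    if (n <= 1.5) "non-cooperative" else if (n >= 2) "cooperative" else
      "intermediate"
  structure(list(ec50_ratio = killing$ec50 / binding$ec50,
                 hill_n_ratio = killing$hill_n / binding$hill_n,
                 binding_class = classify(binding$hill_n),
                 killing_class = classify(killing$hill_n),
                 binding_n = binding$hill_n, killing_n = killing$hill_n),
            class = "cooperativity_report")
}

#' @export
print.cooperativity_report <- function(x, ...) {
  cat(sprintf("binding n = %.2f (%s), killing n = %.2f (%s)\n",
              x$binding_n, x$binding_class, x$killing_n, x$killing_class))
  cat(sprintf("  EC50 ratio (killing/binding) = %.3f, Hill ratio = %.3f\n",
              x$ec50_ratio, x$hill_n_ratio))
  invisible(x)
}

#' IC50 from a dual-wavelength viability plate
#'
#' Converts raw WST-1-style absorbances to viability fractions (signal
#' `A450 - A620` per well, normalized by the mean signal of untreated
#' control wells) and fits a decreasing Hill curve. Control wells with
#' non-positive signal (e.g. `A620 > A450`) are flagged and excluded.
#'
#' @param plate data.frame with columns `concentration` (0 or `NA` marks
#'   control wells), `a450`, `a620`.
#' @param ... passed to [fit_hill()].
#' @return List with `table` (the viability `dose_response_table`), `fit`
#'   (a `hill_fit`; the fitted EC50 is the IC50), and `excluded_wells`
#'   (row indices).
#' @export
ic50_from_viability <- function(plate, ...) {
  d <- as.data.frame(plate)
  if (!all(c("concentration", "a450", "a620") %in% names(d)))
    stop("plate needs columns concentration, a450, a620")
  signal <- d$a450 - d$a620
  is_control <- is.na(d$concentration) | d$concentration == 0
  if (!any(is_control)) stop("no control wells present")
  bad_control <- is_control & signal <= 0
  excluded <- which(bad_control)
  if (length(excluded))
    warning(sprintf("%d control well(s) with non-positive signal excluded",
                    length(excluded)))
  ctrl <- mean(signal[is_control & !bad_control])
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("non-positive control mean signal")
  treated <- !is_control
  tab <- data.frame(concentration = d$concentration[treated],
                    response = signal[treated] / ctrl,
                    replicate = stats::ave(seq_len(sum(treated)),
                                           d$concentration[treated],
                                           FUN = seq_along),
                    kind = "viability")
  class(tab) <- c("dose_response_table", "data.frame")
  fit <- fit_hill(tab, direction = "decreasing", ...)
  list(table = tab, fit = fit, excluded_wells = excluded)
}
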