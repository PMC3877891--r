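# Membrane-probe readouts: steady-state fluorescence anisotropy (TMA-DPH)
# and Laurdan generalized polarization.

#' Steady-state fluorescence anisotropy (l-format)
#'
#' Computes `(Ivv - G*Ivh) / (Ivv + 2*G*Ivh)`, where `Ivv` and `Ivh` are the
#' vertically and horizontally polarized emission components under vertical
#' excitation and `G` corrects for the polarization-dependent detection
#' sensitivity. The theoretical range is `(-0.5, 1]`; for membrane probes it
#' increases with membrane viscosity.
#'
#' @param i_vv,i_vh non-negative intensities (a.u.); vectorized.
#' @param g_factor detection-sensitivity correction G (> 0).
#' @return Anisotropy value(s).
#' @export
anisotropy <- function(i_vv, i_vh, g_factor = 1) {
  if (any(i_vv < 0) || any(i_vh < 0)) stop("intensities must be >= 0")
  if (any(g_factor <= 0)) stop("'g_factor' must be > 0")
  denom <- i_vv + 2 * g_factor * i_vh
  if (any(denom <= 0)) stop("zero total intensity")
  (i_vv - g_factor * i_vh) / denom
}

#' Laurdan generalized polarization
#'
#' `GP = (Iblue - Ired) / (Iblue + Ired)` with the blue edge detected at
#' 435 nm and the red edge at 500 nm; bounded in `[-1, 1]` and increasing
#' with membrane order (decreasing hydration).
#'
#' @param i_blue,i_red non-negative intensities (a.u.); vectorized.
#' @return GP value(s).
#' @export
generalized_polarization <- function(i_blue, i_red) {
  if (any(i_blue < 0) || any(i_red < 0)) stop("intensities must be >= 0")
  total <- i_blue + i_red
  if (any(total <= 0)) stop("zero total intensity")
  (i_blue - i_red) / total
}

#' Summarize probe readouts by condition
#'
#' Computes the per-record readout (anisotropy or GP) and per-condition
#' mean, standard error of the mean and n. With exactly two conditions the
#' difference of means is tested with Welch's two-sample t-test (delegated
#' to [stats::t.test()]).
#'
#' @param records data.frame with a `condition` column and either
#'   (`i_vv`, `i_vh`, optionally `g_factor`) for anisotropy,
#'   (`i_blue`, `i_red`) for GP, or a precomputed `value` column.
#' @param measure `"anisotropy"`, `"gp"` or `"value"` (default: inferred
#'   from the columns present).
#' @return List of class `condition_summary`: `summary` (data.frame with
#'   condition, mean, sem, n), and for two conditions `difference`,
#'   `p_value`.
#' @export
compare_conditions <- function(records,
                               measure = c("auto", "anisotropy", "gp",
                                           "value")) {
  measure <- match.arg(measure)
  d <- as.data.frame(records)
  if (!"condition" %in% names(d)) stop("records need a 'condition' column")
  if (measure == "auto") {
    measure <- if (all(c("i_vv", "i_vh") %in% names(d))) "anisotropy"
    else if (all(c("i_blue", "i_red") %in% names(d))) "gp"
    else if ("value" %in% names(d)) "value"
    else stop("cannot infer the measure from the columns present")
  }
  val <- switch(measure,
    anisotropy = anisotropy(d$i_vv, d$i_vh, d$g_factor %||% 1),
    gp = generalized_polarization(d$i_blue, d$i_red),
    value = d$value)
  cond <- as.character(d$condition)
  counts <- table(cond)
  if (any(counts < 2))
    stop("every condition needs at least 2 records")
  agg <- data.frame(condition = names(counts),
                    mean = as.numeric(tapply(val, cond, mean)),
                    sem = as.numeric(tapply(val, cond, function(v)
                      sd(v) / sqrt(length(v)))),
                    n = as.integer(counts))
  out <- list(summary = agg, measure = measure)
  if (nrow(agg) == 2) {
    tt <- t.test(val[cond == agg$condition[1]],
                 val[cond == agg$condition[2]])
    out$difference <- agg$mean[1] - agg$mean[2]
    out$p_value <- tt$p.value
  }
  structure(out, class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("%s by condition:\n", x$measure))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$difference))
    cat(sprintf("  difference %.4g (Welch p = %.3g)\n", x$difference,
                x$p_value))
  invisible(x)
}
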