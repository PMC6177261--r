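## Quadratic equilibrium binding isotherm for titrations of a labelled DNA
## at fixed concentration D with total protein P:
##   F = b0 + (bM - b0) * [D + P + 1/KA - sqrt((D + P + 1/KA)^2 - 4 P D)] / (2 D)
## The bracket is the exact bound fraction from mass action without the
## free-ligand approximation; the discriminant is floored at zero against
## round-off near stoichiometric binding.

#' Evaluate the quadratic binding isotherm
#'
#' @param P Total protein concentration(s), molar (>= 0).
#' @param D Labelled-DNA concentration, molar (> 0), scalar.
#' @param KA Association constant, 1/molar (> 0).
#' @param b0 Baseline response.
#' @param bM Maximum (saturating) response.
#' @return Response(s) F at each P.
#' @export
eval_isotherm <- function(P, D, KA, b0 = 0, bM = 1) {
  stopifnot(D > 0, KA > 0, all(P >= 0))
  s <- D + P + 1 / KA
  disc <- pmax(s^2 - 4 * P * D, 0)
  b0 + (bM - b0) * (s - sqrt(disc)) / (2 * D)
}

#' Build a titration series
#'
#' @param P Vector of total protein concentrations (molar, strictly
#'   increasing, >= 0).
#' @param F_obs Vector of bound-fraction responses.
#' @param D Labelled-DNA concentration (molar, > 0).
#' @param motif Optional motif label (e.g. `"BM TAATCC"`).
#' @param replicate Optional replicate id vector (same length as `P`).
#' @return Data frame of class `titration_series`.
#' @export
titration_series <- function(P, F_obs, D, motif = NA_character_,
                             replicate = NULL) {
  stopifnot(D > 0, all(P >= 0), all(is.finite(F_obs)),
            length(P) == length(F_obs))
  if (is.null(replicate)) {
    if (is.unsorted(P, strictly = TRUE))
      stop("protein concentrations must be strictly increasing")
  }
  out <- data.frame(P = P, F_obs = F_obs,
                    replicate = if (is.null(replicate)) 1L else replicate)
  structure(out, D = D, motif = motif,
            class = c("titration_series", "data.frame"))
}

#' Fit the quadratic binding isotherm to a titration
#'
#' Nonlinear least squares for `(b0, bM, KA)`, with `KA` parameterised on
#' the log10 scale to enforce positivity and condition the fit. Standard
#' errors come from the Jacobian at the optimum (delta method for `KA` and
#' `Kd = 1/KA`). Initial `KA` is taken from the protein concentration at
#' the half-maximal response unless supplied.
#'
#' @param data A `titration_series` (>= 5 points spanning the transition).
#' @param init Optional named list with any of `b0`, `bM`, `KA`.
#' @return Object of class `quadratic_binding_fit`: estimates `b0`, `bM`,
#'   `KA`, derived `Kd = 1/KA`, standard errors, `rss`, and the fit object.
#' @export
fit_quadratic_isotherm <- function(data, init = NULL) {
  stopifnot(inherits(data, "titration_series"))
  D <- attr(data, "D")
  if (nrow(data) < 5L) stop("need at least 5 titration points")
  P <- data$P; Fo <- data$F_obs
  b0_0 <- init$b0 %||% min(Fo)
  bM_0 <- init$bM %||% max(Fo)
  KA_0 <- init$KA %||% {
    half <- (b0_0 + bM_0) / 2
    Ph <- P[which.min(abs(Fo - half))]
    1 / max(Ph, D / 10, 1e-12)
  }
  rng <- bM_0 - b0_0
  span <- (max(Fo) - min(Fo)) / max(abs(rng), 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      F_obs ~ eval_isotherm(P, D, 10^lKA, b0, bM),
      data = data.frame(P = P, F_obs = Fo),
      start = list(b0 = b0_0, bM = bM_0, lKA = log10(KA_0)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ## degenerate data (e.g. no visible transition): report the starting
    ## values rather than failing, with the poor-constraint warning
    warning("poorly constrained KA: titration does not span the ",
            "transition")
    return(structure(list(
      b0 = b0_0, bM = bM_0, KA = KA_0, Kd = 1 / KA_0,
      se = c(b0 = NA_real_, bM = NA_real_, KA = NA_real_,
             Kd = NA_real_),
      rss = sum((Fo - eval_isotherm(P, D, KA_0, b0_0, bM_0))^2),
      D = D, motif = attr(data, "motif"), n = nrow(data), fit = NULL
    ), class = "quadratic_binding_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  KA <- 10^cf[["lKA"]]
  KA_se <- KA * log(10) * se[["lKA"]]
  ## poorly constrained when the fitted curve never leaves the baselines
  pred <- eval_isotherm(P, D, KA, cf[["b0"]], cf[["bM"]])
  frac <- (pred - cf[["b0"]]) / (cf[["bM"]] - cf[["b0"]])
  if (all(frac < 0.05) || all(frac > 0.95))
    warning("poorly constrained KA: titration does not span the transition")
  structure(list(
    b0 = cf[["b0"]], bM = cf[["bM"]], KA = KA, Kd = 1 / KA,
    se = c(b0 = unname(se[["b0"]]), bM = unname(se[["bM"]]),
           KA = unname(KA_se), Kd = unname(KA_se / KA^2)),
    rss = sum(stats::residuals(fit)^2),
    D = D, motif = attr(data, "motif"), n = nrow(data), fit = fit
  ), class = "quadratic_binding_fit")
}

#' @export
print.quadratic_binding_fit <- function(x, ...) {
  cat(sprintf(
    "quadratic isotherm fit%s: KA = %.3g 1/M (Kd = %.3g M), b0 = %.3g, bM = %.3g, rss = %.3g\n",
    if (is.na(x$motif)) "" else paste0(" [", x$motif, "]"),
    x$KA, x$Kd, x$b0, x$bM, x$rss))
  invisible(x)
}

#' Fit replicated titrations
#'
#' Fits each replicate independently (the default, matching mean +/- SEM
#' reporting over replicates) or pools all points into one fit with shared
#' `b0`/`bM`/`KA`.
#'
#' @param data A `titration_series` with a `replicate` column.
#' @param mode `"independent"` or `"pooled"`.
#' @param init Optional starting values, as in [fit_quadratic_isotherm()].
#' @return For `"independent"`: list with per-replicate `fits`, `KA_mean`,
#'   `KA_sem`, `Kd_mean`. For `"pooled"`: a single `quadratic_binding_fit`.
#' @export
fit_titration_replicates <- function(data, mode = c("independent", "pooled"),
                                     init = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "titration_series"))
  if (mode == "pooled") return(fit_quadratic_isotherm(data, init))
  reps <- unique(data$replicate)
  fits <- lapply(reps, function(r) {
    d <- data[data$replicate == r, , drop = FALSE]
    fit_quadratic_isotherm(
      titration_series(d$P, d$F_obs, attr(data, "D"),
                       motif = attr(data, "motif")), init)
  })
  KA <- vapply(fits, `[[`, numeric(1), "KA")
  list(fits = stats::setNames(fits, paste0("rep", reps)),
       KA_mean = mean(KA),
       KA_sem = stats::sd(KA) / sqrt(length(KA)),
       Kd_mean = mean(1 / KA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
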