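## 1:1 Langmuir kinetics for SPR sensorgrams. Association phase:
##   R(t) = kon c0 Rmax / (kon c0 + koff) * [1 - exp(-(kon c0 + koff) t)]
##          + R_RI + cD t
## with refractive-index jump R_RI and baseline drift cD. Dissociation is
## a single exponential with optional linear drift.

#' Evaluate the association-phase response model
#'
#' @param t Time (s), from injection start.
#' @param c0 Analyte concentration (M, > 0).
#' @param kon Association rate constant (1/M/s).
#' @param koff Dissociation rate constant (1/s).
#' @param Rmax Local maximum response (RU).
#' @param RRI Refractive-index correction (RU).
#' @param cD Baseline drift (RU/s).
#' @return Response (RU) at each `t`.
#' @export
eval_association <- function(t, c0, kon, koff, Rmax, RRI = 0, cD = 0) {
  stopifnot(c0 > 0, kon > 0, koff > 0, Rmax > 0)
  kobs <- kon * c0 + koff
  kon * c0 * Rmax / kobs * (1 - exp(-kobs * t)) + RRI + cD * t
}

#' Build a sensorgram
#'
#' @param t Time (s), increasing; association phase starts at `t = 0`.
#' @param R Response (RU).
#' @param c0 Analyte concentration (M).
#' @param phase `"association"` or `"dissociation"` (scalar or per point).
#' @return Data frame of class `sensorgram`.
#' @export
sensorgram <- function(t, R, c0, phase = "association") {
  stopifnot(length(t) == length(R), !is.unsorted(t), c0 > 0)
  phase <- match.arg(phase, c("association", "dissociation"),
                     several.ok = FALSE)
  structure(data.frame(t = t, R = R), c0 = c0, phase = phase,
            class = c("sensorgram", "data.frame"))
}

## Two-stage initialisation: per-curve single-exponential fits give kobs
## and plateau; kobs ~ kon c0 + koff is linear in c0.
.kobs_init <- function(curves) {
  ks <- vapply(curves, function(sg) {
    single <- .fit_single_exponential(sg$t, sg$R)
    c(kobs = single$kobs, plateau = single$plateau)
  }, numeric(2))
  c0 <- vapply(curves, attr, numeric(1), "c0")
  lf <- stats::lm(ks["kobs", ] ~ c0)
  kon0 <- unname(stats::coef(lf)[2])
  koff0 <- unname(stats::coef(lf)[1])
  ## the linearisation degenerates when kobs barely varies over the
  ## concentration range; fall back to assuming KD ~ median c0
  if (!is.finite(kon0) || kon0 <= 0)
    kon0 <- mean(ks["kobs", ]) / (2 * stats::median(c0))
  if (!is.finite(koff0) || koff0 <= 0) koff0 <- mean(ks["kobs", ]) / 2
  ## plateau = kon c0 Rmax / kobs -> Rmax estimates
  Rmax0 <- max(ks["plateau", ] * ks["kobs", ] / (kon0 * c0))
  list(kon = max(kon0, 1), koff = max(koff0, 1e-6),
       Rmax = max(Rmax0, 1e-3))
}

.fit_single_exponential <- function(t, R) {
  A0 <- max(R) - min(R)
  k0 <- 1 / max(t[which.min(abs(R - (min(R) + 0.63 * A0)))], t[2])
  f <- tryCatch(
    minpack.lm::nlsLM(R ~ A * (1 - exp(-k * t)) + c0i,
                      data = data.frame(t = t, R = R),
                      start = list(A = A0, k = k0, c0i = min(R)),
                      lower = c(0, 1e-8, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(f)) return(list(kobs = k0, plateau = max(R)))
  cf <- stats::coef(f)
  list(kobs = unname(cf[["k"]]), plateau = unname(cf[["A"]] + cf[["c0i"]]))
}

#' Observed-rate fit of a single association curve
#'
#' Fits `R(t) = A [1 - exp(-kobs t)] + RRI + cD t` to one association
#' phase. A single concentration identifies only `kobs = kon c0 + koff`
#' and the plateau, not `kon` and `koff` separately; use
#' [fit_association()] over several concentrations for a global fit, or
#' [kobs_linear_fit()] to linearise several single-curve fits.
#'
#' @param data A `sensorgram` (association phase).
#' @param drift Include the linear drift term (default `TRUE`).
#' @return List with `kobs`, `plateau` (A), `RRI`, `cD`, `c0`, `rss`.
#' @export
fit_association_single <- function(data, drift = TRUE) {
  stopifnot(inherits(data, "sensorgram"))
  if (attr(data, "phase") != "association")
    stop("expected an association-phase sensorgram")
  t <- data$t; R <- data$R
  st <- .fit_single_exponential(t, R)
  df <- data.frame(t = t, R = R)
  f <- if (drift) {
    minpack.lm::nlsLM(R ~ A * (1 - exp(-k * t)) + RRI + cD * t, data = df,
                      start = list(A = st$plateau - min(R), k = st$kobs,
                                   RRI = min(R), cD = 0),
                      lower = c(0, 1e-8, -Inf, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300))
  } else {
    minpack.lm::nlsLM(R ~ A * (1 - exp(-k * t)) + RRI, data = df,
                      start = list(A = st$plateau - min(R), k = st$kobs,
                                   RRI = min(R)),
                      lower = c(0, 1e-8, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  cf <- stats::coef(f)
  list(kobs = unname(cf[["k"]]), plateau = unname(cf[["A"]]),
       RRI = unname(cf[["RRI"]]),
       cD = if (drift) unname(cf[["cD"]]) else 0,
       c0 = attr(data, "c0"), rss = sum(stats::residuals(f)^2))
}

#' Linearise observed rates against concentration
#'
#' For a 1:1 interaction, `kobs = kon c0 + koff`: an ordinary linear fit
#' of per-curve observed rates on concentration gives `kon` (slope) and
#' `koff` (intercept).
#'
#' @param kobs Vector of observed rates (1/s).
#' @param c0 Matching analyte concentrations (M).
#' @return List with `kon`, `koff` and the underlying `lm` fit.
#' @export
kobs_linear_fit <- function(kobs, c0) {
  stopifnot(length(kobs) == length(c0), length(c0) >= 2L)
  f <- stats::lm(kobs ~ c0)
  cf <- stats::coef(f)
  list(kon = unname(cf[[2]]), koff = unname(cf[[1]]), fit = f)
}

#' Global kinetic fit of association sensorgrams
#'
#' Fits the 1:1 association model jointly over sensorgrams at several
#' analyte concentrations, sharing `kon`, `koff` and `Rmax` across curves
#' with a per-curve refractive-index correction `RRI` and a shared drift
#' `cD`. Rate constants are parameterised on the log10 scale. Initial
#' values come from a two-stage observed-rate linearisation unless
#' supplied.
#'
#' @param curves List of association-phase `sensorgram`s (>= 3
#'   concentrations for the global fit).
#' @param init Optional named list with any of `kon`, `koff`, `Rmax`.
#' @param drift Include the shared linear drift term (default `TRUE`).
#' @return Object of class `kinetic_fit`: `kon`, `koff`, `Rmax`, `RRI`
#'   (per curve), `cD`, standard errors, derived `KD = koff/kon` and
#'   residence time `tau = 1/koff`.
#' @export
fit_association <- function(curves, init = NULL, drift = TRUE) {
  stopifnot(is.list(curves), length(curves) >= 3L)
  lapply(curves, function(sg) {
    stopifnot(inherits(sg, "sensorgram"))
    if (attr(sg, "phase") != "association")
      stop("all curves must be association phase")
    if (attr(sg, "c0") <= 0) stop("analyte concentration must be > 0")
  })
  c0s <- vapply(curves, attr, numeric(1), "c0")
  if (length(unique(c0s)) < 3L)
    stop("global fit needs >= 3 distinct concentrations")
  ini <- .kobs_init(curves)
  kon0 <- init$kon %||% ini$kon
  koff0 <- init$koff %||% ini$koff
  Rmax0 <- init$Rmax %||% ini$Rmax
  m <- length(curves)
  big <- data.frame(
    t = unlist(lapply(curves, `[[`, "t")),
    R = unlist(lapply(curves, `[[`, "R")),
    curve = rep(seq_len(m), vapply(curves, nrow, integer(1))),
    c0 = rep(c0s, vapply(curves, nrow, integer(1))))
  model_fn <- function(par) {
    kon <- 10^par[1]; koff <- 10^par[2]; Rmax <- par[3]
    RRI <- par[3L + seq_len(m)]
    cD <- if (drift) par[4L + m] else 0
    kobs <- kon * big$c0 + koff
    kon * big$c0 * Rmax / kobs * (1 - exp(-kobs * big$t)) +
      RRI[big$curve] + cD * big$t
  }
  resid_fn <- function(par) big$R - model_fn(par)
  par0 <- c(log10(kon0), log10(koff0), Rmax0,
            vapply(curves, function(sg) min(sg$R), numeric(1)),
            if (drift) 0)
  nl <- minpack.lm::nls.lm(
    par0, fn = resid_fn,
    lower = c(-2, -8, 1e-6, rep(-Inf, m), if (drift) -Inf),
    upper = c(12, 4, Inf, rep(Inf, m), if (drift) Inf),
    control = minpack.lm::nls.lm.control(maxiter = 400))
  par <- nl$par
  kon <- 10^par[1]; koff <- 10^par[2]
  ## SEs from the Jacobian (delta method for the log-scale rates)
  se <- tryCatch({
    J <- nl$hessian
    s2 <- sum(nl$fvec^2) / (length(nl$fvec) - length(par))
    sqrt(diag(s2 * solve(J)))
  }, error = function(e) rep(NA_real_, length(par)))
  koff_low <- par[2] <= -8 + 1e-6
  if (koff_low) warning("koff hit its lower bound; dissociation too slow ",
                        "to resolve on this time base")
  structure(list(
    kon = kon, koff = koff, Rmax = par[3],
    RRI = par[3L + seq_len(m)],
    cD = if (drift) par[4L + m] else 0,
    se = c(kon = kon * log(10) * se[1], koff = koff * log(10) * se[2],
           Rmax = se[3]),
    KD = koff / kon, tau = 1 / koff,
    c0 = c0s, rss = sum(nl$fvec^2), converged = nl$info %in% 1:3,
    koff_at_bound = koff_low
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "kinetic fit: kon = %.3g 1/M/s, koff = %.3g 1/s, Rmax = %.3g RU\n",
    x$kon, x$koff, x$Rmax))
  cat(sprintf("  KD = %.3g M, residence time tau = %.3g s\n", x$KD, x$tau))
  invisible(x)
}

#' Fit the dissociation phase
#'
#' Single-exponential decay with baseline and optional linear drift:
#' `R(t) = R1 exp(-koff (t - t1)) + base (+ cD (t - t1))`. The signal must
#' actually decay; a non-decreasing trace raises an error.
#'
#' @param data A dissociation-phase `sensorgram`; `t1` is its first time.
#' @param drift Include a linear drift term (default `FALSE`).
#' @return List with `koff`, `R1`, `base`, `cD`, `tau`, `rss`.
#' @export
fit_dissociation <- function(data, drift = FALSE) {
  stopifnot(inherits(data, "sensorgram"))
  if (attr(data, "phase") != "dissociation")
    stop("expected a dissociation-phase sensorgram")
  t1 <- data$t[1]
  tt <- data$t - t1
  R <- data$R
  dec <- stats::coef(stats::lm(R ~ tt))[[2]]
  total_drop <- -dec * max(tt)
  if (!is.finite(dec) || total_drop <= 1e-8 * max(abs(R), 1))
    stop("signal does not decay; cannot fit a dissociation rate")
  A0 <- max(R) - min(R)
  k0 <- max(-dec / max(A0, 1e-12), 1e-6)
  df <- data.frame(tt = tt, R = R)
  f <- if (drift) {
    minpack.lm::nlsLM(R ~ R1 * exp(-k * tt) + base + cD * tt, data = df,
                      start = list(R1 = A0, k = k0, base = min(R), cD = 0),
                      lower = c(0, 1e-8, -Inf, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300))
  } else {
    minpack.lm::nlsLM(R ~ R1 * exp(-k * tt) + base, data = df,
                      start = list(R1 = A0, k = k0, base = min(R)),
                      lower = c(0, 1e-8, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  cf <- stats::coef(f)
  list(koff = unname(cf[["k"]]), R1 = unname(cf[["R1"]]),
       base = unname(cf[["base"]]),
       cD = if (drift) unname(cf[["cD"]]) else 0,
       tau = 1 / unname(cf[["k"]]), rss = sum(stats::residuals(f)^2))
}

#' Residence time from a kinetic fit
#'
#' @param fit A `kinetic_fit`, or anything with a positive `koff` element.
#' @return Mean complex lifetime `tau = 1/koff` in seconds.
#' @export
residence_time <- function(fit) {
  koff <- if (is.list(fit)) fit$koff else fit
  stopifnot(is.numeric(koff), koff > 0)
  1 / koff
}

#' Compare binding preference between two proteins on two motifs
#'
#' Per-protein preference is the affinity ratio `KA(BM)/KA(ZM)`; the
#' evolutionary shift is `preference(B)/preference(A)`. Equilibrium fits
#' (`quadratic_binding_fit`, affinity `KA`) and kinetic fits
#' (`kinetic_fit`, affinity `1/KD`) are on different scales and cannot be
#' mixed unless `allow_mixed = TRUE`. For four kinetic fits, residence-time
#' ratios are reported as well.
#'
#' @param fitA_BM,fitA_ZM Fits for protein A on motifs BM and ZM.
#' @param fitB_BM,fitB_ZM Fits for protein B on the same motifs.
#' @param allow_mixed Permit mixing equilibrium and kinetic affinities.
#' @return Object of class `preference_comparison`: per-protein
#'   preferences, fold changes per motif, the preference `shift`, its
#'   `log10_shift`, and (for kinetic input) residence-time ratios.
#' @export
compare_preference <- function(fitA_BM, fitA_ZM, fitB_BM, fitB_ZM,
                               allow_mixed = FALSE) {
  fits <- list(fitA_BM, fitA_ZM, fitB_BM, fitB_ZM)
  kinds <- vapply(fits, function(f) {
    if (inherits(f, "quadratic_binding_fit")) "equilibrium"
    else if (inherits(f, "kinetic_fit")) "kinetic"
    else stop("fits must be quadratic_binding_fit or kinetic_fit objects")
  }, character(1))
  if (length(unique(kinds)) > 1L && !allow_mixed)
    stop("mixing equilibrium and kinetic affinities; ",
         "set allow_mixed = TRUE to compare anyway")
  ka <- vapply(fits, function(f) {
    if (inherits(f, "quadratic_binding_fit")) f$KA else 1 / f$KD
  }, numeric(1))
  prefA <- ka[1] / ka[2]
  prefB <- ka[3] / ka[4]
  out <- list(
    preference_A = prefA, preference_B = prefB,
    fold_BM = ka[3] / ka[1], fold_ZM = ka[4] / ka[2],
    shift = prefB / prefA, log10_shift = log10(prefB / prefA),
    kind = unique(kinds))
  if (all(kinds == "kinetic")) {
    tau <- vapply(fits, `[[`, numeric(1), "tau")
    out$tau_ratio_BM <- tau[3] / tau[1]
    out$tau_ratio_ZM <- tau[4] / tau[2]
  }
  structure(out, class = "preference_comparison")
}

#' @export
print.preference_comparison <- function(x, ...) {
  cat(sprintf("preference comparison (%s affinities)\n",
              paste(x$kind, collapse = "/")))
  cat(sprintf("  preference A (BM/ZM): %.3g;  preference B: %.3g\n",
              x$preference_A, x$preference_B))
  cat(sprintf("  fold change BM: %.3g;  fold change ZM: %.3g\n",
              x$fold_BM, x$fold_ZM))
  cat(sprintf("  preference shift B/A: %.3g (10^%.2f)\n",
              x$shift, x$log10_shift))
  invisible(x)
}
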