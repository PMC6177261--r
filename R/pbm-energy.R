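## Position-specific binding-energy (PWM energy) model: additive per-base
## energies in RT units embedded in a saturating occupancy function with a
## chemical potential, response scale and background, evaluated over all
## probe windows on both strands.

#' Construct a position-energy binding model
#'
#' @param eps Numeric L x 4 matrix of energies in RT units; columns are
#'   A, C, G, T. Lower energy = more favourable.
#' @param mu Chemical potential (RT units); occupancy of a window with
#'   energy E is `1 / (1 + exp(E - mu))`.
#' @param beta Response scale (intensity units per unit occupancy, > 0).
#' @param bg Background intensity offset (>= 0).
#' @param weights Optional positional window weights (recycled over
#'   windows; default uniform 1).
#' @return Object of class `energy_model`.
#' @export
energy_model <- function(eps, mu = 0, beta = 1, bg = 0.1, weights = NULL) {
  eps <- as.matrix(eps)
  if (ncol(eps) != 4L) stop("eps must have 4 columns (A, C, G, T)")
  colnames(eps) <- DNA_BASES
  stopifnot(beta > 0, bg >= 0, is.finite(mu))
  structure(list(eps = eps, mu = mu, beta = beta, bg = bg,
                 L = nrow(eps), weights = weights),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("energy_model: motif length %d, mu = %.3f, beta = %.3g, bg = %.3g\n",
              x$L, x$mu, x$beta, x$bg))
  print(round(x$eps, 3))
  invisible(x)
}

#' Mean-centre an energy model's gauge
#'
#' Adding a constant to all four energies at one position and compensating
#' the chemical potential leaves every predicted intensity unchanged; the
#' reported gauge centres each position's energies to mean zero.
#'
#' @param model An `energy_model`.
#' @return The same model in the mean-centred gauge.
#' @export
center_energy_model <- function(model) {
  m <- rowMeans(model$eps)
  model$eps <- model$eps - m
  model$mu <- model$mu - sum(m)
  model
}

## Probe sequences -> integer base-code matrix (n x len), A=1..T=4.
.base_codes <- function(seqs) {
  len <- nchar(seqs[1])
  m <- matrix(0L, length(seqs), len)
  for (j in seq_len(len))
    m[, j] <- match(substring(seqs, j, j), DNA_BASES)
  if (anyNA(m)) stop("probe sequences must be over A/C/G/T")
  m
}

## Window energies for one strand: list of n-vectors, one per window.
## Scanning the reverse strand is equivalent to scanning forward windows
## with the position-reversed, base-complemented energy matrix.
.strand_eps <- function(eps) eps[rev(seq_len(nrow(eps))), 4:1, drop = FALSE]

## Occupancy sum and (optionally) per-window logistic terms.
.occupancy <- function(B, eps, mu, keep_terms = FALSE) {
  L <- nrow(eps)
  nwin <- ncol(B) - L + 1L
  n <- nrow(B)
  occ <- numeric(n)
  terms <- if (keep_terms) vector("list", 2L * nwin) else NULL
  strands <- list(eps, .strand_eps(eps))
  ti <- 0L
  for (s in 1:2) {
    es <- strands[[s]]
    for (j in seq_len(nwin)) {
      E <- numeric(n)
      for (p in seq_len(L)) E <- E + es[p, ][B[, j + p - 1L]]
      sig <- 1 / (1 + exp(E - mu))
      occ <- occ + sig
      if (keep_terms) {
        ti <- ti + 1L
        terms[[ti]] <- list(sig = sig, j = j, strand = s)
      }
    }
  }
  list(occ = occ, terms = terms, nwin = nwin)
}

#' Predict probe intensities under an energy model
#'
#' Predicted intensity is `bg + beta * sum_w 1/(1 + exp(E_w - mu))` over
#' all motif-length windows `w` of the probe on both strands, where `E_w`
#' is the additive window energy.
#'
#' @param model An `energy_model`.
#' @param seqs Character vector of probe sequences (equal length, >= L).
#' @return Numeric vector of predicted intensities.
#' @export
predict_intensity <- function(model, seqs) {
  B <- .base_codes(seqs)
  if (ncol(B) < model$L) stop("probes shorter than the motif")
  model$bg + model$beta * .occupancy(B, model$eps, model$mu)$occ
}

#' Seed an energy model from top-scoring k-mers
#'
#' Builds a crude starting model for [fit_energy_model()]: the highest
#' E-score word of length `L` gets energy `-seed_depth` RT at its matching
#' base per position (0 elsewhere), and the scale/background are set from
#' the intensity range.
#'
#' @param probes Probe table (see [compute_escores()]).
#' @param L Motif length (6 or 8; scores of that k are computed).
#' @param seed_depth Energy advantage of the seed base (RT units).
#' @return An `energy_model`.
#' @export
init_energy_model <- function(probes, L = 6L, seed_depth = 2) {
  t8 <- compute_escores(probes, k = 8L)
  tb <- if (L == 6L) sixmer_scores(t8) else t8
  if (L != 6L && L != 8L) stop("L must be 6 or 8")
  seed <- tb$kmer[which.max(tb$escore)]
  eps <- matrix(0, L, 4L)
  idx <- match(strsplit(seed, "")[[1]], DNA_BASES)
  eps[cbind(seq_len(L), idx)] <- -seed_depth
  y <- probes$intensity
  center_energy_model(energy_model(
    eps, mu = -seed_depth * L / 2,
    beta = max(stats::quantile(y, 0.99) - stats::median(y), 1e-3),
    bg = stats::median(y)))
}

#' Fit a position-energy model to probe intensities
#'
#' Nonlinear least squares for the parameters of the additive
#' position-energy occupancy model (per-position base energies, chemical
#' potential, response scale, background), minimising the squared error
#' between observed and predicted probe intensities over all windows on
#' both strands. Optimisation uses L-BFGS-B with analytic gradients; the
#' returned energies are mean-centred per position.
#'
#' @param probes Probe table with `sequence` and `intensity` columns.
#' @param init An `energy_model` giving starting parameters (e.g. from
#'   [init_energy_model()]).
#' @param maxit Iteration cap per start; non-convergence gives a warning
#'   and returns the best-found model.
#' @param start_scales Deterministic multi-start: the fit is repeated
#'   from the initial model with its energies and chemical potential
#'   multiplied by each scale, and the lowest-RSS solution is kept. The
#'   occupancy regression is non-convex (deeply unfavourable energies sit
#'   in a saturated, near-zero-gradient region), so a single start can
#'   stall in a local basin.
#' @return The fitted `energy_model`, with attributes `rss`, `converged`,
#'   and `r2` (in-sample, at probe level).
#' @export
fit_energy_model <- function(probes, init, maxit = 1500L,
                             start_scales = c(1, 1.5, 0.5)) {
  .check_probes(probes)
  stopifnot(inherits(init, "energy_model"))
  B <- .base_codes(probes$sequence)
  y <- probes$intensity
  L <- init$L
  if (ncol(B) < L) stop("probes shorter than the motif")
  n <- nrow(B)
  nwin <- ncol(B) - L + 1L
  ## Precompute, per strand, the flat index of (position, base) for every
  ## window of every probe: IDX[w, p] points into as.vector(eps) (L x 4).
  ## Reverse-strand windows read the position-reversed complement, which
  ## is equivalent to indexing eps at (L+1-p, 5-base).
  W <- n * nwin
  IDX <- matrix(0L, 2L * W, L)
  probe_of <- integer(2L * W)
  for (j in seq_len(nwin)) {
    rows <- (j - 1L) * n + seq_len(n)
    probe_of[rows] <- seq_len(n)
    probe_of[W + rows] <- seq_len(n)
    for (p in seq_len(L)) {
      b <- B[, j + p - 1L]
      IDX[rows, p] <- p + (b - 1L) * L
      IDX[W + rows, L + 1L - p] <- (L + 1L - p) + (4L - b) * L
    }
  }
  unpack <- function(par) {
    list(eps = matrix(par[seq_len(4L * L)], L, 4L),
         mu = par[4L * L + 1L],
         beta = exp(par[4L * L + 2L]),
         bg = par[4L * L + 3L])
  }
  window_sig <- function(eps_flat, mu) {
    E <- matrix(eps_flat[IDX], ncol = L)
    E <- rowSums(E)
    1 / (1 + exp(E - mu))
  }
  fn <- function(par) {
    p <- unpack(par)
    sig <- window_sig(as.vector(p$eps), p$mu)
    occ <- rowsum(sig, probe_of)[, 1L]
    sum((p$bg + p$beta * occ - y)^2)
  }
  gr <- function(par) {
    p <- unpack(par)
    sig <- window_sig(as.vector(p$eps), p$mu)
    occ <- rowsum(sig, probe_of)[, 1L]
    pred <- p$bg + p$beta * occ
    r2 <- 2 * (pred - y)
    v <- (r2[probe_of] * p$beta) * (sig * (1 - sig))
    g_eps <- numeric(4L * L)
    for (p_ in seq_len(L)) {
      agg <- rowsum(v, IDX[, p_])
      ii <- as.integer(rownames(agg))
      g_eps[ii] <- g_eps[ii] - agg[, 1L]
    }
    c(g_eps, sum(v), sum(r2 * p$beta * occ), sum(r2))
  }
  opt <- NULL
  for (s in start_scales) {
    par0 <- c(as.vector(init$eps) * s, init$mu * s, log(init$beta),
              init$bg)
    o <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      lower = c(rep(-30, 4L * L), -60, log(1e-12), 0),
                      upper = c(rep(30, 4L * L), 60, log(1e12), Inf),
                      control = list(maxit = maxit))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  if (opt$convergence != 0L)
    warning("energy-model fit did not converge (code ", opt$convergence,
            "); returning best-found parameters")
  p <- unpack(opt$par)
  fit <- center_energy_model(energy_model(p$eps, p$mu, p$beta, p$bg))
  pred <- predict_intensity(fit, probes$sequence)
  structure(fit,
            class = class(fit),
            rss = opt$value,
            converged = opt$convergence == 0L,
            r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2))
}

#' Reverse-complement image of an energy model
#'
#' Because prediction scans both strands, an energy model and its
#' position-reversed, base-complemented image produce identical predicted
#' intensities for every probe: the model is identifiable only up to this
#' orientation. This helper returns the image.
#'
#' @param model An `energy_model`.
#' @return The reverse-complement-equivalent `energy_model`.
#' @export
revcomp_energy_model <- function(model) {
  model$eps <- .strand_eps(model$eps)
  colnames(model$eps) <- DNA_BASES
  model
}

#' Orient a fitted energy model against a reference
#'
#' Chooses between a model and its reverse-complement image (which make
#' identical predictions) by whichever is closer to `ref` in maximum
#' absolute energy difference. Both models are compared in the
#' mean-centred gauge.
#'
#' @param model A fitted `energy_model`.
#' @param ref The reference `energy_model` to orient against.
#' @return `model` or its reverse-complement image, mean-centred.
#' @export
orient_energy_model <- function(model, ref) {
  m <- center_energy_model(model)
  r <- center_energy_model(ref)
  mrc <- center_energy_model(revcomp_energy_model(m))
  if (max(abs(m$eps - r$eps)) <= max(abs(mrc$eps - r$eps))) m else mrc
}

#' Coefficient of determination on held-out 8-mer median intensities
#'
#' Predicts held-out probe intensities from a fitted model, summarises
#' observed and predicted intensities as per-8-mer medians (over the
#' probes containing each canonical 8-mer), and returns
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param model A fitted `energy_model`.
#' @param heldout Probe table from an independent replicate.
#' @param rescale Allow a linear rescaling of the predictions before
#'   computing `R^2` (default `TRUE`): replicates routinely differ in
#'   overall signal strength, and the quantity of interest is the variance
#'   in observed medians the predictions explain, not their absolute
#'   scale. With `rescale = FALSE` the raw squared-error `R^2` is used.
#' @return R-squared (can be negative for predictions worse than the mean).
#' @export
evaluate_r2 <- function(model, heldout, rescale = TRUE) {
  .check_probes(heldout)
  pred <- predict_intensity(model, heldout$sequence)
  pairs <- .kmer_probe_pairs(heldout$sequence, 8L)
  obs_med <- vapply(split(pairs$probe, pairs$kmer),
                    function(i) stats::median(heldout$intensity[i]),
                    numeric(1))
  pred_med <- vapply(split(pairs$probe, pairs$kmer),
                     function(i) stats::median(pred[i]), numeric(1))
  .r2 <- function(obs, prd, rescale) {
    if (rescale) {
      if (stats::sd(prd) == 0) return(0)
      prd <- stats::fitted(stats::lm(obs ~ prd))
    }
    1 - sum((obs - prd)^2) / sum((obs - mean(obs))^2)
  }
  .r2(obs_med, pred_med, rescale)
}

#' Replicate-vs-replicate R-squared of 8-mer median intensities
#'
#' The experimental reproducibility ceiling against which model
#' predictions are judged.
#'
#' @param a,b Probe tables of two replicates over the same probe set.
#' @param rescale Allow a linear rescaling between replicates (default
#'   `TRUE`; see [evaluate_r2()]).
#' @return R-squared of replicate b's 8-mer medians on replicate a's.
#' @export
replicate_r2 <- function(a, b, rescale = TRUE) {
  med8 <- function(p) {
    pr <- .kmer_probe_pairs(p$sequence, 8L)
    vapply(split(pr$probe, pr$kmer),
           function(i) stats::median(p$intensity[i]), numeric(1))
  }
  ma <- med8(a); mb <- med8(b)
  common <- intersect(names(ma), names(mb))
  x <- ma[common]; yv <- mb[common]
  if (rescale) {
    if (stats::sd(x) == 0) return(0)
    x <- stats::fitted(stats::lm(yv ~ x))
  }
  1 - sum((yv - x)^2) / sum((yv - mean(yv))^2)
}

#' Energy logo matrix
#'
#' Per position and base, the letter value is that base's main effect on
#' binding energy relative to the mean of all bases at the position, in RT
#' units (the model is mean-centred first, so values are signed: negative
#' = favourable, drawn below the axis in the conventional rendering;
#' letter height is the absolute value).
#'
#' @param model An `energy_model`.
#' @return 4 x L numeric matrix of class `logo_matrix` (rows A, C, G, T).
#' @export
energy_logo <- function(model) {
  cm <- center_energy_model(model)
  structure(t(cm$eps), class = c("logo_matrix", "matrix", "array"))
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("energy logo (RT units; negative = favourable):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Plot an energy logo
#'
#' Simple base-graphics rendering: letters scaled by |energy effect|,
#' favourable bases below the axis.
#'
#' @param x A `logo_matrix`.
#' @param ... Passed to [graphics::plot()].
#' @method plot logo_matrix
#' @export
plot.logo_matrix <- function(x, ...) {
  L <- ncol(x)
  ylim <- range(-x, 0) + c(-0.1, 0.1) * max(abs(x))
  graphics::plot(NA, xlim = c(0.5, L + 0.5), ylim = ylim,
                 xlab = "motif position", ylab = "-energy effect (RT)", ...)
  graphics::abline(h = 0, col = "grey")
  cols <- c(A = "forestgreen", C = "blue", G = "orange", T = "red")
  for (j in seq_len(L)) for (b in rownames(x)) {
    v <- -x[b, j]          # favourable (negative energy) plotted upward
    if (abs(v) < 1e-9) next
    graphics::text(j, v, b, col = cols[[b]],
                   cex = 0.6 + 2.2 * abs(v) / max(abs(x)))
  }
  invisible(x)
}
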