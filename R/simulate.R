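## Synthetic-data generators for the five input kinds the analysis
## consumes. Forward models reuse the exact evaluation code of the fitting
## modules (transition_prob, predict_intensity, eval_isotherm,
## eval_association), so simulators and fits share a single source of
## truth. Every generator takes an explicit seed.

#' Simulate an alignment along a tree under LG + discrete gamma
#'
#' Draws the root sequence from the stationary frequencies, assigns each
#' site one of the model's gamma rate categories, and evolves states down
#' every branch by the transition probabilities. The true sequence at
#' every internal node is recorded.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param model An [lg_gamma_model()].
#' @param n_sites Number of alignment columns.
#' @param seed Integer seed.
#' @return List with `alignment` (an [amino_alignment()] over the tips),
#'   `node_sequences` (named character vector; internal nodes, labelled
#'   where the tree is), and `site_rates`.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed) {
  stopifnot(!is.null(tree$edge.length), n_sites >= 1L)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  rates <- model$rates[sample.int(model$k, n_sites, replace = TRUE)]
  states <- matrix(NA_integer_, nnode, n_sites)
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                               prob = model$pi)
  po <- ape::reorder.phylo(tree, "postorder")
  ## preorder: parents before children
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    len <- po$edge.length[e]
    ## distinct P(t r) per category value actually used
    for (r in unique(rates)) {
      sel <- which(rates == r)
      P <- transition_prob(model, len * r)
      cur <- states[p, sel]
      states[ch, sel] <- vapply(cur, function(s) {
        sample.int(20L, 1L, prob = P[s, ])
      }, integer(1))
    }
  }
  tipm <- matrix(AA_ALPHA[states[seq_len(ntip), , drop = FALSE]],
                 ntip, n_sites)
  rownames(tipm) <- tree$tip.label
  node_idx <- (ntip + 1L):nnode
  node_seq <- apply(states[node_idx, , drop = FALSE], 1, function(s)
    paste(AA_ALPHA[s], collapse = ""))
  names(node_seq) <- if (!is.null(tree$node.label) &&
                         length(tree$node.label) == tree$Nnode) {
    ifelse(nzchar(tree$node.label), tree$node.label,
           paste0("node", node_idx))
  } else paste0("node", node_idx)
  list(alignment = amino_alignment(tipm),
       node_sequences = node_seq,
       site_rates = rates)
}

#' Simulate a protein-binding-microarray probe table
#'
#' Uniform-random probe sequences are scored by the energy model's
#' occupancy (all windows, both strands) and perturbed by multiplicative
#' log-normal noise; replicates get independent noise and an optional
#' replicate-specific intensity scale (one replicate is typically
#' stronger than the other in practice).
#'
#' @param model An [energy_model()] (the ground truth).
#' @param n_probes Number of distinct probes (default 8000).
#' @param probe_len Probe variable-region length (default 36 nt).
#' @param noise_sd Log-scale noise standard deviation (default 0.2).
#' @param n_replicates Number of replicates (default 2).
#' @param replicate_scale Per-replicate intensity scale factors (recycled;
#'   default 1).
#' @param seed Integer seed.
#' @return Probe table data frame (`probe_id`, `sequence`, `intensity`,
#'   `replicate`) suitable for [compute_escores()].
#' @export
simulate_pbm <- function(model, n_probes = 8000L, probe_len = 36L,
                         noise_sd = 0.2, n_replicates = 2L,
                         replicate_scale = 1, seed = 1L) {
  stopifnot(probe_len >= model$L, n_probes >= 2L)
  set.seed(seed)
  seqs <- vapply(seq_len(n_probes), function(i)
    paste(sample(DNA_BASES, probe_len, replace = TRUE), collapse = ""),
    character(1))
  base <- predict_intensity(model, seqs)
  scale <- rep_len(replicate_scale, n_replicates)
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    noise <- if (noise_sd > 0)
      exp(stats::rnorm(n_probes, 0, noise_sd)) else 1
    data.frame(probe_id = sprintf("probe_%05d", seq_len(n_probes)),
               sequence = seqs,
               intensity = base * scale[r] * noise,
               replicate = r)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate an equilibrium titration
#'
#' Forward-evaluates the quadratic isotherm ([eval_isotherm()]) on a
#' protein-concentration grid and adds Gaussian noise.
#'
#' @param KA Association constant (1/M).
#' @param D Labelled-DNA concentration (M).
#' @param P_grid Total protein concentrations (M, increasing).
#' @param b0,bM Baseline and maximum response.
#' @param noise_sd Gaussian response noise (default 0).
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param motif Optional motif label.
#' @return A [titration_series()].
#' @export
simulate_titration <- function(KA, D, P_grid, b0 = 0, bM = 1,
                               noise_sd = 0, n_reps = 1L, seed = 1L,
                               motif = NA_character_) {
  set.seed(seed)
  tru <- eval_isotherm(P_grid, D, KA, b0, bM)
  P <- rep(P_grid, n_reps)
  F_obs <- rep(tru, n_reps) +
    if (noise_sd > 0) stats::rnorm(length(P), 0, noise_sd) else 0
  titration_series(P, F_obs, D, motif = motif,
                   replicate = rep(seq_len(n_reps), each = length(P_grid)))
}

#' Simulate SPR sensorgrams
#'
#' Association per the 1:1 model ([eval_association()]); the dissociation
#' phase continues from the association endpoint with exponential decay of
#' the bound signal plus the same baseline drift. Gaussian RU noise is
#' added to both phases.
#'
#' @param kon,koff,Rmax Kinetic ground truth.
#' @param RRI Refractive-index offset(s), recycled per concentration.
#' @param cD Baseline drift (RU/s).
#' @param c0_list Analyte concentrations (M).
#' @param t_assoc Association-phase duration (s).
#' @param t_dissoc Dissociation-phase duration (s; 0 = none).
#' @param dt Sampling interval (s).
#' @param noise_sd RU noise standard deviation.
#' @param seed Integer seed.
#' @return List with `association` and `dissociation`: lists of
#'   [sensorgram()]s per concentration.
#' @export
simulate_sensorgram <- function(kon, koff, Rmax, RRI = 0, cD = 0,
                                c0_list, t_assoc = 120, t_dissoc = 300,
                                dt = 1, noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  RRI <- rep_len(RRI, length(c0_list))
  assoc <- vector("list", length(c0_list))
  dissoc <- vector("list", length(c0_list))
  for (i in seq_along(c0_list)) {
    c0 <- c0_list[i]
    ta <- seq(0, t_assoc, by = dt)
    Ra <- eval_association(ta, c0, kon, koff, Rmax, RRI[i], cD)
    if (noise_sd > 0) Ra <- Ra + stats::rnorm(length(ta), 0, noise_sd)
    assoc[[i]] <- sensorgram(ta, Ra, c0, "association")
    if (t_dissoc > 0) {
      td <- seq(t_assoc, t_assoc + t_dissoc, by = dt)
      bound_end <- eval_association(t_assoc, c0, kon, koff, Rmax, 0, 0)
      Rd <- bound_end * exp(-koff * (td - t_assoc)) + RRI[i] + cD * td
      if (noise_sd > 0) Rd <- Rd + stats::rnorm(length(td), 0, noise_sd)
      dissoc[[i]] <- sensorgram(td, Rd, c0, "dissociation")
    }
  }
  list(association = assoc, dissociation = dissoc)
}
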