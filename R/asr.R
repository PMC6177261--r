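## Felsenstein pruning machinery.
##
## Partial likelihoods are kept per rate category with per-site log scaling
## (each internal node's site rows are rescaled by their maximum), so the
## same code is stable from 4-taxon toys up to large alignments.

## Tip conditional-likelihood matrix: sites x 20; gaps/unknowns -> all ones.
.tip_clv <- function(aln_row) {
  S <- length(aln_row)
  m <- matrix(0, S, 20L)
  gap <- aln_row == "-"
  m[gap, ] <- 1
  idx <- match(aln_row[!gap], AA_ALPHA)
  m[cbind(which(!gap), idx)] <- 1
  m
}

## Full down (postorder) pass for one rate multiplier.
## Returns scaled conditional likelihoods D, per-edge child contributions,
## and cumulative per-site log scales.
.down_pass <- function(tipclv, po_edge, edge_len, rate, model, S) {
  nnode <- max(po_edge)
  D <- vector("list", nnode)
  ntip <- length(tipclv)
  for (i in seq_len(ntip)) D[[i]] <- tipclv[[i]]
  cumsc <- matrix(0, S, nnode)
  contribs <- vector("list", nrow(po_edge))
  for (e in seq_len(nrow(po_edge))) {
    p <- po_edge[e, 1L]; ch <- po_edge[e, 2L]
    P <- transition_prob(model, edge_len[e] * rate)
    ctr <- D[[ch]] %*% t(P)
    contribs[[e]] <- ctr
    if (is.null(D[[p]])) {
      D[[p]] <- ctr
      cumsc[, p] <- cumsc[, ch]
    } else {
      D[[p]] <- D[[p]] * ctr
      cumsc[, p] <- cumsc[, p] + cumsc[, ch]
    }
    m <- D[[p]][cbind(seq_len(S), max.col(D[[p]], ties.method = "first"))]
    D[[p]] <- D[[p]] / m
    cumsc[, p] <- cumsc[, p] + log(m)
  }
  list(D = D, contribs = contribs, cumsc = cumsc)
}

## Up (preorder) pass: outside partial likelihoods G per node, with their
## own per-site log scales. G[root] = pi (broadcast).
.up_pass <- function(down, po_edge, edge_len, rate, model, S, root) {
  nnode <- max(po_edge)
  G <- vector("list", nnode)
  gsc <- matrix(0, S, nnode)
  G[[root]] <- matrix(model$pi, S, 20L, byrow = TRUE)
  for (e in rev(seq_len(nrow(po_edge)))) {
    p <- po_edge[e, 1L]; ch <- po_edge[e, 2L]
    P <- transition_prob(model, edge_len[e] * rate)
    sib <- down$D[[p]] / down$contribs[[e]]
    Gc <- (G[[p]] * sib) %*% P
    sc <- gsc[, p] + down$cumsc[, p] - down$cumsc[, ch]
    m <- Gc[cbind(seq_len(S), max.col(Gc, ties.method = "first"))]
    G[[ch]] <- Gc / m
    gsc[, ch] <- sc + log(m)
  }
  list(G = G, gsc = gsc)
}

## Shared setup: validate, reorder, build tip CLVs.
.pruning_setup <- function(aln, tree, model) {
  .check_aln_tree(aln, tree)
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- match(po$tip.label, rownames(aln))
  tipclv <- lapply(ord, function(i) .tip_clv(unclass(aln)[i, ]))
  list(po = po, tipclv = tipclv, S = ncol(aln),
       root = length(tree$tip.label) + 1L)
}

#' Phylogenetic log-likelihood under LG + discrete gamma
#'
#' Computes the log-likelihood of an aligned set of protein sequences on a
#' fixed rooted tree by the pruning algorithm, integrating over the model's
#' equal-weight discrete-gamma rate categories. Gap and unknown characters
#' are treated as missing data (conditional likelihood of ones).
#'
#' @param aln An [amino_alignment()].
#' @param tree A rooted `phylo` tree whose tip labels match `rownames(aln)`.
#' @param model An [lg_gamma_model()].
#' @param per_site If `TRUE`, also return the per-site log-likelihoods.
#' @return The total log-likelihood (numeric scalar), or a list with
#'   `loglik` and `site_loglik` when `per_site = TRUE`.
#' @export
tree_log_likelihood <- function(aln, tree, model, per_site = FALSE) {
  st <- .pruning_setup(aln, tree, model)
  S <- st$S
  sitell_k <- matrix(NA_real_, S, model$k)
  for (k in seq_len(model$k)) {
    dn <- .down_pass(st$tipclv, st$po$edge, st$po$edge.length,
                     model$rates[k], model, S)
    lr <- drop(dn$D[[st$root]] %*% model$pi)
    sitell_k[, k] <- log(lr) + dn$cumsc[, st$root]
  }
  ## log( sum_k w_k exp(ll_k) ), stabilised
  M <- apply(sitell_k, 1, max)
  site_ll <- M + log(rowSums(exp(sitell_k - M) *
                               rep(model$weights, each = S)))
  if (per_site) list(loglik = sum(site_ll), site_loglik = site_ll)
  else sum(site_ll)
}

#' Optimize branch lengths and gamma shape by maximum likelihood
#'
#' Coordinate-wise optimisation on a fixed topology: each branch length is
#' updated in turn by bounded scalar search on `[1e-8, 20]`, followed by a
#' bounded search for the gamma shape, iterated until the log-likelihood
#' improves by less than `tol` between sweeps.
#'
#' @inheritParams tree_log_likelihood
#' @param fit_shape Optimise the gamma shape alpha as well (default `TRUE`).
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_sweeps Sweep cap; a warning is issued if reached.
#' @return List with `tree` (ML branch lengths), `model` (ML shape),
#'   `loglik`, `converged`, and `n_sweeps`.
#' @export
optimize_parameters <- function(aln, tree, model, fit_shape = TRUE,
                                tol = 1e-6, max_sweeps = 50L) {
  .check_aln_tree(aln, tree)
  tr <- tree
  mod <- model
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  cur <- tree_log_likelihood(aln, tr, mod)
  converged <- FALSE
  sweep <- 0L
  while (sweep < max_sweeps) {
    sweep <- sweep + 1L
    for (e in seq_along(tr$edge.length)) {
      f <- function(b) {
        tr2 <- tr; tr2$edge.length[e] <- b
        -tree_log_likelihood(aln, tr2, mod)
      }
      op <- stats::optimize(f, c(1e-8, 20), tol = 1e-6)
      if (-op$objective > cur - 1e-12) {
        tr$edge.length[e] <- op$minimum
        cur <- -op$objective
      }
    }
    if (fit_shape) {
      g <- function(la) {
        -tree_log_likelihood(aln, tr, lg_gamma_model(exp(la), mod$k))
      }
      op <- stats::optimize(g, log(c(0.02, 100)), tol = 1e-5)
      if (-op$objective > cur - 1e-12) {
        mod <- lg_gamma_model(exp(op$minimum), mod$k)
        cur <- -op$objective
      }
    }
    new <- tree_log_likelihood(aln, tr, mod)
    if (sweep > 1L && new - prev < tol) { converged <- TRUE; cur <- new; break }
    prev <- new
    cur <- new
  }
  if (!converged)
    warning("branch-length optimisation did not converge in ",
            max_sweeps, " sweeps; returning best-found values")
  list(tree = tr, model = mod, loglik = cur,
       converged = converged, n_sweeps = sweep)
}

#' Marginal ancestral posterior probabilities at an internal node
#'
#' Empirical-Bayes marginal reconstruction: per site, the posterior
#' probability of each amino acid at the queried node, integrating over all
#' other nodes and over the discrete-gamma rate categories (weighted by
#' their site-specific posterior). The posterior is computed on the rooted
#' input tree as given.
#'
#' @inheritParams tree_log_likelihood
#' @param node Internal-node label (e.g. `"AncZB"`).
#' @return Object of class `ancestral_posterior`: list with `node`, `pp`
#'   (sites x 20 matrix, rows summing to 1), `ml_state`, `ml_pp`.
#' @export
marginal_posteriors <- function(aln, tree, model, node) {
  st <- .pruning_setup(aln, tree, model)
  v <- .node_number(tree, node)
  ## map node numbers: reorder() keeps ape node numbering, so v is valid
  S <- st$S
  num <- matrix(0, S, 20L)   # running, rescaled per-site
  lsc <- NULL                # per category: log scale per site
  joint <- vector("list", model$k)
  for (k in seq_len(model$k)) {
    dn <- .down_pass(st$tipclv, st$po$edge, st$po$edge.length,
                     model$rates[k], model, S)
    up <- .up_pass(dn, st$po$edge, st$po$edge.length,
                   model$rates[k], model, S, st$root)
    J <- if (v == st$root) {
      dn$D[[v]] * matrix(model$pi, S, 20L, byrow = TRUE)
    } else dn$D[[v]] * up$G[[v]]
    sc <- dn$cumsc[, v] + (if (v == st$root) 0 else up$gsc[, v])
    joint[[k]] <- list(J = J, sc = sc + log(model$weights[k]))
  }
  scs <- matrix(vapply(joint, function(z) z$sc, numeric(S)), nrow = S)
  M <- apply(scs, 1, max)
  pp <- matrix(0, S, 20L)
  for (k in seq_len(model$k))
    pp <- pp + joint[[k]]$J * exp(joint[[k]]$sc - M)
  pp <- pp / rowSums(pp)
  colnames(pp) <- AA_ALPHA
  ml_idx <- max.col(pp, ties.method = "first")  # alphabetical = first index
  structure(list(node = node, pp = pp,
                 ml_state = AA_ALPHA[ml_idx],
                 ml_pp = pp[cbind(seq_len(S), ml_idx)]),
            class = "ancestral_posterior")
}

#' @export
print.ancestral_posterior <- function(x, ...) {
  cat(sprintf("ancestral_posterior at node '%s': %d sites, mean ML PP %.3f\n",
              x$node, nrow(x$pp), mean(x$ml_pp)))
  invisible(x)
}

#' ML and AltAll ancestral sequences from a marginal posterior
#'
#' The ML sequence takes the maximum-posterior state per site (ties broken
#' in alphabetical amino-acid order and flagged). Ambiguously reconstructed
#' sites are those where any non-ML state has posterior probability
#' strictly greater than `alt_threshold`; the AltAll sequence carries the
#' second-best state at all of those sites simultaneously. Also reports the
#' mean posterior probability of each sequence and the expected number of
#' erroneously reconstructed sites, `sum(1 - ml_pp)`.
#'
#' @param posterior An `ancestral_posterior`.
#' @param alt_threshold Ambiguity cutoff on the best non-ML posterior
#'   (default 0.2, strict inequality).
#' @return Object of class `ancestral_sequence_set`.
#' @export
ancestral_sequences <- function(posterior, alt_threshold = 0.2) {
  stopifnot(inherits(posterior, "ancestral_posterior"))
  pp <- posterior$pp
  S <- nrow(pp)
  ml_idx <- max.col(pp, ties.method = "first")
  ties <- which(rowSums(pp == pp[cbind(seq_len(S), ml_idx)]) > 1L)
  ## best non-ML state per site
  pp2 <- pp
  pp2[cbind(seq_len(S), ml_idx)] <- -Inf
  alt_idx <- max.col(pp2, ties.method = "first")
  alt_pp <- pp2[cbind(seq_len(S), alt_idx)]
  ambiguous <- which(alt_pp > alt_threshold)
  alt_seq_idx <- ml_idx
  alt_seq_idx[ambiguous] <- alt_idx[ambiguous]
  ml_pp <- pp[cbind(seq_len(S), ml_idx)]
  structure(list(
    node = posterior$node,
    ml = paste(AA_ALPHA[ml_idx], collapse = ""),
    altall = paste(AA_ALPHA[alt_seq_idx], collapse = ""),
    ambiguous_sites = data.frame(
      site = ambiguous,
      ml_state = AA_ALPHA[ml_idx[ambiguous]],
      ml_pp = ml_pp[ambiguous],
      alt_state = AA_ALPHA[alt_idx[ambiguous]],
      alt_pp = alt_pp[ambiguous]),
    tied_sites = ties,
    mean_pp = mean(ml_pp),
    altall_mean_pp = mean(pp[cbind(seq_len(S), alt_seq_idx)]),
    expected_errors = sum(1 - ml_pp),
    alt_threshold = alt_threshold
  ), class = "ancestral_sequence_set")
}

#' @export
print.ancestral_sequence_set <- function(x, ...) {
  cat(sprintf("ancestral sequences at '%s'\n", x$node))
  cat("  ML:     ", x$ml, "\n  AltAll: ", x$altall, "\n", sep = "")
  cat(sprintf("  mean PP %.3f; %d ambiguous site(s) (PP > %.2f); expected errors %.2f\n",
              x$mean_pp, nrow(x$ambiguous_sites), x$alt_threshold,
              x$expected_errors))
  invisible(x)
}

#' List substitutions between two aligned ancestral sequences
#'
#' @param anc Ancestral (parent-node) sequence, string or character vector.
#' @param der Derived (child-node) sequence of equal length.
#' @return Data frame with columns `site`, `from`, `to`, `diagnostic`
#'   (initialised `NA`, filled by [flag_diagnostic()]), and a `label`
#'   column in the conventional lowercase-ancestral/uppercase-derived form
#'   (e.g. `"q50K"`).
#' @export
count_substitutions <- function(anc, der) {
  a <- if (length(anc) == 1L) strsplit(anc, "")[[1]] else anc
  d <- if (length(der) == 1L) strsplit(der, "")[[1]] else der
  if (length(a) != length(d))
    stop("sequences differ in length (", length(a), " vs ", length(d), ")")
  i <- which(a != d)
  data.frame(site = i, from = a[i], to = d[i],
             diagnostic = rep(NA, length(i)),
             label = paste0(tolower(a[i]), i, toupper(d[i])))
}

#' Flag phylogenetically diagnostic substitutions
#'
#' A substitution is diagnostic when its derived state is present and
#' identical in every extant sequence of the descendant clade at that
#' alignment column (a gap in any clade member means not conserved).
#'
#' @param subs Substitution table from [count_substitutions()].
#' @param aln The extant [amino_alignment()].
#' @param tree The `phylo` tree the clade is defined on.
#' @param clade Internal-node label of the descendant clade, or a character
#'   vector of tip names (checked for monophyly on `tree`).
#' @return `subs` with the `diagnostic` column filled in (logical).
#' @export
flag_diagnostic <- function(subs, aln, tree, clade) {
  if (length(clade) == 1L && !clade %in% rownames(aln)) {
    tips <- ape::extract.clade(tree, .node_number(tree, clade))$tip.label
  } else {
    tips <- clade
    if (!all(tips %in% tree$tip.label))
      stop("unknown tip name(s): ",
           paste(setdiff(tips, tree$tip.label), collapse = ", "))
    if (length(tips) > 1L && !ape::is.monophyletic(tree, tips))
      stop("supplied tips are not monophyletic on the tree")
  }
  sub_aln <- unclass(aln)[tips, , drop = FALSE]
  subs$diagnostic <- vapply(seq_len(nrow(subs)), function(i) {
    col <- sub_aln[, subs$site[i]]
    all(col == subs$to[i])
  }, logical(1))
  subs
}
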