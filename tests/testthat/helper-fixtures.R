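# Shared fixtures, all built in code.

quartet_tree <- function() {
  ape::read.tree(
    text = "((t1:0.1,t2:0.23)n1:0.12,(t3:0.3,t4:0.05)n2:0.08)r;")
}

five_taxon_tree <- function() {
  ape::read.tree(text = paste0(
    "(((t1:0.15,t2:0.12)n1:0.1,t3:0.3)n2:0.08,",
    "(t4:0.2,t5:0.12)n3:0.12)r;"))
}

# Brute-force tree likelihood + marginal posterior at a chosen internal
# node, by full enumeration of internal-state assignments (independent of
# the pruning code path except for transition_prob, the shared primitive).
brute_force_quartet <- function(aln, tree, model, node_label = NULL) {
  A <- unclass(aln)
  S <- ncol(A)
  aa <- sort(rownames(lg_exchangeabilities()))
  ntip <- length(tree$tip.label)
  labs <- tree$node.label
  edge <- tree$edge
  elen <- tree$edge.length
  pi <- model$pi
  node_ids <- (ntip + 1L):(ntip + tree$Nnode)
  root <- ntip + 1L
  want <- if (is.null(node_label)) NA_integer_ else
    ntip + match(node_label, labs)
  total <- numeric(S)
  post <- matrix(0, S, 20L)
  n_int <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(1:20), n_int)))
  for (k in seq_len(model$k)) {
    P <- lapply(elen, function(b) transition_prob(model, b * model$rates[k]))
    for (s in seq_len(S)) {
      tipstate <- match(A[, s], aa)[match(tree$tip.label, rownames(A))]
      for (g in seq_len(nrow(grid))) {
        st <- c(tipstate, grid[g, ])
        lik <- pi[st[root]]
        for (e in seq_len(nrow(edge))) {
          p <- st[edge[e, 1L]]; ch <- st[edge[e, 2L]]
          ## gap tip (NA state): marginalise, contributing sum(P) = 1
          lik <- lik * (if (is.na(ch)) sum(P[[e]][p, ]) else P[[e]][p, ch])
          if (lik == 0) break
        }
        w <- lik * model$weights[k]
        total[s] <- total[s] + w
        if (!is.na(want))
          post[s, grid[g, want - ntip]] <- post[s, grid[g, want - ntip]] + w
      }
    }
  }
  list(loglik = sum(log(total)),
       posterior = if (is.na(want)) NULL else post / total)
}

# Tiny deterministic probe table for E-score oracles.
toy_probes <- function() {
  data.frame(
    probe_id = sprintf("p%02d", 1:12),
    sequence = c(
      "TAATCCGATAGC", "GCTAATCCGTAC", "ACGTAATCCGGT", "TTGATAATCCAA",
      "CCGGATTAGCAT", "ATGGATTACGCA",
      "ACGTACGTACGT", "GGGTTTCCCAAA", "CATGCATGCATG", "AGCTAGCTAGCT",
      "TTTTGGGGCCCC", "ACACGTGTGCAC"),
    intensity = c(90, 85, 80, 75, 70, 65, 30, 28, 26, 24, 22, 20))
}
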