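# Marginal ancestral reconstruction, AltAll, substitution accounting.

test_that("marginal posteriors match brute-force enumeration", {
  m <- lg_gamma_model(alpha = 0.6, k = 3)
  tr <- quartet_tree()
  sim <- simulate_alignment(tr, m, 2, seed = 11)
  for (nd in c("n1", "n2", "r")) {
    bf <- brute_force_quartet(sim$alignment, tr, m, node_label = nd)
    po <- marginal_posteriors(sim$alignment, tr, m, nd)
    expect_equal(max(abs(po$pp - bf$posterior)), 0, tolerance = 1e-10)
    expect_equal(rowSums(po$pp), rep(1, 2), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("zero-length branches pin the posterior to the tip state", {
  m <- lg_gamma_model(alpha = 1, k = 2)
  tr <- quartet_tree()
  tr$edge.length[] <- 0
  aln <- amino_alignment(c(t1 = "K", t2 = "K", t3 = "K", t4 = "K"))
  for (nd in c("n1", "n2", "r")) {
    po <- marginal_posteriors(aln, tr, m, nd)
    expect_equal(unname(po$pp[1, "K"]), 1, tolerance = 1e-12)
    expect_identical(po$ml_state, "K")
  }
  expect_error(marginal_posteriors(aln, tr, m, "nope"),
               "available labels")
})

test_that("ML/AltAll sequences follow the ambiguity rule", {
  ## hand-built posterior: site 1 unambiguous; site 2 has a 0.3
  ## alternative; site 3 has an alternative at exactly 0.20 (strict rule:
  ## not ambiguous)
  pp <- matrix(0, 3, 20, dimnames = list(NULL, sort(rownames(
    lg_exchangeabilities()))))
  pp[1, "K"] <- 1
  pp[2, "K"] <- 0.6; pp[2, "Q"] <- 0.3; pp[2, "R"] <- 0.1
  pp[3, "M"] <- 0.8; pp[3, "R"] <- 0.2
  po <- structure(list(node = "x", pp = pp,
                       ml_state = c("K", "K", "M"),
                       ml_pp = c(1, 0.6, 0.8)),
                  class = "ancestral_posterior")
  s <- ancestral_sequences(po, alt_threshold = 0.2)
  expect_identical(s$ml, "KKM")
  expect_identical(s$altall, "KQM")
  expect_identical(s$ambiguous_sites$site, 2L)
  expect_identical(s$ambiguous_sites$alt_state, "Q")
  expect_equal(s$mean_pp, mean(c(1, 0.6, 0.8)))
  expect_equal(s$expected_errors, 0 + 0.4 + 0.2)
  ## fully resolved posterior: AltAll equals ML, no expected errors
  pp0 <- pp; pp0[] <- 0; pp0[cbind(1:3, c(1, 2, 3))] <- 1
  po0 <- structure(list(node = "x", pp = pp0,
                        ml_state = colnames(pp0)[1:3],
                        ml_pp = rep(1, 3)),
                   class = "ancestral_posterior")
  s0 <- ancestral_sequences(po0)
  expect_identical(s0$ml, s0$altall)
  expect_equal(nrow(s0$ambiguous_sites), 0L)
  expect_equal(s0$expected_errors, 0)
})

test_that("ML sequence mean PP is never below AltAll mean PP", {
  m <- lg_gamma_model(alpha = 0.8, k = 4)
  tr <- five_taxon_tree()
  for (seed in 1:5) {
    sim <- simulate_alignment(tr, m, 40, seed = seed)
    for (nd in c("n1", "n2", "n3")) {
      s <- ancestral_sequences(
        marginal_posteriors(sim$alignment, tr, m, nd))
      expect_gte(s$mean_pp, s$altall_mean_pp)
    }
  }
})

test_that("ancestral states are recovered on short-branch simulations", {
  ## every branch <= 0.1 substitutions/site: recovery above 95%
  tr <- five_taxon_tree()
  tr$edge.length <- pmin(tr$edge.length, 0.1)
  m <- lg_gamma_model(alpha = 0.9, k = 4)
  sim <- simulate_alignment(tr, m, 1000, seed = 9)
  for (nd in c("n1", "n2", "n3")) {
    po <- marginal_posteriors(sim$alignment, tr, m, nd)
    truth <- strsplit(sim$node_sequences[[nd]], "")[[1]]
    expect_gt(mean(po$ml_state == truth), 0.95)
  }
})

test_that("substitution lists and diagnostic flags are correct", {
  expect_equal(nrow(count_substitutions("KQRM", "KQRM")), 0L)
  s <- count_substitutions("KARNDE", "KTRNDQ")
  expect_identical(s$site, c(2L, 6L))
  expect_identical(s$label, c("a2T", "e6Q"))
  expect_error(count_substitutions("KK", "K"), "length")
  ## constructed clade: derived state conserved in all members at site 2
  ## but reverted in one member at site 6
  aln <- amino_alignment(c(b1 = "KTRNDQ", b2 = "KTRNDQ", b3 = "KTRNDE",
                           z1 = "KARNDE", z2 = "KARNDE"))
  tr <- ape::read.tree(
    text = "((b1:1,(b2:1,b3:1):1)B:1,(z1:1,z2:1)Z:1)r;")
  fl <- flag_diagnostic(s, aln, tr, "B")
  expect_identical(fl$diagnostic, c(TRUE, FALSE))
  ## single-member clade carrying the derived state is diagnostic
  fl1 <- flag_diagnostic(s, aln, tr, c("b1"))
  expect_identical(fl1$diagnostic, c(TRUE, TRUE))
  ## a gap in the clade at the site means not conserved
  aln2 <- amino_alignment(c(b1 = "KTRNDQ", b2 = "K-RNDQ", b3 = "KTRNDQ",
                            z1 = "KARNDE", z2 = "KARNDE"))
  fl2 <- flag_diagnostic(s, aln2, tr, "B")
  expect_identical(fl2$diagnostic, c(FALSE, TRUE))
  ## non-monophyletic tip set is rejected
  expect_error(flag_diagnostic(s, aln, tr, c("b1", "z1")),
               "monophyletic")
})

test_that("optimization improves the likelihood and is a fixed point", {
  m <- lg_gamma_model(alpha = 0.9, k = 4)
  tr <- quartet_tree()
  sim <- simulate_alignment(tr, m, 200, seed = 2)
  tr0 <- tr; tr0$edge.length[] <- 0.05
  ll0 <- tree_log_likelihood(sim$alignment, tr0, m)
  opt <- optimize_parameters(sim$alignment, tr0, m, fit_shape = TRUE)
  expect_gte(opt$loglik, ll0)
  expect_true(opt$converged)
  ## re-optimizing from the optimum barely moves the likelihood
  opt2 <- optimize_parameters(sim$alignment, opt$tree, opt$model,
                              fit_shape = TRUE)
  expect_lt(abs(opt2$loglik - opt$loglik), 1e-4)
  ## identical sequences: all branch lengths collapse to the lower bound
  alnI <- amino_alignment(c(t1 = "KQRM", t2 = "KQRM", t3 = "KQRM",
                            t4 = "KQRM"))
  optI <- optimize_parameters(alnI, tr0, m, fit_shape = FALSE)
  expect_true(all(optI$tree$edge.length <= 1e-6))
})

test_that("optimizer agrees with an independent ML implementation", {
  skip_if_not_installed("phangorn")
  tr <- ape::read.tree(
    text = "((t1:0.15,t2:0.12)n1:0.14,(t3:0.25,t4:0.1)n2:0.06)r;")
  m <- lg_gamma_model(alpha = 0.9, k = 4)
  sim <- simulate_alignment(tr, m, 400, seed = 2)
  tr0 <- tr; tr0$edge.length[] <- 0.1
  opt <- optimize_parameters(sim$alignment, tr0, m, fit_shape = FALSE)
  chars <- t(vapply(alignment_sequences(sim$alignment),
                    function(s) strsplit(s, "")[[1]],
                    character(ncol(sim$alignment))))
  pd <- phangorn::phyDat(chars, type = "AA")
  ph <- phangorn::pml(ape::unroot(tr0), pd, model = "LG", k = 4,
                      shape = 0.9)
  ph <- phangorn::optim.pml(ph, optEdge = TRUE, optNni = FALSE,
                            control = phangorn::pml.control(
                              trace = 0, eps = 1e-8))
  expect_equal(opt$loglik, ph$logLik, tolerance = 1e-7)
  expect_equal(sum(opt$tree$edge.length), sum(ph$tree$edge.length),
               tolerance = 1e-4)
})

test_that("branch lengths are recovered from simulated data", {
  ## 4 taxa, 8000 sites (so ML sampling noise sits well inside the 15%
  ## band); the two root-adjacent edges are compared as their sum (only
  ## the sum is identifiable under a reversible model)
  tr <- ape::read.tree(
    text = "((t1:0.15,t2:0.12)n1:0.14,(t3:0.25,t4:0.1)n2:0.06)r;")
  m <- lg_gamma_model(alpha = 0.9, k = 4)
  sim <- simulate_alignment(tr, m, 8000, seed = 1)
  tr0 <- tr; tr0$edge.length[] <- 0.1
  opt <- optimize_parameters(sim$alignment, tr0, m, fit_shape = FALSE)
  est <- opt$tree$edge.length
  root_rows <- which(opt$tree$edge[, 1] == 5L)
  nonroot <- setdiff(seq_along(est), root_rows)
  expect_lt(max(abs(est[nonroot] / tr$edge.length[nonroot] - 1)), 0.15)
  expect_lt(abs(sum(est[root_rows]) / sum(tr$edge.length[root_rows]) - 1),
            0.15)
})
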