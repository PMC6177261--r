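# Rank-based E-scores, 6-mer averaging, correlations, clustering.

# Independent oracle: direct pairwise comparison count on the truncated
# top halves of foreground and background.
brute_escore <- function(kmer, probes, truncated = TRUE) {
  fg_mask <- grepl(kmer, probes$sequence) |
    grepl(revcomp(kmer), probes$sequence)
  fg <- probes$intensity[fg_mask]
  bg <- probes$intensity[!fg_mask]
  if (!length(fg) || !length(bg)) return(NA_real_)
  f <- if (truncated) ceiling(length(fg) / 2) else length(fg)
  b <- if (truncated) ceiling(length(bg) / 2) else length(bg)
  fgs <- sort(fg, decreasing = TRUE)[seq_len(f)]
  bgs <- sort(bg, decreasing = TRUE)[seq_len(b)]
  U <- sum(outer(fgs, bgs, ">")) + 0.5 * sum(outer(fgs, bgs, "=="))
  U / (f * b) - 0.5
}

test_that("E-scores match the brute-force rank statistic on a toy set", {
  probes <- toy_probes()
  for (trunc in c(TRUE, FALSE)) {
    tab <- compute_escores(probes, k = 8L, truncated = trunc)
    expected <- vapply(tab$kmer, brute_escore, numeric(1),
                       probes = probes, truncated = trunc)
    expect_equal(tab$escore, unname(expected), tolerance = 1e-12)
  }
})

test_that("complete separation gives the E-score bounds", {
  probes <- toy_probes()
  tab <- compute_escores(probes, 8L)
  ## TAATCC-containing probes all rank above the rest
  expect_equal(tab$escore[tab$kmer == canonical_kmer("TAATCCGA")], 0.5)
  ## reversing the intensities flips the sign exactly
  probes2 <- probes
  probes2$intensity <- rev(probes$intensity)
  tab2 <- compute_escores(probes2, 8L)
  expect_equal(tab2$escore[tab2$kmer == canonical_kmer("TAATCCGA")], -0.5)
  expect_true(all(tab$escore >= -0.5 & tab$escore <= 0.5))
})

test_that("E-scores are rank-invariant to monotone intensity transforms", {
  set.seed(42)
  probes <- simulate_pbm(motif_energy_model("TAATCC"), n_probes = 300,
                         noise_sd = 0.3, n_replicates = 1, seed = 8)
  t1 <- compute_escores(probes, 8L)
  for (f in list(function(x) x^3, function(x) log(x),
                 function(x) 5 * x + 2)) {
    p2 <- probes; p2$intensity <- f(probes$intensity)
    t2 <- compute_escores(p2, 8L)
    expect_equal(t1$escore, t2$escore, tolerance = 1e-12)
  }
})

test_that("a k-mer and its reverse complement share one record", {
  probes <- toy_probes()
  tab <- compute_escores(probes, 8L)
  expect_true(all(tab$kmer == canonical_kmer(tab$kmer)))
  expect_false(any(duplicated(tab$kmer)))
  ## probes rewritten as reverse complements give identical tables
  p_rc <- probes; p_rc$sequence <- revcomp(probes$sequence)
  tab_rc <- compute_escores(p_rc, 8L)
  m <- merge(as.data.frame(tab), as.data.frame(tab_rc), by = "kmer")
  expect_equal(m$escore.x, m$escore.y, tolerance = 1e-12)
})

test_that("content-independent intensities give near-zero mean E-score", {
  ## the untruncated rescaled rank-sum is exactly centred under the
  ## null; the truncated variant carries a small negative bias when
  ## foregrounds are sparse (see the methods vignette)
  means <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    probes <- data.frame(
      probe_id = sprintf("p%03d", 1:200),
      sequence = vapply(1:200, function(j)
        paste(sample(c("A", "C", "G", "T"), 24, replace = TRUE),
              collapse = ""), character(1)),
      intensity = exp(rnorm(200)))
    mean(compute_escores(probes, 8L, truncated = FALSE)$escore)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.02)
})

test_that("6-mer scores are containment means of 8-mer scores", {
  ## toy table of five 8-mers, verified against exhaustive listing
  kmers <- canonical_kmer(c("TAATCCGA", "ATAATCCG", "GGGGTAAT",
                            "ACGTACGT", "TTTTAAAA"))
  tab8 <- structure(
    data.frame(kmer = kmers, escore = c(0.5, 0.4, 0.2, -0.1, 0.05)),
    k = 8L, class = c("kmer_score_table", "data.frame"))
  tab6 <- sixmer_scores(tab8)
  ## exhaustive containment from first principles
  for (i in seq_len(nrow(tab6))) {
    six <- tab6$kmer[i]
    inside <- vapply(kmers, function(k8) {
      any(c(six, revcomp(six)) %in% c(substring(k8, 1:3, 6:8),
                                      substring(revcomp(k8), 1:3, 6:8)))
    }, logical(1))
    expect_equal(tab6$escore[i], mean(tab8$escore[inside]),
                 tolerance = 1e-12, label = six)
  }
  ## a 6-mer present in exactly one 8-mer inherits that score
  only <- tab6[tab6$n_parents == 1L, ]
  expect_gt(nrow(only), 0L)
  ## constancy: identical 8-mer scores propagate unchanged
  tabc <- tab8; tabc$escore <- rep(0.3, 5)
  expect_true(all(abs(sixmer_scores(tabc)$escore - 0.3) < 1e-12))
  ## linearity: affine rescale of inputs rescales outputs affinely
  taba <- tab8; taba$escore <- 2 * tab8$escore + 0.1
  expect_equal(sixmer_scores(taba)$escore, 2 * tab6$escore + 0.1,
               tolerance = 1e-12)
})

test_that("specificity correlations behave like Pearson r", {
  a <- structure(data.frame(kmer = c("AAAAAA", "CCCCCC", "GGGGGG"),
                            escore = c(0.4, 0.1, -0.2)),
                 k = 6L, class = c("kmer_score_table", "data.frame"))
  b <- a; b$escore <- -a$escore
  expect_equal(correlate_specificities(a, a), 1)
  expect_equal(correlate_specificities(a, b), -1)
  flat <- a; flat$escore <- rep(0.2, 3)
  expect_error(correlate_specificities(a, flat), "zero variance")
  other <- a; other$kmer <- c("AAAAAA", "CCCCCC", "TTTTTT")
  expect_error(correlate_specificities(a, other), "universe")
})

test_that("same-model constructs correlate above shuffled-model ones", {
  mo <- motif_energy_model("TAATCC")
  shuf <- motif_energy_model("CATCTA")  # same composition, shuffled
  p1 <- simulate_pbm(mo, n_probes = 600, noise_sd = 0.25,
                     n_replicates = 1, seed = 31)
  p2 <- simulate_pbm(mo, n_probes = 600, noise_sd = 0.25,
                     n_replicates = 1, seed = 32)
  p3 <- simulate_pbm(shuf, n_probes = 600, noise_sd = 0.25,
                     n_replicates = 1, seed = 33)
  s1 <- sixmer_scores(compute_escores(p1, 8L))
  s2 <- sixmer_scores(compute_escores(p2, 8L))
  s3 <- sixmer_scores(compute_escores(p3, 8L))
  common <- Reduce(intersect, list(s1$kmer, s2$kmer, s3$kmer))
  sub <- function(s) {
    out <- s[match(common, s$kmer), ]
    attr(out, "k") <- 6L
    class(out) <- c("kmer_score_table", "data.frame")
    out
  }
  r_same <- correlate_specificities(sub(s1), sub(s2))
  r_diff <- correlate_specificities(sub(s1), sub(s3))
  expect_gt(r_same, r_diff)
})

test_that("clustering separates planted motifs and finds their logos", {
  pA <- simulate_pbm(motif_energy_model("TAATTA"), n_probes = 3000,
                     noise_sd = 0, n_replicates = 1, seed = 21)
  pB <- simulate_pbm(motif_energy_model("TAATCC"), n_probes = 3000,
                     noise_sd = 0, n_replicates = 1, seed = 22)
  tabs <- list(A = compute_escores(pA, 8L), B = compute_escores(pB, 8L))
  cl <- cluster_profiles(tabs, threshold = 0.45)
  expect_length(unique(cl$cluster), 2L)
  ## each cluster is specific to one construct
  means <- t(vapply(sort(unique(cl$cluster)), function(g) {
    colMeans(cl$matrix[rownames(cl$matrix) %in%
                         names(cl$cluster)[cl$cluster == g], ,
                       drop = FALSE])
  }, numeric(2)))
  expect_true(all(apply(means, 1, max) > 0.4))
  expect_true(all(apply(means, 1, min) < 0.2))
  ## consensus logos display the planted hexamers (either strand)
  hexin <- function(hex) any(grepl(hex, cl$consensus) |
                               grepl(revcomp(hex), cl$consensus))
  expect_true(hexin("TAATTA"))
  expect_true(hexin("TAATCC"))
  ## every retained 8-mer sits in exactly one cluster
  expect_setequal(names(cl$cluster), rownames(cl$matrix))
  ## a threshold above the E-score ceiling leaves nothing
  expect_error(cluster_profiles(tabs, threshold = 0.51), "no 8-mer")
  ## two identical constructs: clustering degenerates gracefully, the
  ## two profile columns are identical and every 8-mer keeps one leaf
  cl2 <- cluster_profiles(list(x = tabs$A, y = tabs$A), threshold = 0.45)
  expect_equal(cl2$matrix[, "x"], cl2$matrix[, "y"])
  expect_false(any(duplicated(names(cl2$cluster))))
})
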