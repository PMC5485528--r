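mk_dm <- function(d, ids = rownames(d), positions = 1000L) {
  dimnames(d) <- list(ids, ids)
  structure(list(sample_ids = ids, diff_counts = d,
                 positions_used = positions, deletion_mode = "complete"),
            class = "distance_matrix")
}

two_taxon_tree <- function(t1, t2, labels = c("x", "y")) {
  structure(list(edge = matrix(c(3L, 1L, 3L, 2L), ncol = 2, byrow = TRUE),
                 edge.length = c(t1, t2), tip.label = labels, Nnode = 1L),
            class = "phylo")
}

test_that("three samples get the closed-form star tree", {
  d <- matrix(c(0, 6, 8, 6, 0, 10, 8, 10, 0), 3, 3)
  dm <- mk_dm(d, c("a", "b", "c"), positions = 100L)
  tr <- nj_tree(dm)
  expect_identical(ape::Ntip(tr), 3L)
  # three-point formulas on per-site distances
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (0.06 + 0.08 - 0.10) / 2, tolerance = 1e-12)
  expect_equal(unname(bl["b"]), (0.06 + 0.10 - 0.08) / 2, tolerance = 1e-12)
  expect_equal(unname(bl["c"]), (0.08 + 0.10 - 0.06) / 2, tolerance = 1e-12)
  expect_error(nj_tree(mk_dm(matrix(0, 2, 2), c("a", "b"))), "at least 3")
})

test_that("NJ recovers an additive four-taxon topology", {
  # tree ((a:2,b:3):4,(c:2,d:5)) in count units over 1000 sites
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 5
  d["a", "c"] <- d["c", "a"] <- 8
  d["a", "d"] <- d["d", "a"] <- 11
  d["b", "c"] <- d["c", "b"] <- 9
  d["b", "d"] <- d["d", "b"] <- 12
  d["c", "d"] <- d["d", "c"] <- 7
  # four-point oracle: ab|cd iff d(a,b)+d(c,d) is the smallest pairing
  sums <- c(ab_cd = d["a", "b"] + d["c", "d"],
            ac_bd = d["a", "c"] + d["b", "d"],
            ad_bc = d["a", "d"] + d["b", "c"])
  expect_identical(names(which.min(sums)), "ab_cd")
  tr <- nj_tree(mk_dm(d))
  expect_true(has_bipartition(tr, c("a", "b")))
  expect_true(all(tr$edge.length >= 0))
})

test_that("the published matrix groups the heart sample with the LA and Bremen skins", {
  dm <- auk_pairwise_table()
  tr <- nj_tree(dm)
  expect_true(has_bipartition(tr, c("MK134_Bremen", "MK136_LA",
                                    "LastGA2_Heart")))
  # the identical pair sits on a zero-length cherry
  expect_true(has_bipartition(tr, c("MK131_LastGA1", "MK135_Brussels")))
})

test_that("HKY likelihood reduces to the Jukes-Cantor closed form", {
  tr <- two_taxon_tree(0.05, 0.07)
  msa <- mk_msa(list(x = "A", y = "A"))
  pp <- phylo_params(kappa = 1, base_freqs = rep(0.25, 4))
  t <- 0.12
  expected <- log(0.25) + log(0.25 + 0.75 * exp(-4 * t / 3))
  expect_equal(hky_loglik(tr, msa, pp), expected, tolerance = 1e-10)
  # differing leaves
  msa2 <- mk_msa(list(x = "A", y = "G"))
  expected2 <- log(0.25) + log(0.25 - 0.25 * exp(-4 * t / 3))
  expect_equal(hky_loglik(tr, msa2, pp), expected2, tolerance = 1e-10)
})

test_that("pruning equals exhaustive internal-state summation", {
  set.seed(91)
  for (trial in 1:3) {
    tr <- ape::rtree(4, rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.01, 0.5)
    mat <- matrix(sample(c("A", "C", "G", "T"), 4 * 12, replace = TRUE),
                  nrow = 4, dimnames = list(tr$tip.label, NULL))
    rows <- apply(mat, 1, paste, collapse = "")
    msa <- mk_msa(as.list(rows))
    pi <- c(0.3, 0.25, 0.2, 0.25)
    kappa <- 3.2
    got <- hky_loglik(tr, msa, phylo_params(kappa = kappa, base_freqs = pi))
    want <- oracle_hky_loglik(tr, mat, kappa, pi)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("saturated branches converge to the base-frequency likelihood", {
  tr <- two_taxon_tree(20, 20)
  msa <- mk_msa(list(x = "AC", y = "GT"))
  pi <- c(0.3, 0.25, 0.2, 0.25)
  ll <- hky_loglik(tr, msa, phylo_params(kappa = 2, base_freqs = pi))
  want <- log(pi[1]) + log(pi[3]) + log(pi[2]) + log(pi[4])
  expect_equal(ll, want, tolerance = 1e-6)
})

test_that("likelihood is invariant to re-rooting and pattern order", {
  set.seed(92)
  tr <- ape::rtree(5, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.02, 0.3)
  mat <- matrix(sample(c("A", "C", "G", "T"), 5 * 200, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), nrow = 5,
                dimnames = list(tr$tip.label, NULL))
  rows <- apply(mat, 1, paste, collapse = "")
  msa <- mk_msa(as.list(rows))
  pp <- phylo_params(kappa = 2.5, base_freqs = c(0.3, 0.25, 0.2, 0.25))
  base_ll <- hky_loglik(tr, msa, pp)
  for (tip in tr$tip.label[1:3]) {
    rerooted <- ape::unroot(ape::root(tr, outgroup = tip))
    expect_equal(hky_loglik(rerooted, msa, pp), base_ll, tolerance = 1e-8)
  }
  # site-pattern compression: per-column sum equals whole-alignment value
  percol <- sum(vapply(seq_len(ncol(mat)), function(s) {
    m1 <- as.list(apply(mat[, s, drop = FALSE], 1, paste, collapse = ""))
    hky_loglik(tr, mk_msa(m1), pp)
  }, numeric(1)))
  expect_equal(base_ll, percol, tolerance = 1e-10)
})

test_that("branch optimisation improves the likelihood and finds fixed points", {
  set.seed(93)
  tr <- ape::rtree(5, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 0.2)
  mat <- matrix(sample(c("A", "C", "G", "T"), 5 * 300, replace = TRUE),
                nrow = 5, dimnames = list(tr$tip.label, NULL))
  rows <- apply(mat, 1, paste, collapse = "")
  msa <- mk_msa(as.list(rows))
  pp <- phylo_params(kappa = 2, base_freqs = rep(0.25, 4))
  start_ll <- hky_loglik(tr, msa, pp)
  fit <- optimize_branches(tr, msa, pp)
  expect_gte(fit$loglik, start_ll)
  # re-optimising an optimum moves the likelihood less than the tolerance
  fit2 <- optimize_branches(fit$tree, msa, pp, max_sweeps = 2L)
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-4)
})

test_that("identical sister sequences get zero-length terminal branches", {
  seqs <- list(a = rand_dna(400, 94), c = rand_dna(400, 95),
               d = rand_dna(400, 96))
  seqs$b <- seqs$a                      # identical pair, mirrors the
  seqs <- seqs[c("a", "b", "c", "d")]   # organ/skin match
  msa <- mk_msa(seqs)
  dm <- pairwise_diffs(msa)
  tr <- nj_tree(dm)
  fit <- optimize_branches(tr, msa, phylo_params(kappa = 2))
  bl <- setNames(fit$tree$edge.length,
                 ifelse(fit$tree$edge[, 2] <= 4,
                        fit$tree$tip.label[fit$tree$edge[, 2]], ""))
  expect_lt(bl["a"], 1e-5)
  expect_lt(bl["b"], 1e-5)
})

test_that("branch lengths are recovered on simulated alignments", {
  # simulate sites down a fixed 5-taxon tree under JC-like conditions
  set.seed(97)
  tr <- ape::read.tree(text = "((a:0.05,b:0.08):0.10,(c:0.06,d:0.04):0.09,e:0.12);")
  pi <- rep(0.25, 4)
  kappa <- 1
  Q <- oracle_hky_Q(kappa, pi)
  Pm <- lapply(tr$edge.length, function(t) oracle_expm(Q * t))
  S <- 15000L
  nt <- 5L
  states <- matrix(0L, nt + tr$Nnode, S)
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])
  states[root, ] <- sample.int(4L, S, replace = TRUE, prob = pi)
  ord <- order(tr$edge[, 1])               # parents before children here
  for (k in ord) {
    pa <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    P <- Pm[[k]]
    st <- states[pa, ]
    states[ch, ] <- vapply(seq_len(S), function(s)
      sample.int(4L, 1L, prob = P[st[s], ]), integer(1))
  }
  b <- c("A", "C", "G", "T")
  mat <- matrix(b[states[1:nt, ]], nrow = nt,
                dimnames = list(tr$tip.label, NULL))
  rows <- apply(mat, 1, paste, collapse = "")
  msa <- mk_msa(as.list(rows))
  start <- nj_tree(mk_dm(oracle_pairwise_diffs(mat, "complete"),
                         ids = tr$tip.label, positions = S))
  fit <- optimize_branches(start, msa,
                           phylo_params(kappa = 1, base_freqs = pi))
  # terminal branches within 20% relative error of truth
  true_bl <- setNames(tr$edge.length, ifelse(tr$edge[, 2] <= nt,
                                             tr$tip.label[tr$edge[, 2]], "I"))
  got_bl <- setNames(fit$tree$edge.length,
                     ifelse(fit$tree$edge[, 2] <= nt,
                            fit$tree$tip.label[fit$tree$edge[, 2]], "I"))
  for (tip in tr$tip.label)
    expect_lt(abs(got_bl[tip] - true_bl[tip]) / true_bl[tip], 0.20)
})

test_that("bootstrap support is reproducible and finds strong signal", {
  # planted 5-taxon alignment with one heavily supported split ab|cde
  set.seed(98)
  n_signal <- 200; n_noise <- 300
  cols <- character(0)
  base_pairs <- expand.grid(x = c("A", "C", "G", "T"),
                            y = c("A", "C", "G", "T"),
                            stringsAsFactors = FALSE)
  base_pairs <- base_pairs[base_pairs$x != base_pairs$y, ]
  sig <- base_pairs[sample.int(nrow(base_pairs), n_signal, replace = TRUE), ]
  mat <- rbind(a = c(sig$x, sample(c("A", "C", "G", "T"), n_noise, TRUE)),
               b = c(sig$x, sample(c("A", "C", "G", "T"), n_noise, TRUE)))
  mat <- rbind(mat,
               c = c(sig$y, sample(c("A", "C", "G", "T"), n_noise, TRUE)),
               d = c(sig$y, sample(c("A", "C", "G", "T"), n_noise, TRUE)),
               e = c(sig$y, sample(c("A", "C", "G", "T"), n_noise, TRUE)))
  rows <- apply(mat, 1, paste, collapse = "")
  msa <- mk_msa(as.list(rows))
  pp <- phylo_params(kappa = 2, n_bootstrap = 100L, seed = 5L)
  bs <- bootstrap_support(msa, pp)
  expect_true(has_bipartition(bs$fit$tree, c("a", "b")))
  # the ab|cde split is near-unanimous
  expect_gte(max(bs$support), 95)
  # identical seed, identical supports; different seed may differ
  bs2 <- bootstrap_support(msa, pp)
  expect_identical(bs$support, bs2$support)
  expect_identical(ape::write.tree(bs$tree), ape::write.tree(bs2$tree))
  # default replicate count follows the study design
  expect_identical(phylo_params()$n_bootstrap, 500L)
})

test_that("pruning agrees with an independent phylogenetics library", {
  skip_if_not_installed("phangorn")
  set.seed(99)
  tr <- ape::rtree(6, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.02, 0.4)
  mat <- matrix(sample(c("A", "C", "G", "T"), 6 * 150, replace = TRUE),
                nrow = 6, dimnames = list(tr$tip.label, NULL))
  rows <- apply(mat, 1, paste, collapse = "")
  msa <- mk_msa(as.list(rows))
  pi <- c(0.28, 0.24, 0.22, 0.26)
  kappa <- 2.7
  got <- hky_loglik(tr, msa, phylo_params(kappa = kappa, base_freqs = pi))
  dat <- phangorn::phyDat(mat, type = "DNA")
  fit <- phangorn::pml(tr, dat, bf = pi, Q = c(1, kappa, 1, 1, kappa, 1))
  expect_equal(got, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})
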