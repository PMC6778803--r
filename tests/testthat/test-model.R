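test_that("conditional gamete probabilities match the worked hexaploid case", {
  psi1 <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2, byrow = TRUE)
  for (r in c(0.1, 0.25)) {
    expect_equal(gamete_prob_given_config(c(1, 3, 5), c(1, 4, 6), psi1, r, 6),
                 (1 - r) * r^2 / 2^3)
    expect_identical(
      gamete_prob_given_config(c(1, 2, 5), c(1, 2, 5), psi1, r, 6), 0)
  }
  # l = 0 at r = 0 for a consistent parental gamete
  expect_equal(gamete_prob_given_config(c(1, 3, 5), c(1, 3, 5), psi1, 0, 6),
               1 / 2^3)
})

test_that("averaging over configurations reproduces the closed form", {
  for (m in c(2, 4, 6)) {
    cfgs <- oracle_matchings(m)
    ss <- oracle_subsets(m)
    set.seed(m)
    picks <- replicate(8, list(S1 = sample(ss, 1)[[1]], S2 = sample(ss, 1)[[1]]),
                       simplify = FALSE)
    for (r in c(0, 0.1, 0.25, 0.5)) {
      for (p in picks) {
        eq3 <- mean(vapply(cfgs, function(psi)
          gamete_prob_given_config(p$S1, p$S2, psi, r, m), numeric(1)))
        expect_equal(eq3, gamete_prob(p$S1, p$S2, r, m), tolerance = 1e-12)
      }
    }
  }
})

test_that("gamete probabilities normalize and reduce correctly", {
  for (m in c(2, 4, 6)) {
    ss <- oracle_subsets(m)
    for (r in c(0, 0.17, 0.5)) {
      tot <- sum(outer(seq_along(ss), seq_along(ss),
                       Vectorize(function(a, b)
                         gamete_prob(ss[[a]], ss[[b]], r, m))))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
  # diploid limit: parental (1-r)/2, recombinant r/2
  r <- 0.3
  expect_equal(gamete_prob(1, 1, r, 2), (1 - r) / 2)
  expect_equal(gamete_prob(1, 2, r, 2), r / 2)
})

test_that("gametic transition matrices are doubly stochastic and conditional", {
  for (m in c(2, 4, 6)) {
    for (r in c(0.01, 0.2, 0.5)) {
      Tm <- gametic_transition_matrix(r, m)
      expect_equal(rowSums(Tm), rep(1, nrow(Tm)), tolerance = 1e-12)
      expect_equal(colSums(Tm), rep(1, nrow(Tm)), tolerance = 1e-12)
    }
  }
  expect_equal(gametic_transition_matrix(0.2, 2),
               matrix(c(0.8, 0.2, 0.2, 0.8), 2), ignore_attr = TRUE)
  # Bayes: transition = joint / marginal (uniform marginal 1/n_gametes)
  m <- 4; r <- 0.23
  ss <- oracle_subsets(m)
  for (i in c(1, 4)) {
    joint <- vapply(ss, function(s2) gamete_prob(ss[[i]], s2, r, m),
                    numeric(1))
    expect_equal(gametic_transition_matrix(r, m)[i, ], joint / sum(joint),
                 tolerance = 1e-12)
  }
})

test_that("genotypic transitions factorize over parents and normalize", {
  m <- 4; r <- 0.12
  ng <- choose(m, m / 2)
  Tm <- gametic_transition_matrix(r, m)
  set.seed(2)
  for (rep in 1:20) {
    i <- sample.int(ng, 1); h <- sample.int(ng, 1)
    i1 <- sample.int(ng, 1); h1 <- sample.int(ng, 1)
    expect_equal(genotypic_transition(genotype_index(i, h, m),
                                      genotype_index(i1, h1, m), r, m),
                 Tm[i, i1] * Tm[h, h1], tolerance = 1e-12)
  }
  for (m in c(2, 4)) {
    g <- choose(m, m / 2)^2
    j <- g - 1L
    row <- vapply(seq_len(g), function(j1)
      genotypic_transition(j, j1, 0.3, m), numeric(1))
    expect_equal(sum(row), 1, tolerance = 1e-12)
    # r = 0: identity over genotype states
    row0 <- vapply(seq_len(g), function(j1)
      genotypic_transition(j, j1, 0, m), numeric(1))
    expect_equal(row0, as.numeric(seq_len(g) == j))
  }
})

test_that("initial state is uniform over genotype states", {
  expect_equal(initial_state(1, 4), 1 / 36)
  expect_equal(initial_state(3, 2), 1 / 4)
  expect_equal(sum(initial_state(1:36, 4)), 1)
})

test_that("delta_dosage counts parental contributions separately", {
  m <- 4
  j <- genotype_index(gamete_rank(c(1, 3), m), gamete_rank(c(1, 4), m), m)
  expect_identical(delta_dosage(j, marker_phase(c(1, 2), 1, m), m), 2L)
  ph0 <- marker_phase(integer(0), integer(0), m)
  phF <- marker_phase(1:m, 1:m, m)
  expect_true(all(delta_dosage(1:36, ph0, m) == 0L))
  expect_true(all(delta_dosage(1:36, phF, m) == m))
})

test_that("emission functions behave as a symmetric error channel", {
  m <- 4
  expect_identical(emission_global_error(2, 2, 0, m), 1)
  expect_identical(emission_global_error(1, 2, 0, m), 0)
  eps <- 0.05
  # total probability over the m+1 observable classes
  expect_equal(emission_global_error(2, 2, eps, m) +
                 m * emission_global_error(0, 2, eps, m), 1)
  # the global-error emission is the prior emission with the matching prior
  pi1 <- c(eps / m, 1 - eps, eps / m, eps / m, eps / m)  # observed O = 1
  for (delta in 0:m) {
    expect_equal(emission_prior(delta, pi1),
                 emission_global_error(1, delta, eps, m))
  }
  pk <- c(0, 1 / 6, 2 / 3, 1 / 6, 0)
  expect_equal(emission_prior(2, pk), 2 / 3)
  expect_equal(emission_prior(0, pk), 0)
  expect_equal(emission_prior(3, rep(1 / (m + 1), m + 1)), 1 / (m + 1))
})

test_that("polysomic priors are hypergeometric convolutions", {
  expect_equal(polysomic_prior(0, 0, 4), c(1, 0, 0, 0, 0))
  expect_equal(polysomic_prior(1, 0, 4), c(0.5, 0.5, 0, 0, 0))
  expect_equal(polysomic_prior(2, 0, 4), c(1 / 6, 4 / 6, 1 / 6, 0, 0))
  # independent oracle: enumerate transmitted subsets directly
  for (m in c(2, 4, 6)) {
    ss <- oracle_subsets(m)
    set.seed(m)
    for (rep in 1:5) {
      dP <- sample(0:m, 1); dQ <- sample(0:m, 1)
      phiP <- seq_len(dP); phiQ <- seq_len(dQ)
      tab <- numeric(m + 1)
      for (sP in ss) for (sQ in ss) {
        d <- length(intersect(phiP, sP)) + length(intersect(phiQ, sQ))
        tab[d + 1] <- tab[d + 1] + 1 / length(ss)^2
      }
      expect_equal(polysomic_prior(dP, dQ, m), tab, tolerance = 1e-12)
    }
  }
})

test_that("feasible dosage classes match the u-operator count and support", {
  expect_length(feasible_dosage_classes(2, 3, 6), 6)
  expect_identical(feasible_dosage_classes(0, 0, 4), 0L:0L)
  expect_identical(feasible_dosage_classes(2, 2, 4), 0:4)
  for (m in c(2, 4, 6, 8)) {
    for (dP in 0:m) {
      for (dQ in 0:m) {
        feas <- feasible_dosage_classes(dP, dQ, m)
        u <- function(x) abs(abs(x - m / 2) - m / 2)
        expect_length(feas, u(dP) + u(dQ) + 1)
        expect_identical(which(polysomic_prior(dP, dQ, m) > 1e-14) - 1L,
                         as.integer(feas))
      }
    }
  }
})

test_that("dosage marginals are uniform-in-state but not independent at r = 0.5", {
  # the bivalent-partition constraint correlates loci even at r = 0.5:
  # transition rows are (1/2)^(m/2)/choose(m/2, l), not uniform
  Tm <- gametic_transition_matrix(0.5, 4)
  expect_equal(Tm[1, 1], 1 / 4)           # l = 0
  expect_equal(Tm[1, 2], 1 / 8)           # l = 1
  expect_false(isTRUE(all.equal(Tm[1, ], rep(1 / 6, 6))))
  # but the one-locus marginal stays uniform
  expect_equal(colSums(Tm) / 6, rep(1 / 6, 6), tolerance = 1e-12)
})
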