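# helper: build a chain_model from a simulated population
chain_from_sim <- function(sim, epsilon = 0, r_init = NULL) {
  ds <- sim$dataset
  m <- ds$m
  pri <- polyphase:::dataset_priors(ds, epsilon = epsilon)
  tolist <- function(H) lapply(seq_len(ncol(H)), function(k) which(H[, k] == 1L))
  if (is.null(r_init)) r_init <- rep(0.01, ds$n_mrk - 1L)
  chain_model(tolist(sim$truth$HP), tolist(sim$truth$HQ), r_init, pri, m)
}

test_that("diploid three-marker likelihood equals brute-force path sums", {
  m <- 2
  sim <- simulate_population(sim_config(m, n = 12, z = 3,
                                        distances = c(5, 10), seed = 21))
  ch <- chain_from_sim(sim, r_init = c(0.07, 0.13))
  fb <- forward_backward(ch)
  # oracle: enumerate all 4^3 genotype paths per individual
  g <- 4
  pri <- polyphase:::dataset_priors(sim$dataset)
  tolist <- function(H) lapply(seq_len(ncol(H)), function(k) which(H[, k] == 1L))
  phiP <- tolist(sim$truth$HP); phiQ <- tolist(sim$truth$HQ)
  for (ind in 1:12) {
    tot <- 0
    for (j1 in 1:g) for (j2 in 1:g) for (j3 in 1:g) {
      em <- prod(vapply(1:3, function(k) {
        ph <- marker_phase(phiP[[k]], phiQ[[k]], m)
        d <- delta_dosage(c(j1, j2, j3)[k], ph, m)
        pri[d + 1, k, ind]
      }, numeric(1)))
      tot <- tot + (1 / g) * genotypic_transition(j1, j2, 0.07, m) *
        genotypic_transition(j2, j3, 0.13, m) * em
    }
    expect_equal(fb$loglik_ind[ind], log(tot), tolerance = 1e-10)
  }
})

test_that("forward-backward identities and scaling hold", {
  m <- 4
  sim <- simulate_population(sim_config(m, n = 30, z = 5, seed = 31))
  ch <- chain_from_sim(sim)
  fb <- forward_backward(ch)
  # sum_j alpha_k beta_k = 1 at every marker under this scaling
  for (k in 1:5) {
    expect_equal(colSums(fb$alpha[[k]] * fb$beta[[k]]), rep(1, 30),
                 tolerance = 1e-10)
  }
  # uniform priors: loglik = n * z * log(1/(m+1))
  pri_u <- array(1 / (m + 1), dim = c(m + 1, 5, 30))
  tolist <- function(H) lapply(seq_len(ncol(H)), function(k) which(H[, k] == 1L))
  ch_u <- chain_model(tolist(sim$truth$HP), tolist(sim$truth$HQ),
                      rep(0.01, 4), pri_u, m)
  fb_u <- forward_backward(ch_u)
  expect_equal(fb_u$loglik, 30 * 5 * log(1 / (m + 1)), tolerance = 1e-9)
  # genotype posteriors normalize; uniform when emissions are uninformative
  po <- genotype_posterior(ch_u, fb_u)
  expect_equal(colSums(po[[3]]), rep(1, 30), tolerance = 1e-12)
  expect_equal(max(abs(po[[1]] - 1 / 36)), 0, tolerance = 1e-12)
})

test_that("likelihood is invariant under chain reversal", {
  m <- 4
  sim <- simulate_population(sim_config(m, n = 40, z = 6, seed = 41))
  ch <- chain_from_sim(sim, r_init = seq(0.01, 0.06, length.out = 5))
  fb <- forward_backward(ch)
  pri <- polyphase:::dataset_priors(sim$dataset)
  tolist <- function(H) lapply(seq_len(ncol(H)), function(k) which(H[, k] == 1L))
  z <- 6
  ch_rev <- chain_model(rev(tolist(sim$truth$HP)), rev(tolist(sim$truth$HQ)),
                        rev(ch$r), pri[, z:1, , drop = FALSE], m)
  fb_rev <- forward_backward(ch_rev)
  expect_equal(fb$loglik, fb_rev$loglik, tolerance = 1e-8)
})

test_that("state-pair posteriors normalize, marginalize and localize", {
  m <- 2
  sim <- simulate_population(sim_config(m, n = 25, z = 3,
                                        distances = c(2, 2), seed = 51))
  ch <- chain_from_sim(sim)
  fb <- forward_backward(ch)
  for (ind in c(1, 13)) {
    xi <- state_pair_posterior(ch, fb, 1, ind)
    expect_equal(sum(xi), 1, tolerance = 1e-12)
    expect_true(all(xi >= 0))
    # marginal over the second state equals the single-state posterior
    po <- genotype_posterior(ch, fb)
    expect_equal(rowSums(xi), po[[1]][, ind], tolerance = 1e-10)
  }
  # when observed dosages pin the states uniquely (0 = both recessive
  # gametes, 2 = both dominant at a simplex/simplex diploid marker),
  # xi is a point mass on the true pair
  dos <- sim$dataset$dosages
  pin <- which(dos[1, ] %in% c(0, 2) & dos[2, ] %in% c(0, 2))
  if (length(pin)) {
    ind <- pin[1]
    xi <- state_pair_posterior(ch, fb, 1, ind)
    expect_equal(max(xi), 1, tolerance = 1e-9)
  }
})

test_that("EM updates are monotone and recover simulated parameters", {
  m <- 4
  sim <- simulate_population(sim_config(m, n = 200, z = 10, seed = 61,
                                        scenario = "A"))
  ch <- chain_from_sim(sim)
  ft <- fit_chain(ch, tol = 1e-5)
  expect_true(all(diff(ft$trace) > -1e-6))
  rms <- map_rms_distance(haldane_cM(ft$r), haldane_cM(sim$truth$r))
  expect_lt(rms, 1)        # sub-centimorgan recovery at n = 200
  # r = 0 data drive the estimate to the lower clamp
  sim0 <- simulate_population(sim_config(m, n = 60, z = 3,
                                         distances = 1e-9, seed = 62))
  ft0 <- fit_chain(chain_from_sim(sim0, r_init = c(0.1, 0.1)),
                   tol = 1e-7, max_iter = 5000)
  expect_true(all(ft0$r < 1e-5))
})

test_that("a two-marker chain fit equals the two-point estimate", {
  m <- 4
  sim <- sim_two_markers(m, 300, 0.1, list(1:2, 1:2), list(1:3, c(1, 2, 4)), 71)
  ch <- chain_from_sim(sim, r_init = 0.25)
  ft <- fit_chain(ch, tol = 1e-9, max_iter = 5000)
  pri <- polyphase:::dataset_priors(sim$dataset)
  est <- twopoint_estimate(matrix(pri[, 1, ], m + 1),
                           matrix(pri[, 2, ], m + 1),
                           c(2, 2), c(3, 3), c(2, 2), m,
                           tol = 1e-9, max_iter = 5000)
  expect_equal(ft$r, est$r_hat, tolerance = 1e-4)
  expect_equal(ft$loglik, est$loglike, tolerance = 1e-6)
})

test_that("contradictory data at epsilon = 0 error or flag as requested", {
  m <- 4
  sim <- simulate_population(sim_config(m, n = 10, z = 3, seed = 81))
  ds <- sim$dataset
  # corrupt one observation to an infeasible class for its marker
  feas <- feasible_dosage_classes(ds$markers$dP[2], ds$markers$dQ[2], m)
  ds$dosages[2, 4] <- setdiff(0:m, feas)[1]
  pri <- polyphase:::dataset_priors(ds)
  tolist <- function(H) lapply(seq_len(ncol(H)), function(k) which(H[, k] == 1L))
  ch <- chain_model(tolist(sim$truth$HP), tolist(sim$truth$HQ),
                    rep(0.01, 2), pri, m)
  expect_error(forward_backward(ch, on_zero = "error"),
               "individual 4 at marker 2")
  fb <- forward_backward(ch, on_zero = "neginf")
  expect_identical(fb$loglik_ind[4], -Inf)
  expect_true(all(is.finite(fb$loglik_ind[-4])))
})
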