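test_that("canonical forms identify row-permutation equivalence", {
  set.seed(91)
  H <- matrix(rbinom(12, 1, 0.5), 4, 3)
  expect_identical(canonical_form(canonical_form(H)), canonical_form(H))
  # every row permutation maps to the same form
  library(utils)
  perms3 <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2))
  for (p in perms3) {
    expect_identical(canonical_form(H[p, ]), canonical_form(H))
  }
  # non-equivalent matrices map to distinct forms: exhaustive over all
  # permutations of a 4 x 3 pair differing by one dosage-preserving swap
  H2 <- H
  col <- which(colSums(H) %in% 1:3)[1]
  i1 <- which(H[, col] == 1)[1]; i0 <- which(H[, col] == 0)[1]
  H2[i1, col] <- 0L; H2[i0, col] <- 1L
  allperm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in allperm(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  equiv <- any(vapply(allperm(1:4), function(p)
    identical(H2[p, ], H), logical(1)))
  if (!equiv) {
    expect_false(identical(canonical_form(H2), canonical_form(H)))
  }
})

test_that("compare_phase accepts permutations and rejects real changes", {
  set.seed(92)
  HP <- matrix(rbinom(20, 1, 0.4), 4, 5)
  HQ <- matrix(rbinom(20, 1, 0.4), 4, 5)
  expect_true(all(compare_phase(HP, HQ, HP, HQ)))
  expect_true(all(compare_phase(HP[c(3, 1, 4, 2), ], HQ[c(2, 1, 4, 3), ],
                                HP, HQ)))
  # a dosage-preserving cell swap that changes the row multiset:
  # rows (1,1),(1,0),(0,0),(0,0) vs (1,0),(1,0),(0,1),(0,0)
  A1 <- matrix(c(1, 1, 0, 0,  1, 0, 0, 0), 4, 2)
  A2 <- matrix(c(1, 1, 0, 0,  0, 0, 1, 0), 4, 2)
  B <- matrix(rbinom(8, 1, 0.4), 4, 2)
  cmp <- compare_phase(A2, B, A1, B)
  expect_false(cmp[["P"]])
  expect_true(cmp[["Q"]])
  expect_error(compare_phase(HP[, 1:3], HQ, HP, HQ), "shapes")
})

test_that("candidate expansion respects eta and permutation redundancy", {
  m <- 4
  # with eta = Inf every subset assignment survives, modulo redundancy
  cand0 <- list(list(phiP = list(c(1, 2)), phiQ = list(1L),
                     r = numeric(0), loglik = NA_real_))
  profiles <- list(list(k = 1,
                        P = c(`0` = 0, `1` = 0, `2` = 0),
                        Q = c(`0` = 0, `1` = 0)))
  cfg <- phasing_config(eta = Inf, multipoint_lod = 10)
  ex <- extend_candidates(cand0, 2L, 1L, profiles, cfg, m)
  # P: subsets of size 2 against {1,2} have w = 0 (1 class), 1 (4), 2 (1);
  # redundancy leaves one representative per (wP, wQ) class here
  keyP <- vapply(ex, function(cc)
    length(intersect(cc$phiP[[2]], c(1, 2))), numeric(1))
  keyQ <- vapply(ex, function(cc)
    length(intersect(cc$phiQ[[2]], 1L)), numeric(1))
  expect_setequal(paste(keyP, keyQ), c("0 0", "0 1", "1 0", "1 1",
                                       "2 0", "2 1"))
  expect_length(ex, 6)
  # eta pruning: only wP = 2 and wQ = 1 partitions survive
  profiles2 <- list(list(k = 1,
                         P = c(`0` = 9, `1` = 9, `2` = 0),
                         Q = c(`0` = 9, `1` = 0)))
  cfg2 <- phasing_config(eta = 3)
  ex2 <- extend_candidates(cand0, 2L, 1L, profiles2, cfg2, m)
  expect_length(ex2, 1)
  expect_identical(ex2[[1]]$phiP[[2]], c(1L, 2L))
  expect_identical(ex2[[1]]$phiQ[[2]], 1L)
  # a null marker adds exactly one empty assignment
  ex3 <- extend_candidates(cand0, 0L, 0L, profiles, cfg, m)
  expect_length(ex3, 1)
  expect_length(ex3[[1]]$phiP[[2]], 0)
})

test_that("unpruned sequential search equals the exhaustive ML phase", {
  m <- 4
  set.seed(93)
  sim <- simulate_population(
    sim_config(m, n = 150, z = 3, distances = 2, seed = 94,
               dosP = c(1, 2, 1), dosQ = c(2, 1, 1), scenario = "C"))
  cfg <- phasing_config(eta = 1e6, multipoint_lod = 1e6,
                        max_candidates = 10000L, refresh_sweeps = 10L)
  map <- phase_chain(sim$dataset, config = cfg)
  # exhaustive oracle over all phase assignments, deduplicated by
  # canonical form, each fit by full EM
  ds <- sim$dataset
  pri <- polyphase:::dataset_priors(ds)
  subs <- function(d) if (d == 0) list(integer(0)) else
    lapply(seq_len(ncol(combn(m, d))), function(j) combn(m, d)[, j])
  best_ll <- -Inf; best <- NULL; seen <- character(0)
  for (p1 in subs(ds$markers$dP[1])) for (p2 in subs(ds$markers$dP[2]))
    for (p3 in subs(ds$markers$dP[3]))
      for (q1 in subs(ds$markers$dQ[1])) for (q2 in subs(ds$markers$dQ[2]))
        for (q3 in subs(ds$markers$dQ[3])) {
          phiP <- list(p1, p2, p3); phiQ <- list(q1, q2, q3)
          key <- polyphase:::phase_key(phiP, phiQ, m)
          if (key %in% seen) next
          seen <- c(seen, key)
          ft <- fit_chain(chain_model(phiP, phiQ, c(0.02, 0.02), pri, m),
                          tol = 1e-5, on_zero = "neginf")
          if (ft$loglik > best_ll) {
            best_ll <- ft$loglik
            best <- list(phiP = phiP, phiQ = phiQ)
          }
        }
  cmp <- compare_phase(map$HP, map$HQ,
                       polyphase:::phase_to_H(best$phiP, m),
                       polyphase:::phase_to_H(best$phiQ, m))
  expect_true(all(cmp))
  # same maximum up to EM convergence depth
  expect_lt(abs(map$loglik - best_ll), 0.2)
})

test_that("single candidates and two-marker chains behave degenerately", {
  m <- 4
  sim <- sim_two_markers(m, 120, 0.05, list(1, 1), list(c(1, 2), c(1, 3)), 95)
  map <- phase_chain(sim$dataset, config = phasing_config(eta = 3))
  expect_equal(nrow(map$markers), 2)
  cmp <- compare_phase(map$HP, map$HQ, sim$truth$HP, sim$truth$HQ)
  expect_true(all(cmp))
  # score_and_prune retains a lone candidate with lod 0
  pri <- polyphase:::dataset_priors(sim$dataset)
  cand <- list(list(phiP = list(1L, 1L), phiQ = list(c(1L, 2L), c(1L, 3L)),
                    r = 0.05, loglik = NA_real_))
  out <- score_and_prune(cand, pri, phasing_config(), m)
  expect_length(out, 1)
  expect_equal(out[[1]]$lod, 0)
})

test_that("scenario-A chains are phased correctly end to end", {
  st <- run_simulation_study(m = 4, n_rep = 2, n = 200, z = 10,
                             scenario = "A",
                             config = phasing_config(eta = 3),
                             seed = 96)
  expect_true(all(st$correctP))
  expect_true(all(st$correctQ))
  expect_true(all(st$rms_cM < 2))
})
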