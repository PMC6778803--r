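# Independent oracles used across test files.  These deliberately avoid the
# package's own combinatorial machinery: matchings are generated from raw
# permutations, transition tables by direct subset arithmetic.

# All perfect matchings of 1..m via brute-force permutations, canonicalized
# as sorted lists of sorted pairs.
oracle_matchings <- function(m) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  seen <- new.env()
  for (p in perms(seq_len(m))) {
    pairs <- matrix(p, ncol = 2L, byrow = TRUE)
    pairs <- t(apply(pairs, 1L, sort))
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    assign(paste(t(pairs), collapse = "-"), pairs, envir = seen)
  }
  lapply(ls(seen), get, envir = seen)
}

# All size-(m/2) subsets of 1..m in lexicographic order, as a list.
oracle_subsets <- function(m) {
  cols <- combn(m, m / 2)
  lapply(seq_len(ncol(cols)), function(j) cols[, j])
}

# Full genotype transition matrix at ploidy m by direct subset arithmetic
# (row j = (i-1)*ng + h as in the package layout docs, but built without
# the package's rank/index helpers).
oracle_genotype_transition <- function(r, m) {
  ss <- oracle_subsets(m)
  ng <- length(ss)
  gam <- matrix(0, ng, ng)
  for (i in seq_len(ng)) {
    for (i1 in seq_len(ng)) {
      l <- m / 2 - length(intersect(ss[[i]], ss[[i1]]))
      gam[i, i1] <- (1 - r)^(m / 2 - l) * r^l / choose(m / 2, l)
    }
  }
  kronecker(gam, gam)   # index (i-1)*ng + h: P slow, Q fast
}

# Dosage implied by genotype state j under explicit phase subsets.
oracle_delta <- function(j, phiP, phiQ, m) {
  ss <- oracle_subsets(m)
  ng <- length(ss)
  i <- (j - 1) %/% ng + 1
  h <- (j - 1) %% ng + 1
  length(intersect(phiP, ss[[i]])) + length(intersect(phiQ, ss[[h]]))
}

# Brute-force collapsed dosage table (aggregating the full g x g genotype
# transition space with uniform initial state) for explicit phase subsets.
oracle_collapsed <- function(phiPk, phiPk1, phiQk, phiQk1, r, m) {
  Tg <- oracle_genotype_transition(r, m)
  g <- nrow(Tg)
  d1 <- vapply(seq_len(g), oracle_delta, numeric(1), phiPk, phiQk, m)
  d2 <- vapply(seq_len(g), oracle_delta, numeric(1), phiPk1, phiQk1, m)
  A <- matrix(0, m + 1, m + 1)
  for (j in seq_len(g)) {
    for (j1 in seq_len(g)) {
      A[d1[j] + 1, d2[j1] + 1] <- A[d1[j] + 1, d2[j1] + 1] + Tg[j, j1] / g
    }
  }
  A
}

# Representative phase subsets for a sharing value, chosen differently from
# the package's canonical representative (allele blocks at the *end* of the
# homolog list), so collapse tests double as partition-invariance tests.
oracle_representative <- function(d1, d2, w, m) {
  phi1 <- if (d1 > 0) (m - d1 + 1):m else integer(0)
  shared <- if (w > 0) (m - w + 1):m else integer(0)
  rest <- setdiff(m:1, phi1)[seq_len(d2 - w)]
  list(phi1 = phi1, phi2 = sort(c(shared, rest)))
}

# Indicator prior matrix from hard dosage calls.
indicator_priors <- function(obs, m) {
  p <- matrix(0, m + 1, length(obs))
  p[cbind(obs + 1L, seq_along(obs))] <- 1
  p
}

# Tiny two-marker simulated dataset used by several files.
sim_two_markers <- function(m, n, r, HPcols, HQcols, seed) {
  HP <- matrix(0L, m, 2)
  HQ <- matrix(0L, m, 2)
  HP[HPcols[[1]], 1] <- 1L; HP[HPcols[[2]], 2] <- 1L
  HQ[HQcols[[1]], 1] <- 1L; HQ[HQcols[[2]], 2] <- 1L
  simulate_population(
    sim_config(m, n = n, z = 2, distances = haldane_cM(r), seed = seed),
    parents = list(HP = HP, HQ = HQ))
}
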