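# Two-marker engine: the g_m genotype states are collapsed into (m+1)^2
# dosage cells, the recombination fraction is estimated per linkage-phase
# partition by EM, and LOD scores are computed for linkage (vs r = 0.5) and
# phase (vs the best-scoring partition).
#
# A linkage-phase partition for a marker pair is indexed per parent by the
# sharing value w: the number of homologs carrying the counted allele at
# both loci.  Any representative pair of homolog subsets with that sharing
# value yields the same collapsed table, so one canonical representative is
# used per partition.

#' Sharing values compatible with two marker dosages
#'
#' The possible numbers of homologs carrying the counted allele at both of
#' two loci in one parent, given the locus dosages: the contiguous range
#' \code{max(0, dk + dk1 - m) .. min(dk, dk1)}, which contains
#' \eqn{\min\{u(d_k), u(d_{k'})\} + 1} values.
#'
#' @param dk,dk1 parental dosages of the two markers, in \code{0..m}.
#' @inheritParams ploidy_context
#' @return increasing integer vector of sharing values.
#' @export
enumerate_sharing_values <- function(dk, dk1, m) {
  m <- check_ploidy(m)
  stopifnot(dk >= 0, dk <= m, dk1 >= 0, dk1 <= m)
  max(0, dk + dk1 - m):min(dk, dk1)
}

# Canonical representative pair of homolog subsets for sharing value w.
sharing_representative <- function(dk, dk1, w, m) {
  if (!(w %in% enumerate_sharing_values(dk, dk1, m))) {
    stop("sharing value ", w, " impossible for dosages (", dk, ", ", dk1,
         ") at ploidy ", m, call. = FALSE)
  }
  list(phi1 = seq_len(dk),
       phi2 = c(seq_len(w), if (dk1 > w) dk + seq_len(dk1 - w)))
}

# Count array for one parent and one phase pair: N[a+1, a1+1, l+1] is the
# number of ordered gamete-state pairs whose dosage contributions at the
# two loci are (a, a1) and whose recombinant-bivalent count is l.
# Cached per (m, dk, dk1, w); dimensions (m/2+1)^3.
parent_pair_counts <- function(dk, dk1, w, m) {
  key <- paste0("ppc_", m, "_", dk, "_", dk1, "_", w)
  cache_get(key, function() {
    rep_ <- sharing_representative(dk, dk1, w, m)
    ng <- choose(m, m / 2)
    d1 <- delta_profile(rep_$phi1, m)
    d2 <- delta_profile(rep_$phi2, m)
    L <- recomb_count_matrix(m)
    a  <- rep(d1, times = ng)
    a1 <- rep(d2, each = ng)
    l  <- as.vector(t(L))          # L symmetric; orientation irrelevant
    K <- m / 2 + 1L
    idx <- 1L + a + a1 * K + l * K * K
    array(tabulate(idx, nbins = K^3), dim = c(K, K, K))
  })
}

# Same counts for an explicit (non-representative) phase pair; used to test
# partition invariance.
parent_pair_counts_explicit <- function(phi1, phi2, m) {
  ng <- choose(m, m / 2)
  d1 <- delta_profile(phi1, m)
  d2 <- delta_profile(phi2, m)
  L <- recomb_count_matrix(m)
  K <- m / 2 + 1L
  idx <- 1L + rep(d1, times = ng) + rep(d2, each = ng) * K +
    as.vector(t(L)) * K * K
  array(tabulate(idx, nbins = K^3), dim = c(K, K, K))
}

# Full 2-D convolution of two matrices (supports of parental dosage
# contributions); sizes are at most (m/2+1)^2 so direct loops suffice.
conv2d <- function(X, Y) {
  out <- matrix(0, nrow(X) + nrow(Y) - 1L, ncol(X) + ncol(Y) - 1L)
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      if (Y[i, j] != 0) {
        out[i:(i + nrow(X) - 1L), j:(j + ncol(X) - 1L)] <-
          out[i:(i + nrow(X) - 1L), j:(j + ncol(X) - 1L)] + Y[i, j] * X
      }
    }
  }
  out
}

# Per-parent joint gamete-dosage table at the two loci, plus the same table
# weighted by the recombinant count (for EM E-steps).
parent_joint <- function(N, r, m) {
  K <- m / 2 + 1L
  f <- (1 - r)^(m / 2 - (0:(K - 1L))) * r^(0:(K - 1L)) /
    choose(m / 2, 0:(K - 1L))
  A <- matrix(0, K, K); Lw <- matrix(0, K, K)
  for (l in seq_len(K)) {
    A  <- A  + N[, , l] * f[l]
    Lw <- Lw + N[, , l] * f[l] * (l - 1L)
  }
  ng <- choose(m, m / 2)
  list(A = A / ng, Lw = Lw / ng)
}

# Polynomial representation of the collapsed table: A(r) = sum_s K_s *
# (1-r)^(m-s) r^s over the total recombinant count s = lP + lQ.  K_s is
# stored column-s of a ((m+1)^2 x (m+1)) matrix so A(r) and the
# recombinant-weighted table are two matrix-vector products.  Cached per
# (m, dosages, sharing pair); this makes repeated evaluation across EM
# iterations and the pairwise matrix cheap.
pair_poly <- function(dP_pair, dQ_pair, phase, m) {
  key <- paste0("poly_", m, "_", dP_pair[1], "_", dP_pair[2], "_",
                dQ_pair[1], "_", dQ_pair[2], "_", phase[1], "_", phase[2])
  cache_get(key, function() {
    NP <- parent_pair_counts(dP_pair[1], dP_pair[2], phase[1], m)
    NQ <- parent_pair_counts(dQ_pair[1], dQ_pair[2], phase[2], m)
    ng <- choose(m, m / 2)
    K <- m / 2 + 1L
    CP <- lapply(seq_len(K), function(l)
      NP[, , l] / (ng * choose(m / 2, l - 1L)))
    CQ <- lapply(seq_len(K), function(l)
      NQ[, , l] / (ng * choose(m / 2, l - 1L)))
    Ks <- matrix(0, (m + 1L)^2, m + 1L)
    for (lP in 0:(m / 2)) {
      for (lQ in 0:(m / 2)) {
        s <- lP + lQ
        Ks[, s + 1L] <- Ks[, s + 1L] +
          as.vector(conv2d(CP[[lP + 1L]], CQ[[lQ + 1L]]))
      }
    }
    Ks
  })
}

poly_powers <- function(r, m) (1 - r)^(m - (0:m)) * r^(0:m)

#' Collapsed joint dosage distribution for a marker pair
#'
#' The \code{(m+1) x (m+1)} table whose (a+1, b+1) entry is the probability
#' that a random offspring shows dosage a at the first marker and b at the
#' second, given the parental dosages, the sharing-pair linkage phase
#' \code{(wP, wQ)} and the recombination fraction.  Built as the 2-D
#' convolution of the two independent parental gamete-dosage tables; the
#' grand sum is 1.
#'
#' @param dP_pair,dQ_pair integer length-2 vectors: dosages of the two
#'   markers in parents P and Q.
#' @param phase integer length-2 vector \code{c(wP, wQ)} of sharing values.
#' @param r recombination fraction in \code{[0, 0.5]}.
#' @inheritParams ploidy_context
#' @return \code{(m+1) x (m+1)} probability matrix.
#' @export
collapsed_joint <- function(dP_pair, dQ_pair, phase, r, m) {
  m <- check_ploidy(m)
  Ks <- pair_poly(dP_pair, dQ_pair, phase, m)
  matrix(Ks %*% poly_powers(r, m), m + 1L, m + 1L)
}

#' Two-point log-likelihood given a collapsed table
#'
#' \eqn{\sum_i \log(\pi_i^k \, A \, (\pi_i^{k'})^T)} over individuals, with
#' hard dosage calls entering as indicator priors.
#'
#' @param priorK,priorK1 \code{(m+1) x n} matrices of per-individual dosage
#'   priors at the two markers.
#' @param A collapsed joint table from \code{\link{collapsed_joint}}.
#' @return log-likelihood.
#' @export
twopoint_loglik <- function(priorK, priorK1, A) {
  csK <- colSums(priorK); csK1 <- colSums(priorK1)
  if (any(csK <= 0) || any(csK1 <= 0)) {
    stop("all-zero prior for individual ",
         which(c(csK, csK1) <= 0)[1] %% ncol(priorK), call. = FALSE)
  }
  li <- colSums(priorK * (A %*% priorK1))
  if (any(li <= 0)) {
    stop("zero two-point likelihood for individual ", which(li <= 0)[1],
         "; filter impossible dosages first", call. = FALSE)
  }
  sum(log(li))
}

# Is the pair informative at all (does A depend on r)?
pair_informative <- function(dP_pair, dQ_pair, phase, m) {
  A1 <- collapsed_joint(dP_pair, dQ_pair, phase, 0.1, m)
  A2 <- collapsed_joint(dP_pair, dQ_pair, phase, 0.4, m)
  max(abs(A1 - A2)) > 1e-12
}

#' Two-point estimation of the recombination fraction
#'
#' Maximizes the collapsed two-point likelihood over \code{r} for a fixed
#' sharing-pair phase, by EM: the E-step computes the expected proportion
#' of recombinant bivalents per dosage cell, the M-step averages it over
#' individuals.  Equivalent to the multipoint fit restricted to two
#' markers.
#'
#' @inheritParams twopoint_loglik
#' @inheritParams collapsed_joint
#' @param r_init starting value.
#' @param tol convergence tolerance on \code{|r change|}.
#' @param max_iter maximum EM iterations.
#' @return object of class \code{twopoint_result}: list with \code{r_hat},
#'   \code{loglike}, \code{phase} (\code{c(wP, wQ)}), \code{lod_linkage}
#'   (vs r = 0.5), \code{lod_phase} (filled by \code{\link{scan_phases}};
#'   \code{NA} here) and \code{uninformative}.
#' @export
twopoint_estimate <- function(priorK, priorK1, dP_pair, dQ_pair, phase, m,
                              r_init = 0.25, tol = 1e-6, max_iter = 200L) {
  m <- check_ploidy(m)
  Ks <- pair_poly(dP_pair, dQ_pair, phase, m)
  if (!pair_informative(dP_pair, dQ_pair, phase, m)) {
    A <- collapsed_joint(dP_pair, dQ_pair, phase, 0.5, m)
    ll <- twopoint_loglik(priorK, priorK1, A)
    return(structure(list(r_hat = 0.5, loglike = ll, phase = phase,
                          lod_linkage = 0, lod_phase = NA_real_,
                          uninformative = TRUE),
                     class = "twopoint_result"))
  }
  r <- r_init
  for (it in seq_len(max_iter)) {
    ps <- poly_powers(r, m)
    A <- matrix(Ks %*% ps, m + 1L, m + 1L)
    Erec <- matrix(Ks %*% (ps * (0:m)), m + 1L, m + 1L)  # E[lP+lQ]*A per cell
    li <- colSums(priorK * (A %*% priorK1))
    ei <- colSums(priorK * (Erec %*% priorK1))
    if (any(li <= 0)) {
      stop("zero two-point likelihood for individual ", which(li <= 0)[1],
           "; filter impossible dosages first", call. = FALSE)
    }
    r_new <- min(max(mean(ei / li) / m, 1e-7), 0.5)
    done <- abs(r_new - r) < tol
    r <- r_new
    if (done) break
  }
  A <- collapsed_joint(dP_pair, dQ_pair, phase, r, m)
  ll <- twopoint_loglik(priorK, priorK1, A)
  ll_null <- twopoint_loglik(priorK, priorK1,
                             collapsed_joint(dP_pair, dQ_pair, phase, 0.5, m))
  structure(list(r_hat = r, loglike = ll, phase = phase,
                 lod_linkage = max(0, (ll - ll_null) / log(10)),
                 lod_phase = NA_real_, uninformative = FALSE),
            class = "twopoint_result")
}

#' @export
print.twopoint_result <- function(x, ...) {
  cat(sprintf(
    "two-point: r_hat = %.4f | phase (wP, wQ) = (%d, %d) | LOD linkage = %.2f | LOD phase = %s%s\n",
    x$r_hat, x$phase[1], x$phase[2], x$lod_linkage,
    ifelse(is.na(x$lod_phase), "NA", sprintf("%.2f", x$lod_phase)),
    if (isTRUE(x$uninformative)) " [uninformative]" else ""))
  invisible(x)
}

#' Evaluate all sharing-pair phases for a marker pair
#'
#' Estimates the recombination fraction under every sharing-value pair
#' \code{(wP, wQ)} compatible with the parental dosages, and scores each
#' phase by its LOD relative to the best (best has \code{lod_phase = 0}).
#'
#' @inheritParams twopoint_estimate
#' @return object of class \code{twopoint_scan}: list of
#'   \code{twopoint_result}s sorted by decreasing log-likelihood; ties keep
#'   the enumeration order of \code{(wP, wQ)}, lowest first.
#' @export
scan_phases <- function(priorK, priorK1, dP_pair, dQ_pair, m, ...) {
  wPs <- enumerate_sharing_values(dP_pair[1], dP_pair[2], m)
  wQs <- enumerate_sharing_values(dQ_pair[1], dQ_pair[2], m)
  res <- list()
  for (wQ in wQs) for (wP in wPs) {
    res[[length(res) + 1L]] <-
      twopoint_estimate(priorK, priorK1, dP_pair, dQ_pair, c(wP, wQ), m, ...)
  }
  ll <- vapply(res, `[[`, numeric(1), "loglike")
  best <- max(ll)
  ord <- order(-ll)   # stable: preserves enumeration order among ties
  res <- res[ord]
  for (i in seq_along(res)) {
    res[[i]]$lod_phase <- (best - res[[i]]$loglike) / log(10)
  }
  structure(res, class = "twopoint_scan")
}

#' @export
print.twopoint_scan <- function(x, ...) {
  cat("two-point phase scan:", length(x), "partitions\n")
  for (r in x) print(r)
  invisible(x)
}

#' Pairwise recombination-fraction matrices
#'
#' Runs the full two-point phase scan for every unordered marker pair and
#' records the best-phase estimate.
#'
#' @param dataset a \code{\link{dosage_data}} object (hard calls are turned
#'   into indicator priors; missing values into polysomic priors).
#' @param epsilon global genotyping error rate used when building priors.
#' @param verbose print progress.
#' @return object of class \code{pairwise_rf}: list of symmetric matrices
#'   \code{r_hat}, \code{lod_linkage}, \code{wP}, \code{wQ},
#'   \code{lod_phase_gap} (LOD of the second-best phase; \code{Inf} when
#'   there is a single partition), plus the per-pair scans.
#' @export
pairwise_rf_matrix <- function(dataset, epsilon = 0, verbose = FALSE) {
  z <- dataset$n_mrk
  stopifnot(z >= 2)
  m <- dataset$m
  priors <- dataset_priors(dataset, epsilon = epsilon)
  nm <- dataset$markers$name
  mk <- function() matrix(NA_real_, z, z, dimnames = list(nm, nm))
  out <- list(r_hat = mk(), lod_linkage = mk(), wP = mk(), wQ = mk(),
              lod_phase_gap = mk(), scans = list())
  for (k in seq_len(z - 1L)) {
    for (k1 in (k + 1L):z) {
      sc <- scan_phases(matrix(priors[, k, ], m + 1),
                        matrix(priors[, k1, ], m + 1),
                        c(dataset$markers$dP[k], dataset$markers$dP[k1]),
                        c(dataset$markers$dQ[k], dataset$markers$dQ[k1]), m)
      b <- sc[[1]]
      out$r_hat[k, k1] <- out$r_hat[k1, k] <- b$r_hat
      out$lod_linkage[k, k1] <- out$lod_linkage[k1, k] <- b$lod_linkage
      out$wP[k, k1] <- out$wP[k1, k] <- b$phase[1]
      out$wQ[k, k1] <- out$wQ[k1, k] <- b$phase[2]
      gap <- if (length(sc) > 1L) sc[[2]]$lod_phase else Inf
      out$lod_phase_gap[k, k1] <- out$lod_phase_gap[k1, k] <- gap
      out$scans[[paste(nm[k], nm[k1], sep = "|")]] <- sc
    }
    if (verbose) message("pairwise: marker ", k, " of ", z)
  }
  structure(out, class = "pairwise_rf")
}

#' Fisher information of the two-point likelihood
#'
#' Expected information about the recombination fraction carried by one
#' offspring observed at two markers, for a given sharing-pair phase:
#' \eqn{I(r) = \sum_{cells} A'(r)^2 / A(r)}, computed analytically from the
#' polynomial structure of the collapsed table (exact enumeration over the
#' \code{(m+1)^2} dosage cells).
#'
#' @inheritParams collapsed_joint
#' @return nonnegative information value.
#' @export
fisher_information <- function(r, dP_pair, dQ_pair, phase, m) {
  m <- check_ploidy(m)
  stopifnot(r > 0, r < 0.5)
  Ks <- pair_poly(dP_pair, dQ_pair, phase, m)
  s <- 0:m
  p <- poly_powers(r, m)
  q1 <- s / r - (m - s) / (1 - r)
  q2 <- q1^2 - s / r^2 - (m - s) / (1 - r)^2
  A <- Ks %*% p
  Ad <- Ks %*% (p * q1)
  Add <- Ks %*% (p * q2)
  pos <- A > 0
  sum(Ad[pos]^2 / A[pos]) - sum(Add[pos])
}
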