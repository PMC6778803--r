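# Multipoint HMM over the g_m genotype states of an ordered, phased marker
# chain: scaled forward-backward, EM re-estimation of the recombination
# fraction vector, chain log-likelihood, genotype posteriors.
#
# The genotype transition factorizes over the two parents (a Kronecker
# product of two gametic transition matrices), so all propagation is done
# with n_gametes x n_gametes matrix products instead of g_m x g_m ones.
# State vectors of length g_m are stored with the parent-Q gamete rank
# varying fastest: position j = (i - 1) * n_gametes + h.

# Row permutation that swaps the (Q-rank, P-rank) sub-indices of a
# length-ng^2 state vector; cached per ng.  Subscripting with it is the
# fast equivalent of transposing each individual's ng x ng slice.
swap_index <- function(ng) {
  cache_get(paste0("swapidx_", ng), function() {
    as.vector(t(matrix(seq_len(ng^2), ng, ng)))
  })
}

# Propagate X (g x n matrix, one column per individual) through the
# factorized kernel: out[h',i'] = sum_{h,i} X[h,i] MQ[h,h'] MP[i,i'].
# MP acts on the parent-P rank (slow index), MQ on the parent-Q rank (fast
# index).  Both gametic matrices are symmetric, so the same routine serves
# forward and backward recursions and quadratic forms.
kron_mult <- function(MP, MQ, X, ng, n) {
  pidx <- swap_index(ng)
  Y <- matrix(crossprod(MQ, matrix(X, ng, ng * n)),    # [h', (i, ind)]
              ng * ng, n)[pidx, , drop = FALSE]        # [i, h', ind]
  matrix(crossprod(MP, matrix(Y, ng, ng * n)),         # [i', (h', ind)]
         ng * ng, n)[pidx, , drop = FALSE]             # [h', i', ind]
}

#' Phased marker chain model
#'
#' Bundles everything the multipoint HMM needs: an ordered set of markers
#' with their parental phases (homolog subsets carrying the counted
#' allele), a recombination fraction per interval, and per-individual,
#' per-marker dosage priors used as emissions.
#'
#' @param phiP,phiQ lists of length z; element k is the integer homolog
#'   subset of parent P (resp. Q) carrying the counted allele at marker k.
#' @param r numeric vector of z-1 recombination fractions (clamped into
#'   \code{[1e-7, 0.5]}).
#' @param priors numeric array of dimension \code{(m+1, z, n)}: dosage-class
#'   distribution per marker per individual.  An all-zero column is
#'   replaced by the polysomic prior for that marker's parental dosages,
#'   with a warning.
#' @inheritParams ploidy_context
#' @return object of class \code{chain_model}.
#' @export
chain_model <- function(phiP, phiQ, r, priors, m) {
  m <- check_ploidy(m)
  z <- length(phiP)
  stopifnot(length(phiQ) == z, z >= 2, length(r) == z - 1)
  stopifnot(length(dim(priors)) == 3, dim(priors)[1] == m + 1,
            dim(priors)[2] == z)
  n <- dim(priors)[3]
  r <- pmin(pmax(r, 1e-7), 0.5)
  ng <- choose(m, m / 2)
  E <- vector("list", z)
  for (k in seq_len(z)) {
    pk <- matrix(priors[, k, ], m + 1, n)
    cs <- colSums(pk)
    bad <- which(cs <= 0)
    if (length(bad)) {
      warning("all-zero prior column(s) at marker ", k, " for ",
              length(bad), " individual(s); replaced by polysomic prior")
      pk[, bad] <- polysomic_prior(length(phiP[[k]]), length(phiQ[[k]]), m)
    } else if (any(abs(cs - 1) > 1e-6)) {
      stop("prior columns at marker ", k, " do not sum to 1", call. = FALSE)
    }
    delta <- as.vector(outer(delta_profile(phiQ[[k]], m),
                             delta_profile(phiP[[k]], m), "+"))
    E[[k]] <- matrix(pk[delta + 1L, ], ng * ng, n)
  }
  structure(list(phiP = phiP, phiQ = phiQ, r = r, m = m, z = z, n = n,
                 ng = ng, E = E),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat("chain_model: ploidy", x$m, "|", x$z, "markers |", x$n,
      "individuals | r in [", format(min(x$r), digits = 3), ",",
      format(max(x$r), digits = 3), "]\n")
  invisible(x)
}

#' Scaled forward-backward pass
#'
#' Runs the scaled forward and backward recursions over the genotype state
#' space for every individual.  With the per-marker scaling used here,
#' \code{sum_j alpha_k(j) * beta_k(j) = 1} at every marker, and the chain
#' log-likelihood is the sum of log scaling factors.
#'
#' @param chain a \code{\link{chain_model}}.
#' @param on_zero what to do when an individual's data have probability
#'   zero under the chain (contradictory observation at error rate 0):
#'   \code{"error"} stops naming the individual and marker;
#'   \code{"neginf"} records log-likelihood \code{-Inf} for that individual
#'   and continues (used when scoring candidate phases).
#' @return object of class \code{forward_backward}: list with \code{alpha},
#'   \code{beta} (lists of g x n matrices), \code{scale} (z x n),
#'   \code{loglik_ind} (per individual; \code{-Inf} where flagged),
#'   \code{loglik} (total) and \code{dead} (logical).
#' @export
forward_backward <- function(chain, on_zero = c("error", "neginf")) {
  on_zero <- match.arg(on_zero)
  ng <- chain$ng; n <- chain$n; z <- chain$z; m <- chain$m
  g <- ng * ng
  alpha <- vector("list", z)
  beta <- vector("list", z)
  scale <- matrix(NA_real_, z, n)
  dead <- rep(FALSE, n)
  Tlist <- lapply(chain$r, gametic_transition_matrix, m = m)

  a <- chain$E[[1]] / g
  for (k in seq_len(z)) {
    if (k > 1L) {
      a <- kron_mult(Tlist[[k - 1L]], Tlist[[k - 1L]], a, ng, n) *
        chain$E[[k]]
    }
    s <- colSums(a)
    zero <- s <= 0 & !dead
    if (any(zero)) {
      if (on_zero == "error") {
        stop("zero chain probability for individual ", which(zero)[1],
             " at marker ", k, " (contradictory data at error rate 0)",
             call. = FALSE)
      }
      dead <- dead | zero
      a[, zero] <- 1 / g
      s[zero] <- 1
    }
    s[dead & s <= 0] <- 1
    scale[k, ] <- s
    a <- sweep(a, 2L, s, "/")
    alpha[[k]] <- a
  }

  b <- matrix(1, g, n)
  beta[[z]] <- b
  for (k in seq(z - 1L, 1L)) {
    b <- kron_mult(Tlist[[k]], Tlist[[k]],
                   chain$E[[k + 1L]] * b, ng, n)
    b <- sweep(b, 2L, scale[k + 1L, ], "/")
    beta[[k]] <- b
  }

  loglik_ind <- colSums(log(scale))
  loglik_ind[dead] <- -Inf
  structure(list(alpha = alpha, beta = beta, scale = scale,
                 loglik_ind = loglik_ind,
                 loglik = if (any(dead)) -Inf else sum(loglik_ind),
                 dead = dead, Tlist = Tlist),
            class = "forward_backward")
}

#' Pairwise genotype-state posterior for one interval
#'
#' The posterior probability of each genotype-state pair at markers k and
#' k+1 given all observations, for a single individual; sums to 1 over the
#' \eqn{g_m^2} pairs.
#'
#' @param chain a \code{\link{chain_model}}.
#' @param fb result of \code{\link{forward_backward}}.
#' @param k interval index in \code{1..z-1}.
#' @param individual individual index.
#' @return a g x g matrix; rows index the state at marker k, columns at
#'   marker k+1.
#' @export
state_pair_posterior <- function(chain, fb, k, individual = 1L) {
  stopifnot(k >= 1, k < chain$z)
  ng <- chain$ng
  A <- fb$alpha[[k]][, individual]
  C <- (chain$E[[k + 1L]] * fb$beta[[k + 1L]])[, individual]
  Tm <- fb$Tlist[[k]]
  xi <- outer(A, C) * kronecker(Tm, Tm)
  xi / sum(xi)
}

#' One EM update of the recombination fraction vector
#'
#' Replaces each interval's recombination fraction by the posterior
#' expected proportion of recombinant bivalents,
#' \eqn{r_k \leftarrow \frac{1}{n}\sum_i E[(l_P + l_Q)/m \mid O_i]},
#' computed from the forward-backward quantities through the factorized
#' kernel (no g x g matrices are formed).
#'
#' @inheritParams state_pair_posterior
#' @return numeric vector of updated recombination fractions, clamped to
#'   \code{[1e-7, 0.5]}.
#' @export
em_update <- function(chain, fb) {
  ng <- chain$ng; n <- chain$n; m <- chain$m
  L <- recomb_count_matrix(m)
  alive <- !fb$dead
  r_new <- numeric(chain$z - 1L)
  pidx <- swap_index(ng)
  perm <- function(Xm) {                       # [a,(b,ind)] -> [b,(a,ind)]
    matrix(matrix(Xm, ng * ng, n)[pidx, , drop = FALSE], ng, ng * n)
  }
  for (k in seq_len(chain$z - 1L)) {
    Tm <- fb$Tlist[[k]]
    TL <- Tm * L
    A <- matrix(perm(fb$alpha[[k]]), ng * ng, n)   # [i, h, ind] layout
    C <- matrix(chain$E[[k + 1L]] * fb$beta[[k + 1L]], ng, ng * n)
    # contract the Q index first (shared by Z and nP), then the P index;
    # results stay in [i, h, ind] layout matching A above
    Y1 <- perm(crossprod(Tm, C))
    Y2 <- perm(crossprod(TL, C))
    Z  <- colSums(A * matrix(crossprod(Tm, Y1), ng * ng, n))
    nP <- colSums(A * matrix(crossprod(TL, Y1), ng * ng, n))
    nQ <- colSums(A * matrix(crossprod(Tm, Y2), ng * ng, n))
    e <- (nP + nQ) / (m * Z)
    r_new[k] <- mean(e[alive & Z > 0])
  }
  pmin(pmax(r_new, 1e-7), 0.5)
}

#' Fit a phased chain by forward-backward EM
#'
#' Alternates the scaled forward-backward pass with the EM update of the
#' recombination-fraction vector until the largest change in any interval
#' falls below \code{tol} or \code{max_iter} sweeps are reached.
#'
#' @param chain a \code{\link{chain_model}}.
#' @param tol convergence tolerance on \code{max_k |r_k change|}.
#' @param max_iter maximum EM sweeps.
#' @param on_zero passed to \code{\link{forward_backward}}.
#' @return list with \code{r} (estimates), \code{loglik} (at the final r),
#'   \code{n_iter}, \code{trace} (log-likelihood per sweep, non-decreasing)
#'   and \code{chain} (updated model).
#' @export
fit_chain <- function(chain, tol = 1e-4, max_iter = 1000L,
                      on_zero = "error") {
  trace <- numeric(0)
  iter <- 0L
  repeat {
    fb <- forward_backward(chain, on_zero = on_zero)
    trace <- c(trace, fb$loglik)
    if (!is.finite(fb$loglik) && fb$loglik > 0) {
      stop("non-finite chain likelihood", call. = FALSE)
    }
    if (identical(fb$loglik, -Inf)) {
      return(list(r = chain$r, loglik = -Inf, n_iter = iter, trace = trace,
                  chain = chain))
    }
    iter <- iter + 1L
    r_new <- em_update(chain, fb)
    delta <- max(abs(r_new - chain$r))
    chain$r <- r_new
    if (delta < tol || iter >= max_iter) break
  }
  fb <- forward_backward(chain, on_zero = on_zero)
  list(r = chain$r, loglik = fb$loglik, n_iter = iter,
       trace = c(trace, fb$loglik), chain = chain)
}

#' Per-marker genotype-state posterior
#'
#' Posterior distribution over the \eqn{g_m} genotype states at every
#' marker for every individual, conditioned on the whole chain.
#'
#' @inheritParams state_pair_posterior
#' @return list of length z of g x n matrices, each column summing to 1.
#' @export
genotype_posterior <- function(chain, fb) {
  lapply(seq_len(chain$z), function(k) {
    p <- fb$alpha[[k]] * fb$beta[[k]]
    sweep(p, 2L, colSums(p), "/")
  })
}
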