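# Probability model for bivalent meiosis and dosage observation:
# gamete/genotype transition probabilities, initial state, dosage emission,
# and polysomic segregation priors.

#' Gamete probability conditional on a bivalent configuration
#'
#' Probability of observing the two-locus gamete \code{(S_k, S_k1)} given
#' that meiosis formed the bivalent configuration \code{psi}: it is
#' \eqn{(1-r)^{m/2-l} r^l / 2^{m/2}} when every bivalent contributes exactly
#' one homolog to each locus subset, and 0 when the gamete cannot be
#' produced from \code{psi} (two partners of one bivalent migrate to
#' opposite poles and cannot co-occur in a gamete).
#'
#' @param S_k,S_k1 homolog subsets of size \code{m/2} at the two loci.
#' @param psi an \code{m/2 x 2} matrix of homolog pairs (one element of
#'   \code{\link{enumerate_bivalent_configs}}).
#' @param r recombination fraction in \code{[0, 0.5]}.
#' @inheritParams ploidy_context
#' @return probability.
#' @export
gamete_prob_given_config <- function(S_k, S_k1, psi, r, m) {
  m <- check_ploidy(m)
  stopifnot(r >= 0, r <= 0.5)
  for (b in seq_len(nrow(psi))) {
    pair <- psi[b, ]
    if (sum(S_k %in% pair) != 1L || sum(S_k1 %in% pair) != 1L) return(0)
  }
  l <- recombinant_count(S_k, S_k1, m)
  (1 - r)^(m / 2 - l) * r^l / 2^(m / 2)
}

#' Unconditional two-locus gamete probability
#'
#' Probability of a two-locus gamete averaged over all bivalent
#' configurations under random (non-preferential) pairing:
#' \eqn{l!\,(m/2-l)!/w_m \cdot (1-r)^{m/2-l} r^l / 2^{m/2}}, where
#' \eqn{l!\,(m/2-l)!} counts the configurations consistent with the gamete.
#'
#' @inheritParams gamete_prob_given_config
#' @return probability.
#' @export
gamete_prob <- function(S_k, S_k1, r, m) {
  m <- check_ploidy(m)
  stopifnot(r >= 0, r <= 0.5)
  l <- recombinant_count(S_k, S_k1, m)
  w <- count_bivalent_configs(m)
  factorial(l) * factorial(m / 2 - l) / w *
    (1 - r)^(m / 2 - l) * r^l / 2^(m / 2)
}

#' Gametic transition probability
#'
#' Conditional probability of the gamete state at locus k+1 given the state
#' at locus k: \eqn{(1-r)^{m/2-l} r^l / \binom{m/2}{l}} with \eqn{l} the
#' recombinant-bivalent count between the two ranked states.
#'
#' @param i,i1 gamete state ranks at loci k and k+1.
#' @param r recombination fraction in \code{[0, 0.5]}.
#' @inheritParams ploidy_context
#' @return probability.
#' @seealso \code{\link{gametic_transition_matrix}} for the full matrix.
#' @export
gametic_transition <- function(i, i1, r, m) {
  m <- check_ploidy(m)
  stopifnot(r >= 0, r <= 0.5)
  l <- recomb_count_matrix(m)[i, i1]
  (1 - r)^(m / 2 - l) * r^l / choose(m / 2, l)
}

#' Full gametic transition matrix
#'
#' @inheritParams gametic_transition
#' @return symmetric, doubly stochastic \code{n_gametes x n_gametes} matrix.
#' @export
gametic_transition_matrix <- function(r, m) {
  m <- check_ploidy(m)
  stopifnot(r >= 0, r <= 0.5)
  L <- recomb_count_matrix(m)
  (1 - r)^(m / 2 - L) * r^L / choose(m / 2, L)
}

#' Genotypic transition probability
#'
#' Transition between offspring genotype states at adjacent loci: the
#' product of the two independent parental gametic transitions,
#' \eqn{(1-r)^{m-l_P-l_Q} r^{l_P+l_Q} / (\binom{m/2}{l_P}\binom{m/2}{l_Q})},
#' evaluated from the per-parent recombinant counts without building the
#' \eqn{g_m \times g_m} matrix.
#'
#' @param j,j1 genotype state indices at loci k and k+1.
#' @inheritParams gametic_transition
#' @return probability.
#' @export
genotypic_transition <- function(j, j1, r, m) {
  l <- unname(genotype_pair_counts(j, j1, m))
  (1 - r)^(m - l[1] - l[2]) * r^(l[1] + l[2]) /
    (choose(m / 2, l[1]) * choose(m / 2, l[2]))
}

#' Initial genotype state distribution
#'
#' Uniform over the \eqn{g_m} genotype states: every pair of parental
#' gametes is equally likely a priori.
#'
#' @inheritParams genotypic_transition
#' @return probability \eqn{1/g_m}.
#' @export
initial_state <- function(j, m) {
  m <- check_ploidy(m)
  ng <- choose(m, m / 2)
  if (any(j < 1 | j > ng^2)) stop("genotype index out of range", call. = FALSE)
  rep(1 / ng^2, length(j))
}

#' Marker phase: homologs carrying the counted allele
#'
#' A per-marker linkage phase assigns the counted allele to a subset of each
#' parent's homologs; the subset sizes are the parental dosages.
#'
#' @param phiP,phiQ integer vectors of homolog labels in \code{1..m}
#'   (possibly empty) carrying the counted allele in parents P and Q.
#' @inheritParams ploidy_context
#' @return object of class \code{marker_phase}.
#' @export
marker_phase <- function(phiP, phiQ, m) {
  m <- check_ploidy(m)
  phiP <- as.integer(phiP); phiQ <- as.integer(phiQ)
  for (phi in list(phiP, phiQ)) {
    if (anyDuplicated(phi) || any(phi < 1L | phi > m)) {
      stop("phase subsets must be duplicate-free subsets of 1..", m,
           call. = FALSE)
    }
  }
  structure(list(phiP = sort(phiP), phiQ = sort(phiQ), m = m),
            class = "marker_phase")
}

# Vector over gamete ranks of |phi intersect S(i)|: the dosage contributed
# by one parent's gamete under phase subset phi.
delta_profile <- function(phi, m) {
  inc <- gamete_incidence(m)
  if (length(phi) == 0L) return(integer(ncol(inc)))
  as.integer(colSums(inc[phi, , drop = FALSE]))
}

#' Dosage determined by a genotype state under a marker phase
#'
#' The dosage an offspring in genotype state \code{j} exhibits at a marker
#' whose counted allele sits on homologs \code{phiP} of P and \code{phiQ}
#' of Q: the parental contributions are counted on each inherited gamete
#' separately (the two parental homolog sets are distinguishable), so the
#' result ranges over \code{0..m}.
#'
#' @param j genotype state index (vectorized).
#' @param phase a \code{\link{marker_phase}}.
#' @inheritParams ploidy_context
#' @return integer dosage(s) in \code{0..m}.
#' @export
delta_dosage <- function(j, phase, m) {
  m <- check_ploidy(m)
  s <- genotype_split(j, m)
  delta_profile(phase$phiP, m)[s$i] + delta_profile(phase$phiQ, m)[s$h]
}

#' Emission probability under a global genotyping error rate
#'
#' Probability of observing dosage \code{O} when the genotype state implies
#' dosage \code{delta}: \eqn{1-\epsilon} on agreement, \eqn{\epsilon/m}
#' otherwise (a symmetric error channel over the other m classes).
#'
#' @param O observed dosage in \code{0..m}.
#' @param delta dosage implied by the genotype state.
#' @param epsilon global genotyping error rate in \code{[0, 1)}.
#' @inheritParams ploidy_context
#' @return probability.
#' @export
emission_global_error <- function(O, delta, epsilon, m) {
  m <- check_ploidy(m)
  stopifnot(epsilon >= 0, epsilon < 1)
  ifelse(O == delta, 1 - epsilon, epsilon / m)
}

#' Emission probability from a per-individual dosage prior
#'
#' When the genotype caller supplies a probability distribution over the
#' m+1 dosage classes, the emission for a state with implied dosage
#' \code{delta} is simply the prior mass on that class.
#'
#' @param delta implied dosage in \code{0..m} (vectorized).
#' @param prior numeric vector of length m+1 over dosage classes 0..m.
#' @return probability.
#' @export
emission_prior <- function(delta, prior) {
  prior[delta + 1L]
}

#' Polysomic segregation prior for offspring dosage
#'
#' Distribution of offspring dosage at a single marker under polysomic
#' inheritance given the parental dosages: each parent transmits a random
#' half of its homologs, so the number of counted-allele copies per gamete
#' is hypergeometric, and the offspring dosage is the convolution of the
#' two parental gamete-dosage distributions.  Used as the emission prior
#' for missing observations.
#'
#' @param dP,dQ parental dosages in \code{0..m}.
#' @inheritParams ploidy_context
#' @return numeric vector of length m+1 over dosage classes 0..m.
#' @export
polysomic_prior <- function(dP, dQ, m) {
  m <- check_ploidy(m)
  stopifnot(dP >= 0, dP <= m, dQ >= 0, dQ <= m)
  a <- 0:(m / 2)
  pP <- stats::dhyper(a, dP, m - dP, m / 2)
  pQ <- stats::dhyper(a, dQ, m - dQ, m / 2)
  out <- numeric(m + 1)
  for (x in a) {
    out[x + 1:(m / 2 + 1)] <- out[x + 1:(m / 2 + 1)] + pP[x + 1] * pQ
  }
  out
}

# u-operator: number of distinct offspring dosage classes contributed by a
# parent with dosage d, minus one; u(d) = ||d - m/2| - m/2| = min(d, m - d).
u_op <- function(d, m) {
  abs(abs(d - m / 2) - m / 2)
}

#' Feasible offspring dosage classes
#'
#' The contiguous set of offspring dosages with nonzero polysomic
#' probability given parental dosages; its cardinality is
#' \eqn{u(d_P) + u(d_Q) + 1} with \eqn{u(x) = ||x - m/2| - m/2|}.
#'
#' @inheritParams polysomic_prior
#' @return integer vector of feasible dosage classes.
#' @export
feasible_dosage_classes <- function(dP, dQ, m) {
  m <- check_ploidy(m)
  stopifnot(dP >= 0, dP <= m, dQ >= 0, dQ <= m)
  lo <- max(0, dP - m / 2) + max(0, dQ - m / 2)
  hi <- min(dP, m / 2) + min(dQ, m / 2)
  lo:hi
}
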