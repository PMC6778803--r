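# Meiosis and full-sib population simulator under the model's assumptions:
# random bivalent pairing (optionally biased toward a fixed partner
# matching), independent per-interval recombination within each bivalent,
# offspring observed as SNP allele dosages.  Plus the mapping function and
# evaluation metrics.

#' Haldane mapping function
#'
#' Converts a recombination fraction to map distance,
#' \eqn{d = -50\,\ln(1 - 2r)} cM, and back,
#' \eqn{r = (1 - e^{-d/50})/2}.
#'
#' @param r recombination fraction(s) in \code{[0, 0.5)}.
#' @param d map distance(s) in cM.
#' @return \code{haldane_cM}: distance in cM; \code{haldane_r}:
#'   recombination fraction.
#' @export
haldane_cM <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("Haldane distance is infinite at r = 0.5 and undefined outside ",
         "[0, 0.5)", call. = FALSE)
  }
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cM
#' @export
haldane_r <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-d / 50)) / 2
}

#' Root-mean-square distance between two maps
#'
#' \eqn{\sqrt{(\hat d - d)^T (\hat d - d) / (z - 1)}} over the z-1 interval
#' lengths of two maps on the same markers; a value of 1 cM means the maps
#' differ by 1 cM per interval on average.
#'
#' @param d_hat,d_true numeric vectors of interval lengths (cM).
#' @return RMS difference in cM.
#' @export
map_rms_distance <- function(d_hat, d_true) {
  if (length(d_hat) != length(d_true)) {
    stop("interval vectors have different lengths", call. = FALSE)
  }
  sqrt(mean((d_hat - d_true)^2))
}

#' Simulate parental haplotypes
#'
#' Builds an m x z binary homolog matrix whose column sums are the marker
#' dosages, with the counted allele placed according to the scenario:
#' \describe{
#'   \item{A}{always on homologs 1..d (alleles concentrated on the leading
#'     homologs; the easiest phasing scenario);}
#'   \item{B}{on a contiguous block of d homologs whose start is drawn
#'     uniformly from the first m/2 rows (truncated so the block fits);}
#'   \item{C}{on a uniformly random subset of d homologs (the hardest
#'     scenario).}
#' }
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param z number of markers.
#' @param dosages integer vector of length z of marker dosages in
#'   \code{0..m}; by default drawn uniformly from \code{1..m-1}.
#' @param scenario \code{"A"}, \code{"B"} or \code{"C"}.
#' @inheritParams ploidy_context
#' @return m x z binary integer matrix.
#' @export
make_parent_haplotypes <- function(m, z, dosages = NULL,
                                   scenario = c("A", "B", "C")) {
  m <- check_ploidy(m)
  scenario <- match.arg(scenario)
  if (is.null(dosages)) {
    dosages <- sample(seq_len(m - 1L), z, replace = TRUE)
  }
  stopifnot(length(dosages) == z)
  if (any(dosages < 0 | dosages > m)) {
    stop("dosages must lie in 0..m", call. = FALSE)
  }
  H <- matrix(0L, m, z)
  for (k in seq_len(z)) {
    d <- dosages[k]
    if (d == 0L) next
    rows <- switch(scenario,
      A = seq_len(d),
      B = {
        start <- sample.int(min(m / 2, m - d + 1L), 1L)
        start + seq_len(d) - 1L
      },
      C = sample.int(m, d))
    H[rows, k] <- 1L
  }
  H
}

fixed_matching <- function(m) {
  matrix(seq_len(m), ncol = 2L, byrow = TRUE)
}

#' Simulate one meiosis
#'
#' Samples a bivalent configuration (uniform over all perfect matchings
#' when \code{preferential = 0}; with probability \code{preferential} the
#' fixed partner matching (1,2)(3,4)... is used instead), then lets the
#' transmitted homolog of each bivalent switch to its partner across
#' interval k with probability \code{r[k]}, independently across bivalents
#' (no interference, no obligate chiasma -- exactly the process the HMM
#' assumes).
#'
#' @param H parental m x z haplotype matrix.
#' @param r numeric vector of z-1 interval recombination fractions.
#' @param preferential pairing-bias mixture weight in \code{[0, 1]}.
#' @return list with \code{subset} (m/2 x z matrix: transmitted homolog per
#'   bivalent per marker), \code{dose} (length-z vector of allele counts
#'   contributed by this gamete) and \code{psi} (the sampled bivalent
#'   configuration, rows of homolog pairs).
#' @export
simulate_meiosis <- function(H, r, preferential = 0) {
  m <- nrow(H)
  z <- ncol(H)
  stopifnot(length(r) == z - 1L, all(r >= 0 & r <= 0.5),
            preferential >= 0, preferential <= 1)
  if (preferential > 0 && stats::runif(1) < preferential) {
    psi <- fixed_matching(m)
  } else {
    cfgs <- cache_get(paste0("cfgs_", m),
                      function() enumerate_bivalent_configs(m, cap = m))
    psi <- cfgs[[sample.int(length(cfgs), 1L)]]
  }
  nb <- m / 2
  S <- matrix(0L, nb, z)
  side <- sample(c(1L, 2L), nb, replace = TRUE)
  for (k in seq_len(z)) {
    S[, k] <- psi[cbind(seq_len(nb), side)]
    if (k < z) {
      flip <- stats::runif(nb) < r[k]
      side[flip] <- 3L - side[flip]
    }
  }
  dose <- vapply(seq_len(z), function(k) sum(H[S[, k], k]), numeric(1))
  list(subset = S, dose = as.integer(dose), psi = psi)
}

#' Simulation configuration
#'
#' @param m even ploidy.
#' @param n number of offspring.
#' @param z number of markers.
#' @param distances interval lengths in cM (length z-1; recycled), default
#'   1 cM throughout.
#' @param scenario haplotype placement scenario, see
#'   \code{\link{make_parent_haplotypes}}.
#' @param dosP,dosQ optional fixed parental dosage vectors.
#' @param preferential pairing-bias weight in \code{[0, 1]}.
#' @param epsilon dosage observation error rate (symmetric channel).
#' @param seed integer seed.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(m, n = 200L, z = 10L, distances = 1,
                       scenario = "A", dosP = NULL, dosQ = NULL,
                       preferential = 0, epsilon = 0, seed = 1L) {
  m <- check_ploidy(m)
  distances <- rep_len(distances, z - 1L)
  stopifnot(n >= 1, z >= 2, all(distances > 0))
  structure(list(m = m, n = as.integer(n), z = as.integer(z),
                 distances = distances, scenario = scenario,
                 dosP = dosP, dosQ = dosQ, preferential = preferential,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a full-sib dosage dataset with ground truth
#'
#' Generates parental haplotypes (unless given), simulates n offspring as
#' the union of one meiotic gamete from each parent, and observes each
#' offspring-marker dosage either exactly or through a symmetric error
#' channel at rate \code{epsilon}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param parents optional list \code{list(HP = , HQ = )} of m x z matrices.
#' @return list with \code{dataset} (a \code{\link{dosage_data}}) and
#'   \code{truth} (list: \code{HP}, \code{HQ}, \code{r}, true dosage matrix
#'   \code{dose}, and per-offspring transmitted homolog subsets
#'   \code{tracksP}, \code{tracksQ}).
#' @export
simulate_population <- function(config, parents = NULL) {
  set.seed(config$seed)
  m <- config$m; n <- config$n; z <- config$z
  r <- haldane_r(config$distances)
  if (is.null(parents)) {
    HP <- make_parent_haplotypes(m, z, config$dosP, config$scenario)
    HQ <- make_parent_haplotypes(m, z, config$dosQ, config$scenario)
  } else {
    HP <- parents$HP; HQ <- parents$HQ
    stopifnot(all(dim(HP) == c(m, z)), all(dim(HQ) == c(m, z)))
  }
  dose <- matrix(0L, z, n)
  tracksP <- vector("list", n)
  tracksQ <- vector("list", n)
  for (ind in seq_len(n)) {
    gP <- simulate_meiosis(HP, r, config$preferential)
    gQ <- simulate_meiosis(HQ, r, config$preferential)
    tracksP[[ind]] <- gP$subset
    tracksQ[[ind]] <- gQ$subset
    dose[, ind] <- gP$dose + gQ$dose
  }
  obs <- dose
  if (config$epsilon > 0) {
    err <- matrix(stats::runif(z * n) < config$epsilon, z, n)
    if (any(err)) {
      wrong <- function(true) {
        s <- sample.int(m, 1L)          # uniform over the m other classes
        (true + s) %% (m + 1L)
      }
      obs[err] <- vapply(dose[err], wrong, integer(1))
    }
  }
  ds <- dosage_data(
    markers = data.frame(name = sprintf("M%d", seq_len(z)),
                         dP = colSums(HP), dQ = colSums(HQ)),
    dosages = obs, m = m)
  list(dataset = ds,
       truth = list(HP = HP, HQ = HQ, r = r, dose = dose,
                    tracksP = tracksP, tracksQ = tracksQ))
}

#' Replicated phasing study
#'
#' Runs a Simulation-1-style study: for each replicate, simulate a
#' population, phase it sequentially, and record whether each parent's
#' linkage phase was recovered (up to homolog permutation) and -- when both
#' were -- the RMS map distance between estimated and true maps.
#'
#' @param m ploidy.
#' @param n_rep number of replicate populations.
#' @param n,z,distances,scenario,preferential,epsilon,dosP,dosQ passed to
#'   \code{\link{sim_config}}.
#' @param config a \code{\link{phasing_config}}.
#' @param seed master seed; per-replicate seeds are spawned from it.
#' @param verbose print per-replicate progress.
#' @return object of class \code{sim_study}: a data frame with one row per
#'   replicate (\code{rep}, \code{seed}, \code{correctP}, \code{correctQ},
#'   \code{rms_cM}, \code{loglik}, \code{n_skipped}); the summary method
#'   reports percent correct per parent.
#' @export
run_simulation_study <- function(m, n_rep, n = 200L, z = 10L, distances = 1,
                                 scenario = "A", preferential = 0,
                                 epsilon = 0, dosP = NULL, dosQ = NULL,
                                 config = phasing_config(eta = 3),
                                 seed = 1L, verbose = FALSE) {
  if (n_rep == 0L) {
    return(structure(data.frame(rep = integer(0), seed = integer(0),
                                correctP = logical(0), correctQ = logical(0),
                                rms_cM = numeric(0), loglik = numeric(0),
                                n_skipped = integer(0)),
                     class = c("sim_study", "data.frame")))
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  rows <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    sim <- simulate_population(sim_config(
      m, n = n, z = z, distances = distances, scenario = scenario,
      dosP = dosP, dosQ = dosQ, preferential = preferential,
      epsilon = epsilon, seed = seeds[i]))
    map <- phase_chain(sim$dataset, config = config)
    ok <- c(P = FALSE, Q = FALSE)
    rms <- NA_real_
    if (length(map$skipped) == 0L) {
      ok <- compare_phase(map$HP, map$HQ, sim$truth$HP, sim$truth$HQ)
      if (all(ok)) {
        rms <- map_rms_distance(haldane_cM(map$r),
                                haldane_cM(sim$truth$r))
      }
    }
    rows[[i]] <- data.frame(rep = i, seed = seeds[i],
                            correctP = ok[["P"]], correctQ = ok[["Q"]],
                            rms_cM = rms, loglik = map$loglik,
                            n_skipped = length(map$skipped))
    if (verbose) {
      message(sprintf("replicate %d/%d: P %s Q %s rms %.3f", i, n_rep,
                      ok[["P"]], ok[["Q"]], rms))
    }
  }
  structure(do.call(rbind, rows), class = c("sim_study", "data.frame"))
}

#' @export
summary.sim_study <- function(object, ...) {
  out <- list(n_rep = nrow(object),
              pct_correct_P = 100 * mean(object$correctP),
              pct_correct_Q = 100 * mean(object$correctQ),
              median_rms_cM = stats::median(object$rms_cM, na.rm = TRUE))
  class(out) <- "summary.sim_study"
  out
}

#' @export
print.summary.sim_study <- function(x, ...) {
  cat(sprintf(
    "phasing study: %d replicates | correct phase P %.1f%% Q %.1f%% | median RMS %.3f cM\n",
    x$n_rep, x$pct_correct_P, x$pct_correct_Q, x$median_rms_cM))
  invisible(x)
}
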