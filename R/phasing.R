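# Sequential linkage-phase search: two-point pruning of candidate phases,
# homolog-permutation redundancy elimination, multipoint HMM scoring with
# LOD pruning, and a final map refit.
#
# A full linkage phase for one parent is an m x z binary homolog matrix H:
# row i, column k is 1 iff homolog i carries the counted allele at marker
# k.  Permuting the rows of H (relabelling the homologs) leaves the
# likelihood unchanged, so phases are compared through a canonical form.

#' Canonical form of a homolog matrix
#'
#' Sorts the rows (homologs) of a binary phase matrix into a fixed total
#' order -- rows read as binary words, descending -- so that two matrices
#' are row-permutation equivalent iff their canonical forms are equal.
#'
#' @param H an m x z binary matrix (markers in columns).
#' @return the row-sorted matrix.
#' @export
canonical_form <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) <= 1L) return(H)
  ord <- do.call(order, lapply(seq_len(ncol(H)), function(j) -H[, j]))
  H[ord, , drop = FALSE]
}

phase_to_H <- function(phi_list, m) {
  H <- matrix(0L, m, length(phi_list))
  for (k in seq_along(phi_list)) H[phi_list[[k]], k] <- 1L
  H
}

phase_key <- function(phiP, phiQ, m) {
  paste(paste(canonical_form(phase_to_H(phiP, m)), collapse = ""),
        paste(canonical_form(phase_to_H(phiQ, m)), collapse = ""),
        sep = "/")
}

#' Compare an estimated phase against the truth
#'
#' Two phases are considered identical when the homolog matrices agree up
#' to a row permutation, per parent.
#'
#' @param est_HP,est_HQ estimated m x z homolog matrices.
#' @param true_HP,true_HQ true matrices of the same shape.
#' @return named logical vector \code{c(P = , Q = )}.
#' @export
compare_phase <- function(est_HP, est_HQ, true_HP, true_HQ) {
  if (!all(dim(est_HP) == dim(true_HP)) || !all(dim(est_HQ) == dim(true_HQ))) {
    stop("phase matrices have mismatching shapes", call. = FALSE)
  }
  c(P = identical(canonical_form(est_HP) == 1L, canonical_form(true_HP) == 1L),
    Q = identical(canonical_form(est_HQ) == 1L, canonical_form(true_HQ) == 1L))
}

all_subsets <- function(m, d) {
  if (d == 0L) return(list(integer(0)))
  cols <- utils::combn(m, d)
  lapply(seq_len(ncol(cols)), function(j) cols[, j])
}

#' Phasing configuration
#'
#' Tuning parameters of the sequential phase search.
#'
#' @param eta two-point LOD threshold: a candidate assignment of a new
#'   marker is kept only if, against every windowed phased marker, its
#'   implied sharing value lies in a partition whose two-point LOD (vs the
#'   best partition) is below \code{eta}.
#' @param multipoint_lod retention threshold on the HMM LOD between
#'   insertion rounds.
#' @param window number of terminal phased markers used for the two-point
#'   checks.
#' @param max_candidates hard cap on candidates kept per round (safety).
#' @param refresh_sweeps EM sweeps used when scoring candidates during
#'   insertion (full EM is reserved for the final refit).
#' @param r_new_interval initial recombination fraction assigned to the
#'   interval created by inserting a marker.
#' @param epsilon global genotyping error rate used when building priors
#'   from hard dosage calls.
#' @return object of class \code{phasing_config}.
#' @export
phasing_config <- function(eta = 5, multipoint_lod = 10, window = 50L,
                           max_candidates = 500L, refresh_sweeps = 5L,
                           r_new_interval = 0.01, epsilon = 0) {
  stopifnot(eta > 0, multipoint_lod > 0, window >= 1)
  structure(list(eta = eta, multipoint_lod = multipoint_lod,
                 window = as.integer(window),
                 max_candidates = as.integer(max_candidates),
                 refresh_sweeps = as.integer(refresh_sweeps),
                 r_new_interval = r_new_interval, epsilon = epsilon),
            class = "phasing_config")
}

# Per-parent LOD profile of a two-point scan: for each sharing value of one
# parent, the LOD (vs the overall best) of the best joint phase using it.
parent_lod_profiles <- function(scan) {
  ll <- vapply(scan, `[[`, numeric(1), "loglike")
  wP <- vapply(scan, function(x) x$phase[1], numeric(1))
  wQ <- vapply(scan, function(x) x$phase[2], numeric(1))
  best <- max(ll)
  profile <- function(w) {
    vals <- sort(unique(w))
    out <- vapply(vals, function(v) (best - max(ll[w == v])) / log(10),
                  numeric(1))
    names(out) <- vals
    out
  }
  list(P = profile(wP), Q = profile(wQ))
}

#' Expand phase candidates with a new marker
#'
#' For each retained candidate, every homolog-subset assignment of the new
#' marker whose implied sharing value against each windowed phased marker
#' lies in a two-point partition with LOD below \code{eta} is appended; the
#' two parents are expanded independently and crossed, and row-permutation
#' redundant expansions are removed via \code{\link{canonical_form}}.
#'
#' @param candidates list of candidates (each a list with \code{phiP},
#'   \code{phiQ}, \code{r}, \code{loglik}).
#' @param dP_new,dQ_new parental dosages of the marker being inserted.
#' @param profiles list, one element per windowed marker, each of the form
#'   \code{list(k = <position in the candidate's phase>, P = <LOD profile
#'   over wP>, Q = <LOD profile over wQ>)} from
#'   \code{\link{parent_lod_profiles}}.
#' @param config a \code{\link{phasing_config}}.
#' @inheritParams ploidy_context
#' @return expanded, deduplicated candidate list (possibly empty).
#' @export
extend_candidates <- function(candidates, dP_new, dQ_new, profiles, config,
                              m) {
  subsP <- all_subsets(m, dP_new)
  subsQ <- all_subsets(m, dQ_new)
  out <- list()
  seen <- character(0)
  for (cand in candidates) {
    keep_side <- function(subs, phi_hist, side) {
      Filter(function(phi) {
        for (pr in profiles) {
          w <- length(intersect(phi, phi_hist[[pr$k]]))
          if (pr[[side]][[as.character(w)]] >= config$eta) return(FALSE)
        }
        TRUE
      }, subs)
    }
    okP <- keep_side(subsP, cand$phiP, "P")
    okQ <- keep_side(subsQ, cand$phiQ, "Q")
    for (pP in okP) {
      for (pQ in okQ) {
        phiP <- c(cand$phiP, list(pP))
        phiQ <- c(cand$phiQ, list(pQ))
        key <- phase_key(phiP, phiQ, m)
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <-
          list(phiP = phiP, phiQ = phiQ,
               r = c(cand$r, config$r_new_interval), loglik = NA_real_)
      }
    }
  }
  out
}

#' Score candidates by multipoint likelihood and prune
#'
#' Each candidate chain is given a short EM refresh (its existing interval
#' estimates extended by \code{r_new_interval} for the new interval) and
#' scored by the HMM log-likelihood; candidates whose LOD against the best
#' exceeds \code{multipoint_lod} are dropped, and at most
#' \code{max_candidates} survive.
#'
#' @inheritParams extend_candidates
#' @param priors \code{(m+1) x z_cur x n} prior array restricted to the
#'   phased markers, in candidate column order.
#' @return retained candidates, sorted by decreasing log-likelihood, each
#'   with updated \code{r}, \code{loglik} and \code{lod} (best has 0).
#' @export
score_and_prune <- function(candidates, priors, config, m) {
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    ch <- chain_model(cand$phiP, cand$phiQ, cand$r, priors, m)
    ft <- fit_chain(ch, tol = 0, max_iter = config$refresh_sweeps,
                    on_zero = "neginf")
    candidates[[i]]$r <- ft$r
    candidates[[i]]$loglik <- ft$loglik
  }
  ll <- vapply(candidates, `[[`, numeric(1), "loglik")
  candidates <- candidates[order(-ll)]
  ll <- sort(ll, decreasing = TRUE)
  lod <- (ll[1] - ll) / log(10)
  keep <- which(lod < config$multipoint_lod | seq_along(lod) == 1L)
  if (length(keep) > config$max_candidates) {
    warning("candidate explosion: keeping top ", config$max_candidates,
            " of ", length(keep), " by likelihood")
    keep <- keep[seq_len(config$max_candidates)]
  }
  candidates <- candidates[keep]
  for (i in seq_along(candidates)) candidates[[i]]$lod <- lod[keep[i]]
  candidates
}

#' Sequential phasing of an ordered marker chain
#'
#' Inserts markers one at a time in the given order.  Each insertion
#' expands the surviving phase candidates with every assignment of the new
#' marker that passes the two-point LOD screen against a window of terminal
#' phased markers, removes homolog-permutation redundancy, scores the
#' expansions by multipoint HMM likelihood, and retains those within
#' \code{multipoint_lod} of the best.  After the last insertion the winning
#' phase is refit by full EM.  A marker for which no assignment survives
#' the screen is skipped and reported.
#'
#' @param dataset a \code{\link{dosage_data}} object.
#' @param order integer or character vector giving the marker order
#'   (default: file order).
#' @param config a \code{\link{phasing_config}}.
#' @param verbose print per-insertion progress.
#' @return object of class \code{phased_map}: list with \code{markers}
#'   (data frame: name, dP, dQ, position in Haldane cM), \code{HP},
#'   \code{HQ} (m x z binary homolog matrices), \code{r} (fitted
#'   recombination fractions), \code{loglik}, \code{skipped} (marker names)
#'   and \code{diagnostics} (candidate counts per round).
#' @export
phase_chain <- function(dataset, order = NULL, config = phasing_config(),
                        verbose = FALSE) {
  m <- dataset$m
  if (is.null(order)) order <- seq_len(dataset$n_mrk)
  if (is.character(order)) order <- match(order, dataset$markers$name)
  stopifnot(!anyNA(order), length(order) >= 2)
  priors_all <- dataset_priors(dataset, epsilon = config$epsilon)
  dP <- dataset$markers$dP[order]
  dQ <- dataset$markers$dQ[order]
  nm <- dataset$markers$name[order]

  kept <- 1L                       # positions within 'order' already phased
  candidates <- list(list(phiP = list(seq_len(dP[1])),
                          phiQ = list(seq_len(dQ[1])),
                          r = numeric(0), loglik = NA_real_))
  skipped <- character(0)
  diag_counts <- data.frame(marker = nm[1], expanded = 1L, retained = 1L)

  for (idx in seq_along(order)[-1L]) {
    win <- utils::tail(seq_along(kept), config$window)
    profiles <- lapply(win, function(pos) {
      k <- order[kept[pos]]
      sc <- scan_phases(matrix(priors_all[, k, ], m + 1),
                        matrix(priors_all[, order[idx], ], m + 1),
                        c(dataset$markers$dP[k], dP[idx]),
                        c(dataset$markers$dQ[k], dQ[idx]), m)
      c(list(k = pos), parent_lod_profiles(sc))
    })
    expanded <- extend_candidates(candidates, dP[idx], dQ[idx], profiles,
                                  config, m)
    if (length(expanded) == 0L) {
      skipped <- c(skipped, nm[idx])
      warning("no phase assignment for marker ", nm[idx],
              " passed the two-point screen (eta = ", config$eta,
              "); marker skipped")
      next
    }
    kept <- c(kept, idx)
    pri <- priors_all[, order[kept], , drop = FALSE]
    candidates <- score_and_prune(expanded, pri, config, m)
    diag_counts <- rbind(diag_counts,
                         data.frame(marker = nm[idx],
                                    expanded = length(expanded),
                                    retained = length(candidates)))
    if (verbose) {
      message("inserted ", nm[idx], ": ", length(expanded),
              " candidates expanded, ", length(candidates), " retained")
    }
  }

  best <- candidates[[1]]
  pri <- priors_all[, order[kept], , drop = FALSE]
  ch <- chain_model(best$phiP, best$phiQ, best$r, pri, m)
  ft <- fit_chain(ch, on_zero = "neginf")
  pos_cM <- c(0, cumsum(haldane_cM(ft$r)))
  structure(list(
    markers = data.frame(name = nm[kept], dP = dP[kept], dQ = dQ[kept],
                         position = pos_cM),
    HP = phase_to_H(best$phiP, m), HQ = phase_to_H(best$phiQ, m),
    r = ft$r, loglik = ft$loglik, m = m, skipped = skipped,
    diagnostics = diag_counts, config = config),
    class = "phased_map")
}

#' @export
print.phased_map <- function(x, ...) {
  cat("phased map: ploidy", x$m, "|", nrow(x$markers), "markers | length",
      round(max(x$markers$position), 2), "cM | loglik",
      round(x$loglik, 2), "\n")
  if (length(x$skipped)) cat("skipped markers:",
                             paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
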