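# Combinatorial state machinery: bivalent pairing configurations, gamete and
# genotype state enumeration/ranking, and recombinant-bivalent counting.
#
# Conventions used throughout the package:
#   * homologs of each parent are labelled 1..m (1-based);
#   * a gamete state is the size-m/2 subset of homolog labels transmitted to
#     an offspring, ranked 1..choose(m, m/2) in lexicographic order of the
#     sorted label tuples;
#   * a genotype state j combines a parent-P gamete rank i and a parent-Q
#     gamete rank h as j = (i - 1) * choose(m, m/2) + h.

.polyphase_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (!exists(key, envir = .polyphase_cache, inherits = FALSE)) {
    assign(key, make(), envir = .polyphase_cache)
  }
  get(key, envir = .polyphase_cache, inherits = FALSE)
}

check_ploidy <- function(m) {
  if (length(m) != 1L || !is.numeric(m) || is.na(m) || m != round(m) ||
      m < 2 || m %% 2 != 0) {
    stop("invalid ploidy: 'm' must be a single even integer >= 2, got ",
         deparse(substitute(m)), " = ", paste(m, collapse = ","),
         call. = FALSE)
  }
  as.integer(m)
}

#' Ploidy context: state-space sizes for an even ploidy level
#'
#' Collects the quantities that size every state space in the model: the
#' number of gamete states \eqn{\binom{m}{m/2}}, the number of offspring
#' genotype states \eqn{g_m = \binom{m}{m/2}^2}, and the number of distinct
#' bivalent pairing configurations \eqn{w_m}.
#'
#' @param m even integer ploidy level (2 = diploid, 4 = tetraploid, ...).
#' @return An object of class \code{ploidy_context}: a list with elements
#'   \code{m}, \code{n_gametes}, \code{g} and \code{w}.
#' @examples
#' ploidy_context(4)  # 6 gamete states, 36 genotype states, 3 pairings
#' @export
ploidy_context <- function(m) {
  m <- check_ploidy(m)
  ng <- choose(m, m / 2)
  structure(list(m = m, n_gametes = ng, g = ng^2,
                 w = count_bivalent_configs(m)),
            class = "ploidy_context")
}

#' @export
print.ploidy_context <- function(x, ...) {
  cat("ploidy m =", x$m, "| gamete states =", x$n_gametes,
      "| genotype states =", x$g, "| bivalent configurations =", x$w, "\n")
  invisible(x)
}

#' Number of bivalent pairing configurations
#'
#' Counts the perfect matchings of \code{m} homologs into \code{m/2}
#' bivalents: \eqn{w_m = \frac{1}{(m/2)!}\prod_{i=1}^{m/2}\binom{2i}{2}},
#' i.e. 1, 3, 15, 105 for m = 2, 4, 6, 8.
#'
#' @inheritParams ploidy_context
#' @return integer count \eqn{w_m}.
#' @export
count_bivalent_configs <- function(m) {
  m <- check_ploidy(m)
  prod(choose(2 * seq_len(m / 2), 2)) / factorial(m / 2)
}

#' Enumerate all bivalent pairing configurations
#'
#' Lists every perfect matching of the homologs \code{1..m} into unordered
#' pairs, in a canonical deterministic order (the lowest unpaired homolog is
#' matched in turn with each larger one, recursively).  Intended for oracle
#' tests and for the meiosis simulator; the probability model itself uses
#' closed forms and needs no enumeration.
#'
#' @inheritParams ploidy_context
#' @param cap refuse to enumerate beyond this ploidy (default 8; the count
#'   grows as a double factorial).
#' @return list of length \eqn{w_m}; each element is an \code{m/2 x 2}
#'   integer matrix, one row per bivalent.
#' @export
enumerate_bivalent_configs <- function(m, cap = 8L) {
  m <- check_ploidy(m)
  if (m > cap) {
    stop("refusing to enumerate bivalent configurations for m = ", m,
         " (cap = ", cap, "); raise 'cap' explicitly if really needed",
         call. = FALSE)
  }
  rec <- function(left) {
    if (length(left) == 0L) return(list(integer(0)))
    a <- left[1L]
    out <- list()
    for (b in left[-1L]) {
      for (tail in rec(setdiff(left, c(a, b)))) {
        out[[length(out) + 1L]] <- c(a, b, tail)
      }
    }
    out
  }
  lapply(rec(seq_len(m)), function(v) {
    matrix(v, ncol = 2L, byrow = TRUE,
           dimnames = list(NULL, c("h1", "h2")))
  })
}

# All size-m/2 homolog subsets as a (m/2) x n_gametes matrix, columns in
# lexicographic order (combn's order).  Cached per ploidy.
gamete_subsets <- function(m) {
  m <- check_ploidy(m)
  cache_get(paste0("subsets_", m), function() utils::combn(m, m / 2))
}

# m x n_gametes 0/1 incidence matrix of homolog membership per gamete state.
gamete_incidence <- function(m) {
  m <- check_ploidy(m)
  cache_get(paste0("incidence_", m), function() {
    ss <- gamete_subsets(m)
    inc <- matrix(0L, nrow = m, ncol = ncol(ss))
    for (j in seq_len(ncol(ss))) inc[ss[, j], j] <- 1L
    inc
  })
}

#' Rank and unrank gamete states
#'
#' Bijection between size-\code{m/2} homolog subsets and their 1-based
#' position in the lexicographic order of sorted label tuples; for m = 4 the
#' order is \{1,2\}, \{1,3\}, \{1,4\}, \{2,3\}, \{2,4\}, \{3,4\}.
#'
#' @param S integer vector of homolog labels, a subset of \code{1..m} of
#'   size \code{m/2} (any order; duplicates are an error).
#' @param rank 1-based rank in \code{1..choose(m, m/2)}.
#' @inheritParams ploidy_context
#' @return \code{gamete_rank}: the integer rank; \code{gamete_unrank}: the
#'   sorted homolog subset.
#' @export
gamete_rank <- function(S, m) {
  m <- check_ploidy(m)
  S <- as.integer(S)
  if (length(S) != m / 2 || anyDuplicated(S) || any(S < 1L | S > m)) {
    stop("'S' must be a subset of 1..", m, " of size ", m / 2, call. = FALSE)
  }
  S <- sort(S)
  # combinatorial number system, lexicographic variant
  r <- 1L
  prev <- 0L
  left <- m %/% 2L
  for (pos in seq_len(m %/% 2L)) {
    x <- S[pos]
    if (x > prev + 1L) {
      for (y in (prev + 1L):(x - 1L)) {
        r <- r + choose(m - y, left - 1L)
      }
    }
    prev <- x
    left <- left - 1L
  }
  as.integer(r)
}

#' @rdname gamete_rank
#' @export
gamete_unrank <- function(rank, m) {
  m <- check_ploidy(m)
  ng <- choose(m, m / 2)
  if (length(rank) != 1L || is.na(rank) || rank < 1 || rank > ng) {
    stop("'rank' must lie in 1..", ng, call. = FALSE)
  }
  gamete_subsets(m)[, rank]
}

#' Recombinant-bivalent count between two gamete states
#'
#' Number of bivalents that delivered a recombinant chromosome between two
#' adjacent loci, given the homolog subsets transmitted at each locus:
#' \eqn{l = m/2 - |S_k \cap S_{k+1}|}.  A shared label means the same
#' homolog was transmitted at both loci (parental); each non-shared label
#' marks a partner switch within one bivalent (recombinant).
#'
#' @param S_k,S_k1 homolog subsets of size \code{m/2} at the two loci.
#' @inheritParams ploidy_context
#' @return integer in \code{0..m/2}.
#' @export
recombinant_count <- function(S_k, S_k1, m) {
  m <- check_ploidy(m)
  if (length(S_k) != m / 2 || length(S_k1) != m / 2) {
    stop("both subsets must have size m/2 = ", m / 2, call. = FALSE)
  }
  as.integer(m / 2 - length(intersect(S_k, S_k1)))
}

# n_gametes x n_gametes matrix of recombinant-bivalent counts, cached.
recomb_count_matrix <- function(m) {
  m <- check_ploidy(m)
  cache_get(paste0("rcmat_", m), function() {
    inc <- gamete_incidence(m)
    m / 2 - crossprod(inc)
  })
}

#' Genotype state indexing
#'
#' A genotype state combines a parent-P gamete rank \code{i} and a parent-Q
#' gamete rank \code{h} into \code{j = (i - 1) * choose(m, m/2) + h};
#' \code{genotype_split} inverts the map.
#'
#' @param i,h parental gamete ranks.
#' @param j genotype state index in \code{1..g_m}.
#' @inheritParams ploidy_context
#' @return \code{genotype_index}: integer \code{j}; \code{genotype_split}: a
#'   list with elements \code{i} and \code{h}.
#' @export
genotype_index <- function(i, h, m) {
  m <- check_ploidy(m)
  ng <- choose(m, m / 2)
  if (any(i < 1 | i > ng) || any(h < 1 | h > ng)) {
    stop("gamete ranks must lie in 1..", ng, call. = FALSE)
  }
  as.integer((i - 1L) * ng + h)
}

#' @rdname genotype_index
#' @export
genotype_split <- function(j, m) {
  m <- check_ploidy(m)
  ng <- choose(m, m / 2)
  if (any(j < 1 | j > ng^2)) {
    stop("genotype index must lie in 1..", ng^2, call. = FALSE)
  }
  list(i = as.integer((j - 1L) %/% ng + 1L), h = as.integer((j - 1L) %% ng + 1L))
}

#' Per-parent recombinant counts for a pair of genotype states
#'
#' Decomposes the genotype indices into parental gamete ranks and counts
#' recombinant bivalents per parent, without ever materializing the
#' \eqn{g_m \times g_m} transition space.
#'
#' @param j,j1 genotype state indices at two adjacent loci.
#' @inheritParams ploidy_context
#' @return integer vector \code{c(lP, lQ)}.
#' @export
genotype_pair_counts <- function(j, j1, m) {
  m <- check_ploidy(m)
  a <- genotype_split(j, m)
  b <- genotype_split(j1, m)
  L <- recomb_count_matrix(m)
  c(lP = as.integer(L[a$i, b$i]), lQ = as.integer(L[a$h, b$h]))
}
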