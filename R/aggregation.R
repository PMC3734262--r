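#' Spearman footrule distance between two rankings
#'
#' The sum over genes of the absolute difference between the gene's
#' (1-based) positions in the two orderings. The weighted variant replaces
#' positions with the lists' stability scores rescaled onto the position
#' range [1, n], so that methods which separate genes strongly count more.
#'
#' @param a,b orderings: character vectors (most stable first) or ranked
#'   lists (`list(genes = ..., scores = ...)`). Both must be permutations
#'   of the same gene set.
#' @param weighted use score-weighted positions; requires scores on both
#'   lists (default `FALSE`)
#' @return non-negative numeric distance
#' @examples
#' footrule_distance(c("a", "b", "c", "d"), c("d", "c", "b", "a"))  # 8
#' @export
footrule_distance <- function(a, b, weighted = FALSE) {
  ga <- if (is.list(a)) a$genes else a
  gb <- if (is.list(b)) b$genes else b
  if (!setequal(ga, gb) || length(ga) != length(gb) ||
      anyDuplicated(ga) || anyDuplicated(gb))
    stop("orderings must be permutations of the same gene set")
  if (weighted) {
    wa <- position_weights(a)
    wb <- position_weights(b)
    sum(abs(wa[ga] - wb[ga]))
  } else {
    pa <- stats::setNames(seq_along(ga), ga)
    pb <- stats::setNames(seq_along(gb), gb)
    sum(abs(pa[ga] - pb[ga]))
  }
}

position_weights <- function(x) {
  genes <- if (is.list(x)) x$genes else x
  n <- length(genes)
  s <- if (is.list(x)) x$scores else NULL
  if (is.null(s) || diff(range(s)) == 0)
    return(stats::setNames(seq_len(n), genes))
  w <- 1 + (n - 1) * (s - min(s)) / (max(s) - min(s))
  stats::setNames(w, genes)
}

# positions of every gene (columns, in label order of `genes`) for each
# candidate ordering (rows of `orderings`, entries = gene indices)
invert_orderings <- function(orderings, n) {
  N <- nrow(orderings)
  pos <- matrix(0L, N, n)
  rows <- seq_len(N)
  for (k in seq_len(n)) pos[cbind(rows, orderings[, k])] <- k
  pos
}

# mean (weighted) footrule objective of candidate orderings against the
# input lists; `list_pos` is a matrix lists x genes of target positions
mean_footrule <- function(pos, list_pos) {
  obj <- 0
  for (l in seq_len(nrow(list_pos))) {
    obj <- obj + rowSums(abs(sweep(pos, 2L, list_pos[l, ])))
  }
  obj / nrow(list_pos)
}

prepare_lists <- function(lists, weighted) {
  glists <- lapply(lists, function(x) if (is.list(x)) x$genes else x)
  genes <- sort(glists[[1L]])
  for (g in glists)
    if (!setequal(g, genes) || length(g) != length(genes))
      stop("all input lists must rank the same gene set")
  n <- length(genes)
  list_pos <- t(vapply(lists, function(x) {
    w <- if (weighted) position_weights(x)
         else stats::setNames(seq_len(n), if (is.list(x)) x$genes else x)
    unname(w[genes])
  }, numeric(n)))
  list(genes = genes, n = n, list_pos = list_pos)
}

new_consensus <- function(genes, objective, algorithm, iterations, seed,
                          converged) {
  structure(list(genes = genes, objective = objective,
                 algorithm = algorithm, iterations = iterations,
                 seed = seed, converged = converged),
            class = "consensus_ranking")
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("Consensus ranking (", x$algorithm, ", objective ",
      format(x$objective, digits = 6), ")\n", sep = "")
  cat(paste(x$genes, collapse = " > "), "\n")
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Exhaustive consensus ranking (small panels)
#'
#' Enumerates all n! orderings and returns a global minimiser of the mean
#' (optionally weighted) footrule distance to the input lists; ties go to
#' the lexicographically smallest ordering of gene labels. Serves as the
#' exact oracle against which the Cross-Entropy optimiser is validated.
#'
#' @param lists list of orderings (character vectors or ranked lists)
#' @param weighted use score-weighted footrule distances (default `FALSE`)
#' @return a `consensus_ranking`
#' @export
aggregate_bruteforce <- function(lists, weighted = FALSE) {
  prep <- prepare_lists(lists, weighted)
  if (prep$n > 8L)
    stop("exhaustive search is limited to 8 genes; use aggregate_ce()")
  perms <- all_permutations(prep$n)       # lexicographic by construction
  pos <- invert_orderings(perms, prep$n)
  obj <- mean_footrule(pos, prep$list_pos)
  best <- which.min(obj)                  # first minimum = lex smallest
  new_consensus(prep$genes[perms[best, ]], obj[best], "brute_force",
                1L, NA_integer_, TRUE)
}

#' Cross-Entropy Monte-Carlo consensus ranking
#'
#' Maintains an n x n probability matrix over (gene, position). Each
#' iteration samples `sample_size` orderings (genes drawn per position
#' without replacement, proportional to the current probabilities), scores
#' them by the mean footrule distance to the input lists, keeps the
#' `rarity`-quantile elite, and re-estimates the matrix as a smoothed
#' mixture of the elite frequencies and the previous matrix. Stops when
#' the elite objective has not changed for 5 consecutive iterations (or at
#' `max_iter`); the best ordering ever sampled is returned.
#'
#' @inheritParams aggregate_bruteforce
#' @param sample_size orderings sampled per iteration (default 500)
#' @param rarity elite fraction in (0, 1) (default 0.1)
#' @param smoothing weight of the elite frequencies in the probability
#'   update, in (0, 1] (default 0.7)
#' @param max_iter iteration cap (default 200)
#' @param tol objective change regarded as "unchanged" (default 1e-8)
#' @param seed integer seed (required; the optimiser is stochastic)
#' @return a `consensus_ranking` with optimiser metadata
#' @export
aggregate_ce <- function(lists, sample_size = 500L, rarity = 0.1,
                         smoothing = 0.7, max_iter = 200L, tol = 1e-8,
                         seed, weighted = FALSE) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for the Cross-Entropy optimiser")
  if (rarity <= 0 || rarity >= 1) stop("rarity must be in (0, 1)")
  if (smoothing <= 0 || smoothing > 1) stop("smoothing must be in (0, 1]")
  prep <- prepare_lists(lists, weighted)
  n <- prep$n
  if (n < 2L) stop("need at least 2 genes")
  set.seed(seed)
  p <- matrix(1 / n, n, n)                # gene x position probabilities
  N <- as.integer(sample_size)
  m_elite <- max(1L, ceiling(rarity * N))
  best_obj <- Inf
  best_ord <- seq_len(n)
  prev_elite <- Inf
  stagnant <- 0L
  iter <- 0L
  converged <- FALSE
  rows <- seq_len(N)
  while (iter < max_iter) {
    iter <- iter + 1L
    # sample orderings position by position (Gumbel-max categorical draws
    # among the genes still available in each sample)
    avail <- matrix(TRUE, N, n)
    orderings <- matrix(0L, N, n)
    for (k in seq_len(n)) {
      logits <- matrix(log(p[, k]), N, n, byrow = TRUE) -
        log(-log(matrix(stats::runif(N * n), N, n)))
      logits[!avail] <- -Inf
      choice <- max.col(logits, ties.method = "first")
      orderings[, k] <- choice
      avail[cbind(rows, choice)] <- FALSE
    }
    pos <- invert_orderings(orderings, n)
    obj <- mean_footrule(pos, prep$list_pos)
    ord <- order(obj)
    if (obj[ord[1L]] < best_obj) {
      best_obj <- obj[ord[1L]]
      best_ord <- orderings[ord[1L], ]
    }
    elite <- orderings[ord[seq_len(m_elite)], , drop = FALSE]
    f <- matrix(0, n, n)
    for (k in seq_len(n))
      f[, k] <- tabulate(elite[, k], nbins = n) / m_elite
    p <- smoothing * f + (1 - smoothing) * p
    # guard against collapsed columns
    p[p < 1e-12] <- 1e-12
    p <- sweep(p, 2L, colSums(p), "/")
    elite_obj <- obj[ord[1L]]
    if (is.finite(prev_elite) && abs(elite_obj - prev_elite) <= tol) {
      stagnant <- stagnant + 1L
    } else stagnant <- 0L
    prev_elite <- elite_obj
    if (stagnant >= 5L) { converged <- TRUE; break }
  }
  new_consensus(prep$genes[best_ord], best_obj, "cross_entropy",
                iter, as.integer(seed), converged)
}
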