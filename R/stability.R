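#' @title Expression-stability algorithms
#' @description Five independent algorithms that score candidate reference
#'   genes from a Cq panel: the Brunner stability index (CV x regression
#'   slope on Cq), geNorm (pairwise log-ratio variation on relative
#'   quantities), NormFinder (intra/intergroup variance decomposition),
#'   BestKeeper (dispersion about the geometric mean Cq plus correlation
#'   with the panel index) and the comparative delta-Ct method (mean SD of
#'   pairwise Cq differences). Lower scores mean more stable expression in
#'   every method.
#' @name stability
NULL

new_stability_result <- function(method, scope, table, score_col) {
  score <- table[[score_col]]
  ord <- order(score, table$gene)
  structure(list(method = method, scope = scope, table = table,
                 score_col = score_col,
                 ranking = table$gene[ord]),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Stability result [", x$method, "], scope '", x$scope, "'\n", sep = "")
  tab <- x$table[order(x$table[[x$score_col]]), ]
  rownames(tab) <- NULL
  print(tab, digits = 4)
  invisible(x)
}

as_rq_mat <- function(rq) {
  m <- if (inherits(rq, "rq_matrix")) rq$rq else rq
  if (!is.matrix(m) || !is.numeric(m))
    stop("expected an rq_matrix or a numeric matrix of relative quantities")
  if (any(m[!is.na(m)] <= 0))
    stop("relative quantities must be strictly positive")
  m
}

as_cq_mat <- function(cq) {
  if (inherits(cq, "cq_matrix")) cq$cq else cq
}

pairwise_sd <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  stats::sd(a[ok] - b[ok])
}

#' Brunner stability index
#'
#' For each gene the Cq coefficient of variation (CV, %) and the slope of
#' the gene's per-reaction Cq regressed on the per-reaction mean Cq over
#' all genes are combined into the stability index `SI = CV * |slope|`.
#' A low CV means predictable expression; a low slope means insensitivity
#' to general expression-promoting conditions; genes with the lowest SI
#' make the best reference candidates. Unlike the ratio-based methods, SI
#' depends on the absolute Cq level through the CV denominator.
#'
#' @param cq a [cq_matrix()] (or bare genes x reactions matrix) restricted
#'   to one analysis scope
#' @param scope label attached to the result (default `"all"`)
#' @return a `stability_result` with columns `gene`, `mean`, `sd`, `cv`,
#'   `slope`, `intercept`, `si`; ranking by ascending SI
#' @export
stability_index <- function(cq, scope = "all") {
  m <- as_cq_mat(cq)
  if (ncol(m) < 3L) stop("stability index needs at least 3 reactions")
  overall <- colMeans(m, na.rm = TRUE)
  if (isTRUE(all.equal(stats::var(overall, na.rm = TRUE), 0)) ||
      stats::var(overall, na.rm = TRUE) == 0) {
    warning("zero variance in per-reaction overall means; slopes set to 0")
    zero_var <- TRUE
  } else zero_var <- FALSE
  rows <- lapply(rownames(m), function(g) {
    y <- m[g, ]
    mu <- mean(y, na.rm = TRUE)
    sdv <- stats::sd(y, na.rm = TRUE)
    cv <- 100 * sdv / mu
    ok <- !is.na(y) & !is.na(overall)
    if (zero_var || stats::var(overall[ok]) == 0) {
      slope <- 0; intercept <- mu
    } else {
      slope <- stats::cov(overall[ok], y[ok]) / stats::var(overall[ok])
      intercept <- mean(y[ok]) - slope * mean(overall[ok])
    }
    data.frame(gene = g, mean = mu, sd = sdv, cv = cv, slope = slope,
               intercept = intercept, si = cv * abs(slope),
               stringsAsFactors = FALSE)
  })
  new_stability_result("SI", scope, do.call(rbind, rows), "si")
}

#' geNorm M values
#'
#' For genes j != k the pairwise variation `V_jk` is the SD over reactions
#' of `log2(rq_j / rq_k)`; a gene's M value is the mean of its pairwise
#' variations with all other genes. M is invariant to rescaling any gene's
#' relative quantities (only ratios enter).
#'
#' @param rq an `rq_matrix` from [cq_to_rq()] (or bare positive matrix)
#' @return named numeric vector of per-gene M values
#' @export
genorm_m_values <- function(rq) {
  m <- as_rq_mat(rq)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("geNorm needs at least 2 genes and 2 reactions")
  a <- log2(m)
  K <- nrow(m)
  V <- matrix(0, K, K, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(K - 1L)) for (k in (j + 1L):K) {
    V[j, k] <- V[k, j] <- pairwise_sd(a[j, ], a[k, ])
  }
  rowSums(V, na.rm = TRUE) / (K - 1L)
}

#' geNorm ranking by iterative exclusion
#'
#' Repeatedly computes M values on the current gene set and excludes the
#' least stable gene (highest M), recording each gene's average stability
#' `M_A` at its exclusion step; the final two genes share the last M_A and
#' cannot be ranked further. The ranking is the reverse exclusion order.
#' Genes with `M_A` above 1 are flagged as unacceptable for heterogeneous
#' sample sets.
#'
#' @inheritParams genorm_m_values
#' @param scope label attached to the result
#' @return a `stability_result` with columns `gene`, `M` (full-panel M),
#'   `M_A` (stability at exclusion step) and `acceptable` (`M_A <= 1`)
#' @export
genorm_ranking <- function(rq, scope = "all") {
  m <- as_rq_mat(rq)
  if (nrow(m) < 3L) stop("geNorm ranking needs at least 3 genes")
  full_M <- genorm_m_values(m)
  remaining <- rownames(m)
  m_a <- stats::setNames(numeric(length(remaining)), remaining)
  exclusion <- character(0)
  tie_seen <- FALSE
  while (length(remaining) > 2L) {
    M <- genorm_m_values(m[remaining, , drop = FALSE])
    mx <- max(M)
    worst <- names(M)[M >= mx - 1e-12]
    if (length(worst) > 1L) {
      tie_seen <- TRUE
      worst <- sort(worst, decreasing = TRUE)[1L]  # drop latest label first
    }
    m_a[worst] <- M[worst]
    exclusion <- c(exclusion, worst)
    remaining <- setdiff(remaining, worst)
  }
  last_M <- genorm_m_values(m[remaining, , drop = FALSE])
  m_a[remaining] <- mean(last_M)          # final pair shares the last M_A
  if (tie_seen)
    warning("ties in M during exclusion; broken by gene label order")
  ranking <- c(sort(remaining), rev(exclusion))
  tab <- data.frame(gene = rownames(m), M = unname(full_M[rownames(m)]),
                    M_A = unname(m_a[rownames(m)]),
                    acceptable = unname(m_a[rownames(m)] <= 1),
                    stringsAsFactors = FALSE)
  res <- new_stability_result("geNorm", scope, tab, "M_A")
  res$ranking <- ranking
  res
}

#' Coefficient of variation of normalised relative quantities
#'
#' Normalises every gene by the per-reaction geometric mean of a reference
#' set and reports the CV (SD / mean) of the normalised values.
#'
#' @inheritParams genorm_m_values
#' @param reference_set character vector of reference gene labels
#' @return named numeric vector of per-gene CV values
#' @export
genorm_cv <- function(rq, reference_set) {
  m <- as_rq_mat(rq)
  if (!length(reference_set)) stop("reference set must be non-empty")
  if (!all(reference_set %in% rownames(m)))
    stop("reference gene(s) absent from the panel")
  nf <- apply(m[reference_set, , drop = FALSE], 2L, geometric_mean,
              na.rm = TRUE)
  z <- sweep(m, 2L, nf, "/")
  apply(z, 1L, function(v) stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE))
}

#' Pairwise variation series V(n/n+1)
#'
#' Determines how many reference genes a normalisation factor needs.
#' `NF_n` is the per-reaction geometric mean of the top n ranked genes;
#' `V(n/n+1)` is the SD over reactions of `log2(NF_n / NF_{n+1})`. The
#' smallest n with V below the cutoff (conventionally 0.15) is the minimal
#' number of reference genes; adding more genes beyond it brings no
#' practical improvement.
#'
#' @inheritParams genorm_m_values
#' @param ranking character vector of genes ordered most to least stable
#'   (length K >= 3)
#' @param cutoff V threshold for the minimal-n decision (default 0.15)
#' @param scope label attached to the result
#' @return an object of class `pairwise_variation`: list with `v` (named
#'   vector `V2/3` ... `V(K-1)/K`), `minimal_n`, `optimal_n`, `cutoff`
#' @export
pairwise_variation <- function(rq, ranking, cutoff = 0.15, scope = "all") {
  m <- as_rq_mat(rq)
  K <- length(ranking)
  if (K < 3L) stop("pairwise variation needs a ranking of at least 3 genes")
  if (!all(ranking %in% rownames(m)))
    stop("ranking contains gene(s) absent from the panel")
  nf <- function(n) apply(m[ranking[seq_len(n)], , drop = FALSE], 2L,
                          geometric_mean, na.rm = TRUE)
  v <- vapply(2:(K - 1L), function(n) {
    stats::sd(log2(nf(n) / nf(n + 1L)), na.rm = TRUE)
  }, numeric(1))
  names(v) <- sprintf("V%d/%d", 2:(K - 1L), 3:K)
  below <- which(v < cutoff)
  if (length(below)) minimal_n <- below[1L] + 1L
  else {
    warning("no V value below the cutoff; minimal_n set to the panel size")
    minimal_n <- K
  }
  structure(list(scope = scope, v = v,
                 minimal_n = as.integer(minimal_n),
                 optimal_n = as.integer(which.min(v) + 1L),
                 cutoff = cutoff),
            class = "pairwise_variation")
}

#' @export
print.pairwise_variation <- function(x, ...) {
  cat("Pairwise variation, scope '", x$scope, "'\n", sep = "")
  print(round(x$v, 4))
  cat("minimal n (V <", x$cutoff, "):", x$minimal_n,
      "| optimal n:", x$optimal_n, "\n")
  invisible(x)
}

#' NormFinder stability values
#'
#' Works on `y = log2(rq)`, column-centred by the per-reaction mean across
#' genes so that global (sample-loading) variation cancels. Without groups
#' the stability value is the bias-corrected SD of a gene's centred values
#' (the centring over K genes contracts variance by (K-1)/K, which is
#' undone). With groups, each gene's intragroup variance and shrunken
#' intergroup deviation are combined:
#' `rho_g = mean over groups of (|d_shrunk| + sqrt(s2/n))`, with the
#' deviation d shrunk by `gamma2 / (gamma2 + s2/n)` where `gamma2` is the
#' across-genes mean squared deviation (moment estimator).
#'
#' @inheritParams genorm_m_values
#' @param groups optional character vector of group labels, one per
#'   reaction; each group needs at least 2 reactions
#' @param scope label attached to the result
#' @return a `stability_result` with column `rho` (log2 units); ranking by
#'   ascending rho
#' @export
normfinder_stability <- function(rq, groups = NULL, scope = "all") {
  m <- as_rq_mat(rq)
  if (nrow(m) < 3L) stop("NormFinder needs at least 3 genes")
  y <- log2(m)
  K <- nrow(y)
  centred <- sweep(y, 2L, colMeans(y, na.rm = TRUE))
  if (is.null(groups)) {
    rho <- apply(centred, 1L, function(v) {
      stats::sd(v, na.rm = TRUE) * sqrt(K / (K - 1L))
    })
  } else {
    groups <- as.character(groups)
    if (length(groups) != ncol(m))
      stop("'groups' must have one label per reaction")
    tab <- table(groups)
    if (length(tab) < 2L) stop("grouped mode needs at least 2 groups")
    if (any(tab < 2L)) stop("every group needs at least 2 reactions")
    glabs <- names(tab)
    overall <- rowMeans(centred, na.rm = TRUE)
    d <- s2 <- matrix(NA_real_, K, length(glabs),
                      dimnames = list(rownames(m), glabs))
    for (a in glabs) {
      z <- centred[, groups == a, drop = FALSE]
      d[, a] <- rowMeans(z, na.rm = TRUE) - overall
      s2[, a] <- apply(z, 1L, function(v) stats::var(v, na.rm = TRUE))
    }
    gamma2 <- mean(d^2)
    n_a <- as.numeric(tab[glabs])
    se2 <- sweep(s2, 2L, n_a, "/")               # s2 / n per group
    d_shrunk <- d * gamma2 / (gamma2 + se2)
    rho <- rowMeans(abs(d_shrunk) + sqrt(se2))
  }
  tab <- data.frame(gene = rownames(m), rho = unname(rho),
                    stringsAsFactors = FALSE)
  new_stability_result("NormFinder", scope, tab, "rho")
}

#' BestKeeper descriptive index
#'
#' A descriptive screen on raw Cq: per gene, the dispersion `sd_cp` is the
#' mean absolute deviation of Cq about the gene's geometric mean Cq (the
#' published BestKeeper convention, despite the conventional "SD" label),
#' `cv_bk = 100 * sd_cp / geomean`. The BestKeeper index is the
#' per-reaction geometric mean of all genes' Cq; each gene's Pearson
#' correlation with the index (`r_index`) is reported descriptively but
#' does not enter the ranking, which is by ascending `sd_cp`.
#'
#' @param cq a [cq_matrix()] (or bare matrix) restricted to one scope
#' @param scope label attached to the result
#' @return a `stability_result` with columns `geomean`, `sd_cp`, `cv_bk`,
#'   `r_index` (`NA` for constant genes)
#' @export
bestkeeper <- function(cq, scope = "all") {
  m <- as_cq_mat(cq)
  if (nrow(m) < 2L) stop("BestKeeper needs at least 2 genes")
  gm <- apply(m, 1L, geometric_mean, na.rm = TRUE)
  sd_cp <- vapply(seq_len(nrow(m)), function(g) {
    mean(abs(m[g, ] - gm[g]), na.rm = TRUE)
  }, numeric(1))
  index <- apply(m, 2L, geometric_mean, na.rm = TRUE)
  r_index <- vapply(seq_len(nrow(m)), function(g) {
    v <- m[g, ]
    ok <- !is.na(v) & !is.na(index)
    if (stats::sd(v[ok]) == 0 || stats::sd(index[ok]) == 0) return(NA_real_)
    stats::cor(v[ok], index[ok])
  }, numeric(1))
  tab <- data.frame(gene = rownames(m), geomean = unname(gm),
                    sd_cp = sd_cp, cv_bk = 100 * sd_cp / unname(gm),
                    r_index = r_index, stringsAsFactors = FALSE)
  new_stability_result("BestKeeper", scope, tab, "sd_cp")
}

#' Comparative delta-Ct stability
#'
#' For every gene pair (g, h) the SD over reactions of the Cq difference
#' `Cq_g - Cq_h` is computed; a gene's score is the mean of its pairwise
#' SDs with all other genes. With all efficiencies equal to 2 this is
#' mathematically identical to the geNorm M value on the corresponding
#' relative quantities (log2 ratios equal negated Cq differences up to a
#' constant).
#'
#' @inheritParams bestkeeper
#' @return a `stability_result` with column `mean_sd` (cycles); ranking by
#'   ascending mean SD
#' @export
delta_ct_stability <- function(cq, scope = "all") {
  m <- as_cq_mat(cq)
  if (nrow(m) < 2L) stop("delta-Ct needs at least 2 genes")
  K <- nrow(m)
  S <- matrix(0, K, K)
  for (j in seq_len(K - 1L)) for (k in (j + 1L):K) {
    S[j, k] <- S[k, j] <- pairwise_sd(m[j, ], m[k, ])
  }
  tab <- data.frame(gene = rownames(m),
                    mean_sd = rowSums(S, na.rm = TRUE) / (K - 1L),
                    stringsAsFactors = FALSE)
  new_stability_result("dCt", scope, tab, "mean_sd")
}

#' Run all five stability methods on one scope
#'
#' Convenience wrapper: converts Cq to relative quantities with the given
#' efficiencies, runs the Brunner stability index, geNorm, NormFinder,
#' BestKeeper and the comparative delta-Ct method, and returns the five
#' `stability_result`s.
#'
#' @param cq a [cq_matrix()]
#' @param eff an [efficiency_table()] or `NULL` for E = 2
#' @param scope panel label or `"all"`; the Cq matrix is subset with
#'   [subset_scope()]
#' @param groups optional column of the annotations to use as NormFinder
#'   groups (e.g. `"group"`), or an explicit vector of labels; `NULL` for
#'   no-group mode
#' @return named list of five `stability_result` objects
#'   (`SI`, `geNorm`, `NormFinder`, `BestKeeper`, `dCt`)
#' @export
stability_suite <- function(cq, eff = NULL, scope = "all", groups = NULL) {
  stopifnot(inherits(cq, "cq_matrix"))
  sc <- subset_scope(cq, scope)
  rq <- cq_to_rq(sc, eff)
  grp <- NULL
  if (!is.null(groups)) {
    grp <- if (length(groups) == 1L && groups %in% names(sc$annotations))
      sc$annotations[[groups]] else groups
  }
  list(SI = stability_index(sc, scope),
       geNorm = genorm_ranking(rq, scope),
       NormFinder = normfinder_stability(rq, grp, scope),
       BestKeeper = bestkeeper(sc, scope),
       dCt = delta_ct_stability(sc, scope))
}

#' Extract ranked lists from stability results
#'
#' @param results list of `stability_result` objects (e.g. from
#'   [stability_suite()])
#' @return list of ranked lists (`method`, `genes`, `scores`) suitable for
#'   [aggregate_ce()] / [aggregate_bruteforce()]
#' @export
stability_rankings <- function(results) {
  lapply(results, function(r) {
    scores <- r$table[[r$score_col]][match(r$ranking, r$table$gene)]
    list(method = r$method, genes = r$ranking, scores = scores)
  })
}
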