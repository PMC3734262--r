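#' Per-reaction normalisation factor
#'
#' The normalisation factor at each reaction is the geometric mean of the
#' reference genes' relative quantities, following the multi-reference
#' normalisation convention.
#'
#' @param rq an `rq_matrix` (or bare positive matrix)
#' @param reference_genes character vector of reference gene labels
#' @return object of class `normalization_factor`: list with
#'   `reference_genes` and `nf` (named positive vector, one per reaction)
#' @export
normalization_factor <- function(rq, reference_genes) {
  m <- as_rq_mat(rq)
  if (!length(reference_genes)) stop("reference gene list must be non-empty")
  if (!all(reference_genes %in% rownames(m)))
    stop("reference gene(s) absent: ",
         paste(setdiff(reference_genes, rownames(m)), collapse = ", "))
  nf <- apply(m[reference_genes, , drop = FALSE], 2L, geometric_mean,
              na.rm = TRUE)
  structure(list(reference_genes = reference_genes, nf = nf),
            class = "normalization_factor")
}

# collapse technical replicates on the Cq scale (mean per
# panel/condition/bio_rep sample); standard practice for quantification,
# unlike the stability stage where each reaction is an observation
average_tech_reps <- function(cq) {
  stopifnot(inherits(cq, "cq_matrix"))
  ann <- cq$annotations
  key <- paste(ann$panel, ann$condition, ann$bio_rep, sep = "\r")
  samples <- !duplicated(key)
  idx <- match(key, key[samples])
  m <- matrix(NA_real_, nrow(cq$cq), sum(samples))
  for (s in seq_len(sum(samples))) {
    m[, s] <- rowMeans(cq$cq[, idx == s, drop = FALSE], na.rm = TRUE)
  }
  m[is.nan(m)] <- NA_real_
  ann2 <- ann[samples, , drop = FALSE]
  ann2$tech_rep <- 1L
  ann2$reaction_id <- paste(ann2$panel, ann2$condition, ann2$bio_rep,
                            sep = ".")
  dimnames(m) <- list(rownames(cq$cq), ann2$reaction_id)
  cq_matrix(m, ann2)
}

# default calibrator lookup: for a non-mock condition, the mock condition
# in the same panel sharing the label prefix before the final ".", else
# the panel's single mock condition
default_calibrator <- function(ann) {
  cells <- unique(ann[, c("panel", "condition", "is_mock")])
  out <- character(0)
  for (p in unique(cells$panel)) {
    pc <- cells[cells$panel == p, ]
    mocks <- pc$condition[pc$is_mock]
    for (cond in pc$condition) {
      if (cond %in% mocks) { cal <- cond }
      else {
        guess <- sub("\\.[^.]*$", ".mock", cond)
        cal <- if (guess %in% mocks) guess
               else if (length(mocks) == 1L) mocks
               else NA_character_
      }
      if (is.na(cal))
        stop("no calibrator (mock) condition found for block ",
             p, " / ", cond)
      out[paste(p, cond, sep = "\r")] <- cal
    }
  }
  out
}

#' Efficiency-corrected relative expression of a target gene
#'
#' Technical replicates are first averaged on the Cq scale; Cq values are
#' then converted to efficiency-corrected relative quantities, the target
#' is divided by the normalisation factor (geometric mean of the reference
#' genes), and each condition's fold change is the mean normalised
#' quantity over its biological replicates divided by that of its
#' calibrator condition. The SD is computed over biological replicates of
#' the per-replicate fold changes. Calibrator conditions report a fold
#' change of 1 by construction.
#'
#' @param cq a [cq_matrix()] containing the target and reference genes
#' @param target target gene label
#' @param references character vector of reference gene labels
#' @param eff an [efficiency_table()] or `NULL` for E = 2
#' @param calibrator `NULL` for the default mock-matching rule (a
#'   condition's calibrator is the mock condition in the same panel with
#'   the same time-point prefix, else the panel's single mock condition),
#'   or a named character vector mapping `"panel\rcondition"` keys to
#'   calibrator condition labels, or a single condition label used for
#'   every block of every panel
#' @return object of class `expression_profile`: data frame with columns
#'   `panel`, `condition`, `group`, `calibrator`, `fold_change`, `sd`,
#'   `n_bio`
#' @export
normalized_expression <- function(cq, target, references, eff = NULL,
                                  calibrator = NULL) {
  stopifnot(inherits(cq, "cq_matrix"))
  if (!target %in% rownames(cq$cq)) stop("target gene absent: ", target)
  if (target %in% references)
    stop("target gene cannot be its own reference")
  avg <- average_tech_reps(cq)
  rq <- cq_to_rq(avg, eff)
  nf <- normalization_factor(rq, references)
  q <- rq$rq[target, ] / nf$nf
  ann <- avg$annotations

  cal_map <- if (is.null(calibrator)) default_calibrator(ann)
  else if (length(calibrator) == 1L && is.null(names(calibrator))) {
    cells <- unique(ann[, c("panel", "condition")])
    stats::setNames(rep(calibrator, nrow(cells)),
                    paste(cells$panel, cells$condition, sep = "\r"))
  } else calibrator

  cells <- unique(ann[, c("panel", "condition", "group")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- cells$panel[i]; cond <- cells$condition[i]
    key <- paste(p, cond, sep = "\r")
    cal <- cal_map[[key]]
    if (is.null(cal) || is.na(cal))
      stop("no calibrator defined for block ", p, " / ", cond)
    cal_q <- q[ann$panel == p & ann$condition == cal]
    cal_q <- cal_q[!is.na(cal_q)]
    if (!length(cal_q))
      stop("calibrator condition '", cal, "' has no data in panel ", p)
    this_q <- q[ann$panel == p & ann$condition == cond]
    this_q <- this_q[!is.na(this_q)]
    per_rep <- this_q / mean(cal_q)
    data.frame(panel = p, condition = cond, group = cells$group[i],
               calibrator = cal,
               fold_change = mean(per_rep),
               sd = if (length(per_rep) > 1L) stats::sd(per_rep) else 0,
               n_bio = length(per_rep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("expression_profile", "data.frame")
  attr(out, "target") <- target
  attr(out, "references") <- references
  out
}

#' Normalisation-bias contrast between reference choices
#'
#' Quantifies how much the reported expression profile of a target gene
#' shifts when an unstable reference replaces the recommended reference
#' set: the profile is computed under both choices and the per-condition
#' bias is `log2(fold_worst / fold_best)`.
#'
#' @inheritParams normalized_expression
#' @param best_refs recommended reference gene labels
#' @param worst_ref single unstable reference gene label
#' @return list with `best` and `worst` (two `expression_profile`s) and
#'   `bias` (data frame with per-condition log2 bias)
#' @export
bias_contrast <- function(cq, target, best_refs, worst_ref, eff = NULL,
                          calibrator = NULL) {
  best <- normalized_expression(cq, target, best_refs, eff, calibrator)
  worst <- normalized_expression(cq, target, worst_ref, eff, calibrator)
  stopifnot(identical(best$condition, worst$condition))
  bias <- data.frame(panel = best$panel, condition = best$condition,
                     bias = log2(worst$fold_change / best$fold_change),
                     stringsAsFactors = FALSE)
  list(best = best, worst = worst, bias = bias)
}
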