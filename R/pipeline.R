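#' Run the full reference-gene evaluation workflow
#'
#' Executes the complete workflow on a Cq panel: per-scope stability
#' scoring by all five methods, pairwise-variation analysis of the geNorm
#' ranking, Cross-Entropy consensus aggregation of the five rankings, and
#' (optionally) efficiency-corrected quantification of a target gene
#' normalised to the top consensus references. Results can be written as
#' one CSV per method and scope plus a machine-readable JSON bundle.
#'
#' @param cq a [cq_matrix()]
#' @param eff an [efficiency_table()] or `NULL` for E = 2
#' @param scopes `"each"` (default) analyses every panel plus the pooled
#'   `"all"` scope; otherwise a character vector of scope labels
#' @param groups optional NormFinder grouping (annotation column name or
#'   label vector); `NULL` for no-group mode
#' @param target optional target gene for validation quantification; it is
#'   excluded from the stability candidate set
#' @param n_references number of top consensus genes used as the reference
#'   set for quantification (default 2)
#' @param calibrator calibrator specification passed to
#'   [normalized_expression()]
#' @param cutoff pairwise-variation cutoff (default 0.15)
#' @param seed integer seed for the Cross-Entropy optimiser (required)
#' @param out_dir optional output directory for CSV/JSON artifacts
#' @param ... further arguments passed to [aggregate_ce()]
#' @return invisibly, a list with one element per scope (each holding
#'   `stability`, `pairwise_variation`, `consensus`, `top_references`) and,
#'   if a target was given, `quantification` per scope
#' @export
run_full_pipeline <- function(cq, eff = NULL, scopes = "each", groups = NULL,
                              target = NULL, n_references = 2L,
                              calibrator = NULL, cutoff = 0.15,
                              seed = NULL, out_dir = NULL, ...) {
  stopifnot(inherits(cq, "cq_matrix"))
  if (is.null(seed))
    stop("a seed is required: the consensus aggregation stage is stochastic")
  if (identical(scopes, "each"))
    scopes <- c(unique(cq$annotations$panel), "all")
  candidates <- setdiff(rownames(cq$cq), target)
  cand_cq <- structure(list(cq = cq$cq[candidates, , drop = FALSE],
                            annotations = cq$annotations),
                       class = "cq_matrix")
  bundle <- list(seed = as.integer(seed), scopes = list())
  for (i in seq_along(scopes)) {
    sc <- scopes[i]
    res <- stability_suite(cand_cq, eff, sc, groups)
    rq <- cq_to_rq(subset_scope(cand_cq, sc), eff)
    pv <- pairwise_variation(rq, res$geNorm$ranking, cutoff, sc)
    cons <- aggregate_ce(stability_rankings(res),
                         seed = as.integer(seed) + i, ...)
    top <- cons$genes[seq_len(min(n_references, length(cons$genes)))]
    entry <- list(stability = res, pairwise_variation = pv,
                  consensus = cons, top_references = top)
    if (!is.null(target) && !identical(sc, "all")) {
      entry$quantification <- tryCatch(
        normalized_expression(subset_scope(cq, sc), target, top, eff,
                              calibrator),
        error = function(e) {
          message("[quantify] scope ", sc, " skipped: ", conditionMessage(e))
          NULL
        })
    }
    bundle$scopes[[sc]] <- entry
  }
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  invisible(bundle)
}

#' Write pipeline results as CSV tables and a JSON bundle
#'
#' Emits one CSV per stability method and scope (columns in the
#' conventional order: mean, SD, CV, slope, intercept, SI for the
#' stability index), a consensus table of ordered genes per scope, and a
#' JSON bundle of all rankings and statistics. Output is deterministic
#' given the pipeline seed: no timestamps are written.
#'
#' @param bundle result of [run_full_pipeline()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  consensus_rows <- list()
  for (sc in names(bundle$scopes)) {
    entry <- bundle$scopes[[sc]]
    safe <- gsub("[^A-Za-z0-9_-]", "_", sc)
    for (mth in names(entry$stability)) {
      tab <- entry$stability[[mth]]$table
      tab <- tab[order(tab[[entry$stability[[mth]]$score_col]]), ]
      p <- file.path(out_dir, sprintf("stability_%s_%s.csv", mth, safe))
      utils::write.csv(tab, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    consensus_rows[[sc]] <- data.frame(
      scope = sc, rank = seq_along(entry$consensus$genes),
      gene = entry$consensus$genes, stringsAsFactors = FALSE)
    if (!is.null(entry$quantification)) {
      p <- file.path(out_dir, sprintf("quantification_%s.csv", safe))
      utils::write.csv(entry$quantification, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  p <- file.path(out_dir, "consensus.csv")
  utils::write.csv(do.call(rbind, consensus_rows), p, row.names = FALSE)
  paths <- c(paths, p)

  json <- list(seed = bundle$seed, scopes = lapply(bundle$scopes, function(e) {
    list(rankings = lapply(e$stability, function(r) r$ranking),
         scores = lapply(e$stability, function(r) {
           stats::setNames(as.list(r$table[[r$score_col]]), r$table$gene)
         }),
         pairwise_variation = list(v = as.list(e$pairwise_variation$v),
                                   minimal_n = e$pairwise_variation$minimal_n,
                                   optimal_n = e$pairwise_variation$optimal_n),
         consensus = list(genes = e$consensus$genes,
                          objective = e$consensus$objective,
                          iterations = e$consensus$iterations,
                          converged = e$consensus$converged),
         top_references = e$top_references)
  }))
  p <- file.path(out_dir, "bundle.json")
  jsonlite::write_json(json, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Published strawberry reference-panel summary statistics
#'
#' Per-gene summary statistics (mean Cq, SD, CV %, regression slope and
#' intercept, stability index) for a published 13-gene strawberry
#' defense-response RT-qPCR reference panel, covering seven experiment
#' panels plus the pooled analysis (104 gene x scope rows). Used to check
#' the package's stability-index arithmetic against independently computed
#' values.
#'
#' @return data frame with columns `scope`, `n`, `gene`, `mean`, `sd`,
#'   `cv`, `slope`, `intercept`, `si`
#' @export
published_stability_panel <- function() {
  path <- system.file("extdata", "strawberry_stability_panel.csv",
                      package = "qpcrstab", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
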