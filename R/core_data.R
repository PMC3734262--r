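#' Construct a Cq matrix with reaction annotations
#'
#' The universal input object of the package: a genes x reactions matrix of
#' quantification-cycle (Cq) values together with per-reaction annotations.
#' Each reaction (one well) is a single observation; technical replicates are
#' deliberately *not* pre-averaged, so that replicate scatter contributes to
#' every downstream stability statistic.
#'
#' @param cq numeric matrix, genes in rows, reactions in columns. Row names
#'   are amplicon labels, column names reaction ids. Missing wells are `NA`;
#'   present values must be finite and in (0, 45) cycles.
#' @param annotations data frame with one row per reaction and columns
#'   `reaction_id`, `panel`, `condition`, `group`, `bio_rep`, `tech_rep`,
#'   `is_mock`. Row order must match the columns of `cq`.
#' @return an object of class `cq_matrix`: a list with elements `cq`
#'   (numeric matrix) and `annotations` (data frame).
#' @examples
#' cq <- matrix(c(20, 21, 15, 16), 2, 2, byrow = TRUE,
#'              dimnames = list(c("gA", "gB"), c("r1", "r2")))
#' ann <- data.frame(reaction_id = c("r1", "r2"), panel = "P1",
#'                   condition = c("c1", "c2"), group = "none",
#'                   bio_rep = 1L, tech_rep = 1L, is_mock = FALSE)
#' cq_matrix(cq, ann)
#' @export
cq_matrix <- function(cq, annotations) {
  if (!is.matrix(cq) || !is.numeric(cq))
    stop("'cq' must be a numeric matrix (genes x reactions)")
  if (is.null(rownames(cq)) || is.null(colnames(cq)))
    stop("'cq' must carry gene row names and reaction column names")
  if (anyDuplicated(rownames(cq)))
    stop("duplicated gene labels: ",
         paste(unique(rownames(cq)[duplicated(rownames(cq))]), collapse = ", "))
  if (anyDuplicated(colnames(cq)))
    stop("duplicated reaction ids: ",
         paste(unique(colnames(cq)[duplicated(colnames(cq))]), collapse = ", "))
  present <- cq[!is.na(cq)]
  if (any(!is.finite(present)))
    stop("non-finite Cq values present")
  if (any(present <= 0 | present >= 45))
    stop("Cq values must lie in (0, 45) cycles")
  annotations <- validate_annotations(annotations)
  if (nrow(annotations) != ncol(cq))
    stop("annotation rows (", nrow(annotations),
         ") do not match reaction columns (", ncol(cq), ")")
  if (!identical(as.character(annotations$reaction_id), colnames(cq)))
    stop("annotation reaction ids must match 'cq' column names in order")
  structure(list(cq = cq, annotations = annotations), class = "cq_matrix")
}

validate_annotations <- function(ann) {
  needed <- c("reaction_id", "panel", "condition", "group",
              "bio_rep", "tech_rep", "is_mock")
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols))
    stop("annotation columns missing: ", paste(missing_cols, collapse = ", "))
  ann <- as.data.frame(ann)[, needed]
  ann$reaction_id <- as.character(ann$reaction_id)
  ann$panel <- as.character(ann$panel)
  ann$condition <- as.character(ann$condition)
  ann$group <- as.character(ann$group)
  ann$bio_rep <- as.integer(ann$bio_rep)
  ann$tech_rep <- as.integer(ann$tech_rep)
  ann$is_mock <- as.logical(ann$is_mock)
  if (any(ann$bio_rep < 1L) || any(ann$tech_rep < 1L))
    stop("bio_rep and tech_rep must be positive integers")
  key <- paste(ann$panel, ann$condition, ann$bio_rep, ann$tech_rep,
               sep = "\r")
  if (anyDuplicated(key))
    stop("(panel, condition, bio_rep, tech_rep) must uniquely ",
         "identify a reaction")
  rownames(ann) <- NULL
  ann
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat("Cq matrix: ", nrow(x$cq), " genes x ", ncol(x$cq), " reactions\n",
      sep = "")
  cat("Panels:", paste(unique(x$annotations$panel), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$cq))
  if (nmiss) cat("Missing wells:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.cq_matrix <- function(x) dim(x$cq)

#' Genes of a Cq matrix
#' @param x a `cq_matrix`
#' @return character vector of amplicon labels
#' @export
genes <- function(x) rownames(x$cq)

#' Restrict a Cq matrix to one analysis scope
#'
#' Selects the reactions of a single experiment panel (or all reactions for
#' the pooled `"all"` scope) and applies the missing-data policy: genes with
#' fewer than 3 present Cq values in the scope are dropped with a warning.
#'
#' @param x a `cq_matrix`
#' @param scope a panel label, or `"all"` for the pooled analysis
#' @param min_present minimum number of present values a gene needs to stay
#'   in the scope (default 3)
#' @return a `cq_matrix` restricted to the scope
#' @export
subset_scope <- function(x, scope = "all", min_present = 3L) {
  stopifnot(inherits(x, "cq_matrix"))
  keep <- if (identical(scope, "all")) rep(TRUE, ncol(x$cq))
          else x$annotations$panel == scope
  if (!any(keep)) stop("no reactions in scope '", scope, "'")
  cq <- x$cq[, keep, drop = FALSE]
  ann <- x$annotations[keep, , drop = FALSE]
  rownames(ann) <- NULL
  n_present <- rowSums(!is.na(cq))
  drop <- n_present < min_present
  if (any(drop)) {
    warning("dropping gene(s) with < ", min_present, " present Cq values in ",
            "scope '", scope, "': ",
            paste(rownames(cq)[drop], collapse = ", "))
    cq <- cq[!drop, , drop = FALSE]
  }
  structure(list(cq = cq, annotations = ann), class = "cq_matrix")
}

#' Read a Cq table and its reaction annotations
#'
#' Reads a delimited text file with genes in rows (first column = gene label,
#' header = reaction ids) plus a CSV of reaction annotations. Decimal commas,
#' as printed in many qPCR software exports, are accepted alongside decimal
#' points.
#'
#' @param path path to the Cq table (TSV or CSV; the delimiter is sniffed
#'   from the header line)
#' @param annotation_path path to the annotation CSV with columns
#'   `reaction_id`, `panel`, `condition`, `group`, `bio_rep`, `tech_rep`,
#'   `is_mock`
#' @return a `cq_matrix`
#' @seealso [write_cq_table()] for the inverse operation
#' @export
read_cq_table <- function(path, annotation_path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("no data rows in ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no data rows in ", path)
  gene_labels <- raw[[1L]]
  if (anyDuplicated(gene_labels))
    stop("duplicated gene labels in ", path)
  body <- raw[, -1L, drop = FALSE]
  cq <- matrix(NA_real_, nrow(body), ncol(body),
               dimnames = list(gene_labels, colnames(body)))
  for (j in seq_len(ncol(body))) {
    cell <- trimws(body[[j]])
    cell[cell %in% c("", "NA", "ND")] <- NA
    val <- suppressWarnings(as.numeric(sub(",", ".", cell, fixed = TRUE)))
    bad <- !is.na(cell) & is.na(val)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("non-numeric Cq value '", cell[i], "' at gene ", gene_labels[i],
           ", reaction ", colnames(body)[j])
    }
    cq[, j] <- val
  }
  ann <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
  ann <- validate_annotations(ann)
  unknown <- setdiff(ann$reaction_id, colnames(cq))
  if (length(unknown))
    stop("annotation reaction id(s) not present in the Cq table: ",
         paste(unknown, collapse = ", "))
  missing_ann <- setdiff(colnames(cq), ann$reaction_id)
  if (length(missing_ann))
    stop("reaction(s) lacking annotation: ",
         paste(missing_ann, collapse = ", "))
  ann <- ann[match(colnames(cq), ann$reaction_id), , drop = FALSE]
  cq_matrix(cq, ann)
}

#' Write a Cq matrix and its annotations to delimited text
#'
#' @param x a `cq_matrix`
#' @param path output path for the Cq table (TSV)
#' @param annotation_path output path for the annotation CSV
#' @param digits significant digits to keep (default 15, round-trip safe)
#' @return invisibly, `x`
#' @export
write_cq_table <- function(x, path, annotation_path, digits = 15L) {
  stopifnot(inherits(x, "cq_matrix"))
  tab <- data.frame(gene = rownames(x$cq),
                    signif(x$cq, digits),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(x$annotations, annotation_path, row.names = FALSE)
  invisible(x)
}

#' Construct a per-amplicon PCR efficiency table
#'
#' Stores the mean per-cycle amplification factor E of each amplicon,
#' its standard deviation over reactions, and the number of reactions
#' used. E = 2 means perfect doubling per cycle; values at or below 1
#' are rejected because they imply no amplification.
#'
#' @param gene character vector of amplicon labels
#' @param mean_E numeric, mean amplification factor per cycle, in (1, 2.2]
#' @param sd_E numeric, standard deviation of E (default 0)
#' @param n_reactions integer, number of reactions behind each mean (default 1)
#' @return an object of class `efficiency_table` (a data frame)
#' @export
efficiency_table <- function(gene, mean_E, sd_E = 0, n_reactions = 1L) {
  if (anyDuplicated(gene)) stop("duplicated amplicon labels")
  if (any(!is.finite(mean_E)) || any(mean_E <= 1))
    stop("mean_E must be > 1 (amplification factor per cycle)")
  if (any(mean_E > 2.2))
    warning("mean_E above 2.2 is implausible for PCR")
  out <- data.frame(gene = as.character(gene), mean_E = as.numeric(mean_E),
                    sd_E = as.numeric(sd_E),
                    n_reactions = as.integer(n_reactions),
                    stringsAsFactors = FALSE)
  class(out) <- c("efficiency_table", "data.frame")
  out
}

#' Default efficiency table (perfect doubling)
#'
#' @param gene character vector of amplicon labels
#' @return an `efficiency_table` with E = 2 for every amplicon
#' @export
default_efficiency <- function(gene) efficiency_table(gene, rep(2, length(gene)))

efficiency_for <- function(eff, gene_labels) {
  if (is.null(eff)) return(stats::setNames(rep(2, length(gene_labels)),
                                           gene_labels))
  stopifnot(inherits(eff, "efficiency_table"))
  idx <- match(gene_labels, eff$gene)
  E <- ifelse(is.na(idx), 2, eff$mean_E[idx])
  if (any(E <= 1)) stop("efficiency must be > 1 for quantification")
  stats::setNames(E, gene_labels)
}

#' Convert Cq values to efficiency-corrected relative quantities
#'
#' For each gene g the relative quantity at reaction i is
#' `rq = E_g ^ (minCq_g - cq_gi)`, i.e. quantities are expressed relative to
#' the gene's most abundant (minimum-Cq) reaction, so `rq` lies in (0, 1].
#' The calibration constant cancels in every downstream ratio-based
#' statistic, so the choice of calibrator is consequence-free.
#'
#' @param cq a `cq_matrix`
#' @param eff an `efficiency_table`, or `NULL` for E = 2 everywhere
#' @return an object of class `rq_matrix`: list with `rq` (matrix, same
#'   shape as the Cq matrix) and `annotations`
#' @examples
#' cq <- matrix(c(20, 21), 1, 2, dimnames = list("gA", c("r1", "r2")))
#' ann <- data.frame(reaction_id = c("r1", "r2"), panel = "P", condition = "c",
#'                   group = c("a", "b"), bio_rep = 1L, tech_rep = 1L,
#'                   is_mock = FALSE)
#' cq_to_rq(cq_matrix(cq, ann))$rq   # 1 and 0.5 at E = 2
#' @export
cq_to_rq <- function(cq, eff = NULL) {
  stopifnot(inherits(cq, "cq_matrix"))
  E <- efficiency_for(eff, rownames(cq$cq))
  all_missing <- rowSums(!is.na(cq$cq)) == 0L
  if (any(all_missing))
    stop("gene(s) with no observed Cq: ",
         paste(rownames(cq$cq)[all_missing], collapse = ", "))
  min_cq <- apply(cq$cq, 1L, min, na.rm = TRUE)
  rq <- E ^ (min_cq - cq$cq)   # E, min_cq recycle along rows
  structure(list(rq = rq, annotations = cq$annotations), class = "rq_matrix")
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat("Relative-quantity matrix: ", nrow(x$rq), " genes x ", ncol(x$rq),
      " reactions\n", sep = "")
  invisible(x)
}

#' Geometric mean
#'
#' @param values positive numeric vector (length >= 1); `NA`s dropped when
#'   `na.rm = TRUE`
#' @param na.rm drop missing values first (default `FALSE`)
#' @return `exp(mean(log(values)))`
#' @export
geometric_mean <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (!length(values)) stop("geometric mean of an empty vector")
  if (any(is.na(values)) || any(values <= 0))
    stop("geometric mean requires strictly positive values")
  exp(mean(log(values)))
}
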