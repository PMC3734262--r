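#' Default experimental design for the synthetic study
#'
#' Seven panels totalling 48 experimental cells: a five-stage fruit-ripening
#' series, four fungal-infection panels (fruit, crown and petiole tissue in
#' two cultivars, mock vs infected time courses), and two hormone-elicitation
#' panels (mock / salicylic acid / methyl jasmonate time courses). With the
#' default 2 biological x 2 technical replicates this yields 192 reactions
#' per gene.
#'
#' @return data frame with columns `panel`, `condition`, `group`, `is_mock`
#' @export
default_study_design <- function() {
  cell <- function(panel, condition, group, is_mock)
    data.frame(panel = panel, condition = condition, group = group,
               is_mock = is_mock, stringsAsFactors = FALSE)
  rbind(
    cell("RCF", c("G", "W", "R", "OR", "SE"), "none", FALSE),
    cell("FCF", "mock", "mock", TRUE),
    cell("FCF", paste0("grade", 1:4), "infected", FALSE),
    cell("FCC", paste0("d", c(1, 3, 5, 7), ".mock"), "mock", TRUE),
    cell("FCC", paste0("d", c(1, 3, 5, 7), ".inf"), "infected", FALSE),
    cell("FCP", paste0("d", c(1, 3, 5, 7), ".mock"), "mock", TRUE),
    cell("FCP", paste0("d", c(1, 3, 5, 7), ".inf"), "infected", FALSE),
    cell("FAP", paste0("d", c(3, 5, 7), ".mock"), "mock", TRUE),
    cell("FAP", paste0("d", c(1, 3, 5, 7), ".inf"), "infected", FALSE),
    cell("HCY", paste0("h", c(12, 24, 48), ".mock"), "mock", TRUE),
    cell("HCY", paste0("h", c(12, 24, 48), ".SA"), "SA", FALSE),
    cell("HCY", paste0("h", c(12, 24, 48), ".MeJA"), "MeJA", FALSE),
    cell("HCC", paste0("h", c(4, 6), ".mock"), "mock", TRUE),
    cell("HCC", paste0("h", c(4, 6), ".SA"), "SA", FALSE),
    cell("HCC", paste0("h", c(4, 6), ".MeJA"), "MeJA", FALSE)
  )
}

#' Configuration for the synthetic Cq study generator
#'
#' The generative model on the Cq (log) scale is
#' `Cq[g,c,b,t] = b_g + s_g * L_c + delta_g(group(c)) + u[g,c,b] + e[g,c,b,t]`
#' with condition loads `L_c ~ N(0,1)` shared across genes, biological noise
#' `u ~ N(0, sigma_bio_g^2)` per biological replicate and technical noise
#' `e ~ N(0, sigma_tech_g^2)` per reaction.
#'
#' Defaults emulate a 13-gene reference panel evaluated over 7 experiment
#' panels (48 cells) with 2 x 2 replicates: baselines drawn uniformly on
#' [8, 30] cycles, per-gene combined noise SD ramping linearly from 0.2 to
#' 1.7 cycles (split equally between biological and technical components),
#' load sensitivity ramping from 0 to 0.6, and no group effects. Gene 1 is
#' therefore a designed "true reference" (zero load sensitivity, minimal
#' noise).
#'
#' @param n_genes number of candidate genes (default 13)
#' @param design data frame of experimental cells as in
#'   [default_study_design()], or `NULL` to use the default; alternatively a
#'   list of `(panel, n_conditions, n_groups)` triples from which a generic
#'   design is built
#' @param bio_reps,tech_reps replicate counts (defaults 2 and 2)
#' @param baseline per-gene baseline Cq; `NULL` (default) draws uniformly
#'   on [8, 30] at simulation time
#' @param slope per-gene load sensitivity s_g (>= 0)
#' @param sigma_bio,sigma_tech per-gene noise SDs (cycles)
#' @param group_effect matrix of per-gene, per-group Cq shifts (genes x
#'   groups, dimnames required), or `NULL` for none
#' @param seed integer seed controlling all randomness
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_genes = 13L,
                       design = NULL,
                       bio_reps = 2L,
                       tech_reps = 2L,
                       baseline = NULL,
                       slope = NULL,
                       sigma_bio = NULL,
                       sigma_tech = NULL,
                       group_effect = NULL,
                       seed = 1L) {
  if (bio_reps < 1L || tech_reps < 1L)
    stop("replicate counts must be positive")
  if (is.null(design)) design <- default_study_design()
  if (!is.data.frame(design)) design <- build_generic_design(design)
  stopifnot(all(c("panel", "condition", "group", "is_mock") %in% names(design)))
  ramp <- seq(0.2, 1.7, length.out = n_genes) # combined noise SD, cycles
  if (is.null(sigma_bio)) sigma_bio <- ramp / sqrt(2)
  if (is.null(sigma_tech)) sigma_tech <- ramp / sqrt(2)
  if (is.null(slope)) slope <- seq(0, 0.6, length.out = n_genes)
  if (any(sigma_bio < 0) || any(sigma_tech < 0) || any(slope < 0))
    stop("sigma_bio, sigma_tech and slope must be non-negative")
  structure(list(n_genes = as.integer(n_genes), design = design,
                 bio_reps = as.integer(bio_reps),
                 tech_reps = as.integer(tech_reps),
                 baseline = baseline, slope = slope,
                 sigma_bio = sigma_bio, sigma_tech = sigma_tech,
                 group_effect = group_effect, seed = as.integer(seed)),
            class = "sim_config")
}

build_generic_design <- function(panels) {
  rows <- lapply(panels, function(p) {
    label <- as.character(p[[1L]]); nc <- as.integer(p[[2L]])
    ng <- as.integer(p[[3L]])
    grp <- if (ng <= 1L) rep("none", nc)
           else c("mock", paste0("grp", seq_len(ng - 1L)))[
             rep(seq_len(ng), length.out = nc)]
    data.frame(panel = label, condition = paste0("c", seq_len(nc)),
               group = grp, is_mock = grp == "mock",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a Cq study with known ground truth
#'
#' Draws a full Cq panel under the model described in [sim_config()] and
#' returns it together with the realised generator parameters and the
#' implied true stability order. A gene's total perturbation score is
#' `tau_g = sqrt(sigma_bio^2 + sigma_tech^2) + s_g * SD(L) + SD(delta_g,.)`;
#' genes sorted by ascending tau form the ground-truth stability ranking
#' that parameter-recovery tests compare against.
#'
#' @param config a `sim_config`
#' @return list with elements `cq` (a [cq_matrix()]) and `truth` (list with
#'   `params` data frame, `loads`, and `true_stability_order`)
#' @examples
#' sim <- simulate_study(sim_config(seed = 42))
#' dim(sim$cq)           # 13 genes x 192 reactions
#' head(sim$truth$true_stability_order)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  gene_labels <- sprintf("G%02d", seq_len(ng))
  baseline <- config$baseline
  if (is.null(baseline)) baseline <- stats::runif(ng, 8, 30)
  if (length(baseline) != ng || length(config$slope) != ng ||
      length(config$sigma_bio) != ng || length(config$sigma_tech) != ng)
    stop("per-gene parameter vectors must have length n_genes")

  design <- config$design
  n_cells <- nrow(design)
  loads <- stats::rnorm(n_cells)             # shared condition loads
  loads <- loads - mean(loads)               # zero-mean by construction

  ge <- config$group_effect
  group_shift <- function(g, grp) {
    if (is.null(ge)) return(0)
    if (is.null(rownames(ge)) || is.null(colnames(ge)))
      stop("group_effect needs gene row names and group column names")
    gl <- gene_labels[g]
    if (!gl %in% rownames(ge) || !grp %in% colnames(ge)) return(0)
    ge[gl, grp]
  }

  br <- config$bio_reps; tr <- config$tech_reps
  reactions <- data.frame(
    cell = rep(seq_len(n_cells), each = br * tr),
    bio_rep = rep(rep(seq_len(br), each = tr), times = n_cells),
    tech_rep = rep(seq_len(tr), times = n_cells * br)
  )
  n_rx <- nrow(reactions)
  ann <- data.frame(
    reaction_id = sprintf("%s.%s.b%d.t%d",
                          design$panel[reactions$cell],
                          design$condition[reactions$cell],
                          reactions$bio_rep, reactions$tech_rep),
    panel = design$panel[reactions$cell],
    condition = design$condition[reactions$cell],
    group = design$group[reactions$cell],
    bio_rep = reactions$bio_rep,
    tech_rep = reactions$tech_rep,
    is_mock = design$is_mock[reactions$cell],
    stringsAsFactors = FALSE
  )

  cq <- matrix(NA_real_, ng, n_rx, dimnames = list(gene_labels,
                                                   ann$reaction_id))
  bio_key <- paste(reactions$cell, reactions$bio_rep)
  bio_idx <- match(bio_key, unique(bio_key))
  n_bio <- max(bio_idx)
  for (g in seq_len(ng)) {
    u <- stats::rnorm(n_bio, 0, config$sigma_bio[g])
    e <- stats::rnorm(n_rx, 0, config$sigma_tech[g])
    shift <- vapply(design$group[reactions$cell],
                    function(grp) group_shift(g, grp), numeric(1))
    cq[g, ] <- baseline[g] + config$slope[g] * loads[reactions$cell] +
      shift + u[bio_idx] + e
  }

  sd_delta <- vapply(seq_len(ng), function(g) {
    grps <- unique(design$group)
    if (is.null(ge) || length(grps) < 2L) return(0)
    d <- vapply(grps, function(grp) group_shift(g, grp), numeric(1))
    stats::sd(d)
  }, numeric(1))
  tau <- sqrt(config$sigma_bio^2 + config$sigma_tech^2) +
    config$slope * stats::sd(loads) + sd_delta
  params <- data.frame(gene = gene_labels, baseline = baseline,
                       slope = config$slope, sigma_bio = config$sigma_bio,
                       sigma_tech = config$sigma_tech, sd_delta = sd_delta,
                       tau = tau, stringsAsFactors = FALSE)
  truth <- list(params = params, loads = loads,
                true_stability_order = gene_labels[order(tau)])
  list(cq = cq_matrix(cq, ann), truth = truth)
}

#' Simulate raw amplification curves with a logistic plateau
#'
#' Noiseless fluorescence follows
#' `F_c = plateau * F0 * E^c / (plateau + F0 * (E^c - 1))`, the solution of
#' logistic amplification: exactly exponential (`F0 * E^c`) while far below
#' the plateau, saturating at `plateau`. Gaussian read noise is added per
#' cycle and readings are clipped at zero.
#'
#' @param n_curves number of curves to draw
#' @param E_true true per-cycle amplification factor, in (1, 2]
#' @param F0 initial template fluorescence equivalent (default 1e-6)
#' @param plateau fluorescence cap (default 10; `Inf` gives a pure
#'   exponential)
#' @param noise_sd per-cycle Gaussian read noise SD (default 2e-3,
#'   i.e. 0.02 % of the plateau — typical real-time PCR baseline scatter)
#' @param n_cycles cycles per curve (default 40)
#' @param amplicon amplicon label attached to the curves
#' @param seed integer seed
#' @return list of `amplification_curve` objects (lists with `reaction_id`,
#'   `amplicon`, `fluorescence`)
#' @export
simulate_amplification_curves <- function(n_curves, E_true = 1.8, F0 = 1e-6,
                                          plateau = 10, noise_sd = 2e-3,
                                          n_cycles = 40L, amplicon = "amp1",
                                          seed = 1L) {
  if (!is.finite(E_true) || E_true <= 1 || E_true > 2)
    stop("E_true must lie in (1, 2]")
  if (F0 <= 0) stop("F0 must be positive")
  if (plateau <= F0) stop("plateau must exceed F0")
  set.seed(seed)
  cycles <- seq_len(n_cycles)
  clean <- if (is.infinite(plateau)) F0 * E_true ^ cycles
           else plateau * F0 * E_true ^ cycles /
                (plateau + F0 * (E_true ^ cycles - 1))
  lapply(seq_len(n_curves), function(i) {
    f <- clean + stats::rnorm(n_cycles, 0, noise_sd)
    structure(list(reaction_id = sprintf("%s.r%03d", amplicon, i),
                   amplicon = amplicon,
                   fluorescence = pmax(f, 0)),
              class = "amplification_curve")
  })
}
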