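# four-gene panel with a mock/infected time course; gene G04 is the target
quant_config <- function(target_shift = -3, worst_shift = 0, noise = 0.02,
                         seed = 1) {
  design <- rbind(
    data.frame(panel = "P", condition = paste0("t", 1:2, ".mock"),
               group = "mock", is_mock = TRUE),
    data.frame(panel = "P", condition = paste0("t", 1:2, ".inf"),
               group = "infected", is_mock = FALSE))
  ge <- matrix(c(worst_shift, target_shift), 2, 1,
               dimnames = list(c("G03", "G04"), "infected"))
  sim_config(n_genes = 4, design = design, baseline = c(20, 24, 22, 26),
             slope = rep(0, 4), sigma_bio = rep(noise, 4),
             sigma_tech = rep(noise, 4), group_effect = ge, seed = seed)
}

test_that("normalisation factor is the geometric mean of the references", {
  rq <- rbind(r1 = c(4, 1), r2 = c(1, 1), r3 = c(2, 8))
  nf <- normalization_factor(rq, c("r1", "r2"))
  expect_equal(unname(nf$nf), c(2, 1))
  expect_equal(unname(normalization_factor(rq, "r3")$nf), c(2, 8))
  expect_equal(unname(normalization_factor(rq, c("r1", "r2", "r3"))$nf[1]),
               exp(mean(log(c(4, 1, 2)))))
  expect_error(normalization_factor(rq, character(0)), "non-empty")
  expect_error(normalization_factor(rq, "nope"), "absent")
})

test_that("mock conditions self-calibrate to fold change 1", {
  sim <- simulate_study(quant_config())
  prof <- normalized_expression(sim$cq, "G04", c("G01", "G02"))
  mocks <- prof[prof$group == "mock", ]
  expect_equal(mocks$fold_change, rep(1, nrow(mocks)))
})

test_that("a target behaving like the references gives a flat profile of 1", {
  sim <- simulate_study(quant_config(target_shift = 0, noise = 0))
  prof <- normalized_expression(sim$cq, "G04", c("G01", "G02"))
  expect_equal(prof$fold_change, rep(1, nrow(prof)), tolerance = 1e-10)
})

test_that("an 8-fold induction (dCq = -3 at E = 2) is recovered", {
  # noiseless: exact; noisy: within 10 % across seeds
  sim0 <- simulate_study(quant_config(noise = 0))
  prof0 <- normalized_expression(sim0$cq, "G04", c("G01", "G02"))
  expect_equal(prof0$fold_change[prof0$group == "infected"], c(8, 8),
               tolerance = 1e-10)
  for (s in 1:10) {
    sim <- simulate_study(quant_config(seed = s))
    prof <- normalized_expression(sim$cq, "G04", c("G01", "G02"))
    folds <- prof$fold_change[prof$group == "infected"]
    expect_true(all(abs(folds / 8 - 1) < 0.1))
  }
})

test_that("fold changes are invariant to per-gene additive Cq offsets", {
  sim <- simulate_study(quant_config())
  prof <- normalized_expression(sim$cq, "G04", c("G01", "G02"))
  shifted <- sim$cq$cq
  shifted["G01", ] <- shifted["G01", ] + 4
  shifted["G04", ] <- shifted["G04", ] - 2
  cq2 <- cq_matrix(shifted, sim$cq$annotations)
  prof2 <- normalized_expression(cq2, "G04", c("G01", "G02"))
  expect_equal(prof2$fold_change, prof$fold_change, tolerance = 1e-10)
})

test_that("with perfectly stable references normalisation equals plain
           efficiency-corrected fold changes", {
  sim <- simulate_study(quant_config(noise = 0))
  prof <- normalized_expression(sim$cq, "G04", c("G01", "G02"))
  # references are exactly constant, so NF is constant and cancels:
  # fold = E^(Cq_mock - Cq_cond) relative to the matched mock
  ann <- sim$cq$annotations
  for (i in which(prof$group == "infected")) {
    cond <- prof$condition[i]; cal <- prof$calibrator[i]
    dcq <- mean(sim$cq$cq["G04", ann$condition == cal]) -
      mean(sim$cq$cq["G04", ann$condition == cond])
    expect_equal(prof$fold_change[i], 2^dcq, tolerance = 1e-10)
  }
})

test_that("bias contrast isolates a distorted reference", {
  # worst reference indistinguishable from the good ones -> zero bias
  sim <- simulate_study(quant_config(noise = 0))
  b0 <- bias_contrast(sim$cq, "G04", c("G01", "G02"), "G03")
  expect_equal(b0$bias$bias, rep(0, nrow(b0$bias)), tolerance = 1e-10)

  # +1 cycle treatment effect on the worst reference -> +1 log2 bias
  sim1 <- simulate_study(quant_config(worst_shift = 1, noise = 0))
  b1 <- bias_contrast(sim1$cq, "G04", c("G01", "G02"), "G03")
  inf <- b1$bias$bias[grepl("inf", b1$bias$condition)]
  expect_equal(inf, rep(1, length(inf)), tolerance = 1e-10)

  # opposite distortion flips the sign
  sim2 <- simulate_study(quant_config(worst_shift = -1, noise = 0))
  b2 <- bias_contrast(sim2$cq, "G04", c("G01", "G02"), "G03")
  inf2 <- b2$bias$bias[grepl("inf", b2$bias$condition)]
  expect_equal(inf2, rep(-1, length(inf2)), tolerance = 1e-10)
})

test_that("missing calibrators and invalid targets are rejected", {
  sim <- simulate_study(quant_config())
  expect_error(normalized_expression(sim$cq, "nope", "G01"), "absent")
  expect_error(normalized_expression(sim$cq, "G04", "G04"), "own reference")
  # a panel without any mock condition has no default calibrator
  design <- data.frame(panel = "Q", condition = c("a", "b"),
                       group = "none", is_mock = FALSE)
  cfg <- sim_config(n_genes = 3, design = design, baseline = c(20, 22, 24),
                    slope = rep(0, 3), sigma_bio = rep(0.05, 3),
                    sigma_tech = rep(0.05, 3), seed = 2)
  sim2 <- simulate_study(cfg)
  expect_error(normalized_expression(sim2$cq, "G03", "G01"), "calibrator")
  # but an explicit calibrator condition works
  prof <- normalized_expression(sim2$cq, "G03", "G01", calibrator = "a")
  expect_equal(prof$fold_change[prof$condition == "a"], 1)
})
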