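test_that("stability index equals CV x |slope| with closed-form OLS slope", {
  set.seed(31)
  m <- matrix(runif(12, 15, 30), 3, 4,
              dimnames = list(c("gA", "gB", "gC"), NULL))
  res <- stability_index(make_cq(m))
  overall <- colMeans(m)
  for (g in rownames(m)) {
    row <- res$table[res$table$gene == g, ]
    expect_equal(row$mean, mean(m[g, ]))
    expect_equal(row$sd, sd(m[g, ]))
    expect_equal(row$cv, 100 * sd(m[g, ]) / mean(m[g, ]))
    slope <- cov(overall, m[g, ]) / var(overall)   # closed form
    expect_equal(row$slope, slope, tolerance = 1e-12)
    expect_equal(row$intercept, mean(m[g, ]) - slope * mean(overall),
                 tolerance = 1e-12)
    expect_equal(row$si, row$cv * abs(slope))
  }
})

test_that("a constant gene in a varying panel ranks first with SI = 0", {
  set.seed(8)
  m <- rbind(gA = rep(21, 10), gB = runif(10, 18, 25), gC = runif(10, 10, 30))
  colnames(m) <- NULL
  res <- stability_index(make_cq(m))
  row <- res$table[res$table$gene == "gA", ]
  expect_equal(row$sd, 0)
  expect_equal(row$si, 0)
  expect_equal(res$ranking[1], "gA")
})

test_that("geNorm M values match the hand-computed 3-gene toy", {
  rq <- rbind(g1 = c(1, .5, .25, .125),
              g2 = c(1, .5, .25, .125),
              g3 = c(1, 1, 1, 1))
  M <- genorm_m_values(rq)
  expect_equal(unname(M["g3"]), sd(c(0, 1, 2, 3)))        # 1.2910
  expect_equal(unname(M["g1"]), sd(c(0, 1, 2, 3)) / 2)    # 0.6455
  expect_equal(unname(M["g2"]), sd(c(0, 1, 2, 3)) / 2)
  expect_equal(unname(M["g3"]), 1.290994, tolerance = 1e-6)

  # ratio invariance: rescaling one gene leaves every M unchanged
  rq2 <- rq; rq2["g2", ] <- rq2["g2", ] * 17
  expect_equal(genorm_m_values(rq2), M, tolerance = 1e-12)

  # proportional genes have V = 0
  rq3 <- rbind(a = c(1, .5, .25), b = 2 * c(1, .5, .25))
  expect_equal(unname(genorm_m_values(rq3)), c(0, 0))
  expect_error(genorm_m_values(rbind(a = c(1, 0), b = c(1, 1))), "positive")
})

test_that("geNorm iterative exclusion ranks the toy panel correctly", {
  rq <- rbind(g1 = c(1, .5, .25, .125),
              g2 = c(1, .5, .25, .125),
              g3 = c(1, 1, 1, 1))
  res <- genorm_ranking(rq)
  expect_equal(res$ranking, c("g1", "g2", "g3"))   # g3 excluded first
  tab <- res$table
  expect_equal(tab$M_A[tab$gene == "g3"], 1.290994, tolerance = 1e-6)
  expect_true(all(tab$M_A[tab$gene %in% c("g1", "g2")] == 0))
  expect_true(all(tab$acceptable[tab$gene != "g3"]))

  # degenerate panel: identical up to scale -> all M = 0, label order, warning
  rq4 <- rbind(gC = c(1, .5, .25), gA = 2 * c(1, .5, .25),
               gB = 5 * c(1, .5, .25))
  expect_warning(res4 <- genorm_ranking(rq4), "tie")
  expect_equal(res4$ranking, c("gA", "gB", "gC"))
  expect_lt(max(res4$table$M), 1e-12)
})

test_that("normalised-CV matches hand computation and degenerate cases", {
  # gene proportional to the normalisation factor -> cv_norm = 0
  rq <- rbind(ref1 = c(1, 2, 4), ref2 = c(1, 2, 4), tgt = 3 * c(1, 2, 4))
  cvn <- genorm_cv(rq, c("ref1", "ref2"))
  expect_equal(unname(cvn["tgt"]), 0, tolerance = 1e-12)

  # self-normalisation
  expect_equal(unname(genorm_cv(rq, "tgt")["tgt"]), 0, tolerance = 1e-12)

  # z = (1, 1, 2) toy
  rq2 <- rbind(ref = c(1, 1, 1), g = c(1, 1, 2))
  expect_equal(unname(genorm_cv(rq2, "ref")["g"]),
               sd(c(1, 1, 2)) / mean(c(1, 1, 2)))
  expect_equal(unname(genorm_cv(rq2, "ref")["g"]), 0.433013,
               tolerance = 1e-6)
  expect_error(genorm_cv(rq2, character(0)), "non-empty")
})

test_that("pairwise variation detects shared profiles and honours hand math", {
  prof <- c(1, .5, .25, .125, 2)
  rq <- rbind(a = prof, b = 2 * prof, c = .5 * prof, d = 7 * prof)
  pv <- pairwise_variation(rq, c("a", "b", "c", "d"))
  expect_equal(unname(pv$v), rep(0, 2))
  expect_equal(pv$minimal_n, 2L)

  set.seed(12)
  rq2 <- matrix(exp(rnorm(16)), 4, 4,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  # noisy panel: V typically stays above the cutoff, which warns
  pv2 <- suppressWarnings(pairwise_variation(rq2, c("a", "b", "c", "d")))
  nf2 <- apply(rq2[c("a", "b"), ], 2, function(v) exp(mean(log(v))))
  nf3 <- apply(rq2[c("a", "b", "c"), ], 2, function(v) exp(mean(log(v))))
  expect_equal(unname(pv2$v["V2/3"]), sd(log2(nf2 / nf3)), tolerance = 1e-12)

  expect_error(pairwise_variation(rq2, c("a", "b")), "at least 3")
})

test_that("NormFinder ranks a shared-profile gene as most stable", {
  set.seed(44)
  x <- runif(30, 18, 22)
  rq <- rbind(g1 = 2^-x, g2 = 2^-x, g3 = 2^-(x + rnorm(30, 0, 0.5)))
  res <- normfinder_stability(rq)
  tab <- res$table
  expect_equal(min(tab$rho), tab$rho[tab$gene == "g1"])
  expect_gt(tab$rho[tab$gene == "g3"], tab$rho[tab$gene == "g1"])
})

test_that("NormFinder recovers a noise-SD gradient across seeds", {
  # 8 genes with sigma ramping 0.05..0.75; at 50 reactions the sampling
  # error of an SD is ~10 %, so adjacent genes can swap — require strong
  # rank agreement rather than a perfect order
  sigmas <- seq(0.05, 0.75, by = 0.1)
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    m <- t(vapply(sigmas, function(sg) 20 + rnorm(50, 0, sg), numeric(50)))
    rownames(m) <- sprintf("g%d", 1:8)
    rho <- normfinder_stability(2^-m)$table$rho
    if (cor(rho, sigmas, method = "spearman") >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("a group shift strictly increases NormFinder grouped-mode rho", {
  groups <- rep(c("mock", "inf"), each = 10)
  base <- function(delta) {
    set.seed(77)
    m <- rbind(g1 = 20 + rnorm(20, 0, 0.2),
               g2 = 24 + rnorm(20, 0, 0.2),
               g3 = 18 + rnorm(20, 0, 0.2) + delta * (groups == "inf"))
    normfinder_stability(2^-m, groups = groups)$table
  }
  t0 <- base(0); t1 <- base(1)
  expect_gt(t1$rho[t1$gene == "g3"], t0$rho[t0$gene == "g3"])
  expect_error(normfinder_stability(2^-matrix(runif(9, 1, 2), 3, 3,
                                              dimnames = list(letters[1:3],
                                                              NULL)),
                                    groups = c("a", "a", "b")),
               "at least 2 reactions")
})

test_that("BestKeeper matches hand-computed dispersion about the geomean", {
  m <- rbind(gA = c(19, 20, 21), gB = c(25, 26, 24), gC = c(22, 22, 22))
  res <- bestkeeper(make_cq(m))
  tab <- res$table
  gm <- exp(mean(log(c(19, 20, 21))))
  expect_equal(tab$geomean[tab$gene == "gA"], gm)
  expect_equal(tab$sd_cp[tab$gene == "gA"], mean(abs(c(19, 20, 21) - gm)))
  expect_equal(tab$sd_cp[tab$gene == "gA"], 0.6722269, tolerance = 1e-6)
  # constant gene: zero dispersion, first rank, undefined index correlation
  expect_equal(tab$sd_cp[tab$gene == "gC"], 0)
  expect_equal(res$ranking[1], "gC")
  expect_true(is.na(tab$r_index[tab$gene == "gC"]))

  m2 <- rbind(gA = c(19, 21, 20), gB = c(19, 21, 20))
  res2 <- bestkeeper(make_cq(m2))
  expect_equal(res2$table$r_index, c(1, 1))
})

test_that("delta-Ct scores equal averaged hand-computed pairwise SDs", {
  m <- rbind(gA = c(19, 20, 21, 22), gB = c(21, 22, 23, 24),
             gC = c(20, 22, 21, 25))
  res <- delta_ct_stability(make_cq(m))
  tab <- res$table
  s_ab <- sd(m["gA", ] - m["gB", ]); s_ac <- sd(m["gA", ] - m["gC", ])
  s_bc <- sd(m["gB", ] - m["gC", ])
  expect_equal(tab$mean_sd[tab$gene == "gA"], mean(c(s_ab, s_ac)))
  expect_equal(tab$mean_sd[tab$gene == "gB"], mean(c(s_ab, s_bc)))
  expect_equal(tab$mean_sd[tab$gene == "gC"], mean(c(s_ac, s_bc)))
  expect_equal(s_ab, 0)  # parallel genes
})

test_that("geNorm M on RQ at E = 2 equals the delta-Ct score exactly", {
  for (s in 1:5) {
    x <- random_cq(6, 15, seed = 100 + s)
    M <- genorm_m_values(cq_to_rq(x))
    dct <- delta_ct_stability(x)$table
    expect_equal(unname(M[dct$gene]), dct$mean_sd, tolerance = 1e-12)
  }
})

test_that("ratio-based scores are invariant to per-gene Cq offsets, SI is not", {
  x <- random_cq(5, 20, seed = 55)
  shifted <- x$cq; shifted["g3", ] <- shifted["g3", ] + 2.5
  y <- make_cq(shifted)

  expect_equal(genorm_m_values(cq_to_rq(y)), genorm_m_values(cq_to_rq(x)),
               tolerance = 1e-12)
  expect_equal(delta_ct_stability(y)$table$mean_sd,
               delta_ct_stability(x)$table$mean_sd, tolerance = 1e-12)
  expect_equal(normfinder_stability(cq_to_rq(y))$table$rho,
               normfinder_stability(cq_to_rq(x))$table$rho,
               tolerance = 1e-12)
  expect_equal(bestkeeper(y)$table$sd_cp, bestkeeper(x)$table$sd_cp,
               tolerance = 1e-12)
  # SI's CV depends on the mean Cq level: documented asymmetry
  si_x <- stability_index(x)$table; si_y <- stability_index(y)$table
  expect_false(isTRUE(all.equal(si_x$cv[si_x$gene == "g3"],
                                si_y$cv[si_y$gene == "g3"])))
})

test_that("every method places the designed true reference in its top 3", {
  ok <- 0L
  for (s in 1:25) {
    sim <- simulate_study(sim_config(seed = 400 + s))
    suite <- stability_suite(sim$cq, scope = "all")
    best <- sim$truth$true_stability_order[1]
    if (all(vapply(suite, function(r) best %in% r$ranking[1:3], logical(1))))
      ok <- ok + 1L
  }
  expect_gte(ok, 24L)
})
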