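rand_inc <- function(n = 8, s = 10, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rbinom(n * s, 1, p), n, s,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("sp", seq_len(s))))
  community_matrix(x, "incidence")
}

test_that("c0 preserves column sums while freeing richness", {
  set.seed(1)
  m <- rand_inc(10, 12)
  ones <- community_matrix(matrix(1, 3, 3,
                                  dimnames = list(paste0("s", 1:3),
                                                  paste0("p", 1:3))),
                           "incidence")
  expect_equal(unclass(randomize_c0(ones)), unclass(ones), ignore_attr = TRUE)
  for (rep in 1:50) {
    r <- randomize_c0(m)
    expect_equal(colSums(r), colSums(m))
    expect_true(all(unclass(r) %in% c(0, 1)))
  }
  expect_error(randomize_c0(toy_bundle()$biomass), "incidence")
})

test_that("c0 places single presences uniformly across samples", {
  m <- community_matrix(matrix(c(1, 0, 0), 3, 1,
                               dimnames = list(c("a", "b", "c"), "sp")),
                        "incidence")
  set.seed(99)
  hits <- table(factor(replicate(3000, which(unclass(randomize_c0(m)) == 1)),
                       levels = 1:3))
  # exact enumeration: each row with probability 1/3
  expect_gt(chisq.test(hits, p = rep(1 / 3, 3))$p.value, 0.01)
})

test_that("c0_samp permutes column value multisets exactly", {
  set.seed(7)
  x <- matrix(rexp(40) * rbinom(40, 1, 0.6), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("sp", 1:5)))
  m <- community_matrix(x, "biomass")
  for (rep in 1:50) {
    r <- randomize_c0_samp(m)
    expect_equal(colSums(r), colSums(m))
    expect_equal(colSums(unclass(r) > 0), colSums(x > 0))
    for (j in 1:5) expect_equal(sort(unname(unclass(r)[, j])),
                                sort(unname(x[, j])))
  }
  expect_error(randomize_c0_samp(rand_inc()), "biomass")
})

test_that("c0_samp reaches all joint column orders uniformly on a 2x2 case", {
  m <- community_matrix(matrix(c(1, 3, 2, 4), 2, 2,
                               dimnames = list(c("r1", "r2"), c("A", "B"))),
                        "biomass")
  set.seed(5)
  draws <- replicate(4000, paste(as.numeric(unclass(randomize_c0_samp(m))),
                                 collapse = ","))
  tab <- table(draws)
  expect_equal(length(tab), 4)  # 2 orders per column, independent
  expect_gt(chisq.test(tab, p = rep(0.25, 4))$p.value, 0.01)
})

test_that("null ensembles are reproducible and bounded", {
  b <- toy_bundle()
  e1 <- build_null_ensemble(b$incidence, b$traits, n_iter = 120, seed = 3,
                            metrics = c("S", "RaoQ", "FDis"))
  e2 <- build_null_ensemble(b$incidence, b$traits, n_iter = 120, seed = 3,
                            metrics = c("S", "RaoQ", "FDis"))
  expect_identical(e1, e2)
  expect_true(all(e1$n_iter <= 120))
  expect_true(all(e1$null_sd >= 0, na.rm = TRUE))
  expect_error(build_null_ensemble(b$incidence, b$traits, n_iter = 100,
                                   strict = TRUE),
               "seed")
})

test_that("null richness matches the analytic c0 expectation", {
  set.seed(21)
  m <- rand_inc(12, 20, 0.4)
  # under independent uniform column placement, E[S_k] = sum_j c_j / n
  expected <- sum(colSums(m)) / nrow(m)
  tr <- rand_traits(20)
  rownames(tr) <- colnames(m)
  e <- build_null_ensemble(m, tr, n_iter = 400, seed = 8,
                           metrics = "S")
  se <- e$null_sd / sqrt(e$n_iter)
  expect_true(all(abs(e$null_mean - expected) <= 3 * pmax(se, 1e-9)))
})

test_that("standardized effect sizes follow (obs - mean)/sd", {
  obs <- data.frame(sample_id = "s1", basis = "incidence", metric = "FDis",
                    observed = 2, stringsAsFactors = FALSE)
  ens <- data.frame(sample_id = "s1", basis = "incidence", metric = "FDis",
                    n_iter = 500L, null_mean = 0, null_sd = 1, usable = TRUE,
                    stringsAsFactors = FALSE)
  expect_equal(standardized_effect_size(obs, ens)$ses, 2)
  ens$null_mean <- 2
  expect_equal(standardized_effect_size(obs, ens)$ses, 0)
  ens$null_sd <- 0; ens$usable <- FALSE
  expect_true(is.na(standardized_effect_size(obs, ens)$ses))
})

test_that("test_ses_zero branches and directions behave as specified", {
  set.seed(1)
  null_sample <- rnorm(20)
  r0 <- test_ses_zero(null_sample)
  expect_gt(r0$p_value, 0.05)
  expect_equal(r0$direction, "none")
  shifted <- rnorm(20, mean = 3)
  r1 <- test_ses_zero(shifted)
  expect_lt(r1$p_value, 0.05)
  expect_equal(r1$direction, "positive")
  expect_warning(r2 <- test_ses_zero(rep(-1, 5)), "identical")
  expect_equal(r2$test_used, "wilcoxon")
  expect_equal(r2$direction, "negative")
  expect_error(test_ses_zero(c(1, 2)), "at least 3")
})

test_that("t and wilcoxon agree in direction on strongly shifted samples", {
  set.seed(3)
  agree <- 0
  for (rep in 1:200) {
    x <- rnorm(20, mean = 2)
    tt <- t.test(x)$p.value < 0.05 && median(x) > 0
    ww <- suppressWarnings(wilcox.test(x[x != 0])$p.value) < 0.05 &&
      median(x) > 0
    agree <- agree + (tt == ww)
  }
  expect_gte(agree / 200, 0.99)
})

test_that("assembly verdicts map sign and family as specified", {
  mk <- function(p, dir) list(test_used = "t", p_value = p, direction = dir,
                              n = 10)
  expect_equal(classify_assembly("fd", mk(0.01, "negative"))$label,
               "habitat_filtering")
  expect_equal(classify_assembly("fd", mk(0.01, "positive"))$label,
               "limiting_similarity")
  expect_equal(classify_assembly("fd", mk(0.4, "none"))$label, "random")
  expect_equal(classify_assembly("cwm", mk(0.003, "positive"))$label,
               "trait_divergence")
  expect_equal(classify_assembly("cwm", mk(0.003, "negative"))$label,
               "trait_convergence")
  expect_error(classify_assembly("other", mk(0.5, "none")))
})

test_that("ses_trend recovers monotone trends and errors on bad input", {
  tp <- c(50, 80, 120, 300, 500)
  expect_equal(ses_trend(1:5, tp)$rho, 1)
  expect_equal(ses_trend(5:1, tp)$rho, -1)
  expect_error(ses_trend(1:3, tp[1:3]), "at least 5")
  expect_error(ses_trend(rep(1, 5), tp), "constant")
  # permutation null: rho small on average
  set.seed(9)
  rhos <- replicate(200, ses_trend(sample(1:20), runif(20, 40, 600))$rho)
  expect_lt(abs(mean(rhos)), 0.1)
})
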