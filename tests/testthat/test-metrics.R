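space_from_coords <- function(X) {
  # wrap raw coordinates as a trait_space for the public metric functions
  rownames(X) <- sprintf("sp%02d", seq_len(nrow(X)))
  structure(list(species_ids = rownames(X), coordinates = X,
                 eigenvalues = rep(1, ncol(X)), m = ncol(X),
                 correction = "none", quality = 1), class = "trait_space")
}

test_that("simpson diversity follows 1 - sum(p^2)", {
  expect_equal(simpson_diversity(1), 0)
  expect_equal(simpson_diversity(c(0.5, 0.5)), 0.5)
  expect_equal(simpson_diversity(c(0.5, 0.3, 0.2)), 0.62)
  expect_error(simpson_diversity(numeric(0)), "empty")
  expect_error(simpson_diversity(c(0.5, 0.2)), "sum to 1")
})

test_that("RaoQ matches the double-loop oracle and its edge cases", {
  expect_equal(rao_quadratic_entropy(matrix(0, 1, 1), 1), 0)
  d2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(rao_quadratic_entropy(d2, c(0.5, 0.5)), 0.5)
  set.seed(77)
  for (rep in 1:20) {
    s <- sample(3:6, 1)
    d <- matrix(runif(s * s), s, s); d <- (d + t(d)) / 2; diag(d) <- 0
    p <- rand_weights(s)
    expect_equal(rao_quadratic_entropy(d, p), oracle_rao(d, p),
                 tolerance = 1e-12)
    expect_equal(rao_quadratic_entropy(d, p, "squared_halved"),
                 oracle_rao(d^2 / 2, p), tolerance = 1e-12)
  }
  expect_error(rao_quadratic_entropy(d2, c(1, 0, 0)), "disagree")
})

test_that("functional redundancy is 1 - Q/D with guarded edge cases", {
  expect_equal(functional_redundancy(0, 0.5), 1)
  expect_equal(functional_redundancy(0.5, 0.5), 0)
  expect_equal(functional_redundancy(0.25, 0.5), 0.5)
  expect_true(is.na(functional_redundancy(0, 0)))
  expect_error(functional_redundancy(0.6, 0.5), "corruption")
})

test_that("FRic equals hull volumes on constructed cases", {
  sp <- space_from_coords(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(functional_richness(sp, sp$species_ids), 0.5)
  sp2 <- space_from_coords(rbind(c(0, 0), c(1, 0), c(0, 1), c(0.25, 0.25)))
  expect_equal(functional_richness(sp2, sp2$species_ids), 0.5)
  # collinear points: degenerate hull -> NA
  sp3 <- space_from_coords(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_true(is.na(functional_richness(sp3, sp3$species_ids)))
  # duplicated coordinates collapse onto one point
  sp4 <- space_from_coords(rbind(c(0, 0), c(1, 0), c(0, 1), c(0, 1)))
  expect_equal(functional_richness(sp4, sp4$species_ids), 0.5)
})

test_that("FEve is 1 for perfectly even configurations and NA for s < 3", {
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  sp <- space_from_coords(eq)
  expect_equal(functional_evenness(sp, sp$species_ids, rep(1 / 3, 3)), 1)
  sp2 <- space_from_coords(rbind(c(0, 0), c(1, 0)))
  expect_true(is.na(functional_evenness(sp2, sp2$species_ids, c(0.5, 0.5))))
})

test_that("FDiv is 1 for equidistant configurations", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  sp <- space_from_coords(sq)
  expect_equal(functional_divergence(sp, sp$species_ids, rep(0.25, 4)), 1)
})

test_that("FDis matches hand cases", {
  sp <- space_from_coords(rbind(c(0, 0), c(1, 0)))
  expect_equal(functional_dispersion(sp, sp$species_ids, c(0.5, 0.5)), 0.5)
  sp1 <- space_from_coords(matrix(c(2, 3), 1, 2))
  expect_equal(functional_dispersion(sp1, sp1$species_ids, 1), 0)
})

test_that("all indices agree with brute-force oracles on random communities", {
  set.seed(123)
  for (rep in 1:40) {
    m <- sample(2:3, 1)
    s <- sample((m + 2):7, 1)
    X <- matrix(runif(s * m), s, m)
    p <- rand_weights(s)
    sp <- space_from_coords(X)
    ids <- sp$species_ids
    expect_equal(functional_richness(sp, ids), oracle_fric(X),
                 tolerance = 1e-10)
    expect_equal(functional_evenness(sp, ids, p), oracle_feve(X, p),
                 tolerance = 1e-10)
    expect_equal(functional_divergence(sp, ids, p), oracle_fdiv(X, p),
                 tolerance = 1e-10)
    expect_equal(functional_dispersion(sp, ids, p), oracle_fdis(X, p),
                 tolerance = 1e-10)
  }
})

test_that("FRic never decreases when species are added at fixed axes", {
  set.seed(31)
  X <- matrix(runif(20), 10, 2)
  sp <- space_from_coords(X)
  v1 <- functional_richness(sp, sp$species_ids[1:6])
  v2 <- functional_richness(sp, sp$species_ids[1:9])
  v3 <- functional_richness(sp, sp$species_ids)
  expect_true(v1 <= v2 + 1e-12 && v2 <= v3 + 1e-12)
})

test_that("FEve and FDiv stay in [0,1] over random communities", {
  set.seed(55)
  for (rep in 1:30) {
    s <- sample(4:9, 1)
    X <- matrix(runif(2 * s), s, 2)
    p <- rand_weights(s)
    sp <- space_from_coords(X)
    fe <- functional_evenness(sp, sp$species_ids, p)
    fd <- functional_divergence(sp, sp$species_ids, p)
    expect_true(fe >= -1e-12 && fe <= 1 + 1e-12)
    expect_true(fd >= -1e-12 && fd <= 1 + 1e-12)
  }
})

test_that("CWMs are relative-abundance fractions that sum to one per trait", {
  b <- toy_bundle()
  cw <- community_weighted_means(b$biomass, b$traits)
  # habitats: a,b,c pelagic; d littoral. sample s1 biomass = (2, 0, 2, 2)
  pel <- cw$cwm[cw$sample_id == "s1" & cw$category == "pelagic"]
  expect_equal(pel, 4 / 6)
  sums <- tapply(cw$cwm, list(cw$sample_id, cw$trait), sum)
  expect_equal(unname(as.numeric(sums)), rep(1, length(sums)),
               tolerance = 1e-12)
  # all-pelagic community
  tr <- b$traits; tr$habitat <- "pelagic"
  cw2 <- community_weighted_means(b$biomass, tr)
  expect_true(all(cw2$cwm[cw2$category == "pelagic"] == 1))
  expect_true(all(cw2$cwm[cw2$category == "littoral"] == 0))
})

test_that("fd_profile produces one row per sample per basis with NA cascades", {
  b <- toy_bundle()
  prof <- fd_profile(incidence = b$incidence, biomass = b$biomass,
                     traits = b$traits)
  expect_equal(nrow(prof$fd), 6)
  expect_setequal(unique(prof$fd$basis), c("incidence", "biomass"))
  expect_equal(prof$fd$FD, (prof$fd$FDis + prof$fd$RaoQ) / 2)
  # monoculture: everything geometric is NA/zero
  x1 <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("m1", "m2"), c("a", "b", "c")))
  p1 <- fd_profile(incidence = community_matrix(x1, "incidence"),
                   traits = b$traits)
  row1 <- p1$fd[p1$fd$sample_id == "m1", ]
  expect_equal(row1$S, 1)
  expect_equal(row1$FDis, 0)
  expect_equal(row1$RaoQ, 0)
  expect_true(is.na(row1$FRic) && is.na(row1$FEve) && is.na(row1$FDiv) &&
                is.na(row1$FRed))
  rs <- attr(p1$fd, "reasons")
  expect_true("monoculture" %in% rs$reason_code)
})

test_that("metrics are invariant to species order and biomass scaling", {
  b <- toy_bundle()
  prof <- fd_profile(biomass = b$biomass, traits = b$traits)
  perm <- c("c", "a", "d", "b")
  bio2 <- community_matrix(unclass(b$biomass)[, perm] * 1000, "biomass")
  prof2 <- fd_profile(biomass = bio2, traits = b$traits[perm, ])
  for (mm in c("S", "D", "FRic", "FEve", "FDiv", "FDis", "RaoQ", "FRed"))
    expect_equal(prof$fd[[mm]], prof2$fd[[mm]], tolerance = 1e-10,
                 label = mm)
})

test_that("simpson agrees with the vegan oracle on the FD weight vectors", {
  b <- toy_bundle()
  h <- unclass(hellinger_transform(b$biomass))
  P <- h / rowSums(h)  # the weight vector the FD indices and D share
  prof <- fd_profile(biomass = b$biomass, traits = b$traits)
  expect_equal(prof$fd$D, unname(vegan::diversity(P, index = "simpson")),
               tolerance = 1e-12)
})
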