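test_that("default codebook has the 17-category vocabulary", {
  cb <- default_codebook()
  expect_equal(nrow(cb), 17)
  counts <- table(cb$trait_name)
  expect_equal(unname(counts[c("size_class", "feeding_type", "trophic_group",
                               "habitat")]), c(3, 8, 4, 2),
               ignore_attr = TRUE)
  expect_equal(cb$trait_kind[cb$trait_name == "size_class"],
               rep("ordinal", 3))
})

test_that("community_matrix validates values and ids", {
  x <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_s3_class(community_matrix(x, "incidence"), "community_matrix")
  expect_error(community_matrix(x * 2, "incidence"), "0 and 1")
  expect_error(community_matrix(x - 2, "biomass"), "negative")
  xd <- x; rownames(xd) <- c("s1", "s1")
  expect_error(community_matrix(xd, "incidence"), "duplicate sample")
})

test_that("hellinger transform matches the closed form and preserves zeros", {
  m <- community_matrix(
    matrix(c(4, 0, 1, 1, 2, 0), 2, 3, byrow = TRUE,
           dimnames = list(c("s1", "s2"), c("a", "b", "c"))),
    basis = "biomass")
  # rows are (4,0,?) style cases: first row (4,0,1)? keep spec rows exact:
  m1 <- community_matrix(matrix(c(4, 0), 1, 2,
                                dimnames = list("s", c("a", "b"))), "biomass")
  expect_equal(as.numeric(hellinger_transform(m1)), c(1, 0))
  m2 <- community_matrix(matrix(c(1, 1, 2), 1, 3,
                                dimnames = list("s", c("a", "b", "c"))),
                         "biomass")
  expect_equal(as.numeric(hellinger_transform(m2)),
               c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-12)
  m3 <- community_matrix(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
                                dimnames = list(c("s1", "s2"), c("a", "b"))),
                         "biomass")
  expect_error(hellinger_transform(m3), "zero total")
})

test_that("hellinger rows have unit sum of squares for random matrices", {
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(rexp(30) * rbinom(30, 1, 0.7), 5, 6)
    x[rowSums(x) == 0, 1] <- 1
    dimnames(x) <- list(paste0("s", 1:5), paste0("sp", 1:6))
    h <- hellinger_transform(community_matrix(x, "biomass"))
    expect_equal(rowSums(unclass(h)^2), rep(1, 5), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(unclass(h) == 0, x == 0)
  }
})

test_that("relative abundance normalizes biomass and equalizes incidence", {
  b <- community_matrix(matrix(c(10, 30, 60), 1, 3,
                               dimnames = list("s", c("a", "b", "c"))),
                        "biomass")
  expect_equal(unname(relative_abundance(b, "s")), c(0.1, 0.3, 0.6))
  i <- community_matrix(matrix(c(1, 0, 1), 1, 3,
                               dimnames = list("s", c("a", "b", "c"))),
                        "incidence")
  expect_equal(unname(relative_abundance(i, "s")), c(0.5, 0, 0.5))
  z <- community_matrix(matrix(c(0, 0, 0, 1, 1, 0), 2, 3, byrow = TRUE,
                               dimnames = list(c("s0", "s1"),
                                               c("a", "b", "c"))),
                        "biomass")
  expect_error(relative_abundance(z, "s0"), "empty")
})

test_that("trophic states follow the half-open TP intervals", {
  expect_equal(as.character(classify_trophic_state(80)), "eutrophic")
  expect_equal(as.character(classify_trophic_state(150)), "hypereutrophic")
  expect_equal(as.character(classify_trophic_state(300)),
               "highly_hypereutrophic")
  expect_equal(as.character(classify_trophic_state(100)), "hypereutrophic")
  expect_warning(st <- classify_trophic_state(20), "below")
  expect_equal(as.character(st), "eutrophic")
  expect_error(classify_trophic_state(0), "positive")
  # monotone in TP
  tp <- sort(c(runif(50, 41, 1000)))
  expect_true(!is.unsorted(classify_trophic_state(tp)))
})

test_that("load_tables round-trips and cross-validates the bundle", {
  b <- toy_bundle()
  dir <- write_toy_csvs(b)
  got <- load_tables(file.path(dir, "community.csv"),
                     file.path(dir, "traits.csv"),
                     file.path(dir, "environment.csv"), mode = "incidence")
  expect_equal(dim(got$community), c(3, 4))
  expect_equal(unclass(got$community), unclass(b$incidence),
               ignore_attr = TRUE)
  expect_equal(got$traits, b$traits)
  expect_equal(got$env$TP, b$env$TP)
  expect_equal(as.character(got$env$trophic_state),
               c("eutrophic", "hypereutrophic", "highly_hypereutrophic"))
  # write -> load round-trips bit-identically
  dir2 <- tempfile("rt")
  write_tables(list(community = got$community, traits = got$traits,
                    env = got$env), dir2)
  expect_identical(readLines(file.path(dir, "community.csv")),
                   readLines(file.path(dir2, "community.csv")))
  expect_identical(readLines(file.path(dir, "traits.csv")),
                   readLines(file.path(dir2, "traits.csv")))
})

test_that("loader errors name the offending species and traits", {
  b <- toy_bundle()
  dir <- write_toy_csvs(b)
  # codebook violation
  tr <- b$traits
  tr["b", "trophic_group"] <- "piscivorous"
  pondFD:::write_id_csv(tr, file.path(dir, "traits_bad.csv"), "species_id")
  expect_error(
    load_tables(file.path(dir, "community.csv"),
                file.path(dir, "traits_bad.csv"),
                file.path(dir, "environment.csv"), mode = "incidence"),
    "piscivorous.*|trophic_group")
  # referential integrity
  tr2 <- b$traits[c("a", "b", "c"), ]
  pondFD:::write_id_csv(tr2, file.path(dir, "traits_miss.csv"), "species_id")
  expect_error(
    load_tables(file.path(dir, "community.csv"),
                file.path(dir, "traits_miss.csv"),
                file.path(dir, "environment.csv"), mode = "incidence"),
    "\\bd\\b")
  # incidence file with non-binary values
  xb <- unclass(b$biomass)
  pondFD:::write_id_csv(as.data.frame(xb), file.path(dir, "comm_bio.csv"),
                        "sample_id")
  expect_error(
    load_tables(file.path(dir, "comm_bio.csv"),
                file.path(dir, "traits.csv"),
                file.path(dir, "environment.csv"), mode = "incidence"),
    "0 and 1")
})

test_that("drop_empty_samples removes and logs empty rows", {
  x <- matrix(c(1, 0, 0, 0, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  x[1, ] <- 0
  m <- community_matrix(x, "incidence")
  expect_message(m2 <- drop_empty_samples(m), "s1")
  expect_equal(rownames(m2), "s2")
})
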