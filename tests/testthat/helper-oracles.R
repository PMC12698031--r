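# Independent brute-force oracles. These deliberately re-derive every
# quantity from the defining formula (double loops, exhaustive facet
# enumeration, explicit edge-sorted MST) and never call the package's
# fast paths.

oracle_rao <- function(d, p) {
  q <- 0
  for (i in seq_along(p))
    for (j in seq_along(p)) q <- q + p[i] * p[j] * d[i, j]
  q
}

oracle_simpson <- function(p) 1 - sum(p^2)

oracle_fdis <- function(X, p) {
  ctr <- rep(0, ncol(X))
  for (i in seq_len(nrow(X))) ctr <- ctr + p[i] * X[i, ]
  sum(vapply(seq_len(nrow(X)),
             function(i) p[i] * sqrt(sum((X[i, ] - ctr)^2)), 0))
}

# exhaustive facet enumeration for points in general position (s <= ~9):
# a d-subset is a hull facet iff all remaining points fall strictly on one
# side of its hyperplane
oracle_hull <- function(x) {
  n <- nrow(x); d <- ncol(x)
  if (d == 1) {
    v <- max(x) - min(x)
    return(list(volume = if (v > 0) v else NA_real_,
                vertices = unique(c(which.min(x), which.max(x))),
                degenerate = v <= 0))
  }
  if (n < d + 1) return(list(volume = NA_real_, vertices = integer(0),
                             degenerate = TRUE))
  ctr <- colMeans(x)
  combos <- utils::combn(n, d)
  vol <- 0; isv <- rep(FALSE, n); any_facet <- FALSE
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    E <- x[idx[-1], , drop = FALSE] - matrix(x[idx[1], ], d - 1, d, byrow = TRUE)
    nrm <- vapply(seq_len(d), function(j)
      (-1)^(j + 1) * det(E[, -j, drop = FALSE]), 0)
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) next
    nrm <- nrm / nn
    off <- sum(nrm * x[idx[1], ])
    s <- x[-idx, , drop = FALSE] %*% nrm - off
    if (all(s < -1e-9) || all(s > 1e-9)) {
      any_facet <- TRUE
      M <- x[idx, , drop = FALSE] - matrix(ctr, d, d, byrow = TRUE)
      vol <- vol + abs(det(M)) / factorial(d)
      isv[idx] <- TRUE
    }
  }
  if (!any_facet) return(list(volume = NA_real_, vertices = integer(0),
                              degenerate = TRUE))
  list(volume = vol, vertices = which(isv), degenerate = FALSE)
}

oracle_fric <- function(X) oracle_hull(X)$volume

oracle_fdiv <- function(X, p) {
  if (nrow(X) < 3) return(NA_real_)
  h <- oracle_hull(X)
  if (h$degenerate) return(NA_real_)
  G <- colMeans(X[h$vertices, , drop = FALSE])
  dG <- apply(X, 1, function(r) sqrt(sum((r - G)^2)))
  mdG <- mean(dG)
  dd <- sum(p * (dG - mdG))
  dad <- sum(p * abs(dG - mdG))
  (dd + mdG) / (dad + mdG)
}

# MST by explicit edge sort (Kruskal with naive component labels)
oracle_mst <- function(X) {
  s <- nrow(X)
  edges <- NULL
  for (i in 1:(s - 1))
    for (j in (i + 1):s)
      edges <- rbind(edges, c(i, j, sqrt(sum((X[i, ] - X[j, ])^2))))
  edges <- edges[order(edges[, 3], edges[, 1], edges[, 2]), , drop = FALSE]
  comp <- seq_len(s)
  keep <- NULL
  for (e in seq_len(nrow(edges))) {
    a <- comp[edges[e, 1]]; b <- comp[edges[e, 2]]
    if (a != b) {
      comp[comp == b] <- a
      keep <- rbind(keep, edges[e, ])
    }
  }
  keep
}

oracle_feve <- function(X, p) {
  s <- nrow(X)
  if (s < 3) return(NA_real_)
  mst <- oracle_mst(X)
  ew <- mst[, 3] / (p[mst[, 1]] + p[mst[, 2]])
  if (sum(ew) <= 0) return(NA_real_)
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

# random weight vector summing to one
rand_weights <- function(s) {
  w <- runif(s, 0.1, 1)
  w / sum(w)
}

# random valid trait table over the default codebook
rand_traits <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cb <- default_codebook()
  out <- data.frame(row.names = sprintf("t%02d", seq_len(n)))
  for (tr in unique(cb$trait_name))
    out[[tr]] <- sample(cb$category[cb$trait_name == tr], n, replace = TRUE)
  out
}

# tiny deterministic bundle used across I/O and metric tests
toy_bundle <- function() {
  x <- matrix(c(1, 0, 1, 1,
                0, 1, 1, 0,
                1, 1, 0, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c", "d")))
  traits <- data.frame(
    size_class = c("<200", "200-600", ">600", "<200"),
    feeding_type = c("microphagous", "D_filtration", "tactile_raptorial",
                     "raptorial_rotifer"),
    trophic_group = c("herbivorous", "herbivorous", "omnivorous",
                      "carnivorous"),
    habitat = c("pelagic", "pelagic", "pelagic", "littoral"),
    row.names = c("a", "b", "c", "d"), stringsAsFactors = FALSE)
  env <- data.frame(TP = c(80, 150, 420), pond = c("p1", "p2", "p3"),
                    month = c(7, 7, 7), row.names = c("s1", "s2", "s3"),
                    stringsAsFactors = FALSE)
  list(incidence = community_matrix(x, basis = "incidence"),
       biomass = community_matrix(x * c(2, 5, 9), basis = "biomass"),
       traits = traits, env = env)
}

write_toy_csvs <- function(bundle, dir = tempfile("toy")) {
  dir.create(dir)
  write_tables(list(community = bundle$incidence, traits = bundle$traits,
                    env = bundle$env), dir)
  dir
}
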