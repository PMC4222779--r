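# Build a synthetic ProcrustesFit whose aligned shapes are exactly
# mean + beta * (CS - mean(CS)) plus optional noise, bypassing GPA, to test
# the regression in isolation.
linear_fit_fixture <- function(n = 12, k = 10, noise_sd = 0, seed = 101) {
  set.seed(seed)
  mean_shape <- matrix(rnorm(k * 3), k, 3,
                       dimnames = list(as.character(1:k), c("x", "y", "z")))
  beta <- matrix(rnorm(k * 3, sd = 0.02), k, 3,
                 dimnames = dimnames(mean_shape))
  cs <- seq(5, 10, length.out = n)
  shapes <- lapply(seq_len(n), function(i)
    mean_shape + beta * (cs[i] - mean(cs)) +
      matrix(rnorm(k * 3, sd = noise_sd), k, 3))
  names(shapes) <- paste0("s", seq_len(n))
  list(fit = list(aligned = shapes, centroid_sizes = cs),
       mean_shape = mean_shape, beta = beta, cs = cs)
}

test_that("a noiseless linear ontogeny is recovered exactly", {
  fx <- linear_fit_fixture()
  af <- regress_shape_on_size(fx$fit)
  expect_equal(af$pct_variance, 100, tolerance = 1e-6)
  expect_equal(af$slopes, fx$beta, tolerance = 1e-9)
  expect_equal(af$mean_shape, fx$mean_shape, tolerance = 1e-9)
  # regression score vs CS is exactly linear (lm warns about the perfect
  # fit, which is the point here)
  r2 <- suppressWarnings(
    summary(lm(af$regression_scores ~ af$centroid_sizes))$r.squared)
  expect_equal(r2, 1, tolerance = 1e-9)
})

test_that("size-independent noise yields near-zero variance explained", {
  set.seed(55)
  k <- 36
  shapes <- lapply(1:29, function(i)
    matrix(rnorm(k * 3, sd = 0.05), k, 3,
           dimnames = list(as.character(1:k), NULL)))
  names(shapes) <- paste0("s", 1:29)
  af <- regress_shape_on_size(list(aligned = shapes,
                                   centroid_sizes = seq(6, 9, length.out = 29)))
  expect_lt(af$pct_variance, 15)
  expect_gt(af$pct_variance, 0)
})

test_that("pct variance equals an independent projection-matrix oracle", {
  fx <- linear_fit_fixture(n = 9, k = 5, noise_sd = 0.05, seed = 7)
  af <- regress_shape_on_size(fx$fit)
  y <- t(vapply(fx$fit$aligned, as.vector, numeric(15)))
  x <- cbind(1, fx$cs)
  h <- x %*% solve(crossprod(x)) %*% t(x)
  yc <- sweep(y, 2, colMeans(y))
  pct_oracle <- 100 * sum((h %*% yc)^2) / sum(yc^2)
  expect_equal(af$pct_variance, pct_oracle, tolerance = 1e-9)
})

test_that("regression scores satisfy the projection identities", {
  fx <- linear_fit_fixture(noise_sd = 0.01, seed = 19)
  af <- regress_shape_on_size(fx$fit)
  expect_equal(regression_score(af, af$mean_shape), 0, tolerance = 1e-12)
  bnorm <- sqrt(sum(af$slopes^2))
  expect_equal(regression_score(af, af$mean_shape + af$slopes), bnorm,
               tolerance = 1e-9)
  # adding a vector orthogonal to the coefficient vector changes nothing
  set.seed(3)
  v <- matrix(rnorm(length(af$slopes)), nrow(af$slopes), 3)
  b <- as.vector(af$slopes)
  v <- v - matrix(b * sum(as.vector(v) * b) / sum(b^2), nrow(v), 3)
  s0 <- regression_score(af, af$mean_shape + 0.3 * af$slopes)
  s1 <- regression_score(af, af$mean_shape + 0.3 * af$slopes + v)
  expect_equal(s0, s1, tolerance = 1e-9)
})

test_that("ontogenetic vectors are linear in the size increment", {
  fx <- linear_fit_fixture(seed = 29)
  af <- regress_shape_on_size(fx$fit)
  v0 <- ontogenetic_vectors(af, delta_cs = 0)
  expect_equal(v0[c("x1", "y1", "z1")], v0[c("x0", "y0", "z0")],
               ignore_attr = TRUE)
  v1 <- ontogenetic_vectors(af, delta_cs = 1)
  v2 <- ontogenetic_vectors(af, delta_cs = 2)
  expect_equal(as.matrix(v2[c("x1", "y1", "z1")]) -
                 as.matrix(v2[c("x0", "y0", "z0")]),
               2 * (as.matrix(v1[c("x1", "y1", "z1")]) -
                      as.matrix(v1[c("x0", "y0", "z0")])),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the fitted slope field recovers the injected trajectory", {
  p <- default_study_design(seed = 31L)
  sim <- simulate_dataset(p)
  sm <- specimen_mean_shapes(sim$dataset, c("obs1", "obs2", "obs3"))
  af <- regress_shape_on_size(gpa(sm$shapes))
  # rotate the fitted field into the template frame before comparing
  b <- craniomorph:::base_shape()
  op <- ordinary_procrustes(af$mean_shape, b)
  slopes_t <- as.vector(af$slopes %*% op$rotation)
  inj <- as.vector(p$allometry_vector)
  cosine <- sum(slopes_t * inj) /
    sqrt(sum(slopes_t^2) * sum(inj^2))
  expect_gt(cosine, 0.95)
  # facial bilateral landmarks move rostrally (+x) and toward the midline
  sch <- builtin_scheme()
  slopes_m <- matrix(slopes_t, ncol = 3)
  facial_bil <- sch$subset %in% c("Nasal", "MaxMand") & sch$side != "midline"
  expect_gt(mean(slopes_m[facial_bil, 1]), 0)
  expect_lt(mean(slopes_m[facial_bil, 2] * sign(b[facial_bil, 2])), 0)
})

test_that("subset removal leaves the allometric pattern intact", {
  p <- default_study_design(seed = 1L)
  sim <- simulate_dataset(p)
  sc <- subset_experiment(sim$dataset, observers = c("obs1", "obs2", "obs3"))
  expect_named(sc$pct_variance, c("all", "minus_trouble", "minus_nasal",
                                  "minus_maxmand", "minus_nonfacial"))
  # identical subsets give zero angles
  expect_equal(max(sc$angles$angle_deg[sc$angles$subset == "all"]), 0,
               tolerance = 1e-4)
  expect_lt(max(sc$angles$angle_deg), 15)
  # the non-facial landmarks carry the size proxy: removing them weakens
  # the regression more than removing any facial subset
  expect_lt(sc$pct_variance["minus_nonfacial"], sc$pct_variance["all"])
  expect_equal(unname(sc$route[c("all", "minus_nonfacial")]),
               c("baseline", "gpa-aligned"))
})

test_that("anchor handling in the subset experiment is explicit", {
  p <- sim_params(n_specimens = c(3L, 3L, 3L), seed = 13L)
  sim <- simulate_dataset(p)
  expect_error(
    subset_experiment(sim$dataset, observers = c("obs1", "obs2", "obs3"),
                      subsets = list(no_anchor = c(1L)),
                      require_anchors = TRUE),
    "anchor")
  sc <- subset_experiment(sim$dataset, observers = c("obs1", "obs2", "obs3"),
                          subsets = list(no_anchor = c(1L)))
  expect_equal(unname(sc$route["no_anchor"]), "gpa-aligned")
})
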