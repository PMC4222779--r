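test_that("intraobserver distances respond to exact displacements", {
  b <- base_config()
  # identical trials -> all distances zero
  ds <- make_manual_dataset("s1", "E10.5", "o1", 1:2, function(s, o, tr) b)
  expect_equal(max(intraobserver_error(ds)$distance), 0)

  # shifting landmark 5 by (0.1, 0, 0) in trial 2 moves only its distance
  ds2 <- make_manual_dataset("s1", "E10.5", "o1", 1:2, function(s, o, tr) {
    m <- b
    if (tr == 2) m["5", 1] <- m["5", 1] + 0.1
    m
  })
  ie <- intraobserver_error(ds2, pool_bilateral = FALSE)
  expect_equal(ie$distance[ie$label == "5"], 0.1)
  expect_equal(max(ie$distance[ie$label != "5"]), 0)

  # pooled labels merge sides but keep one row per instance
  ie_pooled <- intraobserver_error(ds2)
  expect_equal(sum(ie_pooled$label == "7/24"), 2L)

  ds3 <- make_manual_dataset("s1", "E10.5", "o1", 1:3, function(s, o, tr) b)
  expect_error(intraobserver_error(ds3), "exactly 2 trials")
})

test_that("interobserver centroid size matches hand-computable cases", {
  b <- base_config()
  # coinciding observers -> CS identically zero
  ds <- make_manual_dataset("s1", "E10.5", c("o1", "o2", "o3"), 1:2,
                            function(s, o, tr) b)
  expect_equal(max(interobserver_error(ds)$cs), 0)

  # observer means at (-d,0,0), 0, (d,0,0) around each landmark -> d*sqrt(2)
  d <- 0.04
  off <- c(o1 = -d, o2 = 0, o3 = d)
  ds2 <- make_manual_dataset("s1", "E10.5", c("o1", "o2", "o3"), 1:2,
                             function(s, o, tr) {
                               m <- b; m[, 1] <- m[, 1] + off[[o]]; m
                             })
  ie <- interobserver_error(ds2)
  expect_equal(ie$cs, rep(d * sqrt(2), 36), tolerance = 1e-12)

  expect_error(interobserver_error(ds2, observers = "o1"), "at least 2")
})

test_that("interobserver CS equals a brute-force recomputation", {
  set.seed(31)
  b <- base_config()
  noise <- lapply(c(o1 = 1, o2 = 2, o3 = 3), function(i)
    matrix(rnorm(36 * 3, sd = 0.05), 36, 3))
  ds <- make_manual_dataset(c("s1", "s2"), c("E10.5", "E11.5"),
                            c("o1", "o2", "o3"), 1:2,
                            function(s, o, tr)
                              b + noise[[o]] + as.numeric(s == "s2"))
  ie <- interobserver_error(ds)
  for (i in sample(nrow(ie), 10)) {
    pts <- t(vapply(c("o1", "o2", "o3"), function(o) {
      m1 <- craniomorph:::config_matrix(ds, ie$specimen[i], o, 1)
      m2 <- craniomorph:::config_matrix(ds, ie$specimen[i], o, 2)
      (m1[as.character(ie$landmark[i]), ] +
         m2[as.character(ie$landmark[i]), ]) / 2
    }, numeric(3)))
    expect_equal(ie$cs[i], cs_oracle(pts), tolerance = 1e-12)
  }

  # invariance to global translation and observer relabeling
  ds_shift <- make_manual_dataset(c("s1", "s2"), c("E10.5", "E11.5"),
                                  c("o1", "o2", "o3"), 1:2,
                                  function(s, o, tr)
                                    b + noise[[o]] + as.numeric(s == "s2") + 5)
  expect_equal(interobserver_error(ds_shift)$cs, ie$cs, tolerance = 1e-9)
})

test_that("observer deviations from the specimen mean are exact", {
  b <- base_config()
  # single observer: the mean is the observation itself
  ds1 <- make_manual_dataset("s1", "E10.5", "o1", 1:2, function(s, o, tr) b)
  expect_equal(max(deviation_from_mean(ds1)$distance), 0)

  # two observers offset by +/- 0.05 along x -> both deviations 0.05
  ds2 <- make_manual_dataset("s1", "E10.5", c("o1", "o2"), 1:2,
                             function(s, o, tr) {
                               m <- b
                               m[, 1] <- m[, 1] + if (o == "o1") 0.05 else -0.05
                               m
                             })
  expect_equal(deviation_from_mean(ds2)$distance, rep(0.05, 72),
               tolerance = 1e-12)

  # brute force on a random 3-specimen dataset
  set.seed(8)
  obs_noise <- array(rnorm(36 * 3 * 4 * 2 * 3, sd = 0.03),
                     dim = c(36, 3, 4, 2, 3),
                     dimnames = list(NULL, NULL, paste0("o", 1:4), NULL,
                                     paste0("s", 1:3)))
  ds3 <- make_manual_dataset(paste0("s", 1:3), rep("E12.5", 3),
                             paste0("o", 1:4), 1:2,
                             function(s, o, tr)
                               b + obs_noise[, , o, tr, s])
  dev <- deviation_from_mean(ds3)
  for (i in sample(nrow(dev), 12)) {
    om <- vapply(paste0("o", 1:4), function(o) {
      m1 <- craniomorph:::config_matrix(ds3, dev$specimen[i], o, 1)
      m2 <- craniomorph:::config_matrix(ds3, dev$specimen[i], o, 2)
      (m1[as.character(dev$landmark[i]), ] +
         m2[as.character(dev$landmark[i]), ]) / 2
    }, numeric(3))
    expect_equal(dev$distance[i],
                 sqrt(sum((om[, dev$observer[i]] - rowMeans(om))^2)),
                 tolerance = 1e-12)
  }
})

test_that("placement ANOVA matches the projection-matrix oracle", {
  # balanced 3 specimens x 4 landmarks x 2 observers toy design
  toy <- expand.grid(specimen = paste0("s", 1:3),
                     landmark = 1:4,
                     observer = c("A", "B"),
                     stringsAsFactors = FALSE)
  set.seed(12)
  toy$distance <- abs(rnorm(nrow(toy), mean = 0.05, sd = 0.02))
  toy$age <- "E10.5"
  an <- placement_anova(toy)
  oracle <- seq_ss_oracle(toy$distance,
                          list(toy$specimen, toy$landmark, toy$observer))
  expect_equal(an$sum_sq[1:3], oracle$ss, tolerance = 1e-10)
  expect_equal(an$sum_sq[4], oracle$resid_ss, tolerance = 1e-10)
  expect_equal(an$df, c(2L, 3L, 1L, nrow(toy) - 1L - 2L - 3L - 1L))

  # SS decomposition and df-sum identities
  expect_equal(sum(an$sum_sq),
               sum((toy$distance - mean(toy$distance))^2),
               tolerance = 1e-9)
  expect_equal(sum(an$df), nrow(toy) - 1L)
})

test_that("sequential SS are order-invariant for balanced designs", {
  toy <- expand.grid(specimen = paste0("s", 1:3),
                     landmark = 1:4,
                     observer = c("A", "B"),
                     stringsAsFactors = FALSE)
  set.seed(13)
  toy$distance <- abs(rnorm(nrow(toy), 0.05, 0.02))
  factors <- list(specimen = toy$specimen, landmark = toy$landmark,
                  observer = toy$observer)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  base_ss <- seq_ss_oracle(toy$distance, factors)$ss
  for (p in perms) {
    ss <- seq_ss_oracle(toy$distance, factors[p])$ss
    expect_equal(ss[order(p)], base_ss, tolerance = 1e-10)
  }
  # and the package's anova agrees with the identity ordering
  toy$age <- "E10.5"
  an <- placement_anova(toy)
  expect_equal(an$sum_sq[1:3], base_ss, tolerance = 1e-10)
})

test_that("degenerate and unbalanced ANOVA inputs are handled", {
  toy <- expand.grid(specimen = paste0("s", 1:3), landmark = 1:4,
                     observer = c("A", "B"), stringsAsFactors = FALSE)
  toy$age <- "E10.5"
  toy$distance <- 0.07   # constant response
  an <- placement_anova(toy)
  expect_equal(an$sum_sq, rep(0, 4), tolerance = 1e-20)
  expect_true(all(is.na(an$p_value)))
  expect_error(placement_anova(toy[-1, ]), "unbalanced")
})

test_that("error summaries are exact order statistics", {
  tab <- data.frame(label = "5", observer = "o1", distance = 3)
  s <- summarize_error(tab, c("label", "observer"))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 3)
  expect_equal(s$n, 1)

  tab2 <- data.frame(label = "5", observer = "o1", distance = c(1, 2, 3, 4, 5))
  expect_equal(summarize_error(tab2, "label")$median, 3)

  set.seed(21)
  tab3 <- data.frame(label = sample(c("a", "b", "c"), 60, TRUE),
                     age = sample(embryo_ages(), 60, TRUE),
                     distance = rexp(60, 10))
  s3 <- summarize_error(tab3, c("label", "age"))
  for (i in seq_len(nrow(s3))) {
    v <- tab3$distance[tab3$label == s3$label[i] & tab3$age == s3$age[i]]
    expect_equal(s3$median[i], unname(quantile(v, 0.5)))
    expect_equal(s3$n[i], as.numeric(length(v)))
  }
})

test_that("trouble flagging is threshold-monotone and empty when clean", {
  set.seed(3)
  intra <- data.frame(label = rep(c("2", "3", "7/24"), each = 20),
                      age = "E10.5", observer = "o1",
                      distance = runif(60, 0, 0.02))
  inter <- data.frame(landmark = rep(c(2L, 3L, 7L), each = 10),
                      label = rep(c("2", "3", "7/24"), each = 10),
                      age = "E10.5", cs = runif(30, 0, 0.02))
  expect_equal(flag_trouble(intra, inter, inter_threshold = 1),
               character(0))
  # raising the intra threshold above the global max flags nothing
  expect_equal(flag_trouble(intra, NULL, intra_threshold = 1), character(0))
  # lowering it below the minimum flags everything
  expect_setequal(flag_trouble(intra, NULL, intra_threshold = 0),
                  c("2", "3", "7/24"))
})
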