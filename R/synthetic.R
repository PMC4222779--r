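# Synthetic ontogenetic landmark data with the statistical structure the
# downstream analyses assume: per-age template shapes, specimen-level shape
# variation, a linear allometric trend in centroid size, stable
# per-(observer, landmark) bias, and isotropic Gaussian trial noise.
#
# The template is a stylized, bilaterally symmetric 36-point embryo head.
# It is topologically faithful (midline vs bilateral placement, facial vs
# non-facial position, mm scale) but makes no claim of anatomical accuracy.

# Hand-placed template coordinates in head units (+x rostral, +y left,
# +z dorsal; midline exactly y = 0).  One row per midline landmark or left
# member of a pair; right members are mirrored in y.
.template_table <- function() {
  tab <- rbind(
    `1`  = c(-0.20,  0.00,  0.95),
    `2`  = c( 0.55,  0.00,  0.75),
    `3`  = c( 0.80,  0.00,  0.35),
    `4`  = c( 1.00,  0.00,  0.00),
    `5`  = c( 0.95,  0.00, -0.25),
    `6`  = c( 0.75,  0.18,  0.30),
    `7`  = c( 0.60,  0.38,  0.35),
    `8`  = c( 0.45,  0.55,  0.20),
    `9`  = c( 0.50,  0.50, -0.05),
    `10` = c( 0.25,  0.60, -0.10),
    `11` = c( 0.80,  0.30, -0.05),
    `12` = c( 0.85,  0.20, -0.20),
    `13` = c( 0.90,  0.32,  0.10),
    `14` = c( 0.90,  0.18,  0.05),
    `15` = c( 0.85,  0.25,  0.18),
    `16` = c( 0.55,  0.45, -0.35),
    `17` = c( 0.40,  0.65, -0.25),
    `18` = c(-0.30,  0.55, -0.35),
    `20` = c( 0.60,  0.15, -0.45),
    `21` = c( 0.10,  0.50, -0.55),
    `22` = c(-0.90,  0.00,  0.10))
  colnames(tab) <- c("x", "y", "z")
  tab
}

# Internal: unit-centroid-size base shape, rows in scheme order.
base_shape <- function(scheme = builtin_scheme()) {
  tab <- .template_table()
  m <- t(vapply(seq_len(nrow(scheme)), function(i) {
    id <- scheme$id[i]
    if (scheme$side[i] == "right") {
      p <- tab[as.character(scheme$pair_id[i]), ]
      c(p["x"], -p["y"], p["z"])
    } else tab[as.character(id), ]
  }, numeric(3)))
  dimnames(m) <- list(scheme$id, c("x", "y", "z"))
  m <- center_shape(m)
  m / centroid_size(m)
}

# Internal: unit ontogenetic shape direction.  Facial bilateral landmarks
# move rostrally and toward the midline, midline facial landmarks rostrally
# and ventrally, non-facial landmarks caudally and dorsally -- then the
# field is centered and made orthogonal to the similarity transformations
# (uniform scaling and the three infinitesimal rotations) of the base shape,
# so it is a pure shape direction that survives Procrustes superimposition.
allometry_direction <- function(scheme = builtin_scheme(),
                                base = base_shape(scheme)) {
  k <- nrow(scheme)
  a <- matrix(0, k, 3, dimnames = dimnames(base))
  facial <- scheme$subset %in% c("Nasal", "MaxMand")
  for (i in seq_len(k)) {
    if (facial[i] && scheme$side[i] != "midline") {
      a[i, ] <- c(0.5, -sign(base[i, 2]) * 0.6, -0.2)
    } else if (facial[i]) {
      a[i, ] <- c(0.5, 0, -0.5)
    } else {
      a[i, ] <- c(-0.6, 0, 0.5)
    }
  }
  a <- center_shape(a)
  # remove components along scaling (base itself) and rotations of base
  gens <- cbind(as.vector(base),
                as.vector(cbind(-base[, 2], base[, 1], 0)),    # rot about z
                as.vector(cbind(-base[, 3], 0, base[, 1])),    # rot about y
                as.vector(cbind(0, -base[, 3], base[, 2])))    # rot about x
  q <- qr.Q(qr(gens))
  av <- as.vector(a)
  av <- av - q %*% crossprod(q, av)
  a <- matrix(av, k, 3, dimnames = dimnames(base))
  # re-impose exact bilateral symmetry (the projection introduces only
  # rounding-level asymmetry, but midline y must be exactly zero)
  a[scheme$side == "midline", 2] <- 0
  li <- which(scheme$side == "left")
  ri <- match(scheme$pair_id[li], scheme$id)
  sx <- (a[li, 1] + a[ri, 1]) / 2
  sy <- (a[li, 2] - a[ri, 2]) / 2
  sz <- (a[li, 3] + a[ri, 3]) / 2
  a[li, ] <- cbind(sx, sy, sz)
  a[ri, ] <- cbind(sx, -sy, sz)
  a / sqrt(sum(a^2))
}

#' Simulation parameters for a multi-observer landmarking design
#'
#' Defaults reproduce the reference study design: 10/9/10 specimens at
#' E10.5/E11.5/E12.5, four observers (three experienced plus one novice)
#' each digitizing every specimen in two trials, per-age centroid-size
#' growth targets of 6/7.5/9 mm, experienced-observer trial noise of
#' 0.02 mm (median two-trial displacement about 0.045 mm, below the 0.1 mm
#' reference) and novice noise of 0.06 mm (median about 0.13 mm, above it),
#' observer bias of 0.05 mm, and a 2.5-fold error inflation on the
#' trouble-flagged landmarks.  The allometric slope defaults to the value
#' returned by [calibrate_allometry_slope()], targeting 80% of shape
#' variance explained by centroid size under these noise levels.
#'
#' @param n_specimens Integer vector of per-age specimen counts.
#' @param n_observers Number of observers.
#' @param n_trials Number of digitizing trials per observer.
#' @param sigma_specimen Specimen-level shape s.d. (mm, per coordinate).
#' @param sigma_trial Per-observer trial noise s.d. (mm); recycled to
#'   `n_observers`.
#' @param observer_bias_scale S.d. (mm) of the fixed per-(observer,
#'   landmark) bias offsets; a vector is recycled to one scale per
#'   observer (observers with larger scales deviate more from the
#'   consensus, which is what the placement ANOVA's observer effect
#'   detects).
#' @param trouble_inflation Multiplier (>= 1) on bias and trial noise s.d.
#'   for trouble-flagged landmarks.
#' @param trouble_ids Landmark ids receiving the inflation; defaults to the
#'   scheme's trouble column.
#' @param growth Per-age centroid-size targets (mm), strictly increasing.
#' @param cs_cv Within-age coefficient of variation of specimen centroid
#'   size.
#' @param allometry_vector Unit shape direction of ontogenetic change
#'   (k x 3, zero column means); default [allometry_direction()].
#' @param allometry_slope Shape displacement (Procrustes units) per mm of
#'   centroid size; `NULL` (default) triggers the closed-form calibration.
#' @param experienced Logical vector marking experienced observers.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_specimens = c(10L, 9L, 10L),
                       n_observers = 4L,
                       n_trials = 2L,
                       sigma_specimen = 0.05,
                       sigma_trial = c(0.02, 0.02, 0.02, 0.06),
                       observer_bias_scale = 0.05,
                       trouble_inflation = 2.5,
                       trouble_ids = NULL,
                       growth = c(6, 7.5, 9),
                       cs_cv = 0.04,
                       allometry_vector = NULL,
                       allometry_slope = NULL,
                       experienced = c(TRUE, TRUE, TRUE, FALSE),
                       seed = 1L) {
  scheme <- builtin_scheme()
  if (is.null(allometry_vector)) allometry_vector <- allometry_direction(scheme)
  if (is.null(trouble_ids)) trouble_ids <- scheme$id[scheme$trouble]
  bad <- setdiff(trouble_ids, scheme$id)
  if (length(bad)) stop("unknown trouble id(s): ", paste(bad, collapse = ", "))
  sigma_trial <- rep_len(sigma_trial, n_observers)
  observer_bias_scale <- rep_len(observer_bias_scale, n_observers)
  experienced <- rep_len(experienced, n_observers)
  p <- structure(list(n_specimens = as.integer(n_specimens),
                      n_observers = as.integer(n_observers),
                      n_trials = as.integer(n_trials),
                      sigma_specimen = sigma_specimen,
                      sigma_trial = sigma_trial,
                      observer_bias_scale = observer_bias_scale,
                      trouble_inflation = trouble_inflation,
                      trouble_ids = as.integer(trouble_ids),
                      growth = growth, cs_cv = cs_cv,
                      allometry_vector = allometry_vector,
                      allometry_slope = allometry_slope,
                      experienced = experienced,
                      seed = as.integer(seed), scheme = scheme),
                 class = "sim_params")
  validate_sim_params(p)
  if (is.null(p$allometry_slope))
    p$allometry_slope <- calibrate_allometry_slope(p)
  p
}

validate_sim_params <- function(p) {
  if (length(p$n_specimens) != 3 || any(p$n_specimens < 1))
    stop("n_specimens must give a positive count for each of the three ages")
  if (any(c(p$sigma_specimen, p$sigma_trial, p$observer_bias_scale,
            p$cs_cv) < 0))
    stop("all standard deviations must be >= 0")
  if (p$trouble_inflation < 1) stop("trouble_inflation must be >= 1")
  if (length(p$growth) != 3 || any(diff(p$growth) <= 0))
    stop("growth targets must be strictly increasing across E10.5..E12.5")
  a <- p$allometry_vector
  if (!isTRUE(all.equal(sum(a^2), 1, tolerance = 1e-8)) ||
      max(abs(colMeans(a))) > 1e-8)
    stop("allometry_vector must have unit norm and zero mean per axis")
  invisible(TRUE)
}

#' The reference study design
#'
#' Convenience wrapper returning [sim_params()] defaults — the balanced
#' 10/9/10-specimen, 4-observer, 2-trial design — with a chosen seed.
#'
#' @param seed Integer seed.
#' @return A `sim_params` object.
#' @export
default_study_design <- function(seed = 1L) sim_params(seed = seed)

#' Calibrate the allometric slope for a target variance explained
#'
#' Closed-form choice of the shape-on-size slope such that the expected
#' proportion of Procrustes-coordinate variance explained by the regression
#' on centroid size equals `target_r2`, given the design's centroid-size
#' spread and the effective per-coordinate noise (specimen shape variation
#' plus trial noise averaged over the experienced observers, mapped to
#' shape scale and spread over the 3k - 7 Procrustes degrees of freedom;
#' fixed observer bias cancels between specimens and does not enter).
#' Accounts for the overfitting term of per-coordinate least squares at
#' finite sample size.
#'
#' @param params A `sim_params` object (its `allometry_slope` is ignored).
#' @param target_r2 Target proportion of variance explained, in (0, 1).
#' @return Slope in shape units per mm of centroid size.
#' @export
calibrate_allometry_slope <- function(params, target_r2 = 0.8) {
  p <- params
  scheme <- p$scheme
  k <- nrow(scheme)
  n <- sum(p$n_specimens)
  cs <- rep(p$growth, p$n_specimens)
  sxx <- sum((cs - mean(cs))^2) + sum((p$cs_cv * cs)^2)

  obs <- which(p$experienced)
  if (!length(obs)) obs <- seq_len(p$n_observers)
  o <- length(obs)
  tr <- p$n_trials
  n_trouble <- sum(scheme$id %in% p$trouble_ids)
  infl <- (n_trouble * p$trouble_inflation^2 + (k - n_trouble)) / k
  # observer bias is fixed per (observer, landmark): averaging the same
  # observers for every specimen shifts all mean shapes identically, so it
  # adds nothing to between-specimen variance; only specimen-level shape
  # noise and averaged trial noise dilute the allometric signal
  sigma_eff2 <- p$sigma_specimen^2 +
    infl * sum(p$sigma_trial[obs]^2) / (o^2 * tr)
  cs_bar <- mean(cs)
  sigma_sh2 <- sigma_eff2 / cs_bar^2
  q <- 3 * k - 7
  s_signal <- q * sigma_sh2 * (target_r2 * (n - 1) - 1) / (1 - target_r2)
  sqrt(s_signal / sxx)
}

#' Template configuration for an embryonic age
#'
#' The noise-free, bilaterally symmetric 36-landmark head shape at an age's
#' centroid-size target, displaced along the allometric direction according
#' to the age's size relative to the design's mean size and rescaled so its
#' centroid size equals the growth target exactly.  Midline landmarks lie
#' exactly on the midsagittal plane (y = 0).
#'
#' @param age One of `"E10.5"`, `"E11.5"`, `"E12.5"`.
#' @param params A `sim_params` object.
#' @return k x 3 matrix (mm), rownames the landmark ids.
#' @export
make_template <- function(age, params = sim_params()) {
  age <- match.arg(age, embryo_ages())
  cs_a <- params$growth[match(age, embryo_ages())]
  cs_bar <- mean(rep(params$growth, params$n_specimens))
  b <- base_shape(params$scheme)
  delta <- params$allometry_slope * (cs_a - cs_bar)
  s <- b + delta * params$allometry_vector
  cs_a * s / centroid_size(s)
}

#' Simulate a balanced multi-observer landmark dataset
#'
#' Generative model, per observation (specimen x observer x trial x
#' landmark):
#' `coords = specimen_true + bias(observer, landmark) + trial noise`,
#' where `specimen_true` is the age template displaced along the allometry
#' vector in proportion to the specimen's centroid size (drawn around the
#' age target with CV `cs_cv`) plus isotropic specimen-level shape noise;
#' `bias` is a fixed per-(observer, landmark) offset drawn once per
#' simulation with s.d. `observer_bias_scale`; trial noise is isotropic
#' Gaussian with the observer's `sigma_trial`.  Bias and trial noise s.d.
#' are multiplied by `trouble_inflation` at trouble-flagged landmarks.
#' All draws come from R's Mersenne-Twister stream seeded with
#' `params$seed` (normal deviates by inversion), so a dataset is bit
#' reproducible from its parameters alone.
#'
#' @param params A `sim_params` object.
#' @return A list with `dataset` (a [trial_dataset()]) and `truth`, the
#'   ground-truth record: per-age templates, per-specimen true
#'   configurations and centroid sizes, per-(observer, landmark) bias
#'   vectors, and the allometry vector and slope.
#' @export
simulate_dataset <- function(params = sim_params()) {
  p <- params
  validate_sim_params(p)
  scheme <- p$scheme
  k <- nrow(scheme)
  ages <- rep(embryo_ages(), p$n_specimens)
  n <- length(ages)
  specimens <- sprintf("%s_s%02d", gsub("[^0-9.]", "", ages),
                       unlist(lapply(p$n_specimens, seq_len)))
  specimens <- paste0("E", specimens)
  observers <- sprintf("obs%d", seq_len(p$n_observers))
  sd_mult <- ifelse(scheme$id %in% p$trouble_ids, p$trouble_inflation, 1)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(p$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  # 1. specimen centroid sizes
  cs_target <- rep(p$growth, p$n_specimens)
  cs <- cs_target * (1 + p$cs_cv * stats::rnorm(n))
  cs_bar <- mean(rep(p$growth, p$n_specimens))
  b <- base_shape(scheme)

  # 2. specimen true configurations
  true_shapes <- vector("list", n)
  for (i in seq_len(n)) {
    delta <- p$allometry_slope * (cs[i] - cs_bar)
    s <- b + delta * p$allometry_vector
    s <- cs[i] * s / centroid_size(s)
    true_shapes[[i]] <- s + matrix(stats::rnorm(3 * k, sd = p$sigma_specimen),
                                   k, 3)
    dimnames(true_shapes[[i]]) <- dimnames(b)
  }
  names(true_shapes) <- specimens

  # 3. per-(observer, landmark) bias (raw draws scaled, so the bias field
  #    is proportional to observer_bias_scale at fixed seed)
  bias <- lapply(seq_len(p$n_observers), function(oi) {
    raw <- matrix(stats::rnorm(3 * k), k, 3)
    m <- p$observer_bias_scale[oi] * sd_mult * raw
    dimnames(m) <- dimnames(b)
    m
  })
  names(bias) <- observers

  # 4. observations
  rows <- vector("list", n * p$n_observers * p$n_trials)
  ri <- 0L
  for (i in seq_len(n)) {
    for (oi in seq_len(p$n_observers)) {
      for (tr in seq_len(p$n_trials)) {
        noise <- matrix(stats::rnorm(3 * k), k, 3) *
          (p$sigma_trial[oi] * sd_mult)
        obs <- true_shapes[[i]] + bias[[oi]] + noise
        ri <- ri + 1L
        rows[[ri]] <- data.frame(specimen = specimens[i], age = ages[i],
                                 observer = observers[oi], trial = tr,
                                 landmark = scheme$id,
                                 x = obs[, 1], y = obs[, 2], z = obs[, 3],
                                 stringsAsFactors = FALSE)
      }
    }
  }
  dataset <- trial_dataset(do.call(rbind, rows), scheme = scheme)

  templates <- lapply(embryo_ages(), function(a) make_template(a, p))
  names(templates) <- embryo_ages()
  truth <- list(templates = templates, true_shapes = true_shapes,
                centroid_sizes = stats::setNames(cs, specimens),
                ages = stats::setNames(ages, specimens),
                bias = bias, allometry_vector = p$allometry_vector,
                allometry_slope = p$allometry_slope,
                observers = observers,
                experienced = stats::setNames(p$experienced, observers))
  list(dataset = dataset, truth = truth)
}
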