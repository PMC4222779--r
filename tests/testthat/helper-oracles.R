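# Independent oracles used to cross-check the package's numerics.  These
# deliberately avoid the implementation paths they test.

# Brute-force ordinary-Procrustes residual: minimize over rotations
# parameterized by Euler angles (coarse grid + Nelder-Mead refinement),
# with the scale solved in closed form for each rotation.  Proper rotations
# only.
brute_force_opa_residual <- function(source, target) {
  sc <- sweep(source, 2, colMeans(source))
  tc <- sweep(target, 2, colMeans(target))
  rot <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cg <- cos(ang[3]); sg <- sin(ang[3])
    rz1 <- rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1))
    ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
    rz2 <- rbind(c(cg, -sg, 0), c(sg, cg, 0), c(0, 0, 1))
    rz1 %*% ry %*% rz2
  }
  resid <- function(ang) {
    r <- rot(ang)
    beta <- sum((sc %*% r) * tc) / sum(sc^2)
    if (beta < 0) beta <- 0   # scale must be non-negative
    sum((beta * sc %*% r - tc)^2)
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid) for (b in seq(0, pi, length.out = 7)) for (g in grid) {
    v <- resid(c(a, b, g))
    if (v < best) { best <- v; best_ang <- c(a, b, g) }
  }
  opt <- stats::optim(best_ang, resid, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  sqrt(opt$value)
}

# Sequential sums of squares for a balanced main-effects model, computed by
# projections onto successively augmented column spaces of hand-built
# indicator matrices (normal-equations route; independent of lm/anova).
seq_ss_oracle <- function(y, factors) {
  n <- length(y)
  x <- matrix(1, n, 1)
  ss <- numeric(length(factors))
  fitted_prev <- qr.fitted(qr(x), y)
  for (j in seq_along(factors)) {
    f <- factor(factors[[j]])
    ind <- outer(f, levels(f), `==`) + 0
    x <- cbind(x, ind)
    fitted <- qr.fitted(qr(x), y)
    ss[j] <- sum((fitted - fitted_prev)^2)
    fitted_prev <- fitted
  }
  resid_ss <- sum((y - fitted_prev)^2)
  list(ss = ss, resid_ss = resid_ss)
}

# Direct recomputation of the centroid size of a point set.
cs_oracle <- function(m) {
  ctr <- colMeans(m)
  sqrt(sum(sweep(m, 2, ctr)^2))
}

# Build a tiny hand-rolled trial dataset: one entry per
# (specimen, observer, trial), coordinates supplied by `coord_fun(spec,
# obs, trial)` returning a 36 x 3 matrix in scheme order.
make_manual_dataset <- function(specimens, ages, observers, trials,
                                coord_fun) {
  sch <- builtin_scheme()
  rows <- list()
  for (i in seq_along(specimens)) for (o in observers) for (tr in trials) {
    m <- coord_fun(specimens[i], o, tr)
    rows[[length(rows) + 1L]] <- data.frame(
      specimen = specimens[i], age = ages[i], observer = o, trial = tr,
      landmark = sch$id, x = m[, 1], y = m[, 2], z = m[, 3],
      stringsAsFactors = FALSE)
  }
  trial_dataset(do.call(rbind, rows))
}

# A generic non-degenerate base configuration for manual datasets.
base_config <- function() {
  sch <- builtin_scheme()
  set.seed(4242)
  m <- matrix(stats::rnorm(nrow(sch) * 3, sd = 1), nrow(sch), 3)
  rownames(m) <- sch$id
  m
}
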