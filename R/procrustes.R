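# Superimposition machinery: centroid size, ordinary (two-shape) Procrustes
# alignment, generalized Procrustes analysis, and a three-anchor baseline
# registration used when comparing landmark subsets in a common frame.
#
# Conventions: shapes are k x 3 matrices (mm) with landmark ids as rownames;
# reflections are forbidden throughout (embryo heads are chiral), enforced
# as det(rotation) = +1.

center_shape <- function(x) sweep(x, 2, colMeans(x))

#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometrics size measure:
#' CS = sqrt(sum_i ||x_i - xbar||^2), the square root of the summed squared
#' distances of the landmarks from their centroid.  Used throughout as the
#' proxy for developmental age.
#'
#' @param shape A k x 3 (or k x d) numeric matrix, one landmark per row.
#' @return Non-negative scalar (mm for raw configurations).
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
#' centroid_size(sq)  # sqrt(2)
#' @export
centroid_size <- function(shape) {
  shape <- as.matrix(shape)
  sqrt(sum(center_shape(shape)^2))
}

# Internal: optimal rotation of (centered) source onto (centered) target,
# proper only (no reflection): Kabsch with sign-corrected smallest singular
# pair.
kabsch_rotation <- function(source_c, target_c) {
  m <- crossprod(source_c, target_c)      # 3 x 3
  sv <- svd(m)
  s <- diag(3)
  if (det(sv$u %*% t(sv$v)) < 0) s[3, 3] <- -1
  sv$u %*% s %*% t(sv$v)
}

#' Ordinary (two-shape) Procrustes alignment
#'
#' Least-squares similarity alignment of `source` onto `target`: translation,
#' proper rotation (determinant +1; reflections disallowed), and optionally
#' scale.  The building block of the generalized fit.
#'
#' @param source,target k x 3 matrices with matching landmark rows, k >= 3.
#' @param scale Estimate a scale factor (default `TRUE`).
#' @return A list with `rotation` (3 x 3, det +1), `scale`, `translation`
#'   (length-3; aligned = scale * source %*% rotation + translation),
#'   `aligned` (the transformed source), and `residual`
#'   (sqrt of the summed squared aligned-to-target distances).
#' @export
ordinary_procrustes <- function(source, target, scale = TRUE) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) == nrow(target), nrow(source) >= 3, ncol(source) == 3)
  sc <- center_shape(source); tc <- center_shape(target)
  if (sum(sc^2) == 0 || sum(tc^2) == 0)
    stop("degenerate configuration: all landmarks coincide")
  r <- kabsch_rotation(sc, tc)
  beta <- if (scale) sum((sc %*% r) * tc) / sum(sc^2) else 1
  aligned_c <- beta * sc %*% r
  translation <- colMeans(target) - colMeans(source %*% (beta * r))
  aligned <- sweep(aligned_c, 2, colMeans(target), `+`)
  dimnames(aligned) <- dimnames(target)
  list(rotation = r, scale = beta, translation = translation,
       aligned = aligned, residual = sqrt(sum((aligned - target)^2)))
}

#' Generalized Procrustes analysis
#'
#' Full GPA with scaling: each configuration is centered and scaled to unit
#' centroid size, rotated onto the current consensus, and the consensus
#' (arithmetic mean of aligned shapes, re-centered) is iterated until its
#' root-mean-square change falls below `tol`.  Raw centroid sizes are
#' retained as the size variable for downstream allometric regression.
#'
#' @param shapes List of k x 3 matrices with identical landmark rows.
#' @param tol Convergence tolerance on the consensus RMS change.
#' @param max_iter Iteration cap; non-convergence is flagged, not fatal.
#' @param tangent Optionally project aligned shapes orthogonally onto the
#'   tangent plane at the consensus (default `FALSE`; differences are tiny
#'   at within-sample shape scales).
#' @return An object of class `procrustes_fit`: list with `aligned` (list of
#'   unit-size aligned shapes), `consensus`, `centroid_sizes` (raw, mm),
#'   `iterations`, and `converged`.
#' @export
gpa <- function(shapes, tol = 1e-10, max_iter = 100L, tangent = FALSE) {
  stopifnot(length(shapes) >= 2)
  k <- nrow(shapes[[1]])
  cs <- vapply(shapes, centroid_size, numeric(1))
  unit <- lapply(shapes, function(s) center_shape(as.matrix(s)) / centroid_size(s))

  consensus <- unit[[1]]
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    aligned <- lapply(unit, function(s) s %*% kabsch_rotation(s, consensus))
    new_consensus <- center_shape(Reduce(`+`, aligned) / length(aligned))
    drift <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (drift < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  aligned <- lapply(unit, function(s) s %*% kabsch_rotation(s, consensus))
  if (tangent) {
    v <- as.vector(consensus); v <- v / sqrt(sum(v^2))
    aligned <- lapply(aligned, function(a) {
      av <- as.vector(a)
      matrix(av - (sum(av * v) - sum(v * as.vector(consensus))) * v,
             nrow = k, dimnames = dimnames(a))
    })
  }
  aligned <- lapply(aligned, function(a) {
    dimnames(a) <- dimnames(shapes[[1]]); a
  })
  dimnames(consensus) <- dimnames(shapes[[1]])
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = cs, iterations = iterations,
                 converged = converged),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("GPA fit:", length(x$aligned), "shapes x", nrow(x$consensus),
      "landmarks;", x$iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Full Procrustes distance between two aligned shapes
#'
#' Root summed squared difference after optimally rotating `a` onto `b`
#' (both already centered/scaled, e.g. out of [gpa()]).
#'
#' @param a,b k x 3 matrices.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  ac <- center_shape(as.matrix(a)); bc <- center_shape(as.matrix(b))
  r <- kabsch_rotation(ac, bc)
  sqrt(sum((ac %*% r - bc)^2))
}

#' Baseline (three-anchor) superimposition
#'
#' Registers each shape into the common coordinate frame defined by three
#' anchor landmarks: anchor 1 at the origin, anchor 2 on the +x axis,
#' anchor 3 in the xy-plane with positive y.  Because the frame depends only
#' on the anchors, subsets of landmarks that share the anchors end up with
#' parallel axes and directly comparable coordinates.  Rigid motion only
#' (right-handed frame; no reflection); optionally each shape is scaled to
#' unit centroid size first.
#'
#' @param shapes List of k x 3 matrices; rownames must contain `anchor_ids`.
#' @param anchor_ids Length-3 vector of landmark ids (coercible to the
#'   rownames), non-collinear in every shape.
#' @param scale Scale each shape to unit centroid size before registration
#'   (default `TRUE`, so subset coordinates are commensurate with Procrustes
#'   coordinates).
#' @return List of transformed k x 3 matrices.
#' @export
baseline_superimpose <- function(shapes, anchor_ids, scale = TRUE) {
  stopifnot(length(anchor_ids) == 3)
  lapply(shapes, function(s) {
    s <- as.matrix(s)
    idx <- match(as.character(anchor_ids), rownames(s))
    if (anyNA(idx))
      stop("anchor id(s) absent from shape: ",
           paste(anchor_ids[is.na(idx)], collapse = ", "))
    if (scale) s <- s / centroid_size(s)
    a <- s[idx, ]
    e1 <- a[2, ] - a[1, ]
    n1 <- sqrt(sum(e1^2))
    v2 <- a[3, ] - a[1, ]
    e3 <- c(e1[2] * v2[3] - e1[3] * v2[2],
            e1[3] * v2[1] - e1[1] * v2[3],
            e1[1] * v2[2] - e1[2] * v2[1])
    n3 <- sqrt(sum(e3^2))
    if (n1 == 0 || n3 / n1 < 1e-12)
      stop("collinear (or coincident) anchor landmarks")
    e1 <- e1 / n1
    e3 <- e3 / n3
    e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
            e3[3] * e1[1] - e3[1] * e1[3],
            e3[1] * e1[2] - e3[2] * e1[1])
    out <- sweep(s, 2, a[1, ]) %*% cbind(e1, e2, e3)
    colnames(out) <- c("x", "y", "z")
    out
  })
}
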