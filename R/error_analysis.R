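# Landmark placement error: intraobserver trial-to-trial distances,
# interobserver dispersion (centroid size of observer means), deviations
# from the specimen mean, the balanced three-factor placement ANOVA, and
# trouble-landmark flagging.

# Internal: observer trial-mean coordinates, one row per
# (age, specimen, observer, landmark), with side/label annotation.
observer_trial_means <- function(dataset, observers = NULL) {
  cc <- dataset$coords
  if (!is.null(observers)) {
    bad <- setdiff(observers, dataset$design$observers)
    if (length(bad)) stop("unknown observer(s): ", paste(bad, collapse = ", "))
    cc <- cc[cc$observer %in% observers, ]
  }
  g <- paste(cc$specimen, cc$observer, cc$landmark, sep = "\r")
  m <- rowsum(as.matrix(cc[c("x", "y", "z")]), g)
  m <- m / as.vector(table(g)[rownames(m)])
  meta <- do.call(rbind, strsplit(rownames(m), "\r", fixed = TRUE))
  out <- data.frame(specimen = meta[, 1], observer = meta[, 2],
                    landmark = as.integer(meta[, 3]),
                    x = m[, 1], y = m[, 2], z = m[, 3],
                    stringsAsFactors = FALSE)
  sp_age <- unique(cc[c("specimen", "age")])
  out$age <- sp_age$age[match(out$specimen, sp_age$specimen)]
  sch <- dataset$scheme
  out$side <- sch$side[match(out$landmark, sch$id)]
  out$label <- landmark_label(out$landmark, sch)
  rownames(out) <- NULL
  out
}

#' Intraobserver landmark placement error
#'
#' The Euclidean distance (mm) between the positions an observer assigned to
#' a landmark in the two digitizing trials — one distance per (specimen,
#' observer, landmark instance).  Left and right members of a bilateral pair
#' show similar error patterns, so by default both sides are pooled under
#' the pair's joint label (values are kept, only the label is merged).
#'
#' @param dataset A `trial_dataset` with exactly two trials.
#' @param pool_bilateral Report bilateral landmarks under the pooled
#'   `"low/high"` label (default `TRUE`).
#' @return Data frame with columns `age, observer, specimen, landmark,
#'   side, label, distance`.
#' @export
intraobserver_error <- function(dataset, pool_bilateral = TRUE) {
  if (dataset$design$n_trials != 2L)
    stop("intraobserver error requires exactly 2 trials per observer; got ",
         dataset$design$n_trials)
  cc <- dataset$coords
  trials <- dataset$design$trials
  key <- function(d) order(d$specimen, d$observer, d$landmark)
  t1 <- cc[cc$trial == trials[1], ]; t1 <- t1[key(t1), ]
  t2 <- cc[cc$trial == trials[2], ]; t2 <- t2[key(t2), ]
  stopifnot(all(t1$landmark == t2$landmark),
            all(t1$specimen == t2$specimen))
  d <- sqrt(rowSums((as.matrix(t1[c("x", "y", "z")]) -
                       as.matrix(t2[c("x", "y", "z")]))^2))
  sch <- dataset$scheme
  out <- data.frame(age = t1$age, observer = t1$observer,
                    specimen = t1$specimen, landmark = t1$landmark,
                    side = sch$side[match(t1$landmark, sch$id)],
                    label = if (pool_bilateral)
                      landmark_label(t1$landmark, sch)
                    else as.character(t1$landmark),
                    distance = d, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Interobserver landmark placement error
#'
#' For each (specimen, landmark instance): average each selected observer's
#' trials into an observer-mean point, then report the centroid size of
#' those observer means, CS = sqrt(sum_o ||p_o - pbar||^2) — the dispersion
#' of the observers' interpretations of the landmark.  Left and right sides
#' of bilateral landmarks are kept separate.
#'
#' @param dataset A `trial_dataset`.
#' @param observers Observers to include (>= 2); the study convention is
#'   the experienced subset.  Default: all observers.
#' @return Data frame with columns `age, specimen, landmark, side, label,
#'   cs` (mm).
#' @export
interobserver_error <- function(dataset, observers = NULL) {
  if (is.null(observers)) observers <- dataset$design$observers
  if (length(observers) < 2)
    stop("interobserver error requires at least 2 observers")
  om <- observer_trial_means(dataset, observers)
  g <- paste(om$specimen, om$landmark, sep = "\r")
  xyz <- as.matrix(om[c("x", "y", "z")])
  ctr <- rowsum(xyz, g)
  ctr <- ctr / as.vector(table(g)[rownames(ctr)])
  dev2 <- rowSums((xyz - ctr[g, , drop = FALSE])^2)
  cs2 <- rowsum(dev2, g)
  out <- om[!duplicated(g), c("age", "specimen", "landmark", "side", "label")]
  out$cs <- sqrt(cs2[paste(out$specimen, out$landmark, sep = "\r"), 1])
  ord <- order(match(out$age, embryo_ages()), out$specimen,
               match(out$landmark, dataset$scheme$id))
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Deviation of each observer from the specimen mean
#'
#' Observer coordinates are the mean of that observer's trials; the
#' specimen mean is the average of those observer means over the included
#' observers.  The deviation is the Euclidean distance (mm) between an
#' observer's coordinates and the specimen mean — the response variable of
#' the placement ANOVA.
#'
#' @param dataset A `trial_dataset`.
#' @param observers Observers to include; default all (the configuration
#'   consistent with the reported ANOVA degrees of freedom).
#' @return Data frame with columns `age, specimen, landmark, side, label,
#'   observer, distance`.
#' @export
deviation_from_mean <- function(dataset, observers = NULL) {
  om <- observer_trial_means(dataset, observers)
  g <- paste(om$specimen, om$landmark, sep = "\r")
  xyz <- as.matrix(om[c("x", "y", "z")])
  ctr <- rowsum(xyz, g)
  ctr <- ctr / as.vector(table(g)[rownames(ctr)])
  out <- om[c("age", "specimen", "landmark", "side", "label", "observer")]
  out$distance <- sqrt(rowSums((xyz - ctr[g, , drop = FALSE])^2))
  ord <- order(match(out$age, embryo_ages()), out$specimen, out$observer,
               out$landmark)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Balanced placement ANOVA per embryonic age
#'
#' For each age, fits the additive main-effects linear model
#' `distance ~ specimen + landmark + observer` to the observer-deviation
#' distances (one observation per specimen x landmark instance x observer)
#' and reports sequential sums of squares, F statistics, and p-values
#' against the residual.  Under the required balance the sequential SS are
#' invariant to factor order.  Degrees of freedom are (S-1), (L-1), (O-1),
#' and N-1-(S-1)-(L-1)-(O-1); with the full reference design they are
#' 9/35/3 with residual 1392 at E10.5 and E12.5 and 8/35/3 with residual
#' 1249 at E11.5.
#'
#' @param deviation_table Output of [deviation_from_mean()].
#' @return Data frame of class `placement_anova` with columns `age, term,
#'   df, sum_sq, f_value, p_value` (`term` one of `"Specimen"`,
#'   `"Landmark"`, `"Observer"`, `"Residual"`; residual rows carry `NA`
#'   F and p).
#' @export
placement_anova <- function(deviation_table) {
  dt <- deviation_table
  need <- c("age", "specimen", "landmark", "observer", "distance")
  stopifnot(all(need %in% names(dt)))
  out <- lapply(intersect(embryo_ages(), unique(dt$age)), function(a) {
    d <- dt[dt$age == a, ]
    tab <- table(d$specimen, d$landmark, d$observer)
    if (any(tab != 1L))
      stop("unbalanced design at ", a,
           ": every specimen x landmark x observer cell must appear exactly once")
    d$specimen <- factor(d$specimen)
    d$landmark <- factor(d$landmark)
    d$observer <- factor(d$observer)
    n <- nrow(d)
    dfs <- c(nlevels(d$specimen) - 1L, nlevels(d$landmark) - 1L,
             nlevels(d$observer) - 1L)
    dfs <- c(dfs, n - 1L - sum(dfs))
    tot <- sum((d$distance - mean(d$distance))^2)
    if (tot <= 1e-20 * max(1, mean(d$distance)^2) * n) {
      # constant response: zero SS everywhere, F and p undefined
      return(data.frame(age = a,
                        term = c("Specimen", "Landmark", "Observer",
                                 "Residual"),
                        df = dfs, sum_sq = rep(0, 4),
                        f_value = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(distance ~ specimen + landmark + observer, data = d)
    an <- stats::anova(fit)
    terms <- c(specimen = "Specimen", landmark = "Landmark",
               observer = "Observer", Residuals = "Residual")
    data.frame(age = a, term = unname(terms[rownames(an)]),
               df = an$Df, sum_sq = an$`Sum Sq`,
               f_value = ifelse(is.finite(an$`F value`), an$`F value`, NA),
               p_value = ifelse(is.finite(an$`Pr(>F)`), an$`Pr(>F)`, NA),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("placement_anova", "data.frame")
  out
}

#' Boxplot summary statistics of an error table
#'
#' Median, quartiles (type-7), Tukey whiskers, and group size for grouped
#' error values — the numbers behind per-landmark error boxplots, with the
#' 0.1 mm working reference in mind for intraobserver distances.
#'
#' @param table A data frame holding the error values.
#' @param group_by Character vector of grouping columns, e.g.
#'   `c("label", "observer")` or `c("label", "age")`.
#' @param value Name of the value column; default auto-detects
#'   `"distance"` then `"cs"`.
#' @return Data frame with the grouping columns plus `n, whisker_lo, q1,
#'   median, q3, whisker_hi`.
#' @export
summarize_error <- function(table, group_by, value = NULL) {
  if (is.null(value))
    value <- intersect(c("distance", "cs"), names(table))[1]
  stopifnot(!is.na(value), all(group_by %in% names(table)))
  key <- interaction(table[group_by], drop = TRUE, sep = "\r")
  groups <- split(table[[value]], key)
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning("excluding ", sum(empty), " empty group(s)")
    groups <- groups[!empty]
  }
  stats <- t(vapply(groups, function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    bs <- grDevices::boxplot.stats(v)$stats
    c(length(v), bs[1], q[1], q[2], q[3], bs[5])
  }, numeric(6)))
  meta <- do.call(rbind, strsplit(rownames(stats), "\r", fixed = TRUE))
  out <- data.frame(meta, stats, stringsAsFactors = FALSE)
  names(out) <- c(group_by, "n", "whisker_lo", "q1", "median", "q3",
                  "whisker_hi")
  rownames(out) <- NULL
  out
}

#' Flag trouble landmarks from error statistics
#'
#' A landmark (pooled label) is flagged when its median intraobserver
#' distance exceeds `intra_threshold` at any age for any observer in
#' `intra_table` (conventionally the experienced observers' 0.1 mm working
#' reference), or when the median interobserver centroid size of either of
#' its instances at any age exceeds `inter_threshold` (default: the 90th
#' percentile of the per-(instance, age) median CS values).
#'
#' @param intra_table Output of [intraobserver_error()], typically
#'   restricted to experienced observers.
#' @param inter_table Output of [interobserver_error()]; `NULL` to flag on
#'   intraobserver error alone.
#' @param intra_threshold Median-distance threshold, mm (default 0.1).
#' @param inter_threshold Median-CS threshold, mm; `NULL` for the
#'   percentile default.
#' @return Sorted character vector of flagged pooled labels.
#' @export
flag_trouble <- function(intra_table, inter_table = NULL,
                         intra_threshold = 0.1, inter_threshold = NULL) {
  med_i <- stats::aggregate(distance ~ label + age + observer,
                            data = intra_table, FUN = stats::median)
  flagged <- unique(med_i$label[med_i$distance > intra_threshold])
  if (!is.null(inter_table)) {
    med_o <- stats::aggregate(cs ~ landmark + label + age,
                              data = inter_table, FUN = stats::median)
    if (is.null(inter_threshold))
      inter_threshold <- stats::quantile(med_o$cs, 0.9, names = FALSE)
    flagged <- union(flagged, unique(med_o$label[med_o$cs > inter_threshold]))
  }
  sch <- builtin_scheme()
  all_labels <- unique(landmark_label(sch$id, sch))
  sort_key <- match(flagged, all_labels)
  flagged[order(sort_key)]
}
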