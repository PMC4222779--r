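#' Construct a balanced trial dataset of landmark configurations
#'
#' A trial dataset is the long-format collection of 3D landmark coordinates
#' (in mm) indexed by specimen, embryonic age, observer, and digitizing
#' trial.  The design must be balanced: every (specimen, observer, trial)
#' cell contains exactly one full configuration of the scheme's landmarks.
#'
#' @param coords Data frame with columns
#'   `specimen, age, observer, trial, landmark, x, y, z`.
#' @param scheme A `landmark_scheme` (default [builtin_scheme()]).
#' @return An object of class `trial_dataset`: a list with elements
#'   `coords` (the validated, canonically ordered data frame), `scheme`,
#'   and `design` (`n_specimens` per age, `n_observers`, `n_trials`).
#' @export
trial_dataset <- function(coords, scheme = builtin_scheme()) {
  req <- c("specimen", "age", "observer", "trial", "landmark", "x", "y", "z")
  miss <- setdiff(req, names(coords))
  if (length(miss))
    stop("coords is missing column(s): ", paste(miss, collapse = ", "))
  coords <- as.data.frame(coords)[req]
  coords$specimen <- as.character(coords$specimen)
  coords$age <- as.character(coords$age)
  coords$observer <- as.character(coords$observer)
  coords$trial <- as.integer(coords$trial)
  coords$landmark <- as.integer(coords$landmark)

  bad_age <- setdiff(unique(coords$age), embryo_ages())
  if (length(bad_age))
    stop("unknown age label(s): ", paste(bad_age, collapse = ", "))
  bad_lm <- setdiff(unique(coords$landmark), scheme$id)
  if (length(bad_lm))
    stop("unknown landmark id(s): ", paste(sort(bad_lm), collapse = ", "))
  if (!all(is.finite(coords$x) & is.finite(coords$y) & is.finite(coords$z)))
    stop("non-finite coordinates present")

  # every configuration must carry each scheme landmark exactly once
  key <- interaction(coords$specimen, coords$observer, coords$trial,
                     drop = TRUE)
  for (k in levels(key)) {
    lm <- coords$landmark[key == k]
    absent <- setdiff(scheme$id, lm)
    if (length(absent))
      stop("configuration ", k, " is missing landmark id(s): ",
           paste(sort(absent), collapse = ", "))
    if (anyDuplicated(lm))
      stop("configuration ", k, " has duplicated landmark id(s)")
  }

  # one age per specimen
  sp_age <- unique(coords[c("specimen", "age")])
  if (anyDuplicated(sp_age$specimen))
    stop("specimen(s) assigned to more than one age")

  # balance: every (specimen, observer, trial) cell present
  observers <- sort(unique(coords$observer))
  trials <- sort(unique(coords$trial))
  cells <- unique(coords[c("specimen", "observer", "trial")])
  want <- expand.grid(specimen = sp_age$specimen, observer = observers,
                      trial = trials, stringsAsFactors = FALSE)
  got <- paste(cells$specimen, cells$observer, cells$trial)
  missing_cells <- want[!(paste(want$specimen, want$observer, want$trial)
                          %in% got), ]
  if (nrow(missing_cells))
    stop("unbalanced design; missing (specimen, observer, trial) cells: ",
         paste(paste(missing_cells$specimen, missing_cells$observer,
                     missing_cells$trial, sep = "/"),
               collapse = ", "))

  ord <- order(match(coords$age, embryo_ages()), coords$specimen,
               coords$observer, coords$trial,
               match(coords$landmark, scheme$id))
  coords <- coords[ord, ]
  rownames(coords) <- NULL

  n_spec <- vapply(embryo_ages(), function(a)
    length(unique(coords$specimen[coords$age == a])), integer(1))
  structure(list(coords = coords, scheme = scheme,
                 design = list(n_specimens = n_spec,
                               n_observers = length(observers),
                               n_trials = length(trials),
                               observers = observers, trials = trials)),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- x$design
  cat("Trial dataset:", sum(d$n_specimens), "specimens (",
      paste(d$n_specimens, collapse = "/"), "at",
      paste(embryo_ages(), collapse = "/"), "),",
      d$n_observers, "observers x", d$n_trials, "trials,",
      nrow(x$scheme), "landmarks\n")
  invisible(x)
}

# Internal: one configuration as a k x 3 matrix, rows in scheme order.
config_matrix <- function(dataset, specimen, observer, trial) {
  cc <- dataset$coords
  sel <- cc$specimen == specimen & cc$observer == observer & cc$trial == trial
  m <- as.matrix(cc[sel, c("x", "y", "z")])
  rownames(m) <- cc$landmark[sel]
  m
}

#' Per-specimen mean configurations
#'
#' Averages each selected observer's two (or more) trials into an observer
#' mean, then averages those observer means into one configuration per
#' specimen.  These per-specimen means are the shapes that enter the
#' ontogenetic (allometric) analysis.
#'
#' @param dataset A `trial_dataset`.
#' @param observers Character vector of observers to include (default: all).
#' @return A list with `shapes` (list of k x 3 matrices, one per specimen,
#'   rows in scheme order), `specimen`, and `age` vectors.
#' @export
specimen_mean_shapes <- function(dataset, observers = NULL) {
  cc <- dataset$coords
  if (is.null(observers)) observers <- dataset$design$observers
  bad <- setdiff(observers, dataset$design$observers)
  if (length(bad)) stop("unknown observer(s): ", paste(bad, collapse = ", "))
  cc <- cc[cc$observer %in% observers, ]

  sp_age <- unique(cc[c("specimen", "age")])
  sp_age <- sp_age[order(match(sp_age$age, embryo_ages()), sp_age$specimen), ]
  ids <- dataset$scheme$id
  shapes <- lapply(sp_age$specimen, function(sp) {
    sub <- cc[cc$specimen == sp, ]
    # observer trial means, then mean of observer means
    g1 <- paste(sub$observer, sub$landmark)
    om <- rowsum(as.matrix(sub[c("x", "y", "z")]), g1)
    om <- om / as.vector(table(g1)[rownames(om)])
    lm_of <- sub("^\\S+ ", "", rownames(om))
    m <- rowsum(om, lm_of)
    m <- m / as.vector(table(lm_of)[rownames(m)])
    m <- m[match(as.character(ids), rownames(m)), , drop = FALSE]
    rownames(m) <- ids
    m
  })
  names(shapes) <- sp_age$specimen
  list(shapes = shapes, specimen = sp_age$specimen, age = sp_age$age)
}
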