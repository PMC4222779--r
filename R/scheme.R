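#' Embryonic ages covered by the landmark scheme
#'
#' The three embryonic-day categories the landmark set is defined for.
#' Ages are categorical labels; no fractional-day arithmetic is performed
#' anywhere in the package.
#'
#' @return Character vector `c("E10.5", "E11.5", "E12.5")`.
#' @export
embryo_ages <- function() c("E10.5", "E11.5", "E12.5")

# Internal: raw scheme table in canonical listing order (left before right).
# Bilateral pairs are (n, n + 17); ids 19 and 36 are deliberately absent.
.scheme_rows <- function() {
  mk <- function(id, name, side, pair, subset, trouble) {
    data.frame(id = id, name = name, side = side,
               pair_id = if (is.null(pair)) NA_integer_ else pair,
               subset = subset, trouble = trouble,
               stringsAsFactors = FALSE)
  }
  pair <- function(id, name, subset, trouble = FALSE) {
    rbind(mk(id, name, "left", id + 17L, subset, trouble),
          mk(id + 17L, name, "right", id, subset, trouble))
  }
  rbind(
    mk(1L,  "forebrain-midbrain dorsal midline point", "midline", NULL, "NonFacial", FALSE),
    mk(2L,  "dorso-rostral midline extent of forebrain", "midline", NULL, "NonFacial", TRUE),
    mk(3L,  "midline dorsal-most extent of face", "midline", NULL, "Nasal", FALSE),
    mk(4L,  "midline rostral-most extent of medial nasal processes", "midline", NULL, "Nasal", FALSE),
    mk(5L,  "ventral midline point on primary palate", "midline", NULL, "Nasal", FALSE),
    pair(6L,  "medial nasal process / forebrain border", "Nasal"),
    pair(7L,  "dorsal extent of rostral lateral nasal process", "Nasal", TRUE),
    pair(8L,  "dorso-caudal-most point of lateral nasal process", "NonFacial"),
    pair(9L,  "caudal lateral nasal / maxillary intersection (nasolacrimal)", "Nasal"),
    pair(10L, "caudo-lateral projection of dorsal maxillary edge", "MaxMand", TRUE),
    pair(11L, "nasal aperture lateral nasal / maxillary intersection", "MaxMand"),
    pair(12L, "rostro-ventral medial nasal / maxillary intersection", "Nasal"),
    pair(13L, "rostro-caudal-most extension of lateral nasal prominence", "Nasal", TRUE),
    pair(14L, "middle of medial side of nasal aperture", "Nasal"),
    pair(15L, "dorsal-most point of nasal aperture", "Nasal"),
    pair(16L, "corner of developing mouth", "MaxMand"),
    pair(17L, "lateral extent of center of maxillary process", "MaxMand", TRUE),
    pair(18L, "trigeminal ganglion / pontine flexure intersection", "NonFacial", TRUE),
    pair(20L, "medial rostral dorsal corner of mandibular process", "MaxMand"),
    pair(21L, "ventral caudal-most point of forebrain bulge", "NonFacial", TRUE),
    mk(22L, "caudal-most midline point on back of head", "midline", NULL, "NonFacial", FALSE)
  )
}

#' The standard 36-landmark embryonic craniofacial scheme
#'
#' Returns the canonical catalogue of 36 ectodermal surface landmarks for
#' E10.5--E12.5 mouse embryo heads: 6 midline landmarks and 15 bilateral
#' pairs.  Landmark ids run 1--38 with ids 19 and 36 unused (the gap is
#' preserved without interpretation).  Each landmark carries an anatomical
#' subset (`"Nasal"`, `"MaxMand"`, `"NonFacial"`) and a trouble flag marking
#' points with known elevated placement error.
#'
#' @return An object of class `landmark_scheme`: a data frame with columns
#'   `id`, `name`, `side` (`"midline"`, `"left"`, `"right"`), `pair_id`
#'   (contralateral id, `NA` for midline), `subset`, and `trouble`, in the
#'   canonical listing order (left before right within each pair).
#' @examples
#' sch <- builtin_scheme()
#' nrow(sch)                      # 36
#' subset(sch, id == 9)$pair_id   # 26
#' @export
builtin_scheme <- function() {
  sch <- .scheme_rows()
  class(sch) <- c("landmark_scheme", "data.frame")
  sch
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", nrow(x), "landmarks (",
      sum(x$side == "midline"), "midline,",
      sum(x$side != "midline") / 2, "bilateral pairs )\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Pooled label for a landmark
#'
#' Bilateral landmarks are conventionally reported under a joint
#' `"low/high"` label (e.g. landmark 7 and its contralateral partner 24 are
#' reported as `"7/24"`); midline landmarks keep their plain id.
#'
#' @param id Integer vector of landmark ids.
#' @param scheme A `landmark_scheme`.
#' @return Character vector of labels.
#' @export
landmark_label <- function(id, scheme = builtin_scheme()) {
  idx <- match(id, scheme$id)
  if (anyNA(idx)) stop("unknown landmark id(s): ",
                       paste(id[is.na(idx)], collapse = ", "))
  pid <- scheme$pair_id[idx]
  ifelse(is.na(pid), as.character(id),
         paste0(pmin(id, pid), "/", pmax(id, pid)))
}

#' Landmark ids belonging to a Table-defined subset
#'
#' @param subset One of `"Nasal"`, `"MaxMand"`, `"NonFacial"`, or
#'   `"Trouble"` (the trouble-flag column).
#' @param scheme A `landmark_scheme`.
#' @return Integer vector of landmark ids.
#' @export
subset_ids <- function(subset = c("Nasal", "MaxMand", "NonFacial", "Trouble"),
                       scheme = builtin_scheme()) {
  subset <- match.arg(subset)
  if (subset == "Trouble") scheme$id[scheme$trouble]
  else scheme$id[scheme$subset == subset]
}

#' Landmarks recommended for removal from the standard set
#'
#' The five landmarks (pooled labels) whose intra- or inter-observer error is
#' high enough, across ages, that removal from the standard set is
#' recommended rather than a clarified definition.  Note this is a strict
#' subset of the scheme's trouble column, which additionally flags 10/27 and
#' 13/30 (whose definitions are considered clarifiable).
#'
#' @param as Return `"labels"` (pooled, default) or `"ids"`.
#' @return Character vector of pooled labels, or integer ids.
#' @export
suggested_removals <- function(as = c("labels", "ids")) {
  as <- match.arg(as)
  if (as == "labels") c("2", "7/24", "17/34", "18/35", "21/38")
  else c(2L, 7L, 24L, 17L, 34L, 18L, 35L, 21L, 38L)
}

#' Export a landmark scheme as JSON
#'
#' @param scheme A `landmark_scheme`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to file.
#' @export
scheme_to_json <- function(scheme = builtin_scheme(), path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(scheme), dataframe = "rows",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# Internal: validate structural invariants of a scheme.
validate_scheme <- function(scheme) {
  stopifnot(nrow(scheme) == 36L,
            !any(c(19L, 36L) %in% scheme$id),
            !anyDuplicated(scheme$id))
  mid <- scheme$side == "midline"
  stopifnot(sum(mid) == 6L, all(is.na(scheme$pair_id[mid])))
  bil <- scheme[!mid, ]
  stopifnot(all(scheme$pair_id[match(bil$pair_id, scheme$id)] == bil$id))
  invisible(TRUE)
}
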