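#' The canonical 41-point palatal template schema
#'
#' Returns the landmark schema used throughout the package: 5 fixed anatomical
#' landmarks, 12 curve semilandmarks (left/right alveolar curves and the median
#' palatine suture) and 24 surface semilandmarks (12 per hemi-palate), with the
#' bilateral pairing map that makes reflection/relabelling well defined.
#'
#' Landmark ids are 1-based and fixed: 1 Incisor, 2/3 Ento-left/right,
#' 4 Post-foramen, 5 Middle; 6-9 curve semilandmarks left, 10-13 right;
#' 14-25 surface semilandmarks right, 26-37 left; 38-41 curve semilandmarks
#' on the median suture. Midline points (1, 4, 5, 38-41) pair with themselves;
#' the remaining 34 points pair across the midsagittal plane (2-3, 6-9 with
#' 10-13 in order, 14-25 with 26-37 in order).
#'
#' @return An object of class \code{asym_schema}: a data frame with columns
#'   \code{id}, \code{name}, \code{role} (fixed/curve/surface), \code{side}
#'   (left/right/midline), \code{pair_id} and \code{curve_id}, plus attribute
#'   \code{midplane_ids} giving the ordered midline landmark ids.
#' @export
#' @examples
#' sch <- palate_schema()
#' table(sch$role)
#' sch$pair_id[2:3]   # Ento-left <-> Ento-right
palate_schema <- function() {
  path <- system.file("extdata", "palate_schema.json", package = "palatasym")
  if (nzchar(path) && file.exists(path)) {
    return(read_schema_json(path))
  }
  build_palate_schema()
}

# Construct the canonical schema in code (also used to generate the shipped
# JSON resource).
build_palate_schema <- function() {
  df <- data.frame(
    id = 1:41,
    name = c(
      "Incisor", "Ento-left", "Ento-right", "Post-foramen", "Middle",
      rep("Curve sml left", 4), rep("Curve sml right", 4),
      rep("Surface sml right", 12), rep("Surface sml left", 12),
      rep("Curve sml middle", 4)
    ),
    role = c(rep("fixed", 5), rep("curve", 8), rep("surface", 24),
             rep("curve", 4)),
    side = c("midline", "left", "right", "midline", "midline",
             rep("left", 4), rep("right", 4),
             rep("right", 12), rep("left", 12),
             rep("midline", 4)),
    pair_id = c(1L, 3L, 2L, 4L, 5L,
                10:13, 6:9,
                26:37, 14:25,
                38:41),
    curve_id = c(rep(NA_character_, 5),
                 rep("curve_left", 4), rep("curve_right", 4),
                 rep(NA_character_, 24),
                 rep("curve_middle", 4)),
    stringsAsFactors = FALSE
  )
  attr(df, "midplane_ids") <- c(1L, 4L, 5L, 38L, 39L, 40L, 41L)
  # anchoring of curves to fixed endpoints (configurable interpretation)
  attr(df, "curve_anchors") <- list(
    curve_left = c(1L, 2L), curve_right = c(1L, 3L), curve_middle = c(4L, 5L)
  )
  class(df) <- c("asym_schema", "data.frame")
  validate_schema(df)
  df
}

read_schema_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  df <- as.data.frame(obj$points, stringsAsFactors = FALSE)
  df$id <- as.integer(df$id)
  df$pair_id <- as.integer(df$pair_id)
  df$curve_id[is.na(df$curve_id) | df$curve_id == ""] <- NA_character_
  attr(df, "midplane_ids") <- as.integer(obj$midplane_ids)
  if (!is.null(obj$curve_anchors)) {
    attr(df, "curve_anchors") <- lapply(obj$curve_anchors, as.integer)
  }
  class(df) <- c("asym_schema", "data.frame")
  validate_schema(df)
  df
}

write_schema_json <- function(schema, path) {
  obj <- list(
    points = as.data.frame(unclass(schema), stringsAsFactors = FALSE),
    midplane_ids = attr(schema, "midplane_ids"),
    curve_anchors = attr(schema, "curve_anchors")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Validate a landmark schema
#'
#' Enforces the structural invariants any user-supplied schema must satisfy:
#' unique ids, the pairing map is an involution whose fixed points are exactly
#' the midline landmarks, paired points carry mirrored sides and matching
#' roles/curve membership.
#'
#' @param schema an \code{asym_schema} (or conforming data frame).
#' @return The schema, invisibly; stops on any violation.
#' @export
validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema))
  req <- c("id", "name", "role", "side", "pair_id")
  if (!all(req %in% names(schema)))
    stop("schema must have columns: ", paste(req, collapse = ", "))
  n <- nrow(schema)
  if (anyDuplicated(schema$id)) stop("schema ids must be unique")
  if (!all(schema$role %in% c("fixed", "curve", "surface")))
    stop("schema roles must be fixed/curve/surface")
  if (!all(schema$side %in% c("left", "right", "midline")))
    stop("schema sides must be left/right/midline")
  idx <- match(schema$pair_id, schema$id)
  if (anyNA(idx)) stop("pair_id refers to unknown landmark id")
  # involution
  if (!all(schema$pair_id[idx] == schema$id))
    stop("pairing map is not an involution")
  mid <- schema$side == "midline"
  if (!all((schema$pair_id == schema$id) == mid))
    stop("midline landmarks (and only those) must be self-paired")
  # mirrored sides and matching roles
  opp <- c(left = "right", right = "left", midline = "midline")
  if (!all(schema$side[idx] == unname(opp[schema$side])))
    stop("paired landmarks must lie on opposite sides")
  if (!all(schema$role[idx] == schema$role))
    stop("paired landmarks must share a role")
  if ("curve_id" %in% names(schema)) {
    a <- schema$curve_id; b <- schema$curve_id[idx]
    both <- !is.na(a) & !is.na(b) & !mid
    # left curve pairs with right curve: membership must map consistently
    if (any(both) && any(a[both] == b[both]))
      stop("paired curve semilandmarks must belong to mirrored curves")
  }
  invisible(schema)
}

#' Construct a single landmark configuration
#'
#' @param coordinates numeric 41 x 3 matrix (or p x 3 for a custom schema),
#'   in mm for raw digitized data.
#' @param individual_id specimen identifier.
#' @param age_group age-group label (the study uses Roman numerals I-VI).
#' @param sex \code{"M"}, \code{"F"} or \code{"ND"}.
#' @param collection provenance label of the skeletal collection.
#' @param is_reflected_copy whether this configuration is a reflected and
#'   relabelled copy of an original.
#' @return An object of class \code{landmark_config}.
#' @export
landmark_config <- function(coordinates, individual_id,
                            age_group = NA_character_, sex = NA_character_,
                            collection = NA_character_,
                            is_reflected_copy = FALSE) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  structure(list(
    individual_id = as.character(individual_id),
    coordinates = coordinates,
    age_group = as.character(age_group),
    sex = as.character(sex),
    collection = as.character(collection),
    is_reflected_copy = isTRUE(is_reflected_copy)
  ), class = "landmark_config")
}

#' Validate a configuration against a schema
#'
#' Report-based validation: returns a character vector of violations,
#' empty when the configuration conforms.
#'
#' @param config a \code{landmark_config}.
#' @param schema an \code{asym_schema}.
#' @return character vector of violation messages (length 0 if valid).
#' @export
validate_configuration <- function(config, schema = palate_schema()) {
  out <- character(0)
  x <- config$coordinates
  if (!is.matrix(x) || ncol(x) != 3)
    out <- c(out, "coordinates must be a p x 3 matrix")
  if (is.matrix(x) && nrow(x) != nrow(schema))
    out <- c(out, sprintf("size mismatch: %d rows, schema has %d points",
                          nrow(x), nrow(schema)))
  if (is.matrix(x) && !all(is.finite(x)))
    out <- c(out, "non-finite coordinate values present")
  if (is.matrix(x) && ncol(x) == 3 && all(is.finite(x))) {
    cs <- tryCatch(centroid_size(x), error = function(e) 0)
    if (!isTRUE(cs > 0))
      out <- c(out, "zero centroid size (degenerate configuration)")
  }
  out
}

#' Assemble a population dataset
#'
#' Bundles configurations that share a schema into the array-based container
#' used by all downstream stages: a p x 3 x n coordinate array plus a
#' per-specimen metadata table.
#'
#' @param configurations list of \code{landmark_config} objects.
#' @param schema shared \code{asym_schema}.
#' @param provenance free-form list (e.g. source file, simulation ground truth).
#' @return An object of class \code{landmark_dataset} with elements
#'   \code{schema}, \code{coords} (p x 3 x n array), \code{info}
#'   (data frame with individual_id, age_group, sex, collection,
#'   is_reflected_copy) and \code{provenance}.
#' @export
landmark_dataset <- function(configurations, schema = palate_schema(),
                             provenance = list()) {
  bad <- lapply(configurations, validate_configuration, schema = schema)
  nb <- vapply(bad, length, 1L)
  if (any(nb > 0))
    stop("invalid configuration(s): ",
         paste(unique(unlist(bad)), collapse = "; "))
  info <- data.frame(
    individual_id = vapply(configurations, `[[`, "", "individual_id"),
    age_group = vapply(configurations, `[[`, "", "age_group"),
    sex = vapply(configurations, `[[`, "", "sex"),
    collection = vapply(configurations, `[[`, "", "collection"),
    is_reflected_copy = vapply(configurations, `[[`, TRUE, "is_reflected_copy"),
    stringsAsFactors = FALSE
  )
  orig <- info$individual_id[!info$is_reflected_copy]
  if (anyDuplicated(orig))
    stop("duplicate individual_id among original configurations")
  p <- nrow(schema)
  coords <- array(NA_real_, c(p, 3, nrow(info)),
                  dimnames = list(schema$id, c("x", "y", "z"),
                                  make.unique(info$individual_id)))
  for (i in seq_along(configurations))
    coords[, , i] <- configurations[[i]]$coordinates
  structure(list(schema = schema, coords = coords, info = info,
                 provenance = provenance),
            class = "landmark_dataset")
}

# Internal fast constructor from an array + info table (skips re-validation
# of every slice; used by simulators and IO).
dataset_from_array <- function(coords, info, schema = palate_schema(),
                               provenance = list()) {
  stopifnot(dim(coords)[1] == nrow(schema), dim(coords)[2] == 3,
            dim(coords)[3] == nrow(info))
  dimnames(coords) <- list(schema$id, c("x", "y", "z"),
                           make.unique(as.character(info$individual_id)))
  structure(list(schema = schema, coords = coords, info = info,
                 provenance = provenance),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  n <- dim(x$coords)[3]
  cat(sprintf("Landmark dataset: %d configurations x %d landmarks (3D)\n",
              n, dim(x$coords)[1]))
  nr <- sum(x$info$is_reflected_copy)
  if (nr > 0) cat(sprintf("  %d originals + %d reflected copies\n", n - nr, nr))
  if (!all(is.na(x$info$age_group)))
    cat("  groups:", paste(names(table(x$info$age_group)), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.asym_schema <- function(x, ...) {
  cat(sprintf("Landmark schema: %d points (%d fixed, %d curve, %d surface)\n",
              nrow(x), sum(x$role == "fixed"), sum(x$role == "curve"),
              sum(x$role == "surface")))
  cat("  midline ids:", paste(attr(x, "midplane_ids"), collapse = " "), "\n")
  invisible(x)
}

# number of configurations helper
n_configs <- function(dataset) dim(dataset$coords)[3]
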