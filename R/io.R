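# Readers and writers for landmark interchange formats, triangle meshes and
# result tables. All coordinates are in mm on disk; no unit conversion is
# ever applied implicitly.

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Read a landmark file
#'
#' Supported dialects: \code{csv} (long format, one row per landmark with
#' columns individual_id, landmark_id, x, y, z and optional age_group, sex,
#' collection), \code{tps} (LM3=/LM= blocks with ID= lines), and
#' \code{morphologika} ([individuals]/[landmarks]/[dimensions]/[names]/
#' [labels]/[rawpoints] sections).
#'
#' @param path file path.
#' @param format one of \code{"csv"}, \code{"tps"}, \code{"morphologika"}.
#' @param schema schema the configurations must conform to.
#' @return a \code{landmark_dataset}.
#' @export
read_landmarks <- function(path, format = c("csv", "tps", "morphologika"),
                           schema = palate_schema()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         csv = read_landmarks_csv(path, schema),
         tps = read_landmarks_tps(path, schema),
         morphologika = read_landmarks_morphologika(path, schema))
}

read_landmarks_csv <- function(path, schema) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "landmark_id", "x", "y", "z")
  if (!all(req %in% names(df)))
    stop("CSV landmark file must have columns: ", paste(req, collapse = ", "))
  p <- nrow(schema)
  ids <- unique(df$individual_id)
  configs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- df[df$individual_id == ids[i], , drop = FALSE]
    if (nrow(sub) != p)
      stop(sprintf("specimen '%s' has %d landmark rows, expected %d",
                   ids[i], nrow(sub), p))
    sub <- sub[order(sub$landmark_id), , drop = FALSE]
    if (!all(sub$landmark_id == schema$id))
      stop(sprintf("specimen '%s': landmark ids do not match the schema",
                   ids[i]))
    co <- as.matrix(sub[, c("x", "y", "z")])
    if (any(!is.finite(co)))
      stop(sprintf("specimen '%s': non-finite coordinates", ids[i]))
    meta <- function(col) if (col %in% names(sub)) sub[[col]][1] else NA
    configs[[i]] <- landmark_config(
      co, ids[i], age_group = meta("age_group"), sex = meta("sex"),
      collection = meta("collection"),
      is_reflected_copy = isTRUE(as.logical(meta("is_reflected_copy"))))
  }
  landmark_dataset(configs, schema, provenance = list(source = path))
}

read_landmarks_tps <- function(path, schema) {
  lines <- readLines(path)
  p <- nrow(schema)
  configs <- list()
  i <- 1; spec_no <- 0
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1; next }
    m <- regmatches(ln, regexec("^LM3?=(\\d+)$", ln))[[1]]
    if (length(m) == 0)
      stop("TPS parse error at line ", i, ": expected LM=/LM3= record")
    nl <- as.integer(m[2]); spec_no <- spec_no + 1
    if (nl != p)
      stop(sprintf("TPS specimen %d declares %d landmarks, expected %d",
                   spec_no, nl, p))
    if (i + nl > length(lines))
      stop("TPS file truncated in specimen ", spec_no)
    block <- lines[(i + 1):(i + nl)]
    co <- t(vapply(strsplit(trimws(block), "\\s+"), function(v) {
      if (length(v) != 3) stop("TPS specimen ", spec_no,
                               ": coordinate line is not 3D")
      as.numeric(v)
    }, numeric(3)))
    if (any(!is.finite(co)))
      stop("TPS specimen ", spec_no, ": malformed coordinates")
    i <- i + nl + 1
    id <- sprintf("specimen_%d", spec_no)
    while (i <= length(lines) && grepl("^(ID|IMAGE|SCALE)=",
                                       trimws(lines[i]))) {
      kv <- trimws(lines[i])
      if (grepl("^ID=", kv)) id <- sub("^ID=", "", kv)
      i <- i + 1
    }
    configs[[spec_no]] <- landmark_config(co, id)
  }
  if (length(configs) == 0) stop("TPS file contains no specimens")
  landmark_dataset(configs, schema, provenance = list(source = path))
}

read_landmarks_morphologika <- function(path, schema) {
  lines <- readLines(path)
  p <- nrow(schema)
  sec <- function(name) {
    hit <- grep(paste0("^\\[", name, "\\]$"), trimws(lines), ignore.case = TRUE)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  n <- as.integer(trimws(lines[sec("individuals") + 1]))
  nl <- as.integer(trimws(lines[sec("landmarks") + 1]))
  nd <- as.integer(trimws(lines[sec("dimensions") + 1]))
  if (is.na(n) || is.na(nl)) stop("morphologika header incomplete")
  if (!is.na(nd) && nd != 3) stop("unsupported dimension: ", nd)
  if (nl != p) stop(sprintf("file declares %d landmarks, expected %d", nl, p))
  names_at <- sec("names")
  ids <- if (!is.na(names_at)) trimws(lines[(names_at + 1):(names_at + n)])
         else sprintf("specimen_%d", seq_len(n))
  labels <- NULL
  lab_at <- sec("labels"); labval_at <- sec("labelvalues")
  if (!is.na(lab_at) && !is.na(labval_at)) {
    lab_names <- strsplit(trimws(lines[lab_at + 1]), "\\s+")[[1]]
    vals <- lapply((labval_at + 1):(labval_at + n), function(j)
      strsplit(trimws(lines[j]), "\\s+")[[1]])
    labels <- do.call(rbind, lapply(vals, function(v) {
      if (length(v) != length(lab_names))
        stop("morphologika labelvalues row malformed")
      stats::setNames(as.list(v), lab_names)
    }))
  }
  raw_at <- sec("rawpoints")
  if (is.na(raw_at)) stop("morphologika file lacks [rawpoints]")
  body <- lines[(raw_at + 1):length(lines)]
  body <- body[trimws(body) != ""]
  configs <- vector("list", n)
  j <- 1
  for (i in seq_len(n)) {
    if (j > length(body) || !grepl("^'", trimws(body[j])))
      stop("morphologika rawpoints truncated at specimen ", i)
    j <- j + 1
    if (j + nl - 1 > length(body))
      stop("morphologika rawpoints truncated at specimen ", i)
    co <- t(vapply(strsplit(trimws(body[j:(j + nl - 1)]), "\\s+"),
                   function(v) as.numeric(v[1:3]), numeric(3)))
    if (any(!is.finite(co)))
      stop("morphologika specimen ", i, ": malformed coordinates")
    j <- j + nl
    get_lab <- function(col) {
      if (!is.null(labels) && col %in% colnames(labels))
        as.character(labels[i, col][[1]]) else NA_character_
    }
    configs[[i]] <- landmark_config(
      co, ids[i], age_group = get_lab("age_group"), sex = get_lab("sex"),
      collection = get_lab("collection"))
  }
  landmark_dataset(configs, schema, provenance = list(source = path))
}

#' Write a landmark file
#'
#' Inverse of \code{read_landmarks()}; round trips are lossless to well below
#' 1e-9 mm and deterministic (writing the re-read dataset reproduces the file
#' byte for byte).
#'
#' @param dataset a \code{landmark_dataset}.
#' @param path output path.
#' @param format one of \code{"csv"}, \code{"tps"}, \code{"morphologika"}.
#' @return the path, invisibly.
#' @export
write_landmarks <- function(dataset, path,
                            format = c("csv", "tps", "morphologika")) {
  format <- match.arg(format)
  n <- dim(dataset$coords)[3]
  info <- dataset$info
  schema <- dataset$schema
  p <- nrow(schema)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "csv") {
    writeLines(paste("individual_id", "landmark_id", "x", "y", "z",
                     "age_group", "sex", "collection", "is_reflected_copy",
                     sep = ","), con)
    for (i in seq_len(n)) {
      co <- dataset$coords[, , i]
      writeLines(paste(info$individual_id[i], schema$id,
                       fmt_num(co[, 1]), fmt_num(co[, 2]), fmt_num(co[, 3]),
                       info$age_group[i], info$sex[i], info$collection[i],
                       info$is_reflected_copy[i], sep = ","), con)
    }
  } else if (format == "tps") {
    for (i in seq_len(n)) {
      co <- dataset$coords[, , i]
      writeLines(sprintf("LM3=%d", p), con)
      writeLines(paste(fmt_num(co[, 1]), fmt_num(co[, 2]), fmt_num(co[, 3])),
                 con)
      writeLines(paste0("ID=", info$individual_id[i]), con)
    }
  } else {
    writeLines(c("[individuals]", as.character(n), "[landmarks]",
                 as.character(p), "[dimensions]", "3", "[names]",
                 if (n > 0) info$individual_id else character(0),
                 "[labels]", "age_group sex collection", "[labelvalues]",
                 if (n > 0) paste(info$age_group, info$sex, info$collection)
                 else character(0),
                 "[rawpoints]"), con)
    for (i in seq_len(n)) {
      co <- dataset$coords[, , i]
      writeLines(paste0("'", info$individual_id[i]), con)
      writeLines(paste(fmt_num(co[, 1]), fmt_num(co[, 2]), fmt_num(co[, 3])),
                 con)
    }
  }
  invisible(path)
}

#' Read surface and curve geometry
#'
#' Meshes are read from ASCII PLY, OBJ or STL (by file extension) and must be
#' triangulated; curves from CSV polylines with columns x, y, z in order.
#'
#' @param mesh_path path to a mesh file, or \code{NULL}.
#' @param curve_paths named list/vector of CSV polyline paths (names become
#'   curve ids).
#' @return a validated \code{geometry_bundle}.
#' @export
read_geometry <- function(mesh_path = NULL, curve_paths = list()) {
  surface <- NULL
  if (!is.null(mesh_path)) {
    ext <- tolower(tools::file_ext(mesh_path))
    surface <- switch(ext,
                      ply = read_ply(mesh_path),
                      obj = read_obj(mesh_path),
                      stl = read_stl_ascii(mesh_path),
                      stop("unsupported mesh format: .", ext))
  }
  curves <- lapply(curve_paths, function(pth) {
    df <- utils::read.csv(pth, stringsAsFactors = FALSE)
    if (!all(c("x", "y", "z") %in% names(df)))
      stop("curve CSV must have columns x, y, z: ", pth)
    if (nrow(df) < 2) stop("empty or single-point curve: ", pth)
    as.matrix(df[, c("x", "y", "z")])
  })
  geometry_bundle(surface = surface, curves = curves)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "ply") stop("not a PLY file: ", path)
  if (!any(grepl("format\\s+ascii", lines[1:10])))
    stop("only ASCII PLY is supported")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", lines[1:hdr_end], value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", lines[1:hdr_end], value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY header incomplete")
  vl <- lines[(hdr_end + 1):(hdr_end + nv)]
  v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(x) as.numeric(x[1:3]), numeric(3)))
  fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  f <- t(vapply(strsplit(trimws(fl), "\\s+"), function(x) {
    k <- as.integer(x[1])
    if (k != 3) stop("non-triangulated PLY face (", k, " vertices)")
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  list(vertices = v, faces = f)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0) stop("OBJ file lacks v/f records")
  v <- t(vapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                function(x) as.numeric(x[x != ""][1:3]), numeric(3)))
  f <- t(vapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    x <- x[x != ""]
    if (length(x) != 3) stop("non-triangulated OBJ face")
    as.integer(sub("/.*$", "", x))
  }, integer(3)))
  list(vertices = v, faces = f)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path)
  if (!grepl("^\\s*solid", lines[1])) stop("only ASCII STL is supported")
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed STL: vertex count not a multiple of 3")
  pts <- t(vapply(strsplit(trimws(sub("^\\s*vertex", "", vl)), "\\s+"),
                  function(x) as.numeric(x[x != ""][1:3]), numeric(3)))
  # merge duplicate vertices
  key <- apply(pts, 1, function(r) paste(fmt_num(r), collapse = "_"))
  uk <- !duplicated(key)
  v <- pts[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = v, faces = f)
}

#' Write an ASCII PLY mesh
#'
#' @param surface mesh list (vertices, faces).
#' @param path output path.
#' @export
write_ply <- function(surface, path) {
  v <- surface$vertices; f <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
  writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Deterministic tab-separated output (no quoting, no row names, fixed
#' column order) used for all pipeline tables.
#'
#' @param rows a data frame.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  num <- vapply(rows, is.numeric, TRUE)
  out <- rows
  for (j in which(num)) out[[j]] <- fmt_num(rows[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
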