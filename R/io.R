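# PLY (ascii + binary_little_endian) and PCD (ascii) point-cloud I/O.
# Part labels travel as an integer per-vertex property named "part" (PLY),
# a "part" field (PCD), or a sidecar "<file>.labels" text file (one label
# per line, point order). All coordinates are interpreted as cm.

ply_type_info <- function(type) {
  switch(type,
         "char" = , "int8" = list(size = 1L, what = "integer", signed = TRUE),
         "uchar" = , "uint8" = list(size = 1L, what = "integer",
                                    signed = FALSE),
         "short" = , "int16" = list(size = 2L, what = "integer",
                                    signed = TRUE),
         "ushort" = , "uint16" = list(size = 2L, what = "integer",
                                      signed = FALSE),
         "int" = , "int32" = list(size = 4L, what = "integer",
                                  signed = TRUE),
         "uint" = , "uint32" = list(size = 4L, what = "integer",
                                    signed = TRUE),  # R has no uint32
         "float" = , "float32" = list(size = 4L, what = "double",
                                      signed = TRUE),
         "double" = , "float64" = list(size = 8L, what = "double",
                                       signed = TRUE),
         stop("unsupported PLY property type: ", type))
}

#' Read a PLY point cloud
#'
#' Supports ascii and binary_little_endian PLY with a vertex element
#' carrying at least x, y, z; an integer vertex property named `part` is
#' picked up as part labels. List (face) properties after the vertex data
#' are ignored.
#'
#' @param path file path.
#' @return a `point_cloud`, or `labeled_point_cloud` when labels are found.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) stop("malformed PLY: missing 'ply' magic")
  fmt <- NULL
  n_vertex <- NULL
  props <- list()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed PLY: header not terminated")
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (tok[1L] == "end_header") break
    if (tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format: ", fmt)
    } else if (tok[1L] == "element") {
      in_vertex <- tok[2L] == "vertex"
      if (in_vertex) n_vertex <- as.integer(tok[3L])
      else if (is.null(n_vertex))
        stop("malformed PLY: element '", tok[2L],
             "' precedes the vertex element")
    } else if (tok[1L] == "property" && in_vertex) {
      if (tok[2L] == "list")
        stop("malformed PLY: list property in vertex element")
      props[[tok[3L]]] <- tok[2L]
    }
  }
  if (is.null(n_vertex)) stop("malformed PLY: no vertex element")
  if (!all(c("x", "y", "z") %in% names(props)))
    stop("malformed PLY: vertex element lacks x/y/z properties")
  nm <- names(props)
  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < n_vertex)
      stop("malformed PLY: expected ", n_vertex, " vertex records, found ",
           length(txt))
    fields <- strsplit(trimws(txt[seq_len(n_vertex)]), "\\s+")
    bad <- which(lengths(fields) != length(props))
    if (length(bad))
      stop("malformed PLY: vertex record ", bad[1L], " has ",
           lengths(fields)[bad[1L]], " fields, expected ", length(props))
    M <- matrix(as.numeric(unlist(fields)), nrow = n_vertex,
                byrow = TRUE, dimnames = list(NULL, nm))
  } else {
    info <- lapply(unname(props), ply_type_info)
    stride <- sum(vapply(info, `[[`, integer(1L), "size"))
    raw <- readBin(con, "raw", n = n_vertex * stride)
    if (length(raw) < n_vertex * stride)
      stop("malformed PLY: truncated binary vertex data")
    M <- matrix(0, n_vertex, length(props), dimnames = list(NULL, nm))
    offset <- 0L
    for (p in seq_along(info)) {
      sz <- info[[p]]$size
      pick <- as.vector(outer(seq_len(sz),
                              (seq_len(n_vertex) - 1L) * stride + offset,
                              `+`))
      M[, p] <- readBin(raw[pick], info[[p]]$what, n = n_vertex,
                        size = sz, signed = info[[p]]$signed,
                        endian = "little")
      offset <- offset + sz
    }
  }
  cloud <- point_cloud(M[, c("x", "y", "z"), drop = FALSE])
  if ("part" %in% nm)
    cloud <- labeled_point_cloud(cloud, as.integer(M[, "part"]))
  cloud
}

#' Write a PLY point cloud
#'
#' Coordinates are written as doubles (bit-exact round trips in both
#' formats); labels, when present, as a `uchar` vertex property `part`.
#'
#' @param cloud a `point_cloud` or `labeled_point_cloud`.
#' @param path output path.
#' @param format `"ascii"` or `"binary"` (binary_little_endian).
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, format = c("ascii", "binary")) {
  format <- match.arg(format)
  n <- n_points(cloud)
  labeled <- !is.null(cloud$labels)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (format == "ascii") "ascii" else
                     "binary_little_endian"),
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           if (labeled) "property uchar part",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "ascii") {
    rows <- sprintf("%.17g %.17g %.17g", cloud$points[, 1L],
                    cloud$points[, 2L], cloud$points[, 3L])
    if (labeled) rows <- paste(rows, cloud$labels)
    writeLines(rows, con)
  } else {
    for (i in seq_len(n)) {
      writeBin(as.double(cloud$points[i, ]), con, size = 8L,
               endian = "little")
      if (labeled)
        writeBin(as.raw(cloud$labels[i]), con)
    }
  }
  invisible(path)
}

#' Read a PCD point cloud (ascii)
#' @param path file path.
#' @return a `point_cloud` or `labeled_point_cloud` (when a `part` field
#'   is present).
#' @export
read_pcd <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  hval <- function(key) {
    hit <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    strsplit(trimws(hit[1L]), "\\s+")[[1L]][-1L]
  }
  fields <- hval("FIELDS")
  if (is.null(fields)) stop("malformed PCD: missing FIELDS header")
  if (!all(c("x", "y", "z") %in% fields))
    stop("malformed PCD: FIELDS lack x/y/z")
  npts <- as.integer(hval("POINTS")[1L])
  data_line <- grep("^DATA\\b", lines)
  if (length(data_line) == 0L) stop("malformed PCD: missing DATA header")
  mode <- hval("DATA")[1L]
  if (mode != "ascii")
    stop("unsupported PCD DATA mode: ", mode, " (only ascii)")
  body <- lines[-seq_len(data_line[1L])]
  body <- body[nzchar(trimws(body))]
  if (length(body) < npts)
    stop("malformed PCD: expected ", npts, " points, found ", length(body))
  rec <- strsplit(trimws(body[seq_len(npts)]), "\\s+")
  bad <- which(lengths(rec) != length(fields))
  if (length(bad))
    stop("malformed PCD: record ", bad[1L], " has wrong field count")
  M <- matrix(as.numeric(unlist(rec)), nrow = npts, byrow = TRUE,
              dimnames = list(NULL, fields))
  cloud <- point_cloud(M[, c("x", "y", "z"), drop = FALSE])
  if ("part" %in% fields)
    cloud <- labeled_point_cloud(cloud, as.integer(M[, "part"]))
  cloud
}

#' Write a PCD point cloud (ascii)
#' @param cloud a `point_cloud` or `labeled_point_cloud`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pcd <- function(cloud, path) {
  n <- n_points(cloud)
  labeled <- !is.null(cloud$labels)
  fields <- if (labeled) "x y z part" else "x y z"
  k <- if (labeled) 4L else 3L
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", fields),
           paste("SIZE", paste(rep(8L, k), collapse = " ")),
           paste("TYPE", paste(c("F", "F", "F", if (labeled) "I"),
                               collapse = " ")),
           paste("COUNT", paste(rep(1L, k), collapse = " ")),
           sprintf("WIDTH %d", n), "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           sprintf("POINTS %d", n), "DATA ascii")
  rows <- sprintf("%.17g %.17g %.17g", cloud$points[, 1L],
                  cloud$points[, 2L], cloud$points[, 3L])
  if (labeled) rows <- paste(rows, cloud$labels)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a point cloud from PLY or PCD
#'
#' The format is inferred from the extension unless given. A sidecar label
#' file `<path>.labels` (one integer per line, point order) is honoured
#' when the file itself carries no `part` property.
#'
#' @param path file path.
#' @param format `"ply"`, `"pcd"` or `NULL` (infer from extension).
#' @return a `point_cloud` or `labeled_point_cloud`.
#' @export
read_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  cloud <- switch(format,
                  ply = read_ply(path),
                  pcd = read_pcd(path),
                  stop("unsupported cloud format: ", format))
  sidecar <- paste0(path, ".labels")
  if (is.null(cloud$labels) && file.exists(sidecar)) {
    labels <- scan(sidecar, what = integer(), quiet = TRUE)
    cloud <- labeled_point_cloud(cloud, labels)
  }
  cloud
}

#' Write a point cloud to PLY or PCD
#' @param cloud a `point_cloud` or `labeled_point_cloud`.
#' @param path output path (extension selects the format unless given).
#' @param format `"ply"`, `"pcd"` or `NULL`.
#' @param ply_mode `"ascii"` or `"binary"` for PLY output.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = NULL, ply_mode = "ascii") {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
         ply = write_ply(cloud, path, ply_mode),
         pcd = write_pcd(cloud, path),
         stop("unsupported cloud format: ", format))
}

#' Serialize a measurement report to JSON
#'
#' The run configuration is embedded so any artifact can be regenerated
#' from it.
#'
#' @param report a `measurement_report` from [measure_all()].
#' @param path output path; `NULL` returns the JSON string.
#' @param id optional animal identifier stored in the report.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_report <- function(report, path = NULL, id = NULL) {
  payload <- list(id = id,
                  values = as.list(report$values),
                  keypoints = lapply(report$keypoints, as.list),
                  diagnostics = list(
                    repaired = report$diagnostics$repaired,
                    slice_sizes = report$diagnostics$slice_sizes,
                    errors = report$diagnostics$errors),
                  config = unclass(report$config))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Read a serialized measurement report
#' @param path JSON path written by [write_report()].
#' @return a `measurement_report`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  values <- vapply(payload$values, function(v)
    if (is.null(v)) NA_real_ else as.numeric(v), numeric(1L))
  cfg <- do.call(measure_config, payload$config)
  structure(list(values = values,
                 keypoints = lapply(payload$keypoints, unlist),
                 diagnostics = payload$diagnostics,
                 config = cfg, id = payload$id),
            class = "measurement_report")
}

#' One-row CSV form of a measurement report
#' @param report a `measurement_report`.
#' @param id animal identifier.
#' @return data.frame with columns id, WH, HH, BL, TC, AC, CC, repaired.
#' @export
report_row <- function(report, id = NA) {
  cbind(data.frame(id = id),
        as.data.frame(as.list(report$values)),
        data.frame(repaired = isTRUE(report$diagnostics$repaired)))
}
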