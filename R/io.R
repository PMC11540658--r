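#' Read a point cloud from PLY or XYZ
#'
#' Supports ASCII and binary-little-endian PLY (vertex element with
#' `x,y,z` and optional `red,green,blue` as uchar, float or double) and
#' whitespace-delimited XYZ / XYZRGB text. If a sidecar metadata file
#' `<path>.json` exists (written by [write_point_cloud()]), its
#' `is_metric` flag is honored; otherwise the cloud is read as
#' non-metric reconstruction units.
#'
#' @param path file path.
#' @param format `"ply"`, `"xyz"` or `"auto"` (by extension, falling
#'   back to content sniffing).
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "ply") {
      "ply"
    } else if (ext %in% c("xyz", "txt", "pts")) {
      "xyz"
    } else {
      first <- readBin(path, "raw", n = 3L)
      if (identical(rawToChar(first), "ply")) "ply" else "xyz"
    }
  }
  cloud <- switch(format,
    ply = read_ply_points(path),
    xyz = read_xyz_points(path)
  )
  meta <- read_sidecar(path)
  if (!is.null(meta) && isTRUE(meta$is_metric)) {
    attr(cloud, "is_metric") <- TRUE
  }
  cloud
}

#' Write a point cloud to PLY or XYZ
#'
#' Round-trips losslessly through [read_point_cloud()]: PLY coordinates
#' (and colors) are stored as doubles, XYZ text uses 17 significant
#' digits. A sidecar `<path>.json` records `is_metric` (and the scale
#' factor, if the cloud carries one) so metric status survives the
#' round-trip.
#'
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @param format `"ply"` or `"xyz"` (default from extension, else ply).
#' @param binary for PLY, write binary little-endian (default) or ASCII.
#' @param sidecar write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = NULL, binary = TRUE,
                              sidecar = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz") "xyz" else "ply"
  }
  format <- match.arg(format, c("ply", "xyz"))
  switch(format,
    ply = write_ply_points(cloud, path, binary = binary),
    xyz = write_xyz_points(cloud, path)
  )
  if (sidecar) {
    meta <- list(is_metric = is_metric(cloud))
    sf <- attr(cloud, "scale_factor")
    if (!is.null(sf)) meta$scale_factor <- sf
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) return(NULL)
  tryCatch(jsonlite::read_json(sc), error = function(e) NULL)
}

# ---- PLY ------------------------------------------------------------------

ply_type_size <- c(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

read_ply_header <- function(con) {
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) stop("malformed PLY header: missing 'ply' magic")
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) stop("malformed PLY header: no end_header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(0), types = character(0),
                  list_types = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("malformed PLY header: property before element")
      if (tok[2] == "list") {
        cur$props <- c(cur$props, tok[5])
        cur$types <- c(cur$types, "list")
        cur$list_types[[tok[5]]] <- c(count = tok[3], item = tok[4])
      } else {
        cur$props <- c(cur$props, tok[3])
        cur$types <- c(cur$types, tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop("malformed PLY header: unrecognized line '", line, "'")
    }
  }
  if (is.null(fmt)) stop("malformed PLY header: no format line")
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt)
  }
  list(format = fmt, elements = elements)
}

read_ply_points <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_ply_header(con)
  if (!"vertex" %in% names(hdr$elements)) {
    stop("PLY file has no vertex element: ", path)
  }
  vert <- hdr$elements$vertex
  if (!all(c("x", "y", "z") %in% vert$props)) {
    stop("PLY vertex element lacks x/y/z properties")
  }
  if (any(vert$types == "list")) stop("list properties on vertices unsupported")
  pre <- names(hdr$elements)[seq_len(match("vertex", names(hdr$elements)) - 1L)]
  if (length(pre) > 0) stop("PLY elements before vertex are unsupported")

  n <- vert$count
  vals <- if (hdr$format == "ascii") {
    read_ply_vertices_ascii(con, n, vert)
  } else {
    read_ply_vertices_binary(con, n, vert)
  }
  cols <- NULL
  if (all(c("red", "green", "blue") %in% vert$props)) {
    cols <- cbind(vals[["red"]], vals[["green"]], vals[["blue"]])
    ctype <- vert$types[match("red", vert$props)]
    if (ctype %in% c("uchar", "uint8")) cols <- cols / 255
  }
  point_cloud(cbind(vals[["x"]], vals[["y"]], vals[["z"]]), colors = cols)
}

read_ply_vertices_ascii <- function(con, n, vert) {
  out <- lapply(vert$props, function(p) numeric(n))
  names(out) <- vert$props
  if (n == 0) return(out)
  lines <- readLines(con, n = n)
  if (length(lines) < n) stop("PLY truncated: expected ", n, " vertex lines")
  toks <- strsplit(trimws(lines), "\\s+")
  np <- length(vert$props)
  for (i in seq_len(n)) {
    ti <- toks[[i]]
    if (length(ti) < np) {
      stop("PLY vertex line ", i, " has ", length(ti), " values, expected ", np)
    }
    v <- suppressWarnings(as.numeric(ti[seq_len(np)]))
    if (any(is.na(v))) {
      stop("non-numeric value in PLY vertex line ", i, ": '", lines[i], "'")
    }
    for (j in seq_len(np)) out[[j]][i] <- v[j]
  }
  out
}

read_ply_vertices_binary <- function(con, n, vert) {
  sizes <- ply_type_size[vert$types]
  if (any(is.na(sizes))) stop("unknown PLY property type")
  rowsize <- sum(sizes)
  raw <- readBin(con, "raw", n = n * rowsize)
  if (length(raw) < n * rowsize) stop("PLY binary payload truncated")
  offsets <- c(0L, cumsum(sizes))
  out <- vector("list", length(vert$props))
  names(out) <- vert$props
  base <- rep((seq_len(n) - 1L) * rowsize, each = 1L)
  for (j in seq_along(vert$props)) {
    sz <- sizes[j]
    idx <- as.vector(outer(seq_len(sz), base + offsets[j], `+`))
    bytes <- raw[idx]
    type <- vert$types[j]
    out[[j]] <- switch(type,
      float = , float32 = readBin(bytes, "double", n = n, size = 4,
                                  endian = "little"),
      double = , float64 = readBin(bytes, "double", n = n, size = 8,
                                   endian = "little"),
      uchar = , uint8 = as.numeric(readBin(bytes, "integer", n = n, size = 1,
                                           signed = FALSE, endian = "little")),
      char = , int8 = as.numeric(readBin(bytes, "integer", n = n, size = 1,
                                         signed = TRUE, endian = "little")),
      ushort = , uint16 = as.numeric(readBin(bytes, "integer", n = n, size = 2,
                                             signed = FALSE, endian = "little")),
      short = , int16 = as.numeric(readBin(bytes, "integer", n = n, size = 2,
                                           signed = TRUE, endian = "little")),
      int = , int32 = as.numeric(readBin(bytes, "integer", n = n, size = 4,
                                         endian = "little")),
      stop("unsupported binary PLY property type: ", type)
    )
  }
  out
}

write_ply_points <- function(cloud, path, binary = TRUE) {
  m <- pc_matrix(cloud)
  cols <- pc_colors(cloud)
  props <- c("x", "y", "z", if (!is.null(cols)) c("red", "green", "blue"))
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", nrow(m)),
    sprintf("property double %s", props),
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  dat <- if (is.null(cols)) m else cbind(m, cols)
  if (nrow(dat) > 0) {
    if (binary) {
      writeBin(as.vector(t(dat)), con, size = 8, endian = "little")
    } else {
      lines <- apply(dat, 1, function(r) {
        paste(sprintf("%.17g", r), collapse = " ")
      })
      writeLines(lines, con, sep = "\n")
    }
  }
  invisible(path)
}

# ---- XYZ ------------------------------------------------------------------

read_xyz_points <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(point_cloud())
  toks <- strsplit(trimws(lines), "[\\s,]+", perl = TRUE)
  nc <- lengths(toks)
  bad <- which(!nc %in% c(3L, 6L))
  if (length(bad) > 0) {
    stop("XYZ row ", bad[1], " has ", nc[bad[1]],
         " columns (expected 3 or 6): '", lines[bad[1]], "'")
  }
  if (length(unique(nc)) > 1) {
    stop("XYZ file mixes 3- and 6-column rows (first mismatch at row ",
         which(nc != nc[1])[1], ")")
  }
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad) > 0) {
    stop("non-numeric value in XYZ row ", bad[1], ": '", lines[bad[1]], "'")
  }
  m <- do.call(rbind, vals)
  cols <- if (ncol(m) == 6L) {
    cm <- m[, 4:6, drop = FALSE]
    if (nrow(cm) > 0 && max(cm) > 1) cm <- cm / 255  # 0-255 dialect
    cm
  } else {
    NULL
  }
  point_cloud(m[, 1:3, drop = FALSE], colors = cols)
}

write_xyz_points <- function(cloud, path) {
  dat <- pc_matrix(cloud)
  cols <- pc_colors(cloud)
  if (!is.null(cols)) dat <- cbind(dat, cols)
  con <- file(path, "wb")  # wb: deterministic bytes across platforms
  on.exit(close(con))
  if (nrow(dat) > 0) {
    lines <- apply(dat, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}
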