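#' Read an STL surface file
#'
#' Reads both STL dialects: ASCII (`solid ... facet normal ... vertex ...`)
#' and binary (80-byte header, little-endian uint32 facet count, 50 bytes per
#' facet). Coordinates are taken as millimetres. The raw soup of per-facet
#' vertices is welded into an indexed mesh.
#'
#' @param path file path.
#' @param weld_tol weld tolerance in mm (default 1e-6; STL stores no
#'   connectivity, so welding is mandatory).
#' @return a [tooth_mesh].
#' @export
read_stl <- function(path, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0) stop("empty STL file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(84, sz))
  is_binary <- FALSE
  if (sz >= 84) {
    nfac <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (!is.na(nfac) && nfac >= 0 && sz == 84 + 50 * as.numeric(nfac))
      is_binary <- TRUE
  }
  if (is_binary) {
    if (nfac == 0) stop("empty STL file (0 facets): ", path)
    body <- readBin(con, "raw", n = 50 * as.numeric(nfac))
    if (length(body) < 50 * nfac)
      stop(sprintf("malformed binary STL: truncated at byte %d of %s",
                   84 + length(body), path))
    m <- matrix(body, nrow = 50)
    coords <- readBin(as.vector(m[1:48, ]), "numeric", size = 4,
                      n = 12 * nfac, endian = "little")
    cm <- matrix(coords, nrow = 12)          # per facet: normal + 3 vertices
    vraw <- matrix(as.vector(cm[4:12, ]), ncol = 3, byrow = TRUE)
    if (!all(is.finite(vraw)))
      stop("malformed binary STL: non-finite vertex coordinates in ", path)
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\b", lines)
    if (length(vl) == 0)
      stop("malformed STL: no 'vertex' records found (line 1) in ", path)
    if (length(vl) %% 3 != 0)
      stop(sprintf(
        "malformed ASCII STL: vertex count %d not a multiple of 3 (last vertex at line %d) in %s",
        length(vl), vl[length(vl)], path))
    txt <- sub("^\\s*vertex\\s+", "", lines[vl])
    parts <- strsplit(trimws(txt), "\\s+")
    bad <- which(lengths(parts) != 3)
    if (length(bad))
      stop(sprintf("malformed ASCII STL: bad vertex at line %d in %s",
                   vl[bad[1]], path))
    vraw <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                   ncol = 3, byrow = TRUE)
    if (any(!is.finite(vraw))) {
      bad <- which(!is.finite(rowSums(vraw)))[1]
      stop(sprintf("malformed ASCII STL: non-numeric vertex at line %d in %s",
                   vl[bad], path))
    }
  }
  nf <- nrow(vraw) / 3
  faces <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  tooth_mesh(vraw, faces, weld = TRUE, weld_tol = weld_tol)
}

#' Write an STL surface file
#'
#' @param mesh a [tooth_mesh].
#' @param path output path.
#' @param binary write the binary dialect (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  V <- mesh$vertices
  F <- mesh$faces
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(c(utf8ToInt("toothfusion binary STL"),
                      rep(0L, 80 - nchar("toothfusion binary STL")))), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    tri <- cbind(n,
                 V[F[, 1], , drop = FALSE],
                 V[F[, 2], , drop = FALSE],
                 V[F[, 3], , drop = FALSE])
    fbytes <- writeBin(as.numeric(t(tri)), raw(), size = 4, endian = "little")
    block <- matrix(raw(1), nrow = 50, ncol = nrow(F))
    block[1:48, ] <- matrix(fbytes, nrow = 48)
    writeBin(as.vector(block), con)
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    out <- character(7 * nrow(F) + 2)
    out[1] <- "solid toothfusion"
    k <- 2L
    for (i in seq_len(nrow(F))) {
      out[k] <- sprintf("  facet normal %s %s %s",
                        fmt(n[i, 1]), fmt(n[i, 2]), fmt(n[i, 3]))
      out[k + 1L] <- "    outer loop"
      for (j in 1:3) {
        v <- V[F[i, j], ]
        out[k + 1L + j] <- sprintf("      vertex %s %s %s",
                                   fmt(v[1]), fmt(v[2]), fmt(v[3]))
      }
      out[k + 5L] <- "    endloop"
      out[k + 6L] <- "  endfacet"
      k <- k + 7L
    }
    out[k] <- "endsolid toothfusion"
    writeLines(out, path)
  }
  invisible(path)
}
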