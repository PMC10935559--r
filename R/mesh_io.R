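# OBJ and STL readers/writers. OBJ preserves vertex order round-trip; STL is
# available in ASCII and binary flavors (binary STL duplicates vertices per
# facet, as the format requires).

#' Write a mesh to a Wavefront OBJ file
#'
#' Vertex order is preserved exactly, so `read_obj(write_obj(m))` round-trips.
#' @param mesh `pf_mesh`.
#' @param path output file.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "pf_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pftwin OBJ export", con)
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ file
#' @param path OBJ file with `v` and triangular `f` records.
#' @return `pf_mesh`.
#' @export
read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  if (!length(vl) || !length(fl)) stop("no vertices/faces in OBJ: ", path)
  v <- matrix(as.numeric(unlist(strsplit(trimws(sub("^v", "", vl)), "\\s+"))),
              ncol = 3, byrow = TRUE)
  ftok <- strsplit(trimws(sub("^f", "", fl)), "\\s+")
  if (any(lengths(ftok) != 3L)) stop("only triangular faces supported")
  f <- matrix(as.integer(sub("/.*$", "", unlist(ftok))), ncol = 3, byrow = TRUE)
  pf_mesh(v, f)
}

#' Write a mesh as STL (ASCII or binary)
#' @param mesh `pf_mesh`.
#' @param path output file.
#' @param binary write the 80-byte-header binary flavor (default ASCII).
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "pf_mesh"))
  nf <- nrow(mesh$faces)
  tri <- lapply(1:3, function(k) mesh$vertices[mesh$faces[, k], , drop = FALSE])
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.numeric(c(mesh$face_normals[i, ], tri[[1]][i, ],
                            tri[[2]][i, ], tri[[3]][i, ])),
               con, size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid pftwin", con)
    for (i in seq_len(nf)) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", mesh$face_normals[i, 1],
                mesh$face_normals[i, 2], mesh$face_normals[i, 3]),
        "    outer loop",
        sprintf("      vertex %.17g %.17g %.17g",
                c(tri[[1]][i, 1], tri[[2]][i, 1], tri[[3]][i, 1]),
                c(tri[[1]][i, 2], tri[[2]][i, 2], tri[[3]][i, 2]),
                c(tri[[1]][i, 3], tri[[2]][i, 3], tri[[3]][i, 3])),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid pftwin", con)
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary autodetected)
#'
#' STL stores one vertex triple per facet; identical vertices are merged on
#' read (exact coordinate match).
#' @param path STL file.
#' @return `pf_mesh`.
#' @export
read_stl <- function(path) {
  head5 <- readBin(path, "raw", 5L)
  is_ascii <- identical(rawToChar(head5), "solid") && {
    # binary files may also start with 'solid'; check facet keyword
    txt <- tryCatch(readLines(path, n = 20L, warn = FALSE),
                    error = function(e) character())
    any(grepl("facet", txt))
  }
  if (is_ascii) {
    ln <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", ln, value = TRUE)
    v <- matrix(as.numeric(unlist(strsplit(trimws(sub("vertex", "", vl)),
                                           "\\s+"))), ncol = 3, byrow = TRUE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    nf <- readBin(con, "integer", 1L, size = 4, endian = "little")
    v <- matrix(0, nf * 3L, 3L)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "numeric", 12L, size = 4, endian = "little")
      v[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", 2L)
    }
  }
  key <- apply(v, 1, function(r) paste(sprintf("%.12g", r), collapse = "|"))
  uid <- !duplicated(key)
  map <- match(key, key[uid])
  f <- matrix(map, ncol = 3, byrow = TRUE)
  pf_mesh(v[uid, , drop = FALSE], f)
}
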