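# FreeSurfer binary formats: triangle surface, new-format curv overlay,
# annot parcellation. All are big-endian; vertex indices are 0-based on disk
# and converted to 1-based in memory.

FS_TRIANGLE_MAGIC <- c(0xffL, 0xffL, 0xfeL)
FS_CURV_MAGIC <- c(0xffL, 0xffL, 0xffL)

read_int3 <- function(con) {
  b <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  if (length(b) < 3) stop_arg("file truncated: missing magic number")
  sum(b * c(65536, 256, 1))
}

write_int3 <- function(con, bytes) {
  writeBin(as.raw(bytes), con)
}

#' Read a triangulated surface file
#'
#' Reads a cortical surface mesh from a FreeSurfer binary triangle file or a
#' GIFTI (.gii) surface. Vertex order is preserved exactly as stored.
#'
#' @param path file path.
#' @param format `"freesurfer-surf"`, `"gifti"`, or `"auto"` (by extension).
#' @return A [surface_mesh()].
#' @export
read_surface <- function(path, format = c("auto", "freesurfer-surf", "gifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_arg("surface file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti"
              else "freesurfer-surf"
  if (format == "gifti") return(read_gifti_surface(path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (magic != 0xfffffe)
    stop_arg("not a FreeSurfer triangle surface (bad magic 0x%x): %s",
             magic, path)
  # creator comment: terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) stop_arg("file truncated in creator comment: %s", path)
    if (prev == as.raw(10) && b == as.raw(10)) break
    prev <- b
  }
  counts <- readBin(con, "integer", n = 2, size = 4, endian = "big")
  if (length(counts) < 2 || any(counts < 0))
    stop_arg("file truncated: missing vertex/face counts: %s", path)
  nv <- counts[1]; nf <- counts[2]
  vx <- readBin(con, "numeric", n = 3 * nv, size = 4, endian = "big")
  if (length(vx) < 3 * nv)
    stop_arg("file truncated in vertex block (expected %d floats): %s",
             3 * nv, path)
  fc <- readBin(con, "integer", n = 3 * nf, size = 4, endian = "big")
  if (length(fc) < 3 * nf)
    stop_arg("file truncated in face block (expected %d ints): %s",
             3 * nf, path)
  surface_mesh(matrix(vx, ncol = 3, byrow = TRUE),
               matrix(fc, ncol = 3, byrow = TRUE) + 1L)
}

#' Write a triangulated surface file
#'
#' @param mesh a [surface_mesh()].
#' @param path destination path.
#' @param format `"freesurfer-surf"` or `"gifti"`.
#' @export
write_surface <- function(mesh, path,
                          format = c("freesurfer-surf", "gifti")) {
  format <- match.arg(format)
  if (format == "gifti") return(write_gifti_surface(mesh, path))
  con <- file(path, "wb")
  on.exit(close(con))
  write_int3(con, FS_TRIANGLE_MAGIC)
  writeBin(charToRaw("created by surfmvpa\n\n"), con)
  writeBin(as.integer(c(nrow(mesh$vertices), nrow(mesh$faces))), con,
           size = 4, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

#' Write a per-vertex scalar overlay
#'
#' Writes one finite scalar per vertex in FreeSurfer "curv" new format or as a
#' GIFTI functional array. Values are stored as float32, so round-trips are
#' exact only to single precision.
#'
#' @param values numeric vector, one value per vertex.
#' @param path destination path.
#' @param format `"freesurfer-curv"` or `"gifti"`.
#' @param n_vertices optional expected vertex count of the target mesh; a
#'   mismatch is a dimension error.
#' @param n_faces face count recorded in the curv header (metadata only).
#' @export
write_overlay <- function(values, path,
                          format = c("freesurfer-curv", "gifti"),
                          n_vertices = NULL, n_faces = 0L) {
  format <- match.arg(format)
  if (!is.null(n_vertices) && length(values) != n_vertices)
    stop_arg("overlay has %d values but the mesh has %d vertices",
             length(values), n_vertices)
  if (!all(is.finite(values))) stop_arg("overlay values must be finite")
  if (format == "gifti") return(write_gifti_scalar(values, path))
  con <- file(path, "wb")
  on.exit(close(con))
  write_int3(con, FS_CURV_MAGIC)
  writeBin(as.integer(c(length(values), n_faces, 1L)), con, size = 4,
           endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}

#' Read a per-vertex scalar overlay
#'
#' @param path file path.
#' @param format `"auto"`, `"freesurfer-curv"` or `"gifti"`.
#' @return numeric vector of per-vertex values.
#' @export
read_overlay <- function(path, format = c("auto", "freesurfer-curv", "gifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_arg("overlay file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti"
              else "freesurfer-curv"
  if (format == "gifti") return(read_gifti_scalar(path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (magic != 0xffffff)
    stop_arg("not a new-format curv file (bad magic 0x%x): %s", magic, path)
  hdr <- readBin(con, "integer", n = 3, size = 4, endian = "big")
  if (length(hdr) < 3) stop_arg("file truncated in curv header: %s", path)
  nv <- hdr[1]
  vals <- readBin(con, "numeric", n = nv * hdr[3], size = 4, endian = "big")
  if (length(vals) < nv) stop_arg("file truncated in curv data: %s", path)
  vals[seq_len(nv)]
}

# label id (1-based) -> annot RGB code; bijective for up to 2^24 labels
annot_code <- function(label) {
  id <- label - 1L
  r <- id %% 256L; g <- (id %/% 256L) %% 256L; b <- id %/% 65536L
  r + g * 256L + b * 65536L
}

#' Write a parcellation as a FreeSurfer annot file
#'
#' Each label gets a generated colour-table entry whose RGB code encodes the
#' label id, so the mapping survives a round trip bit-exactly.
#'
#' @param parcellation a [parcellation] object (or plain 1-based assignment
#'   vector).
#' @param path destination path.
#' @export
write_annot <- function(parcellation, path) {
  assignment <- if (inherits(parcellation, "parcellation"))
    parcellation$assignment else as.integer(parcellation)
  labels <- sort(unique(assignment))
  con <- file(path, "wb")
  on.exit(close(con))
  nv <- length(assignment)
  writeBin(as.integer(nv), con, size = 4, endian = "big")
  inter <- integer(2 * nv)
  inter[seq(1, 2 * nv, 2)] <- seq_len(nv) - 1L
  inter[seq(2, 2 * nv, 2)] <- annot_code(assignment)
  writeBin(inter, con, size = 4, endian = "big")
  writeBin(1L, con, size = 4, endian = "big")           # TAG_OLD_COLORTABLE
  writeBin(-2L, con, size = 4, endian = "big")          # ctab version 2
  writeBin(as.integer(max(labels)), con, size = 4, endian = "big")
  fname <- "surfmvpa_generated"
  writeBin(as.integer(nchar(fname) + 1L), con, size = 4, endian = "big")
  writeBin(c(charToRaw(fname), as.raw(0)), con)
  writeBin(as.integer(length(labels)), con, size = 4, endian = "big")
  for (l in labels) {
    writeBin(as.integer(l - 1L), con, size = 4, endian = "big")
    nm <- sprintf("label_%d", l)
    writeBin(as.integer(nchar(nm) + 1L), con, size = 4, endian = "big")
    writeBin(c(charToRaw(nm), as.raw(0)), con)
    code <- annot_code(l)
    writeBin(as.integer(c(code %% 256L, (code %/% 256L) %% 256L,
                          code %/% 65536L, 0L)), con, size = 4, endian = "big")
  }
  invisible(path)
}

#' Read a FreeSurfer annot file into a label assignment
#'
#' @param path annot file path.
#' @return integer vector of 1-based label ids per vertex; colour codes are
#'   mapped back through the embedded colour table.
#' @export
read_annot <- function(path) {
  if (!file.exists(path)) stop_arg("annot file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  nv <- readBin(con, "integer", size = 4, endian = "big")
  if (length(nv) != 1 || nv <= 0) stop_arg("bad vertex count in annot: %s", path)
  inter <- readBin(con, "integer", n = 2 * nv, size = 4, endian = "big")
  if (length(inter) < 2 * nv) stop_arg("file truncated in annot data: %s", path)
  codes <- inter[seq(2, 2 * nv, 2)]
  tag <- readBin(con, "integer", size = 4, endian = "big")
  if (length(tag) == 1 && tag == 1L) {
    version <- readBin(con, "integer", size = 4, endian = "big")
    if (version != -2L) stop_arg("unsupported annot colortable version %d", version)
    readBin(con, "integer", size = 4, endian = "big")   # max structure id
    ln <- readBin(con, "integer", size = 4, endian = "big")
    readBin(con, "raw", n = ln)
    ne <- readBin(con, "integer", size = 4, endian = "big")
    code2label <- new.env()
    for (i in seq_len(ne)) {
      sid <- readBin(con, "integer", size = 4, endian = "big")
      ln <- readBin(con, "integer", size = 4, endian = "big")
      readBin(con, "raw", n = ln)
      rgba <- readBin(con, "integer", n = 4, size = 4, endian = "big")
      code <- rgba[1] + rgba[2] * 256L + rgba[3] * 65536L
      assign(as.character(code), sid + 1L, envir = code2label)
    }
    out <- vapply(as.character(codes), function(k) {
      v <- code2label[[k]]
      if (is.null(v)) stop_arg("annot colour code %s missing from table", k)
      v
    }, integer(1), USE.NAMES = FALSE)
    return(out)
  }
  # no colour table: the generated encoding stores label - 1 directly
  codes + 1L
}
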