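# File I/O: documented plain-text mesh format and legacy VTK export.

#' Write a mesh in the package's plain-text format
#'
#' Format (whitespace-delimited):
#' ```
#' foamfea-mesh <dim> <depth>
#' nodes <n>
#' <id> <x> <y> [<z>]        (one line per node)
#' elements <ne>
#' <id> <region> <n1> ... <n4|n8>
#' set <name> <count>
#' <ids...>                  (one or more lines)
#' ```
#'
#' @param mesh A `fea_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "fea_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("foamfea-mesh %d %.17g", mesh$dim, mesh$depth), con)
  writeLines(sprintf("nodes %d", nrow(mesh$nodes)), con)
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   apply(format(mesh$nodes, digits = 17, trim = TRUE,
                                scientific = FALSE), 1, paste,
                         collapse = " ")), con)
  writeLines(sprintf("elements %d", nrow(mesh$elements)), con)
  writeLines(paste(seq_len(nrow(mesh$elements)), mesh$region,
                   apply(mesh$elements, 1, paste, collapse = " ")), con)
  for (nm in names(mesh$sets)) {
    ids <- mesh$sets[[nm]]
    writeLines(sprintf("set %s %d", nm, length(ids)), con)
    if (length(ids)) writeLines(paste(ids, collapse = " "), con)
  }
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' @param path Input path.
#' @return A `fea_mesh`.
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  if (hdr[1] != "foamfea-mesh") stop("not a foamfea mesh file", call. = FALSE)
  dim_ <- as.integer(hdr[2])
  depth <- as.numeric(hdr[3])
  i <- 2L
  stopifnot(startsWith(lines[i], "nodes "))
  n <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
  ndat <- utils::read.table(text = lines[(i + 1):(i + n)])
  nodes <- as.matrix(ndat[, -1, drop = FALSE])
  dimnames(nodes) <- NULL
  i <- i + n + 1L
  stopifnot(startsWith(lines[i], "elements "))
  ne <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
  edat <- utils::read.table(text = lines[(i + 1):(i + ne)],
                            colClasses = c("integer", "character",
                                           rep("integer",
                                               if (dim_ == 2L) 4L else 8L)))
  region <- edat[[2]]
  elements <- as.matrix(edat[, -(1:2), drop = FALSE])
  dimnames(elements) <- NULL
  i <- i + ne + 1L
  sets <- list()
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    hd <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    stopifnot(hd[1] == "set")
    cnt <- as.integer(hd[3])
    ids <- integer(0)
    i <- i + 1L
    while (length(ids) < cnt) {
      ids <- c(ids, as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      i <- i + 1L
    }
    sets[[hd[2]]] <- ids
  }
  fea_mesh(nodes, elements, region, sets, depth = depth)
}

#' Export a mesh (and optional fields) as a legacy VTK unstructured grid
#'
#' ASCII VTK 2.0 format readable by ParaView and similar tools. 2-D
#' quadrilaterals are written as `VTK_QUAD` (cell type 9), hexahedra as
#' `VTK_HEXAHEDRON` (type 12).
#'
#' @param mesh A `fea_mesh`.
#' @param path Output `.vtk` path.
#' @param point_data Named list of per-node scalar vectors or matrices
#'   (vectors of dim columns).
#' @param cell_data Named list of per-element scalar vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  stopifnot(inherits(mesh, "fea_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elements)
  npe <- ncol(mesh$elements)
  xyz <- cbind(mesh$nodes,
               matrix(0, n, 3 - ncol(mesh$nodes)))
  writeLines(c("# vtk DataFile Version 2.0",
               "foamfea export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(format(xyz, digits = 9, trim = TRUE, scientific = TRUE),
                   1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", ne, ne * (npe + 1L)), con)
  writeLines(paste(npe, apply(mesh$elements - 1L, 1, paste, collapse = " ")),
             con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(if (npe == 4L) 9L else 12L, ne)), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        v3 <- cbind(v, matrix(0, nrow(v), 3 - ncol(v)))
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(format(v3, digits = 9, trim = TRUE,
                                scientific = TRUE), 1, paste,
                         collapse = " "), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(v, digits = 9, trim = TRUE, scientific = TRUE), con)
      }
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], digits = 9, trim = TRUE,
                        scientific = TRUE), con)
    }
  }
  invisible(path)
}

#' Read back a scalar cell field from a legacy VTK file
#'
#' Minimal reader for round-tripping fields written by [write_vtk()].
#'
#' @param path VTK path.
#' @param name Field name.
#' @return Numeric vector of per-cell values.
#' @export
read_vtk_cell_field <- function(path, name) {
  lines <- readLines(path)
  i <- grep("^CELL_DATA", lines)
  if (!length(i)) stop("no CELL_DATA in ", path, call. = FALSE)
  ne <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
  j <- grep(paste0("^SCALARS ", name, " "), lines)
  j <- j[j > i][1]
  if (is.na(j)) stop("field '", name, "' not found", call. = FALSE)
  as.numeric(lines[(j + 2):(j + 1 + ne)])
}
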