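#' @include mesh.R
NULL

#' Read a tetrahedral mesh from Gmsh MSH (v2.2 ASCII) or legacy VTK
#'
#' The format is chosen by file extension (\code{.msh} or \code{.vtk}).
#' Volumetric cells must be tetrahedra; lower-dimensional elements in MSH
#' files (points, lines, surface triangles) are skipped. An integer cell-data
#' field (MSH physical tag, or the first integer \code{CELL_DATA} scalar in
#' VTK) is kept as the tissue label. Coordinates are assumed to be in mm.
#'
#' @param path file path.
#' @return a [TumorMesh-class].
#' @seealso [writeMeshVTK()], [writeMeshMSH()]
#' @export
readMesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    msh = readMeshMSH(path),
    vtk = readMeshVTK(path),
    stop(sprintf("unsupported mesh format '.%s' (use .msh or .vtk)", ext))
  )
}

readMeshMSH <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop(sprintf("MSH file lacks a $%s section", name))
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(trimws(sec("MeshFormat")[1L]), "\\s+")[[1L]]
  if (!startsWith(fmt[1L], "2"))
    stop(sprintf("unsupported MSH version %s (need 2.x ASCII)", fmt[1L]))
  nodeLines <- sec("Nodes")
  nn <- as.integer(nodeLines[1L])
  ntab <- matrix(scan(text = nodeLines[-1L], quiet = TRUE), nn, 4L, byrow = TRUE)
  ids <- as.integer(ntab[, 1L])
  vertices <- ntab[order(ids), 2:4, drop = FALSE]
  remap <- integer(max(ids))
  remap[sort(ids)] <- seq_len(nn)
  elemLines <- sec("Elements")
  ne <- as.integer(elemLines[1L])
  cells <- matrix(0L, 0L, 4L)
  labs <- integer(0)
  cellRows <- vector("list", ne)
  labRows <- integer(ne)
  nc <- 0L
  for (ln in elemLines[-1L]) {
    tok <- as.integer(strsplit(trimws(ln), "\\s+")[[1L]])
    type <- tok[2L]
    if (type %in% c(15L, 1L, 2L, 3L)) next
    if (type != 4L)
      stop(sprintf("element %d has non-tetrahedral type %d", tok[1L], type))
    ntags <- tok[3L]
    nodes <- tok[(4L + ntags):(7L + ntags)]
    nc <- nc + 1L
    cellRows[[nc]] <- remap[nodes]
    labRows[nc] <- if (ntags >= 1L) tok[4L] else 0L
  }
  if (nc == 0L) stop("MSH file contains no tetrahedra")
  cells <- do.call(rbind, cellRows[seq_len(nc)])
  labs <- labRows[seq_len(nc)]
  if (all(labs == 0L)) labs <- integer(0)
  checkDegenerate(vertices, cells)
  newTumorMesh(vertices, cells, labels = labs)
}

checkDegenerate <- function(vertices, cells) {
  s <- cellSignedVolumes6(vertices, cells)
  bad <- which(s == 0)
  if (length(bad))
    stop(sprintf("degenerate (zero-volume) cells at indices: %s",
                 paste(head(bad, 10L), collapse = ", ")))
}

readMeshVTK <- function(path) {
  lines <- readLines(path)
  up <- toupper(lines)
  if (!any(grepl("DATASET\\s+UNSTRUCTURED_GRID", up)))
    stop("VTK file is not an unstructured grid")
  toks <- scan(text = lines[-(1:2)], what = "character", quiet = TRUE)
  tu <- toupper(toks)
  ipts <- match("POINTS", tu)
  np <- as.integer(toks[ipts + 1L])
  coords <- as.numeric(toks[(ipts + 3L):(ipts + 2L + 3L * np)])
  vertices <- matrix(coords, np, 3L, byrow = TRUE)
  icell <- match("CELLS", tu)
  ncell <- as.integer(toks[icell + 1L])
  total <- as.integer(toks[icell + 2L])
  conn <- as.integer(toks[(icell + 3L):(icell + 2L + total)])
  itype <- match("CELL_TYPES", tu)
  types <- as.integer(toks[(itype + 2L):(itype + 1L + ncell)])
  if (any(types != 10L))
    stop(sprintf("non-tetrahedral VTK cell type(s): %s",
                 paste(unique(types[types != 10L]), collapse = ", ")))
  pos <- 1L
  cells <- matrix(0L, ncell, 4L)
  for (i in seq_len(ncell)) {
    k <- conn[pos]
    if (k != 4L) stop(sprintf("cell %d has %d vertices; expected 4", i, k))
    cells[i, ] <- conn[(pos + 1L):(pos + 4L)] + 1L
    pos <- pos + 1L + k
  }
  labs <- integer(0)
  icd <- match("CELL_DATA", tu)
  if (!is.na(icd)) {
    isc <- which(tu == "SCALARS" & seq_along(tu) > icd)[1L]
    if (!is.na(isc)) {
      ilt <- which(tu == "LOOKUP_TABLE" & seq_along(tu) > isc)[1L]
      labs <- as.integer(toks[(ilt + 2L):(ilt + 1L + ncell)])
    }
  }
  checkDegenerate(vertices, cells)
  newTumorMesh(vertices, cells, labels = labs)
}

#' Write a mesh (and optional fields) as a legacy VTK unstructured grid
#'
#' @param mesh a [TumorMesh-class].
#' @param path output file path.
#' @param pointData named list of per-vertex numeric vectors (e.g. phi,
#'   sigma, n).
#' @param cellData named list of per-cell vectors; the mesh tissue labels are
#'   added automatically when present.
#' @return (invisibly) \code{path}.
#' @export
writeMeshVTK <- function(mesh, path, pointData = list(), cellData = list()) {
  stopifnot(is(mesh, "TumorMesh"))
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh@vertices
  cells <- mesh@cells - 1L
  writeLines(c("# vtk DataFile Version 3.0",
               "gbmsim unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("CELLS %d %d", nrow(cells), 5L * nrow(cells)), con)
  writeLines(sprintf("4 %d %d %d %d", cells[, 1L], cells[, 2L], cells[, 3L], cells[, 4L]), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(cells)), con)
  writeLines(rep("10", nrow(cells)), con)
  if (length(mesh@labels)) cellData <- c(list(tissue_label = mesh@labels), cellData)
  if (length(cellData)) {
    writeLines(sprintf("CELL_DATA %d", nrow(cells)), con)
    for (nm in names(cellData)) {
      x <- cellData[[nm]]
      if (is.integer(x)) {
        writeLines(c(sprintf("SCALARS %s int 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%d", x), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.17g", x), con)
      }
    }
  }
  if (length(pointData)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(pointData)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", pointData[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write a mesh in Gmsh MSH v2.2 ASCII format
#'
#' @param mesh a [TumorMesh-class].
#' @param path output file path.
#' @return (invisibly) \code{path}.
#' @export
writeMeshMSH <- function(mesh, path) {
  stopifnot(is(mesh, "TumorMesh"))
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh@vertices
  cells <- mesh@cells
  labs <- if (length(mesh@labels)) mesh@labels else rep(1L, nrow(cells))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               sprintf("%d", nrow(v))), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(v)),
                     v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(c("$EndNodes", "$Elements", sprintf("%d", nrow(cells))), con)
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(nrow(cells)),
                     labs, labs, cells[, 1L], cells[, 2L], cells[, 3L], cells[, 4L]), con)
  writeLines("$EndElements", con)
  invisible(path)
}
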