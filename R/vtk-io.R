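# Minimal ASCII VTK XML (.vtp/.vtu) writer/reader for time series of
# surface WSS and volume velocity fields, plus the JSON series manifest.
# Connectivity is 0-based on disk (VTK convention), 1-based in memory;
# geometry is stored in mm with units recorded in the manifest.

fmtNum <- function(x) sprintf("%.17g", x)

dataArrayXML <- function(name, values, components = 1L, type = "Float64") {
  sprintf('<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
          type, name, components,
          paste(fmtNum(if (is.matrix(values)) as.vector(t(values)) else values),
                collapse = " "))
}

pointDataXML <- function(pointData) {
  if (!length(pointData)) return("<PointData>\n</PointData>")
  parts <- vapply(names(pointData), function(nm) {
    v <- pointData[[nm]]
    dataArrayXML(nm, v, components = if (is.matrix(v)) ncol(v) else 1L)
  }, character(1))
  paste0("<PointData>\n", paste(parts, collapse = "\n"), "\n</PointData>")
}

writeVTP <- function(path, vertices, triangles, pointData = list()) {
  np <- nrow(vertices); nc <- nrow(triangles)
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
    '<PolyData>\n',
    sprintf('<Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">\n', np, nc),
    "<Points>\n", dataArrayXML("Points", vertices, 3L), "\n</Points>\n",
    pointDataXML(pointData), "\n",
    "<Polys>\n",
    sprintf('<DataArray type="Int64" Name="connectivity" format="ascii">\n%s\n</DataArray>\n',
            paste(as.vector(t(triangles)) - 1L, collapse = " ")),
    sprintf('<DataArray type="Int64" Name="offsets" format="ascii">\n%s\n</DataArray>\n',
            paste(seq_len(nc) * 3L, collapse = " ")),
    "</Polys>\n</Piece>\n</PolyData>\n</VTKFile>\n")
  writeLines(xml, path, sep = "")
}

writeVTU <- function(path, vertices, tets, pointData = list()) {
  np <- nrow(vertices); nc <- nrow(tets)
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    '<UnstructuredGrid>\n',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">\n', np, nc),
    "<Points>\n", dataArrayXML("Points", vertices, 3L), "\n</Points>\n",
    pointDataXML(pointData), "\n",
    "<Cells>\n",
    sprintf('<DataArray type="Int64" Name="connectivity" format="ascii">\n%s\n</DataArray>\n',
            paste(as.vector(t(tets)) - 1L, collapse = " ")),
    sprintf('<DataArray type="Int64" Name="offsets" format="ascii">\n%s\n</DataArray>\n',
            paste(seq_len(nc) * 4L, collapse = " ")),
    sprintf('<DataArray type="UInt8" Name="types" format="ascii">\n%s\n</DataArray>\n',
            paste(rep(10L, nc), collapse = " ")),
    "</Cells>\n</Piece>\n</UnstructuredGrid>\n</VTKFile>\n")
  writeLines(xml, path, sep = "")
}

parseArrayNode <- function(node) {
  vals <- as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  nc <- xml2::xml_attr(node, "NumberOfComponents")
  nc <- if (is.na(nc)) 1L else as.integer(nc)
  if (nc > 1) matrix(vals, ncol = nc, byrow = TRUE) else vals
}

readVTK <- function(path) {
  if (!file.exists(path)) stopFormat("series file missing: %s", path)
  doc <- xml2::read_xml(path)
  type <- xml2::xml_attr(doc, "type")
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts <- parseArrayNode(xml2::xml_find_first(piece, "./Points/DataArray"))
  pdNodes <- xml2::xml_find_all(piece, "./PointData/DataArray")
  pointData <- list()
  for (nd in pdNodes) pointData[[xml2::xml_attr(nd, "Name")]] <- parseArrayNode(nd)
  cellParent <- if (type == "PolyData") "Polys" else "Cells"
  conNode <- xml2::xml_find_first(piece, sprintf("./%s/DataArray[@Name='connectivity']", cellParent))
  offNode <- xml2::xml_find_first(piece, sprintf("./%s/DataArray[@Name='offsets']", cellParent))
  con <- as.integer(parseArrayNode(conNode)) + 1L
  off <- as.integer(parseArrayNode(offNode))
  k <- if (type == "PolyData") 3L else 4L
  if (any(diff(c(0L, off)) != k))
    stopFormat("%s: only pure triangle/tetrahedron pieces are supported", path)
  cells <- matrix(con, ncol = k, byrow = TRUE)
  list(type = type, points = pts, cells = cells, pointData = pointData)
}

# area-weighted node normals from triangle winding
computeNodeNormals <- function(vertices, triangles) {
  e1 <- vertices[triangles[, 2], , drop = FALSE] - vertices[triangles[, 1], , drop = FALSE]
  e2 <- vertices[triangles[, 3], , drop = FALSE] - vertices[triangles[, 1], , drop = FALSE]
  fn <- rowCross(e1, e2)  # 2*area-weighted facet normal
  idx <- as.vector(triangles)
  acc <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    a <- rowsum(rep(fn[, k], 3), idx)
    acc[as.integer(rownames(a)), k] <- a[, 1]
  }
  rowUnit(acc)
}

#' Write a surface or volume field as a VTK XML time series
#'
#' One ASCII `.vtp` (surface, point array `wss` \[Pa\]) or `.vtu`
#' (volume, point array `velocity` \[m/s\]) file per time step plus a
#' JSON manifest recording the period, time values, file list, field
#' units and geometry units (mm). Mesh annotations (normals, stations,
#' local frames) ride along as additional point arrays so a round trip
#' reconstructs the field exactly.
#'
#' @param field a [SurfaceField-class] or [VolumeField-class].
#' @param dir output directory (created if needed).
#' @param basename file prefix.
#' @return the manifest path, invisibly.
#' @export
writeSeries <- function(field, dir, basename = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  isSurf <- is(field, "SurfaceField")
  if (is.null(basename)) basename <- if (isSurf) "surface" else "volume"
  nt <- length(field@times)
  ext <- if (isSurf) "vtp" else "vtu"
  files <- sprintf("%s_%04d.%s", basename, seq_len(nt) - 1L, ext)
  for (ti in seq_len(nt)) {
    if (isSurf) {
      s <- field@surface
      pd <- list(Normals = s@normals, station = s@station,
                 wss = matrix(field@wss[, , ti], ncol = 3))
      if (!is.null(s@frame))
        pd <- c(pd, list(axis = s@frame$axis, azimuth = s@frame$azimuth,
                         rlocal = s@frame$rlocal))
      writeVTP(file.path(dir, files[ti]), s@vertices, s@triangles, pd)
    } else {
      m <- field@mesh
      pd <- list(station = m@station, rho = m@rho, rhoNorm = m@rhoNorm,
                 rlocal = m@rlocal, axis = m@axis, azimuth = m@azimuth,
                 boundary = as.numeric(m@boundary),
                 velocity = matrix(field@velocity[, , ti], ncol = 3))
      if (!is.null(field@vorticityExact))
        pd$vorticity_exact <- matrix(field@vorticityExact[, , ti], ncol = 3)
      writeVTU(file.path(dir, files[ti]), m@vertices, m@tets, pd)
    }
  }
  manifest <- list(
    kind = if (isSurf) "surface" else "volume",
    period_s = field@period, times = field@times, files = files,
    fields = if (isSurf) list(list(name = "wss", units = "Pa", components = 3))
             else list(list(name = "velocity", units = "m/s", components = 3)),
    geometry_units = "mm")
  mpath <- file.path(dir, paste0(basename, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mpath)
}

#' Read a VTK XML time series back into a field object
#'
#' Validates the manifest (times strictly increasing within the period,
#' one file per time), checks node-count consistency across steps, and
#' reassembles a [SurfaceField-class] or [VolumeField-class]. Surface
#' series lacking a `Normals` array get area-weighted node normals
#' recomputed from the triangle winding (reported via a message).
#'
#' @param manifestPath path to the `*_manifest.json` written by
#'   [writeSeries()].
#' @return a [SurfaceField-class] or [VolumeField-class].
#' @export
readSeries <- function(manifestPath) {
  if (!file.exists(manifestPath)) stopFormat("manifest missing: %s", manifestPath)
  man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  for (fld in c("kind", "period_s", "times", "files"))
    if (is.null(man[[fld]])) stopFormat("manifest lacks '%s': %s", fld, manifestPath)
  times <- as.numeric(man$times)
  if (length(man$files) != length(times))
    stopFormat("manifest %s: %d files for %d times", manifestPath,
               length(man$files), length(times))
  if (any(diff(times) <= 0)) stopFormat("manifest %s: times not strictly increasing", manifestPath)
  dir <- dirname(manifestPath)
  nt <- length(times)
  first <- NULL
  fieldName <- if (man$kind == "surface") "wss" else "velocity"
  series <- vector("list", nt)
  for (ti in seq_len(nt)) {
    f <- file.path(dir, man$files[ti])
    v <- readVTK(f)
    if (is.null(v$pointData[[fieldName]]))
      stopFormat("%s: required field array '%s' missing", f, fieldName)
    if (is.null(first)) first <- v
    else if (nrow(v$points) != nrow(first$points))
      stopFormat("%s (time index %d): node count %d differs from %d",
                 f, ti, nrow(v$points), nrow(first$points))
    series[[ti]] <- v$pointData
  }
  n <- nrow(first$points)
  arr <- array(0, dim = c(n, 3, nt))
  for (ti in seq_len(nt)) arr[, , ti] <- series[[ti]][[fieldName]]

  pd <- first$pointData
  station <- if (!is.null(pd$station)) pd$station else rep(NA_real_, n)
  if (man$kind == "surface") {
    normals <- pd$Normals
    if (is.null(normals)) {
      message("surface series lacks normals; recomputing area-weighted node normals")
      normals <- computeNodeNormals(first$points, first$cells)
    }
    frame <- if (!is.null(pd$axis))
      list(axis = pd$axis, azimuth = pd$azimuth, rlocal = pd$rlocal) else NULL
    surf <- new("TriSurface", vertices = first$points, triangles = first$cells,
                normals = normals, station = station, frame = frame)
    new("SurfaceField", surface = surf, times = times,
        period = as.numeric(man$period_s), wss = arr)
  } else {
    zeros <- rep(0, n)
    mesh <- new("TetraMesh", vertices = first$points, tets = first$cells,
                station = station,
                rho = if (!is.null(pd$rho)) pd$rho else zeros,
                rhoNorm = if (!is.null(pd$rhoNorm)) pd$rhoNorm else zeros,
                rlocal = if (!is.null(pd$rlocal)) pd$rlocal else zeros,
                axis = if (!is.null(pd$axis)) pd$axis else matrix(0, n, 3),
                azimuth = if (!is.null(pd$azimuth)) pd$azimuth else matrix(0, n, 3),
                boundary = if (!is.null(pd$boundary)) pd$boundary > 0.5 else rep(TRUE, n))
    vort <- NULL
    if (!is.null(pd$vorticity_exact)) {
      vort <- array(0, dim = c(n, 3, nt))
      for (ti in seq_len(nt)) vort[, , ti] <- series[[ti]]$vorticity_exact
    }
    new("VolumeField", mesh = mesh, times = times,
        period = as.numeric(man$period_s), velocity = arr, vorticityExact = vort)
  }
}
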