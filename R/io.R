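#' Read and write weighted point clouds
#'
#' Lossless round-trip of points, weights, normals and label in three
#' formats: ASCII PLY with a custom per-vertex `weight` property, VTK
#' PolyData (`.vtp`, ASCII), and a native RDS container. A PLY/VTP file
#' without a weight field is read with uniform `1/M` weights and a warning.
#'
#' @param path file path; the format is taken from the extension unless
#'   `format` is given.
#' @param format one of `"ply"`, `"vtp"`, `"rds"`.
#' @return `readCloud` returns a `weighted_point_cloud`; `writeCloud`
#'   returns `path` invisibly.
#' @export
readCloud <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         ply = readCloudPly(path),
         vtp = readCloudVtp(path),
         rds = {
           cl <- readRDS(path)
           if (!inherits(cl, "weighted_point_cloud"))
             stop("RDS file does not contain a weighted_point_cloud")
           cl
         },
         stop(sprintf("unknown cloud format '%s'", format)))
}

#' @rdname readCloud
#' @param cloud a `weighted_point_cloud`.
#' @export
writeCloud <- function(cloud, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         ply = writeCloudPly(cloud, path),
         vtp = writeCloudVtp(cloud, path),
         rds = saveRDS(cloud, path),
         stop(sprintf("unknown cloud format '%s'", format)))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || identical(a, "")) b else a

fmtNum <- function(x) formatC(x, format = "g", digits = 17)

writeCloudPly <- function(cloud, path) {
  m <- nPoints(cloud)
  hasN <- !is.null(cloud$normals)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("comment label %s", cloud$label),
           sprintf("element vertex %d", m),
           "property double x", "property double y", "property double z")
  if (hasN) hdr <- c(hdr, "property double nx", "property double ny",
                     "property double nz")
  hdr <- c(hdr, "property double weight", "end_header")
  body <- cbind(cloud$points, if (hasN) cloud$normals, cloud$weights)
  lines <- apply(body, 1L, function(r) paste(fmtNum(r), collapse = " "))
  writeLines(c(hdr, lines), path)
}

readCloudPly <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1L] != "ply")
    stop(sprintf("malformed PLY '%s': missing 'ply' magic line", path))
  endHdr <- match("end_header", lines)
  if (is.na(endHdr)) stop(sprintf("malformed PLY '%s': no end_header", path))
  hdr <- lines[seq_len(endHdr)]
  vline <- grep("^element vertex ", hdr, value = TRUE)
  if (length(vline) != 1L)
    stop(sprintf("malformed PLY '%s': element vertex missing", path))
  m <- as.integer(sub("^element vertex ", "", vline))
  props <- sub("^property \\S+ ", "", grep("^property ", hdr, value = TRUE))
  label <- sub("^comment label ?", "",
               grep("^comment label", hdr, value = TRUE)[1L])
  if (is.na(label)) label <- ""
  vals <- scan(text = lines[endHdr + seq_len(m)], quiet = TRUE)
  if (length(vals) != m * length(props))
    stop(sprintf(
      "malformed PLY '%s': %d values for %d vertices x %d properties",
      path, length(vals), m, length(props)))
  dat <- matrix(vals, nrow = m, byrow = TRUE)
  colnames(dat) <- props
  if (!all(c("x", "y", "z") %in% props))
    stop(sprintf("malformed PLY '%s': missing coordinate property", path))
  pts <- unname(dat[, c("x", "y", "z"), drop = FALSE])
  normals <- if (all(c("nx", "ny", "nz") %in% props))
    unname(dat[, c("nx", "ny", "nz"), drop = FALSE])
  if ("weight" %in% props) {
    w <- dat[, "weight"]
  } else {
    warning(sprintf("PLY '%s' has no weight property; using uniform weights",
                    path))
    w <- rep(1 / m, m)
  }
  weightedPointCloud(pts, w, normals, label = label)
}

writeCloudVtp <- function(cloud, path) {
  m <- nPoints(cloud)
  hasN <- !is.null(cloud$normals)
  da <- function(name, mat, comps) {
    sprintf(paste0('      <DataArray type="Float64" Name="%s" ',
                   'NumberOfComponents="%d" format="ascii">\n%s\n',
                   "      </DataArray>"),
            name, comps, paste(fmtNum(as.vector(t(mat))), collapse = " "))
  }
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    sprintf('  <PolyData label="%s">', cloud$label),
    sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="0">', m),
    "    <Points>",
    da("Points", cloud$points, 3L),
    "    </Points>",
    "    <PointData>",
    da("weight", matrix(cloud$weights, ncol = 1L), 1L),
    if (hasN) da("normals", cloud$normals, 3L),
    "    </PointData>",
    "    </Piece>",
    "  </PolyData>",
    "</VTKFile>")
  writeLines(xml, path)
}

readCloudVtp <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("malformed VTP '%s': %s", path, conditionMessage(e))))
  getArr <- function(xp) {
    node <- xml2::xml_find_first(doc, xp)
    if (inherits(node, "xml_missing")) return(NULL)
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  pts <- getArr(".//Points/DataArray")
  if (is.null(pts)) stop(sprintf("malformed VTP '%s': no Points array", path))
  pts <- matrix(pts, ncol = 3L, byrow = TRUE)
  m <- nrow(pts)
  w <- getArr(".//PointData/DataArray[@Name='weight']")
  if (is.null(w)) {
    warning(sprintf("VTP '%s' has no weight array; using uniform weights",
                    path))
    w <- rep(1 / m, m)
  }
  nrm <- getArr(".//PointData/DataArray[@Name='normals']")
  if (!is.null(nrm)) nrm <- matrix(nrm, ncol = 3L, byrow = TRUE)
  label <- xml2::xml_attr(xml2::xml_find_first(doc, ".//PolyData"), "label")
  weightedPointCloud(pts, w, nrm, label = label %||% "")
}
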