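# Plain-text I/O: legacy-ASCII VTK writers for surfaces and path lines, OBJ
# export, CSV metric tables, and mesh readers (legacy VTK unstructured and
# Gmsh 2.2 ASCII) with boundary tags normalized to inlet/outlet/wall.

# Triangulate the collocation lattice of a spectral surface (quads split
# into triangles, poles capped with fans).
surface_triangulation <- function(surface, q = surface$order) {
  g <- sh_grid(q)
  nlat <- g$nlat; nlon <- g$nlon
  idx <- function(i, j) (i - 1L) * nlon + ((j - 1L) %% nlon) + 1L
  tris <- list()
  for (i in seq_len(nlat - 1L)) {
    j <- seq_len(nlon)
    tris[[2L * i - 1L]] <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    tris[[2L * i]] <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  npts <- nlat * nlon
  # pole caps
  top <- cbind(npts + 1L, idx(1L, seq_len(nlon) + 1L), idx(1L, seq_len(nlon)))
  bot <- cbind(npts + 2L, idx(nlat, seq_len(nlon)), idx(nlat, seq_len(nlon) + 1L))
  b <- if (q == surface$order) sh_basis(surface$order) else sh_resample_basis(surface$order, q)
  pts <- b$Y %*% surface$coefficients
  pole_mats <- sh_eval_matrices(surface$order, c(1e-7, pi - 1e-7), c(0, 0), "Y")$Y
  pts <- rbind(pts, pole_mats %*% surface$coefficients)
  list(points = pts, triangles = do.call(rbind, c(tris, list(top, bot))))
}

#' Export a surface snapshot
#'
#' Writes the triangulated membrane surface as legacy-ASCII VTK polydata or
#' Wavefront OBJ.
#'
#' @param surface an [sh_surface()].
#' @param path output file; format from extension (`.vtk` or `.obj`).
#' @param scalars optional named list of per-vertex scalar vectors (VTK
#'   only; values for the two pole points are appended as means).
#' @return the path, invisibly.
#' @export
write_surface <- function(surface, path, scalars = NULL) {
  tr <- surface_triangulation(surface)
  ext <- tolower(tools::file_ext(path))
  np <- nrow(tr$points)
  if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", tr$points[, 1], tr$points[, 2],
                       tr$points[, 3]), con)
    writeLines(sprintf("f %d %d %d", tr$triangles[, 1], tr$triangles[, 2],
                       tr$triangles[, 3]), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "rbcflow surface", "ASCII",
                 "DATASET POLYDATA", sprintf("POINTS %d double", np)), con)
    writeLines(sprintf("%.9g %.9g %.9g", tr$points[, 1], tr$points[, 2],
                       tr$points[, 3]), con)
    nt <- nrow(tr$triangles)
    writeLines(sprintf("POLYGONS %d %d", nt, 4L * nt), con)
    writeLines(sprintf("3 %d %d %d", tr$triangles[, 1] - 1L,
                       tr$triangles[, 2] - 1L, tr$triangles[, 3] - 1L), con)
    if (!is.null(scalars)) {
      writeLines(sprintf("POINT_DATA %d", np), con)
      for (nm in names(scalars)) {
        v <- scalars[[nm]]
        if (length(v) == np - 2L) v <- c(v, mean(v), mean(v))
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.9g", v), con)
      }
    }
  }
  invisible(path)
}

#' Write path lines as VTK polylines
#'
#' One polyline per particle, with named per-vertex scalar arrays (e.g. a
#' damage metric from [damage_map()]).
#'
#' @param map a tibble with `cell_id` (or `particle`), `x`, `y`, `z` and any
#'   scalar columns.
#' @param path output `.vtk` file.
#' @param scalars character vector of scalar column names to attach.
#' @return the path, invisibly.
#' @export
write_pathlines_vtk <- function(map, path, scalars = "value") {
  id_col <- if ("cell_id" %in% names(map)) "cell_id" else "particle"
  map <- map[order(map[[id_col]], map$time), , drop = FALSE]
  ids <- unique(map[[id_col]])
  np <- nrow(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "rbcflow path lines", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", np)), con)
  writeLines(sprintf("%.9g %.9g %.9g", map$x, map$y, map$z), con)
  runs <- split(seq_len(np) - 1L, match(map[[id_col]], ids))
  total <- sum(vapply(runs, length, 1L)) + length(runs)
  writeLines(sprintf("LINES %d %d", length(runs), total), con)
  for (rr in runs) writeLines(paste(c(length(rr), rr), collapse = " "), con)
  sc <- intersect(scalars, names(map))
  if (length(sc)) {
    writeLines(sprintf("POINT_DATA %d", np), con)
    for (nm in sc) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", map[[nm]]), con)
    }
  }
  invisible(path)
}

#' Read a tetrahedral mesh
#'
#' Reads legacy-ASCII VTK unstructured grids (tetrahedra, with an optional
#' integer cell array naming boundary triangles) or Gmsh 2.2 ASCII `.msh`
#' files whose physical names include inlet/outlet/wall tags. Boundary
#' labels are normalized to `inlet`, `outlet`, `wall`; 1-based node indexing
#' is used internally regardless of the file dialect.
#'
#' @param path mesh file (`.vtk` or `.msh`).
#' @return a [tet_flow_field()] skeleton (single zero frame).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "msh") read_mesh_gmsh(path) else read_mesh_vtk(path)
}

read_mesh_gmsh <- function(path) {
  ln <- readLines(path)
  sec <- function(name) {
    i0 <- grep(paste0("^\\$", name, "$"), ln)
    i1 <- grep(paste0("^\\$End", name, "$"), ln)
    if (!length(i0)) return(NULL)
    ln[(i0 + 1L):(i1 - 1L)]
  }
  phys <- sec("PhysicalNames")
  phys_map <- list()
  if (!is.null(phys)) {
    for (l in phys[-1]) {
      p <- strsplit(trimws(l), "\\s+")[[1]]
      if (length(p) >= 3L) {
        nm <- tolower(gsub("\"", "", paste(p[-(1:2)], collapse = " ")))
        lab <- if (grepl("inlet", nm)) "inlet"
        else if (grepl("outlet", nm)) "outlet"
        else if (grepl("wall", nm)) "wall" else nm
        phys_map[[p[2]]] <- lab
      }
    }
  }
  nd <- sec("Nodes")
  nn <- as.integer(nd[1])
  nm <- matrix(as.numeric(unlist(strsplit(trimws(nd[2:(nn + 1L)]), "\\s+"))),
               ncol = 4L, byrow = TRUE)
  nodes <- nm[order(nm[, 1]), 2:4, drop = FALSE]
  el <- sec("Elements")
  ne <- as.integer(el[1])
  tets <- list(); bnd <- list()
  for (l in el[2:(ne + 1L)]) {
    p <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    typ <- p[2]; ntags <- p[3]
    conn <- p[(4L + ntags):length(p)]
    if (typ == 4L) tets[[length(tets) + 1L]] <- conn
    else if (typ == 2L) {
      lab <- phys_map[[as.character(p[4])]]
      if (is.null(lab)) lab <- "wall"
      bnd[[length(bnd) + 1L]] <- c(conn, lab)
    }
  }
  tets <- do.call(rbind, tets)
  bnd <- do.call(rbind, bnd)
  boundary <- data.frame(n1 = as.integer(bnd[, 1]), n2 = as.integer(bnd[, 2]),
                         n3 = as.integer(bnd[, 3]), label = bnd[, 4],
                         stringsAsFactors = FALSE)
  vol <- tet_volumes(nodes, tets)
  tets[vol < 0, c(3, 4)] <- tets[vol < 0, c(4, 3)]
  tet_flow_field(nodes, tets, boundary, matrix(0, nrow(nodes), 3))
}

read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  vals <- scan(text = ln[(ip + 1L):length(ln)], what = numeric(),
               n = 3L * np, quiet = TRUE)
  nodes <- matrix(vals, ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  hdr <- strsplit(ln[ic], "\\s+")[[1]]
  nc <- as.integer(hdr[2])
  cell_lines <- ln[(ic + 1L):(ic + nc)]
  it <- grep("^CELL_TYPES", ln)[1]
  types <- scan(text = ln[(it + 1L):length(ln)], what = integer(), n = nc,
                quiet = TRUE)
  label_arr <- NULL
  il <- grep("^SCALARS\\s+(boundary|label|tag)", ln, ignore.case = TRUE)
  if (length(il)) {
    label_arr <- scan(text = ln[(il[1] + 2L):length(ln)], what = integer(),
                      n = nc, quiet = TRUE)
  }
  tets <- list(); bnd <- list(); bl <- list()
  for (i in seq_len(nc)) {
    p <- as.integer(strsplit(trimws(cell_lines[i]), "\\s+")[[1]])
    if (types[i] == 10L) tets[[length(tets) + 1L]] <- p[2:5] + 1L
    else if (types[i] == 5L) {
      bnd[[length(bnd) + 1L]] <- p[2:4] + 1L
      bl[[length(bl) + 1L]] <- if (is.null(label_arr)) 3L else label_arr[i]
    }
  }
  tets <- do.call(rbind, tets)
  vol <- tet_volumes(nodes, tets)
  tets[vol < 0, c(3, 4)] <- tets[vol < 0, c(4, 3)]
  labmap <- c("inlet", "outlet", "wall")
  bmat <- do.call(rbind, bnd)
  boundary <- data.frame(n1 = bmat[, 1], n2 = bmat[, 2], n3 = bmat[, 3],
                         label = labmap[pmin(pmax(unlist(bl), 1L), 3L)],
                         stringsAsFactors = FALSE)
  tet_flow_field(nodes, tets, boundary, matrix(0, nrow(nodes), 3))
}

#' Write a pipe fixture mesh as legacy VTK
#'
#' Unstructured-grid export including boundary triangles with an integer
#' `boundary` cell array (1 inlet, 2 outlet, 3 wall), readable back with
#' [read_mesh()].
#'
#' @param field a [tet_flow_field()].
#' @param path output `.vtk` file.
#' @return the path, invisibly.
#' @export
write_mesh_vtk <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  np <- nrow(field$nodes)
  nt <- nrow(field$tets); nb <- nrow(field$boundary)
  writeLines(c("# vtk DataFile Version 3.0", "rbcflow mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", np)), con)
  writeLines(sprintf("%.9g %.9g %.9g", field$nodes[, 1], field$nodes[, 2],
                     field$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nt + nb, 5L * nt + 4L * nb), con)
  writeLines(sprintf("4 %d %d %d %d", field$tets[, 1] - 1L, field$tets[, 2] - 1L,
                     field$tets[, 3] - 1L, field$tets[, 4] - 1L), con)
  writeLines(sprintf("3 %d %d %d", field$boundary$n1 - 1L, field$boundary$n2 - 1L,
                     field$boundary$n3 - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt + nb), con)
  writeLines(c(rep("10", nt), rep("5", nb)), con)
  writeLines(sprintf("CELL_DATA %d", nt + nb), con)
  writeLines(c("SCALARS boundary int 1", "LOOKUP_TABLE default"), con)
  lab <- c(rep(0L, nt), match(field$boundary$label, c("inlet", "outlet", "wall")))
  writeLines(as.character(lab), con)
  invisible(path)
}

#' Write per-node velocity frames
#'
#' One whitespace-separated text file per frame (`u v w` per node) plus a
#' small index file with the period and frame count.
#'
#' @param field a [tet_flow_field()] with frames.
#' @param dir output directory (created).
#' @param prefix file-name prefix.
#' @return the index-file path, invisibly.
#' @export
write_frames <- function(field, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(field$frames)) {
    utils::write.table(field$frames[[i]],
                       file.path(dir, sprintf("%s_%03d.txt", prefix, i)),
                       row.names = FALSE, col.names = c("u", "v", "w"))
  }
  idx <- file.path(dir, paste0(prefix, "_index.txt"))
  writeLines(c(sprintf("period %.9g", field$period),
               sprintf("nframes %d", length(field$frames))), idx)
  invisible(idx)
}

#' Write a far-field history as CSV
#'
#' Columns: `t`, `Ux`, `Uy`, `Uz`, and the nine gradient entries `g11..g33`
#' (SI units), read back with [read_far_field_csv()].
#'
#' @param history a [far_field_history()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_far_field_csv <- function(history, path) {
  df <- data.frame(t = history$times, history$U, history$gradU)
  names(df) <- c("t", "Ux", "Uy", "Uz",
                 paste0("g", outer(1:3, 1:3, paste0)[cbind(rep(1:3, each = 3), rep(1:3, 3))]))
  names(df) <- c("t", "Ux", "Uy", "Uz",
                 c("g11", "g12", "g13", "g21", "g22", "g23", "g31", "g32", "g33"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_far_field_csv
#' @export
read_far_field_csv <- function(path) {
  df <- utils::read.csv(path)
  far_field_history(df$t, as.matrix(df[, c("Ux", "Uy", "Uz")]),
                    as.matrix(df[, paste0("g", c(11, 12, 13, 21, 22, 23, 31, 32, 33))]))
}
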