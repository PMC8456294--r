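#' Write a scalar field to a legacy VTK file
#'
#' Writes the node positions and a scalar (e.g. a density map or propagator
#' slice) as an ASCII legacy-VTK unstructured point cloud, viewable in
#' ParaView.  Axisymmetric domains are written in (x = r, y = 0, z) form.
#'
#' @param domain An `npc_domain`.
#' @param values Numeric vector of nodal values.
#' @param file Output path.
#' @param name Scalar field name.
#' @return The path, invisibly.
#' @export
write_vtk_points <- function(domain, values, file, name = "scalar") {
  stopifnot(length(values) == domain$n)
  pts <- if (domain$type == "axisym")
    cbind(domain$nodes[, "r"], 0, domain$nodes[, "z"])
  else domain$nodes
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "npcbarrier scalar field", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", domain$n)), con)
  utils::write.table(format(pts, digits = 7, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("POINT_DATA %d", domain$n),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(values, digits = 7, trim = TRUE), con)
  invisible(file)
}

#' Write a density map to VTK
#'
#' @param density An [mean_density()] result.
#' @param file Output path.
#' @export
write_vtk_density <- function(density, file) {
  write_vtk_points(density$domain, density$rho, file, name = "segment_density")
}

#' Write a critical-diameter report to JSON
#'
#' @param scan An `npc_scan`.
#' @param file Output path.
#' @export
write_dstar_json <- function(scan, file) {
  meta <- attr(scan, "meta")
  d_star <- critical_diameter(scan)
  jsonlite::write_json(list(kind = meta$kind,
                            d_star_nm = if (is.na(d_star)) NULL else d_star,
                            crossing = !is.na(d_star)),
                       file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
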