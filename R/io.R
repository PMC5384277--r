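# File interchange: binary STL of the phantom surface of revolution,
# legacy-ASCII VTK structured grids with optional fields, CSV profile and
# residual tables, JSON configuration round-trips.

#' Export the phantom surface of revolution as binary STL
#'
#' @param phantom an `airway_phantom`
#' @param path output file
#' @param n_theta azimuthal facets (default 48)
#' @param n_z axial stations (default 200)
#' @return `path`, invisibly
#' @export
write_stl <- function(phantom, path, n_theta = 48, n_z = 200) {
  z <- seq(0, phantom$length, length.out = n_z)
  r <- phantom$radius_fun(z)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)
  tri <- list()
  for (i in seq_len(n_z - 1)) {
    for (k in seq_len(n_theta)) {
      p00 <- c(r[i] * cos(th[k]), r[i] * sin(th[k]), z[i])
      p01 <- c(r[i] * cos(th[k + 1]), r[i] * sin(th[k + 1]), z[i])
      p10 <- c(r[i + 1] * cos(th[k]), r[i + 1] * sin(th[k]), z[i + 1])
      p11 <- c(r[i + 1] * cos(th[k + 1]), r[i + 1] * sin(th[k + 1]),
               z[i + 1])
      tri[[length(tri) + 1]] <- rbind(p00, p01, p11)
      tri[[length(tri) + 1]] <- rbind(p00, p11, p10)
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(length(tri)), con, size = 4, endian = "little")
  for (t3 in tri) {
    e1 <- t3[2, ] - t3[1, ]; e2 <- t3[3, ] - t3[1, ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, t(t3))), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Export a grid (and optionally a flow field) as legacy VTK
#'
#' Writes the meridional (z, r) structured grid as a VTK legacy ASCII
#' STRUCTURED_GRID; with a field, attaches pressure and velocity point
#' data interpolated to the grid nodes.
#'
#' @param grid an `axi_grid`
#' @param path output file
#' @param field optional `flow_field`
#' @return `path`, invisibly
#' @export
write_vtk <- function(grid, path, field = NULL) {
  nzp <- grid$nz + 1; nrp <- grid$nr + 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric airway grid (meridional plane, metres)",
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nzp, nrp),
               sprintf("POINTS %d double", nzp * nrp)), con)
  pts <- character(nzp * nrp)
  k <- 1
  for (j in seq_len(nrp)) {
    for (i in seq_len(nzp)) {
      pts[k] <- sprintf("%.9g %.9g 0", grid$zf[i],
                        grid$etaf[j] * grid$Rf[i])
      k <- k + 1
    }
  }
  writeLines(pts, con)
  if (!is.null(field)) {
    # node-interpolated scalars: nearest cell-centered values padded
    pad <- function(m) {  # nz x nr -> (nz+1) x (nr+1)
      m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
      m2 <- cbind(m2[, 1, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
      (m2[-1, -1] + m2[-1, -ncol(m2)] + m2[-nrow(m2), -1] +
         m2[-nrow(m2), -ncol(m2)]) / 4
    }
    pn <- pad(field$p)
    writeLines(c(sprintf("POINT_DATA %d", nzp * nrp),
                 "SCALARS pressure double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", as.numeric(pn)), con)
    un <- rbind(field$u, field$u[nrow(field$u), ])[seq_len(nzp), ]
    un <- cbind(un[, 1], un, un[, ncol(un)])
    un <- (un[, -1] + un[, -ncol(un)]) / 2
    vn <- rbind(field$v[1, ], field$v, field$v[nrow(field$v), ])
    vn <- (vn[-1, ] + vn[-nrow(vn), ])[seq_len(nzp), ]
    writeLines("VECTORS velocity double", con)
    writeLines(sprintf("%.9g %.9g 0", as.numeric(un), as.numeric(vn)), con)
  }
  invisible(path)
}

#' Export the (z, radius, area) profile as CSV
#' @param phantom an `airway_phantom`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_profile_csv <- function(phantom, path) {
  utils::write.csv(data.frame(z_mm = phantom$z, radius_mm = phantom$radius,
                              area_mm2 = phantom$area),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write / read a pipeline configuration as JSON
#'
#' The configuration round-trips losslessly: `read_config(write_config(x))`
#' reproduces `x`.
#'
#' @param config a [pipeline_config()]
#' @param path JSON file
#' @return `path` (write) or the configuration (read)
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # a NULL component (e.g. out_dir) serializes as {}; map it back
  raw <- lapply(raw, function(x) {
    if (is.list(x) && length(x) == 0) NULL else x
  })
  do.call(pipeline_config, raw)
}
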