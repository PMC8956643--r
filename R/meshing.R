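# Linear tetrahedral meshes: generation on a binary mask, landmark-free
# morphing through registration transforms, and per-element quality metrics.
# Morphing moves vertices only — connectivity is never touched — so meshes
# morphed from one canonical mesh are isotopological across the population.

#' Tetrahedral mesh
#'
#' @param vertices V x 3 matrix of world coordinates, mm.
#' @param elements E x 4 matrix of 1-based vertex indices, consistently
#'   oriented (positive signed volumes in the canonical mesh).
#' @param provenance `"canonical"` or an identifier of the specimen the mesh
#'   was morphed onto.
#' @export
tet_mesh <- function(vertices, elements, provenance = "canonical") {
  vertices <- as.matrix(vertices)
  elements <- matrix(as.integer(elements), ncol = 4)
  stopifnot(ncol(vertices) == 3, max(elements) <= nrow(vertices), min(elements) >= 1)
  structure(list(vertices = vertices, elements = elements, provenance = provenance),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh (", x$provenance, "): ", nrow(x$vertices), " vertices, ",
      nrow(x$elements), " tetrahedra\n", sep = "")
  invisible(x)
}

#' Signed volumes, centroids and edge lengths of mesh elements
#'
#' @param mesh a [tet_mesh].
#' @export
element_volumes <- function(mesh) {
  v <- mesh$vertices; e <- mesh$elements
  a <- v[e[, 2], , drop = FALSE] - v[e[, 1], , drop = FALSE]
  b <- v[e[, 3], , drop = FALSE] - v[e[, 1], , drop = FALSE]
  cc <- v[e[, 4], , drop = FALSE] - v[e[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
   a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
   a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' @rdname element_volumes
#' @export
element_centroids <- function(mesh) {
  v <- mesh$vertices; e <- mesh$elements
  (v[e[, 1], , drop = FALSE] + v[e[, 2], , drop = FALSE] +
   v[e[, 3], , drop = FALSE] + v[e[, 4], , drop = FALSE]) / 4
}

#' @rdname element_volumes
#' @export
edge_lengths <- function(mesh) {
  e <- mesh$elements
  pairs <- rbind(e[, c(1, 2)], e[, c(1, 3)], e[, c(1, 4)],
                 e[, c(2, 3)], e[, c(2, 4)], e[, c(3, 4)])
  pairs <- unique(cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])))
  sqrt(rowSums((mesh$vertices[pairs[, 1], , drop = FALSE] -
                mesh$vertices[pairs[, 2], , drop = FALSE])^2))
}

# Kuhn (Freudenthal) subdivision of the unit cube into six conforming,
# positively oriented tetrahedra (corner offsets in binary index order).
kuhn_tets <- local({
  corner_id <- function(p) 1L + p[1] + 2L * p[2] + 4L * p[3]
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  t(vapply(perms, function(pr) {
    p <- c(0L, 0L, 0L)
    ids <- integer(4); ids[1] <- corner_id(p)
    for (k in 1:3) { p[pr[k]] <- 1L; ids[k + 1] <- corner_id(p) }
    ids
  }, integer(4)))
})

#' Mesh a binary mask with linear tetrahedra
#'
#' Lattice mesher: the mask domain is covered with a regular cube grid whose
#' cell size is chosen so the median tetrahedron edge comes out near
#' `edge_length`; cells whose centre lies inside the mask are each split
#' into six conforming tetrahedra (Kuhn subdivision). If the included cells
#' form several connected components, the largest is kept with a warning.
#' The mesh volume tracks the mask voxel volume within a few percent for
#' smooth shapes resolved by several cells.
#'
#' @param mask binary 3D array or [masked_image] (whose whole-bone mask is
#'   then meshed — pass the trabecular mask array for HMA meshes).
#' @param edge_length characteristic element edge length, mm.
#' @param spacing,origin geometry of `mask` when given as a plain array.
#' @return a [tet_mesh] with provenance `"canonical"`.
#' @export
mesh_from_mask <- function(mask, edge_length, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0)) {
  if (inherits(mask, "masked_image")) {
    spacing <- mask$spacing; origin <- mask$origin; mask <- mask$mask > 0
  } else mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  if (edge_length <= 0) stop("edge_length must be > 0")
  # cube side: tet edges in a Kuhn cell are {h, h*sqrt(2), h*sqrt(3)};
  # h = edge_length / 1.2 puts the median shared edge near edge_length
  h <- edge_length / 1.2
  idx <- which(mask, arr.ind = TRUE) - 1L
  lo_w <- origin + (apply(idx, 2, min) - 0.5) * spacing
  hi_w <- origin + (apply(idx, 2, max) + 0.5) * spacing
  nc <- pmax(1L, as.integer(ceiling((hi_w - lo_w) / h)))
  # cell (i,j,k) 0-based spans lo_w + [i, i+1] * h
  centres <- lapply(1:3, function(a) lo_w[a] + (seq_len(nc[a]) - 0.5) * h)
  cc <- as.matrix(expand.grid(centres[[1]], centres[[2]], centres[[3]]))
  geom <- list(dim = dim(mask), spacing = spacing, origin = origin)
  inside <- interp_nearest(array(as.numeric(mask), dim(mask)),
                           world_to_index(geom, cc)) > 0.5
  cells <- array(inside, nc)
  if (!any(cells)) stop("mesher failure: no grid cell centre falls inside the mask")
  comp <- largest_component(cells)
  if (comp$n_components > 1L) {
    warning("mask split into ", comp$n_components,
            " components; meshing the largest")
  }
  cells <- comp$component
  cell_idx <- which(cells, arr.ind = TRUE) - 1L
  np <- nc + 1L
  vert_id <- function(i, j, k) 1 + i + j * np[1] + k * np[1] * np[2]
  elems <- matrix(0L, nrow(cell_idx) * 6L, 4L)
  row <- 1L
  for (tt in 1:6) {
    ids <- kuhn_tets[tt, ]
    cols <- sapply(ids, function(cid) {
      p <- c((cid - 1L) %% 2L, ((cid - 1L) %/% 2L) %% 2L, (cid - 1L) %/% 4L)
      vert_id(cell_idx[, 1] + p[1], cell_idx[, 2] + p[2], cell_idx[, 3] + p[3])
    })
    elems[seq(row, row + nrow(cell_idx) - 1L), ] <- cols
    row <- row + nrow(cell_idx)
  }
  used <- sort(unique(as.integer(elems)))
  remap <- integer(prod(np)); remap[used] <- seq_along(used)
  elems <- matrix(remap[elems], ncol = 4)
  u0 <- used - 1L
  vi <- u0 %% np[1]; vj <- (u0 %/% np[1]) %% np[2]; vk <- u0 %/% (np[1] * np[2])
  verts <- cbind(lo_w[1] + vi * h, lo_w[2] + vj * h, lo_w[3] + vk * h)
  mesh <- tet_mesh(verts, elems)
  neg <- element_volumes(mesh) < 0
  if (any(neg)) mesh$elements[neg, c(3, 4)] <- mesh$elements[neg, c(4, 3)]
  mesh
}

#' Morph a mesh through a transform
#'
#' Moves every vertex through the fixed-to-moving point map (canonical to
#' individual direction); connectivity is untouched, preserving
#' isotopology. Elements whose signed volume becomes negative (inverted by
#' the deformation) are counted in the `n_inverted` attribute.
#'
#' @param mesh a [tet_mesh] (canonical space).
#' @param t a transform (e.g. the per-specimen composite from the SDM).
#' @param provenance label for the morphed mesh.
#' @export
morph_mesh <- function(mesh, t, provenance = "morphed") {
  out <- tet_mesh(transform_points(t, mesh$vertices), mesh$elements, provenance)
  attr(out, "n_inverted") <- sum(element_volumes(out) < 0)
  out
}

tet_face_areas <- function(v, e) {
  area <- function(p, q, r) {
    u <- q - p; w <- r - p
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    sqrt(rowSums(cr^2)) / 2
  }
  p1 <- v[e[, 1], , drop = FALSE]; p2 <- v[e[, 2], , drop = FALSE]
  p3 <- v[e[, 3], , drop = FALSE]; p4 <- v[e[, 4], , drop = FALSE]
  cbind(area(p2, p3, p4),  # face opposite vertex 1
        area(p1, p3, p4),
        area(p1, p2, p4),
        area(p1, p2, p3))
}

#' Tet-collapse quality metric
#'
#' Per element, the minimum over the four vertices of the vertex height
#' divided by the square root of the opposite face area, normalized by the
#' regular-tetrahedron value `2 * sqrt(2) * 3^(-3/4)` so an optimal
#' (regular) tetrahedron scores exactly 1 and a fully collapsed one 0.
#' Scale- and rigid-motion-invariant; clamped to \[0, 1\].
#'
#' @param mesh a [tet_mesh].
#' @return numeric vector, one value per element.
#' @export
tet_collapse <- function(mesh) {
  A <- tet_face_areas(mesh$vertices, mesh$elements)
  V <- abs(element_volumes(mesh))
  ratios <- 3 * V / A / sqrt(A)   # h_i / sqrt(A_i), h_i = 3V / A_i
  ratios[!is.finite(ratios)] <- 0
  val <- apply(ratios, 1, min) / (2 * sqrt(2) * 3^(-3 / 4))
  pmin(pmax(val, 0), 1)
}

tet_circumradius <- function(v, e) {
  p1 <- v[e[, 1], , drop = FALSE]
  out <- rep(NA_real_, nrow(e))
  b <- cbind(rowSums((v[e[, 2], , drop = FALSE])^2) - rowSums(p1^2),
             rowSums((v[e[, 3], , drop = FALSE])^2) - rowSums(p1^2),
             rowSums((v[e[, 4], , drop = FALSE])^2) - rowSums(p1^2)) / 2
  for (i in seq_len(nrow(e))) {
    A <- rbind(v[e[i, 2], ] - v[e[i, 1], ],
               v[e[i, 3], ] - v[e[i, 1], ],
               v[e[i, 4], ] - v[e[i, 1], ])
    ctr <- tryCatch(solve(A, b[i, ]), error = function(err) NULL)
    if (!is.null(ctr)) out[i] <- sqrt(sum((ctr - v[e[i, 1], ])^2))
  }
  out
}

#' Volume-skew quality metric
#'
#' Per element, `(V_ideal - V) / V_ideal`, where `V_ideal` is the volume of
#' the equilateral tetrahedron sharing the element's circumradius: 0 for an
#' equilateral element, 1 for a degenerate one (coplanar vertices, whose
#' circumsphere is undefined, score 1). Clamped to \[0, 1\].
#'
#' @param mesh a [tet_mesh].
#' @return numeric vector, one value per element.
#' @export
volume_skew <- function(mesh) {
  R <- tet_circumradius(mesh$vertices, mesh$elements)
  V <- abs(element_volumes(mesh))
  a_ideal <- sqrt(8 / 3) * R
  v_ideal <- a_ideal^3 / (6 * sqrt(2))
  val <- (v_ideal - V) / v_ideal
  val[!is.finite(val)] <- 1
  pmin(pmax(val, 0), 1)
}

#' Aspect ratio (longest edge over minimum height)
#'
#' Reported alongside tet-collapse and volume-skew; >= 1, with large values
#' flagging sliver elements. The conventional acceptance guideline used for
#' morphed meshes is fewer than 5% of elements above 5.
#'
#' @param mesh a [tet_mesh].
#' @export
aspect_ratio <- function(mesh) {
  v <- mesh$vertices; e <- mesh$elements
  longest <- matrix(0, nrow(e), 6)
  combs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in seq_along(combs)) {
    longest[, k] <- sqrt(rowSums((v[e[, combs[[k]][1]], , drop = FALSE] -
                                  v[e[, combs[[k]][2]], , drop = FALSE])^2))
  }
  lmax <- apply(longest, 1, max)
  A <- tet_face_areas(v, e)
  V <- abs(element_volumes(mesh))
  hmin <- apply(3 * V / A, 1, min)
  out <- lmax / hmin
  out[!is.finite(out)] <- Inf
  out
}

#' Summarise mesh quality
#'
#' @param mesh a [tet_mesh].
#' @return data.frame with mean, sd, min, max of tet-collapse, volume-skew
#'   and aspect ratio plus the failure fractions (volume-skew > 0.9,
#'   aspect ratio > 5).
#' @export
mesh_quality <- function(mesh) {
  tc <- tet_collapse(mesh); vs <- volume_skew(mesh); ar <- aspect_ratio(mesh)
  summ <- function(x) c(mean = mean(x[is.finite(x)]), sd = stats::sd(x[is.finite(x)]),
                        min = min(x), max = max(x[is.finite(x)]))
  out <- data.frame(metric = c("tet_collapse", "volume_skew", "aspect_ratio"),
                    rbind(summ(tc), summ(vs), summ(ar)))
  attr(out, "pct_failed_volume_skew") <- 100 * mean(vs > 0.9)
  attr(out, "pct_failed_aspect_ratio") <- 100 * mean(!is.finite(ar) | ar > 5)
  out
}

#' Write / read a tetrahedral mesh as legacy VTK
#'
#' ASCII legacy VTK unstructured grid with optional per-element (cell data)
#' scalar fields; element ordering is preserved on round trip.
#'
#' @param mesh a [tet_mesh].
#' @param path output `.vtk` file.
#' @param cell_data named list of numeric vectors (one value per element).
#' @export
write_mesh_vtk <- function(mesh, path, cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); ne <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               paste("tet mesh:", mesh$provenance),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nv, "double")), con)
  utils::write.table(format(mesh$vertices, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste("CELLS", ne, ne * 5), con)
  utils::write.table(cbind(4L, mesh$elements - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(paste("CELL_TYPES", ne), con)
  writeLines(as.character(rep(10L, ne)), con)
  if (length(cell_data)) {
    writeLines(paste("CELL_DATA", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
      writeLines(formatC(cell_data[[nm]], format = "g", digits = 17), con)
    }
  }
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):(ip + nv)], quiet = TRUE)
  verts <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  ne <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cl <- scan(text = lines[(ic + 1):(ic + ne)], quiet = TRUE)
  cl <- matrix(cl, ncol = 5, byrow = TRUE)
  stopifnot(all(cl[, 1] == 4))
  mesh <- tet_mesh(verts, cl[, 2:5] + 1L)
  cd_start <- grep("^CELL_DATA", lines)
  cell_data <- list()
  if (length(cd_start)) {
    i <- cd_start[1] + 1L
    while (i <= length(lines)) {
      if (grepl("^SCALARS", lines[i])) {
        nm <- strsplit(lines[i], "\\s+")[[1]][2]
        vals <- scan(text = lines[(i + 2):(i + 1 + ne)], quiet = TRUE)
        cell_data[[nm]] <- vals
        i <- i + 2L + ne
      } else i <- i + 1L
    }
  }
  attr(mesh, "cell_data") <- cell_data
  mesh
}
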