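# Triangle meshes: construction, derived geometry (areas, adjacency, edge
# lengths), synthetic mesh generators, boundary detection, geodesic discs,
# and plain-text OFF input/output.

#' Build a triangle mesh with derived geometry
#'
#' @param vertices Numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces Integer matrix, one row per triangle, 1-based vertex indices.
#' @return A `triangle_mesh`: list with `vertices`, `faces`, `edges` (unique
#'   vertex pairs), `edge_lengths` (mm), `mean_edge` (mm), `triangle_areas`
#'   (mm^2), `vertex_areas` (barycentric one-third lumping, mm^2), and
#'   `adjacency` (sparse symmetric pattern).
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  n <- nrow(vertices)
  if (any(faces < 1L | faces > n)) stop("faces index nonexistent vertices")

  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- (e[, 1] - 1) * n + e[, 2]
  edge_face_count <- table(key)
  edges <- e[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  edge_lengths <- sqrt(rowSums((vertices[edges[, 1], , drop = FALSE] -
                                vertices[edges[, 2], , drop = FALSE])^2))

  ab <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  ac <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  tri_areas <- 0.5 * sqrt(rowSums(cr^2))
  if (any(tri_areas <= 0)) stop("degenerate (zero-area) triangle in mesh")
  inc <- rowsum(rep(tri_areas / 3, 3), as.vector(faces))
  vertex_areas <- numeric(n)
  vertex_areas[as.integer(rownames(inc))] <- inc

  adjacency <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                                    j = c(edges[, 2], edges[, 1]),
                                    x = 1, dims = c(n, n))
  # edge ids seen in exactly one face lie on the boundary
  bkey <- as.numeric(names(edge_face_count))[edge_face_count == 1]
  boundary_edges <- cbind((bkey - 1) %/% n + 1, (bkey - 1) %% n + 1)

  structure(list(vertices = vertices, faces = faces, edges = edges,
                 edge_lengths = edge_lengths, mean_edge = mean(edge_lengths),
                 triangle_areas = tri_areas, vertex_areas = vertex_areas,
                 adjacency = adjacency, boundary_edges = boundary_edges),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, %d edges\n",
              nrow(x$vertices), nrow(x$faces), nrow(x$edges)))
  cat(sprintf("  mean edge %.3f mm, total area %.1f mm^2, %d boundary edges\n",
              x$mean_edge, sum(x$triangle_areas), nrow(x$boundary_edges)))
  invisible(x)
}

#' Vertices on the mesh boundary
#'
#' A vertex is on the boundary when it belongs to an edge shared by exactly
#' one triangle. Closed meshes (spheres) have none.
#'
#' @param mesh A `triangle_mesh`.
#' @return Integer vector of boundary vertex indices (possibly empty).
#' @export
mesh_boundary_vertices <- function(mesh) {
  sort(unique(as.vector(mesh$boundary_edges)))
}

.icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v / sqrt(rowSums(v^2))[1], f = f)
}

.subdivide <- function(v, f) {
  n <- nrow(v)
  midkey <- new.env(hash = TRUE)
  verts <- v
  getmid <- function(a, b) {
    k <- paste(min(a, b), max(a, b))
    id <- midkey[[k]]
    if (is.null(id)) {
      verts <<- rbind(verts, (v[a, ] + v[b, ]) / 2)
      id <- nrow(verts)
      midkey[[k]] <- id
    }
    id
  }
  nf <- matrix(0L, nrow(f) * 4, 3)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
    ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
    nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                     c(c, ca, bc), c(ab, bc, ca))
  }
  list(v = verts, f = nf)
}

#' Generate a synthetic analysis mesh
#'
#' Either a closed icosphere or a flat equilateral-lattice patch, with a
#' prescribed mean edge length — a stand-in for a registered cortical
#' template mesh when exercising the pipeline on simulated data.
#'
#' @param kind `"flat_patch"` (size = side length(s) in mm) or `"sphere"`
#'   (size = approximate radius in mm; the radius is rescaled so the mean
#'   edge hits the target, which is what smoothing and resel computations
#'   depend on).
#' @param target_edge_mm Desired mean edge length in mm (default 0.77).
#' @param size Patch side length in mm (scalar or `c(width, height)`) or
#'   approximate sphere radius.
#' @return A `triangle_mesh`. Realized mean edge is within 10% of target.
#' @export
make_mesh <- function(kind = c("flat_patch", "sphere"), target_edge_mm = 0.77,
                      size = 40) {
  kind <- match.arg(kind)
  stopifnot(target_edge_mm > 0)
  if (kind == "flat_patch") {
    sz <- rep(size, length.out = 2)
    h <- target_edge_mm
    dy <- h * sqrt(3) / 2
    nc <- max(2L, round(sz[1] / h) + 1L)
    nr <- max(2L, round(sz[2] / dy) + 1L)
    if (nc * nr < 100) stop("patch too small: fewer than 100 vertices")
    idx <- function(i, j) (j - 1L) * nc + i  # i column, j row
    xs <- rep(seq_len(nc) - 1L, nr) * h +
      rep((seq_len(nr) - 1L) %% 2L, each = nc) * h / 2
    ys <- rep(seq_len(nr) - 1L, each = nc) * dy
    v <- cbind(xs, ys, 0)
    faces <- vector("list", nr - 1L)
    for (j in seq_len(nr - 1L)) {
      i <- seq_len(nc - 1L)
      if ((j - 1L) %% 2L == 0L) {  # row j unshifted, row j+1 shifted right
        f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
        f2 <- cbind(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
      } else {
        f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
        f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
      }
      faces[[j]] <- rbind(f1, f2)
    }
    triangle_mesh(v, do.call(rbind, faces))
  } else {
    ico <- .icosahedron()
    # icosahedron edge at unit circumradius is ~1.051; halves per subdivision
    n_sub <- max(0L, round(log2(1.05146 * size / target_edge_mm)))
    for (k in seq_len(n_sub)) ico <- .subdivide(ico$v, ico$f)
    v <- ico$v / sqrt(rowSums(ico$v^2))
    if (nrow(v) < 100) stop("sphere too small: fewer than 100 vertices")
    m <- triangle_mesh(v, ico$f)
    triangle_mesh(v * (target_edge_mm / m$mean_edge), ico$f)
  }
}

#' Geodesic distances from a source vertex
#'
#' Shortest-path (edge-graph) distances, a standard approximation of
#' geodesic distance at the scales used for effect discs and kernels.
#'
#' @param mesh A `triangle_mesh`.
#' @param from Source vertex index.
#' @return Numeric vector of distances (mm) to every vertex.
#' @export
geodesic_distances <- function(mesh, from) {
  g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
  as.vector(igraph::distances(g, v = from, weights = mesh$edge_lengths))
}

#' Vertices within a geodesic disc
#'
#' @param mesh A `triangle_mesh`.
#' @param center Center vertex index.
#' @param radius_mm Disc radius in mm.
#' @return Integer vertex indices with geodesic distance `<= radius_mm`.
#' @export
geodesic_disc <- function(mesh, center, radius_mm) {
  stopifnot(radius_mm > 0)
  which(geodesic_distances(mesh, center) <= radius_mm)
}

#' Read / write a mesh in OFF format
#'
#' Plain-text OFF is the portable fallback interchange format used by this
#' package for surface geometry.
#'
#' @param path File path.
#' @return `read_off()`: a `triangle_mesh`.
#' @export
read_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (toupper(trimws(ln[1])) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = ln[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(scan(text = paste(ln[3:(2 + nv)], collapse = "\n"), quiet = TRUE),
              ncol = 3, byrow = TRUE)
  fr <- matrix(scan(text = paste(ln[(3 + nv):(2 + nv + nf)], collapse = "\n"),
                    quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fr[, 1] != 3)) stop("non-triangular face in OFF file")
  triangle_mesh(v, fr[, 2:4] + 1L)
}

#' @rdname read_off
#' @param mesh A `triangle_mesh` to write.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  utils::write.table(format(mesh$vertices, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
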