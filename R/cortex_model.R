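# Toy cortical geometry: two-hemisphere deformed spherical-cap patches with
# contiguous anatomical-style ROI parcels, triangle-mesh adjacency, and a
# smooth synthetic sensor lead field.

#' Default posterior-cortex ROI set
#'
#' The 16 anatomical-style regions of interest used throughout the pipeline,
#' mirroring a standard parcellation of posterior cortex (primary visual,
#' ventral "what"-stream, parietal "where"-stream, and temporal regions).
#'
#' @return character vector of 16 ROI names.
#' @export
default_roi_names <- function() {
  c("pericalcarine", "cuneus", "lingual", "fusiform",
    "inferior_temporal", "lateral_occipital", "precuneus", "isthmus_cingulate",
    "inferior_parietal", "superior_parietal", "STS_banks", "middle_temporal",
    "superior_temporal", "supramarginal", "parahippocampal", "posterior_cingulate")
}

#' Uniform ROI fraction specification
#'
#' @param roi_names character vector of ROI names.
#' @return named numeric vector of equal fractions summing to 1.
#' @export
uniform_roi_spec <- function(roi_names = default_roi_names()) {
  stats::setNames(rep(1 / length(roi_names), length(roi_names)), roi_names)
}

# Largest-remainder apportionment of n among fractions (all parts >= 1).
apportion_counts <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  base[base < 1] <- 1
  deficit <- n - sum(base)
  if (deficit > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    idx <- rep_len(ord, deficit)
    for (i in idx) base[i] <- base[i] + 1
  } else if (deficit < 0) {
    ord <- order(base, decreasing = TRUE)
    k <- -deficit
    j <- 1
    while (k > 0) {
      i <- ord[(j - 1) %% length(ord) + 1]
      if (base[i] > 1) { base[i] <- base[i] - 1; k <- k - 1 }
      j <- j + 1
    }
  }
  base
}

# Row-major grid layout holding exactly n vertices: full rows of nc columns
# plus an optional shorter last row.
grid_rows <- function(n) {
  nc <- ceiling(n / floor(sqrt(n)))
  nr_full <- n %/% nc
  rem <- n %% nc
  lens <- c(rep(nc, nr_full), if (rem > 0) rem)
  list(lens = lens, nc = nc)
}

# Triangulate between two consecutive rows given start indices and lengths
# (len2 <= len1). Returns a matrix of vertex-index triples.
strip_triangles <- function(start1, len1, start2, len2) {
  tris <- list()
  m <- min(len1, len2)
  if (m >= 2) {
    for (j in seq_len(m - 1)) {
      a <- start1 + j - 1; b <- start2 + j - 1
      tris[[length(tris) + 1L]] <- c(a, b, b + 1)
      tris[[length(tris) + 1L]] <- c(a, b + 1, a + 1)
    }
  }
  if (len1 > len2 && len2 >= 1) {
    b_last <- start2 + len2 - 1
    for (j in seq(from = max(len2, 1), to = len1 - 1)) {
      a <- start1 + j - 1
      tris[[length(tris) + 1L]] <- c(a, b_last, a + 1)
    }
  }
  do.call(rbind, tris)
}

rotation_to <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  c_ <- sum(z * axis)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) return(diag(3) * sign(c_))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

build_hemisphere_patch <- function(n, side, seed) {
  g <- grid_rows(n)
  lens <- g$lens; nc <- g$nc
  n_rows <- length(lens)
  # seeded smooth radial deformation
  bump <- with_seed(seed, list(a = stats::runif(3, 0.005, 0.02),
                               ph = stats::runif(3, 0, 2 * pi),
                               ch = stats::runif(3, 0, 2 * pi)))
  r0 <- 50  # mm, cortical shell radius
  axis <- if (side == "left") c(-0.45, -0.55, 0.70) else c(0.45, -0.55, 0.70)
  center <- if (side == "left") c(-10, 0, 0) else c(10, 0, 0)
  rot <- rotation_to(axis)

  pos <- matrix(0, n, 3)
  radial <- matrix(0, n, 3)
  idx <- 0L
  for (r in seq_len(n_rows)) {
    v <- if (n_rows > 1) (r - 1) / (n_rows - 1) else 0
    for (j in seq_len(lens[r])) {
      idx <- idx + 1L
      u <- if (nc > 1) (j - 1) / (nc - 1) else 0
      polar <- 0.15 + v * 1.0
      azim <- (u - 0.5) * 1.5
      d_local <- c(sin(polar) * cos(azim + pi / 2), sin(polar) * sin(azim + pi / 2), cos(polar))
      d <- as.vector(rot %*% d_local)
      rad <- r0 * (1 + sum(bump$a * sin(seq_len(3) * pi * u + bump$ph) *
                             sin(seq_len(3) * pi * v + bump$ch)))
      pos[idx, ] <- center + rad * d
      radial[idx, ] <- d
    }
  }

  starts <- cumsum(c(1, lens[-n_rows]))
  tris <- list()
  for (r in seq_len(n_rows - 1)) {
    tris[[r]] <- strip_triangles(starts[r], lens[r], starts[r + 1], lens[r + 1])
  }
  tris <- do.call(rbind, tris)

  # vertex normals: average incident face normals, oriented outward
  nrm <- matrix(0, n, 3)
  for (k in seq_len(nrow(tris))) {
    t3 <- tris[k, ]
    e1 <- pos[t3[2], ] - pos[t3[1], ]
    e2 <- pos[t3[3], ] - pos[t3[1], ]
    fn <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    ctr_dir <- radial[t3[1], ] + radial[t3[2], ] + radial[t3[3], ]
    if (sum(fn * ctr_dir) < 0) fn <- -fn
    for (vv in t3) nrm[vv, ] <- nrm[vv, ] + fn
  }
  zero_rows <- rowSums(nrm^2) < 1e-20
  nrm[zero_rows, ] <- radial[zero_rows, ]
  nrm <- nrm / sqrt(rowSums(nrm^2))

  list(positions = pos, triangles = tris, normals = nrm)
}

# FIFO region growing from farthest-point-sampled seeds; keeps every parcel
# connected and close to its target size.
grow_rois <- function(positions, neighbors, roi_names, targets, seed) {
  n <- nrow(positions)
  k <- length(roi_names)
  seeds <- integer(k)
  seeds[1] <- with_seed(seed, sample.int(n, 1))
  mind <- colSums((t(positions) - positions[seeds[1], ])^2)
  if (k > 1) for (i in 2:k) {
    seeds[i] <- which.max(mind)
    di <- colSums((t(positions) - positions[seeds[i], ])^2)
    mind <- pmin(mind, di)
  }
  label <- integer(n)  # 0 = unassigned
  sizes <- integer(k)
  queues <- vector("list", k)
  for (i in seq_len(k)) {
    label[seeds[i]] <- i
    sizes[i] <- 1L
    queues[[i]] <- neighbors[[seeds[i]]]
  }
  repeat {
    qlen <- vapply(queues, length, 1L)
    active <- which(qlen > 0)
    if (length(active) == 0) break
    i <- active[which.max(targets[active] - sizes[active])]
    v <- queues[[i]][1]
    queues[[i]] <- queues[[i]][-1]
    if (label[v] == 0L) {
      label[v] <- i
      sizes[i] <- sizes[i] + 1L
      queues[[i]] <- c(queues[[i]], neighbors[[v]][label[neighbors[[v]]] == 0L])
    }
  }
  # absorb any stragglers into a labeled neighbor
  while (any(label == 0L)) {
    progressed <- FALSE
    for (v in which(label == 0L)) {
      lab_nb <- label[neighbors[[v]]]
      lab_nb <- lab_nb[lab_nb > 0]
      if (length(lab_nb)) { label[v] <- lab_nb[1]; progressed <- TRUE }
    }
    if (!progressed) { label[label == 0L] <- 1L; break }
  }
  roi_names[label]
}

neighbors_from_triangles <- function(n, triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  nb <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    nb[[e[k, 1]]] <- c(nb[[e[k, 1]]], e[k, 2])
    nb[[e[k, 2]]] <- c(nb[[e[k, 2]]], e[k, 1])
  }
  list(neighbors = nb, edges = e)
}

#' Build a toy two-hemisphere cortical mesh
#'
#' Constructs two disjoint deformed spherical-cap patches (left and right
#' hemisphere), triangulated from a structured grid, with outward unit
#' normals and contiguous ROI parcels produced by seeded region growing from
#' farthest-point-sampled seeds. A stand-in for a decimated cortical surface
#' (on the order of 1,000 vertices per hemisphere at full scale); all
#' downstream machinery (adjacency-based clustering, ROI averaging, lead
#' fields) operates on it exactly as it would on real anatomy.
#'
#' @param n_vertices_per_hemisphere integer >= 16, vertices per hemisphere.
#' @param roi_spec named numeric vector mapping ROI name to fraction of
#'   vertices; fractions must sum to 1 (tolerance 1e-9). Default: uniform
#'   over [default_roi_names()].
#' @param seed integer; the mesh is bit-identical for a fixed seed.
#' @return an object of class \code{cortical_mesh} with fields
#'   \code{positions} (n x 3, mm), \code{triangles} (m x 3 vertex indices),
#'   \code{normals} (n x 3 unit vectors), \code{hemisphere} (factor
#'   left/right), \code{roi} (character per vertex).
#' @export
build_toy_cortex <- function(n_vertices_per_hemisphere,
                             roi_spec = uniform_roi_spec(),
                             seed = 1L) {
  n <- n_vertices_per_hemisphere
  if (!is_scalar_num(n) || n < 16)
    config_error("n_vertices_per_hemisphere must be a single integer >= 16 (got %s)", n)
  if (is.null(names(roi_spec)) || any(!nzchar(names(roi_spec))))
    config_error("roi_spec must be a named vector of fractions")
  if (abs(sum(roi_spec) - 1) > 1e-9)
    config_error("roi_spec fractions must sum to 1 (got %.12f)", sum(roi_spec))
  if (n < length(roi_spec))
    config_error("n_vertices_per_hemisphere = %d too small to host %d ROIs", n, length(roi_spec))
  n <- as.integer(n)

  sides <- c("left", "right")
  parts <- lapply(seq_along(sides), function(i) {
    build_hemisphere_patch(n, sides[i], derive_seed(seed, "hemi", i))
  })

  positions <- rbind(parts[[1]]$positions, parts[[2]]$positions)
  normals <- rbind(parts[[1]]$normals, parts[[2]]$normals)
  triangles <- rbind(parts[[1]]$triangles, parts[[2]]$triangles + n)
  hemisphere <- factor(rep(sides, each = n), levels = sides)

  targets <- apportion_counts(n, roi_spec)
  roi <- character(2L * n)
  for (i in seq_along(sides)) {
    nbl <- neighbors_from_triangles(n, parts[[i]]$triangles)$neighbors
    roi[seq_len(n) + (i - 1L) * n] <-
      grow_rois(parts[[i]]$positions, nbl, names(roi_spec), targets,
                derive_seed(seed, "roi", i))
  }

  mesh <- structure(list(positions = positions, triangles = triangles,
                         normals = normals, hemisphere = hemisphere, roi = roi,
                         n_vertices = 2L * n, seed = as.integer(seed)),
                    class = "cortical_mesh")
  missing <- setdiff(names(roi_spec), unique(roi))
  if (length(missing))
    config_error("ROI(s) %s ended up empty", paste(missing, collapse = ", "))
  mesh
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("cortical_mesh: %d vertices (%d per hemisphere), %d triangles, %d ROIs\n",
              x$n_vertices, x$n_vertices / 2L, nrow(x$triangles),
              length(unique(x$roi))))
  invisible(x)
}

#' Vertex adjacency from shared triangle edges
#'
#' Two vertices are adjacent iff they share a triangle edge. The relation is
#' symmetric and irreflexive and never joins the two hemispheres (each
#' hemisphere is a separate cortical sheet, so clusters cannot span them).
#'
#' @param mesh a \code{cortical_mesh}, or any list with \code{triangles} and
#'   \code{n_vertices} (and optionally \code{hemisphere}).
#' @return an object of class \code{mesh_adjacency}: \code{n}, \code{edges}
#'   (m x 2, first column < second), \code{neighbors} (list of integer
#'   vectors).
#' @export
vertex_adjacency <- function(mesh) {
  tri <- mesh$triangles
  if (is.null(tri) || nrow(tri) < 1) data_error("mesh has no triangles")
  if (any(tri[, 1] == tri[, 2] | tri[, 2] == tri[, 3] | tri[, 1] == tri[, 3]))
    data_error("degenerate triangle with a repeated vertex")
  n <- if (!is.null(mesh$n_vertices)) mesh$n_vertices else max(tri)
  res <- neighbors_from_triangles(n, tri)
  if (!is.null(mesh$hemisphere)) {
    h <- mesh$hemisphere
    if (any(h[res$edges[, 1]] != h[res$edges[, 2]]))
      data_error("adjacency edge joins different hemispheres")
  }
  structure(list(n = n, edges = res$edges,
                 neighbors = lapply(res$neighbors, function(v) sort(unique(v)))),
            class = "mesh_adjacency")
}

# Generic adjacency container from an explicit edge list (used for
# time-frequency lattices and test fixtures).
adjacency_from_edges <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                                         pmax(edges[, 1], edges[, 2])))
  nb <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    nb[[edges[k, 1]]] <- c(nb[[edges[k, 1]]], edges[k, 2])
    nb[[edges[k, 2]]] <- c(nb[[edges[k, 2]]], edges[k, 1])
  }
  structure(list(n = as.integer(n), edges = edges,
                 neighbors = lapply(nb, function(v) sort(unique(v)))),
            class = "mesh_adjacency")
}

#' Export / import a mesh as ASCII OFF plus a label table
#'
#' The OFF file stores vertices and triangular faces (0-based indices); the
#' label table is tab-delimited \code{vertex_index<TAB>roi_name} (0-based).
#' Hemisphere is recoverable from vertex order (first half left, second half
#' right) and is stored as a comment.
#'
#' @param mesh a \code{cortical_mesh}.
#' @param off_path path for the OFF geometry file.
#' @param label_path path for the label table.
#' @return invisibly, the mesh.
#' @export
write_mesh_off <- function(mesh, off_path, label_path) {
  con <- file(off_path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("# oscmeg cortical_mesh; first %d vertices = left hemisphere",
                     mesh$n_vertices / 2L), con)
  writeLines(sprintf("%d %d 0", mesh$n_vertices, nrow(mesh$triangles)), con)
  utils::write.table(format(mesh$positions, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(vertex_index = seq_len(mesh$n_vertices) - 1L,
                                roi_name = mesh$roi),
                     label_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mesh)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(off_path, label_path) {
  lines <- readLines(off_path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "OFF") data_error("not an OFF file: %s", off_path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  vals <- scan(text = lines[3:(2 + nv)], quiet = TRUE)
  positions <- matrix(vals, nv, 3, byrow = TRUE)
  fvals <- scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE)
  fm <- matrix(fvals, nf, 4, byrow = TRUE)
  triangles <- fm[, 2:4, drop = FALSE] + 1L
  labels <- utils::read.delim(label_path, stringsAsFactors = FALSE)
  roi <- labels$roi_name[order(labels$vertex_index)]
  hemisphere <- factor(rep(c("left", "right"), each = nv / 2L),
                       levels = c("left", "right"))
  adjn <- neighbors_from_triangles(nv, triangles)
  # recompute normals from geometry (not persisted in OFF)
  nrm <- matrix(0, nv, 3)
  ctr_l <- colMeans(positions[seq_len(nv / 2), , drop = FALSE])
  ctr_r <- colMeans(positions[(nv / 2 + 1):nv, , drop = FALSE])
  for (k in seq_len(nf)) {
    t3 <- triangles[k, ]
    e1 <- positions[t3[2], ] - positions[t3[1], ]
    e2 <- positions[t3[3], ] - positions[t3[1], ]
    fn <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    ctr <- if (t3[1] <= nv / 2) ctr_l else ctr_r
    out_dir <- positions[t3[1], ] - ctr * 0.2
    if (sum(fn * out_dir) < 0) fn <- -fn
    for (vv in t3) nrm[vv, ] <- nrm[vv, ] + fn
  }
  nrm <- nrm / sqrt(rowSums(nrm^2))
  structure(list(positions = positions, triangles = triangles, normals = nrm,
                 hemisphere = hemisphere, roi = roi, n_vertices = nv,
                 seed = NA_integer_),
            class = "cortical_mesh")
}
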