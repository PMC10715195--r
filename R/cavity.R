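# Grid-based detection and classification of internal voids.
#
# Two-probe definition: a grid point is accessible to a probe of radius r
# iff no atom center lies within (vdW radius + r).  Bulk solvent is the
# flood fill of bulk-probe-accessible points from the box boundary,
# morphologically closed by the bulk-probe radius (so the thin accessible
# skin hugging the outer surface is claimed by solvent).  Candidate void
# points are small-probe accessible and outside bulk solvent; their
# 6-connected components are classified by mouth count: >= 2 mouths is a
# tunnel, 1 a pocket, 0 an enclosed cavity.

# linear-index helpers for a (nx, ny, nz) grid
grid_linear <- function(ix, iy, iz, nx, ny) {
  ix + nx * (iy - 1L) + nx * ny * (iz - 1L)
}

# integer offsets of a ball of radius r (in voxels) around the origin
ball_offsets <- function(r_vox) {
  r <- ceiling(r_vox)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= r_vox^2, , drop = FALSE]
  as.matrix(g)
}

# mark all voxels within radius (in voxels) of each center (voxel coords);
# used for the bulk-region dilation where centers sit on the grid
mark_balls <- function(mask_dim, centers, radius_vox) {
  nx <- mask_dim[1]; ny <- mask_dim[2]; nz <- mask_dim[3]
  off <- ball_offsets(radius_vox)
  marked <- logical(nx * ny * nz)
  for (k in seq_len(nrow(centers))) {
    ix <- centers[k, 1] + off[, 1]
    iy <- centers[k, 2] + off[, 2]
    iz <- centers[k, 3] + off[, 3]
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny & iz >= 1L & iz <= nz
    marked[grid_linear(ix[ok], iy[ok], iz[ok], nx, ny)] <- TRUE
  }
  marked
}

# mark voxels whose real-space position lies within radius_A of an atom;
# exact Euclidean test against the true atom coordinates (no rounding of
# atom centers to the grid, which would bias void volumes)
mark_atom_balls <- function(mask_dim, xyz, radius_A, lo, spacing) {
  nx <- mask_dim[1]; ny <- mask_dim[2]; nz <- mask_dim[3]
  off <- ball_offsets(radius_A / spacing + 1)
  off_pos <- off * spacing
  marked <- logical(nx * ny * nz)
  r2 <- radius_A^2
  for (k in seq_len(nrow(xyz))) {
    base <- c(round((xyz[k, 1] - lo[1]) / spacing),
              round((xyz[k, 2] - lo[2]) / spacing),
              round((xyz[k, 3] - lo[3]) / spacing))
    vx <- lo[1] + (base[1] + off[, 1]) * spacing
    vy <- lo[2] + (base[2] + off[, 2]) * spacing
    vz <- lo[3] + (base[3] + off[, 3]) * spacing
    d2 <- (vx - xyz[k, 1])^2 + (vy - xyz[k, 2])^2 + (vz - xyz[k, 3])^2
    sel <- d2 <= r2
    ix <- base[1] + off[sel, 1] + 1L
    iy <- base[2] + off[sel, 2] + 1L
    iz <- base[3] + off[sel, 3] + 1L
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny & iz >= 1L & iz <= nz
    marked[grid_linear(ix[ok], iy[ok], iz[ok], nx, ny)] <- TRUE
  }
  marked
}

# 6-connected flood fill over 'open' voxels from the given seed indices;
# returns logical vector of reached voxels
flood_fill6 <- function(open, seeds, nx, ny, nz) {
  n <- nx * ny * nz
  reached <- logical(n)
  frontier <- seeds[open[seeds] & !reached[seeds]]
  reached[frontier] <- TRUE
  while (length(frontier) > 0) {
    ix <- ((frontier - 1L) %% nx) + 1L
    iy <- (((frontier - 1L) %/% nx) %% ny) + 1L
    iz <- ((frontier - 1L) %/% (nx * ny)) + 1L
    nbrs <- c(frontier[ix > 1L] - 1L, frontier[ix < nx] + 1L,
              frontier[iy > 1L] - nx, frontier[iy < ny] + nx,
              frontier[iz > 1L] - nx * ny, frontier[iz < nz] + nx * ny)
    nbrs <- unique(nbrs[open[nbrs] & !reached[nbrs]])
    reached[nbrs] <- TRUE
    frontier <- nbrs
  }
  reached
}

# voxels of 'mask' having at least one 6-neighbor outside 'mask'
mask_boundary <- function(mask, nx, ny, nz) {
  idx <- which(mask)
  ix <- ((idx - 1L) %% nx) + 1L
  iy <- (((idx - 1L) %/% nx) %% ny) + 1L
  iz <- ((idx - 1L) %/% (nx * ny)) + 1L
  on_edge <- ix == 1L | ix == nx | iy == 1L | iy == ny | iz == 1L | iz == nz
  inner <- idx[!on_edge]
  if (length(inner) > 0) {
    nb_out <- !mask[inner - 1L] | !mask[inner + 1L] |
      !mask[inner - nx] | !mask[inner + nx] |
      !mask[inner - nx * ny] | !mask[inner + nx * ny]
    c(idx[on_edge], inner[nb_out])
  } else {
    idx[on_edge]
  }
}

#' Detect internal voids on a grid
#'
#' @param struct An `srb_structure` (or any object with an `atoms` data
#'   frame carrying `element`, `x`, `y`, `z`).
#' @param probe_small Small probe radius in Angstrom (default 0.9, the
#'   probe used for cavity prediction).
#' @param probe_bulk Bulk-solvent probe radius in Angstrom (default 3.0).
#' @param spacing Grid spacing in Angstrom (default 1.0; a warning is
#'   issued when it exceeds `probe_small`).
#' @param radii Named per-element van der Waals radii; unlisted elements
#'   get 1.7 A.
#' @return An object of class `srb_cavity_report`: `components` (data
#'   frame `id`, `n_points`, `volume`, `n_mouths`, `class`), `spacing`,
#'   `probe_small`, `probe_bulk`, and `points` (list of n x 3 coordinate
#'   matrices of the void grid points per component).
#' @export
grid_voids <- function(struct, probe_small = 0.9, probe_bulk = 3.0,
                       spacing = 1.0, radii = VDW_RADII) {
  stopifnot(probe_bulk > probe_small, probe_small > 0)
  at <- struct$atoms
  if (is.null(at) || nrow(at) == 0) stop("empty structure", call. = FALSE)
  if (spacing > probe_small) {
    warning("grid spacing exceeds probe_small; voids may be missed")
  }
  xyz <- as.matrix(at[c("x", "y", "z")])
  r_atom <- unname(radii[at$element])
  r_atom[is.na(r_atom)] <- VDW_DEFAULT
  margin <- max(r_atom) + probe_bulk + 2 * spacing
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  # blocked masks per distinct radius class, exact distances to atoms
  blocked_small <- logical(nx * ny * nz)
  blocked_bulk <- logical(nx * ny * nz)
  for (r in unique(r_atom)) {
    sel <- r_atom == r
    blocked_small <- blocked_small |
      mark_atom_balls(dims, xyz[sel, , drop = FALSE], r + probe_small, lo, spacing)
    blocked_bulk <- blocked_bulk |
      mark_atom_balls(dims, xyz[sel, , drop = FALSE], r + probe_bulk, lo, spacing)
  }
  # bulk solvent: flood bulk-accessible space from the box faces
  face <- which_box_faces(nx, ny, nz)
  bulk_core <- flood_fill6(!blocked_bulk, face, nx, ny, nz)
  # morphological closing: dilate the bulk core by the bulk-probe radius
  bseed <- mask_boundary(bulk_core, nx, ny, nz)
  dilated <- mark_balls(dims, cbind(((bseed - 1L) %% nx) + 1L,
                                    (((bseed - 1L) %/% nx) %% ny) + 1L,
                                    ((bseed - 1L) %/% (nx * ny)) + 1L),
                        probe_bulk / spacing)
  bulk_region <- bulk_core | dilated
  void <- !blocked_small & !bulk_region
  # 6-connected components of the void
  comp <- integer(nx * ny * nz)
  remaining <- which(void)
  cid <- 0L
  comp_points <- list()
  rows <- list()
  while (length(remaining) > 0) {
    cid <- cid + 1L
    reached <- flood_fill6(void & comp == 0L, remaining[1], nx, ny, nz)
    comp[reached] <- cid
    idx <- which(reached)
    remaining <- remaining[comp[remaining] == 0L]
    # mouths: void voxels of this component with a bulk 6-neighbor,
    # clustered with 26-connectivity
    mouth_vox <- interface_voxels(idx, bulk_region, nx, ny, nz)
    n_mouths <- count_clusters26(mouth_vox, nx, ny)
    klass <- if (n_mouths >= 2) "tunnel" else if (n_mouths == 1) "pocket" else "cavity"
    pts <- cbind(x = lo[1] + (((idx - 1L) %% nx)) * spacing,
                 y = lo[2] + ((((idx - 1L) %/% nx) %% ny)) * spacing,
                 z = lo[3] + (((idx - 1L) %/% (nx * ny))) * spacing)
    comp_points[[cid]] <- pts
    rows[[cid]] <- data.frame(id = cid, n_points = length(idx),
                              volume = length(idx) * spacing^3,
                              n_mouths = n_mouths, class = klass,
                              stringsAsFactors = FALSE)
  }
  components <- if (cid == 0) {
    data.frame(id = integer(), n_points = integer(), volume = numeric(),
               n_mouths = integer(), class = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  structure(list(structure_id = struct$id, components = components,
                 spacing = spacing, probe_small = probe_small,
                 probe_bulk = probe_bulk, points = comp_points),
            class = "srb_cavity_report")
}

# indices of all voxels on the 6 faces of the box
which_box_faces <- function(nx, ny, nz) {
  idx <- seq_len(nx * ny * nz)
  ix <- ((idx - 1L) %% nx) + 1L
  iy <- (((idx - 1L) %/% nx) %% ny) + 1L
  iz <- ((idx - 1L) %/% (nx * ny)) + 1L
  idx[ix == 1L | ix == nx | iy == 1L | iy == ny | iz == 1L | iz == nz]
}

# component voxels that touch bulk through a 6-face
interface_voxels <- function(idx, bulk, nx, ny, nz) {
  ix <- ((idx - 1L) %% nx) + 1L
  iy <- (((idx - 1L) %/% nx) %% ny) + 1L
  iz <- ((idx - 1L) %/% (nx * ny)) + 1L
  touch <- rep(FALSE, length(idx))
  touch[ix > 1L] <- touch[ix > 1L] | bulk[idx[ix > 1L] - 1L]
  touch[ix < nx] <- touch[ix < nx] | bulk[idx[ix < nx] + 1L]
  touch[iy > 1L] <- touch[iy > 1L] | bulk[idx[iy > 1L] - nx]
  touch[iy < ny] <- touch[iy < ny] | bulk[idx[iy < ny] + nx]
  touch[iz > 1L] <- touch[iz > 1L] | bulk[idx[iz > 1L] - nx * ny]
  touch[iz < nz] <- touch[iz < nz] | bulk[idx[iz < nz] + nx * ny]
  idx[touch]
}

# number of 26-connected clusters among a (small) voxel index set
count_clusters26 <- function(idx, nx, ny) {
  if (length(idx) == 0) return(0L)
  co <- cbind(((idx - 1L) %% nx) + 1L,
              (((idx - 1L) %/% nx) %% ny) + 1L,
              ((idx - 1L) %/% (nx * ny)) + 1L)
  n <- nrow(co)
  label <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (label[s] > 0L) next
    cid <- cid + 1L
    frontier <- s
    label[s] <- cid
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (f in frontier) {
        adj <- which(label == 0L &
                       abs(co[, 1] - co[f, 1]) <= 1L &
                       abs(co[, 2] - co[f, 2]) <= 1L &
                       abs(co[, 3] - co[f, 3]) <= 1L)
        label[adj] <- cid
        nxt <- c(nxt, adj)
      }
      frontier <- nxt
    }
  }
  cid
}

#' @export
print.srb_cavity_report <- function(x, ...) {
  cat(sprintf("srb_cavity_report %s: %d void component(s) at %.2f A spacing\n",
              x$structure_id, nrow(x$components), x$spacing))
  if (nrow(x$components) > 0) print(x$components)
  invisible(x)
}

#' Summarize cavity reports across a cohort
#'
#' @param reports A list of `srb_cavity_report` objects.
#' @return A list with `per_structure` (structure id, class and volume of
#'   the largest component, has_tunnel flag) and `tunnel_fraction` (the
#'   fraction of structures possessing at least one tunnel).
#' @export
summarize_voids <- function(reports) {
  if (length(reports) == 0) {
    return(list(per_structure = data.frame(structure_id = character(),
                                           largest_class = character(),
                                           largest_volume = numeric(),
                                           has_tunnel = logical()),
                tunnel_fraction = NA_real_))
  }
  rows <- lapply(reports, function(r) {
    cm <- r$components
    if (nrow(cm) == 0) {
      data.frame(structure_id = r$structure_id,
                 largest_class = "none", largest_volume = 0,
                 has_tunnel = FALSE, stringsAsFactors = FALSE)
    } else {
      top <- cm[which.max(cm$volume), , drop = FALSE]
      data.frame(structure_id = r$structure_id,
                 largest_class = top$class, largest_volume = top$volume,
                 has_tunnel = any(cm$class == "tunnel"),
                 stringsAsFactors = FALSE)
    }
  })
  per_structure <- do.call(rbind, rows)
  list(per_structure = per_structure,
       tunnel_fraction = mean(per_structure$has_tunnel))
}
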