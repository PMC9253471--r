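# Phantom builders and independent oracles shared across the test files.

# straight-line streamline between two world points
line_stream <- function(a, b) streamline(rbind(a, b))

# the crossing-bundle phantom: every control has an x-axis bundle through
# the grid centre; controls 1..n_cross also have a y-axis bundle through
# the centre while the rest carry it shifted by `shift` mm in z (away from
# a central lesion).
crossing_controls <- function(n_controls = 10L, n_cross = 6L, shift = 4) {
  mk <- function(dz) tractogram(list(
    line_stream(c(2, 8, 8), c(13, 8, 8)),
    line_stream(c(8, 2, 8 + dz), c(8, 13, 8 + dz))))
  c(replicate(n_cross, mk(0), simplify = FALSE),
    replicate(n_controls - n_cross, mk(shift), simplify = FALSE))
}

phantom_grid <- function(n = 16L, vox = 1) template_grid(rep(n, 3L), vox)

# ---- independent oracles ----

# dense-sampling voxelisation oracle: manual arithmetic point generation
# (independent of resample_streamline) + nearest-voxel mapping
voxel_oracle <- function(points, grid, step = 0.01) {
  pts <- NULL
  for (i in seq_len(nrow(points) - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    f <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    pts <- rbind(pts, outer(1 - f, a) + outer(f, b))
  }
  ijk <- world_to_voxel(grid, pts)
  ijk <- ijk[in_grid(grid, ijk), , drop = FALSE]
  unique_rows <- !duplicated(paste(ijk[, 1], ijk[, 2], ijk[, 3]))
  ijk[unique_rows, , drop = FALSE]
}

sort_rows <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]

# as voxel_oracle but keeping one row per sample point (for chord-length
# estimates from dense sample counts)
voxel_oracle_points <- function(points, grid, step = 0.01) {
  pts <- NULL
  for (i in seq_len(nrow(points) - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    f <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    pts <- rbind(pts, outer(1 - f, a) + outer(f, b))
  }
  ijk <- world_to_voxel(grid, pts)
  ijk[in_grid(grid, ijk), , drop = FALSE]
}

# brute-force TFCE oracle: explicit discrete threshold sum with igraph
# connected components (independent of the package's C++ kernel)
tfce_oracle <- function(stat, mask, H = 2, E = 0.5, dh = 0.1, conn = 26) {
  d <- dim(stat)
  coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                  z = seq_len(d[3])))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(conn),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  enh <- array(0, d)
  mx <- max(stat[mask != 0], 0)
  hs <- seq_len(floor(mx / dh + 1e-9)) * dh
  for (h in hs) {
    active <- which(mask != 0 & stat >= h - 1e-12)
    if (!length(active)) next
    amap <- integer(prod(d)); amap[active] <- seq_along(active)
    edges <- NULL
    ac <- coords[active, , drop = FALSE]
    for (r in seq_len(nrow(offs))) {
      nb <- sweep(ac, 2L, offs[r, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      nbl <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
      hit <- amap[nbl] > 0
      if (any(hit))
        edges <- rbind(edges, cbind(which(ok)[hit], amap[nbl[hit]]))
    }
    g <- igraph::make_empty_graph(n = length(active), directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)
    enh[active] <- enh[active] + comp$csize[comp$membership]^E * h^H * dh
  }
  enh
}

# normal-equations OLS oracle
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

# independent full-permutation enumerator (heap's algorithm, unlike the
# package's positional-insertion construction)
perms_oracle <- function(n) {
  out <- list()
  a <- seq_len(n)
  rec <- function(k) {
    if (k == 1L) { out[[length(out) + 1L]] <<- a; return(invisible()) }
    for (i in seq_len(k)) {
      rec(k - 1L)
      j <- if (k %% 2L == 0L) i else 1L
      tmp <- a[j]; a[j] <<- a[k]; a[k] <<- tmp
    }
  }
  rec(n)
  do.call(rbind, out)
}
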