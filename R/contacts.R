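## Friends-of-friends contact clustering.
##
## Overlap points are grouped single-linkage: two points are "friends"
## when their Cartesian distance is at most the threshold (+1e-9 A to
## absorb float error), and clusters are the connected components of the
## friendship relation. At the default threshold (= grid spacing) on grid
## points this is exactly 6-neighbourhood connected-component labelling;
## the 26-connectivity variant links diagonal grid neighbours too.

#' Cluster overlap points into contacts
#'
#' @param points Data frame of points: either an `overlap_points` result
#'   (grid indices present) or any set of `x`, `y`, `z` coordinates.
#' @param threshold Linkage distance in Angstrom; defaults to the grid
#'   spacing the points were generated on.
#' @param connectivity `6` (default, literal threshold) or `26`
#'   (diagonal grid neighbours linked as well, i.e. an effective threshold
#'   of `sqrt(3) * threshold`).
#' @return The input data frame with a `cluster_id` column added.
#'   Clusters are numbered 1..K by decreasing size, ties broken by the
#'   lexicographically smallest grid index (or coordinates) of a member.
#'   Empty input yields an empty result, not an error.
#' @export
cluster_contacts <- function(points, threshold = NULL, connectivity = 6) {
  if (!connectivity %in% c(6, 26)) .stopf("connectivity must be 6 or 26")
  n <- nrow(points)
  if (n == 0L) {
    points$cluster_id <- integer(0)
    return(points)
  }
  grid <- attr(points, "grid")
  if (is.null(threshold)) {
    if (is.null(grid)) .stopf("no grid attribute: give 'threshold' explicitly")
    threshold <- grid$spacing
  }
  if (threshold <= 0) .stopf("threshold must be positive")
  eff <- if (connectivity == 26) sqrt(3) * threshold else threshold
  eps <- 1e-9

  gridded <- all(c("ix", "iy", "iz") %in% names(points)) && !is.null(grid)
  if (gridded) {
    edges <- .grid_edges(points, grid$spacing, eff + eps)
  } else {
    if (n > 20000L)
      .stopf("distance-based clustering limited to 20000 points; gridded input scales further")
    edges <- .dense_edges(as.matrix(points[, c("x", "y", "z")]), eff + eps)
  }
  comp <- .connected_components(n, edges)

  ## deterministic numbering: size desc, then smallest member in the
  ## package point ordering (lexicographic grid index / coordinates)
  ord <- if (gridded) order(points$ix, points$iy, points$iz)
         else order(points$x, points$y, points$z)
  rank_in_order <- integer(n)
  rank_in_order[ord] <- seq_len(n)
  size <- tabulate(comp)
  first <- vapply(seq_along(size), function(k)
    min(rank_in_order[comp == k]), numeric(1))
  new_id <- integer(length(size))
  new_id[order(-size, first)] <- seq_along(size)
  points$cluster_id <- new_id[comp]
  points
}

## neighbour edges among lattice points: enumerate the integer offsets
## reachable within the threshold and match shifted keys (vectorised)
.grid_edges <- function(points, spacing, thr) {
  kmax <- floor(thr / spacing)
  if (kmax < 1) return(matrix(integer(0), ncol = 2))
  off <- expand.grid(ox = -kmax:kmax, oy = -kmax:kmax, oz = -kmax:kmax)
  off <- off[(off$ox^2 + off$oy^2 + off$oz^2) * spacing^2 <= thr^2, ]
  ## keep one representative of each +/- pair, drop the null offset
  off <- off[off$ox > 0 | (off$ox == 0 & off$oy > 0) |
             (off$ox == 0 & off$oy == 0 & off$oz > 0), , drop = FALSE]
  base <- max(points$ix, points$iy, points$iz) + max(kmax, 1) + 2
  key <- (points$ix * base + points$iy) * base + points$iz
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    shifted <- ((points$ix + off$ox[k]) * base + points$iy + off$oy[k]) *
      base + points$iz + off$oz[k]
    hit <- match(shifted, key)
    ok <- !is.na(hit)
    from <- c(from, which(ok)); to <- c(to, hit[ok])
  }
  cbind(from, to)
}

## all pairs within the threshold, blockwise O(n^2)
.dense_edges <- function(xyz, thr) {
  n <- nrow(xyz)
  from <- integer(0); to <- integer(0)
  block <- 2000L
  for (s in seq(1L, n, by = block)) {
    rows <- s:min(s + block - 1L, n)
    d2 <- outer(rowSums(xyz[rows, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[rows, , drop = FALSE] %*% t(xyz)
    hit <- which(d2 <= thr^2, arr.ind = TRUE)
    i <- rows[hit[, 1]]; j <- hit[, 2]
    keep <- i < j
    from <- c(from, i[keep]); to <- c(to, j[keep])
  }
  cbind(from, to)
}

## connected components by union-find (path-halving) over the edge list
.connected_components <- function(n, edges) {
  parent <- seq_len(n)
  m <- nrow(edges)
  if (m > 0) {
    ef <- edges[, 1]; et <- edges[, 2]
    for (k in seq_len(m)) {
      a <- ef[k]
      while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
      b <- et[k]
      while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
      if (a != b) parent[b] <- a
    }
  }
  for (i in seq_len(n)) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    a <- i
    while (parent[a] != r) { nxt <- parent[a]; parent[a] <- r; a <- nxt }
  }
  match(parent, unique(parent))
}

#' Summarise contact clusters
#'
#' One row per cluster with the point count, the strongest overlap
#' (`max_ln_rho_product`), the closest approach (`min_sumdle`) and the
#' dominant ligand-receptor atom pair (the modal top-contributor pair,
#' ties resolved to the lower serial pair).
#'
#' @param points An `overlap_points` data frame with `cluster_id` (from
#'   [cluster_contacts()]).
#' @param receptor,ligand Optional poses used to annotate the dominant
#'   atoms with names and residues.
#' @return Data frame ordered by `cluster_id`.
#' @export
summarize_clusters <- function(points, receptor = NULL, ligand = NULL) {
  if (!"cluster_id" %in% names(points))
    .stopf("points have no cluster_id; run cluster_contacts() first")
  if (nrow(points) == 0L)
    return(data.frame(cluster_id = integer(0), n_points = integer(0),
                      min_sumdle = numeric(0),
                      max_ln_rho_product = numeric(0),
                      lig_serial = integer(0), enz_serial = integer(0)))
  out <- do.call(rbind, lapply(split(points, points$cluster_id), function(cl) {
    pair <- paste(cl$lig_serial, cl$enz_serial, sep = "_")
    cnt <- table(pair)
    cand <- names(cnt)[cnt == max(cnt)]
    sp <- do.call(rbind, strsplit(cand, "_"))
    pick <- order(as.integer(sp[, 1]), as.integer(sp[, 2]))[1]
    data.frame(
      cluster_id = cl$cluster_id[1], n_points = nrow(cl),
      min_sumdle = min(cl$sumdle),
      max_ln_rho_product = max(log(cl$rho_ligand * cl$rho_enzyme)),
      lig_serial = as.integer(sp[pick, 1]),
      enz_serial = as.integer(sp[pick, 2]))
  }))
  if (!is.null(ligand)) {
    i <- match(out$lig_serial, ligand$serial)
    out$lig_name <- ligand$name[i]
  }
  if (!is.null(receptor)) {
    i <- match(out$enz_serial, receptor$serial)
    out$enz_name <- receptor$name[i]
    out$enz_resname <- receptor$resname[i]
    out$enz_resno <- receptor$resno[i]
  }
  out <- out[order(out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export cluster summaries as TSV
#'
#' @param clusters Result of [summarize_clusters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  out <- clusters
  for (cc in c("min_sumdle", "max_ln_rho_product"))
    out[[cc]] <- .fmt_num(out[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
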