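## 26-connectivity connected components over a logical 3D array.
## Returns a list of integer vectors of linear voxel indices.
label_components <- function(flag, dim) {
  vox <- which(flag)
  if (length(vox) == 0) return(list())
  pos <- integer(prod(dim)); pos[vox] <- seq_along(vox)
  ijk <- index_to_ijk(vox, dim)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  # half the offsets suffice (each undirected adjacency counted once)
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & (offs$dy > 0 | (offs$dy == 0 & offs$dz > 0))), ]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    ni <- ijk[, 1] + offs$dx[r]; nj <- ijk[, 2] + offs$dy[r]; nk <- ijk[, 3] + offs$dz[r]
    ok <- ni >= 1 & ni <= dim[1] & nj >= 1 & nj <= dim[2] & nk >= 1 & nk <= dim[3]
    nl <- ni[ok] + (nj[ok] - 1L) * dim[1] + (nk[ok] - 1L) * dim[1] * dim[2]
    hit <- pos[nl] > 0
    if (any(hit)) edges <- rbind(edges, cbind(pos[vox[ok]][hit], pos[nl][hit]))
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  split(vox, memb)
}

## observed clusters of a statistic map above |thr|, sign-separated
extract_clusters <- function(stat, mask, thr_abs, min_extent, affine, gc = NULL,
                             gc_thr = 0) {
  dim <- dim(stat)
  out <- list()
  for (sgn in c(1, -1)) {
    flag <- !is.na(stat) & mask & (sgn * stat > thr_abs)
    if (gc_thr > 0 && !is.null(gc)) flag <- flag & !is.na(gc) & abs(gc) > gc_thr
    comps <- label_components(flag, dim)
    comps <- comps[lengths(comps) > min_extent]
    for (cv in comps) {
      pk <- cv[which.max(abs(stat[cv]))]
      w <- voxel_to_world(index_to_ijk(pk, dim), affine)
      out[[length(out) + 1L]] <- list(
        sign = sgn, peak_x = w[1], peak_y = w[2], peak_z = w[3],
        peak_stat = stat[pk],
        peak_gc = if (is.null(gc)) NA_real_ else gc[pk],
        n_voxels = length(cv), mass = sum(abs(stat[cv])), voxels = cv)
    }
  }
  if (!length(out)) {
    return(data.frame(cluster_id = integer(0), sign = numeric(0),
                      peak_x = numeric(0), peak_y = numeric(0), peak_z = numeric(0),
                      peak_stat = numeric(0), peak_gc = numeric(0),
                      n_voxels = integer(0), mass = numeric(0)))
  }
  df <- do.call(rbind, lapply(out, function(cl)
    data.frame(cl[setdiff(names(cl), "voxels")])))
  df <- cbind(cluster_id = seq_len(nrow(df)), df)
  attr(df, "voxels") <- lapply(out, `[[`, "voxels")
  df
}

## max cluster mass of a null map under the same forming rule
null_max_mass <- function(stat, mask, thr_abs, min_extent, gc = NULL, gc_thr = 0) {
  mx <- 0
  dim <- dim(stat)
  for (sgn in c(1, -1)) {
    flag <- !is.na(stat) & mask & (sgn * stat > thr_abs)
    if (gc_thr > 0 && !is.null(gc)) flag <- flag & !is.na(gc) & abs(gc) > gc_thr
    if (!any(flag)) next
    comps <- label_components(flag, dim)
    comps <- comps[lengths(comps) > min_extent]
    if (length(comps))
      mx <- max(mx, vapply(comps, function(cv) sum(abs(stat[cv])), 0))
  }
  mx
}

perm_cluster_pvalues <- function(masses, null_masses) {
  vapply(masses, function(m) (1 + sum(null_masses >= m)) / (length(null_masses) + 1), 0)
}

#' Cluster-level FDR inference for a voxel-wise group contrast
#'
#' Forms clusters of supra-threshold voxels (two-sided voxel p, 26-neighbor
#' connectivity), filters by extent, assigns each cluster a p-value from a
#' permutation null of the maximum cluster mass (group labels permuted,
#' covariates kept with the images), and applies Benjamini-Hochberg FDR
#' across clusters.
#'
#' @param images a `gmv_image_set`.
#' @param group two-level group vector.
#' @param covariates optional nuisance covariate data.frame.
#' @param forming_p two-sided voxel-level forming threshold (default 0.001).
#' @param min_extent minimum cluster extent in voxels (clusters must exceed it).
#' @param n_perm number of label permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @param fdr_alpha FDR level defining `significant`.
#' @param group1 positive side of the contrast.
#' @return list(tmap, clusters): `clusters` is a data.frame with one row per
#'   cluster (peak world coordinates, peak t, extent, mass, p, q,
#'   significant), cluster voxel lists in `attr(, "voxels")`.
#' @export
cluster_level_fdr <- function(images, group, covariates = NULL,
                              forming_p = 0.001, min_extent = 0,
                              n_perm = 500, seed = 1, fdr_alpha = 0.05,
                              group1 = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  tmap <- voxelwise_glm_ttest(images, group, covariates, group1)
  thr <- stats::qt(1 - forming_p / 2, tmap$df)
  cl <- extract_clusters(tmap$statistic, images$mask, thr, min_extent, images$affine)
  if (nrow(cl) > 0) {
    set.seed(as.integer(seed))
    nm <- vapply(seq_len(n_perm), function(b) {
      tp <- voxelwise_glm_ttest(images, sample(as.character(group)),
                                covariates, group1)
      null_max_mass(tp$statistic, images$mask, thr, min_extent)
    }, 0)
    cl$p <- perm_cluster_pvalues(cl$mass, nm)
    cl$q <- stats::p.adjust(cl$p, "BH")
    cl$significant <- cl$q < fdr_alpha
  } else {
    cl$p <- numeric(0); cl$q <- numeric(0); cl$significant <- logical(0)
  }
  list(tmap = tmap, clusters = cl)
}
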