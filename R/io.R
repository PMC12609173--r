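#' Read and validate a phenotype CSV
#'
#' Expects the column layout written by [write_phenotype()] (subject_id,
#' group, wmh_volume, fazekas, age, sex, education_years, tiv, global_gmv,
#' moca, mmse, dst, tmt_a). Row order is preserved.
#'
#' @param path CSV path.
#' @param allow_na_scores allow missing dst / tmt_a.
#' @return validated phenotype data.frame.
#' @export
read_phenotype <- function(path, allow_na_scores = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- c("wmh_volume", "age", "education_years", "tiv", "global_gmv",
           "moca", "mmse", "dst", "tmt_a")
  for (cn in intersect(num, names(tab))) {
    tab[[cn]] <- suppressWarnings(as.numeric(tab[[cn]]))
  }
  if ("fazekas" %in% names(tab)) tab$fazekas <- as.integer(tab$fazekas)
  validate_cohort(tab, allow_na_scores = allow_na_scores)
  tab
}

#' Write a phenotype table to CSV
#' @param cohort phenotype data.frame.
#' @param path output CSV path.
#' @export
write_phenotype <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

nifti_from_array <- function(arr, affine, voxel_size) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- rep(voxel_size, 3)
  RNifti::sform(im) <- structure(affine, code = 2L)
  RNifti::qform(im) <- structure(affine, code = 2L)
  im
}

#' Write a grey-matter image set as per-subject NIfTI files
#'
#' @param images a `gmv_image_set`.
#' @param dir output directory (created if needed).
#' @param gzip write .nii.gz (default) or .nii.
#' @return named character vector of file paths (subjects plus `mask`).
#' @export
write_image_set <- function(images, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  paths <- vapply(seq_along(images$subject_id), function(i) {
    f <- file.path(dir, paste0(images$subject_id[i], ext))
    RNifti::writeNifti(nifti_from_array(array(images$data[i, ], images$dim),
                                        images$affine, images$voxel_size), f)
    f
  }, "")
  mf <- file.path(dir, paste0("mask", ext))
  RNifti::writeNifti(nifti_from_array(array(as.numeric(images$mask), images$dim),
                                      images$affine, images$voxel_size), mf)
  stats::setNames(c(paths, mf), c(images$subject_id, "mask"))
}

#' Read a grey-matter image set from NIfTI files
#'
#' All volumes must share shape and affine (tolerance 1e-4). The mask is
#' binarized at > 0.
#'
#' @param paths per-subject NIfTI paths (names become subject ids).
#' @param mask_path mask NIfTI path.
#' @return a `gmv_image_set`.
#' @export
read_image_set <- function(paths, mask_path) {
  if (length(paths) < 1) stop("no image paths given")
  first <- RNifti::readNifti(paths[1])
  dm <- dim(first)
  aff <- unclass(RNifti::xform(first))
  data <- matrix(NA_real_, length(paths), prod(dm))
  data[1, ] <- as.numeric(first)
  for (i in seq_along(paths)[-1]) {
    im <- RNifti::readNifti(paths[i])
    if (!identical(dim(im), dm))
      stop("image shape mismatch in file: ", paths[i])
    if (max(abs(unclass(RNifti::xform(im)) - aff)) > 1e-4)
      stop("affine mismatch in file: ", paths[i])
    data[i, ] <- as.numeric(im)
  }
  mk <- RNifti::readNifti(mask_path)
  if (!identical(dim(mk), dm)) stop("mask shape mismatch: ", mask_path)
  mask <- array(as.numeric(mk) > 0, dm)
  if (!any(mask)) stop("mask is empty")
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  structure(list(data = data, dim = dm, mask = mask, affine = aff,
                 voxel_size = aff[1, 1], subject_id = ids),
            class = "gmv_image_set")
}

#' Write a statistic map as NIfTI
#'
#' @param stat 3D array (NA outside mask becomes 0).
#' @param affine 4x4 affine.
#' @param path output path.
#' @param voxel_size voxel size in mm.
#' @export
write_stat_map <- function(stat, affine, path, voxel_size = abs(affine[1, 1])) {
  arr <- stat
  arr[is.na(arr)] <- 0
  RNifti::writeNifti(nifti_from_array(arr, affine, voxel_size), path)
  invisible(path)
}

#' Write a cluster table as TSV
#'
#' Columns mirror the cluster-inventory layout of the study's tables:
#' cluster id, peak world coordinates, peak statistic (and GC where
#' available), extent, p and FDR q.
#'
#' @param clusters cluster data.frame.
#' @param path output TSV path.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a causal graph to GraphML
#'
#' @param graph a `cascn_graph`.
#' @param path output .graphml path.
#' @export
write_graphml <- function(graph, path) {
  g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                     vertices = data.frame(name = graph$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

## tiny stable FNV-1a hash of a config (hex string) for output provenance
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
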