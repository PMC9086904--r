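# ROI sample containers and on-disk formats.
#
# A `roi_sample_set` holds, for one subject, the vector of voxel-wise
# gray-matter volume (GMV) values inside each atlas region. Region ordering
# is the single source of truth: every downstream matrix indexes against
# it, and all subjects in a cohort must share it.

#' Construct an ROI sample set
#'
#' @param subject_id character scalar.
#' @param samples named list of numeric vectors, one per region, in atlas
#'   order; names are region names.
#' @param labels optional integer atlas labels parallel to `samples`
#'   (defaults to 1..n).
#' @return an object of class `roi_sample_set`.
#' @export
roi_sample_set <- function(subject_id, samples, labels = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1)
  if (!is.list(samples) || is.null(names(samples)) ||
      any(!nzchar(names(samples)))) {
    stop("'samples' must be a named list of numeric vectors")
  }
  if (anyDuplicated(names(samples))) stop("duplicated region names")
  if (is.null(labels)) labels <- seq_along(samples)
  labels <- as.integer(labels)
  if (length(labels) != length(samples)) {
    stop("'labels' length must match 'samples'")
  }
  for (nm in names(samples)) {
    v <- samples[[nm]]
    if (!is.numeric(v)) stop("samples for region ", nm, " are not numeric")
    if (any(!is.finite(v))) stop("non-finite sample values in region ", nm)
  }
  short <- names(samples)[vapply(samples, length, 1L) < 2]
  obj <- structure(
    list(subject_id = subject_id, roi_names = names(samples),
         roi_labels = labels, samples = samples, flagged = short),
    class = "roi_sample_set"
  )
  if (length(short)) {
    warning("regions with fewer than 2 samples: ",
            paste(short, collapse = ", "))
  }
  obj
}

#' @export
print.roi_sample_set <- function(x, ...) {
  n <- vapply(x$samples, length, 1L)
  cat(sprintf("roi_sample_set '%s': %d regions, %d-%d voxels per region\n",
              x$subject_id, length(n), min(n), max(n)))
  invisible(x)
}

#' Extract per-region voxel samples from a gray-matter map and an atlas
#'
#' For each expected atlas label, collects the GM-map values at voxels
#' carrying that label. Voxels with GM value <= 0 are treated as background
#' and excluded. Labels present in the atlas image but absent from the
#' expected label table are an error; expected labels missing from the
#' image yield an empty, flagged region.
#'
#' @param gm_image numeric array or path to a NIfTI file.
#' @param atlas_image integer-labeled array or NIfTI path, same grid as
#'   `gm_image`.
#' @param labels data.frame with columns `label` and `name` defining the
#'   expected parcellation (default [aal116_labels()]).
#' @param subject_id subject identifier stored in the result.
#' @return a [roi_sample_set].
#' @export
extract_roi_samples <- function(gm_image, atlas_image,
                                labels = aal116_labels(),
                                subject_id = "subject") {
  if (is.character(gm_image)) gm_image <- read_nifti(gm_image)
  if (is.character(atlas_image)) atlas_image <- read_nifti(atlas_image)
  if (!identical(dim(gm_image), dim(atlas_image))) {
    stop("gray-matter map and atlas have different grid dimensions: ",
         paste(dim(gm_image), collapse = "x"), " vs ",
         paste(dim(atlas_image), collapse = "x"))
  }
  atlas <- as.integer(round(as.vector(atlas_image)))
  gm <- as.numeric(as.vector(gm_image))
  present <- sort(unique(atlas[atlas != 0L]))
  unknown <- setdiff(present, labels$label)
  if (length(unknown)) {
    stop("atlas contains label(s) not in the expected parcellation: ",
         paste(unknown, collapse = ", "))
  }
  ord <- order(labels$label)
  labels <- labels[ord, , drop = FALSE]
  samples <- lapply(labels$label, function(lb) {
    v <- gm[atlas == lb]
    v[v > 0]  # non-positive GM values are background
  })
  names(samples) <- labels$name
  suppressWarnings(
    rs <- roi_sample_set(subject_id, samples, labels = labels$label)
  )
  if (length(rs$flagged)) {
    warning("regions with fewer than 2 voxels after extraction: ",
            paste(rs$flagged, collapse = ", "))
  }
  rs
}

#' Write / read ROI sample tables
#'
#' Samples are stored as a two-column TSV (`roi_label`, `voxel_value`)
#' with one row per voxel, regions in atlas order. The round-trip is
#' lossless at full double precision.
#'
#' @param x a [roi_sample_set].
#' @param path file path.
#' @return `write_roi_table` returns `path` invisibly; `read_roi_table`
#'   returns a [roi_sample_set].
#' @export
write_roi_table <- function(x, path) {
  stopifnot(inherits(x, "roi_sample_set"))
  n <- vapply(x$samples, length, 1L)
  df <- data.frame(
    roi_label = rep(x$roi_names, n),
    voxel_value = format(unlist(x$samples, use.names = FALSE), digits = 17,
                         trim = TRUE, scientific = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @param subject_id subject id for the read set; defaults to the file
#'   base name.
#' @export
read_roi_table <- function(path, subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character"))
  if (!all(c("roi_label", "voxel_value") %in% names(df))) {
    stop("ROI table must have columns 'roi_label' and 'voxel_value'")
  }
  vals <- suppressWarnings(as.numeric(df$voxel_value))
  if (any(is.na(vals))) stop("non-numeric voxel_value entries in ", path)
  rois <- unique(df$roi_label)  # first-appearance order == atlas order
  samples <- split(vals, factor(df$roi_label, levels = rois))
  roi_sample_set(subject_id, samples)
}

#' Construct a morphological network
#'
#' A per-subject symmetric matrix of KL-divergence-based similarities in
#' `[0, 1]` with zero diagonal, indexed by region name.
#'
#' @param subject_id character scalar.
#' @param matrix symmetric numeric matrix with values in `[0, 1]`, zero
#'   diagonal, dimnames set to region names.
#' @return an object of class `morph_network`.
#' @export
morph_network <- function(subject_id, matrix) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    stop("'matrix' must be square")
  }
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- colnames(matrix) <- paste0("ROI", seq_len(nrow(matrix)))
  }
  if (!identical(rownames(matrix), colnames(matrix))) {
    stop("row and column names must agree")
  }
  if (max(abs(matrix - t(matrix))) > 1e-12) {
    stop("matrix is not symmetric (tolerance 1e-12)")
  }
  if (any(diag(matrix) != 0)) stop("diagonal must be zero")
  if (min(matrix) < 0 || max(matrix) > 1) {
    stop("value outside [0,1] in similarity matrix")
  }
  structure(list(subject_id = subject_id, roi_names = rownames(matrix),
                 matrix = matrix),
            class = "morph_network")
}

#' @export
print.morph_network <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf(
    "morph_network '%s': %d regions, similarity range [%.4f, %.4f]\n",
    x$subject_id, nrow(x$matrix), min(off), max(off)))
  invisible(x)
}

#' Write / read a morphological network as TSV
#'
#' The matrix is stored with a header row and a leading column of region
#' names. `read_network` enforces the class invariants: symmetry to
#' 1e-12, zero diagonal and values in `[0, 1]`.
#'
#' @param network a [morph_network].
#' @param path file path.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "morph_network"))
  m <- network$matrix
  df <- data.frame(roi = rownames(m),
                   apply(m, 2, format, digits = 17, trim = TRUE,
                         scientific = FALSE),
                   check.names = FALSE)
  names(df) <- c("roi", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @param subject_id subject id; defaults to the file base name.
#' @export
read_network <- function(path, subject_id = NULL) {
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "roi") stop("network TSV must start with a 'roi' column")
  rois <- df$roi
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    m2 <- suppressWarnings(apply(m, 2, as.numeric))
    if (any(is.na(m2))) stop("non-numeric entries in network matrix")
    m <- m2
  }
  if (!identical(colnames(m), rois)) {
    stop("network row and column region names disagree")
  }
  rownames(m) <- rois
  morph_network(subject_id, m)
}
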