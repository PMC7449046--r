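#' SLIC superpixel parameters
#'
#' @param S superpixel size in pixels (grid spacing of the initial cluster
#'   centers; >= 2).
#' @param C compactness coefficient (> 0) weighting spatial against color
#'   distance; color channels are scaled to [0, 1] so C is
#'   image-independent.
#' @param N number of assignment/update iterations (>= 1).
#' @return an object of class \code{slic_params}.
#' @export
slic_params <- function(S = 15L, C = 0.2, N = 50L) {
  if (S < 2) stop("slic_params: S must be >= 2", call. = FALSE)
  if (C <= 0) stop("slic_params: C must be > 0", call. = FALSE)
  if (N < 1) stop("slic_params: N must be >= 1", call. = FALSE)
  structure(list(S = as.integer(S), C = C, N = as.integer(N)),
            class = "slic_params")
}

#' SLIC superpixel segmentation
#'
#' Simple linear iterative clustering: k-means-style clustering in combined
#' color-position space with grid-initialized centers spaced S apart, the
#' compactness C weighting spatial distance, and N iterations, followed by
#' connectivity enforcement (orphan fragments smaller than S^2/4 are merged
#' into a neighboring region). Deterministic for fixed input and parameters.
#'
#' @param image H x W x 3 integer array (0..255) or double array in [0, 1].
#' @param params a \code{\link{slic_params}}.
#' @return list of class \code{superpixel_map}: \code{regions} (H x W
#'   integer matrix of dense 0-based region ids), \code{n_regions},
#'   \code{params}.
#' @export
slic_segment <- function(image, params = slic_params()) {
  stopifnot(inherits(params, "slic_params"))
  d <- dim(image)
  if (length(d) != 3L || d[3] < 3L)
    stop("slic_segment: image must be H x W x 3", call. = FALSE)
  if (d[1] < params$S || d[2] < params$S)
    stop("slic_segment: image smaller than S in at least one dimension",
         call. = FALSE)
  x <- as.double(image)
  if (max(x) > 1) x <- x / 255
  regions <- .cpp_slic(x, d[1], d[2], params$S, params$C, params$N)
  structure(list(regions = regions,
                 n_regions = attr(regions, "n_regions"),
                 params = params),
            class = "superpixel_map")
}

#' Relabel one superpixel region of a class mask
#'
#' Sets every pixel of the region to the new class and leaves all other
#' pixels untouched; the input mask is not mutated. This is the batch
#' analogue of the interactive click-to-correct step: an external viewer
#' produces (region id, class) edits that are applied here.
#'
#' @param mask H x W integer matrix with labels 0/1/2.
#' @param spmap a \code{superpixel_map} from \code{\link{slic_segment}}.
#' @param region_id 0-based region id (< n_regions).
#' @param new_class target label in \{0, 1, 2\}.
#' @return the modified mask (a new matrix).
#' @export
relabel_region <- function(mask, spmap, region_id, new_class) {
  stopifnot(inherits(spmap, "superpixel_map"))
  if (!all(dim(mask) == dim(spmap$regions)))
    stop("relabel_region: mask and region map shapes differ", call. = FALSE)
  if (length(region_id) != 1 || region_id < 0 ||
      region_id >= spmap$n_regions)
    stop("relabel_region: unknown region_id ", region_id, call. = FALSE)
  if (!new_class %in% 0:2)
    stop("relabel_region: invalid class ", new_class, call. = FALSE)
  out <- mask
  out[spmap$regions == region_id] <- as.integer(new_class)
  out
}

#' Apply a table of region edits to a mask
#'
#' @param mask H x W integer matrix.
#' @param spmap a \code{superpixel_map}.
#' @param edits data.frame with columns \code{region_id} and
#'   \code{new_class}.
#' @return the edited mask.
#' @export
apply_region_edits <- function(mask, spmap, edits) {
  for (i in seq_len(nrow(edits)))
    mask <- relabel_region(mask, spmap, edits$region_id[i],
                           edits$new_class[i])
  mask
}

#' Majority-vote cleanup of a predicted mask over superpixels
#'
#' Sets every pixel of each superpixel to the modal predicted class within
#' it (ties break toward the lower class index). A batch, non-interactive
#' analogue of manual correction: isolated misclassified pixels inside a
#' perceptually homogeneous region are absorbed by the region's majority.
#'
#' @param mask H x W integer matrix with labels 0/1/2.
#' @param spmap a \code{superpixel_map} for the same image.
#' @return the cleaned mask (a new matrix).
#' @export
majority_vote_cleanup <- function(mask, spmap) {
  stopifnot(inherits(spmap, "superpixel_map"))
  if (!all(dim(mask) == dim(spmap$regions)))
    stop("majority_vote_cleanup: shape mismatch", call. = FALSE)
  ## counts[region, class] via one pass
  reg <- as.vector(spmap$regions)
  counts <- matrix(0L, spmap$n_regions, 3L)
  for (k in 0:2) {
    t <- tabulate(reg[as.vector(mask) == k] + 1L, nbins = spmap$n_regions)
    counts[, k + 1L] <- t
  }
  modal <- max.col(counts, ties.method = "first") - 1L
  out <- matrix(modal[reg + 1L], nrow(mask), ncol(mask))
  storage.mode(out) <- "integer"
  out
}
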