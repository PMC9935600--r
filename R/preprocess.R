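#' Normalize a projection stack to the 0-1 range
#'
#' Divides the counts by `scale` (default: the stack's own maximum). When
#' preparing training pairs, the fast stack of a subject is normalized by the
#' *full-time* stack's maximum so the count-level contrast between the two is
#' preserved (a fast stack thinned at p then peaks near p, not 1).
#'
#' @param stack a `projection_stack` or 3D array.
#' @param scale positive scalar to divide by, or `NULL` to use the maximum.
#' @return list with `data` (normalized array) and `scale`.
#' @export
normalize_stack <- function(stack, scale = NULL) {
  arr <- if (inherits(stack, "projection_stack")) stack$counts
         else as.array(stack)
  if (is.null(scale)) {
    scale <- max(arr)
    if (scale <= 0) stop("cannot normalize an all-zero stack")
  }
  if (scale <= 0) stop("normalization scale must be positive")
  list(data = arr / scale, scale = scale)
}

#' @rdname normalize_stack
#' @param arr normalized array.
#' @export
denormalize_stack <- function(arr, scale) {
  if (scale <= 0) stop("normalization scale must be positive")
  as.array(arr) * scale
}

#' Embed / strip the binary defect-information block
#'
#' Appends `n_slices` constant slices holding the subject's binary defect
#' label (0 = no defect, 1 = defect) at the tail of the view axis, turning a
#' `V x nx x nz` stack into `(V + n_slices) x nx x nz`. The original views
#' are untouched; [strip_defect_block()] is the exact inverse.
#'
#' @param stack_array 3D array `(V, nx, nz)`.
#' @param defect_label 0 or 1.
#' @param n_slices number of label slices (default 4).
#' @return 3D array with the label block appended.
#' @export
embed_defect_block <- function(stack_array, defect_label, n_slices = 4L) {
  arr <- as.array(stack_array)
  if (length(dim(arr)) != 3L) stop("stack_array must be 3D (V, nx, nz)")
  if (!defect_label %in% c(0, 1))
    stop("defect_label must be binary (0 or 1)")
  d <- dim(arr)
  out <- array(as.numeric(defect_label), c(d[1] + n_slices, d[2], d[3]))
  out[seq_len(d[1]), , ] <- arr
  out
}

#' @rdname embed_defect_block
#' @export
strip_defect_block <- function(stack_array, n_slices = 4L) {
  arr <- as.array(stack_array)
  d <- dim(arr)
  if (d[1] <= n_slices) stop("stack has no room for a defect block")
  arr[seq_len(d[1] - n_slices), , , drop = FALSE]
}

#' Build a normalized training sample from a fast/full-time stack pair
#'
#' @param fast a fast-acquisition `projection_stack` (the network input).
#' @param ft the full-time `projection_stack` of the same subject (target).
#' @param defect_label binary defect label of the subject.
#' @param shared_scale logical; normalize both stacks by the FT maximum
#'   (default) rather than each by its own maximum.
#' @return list with `input`, `target` (normalized arrays), `defect_label`
#'   and `norm_scale`.
#' @export
make_training_sample <- function(fast, ft, defect_label = 0L,
                                 shared_scale = TRUE) {
  ftn <- normalize_stack(ft)
  fan <- if (shared_scale) normalize_stack(fast, scale = ftn$scale)
         else normalize_stack(fast)
  list(input = fan$data, target = ftn$data,
       defect_label = as.integer(defect_label), norm_scale = ftn$scale)
}
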