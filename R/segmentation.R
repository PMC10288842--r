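#' Liver-reference MTV segmentation threshold
#'
#' Pathologic somatostatin-receptor expression is defined as SUV higher than
#' 1.5 times the mean liver SUV plus two liver standard deviations:
#' `threshold = 1.5 * suv_mean + 2 * suv_sd`.
#'
#' @param liver Either the one-row tibble returned by [reference_stats()]
#'   for a liver VOI, or a numeric liver mean SUV.
#' @param suv_sd Liver SUV standard deviation; only used when `liver` is
#'   numeric.
#' @return The segmentation threshold in SUV units.
#' @examples
#' segmentation_threshold(4.41, 1.14) # 8.895
#' @export
segmentation_threshold <- function(liver, suv_sd = NULL) {
  if (is.data.frame(liver)) {
    stopifnot(nrow(liver) == 1L, all(c("suv_mean", "suv_sd") %in% names(liver)))
    suv_mean <- liver$suv_mean
    suv_sd <- liver$suv_sd
  } else {
    suv_mean <- liver
    if (is.null(suv_sd)) {
      abort("Provide `suv_sd` when `liver` is a plain mean.",
        class = "mtvsurv_invalid_argument")
    }
  }
  if (!is.finite(suv_mean) || !is.finite(suv_sd) || suv_mean < 0 || suv_sd < 0) {
    abort("Liver mean and SD must be finite and >= 0.",
      class = "mtvsurv_invalid_argument")
  }
  1.5 * suv_mean + 2 * suv_sd
}

# Offsets of the 6- or 26-neighborhood in 3D, excluding the centre.
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

# Label connected components among the voxels listed in `idx` (n x 3 index
# matrix) on a grid of dimensions `dims`. Returns an integer membership
# vector aligned with the rows of idx. Adjacency edges are built vectorized
# per neighbour offset and components come from igraph.
label_components <- function(idx, dims, connectivity = 26) {
  n <- nrow(idx)
  if (n == 0L) return(integer(0))
  lin <- as.integer(idx[, 1] + (idx[, 2] - 1L) * dims[1] +
    (idx[, 3] - 1L) * dims[1] * dims[2])
  pos <- integer(prod(dims))
  pos[lin] <- seq_len(n)
  offs <- neighbor_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    ni <- idx[, 1] + offs[r, 1]
    nj <- idx[, 2] + offs[r, 2]
    nk <- idx[, 3] + offs[r, 3]
    ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] &
      nk >= 1L & nk <= dims[3]
    if (!any(ok)) next
    nlin <- ni[ok] + (nj[ok] - 1L) * dims[1] + (nk[ok] - 1L) * dims[1] * dims[2]
    nb <- pos[nlin]
    hit <- nb > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Segment the molecular tumor volume above a threshold
#'
#' Emulates semi-automatic workstation segmentation of non-physiologic
#' tracer uptake: voxels with SUV strictly above the threshold are grouped
#' into connected components (26-neighborhood by default); components mostly
#' covered by a caller-supplied exclusion mask — standing in for the
#' physician's removal of physiological uptake such as kidney or pituitary —
#' are dropped and counted; components smaller than `min_lesion_ml` are
#' dropped. The remaining components are the lesions and their volumes sum
#' to the total MTV.
#'
#' @param volume A [pet_volume()].
#' @param threshold SUV threshold (`>= 0`); voxels must be strictly greater
#'   to be foreground. Typically from [segmentation_threshold()].
#' @param exclusion_mask Optional logical array on the same grid flagging
#'   physiological uptake.
#' @param min_lesion_ml Minimum lesion volume in ml; smaller components are
#'   discarded. Default 0 (no minimum).
#' @param connectivity 26 (default) or 6.
#' @param exclusion_overlap A component is dropped when the fraction of its
#'   voxels inside `exclusion_mask` exceeds this value. Default 0.5.
#' @return An object of class `mtv_segmentation`: lesion table (tibble with
#'   `lesion_id`, `n_voxels`, `volume_ml`, `suv_max`, `suv_mean`), the
#'   threshold used, `total_mtv_ml`, `excluded_component_count`, and the
#'   integer label array (`0` = background).
#' @examples
#' vol <- pet_volume(array(1, dim = c(10, 10, 10)), spacing = c(2, 2, 2))
#' vol[4:6, 4:6, 4:6] <- 12
#' segment_mtv(vol, threshold = 8.895)
#' @export
segment_mtv <- function(volume, threshold, exclusion_mask = NULL,
                        min_lesion_ml = 0, connectivity = c(26, 6),
                        exclusion_overlap = 0.5) {
  stopifnot(inherits(volume, "pet_volume"))
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
  connectivity <- as.integer(connectivity)
  if (!is.finite(threshold) || threshold < 0) {
    abort("`threshold` must be finite and >= 0.",
      class = "mtvsurv_invalid_argument")
  }
  if (!is.null(exclusion_mask) && !identical(dim(exclusion_mask), dim(volume))) {
    abort("`exclusion_mask` grid does not match the volume.",
      class = "mtvsurv_shape_error")
  }
  dims <- dim(volume)
  vv <- voxel_volume_ml(volume)
  fg <- volume > threshold
  idx <- which(fg, arr.ind = TRUE)
  labels <- array(0L, dim = dims)
  excluded <- 0L
  lesions <- tibble(
    lesion_id = integer(), n_voxels = integer(), volume_ml = numeric(),
    suv_max = numeric(), suv_mean = numeric()
  )
  if (nrow(idx) > 0L) {
    memb <- label_components(idx, dims, connectivity)
    lin <- idx[, 1] + (idx[, 2] - 1L) * dims[1] + (idx[, 3] - 1L) * dims[1] * dims[2]
    comp_ids <- sort(unique(memb))
    keep_id <- 0L
    for (cid in comp_ids) {
      sel <- memb == cid
      clin <- lin[sel]
      if (!is.null(exclusion_mask)) {
        frac <- mean(exclusion_mask[clin])
        if (frac > exclusion_overlap) {
          excluded <- excluded + 1L
          next
        }
      }
      vol_ml <- sum(sel) * vv
      if (vol_ml < min_lesion_ml) next
      keep_id <- keep_id + 1L
      labels[clin] <- keep_id
      vals <- volume[clin]
      lesions <- dplyr::bind_rows(lesions, tibble(
        lesion_id = keep_id, n_voxels = sum(sel), volume_ml = vol_ml,
        suv_max = max(vals), suv_mean = mean(vals)
      ))
    }
  }
  structure(
    list(
      lesions = lesions,
      threshold = threshold,
      total_mtv_ml = sum(lesions$volume_ml),
      excluded_component_count = excluded,
      labels = labels,
      connectivity = connectivity,
      min_lesion_ml = min_lesion_ml,
      voxel_volume_ml = vv,
      spacing = attr(volume, "spacing")
    ),
    class = "mtv_segmentation"
  )
}

#' @export
print.mtv_segmentation <- function(x, ...) {
  cat(sprintf(
    "<mtv_segmentation> threshold %.4g SUV, %d lesion(s), total MTV %.4g ml (%d excluded)\n",
    x$threshold, nrow(x$lesions), x$total_mtv_ml, x$excluded_component_count))
  if (nrow(x$lesions) > 0) print(x$lesions, ...)
  invisible(x)
}

#' Total molecular tumor volume of a segmentation
#'
#' @param seg An `mtv_segmentation` from [segment_mtv()].
#' @return Total MTV in ml.
#' @export
total_mtv <- function(seg) {
  stopifnot(inherits(seg, "mtv_segmentation"))
  seg$total_mtv_ml
}

#' SUV metrics of the largest segmented lesion
#'
#' Returns SUVmax and the MTV-based SUVmean (mean over segmented voxels) of
#' the lesion with the largest volume. Ties on volume go to the lesion with
#' the higher SUVmax, then to the lower lesion id (seed order) for
#' determinism.
#'
#' @param seg An `mtv_segmentation` from [segment_mtv()].
#' @return One-row tibble with `lesion_id`, `volume_ml`, `suv_max`,
#'   `suv_mean`.
#' @export
largest_lesion_metrics <- function(seg) {
  stopifnot(inherits(seg, "mtv_segmentation"))
  if (nrow(seg$lesions) == 0L) {
    abort("Segmentation contains no lesions.",
      class = "mtvsurv_empty_segmentation")
  }
  seg$lesions |>
    dplyr::arrange(dplyr::desc(.data$volume_ml), dplyr::desc(.data$suv_max),
      .data$lesion_id) |>
    dplyr::slice(1) |>
    dplyr::select("lesion_id", "volume_ml", "suv_max", "suv_mean")
}

#' @method tidy mtv_segmentation
#' @export
tidy.mtv_segmentation <- function(x, ...) x$lesions

#' @method glance mtv_segmentation
#' @export
glance.mtv_segmentation <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    n_lesions = nrow(x$lesions),
    total_mtv_ml = x$total_mtv_ml,
    excluded_component_count = x$excluded_component_count,
    connectivity = x$connectivity,
    min_lesion_ml = x$min_lesion_ml
  )
}
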