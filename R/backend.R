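# The pluggable segmentation slot. Backends consume an image volume and
# return a label volume on the identical grid. Two kinds are provided: a
# deterministic Hounsfield-threshold stub (the test backend), and an
# external-command adapter speaking the NIfTI-in/NIfTI-out contract that
# model frameworks such as nnU-net use.

#' Specify a segmentation backend
#'
#' @param kind `"threshold_stub"` or `"external_command"`.
#' @param hu_low,hu_high Threshold window in HU (stub); `hu_low < hu_high`.
#' @param min_component_voxels Drop 26-connected components smaller than
#'   this many voxels (stub; 0 disables).
#' @param keep_largest_only Keep only the largest component (stub); ties are
#'   broken by the lowest linear voxel index of a component's seed.
#' @param command Command template with `{input_nifti}` and `{output_nifti}`
#'   placeholders (external).
#' @param timeout_seconds Wall-clock limit for the external command.
#' @return A `backend_spec`.
#' @export
backend_spec <- function(kind = c("threshold_stub", "external_command"),
                         hu_low = 40, hu_high = 80,
                         min_component_voxels = 0L,
                         keep_largest_only = FALSE,
                         command = NULL,
                         timeout_seconds = 600) {
  kind <- match.arg(kind)
  if (kind == "threshold_stub") {
    if (!(hu_low < hu_high)) stop("hu_low must be < hu_high", call. = FALSE)
    if (min_component_voxels < 0L) stop("min_component_voxels must be >= 0", call. = FALSE)
  } else {
    if (is.null(command) || !nzchar(command)) stop("external_command requires a command template", call. = FALSE)
    if (!grepl("{input_nifti}", command, fixed = TRUE) ||
        !grepl("{output_nifti}", command, fixed = TRUE)) {
      stop("command template must contain {input_nifti} and {output_nifti}", call. = FALSE)
    }
    if (timeout_seconds <= 0) stop("timeout_seconds must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, hu_low = hu_low, hu_high = hu_high,
                 min_component_voxels = as.integer(min_component_voxels),
                 keep_largest_only = isTRUE(keep_largest_only),
                 command = command, timeout_seconds = timeout_seconds),
            class = "backend_spec")
}

#' 26-connected components of a 3-D mask
#'
#' Component labelling via a vectorised neighbour edge list over the mask
#' voxels and graph components ('igraph'); 26-neighbourhood (face, edge and
#' corner adjacency).
#'
#' @param mask 3-D logical array.
#' @return Integer array of the same shape: 0 outside the mask, component
#'   ids (numbered by ascending smallest linear voxel index) inside.
#' @export
connected_components_26 <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  out <- array(0L, dim = dims)
  if (!length(idx)) return(out)
  vox_id <- integer(prod(dims))
  vox_id[idx] <- seq_along(idx)
  ar <- arrayInd(idx, dims)
  shifts <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, dk = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  # half the shifts suffice for an undirected edge list
  shifts <- shifts[seq_len(nrow(shifts) / 2), , drop = FALSE]
  edges <- list()
  for (s in seq_len(nrow(shifts))) {
    nb <- sweep(ar, 2, shifts[s, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] + (nb[ok, 3] - 1L) * dims[1] * dims[2]
    nb_id <- vox_id[nb_lin]
    here <- which(ok)[nb_id > 0L]
    if (!length(here)) next
    edges[[length(edges) + 1L]] <- rbind(here, nb_id[nb_id > 0L])
  }
  if (length(edges)) {
    g <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                            n = length(idx), directed = FALSE)
    membership <- igraph::components(g)$membership
  } else {
    membership <- seq_along(idx)
  }
  # renumber components by ascending seed (smallest linear index)
  seed <- vapply(split(idx, membership), min, 0)
  renum <- integer(length(seed))
  renum[order(seed)] <- seq_along(seed)
  out[idx] <- renum[membership]
  out
}

.segment_threshold <- function(volume, spec) {
  mask <- volume$voxels >= spec$hu_low & volume$voxels <= spec$hu_high
  if ((spec$min_component_voxels > 0L || spec$keep_largest_only) && any(mask)) {
    comp <- connected_components_26(mask)
    sizes <- tabulate(comp[comp > 0L])
    keep <- which(sizes >= spec$min_component_voxels)
    if (spec$keep_largest_only && length(keep)) {
      # ties broken by lowest-index seed: components are numbered by seed,
      # so which.max picks the earliest-seed component among the largest
      keep <- keep[which.max(sizes[keep])]
    }
    mask <- array(comp %in% keep & comp > 0L, dim = dim(mask))
  }
  labels <- array(0L, dim = dim(mask))
  labels[mask] <- 1L
  label_volume(labels, volume$geometry)
}

.segment_external <- function(volume, spec) {
  work <- tempfile("ctqv_backend_")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE), add = TRUE)
  input <- file.path(work, "input.nii.gz")
  output <- file.path(work, "output.nii.gz")
  write_nifti(volume, input)
  cmd <- gsub("{input_nifti}", shQuote(input), spec$command, fixed = TRUE)
  cmd <- gsub("{output_nifti}", shQuote(output), cmd, fixed = TRUE)
  status <- tryCatch(
    system(cmd, intern = FALSE, timeout = spec$timeout_seconds),
    error = function(e) -1L, warning = function(w) -1L
  )
  if (!identical(as.integer(status), 0L)) {
    stop(errorCondition(
      sprintf("segmentation backend command failed (exit status %s): %s", status, cmd),
      class = c("ctqv_backend_error", "ctqv_error")))
  }
  if (!file.exists(output)) {
    stop(errorCondition("segmentation backend produced no output mask",
                        class = c("ctqv_backend_error", "ctqv_error")))
  }
  tryCatch(read_nifti_labels(output, volume$geometry),
           ctqv_error = function(e) {
             stop(errorCondition(paste0("backend output mask invalid: ", conditionMessage(e)),
                                 class = c("ctqv_backend_error", "ctqv_error")))
           })
}

#' Run a segmentation backend on an image volume
#'
#' The threshold stub labels voxels with `hu_low <= HU <= hu_high` as label
#' 1, drops 26-connected components below `min_component_voxels`, and
#' optionally keeps only the largest component. It is a pure function of its
#' inputs. The external adapter writes the volume as NIfTI, substitutes the
#' file paths into the command template, runs it, and validates the returned
#' mask against the source geometry.
#'
#' @param volume An [image_volume()].
#' @param spec A [backend_spec()].
#' @return A [label_volume()] on the identical geometry.
#' @export
segment_volume <- function(volume, spec) {
  stopifnot(inherits(volume, "image_volume"), inherits(spec, "backend_spec"))
  switch(spec$kind,
         threshold_stub = .segment_threshold(volume, spec),
         external_command = .segment_external(volume, spec))
}
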