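#' Landmark dataset container
#'
#' A `landmark_dataset` holds digitized 2-D landmark configurations for a set
#' of specimens (optionally with repeated digitizations of each specimen).
#' Each landmark carries a label (e.g. `"MP1"`) and a role: `"reference"`
#' landmarks sit on stable anatomy (wing-vein junctions and vein-margin
#' intersections) and are used to estimate the Procrustes superimposition;
#' `"measurement"` points sit at pattern-vein intersections and are the
#' objects of the correlation analysis — they are transformed by the
#' reference fit but never used to estimate it.
#'
#' @param coords numeric array `k x 2 x m`: `k` landmarks, x/y columns, `m`
#'   configurations (specimen-replicate combinations). Coordinates are in the
#'   digitizer's pixel units.
#' @param labels character vector of length `k`; unique landmark labels.
#' @param roles character vector of length `k`; each `"reference"` or
#'   `"measurement"`.
#' @param specimen character vector of length `m` of specimen ids.
#' @param replicate integer vector of length `m` of digitization replicate
#'   ids (>= 1). Defaults to all 1.
#' @param species optional species label for the whole dataset.
#'
#' @return An object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(coords, labels, roles, specimen,
                             replicate = rep(1L, dim(coords)[3]),
                             species = "") {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 2L)
    stop("`coords` must be a k x 2 x m array", call. = FALSE)
  k <- dim(coords)[1]
  m <- dim(coords)[3]
  labels <- as.character(labels)
  roles <- as.character(roles)
  if (length(labels) != k || length(roles) != k)
    stop("`labels` and `roles` must have one entry per landmark", call. = FALSE)
  if (anyDuplicated(labels))
    stop("landmark labels must be unique within a configuration", call. = FALSE)
  if (!all(roles %in% c("reference", "measurement")))
    stop("roles must be 'reference' or 'measurement'", call. = FALSE)
  if (sum(roles == "reference") < 3L)
    stop("at least 3 reference landmarks are required for a rigid fit",
         call. = FALSE)
  specimen <- as.character(specimen)
  replicate <- as.integer(replicate)
  if (length(specimen) != m || length(replicate) != m)
    stop("`specimen` and `replicate` must have one entry per configuration",
         call. = FALSE)
  if (any(replicate < 1L))
    stop("replicate ids must be >= 1", call. = FALSE)
  key <- paste(specimen, replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (specimen, replicate) pair in dataset", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  dimnames(coords) <- list(labels, c("x", "y"), NULL)
  structure(
    list(coords = coords, labels = labels, roles = roles,
         specimen = specimen, replicate = replicate, species = species),
    class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("Landmark dataset", if (nzchar(x$species)) paste0("(", x$species, ")"),
      "\n")
  cat("  specimens:   ", length(unique(x$specimen)), "\n")
  cat("  replicates:  ", paste(sort(unique(x$replicate)), collapse = ", "),
      "\n")
  cat("  landmarks:   ", sum(x$roles == "reference"), "reference +",
      sum(x$roles == "measurement"), "measurement\n")
  invisible(x)
}

#' Number of configurations in a landmark dataset
#' @param x a `landmark_dataset`
#' @return integer count of specimen-replicate configurations.
#' @export
n_configurations <- function(x) {
  stopifnot(inherits(x, "landmark_dataset"))
  dim(x$coords)[3]
}

#' Subset a landmark dataset by specimen
#'
#' Keeps (or drops) whole specimens, all replicates included. Used by the
#' leave-one-out stability analysis.
#'
#' @param x a `landmark_dataset`
#' @param keep character vector of specimen ids to retain.
#' @return a `landmark_dataset` restricted to `keep`.
#' @export
subset_specimens <- function(x, keep) {
  stopifnot(inherits(x, "landmark_dataset"))
  sel <- x$specimen %in% keep
  if (!any(sel)) stop("no configurations left after subsetting", call. = FALSE)
  landmark_dataset(x$coords[, , sel, drop = FALSE], x$labels, x$roles,
                   x$specimen[sel], x$replicate[sel], x$species)
}

# internal: coordinates of one role as k x 2 x m array, plus labels
.role_coords <- function(x, role) {
  idx <- which(x$roles == role)
  list(coords = x$coords[idx, , , drop = FALSE], labels = x$labels[idx])
}
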