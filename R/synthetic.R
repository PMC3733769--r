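#' Specification for a synthetic landmark dataset with planted modules
#'
#' Describes a generator that emulates the covariance structure the
#' correlation-network analysis assumes: measurement points partitioned
#' into modules whose members share a per-specimen common displacement
#' (tightly coupled units), everything else varying independently, the
#' whole configuration perturbed by a per-specimen rigid-similarity
#' nuisance, and replicate digitizations adding small error.
#'
#' All scales are in the template's pixel units (reference ring radius 100).
#'
#' @param n_specimens number of specimens.
#' @param k_reference number of reference landmarks (>= 3).
#' @param modules list of disjoint character vectors of measurement-point
#'   labels — the planted modules. Labels not covered by any module vary
#'   independently.
#' @param k_measurement total number of measurement points; defaults to the
#'   number of labels covered by `modules`.
#' @param module_effect_sd sd of the shared per-specimen module
#'   displacement (per coordinate).
#' @param noise_sd sd of independent per-landmark noise (per coordinate).
#' @param digitization_sd sd of replicate digitization error (per
#'   coordinate, applied after the nuisance transform).
#' @param replicates digitization replicates per specimen (>= 1).
#' @param rotation_range,translation_range,scale_range ranges of the
#'   per-specimen rigid-similarity nuisance: rotation angle (radians),
#'   translation (+/- per coordinate), and scale factor.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_specimens = 24L, k_reference = 21L,
                           modules = list(paste0("MP", 1:2),
                                          paste0("MP", c(3:6, 11)),
                                          paste0("MP", c(7:10, 12:14)),
                                          paste0("MP", 15:19)),
                           k_measurement = NULL,
                           module_effect_sd = 5, noise_sd = 1,
                           digitization_sd = 0.2, replicates = 2L,
                           rotation_range = c(-pi, pi),
                           translation_range = 50,
                           scale_range = c(0.8, 1.25), seed = 1L) {
  all_members <- unlist(modules)
  if (anyDuplicated(all_members))
    stop("spec error: planted modules must be disjoint", call. = FALSE)
  if (is.null(k_measurement)) k_measurement <- length(all_members)
  if (k_measurement < length(all_members))
    stop("spec error: k_measurement smaller than module membership",
         call. = FALSE)
  if (any(c(module_effect_sd, noise_sd, digitization_sd) < 0))
    stop("spec error: sd parameters must be >= 0", call. = FALSE)
  if (replicates < 1L) stop("spec error: replicates must be >= 1",
                            call. = FALSE)
  if (k_reference < 3L) stop("spec error: need >= 3 reference landmarks",
                             call. = FALSE)
  structure(
    list(n_specimens = as.integer(n_specimens),
         k_reference = as.integer(k_reference),
         k_measurement = as.integer(k_measurement),
         modules = modules, module_effect_sd = module_effect_sd,
         noise_sd = noise_sd, digitization_sd = digitization_sd,
         replicates = as.integer(replicates),
         rotation_range = rotation_range,
         translation_range = translation_range,
         scale_range = scale_range, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Preset synthetic specs matching the two study designs
#'
#' `"oexcavata_like"`: 21 reference landmarks, 19 measurement points,
#' n = 24 specimens, 4 planted modules of sizes 2/5/7/5 (the module
#' composition reported for the leaf-patterned wing:
#' MP1-2, MP3-6+11, MP7-10+12-14, MP15-19). `"tjuno_like"`: 18 reference
#' landmarks, 16 measurement points, n = 16, 4 planted modules of sizes
#' 3/4/5/4 (MP1-3, MP4-7, MP8-12, MP13-16). Both with 2 digitization
#' replicates and an effect-to-noise sd ratio of 5.
#'
#' @param species `"oexcavata_like"` or `"tjuno_like"`.
#' @param seed integer seed.
#' @return a [synthetic_spec()].
#' @export
paper_shaped_spec <- function(species = c("oexcavata_like", "tjuno_like"),
                              seed = 1L) {
  species <- match.arg(species)
  if (species == "oexcavata_like") {
    synthetic_spec(n_specimens = 24L, k_reference = 21L,
                   modules = list(paste0("MP", 1:2),
                                  paste0("MP", c(3:6, 11)),
                                  paste0("MP", c(7:10, 12:14)),
                                  paste0("MP", 15:19)),
                   seed = seed)
  } else {
    synthetic_spec(n_specimens = 16L, k_reference = 18L,
                   modules = list(paste0("MP", 1:3), paste0("MP", 4:7),
                                  paste0("MP", 8:12), paste0("MP", 13:16)),
                   seed = seed)
  }
}

# internal: template shape — reference landmarks on a 100 px ring around
# (250, 250), measurement points on a 60 px inner ring, labels MP1..MPk in
# angular order so planted modules are spatially contiguous
.template_shape <- function(k_ref, k_mp) {
  ang_ref <- 2 * pi * (seq_len(k_ref) - 1) / k_ref
  ang_mp <- 2 * pi * (seq_len(k_mp) - 1) / k_mp
  list(reference = cbind(250 + 100 * cos(ang_ref),
                         250 + 100 * sin(ang_ref)),
       measurement = cbind(250 + 60 * cos(ang_mp),
                           250 + 60 * sin(ang_mp)))
}

#' Generate a synthetic landmark dataset with planted modular covariance
#'
#' Builds a template (reference ring + measurement-point ring), then per
#' specimen: each planted module draws one shared 2-D displacement
#' (`sd = module_effect_sd`) added to all its members; every measurement
#' point additionally gets independent noise (`noise_sd`); reference
#' landmarks get independent noise only. The whole configuration then
#' receives a random rotation/translation/scale nuisance, and each
#' replicate adds digitization noise after the nuisance. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a [landmark_dataset()]), `planted` (the
#'   planted [canonical_partition()], singletons for uncovered points), and
#'   `truth` (the nuisance-free measurement coordinates, `k_mp x 2 x n`, as
#'   oracle for alignment tests).
#' @export
generate_landmarks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(spec$seed)

  k_ref <- spec$k_reference
  k_mp <- spec$k_measurement
  n <- spec$n_specimens
  r <- spec$replicates
  tmpl <- .template_shape(k_ref, k_mp)
  mp_labels <- paste0("MP", seq_len(k_mp))
  ref_labels <- paste0("R", seq_len(k_ref))
  mod_idx <- lapply(spec$modules, function(mm) match(mm, mp_labels))
  if (anyNA(unlist(mod_idx)))
    stop("spec error: module labels outside MP1..MP", k_mp, call. = FALSE)

  k <- k_ref + k_mp
  coords <- array(NA_real_, c(k, 2, n * r))
  truth <- array(NA_real_, c(k_mp, 2, n),
                 dimnames = list(mp_labels, c("x", "y"), NULL))
  specimen <- character(n * r)
  replicate <- integer(n * r)
  cfg <- 0L
  for (i in seq_len(n)) {
    mp <- tmpl$measurement
    for (m in seq_along(mod_idx)) {
      delta <- stats::rnorm(2, 0, spec$module_effect_sd)
      mp[mod_idx[[m]], 1] <- mp[mod_idx[[m]], 1] + delta[1]
      mp[mod_idx[[m]], 2] <- mp[mod_idx[[m]], 2] + delta[2]
    }
    mp <- mp + matrix(stats::rnorm(2 * k_mp, 0, spec$noise_sd), k_mp, 2)
    ref <- tmpl$reference +
      matrix(stats::rnorm(2 * k_ref, 0, spec$noise_sd), k_ref, 2)
    truth[, , i] <- mp

    theta <- stats::runif(1, spec$rotation_range[1], spec$rotation_range[2])
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    scl <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
    trans <- stats::runif(2, -spec$translation_range,
                          spec$translation_range)
    full <- rbind(ref, mp)
    full <- scl * full %*% rot
    full <- sweep(full, 2, trans, "+")
    for (j in seq_len(r)) {
      cfg <- cfg + 1L
      coords[, , cfg] <- full +
        matrix(stats::rnorm(2 * k, 0, spec$digitization_sd), k, 2)
      specimen[cfg] <- sprintf("S%02d", i)
      replicate[cfg] <- j
    }
  }
  ds <- landmark_dataset(coords, c(ref_labels, mp_labels),
                         c(rep("reference", k_ref),
                           rep("measurement", k_mp)),
                         specimen, replicate, species = "synthetic")
  assign <- rep(NA_integer_, k_mp)
  names(assign) <- mp_labels
  for (m in seq_along(mod_idx)) assign[mod_idx[[m]]] <- m
  free <- which(is.na(assign))
  if (length(free)) assign[free] <- length(mod_idx) + seq_along(free)
  list(dataset = ds,
       planted = canonical_partition(assign, mp_labels),
       truth = truth)
}
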