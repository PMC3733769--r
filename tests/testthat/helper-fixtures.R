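# shared fixture builders

# random weighted network: each pair carries an edge with prob `density`,
# weight U(0,1)
make_random_network <- function(k, seed, density = 0.5) {
  set.seed(seed)
  w <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (stats::runif(1) < density) w[i, j] <- w[j, i] <- stats::runif(1)
  }
  corr_network(w, paste0("N", seq_len(k)))
}

# two disjoint m-cliques with unit weights, labels A1..Am, B1..Bm
make_clique_pair <- function(m = 3) {
  k <- 2 * m
  w <- matrix(0, k, k)
  w[seq_len(m), seq_len(m)] <- 1
  w[(m + 1):k, (m + 1):k] <- 1
  diag(w) <- 0
  corr_network(w, c(paste0("A", seq_len(m)), paste0("B", seq_len(m))))
}

# tiny landmark dataset: `n` specimens x `r` replicates, k_ref reference
# landmarks on a ring, k_mp measurement points, pure noise
make_noise_dataset <- function(n = 6, r = 1, k_ref = 5, k_mp = 4,
                               noise_sd = 0.01, seed = 1) {
  spec <- synthetic_spec(
    n_specimens = n, k_reference = k_ref,
    modules = list(), k_measurement = k_mp,
    module_effect_sd = 0, noise_sd = noise_sd,
    digitization_sd = if (r > 1) noise_sd / 2 else 0, replicates = r,
    seed = seed)
  generate_landmarks(spec)
}

# rigid-similarity transform applied to every configuration of a dataset,
# drawn per configuration
perturb_rigid <- function(dataset, seed) {
  set.seed(seed)
  coords <- dataset$coords
  for (i in seq_len(dim(coords)[3])) {
    th <- stats::runif(1, -pi, pi)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    s <- stats::runif(1, 0.5, 2)
    tr <- stats::runif(2, -100, 100)
    coords[, , i] <- sweep(s * coords[, , i] %*% rot, 2, tr, "+")
  }
  landmark_dataset(coords, dataset$labels, dataset$roles,
                   dataset$specimen, dataset$replicate, dataset$species)
}

partition_key <- function(p)
  paste(vapply(p, paste, "", collapse = ","), collapse = "|")
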