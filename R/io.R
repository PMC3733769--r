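#' Read a landmark dataset from file
#'
#' Two dialects are supported. The CSV dialect is the canonical interchange
#' format: one row per landmark with columns
#' `specimen, replicate, label, role, x, y`; row order within the first
#' configuration defines the landmark order. The TPS dialect reads classic
#' `LM=` / coordinate-line / `ID=` (or `IMAGE=`) records; TPS files carry no
#' role or label tags, so these are supplied through the `roles` and `labels`
#' arguments (a per-index role map), keeping the standard format standard.
#'
#' @param path path to the file.
#' @param format `"csv"` or `"tps"`.
#' @param roles for TPS input: character vector, one role
#'   (`"reference"`/`"measurement"`) per landmark index.
#' @param labels for TPS input: optional landmark labels; defaults to
#'   `L1..Lk`.
#' @param species species label attached to the dataset.
#' @return a [landmark_dataset()].
#' @export
read_landmarks <- function(path, format = c("csv", "tps"), roles = NULL,
                           labels = NULL, species = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") .read_landmarks_csv(path, species)
  else .read_landmarks_tps(path, roles, labels, species)
}

.read_landmarks_csv <- function(path, species) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "replicate", "label", "role", "x", "y")
  if (!all(need %in% names(df)))
    stop("CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("parse error: non-numeric coordinates in ", path, call. = FALSE)
  key <- paste(df$specimen, df$replicate, sep = "\r")
  cfgs <- split(df, factor(key, levels = unique(key)))
  first <- cfgs[[1]]
  k <- nrow(first)
  coords <- array(NA_real_, c(k, 2, length(cfgs)))
  specimen <- character(length(cfgs))
  replicate <- integer(length(cfgs))
  for (i in seq_along(cfgs)) {
    cfg <- cfgs[[i]]
    if (nrow(cfg) != k)
      stop("structure error: specimen ", cfg$specimen[1], " replicate ",
           cfg$replicate[1], " has ", nrow(cfg), " landmarks, expected ", k,
           call. = FALSE)
    if (!identical(cfg$label, first$label) ||
        !identical(cfg$role, first$role))
      stop("structure error: label/role sequence differs for specimen ",
           cfg$specimen[1], call. = FALSE)
    coords[, 1, i] <- cfg$x
    coords[, 2, i] <- cfg$y
    specimen[i] <- as.character(cfg$specimen[1])
    replicate[i] <- as.integer(cfg$replicate[1])
  }
  landmark_dataset(coords, first$label, first$role, specimen, replicate,
                   species)
}

.read_landmarks_tps <- function(path, roles, labels, species) {
  if (is.null(roles))
    stop("TPS input needs a `roles` map (one role per landmark index)",
         call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  configs <- list()
  ids <- character()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("parse error at line ", i, ": expected LM= record", call. = FALSE)
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("parse error at line ", i, ": bad landmark count", call. = FALSE)
    if (i + k > length(lines))
      stop("parse error at line ", i, ": truncated coordinate block",
           call. = FALSE)
    xy <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      parts <- strsplit(lines[i + j], "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2L || anyNA(vals))
        stop("parse error at line ", i + j, ": expected two coordinates",
             call. = FALSE)
      xy[j, ] <- vals
    }
    i <- i + k + 1L
    id <- NA_character_
    while (i <= length(lines) && nzchar(lines[i]) &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      if (grepl("^(ID|IMAGE)\\s*=", lines[i], ignore.case = TRUE) &&
          is.na(id))
        id <- sub("^(ID|IMAGE)\\s*=\\s*", "", lines[i], ignore.case = TRUE)
      i <- i + 1L
    }
    if (is.na(id)) id <- paste0("spec", length(configs) + 1L)
    configs[[length(configs) + 1L]] <- xy
    ids <- c(ids, id)
  }
  if (!length(configs)) stop("parse error: no TPS records in ", path,
                             call. = FALSE)
  k <- nrow(configs[[1]])
  bad <- which(vapply(configs, nrow, 0L) != k)
  if (length(bad))
    stop("structure error: record ", bad[1], " has ",
         nrow(configs[[bad[1]]]), " landmarks, expected ", k, call. = FALSE)
  if (length(roles) != k)
    stop("roles map length ", length(roles), " != landmark count ", k,
         call. = FALSE)
  if (is.null(labels)) labels <- paste0("L", seq_len(k))
  coords <- array(unlist(configs), c(k, 2, length(configs)))
  landmark_dataset(coords, labels, roles, ids, rep(1L, length(configs)),
                   species)
}

#' Write a landmark dataset to the canonical CSV dialect
#'
#' @param x a `landmark_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(x, path) {
  stopifnot(inherits(x, "landmark_dataset"))
  m <- n_configurations(x)
  k <- length(x$labels)
  df <- data.frame(
    specimen = rep(x$specimen, each = k),
    replicate = rep(x$replicate, each = k),
    label = rep(x$labels, m),
    role = rep(x$roles, m),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pairwise Rv coefficient matrix
#'
#' Reads a labeled table of Rv coefficients between measurement points, as
#' deposited with published analyses: either a full symmetric matrix or a
#' lower-triangular one (upper entries empty). The result is always a full
#' symmetric matrix with unit diagonal.
#'
#' @param path CSV file with row and column labels.
#' @return an [rv_matrix_obj()] with `n_specimens = NA` (unknown provenance).
#' @export
read_rv_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  vals <- as.matrix(df)
  if (nrow(vals) != ncol(vals) ||
      !identical(rownames(vals), colnames(vals)))
    stop("structure error: row/column label sets differ", call. = FALSE)
  labels <- rownames(vals)
  k <- length(labels)
  full <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    lo <- vals[max(i, j), min(i, j)]
    hi <- vals[min(i, j), max(i, j)]
    v <- if (!is.na(lo)) lo else hi
    if (!is.na(lo) && !is.na(hi) && abs(lo - hi) > 1e-8 && i != j)
      stop("value error: asymmetric entries for (", labels[i], ", ",
           labels[j], ")", call. = FALSE)
    full[i, j] <- v
  }
  diag(full) <- 1
  if (anyNA(full))
    stop("structure error: missing entries in Rv table", call. = FALSE)
  if (any(full < 0 | full > 1))
    stop("value error: Rv entries must lie in [0, 1]", call. = FALSE)
  rv_matrix_obj(full, labels, n_specimens = NA_integer_)
}

#' Write an Rv matrix as a full symmetric labeled CSV
#' @param rv an `rv_matrix` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rv_matrix <- function(rv, path) {
  stopifnot(inherits(rv, "rv_matrix"))
  utils::write.csv(rv$values, path, quote = FALSE)
  invisible(path)
}

#' Write a correlation network to file
#'
#' `"edgelist"` writes a plain whitespace edge list (`MP1 MP2 0.5`, one line
#' per edge, weights at 10 significant digits) preceded by comment lines
#' listing the node set and the threshold, so that isolated nodes and the
#' threshold survive a round trip. `"graphml"` delegates to igraph.
#'
#' @param net a [corr_network()].
#' @param path output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(net, "corr_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph_network(net), path, format = "graphml")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# nodes:", paste(net$labels, collapse = " ")), con)
  writeLines(paste("# tau:", if (is.null(net$tau)) "none" else
    sprintf("%.10g", net$tau)), con)
  k <- length(net$labels)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    w <- net$weights[i, j]
    if (w > 0)
      writeLines(sprintf("%s %s %.10g", net$labels[i], net$labels[j], w),
                 con)
  }
  invisible(path)
}

#' Read a correlation network written by [write_network()]
#' @param path input path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return a [corr_network()].
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    labels <- igraph::V(g)$name
    k <- length(labels)
    w <- matrix(0, k, k, dimnames = list(labels, labels))
    el <- igraph::as_edgelist(g, names = TRUE)
    ew <- igraph::E(g)$weight
    for (e in seq_len(nrow(el))) {
      w[el[e, 1], el[e, 2]] <- ew[e]
      w[el[e, 2], el[e, 1]] <- ew[e]
    }
    tau <- igraph::graph_attr(g, "tau")
    if (is.null(tau) || is.na(tau)) tau <- NULL
    return(corr_network(w, labels, tau))
  }
  lines <- readLines(path, warn = FALSE)
  nodeln <- grep("^# nodes:", lines, value = TRUE)
  if (!length(nodeln)) stop("parse error: missing '# nodes:' header",
                            call. = FALSE)
  labels <- strsplit(sub("^# nodes:\\s*", "", nodeln[1]), "\\s+")[[1]]
  tauln <- grep("^# tau:", lines, value = TRUE)
  tau <- NULL
  if (length(tauln)) {
    tv <- sub("^# tau:\\s*", "", tauln[1])
    if (tv != "none") tau <- as.numeric(tv)
  }
  k <- length(labels)
  w <- matrix(0, k, k, dimnames = list(labels, labels))
  for (ln in lines[!grepl("^#", lines) & nzchar(lines)]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 3L)
      stop("parse error: bad edge line '", ln, "'", call. = FALSE)
    a <- parts[1]; b <- parts[2]
    if (!a %in% labels || !b %in% labels)
      stop("parse error: unknown node in edge '", ln, "'", call. = FALSE)
    w[a, b] <- w[b, a] <- as.numeric(parts[3])
  }
  corr_network(w, labels, tau)
}
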