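# XYZ and ensemble-manifest file formats.  All coordinates in Angstrom.

#' Read an (optionally multi-frame) XYZ file
#'
#' Standard two-header-line dialect: atom count, comment, then one
#' `element x y z` line per atom; frames may be concatenated.
#'
#' @param path XYZ file.
#' @param carbon_map named integer vector attached to every geometry, or
#'   `NULL` to infer the canonical alpha-terpinene labelling when the
#'   atom list matches the builder geometry (10 C + 16 H in canonical
#'   order), else no labels.
#' @return list of [molecular_geometry()] (one per frame).
#' @export
read_xyz <- function(path, carbon_map = NULL) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > length(lines))]
  out <- list()
  i <- 1L
  frame <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1)
      stop("XYZ parse error at line ", i, ": invalid atom count (frame ",
           frame, ")")
    if (i + 1L + nat > length(lines))
      stop("XYZ parse error: truncated frame ", frame, " starting at line ", i)
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4)
    if (length(bad))
      stop("XYZ parse error at line ", i + 1L + bad[1],
           ": expected element + 3 coordinates (frame ", frame, ")")
    el <- vapply(toks, `[[`, character(1), 1)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop("XYZ parse error in frame ", frame, ": non-numeric coordinate")
    cm <- carbon_map
    if (is.null(cm)) {
      canon <- terpinene_zmatrix()$element
      cm <- if (length(el) == length(canon) && all(el == canon))
        terpinene_carbon_map() else integer()
    }
    out[[frame]] <- molecular_geometry(el, xyz, cm)
    i <- i + 2L + nat
    frame <- frame + 1L
  }
  if (!length(out)) stop("no frames in XYZ file: ", path)
  out
}

#' Write geometries as a (multi-frame) XYZ file
#'
#' @param geometries a [molecular_geometry()] or list of them.
#' @param path output file.
#' @param comments comment line per frame (recycled).
#' @export
write_xyz <- function(geometries, path, comments = "") {
  if (inherits(geometries, "molecular_geometry"))
    geometries <- list(geometries)
  comments <- rep_len(comments, length(geometries))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(geometries)) {
    g <- geometries[[k]]
    writeLines(as.character(length(g$elements)), con)
    writeLines(comments[k], con)
    writeLines(sprintf("%s %.8f %.8f %.8f", g$elements,
                       g$coords[, 1], g$coords[, 2], g$coords[, 3]), con)
  }
}

#' Read a carbon-label sidecar mapping
#'
#' Two-column text: carbon label and 0-based atom index.
#'
#' @param path text file.
#' @return named integer vector (1-based indices) for [molecular_geometry()].
#' @export
read_carbon_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("label", "index0"),
                           stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab$index0) + 1L, tab$label)
}

#' Write an ensemble to a manifest + multi-frame XYZ trajectories
#'
#' The manifest is a CSV with columns `trajectory_id`, `time_fs`,
#' `state`, `weight`, `xyz_path`; one multi-frame XYZ per trajectory.
#'
#' @param ens a [wavepacket_ensemble()].
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (k in seq_along(ens$trajectories)) {
    tr <- ens$trajectories[[k]]
    xyz_rel <- sprintf("traj_%04d.xyz", k)
    geoms <- lapply(seq_along(tr$times), function(i)
      molecular_geometry(ens$elements, tr$coords[, , i], ens$carbon_map))
    write_xyz(geoms, file.path(dir, xyz_rel),
              comments = sprintf("t= %.6f fs state= %s", tr$times, tr$state))
    rows[[k]] <- data.frame(trajectory_id = k, time_fs = tr$times,
                            state = tr$state, weight = tr$weight,
                            xyz_path = xyz_rel)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read an ensemble from a manifest written by [write_ensemble()]
#'
#' @param manifest path to the manifest CSV.
#' @param carbon_map carbon labelling for the frames (default: inferred).
#' @return a [wavepacket_ensemble()].
#' @export
read_ensemble <- function(manifest, carbon_map = NULL) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("trajectory_id", "time_fs", "state", "weight", "xyz_path")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  dir <- dirname(manifest)
  ids <- sort(unique(tab$trajectory_id))
  time_grid <- sort(unique(tab$time_fs))
  trajectories <- vector("list", length(ids))
  elements <- NULL; cmap <- NULL
  for (k in seq_along(ids)) {
    sub <- tab[tab$trajectory_id == ids[k], ]
    sub <- sub[order(sub$time_fs), ]
    geoms <- read_xyz(file.path(dir, sub$xyz_path[1]), carbon_map)
    if (length(geoms) != nrow(sub))
      stop("trajectory ", ids[k], ": XYZ frame count does not match manifest")
    if (is.null(elements)) {
      elements <- geoms[[1]]$elements
      cmap <- geoms[[1]]$carbon_map
    }
    coords <- array(0, c(length(elements), 3, nrow(sub)))
    for (i in seq_along(geoms)) coords[, , i] <- geoms[[i]]$coords
    trajectories[[k]] <- weighted_trajectory(sub$time_fs, coords, sub$state,
                                             sub$weight)
  }
  wavepacket_ensemble(trajectories, time_grid, elements, cmap)
}
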