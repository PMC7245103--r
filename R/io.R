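#' Write a trajectory as tidy CSV
#'
#' One row per (time, species): columns `time`, `species`, `count`,
#' `replicate`.
#'
#' @param traj A `trajectory`.
#' @param path Output CSV path.
#' @param replicate Replicate label recorded in the file (default 1).
#' @export
write_trajectory_csv <- function(traj, path, replicate = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(
    time = rep(traj$grid, each = nrow(traj$counts)),
    species = rep(rownames(traj$counts), times = length(traj$grid)),
    count = as.vector(traj$counts),
    replicate = replicate)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an ensemble summary as CSV
#'
#' One row per (time, species): columns `time`, `species`, `mean`, `var`.
#'
#' @param ens An `ensemble_result`.
#' @param path Output CSV path.
#' @export
write_ensemble_csv <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble_result"))
  df <- data.frame(
    time = rep(ens$grid, each = nrow(ens$mean)),
    species = rep(rownames(ens$mean), times = length(ens$grid)),
    mean = as.vector(ens$mean),
    var = as.vector(ens$var))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export / import a reaction network as JSON
#'
#' Serializes species, reactions (with assigned constants and template
#' annotations) and network options; `read_network_json` restores an
#' identical `reaction_network`.
#'
#' @param network A `reaction_network`.
#' @param path JSON path.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  jsonlite::write_json(
    list(species = network$species, reactions = network$reactions,
         max_nuclearity = network$max_nuclearity,
         lineage_threshold = network$lineage_threshold,
         growth = network$growth, metadata = network$metadata),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- as.data.frame(raw$species, stringsAsFactors = FALSE)
  rx <- as.data.frame(raw$reactions, stringsAsFactors = FALSE)
  for (col in c("r2", "p2", "template_id")) {
    if (!col %in% names(rx)) rx[[col]] <- NA_character_
    rx[[col]][vapply(rx[[col]], is.null, logical(1))] <- NA_character_
    rx[[col]] <- as.character(rx[[col]])
  }
  structure(list(species = sp, reactions = rx,
                 max_nuclearity = as.integer(raw$max_nuclearity),
                 lineage_threshold = as.integer(raw$lineage_threshold),
                 growth = raw$growth,
                 metadata = raw$metadata %||% list()),
            class = "reaction_network")
}

#' Export the reaction list as a flat CSV edge list
#'
#' One row per reaction with reactants, products, kind, base constant and
#' template annotation, for consumption by graph tools.
#'
#' @param network A `reaction_network`.
#' @param path CSV path.
#' @export
write_network_csv <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  utils::write.csv(network$reactions, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the resolved configuration, seeds and package version alongside
#' every output directory, sufficient to reproduce the artifacts exactly.
#'
#' @param path Output JSON path.
#' @param config The resolved configuration (list).
#' @param seeds Integer seeds used.
#' @param extra Optional named list of additional entries.
#' @export
write_manifest <- function(path, config, seeds, extra = list()) {
  manifest <- c(list(
    package = "mobluesim",
    version = as.character(utils::packageVersion("mobluesim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = seeds), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
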