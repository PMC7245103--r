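#' Load the cluster-structure registry
#'
#' Reads the registry of known polyoxomolybdate clusters ({PMo12}, {Mo36},
#' {Mo132}, {Mo154}, the compound-1 {Mo124Ce4} nanoring, ...) together with
#' the building-block table ({Mo1}, corner/edge {Mo2} dimers, {Mo6}, {Mo8},
#' ...). Compositions are stored only where a building-block breakdown is
#' actually known; otherwise a record carries its nuclearity alone.
#'
#' @param path Path to a registry JSON file. Defaults to the registry shipped
#'   with the package.
#' @return An object of class `cluster_registry`: a list with elements
#'   `building_blocks` (data.frame: `label`, `mo_count`, `non_mo_note`) and
#'   `clusters` (named list of `cluster_record` objects).
#' @examples
#' reg <- load_cluster_registry()
#' names(reg$clusters)
#' @export
load_cluster_registry <- function(path = system.file("extdata", "cluster_registry.json",
                                                     package = "mobluesim")) {
  stopifnot(nzchar(path), file.exists(path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  bb <- do.call(rbind, lapply(raw$building_blocks, function(b) {
    data.frame(label = b$label, mo_count = as.integer(b$mo_count),
               non_mo_note = b$non_mo_note %||% "", stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(bb$label)) stop("duplicate building-block labels in registry")
  if (any(bb$mo_count < 0)) stop("building-block mo_count must be non-negative")
  clusters <- lapply(raw$clusters, function(cl) {
    cluster_record(
      name = cl$name,
      composition = if (!is.null(cl$composition)) unlist(cl$composition) else NULL,
      nuclearity = cl$nuclearity %||% NULL,
      mo_vi = cl$mo_vi %||% NULL,
      mo_v = cl$mo_v %||% NULL,
      heteroatoms = if (!is.null(cl$heteroatoms)) unlist(cl$heteroatoms) else NULL,
      note = cl$note %||% ""
    )
  })
  names(clusters) <- vapply(clusters, function(x) x$name, character(1))
  if (anyDuplicated(names(clusters))) stop("duplicate cluster names in registry")
  structure(list(building_blocks = bb, clusters = clusters),
            class = "cluster_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a cluster record
#'
#' A formula-level description of a discrete cluster: optional building-block
#' composition, optional Mo(VI)/Mo(V) split, optional heteroatom counts.
#'
#' @param name Canonical label, e.g. `"{Mo132}"`.
#' @param composition Named integer vector mapping building-block labels to
#'   counts, or `NULL` when the breakdown is unknown.
#' @param nuclearity Total Mo atoms; may be omitted when `composition` is given.
#' @param mo_vi,mo_v Counts of Mo(VI) and Mo(V) centers, or `NULL` if unknown.
#' @param heteroatoms Named integer vector of non-Mo heteroatom counts.
#' @param note Free-text annotation.
#' @return An object of class `cluster_record`.
#' @export
cluster_record <- function(name, composition = NULL, nuclearity = NULL,
                           mo_vi = NULL, mo_v = NULL, heteroatoms = NULL,
                           note = "") {
  stopifnot(is.character(name), length(name) == 1L)
  num_ok <- function(x) is.null(x) || (length(x) == 1L && is.finite(x) && x >= 0)
  if (!num_ok(mo_vi) || !num_ok(mo_v) || !num_ok(nuclearity))
    stop("nuclearity, mo_vi and mo_v must be single non-negative numbers or NULL")
  if (!is.null(composition)) {
    if (is.null(names(composition)) || any(!nzchar(names(composition))))
      stop("composition must be a named vector of building-block counts")
    if (any(composition < 0)) stop("composition counts must be non-negative")
    composition <- vapply(composition, as.integer, integer(1))
  }
  structure(list(name = name, composition = composition,
                 nuclearity = if (is.null(nuclearity)) NULL else as.integer(nuclearity),
                 mo_vi = if (is.null(mo_vi)) NULL else as.integer(mo_vi),
                 mo_v = if (is.null(mo_v)) NULL else as.integer(mo_v),
                 heteroatoms = heteroatoms, note = note),
            class = "cluster_record")
}

#' @export
print.cluster_record <- function(x, ...) {
  cat(x$name, "- nuclearity", cluster_nuclearity(x), "\n")
  if (!is.null(x$mo_vi) && !is.null(x$mo_v))
    cat("  Mo(VI):", x$mo_vi, " Mo(V):", x$mo_v,
        sprintf(" (%d-electron reduced)\n", x$mo_v))
  if (!is.null(x$composition))
    cat("  composition:", paste(names(x$composition), x$composition,
                                sep = "x", collapse = " + "), "\n")
  invisible(x)
}

#' @export
print.cluster_registry <- function(x, ...) {
  cat("<cluster_registry>", length(x$clusters), "clusters,",
      nrow(x$building_blocks), "building blocks\n")
  for (cl in x$clusters) print(cl)
  invisible(x)
}

#' Total Mo nuclearity implied by a building-block composition
#'
#' Sums `count * mo_count` over the composition, the bookkeeping used to
#' verify e.g. that 12 {Mo8} + 8 {Mo2} + 12 {Mo1} units give a 124-Mo ring.
#'
#' @param composition Named integer vector: building-block label -> count.
#' @param registry A `cluster_registry` supplying `mo_count` per label.
#' @return Integer nuclearity (0 for an empty composition).
#' @examples
#' reg <- load_cluster_registry()
#' nuclearity_from_composition(c(Mo8 = 12, Mo2 = 8, Mo1 = 12), reg)
#' @export
nuclearity_from_composition <- function(composition, registry = load_cluster_registry()) {
  stopifnot(inherits(registry, "cluster_registry"))
  if (length(composition) == 0L) return(0L)
  if (is.null(names(composition))) stop("composition must be named by building-block label")
  if (any(composition < 0)) stop("composition counts must be non-negative")
  idx <- match(names(composition), registry$building_blocks$label)
  if (anyNA(idx)) {
    stop("unknown building-block label(s): ",
         paste(names(composition)[is.na(idx)], collapse = ", "))
  }
  as.integer(sum(composition * registry$building_blocks$mo_count[idx]))
}

#' Nuclearity of a cluster record
#'
#' Uses the declared nuclearity when present, otherwise derives it from the
#' composition.
#'
#' @param record A `cluster_record`.
#' @param registry Registry used to resolve composition labels.
#' @return Integer nuclearity.
#' @export
cluster_nuclearity <- function(record, registry = load_cluster_registry()) {
  stopifnot(inherits(record, "cluster_record"))
  if (!is.null(record$nuclearity)) return(record$nuclearity)
  if (!is.null(record$composition))
    return(nuclearity_from_composition(record$composition, registry))
  stop("record '", record$name, "' has neither nuclearity nor composition")
}

#' Number of reducing electrons stored in a cluster
#'
#' One electron per Mo(V) center: a cluster with `mo_v` Mo(V) sites is
#' `mo_v`-electron reduced (e.g. the compound-1 ring is 24-electron reduced,
#' its {PMo12} host 2-electron reduced).
#'
#' @param record A `cluster_record` with `mo_v` specified.
#' @return Integer electron count.
#' @export
reduced_electron_count <- function(record) {
  stopifnot(inherits(record, "cluster_record"))
  if (is.null(record$mo_v))
    stop("record '", record$name, "' has no Mo(V) count; reduction state unknown")
  record$mo_v
}

#' Percentage of molybdenum centers reduced by a stoichiometric reductant
#'
#' For a reductant delivering `electrons_per_reductant` electrons per anion
#' (2 for dithionite, S2O4^2-), the fraction of Mo(VI) centers converted to
#' Mo(V) is `electrons_per_reductant * [reductant] / [Mo]`, capped at 100%.
#'
#' @param mo_molar Total molybdenum concentration (M), > 0.
#' @param reductant_molar Reductant concentration (M), >= 0.
#' @param electrons_per_reductant Electrons delivered per reductant anion;
#'   default 2 (dithionite).
#' @return Percentage in \[0, 100\].
#' @examples
#' reduction_fraction_percent(0.075, 0.023)  # > 60% of Mo centers reduced
#' @export
reduction_fraction_percent <- function(mo_molar, reductant_molar,
                                       electrons_per_reductant = 2L) {
  if (!is.finite(mo_molar) || mo_molar <= 0) stop("mo_molar must be > 0")
  if (!is.finite(reductant_molar) || reductant_molar < 0)
    stop("reductant_molar must be >= 0")
  if (electrons_per_reductant < 0) stop("electrons_per_reductant must be >= 0")
  min(100, 100 * electrons_per_reductant * reductant_molar / mo_molar)
}

#' Validate a cluster registry
#'
#' Recomputes each record's internal sums and reports violations as data,
#' not errors: a record whose Mo(VI)+Mo(V) split disagrees with its
#' nuclearity, a composition naming an unknown building block, or negative
#' counts.
#'
#' @param registry A `cluster_registry`.
#' @return A data.frame with columns `record` and `violation`; zero rows when
#'   every record is consistent.
#' @export
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "cluster_registry"))
  out <- list()
  add <- function(record, msg) out[[length(out) + 1L]] <<-
    data.frame(record = record, violation = msg, stringsAsFactors = FALSE)
  for (cl in registry$clusters) {
    comp_nuc <- NULL
    if (!is.null(cl$composition)) {
      unknown <- setdiff(names(cl$composition), registry$building_blocks$label)
      if (length(unknown)) {
        add(cl$name, paste("unknown building block(s):", paste(unknown, collapse = ", ")))
      } else {
        comp_nuc <- nuclearity_from_composition(cl$composition, registry)
      }
      if (any(cl$composition < 0)) add(cl$name, "negative composition count")
    }
    if (!is.null(comp_nuc) && !is.null(cl$nuclearity) && comp_nuc != cl$nuclearity)
      add(cl$name, sprintf("declared nuclearity %d != composition nuclearity %d",
                           cl$nuclearity, comp_nuc))
    nuc <- if (!is.null(cl$nuclearity)) cl$nuclearity else comp_nuc
    if (!is.null(cl$mo_vi) && !is.null(cl$mo_v) && !is.null(nuc) &&
        cl$mo_vi + cl$mo_v != nuc)
      add(cl$name, sprintf("mo_vi + mo_v = %d != nuclearity %d",
                           cl$mo_vi + cl$mo_v, nuc))
    for (f in c("mo_vi", "mo_v")) {
      if (!is.null(cl[[f]]) && cl[[f]] < 0) add(cl$name, paste("negative", f))
    }
  }
  if (length(out) == 0L)
    return(data.frame(record = character(), violation = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
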