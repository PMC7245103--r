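#' Default run configuration
#'
#' The reference study conditions used throughout the package: the full
#' assembly network up to the {Mo154} wheel with building-block growth,
#' default templation, an all-monomer initial pool, and a horizon long
#' enough for the giant structures to assemble and reach steady state.
#'
#' @return A named list understood by [validate_run_config()].
#' @export
default_run_config <- function() {
  list(
    params = list(),
    network = list(max_nuclearity = 154L, targets = "default",
                   growth = "auto", template_rules = "default"),
    init_counts = list(M1 = 3000L),
    horizon = 40,
    grid_points = 201L,
    n_reps = 1L,
    seed = 1L
  )
}

#' Load a run configuration file
#'
#' JSON natively; YAML accepted as a convenience (normalized to JSON in the
#' manifest).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` configuration.
#' @return The validated, default-filled configuration list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

#' Validate and resolve a run configuration
#'
#' Fills defaults from [default_run_config()], rejects unknown keys at every
#' level, and type-checks every field (schema errors name the offending
#' key).
#'
#' @param cfg A configuration list.
#' @return The resolved configuration.
#' @export
validate_run_config <- function(cfg) {
  def <- default_run_config()
  if (!is.list(cfg)) stop("config must be a JSON/YAML object")
  unknown <- setdiff(names(cfg), c(names(def), "output_dir"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(def, cfg)

  bad_param <- setdiff(names(out$params),
                       names(formals(rate_params)))
  if (length(bad_param))
    stop("unknown params key(s): ", paste(bad_param, collapse = ", "))
  do.call(rate_params, out$params)  # errors on invalid values (e.g. D <= 0)

  net_keys <- c("max_nuclearity", "targets", "growth", "template_rules",
                "inhibitor")
  bad_net <- setdiff(names(out$network), net_keys)
  if (length(bad_net))
    stop("unknown network key(s): ", paste(bad_net, collapse = ", "))
  if (!is.numeric(out$network$max_nuclearity) || out$network$max_nuclearity < 1)
    stop("network.max_nuclearity must be a positive integer")
  if (!is.null(out$network$inhibitor)) {
    inh <- out$network$inhibitor
    bad_inh <- setdiff(names(inh), c("binding_k", "release_k", "bound_targets"))
    if (length(bad_inh))
      stop("unknown inhibitor key(s): ", paste(bad_inh, collapse = ", "))
  }
  if (!is.numeric(out$horizon) || out$horizon <= 0)
    stop("horizon must be > 0")
  if (!is.numeric(out$grid_points) || out$grid_points < 2)
    stop("grid_points must be >= 2")
  if (!is.numeric(out$n_reps) || out$n_reps < 1)
    stop("n_reps must be >= 1")
  if (length(out$init_counts) == 0 || is.null(names(out$init_counts)))
    stop("init_counts must be a named object of species counts")
  out
}

#' Instantiate model objects from a configuration
#'
#' @param cfg A resolved configuration (see [validate_run_config()]).
#' @return List with `network`, `params`, `init_counts`, `horizon`, `grid`,
#'   `n_reps`, `seed`.
#' @export
build_from_config <- function(cfg) {
  cfg <- validate_run_config(cfg)
  params <- do.call(rate_params, cfg$params)
  targets <- if (identical(cfg$network$targets, "default")) default_targets()
             else if (identical(cfg$network$targets, "none")) NULL
             else as.data.frame(cfg$network$targets)
  rules <- if (identical(cfg$network$template_rules, "default")) NULL
           else if (identical(cfg$network$template_rules, "none")) list()
           else cfg$network$template_rules
  net <- mob_network(cfg$network$max_nuclearity, params, targets = targets,
                     growth = cfg$network$growth, template_rules = rules)
  if (!is.null(cfg$network$inhibitor)) {
    inh <- cfg$network$inhibitor
    net <- extend_with_inhibitor(net, inh$binding_k, inh$release_k,
                                 inh$bound_targets %||% c("M6", "M36c"))
  }
  init <- unlist(cfg$init_counts)
  list(network = net, params = params, init_counts = init,
       horizon = cfg$horizon,
       grid = seq(0, cfg$horizon, length.out = cfg$grid_points),
       n_reps = as.integer(cfg$n_reps), seed = as.integer(cfg$seed))
}
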