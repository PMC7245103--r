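#' Default assembly targets
#'
#' The three well-defined products tracked by the model: the {Mo36} template
#' (corner-dimer lineage, also a template), the {Mo132} Keplerate ball
#' (edge-dimer lineage) and the {Mo154} molybdenum-blue wheel (corner-dimer
#' lineage).
#'
#' @return A data.frame with columns `nuclearity`, `lineage`, `is_template`.
#' @export
default_targets <- function() {
  data.frame(
    nuclearity = c(36L, 132L, 154L),
    lineage = c("corner_dimer_path", "edge_dimer_path", "corner_dimer_path"),
    is_template = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

species_id <- function(nuclearity, lineage) {
  suffix <- c(generic = "", corner_dimer_path = "c", edge_dimer_path = "e")[lineage]
  paste0("M", nuclearity, suffix)
}

#' Enumerate the coarse-grained species space
#'
#' Species are identified by nuclearity only (two intermediates with the same
#' Mo count are the same species), with two exceptions: nuclearity 2 splits
#' into the corner-bonded dimer `M2c` and the reduced edge-bonded dimer
#' `M2e`, and intermediates above `lineage_threshold` carry a lineage tag —
#' `corner_dimer_path` feeding the {Mo154} wheel, `edge_dimer_path` feeding
#' the {Mo132} ball — since the two dimers play different structural roles in
#' the final structures. Free bonding sites are `N - n` for a species of
#' nuclearity `n` on a path to its next target `N` (0 only for completed
#' targets), and `max(max_nuclearity - n, 1)` for generic species.
#'
#' Above the threshold, lineage species are enumerated in steps of
#' `lineage_step`. The default is 2 whenever every declared target has even
#' nuclearity (as {Mo36}, {Mo132} and {Mo154} do): growth on a lineage then
#' proceeds by whole building blocks — the lineage's own dimer and the
#' {Mo6} hexad — which makes the dimer supply, and hence the dimerization
#' ratio D, the currency of wheel and ball formation. `lineage_step = 1`
#' enumerates every intermediate nuclearity instead.
#'
#' @param max_nuclearity Largest species tracked (>= 1).
#' @param targets `NULL`, or a data.frame like [default_targets()].
#' @param lineage_threshold Nuclearity above which intermediates are
#'   lineage-tagged (default 6).
#' @param lineage_step Spacing of lineage-tagged nuclearities; `NULL` (the
#'   default) resolves to 2 when targets are declared and all even, else 1.
#' @return A data.frame of species with columns `id`, `nuclearity`,
#'   `lineage`, `free_sites`, `is_template`, `is_target`.
#' @examples
#' enumerate_species(3)           # monomer, two dimers, trimer
#' @export
enumerate_species <- function(max_nuclearity, targets = NULL,
                              lineage_threshold = 6L, lineage_step = NULL) {
  stopifnot(max_nuclearity >= 1)
  max_nuclearity <- as.integer(max_nuclearity)
  lineage_threshold <- as.integer(lineage_threshold)
  if (!is.null(targets)) {
    stopifnot(is.data.frame(targets),
              all(c("nuclearity", "lineage", "is_template") %in% names(targets)))
    if (any(targets$nuclearity > max_nuclearity))
      stop("max_nuclearity (", max_nuclearity,
           ") is smaller than the largest target (", max(targets$nuclearity), ")")
    if (!all(targets$lineage %in% c("corner_dimer_path", "edge_dimer_path")))
      stop("target lineage must be corner_dimer_path or edge_dimer_path")
  }
  if (is.null(lineage_step)) {
    lineage_step <- if (!is.null(targets) && nrow(targets) &&
                        all(targets$nuclearity %% 2L == 0L)) 2L else 1L
  }
  lineage_step <- as.integer(lineage_step)
  stopifnot(lineage_step %in% c(1L, 2L))
  if (!is.null(targets) && lineage_step == 2L &&
      any(targets$nuclearity %% 2L != 0L))
    stop("lineage_step = 2 requires all targets to have even nuclearity")
  tlin <- function(lin) {
    if (is.null(targets)) integer(0)
    else sort(targets$nuclearity[targets$lineage == lin])
  }
  corner_targets <- tlin("corner_dimer_path")
  edge_targets <- tlin("edge_dimer_path")
  # lineage paths stop at their topmost target when targets are declared
  corner_cap <- if (length(corner_targets)) max(corner_targets) else max_nuclearity
  edge_cap <- if (length(edge_targets)) max(edge_targets) else max_nuclearity

  free_sites_of <- function(n, lin) {
    tg <- switch(lin, corner_dimer_path = corner_targets,
                 edge_dimer_path = edge_targets, integer(0))
    above <- tg[tg >= n]
    if (length(above)) above[1] - n else max(max_nuclearity - n, 1L)
  }
  rows <- list()
  add <- function(n, lin) {
    fs <- free_sites_of(n, lin)
    is_tgt <- FALSE
    is_tmpl <- FALSE
    if (!is.null(targets)) {
      hit <- targets$nuclearity == n & targets$lineage == lin
      if (any(hit)) {
        is_tgt <- TRUE
        is_tmpl <- any(targets$is_template[hit])
        fs <- 0L
      }
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      id = species_id(n, lin), nuclearity = n, lineage = lin,
      free_sites = as.integer(fs), is_template = is_tmpl, is_target = is_tgt,
      stringsAsFactors = FALSE)
  }
  add(1L, "generic")
  if (max_nuclearity >= 2L) {
    add(2L, "corner_dimer_path")
    add(2L, "edge_dimer_path")
  }
  for (n in seq_len(min(lineage_threshold, max_nuclearity))) {
    if (n >= 3L) add(n, "generic")
  }
  if (max_nuclearity > lineage_threshold) {
    start <- if (lineage_step == 2L) lineage_threshold + 2L
             else lineage_threshold + 1L
    for (n in if (start <= max_nuclearity)
           seq(start, max_nuclearity, by = lineage_step) else integer(0)) {
      if (n <= corner_cap) add(n, "corner_dimer_path")
      if (n <= edge_cap) add(n, "edge_dimer_path")
    }
  }
  sp <- do.call(rbind, rows)
  rownames(sp) <- NULL
  sp
}

#' Enumerate all synthesis/degradation reactions over a species set
#'
#' Every lineage-compatible pair (A, B) with combined nuclearity within the
#' cap yields one bimolecular synthesis `A + B -> C` and its reverse
#' unimolecular degradation `C -> A + B`, so every reaction is reversible and
#' nuclearity is conserved exactly. The two dimers act as lineage carriers:
#' a product above the lineage threshold requires exactly one lineage among
#' its reactants (corner with corner or generic, edge with edge or generic);
#' mixed corner/edge syntheses are disallowed there, while products at or
#' below the threshold are generic and unrestricted. The monomer pairing
#' `M1 + M1` branches into both dimer channels when both dimers are present.
#'
#' @param species Data.frame from [enumerate_species()].
#' @param max_nuclearity Cap on product nuclearity.
#' @param growth `"all_pairs"` (any two species may combine), `"blocks"`
#'   (at least one reactant must be a building block: `M1`, `M2c`, `M2e`,
#'   `M6`), or `"auto"` (blocks when `max_nuclearity > 40`, else all pairs) —
#'   the combinatorial control that keeps giant networks tractable.
#' @param lineage_threshold Mixing/lineage threshold used during enumeration;
#'   must match the one used for `species`.
#' @param reduced_dimer_in_ladder Allow the reduced edge-bonded dimer to
#'   incorporate into the small generic clusters (nuclearity 3..6)? Default
#'   `FALSE`: the {Mo3}..{Mo6} ladder is fully oxidized, so it is built from
#'   monomers and corner-bonded dimers only, and the edge dimer's productive
#'   fate is the reduced {Mo132} ball lineage.
#' @param monomer_in_ladder Allow free monomers to add directly onto the
#'   small generic clusters? Default `FALSE`: monomers enter the assembly
#'   cascade only through dimerization, and the {Mo6} hexad condenses from
#'   three corner dimers, which makes the hexad supply (and everything
#'   templated through it) respond sharply to the dimerization ratio.
#' @param templates_terminal Treat completed template species ({Mo36}) as
#'   closed structures that catalyze but never react: they form, degrade and
#'   template, and the wheel path branches off the corner lineage below
#'   them. Default `TRUE`; the template is then a genuinely catalytic pool
#'   rather than a consumed intermediate.
#' @param hexad_checkpoint_interval Optional stricter stoichiometry: when an
#'   integer is given, every this many Mo along a lineage path (counted from
#'   the entry species at nuclearity 8) the growth step must be a {Mo6}
#'   addition and all other steps are dimer additions, pinning pentagonal
#'   hexad-derived centers at regular positions. Default `NULL` (off): the
#'   hexad dependence of the giants is already carried by the
#'   corner-dimer-rooted hexad supply.
#' @return A `reaction_network` object (see [validate_network()]), with
#'   `base_k` unset until [assign_base_constants()] is applied.
#' @export
enumerate_reactions <- function(species, max_nuclearity,
                                growth = c("auto", "all_pairs", "blocks"),
                                lineage_threshold = 6L,
                                reduced_dimer_in_ladder = FALSE,
                                monomer_in_ladder = FALSE,
                                templates_terminal = TRUE,
                                hexad_checkpoint_interval = NULL) {
  growth <- match.arg(growth)
  if (growth == "auto")
    growth <- if (max_nuclearity > 40) "blocks" else "all_pairs"
  block_ids <- intersect(c("M1", "M2c", "M2e", "M6"), species$id)
  ids <- species$id
  nucs <- species$nuclearity
  lins_all <- species$lineage
  is_block <- ids %in% block_ids
  has <- function(id) id %in% ids

  n_sp <- length(ids)
  r1v <- character(0); r2v <- character(0); p1v <- character(0)
  add_syn <- function(a, b, p) {
    r1v[length(r1v) + 1L] <<- a
    r2v[length(r2v) + 1L] <<- b
    p1v[length(p1v) + 1L] <<- p
  }
  is_tmpl <- species$is_template
  for (i in seq_len(n_sp)) {
    for (j in i:n_sp) {
      n_prod <- nucs[i] + nucs[j]
      if (n_prod > max_nuclearity) next
      if (growth == "blocks" && !(is_block[i] || is_block[j])) next
      # a completed template is a closed structure: it accelerates other
      # reactions but does not itself grow; the wheel path above it is
      # reached by hexad additions that bypass the closed cluster
      if (templates_terminal && (is_tmpl[i] || is_tmpl[j])) next
      if (n_prod == 2L) {
        # the monomer self-pairing branches into both dimer channels
        if (has("M2c")) add_syn(ids[i], ids[j], "M2c")
        if (has("M2e")) add_syn(ids[i], ids[j], "M2e")
        next
      }
      if (n_prod <= lineage_threshold) {
        # the small-cluster ladder ({Mo3}..{Mo6}) is fully oxidized: the
        # reduced edge-bonded dimer does not incorporate into it
        if (!reduced_dimer_in_ladder && ("M2e" %in% c(ids[i], ids[j]))) next
        # and with monomer_in_ladder = FALSE the hexad is condensed from
        # corner dimers alone ({Mo6} = 3 x {Mo2c}), monomers entering the
        # assembly cascade only through dimerization
        if (!monomer_in_ladder && ("M1" %in% c(ids[i], ids[j]))) next
        p <- species_id(n_prod, "generic")
        if (has(p)) add_syn(ids[i], ids[j], p)
      } else {
        lins <- unique(setdiff(c(lins_all[i], lins_all[j]), "generic"))
        if (length(lins) != 1L) next  # no lineage carrier, or corner/edge mix
        # hexad checkpoints: the Keplerate carries pentagonal
        # {Mo6}-derived centers at regular positions, so along the edge
        # (ball) lineage the growth step at those positions must
        # incorporate a hexad, and between them growth proceeds by
        # edge-dimer linkers only
        if (!is.null(hexad_checkpoint_interval) &&
            lins == "edge_dimer_path") {
          at_checkpoint <- n_prod >= 8L &&
            (n_prod - 8L) %% hexad_checkpoint_interval == 0L
          has_hexad <- "M6" %in% c(ids[i], ids[j])
          if (at_checkpoint != has_hexad) next
        }
        p <- species_id(n_prod, lins)
        if (has(p)) add_syn(ids[i], ids[j], p)
      }
    }
  }
  syn <- data.frame(r1 = r1v, r2 = r2v, p1 = p1v, stringsAsFactors = FALSE)
  n_syn <- nrow(syn)
  reactions <- rbind(
    data.frame(kind = rep("synthesis", n_syn), r1 = syn$r1, r2 = syn$r2,
               p1 = syn$p1, p2 = rep(NA_character_, n_syn),
               stringsAsFactors = FALSE),
    data.frame(kind = rep("degradation", n_syn), r1 = syn$p1,
               r2 = rep(NA_character_, n_syn), p1 = syn$r1, p2 = syn$r2,
               stringsAsFactors = FALSE)
  )
  if (nrow(reactions)) {
    reactions$base_k <- NA_real_
    reactions$template_id <- NA_character_
    reactions$plain_rate <- FALSE
    reactions$id <- ifelse(
      reactions$kind == "synthesis",
      paste0(reactions$r1, "+", reactions$r2, ">", reactions$p1),
      paste0(reactions$r1, ">", reactions$p1, "+", reactions$p2))
  } else {
    reactions$base_k <- numeric(0); reactions$template_id <- character(0)
    reactions$plain_rate <- logical(0); reactions$id <- character(0)
  }
  rownames(reactions) <- NULL
  structure(list(species = species, reactions = reactions,
                 max_nuclearity = as.integer(max_nuclearity),
                 lineage_threshold = as.integer(lineage_threshold),
                 growth = growth, metadata = list()),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network>", nrow(x$species), "species,",
      nrow(x$reactions), "reactions (max nuclearity", x$max_nuclearity,
      "- growth:", x$growth, ")\n")
  tgt <- x$species$id[x$species$is_target]
  if (length(tgt)) cat("  targets:", paste(tgt, collapse = ", "), "\n")
  n_tmpl <- sum(!is.na(x$reactions$template_id))
  if (n_tmpl) cat("  templated reactions:", n_tmpl, "\n")
  invisible(x)
}

#' Check the structural invariants of a reaction network
#'
#' Verifies that every reaction endpoint resolves to a declared species, that
#' nuclearity is conserved by every reaction, that the synthesis/degradation
#' pairing is a bijection, and that no (reactants, products, kind) triple is
#' duplicated.
#'
#' @param network A `reaction_network`.
#' @return Character vector of violations; empty when the network is valid.
#' @export
validate_network <- function(network) {
  sp <- network$species
  rx <- network$reactions
  bad <- character(0)
  nuc <- stats::setNames(sp$nuclearity, sp$id)
  endpoints <- c(rx$r1, rx$r2, rx$p1, rx$p2, rx$template_id)
  unresolved <- setdiff(stats::na.omit(unique(endpoints)), sp$id)
  if (length(unresolved))
    bad <- c(bad, paste("unresolved species:", paste(unresolved, collapse = ", ")))
  if (nrow(rx) && !length(unresolved)) {
    lhs <- nuc[rx$r1] + ifelse(is.na(rx$r2), 0L, nuc[rx$r2])
    rhs <- nuc[rx$p1] + ifelse(is.na(rx$p2), 0L, nuc[rx$p2])
    if (any(lhs != rhs))
      bad <- c(bad, paste("nuclearity not conserved in:",
                          paste(rx$id[lhs != rhs], collapse = ", ")))
    syn <- rx[rx$kind == "synthesis", ]
    deg <- rx[rx$kind == "degradation", ]
    key_syn <- paste(syn$r1, syn$r2, syn$p1)
    key_deg <- paste(deg$p1, deg$p2, deg$r1)
    if (!setequal(key_syn, key_deg) || length(key_syn) != length(key_deg))
      bad <- c(bad, "synthesis/degradation pairing is not a bijection")
    if (anyDuplicated(rx$id))
      bad <- c(bad, paste("duplicate reactions:",
                          paste(unique(rx$id[duplicated(rx$id)]), collapse = ", ")))
  }
  two <- sp$id[sp$nuclearity == 2L & !startsWith(sp$id, "Inh")]
  if (length(two) > 2L) bad <- c(bad, "more than two species of nuclearity 2")
  bad
}

#' Assign base rate constants to an enumerated network
#'
#' Every unimolecular degradation gets `k_uni_default` (1.0), except
#' degradation of the completed giant structures — the targets at the top of
#' their lineage, {Mo132} and {Mo154} in the default network — which are
#' stable and degrade at `k_d << 1` ({Mo36} too when
#' `params$kd_applies_to_mo36`). The two monomer dimerization channels share
#' the base bimolecular constant but in ratio `D` (corner : edge):
#' `k(M2c) = k_bi_base * 2D/(1+D)`, `k(M2e) = k_bi_base * 2/(1+D)`, so their
#' sum is independent of `D`. All other syntheses get `k_bi_base`.
#'
#' @param network A `reaction_network`.
#' @param params A [rate_params()] object (errors if `D <= 0`).
#' @return The network with `base_k` filled in and the parameters echoed in
#'   `metadata$params`.
#' @export
assign_base_constants <- function(network, params) {
  stopifnot(inherits(network, "reaction_network"))
  validate_rate_params(params)
  sp <- network$species
  rx <- network$reactions
  lineage_cap <- function(lin) {
    n <- sp$nuclearity[sp$lineage == lin]
    if (length(n)) max(n) else NA_integer_
  }
  stable <- sp$id[sp$is_target &
                    (sp$nuclearity == ifelse(sp$lineage == "corner_dimer_path",
                                             lineage_cap("corner_dimer_path"),
                                             lineage_cap("edge_dimer_path")))]
  if (params$kd_applies_to_mo36)
    stable <- union(stable, sp$id[sp$is_target & sp$nuclearity == 36L])
  keep_plain <- rx$plain_rate
  is_deg <- rx$kind == "degradation"
  rx$base_k[is_deg & !keep_plain] <- params$k_uni_default
  rx$base_k[is_deg & rx$r1 %in% stable & !keep_plain] <- params$k_d
  is_syn <- rx$kind == "synthesis" & !keep_plain
  rx$base_k[is_syn] <- params$k_bi_base
  # slow condensation of the small oxidized clusters ({Mo3}..{Mo6})
  nuc_p_all <- stats::setNames(sp$nuclearity, sp$id)[rx$p1]
  ladder <- is_syn & nuc_p_all <= network$lineage_threshold & nuc_p_all > 2L
  rx$base_k[ladder] <- params$k_bi_base * params$k_ladder_factor
  # the oxidized corner dimer is a sluggish linker: its uptake into
  # lineage growth (above the small-cluster ladder) is slowed
  nuc_p <- stats::setNames(sp$nuclearity, sp$id)[rx$p1]
  corner_link <- is_syn & nuc_p > network$lineage_threshold &
    (rx$r1 == "M2c" | rx$r2 == "M2c")
  corner_link[is.na(corner_link)] <- FALSE
  rx$base_k[corner_link] <- params$k_bi_base * params$corner_link_factor
  rx$base_k[is_syn & rx$p1 == "M2c"] <- params$k_bi_base * 2 * params$D / (1 + params$D)
  rx$base_k[is_syn & rx$p1 == "M2e"] <- params$k_bi_base * 2 / (1 + params$D)
  network$reactions <- rx
  network$metadata$params <- unclass(params)
  network$metadata$stable_targets <- stable
  network
}

#' Default templation rules
#'
#' The {Mo36} template accelerates (i) syntheses on the {Mo154} path — every
#' corner-lineage product above nuclearity 36 — accounting for the wheel
#' being templated by {Mo36}; (ii) syntheses producing the {Mo6} building
#' block, the embedded cycle feeding every downstream structure; and (iii)
#' syntheses along its own corner-lineage assembly path, the molecular
#' recognition by which one completed cluster coordinates incoming
#' fragments — the direct self-replication route. Together (ii) and (iii)
#' close the autocatalytic set.
#'
#' @param network A `reaction_network` containing the {Mo36} target.
#' @return A list of rules, each `list(template = <id>, products = <ids>)`.
#' @export
default_template_rules <- function(network) {
  sp <- network$species
  mo36 <- sp$id[sp$is_target & sp$nuclearity == 36L]
  if (length(mo36) != 1L)
    stop("default template rules require a single {Mo36} target species")
  corner <- sp$id[sp$lineage == "corner_dimer_path" & sp$nuclearity > 2L]
  ladder <- sp$id[sp$lineage == "generic" & sp$nuclearity > 2L]
  prods <- intersect(c(ladder, corner), sp$id)
  list(list(template = mo36, products = prods))
}

#' Annotate reactions with template acceleration
#'
#' Marks every synthesis whose product appears in a rule with the rule's
#' template species; templated syntheses run `template_factor` times faster
#' while the template is present. An empty rule list is the ablation
#' configuration: no reaction is templated, removing the embedded
#' autocatalytic cycle.
#'
#' @param network A `reaction_network`.
#' @param rules List of `list(template, products)` rules, e.g.
#'   [default_template_rules()]; `list()` for ablation.
#' @return The network with `template_id` set on matching syntheses.
#' @export
annotate_templates <- function(network, rules = default_template_rules(network)) {
  stopifnot(inherits(network, "reaction_network"), is.list(rules))
  rx <- network$reactions
  rx$template_id <- NA_character_
  for (rule in rules) {
    ids <- c(rule$template, rule$products)
    unknown <- setdiff(ids, network$species$id)
    if (length(unknown))
      stop("template rule names unknown species: ", paste(unknown, collapse = ", "))
    hit <- rx$kind == "synthesis" & rx$p1 %in% rule$products
    rx$template_id[hit] <- rule$template
  }
  network$reactions <- rx
  network$metadata$template_rules <- rules
  network
}

#' Extend a network with an unproductive inhibitor
#'
#' Models hydrogen-bonding carboxylic-acid inhibitors (oxalic, trimesic acid)
#' that bind constituents of the autocatalytic set in an unproductive manner:
#' a new inhibitor species `Inh` binds reversibly to each species in
#' `bound_targets`, `Inh + X <-> Inh:X`, and the complex participates in no
#' other reaction. Binding and release constants are used as given (no
#' collision prefactor, templation or completion bias), and the complex
#' carries its cluster's nuclearity so total Mo mass stays conserved.
#' `binding_k = 0` leaves the dynamics identical to the unextended network.
#'
#' @param network A `reaction_network` with constants assigned.
#' @param binding_k,release_k Non-negative rate constants.
#' @param bound_targets Species ids the inhibitor sequesters (default the
#'   {Mo6} block and the {Mo36} template).
#' @return The extended `reaction_network`.
#' @export
extend_with_inhibitor <- function(network, binding_k, release_k,
                                  bound_targets = c("M6", "M36c")) {
  stopifnot(inherits(network, "reaction_network"))
  if (!is.finite(binding_k) || binding_k < 0 || !is.finite(release_k) || release_k < 0)
    stop("binding_k and release_k must be non-negative")
  unknown <- setdiff(bound_targets, network$species$id)
  if (length(unknown))
    stop("bound_targets not in network: ", paste(unknown, collapse = ", "))
  sp <- network$species
  nuc <- stats::setNames(sp$nuclearity, sp$id)
  new_sp <- data.frame(
    id = c("Inh", paste0("Inh:", bound_targets)),
    nuclearity = c(0L, unname(nuc[bound_targets])),
    lineage = "generic", free_sites = 0L,
    is_template = FALSE, is_target = FALSE, stringsAsFactors = FALSE)
  rx_new <- do.call(rbind, lapply(bound_targets, function(x) {
    cx <- paste0("Inh:", x)
    data.frame(
      kind = c("synthesis", "degradation"),
      r1 = c("Inh", cx), r2 = c(x, NA_character_),
      p1 = c(cx, "Inh"), p2 = c(NA_character_, x),
      base_k = c(binding_k, release_k),
      template_id = NA_character_, plain_rate = TRUE,
      id = c(paste0("Inh+", x, ">", cx), paste0(cx, ">Inh+", x)),
      stringsAsFactors = FALSE)
  }))
  network$species <- rbind(sp, new_sp)
  network$reactions <- rbind(network$reactions, rx_new)
  network$metadata$inhibitor <- list(binding_k = binding_k,
                                     release_k = release_k,
                                     bound_targets = bound_targets)
  network
}

#' Build the default molybdenum-blue assembly network
#'
#' Convenience constructor wiring the full pipeline: species enumeration up
#' to the {Mo154} wheel with the default targets, reaction enumeration
#' (building-block growth for giant networks), base-constant assignment and
#' default templation.
#'
#' @param max_nuclearity Cap, default 154.
#' @param params A [rate_params()] object.
#' @param targets Target table, default [default_targets()].
#' @param growth Growth mode passed to [enumerate_reactions()].
#' @param template_rules Templation rules, or `list()` for the ablated
#'   (template-free) model; default [default_template_rules()].
#' @param ... Further options forwarded to [enumerate_reactions()]
#'   (`reduced_dimer_in_ladder`, `monomer_in_ladder`,
#'   `hexad_checkpoint_interval`).
#' @return A ready-to-simulate `reaction_network`.
#' @examples
#' net <- mob_network(40, rate_params(D = 1), targets = default_targets()[1, ])
#' net
#' @export
mob_network <- function(max_nuclearity = 154L, params = rate_params(),
                        targets = default_targets(),
                        growth = "auto", template_rules = NULL, ...) {
  sp <- enumerate_species(max_nuclearity, targets)
  net <- enumerate_reactions(sp, max_nuclearity, growth = growth, ...)
  net <- assign_base_constants(net, params)
  if (is.null(template_rules)) {
    has36 <- any(sp$is_target & sp$nuclearity == 36L)
    template_rules <- if (has36) default_template_rules(net) else list()
  }
  annotate_templates(net, template_rules)
}
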