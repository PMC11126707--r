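#' Load and validate a metabolic flux network
#'
#' A flux network declares metabolite/physiology species (some observable via
#' a biomarker with a population reference level, some latent), directed or
#' reversible fluxes between them, and the biomarker input sets under which
#' the network is fitted.  The observable model is log-linear quasi-steady
#' state: the log deviation of each observable species from its reference
#' level is the signed sum of the log flux deviations of its producing and
#' consuming fluxes (see [predict_observables()]).
#'
#' @param input_set Which biomarker configuration the network is restricted
#'   to: `"identification-10"` (the ten-biomarker identification panel),
#'   `"incomplete-11"` (ten plus ACR), or `"complete-14"` (ten plus albumin,
#'   ALT, AST and hematocrit).  Input sets beyond these can be declared in a
#'   custom definition file.
#' @param definition Path to a YAML network definition, or an equivalent
#'   nested list.  Defaults to the definition shipped with the package
#'   (21 informative fluxes over glucose, ROS/HbA1c, respiration-circulation,
#'   blood pressure, lipid, kidney-creatinine and albumin-ACR pathways).
#' @return A `gmf_network` object: list with `species` and `fluxes` tibbles,
#'   the signed incidence matrix `incidence` (species x fluxes; +1 produced,
#'   -1 consumed), `input_set`, the observable biomarker vector `inputs`, and
#'   `flux_ids` of the informative fluxes.
#' @examples
#' net <- gmf_network("complete-14")
#' net
#' @export
gmf_network <- function(input_set = "complete-14", definition = NULL) {
  def <- if (is.null(definition)) {
    yaml::read_yaml(system.file("extdata", "gmf_network.yaml", package = "gmftwin"))
  } else if (is.character(definition)) {
    yaml::read_yaml(definition)
  } else {
    definition
  }

  species <- purrr::map_dfr(def$species, function(s) {
    tibble(
      species_id = s$id,
      biomarker = s$biomarker %||% NA_character_,
      reference_level = as.numeric(s$reference_level %||% NA_real_)
    )
  })
  fluxes <- purrr::map_dfr(def$fluxes, function(f) {
    tibble(
      flux_id = f$id,
      substrates = list(as.character(unlist(f$substrates) %||% character())),
      products = list(as.character(unlist(f$products) %||% character())),
      reversible = isTRUE(f$reversible),
      pathway_group = f$pathway_group %||% NA_character_,
      informative = isTRUE(f$informative)
    )
  })

  validate_network_definition(species, fluxes)

  input_sets <- def$input_sets
  if (!input_set %in% names(input_sets)) {
    abort(paste0("Unknown input set '", input_set, "'. Available: ",
                 paste(names(input_sets), collapse = ", ")))
  }
  inputs <- as.character(unlist(input_sets[[input_set]]))

  unmapped <- setdiff(inputs, species$biomarker[!is.na(species$biomarker)])
  if (length(unmapped) > 0) {
    abort(paste0("Input biomarker(s) without a mapped species: ",
                 paste(unmapped, collapse = ", ")), class = "gmftwin_network_error")
  }

  A <- build_incidence(species, fluxes)

  # every configured input biomarker must be touched by at least one flux
  obs_species <- species$species_id[match(inputs, species$biomarker)]
  untouched <- obs_species[rowSums(abs(A[obs_species, , drop = FALSE])) == 0]
  if (length(untouched) > 0) {
    abort(paste0("Observable species touched by no flux: ",
                 paste(untouched, collapse = ", ")), class = "gmftwin_network_error")
  }

  declared <- def$informative_count %||% sum(fluxes$informative)
  if (sum(fluxes$informative) != declared) {
    abort(paste0("Definition declares ", declared, " informative fluxes but ",
                 sum(fluxes$informative), " are marked informative."),
          class = "gmftwin_network_error")
  }

  structure(
    list(
      species = species,
      fluxes = fluxes,
      incidence = A,
      input_set = input_set,
      inputs = inputs,
      flux_ids = fluxes$flux_id[fluxes$informative]
    ),
    class = "gmf_network"
  )
}

validate_network_definition <- function(species, fluxes) {
  dup <- fluxes$flux_id[duplicated(fluxes$flux_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate flux_id: ", paste(unique(dup), collapse = ", ")),
          class = "gmftwin_network_error")
  }
  dup_sp <- species$species_id[duplicated(species$species_id)]
  if (length(dup_sp) > 0) {
    abort(paste0("Duplicate species: ", paste(unique(dup_sp), collapse = ", ")),
          class = "gmftwin_network_error")
  }
  bad_ref <- species$species_id[!is.na(species$biomarker) &
                                  (is.na(species$reference_level) |
                                     species$reference_level <= 0)]
  if (length(bad_ref) > 0) {
    abort(paste0("Observable species without positive reference level: ",
                 paste(bad_ref, collapse = ", ")), class = "gmftwin_network_error")
  }
  for (i in seq_len(nrow(fluxes))) {
    subs <- fluxes$substrates[[i]]; prods <- fluxes$products[[i]]
    unknown <- setdiff(c(subs, prods), species$species_id)
    if (length(unknown) > 0) {
      abort(paste0("Flux '", fluxes$flux_id[i], "' references unknown species: ",
                   paste(unknown, collapse = ", ")), class = "gmftwin_network_error")
    }
    overlap <- intersect(subs, prods)
    if (length(overlap) > 0) {
      abort(paste0("Flux '", fluxes$flux_id[i],
                   "' has species on both sides: ", paste(overlap, collapse = ", ")),
            class = "gmftwin_network_error")
    }
  }
  # connectivity of the undirected species graph (species linked if they share
  # a flux); species touched by no flux at all are disconnected by definition
  A <- build_incidence(species, fluxes)
  touched <- rownames(A)[rowSums(abs(A)) > 0]
  if (length(touched) > 1) {
    comp <- setNames(seq_along(touched), touched)
    for (i in seq_len(nrow(fluxes))) {
      members <- intersect(c(fluxes$substrates[[i]], fluxes$products[[i]]), touched)
      if (length(members) > 1) {
        target <- min(comp[members])
        comp[comp %in% comp[members]] <- target
      }
    }
    if (length(unique(comp)) > 1) {
      small <- names(comp)[comp != as.integer(names(sort(table(comp), decreasing = TRUE))[1])]
      abort(paste0("Species graph is disconnected; offending component contains: ",
                   paste(small, collapse = ", ")), class = "gmftwin_network_error")
    }
  }
  invisible(TRUE)
}

build_incidence <- function(species, fluxes) {
  A <- matrix(0, nrow(species), nrow(fluxes),
              dimnames = list(species$species_id, fluxes$flux_id))
  for (i in seq_len(nrow(fluxes))) {
    A[fluxes$substrates[[i]], i] <- -1
    A[fluxes$products[[i]], i] <- 1
  }
  A
}

#' @export
print.gmf_network <- function(x, ...) {
  cat("<gmf_network> input set '", x$input_set, "'\n", sep = "")
  cat("  species:    ", nrow(x$species), " (", length(x$inputs), " observable under this set)\n", sep = "")
  cat("  fluxes:     ", nrow(x$fluxes), " (", length(x$flux_ids), " informative)\n", sep = "")
  cat("  pathways:   ", paste(unique(x$fluxes$pathway_group), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Signed stoichiometric incidence matrix
#'
#' One row per species and one column per flux; +1 where the flux produces
#' the species, -1 where it consumes it, 0 otherwise.  A reversible edge is a
#' single signed column (net flux, positive in the forward direction as
#' written).
#'
#' @param network A [gmf_network()].
#' @return Numeric matrix (species x fluxes).
#' @export
incidence_matrix <- function(network) {
  stopifnot(inherits(network, "gmf_network"))
  network$incidence
}

# incidence restricted to the observable species of the active input set,
# rows named by biomarker, columns = informative fluxes
observable_incidence <- function(network) {
  sp <- network$species
  obs <- sp[match(network$inputs, sp$biomarker), ]
  A <- network$incidence[obs$species_id, network$flux_ids, drop = FALSE]
  rownames(A) <- obs$biomarker
  A
}

#' Structurally identifiable fluxes of an input set
#'
#' Under a fixed input set, a flux whose observable signature (its column of
#' the observable incidence) is a linear combination of the signatures of
#' earlier fluxes is structurally aliased: its fitted value is an exact
#' linear function of theirs for every patient and every missingness
#' pattern, so it carries no separable information.  This returns the fluxes
#' kept by a greedy left-to-right scan (network order), i.e. a maximal
#' independent subset whose size equals the rank of the observable
#' incidence.
#'
#' @param network A [gmf_network()].
#' @return Character vector of identifiable flux ids.
#' @export
identifiable_fluxes <- function(network) {
  A <- observable_incidence(network)
  keep <- character()
  basis <- matrix(0, nrow(A), 0)
  for (j in seq_len(ncol(A))) {
    a <- A[, j]
    if (sum(a^2) == 0) next
    resid <- if (ncol(basis) == 0) a else a - basis %*% crossprod(basis, a)
    if (sqrt(sum(resid^2)) > 1e-8 * sqrt(sum(a^2))) {
      keep <- c(keep, colnames(A)[j])
      basis <- cbind(basis, resid / sqrt(sum(resid^2)))
    }
  }
  keep
}

reference_levels <- function(network) {
  sp <- network$species
  obs <- sp[match(network$inputs, sp$biomarker), ]
  setNames(obs$reference_level, obs$biomarker)
}

#' Predict observable log deviations from a flux deviation vector
#'
#' The forward model: `y = A_obs u`, where `u` holds log flux deviations for
#' the informative fluxes and `A_obs` is the incidence matrix restricted to
#' the observable species of the network's input set.  Entry `y_i` is the
#' predicted `log(x_i / reference_level_i)` for biomarker `i`.
#'
#' @param u Numeric vector of log flux deviations, one per informative flux
#'   (optionally named by flux id).
#' @param network A [gmf_network()].
#' @return Named numeric vector of predicted log biomarker deviations.
#' @export
predict_observables <- function(u, network) {
  A <- observable_incidence(network)
  if (length(u) != ncol(A)) {
    abort(paste0("Flux vector has length ", length(u), " but the network has ",
                 ncol(A), " informative fluxes."), class = "gmftwin_dim_error")
  }
  drop(A %*% as.numeric(u))
}
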