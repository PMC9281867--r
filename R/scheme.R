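#' Path to the packaged reaction-scheme parameter file
#'
#' The default parameterisation of the coagulation network (species list,
#' reactions, rate constants, reference plasma concentrations, summary
#' configuration and anticoagulant defaults) ships as a human-readable YAML
#' file. Copy and edit it to run an alternative parameterisation.
#'
#' @return Absolute path to the YAML parameter file.
#' @export
clotsim_param_file <- function() {
  system.file("extdata", "coagulation_scheme.yaml", package = "clotsim",
              mustWork = TRUE)
}

#' Load and validate a reaction-scheme parameter file
#'
#' Parses a YAML parameter file describing the mass-action reaction network,
#' validates it (species uniqueness, rate-constant resolution, positivity,
#' unit/kind consistency) and audits stoichiometric conservation of every
#' zymogen and inhibitor lineage across every reaction.
#'
#' @param path Path to a YAML parameter file; defaults to the packaged scheme.
#' @return An object of class `coag_scheme`: a list with elements `species`,
#'   `reactions`, `rates` (named numeric vector), `rate_units`, `lineages`,
#'   `reference`, `initial`, `summaries`, `drugs`, `path`, `hash`, and
#'   precomputed `matrices` (stoichiometry matrix `S`, reactant indices
#'   `r1`/`r2`, rate vector `k`).
#' @export
load_scheme <- function(path = clotsim_param_file()) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path)
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("malformed parameter file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  scheme <- build_scheme(raw)
  scheme$path <- path
  scheme$hash <- unname(tools::md5sum(path))
  scheme
}

#' Build the default coagulation reaction scheme
#'
#' Convenience wrapper around [load_scheme()] returning the packaged
#' 34-species tissue-factor-pathway scheme with its rate constants.
#'
#' @return A validated `coag_scheme` object (see [load_scheme()]).
#' @export
build_default_scheme <- function() {
  load_scheme(clotsim_param_file())
}

# Construct and validate a coag_scheme from a parsed parameter list.
build_scheme <- function(raw) {
  for (field in c("species", "rate_constants", "reactions", "lineages",
                  "reference_concentrations")) {
    if (is.null(raw[[field]])) {
      stop("parameter file is missing required section '", field, "'")
    }
  }
  species <- as.character(unlist(raw$species))
  if (anyDuplicated(species)) {
    stop("duplicate species name: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }

  rates <- vapply(raw$rate_constants, function(x) as.numeric(x$value), 0)
  rate_units <- vapply(raw$rate_constants, function(x) as.character(x$units), "")
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    bad <- names(rates)[!is.finite(rates) | rates <= 0]
    stop("rate constant not a positive number: ", paste(bad, collapse = ", "))
  }

  reactions <- lapply(raw$reactions, function(r) {
    list(reactants = as.character(unlist(r$reactants)),
         products = as.character(unlist(r$products)),
         k = as.character(r$k),
         kind = as.character(r$kind))
  })
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    unknown <- setdiff(c(r$reactants, r$products), species)
    if (length(unknown) > 0) {
      stop("reaction ", i, " references unknown species: ",
           paste(unknown, collapse = ", "))
    }
    if (!(r$k %in% names(rates))) {
      stop("reaction ", i, " references missing rate constant '", r$k, "'")
    }
    if (length(r$reactants) > 2) {
      stop("reaction ", i, " has more than two reactants; ",
           "mass-action scheme supports uni- and bimolecular steps only")
    }
    if (!(r$kind %in% c("binding", "dissociation", "catalysis", "inactivation"))) {
      stop("reaction ", i, " has unknown kind '", r$kind, "'")
    }
    expected_units <- if (length(r$reactants) == 2) "M-1 s-1" else "s-1"
    if (rate_units[[r$k]] != expected_units) {
      stop("rate constant '", r$k, "' has units '", rate_units[[r$k]],
           "' but reaction ", i, " requires '", expected_units, "'")
    }
  }

  lineages <- lapply(raw$lineages, function(weights) {
    w <- vapply(weights, as.numeric, 0)
    unknown <- setdiff(names(w), species)
    if (length(unknown) > 0) {
      stop("lineage references unknown species: ",
           paste(unknown, collapse = ", "))
    }
    w
  })

  reference <- vapply(raw$reference_concentrations, as.numeric, 0)
  if (any(reference <= 0)) {
    stop("reference concentrations must be positive")
  }

  scheme <- structure(
    list(species = species,
         reactions = reactions,
         rates = rates,
         rate_units = rate_units,
         lineages = lineages,
         reference = reference,
         initial = raw$initial,
         summaries = raw$summaries,
         drugs = raw$drugs,
         version = raw$version,
         name = raw$name),
    class = "coag_scheme")
  scheme$matrices <- scheme_matrices(scheme)

  audit <- audit_conservation(scheme)
  if (!all(audit$conserved)) {
    bad <- which(!audit$conserved)
    stop("lineage conservation violated in reaction(s): ",
         paste(bad, collapse = ", "))
  }
  scheme
}

# Precompute the stoichiometry matrix and mass-action index vectors.
scheme_matrices <- function(scheme) {
  nsp <- length(scheme$species)
  nr <- length(scheme$reactions)
  S <- matrix(0, nsp, nr, dimnames = list(scheme$species, NULL))
  r1 <- integer(nr)
  r2 <- integer(nr)
  k <- numeric(nr)
  for (j in seq_len(nr)) {
    r <- scheme$reactions[[j]]
    ri <- match(r$reactants, scheme$species)
    pi <- match(r$products, scheme$species)
    for (i in ri) S[i, j] <- S[i, j] - 1
    for (i in pi) S[i, j] <- S[i, j] + 1
    r1[j] <- ri[1]
    r2[j] <- if (length(ri) == 2) ri[2] else 0L
    k[j] <- scheme$rates[[r$k]]
  }
  list(S = S, r1 = r1, r2 = r2, k = k)
}

#' Audit stoichiometric lineage conservation of every reaction
#'
#' For each reaction and each lineage (prothrombin, FV, FVII, FVIII, FIX, FX,
#' TF, TFPI, AT, plus any drug lineage), checks that the lineage-weighted sum
#' of reactant stoichiometries equals that of the products, i.e. that no
#' reaction creates or destroys material of any lineage.
#'
#' @param scheme A `coag_scheme`.
#' @return A data frame with one row per reaction: `reaction`, `conserved`,
#'   and the worst absolute lineage imbalance `max_imbalance`.
#' @export
audit_conservation <- function(scheme) {
  nr <- length(scheme$reactions)
  imbalance <- numeric(nr)
  for (j in seq_len(nr)) {
    r <- scheme$reactions[[j]]
    worst <- 0
    for (lin in names(scheme$lineages)) {
      w <- scheme$lineages[[lin]]
      lhs <- sum(w[r$reactants[r$reactants %in% names(w)]])
      rhs <- sum(w[r$products[r$products %in% names(w)]])
      worst <- max(worst, abs(lhs - rhs))
    }
    imbalance[j] <- worst
  }
  data.frame(reaction = seq_len(nr),
             conserved = imbalance == 0,
             max_imbalance = imbalance)
}

# Lineage weight vector over the full species set (zeros where absent).
lineage_weights <- function(scheme, lineage) {
  if (!(lineage %in% names(scheme$lineages))) {
    stop("unknown lineage '", lineage, "'")
  }
  w <- stats::setNames(numeric(length(scheme$species)), scheme$species)
  ln <- scheme$lineages[[lineage]]
  w[names(ln)] <- ln
  w
}

#' @export
print.coag_scheme <- function(x, ...) {
  cat("Coagulation reaction scheme '", x$name, "' (version ", x$version, ")\n",
      sep = "")
  cat("  species:   ", length(x$species), "\n", sep = "")
  cat("  reactions: ", length(x$reactions), "\n", sep = "")
  cat("  rate constants: ", length(x$rates), "\n", sep = "")
  cat("  lineages:  ", paste(names(x$lineages), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
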