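# Community model assembly.
#
# Taxa keep private compartments; a shared lumen compartment couples them.
# For lumen metabolite m the steady-state balance reads
#     sum_i a_i * v_i,ex(m) - v_env(m) = 0
# where a_i is the relative abundance of taxon i, v_i,ex its exchange flux
# (per gDW of taxon i, > 0 export into the lumen) and v_env the
# environment exchange (> 0 export out of the community, < 0 diet import).
# Community growth is the abundance-weighted sum mu_c = sum_i a_i mu_i.
# Metabolite id scheme: "<taxon>__<met>" internal, "<met>_lu" lumen.

#' Filter and renormalize relative abundances
#'
#' Drops taxa whose relative abundance falls below the cutoff (default
#' 1e-4) and renormalizes the survivors to sum to one. The operation is
#' idempotent.
#'
#' @param raw named non-negative abundance vector.
#' @param cutoff abundance threshold below which a taxon is excluded.
#' @return named abundance vector summing to one.
#' @export
filter_abundances <- function(raw, cutoff = 1e-4) {
  if (any(raw < 0) || all(raw == 0)) {
    stop("abundances must be non-negative and not all zero", call. = FALSE)
  }
  keep <- raw >= cutoff
  if (!any(keep)) {
    stop("empty community: all abundances below cutoff ", cutoff,
         call. = FALSE)
  }
  out <- raw[keep]
  out / sum(out)
}

#' Assemble a lumen-coupled community model
#'
#' Combines per-taxon models and relative abundances into one
#' stoichiometric system. Each taxon's internal network is embedded
#' unchanged in a private compartment; its exchange reactions are rewired
#' to the shared lumen with the abundance as the coupling coefficient, and
#' every lumen metabolite receives an environment exchange whose uptake is
#' closed until a diet is applied (secretion stays open).
#'
#' @param models list of \code{taxon_model} objects.
#' @param abundances named relative-abundance vector (names must match the
#'   models' taxon labels 1:1; normally the output of
#'   \code{\link{filter_abundances}}).
#' @return an object of class \code{"community_model"}.
#' @export
assemble_community <- function(models, abundances) {
  labels <- vapply(models, `[[`, "", "taxon")
  names(models) <- labels
  if (is.null(names(abundances)) ||
      !setequal(names(abundances), labels) ||
      length(abundances) != length(labels)) {
    stop("model labels and abundance names must match 1:1", call. = FALSE)
  }
  for (m in models) validate_taxon_model(m)
  abundances <- abundances[labels] / sum(abundances)

  lumen_mets <- character(0)
  for (m in models) {
    ex <- Filter(function(r) r$role == "exchange", m$reactions)
    lumen_mets <- union(lumen_mets, unlist(lapply(ex, function(r) names(r$stoich))))
  }
  lumen_mets <- sort(lumen_mets)

  met_ids <- c(unlist(lapply(models, function(m)
                 paste0(m$taxon, "__", m$metabolites$id)), use.names = FALSE),
               paste0(lumen_mets, "_lu"))

  rxn_id <- character(0); rxn_taxon <- character(0); rxn_role <- character(0)
  lb <- numeric(0); ub <- numeric(0)
  triplets <- list()  # (met index, rxn index, coef)
  met_index <- stats::setNames(seq_along(met_ids), met_ids)
  jj <- 0L
  add_rxn <- function(id, taxon, role, stoich, l, u) {
    jj <<- jj + 1L
    rxn_id[jj] <<- id; rxn_taxon[jj] <<- taxon; rxn_role[jj] <<- role
    lb[jj] <<- l; ub[jj] <<- u
    triplets[[jj]] <<- cbind(met_index[names(stoich)], jj, unname(stoich))
  }

  for (m in models) {
    a <- abundances[[m$taxon]]
    for (r in m$reactions) {
      if (r$role == "exchange") {
        met <- names(r$stoich)
        add_rxn(paste0(m$taxon, "__", r$id), m$taxon, "taxon-exchange",
                stats::setNames(c(-1, a),
                                c(paste0(m$taxon, "__", met),
                                  paste0(met, "_lu"))),
                r$lb, r$ub)
      } else {
        add_rxn(paste0(m$taxon, "__", r$id), m$taxon,
                if (r$role == "biomass") "biomass" else "internal",
                stats::setNames(unname(r$stoich),
                                paste0(m$taxon, "__", names(r$stoich))),
                r$lb, r$ub)
      }
    }
  }
  for (met in lumen_mets) {
    add_rxn(paste0("EX_", met, "_lu"), NA_character_, "lumen-exchange",
            stats::setNames(-1, paste0(met, "_lu")),
            0, DEFAULT_FLUX_MAX)
  }

  S <- matrix(0, length(met_ids), jj, dimnames = list(met_ids, rxn_id))
  for (t in triplets) S[t[, 1] + (t[, 2] - 1) * nrow(S)] <- t[, 3]

  structure(list(
    taxa = abundances,
    models = models,
    S = S,
    reactions = data.frame(id = rxn_id, taxon = rxn_taxon, role = rxn_role,
                           stringsAsFactors = FALSE),
    lb = stats::setNames(lb, rxn_id),
    ub = stats::setNames(ub, rxn_id),
    lumen_mets = lumen_mets,
    biomass_cols = stats::setNames(
      match(paste0(labels, "__",
                   vapply(models, `[[`, "", "biomass_id")), rxn_id),
      labels),
    diet = NULL),
    class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("community_model:", length(x$taxa), "taxa,", nrow(x$S), "metabolites,",
      ncol(x$S), "reactions,", length(x$lumen_mets), "lumen metabolites\n")
  if (!is.null(x$diet)) cat("diet:", attr(x$diet, "style"), "\n")
  invisible(x)
}

#' Apply a diet specification to a community model
#'
#' Sets the uptake bound (lower bound, import is negative flux) of every
#' lumen environment exchange named in the diet; lumen exchanges absent
#' from the diet get uptake 0 (secretion stays unbounded). Diet entries
#' that do not match any lumen exchange are ignored with a warning, since
#' realistic diet tables list nutrients a given community cannot use.
#'
#' @param community a \code{community_model}.
#' @param diet a diet specification data frame (see
#'   \code{\link{generate_diet}}) with columns \code{reaction_id} (VMH
#'   style, e.g. \code{EX_glc(e)}), \code{max_uptake}, \code{class},
#'   \code{energy_density}.
#' @return the community with diet bounds applied.
#' @export
apply_diet <- function(community, diet) {
  stopifnot(inherits(community, "community_model"))
  lumen_ids <- paste0("EX_", community$lumen_mets, "_lu")
  community$lb[lumen_ids] <- 0
  mets <- sub("^EX_(.*)\\(e\\)$", "\\1", diet$reaction_id)
  for (k in seq_len(nrow(diet))) {
    target <- paste0("EX_", mets[k], "_lu")
    if (target %in% lumen_ids) {
      community$lb[target] <- -abs(diet$max_uptake[k])
    } else {
      warning("diet entry ", diet$reaction_id[k],
              " matches no lumen exchange; ignored", call. = FALSE)
    }
  }
  community$diet <- diet
  community
}

# ---- serialization ----------------------------------------------------

taxon_model_to_list <- function(model) {
  list(
    taxon = model$taxon,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(model$reactions, function(r)
      list(id = r$id, stoichiometry = as.list(r$stoich),
           lb = r$lb, ub = r$ub,
           is_biomass = identical(r$role, "biomass"),
           is_exchange = identical(r$role, "exchange"))))
}

taxon_model_from_list <- function(x) {
  rxns <- lapply(x$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    list(id = r$id, stoich = st, lb = r$lb, ub = r$ub,
         role = if (isTRUE(r$is_biomass)) "biomass"
                else if (isTRUE(r$is_exchange)) "exchange" else "internal")
  })
  if (!any(vapply(rxns, function(r) r$role == "biomass", TRUE))) {
    stop("invalid model: no reaction flagged is_biomass", call. = FALSE)
  }
  m <- structure(list(
    taxon = x$taxon,
    metabolites = data.frame(
      id = vapply(x$metabolites, `[[`, "", "id"),
      compartment = vapply(x$metabolites, `[[`, "", "compartment"),
      stringsAsFactors = FALSE),
    reactions = rxns,
    biomass_id = rxns[[which(vapply(rxns, function(r) r$role == "biomass", TRUE))]]$id,
    seed = NA_integer_),
    class = "taxon_model")
  validate_taxon_model(m)
}

#' Write / read a community model (JSON)
#'
#' The on-disk schema stores each taxon's model (metabolites, reactions
#' with stoichiometry, bounds, biomass/exchange flags) together with its
#' relative abundance; reading reassembles the community, so a write/read
#' round trip reproduces the assembled model exactly.
#'
#' @param community a \code{community_model}.
#' @param path file path.
#' @return \code{read_community} returns a \code{community_model};
#'   \code{write_community} returns \code{path} invisibly.
#' @export
write_community <- function(community, path) {
  stopifnot(inherits(community, "community_model"))
  payload <- list(
    taxa = lapply(names(community$taxa), function(tx)
      list(taxon = tx, abundance = unname(community$taxa[[tx]]),
           model = taxon_model_to_list(community$models[[tx]]))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_community
#' @export
read_community <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse community JSON '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  models <- lapply(payload$taxa, function(t) taxon_model_from_list(t$model))
  ab <- stats::setNames(
    vapply(payload$taxa, `[[`, 0, "abundance"),
    vapply(payload$taxa, `[[`, "", "taxon"))
  assemble_community(models, ab)
}

#' Import a taxon model from an SBML subset
#'
#' Supports the core SBML constructs a flux model needs: species,
#' reactions with reactant/product stoichiometry, reversibility, and flux
#' bounds given either as \code{fbc} attributes with referenced parameters
#' or defaulted from reversibility. Rules, events and other dynamic
#' constructs are rejected by name. The biomass reaction is recognized by
#' an id containing "biomass" (case-insensitive); exchange reactions are
#' those touching a single species.
#'
#' @param path SBML file path.
#' @param taxon taxon label for the imported model (default: SBML model id).
#' @return a \code{taxon_model}.
#' @export
read_sbml_model <- function(path, taxon = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  for (bad in c("listOfRules", "listOfEvents", "listOfConstraints")) {
    if (length(xml2::xml_find_all(doc, paste0(".//", bad)))) {
      stop("unsupported SBML construct: ", bad, call. = FALSE)
    }
  }
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_name(model_node))) stop("no <model> element", call. = FALSE)
  if (is.null(taxon)) taxon <- xml2::xml_attr(model_node, "id")

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_ids <- xml2::xml_attr(species, "id")

  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rxn_nodes)) stop("no reactions in SBML model", call. = FALSE)
  reactions <- lapply(rxn_nodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    refs <- function(which, sign) {
      nodes <- xml2::xml_find_all(rn, paste0("./", which, "/speciesReference"))
      if (!length(nodes)) return(numeric(0))
      coef <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, xml2::xml_attr(nodes, "species"))
    }
    st <- c(refs("listOfReactants", -1), refs("listOfProducts", 1))
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    lbp <- xml2::xml_attr(rn, "lowerFluxBound")
    ubp <- xml2::xml_attr(rn, "upperFluxBound")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lbv <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]]
           else if (rev) -DEFAULT_FLUX_MAX else 0
    ubv <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]]
           else DEFAULT_FLUX_MAX
    role <- if (grepl("biomass", rid, ignore.case = TRUE)) "biomass"
            else if (length(st) == 1) "exchange" else "internal"
    list(id = rid, stoich = st, lb = lbv, ub = ubv, role = role)
  })
  if (!any(vapply(reactions, function(r) r$role == "biomass", TRUE))) {
    stop("invalid model: no biomass reaction found in SBML", call. = FALSE)
  }
  m <- structure(list(
    taxon = taxon,
    metabolites = data.frame(id = sp_ids, compartment = "internal",
                             stringsAsFactors = FALSE),
    reactions = reactions,
    biomass_id = reactions[[which(vapply(reactions, function(r)
      r$role == "biomass", TRUE))[1]]]$id,
    seed = NA_integer_),
    class = "taxon_model")
  validate_taxon_model(m)
}
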