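# Per-taxon toy genome-scale models.
#
# A taxon model is a stoichiometric network: metabolites in rows, reactions
# in columns, flux bounds in mmol/gDW/h, and a single biomass reaction
# normalized so that unit flux corresponds to a growth rate of 1/h.
# Exchange reactions touch exactly one metabolite; flux > 0 is export,
# flux < 0 is import (the convention used throughout the package).

DEFAULT_UPTAKE_CAP <- 10    # mmol/gDW/h kinetic cap on any single uptake
DEFAULT_FLUX_MAX   <- 1000  # generic reaction capacity

#' Define a taxon archetype
#'
#' An archetype is the phenotype recipe from which a toy metabolic model is
#' generated: which metabolites the organism consumes, which it secretes
#' (with molar yields per mol of substrate), and its biomass yield.
#'
#' @param name taxon label.
#' @param consumes character vector of consumed metabolite labels; the
#'   first entry is the primary carbon source.
#' @param secretes named numeric vector of secretion yields
#'   (mol product per mol substrate); may be empty or zero.
#' @param growth_yield gDW biomass per mmol substrate (> 0).
#' @return an object of class \code{"taxon_archetype"}.
#' @export
taxon_archetype <- function(name, consumes, secretes = numeric(0),
                            growth_yield = 0.05) {
  if (length(consumes) < 1) {
    stop("archetype must consume at least one metabolite (energy source)",
         call. = FALSE)
  }
  if (length(secretes) && is.null(names(secretes))) {
    stop("secretes must be a named numeric vector of yields", call. = FALSE)
  }
  if (any(names(secretes) %in% consumes)) {
    stop("secretes and consumes must be disjoint", call. = FALSE)
  }
  if (any(secretes < 0) || growth_yield <= 0) {
    stop("yields must be non-negative and growth_yield positive",
         call. = FALSE)
  }
  structure(list(name = name, consumes = consumes,
                 secretes = secretes, growth_yield = growth_yield),
            class = "taxon_archetype")
}

#' Generate a toy taxon metabolic model from an archetype
#'
#' Builds a mass-balanced network: one uptake exchange per consumed
#' metabolite, a conversion reaction per substrate yielding biomass
#' precursor and the declared secretion products, a linear chain of
#' intermediate reactions on the primary substrate (padding to \code{size}
#' reactions), one secretion exchange per product, and a single biomass
#' reaction. Every internal metabolite takes part in at least two
#' reactions, so steady state is attainable with nonzero flux.
#'
#' @param archetype a \code{\link{taxon_archetype}}.
#' @param size target reaction count (>= 4); if smaller than the natural
#'   reaction count implied by the archetype, the natural count is used.
#' @param seed integer; generation is deterministic, the seed is recorded
#'   for provenance.
#' @return an object of class \code{"taxon_model"}.
#' @examples
#' arch <- taxon_archetype("toy", consumes = "glc",
#'                         secretes = c(acetate = 1.5))
#' mod <- generate_taxon_model(arch, size = 5)
#' @export
generate_taxon_model <- function(archetype, size = 8L, seed = 0L) {
  stopifnot(inherits(archetype, "taxon_archetype"))
  if (size < 4) stop("size must be at least 4", call. = FALSE)
  if (length(archetype$consumes) < 1) {
    stop("archetype has no energy source", call. = FALSE)
  }
  cons <- archetype$consumes
  prods <- names(archetype$secretes)
  cs <- cons[1]

  n_min <- length(cons) + length(prods) + length(cons) + 1
  n_chain <- max(0L, as.integer(size) - n_min)

  mets <- c(cons, prods,
            if (n_chain > 0) paste0("im", seq_len(n_chain)), "bm")
  reactions <- list()

  for (m in cons) {
    reactions[[length(reactions) + 1L]] <- list(
      id = paste0("EX_", m), stoich = stats::setNames(-1, m),
      lb = -DEFAULT_UPTAKE_CAP, ub = DEFAULT_FLUX_MAX, role = "exchange")
  }
  for (p in prods) {
    reactions[[length(reactions) + 1L]] <- list(
      id = paste0("EX_", p), stoich = stats::setNames(-1, p),
      lb = 0, ub = DEFAULT_FLUX_MAX, role = "exchange")
  }

  # linear chain on the primary substrate: cs -> im1 -> ... -> im_k
  feed <- cs
  if (n_chain > 0) {
    for (i in seq_len(n_chain)) {
      im <- paste0("im", i)
      reactions[[length(reactions) + 1L]] <- list(
        id = paste0("CHAIN_", i),
        stoich = stats::setNames(c(-1, 1), c(feed, im)),
        lb = 0, ub = DEFAULT_FLUX_MAX, role = "internal")
      feed <- im
    }
  }

  # one conversion per substrate: substrate -> yield_g bm + sum yields
  for (m in cons) {
    src <- if (m == cs) feed else m
    st <- c(-1, archetype$growth_yield)
    nm <- c(src, "bm")
    if (length(prods)) {
      st <- c(st, unname(archetype$secretes))
      nm <- c(nm, prods)
    }
    keep <- st != 0 | nm %in% c(src, "bm")
    reactions[[length(reactions) + 1L]] <- list(
      id = paste0("CONV_", m), stoich = stats::setNames(st[keep], nm[keep]),
      lb = 0, ub = DEFAULT_FLUX_MAX, role = "internal")
  }

  reactions[[length(reactions) + 1L]] <- list(
    id = "BIOMASS", stoich = c(bm = -1),
    lb = 0, ub = DEFAULT_FLUX_MAX, role = "biomass")

  structure(list(
    taxon = archetype$name,
    metabolites = data.frame(id = mets, compartment = "internal",
                             stringsAsFactors = FALSE),
    reactions = reactions,
    biomass_id = "BIOMASS",
    seed = as.integer(seed)),
    class = "taxon_model")
}

#' @export
print.taxon_model <- function(x, ...) {
  cat("taxon_model:", x$taxon, "-", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  invisible(x)
}

# Assemble the dense stoichiometric matrix and bound vectors of one model.
taxon_matrices <- function(model) {
  mets <- model$metabolites$id
  rids <- vapply(model$reactions, `[[`, "", "id")
  S <- matrix(0, length(mets), length(rids),
              dimnames = list(mets, rids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  list(S = S,
       lb = vapply(model$reactions, `[[`, 0, "lb"),
       ub = vapply(model$reactions, `[[`, 0, "ub"),
       roles = vapply(model$reactions, `[[`, "", "role"),
       ids = rids)
}

validate_taxon_model <- function(model) {
  if (!inherits(model, "taxon_model")) stop("not a taxon_model", call. = FALSE)
  roles <- vapply(model$reactions, `[[`, "", "role")
  if (sum(roles == "biomass") != 1) {
    stop("taxon model must have exactly one biomass reaction", call. = FALSE)
  }
  for (r in model$reactions) {
    if (r$lb > r$ub) stop("reaction ", r$id, ": lb > ub", call. = FALSE)
    if (r$role == "exchange" && length(r$stoich) != 1) {
      stop("exchange reaction ", r$id,
           " must touch exactly one metabolite", call. = FALSE)
    }
    unknown <- setdiff(names(r$stoich), model$metabolites$id)
    if (length(unknown)) {
      stop("reaction ", r$id, " references unknown metabolite ",
           unknown[1], call. = FALSE)
    }
  }
  invisible(model)
}
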