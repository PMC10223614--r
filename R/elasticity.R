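# Elasticity coefficients of exchange fluxes.
#
# epsilon = d ln|v| / d ln p, estimated by a one-sided forward difference
# on the log scale with step h (default 0.1, i.e. a 10.5% native-scale
# parameter increase): epsilon = (ln|v(p e^h)| - ln|v(p)|) / h. The
# perturbed community is re-solved by the cooperative trade-off. Flux
# direction is ignored through the absolute value but recorded separately.
# Elasticities are undefined (never +/- infinite) when the baseline or
# perturbed flux magnitude falls below the 1e-6 flux epsilon. Parameters
# are encoded as "abundance:<taxon>" (relative abundance, perturbed before
# renormalization) or "diet:<reaction_id>" (diet uptake bound).

.parse_param <- function(parameter) {
  parts <- strsplit(parameter, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("abundance", "diet")) {
    stop("parameter must be 'abundance:<taxon>' or 'diet:<reaction_id>'",
         call. = FALSE)
  }
  list(type = parts[1], target = parts[2])
}

# rebuild the community with one parameter multiplied by exp(h)
.perturb_community <- function(community, parameter, h) {
  p <- .parse_param(parameter)
  if (p$type == "abundance") {
    if (!p$target %in% names(community$taxa)) {
      stop("taxon not in community: ", p$target, call. = FALSE)
    }
    ab <- community$taxa
    ab[p$target] <- ab[p$target] * exp(h)
    out <- assemble_community(community$models, ab / sum(ab))
    if (!is.null(community$diet)) out <- apply_diet(out, community$diet)
    out
  } else {
    target <- paste0("EX_", sub("^EX_(.*)\\(e\\)$", "\\1", p$target), "_lu")
    if (!target %in% names(community$lb)) {
      stop("diet parameter matches no lumen exchange: ", p$target,
           call. = FALSE)
    }
    if (community$lb[target] >= 0) {
      stop("diet bound for ", p$target, " is zero; elasticity needs p > 0",
           call. = FALSE)
    }
    community$lb[target] <- community$lb[target] * exp(h)
    community
  }
}

.elasticity_record <- function(flux, parameter, eps, direction, status, h) {
  p <- .parse_param(parameter)
  data.frame(flux = flux, parameter = parameter, param_type = p$type,
             taxon = if (p$type == "abundance") p$target else NA_character_,
             elasticity = eps, direction = direction, status = status,
             h = h, stringsAsFactors = FALSE)
}

#' Elasticity of one exchange flux with respect to one parameter
#'
#' @param community a diet-bounded \code{community_model}.
#' @param flux reaction id of the flux of interest (e.g.
#'   \code{"EX_acetate_lu"}).
#' @param parameter \code{"abundance:<taxon>"} or
#'   \code{"diet:<reaction_id>"}.
#' @param h log-scale step size (> 0), default 0.1.
#' @param tau trade-off fraction used for both baseline and perturbed
#'   solves.
#' @param baseline optionally a precomputed baseline
#'   \code{flux_solution} (shared across a profile).
#' @return one-row data frame: flux, parameter, param_type, taxon,
#'   elasticity, direction (sign of the baseline flux), status
#'   (\code{"ok"}, \code{"undefined"}, \code{"infeasible"}), h.
#' @export
elasticity <- function(community, flux, parameter, h = 0.1, tau = 0.7,
                       baseline = NULL) {
  stopifnot(inherits(community, "community_model"), h > 0)
  if (is.null(baseline)) baseline <- cooperative_tradeoff(community, tau)
  if (!flux %in% names(baseline$fluxes)) {
    stop("flux not in model: ", flux, call. = FALSE)
  }
  v0 <- baseline$fluxes[[flux]]
  direction <- sign(v0)
  if (abs(v0) <= FLUX_EPSILON) {
    return(.elasticity_record(flux, parameter, NA_real_, direction,
                              "undefined", h))
  }
  pert <- tryCatch(
    cooperative_tradeoff(.perturb_community(community, parameter, h), tau),
    error = function(e) NULL)
  if (is.null(pert) || pert$status != "optimal") {
    return(.elasticity_record(flux, parameter, NA_real_, direction,
                              "infeasible", h))
  }
  v1 <- pert$fluxes[[flux]]
  if (abs(v1) <= FLUX_EPSILON) {
    return(.elasticity_record(flux, parameter, NA_real_, direction,
                              "undefined", h))
  }
  eps <- (log(abs(v1)) - log(abs(v0))) / h
  .elasticity_record(flux, parameter, eps, direction, "ok", h)
}

#' Elasticity profile over flux and parameter panels
#'
#' One record per (flux, parameter) pair. The baseline is solved once and
#' each parameter's perturbed community once, shared across the flux
#' panel, so a profile of f fluxes times p parameters costs p + 1 solves.
#' Records are ordered by parameter then flux.
#'
#' @param community a diet-bounded \code{community_model}.
#' @param fluxes character vector of reaction ids.
#' @param parameters character vector of parameter codes.
#' @inheritParams elasticity
#' @return data frame of elasticity records.
#' @export
elasticity_profile <- function(community, fluxes, parameters, h = 0.1,
                               tau = 0.7) {
  baseline <- cooperative_tradeoff(community, tau)
  out <- list()
  for (parameter in parameters) {
    pert <- tryCatch(
      cooperative_tradeoff(.perturb_community(community, parameter, h), tau),
      error = function(e) NULL)
    for (flux in fluxes) {
      v0 <- baseline$fluxes[[flux]]
      if (is.null(v0)) stop("flux not in model: ", flux, call. = FALSE)
      direction <- sign(v0)
      rec <- if (abs(v0) <= FLUX_EPSILON) {
        .elasticity_record(flux, parameter, NA_real_, direction,
                           "undefined", h)
      } else if (is.null(pert) || pert$status != "optimal") {
        .elasticity_record(flux, parameter, NA_real_, direction,
                           "infeasible", h)
      } else {
        v1 <- pert$fluxes[[flux]]
        if (abs(v1) <= FLUX_EPSILON) {
          .elasticity_record(flux, parameter, NA_real_, direction,
                             "undefined", h)
        } else {
          .elasticity_record(flux, parameter,
                             (log(abs(v1)) - log(abs(v0))) / h,
                             direction, "ok", h)
        }
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify one taxon of a matched pair by elasticity-variance width
#'
#' Compares the variance of defined elasticities across the flux panel,
#' restricted to the taxon's abundance parameter, between the ADHD and
#' control members of a pair. Labels: \code{"ADHD"} when the ADHD variance
#' exceeds the control variance by more than the relative threshold
#' \code{theta}, \code{"Control"} for the reverse, \code{"Same"}
#' otherwise, and \code{"NA"} when the taxon is absent from either
#' member's profile or either side has fewer than 2 defined elasticities.
#'
#' @param profile_adhd,profile_control elasticity profile data frames
#'   computed on the same flux/parameter panels.
#' @param taxon taxon label.
#' @param theta relative variance-width threshold (default 0.2; "wider"
#'   means more than 20\% larger variance).
#' @return list with \code{taxon} and \code{label}.
#' @export
compare_pair_variances <- function(profile_adhd, profile_control, taxon,
                                   theta = 0.2) {
  pick <- function(pr) {
    sel <- pr$param_type == "abundance" & !is.na(pr$taxon) &
      pr$taxon == taxon
    if (!any(sel)) return(NULL)
    e <- pr$elasticity[sel & pr$status == "ok"]
    e[is.finite(e)]
  }
  ea <- pick(profile_adhd)
  ec <- pick(profile_control)
  if (is.null(ea) || is.null(ec) || length(ea) < 2 || length(ec) < 2) {
    return(list(taxon = taxon, label = "NA"))
  }
  va <- stats::var(ea)
  vc <- stats::var(ec)
  label <- if (va > (1 + theta) * vc) "ADHD"
           else if (vc > (1 + theta) * va) "Control"
           else "Same"
  list(taxon = taxon, label = label)
}

#' Write an elasticity profile as TSV
#'
#' Columns: sample_id, flux_id, parameter_id, elasticity, direction,
#' status.
#'
#' @param profile an elasticity profile data frame.
#' @param sample_id sample label recorded in the first column.
#' @param path output file.
#' @export
write_elasticities <- function(profile, sample_id, path) {
  utils::write.table(
    data.frame(sample_id = sample_id, flux_id = profile$flux,
               parameter_id = profile$parameter,
               elasticity = profile$elasticity,
               direction = profile$direction, status = profile$status,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
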