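# Flux balance analysis and the cooperative trade-off.
#
# Single-model FBA maximizes the biomass flux; community FBA maximizes the
# abundance-weighted community growth mu_c = sum_i a_i mu_i. The
# cooperative trade-off solves a second-stage quadratic program that fixes
# a fraction tau of the maximal community growth and minimizes the sum of
# squared per-taxon growth rates, distributing growth across taxa instead
# of letting the fastest grower take everything. Growth rates are unique
# under the strictly convex stage-2 objective; other fluxes may not be,
# and reports should rely on minimize_intake() where flux identity
# matters.

FLUX_EPSILON <- 1e-6  # |flux| below this is treated as zero

new_flux_solution <- function(fluxes, community, objective, status,
                              extra = list()) {
  growth <- if (is.null(fluxes)) NULL else
    stats::setNames(fluxes[community$biomass_cols], names(community$taxa))
  res <- c(list(
    fluxes = fluxes,
    growth = growth,
    community_growth = if (is.null(growth)) NA_real_
                       else sum(community$taxa * growth),
    objective = objective,
    status = status,
    residual = if (is.null(fluxes)) NA_real_
               else max(abs(community$S %*% fluxes)),
    reactions = community$reactions,
    abundances = community$taxa), extra)
  structure(res, class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status, "- community growth",
      format(x$community_growth, digits = 6), "1/h\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes growth at steady state (\code{S v = 0}) under flux bounds.
#' For a \code{taxon_model} the objective is its biomass flux; for a
#' \code{community_model} it is the abundance-weighted community growth.
#'
#' @param model a \code{taxon_model} or \code{community_model}.
#' @return a \code{flux_solution} with per-taxon growth rates, community
#'   growth, objective value and solver status.
#' @export
fba <- function(model) {
  if (inherits(model, "taxon_model")) {
    # standalone model: exchanges face an unconstrained environment, so
    # uptake is limited only by the model's own exchange bounds
    model <- assemble_community(list(model),
                                stats::setNames(1, model$taxon))
    env <- model$reactions$role == "lumen-exchange"
    model$lb[env] <- -DEFAULT_FLUX_MAX
  }
  stopifnot(inherits(model, "community_model"))
  obj <- numeric(ncol(model$S))
  obj[model$biomass_cols] <- model$taxa
  ans <- solve_lp(obj, Seq = model$S, lb = model$lb, ub = model$ub)
  sol <- if (is.null(ans$solution)) NULL else
    stats::setNames(ans$solution, colnames(model$S))
  new_flux_solution(sol, model, ans$objective, ans$status)
}

#' Cooperative trade-off growth allocation
#'
#' Two stages: (1) maximize community growth \code{mu_c = sum a_i mu_i},
#' giving \code{mu_c*}; (2) minimize \code{sum_i mu_i^2} subject to
#' \code{mu_c >= tau * mu_c*} and all flux balance constraints. With
#' \code{tau < 1} and any slack to trade, the growth constraint binds, so
#' the achieved community growth equals \code{tau * mu_c*} to solver
#' tolerance.
#'
#' @param community a \code{community_model} (diet applied).
#' @param tau trade-off fraction in (0, 1]; default 0.7.
#' @param ridge tiny regularization on non-growth fluxes that makes the
#'   stage-2 program strictly convex (pins them to the minimum-norm
#'   optimum).
#' @return a \code{flux_solution}; additionally carries \code{mu_max}
#'   (stage-1 optimum) and \code{tau}.
#' @export
cooperative_tradeoff <- function(community, tau = 0.7, ridge = 1e-8) {
  stopifnot(inherits(community, "community_model"))
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]", call. = FALSE)
  stage1 <- fba(community)
  if (stage1$status != "optimal") {
    stop("cooperative trade-off stage 1 (max community growth): ",
         stage1$status, call. = FALSE)
  }
  mu_max <- stage1$community_growth
  n <- ncol(community$S)
  gcols <- community$biomass_cols
  D <- rep(2 * ridge, n); D[gcols] <- 2
  Dmat <- diag(n); diag(Dmat) <- D
  arow <- numeric(n); arow[gcols] <- community$taxa
  # microscopic slack keeps the growth floor attainable at tau = 1, where
  # the stage-1 optimum is only known to solver precision
  slack <- 1e-9 * max(1, abs(mu_max))
  ans <- solve_qp(Dmat, rep(0, n), Seq = community$S,
                  Aineq = matrix(arow, 1), bineq = tau * mu_max - slack,
                  lb = community$lb, ub = community$ub)
  if (ans$status != "optimal") {
    stop("cooperative trade-off stage 2 (quadratic allocation): ",
         ans$status, call. = FALSE)
  }
  v <- stats::setNames(ans$solution, colnames(community$S))
  new_flux_solution(v, community, sum(v[gcols]^2), "optimal",
                    extra = list(mu_max = mu_max, tau = tau))
}

#' Minimal metabolite intake at a growth floor
#'
#' Minimizes the total lumen import magnitude (sum over environment
#' exchanges of \code{max(0, -v)}) subject to community growth at least
#' \code{growth_floor} and all flux balance constraints — the
#' "lowest possible metabolite intake" selection among optimal-growth
#' communities.
#'
#' @param community a \code{community_model}.
#' @param growth_floor required community growth (1/h); must not exceed
#'   the maximal achievable growth.
#' @return a \code{flux_solution}; additionally carries
#'   \code{total_intake}.
#' @export
minimize_intake <- function(community, growth_floor) {
  stopifnot(inherits(community, "community_model"))
  stage1 <- fba(community)
  if (stage1$status != "optimal" ||
      growth_floor > stage1$community_growth + 1e-6) {
    community$reactions <- community$reactions
    return(new_flux_solution(NULL, community, NA_real_, "infeasible",
                             extra = list(total_intake = NA_real_)))
  }
  n <- ncol(community$S)
  env <- which(community$reactions$role == "lumen-exchange")
  k <- length(env)
  # split each environment exchange v = p - q with p (export) taking the
  # original column and q (import) a mirrored one; minimizing sum(q)
  # needs only equality rows, bounds and the single growth-floor row
  Seq <- cbind(community$S, -community$S[, env, drop = FALSE])
  lb2 <- c(community$lb, rep(0, k))
  lb2[env] <- 0
  ub2 <- c(community$ub, pmax(0, -community$lb[env]))
  arow <- numeric(n + k)
  arow[community$biomass_cols] <- community$taxa
  obj <- c(rep(0, n), rep(-1, k))  # maximize -sum(q)
  ans <- solve_lp(obj, Seq = Seq, Aineq = matrix(arow, 1),
                  bineq = growth_floor, lb = lb2, ub = ub2)
  if (ans$status != "optimal") {
    return(new_flux_solution(NULL, community, NA_real_, ans$status,
                             extra = list(total_intake = NA_real_)))
  }
  v <- ans$solution[seq_len(n)]
  v[env] <- v[env] - ans$solution[n + seq_len(k)]
  v <- stats::setNames(v, colnames(community$S))
  new_flux_solution(v, community, -ans$objective, "optimal",
                    extra = list(total_intake = -ans$objective))
}

#' Lumen environment exchange fluxes of a solution
#'
#' @param solution a \code{flux_solution} from a community solve.
#' @return named numeric vector by metabolite label; > 0 export out of the
#'   community, < 0 import from the diet.
#' @export
lumen_exchange_fluxes <- function(solution) {
  stopifnot(inherits(solution, "flux_solution"))
  env <- solution$reactions$role == "lumen-exchange"
  ids <- solution$reactions$id[env]
  stats::setNames(solution$fluxes[ids],
                  sub("^EX_(.*)_lu$", "\\1", ids))
}

#' Write a flux solution as TSV
#'
#' Columns: reaction_id, taxon, flux, direction (import/export/none at the
#' 1e-6 flux epsilon).
#'
#' @param solution a \code{flux_solution}.
#' @param path output file.
#' @export
write_fluxes <- function(solution, path) {
  stopifnot(inherits(solution, "flux_solution"),
            solution$status == "optimal")
  fl <- solution$fluxes[solution$reactions$id]
  dir <- ifelse(fl > FLUX_EPSILON, "export",
                ifelse(fl < -FLUX_EPSILON, "import", "none"))
  utils::write.table(
    data.frame(reaction_id = solution$reactions$id,
               taxon = solution$reactions$taxon,
               flux = unname(fl), direction = dir,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
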