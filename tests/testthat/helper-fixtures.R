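# Shared fixtures and independent oracles.

# Vertex-enumeration LP oracle for max c'v s.t. S v = 0, lb <= v <= ub.
# Enumerates candidate active sets (all equality rows plus n - m bound
# constraints at either end) and keeps the best feasible basic solution.
# Exponential, only for n <= ~7.
enumerate_lp <- function(S, lb, ub, cc) {
  n <- length(cc); m <- nrow(S)
  best <- -Inf
  if (n - m < 0) return(NA_real_)
  combs <- utils::combn(n, n - m)
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    nb <- length(idx)
    for (mask in 0:(2^max(nb, 0) - 1)) {
      vals <- if (nb > 0) {
        ifelse(bitwAnd(mask, 2^(seq_len(nb) - 1)) > 0, ub[idx], lb[idx])
      } else numeric(0)
      rest <- setdiff(seq_len(n), idx)
      v <- numeric(n)
      if (length(rest) > 0) {
        sol <- tryCatch(
          qr.solve(S[, rest, drop = FALSE],
                   if (nb > 0) -S[, idx, drop = FALSE] %*% vals
                   else rep(0, m)),
          error = function(e) NULL)
        if (is.null(sol)) next
        v[rest] <- sol
      }
      if (nb > 0) v[idx] <- vals
      if (all(v >= lb - 1e-9) && all(v <= ub + 1e-9) &&
          max(abs(S %*% v)) < 1e-8) {
        best <- max(best, sum(cc * v))
      }
    }
  }
  best
}

random_fba_lp <- function(n = 5, m = 2) {
  S <- matrix(sample(-2:2, m * n, TRUE), m, n)
  lb <- ifelse(stats::runif(n) < 0.5, 0, -stats::runif(n, 0, 5))
  ub <- stats::runif(n, 0, 10)
  cc <- stats::rnorm(n)
  list(S = S, lb = lb, ub = ub, cc = cc)
}

# A single linear-chain taxon: substrate -> yield * biomass, nothing else.
chain_archetype <- function(name = "chain", yield = 1) {
  taxon_archetype(name, consumes = "glc", secretes = numeric(0),
                  growth_yield = yield)
}

# Minimal two-member cross-feeding pair: a feeder secreting acetate and a
# consumer that can only grow on acetate (its glc uptake is shut).
cross_feeding_models <- function() {
  feeder <- generate_taxon_model(
    taxon_archetype("feeder", "glc", c(acetate = 1)), size = 4)
  consumer <- generate_taxon_model(
    taxon_archetype("consumer", c("glc", "acetate")), size = 6)
  # shut the consumer's own carbon source
  for (k in seq_along(consumer$reactions)) {
    if (consumer$reactions[[k]]$id == "EX_glc") {
      consumer$reactions[[k]]$lb <- 0
    }
  }
  list(feeder = feeder, consumer = consumer)
}

# diet supplying only glucose at the given bound
glc_diet <- function(bound = 10) {
  data.frame(reaction_id = "EX_glc(e)", max_uptake = bound,
             class = "carbohydrate", energy_density = 0.72,
             stringsAsFactors = FALSE)
}
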