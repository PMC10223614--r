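# Synthetic inputs: taxon roster, diets, paired abundance tables, trees.
#
# Everything the pipeline consumes can be generated here so that the whole
# analysis runs without external databases. The default roster names 12
# gut taxa with producer/consumer roles matching their literature
# phenotypes (e.g. S. variabile as a butyrate producer that also converts
# acetate, R. bromii as a starch degrader). Secretion yields are the
# generator's calibration constants: under the healthy preset and a
# western-style diet the community lumen SCFA export ratio
# acetate:butyrate:propionate is calibrated to approximately 3:1:1.

# kcal per mmol: Atwater factors (9 kcal/g lipid, 4 kcal/g carbohydrate
# and protein, 2 kcal/g fermentable fiber) times molar mass
ENERGY_DENSITY <- c(
  glc = 0.720, starch = 0.648, palm = 2.304,
  glu_L = 0.588, trp_L = 0.816, tyr_L = 0.724, phe_L = 0.660,
  fiber = 0.324)

NUTRIENT_CLASS <- c(
  glc = "carbohydrate", starch = "carbohydrate", palm = "lipid",
  glu_L = "protein", trp_L = "protein", tyr_L = "protein",
  phe_L = "protein", fiber = "other")

#' Default taxon archetype roster
#'
#' Twelve gut taxa with consumer/producer roles: SCFA producers (acetate,
#' butyrate, propionate, formate), amino-acid consumers, starch degraders,
#' an acetate-to-butyrate cross-feeder (S. variabile) and the probiotic
#' L. rhamnosus. Secretion yields are calibrated so the healthy preset
#' exports SCFAs at roughly 3:1:1 acetate:butyrate:propionate.
#'
#' @return named list of \code{\link{taxon_archetype}} objects.
#' @export
taxon_archetypes <- function() {
  a <- list(
    taxon_archetype("A_putredinis", c("glc", "trp_L"),
                    c(acetate = 0.50, formate = 0.30)),
    taxon_archetype("B_uniformis", c("glc", "trp_L"),
                    c(acetate = 0.40, propionate = 0.15)),
    taxon_archetype("B_vulgatus", c("glc", "palm"),
                    c(acetate = 0.35, propionate = 0.17)),
    taxon_archetype("B_adolescentis", c("glc", "tyr_L", "phe_L"),
                    c(acetate = 0.55, formate = 0.25)),
    taxon_archetype("C_catus", c("glc"),
                    c(propionate = 0.21, butyrate = 0.32)),
    taxon_archetype("C_comes", c("glc", "glu_L"),
                    c(butyrate = 0.72)),
    taxon_archetype("C_aerofaciens", c("glc", "starch"),
                    c(acetate = 0.40, glu_L = 0.10, H2 = 0.20)),
    taxon_archetype("S_variabile", c("glc", "acetate", "tyr_L", "phe_L"),
                    c(butyrate = 0.80)),
    taxon_archetype("P_copri", c("starch", "fiber", "glc"),
                    c(propionate = 0.17, acetate = 0.20)),
    taxon_archetype("R_bromii", c("starch"),
                    c(acetate = 0.45, H2 = 0.25)),
    taxon_archetype("D_longicatena", c("glc", "trp_L", "formate"),
                    c(acetate = 0.35, H2 = 0.15)),
    taxon_archetype("L_rhamnosus", c("glc"),
                    c(acetate = 0.45)))
  stats::setNames(a, vapply(a, `[[`, "", "name"))
}

# healthy-gut baseline composition (relative abundance)
HEALTHY_ABUNDANCES <- c(
  A_putredinis = 0.08, B_uniformis = 0.15, B_vulgatus = 0.13,
  B_adolescentis = 0.06, C_catus = 0.06, C_comes = 0.08,
  C_aerofaciens = 0.07, S_variabile = 0.07, P_copri = 0.12,
  R_bromii = 0.10, D_longicatena = 0.06, L_rhamnosus = 0.02)

#' Generate a diet specification
#'
#' Realizes a diet style as per-nutrient exchange uptake bounds
#' (mmol/gDW/h) with nutrient class and energy density (kcal/mmol,
#' Atwater factors times molar mass). The macro-class energy fractions of
#' the generated table match the style's targets: western 50/35/15
#' carbohydrate/lipid/protein, atkins 1.7/70/24 with a 4.3% fermentable
#' fiber component, vegan 63.35/20.99/15.66.
#'
#' @param style one of \code{"western"}, \code{"atkins"}, \code{"vegan"}.
#' @param total_energy total dietary energy supply rate (kcal/gDW/h)
#'   distributed across nutrients.
#' @return data frame with columns \code{reaction_id} (VMH style, e.g.
#'   \code{EX_glc(e)}), \code{max_uptake}, \code{class},
#'   \code{energy_density}; attribute \code{"style"}.
#' @export
generate_diet <- function(style = c("western", "atkins", "vegan"),
                          total_energy = 10) {
  style <- tryCatch(match.arg(style),
                    error = function(e) stop("unknown diet style: ",
                                             style[1], call. = FALSE))
  targets <- switch(style,
    western = c(carbohydrate = 50, lipid = 35, protein = 15, other = 0),
    atkins  = c(carbohydrate = 1.7, lipid = 70, protein = 24, other = 4.3),
    vegan   = c(carbohydrate = 63.35, lipid = 20.99, protein = 15.66,
                other = 0))
  # intra-class energy shares
  shares <- list(
    carbohydrate = c(glc = 0.6, starch = 0.4),
    lipid = c(palm = 1),
    protein = c(glu_L = 0.4, trp_L = 0.2, tyr_L = 0.2, phe_L = 0.2),
    other = c(fiber = 1))
  rows <- list()
  for (cl in names(targets)) {
    e_class <- total_energy * targets[[cl]] / 100
    if (e_class == 0) next
    for (nut in names(shares[[cl]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = paste0("EX_", nut, "(e)"),
        max_uptake = e_class * shares[[cl]][[nut]] / ENERGY_DENSITY[[nut]],
        class = cl,
        energy_density = ENERGY_DENSITY[[nut]],
        stringsAsFactors = FALSE)
    }
  }
  diet <- do.call(rbind, rows)
  rownames(diet) <- NULL
  attr(diet, "style") <- style
  diet
}

#' Energy fractions of a diet specification
#'
#' Percent of total dietary energy carried by each nutrient class, where a
#' nutrient's energy supply is its uptake bound times its energy density.
#'
#' @param diet a diet specification data frame.
#' @return named numeric vector (percent) over the classes present.
#' @export
diet_energy_fractions <- function(diet) {
  stopifnot(is.data.frame(diet),
            all(c("max_uptake", "class", "energy_density") %in% names(diet)))
  energy <- diet$max_uptake * diet$energy_density
  total <- sum(energy)
  if (total <= 0) stop("diet carries no energy", call. = FALSE)
  100 * vapply(split(energy, diet$class), sum, 0) / total
}

#' Specification of planted group effects
#'
#' Describes how ADHD members of synthetic pairs differ from their matched
#' controls: log-fold abundance shifts, log-abundance noise, and the taxa
#' designated to show inflated elasticity variance.
#'
#' @param elastic_taxa taxa designated for wider elasticity variance in
#'   ADHD members.
#' @param abundance_shifts named numeric vector of log-fold changes (ADHD
#'   vs control).
#' @param noise_sd standard deviation of log-abundance noise (>= 0).
#' @param seed integer RNG seed.
#' @export
effect_spec <- function(elastic_taxa = character(0),
                        abundance_shifts = numeric(0),
                        noise_sd = 0.3, seed = 1L) {
  stopifnot(noise_sd >= 0, all(is.finite(abundance_shifts)))
  structure(list(elastic_taxa = elastic_taxa,
                 abundance_shifts = abundance_shifts,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "effect_spec")
}

#' Generate a paired case/control abundance study
#'
#' Builds \code{2 * n_pairs} samples organized in age- and gender-matched
#' ADHD/control pairs. Each pair draws a shared baseline log-abundance
#' profile (roster baseline plus pair-level lognormal variation); the ADHD
#' member additionally receives the planted log-fold shifts. Multiplicative
#' lognormal noise is applied per member, abundances are renormalized, and
#' integer counts are drawn by multinomial sampling at the given depth
#' (Chao1 needs singletons and doubletons, which relative abundances
#' cannot supply).
#'
#' @param n_pairs number of pairs (>= 1).
#' @param taxa taxon labels (non-empty).
#' @param effect an \code{\link{effect_spec}}.
#' @param depth multinomial count depth per sample.
#' @return an object of class \code{"paired_study"}: list with
#'   \code{abundance} (samples x taxa relative abundances), \code{counts}
#'   (integer matrix), \code{metadata} (sample_id, age, gender, status,
#'   pair_id).
#' @export
generate_paired_study <- function(n_pairs, taxa, effect = effect_spec(),
                                  depth = 10000L) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (length(taxa) < 1) stop("taxa must be non-empty", call. = FALSE)
  set.seed(effect$seed)
  nt <- length(taxa)
  base_w <- rep(1 / nt, nt)
  known <- taxa %in% names(HEALTHY_ABUNDANCES)
  base_w[known] <- HEALTHY_ABUNDANCES[taxa[known]]
  log_base <- log(base_w / sum(base_w))
  shifts <- numeric(nt)
  hit <- taxa %in% names(effect$abundance_shifts)
  shifts[hit] <- effect$abundance_shifts[taxa[hit]]

  ab <- matrix(0, 2 * n_pairs, nt,
               dimnames = list(NULL, taxa))
  meta <- data.frame(sample_id = character(2 * n_pairs), age = integer(2 * n_pairs),
                     gender = character(2 * n_pairs),
                     status = character(2 * n_pairs),
                     pair_id = character(2 * n_pairs),
                     stringsAsFactors = FALSE)
  for (p in seq_len(n_pairs)) {
    age <- max(12L, round(stats::rnorm(1, 19.5, 2.5)))
    gender <- sample(c("M", "F"), 1, prob = c(0.6, 0.4))
    pair_base <- log_base + stats::rnorm(nt, 0, 0.5)
    for (member in c("ADHD", "Control")) {
      lg <- pair_base + stats::rnorm(nt, 0, effect$noise_sd)
      if (member == "ADHD") lg <- lg + shifts
      i <- 2 * (p - 1) + if (member == "ADHD") 1 else 2
      w <- exp(lg)
      ab[i, ] <- w / sum(w)
      meta$sample_id[i] <- sprintf("P%02d_%s", p, member)
      meta$age[i] <- age
      meta$gender[i] <- gender
      meta$status[i] <- member
      meta$pair_id[i] <- sprintf("P%02d", p)
    }
  }
  rownames(ab) <- meta$sample_id
  counts <- t(apply(ab, 1, function(p) stats::rmultinom(1, depth, p)[, 1]))
  dimnames(counts) <- dimnames(ab)
  structure(list(abundance = ab, counts = counts, metadata = meta,
                 depth = as.integer(depth)),
            class = "paired_study")
}

#' @export
print.paired_study <- function(x, ...) {
  cat("paired_study:", nrow(x$abundance), "samples,",
      ncol(x$abundance), "taxa,",
      length(unique(x$metadata$pair_id)), "pairs\n")
  invisible(x)
}

#' Generate a random taxon phylogeny
#'
#' Random binary coalescent-style topology with exponentially distributed
#' branch lengths; every taxon appears as exactly one leaf.
#'
#' @param taxa leaf labels (>= 2, unique).
#' @param seed integer RNG seed.
#' @return an \code{ape} \code{phylo} object.
#' @export
generate_tree <- function(taxa, seed = 1L) {
  if (length(taxa) < 2) stop("need at least 2 taxa", call. = FALSE)
  if (anyDuplicated(taxa)) stop("duplicate taxon labels", call. = FALSE)
  set.seed(seed)
  tr <- ape::rcoal(length(taxa), tip.label = taxa)
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  tr
}

#' The calibrated healthy community preset
#'
#' Builds the 12-taxon roster community at the healthy baseline
#' composition, applies the abundance cutoff, and puts it on a diet.
#' This is the documented preset whose lumen SCFA export ratio is
#' calibrated to approximately 3:1:1 acetate:butyrate:propionate under the
#' western-style diet.
#'
#' @param diet_style diet style passed to \code{\link{generate_diet}}.
#' @param abundances override the baseline composition (named vector).
#' @param cutoff abundance cutoff applied before assembly.
#' @param size per-taxon model size passed to
#'   \code{\link{generate_taxon_model}}.
#' @return a diet-bounded \code{community_model}.
#' @export
healthy_community <- function(diet_style = "western",
                              abundances = HEALTHY_ABUNDANCES,
                              cutoff = 1e-4, size = 8L) {
  arch <- taxon_archetypes()
  ab <- filter_abundances(abundances, cutoff)
  models <- lapply(arch[names(ab)], generate_taxon_model, size = size)
  comm <- assemble_community(models, ab)
  apply_diet(comm, generate_diet(diet_style))
}

#' Generate a matched pair of elasticity profiles with a planted effect
#'
#' Emulates the elasticity tables of a case/control comparison: for every
#' (flux, taxon-abundance parameter) cell a baseline elasticity is drawn
#' once and shared by both members; the ADHD member's elasticities for the
#' designated taxa have their spread around the cell mean inflated by
#' \code{sqrt(inflation)} (variance times \code{inflation}); independent
#' observation noise (relative to the baseline spread) is added per
#' member. With zero inflation and zero noise the two profiles are
#' identical. The default noise is set by design: the log variance ratio
#' of the two members fluctuates with standard deviation about
#' sqrt(2) * 2 * noise_sd / sqrt(nf - 1) under the null, so noise_sd =
#' 0.05 keeps the probability of a spurious ADHD/Control label (ratio
#' beyond the 20% width threshold) below 1% for the default 8-flux
#' panel.
#'
#' @param taxa taxon labels (the abundance-parameter panel).
#' @param fluxes flux labels (the flux panel).
#' @param elastic_taxa taxa planted with inflated variance in the ADHD
#'   member.
#' @param inflation variance inflation factor (>= 1).
#' @param noise_sd observation noise as a fraction of the baseline
#'   elasticity spread.
#' @param seed integer RNG seed.
#' @return list with elements \code{adhd} and \code{control}, each an
#'   elasticity profile data frame as returned by
#'   \code{\link{elasticity_profile}}.
#' @export
generate_elasticity_pair <- function(taxa,
                                     fluxes = c("EX_acetate_lu",
                                                "EX_butyrate_lu",
                                                "EX_propionate_lu",
                                                "EX_formate_lu",
                                                "EX_glu_L_lu",
                                                "EX_trp_L_lu",
                                                "EX_tyr_L_lu",
                                                "EX_phe_L_lu"),
                                     elastic_taxa = character(0),
                                     inflation = 3, noise_sd = 0.05,
                                     seed = 1L) {
  stopifnot(inflation >= 1, noise_sd >= 0)
  set.seed(seed)
  nf <- length(fluxes)
  mk <- function() data.frame(
    flux = rep(fluxes, times = length(taxa)),
    parameter = rep(paste0("abundance:", taxa), each = nf),
    param_type = "abundance",
    taxon = rep(taxa, each = nf),
    elasticity = NA_real_, direction = 1, status = "ok", h = 0.1,
    stringsAsFactors = FALSE)
  adhd <- mk(); control <- mk()
  sd_base <- 0.5
  for (t in taxa) {
    mu <- stats::rnorm(1, 0, 1)
    base <- mu + stats::rnorm(nf, 0, sd_base)
    idx <- adhd$taxon == t
    ctrl_e <- base + stats::rnorm(nf, 0, noise_sd * sd_base)
    infl <- if (t %in% elastic_taxa) sqrt(inflation) else 1
    adhd_e <- mu + infl * (base - mu) + stats::rnorm(nf, 0, noise_sd * sd_base)
    control$elasticity[idx] <- ctrl_e
    adhd$elasticity[idx] <- adhd_e
  }
  list(adhd = adhd, control = control)
}

# ---- plain-text I/O ---------------------------------------------------

#' Write / read a paired study (CSV pair)
#'
#' The abundance CSV has the sample id in the first column and one column
#' per taxon; the companion metadata CSV has columns sample_id, age,
#' gender, status, pair_id. A counts CSV with the same layout as the
#' abundance table is written alongside.
#'
#' @param study a \code{paired_study}.
#' @param dir output directory (created if missing).
#' @return \code{read_study} returns a \code{paired_study}.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "paired_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ab <- data.frame(sample_id = rownames(study$abundance),
                   study$abundance, check.names = FALSE)
  ct <- data.frame(sample_id = rownames(study$counts),
                   study$counts, check.names = FALSE)
  utils::write.csv(ab, file.path(dir, "abundance.csv"), row.names = FALSE)
  utils::write.csv(ct, file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(study$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  ab <- utils::read.csv(file.path(dir, "abundance.csv"), check.names = FALSE)
  ct <- utils::read.csv(file.path(dir, "counts.csv"), check.names = FALSE)
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  abm <- as.matrix(ab[, -1, drop = FALSE])
  rownames(abm) <- ab$sample_id
  ctm <- as.matrix(ct[, -1, drop = FALSE])
  rownames(ctm) <- ct$sample_id
  structure(list(abundance = abm, counts = ctm, metadata = meta,
                 depth = as.integer(round(sum(ctm[1, ])))),
            class = "paired_study")
}

#' Write / read a diet specification (TSV)
#'
#' @param diet a diet specification data frame.
#' @param path file path.
#' @export
write_diet <- function(diet, path) {
  utils::write.table(diet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_diet
#' @export
read_diet <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
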