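# End-to-end pipeline: generate inputs, build and solve communities under
# each diet, profile elasticities and pair labels, compute diversity,
# apply the probiotic intervention, and write every artifact with a
# manifest (config, seed, per-file checksums). One global seed fans out
# to per-stage seeds by stable integer hashing so stages can be re-run in
# isolation.

stage_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483647)
}

#' Pipeline configuration
#'
#' @param seed global RNG seed; per-stage seeds are derived from it.
#' @param n_pairs number of matched ADHD/control pairs.
#' @param taxa taxon roster (default: the 12-taxon archetype roster).
#' @param diet_styles diet styles to run.
#' @param tau cooperative trade-off fraction.
#' @param cutoff abundance cutoff.
#' @param h elasticity log-scale step.
#' @param theta pair-label variance-width threshold.
#' @param probiotic probiotic taxon for the intervention stage.
#' @param reference_sample control sample id used as the healthy
#'   reference for dose fitting, or \code{NULL} to pick one at random
#'   (seeded).
#' @param effect planted-effect specification for the study generator.
#' @param flux_panel lumen exchange fluxes profiled by the elasticity
#'   stage.
#' @param model_size per-taxon model size.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1L, n_pairs = 10L,
                            taxa = names(taxon_archetypes()),
                            diet_styles = c("western", "atkins", "vegan"),
                            tau = 0.7, cutoff = 1e-4, h = 0.1,
                            theta = 0.2, probiotic = "L_rhamnosus",
                            reference_sample = NULL,
                            effect = NULL,
                            flux_panel = c("EX_acetate_lu",
                                           "EX_butyrate_lu",
                                           "EX_propionate_lu",
                                           "EX_formate_lu"),
                            model_size = 8L) {
  stopifnot(tau > 0, tau <= 1, h > 0, n_pairs >= 1)
  if (is.null(effect)) effect <- effect_spec(seed = stage_seed(seed, 1))
  structure(list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                 taxa = taxa, diet_styles = diet_styles, tau = tau,
                 cutoff = cutoff, h = h, theta = theta,
                 probiotic = probiotic,
                 reference_sample = reference_sample, effect = effect,
                 flux_panel = flux_panel,
                 model_size = as.integer(model_size)),
            class = "pipeline_config")
}

.build_sample_community <- function(abundance_row, models, diet, cutoff) {
  ab <- filter_abundances(abundance_row, cutoff)
  comm <- assemble_community(models[names(ab)], ab)
  apply_diet(comm, diet)
}

#' Run the full analysis pipeline
#'
#' Stages: generate (paired study, tree, diets), build (community per
#' sample), grow (cooperative trade-off then minimal intake under each
#' diet), elasticity (profiles and pair labels per diet), diversity
#' (alpha report, Bray-Curtis and UniFrac matrices, group tests),
#' intervene (probiotic dose fit and flux shifts), and a manifest tying
#' every artifact to the config and seed. A stage failure aborts with the
#' stage name after persisting the partial manifest.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(config = unclass(config)["seed" != names(unclass(config))],
                   seed = config$seed, stages = list(), files = list())
  manifest$config$effect <- unclass(manifest$config$effect)
  persist <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    persist()
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(stage, fun) {
    log <- character(0)
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) fail(stage, e)),
      warning = function(w) {
        log <<- c(log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[stage]] <<- c(list(status = "ok"), res,
                                   if (length(log))
                                     list(warnings = unique(log)))
    persist()
  }

  arch <- taxon_archetypes()[config$taxa]
  models <- lapply(arch, generate_taxon_model, size = config$model_size,
                   seed = stage_seed(config$seed, 2))
  study <- NULL; tree <- NULL; diets <- NULL
  solutions <- list()   # [[diet]][[sample_id]]

  run_stage("generate", function() {
    study <<- generate_paired_study(config$n_pairs, config$taxa,
                                    config$effect)
    tree <<- generate_tree(config$taxa, stage_seed(config$seed, 3))
    diets <<- stats::setNames(lapply(config$diet_styles, generate_diet),
                              config$diet_styles)
    write_study(study, file.path(out_dir, "study"))
    ape::write.tree(tree, file.path(out_dir, "taxa.nwk"))
    for (st in names(diets)) {
      write_diet(diets[[st]], file.path(out_dir, paste0("diet_", st, ".tsv")))
    }
    list(n_samples = nrow(study$abundance))
  })

  run_stage("grow", function() {
    ratios <- list()
    for (st in names(diets)) {
      dir.create(file.path(out_dir, "fluxes", st), recursive = TRUE,
                 showWarnings = FALSE)
      solutions[[st]] <<- list()
      for (sid in rownames(study$abundance)) {
        comm <- .build_sample_community(study$abundance[sid, ], models,
                                        diets[[st]], config$cutoff)
        sol <- cooperative_tradeoff(comm, config$tau)
        pars <- minimize_intake(comm, sol$community_growth - 1e-9)
        solutions[[st]][[sid]] <<- sol
        write_fluxes(pars, file.path(out_dir, "fluxes", st,
                                     paste0(sid, ".tsv")))
        ratios[[paste(st, sid, sep = "/")]] <-
          sol$community_growth / sol$mu_max
      }
    }
    list(tradeoff_ratio = ratios)
  })

  run_stage("elasticity", function() {
    labels_by_diet <- list()
    for (st in names(diets)) {
      profiles <- list()
      for (sid in rownames(study$abundance)) {
        comm <- .build_sample_community(study$abundance[sid, ], models,
                                        diets[[st]], config$cutoff)
        pars <- paste0("abundance:", names(comm$taxa))
        prof <- elasticity_profile(comm, config$flux_panel, pars,
                                   h = config$h, tau = config$tau)
        profiles[[sid]] <- prof
        write_elasticities(prof, sid,
                           file.path(out_dir, "fluxes", st,
                                     paste0(sid, "_elasticity.tsv")))
      }
      grid <- pair_label_table(profiles, study$metadata, config$taxa,
                               theta = config$theta)
      utils::write.table(grid, file.path(out_dir,
                                         paste0("pair_labels_", st, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      labels_by_diet[[st]] <- table(unlist(grid[-1]))
    }
    list(label_counts = lapply(labels_by_diet, as.list))
  })

  run_stage("diversity", function() {
    rep <- diversity_report(study)
    utils::write.csv(rep, file.path(out_dir, "alpha_diversity.csv"),
                     row.names = FALSE)
    n <- nrow(study$counts)
    bc <- matrix(0, n, n, dimnames = list(rownames(study$counts),
                                          rownames(study$counts)))
    uw <- bc; ww <- bc
    for (a in seq_len(n)) for (b in seq_len(n)) if (a < b) {
      bc[a, b] <- bc[b, a] <- bray_curtis(study$counts[a, ],
                                          study$counts[b, ])
      uw[a, b] <- uw[b, a] <- unifrac(study$counts[a, ], study$counts[b, ],
                                      tree, weighted = FALSE)
      ww[a, b] <- ww[b, a] <- unifrac(study$counts[a, ], study$counts[b, ],
                                      tree, weighted = TRUE)
    }
    for (nm in c("bray_curtis", "unifrac_unweighted", "unifrac_weighted")) {
      m <- switch(nm, bray_curtis = bc, unifrac_unweighted = uw,
                  unifrac_weighted = ww)
      utils::write.table(m, file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE)
    }
    is_adhd <- study$metadata$status == "ADHD"
    tests <- do.call(rbind, lapply(
      c("richness", "chao1", "shannon", "simpson_D", "evenness"),
      function(ix) {
        mw <- mann_whitney_u(rep[[ix]][is_adhd], rep[[ix]][!is_adhd])
        # a constant index (e.g. richness when every taxon is observed
        # in every sample) has no variance to compare
        ft <- tryCatch(
          f_test_variance(rep[[ix]][is_adhd], rep[[ix]][!is_adhd]),
          error = function(e) list(F = NA_real_, p = NA_real_))
        data.frame(comparison = ix,
                   mwu_U = mw$U, mwu_p = mw$p,
                   f_stat = ft$F, f_p = ft$p, stringsAsFactors = FALSE)
      }))
    utils::write.table(tests, file.path(out_dir, "group_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(mean_shannon = mean(rep$shannon))
  })

  run_stage("intervene", function() {
    meta <- study$metadata
    controls <- meta$sample_id[meta$status == "Control"]
    ref <- config$reference_sample
    if (is.null(ref)) {
      set.seed(stage_seed(config$seed, 4))
      ref <- sample(controls, 1)
    }
    ref_ab <- study$abundance[ref, ]
    shifts <- list()
    for (sid in meta$sample_id[meta$status == "ADHD"]) {
      dose <- fit_probiotic_dose(study$abundance[sid, ], ref_ab,
                                 config$probiotic)
      row <- study$abundance[sid, ]
      row[config$probiotic] <- row[config$probiotic] + dose
      row <- row / sum(row)
      for (st in names(diets)) {
        comm_post <- .build_sample_community(row, models, diets[[st]],
                                             config$cutoff)
        post <- cooperative_tradeoff(comm_post, config$tau)
        shift <- compare_flux_shift(solutions[[st]][[sid]], post)
        utils::write.table(shift,
                           file.path(out_dir, "fluxes", st,
                                     paste0(sid, "_shift.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        shifts[[paste(st, sid, sep = "/")]] <- list(
          dose = dose,
          mean_abs_change = mean(abs(shift$percent_change), na.rm = TRUE))
      }
    }
    list(reference = ref, shifts = shifts)
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- as.list(stats::setNames(
    unname(tools::md5sum(files)),
    sub(paste0("^", out_dir, "/?"), "", files)))
  persist()
  invisible(manifest)
}

#' Pair-label grid for a set of per-sample elasticity profiles
#'
#' Builds the taxon-by-pair grid of ADHD/Control/Same/NA labels from the
#' per-member elasticity-variance comparison.
#'
#' @param profiles named list of elasticity profile data frames, keyed by
#'   sample id.
#' @param metadata study metadata (sample_id, status, pair_id).
#' @param taxa taxa to label (grid rows).
#' @param theta relative variance-width threshold.
#' @return data frame: first column \code{taxon}, one column per pair.
#' @export
pair_label_table <- function(profiles, metadata, taxa, theta = 0.2) {
  pairs <- unique(metadata$pair_id)
  grid <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  for (p in pairs) {
    sid_a <- metadata$sample_id[metadata$pair_id == p &
                                metadata$status == "ADHD"]
    sid_c <- metadata$sample_id[metadata$pair_id == p &
                                metadata$status == "Control"]
    grid[[p]] <- vapply(taxa, function(tx)
      compare_pair_variances(profiles[[sid_a]], profiles[[sid_c]], tx,
                             theta = theta)$label, "")
  }
  grid
}

#' Cross-diet metabolite panel summary
#'
#' Aggregates lumen exchange fluxes of the panel metabolites per
#' metabolite, diet and status: mean flux, direction, and a significance
#' flag at the 1 mmol/gDW/h threshold (fluxes below it are reported as
#' insignificant).
#'
#' @param entries list of entries, each a list with elements
#'   \code{solution} (an optimal \code{flux_solution}), \code{diet} and
#'   \code{status}.
#' @param panel metabolite labels.
#' @param threshold significance threshold on |flux| (mmol/gDW/h).
#' @return data frame: metabolite, diet, status, flux, direction,
#'   significant.
#' @export
summarize_metabolite_panel <- function(entries,
                                       panel = c("acetate", "butyrate",
                                                 "propionate", "formate",
                                                 "glu_L", "trp_L",
                                                 "tyr_L", "phe_L"),
                                       threshold = 1) {
  key <- vapply(entries, function(e) paste(e$diet, e$status, sep = "|"), "")
  out <- list()
  for (k in unique(key)) {
    sols <- entries[key == k]
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    fl <- rowMeans(vapply(sols, function(e) {
      le <- lumen_exchange_fluxes(e$solution)
      vapply(panel, function(m) if (m %in% names(le)) le[[m]] else 0, 0)
    }, numeric(length(panel))))
    out[[k]] <- data.frame(
      metabolite = panel, diet = parts[1], status = parts[2],
      flux = unname(fl),
      direction = ifelse(fl > FLUX_EPSILON, "export",
                         ifelse(fl < -FLUX_EPSILON, "import", "none")),
      significant = abs(fl) >= threshold,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
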