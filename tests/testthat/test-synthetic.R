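# Generators: taxon models, paired studies, diets, trees.

test_that("a minimal acetate producer grows and exports acetate", {
  arch <- taxon_archetype("toy", "glc", c(acetate = 1.5),
                          growth_yield = 0.1)
  mod <- generate_taxon_model(arch, size = 4)
  expect_length(mod$reactions, 4)
  sol <- fba(mod)
  expect_equal(sol$status, "optimal")
  # uptake cap 10: growth = 0.1 * 10, acetate export = 1.5 * 10
  expect_equal(unname(sol$community_growth), 1.0, tolerance = 1e-6)
  expect_equal(unname(sol$fluxes[["toy__EX_acetate"]]), 15, tolerance = 1e-5)
})

test_that("zero secretion yield leaves only carbon uptake and biomass active", {
  arch <- taxon_archetype("lean", "glc", c(acetate = 0))
  sol <- fba(generate_taxon_model(arch, size = 5))
  expect_equal(sol$status, "optimal")
  active <- names(sol$fluxes)[abs(sol$fluxes) > 1e-6]
  expect_false("lean__EX_acetate" %in% active)
  expect_true(all(c("lean__EX_glc", "lean__BIOMASS") %in% active))
})

test_that("model generation is deterministic and validates its inputs", {
  arch <- taxon_archetype("t", c("glc", "acetate"), c(butyrate = 0.4))
  expect_identical(generate_taxon_model(arch, 8, seed = 3),
                   generate_taxon_model(arch, 8, seed = 3))
  expect_error(generate_taxon_model(arch, size = 3), "at least 4")
  expect_error(taxon_archetype("t", character(0)), "energy source")
  expect_error(taxon_archetype("t", "glc", c(glc = 1)), "disjoint")
  # internal mass balance: every internal metabolite in >= 2 reactions
  mod <- generate_taxon_model(arch, 10)
  for (met in mod$metabolites$id) {
    touching <- sum(vapply(mod$reactions,
                           function(r) met %in% names(r$stoich), TRUE))
    expect_gte(touching, 2)
  }
})

test_that("paired studies are matched, normalized and respect planted shifts", {
  study <- generate_paired_study(10, names(taxon_archetypes()))
  expect_equal(nrow(study$abundance), 20)
  expect_equal(length(unique(study$metadata$pair_id)), 10)
  expect_equal(unname(rowSums(study$abundance)), rep(1, 20),
               tolerance = 1e-12)
  for (p in unique(study$metadata$pair_id)) {
    members <- study$metadata[study$metadata$pair_id == p, ]
    expect_setequal(members$status, c("ADHD", "Control"))
    expect_equal(length(unique(members$age)), 1)
    expect_equal(length(unique(members$gender)), 1)
  }

  # zero noise, zero shift: members identical
  quiet <- generate_paired_study(3, c("A", "B", "C"),
                                 effect_spec(noise_sd = 0, seed = 7))
  for (p in 1:3) {
    expect_equal(quiet$abundance[2 * p - 1, ], quiet$abundance[2 * p, ])
  }

  # +1 log-unit shift with zero noise: e^1 fold before renormalization
  shifted <- generate_paired_study(
    4, c("A", "B", "C"),
    effect_spec(abundance_shifts = c(A = 1), noise_sd = 0, seed = 7))
  for (p in 1:4) {
    adhd <- shifted$abundance[2 * p - 1, ]
    ctrl <- shifted$abundance[2 * p, ]
    # ratios relative to an unshifted taxon recover e^1
    expect_equal(unname((adhd["A"] / adhd["B"]) / (ctrl["A"] / ctrl["B"])),
                 exp(1), tolerance = 1e-9)
  }
  expect_error(generate_paired_study(2, character(0)), "non-empty")
})

test_that("diet styles hit their macro energy targets", {
  atkins <- diet_energy_fractions(generate_diet("atkins"))
  expect_equal(unname(atkins["lipid"]), 70, tolerance = 0.1)
  expect_equal(unname(atkins["carbohydrate"]), 1.7, tolerance = 0.1)
  expect_equal(unname(atkins["protein"]), 24, tolerance = 0.1)
  vegan <- diet_energy_fractions(generate_diet("vegan"))
  expect_equal(unname(vegan["carbohydrate"]), 63.35, tolerance = 0.1)
  expect_equal(unname(vegan["protein"]), 15.66, tolerance = 0.1)
  for (style in c("western", "atkins", "vegan")) {
    d <- generate_diet(style)
    expect_true(all(d$max_uptake >= 0))
    fr <- diet_energy_fractions(d)
    expect_equal(sum(fr), 100, tolerance = 1e-9)
  }
  expect_error(generate_diet("paleo"), "unknown diet style")
})

test_that("energy fractions follow their definition on hand-built diets", {
  one <- data.frame(reaction_id = "EX_palm(e)", max_uptake = 2,
                    class = "lipid", energy_density = 2.3)
  expect_equal(unname(diet_energy_fractions(one)), 100)
  two <- data.frame(reaction_id = c("EX_glc(e)", "EX_glu_L(e)"),
                    max_uptake = c(1, 2),
                    class = c("carbohydrate", "protein"),
                    energy_density = c(2, 1))
  expect_equal(unname(diet_energy_fractions(two)),
               c(50, 50))
  zero <- data.frame(reaction_id = "EX_h2o(e)", max_uptake = 5,
                     class = "other", energy_density = 0)
  expect_error(diet_energy_fractions(zero), "no energy")
})

test_that("generated trees are binary with all taxa as leaves", {
  taxa <- names(taxon_archetypes())
  tr <- generate_tree(taxa, seed = 4)
  expect_setequal(tr$tip.label, taxa)
  expect_equal(tr$Nnode, length(taxa) - 1)  # binary rooted
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(generate_tree(taxa, seed = 4)),
                   ape::write.tree(tr))
  expect_error(generate_tree(c("A", "A")), "duplicate")
  expect_error(generate_tree("A"), "at least 2")
})

test_that("study round-trips through the CSV layout", {
  study <- generate_paired_study(3, c("A", "B", "C"),
                                 effect_spec(seed = 9))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  back <- read_study(dir)
  expect_equal(back$abundance, study$abundance, tolerance = 1e-12)
  expect_equal(back$counts, study$counts)
  expect_equal(back$metadata$pair_id, study$metadata$pair_id)
})
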