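# Elasticities: finite differences, profiles, pair labels.

# single linear chain: growth and all fluxes scale 1:1 with the diet
# uptake bound, so every defined elasticity wrt that bound is exactly 1
linear_chain_community <- function(bound = 5) {
  mod <- generate_taxon_model(chain_archetype(yield = 0.5), size = 4)
  apply_diet(assemble_community(list(mod), c(chain = 1)), glc_diet(bound))
}

test_that("the log-scale step of 0.1 is a 10.5% native increase", {
  expect_equal(round(100 * (exp(0.1) - 1), 1), 10.5)
})

test_that("a linear-response toy has unit elasticity wrt its uptake bound", {
  comm <- linear_chain_community(5)
  rec <- elasticity(comm, "chain__BIOMASS", "diet:EX_glc(e)", h = 0.1)
  expect_equal(rec$status, "ok")
  expect_equal(rec$elasticity, 1, tolerance = 1e-6)
  rec2 <- elasticity(comm, "EX_glc_lu", "diet:EX_glc(e)", h = 0.1)
  expect_equal(rec2$elasticity, 1, tolerance = 1e-6)
  expect_equal(rec2$direction, -1)  # glucose is imported at baseline
})

test_that("elasticity is invariant to the flux's units", {
  # scaling the biomass stoichiometry changes |v| but not d ln v/d ln p
  comm <- linear_chain_community(5)
  r1 <- elasticity(comm, "chain__CONV_glc", "diet:EX_glc(e)", h = 0.1)
  mod2 <- generate_taxon_model(chain_archetype(yield = 0.05), size = 4)
  comm2 <- apply_diet(assemble_community(list(mod2), c(chain = 1)),
                      glc_diet(5))
  r2 <- elasticity(comm2, "chain__CONV_glc", "diet:EX_glc(e)", h = 0.1)
  expect_equal(r1$elasticity, r2$elasticity, tolerance = 1e-6)
})

test_that("a disconnected taxon's abundance has (near) zero elasticity", {
  # bystander cannot touch the chain's substrate or products
  bystander <- generate_taxon_model(
    taxon_archetype("bystander", "starch", c(H2 = 0.2)), size = 5)
  chain <- generate_taxon_model(chain_archetype(yield = 0.5), size = 4)
  comm <- apply_diet(
    assemble_community(list(chain, bystander),
                       c(chain = 0.5, bystander = 0.5)),
    rbind(glc_diet(5),
          data.frame(reaction_id = "EX_starch(e)", max_uptake = 5,
                     class = "carbohydrate", energy_density = 0.648)))
  # per-gDW chain fluxes are set by the lumen glucose supply per unit
  # abundance; perturbing the bystander changes both abundances after
  # renormalization. Use the community-level export, which is abundance
  # weighted and decoupled from the bystander.
  rec <- elasticity(comm, "EX_H2_lu", "diet:EX_glc(e)", h = 0.1)
  expect_equal(rec$elasticity, 0, tolerance = 1e-6)
})

test_that("undefined baselines never produce infinite elasticities", {
  comm <- linear_chain_community(5)
  # the chain secretes nothing: acetate flux does not exist; a zero flux
  # is exercised through the closed starch route of a two-taxon community
  rec <- elasticity(comm, "chain__EX_glc", "diet:EX_glc(e)", h = 0.1)
  expect_equal(rec$status, "ok")
  mod <- generate_taxon_model(taxon_archetype("a", "glc",
                                              c(acetate = 0)), 5)
  c2 <- apply_diet(assemble_community(list(mod), c(a = 1)), glc_diet(5))
  rec0 <- elasticity(c2, "a__EX_acetate", "diet:EX_glc(e)", h = 0.1)
  expect_equal(rec0$status, "undefined")
  expect_true(is.na(rec0$elasticity))
})

test_that("forward-difference error shrinks linearly with the step", {
  # curved response: with glucose in excess, the quadratic allocation
  # gives mu_i proportional to a_i, so the sole producer's community
  # acetate export is a smooth rational function of its abundance
  # parameter (through the renormalization a_x = p / (p + a_y))
  mx <- generate_taxon_model(
    taxon_archetype("x", "glc", c(acetate = 0.5),
                    growth_yield = 0.05), 5)
  my <- generate_taxon_model(
    taxon_archetype("y", "glc", numeric(0), growth_yield = 0.08), 4)
  comm <- apply_diet(assemble_community(list(mx, my), c(x = .4, y = .6)),
                     glc_diet(50))  # non-binding carbon supply
  eps_at <- function(h) elasticity(comm, "EX_acetate_lu", "abundance:x",
                                   h = h)$elasticity
  e1 <- eps_at(0.2); e2 <- eps_at(0.1); e3 <- eps_at(0.05)
  # Richardson: (e(2h) - e(h)) should be about twice (e(h) - e(h/2))
  d1 <- e1 - e2; d2 <- e2 - e3
  expect_gt(abs(d2), 1e-6)  # the response is genuinely curved
  expect_equal(d1 / d2, 2, tolerance = 0.35)
})

test_that("profiles cover the panel grid deterministically", {
  comm <- healthy_community("western")
  fluxes <- c("EX_acetate_lu", "EX_butyrate_lu", "EX_propionate_lu")
  params <- paste0("abundance:", c("B_uniformis", "C_comes",
                                   "S_variabile", "R_bromii"))
  prof <- elasticity_profile(comm, fluxes, params, h = 0.1)
  expect_equal(nrow(prof), 12)
  expect_true(all(is.finite(prof$elasticity) | prof$status != "ok"))
  prof2 <- elasticity_profile(comm, fluxes, params, h = 0.1)
  expect_identical(prof, prof2)
})

test_that("pair labels: identical profiles are Same, absences are NA", {
  pair <- generate_elasticity_pair(c("A", "B"), elastic_taxa = character(0),
                                   noise_sd = 0, seed = 2)
  expect_equal(compare_pair_variances(pair$adhd, pair$control, "A")$label,
               "Same")
  # taxon missing from one member's profile
  expect_equal(compare_pair_variances(pair$adhd, pair$control, "Z")$label,
               "NA")
  dropped <- pair$control[pair$control$taxon != "A", ]
  expect_equal(compare_pair_variances(pair$adhd, dropped, "A")$label, "NA")
})

test_that("planted variance inflation is recovered as an ADHD label", {
  pair <- generate_elasticity_pair(c("A", "B", "C"), elastic_taxa = "B",
                                   inflation = 3, noise_sd = 0, seed = 3)
  expect_equal(compare_pair_variances(pair$adhd, pair$control, "B")$label,
               "ADHD")
  expect_equal(compare_pair_variances(pair$adhd, pair$control, "A")$label,
               "Same")
  # reversed orientation labels Control
  expect_equal(compare_pair_variances(pair$control, pair$adhd, "B")$label,
               "Control")
})

test_that("zero planted effect keeps real-pipeline pair comparisons Same", {
  study <- generate_paired_study(2, names(taxon_archetypes()),
                                 effect_spec(noise_sd = 0, seed = 11))
  models <- lapply(taxon_archetypes(), generate_taxon_model, size = 8)
  diet <- generate_diet("western")
  fluxes <- c("EX_acetate_lu", "EX_butyrate_lu", "EX_propionate_lu",
              "EX_formate_lu")
  for (p in unique(study$metadata$pair_id)) {
    sids <- study$metadata$sample_id[study$metadata$pair_id == p]
    profs <- lapply(sids, function(sid) {
      ab <- filter_abundances(study$abundance[sid, ])
      comm <- apply_diet(assemble_community(models[names(ab)], ab), diet)
      elasticity_profile(comm, fluxes,
                         paste0("abundance:", names(ab)), h = 0.1)
    })
    for (tx in c("B_uniformis", "S_variabile", "C_comes")) {
      lab <- compare_pair_variances(profs[[1]], profs[[2]], tx)$label
      expect_true(lab %in% c("Same", "NA"))
    }
  }
})
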