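# Community assembly, abundance filtering, diets, serialization.

test_that("abundance filtering drops sub-cutoff taxa and renormalizes", {
  raw <- c(a = 0.5, b = 0.49995, c = 0.00005)
  out <- filter_abundances(raw, 1e-4)
  expect_named(out, c("a", "b"))
  expect_equal(unname(out), c(0.5 / 0.99995, 0.49995 / 0.99995),
               tolerance = 1e-12)
  # already above cutoff: just rescaled
  expect_equal(unname(filter_abundances(c(a = 2, b = 2))), c(0.5, 0.5))
  # idempotent
  expect_equal(filter_abundances(out), out)
  expect_error(filter_abundances(c(a = 1e-5, b = 2e-5)), "empty community")
})

test_that("a one-taxon community reproduces single-model FBA", {
  mod <- generate_taxon_model(
    taxon_archetype("solo", "glc", c(acetate = 1)), size = 5)
  single <- fba(mod)
  comm <- apply_diet(assemble_community(list(mod), c(solo = 1)),
                     glc_diet(10))
  community <- fba(comm)
  expect_equal(community$community_growth, single$community_growth,
               tolerance = 1e-7)
})

test_that("two copies of one model at equal abundance keep the growth", {
  arch <- taxon_archetype("x", "glc", c(acetate = 0.5))
  m1 <- generate_taxon_model(arch, 5)
  m2 <- m1; m2$taxon <- "y"
  solo <- fba(apply_diet(assemble_community(list(m1), c(x = 1)),
                         glc_diet(10)))
  duo <- fba(apply_diet(assemble_community(list(m1, m2), c(x = .5, y = .5)),
                        glc_diet(10)))
  expect_equal(duo$community_growth, solo$community_growth,
               tolerance = 1e-6)
})

test_that("assembly validates labels and biomass", {
  mod <- generate_taxon_model(taxon_archetype("a", "glc"), 4)
  expect_error(assemble_community(list(mod), c(b = 1)), "match 1:1")
  broken <- mod
  broken$reactions <- Filter(function(r) r$role != "biomass",
                             broken$reactions)
  expect_error(assemble_community(list(broken), c(a = 1)),
               "exactly one biomass")
})

test_that("diets gate community growth through lumen uptake bounds", {
  comm <- healthy_community("western")
  # empty diet: no carbon, no growth
  empty <- comm
  empty$lb[grepl("_lu$", names(empty$lb))] <- 0
  expect_lt(fba(empty)$community_growth, 1e-9)

  # doubling every bound cannot decrease growth
  double <- generate_diet("western")
  double$max_uptake <- 2 * double$max_uptake
  g1 <- fba(comm)$community_growth
  g2 <- fba(apply_diet(comm, double))$community_growth
  expect_gte(g2, g1 - 1e-9)

  # western and vegan move lumen acetate export differently
  ac_w <- lumen_exchange_fluxes(
    cooperative_tradeoff(healthy_community("western")))["acetate"]
  ac_v <- lumen_exchange_fluxes(
    cooperative_tradeoff(healthy_community("vegan")))["acetate"]
  expect_gt(abs(ac_w - ac_v), 1e-3)

  # unmatched diet entries warn but are ignored
  odd <- rbind(generate_diet("western"),
               data.frame(reaction_id = "EX_vitamin_b12(e)",
                          max_uptake = 1, class = "other",
                          energy_density = 0))
  expect_warning(apply_diet(comm, odd), "vitamin_b12")
})

test_that("every optimal solution satisfies steady state to 1e-6", {
  comm <- healthy_community("western")
  for (sol in list(fba(comm), cooperative_tradeoff(comm, 0.7),
                   minimize_intake(comm, 0.1))) {
    expect_equal(sol$status, "optimal")
    expect_lt(sol$residual, 1e-6)
  }
})

test_that("lumen export never exceeds abundance-weighted secretion capacity", {
  comm <- healthy_community("western")
  sol <- cooperative_tradeoff(comm, 0.7)
  le <- lumen_exchange_fluxes(sol)
  for (met in names(le)) {
    if (le[[met]] <= 0) next
    # capacity: sum over taxa of abundance * taxon-exchange upper bound
    ids <- comm$reactions$id[comm$reactions$role == "taxon-exchange" &
                             grepl(paste0("__EX_", met, "$"),
                                   comm$reactions$id)]
    cap <- sum(vapply(ids, function(id) {
      tx <- comm$reactions$taxon[comm$reactions$id == id]
      comm$taxa[[tx]] * comm$ub[[id]]
    }, 0))
    expect_lte(le[[met]], cap + 1e-6)
  }
})

test_that("community JSON round-trips exactly", {
  comm <- healthy_community("western")
  path <- withr::local_tempfile(fileext = ".json")
  write_community(comm, path)
  back <- apply_diet(read_community(path), generate_diet("western"))
  expect_equal(back$S, comm$S)
  expect_equal(back$taxa, comm$taxa)
  expect_equal(back$lb, comm$lb)
  expect_equal(back$ub, comm$ub)
})

test_that("malformed model files are rejected with context", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", path)
  expect_error(read_community(path), "parse")

  # JSON model with no biomass flag
  mod <- generate_taxon_model(taxon_archetype("a", "glc"), 4)
  comm <- assemble_community(list(mod), c(a = 1))
  write_community(comm, path)
  txt <- gsub('"is_biomass":true', '"is_biomass":false', readLines(path))
  writeLines(txt, path)
  expect_error(read_community(path), "is_biomass")
})

test_that("the SBML subset imports species, reactions and bounds", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="toy_bug">',
    '<listOfParameters>',
    '<parameter id="lb_neg10" value="-10"/>',
    '<parameter id="ub_1000" value="1000"/>',
    '</listOfParameters>',
    '<listOfSpecies>',
    '<species id="glc" compartment="c"/>',
    '<species id="bm" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_glc" reversible="true" lowerFluxBound="lb_neg10" upperFluxBound="ub_1000">',
    '<listOfReactants><speciesReference species="glc" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '<reaction id="CONV" reversible="false">',
    '<listOfReactants><speciesReference species="glc" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="bm" stoichiometry="0.1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="biomass_toy" reversible="false">',
    '<listOfReactants><speciesReference species="bm" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '</model>',
    '</sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  mod <- read_sbml_model(path)
  expect_s3_class(mod, "taxon_model")
  expect_equal(mod$taxon, "toy_bug")
  ex <- Filter(function(r) r$id == "EX_glc", mod$reactions)[[1]]
  expect_equal(ex$lb, -10)
  sol <- fba(mod)
  expect_equal(sol$community_growth, 1, tolerance = 1e-6)  # 0.1 * 10

  # unsupported constructs named in the error
  bad <- sub("<listOfReactions>", "<listOfRules/><listOfReactions>",
             paste(sbml, collapse = "\n"))
  writeLines(bad, path)
  expect_error(read_sbml_model(path), "listOfRules")
})

test_that("the packaged synthetic SBML example imports and grows", {
  path <- system.file("extdata", "toy_taxon_synthetic.xml",
                      package = "commfba")
  mod <- read_sbml_model(path)
  sol <- fba(mod)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$community_growth, 0.5, tolerance = 1e-6)  # 0.05 * 10
})
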