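test_that("minFlux finds the acetate cycle with the expected support and net", {
  toy <- build_reference_toy(planted = "acetate_cycle", n_decoys = 5, seed = 3)
  sol <- find_min_flux(toy, conversion_target(), search_config())
  expect_s3_class(sol, "pathway_solution")
  expect_identical(sol$support, c("ack", "acs", "ak", "pta"))
  expect_true(stoich_equal(sol$achieved, qualifying_conversion))
  expect_true(sol$objective == rq(4))
  expect_true(sol$exact)
  expect_true(sol$qualifies)
})

test_that("the Ppdk-malate-shunt cycle runs Ppdk in reverse and transhydrogenates", {
  toy <- build_reference_toy(planted = "ppdk_malate_shunt")
  sol <- find_min_flux(toy, conversion_target(), search_config())
  expect_identical(sol$support, sort(c("ppdk", "pepck", "mdh", "me", "ak", "ndk")))
  expect_true(sol$fluxes["ppdk"] < 0)
  expect_true(stoich_coef(sol$achieved, "nadh") == rq(-1))
  expect_true(stoich_coef(sol$achieved, "nadph") == rq(1))
  expect_true(classify_solution(sol) == rq(1))
})

test_that("a model without PP_i producers is reported infeasible, not an error", {
  toy <- build_reference_toy(planted = "acetate_cycle")
  toy$reactions <- toy$reactions[names(toy$reactions) != "acs"]
  sol <- find_min_flux(toy, conversion_target(), search_config())
  expect_s3_class(sol, "pathway_infeasible")
})

test_that("enumeration recovers all four planted mechanisms, each once, in flux order", {
  toy <- build_reference_toy()
  sols <- enumerate_pathways(toy, conversion_target(),
                             search_config(max_solutions = 10))
  expect_length(sols, 4)
  objs <- vapply(sols, function(s) as.numeric(s$objective), numeric(1))
  expect_identical(objs, c(1.5, 3, 4, 6))
  expect_identical(
    support_keys(sols),
    sort(c("atpase,ppase_mem", "ags,glgA,glgP", "ack,acs,ak,pta",
           "ak,mdh,me,ndk,pepck,ppdk")))
  # k = 1 equals find_min_flux
  one <- enumerate_pathways(toy, conversion_target(), search_config(max_solutions = 1))
  expect_length(one, 1)
  expect_identical(one[[1]]$support,
                   find_min_flux(toy, conversion_target(), search_config())$support)
})

test_that("no enumerated support strictly contains another", {
  toy <- build_reference_toy()
  sols <- enumerate_pathways(toy, conversion_target(),
                             search_config(max_solutions = 10))
  for (i in seq_along(sols)) {
    for (j in seq_along(sols)) {
      if (i == j) next
      expect_false(all(sols[[i]]$support %in% sols[[j]]$support))
    }
  }
})

test_that("enumeration is deterministic", {
  toy <- build_reference_toy(n_decoys = 10, seed = 5)
  a <- enumerate_pathways(toy, conversion_target(), search_config(max_solutions = 10))
  b <- enumerate_pathways(toy, conversion_target(), search_config(max_solutions = 10))
  expect_identical(lapply(a, function(s) s$support),
                   lapply(b, function(s) s$support))
  expect_identical(lapply(a, function(s) as.numeric(s$fluxes)),
                   lapply(b, function(s) as.numeric(s$fluxes)))
})

test_that("classification: qualifying, over-budget and better-than-budget mechanisms", {
  expect_true(classify_solution(qualifying_conversion) == rq(1))
  # direct hydrolysis pseudo-solution costs 2 ATP_eq per PP_i
  dh <- stoich(c("atp", "amp", "ppi"), c(-1, 1, 1))
  expect_true(classify_solution(dh) == rq(2))
  # membrane PPase toy produces 2 PP_i per ATP
  toy <- build_reference_toy(planted = "membrane_ppase")
  sol <- find_min_flux(toy, conversion_target(), search_config())
  expect_identical(sol$support, c("atpase", "ppase_mem"))
  expect_true(classify_solution(sol) == rq(1, 2))
  expect_true(sol$qualifies)
  expect_error(classify_solution(stoich("atp", -1)), "no PP_i")
})

test_that("forbidden-reaction filtering keeps only untouched mechanisms", {
  toy <- build_reference_toy()
  sols <- enumerate_pathways(toy, conversion_target(),
                             search_config(max_solutions = 10))
  filt <- filter_by_reactions(sols, c("ppase_mem", "ags"))
  expect_identical(support_keys(filt),
                   sort(c("ack,acs,ak,pta", "ak,mdh,me,ndk,pepck,ppdk")))
  expect_identical(filter_by_reactions(sols, character()), sols)
  all_ids <- unique(unlist(lapply(sols, function(s) s$support)))
  expect_length(filter_by_reactions(sols, all_ids), 0)
})

test_that("forbidding reactions in the config excludes them from the search", {
  toy <- build_reference_toy()
  sols <- enumerate_pathways(toy, conversion_target(),
                             search_config(max_solutions = 10,
                                           forbidden_reactions = c("ppase_mem", "ags")))
  expect_identical(support_keys(sols),
                   sort(c("ack,acs,ak,pta", "ak,mdh,me,ndk,pepck,ppdk")))
})

test_that("augmented search restores a deleted key enzyme via the pool", {
  toy <- build_reference_toy()
  toy$reactions <- toy$reactions[names(toy$reactions) != "acs"]
  pool <- list(parse_reaction_equation("ac + atp + coa -> accoa + amp + ppi",
                                       "acs", enzyme = "Acetyl-CoA synthetase"))
  cfg <- search_config(max_solutions = 10, augmentation_pool = pool, max_added = 1)
  sols <- augmented_search(toy, pool, conversion_target(), cfg)
  ace <- Filter(function(s) "acs" %in% s$support, sols)
  expect_length(ace, 1)
  expect_identical(ace[[1]]$added_reactions, "acs")
  expect_identical(ace[[1]]$support, c("ack", "acs", "ak", "pta"))
  # solutions not using the pool report no added reactions
  other <- Filter(function(s) !("acs" %in% s$support), sols)
  expect_true(all(vapply(other, function(s) length(s$added_reactions) == 0L,
                         logical(1))))
})

test_that("max_added = 0 reduces the augmented search to plain enumeration", {
  toy <- build_reference_toy(planted = c("membrane_ppase", "glycogen_cycle"))
  pool <- list(parse_reaction_equation("ac + atp + coa -> accoa + amp + ppi", "acs"))
  cfg <- search_config(max_solutions = 10, augmentation_pool = pool, max_added = 0)
  aug <- augmented_search(toy, pool, conversion_target(), cfg)
  base <- enumerate_pathways(toy, conversion_target(), search_config(max_solutions = 10))
  expect_identical(support_keys(aug), support_keys(base))
})

test_that("a cycle needing two pool reactions stays infeasible under max_added = 1", {
  toy <- build_reference_toy(planted = "glycogen_cycle")
  # remove two of the three glycogen-cycle steps; both sit in the pool
  toy$reactions <- toy$reactions[!names(toy$reactions) %in% c("glgA", "glgP")]
  pool <- list(parse_reaction_equation("adpg -> glyc + adp", "glgA"),
               parse_reaction_equation("glyc + pi -> g1p", "glgP"))
  cfg <- search_config(max_solutions = 10, augmentation_pool = pool, max_added = 1)
  expect_length(augmented_search(toy, pool, conversion_target(), cfg), 0)
  cfg2 <- search_config(max_solutions = 10, augmentation_pool = pool, max_added = 2)
  sols <- augmented_search(toy, pool, conversion_target(), cfg2)
  expect_length(sols, 1)
  expect_identical(sort(sols[[1]]$added_reactions), c("glgA", "glgP"))
})

test_that("brute-force oracle agrees with enumeration on a small fixture", {
  toy <- build_reference_toy(planted = c("glycogen_cycle", "acetate_cycle"))
  orc <- brute_force_oracle(toy, conversion_target(), max_support_size = 4)
  sols <- enumerate_pathways(toy, conversion_target(), search_config(max_solutions = 10))
  expect_identical(sort(vapply(orc, paste, character(1), collapse = ",")),
                   support_keys(sols))
})

test_that("oracle edge cases: empty model, single-reaction target, guard", {
  empty <- metabolic_model(fx$metabolites, list())
  expect_length(brute_force_oracle(empty, conversion_target()), 0)
  single <- metabolic_model(
    fx$metabolites,
    list(parse_reaction_equation("atp + pi -> adp + ppi", "direct")))
  orc <- brute_force_oracle(single, conversion_target(), max_support_size = 1)
  expect_identical(orc, list("direct"))
  big <- build_reference_toy(n_decoys = 50, seed = 1)
  expect_error(brute_force_oracle(big, conversion_target(), max_support_size = 20),
               "guard")
})

test_that("strict targets pin the exchange exactly and reject the 2:1 PPase mechanism", {
  toy <- build_reference_toy()
  strict <- conversion_target(strict = TRUE)
  sols <- enumerate_pathways(toy, strict, search_config(max_solutions = 10))
  keys <- support_keys(sols)
  expect_false("atpase,ppase_mem" %in% keys)
  # every strict solution hits the pinned exchange exactly (co-conversion
  # pairs like NADH/NAD+ may still appear)
  for (s in sols) {
    for (m in c("atp", "pi", "adp", "ppi")) {
      expect_true(stoich_coef(s$achieved, m) ==
                    stoich_coef(qualifying_conversion, m))
    }
  }
})

test_that("solutions are verified by exact substitution of rational fluxes", {
  toy <- build_reference_toy()
  sols <- enumerate_pathways(toy, conversion_target(), search_config(max_solutions = 10))
  for (s in sols) {
    expect_true(s$exact)
    recomputed <- combine(toy$reactions[s$support], s$fluxes[s$support])
    expect_true(stoich_equal(recomputed, s$achieved))
    # every support member carries truly nonzero flux
    expect_true(all(abs(as.numeric(s$fluxes)) > 1e-7))
  }
})
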