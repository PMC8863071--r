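test_that("reaction equations parse with signed coefficients", {
  r <- parse_reaction_equation("atp + pi -> adp + ppi", "t1")
  expect_true(stoich_equal(r$stoich, qualifying_conversion))
  expect_false(r$reversible)

  ags <- parse_reaction_equation("g1p + atp -> adpg + ppi", "ags")
  expect_true(stoich_equal(ags$stoich,
                           stoich(c("g1p", "atp", "adpg", "ppi"), c(-1, -1, 1, 1))))

  rev <- parse_reaction_equation("a + 2 b <-> 3/2 c", "t2", reversible = FALSE)
  expect_true(rev$reversible)  # <-> overrides the flag
  expect_true(stoich_coef(rev$stoich, "c") == rq(3, 2))
  expect_true(stoich_coef(rev$stoich, "b") == rq(-2))
})

test_that("degenerate and malformed equations are rejected with the offending token", {
  expect_error(parse_reaction_equation("a -> a", "bad"), "net-empty")
  expect_error(parse_reaction_equation("a + -> b", "bad"), "empty term")
  expect_error(parse_reaction_equation("a -> b -> c", "bad"), "exactly one")
  expect_error(parse_reaction_equation("2 3 a -> b", "bad"), "malformed term")
  expect_error(parse_reaction_equation("a -> 3", "bad"), "metabolite id")
  expect_error(parse_reaction_equation("1x a -> b", "bad"), "malformed coefficient")
})

test_that("same metabolite on both sides keeps the net coefficient", {
  r <- parse_reaction_equation("2 a + b -> a + c", "net")
  expect_true(stoich_coef(r$stoich, "a") == rq(-1))
})

test_that("parse -> format -> parse round-trips the stoichiometry", {
  eqs <- c("atp + pi -> adp + ppi",
           "pep + amp + ppi <-> pyr + atp + pi",
           "cb + h2o -> 2 glc",
           "3/2 a + 1/2 b -> c")
  for (eq in eqs) {
    r <- parse_reaction_equation(eq, "rt")
    txt <- format_reaction_equation(r$stoich, r$reversible)
    r2 <- parse_reaction_equation(txt, "rt")
    expect_true(stoich_equal(r$stoich, r2$stoich))
  }
})

test_that("combine composes lumped reactions with exact cancellation", {
  # acetate cycle: Pta + Ack + Acs + adenylate kinase (run in reverse)
  pta <- parse_reaction_equation("accoa + pi <-> acp + coa", "pta")
  ack <- parse_reaction_equation("acp + adp <-> ac + atp", "ack")
  acs <- parse_reaction_equation("ac + atp + coa -> accoa + amp + ppi", "acs")
  ak <- parse_reaction_equation("2 adp <-> atp + amp", "ak")
  net <- combine(list(pta, ack, acs, ak), c(1, 1, 1, -1))
  expect_true(stoich_equal(net, qualifying_conversion))

  expect_length(combine(list()), 0)

  # glycogen cycle nets the same conversion
  ags <- parse_reaction_equation("g1p + atp -> adpg + ppi", "ags")
  glgA <- parse_reaction_equation("adpg -> glyc + adp", "glgA")
  glgP <- parse_reaction_equation("glyc + pi -> g1p", "glgP")
  expect_true(stoich_equal(combine(list(ags, glgA, glgP)), qualifying_conversion))
})

test_that("running an irreversible reaction backwards is an error, not a flip", {
  acs <- parse_reaction_equation("ac + atp + coa -> accoa + amp + ppi", "acs")
  expect_error(combine(list(acs), -1), "irreversible")
})

test_that("combine(r, 1) round-trips the parser output", {
  set.seed(4)
  mets <- letters[1:6]
  for (i in 1:25) {
    lhs <- sample(mets, 2)
    rhs <- setdiff(mets, lhs)[1:2]
    cl <- sample(1:3, 2, replace = TRUE)
    cr <- sample(1:3, 2, replace = TRUE)
    eq <- paste(paste(cl, lhs, collapse = " + "), "->",
                paste(cr, rhs, collapse = " + "))
    r <- parse_reaction_equation(eq, "p")
    expect_true(stoich_equal(combine(list(r), 1), r$stoich))
  }
})

test_that("energy-equivalent folding matches hand-derived nets and is idempotent", {
  # 4x Ppdk forward: net 8 ADP_eq phosphorylated to 8 ATP_eq
  ppdk4 <- stoich(c("pep", "amp", "ppi", "pyr", "atp", "pi"),
                  c(-4, -4, -4, 4, 4, 4))
  f <- fold_energy_equivalents(ppdk4)
  expect_true(stoich_coef(f, "adp_eq") == rq(-8))
  expect_true(stoich_coef(f, "atp_eq") == rq(8))

  # direct hydrolysis ATP -> AMP + PPi costs 2 ATP_eq after AK balancing
  dh <- fold_energy_equivalents(stoich(c("atp", "amp", "ppi"), c(-1, 1, 1)))
  expect_true(stoich_equal(dh, stoich(c("atp_eq", "adp_eq", "ppi"), c(-2, 2, 1))))

  # ADP-only map is unchanged apart from the renaming
  adp_only <- stoich(c("adp", "x"), c(-3, 1))
  f2 <- fold_energy_equivalents(adp_only)
  expect_true(stoich_coef(f2, "adp_eq") == rq(-3))
  expect_true(stoich_equal(fold_energy_equivalents(f2), f2))
})

test_that("folding conserves the high-energy phosphoanhydride bond count", {
  set.seed(9)
  ids <- c("atp", "adp", "amp", "gtp", "gdp", "ppi", "pi", "x")
  for (i in 1:30) {
    co <- sample(-4:4, length(ids), replace = TRUE)
    keep <- co != 0
    if (!any(keep)) next
    s <- stoich(ids[keep], co[keep])
    f <- fold_energy_equivalents(s)
    expect_true(phosphoanhydride_count(s) == phosphoanhydride_count(f))
    expect_true(stoich_equal(fold_energy_equivalents(f), f))
  }
})

test_that("elemental balance checks use declared atom counts", {
  mets <- fx$metabolites
  eq1 <- stoich(c("cb", "ppi", "adp_eq", "nad", "pyr", "atp_eq", "pi", "nadh", "h"),
                c(-1, -6, -10, -4, 4, 10, 2, 4, 4))
  expect_true(check_balance(eq1, "phosphorus", mets))
  expect_true(check_balance(eq1, "carbon", mets))
  expect_false(check_balance(stoich(c("atp", "adp"), c(-1, 1)), "phosphorus", mets))
  expect_true(check_balance(stoich(), "phosphorus", mets))
  expect_error(check_balance(stoich("mystery", 1), "phosphorus", mets), "mystery")
})

test_that("model registry enforces unique ids and registered metabolites", {
  mets <- metabolite_table(c("a", "b"))
  r1 <- parse_reaction_equation("a -> b", "r1")
  expect_error(metabolic_model(mets, list(r1, r1)), "duplicate reaction ids")
  r2 <- parse_reaction_equation("a -> zz", "r2")
  expect_error(metabolic_model(mets, list(r2)), "unregistered")
  m <- metabolic_model(mets, list(r1))
  expect_s3_class(m, "metabolic_model")
})

test_that("reaction and metabolite tables round-trip through files", {
  toy <- build_reference_toy(planted = "acetate_cycle")
  rx_path <- tempfile(fileext = ".tsv")
  met_path <- tempfile(fileext = ".tsv")
  write_reaction_table(toy$reactions, rx_path)
  write_metabolite_table(toy$metabolites, met_path)
  rx2 <- read_reaction_table(rx_path)
  mets2 <- read_metabolite_table(met_path)
  expect_identical(names(rx2), names(toy$reactions))
  for (id in names(rx2)) {
    expect_true(stoich_equal(rx2[[id]]$stoich, toy$reactions[[id]]$stoich))
    expect_identical(rx2[[id]]$reversible, toy$reactions[[id]]$reversible)
  }
  expect_identical(mets2$id, toy$metabolites$id)
  expect_identical(mets2$P, toy$metabolites$P)
})
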