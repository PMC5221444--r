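reg <- std_reactions()
t4cond <- digester_conditions()

test_that("registry reactions return dG0' exactly at unit activities and pH 7", {
  unit <- conditions(activities = c(propionate = 1, acetate = 1,
                                    `HCO3-` = 1, H2 = 1, CH4 = 1), pH = 7)
  for (r in reg)
    expect_equal(delta_g_prime(r, unit), r$dg0_prime)
})

test_that("published free-energy cells are reproduced", {
  expect_equal(
    delta_g_prime(reg$hydrogenotrophic_methanogenesis,
                  digester_conditions(ph2 = 1e-4)), -32, tolerance = 1 / 32)
  expect_equal(
    delta_g_prime(reg$propionate_oxidation,
                  digester_conditions(ph2 = 1e-1)), 48, tolerance = 1 / 48)
})

test_that("delta_g_prime matches a term-by-term oracle on random inputs", {
  set.seed(42)
  for (i in 1:30) {
    r <- random_reaction()
    cond <- random_conditions()
    expect_equal(delta_g_prime(r, cond), oracle_delta_g(r, cond))
  }
})

test_that("delta_g_prime validates its inputs", {
  r <- reaction("bad", c(unobtainium = -1, H2 = 1), 10)
  expect_error(delta_g_prime(r, t4cond), "unobtainium")
  expect_error(conditions(activities = c(H2 = -1)), "positive")
  expect_error(conditions(activities = c(`H+` = 1e-7)), "pH")
})

test_that("combining propionate oxidation with 0.75 x hydrogenotrophic methanogenesis gives the coculture equation", {
  comb <- combine_reactions(
    list(reg$propionate_oxidation, reg$hydrogenotrophic_methanogenesis),
    c(1, 0.75))
  want <- c(propionate = -1, H2O = -0.75, acetate = 1, CH4 = 0.75,
            `HCO3-` = 0.25, `H+` = 0.25)
  expect_equal(comb$stoichiometry[order(names(comb$stoichiometry))],
               want[order(names(want))])
})

test_that("a reaction combined with its negation cancels exactly", {
  comb <- combine_reactions(list(reg$sao, reg$sao), c(1, -1))
  expect_length(comb$stoichiometry, 0)
  expect_equal(comb$dg0_prime, 0)
  expect_error(combine_reactions(list(), numeric()), "non-empty")
})

test_that("acetate oxidation plus hydrogenotrophic methanogenesis equals acetoclastic methanogenesis", {
  comb <- combine_reactions(
    list(reg$sao, reg$hydrogenotrophic_methanogenesis), c(1, 1))
  am <- reg$acetoclastic_methanogenesis
  expect_equal(comb$stoichiometry[order(names(comb$stoichiometry))],
               am$stoichiometry[order(names(am$stoichiometry))])
  expect_equal(comb$dg0_prime, 104.6 - 135.6)
  # and the identity carries to arbitrary conditions
  set.seed(7)
  for (i in 1:5) {
    cond <- random_conditions()
    expect_equal(delta_g_prime(comb, cond), delta_g_prime(am, cond))
  }
})

test_that("free energies are additive under reaction combination", {
  set.seed(99)
  for (i in 1:10) {
    r1 <- random_reaction(); r2 <- random_reaction()
    m <- runif(2, -2, 2)
    cond <- random_conditions()
    comb <- combine_reactions(list(r1, r2), m)
    expect_equal(delta_g_prime(comb, cond),
                 m[1] * delta_g_prime(r1, cond) +
                   m[2] * delta_g_prime(r2, cond))
  }
})

test_that("homoacetogenesis is the antisymmetric image of acetate oxidation", {
  set.seed(3)
  for (i in 1:8) {
    cond <- random_conditions()
    expect_equal(delta_g_prime(reg$aha, cond),
                 -delta_g_prime(reg$sao, cond))
  }
})

test_that("a tenfold pH2 change shifts dG' by nu * RT * ln 10", {
  RT <- 8.314e-3 * 310.15
  for (rn in c("propionate_oxidation", "hydrogenotrophic_methanogenesis",
               "sao", "aha")) {
    r <- reg[[rn]]
    nu <- r$stoichiometry[["H2"]]
    d <- delta_g_prime(r, digester_conditions(ph2 = 1e-3)) -
      delta_g_prime(r, digester_conditions(ph2 = 1e-4))
    expect_equal(d, nu * RT * log(10))
    # monotone in pH2 with the sign of nu
    sweep <- vapply(10^seq(-7, -1), function(p)
      delta_g_prime(r, digester_conditions(ph2 = p)), 0)
    expect_true(all(sign(diff(sweep)) == sign(nu)))
  }
})

test_that("acetoclastic methanogenesis is independent of pH2", {
  vals <- vapply(10^seq(-7, -1), function(p)
    delta_g_prime(reg$acetoclastic_methanogenesis,
                  digester_conditions(ph2 = p)), 0)
  expect_equal(diff(range(vals)), 0)
})

test_that("the acetate-oxidation crossover sits near 5e-5 atm", {
  x <- h2_crossover(reg$sao, t4cond)
  expect_equal(x, 5e-5, tolerance = 0.10)
  # the crossover is a genuine root
  expect_equal(delta_g_prime(reg$sao, digester_conditions(ph2 = x)), 0,
               tolerance = 1e-9)
})

test_that("crossover agrees with a bracketing root search and the table signs", {
  x <- h2_crossover(reg$hydrogenotrophic_methanogenesis, t4cond)
  expect_equal(x, 4.6e-6, tolerance = 0.02)
  # sign change bracket printed in the sweep: positive at 1e-6, negative at 1e-5
  expect_gt(delta_g_prime(reg$hydrogenotrophic_methanogenesis,
                          digester_conditions(ph2 = 1e-6)), 0)
  expect_lt(delta_g_prime(reg$hydrogenotrophic_methanogenesis,
                          digester_conditions(ph2 = 1e-5)), 0)
  # independent bisection oracle
  f <- function(p) delta_g_prime(reg$hydrogenotrophic_methanogenesis,
                                 digester_conditions(ph2 = p))
  root <- uniroot(f, c(1e-8, 1e-2), tol = 1e-12)$root
  expect_equal(x, root, tolerance = 1e-6)
})

test_that("crossover requires a hydrogen term", {
  expect_error(h2_crossover(reg$acetoclastic_methanogenesis, t4cond),
               "no H2")
})

test_that("free_energy_table preserves row order and reaction antisymmetry", {
  ph2 <- c(1e-1, 1e-2, 1e-3, 1e-4, 5e-5, 1e-5, 1e-6, 1e-7)
  ft <- free_energy_table(reg, t4cond, ph2)
  expect_identical(dim(unclass(ft)), c(8L, 5L))
  expect_identical(attr(ft, "ph2"), ph2)
  expect_equal(unname(unclass(ft)[, "sao"]), -unname(unclass(ft)[, "aha"]))
  # balanced row: methanogenesis pathways equal, acetate oxidation at zero
  row <- unclass(ft)["5e-05", ]
  expect_equal(unname(row["hydrogenotrophic_methanogenesis"]), -25,
               tolerance = 1 / 25)
  expect_equal(unname(row["acetoclastic_methanogenesis"]), -25,
               tolerance = 1 / 25)
  expect_lt(abs(row["sao"]), 1)
})

test_that("the syntrophic window brackets the feasible pH2 range", {
  w <- h2_window(reg$propionate_oxidation,
                 reg$hydrogenotrophic_methanogenesis, t4cond)
  expect_false(w$empty)
  expect_equal(w$lower, 4.6e-6, tolerance = 0.02)
  expect_equal(w$upper, 2.0e-4, tolerance = 0.02)
  expect_true(w$lower < 1e-5 && 1e-4 < w$upper)
  expect_true(1e-6 < w$lower && w$upper < 1e-3)
  expect_error(h2_window(reg$hydrogenotrophic_methanogenesis, reg$sao,
                         t4cond), "positive H2")
})

test_that("reaction sets round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_reactions(reg, path)
  back <- read_reactions(path)
  expect_identical(names(back), names(reg))
  for (nm in names(reg)) {
    expect_equal(back[[nm]]$stoichiometry, reg[[nm]]$stoichiometry)
    expect_equal(back[[nm]]$dg0_prime, reg[[nm]]$dg0_prime)
  }
})
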