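test_that("pKa temperature correction behaves at the reference point and limits", {
  cps <- acid_base_couples()
  # van 't Hoff couples return the reference value exactly at 25 C
  for (nm in c("sulfate", "acetate", "ammonium", "fluoride")) {
    expect_equal(pKa_at_temperature(cps[[nm]], 25), cps[[nm]]$pKa_25)
  }
  # zero enthalpy proxy: no temperature dependence
  flat <- cps$acetate; flat$dH <- 0
  expect_equal(pKa_at_temperature(flat, 5), flat$pKa_25)
  expect_equal(pKa_at_temperature(flat, 95), flat$pKa_25)
  # the empirical carbonate polynomial against published tabulations
  expect_equal(pKa_at_temperature(cps$carbonate_1, 25), 6.35, tolerance = 0.005)
  expect_true(abs(pKa_at_temperature(cps$carbonate_1, 12.6) - 6.43) < 0.02)
  expect_true(abs(pKa_at_temperature(cps$carbonate_1, 35) - 6.31) < 0.02)
  expect_equal(pKa_at_temperature(cps$carbonate_2, 25), 10.33,
               tolerance = 0.005)
  expect_error(pKa_at_temperature(cps$acetate, 120), "0-100")
  # exothermic bisulfate dissociation: pKa rises with temperature
  expect_gt(pKa_at_temperature(cps$sulfate, 37.2), cps$sulfate$pKa_25)
})

test_that("ionic strength is the half sum of m z^2", {
  expect_equal(ionic_strength(numeric(0), integer(0)), 0)
  expect_equal(ionic_strength(c(0.01, 0.01), c(1, -1)), 0.01)
  # a 2:1 electrolyte at 4.2 mM: I = (2*4.2e-3 + 4.2e-3*4) / 2
  expect_equal(ionic_strength(c(2 * 4.2e-3, 4.2e-3), c(1, -2)),
               0.5 * (2 * 4.2e-3 + 4.2e-3 * 4))
})

test_that("extended Debye-Huckel activity coefficients match tabulated behaviour", {
  expect_equal(activity_coefficient(1, 0, 25), 1)
  expect_equal(activity_coefficient(-2, 0, 25), 1)
  expect_equal(activity_coefficient(0, 0.5, 25), 1)
  # Na+ at I = 0.005, 25 C: classic tabulations give ~0.925-0.93
  g_na <- activity_coefficient(1, 0.005, 25, ion_size = 4)
  expect_true(g_na > 0.92 && g_na < 0.935)
  # gamma -> 1 as I -> 0
  for (z in 1:3) {
    gs <- vapply(c(1e-2, 1e-4, 1e-6, 1e-10), function(I)
      activity_coefficient(z, I, 25), numeric(1))
    expect_true(all(diff(gs) > 0))
    expect_equal(gs[4], 1, tolerance = 1e-3)
  }
  # gamma decreases with |z| at fixed I
  gs_z <- vapply(1:3, function(z) activity_coefficient(z, 0.01, 25, 4),
                 numeric(1))
  expect_true(all(diff(gs_z) < 0))
  # 25 C solvent coefficients near their textbook values
  AB <- debye_huckel_AB(25)
  expect_equal(AB[["A"]], 0.51, tolerance = 0.005)
  expect_equal(AB[["B"]], 0.33, tolerance = 0.005)
})

test_that("protonated fraction follows the Henderson-Hasselbalch relation", {
  expect_equal(fraction_protonated(4.756, 4.756), 0.5)
  # acetic acid at pH 5.6: an eighth of the pool stays protonated
  expect_equal(fraction_protonated(5.6, 4.756), 0.1253, tolerance = 1e-3)
  # spring-water acetate at pH 3.76 is mostly acid
  expect_equal(fraction_protonated(3.76, 4.756), 0.908, tolerance = 1e-3)
  # strictly decreasing in pH
  f <- fraction_protonated(seq(2, 9, by = 0.25), 4.756)
  expect_true(all(diff(f) < 0))
  # activity-corrected variant shifts the ratio by gamma_acid/gamma_base
  expect_equal(fraction_protonated(5, 5, gamma_acid = 1, gamma_base = 0.9),
               1 / (1 + 1 / 0.9))
})

test_that("speciate conserves mass and normalises fractions", {
  waters <- spring_waters()
  for (w in waters) {
    sp <- speciate(w, pH = if (is.na(w$field_pH)) 4 else w$field_pH)
    tab <- sp$species[sp$species$component != "water", ]
    for (comp in unique(tab$component)) {
      tot <- w$totals[[comp]]
      if (tot == 0) next
      rows <- tab[tab$component == comp, ]
      expect_equal(sum(rows$molality), tot, tolerance = 1e-12)
      expect_equal(sum(rows$fraction), 1, tolerance = 1e-9)
    }
    expect_gte(sp$ionic_strength, 0)
  }
})

test_that("speciation limits behave: CO2 at acidic pH, sulfate at high pH", {
  amp <- spring_waters()$Amphitheater_2017
  sp <- speciate(amp, pH = 3.77)
  f_co2 <- sp$species$fraction[sp$species$species == "CO2(aq)"]
  expect_equal(f_co2, 0.997, tolerance = 1e-3)
  # far above the bisulfate pKa, sulfate is entirely the divalent anion
  sp6 <- speciate(amp, pH = 6.5)
  f_so4 <- sp6$species$fraction[sp6$species$species == "SO4-2"]
  expect_gt(f_so4, 0.999)
  # ideal-solution Henderson-Hasselbalch puts bisulfate near 10% of total
  # sulfate at the Hot Spring Basin field pH
  expect_equal(fraction_protonated(2.95, 1.99), 0.0988, tolerance = 1e-3)
})

test_that("speciate agrees with a brute-force mass-action root-find", {
  totals <- c(Na = 2e-3, acetate = 1e-3, SO4 = 1.5e-3)
  pH <- 4.2; TC <- 30
  w <- water_composition(totals, temperature_C = TC)
  sp <- speciate(w, pH = pH)
  oracle <- oracle_toy_speciation(totals, pH, TC)
  expect_equal(sp$ionic_strength, oracle$I, tolerance = 1e-8)
  get_m <- function(s) sp$species$molality[sp$species$species == s]
  # oracle orders species (acid, base) per component after H+/OH-/Na+
  expect_equal(get_m("CH3COOH"), oracle$m[[4]], tolerance = 1e-8)
  expect_equal(get_m("CH3COO-"), oracle$m[[5]], tolerance = 1e-8)
  expect_equal(get_m("HSO4-"), oracle$m[[6]], tolerance = 1e-8)
  expect_equal(get_m("SO4-2"), oracle$m[[7]], tolerance = 1e-8)
})

test_that("charge imbalance is percent of mean charge", {
  # exactly balanced toy solution at neutral-ish pH
  bal <- water_composition(c(Na = 1e-3, Cl = 1e-3), temperature_C = 25)
  expect_lt(abs(charge_imbalance(speciate(bal, pH = 7))), 0.01)
  # 1 mM Na+ against 0.5 mM Cl-: (1 - 0.5) / 0.75 = +66.7%
  tox <- water_composition(c(Na = 1e-3, Cl = 5e-4), temperature_C = 25)
  expect_equal(charge_imbalance(speciate(tox, pH = 7)), 100 * 0.5 / 0.75,
               tolerance = 1e-2)
})

test_that("charge-balance pH solver closes the loop", {
  # strong-acid limit: 1 mM Cl- alone needs ~1 mM H+, i.e. pH ~ 3
  hcl <- water_composition(c(Cl = 1e-3), temperature_C = 25)
  ph <- solve_ph_charge_balance(hcl)
  expect_equal(as.numeric(ph), 3.0, tolerance = 0.03)
  # round trip: re-speciating at the solved pH balances to < 1e-4 %
  for (w in spring_waters()) {
    ph_cb <- solve_ph_charge_balance(w)
    expect_lt(abs(charge_imbalance(speciate(w, pH = as.numeric(ph_cb)))),
              1e-4)
  }
  # pure water balances at the neutral point of Kw(T)
  pure <- water_composition(c(Na = 0), temperature_C = 25)
  expect_equal(as.numeric(solve_ph_charge_balance(pure)), 13.996 / 2,
               tolerance = 0.01)
})

test_that("perturbed acidic-spring compositions keep solving to acidic pH", {
  hsb <- spring_waters()$Hot_Spring_Basin
  for (s in 1:25) {
    w <- simulate_water(hsb, perturbation = 0.1, seed = s)
    ph <- as.numeric(solve_ph_charge_balance(w))
    expect_true(ph > 1 && ph < 4)
  }
  # zero perturbation returns the template unchanged
  expect_identical(simulate_water(hsb, 0, seed = 1), hsb)
})

test_that("water composition constructor enforces invariants", {
  expect_error(water_composition(c(Na = -1e-3), 25), ">= 0")
  expect_error(water_composition(c(Xx = 1e-3), 25), "unknown components")
  expect_error(water_composition(c(Na = 1e-3), 150), "0-100")
  expect_error(speciate(water_composition(c(Na = 1e-3), 25)), "pH")
})
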