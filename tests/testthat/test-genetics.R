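# Genotype enumeration, gamete distributions, and the SEM transform.

test_that("genotype enumeration is complete, canonical, and stable", {
  spec <- design_spec("CIS_AUTO", "SIMPLIFIED")
  f <- enumerate_genotypes(spec, "female")
  expect_length(f, 10)             # 4 alleles -> 4*5/2 unordered pairs
  expect_identical(f, enumerate_genotypes(spec, "female"))
  expect_false(anyDuplicated(f) > 0)
  expect_true(all(c("GW", "WW", "HH", "VW") %in% f))

  sx <- design_spec("CIS_X", "SIMPLIFIED")
  m <- enumerate_genotypes(sx, "male")
  expect_identical(m, c("GY", "HY", "VY", "WY"))  # hemizygous: allele + Y

  tt <- design_spec("TRANS_AUTO_AUTO", "SIMPLIFIED")
  expect_length(enumerate_genotypes(tt, "female"), 30)  # 10 x 3 sem pairs

  # alphabet grows with flavor and sem_resistance
  expect_length(enumerate_genotypes(
    design_spec("CIS_AUTO", "REDUCED"), "female"), 15)     # 5 alleles
  expect_length(enumerate_genotypes(
    design_spec("CIS_AUTO", "COMPLETE", sem_resistance = TRUE),
    "female"), 28)                                          # 7 alleles

  # offspring index adds the lethal token for SIMPLIFIED only
  expect_length(enumerate_genotypes(spec, "female", offspring = TRUE), 15)
  expect_length(enumerate_genotypes(
    design_spec("CIS_AUTO", "REDUCED"), "female", offspring = TRUE), 15)
})

test_that("invalid design configuration is rejected with the field named", {
  expect_error(design_spec("NOPE"), "design_id")
  expect_error(design_spec("CIS_AUTO", "WRONG"), "flavor")
  expect_error(drive_params(1.2, 0.5), "p")
  expect_error(sem_params(0.5, -0.1, 0.5), "b")
  spec <- design_spec("CIS_AUTO", "SIMPLIFIED")
  expect_error(drive_gamete_dist("ZZ", drive_params(0.5, 1), spec),
               "domain error")
})

test_that("homing gamete distributions match the repair-tree arithmetic", {
  spec <- design_spec("CIS_AUTO", "SIMPLIFIED")
  # cleavage 50%, HR 100%: cleaved (0.5) -> GG -> all G; else 1/2 G 1/2 W
  d <- drive_gamete_dist("GW", drive_params(0.5, 1), spec)
  expect_equal(d, c(G = 0.75, W = 0.25))
  # no drive allele present: Mendelian
  expect_equal(drive_gamete_dist("WW", drive_params(0.9, 0.2), spec),
               c(W = 1))
  # full cleavage, all NHEJ: half drive, half lethal token
  expect_equal(drive_gamete_dist("GW", drive_params(1, 0), spec),
               c(B0 = 0.5, G = 0.5))
  # REDUCED routes NHEJ to R, COMPLETE splits by rho
  expect_equal(
    drive_gamete_dist("GW", drive_params(1, 0),
                      design_spec("CIS_AUTO", "REDUCED")),
    c(G = 0.5, R = 0.5))
  dC <- drive_gamete_dist("GW", drive_params(1, 0, rho = 0.25),
                          design_spec("CIS_AUTO", "COMPLETE"))
  expect_equal(dC, c(B = 0.5 * 0.75, G = 0.5, R = 0.5 * 0.25))
  # V and R are cut-resistant: no homing against them
  expect_equal(drive_gamete_dist("VW", drive_params(1, 1), spec),
               c(V = 0.5, W = 0.5))
})

test_that("inducible drive homes only when the molecule is present", {
  spec <- design_spec("CIS_AUTO", "SIMPLIFIED", inducible_drive = TRUE,
                      inducible_sem = FALSE)
  dp <- drive_params(0.5, 1)
  expect_equal(drive_gamete_dist("GW", dp, spec, molecule_present = FALSE),
               c(G = 0.5, W = 0.5))
  expect_equal(drive_gamete_dist("GW", dp, spec, molecule_present = TRUE),
               c(G = 0.75, W = 0.25))
})

test_that("SEM transform activates, resolves, and gates correctly", {
  spec <- design_spec("CIS_AUTO", "SIMPLIFIED", inducible_sem = TRUE)
  sp <- sem_params(0.5, 1, 1)
  # activation: G -> H at rate a
  expect_equal(sem_transform(c(G = 1), "GG", sp, spec,
                             molecule_present = TRUE),
               c(G = 0.5, H = 0.5))
  # parental H resolves by SSA: b*c to V
  expect_equal(sem_transform(c(H = 1), "HH", sp, spec,
                             molecule_present = TRUE), c(V = 1))
  # b(1-c) to susceptible W; 1-b stays H without sem_resistance
  expect_equal(sem_transform(c(H = 1), "HH", sem_params(0, 0.5, 0.25),
                             spec, TRUE),
               c(H = 0.5, V = 0.125, W = 0.375))
  # ... or becomes S with sem_resistance
  specS <- design_spec("CIS_AUTO", "SIMPLIFIED", sem_resistance = TRUE)
  expect_equal(sem_transform(c(H = 1), "HH", sem_params(0, 0.5, 1),
                             specS, TRUE),
               c(S = 0.5, V = 0.5))
  # identity when uninduced
  d <- c(G = 0.5, W = 0.5)
  expect_identical(sem_transform(d, "GW", sp, spec,
                                 molecule_present = FALSE), d)
  # trans design: no E element in the parent -> identity
  tspec <- design_spec("TRANS_AUTO_AUTO", "SIMPLIFIED")
  d2 <- drive_gamete_dist("GG:ww", drive_params(0.5, 1), tspec)
  expect_identical(sem_transform(d2, "GG:ww", sp, tspec, TRUE), d2)
  d3 <- drive_gamete_dist("GG:Ew", drive_params(0.5, 1), tspec)
  out3 <- sem_transform(d3, "GG:Ew", sp, tspec, TRUE)
  expect_equal(sum(grepl("^H", names(out3)) * out3), 0.5)
})

test_that("gamete distributions conserve mass across random parameters", {
  set.seed(401)
  for (d in ALL_DESIGNS) for (f in ALL_FLAVORS) {
    spec <- design_spec(d, f, sem_resistance = runif(1) < 0.5)
    dp <- drive_params(runif(1), runif(1), runif(1))
    sp <- sem_params(runif(1), runif(1), runif(1))
    for (sex in c("female", "male")) {
      gs <- enumerate_genotypes(spec, sex)
      for (g in sample(gs, min(5, length(gs)))) {
        gd <- drive_gamete_dist(g, dp, spec, molecule_present = TRUE)
        expect_lt(abs(sum(gd) - 1), 1e-12)
        st <- sem_transform(gd, g, sp, spec, molecule_present = TRUE)
        expect_lt(abs(sum(st) - 1), 1e-12)
        expect_true(all(st >= 0))
      }
    }
  }
})

test_that("analytic gametes match the Monte-Carlo branching-tree oracle", {
  set.seed(402)
  n <- 2e5
  for (d in ALL_DESIGNS) {
    spec <- design_spec(d, sample(ALL_FLAVORS, 1),
                        sem_resistance = runif(1) < 0.5)
    dp <- drive_params(runif(1), runif(1), runif(1))
    sp <- sem_params(runif(1), runif(1), runif(1))
    for (sex in c("female", "male")) {
      gs <- enumerate_genotypes(spec, sex)
      for (g in sample(gs, 2)) {
        analytic <- sem_transform(
          drive_gamete_dist(g, dp, spec, TRUE), g, sp, spec,
          molecule_present = TRUE)
        mc <- mc_gamete_oracle(g, dp, sp, spec, molecule = TRUE, n = n)
        expect_oracle_match(analytic, mc, n)
      }
    }
  }
})

test_that("expected drive share from a G/W parent is monotone in p and q", {
  spec <- design_spec("CIS_AUTO", "SIMPLIFIED")
  grid <- seq(0, 1, by = 0.2)
  share <- function(p, q) {
    d <- drive_gamete_dist("GW", drive_params(p, q), spec)
    if ("G" %in% names(d)) d[["G"]] else 0
  }
  for (q in grid) {
    s <- vapply(grid, share, 0, q = q)
    expect_true(all(diff(s) >= -1e-12))
  }
  for (p in grid) {
    s <- vapply(grid, function(q) share(p, q), 0)
    expect_true(all(diff(s) >= -1e-12))
  }
})
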