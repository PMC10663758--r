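test_that("fraction validation enforces range and sum-to-one", {
  expect_true(validate_fractions(c(0.5, 0.3, 0.2), "ok"))
  expect_true(validate_fractions(c(1, 0, 0), "boundary"))
  rep <- validate_fractions(c(0.5, 0.5, 0.5), "bad", stop_on_error = FALSE)
  expect_s3_class(rep, "fraction_violation")
  expect_match(rep$problems, "sum=1.5", all = FALSE)
  expect_error(validate_fractions(c(0.5, 0.5, 0.5), "bad"), "sum=1.5")
  expect_error(validate_fractions(c(0.5, NA, 0.5), "bad"),
               "non-finite value at index 2")
  rep2 <- validate_fractions(c(1.2, -0.2), "bad", stop_on_error = FALSE)
  expect_match(rep2$problems, "outside", all = FALSE)
})

test_that("lattice construction realises the requested geometry", {
  # 6x6 cellulose-only bundle: chains x (bonds + 1) monomers
  cfg <- microfibril_config(n_bonds_per_chain = 200,
                            cross_section = "corn_stover",
                            frac_cellulose = 1, frac_hemicellulose = 0,
                            frac_lignin = 0)
  fib <- build_microfibril(cfg)
  expect_equal(fib$n_sites, 36)
  expect_equal(sum(fib$initial_counts), 36 * 201)
  expect_equal(unname(fib$initial_counts["cellulose"]), 7236)
  expect_equal(sum(!is.na(fib$bond_intact) & fib$bond_intact), 7200)

  # minimal single-chain fibril
  tiny <- build_microfibril(toy_config(n_bonds = 1))
  expect_equal(sum(tiny$initial_counts), 2)
  expect_equal(sum(tiny$bond_intact, na.rm = TRUE), 1)

  # a substrate with no cellulose core is infeasible
  expect_error(build_microfibril(microfibril_config(
    frac_cellulose = 0, frac_hemicellulose = 0, frac_lignin = 1)),
    "infeasible")
})

test_that("realised composition approaches requested fractions with size", {
  mk <- function(preset) {
    set.seed(99)
    build_microfibril(microfibril_config(
      n_bonds_per_chain = 20, cross_section = preset,
      frac_cellulose = 0.6, frac_hemicellulose = 0.25, frac_lignin = 0.15))
  }
  req <- c(cellulose = 0.6, hemicellulose = 0.25, lignin = 0.15)
  err_small <- max(abs(mk("demo")$realized_composition - req))
  err_large <- max(abs(mk("spruce")$realized_composition - req))
  expect_lt(err_large, err_small)
  expect_lt(err_large, 0.01)
})

test_that("crystallinity assignment hits its amorphous target", {
  # fully crystalline
  f1 <- new_fibril(toy_config(n_bonds = 60, preset = "demo",
                              crystalline = 1))
  expect_equal(sum(!f1$crystalline), 0)
  # fully amorphous
  f0 <- new_fibril(toy_config(n_bonds = 60, preset = "demo",
                              crystalline = 0))
  expect_equal(sum(f0$crystalline), 0)
  # 95% crystallinity on the 36-chain, 200-bond bundle: realised amorphous
  # cellulose fraction stays within 2 percentage points of 5%
  cfg <- microfibril_config(n_bonds_per_chain = 200,
                            cross_section = "corn_stover",
                            frac_cellulose = 1, frac_hemicellulose = 0,
                            frac_lignin = 0,
                            crystalline_frac_cellulose = 0.95)
  realized <- vapply(1:100, function(s) {
    cfg$rng_seed <- s
    new_fibril(cfg)$realized_amorphous[["cellulose"]]
  }, numeric(1))
  expect_true(all(abs(realized - 0.05) <= 0.02))
})

test_that("identical configuration and seed give identical fibrils", {
  cfg <- microfibril_config(n_bonds_per_chain = 30, cross_section = "demo",
                            crystalline_frac_cellulose = 0.5, rng_seed = 11)
  expect_identical(new_fibril(cfg), new_fibril(cfg))
})

test_that("exposure follows surface occupancy and occlusion", {
  # single cellulose chain fully wrapped in lignin: no exposed cellulose
  wrapped_cfg <- microfibril_config(
    n_bonds_per_chain = 10, cross_section = "single",
    frac_cellulose = 1 / 9, frac_hemicellulose = 0, frac_lignin = 8 / 9,
    crystalline_frac_cellulose = 0, defect_density = 0)
  fib <- new_fibril(wrapped_cfg)
  eb <- exposed_bonds(fib)
  expect_equal(sum(eb$polymer == "cellulose"), 0)

  # removing the lignin sheath exposes every cellulose bond
  fib$in_fibril[fib$sites$polymer == "lignin", ] <- FALSE
  eb2 <- exposed_bonds(fib)
  expect_equal(sum(eb2$polymer == "cellulose"), 10)

  # cellulose-only bundle: every bond of the boundary chains is exposed,
  # interior-chain bonds are shielded by the outer chains
  fib3 <- new_fibril(toy_config(n_bonds = 12, preset = "demo"))
  eb3 <- exposed_bonds(fib3)
  interior <- fib3$sites$site[fib3$sites$row == 2 & fib3$sites$col == 2]
  expect_equal(nrow(eb3), 8 * 12)
  expect_false(interior %in% eb3$site)
})

test_that("exposed set only grows when outer material is removed", {
  fib <- new_fibril(microfibril_config(
    n_bonds_per_chain = 12, cross_section = "demo",
    frac_cellulose = 0.4, frac_hemicellulose = 0.3, frac_lignin = 0.3,
    rng_seed = 5))
  key <- function(f) {
    eb <- exposed_bonds(f)
    eb <- eb[eb$polymer != "lignin", ]
    paste(eb$site, eb$bond)
  }
  before <- key(fib)
  fib$in_fibril[fib$sites$polymer == "lignin", ] <- FALSE
  after <- key(fib)
  expect_true(all(before %in% after))
  expect_gt(length(after), length(before))
})

test_that("composition report conserves monomer counts", {
  fib <- new_fibril(microfibril_config(
    n_bonds_per_chain = 12, cross_section = "demo",
    frac_cellulose = 0.6, frac_hemicellulose = 0.25, frac_lignin = 0.15))
  rep <- composition_report(fib)
  expect_equal(rep$solubilized, c(0, 0, 0))
  expect_equal(rep$in_fibril + rep$solubilized, rep$initial)
  expect_equal(sum(rep$initial), sum(fib$initial_counts))
  # after removing all cellulose, the deficit shows up as solubilized
  fib$in_fibril[fib$sites$polymer == "cellulose", ] <- FALSE
  rep2 <- composition_report(fib)
  expect_equal(rep2$in_fibril[rep2$polymer == "cellulose"], 0)
  expect_equal(rep2$in_fibril + rep2$solubilized, rep2$initial)
})
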