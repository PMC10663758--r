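test_that("channel enumeration covers actable targets only", {
  # two identical exposed amorphous bonds, EG only: two equal channels
  st <- toy_state(n_bonds = 2, E = 2,
                  kinetic = list(kcat_EG = 10, Km_EG = 4))
  ch <- enumerate_channels(st)
  expect_equal(nrow(ch), 2)
  expect_equal(ch$enzyme, c("EG", "EG"))
  # hand-computed rate: kcat*E/(Km + S), S = 2 bonds / V = 0.02
  expect_equal(ch$propensity, rep(10 * 2 / (4 + 0.02), 2))

  # a cellulase-free cocktail on a cellulose-only fibril has no channels
  st2 <- toy_state(n_bonds = 2,
                   fractions = c(EG = 0, CBH = 0, BGL = 0, XYL = 1))
  expect_equal(nrow(enumerate_channels(st2)), 0)

  # fully digested fibril with empty pool is absorbing
  st3 <- toy_state(n_bonds = 2)
  st3$fibril$in_fibril[] <- FALSE
  expect_equal(nrow(enumerate_channels(st3)), 0)
})

test_that("event drawing matches the exponential/multinomial law", {
  mk <- function(a) data.frame(channel = as.character(seq_along(a)),
                               enzyme = rep("EG", length(a)),
                               type = rep("bond", length(a)),
                               site = rep(1L, length(a)),
                               index = seq_along(a),
                               side = rep(NA, length(a)), propensity = a)
  set.seed(101)
  one <- mk(2)
  draws <- replicate(10000, draw_event(one)$dt)
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.5 / sqrt(10000))
  two <- mk(c(3, 1))
  picks <- replicate(10000, draw_event(two)$channel$index)
  p1 <- mean(picks == 1)
  expect_lt(abs(p1 - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  # exhausted system signals completion rather than erroring
  expect_true(draw_event(mk(numeric(0)))$finished)
})

test_that("event application follows each enzyme's mechanism", {
  # BGL stoichiometry: cellobiose - 1, glucose + 2
  st <- toy_state(n_bonds = 2, fractions = c(EG = 0, CBH = 0, BGL = 1,
                                             XYL = 0),
                  pool = c(glucose = 0, cellobiose = 5, xylose = 0))
  st2 <- apply_event(st, list(enzyme = "BGL", type = "solution",
                              site = NA, index = NA, side = NA))
  expect_equal(unname(st2$pool[c("cellobiose", "glucose")]), c(4, 2))

  # EG fragment solubilisation depends on the cutoff
  eg_ch <- list(enzyme = "EG", type = "bond", site = 1, index = 1, side = NA)
  stA <- toy_state(n_bonds = 2, cutoff = 2)
  stA2 <- apply_event(stA, eg_ch)
  expect_equal(sum(stA2$fibril$in_fibril), 0)       # both fragments leave
  expect_equal(unname(stA2$pool[["glucose"]]), 1)   # 1-mer as glucose
  expect_equal(unname(stA2$pool[["cellobiose"]]), 1)
  stB <- toy_state(n_bonds = 2, cutoff = 1)
  stB2 <- apply_event(stB, eg_ch)
  expect_equal(sum(stB2$fibril$in_fibril), 2)       # dimer stays in fibril
  expect_equal(unname(stB2$pool[["glucose"]]), 1)
  # replaying the same cleavage is a consistency error
  expect_error(apply_event(stA2, eg_ch), "stale channel")

  # processive CBH run: k cellobiose from a 2k-monomer chain
  st <- toy_state(n_bonds = 9, cutoff = 1,
                  fractions = c(EG = 0, CBH = 1, BGL = 0, XYL = 0),
                  kinetic = list(processivity_CBH = 1e4))
  set.seed(1)
  st2 <- apply_event(st, list(enzyme = "CBH", type = "end", site = 1,
                              index = 1, side = "L"))
  expect_equal(unname(st2$pool[["cellobiose"]]), 5)
  expect_equal(sum(st2$fibril$in_fibril), 0)
  # odd-length chain: leftover monomer within the cutoff is solubilised
  st <- toy_state(n_bonds = 8, cutoff = 1,
                  fractions = c(EG = 0, CBH = 1, BGL = 0, XYL = 0),
                  kinetic = list(processivity_CBH = 1e4))
  set.seed(1)
  st2 <- apply_event(st, list(enzyme = "CBH", type = "end", site = 1,
                              index = 9, side = "R"))
  expect_equal(unname(st2$pool[["cellobiose"]]), 4)
  expect_equal(unname(st2$pool[["glucose"]]), 1)
  expect_equal(glucose_equivalents(st2), 9)
})

test_that("conversion percentages track solubilised equivalents", {
  doc <- quick_params(sample = list(species_preset = "corn_stover",
                                    frac_cellulose = 1,
                                    frac_hemicellulose = 0, frac_lignin = 0),
                      simulation = list(n_bonds_per_chain = 200L))
  set.seed(1)
  st <- new_state(doc)
  expect_equal(conversion_percent(st, "glucose"), 0)
  st$pool[["cellobiose"]] <- 1800
  expect_equal(conversion_percent(st, "glucose"), 100 * 3600 / 7236)
  expect_true(is.na(conversion_percent(st, "xylose")))
  expect_error(conversion_percent(st, "lignin"), "not converted")
  st$pool[["glucose"]] <- 7236 - 3600
  expect_equal(conversion_percent(st, "cellulose"), 100)
})

test_that("trajectories are reproducible, conservative and monotone", {
  doc <- quick_params(simulation = list(t_end = 24))
  a <- run_simulation(doc, seed = 7)
  b <- run_simulation(doc, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(run_simulation(doc, seed = 8))))
  # conversions start at zero, never decrease, stay within [0, 100]
  for (col in c("glucose_conversion", "xylose_conversion")) {
    expect_equal(a[[col]][1], 0)
    expect_true(all(diff(a[[col]]) >= 0))
    expect_true(all(a[[col]] >= 0 & a[[col]] <= 100))
  }
  expect_true(all(diff(a$time) > 0))
  # sugar equivalents are conserved through the whole event sequence
  st <- attr(a, "state")
  expect_equal(glucose_equivalents(st),
               unname(st$initial_fibril[["cellulose"]]))
  expect_equal(xylose_equivalents(st),
               unname(st$initial_fibril[["hemicellulose"]]))
  expect_error(run_simulation(doc, t_end = 0), "t_end")
})

test_that("a substrate with no actable channel yields flat curves", {
  doc <- quick_params(sample = list(
    frac_cellulose = 1, frac_hemicellulose = 0, frac_lignin = 0,
    frac_EG = 0, frac_CBH = 0, frac_BGL = 0, frac_XYL = 1))
  tc <- run_simulation(doc, seed = 1, t_end = 5)
  expect_true(all(tc$glucose_conversion == 0))
  expect_true(all(rowSums(tc[, grep("events", names(tc))]) == 0))
})

test_that("excess cellulases digest an amorphous fibril completely", {
  doc <- quick_params(
    sample = list(species_preset = "single", frac_cellulose = 1,
                  frac_hemicellulose = 0, frac_lignin = 0,
                  crystalline_frac_cellulose = 0, defect_density = 0,
                  frac_EG = 0.3, frac_CBH = 0.4, frac_BGL = 0.3,
                  frac_XYL = 0, total_enzyme_concentration = 10),
    simulation = list(n_bonds_per_chain = 12L))
  tc <- run_simulation(doc, seed = 3, t_end = 500)
  n <- nrow(tc)
  expect_equal(tc$glucose_conversion[n], 100)
  # full digestion ends in glucose only (BGL finishes the cellobiose)
  st <- attr(tc, "state")
  expect_equal(unname(st$pool[["cellobiose"]]), 0)
  expect_equal(unname(st$pool[["glucose"]]), 13)
})

test_that("EG and CBH act synergistically on a semi-crystalline fibril", {
  # With a minimal solubilisation cutoff, cellobiose is CBH's signature
  # product: EG alone releases none, CBH alone is limited by the few
  # initial chain ends, and together EG's internal cleavages create new
  # ends for CBH -- so the mixed cocktail releases more cellobiose than
  # the two single-enzyme cocktails combined, at equal total loading.
  base <- list(species_preset = "demo", frac_cellulose = 1,
               frac_hemicellulose = 0, frac_lignin = 0,
               crystalline_frac_cellulose = 0.5, frac_XYL = 0,
               frac_BGL = 0, total_enzyme_concentration = 0.03)
  release <- function(fEG, fCBH, seed) {
    doc <- quick_params(sample = c(base, list(frac_EG = fEG,
                                              frac_CBH = fCBH)),
                        simulation = list(n_bonds_per_chain = 60L,
                                          solubilization_cutoff = 1L))
    tc <- run_simulation(doc, seed = seed, t_end = 48)
    unname(attr(tc, "state")$pool[["cellobiose"]])
  }
  seeds <- 1:10
  both <- mean(vapply(seeds, function(s) release(0.5, 0.5, s), numeric(1)))
  eg <- mean(vapply(seeds, function(s) release(1, 0, s), numeric(1)))
  cbh <- mean(vapply(seeds, function(s) release(0, 1, s), numeric(1)))
  expect_gt(both, eg + cbh)
})

test_that("relative activity normalises each enzyme to its own peak", {
  doc <- quick_params(simulation = list(t_end = 12))
  tc <- run_simulation(doc, seed = 2)
  act <- relative_activity(tc)
  for (e in c("EG", "CBH", "BGL", "XYL")) {
    expect_true(all(act[[e]] >= 0 & act[[e]] <= 1))
    if (any(tc[[paste0("events_", e)]] > 0)) expect_equal(max(act[[e]]), 1)
  }
})

test_that("replicate averaging preserves the recording grid", {
  doc <- quick_params(simulation = list(t_end = 6))
  avg <- simulate_replicates(doc, seeds = 1:3)
  one <- run_simulation(doc, seed = 1)
  expect_equal(avg$time, one$time)
  expect_equal(attr(avg, "replicates"), 3)
  expect_true(all(diff(avg$glucose_conversion) >= 0))
})
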