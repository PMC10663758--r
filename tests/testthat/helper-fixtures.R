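# Shared fixture builders: all fixtures are constructed in code.

# Reduced parameter document with overrides applied to the first sample
# and/or the named sections.
quick_params <- function(sample = list(), kinetic = list(),
                         simulation = list(), n_samples = 1) {
  doc <- demo_params(n_samples)
  doc$simulation <- utils::modifyList(doc$simulation, simulation)
  doc$kinetic <- utils::modifyList(doc$kinetic, kinetic)
  if (length(sample))
    for (k in seq_len(n_samples))
      doc$samples[[k]] <- utils::modifyList(doc$samples[[k]], sample)
  validate_document(doc)
}

# Cellulose-only toy configuration: one chain (or a preset core), no
# hemicellulose/lignin sheath, fully amorphous by default.
toy_config <- function(n_bonds = 2, preset = "single", crystalline = 0,
                       seed = 1) {
  microfibril_config(
    n_bonds_per_chain = n_bonds, cross_section = preset,
    frac_cellulose = 1, frac_hemicellulose = 0, frac_lignin = 0,
    crystalline_frac_cellulose = crystalline,
    crystalline_frac_hemicellulose = 0,
    defect_density = 0, rng_seed = seed)
}

# Toy state: cellulose-only fibril with a chosen cocktail.
toy_state <- function(n_bonds = 2, preset = "single",
                      fractions = c(EG = 1, CBH = 0, BGL = 0, XYL = 0),
                      crystalline = 0, cutoff = 1, E = 0.03,
                      kinetic = list(), pool = c(glucose = 0,
                                                 cellobiose = 0,
                                                 xylose = 0),
                      seed = 1) {
  doc <- demo_params()
  doc$simulation$n_bonds_per_chain <- as.integer(n_bonds)
  doc$simulation$solubilization_cutoff <- as.integer(cutoff)
  doc$kinetic <- utils::modifyList(doc$kinetic, kinetic)
  doc$samples[[1]] <- utils::modifyList(doc$samples[[1]], list(
    species_preset = preset, frac_cellulose = 1, frac_hemicellulose = 0,
    frac_lignin = 0, crystalline_frac_cellulose = crystalline,
    defect_density = 0, total_enzyme_concentration = E,
    frac_EG = unname(fractions["EG"]), frac_CBH = unname(fractions["CBH"]),
    frac_BGL = unname(fractions["BGL"]), frac_XYL = unname(fractions["XYL"]),
    initial_glucose = unname(pool["glucose"]),
    initial_cellobiose = unname(pool["cellobiose"]),
    initial_xylose = unname(pool["xylose"])))
  set.seed(seed)
  new_state(validate_document(doc))
}

# Glucose equivalents currently accounted (fibril + pool).
glucose_equivalents <- function(state) {
  sum(state$fibril$in_fibril[state$fibril$sites$polymer == "cellulose", ,
                             drop = FALSE]) +
    2 * state$pool[["cellobiose"]] + state$pool[["glucose"]]
}

xylose_equivalents <- function(state) {
  sum(state$fibril$in_fibril[state$fibril$sites$polymer == "hemicellulose", ,
                             drop = FALSE]) + state$pool[["xylose"]]
}
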