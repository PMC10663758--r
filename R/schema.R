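# Canonical parameter schema: three sections with exactly 14 (simulation),
# 18 (kinetic) and 18 (per-sample initial configuration) named parameters,
# 50 in total.  Every parameter carries a declared legal range used by the
# validators in io.R.

.schema_rows <- function(section, rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], type = r[[2]],
               min = as.numeric(r[[3]]), max = as.numeric(r[[4]]),
               default = I(list(r[[5]])), description = r[[6]],
               stringsAsFactors = FALSE)
  }))
  df$section <- section
  df
}

.build_schema <- function() {
  sim <- .schema_rows("simulation", list(
    list("t_end", "real", 1e-6, 1e5, 72, "simulation horizon [h]"),
    list("record_interval", "real", 1e-6, 1e4, 0.5, "recording interval [h]"),
    list("replicates", "int", 1, 1000, 3, "trajectories averaged per evaluation"),
    list("rng_seed", "int", 0, 2147483646, 1, "default random seed"),
    list("solubilization_cutoff", "int", 1, 1000, 6,
         "fragments of at most this many monomers leave the fibril"),
    list("reaction_volume", "real", 1e-9, 1e12, 100,
         "volume constant mapping counts to concentration units"),
    list("n_bonds_per_chain", "int", 1, 100000, 200,
         "glycosidic bonds per chain (fibril length)"),
    list("max_events", "int", 1, 1e9, 1e7, "safety cap on Gillespie events"),
    list("record_enzyme_activity", "flag", 0, 1, 1,
         "record per-enzyme event counts per window"),
    list("write_event_log", "flag", 0, 1, 0, "keep the full event log"),
    list("stop_when_digested", "flag", 0, 1, 1,
         "stop early once no reaction channel remains"),
    list("output_digits", "int", 1, 17, 6, "digits in written output tables"),
    list("n_threads", "int", 1, 1024, 1,
         "CPU threads for multi-replicate runs (1 = serial)"),
    list("verbose", "flag", 0, 1, 0, "progress messages to stderr")
  ))
  kin <- .schema_rows("kinetic", list(
    list("kcat_EG", "real", 0, 1e9, 40, "EG turnover number [1/h]"),
    list("kcat_CBH", "real", 0, 1e9, 12, "CBH run-initiation turnover [1/h]"),
    list("kcat_BGL", "real", 0, 1e9, 900, "BGL turnover number [1/h]"),
    list("kcat_XYL", "real", 0, 1e9, 60, "XYL turnover number [1/h]"),
    list("Km_EG", "real", 1e-12, 1e9, 25, "EG Michaelis constant [conc]"),
    list("Km_CBH", "real", 1e-12, 1e9, 10, "CBH Michaelis constant [conc]"),
    list("Km_BGL", "real", 1e-12, 1e9, 2.5, "BGL Michaelis constant [conc]"),
    list("Km_XYL", "real", 1e-12, 1e9, 25, "XYL Michaelis constant [conc]"),
    list("Ki_glucose", "real", 1e-12, 1e12, 50,
         "competitive inhibition constant of cellulases by glucose [conc]"),
    list("Ki_cellobiose", "real", 1e-12, 1e12, 10,
         "competitive inhibition constant of cellulases by cellobiose [conc]"),
    list("K_lignin", "real", 0, 1e6, 0.5,
         "non-productive lignin adsorption partition strength [-]"),
    list("footprint_EG", "int", 1, 1000, 2, "bonds occluded by a bound EG"),
    list("footprint_CBH", "int", 1, 1000, 4, "bonds occluded by a bound CBH"),
    list("footprint_XYL", "int", 1, 1000, 2, "bonds occluded by a bound XYL"),
    list("processivity_CBH", "real", 1, 1e4, 30,
         "mean consecutive CBH cleavages per binding"),
    list("crystalline_factor_EG", "real", 0, 1, 0.15,
         "EG rate multiplier on crystalline bonds"),
    list("crystalline_factor_CBH", "real", 0, 1, 0.5,
         "CBH step success probability on crystalline bonds"),
    list("crystalline_factor_XYL", "real", 0, 1, 0.15,
         "XYL rate multiplier on crystalline hemicellulose")
  ))
  cfg <- .schema_rows("config", list(
    list("sample_name", "string", NA, NA, "sample_1", "sample identifier"),
    list("species_preset", "string", NA, NA, "corn_stover",
         "cross-section preset (plant species)"),
    list("frac_cellulose", "real", 0, 1, 0.60, "cellulose fraction of monomers"),
    list("frac_hemicellulose", "real", 0, 1, 0.25, "hemicellulose fraction"),
    list("frac_lignin", "real", 0, 1, 0.15, "lignin fraction"),
    list("crystalline_frac_cellulose", "real", 0, 1, 0.02,
         "crystalline fraction of cellulose"),
    list("crystalline_frac_hemicellulose", "real", 0, 1, 0.02,
         "crystalline fraction of hemicellulose"),
    list("defect_density", "real", 0, 100, 1,
         "expected amorphous defect patches per chain"),
    list("defect_patch_length", "int", 1, 10000, 5, "monomers per defect patch"),
    list("end_amorphous_length", "int", 0, 10000, 2,
         "chain-end monomers treated as boundary-amorphous first"),
    list("frac_EG", "real", 0, 1, 0.25, "EG fraction of the cocktail"),
    list("frac_CBH", "real", 0, 1, 0.45, "CBH fraction of the cocktail"),
    list("frac_BGL", "real", 0, 1, 0.15, "BGL fraction of the cocktail"),
    list("frac_XYL", "real", 0, 1, 0.15, "XYL fraction of the cocktail"),
    list("total_enzyme_concentration", "real", 0, 1e6, 0.03,
         "total enzyme concentration [conc]"),
    list("initial_glucose", "real", 0, 1e9, 0, "initial glucose pool [count]"),
    list("initial_cellobiose", "real", 0, 1e9, 0,
         "initial cellobiose pool [count]"),
    list("initial_xylose", "real", 0, 1e9, 0, "initial xylose pool [count]")
  ))
  rbind(sim, kin, cfg)
}

.schema_env <- new.env(parent = emptyenv())

#' Canonical parameter schema
#'
#' The model is controlled by exactly 50 named parameters split over three
#' sections: 14 simulation (run-control) parameters, 18 kinetic parameters
#' shared by all samples, and 18 initial-configuration parameters describing
#' one substrate sample and its enzyme cocktail.  Every parameter has a
#' declared type and legal range; readers reject unknown keys, missing keys
#' and out-of-range values, and fraction groups (substrate composition,
#' cocktail composition) must sum to one.
#'
#' @return A data frame with columns `section`, `name`, `type`, `min`,
#'   `max`, `default` (list column) and `description`.
#' @export
#' @examples
#' table(parameter_schema()$section)
parameter_schema <- function() {
  if (is.null(.schema_env$schema)) .schema_env$schema <- .build_schema()
  .schema_env$schema
}

schema_section <- function(section) {
  s <- parameter_schema()
  s[s$section == section, , drop = FALSE]
}

schema_defaults <- function(section) {
  s <- schema_section(section)
  setNames(lapply(s$default, identity), s$name)
}

#' Cross-section presets for the microfibril core
#'
#' The shape of the microfibril cross-section (and hence the number of
#' cellulose chains in the core bundle) depends on the plant species the
#' material comes from.  The presets are package choices, not literature
#' measurements: `demo` is a reduced 3x3 bundle sized for fast runs, the
#' others are plausibly sized rectangular bundles for common feedstocks.
#'
#' @return Data frame with columns `name`, `core_rows`, `core_cols`,
#'   `description`.
#' @export
species_presets <- function() {
  data.frame(
    name = c("single", "demo", "corn_stover", "wheat_straw", "spruce"),
    core_rows = c(1L, 3L, 6L, 4L, 8L),
    core_cols = c(1L, 3L, 6L, 9L, 8L),
    description = c(
      "single-chain toy cross-section",
      "reduced 3x3 cellulose core for demonstrations and tests",
      "6x6 cellulose core, herbaceous feedstock",
      "4x9 flattened cellulose core",
      "8x8 cellulose core, softwood"),
    stringsAsFactors = FALSE)
}

#' Enzyme kinetic preset catalogue
#'
#' A small static catalogue of per-organism kcat/Km options for the four
#' cocktail enzymes, standing in for live kinetic-database queries.  Values
#' are curated illustrative numbers on the package's arbitrary concentration
#' scale (see the methods vignette), not measurements traceable to a
#' specific assay.
#'
#' @return Data frame with columns `enzyme`, `organism`, `kcat`, `Km`,
#'   `reference`.
#' @export
enzyme_presets <- function() {
  path <- system.file("extdata", "enzyme_presets.tsv", package = "sacchsim")
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(df$enzyme %in% c("EG", "CBH", "BGL", "XYL")),
            all(df$kcat > 0), all(df$Km > 0))
  df
}
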