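# Kinetics: enzyme specifications and per-bond reaction propensities.
#
# Every propensity has the Michaelis-Menten-like per-target form
#   rate = kcat * E_free / (Km * inhibition + S) * crystalline_factor * steric
# with E_free the free-enzyme concentration after non-productive lignin
# adsorption, S a concentration proxy for the accessible substrate
# (actable-target count / reaction volume), competitive end-product
# inhibition scaling Km for the cellulases, and a crystallinity multiplier
# where the target is crystalline.  Units: kcat in events per hour, Km/Ki
# and concentrations on one arbitrary concentration scale.

ENZYMES <- c("EG", "CBH", "BGL", "XYL")

#' Enzyme specification
#'
#' @param name One of `"EG"`, `"CBH"`, `"BGL"`, `"XYL"`.
#' @param kcat Turnover number, events per hour per enzyme.
#' @param Km Michaelis constant (concentration units).
#' @param footprint Bonds occluded when bound (steric size), >= 1.
#' @param Ki_glucose,Ki_cellobiose Competitive inhibition constants
#'   (cellulases only; ignored for XYL).
#' @param K_lignin Non-productive lignin adsorption partition strength
#'   (dimensionless; 0 disables adsorption).
#' @param crystalline_rate_factor Multiplier in \[0, 1\] applied on
#'   crystalline targets (for CBH it is the per-step success probability).
#' @param processivity Expected consecutive cleavages per CBH binding
#'   (>= 1; ignored for the other enzymes).
#' @return List of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, kcat, Km, footprint = 1L,
                        Ki_glucose = Inf, Ki_cellobiose = Inf,
                        K_lignin = 0, crystalline_rate_factor = 1,
                        processivity = 1) {
  name <- match.arg(name, ENZYMES)
  if (!is.finite(kcat) || kcat < 0) stop("kcat must be >= 0", call. = FALSE)
  if (!is.finite(Km) || Km <= 0) stop("Km must be > 0", call. = FALSE)
  if (name %in% c("EG", "CBH", "BGL")) {
    if (Ki_glucose <= 0 || Ki_cellobiose <= 0)
      stop(sprintf("%s: inhibition constants must be > 0", name),
           call. = FALSE)
  }
  stopifnot(footprint >= 1, K_lignin >= 0,
            crystalline_rate_factor >= 0, crystalline_rate_factor <= 1,
            processivity >= 1)
  structure(list(name = name, kcat = kcat, Km = Km,
                 footprint = as.integer(footprint),
                 Ki_glucose = Ki_glucose, Ki_cellobiose = Ki_cellobiose,
                 K_lignin = K_lignin,
                 crystalline_rate_factor = crystalline_rate_factor,
                 processivity = processivity),
            class = "enzyme_spec")
}

#' Cocktail specification
#'
#' @param total_enzyme_concentration Total enzyme concentration (>= 0).
#' @param fractions Named proportions for `EG`, `CBH`, `BGL`, `XYL`;
#'   must pass [validate_fractions()].
#' @return List of class `cocktail_spec`.
#' @export
cocktail_spec <- function(total_enzyme_concentration,
                          fractions = c(EG = 0.25, CBH = 0.45,
                                        BGL = 0.15, XYL = 0.15)) {
  stopifnot(total_enzyme_concentration >= 0)
  if (!setequal(names(fractions), ENZYMES))
    stop("cocktail fractions must be named EG, CBH, BGL, XYL", call. = FALSE)
  validate_fractions(unname(fractions[ENZYMES]), "cocktail composition")
  structure(list(total_enzyme_concentration = total_enzyme_concentration,
                 fractions = fractions[ENZYMES]), class = "cocktail_spec")
}

# Build the four enzyme_spec objects from a kinetic parameter section.
enzymes_from_kinetic <- function(kin) {
  list(
    EG = enzyme_spec("EG", kin$kcat_EG, kin$Km_EG, kin$footprint_EG,
                     kin$Ki_glucose, kin$Ki_cellobiose, kin$K_lignin,
                     kin$crystalline_factor_EG),
    CBH = enzyme_spec("CBH", kin$kcat_CBH, kin$Km_CBH, kin$footprint_CBH,
                      kin$Ki_glucose, kin$Ki_cellobiose, kin$K_lignin,
                      kin$crystalline_factor_CBH,
                      processivity = kin$processivity_CBH),
    BGL = enzyme_spec("BGL", kin$kcat_BGL, kin$Km_BGL, 1L,
                      kin$Ki_glucose, kin$Ki_cellobiose, kin$K_lignin),
    XYL = enzyme_spec("XYL", kin$kcat_XYL, kin$Km_XYL, kin$footprint_XYL,
                      K_lignin = kin$K_lignin,
                      crystalline_rate_factor = kin$crystalline_factor_XYL))
}

#' Competitive end-product inhibition factor
#'
#' Cellulases (EG, CBH, BGL) are competitively inhibited by accumulated
#' glucose and cellobiose: the factor `1 + G/Ki_glucose + C/Ki_cellobiose`
#' multiplies Km in the rate law.  Xylanase is not inhibited (factor 1).
#'
#' @param enzyme An [enzyme_spec()].
#' @param pool Named vector or list with concentrations `glucose` and
#'   `cellobiose` (xylose is ignored).
#' @return Multiplier >= 1.
#' @export
inhibition_factor <- function(enzyme, pool) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (enzyme$name == "XYL") return(1)
  g <- pool[["glucose"]]; cb <- pool[["cellobiose"]]
  stopifnot(g >= 0, cb >= 0)
  if (enzyme$Ki_glucose <= 0 || enzyme$Ki_cellobiose <= 0)
    stop("inhibition constants must be > 0", call. = FALSE)
  1 + g / enzyme$Ki_glucose + cb / enzyme$Ki_cellobiose
}

#' Free-enzyme fraction after non-productive lignin adsorption
#'
#' Lignin sequesters enzymes in a quasi-equilibrium partition: the fraction
#' of the enzyme pool remaining free is
#' `1 / (1 + K_lignin * exposed_lignin_sites / max(total_binding_sites, 1))`,
#' monotonically decreasing in the exposed lignin surface.
#'
#' @param enzyme An [enzyme_spec()].
#' @param exposed_lignin_sites Count of exposed lignin monomers.
#' @param total_binding_sites Total count of exposed surface monomers.
#' @return Proportion in (0, 1\].
#' @export
free_enzyme_fraction <- function(enzyme, exposed_lignin_sites,
                                 total_binding_sites) {
  stopifnot(exposed_lignin_sites >= 0,
            total_binding_sites >= exposed_lignin_sites)
  1 / (1 + enzyme$K_lignin * exposed_lignin_sites /
         max(total_binding_sites, 1))
}

#' Steric availability of a bond
#'
#' A bond can only be attacked if the footprint-length window centred on it
#' overlaps no interval already occupied by a bound enzyme on the same or a
#' laterally adjacent chain.
#'
#' @param bond List or vector with `site` and `bond` (bond index).
#' @param bound_intervals Data frame (possibly empty) with columns `site`,
#'   `start`, `end` giving occupied bond ranges; intervals do not overlap.
#' @param footprint Window length in bonds (>= 1).
#' @param nbr Optional neighbour index matrix (as in a `microfibril`);
#'   when supplied, intervals on the four adjacent chains also block.
#' @return 1 if the bond is sterically free, 0 otherwise.
#' @export
steric_free <- function(bond, bound_intervals, footprint, nbr = NULL) {
  if (is.null(bound_intervals) || NROW(bound_intervals) == 0) return(1)
  stopifnot(footprint >= 1)
  b <- bond[["bond"]]; s <- bond[["site"]]
  lo <- b - floor((footprint - 1) / 2)
  hi <- b + ceiling((footprint - 1) / 2)
  sites <- s
  if (!is.null(nbr)) sites <- c(sites, nbr[s, ][!is.na(nbr[s, ])])
  hit <- bound_intervals$site %in% sites &
    bound_intervals$end >= lo & bound_intervals$start <= hi
  if (any(hit)) 0 else 1
}

#' Per-target reaction propensity
#'
#' Computes the propensity (events per hour) of one enzyme acting on one
#' target under the full rate law, or zero for targets the enzyme cannot
#' act on: EG cleaves only exposed amorphous cellulose bonds (crystalline
#' bonds at the reduced `crystalline_rate_factor`), CBH initiates only at
#' exposed cellulose chain ends, BGL acts only on soluble cellobiose, XYL
#' on exposed hemicellulose bonds.
#'
#' @param enzyme An [enzyme_spec()].
#' @param free_conc Free concentration of this enzyme (after lignin
#'   adsorption).
#' @param substrate_conc Accessible-substrate concentration proxy
#'   (actable targets / reaction volume; cellobiose concentration for BGL).
#' @param pool Product pool (named concentrations) for inhibition.
#' @param crystalline Is the target crystalline?
#' @param steric Steric availability indicator (0 or 1).
#' @param actable Does the enzyme mechanism apply to this target at all?
#' @return Propensity in events per hour (>= 0, finite).
#' @export
bond_propensity <- function(enzyme, free_conc, substrate_conc, pool,
                            crystalline = FALSE, steric = 1,
                            actable = TRUE) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (!actable || steric == 0) return(0)
  inh <- inhibition_factor(enzyme, pool)
  rate <- enzyme$kcat * free_conc / (enzyme$Km * inh + substrate_conc)
  if (crystalline) rate <- rate * enzyme$crystalline_rate_factor
  stopifnot(is.finite(rate), rate >= 0)
  rate
}
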