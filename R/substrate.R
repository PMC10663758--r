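# Substrate: monomer-resolved 3D microfibril on a square lattice.
#
# Each lattice site (row, col) of the cross-section carries one axial chain
# of L = n_bonds_per_chain + 1 monomers.  The cellulose core occupies an
# inner rectangle given by the species preset; hemicellulose fills the
# concentric rectangular rings around it, lignin the rings outside those.
# Fractional rings are realised by randomly occupying a subset of the
# outermost ring's sites, so realised composition tracks the requested
# fractions as closely as the lattice allows.

POLYMERS <- c("cellulose", "hemicellulose", "lignin")
SUGAR_OF <- c(cellulose = "glucose", hemicellulose = "xylose",
              lignin = "monolignol")

#' Validate a distribution of fractions
#'
#' Checks that every value lies in \[0, 1\] and that the values sum to one
#' within a tolerance of 1e-9.  Used for the substrate composition
#' (cellulose/hemicellulose/lignin) and the cocktail composition
#' (EG/CBH/BGL/XYL); every group of parameters forming a distribution must
#' sum to one.
#'
#' @param values Numeric vector of proportions.
#' @param label Name of the group, used in error reports.
#' @return Invisibly `TRUE` if valid, otherwise an object of class
#'   `fraction_violation` (also condition-signalled via `stop()` when
#'   `stop_on_error = TRUE`).
#' @param stop_on_error If `TRUE` (default) raise an error on violation,
#'   otherwise return the violation report.
#' @export
#' @examples
#' validate_fractions(c(0.5, 0.3, 0.2), "composition")
validate_fractions <- function(values, label = "fractions",
                               stop_on_error = TRUE) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values))
    msg <- sprintf("%s: non-finite value at index %s", label,
                   paste(bad, collapse = ", "))
    stop(msg, call. = FALSE)
  }
  problems <- character(0)
  out_of_range <- which(values < 0 | values > 1)
  if (length(out_of_range)) {
    problems <- c(problems, sprintf(
      "entries outside [0,1] at index %s (values %s)",
      paste(out_of_range, collapse = ", "),
      paste(signif(values[out_of_range], 6), collapse = ", ")))
  }
  s <- sum(values)
  if (abs(s - 1) > 1e-9) {
    problems <- c(problems, sprintf("sum=%.10g (must equal 1)", s))
  }
  if (length(problems) == 0) return(invisible(TRUE))
  report <- structure(list(label = label, values = values,
                           problems = problems),
                      class = "fraction_violation")
  if (stop_on_error) {
    stop(sprintf("%s: %s", label, paste(problems, collapse = "; ")),
         call. = FALSE)
  }
  report
}

#' Microfibril configuration
#'
#' Collects the geometric and compositional knobs of the substrate.  The
#' composition fractions select how many lattice sites each polymer gets
#' (every site carries a full axial chain, so site fractions equal monomer
#' fractions); the crystalline fractions and defect parameters drive
#' [assign_crystallinity()].
#'
#' @param n_bonds_per_chain Glycosidic bonds per chain (chain length minus
#'   one).  The full-size default used in the reference configuration is
#'   200; the bundled demo substrate uses 60.
#' @param cross_section Name of a species preset from [species_presets()].
#' @param frac_cellulose,frac_hemicellulose,frac_lignin Composition
#'   fractions, must sum to one.
#' @param crystalline_frac_cellulose,crystalline_frac_hemicellulose
#'   Crystalline fraction per polymer in \[0, 1\].
#' @param defect_density Expected amorphous defect patches per chain
#'   (Poisson mean).
#' @param defect_patch_length Monomers per defect patch.
#' @param end_amorphous_length Chain-end monomers treated as
#'   boundary-amorphous candidates first.
#' @param rng_seed Integer seed used by [new_fibril()].
#' @return A list of class `microfibril_config`.
#' @export
microfibril_config <- function(n_bonds_per_chain = 200,
                               cross_section = "demo",
                               frac_cellulose = 0.6,
                               frac_hemicellulose = 0.25,
                               frac_lignin = 0.15,
                               crystalline_frac_cellulose = 0.02,
                               crystalline_frac_hemicellulose = 0.02,
                               defect_density = 1,
                               defect_patch_length = 5,
                               end_amorphous_length = 2,
                               rng_seed = 1L) {
  stopifnot(n_bonds_per_chain >= 1,
            crystalline_frac_cellulose >= 0, crystalline_frac_cellulose <= 1,
            crystalline_frac_hemicellulose >= 0,
            crystalline_frac_hemicellulose <= 1,
            defect_density >= 0, defect_patch_length >= 1,
            end_amorphous_length >= 0)
  presets <- species_presets()
  if (!cross_section %in% presets$name) {
    stop(sprintf("unknown cross-section preset '%s' (available: %s)",
                 cross_section, paste(presets$name, collapse = ", ")),
         call. = FALSE)
  }
  validate_fractions(c(frac_cellulose, frac_hemicellulose, frac_lignin),
                     "substrate composition")
  structure(list(
    n_bonds_per_chain = as.integer(n_bonds_per_chain),
    cross_section = cross_section,
    frac_cellulose = frac_cellulose,
    frac_hemicellulose = frac_hemicellulose,
    frac_lignin = frac_lignin,
    crystalline_frac_cellulose = crystalline_frac_cellulose,
    crystalline_frac_hemicellulose = crystalline_frac_hemicellulose,
    defect_density = defect_density,
    defect_patch_length = as.integer(defect_patch_length),
    end_amorphous_length = as.integer(end_amorphous_length),
    rng_seed = as.integer(rng_seed)), class = "microfibril_config")
}

# Rectangular ring index of a site around the core rectangle:
# 0 inside the core, k on the k-th concentric ring.
.ring_index <- function(row, col, core_rows, core_cols) {
  dr <- pmax(0L, 1L - row, row - core_rows)
  dc <- pmax(0L, 1L - col, col - core_cols)
  pmax(dr, dc)
}

# All sites of ring k around an r x c core, as a matrix of (row, col).
.ring_sites <- function(k, r, c) {
  if (k == 0) {
    return(cbind(row = rep(seq_len(r), each = c),
                 col = rep(seq_len(c), times = r)))
  }
  rows <- (1 - k):(r + k)
  cols <- (1 - k):(c + k)
  top <- cbind(row = rows[1], col = cols)
  bottom <- cbind(row = rows[length(rows)], col = cols)
  mids <- rows[-c(1, length(rows))]
  left <- cbind(row = mids, col = cols[1])
  right <- cbind(row = mids, col = cols[length(cols)])
  m <- rbind(top, bottom, left, right)
  colnames(m) <- c("row", "col")
  m
}

#' Build the microfibril lattice
#'
#' Places the cellulose core on the innermost cross-section sites, wraps it
#' in hemicellulose rings and then lignin rings, choosing ring occupancy so
#' that the realised monomer fractions match the requested composition as
#' closely as the lattice allows.  Partially filled rings are realised by a
#' random (seeded via the current RNG state) subset of the ring's sites.
#' Every chain has `n_bonds_per_chain + 1` monomers; lignin sites carry
#' monolignol monomers with no cleavable bonds.
#'
#' @param config A [microfibril_config()].
#' @return An object of class `microfibril`; see Details.
#' @details The object is a list with elements `sites` (data frame: site id,
#'   row, col, polymer, ring), `L` (monomers per chain), logical matrices
#'   `in_fibril` and `crystalline` (sites x axial position), `bond_intact`
#'   (sites x L-1), a neighbour index matrix `nbr`, the initial per-polymer
#'   monomer counts, and the realised composition fractions.
#' @export
build_microfibril <- function(config) {
  stopifnot(inherits(config, "microfibril_config"))
  presets <- species_presets()
  p <- presets[presets$name == config$cross_section, ]
  r <- p$core_rows; c <- p$core_cols
  n_core <- r * c
  fc <- config$frac_cellulose
  fh <- config$frac_hemicellulose
  fl <- config$frac_lignin
  if (fc <= 0) {
    stop(paste0("composition infeasible: frac_cellulose must be > 0 so the ",
                "core bundle has chains (feasible range: frac_cellulose in ",
                "(0, 1], hemicellulose and lignin fractions in [0, 1) with ",
                "all three summing to 1)"), call. = FALSE)
  }
  n_hemi <- round(n_core * fh / fc)
  n_lig <- round(n_core * fl / fc)

  take_ring_sites <- function(n_needed, start_ring, leftover) {
    # Returns list(sites = matrix(row,col), next_ring, leftover) where
    # leftover are unoccupied sites of the last touched ring.
    out <- NULL
    k <- start_ring
    while (n_needed > 0) {
      avail <- leftover
      if (is.null(avail) || nrow(avail) == 0) {
        avail <- .ring_sites(k, r, c)
        k <- k + 1L
      }
      if (nrow(avail) <= n_needed) {
        out <- rbind(out, avail)
        n_needed <- n_needed - nrow(avail)
        leftover <- NULL
      } else {
        pick <- sample.int(nrow(avail), n_needed)
        out <- rbind(out, avail[pick, , drop = FALSE])
        leftover <- avail[-pick, , drop = FALSE]
        n_needed <- 0
      }
    }
    list(sites = out, next_ring = k, leftover = leftover)
  }

  core <- .ring_sites(0L, r, c)
  hemi <- take_ring_sites(n_hemi, 1L, NULL)
  lig <- take_ring_sites(n_lig, hemi$next_ring, hemi$leftover)

  all_sites <- rbind(core, hemi$sites, lig$sites)
  polymer <- c(rep("cellulose", nrow(core)),
               rep("hemicellulose", if (is.null(hemi$sites)) 0 else nrow(hemi$sites)),
               rep("lignin", if (is.null(lig$sites)) 0 else nrow(lig$sites)))
  n_sites <- nrow(all_sites)
  sites <- data.frame(site = seq_len(n_sites),
                      row = as.integer(all_sites[, "row"]),
                      col = as.integer(all_sites[, "col"]),
                      polymer = polymer,
                      ring = .ring_index(all_sites[, "row"], all_sites[, "col"],
                                         r, c),
                      stringsAsFactors = FALSE)

  L <- config$n_bonds_per_chain + 1L
  in_fibril <- matrix(TRUE, n_sites, L)
  crystalline <- matrix(NA, n_sites, L)
  bond_intact <- matrix(TRUE, n_sites, L - 1L)
  bond_intact[sites$polymer == "lignin", ] <- NA

  # 4-neighbour lookup: index of the occupied site at (row +- 1, col +- 1),
  # NA when that lattice position is unoccupied (fibril surface).
  key <- paste(sites$row, sites$col)
  lookup <- setNames(sites$site, key)
  nbr <- cbind(
    up    = unname(lookup[paste(sites$row - 1L, sites$col)]),
    down  = unname(lookup[paste(sites$row + 1L, sites$col)]),
    left  = unname(lookup[paste(sites$row, sites$col - 1L)]),
    right = unname(lookup[paste(sites$row, sites$col + 1L)]))

  counts <- c(cellulose = sum(polymer == "cellulose") * L,
              hemicellulose = sum(polymer == "hemicellulose") * L,
              lignin = sum(polymer == "lignin") * L)
  realized <- counts / sum(counts)

  structure(list(
    sites = sites, L = L, n_sites = n_sites,
    in_fibril = in_fibril, crystalline = crystalline,
    bond_intact = bond_intact, nbr = nbr,
    initial_counts = counts,
    realized_composition = realized,
    realized_amorphous = c(cellulose = NA_real_, hemicellulose = NA_real_),
    config = config), class = "microfibril")
}

#' Assign crystalline/amorphous phase to every monomer
#'
#' Amorphous material is placed first at the fibril boundaries -- chain-end
#' monomers, then monomers of boundary chains (sites with at least one
#' unoccupied lateral neighbour or a neighbour of a different polymer) --
#' and then as randomly seeded interior defect patches of
#' `defect_patch_length` monomers (patch count per chain ~
#' Poisson(`defect_density`), uniform axial start), until the realised
#' amorphous fraction reaches `1 - crystalline_frac` for that polymer.  The
#' final patch is truncated so the realised fraction stays within one
#' patch length of the target.  Uses the current RNG state.
#'
#' @param fibril A [build_microfibril()] result.
#' @param config The same [microfibril_config()].
#' @return The fibril with its `crystalline` matrix filled in and
#'   `realized_amorphous` recorded.
#' @export
assign_crystallinity <- function(fibril, config = fibril$config) {
  stopifnot(inherits(fibril, "microfibril"))
  L <- fibril$L
  for (poly in c("cellulose", "hemicellulose")) {
    rows <- which(fibril$sites$polymer == poly)
    if (length(rows) == 0) next
    cf <- if (poly == "cellulose") config$crystalline_frac_cellulose else
      config$crystalline_frac_hemicellulose
    n_mono <- length(rows) * L
    target <- round((1 - cf) * n_mono)
    amorph <- matrix(FALSE, length(rows), L)

    mark <- function(idx) {
      # idx: matrix cell indices into amorph; marks up to remaining target
      idx <- idx[!amorph[idx]]
      remaining <- target - sum(amorph)
      if (remaining <= 0 || length(idx) == 0) return(invisible(NULL))
      amorph[idx[seq_len(min(length(idx), remaining))]] <<- TRUE
      invisible(NULL)
    }

    # 1) chain ends
    e <- min(config$end_amorphous_length, L)
    if (e > 0) {
      ax <- c(seq_len(e), (L - e + 1L):L)
      ax <- unique(ax[ax >= 1 & ax <= L])
      cells <- as.vector(outer(seq_along(rows), (ax - 1L) * length(rows), "+"))
      mark(sample(cells))
    }
    # 2) boundary chains (site has a missing or different-polymer neighbour)
    nbr_poly <- matrix(fibril$sites$polymer[fibril$nbr[rows, , drop = FALSE]],
                       nrow = length(rows))
    is_boundary <- apply(is.na(fibril$nbr[rows, , drop = FALSE]) |
                           nbr_poly != poly, 1, any)
    if (any(is_boundary) && sum(amorph) < target) {
      brows <- which(is_boundary)
      cells <- as.vector(outer(brows, (seq_len(L) - 1L) * length(rows), "+"))
      mark(sample(cells))
    }
    # 3) Poisson defect patches per chain, then extra patches to the target
    plen <- config$defect_patch_length
    seed_patch <- function(chain) {
      start <- sample.int(L, 1)
      idx <- start:min(L, start + plen - 1L)
      mark(chain + (idx - 1L) * length(rows))
    }
    n_patches <- rpois(length(rows), config$defect_density)
    for (i in seq_along(rows)) {
      for (k in seq_len(n_patches[i])) {
        if (sum(amorph) >= target) break
        seed_patch(i)
      }
    }
    attempts <- 0L
    while (sum(amorph) < target && attempts < 100000L) {
      seed_patch(sample.int(length(rows), 1))
      attempts <- attempts + 1L
    }
    if (sum(amorph) < target) {
      # degenerate fallback: fill from remaining crystalline positions
      left <- which(!amorph)
      mark(sample(left))
      warning(sprintf(
        "amorphous target for %s reached only by non-patch filling", poly))
    }
    fibril$crystalline[rows, ] <- !amorph
    fibril$realized_amorphous[poly] <- sum(amorph) / n_mono
  }
  fibril
}

#' Build a fibril and assign its crystallinity in one seeded step
#'
#' Seeds the RNG from `config$rng_seed`, then calls [build_microfibril()]
#' and [assign_crystallinity()].  Identical configurations (including seed)
#' give bitwise-identical fibrils.
#'
#' @inheritParams build_microfibril
#' @return A `microfibril`.
#' @export
new_fibril <- function(config) {
  set.seed(config$rng_seed)
  assign_crystallinity(build_microfibril(config), config)
}

# Surface exposure: a monomer is exposed iff at least one of its six lattice
# neighbours (4 lateral at the same axial index, 2 axial along its own
# chain) is unoccupied by in-fibril material.  Occlusion of cellulose by
# hemicellulose/lignin sheaths, of hemicellulose by lignin, and of interior
# chains by outer chains all follow from this single rule, and removing
# material can only enlarge the exposed set.
exposed_monomers <- function(fibril) {
  inf <- fibril$in_fibril
  n <- nrow(inf); L <- ncol(inf)
  dummy <- rbind(inf, FALSE)           # row n+1 = "no site there"
  idx <- fibril$nbr
  idx[is.na(idx)] <- n + 1L
  lateral_full <- dummy[idx[, 1], , drop = FALSE] &
    dummy[idx[, 2], , drop = FALSE] &
    dummy[idx[, 3], , drop = FALSE] &
    dummy[idx[, 4], , drop = FALSE]
  left_full <- cbind(FALSE, inf[, -L, drop = FALSE])
  right_full <- cbind(inf[, -1, drop = FALSE], FALSE)
  inf & !(lateral_full & left_full & right_full)
}

#' Exposed intact bonds of the fibril
#'
#' A bond is exposed when both of its monomers are in the fibril, the bond
#' is intact, and both monomers sit on the fibril surface (at least one
#' unoccupied neighbouring lattice position).  Cellulose bonds buried under
#' hemicellulose or lignin sheaths, and interior-core bonds shielded by
#' outer chains, are not exposed; solubilising the covering material exposes
#' them.  Lignin surface monomers are always exposed (they have no bonds but
#' provide adsorption sites).
#'
#' @param fibril A `microfibril`.
#' @return Data frame with columns `site`, `bond` (bond i joins monomers i
#'   and i+1), `polymer`, `crystalline` (TRUE if either endpoint is
#'   crystalline).
#' @export
exposed_bonds <- function(fibril) {
  expo <- exposed_monomers(fibril)
  L <- fibril$L
  both <- fibril$bond_intact &
    fibril$in_fibril[, -L, drop = FALSE] & fibril$in_fibril[, -1, drop = FALSE] &
    expo[, -L, drop = FALSE] & expo[, -1, drop = FALSE]
  both[is.na(both)] <- FALSE
  idx <- which(both, arr.ind = TRUE)
  cr <- fibril$crystalline[cbind(idx[, 1], idx[, 2])] |
    fibril$crystalline[cbind(idx[, 1], idx[, 2] + 1L)]
  data.frame(site = fibril$sites$site[idx[, 1]],
             bond = as.integer(idx[, 2]),
             polymer = fibril$sites$polymer[idx[, 1]],
             crystalline = as.logical(cr),
             stringsAsFactors = FALSE)
}

#' Monomer census by polymer, phase and status
#'
#' @param fibril A `microfibril`.
#' @return Data frame with one row per polymer: initial, in-fibril and
#'   solubilized monomer counts plus in-fibril crystalline/amorphous
#'   splits.  Counts are conserved: in-fibril + solubilized equals the
#'   initial total for every polymer.
#' @export
composition_report <- function(fibril) {
  polys <- POLYMERS
  out <- lapply(polys, function(p) {
    rows <- fibril$sites$polymer == p
    inf <- fibril$in_fibril[rows, , drop = FALSE]
    cry <- fibril$crystalline[rows, , drop = FALSE]
    n_in <- sum(inf)
    data.frame(polymer = p, monomer = unname(SUGAR_OF[p]),
               initial = unname(fibril$initial_counts[p]),
               in_fibril = n_in,
               solubilized = unname(fibril$initial_counts[p]) - n_in,
               crystalline = if (p == "lignin") NA_integer_ else
                 sum(inf & cry, na.rm = TRUE),
               amorphous = if (p == "lignin") NA_integer_ else
                 sum(inf & !cry, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.microfibril <- function(x, ...) {
  cat(sprintf("<microfibril> %s cross-section, %d chains x %d monomers\n",
              x$config$cross_section, x$n_sites, x$L))
  comp <- x$realized_composition
  cat(sprintf("  composition (realised): cellulose %.3f, hemicellulose %.3f, lignin %.3f\n",
              comp["cellulose"], comp["hemicellulose"], comp["lignin"]))
  if (!is.na(x$realized_amorphous["cellulose"]))
    cat(sprintf("  amorphous fraction: cellulose %.3f, hemicellulose %s\n",
                x$realized_amorphous["cellulose"],
                ifelse(is.na(x$realized_amorphous["hemicellulose"]), "-",
                       sprintf("%.3f", x$realized_amorphous["hemicellulose"]))))
  invisible(x)
}
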