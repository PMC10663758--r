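# Gillespie engine: channel enumeration, event sampling, state update and
# time-course recording.
#
# The reaction channels at any instant are: EG cleavage of each exposed
# cellulose bond (amorphous at full rate, crystalline at the reduced
# factor), CBH run initiation at each exposed cellulose fragment end
# (fragments of >= 2 monomers), XYL cleavage of each exposed hemicellulose
# bond, and one solution channel for BGL hydrolysis of cellobiose.  After
# every event the full channel census is recomputed with vectorised matrix
# operations; at the lattice sizes the package targets this is cheaper and
# safer than incremental neighbourhood updates.

# Internal aggregated channel census.  Targets sharing a rate law are
# grouped into classes; each class stores its per-target propensity and the
# member cell indices, so the engine samples a class then a uniform member.
channel_census <- function(state) {
  fib <- state$fibril
  L <- fib$L
  inf <- fib$in_fibril
  expo <- exposed_monomers(fib)
  poly <- fib$sites$polymer
  cell <- poly == "cellulose"
  hemi <- poly == "hemicellulose"
  lign <- poly == "lignin"

  bi <- fib$bond_intact
  bi[is.na(bi)] <- FALSE
  conn <- bi & inf[, -L, drop = FALSE] & inf[, -1, drop = FALSE]
  bonds_ok <- conn & expo[, -L, drop = FALSE] & expo[, -1, drop = FALSE]
  cr <- fib$crystalline
  bond_cr <- cr[, -L, drop = FALSE] | cr[, -1, drop = FALSE]

  eg <- bonds_ok; eg[!cell, ] <- FALSE
  xy <- bonds_ok; xy[!hemi, ] <- FALSE
  eg_am <- eg & !bond_cr; eg_cr <- eg & bond_cr
  xy_am <- xy & !bond_cr; xy_cr <- xy & bond_cr

  prev_conn <- cbind(FALSE, conn)
  next_conn <- cbind(conn, FALSE)
  lend <- inf & expo & !prev_conn & next_conn
  rend <- inf & expo & !next_conn & prev_conn
  lend[!cell, ] <- FALSE; rend[!cell, ] <- FALSE
  # phase of the cellobiose pair a CBH run would remove first
  cr_next <- cbind(cr[, -1, drop = FALSE], NA)
  cr_prev <- cbind(NA, cr[, -L, drop = FALSE])
  lend_cr <- cr | cr_next
  rend_cr <- cr | cr_prev
  l_am <- lend & !lend_cr; l_cr <- lend & lend_cr
  r_am <- rend & !rend_cr; r_cr <- rend & rend_cr

  # steric exclusion against explicitly occupied intervals (normally none)
  bints <- state$bound_intervals
  filt <- function(mask, footprint) {
    if (is.null(bints) || NROW(bints) == 0) return(mask)
    for (m in which(mask)) {
      s <- (m - 1L) %% fib$n_sites + 1L
      b <- (m - 1L) %/% fib$n_sites + 1L
      if (steric_free(c(site = s, bond = b), bints, footprint,
                      fib$nbr) == 0) mask[m] <- FALSE
    }
    mask
  }
  enz <- state$enzymes
  eg_am <- filt(eg_am, enz$EG$footprint); eg_cr <- filt(eg_cr, enz$EG$footprint)
  xy_am <- filt(xy_am, enz$XYL$footprint); xy_cr <- filt(xy_cr, enz$XYL$footprint)
  l_am <- filt(l_am, enz$CBH$footprint); l_cr <- filt(l_cr, enz$CBH$footprint)
  r_am <- filt(r_am, enz$CBH$footprint); r_cr <- filt(r_cr, enz$CBH$footprint)

  V <- state$V
  pool_conc <- c(glucose = state$pool[["glucose"]] / V,
                 cellobiose = state$pool[["cellobiose"]] / V,
                 xylose = state$pool[["xylose"]] / V)
  lig_sites <- sum(expo[lign, , drop = FALSE])
  tot_sites <- sum(expo)
  cock <- state$cocktail
  E_free <- function(e) {
    cock$total_enzyme_concentration * cock$fractions[[e]] *
      free_enzyme_fraction(enz[[e]], lig_sites, tot_sites)
  }

  n <- list(eg_am = sum(eg_am), eg_cr = sum(eg_cr),
            xy_am = sum(xy_am), xy_cr = sum(xy_cr),
            l_am = sum(l_am), l_cr = sum(l_cr),
            r_am = sum(r_am), r_cr = sum(r_cr))

  rate_eg <- bond_propensity(enz$EG, E_free("EG"),
                             (n$eg_am + n$eg_cr) / V, pool_conc)
  rate_xy <- bond_propensity(enz$XYL, E_free("XYL"),
                             (n$xy_am + n$xy_cr) / V, pool_conc)
  n_ends <- n$l_am + n$l_cr + n$r_am + n$r_cr
  rate_cbh <- bond_propensity(enz$CBH, E_free("CBH"), n_ends / V, pool_conc)
  cb_count <- state$pool[["cellobiose"]]
  rate_bgl <- if (cb_count > 0)
    bond_propensity(enz$BGL, E_free("BGL"), pool_conc[["cellobiose"]],
                    pool_conc) else 0

  classes <- list(
    list(id = "EG_am", enzyme = "EG", type = "bond", side = NA,
         rate = rate_eg, a = n$eg_am * rate_eg, members = which(eg_am)),
    list(id = "EG_cr", enzyme = "EG", type = "bond", side = NA,
         rate = rate_eg * enz$EG$crystalline_rate_factor,
         a = n$eg_cr * rate_eg * enz$EG$crystalline_rate_factor,
         members = which(eg_cr)),
    list(id = "CBH_am_L", enzyme = "CBH", type = "end", side = "L",
         rate = rate_cbh, a = n$l_am * rate_cbh, members = which(l_am)),
    list(id = "CBH_cr_L", enzyme = "CBH", type = "end", side = "L",
         rate = rate_cbh * enz$CBH$crystalline_rate_factor,
         a = n$l_cr * rate_cbh * enz$CBH$crystalline_rate_factor,
         members = which(l_cr)),
    list(id = "CBH_am_R", enzyme = "CBH", type = "end", side = "R",
         rate = rate_cbh, a = n$r_am * rate_cbh, members = which(r_am)),
    list(id = "CBH_cr_R", enzyme = "CBH", type = "end", side = "R",
         rate = rate_cbh * enz$CBH$crystalline_rate_factor,
         a = n$r_cr * rate_cbh * enz$CBH$crystalline_rate_factor,
         members = which(r_cr)),
    list(id = "XYL_am", enzyme = "XYL", type = "bond", side = NA,
         rate = rate_xy, a = n$xy_am * rate_xy, members = which(xy_am)),
    list(id = "XYL_cr", enzyme = "XYL", type = "bond", side = NA,
         rate = rate_xy * enz$XYL$crystalline_rate_factor,
         a = n$xy_cr * rate_xy * enz$XYL$crystalline_rate_factor,
         members = which(xy_cr)),
    list(id = "BGL", enzyme = "BGL", type = "solution", side = NA,
         rate = rate_bgl, a = cb_count * rate_bgl, members = integer(0)))
  classes
}

#' Initialise a simulation state
#'
#' Builds the microfibril for one sample of a parameter document (geometry,
#' layers and crystallinity use the current RNG state), sets up the product
#' pool and enzyme cocktail, and records the initial monomer totals used by
#' [conversion_percent()].
#'
#' @param params A validated `sacch_params` document.
#' @param sample Index of the initial-configuration section to use.
#' @return A list of class `sacch_state`.
#' @export
new_state <- function(params, sample = 1) {
  params <- validate_document(params)
  sim <- params$simulation
  cfg <- params$samples[[sample]]
  fc <- microfibril_config(
    n_bonds_per_chain = sim$n_bonds_per_chain,
    cross_section = cfg$species_preset,
    frac_cellulose = cfg$frac_cellulose,
    frac_hemicellulose = cfg$frac_hemicellulose,
    frac_lignin = cfg$frac_lignin,
    crystalline_frac_cellulose = cfg$crystalline_frac_cellulose,
    crystalline_frac_hemicellulose = cfg$crystalline_frac_hemicellulose,
    defect_density = cfg$defect_density,
    defect_patch_length = cfg$defect_patch_length,
    end_amorphous_length = cfg$end_amorphous_length,
    rng_seed = sim$rng_seed)
  fib <- assign_crystallinity(build_microfibril(fc), fc)
  pool <- c(glucose = cfg$initial_glucose,
            cellobiose = cfg$initial_cellobiose,
            xylose = cfg$initial_xylose)
  cock <- cocktail_spec(cfg$total_enzyme_concentration,
                        c(EG = cfg$frac_EG, CBH = cfg$frac_CBH,
                          BGL = cfg$frac_BGL, XYL = cfg$frac_XYL))
  structure(list(
    fibril = fib, pool = pool, clock = 0,
    enzymes = enzymes_from_kinetic(params$kinetic),
    cocktail = cock,
    V = sim$reaction_volume,
    cutoff = sim$solubilization_cutoff,
    bound_intervals = NULL,
    initial_pool = pool,
    initial_fibril = fib$initial_counts,
    n_events = 0L), class = "sacch_state")
}

#' Enumerate all reaction channels of a state
#'
#' Reference enumeration used for testing and inspection: one row per
#' (enzyme, actable target) plus the BGL solution channel, with the
#' per-target propensity.  An empty frame means the state is absorbing.
#'
#' @param state A `sacch_state`.
#' @return Data frame with columns `channel`, `enzyme`, `type`, `site`,
#'   `index`, `side`, `propensity`.
#' @export
enumerate_channels <- function(state) {
  classes <- channel_census(state)
  n_sites <- state$fibril$n_sites
  rows <- lapply(classes, function(cl) {
    if (cl$type == "solution") {
      if (cl$a <= 0) return(NULL)
      return(data.frame(channel = cl$id, enzyme = cl$enzyme, type = cl$type,
                        site = NA_integer_, index = NA_integer_,
                        side = NA_character_,
                        propensity = cl$a, stringsAsFactors = FALSE))
    }
    if (length(cl$members) == 0 || cl$rate <= 0) return(NULL)
    s <- (cl$members - 1L) %% n_sites + 1L
    i <- (cl$members - 1L) %/% n_sites + 1L
    data.frame(channel = cl$id, enzyme = cl$enzyme, type = cl$type,
               site = s, index = i,
               side = if (is.na(cl$side)) NA_character_ else cl$side,
               propensity = cl$rate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(channel = character(0), enzyme = character(0),
                      type = character(0), site = integer(0),
                      index = integer(0), side = character(0),
                      propensity = numeric(0), stringsAsFactors = FALSE)
  }
  out
}

#' Draw the next Gillespie event
#'
#' Samples the waiting time `dt ~ Exponential(a0)` (`a0` the summed
#' propensity) and one channel with probability proportional to its
#' propensity, using the current RNG state.
#'
#' @param channels Data frame from [enumerate_channels()].
#' @return `list(finished = TRUE)` when no reaction is possible, otherwise
#'   `list(finished = FALSE, channel = <row>, dt = <hours>)`.
#' @export
draw_event <- function(channels) {
  a0 <- sum(channels$propensity)
  if (!is.finite(a0) || a0 <= 0) return(list(finished = TRUE))
  dt <- rexp(1, a0)
  i <- sample.int(nrow(channels), 1, prob = channels$propensity)
  list(finished = FALSE, channel = channels[i, , drop = FALSE], dt = dt)
}

# --- event application -----------------------------------------------------

# Maximal intact fragment of the chain at `site` containing monomer `a`.
.fragment_extent <- function(fib, site, a) {
  inf <- fib$in_fibril[site, ]
  bi <- fib$bond_intact[site, ]
  lo <- a
  while (lo > 1 && isTRUE(bi[lo - 1]) && inf[lo - 1]) lo <- lo - 1
  hi <- a
  while (hi < fib$L && isTRUE(bi[hi]) && inf[hi + 1]) hi <- hi + 1
  c(lo, hi)
}

# Remove fragment [lo, hi] from the fibril and credit the product pool.
.solubilize <- function(state, site, lo, hi) {
  len <- hi - lo + 1L
  state$fibril$in_fibril[site, lo:hi] <- FALSE
  poly <- state$fibril$sites$polymer[site]
  if (poly == "cellulose") {
    state$pool[["cellobiose"]] <- state$pool[["cellobiose"]] + len %/% 2
    state$pool[["glucose"]] <- state$pool[["glucose"]] + len %% 2
  } else if (poly == "hemicellulose") {
    state$pool[["xylose"]] <- state$pool[["xylose"]] + len
  }
  state
}

.apply_cleave <- function(state, site, b) {
  fib <- state$fibril
  if (!isTRUE(fib$bond_intact[site, b]) ||
      !fib$in_fibril[site, b] || !fib$in_fibril[site, b + 1L])
    stop("stale channel: bond no longer intact", call. = FALSE)
  state$fibril$bond_intact[site, b] <- FALSE
  left <- .fragment_extent(state$fibril, site, b)
  right <- .fragment_extent(state$fibril, site, b + 1L)
  if (left[2] - left[1] + 1L <= state$cutoff)
    state <- .solubilize(state, site, left[1], left[2])
  if (right[2] - right[1] + 1L <= state$cutoff)
    state <- .solubilize(state, site, right[1], right[2])
  state
}

.apply_cbh <- function(state, site, a, side) {
  fib <- state$fibril
  if (!fib$in_fibril[site, a]) stop("stale channel: end gone", call. = FALSE)
  ext <- .fragment_extent(fib, site, a)
  lo <- ext[1]; hi <- ext[2]
  enz <- state$enzymes$CBH
  p_cont <- 1 - 1 / enz$processivity
  f_cr <- enz$crystalline_rate_factor
  first <- TRUE
  repeat {
    len <- hi - lo + 1L
    if (len < 2L) break
    pair <- if (side == "L") c(lo, lo + 1L) else c(hi - 1L, hi)
    cr_pair <- isTRUE(any(state$fibril$crystalline[site, pair]))
    if (!first) {
      if (runif(1) >= p_cont) break
      if (cr_pair && runif(1) >= f_cr) break
    }
    if (side == "L") {
      if (len > 2L) state$fibril$bond_intact[site, lo + 1L] <- FALSE
      state$fibril$in_fibril[site, pair] <- FALSE
      lo <- lo + 2L
    } else {
      if (len > 2L) state$fibril$bond_intact[site, hi - 2L] <- FALSE
      state$fibril$in_fibril[site, pair] <- FALSE
      hi <- hi - 2L
    }
    state$pool[["cellobiose"]] <- state$pool[["cellobiose"]] + 1
    first <- FALSE
  }
  len <- hi - lo + 1L
  if (len >= 1L && len <= state$cutoff && lo <= hi &&
      any(state$fibril$in_fibril[site, lo:hi]))
    state <- .solubilize(state, site, lo, hi)
  state
}

#' Apply one reaction event to the state
#'
#' EG: cleaves the bond and solubilises resulting fragments at or below the
#' solubilisation cutoff (soluble cello-oligomers are booked as cellobiose
#' plus glucose equivalents).  CBH: executes a processive run from the
#' chain end, releasing one cellobiose per step; the run ends by the
#' geometric continuation draw (mean length = processivity), at a
#' crystalline step failure, or at the fragment end.  BGL: cellobiose - 1,
#' glucose + 2.  XYL: cleaves the hemicellulose bond; solubilised fragments
#' enter the pool as xylose monomer equivalents.
#'
#' @param state A `sacch_state`.
#' @param channel One-row data frame (a row of [enumerate_channels()]) or a
#'   list with fields `enzyme`, `type`, `site`, `index`, `side`.
#' @return The updated state.
#' @export
apply_event <- function(state, channel) {
  enzyme <- channel$enzyme
  if (enzyme == "BGL") {
    if (state$pool[["cellobiose"]] < 1)
      stop("stale channel: no cellobiose left", call. = FALSE)
    state$pool[["cellobiose"]] <- state$pool[["cellobiose"]] - 1
    state$pool[["glucose"]] <- state$pool[["glucose"]] + 2
  } else if (enzyme %in% c("EG", "XYL")) {
    state <- .apply_cleave(state, channel$site, channel$index)
  } else if (enzyme == "CBH") {
    state <- .apply_cbh(state, channel$site, channel$index, channel$side)
  } else {
    stop(sprintf("unknown enzyme '%s'", enzyme), call. = FALSE)
  }
  state$n_events <- state$n_events + 1L
  state
}

#' Conversion percentage of a polymer
#'
#' Solubilised monomer equivalents as a percentage of the initial in-fibril
#' monomer count of that sugar type; cellobiose counts as two glucose
#' equivalents toward glucan conversion.  Initial (pre-loaded) pool
#' contents do not count as conversion.
#'
#' @param state A `sacch_state`.
#' @param polymer `"cellulose"` (alias `"glucose"`) or `"hemicellulose"`
#'   (alias `"xylose"`); lignin is not converted and is rejected.
#' @return Percentage in \[0, 100\] (NA when the fibril contains none of
#'   the polymer).
#' @export
conversion_percent <- function(state, polymer) {
  polymer <- match.arg(polymer, c("cellulose", "glucose", "hemicellulose",
                                  "xylose", "lignin"))
  if (polymer == "lignin")
    stop("lignin is not converted; conversion is undefined", call. = FALSE)
  if (polymer %in% c("cellulose", "glucose")) {
    init <- state$initial_fibril[["cellulose"]]
    if (init == 0) return(NA_real_)
    sol <- (state$pool[["glucose"]] - state$initial_pool[["glucose"]]) +
      2 * (state$pool[["cellobiose"]] - state$initial_pool[["cellobiose"]])
  } else {
    init <- state$initial_fibril[["hemicellulose"]]
    if (init == 0) return(NA_real_)
    sol <- state$pool[["xylose"]] - state$initial_pool[["xylose"]]
  }
  100 * sol / init
}

#' Run one stochastic saccharification trajectory
#'
#' Seeds the RNG, builds the sample's microfibril, and iterates the
#' Gillespie draw/apply loop until the clock reaches `t_end`, no channel
#' remains, or the event cap is hit.  Glucose and xylose conversions and
#' per-enzyme event counts are recorded at fixed intervals.
#'
#' @param params A `sacch_params` document.
#' @param seed Integer seed (defaults to the document's `rng_seed`).
#' @param t_end Simulation horizon in hours (defaults to the document's).
#' @param record_interval Recording interval in hours.
#' @param sample Which initial-configuration section to simulate.
#' @return A data frame of class `sacch_timecourse` with columns `time`,
#'   `glucose_conversion`, `xylose_conversion` and `events_EG`,
#'   `events_CBH`, `events_BGL`, `events_XYL` (events per recording
#'   window); the final `sacch_state` is attached as attribute `state`.
#' @export
run_simulation <- function(params, seed = NULL, t_end = NULL,
                           record_interval = NULL, sample = 1) {
  params <- validate_document(params)
  sim <- params$simulation
  if (is.null(seed)) seed <- sim$rng_seed
  if (is.null(t_end)) t_end <- sim$t_end
  if (is.null(record_interval)) record_interval <- sim$record_interval
  if (!is.finite(t_end) || t_end <= 0)
    stop("t_end must be > 0", call. = FALSE)
  set.seed(as.integer(seed) %% 2147483647L)
  state <- new_state(params, sample = sample)

  rec <- seq(0, t_end, by = record_interval)
  if (tail(rec, 1) < t_end) rec <- c(rec, t_end)
  nrec <- length(rec)
  glc <- xyl <- numeric(nrec)
  ev <- matrix(0L, nrec, 4, dimnames = list(NULL, ENZYMES))
  snap <- function(i) {
    glc[i] <<- conversion_percent(state, "glucose")
    xyl[i] <<- conversion_percent(state, "xylose")
  }
  win <- setNames(integer(4), ENZYMES)
  snap(1)
  ri <- 2L
  flush_until <- function(t_next) {
    while (ri <= nrec && rec[ri] < t_next) {
      snap(ri); ev[ri, ] <<- win; win[] <<- 0L
      ri <<- ri + 1L
    }
  }
  repeat {
    if (state$n_events >= sim$max_events) break
    classes <- channel_census(state)
    a <- vapply(classes, `[[`, numeric(1), "a")
    a0 <- sum(a)
    if (a0 <= 0) break
    dt <- rexp(1, a0)
    t_new <- state$clock + dt
    if (t_new > t_end) { flush_until(Inf); state$clock <- t_end; break }
    flush_until(t_new)
    ci <- sample.int(length(a), 1, prob = a)
    cl <- classes[[ci]]
    if (cl$type == "solution") {
      ch <- list(enzyme = cl$enzyme, type = cl$type,
                 site = NA, index = NA, side = NA)
    } else {
      m <- cl$members[[if (length(cl$members) == 1) 1 else
        sample.int(length(cl$members), 1)]]
      ch <- list(enzyme = cl$enzyme, type = cl$type,
                 site = (m - 1L) %% state$fibril$n_sites + 1L,
                 index = (m - 1L) %/% state$fibril$n_sites + 1L,
                 side = cl$side)
    }
    state <- apply_event(state, ch)
    state$clock <- t_new
    win[ch$enzyme] <- win[ch$enzyme] + 1L
  }
  flush_until(Inf)
  out <- data.frame(time = rec, glucose_conversion = glc,
                    xylose_conversion = xyl,
                    events_EG = ev[, "EG"], events_CBH = ev[, "CBH"],
                    events_BGL = ev[, "BGL"], events_XYL = ev[, "XYL"])
  attr(out, "seed") <- seed
  attr(out, "sample") <- sample
  attr(out, "sample_name") <- params$samples[[sample]]$sample_name
  attr(out, "state") <- state
  class(out) <- c("sacch_timecourse", "data.frame")
  out
}

#' Average several replicate trajectories
#'
#' @param params A `sacch_params` document.
#' @param seeds Integer vector of seeds, one per replicate.
#' @param ... Passed to [run_simulation()].
#' @return A `sacch_timecourse` with the element-wise mean of conversions
#'   and event counts over replicates.
#' @export
simulate_replicates <- function(params, seeds, ...) {
  runs <- lapply(seeds, function(s) run_simulation(params, seed = s, ...))
  out <- runs[[1]]
  num <- setdiff(names(out), "time")
  for (cn in num) {
    out[[cn]] <- rowMeans(do.call(cbind, lapply(runs, `[[`, cn)))
  }
  attr(out, "seed") <- seeds
  attr(out, "state") <- NULL
  attr(out, "replicates") <- length(seeds)
  class(out) <- c("sacch_timecourse", "data.frame")
  out
}

#' Per-enzyme relative activity
#'
#' Events per recording window, normalised for each enzyme by its own
#' trajectory maximum (an enzyme that never acted stays at zero).
#'
#' @param timecourse A `sacch_timecourse`.
#' @return Data frame with `time` and one column per enzyme in \[0, 1\].
#' @export
relative_activity <- function(timecourse) {
  out <- data.frame(time = timecourse$time)
  for (e in ENZYMES) {
    v <- timecourse[[paste0("events_", e)]]
    m <- max(v)
    out[[e]] <- if (m > 0) v / m else v * 0
  }
  out
}

#' @export
print.sacch_timecourse <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<sacch_timecourse> %d records over %.3g h%s\n", n,
              x$time[n],
              if (!is.null(attr(x, "replicates")))
                sprintf(" (mean of %d replicates)", attr(x, "replicates"))
              else ""))
  cat(sprintf("  final conversion: glucose %.2f%%, xylose %s\n",
              x$glucose_conversion[n],
              if (is.na(x$xylose_conversion[n])) "-" else
                sprintf("%.2f%%", x$xylose_conversion[n])))
  invisible(x)
}

#' @export
plot.sacch_timecourse <- function(x, which = c("conversion", "activity"),
                                  ...) {
  which <- match.arg(which)
  if (which == "conversion") {
    matplot(x$time, cbind(x$glucose_conversion, x$xylose_conversion),
            type = "l", lty = 1, col = c("darkgreen", "goldenrod"),
            xlab = "time [h]", ylab = "conversion [%]", ylim = c(0, 100),
            ...)
    legend("topleft", c("glucose", "xylose"), lty = 1,
           col = c("darkgreen", "goldenrod"), bty = "n")
  } else {
    act <- relative_activity(x)
    matplot(act$time, as.matrix(act[, ENZYMES]), type = "l", lty = 1,
            xlab = "time [h]", ylab = "relative activity", ...)
    legend("topright", ENZYMES, lty = 1, col = seq_along(ENZYMES), bty = "n")
  }
  invisible(x)
}
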