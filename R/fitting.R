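# Fitting: hybrid random/directed generational search matching simulated
# glucan/xylan conversion curves to experimental time courses.
#
# Chosen parameters p_i are optimised over generations; within a
# generation, N_subsets candidate sets ("sub-generations") are evaluated.
# In random mode each fitted parameter is drawn uniformly in
# [p (1 - delta), p (1 + delta)] (clipped to its legal range, with
# distribution-constrained groups re-normalised to sum one).  When a
# generation improves on the previous best, its winning displacement
# vector defines a directed line search for the next generation; when it
# does not, the search reverts to the previous best and re-randomises.
# The reported optimum is the minimum over every sub-generation ever
# evaluated.

#' Mean squared deviation between simulation and experiment
#'
#' The simulated (replicate-averaged) conversion curve is linearly
#' interpolated at the experimental time points; the returned objective is
#' the mean of the squared deviations.  Multi-series objectives sum this
#' quantity over all series of all samples.
#'
#' @param simulated A `sacch_timecourse` (typically from
#'   [simulate_replicates()]).
#' @param experimental Data frame with columns `time` and `conversion`.
#' @param sugar Which simulated series to compare: `"glucose"` or
#'   `"xylose"`.
#' @return Non-negative scalar.
#' @export
series_variance <- function(simulated, experimental, sugar = "glucose") {
  sugar <- match.arg(sugar, c("glucose", "xylose"))
  col <- paste0(sugar, "_conversion")
  if (max(experimental$time) > max(simulated$time) + 1e-9)
    stop("experimental time extends beyond the simulation horizon",
         call. = FALSE)
  sim_y <- approx(simulated$time, simulated[[col]],
                  xout = experimental$time, rule = 1)$y
  mean((experimental$conversion - sim_y)^2)
}

#' Coefficient of determination of a fit
#'
#' `1 - SS_res / SS_tot` evaluated at the experimental time points, with
#' the simulated curve linearly interpolated.
#'
#' @inheritParams series_variance
#' @return Scalar <= 1.
#' @export
r_squared <- function(simulated, experimental, sugar = "glucose") {
  if (nrow(experimental) < 2)
    stop("need at least two experimental points", call. = FALSE)
  ss_tot <- sum((experimental$conversion - mean(experimental$conversion))^2)
  if (ss_tot <= 0)
    stop("experimental series has zero variance; R^2 undefined",
         call. = FALSE)
  col <- paste0(match.arg(sugar, c("glucose", "xylose")), "_conversion")
  sim_y <- approx(simulated$time, simulated[[col]],
                  xout = experimental$time, rule = 1)$y
  1 - sum((experimental$conversion - sim_y)^2) / ss_tot
}

#' Propose the sub-generations of one generation
#'
#' Random mode (`direction = NULL`): each fitted parameter is drawn
#' uniformly in `[p (1 - delta), p (1 + delta)]`.  Directed mode: the
#' proposals lie along the supplied displacement vector at integer scales
#' 1..N_subsets.  Either way proposals are clipped to their legal ranges
#' and distribution-constrained groups are re-normalised to sum one.
#'
#' @param current Named numeric vector of current parameter values.
#' @param delta Relative half-range in (0, 1\].
#' @param n_subsets Number of proposals.
#' @param direction Optional displacement vector (same names as
#'   `current`) from the previous improving step.
#' @param lower,upper Legal range per parameter.
#' @param renormalize Function applied to each proposal (used to restore
#'   sum-to-one groups); defaults to identity.
#' @return List of `n_subsets` named vectors.
#' @export
propose_subgenerations <- function(current, delta, n_subsets,
                                   direction = NULL,
                                   lower = rep(-Inf, length(current)),
                                   upper = rep(Inf, length(current)),
                                   renormalize = identity) {
  stopifnot(delta >= 0, delta <= 1, n_subsets >= 1)
  clip <- function(x) pmin(pmax(x, lower), upper)
  lapply(seq_len(n_subsets), function(k) {
    if (is.null(direction)) {
      half <- abs(current) * delta
      prop <- current + runif(length(current), -half, half)
    } else {
      prop <- current + k * direction
    }
    renormalize(setNames(clip(prop), names(current)))
  })
}

#' Hybrid random/directed generational minimiser
#'
#' Generic driver used by [run_fit()]; the objective can be any function
#' of a named parameter vector (e.g. a surrogate for testing).  The
#' accepted-generation best objective is non-increasing by construction,
#' and the returned optimum is the minimum over every evaluation.
#'
#' @param par Named numeric starting vector.
#' @param fn Objective function (vector in, scalar out); evaluations that
#'   fail score `+Inf` and the search continues.
#' @param lower,upper Legal range per parameter.
#' @param delta Relative proposal half-range in (0, 1\].
#' @param n_gens Number of generations.
#' @param n_subsets Sub-generations per generation.
#' @param renormalize Proposal post-processor (see
#'   [propose_subgenerations()]).
#' @param verbose Progress messages.
#' @return List with `par` (best vector), `value`, `trace` (per-generation
#'   data frame), `evals` (full evaluation log) and `params` (matrix of
#'   every evaluated vector).
#' @export
generational_search <- function(par, fn, lower, upper, delta = 0.25,
                                n_gens = 30, n_subsets = 8,
                                renormalize = identity, verbose = FALSE) {
  stopifnot(n_gens >= 1, n_subsets >= 1, length(par) >= 1)
  safe_fn <- function(p) {
    v <- tryCatch(fn(p), error = function(e) {
      warning(sprintf("objective evaluation failed (%s); scored +Inf",
                      conditionMessage(e)), call. = FALSE)
      Inf
    })
    if (!is.finite(v) && !identical(v, Inf)) Inf else v
  }
  f0 <- safe_fn(par)
  evals <- list(list(generation = 0L, subgen = 0L, value = f0))
  pmat <- matrix(par, nrow = 1, dimnames = list(NULL, names(par)))
  seed_par <- par; seed_val <- f0
  best_par <- par; best_val <- f0
  direction <- NULL
  trace <- vector("list", n_gens)
  for (g in seq_len(n_gens)) {
    props <- propose_subgenerations(seed_par, delta, n_subsets,
                                    direction = direction,
                                    lower = lower, upper = upper,
                                    renormalize = renormalize)
    vals <- vapply(props, safe_fn, numeric(1))
    for (k in seq_len(n_subsets)) {
      evals[[length(evals) + 1L]] <- list(generation = g, subgen = k,
                                          value = vals[k])
    }
    pmat <- rbind(pmat, do.call(rbind, props))
    k_min <- which.min(vals)
    gen_best <- vals[k_min]
    accepted <- is.finite(gen_best) && gen_best < seed_val
    mode <- if (is.null(direction)) "random" else "directed"
    if (accepted) {
      direction <- props[[k_min]] - seed_par
      seed_par <- props[[k_min]]
      seed_val <- gen_best
    } else {
      direction <- NULL
    }
    if (gen_best < best_val) {
      best_val <- gen_best; best_par <- props[[k_min]]
    }
    trace[[g]] <- data.frame(generation = g, mode = mode,
                             best_subgen = k_min, variance = gen_best,
                             accepted = accepted,
                             seed_variance = seed_val,
                             stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("generation %d (%s): best subgen %d, variance %.6g%s",
                      g, mode, k_min, gen_best,
                      if (accepted) " *" else ""))
  }
  evals <- do.call(rbind, lapply(evals, as.data.frame))
  list(par = best_par, value = best_val,
       trace = do.call(rbind, trace), evals = evals, params = pmat)
}

# --- fit specification and packing ----------------------------------------

.fittable_names <- function(section) {
  sch <- schema_section(section)
  sch$name[sch$type %in% c("real", "int")]
}

.pack_start <- function(params, fit_kinetic, fit_config) {
  theta <- numeric(0)
  for (nm in fit_kinetic) theta[nm] <- params$kinetic[[nm]]
  for (k in seq_along(params$samples)) {
    for (nm in fit_config) {
      theta[sprintf("%s@%d", nm, k)] <- params$samples[[k]][[nm]]
    }
  }
  theta
}

.theta_bounds <- function(theta_names) {
  sch <- parameter_schema()
  base <- sub("@[0-9]+$", "", theta_names)
  idx <- match(base, sch$name)
  list(lower = sch$min[idx], upper = sch$max[idx])
}

.unpack_theta <- function(params, theta) {
  for (nm in names(theta)) {
    if (grepl("@", nm)) {
      parts <- strsplit(nm, "@", fixed = TRUE)[[1]]
      k <- as.integer(parts[2])
      params$samples[[k]][[parts[1]]] <- unname(theta[nm])
    } else {
      params$kinetic[[nm]] <- unname(theta[nm])
    }
  }
  params
}

# Restore sum-to-one fraction groups in a proposal: fitted members of a
# group are rescaled so the group (including unfitted, fixed members) sums
# to one.
.make_renormalizer <- function(params, theta_names) {
  jobs <- list()
  for (k in seq_along(params$samples)) {
    for (g in names(FRACTION_GROUPS)) {
      members <- FRACTION_GROUPS[[g]]
      tn <- sprintf("%s@%d", members, k)
      fitted_in <- tn %in% theta_names
      if (!any(fitted_in)) next
      fixed_sum <- sum(unlist(params$samples[[k]][members[!fitted_in]]))
      jobs[[length(jobs) + 1L]] <- list(names = tn[fitted_in],
                                        target = 1 - fixed_sum)
    }
  }
  if (length(jobs) == 0) return(identity)
  function(theta) {
    for (job in jobs) {
      v <- pmin(pmax(theta[job$names], 0), 1)
      s <- sum(v)
      theta[job$names] <- if (s > 0) v * job$target / s else
        rep(job$target / length(v), length(v))
    }
    theta
  }
}

#' Specify a fit
#'
#' @param params Starting `sacch_params` document; its samples (1-5) give
#'   the per-sample starting initial configurations, its kinetic section
#'   the shared starting kinetics.
#' @param samples Named list (one entry per document sample, same order)
#'   of lists with elements `glucose` and/or `xylose`: experimental series
#'   data frames (columns `time`, `conversion`) as returned by
#'   [read_timecourse_tsv()].
#' @param fit_kinetic Character vector of kinetic parameter names to fit
#'   (shared across samples).
#' @param fit_config Character vector of initial-configuration parameter
#'   names to fit (independently per sample).
#' @param delta Relative proposal half-range in (0, 1\].
#' @param n_gens,n_subsets,replicates Search settings: generations,
#'   sub-generations per generation, trajectories averaged per evaluation.
#' @param seed Integer seed controlling the whole fit.
#' @param t_end Simulation horizon; defaults to the latest experimental
#'   time point.
#' @return List of class `sacch_fit_spec`.
#' @export
fit_spec <- function(params, samples, fit_kinetic = character(0),
                     fit_config = character(0), delta = 0.25,
                     n_gens = 30, n_subsets = 8, replicates = 3,
                     seed = 1, t_end = NULL) {
  params <- validate_document(params)
  if (length(samples) < 1 || length(samples) > 5)
    stop("between one and five samples are supported (got ",
         length(samples), ")", call. = FALSE)
  if (length(samples) != length(params$samples))
    stop("document must have one initial-configuration section per sample",
         call. = FALSE)
  stopifnot(delta > 0 || length(c(fit_kinetic, fit_config)) == 0,
            delta <= 1, n_gens >= 1, n_subsets >= 1, replicates >= 1)
  bad <- setdiff(fit_kinetic, .fittable_names("kinetic"))
  if (length(bad)) stop("not fittable kinetic parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(fit_config, .fittable_names("config"))
  if (length(bad)) stop("not fittable configuration parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  t_max <- 0
  for (s in samples) {
    for (sugar in c("glucose", "xylose")) {
      if (!is.null(s[[sugar]])) {
        ser <- s[[sugar]]
        stopifnot(is.data.frame(ser), all(c("time", "conversion") %in%
                                            names(ser)))
        if (any(diff(ser$time) <= 0))
          stop("experimental times must be strictly increasing",
               call. = FALSE)
        t_max <- max(t_max, max(ser$time))
      }
    }
  }
  if (t_max <= 0) stop("no experimental series supplied", call. = FALSE)
  if (is.null(t_end)) t_end <- t_max
  if (t_end < t_max)
    stop("t_end must cover the experimental time range", call. = FALSE)
  structure(list(params = params, samples = samples,
                 fit_kinetic = fit_kinetic, fit_config = fit_config,
                 delta = delta, n_gens = n_gens, n_subsets = n_subsets,
                 replicates = replicates, seed = as.integer(seed),
                 t_end = t_end), class = "sacch_fit_spec")
}

# The simulation seeds are frozen across candidate evaluations (common
# random numbers): every sub-generation is scored against the same
# replicate noise realisation, so comparisons between candidates reflect
# their parameter values rather than sampling noise.  Without this, the
# minimum over hundreds of noisy evaluations systematically fits the
# noise (winner's curse) instead of the data.
.fit_objective <- function(spec) {
  function(theta) {
    doc <- .unpack_theta(spec$params, theta)
    total <- 0
    for (k in seq_along(spec$samples)) {
      seeds <- (spec$seed * 97L + seq_len(spec$replicates) * 7919L +
                  k * 13L) %% 21474832L
      sim <- simulate_replicates(doc, seeds, t_end = spec$t_end, sample = k)
      for (sugar in c("glucose", "xylose")) {
        ser <- spec$samples[[k]][[sugar]]
        if (!is.null(ser)) total <- total + series_variance(sim, ser, sugar)
      }
    }
    total
  }
}

#' Fit model parameters to experimental time courses
#'
#' Runs the hybrid random/directed generational search on the summed
#' per-series mean squared deviation.  Kinetic parameters are shared
#' across samples in every proposal; initial-configuration parameters vary
#' per sample, and the returned per-sample configurations are distinct
#' records even when numerically equal.
#'
#' @param spec A [fit_spec()].
#' @param verbose Progress messages.
#' @return An object of class `sacch_fit` with components `par` (best
#'   fitted vector), `params` (best-fit parameter document), `value`
#'   (best variance), `trace`, `evals`, `r_squared` (per fitted series),
#'   `fitted_curves` and the spec; methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`, `fitted`, `simulate`.
#' @export
run_fit <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sacch_fit_spec"))
  theta0 <- .pack_start(spec$params, spec$fit_kinetic, spec$fit_config)
  fn <- .fit_objective(spec)
  set.seed(spec$seed)
  if (length(theta0) == 0) {
    v0 <- fn(numeric(0))
    res <- list(par = theta0, value = v0,
                trace = data.frame(generation = 1L, mode = "none",
                                   best_subgen = 0L, variance = v0,
                                   accepted = FALSE, seed_variance = v0),
                evals = data.frame(generation = 0L, subgen = 0L,
                                   value = v0),
                params = matrix(numeric(0), nrow = 1))
  } else {
    b <- .theta_bounds(names(theta0))
    res <- generational_search(
      theta0, fn, lower = b$lower, upper = b$upper, delta = spec$delta,
      n_gens = spec$n_gens, n_subsets = spec$n_subsets,
      renormalize = .make_renormalizer(spec$params, names(theta0)),
      verbose = verbose)
  }
  best_doc <- .unpack_theta(spec$params, res$par)
  # refit curves and R^2 at the optimum, on fresh seeds and with at least
  # five trajectories so the report is not dominated by replicate noise
  n_report <- max(spec$replicates, 5L)
  fitted_curves <- list()
  r2 <- numeric(0)
  for (k in seq_along(spec$samples)) {
    seeds <- (spec$seed * 31L + seq_len(n_report) * 271L + k) %%
      21474832L
    sim <- simulate_replicates(best_doc, seeds, t_end = spec$t_end,
                               sample = k)
    nm <- best_doc$samples[[k]]$sample_name
    fitted_curves[[nm]] <- sim
    for (sugar in c("glucose", "xylose")) {
      ser <- spec$samples[[k]][[sugar]]
      if (!is.null(ser) && nrow(ser) >= 2 && var(ser$conversion) > 0) {
        r2[sprintf("%s:%s", nm, sugar)] <- r_squared(sim, ser, sugar)
      }
    }
  }
  structure(list(par = res$par, params = best_doc, value = res$value,
                 trace = res$trace, evals = res$evals,
                 eval_params = res$params,
                 r_squared = r2, fitted_curves = fitted_curves,
                 spec = spec, call = sys.call()),
            class = "sacch_fit")
}

# --- methods ---------------------------------------------------------------

#' @export
coef.sacch_fit <- function(object, ...) object$par

#' @export
print.sacch_fit <- function(x, ...) {
  cat(sprintf("<sacch_fit> %d fitted parameter(s), %d sample(s)\n",
              length(x$par), length(x$spec$samples)))
  cat(sprintf("  best variance: %.6g\n", x$value))
  if (length(x$par)) {
    cat("  coefficients:\n")
    print(signif(x$par, 5))
  }
  if (length(x$r_squared)) {
    cat("  R^2:\n")
    print(signif(x$r_squared, 4))
  }
  invisible(x)
}

#' @export
summary.sacch_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.sacch_fit")
}

#' @export
print.summary.sacch_fit <- function(x, ...) {
  print(x$fit)
  cat("\nGeneration trace:\n")
  print(x$fit$trace, row.names = FALSE)
  invisible(x)
}

#' Predict saccharification of new samples from a fitted model
#'
#' Runs forward simulations with the fitted shared kinetics and the
#' supplied composition/crystallinity configurations of unseen samples.
#'
#' @param object A `sacch_fit`.
#' @param newdata List of initial-configuration lists.  Each may be
#'   partial; missing fields are taken from the schema defaults, but
#'   `frac_cellulose`, `frac_hemicellulose`, `frac_lignin`,
#'   `crystalline_frac_cellulose` and `crystalline_frac_hemicellulose`
#'   must be supplied explicitly.
#' @param seed Integer seed.
#' @param t_end Horizon in hours (default: the fit's horizon).
#' @param replicates Trajectories averaged per sample.
#' @param ... Unused.
#' @return Named list of `sacch_timecourse` objects, one per new sample.
#' @export
predict.sacch_fit <- function(object, newdata, seed = 1, t_end = NULL,
                              replicates = NULL, ...) {
  if (is.null(t_end)) t_end <- object$spec$t_end
  if (is.null(replicates)) replicates <- object$spec$replicates
  required <- c("frac_cellulose", "frac_hemicellulose", "frac_lignin",
                "crystalline_frac_cellulose",
                "crystalline_frac_hemicellulose")
  out <- list()
  for (i in seq_along(newdata)) {
    cfg <- newdata[[i]]
    miss <- setdiff(required, names(cfg))
    if (length(miss))
      stop(sprintf("new sample %d: missing required field(s): %s",
                   i, paste(miss, collapse = ", ")), call. = FALSE)
    full <- modifyList(schema_defaults("config"), cfg)
    if (is.null(cfg$sample_name))
      full$sample_name <- sprintf("prediction_%d", i)
    doc <- object$params
    doc$samples <- list(full)
    doc <- validate_document(doc)
    seeds <- (as.integer(seed) * 53L + i * 101L +
                seq_len(replicates) * 907L) %% 21474832L
    out[[full$sample_name]] <- simulate_replicates(doc, seeds,
                                                   t_end = t_end,
                                                   sample = 1)
  }
  out
}

#' @export
fitted.sacch_fit <- function(object, ...) object$fitted_curves

#' @export
residuals.sacch_fit <- function(object, ...) {
  out <- list()
  for (k in seq_along(object$spec$samples)) {
    nm <- object$params$samples[[k]]$sample_name
    sim <- object$fitted_curves[[nm]]
    for (sugar in c("glucose", "xylose")) {
      ser <- object$spec$samples[[k]][[sugar]]
      if (is.null(ser)) next
      sim_y <- approx(sim$time, sim[[paste0(sugar, "_conversion")]],
                      xout = ser$time, rule = 1)$y
      out[[sprintf("%s:%s", nm, sugar)]] <-
        data.frame(time = ser$time, residual = ser$conversion - sim_y)
    }
  }
  out
}

#' @export
plot.sacch_fit <- function(x, ...) {
  ns <- length(x$spec$samples)
  op <- par(mfrow = c(1, ns)); on.exit(par(op))
  for (k in seq_len(ns)) {
    nm <- x$params$samples[[k]]$sample_name
    sim <- x$fitted_curves[[nm]]
    plot(sim$time, sim$glucose_conversion, type = "l", lty = 2,
         col = "darkgreen", ylim = c(0, 100), xlab = "time [h]",
         ylab = "conversion [%]", main = nm, ...)
    lines(sim$time, sim$xylose_conversion, lty = 2, col = "goldenrod")
    for (sugar in c("glucose", "xylose")) {
      ser <- x$spec$samples[[k]][[sugar]]
      if (!is.null(ser))
        points(ser$time, ser$conversion, pch = 19,
               col = if (sugar == "glucose") "darkgreen" else "goldenrod")
    }
  }
  invisible(x)
}

#' Simulate from a fitted model
#'
#' @param object A `sacch_fit`.
#' @param nsim Number of trajectories.
#' @param seed Integer seed.
#' @param sample Which fitted sample to simulate.
#' @param ... Passed to [run_simulation()].
#' @return List of `sacch_timecourse` objects.
#' @export
simulate.sacch_fit <- function(object, nsim = 1, seed = 1, sample = 1,
                               ...) {
  lapply(seq_len(nsim), function(i)
    run_simulation(object$params, seed = as.integer(seed) + i - 1L,
                   t_end = object$spec$t_end, sample = sample, ...))
}
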