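#' Construct a donor concentration profile
#'
#' A donor profile holds the molar initial conditions of the ten species a
#' donor's plasma panel determines: zymogens FII, FV, FVII (with its trace
#' activated FVIIa), FVIII, FIX, FX, initiator TF and inhibitors TFPI and AT.
#' All other model species start at zero.
#'
#' @param TF,FII,FV,FVII,FVIIa,FVIII,FIX,FX,TFPI,AT Initial molar
#'   concentrations (M); defaults are the reference plasma values of the
#'   packaged scheme with FVIIa at 1% of total FVII.
#' @return Named numeric vector of class `donor_profile`.
#' @export
donor_profile <- function(TF = 5e-12, FII = 1.4e-6, FV = 2e-8,
                          FVII = 9.9e-9, FVIIa = 1e-10, FVIII = 7e-10,
                          FIX = 9e-8, FX = 1.6e-7, TFPI = 2.5e-9,
                          AT = 3.4e-6) {
  p <- c(TF = TF, FII = FII, FV = FV, FVII = FVII, FVIIa = FVIIa,
         FVIII = FVIII, FIX = FIX, FX = FX, TFPI = TFPI, AT = AT)
  validate_profile(p)
  structure(p, class = "donor_profile")
}

validate_profile <- function(p) {
  if (any(!is.finite(p))) {
    stop("profile contains non-finite concentrations: ",
         paste(names(p)[!is.finite(p)], collapse = ", "))
  }
  if (any(p < 0)) {
    stop("profile contains negative concentrations: ",
         paste(names(p)[p < 0], collapse = ", "))
  }
  invisible(p)
}

#' Expand a donor profile into a full model state
#'
#' @param profile A `donor_profile` (or named numeric vector naming a subset
#'   of model species).
#' @param scheme A `coag_scheme`.
#' @return Named numeric state vector over all scheme species, unspecified
#'   species at zero.
#' @export
initial_state <- function(profile, scheme) {
  validate_profile(profile)
  unknown <- setdiff(names(profile), scheme$species)
  if (length(unknown) > 0) {
    stop("profile names species absent from the scheme: ",
         paste(unknown, collapse = ", "))
  }
  state <- stats::setNames(numeric(length(scheme$species)), scheme$species)
  state[names(profile)] <- as.numeric(profile)
  state
}

#' Mass-action reaction velocities
#'
#' @param state Named nonnegative state vector over the scheme's species.
#' @param scheme A `coag_scheme`.
#' @return Numeric vector of per-reaction velocities (M/s).
#' @export
reaction_velocities <- function(state, scheme) {
  m <- scheme$matrices
  v <- m$k * state[m$r1]
  bi <- m$r2 > 0
  v[bi] <- v[bi] * state[m$r2[bi]]
  unname(v)
}

#' Time derivative of the model state
#'
#' Sums mass-action terms over all reactions: for state x and stoichiometry
#' matrix S, dx/dt = S v(x) with v_j = k_j times the product of reactant
#' concentrations. For prothrombin this reduces to the three-term balance
#' d[II]/dt = -k16 [Xa][II] - k30 [Va:Xa][II] + k29 [Va:Xa:II].
#'
#' @inheritParams reaction_velocities
#' @return Named numeric vector d(state)/dt (M/s).
#' @export
derivative <- function(state, scheme) {
  if (is.null(names(state))) {
    stop("state must be named")
  }
  state <- state[scheme$species]
  v <- reaction_velocities(state, scheme)
  drop(scheme$matrices$S %*% v)
}

# Stage the scheme in the compiled backend. Returns invisibly.
stage_compiled_scheme <- function(scheme) {
  m <- scheme$matrices
  .Call(C_set_scheme, m$S, as.numeric(m$k), as.integer(m$r1),
        as.integer(m$r2))
  invisible(NULL)
}

#' Simulate the coagulation cascade for one donor
#'
#' Integrates the stiff mass-action system with an adaptive solver
#' (deSolve's lsoda) from the donor's initial conditions and samples the
#' solution on a regular output grid. Negative excursions smaller than the
#' absolute tolerance are clipped to zero; larger ones raise an error.
#'
#' @param profile A `donor_profile` or named numeric vector of initial molar
#'   concentrations.
#' @param scheme A `coag_scheme`.
#' @param horizon Simulation horizon in seconds (default 1200 s, covering the
#'   ~20 min over which the slowest factors deplete).
#' @param grid Output sampling interval in seconds (default 1 s).
#' @param rtol,atol Relative and absolute solver tolerances (defaults 1e-8
#'   and 1e-14 M; the species span pM to uM, hence the tight atol).
#' @param clip_tol Clipping tolerance: negative excursions larger (more
#'   negative) than `-clip_tol` abort the simulation; smaller ones are set
#'   to zero. Default 100 x `atol` (1e-12 M), comfortably above the solver's
#'   local error yet far below any biologically meaningful level.
#' @param engine `"compiled"` (default) or `"R"` for the pure-R derivative;
#'   both evaluate the same scheme and agree to solver tolerance.
#' @return Object of class `coag_trajectory`: list with `time` (seconds),
#'   `conc` (time-by-species matrix, M), and `meta` (tolerances, horizon,
#'   grid, engine, scheme name/hash, diagnostics).
#' @export
simulate_donor <- function(profile, scheme, horizon = 1200, grid = 1,
                           rtol = 1e-8, atol = 1e-14, clip_tol = 100 * atol,
                           engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0) {
    stop("horizon must be a positive number of seconds")
  }
  state <- initial_state(profile, scheme)
  times <- seq(0, horizon, by = grid)
  if (times[length(times)] < horizon) {
    times <- c(times, horizon)
  }

  if (engine == "compiled") {
    stage_compiled_scheme(scheme)
    sol <- deSolve::ode(y = unname(state), times = times, func = "C_derivs",
                        parms = numeric(0), dllname = "clotsim",
                        initfunc = NULL, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  } else {
    rhs <- function(t, y, parms) {
      names(y) <- scheme$species
      list(unname(derivative(y, scheme)))
    }
    sol <- deSolve::ode(y = unname(state), times = times, func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  }

  istate <- attr(sol, "istate")
  last_time <- sol[nrow(sol), 1]
  if (last_time < horizon - 1e-9) {
    stop("integrator failed at t = ", signif(last_time, 6),
         " s (of ", horizon, " s)")
  }

  conc <- sol[, -1, drop = FALSE]
  colnames(conc) <- scheme$species
  # clip numerical negatives below the clipping tolerance
  low <- min(conc)
  if (low < -clip_tol) {
    stop("negative concentration beyond clipping tolerance: min = ",
         signif(low, 4), " M")
  }
  conc[conc < 0] <- 0

  structure(
    list(time = sol[, 1],
         conc = conc,
         meta = list(horizon = horizon, grid = grid, rtol = rtol,
                     atol = atol, engine = engine,
                     scheme = scheme$name, scheme_hash = scheme$hash,
                     n_steps = if (length(istate) >= 3) istate[3] else NA)),
    class = "coag_trajectory")
}

#' @export
print.coag_trajectory <- function(x, ...) {
  cat("Coagulation trajectory: ", length(x$time), " time points over ",
      max(x$time), " s, ", ncol(x$conc), " species\n", sep = "")
  iia <- x$conc[, "FIIa"]
  cat("  peak free thrombin: ", signif(max(iia) * 1e9, 4), " nM at ",
      x$time[which.max(iia)], " s\n", sep = "")
  invisible(x)
}

#' Stoichiometry-weighted lineage totals along a trajectory
#'
#' For each zymogen/inhibitor lineage, sums the lineage-weighted
#' concentrations of every species carrying that lineage at each time point.
#' Mass action conserves these totals exactly; the numerical solution
#' conserves them to solver tolerance, which [check_conservation()] verifies.
#'
#' @param trajectory A `coag_trajectory`.
#' @param scheme The `coag_scheme` it was simulated with.
#' @param lineages Character vector of lineage names (default: all).
#' @return Time-by-lineage matrix of totals (M).
#' @export
conserved_totals <- function(trajectory, scheme,
                             lineages = names(scheme$lineages)) {
  W <- vapply(lineages, function(l) lineage_weights(scheme, l),
              numeric(length(scheme$species)))
  totals <- trajectory$conc %*% W
  colnames(totals) <- lineages
  totals
}

#' Maximum relative conservation drift per lineage
#'
#' @inheritParams conserved_totals
#' @return Named numeric vector: per lineage, max |total(t) - total(0)| /
#'   max(total(0), atol-scale). Lineages starting at zero drift are reported
#'   on an absolute scale relative to 1 pM.
#' @export
check_conservation <- function(trajectory, scheme,
                               lineages = names(scheme$lineages)) {
  totals <- conserved_totals(trajectory, scheme, lineages)
  t0 <- totals[1, ]
  scale <- pmax(t0, 1e-12)
  drift <- apply(abs(sweep(totals, 2, t0)), 2, max) / scale
  drift
}

#' Thrombin series from a trajectory
#'
#' @param trajectory A `coag_trajectory`.
#' @param measure `"free"` for free FIIa (the default headline), or
#'   `"total"` for total thrombin activity FIIa + 1.2 x meizothrombin.
#' @return Numeric vector (M) over the trajectory's time grid.
#' @export
thrombin <- function(trajectory, measure = c("free", "total")) {
  measure <- match.arg(measure)
  iia <- trajectory$conc[, "FIIa"]
  if (measure == "free") {
    return(iia)
  }
  iia + 1.2 * trajectory$conc[, "mIIa"]
}
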