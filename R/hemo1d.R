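#' Elastic wall model
#'
#' Thin-wall elastic tube description used by the 1D solver.  The derived
#' stiffness is `beta = E h0 / (r0 (1 - sigma^2))` (Pa) and the reference area
#' `A0 = pi r0^2` (mm^2).
#'
#' @param E Young's modulus (Pa).
#' @param r0 reference radius (mm).
#' @param h0 reference wall thickness (mm); alternatively give `h0_ratio`.
#' @param h0_ratio wall thickness as a fraction of `r0` (default 0.1 when
#'   `h0` is missing).
#' @param sigma Poisson ratio (0 <= sigma < 1).
#' @param P0 reference pressure (Pa) at which `A = A0`.
#' @return object of class `wall_model`.
#' @examples
#' w <- wall_model(E = 4e5, r0 = 3, h0 = 0.3)
#' w$beta  # 53333 Pa
#' @export
wall_model <- function(E, r0, h0 = NULL, h0_ratio = NULL, sigma = 0.5,
                       P0 = mmHg_to_Pa(85)) {
  if (is.null(h0)) {
    if (is.null(h0_ratio)) h0_ratio <- 0.1
    h0 <- h0_ratio * r0
  }
  stopifnot(E > 0, r0 > 0, h0 > 0, sigma >= 0, sigma < 1)
  structure(list(E = E, h0 = h0, r0 = r0, A0 = pi * r0^2, P0 = P0,
                 sigma = sigma, beta = E * h0 / (r0 * (1 - sigma^2))),
            class = "wall_model")
}

#' Blood fluid properties
#'
#' @param rho density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @param KR momentum friction coefficient (m^2/s); the default follows the
#'   flat-profile convention `22 pi nu`; `KR_model = "poiseuille"` uses
#'   `8 pi nu`.  Note the friction profile and the Poiseuille wall-shear
#'   post-processing assume different velocity profiles; both are exposed.
#' @param KR_model `"flat"` (default) or `"poiseuille"`, ignored when `KR` is
#'   given.
#' @return object of class `fluid_props` with derived `nu = mu/rho`.
#' @export
fluid_props <- function(rho = 1060, mu = 0.004, KR = NULL,
                        KR_model = c("flat", "poiseuille")) {
  KR_model <- match.arg(KR_model)
  stopifnot(rho > 0, mu > 0)
  nu <- mu / rho
  if (is.null(KR)) KR <- if (KR_model == "flat") 22 * pi * nu else 8 * pi * nu
  structure(list(rho = rho, mu = mu, nu = nu, KR = KR), class = "fluid_props")
}

#' Tube law: pressure from area (and its inverse)
#'
#' `P = P0 + beta (sqrt(A/A0) - 1)`; the inverse is exact.
#'
#' @param A cross-sectional area (same units as `wall$A0`, mm^2 by
#'   convention); must be positive.
#' @param P pressure (Pa); must exceed the collapse limit `P0 - beta`.
#' @param wall a [wall_model()].
#' @return pressure in Pa (`tube_law`) or area (`tube_law_inv`).
#' @export
tube_law <- function(A, wall) {
  stopifnot(inherits(wall, "wall_model"))
  if (any(A <= 0)) stop("non-positive area")
  wall$P0 + wall$beta * (sqrt(A / wall$A0) - 1)
}

#' @rdname tube_law
#' @export
tube_law_inv <- function(P, wall) {
  stopifnot(inherits(wall, "wall_model"))
  if (any(P <= wall$P0 - wall$beta))
    stop("pressure at or below the collapse limit P0 - beta")
  wall$A0 * ((P - wall$P0) / wall$beta + 1)^2
}

#' Pulse wave speed
#'
#' `c(A) = sqrt(beta sqrt(A) / (2 rho sqrt(A0)))`; at `A = A0` this is the
#' Moens-Korteweg speed `sqrt(E h0 / (2 rho r0 (1 - sigma^2)))`.
#'
#' @param A area (same units as `wall$A0`).
#' @param wall a [wall_model()].
#' @param fluid a [fluid_props()].
#' @return wave speed in m/s.
#' @export
wave_speed <- function(A, wall, fluid) {
  stopifnot(inherits(wall, "wall_model"), inherits(fluid, "fluid_props"))
  if (any(A <= 0)) stop("non-positive area")
  sqrt(wall$beta * sqrt(A) / (2 * fluid$rho * sqrt(wall$A0)))
}

#' Vessel state container
#'
#' @param s node arc positions (mm), uniformly spaced.
#' @param A areas (mm^2), positive.
#' @param Q flow rates (ml/s).
#' @param wall a [wall_model()] (pressure is derived through the tube law).
#' @param t current time (s).
#' @return object of class `vessel_state` with derived `P` (Pa).
#' @export
vessel_state <- function(s, A, Q, wall, t = 0) {
  stopifnot(length(s) == length(A), length(A) == length(Q), length(s) >= 3)
  if (any(A <= 0)) stop("non-positive area")
  ds <- diff(s)
  if (diff(range(ds)) > 1e-9 * mean(ds)) stop("s grid must be uniform")
  structure(list(s = s, A = A, Q = Q, P = tube_law(A, wall), t = t),
            class = "vessel_state")
}

#' Advance interior nodes one time step (Richtmyer Lax-Wendroff)
#'
#' Conservative two-step Lax-Wendroff update of `(A, Q)` with flux
#' `(Q, Q^2/A + beta A^{3/2} / (3 rho sqrt(A0)))` and friction source
#' `(0, -K_R Q/A)`; pressure is recomputed from the tube law.  End nodes are
#' left unchanged (they belong to boundary couplings).  Errors on CFL
#' violation (with a suggested dt) and on area collapse.
#'
#' @param state a [vessel_state()].
#' @param wall a [wall_model()].
#' @param fluid a [fluid_props()].
#' @param dt time step (s).
#' @param cfl_limit maximum admissible Courant number (default 1).
#' @return the updated `vessel_state` at `t + dt`.
#' @export
advance_step <- function(state, wall, fluid, dt, cfl_limit = 1) {
  stopifnot(inherits(state, "vessel_state"))
  ds_m <- mm_to_m(state$s[2] - state$s[1])
  A_si <- mm2_to_m2(state$A)
  Q_si <- ml_to_m3(state$Q)
  lam <- abs(Q_si / A_si) + wave_speed(state$A, wall, fluid)
  if (dt > cfl_limit * ds_m / max(lam))
    stop(sprintf("CFL violation: dt = %.3g s exceeds limit; use dt <= %.3g s",
                 dt, cfl_limit * ds_m / max(lam)))
  out <- .lw_interior_step_cpp(A_si, Q_si, mm2_to_m2(wall$A0), wall$beta,
                               wall$P0, fluid$rho, fluid$KR, ds_m, dt)
  A_new <- m2_to_mm2(out$A)
  if (any(A_new <= 0))
    stop("collapse: non-positive area after step; reduce dt or stiffen the wall")
  vessel_state(state$s, A_new, m3_to_ml(out$Q), wall, t = state$t + dt)
}

#' RCR Windkessel terminal state
#'
#' Three-element Windkessel (proximal resistance R1, compliance C, distal
#' resistance R2 against outflow pressure `Pout`).  All SI: Pa s/m^3, m^3/Pa,
#' Pa.
#'
#' @param R1,R2 resistances (Pa s/m^3), positive.
#' @param C compliance (m^3/Pa), positive.
#' @param Pout outflow (venous) pressure (Pa).
#' @param Pc initial capacitor pressure (Pa), defaults to `Pout`.
#' @return object of class `windkessel_state`.
#' @export
windkessel_state <- function(R1, R2, C, Pout, Pc = Pout) {
  stopifnot(R1 > 0, R2 > 0, C > 0)
  structure(list(R1 = R1, R2 = R2, C = C, Pout = Pout, Pc = Pc),
            class = "windkessel_state")
}

#' Advance a Windkessel terminal one time step
#'
#' Implicit-Euler update of the capacitor pressure
#' `dPc/dt = (Q_in - (Pc - Pout)/R2) / C`; the terminal pressure seen by the
#' 1D segment is `P = Pc + R1 Q_in`.
#'
#' @param Q_in inflow into the terminal (m^3/s).
#' @param wk a [windkessel_state()].
#' @param dt time step (s), positive.
#' @return list with `P` (terminal pressure, Pa) and the updated `wk`.
#' @export
windkessel_step <- function(Q_in, wk, dt) {
  stopifnot(inherits(wk, "windkessel_state"), dt > 0)
  denom <- 1 + dt / (wk$R2 * wk$C)
  wk$Pc <- (wk$Pc + dt / wk$C * (Q_in + wk$Pout / wk$R2)) / denom
  list(P = wk$Pc + wk$R1 * Q_in, wk = wk)
}

#' Young-type stenosis element
#'
#' Empirical 0D pressure-drop element with viscous, turbulent and inertial
#' terms.  The default viscous coefficient follows Young's relation
#' `Kv = 32 (Ls / (2 r0)) (A0/As)^2`, which reduces to the Poiseuille drop for
#' a non-stenosed element.
#'
#' @param A0_sten nominal (non-stenosed) area (mm^2).
#' @param severity area severity `1 - As/A0` in `[0, 1)`; alternatively give
#'   `As` directly.
#' @param As minimal (stenotic) area (mm^2).
#' @param Ls stenosis length (mm), positive.
#' @param Kv,Kt,Ku empirical coefficients (defaults: Young's `Kv` relation,
#'   `Kt = 1.52`, `Ku = 1.2`).
#' @return object of class `stenosis_element`.
#' @export
stenosis_element <- function(A0_sten, severity = NULL, As = NULL, Ls = 10,
                             Kv = NULL, Kt = 1.52, Ku = 1.2) {
  stopifnot(A0_sten > 0, Ls > 0)
  if (is.null(As)) {
    if (is.null(severity)) stop("give `severity` or `As`")
    if (severity < 0 || severity >= 1) stop("severity must be in [0, 1)")
    As <- (1 - severity) * A0_sten
  }
  if (As <= 0 || As > A0_sten) stop("require 0 < As <= A0_sten")
  r0 <- sqrt(A0_sten / pi)
  if (is.null(Kv)) Kv <- 32 * (Ls / (2 * r0)) * (A0_sten / As)^2
  structure(list(A0_sten = A0_sten, As = As, Ls = Ls, Kv = Kv, Kt = Kt,
                 Ku = Ku, severity = 1 - As / A0_sten),
            class = "stenosis_element")
}

#' Stenosis pressure drop
#'
#' `dP = Kv mu/(2 r0 A0) Q + Kt rho/(2 A0^2) (A0/As - 1)^2 Q |Q|
#'      + Ku rho Ls / A0 dQ/dt`, applied in the solver as an internal
#' interface condition (pressure jump with continuous flow).
#'
#' @param Q flow rate (ml/s).
#' @param dQdt flow acceleration (ml/s^2).
#' @param sten a [stenosis_element()].
#' @param fluid a [fluid_props()].
#' @return pressure drop in Pa.
#' @export
stenosis_pressure_drop <- function(Q, dQdt = 0, sten, fluid) {
  stopifnot(inherits(sten, "stenosis_element"), inherits(fluid, "fluid_props"))
  co <- stenosis_si_coefficients(sten, fluid)
  Q_si <- ml_to_m3(Q)
  co$kv * Q_si + co$kt * Q_si * abs(Q_si) + co$ku * ml_to_m3(dQdt)
}

# collapse the element into SI coefficients dP = kv Q + kt Q|Q| + ku dQ/dt
stenosis_si_coefficients <- function(sten, fluid) {
  A0 <- mm2_to_m2(sten$A0_sten)
  As <- mm2_to_m2(sten$As)
  r0 <- sqrt(A0 / pi)
  Ls <- mm_to_m(sten$Ls)
  list(kv = sten$Kv * fluid$mu / (2 * r0 * A0),
       kt = sten$Kt * fluid$rho / (2 * A0^2) * (A0 / As - 1)^2,
       ku = sten$Ku * fluid$rho * Ls / A0)
}

#' Solver configuration
#'
#' @param ds solver grid width Delta-s (mm, default 1).
#' @param cfl Courant number for the time step (default 0.5).
#' @param max_cycles cap on cardiac cycles (default 20).
#' @param tol_cycle relative cycle-to-cycle pressure change for convergence
#'   (default 1e-3).
#' @param n_out stored samples per cycle (default 100; the converged cycle is
#'   returned at `n_out + 1` time points including both cycle endpoints).
#' @param junction_pressure `"static"` (default) or `"total"` pressure
#'   continuity at junctions.
#' @param newton_tol,newton_maxit Newton controls for boundary couplings.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(ds = 1, cfl = 0.5, max_cycles = 20, tol_cycle = 1e-3,
                          n_out = 100, junction_pressure = c("static", "total"),
                          newton_tol = 1e-13, newton_maxit = 50) {
  junction_pressure <- match.arg(junction_pressure)
  structure(list(ds = ds, cfl = cfl, max_cycles = max_cycles,
                 tol_cycle = tol_cycle, n_out = n_out,
                 junction_pressure = junction_pressure,
                 newton_tol = newton_tol, newton_maxit = newton_maxit),
            class = "solver_config")
}

#' Simulation configuration
#'
#' @param inflow tabulated inflow waveform: data frame with `t` (s, covering
#'   one period) and `Q` (ml/s); see [default_inflow_waveform()].
#' @param period cardiac period T (s).
#' @param fluid a [fluid_props()].
#' @param solver a [solver_config()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(inflow, period = 1, fluid = fluid_props(),
                       solver = solver_config()) {
  stopifnot(is.data.frame(inflow), all(c("t", "Q") %in% names(inflow)))
  structure(list(inflow = inflow, period = period, fluid = fluid,
                 solver = solver), class = "sim_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file may contain `period`, `fluid` (rho, mu, KR or KR_model), `solver`
#' (any [solver_config()] field) and `inflow` (either a table `{t: [...],
#' Q: [...]}` or a preset `{preset: "half_sine", T:, SV:}`).
#'
#' @param path configuration file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  period <- if (!is.null(obj$period)) obj$period else 1
  fl <- do.call(fluid_props, as.list(obj$fluid))
  sv <- do.call(solver_config, as.list(obj$solver))
  inflow <- if (!is.null(obj$inflow$preset)) {
    default_inflow_waveform(T_period = obj$inflow$T, stroke_volume = obj$inflow$SV)
  } else data.frame(t = obj$inflow$t, Q = obj$inflow$Q)
  sim_config(inflow, period = period, fluid = fl, solver = sv)
}

# merge wall defaults with per-segment overrides and segment mean radius
segment_wall_model <- function(network, id) {
  w <- network$wall
  ov <- network$segment_wall[[as.character(id)]]
  if (!is.null(ov)) w[names(ov)] <- ov
  r0 <- mean(network$segments[[as.character(id)]]$points$r)
  wall_model(E = w$E, r0 = r0, h0 = w$h0, h0_ratio = w$h0_ratio,
             sigma = if (is.null(w$sigma)) 0.5 else w$sigma,
             P0 = if (is.null(w$P0)) mmHg_to_Pa(85) else w$P0)
}

#' Run a 1D-0D pulse-wave simulation on a network
#'
#' Discretises every segment on the `ds` grid (a segment carrying a stenosis
#' is split at the element into two tubes coupled by the Young pressure-drop
#' interface), couples junctions by characteristic matching with exact mass
#' conservation and static- (or total-) pressure continuity, terminals by RCR
#' Windkessel elements and the inlet by the prescribed periodic flow, then
#' advances Richtmyer Lax-Wendroff cycles until the maximum relative
#' cycle-to-cycle pressure change drops below `tol_cycle` (cap
#' `max_cycles`).
#'
#' @param network a validated [assemble_network()] result.
#' @param config a [sim_config()].
#' @param warm_pc optional vector of initial capacitor pressures (Pa), one per
#'   terminal.
#' @return object of class `solution_field`: per-segment `s` (mm) and
#'   time-by-node matrices `A` (mm^2), `P` (Pa), `Q` (ml/s) over one converged
#'   cycle (`times` in s), plus convergence and conservation reports.
#' @export
simulate_network <- function(network, config, warm_pc = NULL) {
  stopifnot(inherits(network, "vascular_network"), inherits(config, "sim_config"))
  sv <- config$solver
  fl <- config$fluid
  ids <- names(network$segments)

  tubes <- list()
  tubemap <- list()   # per tube: segment id, part, s_offset (mm)
  seg_tube <- list()  # per segment id: tube indices in order

  sten_by_seg <- list()
  for (st in network$stenoses)
    sten_by_seg[[as.character(st$segment)]] <- st

  add_tube <- function(L_mm, wall, seg_id, part, offset) {
    n <- max(2L, as.integer(round(L_mm / sv$ds)) + 1L)
    ds_m <- mm_to_m(L_mm) / (n - 1)
    A0 <- mm2_to_m2(wall$A0)
    tubes[[length(tubes) + 1]] <<- list(
      n = n, ds = ds_m, A0 = A0, beta = wall$beta, P0 = wall$P0,
      rho = fl$rho, KR = fl$KR, A = rep(A0, n), Q = rep(0, n))
    tubemap[[length(tubemap) + 1]] <<- list(segment = seg_id, part = part,
                                            offset = offset, length_mm = L_mm,
                                            wall = wall)
    length(tubes)
  }

  sten_couplings <- list()
  for (id in ids) {
    seg <- network$segments[[id]]
    L <- segment_arclength(seg)
    wall <- segment_wall_model(network, id)
    st <- sten_by_seg[[id]]
    if (is.null(st)) {
      ti <- add_tube(L, wall, id, 1L, 0)
      seg_tube[[id]] <- ti
    } else {
      pos <- st$position_mm
      t1 <- add_tube(pos, wall, id, 1L, 0)
      t2 <- add_tube(L - pos, wall, id, 2L, pos)
      seg_tube[[id]] <- c(t1, t2)
      sten <- stenosis_element(A0_sten = wall$A0, severity = st$severity,
                               Ls = st$length_mm, Kv = st$Kv, Kt = st$Kt,
                               Ku = st$Ku)
      co <- stenosis_si_coefficients(sten, fl)
      sten_couplings[[length(sten_couplings) + 1]] <-
        list(tubeL = t1, tubeR = t2, kv = co$kv, kt = co$kt, ku = co$ku, Q0 = 0)
    }
  }

  end_tube <- function(att) {
    tl <- seg_tube[[as.character(att$segment)]]
    if (att$end == "start") list(tube = tl[1], side = 0L)
    else list(tube = tl[length(tl)], side = 1L)
  }

  inlets <- list(end_tube(network$inlet))
  terminals <- lapply(seq_along(network$terminals), function(k) {
    tm <- network$terminals[[k]]
    et <- end_tube(tm)
    pc0 <- if (!is.null(warm_pc)) warm_pc[k] else
      if (!is.null(tm$Pc0)) tm$Pc0 else
        if (is.null(network$wall$P0)) mmHg_to_Pa(85) else network$wall$P0
    list(tube = et$tube, side = et$side, R1 = tm$R1, R2 = tm$R2, C = tm$C,
         Pout = tm$Pout, Pc0 = pc0)
  })
  junctions <- lapply(network$junctions, function(j) {
    ets <- lapply(j, end_tube)
    list(tubes = vapply(ets, `[[`, numeric(1), "tube"),
         sides = vapply(ets, `[[`, integer(1), "side"))
  })

  inflow_t <- config$inflow$t
  inflow_q <- ml_to_m3(config$inflow$Q)

  c0max <- max(vapply(tubes, function(tb) sqrt(tb$beta / (2 * tb$rho)), numeric(1)))
  u_est <- 2.5 * max(abs(inflow_q)) / tubes[[inlets[[1]]$tube]]$A0
  lam_est <- 1.3 * c0max + max(u_est, 1)
  ds_min <- min(vapply(tubes, `[[`, numeric(1), "ds"))
  steps <- ceiling(config$period / (sv$cfl * ds_min / lam_est))
  steps <- as.integer(ceiling(steps / sv$n_out) * sv$n_out)
  dt <- config$period / steps

  raw <- .run_network_cpp(tubes, junctions, terminals, inlets, sten_couplings,
                          list(), inflow_t, inflow_q, config$period, dt,
                          steps, steps %/% sv$n_out, sv$max_cycles,
                          sv$tol_cycle, sv$junction_pressure == "total",
                          sv$newton_tol, sv$newton_maxit)
  if (!raw$converged)
    warning(sprintf("simulation not converged after %d cycles (last change %.2e)",
                    raw$cycles, raw$conv_history[raw$cycles]))

  segments_out <- list()
  for (id in ids) {
    tl <- seg_tube[[id]]
    s_all <- numeric(0); A <- NULL; P <- NULL; Q <- NULL
    for (k in seq_along(tl)) {
      ti <- tl[k]
      tm <- tubemap[[ti]]
      n <- tubes[[ti]]$n
      s_loc <- tm$offset + seq(0, tm$length_mm, length.out = n)
      Ak <- m2_to_mm2(raw$tubes[[ti]]$A)
      Pk <- raw$tubes[[ti]]$P
      Qk <- m3_to_ml(raw$tubes[[ti]]$Q)
      if (k > 1) {  # drop duplicated interface node (left value kept)
        s_loc <- s_loc[-1]; Ak <- Ak[, -1, drop = FALSE]
        Pk <- Pk[, -1, drop = FALSE]; Qk <- Qk[, -1, drop = FALSE]
      }
      s_all <- c(s_all, s_loc)
      A <- cbind(A, Ak); P <- cbind(P, Pk); Q <- cbind(Q, Qk)
    }
    segments_out[[id]] <- list(s = s_all, A = A, P = P, Q = Q,
                               index = as.integer(id),
                               wall = tubemap[[tl[1]]]$wall)
  }

  cons <- raw$conservation
  structure(list(
    times = raw$times, period = config$period, segments = segments_out,
    converged = raw$converged, cycles = raw$cycles,
    conv_history = raw$conv_history[seq_len(raw$cycles)],
    conservation = list(
      inlet_volume_ml = m3_to_ml(cons$inlet_volume),
      terminal_volumes_ml = m3_to_ml(cons$terminal_volumes),
      stored_start_ml = m3_to_ml(cons$stored_start),
      stored_end_ml = m3_to_ml(cons$stored_end),
      max_junction_defect_mls = m3_to_ml(cons$max_junction_defect),
      max_courant = cons$max_courant),
    terminal_pc = raw$terminal_pc, dt = raw$dt, fluid = fl,
    network = network), class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  cat("solution_field:", length(x$segments), "segments,",
      length(x$times), "time samples over T =", x$period, "s;",
      if (x$converged) "converged" else "NOT converged", "after", x$cycles,
      "cycles\n")
  cons <- x$conservation
  bal <- mass_balance_error(x)
  cat(sprintf("  mass balance error %.3g%%; max junction defect %.3g ml/s; max Courant %.2f\n",
              100 * bal, cons$max_junction_defect_mls, cons$max_courant))
  invisible(x)
}

#' Relative global mass-balance error of a converged cycle
#'
#' `|inlet volume - terminal volumes - storage change| / inlet volume`.
#'
#' @param solution a `solution_field`.
#' @return relative error (fraction).
#' @export
mass_balance_error <- function(solution) {
  cons <- solution$conservation
  stored <- cons$stored_end_ml - cons$stored_start_ml
  abs(cons$inlet_volume_ml - sum(cons$terminal_volumes_ml) - stored) /
    max(cons$inlet_volume_ml, .Machine$double.eps)
}

#' Simulate a single tube with simple boundary conditions
#'
#' Standalone single-vessel runner used for wave-propagation experiments:
#' both ends are non-reflecting (the incoming characteristic invariant is
#' pinned to the initial state), and the run covers a fixed duration rather
#' than cardiac cycles.
#'
#' @param wall a [wall_model()].
#' @param fluid a [fluid_props()].
#' @param length_mm tube length (mm).
#' @param t_end duration (s).
#' @param ds grid width (mm).
#' @param A0_init optional initial area profile (mm^2, length n); default
#'   uniform `wall$A0`.
#' @param Q_init optional initial flow profile (ml/s); default 0.
#' @param n_out stored samples.
#' @param cfl Courant number.
#' @return list with `times` (s), `s` (mm), and time-by-node `A` (mm^2),
#'   `P` (Pa), `Q` (ml/s).
#' @export
simulate_tube <- function(wall, fluid, length_mm, t_end, ds = 1,
                          A0_init = NULL, Q_init = NULL, n_out = 200,
                          cfl = 0.5) {
  n <- as.integer(round(length_mm / ds)) + 1L
  ds_m <- mm_to_m(length_mm) / (n - 1)
  A <- if (is.null(A0_init)) rep(wall$A0, n) else A0_init
  Q <- if (is.null(Q_init)) rep(0, n) else Q_init
  stopifnot(length(A) == n, length(Q) == n)
  tube <- list(n = n, ds = ds_m, A0 = mm2_to_m2(wall$A0), beta = wall$beta,
               P0 = wall$P0, rho = fluid$rho, KR = fluid$KR,
               A = mm2_to_m2(A), Q = ml_to_m3(Q))
  cmax <- max(wave_speed(A, wall, fluid)) + max(abs(ml_to_m3(Q) / mm2_to_m2(A)))
  steps <- ceiling(t_end / (cfl * ds_m / (1.3 * cmax)))
  steps <- as.integer(ceiling(steps / n_out) * n_out)
  dt <- t_end / steps
  raw <- .run_network_cpp(list(tube), list(), list(), list(), list(),
                          list(list(tube = 1, side = 0L),
                               list(tube = 1, side = 1L)),
                          numeric(0), numeric(0), t_end, dt, steps,
                          steps %/% n_out, 1L, 0, FALSE, 1e-13, 50L)
  list(times = raw$times, s = seq(0, length_mm, length.out = n),
       A = m2_to_mm2(raw$tubes[[1]]$A), P = raw$tubes[[1]]$P,
       Q = m3_to_ml(raw$tubes[[1]]$Q),
       max_courant = raw$conservation$max_courant)
}

#' Write per-segment solution tables as CSV
#'
#' One file per segment with columns `segment`, `t` (s), `s` (mm), `A`
#' (mm^2), `P` (mmHg), `Q` (ml/s).
#'
#' @param solution a `solution_field`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_solution_csv <- function(solution, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(solution$segments)) {
    sg <- solution$segments[[id]]
    nt <- length(solution$times); ns <- length(sg$s)
    df <- data.frame(
      segment = as.integer(id),
      t = rep(solution$times, each = ns),
      s = rep(sg$s, times = nt),
      A = as.vector(t(sg$A)),
      P = Pa_to_mmHg(as.vector(t(sg$P))),
      Q = as.vector(t(sg$Q)))
    utils::write.csv(df, file.path(dir, sprintf("segment_%s.csv", id)),
                     row.names = FALSE)
  }
  invisible(dir)
}
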