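#' Remodeling configuration
#'
#' Controls the constant-WSS adaptation loop: arteries regulate their
#' cross-sectional area to restore wall shear stress to a homeostatic target
#' when the flow they carry changes.
#'
#' @param segments arterial indices of the adaptive segments.
#' @param target per-segment target TAWSS (Pa), a single value recycled, or
#'   `"baseline"` to compute targets from a stenosis-free reference run.
#' @param omega relaxation factor in (0, 1]; each update multiplies the
#'   radius by `(tawss/target)^(omega/3)`.
#' @param tol relative TAWSS tolerance for convergence.
#' @param max_iter outer-iteration cap.
#' @param adapt_h0 also scale the wall thickness with the radius (keeps
#'   `h0/r0` constant); by default `h0` is kept fixed.
#' @return list of class `remodel_config`.
#' @export
remodel_config <- function(segments, target = "baseline", omega = 0.5,
                           tol = 0.02, max_iter = 30, adapt_h0 = FALSE) {
  stopifnot(length(segments) >= 1, omega > 0, omega <= 1, tol > 0)
  structure(list(segments = as.integer(segments), target = target,
                 omega = omega, tol = tol, max_iter = max_iter,
                 adapt_h0 = adapt_h0), class = "remodel_config")
}

#' Core constant-WSS fixed-point iteration
#'
#' Iteratively multiplies the radii by `(tau(r)/target)^(omega/3)` until the
#' maximum relative
#' TAWSS error drops below `tol`.  The exponent 1/3 is the constant-WSS fixed
#' point of the Poiseuille relation `tau = 4 mu Q / (pi r^3)` at fixed flow;
#' `omega` relaxes the update for stability on coupled networks.  Aborts if
#' the error grows for three consecutive iterations.
#'
#' @param tawss_fn function mapping a radius vector to a TAWSS vector (Pa).
#' @param r initial radii (mm), positive.
#' @param target target TAWSS values (Pa), positive, recycled to `length(r)`.
#' @param omega relaxation factor in (0, 1].
#' @param tol relative TAWSS tolerance.
#' @param max_iter iteration cap.
#' @return list with `r` (final radii), `converged`, `iterations` and a
#'   `trace` data frame (iteration, segment, radius, tawss, rel_error).
#' @export
remodel_iterate <- function(tawss_fn, r, target, omega = 0.5, tol = 0.02,
                            max_iter = 30) {
  stopifnot(all(r > 0), all(target > 0), omega > 0, omega <= 1)
  target <- rep_len(target, length(r))
  trace <- list()
  err_prev <- Inf
  grow <- 0L
  converged <- FALSE
  it <- 0L
  repeat {
    tau <- tawss_fn(r)
    if (any(!is.finite(tau)) || any(tau <= 0))
      stop("tawss_fn returned non-positive or non-finite TAWSS")
    rel <- abs(tau - target) / target
    trace[[length(trace) + 1]] <- data.frame(
      iteration = it, segment = seq_along(r), radius = r, tawss = tau,
      rel_error = rel)
    err <- max(rel)
    if (err < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    grow <- if (err > err_prev) grow + 1L else 0L
    if (grow >= 3L)
      stop("remodeling diverged: error grew for three consecutive iterations")
    err_prev <- err
    r <- r * (tau / target)^(omega / 3)
    it <- it + 1L
  }
  list(r = r, converged = converged, iterations = it,
       trace = do.call(rbind, trace))
}

#' Remodel network segments to a target wall shear stress
#'
#' Outer loop: simulate the network, compute each adaptive segment's mean
#' TAWSS, scale its radius by the constant-WSS factor
#' `(tawss/target)^(omega/3)` (rescaling `A0 = pi r^2`), and repeat
#' until every adaptive segment is within `tol` of its target.  With
#' `target = "baseline"` the targets come from a reference run of the same
#' network with all stenoses removed.
#'
#' @param network a `vascular_network`.
#' @param config a [sim_config()].
#' @param remodel a [remodel_config()].
#' @return list with the adapted `network`, the final `solution`, the
#'   per-iteration `trace`, `converged`, `iterations`, `targets` and the
#'   final `radius_scale` per adaptive segment.
#' @export
remodel_to_target_wss <- function(network, config, remodel) {
  stopifnot(inherits(network, "vascular_network"),
            inherits(remodel, "remodel_config"))
  seg_ids <- as.character(remodel$segments)
  if (!all(seg_ids %in% names(network$segments)))
    stop("adaptive segment(s) not in network: ",
         paste(setdiff(seg_ids, names(network$segments)), collapse = ", "))

  targets <- if (identical(remodel$target, "baseline")) {
    ref <- simulate_network(remove_stenoses(network), config)
    solution_wss(ref)$segment_tawss[seg_ids]
  } else rep_len(remodel$target, length(seg_ids))
  if (any(targets <= 0)) stop("targets must be positive")

  r0 <- vapply(seg_ids, function(id)
    mean(network$segments[[id]]$points$r), numeric(1))
  cur <- network
  last_solution <- NULL
  warm <- NULL

  tawss_fn <- function(r) {
    scale <- r / vapply(seg_ids, function(id)
      mean(cur$segments[[id]]$points$r), numeric(1))
    names(scale) <- seg_ids
    cur <<- scale_segment_radii(cur, scale)
    if (remodel$adapt_h0 && !is.null(cur$wall$h0)) {
      # absolute h0 with adapt_h0: express as per-segment override scaling
      for (id in seg_ids) {
        ov <- cur$segment_wall[[id]]
        h0 <- if (!is.null(ov$h0)) ov$h0 else cur$wall$h0
        cur$segment_wall[[id]] <- utils::modifyList(
          if (is.null(ov)) list() else ov, list(h0 = h0 * scale[[id]]))
      }
    }
    last_solution <<- simulate_network(cur, config, warm_pc = warm)
    warm <<- last_solution$terminal_pc
    solution_wss(last_solution)$segment_tawss[seg_ids]
  }

  res <- remodel_iterate(tawss_fn, r0, targets, omega = remodel$omega,
                         tol = remodel$tol, max_iter = remodel$max_iter)
  if (!res$converged)
    warning("remodeling reached the iteration cap without converging")
  list(network = cur, solution = last_solution, trace = res$trace,
       converged = res$converged, iterations = res$iterations,
       targets = targets, radius_scale = res$r / r0)
}
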