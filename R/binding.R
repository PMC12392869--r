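#' Binding characterization models
#'
#' Three model families characterize purified binders: (i) 1:1 Langmuir
#' biosensor kinetics with a global (kon, koff, Rmax) fit across analyte
#' concentrations, (ii) a three-parameter saturation dose-response for
#' on-cell K_D (background MFI, maximum MFI, K_D), and (iii) a global
#' competition fit with plateaus shared across competitors and one EC50
#' each, converted to K_D through `K_D = EC50 / (1 + C_L / K_D_L)` where
#' `C_L` is the labelled-tracer concentration and `K_D_L` its own affinity.
#'
#' Concentrations are handled in nM throughout the fitting interfaces (the
#' scale the assays are read on); molar equivalents are reported alongside.
#'
#' @name binding-models
NULL

#' Construct a kinetic trace
#'
#' @param time seconds, strictly increasing
#' @param response sensor response units
#' @param phase "association" or "dissociation"
#' @param concentration_nM analyte concentration (association phase must be
#'   positive)
#' @param series_id identifier linking the association/dissociation pair
#' @param buffer metadata tag ("resting", "active", "inactive", "low_pH")
#' @return object of class `kinetic_trace`
#' @export
kinetic_trace <- function(time, response, phase, concentration_nM,
                          series_id = "s1", buffer = "resting") {
  phase <- match.arg(phase, c("association", "dissociation"))
  if (any(diff(time) <= 0)) {
    stop("invalid input: time must be strictly increasing", call. = FALSE)
  }
  if (phase == "association" && concentration_nM <= 0) {
    stop("invalid input: association requires positive concentration",
         call. = FALSE)
  }
  structure(list(time = time, response = response, phase = phase,
                 concentration_nM = concentration_nM, series_id = series_id,
                 buffer = buffer),
            class = "kinetic_trace")
}

#' Simulate a 1:1 binding trace pair
#'
#' Association: `R(t) = Req (1 - exp(-(kon C + koff) t))` with
#' `Req = Rmax C / (C + K_D)`; dissociation continues from the association
#' end point as `R_end exp(-koff t)`.  Gaussian noise of standard deviation
#' `noise_sd` is added when positive; deterministic given the seed.
#'
#' @param kon association rate, 1/(M s)
#' @param koff dissociation rate, 1/s
#' @param rmax saturating response
#' @param concentration_nM analyte concentration, nM
#' @param association_time,dissociation_time phase durations, s
#' @param n_points samples per phase
#' @param noise_sd Gaussian noise SD (response units)
#' @param seed RNG seed for the noise
#' @param series_id identifier for the pair
#' @return list of two [kinetic_trace()]s (association, dissociation)
#' @export
simulate_1to1_trace <- function(kon, koff, rmax, concentration_nM,
                                association_time = 600, dissociation_time = 600,
                                n_points = 60, noise_sd = 0, seed = 0,
                                series_id = "s1") {
  if (any(c(kon, koff, rmax, concentration_nM, association_time,
            dissociation_time) < 0)) {
    stop("invalid input: rates, response and times must be non-negative",
         call. = FALSE)
  }
  C <- concentration_nM * 1e-9
  kd <- koff / kon
  req <- rmax * C / (C + kd)
  kobs <- kon * C + koff
  ta <- seq(association_time / n_points, association_time, length.out = n_points)
  td <- seq(dissociation_time / n_points, dissociation_time, length.out = n_points)
  ra <- req * (1 - exp(-kobs * ta))
  rend <- req * (1 - exp(-kobs * association_time))
  rd <- rend * exp(-koff * td)
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(2 * n_points, 0, noise_sd))
    ra <- ra + noise[seq_len(n_points)]
    rd <- rd + noise[n_points + seq_len(n_points)]
  }
  list(association = kinetic_trace(ta, ra, "association", concentration_nM,
                                   series_id),
       dissociation = kinetic_trace(td, rd, "dissociation", concentration_nM,
                                    series_id))
}

# model responses for one series given (kon, koff, rmax)
predict_1to1 <- function(kon, koff, rmax, trace, association_time) {
  C <- trace$concentration_nM * 1e-9
  kd <- koff / kon
  req <- rmax * C / (C + kd)
  kobs <- kon * C + koff
  if (trace$phase == "association") {
    req * (1 - exp(-kobs * trace$time))
  } else {
    rend <- req * (1 - exp(-kobs * association_time))
    rend * exp(-koff * trace$time)
  }
}

#' Global 1:1 kinetic fit
#'
#' Fits one (kon, koff, Rmax) triple to all traces jointly by
#' Levenberg-Marquardt least squares in log-parameter space, with 5
#' log-spaced kon starts; the best (lowest SSE) solution is returned, so the
#' fit is deterministic.  `K_D = koff / kon` by construction.  With a single
#' concentration and no dissociation data the problem is weakly identified;
#' this is flagged (`identifiable = FALSE`) rather than hidden.
#'
#' @param traces list of [kinetic_trace()]s (or pairs from
#'   [simulate_1to1_trace()], which are flattened)
#' @return object of class `kinetic_fit`: `kon`, `koff`, `rmax`, `kd_molar`,
#'   `kd_nM`, `residual_norm`, `identifiable`
#' @export
fit_1to1_global <- function(traces) {
  if (inherits(traces, "kinetic_trace")) traces <- list(traces)
  flat <- list()
  for (t in traces) {
    if (inherits(t, "kinetic_trace")) flat[[length(flat) + 1L]] <- t
    else for (u in t) flat[[length(flat) + 1L]] <- u
  }
  phases <- vapply(flat, function(t) t$phase, character(1))
  if (!any(phases == "association")) {
    stop("invalid input: need at least one association trace", call. = FALSE)
  }
  # association end time per series, for dissociation initial response
  assoc_end <- new.env()
  for (t in flat) if (t$phase == "association") {
    assign(t$series_id, max(t$time), envir = assoc_end)
  }
  tmax_default <- max(vapply(flat[phases == "association"],
                             function(t) max(t$time), numeric(1)))
  rmax0 <- max(vapply(flat, function(t) max(abs(t$response)), numeric(1)))
  resid_fun <- function(p) {
    kon <- exp(p[1]); koff <- exp(p[2]); rmax <- exp(p[3])
    unlist(lapply(flat, function(t) {
      ta <- if (t$phase == "dissociation") {
        get0(t$series_id, envir = assoc_end, ifnotfound = tmax_default)
      } else max(t$time)
      t$response - predict_1to1(kon, koff, rmax, t, ta)
    }))
  }
  starts <- lapply(10^seq(4, 7, length.out = 5), function(k0)
    c(log(k0), log(1e-3), log(max(rmax0, 1e-6))))
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(par = s, fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("1:1 fit failed from all starts", call. = FALSE)
  p <- best$fit$par
  kon <- exp(p[1]); koff <- exp(p[2]); rmax <- exp(p[3])
  n_conc <- length(unique(vapply(flat[phases == "association"],
                                 function(t) t$concentration_nM, numeric(1))))
  identifiable <- n_conc >= 2 || any(phases == "dissociation")
  structure(list(kon = kon, koff = koff, rmax = rmax,
                 kd_molar = koff / kon, kd_nM = koff / kon * 1e9,
                 residual_norm = sqrt(best$sse),
                 identifiable = identifiable),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1:1 kinetic fit: kon %.3g /(M s), koff %.3g /s, KD %.3g nM%s\n",
              x$kon, x$koff, x$kd_nM,
              if (x$identifiable) "" else " (weakly identified)"))
  invisible(x)
}

#' Three-parameter dose-response fit
#'
#' Ascending form `MFI(c) = bg + (max - bg) c / (c + K_D)`; descending form
#' `MFI(c) = bg + (max - bg) K_D / (c + K_D)` (used for competition-style
#' curves, where the fitted constant is an EC50).  Standard errors come from
#' the curvature at the optimum.
#'
#' @param concentrations_nM concentrations, nM (>= 4 points spanning the
#'   inflection)
#' @param mfi measured mean fluorescence intensities
#' @param direction "ascending" (default) or "descending"
#' @return object of class `dose_response_fit`: `kd_nM`, `kd_molar`,
#'   `background`, `maximum`, `se` (named vector), `residual_norm`
#' @export
fit_dose_response3 <- function(concentrations_nM, mfi,
                               direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  stopifnot(length(concentrations_nM) == length(mfi))
  if (length(mfi) < 4) {
    stop("invalid input: need >= 4 dose points", call. = FALSE)
  }
  if (diff(range(mfi)) <= 1e-9 * max(abs(mfi), 1)) {
    stop("identifiability error: responses show no curvature", call. = FALSE)
  }
  c_nM <- concentrations_nM
  asc <- direction == "ascending"
  lo0 <- min(mfi); hi0 <- max(mfi)
  kd0 <- stats::median(c_nM[c_nM > 0])
  model <- function(p, c) {
    bg <- p[1]; mx <- p[2]; kd <- exp(p[3])
    if (asc) bg + (mx - bg) * c / (c + kd) else bg + (mx - bg) * kd / (c + kd)
  }
  resid_fun <- function(p) mfi - model(p, c_nM)
  starts <- lapply(kd0 * 10^seq(-2, 2, length.out = 5), function(k)
    c(lo0, hi0, log(k)))
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(par = s, fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("dose-response fit failed", call. = FALSE)
  p <- best$fit$par
  kd <- exp(p[3])
  # delta-method SEs from the Gauss-Newton curvature at the optimum
  se <- tryCatch({
    dof <- max(1L, length(mfi) - 3L)
    cv <- solve(best$fit$hessian) * best$sse / dof
    c(sqrt(cv[1, 1]), sqrt(cv[2, 2]), sqrt(cv[3, 3]) * kd)
  }, error = function(e) rep(NA_real_, 3))
  structure(list(kd_nM = kd, kd_molar = kd * 1e-9,
                 background = p[1], maximum = p[2],
                 se = stats::setNames(se, c("background", "maximum", "kd_nM")),
                 residual_norm = sqrt(best$sse), direction = direction),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("dose-response fit (%s): KD %.3g nM, bg %.3g, max %.3g\n",
              x$direction, x$kd_nM, x$background, x$maximum))
  invisible(x)
}

#' Convert a competition EC50 to a dissociation constant
#'
#' `K_D = EC50 / (1 + C_L / K_D_L)`, the standard correction for the
#' labelled-tracer occupancy; with `C_L -> 0` the EC50 is the K_D itself.
#'
#' @param ec50_nM fitted half-inhibition concentration, nM
#' @param c_l_nM labelled-tracer concentration, nM
#' @param kd_l_nM labelled-tracer dissociation constant, nM
#' @return competitor K_D, nM
#' @examples
#' ec50_to_kd(3.268, 5, 1.9)  # ~ 0.9 nM
#' @export
ec50_to_kd <- function(ec50_nM, c_l_nM, kd_l_nM) {
  if (any(c(ec50_nM, c_l_nM, kd_l_nM) <= 0)) {
    stop("invalid input: all concentrations must be positive", call. = FALSE)
  }
  ec50_nM / (1 + c_l_nM / kd_l_nM)
}

#' Global competition fit with shared plateaus
#'
#' All competitor curves are fit jointly to the descending three-parameter
#' dose-response `MFI(x) = min + (max - min) / (1 + x / EC50_i)` with one
#' shared (max, min) pair and one EC50 per competitor, then each EC50 is
#' converted to a K_D via [ec50_to_kd()].  A competitor whose curve never
#' drops below the midpoint within the probed range has its EC50 flagged as
#' a lower bound.
#'
#' @param curves named list, one element per competitor, each a data.frame
#'   with columns `conc_nM` and `mfi`
#' @param c_l_nM labelled-tracer concentration, nM
#' @param kd_l_nM labelled-tracer affinity, nM
#' @return object of class `competition_fit`: `maximum`, `minimum`,
#'   `per_competitor` data.frame (`competitor`, `ec50_nM`, `kd_nM`,
#'   `kd_molar`, `ec50_is_lower_bound`), `residual_norm`
#' @export
fit_competition_global <- function(curves, c_l_nM, kd_l_nM) {
  stopifnot(is.list(curves), length(curves) >= 1)
  if (is.null(names(curves))) names(curves) <- paste0("competitor", seq_along(curves))
  nm <- names(curves)
  k <- length(curves)
  all_mfi <- unlist(lapply(curves, function(d) d$mfi))
  hi0 <- max(all_mfi); lo0 <- min(all_mfi)
  ec0 <- vapply(curves, function(d) {
    mid <- (max(d$mfi) + min(d$mfi)) / 2
    i <- which.min(abs(d$mfi - mid))
    max(d$conc_nM[i], min(d$conc_nM[d$conc_nM > 0]))
  }, numeric(1))
  resid_fun <- function(p) {
    mx <- p[1]; mn <- p[2]; ec <- exp(p[2 + seq_len(k)])
    unlist(lapply(seq_len(k), function(i) {
      d <- curves[[i]]
      d$mfi - (mn + (mx - mn) / (1 + d$conc_nM / ec[i]))
    }))
  }
  starts <- lapply(10^seq(-1, 1, length.out = 5), function(f)
    c(hi0, lo0, log(ec0 * f)))
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(par = s, fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 400, ftol = 1e-12, ptol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("competition fit failed", call. = FALSE)
  p <- unname(best$fit$par)
  ec50 <- exp(p[2 + seq_len(k)])
  # a curve that never reaches the fitted midpoint only bounds its EC50
  lbound <- vapply(seq_len(k), function(i) {
    d <- curves[[i]]
    min(d$mfi) > (p[1] + p[2]) / 2
  }, logical(1))
  kd <- ec50_to_kd(ec50, c_l_nM, kd_l_nM)
  structure(list(maximum = p[1], minimum = p[2],
                 per_competitor = data.frame(
                   competitor = nm, ec50_nM = ec50, kd_nM = kd,
                   kd_molar = kd * 1e-9, ec50_is_lower_bound = lbound,
                   row.names = NULL),
                 c_l_nM = c_l_nM, kd_l_nM = kd_l_nM,
                 residual_norm = sqrt(best$sse)),
            class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("competition fit: shared max %.3g / min %.3g (tracer %.3g nM, KD %.3g nM)\n",
              x$maximum, x$minimum, x$c_l_nM, x$kd_l_nM))
  print(x$per_competitor)
  invisible(x)
}
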