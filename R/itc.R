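# One-site ITC binding model: titration geometry, forward simulation of the
# Wiseman isotherm in a perfusion cell, nonlinear least-squares fitting, and
# derived thermodynamics.
#
# Units: volumes in ul, concentrations in uM, raw heats in ucal, normalized
# heats and enthalpies in kcal/mol. Internally heats are carried in
# "pico-kcal" (uM * ul * kcal/mol = 1e-12 kcal); 1 ucal = 1e3 pico-kcal.

.R_kcal <- 1.9872e-3 # gas constant, kcal / mol / K
.pkcal_per_ucal <- 1e3

#' Titration protocol for a perfusion-cell ITC experiment
#'
#' Defaults follow the common bromodomain protocol on a 200 ul perfusion
#' cell: one initial 0.4 ul injection (discarded during analysis) followed by
#' 18 injections of 2 ul, peptide in the syringe at 1.6 mM titrated into
#' protein at 90 uM, at 15 degrees C.
#'
#' @param cell_volume Cell volume V0 in ul.
#' @param injection_volumes Vector of injection volumes in ul; the first
#'   entry is the initial (discarded) injection.
#' @param syringe_conc Syringe (titrant) concentration X0 in uM.
#' @param cell_conc Cell (macromolecule) concentration M0 in uM.
#' @param temperature Temperature in K.
#' @return An object of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_volume = 200,
                         injection_volumes = c(0.4, rep(2, 18)),
                         syringe_conc = 1600, cell_conc = 90,
                         temperature = 288.15) {
  stopifnot_scalar_number(cell_volume, "cell_volume", lower = 1e-9)
  stopifnot_scalar_number(syringe_conc, "syringe_conc", lower = 1e-12)
  stopifnot_scalar_number(cell_conc, "cell_conc", lower = 1e-12)
  stopifnot_scalar_number(temperature, "temperature", lower = 1e-9)
  if (length(injection_volumes) < 1 || any(injection_volumes <= 0)) {
    abort("injection_volumes must be positive")
  }
  structure(
    list(
      cell_volume = cell_volume,
      injection_volumes = as.numeric(injection_volumes),
      syringe_conc = syringe_conc,
      cell_conc = cell_conc,
      temperature = temperature
    ),
    class = "itc_protocol"
  )
}

#' One-site binding parameters
#'
#' @param N Stoichiometry (binding sites per macromolecule), > 0.
#' @param kd Dissociation constant in uM, > 0.
#' @param dH Binding enthalpy in kcal/mol.
#' @param offset Constant dilution-heat offset in kcal per mol of injectant.
#' @return An object of class `one_site_params` (a named list).
#' @export
one_site_params <- function(N = 1, kd, dH, offset = 0) {
  stopifnot_scalar_number(N, "N", lower = 1e-12)
  stopifnot_scalar_number(kd, "kd", lower = 1e-12)
  stopifnot_scalar_number(dH, "dH")
  stopifnot_scalar_number(offset, "offset")
  structure(list(N = N, kd = kd, dH = dH, offset = offset),
            class = "one_site_params")
}

#' Cell concentrations after each injection
#'
#' Applies the standard perfusion-cell dilution correction: with cumulative
#' injected volume \eqn{dV_i}, the macromolecule concentration is
#' \eqn{M_t = M_0 (1 - dV/2V_0) / (1 + dV/2V_0)} and the total titrant
#' concentration \eqn{X_t = X_0 (dV/V_0) / (1 + dV/2V_0)}. \eqn{M_t}
#' decreases and \eqn{X_t} increases monotonically with the injections.
#'
#' @param protocol An [itc_protocol()].
#' @return A tibble with one row per injection: `injection`, `volume`,
#'   `cumulative_volume`, `Mt`, `Xt` (uM) and `molar_ratio` (Xt/Mt).
#' @export
itc_concentrations <- function(protocol) {
  stopifnot(inherits(protocol, "itc_protocol"))
  v <- protocol$injection_volumes
  V0 <- protocol$cell_volume
  dV <- cumsum(v)
  if (any(dV >= 2 * V0)) {
    abort("cumulative injected volume reaches 2 * cell volume; dilution model invalid")
  }
  d2 <- dV / (2 * V0)
  Mt <- protocol$cell_conc * (1 - d2) / (1 + d2)
  Xt <- protocol$syringe_conc * (dV / V0) / (1 + d2)
  tibble::tibble(
    injection = seq_along(v),
    volume = v,
    cumulative_volume = dV,
    Mt = Mt,
    Xt = Xt,
    molar_ratio = Xt / Mt
  )
}

# Fraction of macromolecule sites occupied: physical root of the one-site
# mass-action quadratic. Vectorized over Xt, Mt.
one_site_theta <- function(Xt, Mt, N, kd) {
  r <- Xt / (N * Mt)
  b <- 1 + r + kd / (N * Mt)
  disc <- b^2 - 4 * r
  stopifnot(all(disc >= 0)) # guaranteed for kd > 0
  (b - sqrt(disc)) / 2
}

# Expected molar heats (kcal/mol of injectant) for every injection.
one_site_molar_heats <- function(N, kd, dH, offset, protocol,
                                 conc = itc_concentrations(protocol)) {
  V0 <- protocol$cell_volume
  v <- protocol$injection_volumes
  # cumulative heat content of the cell, pico-kcal
  Q <- N * one_site_theta(conc$Xt, conc$Mt, N, kd) * conc$Mt * dH * V0
  Qprev <- c(0, Q[-length(Q)])
  moles <- protocol$syringe_conc * v # pico-mol
  dQ <- Q - Qprev + (v / V0) * (Q + Qprev) / 2 + offset * moles
  dQ / moles
}

#' Simulate a one-site binding isotherm
#'
#' Forward-simulates the injection heats of a one-site (Wiseman) titration
#' under a protocol: for each injection the bound fraction comes from the
#' mass-action quadratic, the cell heat content is \eqn{Q_i = N \Theta_i
#' M_{t,i} \Delta H V_0}, and the measured injection heat corrects for the
#' displaced-volume heat, \eqn{\Delta Q_i = Q_i - Q_{i-1} + (v_i/V_0)(Q_i +
#' Q_{i-1})/2}, plus the dilution offset times moles injected. Gaussian noise
#' of standard deviation `noise_sd` (ucal) is added to the raw heats; the
#' first injection is flagged for discarding.
#'
#' @param params A [one_site_params()].
#' @param protocol An [itc_protocol()].
#' @param noise_sd Gaussian noise on raw heats, in ucal (default 0).
#' @param seed Optional integer seed; the simulation is deterministic given
#'   the seed and does not disturb the caller's RNG state.
#' @return A tibble of class `itc_isotherm` with columns `injection`,
#'   `volume`, `molar_ratio`, `raw_heat` (ucal), `molar_heat` (kcal/mol of
#'   injectant) and `discard` (logical, `TRUE` for the initial injection).
#'   The protocol is attached as attribute `"protocol"`.
#' @export
simulate_isotherm <- function(params, protocol = itc_protocol(),
                              noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "one_site_params"))
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  conc <- itc_concentrations(protocol)
  molar <- one_site_molar_heats(params$N, params$kd, params$dH, params$offset,
                                protocol, conc)
  moles <- protocol$syringe_conc * protocol$injection_volumes
  raw <- molar * moles / .pkcal_per_ucal # ucal
  if (noise_sd > 0) {
    raw <- raw + with_seed_or_current(seed, rnorm(length(raw), sd = noise_sd))
  }
  out <- tibble::tibble(
    injection = conc$injection,
    volume = conc$volume,
    molar_ratio = conc$molar_ratio,
    raw_heat = raw,
    molar_heat = raw * .pkcal_per_ucal / moles,
    discard = conc$injection == 1
  )
  attr(out, "protocol") <- protocol
  class(out) <- c("itc_isotherm", class(out))
  out
}

#' Read / write an isotherm CSV
#'
#' The on-disk format is a plain CSV with columns `injection`, `volume`
#' (ul), `raw_heat` (ucal) and optionally `molar_ratio`; the first injection
#' is the initial one and is discarded at fit time.
#'
#' @param path CSV path.
#' @param protocol An [itc_protocol()] supplying concentrations (required to
#'   recompute molar ratios and molar heats if absent from the file).
#' @return For `read_isotherm`, an `itc_isotherm` tibble.
#' @export
read_isotherm <- function(path, protocol) {
  d <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                       progress = FALSE)
  req <- c("injection", "volume", "raw_heat")
  missing <- setdiff(req, names(d))
  if (length(missing) > 0) {
    abort(paste0("isotherm file is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!isTRUE(all.equal(d$volume, protocol$injection_volumes))) {
    abort("isotherm injection volumes do not match the protocol")
  }
  conc <- itc_concentrations(protocol)
  moles <- protocol$syringe_conc * d$volume
  out <- tibble::tibble(
    injection = as.integer(d$injection),
    volume = d$volume,
    molar_ratio = conc$molar_ratio,
    raw_heat = d$raw_heat,
    molar_heat = d$raw_heat * .pkcal_per_ucal / moles,
    discard = seq_len(nrow(d)) == 1
  )
  attr(out, "protocol") <- protocol
  class(out) <- c("itc_isotherm", class(out))
  out
}

#' @rdname read_isotherm
#' @param isotherm An `itc_isotherm` tibble.
#' @export
write_isotherm <- function(isotherm, path) {
  out <- tibble::tibble(
    injection = isotherm$injection,
    volume = isotherm$volume,
    raw_heat = isotherm$raw_heat,
    molar_ratio = isotherm$molar_ratio
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Derived binding thermodynamics
#'
#' Free energy from the dissociation constant, \eqn{\Delta G = RT
#' \ln(K_D \cdot 10^{-6})} (Kd in uM, reference state 1 M), and the entropic
#' term \eqn{-T \Delta S = \Delta G - \Delta H}.
#'
#' @param kd Dissociation constant in uM.
#' @param dH Binding enthalpy in kcal/mol.
#' @param temperature Temperature in K.
#' @return A tibble with columns `dG` and `minus_TdS` (kcal/mol).
#' @export
itc_thermodynamics <- function(kd, dH, temperature) {
  dG <- .R_kcal * temperature * log(kd * 1e-6)
  tibble::tibble(dG = dG, minus_TdS = dG - dH)
}

# Heuristic self-initialization from the isotherm shape.
one_site_init <- function(isotherm, protocol) {
  keep <- !isotherm$discard
  q <- isotherm$molar_heat[keep]
  r <- isotherm$molar_ratio[keep]
  n <- length(q)
  early <- mean(q[seq_len(min(2, n))])
  late <- mean(q[seq.int(max(1, n - 2), n)])
  dH0 <- early - late
  offset0 <- late
  half <- late + dH0 / 2
  # molar ratio where the curve crosses half amplitude ~ stoichiometry
  cross <- which(diff(sign(q - half)) != 0)
  N0 <- if (length(cross) > 0) r[cross[1]] else 1
  N0 <- min(max(N0, 0.3), 3)
  # transition steepness ~ c = N*M/kd; steeper transition, tighter binding
  slope <- max(abs(diff(q) / diff(r)))
  c0 <- min(max(4 * slope / max(abs(dH0), 1e-9), 0.05), 1e4)
  kd0 <- min(max(N0 * protocol$cell_conc / c0, 1e-3), 1e5)
  list(N = N0, kd = kd0, dH = dH0, offset = offset0)
}

#' Fit the one-site binding model to an isotherm
#'
#' Bounded Levenberg-Marquardt least squares on the molar heats of all
#' non-discarded injections, over stoichiometry N, dissociation constant Kd,
#' enthalpy dH and a constant dilution offset. When no initial guess is
#' supplied the fit self-initializes from the isotherm shape (N from the
#' molar ratio at half amplitude, dH from the early-minus-late plateau
#' difference, offset from the final plateau, Kd from the transition
#' steepness) and falls back to a small multi-start if the first attempt does
#' not converge. Bounds: N in \[0.1, 10\], Kd in \[1e-3, 1e5\] uM.
#'
#' Isotherms whose amplitude is below 3x the estimated noise level are
#' refused with a "flat isotherm" error, since no binding signal is present
#' to constrain the parameters.
#'
#' @param isotherm An `itc_isotherm` tibble (at least 6 non-discarded
#'   injections).
#' @param protocol The matching [itc_protocol()]; defaults to the protocol
#'   attached to the isotherm.
#' @param init Optional [one_site_params()] initial guess.
#' @param n_starts Number of multi-start attempts on non-convergence.
#' @return An object of class `one_site_fit`: a list with elements `params`
#'   ([one_site_params()]), `sse`, `dG`, `minus_TdS`, `converged`, `stderr`
#'   (named vector from the local quadratic approximation), `fitted`
#'   (tibble of molar ratio, observed and fitted molar heat) and `protocol`.
#' @export
fit_one_site <- function(isotherm, protocol = attr(isotherm, "protocol"),
                         init = NULL, n_starts = 3) {
  if (is.null(protocol)) abort("no protocol supplied or attached to the isotherm")
  keep <- !isotherm$discard
  if (sum(keep) < 6) abort("at least 6 non-discarded injections are required")
  obs <- isotherm$molar_heat

  # flat-isotherm guard: amplitude must exceed 3x the noise estimate
  q <- obs[keep]
  noise_est <- max(sd(diff(tail(q, 5))) / sqrt(2), 1e-9)
  if (diff(range(q)) < 3 * noise_est) {
    abort("flat isotherm: signal amplitude below 3x estimated noise; fit refused")
  }

  conc <- itc_concentrations(protocol)
  residuals_fn <- function(par) {
    pred <- one_site_molar_heats(par[["N"]], par[["kd"]], par[["dH"]],
                                 par[["offset"]], protocol, conc)
    (pred - obs)[keep]
  }
  lower <- c(N = 0.1, kd = 1e-3, dH = -Inf, offset = -Inf)
  upper <- c(N = 10, kd = 1e5, dH = Inf, offset = Inf)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14, ptol = 1e-12)

  run_fit <- function(start) {
    start <- unlist(start[c("N", "kd", "dH", "offset")])
    start <- pmin(pmax(start, lower), upper)
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = residuals_fn, control = ctrl)
  }

  start0 <- if (is.null(init)) one_site_init(isotherm, protocol) else
    init[c("N", "kd", "dH", "offset")]
  fit <- run_fit(start0)
  best <- fit
  if (!(fit$info %in% 1:3) && n_starts > 1) {
    alt_c <- c(1, 10, 0.1)
    for (k in seq_len(min(n_starts - 1, length(alt_c)))) {
      alt <- start0
      alt$kd <- min(max(as.numeric(start0$N) * protocol$cell_conc / alt_c[k],
                        1e-3), 1e5)
      f2 <- run_fit(alt)
      if (f2$deviance < best$deviance) best <- f2
      if (best$info %in% 1:3) break
    }
  }
  fit <- best

  par <- as.list(fit$par)
  params <- one_site_params(N = par$N, kd = par$kd, dH = par$dH,
                            offset = par$offset)
  sse <- fit$deviance
  dof <- sum(keep) - 4
  # local quadratic approximation: sigma^2 (J'J)^-1 with a central-difference
  # Jacobian at the solution (minpack's returned hessian can be stale)
  stderr <- tryCatch({
    sigma2 <- sse / max(dof, 1)
    p_hat <- fit$par
    J <- vapply(seq_along(p_hat), function(j) {
      h <- max(abs(p_hat[j]) * 1e-6, 1e-9)
      hi <- p_hat; hi[j] <- hi[j] + h
      lo <- p_hat; lo[j] <- lo[j] - h
      (residuals_fn(hi) - residuals_fn(lo)) / (2 * h)
    }, numeric(sum(keep)))
    setNames(sqrt(diag(sigma2 * solve(crossprod(J)))), names(p_hat))
  }, error = function(e) setNames(rep(NA_real_, 4), names(fit$par)))
  thermo <- itc_thermodynamics(params$kd, params$dH, protocol$temperature)
  pred <- one_site_molar_heats(params$N, params$kd, params$dH, params$offset,
                               protocol, conc)
  structure(
    list(
      params = params,
      sse = sse,
      dG = thermo$dG,
      minus_TdS = thermo$minus_TdS,
      converged = fit$info %in% 1:3,
      stderr = stderr,
      fitted = tibble::tibble(
        injection = isotherm$injection,
        molar_ratio = isotherm$molar_ratio,
        observed = obs,
        fitted = pred,
        discard = isotherm$discard
      ),
      protocol = protocol
    ),
    class = "one_site_fit"
  )
}

#' @export
print.one_site_fit <- function(x, ...) {
  p <- x$params
  cat("One-site ITC fit\n")
  cat(sprintf("  N      = %.3f\n", p$N))
  cat(sprintf("  Kd     = %.3g uM\n", p$kd))
  cat(sprintf("  dH     = %.3f kcal/mol\n", p$dH))
  cat(sprintf("  offset = %.4f kcal/mol\n", p$offset))
  cat(sprintf("  dG     = %.3f kcal/mol, -TdS = %.3f kcal/mol\n",
              x$dG, x$minus_TdS))
  cat(sprintf("  SSE    = %.4g, converged: %s\n", x$sse, x$converged))
  invisible(x)
}

#' Tidy a one-site ITC fit
#'
#' @param x A `one_site_fit` object.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @method tidy one_site_fit
#' @export
tidy.one_site_fit <- function(x, ...) {
  est <- unlist(x$params)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(x$stderr[names(est)])
  )
}

#' One-row summary of a one-site ITC fit
#'
#' @param x A `one_site_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the parameters, derived thermodynamics,
#'   `sse` and `converged`.
#' @method glance one_site_fit
#' @export
glance.one_site_fit <- function(x, ...) {
  tibble::tibble(
    N = x$params$N,
    kd = x$params$kd,
    dH = x$params$dH,
    offset = x$params$offset,
    dG = x$dG,
    minus_TdS = x$minus_TdS,
    sse = x$sse,
    converged = x$converged
  )
}
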