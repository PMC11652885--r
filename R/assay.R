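# Cell-based channel-activity analytics: response normalisation, antagonist
# hit calling, competition 4PL IC50 fitting, orthosteric/allosteric
# mechanism classification, repellency indices, and the seeded synthetic
# dose-response generator.

#' Normalise raw signals against the agonist-only control
#'
#' The agonist-only luminescent response defines 100% receptor response for
#' each experimental set.
#'
#' @param raw_signal numeric vector of raw compound-well signals.
#' @param control_signal agonist-only control signal (scalar or vector of
#'   replicates, averaged).
#' @return list: `response_pct` (per replicate), `mean`, `se`.
#' @export
normalize_response <- function(raw_signal, control_signal) {
  ctrl <- mean(control_signal)
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop("control signal must be positive")
  }
  pct <- 100 * raw_signal / ctrl
  list(response_pct = pct, mean = mean(pct),
       se = if (length(pct) > 1) stats::sd(pct) / sqrt(length(pct)) else NA_real_)
}

#' Call a compound an antagonist hit
#'
#' A compound whose primary (compound-only) addition already opens the
#' channel (>= 15% response) is excluded as agonist-like; otherwise it is a
#' hit iff the secondary response upon agonist addition is <= 60% of the
#' agonist-only response (>= 40% inhibition). Both cutoffs follow the
#' campaign's conventions: 60 is inclusive, 15 exclusive.
#'
#' @param secondary_response_pct % response upon agonist addition.
#' @param primary_response_pct % response of the compound alone.
#' @return `"hit"`, `"not_hit"` or `"excluded_agonist_like"`.
#' @export
call_antagonist <- function(secondary_response_pct, primary_response_pct = 0) {
  stopifnot(is.finite(secondary_response_pct),
            is.finite(primary_response_pct))
  if (primary_response_pct >= 15) return("excluded_agonist_like")
  if (secondary_response_pct <= 60) "hit" else "not_hit"
}

.fourpl <- function(conc_uM, a1, a2, log_ic50, p) {
  x <- log10(conc_uM)
  a2 + (a1 - a2) / (1 + 10^((log_ic50 - x) * p))
}

#' Fit a four-parameter logistic competition curve
#'
#' Least-squares fit of `y = A2 + (A1 - A2) / (1 + 10^((log10(IC50) - x) p))`
#' with `x = log10(concentration)`, `A1`/`A2` the bottom/top asymptotes and
#' `p` the Hill slope. Multi-start Nelder-Mead over a deterministic grid of
#' initial Hill slopes and inflection points.
#'
#' @param concentrations_uM antagonist concentrations (>= 4 distinct, > 0).
#' @param responses_pct % responses, one per concentration entry (replicates
#'   are supplied as repeated concentrations).
#' @param agonist_uM agonist level of the series (annotation only).
#' @return list of class `fourpl_fit`: `a1_bottom`, `a2_top`, `hill_p`,
#'   `ic50_uM`, `pic50`, `r_squared`, `rss`, `extrapolated`, `agonist_uM`.
#' @export
fit_4pl <- function(concentrations_uM, responses_pct, agonist_uM = NA_real_) {
  conc <- as.numeric(concentrations_uM)
  y <- as.numeric(responses_pct)
  stopifnot(length(conc) == length(y))
  if (any(conc <= 0)) stop("concentrations must be strictly positive")
  if (length(unique(conc)) < 4) {
    stop("need at least 4 distinct concentrations")
  }
  if (stats::sd(y) == 0) stop("constant responses: 4PL fit undefined")
  x <- log10(conc)
  rss_fun <- function(par) {
    pred <- .fourpl(conc, par[1], par[2], par[3], exp(par[4]))
    sum((y - pred)^2)
  }
  starts <- expand.grid(
    log_ic50 = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    log_p = log(c(0.5, 1, 2))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(min(y), max(y), starts$log_ic50[i], starts$log_p[i])
    fit <- tryCatch(
      stats::optim(par0, rss_fun, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("4PL fit failed from every start")
  # polish with BFGS
  polished <- tryCatch(
    stats::optim(best$par, rss_fun, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14)),
    error = function(e) best)
  if (polished$value <= best$value) best <- polished
  par <- best$par
  a1 <- min(par[1], par[2]); a2 <- max(par[1], par[2])
  ic50 <- 10^par[3]
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - best$value / tss
  rng <- range(conc)
  structure(list(
    a1_bottom = a1, a2_top = a2, hill_p = exp(par[4]),
    ic50_uM = ic50, pic50 = -log10(ic50 * 1e-6),
    r_squared = r2, rss = best$value,
    extrapolated = ic50 < 0.1 * rng[1] || ic50 > 10 * rng[2],
    agonist_uM = agonist_uM
  ), class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> IC50 %.3g uM (pIC50 %.2f), Hill %.2f, A1 %.1f, A2 %.1f, R2 %.3f\n",
    x$ic50_uM, x$pic50, x$hill_p, x$a1_bottom, x$a2_top, x$r_squared))
  invisible(x)
}

#' Global 4PL fit of a competition series
#'
#' Jointly fits several dose-response curves (one per agonist level) with
#' shared bottom/top asymptotes and Hill slope but one IC50 per curve —
#' the standard way to stabilise IC50 shifts across a competition series.
#'
#' @param curves list of curves, each with `concentrations_uM`,
#'   `responses_pct` and `agonist_uM` (as produced by [simulate_assay()]).
#' @return list of `fourpl_fit` objects (one per curve, shared asymptotes
#'   and slope), in input order.
#' @export
fit_4pl_global <- function(curves) {
  K <- length(curves)
  stopifnot(K >= 2)
  singles <- lapply(curves, function(cu) {
    fit_4pl(cu$concentrations_uM, cu$responses_pct, cu$agonist_uM)
  })
  conc <- lapply(curves, function(cu) as.numeric(cu$concentrations_uM))
  resp <- lapply(curves, function(cu) as.numeric(cu$responses_pct))
  rss_fun <- function(par) {
    a1 <- par[1]; a2 <- par[2]; p <- exp(par[3])
    sum(vapply(seq_len(K), function(k) {
      pred <- .fourpl(conc[[k]], a1, a2, par[3 + k], p)
      sum((resp[[k]] - pred)^2)
    }, numeric(1)))
  }
  par0 <- c(mean(vapply(singles, function(f) f$a1_bottom, numeric(1))),
            mean(vapply(singles, function(f) f$a2_top, numeric(1))),
            log(mean(vapply(singles, function(f) f$hill_p, numeric(1)))),
            vapply(singles, function(f) log10(f$ic50_uM), numeric(1)))
  fit <- stats::optim(par0, rss_fun, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  fit <- stats::optim(fit$par, rss_fun, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  par <- fit$par
  a1 <- min(par[1], par[2]); a2 <- max(par[1], par[2])
  lapply(seq_len(K), function(k) {
    y <- resp[[k]]
    pred <- .fourpl(conc[[k]], a1, a2, par[3 + k], exp(par[3]))
    rng <- range(conc[[k]])
    ic50 <- 10^par[3 + k]
    structure(list(
      a1_bottom = a1, a2_top = a2, hill_p = exp(par[3]),
      ic50_uM = ic50, pic50 = -log10(ic50 * 1e-6),
      r_squared = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
      rss = sum((y - pred)^2),
      extrapolated = ic50 < 0.1 * rng[1] || ic50 > 10 * rng[2],
      agonist_uM = curves[[k]]$agonist_uM
    ), class = "fourpl_fit")
  })
}

#' Classify antagonist mechanism from agonist-shifted IC50s
#'
#' A competitive (orthosteric) antagonist is surmountable: its apparent
#' IC50 grows with the agonist concentration. An allosteric antagonist's
#' IC50 is agonist-independent. The call is `"orthosteric"` when the IC50s
#' increase monotonically across the agonist series and the 150/50 uM fold
#' shift reaches `fold_threshold`; `"allosteric"` when the fold shift stays
#' below the threshold; `"indeterminate"` otherwise (non-monotone above
#' threshold, missing levels, or poor fits).
#'
#' @param fits list of `fourpl_fit` objects with distinct `agonist_uM`
#'   levels (typically 50, 100, 150), or a list of raw curves (elements
#'   with `concentrations_uM`) which is then fitted globally with
#'   [fit_4pl_global()] — the preferred, lower-variance route.
#' @param fold_threshold minimum high/low-agonist IC50 ratio to call a
#'   surmountable shift (default 1.3).
#' @param min_r_squared fit-quality gate (default 0.8).
#' @param mono_tol relative tolerance of the monotonicity check: each step
#'   of the IC50 series may dip by at most this fraction before the series
#'   counts as non-monotone (default 0.15, absorbing fit noise at the
#'   assay's triplicate/5%-noise scale).
#' @return list of class `mechanism_call`: `call`, `fold_shift`,
#'   `ic50_by_agonist`, `reason`.
#' @export
classify_mechanism <- function(fits, fold_threshold = 1.3,
                               min_r_squared = 0.8, mono_tol = 0.15) {
  if (length(fits) > 0 && !is.null(fits[[1]]$concentrations_uM)) {
    fits <- fit_4pl_global(fits)
  }
  ag <- vapply(fits, function(f) f$agonist_uM, numeric(1))
  if (any(is.na(ag)) || anyDuplicated(ag) || length(ag) < 3) {
    return(structure(list(call = "indeterminate", fold_shift = NA_real_,
                          ic50_by_agonist = NULL,
                          reason = "need >= 3 distinct agonist levels"),
                     class = "mechanism_call"))
  }
  ord <- order(ag)
  ic50 <- vapply(fits, function(f) f$ic50_uM, numeric(1))[ord]
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))[ord]
  ic50_map <- stats::setNames(ic50, ag[ord])
  if (any(r2 < min_r_squared)) {
    return(structure(list(call = "indeterminate",
                          fold_shift = ic50[length(ic50)] / ic50[1],
                          ic50_by_agonist = ic50_map,
                          reason = "fit quality below threshold"),
                     class = "mechanism_call"))
  }
  # the competitive shift law IC50([A]) = Kb (1 + [A]/EC50) is linear in
  # the agonist concentration, so the fold shift is estimated from a
  # least-squares line over all levels (stabler than the raw endpoint
  # ratio under fit noise); the raw series is kept for the monotone check
  ag_s <- ag[ord]
  line <- stats::lm(ic50 ~ ag_s)
  ends <- unname(stats::predict(line, data.frame(ag_s = range(ag_s))))
  fold <- if (ends[1] > 0) ends[2] / ends[1] else ic50[length(ic50)] / ic50[1]
  monotone <- all(ic50[-1] >= ic50[-length(ic50)] * (1 - mono_tol))
  call <- if (fold >= fold_threshold && monotone) {
    "orthosteric"
  } else if (fold < fold_threshold) {
    "allosteric"
  } else {
    "indeterminate"
  }
  structure(list(call = call, fold_shift = fold, ic50_by_agonist = ic50_map,
                 reason = if (call == "indeterminate") {
                   "non-monotone IC50 series above fold threshold"
                 }),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("<mechanism_call> ", x$call,
      if (is.finite(x$fold_shift)) sprintf(" (fold shift %.2f)", x$fold_shift),
      "\n", sep = "")
  invisible(x)
}

#' Repellency index from landing counts
#'
#' `RI = 1 - T/C` with `T` landings on the treated hand and `C` on the
#' control; reported both as a fraction and as a percentage.
#'
#' @param treatment_landings non-negative count T.
#' @param control_landings positive count C.
#' @return list of class `repellency_result`: `ri` (fraction), `ri_percent`.
#' @export
repellency_index <- function(treatment_landings, control_landings) {
  if (control_landings <= 0) stop("control landings must be > 0")
  if (treatment_landings < 0) stop("treatment landings must be >= 0")
  ri <- 1 - treatment_landings / control_landings
  structure(list(ri = ri, ri_percent = 100 * ri,
                 treatment_landings = treatment_landings,
                 control_landings = control_landings),
            class = "repellency_result")
}

#' Simulate competition dose-response curves
#'
#' Generates replicate % responses on a 4PL truth with Gaussian noise. In
#' `"competitive"` mode the apparent IC50 follows the Schild-consistent
#' shift `IC50([A]) = Kb (1 + [A]/EC50)`; in `"noncompetitive"` mode the
#' IC50 is agonist-independent at `Kb`.
#'
#' @param mechanism `"competitive"` or `"noncompetitive"`.
#' @param kb_uM antagonist potency constant (default 25 uM).
#' @param agonist_uM agonist levels (default `c(50, 100, 150)`).
#' @param agonist_ec50_uM agonist EC50 for the shift law (default 100 uM,
#'   the assay's reference level).
#' @param a1_bottom,a2_top,hill_p 4PL truth (defaults 0, 100, 1).
#' @param concentrations_uM tested antagonist series (default 8 log-spaced
#'   points over 1-1000 uM, the assayed range).
#' @param n_replicates replicates per concentration (default 3).
#' @param sigma Gaussian noise sd in % response units (default 5).
#' @param seed integer seed.
#' @return list of per-agonist-level curves, each a list with
#'   `agonist_uM`, `true_ic50_uM`, `concentrations_uM`, `responses_pct`.
#' @export
simulate_assay <- function(mechanism = c("competitive", "noncompetitive"),
                           kb_uM = 25, agonist_uM = c(50, 100, 150),
                           agonist_ec50_uM = 100,
                           a1_bottom = 0, a2_top = 100, hill_p = 1,
                           concentrations_uM = 10^seq(0, 3, length.out = 8),
                           n_replicates = 3, sigma = 5, seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(sigma >= 0, kb_uM > 0, n_replicates >= 1,
            all(concentrations_uM > 0))
  .with_seed(seed, lapply(agonist_uM, function(a) {
    ic50 <- if (mechanism == "competitive") {
      kb_uM * (1 + a / agonist_ec50_uM)
    } else {
      kb_uM
    }
    conc <- rep(concentrations_uM, each = n_replicates)
    mu <- .fourpl(conc, a1_bottom, a2_top, log10(ic50), hill_p)
    list(agonist_uM = a, true_ic50_uM = ic50, concentrations_uM = conc,
         responses_pct = mu + stats::rnorm(length(conc), 0, sigma))
  }))
}
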