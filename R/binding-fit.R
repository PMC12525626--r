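#' Convert polarized intensities to millipolarization
#'
#' FP = (F_parallel - F_perpendicular) / (F_parallel + F_perpendicular),
#' scaled to millipolarization units (mP). Bounded in \[-1000, 1000\].
#'
#' @param f_parallel,f_perpendicular Fluorescence intensities parallel
#'   and perpendicular to the excitation plane (arbitrary units, >= 0).
#' @return FP in mP (vectorised).
#' @export
#' @examples
#' fp_millipolarization(3, 1)   # 500 mP
fp_millipolarization <- function(f_parallel, f_perpendicular) {
  total <- f_parallel + f_perpendicular
  if (any(total <= 0)) {
    stop_input("total intensity must be positive")
  }
  1000 * (f_parallel - f_perpendicular) / total
}

#' Read an FP plate CSV
#'
#' Columns: `conc` (protein concentration, uM) plus either `f_parallel`
#' and `f_perpendicular` intensities or a precomputed `fp` column (mP).
#' Optional columns: `replicate_id` (default 1) and a logical
#' `is_baseline` flag marking no-protein wells (when absent, wells with
#' `conc == 0` are taken as baseline).
#'
#' @param path File path.
#' @return Data frame of wells with columns `conc`, `fp`,
#'   `replicate_id`, `is_baseline`.
#' @export
read_fp_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"conc" %in% names(df)) stop_input("plate file needs a conc column")
  if (!"fp" %in% names(df)) {
    if (!all(c("f_parallel", "f_perpendicular") %in% names(df))) {
      stop_input("plate file needs fp or f_parallel/f_perpendicular")
    }
    df$fp <- fp_millipolarization(df$f_parallel, df$f_perpendicular)
  }
  if (!"replicate_id" %in% names(df)) df$replicate_id <- 1L
  if (!"is_baseline" %in% names(df)) df$is_baseline <- df$conc == 0
  df$is_baseline <- as.logical(df$is_baseline)
  df[, c("conc", "fp", "replicate_id", "is_baseline")]
}

#' Baseline-correct FP wells into a titration
#'
#' Subtracts, within each replicate group (each separate experiment),
#' the mean FP of that group's no-protein wells from every measured
#' well, yielding delta-FP values in mP.
#'
#' @param wells Data frame with columns `conc`, `fp`, `replicate_id`,
#'   `is_baseline` (see [read_fp_plate()]).
#' @param peptide_name,arc_variant Optional labels carried on the result.
#' @return An `fp_titration`: data frame with columns `conc`,
#'   `delta_fp`, `replicate_id` and attributes `peptide_name`,
#'   `arc_variant`.
#' @export
baseline_correct <- function(wells, peptide_name = NA, arc_variant = NA) {
  stopifnot(all(c("conc", "fp", "replicate_id", "is_baseline")
                %in% names(wells)))
  groups <- split(wells, wells$replicate_id)
  out <- lapply(groups, function(g) {
    base <- g$fp[g$is_baseline]
    if (length(base) == 0) {
      stop_input("no baseline (no-protein) wells in replicate group ",
                 g$replicate_id[1])
    }
    meas <- g[!g$is_baseline, , drop = FALSE]
    data.frame(conc = meas$conc, delta_fp = meas$fp - mean(base),
               replicate_id = meas$replicate_id,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  fp_titration(res, peptide_name = peptide_name, arc_variant = arc_variant)
}

fp_titration <- function(points, peptide_name = NA, arc_variant = NA) {
  stopifnot(all(c("conc", "delta_fp") %in% names(points)))
  if (any(points$conc < 0)) stop_input("concentrations must be >= 0")
  if (!"replicate_id" %in% names(points)) points$replicate_id <- 1L
  structure(points, class = c("fp_titration", "data.frame"),
            peptide_name = peptide_name, arc_variant = arc_variant)
}

#' One-site total-binding model
#'
#' delta-FP(x) = Bmax * x / (Kd + x) + NS * x: a hyperbolic specific
#' term plus a linear nonspecific term, with the constant background
#' fixed at zero because titrations are baseline-corrected. The fitted
#' x is the total ARC concentration (no ligand-depletion correction),
#' the standard analysis when the fluorescent tracer concentration is
#' far below Kd.
#'
#' @param conc Concentration (uM).
#' @param kd Dissociation constant (uM).
#' @param bmax Saturating specific signal (mP).
#' @param ns Nonspecific slope (mP per uM).
#' @param background Constant offset (mP), default 0.
#' @return Predicted delta-FP (mP).
#' @export
one_site_total <- function(conc, kd, bmax, ns, background = 0) {
  bmax * conc / (kd + conc) + ns * conc + background
}

#' Fit a titration with the one-site total-binding model
#'
#' Nonlinear least squares over all points (replicates enter as
#' separate observations). Kd is fitted on the log scale, which keeps
#' its trajectory positive; standard errors come from the Jacobian-based
#' covariance at the optimum (SE of Kd by the delta method from
#' SE of log Kd). Initialisation: Kd at the concentration nearest
#' half-maximal delta-FP, Bmax at the maximal delta-FP, NS at 0.
#'
#' @param titration An `fp_titration` (or data frame with `conc` and
#'   `delta_fp`); at least 5 distinct concentrations.
#' @param init Optional named list with any of `kd`, `bmax`, `ns`.
#' @param constrain_ns Logical; constrain the nonspecific slope to be
#'   non-negative (default FALSE).
#' @param include_background Logical; add a fitted constant offset
#'   (default FALSE, appropriate for baseline-corrected data).
#' @return A `fit_result` list: `kd`, `bmax`, `ns`, `background`,
#'   `se_kd`, `se_bmax`, `se_ns`, `rss`, `converged`, `n_points`,
#'   `kd_identifiable` (FALSE when SE(Kd) >= 10 x Kd or the fit failed)
#'   and `message`.
#' @export
#' @examples
#' tt <- simulate_titration(kd = 2, bmax = 200, ns = 0)
#' fit_one_site_total(tt)$kd
fit_one_site_total <- function(titration, init = NULL,
                               constrain_ns = FALSE,
                               include_background = FALSE) {
  d <- as.data.frame(titration)[, c("conc", "delta_fp")]
  d <- d[is.finite(d$conc) & is.finite(d$delta_fp), , drop = FALSE]
  if (length(unique(d$conc[d$conc > 0])) < 5) {
    stop_input("need at least 5 distinct positive concentrations")
  }
  init <- init %||% list()
  bmax0 <- init$bmax %||% max(d$delta_fp)
  if (bmax0 <= 0) bmax0 <- max(abs(d$delta_fp), 1)
  half <- bmax0 / 2
  kd0 <- init$kd %||% d$conc[which.min(abs(d$delta_fp - half))]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(d$conc[d$conc > 0])
  ns0 <- init$ns %||% 0
  par <- c(lkd = log(kd0), bmax = bmax0, ns = ns0)
  lower <- c(lkd = -Inf, bmax = -Inf,
             ns = if (constrain_ns) 0 else -Inf)
  if (include_background) {
    par <- c(par, bg = 0)
    lower <- c(lower, bg = -Inf)
  }
  predict_par <- function(p, x) {
    one_site_total(x, exp(p[["lkd"]]), p[["bmax"]], p[["ns"]],
                   if (include_background) p[["bg"]] else 0)
  }
  resid_fn <- function(p) d$delta_fp - predict_par(p, d$conc)
  run_lm <- function(p0) {
    tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) e)
  }
  # multi-start: the requested start, the data-driven heuristic start,
  # and shifted Kd guesses, so a poor initialisation cannot strand the
  # optimiser; lowest RSS wins
  bmax_h <- max(d$delta_fp)
  if (bmax_h <= 0) bmax_h <- max(abs(d$delta_fp), 1)
  kd_h <- d$conc[which.min(abs(d$delta_fp - bmax_h / 2))]
  if (!is.finite(kd_h) || kd_h <= 0) kd_h <- stats::median(d$conc[d$conc > 0])
  heuristic <- par
  heuristic[c("lkd", "bmax", "ns")] <- c(log(kd_h), bmax_h, 0)
  starts <- list(par, heuristic)
  for (fac in c(0.1, 10)) {
    alt <- par
    alt[["lkd"]] <- par[["lkd"]] + log(fac)
    starts <- c(starts, list(alt))
  }
  fits <- lapply(starts, run_lm)
  ok <- !vapply(fits, inherits, logical(1), "error")
  fit <- if (any(ok)) {
    fits[ok][[which.min(vapply(fits[ok], stats::deviance, numeric(1)))]]
  } else fits[[1]]
  failed <- inherits(fit, "error")
  converged <- !failed && fit$info %in% 1:4
  if (failed) {
    return(structure(list(kd = NA_real_, bmax = NA_real_, ns = NA_real_,
                          background = if (include_background) NA_real_ else 0,
                          se_kd = NA_real_, se_bmax = NA_real_,
                          se_ns = NA_real_, rss = NA_real_,
                          converged = FALSE, n_points = nrow(d),
                          kd_identifiable = FALSE,
                          message = conditionMessage(fit)),
                     class = "fit_result"))
  }
  est <- fit$par
  kd <- exp(est[["lkd"]])
  # Jacobian-based covariance at the optimum: s^2 (J'J)^-1, with J by
  # central finite differences on the prediction function
  J <- vapply(seq_along(est), function(j) {
    h <- pmax(1e-7, 1e-7 * abs(est[[j]]))
    up <- est; up[[j]] <- up[[j]] + h
    dn <- est; dn[[j]] <- dn[[j]] - h
    (predict_par(up, d$conc) - predict_par(dn, d$conc)) / (2 * h)
  }, numeric(nrow(d)))
  rss <- sum(resid_fn(est)^2)
  dof <- nrow(d) - length(est)
  se <- tryCatch({
    covm <- chol2inv(chol(crossprod(J))) * (rss / max(dof, 1))
    stats::setNames(sqrt(pmax(diag(covm), 0)), names(est))
  }, error = function(e) NULL)
  se_lkd <- if (is.null(se)) NA_real_ else se[["lkd"]]
  se_kd <- kd * se_lkd                    # delta method on log Kd
  se_bmax <- if (is.null(se)) NA_real_ else se[["bmax"]]
  # Kd only means something when a specific component is resolved:
  # Bmax must clear its own uncertainty and SE(Kd) must stay < 10 Kd
  identifiable <- converged && !is.null(se) && is.finite(se_kd) &&
    se_kd < 10 * kd && is.finite(se_bmax) &&
    abs(est[["bmax"]]) > 2 * se_bmax
  structure(list(
    kd = kd,
    bmax = est[["bmax"]],
    ns = est[["ns"]],
    background = if (include_background) est[["bg"]] else 0,
    se_kd = se_kd,
    se_bmax = se_bmax,
    se_ns = if (is.null(se)) NA_real_ else se[["ns"]],
    rss = rss,
    converged = converged,
    n_points = nrow(d),
    kd_identifiable = identifiable,
    message = fit$message %||% ""),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("One-site total-binding fit (", x$n_points, " points)\n", sep = "")
  cat(sprintf("  Kd   = %.4g +/- %.2g uM%s\n", x$kd, x$se_kd,
              if (!x$kd_identifiable) "  [Kd not identifiable]" else ""))
  cat(sprintf("  Bmax = %.4g +/- %.2g mP\n", x$bmax, x$se_bmax))
  cat(sprintf("  NS   = %.4g +/- %.2g mP/uM\n", x$ns, x$se_ns))
  cat(sprintf("  RSS  = %.4g; converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' Affinity fold change from a pair of Kd values
#'
#' Returns `kd_reference / kd_variant`; values above 1 indicate an
#' affinity gain of the variant (e.g. the phosphorylated peptide) over
#' the reference.
#'
#' @param kd_reference,kd_variant Dissociation constants (uM, > 0).
#' @return Dimensionless fold change.
#' @export
#' @examples
#' fold_change(19.3, 1.6)               # 12-fold gain
#' fold_change_label(fold_change(19.3, 1.6))
fold_change <- function(kd_reference, kd_variant) {
  if (any(kd_reference <= 0) || any(kd_variant <= 0)) {
    stop_input("Kd values must be positive")
  }
  kd_reference / kd_variant
}

#' @rdname fold_change
#' @param fold Numeric fold change.
#' @export
fold_change_label <- function(fold) {
  paste0(signif(fold, 2), "-fold")
}

#' Simulate an FP titration from the one-site total-binding model
#'
#' Generates delta-FP values on a concentration grid (default a
#' 12-point 2-fold dilution series from 200 uM) with optional Gaussian
#' noise. With a seed the draw is bitwise reproducible.
#'
#' @param kd,bmax,ns Model parameters (uM, mP, mP/uM); `kd`, `bmax`
#'   must be >= 0.
#' @param concs Concentration grid (uM).
#' @param noise_sd Gaussian noise standard deviation (mP); 0 for
#'   noise-free data.
#' @param seed RNG seed; required when `noise_sd > 0`.
#' @param replicates Number of replicate series; default 1.
#' @param peptide_name,arc_variant Optional labels.
#' @return An `fp_titration`.
#' @export
simulate_titration <- function(kd, bmax, ns = 0,
                               concs = 200 / 2^(0:11),
                               noise_sd = 0, seed = NULL,
                               replicates = 1L,
                               peptide_name = NA, arc_variant = NA) {
  if (kd < 0 || bmax < 0) stop_input("kd and bmax must be >= 0")
  if (noise_sd > 0 && is.null(seed)) {
    stop_input("a seed is required for noisy simulations")
  }
  if (!is.null(seed)) set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    mu <- one_site_total(concs, kd, bmax, ns)
    noise <- if (noise_sd > 0) stats::rnorm(length(concs), 0, noise_sd)
             else 0
    data.frame(conc = concs, delta_fp = mu + noise, replicate_id = r)
  }))
  fp_titration(pts, peptide_name = peptide_name, arc_variant = arc_variant)
}

#' Plot a titration and its fit
#'
#' Base-graphics semilog plot of delta-FP against concentration with
#' the fitted one-site total-binding curve overlaid.
#'
#' @param titration An `fp_titration`.
#' @param fit Optional `fit_result` to overlay.
#' @param ... Passed to [plot()].
#' @export
plot_titration <- function(titration, fit = NULL, ...) {
  d <- as.data.frame(titration)
  d <- d[d$conc > 0, , drop = FALSE]
  plot(d$conc, d$delta_fp, log = "x",
       xlab = "[ARC] (uM)", ylab = expression(Delta * "FP (mP)"), ...)
  if (!is.null(fit) && isTRUE(fit$converged)) {
    xx <- exp(seq(log(min(d$conc)), log(max(d$conc)), length.out = 200))
    graphics::lines(xx, one_site_total(xx, fit$kd, fit$bmax, fit$ns,
                                       fit$background))
  }
  invisible(NULL)
}
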