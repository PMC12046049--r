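#' Assemble a titration dataset
#'
#' Validates and tags a long-format table of replicate signal fractions
#' across a concentration series, the substrate for [fit_kd()].
#'
#' @param data data frame with columns `f_total`, `h_total`, `replicate`,
#'   `species`, `fraction` (species one of `monomer`, `homodimer`,
#'   `heterodimer`, `h_monomer`). Concentrations in molar unless `unit`
#'   says otherwise.
#' @param signal_model intensity response model the fractions were
#'   computed under; see [simulate_titration()].
#' @param label free-text dataset label.
#' @param unit concentration unit of `f_total`/`h_total`.
#' @return the data frame, classed `"titration_data"`, concentrations in
#'   molar.
#' @export
titration_data <- function(data,
                           signal_model = c("species-molar",
                                            "per-subunit"),
                           label = "", unit = "M") {
  signal_model <- match.arg(signal_model)
  need <- c("f_total", "h_total", "replicate", "species", "fraction")
  if (!all(need %in% names(data)))
    stop("titration_data: missing columns: ",
         paste(setdiff(need, names(data)), collapse = ", "),
         call. = FALSE)
  data$f_total <- as_molar(data$f_total, unit)
  data$h_total <- as_molar(data$h_total, unit)
  # each (point, replicate) must be a complete simplex
  key <- interaction(data$f_total, data$h_total, data$replicate,
                     drop = TRUE)
  sums <- tapply(data$fraction, key, sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("titration_data: replicate fractions must sum to 1 (+/- 1e-6)",
         call. = FALSE)
  if (length(unique(data$f_total)) < 3)
    warning("titration_data: fewer than 3 concentration points; ",
            "KD fitting requires >= 3", call. = FALSE)
  structure(data, class = c("titration_data", "data.frame"),
            signal_model = signal_model, label = label)
}

# Forward-model fractions at one titration point. Uses the analytic
# homodimer solution when no chaperone is in play.
.predict_fractions <- function(kd_homo, kd_hetero, f_total, h_total,
                               signal_model) {
  st <- if (h_total == 0 || !is.finite(kd_hetero))
    homodimer_closed_form(kd_homo, f_total)
  else
    solve_species(eq_system(kd_homo, kd_hetero, f_total, h_total))
  if (h_total > 0 && !is.finite(kd_hetero)) st$h_mono <- h_total
  .signal_fractions(st, signal_model)
}

# Sum of squared residuals for one replicate's observations at a trial
# log10 KD. `which` selects the fitted species columns.
.sse_titration <- function(log10kd, obs, mode, kd_homo, signal_model) {
  kd <- 10^log10kd
  sse <- 0
  for (i in seq_len(nrow(obs$points))) {
    p <- obs$points[i, ]
    pred <- if (mode == "homodimer")
      .predict_fractions(kd, Inf, p$f_total, 0, signal_model)
    else
      .predict_fractions(kd_homo, kd, p$f_total, p$h_total, signal_model)
    if (mode == "homodimer") {
      # dimer-signal fraction among F species
      pd <- pred[["homodimer"]] /
        (pred[["monomer"]] + pred[["homodimer"]])
      sse <- sse + (obs$dimer_frac[i] - pd)^2
    } else {
      sse <- sse + sum((obs$frac[i, ] - pred)^2)
    }
  }
  sse
}

# Reshape one replicate of a titration_data into the structure the
# objective consumes.
.replicate_obs <- function(data, rep_id, mode) {
  d <- data[data$replicate == rep_id, , drop = FALSE]
  pts <- unique(d[, c("f_total", "h_total")])
  pts <- pts[order(pts$f_total), , drop = FALSE]
  if (mode == "homodimer") {
    dimer_frac <- vapply(seq_len(nrow(pts)), function(i) {
      di <- d[d$f_total == pts$f_total[i], ]
      fm <- di$fraction[di$species == "monomer"]
      fd <- di$fraction[di$species == "homodimer"]
      fd / (fm + fd)
    }, numeric(1))
    list(points = pts, dimer_frac = dimer_frac)
  } else {
    species <- c("monomer", "homodimer", "h_monomer", "heterodimer")
    frac <- t(vapply(seq_len(nrow(pts)), function(i) {
      di <- d[d$f_total == pts$f_total[i] &
                d$h_total == pts$h_total[i], ]
      vapply(species, function(s) di$fraction[di$species == s][1],
             numeric(1))
    }, numeric(4)))
    colnames(frac) <- species
    list(points = pts, frac = frac)
  }
}

.fit_one <- function(obs, mode, kd_homo, signal_model, bracket) {
  opt <- stats::optimize(.sse_titration, log10(bracket), obs = obs,
                         mode = mode, kd_homo = kd_homo,
                         signal_model = signal_model, tol = 1e-10)
  list(kd = 10^opt$minimum, sse = opt$objective,
       at_boundary = min(abs(opt$minimum - log10(bracket))) < 0.01)
}

#' Fit a dissociation constant to titration data
#'
#' Estimates the dissociation constant of the homodimer, the heterodimer
#' (with the homodimer KD held fixed from an independent fit), or a 1:1
#' peptide-binding isotherm, by least squares over a bracketed search in
#' log10(KD). By default each replicate is fitted independently and the
#' estimate is reported as mean +/- SD across replicates.
#'
#' @param data for modes `homodimer`/`heterodimer`, a [titration_data()]
#'   (or plain data frame with its columns, molar units); for mode
#'   `peptide`, a data frame with columns `ligand_total` (molar),
#'   `replicate`, `fraction_bound`.
#' @param mode what to fit.
#' @param kd_homo for mode `heterodimer`: homodimer KD, either a
#'   `kd_fit`, or `c(kd, sd)` in molar. Its uncertainty is propagated by
#'   refitting at `kd +/- sd` and adding the spread in quadrature.
#' @param replicates `"independent"` (fit each replicate, report
#'   mean +/- SD; the default) or `"mean"` (single fit to replicate-mean
#'   observations; SD then comes only from `kd_homo` propagation or
#'   [bootstrap_kd()]).
#' @param bracket KD search interval in molar.
#' @param signal_model overrides the dataset's tag if given.
#' @param isotherm_mode passed to [peptide_isotherm()] for mode
#'   `peptide`.
#' @return an object of class `"kd_fit"` with components `kd`, `sd`
#'   (molar), `n_replicates`, `residual_rms`, `per_replicate`, `method`,
#'   `mode`, plus the data and settings used. Standard methods
#'   (`print`, `summary`, `coef`, `predict`, `plot`, `residuals`,
#'   `simulate`) apply.
#' @export
fit_kd <- function(data,
                   mode = c("homodimer", "heterodimer", "peptide"),
                   kd_homo = NULL,
                   replicates = c("independent", "mean"),
                   bracket = c(1e-12, 1e-2),
                   signal_model = NULL,
                   isotherm_mode = "free_ligand_approx") {
  mode <- match.arg(mode)
  replicates <- match.arg(replicates)
  cl <- match.call()

  if (mode == "peptide")
    return(.fit_peptide(data, replicates, bracket, isotherm_mode, cl))

  if (is.null(signal_model))
    signal_model <- attr(data, "signal_model")
  if (is.null(signal_model)) signal_model <- "species-molar"
  if (length(unique(data$f_total)) < 3)
    stop("fit_kd: >= 3 concentration points required", call. = FALSE)

  if (mode == "homodimer" && any(data$h_total != 0))
    stop("fit_kd: homodimer mode requires h_total = 0 at every point",
         call. = FALSE)
  if (mode == "heterodimer") {
    if (any(data$h_total <= 0))
      stop("fit_kd: heterodimer mode requires h_total > 0 at every point",
           call. = FALSE)
    if (is.null(kd_homo))
      stop("fit_kd: heterodimer mode requires kd_homo from an ",
           "independent homodimer fit", call. = FALSE)
    if (inherits(kd_homo, "kd_fit")) kd_homo <- c(kd_homo$kd, kd_homo$sd)
    if (length(kd_homo) == 1) kd_homo <- c(kd_homo, 0)
  }
  kh <- if (mode == "heterodimer") kd_homo[1] else NA_real_

  rep_ids <- sort(unique(data$replicate))
  if (replicates == "independent") {
    fits <- lapply(rep_ids, function(r)
      .fit_one(.replicate_obs(data, r, mode), mode, kh, signal_model,
               bracket))
    kds <- vapply(fits, `[[`, numeric(1), "kd")
    kd_hat <- mean(kds)
    sd_rep <- if (length(kds) > 1) stats::sd(kds) else {
      warning("fit_kd: single replicate; SD reported as 0",
              call. = FALSE)
      0
    }
    at_boundary <- any(vapply(fits, `[[`, logical(1), "at_boundary"))
  } else {
    mobs <- .mean_obs(data, rep_ids, mode)
    f <- .fit_one(mobs, mode, kh, signal_model, bracket)
    kds <- f$kd
    kd_hat <- f$kd
    sd_rep <- 0
    at_boundary <- f$at_boundary
  }

  sd_total <- sd_rep
  if (mode == "heterodimer" && kd_homo[2] > 0) {
    mobs <- .mean_obs(data, rep_ids, mode)
    k_lo <- .fit_one(mobs, mode, kd_homo[1] - kd_homo[2], signal_model,
                     bracket)$kd
    k_hi <- .fit_one(mobs, mode, kd_homo[1] + kd_homo[2], signal_model,
                     bracket)$kd
    spread <- abs(k_hi - k_lo) / 2
    sd_total <- sqrt(sd_rep^2 + spread^2)
  }

  mobs <- .mean_obs(data, rep_ids, mode)
  rss <- .sse_titration(log10(kd_hat), mobs, mode, kh, signal_model)
  n_res <- if (mode == "homodimer") nrow(mobs$points) else
    4L * nrow(mobs$points)

  # no-curvature guard: an all-monomer or all-dimer dataset cannot
  # constrain the KD
  dimfrac <- if (mode == "homodimer") mobs$dimer_frac else
    mobs$frac[, "heterodimer"]
  if (max(dimfrac) < 0.05 || min(dimfrac) > 0.95) at_boundary <- TRUE

  flags <- character(0)
  if (at_boundary) {
    flags <- "boundary"
    warning("fit_kd: estimate at the edge of the search bracket or ",
            "data carry no curvature", call. = FALSE)
  }

  structure(list(kd = kd_hat, sd = sd_total,
                 n_replicates = length(rep_ids),
                 residual_rms = sqrt(rss / n_res),
                 per_replicate = kds,
                 method = paste0("least-squares/", replicates),
                 mode = mode, kd_homo = if (mode == "heterodimer")
                   kd_homo else NULL,
                 signal_model = signal_model, bracket = bracket,
                 flags = flags, data = data, call = cl),
            class = "kd_fit")
}

.mean_obs <- function(data, rep_ids, mode) {
  obs <- lapply(rep_ids, function(r) .replicate_obs(data, r, mode))
  out <- obs[[1]]
  if (mode == "homodimer")
    out$dimer_frac <- rowMeans(vapply(obs, `[[`,
                                      numeric(nrow(out$points)),
                                      "dimer_frac"))
  else
    out$frac <- Reduce(`+`, lapply(obs, `[[`, "frac")) / length(obs)
  out
}

.fit_peptide <- function(data, replicates, bracket, isotherm_mode, cl) {
  need <- c("ligand_total", "replicate", "fraction_bound")
  if (!all(need %in% names(data)))
    stop("fit_kd(peptide): need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!any(data$fraction_bound > 0.1 & data$fraction_bound < 0.9))
    warning("fit_kd(peptide): no observation in (0.1, 0.9); KD is ",
            "poorly constrained", call. = FALSE)
  sse <- function(log10kd, d) {
    pred <- peptide_isotherm(10^log10kd, d$ligand_total,
                             mode = isotherm_mode)
    sum((d$fraction_bound - pred)^2)
  }
  rep_ids <- sort(unique(data$replicate))
  fit1 <- function(d) {
    opt <- stats::optimize(sse, log10(bracket), d = d, tol = 1e-10)
    list(kd = 10^opt$minimum,
         at_boundary = min(abs(opt$minimum - log10(bracket))) < 0.01)
  }
  if (replicates == "independent" && length(rep_ids) > 1) {
    fits <- lapply(rep_ids, function(r)
      fit1(data[data$replicate == r, ]))
    kds <- vapply(fits, `[[`, numeric(1), "kd")
    kd_hat <- mean(kds); sd_rep <- stats::sd(kds)
    at_boundary <- any(vapply(fits, `[[`, logical(1), "at_boundary"))
  } else {
    f <- fit1(data)
    kds <- kd_hat <- f$kd; sd_rep <- 0
    at_boundary <- f$at_boundary
    if (replicates == "independent")
      warning("fit_kd: single replicate; SD reported as 0",
              call. = FALSE)
  }
  flags <- character(0)
  if (at_boundary) {
    flags <- "boundary"
    warning("fit_kd(peptide): estimate at the edge of the search ",
            "bracket", call. = FALSE)
  }
  rss <- sse(log10(kd_hat), data)
  structure(list(kd = kd_hat, sd = sd_rep,
                 n_replicates = length(rep_ids),
                 residual_rms = sqrt(rss / nrow(data)),
                 per_replicate = kds,
                 method = paste0("least-squares/", replicates),
                 mode = "peptide", kd_homo = NULL,
                 signal_model = NULL, bracket = bracket,
                 isotherm_mode = isotherm_mode,
                 flags = flags, data = data, call = cl),
            class = "kd_fit")
}

#' Bootstrap uncertainty for a KD fit
#'
#' Resamples replicates with replacement at every titration point,
#' refits the replicate-mean of each resample, and reports the standard
#' deviation of the bootstrap KD distribution. Deterministic for a fixed
#' seed.
#'
#' @param data as in [fit_kd()].
#' @param mode,kd_homo,... passed to [fit_kd()].
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer RNG seed.
#' @return a `"kd_fit"` whose `sd` is the bootstrap SD and whose
#'   `boot_kds` component holds the resampled estimates.
#' @export
bootstrap_kd <- function(data, mode = "homodimer", kd_homo = NULL,
                         n_boot = 200L, seed = 1L, ...) {
  if (n_boot < 100)
    stop("bootstrap_kd: n_boot >= 100 required", call. = FALSE)
  base_fit <- suppressWarnings(
    fit_kd(data, mode = mode, kd_homo = kd_homo, replicates = "mean",
           ...))
  rep_ids <- sort(unique(data$replicate))
  key_cols <- if (mode == "peptide") "ligand_total" else
    c("f_total", "h_total")
  pts <- unique(data[, key_cols, drop = FALSE])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boot_kds <- vapply(seq_len(n_boot), function(b) {
    res <- lapply(seq_len(nrow(pts)), function(i) {
      sel <- rep(TRUE, nrow(data))
      for (k in key_cols) sel <- sel & data[[k]] == pts[i, k]
      draw <- sample(rep_ids, length(rep_ids), replace = TRUE)
      do.call(rbind, lapply(seq_along(draw), function(j) {
        d <- data[sel & data$replicate == draw[j], , drop = FALSE]
        d$replicate <- j
        d
      }))
    })
    boot <- do.call(rbind, res)
    attr(boot, "signal_model") <- attr(data, "signal_model")
    suppressWarnings(
      fit_kd(boot, mode = mode, kd_homo = kd_homo,
             replicates = "mean", ...))$kd
  }, numeric(1))
  out <- base_fit
  out$sd <- stats::sd(boot_kds)
  out$boot_kds <- boot_kds
  out$method <- sprintf("bootstrap (n=%d, seed=%d)", n_boot, seed)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("KD fit (%s, %s)\n", x$mode, x$method))
  cat(sprintf("  KD = %.4g M (%.4g nM)  +/- %.3g M\n",
              x$kd, x$kd * 1e9, x$sd))
  cat(sprintf("  replicates: %d, residual RMS: %.3g\n",
              x$n_replicates, x$residual_rms))
  if (length(x$flags))
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) c(kd = object$kd)

#' @export
summary.kd_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.kd_fit")
}

#' @export
print.summary.kd_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (length(f$per_replicate) > 1) {
    cat("  per-replicate KDs (nM):",
        paste(sprintf("%.4g", f$per_replicate * 1e9), collapse = ", "),
        "\n")
  }
  if (!is.null(f$kd_homo))
    cat(sprintf("  homodimer KD held at %.4g M (sd %.3g M)\n",
                f$kd_homo[1], f$kd_homo[2]))
  invisible(x)
}

#' Predict signal fractions (or fraction bound) from a KD fit
#'
#' @param object a `"kd_fit"`.
#' @param newdata for titration modes, a vector of total F
#'   concentrations (molar) or a data frame with `f_total` and
#'   `h_total`; for peptide mode, a vector of ligand concentrations.
#'   Defaults to the fitted data's design.
#' @param ... unused.
#' @return a data frame of predicted fractions (titration modes) or a
#'   numeric vector (peptide mode).
#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  if (object$mode == "peptide") {
    L <- if (is.null(newdata)) object$data$ligand_total else newdata
    return(peptide_isotherm(object$kd, L, mode = object$isotherm_mode))
  }
  if (is.null(newdata)) {
    newdata <- unique(object$data[, c("f_total", "h_total")])
  } else if (!is.data.frame(newdata)) {
    newdata <- data.frame(f_total = newdata,
                          h_total = if (object$mode == "homodimer") 0
                          else unique(object$data$h_total)[1])
  }
  kd_homo <- if (object$mode == "homodimer") object$kd else
    object$kd_homo[1]
  kd_het <- if (object$mode == "homodimer") Inf else object$kd
  out <- do.call(rbind, lapply(seq_len(nrow(newdata)), function(i) {
    fr <- .predict_fractions(kd_homo, kd_het, newdata$f_total[i],
                             newdata$h_total[i], object$signal_model)
    as.data.frame(as.list(fr))
  }))
  cbind(newdata, out)
}

#' @export
residuals.kd_fit <- function(object, ...) {
  if (object$mode == "peptide")
    return(object$data$fraction_bound - predict(object))
  pred <- predict(object)
  key <- c("f_total", "h_total")
  obs <- object$data
  sp_col <- c(monomer = "monomer", homodimer = "homodimer",
              heterodimer = "heterodimer", h_monomer = "h_monomer")
  vapply(seq_len(nrow(obs)), function(i) {
    j <- which(pred$f_total == obs$f_total[i] &
                 pred$h_total == obs$h_total[i])[1]
    obs$fraction[i] - pred[j, sp_col[[obs$species[i]]]]
  }, numeric(1))
}

#' @export
plot.kd_fit <- function(x, ...) {
  if (x$mode == "peptide") {
    L <- x$data$ligand_total
    grid <- 10^seq(log10(min(L)), log10(max(L)), length.out = 100)
    graphics::plot(L, x$data$fraction_bound, log = "x",
                   xlab = "ligand total (M)", ylab = "fraction bound",
                   main = sprintf("KD = %.3g M", x$kd), ...)
    graphics::lines(grid, predict(x, grid))
    return(invisible(x))
  }
  d <- x$data
  dim_sp <- if (x$mode == "homodimer") "homodimer" else "heterodimer"
  obs <- d[d$species == dim_sp, ]
  grid_f <- 10^seq(log10(min(d$f_total)), log10(max(d$f_total)),
                   length.out = 100)
  nd <- data.frame(f_total = grid_f,
                   h_total = if (x$mode == "homodimer") 0 else
                     unique(d$h_total)[1])
  pr <- predict(x, nd)
  graphics::plot(obs$f_total, obs$fraction, log = "x",
                 xlab = "F total (M)",
                 ylab = paste(dim_sp, "signal fraction"),
                 main = sprintf("KD = %.3g M (+/- %.2g)", x$kd, x$sd),
                 ...)
  graphics::lines(pr$f_total, pr[[dim_sp]])
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new noisy titration datasets at the fitted KD over the same
#' design, with noise SD taken from the fit's residual RMS (truncated at
#' zero and renormalised, as in [gen_titration()]).
#'
#' @param object a `"kd_fit"` from a titration mode.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `titration_data` objects (or a single one if
#'   `nsim = 1`).
#' @export
simulate.kd_fit <- function(object, nsim = 1, seed = 1L, ...) {
  if (object$mode == "peptide")
    stop("simulate() is provided for titration fits", call. = FALSE)
  des <- unique(object$data[, c("f_total", "h_total")])
  kd_homo <- if (object$mode == "homodimer") object$kd else
    object$kd_homo[1]
  kd_het <- if (object$mode == "homodimer") Inf else object$kd
  sims <- lapply(seq_len(nsim), function(i)
    gen_titration(kd_homo = kd_homo, kd_hetero = kd_het,
                  f_total_series = sort(unique(des$f_total)),
                  h_total = des$h_total[1],
                  n_replicates = object$n_replicates,
                  noise_sd = object$residual_rms,
                  seed = seed + i - 1L,
                  signal_model = object$signal_model))
  if (nsim == 1) sims[[1]] else sims
}
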