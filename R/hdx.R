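#' Theoretical maximum deuterium uptake of a peptide
#'
#' Number of exchange-competent backbone amides: peptide length minus
#' one (the N-terminal residue back-exchanges too fast to observe)
#' minus any prolines at positions 2 onwards (no amide hydrogen).
#'
#' @param sequence one-letter amino-acid sequence, length >= 2.
#' @return maximum uptake in Da (integer-valued numeric).
#' @export
#' @examples
#' max_uptake("APPA")  # 1
max_uptake <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- strsplit(toupper(s), "")[[1]]
    if (length(aa) < 2 || !all(aa %in% strsplit(
      "ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
      stop("max_uptake: need a valid one-letter sequence of length >= 2",
           call. = FALSE)
    (length(aa) - 1) - sum(aa[-1] == "P")
  }, numeric(1), USE.NAMES = FALSE)
}

#' Differential deuterium uptake between two states
#'
#' For every peptide and labelling time present in both states, the
#' difference of replicate-mean uptakes `mean(state_a) - mean(state_b)`
#' with the replicate SDs carried through. The difference is
#' antisymmetric in the two states; with `state_a` the complex and
#' `state_b` the free protein, negative differences denote protection
#' from exchange in the complex (the Woods-plot convention). Each
#' difference is tested for
#' significance (see [hdx_significance()]) and expressed as a fraction
#' of the peptide's theoretical maximum uptake.
#'
#' @param table long-format uptake table: columns `sequence`, `start`,
#'   `end`, `state`, `timepoint_s`, `replicate`, `uptake_Da`.
#' @param state_a,state_b state labels (difference is a minus b).
#' @param alpha two-tailed significance level.
#' @param method,bonferroni passed to [hdx_significance()].
#' @return data frame of class `"hdx_diff"`, one row per peptide x
#'   timepoint: `sequence`, `start`, `end`, `timepoint_s`, `delta`
#'   (Da), `sd_a`, `sd_b`, `n_a`, `n_b`, `ci_halfwidth`, `p_value`,
#'   `significant`, `fraction_of_max`. Peptides with missing replicate
#'   cells in either state are excluded with a warning.
#' @export
uptake_difference <- function(table, state_a, state_b, alpha = 0.01,
                              method = c("ttest", "welch", "pooled"),
                              bonferroni = FALSE) {
  method <- match.arg(method)
  need <- c("sequence", "start", "end", "state", "timepoint_s",
            "replicate", "uptake_Da")
  if (!all(need %in% names(table)))
    stop("uptake_difference: missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "),
         call. = FALSE)
  for (s in c(state_a, state_b))
    if (!s %in% table$state)
      stop("uptake_difference: state not present: ", s, call. = FALSE)

  peps <- unique(table[, c("sequence", "start", "end")])
  tps <- sort(unique(table$timepoint_s))
  n_rep <- max(table$replicate)
  rows <- list(); dropped <- character(0)
  for (i in seq_len(nrow(peps))) {
    sel_p <- table$sequence == peps$sequence[i] &
      table$start == peps$start[i]
    for (tp in tps) {
      a <- table$uptake_Da[sel_p & table$timepoint_s == tp &
                             table$state == state_a]
      b <- table$uptake_Da[sel_p & table$timepoint_s == tp &
                             table$state == state_b]
      if (length(a) < n_rep || length(b) < n_rep ||
          anyNA(a) || anyNA(b)) {
        dropped <- union(dropped, peps$sequence[i])
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        sequence = peps$sequence[i], start = peps$start[i],
        end = peps$end[i], timepoint_s = tp,
        delta = mean(a) - mean(b),
        sd_a = stats::sd(a), sd_b = stats::sd(b),
        n_a = length(a), n_b = length(b))
    }
  }
  if (length(dropped))
    warning("uptake_difference: peptides excluded for missing ",
            "replicates: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("uptake_difference: no complete peptide/timepoint cells",
         call. = FALSE)
  out$fraction_of_max <- out$delta / max_uptake(out$sequence)
  out <- hdx_significance(out, alpha = alpha, method = method,
                          bonferroni = bonferroni)
  structure(out, class = c("hdx_diff", "data.frame"),
            states = c(state_a, state_b), alpha = alpha)
}

#' Peptide-level significance of uptake differences
#'
#' Two-tailed test of each uptake difference at level `alpha`. The
#' default is a per-peptide two-sample Student t-test (pooled variance,
#' `n_a + n_b - 2` degrees of freedom), which is exactly calibrated for
#' the balanced equal-replicate designs HDX experiments use; Welch's
#' unequal-variance variant is available but runs conservative at
#' triplicate depth (its Satterthwaite degrees of freedom fall below
#' the pooled value). A global pooled-SD variant instead applies one
#' threshold `t_crit * sqrt(s_pooled^2 (1/n_a + 1/n_b))` computed from
#' all records. When both states have zero variance, a nonzero
#' difference is significant by convention (and flagged in the
#' `degenerate` column); a zero difference is not.
#'
#' @param records data frame with columns `delta`, `sd_a`, `sd_b`,
#'   `n_a`, `n_b` (as built by [uptake_difference()]).
#' @param alpha two-tailed level (default 0.01, i.e. 99% confidence).
#' @param method `"ttest"` (per-peptide Student), `"welch"`
#'   (per-peptide Welch) or `"pooled"` (global threshold).
#' @param bonferroni apply Bonferroni correction across records.
#' @return `records` with columns `p_value`, `ci_halfwidth`,
#'   `significant`, `degenerate` added or replaced.
#' @export
hdx_significance <- function(records, alpha = 0.01,
                             method = c("ttest", "welch", "pooled"),
                             bonferroni = FALSE) {
  method <- match.arg(method)
  n <- nrow(records)
  p <- ci <- numeric(n)
  degen <- logical(n)
  if (method %in% c("ttest", "welch")) {
    for (i in seq_len(n)) {
      r <- records[i, ]
      if (r$n_a < 2 || r$n_b < 2)
        stop("hdx_significance: >= 2 replicates per state required",
             call. = FALSE)
      if (method == "ttest") {
        s2 <- ((r$n_a - 1) * r$sd_a^2 + (r$n_b - 1) * r$sd_b^2) /
          (r$n_a + r$n_b - 2)
        se2 <- s2 * (1 / r$n_a + 1 / r$n_b)
        df <- r$n_a + r$n_b - 2
      } else {
        se2 <- r$sd_a^2 / r$n_a + r$sd_b^2 / r$n_b
        df <- if (se2 > 0)
          se2^2 / (r$sd_a^4 / (r$n_a^2 * (r$n_a - 1)) +
                     r$sd_b^4 / (r$n_b^2 * (r$n_b - 1))) else NA
      }
      if (se2 == 0) {
        degen[i] <- TRUE
        p[i] <- if (r$delta == 0) 1 else 0
        ci[i] <- 0
        next
      }
      tstat <- r$delta / sqrt(se2)
      p[i] <- 2 * stats::pt(-abs(tstat), df)
      ci[i] <- stats::qt(1 - alpha / 2, df) * sqrt(se2)
    }
  } else {
    s2 <- ((records$n_a - 1) * records$sd_a^2 +
             (records$n_b - 1) * records$sd_b^2) /
      (records$n_a + records$n_b - 2)
    pooled <- mean(s2)
    df <- sum(records$n_a + records$n_b - 2)
    se <- sqrt(pooled * (1 / records$n_a + 1 / records$n_b))
    thr <- stats::qt(1 - alpha / 2, df) * se
    p <- 2 * stats::pt(-abs(records$delta) / pmax(se, .Machine$double.eps),
                       df)
    ci <- thr
  }
  if (bonferroni) p <- pmin(p * n, 1)
  records$p_value <- p
  records$ci_halfwidth <- ci
  records$degenerate <- degen
  records$significant <- p < alpha
  if (any(degen & records$significant))
    warning("hdx_significance: zero-variance records with nonzero ",
            "difference marked significant by convention",
            call. = FALSE)
  records
}

#' Project peptide-level differences onto residues
#'
#' Assigns each residue the aggregate of `fraction_of_max` values from
#' all significant peptides covering it. Because enzymatic digestion
#' limits resolution, overlapping peptides can disagree; the `rule`
#' resolves this: `max_protection` keeps the most negative value,
#' `mean` averages, `min_abs` keeps the value closest to zero.
#' Residues covered by no significant peptide are `NA` (no data), never
#' 0.
#'
#' @param records an `"hdx_diff"` (typically filtered to one
#'   timepoint).
#' @param rule aggregation rule.
#' @param residues residue range to report; defaults to the span of the
#'   records.
#' @return data frame with columns `resno`, `value`, `n_peptides`.
#' @export
project_to_residues <- function(records,
                                rule = c("max_protection", "mean",
                                         "min_abs"),
                                residues = NULL) {
  rule <- match.arg(rule)
  sig <- records[records$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    stop("project_to_residues: no significant records", call. = FALSE)
  if (is.null(residues))
    residues <- seq(min(records$start), max(records$end))
  value <- rep(NA_real_, length(residues))
  n_pep <- integer(length(residues))
  for (k in seq_along(residues)) {
    r <- residues[k]
    v <- sig$fraction_of_max[sig$start <= r & sig$end >= r]
    n_pep[k] <- length(v)
    if (length(v) == 0) next
    value[k] <- switch(rule,
                       max_protection = v[which.min(v)],
                       mean = mean(v),
                       min_abs = v[which.min(abs(v))])
  }
  data.frame(resno = residues, value = value, n_peptides = n_pep)
}

#' Write a Woods-plot table
#'
#' Serialises peptide-level differences in the layout a Woods plot is
#' drawn from: one row per peptide per timepoint with its sequence
#' span, difference, confidence halfwidth and significance call.
#'
#' @param diff an `"hdx_diff"`.
#' @param file output CSV path.
#' @return invisibly, `file`.
#' @export
write_woods_csv <- function(diff, file) {
  utils::write.csv(
    diff[, c("start", "end", "timepoint_s", "delta", "ci_halfwidth",
             "significant", "fraction_of_max")],
    file, row.names = FALSE)
  invisible(file)
}
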