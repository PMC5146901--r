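#' Evaluate a single-component cosinor curve
#'
#' Computes \eqn{f(t) = M + A \cos(\pi t / 12 - \phi)}, the fixed-period
#' (24 h) cosine model used throughout daily-rhythmicity analysis. The curve
#' peaks at \eqn{t = 12\phi/\pi} (mod 24) Zeitgeber hours.
#'
#' @param t Time in hours (Zeitgeber time). Vectorised.
#' @param mesor Rhythm-adjusted mean level M.
#' @param amplitude Oscillation amplitude A (half the peak-to-trough extent),
#'   must be non-negative.
#' @param acrophase Acrophase \eqn{\phi} in radians.
#' @return Numeric vector of expression levels, same length as `t`.
#' @examples
#' cosinor_signal(0, mesor = 0.5, amplitude = 0.3, acrophase = 0)   # 0.8
#' cosinor_signal(12, mesor = 0.5, amplitude = 0.3, acrophase = 0)  # 0.2
#' @export
cosinor_signal <- function(t, mesor, amplitude, acrophase) {
  stopifnot(amplitude >= 0)
  mesor + amplitude * cos(pi * t / 12 - acrophase)
}

#' Convert an acrophase in radians to Zeitgeber hours
#'
#' For a 24-h period the fitted peak falls at \eqn{\phi \cdot 12/\pi} hours;
#' the result is wrapped to `[0, 24)`.
#'
#' @param acrophase_rad Acrophase in radians (any finite value).
#' @return Peak time in hours, in `[0, 24)`.
#' @examples
#' acrophase_to_zt(pi)    # 12
#' acrophase_to_zt(5.37)  # ~20.51
#' @export
acrophase_to_zt <- function(acrophase_rad) {
  stopifnot(all(is.finite(acrophase_rad)))
  (acrophase_rad * 12 / pi) %% 24
}

#' Fit a single cosinor by least squares
#'
#' Ordinary least squares of `values` on the basis
#' \eqn{\{1, \cos(\pi t/12), \sin(\pi t/12)\}} gives the mesor M and the
#' rectangular coefficients \eqn{(\beta, \gamma)}; amplitude
#' \eqn{A = \sqrt{\beta^2 + \gamma^2}} and acrophase
#' \eqn{\phi = \mathrm{atan2}(\gamma, \beta)} wrapped to `[0, 2\pi)`, so the
#' fitted curve peaks at ZT \eqn{12\phi/\pi}. The amplitude standard error is
#' obtained by the delta method from the OLS coefficient covariance,
#' \deqn{Var(A) = (\beta^2 Var(\beta) + \gamma^2 Var(\gamma) +
#'   2\beta\gamma Cov(\beta,\gamma)) / A^2,}
#' and the rhythmicity statistic is the amplitude noise/signal ratio
#' \eqn{P = SE(A)/A}: a gene is classed rhythmic when \eqn{P <} `threshold`
#' (strict). When A is numerically zero P is set to `Inf` (arrhythmic).
#'
#' @param times Observation times in hours. At least 4 observations spanning
#'   at least 3 distinct phase positions (times mod 24) are required.
#' @param values Expression levels, same length as `times`.
#' @param gene Optional gene label stored in the result.
#' @param threshold Rhythmicity cutoff on P = SE(A)/A (default 0.3).
#' @return An object of class `cosinor_fit`: a list with elements `gene`,
#'   `mesor`, `amplitude`, `acrophase_rad`, `acrophase_zt`, `se_amplitude`,
#'   `p_ns`, `rhythmic`, `n_obs`, `beta`, `gamma`, `residual_variance`.
#' @examples
#' zt <- rep(seq(0, 24, by = 3), each = 6)
#' y <- cosinor_signal(zt, 0.5, 0.3, 2.0)
#' fit_cosinor(zt, y)
#' @export
fit_cosinor <- function(times, values, gene = NA_character_, threshold = 0.3) {
  stopifnot(length(times) == length(values))
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  n <- length(values)
  if (n < 4L) stop("cosinor fit needs at least 4 observations, got ", n)
  phases <- round(times %% 24, 9)
  if (length(unique(phases)) < 3L) {
    stop("degenerate design: need >= 3 distinct phase positions (times mod 24)")
  }
  cosb <- cos(pi * times / 12)
  sinb <- sin(pi * times / 12)
  fit <- stats::lm(values ~ cosb + sinb)
  cf <- stats::coef(fit)
  mesor <- unname(cf[1L]); beta <- unname(cf[2L]); gamma <- unname(cf[3L])
  amplitude <- sqrt(beta^2 + gamma^2)
  acro <- atan2(gamma, beta) %% (2 * pi)
  # a noiseless series is a legitimate input (SE(A) = 0); silence only the
  # perfect-fit note summary.lm emits for it
  vc <- withCallingHandlers(
    stats::vcov(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  se_a <- amplitude_se_delta(beta, gamma, vc[2:3, 2:3])
  p_ns <- if (amplitude < 1e-12) Inf else se_a / amplitude
  structure(list(
    gene = gene,
    mesor = mesor,
    amplitude = amplitude,
    acrophase_rad = acro,
    acrophase_zt = acrophase_to_zt(acro),
    se_amplitude = se_a,
    p_ns = p_ns,
    rhythmic = classify_rhythmic(p_ns, threshold),
    threshold = threshold,
    n_obs = n,
    beta = beta,
    gamma = gamma,
    residual_variance = sum(stats::residuals(fit)^2) / (n - 3)
  ), class = "cosinor_fit")
}

# Delta-method SE of A = sqrt(beta^2 + gamma^2) given the 2x2 covariance of
# (beta, gamma). Degenerate amplitude (A ~ 0) returns the RMS component SE so
# the caller can map P to +Inf rather than 0/0.
amplitude_se_delta <- function(beta, gamma, vc) {
  a2 <- beta^2 + gamma^2
  if (a2 < 1e-24) return(sqrt(mean(diag(vc))))
  var_a <- (beta^2 * vc[1, 1] + gamma^2 * vc[2, 2] +
              2 * beta * gamma * vc[1, 2]) / a2
  sqrt(max(var_a, 0))
}

#' Standard error of the fitted amplitude
#'
#' Extracts the delta-method SE(A) from a [fit_cosinor()] result.
#'
#' @param fit A `cosinor_fit` object.
#' @return SE(A), in expression units.
#' @export
amplitude_se <- function(fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  fit$se_amplitude
}

#' Classify rhythmicity from the amplitude noise/signal statistic
#'
#' A gene is considered to display daily rhythmicity when P = SE(A)/A falls
#' strictly below the threshold; P equal to the threshold, or infinite
#' (zero-amplitude fit), is arrhythmic.
#'
#' @param p_ns Noise/signal statistic, non-negative or `Inf`. Vectorised.
#' @param threshold Cutoff, default 0.3.
#' @return Logical vector.
#' @export
classify_rhythmic <- function(p_ns, threshold = 0.3) {
  stopifnot(all(p_ns >= 0 | is.infinite(p_ns)))
  p_ns < threshold
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "Cosinor fit%s (n = %d)\n  mesor %.4f  amplitude %.4f (SE %.4f)\n  acrophase %.4f rad = ZT %.2f h\n  P = SE(A)/A = %.4f -> %s\n",
    if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"), x$n_obs,
    x$mesor, x$amplitude, x$se_amplitude, x$acrophase_rad, x$acrophase_zt,
    x$p_ns, if (x$rhythmic) "rhythmic" else "not rhythmic"))
  invisible(x)
}

#' Per-gene rhythmicity report
#'
#' Fits a single cosinor to each gene of a relative-expression table and
#' returns one row per gene with amplitude, P = SE(A)/A, mesor, acrophase in
#' radians and Zeitgeber hours, and the rhythmic flag — the layout of a
#' rhythmicity-parameters table. Genes whose fit fails (too few observations,
#' degenerate design) yield an `NA` row with the message in `note`; the batch
#' never aborts.
#'
#' @param expr Relative-expression table: data frame with columns
#'   `sample_id`, `gene`, `zt`, `replicate`, `value`.
#' @param genes Genes to report, in output order. Default: unique genes of
#'   `expr` in order of appearance.
#' @param fit_on `"replicates"` fits all individual observations (default);
#'   `"timepoint_means"` fits the per-ZT arithmetic means.
#' @param threshold Rhythmicity cutoff on P (default 0.3).
#' @return A `data.frame` with columns `gene`, `amplitude`, `p_value`,
#'   `mesor`, `acrophase`, `zt_h`, `rhythmic`, `note`.
#' @export
rhythm_table <- function(expr, genes = unique(expr$gene),
                         fit_on = c("replicates", "timepoint_means"),
                         threshold = 0.3) {
  fit_on <- match.arg(fit_on)
  stopifnot(all(c("gene", "zt", "value") %in% names(expr)))
  rows <- lapply(genes, function(g) {
    d <- expr[expr$gene == g, , drop = FALSE]
    if (fit_on == "timepoint_means") {
      m <- tapply(d$value, d$zt, mean)
      tt <- as.numeric(names(m)); vv <- as.numeric(m)
    } else {
      tt <- d$zt; vv <- d$value
    }
    fit <- tryCatch(fit_cosinor(tt, vv, gene = g, threshold = threshold),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(gene = g, amplitude = NA_real_, p_value = NA_real_,
                 mesor = NA_real_, acrophase = NA_real_, zt_h = NA_real_,
                 rhythmic = NA, note = conditionMessage(fit),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, amplitude = fit$amplitude, p_value = fit$p_ns,
                 mesor = fit$mesor, acrophase = fit$acrophase_rad,
                 zt_h = fit$acrophase_zt, rhythmic = fit$rhythmic,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count rhythmic genes in a rhythm table
#'
#' @param table A rhythm table (from [rhythm_table()] or a transcribed
#'   published table) with columns `gene` and `p_value`.
#' @param gene_subset Genes to count over; all must be present in `table`.
#' @param threshold Strict cutoff on the P value (default 0.3).
#' @return Integer count of subset genes with `p_value < threshold`.
#' @export
count_rhythmic <- function(table, gene_subset, threshold = 0.3) {
  missing <- setdiff(gene_subset, table$gene)
  if (length(missing)) {
    stop("genes not present in table: ", paste(missing, collapse = ", "))
  }
  p <- table$p_value[match(gene_subset, table$gene)]
  sum(p < threshold, na.rm = TRUE)
}
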