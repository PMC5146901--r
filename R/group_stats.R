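#' One-way fixed-effects ANOVA across timepoint groups
#'
#' Classical decomposition with F = MS_between / MS_within, computed via
#' [stats::aov()]. Groups with zero within-group variance but unequal means
#' report `F = Inf`, `p = 0`.
#'
#' @param groups List of numeric vectors, one per group (e.g. the replicate
#'   values at each Zeitgeber time). At least 2 groups of >= 2 values each.
#' @return List with `f_statistic`, `p_value`, `mse` (within-group mean
#'   square), `df_error`, `group_sizes`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 values; group(s) ",
         paste(which(sizes < 2L), collapse = ", "), " too small")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  # zero within-group variance is handled explicitly below; muffle the
  # perfect-fit note stats emits for it
  tab <- withCallingHandlers(
    stats::anova(stats::aov(y ~ g)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  mse <- tab$`Mean Sq`[2L]
  dfe <- tab$Df[2L]
  f <- tab$`F value`[1L]
  p <- tab$`Pr(>F)`[1L]
  msb <- tab$`Mean Sq`[1L]
  # numerically-zero within-group variance with real between-group spread
  if (msb > 0 && mse <= 1e-20 * msb) { f <- Inf; p <- 0; mse <- 0 }
  list(f_statistic = f, p_value = p, mse = mse, df_error = dfe,
       group_sizes = as.integer(sizes))
}

# Duncan's least significant range for a span of p ordered means:
# studentized-range quantile at protection level (1-alpha)^(p-1),
# scaled by sqrt(MSE / n_h) with n_h the harmonic mean group size.
duncan_lsr <- function(p, df_error, mse, n_h, alpha) {
  stats::qtukey(p = (1 - alpha)^(p - 1), nmeans = p, df = df_error) *
    sqrt(mse / n_h)
}

#' Duncan's multiple range test with compact letter display
#'
#' Runs a one-way ANOVA, then Duncan's multiple range procedure on the ranked
#' group means: a pair of means `p` ranks apart is declared different when
#' its difference exceeds the least significant range
#' \eqn{R_p = q(p, df; (1-\alpha)^{p-1}) \sqrt{MSE/n_h}} and no enclosing
#' span has already been declared homogeneous (the standard containment
#' rule). Unequal group sizes use the harmonic mean \eqn{n_h}. The resulting
#' non-significance relation is rendered as lower-case letter groups by the
#' insert-and-absorb algorithm, letters ordered by descending mean — two
#' groups share a letter iff their means are not significantly different.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level per comparison (default 0.05).
#' @param labels Group labels (e.g. Zeitgeber times); defaults to
#'   `names(groups)` or 1..k.
#' @return List with `f_statistic`, `p_value`, `letters` (named character
#'   vector, one entry per group in input order), `group_means`, `mse`,
#'   `df_error`.
#' @export
duncan_letters <- function(groups, alpha = 0.05, labels = NULL) {
  aov_res <- one_way_anova(groups)
  k <- length(groups)
  if (is.null(labels)) {
    labels <- if (!is.null(names(groups))) names(groups) else as.character(seq_len(k))
  }
  means <- vapply(groups, mean, numeric(1))
  names(means) <- labels
  n_h <- k / sum(1 / aov_res$group_sizes)

  ord <- order(means, decreasing = TRUE)       # ranked means, largest first
  nonsig <- matrix(FALSE, k, k)                 # in ranked coordinates
  diag(nonsig) <- TRUE
  if (aov_res$mse == 0) {
    # no within-group noise: any difference is significant
    for (i in seq_len(k)) for (j in seq_len(k)) {
      nonsig[i, j] <- means[ord[i]] == means[ord[j]]
    }
  } else {
    # largest spans first so containment can shield inner pairs
    for (span in rev(seq_len(k - 1L))) {
      for (i in seq_len(k - span)) {
        j <- i + span
        if (nonsig[i, j]) next
        diffm <- means[ord[i]] - means[ord[j]]
        rp <- duncan_lsr(span + 1L, aov_res$df_error, aov_res$mse, n_h, alpha)
        if (diffm <= rp) {
          # whole span homogeneous: protect all enclosed pairs
          for (a in i:j) for (b in i:j) nonsig[a, b] <- TRUE
        }
      }
    }
  }
  lett_ranked <- cld_insert_absorb(nonsig)
  letters_out <- character(k)
  letters_out[ord] <- lett_ranked
  names(letters_out) <- labels
  list(f_statistic = aov_res$f_statistic, p_value = aov_res$p_value,
       letters = letters_out, group_means = means,
       mse = aov_res$mse, df_error = aov_res$df_error)
}

# Insert-and-absorb compact letter display. `nonsig` is a symmetric logical
# matrix over groups ordered by descending mean; returns one letter string
# per group in that order. Each maximal run of mutually-compatible groups
# gets a letter; absorbed (subset) letter classes are dropped.
cld_insert_absorb <- function(nonsig) {
  k <- nrow(nonsig)
  if (k == 1L) return("a")
  classes <- list(seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!nonsig[i, j]) {
        # i and j must be separable: every class containing both is split
        hit <- vapply(classes, function(cl) i %in% cl && j %in% cl, logical(1))
        if (!any(hit)) next
        for (ci in which(hit)) {
          cl <- classes[[ci]]
          classes[[ci]] <- setdiff(cl, j)
          classes[[length(classes) + 1L]] <- setdiff(cl, i)
        }
        # absorb: drop classes that are subsets of another
        keep <- rep(TRUE, length(classes))
        for (a in seq_along(classes)) for (b in seq_along(classes)) {
          if (a != b && keep[a] && keep[b] &&
              all(classes[[a]] %in% classes[[b]])) keep[a] <- FALSE
        }
        classes <- classes[keep]
      }
    }
  }
  if (!length(classes)) classes <- list(seq_len(k))
  # order letter classes by the highest-ranked member they contain
  first <- vapply(classes, min, numeric(1))
  classes <- classes[order(first)]
  out <- character(k)
  for (ci in seq_along(classes)) {
    for (g in classes[[ci]]) out[g] <- paste0(out[g], letters[ci])
  }
  out
}

#' Per-gene ANOVA and Duncan letters over a whole expression table
#'
#' @param expr Relative-expression data frame (`gene`, `zt`, `value`, ...).
#' @param genes Genes to analyse (default: all, in order of appearance).
#' @param alpha Duncan significance level.
#' @return Data frame with one row per gene x timepoint: `gene`, `zt`,
#'   `mean`, `sem`, `letters`, `f_statistic`, `p_value`.
#' @export
group_stats_table <- function(expr, genes = unique(expr$gene), alpha = 0.05) {
  rows <- lapply(genes, function(g) {
    d <- expr[expr$gene == g, , drop = FALSE]
    zts <- sort(unique(d$zt))
    grps <- lapply(zts, function(z) d$value[d$zt == z])
    names(grps) <- as.character(zts)
    res <- duncan_letters(grps, alpha = alpha)
    sem <- vapply(grps, function(v) stats::sd(v) / sqrt(length(v)), numeric(1))
    data.frame(gene = g, zt = zts, mean = unname(res$group_means),
               sem = unname(sem), letters = unname(res$letters),
               f_statistic = res$f_statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
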