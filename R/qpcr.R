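#' Relative quantification by the 2^-ddCt method
#'
#' For each sample, \eqn{\Delta Ct = Ct_{target} - Ct_{ref}} (with
#' \eqn{Ct_{ref}} the arithmetic mean Ct over the reference set, equivalent
#' to the geometric mean of reference quantities), then
#' \eqn{\Delta\Delta Ct = \Delta Ct - \Delta Ct_{calibrator}} and the relative
#' expression \eqn{R = 2^{-\Delta\Delta Ct}}. The calibrator rule fixes the
#' "control" term: `global_mean` centres each gene on its mean \eqn{\Delta Ct}
#' across all samples, `zt0_mean` uses the mean \eqn{\Delta Ct} of the ZT0
#' samples, and `min` scales so the most-expressed sample has R = 1. The rule
#' only shifts the expression scale; cosinor P values and acrophases are
#' unaffected.
#'
#' @param ct Ct table: data frame with columns `sample_id`, `gene`, `zt`,
#'   `replicate`, `ct`.
#' @param targets Target gene name(s) to quantify.
#' @param reference Reference gene name or set.
#' @param calibrator Calibrator rule (see Details).
#' @return Relative-expression data frame with columns `sample_id`, `gene`,
#'   `zt`, `replicate`, `value` (all values > 0).
#' @export
delta_delta_ct <- function(ct, targets, reference,
                           calibrator = c("global_mean", "zt0_mean", "min")) {
  calibrator <- match.arg(calibrator)
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(ct)))
  if (length(reference) == 0L) stop("empty reference gene set")
  missing_ref <- setdiff(reference, ct$gene)
  if (length(missing_ref)) {
    stop("reference gene(s) absent from Ct table: ",
         paste(missing_ref, collapse = ", "))
  }
  refs <- ct[ct$gene %in% reference, , drop = FALSE]
  ref_ct <- tapply(refs$ct, refs$sample_id, mean)
  per_target <- lapply(targets, function(g) {
    d <- ct[ct$gene == g, , drop = FALSE]
    if (!nrow(d)) stop("target gene absent from Ct table: ", g)
    rc <- ref_ct[d$sample_id]
    bad <- d$sample_id[is.na(rc)]
    if (length(bad)) {
      stop("sample(s) missing reference Ct for gene ", g, ": ",
           paste(unique(bad), collapse = ", "))
    }
    n_ref <- table(refs$sample_id)[d$sample_id]
    if (any(n_ref < length(reference))) {
      bad <- unique(d$sample_id[n_ref < length(reference)])
      stop("sample(s) missing Ct for some reference gene: ",
           paste(bad, collapse = ", "))
    }
    dct <- d$ct - as.numeric(rc)
    cal <- switch(calibrator,
                  global_mean = mean(dct),
                  zt0_mean = {
                    z0 <- dct[d$zt == 0]
                    if (!length(z0)) stop("no ZT0 samples for gene ", g,
                                          " (zt0_mean calibrator)")
                    mean(z0)
                  },
                  min = min(dct))
    data.frame(sample_id = d$sample_id, gene = g, zt = d$zt,
               replicate = d$replicate, value = 2^(-(dct - cal)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_target)
  rownames(out) <- NULL
  out
}

#' geNorm reference-gene stability analysis
#'
#' Implements the geNorm measure of expression stability. For candidate
#' genes j, k the pairwise variation \eqn{V_{jk}} is the standard deviation
#' over samples of \eqn{\log_2(q_j/q_k)}; the stability value \eqn{M_j} is
#' the mean of \eqn{V_{jk}} over all other genes k. The least stable gene
#' (highest M) is excluded and M recomputed iteratively down to the final
#' pair. Pairwise variations \eqn{V(n/n+1)} compare normalisation factors
#' (per-sample geometric means) of the top-n and top-(n+1) gene sets.
#'
#' @param quantities Per-sample relative quantities of the candidates, either
#'   a samples x genes numeric matrix/data.frame (columns = genes) or a long
#'   data frame with columns `sample_id`, `gene`, `value`. All values must be
#'   > 0; at least 3 genes and 2 samples.
#' @return A `genorm_result`: list with `m_values` (full-panel M per gene),
#'   `ranking` (genes by ascending M), `exclusion_order` (genes removed per
#'   iteration, least stable first), `stepwise_m` (the excluded gene's M at
#'   each iteration), `pairwise_variation` (named vector of V(n/n+1)).
#' @export
genorm_m <- function(quantities) {
  q <- as_quantity_matrix(quantities)
  if (ncol(q) < 3L) stop("geNorm needs >= 3 candidate genes, got ", ncol(q))
  if (nrow(q) < 2L) stop("geNorm needs >= 2 samples, got ", nrow(q))
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("all quantities must be finite and > 0")
  }
  lq <- log2(q)
  m_of <- function(cols) {
    vapply(cols, function(j) {
      others <- setdiff(cols, j)
      mean(vapply(others, function(k) stats::sd(lq[, j] - lq[, k]),
                  numeric(1)))
    }, numeric(1))
  }
  genes <- colnames(q)
  m_full <- m_of(genes)
  names(m_full) <- genes

  remaining <- genes
  exclusion <- character(0)
  stepwise <- numeric(0)
  while (length(remaining) > 2L) {
    m <- m_of(remaining)
    worst <- remaining[which.max(m)]   # ties: first in column order
    exclusion <- c(exclusion, worst)
    stepwise <- c(stepwise, max(m))
    remaining <- setdiff(remaining, worst)
  }
  ranking <- names(sort(m_full))
  nf <- function(set) rowMeans(lq[, set, drop = FALSE])  # log2 geometric mean
  vs <- vapply(2:(length(genes) - 1L), function(n) {
    stats::sd(nf(ranking[1:n]) - nf(ranking[1:(n + 1L)]))
  }, numeric(1))
  names(vs) <- sprintf("V%d/%d", 2:(length(genes) - 1L),
                       3:length(genes))
  structure(list(m_values = m_full, ranking = ranking,
                 exclusion_order = exclusion, stepwise_m = stepwise,
                 pairwise_variation = vs),
            class = "genorm_result")
}

as_quantity_matrix <- function(quantities) {
  if (is.data.frame(quantities) &&
      all(c("sample_id", "gene", "value") %in% names(quantities))) {
    wide <- stats::reshape(
      quantities[, c("sample_id", "gene", "value")],
      idvar = "sample_id", timevar = "gene", direction = "wide")
    m <- as.matrix(wide[, -1L, drop = FALSE])
    colnames(m) <- sub("^value\\.", "", colnames(m))
    rownames(m) <- wide$sample_id
    return(m)
  }
  as.matrix(quantities)
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability analysis\n  ranking (most stable first): ",
      paste(x$ranking, collapse = " > "), "\n  M values:\n", sep = "")
  print(round(x$m_values[x$ranking], 3))
  cat("  pairwise variation:\n")
  print(round(x$pairwise_variation, 3))
  invisible(x)
}

#' Choose a reference-gene set from a geNorm result
#'
#' In `"minimal_set"` mode returns the smallest top-n set (n >= 2) whose
#' pairwise variation V(n/n+1) falls below `v_threshold` (all of the top
#' sets if none does); in `"single"` mode returns only the most stable gene —
#' the usage of studies that normalise to one housekeeping gene.
#'
#' @param result A [genorm_m()] result.
#' @param v_threshold Cutoff on V(n/n+1), conventionally 0.15.
#' @param mode `"minimal_set"` or `"single"`.
#' @return Character vector of selected reference genes.
#' @export
select_reference <- function(result, v_threshold = 0.15,
                             mode = c("minimal_set", "single")) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "genorm_result"))
  if (mode == "single") return(result$ranking[1L])
  v <- result$pairwise_variation
  hit <- which(v < v_threshold)
  n <- if (length(hit)) hit[1L] + 1L else length(result$ranking)
  result$ranking[seq_len(n)]
}
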