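#' Per-timepoint mean expression profile of a gene
#'
#' Replicates are distinct individuals, so gene pairs are compared on their
#' per-Zeitgeber-time mean profiles rather than on (unpaired) replicate
#' values.
#'
#' @param expr Relative-expression data frame (`gene`, `zt`, `value`).
#' @param gene Gene identifier.
#' @param timepoints Design timepoints the profile must cover; default: all
#'   ZTs present in `expr`.
#' @return Named numeric vector of per-ZT means, ordered by ZT.
#' @export
mean_profile <- function(expr, gene, timepoints = sort(unique(expr$zt))) {
  d <- expr[expr$gene == gene, , drop = FALSE]
  if (!nrow(d)) stop("gene absent from expression table: ", gene)
  missing <- setdiff(timepoints, d$zt)
  if (length(missing)) {
    stop("gene ", gene, " has no data at timepoint(s) ZT",
         paste(missing, collapse = ", ZT"))
  }
  m <- tapply(d$value, d$zt, mean)
  m <- m[as.character(timepoints)]
  stats::setNames(as.numeric(m), as.character(timepoints))
}

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper around [stats::cor()]: requires equal lengths of
#' at least 3 and non-degenerate variance in both vectors (correlation is
#' undefined for a constant profile).
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  stats::cor(x, y, method = "pearson")
}

#' Categorise a correlation coefficient
#'
#' Direction follows the sign of r; strength follows the magnitude:
#' strong when |r| >= 0.80, moderate when 0.5 < |r| < 0.80, none otherwise
#' (|r| = 0.5 is below the moderate band).
#'
#' @param r Coefficient in `[-1, 1]`. Vectorised.
#' @return Data frame with columns `direction` ("positive"/"negative") and
#'   `strength` ("strong"/"moderate"/"none").
#' @export
classify_correlation <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12))
  data.frame(
    direction = ifelse(r < 0, "negative", "positive"),
    strength = ifelse(abs(r) >= 0.80, "strong",
                      ifelse(abs(r) > 0.5, "moderate", "none")),
    stringsAsFactors = FALSE)
}

#' Rhythm-gated correlation screen over gene pairs
#'
#' Computes Pearson r between mean expression profiles for every unordered
#' pair drawn from `gene_set_a` x `gene_set_b` (within-set pairs included
#' when the sets overlap or a set is compared with itself) and keeps a pair
#' when it passes the screening gate: |r| > `min_abs_r` AND at least one
#' member is flagged rhythmic. All evaluated pairs are returned with their
#' gate status; filter on `gate_passed` for the report.
#'
#' @param expr Relative-expression data frame.
#' @param rhythm Rhythm table with columns `gene` and `rhythmic` covering
#'   every gene of both sets.
#' @param gene_set_a,gene_set_b Gene identifier vectors (set b defaults to
#'   set a, giving all within-set pairs).
#' @param min_abs_r Magnitude gate on |r| (default 0.5, strict).
#' @return Data frame with one row per unordered pair: `gene_a`, `gene_b`,
#'   `r`, `direction`, `strength`, `gate_passed`.
#' @export
correlation_table <- function(expr, rhythm, gene_set_a,
                              gene_set_b = gene_set_a, min_abs_r = 0.5) {
  all_genes <- union(gene_set_a, gene_set_b)
  missing <- setdiff(all_genes, rhythm$gene)
  if (length(missing)) {
    stop("no rhythmicity flag for gene(s): ", paste(missing, collapse = ", "))
  }
  flags <- stats::setNames(rhythm$rhythmic, rhythm$gene)
  profiles <- lapply(stats::setNames(all_genes, all_genes),
                     function(g) mean_profile(expr, g))
  pairs <- unique(t(apply(
    expand.grid(a = gene_set_a, b = gene_set_b, stringsAsFactors = FALSE),
    1L, function(p) sort(unname(p)))))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    r <- tryCatch(pearson_r(profiles[[a]], profiles[[b]]),
                  error = function(e) NA_real_)
    cls <- if (is.na(r)) {
      data.frame(direction = NA_character_, strength = NA_character_)
    } else classify_correlation(r)
    gate <- !is.na(r) && abs(r) > min_abs_r &&
      (isTRUE(flags[[a]]) || isTRUE(flags[[b]]))
    data.frame(gene_a = a, gene_b = b, r = r, direction = cls$direction,
               strength = cls$strength, gate_passed = gate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
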