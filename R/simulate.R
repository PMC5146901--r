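#' Specify one simulated gene
#'
#' A gene is simulated as a 24-h cosinor curve,
#' \eqn{M + A\cos(\pi t/12 - \phi)}, with multiplicative log-normal noise:
#' each observation is the curve value times \eqn{2^\epsilon},
#' \eqn{\epsilon \sim N(0, noise\_sd^2)}. Reference-gene candidates use the
#' same machinery: a stable reference is a flat gene (A = 0); an unstable one
#' additionally drifts linearly on the log2 scale across the day (see
#' [generate_ct_dataset()]).
#'
#' @param name Gene identifier.
#' @param mesor Expected relative expression level, > 0.
#' @param amplitude Oscillation amplitude, `0 <= amplitude <= mesor` so the
#'   noiseless curve stays positive.
#' @param acrophase Acrophase in radians; wrapped to `[0, 2pi)`.
#' @param noise_sd Multiplicative noise scale, in log2 units, >= 0.
#' @param role `"target"`, `"reference_stable"` or `"reference_unstable"`.
#' @return A `gene_spec` object (named list).
#' @export
gene_spec <- function(name, mesor, amplitude = 0, acrophase = 0,
                      noise_sd = 0.1,
                      role = c("target", "reference_stable",
                               "reference_unstable")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L,
            mesor > 0, amplitude >= 0, noise_sd >= 0)
  # for cosinor-modelled roles amplitude is in expression units and must not
  # push the noiseless curve negative; for an unstable reference it is the
  # total log2 drift over the day, where no such cap applies
  if (role != "reference_unstable" && amplitude > mesor) {
    stop("gene '", name, "': amplitude (", amplitude,
         ") must not exceed mesor (", mesor,
         ") or expression goes negative")
  }
  structure(list(name = name, mesor = mesor, amplitude = amplitude,
                 acrophase = acrophase %% (2 * pi), noise_sd = noise_sd,
                 role = role),
            class = "gene_spec")
}

#' Specify the sampling design of a daily-rhythm experiment
#'
#' Defaults mirror a nine-Zeitgeber-time design sampled every 3 h from ZT0
#' through ZT24 with six individuals per timepoint under a 12L:12D
#' photoperiod. ZT24 is a distinct sample set even though its phase
#' duplicates ZT0 in the 24-h model.
#'
#' @param timepoints Zeitgeber times in hours, strictly increasing, in
#'   `[0, 24]`.
#' @param replicates Individuals per timepoint, >= 2.
#' @param photoperiod Light/dark annotation string.
#' @param seed Integer root seed for the random stream.
#' @return A `study_design` object (named list).
#' @export
study_design <- function(timepoints = seq(0, 24, by = 3), replicates = 6L,
                         photoperiod = "12L:12D", seed = 1L) {
  stopifnot(all(diff(timepoints) > 0), all(timepoints >= 0),
            all(timepoints <= 24), replicates >= 2L,
            is.numeric(seed), length(seed) == 1L)
  structure(list(timepoints = timepoints, replicates = as.integer(replicates),
                 photoperiod = photoperiod, seed = as.integer(seed)),
            class = "study_design")
}

# One child seed per gene, derived from the root seed and the gene's position
# in declaration order, so adding genes never perturbs earlier genes' draws.
# Kept below 2^31 - 1.
child_seed <- function(root, index) {
  as.integer((as.double(root) * 48271 + index * 16807) %% 2147483647)
}

sample_ids <- function(design, prefix = "s") {
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      zt = design$timepoints)
  sprintf("%s_ZT%g_r%d", prefix, grid$zt, grid$replicate)
}

#' Generate a seeded relative-expression dataset
#'
#' For every gene, timepoint and replicate draws
#' `cosinor_signal(zt, mesor, amplitude, acrophase) * 2^eps` with
#' `eps ~ N(0, noise_sd^2)`, independently. The same (genes, design, seed)
#' always yields the identical table.
#'
#' @param genes List of [gene_spec()] objects.
#' @param design A [study_design()].
#' @param prefix Sample-id prefix (e.g. a tissue label).
#' @return Data frame with columns `sample_id`, `gene`, `zt`, `replicate`,
#'   `value` (relative expression, > 0 whenever `amplitude < mesor`).
#' @export
generate_expression_dataset <- function(genes, design, prefix = "s") {
  stopifnot(inherits(design, "study_design"))
  genes <- validate_gene_list(genes)
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      zt = design$timepoints)
  ids <- sprintf("%s_ZT%g_r%d", prefix, grid$zt, grid$replicate)
  per_gene <- lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    set.seed(child_seed(design$seed, i))
    eps <- stats::rnorm(nrow(grid), 0, g$noise_sd)
    mu <- cosinor_signal(grid$zt, g$mesor, g$amplitude, g$acrophase)
    data.frame(sample_id = ids, gene = g$name, zt = grid$zt,
               replicate = grid$replicate, value = mu * 2^eps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  rownames(out) <- NULL
  out
}

#' Generate a seeded raw-Ct qPCR dataset
#'
#' Converts simulated expression to cycle-threshold values via
#' `ct = base_ct - log2(expression)`: doubling expression lowers Ct by one
#' cycle. Target genes and stable reference candidates use their cosinor
#' model directly (a stable reference is flat, so its expected Ct is
#' constant). Unstable reference candidates drift linearly on the log2
#' scale across the day, with a total span over 24 h equal to the spec's
#' `amplitude` field interpreted in log2 cycles. Applying [delta_delta_ct()]
#' to the output recovers the generating expression ratios up to the
#' calibrator constant.
#'
#' @inheritParams generate_expression_dataset
#' @param base_ct Cycle threshold corresponding to unit relative expression
#'   (default 22, a typical qPCR midrange).
#' @return Data frame with columns `sample_id`, `gene`, `zt`, `replicate`,
#'   `ct`.
#' @export
generate_ct_dataset <- function(genes, design, base_ct = 22, prefix = "s") {
  stopifnot(inherits(design, "study_design"), is.finite(base_ct))
  genes <- validate_gene_list(genes)
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      zt = design$timepoints)
  ids <- sprintf("%s_ZT%g_r%d", prefix, grid$zt, grid$replicate)
  per_gene <- lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    set.seed(child_seed(design$seed, i))
    eps <- stats::rnorm(nrow(grid), 0, g$noise_sd)
    if (g$role == "reference_unstable") {
      # linear drift in log2 expression: 'amplitude' = total span in cycles
      log2_expr <- log2(g$mesor) + g$amplitude * (grid$zt / 24 - 0.5) + eps
    } else {
      mu <- cosinor_signal(grid$zt, g$mesor, g$amplitude, g$acrophase)
      log2_expr <- log2(mu) + eps
    }
    data.frame(sample_id = ids, gene = g$name, zt = grid$zt,
               replicate = grid$replicate, ct = base_ct - log2_expr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  rownames(out) <- NULL
  out
}

validate_gene_list <- function(genes) {
  if (inherits(genes, "gene_spec")) genes <- list(genes)
  ok <- vapply(genes, inherits, logical(1), "gene_spec")
  if (!all(ok)) stop("`genes` must be a list of gene_spec objects")
  nm <- vapply(genes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate gene names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  genes
}

#' Default reference-gene candidate panel
#'
#' Six candidates mirroring a typical fish-muscle qPCR panel: five stable
#' housekeeping genes with small noise and one unstable candidate whose
#' expression drifts across the day (ribosomal RNA abundance is a classic
#' unstable normaliser).
#'
#' @param noise_sd Log2 noise for the stable candidates.
#' @param drift_cycles Total log2 drift of the unstable candidate over 24 h.
#' @return List of [gene_spec()] objects.
#' @export
reference_panel <- function(noise_sd = 0.12, drift_cycles = 1.2) {
  c(lapply(c("rpl13", "bactin", "gapdh", "hprt1", "rps29"), function(nm)
      gene_spec(nm, mesor = 1, amplitude = 0, noise_sd = noise_sd,
                role = "reference_stable")),
    list(gene_spec("r18s", mesor = 1, amplitude = drift_cycles,
                   noise_sd = noise_sd, role = "reference_unstable")))
}
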