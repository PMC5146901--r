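#' Gene panels of the Chinese-perch muscle study design
#'
#' `clock_genes()` returns the 15 core circadian oscillator genes profiled in
#' both muscle types; `myogenic_genes()` the 11 muscle-related genes
#' (myogenic regulatory factors and other muscle growth/maintenance genes).
#' Names are in normalised lower-case form (see [normalize_gene_names()]).
#'
#' @return Character vector of gene identifiers.
#' @export
clock_genes <- function() {
  c("arntl1", "arntl2", "clock", "cry1", "cry2", "cry3", "crydash",
    "npas2", "nr1d1", "nr1d2", "per1", "per2", "per3", "rora", "tim")
}

#' @rdname clock_genes
#' @export
myogenic_genes <- function() {
  c("foxk2", "mbnl1", "mrf4", "mstn", "murf1", "myf5", "myod", "myog",
    "pdk4", "pcna", "ucp3")
}

#' Normalise gene names to the package's canonical form
#'
#' Lower-cases names and maps common orthographic variants:
#' `"rorα"`/`"ror-alpha"` to `"rora"`, `"cry-dash"` to `"crydash"`.
#'
#' @param x Character vector of gene names.
#' @return Normalised character vector.
#' @export
normalize_gene_names <- function(x) {
  x <- tolower(x)
  x[x %in% c("rorα", "ror-alpha", "roralpha")] <- "rora"
  x[x == "cry-dash"] <- "crydash"
  x
}

#' Published per-gene rhythmicity parameters
#'
#' Returns the packaged transcription of the study's printed rhythmicity
#' tables for fast or slow skeletal muscle: per gene the fitted amplitude,
#' the noise/signal P value, mesor, acrophase (radians, 2 decimals), its
#' Zeitgeber-hour conversion as printed, and whether the row was highlighted
#' as rhythmic (equivalently, P < 0.3). These transcribed values are the
#' data of record for worked examples — the underlying raw expression
#' measurements were never deposited.
#'
#' @param tissue `"fast"` or `"slow"` skeletal muscle.
#' @return Data frame with columns `gene`, `amplitude`, `p_value`, `mesor`,
#'   `acrophase`, `zt_h`, `rhythmic`.
#' @export
published_rhythm_table <- function(tissue = c("fast", "slow")) {
  tissue <- match.arg(tissue)
  path <- system.file("extdata",
                      sprintf("rhythm_params_%s.csv", tissue),
                      package = "rhythmoscope", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build the default simulated gene panel for one tissue
#'
#' Uses the published per-gene cosinor parameters (mesor, amplitude,
#' acrophase) of the chosen tissue as the generating truth, so the synthetic
#' data reproduce the study's design conditions: 26 target genes per tissue
#' on a 9-timepoint, 6-replicate sampling grid.
#'
#' @param tissue `"fast"` or `"slow"`.
#' @param noise_sd Multiplicative noise scale in log2 units applied to every
#'   target gene (default 0.1).
#' @return List of [gene_spec()] objects.
#' @export
default_gene_panel <- function(tissue = c("fast", "slow"), noise_sd = 0.1) {
  tab <- published_rhythm_table(tissue)
  lapply(seq_len(nrow(tab)), function(i) {
    gene_spec(tab$gene[i], mesor = tab$mesor[i],
              # a few printed rows have amplitude slightly above mesor only
              # through 2-decimal rounding; cap to keep the curve positive
              amplitude = min(tab$amplitude[i], tab$mesor[i]),
              acrophase = tab$acrophase[i], noise_sd = noise_sd,
              role = "target")
  })
}

#' Full-length cDNA structure arithmetic
#'
#' Sums the 5'-UTR, open reading frame and 3'-UTR lengths of a transcript.
#' An ORF length that is not a multiple of 3 triggers a warning (a complete
#' ORF is a whole number of codons).
#'
#' @param utr5,orf,utr3 Segment lengths in base pairs, non-negative.
#' @return Total transcript length in base pairs.
#' @examples
#' transcript_structure_total(412, 2697, 589)  # 3698
#' @export
transcript_structure_total <- function(utr5, orf, utr3) {
  if (any(c(utr5, orf, utr3) < 0)) stop("segment lengths must be non-negative")
  if (orf %% 3 != 0) {
    warning("ORF length ", orf, " is not a multiple of 3")
  }
  utr5 + orf + utr3
}
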