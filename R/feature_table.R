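#' Simulate a per-miRNA pri-miRNA feature table
#'
#' One row per miRNA locus with the hairpin-level covariates used in the
#' feature association analysis: an in vitro Microprocessor cleavage score,
#' DRES / midBMW / mGHG motif flags, predicted secondary-structure features
#' (apical loop length, stem length, mismatch count, lower stem length,
#' bulge count) and genomic context (clustered, intronic, from the bundle
#' annotation). By default every feature is drawn independently of the
#' bundle's `idr1_sensitive` truth flag (a fully null table); `assoc_spec`
#' entries couple a named feature to the truth flag -- continuous features
#' are shifted additively by the effect in sensitive loci, flag features
#' have their success probability moved by the effect.
#'
#' @param bundle a `ref_bundle`.
#' @param assoc_spec named numeric of per-feature effects (0 = null); names
#'   must be known features.
#' @param seed integer seed.
#' @return data.frame keyed by `name` with the feature columns above.
#' @export
simulate_feature_table <- function(bundle, assoc_spec = NULL, seed = 1) {
  m <- bundle$mirna_loci
  known <- c("cleavage_score", "DRES", "midBMW", "mGHG", "loop_length",
             "stem_length", "mismatch_count", "lower_stem_length",
             "bulge_count")
  if (!is.null(assoc_spec)) {
    bad <- setdiff(names(assoc_spec), known)
    if (length(bad)) stop("unknown feature in assoc_spec: ",
                          paste(bad, collapse = ", "))
  }
  eff <- function(f) if (!is.null(assoc_spec) && f %in% names(assoc_spec))
    assoc_spec[[f]] else 0
  withr::with_seed(seed, {
    n <- nrow(m)
    s <- as.numeric(m$idr1_sensitive)
    flag <- function(f, p0) {
      p <- pmin(pmax(p0 + eff(f) * s, 0), 1)
      rbinom(n, 1, p) == 1
    }
    out <- data.frame(
      name = m$name,
      cleavage_score = runif(n) + eff("cleavage_score") * s,
      DRES = flag("DRES", 0.4),
      midBMW = flag("midBMW", 0.3),
      mGHG = flag("mGHG", 0.35),
      loop_length = sample(4:30, n, replace = TRUE) +
        round(eff("loop_length") * s),
      stem_length = sample(18:40, n, replace = TRUE) +
        round(eff("stem_length") * s),
      mismatch_count = sample(0:6, n, replace = TRUE) +
        round(eff("mismatch_count") * s),
      lower_stem_length = sample(5:15, n, replace = TRUE) +
        round(eff("lower_stem_length") * s),
      bulge_count = sample(0:4, n, replace = TRUE) +
        round(eff("bulge_count") * s),
      clustered = !is.na(m$cluster_id),
      intronic = m$intronic,
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
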