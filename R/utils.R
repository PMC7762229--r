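## Seed hygiene: run `code` under a fixed RNG seed, restoring the caller's
## RNG state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Canonical spellings for common literature aliases of the model's nodes
## (Greek letters, hyphens, alternative gene symbols).
node_alias_table <- function() {
  c(
    "IFNγ" = "IFNG", "IFN-γ" = "IFNG", "IFNGAMMA" = "IFNG",
    "IFNα/β" = "IFNAB", "IFNA/B" = "IFNAB",
    "GM-CSF" = "GMCSF", "IL-1" = "IL1", "IL-1β" = "IL1b",
    "IL1B" = "IL1b", "IL-4" = "IL4", "IL-13" = "IL13", "IL-10" = "IL10",
    "IL-10s" = "IL10s", "M-CSF" = "MCSF", "CSF1" = "MCSF", "CSF-1" = "MCSF",
    "M-CSFR" = "MCSFR", "CSF1R" = "MCSFR", "IL-4Rα" = "IL4RA",
    "IL4R" = "IL4RA", "IL-10R" = "IL10R", "IL-1R" = "IL1R",
    "NF-κB" = "NFKB", "NF-KB" = "NFKB", "NFKB1" = "NFKB",
    "TNFα" = "TNFA", "TNF-α" = "TNFA", "TNF" = "TNFA",
    "TGFβ" = "TGFB", "TGF-β" = "TGFB", "TGFB1" = "TGFB",
    "HIF1α" = "HIF1A", "HIF-1α" = "HIF1A", "HIF1" = "HIF1A",
    "PPARγ" = "PPARG", "PPAR-γ" = "PPARG",
    "IL-12" = "IL12", "STAT-1" = "STAT1", "STAT-3" = "STAT3",
    "STAT-5" = "STAT5", "STAT-6" = "STAT6"
  )
}

#' Canonicalize node identifiers
#'
#' Maps literature spellings (Greek letters, hyphens, synonyms such as
#' CSF-1) to the canonical node names used by the bundled model.
#' Unrecognized names are returned unchanged.
#'
#' @param x Character vector of node names.
#' @return Character vector of canonical names.
#' @examples
#' canonical_node_names(c("TNFα", "M-CSF", "STAT6"))
#' @export
canonical_node_names <- function(x) {
  tab <- node_alias_table()
  hit <- match(toupper(x), toupper(names(tab)))
  out <- ifelse(is.na(hit), x, unname(tab[hit]))
  out
}
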