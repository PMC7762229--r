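## The bundled macrophage-polarization model ---------------------------------
##
## 10 extracellular signals (inputs) and 30 intracellular components.  The
## three phenotype readouts (M1, M2, NLC) are classification labels computed
## from marker signatures, not dynamic nodes, so the dynamic system has
## N = 40 components.

macrophage_input_nodes <- function() {
  c("IFNG", "LPS", "GMCSF", "IL1", "IC", "IL4", "IL13", "IL10", "MCSF", "HMGB1")
}

## The 30 intracellular update rules.  Three of them -- IFNGR, STAT1, PPARG --
## mix an un-parenthesized OR chain with a trailing "and not (...)" and
## therefore parse differently under the two dialects; all others are
## dialect-invariant.
macrophage_rule_table <- function() {
  c(
    IFNGR  = "IFNG or IFNAB and not (SOCS1)",
    CSF2RA = "GMCSF",
    IL1R   = "IL1 or IL1b",
    TLR4   = "LPS and not (FCGR)",
    FCGR   = "IC and (LPS or IL1)",
    IL4RA  = "IL4 and IL13",
    IL10R  = "IL10 or IL10s",
    MCSFR  = "MCSF",
    STAT1  = "IFNGR or STAT1 and not (STAT6)",
    STAT5  = "CSF2RA and not (STAT3 or IRF4)",
    NFKB   = "(STAT1 or TNFA or TLR4 or IL1R) and not (STAT6 or FCGR or PPARG or KLF4)",
    PPARG  = "IL4RA or MCSFR or ERK and not (STAT6)",
    STAT6  = "IL4RA or MCSFR",
    JMJD3  = "IL4RA or MCSFR",
    STAT3  = "(IL10R or EGF or STAT3) and not (FCGR or PPARG)",
    IRF3   = "TLR4",
    ERK    = "FCGR",
    KLF4   = "STAT6",
    SOCS1  = "STAT6 or STAT1",
    IRF4   = "JMJD3",
    IRF5   = "STAT5 and not (IRF4)",
    IL1b   = "NFKB or TNFA",
    IFNAB  = "IRF3",
    EGF    = "ERK or STAT3",
    IL12   = "STAT1 or STAT5 or NFKB",
    IL10s  = "(PPARG or STAT3) and not (IRF5 or TNFA)",
    TNFA   = "IRF5 and not (IL10s)",
    TGFB   = "STAT3 and (not TNFA)",
    HIF1A  = "(STAT3 or IL10s) and (not STAT1)",
    RAGE   = "HMGB1"
  )
}

## Marker signatures.  A signature is a conjunction of clauses; each clause
## is a disjunction of marker nodes (all intracellular).  The M2 signature
## exists in two readings: "strict" takes PPARG as its own conjunctive
## clause; "disjunctive" folds PPARG into the STAT3/STAT6 clause.
macrophage_signatures <- function(m2_variant = c("strict", "disjunctive")) {
  m2_variant <- match.arg(m2_variant)
  m2 <- if (m2_variant == "strict") {
    list("IL10s", c("STAT3", "STAT6"), "PPARG")
  } else {
    list("IL10s", c("STAT3", "STAT6", "PPARG"))
  }
  list(
    NLC = list("TGFB", "HIF1A", "EGF", "RAGE"),
    M2 = m2,
    M1 = list("IL12", "NFKB", "TNFA", c("STAT1", "STAT5"))
  )
}

#' Build the bundled macrophage-polarization model
#'
#' Constructs the 40-node Boolean network of monocyte polarization (10
#' extracellular signals with identity rules, 30 intracellular components),
#' together with node roles, the M1/M2/NLC marker signatures, and the preset
#' stimulus conditions and perturbations used by the in-silico experiments.
#'
#' @param dialect Rule-parsing dialect for the three precedence-ambiguous
#'   rules (IFNGR, STAT1, PPARG); see [parse_rule()].  The default
#'   `"standard"` (NOT > AND > OR) is the convention of the common
#'   Boolean-network toolkits and is the configuration under which the
#'   model's published attractor counts are reproduced.
#' @param m2_variant Reading of the M2 signature: `"strict"` requires
#'   IL10s, (STAT3 or STAT6) and PPARG; `"disjunctive"` requires IL10s and
#'   (STAT3 or STAT6 or PPARG).
#' @return Object of class `macrophage_model`: a list with elements
#'   `network`, `roles`, `signatures`, `conditions`, `perturbations`,
#'   `dialect`, `m2_variant`.
#' @examples
#' mod <- macrophage_model()
#' mod$network$rules$RAGE
#' @export
macrophage_model <- function(dialect = c("standard", "grouped"),
                             m2_variant = c("strict", "disjunctive")) {
  dialect <- match.arg(dialect)
  m2_variant <- match.arg(m2_variant)
  inputs <- macrophage_input_nodes()
  intra <- macrophage_rule_table()
  rules <- c(setNames(as.list(inputs), inputs), as.list(intra))
  network <- boolean_network(rules, inputs = inputs, dialect = dialect)

  roles <- c(
    setNames(rep("signal", length(inputs)), inputs),
    setNames(rep("intracellular", length(intra)), names(intra))
  )
  receptors <- c("IFNGR", "CSF2RA", "IL1R", "TLR4", "FCGR", "IL4RA",
                 "IL10R", "MCSFR", "RAGE")
  roles[receptors] <- "receptor"

  conditions <- list(
    M1_stimuli = c("IFNG", "GMCSF", "IL1", "LPS"),
    M2_stimuli = c("IC", "IL4", "IL13", "IL10"),
    NLC_stimuli = c("MCSF", "HMGB1")
  )
  perturbations <- list(
    STAT6_KO = c(STAT6 = 0L),
    PPARG_KO = c(PPARG = 0L),
    IL4RA_KO = c(IL4RA = 0L),
    IRF5_KO = c(IRF5 = 0L),
    STAT5_KO = c(STAT5 = 0L),
    IRF4_JMJD3_KO = c(IRF4 = 0L, JMJD3 = 0L),
    STAT3_KO = c(STAT3 = 0L),
    EGF_KO = c(EGF = 0L),
    STAT1_KO = c(STAT1 = 0L),
    EGF_CA = c(EGF = 1L)
  )

  structure(list(
    network = network,
    roles = roles,
    signatures = macrophage_signatures(m2_variant),
    conditions = conditions,
    perturbations = perturbations,
    dialect = dialect,
    m2_variant = m2_variant
  ), class = "macrophage_model")
}

#' @export
print.macrophage_model <- function(x, ...) {
  cat("Macrophage polarization model\n")
  cat(sprintf("  %d nodes: %d signals, %d intracellular (%d receptors)\n",
              length(x$network$nodes), sum(x$roles == "signal"),
              sum(x$roles != "signal"), sum(x$roles == "receptor")))
  cat(sprintf("  dialect: %s; M2 signature: %s\n", x$dialect, x$m2_variant))
  cat("  signatures:", paste(names(x$signatures), collapse = ", "), "\n")
  cat("  preset conditions:", paste(names(x$conditions), collapse = ", "), "\n")
  cat("  preset perturbations:", paste(names(x$perturbations), collapse = ", "), "\n")
  invisible(x)
}

#' Look up a preset condition or perturbation
#'
#' @param model A [macrophage_model()].
#' @param name Preset name, e.g. `"NLC_stimuli"` or `"STAT6_KO"`.
#' @return For a condition preset, the character vector of available
#'   stimuli; for a perturbation preset, the named clamp vector.
#' @export
get_preset <- function(model, name) {
  stopifnot(inherits(model, "macrophage_model"))
  if (name %in% names(model$conditions)) return(model$conditions[[name]])
  if (name %in% names(model$perturbations)) return(model$perturbations[[name]])
  stop("unknown preset: '", name, "'")
}

#' Intracellular (non-input) nodes of a model
#'
#' @param model A [macrophage_model()].
#' @return Character vector of the 30 intracellular node names.
#' @export
intracellular_nodes <- function(model) {
  setdiff(model$network$nodes, model$network$inputs)
}
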