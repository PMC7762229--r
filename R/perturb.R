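## Stimulus conditions and in-silico perturbation experiments -----------------

#' Run a stimulus-condition experiment
#'
#' Makes a chosen subset of extracellular signals available, clamps all
#' other inputs to 0, pools the resulting fixed points, projects them onto
#' the intracellular nodes, deduplicates, flags non-biological states and
#' classifies the profiles.
#'
#' Three semantics are supported for "available":
#' \describe{
#'   \item{`"all_subsets"`}{(default) fixed points are pooled over every
#'     combination of the available stimuli, including none of them -- the
#'     stimuli are free inputs while the rest of the environment is silenced.}
#'   \item{`"nonempty_subsets"`}{as above but at least one stimulus present.}
#'   \item{`"all_on"`}{a single assignment with every listed stimulus ON.}
#' }
#'
#' @param model A [macrophage_model()] (or any `macrophage_model`-shaped
#'   bundle with `network` and `signatures`).
#' @param stimuli Character vector of input nodes to make available, or the
#'   name of a preset condition (e.g. `"NLC_stimuli"`).
#' @param semantics One of `"all_subsets"`, `"nonempty_subsets"`, `"all_on"`.
#' @param policy Classification policy, see [classify_profile()].
#' @return List with `table` (classified `profile_table`) and `counts`
#'   (named integer vector over M0/M1/M2/NLC; non-biological profiles count
#'   in M0).
#' @export
run_condition <- function(model, stimuli,
                          semantics = c("all_subsets", "nonempty_subsets",
                                        "all_on"),
                          policy = c("priority", "strict_exclusive")) {
  semantics <- match.arg(semantics)
  policy <- match.arg(policy)
  network <- model$network
  if (length(stimuli) == 1L && stimuli %in% names(model$conditions)) {
    stimuli <- model$conditions[[stimuli]]
  }
  if (length(stimuli) == 0L) stop("empty stimuli set")
  stopifnot(all(stimuli %in% network$inputs))
  others <- setdiff(network$inputs, stimuli)

  subsets <- if (semantics == "all_on") {
    list(stimuli)
  } else {
    lo <- if (semantics == "all_subsets") 0L else 1L
    unlist(lapply(lo:length(stimuli), function(k) {
      if (k == 0L) return(list(character(0)))
      combn(stimuli, k, simplify = FALSE)
    }), recursive = FALSE)
  }

  pool <- list()
  for (sub in subsets) {
    assign <- setNames(rep(0L, length(network$inputs)), network$inputs)
    assign[sub] <- 1L
    pool[[length(pool) + 1L]] <- enumerate_fixed_points(network, assign)
  }
  fp <- do.call(rbind, pool)
  table <- project_and_dedup(fp, drop_nodes = network$inputs)
  table <- classify_profiles(table, model$signatures, policy)
  cats <- c("M0", sort(names(model$signatures)))
  list(table = table,
       counts = summarize_categories(table, categories = cats)$counts)
}

#' Apply knock-outs / constitutive activations to a model
#'
#' Replaces the clamped nodes' rules by constants (0 = knock-out,
#' 1 = constitutive activation); the clamp overrides the rule in every
#' state.  Everything else in the bundle is untouched.
#'
#' @param model A [macrophage_model()].
#' @param clamps Named 0/1 vector of nodes to clamp, or the name of a
#'   preset perturbation (e.g. `"STAT6_KO"`).
#' @return The perturbed model.
#' @export
apply_perturbation <- function(model, clamps) {
  if (is.character(clamps) && length(clamps) == 1L && is.null(names(clamps))) {
    clamps <- model$perturbations[[clamps]]
    if (is.null(clamps)) stop("unknown perturbation preset")
  }
  if (length(clamps) == 0L) return(model)
  network <- model$network
  stopifnot(all(names(clamps) %in% network$nodes))
  rules <- network$rules
  for (n in names(clamps)) rules[[n]] <- bool_const(clamps[[n]])
  inputs <- setdiff(network$inputs, names(clamps))
  model$network <- boolean_network(rules, inputs = inputs)
  model$clamps <- clamps
  model
}

#' Global category counts of a model over the full stimulus space
#'
#' Enumerates all fixed points over every input assignment, projects onto
#' the intracellular nodes, deduplicates and classifies.
#'
#' @param model A [macrophage_model()] (possibly perturbed).
#' @param intracellular Columns to keep for classification; defaults to the
#'   non-input nodes of the unperturbed bundled model so that perturbed and
#'   baseline counts live on the same profile space.
#' @inheritParams run_condition
#' @return List with `table` and `counts` as in [run_condition()].
#' @export
global_category_counts <- function(model,
                                   policy = c("priority", "strict_exclusive"),
                                   intracellular = NULL) {
  policy <- match.arg(policy)
  fp <- enumerate_all_fixed_points(model$network)
  if (is.null(intracellular)) {
    intracellular <- setdiff(colnames(fp), macrophage_input_nodes())
  }
  drop <- setdiff(colnames(fp), intracellular)
  table <- project_and_dedup(fp, drop_nodes = drop)
  table <- classify_profiles(table, model$signatures, policy)
  cats <- c("M0", sort(names(model$signatures)))
  list(table = table,
       counts = summarize_categories(table, categories = cats)$counts)
}

#' Qualitative effect calls against a baseline
#'
#' @param baseline,perturbed Named category-count vectors over the same
#'   category universe.
#' @param categories Categories to call (default the phenotypes, not M0).
#' @return Named character vector of calls per category:
#'   `"complete_loss"` (baseline > 0, perturbed = 0), `"decrease"`,
#'   `"increase"` or `"unchanged"`.
#' @export
compare_to_baseline <- function(baseline, perturbed,
                                categories = c("M1", "M2", "NLC")) {
  stopifnot(all(categories %in% names(baseline)),
            all(categories %in% names(perturbed)))
  vapply(categories, function(cat) {
    b <- baseline[[cat]]; p <- perturbed[[cat]]
    if (b > 0L && p == 0L) "complete_loss"
    else if (p < b) "decrease"
    else if (p > b) "increase"
    else "unchanged"
  }, character(1))
}

#' Run the preset knock-out / constitutive-activation panel
#'
#' For every preset perturbation, enumerates the perturbed model's fixed
#' points over the full input space, classifies them, and calls the effect
#' on each phenotype against the unperturbed baseline.
#'
#' @param model A [macrophage_model()].
#' @param perturbations Named list of clamp vectors; defaults to the
#'   model's presets.
#' @inheritParams run_condition
#' @return List with `baseline` (count vector) and `experiments`, a named
#'   list of lists `(clamps, counts, calls)`.
#' @export
run_perturbation_panel <- function(model, perturbations = model$perturbations,
                                   policy = c("priority", "strict_exclusive")) {
  policy <- match.arg(policy)
  intr <- intracellular_nodes(model)
  baseline <- global_category_counts(model, policy, intracellular = intr)$counts
  experiments <- lapply(perturbations, function(clamps) {
    pert <- apply_perturbation(model, clamps)
    counts <- global_category_counts(pert, policy, intracellular = intr)$counts
    list(clamps = clamps, counts = counts,
         calls = compare_to_baseline(baseline, counts))
  })
  list(baseline = baseline, experiments = experiments)
}
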