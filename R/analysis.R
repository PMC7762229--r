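## Consolidated polarization analysis -----------------------------------------

#' Full attractor analysis of a macrophage-polarization model
#'
#' Runs the whole pipeline under one declared configuration: fixed-point
#' enumeration over the complete stimulus space, projection onto the
#' intracellular nodes, supervised signature classification, Jaccard-Needham
#' distances with hierarchical density-based clustering,
#' category-vs-cluster correlation, the preset stimulus conditions, and the
#' preset knock-out / constitutive-activation panel.
#'
#' @param model A [macrophage_model()]; the configuration (dialect, M2
#'   signature variant) is carried by the model object.
#' @param policy Classification policy, see [classify_profile()].
#' @param semantics Condition semantics, see [run_condition()].
#' @param min_cluster_size Minimum cluster size for the unsupervised step.
#' @param run_conditions,run_perturbations Logical switches for the two
#'   experiment stages (both on by default).
#' @return Object of class `polarization_analysis` with elements
#'   `config`, `n_fixed_points`, `table` (classified `profile_table`),
#'   `summary`, `category_means`, `distances`, `cluster_labels`,
#'   `cluster_means`, `correlation`, `conditions`, `perturbations`.
#' @examples
#' \donttest{
#' res <- polarization_analysis(macrophage_model())
#' print(res)
#' }
#' @export
polarization_analysis <- function(model = macrophage_model(),
                                  policy = c("priority", "strict_exclusive"),
                                  semantics = c("all_subsets",
                                                "nonempty_subsets", "all_on"),
                                  min_cluster_size = 2L,
                                  run_conditions = TRUE,
                                  run_perturbations = TRUE) {
  policy <- match.arg(policy)
  semantics <- match.arg(semantics)
  config <- list(dialect = model$dialect, m2_variant = model$m2_variant,
                 policy = policy, semantics = semantics,
                 min_cluster_size = as.integer(min_cluster_size))

  fp <- enumerate_all_fixed_points(model$network)
  table <- project_and_dedup(fp, drop_nodes = model$network$inputs)
  table <- classify_profiles(table, model$signatures, policy)
  summ <- summarize_categories(table)

  cats <- names(which(summ$counts > 0L))
  category_means <- t(vapply(cats, function(cat) average_profile(table, cat),
                             numeric(ncol(table$profiles))))
  rownames(category_means) <- cats

  distances <- pairwise_distances(table)
  labels <- cluster_attractors(distances, min_cluster_size)
  clm <- cluster_means(table$profiles, labels)
  correlation <- category_cluster_correlation(category_means, clm)

  conditions <- NULL
  if (run_conditions) {
    conditions <- lapply(model$conditions, function(stimuli) {
      run_condition(model, stimuli, semantics, policy)$counts
    })
  }
  perturbations <- NULL
  if (run_perturbations) {
    perturbations <- run_perturbation_panel(model, policy = policy)
  }

  structure(list(
    config = config,
    n_fixed_points = nrow(fp),
    n_input_assignments = attr(fp, "n_assignments"),
    table = table,
    summary = summ,
    category_means = category_means,
    distances = distances,
    cluster_labels = labels,
    cluster_means = clm,
    correlation = correlation,
    conditions = conditions,
    perturbations = perturbations
  ), class = "polarization_analysis")
}

#' @export
print.polarization_analysis <- function(x, ...) {
  cat("Macrophage polarization analysis\n")
  cat(sprintf("  config: dialect=%s, M2=%s, policy=%s, semantics=%s, min_cluster_size=%d\n",
              x$config$dialect, x$config$m2_variant, x$config$policy,
              x$config$semantics, x$config$min_cluster_size))
  cat(sprintf("  %d fixed points over %d input assignments -> %d unique intracellular profiles\n",
              x$n_fixed_points, x$n_input_assignments,
              x$summary$n_profiles))
  cat("  categories:\n")
  for (cat_ in names(x$summary$counts)) {
    cat(sprintf("    %-4s %4d  (%.1f%%)\n", cat_, x$summary$counts[[cat_]],
                x$summary$percent[[cat_]]))
  }
  ncl <- length(unique(x$cluster_labels[x$cluster_labels > 0L]))
  cat(sprintf("  clustering: %d clusters, %d noise point(s)\n",
              ncl, sum(x$cluster_labels == 0L)))
  if (!is.null(x$conditions)) {
    cat("  conditions:\n")
    for (nm in names(x$conditions)) {
      cnt <- x$conditions[[nm]]
      cat(sprintf("    %-12s %s\n", nm,
                  paste(sprintf("%s=%d", names(cnt), cnt), collapse = " ")))
    }
  }
  if (!is.null(x$perturbations)) {
    cat("  perturbation calls (vs baseline",
        paste(sprintf("%s=%d", names(x$perturbations$baseline),
                      x$perturbations$baseline), collapse = " "), "):\n")
    for (nm in names(x$perturbations$experiments)) {
      calls <- x$perturbations$experiments[[nm]]$calls
      cat(sprintf("    %-14s %s\n", nm,
                  paste(sprintf("%s:%s", names(calls), calls), collapse = "  ")))
    }
  }
  invisible(x)
}

#' @export
summary.polarization_analysis <- function(object, ...) {
  out <- list(
    config = object$config,
    n_fixed_points = object$n_fixed_points,
    n_profiles = object$summary$n_profiles,
    counts = object$summary$counts,
    percent = object$summary$percent,
    n_clusters = length(unique(object$cluster_labels[object$cluster_labels > 0L])),
    conditions = object$conditions,
    perturbation_calls = if (!is.null(object$perturbations)) {
      lapply(object$perturbations$experiments, `[[`, "calls")
    }
  )
  class(out) <- "summary.polarization_analysis"
  out
}

#' @export
print.summary.polarization_analysis <- function(x, ...) {
  utils::str(x, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' The report embeds the configuration that produced it, so every artifact
#' on disk is reproducible from its own metadata.
#'
#' @param x A `polarization_analysis`.
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_analysis_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "polarization_analysis"))
  rep <- list(
    config = x$config,
    n_fixed_points = x$n_fixed_points,
    n_profiles = x$summary$n_profiles,
    counts = as.list(x$summary$counts),
    percent = as.list(round(x$summary$percent, 1)),
    conditions = lapply(x$conditions, as.list),
    perturbations = if (!is.null(x$perturbations)) list(
      baseline = as.list(x$perturbations$baseline),
      calls = lapply(x$perturbations$experiments,
                     function(e) as.list(e$calls))
    )
  )
  json <- jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
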