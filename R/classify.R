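## Profile tables and supervised phenotype classification ---------------------

#' Project fixed points onto a node subset and deduplicate
#'
#' Removes the dropped nodes (typically the extracellular inputs) from each
#' fixed point and collapses identical projections, recording how many full
#' fixed points map to each unique profile.
#'
#' @param fixed_points 0/1 matrix of fixed points (rows) by nodes (columns),
#'   e.g. from [enumerate_all_fixed_points()].
#' @param drop_nodes Character vector of columns to remove before
#'   deduplication (may be empty).
#' @return Object of class `profile_table`: list with `profiles` (0/1
#'   matrix of unique rows, lexicographic order), `multiplicity` (integer),
#'   `category` (character, NA until classified) and `nonbiological`
#'   (logical, NA until filtered/flagged).
#' @export
project_and_dedup <- function(fixed_points, drop_nodes = character(0)) {
  stopifnot(is.matrix(fixed_points))
  stopifnot(all(drop_nodes %in% colnames(fixed_points)))
  keep <- setdiff(colnames(fixed_points), drop_nodes)
  proj <- fixed_points[, keep, drop = FALSE]
  key <- apply(proj, 1L, paste, collapse = "")
  tab <- table(key)
  uniq <- proj[!duplicated(key), , drop = FALSE]
  mult <- as.integer(tab[apply(uniq, 1L, paste, collapse = "")])
  ord <- order_states(uniq)
  structure(list(
    profiles = uniq[ord, , drop = FALSE],
    multiplicity = mult[ord],
    category = rep(NA_character_, nrow(uniq)),
    nonbiological = rep(NA, nrow(uniq))
  ), class = "profile_table")
}

#' @export
print.profile_table <- function(x, ...) {
  cat(sprintf("profile table: %d unique profiles x %d nodes (%d fixed points)\n",
              nrow(x$profiles), ncol(x$profiles), sum(x$multiplicity)))
  if (!all(is.na(x$category))) {
    print(table(x$category))
  }
  invisible(x)
}

## Non-biological states: the all-zero profile, and the profile that is
## all-zero except for the constitutively ligand-driven receptor RAGE.
is_nonbiological <- function(profiles) {
  total <- rowSums(profiles)
  allzero <- total == 0L
  rage_only <- if ("RAGE" %in% colnames(profiles)) {
    total == 1L & profiles[, "RAGE"] == 1L
  } else {
    rep(FALSE, nrow(profiles))
  }
  allzero | rage_only
}

#' Flag and split off non-biological profiles
#'
#' @param table A `profile_table`.
#' @return List with `kept` and `removed` profile tables; in addition the
#'   `nonbiological` flag is filled in on both.
#' @export
filter_nonbiological <- function(table) {
  stopifnot(inherits(table, "profile_table"))
  bad <- is_nonbiological(table$profiles)
  subset_pt <- function(i) {
    structure(list(
      profiles = table$profiles[i, , drop = FALSE],
      multiplicity = table$multiplicity[i],
      category = table$category[i],
      nonbiological = bad[i]
    ), class = "profile_table")
  }
  list(kept = subset_pt(!bad), removed = subset_pt(bad))
}

## Does one binary profile satisfy a signature (conjunction of disjunctive
## marker clauses)?
matches_signature <- function(profile, signature) {
  all(vapply(signature, function(clause) any(profile[clause] == 1L), logical(1)))
}

#' Classify a binary expression profile into a polarization category
#'
#' A profile belongs to a phenotype category when every clause of that
#' category's marker signature has at least one active member.  The M1, M2
#' and NLC categories are mutually exclusive by construction of the
#' classification policy; everything else is M0.
#'
#' @param profile Named 0/1 vector over intracellular nodes (or a
#'   single-row matrix).
#' @param signatures Named list of signatures as in
#'   [macrophage_signatures()]; list order is the priority order.
#' @param policy `"priority"` resolves multi-signature matches by the
#'   signature list order (NLC > M2 > M1 for the bundled model);
#'   `"strict_exclusive"` sends any profile matching two or more signatures
#'   to M0.
#' @return A category name: one of `names(signatures)` or `"M0"`.
#' @export
classify_profile <- function(profile, signatures,
                             policy = c("priority", "strict_exclusive")) {
  policy <- match.arg(policy)
  if (is.matrix(profile)) profile <- profile[1L, ]
  hits <- names(signatures)[vapply(signatures, function(s) {
    matches_signature(profile, s)
  }, logical(1))]
  if (length(hits) == 0L) return("M0")
  if (policy == "priority") return(hits[[1L]])
  if (length(hits) == 1L) hits else "M0"
}

#' Classify every profile of a table
#'
#' Applies [classify_profile()] row-wise and flags the non-biological
#' profiles, which are reported inside the M0 category.
#'
#' @param table A `profile_table`.
#' @inheritParams classify_profile
#' @return The table with `category` and `nonbiological` filled in.
#' @export
classify_profiles <- function(table, signatures,
                              policy = c("priority", "strict_exclusive")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "profile_table"))
  bad <- is_nonbiological(table$profiles)
  cat <- character(nrow(table$profiles))
  for (i in seq_len(nrow(table$profiles))) {
    cat[i] <- if (bad[i]) "M0" else {
      classify_profile(table$profiles[i, ], signatures, policy)
    }
  }
  table$category <- cat
  table$nonbiological <- bad
  table
}

#' Category counts and percentages of a classified table
#'
#' Percentages are reported over all deduplicated profiles (the
#' non-biological profiles count inside M0); the post-filter denominator is
#' also given for transparency.
#'
#' @param table A classified `profile_table`.
#' @param categories Category universe (column order of the result).
#' @return List with `counts`, `percent` (over all rows), `n_profiles`,
#'   `n_biological` and `n_nonbiological`.
#' @export
summarize_categories <- function(table,
                                 categories = c("M0", "M1", "M2", "NLC")) {
  stopifnot(inherits(table, "profile_table"))
  if (nrow(table$profiles) == 0L) stop("empty profile table")
  if (any(is.na(table$category))) stop("table is not classified yet")
  counts <- setNames(integer(length(categories)), categories)
  tab <- base::table(factor(table$category, levels = categories))
  counts[names(tab)] <- as.integer(tab)
  n <- nrow(table$profiles)
  list(
    counts = counts,
    percent = 100 * counts / n,
    n_profiles = n,
    n_biological = sum(!table$nonbiological),
    n_nonbiological = sum(table$nonbiological)
  )
}

#' Averaged activation profile of a category
#'
#' @param table A classified `profile_table`.
#' @param category Category name with at least one member.
#' @return Named numeric vector of per-node mean activation in \[0, 1\].
#' @export
average_profile <- function(table, category) {
  stopifnot(inherits(table, "profile_table"))
  i <- which(table$category == category)
  if (length(i) == 0L) stop("category '", category, "' has no profiles")
  colMeans(table$profiles[i, , drop = FALSE])
}

#' Principal-component coordinates of the profiles
#'
#' Column-centered PCA of the binary profile matrix (no scaling).  The sign
#' of each component is fixed so that its largest-magnitude loading is
#' positive, making coordinates reproducible across platforms.
#'
#' @param table A `profile_table` with at least two rows.
#' @param n_components Number of leading components to return.
#' @return Matrix of row scores (`nrow(table$profiles)` x `n_components`).
#' @export
pca_coordinates <- function(table, n_components = 2L) {
  stopifnot(inherits(table, "profile_table"))
  m <- table$profiles
  if (nrow(m) < 2L) stop("need at least 2 profiles")
  if (all(apply(m, 2L, function(col) length(unique(col)) == 1L))) {
    stop("degenerate table: all columns constant")
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) scores[, j] <- -scores[, j]
  }
  scores
}
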