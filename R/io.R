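## Model and table I/O --------------------------------------------------------
##
## Networks round-trip through the conventional "targets, factors" text
## format: a header line, then one "node, rule" line per node.  Inputs are
## written as identity rules.  Comment lines start with '#'.

#' Read a Boolean network from a "targets, factors" file
#'
#' @param path File path (or a character vector of lines via `text`).
#' @param text Optional character vector of lines, used instead of `path`.
#' @param dialect Parsing dialect, see [parse_rule()].
#' @return A [boolean_network()].
#' @export
read_boolean_network <- function(path, text = NULL,
                                 dialect = c("standard", "grouped")) {
  dialect <- match.arg(dialect)
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0L && grepl("^targets[,\t ]+factors$", lines[1L],
                                  ignore.case = TRUE)) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) stop("no rules found")
  parts <- regmatches(lines, regexpr(",", lines), invert = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) {
    stop("malformed line(s): ", paste(lines[bad], collapse = "; "))
  }
  targets <- trimws(vapply(parts, `[[`, character(1), 1L))
  factors <- trimws(vapply(parts, `[[`, character(1), 2L))
  boolean_network(setNames(as.list(factors), targets), dialect = dialect)
}

#' Write a Boolean network to a "targets, factors" file
#'
#' Rules are written in canonical fully parenthesized form, so the file
#' re-reads identically under either dialect.
#'
#' @param network A [boolean_network()].
#' @param path Output file; if `NULL` the lines are returned.
#' @return The lines, invisibly when written to a file.
#' @export
write_boolean_network <- function(network, path = NULL) {
  stopifnot(inherits(network, "boolean_network"))
  lines <- c("targets, factors",
             vapply(network$nodes, function(n) {
               paste0(n, ", ", serialize_rule(network$rules[[n]]))
             }, character(1)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Export a profile table to CSV
#'
#' One column per node, plus `multiplicity`, `category` and
#' `nonbiological` (and `cluster` when labels are supplied).
#'
#' @param table A `profile_table`.
#' @param path Output file; if `NULL` the data frame is returned.
#' @param cluster_labels Optional integer labels from
#'   [cluster_attractors()].
#' @return The data frame, invisibly when written to a file.
#' @export
write_profile_csv <- function(table, path = NULL, cluster_labels = NULL) {
  stopifnot(inherits(table, "profile_table"))
  df <- as.data.frame(table$profiles)
  df$multiplicity <- table$multiplicity
  df$category <- table$category
  df$nonbiological <- table$nonbiological
  if (!is.null(cluster_labels)) df$cluster <- cluster_labels
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
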