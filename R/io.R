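# Readers and writers for the plain-text formats the package consumes:
# weighted edge lists, reference pair sets, complex catalogs,
# genetic-interaction profile matrices and ranked edge files.
# Tab- or comma-delimited dialect is auto-detected from the first line.

detect_delim <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) return("\t")
  if (grepl("\t", first)) "\t" else ","
}

read_delim_chr <- function(path, delim) {
  # ragged rows surface as NA fields and are reported with line numbers
  # downstream, so readr's own parse warning is redundant here
  suppressWarnings(readr::read_delim(
    path, delim = delim, col_names = FALSE, col_types = readr::cols(.default = "c"),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  ))
}

#' Read a weighted protein-interaction edge list
#'
#' Reads a delimited text file with at least three columns
#' (`protein_a`, `protein_b`, `score`), auto-detecting tab or comma
#' delimiters and an optional header line (recognised by a non-numeric
#' third field). Self-loops are silently dropped, duplicate records of
#' the same unordered pair keep the maximum score, and symmetry is
#' implicit in the unordered-pair representation.
#'
#' Confidence scores are expected in `[0, 1]`. Scores on another scale
#' (e.g. raw log-odds) can be mapped onto the unit interval with
#' `scale = TRUE`, which applies [min_max_scale()] before the cutoff
#' filter. Edges whose (scaled) score falls below `min_score`, or is not
#' strictly positive, are discarded; proteins left without any edge are
#' thereby dropped.
#'
#' @param path Path to a delimited text file.
#' @param min_score Minimum confidence score to retain an edge, in
#'   `[0, 1]`. AP-MS score sets are commonly truncated at a fixed cutoff
#'   (for example 0.1 for bootstrap-scored networks) so that only
#'   high-confidence interactions enter the model.
#' @param scale If `TRUE`, min-max scale the scores onto `[0, 1]` before
#'   filtering. If `FALSE` (default), scores outside `[0, 1]` are an error.
#' @return A tibble with columns `protein_a`, `protein_b`, `score` in
#'   canonical order (`protein_a < protein_b`, sorted).
#' @seealso [as_weighted_network()], [fit_binm()]
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB\t0.8", "B\tA\t0.8", "A\tC\t0.3"), f)
#' read_weighted_edges(f)
#' @export
read_weighted_edges <- function(path, min_score = 0, scale = FALSE) {
  if (!is.numeric(min_score) || min_score < 0 || min_score > 1) {
    abort("`min_score` must lie in [0, 1]", class = "binm_validation_error")
  }
  delim <- detect_delim(path)
  df <- read_delim_chr(path, delim)
  if (nrow(df) == 0) {
    abort("no edges survive cutoff: file is empty", class = "binm_parse_error")
  }
  if (ncol(df) < 3) {
    abort(sprintf("expected >= 3 columns (protein_a, protein_b, score), found %d", ncol(df)),
          class = "binm_parse_error")
  }
  has_header <- is.na(suppressWarnings(as.numeric(df[[3]][1])))
  if (has_header) df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) {
    abort("no edges survive cutoff: file holds a header but no data rows",
          class = "binm_parse_error")
  }
  line_no <- seq_len(nrow(df)) + as.integer(has_header)

  missing_field <- is.na(df[[1]]) | is.na(df[[2]]) | is.na(df[[3]])
  if (any(missing_field)) {
    abort(sprintf("malformed row at line %d: missing column", line_no[which(missing_field)[1]]),
          class = "binm_parse_error")
  }
  score <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(score)) {
    abort(sprintf("malformed row at line %d: non-numeric score '%s'",
                  line_no[which(is.na(score))[1]], df[[3]][which(is.na(score))[1]]),
          class = "binm_parse_error")
  }

  edges <- tibble(
    protein_a = trimws(df[[1]]),
    protein_b = trimws(df[[2]]),
    score = score
  )
  if (scale) {
    edges$score <- min_max_scale(edges$score)
  } else if (any(edges$score < 0 | edges$score > 1)) {
    bad <- which(edges$score < 0 | edges$score > 1)[1]
    abort(sprintf("score %.6g at line %d outside [0, 1]; use scale = TRUE for raw scores",
                  edges$score[bad], line_no[bad]),
          class = "binm_validation_error")
  }

  edges <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
  edges <- edges[edges$score >= min_score & edges$score > 0, , drop = FALSE]
  if (nrow(edges) == 0) {
    abort("no edges survive cutoff", class = "binm_validation_error")
  }
  edges <- canonicalize_pairs(edges)
  edges <- dplyr::summarise(
    dplyr::group_by(edges, .data$protein_a, .data$protein_b),
    score = max(.data$score), .groups = "drop"
  )
  dplyr::arrange(edges, .data$protein_a, .data$protein_b)
}

#' Scale scores linearly onto the unit interval
#'
#' Maps `[min(x), max(x)]` linearly onto `[0, 1]`. A constant input maps
#' to all ones: with no spread, every edge is treated as equally
#' most-confident rather than discarded.
#'
#' @param raw_scores Nonempty numeric vector.
#' @return Numeric vector of the same length, in `[0, 1]`, order-preserving.
#' @examples
#' min_max_scale(c(0, 5, 10))
#' @export
min_max_scale <- function(raw_scores) {
  if (length(raw_scores) == 0) {
    abort("cannot scale an empty score vector", class = "binm_validation_error")
  }
  if (anyNA(raw_scores)) {
    abort("scores contain missing values", class = "binm_validation_error")
  }
  rng <- range(raw_scores)
  if (rng[1] == rng[2]) {
    return(rep(1, length(raw_scores)))
  }
  (raw_scores - rng[1]) / (rng[2] - rng[1])
}

#' Read a reference set of unordered protein pairs
#'
#' Reads a two-column delimited file of protein identifier pairs, such as
#' an export of binary interactions from a curated database or a
#' two-hybrid screen. Pairs are unordered ((a, b) and (b, a) collapse),
#' duplicates are removed, and self-pairs are dropped with a message.
#'
#' @param path Path to a two-column delimited text file (no header).
#' @return A tibble with columns `protein_a`, `protein_b` in canonical
#'   order; zero rows for an empty file.
#' @export
read_reference_pairs <- function(path) {
  delim <- detect_delim(path)
  df <- read_delim_chr(path, delim)
  if (nrow(df) == 0) {
    return(tibble(protein_a = character(), protein_b = character()))
  }
  if (ncol(df) < 2) {
    abort("expected two columns of protein identifiers", class = "binm_parse_error")
  }
  if (any(is.na(df[[1]]) | is.na(df[[2]]))) {
    abort(sprintf("missing identifier at line %d", which(is.na(df[[1]]) | is.na(df[[2]]))[1]),
          class = "binm_parse_error")
  }
  out <- tibble(protein_a = trimws(df[[1]]), protein_b = trimws(df[[2]]))
  n_self <- sum(out$protein_a == out$protein_b)
  if (n_self > 0) {
    inform(sprintf("dropped %d self-pair(s)", n_self))
  }
  as_pair_tbl(out)
}

#' Read a protein-complex catalog
#'
#' One complex per line: a complex name followed by tab-separated member
#' identifiers. Complexes with fewer than two distinct members are
#' dropped with a message; duplicate complex names are an error.
#'
#' @param path Path to the catalog file.
#' @return A long tibble with columns `complex`, `member` (one row per
#'   membership).
#' @export
read_complexes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(complex = character(), member = character()))
  }
  parts <- strsplit(lines, "[\t ]+")
  names_ <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    abort(sprintf("duplicate complex name '%s'", names_[duplicated(names_)][1]),
          class = "binm_parse_error")
  }
  members <- lapply(parts, function(p) unique(p[-1]))
  sizes <- lengths(members)
  n_small <- sum(sizes < 2)
  if (n_small > 0) {
    inform(sprintf("dropped %d complex(es) with fewer than 2 members", n_small))
  }
  keep <- sizes >= 2
  tibble(
    complex = rep(names_[keep], sizes[keep]),
    member = unlist(members[keep])
  )
}

#' Read a genetic-interaction profile matrix
#'
#' Tab-separated matrix with a header row of condition identifiers and
#' one row per protein (row label first). The literal string `NA` marks
#' a missing measurement. The header may or may not carry a leading
#' label for the protein column.
#'
#' @param path Path to the profile matrix.
#' @return A tibble whose first column `protein` holds row labels and
#'   whose remaining numeric columns are named by condition.
#' @export
read_profiles <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    abort("profile file needs a header row and at least one data row",
          class = "binm_parse_error")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1] + 1
    abort(sprintf("ragged row at line %d: %d fields where %d expected",
                  bad, widths[bad - 1], widths[1]),
          class = "binm_parse_error")
  }
  n_cond <- widths[1] - 1
  if (n_cond < 1) {
    abort("profile rows need a protein label plus at least one value",
          class = "binm_parse_error")
  }
  conditions <- if (length(header) == n_cond) header else header[-1]
  if (length(conditions) != n_cond) {
    abort(sprintf("ragged row at line %d: header names %d conditions but rows carry %d values",
                  2, length(conditions), n_cond),
          class = "binm_parse_error")
  }
  proteins <- vapply(rows, `[[`, character(1), 1)
  vals <- vapply(rows, function(r) {
    v <- r[-1]
    v[v == "NA"] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v))) {
      abort(sprintf("non-numeric profile value '%s'", v[which(is.na(num) & !is.na(v))[1]]),
            class = "binm_parse_error")
    }
    num
  }, numeric(n_cond))
  vals <- matrix(vals, ncol = n_cond, byrow = TRUE,
                 dimnames = list(NULL, conditions))
  dplyr::bind_cols(tibble(protein = proteins), as_tibble(vals))
}

#' Write a ranked edge list to a TSV file
#'
#' Writes `rank`, `protein_a`, `protein_b`, `binm_score`, `obs_score`
#' with a header row. Scores are serialized at full double precision so
#' a write/read round-trip reproduces the ranking exactly.
#'
#' @param ranked A nonempty ranking as returned by [rank_edges()].
#' @param path Output path.
#' @return The input, invisibly.
#' @seealso [read_ranked_edges()]
#' @export
write_ranked_edges <- function(ranked, path) {
  cols <- c("rank", "protein_a", "protein_b", "binm_score", "obs_score")
  if (!is.data.frame(ranked) || nrow(ranked) == 0) {
    abort("ranking is empty; nothing to write", class = "binm_validation_error")
  }
  if (!all(cols %in% names(ranked))) {
    abort(sprintf("ranking must carry columns %s", paste(cols, collapse = ", ")),
          class = "binm_validation_error")
  }
  readr::write_tsv(ranked[, cols], path, progress = FALSE)
  invisible(ranked)
}

#' Read a ranked edge list written by [write_ranked_edges()]
#'
#' @param path Path to a ranked-edge TSV.
#' @return A tibble with columns `rank`, `protein_a`, `protein_b`,
#'   `binm_score`, `obs_score`, in file order.
#' @export
read_ranked_edges <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      rank = readr::col_integer(),
      protein_a = readr::col_character(),
      protein_b = readr::col_character(),
      binm_score = readr::col_double(),
      obs_score = readr::col_double()
    ),
    progress = FALSE
  )
}
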