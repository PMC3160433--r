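#' Construct a taxon distance matrix
#'
#' Container for symmetric pairwise distances with an explicit record of
#' pairs that carry no data (e.g. strain pairs never co-sampled in any
#' polychromatic quartet).
#'
#' @param values Symmetric numeric matrix with zero diagonal.
#' @param taxa Taxon identifiers; defaults to the matrix dimnames.
#' @param missing Logical matrix marking pairs without data (default none).
#' @return An object of class `taxon_dist`.
#' @export
taxon_dist <- function(values, taxa = rownames(values), missing = NULL) {
  values <- as.matrix(values)
  if (is.null(taxa)) stopf("taxa must be supplied or present as dimnames")
  if (nrow(values) != ncol(values)) stopf("distance matrix must be square")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12) {
    stopf("distance matrix must be symmetric")
  }
  if (any(abs(diag(values)) > 1e-12, na.rm = TRUE)) {
    stopf("distance matrix must have a zero diagonal")
  }
  dimnames(values) <- list(taxa, taxa)
  if (is.null(missing)) missing <- is.na(values) & !diag(TRUE, nrow(values))
  diag(missing) <- FALSE
  dimnames(missing) <- dimnames(values)
  structure(list(taxa = taxa, values = values, missing = missing),
            class = "taxon_dist")
}

#' @export
as.matrix.taxon_dist <- function(x, ...) x$values

#' @export
as.dist.taxon_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' @export
print.taxon_dist <- function(x, ...) {
  cat(sprintf("<taxon_dist> %d taxa, %d missing pair(s)\n",
              length(x$taxa), sum(x$missing[upper.tri(x$missing)])))
  invisible(x)
}

#' Write a distance matrix as a Nexus file
#'
#' Emits `TAXA` and `DISTANCES` blocks consumable by split-network software
#' (SplitsTree's Neighbor-Net and kin). The matrix must be complete; impute
#' missing pairs first (see [pq_distance()]).
#'
#' @param dist A [taxon_dist()] (or plain symmetric matrix).
#' @param path Output file path.
#' @param digits Decimal digits written (default 6; round-trips to 1e-6).
#' @return `path`, invisibly.
#' @export
write_nexus_distances <- function(dist, path, digits = 6) {
  if (!inherits(dist, "taxon_dist")) dist <- taxon_dist(dist)
  if (any(dist$missing)) {
    stopf("distance matrix has %d pair(s) without data; impute before export",
          sum(dist$missing[upper.tri(dist$missing)]))
  }
  n <- length(dist$taxa)
  lab <- gsub("[^A-Za-z0-9_.]", "_", dist$taxa)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("", con)
  writeLines("BEGIN TAXA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d;", n), con)
  writeLines("  TAXLABELS", con)
  writeLines(paste0("    ", lab), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  writeLines("", con)
  writeLines("BEGIN DISTANCES;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d;", n), con)
  writeLines("  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;", con)
  writeLines("  MATRIX", con)
  fmt <- paste0("%.", digits, "f")
  for (i in seq_len(n)) {
    writeLines(paste0("    ", lab[i], " ",
                      paste(sprintf(fmt, dist$values[i, ]), collapse = " ")), con)
  }
  writeLines("  ;", con)
  writeLines("END;", con)
  invisible(path)
}

#' Read a Nexus distance matrix written by [write_nexus_distances()]
#'
#' @param path Nexus file with `TAXA` and `DISTANCES` blocks
#'   (`TRIANGLE=BOTH`, labelled rows).
#' @return A [taxon_dist()].
#' @export
read_nexus_distances <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("#NEXUS", lines[1], ignore.case = TRUE)) {
    stopf("'%s' is not a Nexus file", path)
  }
  up <- toupper(trimws(lines))
  b <- which(up == "BEGIN DISTANCES;")
  if (length(b) != 1) stopf("'%s' lacks a DISTANCES block", path)
  m_start <- b + which(up[(b + 1):length(up)] == "MATRIX")[1]
  m_end <- m_start + which(trimws(lines[(m_start + 1):length(lines)]) == ";")[1]
  rows <- trimws(lines[(m_start + 1):(m_end - 1)])
  rows <- rows[rows != ""]
  parts <- strsplit(rows, "[ \t]+")
  taxa <- vapply(parts, `[[`, character(1), 1)
  values <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(length(parts))))
  taxon_dist(values, taxa)
}
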