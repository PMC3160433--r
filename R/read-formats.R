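#' Read a phylogenetic forest from Newick files
#'
#' Reads one or more Newick files, each containing one or more trees (one
#' Newick record per line or several records per file), and returns the
#' forest as a list of `phylo` objects. Trees are interpreted as unrooted:
#' a basal bifurcation produced by the Newick root is collapsed so the root
#' becomes an unlabeled internal node. Internal-node labels are read as
#' bootstrap supports on the subtending edge; labels that are proportions
#' (all values at most 1) are rescaled to percent.
#'
#' @param paths Character vector of Newick file paths.
#' @param rescale_proportions Rescale supports to percent when every numeric
#'   support in a tree lies in `[0, 1]`. Default `TRUE`.
#' @return An object of class `gene_forest` (a named list of `phylo` trees;
#'   also a `multiPhylo`). Names are `<file stem>` for single-tree files and
#'   `<file stem>_<k>` otherwise, unless the file names its trees.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A,B)95,(C,D));", tf)
#' forest <- read_forest(tf)
#' ape::Ntip(forest[[1]])
#' @export
read_forest <- function(paths, rescale_proportions = TRUE) {
  trees <- list()
  for (path in paths) {
    if (!file.exists(path)) stopf("forest file not found: %s", path)
    parsed <- tryCatch(
      ape::read.tree(path),
      error = function(e) {
        stopf("malformed Newick in '%s': %s", path, conditionMessage(e))
      }
    )
    if (is.null(parsed)) stopf("malformed Newick in '%s'", path)
    if (is_phylo(parsed)) parsed <- list(parsed)
    stem <- sub("\\.[^.]*$", "", basename(path))
    nm <- names(parsed)
    if (is.null(nm) || any(nm == "")) {
      nm <- if (length(parsed) == 1L) stem else paste0(stem, "_", seq_along(parsed))
    }
    for (k in seq_along(parsed)) {
      tr <- validate_gene_tree(parsed[[k]], path, k,
                               rescale_proportions = rescale_proportions)
      trees[[nm[k]]] <- tr
    }
  }
  structure(trees, class = c("gene_forest", "multiPhylo"))
}

# In a rooted binary tree the two root-child edges carry the same
# bipartition, and support conventions label only one of them. Copy that
# label to both children before unrooting, so ape::unroot (which parks one
# of the labels on the basal node, where the child-label convention never
# looks) cannot lose it.
mirror_root_support <- function(tree) {
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  if (length(kids) != 2 || is.null(tree$node.label)) return(tree)
  inner <- kids[kids > n_tip] - n_tip
  if (length(inner) != 2) return(tree)
  lab <- tree$node.label[inner]
  filled <- !is.na(lab) & lab != ""
  if (sum(filled) == 1) tree$node.label[inner[!filled]] <- lab[filled]
  tree
}

# Validate one tree: unique leaves, supports in range, unrooted form.
validate_gene_tree <- function(tree, path, index, rescale_proportions = TRUE) {
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stopf("duplicate leaf name(s) in '%s' record %d: %s",
          path, index, paste(dup, collapse = ", "))
  }
  if (ape::Ntip(tree) >= 4 && ape::is.rooted(tree)) {
    tree <- mirror_root_support(tree)
    tree <- ape::unroot(tree)
  }
  sup <- node_supports(tree)
  obs <- sup[!is.na(sup)]
  if (length(obs) > 0) {
    if (rescale_proportions && all(obs <= 1)) {
      sup <- sup * 100
      tree$node.label <- ifelse(is.na(sup), tree$node.label, as.character(sup))
    }
    obs <- sup[!is.na(sup)]
    if (any(obs < 0 | obs > 100)) {
      stopf("support value outside [0, 100] in '%s' record %d", path, index)
    }
  }
  tree
}

#' Convert a list of trees into a gene forest
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @param tree_ids Optional character ids; defaults to existing names or
#'   `tree_1 ... tree_n`.
#' @return A `gene_forest`.
#' @export
as_gene_forest <- function(trees, tree_ids = NULL) {
  if (is_phylo(trees)) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(all(vapply(trees, is_phylo, logical(1))))
  ids <- tree_ids %||% names(trees) %||% paste0("tree_", seq_along(trees))
  names(trees) <- ids
  structure(trees, class = c("gene_forest", "multiPhylo"))
}

#' @export
print.gene_forest <- function(x, ...) {
  nt <- vapply(x, ape::Ntip, integer(1))
  cat(sprintf("<gene_forest> %d tree(s), %d-%d leaves\n",
              length(x), if (length(x)) min(nt) else 0L,
              if (length(x)) max(nt) else 0L))
  invisible(x)
}

.hit_columns <- c(
  "query", "subject", "identity_pct", "aln_length", "mismatches",
  "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore"
)

#' Read all-vs-all homology hits (BLAST tabular layout)
#'
#' Parses 12-column tab-separated similarity-search output (the standard
#' tabular layout: query, subject, percent identity, alignment length,
#' mismatches, gap opens, query/subject coordinates, e-value, bit score).
#' Self-hits (query equal to subject) are kept but flagged.
#'
#' @param path Path to a tab-separated hit table without header.
#' @return A tibble with the 12 standard columns plus a logical `self` flag.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("s1\ts2\t98.5\t120\t2\t0\t1\t120\t1\t120\t1e-50\t200", tf)
#' read_hits(tf)
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stopf("hit table not found: %s", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != 12L)
  if (length(bad) > 0) {
    stopf("hit table '%s': line %d has %d column(s), expected 12",
          path, bad[1], nf[bad[1]])
  }
  hits <- readr::read_tsv(
    path,
    col_names = .hit_columns,
    col_types = readr::cols(
      query = readr::col_character(),
      subject = readr::col_character(),
      identity_pct = readr::col_double(),
      aln_length = readr::col_integer(),
      mismatches = readr::col_integer(),
      gap_opens = readr::col_integer(),
      q_start = readr::col_integer(),
      q_end = readr::col_integer(),
      s_start = readr::col_integer(),
      s_end = readr::col_integer(),
      evalue = readr::col_double(),
      bitscore = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100, na.rm = TRUE)) {
    stopf("hit table '%s': identity outside [0, 100]", path)
  }
  if (any(hits$evalue < 0, na.rm = TRUE)) {
    stopf("hit table '%s': negative e-value", path)
  }
  dplyr::mutate(hits, self = .data$query == .data$subject)
}

#' Read and validate a per-sequence annotation table
#'
#' The table maps every sequence id to its genome, taxon class (`MGE`,
#' `EUK`, `ARC`, `BAC`, or `EC1`..`EC30` for individual E. coli strains),
#' host pathogenicity (`PATH`, `NON-PATH`, `OTH`), disease association
#' (`URI`, `HEM`, `GAS`, `OTH`, or `none`; non-`none` only for pathogenic
#' hosts) and a single-letter COG functional category (`X` when unknown).
#'
#' @param path Path to a tab-separated file with a header naming columns
#'   `sequence_id`, `genome_id`, `taxon_class`, `pathogenicity`, `disease`
#'   and optionally `cog_category` (missing column is filled with `"X"`).
#' @return A validated tibble, one row per sequence.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation table not found: %s", path)
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_annotations(ann)
}

#' Validate an in-memory annotation table
#'
#' @param ann A data frame with the columns documented in
#'   [read_annotations()].
#' @return The annotation tibble, with `cog_category` filled in.
#' @export
validate_annotations <- function(ann) {
  ann <- tibble::as_tibble(ann)
  need <- c("sequence_id", "genome_id", "taxon_class", "pathogenicity", "disease")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0) {
    stopf("annotation table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!"cog_category" %in% names(ann)) ann$cog_category <- "X"
  ann$cog_category[is.na(ann$cog_category)] <- "X"
  dup <- unique(ann$sequence_id[duplicated(ann$sequence_id)])
  if (length(dup) > 0) {
    stopf("duplicate sequence id(s): %s", paste(head(dup, 5), collapse = ", "))
  }
  check_tokens <- function(values, allowed, what) {
    bad <- unique(values[!values %in% allowed])
    if (length(bad) > 0) {
      stopf("unknown %s value(s): %s", what, paste(head(bad, 5), collapse = ", "))
    }
  }
  check_tokens(ann$taxon_class, .taxon_classes, "taxon_class")
  check_tokens(ann$pathogenicity, .pathogenicity_levels, "pathogenicity")
  check_tokens(ann$disease, .disease_levels, "disease")
  check_tokens(ann$cog_category, .cog_letters, "cog_category")
  offending <- ann$sequence_id[ann$disease != "none" & ann$pathogenicity != "PATH"]
  if (length(offending) > 0) {
    stopf("disease set for non-PATH sequence(s): %s",
          paste(head(offending, 5), collapse = ", "))
  }
  ann
}

# Leaf -> annotation field lookup with an informative error on unmapped leaves.
annotation_lookup <- function(leaves, ann, field) {
  idx <- match(leaves, ann$sequence_id)
  if (anyNA(idx)) {
    stopf("leaf/sequence id(s) absent from annotations: %s",
          paste(head(leaves[is.na(idx)], 5), collapse = ", "))
  }
  setNames(ann[[field]][idx], leaves)
}

#' Write a homology hit table in the 12-column tabular layout
#'
#' @param hits Hit tibble (extra columns such as `self` are dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- hits[, .hit_columns]
  out$evalue <- formatC(out$evalue, format = "e", digits = 2)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write an annotation table
#'
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Write a forest as Newick
#'
#' One Newick record per tree; tree ids become tree names in the file.
#'
#' @param forest A `gene_forest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forest <- function(forest, path) {
  forest <- as_gene_forest(forest)
  ape::write.tree(structure(unclass(forest), class = "multiPhylo"),
                  file = path, tree.names = TRUE)
  invisible(path)
}
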