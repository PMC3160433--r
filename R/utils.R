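# Internal helpers shared across modules.

# Canonical unordered pair: two character vectors -> sorted key columns.
pair_sort <- function(a, b) {
  swap <- a > b
  tibble::tibble(
    first  = ifelse(swap, b, a),
    second = ifelse(swap, a, b)
  )
}

# Controlled vocabularies for annotation tables.
.taxon_classes <- c("MGE", "EUK", "ARC", "BAC", paste0("EC", 1:30))
.pathogenicity_levels <- c("PATH", "NON-PATH", "OTH")
.disease_levels <- c("URI", "HEM", "GAS", "OTH", "none")
.cog_letters <- LETTERS

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

# Round half away from zero to `digits` — percentage tables print 30.5, not 30.4999.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_phylo <- function(x) inherits(x, "phylo")

# Parent lookup (node -> parent node id, 0 for root) from an ape edge matrix.
parent_vector <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

# Children lists indexed by node id.
children_list <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(n_node)))
}

# Internal-node supports as numeric, NA where absent/non-numeric.
node_supports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(lab))
}
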