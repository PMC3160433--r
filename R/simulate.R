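# Synthetic pangenome forests with a known ground truth. LGT is modelled as
# leaf-level prune-and-regraft on gene trees (the recipient's gene copy
# re-attaches next to the donor's), which is generative scaffolding for
# testing the detectors — the analysis methods themselves assume nothing
# about this mechanism.

#' Simulate a phylogenetic forest with known lateral transfers
#'
#' Draws one species tree over `n_strains` E. coli-like strains (plus
#' `n_outgroups` distant taxa) and derives each gene tree from it:
#' core trees keep every strain, shell trees keep a random subset of at
#' least `min_strains_shell`; a Poisson(`lgt_rate`) number of transfer
#' events per tree each move one recipient leaf next to its donor, with
#' same-pathogenicity donor/recipient pairs favoured by
#' `within_group_bias`; a fraction of events drops a mobile-element leaf
#' beside the recipient. Bootstrap supports are high (90-100) on edges
#' concordant with the species tree and mixed (`transfer_support`) on
#' discordant edges, so support-cutoff logic is exercised. Optional planted
#' modules create groups of trees with identical strain content, an MGE
#' leaf and only pathogenic strains, for module-detection tests.
#'
#' @param n_strains Number of strains (default 30, labelled `EC1..`).
#' @param n_outgroups Number of distant cellular taxa (default 4).
#' @param n_trees Number of gene trees (excluding planted modules).
#' @param core_fraction Fraction of trees carrying every strain
#'   (default 0.4, the regime of a bacterial pangenome's core).
#' @param lgt_rate Expected transfer events per tree (default 1).
#' @param within_group_bias Multiplier (>= 1) on the rate of transfers whose
#'   donor and recipient share pathogenicity status (default 1 = unbiased).
#' @param path_fraction Fraction of strains that are pathogenic
#'   (default 2/3).
#' @param mge_per_event Probability that a transfer event leaves a
#'   mobile-element leaf beside the recipient (default 0.2).
#' @param duplicate_rate Probability that a tree carries a duplicated
#'   strain copy (default 0.1).
#' @param og_inclusion Per-outgroup inclusion probability per tree
#'   (default 0.5).
#' @param min_strains_shell Minimum strains in a shell tree (default 4).
#' @param concordant_support,transfer_support Support ranges (percent) for
#'   species-tree-concordant and discordant internal edges.
#' @param planted_modules Optional list; each element
#'   `list(n_trees =, n_strains =)` plants one module group.
#' @param seed RNG seed; identical seed and configuration reproduce the
#'   output exactly.
#' @return List with `forest` (a `gene_forest`), `annotations` (tibble),
#'   `truth` (per-tree tibble: `tree_id`, `core`, `strains`, `n_lgt`,
#'   `module_id`, `events` list-column) and `species_tree`.
#' @export
simulate_forest <- function(n_strains = 30, n_outgroups = 4, n_trees = 100,
                            core_fraction = 0.4, lgt_rate = 1,
                            within_group_bias = 1, path_fraction = 2 / 3,
                            mge_per_event = 0.2, duplicate_rate = 0.1,
                            og_inclusion = 0.5, min_strains_shell = 4,
                            concordant_support = c(90, 100),
                            transfer_support = c(20, 100),
                            planted_modules = NULL, seed = NULL) {
  if (n_strains < 4) stopf("need at least 4 strains")
  if (core_fraction < 0 || core_fraction > 1) stopf("core_fraction must lie in [0, 1]")
  if (within_group_bias < 1) stopf("within_group_bias must be >= 1")
  if (lgt_rate < 0) stopf("lgt_rate must be non-negative")
  if (min_strains_shell < 4 || min_strains_shell >= n_strains) {
    stopf("min_strains_shell must lie in [4, n_strains)")
  }
  if (!is.null(seed)) set.seed(seed)

  strains <- paste0("EC", seq_len(n_strains))
  outgroups <- if (n_outgroups > 0) paste0("OG", seq_len(n_outgroups)) else character(0)
  n_path <- round(path_fraction * n_strains)
  path_strains <- sort(sample(strains, n_path))
  pathogenicity <- setNames(ifelse(strains %in% path_strains, "PATH", "NON-PATH"),
                            strains)
  disease <- setNames(rep("none", n_strains), strains)
  disease[path_strains] <- sample(c("URI", "HEM", "GAS", "OTH"),
                                  length(path_strains), replace = TRUE)

  species <- ape::rtree(n_strains, tip.label = strains)
  if (n_outgroups > 0) {
    og_part <- if (n_outgroups == 1) paste0(outgroups, ":1") else
      sub(";$", "", ape::write.tree(ape::rtree(n_outgroups, tip.label = outgroups)))
    species <- ape::read.tree(text = paste0(
      "(", sub(";$", "", ape::write.tree(species)), ":1,", og_part, ":1);"))
  }

  n_core <- round(core_fraction * n_trees)
  core_flag <- rep(FALSE, n_trees)
  if (n_core > 0) core_flag[sample.int(n_trees, n_core)] <- TRUE

  trees <- list()
  ann_rows <- list()
  truth_rows <- list()
  mge_counter <- 0L

  build_tree <- function(tree_id, keep_strains, keep_outgroups, is_core,
                         module_id = NA_character_, force_mge = FALSE) {
    keep <- c(keep_strains, keep_outgroups)
    gt <- ape::keep.tip(species, keep)
    # transfer events
    n_ev <- rpois(1, lgt_rate)
    events <- list()
    if (n_ev > 0 && length(keep_strains) >= 2) {
      for (e in seq_len(n_ev)) {
        pairs <- expand.grid(donor = keep_strains, recipient = keep_strains,
                             stringsAsFactors = FALSE)
        pairs <- pairs[pairs$donor != pairs$recipient, ]
        w <- ifelse(pathogenicity[pairs$donor] == pathogenicity[pairs$recipient],
                    within_group_bias, 1)
        k <- sample.int(nrow(pairs), 1, prob = w)
        donor <- pairs$donor[k]; recipient <- pairs$recipient[k]
        gt <- spr_leaf(gt, recipient, donor)
        events[[length(events) + 1L]] <- list(donor = donor, recipient = recipient)
        if (runif(1) < mge_per_event || (force_mge && e == 1)) {
          mge_counter <<- mge_counter + 1L
          gt <- attach_sister(gt, recipient, paste0("MGE", mge_counter))
        }
      }
    }
    if (force_mge && length(events) == 0) {
      mge_counter <<- mge_counter + 1L
      gt <- attach_sister(gt, sample(keep_strains, 1), paste0("MGE", mge_counter))
    }
    # occasional within-strain duplication
    if (runif(1) < duplicate_rate && length(keep_strains) > 0) {
      dup <- sample(keep_strains, 1)
      gt <- attach_sister(gt, dup, paste0(dup, ".2"))
    }
    gt <- assign_supports(gt, species, concordant_support, transfer_support)
    # rename leaves to sequence ids and collect annotations
    genomes <- sub("\\.2$", "", gt$tip.label)
    seq_ids <- paste0(tree_id, "|", gt$tip.label)
    taxon <- genomes
    taxon[grepl("^MGE", genomes)] <- "MGE"
    is_og <- grepl("^OG", genomes)
    taxon[is_og] <- c("BAC", "ARC", "EUK")[
      (as.integer(sub("OG", "", genomes[is_og])) - 1) %% 3 + 1]
    patho <- ifelse(grepl("^EC", genomes), pathogenicity[genomes], "OTH")
    dis <- ifelse(patho == "PATH", disease[genomes], "none")
    ann_rows[[length(ann_rows) + 1L]] <<- tibble::tibble(
      sequence_id = seq_ids, genome_id = genomes, taxon_class = taxon,
      pathogenicity = patho, disease = dis,
      cog_category = sample(c("L", "K", "T", "S", "X"), length(seq_ids),
                            replace = TRUE, prob = c(.2, .1, .1, .2, .4)))
    gt$tip.label <- seq_ids
    truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
      tree_id = tree_id, core = is_core,
      strains = paste(sort(keep_strains), collapse = ","),
      n_lgt = length(events), module_id = module_id,
      events = list(events))
    trees[[tree_id]] <<- gt
    invisible(NULL)
  }

  for (i in seq_len(n_trees)) {
    keep_strains <- if (core_flag[i]) strains else
      sort(sample(strains, sample(min_strains_shell:(n_strains - 1), 1)))
    keep_og <- outgroups[runif(length(outgroups)) < og_inclusion]
    build_tree(sprintf("t%04d", i), keep_strains, keep_og, core_flag[i])
  }

  if (!is.null(planted_modules)) {
    for (m in seq_along(planted_modules)) {
      mod_cfg <- planted_modules[[m]]
      k <- mod_cfg$n_trees %||% 2L
      n_ms <- mod_cfg$n_strains %||% 3L
      mod_strains <- sort(sample(path_strains, min(n_ms, length(path_strains))))
      for (j in seq_len(k)) {
        build_tree(sprintf("mod%d_t%d", m, j), mod_strains, character(0),
                   FALSE, module_id = sprintf("M%03d", m), force_mge = TRUE)
      }
    }
  }

  annotations <- validate_annotations(dplyr::bind_rows(ann_rows))
  list(forest = as_gene_forest(trees),
       annotations = annotations,
       truth = dplyr::bind_rows(truth_rows),
       species_tree = species)
}

# Prune-and-regraft of one leaf: `leaf` re-attaches as sister of `target`.
spr_leaf <- function(tree, leaf, target) {
  if (leaf == target || ape::Ntip(tree) < 3) return(tree)
  pruned <- ape::drop.tip(tree, leaf)
  attach_sister(pruned, target, leaf)
}

# Attach a new tip as sister of an existing tip, halfway down its edge.
attach_sister <- function(tree, target, new_label) {
  where <- match(target, tree$tip.label)
  if (is.null(tree$edge.length)) {
    return(suppressWarnings(phytools::bind.tip(tree, new_label, where = where)))
  }
  pe <- tree$edge.length[tree$edge[, 2] == where]
  phytools::bind.tip(tree, new_label, edge.length = pe / 2,
                     where = where, position = pe / 2)
}

# Supports: edges whose clan (as genome sets) matches a split of the species
# tree restricted to the same genomes draw from `conc`, others from `trans`.
assign_supports <- function(gene_tree, species, conc, trans) {
  n_tip <- ape::Ntip(gene_tree)
  if (gene_tree$Nnode < 1) return(gene_tree)
  genomes <- sub("\\.2$", "", gene_tree$tip.label)
  shared <- intersect(unique(genomes), species$tip.label)
  ref_splits <- character(0)
  if (length(shared) >= 4) {
    sp <- ape::keep.tip(species, shared)
    prep <- pq_prepare(sp, 0)
    ref_splits <- apply(prep$masks, 1, function(side) {
      split_key(sp$tip.label[side], sp$tip.label)
    })
  }
  prep_g <- pq_prepare(gene_tree, 0)
  child <- gene_tree$edge[gene_tree$edge[, 2] > n_tip, 2]
  labels <- rep(NA_character_, gene_tree$Nnode)
  if (length(child) > 0) {
    for (i in seq_along(child)) {
      clan <- unique(genomes[prep_g$masks[i, ]])
      rest <- unique(genomes[!prep_g$masks[i, ]])
      key <- split_key(intersect(clan, shared), shared)
      concordant <- length(intersect(clan, rest)) == 0 &&
        (key == "" || key %in% ref_splits)
      rng <- if (concordant) conc else trans
      labels[child[i] - n_tip] <-
        as.character(round(runif(1, rng[1], rng[2])))
    }
  }
  gene_tree$node.label <- labels
  gene_tree
}

# Canonical key of a bipartition of `universe`: the lexicographically
# smaller side, sorted and collapsed. Trivial splits key to "".
split_key <- function(side, universe) {
  side <- sort(side)
  other <- sort(setdiff(universe, side))
  if (length(side) <= 1 || length(other) <= 1) return("")
  a <- paste(side, collapse = ",")
  b <- paste(other, collapse = ",")
  if (a < b) a else b
}

#' Simulate an all-vs-all homology hit table with known families
#'
#' Emits BLAST-tabular-style hits for `n_families` planted families:
#' within-family hits (both directions, plus self-hits) with identities
#' drawn from the family's identity band and e-values far below the
#' clustering ceiling, plus optional spurious cross-family hits with
#' e-values above the ceiling. Families in the `recent` band (identity
#' exactly 100) always contain at least one cellular and one mobile-element
#' member, emulating candidate recent transfers.
#'
#' @param n_families Number of families (default 20).
#' @param size_range Family-size range (default `c(2, 6)`).
#' @param recent_fraction Fraction of families in the 100%-identity band
#'   (default 0.25); the rest draw identities from `background_band`.
#' @param background_band Identity band of ordinary families
#'   (default `c(70, 95)`).
#' @param genomes Genome pool; default 5 strains plus 2 mobile elements.
#' @param n_spurious Number of spurious cross-family hit pairs with
#'   e-values above `1e-20` (default 0).
#' @param seed RNG seed.
#' @return List with `hits` (12-column tibble plus `self`), `annotations`,
#'   and `truth` (`family_id`, `sequence_id`, `genome_id`, `band`).
#' @export
simulate_hits <- function(n_families = 20, size_range = c(2, 6),
                          recent_fraction = 0.25,
                          background_band = c(70, 95),
                          genomes = c(paste0("EC", 1:5), "MGE1", "MGE2"),
                          n_spurious = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cellular <- genomes[!grepl("^MGE", genomes)]
  mobile <- genomes[grepl("^MGE", genomes)]
  fam_band <- ifelse(seq_len(n_families) <= round(recent_fraction * n_families),
                     "recent", "background")
  truth <- list(); hit_rows <- list()
  for (f in seq_len(n_families)) {
    fid <- sprintf("F%03d", f)
    size <- sample(size_range[1]:size_range[2], 1)
    gs <- sample(genomes, size, replace = TRUE)
    if (fam_band[f] == "recent" && length(mobile) > 0) {
      gs[1] <- sample(cellular, 1)
      gs[2] <- sample(mobile, 1)
    }
    ids <- sprintf("%s_s%d", tolower(fid), seq_len(size))
    truth[[f]] <- tibble::tibble(family_id = fid, sequence_id = ids,
                                 genome_id = gs, band = fam_band[f])
    prs <- if (size >= 2) utils::combn(size, 2) else matrix(0, 2, 0)
    for (p in seq_len(ncol(prs))) {
      a <- prs[1, p]; b <- prs[2, p]
      ident <- if (fam_band[f] == "recent") 100 else
        round(runif(1, background_band[1], background_band[2]), 2)
      ev <- 10^runif(1, -60, -25)
      bs <- round(runif(1, 150, 500), 1)
      hit_rows[[length(hit_rows) + 1L]] <-
        hit_record(ids[a], ids[b], ident, ev, bs)
      hit_rows[[length(hit_rows) + 1L]] <-
        hit_record(ids[b], ids[a], ident, ev * runif(1, 0.5, 2), bs)
    }
    for (s in ids) {
      hit_rows[[length(hit_rows) + 1L]] <- hit_record(s, s, 100, 1e-180, 600)
    }
  }
  truth <- dplyr::bind_rows(truth)
  if (n_spurious > 0 && n_families >= 2) {
    for (k in seq_len(n_spurious)) {
      fams <- sample(n_families, 2)
      a <- sample(truth$sequence_id[truth$family_id == sprintf("F%03d", fams[1])], 1)
      b <- sample(truth$sequence_id[truth$family_id == sprintf("F%03d", fams[2])], 1)
      hit_rows[[length(hit_rows) + 1L]] <-
        hit_record(a, b, round(runif(1, 25, 40), 2), 10^runif(1, -15, -6),
                   round(runif(1, 40, 60), 1))
    }
  }
  hits <- dplyr::bind_rows(hit_rows)
  annotations <- validate_annotations(tibble::tibble(
    sequence_id = truth$sequence_id,
    genome_id = truth$genome_id,
    taxon_class = ifelse(grepl("^MGE", truth$genome_id), "MGE", truth$genome_id),
    pathogenicity = "OTH", disease = "none",
    cog_category = sample(c("L", "K", "S", "X"), nrow(truth), replace = TRUE,
                          prob = c(.3, .1, .2, .4))))
  list(hits = hits, annotations = annotations, truth = truth)
}

hit_record <- function(q, s, ident, ev, bs) {
  tibble::tibble(query = q, subject = s, identity_pct = ident,
                 aln_length = 300L, mismatches = 10L, gap_opens = 0L,
                 q_start = 1L, q_end = 300L, s_start = 1L, s_end = 300L,
                 evalue = ev, bitscore = bs, self = q == s)
}
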