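#' Seed of a mature miRNA
#'
#' Nucleotides 2-8 (1-based, inclusive) from the 5' end — the 7-nt region
#' whose identity defines isomiR groups within a family.
#'
#' @param sequence RNA string(s) of length >= 8.
#' @return Character vector of 7-nt seeds.
#' @export
mirna_seed <- function(sequence) {
  if (any(nchar(sequence) < 8)) stop("mature sequence shorter than 8 nt")
  substr(sequence, 2, 8)
}

.rna_submat <- function(match, mismatch) {
  m <- matrix(mismatch, 4, 4,
              dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
  diag(m) <- match
  m
}

#' Local alignment score and identity between two RNA sequences
#'
#' Optimal Smith-Waterman local alignment under affine gap penalties.
#' Identity is the number of matching columns divided by the number of
#' aligned columns; when no positive-scoring local alignment exists the
#' score is 0 with zero aligned columns.
#'
#' @param a,b non-empty RNA strings.
#' @param scoring numeric vector `(match, mismatch, gap_open, gap_extend)`;
#'   mismatch and gap penalties are negative.
#' @return list with `score`, `aligned_length` and `identity` (NA when the
#'   alignment is empty).
#' @export
local_align_score <- function(a, b, scoring = c(5, -4, -10, -4)) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::RNAString(a), Biostrings::RNAString(b),
    substitutionMatrix = .rna_submat(scoring[1], scoring[2]),
    gapOpening = abs(scoring[3]), gapExtension = abs(scoring[4]),
    type = "local"
  )
  sc <- max(Biostrings::score(aln), 0)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  if (sc == 0 && Biostrings::nmatch(aln) == 0) cols <- 0L
  list(score = sc, aligned_length = cols,
       identity = if (cols > 0) Biostrings::nmatch(aln) / cols else NA_real_)
}

# Vectorized local alignments of a set of sequences against one subject.
# Returns data.frame(score, cols, identity), one row per pattern.
.local_align_set <- function(patterns, subject, scoring = c(5, -4, -10, -4)) {
  if (!methods::is(patterns, "RNAStringSet")) {
    patterns <- Biostrings::RNAStringSet(patterns)
  }
  aln <- Biostrings::pairwiseAlignment(
    patterns, Biostrings::RNAString(subject),
    substitutionMatrix = .rna_submat(scoring[1], scoring[2]),
    gapOpening = abs(scoring[3]), gapExtension = abs(scoring[4]),
    type = "local"
  )
  sc <- pmax(Biostrings::score(aln), 0)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  nm <- Biostrings::nmatch(aln)
  cols[sc == 0 & nm == 0] <- 0L
  data.frame(score = sc, cols = cols,
             identity = ifelse(cols > 0, nm / cols, NA_real_))
}

#' Group mature miRNAs into families by all-against-all similarity
#'
#' Two matures are linked when their optimal local alignment reaches
#' `min_identity` over at least `min_cols` aligned columns; families are
#' the single-linkage (connected) components of the resulting graph over
#' all sequence pairs. Family ids are the lexicographically smallest member
#' id, so the assignment is invariant to input order.
#'
#' @param matures data.frame with columns `id`, `species`, `sequence`
#'   (RNA alphabet, >= 16 nt).
#' @param min_identity minimum identity fraction on the local alignment
#'   (default 0.75).
#' @param min_cols minimum aligned columns (default 14).
#' @param scoring alignment scoring vector, see [local_align_score()].
#' @return `matures` with an added `family_id` column.
#' @export
build_families <- function(matures, min_identity = 0.75, min_cols = 14,
                           scoring = c(5, -4, -10, -4)) {
  stopifnot(all(c("id", "species", "sequence") %in% names(matures)))
  if (nrow(matures) == 0) stop("no mature miRNAs")
  if (anyDuplicated(matures$id)) stop("duplicate mature ids")
  # identical sequences are trivially linked; align unique sequences only
  useq <- sort(unique(matures$sequence))
  nu <- length(useq)
  uset <- Biostrings::RNAStringSet(useq)
  edges <- NULL
  if (nu > 1) {
    edge_list <- lapply(2:nu, function(j) {
      hits <- .local_align_set(uset[seq_len(j - 1)], useq[j], scoring)
      ok <- which(!is.na(hits$identity) & hits$identity >= min_identity &
                    hits$cols >= min_cols)
      if (length(ok) > 0) cbind(ok, j) else NULL
    })
    edges <- do.call(rbind, edge_list)
  }
  g <- igraph::make_empty_graph(n = nu, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership
  seq_comp <- comp[match(matures$sequence, useq)]
  fam_id <- vapply(split(matures$id, seq_comp), function(ids) min(ids), "")
  matures$family_id <- unname(fam_id[as.character(seq_comp)])
  matures
}

#' Assign isomiR groups (miRNA genes) within families
#'
#' Matures in the same family sharing an identical 2-8 seed are isomiRs of
#' one miRNA gene. A gene is flagged `variable` when it carries two or more
#' distinct mature sequences, pooling variants within and between species.
#'
#' @param matures data.frame with `id`, `species`, `sequence`, `family_id`
#'   (output of [build_families()]).
#' @return `matures` with added columns `seed`, `gene_id` (lexicographically
#'   smallest member id of the family-seed group) and `variable`.
#' @export
assign_isomirs <- function(matures) {
  stopifnot("family_id" %in% names(matures))
  matures$seed <- mirna_seed(matures$sequence)
  key <- paste(matures$family_id, matures$seed, sep = "\r")
  gene_id <- vapply(split(matures$id, key), min, "")
  matures$gene_id <- unname(gene_id[key])
  nvar <- vapply(split(matures$sequence, key),
                 function(s) length(unique(s)), 0L)
  matures$variable <- unname(nvar[key] >= 2L)
  matures
}

#' Classify phylogenetic conservation of miRNA genes
#'
#' A gene present in every tip of the species tree is `conserved`; a gene
#' present in exactly one species is `species-specific`; everything else is
#' `non-conserved`. The three classes partition the genes.
#'
#' @param matures data.frame with `gene_id` and `species` columns.
#' @param tree species tree (`phylo`); every species must be a tip.
#' @return data.frame with one row per gene: `gene_id`, `n_species`,
#'   `species` (comma-separated, sorted) and `class`.
#' @export
classify_conservation <- function(matures, tree) {
  validate_species_tree(tree)
  unknown <- setdiff(unique(matures$species), tree$tip.label)
  if (length(unknown) > 0) {
    stop("species not on the tree: ", paste(unknown, collapse = ", "))
  }
  sp <- lapply(split(matures$species, matures$gene_id),
               function(s) sort(unique(s)))
  n_tips <- length(tree$tip.label)
  n_sp <- lengths(sp)
  cls <- ifelse(n_sp == n_tips, "conserved",
                ifelse(n_sp == 1, "species-specific", "non-conserved"))
  data.frame(
    gene_id = names(sp),
    n_species = unname(n_sp),
    species = unname(vapply(sp, paste, "", collapse = ",")),
    class = unname(cls),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Annotate miRNA genes as known or novel against a reference set
#'
#' A gene is `known` when any of its member matures aligns to any reference
#' mature with identity at least `min_identity` computed over the full
#' length of the shorter sequence (matches / shorter length), mirroring a
#' similarity search against a curated mature-miRNA database.
#'
#' @param matures data.frame with `gene_id` and `sequence`.
#' @param reference named character vector of reference mature sequences
#'   (RNA alphabet), non-empty.
#' @param min_identity threshold, default 0.9 (strict `>=`).
#' @return data.frame `gene_id`, `known` (logical).
#' @export
annotate_known <- function(matures, reference, min_identity = 0.9) {
  if (length(reference) == 0) stop("empty reference set")
  useq <- unique(matures$sequence)
  refset <- Biostrings::RNAStringSet(unname(reference))
  known_seq <- vapply(useq, function(s) {
    hits <- Biostrings::pairwiseAlignment(
      refset, Biostrings::RNAString(s),
      substitutionMatrix = .rna_submat(5, -4),
      gapOpening = 10, gapExtension = 4, type = "local"
    )
    frac <- Biostrings::nmatch(hits) /
      pmin(nchar(as.character(reference)), nchar(s))
    any(frac >= min_identity)
  }, TRUE)
  names(known_seq) <- useq
  gk <- vapply(split(matures$sequence, matures$gene_id),
               function(s) any(known_seq[s]), TRUE)
  data.frame(gene_id = names(gk), known = unname(gk),
             stringsAsFactors = FALSE)
}

# Human-readable branch name: tip label for terminal branches, node label
# (or "n<number>") for internal ones; "root" for the root itself.
branch_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  vapply(node, function(nd) {
    if (nd <= n_tip) return(tree$tip.label[nd])
    if (nd == root) return("root")
    if (!is.null(tree$node.label) && nzchar(tree$node.label[nd - n_tip])) {
      return(tree$node.label[nd - n_tip])
    }
    paste0("n", nd)
  }, "")
}

#' Dollo parsimony gain/loss history of a presence/absence character
#'
#' Under Dollo parsimony a character is gained exactly once and may be lost
#' any number of times. The gain is placed on the branch above the most
#' recent common ancestor of the present tips (placing it higher can only
#' add losses), and losses are the maximal subtrees below the gain that
#' contain no present tip. The optimum is unique and minimises gains plus
#' losses under the single-gain constraint.
#'
#' @param tree rooted binary `phylo` with tip labels.
#' @param presence named logical vector over all tips.
#' @return list with `gain_branch` (branch label; `"root"` when the gain
#'   predates the root), `loss_branches` (character vector of branch
#'   labels) and `n_events` (1 + number of losses).
#' @export
dollo_gain_loss <- function(tree, presence) {
  validate_species_tree(tree)
  if (!all(tree$tip.label %in% names(presence))) {
    stop("presence must be named for every tip")
  }
  pres <- presence[tree$tip.label]
  if (!any(pres)) stop("character absent from all tips: no gain to place")
  n_tip <- length(tree$tip.label)
  present_tips <- which(pres)
  gain_node <- if (length(present_tips) == 1) present_tips else {
    ape::getMRCA(tree, present_tips)
  }
  children <- split(tree$edge[, 2], tree$edge[, 1])
  # tips present below each node
  n_present <- integer(max(tree$edge))
  n_present[seq_len(n_tip)] <- as.integer(pres)
  for (nd in rev(sort(unique(tree$edge[, 1])))) {
    n_present[nd] <- sum(n_present[children[[as.character(nd)]]])
  }
  losses <- integer(0)
  if (gain_node > n_tip) {
    stack <- children[[as.character(gain_node)]]
    while (length(stack) > 0) {
      nd <- stack[1]; stack <- stack[-1]
      if (n_present[nd] == 0) {
        losses <- c(losses, nd)          # maximal empty subtree: one loss
      } else if (nd > n_tip) {
        stack <- c(stack, children[[as.character(nd)]])
      }
    }
  }
  list(
    gain_branch = unname(branch_label(tree, unname(gain_node))),
    loss_branches = unname(branch_label(tree, losses)),
    n_events = 1L + length(losses)
  )
}

#' Cross-tabulate sequence variability by conservation class
#'
#' Builds the 2x2 table of conserved vs species-specific genes against
#' variable (>= 2 isomiRs) vs invariant, with row percentages of variable
#' genes to one decimal. Classes with zero genes report `NA` rather than 0.
#'
#' @param classes data.frame from [classify_conservation()].
#' @param matures data.frame with `gene_id` and `variable` (from
#'   [assign_isomirs()]).
#' @return list with `table` (2x2 integer matrix, rows = class, cols =
#'   variable/invariant), `percent_variable` (named, 1 decimal) and the
#'   chi-square inputs.
#' @export
variability_table <- function(classes, matures) {
  gene_var <- vapply(split(matures$variable, matures$gene_id), any, TRUE)
  cls <- classes$class[match(names(gene_var), classes$gene_id)]
  tab <- matrix(0L, 2, 2,
                dimnames = list(c("conserved", "species-specific"),
                                c("variable", "invariant")))
  for (cl in rownames(tab)) {
    v <- gene_var[which(cls == cl)]
    tab[cl, "variable"] <- sum(v)
    tab[cl, "invariant"] <- sum(!v)
  }
  pct <- ifelse(rowSums(tab) > 0,
                round(100 * tab[, "variable"] / rowSums(tab), 1), NA_real_)
  list(table = tab, percent_variable = pct)
}
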