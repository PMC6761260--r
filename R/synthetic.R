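#' Fixed eight-species study tree
#'
#' A rooted, strictly bifurcating eight-tip phylogeny with an African
#' five-species clade (Mzeb, Pnye, Aall, Abur, Nbri) and a Neotropical
#' three-species clade (Acen, Asiq, Azal), branch lengths in relative time
#' units with all tips at depth 1.
#'
#' @return A `phylo` object.
#' @export
cichlid_tree <- function() {
  txt <- paste0(
    "(((((Mzeb:0.05,Pnye:0.05):0.05,Aall:0.1):0.15,Abur:0.25):0.15,",
    "Nbri:0.4):0.6,((Acen:0.2,Asiq:0.2):0.3,Azal:0.5):0.5);"
  )
  tr <- ape::read.tree(text = txt)
  validate_species_tree(tr)
  tr
}

#' Simulation configuration with study defaults
#'
#' Defaults define the emulated study conditions: 8 species on the fixed
#' tree, 200 miRNA families (40% ancestral at the root, the rest gained
#' uniformly across branches), per-branch loss probability 0.15, 22-nt
#' matures, isomiR and clustering propensities higher for root-origin
#' families, 300 target genes with ~1 kb 3' UTRs, 5'-skewed (Beta(1,3))
#' conserved site placement vs uniform species-specific placement, and
#' expression for 6 individuals per species with miRNA-mRNA repression
#' coupling `repression_gamma`.
#'
#' @param ... overrides of any default listed below.
#' @return list of validated simulation parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    tree = cichlid_tree(),
    n_families = 200,
    p_root_family = 0.4,
    loss_rate = 0.15,
    gain_rate = 3,                 # expected gains per branch when
                                   # n_families is NULL (Poisson mode)
    mature_length = 22,
    seed_mut_prob = c(root = 0.02, novel = 0.2),
    isomir_prob = c(root = 0.45, tip = 0.05),
    cluster_prob = c(root = 0.45, tip = 0.15),
    n_scaffolds = 25,
    n_genes = 300,
    utr_length_lognormal = c(meanlog = log(1000), sdlog = 0.35),
    utr_sub_rate = 0.3,            # substitutions / site / unit time
    utr_del_rate = 0.005,          # deletion events / site / unit time
    conserved_site_bias = c(1, 3),
    novel_site_bias = c(1, 1),
    sites_per_conserved_mirna = 12,
    sites_per_novel_mirna = 3,
    repression_gamma = 0.3,
    noise_sigma = 0.3,
    individuals_per_species = 6,
    rng_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown parameter(s): ",
                                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_species_tree(cfg$tree)
  probs <- c(cfg$p_root_family, cfg$loss_rate, cfg$seed_mut_prob,
             cfg$isomir_prob, cfg$cluster_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(cfg$gain_rate, cfg$sites_per_conserved_mirna,
            cfg$sites_per_novel_mirna, cfg$utr_sub_rate,
            cfg$utr_del_rate) < 0)) stop("rates must be >= 0")
  cfg
}

.BASES <- c("A", "C", "G", "U")

.random_rna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# Draw a mature sequence whose 2-8 seed is absent from `used` (an
# environment used as a set); registers the seed.
.draw_unique_mature <- function(len, used) {
  repeat {
    s <- .random_rna(len)
    sd <- substr(s, 2, 8)
    if (is.null(used[[sd]])) {
      used[[sd]] <- TRUE
      return(s)
    }
  }
}

.mutate_seed <- function(seq, used) {
  for (attempt in 1:200) {
    pos <- sample(2:8, 1)
    old <- substr(seq, pos, pos)
    new <- sample(setdiff(.BASES, old), 1)
    cand <- seq
    substr(cand, pos, pos) <- new
    sd <- substr(cand, 2, 8)
    if (is.null(used[[sd]])) {
      used[[sd]] <- TRUE
      return(cand)
    }
  }
  seq  # seed space exhausted: keep the parent seed
}

.mutate_nonseed <- function(seq) {
  len <- nchar(seq)
  pos <- sample(setdiff(seq_len(len), 1:8), 1)
  old <- substr(seq, pos, pos)
  substr(seq, pos, pos) <- sample(setdiff(.BASES, old), 1)
  seq
}

# Deterministic gene ids as used by assign_isomirs(): smallest mature id
# within each (family, seed) group.
.truth_genes <- function(matures) {
  key <- paste(matures$true_family, substr(matures$sequence, 2, 8), sep = "\r")
  gid <- vapply(split(matures$id, key), min, "")
  matures$gene_id <- unname(gid[key])
  matures
}

#' Simulate per-species miRNA repertoires with a planted gain/loss history
#'
#' Each family is gained exactly once (at the root with probability
#' `p_root_family`, otherwise on a branch drawn uniformly) and lost
#' independently on each descendant branch, so every presence pattern is
#' Dollo-consistent by construction. Seeds are unique across families and
#' across seed mutations, making gene identity (family x seed) unambiguous.
#' IsomiRs are 3'-end length variants or non-seed substitutions — 5'-end
#' variants would shift the 2-8 seed and change gene identity, so the
#' generator does not emit them.
#'
#' @param config from [sim_config()].
#' @return list with `matures` (data.frame: `id`, `species`, `sequence`,
#'   `true_family`, `gene_id`, `origin_branch`, `root_origin`),
#'   `premirnas` (data.frame: `id`, `species`, `true_family`, `sequence`,
#'   `mature_ids`) and `truth` (list: `family_origin_branch`,
#'   `conservation` data.frame as produced by [classify_conservation()],
#'   `gene_origin_root` named logical).
#' @export
simulate_repertoires <- function(config = sim_config()) {
  set.seed(config$rng_seed + 101L)
  tree <- config$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  edge_of_child <- stats::setNames(seq_len(nrow(tree$edge)), tree$edge[, 2])
  used_seeds <- new.env(parent = emptyenv())

  fam_ids <- sprintf("fam%03d", seq_len(config$n_families))
  is_root_fam <- stats::runif(config$n_families) < config$p_root_family
  gain_node <- ifelse(is_root_fam, root,
                      sample(tree$edge[, 2], config$n_families, replace = TRUE))

  rows <- list()
  origin_branch <- character(config$n_families)
  for (f in seq_len(config$n_families)) {
    fam <- fam_ids[f]
    seq0 <- .draw_unique_mature(config$mature_length, used_seeds)
    smp <- if (is_root_fam[f]) config$seed_mut_prob[["root"]] else
      config$seed_mut_prob[["novel"]]
    origin_branch[f] <- branch_label(tree, gain_node[f])
    # depth-first descent from the gain node; losses on edges below it
    stack <- list(list(node = gain_node[f], seq = seq0))
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      nd <- cur$node
      if (nd <= n_tip) {
        sp <- tree$tip.label[nd]
        rows[[length(rows) + 1]] <- data.frame(
          id = paste0(sp, "_", fam), species = sp, sequence = cur$seq,
          true_family = fam, root_origin = is_root_fam[f],
          origin_branch = origin_branch[f], stringsAsFactors = FALSE
        )
        next
      }
      for (ch in children[[as.character(nd)]]) {
        if (stats::runif(1) < config$loss_rate) next  # lost on this branch
        s <- cur$seq
        if (stats::runif(1) < smp) s <- .mutate_seed(s, used_seeds)
        stack[[length(stack) + 1]] <- list(node = ch, seq = s)
      }
    }
  }
  matures <- do.call(rbind, rows)
  if (is.null(matures) || nrow(matures) == 0) {
    matures <- data.frame(id = character(), species = character(),
                          sequence = character(), true_family = character(),
                          root_origin = logical(), origin_branch = character(),
                          stringsAsFactors = FALSE)
  }

  # isomiR variants, drawn once per family: a variable family carries one
  # extra mature (3'-end trim of 1-2 nt, floor 16 nt, or a non-seed
  # substitution) in a randomly chosen carrier species
  if (nrow(matures) > 0) {
    fams_present <- unique(matures$true_family)
    p_iso <- ifelse(is_root_fam[match(fams_present, fam_ids)],
                    config$isomir_prob[["root"]],
                    config$isomir_prob[["tip"]])
    variable_fams <- fams_present[stats::runif(length(fams_present)) < p_iso]
    variants <- lapply(variable_fams, function(fam) {
      members <- which(matures$true_family == fam)
      base <- matures[sample(members, 1), ]
      s <- base$sequence
      if (stats::runif(1) < 0.5 && nchar(s) >= 18) {
        s <- substr(s, 1, nchar(s) - sample(1:2, 1))
      } else {
        s <- .mutate_nonseed(s)
      }
      base$id <- paste0(base$id, "_v2")
      base$sequence <- s
      base
    })
    matures <- rbind(matures, do.call(rbind, variants))
  }
  matures <- matures[order(matures$id), , drop = FALSE]
  rownames(matures) <- NULL
  matures <- .truth_genes(matures)

  # one precursor per (species, family): mature embedded in random flanks
  prem_key <- unique(matures[, c("species", "true_family")])
  premirnas <- do.call(rbind, lapply(seq_len(nrow(prem_key)), function(i) {
    sp <- prem_key$species[i]; fam <- prem_key$true_family[i]
    mem <- matures[matures$species == sp & matures$true_family == fam, ]
    data.frame(
      id = paste0(sp, "_", fam, "_pre"), species = sp, true_family = fam,
      sequence = paste0(.random_rna(15), mem$sequence[1], .random_rna(30)),
      mature_ids = paste(mem$id, collapse = ","), stringsAsFactors = FALSE
    )
  }))

  conservation <- classify_conservation(
    data.frame(gene_id = matures$gene_id, species = matures$species,
               stringsAsFactors = FALSE), tree)
  gene_root <- vapply(split(matures$root_origin, matures$gene_id), any, TRUE)

  list(
    matures = matures,
    premirnas = premirnas,
    truth = list(
      family_origin_branch = stats::setNames(origin_branch, fam_ids),
      conservation = conservation,
      gene_origin_root = gene_root
    )
  )
}

#' Simulate genomic coordinates of precursors with planted clusters
#'
#' Per species, each precursor either joins an open cluster chain on the
#' same scaffold and strand at a gap drawn uniformly from \[200, 4000) bp
#' (probability `cluster_prob`, higher for root-origin families), or opens a
#' new location far (>= 100 kb) from every existing one. Chains of two or
#' more members are recorded as planted clusters.
#'
#' @param repertoires from [simulate_repertoires()].
#' @param config from [sim_config()].
#' @return list with `bed` (data.frame in [read_bed()] layout) and
#'   `planted_clusters` (list of member-id vectors).
#' @export
simulate_coordinates <- function(repertoires, config = sim_config()) {
  set.seed(config$rng_seed + 202L)
  prem <- repertoires$premirnas
  fam_root <- vapply(split(repertoires$matures$root_origin,
                           repertoires$matures$true_family), any, TRUE)
  bed_rows <- list()
  planted <- list()
  iso_gap <- 500000L  # comfortably beyond the 100 kb isolation floor
  for (sp in sort(unique(prem$species))) {
    ps <- prem[prem$species == sp, , drop = FALSE]
    ps <- ps[sample.int(nrow(ps)), , drop = FALSE]
    scaffolds <- paste0(sp, "_scf", sprintf("%02d", seq_len(config$n_scaffolds)))
    cursor <- stats::setNames(rep(0L, length(scaffolds)), scaffolds)
    chains <- list()  # each: scaffold, strand, end, members
    for (i in seq_len(nrow(ps))) {
      p_cl <- if (fam_root[[ps$true_family[i]]])
        config$cluster_prob[["root"]] else config$cluster_prob[["tip"]]
      len <- nchar(ps$sequence[i])
      join <- length(chains) > 0 && stats::runif(1) < p_cl
      if (join) {
        ci <- sample.int(length(chains), 1)
        ch <- chains[[ci]]
        start <- ch$end + sample(200:3999, 1)
        end <- start + len
        chains[[ci]]$end <- end
        chains[[ci]]$members <- c(ch$members, ps$id[i])
        scf <- ch$scaffold; strand <- ch$strand
        cursor[scf] <- max(cursor[scf], end)
      } else {
        scf <- sample(scaffolds, 1)
        strand <- sample(c("+", "-"), 1)
        start <- cursor[[scf]] + iso_gap
        end <- start + len
        cursor[scf] <- end
        chains[[length(chains) + 1]] <- list(scaffold = scf, strand = strand,
                                             end = end, members = ps$id[i])
      }
      bed_rows[[length(bed_rows) + 1]] <- data.frame(
        name = ps$id[i], scaffold = scf, start = start, end = end,
        score = 0, strand = strand, stringsAsFactors = FALSE
      )
    }
    planted <- c(planted, Filter(function(ch) length(ch$members) >= 2, chains))
  }
  bed <- do.call(rbind, bed_rows)
  bed <- bed[order(bed$scaffold, bed$start), , drop = FALSE]
  rownames(bed) <- NULL
  list(bed = bed,
       planted_clusters = lapply(planted, function(ch) sort(ch$members)))
}

# Evolve a gapped character matrix (species x columns) down the tree by
# per-branch substitutions and short deletions; protected columns are
# immutable. Returns list of tip character vectors.
.evolve_utr <- function(tree, ancestral, protected, sub_rate, del_rate) {
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- stats::setNames(tree$edge.length, tree$edge[, 2])
  tips <- vector("list", n_tip)
  L <- length(ancestral)
  recurse <- function(node, seq) {
    if (node <= n_tip) {
      tips[[node]] <<- seq
      return(invisible())
    }
    for (ch in children[[as.character(node)]]) {
      b <- blen[[as.character(ch)]]
      s <- seq
      alive <- which(!protected & s != "-")
      if (length(alive) > 0 && b > 0) {
        p_sub <- 1 - exp(-sub_rate * b)
        mut <- alive[stats::runif(length(alive)) < p_sub]
        if (length(mut) > 0) {
          cur <- s[mut]
          s[mut] <- vapply(cur, function(x) sample(setdiff(.BASES, x), 1), "")
        }
        n_del <- stats::rpois(1, del_rate * length(alive) * b)
        if (n_del > 0) {
          for (d in seq_len(n_del)) {
            alive2 <- which(!protected & s != "-")
            if (length(alive2) == 0) break
            at <- sample(alive2, 1)
            dl <- sample(1:3, 1)
            span <- at:min(at + dl - 1, L)
            span <- span[!protected[span]]
            s[span] <- "-"
          }
        }
      }
      recurse(ch, s)
    }
  }
  recurse(n_tip + 1L, ancestral)
  stats::setNames(tips, tree$tip.label)
}

#' Simulate per-gene 3' UTR alignments with planted target sites
#'
#' Each gene starts from a random ancestral UTR (log-normal length).
#' Conserved-miRNA sites are written into the ancestor at Beta-distributed
#' relative positions (default Beta(1,3): 5'-skewed) and protected from
#' mutation, with flanking bases fixed so the planted site type is exactly
#' what a scanner reports. The ancestor then evolves along the tree by
#' substitutions and short deletions; the true alignment is emitted
#' directly, so no aligner ever runs. Species-specific-miRNA sites are
#' written afterwards into the single carrier species at Beta(1,1)
#' positions.
#'
#' @param repertoires from [simulate_repertoires()].
#' @param config from [sim_config()].
#' @return list with `alignments` (named list gene -> named gapped character
#'   vector over all tips), `utr_lengths` (data.frame `gene_id`, `species`,
#'   `length`), `planted_sites` (data.frame `target_gene`, `species`,
#'   `mirna_gene`, `site_type`, `start`, `conserved`) and
#'   `repression_pairs` (data.frame `mirna_gene`, `target_gene`).
#' @export
simulate_utrs_and_sites <- function(repertoires, config = sim_config()) {
  set.seed(config$rng_seed + 303L)
  tree <- config$tree
  tips <- tree$tip.label
  matures <- repertoires$matures
  cons <- repertoires$truth$conservation
  gene_seq <- vapply(split(matures$sequence, matures$gene_id),
                     function(s) s[which.min(nchar(s))[1]], "")
  gene_species <- lapply(split(matures$species, matures$gene_id), unique)
  conserved_mirnas <- cons$gene_id[cons$class == "conserved"]
  ss_mirnas <- cons$gene_id[cons$class == "species-specific"]
  target_ids <- sprintf("g%03d", seq_len(config$n_genes))

  L <- pmax(200L, as.integer(round(stats::rlnorm(
    config$n_genes, config$utr_length_lognormal[["meanlog"]],
    config$utr_length_lognormal[["sdlog"]]))))
  anc <- lapply(L, function(l) sample(.BASES, l, replace = TRUE))
  prot <- lapply(L, function(l) rep(FALSE, l))
  planted <- list()

  type_pool <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
  not_base <- function(b) sample(setdiff(.BASES, b), 1)

  # plant a site (string + type-defining flanks) into character vector `sq`
  # at ungapped-start `st` (1-based); returns modified seq or NULL on clash
  plant <- function(sq, pr, st, mirna_seq, type) {
    ss <- site_strings(mirna_seq)
    str <- ss[[type]]
    len <- nchar(str)
    m8c <- substr(ss[["7mer-m8"]], 1, 1)
    win <- st:(st + len - 1)
    guard <- c(if (st > 1) st - 1, if (st + len <= length(sq)) st + len)
    if (any(pr[c(win, guard)])) return(NULL)
    sq[win] <- strsplit(str, "")[[1]]
    if (st > 1 && type %in% c("6mer", "7mer-A1")) {
      sq[st - 1] <- not_base(m8c)     # 5' flank: no accidental m8 upgrade
    }
    if (st + len <= length(sq) && type %in% c("6mer", "7mer-m8")) {
      sq[st + len] <- not_base("A")   # 3' flank: no accidental A1 upgrade
    }
    list(seq = sq, protect = c(win, guard))
  }

  # conserved sites into ancestors
  for (mg in conserved_mirnas) {
    n_sites <- stats::rpois(1, config$sites_per_conserved_mirna)
    if (n_sites == 0) next
    for (k in seq_len(n_sites)) {
      type <- sample(type_pool, 1, prob = c(0.4, 0.25, 0.25, 0.1))
      placed <- FALSE
      for (attempt in 1:100) {
        gi <- sample.int(config$n_genes, 1)
        len <- nchar(site_strings(gene_seq[[mg]])[[type]])
        rel <- stats::rbeta(1, config$conserved_site_bias[1],
                            config$conserved_site_bias[2])
        st <- 1L + as.integer(round(rel * (L[gi] - len)))
        res <- plant(anc[[gi]], prot[[gi]], st, gene_seq[[mg]], type)
        if (is.null(res)) next
        anc[[gi]] <- res$seq
        prot[[gi]][res$protect] <- TRUE
        planted[[length(planted) + 1]] <- data.frame(
          target_gene = target_ids[gi], species = NA_character_,
          mirna_gene = mg, site_type = type, start = st - 1L,
          conserved = TRUE, stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
      # unplaceable sites are skipped after 100 attempts
    }
  }

  # evolve each gene down the tree (ancestor has no gaps: columns = sites)
  alignments <- vector("list", config$n_genes)
  names(alignments) <- target_ids
  for (gi in seq_len(config$n_genes)) {
    tipseq <- .evolve_utr(tree, anc[[gi]], prot[[gi]],
                          config$utr_sub_rate, config$utr_del_rate)
    alignments[[gi]] <- tipseq
  }

  # species-specific sites into the single carrier species
  for (mg in ss_mirnas) {
    sp <- gene_species[[mg]][1]
    n_sites <- stats::rpois(1, config$sites_per_novel_mirna)
    if (n_sites == 0) next
    for (k in seq_len(n_sites)) {
      type <- sample(type_pool, 1, prob = c(0.4, 0.25, 0.25, 0.1))
      len <- nchar(site_strings(gene_seq[[mg]])[[type]])
      placed <- FALSE
      for (attempt in 1:100) {
        gi <- sample.int(config$n_genes, 1)
        sq <- alignments[[gi]][[sp]]
        ungapped_cols <- which(sq != "-")
        nun <- length(ungapped_cols)
        if (nun < len + 2) next
        rel <- stats::rbeta(1, config$novel_site_bias[1],
                            config$novel_site_bias[2])
        u <- 1L + as.integer(round(rel * (nun - len)))
        cols <- ungapped_cols[u:(u + len - 1)]
        guard_cols <- ungapped_cols[c(max(u - 1, 1), min(u + len, nun))]
        if (any(prot[[gi]][c(cols, guard_cols)])) next
        str <- site_strings(gene_seq[[mg]])[[type]]
        m8c <- substr(site_strings(gene_seq[[mg]])[["7mer-m8"]], 1, 1)
        sq[cols] <- strsplit(str, "")[[1]]
        if (u > 1 && type %in% c("6mer", "7mer-A1")) {
          sq[ungapped_cols[u - 1]] <- not_base(m8c)
        }
        if (u + len <= nun && type %in% c("6mer", "7mer-m8")) {
          sq[ungapped_cols[u + len]] <- not_base("A")
        }
        alignments[[gi]][[sp]] <- sq
        prot[[gi]][c(cols, guard_cols)] <- TRUE  # no later site may overwrite
        planted[[length(planted) + 1]] <- data.frame(
          target_gene = target_ids[gi], species = sp, mirna_gene = mg,
          site_type = type, start = u - 1L, conserved = FALSE,
          stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
    }
  }

  aln_chr <- lapply(alignments, function(a) {
    vapply(a, paste, "", collapse = "")
  })
  utr_lengths <- do.call(rbind, lapply(target_ids, function(g) {
    data.frame(gene_id = g, species = tips,
               length = nchar(gsub("-", "", aln_chr[[g]], fixed = TRUE))[tips],
               stringsAsFactors = FALSE)
  }))
  rownames(utr_lengths) <- NULL
  planted_df <- if (length(planted) > 0) do.call(rbind, planted) else
    data.frame(target_gene = character(), species = character(),
               mirna_gene = character(), site_type = character(),
               start = integer(), conserved = logical(),
               stringsAsFactors = FALSE)
  list(
    alignments = aln_chr,
    utr_lengths = utr_lengths,
    planted_sites = planted_df,
    repression_pairs = unique(planted_df[, c("mirna_gene", "target_gene")])
  )
}

#' Simulate miRNA and mRNA count matrices with repression coupling
#'
#' Per individual, miRNA log-expression is a family base (higher for
#' root-origin families), plus a species effect, plus noise; counts are
#' Poisson draws from the exponentiated values. mRNA log-expression is a
#' gene base minus `repression_gamma` times the sum over its planted
#' targeting miRNAs of (site count x that individual's standardized latent
#' miRNA expression), plus noise, so the coupling strength is scale-free.
#'
#' @param repertoires from [simulate_repertoires()].
#' @param utrs from [simulate_utrs_and_sites()].
#' @param config from [sim_config()].
#' @return list with `mirna_counts`, `mrna_counts` (feature x sample
#'   matrices), `species_of_sample` (named character), `gene_lengths`
#'   (named, nt; for TPM) and `latent` (list of the noise-free expression
#'   matrices used to couple the two layers).
#' @export
simulate_expression <- function(repertoires, utrs, config = sim_config()) {
  set.seed(config$rng_seed + 404L)
  tree <- config$tree
  tips <- tree$tip.label
  n_ind <- config$individuals_per_species
  samples <- as.vector(t(outer(tips, seq_len(n_ind),
                               function(s, i) paste0(s, "_i", i))))
  species_of_sample <- stats::setNames(rep(tips, each = n_ind), samples)

  matures <- repertoires$matures
  mirna_genes <- sort(unique(matures$gene_id))
  gene_root <- repertoires$truth$gene_origin_root[mirna_genes]
  gene_sp <- lapply(split(matures$species, matures$gene_id), unique)

  base_mi <- ifelse(gene_root, log(600), log(150))
  sp_eff <- matrix(stats::rnorm(length(mirna_genes) * length(tips), 0, 0.25),
                   length(mirna_genes), length(tips),
                   dimnames = list(mirna_genes, tips))
  lat_mi <- matrix(0, length(mirna_genes), length(samples),
                   dimnames = list(mirna_genes, samples))
  for (j in seq_along(samples)) {
    sp <- species_of_sample[j]
    lat_mi[, j] <- base_mi + sp_eff[, sp] +
      stats::rnorm(length(mirna_genes), 0, config$noise_sigma)
  }
  present <- vapply(mirna_genes, function(g) tips %in% gene_sp[[g]],
                    logical(length(tips)))
  present_sample <- t(present)[, match(species_of_sample, tips)]
  lat_mi[!present_sample] <- -Inf  # absent miRNA: zero expression
  mirna_counts <- matrix(stats::rpois(length(lat_mi),
                                      ifelse(is.finite(lat_mi),
                                             exp(lat_mi), 0)),
                         nrow(lat_mi), ncol(lat_mi),
                         dimnames = dimnames(lat_mi))

  # standardized latent miRNA expression (zeros included for absent species)
  lat_for_z <- ifelse(is.finite(lat_mi), exp(lat_mi), 0)
  z_mi <- t(scale(t(lat_for_z)))
  z_mi[is.na(z_mi)] <- 0

  target_ids <- sort(unique(utrs$utr_lengths$gene_id))
  base_mr <- stats::setNames(stats::rnorm(length(target_ids), log(400), 0.3),
                             target_ids)
  # per (target gene, mirna, species): planted site counts
  ps <- utrs$planted_sites
  lat_mr <- matrix(rep(base_mr, length(samples)),
                   length(target_ids), length(samples),
                   dimnames = list(target_ids, samples))
  if (nrow(ps) > 0) {
    agg_key <- paste(ps$target_gene, ps$mirna_gene, sep = "\r")
    for (grp in split(seq_len(nrow(ps)), agg_key)) {
      tg <- ps$target_gene[grp[1]]
      mg <- ps$mirna_gene[grp[1]]
      if (!mg %in% mirna_genes) next
      sp_site <- ps$species[grp]
      for (j in seq_along(samples)) {
        sp <- species_of_sample[j]
        n_sites <- sum(is.na(sp_site) | sp_site == sp)
        if (n_sites > 0) {
          lat_mr[tg, j] <- lat_mr[tg, j] -
            config$repression_gamma * n_sites * z_mi[mg, j]
        }
      }
    }
  }
  lat_mr <- lat_mr + matrix(stats::rnorm(length(lat_mr), 0,
                                         config$noise_sigma),
                            nrow(lat_mr), ncol(lat_mr))
  mrna_counts <- matrix(stats::rpois(length(lat_mr), exp(lat_mr)),
                        nrow(lat_mr), ncol(lat_mr),
                        dimnames = dimnames(lat_mr))
  gene_lengths <- stats::setNames(
    1500 + round(tapply(utrs$utr_lengths$length, utrs$utr_lengths$gene_id,
                        mean))[target_ids],
    target_ids)
  list(mirna_counts = mirna_counts, mrna_counts = mrna_counts,
       species_of_sample = species_of_sample,
       gene_lengths = gene_lengths,
       latent = list(mirna = lat_mi, mrna = lat_mr))
}

#' Simulate a gene-to-GO annotation table with one planted enriched term
#'
#' Every gene receives 1-4 background terms at random. The planted term
#' `GO:0000001` is attached preferentially (p = 0.8 vs 0.05) to the genes
#' in the top decile of realized species-specific seed-match density
#' (planted plus chance occurrences, per summed UTR length), emulating a
#' functional category enriched among fast-emerging targets.
#'
#' @param utrs from [simulate_utrs_and_sites()].
#' @param repertoires from [simulate_repertoires()]; used to locate each
#'   species-specific miRNA and scan its carrier's UTRs.
#' @param config from [sim_config()].
#' @param n_terms vocabulary size (default 40).
#' @return list with `annotation` (data.frame `gene_id`, `go_id`) and
#'   `enriched_term`.
#' @export
simulate_annotation <- function(utrs, repertoires, config = sim_config(),
                                n_terms = 40) {
  set.seed(config$rng_seed + 505L)
  genes <- sort(unique(utrs$utr_lengths$gene_id))
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  # realized species-specific site counts: planted and chance occurrences
  cons <- repertoires$truth$conservation
  ss_genes <- cons$gene_id[cons$class == "species-specific"]
  mat <- repertoires$matures
  cnt <- stats::setNames(numeric(length(genes)), genes)
  utr_by_sp <- list()
  for (mg in ss_genes) {
    rows <- which(mat$gene_id == mg)
    sp <- mat$species[rows[1]]
    if (is.null(utr_by_sp[[sp]])) {
      utr_by_sp[[sp]] <- vapply(utrs$alignments[genes], function(a) {
        gsub("-", "", a[[sp]], fixed = TRUE)
      }, "")
    }
    hits <- .scan_seed_many(utr_by_sp[[sp]], mat$sequence[rows[1]])
    if (nrow(hits) > 0) {
      tab <- table(hits$utr)
      cnt[as.integer(names(tab))] <- cnt[as.integer(names(tab))] + tab
    }
  }
  tot_len <- tapply(utrs$utr_lengths$length, utrs$utr_lengths$gene_id, sum)
  dens <- as.numeric(cnt) / as.numeric(tot_len[genes])
  top <- genes[rank(-dens, ties.method = "first") <= ceiling(0.1 * length(genes))]
  rows <- lapply(genes, function(g) {
    k <- sample(1:4, 1)
    tms <- sample(terms[-1], k)
    p1 <- if (g %in% top) 0.8 else 0.05
    if (stats::runif(1) < p1) tms <- c(terms[1], tms)
    data.frame(gene_id = g, go_id = tms, stringsAsFactors = FALSE)
  })
  list(annotation = do.call(rbind, rows), enriched_term = terms[1])
}

#' Run the full synthetic study
#'
#' Chains repertoire, coordinate, UTR/site, expression and annotation
#' simulation under one configuration and seed.
#'
#' @param config from [sim_config()].
#' @return list with elements `config`, `repertoires`, `coordinates`,
#'   `utrs`, `expression`, `annotation`.
#' @export
simulate_study <- function(config = sim_config()) {
  rep <- simulate_repertoires(config)
  coords <- simulate_coordinates(rep, config)
  utrs <- simulate_utrs_and_sites(rep, config)
  expr <- simulate_expression(rep, utrs, config)
  ann <- simulate_annotation(utrs, rep, config)
  list(config = config, repertoires = rep, coordinates = coords,
       utrs = utrs, expression = expr, annotation = ann)
}

#' Write a simulated study to disk in standard formats
#'
#' Emits per-species mature and precursor FASTA, pooled BED6 coordinates,
#' the newick tree, one aligned FASTA per target gene, miRNA and mRNA count
#' TSVs, gene lengths, the GO annotation table and `truth/` TSVs with the
#' planted ground truth.
#'
#' @param study from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  tips <- study$config$tree$tip.label
  for (sp in tips) {
    m <- study$repertoires$matures
    m <- m[m$species == sp, ]
    write_fasta(stats::setNames(m$sequence, m$id),
                file.path(dir, paste0(sp, "_mature.fa")))
    p <- study$repertoires$premirnas
    p <- p[p$species == sp, ]
    write_fasta(stats::setNames(p$sequence, p$id),
                file.path(dir, paste0(sp, "_precursor.fa")))
  }
  write_bed(study$coordinates$bed, file.path(dir, "premirnas.bed"))
  write_species_tree(study$config$tree, file.path(dir, "species_tree.nwk"))
  for (g in names(study$utrs$alignments)) {
    write_fasta(study$utrs$alignments[[g]],
                file.path(dir, "alignments", paste0(g, ".fa")))
  }
  write_expression_tsv(study$expression$mirna_counts,
                       file.path(dir, "mirna_counts.tsv"), "mirna_gene")
  write_expression_tsv(study$expression$mrna_counts,
                       file.path(dir, "mrna_counts.tsv"), "gene_id")
  write_tsv(data.frame(gene_id = names(study$expression$gene_lengths),
                       length = unname(study$expression$gene_lengths)),
            file.path(dir, "gene_lengths.tsv"))
  write_tsv(data.frame(sample = names(study$expression$species_of_sample),
                       species = unname(study$expression$species_of_sample)),
            file.path(dir, "samples.tsv"))
  write_tsv(study$annotation$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(study$repertoires$truth$conservation,
            file.path(dir, "truth", "conservation.tsv"))
  write_tsv(study$utrs$planted_sites,
            file.path(dir, "truth", "planted_sites.tsv"))
  write_tsv(data.frame(
    cluster = seq_along(study$coordinates$planted_clusters),
    members = vapply(study$coordinates$planted_clusters, paste, "",
                     collapse = ",")),
    file.path(dir, "truth", "planted_clusters.tsv"))
  write_tsv(study$utrs$repression_pairs,
            file.path(dir, "truth", "repression_pairs.tsv"))
  invisible(dir)
}
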