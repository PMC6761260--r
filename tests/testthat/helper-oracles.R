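# Independent brute-force oracles used by the property and acceptance tests.
# These deliberately avoid the package's own code paths.

# all four canonical match strings built from first principles
oracle_site_strings <- function(mature) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }
  six <- rc(substr(mature, 2, 7))
  m8c <- chartr("ACGU", "UGCA", substr(mature, 8, 8))
  c("6mer" = six, "7mer-m8" = paste0(m8c, six),
    "7mer-A1" = paste0(six, "A"), "8mer" = paste0(m8c, six, "A"))
}

# plain substring scan (overlapping) of the four match strings with the
# strongest-type-per-seed-window rule
oracle_seed_sites <- function(utr, mature) {
  ss <- oracle_site_strings(mature)
  found <- list()
  for (type in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    str <- ss[[type]]
    len <- nchar(str)
    n <- nchar(utr)
    if (n < len) next
    starts <- 1:(n - len + 1)
    hit <- substring(utr, starts, starts + len - 1) == str
    for (i in starts[hit]) {
      core <- if (type %in% c("7mer-m8", "8mer")) i + 1L else i
      key <- as.character(core)
      if (is.null(found[[key]])) {
        found[[key]] <- data.frame(start = i - 1L, length = len,
                                   site_type = type,
                                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, found)
  if (is.null(out)) {
    return(data.frame(start = integer(), length = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$site_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# connected components (size >= 2) of the pairwise same-scaffold/strand
# gap < max_gap relation
oracle_clusters <- function(bed, max_gap) {
  n <- nrow(bed)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  edges <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bed$scaffold[i] != bed$scaffold[j] ||
          bed$strand[i] != bed$strand[j]) next
      sep <- max(bed$start[i], bed$start[j]) -
        min(bed$end[i], bed$end[j])
      if (sep < max_gap) edges <- c(edges, i, j)
    }
  }
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  groups <- split(bed$name, comp)
  unname(lapply(Filter(function(x) length(x) >= 2, groups), sort))
}

# exhaustive single-gain Dollo minimiser
oracle_dollo <- function(tree, presence) {
  n_tip <- length(tree$tip.label)
  all_nodes <- 1:(n_tip + tree$Nnode)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc_tips <- function(nd) {
    if (nd <= n_tip) return(nd)
    unlist(lapply(kids[[as.character(nd)]], desc_tips))
  }
  pres_tips <- which(presence[tree$tip.label])
  best <- NULL
  for (g in all_nodes) {
    dt <- desc_tips(g)
    if (!all(pres_tips %in% dt)) next
    # maximal empty subtrees below g
    count_losses <- function(nd) {
      if (length(intersect(desc_tips(nd), pres_tips)) == 0) return(1L)
      if (nd <= n_tip) return(0L)
      sum(vapply(kids[[as.character(nd)]], count_losses, 0L))
    }
    losses <- if (g <= n_tip) 0L else
      sum(vapply(kids[[as.character(g)]], count_losses, 0L))
    ev <- 1L + losses
    if (is.null(best) || ev < best$events) best <- list(node = g, events = ev)
  }
  best
}

# full-enumeration two-sided Mann-Whitney p (no ties)
oracle_mwu_p <- function(x, y) {
  vals <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(vals), nx)
  u_of <- function(xi) {
    xs <- vals[xi]; ys <- vals[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_all <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(nx))
  pl <- mean(u_all <= u_obs)
  pg <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pg))
}

# hypergeometric upper tail by direct pmf summation
oracle_fisher_p <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
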