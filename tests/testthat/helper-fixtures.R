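# Shared fixtures. The reduced-scale synthetic study is simulated once per
# test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixtures$study)) {
    cfg <- sim_config(n_families = 40, n_genes = 50,
                      individuals_per_species = 3, rng_seed = 42)
    .fixtures$study <- simulate_study(cfg)
  }
  .fixtures$study
}

tree_from_text <- function(text) ape::read.tree(text = text)

# cluster membership of detect_clusters() as a canonical list of sorted
# member vectors, for set comparison against oracles/truth
membership_groups <- function(clusterset) {
  m <- clusterset$membership
  m <- m[!is.na(m)]
  unname(lapply(split(names(m), m), sort))
}

same_group_sets <- function(a, b) {
  setequal(vapply(a, paste, "", collapse = ","),
           vapply(b, paste, "", collapse = ","))
}
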