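# fixture builders shared across test files; everything generated in code

# one bag row; dead defaults to whatever balances the counts
bag_row <- function(species = "Aa_bb", rep = 1L, year = 1.5,
                    spont = 0L, ga = 0L, stained = 0L, buried = 100L,
                    dead = buried - spont - ga - stained,
                    row_number = 1L, row_sequence = 1L) {
  data.frame(species_id = species, replicate_id = rep,
             years_since_burial = year, row_number = row_number,
             row_sequence = row_sequence, n_buried = buried,
             n_germ_spont = spont, n_germ_ga = ga,
             n_viable_stained = stained, n_dead = dead,
             stringsAsFactors = FALSE)
}

bags <- function(...) bag_records(do.call(rbind, list(...)))

# species records across the design grid with per-year viable counts
species_series <- function(species, viable_by_year,
                           years = seq(1.5, 7.5, by = 1)) {
  stopifnot(length(viable_by_year) == length(years))
  do.call(rbind, lapply(seq_along(years), function(i)
    bag_row(species, rep = 1L, year = years[i],
            stained = viable_by_year[i], row_number = i)))
}

tiny_traits <- function(species, status = "invasive") {
  data.frame(species_id = species,
             invasion_status = rep_len(status, length(species)),
             life_form = "annual", seed_mass = 0.001,
             glossbank_type = "persistent", pre_burial_viability = 90,
             stringsAsFactors = FALSE)
}

# independent oracle: pairwise shared-path correlation by explicit
# tip-to-root path enumeration (never calls phylo_correlation)
corr_by_enumeration <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    path <- node
    while (node != root) {
      node <- parent[node]
      path <- c(path, node)
    }
    path
  }
  depth_of <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + elen[node]
      node <- parent[node]
    }
    d
  }
  C <- diag(ntip)
  for (i in seq_len(ntip - 1)) {
    for (j in (i + 1):ntip) {
      shared <- intersect(path_to_root(i), path_to_root(j))
      # the MRCA is the deepest node on both root paths
      mrca <- shared[which.max(vapply(shared, depth_of, numeric(1)))]
      C[i, j] <- C[j, i] <- depth_of(mrca) /
        sqrt(depth_of(i) * depth_of(j))
    }
  }
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

# quick posterior stub for arithmetic-only tests of lambda summaries
posterior_stub <- function(V, ve = 1, terms = colnames(V)) {
  structure(list(beta = matrix(0, nrow(V), 1,
                               dimnames = list(NULL, "(Intercept)")),
                 V = V, ve = ve, n_retained = nrow(V), terms = terms),
            class = "pglmm_posterior")
}
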