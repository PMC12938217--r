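# Builders for networks with implanted assemblies and for the trained
# fixture shared by the acceptance tests. Implanted assemblies are
# synthetic: member sets are chosen and their mutual excitatory links set
# to a fixed strength, standing in for the end state of associative
# training where a quickly constructed, frozen substrate suffices.

implant_assemblies <- function(sizes, strength = 1.2, seed = 1,
                               params = model_params(w_cap = max(strength, 0.5))) {
  net <- init_network(params, seed = seed)
  set.seed(derive_seed(seed, "implant"))
  circuits <- vector("list", length(sizes))
  ee <- net$conn$ee
  w <- net$conn$ee$w
  taken <- integer()
  for (i in seq_along(sizes)) {
    # members spread over all six areas, disjoint across assemblies
    members <- integer()
    per_area <- ceiling(sizes[i] / 6)
    for (a in 1:6) {
      pool <- setdiff((a - 1L) * 625L + 1:625, taken)
      members <- c(members, sample(pool, per_area))
    }
    members <- members[seq_len(sizes[i])]
    taken <- c(taken, members)
    idx <- which(ee$pre %in% members & ee$post %in% members)
    w[idx] <- strength
    circuits[[i]] <- list(pattern_id = i, members = sort(members),
                          size = length(members))
  }
  net$conn$ee$w <- w
  list(net = net, circuits = circuits)
}

# one trained network + pattern set shared across acceptance criteria;
# built once per session (a few minutes of simulated training)
fixture_trained <- function(reps = 250L, seed = 1L) {
  key <- sprintf("trained_%d_%d", reps, seed)
  memo(key, function() {
    par <- model_params()
    pairs <- generate_pattern_pairs(seed = seed)
    net <- init_network(par, seed = seed)
    set.seed(derive_seed(seed, "noise_warmup"))
    invisible(run_free(net, 400L))
    invisible(run_phase1(net, pairs, reps_per_pair = reps, seed = seed))
    circuits <- identify_cas(net, pairs, seed = seed)
    list(net = net, pairs = pairs, circuits = circuits, params = par)
  })
}
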