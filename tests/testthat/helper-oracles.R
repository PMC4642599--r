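# Shared test utilities: independent closed forms for the fixture
# topologies and a generator of small random instances.

# closed-form source->target reachability for the named fixtures, written
# directly from the path structure (independent of the engine)
closed_form_reachability <- function(name, p) {
  switch(name,
    single_edge = p[1],
    series = p[1] * p[2],
    parallel = 1 - (1 - p[1]) * (1 - p[2]),
    diamond = 1 - (1 - p[1] * p[2]) * (1 - p[3] * p[4]),
    bridge = {
      # edges: 1 s->a, 2 s->b, 3 a->b, 4 a->t, 5 b->t; condition on the bridge
      r_absent <- 1 - (1 - p[1] * p[4]) * (1 - p[2] * p[5])
      # bridge present: reach iff (e1 & e4) or (e5 & (e1 | e2))
      r_present <- p[1] * p[4] + p[5] * (p[1] + p[2] - p[1] * p[2]) -
        p[1] * p[4] * p[5]
      (1 - p[3]) * r_absent + p[3] * r_present
    },
    stop("unknown fixture")
  )
}

# small random instance for engine stress tests; cycles allowed on even
# seeds to exercise non-DAG topologies
random_small_instance <- function(seed, max_edges = 10) {
  # some size draws (few edges, cycles allowed) admit no root/sink split;
  # deterministically reroll the size until a graph exists
  for (k in 0:50) {
    inst <- try(withr::with_seed(seed + k * 7919L, {
      n_nodes <- sample(4:7, 1)
      n_edges <- sample(3:max_edges, 1)
      allow_cycles <- seed %% 2 == 0
      cap <- if (allow_cycles) n_nodes * (n_nodes - 1) else choose(n_nodes, 2)
      net <- generate_network(n_nodes, min(n_edges, cap),
        n_sources = 1, n_targets = 1,
        allow_cycles = allow_cycles, max_tries = 200
      )
      list(
        network = net,
        p = stats::runif(n_edges(net)),
        s = net$sources[1],
        t = net$targets[1]
      )
    }), silent = TRUE)
    if (!inherits(inst, "try-error")) return(inst)
  }
  stop("could not draw a test instance for seed ", seed)
}
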