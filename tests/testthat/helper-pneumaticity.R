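# shared fixtures built in code

# hand-checkable three-tip tree: ((A:1,B:1):1,C:2);
three_tip_tree <- function() {
  read_phylogeny("((A:1,B:1):1,C:2);")
}

# random regression instance on a simulated tree
random_instance <- function(n, seed, p = 2) {
  tr <- simulate_tree(n, seed = seed)
  set.seed(seed + 500000L)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p + 1)
  y <- beta[1] + X %*% beta[-1] + rnorm(n)
  d <- data.frame(species = tr$tip.label, y = as.numeric(y))
  for (j in seq_len(p)) d[[paste0("x", j)]] <- X[, j]
  list(tree = tr, data = d,
       formula = stats::as.formula(
         paste("y ~", paste(paste0("x", seq_len(p)), collapse = " + "))))
}

# random volume triple, possibly with zero air
random_volumes <- function(k, seed) {
  set.seed(seed)
  data.frame(v_bone = runif(k, 1, 500),
             v_marrow = runif(k, 0, 300),
             v_air = ifelse(runif(k) < 0.3, 0, runif(k, 0, 400)))
}
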