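# Shared fixtures: small parameter sets, random-but-plausible states, and a
# deterministic tiny operator build.

make_params <- function(n = 5, ...) {
  model_params(n = n, kernel_n = 2e5, ...)
}

# cached operators for repeated use within a test run
.op_cache <- new.env(parent = emptyenv())
cached_ops <- function(params) {
  key <- paste0("n", params$n, "_k", params$kernel_n, "_s", params$kernel_seed)
  if (is.null(.op_cache[[key]])) .op_cache[[key]] <- build_operators(params)
  .op_cache[[key]]
}

# A randomized state exercising all metabolism/vasculature cases: empty,
# normal-only, crowded, starved and overfull voxels.
random_state <- function(params, seed = 1) {
  set.seed(seed)
  nv <- params$spec$nvox
  st <- init_state(params, seeding = data.frame(i = integer(), j = integer(),
                                                k = integer(),
                                                cells = numeric()))
  kind <- sample(1:5, nv, replace = TRUE)
  st$l <- ifelse(kind >= 3, runif(nv) * 1.2 * params$M, 0)
  st$nc <- ifelse(kind >= 4, runif(nv) * 0.5 * params$M, 0)
  st$nn <- ifelse(kind >= 2, runif(nv) * 0.5 * params$M, 0)
  st$o <- runif(nv) * 2 * params$o0_bar
  st$gl <- runif(nv) * 2 * params$gl0_bar
  st$o_b_max <- runif(nv) * 2 * params$o_b_max0
  st$gl_b_max <- runif(nv) * 2 * params$gl_b_max0
  st$o_b <- runif(nv, -1, 1) * st$o_b_max
  st$gl_b <- runif(nv, -1, 1) * st$gl_b_max
  st$sw <- as.integer(runif(nv) < 0.3)
  st
}
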