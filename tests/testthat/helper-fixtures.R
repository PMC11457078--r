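# Construct a bact_env directly from coordinates (bypassing the generator)
# so tests can place colonies exactly where a hand computation expects them.
make_env <- function(row, col, count = rep(1L, length(row)), size = 100) {
  spec <- environment_spec(size = size, density = sum(count),
                           patchiness = max(1L, sum(count)), seed = 1)
  out <- tibble::tibble(row = as.integer(row), col = as.integer(col),
                        count = as.integer(count))
  attr(out, "spec") <- spec
  class(out) <- c("bact_env", class(out))
  out
}

# every cell of the lattice holds one colony: the fly sees constant influx
saturated_env <- function(size = 10) {
  idx <- expand.grid(row = seq_len(size), col = seq_len(size))
  make_env(idx$row, idx$col, size = size)
}

zero_env <- function(size = 50) {
  generate_environment(environment_spec(size = size, density = 0, seed = 1))
}

# hand-built trajectory for fitness tests
make_trajectory <- function(time, ...) {
  out <- tibble::tibble(time = time, ...)
  class(out) <- c("imd_trajectory", class(out))
  out
}

# hand-built multi-environment pool with known fitness structure
make_pool <- function(F_induced, curves, grid) {
  structure(list(cells = tibble::tibble(density = seq_along(F_induced),
                                        patchiness = 1),
                 F_induced = F_induced, curves = curves, grid = grid,
                 provenance = list()),
            class = "env_pool")
}
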