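#' Specification of a lattice environment of bacterial colonies
#'
#' Environments are square lattices seeded with `density` bacterial
#' colonies grouped into `patchiness` clusters: `patchiness = 1` puts all
#' colonies in a single Gaussian blob (maximally heterogeneous) and
#' `patchiness = density` reduces to one colony per cluster, i.e. uniform
#' placement. Cluster centers are uniform on the lattice; each colony sits
#' at its center plus an isotropic Gaussian offset (`cluster_sd` cells),
#' rounded to the nearest cell with toroidal wrap-around.
#'
#' @param size lattice side length in cells (default 100).
#' @param density total number of colonies, d.
#' @param patchiness number of clusters, p, with `1 <= p <= d`.
#' @param cluster_sd Gaussian scatter of colonies around their cluster
#'   center, in cells.
#' @param seed RNG seed; required for reproducible environments.
#' @return An `env_spec` list.
#' @export
environment_spec <- function(size = 100, density, patchiness = density,
                             cluster_sd = 3, seed = NULL) {
  size <- as.integer(size)
  density <- as.integer(density)
  patchiness <- as.integer(patchiness)
  problems <- character(0)
  if (is.na(size) || size < 2) problems <- c(problems, "size must be >= 2")
  if (is.na(density) || density < 0 || density > size^2) {
    problems <- c(problems, "density must be in [0, size^2]")
  }
  if (density > 0 && (is.na(patchiness) || patchiness < 1 ||
                      patchiness > max(density, 1))) {
    problems <- c(problems, "patchiness must be in [1, density]")
  }
  if (!is.finite(cluster_sd) || cluster_sd <= 0) {
    problems <- c(problems, "cluster_sd must be > 0")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid environment spec: ",
                 paste(problems, collapse = "; ")))
  }
  structure(list(size = size, density = density, patchiness = patchiness,
                 cluster_sd = cluster_sd, seed = seed),
            class = "env_spec")
}

#' Generate a clustered lattice environment
#'
#' Places `spec$patchiness` cluster centers uniformly at random, assigns
#' the `spec$density` colonies to centers as evenly as possible (remainders
#' to randomly chosen centers), and scatters each colony around its center
#' with an isotropic Gaussian offset, rounding to the nearest lattice cell
#' under toroidal wrap. Multiple colonies may land in one cell; the
#' multiplicity is kept in `count` so colony number is conserved.
#'
#' @param spec an [environment_spec()].
#' @return A tibble of class `bact_env` with columns `row`, `col`, `count`
#'   (cells are 1-based) and the spec attached as an attribute.
#' @examples
#' env <- generate_environment(
#'   environment_spec(size = 100, density = 50, patchiness = 1, seed = 7))
#' sum(env$count)
#' @export
generate_environment <- function(spec) {
  stopifnot(inherits(spec, "env_spec"))
  build <- function() {
    if (spec$density == 0) {
      out <- tibble(row = integer(0), col = integer(0), count = integer(0))
    } else {
      p <- spec$patchiness
      d <- spec$density
      centers_r <- runif(p, 0, spec$size)
      centers_c <- runif(p, 0, spec$size)
      per <- rep(d %/% p, p)
      rem <- d %% p
      if (rem > 0) {
        lucky <- sample.int(p, rem)
        per[lucky] <- per[lucky] + 1
      }
      idx <- rep(seq_len(p), per)
      r <- (centers_r[idx] + rnorm(d, sd = spec$cluster_sd)) %% spec$size
      cc <- (centers_c[idx] + rnorm(d, sd = spec$cluster_sd)) %% spec$size
      out <- tibble(row = floor(r) + 1L, col = floor(cc) + 1L) |>
        dplyr::count(.data$row, .data$col, name = "count")
    }
    out
  }
  out <- if (is.null(spec$seed)) build() else
    withr::with_seed(spec$seed, build())
  attr(out, "spec") <- spec
  class(out) <- c("bact_env", class(out))
  out
}

# size x size matrix of per-cell colony counts
env_count_matrix <- function(env) {
  spec <- attr(env, "spec")
  m <- matrix(0, spec$size, spec$size)
  if (nrow(env) > 0) m[cbind(env$row, env$col)] <- env$count
  m
}

#' Mean nearest-neighbor distance among colonies (toroidal)
#'
#' Summary statistic used to verify that the generator's patchiness knob
#' behaves as intended: clustered environments (small p) have a much
#' smaller mean nearest-neighbor distance than uniform ones (p = d).
#' Distances are Euclidean under the toroidal metric; cells holding k > 1
#' colonies contribute k coincident points (pairwise distance 0).
#'
#' @param env a `bact_env` from [generate_environment()].
#' @return Mean nearest-neighbor distance in cells.
#' @export
patchiness_statistic <- function(env) {
  stopifnot(inherits(env, "bact_env"))
  size <- attr(env, "spec")$size
  rows <- rep(env$row, env$count)
  cols <- rep(env$col, env$count)
  n <- length(rows)
  if (n < 2) abort("patchiness_statistic needs at least 2 colonies")
  dr <- abs(outer(rows, rows, "-"))
  dr <- pmin(dr, size - dr)
  dc <- abs(outer(cols, cols, "-"))
  dc <- pmin(dc, size - dc)
  d <- sqrt(dr^2 + dc^2)
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Write / read an environment as plain text
#'
#' One line per occupied cell (`row col count`, tab-separated, with
#' header); the generating spec travels in a JSON sidecar (`<path>.json`)
#' so any environment on disk is regenerable from spec + seed.
#'
#' @param env a `bact_env`.
#' @param path output file path.
#' @return `write_environment()` returns `path` invisibly;
#'   `read_environment()` returns the `bact_env`.
#' @export
write_environment <- function(env, path) {
  stopifnot(inherits(env, "bact_env"))
  utils::write.table(as.data.frame(env)[, c("row", "col", "count")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  spec <- attr(env, "spec")
  jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  spec_raw <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- environment_spec(size = spec_raw$size, density = spec_raw$density,
                           patchiness = spec_raw$patchiness,
                           cluster_sd = spec_raw$cluster_sd,
                           seed = spec_raw$seed)
  out <- tibble(row = as.integer(tab$row), col = as.integer(tab$col),
                count = as.integer(tab$count))
  attr(out, "spec") <- spec
  class(out) <- c("bact_env", class(out))
  out
}
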