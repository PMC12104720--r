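# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

# A small phantom (32x32x16 grid) for fast geometric tests.
tiny_spec <- function(true_ratio = 1, seed = 1L, ...) {
  phantom_spec(grid_shape = c(32L, 32L, 16L), true_ratio = true_ratio,
               n_branches = 4L, seed = seed, ...)
}

cached <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

tiny_phantom <- function(true_ratio = 1, seed = 1L) {
  cached(sprintf("ph_%g_%d", true_ratio, seed),
         generate_phantom(tiny_spec(true_ratio, seed),
                          case_id = sprintf("tiny_r%g_s%d", true_ratio, seed)))
}

default_phantom <- function(true_ratio = 0.5, seed = 7L) {
  cached(sprintf("dph_%g_%d", true_ratio, seed),
         generate_phantom(phantom_spec(true_ratio = true_ratio, seed = seed)))
}

# Independent voxel-count oracle for the hemisphere volume ratio: plain
# loops over array entries, no package volume code.
oracle_ratio <- function(case) {
  gt <- unclass(case$gt_vessels)
  aff <- unclass(if (case$affected_side == "left") case$territory_left
                 else case$territory_right)
  heal <- unclass(if (case$affected_side == "left") case$territory_right
                  else case$territory_left)
  sum(gt[aff]) / sum(gt[heal])
}

# Tiny network config (fast forward/backward in unit tests).
tiny_net_cfg <- function() {
  model_config("scaled", n_stages = 2L, base_channels = 4L,
               rsu_depths = c(2L, 2L), dilated = c(FALSE, TRUE))
}
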