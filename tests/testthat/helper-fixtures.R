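# Small shared fixtures; everything is generated in code at test time.

tiny_config <- function(...) {
  args <- utils::modifyList(list(grid_resolution = 5L, burn_in_steps = 5L,
                                 sampling_days = 5L, replicates = 3L,
                                 seed = 99L),
                            list(...))
  do.call(sim_config, args)
}

# hand-built population with known positions (bypasses random placement)
fixed_population <- function(N, cells, male) {
  structure(list(N = as.integer(N), n = length(cells),
                 id = seq_along(cells), male = male,
                 cell = as.integer(cells)),
            class = "sr_population")
}

# brute-force inverse-distance weights for one source cell, written
# independently of the kernel code (explicit double loop over coordinates)
brute_force_weights <- function(N, src_row, src_col) {
  w <- matrix(0, N, N)
  for (r in seq_len(N)) {
    for (c in seq_len(N)) {
      if (r == src_row && c == src_col) next
      w[r, c] <- 1 / sqrt((r - src_row)^2 + (c - src_col)^2)
    }
  }
  as.vector(w / sum(w)) # column-major, matching cell indexing
}
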