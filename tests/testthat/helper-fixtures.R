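# Shared fixtures, memoized so expensive objects are built once per run.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Small head phantom shared across tests.
small_phantom <- function() {
  memo("small_phantom", function() make_phantom(c(32, 32, 32), seed = 11L))
}

# Ideal noise-free phantom for segmentation recovery checks.
clean_phantom <- function() {
  memo("clean_phantom", function() {
    make_phantom(c(32, 32, 32),
                 phantom_geometry(zte_noise_sd = 0, ct_soft_sd = 0),
                 seed = 11L)
  })
}

small_atlas_db <- function() {
  memo("small_atlas_db", function() {
    make_atlas_database(small_phantom(), n_atlases = 3, deform_amplitude = 4,
                        seed = 21L)
  })
}

# Coarse acquisition for fast reconstruction tests.
fast_model <- function() acquisition_model(n_angles = 60, n_bins = 64)

# Short schedule for cheap dynamic tests (first 26 min of the framing style).
short_schedule <- function() {
  frame_schedule(c(rep(60, 4), rep(120, 2), rep(300, 4)))
}

# Independent queue-based 6-connected flood fill (oracle for shell closure).
oracle_flood_fill <- function(open) {
  dm <- dim(open)
  visited <- array(FALSE, dm)
  idx <- function(x, y, z) x + dm[1] * (y - 1 + dm[2] * (z - 1))
  queue <- integer(0)
  for (x in c(1, dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    queue <- c(queue, idx(x, y, z))
  }
  for (y in c(1, dm[2])) for (x in seq_len(dm[1])) for (z in seq_len(dm[3])) {
    queue <- c(queue, idx(x, y, z))
  }
  for (z in c(1, dm[3])) for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) {
    queue <- c(queue, idx(x, y, z))
  }
  queue <- unique(queue[open[queue]])
  visited[queue] <- TRUE
  offsets <- c(1, -1, dm[1], -dm[1], dm[1] * dm[2], -dm[1] * dm[2])
  coords <- arrayInd(seq_len(prod(dm)), dm)
  while (length(queue) > 0) {
    cur <- queue
    queue <- integer(0)
    for (o in seq_along(offsets)) {
      nb <- cur + offsets[o]
      ax <- (o + 1) %/% 2  # axis of this offset
      ok <- nb >= 1 & nb <= prod(dm)
      # reject wrap-around across array edges
      ok <- ok & abs(coords[pmin(pmax(nb, 1), prod(dm)), ax] - coords[cur, ax]) == 1
      nb <- nb[ok]
      nb <- nb[open[nb] & !visited[nb]]
      if (length(nb)) {
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    queue <- unique(queue)
  }
  visited
}
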