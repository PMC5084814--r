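# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

.cached <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

# small patch for cheap smoothing/cluster tests
small_patch <- function() .cached("small_patch", function() {
  make_mesh("flat_patch", target_edge_mm = 0.77, size = 20)
})

# study-scale patch (~3.2k vertices) matching the analysis conditions
std_patch <- function() .cached("std_patch", function() {
  make_mesh("flat_patch", target_edge_mm = 0.77, size = 40)
})

std_mask <- function() .cached("std_mask", function() {
  m <- std_patch()
  labels <- rep("cortex", nrow(m$vertices))
  labels[mesh_boundary_vertices(m)] <- "boundary"
  build_search_mask(m, labels, exclude = "boundary")
})

std_smoother <- function() .cached("std_smoother", function() {
  build_smoother(std_patch(), fwhm_mm = 8, n_iter = 10)
})

std_subjects <- function() .cached("std_subjects", function() {
  simulate_subject_table(seed = 101)
})

# build an event log from a compact trial description:
# list(trial, timbre, target, presses = data.frame(note, latency))
make_events <- function(trials) {
  do.call(rbind, lapply(trials, function(tr) {
    if (is.null(tr$presses) || nrow(tr$presses) == 0) {
      data.frame(subject = "T", trial = tr$trial, timbre = tr$timbre,
                 target_note = tr$target, pressed_note = NA_character_,
                 latency_s = NA_real_)
    } else {
      data.frame(subject = "T", trial = tr$trial, timbre = tr$timbre,
                 target_note = tr$target, pressed_note = tr$presses$note,
                 latency_s = tr$presses$latency)
    }
  }))
}

# a validated session where every response is `offset` semitones from target
offset_session <- function(offset, n = 24, timbre = "pure") {
  targets <- rep(48:59, length.out = n)
  ev <- data.frame(subject = "T", trial = seq_len(n), timbre = timbre,
                   target_note = midi_to_note(targets),
                   pressed_note = midi_to_note(targets + offset),
                   latency_s = rep(1.5, n))
  validate_session(ev)
}
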