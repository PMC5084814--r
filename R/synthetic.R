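# Synthetic study generators: subject tables, per-vertex qR1 datasets with a
# planted group-effect cluster, and trial-level behavioral key-press logs.
# All generators are pure functions of (parameters, seed).

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  force(expr)
}

#' Simulate a subject metadata table
#'
#' Emulates the demographic structure of a two-group AP study: by default 9
#' non-AP and 8 AP musicians, all non-AP European and the AP group split 3
#' European / 5 Asian (so the Europeans-only subset has n = 12). Ages are
#' uniform on a plausible young-musician range, sex is balanced, APS is
#' drawn high for AP and near chance for non-AP, and -log10(FDT) is
#' Gaussian per group.
#'
#' @param n_nonap,n_ap Group sizes.
#' @param n_asian_nonap,n_asian_ap Asian (ethnicity = 1) counts per group.
#' @param age_range Age range in years (uniform draw).
#' @param match_ages Emulate matched recruitment: interleave the sorted age
#'   draws across groups so group age distributions are matched (the
#'   default), instead of fully independent draws that can produce grossly
#'   mismatched groups a matched cohort would never contain.
#' @param seed Random seed.
#' @return Data frame with `subject_id`, `group`, `ap`, `age`, `sex`
#'   (female = 1), `ethnicity` (Asian = 1), `aps`, `neg_log10_fdt`.
#' @export
simulate_subject_table <- function(n_nonap = 9, n_ap = 8, n_asian_nonap = 0,
                                   n_asian_ap = 5, age_range = c(20, 32),
                                   match_ages = TRUE, seed = 1) {
  stopifnot(n_nonap >= 2, n_ap >= 2,
            n_asian_nonap <= n_nonap, n_asian_ap <= n_ap)
  .with_seed(seed, {
    n <- n_nonap + n_ap
    ap <- rep(c(0L, 1L), c(n_nonap, n_ap))
    eth <- c(sample(rep(c(1L, 0L), c(n_asian_nonap, n_nonap - n_asian_nonap))),
             sample(rep(c(1L, 0L), c(n_asian_ap, n_ap - n_asian_ap))))
    sex <- c(sample(rep(c(1L, 0L), length.out = n_nonap)),
             sample(rep(c(1L, 0L), length.out = n_ap)))
    age <- round(stats::runif(n, age_range[1], age_range[2]), 1)
    if (match_ages) {
      # interleave sorted draws across groups: matched age distributions
      slots <- rep(c(0L, 1L), length.out = n)
      if (sum(slots == 0L) != n_nonap) slots <- 1L - slots
      age_sorted <- sort(age)
      age <- numeric(n)
      age[ap == 0L] <- sample(age_sorted[slots == 0L])
      age[ap == 1L] <- sample(age_sorted[slots == 1L])
    }
    aps <- ifelse(ap == 1,
                  pmin(1, pmax(0.6, stats::rnorm(n, 0.92, 0.06))),
                  pmin(0.75, pmax(0.3, stats::rnorm(n, 0.51, 0.05))))
    fdt <- ifelse(ap == 1, stats::rnorm(n, 2.7, 0.5), stats::rnorm(n, 2.4, 0.25))
    data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      group = factor(ifelse(ap == 1, "AP", "nonAP"), levels = c("nonAP", "AP")),
      ap = ap, age = age,
      sex = sex, ethnicity = eth, aps = aps, neg_log10_fdt = fdt)
  })
}

#' Specification of a planted group effect on the mesh
#'
#' @param center_vertex Center of the effect disc (default: vertex nearest
#'   the mesh centroid).
#' @param radius_mm Geodesic radius of the disc.
#' @param effect_size Group (AP) effect inside the disc, s^-1.
#' @param beta_age,beta_sex,beta_ethnicity Covariate effects, s^-1 per unit.
#' @param noise_sd I.i.d. per-vertex noise SD, s^-1.
#' @param subject_sd Subject random-intercept SD, s^-1.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(center_vertex = NULL, radius_mm = 9,
                        effect_size = 0.017, beta_age = -5e-4,
                        beta_sex = 3e-3, beta_ethnicity = 2e-3,
                        noise_sd = 0.033, subject_sd = 0.003) {
  stopifnot(radius_mm > 0, noise_sd > 0, subject_sd >= 0)
  structure(list(center_vertex = center_vertex, radius_mm = radius_mm,
                 effect_size = effect_size, beta_age = beta_age,
                 beta_sex = beta_sex, beta_ethnicity = beta_ethnicity,
                 noise_sd = noise_sd, subject_sd = subject_sd),
            class = "effect_spec")
}

# smooth low-order polynomial baseline over normalized coordinates;
# statistical stand-in for the real myelination pattern, not anatomy
.baseline_field <- function(mesh, level = 0.65, amp = 0.03) {
  V <- mesh$vertices
  sc <- apply(V, 2, function(v) {
    rg <- range(v)
    if (diff(rg) < 1e-9) rep(0, length(v)) else 2 * (v - rg[1]) / diff(rg) - 1
  })
  level + amp * (0.7 * sc[, 1] + 0.5 * sc[, 2] + 0.4 * sc[, 1] * sc[, 2] +
                 0.6 * (sc[, 1]^2 - 0.5))
}

#' Simulate a per-subject vertex qR1 dataset with a planted effect
#'
#' Each subject's map is a shared smooth baseline plus additive covariate
#' terms (age, sex, ethnicity), a group effect confined to a geodesic disc,
#' a subject random intercept, and i.i.d. vertex noise; values are bounded
#' to the physical qR1 range \[0.25, 10\] s^-1 (bounding events counted).
#' The search mask excludes the mesh boundary.
#'
#' @param mesh A `triangle_mesh`.
#' @param subjects Subject table from [simulate_subject_table()].
#' @param effect An [effect_spec()].
#' @param seed Random seed.
#' @return A `vertex_dataset`: list with `values` (subjects x vertices, in
#'   s^-1), `subjects`, `mesh`, `mask` (`search_mask`), `effect` (the spec
#'   plus `disc` vertex indices), `n_clipped`, `depth`, `hemisphere`.
#' @export
simulate_qr1_dataset <- function(mesh, subjects, effect = effect_spec(),
                                 seed = 1) {
  n_vert <- nrow(mesh$vertices)
  bd <- mesh_boundary_vertices(mesh)
  labels <- rep("cortex", n_vert)
  labels[bd] <- "boundary"
  mask <- if (length(bd) > 0) {
    build_search_mask(mesh, labels, exclude = "boundary")
  } else {
    build_search_mask(mesh, labels)
  }

  center <- effect$center_vertex
  if (is.null(center)) {
    cen <- colMeans(mesh$vertices)
    center <- which.min(colSums((t(mesh$vertices) - cen)^2))
  }
  disc <- geodesic_disc(mesh, center, effect$radius_mm)
  if (any(disc %in% bd)) stop("effect disc exceeds the mesh interior")

  .with_seed(seed, {
    n_sub <- nrow(subjects)
    base <- .baseline_field(mesh)
    in_disc <- as.numeric(seq_len(n_vert) %in% disc)
    fixed <- outer(subjects$age * effect$beta_age +
                   subjects$sex * effect$beta_sex +
                   subjects$ethnicity * effect$beta_ethnicity, rep(1, n_vert)) +
      outer(subjects$ap * effect$effect_size, in_disc)
    Y <- matrix(rep(base, each = n_sub), n_sub, n_vert) + fixed +
      stats::rnorm(n_sub) * effect$subject_sd +
      matrix(stats::rnorm(n_sub * n_vert, sd = effect$noise_sd), n_sub, n_vert)
    n_clipped <- sum(Y < 0.25 | Y > 10)
    Y <- pmin(pmax(Y, 0.25), 10)
    effect$center_vertex <- center
    effect$disc <- disc
    structure(list(values = Y, subjects = subjects, mesh = mesh, mask = mask,
                   effect = effect, n_clipped = n_clipped,
                   depth = "50%", hemisphere = "synthetic"),
              class = "vertex_dataset")
  })
}

#' @export
print.vertex_dataset <- function(x, ...) {
  cat(sprintf("vertex_dataset: %d subjects x %d vertices (%s depth, %s)\n",
              nrow(x$values), ncol(x$values), x$depth, x$hemisphere))
  cat(sprintf("  mask retains %d vertices (%.1f mm^2); planted disc: %d vertices, effect %.4g /s\n",
              sum(x$mask), attr(x$mask, "area_mm2"),
              length(x$effect$disc), x$effect$effect_size))
  invisible(x)
}

#' The fixed 72-trial stimulus design of the AP test
#'
#' 36 pure-tone targets spanning C3..B5 and 36 piano targets spanning
#' E3..D#6, each presented once.
#'
#' @return Data frame with `timbre` and `target_midi` (72 rows, unshuffled;
#'   presentation order is randomized by [simulate_behavior()]).
#' @export
stimulus_design <- function() {
  data.frame(
    timbre = rep(c("pure", "piano"), each = 36),
    target_midi = c(note_to_midi("C3") + 0:35, note_to_midi("E3") + 0:35))
}

#' Behavioral response profile for the simulator
#'
#' @param chroma_accuracy Probability the answered chroma is correct.
#' @param chroma_error_sd Dispersion (SD, semitones) of wrong-chroma
#'   answers; errors follow a discretized wrapped-geometric distribution
#'   over the nonzero corrected-error offsets -5..+6.
#' @param octave_error_rate Named per-timbre probabilities
#'   (`c(pure = , piano = )`) of displacing a correct-chroma answer by an
#'   octave.
#' @param timeout_rate Probability a trial goes unanswered.
#' @param rt_median_s,rt_sigma Lognormal reaction-time parameters (median
#'   in seconds, sigma on the log scale); RTs are truncated to (0.1, 4\].
#' @param late_echo_rate Probability that a trial's event log starts with a
#'   spurious press within 100 ms (a late echo of the previous trial).
#' @return A `behavior_profile` list.
#' @export
behavior_profile <- function(chroma_accuracy = 0.9, chroma_error_sd = 2,
                             octave_error_rate = c(pure = 0.6, piano = 0.15),
                             timeout_rate = 0.05, rt_median_s = 1.6,
                             rt_sigma = 0.35, late_echo_rate = 0.02) {
  stopifnot(chroma_accuracy >= 0, chroma_accuracy <= 1,
            all(octave_error_rate >= 0 & octave_error_rate <= 1),
            timeout_rate >= 0, timeout_rate < 1, rt_median_s > 0.1,
            rt_median_s <= 4)
  structure(list(chroma_accuracy = chroma_accuracy,
                 chroma_error_sd = chroma_error_sd,
                 octave_error_rate = octave_error_rate,
                 timeout_rate = timeout_rate, rt_median_s = rt_median_s,
                 rt_sigma = rt_sigma, late_echo_rate = late_echo_rate),
            class = "behavior_profile")
}

# wrapped-geometric probabilities over nonzero offsets -5..+6 with a given
# root-mean-square spread (semitones)
.chroma_error_probs <- function(sd_semitones) {
  k <- c(-5:-1, 1:6)
  f <- function(q) {
    p <- q^abs(k); p <- p / sum(p)
    sqrt(sum(p * k^2)) - sd_semitones
  }
  lo <- f(1e-4); hi <- f(0.9999)
  q <- if (sd_semitones <= 1 + 1e-9 || lo > 0) 1e-4
       else if (hi < 0) 0.9999
       else stats::uniroot(f, c(1e-4, 0.9999))$root
  p <- q^abs(k)
  list(offsets = k, probs = p / sum(p))
}

#' Simulate the raw key-press log of one AP test session
#'
#' Generates trial-level events under a [behavior_profile()]: timeouts,
#' correct or dispersed chroma answers, octave displacements, truncated
#' lognormal reaction times, and occasional sub-100 ms echo presses. The
#' output feeds straight into [validate_session()].
#'
#' @param profile A `behavior_profile`.
#' @param design Stimulus design data frame (default [stimulus_design()]).
#' @param subject Subject label for the log.
#' @param seed Random seed.
#' @param key_range Playable MIDI range (88-key default).
#' @return Data frame of events: `subject`, `trial`, `timbre`,
#'   `target_note`, `pressed_note` (NA when unanswered), `latency_s`.
#' @export
simulate_behavior <- function(profile, design = stimulus_design(),
                              subject = "S01", seed = 1,
                              key_range = c(21L, 108L)) {
  stopifnot(inherits(profile, "behavior_profile"))
  .with_seed(seed, {
    design <- design[sample(nrow(design)), , drop = FALSE]
    errs <- .chroma_error_probs(profile$chroma_error_sd)
    prev_press <- NA_integer_
    rows <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      tgt <- design$target_midi[i]
      tb <- design$timbre[i]
      ev <- NULL
      if (!is.na(prev_press) && stats::runif(1) < profile$late_echo_rate) {
        ev <- data.frame(subject = subject, trial = i, timbre = tb,
                         target_note = midi_to_note(tgt),
                         pressed_note = midi_to_note(prev_press),
                         latency_s = stats::runif(1, 0.02, 0.1))
      }
      if (stats::runif(1) < profile$timeout_rate) {
        resp <- NA_integer_
      } else {
        off <- if (stats::runif(1) < profile$chroma_accuracy) 0L else
          sample(errs$offsets, 1, prob = errs$probs)
        resp <- tgt + off
        if (stats::runif(1) < profile$octave_error_rate[[tb]]) {
          shift <- sample(c(-12L, 12L), 1)
          if (resp + shift < key_range[1] || resp + shift > key_range[2])
            shift <- -shift
          resp <- resp + shift
        }
        resp <- min(max(resp, key_range[1]), key_range[2])
        rt <- Inf
        while (rt <= 0.1 || rt > 4) {
          rt <- stats::rlnorm(1, log(profile$rt_median_s), profile$rt_sigma)
        }
        ev <- rbind(ev, data.frame(subject = subject, trial = i, timbre = tb,
                                   target_note = midi_to_note(tgt),
                                   pressed_note = midi_to_note(resp),
                                   latency_s = rt))
      }
      if (is.na(resp) && is.null(ev)) {
        ev <- data.frame(subject = subject, trial = i, timbre = tb,
                         target_note = midi_to_note(tgt),
                         pressed_note = NA_character_, latency_s = NA_real_)
      }
      prev_press <- if (!is.na(resp)) resp else prev_press
      rows[[i]] <- ev
    }
    do.call(rbind, rows)
  })
}
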