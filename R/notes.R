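# Pitch arithmetic: note names, MIDI indices, equal temperament, chroma,
# and the octave-corrected error that underlies the AP score.

.NOTE_BASE <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)

#' Convert a note name to its MIDI semitone index
#'
#' Parses labels such as `"A4"`, `"D#6"` or `"Bb3"` under the convention
#' C4 = 60. Flats are accepted and normalized to the equivalent sharp
#' spelling internally.
#'
#' @param name Character vector of note labels: letter, optional accidental
#'   (`#` or `b`), octave number (may be negative).
#' @return Integer vector of MIDI indices.
#' @examples
#' note_to_midi(c("A4", "C3", "D#6"))
#' @export
note_to_midi <- function(name) {
  stopifnot(is.character(name))
  m <- regmatches(name, regexec("^([A-Ga-g])([#b]?)(-?[0-9]+)$", name))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("unparsable note label(s): ", paste(name[bad], collapse = ", "))
  }
  letter <- toupper(vapply(m, `[`, "", 2L))
  acc <- vapply(m, `[`, "", 3L)
  oct <- as.integer(vapply(m, `[`, "", 4L))
  semis <- .NOTE_BASE[letter] + ifelse(acc == "#", 1L, ifelse(acc == "b", -1L, 0L))
  as.integer(12L * (oct + 1L) + semis)
}

#' Convert a MIDI index to a note name (sharps-only spelling)
#'
#' @param midi Integer vector of MIDI indices.
#' @return Character vector such as `"C4"`, `"D#6"`.
#' @export
midi_to_note <- function(midi) {
  names12 <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
  midi <- as.integer(midi)
  paste0(names12[midi %% 12L + 1L], midi %/% 12L - 1L)
}

#' Equal-tempered frequency of a MIDI index
#'
#' Twelve-tone equal temperament anchored at A4 (MIDI 69).
#'
#' @param midi Numeric vector of MIDI indices.
#' @param a4_hz Reference frequency of A4 in Hz (default 440).
#' @return Frequencies in Hz (unrounded; round only for display).
#' @examples
#' midi_to_frequency(69)            # 440
#' round(midi_to_frequency(48), 2)  # C3
#' @export
midi_to_frequency <- function(midi, a4_hz = 440) {
  stopifnot(a4_hz > 0)
  a4_hz * 2^((midi - 69) / 12)
}

#' Pitch chroma of a MIDI index
#'
#' The octave-equivalent pitch class: the remainder of the semitone index
#' modulo 12 (C = 0, ..., B = 11).
#'
#' @param midi Integer vector.
#' @return Integer chroma in 0..11.
#' @export
chroma_of <- function(midi) {
  as.integer(midi) %% 12L
}

#' Octave-corrected error between two chromas
#'
#' Signed circular semitone distance from response chroma `c2` to target
#' chroma `c1`, folded into -5..+6: differences up to 6 semitones are kept,
#' larger ones are wrapped by an octave. A tied distance of 6 maps to +6.
#' `abs()` of the result is the absolute corrected error (ACE) of a trial.
#'
#' @param c1,c2 Integer vectors (chromas or raw MIDI indices; reduced mod 12).
#' @return Signed integer error in -5..6.
#' @examples
#' octave_corrected_error(chroma_of(60), chroma_of(48))  # C4 vs C3: 0
#' @export
octave_corrected_error <- function(c1, c2) {
  d <- (as.integer(c1) - as.integer(c2)) %% 12L
  ifelse(d <= 6L, d, d - 12L)
}

#' AP score from a mean absolute corrected error
#'
#' APS = 1 - m / m_max, where m is the mean absolute corrected error in
#' semitones and m_max = 6 is the largest possible corrected error. APS is
#' 1 for perfect chroma naming and 0.5 at chance.
#'
#' @param mean_ace Mean absolute corrected error, semitones, in \[0, 6\].
#' @param m_max Normalizer, semitones (default 6).
#' @return APS in \[0, 1\].
#' @export
aps_from_ace <- function(mean_ace, m_max = 6) {
  stopifnot(all(mean_ace >= 0 & mean_ace <= m_max))
  1 - mean_ace / m_max
}
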