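# Stage label vocabulary and the numeric encoding used for cycle fitting.
#
# The canonical cyclic order is diestrus -> proestrus -> estrus -> metestrus
# -> diestrus. Stage numbers increase in increments of 1.0 starting from 0.5
# (D = 0.5, P = 1.5, E = 2.5, M = 3.5); 0.0 and 4.0 both name the
# metestrus/diestrus boundary, so arithmetic on stage numbers is modulo 4.

#' Canonical estrous stage names
#'
#' @return Character vector `c("diestrus", "proestrus", "estrus", "metestrus")`
#'   in canonical cyclic order.
#' @export
canonical_stages <- function() c("diestrus", "proestrus", "estrus", "metestrus")

#' Transition stage labels
#'
#' Each transition label names two cyclically adjacent canonical stages in
#' cycle order, e.g. `"proestrus/estrus"`. The boundary at stage number 0
#' (equivalently 4) is `"metestrus/diestrus"`.
#'
#' @return Character vector of the four transition labels.
#' @export
transition_stages <- function() {
  s <- canonical_stages()
  c(paste(s[4], s[1], sep = "/"), paste(s[1], s[2], sep = "/"),
    paste(s[2], s[3], sep = "/"), paste(s[3], s[4], sep = "/"))
}

is_canonical_stage <- function(x) x %in% canonical_stages()
is_transition_stage <- function(x) x %in% transition_stages()

#' Normalize a stage label
#'
#' Maps common aliases (single letters `D/P/E/M`, any capitalisation, and
#' `"a/b"` transition strings) onto the canonical vocabulary.
#'
#' @param x Character vector of raw labels.
#' @param allow_na Logical; if `TRUE`, unknown or empty labels become `NA`
#'   instead of raising an error.
#' @return Character vector of canonical or transition labels.
#' @export
normalize_stage <- function(x, allow_na = TRUE) {
  alias <- c(d = "diestrus", diestrus = "diestrus",
             p = "proestrus", proestrus = "proestrus",
             e = "estrus", estrus = "estrus",
             m = "metestrus", metestrus = "metestrus")
  one <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      if (allow_na) return(NA_character_)
      stopf("empty stage label")
    }
    s <- tolower(trimws(s))
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      if (length(parts) == 2) {
        a <- alias[tolower(trimws(parts[1]))]
        b <- alias[tolower(trimws(parts[2]))]
        if (!is.na(a) && !is.na(b)) {
          lab <- paste(a, b, sep = "/")
          rev_lab <- paste(b, a, sep = "/")
          if (is_transition_stage(lab)) return(lab)
          if (is_transition_stage(rev_lab)) return(rev_lab)
        }
      }
      if (allow_na) return(NA_character_)
      stopf("unrecognised transition label '%s'", s)
    }
    v <- alias[s]
    if (is.na(v)) {
      if (allow_na) return(NA_character_)
      stopf("unrecognised stage label '%s'", s)
    }
    unname(v)
  }
  vapply(as.character(x), one, character(1), USE.NAMES = FALSE)
}

#' Numeric encoding of estrous stages
#'
#' Canonical stages map to midpoint numbers 0.5 (diestrus), 1.5 (proestrus),
#' 2.5 (estrus) and 3.5 (metestrus); transition labels map to the boundary
#' between their two stages (metestrus/diestrus to 0, diestrus/proestrus to 1,
#' and so on).
#'
#' @param stage Character vector of canonical or transition labels.
#' @return Numeric vector of stage numbers in `[0, 4)`.
#' @seealso [number_to_stage()]
#' @export
stage_to_number <- function(stage) {
  stage <- normalize_stage(stage, allow_na = FALSE)
  canon <- canonical_stages()
  trans <- transition_stages()
  vapply(stage, function(s) {
    if (is_canonical_stage(s)) return(match(s, canon) - 0.5)
    match(s, trans) - 1.0  # boundaries at 0, 1, 2, 3
  }, numeric(1), USE.NAMES = FALSE)
}

#' Map a stage number back to a stage label
#'
#' Values are reduced modulo 4 first. `[0,1)` maps to diestrus, `[1,2)` to
#' proestrus, `[2,3)` to estrus, `[3,4)` to metestrus. With
#' `transitions = TRUE`, values lying exactly on a stage boundary (within
#' `tol`) return the corresponding transition label instead; in particular 0
#' (and 4) name the metestrus/diestrus transition.
#'
#' @param x Numeric vector of stage numbers (any real; reduced modulo 4).
#' @param transitions Logical; report boundary values as transition labels.
#' @param tol Numeric tolerance for boundary detection.
#' @return Character vector of stage labels.
#' @export
number_to_stage <- function(x, transitions = FALSE, tol = 1e-9) {
  x <- x %% 4
  vapply(x, function(v) {
    if (transitions) {
      b <- round(v)
      if (abs(v - b) <= tol) return(transition_stages()[(b %% 4) + 1])
    }
    canonical_stages()[floor(v) + 1]
  }, character(1), USE.NAMES = FALSE)
}

#' Stages flanking a position on the stage-number circle
#'
#' Returns the transition label joining the two canonical stages whose
#' midpoints are nearest to `x` on the circle, i.e. the boundary label for the
#' stage boundary closest to `x`. Used to suggest a transition stage when the
#' network and cycle-timing classifications disagree at low confidence.
#'
#' @param x Scalar stage number (any real; reduced modulo 4).
#' @return A transition label such as `"proestrus/estrus"`.
#' @export
nearest_transition <- function(x) {
  b <- round(x %% 4) %% 4
  transition_stages()[b + 1]
}
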