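# Risk-level labels and their grouping into supervision areas.

#' Risk level vocabulary
#'
#' The eight ordinal contamination-risk grades, from high-safety (I) to highest
#' risk (VIII). Levels I-II form the safe area, level III the warning area and
#' levels IV-VIII the danger area.
#'
#' @return Character vector of the eight level names in order.
#' @export
risk_levels <- function() {
  c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")
}

#' Supervision area of each risk level
#'
#' @param level Character vector of levels (`"I"`..`"VIII"`).
#' @return Character vector in `{"safe", "warning", "danger"}`.
#' @export
risk_area <- function(level) {
  idx <- match(level, risk_levels())
  if (anyNA(idx)) {
    stop_dsn("unknown risk level(s): %s",
             paste(unique(level[is.na(idx)]), collapse = ", "))
  }
  c("safe", "safe", "warning", rep("danger", 5L))[idx]
}

#' Map risk levels to 0-based class indices and back
#'
#' `encode_labels` maps levels I..VIII to integers 0..7; `decode_labels` is its
#' inverse and also reports the supervision area of each level. The round trip
#' `decode_labels(encode_labels(x))$level` is the identity on valid input.
#'
#' @param level Character vector of levels.
#' @param index Integer vector of class indices in 0..7.
#' @return `encode_labels`: integer vector. `decode_labels`: data.frame with
#'   columns `level` (factor with all eight levels) and `area`.
#' @export
encode_labels <- function(level) {
  idx <- match(as.character(level), risk_levels()) - 1L
  if (anyNA(idx)) {
    stop_dsn("unknown risk level(s): %s",
             paste(unique(level[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' @rdname encode_labels
#' @export
decode_labels <- function(index) {
  index <- as.integer(index)
  if (any(index < 0L | index > 7L | is.na(index))) {
    stop_dsn("class indices must lie in 0..7")
  }
  lev <- risk_levels()[index + 1L]
  data.frame(level = factor(lev, levels = risk_levels()),
             area = risk_area(lev),
             stringsAsFactors = FALSE)
}

# Canonical label factor used throughout: levels I..VIII in order.
as_level_factor <- function(x) {
  f <- factor(as.character(x), levels = risk_levels())
  if (anyNA(f)) stop_dsn("labels contain values outside I..VIII")
  f
}
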