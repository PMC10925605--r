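#' Six-criterion behavioural arousal score
#'
#' Composite preclinical arousal scale for non-human primates, assessed
#' outside the scanner: exploration of the surrounding world (0-2),
#' spontaneous movements (0-2), response to shaking/prodding (0-2), toe-pinch
#' response (0-2), eye opening (0-2), and corneal reflex (0-1). The total is
#' the sum, ranging from 0 (deep anaesthesia, no responses) to 11 (full
#' wakefulness).
#'
#' @param exploration,spontaneous_movements,shaking_prodding,toe_pinch,eyes_opening
#'   Integer sub-scores in 0-2.
#' @param corneal_reflex Integer sub-score in 0-1.
#' @return Integer total in 0-11.
#' @examples
#' score_arousal(2, 2, 2, 2, 2, 1)  # wakefulness: 11
#' score_arousal(1, 1, 2, 2, 2, 1)  # 9
#' @export
score_arousal <- function(exploration, spontaneous_movements, shaking_prodding,
                          toe_pinch, eyes_opening, corneal_reflex) {
  sub <- c(exploration = exploration,
           spontaneous_movements = spontaneous_movements,
           shaking_prodding = shaking_prodding,
           toe_pinch = toe_pinch,
           eyes_opening = eyes_opening,
           corneal_reflex = corneal_reflex)
  maxes <- c(2L, 2L, 2L, 2L, 2L, 1L)
  for (i in seq_along(sub)) {
    s <- sub[[i]]
    if (length(s) != 1L || !is.finite(s) || s != round(s) ||
        s < 0 || s > maxes[i])
      stop("sub-score `", names(sub)[i], "` must be an integer in 0-",
           maxes[i], " (got ", format(s), ")")
  }
  as.integer(sum(sub))
}

#' Condition-to-arousal-score map
#'
#' Returns the study arousal score associated with an experimental condition
#' label: 11 for wakefulness; 0 for deep anaesthesia (ketamine, deep
#' propofol, deep sevoflurane) and for no-stimulation or ventro-lateral
#' thalamic DBS conditions; 3 for light sevoflurane and low-amplitude
#' centro-median thalamic DBS; 4 for light propofol; 9 for high-amplitude
#' centro-median DBS. Within a condition the score showed no variation
#' across animals, so the map is deterministic.
#'
#' @param condition Character vector of condition labels (see
#'   [arousal_score_map()] for the known labels).
#' @return Integer vector of arousal scores.
#' @examples
#' condition_arousal(c("awake", "ct_high", "vt_high"))
#' @export
condition_arousal <- function(condition) {
  map <- arousal_score_map()
  unknown <- setdiff(unique(condition), names(map))
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         "; known: ", paste(names(map), collapse = ", "))
  unname(vapply(as.character(condition), function(x) map[[x]], integer(1)))
}

#' @rdname condition_arousal
#' @return `arousal_score_map()` returns the full named integer map, read
#'   from the JSON resource shipped with the package.
#' @export
arousal_score_map <- function() {
  path <- system.file("extdata", "arousal_scores.json",
                      package = "eigenmarkers", mustWork = TRUE)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  vapply(m, as.integer, integer(1))
}

#' Read per-run arousal assessments from CSV
#'
#' Expects columns `condition` and `arousal_score` (plus any identifiers);
#' validates scores against 0-11.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_arousal_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("condition", "arousal_score") %in% names(df)))
    stop("arousal CSV needs `condition` and `arousal_score` columns")
  bad <- df$arousal_score < 0 | df$arousal_score > 11
  if (any(bad)) stop("arousal scores outside 0-11 at rows: ",
                     paste(which(bad), collapse = ", "))
  df
}
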