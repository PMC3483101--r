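# Three-level red/orange/green quality state with total order
# green < orange < red.  Stored as an integer (1/2/3) with class "rog".

ROG_LEVELS <- c("green", "orange", "red")

#' Create a ROG quality state
#'
#' The ROG state is the ordered three-level quality flag attached to every
#' validated entity: `"green"` (no problems found) < `"orange"` (potential
#' problems) < `"red"` (problems).
#'
#' @param level `"green"`, `"orange"` or `"red"` (vectorised).
#' @return an object of class `"rog"`.
#' @export
rog <- function(level = "green") {
  i <- match(level, ROG_LEVELS)
  if (anyNA(i)) stop("invalid ROG level: ", paste(level[is.na(i)], collapse = ", "))
  structure(i, class = "rog")
}

#' @export
print.rog <- function(x, ...) {
  cat("<ROG>", paste(ROG_LEVELS[unclass(x)], collapse = " "), "\n")
  invisible(x)
}

#' Worst (maximum) of a set of ROG states
#'
#' Empty input returns green, the default for unscored entities, so that
#' propagation over a childless entity is well defined.
#'
#' @param ... ROG states or level strings.
#' @return a single `"rog"` object.
#' @export
rog_max <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "rog"))
    xs <- xs[[1]]
  lv <- unlist(lapply(xs, function(x) {
    if (inherits(x, "rog")) unclass(x) else match(x, ROG_LEVELS)
  }))
  lv <- lv[!is.na(lv)]
  structure(if (length(lv)) max(lv) else 1L, class = "rog")
}

#' @export
as.character.rog <- function(x, ...) ROG_LEVELS[unclass(x)]

#' Compare ROG states
#'
#' @param e1,e2 `"rog"` objects or level strings.
#' @export
`>=.rog` <- function(e1, e2) .rog_int(e1) >= .rog_int(e2)
#' @export
`>.rog` <- function(e1, e2) .rog_int(e1) > .rog_int(e2)
#' @export
`==.rog` <- function(e1, e2) .rog_int(e1) == .rog_int(e2)

.rog_int <- function(x) if (inherits(x, "rog")) unclass(x) else match(x, ROG_LEVELS)
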