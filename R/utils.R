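# Internal helpers shared across modules.

ROLES <- c("substrate", "product", "side-substrate", "side-product",
           "modifier", "activator", "inhibitor", "undefined")

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Canonical numeric serialization: enough digits that coordinates survive a
# write/read cycle well below the 1e-6 pt round-trip tolerance, without
# printing noise digits.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("0")
    s <- sprintf("%.10g", v)
    s
  }, character(1))
}

parse_num <- function(s) as.numeric(s)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_finite_point <- function(p) {
  is.numeric(p) && length(p) == 2 && all(is.finite(p))
}

# bbox is c(x, y, w, h)
bbox_center <- function(b) c(b[1] + b[3] / 2, b[2] + b[4] / 2)

bbox_from_center <- function(center, w, h) c(center[1] - w / 2, center[2] - h / 2, w, h)

deg2rad <- function(d) d * pi / 180

# Angle convention used throughout arrangement: 0 degrees = up (negative y in
# the y-down screen frame), positive clockwise.
angle_to_unit <- function(deg) {
  r <- deg2rad(deg)
  c(sin(r), -cos(r))
}
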