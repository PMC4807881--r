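# internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so the generators are reproducible without clobbering the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Otsu threshold of an intensity sample
#'
#' Rescales intensities to \[0, 1\], delegates to [EBImage::otsu()] and maps
#' the threshold back to the original scale.
#'
#' @param x numeric vector, matrix or array of intensities.
#' @param levels number of histogram levels.
#' @return threshold on the scale of `x`.
#' @keywords internal
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  r <- range(v)
  if (!is.finite(r[1]) || r[1] == r[2])
    stop_hq("empty_scene", "cannot threshold a constant image")
  scaled <- (v - r[1]) / (r[2] - r[1])
  th <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1L)),
                      range = c(0, 1), levels = levels)
  r[1] + th * (r[2] - r[1])
}

# classed conditions so callers can distinguish failure modes
stop_hq <- function(class, msg, ...) {
  stop(structure(class = c(paste0("hq_", class, "_error"), "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_hq("domain", "%s must be positive and finite", what)
  invisible(x)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))
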