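#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's global
#' RNG state, so seeded package functions have no RNG side effects.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the expression's value.
#' @keywords internal
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Write a reproducibility log for a run
#'
#' Records the configuration hash, seed, package version and timestamp of
#' a run as JSON next to its outputs.
#'
#' @param dir output directory (created if needed).
#' @param config the configuration object used.
#' @param seed the seed used.
#' @param extra optional named list of additional fields.
#' @return the log file path, invisibly.
#' @export
writeRunLog <- function(dir, config, seed, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(list(configHash = rlang::hash(config), seed = seed,
                package = "WSLTiles",
                version = as.character(utils::packageVersion("WSLTiles")),
                rVersion = R.version.string,
                timestamp = format(Sys.time(), tz = "UTC")),
           extra)
  path <- file.path(dir, "run-log.json")
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
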