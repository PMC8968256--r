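#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Stage report for a filtering step
#'
#' Records site and accession counts entering and leaving a pipeline stage
#' together with the parameters that governed it.
#'
#' @param stage stage name.
#' @param sites_in,sites_out,accessions_in,accessions_out integer counts.
#' @param parameters named list of stage parameters.
#' @return A `filter_report` object.
#' @export
filter_report <- function(stage, sites_in, sites_out,
                          accessions_in, accessions_out,
                          parameters = list()) {
  stopifnot(sites_out <= sites_in, accessions_out <= accessions_in)
  structure(
    list(stage = stage,
         sites_in = as.integer(sites_in), sites_out = as.integer(sites_out),
         accessions_in = as.integer(accessions_in),
         accessions_out = as.integer(accessions_out),
         parameters = parameters),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  par_str <- if (length(x$parameters)) {
    paste(names(x$parameters), unlist(x$parameters), sep = "=", collapse = ", ")
  } else "-"
  cat(sprintf("[%s] sites %d -> %d | accessions %d -> %d | %s\n",
              x$stage, x$sites_in, x$sites_out,
              x$accessions_in, x$accessions_out, par_str))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
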