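#' Read and write particle-state snapshots
#'
#' A snapshot stores one record per agent with columns
#' `(id, x, y, theta, sir)` plus a metadata header carrying the model and
#' epidemic parameters and the elapsed time as a JSON block. Two formats are
#' supported: plain CSV with `#`-prefixed header lines, and an RDS binary
#' container holding the same content.
#'
#' @param state a [particle_state()].
#' @param path file path.
#' @param params optional [abp_params()] stored in the header.
#' @param ep optional [sir_params()] stored in the header.
#' @param format `"csv"` or `"rds"` (guessed from the extension by default).
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   returns a list with `state`, `params`, `ep`.
#' @export
write_snapshot <- function(state, path, params = NULL, ep = NULL,
                           format = NULL) {
  format <- format %||% (if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv")
  meta <- list(L = state_L(state), time = attr(state, "time") %||% 0)
  if (!is.null(params)) meta$params <- unclass(params)
  if (!is.null(ep)) meta$ep <- unclass(ep)
  df <- as.data.frame(state)
  if (!"sir" %in% names(df)) df$sir <- "S"
  df <- df[, c("id", "x", "y", "theta", "sir")]
  df$sir <- as.character(df$sir)
  if (format == "rds") {
    saveRDS(list(meta = meta, agents = df), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# swarmsir-snapshot ",
                      jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
               con)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv")
  if (format == "rds") {
    obj <- readRDS(path)
    meta <- obj$meta
    df <- obj$agents
  } else {
    first <- readLines(path, n = 1)
    if (!startsWith(first, "# swarmsir-snapshot"))
      stop("not a swarmsir snapshot file", call. = FALSE)
    meta <- jsonlite::fromJSON(sub("^# swarmsir-snapshot ", "", first))
    df <- read.csv(path, comment.char = "#")
  }
  st <- particle_state(df, L = meta$L, time = meta$time)
  params <- if (!is.null(meta$params)) do.call(abp_params, meta$params[
    c("N", "v0", "r_int", "sigma", "tau", "L", "dt")])
  ep <- if (!is.null(meta$ep)) sir_params(meta$ep$beta_b, meta$ep$gamma)
  list(state = st, params = params, ep = ep)
}

#' Write an epidemic/observable time series to CSV
#'
#' The header carries the package version and, when given, the full model and
#' epidemic configuration as a JSON comment line, so a series file is
#' self-describing. Read back with `read.csv(path, comment.char = "#")`.
#'
#' @param series a tibble as produced by [run_outbreak()] or
#'   [simulate_motion()] (`t, n_s, n_i, n_r, phi, lambda`).
#' @param path file path.
#' @param params optional [abp_params()] recorded in the header.
#' @param ep optional [sir_params()] recorded in the header.
#' @export
write_series <- function(series, path, params = NULL, ep = NULL) {
  meta <- list(swarmsir = as.character(utils::packageVersion("swarmsir")))
  if (!is.null(params)) meta$params <- unclass(params)
  if (!is.null(ep)) meta$ep <- unclass(ep)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# swarmsir-series ",
                    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  write.csv(as.data.frame(series), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a density grid as plain matrix text
#'
#' Stores the smoothed total density as whitespace-separated matrix rows,
#' preceded by `#` header lines holding the bin edges and smoothing width as
#' JSON, followed by the raw infected counts as a second block.
#'
#' @param grid a [render_density_grid()] result.
#' @param path file path.
#' @export
write_density_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(n_bins = grid$n_bins, L = grid$L,
               smooth_width = grid$smooth_width, edges = grid$edges)
  writeLines(paste0("# swarmsir-density ",
                    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  writeLines("# total_smooth", con)
  utils::write.table(grid$total_smooth, con, row.names = FALSE,
                     col.names = FALSE)
  writeLines("# infected", con)
  utils::write.table(grid$infected, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
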